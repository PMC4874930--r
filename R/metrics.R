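# Segmentation agreement metrics and summary arithmetic.

#' Dice overlap coefficient
#'
#' \code{D = 2|A n B| / (|A| + |B|)}: 1 for identical non-empty masks,
#' 0 for disjoint ones. Nonzero labels are treated as the mask.
#'
#' @param a,b \code{\link{label_volume}}s (or logical arrays) on the same
#'   grid.
#' @return Dice coefficient in \code{[0, 1]}.
#' @export
dice <- function(a, b) {
  ma <- if (inherits(a, "label_volume")) a$data != 0L else as.array(a) != 0
  mb <- if (inherits(b, "label_volume")) b$data != 0L else as.array(b) != 0
  if (inherits(a, "label_volume") && inherits(b, "label_volume") &&
      !same_grid(a, b))
    stop("dice: grid mismatch between segmentations")
  if (!identical(dim(ma), dim(mb)))
    stop("dice: grid mismatch between segmentations")
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) stop("dice: both masks are empty")
  2 * sum(ma & mb) / (na + nb)
}

#' Relative improvement in percent
#'
#' \code{100 * (new - old) / old}; for quantities where smaller is better
#' (e.g. segmentation time), use \code{\link{relative_reduction}}.
#'
#' @param new,old the two values; \code{old} must be nonzero.
#' @return percent change.
#' @export
relative_improvement <- function(new, old) {
  if (old == 0) stop("relative_improvement: old value is zero")
  100 * (new - old) / old
}

#' @rdname relative_improvement
#' @export
relative_reduction <- function(new, old) {
  if (old == 0) stop("relative_reduction: old value is zero")
  100 * (old - new) / old
}

#' Majority-vote fusion of segmentations
#'
#' Fuses repeated segmentations of one structure into a consensus mask: a
#' voxel is kept when at least half of the inputs label it. This is a
#' simple substitute for probabilistic label fusion (STAPLE-style
#' expectation maximization), adequate for phantom experiments.
#'
#' @param segmentations list of \code{\link{label_volume}}s on one grid.
#' @param label output label (default 1).
#' @return a consensus \code{\link{label_volume}}.
#' @export
majority_vote <- function(segmentations, label = 1L) {
  stopifnot(length(segmentations) >= 1)
  ref <- segmentations[[1]]
  votes <- array(0L, dim(ref$data))
  for (s in segmentations) {
    if (!same_grid(ref, s)) stop("majority_vote: grid mismatch")
    votes <- votes + (s$data != 0L)
  }
  keep <- votes >= length(segmentations) / 2
  label_volume(array(as.integer(keep) * as.integer(label), dim(ref$data)),
               ref$spacing, ref$origin)
}
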