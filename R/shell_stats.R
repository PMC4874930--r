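# Radial shell statistics: recentering, shell median profile, peak/knee
# landmark detection and the adaptive threshold.
#
# A shell is the set of all nodes at the same level across columns. Its
# median uptake as a function of level is a robust radial profile of the
# lesion; the "peak" pe is the hottest shell and the "knee" kn is the
# uptake where the profile levels off into background. Level indices are
# 1-based in R; the innermost and outermost shells are excluded from all
# landmark scans because they represent extreme, uninteresting solutions.

#' Recenter a seed point to the local uptake maximum
#'
#' Moves the user point to the center of the maximum-uptake voxel whose
#' center lies within \code{radius} mm. Ties are broken by smallest
#' distance to the user point, then by lexicographic voxel index, so the
#' result is deterministic. Recentering should be disabled for necrotic
#' lesions (cold cores), where the local maximum is not representative.
#'
#' @param vol a \code{\link{scalar_volume}}.
#' @param user_point world mm coordinate inside the volume.
#' @param radius search radius in mm (default 7).
#' @param enabled if \code{FALSE}, returns \code{user_point} unchanged.
#' @return world mm coordinate of the chosen center.
#' @export
recenter <- function(vol, user_point, radius = 7.0, enabled = TRUE) {
  user_point <- as.numeric(user_point)
  if (!enabled) return(user_point)
  dm <- dim(vol$data)
  # candidate voxel index window covering the search ball
  lo <- pmax(ceiling((user_point - radius - vol$origin) / vol$spacing) + 1, 1)
  hi <- pmin(floor((user_point + radius - vol$origin) / vol$spacing) + 1, dm)
  if (any(lo > hi))
    stop("recenter: no voxel center within ", radius, " mm of the seed point")
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  grid <- as.matrix(expand.grid(ix = ix, iy = iy, iz = iz))
  centers <- sweep((grid - 1) * rep(vol$spacing, each = nrow(grid)), 2,
                   vol$origin, "+")
  d2 <- rowSums(sweep(centers, 2, user_point, "-")^2)
  keep <- d2 <= radius^2
  if (!any(keep))
    stop("recenter: no voxel center within ", radius, " mm of the seed point")
  grid <- grid[keep, , drop = FALSE]
  centers <- centers[keep, , drop = FALSE]
  d2 <- d2[keep]
  vals <- vol$data[grid]
  # max uptake; ties -> nearest, then lexicographic (x, then y, then z)
  ord <- order(-vals, d2, grid[, 1], grid[, 2], grid[, 3])
  as.numeric(centers[ord[1], ])
}

#' Shell median profile and central-difference gradient
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param vol a \code{\link{scalar_volume}}, or a precomputed
#'   \code{n_node x n_column} uptake matrix.
#' @return an object of class \code{shell_profile} with fields
#'   \code{up_shell} (length n_node shell medians), \code{grad}
#'   (central differences, \code{NA} at both ends), \code{n_node},
#'   \code{gap}.
#' @export
shell_profile <- function(graph, vol) {
  up <- if (is.matrix(vol)) vol else graph_uptake(graph, vol)
  stopifnot(nrow(up) == graph$n_node)
  med <- apply(up, 1, median)
  n <- graph$n_node
  grad <- rep(NA_real_, n)
  grad[2:(n - 1)] <- med[3:n] - med[1:(n - 2)]
  structure(list(up_shell = med, grad = grad, n_node = n, gap = graph$gap),
            class = "shell_profile")
}

#' Locate peak, steepest-descent, leveling-off and knee landmarks
#'
#' The steepest-descent level \code{j_low} minimizes the center-bias
#' weighted gradient \code{((n_node - lv) / n_node) * grad[lv]}; the
#' weight damps rare cases where unrelated outside objects appear in the
#' profile. The modified gradient is a running maximum beyond
#' \code{j_low} (never decreasing there); \code{j_hi} is the first level
#' at which it reaches \code{min(0, max(grad_mod))}, i.e. where the
#' profile stops descending, and the knee interpolates 75\% of the way
#' from the \code{j_low} gradient to the \code{j_hi} gradient. All
#' argmin/argmax ties take the smallest index.
#'
#' @param profile a \code{\link{shell_profile}}.
#' @return the profile with fields \code{grad_mod}, \code{pe},
#'   \code{j_low}, \code{j_hi}, \code{j_knee} (1-based levels) and
#'   \code{kn} added.
#' @export
find_landmarks <- function(profile) {
  stopifnot(inherits(profile, "shell_profile"))
  n <- profile$n_node
  med <- profile$up_shell
  grad <- profile$grad
  rng <- 2:(n - 1)                      # innermost/outermost shells excluded
  if (all(abs(grad[rng]) < 1e-12))
    stop("degenerate shell profile: no uptake gradient around the seed ",
         "(seed likely in homogeneous background)")
  pe <- max(med[rng])
  weight <- (n - rng) / n               # linear center bias
  j_low <- rng[which.min(weight * grad[rng])]
  grad_mod <- rep(NA_real_, n)
  grad_mod[2:j_low] <- grad[2:j_low]
  if (j_low < n - 1) {
    for (lv in (j_low + 1):(n - 1))
      grad_mod[lv] <- max(grad[lv], grad_mod[lv - 1])
  }
  target <- min(0, max(grad_mod[j_low:(n - 1)]))
  cand <- j_low:(n - 1)
  j_hi <- cand[which(grad_mod[cand] >= target - 1e-15)[1]]
  knee_target <- 0.75 * grad_mod[j_hi] + 0.25 * grad_mod[j_low]
  cand <- j_low:j_hi
  j_knee <- cand[which.min(abs(grad_mod[cand] - knee_target))]
  kn <- med[j_knee]
  profile$grad_mod <- grad_mod
  profile$pe <- pe
  profile$j_low <- j_low
  profile$j_hi <- j_hi
  profile$j_knee <- j_knee
  profile$kn <- kn
  profile
}

#' @export
print.shell_profile <- function(x, ...) {
  cat(sprintf("shell_profile: %d levels, gap %g mm\n", x$n_node, x$gap))
  if (!is.null(x$pe))
    cat(sprintf("  pe = %.4g, kn = %.4g, j_low = %d, j_knee = %d, j_hi = %d\n",
                x$pe, x$kn, x$j_low, x$j_knee, x$j_hi))
  invisible(x)
}

#' Compute the boundary uptake threshold
#'
#' The adaptive rule sets the threshold fraction from the peak-to-knee
#' contrast \code{gamma = pe / kn}:
#' \code{Th_pct = 0.8 * exp(-0.15 * gamma^1.5)}, so a contrast of 2 gives
#' roughly a 50\% threshold, high-contrast lesions get relatively lower
#' thresholds and low-contrast lesions moderately higher ones —
#' mimicking how radiation oncologists trace boundaries. Fixed 40\% / 50\%
#' variants use the same \code{Th = kn + Th_pct * (pe - kn)} scale.
#'
#' @param pe peak shell uptake.
#' @param kn knee uptake; values \code{<= 0} are clamped to \code{1e-6} to
#'   keep the contrast finite on noise-free synthetic backgrounds.
#' @param mode \code{"adaptive"} (default), \code{"fixed40"} or
#'   \code{"fixed50"}.
#' @return list with \code{Th}, \code{Th_pct} and \code{gamma}.
#' @export
compute_threshold <- function(pe, kn, mode = c("adaptive", "fixed40",
                                               "fixed50")) {
  mode <- match.arg(mode)
  if (pe < kn) stop("compute_threshold: pe < kn")
  kn <- max(kn, 1e-6)
  pe <- max(pe, kn)
  gamma <- pe / kn
  th_pct <- switch(mode,
                   adaptive = 0.8 * exp(-0.15 * gamma^1.5),
                   fixed40 = 0.4,
                   fixed50 = 0.5)
  list(Th = kn + th_pct * (pe - kn), Th_pct = th_pct, gamma = gamma)
}
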