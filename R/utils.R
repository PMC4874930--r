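# Array utilities: separable Gaussian smoothing, binary morphology with the
# 6-connected cross element, and 6-connected flood fill. Written as shifted
# whole-array operations so they stay vectorized.

# shift a 3-D array by `by` voxels along `axis`, replicating the edge plane
shift_array <- function(a, axis, by, pad = c("edge", "zero")) {
  pad <- match.arg(pad)
  if (by == 0) return(a)
  dm <- dim(a)
  n <- dm[axis]
  src <- seq_len(n) - by
  if (pad == "edge") {
    src <- pmin(pmax(src, 1L), n)
    idx <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
    idx[[axis]] <- src
    return(a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  out <- array(0, dm)
  ok <- src >= 1 & src <= n
  idx_to <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
  idx_from <- idx_to
  idx_to[[axis]] <- which(ok)
  idx_from[[axis]] <- src[ok]
  out[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
    a[idx_from[[1]], idx_from[[2]], idx_from[[3]], drop = FALSE]
  out
}

# separable Gaussian smoothing of a 3-D array; sigma in voxels per axis,
# edge-replicated so a uniform background stays uniform at the borders
gaussian_smooth_array <- function(a, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    rad <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-rad:rad) / s)^2)
    k <- k / sum(k)
    acc <- array(0, dim(a))
    for (t in -rad:rad)
      acc <- acc + k[t + rad + 1] * shift_array(a, axis, t, pad = "edge")
    a <- acc
  }
  a
}

#' Gaussian point-spread blur of a scalar volume
#'
#' Separable Gaussian convolution with the given full width at half
#' maximum (sigma = FWHM / 2.3548), emulating PET reconstruction
#' smoothing. Edges are replicated, so a uniform background is preserved
#' at the volume borders.
#'
#' @param vol a \code{\link{scalar_volume}}.
#' @param fwhm_mm full width at half maximum in mm (scalar or per-axis).
#' @return the blurred \code{scalar_volume}.
#' @export
blur_volume <- function(vol, fwhm_mm) {
  fwhm_mm <- rep(as.numeric(fwhm_mm), length.out = 3)
  sigma_vox <- (fwhm_mm / 2.3548) / vol$spacing
  scalar_volume(gaussian_smooth_array(vol$data, sigma_vox), vol$spacing,
                vol$origin)
}

# 6-connected binary dilation / erosion (3x3x3 cross element)
dilate6 <- function(mask) {
  out <- mask
  for (axis in 1:3) for (by in c(-1L, 1L))
    out <- out | shift_array(mask, axis, by, pad = "zero")
  out
}

erode6 <- function(mask) {
  out <- mask
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    shifted <- shift_array(mask, axis, by, pad = "zero")
    out <- out & shifted
  }
  out
}

# 6-connected component of `mask` containing seed index (1-based triple)
flood6 <- function(mask, seed_idx) {
  comp <- array(FALSE, dim(mask))
  if (!mask[seed_idx[1], seed_idx[2], seed_idx[3]])
    return(comp)
  comp[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  repeat {
    grown <- dilate6(comp) & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

# local maxima (26-neighborhood, strict or plateau-max with tie by index)
# within a mask; returns logical array
local_maxima26 <- function(a, mask) {
  is_max <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- shift_array(a, 1, dx, pad = "zero")
    nb <- shift_array(nb, 2, dy, pad = "zero")
    nb <- shift_array(nb, 3, dz, pad = "zero")
    is_max <- is_max & (a >= nb)
  }
  is_max & mask
}
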