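# Synthetic PET lesion phantoms.
#
# Ground-truthed scenes standing in for clinical scans: spherical lesions
# of configurable radius and uptake on a uniform background, blurred with
# a Gaussian point-spread function (FWHM 5-7 mm, the smoothing applied by
# typical clinical reconstructions), with optional additive Gaussian
# noise. Ground truth is the pre-blur sphere mask, one label per lesion.

#' Specify a synthetic PET phantom
#'
#' @param shape voxel counts per axis (default 96^3).
#' @param spacing voxel size in mm (default 2 mm isotropic).
#' @param background background uptake (default 1.0).
#' @param lesions list of lesions, each a list with \code{center} (mm),
#'   \code{radius} (mm), \code{peak} (uptake) and optional
#'   \code{core_radius} / \code{core_uptake} for necrotic cold cores.
#' @param psf_fwhm_mm Gaussian blur FWHM in mm (default 7; 0 disables).
#' @param noise_sigma additive Gaussian noise standard deviation
#'   (default 0).
#' @param seed RNG seed for the noise (default 1).
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L), spacing = c(2, 2, 2),
                         background = 1.0, lesions = list(),
                         psf_fwhm_mm = 7.0, noise_sigma = 0.0, seed = 1L) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  stopifnot(all(shape >= 2), all(spacing > 0), background >= 0,
            psf_fwhm_mm >= 0, noise_sigma >= 0)
  for (l in lesions) {
    stopifnot(!is.null(l$center), !is.null(l$radius), !is.null(l$peak))
    if (l$radius <= 0) stop("phantom_spec: lesion radius must be positive")
    if (l$peak <= background)
      stop("phantom_spec: lesion peak must exceed background")
  }
  structure(list(shape = as.integer(shape), spacing = spacing,
                 background = background, lesions = lesions,
                 psf_fwhm_mm = psf_fwhm_mm, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom volume and its ground truth
#'
#' Paints each lesion as a binary sphere at peak uptake (optionally with a
#' cold core) over the uniform background, blurs with the Gaussian PSF and
#' adds seeded noise. The ground truth is the pre-blur sphere mask, one
#' label per lesion in list order; overlapping spheres with distinct
#' labels are refused because the truth would be ambiguous.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{volume} (\code{scalar_volume}) and \code{truth}
#'   (\code{label_volume}).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$shape
  vol <- array(spec$background, dm)
  truth <- array(0L, dm)
  cx <- (seq_len(dm[1]) - 1) * spec$spacing[1]
  cy <- (seq_len(dm[2]) - 1) * spec$spacing[2]
  cz <- (seq_len(dm[3]) - 1) * spec$spacing[3]
  for (k in seq_along(spec$lesions)) {
    l <- spec$lesions[[k]]
    d2 <- outer(outer((cx - l$center[1])^2, (cy - l$center[2])^2, "+"),
                (cz - l$center[3])^2, "+")
    mask <- d2 <= l$radius^2
    if (any(truth[mask] != 0L))
      stop("generate_phantom: ground-truth lesions ", k, " and ",
           max(truth[mask]), " overlap; ambiguous truth")
    vol[mask] <- l$peak
    if (!is.null(l$core_radius)) {
      core <- d2 <= l$core_radius^2
      vol[core] <- if (is.null(l$core_uptake)) spec$background else
        l$core_uptake
    }
    truth[mask] <- k
  }
  v <- scalar_volume(vol, spec$spacing)
  if (spec$psf_fwhm_mm > 0) v <- blur_volume(v, spec$psf_fwhm_mm)
  if (spec$noise_sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    v$data <- v$data + array(rnorm(prod(dm), sd = spec$noise_sigma), dm)
  }
  list(volume = v, truth = label_volume(truth, spec$spacing))
}

#' Two-lesion scene for splitting and label-avoidance experiments
#'
#' Two equal spheres (6 mm radius) centered on the x axis, separated by
#' the given center-to-center distance. Small separations with wide PSFs
#' produce a single merged uptake region; large separations with narrow
#' PSFs keep the lesions distinct.
#'
#' @param separation_mm center-to-center distance in mm.
#' @param contrast_ratio lesion peak over background (default 4).
#' @param seed RNG seed for noise.
#' @param fwhm_mm PSF width (default 7 mm).
#' @param radius_mm lesion radius (default 6 mm).
#' @param noise_sigma additive noise sd (default 0).
#' @return list with \code{volume}, \code{truth} and the two lesion
#'   \code{centers} (2 x 3 matrix, mm).
#' @export
adjacent_pair_scene <- function(separation_mm, contrast_ratio = 4, seed = 1L,
                                fwhm_mm = 7.0, radius_mm = 6.0,
                                noise_sigma = 0.0) {
  stopifnot(separation_mm > 0)
  if (separation_mm <= 2 * radius_mm)
    stop("adjacent_pair_scene: spheres of radius ", radius_mm,
         " mm overlap at separation ", separation_mm, " mm")
  shape <- c(96L, 64L, 64L)
  spacing <- c(2, 2, 2)
  # snap the scene midpoint to a voxel center so recentering stays put
  mid <- round((shape - 1) / 2) * spacing
  c1 <- c(mid[1] - separation_mm / 2, mid[2], mid[3])
  c2 <- c(mid[1] + separation_mm / 2, mid[2], mid[3])
  spec <- phantom_spec(
    shape = shape, spacing = spacing, background = 1.0,
    lesions = list(
      list(center = c1, radius = radius_mm, peak = contrast_ratio),
      list(center = c2, radius = radius_mm, peak = contrast_ratio)),
    psf_fwhm_mm = fwhm_mm, noise_sigma = noise_sigma, seed = seed)
  out <- generate_phantom(spec)
  out$centers <- rbind(c1, c2)
  out
}
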