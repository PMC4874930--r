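test_that("ground truth matches the lattice enumeration of the sphere", {
  spec <- phantom_spec(shape = c(41L, 41L, 41L), spacing = c(1, 1, 1),
                       lesions = list(list(center = c(20, 20, 20),
                                           radius = 10, peak = 4)),
                       psf_fwhm_mm = 0, noise_sigma = 0)
  out <- generate_phantom(spec)
  xs <- 0:40
  d2 <- outer(outer((xs - 20)^2, (xs - 20)^2, "+"), (xs - 20)^2, "+")
  expect_equal(sum(out$truth$data != 0L), sum(d2 <= 100))
  # unblurred voxels carry exactly the binary uptake
  expect_setequal(unique(c(out$volume$data)), c(1, 4))
})

test_that("phantoms are reproducible for a fixed seed", {
  spec <- phantom_spec(shape = c(32L, 32L, 32L),
                       lesions = list(list(center = c(31, 31, 31),
                                           radius = 8, peak = 5)),
                       psf_fwhm_mm = 6, noise_sigma = 0.2, seed = 99L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$data, b$truth$data)
  spec2 <- spec; spec2$seed <- 100L
  expect_false(identical(generate_phantom(spec2)$volume$data,
                         a$volume$data))
})

test_that("the point-spread blur softens the rim monotonically", {
  ph <- small_sphere_phantom()       # radius 8, peak 4, FWHM 5
  ctr <- sample_uptake(ph$volume, c(62, 62, 62))
  expect_gt(ctr, 1); expect_lte(ctr, 4)
  # radial profile along +x decreases across the rim
  rs <- seq(2, 20, by = 2)
  prof <- sample_uptake(ph$volume, cbind(62 + rs, 62, 62))
  expect_true(all(diff(prof) < 1e-9))
  expect_gt(prof[1], 3.5)            # deep interior near peak
  expect_lt(prof[length(prof)], 1.1) # far field near background
  # independent check of the blur at the center: direct convolution of
  # the binary sphere with the separable Gaussian kernel
  sigma <- 5 / 2.3548 / 2            # voxel units (2 mm spacing)
  rad <- max(1, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-rad:rad) / sigma)^2); k <- k / sum(k)
  off <- as.matrix(expand.grid(dx = -rad:rad, dy = -rad:rad, dz = -rad:rad))
  w <- k[off[, 1] + rad + 1] * k[off[, 2] + rad + 1] * k[off[, 3] + rad + 1]
  inside <- rowSums((off * 2)^2) <= 64      # offsets from the center, mm
  expect_equal(ctr, sum(w * ifelse(inside, 4, 1)), tolerance = 1e-9)
})

test_that("overlapping distinct-label lesions are refused", {
  spec <- phantom_spec(lesions = list(
    list(center = c(90, 90, 90), radius = 10, peak = 4),
    list(center = c(100, 90, 90), radius = 10, peak = 4)))
  expect_error(generate_phantom(spec), "overlap")
})

test_that("cold cores stay cold and necrotic truth covers the rim", {
  spec <- phantom_spec(shape = c(48L, 48L, 48L),
                       lesions = list(list(center = c(46, 46, 46),
                                           radius = 12, peak = 5,
                                           core_radius = 6)),
                       psf_fwhm_mm = 0, noise_sigma = 0)
  out <- generate_phantom(spec)
  expect_equal(sample_uptake(out$volume, c(46, 46, 46)), 1)  # background
  expect_equal(sample_uptake(out$volume, c(46 + 9, 46, 46)), 5)
  # truth includes the cold core (whole lesion extent)
  ci <- petoss:::voxel_index(out$truth, c(46, 46, 46))[1, ]
  expect_equal(out$truth$data[ci[1], ci[2], ci[3]], 1L)
})

test_that("pair scenes merge or separate depending on blur and distance", {
  far <- adjacent_pair_scene(25, contrast_ratio = 4, fwhm_mm = 5)
  near <- adjacent_pair_scene(14, contrast_ratio = 4, fwhm_mm = 7)
  count_components <- function(vol, thr) {
    mask <- vol$data >= thr
    seen <- array(FALSE, dim(mask))
    ncomp <- 0
    while (any(mask & !seen)) {
      seed <- which(mask & !seen, arr.ind = TRUE)[1, ]
      seen <- seen | petoss:::flood6(mask, seed)
      ncomp <- ncomp + 1
    }
    ncomp
  }
  # at a threshold near the adaptive working point the close pair fuses
  thr <- 1.8
  expect_equal(count_components(far$volume, thr), 2)
  expect_equal(count_components(near$volume, thr), 1)
  # reproducible
  expect_identical(adjacent_pair_scene(25, seed = 3,
                                       noise_sigma = 0.05)$volume$data,
                   adjacent_pair_scene(25, seed = 3,
                                       noise_sigma = 0.05)$volume$data)
  expect_error(adjacent_pair_scene(8, radius_mm = 6), "overlap")
})
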