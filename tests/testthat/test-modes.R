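test_that("label avoidance rejects columns beyond first foreign contact", {
  g <- build_graph(build_sphere_mesh(1), c(20, 20, 20), r = 15, gap = 1)
  arr <- array(0L, c(21, 21, 21))
  lab <- label_volume(arr, c(2, 2, 2))
  # no foreign labels anywhere: zero term
  expect_true(all(label_avoidance_costs(g, lab, own_label = 1L) == 0))
  # a foreign slab met by the +x column at 31 mm
  arr2 <- array(0L, c(21, 21, 21))
  arr2[17:21, , ] <- 2L                     # x >= 32 mm
  lab2 <- label_volume(arr2, c(2, 2, 2))
  lac <- label_avoidance_costs(g, lab2, own_label = 1L)
  # column 1 points along +x: first contact where node x >= 31 (voxel 17
  # spans 31..33 mm), i.e. level 11, rejected from there outward
  expect_true(all(lac[11:15, 1] == 6))
  expect_true(all(lac[1:10, 1] == 0))
  # own label is never avoided
  expect_true(all(label_avoidance_costs(g, lab2, own_label = 2L) == 0))
  # rejection is monotone outward on every column
  expect_true(all(apply(lac, 2, function(x) all(diff(x) >= 0))))
})

test_that("avoided segmentations never overlap existing labels", {
  sc <- fixture("pair18", function()
    adjacent_pair_scene(18, contrast_ratio = 4, fwhm_mm = 5))
  cfg0 <- segmentation_config(r = 40, mesh_level = 3L)
  resB <- segment_lesion(sc$volume, sc$centers[2, ], config = cfg0,
                         label = 2L)
  cfgA <- segmentation_config(r = 40, mesh_level = 3L,
                              avoid_labels = resB$labels)
  resA <- segment_lesion(sc$volume, sc$centers[1, ], config = cfgA)
  expect_equal(sum(resA$labels$data != 0L & resB$labels$data != 0L), 0)
  expect_gt(resA$report$voxel_count, 0)
})

test_that("watershed basins separate the two lesions of a pair scene", {
  sc <- fixture("pair14", function()
    adjacent_pair_scene(14, contrast_ratio = 4, fwhm_mm = 7))
  b <- watershed_basins(sc$volume, Th = 1.8, smooth_fwhm_mm = 3)
  ia <- voxel_index(sc$volume, sc$centers[1, ])[1, ]
  ib <- voxel_index(sc$volume, sc$centers[2, ])[1, ]
  ba <- b[ia[1], ia[2], ia[3]]
  bb <- b[ib[1], ib[2], ib[3]]
  expect_gt(ba, 0); expect_gt(bb, 0)
  expect_true(ba != bb)
  # single isolated sphere: one basin, zero splitting term
  ph <- small_sphere_phantom()
  b1 <- watershed_basins(ph$volume, Th = 1.8, smooth_fwhm_mm = 3)
  expect_equal(length(setdiff(unique(c(b1)), 0L)), 1)
  g <- build_graph(build_sphere_mesh(2), c(62, 62, 62), r = 30, gap = 1)
  expect_true(all(splitting_costs(g, ph$volume, Th = 1.8,
                                  center = c(62, 62, 62)) == 0))
})

test_that("splitting penalizes nodes landing in the neighbor's basin", {
  sc <- fixture("pair14", function()
    adjacent_pair_scene(14, contrast_ratio = 4, fwhm_mm = 7))
  g <- build_graph(build_sphere_mesh(3), c(88, 64, 64), r = 40, gap = 1)
  Th <- 1.8
  pen <- splitting_costs(g, sc$volume, Th, center = c(88, 64, 64))
  pos <- node_positions(g)
  d2b <- rowSums(sweep(pos, 2, sc$centers[2, ], "-")^2)
  up <- sample_uptake(sc$volume, pos)
  in_core_b <- d2b <= 4^2 & up >= Th
  expect_true(any(in_core_b))
  expect_true(all(pen[matrix(in_core_b, g$n_node, g$n_column)] > 0))
  # seed below the threshold is refused
  expect_error(splitting_costs(g, sc$volume, Th = 10,
                               center = c(88, 64, 64)), "below the threshold")
})

test_that("necrotic mode keeps hollow lesions from collapsing", {
  ph <- fixture("hollow", function() {
    spec <- phantom_spec(shape = c(64L, 64L, 64L), spacing = c(2, 2, 2),
                         lesions = list(list(center = c(62, 62, 62),
                                             radius = 14, peak = 4,
                                             core_radius = 7)),
                         psf_fwhm_mm = 5, noise_sigma = 0)
    generate_phantom(spec)
  })
  cfg <- necrotic_config(segmentation_config(r = 30, mesh_level = 2L))
  expect_false(cfg$recenter)
  expect_false(cfg$use_r2)
  res <- segment_lesion(ph$volume, c(62, 62, 62), config = cfg)
  # seed stays at the cold core (no recentering)
  expect_equal(res$report$center, c(62, 62, 62))
  # the segmentation reaches past the hot rim rather than collapsing
  radii <- res$session$solution$radii_mm
  expect_gte(mean(radii), 14 - 3)
  # innermost-node rejection is still active
  expect_true(all(res$session$reject[1:3, ] == 6))
  expect_true(all(res$session$reject[4:res$session$graph$n_node, ] == 0))
})
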