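test_that("recentering finds the hottest voxel with deterministic ties", {
  arr <- array(1, c(21, 21, 21))
  arr[13, 11, 11] <- 9                      # 2 mm away (x +2)
  v <- scalar_volume(arr, c(1, 1, 1))
  seed <- c(10, 10, 10)
  expect_equal(recenter(v, seed), c(12, 10, 10))
  # disabled -> verbatim
  expect_identical(recenter(v, seed, enabled = FALSE), seed)
  # equal maxima at 2 mm and 5 mm -> nearest wins (brute-force scan agrees)
  arr2 <- array(1, c(21, 21, 21))
  arr2[13, 11, 11] <- 9                     # 2 mm
  arr2[11, 16, 11] <- 9                     # 5 mm
  v2 <- scalar_volume(arr2, c(1, 1, 1))
  expect_equal(recenter(v2, seed), c(12, 10, 10))
  # outside any voxel center -> error
  expect_error(recenter(v, c(-50, -50, -50), radius = 2), "7|within|mm")
})

test_that("shell medians and gradients follow their definitions", {
  g <- build_graph(build_sphere_mesh(2), c(47, 47, 47), r = 20, gap = 1)
  # constant volume: all medians equal, all gradients zero
  vc <- scalar_volume(array(5, c(48, 48, 48)), c(2, 2, 2))
  p <- shell_profile(g, vc)
  expect_equal(p$up_shell, rep(5, 20))
  expect_equal(p$grad[2:19], rep(0, 18))
  expect_true(all(is.na(p$grad[c(1, 20)])))
  # median is the majority value on constructed counts
  up <- matrix(0, g$n_node, g$n_column)
  odd_majority <- ceiling((g$n_column + 1) / 2)
  up[, seq_len(odd_majority)] <- 10
  p2 <- shell_profile(g, up)
  expect_equal(p2$up_shell, rep(10, 20))
  # radially linear uptake: central difference of a ramp is -2 * gap
  # (exact on an analytic profile; near-exact on the sampled volume)
  up_lin <- matrix(100 - seq_len(g$n_node) * g$gap, g$n_node, g$n_column)
  p3 <- shell_profile(g, up_lin)
  expect_equal(p3$grad[2:19], rep(-2 * g$gap, 18), tolerance = 1e-12)
  p4 <- shell_profile(g, radial_volume(function(r) 100 - r))
  expect_equal(p4$grad[2:19], rep(-2 * g$gap, 18), tolerance = 0.05)
})

test_that("landmarks follow the weighted-gradient and running-max rules", {
  g <- build_graph(build_sphere_mesh(2), c(47, 47, 47), r = 30, gap = 1)
  # strictly linear decreasing profile: the center bias puts j_low at the
  # innermost admissible level
  up_lin <- matrix(100 - seq_len(g$n_node) * g$gap, g$n_node, g$n_column)
  lm <- find_landmarks(shell_profile(g, up_lin))
  expect_equal(lm$j_low, 2)
  # sigmoid step 10 -> 2 centered at 20 mm: hand-evaluated oracle
  f <- function(r) 2 + 8 / (1 + exp((r - 20) / 2))
  p2 <- shell_profile(g, radial_volume(f))
  lm2 <- find_landmarks(p2)
  # hand-evaluate the landmark formulas on the measured profile
  med <- p2$up_shell
  grad <- c(NA, med[3:30] - med[1:28], NA)
  w <- (30 - (2:29)) / 30
  j_low_oracle <- (2:29)[which.min(w * grad[2:29])]
  expect_equal(lm2$j_low, j_low_oracle)
  expect_true(abs(lm2$j_low - 20) <= 3)
  expect_true(lm2$j_low <= lm2$j_knee && lm2$j_knee <= lm2$j_hi)
  expect_gt(lm2$kn, 2); expect_lt(lm2$kn, 10)
  # modified gradient never decreases beyond j_low
  gm <- lm2$grad_mod[lm2$j_low:(lm2$n_node - 1)]
  expect_true(all(diff(gm) >= -1e-12))
  # degenerate constant profile
  expect_error(find_landmarks(shell_profile(g, scalar_volume(
    array(3, c(48, 48, 48)), c(2, 2, 2)))), "degenerate")
})

test_that("landmark indices are scale invariant, uptake landmarks scale", {
  g <- build_graph(build_sphere_mesh(2), c(47, 47, 47), r = 30, gap = 1)
  f <- function(r) 1 + 3 * exp(-(r / 12)^2)
  v1 <- radial_volume(f)
  v2 <- scalar_volume(v1$data * 7.5, v1$spacing, v1$origin)
  lm1 <- find_landmarks(shell_profile(g, v1))
  lm2 <- find_landmarks(shell_profile(g, v2))
  expect_equal(lm2$j_low, lm1$j_low)
  expect_equal(lm2$j_hi, lm1$j_hi)
  expect_equal(lm2$j_knee, lm1$j_knee)
  expect_equal(lm2$pe, 7.5 * lm1$pe, tolerance = 1e-9)
  expect_equal(lm2$kn, 7.5 * lm1$kn, tolerance = 1e-9)
  th1 <- compute_threshold(lm1$pe, lm1$kn)
  th2 <- compute_threshold(lm2$pe, lm2$kn)
  expect_equal(th2$gamma, th1$gamma, tolerance = 1e-9)
  expect_equal(th2$Th, 7.5 * th1$Th, tolerance = 1e-9)
})

test_that("the knee lands in the rim transition zone of a blurred sphere", {
  ph <- small_sphere_phantom()
  g <- build_graph(build_sphere_mesh(2), c(62, 62, 62), r = 30, gap = 1)
  lm <- find_landmarks(shell_profile(g, ph$volume))
  sigma <- 5 / 2.3548
  knee_radius <- lm$j_knee * g$gap
  expect_gte(knee_radius, 8 - 3 * g$gap)
  expect_lte(knee_radius, 8 + 2.5 * sigma)
})

test_that("the adaptive threshold follows the contrast decay rule", {
  th <- compute_threshold(pe = 2, kn = 1)
  expect_equal(th$Th_pct, 0.8 * exp(-0.15 * 2^1.5), tolerance = 1e-12)
  expect_gte(th$Th_pct, 0.50); expect_lte(th$Th_pct, 0.55)
  expect_equal(th$Th, 1 + th$Th_pct * 1, tolerance = 1e-12)
  th1 <- compute_threshold(pe = 3, kn = 3)
  expect_equal(th1$Th_pct, 0.8 * exp(-0.15), tolerance = 1e-12)
  expect_equal(th1$Th, 3)                    # pe == kn: zero range
  # strictly decreasing in contrast, range (0, 0.8]
  gam <- seq(1, 20, by = 0.25)
  pct <- vapply(gam, function(g) compute_threshold(g, 1)$Th_pct, numeric(1))
  expect_true(all(diff(pct) < 0))
  expect_true(all(pct > 0 & pct <= 0.8))
  # fixed-percentage variants on the same kn/pe scale
  expect_equal(compute_threshold(4, 1, "fixed40")$Th, 1 + 0.4 * 3)
  expect_equal(compute_threshold(4, 1, "fixed50")$Th, 1 + 0.5 * 3)
  expect_error(compute_threshold(1, 2), "pe < kn")
})
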