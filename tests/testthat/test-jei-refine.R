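test_that("global refinement moves the threshold and pins the surface", {
  res <- small_sphere_session()
  s <- res$session
  # a point on the mid-contrast isocontour, 9 mm from center along +x
  pt <- c(62 + 9, 62, 62)
  u <- sample_uptake(s$vol, pt)
  s2 <- global_refine(s, pt)
  expect_equal(s2$Th, u, tolerance = 1e-12)
  anchor <- s2$actions[[1]]$anchor
  expect_equal(s2$solution$levels[anchor$column], anchor$level)
  # overriding: two successive refinements equal applying only the second
  pt2 <- c(62, 62 + 8, 62)
  s3 <- global_refine(s2, pt2)
  s3_direct <- global_refine(s, pt2)
  expect_equal(s3$Th, s3_direct$Th)
  expect_identical(s3$solution$levels, s3_direct$solution$levels)
  # refinement point hotter than the center is refused
  expect_error(global_refine(s, c(62, 62, 62)), "center uptake")
})

test_that("undo restores the previous state bit-exactly", {
  res <- small_sphere_session()
  s <- res$session
  s1 <- global_refine(s, c(62 + 9, 62, 62))
  s2 <- undo_refinement(s1)
  expect_identical(s2$solution$levels, s$solution$levels)
  expect_identical(s2$Th, s$Th)
  expect_identical(s2$base, s$base)
  # stacked: push two, undo two
  sa <- local_refine(s, c(62 + 11, 62, 62))
  sb <- global_refine(sa, c(62, 62 + 8, 62))
  sc <- undo_refinement(undo_refinement(sb))
  expect_identical(sc$solution$levels, s$solution$levels)
  expect_identical(sc$refine_extra, s$refine_extra)
  # empty stack is a warning no-op
  expect_warning(s0 <- undo_refinement(s), "no actions")
  expect_identical(s0$solution$levels, s$solution$levels)
})

test_that("all reachable columns match in a radially symmetric scene", {
  g <- build_graph(build_sphere_mesh(2), c(0, 0, 0), r = 25, gap = 1)
  n <- g$n_node
  # identical radial profile on every column (perfect spherical symmetry)
  prof <- 1 + 3 / (1 + exp((seq_len(n) - 10) / 2))
  up <- matrix(prof, n, g$n_column)
  vol <- scalar_volume(array(1, c(30, 30, 30)), c(2, 2, 2),
                       origin = c(-29, -29, -29))
  env <- build_histogram_envelope(vol, c(0, 0, 0), r = 25)
  s <- jei_session(g, vol, env, Th = 2, center_uptake = 4, up = up)
  anchor <- list(column = 7, level = 10)
  sim <- find_similar_columns(s, anchor)
  ds_all <- petoss:::column_bfs(s$graph, anchor$column, max_depth = 5)
  reach <- sum(is.finite(ds_all)) - 1
  expect_equal(nrow(sim), reach)
  expect_true(all(sim$level == anchor$level))
  expect_true(all(sim$smc < 1e-9))
})

test_that("similarity respects the pattern and level-distance rules", {
  # uptake pattern scaled by 2 relative to the anchor is not similar
  g <- build_graph(build_sphere_mesh(1), c(0, 0, 0), r = 20, gap = 1)
  n <- g$n_node
  up <- matrix(rep(seq(4, 0.2, length.out = n), g$n_column), n, g$n_column)
  up[, 2:g$n_column] <- 2 * up[, 2:g$n_column]
  vol <- scalar_volume(array(1, c(24, 24, 24)), c(2, 2, 2),
                       origin = c(-23, -23, -23))
  env <- build_histogram_envelope(vol, c(0, 0, 0), r = 20)
  s <- jei_session(g, vol, env, Th = 2, center_uptake = 4, up = up)
  anchor <- list(column = 1, level = 10)
  sim <- find_similar_columns(s, anchor)
  # smc equals the anchor profile magnitude S, threshold is 0.1 * S
  expect_false(1 %in% sim$column)
  expect_equal(nrow(sim), 0)
  # identical patterns but matched level capped by the graph distance
  up2 <- matrix(rep(seq(4, 0.2, length.out = n), g$n_column), n,
                g$n_column)
  s2 <- jei_session(g, vol, env, Th = 2, center_uptake = 4, up = up2)
  sim2 <- find_similar_columns(s2, anchor)
  expect_true(all(abs(sim2$level - anchor$level) <= sim2$ds))
})

test_that("local refinement pins the anchor column at the anchor level", {
  res <- small_sphere_session()
  s <- res$session
  pt <- c(62 - 11, 62, 62)
  s2 <- local_refine(s, pt)
  act <- s2$actions[[1]]
  expect_equal(s2$solution$levels[act$anchor$column], act$anchor$level)
  # cost changes are confined to the anchor column and matched columns
  touched <- c(act$anchor$column, act$matched$column)
  delta <- s2$refine_extra - s$refine_extra
  expect_true(all(delta[, -touched] == 0))
  # undo restores
  expect_identical(undo_refinement(s2)$solution$levels, s$solution$levels)
})

test_that("replaying an action log reproduces the session exactly", {
  res <- small_sphere_session()
  s <- res$session
  log <- list(list(kind = "global", x = 62 + 9, y = 62, z = 62),
              list(kind = "local", x = 63, y = 63 - 11, z = 63),
              list(kind = "undo"))
  s1 <- apply_actions(s, log)
  s2 <- apply_actions(s, log)
  expect_identical(s1$solution$levels, s2$solution$levels)
  # log round trip through JSON lines
  p <- tempfile(fileext = ".jsonl")
  write_action_log(log, p)
  acts <- petoss:::read_action_log(p)
  s3 <- apply_actions(s, acts)
  expect_identical(s3$solution$levels, s1$solution$levels)
  # undoing the remaining action returns to the base solution
  s4 <- apply_actions(s1, list(list(kind = "undo")))
  expect_identical(s4$solution$levels, s$solution$levels)
})
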