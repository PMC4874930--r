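test_that("a unique zero-cost ring is found exactly", {
  g <- build_graph(build_sphere_mesh(2), c(0, 0, 0), r = 30, gap = 1)
  cost <- matrix(1, g$n_node, g$n_column)
  cost[17, ] <- 0
  sol <- solve_surface(g, cost)
  expect_true(all(sol$levels == 17))
  expect_equal(sol$objective, 0)
})

test_that("min-cut solutions match full enumeration on octahedron graphs", {
  m <- build_sphere_mesh(0)
  set.seed(101)
  for (trial in 1:25) {
    sc <- sample(1:3, 1)
    sp <- sample(c(0, 0.005, 0.5), 1)
    g <- build_graph(m, c(0, 0, 0), r = 8, gap = 1, sc = sc, sp = sp)
    cost <- matrix(runif(8 * 6), 8, 6)
    sol <- solve_surface(g, cost)
    expect_equal(sol$objective, brute_force_objective(g, cost),
                 tolerance = 1e-9)
    # returned objective is consistent with the returned levels
    expect_equal(sol$objective, surface_objective(g, cost, sol$levels),
                 tolerance = 1e-12)
    # hard constraint feasibility
    e <- g$mesh$edges
    expect_true(all(abs(sol$levels[e[, 1]] - sol$levels[e[, 2]]) <= sc))
  }
})

test_that("the dynamic-programming reference equals enumeration too", {
  m <- build_sphere_mesh(0)
  set.seed(202)
  for (trial in 1:10) {
    g <- build_graph(m, c(0, 0, 0), r = 6, gap = 1, sc = 2,
                     sp = sample(c(0, 0.5), 1))
    cost <- matrix(runif(6 * 6, -1, 2), 6, 6)   # negative costs allowed
    expect_equal(solve_surface_reference(g, cost),
                 brute_force_objective(g, cost), tolerance = 1e-9)
    expect_equal(solve_surface(g, cost)$objective,
                 brute_force_objective(g, cost), tolerance = 1e-9)
  }
})

test_that("soft smoothness is charged once per adjacent pair", {
  g <- build_graph(build_sphere_mesh(1), c(0, 0, 0), r = 10, gap = 1,
                   sc = 3, sp = 0.005)
  # force two adjacent columns to levels 5 and 7 with huge costs elsewhere
  e1 <- g$mesh$edges[1, ]
  cost <- matrix(1000, g$n_node, g$n_column)
  cost[5, ] <- 0                     # default resting level 5
  cost[, e1[1]] <- 1000; cost[5, e1[1]] <- 0
  cost[, e1[2]] <- 1000; cost[7, e1[2]] <- 0
  sol <- solve_surface(g, cost)
  expect_equal(sol$levels[e1[1]], 5)
  expect_equal(sol$levels[e1[2]], 7)
  # objective contains sp * |dj| for each adjacency pair spanning a jump
  expect_equal(sol$objective, surface_objective(g, cost, sol$levels),
               tolerance = 1e-12)
  ref <- sum(cost[cbind(sol$levels, seq_len(g$n_column))])
  soft <- sol$objective - ref
  e <- g$mesh$edges
  expect_equal(soft,
               0.005 * sum(abs(sol$levels[e[, 1]] - sol$levels[e[, 2]])),
               tolerance = 1e-12)
  expect_gte(soft, 0.005 * 2)        # at least the forced 2-level jump
})

test_that("co-optimal ties resolve to the lowest levels deterministically", {
  g <- build_graph(build_sphere_mesh(1), c(0, 0, 0), r = 10, gap = 1,
                   sc = 5, sp = 0)
  cost <- matrix(1, g$n_node, g$n_column)   # every surface co-optimal
  sol <- solve_surface(g, cost)
  expect_true(all(sol$levels == 1))
  sol2 <- solve_surface(g, cost)
  expect_identical(sol$levels, sol2$levels)
})

test_that("raising the cost of a selected node never lowers the optimum", {
  m <- build_sphere_mesh(0)
  set.seed(303)
  for (trial in 1:15) {
    g <- build_graph(m, c(0, 0, 0), r = 8, gap = 1, sc = 2, sp = 0.005)
    cost <- matrix(runif(8 * 6), 8, 6)
    sol <- solve_surface(g, cost)
    i <- sample(6, 1)
    cost2 <- cost
    cost2[sol$levels[i], i] <- cost2[sol$levels[i], i] + runif(1, 0, 3)
    expect_gte(solve_surface(g, cost2)$objective, sol$objective - 1e-12)
  }
})

test_that("re-solving after updates equals a fresh solve", {
  g <- build_graph(build_sphere_mesh(1), c(0, 0, 0), r = 10, gap = 1,
                   sc = 2, sp = 0.005)
  set.seed(404)
  cost <- matrix(runif(10 * 18), 10, 18)
  sol <- solve_surface(g, cost)
  # no change: identical solution
  expect_identical(resolve_with_updates(sol, g, cost)$levels, sol$levels)
  # randomized incremental update sequences always equal fresh solves
  cur <- sol
  for (step in 1:10) {
    i <- sample(18, 1)
    cost[, i] <- runif(10)
    cur <- resolve_with_updates(cur, g, cost)
    fresh <- solve_surface(g, cost)
    expect_identical(cur$levels, fresh$levels)
    expect_equal(cur$objective, fresh$objective, tolerance = 1e-12)
  }
  expect_error(resolve_with_updates(sol, build_graph(build_sphere_mesh(0),
                                                     c(0, 0, 0), r = 10,
                                                     gap = 1), cost),
               "match")
})
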