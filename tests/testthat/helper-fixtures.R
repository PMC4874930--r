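# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# small blurred sphere phantom: 64^3 at 2 mm, radius 8 mm, contrast 4:1
small_sphere_phantom <- function() {
  fixture("small_sphere", function() {
    spec <- phantom_spec(shape = c(64L, 64L, 64L), spacing = c(2, 2, 2),
                         background = 1.0,
                         lesions = list(list(center = c(62, 62, 62),
                                             radius = 8, peak = 4)),
                         psf_fwhm_mm = 5, noise_sigma = 0)
    generate_phantom(spec)
  })
}

# a ready segmentation session on the small sphere (mesh level 2, r = 30)
small_sphere_session <- function() {
  fixture("small_session", function() {
    ph <- small_sphere_phantom()
    cfg <- segmentation_config(r = 30, mesh_level = 2L)
    segment_lesion(ph$volume, c(62, 62, 62), config = cfg)
  })
}

# ramp volume u = a + b*x + c*y + d*z (exact under trilinear interpolation)
ramp_volume <- function(a = 2, b = 0.1, c = 0.05, d = -0.02,
                        dims = c(12, 10, 11), spacing = c(1.5, 2, 2.5),
                        origin = c(-3, 4, 0)) {
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  arr <- a + outer(outer(b * xs, c * ys, "+"), d * zs, "+")
  scalar_volume(arr, spacing, origin)
}

# radially symmetric volume around a center: u(r) = f(r)
radial_volume <- function(f, dims = c(48, 48, 48), spacing = c(2, 2, 2),
                          center = c(47, 47, 47)) {
  xs <- (seq_len(dims[1]) - 1) * spacing[1]
  ys <- (seq_len(dims[2]) - 1) * spacing[2]
  zs <- (seq_len(dims[3]) - 1) * spacing[3]
  d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
              (zs - center[3])^2, "+")
  scalar_volume(f(sqrt(d2)), spacing)
}

# brute-force optimal objective by full enumeration (tiny graphs only)
brute_force_objective <- function(graph, cost) {
  n <- graph$n_node
  nc <- graph$n_column
  stopifnot(n^nc <= 3e6)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), nc)))
  e <- graph$mesh$edges
  feas <- rep(TRUE, nrow(grid))
  for (k in seq_len(nrow(e)))
    feas <- feas & abs(grid[, e[k, 1]] - grid[, e[k, 2]]) <= graph$sc
  node_cost <- matrix(0, nrow(grid), nc)
  for (i in seq_len(nc)) node_cost[, i] <- cost[grid[, i], i]
  soft <- rep(0, nrow(grid))
  for (k in seq_len(nrow(e)))
    soft <- soft + abs(grid[, e[k, 1]] - grid[, e[k, 2]])
  tot <- rowSums(node_cost) + graph$sp * soft
  min(tot[feas])
}
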