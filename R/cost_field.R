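# Per-node cost assembly.
#
# Boundary-like nodes must be cheap, interior/background nodes expensive.
# Above the threshold Th the cost rises linearly from 0 (at Th) to 1 (at
# the center uptake). Below Th the cost is the right-to-left monotone
# envelope of the normalized uptake histogram of the spherical region
# around the seed: common (background) uptake values are expensive, values
# rarer than anything hotter are cheap. A rejection term adds rej = 6 to
# nodes too close to the center and to nodes beyond the point where the
# column's running-minimum uptake has fallen below the region median,
# rejecting trivial solutions and unrelated neighboring objects.

#' Histogram envelope of the spherical region around the seed
#'
#' The volume inside the radius-\code{r} sphere is resampled isotropically
#' (default 1 mm), a 100-bin histogram normalized to maximum 1 is computed
#' over the occupied uptake range, and the right-to-left monotone
#' increasing envelope is taken, giving a non-increasing background
#' likeliness per uptake bin. The median uptake of the same resampled
#' voxel set is returned alongside (used by the rejection term).
#'
#' @param vol a \code{\link{scalar_volume}}.
#' @param center sphere center, world mm.
#' @param r sphere radius in mm.
#' @param bins number of histogram bins (default 100).
#' @param resample_mm isotropic resampling step in mm (default 1).
#' @return an object of class \code{envelope_function} with fields
#'   \code{bin_edges}, \code{values} (non-increasing, max 1),
#'   \code{region_median}, \code{region_max}.
#' @export
build_histogram_envelope <- function(vol, center, r, bins = 100L,
                                     resample_mm = 1.0) {
  center <- as.numeric(center)
  steps <- seq(-r, r, by = resample_mm)
  gx <- center[1] + steps; gy <- center[2] + steps; gz <- center[3] + steps
  # clip the sample lattice to the volume's physical extent
  ext_lo <- vol$origin
  ext_hi <- vol$origin + (dim(vol$data) - 1) * vol$spacing
  gx <- gx[gx >= ext_lo[1] & gx <= ext_hi[1]]
  gy <- gy[gy >= ext_lo[2] & gy <= ext_hi[2]]
  gz <- gz[gz >= ext_lo[3] & gz <= ext_hi[3]]
  if (length(gx) == 0 || length(gy) == 0 || length(gz) == 0)
    stop("build_histogram_envelope: region sphere does not intersect volume")
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  inside <- rowSums(sweep(pts, 2, center, "-")^2) <= r^2
  if (!any(inside))
    stop("build_histogram_envelope: empty spherical region")
  samp <- sample_uptake(vol, pts[inside, , drop = FALSE])
  vmax <- max(samp)
  if (vmax <= 0) vmax <- 1e-6
  edges <- seq(0, vmax, length.out = bins + 1)
  h <- tabulate(pmin(pmax(findInterval(samp, edges, rightmost.closed = TRUE),
                          1L), bins), nbins = bins)
  h <- h / max(h)
  env <- rev(cummax(rev(h)))            # right-to-left monotone envelope
  structure(list(bin_edges = edges, values = env,
                 region_median = median(samp), region_max = vmax),
            class = "envelope_function")
}

#' Evaluate the envelope at uptake values
#'
#' @param env an \code{\link{build_histogram_envelope}} result.
#' @param up numeric uptake values.
#' @return envelope values in \code{[0, 1]}.
#' @export
envelope_lookup <- function(env, up) {
  bins <- length(env$values)
  b <- findInterval(up, env$bin_edges, rightmost.closed = TRUE)
  env$values[pmin(pmax(b, 1L), bins)]
}

#' Base boundary cost of uptake values
#'
#' 0 exactly at the threshold; linear up to 1 at the center uptake above
#' it; histogram-envelope background likeliness below it.
#'
#' @param up uptake value(s) at node positions.
#' @param Th threshold uptake.
#' @param env an \code{\link{build_histogram_envelope}} result.
#' @param center_uptake uptake at the seed center; must exceed \code{Th}.
#' @return numeric cost(s).
#' @export
base_cost <- function(up, Th, env, center_uptake) {
  if (center_uptake <= Th)
    stop("base_cost: center uptake (", signif(center_uptake, 4),
         ") does not exceed the threshold (", signif(Th, 4),
         "); seed is not inside a hot region")
  out <- numeric(length(up))
  at <- abs(up - Th) <= 1e-12
  below <- up < Th & !at
  above <- up > Th & !at
  out[below] <- envelope_lookup(env, up[below])
  out[above] <- (up[above] - Th) / (center_uptake - Th)
  out
}

#' Rejection cost term
#'
#' Adds \code{rej} (default 6, far above the 0–1 base-cost range) to nodes
#' with level below \code{j_min} (the three innermost nodes) and, beyond
#' \code{j_min}, to nodes where the running minimum of the column's uptake
#' from the center outward has dropped below the region median — once a
#' column has crossed background, everything further out stays rejected.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param up \code{n_node x n_column} uptake matrix
#'   (\code{\link{graph_uptake}}).
#' @param region_median median uptake of the spherical region.
#' @param j_min innermost protected level count, 0-based as a level index
#'   (default 3: 0-based levels 0..2 are rejected).
#' @param rej rejection cost (default 6).
#' @param use_r2 apply the running-minimum background test (disabled in
#'   necrotic mode, where cold cores would trigger it falsely).
#' @return \code{n_node x n_column} matrix of 0 / \code{rej}.
#' @export
reject_cost <- function(graph, up, region_median, j_min = 3L, rej = 6,
                        use_r2 = TRUE) {
  n <- graph$n_node
  out <- matrix(0, n, graph$n_column)
  # r1: 0-based j < j_min  <=>  1-based lv <= j_min
  if (j_min >= 1) out[seq_len(min(j_min, n)), ] <- rej
  if (use_r2) {
    runmin <- apply(up, 2, cummin)
    r2 <- runmin < region_median
    # r2 applies only for 0-based j > j_min  <=>  1-based lv >= j_min + 2
    if (j_min + 2 <= n) {
      sel <- (j_min + 2):n
      out[sel, ][r2[sel, ]] <- rej
    }
  }
  out
}

#' Assemble the total per-node cost field
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param vol a \code{\link{scalar_volume}} (used to sample node uptake if
#'   \code{up} is not supplied).
#' @param Th threshold uptake (see \code{\link{compute_threshold}}).
#' @param env histogram envelope
#'   (\code{\link{build_histogram_envelope}}).
#' @param center_uptake uptake at the seed center.
#' @param up optional precomputed uptake matrix.
#' @param mode_terms optional list of extra \code{n_node x n_column} cost
#'   matrices (label avoidance, splitting, refinement), summed into the
#'   \code{extra} component.
#' @param use_r2 passed to \code{\link{reject_cost}}.
#' @return an object of class \code{cost_field} with matrices \code{base},
#'   \code{reject}, \code{extra} and metadata.
#' @export
assemble_costs <- function(graph, vol, Th, env, center_uptake, up = NULL,
                           mode_terms = list(), use_r2 = TRUE) {
  if (is.null(up)) up <- graph_uptake(graph, vol)
  stopifnot(nrow(up) == graph$n_node, ncol(up) == graph$n_column)
  base <- matrix(base_cost(up, Th, env, center_uptake),
                 graph$n_node, graph$n_column)
  reject <- reject_cost(graph, up, env$region_median, use_r2 = use_r2)
  extra <- matrix(0, graph$n_node, graph$n_column)
  for (term in mode_terms) {
    if (!all(dim(term) == dim(extra)))
      stop("assemble_costs: mode term dimensions do not match the graph")
    extra <- extra + term
  }
  structure(list(base = base, reject = reject, extra = extra,
                 Th = Th, center_uptake = center_uptake,
                 region_median = env$region_median,
                 params = list(rej = 6, j_min = 3L)),
            class = "cost_field")
}

#' Total node cost (base + reject + extra)
#'
#' @param costs a \code{\link{assemble_costs}} result.
#' @return \code{n_node x n_column} matrix.
#' @export
total_cost <- function(costs) {
  costs$base + costs$reject + costs$extra
}

#' @export
print.cost_field <- function(x, ...) {
  cat(sprintf("cost_field: %d x %d nodes, Th = %.4g, center uptake = %.4g\n",
              nrow(x$base), ncol(x$base), x$Th, x$center_uptake))
  invisible(x)
}
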