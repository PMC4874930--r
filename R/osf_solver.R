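# Globally optimal surface extraction.
#
# One node per column must be selected, adjacent columns at most sc levels
# apart, minimizing total node cost plus sp * |level difference| summed
# once per unordered adjacent column pair. The problem is transformed to a
# minimum s-t cut (the classic optimal-surface / minimum-closure
# construction): per-column node weights are consecutive cost differences
# with a large negative weight at the bottom node forcing a non-empty
# closed set, intracolumn and hard-constraint arcs get effectively
# infinite capacity, and the soft smoothness penalty becomes bidirectional
# arcs of capacity sp between same-level nodes of adjacent columns. Among
# co-optimal surfaces, the minimal source side of the residual graph is
# taken, which is the componentwise-lowest (hence lexicographically
# smallest) optimal level assignment — deterministic without any cost
# perturbation.

# directed edge list of the flow network; node ids: 1 = source, 2 = sink,
# node (column i, level lv) = 2 + (i-1)*n_node + lv
#
# All capacities are scaled to integers so that max-flow arithmetic in
# doubles is exact (integers below 2^53) and arc saturation is an exact
# comparison — the minimal residual cut is then reliable, with no
# floating-point tolerance.
build_flow_network <- function(graph, cost) {
  n <- graph$n_node
  nc <- graph$n_column
  sc <- graph$sc
  nid <- function(i, lv) 2L + (i - 1L) * n + lv

  edges <- graph$mesh$edges
  ne <- nrow(edges)

  # integer capacity scale: quantizes costs at ~6e-8
  scale <- 2^24
  cost_s <- round(cost * scale)
  sp_s <- round(graph$sp * scale)

  # BIG dominates any finite cut; INF dominates any cut with a BIG arc
  tot <- sum(abs(cost_s)) + sp_s * ne * n + 1
  big <- 2 * (tot + max(abs(cost_s)))
  inf <- 4 * big
  if (8 * big > 2^52)
    stop("build_flow_network: cost magnitudes overflow the exact ",
         "integer capacity range")
  sp <- sp_s

  lvs <- seq_len(n)
  cols <- seq_len(nc)

  # terminal arcs from node weights
  w <- rbind(cost_s[1, , drop = FALSE] - big,
             cost_s[2:n, , drop = FALSE] - cost_s[1:(n - 1), , drop = FALSE])
  ids <- matrix(nid(rep(cols, each = n), rep(lvs, nc)), n, nc)
  neg <- w < 0
  from_t <- c(ifelse(neg, 1L, ids))
  to_t <- c(ifelse(neg, ids, 2L))
  cap_t <- c(abs(w))
  keep <- cap_t > 0
  from_t <- from_t[keep]; to_t <- to_t[keep]; cap_t <- cap_t[keep]

  # intracolumn arcs (lv -> lv-1), infinite
  ic_from <- c(ids[2:n, ])
  ic_to <- c(ids[1:(n - 1), ])

  # hard smoothness arcs between adjacent columns, both orientations
  a <- rep(edges[, 1], each = n); b <- rep(edges[, 2], each = n)
  lv_rep <- rep(lvs, ne)
  lv_lo <- pmax(lv_rep - sc, 1L)
  hc_from <- c(nid(a, lv_rep), nid(b, lv_rep))
  hc_to <- c(nid(b, lv_lo), nid(a, lv_lo))

  from <- c(from_t, ic_from, hc_from)
  to <- c(to_t, ic_to, hc_to)
  cap <- c(cap_t, rep(inf, length(ic_from) + length(hc_from)))

  # soft smoothness arcs, finite capacity sp, both orientations
  if (sp > 0) {
    sp_from <- c(nid(a, lv_rep), nid(b, lv_rep))
    sp_to <- c(nid(b, lv_rep), nid(a, lv_rep))
    from <- c(from, sp_from)
    to <- c(to, sp_to)
    cap <- c(cap, rep(sp, length(sp_from)))
  }
  list(from = from, to = to, cap = cap, n_vertex = 2L + n * nc,
       ids = ids, big = big, inf = inf)
}

#' Objective value of a level assignment
#'
#' Total node cost plus \code{sp} times the absolute level difference over
#' each unordered adjacent column pair.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param costs a \code{\link{assemble_costs}} result or a plain
#'   \code{n_node x n_column} cost matrix.
#' @param levels integer vector of one selected level (1-based) per column.
#' @return numeric objective value.
#' @export
surface_objective <- function(graph, costs, levels) {
  cost <- if (inherits(costs, "cost_field")) total_cost(costs) else costs
  stopifnot(length(levels) == graph$n_column)
  e <- graph$mesh$edges
  sum(cost[cbind(levels, seq_len(graph$n_column))]) +
    graph$sp * sum(abs(levels[e[, 1]] - levels[e[, 2]]))
}

#' Find the globally optimal closed surface
#'
#' Exact minimum-cut solution of the constrained surface problem. Among
#' co-optimal surfaces the componentwise-lowest (lexicographically
#' smallest) level assignment is returned, making results deterministic.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param costs a \code{\link{assemble_costs}} result or a plain
#'   \code{n_node x n_column} cost matrix (refinement terms may make
#'   entries negative; the transformation handles this).
#' @return an object of class \code{surface_solution} with fields
#'   \code{levels} (1-based selected level per column), \code{objective},
#'   \code{radii_mm} and \code{boundary_mesh} (the sphere mesh with each
#'   vertex moved to its selected node).
#' @export
solve_surface <- function(graph, costs) {
  cost <- if (inherits(costs, "cost_field")) total_cost(costs) else costs
  stopifnot(nrow(cost) == graph$n_node, ncol(cost) == graph$n_column)
  net <- build_flow_network(graph, cost)
  g <- igraph::make_graph(rbind(net$from, net$to), n = net$n_vertex,
                          directed = TRUE)
  mf <- igraph::max_flow(g, source = 1, target = 2, capacity = net$cap)
  # minimal source side: vertices reachable in the residual graph
  # (capacities and flows are integers, so saturation tests are exact)
  resid_fwd <- mf$flow < net$cap - 0.5
  resid_bwd <- mf$flow > 0.5
  rfrom <- c(net$from[resid_fwd], net$to[resid_bwd])
  rto <- c(net$to[resid_fwd], net$from[resid_bwd])
  rg <- igraph::make_graph(rbind(rfrom, rto), n = net$n_vertex,
                           directed = TRUE)
  reach <- igraph::subcomponent(rg, 1, mode = "out")
  in_z <- rep(FALSE, net$n_vertex)
  in_z[as.integer(reach)] <- TRUE
  zmat <- matrix(in_z[net$ids], graph$n_node, graph$n_column)
  if (!all(zmat[1, ]))
    stop("solve_surface: internal error, bottom shell not in closed set")
  levels <- apply(zmat, 2, function(z) max(which(z)))
  e <- graph$mesh$edges
  if (any(abs(levels[e[, 1]] - levels[e[, 2]]) > graph$sc))
    stop("solve_surface: internal error, hard constraint violated")
  mesh <- graph$mesh
  mesh$vertices <- sweep(graph$dirs * (levels * graph$gap), 2,
                         graph$center, "+")
  structure(list(levels = as.integer(levels),
                 objective = surface_objective(graph, cost, levels),
                 radii_mm = levels * graph$gap,
                 boundary_mesh = mesh),
            class = "surface_solution")
}

#' Re-solve after cost updates
#'
#' Produces a result identical to \code{\link{solve_surface}} on the
#' updated cost field; starting from the previous solution is an internal
#' efficiency concern, never a semantic one.
#'
#' @param prev the previous \code{surface_solution}.
#' @param graph the same \code{\link{build_graph}} the previous solution
#'   was computed on.
#' @param costs_updated updated cost field or matrix.
#' @return a \code{surface_solution}.
#' @export
resolve_with_updates <- function(prev, graph, costs_updated) {
  stopifnot(inherits(prev, "surface_solution"))
  if (length(prev$levels) != graph$n_column)
    stop("resolve_with_updates: solution does not match graph")
  solve_surface(graph, costs_updated)
}

#' @export
print.surface_solution <- function(x, ...) {
  cat(sprintf(
    "surface_solution: %d columns, objective %.6g, radius %.3g-%.3g mm\n",
    length(x$levels), x$objective, min(x$radii_mm), max(x$radii_mm)))
  invisible(x)
}
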