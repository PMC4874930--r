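# Independent exact reference solver for validation.
#
# Computes the same constrained minimum as solve_surface() by min-sum
# variable elimination (nonserial dynamic programming) over the column
# adjacency graph: unary factors are node costs, pairwise factors encode
# the hard constraint (Inf beyond sc levels) and the soft penalty
# sp * |level difference|. Eliminating columns in greedy min-fill order
# yields the exhaustive minimum exactly. Shares no algorithmic path with
# the min-cut solver, so the two serve as mutual cross-checks; cost is
# exponential in the elimination width, restricting use to small graphs.

# greedy min-fill elimination order over the column adjacency graph
min_fill_order <- function(graph) {
  nc <- graph$n_column
  nbs <- lapply(seq_len(nc), function(i) setdiff(graph$adjacency[[i]], i))
  alive <- rep(TRUE, nc)
  out <- integer(nc)
  for (step in seq_len(nc)) {
    cand <- which(alive)
    fill <- vapply(cand, function(v) {
      s <- intersect(nbs[[v]], cand)
      if (length(s) < 2) return(0L)
      pairs <- utils::combn(s, 2)
      sum(!vapply(seq_len(ncol(pairs)), function(p)
        pairs[2, p] %in% nbs[[pairs[1, p]]], logical(1)))
    }, integer(1))
    v <- cand[which.min(fill)]
    s <- intersect(nbs[[v]], cand)
    for (a in s) nbs[[a]] <- unique(c(setdiff(nbs[[a]], v), setdiff(s, a)))
    alive[v] <- FALSE
    out[step] <- v
  }
  out
}

#' Exact reference surface solver (dynamic programming)
#'
#' Exhaustive-equivalent minimum of the surface objective by min-sum
#' variable elimination. Intended for validating
#' \code{\link{solve_surface}} on small graphs (its cost grows
#' exponentially with the elimination width of the column adjacency
#' graph); returns the optimal objective only, since co-optimal level
#' assignments need not be unique.
#'
#' @param graph a \code{\link{build_graph}} result (small meshes only).
#' @param costs a \code{cost_field} or plain cost matrix.
#' @return the minimal objective value.
#' @export
solve_surface_reference <- function(graph, costs) {
  cost <- if (inherits(costs, "cost_field")) total_cost(costs) else costs
  stopifnot(nrow(cost) == graph$n_node, ncol(cost) == graph$n_column)
  edges <- graph$mesh$edges
  storage.mode(edges) <- "integer"
  .ref_dp_min_cpp(cost, edges, as.numeric(graph$sc), graph$sp,
                  as.integer(min_fill_order(graph)))
}
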