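# Spherical triangle mesh and column-graph construction.
#
# The lesion boundary is modeled as a deformed sphere: a recursively
# subdivided octahedron projected to the unit sphere provides n_column
# evenly spaced directions p_i; along each direction a column of n_node
# sample nodes is placed between the seed center ce_k and radius r. The
# octahedron scheme gives V = 4*4^level + 2 vertices, which yields exactly
# 1026 columns at level 4 (the default working resolution).

#' Build a subdivided-octahedron sphere mesh
#'
#' Recursively subdivides an octahedron and projects all vertices onto the
#' unit sphere, giving a closed 2-manifold triangle mesh with
#' \code{4 * 4^level + 2} vertices and deterministic vertex ordering.
#'
#' @param level non-negative integer subdivision level; level 4 gives the
#'   default 1026 mesh vertices.
#' @return an object of class \code{triangle_mesh} with fields
#'   \code{vertices} (V x 3 unit vectors), \code{triangles} (F x 3 1-based
#'   index triples) and \code{edges} (E x 2 unordered index pairs).
#' @export
build_sphere_mesh <- function(level) {
  if (length(level) != 1 || is.na(level) || level < 0 || level != round(level))
    stop("build_sphere_mesh: 'level' must be a non-negative integer")
  verts <- rbind(c(1, 0, 0), c(-1, 0, 0),
                 c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  tris <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
                c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (lv in seq_len(level)) {
    nv <- nrow(verts)
    # midpoint index cache keyed on the unordered vertex pair
    key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    e1 <- key(tris[, 1], tris[, 2])
    e2 <- key(tris[, 2], tris[, 3])
    e3 <- key(tris[, 3], tris[, 1])
    ekeys <- unique(c(e1, e2, e3))
    mid_of <- setNames(seq_along(ekeys) + nv, ekeys)
    ka <- ekeys %/% (nv + 1); kb <- ekeys %% (nv + 1)
    mids <- verts[ka, , drop = FALSE] + verts[kb, , drop = FALSE]
    mids <- mids / sqrt(rowSums(mids^2))
    verts <- rbind(verts, mids)
    m1 <- mid_of[as.character(e1)]
    m2 <- mid_of[as.character(e2)]
    m3 <- mid_of[as.character(e3)]
    tris <- rbind(cbind(tris[, 1], m1, m3),
                  cbind(tris[, 2], m2, m1),
                  cbind(tris[, 3], m3, m2),
                  cbind(m1, m2, m3))
  }
  dimnames(tris) <- NULL
  edges <- unique(rbind(cbind(pmin(tris[, 1], tris[, 2]),
                              pmax(tris[, 1], tris[, 2])),
                        cbind(pmin(tris[, 2], tris[, 3]),
                              pmax(tris[, 2], tris[, 3])),
                        cbind(pmin(tris[, 3], tris[, 1]),
                              pmax(tris[, 3], tris[, 1]))))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(list(vertices = verts, triangles = tris, edges = edges),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d edges, %d triangles\n",
              nrow(x$vertices), nrow(x$edges), nrow(x$triangles)))
  invisible(x)
}

#' Build the column graph around a seed center
#'
#' Places a column of equally spaced sample nodes along each mesh direction:
#' node level \code{lv} (1-based) of column \code{i} sits at
#' \code{center + lv * gap * p_i}, so the innermost node is \code{gap} mm
#' from the center and the outermost exactly at radius \code{r}. Column
#' adjacency is mesh-edge adjacency.
#'
#' @param mesh a \code{\link{build_sphere_mesh}} result.
#' @param center seed center ce_k, world mm.
#' @param r column radius in mm (default 60).
#' @param gap node spacing along a column in mm (default 1), giving
#'   \code{n_node = round(r / gap)} nodes per column.
#' @param sc hard smoothness constraint: adjacent columns may differ by at
#'   most \code{sc} node levels (default 5).
#' @param sp soft smoothness penalty per level of difference between
#'   adjacent columns (default 0.005).
#' @return an object of class \code{column_graph}.
#' @export
build_graph <- function(mesh, center, r = 60.0, gap = 1.0, sc = 5L,
                        sp = 0.005) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (r <= 0 || gap <= 0) stop("build_graph: r and gap must be positive")
  if (r < 2 * gap) stop("build_graph: r < 2*gap gives degenerate columns")
  if (sc < 0 || sp < 0) stop("build_graph: sc and sp must be non-negative")
  n_col <- nrow(mesh$vertices)
  n_node <- as.integer(round(r / gap))
  adj <- vector("list", n_col)
  for (k in seq_len(nrow(mesh$edges))) {
    a <- mesh$edges[k, 1]; b <- mesh$edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, sort)
  structure(list(mesh = mesh, center = as.numeric(center), r = r, gap = gap,
                 n_column = n_col, n_node = n_node,
                 dirs = mesh$vertices, adjacency = adj,
                 sc = as.integer(sc), sp = sp),
            class = "column_graph")
}

#' @export
print.column_graph <- function(x, ...) {
  cat(sprintf(
    "column_graph: %d columns x %d nodes, r = %g mm, gap = %g mm, sc = %d, sp = %g\n",
    x$n_column, x$n_node, x$r, x$gap, x$sc, x$sp))
  cat(sprintf("  center (%s) mm\n", paste(signif(x$center, 6), collapse = ", ")))
  invisible(x)
}

#' World positions of graph nodes
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param columns optional column subset (1-based); default all.
#' @return a matrix with one row per node, ordered level-fastest within
#'   column, and columns \code{x,y,z} in mm.
#' @export
node_positions <- function(graph, columns = NULL) {
  if (is.null(columns)) columns <- seq_len(graph$n_column)
  lv <- seq_len(graph$n_node)
  radii <- lv * graph$gap
  dirs <- graph$dirs[columns, , drop = FALSE]
  # outer product: (n_node * n_col) x 3
  pos <- dirs[rep(seq_along(columns), each = graph$n_node), , drop = FALSE] *
    rep(radii, length(columns))
  sweep(pos, 2, graph$center, "+")
}

#' Sample uptake at every graph node
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param vol a \code{\link{scalar_volume}}.
#' @return an \code{n_node x n_column} matrix of uptake values.
#' @export
graph_uptake <- function(graph, vol) {
  up <- sample_uptake(vol, node_positions(graph))
  matrix(up, nrow = graph$n_node, ncol = graph$n_column)
}

# breadth-first distances (edge counts) from column `from`, restricted to
# `candidates` when given; unreached columns get Inf
column_bfs <- function(graph, from, max_depth = Inf, candidates = NULL) {
  dist <- rep(Inf, graph$n_column)
  allowed <- rep(FALSE, graph$n_column)
  allowed[if (is.null(candidates)) seq_len(graph$n_column) else candidates] <- TRUE
  if (!allowed[from]) return(dist)
  dist[from] <- 0
  frontier <- from
  d <- 0
  while (length(frontier) > 0 && d < max_depth) {
    d <- d + 1
    nxt <- unique(unlist(graph$adjacency[frontier]))
    nxt <- nxt[allowed[nxt] & !is.finite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Graph geodesic between two columns
#'
#' Number of edges on the shortest path in the column-adjacency graph
#' (optionally restricted to a candidate column set, as used during local
#' refinement). Unreachable pairs return \code{Inf}.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param i,i2 column indices (1-based).
#' @param candidates optional restriction of traversable columns.
#' @return integer distance, or \code{Inf}.
#' @export
graph_geodesic <- function(graph, i, i2, candidates = NULL) {
  stopifnot(i >= 1, i <= graph$n_column, i2 >= 1, i2 <= graph$n_column)
  column_bfs(graph, i, candidates = candidates)[i2]
}

# nearest graph node to a world point: returns list(column, level, dist)
nearest_node <- function(graph, point) {
  v <- as.numeric(point) - graph$center
  s <- as.numeric(graph$dirs %*% v)          # projection onto each direction
  lv <- pmin(pmax(round(s / graph$gap), 1), graph$n_node)
  # squared distance from point to node (column i, level lv_i)
  d2 <- rowSums(sweep(graph$dirs * (lv * graph$gap), 2, v, "-")^2)
  i <- which.min(d2)
  list(column = i, level = lv[i], dist = sqrt(d2[i]))
}
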