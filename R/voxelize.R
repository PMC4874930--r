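# Boundary mesh -> label volume conversion, connectivity cleanup, OR
# merging and gap closing.
#
# Surfaces produced by the solver are star-shaped around the graph center
# (one node per radial column), so the voxel-center inside test is done
# radially and exactly: a voxel center is inside iff its distance to the
# center does not exceed the intersection of its direction ray with the
# plane of the containing mesh triangle (with a 1e-9 mm on-surface
# tolerance). For star-shaped closed meshes this is equivalent to parity
# ray casting but has no edge/vertex degeneracies.

mesh_is_closed <- function(mesh) {
  tr <- mesh$triangles
  ekey <- c(paste(pmin(tr[, 1], tr[, 2]), pmax(tr[, 1], tr[, 2])),
            paste(pmin(tr[, 2], tr[, 3]), pmax(tr[, 2], tr[, 3])),
            paste(pmin(tr[, 3], tr[, 1]), pmax(tr[, 3], tr[, 1])))
  all(table(ekey) == 2L)
}

#' Voxelize a closed boundary surface into a label volume
#'
#' A voxel receives the label iff its center lies inside (or exactly on)
#' the closed surface.
#'
#' @param solution a \code{\link{solve_surface}} result, or a closed
#'   star-shaped \code{triangle_mesh} with world-mm \code{vertices}.
#' @param grid a \code{\link{scalar_volume}} (or \code{label_volume})
#'   defining the output grid.
#' @param label positive integer label to assign (default 1).
#' @param center the star center in mm; taken from the solution's graph
#'   geometry when a \code{surface_solution} is given.
#' @return a \code{\link{label_volume}} on the same grid.
#' @export
mesh_to_labels <- function(solution, grid, label = 1L, center = NULL) {
  if (inherits(solution, "surface_solution")) {
    mesh <- solution$boundary_mesh
    if (is.null(center)) center <- colMeans(mesh$vertices)
  } else {
    mesh <- solution
    if (is.null(center)) center <- colMeans(mesh$vertices)
  }
  stopifnot(inherits(mesh, "triangle_mesh") || is.list(mesh))
  if (!mesh_is_closed(mesh))
    stop("mesh_to_labels: boundary mesh is not closed")
  if (is.null(mesh$edges)) {
    tr <- mesh$triangles
    mesh$edges <- unique(rbind(cbind(pmin(tr[, 1], tr[, 2]),
                                     pmax(tr[, 1], tr[, 2])),
                               cbind(pmin(tr[, 2], tr[, 3]),
                                     pmax(tr[, 2], tr[, 3])),
                               cbind(pmin(tr[, 3], tr[, 1]),
                                     pmax(tr[, 3], tr[, 1]))))
  }
  verts <- mesh$vertices
  tris <- mesh$triangles
  center <- as.numeric(center)
  rel <- sweep(verts, 2, center)
  radii <- sqrt(rowSums(rel^2))
  dirs <- rel / radii
  rmax <- max(radii)

  dm <- dim(grid$data)
  out <- array(0L, dm)
  # candidate voxels: centers within the surface's bounding sphere
  axr <- lapply(1:3, function(ax) {
    cc <- grid$origin[ax] + (seq_len(dm[ax]) - 1) * grid$spacing[ax]
    which(cc >= center[ax] - rmax - 1e-9 & cc <= center[ax] + rmax + 1e-9)
  })
  if (any(vapply(axr, length, 1L) == 0)) {
    return(label_volume(out, grid$spacing, grid$origin))
  }
  cgrid <- as.matrix(expand.grid(x = axr[[1]], y = axr[[2]], z = axr[[3]]))
  pts <- sweep((cgrid - 1) * rep(grid$spacing, each = nrow(cgrid)), 2,
               grid$origin, "+")
  v <- sweep(pts, 2, center, "-")
  dist <- sqrt(rowSums(v^2))
  sel <- dist <= rmax + 1e-9
  inside <- dist <= 1e-9                # the center itself
  todo <- which(sel & !inside)
  if (length(todo) > 0) {
    u <- v[todo, , drop = FALSE] / dist[todo]
    # per-triangle quantities relative to the center
    a <- rel[tris[, 1], , drop = FALSE]
    b <- rel[tris[, 2], , drop = FALSE]
    c3 <- rel[tris[, 3], , drop = FALSE]
    crossm <- function(p, q) cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
                                   p[, 3] * q[, 1] - p[, 1] * q[, 3],
                                   p[, 1] * q[, 2] - p[, 2] * q[, 1])
    n1 <- crossm(a, b); n2 <- crossm(b, c3); n3 <- crossm(c3, a)
    npl <- crossm(b - a, c3 - a)          # plane normal
    na <- rowSums(npl * a)
    # candidate triangles per mesh vertex: incident to the vertex or to
    # one of its mesh neighbors (covers the containing spherical triangle
    # of any direction whose nearest vertex is that vertex)
    tri_of_vert <- lapply(seq_len(nrow(verts)), function(i)
      which(tris[, 1] == i | tris[, 2] == i | tris[, 3] == i))
    nbrs <- lapply(seq_len(nrow(verts)), function(i)
      unique(c(i, mesh$edges[mesh$edges[, 1] == i, 2],
               mesh$edges[mesh$edges[, 2] == i, 1])))
    cand_of_vert <- lapply(seq_len(nrow(verts)), function(i)
      unique(unlist(tri_of_vert[nbrs[[i]]])))
    # group voxels by nearest mesh direction, vectorize within each group
    rsurf <- rep(NA_real_, length(todo))
    chunk <- 50000L
    nearest <- integer(length(todo))
    for (start in seq(1, length(todo), by = chunk)) {
      jj <- start:min(start + chunk - 1L, length(todo))
      nearest[jj] <- max.col(u[jj, , drop = FALSE] %*% t(dirs), "first")
    }
    groups <- split(seq_along(todo), nearest)
    for (gname in names(groups)) {
      gi <- groups[[gname]]
      cand <- cand_of_vert[[as.integer(gname)]]
      uu <- u[gi, , drop = FALSE]
      tol <- 1e-10
      d1 <- uu %*% t(n1[cand, , drop = FALSE])
      d2 <- uu %*% t(n2[cand, , drop = FALSE])
      d3 <- uu %*% t(n3[cand, , drop = FALSE])
      hit <- (d1 >= -tol & d2 >= -tol & d3 >= -tol) |
             (d1 <= tol & d2 <= tol & d3 <= tol)
      den <- uu %*% t(npl[cand, , drop = FALSE])
      tv <- sweep(1 / den, 2, na[cand], "*")
      tv[!hit | !is.finite(tv) | tv <= 0] <- -Inf
      rs <- apply(tv, 1, max)
      rsurf[gi] <- rs
    }
    # rare fallback: directions whose containing triangle was not among
    # the candidates are tested against every triangle
    miss <- which(!is.finite(rsurf))
    for (m in miss) {
      uu <- u[m, ]
      d1 <- n1 %*% uu; d2 <- n2 %*% uu; d3 <- n3 %*% uu
      tol <- 1e-10
      hit <- (d1 >= -tol & d2 >= -tol & d3 >= -tol) |
             (d1 <= tol & d2 <= tol & d3 <= tol)
      tv <- na / as.numeric(npl %*% uu)
      tv[!hit | !is.finite(tv) | tv <= 0] <- -Inf
      rsurf[m] <- max(tv)
    }
    rsurf[!is.finite(rsurf)] <- 0
    inside[todo] <- dist[todo] <= rsurf + 1e-9
  }
  lin <- cgrid[inside, , drop = FALSE]
  out[lin] <- as.integer(label)
  label_volume(out, grid$spacing, grid$origin)
}

#' Keep only the 6-connected component containing the seed
#'
#' Voxelization can leave fragments that are not 6-connected to the main
#' lesion body; those are cleared.
#'
#' @param labels a \code{\link{label_volume}} (treated as a binary mask of
#'   nonzero labels).
#' @param seed world mm point whose voxel must be labeled.
#' @return the cleaned \code{label_volume}.
#' @export
cleanup_components <- function(labels, seed) {
  idx <- voxel_index(labels, seed)[1, ]
  if (any(is.na(idx)))
    stop("cleanup_components: seed point is outside the grid")
  if (labels$data[idx[1], idx[2], idx[3]] == 0L)
    stop("cleanup_components: seed voxel is not labeled")
  comp <- flood6(labels$data != 0L, idx)
  out <- labels$data
  out[!comp] <- 0L
  label_volume(out, labels$spacing, labels$origin)
}

#' Combine segmentations with a voxelwise logical OR
#'
#' Multi-center lesions are segmented once per seed and merged: a voxel is
#' labeled iff it is labeled in any input.
#'
#' @param segmentations list of \code{\link{label_volume}}s on one grid.
#' @param label the label for the merged result (default 1).
#' @return a \code{\link{label_volume}}.
#' @export
merge_or <- function(segmentations, label = 1L) {
  stopifnot(length(segmentations) >= 1)
  ref <- segmentations[[1]]
  acc <- array(FALSE, dim(ref$data))
  for (s in segmentations) {
    if (!same_grid(ref, s)) stop("merge_or: grid mismatch between inputs")
    acc <- acc | (s$data != 0L)
  }
  label_volume(array(as.integer(acc) * as.integer(label), dim(ref$data)),
               ref$spacing, ref$origin)
}

#' Close one-voxel-wide gaps within each label
#'
#' Morphological closing with the 3x3x3 cross element, applied per label
#' and restricted so that gaps between \emph{different} labels are never
#' bridged: an unlabeled voxel is filled only when exactly one label's
#' closing covers it.
#'
#' @param labels a \code{\link{label_volume}}.
#' @param enable if \code{FALSE}, returns the input unchanged.
#' @return a \code{\link{label_volume}}.
#' @export
close_gaps <- function(labels, enable = TRUE) {
  if (!enable) return(labels)
  labs <- setdiff(sort(unique(as.integer(labels$data))), 0L)
  if (length(labs) == 0) return(labels)
  any_label <- labels$data != 0L
  cover_count <- array(0L, dim(labels$data))
  cover_label <- array(0L, dim(labels$data))
  for (L in labs) {
    closed <- erode6(dilate6(labels$data == L))
    fill <- closed & !any_label
    cover_count[fill] <- cover_count[fill] + 1L
    cover_label[fill] <- L
  }
  out <- labels$data
  ok <- cover_count == 1L
  out[ok] <- cover_label[ok]
  label_volume(out, labels$spacing, labels$origin)
}
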