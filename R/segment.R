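# End-to-end segmentation drivers: seed -> recenter -> graph -> shell
# statistics -> threshold -> costs (+ modes) -> optimal surface ->
# voxelization -> connectivity cleanup, with OR-merging of multi-seed
# lesions.

#' Segment one lesion from a seed point
#'
#' Runs the full pipeline for a single seed and returns the refinement
#' session (for optional interactive correction), the label map and a
#' report of the derived quantities.
#'
#' @param vol a \code{\link{scalar_volume}}.
#' @param seed world mm seed point inside the lesion.
#' @param config a \code{\link{segmentation_config}} (use
#'   \code{\link{necrotic_config}} for necrotic lesions).
#' @param label output label id (default 1).
#' @return list with \code{labels} (\code{label_volume}),
#'   \code{session} (\code{jei_session}), \code{report} (list with
#'   \code{Th}, \code{Th_pct}, \code{gamma}, \code{pe}, \code{kn},
#'   \code{j_low}, \code{j_knee}, \code{j_hi}, \code{objective},
#'   \code{voxel_count}, \code{center}).
#' @export
segment_lesion <- function(vol, seed, config = segmentation_config(),
                           label = 1L) {
  center <- recenter(vol, seed, enabled = isTRUE(config$recenter))
  mesh <- build_sphere_mesh(config$mesh_level)
  graph <- build_graph(mesh, center, r = config$r, gap = config$gap,
                       sc = config$sc, sp = config$sp)
  up <- graph_uptake(graph, vol)
  profile <- find_landmarks(shell_profile(graph, up))
  th <- compute_threshold(profile$pe, profile$kn, config$threshold_mode)
  env <- build_histogram_envelope(vol, center, config$r)
  # necrotic lesions have cold centers: normalize costs by the hot rim
  center_uptake <- if (identical(config$cost_reference, "peak"))
    max(profile$pe, sample_uptake(vol, center)) else
    sample_uptake(vol, center)
  mode_terms <- list()
  if (!is.null(config$avoid_labels))
    mode_terms <- c(mode_terms,
                    list(label_avoidance_costs(graph, config$avoid_labels,
                                               own_label = label)))
  if (isTRUE(config$split))
    mode_terms <- c(mode_terms,
                    list(splitting_costs(graph, vol, th$Th, center)))
  if (isTRUE(config$necrotic))
    mode_terms <- c(mode_terms,
                    list(necrotic_rim_costs(graph, up, th$Th)))
  session <- jei_session(graph, vol, env, th$Th, center_uptake, up = up,
                         mode_terms = mode_terms,
                         use_r2 = isTRUE(config$use_r2))
  labels <- session_labels(session, label = label)
  report <- list(Th = th$Th, Th_pct = th$Th_pct, gamma = th$gamma,
                 pe = profile$pe, kn = profile$kn,
                 j_low = profile$j_low, j_knee = profile$j_knee,
                 j_hi = profile$j_hi,
                 objective = session$solution$objective,
                 voxel_count = sum(labels$data != 0L),
                 center = center)
  list(labels = labels, session = session, report = report)
}

#' Voxelize the current session solution
#'
#' @param session a \code{\link{jei_session}}.
#' @param label label id (default 1).
#' @return a cleaned \code{\link{label_volume}} of the current surface.
#' @export
session_labels <- function(session, label = 1L) {
  lab <- mesh_to_labels(session$solution, session$vol, label = label,
                        center = session$graph$center)
  ci <- voxel_index(lab, session$graph$center)[1, ]
  if (!any(is.na(ci)) && lab$data[ci[1], ci[2], ci[3]] != 0L)
    lab <- cleanup_components(lab, session$graph$center)
  lab
}

#' Segment multiple seeds, merging same-label results
#'
#' Seeds sharing a label id are segmented individually and combined with
#' a voxelwise OR (multi-center lesions); different labels are written
#' into one label map in seed order, without overwriting earlier labels.
#'
#' @param vol a \code{\link{scalar_volume}}.
#' @param seeds data frame with columns \code{x}, \code{y}, \code{z} (mm)
#'   and optional \code{label} (default 1).
#' @param config a \code{\link{segmentation_config}}.
#' @return list with \code{labels} (combined \code{label_volume}) and
#'   \code{reports} (one report per seed).
#' @export
segment_lesions <- function(vol, seeds, config = segmentation_config()) {
  stopifnot(is.data.frame(seeds), all(c("x", "y", "z") %in% names(seeds)))
  if (is.null(seeds$label)) seeds$label <- 1L
  combined <- array(0L, dim(vol$data))
  reports <- vector("list", nrow(seeds))
  for (L in unique(seeds$label)) {
    rows <- which(seeds$label == L)
    segs <- list()
    for (k in rows) {
      res <- segment_lesion(vol, c(seeds$x[k], seeds$y[k], seeds$z[k]),
                            config = config, label = L)
      segs <- c(segs, list(res$labels))
      reports[[k]] <- res$report
    }
    merged <- if (length(segs) > 1) merge_or(segs, label = L) else segs[[1]]
    place <- merged$data != 0L & combined == 0L
    combined[place] <- as.integer(L)
  }
  labels <- label_volume(combined, vol$spacing, vol$origin)
  labels <- close_gaps(labels, enable = isTRUE(config$close_gaps))
  list(labels = labels, reports = reports)
}
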