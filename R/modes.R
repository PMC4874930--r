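# Optional segmentation behaviors for ambiguous scenes.
#
# Label avoidance keeps a new segmentation from overwriting existing label
# maps; splitting separates adjacent lesions of similar uptake through
# watershed-derived penalties; necrotic mode disables the two heuristics
# (recentering, background rejection) that misfire inside cold lesion
# cores. The watershed construction ("strong" = markers from a smoothed
# field, "weak" = markers from the raw field) is a reconstruction of the
# behavior the figures describe; its penalties dominate (rej) for the
# robust partition and bias (rej/2) for the sensitive one.

#' Label-avoidance cost term
#'
#' Walking outward along each column, the first node falling in a voxel
#' carrying a different nonzero label marks the onset: that node and every
#' node beyond it on the column receive the rejection cost, so the new
#' surface cannot reach into an existing segmentation. Columns that never
#' touch foreign labels are unchanged.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param existing a \code{\link{label_volume}} of prior segmentations.
#' @param own_label the label being segmented now (its own voxels are not
#'   avoided).
#' @param rej rejection cost (default 6).
#' @return \code{n_node x n_column} cost matrix.
#' @export
label_avoidance_costs <- function(graph, existing, own_label, rej = 6) {
  stopifnot(inherits(existing, "label_volume"))
  pos <- node_positions(graph)
  idx <- voxel_index(existing, pos)
  lab <- rep(0L, nrow(idx))
  ok <- !is.na(idx[, 1])
  lab[ok] <- existing$data[idx[ok, , drop = FALSE]]
  foreign <- matrix(lab != 0L & lab != own_label,
                    graph$n_node, graph$n_column)
  # once a foreign label is hit, every deeper node is rejected too
  onset <- apply(foreign, 2, cummax)
  matrix(rej * onset, graph$n_node, graph$n_column)
}

#' Marker-based watershed partition of the supra-threshold region
#'
#' Voxels with uptake below \code{Th} are ignored. Markers are the
#' 26-neighborhood local maxima of the masked uptake, optionally after
#' Gaussian smoothing; basins grow from the markers by processing masked
#' voxels in order of decreasing uptake, each voxel joining the basin of
#' its hottest already-assigned 26-neighbor (deterministic, ties by voxel
#' index). Masked voxels unreachable from any marker keep basin 0.
#'
#' @param vol a \code{\link{scalar_volume}}.
#' @param Th threshold uptake defining the region.
#' @param smooth_fwhm_mm Gaussian FWHM in mm applied before marker
#'   detection (0 = raw field; markers only — flooding always uses the
#'   raw uptake).
#' @return integer array of basin labels (0 outside the region /
#'   unreached).
#' @export
watershed_basins <- function(vol, Th, smooth_fwhm_mm = 0) {
  mask <- vol$data >= Th
  basins <- array(0L, dim(vol$data))
  if (!any(mask)) return(basins)
  marker_field <- if (smooth_fwhm_mm > 0)
    blur_volume(vol, smooth_fwhm_mm)$data else vol$data
  markers <- local_maxima26(marker_field, mask)
  mi <- which(markers)
  if (length(mi) == 0) return(basins)
  # merge 26-connected marker plateaus into single markers (lowest id wins)
  ids <- array(0L, dim(vol$data))
  ids[mi] <- seq_along(mi)
  repeat {
    changed <- FALSE
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nb <- shift_array(ids, 1, dx, pad = "zero")
      nb <- shift_array(nb, 2, dy, pad = "zero")
      nb <- shift_array(nb, 3, dz, pad = "zero")
      upd <- markers & nb > 0L & nb < ids
      if (any(upd)) {
        ids[upd] <- nb[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  basins[mi] <- match(ids[mi], sort(unique(ids[mi])))
  ord <- order(-vol$data[mask])
  masked_lin <- which(mask)[ord]        # decreasing uptake
  dm <- dim(vol$data)
  nbr_off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbr_off <- nbr_off[rowSums(abs(nbr_off)) > 0, ]
  coords <- arrayInd(masked_lin, dm)
  for (pass in 1:2) {
    todo <- basins[masked_lin] == 0L
    if (!any(todo)) break
    for (m in which(todo)) {
      p <- coords[m, ]
      best <- 0L; bestu <- -Inf
      for (q in seq_len(nrow(nbr_off))) {
        x <- p[1] + nbr_off[q, 1]; y <- p[2] + nbr_off[q, 2]
        z <- p[3] + nbr_off[q, 3]
        if (x < 1 || y < 1 || z < 1 || x > dm[1] || y > dm[2] || z > dm[3])
          next
        bz <- basins[x, y, z]
        if (bz > 0L && vol$data[x, y, z] > bestu) {
          bestu <- vol$data[x, y, z]; best <- bz
        }
      }
      if (best > 0L) basins[p[1], p[2], p[3]] <- best
    }
  }
  basins
}

#' Splitting cost term for adjacent lesions
#'
#' Runs two marker-based watersheds on the supra-threshold region: a
#' "strong" one with markers from a 3 mm smoothed field and a "weak" one
#' with raw markers. Once a column has entered a strong basin other than
#' the seed's, that node and every node beyond it on the column receive
#' \code{+rej} — the penalty is monotone outward, so the surface cannot
#' skip over an adjacent lesion and close behind it. Nodes sitting in a
#' foreign weak basin additionally get a \code{+rej/2} bias.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param vol a \code{\link{scalar_volume}}.
#' @param Th threshold uptake.
#' @param center the (recentered) seed, world mm; must lie in the region.
#' @param rej rejection cost (default 6).
#' @param strong_fwhm_mm marker smoothing for the strong watershed
#'   (default 3 mm).
#' @return \code{n_node x n_column} cost matrix.
#' @export
splitting_costs <- function(graph, vol, Th, center, rej = 6,
                            strong_fwhm_mm = 3.0) {
  ci <- voxel_index(vol, center)[1, ]
  if (any(is.na(ci)) || vol$data[ci[1], ci[2], ci[3]] < Th)
    stop("splitting_costs: seed uptake is below the threshold")
  strong <- watershed_basins(vol, Th, smooth_fwhm_mm = strong_fwhm_mm)
  weak <- watershed_basins(vol, Th, smooth_fwhm_mm = 0)
  pos <- node_positions(graph)
  idx <- voxel_index(vol, pos)
  ok <- !is.na(idx[, 1])
  sb <- rep(0L, nrow(idx)); wb <- rep(0L, nrow(idx))
  sb[ok] <- strong[idx[ok, , drop = FALSE]]
  wb[ok] <- weak[idx[ok, , drop = FALSE]]
  seed_sb <- strong[ci[1], ci[2], ci[3]]
  seed_wb <- weak[ci[1], ci[2], ci[3]]
  foreign_strong <- matrix(sb > 0L & sb != seed_sb,
                           graph$n_node, graph$n_column)
  pen <- rej * apply(foreign_strong, 2, cummax) +
    (rej / 2) * matrix(wb > 0L & wb != seed_wb,
                       graph$n_node, graph$n_column)
  pen
}

#' Necrotic rim-enclosure cost term
#'
#' Cold-cored lesions offer the solver a spurious cheap boundary inside
#' the core. This term rejects every node on a column until the running
#' maximum of the column's uptake has reached the threshold — the surface
#' must first pass through the hot rim before it may close. Columns that
#' never reach the threshold are left untouched.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param up \code{n_node x n_column} uptake matrix.
#' @param Th threshold uptake.
#' @param rej rejection cost (default 6).
#' @return \code{n_node x n_column} cost matrix.
#' @export
necrotic_rim_costs <- function(graph, up, Th, rej = 6) {
  runmax <- apply(up, 2, cummax)
  reached <- apply(runmax >= Th, 2, any)
  pen <- rej * (runmax < Th)
  pen[, !reached] <- 0
  pen
}

#' Default segmentation configuration
#'
#' @param threshold_mode \code{"adaptive"}, \code{"fixed40"} or
#'   \code{"fixed50"}.
#' @param recenter move the seed to the hottest voxel within 7 mm.
#' @param use_r2 apply the running-minimum background rejection.
#' @param avoid_labels optional \code{\link{label_volume}} to avoid.
#' @param split enable watershed splitting.
#' @param close_gaps fill one-voxel gaps within each label.
#' @param r,gap,sc,sp,mesh_level graph construction parameters.
#' @param cost_reference normalize above-threshold costs by the seed
#'   center uptake (\code{"center"}) or the peak shell uptake
#'   (\code{"peak"}, used for necrotic lesions).
#' @param necrotic add the rim-enclosure rejection term
#'   (\code{\link{necrotic_rim_costs}}).
#' @return a named configuration list.
#' @export
segmentation_config <- function(threshold_mode = "adaptive", recenter = TRUE,
                                use_r2 = TRUE, avoid_labels = NULL,
                                split = FALSE, close_gaps = FALSE,
                                r = 60.0, gap = 1.0, sc = 5L, sp = 0.005,
                                mesh_level = 4L,
                                cost_reference = c("center", "peak"),
                                necrotic = FALSE) {
  list(threshold_mode = threshold_mode, recenter = recenter, use_r2 = use_r2,
       avoid_labels = avoid_labels, split = split, close_gaps = close_gaps,
       r = r, gap = gap, sc = sc, sp = sp, mesh_level = mesh_level,
       cost_reference = match.arg(cost_reference), necrotic = necrotic)
}

#' Necrotic-lesion configuration
#'
#' Lesions with cold (necrotic) cores break three assumptions of the base
#' algorithm: recentering would jump to the hot rim instead of the lesion
#' center, the running-minimum background test fires inside the cold core
#' and rejects the whole rim, and the seed-center uptake (which is cold)
#' cannot normalize the above-threshold cost. Necrotic mode disables
#' recentering and the running-minimum rule (keeping the innermost-node
#' rejection) and normalizes costs by the peak shell uptake — the hot rim
#' — instead of the center uptake.
#'
#' @param base_config a \code{\link{segmentation_config}} list.
#' @return the modified configuration.
#' @export
necrotic_config <- function(base_config = segmentation_config()) {
  base_config$recenter <- FALSE
  base_config$use_r2 <- FALSE
  base_config$cost_reference <- "peak"
  base_config$necrotic <- TRUE
  base_config
}
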