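# Just-enough-interaction refinement.
#
# A session wraps one lesion's graph, costs and current optimal surface.
# Global refinement: a single point resets the threshold to the uptake at
# that point, rebuilds the base costs and pins the nearest column to the
# nearest node (cost 1000 on every other node of that column); repeated
# global refinements override each other. Local refinement: a point pins
# its nearest column the same way and gives similar neighboring columns
# (uptake-profile matching within graph distance 5) a notch-shaped cost
# decrease that is narrow near the refined column and wider further away.
# Every action snapshots the prior state, so undo restores it bit-exactly.

ANCHOR_COST <- 1000

#' Start a refinement session from a base segmentation state
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param vol the \code{\link{scalar_volume}} being segmented.
#' @param env histogram envelope of the graph region
#'   (\code{\link{build_histogram_envelope}}).
#' @param Th initial threshold (see \code{\link{compute_threshold}}).
#' @param center_uptake uptake at the seed center.
#' @param up optional precomputed \code{n_node x n_column} uptake matrix.
#' @param mode_terms optional list of extra cost matrices (modes).
#' @param use_r2 apply the running-minimum rejection
#'   (\code{\link{reject_cost}}).
#' @return an object of class \code{jei_session} with the initial optimal
#'   solution computed.
#' @export
jei_session <- function(graph, vol, env, Th, center_uptake, up = NULL,
                        mode_terms = list(), use_r2 = TRUE) {
  if (is.null(up)) up <- graph_uptake(graph, vol)
  costs <- assemble_costs(graph, vol, Th, env, center_uptake, up = up,
                          mode_terms = mode_terms, use_r2 = use_r2)
  s <- structure(list(graph = graph, vol = vol, env = env, up = up,
                      Th = Th, center_uptake = center_uptake,
                      use_r2 = use_r2,
                      mode_extra = costs$extra,   # mode terms, never undone
                      base = costs$base, reject = costs$reject,
                      refine_extra = matrix(0, graph$n_node, graph$n_column),
                      global_anchor = NULL, anchored = integer(0),
                      actions = list(), solution = NULL),
                 class = "jei_session")
  s$solution <- solve_session(s)
  s
}

session_cost_matrix <- function(s) {
  total <- s$base + s$reject + s$mode_extra + s$refine_extra
  if (!is.null(s$global_anchor)) {
    ga <- s$global_anchor
    col <- total[, ga$column]
    col[-ga$level] <- col[-ga$level] + ANCHOR_COST
    total[, ga$column] <- col
  }
  total
}

solve_session <- function(s) {
  solve_surface(s$graph, session_cost_matrix(s))
}

snapshot_state <- function(s) {
  list(Th = s$Th, base = s$base, refine_extra = s$refine_extra,
       global_anchor = s$global_anchor, anchored = s$anchored,
       solution = s$solution)
}

restore_state <- function(s, snap) {
  s$Th <- snap$Th
  s$base <- snap$base
  s$refine_extra <- snap$refine_extra
  s$global_anchor <- snap$global_anchor
  s$anchored <- snap$anchored
  s$solution <- snap$solution
  s
}

#' @export
print.jei_session <- function(x, ...) {
  cat(sprintf(
    "jei_session: %d columns, Th = %.4g, %d action(s) on stack\n",
    x$graph$n_column, x$Th, length(x$actions)))
  if (!is.null(x$solution))
    cat(sprintf("  current objective %.6g\n", x$solution$objective))
  invisible(x)
}

#' Global refinement: reset the threshold through a boundary point
#'
#' The uptake at the given point becomes the new threshold; base costs are
#' rebuilt and the surface is forced through the node nearest the point.
#' A later global refinement overrides an earlier one.
#'
#' @param session a \code{\link{jei_session}}.
#' @param point world mm coordinate the boundary should pass through.
#' @return the updated session (re-solved).
#' @export
global_refine <- function(session, point) {
  s <- session
  new_th <- sample_uptake(s$vol, point)
  if (new_th >= s$center_uptake)
    stop("global_refine: uptake at the refinement point (",
         signif(new_th, 4), ") is not below the center uptake (",
         signif(s$center_uptake, 4), ")")
  snap <- snapshot_state(s)
  anchor <- nearest_node(s$graph, point)
  s$Th <- new_th
  s$base <- matrix(base_cost(s$up, new_th, s$env, s$center_uptake),
                   s$graph$n_node, s$graph$n_column)
  s$global_anchor <- list(column = anchor$column, level = anchor$level)
  s$solution <- solve_session(s)
  s$actions <- c(s$actions, list(list(kind = "global",
                                      point = as.numeric(point),
                                      anchor = anchor, snapshot = snap)))
  s
}

#' Find columns with uptake patterns similar to an anchor node
#'
#' Breadth-first search over column adjacency up to graph distance 5 from
#' the anchor column. A candidate node (column \code{i}, level \code{j})
#' matches when the summed absolute difference of the uptake profiles over
#' a clamped window of +/-3 levels is below 5\% of the candidate's own
#' profile magnitude, and \code{|j - j_anchor| <= ds(i)}. Per column the
#' lowest-difference candidate is kept. Columns skipped for dissimilarity
#' are re-included when at least two thirds of their immediate neighbors
#' matched (closing), taking their lowest-difference candidate.
#'
#' @param session a \code{\link{jei_session}}.
#' @param anchor list with \code{column} and \code{level} of the anchor
#'   node.
#' @param max_ds BFS depth bound (default 5).
#' @return data frame with columns \code{column}, \code{level}, \code{ds},
#'   \code{smc} — the matched node per selected column (anchor column
#'   excluded).
#' @export
find_similar_columns <- function(session, anchor, max_ds = 5L) {
  s <- session
  up <- s$up
  n <- s$graph$n_node
  iL <- anchor$column
  jL <- anchor$level
  ds_all <- column_bfs(s$graph, iL, max_depth = max_ds)
  cand_cols <- which(is.finite(ds_all) & seq_len(s$graph$n_column) != iL)
  win <- -3:3
  ref <- up[pmin(pmax(jL + win, 1L), n), iL]
  best <- lapply(cand_cols, function(i) {
    ds <- ds_all[i]
    jcand <- (jL - ds):(jL + ds)
    jcand <- jcand[jcand >= 1 & jcand <= n]
    if (length(jcand) == 0) return(NULL)
    smc <- vapply(jcand, function(j) {
      prof <- up[pmin(pmax(j + win, 1L), n), i]
      sum(abs(prof - ref))
    }, numeric(1))
    th_sim <- vapply(jcand, function(j) {
      prof <- up[pmin(pmax(j + win, 1L), n), i]
      0.05 * sum(abs(prof))
    }, numeric(1))
    k <- which.min(smc)
    data.frame(column = i, level = jcand[k], ds = ds, smc = smc[k],
               similar = smc[k] < th_sim[k])
  })
  best <- do.call(rbind, best)
  if (is.null(best)) {
    return(data.frame(column = integer(0), level = integer(0),
                      ds = integer(0), smc = numeric(0)))
  }
  selected <- best[best$similar, , drop = FALSE]
  # closing: re-include a skipped column if >= 2/3 of its mesh neighbors
  # were selected by similarity
  skipped <- best[!best$similar, , drop = FALSE]
  if (nrow(skipped) > 0) {
    sel_set <- c(selected$column, iL)
    readd <- vapply(seq_len(nrow(skipped)), function(k) {
      nb <- s$graph$adjacency[[skipped$column[k]]]
      mean(nb %in% sel_set) >= 2 / 3
    }, logical(1))
    selected <- rbind(selected, skipped[readd, , drop = FALSE])
  }
  selected[order(selected$column), c("column", "level", "ds", "smc")]
}

# triangular cost well of depth `a`, half-width growing with graph
# distance w: notch(j, c, a, w) = -a * max(0, 1 - |j - c| / (w + 1))
notch_well <- function(j, center, depth, width) {
  -depth * pmax(0, 1 - abs(j - center) / (width + 1))
}

#' Local refinement: pin the surface through a point and guide neighbors
#'
#' The nearest column is anchored to the nearest node (cost 1000 on its
#' other nodes). Matched similar columns receive a triangular notch-shaped
#' cost decrease of depth 3 centered on their matched level, wider for
#' columns farther (in graph distance) from the anchor. Cost changes from
#' successive local refinements accumulate, but columns already anchored
#' by a user point are never modified again (a new anchor on such a
#' column replaces its anchor level).
#'
#' @param session a \code{\link{jei_session}}.
#' @param point world mm coordinate the boundary should pass through.
#' @param notch_depth depth of the similarity notch (default 3).
#' @return the updated session (re-solved).
#' @export
local_refine <- function(session, point, notch_depth = 3) {
  s <- session
  snap <- snapshot_state(s)
  anchor <- nearest_node(s$graph, point)
  iL <- anchor$column; jL <- anchor$level
  n <- s$graph$n_node
  matched <- find_similar_columns(s, anchor)
  # anchor column: 1000 everywhere except the anchored level (replaces any
  # previous anchor term on this column)
  s$refine_extra[, iL] <- 0
  s$refine_extra[-jL, iL] <- ANCHOR_COST
  # notch wells on matched columns, skipping user-anchored columns
  for (k in seq_len(nrow(matched))) {
    i <- matched$column[k]
    if (i %in% s$anchored || i == iL) next
    s$refine_extra[, i] <- s$refine_extra[, i] +
      notch_well(seq_len(n), matched$level[k], notch_depth, matched$ds[k])
  }
  s$anchored <- unique(c(s$anchored, iL))
  s$solution <- solve_session(s)
  s$actions <- c(s$actions, list(list(kind = "local",
                                      point = as.numeric(point),
                                      anchor = anchor,
                                      matched = matched, snapshot = snap)))
  s
}

#' Undo the most recent refinement action
#'
#' Restores the session state recorded before that action (threshold,
#' costs and solution), bit-exactly. An empty stack is a warning no-op.
#'
#' @param session a \code{\link{jei_session}}.
#' @return the updated session.
#' @export
undo_refinement <- function(session) {
  s <- session
  if (length(s$actions) == 0) {
    warning("undo_refinement: no actions to undo")
    return(s)
  }
  last <- s$actions[[length(s$actions)]]
  s <- restore_state(s, last$snapshot)
  s$actions <- s$actions[-length(s$actions)]
  s
}

#' Replay a refinement action log
#'
#' @param session a fresh \code{\link{jei_session}}.
#' @param actions data frame (or list of lists) with columns \code{kind}
#'   (\code{"global"}, \code{"local"}, \code{"undo"}) and \code{x, y, z}
#'   (mm; ignored for undo).
#' @return the session after all actions.
#' @export
apply_actions <- function(session, actions) {
  if (is.data.frame(actions))
    actions <- lapply(seq_len(nrow(actions)), function(k) as.list(actions[k, ]))
  for (k in seq_along(actions)) {
    act <- actions[[k]]
    session <- switch(as.character(act$kind),
      global = global_refine(session, c(act$x, act$y, act$z)),
      local = local_refine(session, c(act$x, act$y, act$z)),
      undo = undo_refinement(session),
      stop("apply_actions: unknown action kind '", act$kind,
           "' at entry ", k))
  }
  session
}
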