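#' Filter a gene panel by expression fraction
#'
#' Keeps genes expressed (count > 0) by at least `min_frac` of cells,
#' preserving the input order. An empty result is returned with a warning.
#'
#' @param m a [tam_counts] object.
#' @param genes candidate gene ids.
#' @param min_frac minimum expressing-cell fraction (default 0.05).
#' @return Character vector of retained gene ids.
#' @export
filter_panel <- function(m, genes, min_frac = 0.05) {
  frac <- suppressWarnings(expression_fraction(m, genes))
  out <- genes[frac[genes] >= min_frac]
  if (!length(out)) warning("no genes pass the ", min_frac, " expression filter")
  out
}

#' Receptors paired with retained ligands, expression-filtered
#'
#' Looks up the receptors partnered with at least one retained ligand in the
#' pair table (deduplicated, first-appearance order) and then applies the
#' same expression-fraction filter used for ligands.
#'
#' @param ligands retained (already filtered) ligand ids.
#' @param pairs ligand-receptor pair table (columns `ligand`, `receptor`).
#' @param m a [tam_counts] object.
#' @param min_frac minimum expressing-cell fraction (default 0.05).
#' @return Character vector of retained receptor ids.
#' @export
pair_receptors <- function(ligands, pairs, m, min_frac = 0.05) {
  rec <- unique(pairs$receptor[pairs$ligand %in% ligands])
  filter_panel(m, rec, min_frac = min_frac)
}

#' Number of panel genes expressed per cell
#'
#' @param m a [tam_counts] object.
#' @param panel non-empty gene id vector.
#' @return Named integer vector (one entry per cell).
#' @export
per_cell_density <- function(m, panel) {
  stopifnot(inherits(m, "tam_counts"), length(panel) > 0)
  present <- intersect(panel, rownames(m$counts))
  if (!length(present))
    return(stats::setNames(integer(ncol(m$counts)), colnames(m$counts)))
  d <- Matrix::colSums(m$counts[present, , drop = FALSE] > 0)
  stats::setNames(as.integer(d), colnames(m$counts))
}

#' Compare per-cell panel densities between two groups of states
#'
#' @param densities per-cell densities from [per_cell_density].
#' @param groups per-cell group labels aligned with `densities`.
#' @param contrast list of two character vectors of group labels
#'   (side A, side B).
#' @return List with `mean_A`, `mean_B` and the two-sided Mann-Whitney `p`.
#' @export
density_by_group <- function(densities, groups, contrast) {
  stopifnot(length(densities) == length(groups), length(contrast) == 2)
  a <- densities[groups %in% contrast[[1]]]
  b <- densities[groups %in% contrast[[2]]]
  if (!length(a) || !length(b)) stop("empty contrast side")
  list(mean_A = mean(a), mean_B = mean(b), p = mannwhitney(a, b)$p)
}

#' Build the layered activation-state / ligand / receptor graph
#'
#' Directed weighted tri-layer graph: state-to-ligand edges weighted by the
#' fraction of cells of that state expressing the ligand, ligand-to-receptor
#' edges (weight 1) for each pair-table row among retained panels, and
#' receptor-to-state edges weighted by the expressing fraction of the
#' receptor in that state. States with zero cells get weight-0 edges with a
#' warning.
#'
#' @param m a [tam_counts] object.
#' @param states per-cell activation-state labels.
#' @param ligands,receptors retained (filtered) panel gene ids.
#' @param pairs ligand-receptor pair table.
#' @return A `ligrec_graph`: list with `states`, `ligands`, `receptors`,
#'   `sl` (state x ligand weight matrix), `rs` (receptor x state weight
#'   matrix) and `lr` (pair data.frame restricted to the panels, with a
#'   `weight` column of 1).
#' @export
build_graph <- function(m, states, ligands, receptors, pairs) {
  stopifnot(inherits(m, "tam_counts"), length(states) == ncol(m$counts))
  states <- as.factor(states)
  lev <- levels(states)
  if (any(table(states) == 0))
    warning("state(s) with zero cells get weight-0 edges: ",
            paste(lev[table(states) == 0], collapse = ", "))
  expr_frac_by_state <- function(panel) {
    out <- matrix(0, length(lev), length(panel), dimnames = list(lev, panel))
    present <- intersect(panel, rownames(m$counts))
    for (s in lev) {
      idx <- which(states == s)
      if (length(idx) && length(present))
        out[s, present] <-
          Matrix::rowSums(m$counts[present, idx, drop = FALSE] > 0) /
          length(idx)
    }
    out
  }
  sl <- expr_frac_by_state(ligands)
  rs <- t(expr_frac_by_state(receptors))
  lr <- pairs[pairs$ligand %in% ligands & pairs$receptor %in% receptors, ,
              drop = FALSE]
  lr$weight <- rep(1, nrow(lr))
  structure(list(states = lev, ligands = ligands, receptors = receptors,
                 sl = sl, rs = rs, lr = lr),
            class = "ligrec_graph")
}

#' @export
print.ligrec_graph <- function(x, ...) {
  cat("ligrec_graph: ", length(x$states), " states, ", length(x$ligands),
      " ligands, ", length(x$receptors), " receptors, ", nrow(x$lr),
      " pairs\n", sep = "")
  invisible(x)
}

#' Loop importance of a ligand or receptor for an activation state
#'
#' A qualifying loop is the 3-edge cycle state -> ligand -> receptor ->
#' state. The importance of a receptor for a state is the sum, over ligands
#' paired with it, of the loop weight; symmetrically for a ligand over its
#' paired receptors. The default loop weight is the *sum* of the three edge
#' weights; `combine = "product"` multiplies them instead. Nodes with no
#' qualifying loop have importance 0.
#'
#' @param g a `ligrec_graph`.
#' @param node a ligand or receptor id present in the graph.
#' @param state an activation-state label present in the graph.
#' @param combine `"sum"` (default) or `"product"` loop-weight convention.
#' @return Non-negative importance value.
#' @export
loop_importance <- function(g, node, state, combine = c("sum", "product")) {
  combine <- match.arg(combine)
  stopifnot(inherits(g, "ligrec_graph"))
  if (!state %in% g$states) stop("unknown state: ", state)
  is_rec <- node %in% g$receptors
  is_lig <- node %in% g$ligands
  if (!is_rec && !is_lig) stop("unknown node: ", node)
  loops <- if (is_rec) g$lr[g$lr$receptor == node, , drop = FALSE]
           else g$lr[g$lr$ligand == node, , drop = FALSE]
  if (!nrow(loops)) return(0)
  w <- vapply(seq_len(nrow(loops)), function(i) {
    e <- c(g$sl[state, loops$ligand[i]], loops$weight[i],
           g$rs[loops$receptor[i], state])
    if (combine == "sum") sum(e) else prod(e)
  }, 0)
  sum(w)
}

#' Rank ligands and receptors by loop importance for one state
#'
#' Importance is computed with [loop_importance]; nodes are sorted in
#' descending importance with ties broken deterministically by node id, and
#' tied importances share the smaller rank (competition ranking).
#'
#' @param g a `ligrec_graph`.
#' @param state activation-state label.
#' @param combine loop-weight convention passed to [loop_importance].
#' @return List of two data.frames (`receptors`, `ligands`) with columns
#'   `node`, `importance`, `rank`.
#' @export
rank_nodes <- function(g, state, combine = c("sum", "product")) {
  combine <- match.arg(combine)
  rank_one <- function(nodes) {
    imp <- vapply(nodes, loop_importance, 0, g = g, state = state,
                  combine = combine)
    ord <- order(-imp, nodes)
    imp <- imp[ord]; nodes <- nodes[ord]
    rk <- rank(-imp, ties.method = "min")
    data.frame(node = nodes, importance = imp, rank = as.integer(rk),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(receptors = rank_one(g$receptors), ligands = rank_one(g$ligands))
}

#' Export a ligrec graph as an edge list
#'
#' @param g a `ligrec_graph`.
#' @return data.frame with columns `src`, `dst`, `layer`
#'   (`state_ligand`, `ligand_receptor`, `receptor_state`) and `weight`.
#' @export
graph_edge_list <- function(g) {
  stopifnot(inherits(g, "ligrec_graph"))
  sl <- expand.grid(src = g$states, dst = g$ligands,
                    stringsAsFactors = FALSE)
  sl$layer <- "state_ligand"
  sl$weight <- g$sl[cbind(sl$src, sl$dst)]
  lr <- data.frame(src = g$lr$ligand, dst = g$lr$receptor,
                   layer = "ligand_receptor", weight = g$lr$weight)
  rs <- expand.grid(src = g$receptors, dst = g$states,
                    stringsAsFactors = FALSE)
  rs$layer <- "receptor_state"
  rs$weight <- g$rs[cbind(rs$src, rs$dst)]
  rbind(sl, lr, rs)
}
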