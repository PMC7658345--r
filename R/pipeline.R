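#' Validate a pipeline configuration
#'
#' A configuration is a flat named list (YAML-compatible; see
#' [read_pipeline_config]) with input paths and stage parameters. Inputs can
#' be given either as paths (`counts`, `signatures`, `pairs`, optionally
#' `bulk` + `bulk_meta`) or as an in-memory `dataset` (the output of
#' [simulate_tam_cells]), which takes precedence. Referenced files must
#' exist at validation time.
#'
#' @param cfg named list.
#' @return The validated config with defaults filled in.
#' @export
validate_pipeline_config <- function(cfg) {
  defaults <- list(seed = 1, min_cells_gene = 10, depth_sd = 2,
                   min_frac = 0.05, top_n_ordering = 1000,
                   latent_dim = 2, lambda = NULL, K = NULL,
                   min_dp_clusters = 4, prune_min_frac = 0.05, out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$dataset)) {
    req <- c("counts", "signatures", "pairs")
    miss <- setdiff(req, names(cfg))
    if (length(miss))
      stop("config missing required input(s): ", paste(miss, collapse = ", "))
    for (nm in intersect(c("counts", "signatures", "pairs", "bulk",
                           "bulk_meta"), names(cfg)))
      if (!file.exists(cfg[[nm]]))
        stop("config input '", nm, "' does not exist: ", cfg[[nm]])
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path path to a YAML file of flat key-value pairs.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

# short deterministic hash of the parameter list, for artifact headers
param_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), c("dataset", "out_dir"))]),
             collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 0xFFFFFFF)
}

write_artifact <- function(df, path, seed, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# seed=%d param_hash=%s", seed, hash), con)
  utils::write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  close(con)
}

log_stage <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

#' Cells downstream of a branch point, labelled by output branch
#'
#' Given a rooted tree, splits the cells lying beyond a branch point into
#' the two output subtrees (label `A` for the subtree whose adjacent node
#' has the smaller index, `B` for the other). For branch points of degree
#' above 3 the two largest output subtrees are used.
#'
#' @param t a rooted `principal_tree` (after [order_pseudotime]).
#' @param branch_point node index; defaults to the branch point nearest the
#'   root.
#' @return Factor (`A`/`B`) named by cell id, covering downstream cells
#'   only.
#' @export
branch_assignments <- function(t, branch_point = NULL) {
  stopifnot(inherits(t, "principal_tree"), !is.null(t$root_node))
  if (!length(t$branch_points)) stop("tree has no branch point")
  g <- tree_graph(t)
  droot <- igraph::distances(g, v = t$root_node)[1, ]
  if (is.null(branch_point))
    branch_point <- t$branch_points[which.min(droot[t$branch_points])]
  nb <- as.integer(igraph::neighbors(g, branch_point))
  # the neighbour on the root path is the input side
  paths <- igraph::shortest_paths(g, from = t$root_node, to = branch_point)
  path_nodes <- as.integer(paths$vpath[[1]])
  input_nb <- if (length(path_nodes) >= 2)
    path_nodes[length(path_nodes) - 1] else integer(0)
  outs <- setdiff(nb, input_nb)
  subtree <- function(start) {
    g2 <- igraph::delete_vertices(g, branch_point)
    comp <- igraph::components(g2)
    nodes <- as.integer(igraph::V(g2)$name)[comp$membership ==
                                              comp$membership[which(
                                                as.integer(igraph::V(g2)$name) == start)]]
    nodes
  }
  subs <- lapply(outs, subtree)
  if (length(subs) > 2) {
    sizes <- vapply(subs, function(s) sum(t$cell_node %in% s), 0L)
    keep <- order(-sizes)[1:2]
    subs <- subs[keep]; outs <- outs[keep]
  }
  ord <- order(outs)
  subs <- subs[ord]
  lab <- rep(NA_character_, length(t$cell_node))
  lab[t$cell_node %in% subs[[1]]] <- "A"
  lab[t$cell_node %in% subs[[2]]] <- "B"
  out <- factor(lab[!is.na(lab)], levels = c("A", "B"))
  names(out) <- names(t$cell_node)[!is.na(lab)]
  out
}

#' Run the regional TAM analysis pipeline
#'
#' Executes the full stage sequence on the cells of one region: QC filters,
#' log-normalization with tumor-label regression, activation scoring
#' (MPI/AMDI quadrants), composition counts, ligand-receptor densities and
#' loop-importance ranking, ontogeny scores, Census normalization, ordering-
#' gene selection via density-peak clustering, principal-tree pseudotime
#' rooted at the lowest-AMDI state, score-pseudotime correlations, and
#' branch-dependent gene-program discovery at the branch point nearest the
#' root. When `cfg$out_dir` is set, TSV artifacts (with seed and parameter-
#' hash headers) and a JSON run summary are written; re-running with the
#' same config and seed reproduces them byte-identically.
#'
#' @param cfg validated config (see [validate_pipeline_config]); inputs come
#'   from `cfg$dataset` or from the configured paths.
#' @param region `"core"` or `"periphery"`.
#' @return Invisible list bundle with elements `activation`, `composition`,
#'   `ligrec`, `ontogeny`, `tree`, `correlations`, `branch` and `summary`.
#' @export
run_regional_analysis <- function(cfg, region = c("core", "periphery")) {
  region <- match.arg(region)
  cfg <- validate_pipeline_config(cfg)
  hash <- param_hash(cfg)
  set.seed(cfg$seed)
  log_stage("ingest", "loading inputs")
  if (!is.null(cfg$dataset)) {
    ds <- cfg$dataset
    counts <- ds$counts; sigs <- ds$signatures; pairs <- ds$pairs
  } else {
    counts <- read_counts(cfg$counts, format = "mtx")
    sigs <- read_gmt(cfg$signatures)
    pairs <- read_pair_table(cfg$pairs)
  }
  need <- c("pol_pos", "pol_neg", "dif_pos", "dif_neg", "bmdm", "mg",
            "ligands", "receptors")
  miss <- setdiff(need, names(sigs))
  if (length(miss))
    stop("signature collection missing set(s): ", paste(miss, collapse = ", "))
  counts <- subset_counts(counts, cells = counts$cell_meta$region == region)
  if (!ncol(counts$counts)) stop("no cells in region '", region, "'")

  log_stage("ingest", "QC filters")
  counts <- filter_genes_min_cells(counts, cfg$min_cells_gene)
  counts <- filter_cells_depth_outliers(counts, cfg$depth_sd)
  norm <- lognormalize(counts)
  norm <- regress_out_label(norm, counts$cell_meta$tumor_id)

  log_stage("scores", "activation profile")
  act <- activation_scores(norm, sigs$pol_pos, sigs$pol_neg,
                           sigs$dif_pos, sigs$dif_neg)
  comp <- data.frame(state = levels(act$state),
                     n = as.integer(table(act$state)),
                     pct = round(as.integer(table(act$state)) /
                                   nrow(act) * 100, 1))

  log_stage("ligrec", "panel filtering and graph")
  ligands <- filter_panel(counts, sigs$ligands, cfg$min_frac)
  receptors <- pair_receptors(ligands, pairs, counts, cfg$min_frac)
  lig_density <- per_cell_density(counts, ligands)
  rec_density <- if (length(receptors))
    per_cell_density(counts, receptors) else NULL
  imm <- list(c("M0", "M1-pre"), c("M1-like", "M2-like"))
  lig_contrast <- density_by_group(lig_density, as.character(act$state), imm)
  graph <- build_graph(counts, act$state, ligands, receptors, pairs)
  ranks <- lapply(stats::setNames(graph$states, graph$states),
                  function(s) rank_nodes(graph, s))

  log_stage("ontogeny", "BMDM/microglia scores")
  ont <- ontogeny_scores(norm, sigs$bmdm, sigs$mg)

  log_stage("trajectory", "Census, ordering genes, principal tree")
  census <- census_normalize(counts)
  expressed <- filter_panel(counts, rownames(counts$counts), cfg$min_frac)
  emb_all <- embed_tsne(tam_norm(norm$values[expressed, , drop = FALSE],
                                 transforms = norm$transforms),
                        seed = cfg$seed)
  dp <- density_peak_cluster(emb_all, min_peaks = cfg$min_dp_clusters)
  ordering <- select_ordering_genes(census, dp$cluster,
                                    top_n = cfg$top_n_ordering,
                                    min_frac = cfg$min_frac)
  tree <- fit_principal_tree(
    tam_norm(norm$values[intersect(ordering, rownames(norm$values)), ,
                         drop = FALSE], transforms = norm$transforms),
    latent_dim = cfg$latent_dim, K = cfg$K, seed = cfg$seed,
    lambda = cfg$lambda)
  tree <- assign_states(tree, prune_min_frac = cfg$prune_min_frac)
  tree <- order_pseudotime(tree, act$AMDI)
  cors <- list(
    amdi = correlate_score_pseudotime(tree$pseudotime, act$AMDI),
    mpi = correlate_score_pseudotime(tree$pseudotime, act$MPI))

  log_stage("branching", "branch-dependent genes")
  branch_res <- NULL
  if (length(tree$branch_points)) {
    ba <- branch_assignments(tree)
    down <- names(ba)
    if (all(table(ba) >= 20)) {
      sub_counts <- subset_counts(counts, cells = down)
      bt <- branch_dependence_test(sub_counts, tree$pseudotime[down], ba)
      dep <- bt$gene[bt$branch_dependent]
      branch_res <- list(test = bt, assignments = ba)
      if (length(dep) >= 2) {
        sub_norm <- tam_norm(norm$values[, down, drop = FALSE],
                             transforms = norm$transforms)
        curves <- smooth_curves(sub_norm, tree$pseudotime[down], ba, dep)
        cl <- cluster_branch_genes(curves)
        divg <- divergent_clusters(cl, sub_norm, tree$pseudotime[down], ba)
        branch_res$clusters <- cl
        branch_res$divergence <- divg
      }
    } else {
      warning("branch sides have < 20 cells; branch analysis skipped")
    }
  } else {
    warning("no branch point recovered; branch analysis skipped")
  }

  summary <- list(region = region, seed = cfg$seed, param_hash = hash,
                  n_cells = ncol(counts$counts),
                  n_genes = nrow(counts$counts),
                  n_states = tree$n_states,
                  n_branch_points = length(tree$branch_points),
                  cor_amdi_pseudotime = cors$amdi$r,
                  cor_mpi_pseudotime = cors$mpi$r,
                  mean_ligand_density = mean(lig_density),
                  mean_receptor_density = if (is.null(rec_density)) NA
                                          else mean(rec_density),
                  n_branch_dependent =
                    if (is.null(branch_res)) NA_integer_
                    else sum(branch_res$test$branch_dependent))

  bundle <- list(activation = act, composition = comp,
                 ligrec = list(ligands = ligands, receptors = receptors,
                               density_contrast = lig_contrast,
                               graph = graph, ranks = ranks),
                 ontogeny = ont, tree = tree, correlations = cors,
                 branch = branch_res, summary = summary)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, nm) write_artifact(df, file.path(cfg$out_dir, nm),
                                         cfg$seed, hash)
    w(act, paste0(region, "_activation.tsv"))
    w(comp, paste0(region, "_composition.tsv"))
    w(ont, paste0(region, "_ontogeny.tsv"))
    w(data.frame(cell_id = names(tree$pseudotime),
                 state = tree$cell_state,
                 pseudotime = tree$pseudotime),
      paste0(region, "_pseudotime.tsv"))
    w(tree$edges, paste0(region, "_tree_edges.tsv"))
    if (!is.null(branch_res))
      w(branch_res$test, paste0(region, "_branch_test.tsv"))
    json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, na = "null")
    writeLines(json, file.path(cfg$out_dir,
                               paste0(region, "_summary.json")))
  }
  invisible(bundle)
}

#' Composition report with regional chi-squared tests
#'
#' Formats per-label counts, percentages and core-vs-periphery chi-squared
#' p-values the way a demographic table prints them. With a single region
#' present, the p column is blank and a note is attached.
#'
#' @param labels per-cell (or per-sample) category labels.
#' @param regions aligned region labels.
#' @return data.frame report; attribute `note` explains a blank p column.
#' @export
run_table_stats <- function(labels, regions) {
  regions <- as.character(regions)
  if (length(unique(regions)) < 2) {
    tab <- table(labels)
    out <- data.frame(state = names(tab), all_n = as.integer(tab),
                      all_pct = round(as.integer(tab) / sum(tab) * 100),
                      p = NA_real_)
    attr(out, "note") <- "single region; chi-squared not computed"
    return(out)
  }
  composition_table(labels, regions)
}
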