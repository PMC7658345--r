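# Natural-spline basis robust to heavily tied pseudotime: interior knots at
# the quartiles, dropping any knot that collides with a boundary; degenerate
# supports fall back to a linear basis.
ns_basis_safe <- function(x, df = 3) {
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75))
  knots <- unique(qs[qs > min(x) & qs < max(x)])
  if (length(knots) >= 1)
    splines::ns(x, knots = knots)
  else
    matrix(x, ncol = 1, dimnames = list(NULL, "linear"))
}

#' Branch-dependent gene test
#'
#' For cells downstream of one branch point (two output states A and B),
#' tests every gene for branch-dependent expression dynamics: a negative-
#' binomial GLM with a natural-spline basis of pseudotime (df = 3) crossed
#' with the branch label is compared against the spline-only model by
#' likelihood ratio. Pseudotime is first rescaled to 0-100 *within each
#' branch* so that output arms of different geodesic length are comparable
#' (the same convention the smoothed-curve heatmaps use); without this, a
#' pseudotime-only spline can absorb genuine branch differences whenever
#' one arm extends further than the other. Per-gene dispersion is
#' estimated by method of moments
#' (floored at 1e-4) and held fixed in both fits. P-values use a chi-square
#' with the difference in parameter count (4) and are BH-adjusted; genes
#' with q < 0.05 are flagged branch-dependent. Genes expressed in fewer
#' than `min_cells` downstream cells are excluded from testing.
#'
#' @param m a [tam_counts] restricted to the downstream cells (values are
#'   rounded to integers for the NB likelihood).
#' @param pseudotime per-cell pseudotime for those cells.
#' @param branch per-cell branch label, exactly two levels (e.g. "A", "B"),
#'   each with at least 20 cells.
#' @param min_cells expression filter (default 10).
#' @return A `branch_test_result` data.frame: `gene`, `lrt_stat`, `p`, `q`,
#'   `branch_dependent`.
#' @export
branch_dependence_test <- function(m, pseudotime, branch, min_cells = 10) {
  stopifnot(inherits(m, "tam_counts"))
  branch <- factor(as.character(branch))
  stopifnot(length(pseudotime) == ncol(m$counts),
            length(branch) == ncol(m$counts))
  if (nlevels(branch) != 2) stop("branch must have exactly two levels")
  if (any(table(branch) < 20)) stop("each branch needs at least 20 cells")
  cmat <- round(as.matrix(m$counts))
  keep <- rowSums(cmat > 0) >= min_cells
  cmat <- cmat[keep, , drop = FALSE]
  if (!nrow(cmat)) stop("no genes pass the expression filter")
  pt_scaled <- stats::ave(pseudotime, branch, FUN = function(z) {
    if (diff(range(z)) == 0) rep(50, length(z))
    else (z - min(z)) / diff(range(z)) * 100
  })
  ns_basis <- ns_basis_safe(pt_scaled)
  x0 <- cbind(1, ns_basis)
  x1 <- cbind(x0, branch == levels(branch)[2],
              ns_basis * (branch == levels(branch)[2]))
  df_diff <- ncol(x1) - ncol(x0)
  res <- t(apply(cmat, 1, function(y) {
    theta <- 1 / mom_dispersion(y)
    fam <- MASS::negative.binomial(theta)
    f0 <- try(suppressWarnings(stats::glm.fit(x0, y, family = fam)),
              silent = TRUE)
    f1 <- try(suppressWarnings(stats::glm.fit(x1, y, family = fam)),
              silent = TRUE)
    if (inherits(f0, "try-error") || inherits(f1, "try-error"))
      return(c(NA_real_, NA_real_))
    ll <- function(f) sum(stats::dnbinom(y, size = theta,
                                         mu = pmax(f$fitted.values, 1e-8),
                                         log = TRUE))
    stat <- max(0, 2 * (ll(f1) - ll(f0)))
    c(stat, stats::pchisq(stat, df = df_diff, lower.tail = FALSE))
  }))
  out <- data.frame(gene = rownames(cmat), lrt_stat = res[, 1], p = res[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[!is.na(out$p), , drop = FALSE]
  out$q <- stats::p.adjust(out$p, "BH")
  out$branch_dependent <- out$q < 0.05
  class(out) <- c("branch_test_result", "data.frame")
  out
}

#' Smoothed per-branch expression curves on a common pseudotime grid
#'
#' For each branch, pseudotime is rescaled to 0-100 within the branch and a
#' natural-spline (df = 3) mean curve of log-normalized expression is fit
#' per gene, evaluated on a shared `grid_n`-point grid spanning 0 to 100.
#' Rows (genes) are standardized to mean 0 / SD 1 across the concatenated
#' branches for clustering; constant genes become zero rows.
#'
#' @param m a [tam_norm] restricted to the downstream cells (log scale).
#' @param pseudotime,branch per-cell vectors as in
#'   [branch_dependence_test].
#' @param genes genes to smooth (rownames of the output).
#' @param grid_n grid resolution (default 100).
#' @return List with one gene x grid matrix per branch level (standardized
#'   jointly), plus attribute `grid` (the 0-100 grid).
#' @export
smooth_curves <- function(m, pseudotime, branch, genes, grid_n = 100) {
  stopifnot(inherits(m, "tam_norm"))
  branch <- factor(as.character(branch))
  genes <- intersect(genes, rownames(m$values))
  if (!length(genes)) stop("no requested genes present")
  grid <- seq(0, 100, length.out = grid_n)
  curves <- lapply(levels(branch), function(b) {
    idx <- which(branch == b)
    pt <- pseudotime[idx]
    rng <- range(pt)
    pt100 <- if (diff(rng) == 0) rep(50, length(pt))
             else (pt - rng[1]) / diff(rng) * 100
    basis <- ns_basis_safe(pt100)
    xg <- if (is.matrix(basis) && !inherits(basis, "ns"))
      cbind(1, grid) else cbind(1, stats::predict(basis, grid))
    xd <- cbind(1, basis)
    beta <- qr.coef(qr(xd), t(m$values[genes, idx, drop = FALSE]))
    beta[is.na(beta)] <- 0
    t(xg %*% beta)
  })
  names(curves) <- levels(branch)
  joint <- do.call(cbind, curves)
  mu <- rowMeans(joint)
  sdv <- apply(joint, 1, stats::sd)
  flat <- sdv <= 1e-8 * (abs(mu) + 1)   # constant up to floating noise
  std <- lapply(curves, function(cc) {
    z <- (cc - mu) / ifelse(flat, 1, sdv)
    z[flat, ] <- 0
    rownames(z) <- genes
    z
  })
  attr(std, "grid") <- grid
  std
}

#' Cluster branch-dependent genes by curve shape
#'
#' Agglomerative (Ward) clustering of genes with distance one minus the
#' Pearson correlation of their concatenated per-branch smoothed curves.
#' When `k = "auto"` the cluster count maximizing the mean silhouette width
#' over k = 2..10 is chosen; if all curves are identical (silhouette
#' undefined) a single cluster is returned with a warning.
#'
#' @param curves output of [smooth_curves].
#' @param k cluster count, or `"auto"` (default).
#' @return A `gene_curve_cluster`: list with `cluster` (named integer
#'   vector), `n_clusters`, `curves`.
#' @export
cluster_branch_genes <- function(curves, k = "auto") {
  joint <- do.call(cbind, curves)
  n_genes <- nrow(joint)
  if (n_genes < 2) stop("need at least 2 genes to cluster")
  if (!identical(k, "auto") && k > n_genes)
    stop("k exceeds the number of genes")
  cc <- suppressWarnings(stats::cor(t(joint)))
  cc[!is.finite(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  if (all(d < 1e-12)) {
    warning("all curves identical; forcing a single cluster")
    cl <- stats::setNames(rep(1L, n_genes), rownames(joint))
    return(structure(list(cluster = cl, n_clusters = 1L, curves = curves),
                     class = "gene_curve_cluster"))
  }
  hc <- stats::hclust(d, method = "ward.D2")
  if (identical(k, "auto")) {
    ks <- 2:min(10, n_genes - 1)
    sil <- vapply(ks, function(kk) {
      lab <- stats::cutree(hc, kk)
      if (length(unique(lab)) < 2) return(-Inf)
      mean(cluster::silhouette(lab, d)[, "sil_width"])
    }, 0)
    k <- ks[which.max(sil)]
  }
  cl <- stats::cutree(hc, k)
  structure(list(cluster = cl, n_clusters = as.integer(k), curves = curves),
            class = "gene_curve_cluster")
}

#' Divergent gene clusters at a branch point
#'
#' For each gene cluster, builds its meta-gene score among the terminal
#' cells of each branch (top `terminal_frac` of cells by pseudotime within
#' the branch; branches with fewer than 5 terminal cells use all their
#' cells, with a warning) and scores divergence as
#' `|mean_A - mean_B| / pooled SD`. Clusters with divergence >= `threshold`
#' are selected.
#'
#' @param cc a `gene_curve_cluster`.
#' @param m a [tam_norm] over the downstream cells (log scale).
#' @param pseudotime,branch per-cell vectors for those cells.
#' @param terminal_frac fraction of cells counted as terminal (default 0.1).
#' @param threshold divergence selection threshold in pooled-SD units
#'   (default 1).
#' @return data.frame: `cluster`, `n_genes`, `mean_A`, `mean_B`,
#'   `divergence`, `selected`.
#' @export
divergent_clusters <- function(cc, m, pseudotime, branch,
                               terminal_frac = 0.1, threshold = 1) {
  stopifnot(inherits(cc, "gene_curve_cluster"), inherits(m, "tam_norm"))
  branch <- factor(as.character(branch))
  stopifnot(nlevels(branch) == 2)
  term_idx <- lapply(levels(branch), function(b) {
    idx <- which(branch == b)
    n_term <- max(1, floor(terminal_frac * length(idx)))
    if (n_term < 5) {
      warning("branch ", b, " has < 5 terminal cells; using all its cells")
      return(idx)
    }
    idx[order(pseudotime[idx], decreasing = TRUE)[seq_len(n_term)]]
  })
  res <- lapply(sort(unique(cc$cluster)), function(k) {
    genes <- names(cc$cluster)[cc$cluster == k]
    sig_score <- if (all(rownames(m$values) %in% genes)) {
      # cluster covers the whole matrix: no complement, use the centered mean
      colMeans(m$values - rowMeans(m$values))
    } else metagene_score(m, genes, paste0("cluster", k))
    a <- sig_score[term_idx[[1]]]
    b <- sig_score[term_idx[[2]]]
    pooled <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
                     max(1, length(a) + length(b) - 2))
    div <- if (pooled > 0) abs(mean(a) - mean(b)) / pooled
           else if (mean(a) == mean(b)) 0 else Inf
    data.frame(cluster = k, n_genes = length(genes), mean_A = mean(a),
               mean_B = mean(b), divergence = div)
  })
  out <- do.call(rbind, res)
  out$selected <- out$divergence >= threshold
  out
}

#' Correlation between a cluster meta-gene and a pathway meta-gene
#'
#' @param mg_cluster,mg_pathway aligned per-cell meta-gene scores
#'   (n >= 3, non-constant).
#' @return List with Pearson `r` and two-sided `p`.
#' @export
pathway_correlation <- function(mg_cluster, mg_pathway) {
  stopifnot(length(mg_cluster) == length(mg_pathway),
            length(mg_cluster) >= 3)
  if (stats::sd(mg_cluster) == 0 || stats::sd(mg_pathway) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(mg_cluster, mg_pathway, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Local over-representation test of a gene cluster in a set collection
#'
#' One-sided hypergeometric (upper tail including the observed overlap) of
#' the cluster against each set in a GMT-style collection, restricted to a
#' gene universe, with BH adjustment across sets. Sets with no universe
#' intersection are skipped and noted in the `note` column.
#'
#' @param genes cluster gene ids (must be contained in `universe`).
#' @param collection named list of gene sets.
#' @param universe character vector of background gene ids.
#' @return data.frame: `set`, `set_size`, `overlap`, `p`, `q`, `note`.
#' @export
overrepresentation <- function(genes, collection, universe) {
  genes <- unique(genes)
  if (!all(genes %in% universe))
    stop("cluster genes must be contained in the universe")
  n_u <- length(unique(universe))
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    if (!length(set))
      return(data.frame(set = nm, set_size = 0L, overlap = 0L, p = NA_real_,
                        note = "no universe overlap; skipped",
                        stringsAsFactors = FALSE))
    ov <- length(intersect(genes, set))
    p <- stats::phyper(ov - 1, length(set), n_u - length(set),
                       length(genes), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = ov, p = p,
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- stats::p.adjust(out$p[tested], "BH")
  out[, c("set", "set_size", "overlap", "p", "q", "note")]
}

#' Meta-gene correlation in bulk samples of one region
#'
#' Scores each bulk sample with the cluster and pathway meta-genes (after
#' [normalize_bulk]) restricted to the requested mapped region, and returns
#' their Pearson correlation.
#'
#' @param expr genes x samples raw bulk matrix.
#' @param structures per-sample structure (or core/periphery) labels.
#' @param cluster_sig,pathway_sig gene id vectors.
#' @param region `"core"` or `"periphery"`; needs at least 3 samples there.
#' @return List with `r`, `p` and the per-sample `scores` data.frame.
#' @export
bulk_correlation <- function(expr, structures, cluster_sig, pathway_sig,
                             region = c("core", "periphery")) {
  region <- match.arg(region)
  expr <- as.matrix(expr)
  mapped <- if (all(structures %in% c("core", "periphery"))) structures
            else map_ivy_regions(structures)
  keep <- mapped == region
  if (sum(keep) < 3) stop("fewer than 3 samples in region '", region, "'")
  norm <- tam_norm(normalize_bulk(expr[, keep, drop = FALSE]),
                   transforms = "lognorm")
  sc <- data.frame(sample_id = colnames(norm$values),
                   mg_cluster = as.numeric(metagene_score(norm, cluster_sig)),
                   mg_pathway = as.numeric(metagene_score(norm, pathway_sig)),
                   stringsAsFactors = FALSE)
  ct <- pathway_correlation(sc$mg_cluster, sc$mg_pathway)
  list(r = ct$r, p = ct$p, scores = sc)
}
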