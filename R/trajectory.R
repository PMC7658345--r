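#' Census-style relative transcript counts
#'
#' Converts raw counts to relative transcript counts per cell: the per-cell
#' distribution of log relative expression (count/total over nonzero genes)
#' is smoothed with a Gaussian kernel density, its mode located, and the
#' cell rescaled so that the modal relative expression maps to one
#' transcript. The output is depth-invariant: proportional count profiles
#' give identical output. Cells with fewer than 10 nonzero genes cannot
#' support the density estimate and fall back to depth scaling with the
#' median modal scale of the remaining cells (warning).
#'
#' @param m a [tam_counts] object.
#' @return A [tam_counts]-shaped list with `counts` holding the (real
#'   valued, rounded to 6 digits) relative counts as a sparse matrix.
#' @export
census_normalize <- function(m) {
  stopifnot(inherits(m, "tam_counts"))
  cmat <- as.matrix(m$counts)
  tot <- colSums(cmat)
  if (any(tot == 0)) stop("zero-total cells must be filtered before Census")
  rel <- sweep(cmat, 2, tot, `/`)
  n_nonzero <- colSums(cmat > 0)
  modes <- rep(NA_real_, ncol(cmat))
  for (j in which(n_nonzero >= 10)) {
    lx <- log(rel[cmat[, j] > 0, j])
    d <- stats::density(lx)
    modes[j] <- exp(d$x[which.max(d$y)])
  }
  fallback <- is.na(modes)
  if (any(fallback)) {
    warning(sum(fallback), " cell(s) with < 10 nonzero genes use depth-",
            "scaling fallback")
    fill <- if (all(fallback)) 1e-4 else stats::median(modes[!fallback])
    modes[fallback] <- fill
  }
  out <- sweep(rel, 2, modes, `/`)
  structure(list(counts = methods::as(round(out, 6), "CsparseMatrix"),
                 cell_meta = m$cell_meta),
            class = "tam_counts")
}

#' Density-peak clustering in a 2-D embedding
#'
#' Computes for every point a local density `P` (Gaussian kernel, bandwidth
#' 0.2 times the median pairwise distance unless given) and the distance `D`
#' to the nearest point of higher density (the global density maximum gets
#' the maximum pairwise distance). Density peaks are points whose `D` lies
#' at or above its empirical `quantile` and whose `P` clears the
#' `density_floor` quantile; every other point inherits the cluster of its
#' nearest higher-density neighbour. (Requiring *both* statistics in the
#' top 5% sounds symmetric but leaves the second of two equally dense,
#' well-separated clusters undetected about half the time, because the
#' global top-5% of density is dominated by whichever cluster is
#' fractionally denser; the density term is better read as a noise floor,
#' which is how the decision-graph heuristic is used in practice.) Density
#' ties are broken by point index (earlier = denser). If fewer than
#' `min_peaks` points pass both thresholds, the points with the largest
#' gamma = P * D product (the standard density-peak decision-graph
#' criterion) are promoted to peaks so that at least `min_peaks` clusters
#' result; with the default `min_peaks = 1` this reduces to using the
#' global density maximum when nothing passes.
#'
#' @param points n x 2 numeric matrix of coordinates.
#' @param quantile peak threshold on `D` (default 0.95).
#' @param density_floor quantile of `P` a peak must clear (default 0.5).
#' @param bandwidth optional kernel bandwidth override.
#' @param min_peaks minimum number of peaks/clusters to return (default 1).
#' @return A `density_peak_result`: list with `P`, `D`, `peaks` (logical),
#'   `cluster` (integer labels), `bandwidth`.
#' @export
density_peak_cluster <- function(points, quantile = 0.95,
                                 density_floor = 0.5, bandwidth = NULL,
                                 min_peaks = 1) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 1) stop("need at least one point")
  if (n == 1)
    return(structure(list(P = 0, D = 0, peaks = TRUE, cluster = 1L,
                          bandwidth = NA_real_),
                     class = "density_peak_result"))
  dmat <- as.matrix(stats::dist(points))
  med <- stats::median(dmat[upper.tri(dmat)])
  if (is.null(bandwidth)) bandwidth <- 0.2 * med
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    # all points coincide: one cluster
    return(structure(list(P = rep(0, n), D = rep(0, n),
                          peaks = c(TRUE, rep(FALSE, n - 1)),
                          cluster = rep(1L, n), bandwidth = bandwidth),
                     class = "density_peak_result"))
  }
  P <- unname(rowSums(exp(-(dmat / bandwidth)^2 / 2))) - 1  # exclude self
  ord <- order(-P, seq_len(n))  # density order, ties by index
  D <- numeric(n)
  nn_higher <- integer(n)
  D[ord[1]] <- max(dmat)
  nn_higher[ord[1]] <- ord[1]
  for (k in 2:n) {
    i <- ord[k]
    prev <- ord[seq_len(k - 1)]
    j <- prev[which.min(dmat[i, prev])]
    D[i] <- dmat[i, j]
    nn_higher[i] <- j
  }
  p_thr <- stats::quantile(P, density_floor)
  d_thr <- stats::quantile(D, quantile)
  peaks <- P >= p_thr & D >= d_thr
  if (!any(peaks)) peaks[ord[1]] <- TRUE
  if (sum(peaks) < min_peaks) {
    gamma <- P * D
    gamma[D == 0] <- -Inf   # duplicates of a denser point cannot seed
    promote <- order(-gamma, seq_len(n))[seq_len(min(min_peaks, sum(D > 0)))]
    peaks[promote] <- TRUE
  }
  cluster <- integer(n)
  cluster[peaks] <- seq_len(sum(peaks))
  for (k in seq_len(n)) {
    i <- ord[k]
    if (!cluster[i]) cluster[i] <- cluster[nn_higher[i]]
  }
  structure(list(P = P, D = D, peaks = peaks, cluster = cluster,
                 bandwidth = bandwidth),
            class = "density_peak_result")
}

#' t-SNE embedding of cells
#'
#' Barnes-Hut t-SNE (via Rtsne) on the cells, used as the default 2-D
#' manifold step ahead of density-peak clustering. The embedding is seeded
#' and deterministic. Any function returning an n x 2 coordinate matrix can
#' be substituted for it.
#'
#' @param m a [tam_norm] object or genes x cells matrix.
#' @param dims output dimension (default 2).
#' @param perplexity t-SNE perplexity; reduced automatically when the cell
#'   count is small.
#' @param seed integer seed.
#' @return cells x dims coordinate matrix.
#' @export
embed_tsne <- function(m, dims = 2, perplexity = 30, seed = 1) {
  v <- if (inherits(m, "tam_norm")) m$values else as.matrix(m)
  n <- ncol(v)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  if (perplexity < 2) stop("too few cells for a t-SNE embedding")
  set.seed(seed)
  coords <- Rtsne::Rtsne(t(v), dims = dims, perplexity = perplexity,
                         check_duplicates = FALSE)$Y
  rownames(coords) <- colnames(v)
  coords
}

#' PCA embedding of cells
#'
#' Least-squares linear low-dimensional embedding; the default latent space
#' for the principal tree. Any embedding returning an n x 2 coordinate
#' matrix can be substituted.
#'
#' @param m a [tam_norm] object or genes x cells matrix.
#' @param dims number of components (default 2).
#' @return cells x dims coordinate matrix.
#' @export
embed_pca <- function(m, dims = 2) {
  v <- if (inherits(m, "tam_norm")) m$values else as.matrix(m)
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE, rank. = dims)
  coords <- pc$x[, seq_len(dims), drop = FALSE]
  rownames(coords) <- colnames(v)
  coords
}

# Negative-binomial log likelihood at the group-mean MLE with fixed theta.
nb_loglik_groups <- function(y, groups, theta) {
  mu <- stats::ave(y, groups, FUN = mean)
  mu <- pmax(mu, 1e-8)
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

# Method-of-moments NB dispersion (variance = mu + disp * mu^2), floored.
mom_dispersion <- function(y, floor = 1e-4) {
  mu <- mean(y)
  v <- stats::var(y)
  if (!is.finite(v) || mu <= 0) return(floor)
  max((v - mu) / mu^2, floor)
}

#' Select trajectory ordering genes by cluster-wise likelihood ratio
#'
#' For every gene (prefiltered to those expressed in at least `min_frac` of
#' cells), compares a negative-binomial model with per-cluster means against
#' an intercept-only model by likelihood ratio (dispersion estimated per
#' gene by method of moments, floored at 1e-4; with fixed dispersion the
#' per-group NB mean MLE is the group mean, so the test has closed form).
#' P-values come from a chi-square with (k - 1) degrees of freedom and are
#' BH-adjusted; the `top_n` genes by ascending q (ties by p, then gene id)
#' are returned. Clusters with fewer than 3 cells are merged into the
#' cluster with the nearest mean expression profile (warning).
#'
#' @param m a [tam_counts] object (raw or Census relative counts; values are
#'   rounded to integers for the NB likelihood).
#' @param clusters per-cell cluster labels (at least 2 distinct).
#' @param top_n number of genes to return (default 1000).
#' @param min_frac expression prefilter (default 0.05).
#' @return Character vector of gene ids, with the full test table in
#'   attribute `table` (gene, lrt_stat, p, q).
#' @export
select_ordering_genes <- function(m, clusters, top_n = 1000, min_frac = 0.05) {
  stopifnot(inherits(m, "tam_counts"))
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == ncol(m$counts))
  cmat <- round(as.matrix(m$counts))
  keep <- rowMeans(cmat > 0) >= min_frac
  cmat <- cmat[keep, , drop = FALSE]
  if (!nrow(cmat)) stop("no genes pass the expression prefilter")
  tab <- table(clusters)
  while (any(tab < 3) && length(tab) > 1) {
    small <- names(tab)[which.min(tab)]
    cent <- vapply(names(tab), function(cl)
      rowMeans(cmat[, clusters == cl, drop = FALSE]), numeric(nrow(cmat)))
    dists <- colSums((cent - cent[, small])^2)
    target <- names(sort(dists))[2]
    warning("cluster '", small, "' (< 3 cells) merged into '", target, "'")
    clusters[clusters == small] <- target
    tab <- table(clusters)
  }
  if (length(tab) < 2) stop("need at least 2 clusters")
  k <- length(tab)
  res <- t(apply(cmat, 1, function(y) {
    theta <- 1 / mom_dispersion(y)
    ll1 <- nb_loglik_groups(y, clusters, theta)
    ll0 <- nb_loglik_groups(y, rep(1L, length(y)), theta)
    stat <- max(0, 2 * (ll1 - ll0))
    c(stat, stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
  }))
  table <- data.frame(gene = rownames(cmat), lrt_stat = res[, 1],
                      p = res[, 2], q = stats::p.adjust(res[, 2], "BH"),
                      stringsAsFactors = FALSE, row.names = NULL)
  if (top_n > nrow(table)) {
    warning("top_n (", top_n, ") exceeds tested genes (", nrow(table),
            "); returning all")
    top_n <- nrow(table)
  }
  ord <- order(table$q, table$p, table$gene)
  out <- table$gene[ord][seq_len(top_n)]
  attr(out, "table") <- table[ord, , drop = FALSE]
  out
}

#' Fit a principal tree to cells in a low-dimensional embedding
#'
#' Embeds cells (PCA to `latent_dim` dimensions by default, or accepts
#' precomputed coordinates) and fits a tree-structured set of centroids by
#' alternating optimization: (i) soft-assign cells to centroids with a
#' Gaussian kernel, (ii) re-fit centroids by solving the regularized least
#' squares system that shrinks tree-adjacent centroids together, (iii)
#' rebuild the minimum spanning tree over centroids. The penalized objective
#' (assignment cost + entropy + tree-length penalty) is non-increasing
#' across iterations (asserted) and iteration stops when its decrease falls
#' below `tol` (relative) or at `max_iter`.
#'
#' @param m a [tam_norm], matrix (genes x cells), or precomputed cells x d
#'   coordinate matrix when `embedded = TRUE`.
#' @param latent_dim embedding dimension (default 2).
#' @param K number of centroids; default `n_cells / 10` clamped to
#'   \[30, 100\] and capped at the number of distinct cells. Enough
#'   centroids to trace the manifold while keeping the spanning tree from
#'   sprouting noise twigs.
#' @param seed integer seed (centroid initialization via k-means).
#' @param sigma soft-assignment kernel scale; default 0.01 times the total
#'   embedding variance.
#' @param lambda tree-smoothness penalty; default `0.5 * n_cells`, which
#'   keeps the penalty on the same scale as the assignment cost.
#' @param embedded set `TRUE` when `m` is already a cells x d coordinate
#'   matrix.
#' @param max_iter,tol iteration controls.
#' @return A `principal_tree`: list with `centroids`, `edges` (data.frame
#'   `from`, `to`, `length`), `cell_node`, `latent` (cell coordinates),
#'   `objective` (per-iteration trace), `converged`.
#' @export
fit_principal_tree <- function(m, latent_dim = 2, K = NULL, seed = 1,
                               sigma = NULL, lambda = NULL, embedded = FALSE,
                               max_iter = 100, tol = 1e-5) {
  x <- if (embedded) as.matrix(m) else embed_pca(m, dims = latent_dim)
  n <- nrow(x)
  n_distinct <- nrow(unique(x))
  if (is.null(K)) K <- min(max(30, min(round(n / 10), 100)), n_distinct)
  if (K < 3) stop("K must be at least 3")
  if (n < K) stop("need at least K cells")
  set.seed(seed)
  if (K >= n_distinct) {
    K <- n_distinct
    cen <- unique(x)
  } else {
    km <- suppressWarnings(stats::kmeans(x, centers = K, iter.max = 50,
                                         nstart = 1))
    cen <- km$centers
  }
  if (is.null(lambda)) lambda <- 0.5 * n
  if (is.null(sigma)) sigma <- 0.01 * sum(apply(x, 2, stats::var))
  sigma <- max(sigma, 1e-12)
  mst_edges <- function(cen) {
    d2 <- as.matrix(stats::dist(cen))^2
    g <- igraph::graph_from_adjacency_matrix(d2, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    t <- igraph::mst(g)
    igraph::as_edgelist(t, names = FALSE)
  }
  objective <- function(cen, edges, r, d2cells) {
    el <- sum((cen[edges[, 1], ] - cen[edges[, 2], ])^2)
    sum(r * d2cells) + sigma * sum(r * log(pmax(r, 1e-300))) + lambda * el
  }
  obj_trace <- numeric(0)
  edges <- mst_edges(cen)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rowSums(cen^2), `+`) - 2 * x %*% t(cen)
    d2 <- pmax(d2, 0)
    lw <- -d2 / sigma
    lw <- lw - apply(lw, 1, max)
    r <- exp(lw)
    r <- r / rowSums(r)
    obj <- objective(cen, edges, r, d2)
    # centroid update: (Lambda + lambda * L) C = R^T X
    lam <- colSums(r)
    L <- matrix(0, K, K)
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      L[a, a] <- L[a, a] + 1; L[b, b] <- L[b, b] + 1
      L[a, b] <- L[a, b] - 1; L[b, a] <- L[b, a] - 1
    }
    cen <- solve(diag(lam, K) + lambda * L, t(r) %*% x)
    edges <- mst_edges(cen)
    d2 <- outer(rowSums(x^2), rowSums(cen^2), `+`) - 2 * x %*% t(cen)
    d2 <- pmax(d2, 0)
    obj_new <- objective(cen, edges, r, d2)
    obj_trace <- c(obj_trace, obj_new)
    if (obj_new > obj + 1e-8 * abs(obj))
      warning("objective increased at iteration ", it)
    if (it > 1 &&
        abs(obj_trace[it - 1] - obj_new) < tol * abs(obj_trace[it - 1])) break
  }
  converged <- it < max_iter
  if (!converged) warning("principal tree did not converge in ", max_iter,
                          " iterations; returning best fit")
  d2 <- outer(rowSums(x^2), rowSums(cen^2), `+`) - 2 * x %*% t(cen)
  cell_node <- max.col(-d2, ties.method = "first")
  elen <- sqrt(rowSums((cen[edges[, 1], , drop = FALSE] -
                          cen[edges[, 2], , drop = FALSE])^2))
  structure(list(centroids = cen,
                 edges = data.frame(from = edges[, 1], to = edges[, 2],
                                    length = elen),
                 cell_node = stats::setNames(cell_node, rownames(x)),
                 latent = x, objective = obj_trace, K = K,
                 converged = converged),
            class = "principal_tree")
}

#' @export
print.principal_tree <- function(x, ...) {
  nb <- if (!is.null(x$branch_points)) length(x$branch_points) else NA
  cat("principal_tree: ", x$K, " centroids, ", length(x$cell_node),
      " cells", if (!is.na(nb)) paste0(", ", nb, " branch point(s)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.principal_tree <- function(x, color = NULL, ...) {
  graphics::plot(x$latent, col = if (is.null(color)) "grey70"
                 else grDevices::hcl.colors(100)[
                   cut(color, 100, labels = FALSE)],
                 pch = 16, cex = 0.5, xlab = "dim 1", ylab = "dim 2", ...)
  segments_x <- x$centroids[x$edges$from, 1]
  graphics::segments(segments_x, x$centroids[x$edges$from, 2],
                     x$centroids[x$edges$to, 1], x$centroids[x$edges$to, 2],
                     lwd = 2)
  graphics::points(x$centroids, pch = 16, cex = 0.8, col = "black")
  invisible(x)
}

# Collapse terminal twigs supported by fewer than min_frac of the cells:
# remove the twig nodes and reassign their cells to the nearest surviving
# centroid. Node indices are preserved (dropped nodes become isolated).
prune_twigs <- function(t, min_frac) {
  n_cells <- length(t$cell_node)
  repeat {
    deg <- tabulate(c(t$edges$from, t$edges$to), nbins = t$K)
    kept <- sort(unique(c(t$edges$from, t$edges$to)))
    if (!any(deg >= 3)) break
    leaves <- kept[deg[kept] == 1]
    twigs <- lapply(leaves, function(leaf) {
      path <- leaf; cur <- leaf; prev <- NA
      repeat {
        inc <- c(t$edges$to[t$edges$from == cur],
                 t$edges$from[t$edges$to == cur])
        nxt <- setdiff(inc, prev)
        if (!length(nxt)) break
        nxt <- nxt[1]
        if (deg[nxt] >= 3) break
        path <- c(path, nxt); prev <- cur; cur <- nxt
      }
      path
    })
    support <- vapply(twigs, function(tw) sum(t$cell_node %in% tw), 0L)
    worst <- which.min(support)
    if (support[worst] / n_cells >= min_frac) break
    drop <- twigs[[worst]]
    t$edges <- t$edges[!(t$edges$from %in% drop | t$edges$to %in% drop), ,
                       drop = FALSE]
    if (!nrow(t$edges)) break
    survivors <- sort(unique(c(t$edges$from, t$edges$to)))
    moved <- which(t$cell_node %in% drop)
    if (length(moved)) {
      d2 <- outer(rowSums(t$latent[moved, , drop = FALSE]^2),
                  rowSums(t$centroids[survivors, , drop = FALSE]^2), `+`) -
        2 * t$latent[moved, , drop = FALSE] %*%
        t(t$centroids[survivors, , drop = FALSE])
      t$cell_node[moved] <- survivors[max.col(-d2, ties.method = "first")]
    }
  }
  t
}

# igraph object over the tree nodes, weighted by edge length
tree_graph <- function(t) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = t$edges$from, to = t$edges$to),
    directed = FALSE,
    vertices = data.frame(name = seq_len(t$K)))
  igraph::E(g)$weight <- t$edges$length
  g
}

#' Assign trajectory states and locate branch points
#'
#' A state is a maximal tree path between nodes of degree different from 2
#' (leaves and branch points); branch points are nodes of degree 3 or more.
#' Each cell inherits the state of its nearest tree node (branch-point
#' nodes, which border several states, are assigned to their
#' smallest-numbered incident state).
#'
#' With `prune_min_frac > 0`, terminal twigs (a leaf plus its chain of
#' degree-2 nodes up to, but excluding, the nearest branch point) supported
#' by fewer than that fraction of cells are collapsed before states are
#' extracted: their nodes are dropped and their cells reassigned to the
#' nearest remaining centroid. This removes noise-induced micro-branches
#' while leaving any well-populated branching intact.
#'
#' @param t a `principal_tree`.
#' @param prune_min_frac minimum cell fraction a terminal twig must hold to
#'   survive (default 0 = no pruning).
#' @return The tree with added fields `node_state`, `cell_state` (labels
#'   `"S1"`, `"S2"`, ...), `branch_points` (node indices) and `n_states`.
#' @export
assign_states <- function(t, prune_min_frac = 0) {
  stopifnot(inherits(t, "principal_tree"))
  if (prune_min_frac > 0) t <- prune_twigs(t, prune_min_frac)
  deg <- tabulate(c(t$edges$from, t$edges$to), nbins = t$K)
  # union-find over edges: edges sharing a degree-2 node belong to one state
  parent <- seq_len(nrow(t$edges))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (v in which(deg == 2)) {
    inc <- which(t$edges$from == v | t$edges$to == v)
    r1 <- find(inc[1]); r2 <- find(inc[2])
    if (r1 != r2) parent[r2] <- r1
  }
  roots <- vapply(seq_len(nrow(t$edges)), find, 0L)
  state_of_edge <- as.integer(factor(roots, levels = unique(roots)))
  n_states <- max(state_of_edge)
  node_state <- integer(t$K)
  for (e in order(state_of_edge, decreasing = TRUE)) {
    node_state[t$edges$from[e]] <- state_of_edge[e]
    node_state[t$edges$to[e]] <- state_of_edge[e]
  }
  # decreasing order above means smallest state wins at shared (branch) nodes
  t$node_state <- paste0("S", node_state)
  t$cell_state <- stats::setNames(t$node_state[t$cell_node],
                                  names(t$cell_node))
  t$branch_points <- which(deg >= 3)
  t$n_states <- n_states
  t
}

#' Root the tree and compute pseudotime
#'
#' The root is the terminal (leaf) node of the state with the lowest mean
#' AMDI score. Each cell is projected onto its nearest tree edge (continuous
#' position along the segment) and pseudotime is the geodesic distance along
#' the tree (in latent-space edge lengths) from the root to the projected
#' position, shifted so the earliest (root) cell sits at exactly 0. An AMDI
#' tie between states is broken toward the lexicographically smaller state
#' id with a warning.
#'
#' @param t a `principal_tree` with states assigned ([assign_states]).
#' @param amdi per-cell AMDI (maturity) scores aligned with the cells used
#'   to fit the tree.
#' @return The tree with added fields `root_node`, `root_state` and
#'   `pseudotime` (named per-cell vector).
#' @export
order_pseudotime <- function(t, amdi) {
  stopifnot(inherits(t, "principal_tree"), !is.null(t$cell_state))
  stopifnot(length(amdi) == length(t$cell_node))
  means <- tapply(amdi, t$cell_state, mean)
  means <- means[!is.na(means)]
  low <- min(means)
  cand <- sort(names(means)[means == low])
  if (length(cand) > 1)
    warning("mean-AMDI tie between states ", paste(cand, collapse = ", "),
            "; choosing ", cand[1])
  root_state <- cand[1]
  deg <- tabulate(c(t$edges$from, t$edges$to), nbins = t$K)
  kept <- sort(unique(c(t$edges$from, t$edges$to)))
  leaves <- intersect(which(deg == 1 & t$node_state == root_state), kept)
  if (!length(leaves))
    leaves <- intersect(which(t$node_state == root_state), kept)
  g <- tree_graph(t)
  if (length(leaves) > 1) {
    # the terminal end of the root state: the candidate whose local
    # neighbourhood (nearest quartile of tree nodes) has the lowest mean AMDI
    dall <- igraph::distances(g, v = leaves)[, kept, drop = FALSE]
    local_amdi <- vapply(seq_along(leaves), function(i) {
      rad <- stats::quantile(dall[i, ], 0.25)
      near <- kept[dall[i, ] <= rad]
      vals <- amdi[t$cell_node %in% near]
      if (!length(vals)) Inf else mean(vals)
    }, 0)
    leaves <- leaves[which.min(local_amdi)]
  }
  root <- leaves[1]
  droot <- igraph::distances(g, v = root)[1, ]
  # continuous projection of every cell onto its nearest tree edge
  x <- t$latent
  best_d2 <- rep(Inf, nrow(x))
  pt <- numeric(nrow(x))
  for (e in seq_len(nrow(t$edges))) {
    a <- t$edges$from[e]; b <- t$edges$to[e]
    pa <- t$centroids[a, ]; pb <- t$centroids[b, ]
    ab <- pb - pa
    len2 <- sum(ab^2)
    if (len2 == 0) next
    s <- pmin(pmax((sweep(x, 2, pa) %*% ab) / len2, 0), 1)[, 1]
    proj_d2 <- rowSums((x - (rep(1, nrow(x)) %o% pa + s %o% ab))^2)
    upd <- proj_d2 < best_d2
    if (any(upd)) {
      slen <- s[upd] * sqrt(len2)
      pt[upd] <- pmin(droot[a] + slen, droot[b] + sqrt(len2) - slen)
      best_d2[upd] <- proj_d2[upd]
    }
  }
  pt <- pt - min(pt)
  t$root_node <- root
  t$root_state <- root_state
  t$pseudotime <- stats::setNames(pt, names(t$cell_node))
  t
}

#' Pearson correlation between pseudotime and a per-cell score
#'
#' @param pseudotime,score aligned numeric vectors, n >= 3, non-constant.
#' @return List with `r` (Pearson correlation) and two-sided `p` (t-test).
#' @export
correlate_score_pseudotime <- function(pseudotime, score) {
  stopifnot(length(pseudotime) == length(score), length(score) >= 3)
  if (stats::sd(pseudotime) == 0 || stats::sd(score) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(pseudotime, score, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
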