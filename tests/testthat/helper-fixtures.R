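# Small deterministic fixtures and independent oracles used across tests.

# gene x cell count matrix with metadata, from explicit values
toy_counts <- function(mat, region = NULL, tumor = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  n <- ncol(mat)
  if (is.null(region)) region <- rep(c("core", "periphery"), length.out = n)
  if (is.null(tumor)) tumor <- rep("T1", n)
  tam_counts(mat, data.frame(cell_id = colnames(mat), region = region,
                             tumor_id = tumor))
}

random_counts <- function(n_genes, n_cells, lambda = 3, seed = 1) {
  set.seed(seed)
  toy_counts(matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells))
}

# small simulated dataset shared by several planted-signal tests
small_sim <- function(seed = 1, effect_size = 1, n_core = 300, n_peri = 200,
                      n_genes = 500) {
  simulate_tam_cells(synth_config(
    n_cells_core = n_core, n_cells_periphery = n_peri, n_genes = n_genes,
    effect_size = effect_size, seed = seed))
}

# --- independent oracles ----------------------------------------------------

# brute-force AUCell: explicit ranking walk and recovery-curve accumulation
oracle_aucell <- function(values, in_sig, top_frac) {
  n <- length(values)
  w <- max(1L, as.integer(ceiling(top_frac * n)))
  ord <- order(-values, seq_len(n))
  hits <- 0; area <- 0
  for (x in seq_len(w)) {
    if (in_sig[ord[x]]) hits <- hits + 1
    area <- area + hits
  }
  s <- sum(in_sig)
  best <- 0; h <- 0
  for (x in seq_len(w)) { h <- min(x, s); best <- best + h }
  area / best
}

# brute-force 3-cycle loop enumeration over a ligrec graph
oracle_loop_importance <- function(g, node, state, combine = "sum") {
  total <- 0
  for (i in seq_len(nrow(g$lr))) {
    l <- g$lr$ligand[i]; r <- g$lr$receptor[i]
    if (!(node == r || node == l)) next
    e <- c(g$sl[state, l], g$lr$weight[i], g$rs[r, state])
    total <- total + if (combine == "sum") sum(e) else prod(e)
  }
  total
}

# O(n^2) double-loop density-peak P and D
oracle_density_pd <- function(points, bandwidth) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  P <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    P[i] <- P[i] + exp(-(d[i, j] / bandwidth)^2 / 2)
  ord <- order(-P, seq_len(n))
  D <- numeric(n)
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (k == 1) { D[i] <- max(d); next }
    best <- Inf
    for (j in ord[seq_len(k - 1)]) best <- min(best, d[i, j])
    D[i] <- best
  }
  list(P = P, D = D)
}

# exact Mann-Whitney two-sided p by enumerating all rank splits
oracle_mw_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mid <- n * m / 2
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-12)
}
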