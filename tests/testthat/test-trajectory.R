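test_that("Census output is depth-invariant and maps the mode to 1", {
  # identical profiles at 1x and 3x depth give identical relative counts
  prof <- c(5, 8, 0, 3, 12, 7, 2, 9, 4, 6, 1, 10)
  mat <- cbind(c1 = prof, c2 = 3 * prof)
  rownames(mat) <- paste0("g", seq_along(prof))
  out <- census_normalize(toy_counts(mat))
  expect_equal(as.numeric(out$counts[, 1]), as.numeric(out$counts[, 2]),
               tolerance = 1e-8)
  # 80% of nonzero genes share one relative value: that value is the mode
  n <- 50
  mat2 <- matrix(0, n, 1, dimnames = list(paste0("g", 1:n), "c1"))
  mat2[1:40, 1] <- 10
  mat2[41:50, 1] <- c(1, 2, 3, 50, 60, 70, 80, 90, 100, 110)
  out2 <- census_normalize(toy_counts(mat2))
  modal <- as.numeric(out2$counts[1, 1])
  expect_lt(abs(modal - 1), 0.05)
})

test_that("Census falls back to depth scaling for near-empty cells", {
  mat <- matrix(rpois(20 * 3, 6) + 1, 20, 3)
  mat <- cbind(mat, c4 = c(5, rep(0, 19)))
  colnames(mat) <- paste0("c", 1:4)
  expect_warning(out <- census_normalize(toy_counts(mat)), "fallback")
  expect_equal(ncol(out$counts), 4)
})

test_that("density peaks match the brute-force O(n^2) oracle", {
  set.seed(51)
  for (n in c(10, 60, 200)) {
    pts <- matrix(rnorm(2 * n), n, 2)
    got <- density_peak_cluster(pts)
    oracle <- oracle_density_pd(pts, got$bandwidth)
    expect_equal(got$P, oracle$P, tolerance = 1e-12)
    expect_equal(got$D, oracle$D, tolerance = 1e-12)
  }
})

test_that("density-peak clustering separates two distant blobs", {
  good <- 0
  for (s in 1:50) {
    set.seed(600 + s)
    pts <- rbind(matrix(rnorm(200, 0, 1), 100, 2),
                 matrix(rnorm(200, 10, 1), 100, 2))
    got <- density_peak_cluster(pts)
    if (max(got$cluster) == 2) good <- good + 1
  }
  expect_gte(good / 50, 0.95)
})

test_that("density-peak degenerate conventions: n = 1 and coincident points", {
  expect_equal(density_peak_cluster(matrix(0, 1, 2))$cluster, 1L)
  same <- density_peak_cluster(matrix(1, 5, 2))
  expect_equal(unique(same$cluster), 1L)
})

test_that("ordering-gene LRT keeps its size on null data", {
  set.seed(52)
  n_genes <- 400; n_cells <- 100
  mat <- matrix(rnbinom(n_genes * n_cells, mu = 5, size = 2),
                n_genes, n_cells)
  clusters <- rep(1:2, each = n_cells / 2)
  tc <- toy_counts(mat)
  genes <- suppressWarnings(select_ordering_genes(tc, clusters,
                                                  top_n = n_genes))
  tab <- attr(genes, "table")
  frac <- mean(tab$q < 0.05)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / n_genes))
  # p-values roughly uniform: the rejection rate at alpha=0.05 is near 0.05
  expect_lte(mean(tab$p < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / n_genes))
})

test_that("ordering-gene LRT finds genes with a 4-fold cluster difference", {
  hits <- 0
  for (s in 1:25) {
    set.seed(700 + s)
    n_cells <- 200
    clusters <- rep(1:2, each = n_cells / 2)
    mat <- rbind(matrix(rnbinom(99 * n_cells, mu = 5, size = 2), 99, n_cells),
                 rnbinom(n_cells, mu = ifelse(clusters == 1, 2, 8), size = 2))
    rownames(mat) <- paste0("g", 1:100)
    tc <- toy_counts(mat)
    genes <- suppressWarnings(select_ordering_genes(tc, clusters, top_n = 5))
    if ("g100" %in% genes) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.95)
})

test_that("ordering-gene selection handles top_n overflow and tiny clusters", {
  set.seed(53)
  mat <- matrix(rpois(50 * 30, 5), 50, 30)
  tc <- toy_counts(mat)
  expect_warning(g <- select_ordering_genes(tc, rep(1:2, each = 15),
                                            top_n = 999), "returning all")
  expect_lte(length(g), 50)
  cl <- c(rep(1, 24), 2, 2, rep(3, 4))  # the 2-cell cluster gets merged
  expect_warning(select_ordering_genes(tc, cl, top_n = 10), "merged")
  expect_error(select_ordering_genes(tc, rep(1, 30), top_n = 5),
               "at least 2 clusters")
})

test_that("principal tree recovers a noiseless line as a path in order", {
  set.seed(54)
  tpos <- sort(runif(150))
  pts <- cbind(tpos * 10, rep(0, 150))
  rownames(pts) <- paste0("c", 1:150)
  tree <- fit_principal_tree(pts, embedded = TRUE, K = 20, seed = 1)
  tree <- assign_states(tree)
  expect_equal(tree$n_states, 1L)
  expect_length(tree$branch_points, 0)
  tree <- order_pseudotime(tree, amdi = tpos)
  expect_gte(abs(cor(tree$pseudotime, tpos, method = "spearman")), 0.99)
})

test_that("principal tree objective is monotone and K = 3 on 3 cells is a path", {
  set.seed(55)
  pts <- matrix(rnorm(300), 150, 2)
  rownames(pts) <- paste0("c", 1:150)
  tree <- fit_principal_tree(pts, embedded = TRUE, K = 10, seed = 2)
  expect_true(all(diff(tree$objective) <= 1e-8 * abs(tree$objective[-1]) + 1e-9))
  three <- matrix(c(0, 0, 5, 0, 10, 0), 3, 2, byrow = TRUE,
                  dimnames = list(paste0("c", 1:3), NULL))
  t3 <- fit_principal_tree(three, embedded = TRUE, K = 3, seed = 1, lambda = 0.1)
  t3 <- assign_states(t3)
  expect_equal(nrow(t3$edges), 2)
  expect_length(t3$branch_points, 0)
})

test_that("state extraction follows tree combinatorics", {
  # hand-built trees: path, single Y, two cascaded Ys
  mk <- function(edges, K) {
    structure(list(centroids = matrix(seq_len(2 * K), K, 2),
                   edges = data.frame(from = edges[, 1], to = edges[, 2],
                                      length = 1),
                   cell_node = stats::setNames(seq_len(K), paste0("c", 1:K)),
                   latent = matrix(seq_len(2 * K), K, 2), K = K),
              class = "principal_tree")
  }
  path <- assign_states(mk(cbind(1:4, 2:5), 5))
  expect_equal(path$n_states, 1L); expect_length(path$branch_points, 0)
  y1 <- assign_states(mk(rbind(c(1, 2), c(2, 3), c(2, 4)), 4))
  expect_equal(y1$n_states, 3L); expect_equal(y1$branch_points, 2L)
  yy <- assign_states(mk(rbind(c(1, 2), c(2, 3), c(2, 4), c(4, 5), c(4, 6)), 6))
  expect_equal(yy$n_states, 5L)
  expect_length(yy$branch_points, 2)
})

test_that("pseudotime is rooted at the lowest-AMDI terminus and rescale-invariant", {
  set.seed(56)
  tpos <- sort(runif(120))
  pts <- cbind(tpos * 8, rnorm(120, 0, 0.05))
  rownames(pts) <- paste0("c", 1:120)
  tree <- assign_states(fit_principal_tree(pts, embedded = TRUE, K = 12,
                                           seed = 3))
  up <- order_pseudotime(tree, amdi = tpos)        # AMDI rises left to right
  expect_gte(cor(up$pseudotime, tpos, method = "spearman"), 0.95)
  down <- order_pseudotime(tree, amdi = -tpos)     # flip: root at other end
  expect_lte(cor(down$pseudotime, tpos, method = "spearman"), -0.95)
  expect_equal(min(up$pseudotime), 0)
  # uniform rescaling of the latent space preserves the ordering exactly
  tree2 <- assign_states(fit_principal_tree(pts * 7, embedded = TRUE, K = 12,
                                            seed = 3))
  up2 <- order_pseudotime(tree2, amdi = tpos)
  expect_equal(cor(up$pseudotime, up2$pseudotime, method = "spearman"), 1)
})

test_that("pseudotime-score correlation matches the textbook formula", {
  set.seed(57)
  pt <- runif(40); sc <- 2 * pt + rnorm(40, 0, 0.3)
  got <- correlate_score_pseudotime(pt, sc)
  r_hand <- sum((pt - mean(pt)) * (sc - mean(sc))) /
    sqrt(sum((pt - mean(pt))^2) * sum((sc - mean(sc))^2))
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(correlate_score_pseudotime(pt, pt)$r, 1)
  expect_equal(correlate_score_pseudotime(pt, -pt)$r, -1)
  expect_error(correlate_score_pseudotime(pt, rep(1, 40)), "zero variance")
})

test_that("regional polarization wiring flips the MPI-pseudotime sign", {
  signs <- sapply(1:6, function(s) {
    cfg <- synth_config(n_cells_core = 250, n_cells_periphery = 250,
                        n_genes = 400, seed = 900 + s)
    sim <- simulate_tam_cells(cfg)
    out <- c(NA, NA)
    for (i in seq_along(c("core", "periphery"))) {
      region <- c("core", "periphery")[i]
      b <- suppressWarnings(suppressMessages(run_regional_analysis(
        list(dataset = sim, seed = s, top_n_ordering = 150), region)))
      out[i] <- sign(b$correlations$mpi$r)
    }
    out
  })
  expect_gte(mean(signs[1, ] == 1), 0.9)    # core: pro-inflammatory with time
  expect_gte(mean(signs[2, ] == -1), 0.9)   # periphery: anti-inflammatory
})
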