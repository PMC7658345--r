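# Shared fixture: two branches with planted curve programs.
# Genes 1-10 rise along branch A only; genes 11-20 are flat on both; the
# remainder are pure noise.
branch_fixture <- function(seed, n_per_branch = 150, n_genes = 60,
                           fold = 2) {
  set.seed(seed)
  n <- 2 * n_per_branch
  branch <- rep(c("A", "B"), each = n_per_branch)
  pt <- c(sort(runif(n_per_branch)), sort(runif(n_per_branch)))
  mu <- matrix(5, n_genes, n)
  ramp <- ifelse(branch == "A", pt, 0)
  mu[1:10, ] <- 5 * fold^rep(ramp, each = 10)
  mat <- matrix(rnbinom(n_genes * n, mu = mu, size = 3), n_genes, n,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("c", seq_len(n))))
  list(counts = toy_counts(mat), pt = pt, branch = branch)
}

test_that("branch test calibrates on null genes and flags planted ones", {
  fx <- branch_fixture(seed = 61)
  bt <- branch_dependence_test(fx$counts, fx$pt, fx$branch)
  expect_true(all(bt$q >= bt$p))
  planted <- paste0("g", 1:10)
  expect_gte(mean(bt$branch_dependent[bt$gene %in% planted]), 0.9)
  null_flag <- mean(bt$branch_dependent[!bt$gene %in% planted])
  expect_lte(null_flag, 0.1)
  # all-zero gene is excluded, not tested
  mat <- as.matrix(fx$counts$counts)
  mat["g60", ] <- 0
  bt2 <- branch_dependence_test(toy_counts(mat), fx$pt, fx$branch)
  expect_false("g60" %in% bt2$gene)
})

test_that("branch test type-I error stays within its binomial band", {
  set.seed(62)
  n_genes <- 500; n <- 160
  branch <- rep(c("A", "B"), each = n / 2)
  pt <- runif(n)
  mat <- matrix(rnbinom(n_genes * n, mu = 6, size = 2), n_genes, n)
  bt <- branch_dependence_test(toy_counts(mat), pt, branch)
  expect_lte(mean(bt$p < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / nrow(bt)))
})

test_that("branch test power: rising-vs-flat genes are flagged across seeds", {
  flags <- numeric(0)
  for (s in 1:10) {
    fx <- branch_fixture(seed = 800 + s, n_per_branch = 150, n_genes = 40)
    bt <- branch_dependence_test(fx$counts, fx$pt, fx$branch)
    flags <- c(flags, bt$branch_dependent[bt$gene %in% paste0("g", 1:10)])
  }
  expect_gte(mean(flags), 0.9)   # per-gene detection rate across seeds
})

test_that("branch test input contracts", {
  fx <- branch_fixture(seed = 63, n_per_branch = 30)
  expect_error(branch_dependence_test(fx$counts, fx$pt,
                                      rep("A", length(fx$branch))),
               "two levels")
  expect_error(branch_dependence_test(fx$counts, fx$pt,
                                      c(rep("A", 10), rep("B", 50))),
               "at least 20")
})

test_that("smoothed curves recover a linear trend and span the 0-100 grid", {
  set.seed(64)
  n <- 200
  branch <- rep(c("A", "B"), each = n / 2)
  pt <- c(runif(n / 2), runif(n / 2))
  v <- rbind(lin = 2 + 3 * pt, const = rep(1, n)) # linear and constant genes
  v <- rbind(v, noise = rnorm(n))
  colnames(v) <- paste0("c", 1:n)
  nm <- tam_norm(v)
  cur <- smooth_curves(nm, pt, branch, c("lin", "const"), grid_n = 50)
  expect_equal(attr(cur, "grid")[1], 0)
  expect_equal(tail(attr(cur, "grid"), 1), 100)
  expect_equal(unname(cur$A["const", ]), rep(0, 50))  # standardized zeros
  # linear gene: interior grid values match the standardized line within 5%
  grid <- attr(cur, "grid")
  raw_line <- 2 + 3 * grid / 100
  joint <- c(raw_line, raw_line)
  zline <- (joint - mean(joint)) / sd(joint)
  interior <- 10:40
  expect_lt(max(abs(cur$A["lin", interior] - zline[interior])),
            0.05 * diff(range(zline)))
})

test_that("curve clustering recovers planted archetypes and handles edge cases", {
  set.seed(65)
  grid_n <- 50
  rise_a <- c(seq(0, 1, length.out = grid_n), rep(0, grid_n))
  rise_b <- c(rep(0, grid_n), seq(0, 1, length.out = grid_n))
  mk <- function(base, n) t(replicate(n, base + rnorm(2 * grid_n, 0, 0.2)))
  joint <- rbind(mk(rise_a, 50), mk(rise_b, 50))
  rownames(joint) <- paste0("g", 1:100)
  curves <- list(A = joint[, 1:grid_n], B = joint[, -(1:grid_n)])
  cc <- cluster_branch_genes(curves, k = 2)
  truth <- rep(1:2, each = 50)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(cc$cluster, truth)
  expect_gte(ari, 0.9)
  # auto-k also separates the two archetypes
  cc_auto <- cluster_branch_genes(curves)
  expect_equal(cc_auto$n_clusters, 2L)
  # identical curves: forced single cluster with warning
  same <- rbind(g1 = rise_a, g2 = rise_a, g3 = rise_a)
  expect_warning(
    one <- cluster_branch_genes(list(A = same[, 1:grid_n],
                                     B = same[, -(1:grid_n)])),
    "single cluster")
  expect_equal(one$n_clusters, 1L)
  # k = n_genes gives singletons; k > n_genes errors
  singl <- cluster_branch_genes(curves, k = 100)
  expect_equal(length(unique(singl$cluster)), 100L)
  expect_error(cluster_branch_genes(curves, k = 101), "exceeds")
})

test_that("divergence selects branch-specific programs and not shared ones", {
  sel_hits <- 0; null_ok <- 0
  for (s in 1:10) {
    fx <- branch_fixture(seed = 900 + s, n_per_branch = 100, n_genes = 40,
                         fold = 3)
    nm <- lognormalize(fx$counts)
    bt <- branch_dependence_test(fx$counts, fx$pt, fx$branch)
    dep <- bt$gene[bt$branch_dependent]
    if (length(dep) < 2) next
    cur <- smooth_curves(nm, fx$pt, fx$branch, dep)
    cc <- cluster_branch_genes(cur, k = 2)
    divg <- divergent_clusters(cc, nm, fx$pt, fx$branch)
    planted <- paste0("g", 1:10)
    overlap <- vapply(divg$cluster, function(k) {
      genes <- names(cc$cluster)[cc$cluster == k]
      length(intersect(genes, planted)) / length(genes)
    }, 0)
    best <- which.max(overlap)
    if (divg$selected[best]) sel_hits <- sel_hits + 1
    if (all(!divg$selected[-best] | overlap[-best] > 0.5))
      null_ok <- null_ok + 1
  }
  expect_gte(sel_hits / 10, 0.9)
  # identical branches give divergence 0
  set.seed(66)
  v <- matrix(rnorm(200), 4, 50,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:50)))
  nm0 <- tam_norm(cbind(v, v))
  colnames(nm0$values) <- paste0("c", 1:100)
  cc0 <- structure(list(cluster = stats::setNames(rep(1L, 4),
                                                  paste0("g", 1:4)),
                        n_clusters = 1L),
                   class = "gene_curve_cluster")
  d0 <- divergent_clusters(cc0, nm0, rep(1:50, 2),
                           rep(c("A", "B"), each = 50))
  expect_equal(d0$divergence, 0)
})

test_that("meta-gene pathway correlation behaves at its extremes and null", {
  set.seed(67)
  x <- rnorm(100)
  expect_equal(pathway_correlation(x, x)$r, 1)
  expect_error(pathway_correlation(x, rep(1, 100)), "zero variance")
  small <- vapply(1:50, function(i) {
    abs(pathway_correlation(rnorm(500), rnorm(500))$r)
  }, 0)
  expect_gte(mean(small < 0.15), 0.9)
})

test_that("over-representation matches the exact hypergeometric formula", {
  universe <- paste0("g", 1:100)
  cluster <- paste0("g", 1:10)
  collection <- list(hit = cluster, cold = paste0("g", 90:99),
                     all = universe, out = paste0("x", 1:5))
  got <- overrepresentation(cluster, collection, universe)
  # maximal overlap: P(X >= 10) = 1 / choose(100, 10)
  expect_equal(got$p[got$set == "hit"], 1 / choose(100, 10),
               tolerance = 1e-12)
  expect_equal(got$p[got$set == "hit"],
               phyper(9, 10, 90, 10, lower.tail = FALSE), tolerance = 1e-15)
  expect_equal(got$p[got$set == "all"], 1)     # set = universe
  expect_equal(got$p[got$set == "cold"], 1)    # zero overlap, upper tail
  expect_true(is.na(got$p[got$set == "out"]))  # skipped, noted
  expect_match(got$note[got$set == "out"], "skipped")
  expect_error(overrepresentation(c("zz"), collection, universe),
               "contained in the universe")
})

test_that("BH q-values are monotone after sorting by p", {
  set.seed(68)
  fx <- branch_fixture(seed = 68, n_per_branch = 60, n_genes = 50)
  bt <- branch_dependence_test(fx$counts, fx$pt, fx$branch)
  ord <- order(bt$p)
  expect_true(all(diff(bt$q[ord]) >= -1e-12))
})

test_that("bulk meta-gene correlation recovers planted coupling per region", {
  cfg <- synth_config(n_cells_core = 150, n_cells_periphery = 120,
                      n_genes = 300, seed = 69)
  sim <- simulate_tam_cells(cfg)
  bulk <- simulate_tam_bulk(cfg, sim$counts, n_samples_per_region = 4,
                            n_cells_per_sample = 60)
  # pathway-1 against itself: perfect correlation
  r_self <- bulk_correlation(bulk$expr, bulk$sample_meta$structure,
                             sim$signatures$pathway1, sim$signatures$pathway1,
                             "core")
  expect_equal(r_self$r, 1, tolerance = 1e-10)
  expect_error(bulk_correlation(bulk$expr[, 1:2],
                                bulk$sample_meta$structure[1:2],
                                sim$signatures$pathway1,
                                sim$signatures$pathway2, "core"),
               "fewer than 3")
  # planted correlated programs: pathway-1 and the polarization-positive
  # block both rise on core branch-A cells, so their bulk meta-genes couple
  hits <- 0
  for (s in 1:10) {
    cfgs <- synth_config(n_cells_core = 150, n_cells_periphery = 120,
                         n_genes = 300, seed = 950 + s)
    sims <- simulate_tam_cells(cfgs)
    bks <- simulate_tam_bulk(cfgs, sims$counts, n_samples_per_region = 4,
                             n_cells_per_sample = 60)
    r <- bulk_correlation(bks$expr, bks$sample_meta$structure,
                          sims$signatures$pathway1, sims$signatures$pol_pos,
                          "core")
    if (r$r > 0.5) hits <- hits + 1
  }
  expect_gte(hits / 10, 0.9)
})
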