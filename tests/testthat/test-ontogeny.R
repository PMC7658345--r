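test_that("ontogeny scores: symmetry, degenerate zeros, planted signal", {
  set.seed(31)
  v <- matrix(rnorm(80), 10, 8,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:8)))
  nm <- tam_norm(v)
  a <- ontogeny_scores(nm, c("g1", "g2"), c("g3", "g4"))
  b <- ontogeny_scores(nm, c("g3", "g4"), c("g1", "g2"))
  expect_equal(a$bmdm_score, b$mg_score)
  expect_equal(a$mg_score, b$bmdm_score)
  v0 <- matrix(2, 10, 4, dimnames = list(paste0("g", 1:10), paste0("c", 1:4)))
  z <- ontogeny_scores(tam_norm(v0), c("g1", "g2"), c("g3", "g4"))
  expect_equal(z$bmdm_score, rep(0, 4))
  # pure-BMDM cells score higher on the BMDM signature
  sim <- small_sim(seed = 8)
  nm2 <- lognormalize(sim$counts)
  sc <- ontogeny_scores(nm2, sim$signatures$bmdm, sim$signatures$mg)
  pure <- sim$truth$cells$ontogeny_fraction > 0.9
  expect_gt(mean(sc$bmdm_score[pure]), mean(sc$mg_score[pure]))
})

test_that("ROC curve: endpoints, trapezoid consistency, rank equivalence", {
  set.seed(32)
  scores <- rnorm(200)
  truth <- runif(200) < plogis(scores)
  r <- roc_curve(scores, truth)
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(tail(r$curve$fpr, 1), 1); expect_equal(tail(r$curve$tpr, 1), 1)
  # AUC equals the Mann-Whitney rank statistic
  pos <- scores[truth]; neg <- scores[!truth]
  mw <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(r$auc, mw, tolerance = 1e-10)
  expect_error(roc_curve(scores, rep(TRUE, 200)), "both classes")
})

test_that("SVM separability: separable clouds reach AUC >= 0.99", {
  set.seed(33)
  n <- 200
  sc <- data.frame(
    bmdm_score = c(rnorm(n, 0), rnorm(n, 6)),
    mg_score = c(rnorm(n, 6), rnorm(n, 0)))
  regions <- rep(c("periphery", "core"), each = n)
  states <- rep("M0", 2 * n)
  rocs <- region_separability(sc, regions, states, seed = 33)
  expect_gte(rocs$M0$auc, 0.99)
})

test_that("SVM separability: permuted labels give chance-level AUC", {
  set.seed(34)
  aucs <- vapply(1:10, function(i) {
    n <- 120
    sc <- data.frame(bmdm_score = rnorm(2 * n), mg_score = rnorm(2 * n))
    regions <- sample(rep(c("periphery", "core"), each = n))
    suppressWarnings(
      region_separability(sc, regions, rep("M0", 2 * n), seed = i)$M0$auc)
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("SVM separability approaches the Gaussian closed-form AUC", {
  # two unit-variance isotropic clouds, gap delta along one axis:
  # optimal AUC = pnorm(delta / sqrt(2))
  set.seed(35)
  delta <- 1.5
  n <- 1000
  sc <- data.frame(bmdm_score = c(rnorm(n), rnorm(n, delta)),
                   mg_score = rnorm(2 * n))
  regions <- rep(c("periphery", "core"), each = n)
  r <- region_separability(sc, regions, rep("M0", 2 * n), seed = 35)$M0
  expect_lt(abs(r$auc - pnorm(delta / sqrt(2))), 0.05)
})

test_that("separability skips underpowered or single-region states", {
  sc <- data.frame(bmdm_score = rnorm(30), mg_score = rnorm(30))
  expect_warning(
    out <- region_separability(sc, rep("core", 30), rep("M0", 30)),
    "skipped")
  expect_length(out, 0)
})

test_that("DeLong test: identical curves give p = 1; symmetry holds", {
  set.seed(36)
  scores <- rnorm(80); truth <- runif(80) < 0.5
  r1 <- roc_curve(scores, truth)
  expect_equal(delong_test(r1, r1)$p, 1)
  r2 <- roc_curve(rnorm(80), truth)
  expect_equal(delong_test(r1, r2)$p, delong_test(r2, r1)$p, tolerance = 1e-12)
  expect_error(delong_test(r1, roc_curve(rnorm(10), rep(c(TRUE, FALSE), 5))),
               "identical case set")
})

test_that("DeLong test agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  for (i in 1:5) {
    n <- 60
    truth <- rep(c(TRUE, FALSE), n / 2)
    s1 <- rnorm(n) + truth * 1.2
    s2 <- rnorm(n) + truth * 0.3
    got <- delong_test(roc_curve(s1, truth), roc_curve(s2, truth))
    ref <- pROC::roc.test(pROC::roc(truth, s1, quiet = TRUE, direction = "<"),
                          pROC::roc(truth, s2, quiet = TRUE, direction = "<"),
                          method = "delong")
    expect_equal(got$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("DeLong detects strong-vs-random scorers", {
  set.seed(38)
  hits <- 0
  for (i in 1:50) {
    n <- 500
    truth <- rep(c(TRUE, FALSE), n / 2)
    strong <- rnorm(n) + truth * 2
    random <- rnorm(n)
    p <- delong_test(roc_curve(strong, truth), roc_curve(random, truth))$p
    if (p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("DeLong p on a small case agrees with a stratified bootstrap", {
  set.seed(39)
  truth <- rep(c(TRUE, FALSE), 6)
  s1 <- rnorm(12) + truth * 1
  s2 <- rnorm(12)
  got <- delong_test(roc_curve(s1, truth), roc_curve(s2, truth))$p
  # stratified bootstrap of the AUC difference
  pos <- which(truth); neg <- which(!truth)
  diffs <- replicate(10000, {
    ip <- sample(pos, replace = TRUE); ineg <- sample(neg, replace = TRUE)
    idx <- c(ip, ineg); tt <- truth[idx]
    auc <- function(s) mean(outer(s[tt], s[!tt],
                                  function(a, b) (a > b) + 0.5 * (a == b)))
    auc(s1[idx]) - auc(s2[idx])
  })
  d0 <- mean(diffs)
  boot_p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  expect_lt(abs(got - boot_p), 0.05)
})

test_that("Ivy structure mapping is total, case-insensitive, strict", {
  expect_equal(map_ivy_regions("leading edge"), "periphery")
  expect_equal(map_ivy_regions("infiltrating tumour"), "periphery")
  expect_equal(map_ivy_regions("Cellular Tumour"), "core")
  expect_equal(map_ivy_regions("cellular tumor"), "core")
  expect_equal(map_ivy_regions("microvascular proliferation"), "core")
  expect_equal(map_ivy_regions("pseudopalisading cells"), "core")
  expect_equal(map_ivy_regions("Pseudopalisading cells around necrosis"),
               "core")
  expect_error(map_ivy_regions("necrotic zone"), "unknown structure")
})

test_that("bulk validation recovers the planted regional signal", {
  cfg <- synth_config(n_cells_core = 150, n_cells_periphery = 120,
                      n_genes = 300, effect_size = 1, seed = 41)
  sim <- simulate_tam_cells(cfg)
  bulk <- simulate_tam_bulk(cfg, sim$counts, n_samples_per_region = 4,
                            n_cells_per_sample = 60)
  out <- bulk_validation(bulk$expr, sim$signatures$bmdm, sim$signatures$mg,
                         bulk$sample_meta$structure)
  expect_gte(out$roc$auc, 0.9)
  # shuffled labels: chance level on average
  set.seed(42)
  aucs <- vapply(1:20, function(i) {
    sh <- sample(out$scores$region)
    roc_curve(out$scores$bmdm_score - out$scores$mg_score, sh == "core")$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})
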