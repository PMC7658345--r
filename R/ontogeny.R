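#' BMDM and microglia ontogeny scores
#'
#' Meta-gene scores of bone-marrow-derived-macrophage and microglia marker
#' signatures for every cell.
#'
#' @param m a [tam_norm] object (log-normalized).
#' @param bmdm_sig,mg_sig gene id vectors.
#' @return data.frame with columns `cell_id`, `bmdm_score`, `mg_score`.
#' @export
ontogeny_scores <- function(m, bmdm_sig, mg_sig) {
  data.frame(cell_id = colnames(m$values),
             bmdm_score = as.numeric(metagene_score(m, bmdm_sig, "bmdm")),
             mg_score = as.numeric(metagene_score(m, mg_sig, "mg")),
             stringsAsFactors = FALSE)
}

#' Empirical ROC curve and AUC
#'
#' Builds the ROC curve of a continuous score against a binary truth and
#' computes the AUC by the trapezoidal rule (equivalently, the rank/
#' Mann-Whitney statistic). The curve starts at (0,0) and ends at (1,1).
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param truth logical (or two-level) vector; `TRUE` is the positive class.
#' @return A `roc_result`: list with `auc`, `curve` (data.frame `fpr`,
#'   `tpr`), `scores`, `truth`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  if (all(truth) || !any(truth))
    stop("truth must contain both classes")
  ord <- order(-scores)
  s <- scores[ord]; y <- truth[ord]
  # collapse tied thresholds
  keep <- c(diff(s) != 0, TRUE)
  tpr <- c(0, cumsum(y)[keep] / sum(y))
  fpr <- c(0, cumsum(!y)[keep] / sum(!y))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr),
                 scores = scores, truth = truth),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result: AUC = ", format(x$auc, digits = 4), " (",
      sum(x$truth), " positive / ", sum(!x$truth), " negative)\n", sep = "")
  invisible(x)
}

#' Regional separability of ontogeny scores per activation state
#'
#' For each activation state, fits a radial-kernel SVM classifier of region
#' on the two ontogeny scores. Hyperparameters (cost and kernel gamma) are
#' tuned by 10-fold cross-validation on a random 70% training split; the ROC
#' and AUC are computed from continuous decision values on the held-out 30%.
#' States with fewer than 20 cells in either region (or a single region) are
#' skipped with a warning.
#'
#' @param scores data.frame from [ontogeny_scores].
#' @param regions per-cell region labels (`core` / `periphery`).
#' @param states per-cell activation-state labels.
#' @param train_frac training fraction (default 0.7).
#' @param folds cross-validation folds for tuning (default 10).
#' @param cost_grid,gamma_grid tuning grids (defaults `c(0.1, 1, 10)`).
#' @param seed integer seed for the split and fold assignment.
#' @return Named list of `roc_result` objects (one per evaluable state).
#' @export
region_separability <- function(scores, regions, states, train_frac = 0.7,
                                folds = 10, cost_grid = c(0.1, 1, 10),
                                gamma_grid = c(0.1, 1, 10), seed = 1) {
  stopifnot(nrow(scores) == length(regions), length(regions) == length(states))
  set.seed(seed)
  out <- list()
  for (s in unique(as.character(states))) {
    idx <- which(states == s)
    y <- factor(regions[idx], levels = c("periphery", "core"))
    if (nlevels(droplevels(y)) < 2 || any(table(y) < 20)) {
      warning("state ", s, " skipped: needs >= 20 cells in each region")
      next
    }
    x <- as.matrix(scores[idx, c("bmdm_score", "mg_score")])
    n <- length(idx)
    tr <- sample.int(n, round(train_frac * n))
    if (nlevels(droplevels(y[tr])) < 2 || nlevels(droplevels(y[-tr])) < 2) {
      warning("state ", s, " skipped: degenerate train/test split")
      next
    }
    tuned <- e1071::tune.svm(x[tr, , drop = FALSE], y[tr],
                             kernel = "radial",
                             cost = cost_grid, gamma = gamma_grid,
                             tunecontrol = e1071::tune.control(cross = folds))
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = tuned$best.parameters$cost,
                      gamma = tuned$best.parameters$gamma,
                      decision.values = TRUE)
    dvm <- attr(stats::predict(fit, x[-tr, , drop = FALSE],
                               decision.values = TRUE), "decision.values")
    dv <- dvm[, 1]
    # decision-value column is named "A/B" with positive values favoring A;
    # orient so that higher always means core
    if (!grepl("^core", colnames(dvm)[1])) dv <- -dv
    out[[s]] <- roc_curve(dv, y[-tr] == "core")
  }
  out
}

#' DeLong test for two correlated (paired) ROC curves
#'
#' Two-sided z-test on the difference of AUCs using DeLong's structural-
#' component covariance estimate. Both ROC results must be computed on the
#' same cases in the same order. Identical score vectors give p = 1.
#'
#' @param r1,r2 `roc_result` objects on identical case sets.
#' @return List with `auc1`, `auc2`, `z` and two-sided `p`.
#' @export
delong_test <- function(r1, r2) {
  stopifnot(inherits(r1, "roc_result"), inherits(r2, "roc_result"))
  if (length(r1$truth) != length(r2$truth) || any(r1$truth != r2$truth))
    stop("ROC results must share an identical case set")
  truth <- r1$truth
  if (all(truth) || !any(truth)) stop("degenerate truth vector")
  comp <- function(scores) {
    xs <- scores[truth]; ys <- scores[!truth]
    m <- length(xs); n <- length(ys)
    psi <- function(a, b) (a > b) + 0.5 * (a == b)
    v10 <- vapply(xs, function(a) mean(psi(a, ys)), 0)
    v01 <- vapply(ys, function(b) mean(psi(xs, b)), 0)
    list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
  }
  c1 <- comp(r1$scores); c2 <- comp(r2$scores)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / c1$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / c1$n
  d <- c1$auc - c2$auc
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(d) < .Machine$double.eps) 0 else sign(d) * Inf
  } else z <- d / sqrt(var_diff)
  list(auc1 = c1$auc, auc2 = c2$auc, z = z,
       p = if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z)))
}

#' Map the five anatomic bulk structures to core/periphery
#'
#' "leading edge" and "infiltrating tumour" map to periphery; "cellular
#' tumour", "microvascular proliferation" and "pseudopalisading cells" map
#' to core. Matching is case-insensitive and tolerant of the
#' "tumor"/"tumour" spelling and of the long "pseudopalisading cells around
#' necrosis" label.
#'
#' @param labels character vector of structure labels.
#' @return Character vector in `{core, periphery}`.
#' @export
map_ivy_regions <- function(labels) {
  key <- tolower(trimws(labels))
  key <- sub("tumor", "tumour", key, fixed = TRUE)
  key <- sub("^pseudopalisading cells.*$", "pseudopalisading cells", key)
  lut <- c("leading edge" = "periphery", "infiltrating tumour" = "periphery",
           "cellular tumour" = "core",
           "microvascular proliferation" = "core",
           "pseudopalisading cells" = "core")
  bad <- !key %in% names(lut)
  if (any(bad))
    stop("unknown structure label(s): ",
         paste(unique(labels[bad]), collapse = ", "),
         "; accepted: ", paste(names(lut), collapse = ", "))
  unname(lut[key])
}

#' Normalize a bulk expression table
#'
#' Drops genes with zero counts across all samples and transforms to
#' log2(CPM + 1) per sample.
#'
#' @param expr genes x samples non-negative matrix.
#' @return Normalized matrix of the same shape (minus all-zero genes).
#' @export
normalize_bulk <- function(expr) {
  expr <- as.matrix(expr)
  keep <- rowSums(expr) > 0
  expr <- expr[keep, , drop = FALSE]
  cpm <- sweep(expr, 2, colSums(expr), `/`) * 1e6
  log2(cpm + 1)
}

#' Ontogeny scoring and regional AUC on bulk samples
#'
#' Scores each bulk sample with the BMDM and microglia meta-genes (on the
#' normalized table) and computes the ROC of the score difference
#' (bmdm - mg) against the mapped core/periphery region, with core as the
#' positive class. With a single sample per class the AUC is degenerate
#' (0 or 1) and a warning is raised.
#'
#' @param expr genes x samples bulk matrix (raw scale; normalized
#'   internally with [normalize_bulk]).
#' @param bmdm_sig,mg_sig gene id vectors.
#' @param structures per-sample anatomic structure labels (mapped with
#'   [map_ivy_regions]), or already-mapped `core`/`periphery` labels.
#' @return List with `scores` (data.frame `sample_id`, `bmdm_score`,
#'   `mg_score`, `region`) and `roc` (a `roc_result`).
#' @export
bulk_validation <- function(expr, bmdm_sig, mg_sig, structures) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == length(structures))
  region <- if (all(structures %in% c("core", "periphery"))) structures
            else map_ivy_regions(structures)
  norm <- tam_norm(normalize_bulk(expr), transforms = "lognorm")
  sc <- data.frame(sample_id = colnames(expr),
                   bmdm_score = as.numeric(metagene_score(norm, bmdm_sig)),
                   mg_score = as.numeric(metagene_score(norm, mg_sig)),
                   region = region, stringsAsFactors = FALSE)
  if (min(table(region)) < 2)
    warning("a region has a single sample; AUC is degenerate")
  roc <- roc_curve(sc$bmdm_score - sc$mg_score, region == "core")
  list(scores = sc, roc = roc)
}
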