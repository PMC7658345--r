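#' 2x2 chi-squared test with Yates continuity correction
#'
#' Pearson chi-squared on a 2x2 table with the continuity-corrected statistic
#' `sum(max(|O - E| - 0.5, 0)^2 / E)` and an upper-tail p-value on 1 degree
#' of freedom. The correction can be disabled. The table is laid out as
#' rows = outcome (in/out of the category), columns = group (e.g. core,
#' periphery).
#'
#' @param a,b counts of the first row (e.g. in-category core, in-category
#'   periphery is `c`; see below) — the table is `rbind(c(a, b), c(c, d))`.
#' @param c,d counts of the second row.
#' @param yates apply the continuity correction (default `TRUE`).
#' @return A `contingency_result`: list with `table`, `chi2`, `p`, `yates`
#'   and `proportions` (first-row proportion per column).
#' @export
chisq_2x2 <- function(a, b, c, d, yates = TRUE) {
  tab <- rbind(c(a, b), c(c, d))
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin; chi-squared undefined")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - e)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / e)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(table = tab, chi2 = chi2, p = p, yates = yates,
                 proportions = c(a / (a + c), b / (b + d))),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("2x2 chi-squared", if (x$yates) " (Yates-corrected)", ": chi2 = ",
      format(x$chi2, digits = 4), ", p = ", format.pval(x$p, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Regional composition table with per-state chi-squared tests
#'
#' Cross-tabulates per-cell state labels against region labels (`core`,
#' `periphery`) and, for each state, tests whether its proportion differs
#' between regions with a Yates-corrected 2x2 chi-squared (state vs rest).
#'
#' @param states per-cell state labels.
#' @param regions per-cell region labels; must be `core` or `periphery`.
#' @param digits rounding for the percentage columns (default 0, matching a
#'   printed table).
#' @return data.frame with one row per state: counts and percentages for all
#'   cells, core and periphery, plus the chi-squared p-value.
#' @export
composition_table <- function(states, regions, digits = 0) {
  stopifnot(length(states) == length(regions))
  bad <- setdiff(unique(as.character(regions)), c("core", "periphery"))
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  states <- as.factor(states)
  regions <- factor(as.character(regions), levels = c("core", "periphery"))
  tab <- table(states, regions)
  n_core <- sum(tab[, "core"])
  n_peri <- sum(tab[, "periphery"])
  res <- data.frame(state = rownames(tab),
                    all_n = as.integer(rowSums(tab)),
                    all_pct = round(rowSums(tab) / sum(tab) * 100, digits),
                    core_n = as.integer(tab[, "core"]),
                    core_pct = round(tab[, "core"] / n_core * 100, digits),
                    periphery_n = as.integer(tab[, "periphery"]),
                    periphery_pct = round(tab[, "periphery"] / n_peri * 100, digits),
                    stringsAsFactors = FALSE)
  res$p <- vapply(seq_len(nrow(tab)), function(i) {
    chisq_2x2(tab[i, "core"], tab[i, "periphery"],
              n_core - tab[i, "core"], n_peri - tab[i, "periphery"])$p
  }, 0)
  rownames(res) <- NULL
  res
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Uses exact enumeration of all rank splits when `n + m <= 12` (and reports
#' the exact two-sided tail probability of the observed U, ties handled by
#' midranks in the enumeration), and otherwise the normal approximation with
#' tie-corrected variance. When every value is tied across both samples the
#' p-value is 1.
#'
#' @param x,y numeric samples (both non-empty).
#' @return List with `statistic` (U for `x`), `p` and `method`.
#' @export
mannwhitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (length(unique(c(x, y))) == 1)
    return(list(statistic = u, p = 1, method = "degenerate"))
  if (n + m <= 12) {
    combs <- utils::combn(n + m, n)
    us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
    mid <- n * m / 2
    p <- mean(abs(us - mid) >= abs(u - mid) - 1e-12)
    return(list(statistic = u, p = p, method = "exact"))
  }
  mu <- n * m / 2
  ties <- table(r)
  sigma2 <- n * m / 12 * ((n + m + 1) - sum(ties^3 - ties) /
                            ((n + m) * (n + m - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p = 1, method = "degenerate"))
  z <- (u - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(statistic = u, p = min(1, p), method = "normal")
}
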