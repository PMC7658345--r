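#' Meta-gene score of a gene signature
#'
#' A meta-gene is the difference between the centered, log-transformed mean
#' expression of an input gene list and that of all remaining genes. The
#' input matrix is gene-centered internally (centering is idempotent), so a
#' cell population with no expression differences scores exactly zero.
#'
#' @param m a [tam_norm] object (log-normalized).
#' @param sig character vector of signature gene ids (or a single-element
#'   named list as returned by [read_gmt]).
#' @param name optional signature name recorded on the result.
#' @return Named numeric vector of per-cell scores with attributes
#'   `signature_name` and `n_genes_used` (signature genes found in the
#'   matrix).
#' @export
metagene_score <- function(m, sig, name = NULL) {
  stopifnot(inherits(m, "tam_norm"))
  if (is.list(sig)) {
    if (is.null(name)) name <- names(sig)[1]
    sig <- sig[[1]]
  }
  if (is.null(name)) name <- "signature"
  genes <- rownames(m$values)
  in_sig <- genes %in% sig
  if (!any(in_sig))
    stop("no signature genes found in matrix; missing: ",
         paste(utils::head(setdiff(sig, genes), 10), collapse = ", "))
  if (all(in_sig)) stop("signature covers every gene; complement is empty")
  v <- m$values - rowMeans(m$values)
  score <- colMeans(v[in_sig, , drop = FALSE]) -
    colMeans(v[!in_sig, , drop = FALSE])
  attr(score, "signature_name") <- name
  attr(score, "n_genes_used") <- sum(in_sig)
  score
}

#' AUCell-style hard threshold assignment
#'
#' Per cell, genes are ranked by expression (descending; ties broken by input
#' gene order, i.e. row index) and the normalized area under the recovery
#' curve of signature genes within the top `top_frac` of the ranking is
#' computed. The area is normalized so that a signature occupying the very
#' top of the ranking scores 1 and a signature entirely below the window
#' scores 0. Cells are assigned `TRUE` when the AUC reaches `auc_threshold`.
#'
#' @param m a [tam_norm] object.
#' @param sig character vector of signature gene ids.
#' @param auc_threshold assignment cut-off on the normalized AUC.
#' @param top_frac fraction of the ranking forming the evaluation window
#'   (default 0.05).
#' @return Logical per-cell vector with attribute `auc` (the per-cell AUC).
#' @export
aucell_assign <- function(m, sig, auc_threshold, top_frac = 0.05) {
  stopifnot(inherits(m, "tam_norm"))
  genes <- rownames(m$values)
  in_sig <- genes %in% sig
  if (!any(in_sig)) stop("no signature genes found in matrix")
  n_genes <- length(genes)
  w <- max(1L, as.integer(ceiling(top_frac * n_genes)))
  s <- sum(in_sig)
  if (s > w)
    warning("signature (", s, " genes) larger than top window (", w, " ranks)")
  max_area <- sum(pmin(seq_len(w), s))
  auc <- apply(m$values, 2, function(x) {
    ord <- order(-x, seq_along(x))      # ties by input gene index
    hits <- cumsum(in_sig[ord][seq_len(w)])
    sum(hits) / max_area
  })
  out <- auc >= auc_threshold
  names(out) <- colnames(m$values)
  attr(out, "auc") <- stats::setNames(auc, colnames(m$values))
  out
}

#' Macrophage polarization and differentiation indices
#'
#' A signature-based activation surrogate: the raw polarization index (MPI)
#' is the difference of meta-gene scores over a pro-inflammatory-positive and
#' a pro-inflammatory-negative signature, and the raw differentiation index
#' (AMDI) likewise over maturation-positive and maturation-negative
#' signatures. Each raw index is affinely rescaled over cells so that the
#' minimum maps to -50 and the maximum to +50 (a degenerate constant index
#' maps to 0). Higher MPI means more pro-inflammatory; higher AMDI means more
#' mature. Cells are then labelled by quadrant (see [classify_quadrant]).
#'
#' @param m a [tam_norm] object (log-normalized).
#' @param pol_pos,pol_neg,dif_pos,dif_neg character vectors of gene ids for
#'   the four signatures.
#' @return An `activation_profile`: data.frame with columns `cell_id`, `MPI`,
#'   `AMDI` and `state`.
#' @export
activation_scores <- function(m, pol_pos, pol_neg, dif_pos, dif_neg) {
  stopifnot(inherits(m, "tam_norm"))
  raw_mpi <- as.numeric(metagene_score(m, pol_pos, "pol_pos")) -
    as.numeric(metagene_score(m, pol_neg, "pol_neg"))
  raw_amdi <- as.numeric(metagene_score(m, dif_pos, "dif_pos")) -
    as.numeric(metagene_score(m, dif_neg, "dif_neg"))
  rescale50 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(rep(0, length(x)))
    (x - rng[1]) / diff(rng) * 100 - 50
  }
  out <- data.frame(cell_id = colnames(m$values),
                    MPI = rescale50(raw_mpi),
                    AMDI = rescale50(raw_amdi),
                    stringsAsFactors = FALSE)
  out$state <- classify_quadrant(out$AMDI, out$MPI)
  class(out) <- c("activation_profile", "data.frame")
  out
}

#' Quadrant classification of activation scores
#'
#' Maps (AMDI, MPI) score pairs to the four activation-state labels:
#' `M0` (pre-activation; AMDI and MPI on the negative side), `M1-pre`
#' (transitional pro-inflammatory; AMDI negative, MPI positive), `M2-like`
#' (mature anti-inflammatory; AMDI positive, MPI negative) and `M1-like`
#' (mature pro-inflammatory; both positive). A score of exactly 0 counts as
#' the negative side.
#'
#' @param amdi,mpi numeric vectors of equal length (finite).
#' @return Factor with levels `M0`, `M1-pre`, `M1-like`, `M2-like`.
#' @export
classify_quadrant <- function(amdi, mpi) {
  stopifnot(length(amdi) == length(mpi), all(is.finite(amdi)),
            all(is.finite(mpi)))
  state <- ifelse(amdi > 0,
                  ifelse(mpi > 0, "M1-like", "M2-like"),
                  ifelse(mpi > 0, "M1-pre", "M0"))
  factor(state, levels = c("M0", "M1-pre", "M1-like", "M2-like"))
}

#' @export
print.activation_profile <- function(x, ...) {
  cat("activation_profile: ", nrow(x), " cells\n", sep = "")
  print(table(x$state))
  invisible(x)
}
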