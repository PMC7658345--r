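#' Read a count matrix from MatrixMarket or dense TSV
#'
#' For `format = "mtx"`, `path` is the MatrixMarket coordinate file (1-based
#' indices) and the gene/cell sidecars default to `genes.tsv` / `cells.tsv` in
#' the same directory. The genes sidecar is a headerless one-column (or first
#' column used) TSV of gene ids; the cells sidecar is a TSV with a header row
#' containing at least `cell_id`, `region` and `tumor_id`. For
#' `format = "tsv"`, `path` is a dense genes-by-cells table whose header row
#' holds cell ids and first column holds gene ids, and `cells_file` is
#' required. Readers are gzip-transparent.
#'
#' Spike-in quality-control genes (ids starting with `ERCC`, case-insensitive)
#' are removed on read.
#'
#' @param path path to the matrix file.
#' @param format `"mtx"` or `"tsv"`.
#' @param genes_file,cells_file sidecar paths (mtx defaults as above).
#' @return A [tam_counts] object.
#' @export
read_counts <- function(path, format = c("mtx", "tsv"),
                        genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    dirn <- dirname(path)
    if (is.null(genes_file)) genes_file <- file.path(dirn, "genes.tsv")
    if (is.null(cells_file)) cells_file <- file.path(dirn, "cells.tsv")
    for (f in c(genes_file, cells_file))
      if (!file.exists(f)) stop("sidecar file not found: ", f)
    m <- Matrix::readMM(path)
    genes <- utils::read.delim(genes_file, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    meta <- utils::read.delim(cells_file, header = TRUE,
                              stringsAsFactors = FALSE)
    if (length(genes) != nrow(m))
      stop("dimension mismatch: ", genes_file, " lists ", length(genes),
           " genes but ", path, " declares ", nrow(m))
    if (nrow(meta) != ncol(m))
      stop("dimension mismatch: ", cells_file, " lists ", nrow(meta),
           " cells but ", path, " declares ", ncol(m))
    rownames(m) <- genes
    colnames(m) <- meta$cell_id
  } else {
    if (is.null(cells_file)) stop("cells_file is required for format 'tsv'")
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- tab[[1]]
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- genes
    meta <- utils::read.delim(cells_file, header = TRUE,
                              stringsAsFactors = FALSE)
    if (nrow(meta) != ncol(m))
      stop("dimension mismatch: ", cells_file, " lists ", nrow(meta),
           " cells but ", path, " has ", ncol(m))
  }
  out <- tam_counts(m, meta)
  spike <- grepl("^ercc", rownames(out$counts), ignore.case = TRUE)
  if (any(spike)) out <- subset_counts(out, genes = !spike)
  out
}

#' Log-normalize counts
#'
#' Divides each cell's counts by the cell total, multiplies by `scale_factor`
#' and applies `log(1 + x)`. Cells with a zero total are dropped with a
#' warning.
#'
#' @param m a [tam_counts] object.
#' @param scale_factor library-size scale factor (default 10,000).
#' @return A [tam_norm] with the `"lognorm"` flag set.
#' @export
lognormalize <- function(m, scale_factor = 10000) {
  stopifnot(inherits(m, "tam_counts"))
  tot <- Matrix::colSums(m$counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " cell(s) with zero total counts dropped")
    m <- subset_counts(m, cells = tot > 0)
    tot <- tot[tot > 0]
  }
  v <- as.matrix(m$counts) %*% diag(1 / tot, length(tot))
  dimnames(v) <- dimnames(m$counts)
  v <- log1p(v * scale_factor)
  tam_norm(v, transforms = "lognorm", scale_factor = scale_factor,
           cell_meta = m$cell_meta)
}

#' Regress a categorical label out of normalized expression
#'
#' Replaces each gene's values with the residuals of a least-squares fit on
#' the label indicators plus intercept. For indicator regression these
#' residuals are the within-label deviations, so per-gene within-label means
#' are zero afterwards.
#'
#' @param m a [tam_norm] object.
#' @param labels per-cell categorical label (e.g. tumor id), aligned with
#'   the matrix columns.
#' @return A [tam_norm] with the `"regressed"` flag added.
#' @export
regress_out_label <- function(m, labels) {
  stopifnot(inherits(m, "tam_norm"))
  labels <- as.factor(labels)
  if (length(labels) != ncol(m$values))
    stop("labels must cover all ", ncol(m$values), " cells")
  n_per <- table(labels)
  if (any(n_per == 1))
    warning("label(s) with a single cell get residual 0: ",
            paste(names(n_per)[n_per == 1], collapse = ", "))
  v <- m$values
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    v[, idx] <- v[, idx, drop = FALSE] - rowMeans(v[, idx, drop = FALSE])
  }
  tam_norm(v, transforms = union(m$transforms, "regressed"),
           scale_factor = m$scale_factor, cell_meta = m$cell_meta)
}

#' Center and scale each gene
#'
#' Centers every gene to mean zero and scales to unit population standard
#' deviation (divide by n, not n-1). Zero-variance genes are left as all-zero
#' rows, never NaN.
#'
#' @param m a [tam_norm] object.
#' @return A [tam_norm] with `"centered"` and `"scaled"` flags added.
#' @export
center_scale <- function(m) {
  stopifnot(inherits(m, "tam_norm"))
  v <- m$values - rowMeans(m$values)
  sdv <- sqrt(rowMeans(v^2))
  nz <- sdv > 0
  v[nz, ] <- v[nz, , drop = FALSE] / sdv[nz]
  tam_norm(v, transforms = union(m$transforms, c("centered", "scaled")),
           scale_factor = m$scale_factor, cell_meta = m$cell_meta)
}

#' Keep genes expressed in at least `min_cells` cells
#'
#' @param m a [tam_counts] object.
#' @param min_cells minimum number of cells with a nonzero count (default 10).
#' @return A filtered [tam_counts].
#' @export
filter_genes_min_cells <- function(m, min_cells = 10) {
  stopifnot(inherits(m, "tam_counts"))
  n_expr <- Matrix::rowSums(m$counts > 0)
  keep <- n_expr >= min_cells
  if (!any(keep)) stop("all genes removed at min_cells = ", min_cells)
  subset_counts(m, genes = keep)
}

#' Remove cells with outlier sequencing depth
#'
#' Keeps cells whose log10 total count lies within `n_sd` population standard
#' deviations of the mean log10 total. Zero-total cells are removed first with
#' a warning.
#'
#' @param m a [tam_counts] object with at least 3 cells.
#' @param n_sd number of standard deviations (default 2).
#' @return A filtered [tam_counts].
#' @export
filter_cells_depth_outliers <- function(m, n_sd = 2) {
  stopifnot(inherits(m, "tam_counts"))
  if (ncol(m$counts) < 3) stop("need at least 3 cells")
  tot <- Matrix::colSums(m$counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-total cell(s) removed before log transform")
    m <- subset_counts(m, cells = tot > 0)
    tot <- tot[tot > 0]
  }
  lt <- log10(tot)
  mu <- mean(lt)
  sdv <- sqrt(mean((lt - mu)^2))
  keep <- abs(lt - mu) <= n_sd * sdv
  subset_counts(m, cells = keep)
}

#' Fraction of cells expressing each gene
#'
#' @param m a [tam_counts] object.
#' @param genes gene ids to evaluate; genes absent from the matrix get
#'   fraction 0 with a warning.
#' @return Named numeric vector of fractions in \\[0, 1\\].
#' @export
expression_fraction <- function(m, genes) {
  stopifnot(inherits(m, "tam_counts"))
  miss <- setdiff(genes, rownames(m$counts))
  if (length(miss))
    warning("genes absent from matrix get fraction 0: ",
            paste(miss, collapse = ", "))
  frac <- stats::setNames(numeric(length(genes)), genes)
  present <- intersect(genes, rownames(m$counts))
  if (length(present))
    frac[present] <- Matrix::rowSums(m$counts[present, , drop = FALSE] > 0) /
      ncol(m$counts)
  frac
}

#' Read gene signatures from a GMT file
#'
#' GMT is tab-separated: set name, description, then member genes. The reader
#' is gzip-transparent.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Write gene signatures to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written for every set (default the
#'   set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  lines <- vapply(seq_along(sets), function(i) {
    desc <- if (is.null(description)) names(sets)[i] else description
    paste(c(names(sets)[i], desc, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a ligand-receptor pair table
#'
#' Two-column TSV with header `ligand<TAB>receptor`; duplicate pairs are
#' dropped.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `ligand` and `receptor`.
#' @export
read_pair_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab)))
    stop("pair table must have columns 'ligand' and 'receptor'")
  unique(tab[, c("ligand", "receptor")])
}
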