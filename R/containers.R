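#' Single-cell count matrix with per-cell metadata
#'
#' Bundles a gene-by-cell matrix of non-negative integer counts with aligned
#' per-cell metadata. Gene and cell identifiers must be unique; metadata rows
#' align 1:1 with the matrix columns and must carry at least a `region` column
#' (values `"core"` or `"periphery"`) and a `tumor_id` column.
#'
#' @param counts gene-by-cell matrix (dense or `Matrix` sparse) of counts,
#'   with rownames (gene ids) and colnames (cell ids).
#' @param cell_meta data.frame with one row per cell; must contain columns
#'   `cell_id`, `region` and `tumor_id`. Rows are matched to `counts` columns
#'   by `cell_id`.
#' @return An object of class `tam_counts`: a list with elements `counts`
#'   (a `dgCMatrix`) and `cell_meta`.
#' @examples
#' m <- matrix(rpois(12, 3), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' meta <- data.frame(cell_id = colnames(m),
#'                    region = c("core", "core", "periphery", "periphery"),
#'                    tumor_id = "T1")
#' tam_counts(m, meta)
#' @export
tam_counts <- function(counts, cell_meta) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and cell colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(counts < 0)) stop("counts must be non-negative")
  cell_meta <- as.data.frame(cell_meta)
  req <- c("cell_id", "region", "tumor_id")
  miss <- setdiff(req, names(cell_meta))
  if (length(miss)) stop("cell_meta missing columns: ", paste(miss, collapse = ", "))
  if (nrow(cell_meta) != ncol(counts))
    stop("cell_meta has ", nrow(cell_meta), " rows but counts has ",
         ncol(counts), " cells")
  if (!setequal(cell_meta$cell_id, colnames(counts)))
    stop("cell_meta$cell_id does not match counts colnames")
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  structure(list(counts = counts, cell_meta = cell_meta), class = "tam_counts")
}

#' @export
print.tam_counts <- function(x, ...) {
  cat("tam_counts: ", nrow(x$counts), " genes x ", ncol(x$counts), " cells\n",
      sep = "")
  tab <- table(x$cell_meta$region)
  cat("  regions: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.tam_counts <- function(x) dim(x$counts)

#' Subset a tam_counts object
#'
#' @param x a `tam_counts` object.
#' @param genes gene ids or indices (missing keeps all).
#' @param cells cell ids or indices (missing keeps all).
#' @return A `tam_counts` restricted to the requested genes and cells.
#' @export
subset_counts <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "tam_counts"))
  m <- x$counts
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  meta <- x$cell_meta[match(colnames(m), x$cell_meta$cell_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = m, cell_meta = meta), class = "tam_counts")
}

#' Normalized expression matrix
#'
#' A gene-by-cell real-valued matrix together with a record of which
#' transformations have been applied (`"lognorm"`, `"regressed"`,
#' `"centered"`, `"scaled"`).
#'
#' @param values gene-by-cell numeric matrix with dimnames.
#' @param transforms character vector of applied transformation flags.
#' @param scale_factor positive scale factor used by log-normalization.
#' @param cell_meta optional per-cell metadata carried along from the counts.
#' @return An object of class `tam_norm`.
#' @export
tam_norm <- function(values, transforms = character(), scale_factor = 10000,
                     cell_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have dimnames")
  stopifnot(scale_factor > 0)
  structure(list(values = values, transforms = transforms,
                 scale_factor = scale_factor, cell_meta = cell_meta),
            class = "tam_norm")
}

#' @export
print.tam_norm <- function(x, ...) {
  cat("tam_norm: ", nrow(x$values), " genes x ", ncol(x$values), " cells",
      if (length(x$transforms)) paste0(" [", paste(x$transforms, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.tam_norm <- function(x) dim(x$values)

has_transform <- function(x, flag) flag %in% x$transforms
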