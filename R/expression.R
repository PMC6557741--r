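# Expression matrix container, I/O and normalization.

#' Construct an expression matrix object
#'
#' @param values Numeric matrix, cells in rows and genes in columns, with
#'   both dimnames set.
#' @param labels Optional named character vector of cell-type labels covering
#'   every cell, or an unnamed vector in row order.
#' @param normalization One of `"raw"`, `"log"`, `"log_zscore"`.
#' @param dropped_genes Genes removed for missing values during loading.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, labels = NULL, normalization = "raw",
                        dropped_genes = character()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_config("`values` must be a numeric matrix (cells x genes).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_config("`values` needs cell rownames and gene colnames.")
  }
  if (anyDuplicated(colnames(values))) {
    abort_config("Duplicate gene identifiers in expression matrix.")
  }
  if (anyDuplicated(rownames(values))) {
    abort_config("Duplicate cell identifiers in expression matrix.")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels) |> stats::setNames(names(labels) %||% rownames(values))
    missing <- setdiff(rownames(values), names(labels))
    if (length(missing) > 0) {
      abort_config(sprintf("Labels missing for %d cells.", length(missing)))
    }
    labels <- labels[rownames(values)]
  }
  normalization <- match.arg(normalization, c("raw", "log", "log_zscore"))
  structure(
    list(
      values = values,
      labels = labels,
      normalization = normalization,
      dropped_genes = as.character(dropped_genes)
    ),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d cells x %d genes [%s]%s\n",
    nrow(x$values), ncol(x$values), x$normalization,
    if (!is.null(x$labels)) sprintf(", %d cell types", length(unique(x$labels))) else ""
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(x) colnames(x$values)
cell_ids <- function(x) rownames(x$values)

#' Subset cells of an expression matrix
#'
#' @param x An `expr_matrix`.
#' @param cells Cell identifiers or logical/integer index over rows.
#' @return An `expr_matrix` with the selected cells.
#' @export
subset_cells <- function(x, cells) {
  v <- x$values[cells, , drop = FALSE]
  expr_matrix(v, labels = x$labels[rownames(v)],
              normalization = x$normalization, dropped_genes = x$dropped_genes)
}

read_dense_expression <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = delim, header = TRUE, row.names = 1L,
                   check.names = FALSE, colClasses = "character")
  raw <- as.matrix(df)
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw), dimnames = dimnames(raw)))
  bad <- which(is.na(num) & !is.na(raw) & !(trimws(raw) %in% c("NA", "NaN", "")),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_parse(sprintf(
      "Non-numeric value %s at row '%s', column '%s'.",
      raw[bad[1, 1], bad[1, 2]], rownames(num)[bad[1, 1]], colnames(num)[bad[1, 2]]
    ))
  }
  num
}

read_mm_expression <- function(path, gene_file, cell_file, orientation) {
  if (is.null(gene_file) || is.null(cell_file)) {
    abort_config("Matrix-market input needs `gene_file` and `cell_file` id lists.")
  }
  m <- as.matrix(Matrix::readMM(path))
  genes <- readLines(gene_file, warn = FALSE)
  cells <- readLines(cell_file, warn = FALSE)
  if (orientation == "genes_as_rows") {
    dimnames(m) <- list(genes, cells)
  } else {
    dimnames(m) <- list(cells, genes)
  }
  m
}

#' Load an expression matrix from disk
#'
#' Reads either a dense delimited file (TSV or CSV, header row, first column
#' holding row identifiers) or a matrix-market coordinate file with
#' companion gene/cell id lists (one id per line). The caller must state the
#' orientation explicitly; nothing is auto-detected, because a silently
#' transposed matrix is the classic single-cell I/O bug. Genes containing
#' any missing value are dropped (and recorded in `dropped_genes`).
#'
#' @param path Path to the matrix file; `.mtx` selects matrix-market.
#' @param orientation `"cells_as_rows"` or `"genes_as_rows"` describing the
#'   file on disk.
#' @param gene_file,cell_file Id files, required for matrix-market input.
#' @param label_file Optional two-column TSV (`cell_id`, `type`).
#' @return An `expr_matrix` with `normalization = "raw"`.
#' @export
load_expression <- function(path,
                            orientation = c("cells_as_rows", "genes_as_rows"),
                            gene_file = NULL, cell_file = NULL,
                            label_file = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    abort_config(sprintf("Expression file not found: %s", path))
  }
  m <- if (grepl("\\.mtx$", path)) {
    read_mm_expression(path, gene_file, cell_file, orientation)
  } else {
    read_dense_expression(path)
  }
  if (orientation == "genes_as_rows") m <- t(m)
  if (anyDuplicated(colnames(m))) {
    abort_config("Duplicate gene identifiers in expression input.")
  }
  has_na <- apply(m, 2, anyNA)
  dropped <- colnames(m)[has_na]
  if (length(dropped) > 0) {
    inform(sprintf("Dropped %d genes with missing values.", length(dropped)))
    m <- m[, !has_na, drop = FALSE]
  }
  labels <- NULL
  if (!is.null(label_file)) {
    lab <- readr::read_tsv(label_file, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    labels <- stats::setNames(lab[[2]], lab[[1]])
  }
  expr_matrix(m, labels = labels, normalization = "raw", dropped_genes = dropped)
}

#' Write an expression matrix (and labels) to disk
#'
#' Dense TSV, cells as rows, first column `cell_id`.
#'
#' @param x An `expr_matrix`.
#' @param path Output TSV path.
#' @param label_path Optional path for a two-column label TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, label_path = NULL) {
  df <- data.frame(cell_id = rownames(x$values), x$values, check.names = FALSE)
  readr::write_tsv(df, path)
  if (!is.null(label_path)) {
    if (is.null(x$labels)) abort_config("No labels to write.")
    readr::write_tsv(
      tibble(cell_id = names(x$labels), type = unname(x$labels)),
      label_path
    )
  }
  invisible(path)
}

#' Normalize an expression matrix
#'
#' `"log"` applies `ln(1 + x)` elementwise. `"log_zscore"` additionally
#' standardizes every gene across cells (subtract mean, divide by standard
#' deviation); genes with zero variance are left at 0 so gene indexing stays
#' aligned with the connectivity mask. Network input uses `log_zscore`;
#' diversity scoring uses the `log` stage (z-scoring would force every
#' per-gene standard deviation to 1 and make the diversity score vacuous).
#'
#' @param x A raw `expr_matrix`.
#' @param scheme `"log"` or `"log_zscore"` (alias `"log+zscore"`).
#' @return A normalized `expr_matrix`.
#' @export
normalize_expression <- function(x, scheme = c("log_zscore", "log", "log+zscore")) {
  scheme <- match.arg(scheme)
  if (scheme == "log+zscore") scheme <- "log_zscore"
  if (x$normalization != "raw") {
    abort_config("Input must be raw (unnormalized) expression.")
  }
  if (any(x$values < 0)) {
    abort_config("Raw expression must be nonnegative.")
  }
  v <- log1p(x$values)
  if (scheme == "log_zscore") {
    mu <- colMeans(v)
    sdv <- apply(v, 2, sd)
    v <- sweep(v, 2, mu, "-")
    nz <- sdv > 0
    v[, nz] <- sweep(v[, nz, drop = FALSE], 2, sdv[nz], "/")
    v[, !nz] <- 0
  }
  expr_matrix(v, labels = x$labels, normalization = scheme,
              dropped_genes = x$dropped_genes)
}

#' Per-gene standard deviations on the log scale
#'
#' Convenience summary feeding [select_significant_terms()]: standard
#' deviation of `ln(1 + x)` expression across cells, per gene.
#'
#' @param x An `expr_matrix`, raw or log-normalized.
#' @return Named numeric vector over genes.
#' @export
gene_sds <- function(x) {
  v <- switch(x$normalization,
    raw = log1p(x$values),
    log = x$values,
    abort_config("gene_sds needs raw or log-normalized expression (not z-scored).")
  )
  apply(v, 2, sd)
}
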