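# Gene -> hidden-unit connectivity mask.

#' Build the gene-to-unit connectivity mask
#'
#' Produces the binary gene x unit matrix that fixes which input genes feed
#' which first-hidden-layer units. One column per kept GO term (biological
#' process before molecular function), with a 1 wherever the gene is
#' annotated by that term, followed by `n_dense` all-ones columns for the
#' fully connected units.
#'
#' @param x An `expr_matrix` supplying the gene order.
#' @param sel A `term_selection` from [select_significant_terms()].
#' @param n_dense Number of fully connected units appended after the term
#'   units. Default 100.
#' @return A `go_mask`: list with `matrix` (genes x units), `unit_terms`
#'   (term ids for the partially connected columns) and `n_dense`.
#' @export
build_mask <- function(x, sel, n_dense = 100) {
  n_dense <- check_count(n_dense, "n_dense", min = 0L)
  genes <- gene_ids(x)
  # BP columns before MF, preserving candidate order within each namespace
  ns <- sel$table$namespace[match(sel$kept, sel$table$term)]
  ord <- order(match(ns, c("biological_process", "molecular_function",
                           "cellular_component")))
  terms <- sel$kept[ord]

  cols <- lapply(terms, function(t) {
    present <- intersect(sel$genes[[t]], genes)
    if (length(present) == 0) {
      abort_config(sprintf(
        "Kept term %s has no annotated genes in the expression matrix.", t
      ))
    }
    as.numeric(genes %in% present)
  })
  m <- do.call(cbind, c(cols, list(deparse.level = 0)))
  if (n_dense > 0) {
    m <- cbind(m, matrix(1, nrow = length(genes), ncol = n_dense))
  }
  dimnames(m) <- list(genes, c(terms, if (n_dense > 0) sprintf("dense_%03d", seq_len(n_dense))))
  uncovered <- rowSums(m) == 0
  if (any(uncovered)) {
    warn(sprintf(
      "%d genes are connected to no hidden unit (no annotation, no dense units).",
      sum(uncovered)
    ))
  }
  structure(
    list(matrix = m, unit_terms = terms, n_dense = n_dense),
    class = "go_mask"
  )
}

#' @export
print.go_mask <- function(x, ...) {
  cat(sprintf(
    "<go_mask> %d genes x %d units (%d GO terms + %d dense), density %.3f\n",
    nrow(x$matrix), ncol(x$matrix), length(x$unit_terms), x$n_dense,
    mean(x$matrix)
  ))
  invisible(x)
}

#' Write a mask as matrix-market plus a unit map
#'
#' @param mask A `go_mask`.
#' @param path Output `.mtx` path; the unit map TSV is written next to it as
#'   `<path>.units.tsv`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  Matrix::writeMM(Matrix::Matrix(mask$matrix, sparse = TRUE), path)
  readr::write_tsv(
    tibble(
      column = seq_len(ncol(mask$matrix)),
      unit = colnames(mask$matrix),
      kind = c(rep("term", length(mask$unit_terms)), rep("dense", mask$n_dense))
    ),
    paste0(path, ".units.tsv")
  )
  invisible(path)
}
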