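# Ranking GO-term hidden units by importance per cell type.

rank_tibble <- function(terms, scores, top, cell_type, model_kind) {
  if (top > length(terms)) {
    warn(sprintf(
      "Requested top %d but only %d term units exist; returning all.",
      top, length(terms)
    ))
    top <- length(terms)
  }
  ord <- order(-scores, terms) # ties broken lexicographically by term id
  idx <- ord[seq_len(top)]
  tibble(
    cell_type = cell_type,
    model = model_kind,
    rank = seq_len(top),
    term = terms[idx],
    score = unname(scores[idx])
  )
}

#' Rank GO-term units of a GOAE model by activation
#'
#' Importance of a term unit for a cell population is its mean absolute
#' first-hidden-layer activation across those cells (activations are tanh,
#' hence signed). Dense units are excluded. In the published protocol the
#' autoencoder is trained on cells of a single type and the units are then
#' ranked on those same cells.
#'
#' @param fit A `goae_fit` (or `goae_model`).
#' @param cells An `expr_matrix` restricted to the cells of interest,
#'   normalized as for training, same gene order as the model.
#' @param top Number of terms to return, default 10 (clamped with a warning
#'   if fewer term units exist).
#' @param cell_type Label recorded in the output; defaults to the cells'
#'   unique label if available.
#' @return Tibble: `cell_type`, `model`, `rank`, `term`, `score`, sorted by
#'   descending score.
#' @export
rank_goae_terms <- function(fit, cells, top = 10, cell_type = NULL) {
  model <- as_model(fit)
  top <- check_count(top, "top")
  if (!identical(gene_ids(cells), model$gene_ids)) {
    abort_config("Gene order of the expression matrix and model differ.")
  }
  if (nrow(cells$values) < 1) abort_config("Need at least one cell.")
  if (is.null(cell_type)) {
    u <- unique(cells$labels)
    cell_type <- if (length(u) == 1) u else NA_character_
  }
  acts <- masked_forward(cells$values, model$layers[[1]])
  n_terms <- length(model$unit_terms)
  imp <- colMeans(abs(acts[, seq_len(n_terms), drop = FALSE]))
  rank_tibble(model$unit_terms, imp, top, cell_type, "goae")
}

#' Rank GO-term units of a GONN model by weight path
#'
#' The importance of term unit `t` for class `c` is the absolute value of
#' entry `(t, c)` of the product `W2 W3` of the two weight matrices above
#' the term layer — the accumulated linear path weight from the unit to the
#' class output. Dense units are excluded.
#'
#' @param fit A `gonn_fit` (or `gonn_model`).
#' @param top Number of terms per class, default 10.
#' @return Tibble with one ranked block per class: `cell_type`, `model`,
#'   `rank`, `term`, `score`.
#' @export
rank_gonn_terms <- function(fit, top = 10) {
  model <- as_model(fit)
  top <- check_count(top, "top")
  W23 <- model$layers[[2]]$W %*% model$layers[[3]]$W # units x classes
  n_terms <- length(model$unit_terms)
  purrr::map_dfr(seq_along(model$classes), function(ci) {
    imp <- abs(W23[seq_len(n_terms), ci])
    rank_tibble(model$unit_terms, imp, top, model$classes[ci], "gonn")
  })
}

#' Write a term-importance table
#'
#' @param importance Tibble from [rank_goae_terms()] or [rank_gonn_terms()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(importance, path) {
  readr::write_tsv(importance, path)
  invisible(path)
}
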