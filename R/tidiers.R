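# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a term selection
#'
#' One row per candidate term with its namespace, gene counts, diversity
#' score and the kept/removed decision.
#'
#' @param x A `term_selection`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.term_selection <- function(x, ...) x$table

#' @rdname tidy.term_selection
#' @export
glance.term_selection <- function(x, ...) {
  tibble(
    n_candidates = length(x$candidates),
    n_kept = length(x$kept),
    n_redundant = sum(x$table$reason == "redundant", na.rm = TRUE),
    n_low_diversity = sum(x$table$reason == "low_diversity", na.rm = TRUE),
    layer = x$params$layer,
    u_threshold = x$params$u_threshold,
    h_threshold = x$params$h_threshold,
    skip_selection = x$params$skip_selection
  )
}

#' Tidy a trained model fit
#'
#' The per-epoch training loss trace.
#'
#' @param x A `goae_fit` or `gonn_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`.
#' @export
tidy.goae_fit <- function(x, ...) x$trace

#' @rdname tidy.goae_fit
#' @export
tidy.gonn_fit <- function(x, ...) x$trace

fit_glance <- function(x, kind) {
  tibble(
    model = kind,
    n_genes = length(x$model$gene_ids),
    n_term_units = length(x$model$unit_terms),
    n_dense_units = x$model$n_dense,
    epochs = x$config$epochs,
    batch_size = x$config$batch_size,
    learning_rate = x$config$learning_rate,
    optimizer = x$config$optimizer,
    seed = x$config$seed,
    final_loss = x$trace$loss[nrow(x$trace)]
  )
}

#' @rdname tidy.goae_fit
#' @export
glance.goae_fit <- function(x, ...) {
  dplyr::mutate(fit_glance(x, "goae"), latent_dim = x$model$latent_dim)
}

#' @rdname tidy.goae_fit
#' @export
glance.gonn_fit <- function(x, ...) {
  dplyr::mutate(fit_glance(x, "gonn"),
                hidden_dim = x$model$hidden_dim,
                n_classes = length(x$model$classes))
}

#' Tidy a clustering report
#'
#' @param x A `clustering_report`.
#' @param ... Unused.
#' @return Per-run tibble with `run`, `seed`, `k`, `ari`, `nmi`.
#' @export
tidy.clustering_report <- function(x, ...) x$runs

#' @rdname tidy.clustering_report
#' @export
glance.clustering_report <- function(x, ...) {
  tibble(
    k = x$k, n_runs = nrow(x$runs),
    mean_ari = x$mean_ari, mean_nmi = x$mean_nmi,
    sd_ari = sd(x$runs$ari), sd_nmi = sd(x$runs$nmi)
  )
}

#' Tidy an assignment report
#'
#' @param x An `assignment_report`.
#' @param ... Unused.
#' @return Per-query tibble.
#' @export
tidy.assignment_report <- function(x, ...) x$assignments

#' @rdname tidy.assignment_report
#' @export
glance.assignment_report <- function(x, ...) {
  tibble(K = x$K, accuracy = x$accuracy, map = x$map, average = x$average)
}
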