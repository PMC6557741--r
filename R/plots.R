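# ggplot2 graphics for the package's result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a training loss trace
#'
#' @param object A `goae_fit` or `gonn_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.goae_fit <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$epoch, y = .data$loss)) +
    geom_line(color = "steelblue") +
    labs(x = "Epoch", y = "Mean loss", title = "GOAE training loss") +
    theme_minimal()
}

#' @rdname autoplot.goae_fit
#' @export
autoplot.gonn_fit <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$epoch, y = .data$loss)) +
    geom_line(color = "firebrick") +
    labs(x = "Epoch", y = "Mean loss", title = "GONN training loss") +
    theme_minimal()
}

#' Plot per-run clustering scores
#'
#' @param object A `clustering_report`.
#' @param ... Unused.
#' @return A ggplot with one point per run and metric.
#' @export
autoplot.clustering_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$runs, c("ari", "nmi"),
                              names_to = "metric", values_to = "score")
  ggplot(long, aes(x = factor(.data$run), y = .data$score)) +
    geom_point() +
    facet_wrap(~metric, ncol = 1) +
    labs(x = "Run", y = "Score",
         title = sprintf("Clustering scores over %d kmeans++ runs (k = %d)",
                         nrow(object$runs), object$k)) +
    theme_minimal()
}

#' Plot a term-importance ranking
#'
#' @param importance Tibble from [rank_goae_terms()] or [rank_gonn_terms()].
#' @return A ggplot, faceted by cell type.
#' @export
plot_term_importance <- function(importance) {
  ggplot(importance,
         aes(x = stats::reorder(.data$term, .data$score), y = .data$score)) +
    geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    facet_wrap(~cell_type, scales = "free") +
    labs(x = NULL, y = "Importance",
         title = "GO-term hidden units ranked by importance") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
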