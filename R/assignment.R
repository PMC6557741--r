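# Nearest-neighbor cell-type assignment scored by mean average precision.

#' Assign cell types by top-K nearest neighbors
#'
#' For each query cell, the K Euclidean nearest reference cells are
#' retrieved (distance ties broken by reference index for determinism). The
#' predicted type is the majority label among those neighbors (majority ties
#' resolved to the lexicographically smallest type). When query labels are
#' supplied, per-query average precision is computed over the ranked top-K
#' list, treating references of the query's own type as relevant; average
#' precisions are aggregated to the mean average precision (MAP), either
#' macro (averaged within type, then across types; default) or micro (over
#' all queries).
#'
#' @param query_emb Matrix of query embeddings (cells x dims).
#' @param ref_emb Matrix of reference embeddings with the same width.
#' @param ref_labels Cell-type labels of the reference cells (row order or
#'   named by reference rowname).
#' @param query_labels Optional true labels of the query cells, needed for
#'   precision scoring.
#' @param K Number of neighbors, default 100 (must not exceed the usable
#'   reference size).
#' @param exclude_self If `TRUE`, query row i may not retrieve reference row
#'   i (use when query and reference are the same matrix).
#' @param average `"macro"` or `"micro"` MAP aggregation.
#' @return An `assignment_report`: list with `assignments` (tibble: cell,
#'   predicted_type, true_type, average_precision), `per_type` (tibble:
#'   type, n, mean_ap), `map`, `accuracy`, `K`.
#' @export
assign_cell_types <- function(query_emb, ref_emb, ref_labels,
                              query_labels = NULL, K = 100,
                              exclude_self = FALSE,
                              average = c("macro", "micro")) {
  average <- match.arg(average)
  query_emb <- as.matrix(query_emb)
  ref_emb <- as.matrix(ref_emb)
  if (nrow(ref_emb) == 0) abort_config("Empty reference set.")
  if (ncol(query_emb) != ncol(ref_emb)) {
    abort_config("Query and reference embeddings have different widths.")
  }
  if (!is.null(names(ref_labels)) && !is.null(rownames(ref_emb))) {
    ref_labels <- ref_labels[rownames(ref_emb)]
  }
  ref_labels <- as.character(ref_labels)
  if (length(ref_labels) != nrow(ref_emb)) {
    abort_config("Reference labels must cover every reference cell.")
  }
  K <- check_count(K, "K")
  usable <- nrow(ref_emb) - as.integer(exclude_self)
  if (K > usable) {
    abort_config(sprintf("K = %d exceeds the usable reference size (%d).", K, usable))
  }
  if (!is.null(query_labels)) {
    if (!is.null(names(query_labels)) && !is.null(rownames(query_emb))) {
      query_labels <- query_labels[rownames(query_emb)]
    }
    query_labels <- as.character(query_labels)
    if (length(query_labels) != nrow(query_emb)) {
      abort_config("Query labels must cover every query cell.")
    }
  }

  nq <- nrow(query_emb)
  # full pairwise squared distances (problem sizes here are small)
  d2 <- outer(rowSums(query_emb^2), rep(1, nrow(ref_emb))) +
    outer(rep(1, nq), rowSums(ref_emb^2)) -
    2 * query_emb %*% t(ref_emb)

  preds <- character(nq)
  aps <- rep(NA_real_, nq)
  for (i in seq_len(nq)) {
    d <- d2[i, ]
    if (exclude_self) d[i] <- Inf
    ranked <- order(d) # stable: ties by reference index
    top <- ranked[seq_len(K)]
    top_labels <- ref_labels[top]
    tab <- table(top_labels)
    preds[i] <- sort(names(tab)[tab == max(tab)])[1]
    if (!is.null(query_labels)) {
      # with exclude_self the query is reference row i, so one relevant
      # reference (itself) is not retrievable
      rel_total <- sum(ref_labels == query_labels[i]) - as.integer(exclude_self)
      rel <- as.integer(top_labels == query_labels[i])
      denom <- min(K, rel_total)
      aps[i] <- if (denom > 0) sum(rel * cumsum(rel) / seq_len(K)) / denom else NA_real_
    }
  }

  assignments <- tibble(
    cell = rownames(query_emb) %||% as.character(seq_len(nq)),
    predicted_type = preds,
    true_type = if (is.null(query_labels)) NA_character_ else query_labels,
    average_precision = aps
  )
  per_type <- NULL
  map <- NA_real_
  accuracy <- NA_real_
  if (!is.null(query_labels)) {
    accuracy <- mean(preds == query_labels)
    per_type <- assignments |>
      dplyr::group_by(type = .data$true_type) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_ap = mean(.data$average_precision, na.rm = TRUE),
        .groups = "drop"
      )
    map <- if (average == "macro") {
      mean(per_type$mean_ap, na.rm = TRUE)
    } else {
      mean(aps, na.rm = TRUE)
    }
  }
  structure(
    list(
      assignments = assignments, per_type = per_type,
      map = map, accuracy = accuracy, K = K, average = average
    ),
    class = "assignment_report"
  )
}

#' @export
print.assignment_report <- function(x, ...) {
  cat(sprintf(
    "<assignment_report> %d queries, K = %d%s\n",
    nrow(x$assignments), x$K,
    if (!is.na(x$map)) sprintf(", accuracy %.4f, MAP (%s) %.4f",
                               x$accuracy, x$average, x$map) else ""
  ))
  invisible(x)
}

#' Write an assignment report
#'
#' @param report An `assignment_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignment_report <- function(report, path) {
  readr::write_tsv(report$assignments, path)
  invisible(path)
}
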