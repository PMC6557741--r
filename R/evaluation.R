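# Clustering evaluation: kmeans++ on embeddings, adjusted Rand index and
# normalized mutual information computed exactly from the contingency
# table, and the repeated 10-run scoring protocol.

#' k-means clustering with kmeans++ seeding
#'
#' Centers are chosen by the kmeans++ rule (first uniformly at random, each
#' further center with probability proportional to the squared distance to
#' the nearest chosen center), then Lloyd iterations run to convergence or
#' 300 iterations. Deterministic given `seed`.
#'
#' @param embedding Numeric matrix, cells in rows.
#' @param k Number of clusters, `1 <= k <= nrow(embedding)`.
#' @param seed Integer seed.
#' @param n_init Number of independent kmeans++ initializations; the run
#'   with the lowest total within-cluster sum of squares is kept. Default
#'   10, the convention of the standard kmeans++ implementations.
#' @return A `clustering`: list with `labels` (integer cluster per cell,
#'   named if the embedding has rownames), `k`, `seed`, `tot_withinss`.
#' @export
kmeans_pp <- function(embedding, k, seed = 0, n_init = 10) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  k <- check_count(k, "k")
  n_init <- check_count(n_init, "n_init")
  if (k > n) abort_config(sprintf("k = %d exceeds the number of cells (%d).", k, n))
  best <- withr::with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      centers <- kmeanspp_init(embedding, k)
      if (k == 1) {
        ctr <- colMeans(embedding)
        fit <- list(
          cluster = rep(1L, n),
          tot.withinss = sum(sweep(embedding, 2, ctr, "-")^2)
        )
      } else {
        fit <- suppressWarnings(
          kmeans(embedding, centers = centers, iter.max = 300, algorithm = "Lloyd")
        )
      }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
  labels <- best$cluster
  names(labels) <- rownames(embedding)
  structure(
    list(labels = labels, k = k, seed = seed, tot_withinss = best$tot.withinss),
    class = "clustering"
  )
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
    for (j in 2:k) {
      idx <- if (sum(d2) > 0) {
        sample.int(n, 1, prob = d2)
      } else {
        sample.int(n, 1)
      }
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ], "-")^2))
    }
  }
  centers
}

#' Contingency table of two labelings
#'
#' @param x_labels,y_labels Equal-length label vectors.
#' @return List with `n_ij` (integer overlap matrix), `a_i` (row sums),
#'   `b_j` (column sums) and `N`.
#' @export
contingency <- function(x_labels, y_labels) {
  if (length(x_labels) != length(y_labels)) {
    abort_domain("Label vectors must have equal length.")
  }
  if (length(x_labels) == 0) abort_domain("Empty labelings.")
  n_ij <- unclass(table(x_labels, y_labels))
  list(n_ij = n_ij, a_i = rowSums(n_ij), b_j = colSums(n_ij), N = length(x_labels))
}

# TRUE iff x and y induce the same partition of the indices.
same_partition <- function(x, y) {
  ct <- contingency(x, y)$n_ij
  all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement of two partitions, computed exactly from the
#' contingency table with binomial coefficients:
#' `(Index - Expected) / (Max - Expected)`. When the denominator degenerates
#' (both partitions trivial), returns 1 if the partitions are identical and
#' 0 otherwise.
#'
#' @param x_labels,y_labels Equal-length label vectors (length >= 2).
#' @return Score in \[-1, 1\]; 1 for identical partitions.
#' @export
ari <- function(x_labels, y_labels) {
  if (length(x_labels) != length(y_labels)) {
    abort_domain("Label vectors must have equal length.")
  }
  if (length(x_labels) < 2) abort_domain("Need at least 2 objects.")
  ct <- contingency(x_labels, y_labels)
  index <- sum(choose(ct$n_ij, 2))
  sum_a <- sum(choose(ct$a_i, 2))
  sum_b <- sum(choose(ct$b_j, 2))
  expected <- sum_a * sum_b / choose(ct$N, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) {
    return(if (same_partition(x_labels, y_labels)) 1 else 0)
  }
  (index - expected) / (maximum - expected)
}

#' Normalized mutual information
#'
#' `I(X, Y) / sqrt(H(X) H(Y))` with entropies and mutual information in
#' natural logarithms (the normalization is base-invariant) and the
#' `0 * log 0 = 0` convention. If either partition has zero entropy, returns
#' 1 if the partitions are identical and 0 otherwise.
#'
#' @param x_labels,y_labels Equal-length label vectors.
#' @return Score in \[0, 1\].
#' @export
nmi <- function(x_labels, y_labels) {
  ct <- contingency(x_labels, y_labels)
  N <- ct$N
  ent <- function(counts) {
    p <- counts[counts > 0] / N
    -sum(p * log(p))
  }
  hx <- ent(ct$a_i)
  hy <- ent(ct$b_j)
  if (hx == 0 || hy == 0) {
    return(if (same_partition(x_labels, y_labels)) 1 else 0)
  }
  pij <- ct$n_ij / N
  pa <- ct$a_i / N
  pb <- ct$b_j / N
  pe <- outer(pa, pb)
  pos <- pij > 0
  mi <- sum(pij[pos] * log(pij[pos] / pe[pos]))
  min(max(mi / sqrt(hx * hy), 0), 1)
}

#' Repeated clustering evaluation protocol
#'
#' Runs kmeans++ `n_runs` times with seeds `base_seed, base_seed + 1, ...`,
#' scores each run against the true labels with ARI and NMI, and averages —
#' the published protocol uses 10 repetitions.
#'
#' @param embedding Matrix, cells in rows (rownames matching `labels` names
#'   if those are named).
#' @param labels True cell-type labels (vector over cells, in row order or
#'   named by cell).
#' @param k Number of clusters (the known number of cell types; never
#'   inferred).
#' @param n_runs Number of repetitions, default 10.
#' @param base_seed First seed.
#' @return A `clustering_report`: list with `runs` (tibble: run, seed, k,
#'   ari, nmi), `mean_ari`, `mean_nmi`, `k`.
#' @export
repeated_protocol <- function(embedding, labels, k, n_runs = 10, base_seed = 0) {
  if (is.null(labels)) abort_config("True labels are required for scoring.")
  n_runs <- check_count(n_runs, "n_runs")
  if (!is.null(names(labels)) && !is.null(rownames(embedding))) {
    labels <- labels[rownames(embedding)]
  }
  if (length(labels) != nrow(embedding)) {
    abort_config("Labels must cover every embedded cell.")
  }
  runs <- purrr::map_dfr(seq_len(n_runs), function(r) {
    seed <- base_seed + r - 1
    cl <- kmeans_pp(embedding, k, seed = seed)
    tibble(
      run = r, seed = seed, k = k,
      ari = ari(cl$labels, labels),
      nmi = nmi(cl$labels, labels)
    )
  })
  structure(
    list(
      runs = runs,
      mean_ari = mean(runs$ari),
      mean_nmi = mean(runs$nmi),
      k = k
    ),
    class = "clustering_report"
  )
}

#' @export
print.clustering_report <- function(x, ...) {
  cat(sprintf(
    "<clustering_report> k = %d, %d runs: mean ARI %.4f, mean NMI %.4f\n",
    x$k, nrow(x$runs), x$mean_ari, x$mean_nmi
  ))
  invisible(x)
}

#' Write a clustering report
#'
#' Per-run TSV plus a JSON summary of the means.
#'
#' @param report A `clustering_report`.
#' @param path Output TSV path; summary written as `<path>.summary.json`.
#' @return `path`, invisibly.
#' @export
write_clustering_report <- function(report, path) {
  readr::write_tsv(report$runs, path)
  jsonlite::write_json(
    list(k = report$k, n_runs = nrow(report$runs),
         mean_ari = report$mean_ari, mean_nmi = report$mean_nmi),
    paste0(path, ".summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
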