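# Significant-term selection: the three-step pipeline that picks the GO
# terms forming the first hidden layer.
#
# Step 1: candidate terms = layer-3 biological-process and molecular-function
#         terms (after upward annotation propagation).
# Step 2: redundancy pruning -- while any surviving pair of terms has a
#         Jaccard overlap (unique score) strictly greater than the threshold
#         (default 0.5), drop the member with the smaller annotated gene set.
# Step 3: diversity filtering -- drop terms whose mean per-gene expression
#         standard deviation (diversity score) is strictly below the
#         threshold (default 0.1).

#' Unique score of two gene sets
#'
#' Jaccard overlap: size of the intersection over size of the union. Two
#' terms scoring above 0.5 are considered redundant.
#'
#' @param genes_i,genes_j Character vectors of gene identifiers; at least one
#'   must be nonempty.
#' @return Score in \[0, 1\]; symmetric in its arguments.
#' @export
unique_score <- function(genes_i, genes_j) {
  genes_i <- unique(genes_i)
  genes_j <- unique(genes_j)
  n_union <- length(union(genes_i, genes_j))
  if (n_union == 0) {
    abort_domain("unique_score is undefined for two empty gene sets.")
  }
  length(intersect(genes_i, genes_j)) / n_union
}

#' Diversity score of a gene set
#'
#' Mean of the per-gene expression standard deviations over a term's
#' annotated genes. Terms whose genes barely vary across cells carry no
#' clustering signal and are filtered out.
#'
#' @param genes_i Nonempty character vector of genes.
#' @param gene_std Named numeric vector of per-gene standard deviations
#'   covering every gene in `genes_i` (see [gene_sds()]).
#' @return Nonnegative score.
#' @export
diversity_score <- function(genes_i, gene_std) {
  genes_i <- unique(genes_i)
  if (length(genes_i) == 0) {
    abort_domain("diversity_score is undefined for an empty gene set.")
  }
  missing <- setdiff(genes_i, names(gene_std))
  if (length(missing) > 0) {
    abort_domain(sprintf(
      "No standard deviation available for genes: %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  mean(gene_std[genes_i])
}

#' Greedy redundancy removal over a candidate term list
#'
#' Repeatedly finds the surviving pair with the highest unique score; while
#' that score exceeds `threshold` (strictly), the member with fewer
#' annotated genes is removed (ties keep the lexicographically smaller term
#' id). Scores are only ever computed between surviving terms, so an earlier
#' removal cannot trigger a later one. Pairs at exactly the threshold are
#' kept.
#'
#' @param candidates Character vector of term ids (duplicates are ignored).
#' @param ann `go_annotations` covering the candidates.
#' @param threshold Redundancy threshold, default 0.5.
#' @return List with `kept` (character, input order preserved), `removal_log`
#'   (tibble: term, reason, partner, score) and `unique_scores` (tibble of
#'   all candidate pairs with nonzero overlap).
#' @export
remove_redundant <- function(candidates, ann, threshold = 0.5) {
  candidates <- unique(as.character(candidates))
  unannotated <- candidates[!candidates %in% names(ann) | lengths(ann[candidates]) == 0]
  if (length(unannotated) > 0) {
    abort_domain(sprintf(
      "Candidates without annotated genes: %s",
      paste(head(unannotated, 5), collapse = ", ")
    ))
  }
  sets <- ann[candidates]
  sizes <- lengths(sets)

  pairs <- if (length(candidates) >= 2) {
    utils::combn(sort(candidates), 2, simplify = FALSE)
  } else {
    list()
  }
  scores <- purrr::map_dfr(pairs, function(p) {
    tibble(
      term_i = p[[1]], term_j = p[[2]],
      score = unique_score(sets[[p[[1]]]], sets[[p[[2]]]])
    )
  })
  if (nrow(scores) == 0) {
    scores <- tibble(term_i = character(0), term_j = character(0), score = numeric(0))
  }

  alive <- scores[scores$score > 0, , drop = FALSE]
  removed <- tibble(
    term = character(0), reason = character(0),
    partner = character(0), score = numeric(0)
  )
  repeat {
    over <- alive[alive$score > threshold, , drop = FALSE]
    if (nrow(over) == 0) break
    # deterministic pick: highest score, then lexicographic pair
    over <- over[order(-over$score, over$term_i, over$term_j), , drop = FALSE]
    ti <- over$term_i[[1]]
    tj <- over$term_j[[1]]
    if (sizes[[ti]] < sizes[[tj]]) {
      drop_term <- ti
    } else if (sizes[[tj]] < sizes[[ti]]) {
      drop_term <- tj
    } else {
      drop_term <- max(ti, tj) # tie: keep the lexicographically smaller id
    }
    keep_term <- setdiff(c(ti, tj), drop_term)
    removed <- bind_rows(removed, tibble(
      term = drop_term, reason = "redundant",
      partner = keep_term, score = over$score[[1]]
    ))
    alive <- alive[alive$term_i != drop_term & alive$term_j != drop_term, , drop = FALSE]
  }

  list(
    kept = candidates[!candidates %in% removed$term],
    removal_log = removed,
    unique_scores = scores
  )
}

#' Filter terms with low expression diversity
#'
#' Removes terms whose diversity score falls strictly below `threshold`;
#' terms exactly at the threshold are kept.
#'
#' @param terms Character vector of term ids.
#' @param ann `go_annotations` covering `terms`.
#' @param gene_std Named numeric vector of per-gene standard deviations.
#' @param threshold Diversity threshold, default 0.1.
#' @return List with `kept`, `removal_log` (tibble: term, reason, score) and
#'   `diversity` (tibble: term, score for every input term).
#' @export
filter_low_diversity <- function(terms, ann, gene_std, threshold = 0.1) {
  terms <- as.character(terms)
  h <- vapply(terms, function(t) diversity_score(ann[[t]], gene_std), numeric(1))
  low <- terms[h < threshold]
  list(
    kept = terms[!terms %in% low],
    removal_log = tibble(
      term = low, reason = rep("low_diversity", length(low)),
      partner = rep(NA_character_, length(low)), score = unname(h[low])
    ),
    diversity = tibble(term = terms, score = unname(h))
  )
}

#' Select the significant GO terms for the network's hidden layer
#'
#' Runs the full three-step selection: propagate annotations up the DAG,
#' take the candidate terms at `layer` in the biological-process and
#' molecular-function namespaces, prune redundant terms (pairwise unique
#' score strictly above `u_threshold`), then drop low-diversity terms
#' (diversity score strictly below `h_threshold`). Gene sets are restricted
#' to genes present in `gene_std` (i.e. in the expression matrix) before
#' diversity scoring, so absent genes cannot dilute a term's score.
#'
#' @param onto A [go_ontology()].
#' @param ann_raw Raw (unpropagated) `go_annotations`.
#' @param gene_std Named numeric vector of per-gene standard deviations on
#'   the log scale (see [gene_sds()]); its names define the expression genes.
#' @param layer Candidate layer, default 3.
#' @param u_threshold Redundancy threshold, default 0.5.
#' @param h_threshold Diversity threshold, default 0.1.
#' @param namespaces Namespaces admitted as candidates.
#' @param skip_selection If `TRUE`, stop after the candidate step and keep
#'   every annotated candidate (the "no selection" model variant).
#' @return A `term_selection` object: list with `kept` (ordered term ids),
#'   `candidates`, `table` (one row per candidate: term, namespace, layer,
#'   n_genes, n_expressed_genes, diversity, status, reason, partner),
#'   `unique_scores`, `genes` (term -> expressed gene sets for kept terms)
#'   and `params`.
#' @export
select_significant_terms <- function(onto, ann_raw, gene_std,
                                     layer = 3, u_threshold = 0.5,
                                     h_threshold = 0.1,
                                     namespaces = c("biological_process", "molecular_function"),
                                     skip_selection = FALSE) {
  ann <- propagate_annotations(onto, ann_raw)
  cands <- candidate_terms(onto, layer = layer, namespaces = namespaces)
  annotated <- cands[lengths(ann[cands]) > 0]
  if (length(annotated) < length(cands)) {
    warn(sprintf(
      "%d candidate terms have no annotated genes and were skipped.",
      length(cands) - length(annotated)
    ))
  }
  if (length(annotated) == 0) {
    abort_config(
      "No annotated candidate terms at this layer; consider a different layer or namespaces."
    )
  }

  # expression-present gene sets, used for diversity scoring and the mask
  expr_genes <- names(gene_std)
  expr_sets <- lapply(ann[annotated], function(g) intersect(g, expr_genes))

  if (skip_selection) {
    kept <- annotated
    red <- list(
      removal_log = tibble(term = character(0), reason = character(0),
                           partner = character(0), score = numeric(0)),
      unique_scores = tibble(term_i = character(0), term_j = character(0),
                             score = numeric(0))
    )
    div <- list(
      removal_log = red$removal_log[0, ],
      diversity = tibble(term = character(0), score = numeric(0))
    )
  } else {
    red <- remove_redundant(annotated, ann, threshold = u_threshold)
    scorable <- red$kept[lengths(expr_sets[red$kept]) > 0]
    dropped_empty <- setdiff(red$kept, scorable)
    if (length(dropped_empty) > 0) {
      warn(sprintf(
        "%d terms have no annotated genes in the expression matrix; removed.",
        length(dropped_empty)
      ))
    }
    div <- filter_low_diversity(scorable, new_annotations(expr_sets[scorable]),
                                gene_std, threshold = h_threshold)
    if (length(dropped_empty) > 0) {
      div$removal_log <- bind_rows(div$removal_log, tibble(
        term = dropped_empty, reason = "no_expressed_genes",
        partner = NA_character_, score = NA_real_
      ))
    }
    kept <- div$kept
  }

  if (length(kept) == 0) {
    abort_config(paste(
      "Term selection removed every candidate; relax u_threshold/h_threshold",
      "or choose another layer."
    ))
  }

  removal_log <- bind_rows(red$removal_log, div$removal_log)
  all_h <- if (nrow(div$diversity) > 0) {
    stats::setNames(div$diversity$score, div$diversity$term)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  status <- ifelse(annotated %in% kept, "kept", "removed")
  reason <- removal_log$reason[match(annotated, removal_log$term)]
  partner <- removal_log$partner[match(annotated, removal_log$term)]
  tab <- tibble(
    term = annotated,
    namespace = unname(onto$namespace[annotated]),
    layer = layer,
    n_genes = unname(lengths(ann[annotated])),
    n_expressed_genes = unname(lengths(expr_sets[annotated])),
    diversity = unname(all_h[annotated]),
    status = status,
    reason = reason,
    partner = partner
  )

  structure(
    list(
      kept = kept,
      candidates = annotated,
      table = tab,
      unique_scores = red$unique_scores,
      genes = expr_sets[kept],
      params = list(
        layer = layer, u_threshold = u_threshold, h_threshold = h_threshold,
        namespaces = namespaces, skip_selection = skip_selection
      )
    ),
    class = "term_selection"
  )
}

#' @export
print.term_selection <- function(x, ...) {
  cat(sprintf(
    "<term_selection> %d candidates -> %d kept (%d redundant, %d low-diversity)\n",
    length(x$candidates), length(x$kept),
    sum(x$table$reason == "redundant", na.rm = TRUE),
    sum(x$table$reason == "low_diversity", na.rm = TRUE)
  ))
  invisible(x)
}

#' Write a term selection to disk
#'
#' Writes the per-term table as TSV plus a JSON sidecar with the selection
#' parameters.
#'
#' @param sel A `term_selection`.
#' @param path Output TSV path; the sidecar is written next to it as
#'   `<path>.params.json`.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  readr::write_tsv(sel$table, path)
  jsonlite::write_json(sel$params, paste0(path, ".params.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
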