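# Synthetic data: toy ontologies with propagatable annotations and
# planted-cluster expression matrices, so the whole workflow is testable
# without downloads.

#' Specification of a synthetic dataset
#'
#' @param n_types Number of ground-truth cell types.
#' @param cells_per_type Cells generated per type.
#' @param n_genes Total genes.
#' @param n_terms Signature GO terms placed at layer 3 of the toy DAG.
#' @param genes_per_term Genes annotated (disjointly) by each term.
#' @param effect_size Mean shift, in log-expression units, applied to a
#'   type's signature gene block.
#' @param dropout_rate Probability that an expressed value is zeroed
#'   (technical dropout emulation).
#' @param noise_sd Standard deviation of log-space Gaussian noise.
#' @param dag_depth Number of layers in the toy ontology (root = layer 0);
#'   must be at least 4 so the signature terms can sit at layer 3.
#' @param seed Integer seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_types = 5, cells_per_type = 40, n_genes = 500,
                           n_terms = 20, genes_per_term = 15,
                           effect_size = 3, dropout_rate = 0.3,
                           noise_sd = 0.5, dag_depth = 4, seed = 0) {
  spec <- list(
    n_types = check_count(n_types, "n_types"),
    cells_per_type = check_count(cells_per_type, "cells_per_type"),
    n_genes = check_count(n_genes, "n_genes"),
    n_terms = check_count(n_terms, "n_terms"),
    genes_per_term = check_count(genes_per_term, "genes_per_term"),
    effect_size = check_scalar_number(effect_size, "effect_size", min = 0),
    dropout_rate = check_scalar_number(dropout_rate, "dropout_rate", min = 0),
    noise_sd = check_scalar_number(noise_sd, "noise_sd", min = 0),
    dag_depth = check_count(dag_depth, "dag_depth", min = 4L),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (spec$dropout_rate > 1) abort_config("`dropout_rate` must be in [0, 1].")
  structure(spec, class = "synthetic_spec")
}

syn_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a toy ontology with annotations
#'
#' Builds two namespace DAGs (biological process and molecular function),
#' each a chain from the root down to layer 2, whose layer-3 children are
#' the signature terms — roughly half in each namespace. Term `i` annotates
#' the `i`-th disjoint block of `genes_per_term` genes (raw annotation at
#' the term itself; ancestors receive the genes through propagation). If
#' `dag_depth > 4`, a chain of unannotated descendants extends below the
#' first term.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `ontology` (a [go_ontology()]) and `annotations` (raw
#'   `go_annotations` over the signature terms).
#' @export
generate_ontology <- function(spec) {
  if (spec$n_terms * spec$genes_per_term > spec$n_genes) {
    abort_config("n_terms * genes_per_term exceeds n_genes.")
  }
  n_bp <- ceiling(spec$n_terms / 2)
  sig_terms <- sprintf("GO:%07d", seq_len(spec$n_terms))
  ns_of <- rep(c("biological_process", "molecular_function"), c(n_bp, spec$n_terms - n_bp))

  terms <- character(0); namespace <- character(0)
  edge_child <- character(0); edge_parent <- character(0)
  scaffold <- list(biological_process = "GO:1000000", molecular_function = "GO:2000000")
  for (ns in names(scaffold)) {
    root <- scaffold[[ns]]
    chain <- c(root, sprintf("%s%d", substr(root, 1, 9), 1:2)) # layers 0,1,2
    terms <- c(terms, chain)
    namespace[chain] <- ns
    edge_child <- c(edge_child, chain[2:3])
    edge_parent <- c(edge_parent, chain[1:2])
    leaves <- sig_terms[ns_of == ns]
    terms <- c(terms, leaves)
    namespace[leaves] <- ns
    edge_child <- c(edge_child, leaves)
    edge_parent <- c(edge_parent, rep(chain[3], length(leaves)))
  }
  if (spec$dag_depth > 4 && spec$n_terms >= 1) {
    deeper <- sprintf("GO:%07d", 9000000 + seq_len(spec$dag_depth - 4))
    terms <- c(terms, deeper)
    namespace[deeper] <- namespace[[sig_terms[1]]]
    edge_child <- c(edge_child, deeper)
    edge_parent <- c(edge_parent, c(sig_terms[1], deeper[-length(deeper)]))
  }

  onto <- go_ontology(
    terms = terms,
    edges = data.frame(child = edge_child, parent = edge_parent),
    namespace = namespace
  )
  genes <- syn_gene_ids(spec$n_genes)
  blocks <- split(
    genes[seq_len(spec$n_terms * spec$genes_per_term)],
    rep(seq_len(spec$n_terms), each = spec$genes_per_term)
  )
  ann <- new_annotations(stats::setNames(blocks, sig_terms))
  list(ontology = onto, annotations = ann)
}

#' Generate a planted-cluster expression matrix
#'
#' Log-expression is Gaussian noise around a baseline of 1; each cell type
#' elevates the gene block of its signature term (type `t` maps to the
#' `t`-th term, in sorted term order) by `effect_size`. Values are mapped
#' back to the raw scale with `exp(x) - 1`, clipped at 0, and zeroed with
#' probability `dropout_rate` to emulate technical dropout. Genes listed in
#' `constant_genes` are fixed at a constant raw value (no noise, no
#' dropout), giving zero expression variance.
#'
#' @param spec A [synthetic_spec()].
#' @param ann `go_annotations` from [generate_ontology()].
#' @param constant_genes Optional character vector of genes held constant.
#' @return A raw, labelled `expr_matrix` (`n_types * cells_per_type` cells x
#'   `n_genes` genes).
#' @export
generate_expression <- function(spec, ann, constant_genes = character()) {
  if (spec$n_types > length(ann)) {
    abort_config("Each cell type needs its own signature term: n_types > number of terms.")
  }
  genes <- syn_gene_ids(spec$n_genes)
  n_cells <- spec$n_types * spec$cells_per_type
  cells <- sprintf("cell%04d", seq_len(n_cells))
  types <- sprintf("type%02d", seq_len(spec$n_types))
  labels <- stats::setNames(rep(types, each = spec$cells_per_type), cells)
  sig_terms <- sort(names(ann))[seq_len(spec$n_types)]

  values <- withr::with_seed(spec$seed, {
    m <- matrix(rnorm(n_cells * spec$n_genes, mean = 1, sd = spec$noise_sd),
                n_cells, spec$n_genes, dimnames = list(cells, genes))
    for (t in seq_len(spec$n_types)) {
      block <- intersect(ann[[sig_terms[t]]], genes)
      rows <- labels == types[t]
      m[rows, block] <- m[rows, block] + spec$effect_size
    }
    raw <- pmax(expm1(m), 0)
    if (spec$dropout_rate > 0) {
      drop <- matrix(runif(length(raw)) < spec$dropout_rate, nrow(raw), ncol(raw))
      raw[drop] <- 0
    }
    if (length(constant_genes) > 0) {
      raw[, intersect(constant_genes, genes)] <- expm1(1)
    }
    raw
  })
  expr_matrix(values, labels = labels, normalization = "raw")
}

#' The standard synthetic fixture
#'
#' Canonical bundle used throughout the package's tests and examples:
#' 5 types x 40 cells, 500 genes, 20 layer-3 terms of 15 genes each, effect
#' size 3.0, dropout 0.3, noise 0.5. On top of the base design it plants
#' known selection targets: two redundant term pairs (the 17th/19th and
#' 18th/20th terms share 12 of their genes, overlap above 0.5, with the
#' second member of each pair annotating fewer genes) and two constant-gene
#' terms (the 15th and 16th terms' genes carry zero variance). The
#' three-step selection on this fixture therefore removes exactly the 19th
#' and 20th terms as redundant and the 15th and 16th as low-diversity,
#' keeping 16 of the 20 candidates.
#'
#' @param seed Seed for the expression draw, default 0.
#' @param effect_size Mean shift for signature blocks, default 3 (0 gives
#'   the matched null dataset with no planted structure).
#' @return List with `spec`, `ontology`, `annotations` (raw, with the
#'   planted overlaps), `expression` (raw labelled `expr_matrix`),
#'   `constant_terms` and `redundant_terms` (the planted removals).
#' @export
standard_fixture <- function(seed = 0, effect_size = 3) {
  spec <- synthetic_spec(
    n_types = 5, cells_per_type = 40, n_genes = 500, n_terms = 20,
    genes_per_term = 15, effect_size = effect_size, dropout_rate = 0.3,
    noise_sd = 0.5, dag_depth = 4, seed = seed
  )
  base <- generate_ontology(spec)
  ann <- base$annotations
  terms <- sort(names(ann))
  genes <- syn_gene_ids(spec$n_genes)
  spare <- genes[(spec$n_terms * spec$genes_per_term + 1):spec$n_genes]

  # planted redundancy: terms 19/20 re-annotated to overlap terms 17/18
  # (12 shared genes + 2 fresh ones -> unique score 12/17 > 0.5, and the
  # smaller set loses)
  redundant <- c(terms[19], terms[20])
  ann[[terms[19]]] <- c(ann[[terms[17]]][1:12], spare[1:2])
  ann[[terms[20]]] <- c(ann[[terms[18]]][1:12], spare[3:4])
  ann <- new_annotations(unclass(ann))

  # planted low diversity: the gene blocks of terms 15/16 are constant
  constant <- c(terms[15], terms[16])
  constant_genes <- unique(c(ann[[terms[15]]], ann[[terms[16]]]))

  expr <- generate_expression(spec, ann, constant_genes = constant_genes)
  list(
    spec = spec,
    ontology = base$ontology,
    annotations = ann,
    expression = expr,
    constant_terms = constant,
    redundant_terms = redundant
  )
}

#' Write a synthetic bundle to disk
#'
#' Emits the same formats the readers consume: `ontology.obo`,
#' `annotations.gaf`, `expression.tsv` (cells as rows) and `labels.tsv`.
#'
#' @param bundle Output of [standard_fixture()] or a compatible list.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    obo = file.path(dir, "ontology.obo"),
    gaf = file.path(dir, "annotations.gaf"),
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv")
  )
  write_obo(bundle$ontology, paths[["obo"]])
  write_gaf(bundle$annotations, bundle$ontology, paths[["gaf"]])
  write_expression(bundle$expression, paths[["expression"]],
                   label_path = paths[["labels"]])
  invisible(paths)
}
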