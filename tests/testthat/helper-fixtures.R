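# Shared builders for toy ontologies, annotation maps and expression data.
# Everything is constructed in code; no files ship with the tests.

# A small hand-drawn ontology:
#   R -> A -> B -> L1              (L1 at layer 3)
#   R -> C -> L2                   (L2 at layer 2)
#   D is_a B and D is_a C          (diamond: paths of length 3 and 2 -> layer 2)
toy_ontology <- function(namespace = "biological_process") {
  terms <- c("GO:R", "GO:A", "GO:B", "GO:C", "GO:D", "GO:L1", "GO:L2")
  edges <- data.frame(
    child = c("GO:A", "GO:B", "GO:L1", "GO:C", "GO:L2", "GO:D", "GO:D"),
    parent = c("GO:R", "GO:A", "GO:B", "GO:R", "GO:C", "GO:B", "GO:C")
  )
  go_ontology(terms, edges, stats::setNames(rep(namespace, length(terms)), terms))
}

# Random single-root DAG over one namespace: node i >= 2 gets 1-3 parents
# among nodes 1..(i-1). Used to cross-check layering and propagation.
random_dag <- function(n, seed) {
  withr::with_seed(seed, {
    terms <- sprintf("GO:%04d", seq_len(n))
    child <- character(0)
    parent <- character(0)
    for (i in seq(2, n)) {
      k <- sample(1:min(3, i - 1), 1)
      p <- sample(seq_len(i - 1), k)
      child <- c(child, rep(terms[i], k))
      parent <- c(parent, terms[p])
    }
    go_ontology(
      terms, data.frame(child = child, parent = parent),
      stats::setNames(rep("biological_process", n), terms)
    )
  })
}

# igraph breadth-first-search layer oracle: shortest directed path from the
# root following parent -> child edges.
igraph_layers <- function(onto) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = onto$edges$parent, to = onto$edges$child),
    vertices = onto$terms
  )
  root <- setdiff(onto$terms, unique(onto$edges$child))
  d <- igraph::distances(g, v = root, mode = "out")
  stats::setNames(as.integer(d[1, onto$terms]), onto$terms)
}

# tiny labelled expression object in a given normalization state
tiny_expr <- function(values, labels = NULL, normalization = "log_zscore") {
  if (is.null(rownames(values))) rownames(values) <- sprintf("c%02d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("g%02d", seq_len(ncol(values)))
  expr_matrix(values, labels = labels, normalization = normalization)
}

# mask over explicit gene lists
manual_mask <- function(genes, term_genes, n_dense = 0) {
  sel <- structure(
    list(
      kept = names(term_genes),
      candidates = names(term_genes),
      table = tibble::tibble(
        term = names(term_genes),
        namespace = "biological_process",
        status = "kept"
      ),
      genes = term_genes,
      params = list()
    ),
    class = "term_selection"
  )
  x <- tiny_expr(matrix(0, 2, length(genes),
                        dimnames = list(c("c1", "c2"), genes)))
  build_mask(x, sel, n_dense = n_dense)
}

# normalized standard fixture plus selection and mask, shared by the
# heavier tests
fixture_pipeline <- function(seed = 0, effect_size = 3, n_dense = 100) {
  fx <- standard_fixture(seed = seed, effect_size = effect_size)
  gs <- gene_sds(fx$expression)
  sel <- select_significant_terms(fx$ontology, fx$annotations, gs)
  norm <- normalize_expression(fx$expression, "log_zscore")
  mask <- build_mask(norm, sel, n_dense = n_dense)
  list(fx = fx, sel = sel, norm = norm, mask = mask,
       sig_terms = sort(names(fx$annotations))[seq_len(5)])
}

# independent brute-force metric oracles -----------------------------------

# ARI via exhaustive pair counting (no contingency table)
ari_pair_oracle <- function(x, y) {
  n <- length(x)
  a <- b <- c2 <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sx <- x[i] == x[j]
      sy <- y[i] == y[j]
      if (sx && sy) a <- a + 1
      else if (sx && !sy) b <- b + 1
      else if (!sx && sy) c2 <- c2 + 1
      else d <- d + 1
    }
  }
  denom <- (a + b) * (b + d) + (a + c2) * (c2 + d)
  if (denom == 0) {
    # degenerate: identical co-membership structure iff no discordant pair
    return(if (b == 0 && c2 == 0) 1 else 0)
  }
  2 * (a * d - b * c2) / denom
}

# NMI via direct probability tables
nmi_table_oracle <- function(x, y) {
  n <- length(x)
  px <- table(x) / n
  py <- table(y) / n
  pxy <- table(x, y) / n
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 || hy == 0) {
    same <- all(rowSums(table(x, y) > 0) == 1) && all(colSums(table(x, y) > 0) == 1)
    return(if (same) 1 else 0)
  }
  mi <- 0
  for (i in rownames(pxy)) {
    for (j in colnames(pxy)) {
      p <- pxy[i, j]
      if (p > 0) mi <- mi + p * log(p / (px[[i]] * py[[j]]))
    }
  }
  mi / sqrt(hx * hy)
}

# exhaustive nearest-neighbor ranking oracle
knn_rank_oracle <- function(query, ref, exclude_self = FALSE) {
  lapply(seq_len(nrow(query)), function(i) {
    d <- sapply(seq_len(nrow(ref)), function(j) sqrt(sum((query[i, ] - ref[j, ])^2)))
    if (exclude_self) d[i] <- Inf
    order(d)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Short configurations keep these runs fast; the full paper presets are
# exercised by the acceptance suite.
short_cfg <- function(optimizer, lr, epochs = 15, seed = 1) {
  train_config(batch_size = 16, epochs = epochs, learning_rate = lr,
               seed = seed, optimizer = optimizer)
}

small_problem <- function(seed = 0) {
  spec <- synthetic_spec(n_types = 2, cells_per_type = 20, n_genes = 60,
                         n_terms = 4, genes_per_term = 10, effect_size = 3,
                         dropout_rate = 0.2, noise_sd = 0.5, seed = seed)
  base <- generate_ontology(spec)
  expr <- generate_expression(spec, base$annotations)
  gs <- gene_sds(expr)
  sel <- select_significant_terms(base$ontology, base$annotations, gs)
  norm <- normalize_expression(expr, "log_zscore")
  mask <- build_mask(norm, sel, n_dense = 5)
  list(norm = norm, mask = mask)
}

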