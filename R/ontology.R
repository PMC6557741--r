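# Ontology container and OBO parsing.
#
# The ontology is held as a plain DAG over `is_a` edges: GO's other relation
# types (part_of, regulates, ...) do not enter the hierarchy used to place
# terms on layers or to propagate annotations upward.

GO_NAMESPACES <- c("biological_process", "molecular_function", "cellular_component")

#' Construct a Gene Ontology DAG
#'
#' Builds the validated ontology object used throughout the package. Most
#' users will obtain one from [parse_obo()] or [generate_ontology()] rather
#' than calling this directly.
#'
#' @param terms Character vector of non-obsolete term identifiers.
#' @param edges Data frame with columns `child`, `parent` giving `is_a`
#'   relations (child is_a parent).
#' @param namespace Named character vector mapping every term to one of
#'   `biological_process`, `molecular_function`, `cellular_component`.
#' @param obsolete Character vector of obsolete term identifiers (kept only
#'   for bookkeeping; they take no part in the DAG).
#'
#' @return An object of class `go_ontology` with elements `terms`, `edges`
#'   (tibble), `namespace`, `obsolete`, and precomputed `layers` (shortest
#'   `is_a` distance from each term to its namespace root, root = 0).
#' @export
go_ontology <- function(terms, edges, namespace, obsolete = character()) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) {
    abort_integrity("Duplicated term identifiers in ontology.")
  }
  edges <- tibble(
    child = as.character(edges$child),
    parent = as.character(edges$parent)
  )
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms)
  if (length(unknown) > 0) {
    abort_integrity(sprintf(
      "is_a edges reference unknown terms: %s",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  namespace <- namespace[terms]
  if (anyNA(namespace) || !all(namespace %in% GO_NAMESPACES)) {
    abort_integrity("Every term needs a namespace in the three GO categories.")
  }
  names(namespace) <- terms
  onto <- structure(
    list(
      terms = terms,
      edges = edges,
      namespace = namespace,
      obsolete = as.character(obsolete)
    ),
    class = "go_ontology"
  )
  check_acyclic(onto)
  onto$layers <- compute_layers(onto)
  onto
}

#' @export
print.go_ontology <- function(x, ...) {
  ns <- table(x$namespace)
  cat(sprintf(
    "<go_ontology> %d terms (%s), %d is_a edges, %d obsolete\n",
    length(x$terms),
    paste(sprintf("%s: %d", names(ns), as.integer(ns)), collapse = ", "),
    nrow(x$edges), length(x$obsolete)
  ))
  invisible(x)
}

# Kahn topological check over child -> parent edges.
check_acyclic <- function(onto) {
  ord <- topological_order(onto)
  if (length(ord) != length(onto$terms)) {
    abort_integrity("is_a graph contains a cycle; not a valid ontology DAG.")
  }
  invisible(TRUE)
}

# Order in which every term appears after all of its children (descendants
# first). Returns fewer terms than the ontology has iff the graph is cyclic.
topological_order <- function(onto) {
  terms <- onto$terms
  idx <- seq_along(terms)
  names(idx) <- terms
  # children[[p]] = terms with an edge child -> p
  children <- split(onto$edges$child, factor(onto$edges$parent, levels = terms))
  pending <- vapply(children, length, integer(1))
  parents_of <- split(onto$edges$parent, factor(onto$edges$child, levels = terms))
  queue <- terms[pending == 0L] # leaves
  ord <- character(0)
  while (length(queue) > 0) {
    t <- queue[[1]]
    queue <- queue[-1]
    ord <- c(ord, t)
    for (p in parents_of[[t]]) {
      pending[[p]] <- pending[[p]] - 1L
      if (pending[[p]] == 0L) queue <- c(queue, p)
    }
  }
  ord
}

namespace_roots <- function(onto) {
  has_parent <- unique(onto$edges$child)
  vapply(split(onto$terms, onto$namespace[onto$terms]), function(ts) {
    roots <- setdiff(ts, has_parent)
    if (length(roots) != 1L) {
      abort_integrity(sprintf(
        "Namespace subgraph must have exactly one root; found %d.", length(roots)
      ))
    }
    roots
  }, character(1))
}

# Breadth-first layering from each namespace root along parent -> child
# edges. Layer = minimum number of is_a links up to the root.
compute_layers <- function(onto) {
  layers <- rep(NA_integer_, length(onto$terms))
  names(layers) <- onto$terms
  children <- split(onto$edges$child, factor(onto$edges$parent, levels = onto$terms))
  roots <- namespace_roots(onto)
  for (root in roots) {
    frontier <- root
    depth <- 0L
    while (length(frontier) > 0) {
      frontier <- frontier[is.na(layers[frontier])]
      layers[frontier] <- depth
      depth <- depth + 1L
      frontier <- unique(unlist(children[frontier], use.names = FALSE))
    }
  }
  layers
}

#' Layer of a term in the ontology DAG
#'
#' The layer of a term is the minimum number of `is_a` edges separating it
#' from its namespace root; the root itself sits at layer 0.
#'
#' @param onto A [go_ontology()].
#' @param term A term identifier present in `onto`.
#' @return Integer layer.
#' @export
term_layer <- function(onto, term) {
  if (!term %in% onto$terms) {
    abort_domain(sprintf("Term %s is not in the ontology.", term))
  }
  layer <- onto$layers[[term]]
  if (is.na(layer)) {
    abort_integrity(sprintf("Term %s is unreachable from its namespace root.", term))
  }
  layer
}

#' Layers of all terms
#'
#' @param onto A [go_ontology()].
#' @return Tibble with columns `term`, `namespace`, `layer`.
#' @export
term_layers <- function(onto) {
  tibble(
    term = onto$terms,
    namespace = unname(onto$namespace[onto$terms]),
    layer = unname(onto$layers[onto$terms])
  )
}

#' Candidate terms at a given layer
#'
#' Selects the non-obsolete terms sitting at exactly the requested layer in
#' the requested namespaces. By default this reproduces the model's input
#' pool: biological-process and molecular-function terms of the third layer.
#' Ordering is deterministic: namespaces in the order given (biological
#' process before molecular function by default), term identifiers
#' lexicographic within a namespace.
#'
#' @param onto A [go_ontology()].
#' @param layer Layer to select (root = 0). Default 3.
#' @param namespaces Namespaces to include.
#' @return Character vector of term identifiers.
#' @export
candidate_terms <- function(onto, layer = 3,
                            namespaces = c("biological_process", "molecular_function")) {
  layer <- check_count(layer, "layer", min = 0L)
  namespaces <- match.arg(namespaces, GO_NAMESPACES, several.ok = TRUE)
  keep <- !is.na(onto$layers) & onto$layers == layer &
    onto$namespace %in% namespaces
  ts <- onto$terms[keep]
  ns <- onto$namespace[ts]
  ts[order(match(ns, namespaces), ts)]
}

#' Read an ontology from an OBO 1.2/1.4 flat file
#'
#' Parses `[Term]` stanzas; only `is_a` lines become edges (other
#' relationships such as `part_of` are ignored), obsolete terms are dropped
#' from the DAG, and namespaces are recorded. The resulting graph is checked
#' to be acyclic with one root per namespace.
#'
#' @param path Path to the OBO file.
#' @return A [go_ontology()].
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) {
    abort_config(sprintf("OBO file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  terms <- character(0)
  namespace <- character(0)
  obsolete <- character(0)
  edge_child <- character(0)
  edge_parent <- character(0)

  in_term <- FALSE
  cur_id <- NA_character_
  cur_ns <- NA_character_
  cur_obsolete <- FALSE
  cur_parents <- character(0)
  stanza_line <- 0L

  flush_term <- function() {
    if (!in_term) return(invisible(NULL))
    if (is.na(cur_id)) {
      abort_parse(sprintf("[Term] stanza starting at line %d has no id.", stanza_line))
    }
    if (cur_obsolete) {
      obsolete <<- c(obsolete, cur_id)
    } else {
      terms <<- c(terms, cur_id)
      namespace[cur_id] <<- cur_ns
      if (length(cur_parents) > 0) {
        edge_child <<- c(edge_child, rep(cur_id, length(cur_parents)))
        edge_parent <<- c(edge_parent, cur_parents)
      }
    }
    invisible(NULL)
  }

  for (i in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[[i]])
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush_term()
      in_term <- identical(line, "[Term]")
      cur_id <- NA_character_
      cur_ns <- NA_character_
      cur_obsolete <- FALSE
      cur_parents <- character(0)
      stanza_line <- i
      next
    }
    if (!in_term) next
    # strip trailing comments introduced by " ! "
    line <- sub("\\s*!.*$", "", line)
    if (line == "") next
    if (!grepl("^[A-Za-z_]+:", line)) {
      abort_parse(sprintf("Malformed stanza line %d: %s", i, lines[[i]]))
    }
    key <- sub(":.*$", "", line)
    value <- trimws(sub("^[A-Za-z_]+:\\s*", "", line))
    if (key == "id") {
      cur_id <- value
    } else if (key == "namespace") {
      cur_ns <- value
    } else if (key == "is_obsolete") {
      cur_obsolete <- identical(tolower(value), "true")
    } else if (key == "is_a") {
      cur_parents <- c(cur_parents, sub("\\s.*$", "", value))
    }
    # relationship:, name:, def:, ... intentionally ignored
  }
  flush_term()

  # edges whose parent is obsolete are dropped with the obsolete term
  keep_edge <- edge_parent %in% terms & edge_child %in% terms
  go_ontology(
    terms = terms,
    edges = data.frame(child = edge_child[keep_edge], parent = edge_parent[keep_edge]),
    namespace = namespace,
    obsolete = obsolete
  )
}

#' Write an ontology as an OBO flat file
#'
#' Minimal OBO 1.2 writer covering what [parse_obo()] reads: term ids,
#' namespaces, `is_a` edges and obsolete flags.
#'
#' @param onto A [go_ontology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(onto, path) {
  parents <- split(onto$edges$parent, factor(onto$edges$child, levels = onto$terms))
  out <- c("format-version: 1.2", "")
  for (t in onto$terms) {
    out <- c(out,
      "[Term]",
      paste0("id: ", t),
      paste0("name: ", t),
      paste0("namespace: ", onto$namespace[[t]]),
      paste0("is_a: ", parents[[t]]),
      ""
    )
  }
  for (t in onto$obsolete) {
    out <- c(out, "[Term]", paste0("id: ", t), paste0("name: ", t),
             "is_obsolete: true", "")
  }
  writeLines(out, path)
  invisible(path)
}
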