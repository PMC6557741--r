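# Gene-term annotations: GAF parsing and upward propagation over the DAG.

new_annotations <- function(x) {
  x <- lapply(x, function(g) sort(unique(as.character(g))))
  structure(x, class = "go_annotations")
}

#' @export
print.go_annotations <- function(x, ...) {
  cat(sprintf(
    "<go_annotations> %d terms, %d distinct genes\n",
    length(x), length(unique(unlist(x, use.names = FALSE)))
  ))
  invisible(x)
}

#' Convert annotations to a term-gene table
#'
#' @param ann A `go_annotations` object.
#' @return Tibble with columns `term`, `gene`.
#' @export
annotation_table <- function(ann) {
  tibble(
    term = rep(names(ann), lengths(ann)),
    gene = unlist(ann, use.names = FALSE)
  )
}

#' Read gene-term annotations from a GAF 2.x file
#'
#' Reads the 17-column tab-separated Gene Association File format. Comment
#' lines start with `!`. Rows whose qualifier contains `NOT` are dropped
#' (negative annotations), as are rows citing terms absent from the supplied
#' ontology (counted and reported as a warning). Gene identity is taken from
#' the DB Object Symbol column (column 3) by default.
#'
#' @param path Path to the GAF file.
#' @param onto A [go_ontology()] used for referential integrity.
#' @param gene_column Which column identifies the gene: `"symbol"` (column 3,
#'   default) or `"id"` (column 2).
#' @return A `go_annotations` object: raw (unpropagated) term-to-gene sets.
#'   The number of rows dropped for unknown terms is attached as attribute
#'   `n_unknown_terms`.
#' @export
parse_gaf <- function(path, onto, gene_column = c("symbol", "id")) {
  gene_column <- match.arg(gene_column)
  if (!file.exists(path)) {
    abort_config(sprintf("GAF file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  data_rows <- which(!startsWith(lines, "!") & nzchar(lines))
  # sentinel keeps trailing empty fields (columns 16/17 are usually blank)
  fields <- strsplit(paste0(lines[data_rows], "\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  })
  nfield <- lengths(fields)
  bad <- which(nfield != 17L)
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "GAF row at line %d has %d columns; expected 17.",
      data_rows[bad[[1]]], nfield[bad[[1]]]
    ))
  }
  if (length(fields) == 0) {
    return(structure(new_annotations(list()), n_unknown_terms = 0L))
  }
  m <- do.call(rbind, fields)
  gene <- m[, if (gene_column == "symbol") 3L else 2L]
  qualifier <- m[, 4L]
  term <- m[, 5L]
  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  gene <- gene[keep]
  term <- term[keep]
  known <- term %in% onto$terms
  n_unknown <- sum(!known)
  if (n_unknown > 0) {
    warn(sprintf("%d GAF rows cite terms absent from the ontology; dropped.", n_unknown))
  }
  ann <- new_annotations(split(gene[known], term[known]))
  attr(ann, "n_unknown_terms") <- n_unknown
  ann
}

#' Write annotations as a GAF 2.2 file
#'
#' @param ann A `go_annotations` object (term -> gene sets).
#' @param onto A [go_ontology()] supplying namespaces for the aspect column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(ann, onto, path) {
  tab <- annotation_table(ann)
  aspect <- c(
    biological_process = "P",
    molecular_function = "F",
    cellular_component = "C"
  )[onto$namespace[tab$term]]
  rows <- paste(
    "SYN", tab$gene, tab$gene, "", tab$term, "SYN_REF:0000001", "IEA", "",
    aspect, tab$gene, "", "protein", "taxon:0000", "20200101", "scgonet", "", "",
    sep = "\t"
  )
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

#' Propagate annotations up the ontology
#'
#' In GO, a parent term annotates every gene annotated by any of its
#' descendants. This computes, for each term, the union of its own raw gene
#' set and the raw sets of all descendants. The operation is idempotent.
#'
#' @param onto A [go_ontology()].
#' @param ann Raw `go_annotations`.
#' @return Propagated `go_annotations` covering every ontology term (terms
#'   with no annotated descendants get an empty set).
#' @export
propagate_annotations <- function(onto, ann) {
  ord <- topological_order(onto) # children before parents
  children <- split(onto$edges$child, factor(onto$edges$parent, levels = onto$terms))
  sets <- vector("list", length(onto$terms))
  names(sets) <- onto$terms
  for (t in ord) {
    own <- if (t %in% names(ann)) ann[[t]] else character(0)
    from_children <- unlist(sets[children[[t]]], use.names = FALSE)
    sets[[t]] <- sort(unique(c(own, from_children)))
  }
  new_annotations(sets)
}
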