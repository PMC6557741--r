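test_that("parse_obo reads stanzas, skips obsolete terms and non-is_a relations", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: root",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: child one",
    "namespace: biological_process",
    "is_a: GO:0000001 ! root",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: child two",
    "namespace: biological_process",
    "is_a: GO:0000001",
    "relationship: part_of GO:0000002",
    "",
    "[Term]",
    "id: GO:0000009",
    "name: gone",
    "namespace: biological_process",
    "is_obsolete: true",
    "",
    "[Typedef]",
    "id: part_of"
  ), obo)
  onto <- parse_obo(obo)
  expect_setequal(onto$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(nrow(onto$edges), 2)        # part_of did not become an edge
  expect_equal(onto$obsolete, "GO:0000009")
  expect_equal(unname(onto$namespace["GO:0000002"]), "biological_process")
})

test_that("parse_obo rejects cycles and malformed stanza lines", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: GO:1", "namespace: biological_process", "is_a: GO:2", "",
    "[Term]", "id: GO:2", "namespace: biological_process", "is_a: GO:1"
  ), obo)
  expect_error(parse_obo(obo), class = "scgonet_integrity_error")

  bad <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:1", "namespace: biological_process",
               "this line has no key"), bad)
  expect_error(parse_obo(bad), "line 4", class = "scgonet_parse_error")
})

test_that("term layers follow shortest is_a paths to the namespace root", {
  onto <- toy_ontology()
  expect_equal(term_layer(onto, "GO:R"), 0L)
  expect_equal(term_layer(onto, "GO:A"), 1L)
  # GO:D has paths of length 3 (via B) and 2 (via C): shortest wins
  expect_equal(term_layer(onto, "GO:L1"), 3L)
  expect_equal(term_layer(onto, "GO:D"), 2L)
  expect_error(term_layer(onto, "GO:NOPE"), class = "scgonet_domain_error")
})

test_that("term layering agrees with an independent BFS oracle on random DAGs", {
  skip_if_not_installed("igraph")
  for (s in 1:50) {
    onto <- random_dag(n = sample(5:100, 1), seed = s)
    expect_identical(onto$layers[onto$terms], igraph_layers(onto),
                     info = sprintf("dag seed %d", s))
  }
})

test_that("candidate_terms filters by layer and namespace deterministically", {
  # two BP terms and one MF term at layer 3, one CC term at layer 3
  terms <- c("bpR", "bp1", "bp2", "bpA", "bpB",
             "mfR", "mf1", "mf2", "mfA",
             "ccR", "cc1", "cc2", "ccA")
  ns <- stats::setNames(rep(c("biological_process", "molecular_function",
                              "cellular_component"), c(5, 4, 4)), terms)
  edges <- data.frame(
    child = c("bp1", "bp2", "bpA", "bpB", "mf1", "mf2", "mfA", "cc1", "cc2", "ccA"),
    parent = c("bpR", "bp1", "bp2", "bp2", "mfR", "mf1", "mf2", "ccR", "cc1", "cc2")
  )
  onto <- go_ontology(terms, edges, ns)
  expect_equal(candidate_terms(onto, 3), c("bpA", "bpB", "mfA"))
  expect_equal(candidate_terms(onto, 99), character(0))
})

test_that("a term reachable at layer 2 by its shortest path is not a layer-3 candidate", {
  onto <- toy_ontology()
  # GO:D sits at layer 2 even though a length-3 path could be drawn through B
  expect_false("GO:D" %in% candidate_terms(onto, 3))
  expect_true("GO:D" %in% candidate_terms(onto, 2))
})

test_that("parse_gaf deduplicates, honors NOT and referential integrity", {
  onto <- toy_ontology()
  gaf <- withr::local_tempfile(fileext = ".gaf")
  row <- function(gene, term, qualifier = "") {
    paste(c("SYN", gene, gene, qualifier, term, "REF", "IEA", "", "P", gene,
            "", "protein", "taxon:0000", "20200101", "x", "", ""), collapse = "\t")
  }
  writeLines(c(
    "!gaf-version: 2.2",
    row("g1", "GO:L1"), row("g1", "GO:L1"),            # duplicate
    row("g2", "GO:L1", qualifier = "NOT"),             # negative annotation
    row("g3", "GO:MISSING")                            # unknown term
  ), gaf)
  expect_warning(ann <- parse_gaf(gaf, onto), "1 GAF rows")
  expect_equal(ann[["GO:L1"]], "g1")
  expect_equal(attr(ann, "n_unknown_terms"), 1L)
})

test_that("parse_gaf reports the offending row on a column-count error", {
  onto <- toy_ontology()
  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!comment", "too\tfew\tcolumns"), gaf)
  expect_error(parse_gaf(gaf, onto), "line 2", class = "scgonet_parse_error")
})

test_that("annotation propagation is transitive, set-valued and idempotent", {
  onto <- toy_ontology()
  raw <- new_ann <- list("GO:L1" = "g1", "GO:D" = c("g2", "g3"))
  class(raw) <- "go_annotations"
  prop <- propagate_annotations(onto, raw)
  expect_equal(prop[["GO:C"]], c("g2", "g3"))           # leaf -> parent
  expect_equal(prop[["GO:B"]], c("g1", "g2", "g3"))
  # diamond: GO:D reaches the root via two paths, genes appear once
  expect_equal(prop[["GO:R"]], c("g1", "g2", "g3"))
  # idempotent and monotone
  prop2 <- propagate_annotations(onto, prop)
  expect_identical(unclass(prop2)[names(prop2)], unclass(prop)[names(prop)])
  for (t in names(raw)) expect_true(all(raw[[t]] %in% prop[[t]]))
})

test_that("propagation invariants hold on random DAGs", {
  for (s in 1:10) {
    onto <- random_dag(n = 30, seed = 100 + s)
    raw <- withr::with_seed(s, {
      picked <- sample(onto$terms, 8)
      stats::setNames(lapply(picked, function(t) {
        sample(sprintf("g%02d", 1:20), sample(1:4, 1))
      }), picked)
    })
    class(raw) <- "go_annotations"
    prop <- propagate_annotations(onto, raw)
    # parent superset of union of children
    for (i in seq_len(nrow(onto$edges))) {
      expect_true(all(prop[[onto$edges$child[i]]] %in% prop[[onto$edges$parent[i]]]))
    }
    prop2 <- propagate_annotations(onto, prop)
    expect_identical(unclass(prop2)[onto$terms], unclass(prop)[onto$terms])
  }
})

test_that("unique_score is the Jaccard overlap with its edge cases", {
  expect_equal(unique_score(c("g1", "g2"), c("g1", "g2")), 1.0)
  expect_equal(unique_score("g1", "g2"), 0.0)
  expect_equal(unique_score(c("g1", "g2", "g3"), c("g2", "g3", "g4")), 0.5)
  expect_error(unique_score(character(0), character(0)),
               class = "scgonet_domain_error")
  # symmetry and boundary characterization on random sets
  withr::with_seed(7, {
    for (i in 1:20) {
      a <- sample(letters, sample(1:10, 1))
      b <- sample(letters, sample(1:10, 1))
      expect_equal(unique_score(a, b), unique_score(b, a))
      expect_equal(unique_score(a, b) == 1, setequal(a, b))
      expect_equal(unique_score(a, b) == 0, length(intersect(a, b)) == 0)
    }
  })
})

test_that("redundancy removal is strict at the threshold and keeps the larger set", {
  ann <- structure(list(
    A = c("a", "b", "c", "d", "e"),     # 5 genes
    B = c("a", "b", "c", "d"),          # U(A,B) = 4/5 = 0.8 -> B dropped
    C = c("x", "y"),
    D = c("x", "y", "p", "q")           # U(C,D) = 2/4 = 0.5 -> both kept
  ), class = "go_annotations")
  out <- remove_redundant(c("A", "B", "C", "D"), ann)
  expect_setequal(out$kept, c("A", "C", "D"))
  expect_equal(out$removal_log$term, "B")
  expect_equal(out$removal_log$reason, "redundant")
  expect_equal(out$removal_log$partner, "A")
})

test_that("identical gene sets keep exactly one term (the smaller id)", {
  ann <- structure(list(Z = c("a", "b"), Y = c("a", "b")),
                   class = "go_annotations")
  out <- remove_redundant(c("Z", "Y"), ann)
  expect_equal(out$kept, "Y")
  expect_equal(out$removal_log$term, "Z")
})

test_that("redundancy removal ignores candidate duplication", {
  ann <- structure(list(
    A = c("a", "b", "c", "d", "e"), B = c("a", "b", "c", "d"),
    C = c("q", "r", "s")
  ), class = "go_annotations")
  once <- remove_redundant(c("A", "B", "C"), ann)
  twice <- remove_redundant(rep(c("A", "B", "C"), 2), ann)
  expect_identical(once$kept, twice$kept)
})

test_that("diversity scoring averages per-gene standard deviations", {
  expect_equal(diversity_score(c("g1", "g2"), c(g1 = 0, g2 = 0)), 0)
  expect_equal(diversity_score("g1", c(g1 = 0.37)), 0.37)
  expect_equal(diversity_score(c("g1", "g2"), c(g1 = 0.2, g2 = 0.4)), 0.3)
  expect_error(diversity_score(character(0), c(g1 = 1)),
               class = "scgonet_domain_error")
  expect_error(diversity_score("gX", c(g1 = 1)), class = "scgonet_domain_error")
})

test_that("low-diversity filtering is strict below the threshold", {
  ann <- structure(list(A = "g1", B = "g2", C = "g3"),
                   class = "go_annotations")
  gs <- c(g1 = 0.1, g2 = 0.05, g3 = 0.5)
  out <- filter_low_diversity(c("A", "B", "C"), ann, gs, threshold = 0.1)
  expect_equal(out$kept, c("A", "C"))                 # H = 0.1 exactly is kept
  expect_equal(out$removal_log$term, "B")
  expect_equal(out$removal_log$reason, "low_diversity")
  empty <- filter_low_diversity(character(0), ann, gs)
  expect_equal(empty$kept, character(0))
})

test_that("the three-step selection removes exactly the planted terms on the fixture", {
  p <- fixture_pipeline()
  sel <- p$sel
  terms <- sort(names(p$fx$annotations))
  expect_equal(length(sel$candidates), 20)
  expect_equal(length(sel$kept), 16)
  expect_equal(nrow(sel$table[sel$table$status == "removed", ]), 4)
  removed <- sel$table[sel$table$status == "removed", ]
  expect_setequal(removed$term[removed$reason == "redundant"], p$fx$redundant_terms)
  expect_setequal(removed$term[removed$reason == "low_diversity"], p$fx$constant_terms)
})

test_that("skip_selection keeps every candidate and dominates the filtered set", {
  p <- fixture_pipeline()
  gs <- gene_sds(p$fx$expression)
  all_sel <- select_significant_terms(p$fx$ontology, p$fx$annotations, gs,
                                      skip_selection = TRUE)
  expect_equal(length(all_sel$kept), 20)
  expect_true(all(p$sel$kept %in% all_sel$kept))
})

test_that("pathological thresholds raise a configuration error", {
  p <- fixture_pipeline()
  gs <- gene_sds(p$fx$expression)
  expect_error(
    select_significant_terms(p$fx$ontology, p$fx$annotations, gs,
                             u_threshold = 0, h_threshold = Inf),
    class = "scgonet_config_error"
  )
})

test_that("selection tables round-trip through the TSV writer", {
  p <- fixture_pipeline()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_selection(p$sel, tsv)
  back <- readr::read_tsv(tsv, col_types = readr::cols(), progress = FALSE)
  expect_equal(back$term, p$sel$table$term)
  expect_equal(back$status, p$sel$table$status)
  expect_true(file.exists(paste0(tsv, ".params.json")))
})
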