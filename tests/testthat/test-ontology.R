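# Ontology loading, ancestor sequences and fuzzy entity linking.

test_that("load_obo keeps only is-a edges and counts stanzas", {
  g <- fixture_graph()
  expect_s3_class(g, "ontology_graph")
  expect_length(g$ids, 6L)
  expect_identical(sum(lengths(g$parents)), 6L)

  # relationship: lines and trailing "!" comments are dropped
  path <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: X:1", "name: parent", "",
               "[Term]", "id: X:2", "name: other", "",
               "[Term]", "id: X:3", "name: child",
               "is_a: X:1 ! part_of-like comment",
               "relationship: part_of X:2", ""), path)
  g2 <- load_obo(path)
  expect_identical(g2$parents[["X:3"]], "X:1")
})

test_that("obsolete terms are excluded from the graph and from linking", {
  path <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: X:1", "name: live drug", "",
               "[Term]", "id: X:2", "name: dead drug",
               "is_obsolete: true", ""), path)
  g <- load_obo(path)
  expect_identical(g$ids, "X:1")
  # an exact match against the obsolete label is refused
  expect_null(link_entity(g, "dead drug"))
})

test_that("a cyclic is-a relation is rejected with the offending cycle", {
  path <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: C:1", "name: one", "is_a: C:2", "",
               "[Term]", "id: C:2", "name: two", "is_a: C:1", ""), path)
  expect_error(load_obo(path), class = "ontorel_cycle_error")
  expect_error(load_obo(path), "C:1")
})

test_that("ancestor sequences on the 6-term fixture match the closure oracle", {
  g <- fixture_graph()
  # frozen from the brute-force oracle
  expect_identical(ancestors(g, "T:5"), c("T:0", "T:1", "T:3", "T:5"))
  expect_identical(ancestors(g, "T:0"), "T:0")
  expect_identical(common_ancestors(g, "T:5", "T:4"), c("T:0", "T:1"))
  expect_identical(concat_ancestors(g, "T:5", "T:4"),
                   c("T:0", "T:1", "T:3", "T:5", "T:0", "T:1", "T:2", "T:4"))
  expect_identical(concat_ancestors(g, "T:0", "T:0"), c("T:0", "T:0"))
  # depths frozen from the longest-path oracle
  expect_identical(concept_depth(g, "T:0"), 0L)
  expect_identical(concept_depth(g, "T:4"), 2L)
  expect_identical(concept_depth(g, "T:5"), 3L)

  parents <- list("T:0" = character(0), "T:1" = "T:0", "T:2" = "T:0",
                  "T:3" = "T:1", "T:4" = c("T:1", "T:2"), "T:5" = "T:3")
  for (cid in g$ids) {
    expect_identical(ancestors(g, cid), oracle_ancestor_seq(parents, cid))
    expect_identical(concept_depth(g, cid),
                     unname(oracle_depth(parents)[[cid]]))
  }
})

test_that("common-ancestor algebra holds on the fixture", {
  g <- fixture_graph()
  for (a in g$ids) {
    expect_identical(common_ancestors(g, a, a), ancestors(g, a))
    for (b in g$ids) {
      ca <- common_ancestors(g, a, b)
      expect_identical(ca, common_ancestors(g, b, a))
      expect_identical(length(concat_ancestors(g, a, b)),
                       length(ancestors(g, a)) + length(ancestors(g, b)))
      # depth-monotone ordering
      expect_true(!is.unsorted(vapply(ca, concept_depth, integer(1),
                                      graph = g)))
    }
  }
  # subsumption corner case: T:1 is an ancestor of T:5, so it appears in CA
  expect_true("T:1" %in% common_ancestors(g, "T:1", "T:5"))
})

test_that("ancestors match brute-force closure on random DAGs", {
  for (seed in 1:10) {
    n <- 5L + (seed * 7L) %% 46L
    parents <- random_parents(n, seed)
    g <- load_obo(obo_from_parents(parents))
    closure <- oracle_closure(parents)
    d <- oracle_depth(parents)
    for (cid in names(parents)) {
      seq_got <- ancestors(g, cid)
      expect_identical(seq_got[length(seq_got)], cid)
      expect_identical(seq_got, oracle_ancestor_seq(parents, cid))
      expect_identical(concept_depth(g, cid), unname(d[[cid]]))
    }
    # spot-check symmetry on a few pairs
    picks <- utils::head(names(parents), 4L)
    for (a in picks) for (b in picks) {
      expect_identical(common_ancestors(g, a, b),
                       common_ancestors(g, b, a))
    }
  }
})

test_that("unknown concepts raise a classed error", {
  g <- fixture_graph()
  expect_error(ancestors(g, "T:99"), class = "ontorel_unknown_concept")
  expect_error(common_ancestors(g, "T:0", "nope"),
               class = "ontorel_unknown_concept")
  expect_error(concept_depth(g, "nope"),
               class = "ontorel_unknown_concept")
})

test_that("fuzzy linking honors threshold, synonym fallback and tie-breaks", {
  g <- fixture_graph()
  # exact label match
  m <- link_entity(g, "alpha")
  expect_identical(m$concept_id, "T:0")
  expect_identical(m$score, 1)
  expect_identical(m$matched_via, "label")
  # case-insensitive
  expect_identical(link_entity(g, "ALPHA")$score, 1)
  # nothing close enough
  expect_null(link_entity(g, "zzzzzz"))

  # synonym beats a weak label match: normalized Levenshtein computed by
  # dynamic programming gives 1 - 1/8 = 0.875 for aspirin/aspirine
  path <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A:1", "name: acetylsalicylic acid",
               'synonym: "aspirin" EXACT []', ""), path)
  ga <- load_obo(path)
  m <- link_entity(ga, "aspirine")
  expect_identical(m$matched_via, "synonym")
  expect_equal(m$score, 1 - 1 / 8)

  # produced matches always meet the threshold; linking is deterministic
  for (mention in c("alpha", "bete", "gamm", "zzzzzz", "epsilon")) {
    m1 <- link_entity(g, mention, 0.7)
    m2 <- link_entity(g, mention, 0.7)
    expect_identical(m1, m2)
    if (!is.null(m1)) expect_gte(m1$score, 0.7)
  }

  # equal-score ties resolve to the lowest concept id
  path2 <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: B:2", "name: samelabel", "",
               "[Term]", "id: B:1", "name: samelabel", ""), path2)
  expect_identical(link_entity(load_obo(path2), "samelabel")$concept_id,
                   "B:1")
})

test_that("ancestor cache TSV round-trips", {
  g <- fixture_graph()
  links <- data.frame(entity_id = c("e1", "e2"),
                      concept_id = c("T:5", "T:4"),
                      stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_ancestor_cache(g, links, path)
  back <- read_ancestor_cache(path)
  expect_identical(back$entity_id, links$entity_id)
  expect_identical(back$ancestors[[1]], ancestors(g, "T:5"))
  expect_identical(back$ancestors[[2]], ancestors(g, "T:4"))
})
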