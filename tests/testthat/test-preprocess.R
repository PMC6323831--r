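# Candidate pairs, dependency paths, masking, filtering, pipeline.

test_that("candidate pair counts follow choose(E, 2) with gold label join", {
  for (E in 1:6) {
    s <- make_sentence(sprintf("d.s%d", E),
                       sprintf("drug%d", seq_len(max(E, 1L))),
                       entity_pos = seq_len(E))
    expect_identical(nrow(generate_candidate_pairs(s)),
                     as.integer(choose(E, 2L)))
  }
  # 4 entities, 2 gold DDIs -> 6 pairs, 2 positive
  s <- make_sentence("d.s", sprintf("drug%d", 1:4), entity_pos = 1:4,
                     pairs = list(list(1, 2, "effect"),
                                  list(3, 4, "mechanism")))
  pairs <- generate_candidate_pairs(s)
  expect_identical(nrow(pairs), 6L)
  expect_identical(sum(pairs$label != "negative"), 2L)
  expect_identical(sum(pairs$provenance == "gold"), 2L)
  # e1 precedes e2 in text
  ent <- s$entities
  starts <- setNames(ent$char_start, ent$id)
  expect_true(all(starts[pairs$e1] < starts[pairs$e2]))
})

test_that("tokenizer spans slice back to their tokens", {
  for (text in c("aspirin increases the effect of warfarin",
                 "one, two and three-four (five).",
                 "Response to Plenaxis should be monitored")) {
    tk <- tokenize(text)
    for (i in seq_len(nrow(tk))) {
      expect_identical(substr(text, tk$char_start[i] + 1L,
                              tk$char_end[i] + 1L), tk$token[i])
    }
  }
})

test_that("SDP on a chain parse is the index interval between entities", {
  s <- make_sentence("d.s1",
                     c("t1", "aspirin", "t3", "t4", "t5", "warfarin",
                       "t7", "t8"),
                     entity_pos = c(2L, 6L))
  parse <- chain_parser(s$text)
  sdp <- shortest_dependency_path(parse, s$entities[1, ], s$entities[2, ])
  expect_identical(sdp, 2:6)
  expect_identical(parse$tokens[sdp[1]], "aspirin")
  expect_identical(parse$tokens[sdp[length(sdp)]], "warfarin")
})

test_that("SDP through a shared head is the 3-token tree path", {
  parse <- ontorel:::new_dependency_parse(
    tokens = c("aspirin", "affects", "warfarin"),
    char_start = c(0L, 8L, 16L), char_end = c(6L, 14L, 23L),
    head = c(2L, 2L, 2L), label = c("nsubj", "root", "dobj"))
  e1 <- list(char_start = 0L, char_end = 6L)
  e2 <- list(char_start = 16L, char_end = 23L)
  expect_identical(shortest_dependency_path(parse, e1, e2), c(1L, 2L, 3L))
  # degenerate: both entities on the same token
  expect_identical(shortest_dependency_path(parse, e1, e1), 1L)
})

test_that("SDP endpoints are the entity head tokens, path length bounded", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(4:10, 1L)
    toks <- sprintf("w%d", seq_len(n))
    pos <- sort(sample(n, 2L))
    s <- make_sentence("d.s", toks, entity_pos = pos)
    parse <- chain_parser(s$text)
    sdp <- shortest_dependency_path(parse, s$entities[1, ],
                                    s$entities[2, ])
    expect_gte(length(sdp), 1L)
    expect_lte(length(sdp), n)
    expect_identical(sdp[1], pos[1])
    expect_identical(sdp[length(sdp)], pos[2])
  }
})

test_that("unmappable entities raise a classed error", {
  parse <- chain_parser("alpha beta")
  e_bad <- list(char_start = 50L, char_end = 55L)
  expect_error(shortest_dependency_path(parse, e_bad, e_bad),
               class = "ontorel_unmappable_entity")
})

test_that("masking replaces every entity token and only those", {
  path <- c("Plenaxis", "Response", "monitored", "by", "measuring",
            "concentrations", "testosterone")
  masked <- mask_entities(path, c(1L, 7L))
  expect_identical(masked,
                   c("entity", "Response", "monitored", "by", "measuring",
                     "concentrations", "entity"))
  # a third, non-candidate drug on the path is masked too
  expect_identical(mask_entities(path, c(1L, 4L, 7L))[4], "entity")
  # degenerate: all tokens are entities
  expect_identical(mask_entities(c("a", "b"), 1:2), c("entity", "entity"))
  expect_length(mask_entities(c("a", "b"), 1:2), 2L)
})

test_that("supersense inventory has 41 classes and taggers respect it", {
  inv <- supersense_inventory()
  expect_length(inv, 41L)
  expect_identical(sum(startsWith(inv, "noun.")), 26L)
  expect_identical(sum(startsWith(inv, "verb.")), 15L)
  tagger <- make_lexicon_tagger(c(monitored = "verb.perception",
                                  group = "noun.group"))
  out <- tagger(c("Monitored", "by", "group"))
  expect_identical(out, c("verb.perception", "0", "noun.group"))
  expect_identical(null_tagger(c("a", "b")), c("0", "0"))
  expect_error(make_lexicon_tagger(c(x = "not.a.class")))
})

test_that("the three negative-filter rules fire exactly as stated", {
  # 20-pair fixture: 5 sentences x varying entity counts
  anti <- c("contains", "includes")
  mk <- function(id, tokens, pos, texts = NULL) {
    make_sentence(id, tokens, entity_pos = pos, entity_text = texts)
  }
  # rule 1: same text regardless of case
  s1 <- mk("f.s1", c("Aspirin", "resembles", "aspirin"), c(1L, 3L))
  # rule 2: only punctuation/whitespace between the mentions
  s2 <- mk("f.s2", c("warfarin", ",", "heparin", "interact"), c(1L, 3L))
  # kept: real words between mentions
  s3 <- mk("f.s3", c("aspirin", "increases", "the", "effect", "of",
                     "warfarin"), c(1L, 6L))
  # rule 3: both governed by anti-positive lemmas (chain parse:
  # governor of a token is its predecessor)
  s4 <- mk("f.s4", c("x", "contains", "aspirin", "includes", "warfarin"),
           c(3L, 5L))
  # one anti-positive governor only -> kept
  s5 <- mk("f.s5", c("x", "contains", "aspirin", "boosts", "warfarin"),
           c(3L, 5L))
  for (s in list(s1, s2, s3, s4, s5)) {
    pairs <- generate_candidate_pairs(s)
    parts <- filter_negatives(pairs, s, chain_parser(s$text), anti)
    fired <- nrow(parts$auto_negative)
    expected <- switch(s$id, f.s1 = 1L, f.s2 = 1L, f.s3 = 0L, f.s4 = 1L,
                       f.s5 = 0L)
    expect_identical(fired, expected)
    # partition: nothing discarded silently
    expect_identical(nrow(parts$kept) + fired, nrow(pairs))
    key <- function(p) sort(paste(p$e1, p$e2))
    expect_identical(sort(c(key(parts$kept), key(parts$auto_negative))),
                     key(pairs))
  }
  # a 20-pair sentence mixing firing and non-firing cases
  toks <- c("a", sprintf("drug%d", 1:3), "with", "drug4", "plus",
            "drug5", ",", "drug5")
  s6 <- make_sentence("f.s6", toks, entity_pos = c(2L, 3L, 4L, 6L, 8L,
                                                   10L))
  pairs6 <- generate_candidate_pairs(s6)
  expect_identical(nrow(pairs6), 15L)
  parts6 <- filter_negatives(pairs6, s6, chain_parser(s6$text),
                             character(0))
  # drug1|drug2, drug2|drug3 are adjacent (space only); drug5 appears
  # twice (same text, and comma-separated)
  expect_identical(nrow(parts6$auto_negative), 3L)
})

test_that("anti-positive governors are learned from training gold labels", {
  # "contains" governs entities 5x, never in a positive pair
  sents <- lapply(1:5, function(i) {
    make_sentence(sprintf("t.d1.s%d", i),
                  c("it", "contains", sprintf("drugA%d", i),
                    sprintf("near%d", i), sprintf("drugB%d", i)),
                  entity_pos = c(3L, 5L),
                  pairs = list(list(1, 2, "negative")))
  })
  # "boosts" governs an entity of a positive pair -> excluded
  sents[[6]] <- make_sentence("t.d1.s6",
                              c("it", "boosts", "drugC", "over", "drugD"),
                              entity_pos = c(3L, 5L),
                              pairs = list(list(1, 2, "effect")))
  doc <- make_document("t.d1", sents)
  out <- build_anti_positive_list(list(doc), min_count = 3L)
  expect_true("contains" %in% out)
  expect_false("boosts" %in% out)
  # below the count floor (each nearX appears once)
  expect_false(any(sprintf("near%d", 1:5) %in% out) || "over" %in% out)
  # empty corpus
  expect_identical(build_anti_positive_list(list()), character(0))
})

test_that("ontology sequences attach per the fixture oracle", {
  g <- fixture_graph()
  seqs <- attach_ontology_sequences(g, "T:5", "T:4")
  expect_length(seqs$concat, 8L)
  expect_identical(seqs$common, c("T:0", "T:1"))
  # one unlinked entity -> both sequences empty
  empty <- attach_ontology_sequences(g, "T:5", NA_character_)
  expect_identical(empty$concat, character(0))
  expect_identical(empty$common, character(0))
  # both mentions linked to the same concept -> CA equals the ancestors
  expect_identical(attach_ontology_sequences(g, "T:3", "T:3")$common,
                   ancestors(g, "T:3"))
})

test_that("no raw entity surface string reaches the SDP tokens", {
  ds <- shared_synth()
  docs <- ds$corpus$documents[1:6]
  inst <- build_instances(docs, graph = ds$ontology$graph)
  surfaces <- unique(unlist(lapply(docs, function(d) {
    lapply(d$sentences, function(s) s$entities$text)
  })))
  sdp_all <- unlist(lapply(inst, `[[`, "sdp_tokens"))
  expect_length(intersect(sdp_all, surfaces), 0L)
  # feature invariants: equal-length token/class channels, mask present
  for (x in inst) {
    expect_identical(length(x$sdp_tokens), length(x$wordnet))
    if (x$provenance != "auto_negative") {
      expect_identical(x$sdp_tokens[1], "entity")
      expect_identical(x$sdp_tokens[length(x$sdp_tokens)], "entity")
    }
  }
})

test_that("with filtering off, instance count is the pair-count sum", {
  ds <- shared_synth()
  docs <- ds$corpus$documents[1:4]
  inst <- build_instances(docs, graph = NULL, filter = FALSE)
  expected <- sum(unlist(lapply(docs, function(d) {
    vapply(d$sentences, function(s) choose(nrow(s$entities), 2),
           numeric(1))
  })))
  expect_identical(length(inst), as.integer(expected))
})
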