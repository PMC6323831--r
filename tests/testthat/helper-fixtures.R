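# Fixtures and independent oracles shared across test files.

# --- 6-term fixture ontology --------------------------------------------
# T:0 root; T:1,T:2 is_a T:0; T:3 is_a T:1; T:4 is_a T:1 and T:2;
# T:5 is_a T:3. Labels alpha..zeta.

fixture_obo_lines <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: T:0", "name: alpha", "",
    "[Term]", "id: T:1", "name: beta", "is_a: T:0", "",
    "[Term]", "id: T:2", "name: gamma", "is_a: T:0", "",
    "[Term]", "id: T:3", "name: delta", "is_a: T:1", "",
    "[Term]", "id: T:4", "name: epsilon", "is_a: T:1", "is_a: T:2", "",
    "[Term]", "id: T:5", "name: zeta", "is_a: T:3", "")
}

fixture_graph <- local({
  g <- NULL
  function() {
    if (is.null(g)) {
      path <- tempfile(fileext = ".obo")
      writeLines(fixture_obo_lines(), path)
      g <<- load_obo(path)
    }
    g
  }
})

# --- independent oracles -------------------------------------------------

# brute-force transitive closure by iterated relation composition on the
# boolean adjacency matrix (child x parent)
oracle_closure <- function(parents) {
  ids <- names(parents)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (cid in ids) A[cid, parents[[cid]]] <- 1
  R <- A
  repeat {
    R2 <- ((R %*% A) + R) > 0
    storage.mode(R2) <- "double"
    if (identical(R2, R)) break
    R <- R2
  }
  setNames(lapply(ids, function(cid) ids[R[cid, ] > 0]), ids)
}

# longest path from any root by exhaustive relaxation
oracle_depth <- function(parents) {
  ids <- names(parents)
  depth <- setNames(rep(0L, length(ids)), ids)
  repeat {
    changed <- FALSE
    for (cid in ids) {
      for (p in parents[[cid]]) {
        if (depth[[cid]] < depth[[p]] + 1L) {
          depth[[cid]] <- depth[[p]] + 1L
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  depth
}

# oracle ancestor *sequence*: closure sorted by (depth, id), self appended
oracle_ancestor_seq <- function(parents, cid) {
  anc <- oracle_closure(parents)[[cid]]
  d <- oracle_depth(parents)
  c(anc[order(d[anc], anc)], cid)
}

# random DAG as a parents list; edges always point to earlier ids
random_parents <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("N:%03d", seq_len(n))
  parents <- setNames(vector("list", n), ids)
  for (i in seq_len(n)[-1]) {
    k <- sample(0:min(2L, i - 1L), 1L)
    if (k > 0L) {
      earlier <- ids[seq_len(i - 1L)]
      parents[[ids[i]]] <- earlier[sample.int(i - 1L, k)]
    }
  }
  for (i in seq_len(n)) {
    if (is.null(parents[[i]])) parents[[i]] <- character(0)
  }
  parents
}

obo_from_parents <- function(parents, path = tempfile(fileext = ".obo")) {
  lines <- c("format-version: 1.2", "")
  for (cid in names(parents)) {
    lines <- c(lines, "[Term]", sprintf("id: %s", cid),
               sprintf("name: label %s", cid),
               sprintf("is_a: %s", parents[[cid]]), "")
  }
  writeLines(lines, path)
  path
}

# --- sentence construction with exact offsets ----------------------------

# Build a sentence list whose entities sit at given 1-based token
# positions; offsets are computed, never hand-counted.
make_sentence <- function(id, tokens, entity_pos, entity_text = NULL,
                          pairs = NULL, concept_ids = NULL) {
  text <- paste(tokens, collapse = " ")
  starts <- cumsum(c(0L, utils::head(nchar(tokens) + 1L, -1L)))
  ids <- sprintf("%s.e%d", id, seq_along(entity_pos))
  ent <- data.frame(
    id = ids,
    text = if (is.null(entity_text)) tokens[entity_pos] else entity_text,
    char_start = starts[entity_pos],
    char_end = starts[entity_pos] + nchar(tokens[entity_pos]) - 1L,
    entity_type = "drug",
    concept_id = if (is.null(concept_ids)) NA_character_ else concept_ids,
    stringsAsFactors = FALSE)
  pr <- if (is.null(pairs)) {
    data.frame(id = character(0), e1 = character(0), e2 = character(0),
               label = character(0), provenance = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = sprintf("%s.p%d", id, seq_along(pairs)),
               e1 = ids[vapply(pairs, `[[`, numeric(1), 1)],
               e2 = ids[vapply(pairs, `[[`, numeric(1), 2)],
               label = vapply(pairs, function(p) p[[3]], character(1)),
               provenance = "gold", stringsAsFactors = FALSE)
  }
  list(id = id, text = text, entities = ent, pairs = pr)
}

make_document <- function(id, sentences) {
  list(id = id, source_type = ontorel:::source_type_from_id(id),
       sentences = sentences)
}

# --- DDI XML fixture ------------------------------------------------------
# One document, one sentence, 3 entities, 3 pairs (1 effect, 2 negative).

fixture_corpus_path <- function() {
  s <- make_sentence(
    "Fix-DrugBank.d1.s1",
    c("aspirin", "potentiates", "warfarin", "but", "not", "heparin", "."),
    entity_pos = c(1L, 3L, 6L),
    pairs = list(list(1, 2, "effect"), list(1, 3, "negative"),
                 list(2, 3, "negative")))
  path <- tempfile(fileext = ".xml")
  write_ddi_xml(list(make_document("Fix-DrugBank.d1", list(s))), path)
  path
}

# a cached small synthetic dataset shared by several test files
shared_synth <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      ds <<- gen_synthetic_dataset(synthetic_spec(seed = 7,
                                                  n_sentences = 500),
                                   tempfile("synth"))
    }
    ds
  }
})
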