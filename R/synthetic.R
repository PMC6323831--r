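# Deterministic synthetic fixtures: a toy DAG ontology in OBO format, a toy
# annotated corpus in the DDI XML dialect whose pair labels are a planted
# function of ontology ancestry, and random unit word vectors in the
# textual word2vec format. Generation is a pure function of the spec:
# identical specs produce byte-identical files.

SYLLABLES <- c("ba", "be", "bi", "bo", "bu", "da", "de", "di", "do", "du",
               "fa", "fe", "fi", "fo", "fu", "ga", "ge", "gi", "go", "gu",
               "la", "le", "li", "lo", "lu", "ma", "me", "mi", "mo", "mu",
               "na", "ne", "ni", "no", "nu", "ra", "re", "ri", "ro", "ru",
               "sa", "se", "si", "so", "su", "ta", "te", "ti", "to", "tu",
               "za", "ze", "zi", "zo", "zu")

# size-safe sample (never expands a length-1 integer vector into a range)
sample_safe <- function(x, k) x[sample.int(length(x), k)]

make_words <- function(n, min_syl = 2L, max_syl = 4L,
                       exclude = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    w <- paste(sample(SYLLABLES, sample(min_syl:max_syl, 1L),
                      replace = TRUE), collapse = "")
    if (!w %in% out && !w %in% exclude) out <- c(out, w)
  }
  out
}

#' Specification of a synthetic dataset
#'
#' Bundles every knob of the generator; generation is a pure function of
#' this object. The label rule plants the signal: under
#' `label_rule = "common_ancestor"` a candidate pair is positive (with
#' type `positive_type`) exactly when the designated marker concept is a
#' common ancestor of the two linked concepts, independent of the surface
#' wording; under `"entity_ancestor"` the rule keys on the first entity's
#' own ancestry only.
#'
#' @param seed Integer master seed.
#' @param n_concepts Number of ontology concepts (default 40).
#' @param max_depth Maximum is-a depth of the generated DAG (default 4).
#' @param branching Mean branching hint for the tree skeleton (default 3).
#' @param n_sentences Number of corpus sentences (default 500).
#' @param positive_rate Target fraction of positive candidate pairs
#'   (default 0.25).
#' @param positive_type Interaction type of positive pairs (default
#'   `"effect"`).
#' @param label_rule `"common_ancestor"` (default) or `"entity_ancestor"`.
#' @param vocab_size Number of filler words for sentence templates
#'   (default 50).
#' @param vector_dim Word vector dimension (default 50).
#' @param corruption_rate Per-mention probability of a single-character
#'   substitution or deletion of the surface string (default 0.2).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(seed = 1L, n_concepts = 40L, max_depth = 4L,
                           branching = 3L, n_sentences = 500L,
                           positive_rate = 0.25,
                           positive_type = "effect",
                           label_rule = c("common_ancestor",
                                          "entity_ancestor"),
                           vocab_size = 50L, vector_dim = 50L,
                           corruption_rate = 0.2) {
  label_rule <- match.arg(label_rule)
  stopifnot(n_concepts >= max_depth, positive_rate > 0, positive_rate < 1,
            positive_type %in% setdiff(DDI_LABELS, "negative"))
  structure(list(seed = as.integer(seed),
                 n_concepts = as.integer(n_concepts),
                 max_depth = as.integer(max_depth),
                 branching = as.integer(branching),
                 n_sentences = as.integer(n_sentences),
                 positive_rate = positive_rate,
                 positive_type = positive_type, label_rule = label_rule,
                 vocab_size = as.integer(vocab_size),
                 vector_dim = as.integer(vector_dim),
                 corruption_rate = corruption_rate),
            class = "synthetic_spec")
}

# all concepts subsumed by `id` (closure over child edges), excluding id
descendant_set <- function(graph, id) {
  children <- list()
  for (child in names(graph$parents)) {
    for (p in graph$parents[[child]]) {
      children[[p]] <- c(children[[p]], child)
    }
  }
  seen <- character(0)
  frontier <- children[[id]]
  while (length(frontier) > 0L) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(children[frontier], use.names = FALSE))
  }
  seen
}

#' Generate a toy DAG ontology as an OBO file
#'
#' Builds a random rooted DAG of the requested size and depth: a tree
#' skeleton plus a second parent (of strictly smaller depth, preserving
#' acyclicity) for roughly 20% of non-root concepts. Each concept gets a
#' unique pseudo-word label and 0-2 synonyms. A marker concept at depth
#' at least 1 whose descendant count is closest to half the non-root
#' concepts is designated for the label rule, keeping both the marker
#' subtree and its complement populated.
#'
#' @param spec A [synthetic_spec()].
#' @param path Output OBO path.
#' @return List with `path`, the loaded `graph`, and `marker` (the marker
#'   concept id).
#' @export
gen_ontology <- function(spec, path) {
  set.seed(spec$seed)
  n <- spec$n_concepts
  ids <- sprintf("SYN:%06d", seq_len(n))
  depth <- integer(n)
  parent1 <- rep(NA_integer_, n)
  for (i in seq_len(n)[-1]) {
    eligible <- which(depth[seq_len(i - 1L)] < spec$max_depth)
    parent1[i] <- if (length(eligible) == 1L) eligible else {
      sample(eligible, 1L)
    }
    depth[i] <- depth[parent1[i]] + 1L
  }
  parent2 <- rep(NA_integer_, n)
  for (i in seq_len(n)[-1]) {
    shallower <- setdiff(which(depth < depth[i]), parent1[i])
    if (length(shallower) > 0L && stats::runif(1) < 0.2) {
      parent2[i] <- if (length(shallower) == 1L) shallower else {
        sample(shallower, 1L)
      }
    }
  }
  words <- make_words(3L * n)
  labels <- words[seq_len(n)]
  pool <- words[-seq_len(n)]
  n_syn <- sample(0:2, n, replace = TRUE)
  syn_idx <- cumsum(c(0L, n_syn))
  synonyms <- lapply(seq_len(n), function(i) {
    if (n_syn[i] == 0L) character(0) else {
      pool[(syn_idx[i] + 1L):syn_idx[i + 1L]]
    }
  })
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(n)) {
    lines <- c(lines, "[Term]", sprintf("id: %s", ids[i]),
               sprintf("name: %s", labels[i]),
               sprintf('synonym: "%s" EXACT []', synonyms[[i]]),
               if (!is.na(parent1[i])) {
                 sprintf("is_a: %s ! %s", ids[parent1[i]],
                         labels[parent1[i]])
               },
               if (!is.na(parent2[i])) {
                 sprintf("is_a: %s ! %s", ids[parent2[i]],
                         labels[parent2[i]])
               },
               "")
  }
  writeLines(lines, path)
  graph <- load_obo(path)
  cand <- graph$ids[graph$depth >= 1L]
  if (length(cand) == 0L) {
    ontorel_stop("infeasible spec: no concept below the root",
                 "ontorel_infeasible_spec")
  }
  dcount <- vapply(cand, function(id) {
    length(descendant_set(graph, id))
  }, integer(1))
  # the most balanced subtree: descendant count closest to half the
  # non-root concepts, so both the marker pool and its complement stay
  # populated for pair sampling
  target <- (length(graph$ids) - 1L) / 2
  marker <- cand[order(abs(dcount - target), cand)][1]
  if (dcount[marker] < 2L) {
    ontorel_stop("infeasible spec: marker concept has fewer than 2 descendants",
                 "ontorel_infeasible_spec")
  }
  list(path = path, graph = graph, marker = marker)
}

corrupt_surface <- function(s) {
  letters_pool <- strsplit("abcdefghijklmnopqrstuvwxyz", "")[[1]]
  pos <- sample(nchar(s), 1L)
  if (nchar(s) > 3L && stats::runif(1) < 0.5) {
    paste0(substr(s, 1, pos - 1L), substr(s, pos + 1L, nchar(s)))
  } else {
    old <- substr(s, pos, pos)
    new <- sample(setdiff(letters_pool, old), 1L)
    paste0(substr(s, 1, pos - 1L), new, substr(s, pos + 1L, nchar(s)))
  }
}

#' Generate a toy annotated corpus in the DDI XML dialect
#'
#' Each sentence embeds 2-4 entity mentions whose surface strings are
#' ontology labels or synonyms, occasionally corrupted by one character to
#' exercise fuzzy linking. Entities are drawn from the marker concept's
#' subtree with probability `sqrt(positive_rate)` each, so that both
#' members of a pair fall under the marker -- making the pair positive
#' under the common-ancestor rule -- at the target rate. Filler text comes
#' from a label-independent template vocabulary, so surface wording
#' carries no label signal. Sentences are grouped ten per document with
#' ids alternating between drugbank-style and medline-style.
#'
#' @param spec A [synthetic_spec()].
#' @param ontology Result of [gen_ontology()].
#' @param path Output XML path.
#' @return List with `path`, `documents` (as from [read_ddi_xml()]),
#'   `links` (data frame entity_id/concept_id of the true links) and
#'   `positive_fraction` (realized fraction of positive pairs).
#' @export
gen_corpus <- function(spec, ontology, path) {
  set.seed(spec$seed + 1000L)
  graph <- ontology$graph
  marker <- ontology$marker
  dset <- c(marker, descendant_set(graph, marker))
  root <- graph$ids[graph$depth == 0L]
  other <- setdiff(graph$ids, c(dset, root))
  if (length(other) < 2L) {
    ontorel_stop("infeasible spec: marker subtree covers the whole ontology",
                 "ontorel_infeasible_spec")
  }
  # filler words are disjoint from every label and synonym, so surface
  # wording can never leak entity identity into the lexical channels
  fillers <- make_words(spec$vocab_size, min_syl = 2L, max_syl = 3L,
                        exclude = c(unname(graph$label),
                                    unlist(graph$synonyms,
                                           use.names = FALSE)))
  q <- sqrt(spec$positive_rate)
  is_positive <- function(c1, c2) {
    if (spec$label_rule == "common_ancestor") {
      marker %in% common_ancestors(graph, c1, c2)
    } else {
      marker %in% ancestors(graph, c1)
    }
  }
  surface_of <- function(cid) {
    syns <- graph$synonyms[[cid]]
    s <- if (length(syns) > 0L && stats::runif(1) < 0.3) {
      sample_safe(syns, 1L)
    } else graph$label[[cid]]
    if (stats::runif(1) < spec$corruption_rate) s <- corrupt_surface(s)
    s
  }
  documents <- list()
  links <- list()
  n_pos <- 0L
  n_pairs <- 0L
  doc_sent <- 0L
  doc <- NULL
  doc_count <- 0L
  new_doc <- function() {
    doc_count <<- doc_count + 1L
    style <- if (doc_count %% 2L == 1L) "SYN-DrugBank" else "SYN-MedLine"
    list(id = sprintf("%s.d%03d", style, doc_count), sentences = list())
  }
  doc <- new_doc()
  for (si in seq_len(spec$n_sentences)) {
    E <- sample(2:4, 1L, prob = c(0.5, 0.3, 0.2))
    in_marker <- stats::runif(E) < q
    if (sum(in_marker) > length(dset)) {
      in_marker[sample_safe(which(in_marker),
                            sum(in_marker) - length(dset))] <- FALSE
    }
    if (sum(!in_marker) > length(other)) {
      in_marker[sample_safe(which(!in_marker),
                            sum(!in_marker) - length(other))] <- TRUE
    }
    concepts <- character(E)
    concepts[in_marker] <- sample(dset, sum(in_marker))
    concepts[!in_marker] <- sample(other, sum(!in_marker))
    sent_id <- sprintf("%s.s%d", doc$id, length(doc$sentences) + 1L)
    tokens <- sample(fillers, sample(1:2, 1L), replace = TRUE)
    ent_rows <- list()
    for (k in seq_len(E)) {
      surf <- surface_of(concepts[k])
      start <- sum(nchar(tokens)) + length(tokens)  # 0-based offset
      tokens <- c(tokens, surf,
                  sample(fillers, sample(1:3, 1L), replace = TRUE))
      ent_rows[[k]] <- data.frame(
        id = sprintf("%s.e%d", sent_id, k), text = surf,
        char_start = start, char_end = start + nchar(surf) - 1L,
        entity_type = "drug", concept_id = NA_character_,
        stringsAsFactors = FALSE)
    }
    text <- paste(paste(tokens, collapse = " "), ".")
    entities <- do.call(rbind, ent_rows)
    cmb <- utils::combn(seq_len(E), 2L)
    pair_rows <- lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1, j]
      b <- cmb[2, j]
      pos <- is_positive(concepts[a], concepts[b])
      data.frame(id = sprintf("%s.p%d", sent_id, j),
                 e1 = entities$id[a], e2 = entities$id[b],
                 label = if (pos) spec$positive_type else "negative",
                 provenance = "gold", stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, pair_rows)
    n_pos <- n_pos + sum(pairs$label != "negative")
    n_pairs <- n_pairs + nrow(pairs)
    links[[si]] <- data.frame(entity_id = entities$id,
                              concept_id = concepts,
                              stringsAsFactors = FALSE)
    doc$sentences[[length(doc$sentences) + 1L]] <-
      list(id = sent_id, text = text, entities = entities, pairs = pairs)
    if (length(doc$sentences) == 10L || si == spec$n_sentences) {
      doc$source_type <- source_type_from_id(doc$id)
      documents[[length(documents) + 1L]] <- doc
      if (si < spec$n_sentences) doc <- new_doc()
    }
  }
  write_ddi_xml(documents, path)
  list(path = path, documents = documents,
       links = do.call(rbind, links),
       positive_fraction = n_pos / n_pairs)
}

#' Generate random unit word vectors in textual word2vec format
#'
#' One seeded random unit vector per token; vectors carry no semantic
#' signal by construction.
#'
#' @param spec A [synthetic_spec()].
#' @param tokens Character vector of vocabulary tokens.
#' @param path Output path.
#' @return List with `path` and `vectors` (as from [read_word2vec()]).
#' @export
gen_vectors <- function(spec, tokens, path) {
  set.seed(spec$seed + 2000L)
  tokens <- unique(tokens)
  mat <- matrix(stats::rnorm(spec$vector_dim * length(tokens)),
                nrow = spec$vector_dim)
  mat <- sweep(mat, 2, sqrt(colSums(mat^2)), "/")
  colnames(mat) <- tokens
  write_word2vec(mat, path)
  list(path = path, vectors = list(vocab = tokens, vectors = mat))
}

#' Vocabulary of a document list
#'
#' Unique tokens of all sentence texts (via [tokenize()]), plus the given
#' extra tokens (by default the entity mask string).
#'
#' @param documents Document list.
#' @param extra Extra tokens to include (default `"entity"`).
#' @return Character vector.
#' @export
corpus_vocabulary <- function(documents, extra = "entity") {
  toks <- unlist(lapply(documents, function(doc) {
    lapply(doc$sentences, function(s) tokenize(s$text)$token)
  }), use.names = FALSE)
  unique(c(toks, extra))
}

#' Generate a complete synthetic dataset
#'
#' Runs [gen_ontology()], [gen_corpus()] and [gen_vectors()] into a
#' directory and writes a JSON manifest recording the spec, the marker
#' concept and the realized positive fraction.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `spec`, `ontology`, `corpus`, `vectors` and
#'   `manifest` (the manifest path).
#' @export
gen_synthetic_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ontology <- gen_ontology(spec, file.path(dir, "ontology.obo"))
  corpus <- gen_corpus(spec, ontology, file.path(dir, "corpus.xml"))
  vectors <- gen_vectors(spec, corpus_vocabulary(corpus$documents),
                         file.path(dir, "vectors.txt"))
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(spec = unclass(spec), marker = ontology$marker,
         positive_fraction = corpus$positive_fraction,
         n_documents = length(corpus$documents)),
    manifest, auto_unbox = TRUE, digits = NA)
  list(spec = spec, ontology = ontology, corpus = corpus,
       vectors = vectors, manifest = manifest)
}

#' Planted-signal recoverability experiment
#'
#' End-to-end check that the ontology channels, and not lexical leakage,
#' carry the planted label: generates a synthetic ancestry-labeled corpus,
#' trains a model with the requested channels on the first `n_train`
#' sentences and scores detection on the remaining `n_test` sentences.
#' With the ontology channels enabled the planted signal is recoverable;
#' with only the words channel the labels are independent of every input
#' feature by construction.
#'
#' @param seed Seed for generation, initialization and training.
#' @param channels Channel subset for the model (default the two ontology
#'   channels).
#' @param n_train,n_test Sentence counts for the train and test portions
#'   (defaults 500/200).
#' @param dir Working directory for the generated files (default a
#'   tempdir).
#' @param spec_args,config_args Optional overrides passed to
#'   [synthetic_spec()] / [model_config()]. The experiment caps training
#'   at 25 epochs by default; on this separable task the validation loss
#'   plateaus well before that.
#' @return List with `detection_f1`, `classification_f1`, the full
#'   `report`, and the trained `model`.
#' @export
planted_signal_experiment <- function(seed = 1L,
                                      channels = c("concat_ancestors",
                                                   "common_ancestors"),
                                      n_train = 500L, n_test = 200L,
                                      dir = tempfile("planted"),
                                      spec_args = list(),
                                      config_args = list()) {
  spec <- do.call(synthetic_spec,
                  c(list(seed = seed, n_sentences = n_train + n_test),
                    spec_args))
  ds <- gen_synthetic_dataset(spec, dir)
  docs <- ds$corpus$documents
  counts <- vapply(docs, function(d) length(d$sentences), integer(1))
  split_at <- which(cumsum(counts) >= n_train)[1]
  train_docs <- docs[seq_len(split_at)]
  test_docs <- docs[(split_at + 1L):length(docs)]
  graph <- ds$ontology$graph
  train_inst <- build_instances(train_docs, graph = graph)
  test_inst <- build_instances(test_docs, graph = graph)
  wv <- if ("words" %in% channels) {
    read_word2vec(ds$vectors$path)
  } else NULL
  if (is.null(config_args$max_epochs)) config_args$max_epochs <- 25L
  config <- do.call(model_config,
                    c(list(channels = channels, seed = seed,
                           word_dim = spec$vector_dim),
                      config_args))
  model <- build_model(config, word_vectors = wv,
                       onto_vocab = ontology_vocabulary(graph),
                       instances = train_inst)
  model <- train_model(model, train_inst)
  pred <- predict(model, test_inst)
  gold <- instance_gold(test_inst)
  report <- score_pairs(gold, pred)
  list(detection_f1 = report$detection$f1,
       classification_f1 = report$classification$f1,
       report = report, model = model, dataset = ds)
}
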