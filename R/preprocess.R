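# Sentence -> instance preprocessing: candidate-pair generation, dependency
# parsing (pluggable), shortest-dependency-path extraction, entity masking,
# supersense tagging (pluggable), ontology-sequence attachment and
# negative-instance filtering.

#' Tokenize a sentence with character spans
#'
#' Splits on whitespace, keeping runs of word characters (letters, digits,
#' apostrophes, hyphens, underscores) as tokens and every other
#' non-whitespace character as a single-character token.
#'
#' @param text Sentence string.
#' @return Data frame with `token`, `char_start`, `char_end` (0-based,
#'   inclusive).
#' @export
tokenize <- function(text) {
  m <- gregexpr("[[:alnum:]_'-]+|[^[:alnum:][:space:]]", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(0), char_start = integer(0),
                      char_end = integer(0), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(token = regmatches(text, list(m))[[1]],
             char_start = as.integer(m) - 1L,
             char_end = as.integer(m) + len - 2L,
             stringsAsFactors = FALSE)
}

new_dependency_parse <- function(tokens, char_start, char_end, head,
                                 label) {
  n <- length(tokens)
  stopifnot(length(head) == n, length(label) == n,
            all(head >= 1L), all(head <= n))
  roots <- which(head == seq_len(n))
  if (n > 0L && length(roots) != 1L) {
    ontorel_stop("dependency parse must have exactly one root",
                 "ontorel_bad_parse")
  }
  # every token must reach the root (head graph is a tree)
  for (i in seq_len(n)) {
    seen <- integer(0)
    v <- i
    while (head[v] != v) {
      if (v %in% seen) {
        ontorel_stop("dependency heads contain a cycle",
                     "ontorel_bad_parse")
      }
      seen <- c(seen, v)
      v <- head[v]
    }
  }
  structure(list(tokens = tokens, char_start = char_start,
                 char_end = char_end, head = head, label = label),
            class = "dependency_parse")
}

#' Deterministic chain dependency parser
#'
#' A fixture-grade parser usable anywhere a parser function is expected:
#' the first token is the root and every other token's head is its
#' predecessor. Any function mapping a sentence string to a
#' `dependency_parse` (tokens with spans, head indices forming a tree, one
#' root whose head is itself, one label per token) can be plugged in in its
#' place, e.g. an adapter over an external statistical parser.
#'
#' @param text Sentence string.
#' @return A `dependency_parse` object.
#' @export
chain_parser <- function(text) {
  tk <- tokenize(text)
  n <- nrow(tk)
  head <- if (n == 0L) integer(0) else c(1L, seq_len(n - 1L))
  label <- if (n == 0L) character(0) else c("root", rep("dep", n - 1L))
  new_dependency_parse(tk$token, tk$char_start, tk$char_end, head, label)
}

#' Generate all candidate entity pairs of a sentence
#'
#' Produces exactly `choose(E, 2)` unordered pairs for a sentence with E
#' entities, with `e1` the mention occurring earlier in the text. Labels
#' are joined from the sentence's gold pairs (matching regardless of
#' order); pairs without a gold annotation are labeled `negative` with
#' provenance `generated`.
#'
#' @param sentence A sentence list (see [read_ddi_xml()]).
#' @return Data frame with `e1`, `e2`, `label`, `provenance`.
#' @export
generate_candidate_pairs <- function(sentence) {
  ent <- sentence$entities
  out <- data.frame(e1 = character(0), e2 = character(0),
                    label = character(0), provenance = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(ent) < 2L) return(out)
  ord <- order(ent$char_start, ent$char_end, ent$id)
  ids <- ent$id[ord]
  cmb <- utils::combn(ids, 2L)
  gold_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  gp <- sentence$pairs
  gold <- if (is.null(gp) || nrow(gp) == 0L) character(0) else {
    setNames(gp$label, gold_key(gp$e1, gp$e2))
  }
  key <- gold_key(cmb[1, ], cmb[2, ])
  label <- unname(gold[key])
  hit <- !is.na(label)
  data.frame(e1 = cmb[1, ], e2 = cmb[2, ],
             label = ifelse(hit, label, "negative"),
             provenance = ifelse(hit, "gold", "generated"),
             stringsAsFactors = FALSE)
}

# token whose span contains the mention's last character (head-final)
align_token <- function(parse, char_start, char_end) {
  i <- which(parse$char_start <= char_end & parse$char_end >= char_end)
  if (length(i) == 0L) NA_integer_ else i[1]
}

# all tokens overlapping any mention span (for masking)
entity_token_indices <- function(parse, entities) {
  idx <- integer(0)
  for (i in seq_len(nrow(entities))) {
    idx <- c(idx, which(parse$char_start <= entities$char_end[i] &
                        parse$char_end >= entities$char_start[i]))
  }
  sort(unique(idx))
}

path_to_root <- function(parse, i) {
  p <- i
  while (parse$head[i] != i) {
    i <- parse$head[i]
    p <- c(p, i)
  }
  p
}

#' Shortest dependency path between two entity mentions
#'
#' Returns the unique tree path between the head tokens of the two
#' mentions (the token containing each mention's last character), ordered
#' from the `e1` side to the `e2` side, inclusive of both endpoints.
#'
#' @param parse A `dependency_parse`.
#' @param e1,e2 One-row slices of a sentence's `entities` data frame (or
#'   any list with `char_start`/`char_end`).
#' @return Integer vector of token indices.
#' @export
shortest_dependency_path <- function(parse, e1, e2) {
  t1 <- align_token(parse, e1$char_start, e1$char_end)
  t2 <- align_token(parse, e2$char_start, e2$char_end)
  if (is.na(t1) || is.na(t2)) {
    ontorel_stop("entity offsets align with no token",
                 "ontorel_unmappable_entity")
  }
  p1 <- path_to_root(parse, t1)
  p2 <- path_to_root(parse, t2)
  i <- match(TRUE, p1 %in% p2)  # first common node = lowest common ancestor
  lca <- p1[i]
  j <- match(lca, p2)
  c(p1[seq_len(i)], rev(p2[seq_len(j - 1L)]))
}

#' Mask entity tokens on a dependency path
#'
#' Replaces every token belonging to any entity mention on the path --
#' candidate entities and bystander mentions alike -- with one shared
#' generic mask token, leaving length and all other tokens unchanged.
#'
#' @param sdp_tokens Character vector of path tokens.
#' @param entity_positions Integer positions (into `sdp_tokens`) of tokens
#'   belonging to entity mentions.
#' @param mask_token The generic replacement string (default `"entity"`).
#' @return Character vector of the same length.
#' @export
mask_entities <- function(sdp_tokens, entity_positions,
                          mask_token = "entity") {
  sdp_tokens[entity_positions] <- mask_token
  sdp_tokens
}

#' The supersense class inventory
#'
#' The 41 coarse lexical-semantic categories used by the WordNet channel:
#' 26 noun supersenses and 15 verb supersenses. The null class (for masked
#' or untaggable tokens) is `"0"` and is not part of the inventory.
#'
#' @return Character vector of 41 class names.
#' @export
supersense_inventory <- function() {
  c(paste0("noun.", c("Tops", "act", "animal", "artifact", "attribute",
                      "body", "cognition", "communication", "event",
                      "feeling", "food", "group", "location", "motive",
                      "object", "person", "phenomenon", "plant",
                      "possession", "process", "quantity", "relation",
                      "shape", "state", "substance", "time")),
    paste0("verb.", c("body", "change", "cognition", "communication",
                      "competition", "consumption", "contact", "creation",
                      "emotion", "motion", "perception", "possession",
                      "social", "stative", "weather")))
}

SUPERSENSE_NULL <- "0"

#' Build a lexicon-based supersense tagger
#'
#' Returns a tagger function (character vector of tokens in, one class per
#' token out) driven by a fixed word-to-class table. Unknown tokens get the
#' null class. Any function with the same signature whose outputs come
#' from [supersense_inventory()] plus the null class can serve as a
#' tagger, e.g. an adapter over an external WordNet supersense tagger.
#'
#' @param lexicon Named character vector: lowercased token -> class from
#'   [supersense_inventory()].
#' @return A function `tokens -> classes`.
#' @export
make_lexicon_tagger <- function(lexicon) {
  stopifnot(all(lexicon %in% supersense_inventory()))
  names(lexicon) <- tolower(names(lexicon))
  function(tokens) {
    cls <- unname(lexicon[tolower(tokens)])
    ifelse(is.na(cls), SUPERSENSE_NULL, cls)
  }
}

#' Null supersense tagger
#'
#' Tags every token with the null class.
#'
#' @param tokens Character vector.
#' @return Character vector of `"0"` of the same length.
#' @export
null_tagger <- function(tokens) {
  rep(SUPERSENSE_NULL, length(tokens))
}

# lowercased surface form of a token's syntactic head; NA for the root
governor_lemma <- function(parse, token_idx) {
  h <- parse$head[token_idx]
  if (h == token_idx) NA_character_ else tolower(parse$tokens[h])
}

#' Filter candidate pairs by the three negative rules
#'
#' A pair is auto-negative when any rule fires: (1) the two mentions have
#' the same text regardless of case; (2) the only text between them is
#' punctuation and/or whitespace (lists, enumerations, abbreviations); (3)
#' both entities' syntactic governors are on the anti-positive list. The
#' two parts partition the input: nothing is discarded silently.
#'
#' @param pairs Data frame from [generate_candidate_pairs()].
#' @param sentence The sentence the pairs came from.
#' @param parse A `dependency_parse` of the sentence (needed for rule 3;
#'   may be `NULL` when `anti_positive` is empty).
#' @param anti_positive Character vector of anti-positive governor lemmas.
#' @return List with `kept` and `auto_negative` data frames; auto-negative
#'   rows have provenance `auto_negative` (their gold label is preserved so
#'   that scoring can count a filtered-out true interaction as a miss).
#' @export
filter_negatives <- function(pairs, sentence, parse = NULL,
                             anti_positive = character(0)) {
  ent <- sentence$entities
  rownames(ent) <- ent$id
  fires <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- ent[pairs$e1[i], ]
    b <- ent[pairs$e2[i], ]
    # rule 1: same text regardless of case
    if (tolower(a$text) == tolower(b$text)) {
      fires[i] <- TRUE
      next
    }
    # rule 2: only punctuation/whitespace between the mentions
    lo <- min(a$char_end, b$char_end)
    hi <- max(a$char_start, b$char_start)
    between <- if (hi > lo + 1L) {
      substr(sentence$text, lo + 2L, hi)  # 0-based inclusive -> 1-based
    } else ""
    if (grepl("^[[:punct:][:space:]]*$", between)) {
      fires[i] <- TRUE
      next
    }
    # rule 3: both entities have anti-positive governors
    if (length(anti_positive) > 0L && !is.null(parse)) {
      ga <- governor_lemma(parse, align_token(parse, a$char_start,
                                              a$char_end))
      gb <- governor_lemma(parse, align_token(parse, b$char_start,
                                              b$char_end))
      if (!is.na(ga) && !is.na(gb) &&
          ga %in% anti_positive && gb %in% anti_positive) {
        fires[i] <- TRUE
      }
    }
  }
  auto <- pairs[fires, , drop = FALSE]
  if (nrow(auto) > 0L) auto$provenance <- "auto_negative"
  list(kept = pairs[!fires, , drop = FALSE], auto_negative = auto)
}

#' Learn the anti-positive governor list from a training corpus
#'
#' A governor lemma is anti-positive when it governs entity mentions at
#' least `min_count` times across the training documents and never governs
#' an entity that participates in a positive gold pair.
#'
#' @param documents Training documents with gold pairs.
#' @param parser Parser function (default [chain_parser()]).
#' @param min_count Minimum occurrence count (default 3).
#' @return Character vector of governor lemmas, sorted.
#' @export
build_anti_positive_list <- function(documents, parser = chain_parser,
                                     min_count = 3L) {
  counts <- new.env(parent = emptyenv())
  tainted <- new.env(parent = emptyenv())
  for (doc in documents) {
    for (s in doc$sentences) {
      if (nrow(s$entities) == 0L) next
      parse <- parser(s$text)
      pos_ids <- unique(c(s$pairs$e1[s$pairs$label != "negative"],
                          s$pairs$e2[s$pairs$label != "negative"]))
      for (i in seq_len(nrow(s$entities))) {
        ti <- align_token(parse, s$entities$char_start[i],
                          s$entities$char_end[i])
        if (is.na(ti)) next
        g <- governor_lemma(parse, ti)
        if (is.na(g)) next
        assign(g, mget(g, counts, ifnotfound = 0L)[[1]] + 1L, counts)
        if (s$entities$id[i] %in% pos_ids) assign(g, TRUE, tainted)
      }
    }
  }
  lemmas <- ls(counts)
  keep <- vapply(lemmas, function(g) {
    get(g, counts) >= min_count && !exists(g, tainted, inherits = FALSE)
  }, logical(1))
  sort(lemmas[keep])
}

#' Attach ontology ancestor sequences to a linked concept pair
#'
#' @param graph An `ontology_graph`, or `NULL`.
#' @param c1,c2 Linked concept ids (either may be `NA`).
#' @return List with `concat` and `common` character vectors; both empty
#'   when either concept is unlinked or the graph is absent.
#' @export
attach_ontology_sequences <- function(graph, c1, c2) {
  if (is.null(graph) || is.na(c1) || is.na(c2)) {
    return(list(concat = character(0), common = character(0)))
  }
  list(concat = concat_ancestors(graph, c1, c2),
       common = common_ancestors(graph, c1, c2))
}

#' Build classifiable instances from annotated documents
#'
#' Runs the full preprocessing pipeline: candidate-pair generation,
#' negative filtering, dependency parsing, shortest-dependency-path
#' extraction, entity masking, supersense tagging (masked positions get
#' the null class), fuzzy entity linking and ontology-sequence attachment.
#' Pairs whose entities align with no token are dropped with a warning;
#' auto-negative pairs are kept as feature-less instances (they bypass the
#' network at prediction time and are excluded from training).
#'
#' @param documents List of documents (see [read_ddi_xml()]).
#' @param graph An `ontology_graph` or `NULL` (ontology channels empty).
#' @param parser Parser function (default [chain_parser()]).
#' @param tagger Supersense tagger function (default [null_tagger()]).
#' @param link_threshold Fuzzy-linking acceptance threshold.
#' @param mask_token Generic entity mask string.
#' @param filter Apply the negative-filtering rules (default `TRUE`).
#' @param anti_positive Anti-positive governor lemmas for rule 3.
#' @return List of instances; each instance is a list with `doc_id`,
#'   `sentence_id`, `e1`, `e2`, `label`, `provenance`, `sdp_tokens`,
#'   `wordnet`, `concat_seq`, `common_seq`.
#' @export
build_instances <- function(documents, graph = NULL, parser = chain_parser,
                            tagger = null_tagger, link_threshold = 0.7,
                            mask_token = "entity", filter = TRUE,
                            anti_positive = character(0)) {
  link_cache <- new.env(parent = emptyenv())
  link1 <- function(mention, preset) {
    if (!is.na(preset)) return(preset)
    if (is.null(graph)) return(NA_character_)
    key <- paste0("m:", mention)
    if (!exists(key, link_cache, inherits = FALSE)) {
      m <- link_entity(graph, mention, link_threshold)
      assign(key, if (is.null(m)) NA_character_ else m$concept_id,
             link_cache)
    }
    get(key, link_cache)
  }
  out <- list()
  dropped <- 0L
  for (doc in documents) {
    for (s in doc$sentences) {
      pairs <- generate_candidate_pairs(s)
      if (nrow(pairs) == 0L) next
      parse <- parser(s$text)
      parts <- if (filter) {
        filter_negatives(pairs, s, parse, anti_positive)
      } else list(kept = pairs, auto_negative = pairs[0, , drop = FALSE])
      ent <- s$entities
      rownames(ent) <- ent$id
      ent_tokens <- entity_token_indices(parse, ent)
      cids <- setNames(vapply(seq_len(nrow(ent)), function(i) {
        link1(ent$text[i], ent$concept_id[i])
      }, character(1)), ent$id)
      mk <- function(row, provenance, with_features) {
        inst <- list(doc_id = doc$id, sentence_id = s$id,
                     e1 = row$e1, e2 = row$e2, label = row$label,
                     provenance = provenance,
                     sdp_tokens = character(0), wordnet = character(0),
                     concat_seq = character(0), common_seq = character(0))
        if (!with_features) return(inst)
        sdp <- shortest_dependency_path(parse, ent[row$e1, ],
                                        ent[row$e2, ])
        masked_pos <- which(sdp %in% ent_tokens)
        inst$sdp_tokens <- mask_entities(parse$tokens[sdp], masked_pos,
                                         mask_token)
        wn <- tagger(parse$tokens[sdp])
        wn[masked_pos] <- SUPERSENSE_NULL
        inst$wordnet <- wn
        seqs <- attach_ontology_sequences(graph, cids[[row$e1]],
                                          cids[[row$e2]])
        inst$concat_seq <- seqs$concat
        inst$common_seq <- seqs$common
        inst
      }
      for (i in seq_len(nrow(parts$kept))) {
        inst <- tryCatch(mk(parts$kept[i, ], parts$kept$provenance[i],
                            TRUE),
                         ontorel_unmappable_entity = function(e) NULL)
        if (is.null(inst)) {
          dropped <- dropped + 1L
        } else {
          out[[length(out) + 1L]] <- inst
        }
      }
      for (i in seq_len(nrow(parts$auto_negative))) {
        out[[length(out) + 1L]] <-
          mk(parts$auto_negative[i, ], "auto_negative", FALSE)
      }
    }
  }
  if (dropped > 0L) {
    warning(sprintf("%d pair(s) dropped: entity aligns with no token",
                    dropped))
  }
  out
}

#' Gold-label data frame for a set of instances
#'
#' Convenience accessor: one row per instance with its identifying key and
#' gold label, suitable as the `gold` argument of [score_pairs()].
#'
#' @param instances List of instances from [build_instances()].
#' @return Data frame with `doc_id`, `sentence_id`, `e1`, `e2`, `label`.
#' @export
instance_gold <- function(instances) {
  do.call(rbind, lapply(instances, function(x) {
    data.frame(doc_id = x$doc_id, sentence_id = x$sentence_id,
               e1 = x$e1, e2 = x$e2, label = x$label,
               stringsAsFactors = FALSE)
  }))
}
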