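# Corpus reading/writing in the SemEval-2013 Task 9 DDI XML dialect,
# prediction TSV emission, and exact-match gene annotation.
#
# Character offsets follow the corpus convention: 0-based, inclusive on
# both ends ("0-5" covers the first six characters). Discontinuous
# charOffset values ("a-b;c-d") are reduced to their first span.

DDI_LABELS <- c("negative", "mechanism", "effect", "advice", "int")

source_type_from_id <- function(doc_id) {
  if (grepl("drugbank", doc_id, ignore.case = TRUE)) return("drugbank")
  if (grepl("medline", doc_id, ignore.case = TRUE)) return("medline")
  "other"
}

empty_entities <- function() {
  data.frame(id = character(0), text = character(0),
             char_start = integer(0), char_end = integer(0),
             entity_type = character(0), concept_id = character(0),
             stringsAsFactors = FALSE)
}

empty_pairs <- function() {
  data.frame(id = character(0), e1 = character(0), e2 = character(0),
             label = character(0), provenance = character(0),
             stringsAsFactors = FALSE)
}

parse_char_offset <- function(s) {
  first <- strsplit(s, ";", fixed = TRUE)[[1]][1]
  parts <- as.integer(strsplit(first, "-", fixed = TRUE)[[1]])
  c(start = parts[1], end = parts[2])
}

read_sentence_node <- function(node) {
  text <- xml2::xml_attr(node, "text")
  ents <- xml2::xml_find_all(node, "./entity")
  entities <- if (length(ents) == 0L) empty_entities() else {
    off <- t(vapply(xml2::xml_attr(ents, "charOffset"), parse_char_offset,
                    integer(2)))
    data.frame(id = xml2::xml_attr(ents, "id"),
               text = xml2::xml_attr(ents, "text"),
               char_start = off[, "start"], char_end = off[, "end"],
               entity_type = xml2::xml_attr(ents, "type"),
               concept_id = xml2::xml_attr(ents, "concept"),
               stringsAsFactors = FALSE)
  }
  if (nrow(entities) > 0L) {
    n <- nchar(text)
    if (any(entities$char_start < 0 | entities$char_end >= n |
            entities$char_start > entities$char_end)) {
      ontorel_stop(sprintf("entity offsets out of bounds in sentence %s",
                           xml2::xml_attr(node, "id")),
                   "ontorel_parse_error")
    }
  }
  prs <- xml2::xml_find_all(node, "./pair")
  pairs <- if (length(prs) == 0L) empty_pairs() else {
    type <- xml2::xml_attr(prs, "type")
    data.frame(id = xml2::xml_attr(prs, "id"),
               e1 = xml2::xml_attr(prs, "e1"),
               e2 = xml2::xml_attr(prs, "e2"),
               label = ifelse(is.na(type), "negative", type),
               provenance = "gold", stringsAsFactors = FALSE)
  }
  dangling <- setdiff(c(pairs$e1, pairs$e2), entities$id)
  if (length(dangling) > 0L) {
    ontorel_stop(sprintf("pair references unknown entity id(s): %s",
                         paste(dangling, collapse = ", ")),
                 "ontorel_parse_error")
  }
  list(id = xml2::xml_attr(node, "id"), text = text,
       entities = entities, pairs = pairs)
}

#' Read a corpus in the DDI XML dialect
#'
#' Accepts either a single `<document>` root or a wrapper element holding
#' several documents. A pair without a `type` attribute is labeled
#' `negative`; discontinuous `charOffset` values are reduced to their first
#' span. The optional `concept` attribute on entities is read into
#' `concept_id`.
#'
#' @param path Path to the XML file.
#' @return A list of documents; each document is a list with `id`,
#'   `source_type` (`drugbank`, `medline` or `other`, inferred from the
#'   document id) and `sentences`, each sentence a list with `id`, `text`,
#'   an `entities` data frame and a gold `pairs` data frame.
#' @export
read_ddi_xml <- function(path) {
  root <- xml2::read_xml(path)
  doc_nodes <- if (xml2::xml_name(root) == "document") list(root) else {
    xml2::xml_find_all(root, "./document")
  }
  lapply(doc_nodes, function(dn) {
    id <- xml2::xml_attr(dn, "id")
    sentences <- lapply(xml2::xml_find_all(dn, "./sentence"),
                        read_sentence_node)
    sids <- vapply(sentences, `[[`, character(1), "id")
    if (anyDuplicated(sids)) {
      ontorel_stop(sprintf("duplicate sentence ids in document %s", id),
                   "ontorel_parse_error")
    }
    list(id = id, source_type = source_type_from_id(id),
         sentences = sentences)
  })
}

#' Write documents back out in the DDI XML dialect
#'
#' Inverse of [read_ddi_xml()]: reading the written file recovers the same
#' entities (offsets, types) and the same gold pair multiset with labels.
#'
#' @param documents List of documents as returned by [read_ddi_xml()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ddi_xml <- function(documents, path) {
  root <- xml2::xml_new_root("corpus")
  for (doc in documents) {
    dn <- xml2::xml_add_child(root, "document", id = doc$id)
    for (s in doc$sentences) {
      sn <- xml2::xml_add_child(dn, "sentence", id = s$id, text = s$text)
      ent <- s$entities
      for (i in seq_len(nrow(ent))) {
        node <- xml2::xml_add_child(
          sn, "entity", id = ent$id[i], text = ent$text[i],
          type = ent$entity_type[i],
          charOffset = sprintf("%d-%d", ent$char_start[i], ent$char_end[i]))
        if (!is.na(ent$concept_id[i])) {
          xml2::xml_set_attr(node, "concept", ent$concept_id[i])
        }
      }
      pr <- s$pairs
      for (i in seq_len(nrow(pr))) {
        node <- xml2::xml_add_child(
          sn, "pair", id = pr$id[i], e1 = pr$e1[i], e2 = pr$e2[i],
          ddi = if (pr$label[i] == "negative") "false" else "true")
        if (pr$label[i] != "negative") {
          xml2::xml_set_attr(node, "type", pr$label[i])
        }
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Write predicted pairs as a TSV prediction file
#'
#' One row per pair: document id, sentence id, e1, e2, ddi flag (0/1) and
#' interaction type (empty when negative). Pairs auto-negatived by the
#' filtering rules are emitted with flag 0.
#'
#' @param pairs Data frame with columns `doc_id`, `sentence_id`, `e1`,
#'   `e2`, `label`, `provenance`; provenance must be `predicted` or
#'   `auto_negative` for every row.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pairs, path) {
  if (nrow(pairs) > 0L &&
      !all(pairs$provenance %in% c("predicted", "auto_negative"))) {
    ontorel_stop("write_predictions expects predicted or auto_negative pairs",
                 "ontorel_bad_input")
  }
  flag <- as.integer(pairs$label != "negative" &
                     pairs$provenance != "auto_negative")
  type <- ifelse(flag == 1L, pairs$label, "")
  utils::write.table(
    data.frame(pairs$doc_id, pairs$sentence_id, pairs$e1, pairs$e2,
               flag, type, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a prediction TSV written by [write_predictions()]
#'
#' @param path TSV path.
#' @return Data frame with `doc_id`, `sentence_id`, `e1`, `e2`, `label`,
#'   `provenance` (always `"predicted"`).
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = c("character", "character",
                                         "character", "character",
                                         "integer", "character"),
                          col.names = c("doc_id", "sentence_id", "e1", "e2",
                                        "flag", "type"))
  data.frame(doc_id = df$doc_id, sentence_id = df$sentence_id,
             e1 = df$e1, e2 = df$e2,
             label = ifelse(df$flag == 1L, df$type, "negative"),
             provenance = "predicted", stringsAsFactors = FALSE)
}

#' Annotate gene mentions by exact string matching and pair them with
#' phenotypes
#'
#' Adds gene entity mentions wherever a lexicon symbol occurs as an exact,
#' case-sensitive, word-boundary match in a sentence, then creates one gold
#' pair per phenotype-gene co-occurrence, labeled `positive_label` when the
#' (phenotype concept, gene symbol) link is present in `relations` and
#' `negative` otherwise. Phenotype mentions are the pre-existing entities
#' that carry a concept id.
#'
#' @param documents List of documents (see [read_ddi_xml()]); phenotype
#'   entities must already carry `concept_id`.
#' @param lexicon Character vector of gene symbols.
#' @param relations Named list: phenotype concept id -> character vector of
#'   associated gene symbols.
#' @param positive_label Label assigned to linked pairs (default `"int"`).
#' @return The documents with gene mentions and gold pairs added.
#' @export
annotate_genes_by_exact_match <- function(documents, lexicon, relations,
                                          positive_label = "int") {
  stopifnot(positive_label %in% DDI_LABELS)
  lapply(documents, function(doc) {
    doc$sentences <- lapply(doc$sentences, function(s) {
      hits <- list()
      for (sym in lexicon) {
        # hyphens are word-internal (so "NF2-related" does not match NF2),
        # matching the tokenizer's notion of a token
        pat <- paste0("(?<![A-Za-z0-9_-])",
                      gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", sym),
                      "(?![A-Za-z0-9_-])")
        m <- gregexpr(pat, s$text, perl = TRUE)[[1]]
        if (m[1] == -1L) next
        for (k in seq_along(m)) {
          hits[[length(hits) + 1L]] <- data.frame(
            text = sym, char_start = m[k] - 1L,
            char_end = m[k] - 1L + attr(m, "match.length")[k] - 1L,
            stringsAsFactors = FALSE)
        }
      }
      if (length(hits) == 0L) return(s)
      genes <- do.call(rbind, hits)
      genes$id <- sprintf("%s.g%d", s$id, seq_len(nrow(genes)))
      genes$entity_type <- "gene"
      genes$concept_id <- NA_character_
      s$entities <- rbind(s$entities,
                          genes[, names(s$entities), drop = FALSE])
      phen <- s$entities[!is.na(s$entities$concept_id) &
                         s$entities$entity_type != "gene", , drop = FALSE]
      k <- nrow(s$pairs)
      for (i in seq_len(nrow(phen))) {
        linked <- relations[[phen$concept_id[i]]]
        for (j in seq_len(nrow(genes))) {
          k <- k + 1L
          lab <- if (!is.null(linked) && genes$text[j] %in% linked) {
            positive_label
          } else "negative"
          s$pairs <- rbind(s$pairs, data.frame(
            id = sprintf("%s.p%d", s$id, k), e1 = phen$id[i],
            e2 = genes$id[j], label = lab, provenance = "gold",
            stringsAsFactors = FALSE))
        }
      }
      s
    })
    doc
  })
}
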