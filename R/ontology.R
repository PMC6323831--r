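# Ontology graphs: OBO loading, ancestor sequences, fuzzy entity linking.
#
# An ontology is treated as a DAG over concepts where only subsumption
# ("is-a") edges are kept. Ancestry is the transitive closure of is-a;
# ancestor sequences are ordered most-general-first (by longest-path depth
# from a root, ties broken lexicographically by concept id) with the concept
# itself in the final position.

ontorel_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ontorel_error")))
}

check_concept <- function(graph, concept_id) {
  if (length(concept_id) != 1L || is.na(concept_id) ||
      !concept_id %in% graph$ids) {
    ontorel_stop(sprintf("unknown concept id: %s", concept_id),
                 "ontorel_unknown_concept")
  }
  if (isTRUE(graph$obsolete[[concept_id]])) {
    ontorel_stop(sprintf("concept is obsolete: %s", concept_id),
                 "ontorel_unknown_concept")
  }
  invisible(concept_id)
}

#' Load an OBO ontology as a directed acyclic graph
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 file, keeping the id, preferred
#' name, synonyms and `is_a` parents of every term. Only subsumption edges
#' are stored; `relationship:` lines (part-of and the like) are dropped.
#' Obsolete terms are retained for bookkeeping but excluded from the concept
#' set, from edges, from ancestor sequences and from entity linking.
#' Acyclicity of the is-a relation is verified at load time.
#'
#' @param path Path to an OBO file.
#' @return An object of class `ontology_graph` with elements `ids`
#'   (non-obsolete concept ids), `label`, `synonyms`, `obsolete`, `parents`
#'   (named list: child id -> character vector of parent ids) and `depth`
#'   (longest is-a path from any root; roots have depth 0).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: X:1", "name: root",
#'              "[Term]", "id: X:2", "name: leaf", "is_a: X:1"), obo)
#' g <- load_obo(obo)
#' ancestors(g, "X:2")
#' @export
load_obo <- function(path) {
  if (!file.exists(path)) {
    ontorel_stop(sprintf("no such file: %s", path), "ontorel_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)

  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id) || !nzchar(cur$id)) {
      ontorel_stop("malformed [Term] stanza: missing id", "ontorel_parse_error")
    }
    if (cur$id %in% names(terms)) {
      ontorel_stop(sprintf("duplicate term id: %s", cur$id),
                   "ontorel_parse_error")
    }
    terms[[cur$id]] <<- cur
  }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      flush()
      cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) {
        cur <- list(id = NULL, name = NA_character_,
                    synonyms = character(0), parents = character(0),
                    obsolete = FALSE)
      }
      next
    }
    if (!in_term || !nzchar(ln)) next
    m <- regexec("^([A-Za-z_]+):\\s*(.*)$", ln)
    hit <- regmatches(ln, m)[[1]]
    if (length(hit) != 3L) next
    tag <- hit[2]
    val <- hit[3]
    if (tag == "id") {
      cur$id <- trimws(val)
    } else if (tag == "name") {
      cur$name <- trimws(val)
    } else if (tag == "is_a") {
      target <- trimws(sub("!.*$", "", val))
      target <- strsplit(target, "\\s+")[[1]][1]
      cur$parents <- c(cur$parents, target)
    } else if (tag == "synonym") {
      syn <- regmatches(val, regexec('"([^"]*)"', val))[[1]]
      if (length(syn) == 2L) cur$synonyms <- c(cur$synonyms, syn[2])
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(trimws(val), "true")
    }
    # relationship: and all other tags are intentionally ignored
  }
  flush()
  if (length(terms) == 0L) {
    ontorel_stop("no [Term] stanzas found", "ontorel_parse_error")
  }

  all_ids <- names(terms)
  obsolete <- vapply(terms, function(t) isTRUE(t$obsolete), logical(1))
  live <- all_ids[!obsolete]

  parents <- lapply(terms[live], function(t) {
    p <- unique(t$parents)
    bad <- setdiff(p, all_ids)
    if (length(bad) > 0L) {
      ontorel_stop(sprintf("is_a target not defined in file: %s",
                           paste(bad, collapse = ", ")),
                   "ontorel_parse_error")
    }
    p[!obsolete[p]]  # edges into obsolete terms are dropped
  })
  names(parents) <- live

  g <- structure(list(
    ids = sort(live),
    label = vapply(terms[live], `[[`, character(1), "name")[order(live)],
    synonyms = lapply(terms[live], `[[`, "synonyms")[order(live)],
    obsolete = obsolete,
    parents = parents[order(live)]
  ), class = "ontology_graph")
  names(g$label) <- g$ids
  names(g$synonyms) <- g$ids

  verify_acyclic(g)
  g$depth <- compute_depths(g)
  g
}

# edge list child -> parent as a two-column matrix
edge_matrix <- function(graph) {
  child <- rep(names(graph$parents),
               lengths(graph$parents))
  parent <- unlist(graph$parents, use.names = FALSE)
  cbind(child = child, parent = parent)
}

verify_acyclic <- function(graph) {
  em <- edge_matrix(graph)
  if (nrow(em) == 0L) return(invisible(TRUE))
  ig <- igraph::graph_from_edgelist(em, directed = TRUE)
  if (igraph::is_dag(ig)) return(invisible(TRUE))
  ontorel_stop(sprintf("is-a relation contains a cycle, e.g.: %s",
                       paste(find_cycle(graph), collapse = " -> ")),
               "ontorel_cycle_error")
}

# DFS along parent edges until a node repeats; returns one cycle path
find_cycle <- function(graph) {
  color <- new.env(parent = emptyenv())
  path <- character(0)
  result <- NULL
  visit <- function(v) {
    if (!is.null(result)) return()
    st <- mget(v, envir = color, ifnotfound = "white")[[1]]
    if (st == "gray") {
      i <- match(v, path)
      result <<- c(path[i:length(path)], v)
      return()
    }
    if (st == "black") return()
    assign(v, "gray", envir = color)
    path <<- c(path, v)
    for (p in graph$parents[[v]]) visit(p)
    path <<- path[-length(path)]
    assign(v, "black", envir = color)
  }
  for (v in graph$ids) {
    visit(v)
    if (!is.null(result)) break
  }
  result
}

# longest-path depth from any root, DP over a topological order
compute_depths <- function(graph) {
  depth <- setNames(rep(0L, length(graph$ids)), graph$ids)
  em <- edge_matrix(graph)
  if (nrow(em) == 0L) return(depth)
  ig <- igraph::graph_from_edgelist(em[, c("parent", "child"),
                                       drop = FALSE],
                                    directed = TRUE)
  ord <- igraph::V(ig)$name[igraph::topo_sort(ig, mode = "out")]
  for (v in ord) {
    ps <- graph$parents[[v]]
    if (length(ps) > 0L) depth[[v]] <- max(depth[ps]) + 1L
  }
  depth
}

proper_ancestors <- function(graph, concept_id) {
  seen <- character(0)
  frontier <- graph$parents[[concept_id]]
  while (length(frontier) > 0L) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(graph$parents[frontier], use.names = FALSE))
  }
  seen
}

sort_general_first <- function(graph, ids) {
  ids[order(graph$depth[ids], ids)]
}

#' Ancestor sequence of a concept
#'
#' Returns the ancestors of `concept_id` under the transitive closure of
#' is-a, ordered most-general-first (ascending longest-path depth, ties by
#' id), with the concept itself appended as the final element.
#'
#' @param graph An `ontology_graph`.
#' @param concept_id A concept id present in the graph.
#' @return Character vector of concept ids ending in `concept_id`.
#' @export
ancestors <- function(graph, concept_id) {
  check_concept(graph, concept_id)
  c(sort_general_first(graph, proper_ancestors(graph, concept_id)),
    concept_id)
}

#' Common-ancestor sequence of two concepts
#'
#' Intersection of the two ancestor sets (proper ancestors; a concept itself
#' is included only when it subsumes the other or the two are equal),
#' ordered most-general-first. Symmetric in its arguments.
#'
#' @inheritParams ancestors
#' @param c1,c2 Concept ids present in the graph.
#' @return Character vector of concept ids (possibly empty).
#' @export
common_ancestors <- function(graph, c1, c2) {
  check_concept(graph, c1)
  check_concept(graph, c2)
  s1 <- c(proper_ancestors(graph, c1), c1)
  s2 <- c(proper_ancestors(graph, c2), c2)
  sort_general_first(graph, intersect(s1, s2))
}

#' Concatenated ancestor sequence of two concepts
#'
#' `ancestors(c1)` followed by `ancestors(c2)`; each block is internally
#' ordered most-general-first and ends with its own concept.
#'
#' @inheritParams common_ancestors
#' @return Character vector of length
#'   `length(ancestors(graph, c1)) + length(ancestors(graph, c2))`.
#' @export
concat_ancestors <- function(graph, c1, c2) {
  c(ancestors(graph, c1), ancestors(graph, c2))
}

#' Depth of a concept
#'
#' Length of the longest is-a path from any root to the concept; roots have
#' depth 0. Multiple roots are permitted (depth is computed per component).
#'
#' @inheritParams ancestors
#' @return Non-negative integer.
#' @export
concept_depth <- function(graph, concept_id) {
  check_concept(graph, concept_id)
  unname(graph$depth[[concept_id]])
}

# normalized Levenshtein similarity, case-insensitive, in [0, 1]
lev_score <- function(mention, candidates) {
  a <- tolower(mention)
  b <- tolower(candidates)
  d <- as.numeric(utils::adist(a, b))
  1 - d / pmax(nchar(a), nchar(b))
}

best_match <- function(mention, strings, ids) {
  if (length(strings) == 0L) return(NULL)
  keep <- nzchar(strings) & !is.na(strings)
  strings <- strings[keep]
  ids <- ids[keep]
  if (length(strings) == 0L) return(NULL)
  s <- lev_score(mention, strings)
  top <- which(s == max(s))
  top <- top[order(ids[top])][1]  # deterministic: lowest concept id wins
  list(concept_id = ids[top], score = s[top])
}

#' Link a free-text mention to an ontology concept by fuzzy matching
#'
#' Computes the best case-insensitive normalized-Levenshtein match of the
#' mention against preferred labels (score
#' `1 - edit_distance / max(nchar)`). A label match with score at or above
#' the threshold is accepted directly. Otherwise the best synonym match is
#' accepted only if it strictly exceeds the best label score and meets the
#' threshold. Obsolete concepts never match. Ties are broken toward the
#' lowest concept id.
#'
#' @inheritParams ancestors
#' @param mention Non-empty string to link.
#' @param threshold Acceptance threshold in `[0, 1]`; default 0.7.
#' @return A list of class `concept_match` with `concept_id`, `score` and
#'   `matched_via` (`"label"` or `"synonym"`), or `NULL` when nothing
#'   reaches the threshold.
#' @export
link_entity <- function(graph, mention, threshold = 0.7) {
  stopifnot(is.character(mention), length(mention) == 1L, nzchar(mention),
            threshold >= 0, threshold <= 1)
  lab <- best_match(mention, unname(graph$label[graph$ids]), graph$ids)
  if (!is.null(lab) && lab$score >= threshold) {
    return(structure(c(lab, list(matched_via = "label")),
                     class = "concept_match"))
  }
  syn_ids <- rep(graph$ids, lengths(graph$synonyms[graph$ids]))
  syns <- unlist(graph$synonyms[graph$ids], use.names = FALSE)
  syn <- best_match(mention, syns, syn_ids)
  lab_score <- if (is.null(lab)) -Inf else lab$score
  if (!is.null(syn) && syn$score > lab_score && syn$score >= threshold) {
    return(structure(c(syn, list(matched_via = "synonym")),
                     class = "concept_match"))
  }
  NULL
}

#' Cache ancestor sequences to a TSV file
#'
#' Writes one row per entity: entity id, linked concept id, and the
#' comma-joined ancestor sequence of that concept.
#'
#' @inheritParams ancestors
#' @param links A data frame with columns `entity_id` and `concept_id`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ancestor_cache <- function(graph, links, path) {
  stopifnot(all(c("entity_id", "concept_id") %in% names(links)))
  anc <- vapply(links$concept_id, function(cid) {
    paste(ancestors(graph, cid), collapse = ",")
  }, character(1))
  utils::write.table(
    data.frame(entity_id = links$entity_id, concept_id = links$concept_id,
               ancestors = anc, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ancestor-sequence cache written by [write_ancestor_cache()]
#'
#' @param path TSV path.
#' @return Data frame with `entity_id`, `concept_id` and a list column
#'   `ancestors`.
#' @export
read_ancestor_cache <- function(path) {
  df <- utils::read.table(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          col.names = c("entity_id", "concept_id",
                                        "ancestors"))
  df$ancestors <- strsplit(df$ancestors, ",", fixed = TRUE)
  df
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d concepts, %d is-a edges, max depth %d\n",
              length(x$ids), nrow(edge_matrix(x)), max(x$depth)))
  invisible(x)
}

#' @export
print.concept_match <- function(x, ...) {
  cat(sprintf("<concept_match> %s (score %.3f via %s)\n",
              x$concept_id, x$score, x$matched_via))
  invisible(x)
}
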