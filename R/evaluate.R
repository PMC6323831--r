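# Detection and classification scoring in the SemEval style, per-subset
# breakdown, and multi-system overlap (Venn) analysis.
#
# Detection scores positive-vs-negative only; classification additionally
# requires the correct interaction type. Classification metrics are
# micro-averaged over the four positive types: a positive pair predicted
# positive with the wrong type counts as a false positive for the
# predicted type and a false negative for the gold type.

pair_key <- function(df) {
  paste(df$doc_id, df$sentence_id, pmin(df$e1, df$e2),
        pmax(df$e1, df$e2), sep = "\r")
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f, tp = tp, fp = fp, fn = fn)
}

#' Score predictions against gold pairs
#'
#' Both inputs must cover the same instance universe, keyed by document,
#' sentence and unordered entity pair. Detection counts a true positive
#' whenever a gold-positive pair is predicted positive (any type);
#' classification requires an exact type match and is micro-averaged over
#' the positive types.
#'
#' @param gold Data frame with `doc_id`, `sentence_id`, `e1`, `e2`,
#'   `label`.
#' @param predicted Data frame with the same columns (e.g. from
#'   [predict.ontorel_model()]).
#' @return An `evaluation_report`: lists `detection` and `classification`,
#'   each with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
score_pairs <- function(gold, predicted) {
  gk <- pair_key(gold)
  pk <- pair_key(predicted)
  if (anyDuplicated(gk) || anyDuplicated(pk)) {
    ontorel_stop("duplicate pair keys in gold or predictions",
                 "ontorel_universe_mismatch")
  }
  orphans <- c(setdiff(gk, pk), setdiff(pk, gk))
  if (length(orphans) > 0L) {
    ontorel_stop(sprintf("gold/prediction universes differ; orphan keys: %s",
                         paste(gsub("\r", "|", utils::head(orphans, 5)),
                               collapse = "; ")),
                 "ontorel_universe_mismatch")
  }
  g <- gold$label[match(pk, gk)]
  p <- predicted$label
  gpos <- g != "negative"
  ppos <- p != "negative"
  det <- prf(sum(gpos & ppos), sum(!gpos & ppos), sum(gpos & !ppos))
  types <- setdiff(DDI_LABELS, "negative")
  tp <- fp <- fn <- 0L
  per_class <- list()
  for (ty in types) {
    ctp <- sum(g == ty & p == ty)
    cfp <- sum(p == ty & g != ty)
    cfn <- sum(g == ty & p != ty)
    per_class[[ty]] <- prf(ctp, cfp, cfn)
    tp <- tp + ctp
    fp <- fp + cfp
    fn <- fn + cfn
  }
  structure(list(detection = det, classification = prf(tp, fp, fn),
                 per_class = per_class, n = length(gk)),
            class = "evaluation_report")
}

#' Score predictions per document subset
#'
#' Splits gold and predictions by the source type of their document
#' (drugbank, medline, ...) and scores each subset independently, along
#' with the pooled result.
#'
#' @inheritParams score_pairs
#' @param documents The documents the pairs came from (for the
#'   `source_type` of each document id).
#' @return List with `overall` (an `evaluation_report`) and `per_subset`
#'   (named list of reports).
#' @export
score_by_subset <- function(gold, predicted, documents) {
  st <- setNames(vapply(documents, `[[`, character(1), "source_type"),
                 vapply(documents, `[[`, character(1), "id"))
  subset_of <- st[gold$doc_id]
  per <- list()
  for (s in sort(unique(subset_of))) {
    rows <- which(subset_of == s)
    keys <- pair_key(gold[rows, , drop = FALSE])
    prows <- which(pair_key(predicted) %in% keys)
    per[[s]] <- score_pairs(gold[rows, , drop = FALSE],
                            predicted[prows, , drop = FALSE])
  }
  list(overall = score_pairs(gold, predicted), per_subset = per)
}

#' Overlap (Venn) analysis of several systems against the gold standard
#'
#' Partitions the union of the gold-positive key set and each system's
#' predicted-positive key set into every region of the membership lattice.
#' Also reports, per system, the true positives found by that system
#' alone, and the gold pairs found by no system.
#'
#' @param gold Character vector of gold-positive pair keys.
#' @param systems Named list (1-4 elements) of character vectors of
#'   predicted-positive pair keys.
#' @return An `overlap_partition`: `regions` (data frame `region`,
#'   `count`), `unique_tp` (named integer), `missed` (character vector of
#'   gold keys found by no system).
#' @export
overlap_analysis <- function(gold, systems) {
  stopifnot(length(systems) >= 1L, length(systems) <= 4L,
            !is.null(names(systems)), all(nzchar(names(systems))))
  sets <- c(list(gold = unique(gold)), lapply(systems, unique))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL,
                                                               names(sets)))
  region <- apply(member, 1, function(r) {
    paste(names(sets)[r], collapse = "&")
  })
  counts <- table(region)
  regions <- data.frame(region = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
  in_gold <- member[, "gold"]
  sysm <- member[, names(systems), drop = FALSE]
  n_sys <- rowSums(sysm)
  unique_tp <- vapply(names(systems), function(nm) {
    sum(in_gold & n_sys == 1L & sysm[, nm])
  }, integer(1))
  missed <- universe[in_gold & n_sys == 0L]
  structure(list(regions = regions, unique_tp = unique_tp,
                 missed = missed, sets = names(sets)),
            class = "overlap_partition")
}

#' Write an overlap partition as CSV
#'
#' @param partition An `overlap_partition`.
#' @param path Output CSV path (columns `region`, `count`).
#' @return `path`, invisibly.
#' @export
write_overlap_csv <- function(partition, path) {
  utils::write.csv(partition$regions, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to a file).
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(nm, m) {
    sprintf("  %-14s P=%.4f R=%.4f F1=%.4f (TP=%d FP=%d FN=%d)", nm,
            m$precision, m$recall, m$f1, m$tp, m$fp, m$fn)
  }
  cat(sprintf("<evaluation_report> %d pairs\n", x$n))
  cat(fmt("detection", x$detection), sep = "\n")
  cat(fmt("classification", x$classification), sep = "\n")
  invisible(x)
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf("<overlap_partition> sets: %s\n",
              paste(x$sets, collapse = ", ")))
  print(x$regions, row.names = FALSE)
  invisible(x)
}
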