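# Textual word2vec format: a header line "count dim" followed by one line
# per token: the token then `dim` whitespace-separated floats.

#' Read word vectors in the textual word2vec format
#'
#' @param path Path to the vectors file.
#' @return List with `vocab` (character) and `vectors` (dim x count matrix
#'   with tokens as column names).
#' @export
read_word2vec <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  header <- scan(con, what = integer(), n = 2, quiet = TRUE)
  n <- header[1]
  d <- header[2]
  vocab <- character(n)
  mat <- matrix(0, nrow = d, ncol = n)
  for (i in seq_len(n)) {
    fields <- scan(con, what = character(), n = d + 1, quiet = TRUE)
    vocab[i] <- fields[1]
    mat[, i] <- as.numeric(fields[-1])
  }
  colnames(mat) <- vocab
  list(vocab = vocab, vectors = mat)
}

#' Write word vectors in the textual word2vec format
#'
#' @param vectors A dim x count numeric matrix with tokens as column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(vectors, path) {
  stopifnot(is.matrix(vectors), !is.null(colnames(vectors)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", ncol(vectors), nrow(vectors)), con)
  body <- vapply(seq_len(ncol(vectors)), function(i) {
    paste(colnames(vectors)[i],
          paste(sprintf("%.8g", vectors[, i]), collapse = " "))
  }, character(1))
  writeLines(body, con)
  invisible(path)
}
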