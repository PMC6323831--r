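# Network construction, embeddings, training mechanics, persistence.

# a tiny feature-complete instance set over the 6-term fixture ontology
tiny_instances <- function(n = 40L, seed = 5L, labels = NULL) {
  g <- fixture_graph()
  set.seed(seed)
  concepts <- g$ids
  lapply(seq_len(n), function(i) {
    c1 <- sample(concepts, 1L)
    c2 <- sample(concepts, 1L)
    lab <- if (is.null(labels)) {
      if ("T:1" %in% common_ancestors(g, c1, c2)) "effect" else "negative"
    } else labels[[((i - 1L) %% length(labels)) + 1L]]
    list(doc_id = "d1", sentence_id = sprintf("s%d", i),
         e1 = sprintf("s%d.e1", i), e2 = sprintf("s%d.e2", i),
         label = lab, provenance = "gold",
         sdp_tokens = c("entity", sample(c("foo", "bar", "baz"), 1L),
                        "entity"),
         wordnet = c("0", "noun.substance", "0"),
         concat_seq = concat_ancestors(g, c1, c2),
         common_seq = common_ancestors(g, c1, c2))
  })
}

onto_config <- function(max_epochs = 8, seed = 3, ...) {
  model_config(channels = c("concat_ancestors", "common_ancestors"),
               ontology_dim = 8, lstm_units = 12, dense_units = 10,
               batch_size = 8, max_epochs = max_epochs, seed = seed, ...)
}

tiny_model <- function(instances, ...) {
  build_model(onto_config(...),
              onto_vocab = ontology_vocabulary(fixture_graph()))
}

test_that("embedding lookup returns matrix columns, zero for padding", {
  m <- tiny_model(tiny_instances())
  E <- m$params[["emb.concat_ancestors"]]
  expect_identical(ncol(E), length(fixture_graph()$ids) + 1L)
  expect_identical(embed_concept(E, 0L), rep(0, nrow(E)))
  expect_identical(embed_concept(E, 3L), E[, 4L])
  expect_error(embed_concept(E, ncol(E)), class = "ontorel_index_error")
  # seeded random init gives distinct non-zero concept vectors
  expect_false(identical(embed_concept(E, 1L), embed_concept(E, 2L)))
})

test_that("configuration is validated", {
  expect_error(model_config(channels = character(0)),
               class = "ontorel_config_error")
  expect_error(model_config(channels = "telepathy"),
               class = "ontorel_config_error")
  expect_error(model_config(n_classes = 3))
  expect_error(build_model(onto_config(), onto_vocab = NULL),
               class = "ontorel_config_error")
  expect_error(build_model(model_config(channels = "words")),
               class = "ontorel_config_error")
})

test_that("untrained loss on balanced random labels is close to log(n_classes)", {
  inst <- tiny_instances(60L, labels = ontorel:::DDI_LABELS)
  m <- tiny_model(inst)
  expect_lt(abs(model_loss(m, inst) - log(5)) / log(5), 0.1)
})

test_that("softmax rows sum to one and prediction is deterministic", {
  inst <- tiny_instances(40L)
  m <- train_model(tiny_model(inst), inst)
  p1 <- predict(m, inst)
  p2 <- predict(m, inst)
  expect_identical(p1, p2)
  probs <- attr(p1, "probabilities")
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  expect_true(all(p1$label %in% m$labels))
})

test_that("auto-negative instances bypass the network", {
  inst <- tiny_instances(40L)
  auto <- inst[[1]]
  auto$provenance <- "auto_negative"
  auto$sdp_tokens <- character(0)
  auto$wordnet <- character(0)
  auto$concat_seq <- character(0)
  auto$common_seq <- character(0)
  m <- train_model(tiny_model(inst), inst)
  out <- predict(m, c(list(auto), inst[2:3]))
  expect_identical(out$label[1], "negative")
  expect_identical(out$provenance[1], "auto_negative")
  expect_identical(unname(attr(out, "probabilities")[1, "negative"]), 1)
})

test_that("max-pool output is invariant to extra padding", {
  inst <- tiny_instances(10L)
  m <- tiny_model(inst)
  m$max_len <- list(concat_ancestors = 10L, common_ancestors = 6L)
  x1 <- ontorel:::encode_instances(m, inst)
  f1 <- ontorel:::nn_forward(m, m$params, x1)
  m$max_len <- list(concat_ancestors = 17L, common_ancestors = 11L)
  x2 <- ontorel:::encode_instances(m, inst)
  f2 <- ontorel:::nn_forward(m, m$params, x2)
  expect_equal(f1$probs, f2$probs, tolerance = 1e-12)
})

test_that("training splits 80/20, stops early and restores best weights", {
  # random labels: validation loss cannot keep improving, so patience
  # must trigger well before max_epochs
  inst <- tiny_instances(50L, labels = ontorel:::DDI_LABELS)
  cfg_patience <- 2L
  m <- build_model(onto_config(patience = cfg_patience, max_epochs = 30),
                   onto_vocab = ontology_vocabulary(fixture_graph()))
  mt <- train_model(m, inst)
  log <- mt$log
  expect_lt(nrow(log), 30L)
  best <- which.min(log$val_loss)
  # halted exactly `patience` epochs after the last improvement
  expect_identical(nrow(log), best + cfg_patience)
  # restored weights reproduce the best validation loss, not the last one
  set.seed(mt$config$seed)
  n <- length(inst)
  perm <- sample.int(n)
  val <- inst[perm[(floor(0.8 * n) + 1L):n]]
  expect_equal(model_loss(mt, val), min(log$val_loss), tolerance = 1e-9)
})

test_that("too few instances for a split is an error", {
  expect_error(train_model(tiny_model(tiny_instances(4L)),
                           tiny_instances(4L)),
               class = "ontorel_empty_split")
})

test_that("unknown ontology concepts at inference are a vocabulary mismatch", {
  inst <- tiny_instances(20L)
  m <- train_model(tiny_model(inst), inst)
  bad <- inst[[1]]
  bad$concat_seq <- c(bad$concat_seq, "T:99")
  expect_error(predict(m, list(bad)), class = "ontorel_vocab_mismatch")
})

test_that("a words-only model consumes pretrained vectors and maps OOV to unk", {
  set.seed(8)
  vecs <- matrix(rnorm(5 * 4), 5, 4,
                 dimnames = list(NULL, c("entity", "foo", "bar", "baz")))
  wv <- list(vocab = colnames(vecs), vectors = vecs)
  cfg <- model_config(channels = "words", word_dim = 5, lstm_units = 6,
                      dense_units = 6, batch_size = 8, max_epochs = 3,
                      seed = 2)
  inst <- tiny_instances(24L)
  m <- build_model(cfg, word_vectors = wv, instances = inst)
  # pretrained columns are frozen copies
  ch <- m$channels$words
  expect_identical(m$params$emb.words[, ch$vocab[["foo"]] + 1L],
                   unname(vecs[, "foo"]))
  expect_false(ch$trainable)
  mt <- train_model(m, inst)
  novel <- inst[[1]]
  novel$sdp_tokens <- c("entity", "neverseen", "entity")
  out <- predict(mt, list(novel))
  expect_identical(nrow(out), 1L)  # OOV handled via the shared unk vector
})

test_that("save/load round-trips weights, vocabularies and predictions", {
  inst <- tiny_instances(30L)
  m <- train_model(tiny_model(inst), inst)
  dir <- tempfile("model")
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_identical(m2$labels, m$labels)
  expect_identical(m2$channels$concat_ancestors$vocab,
                   m$channels$concat_ancestors$vocab)
  expect_identical(predict(m2, inst), predict(m, inst))

  # missing vocabulary file
  file.remove(file.path(dir, "vocab-common_ancestors.tsv"))
  expect_error(load_model(dir), class = "ontorel_config_error")

  # version mismatch
  dir2 <- tempfile("model")
  save_model(m, dir2)
  meta <- jsonlite::read_json(file.path(dir2, "config.json"))
  meta$version <- "someone-else-9"
  jsonlite::write_json(meta, file.path(dir2, "config.json"),
                       auto_unbox = TRUE)
  expect_error(load_model(dir2), class = "ontorel_version_error")
})

test_that("a loaded model refuses channels it was not built with", {
  inst <- tiny_instances(30L)
  m <- train_model(tiny_model(inst), inst)
  dir <- tempfile("model")
  save_model(m, dir)
  m2 <- load_model(dir)
  m2$config$channels <- c(m2$config$channels, "words")
  expect_error(predict(m2, inst), class = "ontorel_config_error")
})

test_that("detection labels of a 5-class model match collapsed argmax", {
  inst <- tiny_instances(40L)
  m <- train_model(tiny_model(inst), inst)
  out <- predict(m, inst)
  probs <- attr(out, "probabilities")
  argmax <- m$labels[max.col(probs, ties.method = "first")]
  expect_identical(out$label != "negative", argmax != "negative")
})
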