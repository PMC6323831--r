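# Multi-channel LSTM relation classifier.
#
# Architecture, per enabled channel: embedding lookup -> LSTM -> max-pool
# over time. The pooled channel outputs are concatenated, passed through a
# dense layer with sigmoid activation and a softmax output layer. Training
# uses mini-batch Adam on the cross-entropy loss, inverted dropout on the
# embedding and pooled-concatenation layers (never on the penultimate dense
# or the output layer), an 80/20 shuffled train/validation split and early
# stopping on the validation loss with best-weight restoration.
#
# The network is implemented directly with BLAS-backed matrix operations;
# all state lives in plain R matrices so that models serialize to text.

CHANNELS <- c("words", "wordnet", "concat_ancestors", "common_ancestors")
MODEL_VERSION <- "ontorel-1"

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Model configuration
#'
#' @param channels Non-empty subset of `words`, `wordnet`,
#'   `concat_ancestors`, `common_ancestors`.
#' @param word_dim Dimension of the pre-trained word vectors.
#' @param wordnet_dim WordNet-class embedding dimension (default 50).
#' @param ontology_dim Ontology-concept embedding dimension (default 50).
#' @param lstm_units LSTM hidden units per channel (default 100).
#' @param dense_units Units of the penultimate sigmoid dense layer
#'   (default 100).
#' @param dropout_rate Dropout rate in `[0, 1)` applied to the embedding
#'   and pooled layers (default 0.5).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param n_classes 5 (full classification) or 2 (detection-only).
#' @param batch_size Mini-batch size (default 64).
#' @param patience Early-stopping patience in epochs (default 3).
#' @param max_epochs Upper bound on training epochs (default 50).
#' @param seed Seed governing initialization, shuffling and dropout.
#' @param word_trainable Fine-tune the word embeddings (default `FALSE`;
#'   the pre-trained vectors stay frozen).
#' @return A `model_config` object.
#' @export
model_config <- function(channels = CHANNELS, word_dim = 50,
                         wordnet_dim = 50, ontology_dim = 50,
                         lstm_units = 100, dense_units = 100,
                         dropout_rate = 0.5, learning_rate = 0.001,
                         n_classes = 5, batch_size = 64, patience = 3,
                         max_epochs = 50, seed = 1,
                         word_trainable = FALSE) {
  if (length(channels) == 0L || !all(channels %in% CHANNELS)) {
    ontorel_stop("channels must be a non-empty subset of the four channels",
                 "ontorel_config_error")
  }
  stopifnot(dropout_rate >= 0, dropout_rate < 1, n_classes %in% c(2L, 5L),
            lstm_units > 0, dense_units > 0, batch_size > 0, patience >= 1)
  structure(list(channels = unique(channels), word_dim = word_dim,
                 wordnet_dim = wordnet_dim, ontology_dim = ontology_dim,
                 lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 n_classes = as.integer(n_classes),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 word_trainable = isTRUE(word_trainable)),
            class = "model_config")
}

#' Ontology vocabulary: dense concept indices
#'
#' Maps concept ids to dense integer indices starting at 1; index 0 is
#' reserved for padding. From a graph, all non-obsolete concepts are
#' indexed; from a character vector, the sorted unique ids.
#'
#' @param x An `ontology_graph` or a character vector of concept ids.
#' @return Named integer vector (concept id -> index).
#' @export
ontology_vocabulary <- function(x) {
  ids <- if (inherits(x, "ontology_graph")) x$ids else sort(unique(x))
  setNames(seq_along(ids), ids)
}

wordnet_vocab <- function() {
  toks <- c(SUPERSENSE_NULL, supersense_inventory())
  setNames(seq_along(toks), toks)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

channel_dim <- function(config, ch) {
  switch(ch, words = config$word_dim, wordnet = config$wordnet_dim,
         config$ontology_dim)
}

channel_seq <- function(instance, ch) {
  switch(ch, words = instance$sdp_tokens, wordnet = instance$wordnet,
         concat_ancestors = instance$concat_seq,
         common_ancestors = instance$common_seq)
}

#' Build an untrained multi-channel LSTM model
#'
#' Sets up, for every enabled channel, an embedding matrix (dense columns,
#' zero column for padding), LSTM weights and the shared dense and softmax
#' layers. Word embeddings are copied from the pre-trained vectors (plus a
#' randomly initialized shared unknown-word vector); WordNet and ontology
#' embeddings are randomly initialized and tuned during training. All
#' randomness derives from `config$seed`.
#'
#' @param config A [model_config()].
#' @param word_vectors Result of [read_word2vec()]; required when the
#'   `words` channel is enabled.
#' @param onto_vocab Result of [ontology_vocabulary()]; required when an
#'   ontology channel is enabled.
#' @param instances Optional instance list used to restrict the word
#'   vocabulary to observed tokens.
#' @return An `ontorel_model` (untrained).
#' @export
build_model <- function(config, word_vectors = NULL, onto_vocab = NULL,
                        instances = NULL) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  U <- config$lstm_units
  channels <- list()
  params <- list()
  for (ch in config$channels) {
    D <- channel_dim(config, ch)
    if (ch == "words") {
      if (is.null(word_vectors)) {
        ontorel_stop("words channel enabled but no word vectors supplied",
                     "ontorel_config_error")
      }
      if (nrow(word_vectors$vectors) != D) {
        ontorel_stop("word_dim does not match the vector file",
                     "ontorel_config_error")
      }
      vocab_tokens <- word_vectors$vocab
      if (!is.null(instances)) {
        observed <- unique(unlist(lapply(instances, channel_seq,
                                         ch = "words")))
        vocab_tokens <- intersect(vocab_tokens, observed)
      }
      vocab <- setNames(seq_along(vocab_tokens), vocab_tokens)
      E <- cbind(0, word_vectors$vectors[, vocab_tokens, drop = FALSE],
                 stats::runif(D, -0.05, 0.05))
      unk <- length(vocab) + 1L
      vocab <- c(vocab, setNames(unk, "<unk>"))
      trainable <- config$word_trainable
    } else if (ch == "wordnet") {
      vocab <- wordnet_vocab()
      E <- cbind(0, matrix(stats::runif(D * length(vocab), -0.05, 0.05),
                           D, length(vocab)))
      unk <- NA_integer_
      trainable <- TRUE
    } else {
      if (is.null(onto_vocab)) {
        ontorel_stop("ontology channel enabled but no ontology vocabulary",
                     "ontorel_config_error")
      }
      vocab <- onto_vocab
      E <- cbind(0, matrix(stats::runif(D * length(vocab), -0.05, 0.05),
                           D, length(vocab)))
      unk <- NA_integer_
      trainable <- TRUE
    }
    colnames(E) <- NULL
    channels[[ch]] <- list(name = ch, dim = D, vocab = vocab, unk = unk,
                           trainable = trainable)
    params[[paste0("emb.", ch)]] <- E
    params[[paste0("Wx.", ch)]] <- glorot(D, 4L * U)
    params[[paste0("Wh.", ch)]] <- glorot(U, 4L * U)
    b <- rep(0, 4L * U)
    b[U + seq_len(U)] <- 1  # forget-gate bias
    params[[paste0("b.", ch)]] <- b
  }
  K <- length(config$channels) * U
  params$W1 <- glorot(K, config$dense_units)
  params$b1 <- rep(0, config$dense_units)
  # small output init keeps the untrained network near the uniform
  # distribution, so the initial loss is ~ log(n_classes)
  params$W2 <- matrix(stats::runif(config$dense_units * config$n_classes,
                                   -0.01, 0.01),
                      config$dense_units, config$n_classes)
  params$b2 <- rep(0, config$n_classes)
  labels <- if (config$n_classes == 5L) DDI_LABELS else {
    c("negative", "positive")
  }
  structure(list(config = config, channels = channels, params = params,
                 labels = labels, max_len = NULL, trained = FALSE,
                 log = NULL, version = MODEL_VERSION),
            class = "ontorel_model")
}

#' Look up a concept embedding
#'
#' Returns the dense column of the embedding matrix for a concept index;
#' the padding index 0 yields the zero vector.
#'
#' @param embedding An embedding matrix as stored in a model (`dim` rows;
#'   column 1 is the padding column).
#' @param concept_index Integer index in `0 .. vocabulary size`.
#' @return Numeric vector of length `nrow(embedding)`.
#' @export
embed_concept <- function(embedding, concept_index) {
  if (concept_index < 0L || concept_index > ncol(embedding) - 1L) {
    ontorel_stop(sprintf("embedding index out of range: %d", concept_index),
                 "ontorel_index_error")
  }
  embedding[, concept_index + 1L]
}

# sequence -> integer indices under a channel's vocabulary
index_sequence <- function(channel, tokens) {
  idx <- unname(channel$vocab[tokens])
  if (anyNA(idx)) {
    if (!is.na(channel$unk)) {
      idx[is.na(idx)] <- channel$unk
    } else {
      ontorel_stop(sprintf("tokens outside the %s vocabulary: %s",
                           channel$name,
                           paste(unique(tokens[is.na(idx)]),
                                 collapse = ", ")),
                   "ontorel_vocab_mismatch")
    }
  }
  idx
}

# instances -> named list of right-padded B x max_len index matrices;
# over-long sequences are truncated from the left (general) end
encode_instances <- function(model, instances) {
  out <- list()
  for (ch in model$config$channels) {
    channel <- model$channels[[ch]]
    if (is.null(channel)) {
      ontorel_stop(sprintf("model has no %s channel", ch),
                   "ontorel_config_error")
    }
    L <- model$max_len[[ch]]
    X <- matrix(0L, length(instances), L)
    for (i in seq_along(instances)) {
      s <- channel_seq(instances[[i]], ch)
      if (length(s) > L) s <- s[(length(s) - L + 1L):length(s)]
      if (length(s) > 0L) X[i, seq_along(s)] <- index_sequence(channel, s)
    }
    out[[ch]] <- X
  }
  out
}

lstm_channel_forward <- function(P, ch, X, U, train, drop_rate,
                                 keep_cache) {
  E <- P[[paste0("emb.", ch)]]
  Wx <- P[[paste0("Wx.", ch)]]
  Wh <- P[[paste0("Wh.", ch)]]
  b <- P[[paste0("b.", ch)]]
  B <- nrow(X)
  Tn <- ncol(X)
  H <- matrix(0, B, U)
  C <- matrix(0, B, U)
  Hs <- vector("list", Tn)
  caches <- if (keep_cache) vector("list", Tn)
  bmat <- rep(b, each = B)
  iU <- seq_len(U)
  for (t in seq_len(Tn)) {
    idx <- X[, t]
    Xe <- t(E[, idx + 1L, drop = FALSE])
    dm <- NULL
    if (train && drop_rate > 0) {
      dm <- (matrix(stats::runif(length(Xe)), B) >= drop_rate) /
        (1 - drop_rate)
      Xe <- Xe * dm
    }
    Z <- Xe %*% Wx + H %*% Wh + bmat
    i_ <- sigmoid(Z[, iU, drop = FALSE])
    f_ <- sigmoid(Z[, U + iU, drop = FALSE])
    o_ <- sigmoid(Z[, 2L * U + iU, drop = FALSE])
    g_ <- tanh(Z[, 3L * U + iU, drop = FALSE])
    Cnew <- f_ * C + i_ * g_
    tC <- tanh(Cnew)
    Hnew <- o_ * tC
    m <- as.numeric(idx > 0L)
    if (keep_cache) {
      caches[[t]] <- list(Xe = Xe, dm = dm, Hprev = H, Cprev = C, i = i_,
                          f = f_, o = o_, g = g_, tC = tC, m = m)
    }
    H <- m * Hnew + (1 - m) * H
    C <- m * Cnew + (1 - m) * C
    Hs[[t]] <- H
  }
  pooled <- Hs[[1]]
  argt <- matrix(1L, B, U)
  if (Tn > 1L) {
    for (t in 2:Tn) {
      upd <- Hs[[t]] > pooled
      pooled[upd] <- Hs[[t]][upd]
      argt[upd] <- t
    }
  }
  list(pooled = pooled, argt = argt, caches = caches, X = X)
}

lstm_channel_backward <- function(P, ch, fwd, dPool, U) {
  Wx <- P[[paste0("Wx.", ch)]]
  Wh <- P[[paste0("Wh.", ch)]]
  X <- fwd$X
  B <- nrow(X)
  Tn <- ncol(X)
  D <- nrow(P[[paste0("emb.", ch)]])
  gWx <- matrix(0, D, 4L * U)
  gWh <- matrix(0, U, 4L * U)
  gb <- rep(0, 4L * U)
  dXe_list <- vector("list", Tn)
  dH <- matrix(0, B, U)
  dC <- matrix(0, B, U)
  for (t in Tn:1) {
    sel <- fwd$argt == t
    if (any(sel)) dH[sel] <- dH[sel] + dPool[sel]
    ca <- fwd$caches[[t]]
    m <- ca$m
    dHnew <- dH * m
    do_ <- dHnew * ca$tC
    dCnew <- dHnew * ca$o * (1 - ca$tC^2) + dC * m
    dCprev <- dC * (1 - m) + dCnew * ca$f
    di <- dCnew * ca$g
    df <- dCnew * ca$Cprev
    dg <- dCnew * ca$i
    dZ <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                do_ * ca$o * (1 - ca$o),
                dg * (1 - ca$g^2))
    gWx <- gWx + crossprod(ca$Xe, dZ)
    gWh <- gWh + crossprod(ca$Hprev, dZ)
    gb <- gb + colSums(dZ)
    dXe <- tcrossprod(dZ, Wx)
    if (!is.null(ca$dm)) dXe <- dXe * ca$dm
    dXe_list[[t]] <- dXe
    dH <- dH * (1 - m) + tcrossprod(dZ, Wh)
    dC <- dCprev
  }
  gE <- NULL
  G <- do.call(rbind, dXe_list)
  ids <- as.vector(X)
  keep <- ids > 0L
  if (any(keep)) {
    agg <- rowsum(G[keep, , drop = FALSE], group = ids[keep])
    gE <- list(idx = as.integer(rownames(agg)) + 1L, grad = t(agg))
  }
  list(gWx = gWx, gWh = gWh, gb = gb, gE = gE)
}

nn_forward <- function(model, P, Xc, train = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  U <- cfg$lstm_units
  fwd <- list()
  pooled <- list()
  for (ch in cfg$channels) {
    fwd[[ch]] <- lstm_channel_forward(P, ch, Xc[[ch]], U, train,
                                      cfg$dropout_rate, keep_cache)
    pooled[[ch]] <- fwd[[ch]]$pooled
  }
  Pcat <- do.call(cbind, pooled)
  dmp <- NULL
  if (train && cfg$dropout_rate > 0) {
    dmp <- (matrix(stats::runif(length(Pcat)), nrow(Pcat)) >=
              cfg$dropout_rate) / (1 - cfg$dropout_rate)
    Pcat <- Pcat * dmp
  }
  B <- nrow(Pcat)
  Dh <- sigmoid(Pcat %*% P$W1 + rep(P$b1, each = B))
  O <- Dh %*% P$W2 + rep(P$b2, each = B)
  O <- O - apply(O, 1, max)
  ex <- exp(O)
  probs <- ex / rowSums(ex)
  list(probs = probs, fwd = fwd, Pcat = Pcat, dmp = dmp, Dh = Dh)
}

ce_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

nn_backward <- function(model, P, cache, y) {
  cfg <- model$config
  U <- cfg$lstm_units
  B <- nrow(cache$probs)
  dO <- cache$probs
  dO[cbind(seq_len(B), y)] <- dO[cbind(seq_len(B), y)] - 1
  dO <- dO / B
  G <- list()
  G$W2 <- crossprod(cache$Dh, dO)
  G$b2 <- colSums(dO)
  dDh <- tcrossprod(dO, P$W2)
  dZ1 <- dDh * cache$Dh * (1 - cache$Dh)
  G$W1 <- crossprod(cache$Pcat, dZ1)
  G$b1 <- colSums(dZ1)
  dPcat <- tcrossprod(dZ1, P$W1)
  if (!is.null(cache$dmp)) dPcat <- dPcat * cache$dmp
  for (k in seq_along(cfg$channels)) {
    ch <- cfg$channels[k]
    dPool <- dPcat[, (k - 1L) * U + seq_len(U), drop = FALSE]
    gch <- lstm_channel_backward(P, ch, cache$fwd[[ch]], dPool, U)
    G[[paste0("Wx.", ch)]] <- gch$gWx
    G[[paste0("Wh.", ch)]] <- gch$gWh
    G[[paste0("b.", ch)]] <- gch$gb
    if (model$channels[[ch]]$trainable && !is.null(gch$gE)) {
      G[[paste0("emb.", ch)]] <- gch$gE
    }
  }
  G
}

adam_step <- function(P, G, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(G)) {
    g <- G[[nm]]
    if (startsWith(nm, "emb.")) {
      # sparse update on the touched columns only
      idx <- g$idx
      gd <- g$grad
      if (is.null(state$m[[nm]])) {
        state$m[[nm]] <- matrix(0, nrow(P[[nm]]), ncol(P[[nm]]))
        state$v[[nm]] <- matrix(0, nrow(P[[nm]]), ncol(P[[nm]]))
      }
      state$m[[nm]][, idx] <- beta1 * state$m[[nm]][, idx] +
        (1 - beta1) * gd
      state$v[[nm]][, idx] <- beta2 * state$v[[nm]][, idx] +
        (1 - beta2) * gd^2
      mh <- state$m[[nm]][, idx] / corr1
      vh <- state$v[[nm]][, idx] / corr2
      P[[nm]][, idx] <- P[[nm]][, idx] - lr * mh / (sqrt(vh) + eps)
    } else {
      if (is.null(state$m[[nm]])) {
        state$m[[nm]] <- 0 * g
        state$v[[nm]] <- 0 * g
      }
      state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
      state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
      mh <- state$m[[nm]] / corr1
      vh <- state$v[[nm]] / corr2
      P[[nm]] <- P[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(P = P, state = state)
}

encode_labels <- function(model, instances) {
  labs <- vapply(instances, `[[`, character(1), "label")
  if (model$config$n_classes == 2L) {
    labs <- ifelse(labs == "negative", "negative", "positive")
  }
  y <- match(labs, model$labels)
  if (anyNA(y)) {
    ontorel_stop("instance labels outside the model's label inventory",
                 "ontorel_bad_input")
  }
  y
}

#' Mean cross-entropy loss of a model on a set of instances
#'
#' Computed with dropout disabled (inference mode).
#'
#' @param model An `ontorel_model`.
#' @param instances Feature-complete instances.
#' @return Scalar loss.
#' @export
model_loss <- function(model, instances) {
  if (is.null(model$max_len)) {
    model$max_len <- default_max_len(model, instances)
  }
  Xc <- encode_instances(model, instances)
  y <- encode_labels(model, instances)
  ce_loss(nn_forward(model, model$params, Xc)$probs, y)
}

default_max_len <- function(model, instances) {
  ml <- lapply(model$config$channels, function(ch) {
    max(1L, max(vapply(instances, function(x) {
      length(channel_seq(x, ch))
    }, integer(1))))
  })
  setNames(ml, model$config$channels)
}

#' Train the model
#'
#' Shuffles the trainable instances (auto-negative pairs are excluded from
#' training), splits them `split_fraction` / `1 - split_fraction` into
#' train and validation sets, and runs mini-batch Adam until the
#' validation loss has not improved for `patience` consecutive epochs (or
#' `max_epochs` is reached). The weights of the best-validation epoch are
#' restored. Per-channel maximum sequence lengths are fixed to the longest
#' training sequence.
#'
#' @param model An `ontorel_model` from [build_model()].
#' @param instances Instance list from [build_instances()].
#' @param split_fraction Fraction used for training (default 0.8).
#' @param seed Seed for shuffling, batching and dropout (defaults to the
#'   config seed).
#' @param verbose Print per-epoch losses.
#' @return The trained model; `model$log` holds per-epoch train and
#'   validation losses.
#' @export
train_model <- function(model, instances, split_fraction = 0.8,
                        seed = model$config$seed, verbose = FALSE) {
  stopifnot(inherits(model, "ontorel_model"))
  cfg <- model$config
  keep <- vapply(instances, function(x) {
    !identical(x$provenance, "auto_negative")
  }, logical(1))
  instances <- instances[keep]
  if (length(instances) < 5L) {
    ontorel_stop("need at least 5 trainable instances for an 80/20 split",
                 "ontorel_empty_split")
  }
  set.seed(seed)
  n <- length(instances)
  perm <- sample.int(n)
  n_train <- max(1L, floor(split_fraction * n))
  if (n_train == n) n_train <- n - 1L
  train_set <- instances[perm[seq_len(n_train)]]
  val_set <- instances[perm[(n_train + 1L):n]]

  model$max_len <- default_max_len(model, train_set)
  Xtr <- encode_instances(model, train_set)
  ytr <- encode_labels(model, train_set)
  Xval <- encode_instances(model, val_set)
  yval <- encode_labels(model, val_set)

  P <- model$params
  state <- list(t = 0L, m = list(), v = list())
  best_val <- Inf
  best_P <- P
  wait <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  slice <- function(Xc, rows) lapply(Xc, function(X) {
    X[rows, , drop = FALSE]
  })
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n_train)
    batch_losses <- numeric(0)
    for (start in seq(1L, n_train, by = cfg$batch_size)) {
      rows <- ord[start:min(start + cfg$batch_size - 1L, n_train)]
      Xb <- slice(Xtr, rows)
      yb <- ytr[rows]
      cache <- nn_forward(model, P, Xb, train = TRUE, keep_cache = TRUE)
      batch_losses <- c(batch_losses, ce_loss(cache$probs, yb))
      G <- nn_backward(model, P, cache, yb)
      upd <- adam_step(P, G, state, cfg$learning_rate)
      P <- upd$P
      state <- upd$state
    }
    val_loss <- ce_loss(nn_forward(model, P, Xval)$probs, yval)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = mean(batch_losses),
                                 val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %d  train %.4f  val %.4f", epoch,
                      mean(batch_losses), val_loss))
    }
    if (val_loss < best_val - 1e-6) {
      best_val <- val_loss
      best_P <- P
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- best_P
  model$trained <- TRUE
  model$log <- log
  model
}

#' Predict labels for instances
#'
#' Auto-negative instances bypass the network and are labeled `negative`
#' with probability one; all other instances receive the argmax of the
#' softmax output. Dropout is disabled, so prediction is deterministic.
#'
#' @param object A trained `ontorel_model`.
#' @param instances Instance list from [build_instances()].
#' @param ... Unused.
#' @return Data frame with `doc_id`, `sentence_id`, `e1`, `e2`, `label`,
#'   `provenance`; the per-class probability matrix is attached as
#'   attribute `"probabilities"`.
#' @export
predict.ontorel_model <- function(object, instances, ...) {
  model <- object
  if (!isTRUE(model$trained)) {
    ontorel_stop("model has not been trained", "ontorel_config_error")
  }
  n <- length(instances)
  probs <- matrix(0, n, model$config$n_classes,
                  dimnames = list(NULL, model$labels))
  labels <- character(n)
  auto <- vapply(instances, function(x) {
    identical(x$provenance, "auto_negative")
  }, logical(1))
  labels[auto] <- "negative"
  probs[auto, "negative"] <- 1
  idx <- which(!auto)
  if (length(idx) > 0L) {
    Xc <- encode_instances(model, instances[idx])
    p <- nn_forward(model, model$params, Xc)$probs
    probs[idx, ] <- p
    labels[idx] <- model$labels[max.col(p, ties.method = "first")]
  }
  out <- data.frame(
    doc_id = vapply(instances, `[[`, character(1), "doc_id"),
    sentence_id = vapply(instances, `[[`, character(1), "sentence_id"),
    e1 = vapply(instances, `[[`, character(1), "e1"),
    e2 = vapply(instances, `[[`, character(1), "e2"),
    label = labels,
    provenance = ifelse(auto, "auto_negative", "predicted"),
    stringsAsFactors = FALSE)
  attr(out, "probabilities") <- probs
  out
}

write_mat <- function(x, path) {
  x <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(x), ncol(x)), con)
  writeLines(apply(x, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = "\t")
  }), con)
}

read_mat <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  vals <- scan(text = lines[-1], quiet = TRUE)
  matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
}

#' Save a model as a directory of text files
#'
#' Writes the configuration and label inventory as JSON, each channel
#' vocabulary as TSV and each weight matrix as a plain-text matrix file.
#' [load_model()] restores a model whose predictions are identical.
#'
#' @param model An `ontorel_model`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    version = model$version,
    config = unclass(model$config),
    labels = model$labels,
    trained = model$trained,
    max_len = model$max_len,
    channels = lapply(model$channels, function(ch) {
      c(ch[c("name", "dim")],
        if (!is.na(ch$unk)) list(unk = ch$unk),
        list(trainable = ch$trainable))
    }))
  jsonlite::write_json(meta, file.path(path, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  for (ch in names(model$channels)) {
    v <- model$channels[[ch]]$vocab
    utils::write.table(data.frame(token = names(v), index = unname(v)),
                       file.path(path, sprintf("vocab-%s.tsv", ch)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  for (nm in names(model$params)) {
    write_mat(model$params[[nm]],
              file.path(path, sprintf("weights-%s.txt", nm)))
  }
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Model directory.
#' @return An `ontorel_model`.
#' @export
load_model <- function(path) {
  cfg_path <- file.path(path, "config.json")
  if (!file.exists(cfg_path)) {
    ontorel_stop("not a model directory (config.json missing)",
                 "ontorel_config_error")
  }
  meta <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  if (!identical(meta$version, MODEL_VERSION)) {
    ontorel_stop(sprintf("model version mismatch: %s", meta$version),
                 "ontorel_version_error")
  }
  config <- do.call(model_config, meta$config[names(formals(model_config))[
    names(formals(model_config)) %in% names(meta$config)]])
  channels <- list()
  for (ch in config$channels) {
    vpath <- file.path(path, sprintf("vocab-%s.tsv", ch))
    if (!file.exists(vpath)) {
      ontorel_stop(sprintf("vocabulary file missing for channel %s", ch),
                   "ontorel_config_error")
    }
    vt <- utils::read.table(vpath, sep = "\t", quote = "",
                            stringsAsFactors = FALSE, na.strings = NULL,
                            colClasses = c("character", "integer"))
    m <- meta$channels[[ch]]
    channels[[ch]] <- list(name = ch, dim = m$dim,
                           vocab = setNames(vt[[2]], vt[[1]]),
                           unk = if (is.null(m$unk)) NA_integer_ else
                             as.integer(m$unk),
                           trainable = isTRUE(m$trainable))
  }
  params <- list()
  for (f in list.files(path, pattern = "^weights-.*\\.txt$")) {
    nm <- sub("^weights-(.*)\\.txt$", "\\1", f)
    x <- read_mat(file.path(path, f))
    if (nm %in% c("b1", "b2") || startsWith(nm, "b.")) x <- as.vector(x)
    params[[nm]] <- x
  }
  max_len <- meta$max_len
  if (!is.null(max_len)) max_len <- as.list(max_len)
  structure(list(config = config, channels = channels, params = params,
                 labels = meta$labels, max_len = max_len,
                 trained = isTRUE(meta$trained), log = NULL,
                 version = meta$version),
            class = "ontorel_model")
}

#' @export
print.ontorel_model <- function(x, ...) {
  cat(sprintf("<ontorel_model> channels: %s | %d classes | %strained\n",
              paste(x$config$channels, collapse = "+"),
              x$config$n_classes, if (x$trained) "" else "un"))
  invisible(x)
}
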