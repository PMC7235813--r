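# Classification head, token cross-entropy loss, AdamW training loop with
# validation-based model selection, prediction, and checkpointing.

#' Training configuration
#'
#' Defaults mirror standard fine-tuning practice for a pretrained encoder
#' (10 epochs, batch size 32, AdamW at learning rate 1e-5). Training the tiny
#' encoder from random initialization needs a larger step size; see
#' [train_config_desk()].
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param batch_size Sentences per optimization step.
#' @param learning_rate AdamW learning rate (> 0).
#' @param weight_decay Decoupled weight decay, applied to weight matrices
#'   (not biases or layer-norm parameters).
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 10L, batch_size = 32L, learning_rate = 1e-5,
                         weight_decay = 0.01, seed = 1L) {
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            weight_decay >= 0)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 optimizer = "adamw", selection_metric = "micro_f1",
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training configuration
#'
#' Scaled for training the small encoder from scratch on the synthetic
#' corpus: 5 epochs, batch size 32, learning rate 1e-3.
#'
#' @param ... Overrides passed to [train_config()].
#' @return Object of class `train_config`.
#' @export
train_config_desk <- function(...) {
  args <- utils::modifyList(
    list(epochs = 5L, batch_size = 32L, learning_rate = 1e-3, seed = 1L),
    list(...))
  do.call(train_config, args)
}

#' Aggregation strategy configuration
#'
#' @param method One of `"multihead"`, `"concat"`, `"sum_average"`,
#'   `"last_layer"`.
#' @param layer_subset Layers to fuse; see [resolve_layer_subset()].
#' @param n_fusion_heads Fusion heads for `"multihead"` (default 12; must
#'   divide the encoder hidden size).
#' @return Object of class `aggregator_config`.
#' @export
aggregator_config <- function(method = c("multihead", "concat", "sum_average",
                                         "last_layer"),
                              layer_subset = "all", n_fusion_heads = 12L) {
  method <- match.arg(method)
  structure(list(method = method, layer_subset = layer_subset,
                 n_fusion_heads = as.integer(n_fusion_heads)),
            class = "aggregator_config")
}

#' Output head
#'
#' Linear map from the context embedding to the 13 tag logits, followed by a
#' row-wise softmax.
#'
#' @param d Context embedding width.
#' @param seed Seed for Gaussian(0, 0.02) initialization of the weights.
#' @return Object of class `output_head` with fields `W` (d x 13) and `b`.
#' @export
output_head <- function(d, seed = 1L) {
  K <- length(tag_vocabulary())
  with_seed(seed, {
    structure(list(W = init_mat(d, K), b = rep(0, K)), class = "output_head")
  })
}

#' Per-token tag distributions
#'
#' `softmax(E W + b)` per token: each row is a probability distribution over
#' the 13 tags of [tag_vocabulary()] (columns in vocabulary order); the
#' row-wise argmax defines the predicted tag sequence.
#'
#' @param E Context embedding, numeric matrix (n, d).
#' @param head An [output_head()] with matching `d`.
#' @return Numeric matrix (n, 13); rows nonnegative, summing to 1.
#' @export
predict_tag_distributions <- function(E, head) {
  stopifnot(inherits(head, "output_head"))
  if (ncol(E) != nrow(head$W)) {
    stop(sprintf("configuration error: embedding width %d does not match head width %d",
                 ncol(E), nrow(head$W)))
  }
  softmax_rows(sweep(E %*% head$W, 2L, head$b, "+"))
}

# --- AdamW ---------------------------------------------------------------

adamw_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

# Decoupled weight decay applies to weight matrices only (embeddings and
# projections); biases and layer-norm vectors are exempt.
adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (is.matrix(params[[nm]])) {
      upd <- upd + lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

# --- batching ------------------------------------------------------------

# Truncate a sentence to max_len, dropping gold spans that cross the
# boundary (clipped spans are discarded, not shortened).
truncate_sentence <- function(sentence, max_len) {
  n <- length(sentence$tokens)
  if (n <= max_len) return(sentence)
  sp <- sentence$entities
  keep <- sp$end <= max_len
  annotated_sentence(sentence$tokens[seq_len(max_len)],
                     entity_spans(sp$type[keep], sp$start[keep], sp$end[keep]))
}

prepare_examples <- function(sentences, vocab, max_len) {
  vocab_tags <- tag_vocabulary()
  lapply(sentences, function(s) {
    s <- truncate_sentence(s, max_len)
    tags <- spans_to_tags(s$entities, length(s$tokens))
    list(ids = tokens_to_ids(s$tokens, vocab),
         tag_ids = match(tags, vocab_tags),
         n = length(s$tokens))
  })
}

# Pad a list of examples into id/tag matrices plus a validity mask.
pad_batch <- function(examples) {
  B <- length(examples)
  T_ <- max(vapply(examples, `[[`, integer(1), "n"))
  ids <- matrix(PAD_ID, B, T_)
  tags <- matrix(1L, B, T_)
  mask <- matrix(FALSE, B, T_)
  for (b in seq_len(B)) {
    n <- examples[[b]]$n
    ids[b, seq_len(n)] <- examples[[b]]$ids
    tags[b, seq_len(n)] <- examples[[b]]$tag_ids
    mask[b, seq_len(n)] <- TRUE
  }
  list(ids = ids, tags = tags, mask = mask)
}

# --- full forward / backward --------------------------------------------

agg_weight_names <- function(method) {
  switch(method,
         multihead = c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wh", "bh"),
         concat = c("Wc", "bc"),
         character(0))
}

extract_agg_weights <- function(params, method) {
  nms <- agg_weight_names(method)
  if (length(nms) == 0) return(NULL)
  w <- params[paste0("agg.", nms)]
  names(w) <- nms
  w
}

# End-to-end forward over one padded batch; optionally the backward pass.
# `meta` carries encoder config, aggregation method/subset/heads and the
# dropout rate. Returns loss, probabilities and (if requested) gradients for
# every trainable parameter.
model_forward <- function(params, meta, batch, training = FALSE,
                          backward = FALSE) {
  cfg <- meta$encoder_config
  enc <- encoder_forward(params, cfg, batch$ids, batch$mask,
                         training = training)
  stack <- enc$stack
  L <- cfg$n_layers
  subset <- meta$layer_subset
  agg_cache <- NULL
  if (meta$method == "multihead") {
    w <- extract_agg_weights(params, "multihead")
    mf <- multihead_fwd(stack, w, subset, meta$n_fusion_heads,
                        cfg$hidden_size %/% meta$n_fusion_heads)
    E0 <- mf$E
    agg_cache <- mf$cache
  } else if (meta$method == "concat") {
    w <- extract_agg_weights(params, "concat")
    cf <- concat_fwd(stack, w, subset)
    E0 <- cf$E
    agg_cache <- cf$cache
  } else if (meta$method == "sum_average") {
    E0 <- Reduce(`+`, stack[subset]) / length(subset)
  } else { # last_layer
    E0 <- stack[[L]]
  }
  drop_e <- dropout_fwd(E0, cfg$dropout_rate, training)
  lh <- linear_fwd(drop_e$out, params[["head.W"]], params[["head.b"]])
  probs <- softmax_rows(lh$out)
  mvec <- as.vector(t(batch$mask))
  goldvec <- as.vector(t(batch$tags))
  n_valid <- sum(mvec)
  p_gold <- probs[cbind(seq_along(goldvec), goldvec)]
  loss <- -sum(log(pmax(p_gold[mvec], 1e-300))) / n_valid
  out <- list(loss = loss, probs = probs, n_valid = n_valid)
  if (!backward) return(out)

  dlogits <- probs
  dlogits[cbind(seq_along(goldvec), goldvec)] <-
    dlogits[cbind(seq_along(goldvec), goldvec)] - 1
  dlogits[!mvec, ] <- 0
  dlogits <- dlogits / n_valid
  hb <- linear_bwd(dlogits, lh, params[["head.W"]])
  grads <- list("head.W" = hb$dW, "head.b" = hb$db)
  dE0 <- dropout_bwd(hb$dx, drop_e)
  if (meta$method == "multihead") {
    ab <- multihead_bwd(dE0, agg_cache, extract_agg_weights(params, "multihead"))
    dstack <- ab$dstack
    names(ab$grads) <- paste0("agg.", names(ab$grads))
    grads <- c(grads, ab$grads)
  } else if (meta$method == "concat") {
    ab <- concat_bwd(dE0, agg_cache, extract_agg_weights(params, "concat"))
    dstack <- ab$dstack
    names(ab$grads) <- paste0("agg.", names(ab$grads))
    grads <- c(grads, ab$grads)
  } else if (meta$method == "sum_average") {
    dstack <- vector("list", L)
    for (l in subset) dstack[[l]] <- dE0 / length(subset)
  } else {
    dstack <- vector("list", L)
    dstack[[L]] <- dE0
  }
  grads <- c(grads, encoder_backward(dstack, enc, params, cfg))
  out$grads <- grads
  out
}

# Initialize all trainable parameters (encoder + aggregator + head) from
# sub-seeds derived from one master seed.
init_model_params <- function(meta, master_seed) {
  cfg <- meta$encoder_config
  cfg$seed <- master_seed
  params <- init_encoder_params(cfg)
  d <- cfg$hidden_size
  if (meta$method == "multihead") {
    ap <- aggregator_params(d, cfg$n_layers,
                            n_fusion_heads = meta$n_fusion_heads,
                            layer_subset = meta$layer_subset,
                            seed = master_seed + 1L)
    w <- ap$weights
    names(w) <- paste0("agg.", names(w))
    params <- c(params, w)
  } else if (meta$method == "concat") {
    cp <- concat_params(d, cfg$n_layers, layer_subset = meta$layer_subset,
                        seed = master_seed + 1L)
    w <- cp$weights
    names(w) <- paste0("agg.", names(w))
    params <- c(params, w)
  }
  head <- output_head(d, seed = master_seed + 2L)
  params[["head.W"]] <- head$W
  params[["head.b"]] <- head$b
  params
}

# --- training ------------------------------------------------------------

#' Train the tagger end to end
#'
#' Minimizes mean per-token negative log-probability of the gold tags
#' (padding masked) with AdamW, evaluates strict entity-level micro-F1 on the
#' validation set after every epoch, and returns the parameters of the best
#' validation epoch. The whole run - initialization, shuffling, dropout - is
#' a pure function of `train_cfg$seed`.
#'
#' @param train_set,validation_set Lists of [annotated_sentence()]
#'   (non-empty).
#' @param encoder_cfg An [encoder_config()]; `vocab_size` is set from the
#'   training vocabulary.
#' @param aggregator_cfg An [aggregator_config()].
#' @param train_cfg A [train_config()].
#' @param quiet Suppress per-epoch progress lines.
#' @return Object of class `mlner_model`: trained parameters, configs,
#'   vocabulary, the per-epoch `history` data.frame (row `epoch = 0` holds
#'   the pre-training loss and validation score), and `best_epoch`.
#' @export
train <- function(train_set, validation_set, encoder_cfg, aggregator_cfg,
                  train_cfg = train_config_desk(), quiet = TRUE) {
  if (length(train_set) == 0) {
    stop("configuration error: empty training set")
  }
  stopifnot(inherits(encoder_cfg, "encoder_config"),
            inherits(aggregator_cfg, "aggregator_config"),
            inherits(train_cfg, "train_config"))
  vocab <- build_vocab(train_set)
  encoder_cfg$vocab_size <- length(vocab)
  subset <- resolve_layer_subset(aggregator_cfg$layer_subset,
                                 encoder_cfg$n_layers)
  if (aggregator_cfg$method == "multihead" &&
      encoder_cfg$hidden_size %% aggregator_cfg$n_fusion_heads != 0L) {
    stop("configuration error: hidden_size must be divisible by n_fusion_heads")
  }
  meta <- list(encoder_config = encoder_cfg, method = aggregator_cfg$method,
               layer_subset = subset,
               n_fusion_heads = aggregator_cfg$n_fusion_heads)
  maxlen <- encoder_cfg$max_sentence_length
  examples <- prepare_examples(train_set, vocab, maxlen)
  val_gold <- lapply(validation_set, truncate_sentence, max_len = maxlen)

  params <- init_model_params(meta, train_cfg$seed)
  state <- adamw_init(params)
  n <- length(examples)
  batch_starts <- seq(1L, n, by = train_cfg$batch_size)

  eval_split <- function(params, sentences, gold) {
    preds <- predict_tags_internal(params, meta, vocab, sentences)
    rep <- evaluate(gold, preds)
    c(precision = rep$micro$precision, recall = rep$micro$recall,
      f1 = rep$micro$f1)
  }
  mean_loss <- function(params) {
    tot <- 0; ntok <- 0
    for (s in batch_starts) {
      idx <- s:min(s + train_cfg$batch_size - 1L, n)
      b <- pad_batch(examples[idx])
      fw <- model_forward(params, meta, b, training = FALSE)
      tot <- tot + fw$loss * fw$n_valid
      ntok <- ntok + fw$n_valid
    }
    tot / ntok
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_precision = numeric(0), val_recall = numeric(0),
                        val_f1 = numeric(0))
  init_loss <- mean_loss(params)
  m0 <- eval_split(params, validation_set, val_gold)
  history[1, ] <- list(0L, init_loss, m0[["precision"]], m0[["recall"]],
                       m0[["f1"]])
  best <- list(f1 = -Inf, params = NULL, epoch = NA_integer_)

  with_seed(train_cfg$seed + 3L, {
    for (epoch in seq_len(train_cfg$epochs)) {
      perm <- sample.int(n)
      tot <- 0; ntok <- 0
      for (bi in seq_along(batch_starts)) {
        s <- batch_starts[bi]
        idx <- perm[s:min(s + train_cfg$batch_size - 1L, n)]
        b <- pad_batch(examples[idx])
        fw <- model_forward(params, meta, b, training = TRUE, backward = TRUE)
        if (!is.finite(fw$loss)) {
          stop(sprintf("training error: non-finite loss at epoch %d, batch %d",
                       epoch, bi))
        }
        st <- adamw_step(params, fw$grads, state, train_cfg$learning_rate,
                         train_cfg$weight_decay)
        params <- st$params
        state <- st$state
        tot <- tot + fw$loss * fw$n_valid
        ntok <- ntok + fw$n_valid
      }
      m <- eval_split(params, validation_set, val_gold)
      history[epoch + 1L, ] <- list(epoch, tot / ntok, m[["precision"]],
                                    m[["recall"]], m[["f1"]])
      if (m[["f1"]] > best$f1) {
        best <- list(f1 = m[["f1"]], params = params, epoch = epoch)
      }
      if (!quiet) {
        message(sprintf("epoch %d  loss %.4f  val F1 %.4f", epoch, tot / ntok,
                        m[["f1"]]))
      }
    }
  })
  if (is.null(best$params)) { # e.g. validation set empty of entities
    best <- list(f1 = history$val_f1[nrow(history)], params = params,
                 epoch = train_cfg$epochs)
  }
  structure(list(params = best$params, encoder_config = encoder_cfg,
                 aggregator = meta[c("method", "layer_subset",
                                     "n_fusion_heads")],
                 train_config = train_cfg, vocab = vocab,
                 history = history, best_epoch = best$epoch),
            class = "mlner_model")
}

#' @export
print.mlner_model <- function(x, ...) {
  cat(sprintf("<mlner_model> %s fusion over layers {%s}, L=%d d=%d\n",
              x$aggregator$method,
              paste(x$aggregator$layer_subset, collapse = ","),
              x$encoder_config$n_layers, x$encoder_config$hidden_size))
  cat(sprintf("  best epoch %d, validation micro-F1 %.4f\n", x$best_epoch,
              x$history$val_f1[x$history$epoch == x$best_epoch]))
  invisible(x)
}

# Batched greedy decoding. Positions beyond max_sentence_length (which the
# model never sees) are predicted "O" so output lengths match the input.
predict_tags_internal <- function(params, meta, vocab, sentences,
                                  batch_size = 32L) {
  if (length(sentences) == 0L) return(list())
  vocab_tags <- tag_vocabulary()
  maxlen <- meta$encoder_config$max_sentence_length
  out <- vector("list", length(sentences))
  starts <- seq(1L, length(sentences), by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, length(sentences))
    exs <- lapply(sentences[idx], function(sen) {
      toks <- utils::head(sen$tokens, maxlen)
      list(ids = tokens_to_ids(toks, vocab), tag_ids = rep(1L, length(toks)),
           n = length(toks))
    })
    b <- pad_batch(exs)
    fw <- model_forward(params, meta, b, training = FALSE)
    T_ <- ncol(b$ids)
    pick <- max.col(fw$probs, ties.method = "first")
    for (j in seq_along(idx)) {
      nfull <- length(sentences[[idx[j]]]$tokens)
      ncut <- exs[[j]]$n
      rows <- ((j - 1L) * T_ + 1L):((j - 1L) * T_ + ncut)
      tags <- vocab_tags[pick[rows]]
      if (nfull > ncut) tags <- c(tags, rep("O", nfull - ncut))
      out[[idx[j]]] <- tags
    }
  }
  out
}

#' Predict tag sequences for sentences
#'
#' @param model A trained `mlner_model`.
#' @param sentences List of [annotated_sentence()] (gold entities, if any,
#'   are ignored).
#' @return List of character tag vectors, one per sentence, each the length
#'   of the sentence.
#' @export
predict_tags <- function(model, sentences) {
  stopifnot(inherits(model, "mlner_model"))
  predict_tags_internal(model$params,
                        c(list(encoder_config = model$encoder_config),
                          model$aggregator),
                        model$vocab, sentences)
}

#' Tag a column file
#'
#' Reads a CoNLL-style column file, replaces the tags with the model's
#' predictions and writes the result: tokens are byte-identical between input
#' and output and the sentence count is preserved.
#'
#' @param model A trained `mlner_model`.
#' @param column_file_in,column_file_out Input and output paths.
#' @return `column_file_out`, invisibly.
#' @export
predict_file <- function(model, column_file_in, column_file_out) {
  sentences <- read_column_file(column_file_in)
  preds <- predict_tags(model, sentences)
  tagged <- Map(function(s, tg) list(tokens = s$tokens, tags = tg),
                sentences, preds)
  write_column_file(tagged, column_file_out)
  invisible(column_file_out)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores every parameter array under its name (layer index
#' included), the configs, the vocabulary and the training history. A
#' reloaded model reproduces predictions and validation metrics exactly.
#'
#' @param model A `mlner_model`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mlner_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mlner_model")) {
    stop("checkpoint does not contain an mlner_model")
  }
  model
}
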