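# Small trainable transformer encoder exposing the hidden states of every
# layer. The layer stack h_1..h_L (one (n, d) matrix per transform-block,
# h_l = Trm(h_{l-1}), h_0 = the input embedding) is the raw material for the
# multi-level fusion in aggregate.R.

#' Encoder configuration
#'
#' Defaults mirror a BERT-base-sized encoder (12 layers, hidden size 768,
#' 12 self-attention heads, maximum sentence length 64, dropout 0.3). Tests
#' and desk-scale experiments use a much smaller encoder; see
#' [encoder_config_desk()].
#'
#' @param n_layers Number of transform-blocks L (>= 1).
#' @param hidden_size Hidden width d; must be divisible by `n_encoder_heads`.
#' @param n_encoder_heads Self-attention heads inside each transform-block.
#' @param vocab_size Token vocabulary size (including `<pad>` and `<unk>`).
#' @param max_sentence_length Maximum training sentence length; longer
#'   sentences are truncated (gold spans crossing the boundary are dropped,
#'   not clipped).
#' @param dropout_rate Dropout rate in `[0, 1)`, applied during training only.
#' @param ffn_mult Feed-forward width multiplier (inner size `ffn_mult * d`).
#' @param activation Feed-forward activation (`"relu"`).
#' @param seed Integer seed for parameter initialization.
#' @return Object of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 12L, hidden_size = 768L,
                           n_encoder_heads = 12L, vocab_size = 100L,
                           max_sentence_length = 64L, dropout_rate = 0.3,
                           ffn_mult = 4L, activation = "relu", seed = 1L) {
  n_layers <- as.integer(n_layers)
  hidden_size <- as.integer(hidden_size)
  n_encoder_heads <- as.integer(n_encoder_heads)
  stopifnot(n_layers >= 1L, hidden_size >= 1L, n_encoder_heads >= 1L,
            max_sentence_length >= 1L, vocab_size >= 2L,
            dropout_rate >= 0, dropout_rate < 1)
  if (hidden_size %% n_encoder_heads != 0L) {
    stop("hidden_size must be divisible by n_encoder_heads")
  }
  structure(list(n_layers = n_layers, hidden_size = hidden_size,
                 n_encoder_heads = n_encoder_heads,
                 vocab_size = as.integer(vocab_size),
                 max_sentence_length = as.integer(max_sentence_length),
                 dropout_rate = dropout_rate, ffn_mult = as.integer(ffn_mult),
                 activation = match.arg(activation, "relu"),
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Desk-scale encoder configuration
#'
#' A small encoder (4 layers, hidden size 64, 4 heads) that trains from
#' random initialization on one CPU in minutes; used by the synthetic-corpus
#' experiments and tests.
#'
#' @param ... Overrides passed to [encoder_config()].
#' @return Object of class `encoder_config`.
#' @export
encoder_config_desk <- function(...) {
  args <- utils::modifyList(
    list(n_layers = 4L, hidden_size = 64L, n_encoder_heads = 4L,
         max_sentence_length = 64L, dropout_rate = 0.3, seed = 1L),
    list(...))
  do.call(encoder_config, args)
}

# --- vocabulary ---------------------------------------------------------

PAD_ID <- 1L
UNK_ID <- 2L

#' Build a character vocabulary from a corpus
#'
#' @param sentences List of [annotated_sentence()].
#' @return Named integer vector mapping characters to ids; ids 1 and 2 are
#'   reserved for `<pad>` and `<unk>`.
#' @export
build_vocab <- function(sentences) {
  chars <- sort(unique(unlist(lapply(sentences, `[[`, "tokens"))))
  ids <- seq_along(chars) + 2L
  names(ids) <- chars
  c("<pad>" = PAD_ID, "<unk>" = UNK_ID, ids)
}

tokens_to_ids <- function(tokens, vocab) {
  ids <- unname(vocab[tokens])
  ids[is.na(ids)] <- UNK_ID
  as.integer(ids)
}

# --- parameters ---------------------------------------------------------

# Names of one transform-block's parameters, in initialization order.
block_param_names <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
                       "ln1.g", "ln1.b", "W1", "b1", "W2", "b2",
                       "ln2.g", "ln2.b")

layer_prefix <- function(l) sprintf("enc.%02d.", l)

# Expected (nrow, ncol) of every encoder parameter; vectors are length-n
# numeric (ncol = NA).
encoder_param_shapes <- function(cfg) {
  d <- cfg$hidden_size
  f <- cfg$ffn_mult * d
  shapes <- list(
    "emb.tok" = c(cfg$vocab_size, d),
    "emb.seg" = c(1L, d),
    "emb.pos" = c(cfg$max_sentence_length, d)
  )
  for (l in seq_len(cfg$n_layers)) {
    p <- layer_prefix(l)
    shapes[[paste0(p, "Wq")]] <- c(d, d)
    shapes[[paste0(p, "bq")]] <- c(d, NA)
    shapes[[paste0(p, "Wk")]] <- c(d, d)
    shapes[[paste0(p, "bk")]] <- c(d, NA)
    shapes[[paste0(p, "Wv")]] <- c(d, d)
    shapes[[paste0(p, "bv")]] <- c(d, NA)
    shapes[[paste0(p, "Wo")]] <- c(d, d)
    shapes[[paste0(p, "bo")]] <- c(d, NA)
    shapes[[paste0(p, "ln1.g")]] <- c(d, NA)
    shapes[[paste0(p, "ln1.b")]] <- c(d, NA)
    shapes[[paste0(p, "W1")]] <- c(d, f)
    shapes[[paste0(p, "b1")]] <- c(f, NA)
    shapes[[paste0(p, "W2")]] <- c(f, d)
    shapes[[paste0(p, "b2")]] <- c(d, NA)
    shapes[[paste0(p, "ln2.g")]] <- c(d, NA)
    shapes[[paste0(p, "ln2.b")]] <- c(d, NA)
  }
  shapes
}

# Initialize one parameter from its shape spec: Gaussian(0, 0.02) matrices,
# zero biases, unit layer-norm gains.
init_param <- function(name, shape) {
  if (is.na(shape[2])) {
    if (grepl("ln[12]\\.g$", name)) rep(1, shape[1]) else rep(0, shape[1])
  } else {
    init_mat(shape[1], shape[2])
  }
}

init_encoder_params <- function(cfg) {
  shapes <- encoder_param_shapes(cfg)
  with_seed(cfg$seed, {
    params <- vector("list", length(shapes))
    names(params) <- names(shapes)
    for (nm in names(shapes)) params[[nm]] <- init_param(nm, shapes[[nm]])
    params
  })
}

#' Create a tiny trainable encoder
#'
#' @param config An [encoder_config()]; `config$vocab_size` is overridden by
#'   `length(vocab)`.
#' @param vocab Named integer vocabulary from [build_vocab()].
#' @param params Optional pre-built named parameter list (checked against the
#'   expected shapes); if `NULL`, parameters are initialized from
#'   `config$seed`.
#' @return Object of class `mlner_encoder` with fields `config`, `vocab`,
#'   `params`.
#' @export
new_encoder <- function(config, vocab, params = NULL) {
  stopifnot(inherits(config, "encoder_config"))
  config$vocab_size <- length(vocab)
  if (is.null(params)) {
    params <- init_encoder_params(config)
  } else {
    check_param_shapes(params, encoder_param_shapes(config), "encoder")
  }
  structure(list(config = config, vocab = vocab, params = params),
            class = "mlner_encoder")
}

check_param_shapes <- function(params, shapes, what) {
  missing <- setdiff(names(shapes), names(params))
  if (length(missing) > 0) {
    stop(sprintf("adapter error: %s parameters missing: %s", what,
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    p <- params[[nm]]
    ok <- if (is.na(sh[2])) {
      is.numeric(p) && !is.matrix(p) && length(p) == sh[1]
    } else {
      is.matrix(p) && nrow(p) == sh[1] && ncol(p) == sh[2]
    }
    if (!ok) {
      stop(sprintf("adapter error: %s parameter '%s' has the wrong shape",
                   what, nm))
    }
  }
  invisible(TRUE)
}

#' Number of encoder parameters
#' @param encoder An `mlner_encoder`.
#' @return Total scalar parameter count.
#' @export
n_encoder_params <- function(encoder) {
  sum(vapply(encoder$params, length, integer(1)))
}

#' Wrap an external parameter source as an encoder
#'
#' Adapter seam for pretrained weights: any source exposing an
#' [encoder_config()], a vocabulary and a complete named parameter list with
#' the expected shapes is wrapped into an encoder with the same [encode()]
#' contract as the built-in one. An `mlner_encoder` is itself a valid source
#' (identity adapter).
#'
#' @param source An `mlner_encoder`, or a list with fields `config`, `vocab`,
#'   `params`.
#' @return An `mlner_encoder`.
#' @export
load_pretrained_adapter <- function(source) {
  if (inherits(source, "mlner_encoder")) {
    check_param_shapes(source$params, encoder_param_shapes(source$config),
                       "encoder")
    return(source)
  }
  if (!is.list(source) || is.null(source$config) || is.null(source$params) ||
      is.null(source$vocab)) {
    stop("adapter error: source must provide config, vocab and params")
  }
  new_encoder(source$config, source$vocab, params = source$params)
}

# --- forward / backward -------------------------------------------------

# Embedding forward for a padded id matrix (B sentences x T positions,
# sentence-major row order). Output rows: r = (b-1)*T + t.
embed_fwd <- function(params, ids) {
  B <- nrow(ids); T_ <- ncol(ids)
  idvec <- as.vector(t(ids))
  posvec <- rep(seq_len(T_), times = B)
  x <- params[["emb.tok"]][idvec, , drop = FALSE] +
    params[["emb.pos"]][posvec, , drop = FALSE]
  x <- sweep(x, 2L, params[["emb.seg"]][1L, ], "+")
  list(out = x, idvec = idvec, posvec = posvec)
}

embed_bwd <- function(dx, cache, params) {
  dtok <- matrix(0, nrow(params[["emb.tok"]]), ncol(dx))
  agg <- rowsum(dx, group = cache$idvec)
  dtok[as.integer(rownames(agg)), ] <- agg
  dpos <- matrix(0, nrow(params[["emb.pos"]]), ncol(dx))
  aggp <- rowsum(dx, group = cache$posvec)
  dpos[as.integer(rownames(aggp)), ] <- aggp
  list("emb.tok" = dtok, "emb.pos" = dpos,
       "emb.seg" = matrix(colSums(dx), 1L))
}

block_layer_params <- function(params, l) {
  p <- layer_prefix(l)
  out <- params[paste0(p, block_param_names)]
  names(out) <- block_param_names
  out
}

# One transform-block (post-layer-norm): self-attention + residual + LN,
# feed-forward + residual + LN.
block_fwd <- function(x, p, cfg, B, T_, key_mask, training) {
  d <- cfg$hidden_size
  H <- cfg$n_encoder_heads
  dh <- d %/% H
  lq <- linear_fwd(x, p$Wq, p$bq)
  lk <- linear_fwd(x, p$Wk, p$bk)
  lv <- linear_fwd(x, p$Wv, p$bv)
  ctx <- matrix(0, nrow(x), d)
  attn <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T_ + 1L):(b * T_)
    masked <- !key_mask[b, ]
    attn[[b]] <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- head_cols(h, dh)
      S <- (lq$out[rows, cols, drop = FALSE] %*%
              t(lk$out[rows, cols, drop = FALSE])) / sqrt(dh)
      if (any(masked)) S[, masked] <- -Inf
      P <- softmax_rows(S)
      attn[[b]][[h]] <- P
      ctx[rows, cols] <- P %*% lv$out[rows, cols, drop = FALSE]
    }
  }
  lo <- linear_fwd(ctx, p$Wo, p$bo)
  do1 <- dropout_fwd(lo$out, cfg$dropout_rate, training)
  r1 <- x + do1$out
  ln1 <- layernorm_fwd(r1, p$`ln1.g`, p$`ln1.b`)
  f1 <- linear_fwd(ln1$out, p$W1, p$b1)
  rl <- relu_fwd(f1$out)
  f2 <- linear_fwd(rl$out, p$W2, p$b2)
  do2 <- dropout_fwd(f2$out, cfg$dropout_rate, training)
  r2 <- ln1$out + do2$out
  ln2 <- layernorm_fwd(r2, p$`ln2.g`, p$`ln2.b`)
  list(out = ln2$out,
       cache = list(lq = lq, lk = lk, lv = lv, attn = attn, lo = lo,
                    do1 = do1, ln1 = ln1, f1 = f1, rl = rl, f2 = f2,
                    do2 = do2, ln2 = ln2, B = B, T_ = T_))
}

block_bwd <- function(dout, cache, p, cfg) {
  d <- cfg$hidden_size
  H <- cfg$n_encoder_heads
  dh <- d %/% H
  g2 <- layernorm_bwd(dout, cache$ln2, p$`ln2.g`)
  df2 <- dropout_bwd(g2$dx, cache$do2)
  l2b <- linear_bwd(df2, cache$f2, p$W2)
  drl <- relu_bwd(l2b$dx, cache$rl)
  l1b <- linear_bwd(drl, cache$f1, p$W1)
  d_ln1 <- g2$dx + l1b$dx
  g1 <- layernorm_bwd(d_ln1, cache$ln1, p$`ln1.g`)
  dlo_out <- dropout_bwd(g1$dx, cache$do1)
  lob <- linear_bwd(dlo_out, cache$lo, p$Wo)
  dctx <- lob$dx
  B <- cache$B; T_ <- cache$T_
  dQ <- matrix(0, nrow(dctx), d)
  dK <- matrix(0, nrow(dctx), d)
  dV <- matrix(0, nrow(dctx), d)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T_ + 1L):(b * T_)
    for (h in seq_len(H)) {
      cols <- head_cols(h, dh)
      P <- cache$attn[[b]][[h]]
      dc <- dctx[rows, cols, drop = FALSE]
      dP <- dc %*% t(cache$lv$out[rows, cols, drop = FALSE])
      dS <- softmax_rows_bwd(dP, P)
      dQ[rows, cols] <- dS %*% cache$lk$out[rows, cols, drop = FALSE] / sqrt(dh)
      dK[rows, cols] <- t(dS) %*% cache$lq$out[rows, cols, drop = FALSE] / sqrt(dh)
      dV[rows, cols] <- t(P) %*% dc
    }
  }
  lqb <- linear_bwd(dQ, cache$lq, p$Wq)
  lkb <- linear_bwd(dK, cache$lk, p$Wk)
  lvb <- linear_bwd(dV, cache$lv, p$Wv)
  dx <- g1$dx + lqb$dx + lkb$dx + lvb$dx
  grads <- list(Wq = lqb$dW, bq = lqb$db, Wk = lkb$dW, bk = lkb$db,
                Wv = lvb$dW, bv = lvb$db, Wo = lob$dW, bo = lob$db,
                "ln1.g" = g1$dgamma, "ln1.b" = g1$dbeta,
                W1 = l1b$dW, b1 = l1b$db, W2 = l2b$dW, b2 = l2b$db,
                "ln2.g" = g2$dgamma, "ln2.b" = g2$dbeta)
  list(dx = dx, grads = grads)
}

# Full encoder forward over a padded batch. Returns the stack of L per-layer
# activation matrices ((B*T) x d) plus caches for the backward pass.
encoder_forward <- function(params, cfg, ids, key_mask, training = FALSE) {
  emb <- embed_fwd(params, ids)
  B <- nrow(ids); T_ <- ncol(ids)
  L <- cfg$n_layers
  stack <- vector("list", L)
  caches <- vector("list", L)
  h <- emb$out
  for (l in seq_len(L)) {
    res <- block_fwd(h, block_layer_params(params, l), cfg, B, T_, key_mask,
                     training)
    h <- res$out
    stack[[l]] <- h
    caches[[l]] <- res$cache
  }
  list(stack = stack, caches = caches, emb = emb)
}

# Backward through the encoder given per-layer upstream gradients dstack
# (list of length L; NULL entries mean zero gradient into that layer's
# output). Returns named parameter gradients.
encoder_backward <- function(dstack, fwd, params, cfg) {
  L <- cfg$n_layers
  grads <- list()
  dh <- NULL
  for (l in rev(seq_len(L))) {
    dout <- dstack[[l]]
    if (is.null(dout)) dout <- 0
    dout <- dout + if (is.null(dh)) 0 else dh
    if (is.null(dim(dout))) {
      # no gradient reaches this layer or above
      dh <- NULL
      next
    }
    bb <- block_bwd(dout, fwd$caches[[l]], block_layer_params(params, l), cfg)
    dh <- bb$dx
    names(bb$grads) <- paste0(layer_prefix(l), names(bb$grads))
    grads <- c(grads, bb$grads)
  }
  if (!is.null(dh)) {
    grads <- c(grads, embed_bwd(dh, fwd$emb, params))
  }
  grads
}

# --- public single-sentence API -----------------------------------------

#' Input embedding for one sentence
#'
#' The per-token embedding is the elementwise sum of a token lookup, a
#' (single-id) segment lookup and a position lookup.
#'
#' @param encoder An `mlner_encoder`.
#' @param tokens Character vector of single-character tokens; out-of-vocabulary
#'   characters map to `<unk>`, sentences longer than the configured maximum
#'   are truncated.
#' @return Numeric matrix of shape (n, d).
#' @export
embed <- function(encoder, tokens) {
  stopifnot(inherits(encoder, "mlner_encoder"))
  if (length(tokens) < 1) stop("cannot embed an empty sentence")
  tokens <- utils::head(tokens, encoder$config$max_sentence_length)
  ids <- matrix(tokens_to_ids(tokens, encoder$vocab), nrow = 1L)
  embed_fwd(encoder$params, ids)$out
}

#' Encode one sentence into a layer stack
#'
#' Runs the full encoder and returns the hidden states of every
#' transform-block: a list of L matrices of shape (n, d), `h_l = Trm(h_{l-1})`
#' with `h_0` the input embedding. In evaluation mode (`training = FALSE`,
#' the default) the map is deterministic.
#'
#' @inheritParams embed
#' @param training Apply dropout (consumes the current RNG stream).
#' @param truncate If `FALSE`, sentences longer than
#'   `config$max_sentence_length` raise an error instead of being truncated.
#' @return Object of class `layer_stack`: list of L (n, d) matrices.
#' @export
encode <- function(encoder, tokens, training = FALSE, truncate = TRUE) {
  stopifnot(inherits(encoder, "mlner_encoder"))
  if (length(tokens) < 1) stop("cannot encode an empty sentence")
  maxlen <- encoder$config$max_sentence_length
  if (length(tokens) > maxlen) {
    if (!truncate) {
      stop(sprintf("sentence length %d exceeds max_sentence_length %d",
                   length(tokens), maxlen))
    }
    tokens <- utils::head(tokens, maxlen)
  }
  ids <- matrix(tokens_to_ids(tokens, encoder$vocab), nrow = 1L)
  mask <- matrix(TRUE, 1L, length(tokens))
  stack <- encoder_forward(encoder$params, encoder$config, ids, mask,
                           training = training)$stack
  structure(stack, class = "layer_stack",
            d = encoder$config$hidden_size, n = length(tokens))
}
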