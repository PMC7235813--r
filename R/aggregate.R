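# Fusing the encoder's layer stack into one context embedding per token.
#
# The fused attention is PER-TOKEN ATTENTION OVER LAYERS: for each token
# independently, the query is the projected last-layer state of that token,
# and the keys/values are its projected per-layer states for every layer in
# the configured subset. Each head computes scaled dot-product attention over
# the |subset| layer items; head outputs are concatenated and mixed by a
# square projection. Feature-axis concatenation is a distinct baseline
# (aggregate_concat), as are the per-layer mean (aggregate_sum_average) and
# the plain final state (aggregate_last_layer).

#' Resolve a layer-subset shorthand
#'
#' `"all"` means layers 1..L; `"last2"`, `"last4"`, `"last6"` mean the final
#' 2/4/6 layers. An explicit integer vector is validated. The final layer L is
#' always required (the fusion query is built from it).
#'
#' @param layer_subset Shorthand string or integer vector.
#' @param L Number of encoder layers.
#' @return Sorted integer vector of layer indices, containing `L`.
#' @export
resolve_layer_subset <- function(layer_subset, L) {
  L <- as.integer(L)
  if (is.character(layer_subset) && length(layer_subset) == 1L) {
    k <- switch(layer_subset,
                all = L,
                last2 = 2L,
                last4 = 4L,
                last6 = 6L,
                stop(sprintf("configuration error: unknown layer subset '%s'",
                             layer_subset)))
    if (k > L) {
      stop(sprintf(
        "configuration error: layer subset '%s' needs %d layers but the encoder has %d",
        layer_subset, k, L))
    }
    return((L - k + 1L):L)
  }
  subset <- sort(unique(as.integer(layer_subset)))
  if (length(subset) == 0L) {
    stop("configuration error: layer subset is empty")
  }
  if (any(subset < 1L) || any(subset > L)) {
    stop(sprintf("configuration error: layer subset references layers outside 1..%d", L))
  }
  if (!(L %in% subset)) {
    stop("configuration error: the final layer must be part of the layer subset")
  }
  subset
}

#' Parameters of the multi-head layer-fusion attention
#'
#' Holds the query/key/value projections (built per token from the layer
#' states), the head-mixing projection, the head count and the layer subset.
#' All projections are square (d x d); each head sees a contiguous block of
#' `d / n_fusion_heads` features, and the scaled dot-product uses the per-head
#' key dimension as scaling denominator.
#'
#' @param d Hidden size of the encoder.
#' @param L Number of encoder layers.
#' @param n_fusion_heads Number of fusion heads (must divide `d`; default 12).
#' @param layer_subset Layers whose states are fused; see
#'   [resolve_layer_subset()]. Default `"all"`.
#' @param seed Integer seed for initialization (ignored when `weights` given).
#' @param weights Optional named list `Wq, bq, Wk, bk, Wv, bv, Wh, bh` to set
#'   the projections by hand.
#' @return Object of class `aggregator_params`.
#' @export
aggregator_params <- function(d, L, n_fusion_heads = 12L, layer_subset = "all",
                              seed = 1L, weights = NULL) {
  d <- as.integer(d)
  n_fusion_heads <- as.integer(n_fusion_heads)
  if (d %% n_fusion_heads != 0L) {
    stop("configuration error: d must be divisible by n_fusion_heads")
  }
  subset <- resolve_layer_subset(layer_subset, L)
  if (is.null(weights)) {
    weights <- with_seed(seed, list(
      Wq = init_mat(d, d), bq = rep(0, d),
      Wk = init_mat(d, d), bk = rep(0, d),
      Wv = init_mat(d, d), bv = rep(0, d),
      Wh = init_mat(d, d), bh = rep(0, d)))
  } else {
    need <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wh", "bh")
    if (!all(need %in% names(weights))) {
      stop("weights must contain: ", paste(need, collapse = ", "))
    }
    for (nm in c("Wq", "Wk", "Wv", "Wh")) {
      if (!is.matrix(weights[[nm]]) || any(dim(weights[[nm]]) != d)) {
        stop(sprintf("weights$%s must be a %d x %d matrix", nm, d, d))
      }
    }
    for (nm in c("bq", "bk", "bv", "bh")) {
      if (length(weights[[nm]]) != d) {
        stop(sprintf("weights$%s must have length %d", nm, d))
      }
    }
  }
  structure(list(d = d, L = as.integer(L), n_fusion_heads = n_fusion_heads,
                 d_head = d %/% n_fusion_heads, layer_subset = subset,
                 weights = weights),
            class = "aggregator_params")
}

check_stack <- function(stack, d = NULL) {
  if (!is.list(stack) || length(stack) == 0L) {
    stop("a layer stack must be a non-empty list of (n, d) matrices")
  }
  if (!is.null(d) && ncol(stack[[1]]) != d) {
    stop(sprintf("configuration error: stack width %d does not match params d = %d",
                 ncol(stack[[1]]), d))
  }
  invisible(TRUE)
}

# Internal forward: stack entries are (N, d) matrices (N tokens, possibly a
# whole padded batch flattened). Returns E, the (N, S, H) attention array and
# the cache for the backward pass.
multihead_fwd <- function(stack, w, subset, H, d_head,
                          force_uniform = FALSE) {
  L <- length(stack)
  S <- length(subset)
  N <- nrow(stack[[L]])
  d <- ncol(stack[[L]])
  Q <- sweep(stack[[L]] %*% w$Wq, 2L, w$bq, "+")
  Ks <- lapply(subset, function(l) sweep(stack[[l]] %*% w$Wk, 2L, w$bk, "+"))
  Vs <- lapply(subset, function(l) sweep(stack[[l]] %*% w$Wv, 2L, w$bv, "+"))
  alpha <- array(0, dim = c(N, S, H))
  concat <- matrix(0, N, d)
  for (h in seq_len(H)) {
    cols <- head_cols(h, d_head)
    logits <- matrix(0, N, S)
    for (s in seq_len(S)) {
      logits[, s] <- rowSums(Q[, cols, drop = FALSE] *
                               Ks[[s]][, cols, drop = FALSE]) / sqrt(d_head)
    }
    if (force_uniform) logits[] <- 0
    A <- softmax_rows(logits)
    alpha[, , h] <- A
    acc <- matrix(0, N, d_head)
    for (s in seq_len(S)) {
      acc <- acc + A[, s] * Vs[[s]][, cols, drop = FALSE]
    }
    concat[, cols] <- acc
  }
  E <- sweep(concat %*% w$Wh, 2L, w$bh, "+")
  list(E = E, alpha = alpha,
       cache = list(Q = Q, Ks = Ks, Vs = Vs, alpha = alpha, concat = concat,
                    subset = subset, H = H, d_head = d_head, stack = stack,
                    force_uniform = force_uniform))
}

# Backward for multihead_fwd. Returns per-layer stack gradients (list of
# length L, NULL where no gradient flows) and weight gradients.
multihead_bwd <- function(dE, cache, w) {
  subset <- cache$subset
  S <- length(subset)
  H <- cache$H
  d_head <- cache$d_head
  L <- length(cache$stack)
  N <- nrow(dE)
  d <- ncol(dE)
  dWh <- crossprod(cache$concat, dE)
  dbh <- colSums(dE)
  dconcat <- dE %*% t(w$Wh)
  dQ <- matrix(0, N, d)
  dKs <- lapply(seq_len(S), function(s) matrix(0, N, d))
  dVs <- lapply(seq_len(S), function(s) matrix(0, N, d))
  for (h in seq_len(H)) {
    cols <- head_cols(h, d_head)
    A <- cache$alpha[, , h, drop = FALSE]
    dim(A) <- c(N, S)
    dacc <- dconcat[, cols, drop = FALSE]
    dA <- matrix(0, N, S)
    for (s in seq_len(S)) {
      Vh <- cache$Vs[[s]][, cols, drop = FALSE]
      dA[, s] <- rowSums(dacc * Vh)
      dVs[[s]][, cols] <- dVs[[s]][, cols, drop = FALSE] + A[, s] * dacc
    }
    if (!cache$force_uniform) {
      dlog <- softmax_rows_bwd(dA, A)
      for (s in seq_len(S)) {
        dQ[, cols] <- dQ[, cols, drop = FALSE] +
          dlog[, s] * cache$Ks[[s]][, cols, drop = FALSE] / sqrt(d_head)
        dKs[[s]][, cols] <- dKs[[s]][, cols, drop = FALSE] +
          dlog[, s] * cache$Q[, cols, drop = FALSE] / sqrt(d_head)
      }
    }
  }
  dstack <- vector("list", L)
  add_into <- function(l, m) {
    dstack[[l]] <<- if (is.null(dstack[[l]])) m else dstack[[l]] + m
  }
  dWk <- matrix(0, d, d); dbk <- rep(0, d)
  dWv <- matrix(0, d, d); dbv <- rep(0, d)
  for (s in seq_len(S)) {
    l <- subset[s]
    hl <- cache$stack[[l]]
    dWk <- dWk + crossprod(hl, dKs[[s]])
    dbk <- dbk + colSums(dKs[[s]])
    dWv <- dWv + crossprod(hl, dVs[[s]])
    dbv <- dbv + colSums(dVs[[s]])
    add_into(l, dKs[[s]] %*% t(w$Wk) + dVs[[s]] %*% t(w$Wv))
  }
  dWq <- crossprod(cache$stack[[L]], dQ)
  dbq <- colSums(dQ)
  add_into(L, dQ %*% t(w$Wq))
  list(dstack = dstack,
       grads = list(Wq = dWq, bq = dbq, Wk = dWk, bk = dbk,
                    Wv = dWv, bv = dbv, Wh = dWh, bh = dbh))
}

#' Multi-head attention fusion of a layer stack
#'
#' For each token: `Q = Wq h_L + bq` from the final layer; `K_l = Wk h_l +
#' bk` and `V_l = Wv h_l + bv` for every layer `l` in the subset; per head,
#' `softmax(Q K' / sqrt(d_head)) V` over the layer items; heads are
#' concatenated and mixed by `Wh, bh`. Attention weights per token and head
#' are nonnegative and sum to 1 over the layer subset.
#'
#' @param stack Layer stack: list of L matrices of shape (n, d) (e.g. from
#'   [encode()]).
#' @param params An [aggregator_params()] matching `d` and `L`.
#' @param return_attention If `TRUE`, attach the (n, |subset|, heads)
#'   attention array as attribute `"attention"`.
#' @param force_uniform Force all attention logits to zero (uniform weights);
#'   used to check the reduction to the sum-average baseline.
#' @return Context embedding: numeric matrix (n, d).
#' @export
aggregate_multihead <- function(stack, params, return_attention = FALSE,
                                force_uniform = FALSE) {
  stopifnot(inherits(params, "aggregator_params"))
  check_stack(stack, params$d)
  if (length(stack) != params$L) {
    stop(sprintf("configuration error: stack has %d layers but params expect L = %d",
                 length(stack), params$L))
  }
  res <- multihead_fwd(stack, params$weights, params$layer_subset,
                       params$n_fusion_heads, params$d_head,
                       force_uniform = force_uniform)
  out <- res$E
  if (return_attention) attr(out, "attention") <- res$alpha
  out
}

# --- concatenation baseline ---------------------------------------------

#' Parameters for the concatenation baseline
#'
#' @param d Hidden size.
#' @param L Number of encoder layers.
#' @param layer_subset Layers to concatenate (see [resolve_layer_subset()]).
#' @param seed Seed for initialization.
#' @param weights Optional list `Wc` ((k*d) x d) and `bc` (length d).
#' @return Object of class `concat_params`.
#' @export
concat_params <- function(d, L, layer_subset = "all", seed = 1L,
                          weights = NULL) {
  d <- as.integer(d)
  subset <- resolve_layer_subset(layer_subset, L)
  k <- length(subset)
  if (is.null(weights)) {
    weights <- with_seed(seed, list(Wc = init_mat(k * d, d), bc = rep(0, d)))
  } else {
    if (!is.matrix(weights$Wc) || nrow(weights$Wc) != k * d ||
        ncol(weights$Wc) != d || length(weights$bc) != d) {
      stop(sprintf("weights$Wc must be %d x %d and weights$bc length %d",
                   k * d, d, d))
    }
  }
  structure(list(d = d, L = as.integer(L), layer_subset = subset,
                 weights = weights),
            class = "concat_params")
}

concat_fwd <- function(stack, w, subset) {
  X <- do.call(cbind, stack[subset])
  E <- sweep(X %*% w$Wc, 2L, w$bc, "+")
  list(E = E, cache = list(X = X, subset = subset, L = length(stack),
                           d = ncol(stack[[1]])))
}

concat_bwd <- function(dE, cache, w) {
  dX <- dE %*% t(w$Wc)
  dstack <- vector("list", cache$L)
  for (s in seq_along(cache$subset)) {
    cols <- ((s - 1L) * cache$d + 1L):(s * cache$d)
    dstack[[cache$subset[s]]] <- dX[, cols, drop = FALSE]
  }
  list(dstack = dstack,
       grads = list(Wc = crossprod(cache$X, dE), bc = colSums(dE)))
}

#' Concatenation fusion of a layer stack
#'
#' Per token, the selected layers' vectors are concatenated along the feature
#' axis (width `|subset| * d`) and projected back to width `d`.
#'
#' @inheritParams aggregate_multihead
#' @param params A [concat_params()].
#' @return Context embedding: numeric matrix (n, d).
#' @export
aggregate_concat <- function(stack, params) {
  stopifnot(inherits(params, "concat_params"))
  check_stack(stack, params$d)
  concat_fwd(stack, params$weights, params$layer_subset)$E
}

# --- parameter-free baselines -------------------------------------------

#' Sum-average fusion of a layer stack
#'
#' Per token, the elementwise mean of the selected layers' vectors.
#'
#' @inheritParams aggregate_multihead
#' @param layer_subset Layers to average (see [resolve_layer_subset()]).
#' @return Context embedding: numeric matrix (n, d).
#' @export
aggregate_sum_average <- function(stack, layer_subset = "all") {
  check_stack(stack)
  subset <- resolve_layer_subset(layer_subset, length(stack))
  Reduce(`+`, stack[subset]) / length(subset)
}

#' Last-layer baseline
#'
#' Returns the final layer's hidden states unchanged (the plain
#' encoder-with-softmax baseline).
#'
#' @inheritParams aggregate_multihead
#' @return Context embedding: numeric matrix (n, d), identical to `h_L`.
#' @export
aggregate_last_layer <- function(stack) {
  check_stack(stack)
  stack[[length(stack)]]
}
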