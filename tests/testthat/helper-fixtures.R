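# Shared fixture builders: everything is generated in code at test time.

# Random non-overlapping span set over a sentence of `len` characters.
random_span_set <- function(len, max_spans = 4L) {
  occupied <- rep(FALSE, len)
  type <- character(0)
  st <- integer(0)
  en <- integer(0)
  for (i in seq_len(sample(0:max_spans, 1L))) {
    s <- sample(0:(len - 1L), 1L)
    e <- min(len, s + sample(1:3, 1L))
    if (e > s && !any(occupied[(s + 1L):e])) {
      occupied[(s + 1L):e] <- TRUE
      type <- c(type, sample(entity_types(), 1L))
      st <- c(st, s)
      en <- c(en, e)
    }
  }
  entity_spans(type, st, en)
}

# Random layer stack: L matrices of shape (n, d).
random_stack <- function(L, n, d, sd = 1) {
  lapply(seq_len(L), function(l) matrix(rnorm(n * d, sd = sd), n, d))
}

# A tiny corpus plus splits, for fast training tests.
tiny_splits <- function(n = 120L, seed = 7L) {
  corp <- generate_corpus(default_corpus_spec(n_sentences = n, seed = seed))
  split_corpus(corp, seed = seed)
}

tiny_encoder_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_layers = 2L, hidden_size = 16L, n_encoder_heads = 2L), list(...))
  do.call(encoder_config_desk, args)
}

tiny_train_cfg <- function(...) {
  args <- utils::modifyList(list(epochs = 2L, batch_size = 16L), list(...))
  do.call(train_config_desk, args)
}
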