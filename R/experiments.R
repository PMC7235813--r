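# Experiment harnesses over the synthetic corpus: assembling-method
# comparison, layer-subset ablation, and dataset-size curves. Every cell of a
# grid sees identical data splits and identical non-varied hyperparameters
# (asserted via a config hash); each cell is repeated and the median-F1 run
# is reported.

# Stable hash of an R object (used to assert cross-cell fairness).
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x, control = c("exact", "niceNames")), tf)
  unname(tools::md5sum(tf))
}

# Train on train/validation, score on test; one experiment cell run.
run_single <- function(splits, encoder_cfg, aggregator_cfg, train_cfg) {
  model <- train(splits$train, splits$validation, encoder_cfg, aggregator_cfg,
                 train_cfg)
  gold <- lapply(splits$test, truncate_sentence,
                 max_len = encoder_cfg$max_sentence_length)
  preds <- predict_tags(model, splits$test)
  list(model = model, report = evaluate(gold, preds))
}

# Repeat a cell with seeds base_seed + 0..(repeats-1) and return the run
# whose test F1 is the median of the ranking (lower median for even counts).
run_cell <- function(splits, encoder_cfg, aggregator_cfg, train_cfg,
                     repeats, base_seed) {
  seeds <- base_seed + seq_len(repeats) - 1L
  runs <- lapply(seeds, function(s) {
    tc <- train_cfg
    tc$seed <- s
    run_single(splits, encoder_cfg, aggregator_cfg, tc)
  })
  f1s <- vapply(runs, function(r) r$report$micro$f1, numeric(1))
  mid <- order(f1s)[ceiling(repeats / 2)]
  list(chosen = runs[[mid]], seed = seeds[mid], f1s = f1s)
}

check_fair_grid <- function(hashes) {
  if (length(unique(hashes)) != 1L) {
    stop("internal error: grid cells differ in non-varied configuration")
  }
  invisible(TRUE)
}

split_or_corpus <- function(corpus, fractions, split_seed) {
  if (is.list(corpus) && !is.null(corpus$train)) return(corpus)
  split_corpus(corpus, fractions, seed = split_seed)
}

cell_row <- function(name_col, name, cell) {
  m <- cell$chosen$report$micro
  out <- data.frame(name, m$precision, m$recall, m$f1, cell$seed,
                    stringsAsFactors = FALSE)
  names(out) <- c(name_col, "precision", "recall", "f1", "seed")
  out
}

#' Compare layer-assembling methods
#'
#' Trains one model per assembling strategy (multi-head fusion,
#' concatenation, sum-average, last-layer) on identical splits with identical
#' hyperparameters and identical repeat seeds, and reports the median-F1 run
#' per method, scored on the held-out test set.
#'
#' @param corpus List of [annotated_sentence()], or a ready split (a list
#'   with `train` / `validation` / `test`).
#' @param methods Subset of `c("multihead", "concat", "sum_average",
#'   "last_layer")`, reported in the given order.
#' @param encoder_cfg,train_cfg Shared model and training configuration.
#' @param layer_subset Layer subset shared by all methods.
#' @param n_fusion_heads Fusion heads for the multihead method.
#' @param fractions,split_seed Split fractions and shuffle seed (ignored when
#'   `corpus` is already split).
#' @param repeats Runs per cell; the median-F1 run is reported.
#' @param seed Base seed for the repeat runs.
#' @return data.frame with columns `method`, `precision`, `recall`, `f1`
#'   (proportions in \[0, 1\]), `seed`; attribute `"all_f1"` holds every
#'   repeat's F1.
#' @export
compare_assembling <- function(corpus,
                               methods = c("multihead", "concat",
                                           "sum_average", "last_layer"),
                               encoder_cfg = encoder_config_desk(),
                               train_cfg = train_config_desk(),
                               layer_subset = "all", n_fusion_heads = 4L,
                               fractions = c(0.6, 0.2, 0.2), split_seed = 1L,
                               repeats = 1L, seed = 1L) {
  known <- c("multihead", "concat", "sum_average", "last_layer")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) {
    stop("configuration error: unknown assembling method(s): ",
         paste(bad, collapse = ", "))
  }
  splits <- split_or_corpus(corpus, fractions, split_seed)
  rows <- list()
  all_f1 <- list()
  hashes <- character(0)
  for (m in methods) {
    agg <- aggregator_config(m, layer_subset = layer_subset,
                             n_fusion_heads = n_fusion_heads)
    hashes <- c(hashes, config_hash(list(encoder_cfg, train_cfg, layer_subset,
                                         repeats, seed)))
    cell <- run_cell(splits, encoder_cfg, agg, train_cfg, repeats, seed)
    rows[[m]] <- cell_row("method", m, cell)
    all_f1[[m]] <- cell$f1s
  }
  check_fair_grid(hashes)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "all_f1") <- all_f1
  out
}

#' Compare extraction-layer subsets
#'
#' Ablation over the number of encoder layers fused by the multi-head
#' attention: each subset (e.g. all layers, the last four, the last two) is
#' trained on identical splits and seeds; rows are reported in the given
#' order.
#'
#' @inheritParams compare_assembling
#' @param subsets Character shorthands or integer vectors accepted by
#'   [resolve_layer_subset()]; a subset larger than the encoder depth is a
#'   configuration error.
#' @return data.frame with columns `subset`, `precision`, `recall`, `f1`,
#'   `seed`.
#' @export
compare_layer_subsets <- function(corpus,
                                  subsets = c("all", "last6", "last4",
                                              "last2"),
                                  encoder_cfg = encoder_config_desk(),
                                  train_cfg = train_config_desk(),
                                  n_fusion_heads = 4L,
                                  fractions = c(0.6, 0.2, 0.2),
                                  split_seed = 1L, repeats = 1L, seed = 1L) {
  for (s in subsets) resolve_layer_subset(s, encoder_cfg$n_layers)
  splits <- split_or_corpus(corpus, fractions, split_seed)
  rows <- list()
  hashes <- character(0)
  for (s in subsets) {
    agg <- aggregator_config("multihead", layer_subset = s,
                             n_fusion_heads = n_fusion_heads)
    hashes <- c(hashes, config_hash(list(encoder_cfg, train_cfg,
                                         n_fusion_heads, repeats, seed)))
    cell <- run_cell(splits, encoder_cfg, agg, train_cfg, repeats, seed)
    rows[[length(rows) + 1L]] <- cell_row("subset", s, cell)
  }
  check_fair_grid(hashes)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dataset-size learning curve
#'
#' Trains the same model on nested subsets of the training split (the
#' sentences of a smaller fraction are always contained in every larger
#' fraction) and scores each on the fixed validation and test splits.
#'
#' @inheritParams compare_assembling
#' @param train_fractions Fractions of the training split in (0, 1].
#' @param aggregator_cfg Model variant to train at every size.
#' @return data.frame with columns `fraction`, `n_train`, `precision`,
#'   `recall`, `f1`, `seed`; attribute `"train_ids"` lists the sentence
#'   indices used at each fraction (for nestedness checks).
#' @export
learning_curve <- function(corpus,
                           train_fractions = c(0.1, 0.3, 0.5, 0.7, 1.0),
                           aggregator_cfg = aggregator_config("multihead",
                                                              n_fusion_heads = 4L),
                           encoder_cfg = encoder_config_desk(),
                           train_cfg = train_config_desk(),
                           fractions = c(0.6, 0.2, 0.2), split_seed = 1L,
                           repeats = 1L, seed = 1L) {
  if (any(train_fractions <= 0) || any(train_fractions > 1)) {
    stop("configuration error: train fractions must lie in (0, 1]")
  }
  splits <- split_or_corpus(corpus, fractions, split_seed)
  n <- length(splits$train)
  ord <- with_seed(split_seed + 1L, sample.int(n))
  rows <- list()
  train_ids <- list()
  hashes <- character(0)
  for (f in train_fractions) {
    k <- as.integer(max(1L, ceiling(f * n)))
    ids <- sort(ord[seq_len(k)])
    sub <- splits
    sub$train <- splits$train[ids]
    hashes <- c(hashes, config_hash(list(encoder_cfg, train_cfg,
                                         aggregator_cfg, repeats, seed)))
    cell <- run_cell(sub, encoder_cfg, aggregator_cfg, train_cfg, repeats,
                     seed)
    row <- cell_row("fraction", f, cell)
    row$n_train <- k
    rows[[length(rows) + 1L]] <- row[, c("fraction", "n_train", "precision",
                                         "recall", "f1", "seed")]
    train_ids[[as.character(f)]] <- ids
  }
  check_fair_grid(hashes)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "train_ids") <- train_ids
  out
}
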