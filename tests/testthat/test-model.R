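test_that("predict_tag_distributions returns normalized rows", {
  d <- 6L
  head <- output_head(d, seed = 2)
  # zero weights -> uniform 1/13
  head0 <- head
  head0$W[] <- 0
  head0$b[] <- 0
  P <- predict_tag_distributions(matrix(rnorm(3 * d), 3, d), head0)
  expect_equal(P, matrix(1 / 13, 3, 13), tolerance = 1e-12)
  # one dominant bias component wins the argmax everywhere
  headb <- head0
  headb$b[5] <- 50
  P2 <- predict_tag_distributions(matrix(rnorm(4 * d), 4, d), headb)
  expect_true(all(max.col(P2) == 5))
  # random inputs: rows sum to 1, nonnegative
  set.seed(8)
  P3 <- predict_tag_distributions(matrix(rnorm(20 * d, sd = 3), 20, d), head)
  expect_true(all(abs(rowSums(P3) - 1) < 1e-6))
  expect_true(all(P3 >= 0))
  expect_error(predict_tag_distributions(matrix(0, 2, d + 1), head),
               "configuration error")
})

test_that("analytic gradients match central finite differences", {
  cfg <- encoder_config(n_layers = 2L, hidden_size = 8L, n_encoder_heads = 2L,
                        vocab_size = 10L, max_sentence_length = 6L,
                        dropout_rate = 0, seed = 5L)
  batch <- list(ids = rbind(c(3L, 4L, 5L, 1L), c(6L, 7L, 1L, 1L)),
                tags = rbind(c(1L, 2L, 13L, 1L), c(3L, 13L, 1L, 1L)),
                mask = rbind(c(TRUE, TRUE, TRUE, FALSE),
                             c(TRUE, TRUE, FALSE, FALSE)))
  set.seed(42)
  for (method in c("multihead", "concat", "sum_average", "last_layer")) {
    meta <- list(encoder_config = cfg, method = method,
                 layer_subset = if (method == "concat") 2L else 1:2,
                 n_fusion_heads = 2L)
    params <- mlner:::init_model_params(meta, 5L)
    fw <- mlner:::model_forward(params, meta, batch, backward = TRUE)
    expect_setequal(names(fw$grads), names(params)) # every param gets a grad
    for (nm in names(fw$grads)) {
      i <- sample(length(params[[nm]]), 1L)
      eps <- 1e-5
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (mlner:::model_forward(pp, meta, batch)$loss -
                mlner:::model_forward(pm, meta, batch)$loss) / (2 * eps)
      expect_equal(fw$grads[[nm]][i], num, tolerance = 1e-4,
                   label = paste(method, nm))
    }
  }
})

test_that("training learns the separable corpus and selects the best epoch", {
  sp <- tiny_splits(n = 600L, seed = 13L)
  m <- train(sp$train, sp$validation, tiny_encoder_cfg(hidden_size = 32L),
             aggregator_config("multihead", n_fusion_heads = 2L),
             tiny_train_cfg(epochs = 5L, learning_rate = 3e-3, seed = 3L))
  h <- m$history
  # pre-training loss is the uniform-prediction cross-entropy, log(13)
  expect_lt(abs(h$train_loss[h$epoch == 0] - log(13)) / log(13), 0.05)
  # loss decreases between first and last epoch
  expect_lte(h$train_loss[nrow(h)], h$train_loss[h$epoch == 1])
  expect_identical(m$best_epoch,
                   h$epoch[h$epoch > 0][which.max(h$val_f1[h$epoch > 0])])
  expect_gt(max(h$val_f1), 0.5)
})

test_that("training is reproducible and checkpoints roundtrip", {
  sp <- tiny_splits(n = 80L, seed = 5L)
  cfgs <- list(tiny_encoder_cfg(), aggregator_config("sum_average"),
               tiny_train_cfg(epochs = 2L, seed = 21L))
  m1 <- train(sp$train, sp$validation, cfgs[[1]], cfgs[[2]], cfgs[[3]])
  m2 <- train(sp$train, sp$validation, cfgs[[1]], cfgs[[2]], cfgs[[3]])
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  f <- withr::local_tempfile()
  save_model(m1, f)
  m3 <- load_model(f)
  val_f1 <- function(m) {
    evaluate(sp$validation, predict_tags(m, sp$validation))$micro$f1
  }
  expect_identical(val_f1(m3), val_f1(m1))
  expect_identical(val_f1(m1),
                   m1$history$val_f1[m1$history$epoch == m1$best_epoch])
})

test_that("an all-O corpus trains toward the O mode without errors", {
  set.seed(31)
  ctx <- c("u", "v", "w", "x")
  sents <- lapply(1:40, function(i) {
    annotated_sentence(sample(ctx, 6, replace = TRUE))
  })
  m <- train(sents[1:30], sents[31:40], tiny_encoder_cfg(),
             aggregator_config("last_layer"),
             tiny_train_cfg(epochs = 8L, batch_size = 8L,
                            learning_rate = 3e-3, seed = 2L))
  # no entities anywhere: zero-denominator policy reports 0s, loss is low
  expect_identical(m$history$val_f1, rep(0, nrow(m$history)))
  expect_lt(m$history$train_loss[nrow(m$history)], log(13))
  preds <- predict_tags(m, sents[31:40])
  expect_true(all(unlist(preds) == "O"))
})

test_that("training rejects an empty training set", {
  sp <- tiny_splits(n = 20L)
  expect_error(train(list(), sp$validation, tiny_encoder_cfg(),
                     aggregator_config("last_layer"), tiny_train_cfg()),
               "configuration error")
})

test_that("predict_file preserves tokens and sentence structure", {
  sp <- tiny_splits(n = 60L, seed = 17L)
  m <- train(sp$train, sp$validation, tiny_encoder_cfg(),
             aggregator_config("sum_average"), tiny_train_cfg(seed = 4L))
  fin <- withr::local_tempfile()
  fout <- withr::local_tempfile()
  write_column_file(sp$test, fin)
  predict_file(m, fin, fout)
  back <- read_column_file(fout)          # output re-parses
  expect_length(back, length(sp$test))
  tok_col <- function(f) sub("\t.*", "", grep("\t", readLines(f), value = TRUE))
  expect_identical(tok_col(fout), tok_col(fin)) # tokens byte-identical

  # empty input -> empty output
  writeLines(character(0), fin)
  predict_file(m, fin, fout)
  expect_length(read_column_file(fout), 0L)
})

test_that("gold spans crossing the truncation boundary are dropped", {
  s <- annotated_sentence(rep("x", 10),
                          entity_spans(c("Dis", "Med"), c(1, 5), c(3, 8)))
  t6 <- mlner:::truncate_sentence(s, 6L)
  expect_length(t6$tokens, 6L)
  expect_identical(t6$entities$type, "Dis") # Med crossed the boundary
  t10 <- mlner:::truncate_sentence(s, 10L)
  expect_identical(unclass(t10), unclass(s))
})
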