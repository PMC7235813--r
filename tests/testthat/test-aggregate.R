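test_that("attention weights over the layer subset sum to 1", {
  for (seed in 1:100) {
    set.seed(seed)
    L <- c(1L, 2L, 4L, 12L)[(seed %% 4) + 1L]
    d <- c(4L, 8L)[(seed %% 2) + 1L]
    n <- sample(1:6, 1L)
    stack <- random_stack(L, n, d, sd = 2)
    subset <- sort(unique(c(L, sample(seq_len(L), sample(seq_len(L), 1L)))))
    params <- aggregator_params(d, L, n_fusion_heads = 2L,
                                layer_subset = subset, seed = seed)
    E <- aggregate_multihead(stack, params, return_attention = TRUE)
    a <- attr(E, "attention")
    sums <- apply(a, c(1, 3), sum)
    expect_true(all(abs(sums - 1) < 1e-6))
    expect_true(all(a >= 0))
    expect_true(all(is.finite(E)))
  }
})

test_that("all four strategies coincide on the single-layer subset", {
  set.seed(5)
  L <- 3L; d <- 8L; n <- 5L
  stack <- random_stack(L, n, d)
  hL <- stack[[L]]
  expect_identical(aggregate_last_layer(stack), hL)
  expect_equal(aggregate_sum_average(stack, layer_subset = L), hL,
               tolerance = 1e-6)
  cp <- concat_params(d, L, layer_subset = L,
                      weights = list(Wc = diag(d), bc = rep(0, d)))
  expect_equal(aggregate_concat(stack, cp), hL, tolerance = 1e-6)
  mp <- aggregator_params(d, L, n_fusion_heads = 2L, layer_subset = L,
                          weights = list(Wq = diag(d), bq = rep(0, d),
                                         Wk = diag(d), bk = rep(0, d),
                                         Wv = diag(d), bv = rep(0, d),
                                         Wh = diag(d), bh = rep(0, d)))
  E <- aggregate_multihead(stack, mp, return_attention = TRUE)
  # softmax over a single item puts weight exactly 1 on it
  expect_true(all(attr(E, "attention") == 1))
  expect_equal(unclass(E), hL, ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("uniform forced attention reduces multihead to projected sum-average", {
  for (seed in 1:100) {
    set.seed(seed)
    L <- sample(2:5, 1L)
    d <- 8L
    n <- sample(1:5, 1L)
    stack <- random_stack(L, n, d)
    subset <- sort(unique(c(L, sample(seq_len(L), sample(seq_len(L), 1L)))))
    params <- aggregator_params(d, L, n_fusion_heads = 4L,
                                layer_subset = subset, seed = seed + 1000L)
    forced <- aggregate_multihead(stack, params, force_uniform = TRUE)
    w <- params$weights
    mean_v <- sweep(aggregate_sum_average(stack, subset) %*% w$Wv, 2, w$bv, "+")
    expected <- sweep(mean_v %*% w$Wh, 2, w$bh, "+")
    expect_equal(forced, expected, tolerance = 1e-9)
  }
})

test_that("zero query projection equalizes logits, matching forced-uniform", {
  set.seed(77)
  L <- 4L; d <- 8L
  stack <- random_stack(L, 3L, d)
  w <- list(Wq = matrix(0, d, d), bq = rep(0, d),
            Wk = mlner:::init_mat(d, d), bk = rep(0, d),
            Wv = mlner:::init_mat(d, d), bv = rnorm(d),
            Wh = mlner:::init_mat(d, d), bh = rnorm(d))
  params <- aggregator_params(d, L, n_fusion_heads = 2L, weights = w)
  expect_equal(aggregate_multihead(stack, params),
               aggregate_multihead(stack, params, force_uniform = TRUE),
               tolerance = 1e-9)
})

test_that("hand-worked two-layer one-head fusion matches to 1e-9", {
  # d = 2, one head, one token; all numbers below computed by hand from the
  # scaled dot-product recipe (see the frozen arithmetic in the comments)
  h1 <- matrix(c(1, 0), 1, 2)
  h2 <- matrix(c(0, 1), 1, 2)
  w <- list(Wq = diag(2), bq = c(0, 0),
            Wk = diag(2), bk = c(0, 0),
            Wv = matrix(c(1, 3, 2, 4), 2, 2),   # rows of [[1,2],[3,4]]
            bv = c(0.5, -0.5),
            Wh = matrix(c(1, 0, 1, 1), 2, 2),   # rows of [[1,1],[0,1]]
            bh = c(0.1, 0.2))
  params <- aggregator_params(2L, 2L, n_fusion_heads = 1L, weights = w)
  # Q = (0,1); K1 = (1,0), K2 = (0,1); V1 = (1.5,1.5), V2 = (3.5,3.5)
  # logits = (0, 1/sqrt(2)); alpha = (0.33023845067334312, 0.66976154932665688)
  # head  = alpha1*V1 + alpha2*V2 = (2.8395230986533138, 2.8395230986533138)
  # E     = head %*% Wh + bh = (2.9395230986533138, 5.8790461973066277)
  E <- aggregate_multihead(list(h1, h2), params, return_attention = TRUE)
  expect_equal(as.vector(attr(E, "attention")),
               c(0.33023845067334312, 0.66976154932665688), tolerance = 1e-9)
  expect_equal(unclass(E)[1, ], c(2.9395230986533138, 5.8790461973066277),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("concatenation has width |subset| * d and ignores other layers", {
  set.seed(12)
  L <- 4L; d <- 6L; n <- 3L
  stack <- random_stack(L, n, d)
  subset <- c(2L, 4L)
  cp <- concat_params(d, L, layer_subset = subset, seed = 3)
  expect_equal(dim(cp$weights$Wc), c(length(subset) * d, d))
  out <- aggregate_concat(stack, cp)
  # permuting layers outside the subset leaves the output unchanged
  stack2 <- stack
  stack2[[1]] <- stack[[3]]
  stack2[[3]] <- stack[[1]]
  expect_identical(aggregate_concat(stack2, cp), out)
  # ... and so does the multihead fusion
  mp <- aggregator_params(d, L, n_fusion_heads = 2L, layer_subset = subset,
                          seed = 4)
  expect_identical(aggregate_multihead(stack2, mp),
                   aggregate_multihead(stack, mp))
})

test_that("sum-average equals the brute-force mean", {
  set.seed(21)
  stack <- random_stack(5L, 4L, 6L)
  subset <- c(2L, 3L, 5L)
  brute <- (stack[[2]] + stack[[3]] + stack[[5]]) / 3
  expect_equal(aggregate_sum_average(stack, subset), brute, tolerance = 1e-6)
  expect_equal(aggregate_sum_average(lapply(1:3, function(i) stack[[1]])),
               stack[[1]], tolerance = 1e-12)
})

test_that("layer subsets are validated", {
  expect_identical(resolve_layer_subset("all", 4L), 1:4)
  expect_identical(resolve_layer_subset("last2", 4L), 3:4)
  expect_identical(resolve_layer_subset("last4", 12L), 9:12)
  expect_error(resolve_layer_subset("last6", 4L), "configuration error")
  expect_error(resolve_layer_subset(c(1L, 5L), 4L), "configuration error")
  expect_error(resolve_layer_subset(1:2, 4L), "final layer")
  expect_error(resolve_layer_subset(integer(0), 4L), "configuration error")
  expect_error(aggregate_sum_average(random_stack(2L, 2L, 4L), 3L),
               "configuration error")
})
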