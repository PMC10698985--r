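test_that("convolution block preserves length and channels per config", {
  model <- net_init(net_config(window = 8, fmod = 0), seed = 1)
  ctx <- ppistack:::with_seed(1, matrix(rnorm(17 * 40), 17, 40))
  Z <- conv_block_forward(model, ctx)
  expect_identical(dim(Z), c(17L, 8L))
  expect_error(conv_block_forward(model, ctx[0, , drop = FALSE]),
               "zero rows")
  # zero input with zero-initialized biases stays exactly zero
  expect_equal(conv_block_forward(model, matrix(0, 17, 40)),
               matrix(0, 17, 8))
})

test_that("single conv layer matches a sliding-dot-product oracle", {
  x <- c(0.5, -1, 2, 0.25, -0.75, 1.5)           # length 6, one channel
  W <- matrix(c(0.1, -0.2, 0.3, 0.4, -0.5), 5, 1) # kernel 5, one filter
  b <- 0.05
  out <- ppistack:::conv1d_forward(array(x, c(1, 6, 1)), W, b)$out
  xp <- c(0, 0, x, 0, 0)
  oracle <- vapply(1:6, function(l) sum(xp[l:(l + 4)] * W[, 1]) + b, 0)
  expect_equal(as.numeric(out), oracle, tolerance = 1e-12)

  # pooled output matches a windowed-max oracle (stride 1, same padding)
  pooled <- ppistack:::maxpool_forward(out, 3)$out
  op <- c(-Inf, as.numeric(out), -Inf)
  pool_oracle <- vapply(1:6, function(l) max(op[l:(l + 2)]), 0)
  expect_equal(as.numeric(pooled), pool_oracle, tolerance = 1e-12)
})

test_that("attention is a convex combination with unit column sums", {
  model <- net_init(net_config(window = 8, fmod = 0), seed = 2)
  # identical rows: every output equals the heads' projections of that row
  z <- ppistack:::with_seed(3, rnorm(8))
  Z <- matrix(z, 17, 8, byrow = TRUE)
  A <- masked_multihead_attention(model, Z, rep(FALSE, 17))
  expect_identical(dim(A), c(17L, 64L))
  proj <- unlist(lapply(1:4, function(h) {
    as.numeric(model$params[[paste0("attn", h, "_Wv")]] %*% z)
  }))
  for (j in 1:17) expect_equal(A[j, ], proj, tolerance = 1e-9)

  # padded positions receive vanishing attention weight
  Zr <- ppistack:::with_seed(4, matrix(rnorm(17 * 8), 17, 8))
  mask <- rep(FALSE, 17); mask[5] <- TRUE
  W1 <- ppistack:::attention_weights(model, Zr, mask, head = 1)
  expect_true(all(W1[5, ] < 1e-6))
  expect_equal(colSums(W1), rep(1, 17), tolerance = 1e-9)
  expect_error(masked_multihead_attention(model, Zr, rep(TRUE, 17)),
               "all positions")
})

test_that("attention reproduces a hand-unrolled dense computation", {
  cfg <- net_config(window = 1, fmod = 0, heads = 1, head_dim = 2)
  model <- net_init(cfg, seed = 5)
  # small fixed projections, L = 3
  model$params$attn1_Wq <- matrix(seq(0.1, 1.6, by = 0.1), 2, 8)
  model$params$attn1_Wk <- matrix(seq(-0.8, 0.7, by = 0.1), 2, 8)
  model$params$attn1_Wv <- matrix(seq(0.05, 0.80, by = 0.05), 2, 8)
  Z <- matrix(seq(-1, 1.3, by = 0.1), 3, 8)
  A <- masked_multihead_attention(model, Z, rep(FALSE, 3))

  # Eqs. unrolled by hand: q_i, k_i, v_i; e_ij = q_i . k_j / sqrt(d);
  # w_ij = exp(e_ij) / sum_i exp(e_ij); h_j = sum_i w_ij v_i
  q <- lapply(1:3, function(i) model$params$attn1_Wq %*% Z[i, ])
  k <- lapply(1:3, function(i) model$params$attn1_Wk %*% Z[i, ])
  v <- lapply(1:3, function(i) model$params$attn1_Wv %*% Z[i, ])
  E <- outer(1:3, 1:3, Vectorize(function(i, j) sum(q[[i]] * k[[j]])))
  E <- E / sqrt(2)
  for (j in 1:3) {
    w <- exp(E[, j]) / sum(exp(E[, j]))
    hj <- w[1] * v[[1]] + w[2] * v[[2]] + w[3] * v[[3]]
    expect_equal(A[j, ], as.numeric(hj), tolerance = 1e-10)
  }
})

test_that("aggregation is the masked mean of concatenated rows", {
  Z <- matrix(1:34 / 10, 17, 2)
  A <- matrix(34:1 / 10, 17, 2)
  f <- aggregate_features(Z, A, rep(FALSE, 17))
  expect_length(f, 4)
  # constant rows pass through
  Zc <- matrix(rep(c(1, 2), each = 17), 17, 2)
  expect_equal(aggregate_features(Zc, NULL, rep(FALSE, 17)), c(1, 2))
  # masked-mean oracle with 3 padded rows
  mask <- rep(FALSE, 17); mask[c(1, 2, 17)] <- TRUE
  S <- cbind(Z, A)
  expect_equal(aggregate_features(Z, A, mask),
               colMeans(S[!mask, ]), tolerance = 1e-12)
  expect_error(aggregate_features(Z, A, rep(TRUE, 17)), "no non-padded")
  # dimension with reference settings is 8 + 4 * 16 = 72
  model <- net_init(net_config(window = 8, fmod = 0), seed = 1)
  ctx <- build_context_matrix(random_record("agg", 30, 8), 10, 8, 0)
  Zr <- conv_block_forward(model, ctx$f_ctx)
  Ar <- masked_multihead_attention(model, Zr, ctx$pad_mask)
  expect_length(aggregate_features(Zr, Ar, ctx$pad_mask), 72)
})

test_that("predictor head is a calibrated sigmoid map", {
  model <- net_init(net_config(window = 8, fmod = 0), seed = 6)
  d <- model$config$d_fc_in
  expect_identical(d, 112L)
  # zero-initialized final affine layer -> exactly 0.5
  model$params$fc3_W[] <- 0
  model$params$fc3_b <- 0
  x <- ppistack:::with_seed(7, rnorm(d))
  expect_identical(predictor_forward(model, x), 0.5)
  # output in (0,1) for extreme inputs; eval passes are bit-identical
  model <- net_init(net_config(window = 8, fmod = 0), seed = 6)
  for (scale in c(1, 10, 50)) {
    p <- predictor_forward(model, x * scale)
    expect_true(p > 0 && p < 1)
  }
  expect_identical(predictor_forward(model, x), predictor_forward(model, x))
  expect_error(predictor_forward(model, x[-1]), "length")
})

test_that("full forward pass wires the documented dimensions", {
  expect_identical(net_config(window = 8, fmod = 0)$d_fc_in, 112L)
  expect_identical(net_config(window = 8, fmod = 1)$d_fc_in, 95L)
  expect_identical(net_config(window = 8, fmod = 2)$d_fc_in, 122L)

  rec <- random_record("fw", 25, 12)
  fs <- build_residue_feature_set(rec, 2, W = 8, fmod = 0)
  model <- net_init(net_config(window = 8, fmod = 0), seed = 9)
  p <- net_forward(model, fs)
  expect_true(p > 0 && p < 1)
  expect_error(net_forward(net_init(net_config(window = 8, fmod = 1), 1),
                           fs), "module")
})

test_that("output is invariant to the content of padded context rows", {
  rec <- random_record("pad", 20, 21)
  model <- net_init(net_config(window = 8, fmod = 0), seed = 10)
  fs <- build_residue_feature_set(rec, 1, W = 8, fmod = 0)  # 8 padded rows
  p0 <- net_forward(model, fs)
  for (trial in 1:5) {
    fs2 <- fs
    fs2$f_ctx[fs$pad_mask, ] <- ppistack:::with_seed(trial,
      matrix(rnorm(sum(fs$pad_mask) * 40, sd = 5), sum(fs$pad_mask), 40))
    expect_equal(net_forward(model, fs2), p0, tolerance = 1e-12)
  }
})

test_that("the attention-free ablation equals the reduced graph", {
  cfg <- net_config(window = 4, fmod = 0, attention = FALSE)
  expect_identical(cfg$d_agg, 8L)
  model <- net_init(cfg, seed = 13)
  rec <- random_record("na", 20, 22)
  fs <- build_residue_feature_set(rec, 10, W = 4, fmod = 0)
  p <- net_forward(model, fs)
  # oracle: conv block -> mean over non-padded rows -> concat -> head
  Z <- conv_block_forward(model, fs$f_ctx)
  f_agg <- aggregate_features(Z, NULL, fs$pad_mask)
  expect_equal(p, predictor_forward(model, c(f_agg, fs$f_tr)),
               tolerance = 1e-12)
})

test_that("a single head degenerates multi-head attention exactly", {
  cfg <- net_config(window = 4, fmod = 0, heads = 1)
  model <- net_init(cfg, seed = 14)
  expect_identical(cfg$d_agg, 8L + 16L)
  rec <- random_record("sh", 18, 23)
  fs <- build_residue_feature_set(rec, 9, W = 4, fmod = 0)
  Z <- conv_block_forward(model, fs$f_ctx)
  A <- masked_multihead_attention(model, Z, fs$pad_mask)
  expect_identical(dim(A), c(9L, 16L))
  # identical to computing the one head by hand
  Wq <- model$params$attn1_Wq; Wk <- model$params$attn1_Wk
  Wv <- model$params$attn1_Wv
  E <- (Z %*% t(Wq)) %*% t(Z %*% t(Wk)) / sqrt(16)
  Wm <- apply(E, 2, function(col) exp(col - max(col)) /
                sum(exp(col - max(col))))
  expect_equal(A, t(Wm) %*% (Z %*% t(Wv)), tolerance = 1e-10)
})

test_that("attention weight columns sum to one for random inputs", {
  model <- net_init(net_config(window = 6, fmod = 0), seed = 15)
  for (trial in 1:5) {
    Z <- ppistack:::with_seed(30 + trial, matrix(rnorm(13 * 8), 13, 8))
    mask <- rep(FALSE, 13)
    mask[ppistack:::with_seed(40 + trial, sample(13, 3))] <- TRUE
    for (h in 1:4) {
      W <- ppistack:::attention_weights(model, Z, mask, head = h)
      expect_equal(colSums(W), rep(1, 13), tolerance = 1e-9)
    }
  }
})
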