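test_that("configuration validation enforces the structural constraints", {
  expect_s3_class(demux_config(n_classes = 4), "demux_config")
  expect_error(demux_config(n_classes = 1), "n_classes")
  expect_error(tiny_config(input_length = 18L), "multiple")
  expect_error(tiny_config(d_model = 9L), "n_heads")
  expect_error(tiny_config(kernel_sizes = c(4L, 3L, 3L, 3L)), "odd")
  expect_error(tiny_config(tcn_dilations = integer()), "tcn_dilations")
  expect_error(tiny_config(dropout = 1), "dropout")
  expect_silent(tiny_config(n_transformer_layers = 0L))
})

test_that("fused paths share the temporal resolution L/p^2", {
  cfg <- tiny_config()  # L = 16, p = 2
  W <- random_eval_weights(cfg, seed = 1)
  out <- fusion_forward(random_batch(cfg, 3L), cfg, W)
  expect_identical(dim(out$features), c(3L, 2L + 3L + 4L + 5L, 4L))
  expect_identical(out$path_lengths,
                   list(x1 = 8L, x2 = 4L, x3 = 4L, r1 = 4L, r2 = 4L))
})

test_that("identity-configured fusion maps an all-ones input to all ones", {
  # kernel size 1, unit conv weights, zero biases, identity batch norm:
  # every path computes ELU(1) = 1 and averages of ones
  cfg <- tiny_config(fusion_channels = c(1L, 1L, 1L), residual_channels = 1L,
                     kernel_sizes = c(1L, 1L, 1L, 1L))
  W <- init_weights(cfg, seed = 1)
  for (nm in grep("^(f1|f2|f3|fr1)\\.W$", names(W), value = TRUE)) {
    W[[nm]][] <- 1
  }
  for (nm in grep("^(f1|f2|f3|fr1)\\.b$", names(W), value = TRUE)) {
    W[[nm]][] <- 0
  }
  ones <- array(1, dim = c(2L, 1L, 16L))
  out <- fusion_forward(ones, cfg, W, mode = "eval")
  # identity batch norm is exact up to its variance-stabilising epsilon
  expect_equal(max(abs(out$features - 1)), 0, tolerance = 1e-4)
})

test_that("fusion agrees with the loop-based oracle on random inputs", {
  worst <- 0
  for (i in 1:25) {
    cfg <- tiny_config()
    W <- random_eval_weights(cfg, seed = i)
    B <- 1L + i %% 2L
    set.seed(500 + i)
    vals <- array(rnorm(B * 16L), dim = c(B, 1L, 16L))
    out <- fusion_forward(vals, cfg, W, mode = "eval")
    for (b in seq_len(B)) {
      ref <- oracle_fusion_one_read(vals[b, 1L, ], W, cfg)
      worst <- max(worst, max(abs(out$features[b, , ] - ref)))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("attention rows are probability distributions of the right shape", {
  cfg <- tiny_config(n_transformer_layers = 2L)
  W <- random_eval_weights(cfg, seed = 4)
  fused <- fusion_forward(random_batch(cfg, 3L), cfg, W)
  out <- transformer_forward(fused, cfg, W)
  A <- out$attention
  expect_identical(dim(A), c(2L, 2L, 4L, 4L, 3L))
  expect_true(all(A >= 0))
  sums <- apply(A, c(1, 2, 3, 5), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_identical(dim(out$features), c(3L, cfg$d_model, 4L))
})

test_that("a zero-layer transformer is the projected-plus-positional identity", {
  cfg <- tiny_config(n_transformer_layers = 0L)
  W <- random_eval_weights(cfg, seed = 2)
  fused <- fusion_forward(random_batch(cfg, 2L), cfg, W)
  out <- transformer_forward(fused, cfg, W)
  expect_null(out$attention)
  Tlen <- 4L
  pe <- positional_encoding(cfg$d_model, Tlen)
  for (b in 1:2) {
    ref <- W[["proj.W"]] %*% fused$features[b, , ] + W[["proj.b"]] + pe
    expect_equal(out$features[b, , ], ref, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("the TCN is strictly causal for random weight draws", {
  cfg <- tiny_config(input_length = 256L)  # T = 64
  set.seed(77)
  for (i in 1:10) {
    W <- random_eval_weights(cfg, seed = 200 + i)
    x <- array(rnorm(cfg$d_model * 64L), dim = c(1L, cfg$d_model, 64L))
    y0 <- tcn_forward(x, cfg, W)
    t_hit <- sample(2:64, 1L)
    xp <- x
    xp[1L, , t_hit] <- xp[1L, , t_hit] + rnorm(cfg$d_model)
    y1 <- tcn_forward(xp, cfg, W)
    expect_identical(max(abs(y1[, , seq_len(t_hit - 1L), drop = FALSE] -
                             y0[, , seq_len(t_hit - 1L), drop = FALSE])), 0)
    expect_identical(dim(y1), c(1L, cfg$tcn_channels, 64L))
  }
})

test_that("the TCN receptive field matches 2 * sum((k-1) * d)", {
  # kernel 3, dilations (1, 2, 4), two convolutions per block:
  # output at t sees exactly positions >= t - 28
  cfg <- tiny_config(input_length = 256L, tcn_dilations = c(1L, 2L, 4L))
  W <- random_eval_weights(cfg, seed = 31)
  set.seed(31)
  x <- array(rnorm(cfg$d_model * 64L), dim = c(1L, cfg$d_model, 64L))
  y0 <- tcn_forward(x, cfg, W)
  t_out <- 40L
  # perturbation just inside the receptive field changes the output ...
  xin <- x; xin[1L, , t_out - 28L] <- xin[1L, , t_out - 28L] + 10
  expect_gt(max(abs(tcn_forward(xin, cfg, W)[1L, , t_out] -
                    y0[1L, , t_out])), 0)
  # ... and any perturbation strictly before t - 28 does not
  xout <- x
  xout[1L, , seq_len(t_out - 29L)] <-
    xout[1L, , seq_len(t_out - 29L)] + 10
  expect_identical(max(abs(tcn_forward(xout, cfg, W)[1L, , t_out] -
                           y0[1L, , t_out])), 0)
})

test_that("the classifier head pools time and yields one logit per class", {
  cfg <- tiny_config()
  W <- random_eval_weights(cfg, seed = 8)
  # constant-over-time features: pooling must be the identity on channels
  set.seed(8)
  v <- rnorm(cfg$tcn_channels)
  xc <- array(rep(v, each = 1L), dim = c(1L, cfg$tcn_channels, 4L))
  for (t in 1:4) xc[1L, , t] <- v
  lo <- head_forward(xc, cfg, W)
  hid <- pmax(W[["head.W1"]] %*% v + W[["head.b1"]], 0) +
    expm1(pmin(W[["head.W1"]] %*% v + W[["head.b1"]], 0))
  ref <- W[["head.W2"]] %*% hid + W[["head.b2"]]
  expect_equal(as.numeric(lo), as.numeric(ref), tolerance = 1e-12)
  expect_identical(dim(lo), c(1L, cfg$n_classes))
  # zero weights force zero logits, i.e. a uniform softmax
  Wz <- W
  for (nm in c("head.W1", "head.b1", "head.W2", "head.b2")) Wz[[nm]][] <- 0
  lz <- head_forward(xc, cfg, Wz)
  expect_identical(as.numeric(lz), rep(0, cfg$n_classes))
})

test_that("eval-mode forward is deterministic and batch-independent", {
  cfg <- tiny_config(dropout = 0.3)  # dropout present but off in eval
  W <- random_eval_weights(cfg, seed = 5)
  batch <- random_batch(cfg, 8L, seed = 5)
  f1 <- model_forward(batch, cfg, W)
  f2 <- model_forward(batch, cfg, W)
  expect_identical(f1$logits, f2$logits)
  # single read vs the same read inside the batch
  single <- batch
  single$values <- batch$values[3L, , , drop = FALSE]
  fs <- model_forward(single, cfg, W)
  expect_lt(max(abs(fs$logits[1L, ] - f1$logits[3L, ])), 1e-5)
  # permuting the batch permutes the logits identically
  perm <- c(5L, 1L, 8L, 2L, 7L, 3L, 6L, 4L)
  pb <- batch
  pb$values <- batch$values[perm, , , drop = FALSE]
  fp <- model_forward(pb, cfg, W)
  expect_equal(fp$logits, f1$logits[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(model_forward(array(0, c(2, 1, 8)), cfg, W), "input_length")
})

test_that("the parameter count is a pure function of the configuration", {
  cfg <- tiny_config()
  expect_identical(count_params(cfg), count_params(cfg))
  n_direct <- sum(vapply(init_weights(cfg, seed = 99)[
    trainable_names(init_weights(cfg, seed = 99))], length, integer(1)))
  expect_identical(count_params(cfg), n_direct)
  # ablation degenerations build and run
  for (abl in list(tiny_config(n_transformer_layers = 0L),
                   tiny_config(tcn_dilations = 1L))) {
    Wa <- init_weights(abl, seed = 1)
    out <- model_forward(random_batch(abl, 2L), abl, Wa)
    expect_identical(dim(out$logits), c(2L, abl$n_classes))
    expect_true(all(is.finite(out$logits)))
  }
})
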