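# an untrained model object is enough for the structural contracts
make_model_object <- function(cfg, seed = 1L) {
  structure(list(weights = init_weights(cfg, seed = seed), config = cfg,
                 normalize_method = "median_mad",
                 length_policy = "resample", spike_filter = 1L),
            class = "demuxtrans")
}

test_that("attention profiles are normalized, full-length importance maps", {
  cfg <- tiny_config()
  obj <- make_model_object(cfg)
  set.seed(2)
  sig <- raw_signal("r1", rnorm(40))
  prof <- attention_profile(obj, sig)
  expect_s3_class(prof, "attention_profile")
  expect_length(prof$importance, cfg$input_length)
  expect_length(prof$signal, cfg$input_length)
  expect_true(all(prof$importance >= 0))
  expect_equal(sum(prof$importance), 1, tolerance = 1e-6)
  expect_identical(prof$downsample_factor, 4)
  ph <- attention_profile(obj, sig, per_head = TRUE)
  expect_identical(dim(ph$per_head), c(1L, cfg$n_heads, 4L))
})

test_that("zeroed attention projections give a flat profile", {
  cfg <- tiny_config()
  obj <- make_model_object(cfg)
  # zero query/key maps -> uniform softmax rows -> importance 1/L each
  obj$weights[["t1.Wq"]][] <- 0
  obj$weights[["t1.bq"]][] <- 0
  obj$weights[["t1.Wk"]][] <- 0
  obj$weights[["t1.bk"]][] <- 0
  set.seed(3)
  prof <- attention_profile(obj, raw_signal("r1", rnorm(30)))
  expect_equal(prof$importance, rep(1 / cfg$input_length, cfg$input_length),
               tolerance = 1e-9)
})

test_that("profiles do not depend on the surrounding batch", {
  cfg <- tiny_config()
  obj <- make_model_object(cfg, seed = 6)
  set.seed(6)
  sig <- raw_signal("solo", rnorm(50))
  prof <- attention_profile(obj, sig)
  # same read pushed through model_forward inside a batch of 8
  others <- array(rnorm(8 * cfg$input_length), c(8, 1, cfg$input_length))
  x <- standardize_length(normalize_signal(sig, "median_mad"),
                          cfg$input_length, "resample")
  others[3, 1, ] <- x
  fw <- model_forward(others, cfg, obj$weights, return_attention = TRUE)
  imp_T <- apply(fw$attention[, , , , 3, drop = FALSE], 4, mean)
  imp <- rep(imp_T, each = 4); imp <- imp / sum(imp)
  expect_equal(prof$importance, imp, tolerance = 1e-9)
})

test_that("chord matrices are symmetric, hollow and edge-ranked", {
  cfg <- tiny_config(input_length = 32L)  # T = 8
  obj <- make_model_object(cfg, seed = 4)
  set.seed(4)
  sig <- raw_signal("r1", rnorm(64))
  ch <- chord_matrix(obj, sig, top_k = 5L)
  expect_identical(ch$matrix, t(ch$matrix))
  expect_identical(unname(diag(ch$matrix)), rep(0, 8))
  expect_true(all(ch$matrix >= 0))
  expect_identical(nrow(ch$edges), 5L)
  expect_true(all(diff(ch$edges$weight) <= 0))
  expect_true(all(ch$edges$i < ch$edges$j))
  # top-1 edge is the global off-diagonal maximum
  top1 <- chord_matrix(obj, sig, top_k = 1L)$edges
  expect_equal(top1$weight, max(ch$matrix[upper.tri(ch$matrix)]))
  # oversized top_k clamps with a warning
  expect_warning(big <- chord_matrix(obj, sig, top_k = 999L), "clamped")
  expect_identical(nrow(big$edges), 28L)
})

test_that("interpretation artifacts round-trip through json and tsv", {
  cfg <- tiny_config()
  obj <- make_model_object(cfg, seed = 5)
  set.seed(5)
  sig <- raw_signal("rt", rnorm(45))
  prof <- attention_profile(obj, sig)
  pj <- withr::local_tempfile(fileext = ".json")
  pt <- withr::local_tempfile(fileext = ".tsv")
  export_interpretation(prof, pj, "json")
  export_interpretation(prof, pt, "tsv")
  bj <- read_interpretation(pj)
  bt <- read_interpretation(pt)
  expect_equal(bj$importance, prof$importance, tolerance = 1e-12)
  expect_equal(bt$importance, prof$importance, tolerance = 1e-12)
  expect_equal(bj$signal, bt$signal, tolerance = 1e-12)
  expect_identical(bj$read_id, "rt")
  ch <- chord_matrix(obj, sig, top_k = 3L)
  cj <- withr::local_tempfile(fileext = ".json")
  ct <- withr::local_tempfile(fileext = ".tsv")
  export_interpretation(ch, cj, "json")
  export_interpretation(ch, ct, "tsv")
  bcj <- read_interpretation(cj)
  bct <- read_interpretation(ct)
  expect_equal(bcj$edges$weight, ch$edges$weight, tolerance = 1e-12)
  expect_equal(bct$edges$weight, ch$edges$weight, tolerance = 1e-12)
  expect_equal(as.numeric(unlist(bcj$matrix)),
               as.numeric(t(ch$matrix)), tolerance = 1e-12)
})

test_that("a single-position model serializes an empty edge list", {
  cfg <- tiny_config(input_length = 4L)  # T = 1
  obj <- make_model_object(cfg, seed = 7)
  set.seed(7)
  sig <- raw_signal("tiny", rnorm(10))
  expect_warning(ch <- chord_matrix(obj, sig, top_k = 3L), "clamped")
  expect_identical(nrow(ch$edges), 0L)
  pt <- withr::local_tempfile(fileext = ".tsv")
  export_interpretation(ch, pt, "tsv")
  back <- read_interpretation(pt)
  expect_identical(nrow(back$edges), 0L)
})

test_that("trained attention concentrates near the level transition", {
  # two classes of noiseless traces differing only in where a single large
  # level step sits; after training, the profile should put more mass in a
  # +-2*p^2 window around the step than the uniform expectation for most
  # test reads
  cfg <- tiny_config(n_classes = 2L, input_length = 64L, d_model = 16L,
                     n_heads = 4L, ff_dim = 32L, tcn_channels = 16L,
                     tcn_dilations = c(1L, 2L), mlp_hidden = 16L)
  gen_read <- function(id, cls, t0) {
    lv <- if (cls == 0L) c(-1, 1) else c(1, -1)
    x <- c(rep(lv[1], t0), rep(lv[2], 64L - t0)) + rnorm(64L, sd = 0.05)
    raw_signal(id, x, label = cls)
  }
  set.seed(42)
  mk <- function(n, tag) {
    signal_set(lapply(seq_len(n), function(i) {
      gen_read(sprintf("%s%03d", tag, i), i %% 2L, sample(24:40, 1))
    }), n_classes = 2L)
  }
  train <- mk(60L, "tr")
  fit <- demuxtrans(train, NULL, cfg,
                    train_params(epochs = 25L, batch_size = 16L, seed = 2L,
                                 augmentation = NULL),
                    length_policy = "resample", spike_filter = 1L)
  set.seed(43)
  hits <- 0L
  n_test <- 20L
  for (i in seq_len(n_test)) {
    t0 <- sample(24:40, 1)
    sig <- gen_read(sprintf("te%03d", i), i %% 2L, t0)
    prof <- attention_profile(fit, sig)
    win <- max(1, t0 - 8):min(64, t0 + 8)
    if (sum(prof$importance[win]) > length(win) / 64) hits <- hits + 1L
  }
  expect_gt(hits, n_test / 2)
})
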