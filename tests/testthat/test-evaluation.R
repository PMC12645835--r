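test_that("classification metrics match the hand-filled confusion matrix", {
  r <- classification_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_equal(r$accuracy, 0.75)
  expect_identical(unname(r$confusion), matrix(c(1L, 0L, 1L, 2L), 2))
  expect_equal(r$per_class$precision, c(1, 2 / 3))
  expect_equal(r$per_class$recall, c(0.5, 1))
  expect_equal(r$per_class$f1, c(2 / 3, 0.8))
  expect_equal(r$macro_f1, (2 / 3 + 0.8) / 2, tolerance = 1e-12)
  perfect <- classification_metrics(0:3, 0:3, 4)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$per_class$f1, rep(1, 4))
  # a never-predicted class gets precision 0 and an explicit flag
  flagged <- classification_metrics(c(0, 1, 2), c(0, 1, 1), 3)
  expect_equal(flagged$per_class$precision[3], 0)
  expect_match(flagged$zero_denominator, "class 2 precision",
               all = FALSE)
  expect_error(classification_metrics(c(0, 1), c(0), 2), "length")
})

test_that("micro-accuracy equals macro-recall on exactly balanced classes", {
  set.seed(10)
  for (i in 1:20) {
    C <- sample(2:5, 1)
    n_per <- sample(3:10, 1)
    y <- rep(0:(C - 1), each = n_per)
    p <- sample(0:(C - 1), C * n_per, replace = TRUE)
    r <- classification_metrics(y, p, C)
    expect_equal(r$micro_accuracy, r$macro_recall, tolerance = 1e-12)
  }
})

test_that("one-vs-rest AUC matches closed forms and pair enumeration", {
  sc <- function(v) cbind(1 - v, v)
  expect_equal(roc_auc_ovr(c(1, 1, 0, 0), sc(c(0.9, 0.8, 0.4, 0.2)), 1), 1)
  expect_equal(roc_auc_ovr(c(1, 0, 1, 0), sc(rep(0.5, 4)), 1), 0.5)
  # pairs: (.8>.5) (.8>.1) (.3<.5) (.3>.1) -> 3/4
  expect_equal(roc_auc_ovr(c(1, 1, 0, 0), sc(c(0.8, 0.3, 0.5, 0.1)), 1),
               0.75)
  expect_error(roc_auc_ovr(c(1, 1), sc(c(0.2, 0.4)), 1), "undefined")
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), sample(c(1, 2, 8), 1))  # rounding forces ties
    got <- roc_auc_ovr(y, sc(s), 1)
    expect_equal(got, oracle_auc_pairs(s[y == 1], s[y == 0]),
                 tolerance = 1e-9)
  }
})

test_that("homogeneity/completeness match entropy hand computations", {
  expect_equal(homogeneity_completeness(c(0, 0, 1, 1), c(0, 0, 1, 1)),
               c(homogeneity = 1, completeness = 1))
  # each cluster pure -> h = 1; c = 1 - ln2/ln4 = 0.5
  expect_equal(homogeneity_completeness(c(0, 0, 1, 1), c(0, 1, 2, 3)),
               c(homogeneity = 1, completeness = 0.5), tolerance = 1e-12)
  expect_equal(homogeneity_completeness(c(0, 0, 1, 1), c(7, 7, 7, 7)),
               c(homogeneity = 0, completeness = 1))
  expect_error(homogeneity_completeness(c(0, 1), c(0)), "length")
})

test_that("homogeneity/completeness agree with brute force on random labelings", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    y <- sample(0:(sample(2:5, 1) - 1), n, replace = TRUE)
    k <- sample(0:(sample(1:6, 1) - 1), n, replace = TRUE)
    got <- homogeneity_completeness(y, k)
    ref <- oracle_homogeneity_completeness(y, k)
    expect_equal(unname(got), unname(ref), tolerance = 1e-9)
  }
})

test_that("majority-vote mapping scores reads under the dominant label", {
  # cluster A: true {0,0,1}; cluster B: true {1,1} -> A->0, B->1, 4/5
  r <- majority_vote_map(c(0, 0, 1, 1, 1), c(1, 1, 1, 2, 2))
  expect_identical(unname(r$cluster_to_label), c(0L, 1L))
  expect_equal(r$mapped_accuracy, 0.8)
  expect_equal(majority_vote_map(c(0, 1, 2), c(0, 1, 2))$mapped_accuracy, 1)
  one <- majority_vote_map(c(0, 0, 0, 1), rep(5, 4))
  expect_identical(unname(one$cluster_to_label), 0L)
  expect_equal(one$mapped_accuracy, 0.75)
  # a tie between labels resolves to the lowest label index
  tie <- majority_vote_map(c(1, 0), c(3, 3))
  expect_identical(unname(tie$cluster_to_label), 0L)
})

test_that("cluster scores are invariant to relabeling cluster ids", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    y <- sample(0:2, n, replace = TRUE)
    k <- sample(0:3, n, replace = TRUE)
    perm <- sample(10:19)  # injective remapping of ids 0..9
    k2 <- perm[k + 1]
    a <- majority_vote_map(y, k)
    b <- majority_vote_map(y, k2)
    expect_equal(a$homogeneity, b$homogeneity, tolerance = 1e-12)
    expect_equal(a$completeness, b$completeness, tolerance = 1e-12)
    expect_equal(a$mapped_accuracy, b$mapped_accuracy, tolerance = 1e-12)
  }
})

test_that("evaluate joins on read_id and reports AUC and clustering", {
  sets <- tiny_dataset(n_per_class = 6L)
  cfg <- tiny_config(input_length = 32L)
  fit <- demuxtrans(sets$train, NULL, cfg,
                    train_params(epochs = 1L, batch_size = 8L, seed = 9L))
  pred <- predict(fit, sets$test)
  rep1 <- evaluate(pred, sets$test)
  expect_s3_class(rep1$classification, "eval_report")
  expect_length(rep1$classification$per_class_auc, 3L)
  # shuffling the prediction rows changes nothing (join on read_id)
  shuf <- sample(seq_along(pred$read_ids))
  pred2 <- structure(list(prob = pred$prob[shuf, ],
                          class = pred$class[shuf],
                          read_ids = pred$read_ids[shuf]),
                     class = "demuxtrans_pred")
  rep2 <- evaluate(pred2, sets$test)
  expect_equal(rep1$classification$accuracy, rep2$classification$accuracy)
  expect_identical(rep1$classification$confusion,
                   rep2$classification$confusion)
  # missing reads are named
  pred3 <- structure(list(prob = pred$prob[-1, ], class = pred$class[-1],
                          read_ids = pred$read_ids[-1]),
                     class = "demuxtrans_pred")
  expect_error(evaluate(pred3, sets$test), pred$read_ids[1], fixed = TRUE)
  # clustering protocol + JSON report
  truth <- signal_labels(sets$test$signals)
  ids <- vapply(sets$test$signals, `[[`, character(1), "read_id")
  clusters <- setNames(truth, ids)  # perfect clustering
  out <- withr::local_tempfile(fileext = ".json")
  rep4 <- evaluate(pred, sets$test, clusters = clusters, out = out)
  expect_equal(rep4$clustering$homogeneity, 1)
  expect_equal(rep4$clustering$mapped_accuracy, 1)
  js <- jsonlite::read_json(out)
  expect_equal(js$schema_version, 1L)
  expect_equal(js$classification$accuracy, rep4$classification$accuracy)
  expect_equal(js$clustering$completeness, 1)
})
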