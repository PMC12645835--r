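#' Classification metrics
#'
#' Computes the confusion matrix (rows = true, cols = predicted), overall
#' accuracy, per-class precision / recall / F1 and their unweighted
#' (macro) means. A class never predicted has precision defined as 0 and
#' is flagged in `zero_denominator`; likewise recall for a class absent
#' from the truth, so macro scores are always defined.
#'
#' @param y_true,y_pred Integer vectors of 0-based labels, equal length.
#' @param C Number of classes.
#' @return Object of class `eval_report`: list with `accuracy`,
#'   `confusion`, `per_class` (data frame), `macro_precision`,
#'   `macro_recall`, `macro_f1`, `micro_accuracy`, `zero_denominator`
#'   (character vector of flagged class/metric pairs), `n`.
#' @examples
#' r <- classification_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
#' r$accuracy        # 0.75
#' r$macro_f1        # mean of 2/3 and 0.8
#' @export
classification_metrics <- function(y_true, y_pred, C) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred have different lengths")
  }
  if (length(y_true) < 1L) stop("empty input")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  C <- as.integer(C)
  if (any(y_true < 0L | y_true >= C) || any(y_pred < 0L | y_pred >= C)) {
    stop("labels must lie in [0, C)")
  }
  n <- length(y_true)
  confusion <- matrix(0L, C, C,
                      dimnames = list(true = 0:(C - 1L),
                                      pred = 0:(C - 1L)))
  for (i in seq_len(n)) {
    confusion[y_true[i] + 1L, y_pred[i] + 1L] <-
      confusion[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  flagged <- character()
  precision <- numeric(C); recall <- numeric(C)
  for (c in seq_len(C)) {
    if (tp[c] + fp[c] == 0L) {
      precision[c] <- 0
      flagged <- c(flagged, sprintf("class %d precision (never predicted)",
                                    c - 1L))
    } else precision[c] <- tp[c] / (tp[c] + fp[c])
    if (tp[c] + fn[c] == 0L) {
      recall[c] <- 0
      flagged <- c(flagged, sprintf("class %d recall (absent from truth)",
                                    c - 1L))
    } else recall[c] <- tp[c] / (tp[c] + fn[c])
  }
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  acc <- sum(tp) / n
  structure(list(accuracy = acc, confusion = confusion,
                 per_class = data.frame(class = 0:(C - 1L),
                                        precision = precision,
                                        recall = recall, f1 = f1),
                 macro_precision = mean(precision),
                 macro_recall = mean(recall),
                 macro_f1 = mean(f1),
                 micro_accuracy = acc,
                 zero_denominator = flagged, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  macro P/R/F1 %.4f/%.4f/%.4f  (n = %d)\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
              x$n))
  print(x$confusion)
  if (length(x$zero_denominator)) {
    cat("flags:", paste(x$zero_denominator, collapse = "; "), "\n")
  }
  invisible(x)
}

#' One-vs-rest ROC AUC for one class
#'
#' AUC = P(score of a random positive > score of a random negative) +
#' 1/2 P(tie), computed exactly via the rank (Mann-Whitney) formulation,
#' which equals trapezoidal ROC integration.
#'
#' @param y_true Integer vector of 0-based labels.
#' @param scores Probability (or score) matrix `(n, C)`.
#' @param class 0-based class index to treat as positive.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc_ovr(c(1, 1, 0, 0), cbind(c(.1, .7, .5, .9), c(.9, .3, .5, .1)), 1)
#' @export
roc_auc_ovr <- function(y_true, scores, class) {
  scores <- as.matrix(scores)
  if (length(y_true) != nrow(scores)) stop("length mismatch")
  s <- scores[, class + 1L]
  pos <- y_true == class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: class ", class,
         " needs at least one positive and one negative")
  }
  r <- rank(s, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Homogeneity and completeness of a clustering
#'
#' Entropy-based scores over the empirical joint distribution of true
#' class and cluster id (natural logarithms; any base cancels in the
#' ratios). Homogeneity `h = 1 - H(class|cluster)/H(class)` is 1 when
#' every cluster is pure; completeness `c = 1 - H(cluster|class)/H(cluster)`
#' is 1 when each class lands in a single cluster. When the reference
#' entropy is 0 the score is defined as 1.
#'
#' @param y_true Integer vector of true 0-based labels.
#' @param clusters Integer vector of cluster ids (arbitrary coding).
#' @return Named numeric `c(homogeneity =, completeness =)`.
#' @examples
#' homogeneity_completeness(c(0, 0, 1, 1), c(0, 1, 2, 3))  # h 1, c 0.5
#' @export
homogeneity_completeness <- function(y_true, clusters) {
  if (length(y_true) != length(clusters)) stop("length mismatch")
  if (length(y_true) < 1L) stop("empty input")
  n <- length(y_true)
  joint <- table(class = y_true, cluster = clusters) / n
  pc <- rowSums(joint)   # class marginal
  pk <- colSums(joint)   # cluster marginal
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  H_c <- H(pc); H_k <- H(pk)
  # conditional entropies from the joint
  H_c_given_k <- -sum(joint[joint > 0] *
                        log(joint[joint > 0] /
                              rep(pk, each = nrow(joint))[joint > 0]))
  H_k_given_c <- -sum(joint[joint > 0] *
                        log(joint[joint > 0] /
                              matrix(pc, nrow(joint), ncol(joint))[joint > 0]))
  h <- if (H_c == 0) 1 else 1 - H_c_given_k / H_c
  co <- if (H_k == 0) 1 else 1 - H_k_given_c / H_k
  c(homogeneity = h, completeness = co)
}

#' Majority-vote cluster-to-label mapping
#'
#' Assigns each cluster its most frequent true label (ties resolve to the
#' lowest label index), then scores the fraction of reads whose cluster's
#' assigned label matches their true label (`mapped_accuracy`), together
#' with homogeneity and completeness. This is the protocol for comparing
#' an unsupervised clustering against barcode ground truth.
#'
#' @inheritParams homogeneity_completeness
#' @return Object of class `clustering_report`: list with `homogeneity`,
#'   `completeness`, `mapped_accuracy`, `cluster_to_label` (named integer
#'   vector).
#' @examples
#' majority_vote_map(c(0, 0, 1, 1, 1), c(1, 1, 1, 2, 2))$mapped_accuracy
#' @export
majority_vote_map <- function(y_true, clusters) {
  if (length(y_true) != length(clusters)) stop("length mismatch")
  if (length(y_true) < 1L) stop("empty input")
  y_true <- as.integer(y_true)
  ids <- sort(unique(clusters))
  mapping <- vapply(ids, function(k) {
    tab <- table(y_true[clusters == k])
    labs <- as.integer(names(tab))
    labs[which.max(tab)]  # which.max: first max = lowest label index
  }, integer(1L))
  names(mapping) <- as.character(ids)
  mapped <- mapping[match(clusters, ids)]
  hc <- homogeneity_completeness(y_true, clusters)
  structure(list(homogeneity = unname(hc["homogeneity"]),
                 completeness = unname(hc["completeness"]),
                 mapped_accuracy = mean(mapped == y_true),
                 cluster_to_label = mapping),
            class = "clustering_report")
}

#' @export
print.clustering_report <- function(x, ...) {
  cat(sprintf("homogeneity %.4f  completeness %.4f  mapped accuracy %.4f\n",
              x$homogeneity, x$completeness, x$mapped_accuracy))
  invisible(x)
}

#' Evaluate predictions against ground truth
#'
#' Joins predictions and truth on `read_id` (row order is irrelevant),
#' computes the full classification report including per-class one-vs-rest
#' AUC when probabilities are available, and optionally the clustering
#' protocol when cluster assignments are supplied.
#'
#' @param pred A `demuxtrans_pred`, or a path to a predictions TSV
#'   ([write_predictions()]).
#' @param truth A labelled [signal_set()], or a path to a signal table.
#' @param clusters Optional: named integer vector of cluster ids (names =
#'   read_ids), or a path to a two-column `read_id<TAB>cluster_id` TSV.
#' @param out Optional path; the report is written there as JSON.
#' @return List with `classification` (an `eval_report`, plus
#'   `per_class_auc`) and, when clusters are given, `clustering` (a
#'   `clustering_report`).
#' @export
evaluate <- function(pred, truth, clusters = NULL, out = NULL) {
  if (is.character(pred)) pred <- read_predictions(pred)
  if (is.character(truth)) truth <- read_signal_table(truth)
  stopifnot(inherits(pred, "demuxtrans_pred"), inherits(truth, "signal_set"))
  truth_ids <- vapply(truth$signals, `[[`, character(1L), "read_id")
  truth_lab <- signal_labels(truth$signals)
  if (anyNA(truth_lab)) stop("truth contains unlabelled reads")
  m <- match(truth_ids, pred$read_ids)
  if (anyNA(m)) {
    stop("reads missing from predictions: ",
         paste(utils::head(truth_ids[is.na(m)], 10L), collapse = ", "))
  }
  y_true <- truth_lab
  y_pred <- pred$class[m]
  C <- truth$n_classes
  cr <- classification_metrics(y_true, y_pred, C)
  auc <- rep(NA_real_, C)
  for (c in 0:(C - 1L)) {
    auc[c + 1L] <- tryCatch(roc_auc_ovr(y_true, pred$prob[m, , drop = FALSE], c),
                            error = function(e) NA_real_)
  }
  cr$per_class_auc <- auc
  result <- list(classification = cr)
  if (!is.null(clusters)) {
    if (is.character(clusters)) {
      df <- utils::read.delim(clusters, header = TRUE,
                              stringsAsFactors = FALSE)
      if (!all(c("read_id", "cluster_id") %in% names(df))) {
        stop("clusters TSV needs columns read_id, cluster_id")
      }
      clusters <- stats::setNames(df$cluster_id, df$read_id)
    }
    mc <- match(truth_ids, names(clusters))
    if (anyNA(mc)) {
      stop("reads missing from clusters: ",
           paste(utils::head(truth_ids[is.na(mc)], 10L), collapse = ", "))
    }
    result$clustering <- majority_vote_map(y_true, unname(clusters[mc]))
  }
  if (!is.null(out)) write_eval_report(result, out)
  result
}

#' Write an evaluation report as JSON
#'
#' Schema version 1: `schema_version`, `classification` (accuracy,
#' macro/micro scores, per-class table, confusion matrix, per-class AUC,
#' zero-denominator flags) and optionally `clustering`.
#'
#' @param report Result of [evaluate()].
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  cls <- report$classification
  obj <- list(schema_version = 1L,
              classification = list(
                accuracy = cls$accuracy,
                macro_precision = cls$macro_precision,
                macro_recall = cls$macro_recall,
                macro_f1 = cls$macro_f1,
                micro_accuracy = cls$micro_accuracy,
                per_class = cls$per_class,
                per_class_auc = cls$per_class_auc,
                confusion = unclass(cls$confusion),
                zero_denominator = cls$zero_denominator,
                n = cls$n))
  if (!is.null(report$clustering)) {
    cl <- report$clustering
    obj$clustering <- list(homogeneity = cl$homogeneity,
                           completeness = cl$completeness,
                           mapped_accuracy = cl$mapped_accuracy,
                           cluster_to_label = as.list(cl$cluster_to_label))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
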