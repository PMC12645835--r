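#' Mean cross-entropy loss
#'
#' Mean over the batch of `-log softmax(logits)[label]`, computed with the
#' usual max-shift for numerical stability.
#'
#' @param logits Matrix `(batch, n_classes)`.
#' @param labels Integer vector of 0-based class labels in `[0, C)`.
#' @return Non-negative scalar loss.
#' @examples
#' cross_entropy(matrix(0, 2, 4), c(0L, 3L))  # log(4)
#' @export
cross_entropy <- function(logits, labels) {
  logits <- as.matrix(logits)
  C <- ncol(logits)
  if (length(labels) != nrow(logits)) stop("labels length != batch size")
  if (any(labels < 0L | labels >= C)) {
    stop("label out of range [0, ", C, ")")
  }
  mx <- apply(logits, 1L, max)
  sh <- logits - mx
  lse <- log(rowSums(exp(sh)))
  picked <- sh[cbind(seq_len(nrow(logits)), labels + 1L)]
  mean(lse - picked)
}

# softmax over columns of a (C, B) logit matrix
softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

#' Augmentation parameters
#'
#' The standard trio for current-trace classifiers, each independently
#' switchable: additive Gaussian noise, multiplicative amplitude jitter,
#' and circular time shift. Applied per read with probability
#' `apply_prob`.
#'
#' @param noise_sd Additive Gaussian noise s.d. (>= 0).
#' @param scale_range Length-2 `(lo, hi)` with `0 < lo <= 1 <= hi`;
#'   amplitude multiplier drawn uniformly in this range.
#' @param shift_max Maximum circular shift in samples (integer >= 0).
#' @param time_warp Elastic time-warp strength (>= 0): interior anchor
#'   points are jittered by a normal with s.d. `time_warp * L` and the
#'   trace is linearly re-interpolated along the warped axis, emulating
#'   dwell-time variability; 0 disables.
#' @param apply_prob Per-read probability of augmenting, in `[0, 1]`.
#' @return An object of class `aug_params`.
#' @export
aug_params <- function(noise_sd = 0.1, scale_range = c(0.9, 1.1),
                       shift_max = 8L, time_warp = 0.02,
                       apply_prob = 0.5) {
  stopifnot(noise_sd >= 0, length(scale_range) == 2L,
            scale_range[1L] > 0, scale_range[1L] <= 1,
            scale_range[2L] >= 1, shift_max >= 0L, time_warp >= 0,
            apply_prob >= 0, apply_prob <= 1)
  structure(list(noise_sd = noise_sd, scale_range = scale_range,
                 shift_max = as.integer(shift_max),
                 time_warp = time_warp,
                 apply_prob = apply_prob),
            class = "aug_params")
}

#' Augment a signal batch
#'
#' Per read, with probability `apply_prob`: adds Gaussian noise, rescales
#' the amplitude by a uniform draw from `scale_range`, and circularly
#' shifts the trace by an integer uniform in `[-shift_max, shift_max]`.
#' Labels are untouched and the result is deterministic given `seed`.
#'
#' @param batch A `signal_batch`.
#' @param params An [aug_params()] object.
#' @param seed Integer seed.
#' @return The augmented `signal_batch`.
#' @export
augment <- function(batch, params, seed = 0L) {
  stopifnot(inherits(batch, "signal_batch"), inherits(params, "aug_params"))
  with_seed(seed, augment_(batch, params))
}

# unseeded core, usable inside an already-seeded training loop
augment_ <- function(batch, params) {
  vals <- batch$values
  B <- dim(vals)[1L]; L <- dim(vals)[3L]
  for (i in seq_len(B)) {
    if (stats::runif(1L) > params$apply_prob) next
    x <- vals[i, 1L, ]
    if (params$noise_sd > 0) x <- x + stats::rnorm(L, sd = params$noise_sd)
    sc <- stats::runif(1L, params$scale_range[1L], params$scale_range[2L])
    x <- x * sc
    if (params$shift_max > 0L) {
      s <- sample.int(2L * params$shift_max + 1L, 1L) - params$shift_max - 1L
      if (s != 0L) x <- x[((seq_len(L) - 1L - s) %% L) + 1L]
    }
    tw <- if (is.null(params$time_warp)) 0 else params$time_warp
    if (tw > 0) {
      anchors <- seq(1, L, length.out = 9L)
      jit <- anchors
      k <- length(anchors)
      jit[2:(k - 1L)] <- anchors[2:(k - 1L)] +
        stats::rnorm(k - 2L, sd = tw * L)
      jit <- pmin(pmax(sort(jit), 1), L)
      pos <- stats::approx(anchors, jit, xout = seq_len(L))$y
      x <- stats::approx(seq_len(L), x, xout = pos)$y
    }
    vals[i, 1L, ] <- x
  }
  batch$values <- vals
  batch
}

#' Training parameters
#'
#' @param epochs Maximum epochs (>= 0; 0 returns initialised weights).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param weight_decay Decoupled L2 weight decay.
#' @param lr_schedule `"cosine"` (default: cosine decay of the step size
#'   to 1/100 of `learning_rate` over `epochs`) or `"constant"`.
#' @param early_stop_patience Stop after this many epochs without
#'   validation-loss improvement.
#' @param seed Master seed for weight init, shuffling, augmentation and
#'   dropout.
#' @param augmentation An [aug_params()] object, or `NULL` to disable.
#' @return An object of class `train_params`.
#' @export
train_params <- function(epochs = 30L, batch_size = 32L,
                         learning_rate = 1e-3, weight_decay = 1e-4,
                         lr_schedule = c("cosine", "constant"),
                         early_stop_patience = 5L, seed = 1L,
                         augmentation = aug_params()) {
  stopifnot(epochs >= 0L, batch_size >= 1L, learning_rate > 0,
            weight_decay >= 0, early_stop_patience >= 1L)
  lr_schedule <- match.arg(lr_schedule)
  if (!is.null(augmentation)) stopifnot(inherits(augmentation, "aug_params"))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 lr_schedule = lr_schedule,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), augmentation = augmentation),
            class = "train_params")
}

#' Fit the demultiplexing network
#'
#' Trains the fusion-Transformer-TCN classifier on a labelled
#' [signal_set()] with Adam (decoupled weight decay) on the mean
#' cross-entropy, restoring the weights of the best validation epoch and
#' stopping early after `early_stop_patience` non-improving epochs.
#' Every source of randomness (weight init, shuffling, augmentation,
#' dropout) derives from `params$seed`, so a run is exactly reproducible.
#'
#' @param train_set Labelled [signal_set()] used for gradient steps.
#' @param val_set Labelled [signal_set()] used for model selection; when
#'   `NULL`, the final-epoch weights are kept and no early stopping
#'   occurs.
#' @param config A [demux_config()]; `config$n_classes` must equal the
#'   sets' `n_classes`.
#' @param params A [train_params()] object.
#' @param normalize_method,length_policy,spike_filter Preprocessing, as in
#'   [make_batches()].
#' @param log_file Optional path: per-epoch metrics are appended as JSON
#'   lines.
#' @param verbose Print per-epoch progress?
#' @return An object of class `demuxtrans`: list with `weights`, `config`,
#'   `history` (data frame of per-epoch train loss, validation loss and
#'   accuracy), `best_epoch`, `params`, preprocessing settings and
#'   `n_params`.
#' @seealso [predict.demuxtrans()], [save_checkpoint()]
#' @export
demuxtrans <- function(train_set, val_set = NULL, config,
                       params = train_params(),
                       normalize_method = "median_mad",
                       length_policy = "resample",
                       spike_filter = 3L,
                       log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(train_set, "signal_set"),
            inherits(config, "demux_config"),
            inherits(params, "train_params"))
  if (train_set$n_classes != config$n_classes) {
    stop("train_set has ", train_set$n_classes, " classes but config has ",
         config$n_classes)
  }
  if (!is.null(val_set)) {
    stopifnot(inherits(val_set, "signal_set"))
    if (val_set$n_classes != config$n_classes) {
      stop("val_set class count mismatch")
    }
    if (length(val_set$signals) == 0L) stop("empty validation split")
  }
  if (length(train_set$signals) == 0L) stop("empty training split")
  if (anyNA(signal_labels(train_set$signals))) {
    stop("train_set contains unlabelled reads")
  }

  weights <- init_weights(config, seed = params$seed)
  tn <- trainable_names(weights)
  opt <- list(m = lapply(weights[tn], function(w) w * 0),
              v = lapply(weights[tn], function(w) w * 0), t = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_accuracy = numeric())
  best <- list(epoch = 0L, val_loss = Inf, weights = weights)
  L <- config$input_length

  val_batches <- if (!is.null(val_set)) {
    make_batches(val_set, L, params$batch_size,
                 normalize_method = normalize_method,
                 length_policy = length_policy,
                 spike_filter = spike_filter, shuffle = FALSE)
  } else NULL

  run_epochs <- with_seed(params$seed + 1L, {
    stale <- 0L
    done <- 0L
    for (epoch in seq_len(params$epochs)) {
      lr_now <- if (identical(params$lr_schedule, "cosine") &&
                    params$epochs > 1L) {
        frac <- (epoch - 1) / (params$epochs - 1)
        lr_min <- params$learning_rate / 100
        lr_min + (params$learning_rate - lr_min) * (1 + cos(pi * frac)) / 2
      } else params$learning_rate
      batches <- make_batches(train_set, L, params$batch_size,
                              normalize_method = normalize_method,
                              length_policy = length_policy,
                              spike_filter = spike_filter,
                              shuffle = TRUE,
                              seed = sample.int(.Machine$integer.max - 1L, 1L))
      ep_loss <- 0
      n_seen <- 0L
      for (bt in batches) {
        if (!is.null(params$augmentation)) bt <- augment_(bt, params$augmentation)
        B <- dim(bt$values)[1L]
        fw <- nn_forward(arr_to_flat(bt$values), weights, config, B,
                         training = TRUE, keep_cache = TRUE)
        P <- softmax_cols(fw$logits)
        lab1 <- bt$labels + 1L
        eps <- 1e-12
        loss <- -mean(log(pmax(P[cbind(lab1, seq_len(B))], eps)))
        dlogits <- P
        dlogits[cbind(lab1, seq_len(B))] <-
          dlogits[cbind(lab1, seq_len(B))] - 1
        dlogits <- dlogits / B
        grads <- nn_backward(dlogits, weights, config, fw$cache)
        weights[names(fw$run)] <- fw$run  # batch-norm running stats
        upd <- adam_step(weights, grads, opt, tn,
                         lr = lr_now, wd = params$weight_decay)
        weights <- upd$weights
        opt <- upd$opt
        ep_loss <- ep_loss + loss * B
        n_seen <- n_seen + B
      }
      ep_loss <- ep_loss / n_seen
      vl <- NA_real_; va <- NA_real_
      if (!is.null(val_batches)) {
        ev <- eval_batches(val_batches, weights, config)
        vl <- ev$loss; va <- ev$accuracy
      }
      history[nrow(history) + 1L, ] <- list(epoch, ep_loss, vl, va)
      if (!is.null(log_file)) {
        cat(jsonlite::toJSON(list(epoch = epoch, train_loss = ep_loss,
                                  val_loss = vl, val_accuracy = va),
                             auto_unbox = TRUE, digits = NA, na = "null"),
            "\n", sep = "", file = log_file, append = TRUE)
      }
      if (verbose) {
        cat(sprintf("epoch %3d  train %.4f  val %.4f  acc %.4f\n",
                    epoch, ep_loss, vl, va))
      }
      done <- epoch
      if (!is.null(val_batches)) {
        if (vl < best$val_loss) {
          best <- list(epoch = epoch, val_loss = vl, weights = weights)
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= params$early_stop_patience) break
        }
      }
    }
    list(history = history, weights = weights, best = best, done = done)
  })
  history <- run_epochs$history
  best <- run_epochs$best
  final_weights <- if (!is.null(val_set) && best$epoch > 0L) {
    best$weights
  } else run_epochs$weights

  structure(list(weights = final_weights, config = config,
                 history = history,
                 best_epoch = if (!is.null(val_set)) best$epoch
                              else run_epochs$done,
                 params = params,
                 normalize_method = normalize_method,
                 length_policy = length_policy,
                 spike_filter = spike_filter,
                 n_params = count_params(config),
                 package_version = as.character(utils::packageVersion("demuxsig"))),
            class = "demuxtrans")
}

adam_step <- function(weights, grads, opt, tn, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in tn) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    # decoupled weight decay on weight matrices only (biases and norm
    # gains/offsets are vectors and stay undecayed)
    if (wd > 0 && is.matrix(weights[[nm]])) {
      step <- step + lr * wd * weights[[nm]]
    }
    weights[[nm]] <- weights[[nm]] - step
  }
  list(weights = weights, opt = opt)
}

eval_batches <- function(batches, weights, config) {
  tot_loss <- 0; n <- 0L; correct <- 0L
  for (bt in batches) {
    B <- dim(bt$values)[1L]
    fw <- nn_forward(arr_to_flat(bt$values), weights, config, B,
                     training = FALSE)
    P <- softmax_cols(fw$logits)
    lab1 <- bt$labels + 1L
    tot_loss <- tot_loss - sum(log(pmax(P[cbind(lab1, seq_len(B))], 1e-12)))
    pred <- apply(P, 2L, which.max)  # ties: lowest index
    correct <- correct + sum(pred == lab1)
    n <- n + B
  }
  list(loss = tot_loss / n, accuracy = correct / n)
}

#' Predict barcode classes for new reads
#'
#' Runs the fitted model in eval mode (deterministic: dropout off, batch
#' norm on running statistics, so results do not depend on batch size).
#' Ties in the logits resolve to the lowest class index.
#'
#' @param object A fitted [demuxtrans()] model.
#' @param newdata A [signal_set()].
#' @param batch_size Reads per forward pass.
#' @param ... Unused.
#' @return List of class `demuxtrans_pred`: `prob` (matrix `(n, C)`, rows
#'   summing to 1, rownames = read_ids), `class` (0-based predicted
#'   labels), `read_ids`.
#' @export
predict.demuxtrans <- function(object, newdata, batch_size = 64L, ...) {
  stopifnot(inherits(newdata, "signal_set"))
  sf <- if (is.null(object$spike_filter)) 1L else object$spike_filter
  batches <- make_batches(newdata, object$config$input_length, batch_size,
                          normalize_method = object$normalize_method,
                          length_policy = object$length_policy,
                          spike_filter = sf, shuffle = FALSE)
  probs <- NULL; ids <- character()
  for (bt in batches) {
    B <- dim(bt$values)[1L]
    fw <- nn_forward(arr_to_flat(bt$values), object$weights, object$config,
                     B, training = FALSE)
    probs <- rbind(probs, t(softmax_cols(fw$logits)))
    ids <- c(ids, bt$read_ids)
  }
  rownames(probs) <- ids
  cls <- max.col(probs, ties.method = "first") - 1L
  structure(list(prob = probs, class = cls, read_ids = ids),
            class = "demuxtrans_pred")
}

#' Write predictions as TSV
#'
#' Columns `read_id<TAB>pred_label<TAB>probs`, probabilities
#' comma-separated at full precision.
#'
#' @param pred A `demuxtrans_pred` from [predict.demuxtrans()].
#' @param path Output path.
#' @export
write_predictions <- function(pred, path) {
  stopifnot(inherits(pred, "demuxtrans_pred"))
  rows <- vapply(seq_along(pred$read_ids), function(i) {
    paste(pred$read_ids[i], pred$class[i],
          paste(formatC(pred$prob[i, ], digits = 17, format = "g"),
                collapse = ","),
          sep = "\t")
  }, character(1L))
  writeLines(c("read_id\tpred_label\tprobs", rows), path)
  invisible(path)
}

#' Read a predictions TSV
#'
#' @param path Path written by [write_predictions()].
#' @return A `demuxtrans_pred`.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) >= 1L,
            identical(lines[[1L]], "read_id\tpred_label\tprobs"))
  body <- lines[-1L][nzchar(lines[-1L])]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1L), 1L)
  cls <- as.integer(vapply(parts, `[[`, character(1L), 2L))
  prob <- do.call(rbind, lapply(parts, function(p) {
    as.numeric(strsplit(p[[3L]], ",", fixed = TRUE)[[1L]])
  }))
  rownames(prob) <- ids
  structure(list(prob = prob, class = cls, read_ids = ids),
            class = "demuxtrans_pred")
}

#' Save / load a model checkpoint
#'
#' A single-file archive holding the weights, the full configuration and
#' the package version; loading re-validates the configuration.
#'
#' @param object A fitted `demuxtrans` model.
#' @param path Checkpoint path.
#' @return `load_checkpoint` returns the `demuxtrans` object.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "demuxtrans"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "demuxtrans")) stop("not a demuxtrans checkpoint: ", path)
  validate_config(unclass(obj$config))
  obj
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.demuxtrans <- function(x, ...) {
  cat("demuxtrans model:", x$config$n_classes, "classes,",
      format(x$n_params, big.mark = ","), "parameters\n")
  if (nrow(x$history)) {
    cat("  trained", nrow(x$history), "epochs; best epoch", x$best_epoch)
    be <- x$history[x$history$epoch == x$best_epoch, ]
    if (nrow(be) && is.finite(be$val_loss)) {
      cat(sprintf(" (val loss %.4f, val accuracy %.4f)",
                  be$val_loss, be$val_accuracy))
    }
    cat("\n")
  } else {
    cat("  untrained (0 epochs)\n")
  }
  invisible(x)
}

#' @export
summary.demuxtrans <- function(object, ...) {
  structure(list(config = object$config, history = object$history,
                 best_epoch = object$best_epoch,
                 n_params = object$n_params), class = "summary.demuxtrans")
}

#' @export
print.summary.demuxtrans <- function(x, ...) {
  print(x$config)
  cat("parameters:", format(x$n_params, big.mark = ","), "\n")
  if (nrow(x$history)) {
    cat("training history (last 5 epochs):\n")
    print(utils::tail(x$history, 5L), row.names = FALSE)
    cat("best epoch:", x$best_epoch, "\n")
  }
  invisible(x)
}

#' @export
coef.demuxtrans <- function(object, ...) {
  object$weights[trainable_names(object$weights)]
}

#' @export
plot.demuxtrans <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  ylim <- range(c(h$train_loss, h$val_loss), finite = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "steelblue",
                 xlab = "epoch", ylab = "cross-entropy loss", ylim = ylim,
                 main = "demuxtrans training", ...)
  if (any(is.finite(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, col = "firebrick")
    graphics::abline(v = x$best_epoch, lty = 3)
    graphics::legend("topright", c("train", "validation"),
                     col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  }
  invisible(x)
}
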