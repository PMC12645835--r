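#' Attention profile of a single read
#'
#' Runs the model on one read with attention capture, averages the
#' attention weights over layers, heads and query positions to obtain a
#' key-position importance vector at the model's temporal resolution
#' `T = L/p^2`, upsamples it to the raw-sample scale by repeating each
#' value `p^2` times (constant repetition, not interpolation, so mass
#' attribution stays honest to the model's resolution), and renormalizes
#' to sum 1. High-importance regions typically align with sharp current
#' transitions in the trace.
#'
#' @param object A fitted [demuxtrans()] model (or a list with `weights`
#'   and `config`).
#' @param signal A [raw_signal()].
#' @param per_head Return the unaggregated `(layers, heads, T)` importance
#'   array as well?
#' @return Object of class `attention_profile`: list with `signal` (the
#'   normalized, length-standardized trace of length L), `importance`
#'   (length L, non-negative, sums to 1), `downsample_factor` (p^2),
#'   `read_id`, and optionally `per_head`.
#' @export
attention_profile <- function(object, signal, per_head = FALSE) {
  ck <- interpret_setup(object, signal)
  A <- ck$attn  # (layers, heads, T, T, 1)
  Tlen <- dim(A)[3L]
  # mean over layers, heads and query rows -> key importance
  imp_T <- apply(A[, , , , 1L, drop = FALSE], 4L, mean)
  p2 <- ck$cfg$pool_factor^2
  imp <- rep(imp_T, each = p2)
  imp <- imp / sum(imp)
  out <- list(signal = ck$x, importance = imp, downsample_factor = p2,
              read_id = signal$read_id)
  if (per_head) {
    out$per_head <- apply(A[, , , , 1L, drop = FALSE], c(1L, 2L, 4L), mean)
  }
  structure(out, class = "attention_profile")
}

interpret_setup <- function(object, signal) {
  stopifnot(inherits(signal, "raw_signal"))
  cfg <- object$config
  W <- object$weights
  if (is.null(cfg) || is.null(W)) stop("object has no weights/config")
  if (cfg$n_transformer_layers < 1L) {
    stop("attention requires at least one transformer layer")
  }
  nm <- if (!is.null(object$normalize_method)) object$normalize_method
        else "median_mad"
  lp <- if (!is.null(object$length_policy)) object$length_policy
        else "resample"
  sf <- if (is.null(object$spike_filter)) 1L else object$spike_filter
  signal$samples <- spike_filter_samples(signal$samples, sf)
  x <- standardize_length(normalize_signal(signal, nm), cfg$input_length, lp)
  batch <- array(x, dim = c(1L, 1L, cfg$input_length))
  fw <- model_forward(batch, cfg, W, mode = "eval", return_attention = TRUE)
  if (is.null(fw$attention)) stop("model returned no attention")
  list(attn = fw$attention, x = x, cfg = cfg)
}

#' Inter-timepoint attention (chord) matrix
#'
#' Averages attention over layers and heads to a `T x T` matrix,
#' symmetrizes it as `(M + t(M))/2`, zeroes the diagonal, and extracts the
#' `top_k` strongest off-diagonal links as `(i, j, weight)` edges sorted
#' by descending weight — the data behind a chord diagram of long-range
#' dependencies between signal regions.
#'
#' @inheritParams attention_profile
#' @param top_k Number of edges to keep (clamped, with a warning, to the
#'   number of distinct off-diagonal pairs).
#' @return Object of class `chord_matrix`: list with `matrix` (`T x T`,
#'   symmetric, zero diagonal), `edges` (data frame `i`, `j`, `weight`
#'   with `i < j`, 1-based model positions), `downsample_factor`.
#' @export
chord_matrix <- function(object, signal, top_k = 50L) {
  top_k <- as.integer(top_k)
  stopifnot(top_k >= 1L)
  ck <- interpret_setup(object, signal)
  A <- ck$attn
  Tlen <- dim(A)[3L]
  M <- apply(A[, , , , 1L, drop = FALSE], c(3L, 4L), mean)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  max_k <- (Tlen * (Tlen - 1L)) %/% 2L
  if (top_k > max_k) {
    warning("top_k clamped from ", top_k, " to ", max_k)
    top_k <- max_k
  }
  ut <- which(upper.tri(M), arr.ind = TRUE)
  w <- M[ut]
  ord <- order(w, decreasing = TRUE)[seq_len(top_k)]
  edges <- data.frame(i = ut[ord, 1L], j = ut[ord, 2L], weight = w[ord])
  structure(list(matrix = M, edges = edges,
                 downsample_factor = ck$cfg$pool_factor^2,
                 read_id = signal$read_id),
            class = "chord_matrix")
}

#' Export / import interpretability artifacts
#'
#' Serializes an [attention_profile()] or [chord_matrix()] losslessly
#' (full double precision) as JSON or TSV; `read_interpretation` reads
#' either format back. JSON and TSV exports carry identical values.
#'
#' @param x An `attention_profile` or `chord_matrix`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_interpretation <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (inherits(x, "attention_profile")) {
    if (format == "json") {
      jsonlite::write_json(list(type = "attention_profile",
                                read_id = x$read_id,
                                downsample_factor = x$downsample_factor,
                                signal = x$signal,
                                importance = x$importance),
                           path, auto_unbox = TRUE, digits = NA)
    } else {
      lines <- c(paste0("# attention_profile\tread_id=", x$read_id,
                        "\tdownsample_factor=", x$downsample_factor),
                 "signal\timportance",
                 paste(formatC(x$signal, digits = 17, format = "g"),
                       formatC(x$importance, digits = 17, format = "g"),
                       sep = "\t"))
      writeLines(lines, path)
    }
  } else if (inherits(x, "chord_matrix")) {
    if (format == "json") {
      jsonlite::write_json(list(type = "chord_matrix",
                                read_id = x$read_id,
                                downsample_factor = x$downsample_factor,
                                matrix = x$matrix,
                                edges = x$edges),
                           path, auto_unbox = TRUE, digits = NA,
                           matrix = "rowmajor")
    } else {
      lines <- c(paste0("# chord_matrix\tread_id=", x$read_id,
                        "\tdownsample_factor=", x$downsample_factor,
                        "\tT=", nrow(x$matrix)),
                 "i\tj\tweight")
      if (nrow(x$edges)) {
        lines <- c(lines,
                   paste(x$edges$i, x$edges$j,
                         formatC(x$edges$weight, digits = 17, format = "g"),
                         sep = "\t"))
      }
      writeLines(lines, path)
    }
  } else {
    stop("x must be an attention_profile or chord_matrix")
  }
  invisible(path)
}

#' @rdname export_interpretation
#' @export
read_interpretation <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "{")) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (identical(obj$type, "attention_profile")) {
      return(structure(list(signal = obj$signal,
                            importance = obj$importance,
                            downsample_factor = obj$downsample_factor,
                            read_id = obj$read_id),
                       class = "attention_profile"))
    }
    if (identical(obj$type, "chord_matrix")) {
      edges <- as.data.frame(obj$edges)
      if (!nrow(edges)) edges <- data.frame(i = integer(), j = integer(),
                                            weight = numeric())
      return(structure(list(matrix = obj$matrix, edges = edges,
                            downsample_factor = obj$downsample_factor,
                            read_id = obj$read_id),
                       class = "chord_matrix"))
    }
    stop("unknown interpretation type in ", path)
  }
  header <- strsplit(sub("^# ", "", first), "\t", fixed = TRUE)[[1L]]
  kv <- strsplit(header[-1L], "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[[`, character(1L), 2L),
                          vapply(kv, `[[`, character(1L), 1L))
  body <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  if (identical(header[[1L]], "attention_profile")) {
    structure(list(signal = body$signal, importance = body$importance,
                   downsample_factor = as.integer(meta[["downsample_factor"]]),
                   read_id = meta[["read_id"]]),
              class = "attention_profile")
  } else if (identical(header[[1L]], "chord_matrix")) {
    structure(list(matrix = NULL, edges = body,
                   downsample_factor = as.integer(meta[["downsample_factor"]]),
                   read_id = meta[["read_id"]]),
              class = "chord_matrix")
  } else {
    stop("unknown interpretation file: ", path)
  }
}
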