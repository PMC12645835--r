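#' Construct a raw-signal record
#'
#' A `raw_signal` holds one read's current trace: the ordered vector of
#' picoampere-like measurements produced while a molecule translocates the
#' pore, plus an optional integer class label (the barcode index) and a
#' free-text provenance string.
#'
#' @param read_id Character scalar, unique identifier of the read.
#' @param samples Numeric vector of current values, length >= 1, all finite.
#' @param label Optional non-negative integer class index (0-based), or `NULL`.
#' @param source Optional free-text provenance, or `NULL`.
#' @return An object of class `raw_signal`.
#' @examples
#' s <- raw_signal("r1", c(0.5, 1.2, 0.9), label = 0)
#' length(s$samples)
#' @export
raw_signal <- function(read_id, samples, label = NULL, source = NULL) {
  if (!is.character(read_id) || length(read_id) != 1L || is.na(read_id) ||
      !nzchar(read_id)) {
    stop("read_id must be a non-empty character scalar")
  }
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("samples must be non-empty (read_id ", read_id, ")")
  }
  if (!all(is.finite(samples))) {
    stop("samples must all be finite (read_id ", read_id, ")")
  }
  if (!is.null(label)) {
    if (length(label) != 1L || is.na(label) || label < 0 ||
        label != as.integer(label)) {
      stop("label must be a single non-negative integer (read_id ",
           read_id, ")")
    }
    label <- as.integer(label)
  }
  structure(list(read_id = read_id, samples = samples, label = label,
                 source = source),
            class = "raw_signal")
}

#' Construct a signal set
#'
#' An ordered collection of [raw_signal()] records sharing one class
#' vocabulary of `n_classes` barcodes, plus free-form metadata (normalization
#' applied, simulator parameters, ...).
#'
#' @param signals List of `raw_signal` objects.
#' @param n_classes Integer number of barcode classes (>= 1).
#' @param metadata Named list of character metadata.
#' @return An object of class `signal_set`.
#' @export
signal_set <- function(signals, n_classes, metadata = list()) {
  if (!is.list(signals) || !all(vapply(signals, inherits, logical(1L),
                                       "raw_signal"))) {
    stop("signals must be a list of raw_signal objects")
  }
  n_classes <- as.integer(n_classes)
  if (length(n_classes) != 1L || is.na(n_classes) || n_classes < 1L) {
    stop("n_classes must be a single integer >= 1")
  }
  ids <- vapply(signals, `[[`, character(1L), "read_id")
  if (anyDuplicated(ids)) {
    stop("duplicate read_id in signal set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  labels <- signal_labels(signals)
  if (any(!is.na(labels) & labels >= n_classes)) {
    stop("label >= n_classes found")
  }
  structure(list(signals = signals, n_classes = n_classes,
                 metadata = metadata),
            class = "signal_set")
}

signal_labels <- function(signals) {
  vapply(signals, function(s) if (is.null(s$label)) NA_integer_ else s$label,
         integer(1L))
}

#' @export
print.signal_set <- function(x, ...) {
  labels <- signal_labels(x$signals)
  cat("signal_set:", length(x$signals), "reads,", x$n_classes, "classes\n")
  if (length(x$signals)) {
    lens <- lengths(lapply(x$signals, `[[`, "samples"))
    cat("  trace length: median", stats::median(lens),
        "range [", min(lens), ",", max(lens), "]\n")
    if (any(!is.na(labels))) {
      cat("  labelled reads:", sum(!is.na(labels)), "\n")
    }
  }
  invisible(x)
}

#' @export
length.signal_set <- function(x) length(x$signals)

#' Read or write a signal table
#'
#' The native plain-text interchange format is a TSV with header
#' `read_id<TAB>label<TAB>samples`, one read per row, `samples` a
#' comma-separated list of decimals, `label` empty when absent.  Numbers are
#' written with full double precision (17 significant digits) so a
#' write/read round trip is lossless.
#'
#' `dialect = "container"` selects a single-file binary multi-read store
#' instead (see [write_signal_container()]).
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"container"`.
#' @return For `read_signal_table`, a [signal_set()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' s <- signal_set(list(raw_signal("r1", c(1, 2.5), 0)), n_classes = 2)
#' write_signal_table(s, tf)
#' identical(read_signal_table(tf)$signals[[1]]$samples, c(1, 2.5))
#' @export
read_signal_table <- function(path, dialect = c("tsv", "container")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "container") return(read_signal_container(path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop("empty file (missing header): ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("read_id", "label", "samples"))) {
    stop("bad header on line 1 of ", path,
         ": expected 'read_id\\tlabel\\tsamples'")
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  signals <- vector("list", length(body))
  for (i in seq_along(body)) {
    lineno <- i + 1L
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 3L) {
      stop("malformed row on line ", lineno, " of ", path,
           ": expected 3 tab-separated fields, got ", length(fields))
    }
    if (!nzchar(fields[[3L]])) {
      stop("empty samples field on line ", lineno, " of ", path)
    }
    samples <- suppressWarnings(
      as.numeric(strsplit(fields[[3L]], ",", fixed = TRUE)[[1L]]))
    if (anyNA(samples)) {
      stop("non-numeric sample on line ", lineno, " of ", path)
    }
    label <- if (nzchar(fields[[2L]])) {
      lab <- suppressWarnings(as.integer(fields[[2L]]))
      if (is.na(lab)) stop("non-integer label on line ", lineno, " of ", path)
      lab
    } else NULL
    signals[[i]] <- raw_signal(fields[[1L]], samples, label)
  }
  ids <- vapply(signals, `[[`, character(1L), "read_id")
  if (anyDuplicated(ids)) {
    stop("duplicate read_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  labels <- signal_labels(signals)
  n_classes <- if (all(is.na(labels))) 1L else max(labels, na.rm = TRUE) + 1L
  signal_set(signals, n_classes = n_classes,
             metadata = list(source = path))
}

#' @param set A [signal_set()].
#' @rdname read_signal_table
#' @export
write_signal_table <- function(set, path, dialect = c("tsv", "container")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(set, "signal_set"))
  if (dialect == "container") return(write_signal_container(set, path))
  rows <- vapply(set$signals, function(s) {
    paste(s$read_id,
          if (is.null(s$label)) "" else format(s$label),
          paste(formatC(s$samples, digits = 17, format = "g"),
                collapse = ","),
          sep = "\t")
  }, character(1L))
  writeLines(c("read_id\tlabel\tsamples", rows), path, useBytes = TRUE)
  invisible(path)
}

# Binary multi-read container layout (all integers little-endian):
#   bytes 0-7   magic "DMXSIG01"
#   int32       number of reads n
#   per read:
#     int32       id byte length, then that many UTF-8 bytes
#     int32       label (-1 when absent)
#     int32       number of samples m
#     m x float32 samples
#   int32       n_classes
# Samples are stored at float32 precision (the on-disk precision of raw
# nanopore stores); the TSV dialect is the lossless double-precision format.

#' Binary multi-read signal container
#'
#' Single-file binary store with one float32 sample vector per read plus its
#' `read_id` and `label`. The byte layout is fixed and documented in the
#' source; samples round-trip at float32 precision (the TSV dialect is the
#' lossless format).
#'
#' @param set A [signal_set()].
#' @param path File path.
#' @return `read_signal_container` returns a [signal_set()].
#' @export
write_signal_container <- function(set, path) {
  stopifnot(inherits(set, "signal_set"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("DMXSIG01"), con)
  writeBin(length(set$signals), con, size = 4L, endian = "little")
  for (s in set$signals) {
    id <- charToRaw(enc2utf8(s$read_id))
    writeBin(length(id), con, size = 4L, endian = "little")
    writeBin(id, con)
    writeBin(if (is.null(s$label)) -1L else s$label, con, size = 4L,
             endian = "little")
    writeBin(length(s$samples), con, size = 4L, endian = "little")
    writeBin(s$samples, con, size = 4L, endian = "little")
  }
  writeBin(set$n_classes, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_signal_container
#' @export
read_signal_container <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(rawToChar(magic), "DMXSIG01")) {
    stop("not a demuxsig container (bad magic): ", path)
  }
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  signals <- vector("list", n)
  for (i in seq_len(n)) {
    idlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    id <- rawToChar(readBin(con, "raw", idlen))
    label <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    m <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    samples <- readBin(con, "double", m, size = 4L, endian = "little")
    signals[[i]] <- raw_signal(id, samples,
                               label = if (label < 0L) NULL else label)
  }
  n_classes <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  signal_set(signals, n_classes = n_classes,
             metadata = list(source = path))
}

#' Normalize a current trace
#'
#' `median_mad` (the default everywhere in this package) centres by the
#' median and scales by 1.4826 * MAD, a robust estimate of the standard
#' deviation that is insensitive to the spike outliers typical of nanopore
#' currents. `zscore` is the classical (x - mean)/sd; `none` is the
#' identity.
#'
#' @param signal A [raw_signal()] or a bare numeric vector.
#' @param method One of `"median_mad"`, `"zscore"`, `"none"`.
#' @return Same type as the input, with transformed samples.
#' @examples
#' normalize_signal(c(1, 2, 3), "median_mad")  # +- 1/1.4826 around 0
#' @export
normalize_signal <- function(signal,
                             method = c("median_mad", "zscore", "none")) {
  method <- match.arg(method)
  x <- if (inherits(signal, "raw_signal")) signal$samples else as.numeric(signal)
  id <- if (inherits(signal, "raw_signal")) signal$read_id else "<vector>"
  if (length(x) < 1L) stop("empty trace (", id, ")")
  y <- switch(method,
    none = x,
    zscore = {
      s <- stats::sd(x)
      if (!isTRUE(s > 0)) {
        stop("constant trace, zero sd; cannot z-score normalize (", id, ")")
      }
      (x - mean(x)) / s
    },
    median_mad = {
      med <- stats::median(x)
      mad_raw <- stats::median(abs(x - med))
      if (!isTRUE(mad_raw > 0)) {
        stop("degenerate (constant or half-constant) trace, zero MAD; ",
             "cannot median/MAD normalize (", id, ")")
      }
      (x - med) / (1.4826 * mad_raw)
    })
  if (inherits(signal, "raw_signal")) {
    signal$samples <- y
    signal
  } else y
}

#' Standardize a trace to a fixed model input length
#'
#' Barcode signal sits at the start of a read, so the truncation policies
#' keep the first `L` samples (`truncate_head`, the conservative choice for
#' windows cut from longer reads). For traces that *are* the barcode signal
#' end to end — the main use case here — `resample` (the default) linearly
#' interpolates the whole trace onto exactly `L` points, preserving every
#' level transition while removing global dwell-rate variation in read
#' length. Padding policies apply only when the trace is shorter than `L`:
#' `pad_edge` repeats the final value (avoiding a sharp artificial step
#' that convolutions would read as a signal transition), `pad_zero`
#' appends zeros.
#'
#' @param signal A [raw_signal()] or numeric vector.
#' @param L Target length (>= 1).
#' @param policy One of `"resample"`, `"truncate_head"`, `"truncate_tail"`,
#'   `"pad_edge"`, `"pad_zero"`.
#' @return Numeric vector of length exactly `L`.
#' @export
standardize_length <- function(signal, L,
                               policy = c("resample", "truncate_head",
                                          "truncate_tail", "pad_edge",
                                          "pad_zero")) {
  policy <- match.arg(policy)
  x <- if (inherits(signal, "raw_signal")) signal$samples else as.numeric(signal)
  L <- as.integer(L)
  stopifnot(L >= 1L)
  n <- length(x)
  if (n == L) return(x)
  if (policy == "resample") {
    if (n == 1L) return(rep(x, L))
    return(stats::approx(seq_len(n), x, n = L)$y)
  }
  if (n > L) {
    return(switch(policy,
                  truncate_tail = x[(n - L + 1L):n],
                  x[seq_len(L)]))  # head truncation for every other policy
  }
  pad <- switch(policy,
                pad_zero = rep(0, L - n),
                rep(x[n], L - n))  # edge padding is the default fill
  c(x, pad)
}

#' Batch a signal set for the model
#'
#' Normalizes each trace, standardizes its length to `L`, and packs reads
#' into consecutive batches of `batch_size` (the last batch may be smaller).
#' Every read appears in exactly one batch; with `shuffle = TRUE` and a
#' fixed `seed` the composition is reproducible.
#'
#' @param set A [signal_set()].
#' @param L Model input length.
#' @param batch_size Reads per batch (>= 1).
#' @param normalize_method Passed to [normalize_signal()].
#' @param length_policy Passed to [standardize_length()].
#' @param spike_filter Odd width of a running-median prefilter applied
#'   before normalization (1 disables). The default width 3 removes the
#'   isolated single-sample current spikes typical of nanopore traces
#'   while leaving genuine level transitions intact.
#' @param shuffle Randomize read order first?
#' @param seed Integer seed used when `shuffle = TRUE`.
#' @return List of `signal_batch` objects, each a list with `values`
#'   (array `(batch, 1, L)`), `labels` (integer vector or `NULL`),
#'   `lengths` (original lengths), `read_ids`.
#' @export
make_batches <- function(set, L, batch_size,
                         normalize_method = "median_mad",
                         length_policy = "resample",
                         spike_filter = 3L,
                         shuffle = FALSE, seed = 0L) {
  stopifnot(inherits(set, "signal_set"), batch_size >= 1L)
  n <- length(set$signals)
  idx <- seq_len(n)
  if (shuffle) {
    idx <- with_seed(seed, sample.int(n))
  }
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) {
    take <- idx[s:min(s + batch_size - 1L, n)]
    b <- length(take)
    vals <- array(NA_real_, dim = c(b, 1L, L))
    lens <- integer(b)
    labs <- integer(b)
    has_lab <- TRUE
    ids <- character(b)
    for (j in seq_len(b)) {
      sg <- set$signals[[take[j]]]
      sg$samples <- spike_filter_samples(sg$samples, spike_filter)
      x <- tryCatch(normalize_signal(sg, normalize_method),
                    error = function(e) {
                      stop("normalization failed for read ", sg$read_id,
                           ": ", conditionMessage(e), call. = FALSE)
                    })
      vals[j, 1L, ] <- standardize_length(x, L, length_policy)
      lens[j] <- length(sg$samples)
      ids[j] <- sg$read_id
      if (is.null(sg$label)) has_lab <- FALSE else labs[j] <- sg$label
    }
    structure(list(values = vals,
                   labels = if (has_lab) labs else NULL,
                   lengths = lens, read_ids = ids),
              class = "signal_batch")
  })
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# running-median despiking; width 1 (or traces shorter than the window)
# passes through untouched
spike_filter_samples <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L || length(x) < width) return(x)
  if (width %% 2L == 0L) stop("spike_filter width must be odd")
  as.numeric(stats::runmed(x, width))
}
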