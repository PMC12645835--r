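#' Build a k-mer pore model
#'
#' A pore model maps every k-mer over {A,C,G,T} to the expected current
#' level observed while that k-mer occupies the pore. Levels are drawn
#' i.i.d. standard normal on a dimensionless standardized scale (real pore
#' models are approximately normal after median/MAD scaling), so the table
#' is reproducible from `(k, seed)` alone.
#'
#' @param k K-mer length, 1..8.
#' @param seed Integer seed for the level draw.
#' @return An object of class `pore_model`: list with `k`, `levels`
#'   (named numeric, one entry per 4^k k-mers), `seed`.
#' @examples
#' m <- make_pore_model(3, seed = 1)
#' length(m$levels)  # 64
#' @export
make_pore_model <- function(k, seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 8L) stop("k must be an integer in 1..8")
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                           stringsAsFactors = FALSE)))
  levels <- with_seed(seed, stats::rnorm(length(kmers)))
  names(levels) <- kmers
  structure(list(k = k, levels = levels, seed = as.integer(seed)),
            class = "pore_model")
}

#' Simulation parameters for synthetic squiggles
#'
#' Defaults emulate a moderately noisy nanopore run on the standardized
#' current scale (levels ~ N(0,1)): mean dwell of 8 samples per k-mer with
#' over-dispersed (negative-binomial) dwell times as produced by stochastic
#' motor-protein stepping, Gaussian measurement noise, one slow sinusoidal
#' baseline-drift period per read, and sparse large spike outliers.
#'
#' @param dwell_mean Mean samples per k-mer (> 0).
#' @param dwell_dispersion Dispersion phi of the dwell distribution
#'   (variance = mean + phi * mean^2); 0 gives constant dwell.
#' @param noise_sd Gaussian per-sample noise s.d. (>= 0).
#' @param drift_amp Amplitude of the sinusoidal baseline drift (>= 0).
#' @param spike_rate Per-sample probability of an outlier spike, in \[0,1\].
#' @param spike_amp Spike magnitude (>= 0); spikes are +/- spike_amp.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(dwell_mean = 8, dwell_dispersion = 0.5,
                       noise_sd = 0.5, drift_amp = 0.3,
                       spike_rate = 0.01, spike_amp = 5) {
  stopifnot(dwell_mean > 0, dwell_dispersion >= 0, noise_sd >= 0,
            drift_amp >= 0, spike_rate >= 0, spike_rate <= 1,
            spike_amp >= 0)
  structure(list(dwell_mean = dwell_mean,
                 dwell_dispersion = dwell_dispersion,
                 noise_sd = noise_sd, drift_amp = drift_amp,
                 spike_rate = spike_rate, spike_amp = spike_amp),
            class = "sim_params")
}

#' Default barcode panel
#'
#' Greedily samples `n` random barcodes of the given length until all
#' pairwise Hamming distances reach `min_dist`, from an RNG seeded with
#' `seed` — so the default panel is a fixed, reproducible 4-class set
#' mirroring the common 4-barcode direct-RNA multiplexing layout.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nucleotides.
#' @param min_dist Minimum pairwise Hamming distance.
#' @param seed RNG seed.
#' @return An object of class `barcode_panel`: list with `barcodes`
#'   (character vector) and `names` (class names); class index of barcode
#'   `i` is `i - 1`.
#' @export
default_barcode_panel <- function(n = 4L, length = 40L, min_dist = 20L,
                                  seed = 101L) {
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    chosen <- list()
    tries <- 0L
    while (base::length(chosen) < n) {
      tries <- tries + 1L
      if (tries > 10000L) stop("could not build panel; relax min_dist")
      cand <- sample(bases, length, replace = TRUE)
      ok <- all(vapply(chosen, function(b) sum(b != cand) >= min_dist,
                       logical(1L)))
      if (ok) chosen[[base::length(chosen) + 1L]] <- cand
    }
    barcode_panel(vapply(chosen, paste, character(1L), collapse = ""))
  })
}

#' Construct a barcode panel
#'
#' @param barcodes Character vector of nucleotide strings over {A,C,G,T}.
#' @param names Optional class names (defaults to `bc1`, `bc2`, ...).
#' @return An object of class `barcode_panel`.
#' @export
barcode_panel <- function(barcodes, names = NULL) {
  stopifnot(is.character(barcodes), length(barcodes) >= 1L)
  if (any(grepl("[^ACGT]", barcodes))) {
    stop("barcodes must contain only A, C, G, T")
  }
  if (is.null(names)) names <- paste0("bc", seq_along(barcodes))
  stopifnot(length(names) == length(barcodes))
  structure(list(barcodes = barcodes, names = names),
            class = "barcode_panel")
}

#' Simulate one squiggle
#'
#' Emits the successive k-mer levels of `barcode` under `model`, each held
#' for a stochastic dwell time, then layers Gaussian measurement noise, a
#' single-period sinusoidal baseline drift with random phase, and sparse
#' +/- spike outliers. Dwell times are negative-binomial with mean
#' `dwell_mean` and dispersion `dwell_dispersion` (variance
#' `m + phi m^2`), floored at 1 sample; dispersion 0 degenerates to a
#' constant dwell of `round(dwell_mean)` samples, so the noiseless trace
#' length is exactly `(nchar(barcode) - k + 1) * round(dwell_mean)`.
#'
#' @param barcode Nucleotide string over {A,C,G,T}, length >= `model$k`.
#' @param model A [make_pore_model()] pore model.
#' @param params A [sim_params()] object.
#' @param seed Integer seed; identical inputs give identical traces.
#' @param read_id Identifier for the returned [raw_signal()].
#' @param label Optional class index attached to the read.
#' @return A [raw_signal()].
#' @export
simulate_read <- function(barcode, model, params = sim_params(),
                          seed = 1L, read_id = "sim_read", label = NULL) {
  stopifnot(inherits(model, "pore_model"), inherits(params, "sim_params"))
  if (grepl("[^ACGT]", barcode)) {
    stop("barcode contains characters outside {A,C,G,T}: ", barcode)
  }
  k <- model$k
  nk <- nchar(barcode) - k + 1L
  if (nk < 1L) stop("barcode shorter than k")
  kmers <- substring(barcode, seq_len(nk), seq_len(nk) + k - 1L)
  lv <- unname(model$levels[kmers])
  with_seed(seed, {
    dwell <- if (params$dwell_dispersion > 0) {
      pmax(1L, stats::rnbinom(nk, mu = params$dwell_mean,
                              size = 1 / params$dwell_dispersion))
    } else {
      rep(max(1L, as.integer(round(params$dwell_mean))), nk)
    }
    x <- rep(lv, times = dwell)
    n <- length(x)
    if (params$noise_sd > 0) x <- x + stats::rnorm(n, sd = params$noise_sd)
    if (params$drift_amp > 0) {
      phase <- stats::runif(1L, 0, 2 * pi)
      x <- x + params$drift_amp * sin(2 * pi * seq_len(n) / n + phase)
    }
    if (params$spike_rate > 0) {
      hit <- stats::runif(n) < params$spike_rate
      if (any(hit)) {
        x[hit] <- x[hit] + params$spike_amp *
          sample(c(-1, 1), sum(hit), replace = TRUE)
      }
    }
    raw_signal(read_id, x, label = label, source = "squiggle_sim")
  })
}

#' Generate a labelled synthetic dataset with train/val/test splits
#'
#' Simulates `n_per_class` reads per barcode and splits them class-balanced
#' into train/validation/test sets. Per-read seeds are derived
#' deterministically from the master seed, so the same `(panel, model,
#' params, n_per_class, split, seed)` always yields byte-identical splits,
#' and no read_id appears in two splits.
#'
#' @param panel A [barcode_panel()].
#' @param model A [make_pore_model()] pore model.
#' @param params A [sim_params()] object.
#' @param n_per_class Reads per barcode class (>= 3).
#' @param split Numeric `(train, val, test)` fractions, positive, summing
#'   to 1.
#' @param seed Master integer seed.
#' @return Named list of three [signal_set()]s: `train`, `val`, `test`.
#' @export
generate_dataset <- function(panel, model, params = sim_params(),
                             n_per_class = 100L,
                             split = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(inherits(panel, "barcode_panel"), n_per_class >= 3L,
            length(split) == 3L, all(split > 0),
            abs(sum(split) - 1) < 1e-8)
  n_per_class <- as.integer(n_per_class)
  n_tr <- as.integer(round(split[1L] * n_per_class))
  n_va <- as.integer(round(split[2L] * n_per_class))
  n_te <- n_per_class - n_tr - n_va
  if (n_tr < 1L || n_va < 1L || n_te < 1L) {
    stop("impossible split: some split empty for some class (",
         n_tr, "/", n_va, "/", n_te, " per class)")
  }
  ncls <- length(panel$barcodes)
  read_seeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, ncls * n_per_class),
           nrow = ncls))
  sets <- list(train = list(), val = list(), test = list())
  for (ci in seq_len(ncls)) {
    for (ri in seq_len(n_per_class)) {
      part <- if (ri <= n_tr) "train" else if (ri <= n_tr + n_va) "val"
              else "test"
      id <- sprintf("%s_%s_r%04d", part, panel$names[ci], ri)
      sets[[part]][[length(sets[[part]]) + 1L]] <-
        simulate_read(panel$barcodes[ci], model, params,
                      seed = read_seeds[ci, ri], read_id = id,
                      label = ci - 1L)
    }
  }
  meta <- list(simulator = "demuxsig squiggle_sim",
               k = as.character(model$k),
               pore_seed = as.character(model$seed),
               master_seed = as.character(seed),
               n_per_class = as.character(n_per_class),
               dwell_mean = as.character(params$dwell_mean),
               dwell_dispersion = as.character(params$dwell_dispersion),
               noise_sd = as.character(params$noise_sd),
               drift_amp = as.character(params$drift_amp),
               spike_rate = as.character(params$spike_rate),
               spike_amp = as.character(params$spike_amp))
  lapply(sets, signal_set, n_classes = ncls, metadata = meta)
}
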