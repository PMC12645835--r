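#' Model configuration
#'
#' Collects every architectural hyperparameter of the demultiplexing
#' network and validates their mutual constraints. The defaults describe
#' the full-size network (input 512 samples, 128-wide Transformer with 4
#' attention heads and a single encoder layer — the head/layer counts found
#' to work best on real barcode runs); [demux_config_small()] gives a
#' reduced configuration sized for CPU-scale experiments.
#'
#' @param n_classes Number of barcode classes C (>= 2).
#' @param input_length Model input length L; must be divisible by
#'   `pool_factor^2`.
#' @param fusion_channels Integer vector `(c1, c2, c3)`: channels of the
#'   three hierarchical convolutions.
#' @param residual_channels Channels `cr1` of the direct strided
#'   downsampling path.
#' @param kernel_sizes Odd integer vector `(k1, k2, k3, kr1)`.
#' @param pool_factor Temporal pooling factor p (each average-pool halves
#'   the resolution when p = 2; the fused representation lives at L/p^2).
#' @param d_model Transformer width; divisible by `n_heads`.
#' @param n_heads Attention heads.
#' @param n_transformer_layers Encoder layers (0 allowed, for ablation:
#'   the Transformer stage is then the projected-plus-positional identity).
#' @param ff_dim Position-wise feed-forward width.
#' @param tcn_channels Channels of every temporal-convolution block.
#' @param tcn_kernel Causal convolution kernel size.
#' @param tcn_dilations Integer vector of per-block dilations (non-empty).
#' @param dropout Dropout probability in `[0, 1)`.
#' @param mlp_hidden Hidden units of the classifier MLP.
#' @return An object of class `demux_config` (validated named list).
#' @examples
#' cfg <- demux_config(n_classes = 4)
#' cfg$d_model
#' @export
demux_config <- function(n_classes,
                         input_length = 512L,
                         fusion_channels = c(32L, 64L, 64L),
                         residual_channels = 32L,
                         kernel_sizes = c(7L, 7L, 7L, 7L),
                         pool_factor = 2L,
                         d_model = 128L,
                         n_heads = 4L,
                         n_transformer_layers = 1L,
                         ff_dim = 256L,
                         tcn_channels = 128L,
                         tcn_kernel = 3L,
                         tcn_dilations = c(1L, 2L, 4L, 8L),
                         dropout = 0.1,
                         mlp_hidden = 128L) {
  cfg <- list(n_classes = as.integer(n_classes),
              input_length = as.integer(input_length),
              fusion_channels = as.integer(fusion_channels),
              residual_channels = as.integer(residual_channels),
              kernel_sizes = as.integer(kernel_sizes),
              pool_factor = as.integer(pool_factor),
              d_model = as.integer(d_model),
              n_heads = as.integer(n_heads),
              n_transformer_layers = as.integer(n_transformer_layers),
              ff_dim = as.integer(ff_dim),
              tcn_channels = as.integer(tcn_channels),
              tcn_kernel = as.integer(tcn_kernel),
              tcn_dilations = as.integer(tcn_dilations),
              dropout = as.numeric(dropout),
              mlp_hidden = as.integer(mlp_hidden))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (is.na(n_classes) || n_classes < 2L) stop("n_classes must be >= 2")
    if (length(fusion_channels) != 3L || any(fusion_channels < 1L)) {
      stop("fusion_channels must be three positive integers (c1, c2, c3)")
    }
    if (residual_channels < 1L) stop("residual_channels must be positive")
    if (length(kernel_sizes) != 4L || any(kernel_sizes < 1L) ||
        any(kernel_sizes %% 2L == 0L)) {
      stop("kernel_sizes must be four odd positive integers (k1,k2,k3,kr1)")
    }
    if (pool_factor < 1L) stop("pool_factor must be positive")
    if (input_length < 1L || input_length %% pool_factor^2 != 0L) {
      stop("input_length must be a positive multiple of pool_factor^2")
    }
    if (d_model < 1L || n_heads < 1L || d_model %% n_heads != 0L) {
      stop("d_model must be a positive multiple of n_heads")
    }
    if (n_transformer_layers < 0L) {
      stop("n_transformer_layers must be >= 0")
    }
    if (ff_dim < 1L || tcn_channels < 1L || tcn_kernel < 1L ||
        mlp_hidden < 1L) {
      stop("ff_dim, tcn_channels, tcn_kernel, mlp_hidden must be positive")
    }
    if (length(tcn_dilations) < 1L || any(tcn_dilations < 1L)) {
      stop("tcn_dilations must be a non-empty vector of positive integers")
    }
    if (is.na(dropout) || dropout < 0 || dropout >= 1) {
      stop("dropout must be in [0, 1)")
    }
  })
  structure(cfg, class = "demux_config")
}

#' @rdname demux_config
#' @param ... Overrides passed on to [demux_config()].
#' @details `demux_config_small()` is the default desk-scale configuration
#'   used throughout the package's own experiments: input 256 samples,
#'   8/16/16 fusion channels, a 32-wide Transformer (4 heads, 1 layer) and
#'   a 3-block TCN — small enough to train in minutes on one CPU core while
#'   keeping every architectural element of the full model.
#' @export
demux_config_small <- function(n_classes, ...) {
  defaults <- list(n_classes = n_classes,
                   input_length = 256L,
                   fusion_channels = c(8L, 16L, 16L),
                   residual_channels = 8L,
                   kernel_sizes = c(7L, 7L, 7L, 7L),
                   d_model = 32L,
                   n_heads = 4L,
                   n_transformer_layers = 1L,
                   ff_dim = 64L,
                   tcn_channels = 32L,
                   tcn_kernel = 3L,
                   tcn_dilations = c(1L, 2L, 4L),
                   dropout = 0.1,
                   mlp_hidden = 32L)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(demux_config, defaults)
}

#' @export
print.demux_config <- function(x, ...) {
  p2 <- x$pool_factor^2
  cat("demux_config:\n")
  cat("  input L =", x$input_length, " -> fused T =", x$input_length %/% p2,
      "(pool factor", x$pool_factor, ")\n")
  cat("  fusion channels c1/c2/c3 =",
      paste(x$fusion_channels, collapse = "/"),
      " residual cr1 =", x$residual_channels,
      " kernels =", paste(x$kernel_sizes, collapse = "/"), "\n")
  cat("  transformer: d_model =", x$d_model, ", heads =", x$n_heads,
      ", layers =", x$n_transformer_layers, ", ff =", x$ff_dim, "\n")
  cat("  tcn:", x$tcn_channels, "ch, kernel", x$tcn_kernel,
      ", dilations", paste(x$tcn_dilations, collapse = ","), "\n")
  cat("  head: mlp_hidden =", x$mlp_hidden, ", classes =", x$n_classes,
      ", dropout =", x$dropout, "\n")
  invisible(x)
}

#' Read/write a model configuration as YAML
#'
#' The YAML mirrors [demux_config()] field for field.
#'
#' @param path File path.
#' @param cfg A `demux_config`.
#' @return `read_config` returns a validated `demux_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "demux_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(demux_config, raw)
}

# fused channel count cr1 + c1 + c2 + c3
fused_channels <- function(cfg) {
  cfg$residual_channels + sum(cfg$fusion_channels)
}

# temporal length of the fused representation
fused_T <- function(cfg) cfg$input_length %/% cfg$pool_factor^2
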