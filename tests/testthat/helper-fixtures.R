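# Shared fixtures, built in code at test time.

# tiny but fully-featured configuration for fast structural tests
tiny_config <- function(n_classes = 3L, ...) {
  defaults <- list(n_classes = n_classes, input_length = 16L,
                   fusion_channels = c(3L, 4L, 5L), residual_channels = 2L,
                   kernel_sizes = c(3L, 3L, 3L, 3L), pool_factor = 2L,
                   d_model = 8L, n_heads = 2L, n_transformer_layers = 1L,
                   ff_dim = 10L, tcn_channels = 6L, tcn_kernel = 3L,
                   tcn_dilations = c(1L, 2L), dropout = 0,
                   mlp_hidden = 5L)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(demux_config, defaults)
}

# weights with randomized batch-norm running statistics so eval-mode BN is
# exercised non-trivially
random_eval_weights <- function(cfg, seed) {
  W <- init_weights(cfg, seed = seed)
  set.seed(seed + 13L)
  for (nm in grep("\\.bn\\.rm$", names(W), value = TRUE)) {
    W[[nm]] <- rnorm(length(W[[nm]]), sd = 0.5)
  }
  for (nm in grep("\\.bn\\.rv$", names(W), value = TRUE)) {
    W[[nm]] <- runif(length(W[[nm]]), 0.5, 2)
  }
  W
}

# small labelled dataset from the squiggle simulator
tiny_dataset <- function(n_per_class = 6L, noise_sd = 0.3, seed = 11L) {
  panel <- default_barcode_panel(n = 3L, length = 20L, min_dist = 10L,
                                 seed = 5L)
  model <- make_pore_model(3L, seed = 21L)
  generate_dataset(panel, model, sim_params(noise_sd = noise_sd),
                   n_per_class = n_per_class,
                   split = c(1 / 3, 1 / 3, 1 / 3), seed = seed)
}

random_batch <- function(cfg, B, seed = 1L) {
  set.seed(seed)
  structure(list(values = array(rnorm(B * cfg$input_length),
                                dim = c(B, 1L, cfg$input_length)),
                 labels = sample(0:(cfg$n_classes - 1L), B, replace = TRUE),
                 lengths = rep(cfg$input_length, B),
                 read_ids = paste0("r", seq_len(B))),
            class = "signal_batch")
}
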