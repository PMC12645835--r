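# demuxsig

Barcode demultiplexing for nanopore sequencing, directly on the raw
current signal.

Multiplexed nanopore runs pool several samples on one flow cell after
ligating a short known barcode sequence to each sample's molecules.
`demuxsig` assigns each read back to its sample by classifying the
barcode's raw current trace (the *squiggle*) — no basecalling involved.
It is aimed at people building or evaluating signal-level demultiplexers:
everything from the simulator to the classifier to the metrics runs on a
single CPU core in minutes.

## The model

A despiked, median/MAD-normalized, length-standardized trace
`X ∈ R^L` passes through:

1. **Multi-scale feature fusion** — three stacked 1-D convolutions
   (`x1 = AvgPool_p(ELU(BN(Conv_k1(X))))`, similarly `x2`; `x3` without
   pooling) plus two residual downsampling paths (`r1`, a strided
   convolution from the input; `r2 = AvgPool_p(x1)`), concatenated
   channel-wise at the common resolution `T = L/p²`:
   `F = Concat(r1, r2, x2, x3)`.
2. **Transformer encoder** — projection to `d_model`, sinusoidal
   positional encoding, pre-norm encoder layer(s) with multi-head
   scaled-dot-product self-attention (default 4 heads, 1 layer); the
   `T × T` attention maps are kept for interpretation.
3. **Causal TCN** — residual blocks of dilated, strictly left-padded
   convolutions (dilations 1, 2, 4, …), so position `t` never sees the
   future.
4. **Head** — global average pooling and a small MLP to one logit per
   barcode; trained with Adam on mean cross-entropy, cosine step-size
   decay, early stopping on validation loss.

Forward *and* backward passes are hand-written vectorized R over
BLAS-backed matrix products (im2col/GEMM); no deep-learning framework is
required. A k-mer pore-model squiggle simulator (negative-binomial
dwells, Gaussian noise, sinusoidal drift, spike outliers, controllable
class separability) provides labelled data; the evaluation module covers
accuracy/precision/recall/F1, exact one-vs-rest AUC, and the
clustering-comparison protocol (majority-vote cluster→label mapping with
homogeneity and completeness).

## Worked example

```r
library(demuxsig)

panel <- default_barcode_panel()          # 4 barcodes, length 40, Hamming >= 20
pore  <- make_pore_model(k = 3, seed = 101)
sets  <- generate_dataset(panel, pore, sim_params(noise_sd = 0.3),
                          n_per_class = 60, split = c(2/3, 1/6, 1/6), seed = 7)
sets$train
#> signal_set: 160 reads, 4 classes
#>   trace length: median 300 range [ 212 , 403 ]
#>   labelled reads: 160

cfg <- demux_config_small(n_classes = 4)
fit <- demuxtrans(sets$train, sets$val, cfg,
                  train_params(epochs = 10, batch_size = 32, seed = 7))
fit
#> demuxtrans model: 4 classes, 33,252 parameters
#>   trained 10 epochs; best epoch 10 (val loss 0.5321, val accuracy 0.9000)

pred <- predict(fit, sets$test)
print(evaluate(pred, sets$test)$classification)
#> accuracy 0.8500  macro P/R/F1 0.8551/0.8500/0.8492  (n = 40)
#>     pred
#> true 0 1 2  3
#>    0 8 1 1  0
#>    1 2 7 1  0
#>    2 1 0 9  0
#>    3 0 0 0 10
```

Ten epochs on 160 reads is a two-minute smoke run; the accuracy climbs
above 0.98 at the full desk-scale protocol (200 training reads per class,
30 epochs, `noise_sd = 0.1` — see the acceptance script below). Per-class
one-vs-rest AUCs for the run above:

```r
truth <- vapply(sets$test$signals, function(s) s$label, integer(1))
round(sapply(0:3, function(c) roc_auc_ovr(truth, pred$prob, c)), 4)
#> [1] 0.9167 0.9733 0.9800 1.0000
```

Interpretation artifacts (`attention_profile()`, `chord_matrix()`,
`export_interpretation()`) expose where along the trace a trained model
looks; a command-line interface (`inst/cli/demuxsig`) wraps simulate /
convert / train / predict / evaluate / explain for shell use.

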