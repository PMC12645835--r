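# The demultiplexing network, staged as
#   multi-layer feature fusion -> Transformer encoder -> causal TCN ->
#   global average pooling + MLP head.
#
# The fusion stage computes, with p the pooling factor and X the (1, L)
# input trace:
#   x1 = AvgPool_p(ELU(BN(Conv_k1(X))))          length L/p
#   x2 = AvgPool_p(ELU(BN(Conv_k2(x1))))         length L/p^2
#   x3 = ELU(BN(Conv_k3(x2)))                    length L/p^2 (no pooling)
#   r1 = AvgPool_p(ELU(BN(Conv_kr1, stride p(X)))) length L/p^2
#   r2 = AvgPool_p(x1)                           length L/p^2
#   F  = Concat_channels(r1, r2, x2, x3)
# so all four fused paths share the temporal resolution T = L/p^2. The two
# residual paths preserve low- and mid-level detail that the hierarchical
# stack progressively smooths away.

# ---- weight initialisation -------------------------------------------------

he_mat <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
}

xavier_mat <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(1 / nin)), nout, nin)
}

bn_params <- function(C) {
  list(g = rep(1, C), b = rep(0, C), rm = rep(0, C), rv = rep(1, C))
}

add_bn <- function(W, name, C) {
  p <- bn_params(C)
  W[[paste0(name, ".bn.g")]] <- p$g
  W[[paste0(name, ".bn.b")]] <- p$b
  W[[paste0(name, ".bn.rm")]] <- p$rm
  W[[paste0(name, ".bn.rv")]] <- p$rv
  W
}

#' Initialise model weights
#'
#' Draws every learnable tensor from seeded He/Xavier-scaled normals
#' (biases zero, batch/layer-norm gains one). The returned flat named list
#' also carries the batch-norm running statistics (`*.bn.rm`, `*.bn.rv`),
#' which are state, not trainable parameters.
#'
#' @param config A [demux_config()].
#' @param seed Integer seed.
#' @return Named list of weight arrays.
#' @export
init_weights <- function(config, seed = 1L) {
  cfg <- config
  ch <- cfg$fusion_channels
  ks <- cfg$kernel_sizes
  with_seed(seed, {
    W <- list()
    W[["f1.W"]] <- he_mat(ch[1L], 1L * ks[1L]); W[["f1.b"]] <- rep(0, ch[1L])
    W <- add_bn(W, "f1", ch[1L])
    W[["f2.W"]] <- he_mat(ch[2L], ch[1L] * ks[2L]); W[["f2.b"]] <- rep(0, ch[2L])
    W <- add_bn(W, "f2", ch[2L])
    W[["f3.W"]] <- he_mat(ch[3L], ch[2L] * ks[3L]); W[["f3.b"]] <- rep(0, ch[3L])
    W <- add_bn(W, "f3", ch[3L])
    W[["fr1.W"]] <- he_mat(cfg$residual_channels, 1L * ks[4L])
    W[["fr1.b"]] <- rep(0, cfg$residual_channels)
    W <- add_bn(W, "fr1", cfg$residual_channels)
    d <- cfg$d_model
    W[["proj.W"]] <- xavier_mat(d, fused_channels(cfg))
    W[["proj.b"]] <- rep(0, d)
    for (l in seq_len(cfg$n_transformer_layers)) {
      p <- sprintf("t%d.", l)
      W[[paste0(p, "ln1.g")]] <- rep(1, d); W[[paste0(p, "ln1.b")]] <- rep(0, d)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) {
        W[[paste0(p, nm)]] <- xavier_mat(d, d)
      }
      for (nm in c("bq", "bk", "bv", "bo")) {
        W[[paste0(p, nm)]] <- rep(0, d)
      }
      W[[paste0(p, "ln2.g")]] <- rep(1, d); W[[paste0(p, "ln2.b")]] <- rep(0, d)
      W[[paste0(p, "Wf1")]] <- he_mat(cfg$ff_dim, d)
      W[[paste0(p, "bf1")]] <- rep(0, cfg$ff_dim)
      W[[paste0(p, "Wf2")]] <- xavier_mat(d, cfg$ff_dim)
      W[[paste0(p, "bf2")]] <- rep(0, d)
    }
    cin <- d
    for (j in seq_along(cfg$tcn_dilations)) {
      p <- sprintf("tcn%d.", j)
      co <- cfg$tcn_channels
      W[[paste0(p, "A.W")]] <- he_mat(co, cin * cfg$tcn_kernel)
      W[[paste0(p, "A.b")]] <- rep(0, co)
      W <- add_bn(W, paste0(p, "A"), co)
      W[[paste0(p, "B.W")]] <- he_mat(co, co * cfg$tcn_kernel)
      W[[paste0(p, "B.b")]] <- rep(0, co)
      W <- add_bn(W, paste0(p, "B"), co)
      if (cin != co) {
        W[[paste0(p, "R.W")]] <- xavier_mat(co, cin)
        W[[paste0(p, "R.b")]] <- rep(0, co)
      }
      cin <- co
    }
    W[["head.W1"]] <- he_mat(cfg$mlp_hidden, cfg$tcn_channels)
    W[["head.b1"]] <- rep(0, cfg$mlp_hidden)
    W[["head.W2"]] <- xavier_mat(cfg$n_classes, cfg$mlp_hidden)
    W[["head.b2"]] <- rep(0, cfg$n_classes)
    W
  })
}

trainable_names <- function(W) {
  names(W)[!grepl("\\.bn\\.(rm|rv)$", names(W))]
}

#' Number of learnable parameters
#'
#' A pure function of the configuration (batch-norm running statistics are
#' excluded): identical across runs and seeds.
#'
#' @param config A [demux_config()].
#' @return Integer parameter count.
#' @export
count_params <- function(config) {
  W <- init_weights(config, seed = 0L)
  sum(vapply(W[trainable_names(W)], length, integer(1L)))
}

# ---- stage forwards / backwards over flat activations ----------------------

conv_bn_elu_fwd <- function(x, W, name, plan, training, pool) {
  cv <- conv1d_fwd(x, W[[paste0(name, ".W")]], W[[paste0(name, ".b")]], plan)
  bn <- bn_fwd(cv$y, W[[paste0(name, ".bn.g")]], W[[paste0(name, ".bn.b")]],
               W[[paste0(name, ".bn.rm")]], W[[paste0(name, ".bn.rv")]],
               training)
  el <- elu_fwd(bn$y)
  y <- if (pool > 1L) avgpool_fwd(el$y, pool) else el$y
  run <- list()
  if (training) {
    run[[paste0(name, ".bn.rm")]] <- bn$rm
    run[[paste0(name, ".bn.rv")]] <- bn$rv
  }
  list(y = y, run = run,
       cache = list(conv = cv$cache, bn = bn$cache, elu = el$cache,
                    pool = pool, name = name))
}

conv_bn_elu_bwd <- function(dy, W, cache) {
  name <- cache$name
  d <- if (cache$pool > 1L) avgpool_bwd(dy, cache$pool) else dy
  d <- elu_bwd(d, cache$elu)
  bn <- bn_bwd(d, cache$bn)
  cv <- conv1d_bwd(bn$dx, W[[paste0(name, ".W")]], cache$conv)
  g <- list()
  g[[paste0(name, ".W")]] <- cv$dW
  g[[paste0(name, ".b")]] <- cv$db
  g[[paste0(name, ".bn.g")]] <- bn$dgamma
  g[[paste0(name, ".bn.b")]] <- bn$dbeta
  list(dx = cv$dx, grads = g)
}

fusion_fwd_flat <- function(x, W, cfg, B, training) {
  L <- cfg$input_length; p <- cfg$pool_factor
  ks <- cfg$kernel_sizes
  pl1 <- conv_plan(L, B, ks[1L])
  f1 <- conv_bn_elu_fwd(x, W, "f1", pl1, training, pool = p)       # L/p
  pl2 <- conv_plan(L %/% p, B, ks[2L])
  f2 <- conv_bn_elu_fwd(f1$y, W, "f2", pl2, training, pool = p)    # L/p^2
  pl3 <- conv_plan(L %/% p^2, B, ks[3L])
  f3 <- conv_bn_elu_fwd(f2$y, W, "f3", pl3, training, pool = 1L)   # L/p^2
  plr <- conv_plan(L, B, ks[4L], stride = p)
  fr <- conv_bn_elu_fwd(x, W, "fr1", plr, training, pool = p)      # L/p^2
  r2 <- avgpool_fwd(f1$y, p)                                       # L/p^2
  y <- rbind(fr$y, r2, f2$y, f3$y)
  run <- c(f1$run, f2$run, f3$run, fr$run)
  list(y = y, run = run,
       cache = list(f1 = f1$cache, f2 = f2$cache, f3 = f3$cache,
                    fr = fr$cache, p = p,
                    ch = c(cfg$residual_channels, cfg$fusion_channels)))
}

fusion_bwd_flat <- function(dy, W, cache) {
  ch <- cache$ch  # (cr1, c1, c2, c3)
  i1 <- ch[1L]; i2 <- i1 + ch[2L]; i3 <- i2 + ch[3L]; i4 <- i3 + ch[4L]
  d_r1 <- dy[seq_len(i1), , drop = FALSE]
  d_r2 <- dy[(i1 + 1L):i2, , drop = FALSE]
  d_x2 <- dy[(i2 + 1L):i3, , drop = FALSE]
  d_x3 <- dy[(i3 + 1L):i4, , drop = FALSE]
  b3 <- conv_bn_elu_bwd(d_x3, W, cache$f3)
  d_x2 <- d_x2 + b3$dx
  b2 <- conv_bn_elu_bwd(d_x2, W, cache$f2)
  d_x1 <- b2$dx + avgpool_bwd(d_r2, cache$p)
  b1 <- conv_bn_elu_bwd(d_x1, W, cache$f1)
  br <- conv_bn_elu_bwd(d_r1, W, cache$fr)
  list(dx = b1$dx + br$dx, grads = c(b1$grads, b2$grads, b3$grads, br$grads))
}

trans_fwd_flat <- function(x, W, cfg, B, training, want_attention) {
  Tlen <- fused_T(cfg)
  d <- cfg$d_model
  z <- W[["proj.W"]] %*% x + W[["proj.b"]]
  pe <- positional_encoding(d, Tlen)
  z <- z + as.numeric(pe)
  caches <- vector("list", cfg$n_transformer_layers)
  attn <- if (want_attention && cfg$n_transformer_layers > 0L) {
    array(0, c(cfg$n_transformer_layers, cfg$n_heads, Tlen, Tlen, B))
  } else NULL
  x_in <- x
  for (l in seq_len(cfg$n_transformer_layers)) {
    p <- sprintf("t%d.", l)
    ln1 <- ln_fwd(z, W[[paste0(p, "ln1.g")]], W[[paste0(p, "ln1.b")]])
    at <- mha_fwd(ln1$y, W, p, cfg$n_heads, Tlen, B)
    do1 <- dropout_fwd(at$y, cfg$dropout, training)
    z2 <- z + do1$y
    ln2 <- ln_fwd(z2, W[[paste0(p, "ln2.g")]], W[[paste0(p, "ln2.b")]])
    h <- W[[paste0(p, "Wf1")]] %*% ln2$y + W[[paste0(p, "bf1")]]
    ac <- elu_fwd(h)
    f <- W[[paste0(p, "Wf2")]] %*% ac$y + W[[paste0(p, "bf2")]]
    do2 <- dropout_fwd(f, cfg$dropout, training)
    znew <- z2 + do2$y
    caches[[l]] <- list(prefix = p, ln1 = ln1$cache, mha = at$cache,
                        m1 = do1$mask, ln2 = ln2$cache, ffv = ln2$y,
                        elu = ac$cache, ffh = ac$y, m2 = do2$mask)
    if (!is.null(attn)) attn[l, , , , ] <- at$attn
    z <- znew
  }
  list(y = z, attn = attn,
       cache = list(x = x_in, layers = caches, Tlen = Tlen, B = B))
}

trans_bwd_flat <- function(dz, W, cache) {
  g <- list()
  for (l in rev(seq_along(cache$layers))) {
    cc <- cache$layers[[l]]
    p <- cc$prefix
    df <- dropout_bwd(dz, cc$m2)
    g[[paste0(p, "Wf2")]] <- tcrossprod(df, cc$ffh)
    g[[paste0(p, "bf2")]] <- rowSums(df)
    dh <- crossprod(W[[paste0(p, "Wf2")]], df)
    dh <- elu_bwd(dh, cc$elu)
    g[[paste0(p, "Wf1")]] <- tcrossprod(dh, cc$ffv)
    g[[paste0(p, "bf1")]] <- rowSums(dh)
    dv <- crossprod(W[[paste0(p, "Wf1")]], dh)
    ln2 <- ln_bwd(dv, cc$ln2)
    g[[paste0(p, "ln2.g")]] <- ln2$dgamma
    g[[paste0(p, "ln2.b")]] <- ln2$dbeta
    dz2 <- dz + ln2$dx
    da <- dropout_bwd(dz2, cc$m1)
    mh <- mha_bwd(da, W, cc$mha)
    g <- c(g, mh$grads)
    ln1 <- ln_bwd(mh$dx, cc$ln1)
    g[[paste0(p, "ln1.g")]] <- ln1$dgamma
    g[[paste0(p, "ln1.b")]] <- ln1$dbeta
    dz <- dz2 + ln1$dx
  }
  # positional encoding is additive: gradient passes through unchanged
  g[["proj.W"]] <- tcrossprod(dz, cache$x)
  g[["proj.b"]] <- rowSums(dz)
  list(dx = crossprod(W[["proj.W"]], dz), grads = g)
}

tcn_fwd_flat <- function(x, W, cfg, B, training) {
  Tlen <- ncol(x) %/% B
  caches <- vector("list", length(cfg$tcn_dilations))
  run <- list()
  for (j in seq_along(cfg$tcn_dilations)) {
    p <- sprintf("tcn%d.", j)
    dil <- cfg$tcn_dilations[j]
    plan <- conv_plan(Tlen, B, cfg$tcn_kernel, dilation = dil, causal = TRUE)
    a <- conv_bn_elu_fwd(x, W, paste0(p, "A"), plan, training, pool = 1L)
    doA <- dropout_fwd(a$y, cfg$dropout, training)
    b <- conv_bn_elu_fwd(doA$y, W, paste0(p, "B"), plan, training, pool = 1L)
    doB <- dropout_fwd(b$y, cfg$dropout, training)
    if (!is.null(W[[paste0(p, "R.W")]])) {
      res <- W[[paste0(p, "R.W")]] %*% x + W[[paste0(p, "R.b")]]
      has_res_proj <- TRUE
    } else {
      res <- x
      has_res_proj <- FALSE
    }
    y <- doB$y + res
    caches[[j]] <- list(prefix = p, A = a$cache, mA = doA$mask,
                        B = b$cache, mB = doB$mask,
                        has_res_proj = has_res_proj, x = x)
    run <- c(run, a$run, b$run)
    x <- y
  }
  list(y = x, run = run, cache = caches)
}

tcn_bwd_flat <- function(dy, W, cache) {
  g <- list()
  for (j in rev(seq_along(cache))) {
    cc <- cache[[j]]
    p <- cc$prefix
    db <- dropout_bwd(dy, cc$mB)
    bB <- conv_bn_elu_bwd(db, W, cc$B)
    da <- dropout_bwd(bB$dx, cc$mA)
    bA <- conv_bn_elu_bwd(da, W, cc$A)
    if (cc$has_res_proj) {
      g[[paste0(p, "R.W")]] <- tcrossprod(dy, cc$x)
      g[[paste0(p, "R.b")]] <- rowSums(dy)
      dres <- crossprod(W[[paste0(p, "R.W")]], dy)
    } else {
      dres <- dy
    }
    g <- c(g, bA$grads, bB$grads)
    dy <- bA$dx + dres
  }
  list(dx = dy, grads = g)
}

head_fwd_flat <- function(x, W, cfg, B, training) {
  Tlen <- ncol(x) %/% B
  gpool <- gap_fwd(x, Tlen, B)
  h <- W[["head.W1"]] %*% gpool + W[["head.b1"]]
  el <- elu_fwd(h)
  dr <- dropout_fwd(el$y, cfg$dropout, training)
  logits <- W[["head.W2"]] %*% dr$y + W[["head.b2"]]
  list(y = logits,
       cache = list(gpool = gpool, elu = el$cache, hid = dr$y,
                    mask = dr$mask, Tlen = Tlen, B = B))
}

head_bwd_flat <- function(dlogits, W, cache) {
  g <- list()
  g[["head.W2"]] <- tcrossprod(dlogits, cache$hid)
  g[["head.b2"]] <- rowSums(dlogits)
  dh <- crossprod(W[["head.W2"]], dlogits)
  dh <- dropout_bwd(dh, cache$mask)
  dh <- elu_bwd(dh, cache$elu)
  g[["head.W1"]] <- tcrossprod(dh, cache$gpool)
  g[["head.b1"]] <- rowSums(dh)
  dg <- crossprod(W[["head.W1"]], dh)
  list(dx = gap_bwd(dg, cache$Tlen, cache$B), grads = g)
}

# full network forward; x is (1, L*B)
nn_forward <- function(x, W, cfg, B, training = FALSE,
                       want_attention = FALSE, keep_cache = FALSE) {
  fu <- fusion_fwd_flat(x, W, cfg, B, training)
  tr <- trans_fwd_flat(fu$y, W, cfg, B, training, want_attention)
  tc <- tcn_fwd_flat(tr$y, W, cfg, B, training)
  hd <- head_fwd_flat(tc$y, W, cfg, B, training)
  list(logits = hd$y,
       attn = if (want_attention && cfg$n_transformer_layers > 0L)
         tr$attn else NULL,
       run = c(fu$run, tc$run),
       cache = if (keep_cache)
         list(fusion = fu$cache, trans = tr$cache, tcn = tc$cache,
              head = hd$cache) else NULL)
}

nn_backward <- function(dlogits, W, cfg, cache) {
  hd <- head_bwd_flat(dlogits, W, cache$head)
  tc <- tcn_bwd_flat(hd$dx, W, cache$tcn)
  tr <- trans_bwd_flat(tc$dx, W, cache$trans)
  fu <- fusion_bwd_flat(tr$dx, W, cache$fusion)
  c(hd$grads, tc$grads, tr$grads, fu$grads)
}

# ---- array <-> flat conversions -------------------------------------------

# (B, C, T) array (or (B, 1, L) signal_batch values) -> (C, T*B) flat matrix
arr_to_flat <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(2L, 3L, 1L)), nrow = d[2L])
}

# (C, T*B) flat -> (B, C, T) array
flat_to_arr <- function(x, B) {
  C <- nrow(x); Tlen <- ncol(x) %/% B
  aperm(array(x, c(C, Tlen, B)), c(3L, 1L, 2L))
}

batch_values <- function(batch) {
  if (inherits(batch, "signal_batch")) batch$values else batch
}

# ---- public per-stage API --------------------------------------------------

#' Multi-layer feature-fusion forward pass
#'
#' Runs the four-path fusion stage (hierarchical convolutions plus the two
#' residual downsampling paths) and concatenates the paths channel-wise at
#' the common temporal resolution `L / p^2`.
#'
#' @param batch A `signal_batch` (from [make_batches()]) or a numeric array
#'   of shape `(batch, 1, L)`.
#' @param config A [demux_config()].
#' @param weights Weights from [init_weights()] (or a fitted model's).
#' @param mode `"eval"` (batch norm uses running statistics; default) or
#'   `"train"` (batch statistics).
#' @return Object of class `fusion_output`: list with `features` (array
#'   `(batch, cr1 + c1 + c2 + c3, L/p^2)`) and `path_lengths`.
#' @export
fusion_forward <- function(batch, config, weights, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  vals <- batch_values(batch)
  if (dim(vals)[3L] != config$input_length) {
    stop("batch length ", dim(vals)[3L], " does not match configured ",
         "input_length ", config$input_length)
  }
  B <- dim(vals)[1L]
  out <- fusion_fwd_flat(arr_to_flat(vals), weights, config, B,
                         training = identical(mode, "train"))
  p <- config$pool_factor
  L <- config$input_length
  p2 <- p * p
  structure(list(features = flat_to_arr(out$y, B),
                 path_lengths = list(x1 = L %/% p, x2 = L %/% p2,
                                     x3 = L %/% p2, r1 = L %/% p2,
                                     r2 = L %/% p2)),
            class = "fusion_output")
}

#' Transformer encoder forward pass
#'
#' Projects the fused channels to `d_model`, adds fixed sinusoidal
#' positional encodings, and applies `n_transformer_layers` pre-norm
#' encoder layers (multi-head scaled-dot-product self-attention +
#' position-wise feed-forward with residual connections). With zero layers
#' the output is exactly the projected-plus-positional input.
#'
#' @param fused A `fusion_output` or array `(batch, channels, T)`.
#' @inheritParams fusion_forward
#' @return List with `features` (array `(batch, d_model, T)`) and
#'   `attention` (array `(layers, heads, T, T, batch)`, each row over key
#'   positions a probability distribution; `NULL` when there are no
#'   layers).
#' @export
transformer_forward <- function(fused, config, weights,
                                mode = c("eval", "train")) {
  mode <- match.arg(mode)
  a <- if (inherits(fused, "fusion_output")) fused$features else fused
  B <- dim(a)[1L]
  out <- trans_fwd_flat(arr_to_flat(a), weights, config, B,
                        training = identical(mode, "train"),
                        want_attention = TRUE)
  list(features = flat_to_arr(out$y, B),
       attention = if (config$n_transformer_layers > 0L) out$attn else NULL)
}

#' Temporal convolution stack forward pass
#'
#' One residual block per dilation; each block applies (causal dilated
#' convolution, batch norm, ELU, dropout) twice plus a 1x1-matched residual
#' connection. Causal left-padding guarantees the output at position t
#' depends only on inputs at positions <= t and preserves the temporal
#' length.
#'
#' @param contextual Array `(batch, d_model, T)`.
#' @inheritParams fusion_forward
#' @return Array `(batch, tcn_channels, T)`.
#' @export
tcn_forward <- function(contextual, config, weights,
                        mode = c("eval", "train")) {
  mode <- match.arg(mode)
  B <- dim(contextual)[1L]
  out <- tcn_fwd_flat(arr_to_flat(contextual), weights, config, B,
                      training = identical(mode, "train"))
  flat_to_arr(out$y, B)
}

#' Classifier head forward pass
#'
#' Global average pooling over time followed by a one-hidden-layer MLP
#' (ELU, dropout) producing one logit per barcode class.
#'
#' @param tcn_out Array `(batch, tcn_channels, T)`.
#' @inheritParams fusion_forward
#' @return Logit matrix `(batch, n_classes)`.
#' @export
head_forward <- function(tcn_out, config, weights,
                         mode = c("eval", "train")) {
  mode <- match.arg(mode)
  B <- dim(tcn_out)[1L]
  out <- head_fwd_flat(arr_to_flat(tcn_out), weights, config, B,
                       training = identical(mode, "train"))
  t(out$y)
}

#' End-to-end model forward pass
#'
#' Composition of [fusion_forward()], [transformer_forward()],
#' [tcn_forward()] and [head_forward()]. In `"eval"` mode the forward is
#' deterministic: dropout is disabled and batch norm uses its running
#' statistics, so logits are independent of batch composition.
#'
#' @inheritParams fusion_forward
#' @param return_attention Also return the attention tensor?
#' @return List with `logits` (matrix `(batch, n_classes)`) and
#'   `attention` (array `(layers, heads, T, T, batch)` or `NULL`).
#' @export
model_forward <- function(batch, config, weights, mode = c("eval", "train"),
                          return_attention = FALSE) {
  mode <- match.arg(mode)
  vals <- batch_values(batch)
  if (dim(vals)[3L] != config$input_length) {
    stop("batch length ", dim(vals)[3L], " does not match configured ",
         "input_length ", config$input_length)
  }
  B <- dim(vals)[1L]
  out <- nn_forward(arr_to_flat(vals), weights, config, B,
                    training = identical(mode, "train"),
                    want_attention = return_attention)
  list(logits = t(out$logits), attention = out$attn)
}
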