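# Independent straight-line oracles, written directly from the layer
# definitions with plain loops. They share nothing with the package's
# im2col/GEMM implementation beyond the weight-list layout
# W[co, (kk-1)*Cin + ci].

oracle_conv1d <- function(x, W, b, K, stride = 1L, dilation = 1L,
                          causal = FALSE) {
  # x: (Cin, T) one read
  Cin <- nrow(x); Tin <- ncol(x)
  padL <- if (causal) (K - 1L) * dilation else ((K - 1L) %/% 2L) * dilation
  padR <- if (causal) 0L else padL
  xp <- cbind(matrix(0, Cin, padL), x, matrix(0, Cin, padR))
  Tout <- (Tin + padL + padR - ((K - 1L) * dilation + 1L)) %/% stride + 1L
  Cout <- nrow(W)
  y <- matrix(0, Cout, Tout)
  for (co in seq_len(Cout)) {
    for (t in seq_len(Tout)) {
      acc <- b[co]
      for (kk in seq_len(K)) {
        for (ci in seq_len(Cin)) {
          src <- (t - 1L) * stride + (kk - 1L) * dilation + 1L
          acc <- acc + W[co, (kk - 1L) * Cin + ci] * xp[ci, src]
        }
      }
      y[co, t] <- acc
    }
  }
  y
}

oracle_bn_eval <- function(x, g, b, rm, rv, eps = 1e-5) {
  y <- x
  for (c in seq_len(nrow(x))) {
    y[c, ] <- g[c] * (x[c, ] - rm[c]) / sqrt(rv[c] + eps) + b[c]
  }
  y
}

oracle_elu <- function(x) ifelse(x > 0, x, exp(x) - 1)

oracle_avgpool <- function(x, p) {
  Tout <- ncol(x) %/% p
  y <- matrix(0, nrow(x), Tout)
  for (t in seq_len(Tout)) {
    y[, t] <- rowMeans(x[, ((t - 1L) * p + 1L):(t * p), drop = FALSE])
  }
  y
}

# Eqs: x1 = pool(elu(bn(conv1(X)))); x2 = pool(elu(bn(conv2(x1))));
# x3 = elu(bn(conv3(x2))); r1 = pool(elu(bn(conv_r(X, stride p))));
# r2 = pool(x1); out = concat(r1, r2, x2, x3). One read, eval-mode BN.
oracle_fusion_one_read <- function(xrow, W, cfg) {
  p <- cfg$pool_factor
  ks <- cfg$kernel_sizes
  x <- matrix(xrow, nrow = 1L)
  blk <- function(inp, name, K, stride = 1L, pool = TRUE) {
    y <- oracle_conv1d(inp, W[[paste0(name, ".W")]], W[[paste0(name, ".b")]],
                       K, stride = stride)
    y <- oracle_bn_eval(y, W[[paste0(name, ".bn.g")]],
                        W[[paste0(name, ".bn.b")]],
                        W[[paste0(name, ".bn.rm")]],
                        W[[paste0(name, ".bn.rv")]])
    y <- oracle_elu(y)
    if (pool) oracle_avgpool(y, p) else y
  }
  x1 <- blk(x, "f1", ks[1L])
  x2 <- blk(x1, "f2", ks[2L])
  x3 <- blk(x2, "f3", ks[3L], pool = FALSE)
  r1 <- blk(x, "fr1", ks[4L], stride = p)
  r2 <- oracle_avgpool(x1, p)
  rbind(r1, r2, x2, x3)
}

# Brute-force homogeneity/completeness straight from the conditional
# entropy definitions, summing over observed (class, cluster) pairs.
oracle_homogeneity_completeness <- function(y, k) {
  n <- length(y)
  cls <- unique(y); clu <- unique(k)
  H_class <- 0; H_clu <- 0
  for (c in cls) {
    p <- sum(y == c) / n
    H_class <- H_class - p * log(p)
  }
  for (g in clu) {
    p <- sum(k == g) / n
    H_clu <- H_clu - p * log(p)
  }
  H_c_given_k <- 0; H_k_given_c <- 0
  for (c in cls) {
    for (g in clu) {
      pj <- sum(y == c & k == g) / n
      if (pj > 0) {
        H_c_given_k <- H_c_given_k - pj * log(pj / (sum(k == g) / n))
        H_k_given_c <- H_k_given_c - pj * log(pj / (sum(y == c) / n))
      }
    }
  }
  c(h = if (H_class == 0) 1 else 1 - H_c_given_k / H_class,
    c = if (H_clu == 0) 1 else 1 - H_k_given_c / H_clu)
}

# Exhaustive pairwise AUC: every positive/negative pair, ties count 1/2.
oracle_auc_pairs <- function(scores_pos, scores_neg) {
  wins <- 0
  for (sp in scores_pos) {
    for (sn in scores_neg) {
      wins <- wins + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  wins / (length(scores_pos) * length(scores_neg))
}
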