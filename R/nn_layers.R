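# Layer primitives over "flat" activations.
#
# A batched activation is a base matrix of shape (channels, T * B): the
# columns of read b occupy the contiguous block (b-1)*T + 1 .. b*T. All
# heavy operations reduce to BLAS matrix products via an im2col
# formulation; every forward returns the cache its hand-derived backward
# needs. Batch statistics (batch norm) are taken over channels across all
# positions and reads, exactly as a Conv1d + BatchNorm1d stack would.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1
LN_EPS <- 1e-5

# ---- 1D convolution (same / causal / strided) ------------------------------

# Column-gather plan: for output position t (0-based) and tap kk, the source
# column in the zero-padded input is t*stride + kk*dilation (plus the block
# offset). Same padding uses (K-1)/2*d on both sides (K odd); causal padding
# puts all (K-1)*d zeros on the left so position t never sees the future.
.plan_cache <- new.env(parent = emptyenv())

conv_plan <- function(Tin, B, K, stride = 1L, dilation = 1L,
                      causal = FALSE) {
  key <- paste(Tin, B, K, stride, dilation, causal, sep = "|")
  hit <- .plan_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (causal) {
    padL <- (K - 1L) * dilation; padR <- 0L
  } else {
    padL <- padR <- ((K - 1L) %/% 2L) * dilation
  }
  eff <- (K - 1L) * dilation + 1L
  Tout <- (Tin + padL + padR - eff) %/% stride + 1L
  Tpad <- Tin + padL + padR
  bb <- rep.int((0:(B - 1L)) * Tpad, rep.int(K * Tout, B))
  tt <- rep.int(rep.int((0:(Tout - 1L)) * stride, rep.int(K, Tout)), B)
  kk <- rep.int((0:(K - 1L)) * dilation, Tout * B)
  idx <- bb + tt + kk + 1L
  real <- rep.int((0:(B - 1L)) * Tpad, rep.int(Tin, B)) + padL +
    rep.int(1:Tin, B)
  # per-tap column targets: for a fixed tap the targets are all distinct,
  # so the backward scatter-add is K plain indexed additions
  by_tap <- lapply(seq_len(K), function(kk) idx[seq.int(kk, length(idx), K)])
  plan <- list(Tin = Tin, Tout = Tout, Tpad = Tpad, B = B, K = K,
               idx = idx, real = real, by_tap = by_tap)
  .plan_cache[[key]] <- plan
  plan
}

pad_flat <- function(x, plan) {
  C <- nrow(x)
  xpad <- matrix(0, C, plan$Tpad * plan$B)
  xpad[, plan$real] <- x
  xpad
}

# W is (Cout x Cin*K) with column index (kk-1)*Cin + ci, matching the
# row layout produced by the column gather below.
conv1d_fwd <- function(x, W, b, plan) {
  Cin <- nrow(x)
  xpad <- pad_flat(x, plan)
  Xcol <- xpad[, plan$idx, drop = FALSE]
  dim(Xcol) <- c(Cin * plan$K, plan$Tout * plan$B)
  y <- W %*% Xcol + b
  list(y = y, cache = list(Xcol = Xcol, Cin = Cin, plan = plan))
}

conv1d_bwd <- function(dy, W, cache) {
  plan <- cache$plan
  dW <- tcrossprod(dy, cache$Xcol)
  db <- rowSums(dy)
  dXcol <- crossprod(W, dy)                 # (Cin*K, Tout*B)
  Cin <- cache$Cin
  dxpad <- matrix(0, Cin, plan$Tpad * plan$B)
  for (kk in seq_len(plan$K)) {
    rows <- ((kk - 1L) * Cin + 1L):(kk * Cin)
    tgt <- plan$by_tap[[kk]]
    dxpad[, tgt] <- dxpad[, tgt] + dXcol[rows, , drop = FALSE]
  }
  dx <- dxpad[, plan$real, drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# ---- average pooling (window = stride = p) ---------------------------------

avgpool_fwd <- function(x, p) {
  if (p == 1L) return(x)
  N <- ncol(x)
  y <- x[, seq.int(1L, N, p), drop = FALSE]
  for (i in 2:p) y <- y + x[, seq.int(i, N, p), drop = FALSE]
  y / p
}

avgpool_bwd <- function(dy, p) {
  if (p == 1L) return(dy)
  dy[, rep(seq_len(ncol(dy)), each = p), drop = FALSE] / p
}

# ---- ELU -------------------------------------------------------------------

elu_fwd <- function(x) {
  y <- pmax(x, 0) + expm1(pmin(x, 0))   # x for x > 0, exp(x) - 1 otherwise
  list(y = y, cache = list(y = y, pos = (x > 0)))
}

elu_bwd <- function(dy, cache) {
  # derivative is 1 where x > 0 and exp(x) = y + 1 elsewhere
  dy * (1 + (!cache$pos) * cache$y)
}

# ---- batch normalization (per channel) -------------------------------------

bn_fwd <- function(x, gamma, beta, rm, rv, training) {
  if (training) {
    N <- ncol(x)
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * inv
    y <- gamma * xhat + beta
    ub <- if (N > 1L) v * N / (N - 1) else v
    list(y = y,
         cache = list(xhat = xhat, inv = inv, gamma = gamma, N = N),
         rm = (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu,
         rv = (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * ub)
  } else {
    xhat <- (x - rm) / sqrt(rv + BN_EPS)
    list(y = gamma * xhat + beta, cache = NULL, rm = rm, rv = rv)
  }
}

bn_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  N <- cache$N
  dx <- (cache$inv / N) * (N * dxhat - rowSums(dxhat) - xhat * dgamma_term(dxhat, xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dgamma_term <- function(dxhat, xhat) rowSums(dxhat * xhat)

# ---- layer normalization (per position, over channels) ---------------------

ln_fwd <- function(x, gamma, beta) {
  d <- nrow(x)
  mu <- colMeans(x)
  xc <- x - rep(mu, each = d)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * rep(inv, each = d)
  list(y = gamma * xhat + beta,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d))
}

ln_bwd <- function(dy, cache) {
  d <- cache$d
  xhat <- cache$xhat
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- rep(cache$inv / d, each = d) *
    (d * dxhat - rep(s1, each = d) - xhat * rep(s2, each = d))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- dropout (inverted scaling) --------------------------------------------

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# ---- multi-head scaled-dot-product self-attention --------------------------

# x is (d, T*B); returns output (d, T*B) and attention (heads, T, T, B)
# with A[h, q, k, b] the probability that query position q attends to key
# position k in read b.
mha_fwd <- function(x, W, prefix, n_heads, Tlen, B) {
  d <- nrow(x)
  dk <- d %/% n_heads
  scale <- 1 / sqrt(dk)
  Q <- W[[paste0(prefix, "Wq")]] %*% x + W[[paste0(prefix, "bq")]]
  K <- W[[paste0(prefix, "Wk")]] %*% x + W[[paste0(prefix, "bk")]]
  V <- W[[paste0(prefix, "Wv")]] %*% x + W[[paste0(prefix, "bv")]]
  O <- matrix(0, d, Tlen * B)
  A <- array(0, c(n_heads, Tlen, Tlen, B))
  for (b in seq_len(B)) {
    cols <- ((b - 1L) * Tlen + 1L):(b * Tlen)
    for (h in seq_len(n_heads)) {
      rows <- ((h - 1L) * dk + 1L):(h * dk)
      S <- crossprod(Q[rows, cols, drop = FALSE],
                     K[rows, cols, drop = FALSE]) * scale
      S <- S - S[cbind(seq_len(Tlen), max.col(S, ties.method = "first"))]
      E <- exp(S)
      Ah <- E / rowSums(E)
      O[rows, cols] <- tcrossprod(V[rows, cols, drop = FALSE], Ah)
      A[h, , , b] <- Ah
    }
  }
  out <- W[[paste0(prefix, "Wo")]] %*% O + W[[paste0(prefix, "bo")]]
  list(y = out, attn = A,
       cache = list(x = x, Q = Q, K = K, V = V, O = O, A = A,
                    n_heads = n_heads, Tlen = Tlen, B = B, dk = dk,
                    prefix = prefix))
}

mha_bwd <- function(dy, W, cache) {
  p <- cache$prefix
  d <- nrow(dy)
  dk <- cache$dk
  scale <- 1 / sqrt(dk)
  g <- list()
  g[[paste0(p, "Wo")]] <- dy %*% t(cache$O)
  g[[paste0(p, "bo")]] <- rowSums(dy)
  dO <- crossprod(W[[paste0(p, "Wo")]], dy)
  dQ <- matrix(0, d, ncol(dy))
  dK <- matrix(0, d, ncol(dy))
  dV <- matrix(0, d, ncol(dy))
  for (b in seq_len(cache$B)) {
    cols <- ((b - 1L) * cache$Tlen + 1L):(b * cache$Tlen)
    for (h in seq_len(cache$n_heads)) {
      rows <- ((h - 1L) * dk + 1L):(h * dk)
      Ah <- cache$A[h, , , b]
      dOi <- dO[rows, cols, drop = FALSE]
      Vi <- cache$V[rows, cols, drop = FALSE]
      dV[rows, cols] <- dOi %*% Ah
      dA <- crossprod(dOi, Vi)                     # (T, T)
      dS <- Ah * (dA - rowSums(dA * Ah))           # softmax rows
      dQ[rows, cols] <- scale *
        tcrossprod(cache$K[rows, cols, drop = FALSE], dS)
      dK[rows, cols] <- scale *
        cache$Q[rows, cols, drop = FALSE] %*% dS
    }
  }
  x <- cache$x
  g[[paste0(p, "Wq")]] <- dQ %*% t(x); g[[paste0(p, "bq")]] <- rowSums(dQ)
  g[[paste0(p, "Wk")]] <- dK %*% t(x); g[[paste0(p, "bk")]] <- rowSums(dK)
  g[[paste0(p, "Wv")]] <- dV %*% t(x); g[[paste0(p, "bv")]] <- rowSums(dV)
  dx <- crossprod(W[[paste0(p, "Wq")]], dQ) +
    crossprod(W[[paste0(p, "Wk")]], dK) +
    crossprod(W[[paste0(p, "Wv")]], dV)
  list(dx = dx, grads = g)
}

# ---- fixed sinusoidal positional encoding ----------------------------------

positional_encoding <- function(d, Tlen) {
  pe <- matrix(0, d, Tlen)
  t <- 0:(Tlen - 1L)
  for (r in seq_len(d)) {
    i <- (r - 1L) %/% 2L
    angle <- t / 10000^(2 * i / d)
    pe[r, ] <- if ((r - 1L) %% 2L == 0L) sin(angle) else cos(angle)
  }
  pe
}

# ---- per-read global average pooling over time -----------------------------

gap_fwd <- function(x, Tlen, B) {
  grp <- rep(seq_len(B), each = Tlen)
  t(rowsum(t(x), group = grp)) / Tlen
}

gap_bwd <- function(dg, Tlen, B) {
  dg[, rep(seq_len(B), each = Tlen), drop = FALSE] / Tlen
}
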