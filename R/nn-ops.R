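# Differentiable primitives for the 1D U-Net. Activations are arrays of
# shape (channels, time, batch); every forward returns the output plus the
# cache its backward needs. Convolutions run through BLAS-backed C++ kernels.

.as_cube <- function(x, c, t, b) array(x, dim = c(c, t, b))

# ---- convolution -----------------------------------------------------------

op_conv_fwd <- function(x, W, b, k, stride = 1L, pad = 0L) {
  y <- conv1d_fwd_cpp(x, W, if (is.null(b)) numeric(0) else b, k, stride, pad)
  list(y = y, cache = list(x = x, W = W, k = k, stride = stride, pad = pad,
                           has_bias = !is.null(b)))
}

op_conv_bwd <- function(dy, cache) {
  g <- conv1d_bwd_cpp(cache$x, cache$W, dy, cache$k, cache$stride, cache$pad,
                      cache$has_bias)
  list(dx = g$dx, dW = g$dW, db = if (cache$has_bias) as.numeric(g$db) else NULL)
}

# ---- GELU (sigmoid approximation x * sigmoid(1.702 x)) ---------------------

op_gelu_fwd <- function(x) {
  if (is.null(dim(x))) x <- array(x, c(1, length(x), 1))
  list(y = gelu_fwd_cpp(x), cache = x)
}

op_gelu_bwd <- function(dy, cache) {
  gelu_bwd_cpp(cache, dy)
}

# ---- dropout ---------------------------------------------------------------

op_dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, cache = NULL))
  if (is.null(dim(x)) || length(dim(x)) != 3) {
    keep <- (runif(length(x)) >= p) / (1 - p)
    return(list(y = x * keep, cache = keep))
  }
  r <- dropout_fwd_cpp(x, p)
  list(y = r$y, cache = r$mask)
}

op_dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

# ---- group normalization ---------------------------------------------------
# Normalizes over (channels-in-group, time) per group and batch element.

op_groupnorm_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  r <- groupnorm_fwd_cpp(x, gamma, beta, groups, eps)
  list(y = r$y, cache = list(xhat = r$xhat, iv = r$iv, gamma = gamma,
                             groups = groups))
}

op_groupnorm_bwd <- function(dy, cache) {
  groupnorm_bwd_cpp(dy, cache$xhat, cache$iv, cache$gamma, cache$groups)
}

# ---- layer normalization (over channels at each time step) -----------------

op_layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); C <- d[1]
  xm <- matrix(x, C, d[2] * d[3])
  mu <- colMeans(xm)
  va <- colMeans(xm * xm) - mu * mu
  iv <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = C)) * rep(iv, each = C)
  y <- array(xhat * gamma + beta, dim = d)
  list(y = y, cache = list(xhat = xhat, iv = iv, gamma = gamma, dims = d))
}

op_layernorm_bwd <- function(dy, cache) {
  d <- cache$dims; C <- d[1]
  dym <- matrix(dy, C, d[2] * d[3])
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * cache$gamma
  s1 <- colSums(dxhat); s2 <- colSums(dxhat * xhat)
  dx <- (dxhat - rep(s1 / C, each = C) - xhat * rep(s2 / C, each = C)) *
    rep(cache$iv, each = C)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- linear upsampling x2 (align_corners = FALSE) --------------------------

op_upsample2_fwd <- function(x) {
  list(y = upsample2_fwd_cpp(x), cache = dim(x)[2])
}

op_upsample2_bwd <- function(dy, cache) {
  upsample2_bwd_cpp(dy, cache)
}

# ---- softmax over the second index of a (Tq, Tk, S) cube -------------------

.softmax_cols <- function(m) {
  # softmax over dim 1 of a matrix
  T <- nrow(m)
  mx <- m[1, ]
  if (T > 1) for (r in 2:T) mx <- pmax(mx, m[r, ])
  e <- exp(m - rep(mx, each = T))
  e / rep(colSums(e), each = T)
}

# ---- multi-head self-attention --------------------------------------------
# x: (C, T, B); params: Wqkv (3C x C), bqkv (3C), Wo (C x C), bo (C)

op_mha_fwd <- function(x, p, n_heads, dropout_p = 0, training = FALSE) {
  d <- dim(x); C <- d[1]; T <- d[2]; B <- d[3]
  dh <- C %/% n_heads
  xm <- matrix(x, C, T * B)
  qkv <- p$Wqkv %*% xm + p$bqkv
  split_heads <- function(m, off) {
    a <- array(m[(off + 1):(off + C), ], c(dh, n_heads, T, B))
    a <- aperm(a, c(1, 3, 2, 4))
    dim(a) <- c(dh, T, n_heads * B)
    a
  }
  Q <- split_heads(qkv, 0); K <- split_heads(qkv, C); V <- split_heads(qkv, 2 * C)
  S <- bmm_tn_cpp(Q, K) / sqrt(dh)            # (Tq, Tk, HB) slices: Q^T K
  # softmax over keys (second index): transpose each slice for column softmax
  Sp <- aperm(S, c(2, 1, 3))                  # (Tk, Tq, HB)
  P <- .softmax_cols(matrix(Sp, T, T * n_heads * B))
  Pd <- op_dropout_fwd(P, dropout_p, training)
  Pc <- .as_cube(Pd$y, T, T, n_heads * B)     # (Tk, Tq, HB)
  O <- bmm_nn_cpp(V, Pc)                      # (dh, Tq, HB)
  Om <- array(O, c(dh, T, n_heads, B))
  Om <- aperm(Om, c(1, 3, 2, 4))
  dim(Om) <- c(C, T * B)
  y <- array(p$Wo %*% Om + p$bo, c(C, T, B))
  list(y = y, cache = list(xm = xm, Q = Q, K = K, V = V, P = P, Pmask = Pd$cache,
                           Om = Om, dims = d, n_heads = n_heads, dh = dh, p = p))
}

op_mha_bwd <- function(dy, cache) {
  d <- cache$dims; C <- d[1]; T <- d[2]; B <- d[3]
  H <- cache$n_heads; dh <- cache$dh
  dym <- matrix(dy, C, T * B)
  dWo <- dym %*% t(cache$Om)
  dbo <- rowSums(dym)
  dOm <- t(cache$p$Wo) %*% dym                # (C, T*B)
  dO <- array(dOm, c(dh, H, T, B))
  dO <- aperm(dO, c(1, 3, 2, 4)); dim(dO) <- c(dh, T, H * B)
  Pc <- .as_cube(if (is.null(cache$Pmask)) cache$P else cache$P * cache$Pmask,
                 T, T, H * B)
  dV <- bmm_nt_cpp(dO, Pc)                    # dV = dO * P^T  (dh, Tk, HB)
  dP <- bmm_tn_cpp(cache$V, dO)               # (Tk, Tq, HB)
  dPm <- matrix(dP, T, T * H * B)
  if (!is.null(cache$Pmask)) dPm <- dPm * cache$Pmask
  Pm <- cache$P
  sums <- colSums(dPm * Pm)
  dSm <- Pm * (dPm - rep(sums, each = T))     # softmax backward, (Tk, Tq*HB)
  dS <- aperm(.as_cube(dSm, T, T, H * B), c(2, 1, 3)) / sqrt(dh) # (Tq, Tk, HB)
  dQ <- bmm_nn_cpp(cache$K, aperm(dS, c(2, 1, 3)))  # K (dh,Tk) x dS^T -> (dh,Tq)
  dK <- bmm_nn_cpp(cache$Q, dS)                     # Q (dh,Tq) x dS -> (dh,Tk)
  merge_heads <- function(a) {
    m <- array(a, c(dh, T, H, B)); m <- aperm(m, c(1, 3, 2, 4))
    dim(m) <- c(C, T * B); m
  }
  dqkv <- rbind(merge_heads(dQ), merge_heads(dK), merge_heads(dV))
  dWqkv <- dqkv %*% t(cache$xm)
  dbqkv <- rowSums(dqkv)
  dx <- array(t(cache$p$Wqkv) %*% dqkv, d)
  list(dx = dx, dWqkv = dWqkv, dbqkv = dbqkv, dWo = dWo, dbo = dbo)
}

# ---- sinusoidal positional encoding ---------------------------------------

sinusoidal_positions <- function(d_model, T) {
  pos <- 0:(T - 1)
  i <- 0:(d_model %/% 2 - 1)
  freq <- 1 / 10000^(2 * i / d_model)
  ang <- outer(freq, pos)                     # (d/2, T)
  pe <- matrix(0, d_model, T)
  pe[seq(1, d_model, by = 2), ] <- sin(ang)
  pe[seq(2, d_model, by = 2), ] <- cos(ang)
  pe
}
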