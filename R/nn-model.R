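# The multitask self-attention 1D U-Net: a four-level residual encoder,
# a single-layer transformer bottleneck, a skip-connected decoder with
# linear-interpolation upsampling, a residual refinement block, and three
# task heads (waveform, envelope, segmentation).

#' Model configuration
#'
#' Architecture hyperparameters of the multitask self-attention 1D U-Net.
#' Channel counts double at each encoder level; the transformer embedding
#' equals the deepest encoder width.
#'
#' @param in_channels 1 for the radar-HS-only variant (the final model) or 3
#'   for the baseline fed with the heart-sound signal, its first difference
#'   and the unfiltered displacement.
#' @param base_channels Channels at the first level (default 24).
#' @param depth Number of encoder/decoder levels (default 4).
#' @param res_kernel Residual-block convolution kernel (default 5, padding 2).
#' @param down_kernel Strided downsampling kernel (default 4, stride 2,
#'   padding 1).
#' @param dropout Dropout rate in residual blocks and transformer (default 0.2).
#' @param groupnorm_groups Groups for group normalization (default 8).
#' @param transformer_heads,transformer_layers,transformer_ffn Self-attention
#'   heads (8), encoder layers (1) and feed-forward width (768).
#' @param head_kernel Kernel of the first convolution in each output head.
#' @param positional_encoding `"sinusoidal"` (parameter-free) or `"learned"`.
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(in_channels = 1, base_channels = 24, depth = 4,
                         res_kernel = 5, down_kernel = 4, dropout = 0.2,
                         groupnorm_groups = 8, transformer_heads = 8,
                         transformer_layers = 1, transformer_ffn = 768,
                         head_kernel = 3,
                         positional_encoding = c("sinusoidal", "learned")) {
  positional_encoding <- match.arg(positional_encoding)
  channels <- base_channels * 2^(0:(depth - 1))
  embed <- channels[depth]
  stopifnot(all(channels %% groupnorm_groups == 0),
            embed %% transformer_heads == 0,
            transformer_layers >= 1)
  structure(list(
    in_channels = in_channels, base_channels = base_channels, depth = depth,
    encoder_channels = channels, res_kernel = res_kernel,
    down_kernel = down_kernel, dropout = dropout,
    groupnorm_groups = groupnorm_groups, embed = embed,
    transformer_heads = transformer_heads,
    transformer_layers = transformer_layers, transformer_ffn = transformer_ffn,
    head_kernel = head_kernel, positional_encoding = positional_encoding
  ), class = "model_config")
}

.init_conv <- function(ci, co, k, bias = TRUE) {
  bound <- 1 / sqrt(ci * k)
  list(W = matrix(runif(co * ci * k, -bound, bound), co, ci * k),
       b = if (bias) runif(co, -bound, bound) else NULL)
}

.init_norm <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

.init_rb <- function(ci, co, k) {
  p <- list(conv1 = .init_conv(ci, co, k),
            gn = .init_norm(co),
            conv2 = .init_conv(co, co, k))
  if (ci != co) p$proj <- .init_conv(ci, co, 1)
  p
}

#' Build the multitask 1D U-Net
#'
#' Instantiates all trainable parameters. The default configuration carries
#' 2,016,768 trainable parameters (7.69 MiB in float32): a stem convolution
#' to 24 channels, four encoder stages (residual block then bias-free
#' stride-2 downsampling; widths 24, 48, 96, 192), a 192-wide transformer
#' bottleneck (8 heads, feed-forward 768, post-norm), four decoder stages
#' (linear upsampling, bias-free pointwise projection, skip concatenation,
#' residual block), a 24-channel refinement block, and three heads whose
#' final pointwise convolutions are bias-free; the waveform head ends in tanh.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for parameter initialization.
#'
#' @return An object of class `pcg_unet`.
#' @export
build_model <- function(config = model_config(), seed = 1) {
  ch <- config$encoder_channels
  k <- config$res_kernel
  with_seed(seed, {
    params <- list()
    params$stem <- .init_conv(config$in_channels, ch[1], k)
    params$enc <- vector("list", config$depth)
    cin <- ch[1]
    for (i in seq_len(config$depth)) {
      params$enc[[i]] <- list(
        rb = .init_rb(cin, ch[i], k),
        down = .init_conv(ch[i], ch[i], config$down_kernel, bias = FALSE)
      )
      cin <- ch[i]
    }
    d <- config$embed
    bound_attn <- sqrt(6 / (2 * d))
    params$bott <- list(
      proj1 = .init_conv(d, d, 1), gn1 = .init_norm(d),
      layers = lapply(seq_len(config$transformer_layers), function(l) list(
        attn = list(
          Wqkv = matrix(runif(3 * d * d, -bound_attn, bound_attn), 3 * d, d),
          bqkv = rep(0, 3 * d),
          Wo = matrix(runif(d * d, -1 / sqrt(d), 1 / sqrt(d)), d, d),
          bo = rep(0, d)
        ),
        ln1 = .init_norm(d),
        ffn1 = .init_conv(d, config$transformer_ffn, 1),
        ffn2 = .init_conv(config$transformer_ffn, d, 1),
        ln2 = .init_norm(d)
      )),
      proj2 = .init_conv(d, d, 1), gn2 = .init_norm(d)
    )
    if (config$positional_encoding == "learned") {
      params$bott$pos <- matrix(rnorm(d * 125, sd = 0.02), d, 125)
    }
    params$dec <- vector("list", config$depth)
    cin <- ch[config$depth]
    for (i in seq_len(config$depth)) {
      s <- ch[config$depth + 1 - i]
      params$dec[[i]] <- list(
        up = .init_conv(cin, s, 1, bias = FALSE),
        rb = .init_rb(2 * s, s, k)
      )
      cin <- s
    }
    params$refine <- .init_rb(ch[1], ch[1], k)
    hk <- config$head_kernel
    params$heads <- list(
      wav = list(c1 = .init_conv(ch[1], ch[1], hk), c2 = .init_conv(ch[1], 1, 1, bias = FALSE)),
      env = list(c1 = .init_conv(ch[1], ch[1], hk), c2 = .init_conv(ch[1], 1, 1, bias = FALSE)),
      seg = list(c1 = .init_conv(ch[1], ch[1], hk), c2 = .init_conv(ch[1], 4, 1, bias = FALSE))
    )
    structure(list(config = config, params = params), class = "pcg_unet")
  })
}

#' Count trainable parameters
#'
#' @param model A `pcg_unet`.
#' @return Integer number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(model$params)
  n
}

# ---------------------------------------------------------------------------
# forward / backward

.rb_fwd <- function(x, p, k, groups, dropout, training) {
  pad <- (k - 1L) %/% 2L
  c1 <- op_conv_fwd(x, p$conv1$W, p$conv1$b, k, 1L, pad)
  g1 <- op_groupnorm_fwd(c1$y, p$gn$gamma, p$gn$beta, groups)
  a1 <- op_gelu_fwd(g1$y)
  d1 <- op_dropout_fwd(a1$y, dropout, training)
  c2 <- op_conv_fwd(d1$y, p$conv2$W, p$conv2$b, k, 1L, pad)
  if (!is.null(p$proj)) {
    pr <- op_conv_fwd(x, p$proj$W, p$proj$b, 1L, 1L, 0L)
    s <- pr$y
  } else {
    pr <- NULL
    s <- x
  }
  a2 <- op_gelu_fwd(c2$y + s)
  list(y = a2$y, cache = list(c1 = c1$cache, g1 = g1$cache, a1 = a1$cache,
                              d1 = d1$cache, c2 = c2$cache,
                              pr = if (is.null(pr)) NULL else pr$cache,
                              a2 = a2$cache))
}

.rb_bwd <- function(dy, cache) {
  dsum <- op_gelu_bwd(dy, cache$a2)
  b2 <- op_conv_bwd(dsum, cache$c2)
  dd1 <- op_dropout_bwd(b2$dx, cache$d1)
  da1 <- op_gelu_bwd(dd1, cache$a1)
  bg <- op_groupnorm_bwd(da1, cache$g1)
  b1 <- op_conv_bwd(bg$dx, cache$c1)
  dx <- b1$dx
  grads <- list(conv1 = list(W = b1$dW, b = b1$db),
                gn = list(gamma = bg$dgamma, beta = bg$dbeta),
                conv2 = list(W = b2$dW, b = b2$db))
  if (!is.null(cache$pr)) {
    bp <- op_conv_bwd(dsum, cache$pr)
    dx <- dx + bp$dx
    grads$proj <- list(W = bp$dW, b = bp$db)
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = grads)
}

.linear_fwd <- function(x, W, b) {
  d <- dim(x)
  y <- W %*% matrix(x, d[1], d[2] * d[3])
  if (!is.null(b)) y <- y + b
  list(y = array(y, c(nrow(W), d[2], d[3])), cache = list(x = x, W = W))
}

.linear_bwd <- function(dy, cache) {
  d <- dim(cache$x)
  dym <- matrix(dy, dim(dy)[1], d[2] * d[3])
  xm <- matrix(cache$x, d[1], d[2] * d[3])
  list(dx = array(t(cache$W) %*% dym, d),
       dW = dym %*% t(xm), db = rowSums(dym))
}

.transformer_layer_fwd <- function(x, p, n_heads, dropout, training) {
  at <- op_mha_fwd(x, p$attn, n_heads, dropout, training)
  dp1 <- op_dropout_fwd(at$y, dropout, training)
  r1 <- x + dp1$y
  l1 <- op_layernorm_fwd(r1, p$ln1$gamma, p$ln1$beta)
  f1 <- .linear_fwd(l1$y, p$ffn1$W, p$ffn1$b)
  a1 <- op_gelu_fwd(f1$y)
  dpa <- op_dropout_fwd(a1$y, dropout, training)
  f2 <- .linear_fwd(dpa$y, p$ffn2$W, p$ffn2$b)
  dp2 <- op_dropout_fwd(f2$y, dropout, training)
  r2 <- l1$y + dp2$y
  l2 <- op_layernorm_fwd(r2, p$ln2$gamma, p$ln2$beta)
  list(y = l2$y, cache = list(at = at$cache, dp1 = dp1$cache, l1 = l1$cache,
                              f1 = f1$cache, a1 = a1$cache, dpa = dpa$cache,
                              f2 = f2$cache, dp2 = dp2$cache, l2 = l2$cache))
}

.transformer_layer_bwd <- function(dy, cache) {
  bl2 <- op_layernorm_bwd(dy, cache$l2)
  dr2 <- bl2$dx
  ddp2 <- op_dropout_bwd(dr2, cache$dp2)
  bf2 <- .linear_bwd(ddp2, cache$f2)
  ddpa <- op_dropout_bwd(bf2$dx, cache$dpa)
  da1 <- op_gelu_bwd(ddpa, cache$a1)
  bf1 <- .linear_bwd(da1, cache$f1)
  dl1 <- dr2 + bf1$dx
  bl1 <- op_layernorm_bwd(dl1, cache$l1)
  dr1 <- bl1$dx
  ddp1 <- op_dropout_bwd(dr1, cache$dp1)
  bat <- op_mha_bwd(ddp1, cache$at)
  dx <- dr1 + bat$dx
  list(dx = dx, grads = list(
    attn = list(Wqkv = bat$dWqkv, bqkv = bat$dbqkv, Wo = bat$dWo, bo = bat$dbo),
    ln1 = list(gamma = bl1$dgamma, beta = bl1$dbeta),
    ffn1 = list(W = bf1$dW, b = bf1$db),
    ffn2 = list(W = bf2$dW, b = bf2$db),
    ln2 = list(gamma = bl2$dgamma, beta = bl2$dbeta)))
}

.head_fwd <- function(x, p, hk, tanh_out, training) {
  pad <- (hk - 1L) %/% 2L
  c1 <- op_conv_fwd(x, p$c1$W, p$c1$b, hk, 1L, pad)
  a1 <- op_gelu_fwd(c1$y)
  c2 <- op_conv_fwd(a1$y, p$c2$W, p$c2$b, 1L, 1L, 0L)
  if (tanh_out) {
    y <- tanh(c2$y)
    th <- y
  } else {
    y <- c2$y
    th <- NULL
  }
  list(y = y, cache = list(c1 = c1$cache, a1 = a1$cache, c2 = c2$cache, th = th))
}

.head_bwd <- function(dy, cache) {
  if (!is.null(cache$th)) dy <- dy * (1 - cache$th^2)
  b2 <- op_conv_bwd(dy, cache$c2)
  da <- op_gelu_bwd(b2$dx, cache$a1)
  b1 <- op_conv_bwd(da, cache$c1)
  list(dx = b1$dx, grads = list(c1 = list(W = b1$dW, b = b1$db),
                                c2 = list(W = b2$dW, b = NULL)))
}

#' Run the encoder
#'
#' @param model A `pcg_unet`.
#' @param x Input array of shape (in_channels, T, batch); T must be divisible
#'   by `2^depth`.
#'
#' @return List with `bottleneck` (array of shape (192, T/16, batch)) and
#'   `skips` (per-level feature tensors at pre-downsampling resolutions).
#' @export
encode <- function(model, x) {
  fw <- .unet_fwd(model, x, training = FALSE, upto = "encoder")
  list(bottleneck = fw$z, skips = fw$skips)
}

.unet_fwd <- function(model, x, training = FALSE, upto = "full") {
  cfg <- model$config
  p <- model$params
  if (length(dim(x)) != 3) stop("input must be a (channels, time, batch) array")
  d <- dim(x)
  if (d[1] != cfg$in_channels) {
    stop("input has ", d[1], " channels but the model expects ", cfg$in_channels)
  }
  if (d[2] %% 2^cfg$depth != 0) {
    stop("input length must be divisible by ", 2^cfg$depth)
  }
  k <- cfg$res_kernel; g <- cfg$groupnorm_groups; drop <- cfg$dropout
  cache <- list()

  st <- op_conv_fwd(x, p$stem$W, p$stem$b, k, 1L, (k - 1L) %/% 2L)
  cache$stem <- st$cache
  z <- st$y
  skips <- vector("list", cfg$depth)
  cache$enc <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    rb <- .rb_fwd(z, p$enc[[i]]$rb, k, g, drop, training)
    skips[[i]] <- rb$y
    dn <- op_conv_fwd(rb$y, p$enc[[i]]$down$W, NULL, cfg$down_kernel, 2L, 1L)
    cache$enc[[i]] <- list(rb = rb$cache, down = dn$cache)
    z <- dn$y
  }
  if (upto == "encoder") return(list(z = z, skips = skips, cache = cache))

  # bottleneck
  pb <- p$bott
  pj1 <- op_conv_fwd(z, pb$proj1$W, pb$proj1$b, 1L, 1L, 0L)
  gn1 <- op_groupnorm_fwd(pj1$y, pb$gn1$gamma, pb$gn1$beta, g)
  ga <- op_gelu_fwd(gn1$y)
  zt <- ga$y
  Tb <- dim(zt)[2]
  pe <- if (cfg$positional_encoding == "sinusoidal") {
    sinusoidal_positions(cfg$embed, Tb)
  } else {
    if (ncol(pb$pos) != Tb) stop("learned positional encoding length mismatch")
    pb$pos
  }
  zt <- zt + as.numeric(pe)
  cache$bott <- list(pj1 = pj1$cache, gn1 = gn1$cache, ga = ga$cache)
  cache$layers <- vector("list", cfg$transformer_layers)
  for (l in seq_len(cfg$transformer_layers)) {
    tl <- .transformer_layer_fwd(zt, pb$layers[[l]], cfg$transformer_heads,
                                 drop, training)
    cache$layers[[l]] <- tl$cache
    zt <- tl$y
  }
  pj2 <- op_conv_fwd(zt, pb$proj2$W, pb$proj2$b, 1L, 1L, 0L)
  gn2 <- op_groupnorm_fwd(pj2$y, pb$gn2$gamma, pb$gn2$beta, g)
  gb <- op_gelu_fwd(gn2$y)
  cache$bott2 <- list(pj2 = pj2$cache, gn2 = gn2$cache, gb = gb$cache)
  z <- gb$y

  # decoder
  cache$dec <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    sk <- skips[[cfg$depth + 1 - i]]
    up <- op_upsample2_fwd(z)
    pj <- op_conv_fwd(up$y, p$dec[[i]]$up$W, NULL, 1L, 1L, 0L)
    cc <- dim(pj$y)[1]
    cat_y <- array(0, dim = c(2 * cc, dim(pj$y)[2], dim(pj$y)[3]))
    cat_y[1:cc, , ] <- pj$y
    cat_y[(cc + 1):(2 * cc), , ] <- sk
    rb <- .rb_fwd(cat_y, p$dec[[i]]$rb, k, g, drop, training)
    cache$dec[[i]] <- list(up = up$cache, pj = pj$cache, rb = rb$cache, cc = cc)
    z <- rb$y
  }

  rf <- .rb_fwd(z, p$refine, k, g, drop, training)
  cache$refine <- rf$cache
  hk <- cfg$head_kernel
  hw <- .head_fwd(rf$y, p$heads$wav, hk, TRUE, training)
  he <- .head_fwd(rf$y, p$heads$env, hk, FALSE, training)
  hs <- .head_fwd(rf$y, p$heads$seg, hk, FALSE, training)
  cache$heads <- list(wav = hw$cache, env = he$cache, seg = hs$cache)

  list(waveform = hw$y, envelope = he$y, logits = hs$y,
       cache = if (training) cache else NULL, skips = skips, z = z)
}

.unet_bwd <- function(model, cache, dwav, denv, dseg) {
  cfg <- model$config
  g <- list()

  bw <- .head_bwd(dwav, cache$heads$wav)
  be <- .head_bwd(denv, cache$heads$env)
  bs <- .head_bwd(dseg, cache$heads$seg)
  g$heads <- list(wav = bw$grads, env = be$grads, seg = bs$grads)
  dref <- bw$dx + be$dx + bs$dx

  brf <- .rb_bwd(dref, cache$refine)
  g$refine <- brf$grads
  dz <- brf$dx

  g$dec <- vector("list", cfg$depth)
  dskips <- vector("list", cfg$depth)
  for (i in rev(seq_len(cfg$depth))) {
    cd <- cache$dec[[i]]
    brb <- .rb_bwd(dz, cd$rb)
    cc <- cd$cc
    dcat <- brb$dx
    dpj <- dcat[1:cc, , , drop = FALSE]
    dskips[[cfg$depth + 1 - i]] <- dcat[(cc + 1):(2 * cc), , , drop = FALSE]
    bpj <- op_conv_bwd(dpj, cd$pj)
    dup <- op_upsample2_bwd(bpj$dx, cd$up)
    g$dec[[i]] <- list(up = list(W = bpj$dW, b = NULL), rb = brb$grads)
    dz <- dup
  }

  # bottleneck
  bgb <- op_gelu_bwd(dz, cache$bott2$gb)
  bgn2 <- op_groupnorm_bwd(bgb, cache$bott2$gn2)
  bpj2 <- op_conv_bwd(bgn2$dx, cache$bott2$pj2)
  dzt <- bpj2$dx
  g$bott <- list(proj2 = list(W = bpj2$dW, b = bpj2$db),
                 gn2 = list(gamma = bgn2$dgamma, beta = bgn2$dbeta))
  g$bott$layers <- vector("list", cfg$transformer_layers)
  for (l in rev(seq_len(cfg$transformer_layers))) {
    btl <- .transformer_layer_bwd(dzt, cache$layers[[l]])
    g$bott$layers[[l]] <- btl$grads
    dzt <- btl$dx
  }
  if (model$config$positional_encoding == "learned") {
    d <- dim(dzt)
    g$bott$pos <- matrix(rowSums(array(dzt, c(d[1] * d[2], d[3]))), d[1], d[2])
  }
  bga <- op_gelu_bwd(dzt, cache$bott$ga)
  bgn1 <- op_groupnorm_bwd(bga, cache$bott$gn1)
  bpj1 <- op_conv_bwd(bgn1$dx, cache$bott$pj1)
  g$bott$proj1 <- list(W = bpj1$dW, b = bpj1$db)
  g$bott$gn1 <- list(gamma = bgn1$dgamma, beta = bgn1$dbeta)
  dz <- bpj1$dx

  # encoder
  g$enc <- vector("list", cfg$depth)
  for (i in rev(seq_len(cfg$depth))) {
    ce <- cache$enc[[i]]
    bdn <- op_conv_bwd(dz, ce$down)
    drb <- bdn$dx + dskips[[i]]
    brb <- .rb_bwd(drb, ce$rb)
    g$enc[[i]] <- list(rb = brb$grads, down = list(W = bdn$dW, b = NULL))
    dz <- brb$dx
  }
  bst <- op_conv_bwd(dz, cache$stem)
  g$stem <- list(W = bst$dW, b = bst$db)
  g
}

#' Forward pass of the multitask U-Net
#'
#' @param model A `pcg_unet`.
#' @param x Input array (in_channels, T, batch) with T divisible by 16, or a
#'   numeric vector / (T x 1) input for a single radar-HS window.
#' @param training Logical; enables dropout and returns the backward cache.
#'
#' @return An object of class `model_outputs`: list with `waveform`
#'   (1, T, batch; bounded to [-1, 1] by tanh), `envelope` (1, T, batch) and
#'   `logits` (4, T, batch).
#' @export
pcg_forward <- function(model, x, training = FALSE) {
  if (is.null(dim(x))) x <- array(x, c(1, length(x), 1))
  fw <- .unet_fwd(model, x, training = training)
  structure(list(waveform = fw$waveform, envelope = fw$envelope,
                 logits = fw$logits, cache = fw$cache),
            class = "model_outputs")
}

#' @export
print.pcg_unet <- function(x, ...) {
  n <- count_parameters(x)
  cat("<pcg_unet>", x$config$in_channels, "input channel(s),",
      paste(x$config$encoder_channels, collapse = "-"), "encoder channels,\n",
      " transformer", x$config$embed, "/", x$config$transformer_heads,
      "heads /", x$config$transformer_ffn, "ffn;",
      formatC(n, big.mark = ","), "trainable parameters",
      sprintf("(%.2f MiB float32)\n", n * 4 / 2^20))
  invisible(x)
}
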