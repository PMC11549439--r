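#' U-Net configuration
#'
#' A compact 2D U-Net for per-structure semantic segmentation of
#' four-channel fluorescence sections: three encoder levels (8/16/32
#' features, each two 3x3 convolutions + batch normalisation, dropout
#' before each 2x2 max pooling), a 64-feature bottleneck with a 2x2
#' transpose convolution, a mirrored decoder with skip concatenations, and
#' a 3x3 output convolution to two classes with softmax. All convolutions
#' use rectified-linear activations.
#'
#' @param tile_size training/inference tile side in px; must be divisible
#'   by 8 (three 2x2 poolings).
#' @param in_channels input channels (4 fluorescence stains).
#' @param encoder_features features per encoder level.
#' @param bottleneck_features features in the bottleneck.
#' @param dropout dropout rate applied before each max pooling.
#' @param out_classes output classes (2: background/foreground).
#' @param downsample_factor input downsampling before training/inference
#'   (4 for the olfactory bulb, whose relevant features are large-scale).
#' @export
unet_config <- function(tile_size = 512L, in_channels = 4L,
                        encoder_features = c(8L, 16L, 32L),
                        bottleneck_features = 64L, dropout = 0.2,
                        out_classes = 2L, downsample_factor = 1L) {
  if (tile_size %% 2^length(encoder_features) != 0)
    stop_olf("tile_size must be divisible by %d", 2^length(encoder_features))
  if (dropout < 0 || dropout >= 1) stop_olf("dropout must lie in [0, 1)")
  structure(list(tile_size = as.integer(tile_size),
                 in_channels = as.integer(in_channels),
                 encoder_features = as.integer(encoder_features),
                 bottleneck_features = as.integer(bottleneck_features),
                 dropout = dropout, out_classes = as.integer(out_classes),
                 downsample_factor = as.integer(downsample_factor)),
            class = "unet_config")
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

conv_layer <- function(k, cin, cout)
  list(type = "conv", w = he_init(k, cin, cout), b = numeric(cout))

upconv_layer <- function(cin, cout)
  list(type = "upconv",
       w = array(rnorm(4 * cin * cout, 0, sqrt(2 / (4 * cin))),
                 dim = c(2, 2, cin, cout)),
       b = numeric(cout))

bn_layer <- function(c)
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       rm = numeric(c), rv = rep(1, c))

#' Build an untrained U-Net
#'
#' @param config a [unet_config()].
#' @param seed seed for the (He) weight initialisation.
#' @return An object of class `unet_model` holding the configuration, the
#'   parameter tensors, an unset threshold, and an empty training history.
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  f <- config$encoder_features; bf <- config$bottleneck_features
  ci <- config$in_channels
  with_seed(seed, {
    layers <- list(
      enc1_conv1 = conv_layer(3, ci, f[1]), enc1_conv2 = conv_layer(3, f[1], f[1]),
      enc1_bn = bn_layer(f[1]),
      enc2_conv1 = conv_layer(3, f[1], f[2]), enc2_conv2 = conv_layer(3, f[2], f[2]),
      enc2_bn = bn_layer(f[2]),
      enc3_conv1 = conv_layer(3, f[2], f[3]), enc3_conv2 = conv_layer(3, f[3], f[3]),
      enc3_bn = bn_layer(f[3]),
      bot_conv1 = conv_layer(3, f[3], bf), bot_conv2 = conv_layer(3, bf, bf),
      bot_bn = bn_layer(bf), bot_up = upconv_layer(bf, f[3]),
      dec3_conv1 = conv_layer(3, 2 * f[3], f[3]),
      dec3_conv2 = conv_layer(3, f[3], f[3]),
      dec3_bn = bn_layer(f[3]), dec3_up = upconv_layer(f[3], f[2]),
      dec2_conv1 = conv_layer(3, 2 * f[2], f[2]),
      dec2_conv2 = conv_layer(3, f[2], f[2]),
      dec2_bn = bn_layer(f[2]), dec2_up = upconv_layer(f[2], f[1]),
      dec1_conv1 = conv_layer(3, 2 * f[1], f[1]),
      dec1_conv2 = conv_layer(3, f[1], f[1]),
      dec1_bn = bn_layer(f[1]),
      out_conv = conv_layer(3, f[1], config$out_classes))
    structure(list(config = config, layers = layers, threshold = NA_real_,
                   history = NULL), class = "unet_model")
  })
}

#' Number of trainable parameters of a U-Net
#'
#' Counts convolution and transpose-convolution weights and biases plus the
#' batch-normalisation scale/shift pairs (running statistics are not
#' trainable).
#'
#' @param model a `unet_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(ly) {
    if (ly$type == "bn") length(ly$gamma) + length(ly$beta)
    else length(ly$w) + length(ly$b)
  }, numeric(1)))
}

# --- batched layer primitives (lists of H x W x C arrays) ------------------

relu_bwd_mask <- function(z, g) { g[z <= 0] <- 0; g }

conv_fwd <- function(xs, ly, relu = TRUE) {
  zs <- lapply(xs, function(x) .nn_conv_fwd(x, ly$w, ly$b))
  outs <- if (relu) lapply(zs, function(z) { z[z < 0] <- 0; z }) else zs
  list(out = outs, x = xs, z = zs)
}

conv_bwd <- function(cache, ly, gouts, relu = TRUE) {
  gw <- array(0, dim = dim(ly$w)); gb <- numeric(length(ly$b))
  gins <- vector("list", length(gouts))
  for (i in seq_along(gouts)) {
    g <- if (relu) relu_bwd_mask(cache$z[[i]], gouts[[i]]) else gouts[[i]]
    bw <- .nn_conv_bwd(cache$x[[i]], ly$w, g)
    gw <- gw + bw$gw; gb <- gb + bw$gb
    gins[[i]] <- bw$gin
  }
  list(gin = gins, gw = gw, gb = gb)
}

upconv_fwd <- function(xs, ly) {
  zs <- lapply(xs, function(x) .nn_upconv_fwd(x, ly$w, ly$b))
  outs <- lapply(zs, function(z) { z[z < 0] <- 0; z })
  list(out = outs, x = xs, z = zs)
}

upconv_bwd <- function(cache, ly, gouts) {
  gw <- array(0, dim = dim(ly$w)); gb <- numeric(length(ly$b))
  gins <- vector("list", length(gouts))
  for (i in seq_along(gouts)) {
    g <- relu_bwd_mask(cache$z[[i]], gouts[[i]])
    bw <- .nn_upconv_bwd(cache$x[[i]], ly$w, g)
    gw <- gw + bw$gw; gb <- gb + bw$gb
    gins[[i]] <- bw$gin
  }
  list(gin = gins, gw = gw, gb = gb)
}

bn_fwd <- function(xs, ly, training, eps = 1e-5, momentum = 0.1) {
  C <- dim(xs[[1]])[3]
  npix <- length(xs) * prod(dim(xs[[1]])[1:2])
  if (training) {
    mu <- rowSums(vapply(xs, function(x) apply(x, 3, sum), numeric(C))) / npix
    va <- rowSums(vapply(xs, function(x)
      vapply(seq_len(C), function(ch) sum((x[, , ch] - mu[ch])^2), numeric(1)),
      numeric(C))) / npix
    ly$rm <- (1 - momentum) * ly$rm + momentum * mu
    ly$rv <- (1 - momentum) * ly$rv + momentum * va
  } else {
    mu <- ly$rm; va <- ly$rv
  }
  istd <- 1 / sqrt(va + eps)
  xh <- lapply(xs, function(x) {
    for (ch in seq_len(C)) x[, , ch] <- (x[, , ch] - mu[ch]) * istd[ch]
    x
  })
  outs <- lapply(xh, function(x) {
    for (ch in seq_len(C)) x[, , ch] <- ly$gamma[ch] * x[, , ch] + ly$beta[ch]
    x
  })
  list(out = outs, xh = xh, istd = istd, layer = ly, npix = npix)
}

bn_bwd <- function(cache, ly, gouts) {
  C <- length(ly$gamma)
  npix <- cache$npix
  dgamma <- numeric(C); dbeta <- numeric(C)
  sg <- numeric(C); sgx <- numeric(C)
  for (i in seq_along(gouts)) {
    for (ch in seq_len(C)) {
      g <- gouts[[i]][, , ch]
      dbeta[ch] <- dbeta[ch] + sum(g)
      dgamma[ch] <- dgamma[ch] + sum(g * cache$xh[[i]][, , ch])
    }
  }
  sg <- dbeta; sgx <- dgamma
  gins <- lapply(seq_along(gouts), function(i) {
    g <- gouts[[i]]
    for (ch in seq_len(C)) {
      g[, , ch] <- ly$gamma[ch] * cache$istd[ch] *
        (g[, , ch] - sg[ch] / npix - cache$xh[[i]][, , ch] * sgx[ch] / npix)
    }
    g
  })
  list(gin = gins, dgamma = dgamma, dbeta = dbeta)
}

dropout_fwd <- function(xs, p, training) {
  if (!training || p <= 0) return(list(out = xs, masks = NULL, p = p))
  masks <- lapply(xs, function(x)
    array((runif(length(x)) >= p) / (1 - p), dim = dim(x)))
  list(out = mapply(function(x, m) x * m, xs, masks, SIMPLIFY = FALSE),
       masks = masks, p = p)
}

dropout_bwd <- function(cache, gouts) {
  if (is.null(cache$masks)) return(gouts)
  mapply(function(g, m) g * m, gouts, cache$masks, SIMPLIFY = FALSE)
}

pool_fwd <- function(xs) {
  res <- lapply(xs, .nn_pool_fwd)
  list(out = lapply(res, `[[`, "out"), idx = lapply(res, `[[`, "idx"),
       shape = dim(xs[[1]]))
}

pool_bwd <- function(cache, gouts) {
  mapply(function(idx, g)
    .nn_pool_bwd(idx, g, cache$shape[1], cache$shape[2], cache$shape[3]),
    cache$idx, gouts, SIMPLIFY = FALSE)
}

concat_fwd <- function(as, bs) {
  list(out = mapply(function(a, b)
    array(c(a, b), dim = c(dim(a)[1:2], dim(a)[3] + dim(b)[3])),
    as, bs, SIMPLIFY = FALSE),
    ca = dim(as[[1]])[3], cb = dim(bs[[1]])[3])
}

concat_bwd <- function(cache, gouts) {
  ga <- lapply(gouts, function(g) g[, , seq_len(cache$ca), drop = FALSE])
  gb <- lapply(gouts, function(g)
    g[, , cache$ca + seq_len(cache$cb), drop = FALSE])
  list(ga = ga, gb = gb)
}

softmax3 <- function(z) {
  m <- pmax(z[, , 1], z[, , 2])
  e1 <- exp(z[, , 1] - m); e2 <- exp(z[, , 2] - m)
  s <- e1 + e2
  array(c(e1 / s, e2 / s), dim = dim(z))
}

# Full forward pass over a batch (list of H x W x C arrays). Returns class
# probabilities and, in training mode, the caches needed for the backward
# pass. Batch-normalisation statistics are taken over the whole batch.
unet_forward <- function(model, xs, training = FALSE) {
  L <- model$layers; p <- model$config$dropout
  cache <- list()
  cache$e1a <- conv_fwd(xs, L$enc1_conv1)
  cache$e1b <- conv_fwd(cache$e1a$out, L$enc1_conv2)
  cache$e1n <- bn_fwd(cache$e1b$out, L$enc1_bn, training)
  cache$e1d <- dropout_fwd(cache$e1n$out, p, training)
  cache$p1 <- pool_fwd(cache$e1d$out)
  cache$e2a <- conv_fwd(cache$p1$out, L$enc2_conv1)
  cache$e2b <- conv_fwd(cache$e2a$out, L$enc2_conv2)
  cache$e2n <- bn_fwd(cache$e2b$out, L$enc2_bn, training)
  cache$e2d <- dropout_fwd(cache$e2n$out, p, training)
  cache$p2 <- pool_fwd(cache$e2d$out)
  cache$e3a <- conv_fwd(cache$p2$out, L$enc3_conv1)
  cache$e3b <- conv_fwd(cache$e3a$out, L$enc3_conv2)
  cache$e3n <- bn_fwd(cache$e3b$out, L$enc3_bn, training)
  cache$e3d <- dropout_fwd(cache$e3n$out, p, training)
  cache$p3 <- pool_fwd(cache$e3d$out)
  cache$b1 <- conv_fwd(cache$p3$out, L$bot_conv1)
  cache$b2 <- conv_fwd(cache$b1$out, L$bot_conv2)
  cache$bn4 <- bn_fwd(cache$b2$out, L$bot_bn, training)
  cache$u4 <- upconv_fwd(cache$bn4$out, L$bot_up)
  cache$k3 <- concat_fwd(cache$e3n$out, cache$u4$out)
  cache$d3a <- conv_fwd(cache$k3$out, L$dec3_conv1)
  cache$d3b <- conv_fwd(cache$d3a$out, L$dec3_conv2)
  cache$d3n <- bn_fwd(cache$d3b$out, L$dec3_bn, training)
  cache$u5 <- upconv_fwd(cache$d3n$out, L$dec3_up)
  cache$k2 <- concat_fwd(cache$e2n$out, cache$u5$out)
  cache$d2a <- conv_fwd(cache$k2$out, L$dec2_conv1)
  cache$d2b <- conv_fwd(cache$d2a$out, L$dec2_conv2)
  cache$d2n <- bn_fwd(cache$d2b$out, L$dec2_bn, training)
  cache$u6 <- upconv_fwd(cache$d2n$out, L$dec2_up)
  cache$k1 <- concat_fwd(cache$e1n$out, cache$u6$out)
  cache$d1a <- conv_fwd(cache$k1$out, L$dec1_conv1)
  cache$d1b <- conv_fwd(cache$d1a$out, L$dec1_conv2)
  cache$d1n <- bn_fwd(cache$d1b$out, L$dec1_bn, training)
  cache$oc <- conv_fwd(cache$d1n$out, L$out_conv, relu = FALSE)
  probs <- lapply(cache$oc$out, softmax3)
  # persist updated running statistics
  bn_updates <- if (training) list(
    enc1_bn = cache$e1n$layer, enc2_bn = cache$e2n$layer,
    enc3_bn = cache$e3n$layer, bot_bn = cache$bn4$layer,
    dec3_bn = cache$d3n$layer, dec2_bn = cache$d2n$layer,
    dec1_bn = cache$d1n$layer) else NULL
  list(probs = probs, cache = if (training) cache else NULL,
       bn_updates = bn_updates)
}

# Backward pass from softmax + cross-entropy. ys: list of binary masks.
unet_backward <- function(model, fwd, ys) {
  L <- model$layers; cache <- fwd$cache
  n <- length(ys)
  gz <- mapply(function(p, y) {
    npx <- length(y)
    array(c((p[, , 1] - (1 - y)) / (npx * n),
            (p[, , 2] - y) / (npx * n)), dim = dim(p))
  }, fwd$probs, ys, SIMPLIFY = FALSE)
  grads <- list()
  bw <- conv_bwd(cache$oc, L$out_conv, gz, relu = FALSE)
  grads$out_conv <- bw; g <- bw$gin
  bb <- bn_bwd(cache$d1n, L$dec1_bn, g); grads$dec1_bn <- bb; g <- bb$gin
  bw <- conv_bwd(cache$d1b, L$dec1_conv2, g); grads$dec1_conv2 <- bw; g <- bw$gin
  bw <- conv_bwd(cache$d1a, L$dec1_conv1, g); grads$dec1_conv1 <- bw; g <- bw$gin
  sp <- concat_bwd(cache$k1, g); g_skip1 <- sp$ga; g <- sp$gb
  bw <- upconv_bwd(cache$u6, L$dec2_up, g); grads$dec2_up <- bw; g <- bw$gin
  bb <- bn_bwd(cache$d2n, L$dec2_bn, g); grads$dec2_bn <- bb; g <- bb$gin
  bw <- conv_bwd(cache$d2b, L$dec2_conv2, g); grads$dec2_conv2 <- bw; g <- bw$gin
  bw <- conv_bwd(cache$d2a, L$dec2_conv1, g); grads$dec2_conv1 <- bw; g <- bw$gin
  sp <- concat_bwd(cache$k2, g); g_skip2 <- sp$ga; g <- sp$gb
  bw <- upconv_bwd(cache$u5, L$dec3_up, g); grads$dec3_up <- bw; g <- bw$gin
  bb <- bn_bwd(cache$d3n, L$dec3_bn, g); grads$dec3_bn <- bb; g <- bb$gin
  bw <- conv_bwd(cache$d3b, L$dec3_conv2, g); grads$dec3_conv2 <- bw; g <- bw$gin
  bw <- conv_bwd(cache$d3a, L$dec3_conv1, g); grads$dec3_conv1 <- bw; g <- bw$gin
  sp <- concat_bwd(cache$k3, g); g_skip3 <- sp$ga; g <- sp$gb
  bw <- upconv_bwd(cache$u4, L$bot_up, g); grads$bot_up <- bw; g <- bw$gin
  bb <- bn_bwd(cache$bn4, L$bot_bn, g); grads$bot_bn <- bb; g <- bb$gin
  bw <- conv_bwd(cache$b2, L$bot_conv2, g); grads$bot_conv2 <- bw; g <- bw$gin
  bw <- conv_bwd(cache$b1, L$bot_conv1, g); grads$bot_conv1 <- bw; g <- bw$gin
  g <- pool_bwd(cache$p3, g)
  g <- dropout_bwd(cache$e3d, g)
  g <- mapply(`+`, g, g_skip3, SIMPLIFY = FALSE)
  bb <- bn_bwd(cache$e3n, L$enc3_bn, g); grads$enc3_bn <- bb; g <- bb$gin
  bw <- conv_bwd(cache$e3b, L$enc3_conv2, g); grads$enc3_conv2 <- bw; g <- bw$gin
  bw <- conv_bwd(cache$e3a, L$enc3_conv1, g); grads$enc3_conv1 <- bw; g <- bw$gin
  g <- pool_bwd(cache$p2, g)
  g <- dropout_bwd(cache$e2d, g)
  g <- mapply(`+`, g, g_skip2, SIMPLIFY = FALSE)
  bb <- bn_bwd(cache$e2n, L$enc2_bn, g); grads$enc2_bn <- bb; g <- bb$gin
  bw <- conv_bwd(cache$e2b, L$enc2_conv2, g); grads$enc2_conv2 <- bw; g <- bw$gin
  bw <- conv_bwd(cache$e2a, L$enc2_conv1, g); grads$enc2_conv1 <- bw; g <- bw$gin
  g <- pool_bwd(cache$p1, g)
  g <- dropout_bwd(cache$e1d, g)
  g <- mapply(`+`, g, g_skip1, SIMPLIFY = FALSE)
  bb <- bn_bwd(cache$e1n, L$enc1_bn, g); grads$enc1_bn <- bb; g <- bb$gin
  bw <- conv_bwd(cache$e1b, L$enc1_conv2, g); grads$enc1_conv2 <- bw; g <- bw$gin
  bw <- conv_bwd(cache$e1a, L$enc1_conv1, g); grads$enc1_conv1 <- bw
  grads
}

adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    if (ly$type == "bn")
      list(mg = numeric(length(ly$gamma)), vg = numeric(length(ly$gamma)),
           mb = numeric(length(ly$beta)), vb = numeric(length(ly$beta)))
    else
      list(mw = array(0, dim = dim(ly$w)), vw = array(0, dim = dim(ly$w)),
           mb = numeric(length(ly$b)), vb = numeric(length(ly$b)))
  })
}

adam_step <- function(model, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
  for (nm in names(grads)) {
    ly <- model$layers[[nm]]; st <- state[[nm]]; gr <- grads[[nm]]
    if (ly$type == "bn") {
      st$mg <- beta1 * st$mg + (1 - beta1) * gr$dgamma
      st$vg <- beta2 * st$vg + (1 - beta2) * gr$dgamma^2
      st$mb <- beta1 * st$mb + (1 - beta1) * gr$dbeta
      st$vb <- beta2 * st$vb + (1 - beta2) * gr$dbeta^2
      ly$gamma <- ly$gamma - lr * (st$mg / corr1) / (sqrt(st$vg / corr2) + eps)
      ly$beta <- ly$beta - lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
    } else {
      st$mw <- beta1 * st$mw + (1 - beta1) * gr$gw
      st$vw <- beta2 * st$vw + (1 - beta2) * gr$gw^2
      st$mb <- beta1 * st$mb + (1 - beta1) * gr$gb
      st$vb <- beta2 * st$vb + (1 - beta2) * gr$gb^2
      ly$w <- ly$w - lr * (st$mw / corr1) / (sqrt(st$vw / corr2) + eps)
      ly$b <- ly$b - lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
    }
    model$layers[[nm]] <- ly; state[[nm]] <- st
  }
  list(model = model, state = state)
}
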