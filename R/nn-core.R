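# Minimal neural-network core.
#
# A compact, pure-R reference implementation of the handful of layers the
# package needs: im2col convolution, dense layers, batch normalization,
# LeakyReLU/ReLU/tanh/sigmoid, inverted dropout, 2x2 max pooling, nearest
# upsampling, global average pooling, and Adam. Image batches are stored as
# 4-D arrays [H, W, C, N] (column-major, so H varies fastest); dense
# activations as N x d matrices. Every layer exposes a forward pass that
# returns a cache and a backward pass that returns input gradients plus
# per-parameter gradients, which is all that alternating GAN updates and
# head fine-tuning require.
#
# Layers are plain lists: list(type, params, state, cfg). A network is
# list(layers = list(...)). Randomness (weight init, dropout masks) draws
# from the session RNG; callers seed it via with_seed().

nn_dense <- function(d_in, d_out, init_sd = NULL) {
  init_sd <- init_sd %||% sqrt(2 / d_in)
  list(type = "dense",
       params = list(W = matrix(rnorm(d_in * d_out, 0, init_sd), d_in, d_out),
                     b = numeric(d_out)),
       state = list(), cfg = list(d_in = d_in, d_out = d_out))
}

nn_conv <- function(c_in, c_out, k, init_sd = NULL) {
  init_sd <- init_sd %||% sqrt(2 / (k * k * c_in))
  list(type = "conv",
       params = list(W = array(rnorm(k * k * c_in * c_out, 0, init_sd),
                               c(k, k, c_in, c_out)),
                     b = numeric(c_out)),
       state = list(), cfg = list(k = k, c_in = c_in, c_out = c_out,
                                  pad = as.integer(ceiling((k - 1) / 2))))
}

nn_bn <- function(n_feat, kind = c("dense", "conv"), momentum = 0.9,
                  eps = 1e-5) {
  kind <- match.arg(kind)
  list(type = "bn",
       params = list(gamma = rep(1, n_feat), beta = numeric(n_feat)),
       state = list(mean = numeric(n_feat), var = rep(1, n_feat)),
       cfg = list(kind = kind, momentum = momentum, eps = eps,
                  n_feat = n_feat))
}

nn_act <- function(fun = c("relu", "lrelu", "tanh", "sigmoid"),
                   slope = 0.2) {
  fun <- match.arg(fun)
  list(type = "act", params = list(), state = list(),
       cfg = list(fun = fun, slope = slope))
}

nn_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", params = list(), state = list(),
       cfg = list(rate = rate))
}

nn_maxpool <- function() {
  list(type = "maxpool", params = list(), state = list(), cfg = list())
}

nn_upsample <- function() {
  list(type = "upsample", params = list(), state = list(), cfg = list())
}

nn_flatten <- function() {
  list(type = "flatten", params = list(), state = list(), cfg = list())
}

nn_reshape <- function(h, w, c) {
  list(type = "reshape", params = list(), state = list(),
       cfg = list(h = h, w = w, c = c))
}

nn_gap <- function() {
  list(type = "gap", params = list(), state = list(), cfg = list())
}

# --- im2col ------------------------------------------------------------

# Linear indices into a padded [Hp, Wp, C] array (pad `pb` before and `pa`
# after along both spatial axes) such that column j of the patch matrix
# holds the k x k x C receptive field of output pixel j (stride 1, "same"
# output size). Requires pa >= k - 1 - pb. Cached per layer and shape.
im2col_idx <- function(H, W, C, k, pb, pa) {
  Hp <- H + pb + pa
  Wp <- W + pb + pa
  di <- rep(seq_len(k) - 1L, times = k)
  dj <- rep(seq_len(k) - 1L, each = k)
  patch <- as.vector(outer(di + dj * Hp, (seq_len(C) - 1L) * Hp * Wp, `+`))
  corner <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, `+`))
  outer(patch, corner, `+`)
}

# Gather the im2col patch matrix of one [H, W, C] image.
im2col_gather <- function(img, H, W, C, pb, pa, idx) {
  xp <- array(0, c(H + pb + pa, W + pb + pa, C))
  xp[pb + seq_len(H), pb + seq_len(W), ] <- img
  matrix(xp[idx], nrow(idx), ncol(idx))
}

conv_forward <- function(layer, x) {
  cfg <- layer$cfg
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- cfg$k; pb <- cfg$pad; pa <- k - 1L - pb
  key <- paste(H, W, C, sep = "x")
  if (is.null(layer$state$idx_key) || layer$state$idx_key != key) {
    layer$state$idx <- im2col_idx(H, W, C, k, pb, pa)
    layer$state$idx_key <- key
  }
  idx <- layer$state$idx
  Wmat <- matrix(layer$params$W, k * k * C, cfg$c_out)
  out <- array(0, c(H, W, cfg$c_out, N))
  cols <- vector("list", N)
  for (n in seq_len(N)) {
    col <- im2col_gather(x[, , , n], H, W, C, pb, pa, idx)
    cols[[n]] <- col
    o <- crossprod(col, Wmat)                      # (H*W) x c_out
    o <- sweep(o, 2L, layer$params$b, `+`)
    out[, , , n] <- o
  }
  list(out = out, cache = list(cols = cols, dimx = d), layer = layer)
}

# Input gradient of a stride-1 "same" convolution equals a convolution of
# the output gradient with the spatially flipped kernel and swapped
# channel roles, so the backward pass is two matmuls per image.
conv_backward <- function(layer, cache, dout) {
  cfg <- layer$cfg
  d <- cache$dimx
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- cfg$k; pb <- cfg$pad
  qb <- k - 1L - pb; qa <- pb
  key <- paste(H, W, cfg$c_out, "bwd", sep = "x")
  if (is.null(layer$state$bidx_key) || layer$state$bidx_key != key) {
    layer$state$bidx <- im2col_idx(H, W, cfg$c_out, k, qb, qa)
    layer$state$bidx_key <- key
  }
  bidx <- layer$state$bidx
  # flipped kernel: Wrot[a, b, f, c] = W[k+1-a, k+1-b, c, f]
  Wrot <- aperm(layer$params$W[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3))
  Wrmat <- matrix(Wrot, k * k * cfg$c_out, C)
  dW <- matrix(0, k * k * C, cfg$c_out)
  db <- numeric(cfg$c_out)
  dx <- array(0, d)
  for (n in seq_len(N)) {
    dmat <- matrix(dout[, , , n], H * W, cfg$c_out)
    dW <- dW + cache$cols[[n]] %*% dmat
    db <- db + colSums(dmat)
    gcol <- im2col_gather(dout[, , , n], H, W, cfg$c_out, qb, qa, bidx)
    dx[, , , n] <- crossprod(gcol, Wrmat)
  }
  list(dx = dx, grads = list(W = array(dW, dim(layer$params$W)), b = db))
}

# --- other layers ------------------------------------------------------

dense_forward <- function(layer, x) {
  out <- sweep(x %*% layer$params$W, 2L, layer$params$b, `+`)
  list(out = out, cache = list(x = x), layer = layer)
}

dense_backward <- function(layer, cache, dout) {
  list(dx = dout %*% t(layer$params$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

# Channel-major view of a conv tensor: (H*W*N) x C
conv_to_cm <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}

cm_to_conv <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

bn_forward <- function(layer, x, training) {
  cfg <- layer$cfg
  conv_kind <- cfg$kind == "conv"
  m <- if (conv_kind) conv_to_cm(x) else x
  if (training) {
    mu <- colMeans(m)
    xc <- sweep(m, 2L, mu)
    v <- colMeans(xc^2)
    layer$state$mean <- cfg$momentum * layer$state$mean + (1 - cfg$momentum) * mu
    layer$state$var <- cfg$momentum * layer$state$var + (1 - cfg$momentum) * v
  } else {
    mu <- layer$state$mean
    v <- layer$state$var
    xc <- sweep(m, 2L, mu)
  }
  inv_sd <- 1 / sqrt(v + cfg$eps)
  xhat <- sweep(xc, 2L, inv_sd, `*`)
  out <- sweep(sweep(xhat, 2L, layer$params$gamma, `*`), 2L,
               layer$params$beta, `+`)
  if (conv_kind) out <- cm_to_conv(out, dim(x))
  list(out = out,
       cache = list(xhat = xhat, inv_sd = inv_sd, dimx = dim(x),
                    training = training),
       layer = layer)
}

bn_backward <- function(layer, cache, dout) {
  cfg <- layer$cfg
  conv_kind <- cfg$kind == "conv"
  dm <- if (conv_kind) conv_to_cm(dout) else dout
  xhat <- cache$xhat
  n <- nrow(dm)
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2L, layer$params$gamma, `*`)
  if (cache$training) {
    dxc <- sweep(
      dxhat - matrix(colMeans(dxhat), n, ncol(dm), byrow = TRUE) -
        xhat * matrix(colMeans(dxhat * xhat), n, ncol(dm), byrow = TRUE),
      2L, cache$inv_sd, `*`)
  } else {
    dxc <- sweep(dxhat, 2L, cache$inv_sd, `*`)
  }
  if (conv_kind) dxc <- cm_to_conv(dxc, cache$dimx)
  list(dx = dxc, grads = list(gamma = dgamma, beta = dbeta))
}

act_forward <- function(layer, x) {
  out <- switch(layer$cfg$fun,
    relu = pmax(x, 0),
    lrelu = ifelse(x > 0, x, layer$cfg$slope * x),
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)))
  if (is.array(x)) out <- array(out, dim(x))
  list(out = out, cache = list(x = x, out = out), layer = layer)
}

act_backward <- function(layer, cache, dout) {
  g <- switch(layer$cfg$fun,
    relu = dout * (cache$x > 0),
    lrelu = dout * ifelse(cache$x > 0, 1, layer$cfg$slope),
    tanh = dout * (1 - cache$out^2),
    sigmoid = dout * cache$out * (1 - cache$out))
  if (is.array(cache$x)) g <- array(g, dim(cache$x))
  list(dx = g, grads = list())
}

dropout_forward <- function(layer, x, training) {
  if (!training || layer$cfg$rate == 0) {
    return(list(out = x, cache = list(mask = NULL), layer = layer))
  }
  keep <- 1 - layer$cfg$rate
  mask <- (runif(length(x)) < keep) / keep
  out <- x * mask
  if (is.array(x)) out <- array(out, dim(x))
  list(out = out, cache = list(mask = mask), layer = layer)
}

dropout_backward <- function(layer, cache, dout) {
  dx <- if (is.null(cache$mask)) dout else dout * cache$mask
  if (is.array(dout)) dx <- array(dx, dim(dout))
  list(dx = dx, grads = list())
}

maxpool_forward <- function(layer, x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  a <- x[i1, j1, , , drop = FALSE]; b <- x[i2, j1, , , drop = FALSE]
  cc <- x[i1, j2, , , drop = FALSE]; e <- x[i2, j2, , , drop = FALSE]
  out <- pmax(a, b, cc, e)
  list(out = out, cache = list(a = a, b = b, cc = cc, e = e, out = out,
                               dimx = d), layer = layer)
}

maxpool_backward <- function(layer, cache, dout) {
  d <- cache$dimx
  H <- d[1]; W <- d[2]
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  dx <- array(0, d)
  taken <- cache$a == cache$out
  dx[i1, j1, , ] <- dout * taken
  m <- cache$b == cache$out & !taken; taken <- taken | m
  dx[i2, j1, , ] <- dout * m
  m <- cache$cc == cache$out & !taken; taken <- taken | m
  dx[i1, j2, , ] <- dout * m
  m <- cache$e == cache$out & !taken
  dx[i2, j2, , ] <- dout * m
  list(dx = dx, grads = list())
}

upsample_forward <- function(layer, x) {
  d <- dim(x)
  out <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
           drop = FALSE]
  list(out = out, cache = list(dimx = d), layer = layer)
}

upsample_backward <- function(layer, cache, dout) {
  H2 <- dim(dout)[1]; W2 <- dim(dout)[2]
  i1 <- seq(1L, H2, 2L); i2 <- seq(2L, H2, 2L)
  j1 <- seq(1L, W2, 2L); j2 <- seq(2L, W2, 2L)
  dx <- dout[i1, j1, , , drop = FALSE] + dout[i2, j1, , , drop = FALSE] +
    dout[i1, j2, , , drop = FALSE] + dout[i2, j2, , , drop = FALSE]
  list(dx = dx, grads = list())
}

flatten_forward <- function(layer, x) {
  d <- dim(x)
  out <- t(matrix(x, prod(d[1:3]), d[4]))
  list(out = out, cache = list(dimx = d), layer = layer)
}

flatten_backward <- function(layer, cache, dout) {
  list(dx = array(t(dout), cache$dimx), grads = list())
}

reshape_forward <- function(layer, x) {
  cfg <- layer$cfg
  out <- array(t(x), c(cfg$h, cfg$w, cfg$c, nrow(x)))
  list(out = out, cache = list(n = nrow(x), d = ncol(x)), layer = layer)
}

reshape_backward <- function(layer, cache, dout) {
  list(dx = t(matrix(dout, cache$d, cache$n)), grads = list())
}

gap_forward <- function(layer, x) {
  d <- dim(x)
  out <- t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
  list(out = out, cache = list(dimx = d), layer = layer)
}

gap_backward <- function(layer, cache, dout) {
  d <- cache$dimx
  hw <- d[1] * d[2]
  dx <- array(rep(as.vector(t(dout)) / hw, each = hw), d)
  list(dx = dx, grads = list())
}

# --- network-level passes ----------------------------------------------

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    dense = dense_forward(layer, x),
    conv = conv_forward(layer, x),
    bn = bn_forward(layer, x, training),
    act = act_forward(layer, x),
    dropout = dropout_forward(layer, x, training),
    maxpool = maxpool_forward(layer, x),
    upsample = upsample_forward(layer, x),
    flatten = flatten_forward(layer, x),
    reshape = reshape_forward(layer, x),
    gap = gap_forward(layer, x),
    abort(paste("unknown layer type", layer$type)))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    dense = dense_backward(layer, cache, dout),
    conv = conv_backward(layer, cache, dout),
    bn = bn_backward(layer, cache, dout),
    act = act_backward(layer, cache, dout),
    dropout = dropout_backward(layer, cache, dout),
    maxpool = maxpool_backward(layer, cache, dout),
    upsample = upsample_backward(layer, cache, dout),
    flatten = flatten_backward(layer, cache, dout),
    reshape = reshape_backward(layer, cache, dout),
    gap = gap_backward(layer, cache, dout))
}

# Forward through the whole layer list. Returns the output, per-layer caches
# for backprop, and the (possibly state-updated) network.
nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    net$layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, net = net)
}

# Backward from the loss gradient at the output; returns the gradient at the
# input plus a per-layer list of parameter gradients.
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    r <- layer_backward(net$layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

# --- Adam --------------------------------------------------------------

adam_init <- function(net) {
  list(t = 0L,
       m = lapply(net$layers, function(l) lapply(l$params, function(p) p * 0)),
       v = lapply(net$layers, function(l) lapply(l$params, function(p) p * 0)))
}

adam_step <- function(net, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(net$layers)) {
    for (nm in names(net$layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st$m[[i]][[nm]] <- beta1 * st$m[[i]][[nm]] + (1 - beta1) * g
      st$v[[i]][[nm]] <- beta2 * st$v[[i]][[nm]] + (1 - beta2) * g^2
      net$layers[[i]]$params[[nm]] <- net$layers[[i]]$params[[nm]] -
        lr * (st$m[[i]][[nm]] / bc1) / (sqrt(st$v[[i]][[nm]] / bc2) + eps)
    }
  }
  list(net = net, st = st)
}

# Stable row-wise softmax.
softmax_rows <- function(o) {
  e <- exp(o - apply(o, 1L, max))
  e / rowSums(e)
}

# Mean categorical cross-entropy and its gradient at the logits.
softmax_xent <- function(logits, Y) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  loss <- -sum(Y * log(pmax(p, 1e-12))) / n
  list(loss = loss, dlogits = (p - Y) / n, probs = p)
}
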