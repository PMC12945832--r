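# Internal tensor primitives. Feature maps are dense arrays laid out
# (H, W, N, C): with channels last, a 1x1 convolution is a single BLAS
# matrix product after a zero-copy dim<- reshape, and k x k convolutions
# are k^2 shifted products. Everything is double precision and
# deterministic, which keeps finite-difference gradient checks meaningful.

pad_array <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# full k x k convolution, weights (k, k, Ci, Co), same-padding
conv2d_fwd <- function(x, W, b, stride = 1L) {
  k <- dim(W)[1]; Ci <- dim(W)[3]; Co <- dim(W)[4]
  if (dim(x)[4] != Ci) stop("conv2d: channel mismatch")
  pad <- (k - 1L) %/% 2L
  xp <- pad_array(x, pad)
  d <- dim(xp); N <- d[3]
  Ho <- (d[1] - k) %/% stride + 1L
  Wo <- (d[2] - k) %/% stride + 1L
  acc <- matrix(0, Ho * Wo * N, Co)
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    xs <- xp[seq.int(di, by = stride, length.out = Ho),
             seq.int(dj, by = stride, length.out = Wo), , , drop = FALSE]
    dim(xs) <- c(Ho * Wo * N, Ci)
    acc <- acc + xs %*% matrix(W[di, dj, , ], Ci, Co)
  }
  acc <- acc + rep(b, each = Ho * Wo * N)
  dim(acc) <- c(Ho, Wo, N, Co)
  list(y = acc, xp = xp)
}

conv2d_bwd <- function(dy, xp, W, stride = 1L, in_dim) {
  k <- dim(W)[1]; Ci <- dim(W)[3]; Co <- dim(W)[4]
  d <- dim(dy); Ho <- d[1]; Wo <- d[2]; N <- d[3]
  dym <- dy
  dim(dym) <- c(Ho * Wo * N, Co)
  dW <- array(0, dim(W))
  db <- colSums(dym)
  dxp <- array(0, dim(xp))
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    ri <- seq.int(di, by = stride, length.out = Ho)
    cj <- seq.int(dj, by = stride, length.out = Wo)
    xs <- xp[ri, cj, , , drop = FALSE]
    dim(xs) <- c(Ho * Wo * N, Ci)
    dW[di, dj, , ] <- crossprod(xs, dym)
    dxs <- dym %*% t(matrix(W[di, dj, , ], Ci, Co))
    dim(dxs) <- c(Ho, Wo, N, Ci)
    dxp[ri, cj, , ] <- dxp[ri, cj, , , drop = FALSE] + dxs
  }
  pad <- (k - 1L) %/% 2L
  dx <- if (pad > 0L)
    dxp[pad + seq_len(in_dim[1]), pad + seq_len(in_dim[2]), , , drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = db)
}

# pointwise (1x1) convolution, weights (Ci, Co): one BLAS product
pw_fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  ym <- xm %*% W
  ym <- ym + rep(b, each = nrow(ym))
  dim(ym) <- c(d[1], d[2], d[3], ncol(W))
  list(y = ym, xm = xm)
}

pw_bwd <- function(dy, xm, W) {
  d <- dim(dy)
  dym <- dy
  dim(dym) <- c(d[1] * d[2] * d[3], d[4])
  dW <- crossprod(xm, dym)
  db <- colSums(dym)
  dx <- dym %*% t(W)
  dim(dx) <- c(d[1], d[2], d[3], nrow(W))
  list(dx = dx, dW = dW, db = db)
}

# depthwise k x k convolution, weights (k, k, C), same-padding
dw_fwd <- function(x, W, b, stride = 1L) {
  k <- dim(W)[1]; C <- dim(W)[3]
  if (dim(x)[4] != C) stop("depthwise: channel mismatch")
  pad <- (k - 1L) %/% 2L
  xp <- pad_array(x, pad)
  d <- dim(xp); N <- d[3]
  Ho <- (d[1] - k) %/% stride + 1L
  Wo <- (d[2] - k) %/% stride + 1L
  hwn <- Ho * Wo * N
  acc <- array(0, c(Ho, Wo, N, C))
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    xs <- xp[seq.int(di, by = stride, length.out = Ho),
             seq.int(dj, by = stride, length.out = Wo), , , drop = FALSE]
    acc <- acc + xs * rep(W[di, dj, ], each = hwn)
  }
  acc <- acc + rep(b, each = hwn)
  list(y = acc, xp = xp)
}

dw_bwd <- function(dy, xp, W, stride = 1L, in_dim) {
  k <- dim(W)[1]; C <- dim(W)[3]
  d <- dim(dy); Ho <- d[1]; Wo <- d[2]; N <- d[3]
  hwn <- Ho * Wo * N
  dW <- array(0, dim(W))
  dxp <- array(0, dim(xp))
  db <- colSums(matrix(dy, ncol = C))
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    ri <- seq.int(di, by = stride, length.out = Ho)
    cj <- seq.int(dj, by = stride, length.out = Wo)
    xs <- xp[ri, cj, , , drop = FALSE]
    dW[di, dj, ] <- colSums(matrix(xs * dy, ncol = C))
    dxp[ri, cj, , ] <- dxp[ri, cj, , , drop = FALSE] +
      dy * rep(W[di, dj, ], each = hwn)
  }
  pad <- (k - 1L) %/% 2L
  dx <- if (pad > 0L)
    dxp[pad + seq_len(in_dim[1]), pad + seq_len(in_dim[2]), , , drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}
relu_bwd <- function(dy, mask) dy * mask

sigmoid <- function(z) 1 / (1 + exp(-z))

# global average pool to (C, N)
gap_fwd <- function(x) {
  d <- dim(x)
  t(matrix(colSums(matrix(x, nrow = d[1] * d[2])), d[3], d[4])) / (d[1] * d[2])
}

gap_bwd <- function(ds, in_dim) {
  hw <- in_dim[1] * in_dim[2]
  # ds is (C, N); broadcast over pixels in (H, W, N, C) layout
  array(rep(as.vector(t(ds)) / hw, each = hw), in_dim)
}

# squeeze-and-excitation: gate = sigmoid(W2' relu(W1' squeeze(x) + b1) + b2),
# squeeze = global average pool; output = gate (x) channelwise
se_fwd <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  s <- gap_fwd(x)                       # (C, N)
  a1 <- crossprod(W1, s) + b1           # (Cse, N)
  h <- a1 * (a1 > 0)
  a2 <- crossprod(W2, h) + b2           # (C, N)
  g <- sigmoid(a2)
  y <- x * rep(as.vector(t(g)), each = d[1] * d[2])
  list(y = y, s = s, a1 = a1, h = h, g = g)
}

se_bwd <- function(dy, x, cache, W1, W2) {
  d <- dim(x)
  hw <- d[1] * d[2]
  g <- cache$g
  dx <- dy * rep(as.vector(t(g)), each = hw)
  # dL/dg summed over pixels
  dg <- t(matrix(colSums(matrix(dy * x, nrow = hw)), d[3], d[4]))
  da2 <- dg * g * (1 - g)
  dW2 <- cache$h %*% t(da2)
  db2 <- rowSums(da2)
  dh <- W2 %*% da2
  da1 <- dh * (cache$a1 > 0)
  dW1 <- cache$s %*% t(da1)
  db1 <- rowSums(da1)
  ds <- W1 %*% da1
  dx <- dx + gap_bwd(ds, d)
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Desk-scale MBConv network configuration
#'
#' Describes a small MnasNet-style network: a 3x3 stem convolution
#' (stride 2, as in the full-scale architecture) followed by a stack of
#' mobile inverted bottleneck (MBConv) blocks - 1x1 expansion with ReLU,
#' k x k depthwise convolution with ReLU, squeeze-and-excitation gating,
#' linear 1x1 projection, and a residual connection whenever the stride is
#' 1 and input/output channels match - then global average pooling, dropout
#' and a softmax classifier head. No batch normalization is used
#' (deterministic desk-scale setting).
#'
#' @param input_size Square input side in pixels (default 32).
#' @param in_channels Input channels (default 1, grayscale).
#' @param stem_filters Stem output channels (default 8).
#' @param stem_stride Stem stride, 1 or 2 (default 2).
#' @param blocks List of blocks; each is a list with `e` (expansion factor),
#'   `k` (odd kernel size), `stride` (1 or 2), `out` (output channels), `se`
#'   (squeeze-and-excitation reduction ratio).
#' @param classes Number of classes (default 2).
#' @return An object of class `model_config`.
#' @examples
#' cfg <- model_config()
#' resource_cost(cfg)
#' @export
model_config <- function(input_size = 32L, in_channels = 1L,
                         stem_filters = 8L, stem_stride = 2L,
                         blocks = list(
                           list(e = 3, k = 3, stride = 2, out = 16, se = 4),
                           list(e = 3, k = 3, stride = 1, out = 16, se = 4),
                           list(e = 3, k = 3, stride = 2, out = 24, se = 4)),
                         classes = 2L) {
  if (!stem_stride %in% c(1L, 2L)) stop("model_config: strides must be 1 or 2")
  for (bl in blocks) {
    if (!bl$stride %in% c(1L, 2L)) stop("model_config: strides must be 1 or 2")
    if (bl$k %% 2L != 1L) stop("model_config: kernel sizes must be odd")
    if (bl$se < 1) stop("model_config: SE reduction ratio must be >= 1")
  }
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 stem_filters = as.integer(stem_filters),
                 stem_stride = as.integer(stem_stride),
                 blocks = blocks, classes = as.integer(classes)),
            class = "model_config")
}

# Per-layer shape walk shared by init, forward and the resource proxies.
model_plan <- function(cfg) {
  sz <- cfg$input_size
  stem_out <- if (cfg$stem_stride == 2L) sz %/% 2L else sz
  cin <- cfg$stem_filters
  plan <- list(stem = list(k = 3L, cin = cfg$in_channels,
                           cout = cfg$stem_filters, stride = cfg$stem_stride,
                           size_in = sz, size_out = stem_out))
  sz <- stem_out
  for (i in seq_along(cfg$blocks)) {
    bl <- cfg$blocks[[i]]
    ec <- bl$e * cin
    cse <- max(1L, round(ec / bl$se))
    size_out <- if (bl$stride == 2L) sz %/% 2L else sz
    plan[[paste0("b", i)]] <- list(
      cin = cin, ec = ec, cse = cse, cout = bl$out, k = bl$k,
      stride = bl$stride, size_in = sz, size_out = size_out,
      residual = bl$stride == 1L && cin == bl$out)
    cin <- bl$out
    sz <- size_out
  }
  plan$head <- list(cin = cin, cout = cfg$classes, size_in = sz)
  plan
}

#' Initialize model weights
#'
#' Xavier (Glorot) normal uses `sd = sqrt(2 / (fan_in + fan_out))`, He
#' normal `sd = sqrt(2 / fan_in)`. All biases start at zero. Deterministic
#' for a fixed seed.
#'
#' @param cfg A [model_config()].
#' @param scheme `"xavier_normal"` or `"he_normal"`.
#' @param seed Integer seed.
#' @return Named list of weight arrays (class `model_weights`).
#' @export
init_weights <- function(cfg, scheme = c("xavier_normal", "he_normal"),
                         seed = 1L) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  sdev <- function(fan_in, fan_out) {
    if (scheme == "xavier_normal") sqrt(2 / (fan_in + fan_out))
    else sqrt(2 / fan_in)
  }
  rnd <- function(dims, fan_in, fan_out)
    array(stats::rnorm(prod(dims), 0, sdev(fan_in, fan_out)), dims)
  plan <- model_plan(cfg)
  w <- list()
  st <- plan$stem
  w$stem.W <- rnd(c(st$k, st$k, st$cin, st$cout),
                  st$k^2 * st$cin, st$k^2 * st$cout)
  w$stem.b <- numeric(st$cout)
  for (nm in grep("^b[0-9]+$", names(plan), value = TRUE)) {
    p <- plan[[nm]]
    w[[paste0(nm, ".exp.W")]] <- rnd(c(p$cin, p$ec), p$cin, p$ec)
    w[[paste0(nm, ".exp.b")]] <- numeric(p$ec)
    w[[paste0(nm, ".dw.W")]] <- rnd(c(p$k, p$k, p$ec), p$k^2, p$k^2)
    w[[paste0(nm, ".dw.b")]] <- numeric(p$ec)
    w[[paste0(nm, ".se.W1")]] <- rnd(c(p$ec, p$cse), p$ec, p$cse)
    w[[paste0(nm, ".se.b1")]] <- numeric(p$cse)
    w[[paste0(nm, ".se.W2")]] <- rnd(c(p$cse, p$ec), p$cse, p$ec)
    w[[paste0(nm, ".se.b2")]] <- numeric(p$ec)
    w[[paste0(nm, ".proj.W")]] <- rnd(c(p$ec, p$cout), p$ec, p$cout)
    w[[paste0(nm, ".proj.b")]] <- numeric(p$cout)
  }
  hd <- plan$head
  w$head.W <- rnd(c(hd$cin, hd$cout), hd$cin, hd$cout)
  w$head.b <- numeric(hd$cout)
  class(w) <- "model_weights"
  w
}

#' Forward pass through the MBConv network
#'
#' @param weights A `model_weights` list from [init_weights()].
#' @param cfg The matching [model_config()].
#' @param x Input batch: H x W x N array, a single matrix, or a full
#'   (H, W, N, C) array.
#' @param training Logical; enables dropout.
#' @param dropout_p Dropout probability on the pooled feature vector
#'   (inverted dropout; identity at inference).
#' @return List with `probs` (classes x N), `logits`, and `cache` for
#'   [model_backward()].
#' @export
model_forward <- function(weights, cfg, x, training = FALSE, dropout_p = 0) {
  x <- as_input_batch(x)
  if (dim(x)[1] != cfg$input_size || dim(x)[2] != cfg$input_size)
    stop("model_forward: input size does not match the model configuration")
  if (dim(x)[4] != cfg$in_channels)
    stop("model_forward: input channel count does not match the model")
  plan <- model_plan(cfg)
  cache <- list(x_dim = dim(x))
  st <- conv2d_fwd(x, weights$stem.W, weights$stem.b, cfg$stem_stride)
  r <- relu_fwd(st$y)
  cache$stem <- list(xp = st$xp, mask = r$mask)
  z <- r$y
  for (nm in grep("^b[0-9]+$", names(plan), value = TRUE)) {
    p <- plan[[nm]]
    ex <- pw_fwd(z, weights[[paste0(nm, ".exp.W")]],
                 weights[[paste0(nm, ".exp.b")]])
    r1 <- relu_fwd(ex$y)
    dw <- dw_fwd(r1$y, weights[[paste0(nm, ".dw.W")]],
                 weights[[paste0(nm, ".dw.b")]], p$stride)
    r2 <- relu_fwd(dw$y)
    se <- se_fwd(r2$y, weights[[paste0(nm, ".se.W1")]],
                 weights[[paste0(nm, ".se.b1")]],
                 weights[[paste0(nm, ".se.W2")]],
                 weights[[paste0(nm, ".se.b2")]])
    pr <- pw_fwd(se$y, weights[[paste0(nm, ".proj.W")]],
                 weights[[paste0(nm, ".proj.b")]])
    out <- if (p$residual) pr$y + z else pr$y
    cache[[nm]] <- list(exp_xm = ex$xm, r1_mask = r1$mask,
                        r1_dim = dim(r1$y), dw_xp = dw$xp, r2_mask = r2$mask,
                        se_in = r2$y, se = se, proj_xm = pr$xm,
                        residual = p$residual)
    z <- out
  }
  cache$pre_pool_dim <- dim(z)
  feat <- gap_fwd(z)
  if (training && dropout_p > 0) {
    keep <- matrix(stats::runif(length(feat)) >= dropout_p, nrow(feat))
    mask <- keep / (1 - dropout_p)
    featd <- feat * mask
  } else {
    mask <- NULL
    featd <- feat
  }
  logits <- crossprod(weights$head.W, featd) + weights$head.b
  cache$featd <- featd
  cache$drop_mask <- mask
  list(probs = softmax_cols(logits), logits = logits, cache = cache)
}

#' Backward pass: gradients of a loss w.r.t. every weight
#'
#' @param weights,cfg As in [model_forward()].
#' @param cache The cache returned by [model_forward()].
#' @param dlogits Gradient of the loss w.r.t. the logits (classes x N); for
#'   mean cross-entropy this is `(probs - onehot) / N`.
#' @return Named list of gradients matching the weight names.
#' @export
model_backward <- function(weights, cfg, cache, dlogits) {
  plan <- model_plan(cfg)
  g <- list()
  g$head.W <- cache$featd %*% t(dlogits)
  g$head.b <- rowSums(dlogits)
  dfeat <- weights$head.W %*% dlogits
  if (!is.null(cache$drop_mask)) dfeat <- dfeat * cache$drop_mask
  dz <- gap_bwd(dfeat, cache$pre_pool_dim)
  for (nm in rev(grep("^b[0-9]+$", names(plan), value = TRUE))) {
    p <- plan[[nm]]
    cc <- cache[[nm]]
    dres <- if (cc$residual) dz else 0
    pb <- pw_bwd(dz, cc$proj_xm, weights[[paste0(nm, ".proj.W")]])
    g[[paste0(nm, ".proj.W")]] <- pb$dW
    g[[paste0(nm, ".proj.b")]] <- pb$db
    sb <- se_bwd(pb$dx, cc$se_in, cc$se,
                 weights[[paste0(nm, ".se.W1")]],
                 weights[[paste0(nm, ".se.W2")]])
    g[[paste0(nm, ".se.W1")]] <- sb$dW1
    g[[paste0(nm, ".se.b1")]] <- sb$db1
    g[[paste0(nm, ".se.W2")]] <- sb$dW2
    g[[paste0(nm, ".se.b2")]] <- sb$db2
    dd <- relu_bwd(sb$dx, cc$r2_mask)
    db_ <- dw_bwd(dd, cc$dw_xp, weights[[paste0(nm, ".dw.W")]], p$stride,
                  in_dim = cc$r1_dim)
    g[[paste0(nm, ".dw.W")]] <- db_$dW
    g[[paste0(nm, ".dw.b")]] <- db_$db
    de <- relu_bwd(db_$dx, cc$r1_mask)
    eb <- pw_bwd(de, cc$exp_xm, weights[[paste0(nm, ".exp.W")]])
    g[[paste0(nm, ".exp.W")]] <- eb$dW
    g[[paste0(nm, ".exp.b")]] <- eb$db
    dz <- eb$dx + dres
  }
  ds <- relu_bwd(dz, cache$stem$mask)
  sb <- conv2d_bwd(ds, cache$stem$xp, weights$stem.W, cfg$stem_stride,
                   in_dim = cache$x_dim)
  g$stem.W <- sb$dW
  g$stem.b <- sb$db
  g
}

as_input_batch <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  else if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

#' Cross-entropy (negative log-likelihood) accuracy loss
#'
#' Mean negative log-likelihood of the true classes,
#' `-(1/N) * sum_i log p_{i, c_i}`, with probabilities clamped below at
#' `eps` so an exactly-zero predicted probability yields a finite loss.
#'
#' @param probs Classes x N matrix of predicted probabilities.
#' @param labels Integer class labels in `0..C-1` (length N) or a one-hot
#'   C x N matrix.
#' @param eps Probability clamp (default 1e-12).
#' @return Non-negative scalar; 0 iff every true class has probability 1.
#' @export
loss_acc <- function(probs, labels, eps = 1e-12) {
  if (is.matrix(labels)) {
    p_true <- colSums(probs * labels)
  } else {
    p_true <- probs[cbind(as.integer(labels) + 1L, seq_len(ncol(probs)))]
  }
  mean(-log(pmax(p_true, eps)))
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, classes, length(labels))
  Y[cbind(as.integer(labels) + 1L, seq_along(labels))] <- 1
  Y
}

#' Deterministic resource proxies of a model configuration
#'
#' `c_size` is the exact trainable-parameter count in millions; `c_latency`
#' is a hardware-free latency proxy: the multiply-accumulate count of one
#' forward pass (convolutions, squeeze-and-excitation and classifier
#' products) divided by 1e6. Both depend only on the architecture, never on
#' weight values.
#'
#' @param cfg A [model_config()].
#' @return List of class `resource_cost` with `c_size`, `c_latency`,
#'   `params`, `macs`.
#' @export
resource_cost <- function(cfg) {
  plan <- model_plan(cfg)
  params <- 0
  macs <- 0
  st <- plan$stem
  params <- params + st$k^2 * st$cin * st$cout + st$cout
  macs <- macs + st$size_out^2 * st$k^2 * st$cin * st$cout
  for (nm in grep("^b[0-9]+$", names(plan), value = TRUE)) {
    p <- plan[[nm]]
    params <- params + p$cin * p$ec + p$ec +          # expansion
      p$k^2 * p$ec + p$ec +                           # depthwise
      p$ec * p$cse + p$cse + p$cse * p$ec + p$ec +    # SE
      p$ec * p$cout + p$cout                          # projection
    macs <- macs + p$size_in^2 * p$cin * p$ec +
      p$size_out^2 * p$k^2 * p$ec +
      p$ec * p$cse * 2 +
      p$size_out^2 * p$ec +                           # channel gating
      p$size_out^2 * p$ec * p$cout
  }
  hd <- plan$head
  params <- params + hd$cin * hd$cout + hd$cout
  macs <- macs + hd$cin * hd$cout
  structure(list(c_size = params / 1e6, c_latency = macs / 1e6,
                 params = params, macs = macs),
            class = "resource_cost")
}

#' Resource-efficiency and composite losses
#'
#' Two published orderings of the resource-weighted terms exist and both are
#' exposed: `loss_eff(cost, l1, l2) = l1 * c_size + l2 * c_latency`
#' (size-first), and the composite training loss used by the pipeline,
#' `loss_total(L_CE, cost, l1, l2) = L_CE + l1 * c_latency + l2 * c_size`
#' (latency-first, the form the selected coefficients `l1 = 8.7e-3`,
#' `l2 = 4.2e-4` belong to).
#'
#' @param cost A [resource_cost()].
#' @param l1,l2 Non-negative trade-off coefficients.
#' @param L_CE Cross-entropy loss of the candidate.
#' @return Scalar loss value.
#' @export
loss_eff <- function(cost, l1, l2) {
  if (l1 < 0 || l2 < 0) stop("loss_eff: coefficients must be non-negative")
  l1 * cost$c_size + l2 * cost$c_latency
}

#' @rdname loss_eff
#' @export
loss_total <- function(L_CE, cost, l1, l2) {
  if (l1 < 0 || l2 < 0) stop("loss_total: coefficients must be non-negative")
  L_CE + l1 * cost$c_latency + l2 * cost$c_size
}

#' Predict class probabilities for a batch of images
#'
#' @param model A `glioscope_model` (from [train_model()]) or any list with
#'   `weights` and `config`.
#' @param images H x W x N array (or a single matrix).
#' @return Classes x N matrix of probabilities.
#' @export
predict_model <- function(model, images) {
  model_forward(model$weights, model$config, images, training = FALSE)$probs
}
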