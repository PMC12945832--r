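# Shared fixtures, built in code at test time.

# tiny two-block model used by gradient and forward tests
tiny_model_config <- function() {
  model_config(input_size = 8L, stem_filters = 3L, stem_stride = 1L,
               blocks = list(list(e = 2, k = 3, stride = 2, out = 4, se = 2),
                             list(e = 2, k = 3, stride = 1, out = 4, se = 2)),
               classes = 2L)
}

# weights with small random biases so no ReLU pre-activation sits exactly on
# the kink (finite differences are only valid at differentiable points)
jittered_weights <- function(cfg, scheme = "he_normal", seed = 5L) {
  w <- init_weights(cfg, scheme, seed)
  set.seed(seed + 1000L)
  for (nm in names(w)) {
    if (grepl("\\.b[0-9]*$", nm)) w[[nm]] <- stats::rnorm(length(w[[nm]]), 0, 0.05)
  }
  w
}

# small phantom dataset, cached per session
small_phantom_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_dataset(phantom_spec(n_per_class = 30L, seed = 7L))
    }
    cache
  }
})

# small split dataset ready for training
small_training_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- small_phantom_dataset()
      sp <- stratified_split(ds$manifest$patient_id, ds$manifest$label,
                             seed = 11)
      ds <- apply_split(ds, sp)
      st <- channel_stats(subset_images(ds$images,
                                        which(ds$manifest$split == "train")),
                          partition = "train")
      ds$images <- normalize(ds$images, st)
      cache <<- ds
    }
    cache
  }
})

# independent brute-force metric arithmetic (kept deliberately separate from
# the package implementation)
brute_metrics <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  list(sensitivity = tp / (tp + fn),
       precision = tp / (tp + fp),
       specificity = tn / (tn + fp),
       f1 = 2 * (tp / (tp + fp)) * (tp / (tp + fn)) /
         ((tp / (tp + fp)) + (tp / (tp + fn))),
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       mcc = (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}

# naive per-pixel CLAHE reference: same algorithm, written as explicit loops
clahe_reference <- function(image, tile, clip_limit, range = c(0, 1)) {
  nbins <- 256L
  span <- range[2] - range[1]
  H <- nrow(image); W <- ncol(image)
  q <- round((image - range[1]) / span * (nbins - 1L))
  q[q < 0] <- 0; q[q > nbins - 1L] <- nbins - 1L
  Hp <- ceiling(H / tile) * tile; Wp <- ceiling(W / tile) * tile
  qp <- matrix(0L, Hp, Wp)
  for (i in seq_len(Hp)) for (j in seq_len(Wp)) {
    ii <- if (i <= H) i else 2L * H - i + 1L
    jj <- if (j <= W) j else 2L * W - j + 1L
    qp[i, j] <- q[ii, jj]
  }
  ntr <- Hp / tile; ntc <- Wp / tile
  npix <- tile * tile
  maps <- array(0, c(nbins, ntr, ntc))
  for (tr in seq_len(ntr)) for (tc in seq_len(ntc)) {
    h <- numeric(nbins)
    for (i in seq_len(tile)) for (j in seq_len(tile)) {
      v <- qp[(tr - 1L) * tile + i, (tc - 1L) * tile + j]
      h[v + 1L] <- h[v + 1L] + 1
    }
    if (is.finite(clip_limit)) {
      cap <- clip_limit * npix / nbins
      excess <- sum(pmax(h - cap, 0))
      h <- pmin(h, cap) + excess / nbins
    }
    maps[, tr, tc] <- cumsum(h) / npix * (nbins - 1)
  }
  centers_r <- (seq_len(ntr) - 0.5) * tile
  centers_c <- (seq_len(ntc) - 0.5) * tile
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    pi_ <- i - 0.5; pj <- j - 0.5
    r0 <- max(1L, findInterval(pi_, centers_r)); r1 <- min(r0 + 1L, ntr)
    c0 <- max(1L, findInterval(pj, centers_c)); c1 <- min(c0 + 1L, ntc)
    wr <- if (r1 == r0) 0 else (pi_ - centers_r[r0]) / (centers_r[r1] - centers_r[r0])
    wc <- if (c1 == c0) 0 else (pj - centers_c[c0]) / (centers_c[c1] - centers_c[c0])
    wr <- min(1, max(0, wr)); wc <- min(1, max(0, wc))
    b <- q[i, j] + 1L
    m <- (1 - wr) * (1 - wc) * maps[b, r0, c0] +
      (1 - wr) * wc * maps[b, r0, c1] +
      wr * (1 - wc) * maps[b, r1, c0] +
      wr * wc * maps[b, r1, c1]
    out[i, j] <- m / (nbins - 1) * span + range[1]
  }
  out
}
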