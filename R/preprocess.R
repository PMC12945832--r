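#' Contrast Limited Adaptive Histogram Equalization
#'
#' Per-tile histogram equalization with a clip limit. The image is quantized
#' to 256 gray bins, reflect-padded so both dimensions are multiples of the
#' tile size, and a clipped, renormalized equalization mapping is built per
#' tile: each tile histogram is clipped at `clip_limit` times the uniform bin
#' height and the clipped excess is redistributed uniformly over all bins
#' (one pass). Pixel values are then remapped by bilinear interpolation
#' between the mappings of the four surrounding tile centers, and the result
#' is returned in the input's numeric range. Deterministic; idempotence is
#' not claimed.
#'
#' @param image Numeric matrix (single-channel raster).
#' @param tile Tile side length in pixels (default 8).
#' @param clip_limit Clip limit as a multiple of the uniform histogram height
#'   (default 2.0). `Inf` disables clipping (plain adaptive equalization).
#' @param range Length-2 numeric giving the intensity range of `image`.
#'   Default `NULL` infers `c(0, 1)` when all values lie in \[0,1\], else
#'   `c(0, 255)`.
#' @return Numeric matrix of the same size and range.
#' @examples
#' img <- matrix(runif(64 * 64, 0.4, 0.6), 64, 64)
#' out <- clahe(img, tile = 8, clip_limit = 2)
#' @export
clahe <- function(image, tile = 8L, clip_limit = 2.0, range = NULL) {
  if (!is.matrix(image)) stop("clahe: image must be a matrix")
  tile <- as.integer(tile)
  if (tile < 1L) stop("clahe: tile must be a positive integer")
  if (nrow(image) < tile || ncol(image) < tile)
    stop("clahe: image smaller than one tile")
  if (clip_limit <= 0) stop("clahe: clip_limit must be positive")
  if (is.null(range)) {
    range <- if (min(image) >= 0 && max(image) <= 1) c(0, 1) else c(0, 255)
  }
  span <- range[2] - range[1]
  if (span <= 0) stop("clahe: degenerate intensity range")

  nbins <- 256L
  q <- round((image - range[1]) / span * (nbins - 1L))
  q <- pmin(pmax(q, 0L), nbins - 1L) # 0..255 integer bins, dims kept

  H <- nrow(q); W <- ncol(q)
  Hp <- ceiling(H / tile) * tile
  Wp <- ceiling(W / tile) * tile
  qp <- reflect_pad(q, Hp - H, Wp - W)

  ntr <- Hp %/% tile
  ntc <- Wp %/% tile
  npix <- tile * tile

  # 256 x (ntr*ntc) matrix of per-tile equalization mappings (0..255)
  maps <- matrix(0, nbins, ntr * ntc)
  for (tc in seq_len(ntc)) {
    for (tr in seq_len(ntr)) {
      block <- qp[(tr - 1L) * tile + seq_len(tile),
                  (tc - 1L) * tile + seq_len(tile)]
      maps[, (tc - 1L) * ntr + tr] <- clahe_tile_map(block, nbins, npix, clip_limit)
    }
  }

  # bilinear interpolation between the four surrounding tile-center mappings
  centers_r <- (seq_len(ntr) - 0.5) * tile
  centers_c <- (seq_len(ntc) - 0.5) * tile
  ir <- interp_coords(seq_len(H) - 0.5, centers_r, ntr) # pixel centers
  ic <- interp_coords(seq_len(W) - 0.5, centers_c, ntc)

  i0 <- ir$lo[row(q)]; i1 <- ir$hi[row(q)]; wr <- ir$w[row(q)]
  j0 <- ic$lo[col(q)]; j1 <- ic$hi[col(q)]; wc <- ic$w[col(q)]
  bin <- as.vector(q) + 1L
  look <- function(ti, tj) maps[cbind(bin, (tj - 1L) * ntr + ti)]
  mapped <- (1 - wr) * (1 - wc) * look(i0, j0) +
            (1 - wr) * wc       * look(i0, j1) +
            wr       * (1 - wc) * look(i1, j0) +
            wr       * wc       * look(i1, j1)
  out <- matrix(mapped / (nbins - 1) * span + range[1], H, W)
  out
}

# Equalization mapping for one tile: clipped histogram -> scaled CDF.
clahe_tile_map <- function(block, nbins, npix, clip_limit) {
  h <- tabulate(as.vector(block) + 1L, nbins)
  if (is.finite(clip_limit)) {
    cap <- clip_limit * npix / nbins
    excess <- sum(pmax(h - cap, 0))
    h <- pmin(h, cap) + excess / nbins
  }
  cdf <- cumsum(h) / npix
  cdf * (nbins - 1)
}

# Neighbour tile indices and interpolation weight for positions `p` given
# tile-center coordinates (clamped at the borders).
interp_coords <- function(p, centers, nt) {
  lo <- findInterval(p, centers)
  hi <- pmin(lo + 1L, nt)
  lo <- pmax(lo, 1L)
  w <- ifelse(hi == lo, 0,
              (p - centers[lo]) / (centers[hi] - centers[lo]))
  w <- pmin(1, pmax(0, w))
  list(lo = lo, hi = hi, w = w)
}

reflect_pad <- function(m, dr, dc) {
  if (dr > 0) m <- rbind(m, m[nrow(m) - seq_len(dr) + 1L, , drop = FALSE])
  if (dc > 0) m <- cbind(m, m[, ncol(m) - seq_len(dc) + 1L, drop = FALSE])
  m
}

#' Augmentation policy
#'
#' Declares which augmentation operators are enabled and their parameter
#' ranges. Geometric operators preserve image size; no operator ever alters
#' the label. "Kernel filters" are realized as Gaussian blur and unsharp
#' masking; "color jitter" on grayscale means brightness/contrast jitter.
#'
#' @param ops Character vector, subset of `flip_h`, `flip_v`, `rotate`,
#'   `crop`, `zoom`, `stretch`, `sharpen`, `blur`, `brightness`, `contrast`,
#'   `random_erase`.
#' @param rotate_deg Max absolute rotation in degrees (default 15).
#' @param crop_frac Minimum retained side fraction for random crops
#'   (default 0.85).
#' @param zoom_range Multiplicative zoom range (default `c(0.9, 1.1)`).
#' @param blur_sigma Gaussian blur sigma range (default `c(0.5, 1.5)`).
#' @param jitter Brightness/contrast jitter amplitude (default 0.1).
#' @param erase_frac Area-fraction range for random erasing
#'   (default `c(0.02, 0.1)`).
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(ops = c("flip_h", "rotate"),
                           rotate_deg = 15, crop_frac = 0.85,
                           zoom_range = c(0.9, 1.1),
                           blur_sigma = c(0.5, 1.5),
                           jitter = 0.1, erase_frac = c(0.02, 0.1)) {
  known <- c("flip_h", "flip_v", "rotate", "crop", "zoom", "stretch",
             "sharpen", "blur", "brightness", "contrast", "random_erase")
  bad <- setdiff(ops, known)
  if (length(bad)) stop("augment_policy: unknown op(s): ",
                        paste(bad, collapse = ", "))
  structure(list(ops = ops, rotate_deg = rotate_deg, crop_frac = crop_frac,
                 zoom_range = zoom_range, blur_sigma = blur_sigma,
                 jitter = jitter, erase_frac = erase_frac),
            class = "augment_policy")
}

#' Apply a sampled augmentation chain to one image
#'
#' Flips fire with probability 1/2; all other enabled operators are applied
#' with randomly drawn parameters, in the policy's order. The label is
#' returned unchanged. Randomness comes from the ambient RNG (seed before
#' calling for reproducibility).
#'
#' @param image Numeric matrix in \[0,1\].
#' @param label The class label (passed through untouched).
#' @param policy An [augment_policy()]. An empty policy is the identity.
#' @return List with `image`, `label`.
#' @export
augment <- function(image, label, policy) {
  stopifnot(inherits(policy, "augment_policy"))
  for (op in policy$ops) {
    image <- switch(op,
      flip_h = if (stats::runif(1) < 0.5) image[, ncol(image):1] else image,
      flip_v = if (stats::runif(1) < 0.5) image[nrow(image):1, ] else image,
      rotate = rotate_image(image, stats::runif(1, -policy$rotate_deg,
                                                policy$rotate_deg)),
      crop = random_crop(image, stats::runif(1, policy$crop_frac, 1)),
      zoom = affine_resample(image, sx = 1 / stats::runif(1, policy$zoom_range[1],
                                                          policy$zoom_range[2])),
      stretch = affine_resample(image,
                                sx = 1 / stats::runif(1, policy$zoom_range[1],
                                                      policy$zoom_range[2]),
                                sy = 1 / stats::runif(1, policy$zoom_range[1],
                                                      policy$zoom_range[2])),
      blur = gaussian_blur(image, stats::runif(1, policy$blur_sigma[1],
                                               policy$blur_sigma[2])),
      sharpen = unsharp_mask(image, stats::runif(1, policy$blur_sigma[1],
                                                 policy$blur_sigma[2]),
                             amount = stats::runif(1, 0.5, 1.5)),
      brightness = image + stats::runif(1, -policy$jitter, policy$jitter),
      contrast = {
        g <- 1 + stats::runif(1, -policy$jitter, policy$jitter)
        mean(image) + (image - mean(image)) * g
      },
      random_erase = random_erase(image, stats::runif(1, policy$erase_frac[1],
                                                      policy$erase_frac[2])),
      image)
  }
  list(image = pmin(pmax(image, 0), 1), label = label)
}

# Bilinear sampling of `image` at arbitrary (row, col) coordinates, with
# coordinates clamped to the image so geometry ops replicate edges.
bilinear_sample <- function(image, r, cc) {
  H <- nrow(image); W <- ncol(image)
  r <- pmin(H, pmax(1, r)); cc <- pmin(W, pmax(1, cc))
  r0 <- floor(r); c0 <- floor(cc)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- r - r0; fc <- cc - c0
  (1 - fr) * (1 - fc) * image[cbind(r0, c0)] +
    (1 - fr) * fc * image[cbind(r0, c1)] +
    fr * (1 - fc) * image[cbind(r1, c0)] +
    fr * fc * image[cbind(r1, c1)]
}

rotate_image <- function(image, angle_deg) {
  if (angle_deg == 0) return(image)
  H <- nrow(image); W <- ncol(image)
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  dr <- g$r - cy; dc <- g$c - cx
  src_r <- cos(th) * dr - sin(th) * dc + cy
  src_c <- sin(th) * dr + cos(th) * dc + cx
  matrix(bilinear_sample(image, src_r, src_c), H, W)
}

# Resample about the image center with scale factors (sx, sy); sx > 1 zooms
# out (source window larger than the frame), edges replicate.
affine_resample <- function(image, sx = 1, sy = sx) {
  H <- nrow(image); W <- ncol(image)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  matrix(bilinear_sample(image, (g$r - cy) * sx + cy, (g$c - cx) * sy + cx),
         H, W)
}

random_crop <- function(image, frac) {
  H <- nrow(image); W <- ncol(image)
  h <- max(2L, round(H * frac)); w <- max(2L, round(W * frac))
  r0 <- sample.int(H - h + 1L, 1L); c0 <- sample.int(W - w + 1L, 1L)
  crop <- image[r0 + seq_len(h) - 1L, c0 + seq_len(w) - 1L, drop = FALSE]
  # resize the crop back to the original frame
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  src_r <- (g$r - 0.5) * h / H + 0.5
  src_c <- (g$c - 0.5) * w / W + 0.5
  matrix(bilinear_sample(crop, src_r, src_c), H, W)
}

gaussian_blur <- function(image, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_sep(image, k)
}

unsharp_mask <- function(image, sigma, amount = 1) {
  image + amount * (image - gaussian_blur(image, sigma))
}

# Separable same-size convolution with edge replication.
conv_sep <- function(image, k) {
  rad <- (length(k) - 1L) / 2
  H <- nrow(image); W <- ncol(image)
  idx <- function(n, off) pmin(n, pmax(1L, seq_len(n) + off))
  out <- matrix(0, H, W)
  for (o in seq_along(k)) out <- out + k[o] * image[idx(H, o - rad - 1L), ]
  out2 <- matrix(0, H, W)
  for (o in seq_along(k)) out2 <- out2 + k[o] * out[, idx(W, o - rad - 1L)]
  out2
}

random_erase <- function(image, area_frac) {
  H <- nrow(image); W <- ncol(image)
  # aspect ratio in [0.5, 2]
  ar <- exp(stats::runif(1, log(0.5), log(2)))
  h <- max(1L, min(H, round(sqrt(area_frac * H * W * ar))))
  w <- max(1L, min(W, round(sqrt(area_frac * H * W / ar))))
  r0 <- sample.int(H - h + 1L, 1L); c0 <- sample.int(W - w + 1L, 1L)
  image[r0 + seq_len(h) - 1L, c0 + seq_len(w) - 1L] <-
    stats::runif(h * w)
  image
}

#' Per-channel normalization statistics with provenance
#'
#' Computes mean and standard deviation of the pixel values over the images
#' belonging to the stated partition and records that partition. Statistics
#' may only ever come from the training partition; [normalize()] enforces
#' this with a hard error.
#'
#' @param images List of matrices or H x W x N array.
#' @param partition Partition name the images came from (recorded).
#' @return List with `mean`, `sd`, `partition`, class `channel_stats`.
#' @export
channel_stats <- function(images, partition = "train") {
  v <- unlist(lapply(as_image_list(images), as.vector), use.names = FALSE)
  structure(list(mean = mean(v), sd = stats::sd(v), partition = partition),
            class = "channel_stats")
}

#' Normalize images with training-set statistics
#'
#' Applies `(x - mean) / max(sd, eps)` using statistics whose recorded
#' provenance must be the training partition; any other provenance is a data
#' leakage error (hard failure, by design).
#'
#' @param images List of matrices or H x W x N array.
#' @param stats A [channel_stats()] computed on the training partition.
#' @param eps Standard-deviation floor (default 1e-6).
#' @return Images in the same container shape, normalized.
#' @export
normalize <- function(images, stats, eps = 1e-6) {
  stopifnot(inherits(stats, "channel_stats"))
  if (!identical(stats$partition, "train"))
    stop("normalize: data leakage - normalization statistics were computed ",
         "on partition '", stats$partition, "', not on the training set")
  s <- max(stats$sd, eps)
  if (is.list(images)) {
    lapply(images, function(m) (m - stats$mean) / s)
  } else {
    (images - stats$mean) / s
  }
}

as_image_list <- function(images) {
  if (is.list(images)) return(images)
  if (is.matrix(images)) return(list(images))
  if (length(dim(images)) == 3L)
    return(lapply(seq_len(dim(images)[3]), function(i) images[, , i]))
  stop("expected a list of matrices or an H x W x N array")
}
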