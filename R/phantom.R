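#' Specification of the synthetic T2-like phantom dataset
#'
#' Describes the generator that stands in for the restricted clinical
#' cohort: axial-T2-like slices with an elliptical head mask, smooth
#' background structure, a single tumor blob whose texture is
#' class-conditional, compressed global contrast (so adaptive equalization
#' is non-trivial) and additive noise. Class 0 emulates a homogeneous,
#' sharply-margined hyperintense lesion; class 1 a heterogeneous lesion with
#' an irregular, fuzzy margin and lower mean intensity.
#'
#' @param size Image side in pixels (default 32, matching the desk-scale
#'   network input).
#' @param n_per_class Images per class (default 300, i.e. 600 total).
#' @param tumor_mean Per-class within-tumor mean intensity.
#' @param tumor_sd Per-class within-tumor texture standard deviation
#'   (heterogeneity amplitude).
#' @param margin_width Per-class margin softness as a fraction of the image
#'   half-size (small = sharp edge).
#' @param margin_irregularity Per-class amplitude of the angular margin
#'   perturbation.
#' @param heterogeneity_scale Per-class smoothing sigma (pixels) of the
#'   tumor texture field; larger = coarser blotches.
#' @param tumor_radius Range of tumor radius as a fraction of the half-size.
#' @param contrast_compression Factor < 1 compressing global contrast
#'   around mid-gray (default 0.45).
#' @param noise_sigma Additive Gaussian noise level (default 0.02). Set
#'   `noise = "rician"` for magnitude-MRI Rician noise instead.
#' @param noise Noise model, `"gaussian"` (default) or `"rician"`.
#' @param n_classes Number of classes (fixed at 2).
#' @param seed Integer seed; a fixed seed yields an identical dataset.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 32L, n_per_class = 300L,
                         tumor_mean = c(0.90, 0.62),
                         tumor_sd = c(0.01, 0.08),
                         margin_width = c(0.015, 0.12),
                         margin_irregularity = c(0.03, 0.30),
                         heterogeneity_scale = c(0.8, 1.8),
                         tumor_radius = c(0.22, 0.38),
                         contrast_compression = 0.45,
                         noise_sigma = 0.02,
                         noise = c("gaussian", "rician"),
                         n_classes = 2L, seed = 42L) {
  noise <- match.arg(noise)
  if (n_classes != 2L) stop("phantom_spec: only two classes are supported")
  stopifnot(size >= 16L, n_per_class >= 1L)
  structure(list(size = as.integer(size), n_per_class = as.integer(n_per_class),
                 tumor_mean = tumor_mean, tumor_sd = tumor_sd,
                 margin_width = margin_width,
                 margin_irregularity = margin_irregularity,
                 heterogeneity_scale = heterogeneity_scale,
                 tumor_radius = tumor_radius,
                 contrast_compression = contrast_compression,
                 noise_sigma = noise_sigma, noise = noise,
                 n_classes = n_classes, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth random field, normalized to unit standard deviation so amplitude
# parameters mean what they say regardless of the smoothing scale.
smooth_field <- function(size, sigma) {
  f <- gaussian_blur(matrix(stats::rnorm(size * size), size, size), sigma)
  s <- stats::sd(f)
  if (s < 1e-12) return(f * 0)
  f / s
}

#' Generate a single phantom slice
#'
#' Uses the ambient RNG (seed before calling, or use [make_dataset()]).
#'
#' @param spec A [phantom_spec()].
#' @param class_idx Class label, 0 or 1.
#' @return List of class `phantom_image`: `raster` (matrix in \[0,1\]),
#'   `label`, and `tumor_mask` (logical matrix, ground truth for feature
#'   oracles).
#' @export
make_phantom <- function(spec, class_idx) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!class_idx %in% c(0L, 1L)) stop("make_phantom: invalid class index")
  k <- class_idx + 1L
  n <- spec$size
  ax <- seq(-1, 1, length.out = n)
  X <- matrix(ax, n, n, byrow = TRUE) # column coordinate
  Y <- matrix(ax, n, n)               # row coordinate

  # elliptical head mask with slight random semi-axes
  a <- stats::runif(1, 0.80, 0.92)
  b <- stats::runif(1, 0.68, 0.80)
  head <- (X / a)^2 + (Y / b)^2 <= 1

  # smooth background structure around mid-gray tissue intensity
  bg <- 0.5 + 0.02 * smooth_field(n, n / 8) +
    0.01 * smooth_field(n, n / 16)

  # tumor geometry: center inside the head, irregular class-1 margin
  ct <- stats::runif(2, -0.35, 0.35)
  r0 <- stats::runif(1, spec$tumor_radius[1], spec$tumor_radius[2])
  theta <- atan2(Y - ct[1], X - ct[2])
  nharm <- 4L
  amp <- spec$margin_irregularity[k]
  pert <- rep(0, length(theta))
  for (h in seq_len(nharm)) {
    pert <- pert + stats::rnorm(1, 0, amp / nharm) * cos(h * theta) +
      stats::rnorm(1, 0, amp / nharm) * sin(h * theta)
  }
  r_theta <- r0 * (1 + matrix(pert, n, n))
  dist <- sqrt((X - ct[2])^2 + (Y - ct[1])^2)
  # soft margin: 1 inside, 0 outside, transition width per class
  mw <- max(spec$margin_width[k], 1e-3)
  margin <- 1 / (1 + exp((dist - r_theta) / mw))

  # class-conditional tumor texture
  tex <- spec$tumor_mean[k] +
    spec$tumor_sd[k] * smooth_field(n, spec$heterogeneity_scale[k])

  img <- bg * (1 - margin) + tex * margin
  img[!head] <- 0.05

  # compress global contrast so adaptive equalization has work to do
  img <- 0.5 + (img - 0.5) * spec$contrast_compression
  img[!head] <- img[!head] * 0.3

  if (spec$noise_sigma > 0) {
    if (spec$noise == "gaussian") {
      img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sigma), n, n)
    } else {
      img <- sqrt((img + stats::rnorm(n * n, 0, spec$noise_sigma))^2 +
                    stats::rnorm(n * n, 0, spec$noise_sigma)^2)
    }
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(raster = img, label = as.integer(class_idx),
                 tumor_mask = margin > 0.5 & head),
            class = "phantom_image")
}

#' Generate a seeded phantom dataset
#'
#' Produces `2 * n_per_class` phantoms with unique patient identifiers (one
#' image per synthetic patient), balanced classes, and an initially empty
#' `split` column in the manifest. Optionally writes the images and a
#' `manifest.csv` (columns `path,patient_id,label,split`) to `dir`.
#'
#' @param spec A [phantom_spec()].
#' @param dir Optional output directory; images are written as ASCII PGM
#'   (or PNG when `format = "png"` and the png package is available).
#' @param format On-disk image format, `"pgm"` (plain text, default) or
#'   `"png"`.
#' @return List of class `phantom_dataset`: `images` (H x W x N array),
#'   `manifest` (data frame), `masks` (list of logical matrices), `spec`.
#' @examples
#' ds <- make_dataset(phantom_spec(n_per_class = 5, seed = 1))
#' dim(ds$images)
#' @export
make_dataset <- function(spec, dir = NULL, format = c("pgm", "png")) {
  stopifnot(inherits(spec, "phantom_spec"))
  format <- match.arg(format)
  set.seed(spec$seed)
  ntot <- 2L * spec$n_per_class
  labels <- rep(c(0L, 1L), spec$n_per_class)
  images <- array(0, c(spec$size, spec$size, ntot))
  masks <- vector("list", ntot)
  for (i in seq_len(ntot)) {
    ph <- make_phantom(spec, labels[i])
    images[, , i] <- ph$raster
    masks[[i]] <- ph$tumor_mask
  }
  patient_id <- sprintf("SYN%04d", seq_len(ntot))
  path <- rep(NA_character_, ntot)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ext <- if (format == "png") ".png" else ".pgm"
    path <- file.path(dir, paste0(patient_id, ext))
    for (i in seq_len(ntot)) {
      if (format == "png") write_png_gray(images[, , i], path[i])
      else write_pgm(images[, , i], path[i])
    }
  }
  manifest <- data.frame(path = path, patient_id = patient_id,
                         label = labels, split = NA_character_,
                         stringsAsFactors = FALSE)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  structure(list(images = images, manifest = manifest, masks = masks,
                 spec = spec),
            class = "phantom_dataset")
}

#' Hand-crafted texture features of a phantom
#'
#' Two features sufficient to separate the default phantom classes: the
#' intensity variance over the eroded tumor interior (heterogeneity; the
#' interior is used so margin-blend pixels do not swamp the texture signal)
#' and the mean gradient magnitude over the tumor margin band (margin
#' sharpness).
#'
#' @param raster Image matrix.
#' @param mask Logical tumor mask.
#' @return Named numeric vector `c(tumor_var, margin_grad)`.
#' @export
phantom_features <- function(raster, mask) {
  interior <- !binary_dilate(!mask) # one-pixel erosion
  interior2 <- !binary_dilate(!interior)
  if (sum(interior2) >= 9) interior <- interior2
  if (sum(interior) < 4) interior <- mask
  tv <- stats::var(raster[interior])
  gx <- raster[, c(2:ncol(raster), ncol(raster))] - raster
  gy <- raster[c(2:nrow(raster), nrow(raster)), ] - raster
  gm <- sqrt(gx^2 + gy^2)
  # margin band: mask dilated minus eroded (3x3 structuring element)
  dil <- binary_dilate(mask)
  ero <- !binary_dilate(!mask)
  band <- dil & !ero
  mg <- if (any(band)) mean(gm[band]) else 0
  c(tumor_var = tv, margin_grad = mg)
}

binary_dilate <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-H, ]
  out[-H, ] <- out[-H, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -W]
  out[, -W] <- out[, -W] | m[, -1]
  out
}

#' Subset an image container (array or list) by sample index
#'
#' @param images H x W x N array or list of matrices.
#' @param idx Integer indices of the samples to keep.
#' @return Container of the same kind holding the selected images.
#' @export
subset_images <- function(images, idx) {
  if (is.list(images)) images[idx] else images[, , idx, drop = FALSE]
}

#' Apply a split assignment to a dataset manifest
#'
#' @param data A `phantom_dataset`.
#' @param assignment A `split_assignment` from [stratified_split()].
#' @return The dataset with the manifest `split` column filled in.
#' @export
apply_split <- function(data, assignment) {
  m <- match(data$manifest$patient_id, assignment$patient_id)
  if (anyNA(m)) stop("apply_split: assignment is missing some patients")
  data$manifest$split <- assignment$split[m]
  data
}
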