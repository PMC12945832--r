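#' Read and write grayscale images
#'
#' Plain-text ASCII PGM (P2) is the always-available on-disk format for the
#' synthetic phantoms and test fixtures; 8/16-bit grayscale PNG is supported
#' when the png package is installed. Intensities are stored as integers in
#' `0..maxval` and read back into \[0,1\].
#'
#' @param image Numeric matrix in \[0,1\].
#' @param path Output file path.
#' @param maxval Maximum gray value (255 for 8-bit, 65535 for 16-bit).
#' @return `write_*` return `path` invisibly; `read_image` returns a matrix
#'   in \[0,1\].
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  q <- round(pmin(pmax(image, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  # one image row per line
  writeLines(apply(q, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("read_pgm: only plain (P2) PGM is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("read_pgm: truncated pixel data")
  matrix(vals, h, w, byrow = TRUE) / maxval
}

#' @rdname write_pgm
#' @export
write_png_gray <- function(image, path, maxval = 255L) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("write_png_gray: the png package is not installed; use write_pgm()")
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("read_image: the png package is not installed")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(img)
  }
  stop("read_image: unsupported extension '", ext, "'")
}

#' Read a dataset from a directory with a manifest
#'
#' Expects `manifest.csv` with columns `path,patient_id,label,split` and
#' loadable grayscale images of a common size.
#'
#' @param dir Directory produced by [make_dataset()] (or hand-assembled).
#' @return A `phantom_dataset`-shaped list with `images` and `manifest`.
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  need <- c("path", "patient_id", "label", "split")
  if (!all(need %in% names(manifest)))
    stop("read_dataset: manifest must have columns ",
         paste(need, collapse = ","))
  imgs <- lapply(manifest$path, read_image)
  sz <- dim(imgs[[1]])
  images <- array(0, c(sz[1], sz[2], length(imgs)))
  for (i in seq_along(imgs)) images[, , i] <- imgs[[i]]
  structure(list(images = images, manifest = manifest, masks = NULL,
                 spec = NULL),
            class = "phantom_dataset")
}
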