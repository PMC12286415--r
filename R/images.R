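# Small image utilities shared across modules.  Tiles are H x W x 3 numeric
# arrays; pixel values are 8-bit intensities 0..255 unless a function says
# otherwise ("unit scale" = 0..1).

#' Convert an RGB tile to grayscale
#'
#' Applies the fixed luminance convention 0.299 R + 0.587 G + 0.114 B.
#' Grayscale tiles (2-D) pass through unchanged.
#'
#' @param pixels numeric array, `H x W x 3` (or an `H x W` matrix).
#' @return `H x W` numeric matrix on the same intensity scale as the input.
#' @export
rgb_to_gray <- function(pixels) {
  if (is.matrix(pixels)) return(pixels)
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

#' Downscale an image by integer-factor area averaging
#'
#' Each output pixel is the mean of a `factor x factor` block of input
#' pixels, the exact block-average reduction used to bring full-resolution
#' tiles down to the encoder's input side.
#'
#' @param pixels `H x W x C` array or `H x W` matrix; `H`, `W` divisible by
#'   `factor`.
#' @param factor positive integer reduction factor.
#' @return array of dimension `(H/factor) x (W/factor) x C`.
#' @export
downscale_area <- function(pixels, factor) {
  stopifnot(factor >= 1, factor == as.integer(factor))
  if (factor == 1) return(pixels)
  d2 <- FALSE
  if (is.matrix(pixels)) {
    pixels <- array(pixels, c(dim(pixels), 1L))
    d2 <- TRUE
  }
  d <- dim(pixels)
  stopifnot(d[1] %% factor == 0, d[2] %% factor == 0)
  oh <- d[1] %/% factor
  ow <- d[2] %/% factor
  # average rows then columns via reshaping (column-major)
  x <- array(pixels, c(factor, oh, d[2], d[3]))
  x <- colMeans(x)                              # oh x W x C
  x <- aperm(x, c(2, 1, 3))                     # W x oh x C
  x <- array(x, c(factor, ow, oh, d[3]))
  x <- colMeans(x)                              # ow x oh x C
  out <- aperm(x, c(2, 1, 3))
  if (d2) out[, , 1] else out
}

#' Bilinear upsampling of a weight grid
#'
#' Resizes a matrix to an arbitrary target size by bilinear interpolation,
#' with grid cells treated as pixel centres (half-pixel alignment).
#'
#' @param grid numeric matrix.
#' @param out_h,out_w target dimensions.
#' @return `out_h x out_w` numeric matrix.
#' @export
upsample_bilinear <- function(grid, out_h, out_w) {
  gh <- nrow(grid)
  gw <- ncol(grid)
  interp_mat <- function(n_out, n_in) {
    # pixel-centre sampling positions in input coordinates
    pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
    pos <- pmin(pmax(pos, 0), n_in - 1)
    lo <- pmin(floor(pos), n_in - 1)
    hi <- pmin(lo + 1, n_in - 1)
    frac <- pos - lo
    A <- matrix(0, n_out, n_in)
    A[cbind(seq_len(n_out), lo + 1)] <- 1 - frac
    A[cbind(seq_len(n_out), hi + 1)] <-
      A[cbind(seq_len(n_out), hi + 1)] + frac
    A
  }
  interp_mat(out_h, gh) %*% grid %*% t(interp_mat(out_w, gw))
}

#' Mean saturation of a tile
#'
#' Mean HSV saturation over all pixels, used by QC to flag over/under-stained
#' tiles.
#'
#' @param pixels `H x W x 3` array, intensities 0..255.
#' @return scalar in `[0, 1]`.
#' @export
mean_saturation <- function(pixels) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(pixels[, , 1]),
    g = as.vector(pixels[, , 2]),
    b = as.vector(pixels[, , 3]),
    maxColorValue = 255
  )
  mean(hsv["s", ])
}

#' Read an image file as an 8-bit RGB array
#'
#' Reads PNG or TIFF into an `H x W x 3` array with intensities 0..255.
#' Grayscale files are expanded to three identical channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return `H x W x 3` numeric array, 0..255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write an 8-bit RGB array to PNG or TIFF
#'
#' @param pixels `H x W x 3` array, 0..255 (clamped).
#' @param path destination path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  img <- pmin(pmax(pixels / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

# Separable Gaussian blur (edge replication); used by fixtures and tests to
# make controlled blurry tiles.
#' Gaussian-blur a tile
#'
#' @param pixels `H x W x 3` array or matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return blurred array of the same shape.
#' @export
gaussian_blur <- function(pixels, sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_mat <- function(m) {
    n <- nrow(m)
    pad <- m[c(pmin(pmax(1, (1 - r):0), n), 1:n, pmin(pmax(1, (n + 1):(n + r)), n)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * pad[(i - 1) + seq_len(n), , drop = FALSE]
    out
  }
  one <- function(m) t(blur_mat(t(blur_mat(m))))
  if (is.matrix(pixels)) return(one(pixels))
  out <- pixels
  for (c in seq_len(dim(pixels)[3])) out[, , c] <- one(pixels[, , c])
  out
}
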