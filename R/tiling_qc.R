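# Tile extraction and quality control.  A slide is addressed at its
# highest-resolution level only; tiles are fixed-size squares on a regular
# grid, and each tile gets entropy / variance / sharpness metrics plus a QC
# label before anything downstream sees it.

#' Open a slide for tiling
#'
#' Wraps an on-disk image (plain TIFF or PNG, treated as a single-level
#' slide) or an in-memory pixel array in a handle carrying the dimensions
#' used for grid generation.  Pyramidal formats are out of scope; the
#' highest-resolution level is the only level addressed.
#'
#' @param x path to a TIFF/PNG file, or an `H x W x 3` pixel array
#'   (intensities 0..255).
#' @return a `slide_handle` with fields `width`, `height`, `n_levels`,
#'   `path`, and (for in-memory slides) `pixels`.
#' @export
slide_handle <- function(x) {
  if (is.character(x)) {
    pixels <- read_image(x)
    path <- x
  } else {
    stopifnot(is.array(x), length(dim(x)) == 3L)
    pixels <- x
    path <- NA_character_
  }
  structure(
    list(
      width = dim(pixels)[2],
      height = dim(pixels)[1],
      n_levels = 1L,
      path = path,
      pixels = pixels
    ),
    class = "slide_handle"
  )
}

#' @export
print.slide_handle <- function(x, ...) {
  cat(sprintf(
    "<slide_handle> %d x %d px, %d level(s), source: %s\n",
    x$width, x$height, x$n_levels,
    if (is.na(x$path)) "<memory>" else x$path
  ))
  invisible(x)
}

#' Enumerate the full-tile grid of a slide
#'
#' Returns the (col, row) coordinates of every complete `tile_size`-square
#' tile at the top level, 0-based, origin top-left, row-major order.
#' Partial tiles at the right/bottom edge are dropped: the classifier needs
#' a fixed input size and nothing in the method pads.
#'
#' @param slide a `slide_handle`.
#' @param tile_size tile side in pixels.
#' @return data.frame with integer columns `col`, `row`;
#'   `floor(width/tile_size) * floor(height/tile_size)` rows.
#' @export
tile_grid <- function(slide, tile_size) {
  if (!is.numeric(tile_size) || length(tile_size) != 1L ||
      tile_size < 1 || tile_size != as.integer(tile_size)) {
    stop("tile_size must be a positive integer")
  }
  ncol_t <- slide$width %/% tile_size
  nrow_t <- slide$height %/% tile_size
  if (ncol_t == 0 || nrow_t == 0) {
    return(data.frame(col = integer(0), row = integer(0)))
  }
  data.frame(
    col = rep(seq_len(ncol_t) - 1L, times = nrow_t),
    row = rep(seq_len(nrow_t) - 1L, each = ncol_t)
  )
}

#' Extract one tile's pixels
#'
#' @param slide a `slide_handle`.
#' @param col,row 0-based grid coordinates.
#' @param tile_size tile side in pixels.
#' @return `tile_size x tile_size x 3` array.
#' @export
extract_tile <- function(slide, col, row, tile_size) {
  r0 <- row * tile_size
  c0 <- col * tile_size
  stopifnot(r0 + tile_size <= slide$height, c0 + tile_size <= slide$width)
  slide$pixels[r0 + seq_len(tile_size), c0 + seq_len(tile_size), , drop = FALSE]
}

#' Shannon entropy of a tile's intensity histogram
#'
#' Entropy (log base 2) of the 256-bin grayscale histogram; 0 for a
#' constant tile, 8 for a perfectly uniform intensity distribution.
#' Low entropy marks blank glass.
#'
#' @param pixels RGB array or grayscale matrix, intensities 0..255.
#' @return entropy in bits, in `[0, 8]`.
#' @export
tile_entropy <- function(pixels) {
  if (length(pixels) == 0) stop("empty pixel array")
  g <- round(pmin(pmax(rgb_to_gray(pixels), 0), 255))
  p <- tabulate(as.integer(g) + 1L, nbins = 256L)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Population variance of a tile's grayscale intensities
#'
#' @param pixels RGB array or grayscale matrix, intensities 0..255.
#' @return variance in squared 8-bit intensity units (>= 0).
#' @export
tile_variance <- function(pixels) {
  if (length(pixels) == 0) stop("empty pixel array")
  g <- rgb_to_gray(pixels)
  mean(g^2) - mean(g)^2
}

# 3x3 Laplacian (4-neighbour) response of the interior of a matrix.
laplacian_response <- function(g) {
  n <- nrow(g)
  m <- ncol(g)
  i <- 2:(n - 1)
  j <- 2:(m - 1)
  -4 * g[i, j] + g[i - 1, j] + g[i + 1, j] + g[i, j - 1] + g[i, j + 1]
}

#' Sharpness score: variance of the Laplacian
#'
#' Applies a 3x3 Laplacian kernel to the grayscale tile and returns the
#' population variance of the response over the valid (interior) region.
#' Sharp texture gives large values; blurring lowers the score, so tiles
#' below a threshold are flagged as blurred.
#'
#' @param pixels RGB array or grayscale matrix, at least 3x3.
#' @return non-negative scalar in squared intensity units.
#' @export
blur_score <- function(pixels) {
  g <- rgb_to_gray(pixels)
  if (nrow(g) < 3 || ncol(g) < 3) stop("tile smaller than the 3x3 kernel")
  r <- laplacian_response(g)
  mean(r^2) - mean(r)^2
}

#' Quality-control configuration
#'
#' Thresholds for the keep / white / blur / artifact decision.  The white
#' cutoffs (entropy below `entropy_threshold` bits or variance below
#' `variance_threshold`) separate blank glass from tissue; the blur cutoff
#' applies to the variance-of-Laplacian score; tiles whose mean HSV
#' saturation falls outside `saturation_bounds` are flagged as
#' over/under-stained artifacts.  All values are package defaults chosen to
#' separate the synthetic fixture classes, and are configurable.
#'
#' @param tile_size tile side in pixels (default 2048).
#' @param entropy_threshold bits; default 4.
#' @param variance_threshold squared 8-bit intensity units; default 100.
#' @param blur_threshold squared intensity units; default 100.
#' @param saturation_bounds length-2 fractions, default `c(0.05, 0.95)`.
#' @return a `qc_config` list.
#' @export
qc_config <- function(tile_size = 2048L, entropy_threshold = 4.0,
                      variance_threshold = 100.0, blur_threshold = 100.0,
                      saturation_bounds = c(0.05, 0.95)) {
  stopifnot(
    tile_size > 0,
    entropy_threshold >= 0, variance_threshold >= 0, blur_threshold >= 0,
    length(saturation_bounds) == 2L,
    saturation_bounds[1] <= saturation_bounds[2]
  )
  structure(
    list(
      tile_size = as.integer(tile_size),
      entropy_threshold = entropy_threshold,
      variance_threshold = variance_threshold,
      blur_threshold = blur_threshold,
      saturation_bounds = saturation_bounds
    ),
    class = "qc_config"
  )
}

#' Classify a tile's quality
#'
#' Fixed evaluation order: white (entropy or variance below threshold),
#' then blur (sharpness below threshold), then artifact (mean saturation
#' outside bounds), else keep.  Labels are exhaustive and mutually
#' exclusive.
#'
#' @param entropy,variance,blur,saturation tile metrics, as computed by
#'   [tile_entropy()], [tile_variance()], [blur_score()],
#'   [mean_saturation()].
#' @param cfg a [qc_config()].
#' @return one of `"white"`, `"blur"`, `"artifact"`, `"keep"`.
#' @export
qc_classify <- function(entropy, variance, blur, saturation, cfg = qc_config()) {
  if (entropy < cfg$entropy_threshold || variance < cfg$variance_threshold) {
    return("white")
  }
  if (blur < cfg$blur_threshold) {
    return("blur")
  }
  if (saturation < cfg$saturation_bounds[1] ||
      saturation > cfg$saturation_bounds[2]) {
    return("artifact")
  }
  "keep"
}

#' Tile a slide and build its QC manifest
#'
#' Runs the full tiling + QC pass: enumerates the complete-tile grid,
#' computes entropy, variance, sharpness and saturation per tile, and
#' assigns a QC label with [qc_classify()].
#'
#' @param slide a `slide_handle`.
#' @param cfg a [qc_config()]; `cfg$tile_size` sets the grid.
#' @param slide_id identifier written into the manifest.
#' @param class_labels optional character vector (row-major, one per grid
#'   tile) of truth labels; defaults to `"unknown"`.
#' @return a `tile_manifest` data.frame with columns `slide_id`, `col`,
#'   `row`, `size`, `entropy`, `variance`, `blur_score`, `saturation`,
#'   `qc_label`, `class_label`, `path`.
#' @export
qc_slide <- function(slide, cfg = qc_config(), slide_id = "slide",
                     class_labels = NULL) {
  grid <- tile_grid(slide, cfg$tile_size)
  n <- nrow(grid)
  if (!is.null(class_labels)) stopifnot(length(class_labels) == n)
  man <- data.frame(
    slide_id = rep(slide_id, n),
    col = grid$col,
    row = grid$row,
    size = rep(cfg$tile_size, n),
    entropy = numeric(n),
    variance = numeric(n),
    blur_score = numeric(n),
    saturation = numeric(n),
    qc_label = character(n),
    class_label = if (is.null(class_labels)) rep("unknown", n) else class_labels,
    path = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    px <- extract_tile(slide, grid$col[i], grid$row[i], cfg$tile_size)
    man$entropy[i] <- tile_entropy(px)
    man$variance[i] <- tile_variance(px)
    man$blur_score[i] <- blur_score(px)
    man$saturation[i] <- mean_saturation(px)
    man$qc_label[i] <- qc_classify(
      man$entropy[i], man$variance[i], man$blur_score[i], man$saturation[i], cfg
    )
  }
  class(man) <- c("tile_manifest", "data.frame")
  man
}

#' Write / read a tile manifest CSV
#'
#' The manifest schema is the package's interchange format between tiling,
#' training and the slide pipeline.
#'
#' @param manifest a `tile_manifest` data.frame.
#' @param path CSV destination.
#' @return `path` (write) or the manifest (read).
#' @export
write_tile_manifest <- function(manifest, path) {
  write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tile_manifest
#' @export
read_tile_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  class(man) <- c("tile_manifest", "data.frame")
  man
}
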