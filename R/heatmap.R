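# Attention heatmaps: per-token attention weights averaged over the three
# units and all queries, mapped back onto the patch grid, bilinearly
# upsampled to tile resolution and min-max normalised.

#' Compute an attention heatmap for a tile
#'
#' Runs the attention branch on the tile's feature grid, averages the
#' attention weight each patch token receives over the three units and all
#' latent queries, reshapes the result to the patch grid, upsamples it
#' bilinearly to `out_side`, and min-max normalises to `[0, 1]`.  A
#' constant map (uniform attention) is rendered at 0.5 everywhere.
#'
#' @param model a trained `tile_classifier`.
#' @param features `side x side x C` feature grid fed to the model (the
#'   encoder latent view or a downscaled tile).
#' @param out_side side of the upsampled map in pixels (default: the
#'   feature side).
#' @return a `heatmap` list with `grid` (patch-grid weight matrix),
#'   `upsampled` (`out_side` square matrix in `[0, 1]`), `out_side`.
#' @export
compute_heatmap <- function(model, features, out_side = dim(features)[1]) {
  stopifnot(inherits(model, "tile_classifier"))
  if (!isTRUE(model$trained)) {
    stop("model is untrained; train it before computing heatmaps")
  }
  cfg <- model$cfg
  cc <- attention_forward_sample(cfg, model$params, features)
  # mean weight per token over units and queries
  w <- Reduce(`+`, lapply(cc$outs, function(o) colMeans(o$A))) / 3
  g <- cfg$input_side %/% cfg$patch_size
  # token t = (gi-1)*g + gj (row-major patch grid)
  grid <- matrix(w, g, g, byrow = TRUE)
  up <- upsample_bilinear(grid, out_side, out_side)
  structure(
    list(grid = grid, upsampled = normalize_map(up), out_side = out_side),
    class = "heatmap"
  )
}

#' Min-max normalise a heatmap matrix
#'
#' Rescales to `[0, 1]`; a constant matrix maps to 0.5 everywhere.  The
#' operation is idempotent.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_map <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) {
    return(matrix(0.5, nrow(m), ncol(m)))
  }
  (m - rng[1]) / diff(rng)
}

#' Render a heatmap as an RGB overlay
#'
#' Blends a red-emphasis colormap of the attention map over the grayscale
#' tile.  The stored heatmap grid is not modified.
#'
#' @param heatmap a `heatmap` object.
#' @param pixels the source tile (RGB array, 0..255), sized `out_side`.
#' @param alpha blend weight of the colormap (default 0.5).
#' @return RGB array (0..255) of the overlay.
#' @export
heatmap_overlay <- function(heatmap, pixels, alpha = 0.5) {
  h <- heatmap$upsampled
  stopifnot(all(dim(h) == dim(pixels)[1:2]))
  gray <- rgb_to_gray(pixels)
  # red-emphasis map: low weight -> dark blue, high weight -> red
  r <- 255 * pmin(1, 2 * h)
  b <- 255 * pmin(1, 2 * (1 - h))
  g <- 255 * pmax(0, 1 - 2 * abs(h - 0.5))
  out <- array(0, c(dim(h), 3))
  out[, , 1] <- (1 - alpha) * gray + alpha * r
  out[, , 2] <- (1 - alpha) * gray + alpha * g
  out[, , 3] <- (1 - alpha) * gray + alpha * b
  out
}

#' Write a heatmap overlay PNG and/or the raw map as 32-bit TIFF
#'
#' @param heatmap a `heatmap` object.
#' @param pixels source tile for the overlay.
#' @param png_path overlay destination (`NULL` to skip).
#' @param tiff_path raw float map destination (`NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_heatmap <- function(heatmap, pixels, png_path = NULL,
                          tiff_path = NULL) {
  if (!is.null(png_path)) {
    write_image(heatmap_overlay(heatmap, pixels), png_path)
  }
  if (!is.null(tiff_path)) {
    tiff::writeTIFF(heatmap$upsampled, tiff_path, bits.per.sample = 32L,
                    reduce = TRUE)
  }
  invisible(c(png_path, tiff_path))
}
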