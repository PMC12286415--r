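# Seeded synthetic tiles and mosaic slides.  The two tissue classes are
# texture-separable stand-ins for the histology the classifier must learn:
# "recurrent-like" tiles carry a dark horizontal band filled with periodic
# vertical stripes (the corrugation/hyalinization analog) on a pink
# H&E-like background; "non-recurrent-like" tiles are the smooth pink
# background alone.  No histological realism is claimed.

# run code under a temporary RNG state so fixture generation never
# perturbs the caller's random stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of one synthetic tile
#'
#' @param tile_size tile side in pixels.
#' @param class_label `"recurrent"`, `"non_recurrent"` or `"white"`.
#' @param stripe_period stripe period in pixels (>= 2); default
#'   `tile_size / 16`.
#' @param band_fraction fraction of tile height covered by the dark band
#'   (default 0.35).
#' @param noise_sd Gaussian pixel noise standard deviation in 8-bit
#'   intensity units (default 4).
#' @param seed integer RNG seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(tile_size = 2048L,
                         class_label = c("recurrent", "non_recurrent", "white"),
                         stripe_period = max(2L, tile_size %/% 16L),
                         band_fraction = 0.35,
                         noise_sd = 4,
                         seed = 1L) {
  class_label <- match.arg(class_label)
  stopifnot(
    tile_size >= 4, stripe_period >= 2,
    band_fraction >= 0, band_fraction <= 1, noise_sd >= 0
  )
  structure(
    list(
      tile_size = as.integer(tile_size),
      class_label = class_label,
      stripe_period = as.integer(stripe_period),
      band_fraction = band_fraction,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

# Noise-free class template (8-bit RGB) for a given band placement and
# stripe phase.
fixture_template <- function(spec, band_r0 = NULL, phase = 0L) {
  s <- spec$tile_size
  if (spec$class_label == "white") {
    return(array(245, c(s, s, 3)))
  }
  # pink background with a vertical intensity gradient (+-25 top to bottom)
  base <- c(230, 180, 200)
  grad <- seq(-25, 25, length.out = s)
  px <- array(0, c(s, s, 3))
  for (ch in 1:3) px[, , ch] <- base[ch] + grad
  if (spec$class_label == "recurrent") {
    bh <- round(spec$band_fraction * s)
    if (bh > 0) {
      if (is.null(band_r0)) band_r0 <- floor((s - bh) / 2) + 1L
      rows <- band_r0:(band_r0 + bh - 1L)
      # dark band, with square-wave stripes along x inside it
      half <- max(1L, spec$stripe_period %/% 2L)
      stripe <- (((seq_len(s) - 1L + phase) %/% half) %% 2L) == 0L
      for (ch in 1:3) {
        band <- px[rows, , ch] - 50
        band[, stripe] <- band[, stripe] - 60
        px[rows, , ch] <- band
      }
    }
  }
  px
}

#' Generate a synthetic tile
#'
#' Renders the class template for `spec` — with the band's vertical
#' placement and the stripe phase drawn from the seed so recurrent-like
#' tiles differ in where the discriminative texture sits — adds seeded
#' Gaussian pixel noise of standard deviation `noise_sd`, and clamps/rounds
#' to 8-bit integers.  Identical specs give byte-identical tiles.
#'
#' @param spec a [fixture_spec()].
#' @return list with `pixels` (`tile_size` square RGB array, 0..255),
#'   `class_label`, and `band_mask` (logical matrix marking the stripe-band
#'   rows; all `FALSE` for non-recurrent and white tiles).
#' @export
make_tile <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  s <- spec$tile_size
  bh <- round(spec$band_fraction * s)
  out <- with_seed(spec$seed, {
    band_r0 <- if (bh > 0 && bh < s) sample.int(s - bh + 1L, 1L) else 1L
    phase <- sample.int(spec$stripe_period, 1L) - 1L
    px <- fixture_template(spec, band_r0 = band_r0, phase = phase)
    if (spec$noise_sd > 0) px <- px + rnorm(length(px), sd = spec$noise_sd)
    list(px = px, band_r0 = band_r0)
  })
  px <- round(pmin(pmax(out$px, 0), 255))
  band_mask <- matrix(FALSE, s, s)
  if (spec$class_label == "recurrent" && bh > 0) {
    band_mask[out$band_r0:(out$band_r0 + bh - 1L), ] <- TRUE
  }
  list(pixels = px, class_label = spec$class_label, band_mask = band_mask)
}

#' Specification of a synthetic mosaic slide
#'
#' @param grid_cols,grid_rows tile-grid dimensions.
#' @param recurrent_fraction fraction of *tissue* tiles that are
#'   recurrent-like, in `[0, 1]`.
#' @param n_white_tiles number of near-uniform white tiles.
#' @param tile_size tile side in pixels.
#' @param noise_sd pixel noise passed to every tile.
#' @param seed integer RNG seed (placement and per-tile noise).
#' @return a `synthetic_slide_spec` list.
#' @export
synthetic_slide_spec <- function(grid_cols, grid_rows, recurrent_fraction,
                                 n_white_tiles = 0L, tile_size = 2048L,
                                 noise_sd = 4, seed = 1L) {
  n_tiles <- grid_cols * grid_rows
  if (n_white_tiles > n_tiles) {
    stop("n_white_tiles exceeds the number of grid positions")
  }
  stopifnot(recurrent_fraction >= 0, recurrent_fraction <= 1,
            grid_cols >= 1, grid_rows >= 1)
  structure(
    list(
      grid_cols = as.integer(grid_cols),
      grid_rows = as.integer(grid_rows),
      recurrent_fraction = recurrent_fraction,
      n_white_tiles = as.integer(n_white_tiles),
      tile_size = as.integer(tile_size),
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_slide_spec"
  )
}

# derive a per-tile seed from the slide seed; kept under 2^31
tile_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + 104729 * i) %% 2147483629)
}

#' Generate a synthetic mosaic slide with truth manifest
#'
#' Lays out `grid_cols x grid_rows` tiles: `n_white_tiles` near-uniform
#' white tiles at seeded random positions, and among the remaining tissue
#' tiles exactly `round(recurrent_fraction * n_tissue)` recurrent-like
#' ones, the rest non-recurrent-like.  The truth manifest uses the tile
#' manifest schema (metrics columns left `NA`).
#'
#' @param spec a [synthetic_slide_spec()].
#' @param slide_id identifier written into the manifest.
#' @return list with `pixels` (mosaic RGB array), `manifest` (truth
#'   manifest data.frame), and `spec`.
#' @export
make_slide <- function(spec, slide_id = "synthetic_slide") {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  n_tiles <- spec$grid_cols * spec$grid_rows
  n_tissue <- n_tiles - spec$n_white_tiles
  n_rec <- round(spec$recurrent_fraction * n_tissue)
  labels <- with_seed(spec$seed, {
    lab <- rep("non_recurrent", n_tiles)
    pos <- sample.int(n_tiles)
    if (spec$n_white_tiles > 0) {
      lab[pos[seq_len(spec$n_white_tiles)]] <- "white"
    }
    if (n_rec > 0) {
      lab[pos[spec$n_white_tiles + seq_len(n_rec)]] <- "recurrent"
    }
    lab
  })
  s <- spec$tile_size
  mosaic <- array(0, c(spec$grid_rows * s, spec$grid_cols * s, 3))
  grid <- data.frame(
    col = rep(seq_len(spec$grid_cols) - 1L, times = spec$grid_rows),
    row = rep(seq_len(spec$grid_rows) - 1L, each = spec$grid_cols)
  )
  for (i in seq_len(n_tiles)) {
    tspec <- fixture_spec(
      tile_size = s, class_label = labels[i],
      noise_sd = if (labels[i] == "white") min(spec$noise_sd, 1) else spec$noise_sd,
      seed = tile_seed(spec$seed, i)
    )
    tile <- make_tile(tspec)
    rr <- grid$row[i] * s + seq_len(s)
    cc <- grid$col[i] * s + seq_len(s)
    mosaic[rr, cc, ] <- tile$pixels
  }
  manifest <- data.frame(
    slide_id = rep(slide_id, n_tiles),
    col = grid$col,
    row = grid$row,
    size = rep(s, n_tiles),
    entropy = NA_real_,
    variance = NA_real_,
    blur_score = NA_real_,
    saturation = NA_real_,
    qc_label = NA_character_,
    class_label = labels,
    path = NA_character_,
    stringsAsFactors = FALSE
  )
  class(manifest) <- c("tile_manifest", "data.frame")
  list(pixels = mosaic, manifest = manifest, spec = spec)
}

#' Generate a labeled set of synthetic tiles
#'
#' Convenience wrapper producing `n_per_class` recurrent-like and
#' non-recurrent-like tiles each, with per-tile seeds derived from `seed`.
#' With a `transform`, each tile is mapped immediately after generation and
#' only the result is kept, so a full-resolution tile set can be turned
#' into (for example) encoder features without ever holding all raw pixel
#' arrays in memory.
#'
#' @param n_per_class tiles per class.
#' @param tile_size tile side in pixels.
#' @param noise_sd pixel noise standard deviation.
#' @param seed integer RNG seed.
#' @param transform optional function applied to each tile's pixel array;
#'   its return value is stored in place of the pixels.
#' @return list with `tiles` (list of RGB arrays, or of `transform`
#'   results) and `labels` (character vector).
#' @export
make_tile_set <- function(n_per_class, tile_size = 512L, noise_sd = 4,
                          seed = 1L, transform = NULL) {
  n <- 2L * n_per_class
  labels <- rep(c("recurrent", "non_recurrent"), each = n_per_class)
  tiles <- vector("list", n)
  for (i in seq_len(n)) {
    px <- make_tile(fixture_spec(
      tile_size = tile_size, class_label = labels[i],
      noise_sd = noise_sd, seed = tile_seed(seed, i)
    ))$pixels
    tiles[[i]] <- if (is.null(transform)) px else transform(px)
  }
  list(tiles = tiles, labels = labels)
}
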