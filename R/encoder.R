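# Unsupervised tile encoder.  A three-stage strided convolutional
# autoencoder maps a 512 x 512 x 3 scaled tile (flattened length 786,432)
# to a 12,288-element bottleneck, viewable as a 64 x 64 x 3 grid — a x64
# dimensionality reduction.  The bottleneck uses a sigmoid so latent values
# live on the same [0, 1] scale as image intensities, which keeps the
# classifier's two input modes (encoder bottleneck vs downscaled tile)
# interchangeable.

#' Encoder configuration
#'
#' The geometry is fixed by the two printed lengths: flattened input
#' `input_side^2 * input_channels = 786,432` and bottleneck
#' `12,288 = 64 x 64 x 3`, i.e. three stride-2 stages from side 512 to
#' side 64, ending in 3 channels.  Intermediate channel widths are
#' configurable.
#'
#' @param input_side input side in pixels (512).
#' @param input_channels input channels (3).
#' @param n_stages number of stride-2 encode stages (3).
#' @param bottleneck_len bottleneck length (12,288).
#' @param stage_channels channel widths after each encode stage; the last
#'   must be 3.
#' @param seed integer seed for weight initialisation.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(input_side = 512L, input_channels = 3L,
                           n_stages = 3L, bottleneck_len = 12288L,
                           stage_channels = c(16L, 8L, 3L), seed = 1L) {
  if (input_side^2 * input_channels != 786432) {
    stop("invalid config: flattened input length must be 786,432 ",
         "(side 512, 3 channels)")
  }
  if (n_stages != 3L || length(stage_channels) != 3L) {
    stop("invalid config: the encoder has exactly three stages")
  }
  side_out <- input_side / 2^n_stages
  if (bottleneck_len != side_out^2 * stage_channels[n_stages] ||
      bottleneck_len != 12288) {
    stop("invalid config: bottleneck length must be 12,288 (64 x 64 x 3)")
  }
  structure(
    list(
      input_side = as.integer(input_side),
      input_channels = as.integer(input_channels),
      n_stages = as.integer(n_stages),
      bottleneck_len = as.integer(bottleneck_len),
      stage_channels = as.integer(stage_channels),
      seed = as.integer(seed)
    ),
    class = "encoder_config"
  )
}

#' Build an (untrained) tile encoder
#'
#' Initialises the autoencoder weights and reports the fixed dimensions:
#' flattened input length 786,432, bottleneck length 12,288, compression
#' ratio 64.
#'
#' @param cfg an [encoder_config()].
#' @return a `tile_encoder` with fields `cfg`, `params`, `report`,
#'   `trained`.
#' @export
build_encoder <- function(cfg = encoder_config()) {
  stopifnot(inherits(cfg, "encoder_config"))
  ch <- c(cfg$input_channels, cfg$stage_channels)
  params <- with_seed(cfg$seed, {
    p <- list()
    for (i in 1:3) {
      p[[paste0("We", i)]] <- init_conv(3, 3, ch[i], ch[i + 1])
      p[[paste0("be", i)]] <- numeric(ch[i + 1])
    }
    dch <- rev(ch)  # 3, 8, 16, 3
    for (i in 1:3) {
      p[[paste0("Wd", i)]] <- init_conv(3, 3, dch[i], dch[i + 1])
      p[[paste0("bd", i)]] <- numeric(dch[i + 1])
    }
    p
  })
  structure(
    list(
      cfg = cfg,
      params = params,
      report = list(
        input_flat_len = cfg$input_side^2 * cfg$input_channels,
        bottleneck_len = cfg$bottleneck_len,
        compression_ratio = cfg$input_side^2 * cfg$input_channels /
          cfg$bottleneck_len
      ),
      trained = FALSE
    ),
    class = "tile_encoder"
  )
}

#' @export
print.tile_encoder <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<tile_encoder> %s\n  input : %d x %d x %d (flattened %s)\n",
      "  bottleneck : %s (64 x 64 x 3), compression x%d\n"
    ),
    if (x$trained) "trained" else "untrained",
    x$cfg$input_side, x$cfg$input_side, x$cfg$input_channels,
    format(x$report$input_flat_len, big.mark = ","),
    format(x$report$bottleneck_len, big.mark = ","),
    as.integer(x$report$compression_ratio)
  ))
  invisible(x)
}

# forward through the three encode stages; x4d in [0,1], dims (S,S,3,N).
# Returns activations needed for backprop when cache = TRUE.
encoder_forward <- function(params, x4d, cache = FALSE) {
  z1 <- cpp_conv2d_fwd(x4d, params$We1, params$be1, 2L, 1L)
  a1 <- gelu(z1)
  z2 <- cpp_conv2d_fwd(a1, params$We2, params$be2, 2L, 1L)
  a2 <- gelu(z2)
  z3 <- cpp_conv2d_fwd(a2, params$We3, params$be3, 2L, 1L)
  a3 <- sigmoid(z3)
  dim(a3) <- dim(z3)
  if (cache) list(z1 = z1, a1 = a1, z2 = z2, a2 = a2, z3 = z3, a3 = a3)
  else a3
}

decoder_forward <- function(params, z, cache = FALSE) {
  u1 <- cpp_upsample2_fwd(z)
  d1 <- cpp_conv2d_fwd(u1, params$Wd1, params$bd1, 1L, 1L)
  a1 <- gelu(d1)
  u2 <- cpp_upsample2_fwd(a1)
  d2 <- cpp_conv2d_fwd(u2, params$Wd2, params$bd2, 1L, 1L)
  a2 <- gelu(d2)
  u3 <- cpp_upsample2_fwd(a2)
  d3 <- cpp_conv2d_fwd(u3, params$Wd3, params$bd3, 1L, 1L)
  a3 <- sigmoid(d3)
  dim(a3) <- dim(d3)
  if (cache) {
    list(u1 = u1, d1 = d1, a1 = a1, u2 = u2, d2 = d2, a2 = a2,
         u3 = u3, d3 = d3, a3 = a3)
  } else {
    a3
  }
}

# scale integer tiles 0..255 to the unit interval; pass through if already
# scaled
scale_unit <- function(pixels) {
  if (max(pixels) > 1.5) pixels / 255 else pixels
}

# stack a list of H x W x 3 tiles into a (H,W,3,N) batch array
stack_tiles <- function(tiles) {
  d <- dim(tiles[[1]])
  out <- array(0, c(d, length(tiles)))
  for (i in seq_along(tiles)) out[, , , i] <- tiles[[i]]
  out
}

#' Encode a tile to its latent feature
#'
#' Runs the encoder half only.  The result is the 12,288-element bottleneck
#' vector together with its 64 x 64 x 3 grid view (a pure reshape of the
#' same numbers).
#'
#' @param encoder a `tile_encoder`.
#' @param tile `512 x 512 x 3` array, intensities in `[0, 1]` (0..255
#'   accepted and rescaled).
#' @return a `latent_feature` with fields `values` (length 12,288) and
#'   `grid_view` (`64 x 64 x 3`).
#' @export
encode_tile <- function(encoder, tile) {
  stopifnot(inherits(encoder, "tile_encoder"))
  d <- dim(tile)
  if (length(d) != 3L || d[1] != encoder$cfg$input_side ||
      d[2] != encoder$cfg$input_side || d[3] != encoder$cfg$input_channels) {
    stop("tile must be ", encoder$cfg$input_side, " x ",
         encoder$cfg$input_side, " x ", encoder$cfg$input_channels)
  }
  x <- array(scale_unit(tile), c(d, 1L))
  z <- encoder_forward(encoder$params, x)
  grid <- array(z[, , , 1], dim(z)[1:3])
  structure(
    list(values = as.vector(grid), grid_view = grid),
    class = "latent_feature"
  )
}

#' Encode a list of tiles
#'
#' @param encoder a `tile_encoder`.
#' @param tiles list of `512 x 512 x 3` arrays.
#' @param batch_size tiles per forward batch.
#' @return list of `64 x 64 x 3` latent grid views.
#' @export
encode_tiles <- function(encoder, tiles, batch_size = 8L) {
  out <- vector("list", length(tiles))
  i <- 1L
  while (i <= length(tiles)) {
    j <- min(i + batch_size - 1L, length(tiles))
    x <- stack_tiles(lapply(tiles[i:j], scale_unit))
    z <- encoder_forward(encoder$params, x)
    for (k in i:j) out[[k]] <- array(z[, , , k - i + 1], dim(z)[1:3])
    i <- j + 1L
  }
  out
}

#' Train the autoencoder by reconstruction
#'
#' Minimises mean-squared reconstruction error through the mirrored decoder
#' with AdamW (learning rate 1e-4, weight decay 0.001 — the same optimiser
#' settings as the classifier).  Training is unsupervised: no labels are
#' used.
#'
#' Because the network is fully convolutional, optimisation runs on random
#' square crops of the tiles (`crop_size`, default 128): gradients on crops
#' estimate the full-tile objective at a fraction of the cost, and the
#' trained weights apply unchanged to full 512-pixel tiles at inference.
#'
#' @param encoder a `tile_encoder` (weights are the starting point).
#' @param tiles list of `512 x 512 x 3` arrays (>= 2).
#' @param epochs number of passes over the tiles.
#' @param batch_size tiles per optimisation step.
#' @param crop_size training crop side in pixels; must be a multiple of 8.
#'   Set to the tile side to train on whole tiles.
#' @param learning_rate Adam learning rate.
#' @param weight_decay decoupled weight decay.
#' @param seed shuffling/cropping seed.
#' @return the encoder with trained weights, `trained = TRUE`, and
#'   `loss_history` (one mean reconstruction MSE per epoch).
#' @export
train_autoencoder <- function(encoder, tiles, epochs = 5L, batch_size = 8L,
                              crop_size = 128L, learning_rate = 1e-4,
                              weight_decay = 0.001, seed = 1L) {
  stopifnot(inherits(encoder, "tile_encoder"))
  if (length(tiles) < 2L) stop("need at least 2 tiles")
  side <- dim(tiles[[1]])[1]
  stopifnot(crop_size %% 8 == 0, crop_size <= side)
  tiles <- lapply(tiles, scale_unit)
  params <- encoder$params
  state <- adam_init(params)
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(tiles))
      ep_loss <- 0
      n_seen <- 0L
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + batch_size - 1L, length(ord))
        x <- stack_tiles(lapply(tiles[ord[i:j]], function(px) {
          if (crop_size == side) return(px)
          r0 <- sample.int(side - crop_size + 1L, 1L) - 1L
          c0 <- sample.int(side - crop_size + 1L, 1L) - 1L
          px[r0 + seq_len(crop_size), c0 + seq_len(crop_size), , drop = FALSE]
        }))
        nb <- j - i + 1L
        enc <- encoder_forward(params, x, cache = TRUE)
        dec <- decoder_forward(params, enc$a3, cache = TRUE)
        err <- dec$a3 - x
        loss <- mean(err^2)
        ep_loss <- ep_loss + loss * nb
        n_seen <- n_seen + nb
        # backward: MSE -> decoder -> bottleneck -> encoder
        g <- list()
        d_a3 <- 2 * err / length(err)
        d_d3 <- d_a3 * dec$a3 * (1 - dec$a3)
        bw <- cpp_conv2d_bwd(dec$u3, params$Wd3, d_d3, 1L, 1L)
        g$Wd3 <- bw$gw; g$bd3 <- bw$gb
        d_a2 <- cpp_upsample2_bwd(bw$gx) * gelu_grad(dec$d2)
        bw <- cpp_conv2d_bwd(dec$u2, params$Wd2, d_a2, 1L, 1L)
        g$Wd2 <- bw$gw; g$bd2 <- bw$gb
        d_a1 <- cpp_upsample2_bwd(bw$gx) * gelu_grad(dec$d1)
        bw <- cpp_conv2d_bwd(dec$u1, params$Wd1, d_a1, 1L, 1L)
        g$Wd1 <- bw$gw; g$bd1 <- bw$gb
        d_z <- cpp_upsample2_bwd(bw$gx)
        d_z3 <- d_z * enc$a3 * (1 - enc$a3)
        bw <- cpp_conv2d_bwd(enc$a2, params$We3, d_z3, 2L, 1L)
        g$We3 <- bw$gw; g$be3 <- bw$gb
        d_z2 <- bw$gx * gelu_grad(enc$z2)
        bw <- cpp_conv2d_bwd(enc$a1, params$We2, d_z2, 2L, 1L)
        g$We2 <- bw$gw; g$be2 <- bw$gb
        d_z1 <- bw$gx * gelu_grad(enc$z1)
        bw <- cpp_conv2d_bwd(x, params$We1, d_z1, 2L, 1L)
        g$We1 <- bw$gw; g$be1 <- bw$gb
        upd <- adam_step(params, g, state, learning_rate, weight_decay)
        params <- upd$params
        state <- upd$state
        i <- j + 1L
      }
      history[ep] <- ep_loss / n_seen
    }
  })
  encoder$params <- params
  encoder$trained <- TRUE
  encoder$loss_history <- history
  encoder
}

#' Reconstruct tiles through the full autoencoder
#'
#' @param encoder a `tile_encoder`.
#' @param tiles list of `512 x 512 x 3` arrays.
#' @return list of reconstructed arrays on the unit scale.
#' @export
reconstruct_tiles <- function(encoder, tiles) {
  x <- stack_tiles(lapply(tiles, scale_unit))
  z <- encoder_forward(encoder$params, x)
  r <- decoder_forward(encoder$params, z)
  lapply(seq_along(tiles), function(i) array(r[, , , i], dim(r)[1:3]))
}

#' Write the autoencoder loss history as CSV
#'
#' @param encoder a trained `tile_encoder`.
#' @param path CSV destination (`epoch,loss`).
#' @return `path`, invisibly.
#' @export
write_loss_history <- function(encoder, path) {
  stopifnot(!is.null(encoder$loss_history))
  write.csv(
    data.frame(epoch = seq_along(encoder$loss_history),
               loss = encoder$loss_history),
    path, row.names = FALSE
  )
  invisible(path)
}
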