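# Shared trained models, built once per test run.
#
# - small_fit(): a reduced-geometry classifier trained on 48x48 direct
#   features for the fast unit tests.
# - study_fit(): the full study-condition fit (512px tiles, encoder
#   bottleneck path, 200 tiles/class, 25 epochs, batch 15) reused by the
#   end-to-end and heatmap tests.

.fit_cache <- new.env(parent = emptyenv())

small_cfg <- function(seed = 7L) {
  classifier_config(
    input_side = 48L, conv_filters = c(4L, 4L, 4L, 4L), patch_size = 16L,
    n_latents = 3L, latent_dim = 5L, proj_dim = 4L, dropout = 0,
    seed = seed
  )
}

small_feature_set <- function(n_per_class, seed) {
  ts <- make_tile_set(n_per_class, tile_size = 96L, noise_sd = 4, seed = seed,
                      transform = function(px) downscale_area(px, 2L) / 255)
  list(features = ts$tiles, labels = ts$labels)
}

small_fit <- function() {
  if (!is.null(.fit_cache$small)) return(.fit_cache$small)
  train <- small_feature_set(30, seed = 101)
  val <- small_feature_set(8, seed = 202)
  model <- build_classifier(small_cfg())
  # the reduced fixture sees far fewer optimiser steps than the study run,
  # so it trains at a larger learning rate
  model <- train_classifier(model, train, val,
                            train_config(learning_rate = 2e-3, epochs = 15,
                                         seed = 7))
  .fit_cache$small <- list(model = model, train = train, val = val)
  .fit_cache$small
}

study_fit <- function(seed = 1L) {
  if (!is.null(.fit_cache$study)) return(.fit_cache$study)
  ae_tiles <- make_tile_set(25, tile_size = 512L, noise_sd = 4,
                            seed = seed + 500)$tiles
  encoder <- build_encoder(encoder_config(seed = seed))
  encoder <- train_autoencoder(encoder, ae_tiles, epochs = 5, seed = seed)
  rm(ae_tiles)
  ts <- make_tile_set(
    200, tile_size = 512L, noise_sd = 4, seed = seed,
    transform = function(px) tile_features(list(px), encoder)[[1]]
  )
  splits <- split_dataset(data.frame(class_label = ts$labels),
                          train_config(seed = seed))
  sets <- lapply(splits, function(s) {
    list(features = ts$tiles[s$.row], labels = ts$labels[s$.row])
  })
  model <- build_classifier(classifier_config(seed = seed))
  model <- train_classifier(model, sets$train, sets$val,
                            train_config(seed = seed))
  .fit_cache$study <- list(encoder = encoder, model = model, sets = sets)
  .fit_cache$study
}
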