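# Synthetic tile and slide generation: determinism, texture structure,
# composition bookkeeping.

test_that("identical specs give byte-identical tiles", {
  spec <- fixture_spec(tile_size = 64, class_label = "recurrent",
                       noise_sd = 6, seed = 42)
  a <- make_tile(spec)
  b <- make_tile(spec)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$band_mask, b$band_mask)
  # a different seed moves the band / noise
  c <- make_tile(fixture_spec(tile_size = 64, class_label = "recurrent",
                              noise_sd = 6, seed = 43))
  expect_false(identical(a$pixels, c$pixels))
})

test_that("recurrent-like tiles have a stripe autocorrelation peak at the period", {
  period <- 8L
  spec <- fixture_spec(tile_size = 64, class_label = "recurrent",
                       stripe_period = period, noise_sd = 0, seed = 5)
  tile <- make_tile(spec)
  # column profile restricted to the band rows carries the square wave
  profile <- colMeans(rgb_to_gray(tile$pixels)[tile$band_mask[, 1], ])
  lags <- 2:20
  ac <- vapply(lags, function(k) oracle_autocorr(profile, k), numeric(1))
  expect_equal(lags[which.max(ac)], period)
  expect_gt(max(ac), 0.8)

  # the smooth class carries no periodic column structure at all: its
  # column profile is flat (the only template variation runs along rows)
  smooth <- make_tile(fixture_spec(tile_size = 64,
                                   class_label = "non_recurrent",
                                   stripe_period = period, noise_sd = 0,
                                   seed = 5))
  prof2 <- colMeans(rgb_to_gray(smooth$pixels))
  expect_lt(var(prof2), 1e-12)
})

test_that("noise-free class templates are variance-separable", {
  rec <- make_tile(fixture_spec(tile_size = 64, class_label = "recurrent",
                                noise_sd = 0, seed = 1))
  non <- make_tile(fixture_spec(tile_size = 64,
                                class_label = "non_recurrent",
                                noise_sd = 0, seed = 1))
  expect_gt(tile_variance(rec$pixels), tile_variance(non$pixels))
})

test_that("slide composition follows the spec exactly", {
  # 12 positions, 2 white -> 10 tissue; fraction 0.3 -> 3 recurrent
  spec <- synthetic_slide_spec(4, 3, 0.3, n_white_tiles = 2, tile_size = 32,
                               seed = 11)
  sl <- make_slide(spec)
  expect_equal(sum(sl$manifest$class_label == "white"), 2)
  expect_equal(sum(sl$manifest$class_label == "recurrent"), 3)
  expect_equal(sum(sl$manifest$class_label == "non_recurrent"), 7)
  expect_equal(dim(sl$pixels), c(3 * 32, 4 * 32, 3))

  # fraction 0 -> no recurrent tiles
  all_non <- make_slide(synthetic_slide_spec(3, 3, 0, tile_size = 32,
                                             seed = 2))
  expect_equal(sum(all_non$manifest$class_label == "recurrent"), 0)

  expect_error(
    synthetic_slide_spec(2, 2, 0.5, n_white_tiles = 5, tile_size = 32),
    "exceeds"
  )
})

test_that("white tiles in a mosaic are exactly the QC-flagged ones", {
  spec <- synthetic_slide_spec(3, 3, 0.5, n_white_tiles = 4, tile_size = 64,
                               noise_sd = 2, seed = 13)
  sl <- make_slide(spec)
  man <- qc_slide(slide_handle(sl$pixels), qc_config(tile_size = 64))
  expect_identical(man$qc_label == "white",
                   sl$manifest$class_label == "white")
})

test_that("make_slide is deterministic and mosaics match re-extracted tiles", {
  spec <- synthetic_slide_spec(2, 2, 0.5, tile_size = 32, seed = 3)
  a <- make_slide(spec)
  b <- make_slide(spec)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$manifest$class_label, b$manifest$class_label)
})

test_that("make_tile_set transform streams per tile", {
  plain <- make_tile_set(3, tile_size = 32, noise_sd = 2, seed = 7)
  summarised <- make_tile_set(3, tile_size = 32, noise_sd = 2, seed = 7,
                              transform = function(px) mean(px))
  expect_equal(unlist(summarised$tiles),
               vapply(plain$tiles, mean, numeric(1)))
  expect_equal(plain$labels,
               rep(c("recurrent", "non_recurrent"), each = 3))
})
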