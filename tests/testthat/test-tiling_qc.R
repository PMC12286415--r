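# Tiling grid, tile metrics and QC labeling.

make_gray_tile <- function(values, side = NULL) {
  if (is.null(side)) side <- sqrt(length(values))
  g <- matrix(values, side, side)
  array(rep(g, 3), c(side, side, 3))
}

test_that("tile grid enumerates exactly the complete tiles, row-major", {
  slide <- slide_handle(array(128, c(4096, 4096, 3) / c(8, 8, 1)))
  # 512 x 512 slide, tile 256 -> 2 x 2
  g <- tile_grid(slide, 256)
  expect_equal(nrow(g), 4)
  expect_equal(g$col, c(0L, 1L, 0L, 1L))
  expect_equal(g$row, c(0L, 0L, 1L, 1L))

  # exact single tile
  one <- tile_grid(slide_handle(array(0, c(256, 256, 3))), 256)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$col, one$row), c(0L, 0L))

  # partial edges dropped: 625 x 513 with tile 256 -> 2 x 2
  part <- tile_grid(slide_handle(array(0, c(513, 625, 3))), 256)
  expect_equal(nrow(part), 4)
  expect_true(all(part$col < 2) && all(part$row < 2))

  # tile larger than the slide -> empty, not an error
  expect_equal(nrow(tile_grid(slide_handle(array(0, c(100, 100, 3))), 256)), 0)
  expect_error(tile_grid(slide, 0), "positive")
})

test_that("tile count matches the floor-division oracle across geometries", {
  set.seed(31)
  for (i in 1:25) {
    w <- sample(1:90, 1)
    h <- sample(1:90, 1)
    s <- sample(1:40, 1)
    slide <- slide_handle(array(0, c(h, w, 3)))
    g <- tile_grid(slide, s)
    expect_equal(nrow(g), oracle_tile_count(w, h, s))
    expect_equal(anyDuplicated(paste(g$col, g$row)), 0)
  }
})

test_that("entropy matches closed-form histogram cases and is in [0, 8]", {
  expect_equal(tile_entropy(make_gray_tile(rep(128, 64 * 64))), 0)
  half <- make_gray_tile(rep(c(0, 255), each = 2048))
  expect_equal(tile_entropy(half), 1)
  four <- make_gray_tile(rep(c(10, 60, 110, 160), each = 1024))
  expect_equal(tile_entropy(four), 2)
  # uniform over all 256 levels -> the 8-bit maximum
  full <- make_gray_tile(rep(0:255, each = 16))
  expect_equal(tile_entropy(full), 8)
  expect_error(tile_entropy(array(0, c(0, 0, 3))), "empty")
})

test_that("variance matches population formulas", {
  expect_equal(tile_variance(make_gray_tile(rep(128, 1024))), 0)
  half <- make_gray_tile(rep(c(0, 255), each = 512))
  expect_equal(tile_variance(half), 127.5^2)  # 16,256.25
  # discrete uniform over 0..255: (256^2 - 1) / 12
  full <- make_gray_tile(rep(0:255, each = 4))
  expect_equal(tile_variance(full), (256^2 - 1) / 12)
  expect_equal((256^2 - 1) / 12, 5461.25)
})

test_that("entropy and variance are invariant under pixel permutation", {
  set.seed(5)
  vals <- sample(0:255, 32 * 32, replace = TRUE)
  tile <- make_gray_tile(vals)
  perm <- make_gray_tile(sample(vals))
  expect_equal(tile_entropy(tile), tile_entropy(perm))
  expect_equal(tile_variance(tile), tile_variance(perm))
})

test_that("blur score matches a direct Laplacian-convolution oracle", {
  expect_equal(blur_score(make_gray_tile(rep(77, 64))), 0)

  # vertical step edge: left half 0, right half 255
  side <- 16
  g <- matrix(0, side, side)
  g[, (side / 2 + 1):side] <- 255
  kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  expected <- oracle_pop_var(oracle_conv3(g, kernel))
  expect_gt(expected, 0)
  expect_equal(blur_score(array(rep(g, 3), c(side, side, 3))), expected)

  expect_error(blur_score(make_gray_tile(rep(1, 4))), "3x3")
})

test_that("Gaussian smoothing strictly lowers the blur score", {
  tile <- make_tile(fixture_spec(tile_size = 64, class_label = "recurrent",
                                 noise_sd = 8, seed = 3))$pixels
  smoothed <- gaussian_blur(tile, sigma = 2)
  expect_lt(blur_score(smoothed), blur_score(tile))
})

test_that("QC labels follow the fixed decision order and are exclusive", {
  cfg <- qc_config(tile_size = 64)
  # entropy 0 -> white, regardless of the other metrics
  expect_identical(qc_classify(0, 5000, 5000, 0.5, cfg), "white")
  # low variance alone -> white
  expect_identical(qc_classify(6, 50, 5000, 0.5, cfg), "white")
  # passes white checks, fails sharpness -> blur
  expect_identical(qc_classify(6, 500, 50, 0.5, cfg), "blur")
  # passes white and blur, saturation out of bounds -> artifact
  expect_identical(qc_classify(6, 500, 500, 0.99, cfg), "artifact")
  expect_identical(qc_classify(6, 500, 500, 0.01, cfg), "artifact")
  # everything in range -> keep
  expect_identical(qc_classify(6, 500, 500, 0.5, cfg), "keep")
})

test_that("constant white tiles always classify white", {
  cfg <- qc_config(tile_size = 32)
  for (level in c(0, 128, 245, 255)) {
    tile <- array(level, c(32, 32, 3))
    lab <- qc_classify(tile_entropy(tile), tile_variance(tile),
                       blur_score(tile), mean_saturation(tile), cfg)
    expect_identical(lab, "white")
  }
})

test_that("qc_slide builds a complete manifest that round-trips via CSV", {
  sl <- make_slide(synthetic_slide_spec(3, 2, 0.5, n_white_tiles = 1,
                                        tile_size = 64, seed = 9))
  man <- qc_slide(slide_handle(sl$pixels), qc_config(tile_size = 64),
                  slide_id = "s1", class_labels = sl$manifest$class_label)
  expect_equal(nrow(man), 6)
  expect_true(all(man$qc_label %in% c("keep", "white", "blur", "artifact")))
  expect_true(all(man$entropy >= 0 & man$entropy <= 8))
  expect_true(all(man$variance >= 0))

  path <- tempfile(fileext = ".csv")
  write_tile_manifest(man, path)
  back <- read_tile_manifest(path)
  expect_equal(back$qc_label, man$qc_label)
  expect_equal(back$entropy, man$entropy, tolerance = 1e-12)
})
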