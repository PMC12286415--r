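# Attention primitives, classifier construction, parameter accounting and
# the attention-budget search.

test_that("linear projection handles the closed-form cases", {
  expect_equal(linear_project(c(3, 4), matrix(0, 2, 2), c(7, 9)), c(7, 9))
  expect_equal(linear_project(c(3, 4), diag(2), c(0, 0)), c(3, 4))
  W <- matrix(c(1, 0, 0, 2), 2, 2)
  expect_equal(linear_project(c(1, 2), W, c(1, 1)), c(2, 5))
  expect_error(linear_project(c(1, 2, 3), W, c(1, 1)), "dimension mismatch")
})

test_that("cross-attention matches hand-derived small cases", {
  # one key/value pair: weight 1, output = value
  one <- cross_attention(c(1, 2), matrix(c(5, 5), 1), matrix(c(3, 9), 1))
  expect_equal(as.vector(one$weights), 1)
  expect_equal(one$output, c(3, 9))

  # identical keys: uniform weights, output = mean of values
  keys <- matrix(1, 4, 2)
  vals <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 4, 2)
  same <- cross_attention(c(0.3, -0.2), keys, vals)
  expect_equal(as.vector(same$weights), rep(0.25, 4))
  expect_equal(same$output, colMeans(vals))

  # d = 2 worked example: weights softmax(1/sqrt(2), 0)
  ex <- cross_attention(c(1, 0), rbind(c(1, 0), c(0, 1)),
                        rbind(c(1, 0), c(0, 1)))
  w1 <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(as.vector(ex$weights), c(w1, 1 - w1), tolerance = 1e-12)
  expect_equal(round(as.vector(ex$weights), 4), c(0.6698, 0.3302))
  expect_equal(ex$output, c(w1, 1 - w1), tolerance = 1e-12)

  expect_error(cross_attention(c(1, 0), matrix(0, 0, 2), matrix(0, 0, 2)),
               "empty")
})

test_that("cross-attention agrees with the brute-force loop oracle", {
  set.seed(77)
  for (i in 1:50) {
    d <- sample(2:6, 1)
    n <- sample(1:8, 1)
    q <- rnorm(d)
    keys <- matrix(rnorm(n * d), n, d)
    vals <- matrix(rnorm(n * 3), n, 3)
    got <- cross_attention(q, keys, vals)
    ref <- oracle_attention(q, keys, vals)
    expect_equal(as.vector(got$weights), ref$weights, tolerance = 1e-9)
    expect_equal(got$output, ref$output, tolerance = 1e-9)
    expect_equal(sum(got$weights), 1, tolerance = 1e-9)
    expect_true(all(got$weights >= 0))
  }
})

test_that("scaled scores are invariant when d changes but scaled logits are fixed", {
  # two settings engineered so q.k / sqrt(d) takes the same values
  w2 <- cross_attention(c(2, 0), rbind(c(1, 0), c(0, 1)),
                        rbind(c(1, 0), c(0, 1)))$weights
  s <- 2 / sqrt(2)  # the scaled logit in the d = 2 setting
  q4 <- c(s * 2 / 2, 0, 0, 0)  # d = 4: q.k1 / sqrt(4) = s again
  w4 <- cross_attention(q4 * 2, rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)),
                        rbind(c(1, 0), c(0, 1)))$weights
  expect_equal(as.vector(w2), as.vector(w4), tolerance = 1e-12)
})

test_that("the attention branch is symmetric in its three units", {
  set.seed(12)
  feat <- array(runif(32 * 32 * 3), c(32, 32, 3))
  mk_unit <- function() {
    Td <- 16^2 * 3
    list(Wk = matrix(rnorm(Td * 4, sd = 0.1), Td, 4), bk = rnorm(4),
         Wv = matrix(rnorm(Td * 4, sd = 0.1), Td, 4), bv = rnorm(4),
         Wq = matrix(rnorm(5 * 4, sd = 0.1), 5, 4), bq = rnorm(4),
         Wo = matrix(rnorm(4 * 5, sd = 0.1), 4, 5), bo = rnorm(5))
  }
  latent <- matrix(rnorm(3 * 5), 3, 5)
  head <- list(W = matrix(rnorm(15 * 2, sd = 0.1), 15, 2), b = c(0, 0))
  u1 <- mk_unit(); u2 <- mk_unit(); u3 <- mk_unit()

  # identical units reproduce the single-unit output
  same <- iterative_attention_forward(feat, latent, list(u1, u1, u1), head, 16)
  one_unit <- slidewise:::attention_unit_forward(
    slidewise:::patchify(feat, 16), latent, u1
  )
  expect_equal(same$latent_avg, one_unit$Lout, tolerance = 1e-12)

  # permutation invariance
  a <- iterative_attention_forward(feat, latent, list(u1, u2, u3), head, 16)
  b <- iterative_attention_forward(feat, latent, list(u3, u1, u2), head, 16)
  expect_equal(a$output, b$output, tolerance = 1e-12)

  # output is a 2-vector of probabilities
  expect_length(a$output, 2)
  expect_true(all(a$output > 0 & a$output < 1))

  expect_error(iterative_attention_forward(feat, latent, list(u1, u2, u3),
                                           head, 5),
               "does not divide")
})

test_that("classifier construction reproduces the published accounting", {
  model <- build_classifier()
  rep <- count_parameters(model)
  counts <- setNames(rep$params, rep$layer)
  expect_equal(unname(counts["conv1"]), 896)
  expect_equal(unname(counts["conv2"]), 18496)
  expect_equal(unname(counts["conv3"]), 73856)
  expect_equal(unname(counts["conv4"]), 73792)
  expect_equal(unname(counts["dense_out"]), 67)
  expect_equal(unname(counts["attention_branch"]), 348866)
  expect_equal(attr(rep, "total"), sum(rep$params))
  expect_match(rep$output_shape[rep$layer == "concatenate"], "66")

  shapes <- rep$output_shape
  expect_equal(shapes[rep$layer == "conv2"], "(None, 30, 30, 64)")
  expect_equal(shapes[rep$layer == "pool3"], "(None, 6, 6, 128)")
  expect_equal(shapes[rep$layer == "conv4"], "(None, 4, 4, 64)")

  # a config that breaks the tower is rejected, naming the layer
  expect_error(build_classifier(classifier_config(conv_filters = c(16, 64, 128, 64))),
               "conv1")
})

test_that("forward pass emits probabilities and is deterministic", {
  model <- build_classifier(small_cfg())
  set.seed(9)
  feats <- replicate(3, array(runif(48 * 48 * 3), c(48, 48, 3)),
                     simplify = FALSE)
  p1 <- predict_classifier(model, feats)
  p2 <- predict_classifier(model, feats)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("backpropagation matches finite differences", {
  model <- build_classifier(small_cfg(seed = 77))
  set.seed(42)
  n <- 3
  x <- array(runif(48 * 48 * 3 * n), c(48, 48, 3, n))
  y <- c(1, 0, 1)
  fwd <- slidewise:::classifier_forward(model, x, cache = TRUE)
  grads <- slidewise:::classifier_backward(model, fwd, y)
  eps <- 1e-5
  for (nm in c("Wc1", "Wc3", "L", "Wk2", "Wq1", "Wo3", "Wha", "Wout",
               "bc2", "bq3", "bout")) {
    p <- model$params[[nm]]
    for (k in sample(seq_along(p), min(3, length(p)))) {
      m2 <- model
      m2$params[[nm]][k] <- p[k] + eps
      lp <- slidewise:::bce_loss(slidewise:::classifier_forward(m2, x), y)
      m2$params[[nm]][k] <- p[k] - eps
      lm <- slidewise:::bce_loss(slidewise:::classifier_forward(m2, x), y)
      expect_equal(grads[[nm]][k], (lp - lm) / (2 * eps), tolerance = 1e-5,
                   ignore_attr = TRUE)
    }
  }
})

test_that("attention-budget search is exhaustive, deterministic and honest", {
  # tiny family with a planted exact solution
  target <- slidewise:::attention_branch_count(4^2 * 3, 4, 8, 6)
  hit <- attention_config_search(
    budget = target, patch_sizes = 4L, n_latents_range = 2:6,
    latent_dim_range = 4:10, proj_dim_range = 4:8, input_side = 16L
  )
  expect_true(hit$exact)
  expect_equal(hit$achieved, target)
  expect_equal(hit[c("n_latents", "latent_dim", "proj_dim")],
               list(n_latents = 4L, latent_dim = 8L, proj_dim = 6L))

  # budget below the family minimum -> smallest config, exact = FALSE
  low <- attention_config_search(
    budget = 1, patch_sizes = 4L, n_latents_range = 2:3,
    latent_dim_range = 2:3, proj_dim_range = 2:3, input_side = 16L
  )
  expect_false(low$exact)
  expect_equal(low$achieved,
               slidewise:::attention_branch_count(48, 2, 2, 2))

  # deterministic on repeat
  again <- attention_config_search(
    budget = target, patch_sizes = 4L, n_latents_range = 2:6,
    latent_dim_range = 4:10, proj_dim_range = 4:8, input_side = 16L
  )
  expect_identical(hit, again)

  expect_error(attention_config_search(patch_sizes = integer(0)), "empty")
})

test_that("the shipped attention default is the search result for the printed budget", {
  best <- attention_config_search(
    budget = 348867, patch_sizes = c(4L, 8L, 16L),
    n_latents_range = 1:64, latent_dim_range = 1:256,
    proj_dim_range = 1:256
  )
  cfg <- classifier_config()
  expect_equal(best$patch_size, cfg$patch_size)
  expect_equal(best$n_latents, cfg$n_latents)
  expect_equal(best$latent_dim, cfg$latent_dim)
  expect_equal(best$proj_dim, cfg$proj_dim)
  expect_equal(best$achieved, 348866)
  expect_false(best$exact)  # no family member hits 348,867 (mod-3 argument)
})
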