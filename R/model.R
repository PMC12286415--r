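# The hybrid tile classifier: a small convolutional tower (exact published
# geometry: conv 32 'same' -> pool -> conv 64 -> pool -> conv 128 -> pool ->
# conv 64 -> global average pool) in parallel with an iterative
# cross-attention branch in the Perceiver style — image patches become
# key/value tokens, a trainable latent array supplies the queries, three
# attention units run in parallel and their refined latents are averaged —
# then concatenation (64 + 2 = 66) and a sigmoid head.

#' Linear projection
#'
#' The affine map `x %*% W + b` used to form keys, values and queries.
#'
#' @param x feature vector (length `nrow(W)`) or matrix (`n x nrow(W)`).
#' @param W projection matrix.
#' @param b bias vector of length `ncol(W)`.
#' @return projected vector or matrix.
#' @export
linear_project <- function(x, W, b) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(W)) stop("dimension mismatch: x has ", ncol(x),
                               " features, W expects ", nrow(W))
  if (length(b) != ncol(W)) stop("dimension mismatch: bias length ",
                                 length(b), ", W produces ", ncol(W))
  out <- sweep(x %*% W, 2, b, "+")
  if (nrow(out) == 1) drop(out) else out
}

#' Scaled dot-product cross-attention
#'
#' Attention weights are `softmax(q . k_i / sqrt(d))` over the keys, and the
#' output is the weight-averaged sum of the values.  Weights are returned
#' alongside the output (they feed the heatmaps).
#'
#' @param query vector of length `d`, or an `n_q x d` matrix of queries.
#' @param keys `n x d` matrix (rows are keys) or list of vectors.
#' @param values `n x d_v` matrix or list of vectors, same `n` as keys.
#' @return list with `output` (vector, or `n_q x d_v` matrix) and
#'   `weights` (`n_q x n`, rows summing to 1).
#' @export
cross_attention <- function(query, keys, values) {
  if (is.list(keys)) keys <- do.call(rbind, keys)
  if (is.list(values)) values <- do.call(rbind, values)
  if (is.null(keys) || nrow(keys) == 0) stop("empty key set")
  if (nrow(keys) != nrow(values)) stop("keys and values differ in length")
  Q <- if (is.vector(query)) matrix(query, nrow = 1) else query
  d <- ncol(keys)
  if (ncol(Q) != d) stop("query dimension ", ncol(Q),
                         " does not match key dimension ", d)
  A <- softmax_rows(Q %*% t(keys) / sqrt(d))
  out <- A %*% values
  if (nrow(out) == 1) out <- drop(out)
  list(output = out, weights = A)
}

# cut a (side, side, C) feature grid into non-overlapping patch tokens;
# token t = (gi-1)*gw + gj walks the patch grid row-major, and each token
# is the patch sub-array flattened in R's native order.  Length 3*p^2.
patchify <- function(features, patch_size) {
  side <- dim(features)[1]
  if (side %% patch_size != 0) {
    stop("patch_size ", patch_size, " does not divide the feature side ",
         side)
  }
  g <- side %/% patch_size
  n_tok <- g * g
  tok <- matrix(0, n_tok, patch_size^2 * dim(features)[3])
  for (gi in seq_len(g)) {
    rows <- (gi - 1) * patch_size + seq_len(patch_size)
    for (gj in seq_len(g)) {
      cols <- (gj - 1) * patch_size + seq_len(patch_size)
      tok[(gi - 1) * g + gj, ] <- as.vector(features[rows, cols, ])
    }
  }
  tok
}

# one attention unit applied to tokens; latent = NULL means input-derived
# queries.  Returns the refined latent rows plus intermediates for backprop.
attention_unit_forward <- function(tok, latent, u) {
  K <- sweep(tok %*% u$Wk, 2, u$bk, "+")
  V <- sweep(tok %*% u$Wv, 2, u$bv, "+")
  Qsrc <- if (is.null(latent)) tok else latent
  Q <- sweep(Qsrc %*% u$Wq, 2, u$bq, "+")
  P <- ncol(K)
  A <- softmax_rows(Q %*% t(K) / sqrt(P))
  O <- A %*% V
  U <- sweep(O %*% u$Wo, 2, u$bo, "+")
  Lout <- if (is.null(latent)) U else latent + U
  list(K = K, V = V, Q = Q, A = A, O = O, U = U, Lout = Lout)
}

#' Iterative-attention branch forward pass
#'
#' Tokenises the feature grid into non-overlapping patches, runs the three
#' attention units in parallel from the shared trainable latent array,
#' averages the three refined latents elementwise, and maps the result
#' through a sigmoid head to a 2-vector.  Because the units act in parallel
#' on the same latent, the branch is symmetric under unit permutation, and
#' three identical units reproduce a single unit's output.
#'
#' @param features `side x side x C` feature grid (the 64 x 64 x 3 latent
#'   view, or a downscaled tile).
#' @param latent `n_latents x latent_dim` trainable latent array, or `NULL`
#'   for input-derived queries.
#' @param units list of attention-unit parameter sets, each with `Wk`,
#'   `bk`, `Wv`, `bv`, `Wq`, `bq`, `Wo`, `bo`.
#' @param head list with `W` (`(n_q * latent_dim) x 2`) and `b` (length 2).
#' @param patch_size patch side; must divide the feature side.
#' @return list with `output` (length-2 vector, entries in (0, 1)),
#'   `weights` (list of per-unit attention matrices), and `latent_avg`.
#' @export
iterative_attention_forward <- function(features, latent, units, head,
                                        patch_size) {
  tok <- patchify(features, patch_size)
  outs <- lapply(units, function(u) attention_unit_forward(tok, latent, u))
  Lbar <- Reduce(`+`, lapply(outs, `[[`, "Lout")) / length(outs)
  z <- drop(as.vector(Lbar) %*% head$W) + head$b
  list(
    output = sigmoid(z),
    weights = lapply(outs, `[[`, "A"),
    latent_avg = Lbar
  )
}

#' Hybrid classifier configuration
#'
#' Defaults reproduce the published geometry: 64 x 64 x 3 input, conv
#' filters (32, 64, 128, 64) with 3 x 3 kernels ('same' padding on conv1
#' only, 2 x 2 max pooling after conv1-3), three parallel attention units,
#' and a 2-unit sigmoid attention head.  The attention internals
#' (`patch_size` 16, `n_latents` 43, `latent_dim` 245, `proj_dim` 52) are
#' the [attention_config_search()] result closest to the published
#' attention-branch parameter budget of 348,867 (achieved: 348,866; no
#' configuration in the searched family hits the budget exactly).
#'
#' @param input_side input grid side (64).
#' @param input_channels input channels (3).
#' @param conv_filters four conv widths.
#' @param patch_size attention patch side; must divide `input_side`.
#' @param n_latents,latent_dim,proj_dim attention-branch dimensions.
#' @param n_attention_units number of parallel attention units (3).
#' @param attention_out_dim attention head width (2).
#' @param dropout dropout rate before the final dense layer.
#' @param query_source `"latent"` (trainable latent array supplies queries,
#'   the default) or `"input"` (queries derived from the tokens).
#' @param seed integer seed for weight initialisation.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(input_side = 64L, input_channels = 3L,
                              conv_filters = c(32L, 64L, 128L, 64L),
                              patch_size = 16L, n_latents = 43L,
                              latent_dim = 245L, proj_dim = 52L,
                              n_attention_units = 3L,
                              attention_out_dim = 2L, dropout = 0.5,
                              query_source = c("latent", "input"),
                              seed = 1L) {
  query_source <- match.arg(query_source)
  if (n_attention_units != 3L) stop("the model uses exactly 3 attention units")
  if (attention_out_dim != 2L) stop("the attention head outputs 2 features")
  if (input_side %% patch_size != 0) {
    stop("patch_size must divide the input side")
  }
  stopifnot(length(conv_filters) == 4L, dropout >= 0, dropout < 1)
  structure(
    list(
      input_side = as.integer(input_side),
      input_channels = as.integer(input_channels),
      conv_filters = as.integer(conv_filters),
      patch_size = as.integer(patch_size),
      n_latents = as.integer(n_latents),
      latent_dim = as.integer(latent_dim),
      proj_dim = as.integer(proj_dim),
      n_attention_units = 3L,
      attention_out_dim = 2L,
      dropout = dropout,
      query_source = query_source,
      seed = as.integer(seed)
    ),
    class = "classifier_config"
  )
}

# conv-tower output shapes for a config (list of c(side, channels))
conv_tower_shapes <- function(cfg) {
  s <- cfg$input_side
  f <- cfg$conv_filters
  shapes <- list()
  s1 <- s                      # conv1: 'same'
  shapes$conv1 <- c(s1, f[1])
  p1 <- s1 %/% 2L
  shapes$pool1 <- c(p1, f[1])
  s2 <- p1 - 2L                # conv2..4: 'valid'
  shapes$conv2 <- c(s2, f[2])
  p2 <- s2 %/% 2L
  shapes$pool2 <- c(p2, f[2])
  s3 <- p2 - 2L
  shapes$conv3 <- c(s3, f[3])
  p3 <- s3 %/% 2L
  shapes$pool3 <- c(p3, f[3])
  s4 <- p3 - 2L
  shapes$conv4 <- c(s4, f[4])
  if (any(vapply(shapes, function(x) x[1] < 1, logical(1)))) {
    stop("conv tower collapses below 1 x 1 for input side ", s)
  }
  shapes
}

# the published tower geometry, used to validate 64-input configs
reference_shapes <- list(
  conv1 = c(64L, 32L), pool1 = c(32L, 32L),
  conv2 = c(30L, 64L), pool2 = c(15L, 64L),
  conv3 = c(13L, 128L), pool3 = c(6L, 128L),
  conv4 = c(4L, 64L)
)

#' Build the hybrid classifier
#'
#' Initialises all weights from `cfg$seed` and assembles the per-layer
#' parameter report.  For 64 x 64 x 3 input the conv tower must reproduce
#' the published output shapes ((64,64,32) -> (32,32,32) -> (30,30,64) ->
#' (15,15,64) -> (13,13,128) -> (6,6,128) -> (4,4,64) -> 64); a config that
#' breaks them is rejected, naming the first mismatching layer.
#'
#' @param cfg a [classifier_config()].
#' @return a `tile_classifier` with fields `cfg`, `params`, `report`,
#'   `trained`.
#' @export
build_classifier <- function(cfg = classifier_config()) {
  stopifnot(inherits(cfg, "classifier_config"))
  shapes <- conv_tower_shapes(cfg)
  if (cfg$input_side == 64L) {
    for (nm in names(reference_shapes)) {
      if (!identical(unname(shapes[[nm]]), unname(reference_shapes[[nm]]))) {
        stop("config does not reproduce the published geometry: layer ", nm,
             " has shape (", paste(shapes[[nm]], collapse = ", "),
             "), expected (", paste(reference_shapes[[nm]], collapse = ", "),
             ")")
      }
    }
  }
  f <- cfg$conv_filters
  ch <- c(cfg$input_channels, f)
  token_dim <- cfg$patch_size^2 * cfg$input_channels
  n_tok <- (cfg$input_side %/% cfg$patch_size)^2
  n_q <- if (cfg$query_source == "latent") cfg$n_latents else n_tok
  q_in <- if (cfg$query_source == "latent") cfg$latent_dim else token_dim
  params <- with_seed(cfg$seed, {
    p <- list()
    for (i in 1:4) {
      p[[paste0("Wc", i)]] <- init_conv(3, 3, ch[i], ch[i + 1])
      p[[paste0("bc", i)]] <- numeric(ch[i + 1])
    }
    if (cfg$query_source == "latent") {
      p$L <- matrix(rnorm(cfg$n_latents * cfg$latent_dim, sd = 0.02),
                    cfg$n_latents, cfg$latent_dim)
    }
    for (u in 1:3) {
      p[[paste0("Wk", u)]] <- init_dense(token_dim, cfg$proj_dim)
      p[[paste0("bk", u)]] <- numeric(cfg$proj_dim)
      p[[paste0("Wv", u)]] <- init_dense(token_dim, cfg$proj_dim)
      p[[paste0("bv", u)]] <- numeric(cfg$proj_dim)
      p[[paste0("Wq", u)]] <- init_dense(q_in, cfg$proj_dim)
      p[[paste0("bq", u)]] <- numeric(cfg$proj_dim)
      p[[paste0("Wo", u)]] <- init_dense(cfg$proj_dim, cfg$latent_dim)
      p[[paste0("bo", u)]] <- numeric(cfg$latent_dim)
    }
    p$Wha <- init_dense(n_q * cfg$latent_dim, cfg$attention_out_dim)
    p$bha <- numeric(cfg$attention_out_dim)
    p$Wout <- init_dense(f[4] + cfg$attention_out_dim, 1L)
    p$bout <- numeric(1L)
    p
  })
  model <- structure(
    list(cfg = cfg, params = params, trained = FALSE),
    class = "tile_classifier"
  )
  model$report <- count_parameters(model)
  model
}

# parameters of one attention unit / the whole branch, from dimensions
attention_unit_count <- function(token_dim, latent_dim, proj_dim) {
  2 * (token_dim * proj_dim + proj_dim) +      # key + value
    (latent_dim * proj_dim + proj_dim) +       # query
    (proj_dim * latent_dim + latent_dim)       # out-projection
}

attention_branch_count <- function(token_dim, n_latents, latent_dim,
                                   proj_dim, out_dim = 2L) {
  n_latents * latent_dim +
    3 * attention_unit_count(token_dim, latent_dim, proj_dim) +
    (n_latents * latent_dim * out_dim + out_dim)
}

#' Per-layer parameter accounting
#'
#' Counts trainable parameters layer by layer — `kh*kw*Cin*Cout + Cout` for
#' convolutions, `fan_in*fan_out + fan_out` for dense projections,
#' `n_latents*latent_dim` for the latent array — and sums them.  For the
#' default configuration the conv layers count 896 / 18,496 / 73,856 /
#' 73,792, the attention branch 348,866 and the final dense layer 67.
#'
#' @param model a `tile_classifier`.
#' @return a `layer_param_report`: data.frame with columns `layer`,
#'   `output_shape`, `params`, plus a `total` attribute.
#' @export
count_parameters <- function(model) {
  cfg <- model$cfg
  p <- model$params
  shapes <- conv_tower_shapes(cfg)
  att_names <- c(
    if ("L" %in% names(p)) "L",
    as.vector(outer(c("Wk", "bk", "Wv", "bv", "Wq", "bq", "Wo", "bo"),
                    1:3, paste0)),
    "Wha", "bha"
  )
  att_count <- sum(vapply(att_names, function(nm) length(p[[nm]]),
                          numeric(1)))
  sh <- function(s) sprintf("(None, %d, %d, %d)", s[1], s[1], s[2])
  rows <- list(
    c("input", sprintf("(None, %d, %d, %d)", cfg$input_side, cfg$input_side,
                       cfg$input_channels), 0),
    c("conv1", sh(shapes$conv1), length(p$Wc1) + length(p$bc1)),
    c("pool1", sh(shapes$pool1), 0),
    c("conv2", sh(shapes$conv2), length(p$Wc2) + length(p$bc2)),
    c("pool2", sh(shapes$pool2), 0),
    c("conv3", sh(shapes$conv3), length(p$Wc3) + length(p$bc3)),
    c("pool3", sh(shapes$pool3), 0),
    c("conv4", sh(shapes$conv4), length(p$Wc4) + length(p$bc4)),
    c("global_average_pool", sprintf("(None, %d)", cfg$conv_filters[4]), 0),
    c("attention_branch", sprintf("(None, %d)", cfg$attention_out_dim),
      att_count),
    c("concatenate",
      sprintf("(None, %d)", cfg$conv_filters[4] + cfg$attention_out_dim), 0),
    c("dense_out", "(None, 1)", length(p$Wout) + length(p$bout))
  )
  report <- data.frame(
    layer = vapply(rows, `[[`, character(1), 1),
    output_shape = vapply(rows, `[[`, character(1), 2),
    params = as.numeric(vapply(rows, `[[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  attr(report, "total") <- sum(report$params)
  class(report) <- c("layer_param_report", "data.frame")
  report
}

#' @export
print.layer_param_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$params <- format(df$params, big.mark = ",", trim = TRUE)
  print(df, row.names = FALSE, right = FALSE)
  cat(sprintf("Total trainable parameters: %s\n",
              format(attr(x, "total"), big.mark = ",")))
  invisible(x)
}

#' Export a layer report as JSON
#'
#' @param report a `layer_param_report`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_param_report <- function(report, path) {
  jsonlite::write_json(
    list(layers = as.data.frame(report), total = attr(report, "total")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Search attention-branch configurations against a parameter budget
#'
#' The attention branch's internal dimensions are not published; only its
#' total trainable-parameter budget is.  This exhaustively enumerates a
#' family of configurations and returns the one whose branch count is
#' closest to `budget` (ties broken by smallest
#' `(proj_dim, latent_dim, n_latents, patch_size)` lexicographically), with
#' `exact` flagging whether the budget is met exactly.
#'
#' @param budget target parameter count (the published branch budget is
#'   348,867).
#' @param patch_sizes candidate patch sides (must divide `input_side`).
#' @param n_latents_range,latent_dim_range,proj_dim_range integer candidate
#'   vectors.
#' @param input_side,input_channels input grid geometry.
#' @return list with `patch_size`, `n_latents`, `latent_dim`, `proj_dim`,
#'   `achieved`, `exact`, `diff`.
#' @export
attention_config_search <- function(budget = 348867,
                                    patch_sizes = c(4L, 8L, 16L),
                                    n_latents_range = 1:64,
                                    latent_dim_range = 1:256,
                                    proj_dim_range = 1:256,
                                    input_side = 64L, input_channels = 3L) {
  if (length(patch_sizes) == 0 || length(n_latents_range) == 0 ||
      length(latent_dim_range) == 0 || length(proj_dim_range) == 0) {
    stop("empty search family")
  }
  best <- NULL
  D <- rep(latent_dim_range, each = length(proj_dim_range))
  P <- rep(proj_dim_range, times = length(latent_dim_range))
  for (patch in sort(patch_sizes)) {
    if (input_side %% patch != 0) next
    token_dim <- patch^2 * input_channels
    for (N in sort(n_latents_range)) {
      tot <- attention_branch_count(token_dim, N, D, P)
      d <- abs(tot - budget)
      for (j in which(d == min(d))) {
        cand <- list(patch_size = patch, n_latents = N, latent_dim = D[j],
                     proj_dim = P[j], achieved = tot[j],
                     exact = tot[j] == budget, diff = d[j])
        if (is.null(best) || cand$diff < best$diff ||
            (cand$diff == best$diff &&
             (cand$proj_dim < best$proj_dim ||
              (cand$proj_dim == best$proj_dim &&
               (cand$latent_dim < best$latent_dim ||
                (cand$latent_dim == best$latent_dim &&
                 (cand$n_latents < best$n_latents ||
                  (cand$n_latents == best$n_latents &&
                   cand$patch_size < best$patch_size)))))))) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) stop("empty search family (no patch size divides the input side)")
  best
}
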