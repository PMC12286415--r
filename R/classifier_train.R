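# Forward/backward passes and the supervised training loop for the hybrid
# classifier.  The backward pass is hand-derived; test-side it is checked
# against finite differences on a reduced geometry.

# collect the three units' parameter lists from the flat param list
unit_params <- function(p, u) {
  list(Wk = p[[paste0("Wk", u)]], bk = p[[paste0("bk", u)]],
       Wv = p[[paste0("Wv", u)]], bv = p[[paste0("bv", u)]],
       Wq = p[[paste0("Wq", u)]], bq = p[[paste0("bq", u)]],
       Wo = p[[paste0("Wo", u)]], bo = p[[paste0("bo", u)]])
}

# attention branch forward for one sample; returns activations for backprop
attention_forward_sample <- function(cfg, p, x3d) {
  tok <- patchify(x3d, cfg$patch_size)
  latent <- if (cfg$query_source == "latent") p$L else NULL
  outs <- lapply(1:3, function(u) {
    attention_unit_forward(tok, latent, unit_params(p, u))
  })
  Lbar <- Reduce(`+`, lapply(outs, `[[`, "Lout")) / 3
  f <- as.vector(Lbar)
  z <- drop(f %*% p$Wha) + p$bha
  a <- sigmoid(z)
  list(tok = tok, outs = outs, Lbar = Lbar, f = f, z = z, a = a)
}

# backward for one sample given d(loss)/d(a_att); accumulates into g (an
# environment used as a mutable gradient store)
attention_backward_sample <- function(cfg, p, cache, d_a, g) {
  dz <- d_a * cache$a * (1 - cache$a)
  g$Wha <- g$Wha + outer(cache$f, dz)
  g$bha <- g$bha + dz
  dLbar <- matrix(drop(p$Wha %*% dz), nrow(cache$Lbar), ncol(cache$Lbar))
  tok <- cache$tok
  latent_mode <- cfg$query_source == "latent"
  dL <- if (latent_mode) dLbar else NULL  # residual path, summed over units
  sqP <- sqrt(cfg$proj_dim)
  for (u in 1:3) {
    cu <- cache$outs[[u]]
    up <- unit_params(p, u)
    dU <- dLbar / 3
    g[[paste0("Wo", u)]] <- g[[paste0("Wo", u)]] + t(cu$O) %*% dU
    g[[paste0("bo", u)]] <- g[[paste0("bo", u)]] + colSums(dU)
    dO <- dU %*% t(up$Wo)
    dA <- dO %*% t(cu$V)
    dV <- t(cu$A) %*% dO
    g[[paste0("Wv", u)]] <- g[[paste0("Wv", u)]] + t(tok) %*% dV
    g[[paste0("bv", u)]] <- g[[paste0("bv", u)]] + colSums(dV)
    dS <- cu$A * (dA - rowSums(dA * cu$A))
    dQ <- dS %*% cu$K / sqP
    dK <- t(dS) %*% cu$Q / sqP
    g[[paste0("Wk", u)]] <- g[[paste0("Wk", u)]] + t(tok) %*% dK
    g[[paste0("bk", u)]] <- g[[paste0("bk", u)]] + colSums(dK)
    if (latent_mode) {
      g[[paste0("Wq", u)]] <- g[[paste0("Wq", u)]] + t(p$L) %*% dQ
      g[[paste0("bq", u)]] <- g[[paste0("bq", u)]] + colSums(dQ)
      dL <- dL + dQ %*% t(up$Wq)  # residual path already in dL's init
    } else {
      g[[paste0("Wq", u)]] <- g[[paste0("Wq", u)]] + t(tok) %*% dQ
      g[[paste0("bq", u)]] <- g[[paste0("bq", u)]] + colSums(dQ)
    }
  }
  if (latent_mode) g$L <- g$L + dL
  invisible(NULL)
}

# full model forward over a (side, side, C, N) batch
classifier_forward <- function(model, x4d, dropout_mask = NULL,
                               cache = FALSE) {
  p <- model$params
  z1 <- cpp_conv2d_fwd(x4d, p$Wc1, p$bc1, 1L, 1L)
  a1 <- gelu(z1)
  pl1 <- cpp_maxpool_fwd(a1)
  z2 <- cpp_conv2d_fwd(pl1$out, p$Wc2, p$bc2, 1L, 0L)
  a2 <- gelu(z2)
  pl2 <- cpp_maxpool_fwd(a2)
  z3 <- cpp_conv2d_fwd(pl2$out, p$Wc3, p$bc3, 1L, 0L)
  a3 <- gelu(z3)
  pl3 <- cpp_maxpool_fwd(a3)
  z4 <- cpp_conv2d_fwd(pl3$out, p$Wc4, p$bc4, 1L, 0L)
  a4 <- gelu(z4)
  d4 <- dim(a4)
  n <- d4[4]
  gpool <- t(colMeans(array(a4, c(d4[1] * d4[2], d4[3], n))))  # n x C
  att <- lapply(seq_len(n), function(i) {
    attention_forward_sample(model$cfg, p, array(x4d[, , , i], dim(x4d)[1:3]))
  })
  a_att <- do.call(rbind, lapply(att, `[[`, "a"))               # n x 2
  h <- cbind(gpool, a_att)
  hd <- if (is.null(dropout_mask)) h else h * dropout_mask
  zout <- drop(hd %*% p$Wout) + p$bout
  prob <- sigmoid(zout)
  if (!cache) return(prob)
  list(prob = prob, zout = zout, h = h, hd = hd, gpool = gpool, att = att,
       z1 = z1, pl1 = pl1, z2 = z2, pl2 = pl2, z3 = z3, pl3 = pl3,
       z4 = z4, a4 = a4, x = x4d, dropout_mask = dropout_mask)
}

# full backward pass; y in {0,1}; returns gradient list (mean BCE loss)
classifier_backward <- function(model, cache, y) {
  p <- model$params
  cfg <- model$cfg
  n <- length(y)
  g <- new.env(parent = emptyenv())
  for (nm in names(p)) {
    assign(nm, array(0, dim = dim(p[[nm]]) %||% length(p[[nm]])), envir = g)
  }
  dz <- (cache$prob - y) / n
  g$Wout <- g$Wout + t(cache$hd) %*% matrix(dz, ncol = 1)
  g$bout <- g$bout + sum(dz)
  dh <- matrix(dz, ncol = 1) %*% t(p$Wout)
  if (!is.null(cache$dropout_mask)) dh <- dh * cache$dropout_mask
  n_conv <- ncol(cache$gpool)
  dg <- dh[, seq_len(n_conv), drop = FALSE]
  d_a_att <- dh[, n_conv + 1:2, drop = FALSE]
  for (i in seq_len(n)) {
    attention_backward_sample(cfg, p, cache$att[[i]], d_a_att[i, ], g)
  }
  # conv tower backward
  d4 <- dim(cache$a4)
  d_a4 <- array(rep(as.vector(t(dg)) / (d4[1] * d4[2]),
                    each = d4[1] * d4[2]), d4)
  d_z4 <- d_a4 * gelu_grad(cache$z4)
  bw <- cpp_conv2d_bwd(cache$pl3$out, p$Wc4, d_z4, 1L, 0L)
  g$Wc4 <- g$Wc4 + bw$gw; g$bc4 <- g$bc4 + bw$gb
  d_a3 <- cpp_maxpool_bwd(bw$gx, cache$pl3$idx, dim(cache$z3)) *
    gelu_grad(cache$z3)
  bw <- cpp_conv2d_bwd(cache$pl2$out, p$Wc3, d_a3, 1L, 0L)
  g$Wc3 <- g$Wc3 + bw$gw; g$bc3 <- g$bc3 + bw$gb
  d_a2 <- cpp_maxpool_bwd(bw$gx, cache$pl2$idx, dim(cache$z2)) *
    gelu_grad(cache$z2)
  bw <- cpp_conv2d_bwd(cache$pl1$out, p$Wc2, d_a2, 1L, 0L)
  g$Wc2 <- g$Wc2 + bw$gw; g$bc2 <- g$bc2 + bw$gb
  d_a1 <- cpp_maxpool_bwd(bw$gx, cache$pl1$idx, dim(cache$z1)) *
    gelu_grad(cache$z1)
  bw <- cpp_conv2d_bwd(cache$x, p$Wc1, d_a1, 1L, 1L)
  g$Wc1 <- g$Wc1 + bw$gw; g$bc1 <- g$bc1 + bw$gb
  out <- mget(names(p), envir = g)
  # keep matrix gradients shaped like their parameters
  for (nm in names(out)) {
    if (!is.null(dim(p[[nm]]))) dim(out[[nm]]) <- dim(p[[nm]])
  }
  out
}

bce_loss <- function(prob, y, eps = 1e-12) {
  prob <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(prob) + (1 - y) * log(1 - prob))
}

#' Training configuration
#'
#' Defaults are the study settings: learning rate 1e-4, batch size 15,
#' 25 epochs, weight decay 0.001 (decoupled, alongside Adam), binary
#' cross-entropy loss, and a stratified 70:10:20 train/validation/test
#' split.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size tiles per optimisation step.
#' @param epochs training epochs.
#' @param weight_decay decoupled weight-decay rate.
#' @param seed integer seed (splitting, shuffling, dropout).
#' @param split length-3 named fractions summing to 1.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 15L,
                         epochs = 25L, weight_decay = 0.001, seed = 1L,
                         split = c(train = 0.7, val = 0.1, test = 0.2)) {
  stopifnot(
    learning_rate > 0, batch_size >= 1, epochs >= 1, weight_decay >= 0,
    length(split) == 3L, abs(sum(split) - 1) < 1e-8, all(split > 0)
  )
  structure(
    list(
      learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      epochs = as.integer(epochs),
      weight_decay = weight_decay,
      optimizer = "adamw",
      loss = "bce",
      seed = as.integer(seed),
      split = split
    ),
    class = "train_config"
  )
}

# largest-remainder apportionment of n into the split fractions
largest_remainder <- function(n, fractions) {
  q <- n * fractions
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(q - base), seq_along(q))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits a labeled tile manifest into disjoint, exhaustive subsets,
#' stratified by `class_label`, with per-class sizes given by
#' largest-remainder rounding of the split fractions.  Membership is a
#' seeded permutation, so identical seeds give identical splits.
#'
#' @param manifest data.frame with a `class_label` column (both classes
#'   present, >= 10 rows).
#' @param cfg a [train_config()].
#' @return list of three manifests (`train`, `val`, `test`), each carrying
#'   the original row indices in column `.row`.
#' @export
split_dataset <- function(manifest, cfg = train_config()) {
  if (nrow(manifest) < 10) stop("need at least 10 tiles to split")
  classes <- unique(manifest$class_label)
  if (length(classes) < 2) {
    stop("both classes must be present; found only: ",
         paste(classes, collapse = ", "))
  }
  manifest$.row <- seq_len(nrow(manifest))
  parts <- list(train = NULL, val = NULL, test = NULL)
  with_seed(cfg$seed, {
    for (cl in sort(classes)) {
      rows <- manifest[manifest$class_label == cl, , drop = FALSE]
      sizes <- largest_remainder(nrow(rows), cfg$split)
      ord <- sample.int(nrow(rows))
      at <- 0L
      for (k in 1:3) {
        take <- ord[at + seq_len(sizes[k])]
        parts[[k]] <- rbind(parts[[k]], rows[take, , drop = FALSE])
        at <- at + sizes[k]
      }
    }
  })
  lapply(parts, function(df) {
    rownames(df) <- NULL
    df
  })
}

labels_to_binary <- function(labels) {
  if (is.numeric(labels)) return(as.numeric(labels))
  as.numeric(labels == "recurrent")
}

#' Train the hybrid classifier
#'
#' Minimises binary cross-entropy with AdamW under the settings in `cfg`,
#' with positive class "recurrent".  Runs exactly `cfg$epochs` epochs,
#' records per-epoch train/validation loss and accuracy, and retains the
#' weights of the best-validation-loss epoch.
#'
#' @param model a built `tile_classifier`.
#' @param train_set,val_set lists with `features` (list of
#'   `side x side x C` arrays on the unit scale) and `labels`
#'   (`"recurrent"`/`"non_recurrent"` or 0/1).
#' @param cfg a [train_config()].
#' @return the model with trained weights (`best-validation` checkpoint),
#'   `trained = TRUE`, and `history` (data.frame epoch, train_loss,
#'   val_loss, train_acc, val_acc).
#' @export
train_classifier <- function(model, train_set, val_set,
                             cfg = train_config()) {
  stopifnot(inherits(model, "tile_classifier"))
  if (length(train_set$features) == 0 || length(val_set$features) == 0) {
    stop("empty training or validation split")
  }
  y_tr <- labels_to_binary(train_set$labels)
  y_va <- labels_to_binary(val_set$labels)
  params <- model$params
  state <- adam_init(params)
  drop_rate <- model$cfg$dropout
  n_h <- model$cfg$conv_filters[4] + model$cfg$attention_out_dim
  history <- data.frame(
    epoch = seq_len(cfg$epochs), train_loss = NA_real_, val_loss = NA_real_,
    train_acc = NA_real_, val_acc = NA_real_
  )
  best <- list(loss = Inf, params = params)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(y_tr))
      tr_loss <- 0; tr_correct <- 0L
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + cfg$batch_size - 1L, length(ord))
        idx <- ord[i:j]
        x <- stack_tiles(train_set$features[idx])
        y <- y_tr[idx]
        mask <- NULL
        if (drop_rate > 0) {
          mask <- matrix(
            (runif(length(idx) * n_h) >= drop_rate) / (1 - drop_rate),
            length(idx), n_h
          )
        }
        model$params <- params
        cc <- classifier_forward(model, x, dropout_mask = mask, cache = TRUE)
        tr_loss <- tr_loss + bce_loss(cc$prob, y) * length(idx)
        tr_correct <- tr_correct + sum((cc$prob > 0.5) == (y == 1))
        grads <- classifier_backward(model, cc, y)
        upd <- adam_step(params, grads, state, cfg$learning_rate,
                         cfg$weight_decay)
        params <- upd$params
        state <- upd$state
        i <- j + 1L
      }
      model$params <- params
      va_prob <- predict_classifier(model, val_set$features)
      va_loss <- bce_loss(va_prob, y_va)
      history$train_loss[ep] <- tr_loss / length(y_tr)
      history$train_acc[ep] <- tr_correct / length(y_tr)
      history$val_loss[ep] <- va_loss
      history$val_acc[ep] <- mean((va_prob > 0.5) == (y_va == 1))
      if (va_loss < best$loss) best <- list(loss = va_loss, params = params)
    }
  })
  model$params <- best$params
  model$trained <- TRUE
  model$history <- history
  model
}

#' Predict tile probabilities
#'
#' Forward pass in evaluation mode (no dropout).  Probabilities are for the
#' positive ("recurrent") class.
#'
#' @param model a `tile_classifier`.
#' @param features list of `side x side x C` arrays on the unit scale.
#' @param batch_size tiles per forward batch.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_classifier <- function(model, features, batch_size = 32L) {
  out <- numeric(length(features))
  i <- 1L
  while (i <= length(features)) {
    j <- min(i + batch_size - 1L, length(features))
    x <- stack_tiles(features[i:j])
    out[i:j] <- classifier_forward(model, x)
    i <- j + 1L
  }
  out
}

#' Write a training history CSV
#'
#' @param model a trained `tile_classifier`.
#' @param path CSV destination
#'   (`epoch,train_loss,val_loss,train_acc,val_acc`).
#' @return `path`, invisibly.
#' @export
write_history <- function(model, path) {
  stopifnot(!is.null(model$history))
  write.csv(model$history[, c("epoch", "train_loss", "val_loss",
                              "train_acc", "val_acc")],
            path, row.names = FALSE)
  invisible(path)
}
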