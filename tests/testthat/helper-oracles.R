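# Independent brute-force oracles used to pin expected values.  These stay
# deliberately naive (loops, direct definitions) and share no code with the
# package internals they check.

# direct 3x3 convolution of a matrix with a kernel (valid region only)
oracle_conv3 <- function(g, kernel) {
  n <- nrow(g)
  m <- ncol(g)
  out <- matrix(0, n - 2, m - 2)
  for (i in 2:(n - 1)) {
    for (j in 2:(m - 1)) {
      acc <- 0
      for (di in -1:1) for (dj in -1:1) {
        acc <- acc + kernel[di + 2, dj + 2] * g[i + di, j + dj]
      }
      out[i - 1, j - 1] <- acc
    }
  }
  out
}

oracle_pop_var <- function(x) mean((x - mean(x))^2)

# scaled dot-product attention by explicit loops
oracle_attention <- function(q, keys, values) {
  d <- length(q)
  scores <- vapply(seq_len(nrow(keys)), function(i) {
    sum(q * keys[i, ]) / sqrt(d)
  }, numeric(1))
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  out <- rep(0, ncol(values))
  for (i in seq_along(w)) out <- out + w[i] * values[i, ]
  list(weights = w, output = out)
}

# AUC by counting concordant positive-negative pairs (ties count 1/2)
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# lag-k autocorrelation of a 1-D profile
oracle_autocorr <- function(x, k) {
  x <- x - mean(x)
  sum(x[seq_len(length(x) - k)] * x[(k + 1):length(x)]) / sum(x^2)
}

# flat enumeration of complete tiles by floor division
oracle_tile_count <- function(w, h, s) (w %/% s) * (h %/% s)
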