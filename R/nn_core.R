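# Shared neural-network primitives: activations, parameter initialisation
# and the AdamW optimiser.  Parameters live in plain named lists of numeric
# arrays; gradients mirror that structure.  All randomness goes through R's
# RNG so a single set.seed() makes runs reproducible.

# GELU via the exact Gaussian CDF form: gelu(x) = x * pnorm(x).
# Dispatches to the C++ kernel (large conv activations make R's pnorm the
# hot spot).
gelu <- function(x) {
  out <- cpp_gelu(as.numeric(x))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}
gelu_grad <- function(x) {
  out <- cpp_gelu_grad(as.numeric(x))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise softmax, numerically stabilised
softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# He-normal init for conv kernels (dim kh,kw,Cin,Cout)
init_conv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

# Glorot-normal init for dense / projection matrices
init_dense <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
         fan_in, fan_out)
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One AdamW step.  Decoupled weight decay is applied to weight matrices and
# arrays (dim length >= 2) but not to bias vectors or other 1-D parameters,
# the usual convention.
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    p <- params[[nm]] - lr * step
    if (weight_decay > 0 && length(dim(params[[nm]])) >= 2) {
      p <- p - lr * weight_decay * params[[nm]]
    }
    # keep the parameter's original structure (biases stay plain vectors)
    if (is.null(dim(params[[nm]]))) p <- as.vector(p)
    params[[nm]] <- p
  }
  list(params = params, state = state)
}

# accumulate: a + b elementwise over matching named lists
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

grad_scale <- function(g, s) lapply(g, function(x) x * s)
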