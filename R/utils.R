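# Small numeric helpers shared across the network engine.

# Exponential linear unit and its derivative expressed in terms of the
# activation value (elu'(x) = 1 for x > 0, elu(x) + 1 otherwise).
elu <- function(x, alpha = 1) {
  neg <- x < 0
  if (any(neg)) x[neg] <- alpha * (exp(x[neg]) - 1)
  x
}

elu_grad_from_output <- function(y, alpha = 1) {
  g <- rep(1, length(y))
  dim(g) <- dim(y)
  neg <- y < 0
  g[neg] <- y[neg] + alpha
  g
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Overflow-safe log(cosh(x)) = |x| + log1p(exp(-2|x|)) - log(2).
log_cosh <- function(x) {
  a <- abs(x)
  a + log1p(exp(-2 * a)) - log(2)
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so that library calls do not perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Glorot/Xavier uniform initialisation, the Keras default for dense and
# convolutional kernels.
glorot_uniform <- function(fan_in, fan_out, dim_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dim_out), -limit, limit), dim = dim_out)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}
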