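# Internal numerical helpers shared by the representation modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  All stochastic entry points go through
# this so a single master seed makes a whole run reproducible.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(master, stream) {
  as.integer((as.double(master) * 48271 + stream * 16807) %% 2147483647)
}

gauss_init <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
}

xavier_init <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

zeros_like <- function(x) {
  if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
}

# Adam optimiser over a flat named list of parameter arrays.  Moment slots
# are created lazily so disabled modules cost nothing.
adam_init <- function() {
  list(m = list(), v = list(), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- zeros_like(g)
      state$v[[nm]] <- zeros_like(g)
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Row-wise softmax with the usual max-shift for stability.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Backward through row-wise softmax: given dL/dA and A, return dL/dz.
softmax_rows_backward <- function(dA, A) {
  A * (dA - rowSums(A * dA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locale-independent (byte-wise) string sort: vocabulary and identifier
# orderings feed model structure, so they must not depend on collation.
sort_c <- function(x) sort(x, method = "radix")
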