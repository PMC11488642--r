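# Internal numeric helpers shared across the package.

logsumexp <- function(s) {
  m <- max(s)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(s - m)))
}

softmax <- function(s) {
  if (any(!is.finite(s))) {
    stop("non-finite enhancer scores; check beta, weights and the state")
  }
  e <- exp(s - max(s))
  e / sum(e)
}

# Cosine distance 1 - cos(angle); zero vectors are maximally distant.
cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  d <- 1 - sum(a * b) / (na * nb)
  max(d, 0)
}

vec_norm <- function(x) sqrt(sum(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

stopifnot_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  }
  if (strict && x <= lower) stop(sprintf("'%s' must be > %g", name, lower))
  if (!strict && x < lower) stop(sprintf("'%s' must be >= %g", name, lower))
  invisible(x)
}
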