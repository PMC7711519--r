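# Internal numeric helpers shared across the package.

# log(exp(y) - 1), stable for both small and large y.
.logexpm1 <- function(y) {
  out <- numeric(length(y))
  big <- y > 33  # exp(-y) below double precision relative to 1
  out[big] <- y[big] + log1p(-exp(-y[big]))
  out[!big] <- log(expm1(y[!big]))
  out
}

.check_pos_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single finite positive number", name),
         call. = FALSE)
  }
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.  `seed = NULL` uses the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-replicate sub-seed kept within the 32-bit integer range.
.derive_seed <- function(seed, r) {
  as.integer((as.double(seed) * 48271 + as.double(r) * 16807) %% 2147483587)
}

# Accelerated evaluation of the alternating series sum_{k>=0} (-1)^k a(k)
# (Cohen-Villegas-Zagier scheme).  Converges geometrically for the totally
# oscillating sequences that arise from binomial expansions evaluated at the
# boundary of their disc of convergence, where plain truncation merely
# oscillates around the Abel value.
.altsum <- function(afun, n = 40L) {
  d <- (3 + sqrt(8))^n
  d <- (d + 1 / d) / 2
  b <- -1
  cc <- -d
  s <- 0
  for (k in 0:(n - 1L)) {
    cc <- b - cc
    s <- s + cc * afun(k)
    b <- (k + n) * (k - n) * b / ((k + 0.5) * (k + 1))
  }
  s / d
}

# Vectorized variant: `a` holds the first n magnitudes a_0, ..., a_{n-1}.
.altsum_vec <- function(a) {
  n <- length(a)
  d <- (3 + sqrt(8))^n
  d <- (d + 1 / d) / 2
  b <- -1
  cc <- -d
  w <- numeric(n)
  for (k in 0:(n - 1L)) {
    cc <- b - cc
    w[k + 1L] <- cc
    b <- (k + n) * (k - n) * b / ((k + 0.5) * (k + 1))
  }
  sum(w * a) / d
}
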