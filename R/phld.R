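#' The Poisson half-logistic distribution
#'
#' Density, distribution function, quantile function, random generation and
#' raw moments for the Poisson half-logistic distribution (PHLD) with scale
#' `alpha` (units 1/x) and shape `lam` (dimensionless).
#'
#' The PHLD arises by compounding the half-logistic distribution with a
#' zero-truncated Poisson number of latent components.  Writing
#' \eqn{\Delta(x) = (1 - e^{-\alpha x})/(1 + e^{-\alpha x}) = \tanh(\alpha x/2)}
#' for the half-logistic distribution function, the PHLD has
#' \deqn{F(x) = \frac{e^{\lambda \Delta(x)} - 1}{e^{\lambda} - 1}, \qquad
#'       f(x) = \frac{2 \alpha \lambda \, e^{-\alpha x + \lambda \Delta(x)}}
#'                   {(e^{\lambda} - 1)(1 + e^{-\alpha x})^2}, \qquad x \ge 0.}
#' The quantile function is closed form,
#' \eqn{x_p = \frac{2}{\alpha}\,\mathrm{atanh}(\xi)} with
#' \eqn{\xi = \log\{p (e^{\lambda} - 1) + 1\}/\lambda}, which is what
#' [rphld()] inverts for random generation.  As \eqn{\lambda \to 0} the PHLD
#' reduces to the half-logistic distribution with scale `alpha`.
#'
#' All densities and probabilities are evaluated through `expm1`/`log1p`
#' forms so that shapes up to `lam ~ 700` do not overflow.
#'
#' By default the functions are strict about their domains: negative `x`,
#' probabilities outside (0, 1) and non-finite input are errors, which
#' catches unit mistakes in user data.  With `lenient = TRUE` the
#' conventional extensions are returned instead (`dphld`/`pphld` give 0 below
#' the support, `qphld(0)` gives 0 and `qphld(1)` gives `Inf`).
#'
#' @param x,q vector of quantiles (non-negative unless `lenient`).
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param alpha positive scale parameter.
#' @param lam positive shape parameter.
#' @param log logical; if `TRUE` the log-density is returned.
#' @param lenient logical; permit out-of-support input (see Details).
#' @param seed optional integer seed for a reproducible draw; the caller's
#'   RNG state is left untouched.
#' @param r positive integer moment order.
#' @param rel.tol relative tolerance passed to the adaptive quadrature used
#'   for moments.
#'
#' @return `dphld` the (log-)density, `pphld` the distribution function,
#'   `qphld` the quantile function, `rphld` a vector of `n` draws, and
#'   `phld_moment` the raw moment \eqn{E[X^r]} as a single number.
#'
#' @examples
#' dphld(0, alpha = 1, lam = 1)            # alpha*lam / (2*(e - 1))
#' pphld(qphld(0.37, 2, 3.7), 2, 3.7)      # 0.37
#' mean(rphld(2000, 1, 1, seed = 1))       # close to phld_moment(1, 1, 1)
#' phld_moment(1, 1, 1)
#' @name phld
NULL

.check_phld_params <- function(alpha, lam) {
  .check_pos_scalar(alpha, "alpha")
  .check_pos_scalar(lam, "lam")
}

# Half-logistic distribution-function kernel Delta(x) = tanh(alpha x / 2).
.delta_kernel <- function(x, alpha) tanh(alpha * x / 2)

#' @rdname phld
#' @export
dphld <- function(x, alpha, lam, log = FALSE, lenient = FALSE) {
  .check_phld_params(alpha, lam)
  if (any(!is.finite(x))) stop("'x' must be finite", call. = FALSE)
  neg <- x < 0
  if (any(neg) && !lenient) {
    stop("'x' must be non-negative (use lenient = TRUE to map x < 0 to 0)",
         call. = FALSE)
  }
  xx <- pmax(x, 0)
  logf <- log(2) + log(alpha) + log(lam) - alpha * xx +
    lam * .delta_kernel(xx, alpha) - .logexpm1(lam) -
    2 * log1p(exp(-alpha * xx))
  logf[neg] <- -Inf
  if (log) logf else exp(logf)
}

#' @rdname phld
#' @export
pphld <- function(q, alpha, lam, lenient = FALSE) {
  .check_phld_params(alpha, lam)
  if (any(!is.finite(q) & !(q == Inf))) stop("'q' must be finite or Inf", call. = FALSE)
  neg <- q < 0
  if (any(neg) && !lenient) {
    stop("'q' must be non-negative (use lenient = TRUE to map q < 0 to 0)",
         call. = FALSE)
  }
  xx <- pmax(q, 0)
  d <- .delta_kernel(xx, alpha)
  out <- numeric(length(xx))
  pos <- d > 0
  # F = expm1(lam * Delta) / expm1(lam) evaluated in the log domain so that
  # large shapes cannot overflow.
  out[pos] <- exp(.logexpm1(lam * d[pos]) - .logexpm1(lam))
  out[xx == Inf] <- 1
  out[neg] <- 0
  pmin(out, 1)
}

#' @rdname phld
#' @export
qphld <- function(p, alpha, lam, lenient = FALSE) {
  .check_phld_params(alpha, lam)
  if (any(!is.finite(p))) stop("'p' must be finite", call. = FALSE)
  bad <- p < 0 | p > 1 | (!lenient & (p == 0 | p == 1))
  if (any(bad)) {
    stop("'p' must lie in (0, 1) (lenient = TRUE admits the endpoints)",
         call. = FALSE)
  }
  # xi = log(p * (e^lam - 1) + 1) / lam; for very large shapes switch to the
  # logarithmic form log(p) + lam + log1p(...) to avoid overflow of expm1.
  if (lam < 700) {
    xi <- log1p(p * expm1(lam)) / lam
  } else {
    xi <- ifelse(p == 0, 0,
                 (log(p) + lam + log1p((1 - p) * exp(-lam) / pmax(p, 1e-300))) / lam)
  }
  out <- 2 / alpha * atanh(pmin(xi, 1))
  out[p == 0] <- 0
  out[p == 1] <- Inf
  out
}

#' @rdname phld
#' @export
rphld <- function(n, alpha, lam, seed = NULL) {
  .check_phld_params(alpha, lam)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  .with_seed(seed, qphld(stats::runif(n), alpha, lam))
}

#' @rdname phld
#' @export
phld_moment <- function(r, alpha, lam, rel.tol = 1e-10) {
  .check_phld_params(alpha, lam)
  if (!is.numeric(r) || length(r) != 1L || r < 1 || r != round(r)) {
    stop("'r' must be a positive integer", call. = FALSE)
  }
  res <- tryCatch(
    stats::integrate(function(x) x^r * dphld(x, alpha, lam), 0, Inf,
                     rel.tol = rel.tol, subdivisions = 400L),
    error = function(e) stop("moment quadrature failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (res$message != "OK") {
    stop("moment quadrature did not converge: ", res$message, call. = FALSE)
  }
  res$value
}
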