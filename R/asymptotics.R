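# Information matrices, auxiliary integrals, the gradient of R and the
# delta-method confidence interval.
#
# The auxiliary integrals below each have two evaluation routes: adaptive
# quadrature (authoritative throughout the package) and a series expansion
# of the integrand's exponential and binomial kernels.  The binomial index
# sums sit at the boundary of their disc of convergence and are therefore
# only Abel summable; they are evaluated with the accelerated
# alternating-series scheme in `.altsum()` rather than bare truncation.

#' Auxiliary integral for the expected information elements
#'
#' Computes
#' \deqn{\nabla(\alpha, \gamma_1, \gamma_2, \gamma_3, \gamma_4) =
#'   \int_0^\infty \frac{x^{\gamma_1} e^{-\gamma_2 \alpha x +
#'   \gamma_4 \Delta(x)}}{(1 + e^{-\alpha x})^{\gamma_3}}\, dx,}
#' the building block of every expected-information element.  The series
#' route expands \eqn{e^{\gamma_4 \Delta}} (absolutely convergent, truncated
#' by `tol`) and the binomial kernel (alternating, accelerated) and
#' assembles polygamma-weighted beta terms: for \eqn{\gamma_1 \in \{1, 2\}}
#' the beta-function derivatives reduce to digamma/trigamma differences.
#'
#' @param alpha positive scale.
#' @param g1 power of x (0, 1 or 2 for the series route).
#' @param g2 exponential rate multiplier (positive).
#' @param g3 integer power of the binomial kernel.
#' @param g4 coefficient of \eqn{\Delta(x)} in the exponent (non-negative).
#' @param method `"quadrature"` (authoritative) or `"series"`.
#' @param ctrl a [series_control()] for the series route.
#' @return The integral value.
#' @export
nabla_integral <- function(alpha, g1, g2, g3, g4,
                           method = c("quadrature", "series"),
                           ctrl = series_control()) {
  method <- match.arg(method)
  .check_pos_scalar(alpha, "alpha")
  stopifnot(g1 >= 0, g1 == round(g1), g2 > 0, g3 >= 0, g3 == round(g3), g4 >= 0)
  if (method == "quadrature") {
    res <- stats::integrate(function(x) {
      x^g1 * exp(-g2 * alpha * x + g4 * .delta_kernel(x, alpha)) /
        (1 + exp(-alpha * x))^g3
    }, 0, Inf, rel.tol = 1e-12, subdivisions = 400L)
    if (res$message != "OK") stop("nabla quadrature failed: ", res$message,
                                  call. = FALSE)
    return(res$value)
  }
  if (!g1 %in% 0:2) {
    stop("series route implemented for g1 in {0, 1, 2}", call. = FALSE)
  }
  tot <- 0
  for (m in 0:ctrl$max_index) {
    ssum <- .altsum(function(s) {
      a <- m + 1
      b <- g2 + s
      base <- exp(lchoose(g3 + m + s - 1, s) + lbeta(a, b))
      if (g1 == 0) return(base)
      dd <- digamma(b) - digamma(a + b)
      if (g1 == 1) return(-base * dd)
      base * (dd^2 + trigamma(b) - trigamma(a + b))
    }, n = ctrl$accel_terms)
    term <- g4^m / factorial(m) / alpha^(g1 + 1) * ssum
    tot <- tot + term
    if (m > 2 && abs(term) < ctrl$tail_tol * max(abs(tot), 1e-300)) {
      return(tot)
    }
  }
  stop("nabla series did not converge within max_index", call. = FALSE)
}

# Coefficients |h_t| of (1-z)^A (1+z)^{-B} = sum_t (-1)^t |h_t| z^t for
# integer A >= 0, real B >= 0, t = 0..M.
.binprod_coefs <- function(A, B, M) {
  vapply(0:M, function(t) {
    a <- 0:min(A, t)
    sum(exp(lchoose(A, a) + lchoose(B + (t - a) - 1, t - a)))
  }, numeric(1))
}

#' General-case auxiliary integral for the gradient of R
#'
#' Computes
#' \deqn{\zeta(\Theta) = \int_0^\infty x^{\delta_1}
#'   \frac{(1-e^{-\alpha_1 x})^{\delta_3} (1-e^{-\alpha_2 x})^{\delta_4}}
#'        {(1+e^{-\alpha_1 x})^{\delta_5} (1+e^{-\alpha_2 x})^{\delta_6}}
#'   e^{-\delta_2 x + \lambda_1 \Delta_1(x) + \lambda_2 \Delta_2(x)}\, dx}
#' by adaptive quadrature (authoritative) or by a double-exponential series
#' with accelerated alternating binomial sums (cross-check).  `delta[2]` is
#' the absolute exponential rate.
#'
#' @param alpha1,alpha2,lambda1,lambda2 positive marginal parameters.
#' @param delta numeric vector `(delta1, ..., delta6)`; `delta1`, `delta3`,
#'   `delta4` non-negative integers, `delta2 > 0`, `delta5`, `delta6 >= 0`.
#' @param method `"quadrature"` or `"series"`.
#' @param ctrl a [series_control()].
#' @return The integral value.
#' @export
zeta_integral <- function(alpha1, alpha2, lambda1, lambda2, delta,
                          method = c("quadrature", "series"),
                          ctrl = series_control()) {
  method <- match.arg(method)
  stopifnot(length(delta) == 6, all(is.finite(delta)), delta[2] > 0,
            all(delta[-2] >= 0))
  d <- delta
  if (method == "quadrature") {
    res <- stats::integrate(function(x) {
      z1 <- exp(-alpha1 * x); z2 <- exp(-alpha2 * x)
      x^d[1] * (1 - z1)^d[3] * (1 - z2)^d[4] / ((1 + z1)^d[5] * (1 + z2)^d[6]) *
        exp(-d[2] * x + lambda1 * .delta_kernel(x, alpha1) +
              lambda2 * .delta_kernel(x, alpha2))
    }, 0, Inf, rel.tol = 1e-12, subdivisions = 400L)
    if (res$message != "OK") stop("zeta quadrature failed: ", res$message,
                                  call. = FALSE)
    return(res$value)
  }
  if (!d[1] %in% 0:2) {
    stop("series route implemented for delta1 in {0, 1, 2}", call. = FALSE)
  }
  # Substituting v = 1 - e^{-alpha1 x} maps each term of the double
  # exponential expansion to
  #   (1/alpha1^{d1+1}) int_0^1 (-log(1-v))^{d1} v^{d3+i} (1-v)^{d2/a1 - 1}
  #     (2-v)^{-(d5+i)} Phi_j(v) dv,
  # with Phi_j the second marginal's kernel in powers of (1-v)^{a2/a1}.
  # The (2-v) factor expands about v = 0 with positive geometric terms; the
  # Phi_j expansion alternates at the boundary of convergence and is
  # evaluated with the accelerated scheme, its coefficient growth being
  # offset by the beta-function decay in the m index.
  nacc <- ctrl$accel_terms
  br <- alpha2 / alpha1
  b0 <- d[2] / alpha1
  m_idx <- 0:(nacc - 1L)
  tot <- 0
  for (j in 0:ctrl$max_index) {
    wj <- lambda2^j / factorial(j)
    c2 <- .binprod_coefs(d[4] + j, d[6] + j, nacc - 1L)
    jt <- 0
    for (i in 0:ctrl$max_index) {
      wi <- lambda1^i / factorial(i)
      ksum <- 0
      for (k in 0:(ctrl$max_index * 4L)) {
        wk <- exp(lchoose(d[5] + i + k - 1, k) - (d[5] + i + k) * log(2))
        mval <- .altsum_vec(c2 * .beta_dlog(d[3] + i + k + 1, b0 + br * m_idx, d[1]))
        kterm <- wk * mval
        ksum <- ksum + kterm
        if (k > 3 && abs(kterm) < 1e-16 * max(abs(ksum), 1e-300)) break
      }
      term <- wi * wj * ksum / alpha1^(d[1] + 1)
      jt <- jt + term
      if (i > 2 && abs(term) < ctrl$tail_tol) break
    }
    tot <- tot + jt
    if (j > 2 && abs(jt) < ctrl$tail_tol) return(tot)
  }
  stop("zeta series did not converge within max_index", call. = FALSE)
}

# int_0^1 v^{a-1} (1-v)^{b-1} (-log(1-v))^{d1} dv for d1 in {0, 1, 2}:
# the d1-th derivative of the beta function in its second argument, up to
# sign.  Vectorized over `b`.
.beta_dlog <- function(a, b, d1) {
  base <- exp(lbeta(a, b))
  if (d1 == 0) return(base)
  dd <- digamma(a + b) - digamma(b)
  if (d1 == 1) return(base * dd)
  base * (dd^2 + trigamma(b) - trigamma(a + b))
}

#' Common-scale auxiliary integral for the gradient of R
#'
#' Computes
#' \deqn{\zeta^*(\Theta^*) = \int_0^\infty x^{\delta_1}
#'   e^{-\delta_2 \alpha x + (\lambda_1+\lambda_2) \Delta(x)}
#'   \frac{(1-e^{-\alpha x})^{\delta_3}}{(1+e^{-\alpha x})^{\delta_4}}\, dx,}
#' where `d2` multiplies the scale in the exponential rate.  Quadrature is
#' authoritative; the series route mirrors [zeta_integral()] with a single
#' binomial kernel.
#'
#' @param alpha,lambda1,lambda2 positive parameters.
#' @param d1 non-negative integer power of x.
#' @param d2 positive rate multiplier.
#' @param d3 non-negative integer numerator power.
#' @param d4 non-negative denominator power.
#' @param method `"quadrature"` or `"series"`.
#' @param ctrl a [series_control()].
#' @return The integral value.
#' @export
zeta_star_integral <- function(alpha, lambda1, lambda2, d1, d2, d3, d4,
                               method = c("quadrature", "series"),
                               ctrl = series_control()) {
  method <- match.arg(method)
  stopifnot(d1 >= 0, d1 == round(d1), d2 > 0, d3 >= 0, d3 == round(d3), d4 >= 0)
  s <- lambda1 + lambda2
  if (method == "quadrature") {
    res <- stats::integrate(function(x) {
      z <- exp(-alpha * x)
      x^d1 * exp(-d2 * alpha * x + s * .delta_kernel(x, alpha)) *
        (1 - z)^d3 / (1 + z)^d4
    }, 0, Inf, rel.tol = 1e-12, subdivisions = 400L)
    if (res$message != "OK") stop("zeta* quadrature failed: ", res$message,
                                  call. = FALSE)
    return(res$value)
  }
  # With a single marginal the v = 1 - e^{-alpha x} substitution leaves only
  # the positive geometric expansion of (2-v)^{-(d4+i)}: every term is
  # positive and the series is absolutely convergent.
  if (!d1 %in% 0:2) {
    stop("series route implemented for d1 in {0, 1, 2}", call. = FALSE)
  }
  tot <- 0
  for (i in 0:ctrl$max_index) {
    ksum <- 0
    for (k in 0:(ctrl$max_index * 4L)) {
      kterm <- exp(lchoose(d4 + i + k - 1, k) - (d4 + i + k) * log(2)) *
        .beta_dlog(d3 + i + k + 1, d2, d1)
      ksum <- ksum + kterm
      if (k > 3 && kterm < 1e-16 * max(ksum, 1e-300)) break
    }
    term <- s^i / factorial(i) / alpha^(d1 + 1) * ksum
    tot <- tot + term
    if (i > 2 && abs(term) < ctrl$tail_tol) return(tot)
  }
  stop("zeta* series did not converge within max_index", call. = FALSE)
}

#' Observed information at the maximum-likelihood estimate
#'
#' The negative Hessian of the log-likelihood at the fitted parameters,
#' obtained by central finite differences of the analytic score with step
#' \eqn{h = \epsilon^{1/3} \max(|\theta|, 1)}.  This is the default
#' information source for real-data confidence intervals.
#'
#' @param fit a converged [fit_general()] or [fit_common()] result.
#' @param data optional [ss_data()] to evaluate on (defaults to the fit's).
#' @return An object of class `"info_matrix"`: the symmetric matrix with
#'   attributes `kind = "observed_numeric"` and `pd` (positive definite?).
#'   A non-positive-definite result at an interior optimum triggers a
#'   warning and is flagged via `pd = FALSE`.
#' @export
observed_information <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "phld_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (is.null(data)) data <- fit$data
  theta <- unname(fit$theta_hat)
  score <- if (fit$model == "general") score_general else score_common
  p <- length(theta)
  # step kept below theta/2 so boundary fits (tiny shapes) stay feasible
  h <- pmin(.Machine$double.eps^(1/3) * pmax(abs(theta), 1), theta / 2)
  J <- matrix(0, p, p)
  for (j in seq_len(p)) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h[j]; tm[j] <- tm[j] - h[j]
    J[, j] <- (score(tp, data) - score(tm, data)) / (2 * h[j])
  }
  I <- -(J + t(J)) / 2
  pd <- !inherits(tryCatch(chol(I), error = function(e) e), "error")
  if (!pd) warning("observed information is not positive definite; ",
                   "a pseudo-inverse will be used downstream")
  dimnames(I) <- list(names(fit$theta_hat), names(fit$theta_hat))
  structure(I, kind = "observed_numeric", pd = pd, class = "info_matrix")
}

# Per-observation expected-information entries for one PHLD marginal.
.expected_info_one <- function(alpha, lam, method = "quadrature") {
  E <- expm1(lam)
  nb <- function(g1, g2, g3, g4) nabla_integral(alpha, g1, g2, g3, g4,
                                                method = method)
  i_aa <- 1 / alpha^2 + (4 * alpha * lam / E) *
    (nb(2, 2, 3, lam) - nb(2, 3, 4, lam) +
       lam * nb(2, 2, 4, lam) - 2 * lam * nb(2, 3, 5, lam))
  i_al <- -(4 * alpha * lam / E) * nb(1, 2, 4, lam)
  i_ll <- 1 / lam^2 - exp(lam) / E^2
  list(aa = i_aa, al = i_al, ll = i_ll)
}

#' Expected (Fisher) information matrix
#'
#' Assembles \eqn{I(\theta) = -E[\partial^2 \log L / \partial\theta
#' \partial\theta^T]} from [nabla_integral()] terms.  In the general model
#' the matrix is block diagonal across the (alpha1, lambda1) and
#' (alpha2, lambda2) blocks because the likelihood separates; all cross
#' terms are exactly zero.  Signs are those of \eqn{-E[J(\theta)]}, so the
#' matrix is positive definite for admissible parameters.
#'
#' @param theta parameter vector (length 4 general: alpha1, alpha2, lambda1,
#'   lambda2; length 3 common: alpha, lambda1, lambda2).
#' @param n1,n2 sample sizes.
#' @param model `"general"` or `"common"`.
#' @param method integral route passed to [nabla_integral()].
#' @return An `"info_matrix"` with attribute `kind = "expected_series"`.
#' @export
expected_information <- function(theta, n1, n2, model = c("general", "common"),
                                 method = "quadrature") {
  model <- match.arg(model)
  stopifnot(n1 >= 1, n2 >= 1)
  if (model == "general") {
    .check_theta(theta, 4L)
    b1 <- .expected_info_one(theta[1], theta[3], method)
    b2 <- .expected_info_one(theta[2], theta[4], method)
    I <- matrix(0, 4, 4)
    I[1, 1] <- n1 * b1$aa; I[3, 3] <- n1 * b1$ll
    I[1, 3] <- I[3, 1] <- n1 * b1$al
    I[2, 2] <- n2 * b2$aa; I[4, 4] <- n2 * b2$ll
    I[2, 4] <- I[4, 2] <- n2 * b2$al
    dimnames(I) <- list(c("alpha1", "alpha2", "lambda1", "lambda2"),
                        c("alpha1", "alpha2", "lambda1", "lambda2"))
  } else {
    .check_theta(theta, 3L)
    b1 <- .expected_info_one(theta[1], theta[2], method)
    b2 <- .expected_info_one(theta[1], theta[3], method)
    I <- matrix(0, 3, 3)
    I[1, 1] <- (n1 + n2) / theta[1]^2 +
      n1 * (b1$aa - 1 / theta[1]^2) + n2 * (b2$aa - 1 / theta[1]^2)
    I[2, 2] <- n1 * b1$ll
    I[3, 3] <- n2 * b2$ll
    I[1, 2] <- I[2, 1] <- n1 * b1$al
    I[1, 3] <- I[3, 1] <- n2 * b2$al
    dimnames(I) <- list(c("alpha", "lambda1", "lambda2"),
                        c("alpha", "lambda1", "lambda2"))
  }
  pd <- !inherits(tryCatch(chol(I), error = function(e) e), "error")
  structure(I, kind = "expected_series", pd = pd, class = "info_matrix")
}

#' Gradient of the reliability with respect to the model parameters
#'
#' Numeric mode (authoritative) takes central differences of
#' [reliability_quadrature()]; analytic mode assembles the gradient from
#' [zeta_integral()] (general case) or [zeta_star_integral()] (common
#' scale).  The two modes must agree to `1e-4` or an error naming both
#' values is raised.  In the common-scale case the gradient has two
#' components, \eqn{(\partial R/\partial\lambda_1,
#' \partial R/\partial\lambda_2)}: R does not depend on the shared scale.
#'
#' @param spec an [ss_spec()].
#' @param method `"numeric"` or `"analytic"`.
#' @return Named gradient vector (length 4, or 2 when `spec$common_scale`).
#' @export
grad_R <- function(spec, method = c("numeric", "analytic")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "ss_spec"))
  a1 <- spec$alpha1; a2 <- spec$alpha2
  l1 <- spec$lambda1; l2 <- spec$lambda2
  if (spec$common_scale) {
    if (method == "numeric") {
      g <- vapply(1:2, function(k) {
        th <- c(l1, l2)
        h <- min(.Machine$double.eps^(1/3) * max(abs(th[k]), 1), th[k] / 2)
        tp <- th; tm <- th
        tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
        (reliability_quadrature(ss_spec(a1, a1, tp[1], tp[2])) -
            reliability_quadrature(ss_spec(a1, a1, tm[1], tm[2]))) / (2 * h)
      }, numeric(1))
      return(c(dlambda1 = g[1], dlambda2 = g[2]))
    }
    E1 <- expm1(l1); E2 <- expm1(l2)
    cc <- 2 * a1 * l1 / (E1 * E2)
    zs <- function(d1, d2, d3, d4) zeta_star_integral(a1, l1, l2, d1, d2, d3, d4)
    K <- cc * zs(0, 1, 0, 2)
    g1 <- K / l1 - K * exp(l1) / E1 + cc * zs(0, 1, 1, 3)
    g2 <- -K * exp(l2) / E2 + cc * zs(0, 1, 1, 3) + exp(l2) / E2^2
    num <- grad_R(spec, "numeric")
    ana <- c(dlambda1 = g1, dlambda2 = g2)
    if (max(abs(num - ana)) > 1e-4) {
      stop(sprintf("analytic/numeric gradient disagreement: (%s) vs (%s)",
                   paste(signif(ana, 8), collapse = ", "),
                   paste(signif(num, 8), collapse = ", ")), call. = FALSE)
    }
    return(ana)
  }
  if (method == "numeric") {
    th <- c(a1, a2, l1, l2)
    g <- vapply(1:4, function(k) {
      h <- min(.Machine$double.eps^(1/3) * max(abs(th[k]), 1), th[k] / 2)
      tp <- th; tm <- th
      tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
      (reliability_quadrature(ss_spec(tp[1], tp[2], tp[3], tp[4])) -
          reliability_quadrature(ss_spec(tm[1], tm[2], tm[3], tm[4]))) / (2 * h)
    }, numeric(1))
    return(c(dalpha1 = g[1], dalpha2 = g[2], dlambda1 = g[3], dlambda2 = g[4]))
  }
  E1 <- expm1(l1); E2 <- expm1(l2)
  cc <- 2 * a1 * l1 / (E1 * E2)
  zq <- function(d1, d2, d3, d4, d5, d6) {
    zeta_integral(a1, a2, l1, l2, c(d1, d2, d3, d4, d5, d6))
  }
  K <- cc * zq(0, a1, 0, 0, 2, 0)
  ga1 <- K / a1 - cc * zq(1, a1, 0, 0, 2, 0) +
    2 * cc * zq(1, 2 * a1, 0, 0, 3, 0) + 2 * l1 * cc * zq(1, 2 * a1, 0, 0, 4, 0)
  ga2 <- 2 * l2 * cc * zq(1, a1 + a2, 0, 0, 2, 2)
  gl1 <- K / l1 - K * exp(l1) / E1 + cc * zq(0, a1, 1, 0, 3, 0)
  gl2 <- -K * exp(l2) / E2 + cc * zq(0, a1, 0, 1, 2, 1) + exp(l2) / E2^2
  ana <- c(dalpha1 = ga1, dalpha2 = ga2, dlambda1 = gl1, dlambda2 = gl2)
  num <- grad_R(spec, "numeric")
  if (max(abs(num - ana)) > 1e-4) {
    stop(sprintf("analytic/numeric gradient disagreement: (%s) vs (%s)",
                 paste(signif(ana, 8), collapse = ", "),
                 paste(signif(num, 8), collapse = ", ")), call. = FALSE)
  }
  ana
}

#' Delta-method variance and asymptotic confidence interval for R
#'
#' `var_R_delta` computes \eqn{\widehat{\mathrm{Var}}(\hat R) =
#' B(\hat\theta)^T I^{-1} B(\hat\theta)} with \eqn{B} the gradient of R at
#' the fitted parameters and \eqn{I} an information matrix;
#' `asymptotic_ci` turns it into the normal interval
#' \eqn{\hat R \pm z_{\epsilon/2} \sqrt{\mathrm{Var}}}, with endpoints
#' clipped to \[0, 1\] (clipping is flagged on the returned object).
#'
#' @param fit a converged [fit_general()] or [fit_common()] result.
#' @param info an `"info_matrix"`, e.g. from [observed_information()].
#' @return `var_R_delta` a positive number.
#' @export
var_R_delta <- function(fit, info) {
  stopifnot(inherits(fit, "phld_fit"), inherits(info, "info_matrix"))
  th <- fit$theta_hat
  if (fit$model == "general") {
    spec <- ss_spec(th[["alpha1"]], th[["alpha2"]], th[["lambda1"]], th[["lambda2"]])
    B <- unname(grad_R(spec, "numeric"))
  } else {
    spec <- ss_spec(th[["alpha"]], th[["alpha"]], th[["lambda1"]], th[["lambda2"]],
                    common_scale = TRUE)
    B <- c(0, unname(grad_R(spec, "numeric")))  # dR/dalpha = 0
  }
  Iinv <- if (isTRUE(attr(info, "pd"))) {
    solve(unclass(info))
  } else {
    pracma::pinv(unclass(info))
  }
  v <- drop(t(B) %*% Iinv %*% B)
  if (!is.finite(v) || v < 0) stop("delta-method variance is not positive",
                                   call. = FALSE)
  v
}

#' @rdname var_R_delta
#' @param r_hat point estimate of R.
#' @param var delta-method variance from `var_R_delta`.
#' @param level nominal coverage (default 0.95).
#' @return `asymptotic_ci` an [interval_estimate()].
#' @export
asymptotic_ci <- function(r_hat, var, level = 0.95) {
  stopifnot(is.finite(r_hat), is.finite(var), var >= 0, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- r_hat - z * sqrt(var)
  hi <- r_hat + z * sqrt(var)
  clipped <- lo < 0 || hi > 1
  interval_estimate(max(lo, 0), min(hi, 1), level, "asymptotic", clipped)
}
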