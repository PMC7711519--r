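#' Bundle a strength sample and a stress sample
#'
#' @param x numeric vector of strengths (all positive and finite).
#' @param y numeric vector of stresses (all positive and finite).
#' @return An object of class `"ss_data"` with elements `x`, `y`, `n1`, `n2`.
#' @examples
#' ss_data(c(1.2, 0.8, 1.5), c(0.9, 1.1))
#' @export
ss_data <- function(x, y) {
  for (nm in c("x", "y")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) < 1L || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("'%s' must be a non-empty vector of finite positive values", nm),
           call. = FALSE)
    }
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 n1 = length(x), n2 = length(y)),
            class = "ss_data")
}

#' Read a one-value-per-line numeric sample
#'
#' Accepts plain text or single-column CSV: one numeric value per line, blank
#' lines and `#` comments ignored, decimal point locale-independent.
#'
#' @param path file path.
#' @return Numeric vector.
#' @export
read_sample <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  if (any(is.na(vals))) {
    stop("non-numeric entries in ", path, call. = FALSE)
  }
  vals
}

# Per-sample log-likelihood and its gradient in (alpha, lam); every
# two-sample log-likelihood in the package is a sum of two of these.
.ll_one <- function(alpha, lam, v) {
  sum(dphld(v, alpha, lam, log = TRUE))
}

.score_one <- function(alpha, lam, v) {
  z <- exp(-alpha * v)
  d_alpha <- length(v) / alpha - sum(v) + 2 * sum(v * z / (1 + z)) +
    2 * lam * sum(v * z / (1 + z)^2)
  d_lam <- length(v) / lam - length(v) * exp(lam) / expm1(lam) +
    sum(.delta_kernel(v, alpha))
  c(d_alpha, d_lam)
}

.check_theta <- function(theta, p) {
  if (!is.numeric(theta) || length(theta) != p || any(!is.finite(theta)) ||
      any(theta <= 0)) {
    stop(sprintf("'theta' must be a vector of %d finite positive values", p),
         call. = FALSE)
  }
}

#' Log-likelihood and score of the general four-parameter model
#'
#' The joint log-likelihood of the strength sample under
#' \eqn{\mathrm{PHLD}(\alpha_1, \lambda_1)} and the stress sample under
#' \eqn{\mathrm{PHLD}(\alpha_2, \lambda_2)}; it separates into an x-block and
#' a y-block.  `score_general` is the analytic gradient.
#'
#' @param theta parameter vector `(alpha1, alpha2, lambda1, lambda2)`, all
#'   positive.
#' @param data an [ss_data()].
#' @return `loglik_general` a number; `score_general` a length-4 vector.
#' @export
loglik_general <- function(theta, data) {
  stopifnot(inherits(data, "ss_data"))
  .check_theta(theta, 4L)
  .ll_one(theta[1], theta[3], data$x) + .ll_one(theta[2], theta[4], data$y)
}

#' @rdname loglik_general
#' @export
score_general <- function(theta, data) {
  stopifnot(inherits(data, "ss_data"))
  .check_theta(theta, 4L)
  sx <- .score_one(theta[1], theta[3], data$x)
  sy <- .score_one(theta[2], theta[4], data$y)
  c(sx[1], sy[1], sx[2], sy[2])
}

#' Log-likelihood and score of the common-scale model
#'
#' Both samples share the scale \eqn{\alpha}; `theta` is
#' `(alpha, lambda1, lambda2)`.  The maximized value can never exceed the
#' general model's (the models are nested).
#'
#' @param theta parameter vector `(alpha, lambda1, lambda2)`, all positive.
#' @param data an [ss_data()].
#' @return `loglik_common` a number; `score_common` a length-3 vector.
#' @export
loglik_common <- function(theta, data) {
  stopifnot(inherits(data, "ss_data"))
  .check_theta(theta, 3L)
  .ll_one(theta[1], theta[2], data$x) + .ll_one(theta[1], theta[3], data$y)
}

#' @rdname loglik_common
#' @export
score_common <- function(theta, data) {
  stopifnot(inherits(data, "ss_data"))
  .check_theta(theta, 3L)
  sx <- .score_one(theta[1], theta[2], data$x)
  sy <- .score_one(theta[1], theta[3], data$y)
  c(sx[1] + sy[1], sx[2], sy[2])
}

# Convergence check shared by the fitters: the gradient in the log
# parameterization (theta * score), projected onto the feasible box so that
# a shape heading to its lower bound (the half-logistic limit lam -> 0)
# still registers as a converged boundary solution.
.log_bound <- 30
.converged_at <- function(par, g_log) {
  if (!all(is.finite(g_log))) return(FALSE)
  at_lo <- par <= -.log_bound + 1e-8
  at_hi <- par >= .log_bound - 1e-8
  g_log[at_lo & g_log > 0] <- 0  # pushing further out of the box
  g_log[at_hi & g_log < 0] <- 0
  sqrt(sum(g_log^2)) < 1e-4
}

# Maximize one marginal's log-likelihood over (alpha, lam): L-BFGS-B on
# log-parameters (so positivity needs no constraint handling) with the
# analytic gradient mapped through the chain rule.  Default start alpha0 =
# log(3)/median(v) (the shape-free half-logistic median relation), lam0 = 1;
# a small log-grid multi-start backs it up.
.fit_one <- function(v, init = NULL) {
  obj <- function(par) {
    th <- exp(par)
    val <- -.ll_one(th[1], th[2], v)
    if (!is.finite(val)) 1e10 else val
  }
  grad <- function(par) {
    th <- exp(par)
    s <- .score_one(th[1], th[2], v)
    if (!all(is.finite(s))) return(c(0, 0))
    -s * th  # d/d log(theta) = theta * d/d theta
  }
  starts <- list(if (is.null(init)) c(log(log(3) / stats::median(v)), 0)
                 else log(init))
  grid <- expand.grid(a = c(-1, 0, 1), l = c(-1, 0, 1))
  for (g in seq_len(nrow(grid))) {
    starts[[length(starts) + 1L]] <- starts[[1L]] + c(grid$a[g], grid$l[g])
  }
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, obj, grad, method = "L-BFGS-B",
                   lower = -.log_bound, upper = .log_bound,
                   control = list(factr = 10, maxit = 500L)),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value)) next
    ok <- o$convergence == 0 && .converged_at(o$par, -grad(o$par))
    if (isTRUE(ok)) {
      best <- o
      break
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    stop("marginal fit failed for every start", call. = FALSE)
  }
  list(par = exp(best$par), loglik = -best$value,
       counts = unname(best$counts[1]),
       converged = isTRUE(best$convergence == 0 &&
                            .converged_at(best$par, -grad(best$par))))
}

#' Maximum-likelihood fit of the stress-strength models
#'
#' `fit_general` maximizes the four-parameter log-likelihood, which separates
#' into two independent two-parameter problems solved marginally;
#' `fit_common` maximizes the three-parameter common-scale log-likelihood
#' jointly.
#'
#' @param data an [ss_data()]; both samples need at least two observations.
#' @param init optional starting values on the parameter scale (length 4 for
#'   the general model, 3 for the common-scale model).
#' @return An object of class `"phld_fit"`: a list with `theta_hat` (named),
#'   `loglik`, `converged`, `n_iter`, `model` and the `data` used.
#' @examples
#' d <- generate_synthetic(ss_spec(2, 1.9, 3.7, 3.8), 50, 50, seed = 1)
#' fit_general(d)
#' @export
fit_general <- function(data, init = NULL) {
  stopifnot(inherits(data, "ss_data"))
  if (data$n1 < 2L || data$n2 < 2L) {
    stop("fitting requires at least two observations per sample", call. = FALSE)
  }
  if (!is.null(init)) .check_theta(init, 4L)
  fx <- .fit_one(data$x, if (is.null(init)) NULL else init[c(1, 3)])
  fy <- .fit_one(data$y, if (is.null(init)) NULL else init[c(2, 4)])
  theta <- c(alpha1 = fx$par[1], alpha2 = fy$par[1],
             lambda1 = fx$par[2], lambda2 = fy$par[2])
  structure(list(theta_hat = theta, loglik = fx$loglik + fy$loglik,
                 converged = fx$converged && fy$converged,
                 n_iter = fx$counts + fy$counts,
                 model = "general", data = data),
            class = "phld_fit")
}

#' @rdname fit_general
#' @export
fit_common <- function(data, init = NULL) {
  stopifnot(inherits(data, "ss_data"))
  if (data$n1 < 2L || data$n2 < 2L) {
    stop("fitting requires at least two observations per sample", call. = FALSE)
  }
  if (!is.null(init)) .check_theta(init, 3L)
  obj <- function(par) {
    th <- exp(par)
    val <- -loglik_common(th, data)
    if (!is.finite(val)) 1e10 else val
  }
  grad <- function(par) {
    th <- exp(par)
    s <- score_common(th, data)
    if (!all(is.finite(s))) return(c(0, 0, 0))
    -s * th
  }
  start <- if (is.null(init)) {
    c(log(log(3) / stats::median(c(data$x, data$y))), 0, 0)
  } else log(init)
  starts <- list(start)
  for (da in c(-1, 1)) starts[[length(starts) + 1L]] <- start + c(da, 0, 0)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, obj, grad, method = "L-BFGS-B",
                               lower = -.log_bound, upper = .log_bound,
                               control = list(factr = 10, maxit = 500L)),
                  error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value)) next
    if (is.null(best) || o$value < best$value) best <- o
    if (o$convergence == 0 && .converged_at(o$par, -grad(o$par))) break
  }
  if (is.null(best)) stop("common-scale fit failed for every start", call. = FALSE)
  theta <- exp(best$par)
  names(theta) <- c("alpha", "lambda1", "lambda2")
  structure(list(theta_hat = theta, loglik = -best$value,
                 converged = isTRUE(best$convergence == 0 &&
                   .converged_at(best$par, -grad(best$par))),
                 n_iter = unname(best$counts[1]),
                 model = "common", data = data),
            class = "phld_fit")
}

#' @export
print.phld_fit <- function(x, ...) {
  cat(sprintf("PHLD stress-strength fit (%s model)\n", x$model))
  print(round(x$theta_hat, 4))
  cat(sprintf("log-likelihood: %.2f  (converged: %s, n1 = %d, n2 = %d)\n",
              x$loglik, x$converged, x$data$n1, x$data$n2))
  invisible(x)
}

#' Plug-in maximum-likelihood estimate of R
#'
#' By invariance of maximum likelihood, the MLE of the reliability is the
#' reliability evaluated at the fitted parameters: quadrature for the
#' general model, the shape-only representation for the common-scale model.
#'
#' @param fit a converged [fit_general()] or [fit_common()] result.
#' @return The estimated reliability in (0, 1).
#' @export
r_hat_from_fit <- function(fit) {
  stopifnot(inherits(fit, "phld_fit"))
  if (!fit$converged) stop("fit did not converge; refusing plug-in R", call. = FALSE)
  th <- fit$theta_hat
  if (fit$model == "general") {
    reliability_quadrature(ss_spec(th[["alpha1"]], th[["alpha2"]],
                                   th[["lambda1"]], th[["lambda2"]]))
  } else {
    reliability_common_scale(th[["lambda1"]], th[["lambda2"]])
  }
}

#' One-sample Kolmogorov-Smirnov statistic against a fitted PHLD
#'
#' The supremum distance between the empirical distribution function and the
#' PHLD distribution function at the supplied parameters, with the
#' asymptotic Kolmogorov p-value.  No correction is applied for parameters
#' having been estimated from the same sample, so the p-value is the plain
#' one-sample value and is optimistic when used after fitting.
#'
#' @param x numeric sample (positive values).
#' @param alpha,lam PHLD parameters.
#' @return List with `statistic` and `p.value`.
#' @export
ks_statistic <- function(x, alpha, lam) {
  if (length(x) < 1L) stop("empty sample", call. = FALSE)
  xs <- sort(x)
  n <- length(xs)
  fx <- pphld(xs, alpha, lam)
  d <- max(pmax(seq_len(n) / n - fx, fx - (seq_len(n) - 1) / n))
  # asymptotic Kolmogorov tail: P(sqrt(n) D > t) = 2 sum (-1)^{k-1} e^{-2k^2t^2}
  t <- sqrt(n) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  list(statistic = d, p.value = min(max(p, 0), 1))
}
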