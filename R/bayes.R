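# Gamma-prior Bayesian inference for R via Metropolis-Hastings within Gibbs.

#' Gamma prior specification
#'
#' Shape-rate gamma prior for one positive parameter.  The package default,
#' `Gamma(0.001, 0.001)`, is near-flat on the positive half-line.
#'
#' @param a shape (positive).
#' @param b rate (positive).
#' @return An object of class `"gamma_prior"`.
#' @export
gamma_prior <- function(a = 0.001, b = 0.001) {
  .check_pos_scalar(a, "a")
  .check_pos_scalar(b, "b")
  structure(list(a = a, b = b), class = "gamma_prior")
}

#' Sampler configuration
#'
#' @param n_iter total Metropolis-within-Gibbs iterations T (>= 10).
#' @param burn_in_frac fraction of iterations discarded as burn-in.
#' @param seed optional integer seed.
#' @param proposal_sd `"adaptive"` (tuned during burn-in towards 25-45%
#'   acceptance, then frozen so the kept chain is Markov) or a vector of
#'   per-parameter normal proposal standard deviations.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_iter = 10000L, burn_in_frac = 0.1, seed = NULL,
                        proposal_sd = "adaptive", thin = 1L) {
  stopifnot(n_iter >= 10, burn_in_frac >= 0, burn_in_frac < 1, thin >= 1)
  kept <- floor((n_iter - ceiling(burn_in_frac * n_iter)) / thin)
  if (kept < 1) stop("configuration leaves no post-burn-in draws", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in_frac = burn_in_frac,
                 seed = seed, proposal_sd = proposal_sd, thin = as.integer(thin)),
            class = "mcmc_config")
}

.expand_priors <- function(priors, p) {
  if (inherits(priors, "gamma_prior")) priors <- rep(list(priors), p)
  if (length(priors) != p || !all(vapply(priors, inherits, logical(1), "gamma_prior"))) {
    stop(sprintf("'priors' must be one gamma_prior or a list of %d", p),
         call. = FALSE)
  }
  priors
}

# Joint log-posterior (up to a constant): log-likelihood plus gamma prior
# log-kernels (a-1) log(theta) - b theta.
.log_posterior <- function(theta, data, priors, model) {
  if (any(theta <= 0)) return(-Inf)
  ll <- if (model == "general") loglik_general(theta, data)
        else loglik_common(theta, data)
  lp <- sum(vapply(seq_along(theta), function(k) {
    (priors[[k]]$a - 1) * log(theta[k]) - priors[[k]]$b * theta[k]
  }, numeric(1)))
  ll + lp
}

#' Full-conditional log-density of one parameter
#'
#' The log of the unnormalized full conditional of parameter `param_index`
#' given the others, the data and its gamma prior — the target of the
#' corresponding Metropolis-Hastings step.  In the general model the
#' (alpha1, lambda1) conditionals depend only on the strength sample and the
#' (alpha2, lambda2) conditionals only on the stress sample.  Non-positive
#' `value` returns `-Inf` (an automatic rejection), not an error.
#'
#' @param param_index coordinate index (1-4 general: alpha1, alpha2,
#'   lambda1, lambda2; 1-3 common: alpha, lambda1, lambda2).
#' @param value candidate value of that parameter.
#' @param other_params full parameter vector supplying the other coordinates.
#' @param data an [ss_data()].
#' @param priors a [gamma_prior()] or list of them (one per parameter).
#' @param model `"general"` or `"common"`.
#' @return Log-density up to an additive constant.
#' @export
log_conditional <- function(param_index, value, other_params, data, priors,
                            model = c("general", "common")) {
  model <- match.arg(model)
  p <- if (model == "general") 4L else 3L
  stopifnot(param_index >= 1, param_index <= p, length(other_params) == p)
  priors <- .expand_priors(priors, p)
  if (!is.finite(value) || value <= 0) return(-Inf)
  theta <- other_params
  theta[param_index] <- value
  .log_posterior(theta, data, priors, model)
}

#' Metropolis-Hastings-within-Gibbs sampler for the stress-strength model
#'
#' Componentwise random-walk Metropolis with normal proposals: each sweep
#' updates every parameter in turn against its full conditional
#' ([log_conditional()]); proposals at or below zero are rejected through a
#' `-Inf` target (the proposal is symmetric, so the standard ratio applies).
#' During burn-in the proposal scales adapt towards 25-45% acceptance
#' (stochastic-approximation updates of the log-sd) and are then frozen.
#' Each kept draw's reliability is evaluated with the fixed 201-node
#' Gauss-Legendre rule (general model) or the shape-only representation
#' (common scale).
#'
#' @param data an [ss_data()].
#' @param priors a [gamma_prior()] or list of them (one per parameter).
#' @param cfg an [mcmc_config()].
#' @param model `"general"` or `"common"`.
#' @param init optional starting parameter vector (defaults to the MLE).
#' @return An object of class `"posterior_draws"`: list with `params`
#'   (kept draws x p matrix), `r` (reliability per kept draw),
#'   `acceptance` (per-parameter rates over the kept phase), `model`, `cfg`.
#' @export
gibbs_sampler <- function(data, priors = gamma_prior(), cfg = mcmc_config(),
                          model = c("general", "common"), init = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(data, "ss_data"), inherits(cfg, "mcmc_config"))
  p <- if (model == "general") 4L else 3L
  priors <- .expand_priors(priors, p)
  if (is.null(init)) {
    fit0 <- if (model == "general") fit_general(data) else fit_common(data)
    init <- unname(fit0$theta_hat)
  }
  .check_theta(init, p)
  n_iter <- cfg$n_iter
  burn <- ceiling(cfg$burn_in_frac * n_iter)
  adaptive <- identical(cfg$proposal_sd, "adaptive")
  sds <- if (adaptive) pmax(abs(init) * 0.2, 0.05) else {
    stopifnot(is.numeric(cfg$proposal_sd), length(cfg$proposal_sd) == p,
              all(cfg$proposal_sd > 0))
    cfg$proposal_sd
  }
  .with_seed(cfg$seed, {
    theta <- init
    lp <- .log_posterior(theta, data, priors, model)
    keep_idx <- seq(burn + 1L, n_iter, by = cfg$thin)
    kept <- matrix(NA_real_, length(keep_idx), p)
    acc_kept <- integer(p)
    acc_window <- integer(p)
    row <- 0L
    for (t in seq_len(n_iter)) {
      for (k in seq_len(p)) {
        prop <- theta
        prop[k] <- theta[k] + stats::rnorm(1, 0, sds[k])
        lp_prop <- if (prop[k] <= 0) -Inf
                   else .log_posterior(prop, data, priors, model)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
          theta <- prop
          lp <- lp_prop
          if (t > burn) acc_kept[k] <- acc_kept[k] + 1L
          acc_window[k] <- acc_window[k] + 1L
        }
      }
      if (adaptive && t <= burn && t %% 50L == 0L) {
        rate <- acc_window / 50
        sds <- sds * exp(rate - 0.35)
        acc_window[] <- 0L
      }
      if (t %in% keep_idx) {
        row <- row + 1L
        kept[row, ] <- theta
      }
    }
    acceptance <- acc_kept / (n_iter - burn)
    if (any(acceptance == 0)) {
      stop("a coordinate accepted no move after burn-in; ",
           "supply smaller proposal_sd values", call. = FALSE)
    }
    r <- if (model == "general") {
      apply(kept, 1L, function(th) .reliability_gl(th[1], th[2], th[3], th[4]))
    } else {
      apply(kept, 1L, function(th) .rel_common_closed(th[2], th[3]))
    }
    cn <- if (model == "general") c("alpha1", "alpha2", "lambda1", "lambda2")
          else c("alpha", "lambda1", "lambda2")
    colnames(kept) <- cn
    names(acceptance) <- cn
    structure(list(params = kept, r = r, acceptance = acceptance,
                   model = model, cfg = cfg),
              class = "posterior_draws")
  })
}

#' Export posterior draws as CSV
#'
#' One row per kept iteration: the parameters followed by the reliability.
#'
#' @param draws a [gibbs_sampler()] result.
#' @param path output file path.
#' @export
write_draws_csv <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  utils::write.csv(data.frame(draws$params, r = draws$r, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Loss-based Bayes point estimates of R
#'
#' From the posterior draws of the reliability: the posterior mean (squared
#' error loss, SEL), posterior median (absolute error loss, AEL), posterior
#' mode of a Gaussian-kernel density estimate with Silverman bandwidth
#' (MAP), the LINEX estimator \eqn{-\frac{1}{c} \log E[e^{-cR}]} and the
#' general entropy estimator \eqn{(E[R^{-q}])^{-1/q}}.  As \eqn{c \to 0}
#' LINEX tends to SEL, and GEL with `q = -1` equals SEL exactly.
#'
#' @param draws a [gibbs_sampler()] result (or numeric vector of R draws).
#' @param c LINEX asymmetry parameter (non-zero; default 2).
#' @param q general-entropy exponent (non-zero; default 3).
#' @return An object of class `"bayes_estimates"`: list with `sel`, `ael`,
#'   `map`, `linex`, `gel`, and the `c`, `q` used.
#' @export
bayes_point_estimates <- function(draws, c = 2, q = 3) {
  r <- if (inherits(draws, "posterior_draws")) draws$r else as.numeric(draws)
  if (length(r) < 1L) stop("no posterior draws", call. = FALSE)
  if (c == 0) stop("'c' must be non-zero (the c -> 0 limit of LINEX is SEL)",
                   call. = FALSE)
  if (q == 0) stop("'q' must be non-zero (the q -> 0 limit of GEL is log-loss)",
                   call. = FALSE)
  sel <- mean(r)
  ael <- stats::median(r)
  map <- if (stats::var(r) == 0 || length(r) < 5L) r[1] else {
    dd <- stats::density(r, bw = "nrd0")
    dd$x[which.max(dd$y)]
  }
  # LINEX displayed with e^{+cR} would be negative for R in (0,1); the
  # standard e^{-cR} form keeps the estimator in (0,1) and is used here.
  linex <- -log(mean(exp(-c * r))) / c
  gel <- mean(r^(-q))^(-1 / q)
  structure(list(sel = sel, ael = ael, map = map, linex = linex, gel = gel,
                 c = c, q = q),
            class = "bayes_estimates")
}

#' @export
print.bayes_estimates <- function(x, ...) {
  cat(sprintf("Bayes estimates of R: SEL %.5f  AEL %.5f  MAP %.5f  LINEX(c=%g) %.5f  GEL(q=%g) %.5f\n",
              x$sel, x$ael, x$map, x$c, x$linex, x$q, x$gel))
  invisible(x)
}

#' Highest posterior density interval from MCMC draws
#'
#' The shortest interval containing a `level` fraction of the draws,
#' obtained as the minimal-width window of \eqn{\lceil (1-\epsilon) N
#' \rceil} consecutive order statistics (the Chen-Shao construction).
#'
#' @param draws a [gibbs_sampler()] result or numeric vector of R draws.
#' @param level nominal credibility.
#' @return An [interval_estimate()] with method `"hpd"`.
#' @export
hpd_interval <- function(draws, level = 0.95) {
  r <- if (inherits(draws, "posterior_draws")) draws$r else as.numeric(draws)
  N <- length(r)
  eps <- 1 - level
  if (N < 1 / eps) {
    stop(sprintf("need at least %d draws for level %.3f", ceiling(1 / eps),
                 level), call. = FALSE)
  }
  r <- sort(r)
  m <- ceiling(level * N)
  starts <- seq_len(N - m + 1L)
  widths <- r[starts + m - 1L] - r[starts]
  j <- starts[which.min(widths)]
  interval_estimate(r[j], r[j + m - 1L], level, "hpd")
}
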