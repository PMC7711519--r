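# Nonparametric bootstrap confidence intervals for R.

#' Bootstrap resampling distribution of the reliability estimate
#'
#' For each of `B` replicates, the strength and stress samples are resampled
#' independently with replacement at their original sizes, the chosen model
#' is refitted (starting from the original-data MLE for speed and
#' stability), and the plug-in reliability is recorded.  Replicates whose
#' refit fails are counted in `n_failed`; more than 1% failures is an error
#' rather than silent dropping.  Setting `parametric = TRUE` draws the
#' resamples from the fitted PHLD marginals instead.
#'
#' @param data an [ss_data()].
#' @param B number of bootstrap replicates.
#' @param model `"general"` or `"common"`.
#' @param seed optional integer seed.
#' @param parametric logical; parametric instead of nonparametric resampling.
#' @return An object of class `"bootstrap_draws"`: list with `r_star`
#'   (length `B - n_failed`), `B`, `seed`, `n_failed` and `r_hat` (the
#'   original-data estimate).
#' @export
bootstrap_draws <- function(data, B = 1000L, model = c("general", "common"),
                            seed = NULL, parametric = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(data, "ss_data"), B >= 1)
  fit0 <- if (model == "general") fit_general(data) else fit_common(data)
  th0 <- unname(fit0$theta_hat)
  r0 <- r_hat_from_fit(fit0)
  .with_seed(seed, {
    r_star <- numeric(0)
    n_failed <- 0L
    for (b in seq_len(B)) {
      if (parametric) {
        xs <- if (model == "general") rphld(data$n1, th0[1], th0[3])
              else rphld(data$n1, th0[1], th0[2])
        ys <- if (model == "general") rphld(data$n2, th0[2], th0[4])
              else rphld(data$n2, th0[1], th0[3])
      } else {
        xs <- sample(data$x, data$n1, replace = TRUE)
        ys <- sample(data$y, data$n2, replace = TRUE)
      }
      r_b <- tryCatch({
        d_b <- ss_data(xs, ys)
        f_b <- if (model == "general") fit_general(d_b, init = th0)
               else fit_common(d_b, init = th0)
        r_hat_from_fit(f_b)
      }, error = function(e) NA_real_)
      if (is.na(r_b)) n_failed <- n_failed + 1L else r_star <- c(r_star, r_b)
    }
    if (n_failed > 0.01 * B) {
      stop(sprintf("bootstrap refits failed for %d of %d replicates",
                   n_failed, B), call. = FALSE)
    }
    structure(list(r_star = r_star, B = as.integer(B), seed = seed,
                   n_failed = n_failed, r_hat = r0),
              class = "bootstrap_draws")
  })
}

# Order-statistic index rule used by both bootstrap intervals: the tau
# percentile of B sorted draws is draw number ceiling(B * tau) from the
# bottom (type-1 empirical quantile); upper endpoints count symmetrically
# from the top.
.boot_index <- function(B, tau) max(1L, as.integer(ceiling(B * tau)))

#' Percentile bootstrap confidence interval (Bp)
#'
#' The interval between the \eqn{\epsilon/2} and \eqn{1-\epsilon/2} order
#' statistics of the bootstrap reliabilities: draw number
#' \eqn{\lceil B\epsilon/2 \rceil} from the bottom and from the top of the
#' sorted draws.  Both endpoints are members of the draw vector.
#'
#' @param draws a [bootstrap_draws()] result.
#' @param level nominal coverage.
#' @return An [interval_estimate()] with method `"bp"`.
#' @export
percentile_ci <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "bootstrap_draws"))
  r <- sort(draws$r_star)
  B <- length(r)
  if (B < 1L) stop("no bootstrap draws", call. = FALSE)
  eps <- 1 - level
  if (B * eps / 2 < 1 - 1e-9) {
    stop(sprintf("B = %d too small for level %.3f (need B*eps/2 >= 1)",
                 B, level), call. = FALSE)
  }
  k <- .boot_index(B, eps / 2)
  interval_estimate(r[k], r[B + 1L - k], level, "bp")
}

#' Studentized bootstrap confidence interval (Bt)
#'
#' Studentizes each bootstrap reliability as \eqn{t^*_j = (\hat R^*_j - \hat
#' R)/\mathrm{se}(\hat R^*)}, with \eqn{\mathrm{se}} the (population-form)
#' standard deviation of the draws, and returns \eqn{\hat R \pm
#' |t^*_{(\epsilon/2)}| \mathrm{se}} — the symmetric form.  The
#' `two_tailed = TRUE` variant uses the \eqn{(\epsilon/2, 1-\epsilon/2)}
#' percentile pair with tail reversal instead.
#'
#' @param draws a [bootstrap_draws()] result.
#' @param r_hat the original-data estimate (defaults to the one stored in
#'   `draws`).
#' @param level nominal coverage.
#' @param two_tailed logical; use the asymmetric percentile pair.
#' @return An [interval_estimate()] with method `"bt"`.
#' @export
student_t_ci <- function(draws, r_hat = draws$r_hat, level = 0.95,
                         two_tailed = FALSE) {
  stopifnot(inherits(draws, "bootstrap_draws"))
  r <- draws$r_star
  B <- length(r)
  se <- sqrt(mean((r - mean(r))^2))
  if (se <= 0) stop("degenerate bootstrap draws (zero standard error)",
                    call. = FALSE)
  eps <- 1 - level
  if (B * eps / 2 < 1 - 1e-9) {
    stop(sprintf("B = %d too small for level %.3f", B, level), call. = FALSE)
  }
  tstar <- sort((r - r_hat) / se)
  k <- .boot_index(B, eps / 2)
  if (two_tailed) {
    lo <- r_hat - tstar[B + 1L - k] * se
    hi <- r_hat - tstar[k] * se
  } else {
    half <- abs(tstar[k]) * se
    lo <- r_hat - half
    hi <- r_hat + half
  }
  interval_estimate(min(lo, hi), max(lo, hi), level, "bt")
}
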