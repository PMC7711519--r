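# Monte Carlo evaluation harness: bias, MSE, average interval length and
# coverage probability for all estimators of R over simulation cells.

#' Specify one Monte Carlo simulation cell
#'
#' A cell is a true parameter vector, sample sizes, and the replication
#' settings under which every estimator of R is evaluated.  Interval and
#' Bayes machinery can be switched off per cell (`B = 0` skips the
#' bootstrap, `mcmc = NULL` skips the Bayes estimators) so that cheap
#' MLE-only cells run in seconds.
#'
#' @param theta true `(alpha1, alpha2, lambda1, lambda2)`.
#' @param n1,n2 sample sizes per replicate.
#' @param n_reps number of replicates.
#' @param B bootstrap replications per replicate (0 = skip bootstrap CIs).
#' @param mcmc an [mcmc_config()] for the Bayes estimators, or `NULL` to
#'   skip them.
#' @param level nominal interval level.
#' @param seed cell seed; replicate `r` runs on a sub-seed derived
#'   deterministically from it, so cells are reproducible and parallelizable.
#' @param c,q LINEX and general-entropy loss parameters.
#' @return An object of class `"sim_cell_spec"`.
#' @export
sim_cell_spec <- function(theta, n1, n2, n_reps = 1000L, B = 0L, mcmc = NULL,
                          level = 0.95, seed = 1L, c = 2, q = 3) {
  .check_theta(theta, 4L)
  stopifnot(n1 >= 2, n2 >= 2, n_reps >= 1, B >= 0, level > 0, level < 1)
  if (!is.null(mcmc)) stopifnot(inherits(mcmc, "mcmc_config"))
  structure(list(theta = theta, n1 = as.integer(n1), n2 = as.integer(n2),
                 n_reps = as.integer(n_reps), B = as.integer(B), mcmc = mcmc,
                 level = level, seed = as.integer(seed), c = c, q = q),
            class = "sim_cell_spec")
}

#' Run one Monte Carlo cell
#'
#' For each replicate, samples are drawn from the two PHLD marginals by
#' inverse transform, the general model is refitted, and every requested
#' point estimator and interval is computed.  Aggregates per estimator
#' `bias = mean(R_hat) - R` and `mse = mean((R_hat - R)^2)`, and per
#' interval method the average length (ALCI) and empirical coverage (CP) of
#' the true R.  Replicates that fail are excluded and counted; more than 2%
#' failures is an error.
#'
#' @param spec a [sim_cell_spec()].
#' @return An object of class `"sim_cell_result"`: list with `true_R`,
#'   `estimates` (data frame estimator/bias/mse), `intervals` (data frame
#'   method/alci/cp, if any interval was requested), `n_reps_used`,
#'   `n_failed`.
#' @export
run_sim_cell <- function(spec) {
  stopifnot(inherits(spec, "sim_cell_spec"))
  th <- spec$theta
  sspec <- ss_spec(th[1], th[2], th[3], th[4])
  true_R <- reliability_quadrature(sspec)
  want_bayes <- !is.null(spec$mcmc)
  want_boot <- spec$B > 0L
  est_names <- c("mle", if (want_bayes) c("sel", "map", "ael", "linex", "gel"))
  int_names <- c("asci", if (want_boot) c("bp", "bt"), if (want_bayes) "hpd")
  est <- matrix(NA_real_, spec$n_reps, length(est_names),
                dimnames = list(NULL, est_names))
  len <- matrix(NA_real_, spec$n_reps, length(int_names),
                dimnames = list(NULL, int_names))
  cov <- matrix(NA, spec$n_reps, length(int_names),
                dimnames = list(NULL, int_names))
  n_failed <- 0L
  for (r in seq_len(spec$n_reps)) {
    seed_r <- .derive_seed(spec$seed, r)
    ok <- tryCatch(suppressWarnings({
      d <- generate_synthetic(sspec, spec$n1, spec$n2, seed = seed_r)
      fit <- fit_general(d)
      est[r, "mle"] <- r_hat_from_fit(fit)
      v <- var_R_delta(fit, observed_information(fit))
      ci <- asymptotic_ci(est[r, "mle"], v, spec$level)
      len[r, "asci"] <- ci$upper - ci$lower
      cov[r, "asci"] <- ci$lower <= true_R && true_R <= ci$upper
      if (want_boot) {
        bd <- bootstrap_draws(d, B = spec$B, model = "general",
                              seed = .derive_seed(seed_r, 1L))
        for (mth in c("bp", "bt")) {
          ci_b <- if (mth == "bp") percentile_ci(bd, spec$level)
                  else student_t_ci(bd, level = spec$level)
          len[r, mth] <- ci_b$upper - ci_b$lower
          cov[r, mth] <- ci_b$lower <= true_R && true_R <= ci_b$upper
        }
      }
      if (want_bayes) {
        cfg <- spec$mcmc
        cfg$seed <- .derive_seed(seed_r, 2L)
        dr <- gibbs_sampler(d, cfg = cfg, model = "general",
                            init = unname(fit$theta_hat))
        be <- bayes_point_estimates(dr, c = spec$c, q = spec$q)
        est[r, c("sel", "map", "ael", "linex", "gel")] <-
          c(be$sel, be$map, be$ael, be$linex, be$gel)
        ci_h <- hpd_interval(dr, spec$level)
        len[r, "hpd"] <- ci_h$upper - ci_h$lower
        cov[r, "hpd"] <- ci_h$lower <= true_R && true_R <= ci_h$upper
      }
      TRUE
    }), error = function(e) FALSE)
    if (!ok) n_failed <- n_failed + 1L
  }
  if (n_failed > 0.02 * spec$n_reps) {
    stop(sprintf("%d of %d replicates failed", n_failed, spec$n_reps),
         call. = FALSE)
  }
  used <- stats::complete.cases(est[, "mle", drop = FALSE])
  estimates <- data.frame(
    estimator = est_names,
    bias = vapply(est_names, function(e) mean(est[used, e]) - true_R, numeric(1)),
    mse = vapply(est_names, function(e) mean((est[used, e] - true_R)^2), numeric(1)),
    row.names = NULL)
  intervals <- data.frame(
    method = int_names,
    alci = vapply(int_names, function(m) mean(len[used, m]), numeric(1)),
    cp = vapply(int_names, function(m) mean(cov[used, m]), numeric(1)),
    row.names = NULL)
  structure(list(true_R = true_R, estimates = estimates, intervals = intervals,
                 n_reps_used = sum(used), n_failed = n_failed, spec = spec),
            class = "sim_cell_result")
}

#' @export
print.sim_cell_result <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Simulation cell: theta = (%s), n = (%d, %d), %d replicates, true R = %.4f\n",
              paste(s$theta, collapse = ", "), s$n1, s$n2, x$n_reps_used, x$true_R))
  print(transform(x$estimates, bias = round(bias, 4), mse = round(mse, 4)))
  if (nrow(x$intervals)) {
    print(transform(x$intervals, alci = round(alci, 4), cp = round(cp, 3)))
  }
  invisible(x)
}

#' Summarize a grid of simulation cells
#'
#' Runs each cell and stacks the results into one long-format table with a
#' row per (cell, quantity): point estimators contribute bias and MSE rows,
#' interval methods ALCI and CP rows.  Re-running with the same cell seeds
#' reproduces the table exactly.
#'
#' @param cells list of [sim_cell_spec()] objects.
#' @return A long-format `data.frame` with columns `alpha1`, `alpha2`,
#'   `lambda1`, `lambda2`, `n1`, `n2`, `true_R`, `quantity`, `name`, `value`.
#' @export
summarize_grid <- function(cells) {
  stopifnot(length(cells) >= 1,
            all(vapply(cells, inherits, logical(1), "sim_cell_spec")))
  do.call(rbind, lapply(cells, function(sp) {
    res <- run_sim_cell(sp)
    base <- data.frame(alpha1 = sp$theta[1], alpha2 = sp$theta[2],
                       lambda1 = sp$theta[3], lambda2 = sp$theta[4],
                       n1 = sp$n1, n2 = sp$n2, true_R = res$true_R)
    rows <- rbind(
      data.frame(quantity = "bias", name = res$estimates$estimator,
                 value = res$estimates$bias),
      data.frame(quantity = "mse", name = res$estimates$estimator,
                 value = res$estimates$mse),
      if (nrow(res$intervals)) {
        rbind(data.frame(quantity = "alci", name = res$intervals$method,
                         value = res$intervals$alci),
              data.frame(quantity = "cp", name = res$intervals$method,
                         value = res$intervals$cp))
      })
    cbind(base[rep(1L, nrow(rows)), , drop = FALSE], rows, row.names = NULL)
  }))
}
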