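test_that("full conditionals are the likelihood plus gamma prior kernel", {
  d <- generate_synthetic(ss_spec(2, 1.9, 3.7, 3.8), 25, 25, seed = 1)
  near_flat <- gamma_prior(a = 1, b = 1e-12)
  th <- c(2, 1.9, 3.7, 3.8)
  # with an essentially flat prior, conditional differences equal
  # log-likelihood differences
  for (vals in list(c(3.0, 4.2), c(1.1, 2.6))) {
    dc <- log_conditional(3, vals[1], th, d, near_flat, "general") -
      log_conditional(3, vals[2], th, d, near_flat, "general")
    th_a <- th; th_a[3] <- vals[1]
    th_b <- th; th_b[3] <- vals[2]
    dl <- loglik_general(th_a, d) - loglik_general(th_b, d)
    expect_equal(dc, dl, tolerance = 1e-10)
  }
  # conditional for alpha1 matches the marginal posterior kernel assembled
  # directly from the x-sample and its prior
  pr <- gamma_prior(2, 1.5)
  direct_kernel <- function(a1) {
    (d$n1 + pr$a - 1) * log(a1) - a1 * (pr$b + sum(d$x)) +
      th[3] * sum(tanh(a1 * d$x / 2)) - 2 * sum(log1p(exp(-a1 * d$x)))
  }
  vals <- c(1.2, 1.8, 2.4, 3.0, 3.6)
  cond <- vapply(vals, function(v) {
    log_conditional(1, v, th, d, pr, "general")
  }, numeric(1))
  expect_equal(diff(cond), diff(vapply(vals, direct_kernel, numeric(1))),
               tolerance = 1e-8)
  # a stronger rate prior pulls the conditional argmax of alpha1 down
  grid <- seq(0.5, 4, by = 0.01)
  argmax_b <- function(b) {
    vals <- vapply(grid, function(v) {
      log_conditional(1, v, th, d, gamma_prior(2, b), "general")
    }, numeric(1))
    grid[which.max(vals)]
  }
  expect_lt(argmax_b(20), argmax_b(0.1))
  expect_identical(log_conditional(1, -1, th, d, pr, "general"), -Inf)
})

test_that("the sampler is deterministic and honours a dominating prior", {
  d <- generate_synthetic(ss_spec(2, 1.9, 3.7, 3.8), 40, 40, seed = 3)
  cfg <- mcmc_config(n_iter = 600, seed = 99)
  dr1 <- gibbs_sampler(d, cfg = cfg)
  dr2 <- gibbs_sampler(d, cfg = cfg)
  expect_identical(dr1$params, dr2$params)
  expect_identical(dr1$r, dr2$r)
  expect_true(all(dr1$acceptance > 0 & dr1$acceptance < 1))
  expect_true(all(dr1$r > 0 & dr1$r < 1))
  # near-degenerate prior at theta0 forces the posterior R to R(theta0)
  th0 <- c(2, 1.9, 3.7, 3.8)
  priors <- lapply(th0, function(t0) gamma_prior(1e6 * t0, 1e6))
  dr_tight <- gibbs_sampler(d, priors = priors,
                            cfg = mcmc_config(n_iter = 4000, seed = 7))
  r0 <- reliability_quadrature(ss_spec(th0[1], th0[2], th0[3], th0[4]))
  expect_lt(abs(mean(dr_tight$r) - r0), 1e-3)
})

test_that("common-scale sampler runs and its conditionals match the likelihood", {
  d <- generate_synthetic(ss_spec(1.5, 1.5, 2, 1.5), 30, 30, seed = 4)
  dr <- gibbs_sampler(d, cfg = mcmc_config(n_iter = 500, seed = 1),
                      model = "common")
  expect_equal(ncol(dr$params), 3L)
  expect_true(all(dr$r > 0 & dr$r < 1))
  near_flat <- gamma_prior(1, 1e-12)
  th <- c(1.5, 2, 1.5)
  dcond <- log_conditional(2, 2.6, th, d, near_flat, "common") -
    log_conditional(2, 1.4, th, d, near_flat, "common")
  th_a <- th; th_a[2] <- 2.6
  th_b <- th; th_b[2] <- 1.4
  expect_equal(dcond, loglik_common(th_a, d) - loglik_common(th_b, d),
               tolerance = 1e-10)
})

test_that("loss-based point estimates satisfy their identities and orderings", {
  expect_error(bayes_point_estimates(runif(10), c = 0), "non-zero")
  expect_error(bayes_point_estimates(runif(10), q = 0), "non-zero")
  # degenerate posterior: every estimator collapses to the common value
  be0 <- bayes_point_estimates(rep(0.6, 50))
  expect_equal(unlist(be0[c("sel", "ael", "map", "linex", "gel")]),
               rep(0.6, 5), tolerance = 1e-12, ignore_attr = TRUE)
  set.seed(17)
  r <- rbeta(2000, 8, 5)
  be <- bayes_point_estimates(r, c = 1e-4, q = -1)
  expect_lt(abs(be$linex - be$sel), 1e-6)   # LINEX -> SEL as c -> 0
  expect_equal(be$gel, be$sel, tolerance = 1e-12)  # GEL(q = -1) = SEL
  # three-term hand computation of LINEX at c = 2
  be3 <- bayes_point_estimates(c(0.5, 0.6, 0.7), c = 2, q = 3)
  expect_equal(be3$linex,
               -0.5 * log((exp(-1.0) + exp(-1.2) + exp(-1.4)) / 3),
               tolerance = 1e-12)
  # Jensen orderings for positive loss parameters
  be_j <- bayes_point_estimates(r, c = 2, q = 3)
  expect_lte(be_j$linex, be_j$sel)
  expect_lte(be_j$gel, be_j$sel)
})

test_that("highest posterior density interval is the brute-force shortest window", {
  # sorted uniform grid: every admissible window has the same width
  grid <- seq(0.01, 1.00, by = 0.01)
  hpd <- hpd_interval(grid, level = 0.95)
  expect_equal(hpd$upper - hpd$lower, 0.95 * (1.00 - 0.01), tolerance = 0.011)
  # brute force over all candidate windows on peaked draws
  set.seed(23)
  r <- rbeta(500, 20, 10)
  hpd_r <- hpd_interval(r, level = 0.90)
  rs <- sort(r)
  m <- ceiling(0.90 * length(rs))
  widths <- rs[seq(m, length(rs))] - rs[seq_len(length(rs) - m + 1)]
  j <- which.min(widths)
  expect_equal(hpd_r$lower, rs[j], tolerance = 1e-12)
  expect_equal(hpd_r$upper, rs[j + m - 1], tolerance = 1e-12)
  # no wider than the equal-tailed interval on unimodal draws
  eq <- unname(quantile(r, c(0.05, 0.95), type = 1))
  expect_lte(hpd_r$upper - hpd_r$lower, eq[2] - eq[1] + 1e-12)
  # contains the posterior median at moderate levels
  expect_true(hpd_r$lower <= median(r) && median(r) <= hpd_r$upper)
  expect_equal(with(hpd_interval(rep(0.4, 100)), upper - lower), 0)
  expect_error(hpd_interval(runif(10), level = 0.95), "at least")
})

test_that("draw export writes one row per kept iteration", {
  d <- generate_synthetic(ss_spec(2, 2, 2, 2), 20, 20, seed = 5)
  dr <- gibbs_sampler(d, cfg = mcmc_config(n_iter = 200, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(dr, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), length(dr$r))
  expect_named(tab, c("alpha1", "alpha2", "lambda1", "lambda2", "r"))
})
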