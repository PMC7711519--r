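test_that("log-likelihood separates over samples and matches the density", {
  d <- ss_data(1, 1)
  expect_equal(loglik_general(c(1, 1, 1, 1), d),
               2 * dphld(1, 1, 1, log = TRUE), tolerance = 1e-12)
  d2 <- generate_synthetic(ss_spec(2, 1.9, 3.7, 3.8), 15, 10, seed = 4)
  th <- c(1.4, 2.1, 2.0, 3.1)
  direct <- sum(dphld(d2$x, th[1], th[3], log = TRUE)) +
    sum(dphld(d2$y, th[2], th[4], log = TRUE))
  expect_equal(loglik_general(th, d2), direct, tolerance = 1e-10)
  expect_error(loglik_general(c(-1, 1, 1, 1), d2), "positive")
})

test_that("analytic score matches finite differences of the log-likelihood", {
  d <- generate_synthetic(ss_spec(1.5, 1.5, 3, 3.5), 30, 30, seed = 1)
  th <- c(1.5, 1.5, 3.0, 3.5)
  s <- score_general(th, d)
  fd <- vapply(1:4, function(k) {
    h <- 1e-6 * max(abs(th[k]), 1)
    tp <- th; tm <- th
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    (loglik_general(tp, d) - loglik_general(tm, d)) / (2 * h)
  }, numeric(1))
  expect_equal(s, fd, tolerance = 1e-6)
  # score is separable: the alpha2 component ignores the strength sample
  d_perturbed <- ss_data(d$x * 2, d$y)
  expect_identical(score_general(th, d)[2], score_general(th, d_perturbed)[2])
  # common-scale score against finite differences
  th3 <- c(1, 2, 1.5)
  d3 <- generate_synthetic(ss_spec(1, 1, 2, 1.5), 25, 25, seed = 3)
  s3 <- score_common(th3, d3)
  fd3 <- vapply(1:3, function(k) {
    h <- 1e-6
    tp <- th3; tm <- th3
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    (loglik_common(tp, d3) - loglik_common(tm, d3)) / (2 * h)
  }, numeric(1))
  expect_equal(s3, fd3, tolerance = 1e-5)
})

test_that("fitting the fibre strengths reproduces the reference estimates", {
  fit <- fit_general(fiber_data())
  expect_true(fit$converged)
  expect_equal(unname(round(fit$theta_hat, 3)),
               c(2.242, 2.137, 8.318, 4.561), tolerance = 1e-8)
  expect_equal(round(fit$loglik, 2), -109.05)
  # first-order condition at the optimum
  expect_lt(abs(score_general(unname(fit$theta_hat), fiber_data())[3]), 1e-4)
  expect_equal(round(r_hat_from_fit(fit), 4), 0.6133)
})

test_that("fitting the bank waiting times reproduces the reference estimates", {
  fit <- fit_general(bank_data())
  expect_equal(unname(round(fit$theta_hat, 3)),
               c(0.193, 0.237, 1.573, 0.390), tolerance = 1e-8)
  expect_equal(round(fit$loglik, 2), -489.34)
  expect_equal(round(r_hat_from_fit(fit), 5), 0.65995)
})

test_that("the maximum likelihood estimator recovers the truth at large n", {
  d <- generate_synthetic(ss_spec(2, 1.9, 3.7, 3.8), 5000, 5000, seed = 7)
  fit <- fit_general(d)
  expect_true(all(abs(fit$theta_hat / c(2, 1.9, 3.7, 3.8) - 1) < 0.05))
})

test_that("the fitted optimum dominates random perturbations", {
  d <- generate_synthetic(ss_spec(1.8, 2.2, 3, 2), 60, 60, seed = 5)
  fit <- fit_general(d)
  th <- unname(fit$theta_hat)
  set.seed(11)
  for (k in 1:50) {
    pert <- th * exp(rnorm(4, 0, 0.1))
    expect_gte(fit$loglik, loglik_general(pert, d))
  }
})

test_that("the common-scale model is properly nested in the general model", {
  fitc <- fit_common(fiber_data())
  expect_true(fitc$converged)
  expect_lte(fitc$loglik, -109.05 + 0.01)
  # symmetric data: both shapes coincide
  x <- generate_synthetic(ss_spec(1.5, 1.5, 2, 2), 40, 40, seed = 6)$x
  fit_sym <- fit_common(ss_data(x, x))
  expect_equal(fit_sym$theta_hat[["lambda1"]], fit_sym$theta_hat[["lambda2"]],
               tolerance = 1e-6)
  r_sym <- r_hat_from_fit(fit_general(ss_data(x, x)))
  expect_equal(r_sym, 0.5, tolerance = 1e-6)
})

test_that("the Kolmogorov-Smirnov statistic matches the reference values", {
  f1 <- fit_general(fiber_data())
  ks1 <- ks_statistic(fiber_data()$x, f1$theta_hat[["alpha1"]],
                      f1$theta_hat[["lambda1"]])
  expect_equal(round(ks1$statistic, 4), 0.0762)
  f2 <- fit_general(bank_data())
  ks2 <- ks_statistic(bank_data()$x, f2$theta_hat[["alpha1"]],
                      f2$theta_hat[["lambda1"]])
  expect_equal(round(ks2$statistic, 4), 0.0594)
  # sample placed exactly at the (i - 0.5)/n quantiles: distance is 0.5/n
  n <- 25
  xq <- qphld((seq_len(n) - 0.5) / n, 2, 3)
  expect_equal(ks_statistic(xq, 2, 3)$statistic, 0.5 / n, tolerance = 1e-10)
  # p-value agrees with the asymptotic one-sample test in stats
  ref <- suppressWarnings(stats::ks.test(fiber_data()$x, function(q) {
    pphld(q, f1$theta_hat[["alpha1"]], f1$theta_hat[["lambda1"]])
  }, exact = FALSE))
  expect_equal(ks1$p.value, unname(ref$p.value), tolerance = 1e-6)
  expect_error(ks_statistic(numeric(0), 1, 1), "empty")
})

test_that("sample files are read with comments and blank lines ignored", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "1.5", "", "2.25  # trailing", "0.75"), path)
  expect_equal(read_sample(path), c(1.5, 2.25, 0.75))
  expect_error(read_sample(file.path(tempdir(), "nope.txt")), "no such file")
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1.0", "abc"), bad)
  expect_error(read_sample(bad), "non-numeric")
})

test_that("data container rejects invalid samples", {
  expect_error(ss_data(c(1, -2), c(1, 2)), "positive")
  expect_error(ss_data(c(1, NA), c(1, 2)), "positive|finite")
  expect_error(fit_general(ss_data(1, c(1, 2))), "at least two")
})
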