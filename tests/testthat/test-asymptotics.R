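test_that("nabla integral reduces to a gamma integral and is monotone in its rate", {
  # gamma3 = gamma4 = 0: integral of x e^{-2x} = 1/4
  expect_equal(nabla_integral(1, 1, 2, 0, 0), 0.25, tolerance = 1e-10)
  vals <- vapply(c(1, 2, 3), function(g2) nabla_integral(1.3, 1, g2, 3, 2),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("nabla series agrees with quadrature across an admissible grid", {
  set.seed(21)
  for (k in 1:20) {
    alpha <- runif(1, 0.5, 3)
    g1 <- sample(0:2, 1)
    g2 <- sample(2:3, 1)
    g3 <- sample(2:5, 1)
    g4 <- runif(1, 0.3, 4)
    q <- nabla_integral(alpha, g1, g2, g3, g4)
    s <- nabla_integral(alpha, g1, g2, g3, g4, method = "series")
    expect_lt(abs(q - s) / max(abs(q), 1e-12), 1e-5)
  }
})

test_that("zeta integral reduces correctly and its series matches quadrature", {
  # single-marginal reduction: delta4 = delta6 = 0 and lambda2 = 0 is nabla
  q <- zeta_integral(1.4, 2.2, 2.5, 1e-12, c(1, 2 * 1.4, 0, 0, 3, 0))
  expect_equal(q, nabla_integral(1.4, 1, 2, 3, 2.5), tolerance = 1e-8)
  # plain exponential reduction
  q2 <- zeta_integral(1.1, 0.9, 1.5, 2, c(0, 1.1, 0, 0, 0, 0))
  ref <- integrate(function(x) {
    exp(-1.1 * x + 1.5 * tanh(1.1 * x / 2) + 2 * tanh(0.9 * x / 2))
  }, 0, Inf, rel.tol = 1e-11)$value
  expect_equal(q2, ref, tolerance = 1e-8)
  # positivity on a random admissible grid
  set.seed(31)
  for (k in 1:10) {
    dd <- c(sample(0:2, 1), runif(1, 0.5, 3), sample(0:2, 1), sample(0:2, 1),
            sample(0:3, 1), sample(0:3, 1))
    expect_gt(zeta_integral(runif(1, 0.5, 2.5), runif(1, 0.5, 2.5),
                            runif(1, 0.5, 3), runif(1, 0.5, 3), dd), 0)
  }
  # series route
  cases <- list(
    list(a = c(2, 1.9, 3.7, 3.8), d = c(0, 2, 0, 0, 2, 0)),
    list(a = c(2, 1.9, 3.7, 3.8), d = c(1, 2, 1, 0, 3, 0)),
    list(a = c(1, 1.3, 0.8, 0.9), d = c(1, 1, 1, 1, 2, 1)),
    list(a = c(1.5, 2.5, 2, 1.5), d = c(0, 1.5, 0, 1, 2, 1)))
  for (cs in cases) {
    q <- do.call(zeta_integral, c(as.list(cs$a), list(cs$d)))
    s <- do.call(zeta_integral, c(as.list(cs$a), list(cs$d, method = "series")))
    expect_lt(abs(q - s) / abs(q), 1e-5)
  }
})

test_that("zeta-star integral reduces correctly and its series matches quadrature", {
  # delta3 = delta4 = 0 with vanishing shapes: gamma integral
  q <- zeta_star_integral(2, 1e-9, 1e-9, 1, 2, 0, 0)
  expect_equal(q, gamma(2) / (2 * 2)^2, tolerance = 1e-6)
  # coincides with the general integral at a shared scale
  q2 <- zeta_star_integral(1.3, 2, 1.5, 1, 1, 1, 3)
  q2_gen <- zeta_integral(1.3, 1.3, 2, 1.5, c(1, 1.3, 1, 0, 3, 0))
  expect_equal(q2, q2_gen, tolerance = 1e-8)
  # series route at several argument sets
  for (cs in list(c(1, 2, 1.5, 1, 1, 1, 3), c(2.4, 3, 2.2, 0, 1, 0, 2),
                  c(0.7, 1, 2, 2, 2, 2, 4))) {
    q <- do.call(zeta_star_integral, as.list(cs))
    s <- do.call(zeta_star_integral, c(as.list(cs), list(method = "series")))
    expect_lt(abs(q - s) / abs(q), 1e-5)
  }
})

test_that("observed information is block diagonal, replication-linear and accurate", {
  d <- generate_synthetic(ss_spec(1.8, 2.1, 2.5, 3), 200, 200, seed = 5)
  fit <- fit_general(d)
  I <- observed_information(fit)
  expect_true(attr(I, "pd"))
  expect_lt(max(abs(I[1, c(2, 4)]), abs(I[3, c(2, 4)])), 1e-6)
  # doubling the data doubles each entry
  d2 <- ss_data(c(d$x, d$x), c(d$y, d$y))
  I2 <- observed_information(fit, d2)
  expect_equal(unclass(I2), 2 * unclass(I), tolerance = 1e-6,
               ignore_attr = TRUE)
  # second, independent finite-difference scheme on the log-likelihood itself
  th <- unname(fit$theta_hat)
  H <- matrix(0, 4, 4)
  h <- 1e-4 * pmax(abs(th), 1)
  for (i in 1:4) for (j in 1:4) {
    tpp <- th; tpm <- th; tmp <- th; tmm <- th
    tpp[i] <- tpp[i] + h[i]; tpp[j] <- tpp[j] + h[j]
    tpm[i] <- tpm[i] + h[i]; tpm[j] <- tpm[j] - h[j]
    tmp[i] <- tmp[i] - h[i]; tmp[j] <- tmp[j] + h[j]
    tmm[i] <- tmm[i] - h[i]; tmm[j] <- tmm[j] - h[j]
    H[i, j] <- (loglik_general(tpp, d) - loglik_general(tpm, d) -
                  loglik_general(tmp, d) + loglik_general(tmm, d)) /
      (4 * h[i] * h[j])
  }
  expect_equal(unclass(I), -H, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("expected information matches Monte Carlo curvature and large-sample observed", {
  theta <- c(1.5, 2.0, 2.0, 3.0)
  I_exp <- expected_information(theta, 50, 50, "general")
  expect_true(attr(I_exp, "pd"))
  expect_identical(I_exp[1, 2], 0)
  expect_identical(I_exp[1, 4], 0)
  expect_identical(I_exp[2, 3], 0)
  # Monte Carlo average of the numeric negative Hessian at the true theta
  reps <- 300
  acc <- matrix(0, 4, 4)
  vals_11 <- numeric(reps)
  h <- 1e-4 * pmax(abs(theta), 1)
  for (r in seq_len(reps)) {
    d <- generate_synthetic(ss_spec(theta[1], theta[2], theta[3], theta[4]),
                            50, 50, seed = 1000 + r)
    J <- matrix(0, 4, 4)
    for (j in 1:4) {
      tp <- theta; tm <- theta
      tp[j] <- tp[j] + h[j]; tm[j] <- tm[j] - h[j]
      J[, j] <- (score_general(tp, d) - score_general(tm, d)) / (2 * h[j])
    }
    acc <- acc - J
    vals_11[r] <- -J[1, 1]
  }
  mc <- acc / reps
  se_11 <- sd(vals_11) / sqrt(reps)
  expect_lt(abs(mc[1, 1] - I_exp[1, 1]), 3 * se_11)
  expect_equal(unclass(I_exp), (mc + t(mc)) / 2, tolerance = 0.05,
               ignore_attr = TRUE)
  # expected vs observed information on one large sample
  d_big <- generate_synthetic(ss_spec(theta[1], theta[2], theta[3], theta[4]),
                              5000, 5000, seed = 77)
  fit <- fit_general(d_big)
  I_obs <- observed_information(fit)
  I_exp_big <- expected_information(theta, 5000, 5000, "general")
  nz <- abs(unclass(I_exp_big)) > 1e-8
  expect_true(all(abs(I_obs[nz] / I_exp_big[nz] - 1) < 0.05))
})

test_that("common-scale expected information is positive definite and consistent", {
  theta <- c(1.2, 2.0, 1.5)
  I3 <- expected_information(theta, 80, 60, "common")
  expect_true(attr(I3, "pd"))
  d <- generate_synthetic(ss_spec(1.2, 1.2, 2.0, 1.5), 4000, 3000, seed = 13)
  fitc <- fit_common(d)
  I_obs <- observed_information(fitc)
  expect_true(all(diag(I_obs) > 0))
  I3_big <- expected_information(theta, 4000, 3000, "common")
  expect_true(all(abs(diag(I_obs) / diag(I3_big) - 1) < 0.1))
})

test_that("gradient of R has the expected symmetries and cross-method agreement", {
  g_sym <- grad_R(ss_spec(1, 1, 1, 1), "numeric")
  expect_equal(g_sym[["dlambda1"]], -g_sym[["dlambda2"]], tolerance = 1e-6)
  expect_equal(g_sym[["dalpha1"]], -g_sym[["dalpha2"]], tolerance = 1e-6)
  # analytic mode enforces <= 1e-4 agreement with the numeric gradient
  g <- grad_R(ss_spec(2, 1.9, 3.7, 3.8), "analytic")
  expect_length(g, 4)
  g_cs <- grad_R(ss_spec(2, 2, 1.5, 2.5, common_scale = TRUE), "analytic")
  expect_length(g_cs, 2)
  # R is scale-free under the common-scale restriction
  r_a <- vapply(c(0.5, 1, 5), function(a) {
    reliability_quadrature(ss_spec(a, a, 1.5, 2.5))
  }, numeric(1))
  expect_lt(max(r_a) - min(r_a), 1e-8)
})

test_that("delta-method variance and asymptotic interval behave correctly", {
  fit <- fit_general(fiber_data())
  I <- observed_information(fit)
  v <- var_R_delta(fit, I)
  expect_gt(v, 0)
  rh <- r_hat_from_fit(fit)
  ci <- asymptotic_ci(rh, v)
  expect_lt(ci$lower, 0.6133)
  expect_gt(ci$upper, 0.6133)
  expect_false(ci$clipped)
  # interval length shrinks like 1/sqrt(n) on self-replicated data
  d <- fiber_data()
  d4 <- ss_data(rep(d$x, 4), rep(d$y, 4))
  fit4 <- fit_general(d4)
  v4 <- var_R_delta(fit4, observed_information(fit4))
  expect_equal(sqrt(v / v4), 2, tolerance = 0.05)
  # clipping is flagged
  ci_clip <- asymptotic_ci(0.95, 0.01)
  expect_true(ci_clip$clipped)
  expect_lte(ci_clip$upper, 1)
})
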