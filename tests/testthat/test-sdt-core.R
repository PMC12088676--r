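test_that("log-linear correction adds 0.5 per cell and stays inside (0, 1)", {
  r <- log_linear_correct(decision_matrix(10, 0, 0, 10))
  expect_equal(r$H, 10.5 / 11)
  expect_equal(r$FA, 0.5 / 11)
  expect_true(r$corrected)

  r2 <- log_linear_correct(decision_matrix(71, 29, 7, 93))
  expect_equal(r2$H, 71.5 / 101)
  expect_equal(r2$FA, 7.5 / 101)

  expect_error(log_linear_correct(decision_matrix(0, 0, 0, 0)), "present")
  expect_error(log_linear_correct(decision_matrix(3, 4, 0, 0)), "absent")

  # correction shrinks extreme rates towards 0.5
  for (cells in list(c(99, 1, 0, 100), c(1, 99, 100, 0))) {
    m <- do.call(decision_matrix, as.list(cells))
    r <- log_linear_correct(m)
    expect_gt(r$H, 0); expect_lt(r$H, 1)
    expect_gt(r$FA, 0); expect_lt(r$FA, 1)
    raw_h <- m$hits / m$n_present
    expect_lte(abs(r$H - 0.5), abs(raw_h - 0.5) + 1e-12)
  }
})

test_that("z transform and phi match a CDF-inversion oracle", {
  expect_equal(z_transform(0.5), 0)
  expect_error(z_transform(0), "strictly inside")
  expect_error(z_transform(1), "strictly inside")
  for (p in c(0.073, 0.3, 0.71, 0.9545)) {
    expect_equal(z_transform(p), z_oracle(p), tolerance = 1e-8)
    expect_equal(phi_at(p), exp(-z_oracle(p)^2 / 2) / sqrt(2 * pi),
                 tolerance = 1e-8)
    expect_equal(phi_at(p), phi_at(1 - p), tolerance = 1e-12)
  }
  expect_lt(abs(z_transform(0.71) - 0.5534), 1e-4)
  expect_lt(abs(z_transform(0.073) - -1.4538), 1e-4)
  expect_equal(phi_at(0.5), 1 / sqrt(2 * pi))
  expect_lt(abs(phi_at(0.71) - 0.3423), 1e-4)
  expect_lt(abs(phi_at(0.073) - 0.1387), 1e-4)
})

test_that("d' and c reproduce the published detection statistics", {
  r <- rate_pair(0.71, 0.073, corrected = TRUE)
  expect_lt(abs(dprime_yesno(r)$value - 2.01), 0.005)
  expect_lt(abs(criterion_c(r)$value - 0.45), 0.005)

  expect_equal(dprime_yesno(rate_pair(0.3, 0.3))$value, 0)
  expect_equal(criterion_c(rate_pair(0.8, 0.2))$value, 0)
  # by quantile symmetry d'(0.84, 0.16) = 2 z(0.84)
  expect_equal(dprime_yesno(rate_pair(0.84, 0.16))$value,
               2 * z_transform(0.84), tolerance = 1e-12)
  # Exp. 4 noticing criterion from the corrected rates
  expect_lt(abs(criterion_c(rate_pair(0.427, 0.0631))$value - 0.857), 5e-4)
})

test_that("2afc sensitivity carries the 1/sqrt(2) adjustment", {
  r <- rate_pair(0.7264, 0.4554, corrected = TRUE)
  # 0.50487, which the source rounds (half-up) to the printed 0.51
  expect_lt(abs(dprime_2afc(r)$value - 0.5049), 1e-4)
  expect_equal(dprime_2afc(rate_pair(0.4, 0.4))$value, 0)
  expect_equal(dprime_2afc(rate_pair(0.75, 0.25))$value,
               2 * z_transform(0.75) / sqrt(2), tolerance = 1e-12)
  # rate-level antisymmetry: exchanging H and FA negates the statistic
  expect_equal(dprime_2afc(rate_pair(0.4554, 0.7264))$value,
               -dprime_2afc(r)$value, tolerance = 1e-12)
})

test_that("unequal-variance indices reduce to d'/c at sigma = 1 and match the published robustness values", {
  set.seed(41)
  for (i in 1:25) {
    r <- rate_pair(runif(1, 0.02, 0.98), runif(1, 0.02, 0.98))
    expect_equal(d_a(r, 1)$value, dprime_yesno(r)$value, tolerance = 1e-12)
    expect_equal(c_a(r, 1)$value, criterion_c(r)$value, tolerance = 1e-12)
    expect_equal(dprime_2afc(r)$value, dprime_yesno(r)$value / sqrt(2),
                 tolerance = 1e-12)
  }
  r5 <- rate_pair(0.71, 0.073, corrected = TRUE)
  expect_lt(abs(d_a(r5, 1.25)$value - 1.898), 0.005)
  expect_lt(abs(c_a(r5, 1.25)$value - 0.443), 0.005)
  expect_lt(abs(d_a(r5, 0.75)$value - 2.118), 0.005)
  expect_lt(abs(c_a(r5, 0.75)$value - 0.438), 0.005)
  expect_error(d_a(r5, 0), "positive")
  expect_error(c_a(r5, -1), "positive")
})

test_that("analytic variances obey their algebraic identities and published scale", {
  mid <- rate_pair(0.5, 0.5)
  m100 <- decision_matrix(50, 50, 50, 50)
  expect_equal(var_dprime_yesno(mid, m100), 2 * 0.25 / (100 * dnorm(0)^2),
               tolerance = 1e-12)
  expect_equal(var_dprime_2afc(mid, m100), var_dprime_yesno(mid, m100) / 2)
  expect_lt(abs(var_dprime_2afc(mid, m100) - 0.0157), 1e-4)
  expect_lt(abs(var_criterion(mid, m100) - 0.00785), 1e-5)

  set.seed(42)
  for (i in 1:20) {
    r <- rate_pair(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95))
    m <- decision_matrix(rpois(1, 40) + 1, rpois(1, 40) + 1,
                         rpois(1, 40) + 1, rpois(1, 40) + 1)
    v <- var_dprime_yesno(r, m)
    expect_gt(v, 0)
    expect_equal(var_dprime_2afc(r, m), v / 2, tolerance = 1e-12)
    expect_equal(var_criterion(r, m), v / 4, tolerance = 1e-12)
    # doubling both trial totals halves the variance
    m2 <- decision_matrix(2 * m$hits, 2 * m$misses, 2 * m$false_alarms,
                          2 * m$correct_rejections)
    expect_equal(var_dprime_yesno(r, m2), v / 2, tolerance = 1e-12)
  }

  # published-scale standard errors
  r5 <- rate_pair(0.71, 0.073, corrected = TRUE)
  m5 <- decision_matrix(4298, 1754, 146, 1871)  # N2 = 6052, N1 = 2017
  expect_lt(abs(sqrt(var_dprime_yesno(r5, m5)) - 0.045), 1e-3)
  expect_lt(abs(sqrt(var_criterion(r5, m5)) - 0.0226), 5e-4)

  r1 <- rate_pair(0.7264, 0.4554, corrected = TRUE)
  m1 <- decision_matrix(38, 14, 25, 30)
  expect_lt(abs(sqrt(var_dprime_2afc(r1, m1)) - 0.178), 1e-3)
})

test_that("Wald intervals are symmetric, level-monotone, and reproduce the published 2afc CI", {
  e <- dprime_yesno(rate_pair(0.6, 0.4))
  e$variance <- 1
  ci <- wald_ci(e, 0.95)
  expect_equal(ci$ci_low, e$value - 1.959964, tolerance = 1e-6)
  expect_equal(ci$ci_high, e$value + 1.959964, tolerance = 1e-6)
  ci99 <- wald_ci(e, 0.99)
  expect_gt(ci$ci_low, ci99$ci_low)
  expect_lt(ci$ci_high, ci99$ci_high)
  expect_error(wald_ci(dprime_yesno(rate_pair(0.6, 0.4))), "variance")

  m1 <- decision_matrix(38, 14, 25, 30)
  est1 <- dprime_2afc(log_linear_correct(m1), m1)
  expect_lt(abs(est1$ci_low - 0.16), 0.01)
  expect_lt(abs(est1$ci_high - 0.85), 0.01)
})

test_that("degenerate matrices and invalid rates are hard errors", {
  expect_error(decision_matrix(-1, 2, 3, 4), "non-negative")
  expect_error(rate_pair(0, 0.5), "strictly inside")
  expect_error(rate_pair(0.5, 1.2), "strictly inside")
  expect_error(var_dprime_yesno(rate_pair(0.6, 0.4),
                                decision_matrix(1, 1, 0, 0)),
               "absent")
})
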