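test_that("exact binomial p-values equal brute-force enumeration", {
  expect_equal(exact_binomial_test(50, 100, 0.5)$p_value, 1, tolerance = 1e-9)
  expect_equal(exact_binomial_test(0, 10, 0.5)$p_value, 2 / 1024,
               tolerance = 1e-12)
  cases <- list(c(68, 107), c(137, 234), c(3, 20), c(490, 1000), c(0, 7),
                c(12, 12))
  for (ks in cases) {
    for (p0 in c(0.5, 0.3)) {
      expect_equal(exact_binomial_test(ks[1], ks[2], p0)$p_value,
                   exact_p_oracle(ks[1], ks[2], p0), tolerance = 1e-10,
                   label = sprintf("p(%d/%d vs %.1f)", ks[1], ks[2], p0))
    }
  }
  expect_error(exact_binomial_test(5, 4), "between 0 and trials")
  expect_error(exact_binomial_test(2, 4, null_p = 1), "strictly inside")
})

test_that("Clopper-Pearson intervals invert the binomial tails", {
  expect_equal(unname(clopper_pearson_ci(0, 20)[1]), 0)
  expect_equal(unname(clopper_pearson_ci(20, 20)[2]), 1)
  ci <- clopper_pearson_ci(137, 234)
  expect_equal(unname(ci), c(0.5195, 0.6493), tolerance = 5e-5)
  ci1 <- clopper_pearson_ci(68, 107)
  expect_equal(round(unname(ci1), 2), c(0.54, 0.73))
  # interval contains the point estimate
  expect_lt(ci[1], 137 / 234); expect_gt(ci[2], 137 / 234)
  # spot-check against tail-inversion oracle (full sweep in acceptance)
  for (kn in list(c(3, 11), c(0, 5), c(17, 30), c(25, 50))) {
    expect_equal(unname(clopper_pearson_ci(kn[1], kn[2])),
                 cp_oracle(kn[1], kn[2]), tolerance = 1e-8)
  }
})

test_that("proportion Bayes factor reproduces published values and its invariances", {
  expect_equal(proportion_bayes_factor(68, 107), 9.9, tolerance = 0.02 * 9.9)
  expect_equal(proportion_bayes_factor(137, 234), 4.54,
               tolerance = 0.02 * 4.54)
  # symmetric in k and n - k at a centred null
  for (kn in list(c(68, 107), c(10, 40), c(499, 1000))) {
    expect_equal(proportion_bayes_factor(kn[1], kn[2]),
                 proportion_bayes_factor(kn[2] - kn[1], kn[2]),
                 tolerance = 1e-9)
  }
  # data at the null favour the null; evidence grows with the discrepancy
  expect_lt(proportion_bayes_factor(50, 100), 1)
  bfs <- vapply(c(55, 60, 65, 70), proportion_bayes_factor, numeric(1),
                trials = 100)
  expect_true(all(diff(bfs) > 0))
  # coarse trapezoid oracle on the log-odds axis
  k <- 68; n <- 107
  w <- seq(-6, 6, length.out = 20001)
  num <- sum(dbinom(k, n, plogis(w)) * dlogis(w, 0, 0.5)) * diff(w[1:2])
  expect_equal(proportion_bayes_factor(k, n), num / dbinom(k, n, 0.5),
               tolerance = 1e-4)
})

test_that("Holm-Bonferroni adjustment matches the hand step-down rule", {
  expect_equal(holm_bonferroni(c(0.01)), 0.01)
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(numeric(0)), numeric(0))
  # independent step-down oracle
  holm_oracle <- function(p) {
    o <- order(p)
    m <- length(p)
    adj <- cummax(pmin(1, (m - seq_len(m) + 1) * p[o]))
    out <- numeric(m)
    out[o] <- adj
    out
  }
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    a <- holm_bonferroni(p)
    expect_equal(a, holm_oracle(p), tolerance = 1e-12)
    expect_true(all(a >= p - 1e-15))
    expect_true(all(a <= 1))
  }
  # ties stay tied
  a <- holm_bonferroni(c(0.02, 0.02, 0.5))
  expect_equal(a[1], a[2])
  expect_error(holm_bonferroni(c(0.1, 1.2)), "0, 1")
})
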