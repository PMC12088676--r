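test_that("a null observer notices at chance in both conditions", {
  params <- observer_params(detection_dprime = 0, mean_criterion = 0,
                            criterion_sd = 0)
  cfg <- simulation_config("exp5", n_subjects = 10000, seed = 2)
  rec <- simulate_experiment(params, cfg)
  for (cond in c("present", "absent")) {
    sub <- rec[rec$condition == cond, ]
    rate <- mean(sub$noticed == "yes")
    se <- sqrt(0.25 / nrow(sub))
    expect_lt(abs(rate - 0.5), 3 * se)
  }
})

test_that("the Gaussian observer reproduces the closed-form rate mapping", {
  # with tau = 0 and sigma = 1: H = pnorm(d'/2 - c), FA = pnorm(-d'/2 - c)
  params <- observer_params(detection_dprime = 2, mean_criterion = 0.45)
  cfg <- simulation_config("exp5", n_subjects = 100000, seed = 4)
  rec <- simulate_experiment(params, cfg)
  present <- rec$condition == "present"
  H <- mean(rec$noticed[present] == "yes")
  FA <- mean(rec$noticed[!present] == "yes")
  H_true <- pnorm(2 / 2 - 0.45)    # 0.7088
  FA_true <- pnorm(-2 / 2 - 0.45)  # 0.0735
  expect_lt(abs(H - H_true), 3 * sqrt(H_true * (1 - H_true) / sum(present)))
  expect_lt(abs(FA - FA_true),
            3 * sqrt(FA_true * (1 - FA_true) / sum(!present)))
  # present-condition assignment frequency obeys the design fraction
  expect_lt(abs(mean(present) - 0.75), 3 * sqrt(0.75 * 0.25 / nrow(rec)))
})

test_that("simulation is reproducible under its seed and leaves the RNG state alone", {
  params <- design_default_params("exp4")
  cfg <- simulation_config("exp4", n_subjects = 500, seed = 99)
  set.seed(1234)
  before <- .Random.seed
  r1 <- simulate_experiment(params, cfg)
  expect_identical(.Random.seed, before)
  r2 <- simulate_experiment(params, cfg)
  expect_identical(r1, r2)
  r3 <- simulate_experiment(params, simulation_config("exp4", 500, seed = 100))
  expect_false(identical(r1, r3))
})

test_that("feature channels are independent of detection when uncorrelated", {
  params <- observer_params(detection_dprime = 2, mean_criterion = 0.45,
                            feature_dprime_color = 0.3)
  cfg <- simulation_config("exp5", n_subjects = 40000, seed = 6)
  rec <- simulate_experiment(params, cfg)
  present <- rec[rec$condition == "present", ]
  # condition on the stimulus color so the channel means are fixed
  sub <- present[present$stim_color == "orange", ]
  tab <- table(sub$noticed, sub$color_response)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("a correlated feature channel breaks that independence", {
  params <- observer_params(detection_dprime = 2, mean_criterion = 0.45,
                            feature_dprime_color = 0.3,
                            feature_detection_rho = 0.8)
  cfg <- simulation_config("exp5", n_subjects = 40000, seed = 6)
  rec <- simulate_experiment(params, cfg)
  sub <- rec[rec$condition == "present" & rec$stim_color == "orange", ]
  tab <- table(sub$noticed, sub$color_response)
  expect_lt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("congruency suppression raises the incongruent IB rate; off, the rates match", {
  cfg <- simulation_config("exp4", n_subjects = 20000, seed = 8)
  on_params <- observer_params(detection_dprime = 2.8,
                               mean_criterion = 0.85,
                               congruency_suppression = 1)
  cb_on <- congruency_breakdown(simulate_experiment(on_params, cfg))$notice_rates
  ib_on <- cb_on$ib_rate
  names(ib_on) <- cb_on$congruency
  expect_gt(ib_on[["incongruent"]], ib_on[["congruent"]] + 0.2)

  off_params <- observer_params(detection_dprime = 2.8,
                                mean_criterion = 0.85,
                                congruency_suppression = 0)
  cb_off <- congruency_breakdown(simulate_experiment(off_params, cfg))$notice_rates
  expect_lt(abs(diff(cb_off$ib_rate)),
            3 * sqrt(2 * 0.25 / min(cb_off$n)))
})

test_that("parameter recovery is unbiased when the model assumptions hold", {
  # n chosen so the analytic SE (~0.009 for d') makes the bias bound a
  # many-sigma event rather than a coin flip
  params <- observer_params(detection_dprime = 2, mean_criterion = 0.45)
  cfg <- simulation_config("exp5", n_subjects = 200000, seed = 10)
  rec <- recover_parameters(params, cfg)
  expect_lt(abs(rec$bias[["dprime"]]), 0.02)
  expect_lt(abs(rec$bias[["criterion"]]), 0.02)

  null_rec <- recover_parameters(
    observer_params(detection_dprime = 0, mean_criterion = 0),
    simulation_config("exp5", n_subjects = 200000, seed = 12))
  expect_lt(abs(null_rec$bias[["dprime"]]), 0.02)
  expect_lt(abs(null_rec$bias[["criterion"]]), 0.02)

  expect_error(
    recover_parameters(observer_params(criterion_sd = 1),
                       simulation_config("exp5", 100)),
    "criterion_sd")
  expect_error(
    recover_parameters(observer_params(), simulation_config("exp1", 100)),
    "absent")
})

test_that("invalid observer parameters are rejected", {
  expect_error(observer_params(detection_dprime = -1))
  expect_error(observer_params(confidence_criteria = c(1, 0.5, 2)),
               "increasing")
  expect_error(observer_params(guess_bias_color = 1), "guess biases")
  expect_error(simulation_config("exp5", 0), "n_subjects")
  expect_error(simulation_config("exp5", 10, present_fraction = 0),
               "present_fraction")
})
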