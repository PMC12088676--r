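#' Generative parameters of the simulated observer population
#'
#' The simulator draws, for each subject, Gaussian evidence on a detection
#' axis (noise N(0, 1) on absent trials; signal N(d', sigma) on present
#' trials) and an individual decision criterion placed at
#' `mean_criterion + detection_dprime / 2` on that axis, jittered between
#' subjects with SD `criterion_sd` (tau). Because the criterion is measured
#' from the midpoint between the two distribution means, the generative
#' `mean_criterion` equals the c that the analysis estimates, and with
#' tau = 0 and sigma = 1 the pooled rates are exactly
#' H = pnorm(d'/2 - c), FA = pnorm(-d'/2 - c).
#'
#' Feature responses come from channels that are independent of the
#' detection channel by default (`feature_detection_rho = 0`): color and
#' shape are one-interval channels with their own d' and a guessing bias
#' (the probability of choosing the first feature level at zero evidence);
#' the side response uses a criterion-free two-interval difference rule at
#' `location_dprime`. Confidence (0-3) is read off the distance between the
#' evidence sample and the subject's criterion via three ordered offsets,
#' symmetric for "yes" and "no" responses.
#'
#' @param detection_dprime Detection sensitivity (>= 0).
#' @param signal_sigma Relative SD of the signal-plus-noise distribution.
#' @param mean_criterion Mean criterion c (positive = conservative).
#' @param criterion_sd Between-subject criterion jitter tau (>= 0).
#' @param confidence_criteria Three strictly increasing non-negative offsets
#'   partitioning |evidence - criterion| into confidence 0-3.
#' @param feature_dprime_color,feature_dprime_shape One-interval feature
#'   sensitivities (>= 0).
#' @param location_dprime 2afc location sensitivity (>= 0); recovered
#'   directly by the 1/sqrt(2)-adjusted estimator.
#' @param guess_bias_color,guess_bias_shape,guess_bias_side Probability, in
#'   (0, 1), of choosing the first level (or "left") at zero evidence.
#' @param congruency_suppression Fraction in \[0, 1\] by which detection d'
#'   is reduced when the stimulus color mismatches the attended color
#'   (sustained designs with an attended color).
#' @param feature_detection_rho Correlation in \[0, 1) between the detection
#'   evidence and the feature-channel evidence on present trials (0 =
#'   independent channels).
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(detection_dprime = 2,
                            signal_sigma = 1,
                            mean_criterion = 0.45,
                            criterion_sd = 0,
                            confidence_criteria = c(0.5, 1, 1.5),
                            feature_dprime_color = 0.4,
                            feature_dprime_shape = 0.4,
                            location_dprime = 0.5,
                            guess_bias_color = 0.5,
                            guess_bias_shape = 0.5,
                            guess_bias_side = 0.5,
                            congruency_suppression = 0,
                            feature_detection_rho = 0) {
  stopifnot(detection_dprime >= 0, signal_sigma > 0, criterion_sd >= 0,
            feature_dprime_color >= 0, feature_dprime_shape >= 0,
            location_dprime >= 0,
            congruency_suppression >= 0, congruency_suppression <= 1,
            feature_detection_rho >= 0, feature_detection_rho < 1)
  if (length(confidence_criteria) != 3L ||
      any(diff(confidence_criteria) <= 0) || any(confidence_criteria < 0)) {
    stop("confidence_criteria must be three strictly increasing ",
         "non-negative offsets")
  }
  for (b in c(guess_bias_color, guess_bias_shape, guess_bias_side)) {
    if (b <= 0 || b >= 1) stop("guess biases must lie strictly inside (0, 1)")
  }
  structure(as.list(environment())[c(
    "detection_dprime", "signal_sigma", "mean_criterion", "criterion_sd",
    "confidence_criteria", "feature_dprime_color", "feature_dprime_shape",
    "location_dprime", "guess_bias_color", "guess_bias_shape",
    "guess_bias_side", "congruency_suppression", "feature_detection_rho")],
    class = "observer_params")
}

#' Default observer parameters for a study design
#'
#' Fixed emulation parameters per design, anchored to the published
#' group-level statistics of the corresponding experiment (detection d' and
#' c; absent-condition guess rates where reported; feature sensitivities at
#' the non-noticer point estimates). `exp4` uses full congruency suppression
#' to reproduce the qualitative congruent/incongruent noticing asymmetry.
#'
#' @param design Design name or [experiment_design()].
#' @return An `observer_params` object.
#' @export
design_default_params <- function(design) {
  if (inherits(design, "experiment_design")) design <- design$name
  switch(design,
    exp1 = observer_params(detection_dprime = 2, mean_criterion = 0.435,
                           location_dprime = 1.62),
    exp2 = observer_params(detection_dprime = 1.81, mean_criterion = 0.31,
                           feature_dprime_color = 0.38,
                           guess_bias_color = 0.216),  # strong "blue" bias
    exp3 = observer_params(detection_dprime = 2, mean_criterion = 0.435,
                           location_dprime = 0.9),
    exp4 = observer_params(detection_dprime = 2.82, mean_criterion = 0.85,
                           feature_dprime_color = 0.82,
                           feature_dprime_shape = 0.21,
                           location_dprime = 0.07,
                           congruency_suppression = 1),
    exp5 = observer_params(detection_dprime = 2.01, mean_criterion = 0.45,
                           feature_dprime_color = 0.12,
                           feature_dprime_shape = 0.23,
                           location_dprime = 0.03,
                           guess_bias_color = 0.5295,
                           guess_bias_shape = 0.5143,
                           guess_bias_side = 0.5487),
    stop("unknown design: ", design))
}

#' Simulation configuration
#'
#' @param design Design name or [experiment_design()].
#' @param n_subjects Number of simulated subjects (>= 1).
#' @param present_fraction Probability of the present condition; defaults to
#'   the design's value (1 for exp1/exp3, 2/3 for exp2, 3/4 for exp4/exp5).
#' @param seed Integer RNG seed; the simulation uses a single seeded stream
#'   and is fully reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(design, n_subjects, present_fraction = NULL,
                              seed = 1L) {
  if (is.character(design)) design <- experiment_design(design)
  stopifnot(inherits(design, "experiment_design"),
            n_subjects >= 1, n_subjects == round(n_subjects))
  if (is.null(present_fraction)) present_fraction <- design$present_fraction
  if (present_fraction <= 0 || present_fraction > 1) {
    stop("present_fraction must lie in (0, 1]")
  }
  structure(list(design = design, n_subjects = as.integer(n_subjects),
                 present_fraction = present_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a single-critical-trial experiment
#'
#' Draws one critical trial per subject under the Gaussian-evidence observer
#' model of [observer_params()] and the design of [simulation_config()],
#' returning records in the CSV schema of [critical_trial_records].
#'
#' @param params An [observer_params()].
#' @param config A [simulation_config()].
#' @return A validated record data frame with `config$n_subjects` rows.
#' @examples
#' cfg <- simulation_config("exp5", n_subjects = 500, seed = 7)
#' rec <- simulate_experiment(design_default_params("exp5"), cfg)
#' head(rec)
#' @export
simulate_experiment <- function(params, config) {
  stopifnot(inherits(params, "observer_params"),
            inherits(config, "simulation_config"))
  design <- config$design
  n <- config$n_subjects
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  present <- stats::runif(n) < config$present_fraction
  pick <- function(levels) {
    if (is.null(levels)) rep("", n)
    else ifelse(present, sample(levels, n, replace = TRUE), "")
  }
  stim_color <- pick(design$colors)
  stim_shape <- pick(design$shapes)
  stim_side <- pick(design$sides)
  attended <- if (is.null(design$attended_colors)) rep("", n) else
    sample(design$attended_colors, n, replace = TRUE)

  # detection channel
  d_eff <- rep(0, n)
  d_eff[present] <- params$detection_dprime
  if (params$congruency_suppression > 0 && any(attended != "")) {
    incong <- present & attended != "" & stim_color != attended
    d_eff[incong] <- params$detection_dprime *
      (1 - params$congruency_suppression)
  }
  ev_sd <- ifelse(present, params$signal_sigma, 1)
  evidence <- stats::rnorm(n, mean = d_eff, sd = ev_sd)
  crit <- params$mean_criterion + params$detection_dprime / 2 +
    stats::rnorm(n, 0, params$criterion_sd)
  noticed <- ifelse(evidence > crit, "yes", "no")
  confidence <- if (design$has_confidence) {
    findInterval(abs(evidence - crit), params$confidence_criteria)
  } else rep(NA_integer_, n)

  z_det <- (evidence - d_eff) / ev_sd  # standardized detection noise
  rho <- params$feature_detection_rho
  channel_noise <- function() {
    eps <- stats::rnorm(n)
    if (rho > 0) rho * z_det + sqrt(1 - rho^2) * eps else eps
  }

  # one-interval feature channels (first level plays the signal role)
  one_interval_response <- function(levels, stim, dprime, bias) {
    if (is.null(levels)) return(rep("", n))
    mu <- ifelse(stim == levels[1], dprime / 2,
                 ifelse(stim == "", 0, -dprime / 2))
    e <- mu + channel_noise()
    ifelse(e > stats::qnorm(1 - bias), levels[1],
           levels[length(levels)])
  }
  color_response <- if ("color" %in% design$questions) {
    one_interval_response(design$colors, stim_color,
                          params$feature_dprime_color,
                          params$guess_bias_color)
  } else rep("", n)
  shape_response <- if ("shape" %in% design$questions) {
    one_interval_response(design$shapes, stim_shape,
                          params$feature_dprime_shape,
                          params$guess_bias_shape)
  } else rep("", n)

  # 2afc location channel: evidence in each interval, decide on the
  # difference; the bias shifts the (nominally zero) difference criterion
  side_response <- if ("side" %in% design$questions) {
    mu_l <- ifelse(stim_side == "left", params$location_dprime, 0)
    mu_r <- ifelse(stim_side == "right", params$location_dprime, 0)
    diff <- (mu_l + channel_noise()) - (mu_r + stats::rnorm(n))
    thresh <- sqrt(2) * stats::qnorm(1 - params$guess_bias_side)
    ifelse(diff > thresh, "left", "right")
  } else rep("", n)

  records <- data.frame(
    subject_id = sprintf("s%06d", seq_len(n)),
    experiment_id = design$name,
    condition = ifelse(present, "present", "absent"),
    stim_color = stim_color, stim_shape = stim_shape, stim_side = stim_side,
    attended_color = attended,
    noticed = noticed,
    notice_confidence = confidence,
    color_response = color_response,
    shape_response = shape_response,
    side_response = side_response,
    excluded = FALSE,
    exclusion_reason = "",
    stringsAsFactors = FALSE)
  validate_records(records)
}
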