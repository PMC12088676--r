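#' Parameter recovery check for the super-subject estimators
#'
#' Simulates an experiment under the observer model with its assumptions
#' satisfied (no criterion jitter, equal variance), analyzes it with
#' [analyze_experiment()], and reports estimate minus truth for the
#' detection d' and c. With the criterion-midpoint convention the generative
#' parameters are exactly the quantities the analysis estimates, so at large
#' n both biases should vanish (up to the log-linear correction's slight
#' shrinkage and sampling error).
#'
#' @param params An [observer_params()] with `criterion_sd = 0` and
#'   `signal_sigma = 1`.
#' @param config A [simulation_config()] whose design includes an absent
#'   condition.
#' @return A list with `truth`, `estimate`, `bias` (each holding `dprime`
#'   and `criterion`), the `report`, and `n_subjects`.
#' @examples
#' cfg <- simulation_config("exp5", n_subjects = 20000, seed = 3)
#' recover_parameters(design_default_params("exp5"), cfg)$bias
#' @export
recover_parameters <- function(params, config) {
  stopifnot(inherits(params, "observer_params"),
            inherits(config, "simulation_config"))
  if (params$criterion_sd != 0 || params$signal_sigma != 1) {
    stop("recovery assumes criterion_sd = 0 and signal_sigma = 1; use ",
         "criterion_jitter_study() to explore violations")
  }
  if (!config$design$has_absent) {
    stop("recovery of detection d' and c needs a design with absent trials")
  }
  records <- simulate_experiment(params, config)
  report <- analyze_experiment(records, config$design)
  truth <- c(dprime = params$detection_dprime,
             criterion = params$mean_criterion)
  estimate <- c(dprime = report$detection$dprime$value,
                criterion = report$detection$criterion$value)
  list(truth = truth, estimate = estimate, bias = estimate - truth,
       report = report, n_subjects = config$n_subjects)
}

#' Effect of between-subject criterion jitter on pooled estimates
#'
#' For each criterion jitter value tau in `tau_grid`, simulates the design
#' and estimates (a) the one-interval detection d' from the pooled yes/no
#' noticing matrix and (b) the 2afc location d' from the side responses of
#' all present-condition subjects. Criterion variability mixes subjects
#' with different effective operating points and so attenuates the pooled
#' one-interval estimate, while the criterion-free 2afc estimate is
#' unaffected — the asymmetry that makes the 2afc results robust to
#' criterion instability.
#'
#' @param params Baseline [observer_params()] (its `criterion_sd` is
#'   overridden by the grid).
#' @param tau_grid Non-empty numeric vector of jitter SDs; should include 0.
#' @param config A [simulation_config()] whose design has absent trials and
#'   asks the side question (exp4/exp5).
#' @return A data frame with one row per tau: estimated `dprime_yesno` and
#'   `dprime_2afc` with their analytic standard errors.
#' @export
criterion_jitter_study <- function(params, tau_grid, config) {
  stopifnot(inherits(params, "observer_params"),
            inherits(config, "simulation_config"))
  if (length(tau_grid) == 0L) stop("tau_grid must be non-empty")
  if (any(tau_grid < 0)) stop("tau values must be non-negative")
  if (!config$design$has_absent || !"side" %in% config$design$questions) {
    stop("the jitter study needs a design with absent trials and a side ",
         "question (exp4 or exp5)")
  }
  rows <- lapply(seq_along(tau_grid), function(i) {
    p <- params
    p$criterion_sd <- tau_grid[i]
    cfg <- config
    cfg$seed <- config$seed + i - 1L  # independent draws per grid point
    records <- simulate_experiment(p, cfg)

    dm <- detection_matrix(records)
    det <- dprime_yesno(log_linear_correct(dm), dm)

    present <- records[records$condition == "present", , drop = FALSE]
    tm <- twoafc_matrix(present)
    loc <- dprime_2afc(log_linear_correct(tm), tm)

    data.frame(tau = tau_grid[i],
               dprime_yesno = det$value, se_yesno = sqrt(det$variance),
               dprime_2afc = loc$value, se_2afc = sqrt(loc$variance))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
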