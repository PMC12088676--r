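#' Full super-subject analysis of one experiment
#'
#' Runs the complete group-level analysis for a critical-trial dataset:
#'
#' * the inattentional blindness rate (proportion of present-condition
#'   subjects answering "no" to the noticing question);
#' * when the design includes an absent condition, the super-subject
#'   detection statistics d' and c for the noticing question, with analytic
#'   variances and Wald confidence intervals;
#' * for the non-noticer subset, sensitivity on each feature question —
#'   location as 2afc (1/sqrt(2)-adjusted, criterion-free), color and shape
#'   as one-interval d' plus criterion — and the companion percent-correct
#'   test against chance (exact binomial p, Clopper-Pearson CI, Bayes
#'   factor);
#' * for confidence-rating designs, d'_2afc per (response x confidence) bin
#'   with Holm-Bonferroni adjustment across the bins;
#' * for attended-color designs, the congruency breakdown of notice rates;
#' * the absent-condition guessing rates per feature.
#'
#' @param records Validated critical-trial records of a single experiment.
#' @param design An [experiment_design()] (or its name).
#' @param conf_level Confidence level for all intervals.
#' @param sigma Relative SD of the signal-plus-noise distribution for an
#'   optional unequal-variance reanalysis of the detection statistics
#'   (default 1 = equal variance).
#' @return An object of class `experiment_report`.
#' @export
analyze_experiment <- function(records, design, conf_level = 0.95,
                               sigma = 1) {
  if (is.character(design)) design <- experiment_design(design)
  stopifnot(inherits(design, "experiment_design"))
  r <- included_records(records)
  if (nrow(r) == 0L) stop("no non-excluded records to analyze")
  if (!all(r$experiment_id == r$experiment_id[1])) {
    stop("records mix several experiment_id values; analyze one experiment ",
         "at a time")
  }
  present <- r[r$condition == "present", , drop = FALSE]
  if (nrow(present) == 0L) stop("no present-condition records")
  has_absent_records <- any(r$condition == "absent")
  if (design$has_absent != has_absent_records) {
    stop("design/record mismatch: design '", design$name,
         if (design$has_absent) "' expects absent-condition records"
         else "' has no absent condition but the records do")
  }

  report <- list(design = design$name,
                 n_included = nrow(r),
                 n_excluded = sum(records$excluded),
                 n_present = nrow(present),
                 n_absent = nrow(r) - nrow(present),
                 conf_level = conf_level,
                 sigma = sigma)
  report$ib_rate <- mean(present$noticed == "no")

  if (design$has_absent) {
    dm <- detection_matrix(r)
    rates <- log_linear_correct(dm)
    report$detection <- list(
      matrix = dm, rates = rates,
      dprime = if (sigma == 1) dprime_yesno(rates, dm, conf_level)
               else d_a(rates, sigma, dm, conf_level),
      criterion = if (sigma == 1) criterion_c(rates, dm, conf_level)
                  else c_a(rates, sigma, dm, conf_level))
  }

  nonnot <- present[present$noticed == "no", , drop = FALSE]
  report$n_nonnoticers <- nrow(nonnot)
  report$features <- list()
  for (q in design$questions) {
    report$features[[q]] <- analyze_feature(nonnot, q, conf_level)
  }

  if (design$has_confidence) {
    report$confidence_bins <- confidence_bin_analysis(present, conf_level)
  }
  if (!is.null(design$attended_colors)) {
    report$congruency <- congruency_breakdown(r)
  }
  if (design$has_absent) {
    report$absent_guess_rates <- absent_guess_rates(
      r, questions = design$questions)
  }
  class(report) <- "experiment_report"
  report
}

# Sensitivity + percent-correct inference for one feature question among a
# subject subset (the non-noticers, in the standard analysis).
analyze_feature <- function(records, question, conf_level = 0.95) {
  resp_col <- paste0(switch(question, side = "side", question), "_response")
  stim_col <- paste0("stim_", switch(question, side = "side", question))
  usable <- records[records[[resp_col]] != "" & records[[stim_col]] != "", ,
                    drop = FALSE]
  if (nrow(usable) == 0L) {
    stop("no usable records for the ", question, " question")
  }
  correct <- sum(usable[[resp_col]] == usable[[stim_col]])
  ptest <- exact_binomial_test(correct, nrow(usable), null_p = 0.5,
                               conf_level = conf_level)
  ptest$bf10 <- proportion_bayes_factor(correct, nrow(usable))
  if (question == "side") {
    m <- twoafc_matrix(usable)
    rates <- log_linear_correct(m)
    list(question = question, n = nrow(usable),
         percent_correct = correct / nrow(usable),
         proportion_test = ptest, matrix = m, rates = rates,
         dprime = dprime_2afc(rates, m, conf_level))
  } else {
    m <- one_interval_matrix(usable, feature = question)
    rates <- log_linear_correct(m)
    list(question = question, n = nrow(usable),
         percent_correct = correct / nrow(usable),
         proportion_test = ptest, matrix = m, rates = rates,
         dprime = dprime_yesno(rates, m, conf_level),
         criterion = criterion_c(rates, m, conf_level))
  }
}

# d'_2afc per (noticed x confidence) bin over all present-condition
# subjects, with Holm-Bonferroni adjustment of the per-bin tests against
# d' = 0 across however many bins have data. Bins with fewer than 20
# subjects are flagged as under-powered.
confidence_bin_analysis <- function(present, conf_level = 0.95,
                                    min_n = 20L) {
  usable <- present[!is.na(present$notice_confidence) &
                      present$side_response != "", , drop = FALSE]
  if (nrow(usable) == 0L) stop("no confidence-rated records")
  rows <- list()
  for (resp in c("no", "yes")) {
    for (conf in 0:3) {
      bin <- usable[usable$noticed == resp &
                      usable$notice_confidence == conf, , drop = FALSE]
      if (nrow(bin) == 0L) next
      est <- tryCatch({
        m <- twoafc_matrix(bin)
        dprime_2afc(log_linear_correct(m), m, conf_level)
      }, error = function(e) NULL)
      if (is.null(est)) next
      z <- est$value / sqrt(est$variance)
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, confidence = conf, n = nrow(bin),
        dprime_2afc = est$value, se = sqrt(est$variance),
        ci_low = est$ci_low, ci_high = est$ci_high,
        p_value = 2 * stats::pnorm(-abs(z)),
        underpowered = nrow(bin) < min_n)
    }
  }
  out <- do.call(rbind, rows)
  out$p_holm <- holm_bonferroni(out$p_value)
  rownames(out) <- NULL
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment report (%s): %d subjects (%d present, %d absent)\n",
              x$design, x$n_included, x$n_present, x$n_absent))
  cat(sprintf("  IB rate: %.1f%% (%d non-noticers)\n",
              100 * x$ib_rate, x$n_nonnoticers))
  if (!is.null(x$detection)) {
    cat("  Noticing question (all subjects):\n    ")
    print(x$detection$dprime)
    cat("    ")
    print(x$detection$criterion)
  }
  for (f in x$features) {
    cat(sprintf("  %s question (non-noticers, n = %d): %.1f%% correct, BF10 = %.3g\n",
                f$question, f$n, 100 * f$percent_correct,
                f$proportion_test$bf10))
    cat("    ")
    print(f$dprime)
  }
  if (!is.null(x$confidence_bins)) {
    cat("  Confidence bins (d'_2afc by response x confidence):\n")
    print(x$confidence_bins, digits = 3)
  }
  invisible(x)
}

#' Flatten an experiment report to a summary table
#'
#' @param report An `experiment_report`.
#' @return A data frame with one row per statistic (`statistic`, `group`,
#'   `n`, `value`, `ci_low`, `ci_high`), convenient for CSV export.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  rows <- list(data.frame(statistic = "ib_rate", group = "present",
                          n = report$n_present, value = report$ib_rate,
                          ci_low = NA_real_, ci_high = NA_real_))
  est_row <- function(stat, group, n, est) {
    data.frame(statistic = stat, group = group, n = n, value = est$value,
               ci_low = est$ci_low, ci_high = est$ci_high)
  }
  if (!is.null(report$detection)) {
    n <- report$n_included
    rows <- c(rows, list(
      est_row("detection_dprime", "all", n, report$detection$dprime),
      est_row("detection_criterion", "all", n, report$detection$criterion)))
  }
  for (f in report$features) {
    rows <- c(rows, list(
      est_row(paste0(f$question, "_dprime"), "non-noticers", f$n, f$dprime),
      data.frame(statistic = paste0(f$question, "_pct_correct"),
                 group = "non-noticers", n = f$n, value = f$percent_correct,
                 ci_low = f$proportion_test$ci_low,
                 ci_high = f$proportion_test$ci_high)))
    if (!is.null(f$criterion)) {
      rows <- c(rows, list(est_row(paste0(f$question, "_criterion"),
                                   "non-noticers", f$n, f$criterion)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
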