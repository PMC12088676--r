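#' Two-sided exact binomial test against a null proportion
#'
#' Wraps [stats::binom.test()] (two-sided, small-probability-mass rule: the
#' p-value sums the probabilities of all outcomes no more likely than the one
#' observed) and pairs the exact Clopper-Pearson interval with the point
#' estimate. Used to compare non-noticers' forced-choice accuracy with the
#' 50% expected under chance responding.
#'
#' @param successes,trials Integer counts, `0 <= successes <= trials`.
#' @param null_p Null proportion, strictly inside (0, 1); default 0.5.
#' @param conf_level Confidence level for the Clopper-Pearson interval.
#' @return An object of class `proportion_test`: a list with `successes`,
#'   `trials`, `estimate`, `null_p`, `p_value`, `ci_low`, `ci_high`,
#'   `conf_level` and `bf10` (`NA` until filled by
#'   [proportion_bayes_factor()]).
#' @examples
#' exact_binomial_test(68, 107)
#' @export
exact_binomial_test <- function(successes, trials, null_p = 0.5,
                                conf_level = 0.95) {
  check_counts(successes, trials)
  if (!is.numeric(null_p) || null_p <= 0 || null_p >= 1) {
    stop("null_p must lie strictly inside (0, 1)")
  }
  ht <- stats::binom.test(successes, trials, p = null_p,
                          conf.level = conf_level)
  structure(list(successes = as.integer(successes),
                 trials = as.integer(trials),
                 estimate = successes / trials,
                 null_p = null_p,
                 p_value = ht$p.value,
                 ci_low = ht$conf.int[1],
                 ci_high = ht$conf.int[2],
                 conf_level = conf_level,
                 bf10 = NA_real_),
            class = "proportion_test")
}

#' @export
print.proportion_test <- function(x, ...) {
  cat(sprintf(
    "%d/%d = %.1f%% vs %.0f%%: p = %.4g, %d%% CI [%.4f, %.4f]%s\n",
    x$successes, x$trials, 100 * x$estimate, 100 * x$null_p, x$p_value,
    round(100 * x$conf_level), x$ci_low, x$ci_high,
    if (is.na(x$bf10)) "" else sprintf(", BF10 = %.3g", x$bf10)))
  invisible(x)
}

check_counts <- function(successes, trials) {
  if (!is.numeric(successes) || !is.numeric(trials) ||
      length(successes) != 1L || length(trials) != 1L ||
      anyNA(c(successes, trials)) ||
      successes != round(successes) || trials != round(trials)) {
    stop("successes and trials must be single integers")
  }
  if (trials < 1L) stop("trials must be at least 1")
  if (successes < 0L || successes > trials) {
    stop("successes must lie between 0 and trials")
  }
  invisible(NULL)
}

#' Exact (Clopper-Pearson) confidence interval for a binomial proportion
#'
#' Inverts the binomial tail probabilities through the beta-quantile form:
#' lower = qbeta(alpha/2; k, n - k + 1), upper = qbeta(1 - alpha/2; k + 1,
#' n - k), with the conventional boundary values 0 (k = 0) and 1 (k = n).
#'
#' @inheritParams exact_binomial_test
#' @param level Confidence level in (0, 1).
#' @return A length-2 numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson_ci(137, 234)
#' @export
clopper_pearson_ci <- function(successes, trials, level = 0.95) {
  check_counts(successes, trials)
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)")
  }
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' Bayes factor for a binomial proportion against a point null
#'
#' BF10 compares the marginal likelihood of the data under an alternative
#' that places a logistic prior on the log-odds of success — centred at
#' `logit(null_p)` with scale `prior_scale` — against the likelihood at the
#' point null:
#'
#' BF10 = \[ integral of Binom(k; n, plogis(w)) Logistic(w; logit(p0), r) dw \]
#'        / Binom(k; n, p0).
#'
#' The default scale `r = 0.5` matches the conventional default of Bayesian
#' proportion tests. The integrand is evaluated as a likelihood *ratio* in
#' log space, so the quadrature is stable even at very large n, and is
#' integrated adaptively over the whole real line.
#'
#' @inheritParams exact_binomial_test
#' @param prior_scale Positive scale of the logistic prior on the log-odds.
#' @param rel_tol Relative tolerance requested from the quadrature.
#' @return The Bayes factor BF10 (positive scalar). Values above 1 favour the
#'   alternative; at `null_p = 0.5` the BF is symmetric in k and n - k.
#' @examples
#' proportion_bayes_factor(68, 107)   # location accuracy of non-noticers
#' @export
proportion_bayes_factor <- function(successes, trials, null_p = 0.5,
                                    prior_scale = 0.5, rel_tol = 1e-8) {
  check_counts(successes, trials)
  if (!is.numeric(null_p) || null_p <= 0 || null_p >= 1) {
    stop("null_p must lie strictly inside (0, 1)")
  }
  if (!is.numeric(prior_scale) || prior_scale <= 0) {
    stop("prior_scale must be positive")
  }
  mu <- stats::qlogis(null_p)
  log_l0 <- stats::dbinom(successes, trials, null_p, log = TRUE)
  # centre the log likelihood ratio on its value at the (interior-clamped)
  # MLE so the integrand never overflows, even when the data sit hundreds of
  # log units above the null; the shift is undone on the log scale at the end
  p_hat <- min(max(successes / trials, 1 / (trials + 1)),
               trials / (trials + 1))
  shift <- stats::dbinom(successes, trials, p_hat, log = TRUE) - log_l0
  integrand <- function(w) {
    exp(stats::dbinom(successes, trials, stats::plogis(w), log = TRUE) -
          log_l0 - shift) * stats::dlogis(w, mu, prior_scale)
  }
  quad <- tryCatch(
    stats::integrate(integrand, lower = -Inf, upper = Inf,
                     rel.tol = rel_tol, subdivisions = 500L),
    error = function(e) e)
  if (inherits(quad, "error") || quad$message != "OK") {
    # fall back to a wide finite window around the prior mode; if that also
    # fails, report the quadrature diagnostics
    quad <- stats::integrate(integrand, lower = mu - 24 * prior_scale,
                             upper = mu + 24 * prior_scale,
                             rel.tol = rel_tol, subdivisions = 500L)
    if (quad$message != "OK") {
      stop("Bayes factor quadrature did not converge: ", quad$message,
           " (abs.error = ", format(quad$abs.error), ")")
    }
  }
  if (quad$value <= 0) {
    stop("Bayes factor quadrature degenerated to zero mass; widen the ",
         "prior scale or check the inputs")
  }
  exp(shift + log(quad$value))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Standard step-down multiplicity correction via
#' [stats::p.adjust()]: sort ascending, multiply the i-th smallest p-value by
#' (m - i + 1), enforce monotonicity and cap at 1. Used across the eight
#' (response x confidence) bins of the confidence-rating analysis.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the original order (empty input returns an
#'   empty vector).
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03))
#' @export
holm_bonferroni <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0) || any(p_values > 1)) {
    stop("p_values must all lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm")
}
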