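#' Normal quantile (z) transform of a proportion
#'
#' @param p A proportion strictly inside (0, 1).
#' @return The standard-normal quantile of `p`; `z_transform(0.5)` is 0.
#' @export
z_transform <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1)) {
    stop("z_transform is defined only for proportions strictly inside (0, 1)")
  }
  stats::qnorm(p)
}

#' Standard-normal density at the z-transform of a proportion
#'
#' Evaluates phi(p) = (1 / sqrt(2 * pi)) * exp(-z(p)^2 / 2), the ordinate of
#' the standard normal at the quantile of `p`. This is the weight that enters
#' the analytic variance of d' and c: rates near 0 or 1 sit in the flat tails
#' (small phi) and so contribute large variance.
#'
#' @param p A proportion strictly inside (0, 1).
#' @return The density value; maximal (0.3989) at p = 0.5 and symmetric about
#'   it.
#' @export
phi_at <- function(p) {
  stats::dnorm(z_transform(p))
}

new_sdt_estimate <- function(kind, value, variance = NULL,
                             conf_level = 0.95) {
  est <- structure(list(statistic_kind = kind, value = value,
                        variance = variance, ci_low = NA_real_,
                        ci_high = NA_real_, conf_level = conf_level),
                   class = "sdt_estimate")
  if (!is.null(variance)) est <- wald_ci(est, conf_level) else est
}

#' @export
print.sdt_estimate <- function(x, ...) {
  lab <- c(dprime_yesno = "d'", dprime_2afc = "d'_2afc", criterion = "c",
           d_a = "d_a", c_a = "c_a")[x$statistic_kind]
  cat(sprintf("%s = %.4f", lab, x$value))
  if (!is.null(x$variance)) {
    cat(sprintf("  (SE = %.4f, %d%% CI [%.4f, %.4f])",
                sqrt(x$variance), round(100 * x$conf_level),
                x$ci_low, x$ci_high))
  }
  cat("\n")
  invisible(x)
}

# Attach the analytic variance implied by `matrix` (if supplied) using the
# appropriate variance function for the statistic kind. The unequal-variance
# indices reuse the equal-variance delta-method weights; at the modest sigma
# values used for robustness checks the difference is negligible.
maybe_variance <- function(est, rates, matrix, conf_level) {
  if (is.null(matrix)) return(est)
  v <- switch(est$statistic_kind,
              dprime_yesno = ,
              d_a = var_dprime_yesno(rates, matrix),
              dprime_2afc = var_dprime_2afc(rates, matrix),
              criterion = ,
              c_a = var_criterion(rates, matrix))
  est$variance <- v
  wald_ci(est, conf_level)
}

#' Super-subject yes/no sensitivity d'
#'
#' The equal-variance Gaussian sensitivity index d' = z(H) - z(FA): the
#' standardized separation between the noise and signal-plus-noise evidence
#' distributions, independent of where the group places its criterion.
#'
#' @param rates A [rate_pair()] of (corrected) hit and false-alarm rates.
#' @param matrix Optional [decision_matrix()] supplying the trial totals; when
#'   given, the analytic variance ([var_dprime_yesno()]) and a Wald confidence
#'   interval are attached.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An `sdt_estimate`.
#' @examples
#' dprime_yesno(rate_pair(0.71, 0.073))
#' @export
dprime_yesno <- function(rates, matrix = NULL, conf_level = 0.95) {
  stopifnot(inherits(rates, "rate_pair"))
  est <- new_sdt_estimate("dprime_yesno",
                          z_transform(rates$H) - z_transform(rates$FA))
  maybe_variance(est, rates, matrix, conf_level)
}

#' Super-subject response bias (criterion) c
#'
#' c = -(z(H) + z(FA)) / 2, the location of the pooled decision criterion
#' relative to the midpoint of the noise and signal-plus-noise distributions.
#' Positive values are conservative (a preference for "no" independent of the
#' stimulus), negative values liberal; c = 0 exactly when FA = 1 - H.
#'
#' @inheritParams dprime_yesno
#' @return An `sdt_estimate` (variance via [var_criterion()] when `matrix` is
#'   given).
#' @examples
#' criterion_c(rate_pair(0.71, 0.073))
#' @export
criterion_c <- function(rates, matrix = NULL, conf_level = 0.95) {
  stopifnot(inherits(rates, "rate_pair"))
  est <- new_sdt_estimate("criterion",
                          -0.5 * (z_transform(rates$H) + z_transform(rates$FA)))
  maybe_variance(est, rates, matrix, conf_level)
}

#' Two-alternative forced-choice sensitivity d'_2afc
#'
#' For a 2afc question one alternative (e.g. "stimulus on the left") is
#' designated "present" and the matrix is built as if it were a yes/no task;
#' sensitivity is then adjusted downward by 1/sqrt(2) because the observer
#' sees both intervals and decides on their difference, which makes the task
#' theoretically easier than one-interval detection:
#' d'_2afc = (z(H) - z(FA)) / sqrt(2). Swapping which alternative is called
#' "present" flips the sign but not the magnitude.
#'
#' @inheritParams dprime_yesno
#' @return An `sdt_estimate` (variance via [var_dprime_2afc()] when `matrix`
#'   is given).
#' @examples
#' dprime_2afc(rate_pair(0.7264, 0.4554))
#' @export
dprime_2afc <- function(rates, matrix = NULL, conf_level = 0.95) {
  stopifnot(inherits(rates, "rate_pair"))
  est <- new_sdt_estimate("dprime_2afc",
                          (z_transform(rates$H) - z_transform(rates$FA)) / sqrt(2))
  maybe_variance(est, rates, matrix, conf_level)
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop("sigma (relative SD of the signal-plus-noise distribution) must be ",
         "a single positive number")
  }
}

#' Unequal-variance sensitivity index d_a
#'
#' Generalizes d' to a signal-plus-noise distribution whose standard
#' deviation is `sigma` times that of the noise distribution (ROC slope
#' s = 1/sigma): d_a = sqrt(2 / (1 + s^2)) * (z(H) - s * z(FA)). Reduces
#' exactly to [dprime_yesno()] at sigma = 1. Used to check robustness of the
#' equal-variance results to violations of the equal-variance assumption in
#' one-interval tasks.
#'
#' @inheritParams dprime_yesno
#' @param sigma Positive relative standard deviation of the signal-plus-noise
#'   distribution (noise SD fixed at 1).
#' @return An `sdt_estimate` of kind `d_a`.
#' @examples
#' d_a(rate_pair(0.71, 0.073), sigma = 1.25)
#' @export
d_a <- function(rates, sigma, matrix = NULL, conf_level = 0.95) {
  stopifnot(inherits(rates, "rate_pair"))
  check_sigma(sigma)
  s <- 1 / sigma
  val <- sqrt(2 / (1 + s^2)) * (z_transform(rates$H) - s * z_transform(rates$FA))
  est <- new_sdt_estimate("d_a", val)
  maybe_variance(est, rates, matrix, conf_level)
}

#' Unequal-variance bias index c_a
#'
#' The criterion analogue of [d_a()]:
#' c_a = -(sqrt(2) * s / sqrt(1 + s^2)) * (z(H) + z(FA)) / (1 + s) with
#' s = 1/sigma. Reduces exactly to [criterion_c()] at sigma = 1.
#'
#' @inheritParams d_a
#' @return An `sdt_estimate` of kind `c_a`.
#' @examples
#' c_a(rate_pair(0.71, 0.073), sigma = 1.25)
#' @export
c_a <- function(rates, sigma, matrix = NULL, conf_level = 0.95) {
  stopifnot(inherits(rates, "rate_pair"))
  check_sigma(sigma)
  s <- 1 / sigma
  val <- -(sqrt(2) * s / sqrt(1 + s^2)) *
    (z_transform(rates$H) + z_transform(rates$FA)) / (1 + s)
  est <- new_sdt_estimate("c_a", val)
  maybe_variance(est, rates, matrix, conf_level)
}

var_terms <- function(rates, matrix) {
  stopifnot(inherits(rates, "rate_pair"), inherits(matrix, "decision_matrix"))
  if (matrix$n_present < 1L || matrix$n_absent < 1L) {
    stop("variance requires at least one present and one absent trial")
  }
  H <- rates$H; FA <- rates$FA
  c(h = H * (1 - H) / (matrix$n_present * phi_at(H)^2),
    f = FA * (1 - FA) / (matrix$n_absent * phi_at(FA)^2))
}

#' Analytic variance of the pooled yes/no d'
#'
#' The delta-method (Gourevitch-Galanter) variance of d' for a
#' forced-response one-interval task:
#' var(d') = H(1-H) / (N2 * phi(H)^2) + FA(1-FA) / (N1 * phi(FA)^2),
#' where N2 and N1 are the numbers of present and absent trials. Every
#' subject responds (no "not sure" outcome), so each pooled rate is a simple
#' binomial proportion.
#'
#' @param rates A [rate_pair()].
#' @param matrix The [decision_matrix()] supplying N1 and N2.
#' @return The variance (a positive scalar).
#' @export
var_dprime_yesno <- function(rates, matrix) {
  sum(var_terms(rates, matrix))
}

#' Analytic variance of d'_2afc
#'
#' Identical to [var_dprime_yesno()] except for a factor of 2 in the
#' denominator of both terms, reflecting the 1/sqrt(2) scaling of the 2afc
#' statistic: var(d'_2afc) = var(d')/2 at identical rates and trial counts.
#'
#' @inheritParams var_dprime_yesno
#' @return The variance.
#' @export
var_dprime_2afc <- function(rates, matrix) {
  sum(var_terms(rates, matrix)) / 2
}

#' Analytic variance of the criterion c
#'
#' Since c = -(z(H) + z(FA))/2, the delta method gives
#' var(c) = (var(z(H)) + var(z(FA))) / 4 = var(d')/4 at identical inputs.
#'
#' @inheritParams var_dprime_yesno
#' @return The variance.
#' @export
var_criterion <- function(rates, matrix) {
  sum(var_terms(rates, matrix)) / 4
}

#' Wald confidence interval for an SDT estimate
#'
#' value +/- qnorm((1 + level)/2) * sqrt(variance), symmetric around the
#' point estimate.
#'
#' @param estimate An `sdt_estimate` carrying a variance.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return The estimate with `ci_low`, `ci_high` and `conf_level` filled in.
#' @export
wald_ci <- function(estimate, level = 0.95) {
  stopifnot(inherits(estimate, "sdt_estimate"))
  if (is.null(estimate$variance)) {
    stop("no variance available: supply a decision matrix to the estimator ",
         "or set estimate$variance before calling wald_ci()")
  }
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)")
  }
  half <- stats::qnorm((1 + level) / 2) * sqrt(estimate$variance)
  estimate$ci_low <- estimate$value - half
  estimate$ci_high <- estimate$value + half
  estimate$conf_level <- level
  estimate
}
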