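# Build a small record data frame from per-cell counts; every argument is a
# named count of identical rows described by the `...` templates.
make_records <- function(..., experiment_id = "exp5") {
  rows <- list(...)
  template <- list(
    subject_id = NA_character_, experiment_id = experiment_id,
    condition = "present", stim_color = "", stim_shape = "", stim_side = "",
    attended_color = "", noticed = "no", notice_confidence = NA_integer_,
    color_response = "", shape_response = "", side_response = "",
    excluded = FALSE, exclusion_reason = "")
  out <- do.call(rbind, lapply(rows, function(spec) {
    n <- spec$n
    spec$n <- NULL
    row <- utils::modifyList(template, spec)
    df <- as.data.frame(row, stringsAsFactors = FALSE)
    df[rep(1L, n), , drop = FALSE]
  }))
  out$subject_id <- sprintf("s%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# Numerical inversion of the standard-normal CDF by bisection-free root
# finding: an oracle for z_transform that never calls qnorm.
z_oracle <- function(p) {
  stats::uniroot(function(x) stats::pnorm(x) - p, c(-10, 10),
                 tol = 1e-12)$root
}

# Clopper-Pearson oracle: invert the binomial tail probabilities directly
# with uniroot on pbinom (no beta quantiles involved).
cp_oracle <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  lower <- if (k == 0) 0 else
    stats::uniroot(function(p) 1 - stats::pbinom(k - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (k == n) 1 else
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower, upper)
}

# Two-sided exact binomial p-value by brute-force enumeration over all
# outcomes (small-probability-mass rule, with the conventional relative
# tolerance for ties).
exact_p_oracle <- function(k, n, p0 = 0.5) {
  probs <- stats::dbinom(0:n, n, p0)
  min(1, sum(probs[probs <= probs[k + 1] * (1 + 1e-7)]))
}
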