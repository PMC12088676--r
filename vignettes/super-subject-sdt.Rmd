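---
title: "Super-subject signal detection for single-critical-trial experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-subject signal detection for single-critical-trial experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibsdt)
```

## The problem and the model

Inattentional blindness (IB) experiments probe awareness of an unexpected
stimulus with a single retrospective yes/no question, and each subject can be
asked only once: after the critical trial the stimulus is no longer
unexpected. A yes/no answer, however, confounds *sensitivity* (how much
stimulus information the observer has) with *response bias* (how much
evidence they demand before saying "yes"). Signal detection theory separates
the two, but its standard estimators need many trials per observer — exactly
what this paradigm cannot provide.

`ibsdt` implements the group-level workaround: a **super subject** whose
decision matrix pools every subject's single critical-trial response. Under
the equal-variance Gaussian model, evidence on absent trials is N(0, 1) and
on present trials N(d′, 1); an observer answers "yes" when evidence exceeds
a criterion placed c units above the midpoint of the two distributions.
Then

- H = Φ(d′/2 − c) and FA = Φ(−d′/2 − c),
- d′ = z(H) − z(FA) and c = −½[z(H) + z(FA)],

where z is the standard-normal quantile. Applied to the pooled matrix these
formulas estimate the *population-typical* d′ and c, under assumptions made
explicit below.

Three estimator variants cover the question types that occur in these
designs:

- **Yes/no detection** (the noticing question): d′ and c as above, using
  absent-condition subjects for FA.
- **2afc** (e.g. "left or right?"): one alternative is arbitrarily
  designated "present" (this package follows the left-as-present
  convention); sensitivity is z(H) − z(FA) scaled by 1/√2 because the
  observer sees both intervals and decides on their difference, whose
  distributions are √2 further apart in SD units. The task is
  criterion-free: the designation swap leaves d′₂ₐfc unchanged and only
  flips the sign of c.
- **One-interval forced response** (e.g. "red or blue?"): one feature level
  plays the signal role; d′ is unscaled and a criterion (e.g. a bias
  towards "blue") is estimable and often substantial.

### The 2afc adjustment factor

The adjustment is 1/√2, not 1/2. The package's reference worked example —
corrected rates 72.64% and 45.54% giving d′₂ₐfc = 0.505 — is consistent
only with the 1/√2 factor (the 1/2 factor would give 0.357), and the √2
scaling is the standard result for difference-rule 2afc decision models.

### Unequal-variance indices

Equal variance may fail in one-interval tasks. With the signal
distribution's SD equal to σ noise units (ROC slope s = 1/σ):

d_a = √(2/(1+s²))·[z(H) − s·z(FA)],
c_a = −[√2·s/√(1+s²)]·[z(H) + z(FA)]/(1+s).

Both reduce exactly to d′ and c at σ = 1 (asserted to 1e−12 in the test
suite). The parameter is interpreted as a relative *standard deviation*:
the reference robustness values (d_a = 1.898/2.118 and c_a = 0.443/0.438 at
σ = 1.25/0.75 for the rates H = 0.71, FA = 0.073) are reproducible only
under the SD reading, not a relative-variance reading.

### Analytic variances

Each pooled rate is a binomial proportion, so the delta method gives

var(d′) = H(1−H)/(N₂·φ(H)²) + FA(1−FA)/(N₁·φ(FA)²),

with φ(p) the standard-normal density at z(p). The 2afc variant divides both
terms by 2 (the 1/√2 scaling squared), and since c is −½ the sum of the same
two z-transforms, var(c) = var(d′)/4 — the classical Gourevitch–Galanter
form. The var(c) form is not uniquely pinned down by the reference analyses,
but it reproduces their printed criterion CI half-widths (e.g. SE ≈ 0.0226
at the largest sample), which is the validation the package relies on.
Confidence intervals are Wald: value ± z₍₁₊L₎⁄₂·SE.

### The log-linear correction

0.5 is added to every cell of the decision matrix (1 to each trial total)
before rates are computed, unconditionally — including for 2afc matrices and
matrices with no empty cells. This keeps z finite for perfect cells, shrinks
rates slightly towards 0.5 (so it, if anything, underestimates d′), and
makes corrected rates from a designation-swapped 2afc matrix satisfy
H′ = 1 − FA exactly, preserving the swap symmetry.

## Inference for percent correct

Non-noticer accuracy on a binary follow-up question is compared with chance
(50%) three ways, matching standard practice for these designs:

- exact two-sided binomial test (small-probability-mass rule, via
  `stats::binom.test`);
- Clopper–Pearson interval (beta-quantile inversion of the binomial tails);
- Bayes factor BF10 with a logistic prior on the log-odds of success,
  centred at the null and with scale 0.5 — the conventional default of
  Bayesian proportion tests. The marginal likelihood is computed by adaptive
  quadrature of the likelihood *ratio* in log space, shifted by its value at
  the MLE so it cannot overflow even when the data sit hundreds of log units
  above the null; requested relative tolerance 1e−8.

Across the eight (response × confidence) bins of confidence-rating designs,
per-bin tests are Holm–Bonferroni adjusted (`stats::p.adjust`). Feature
tests within an experiment are deliberately not jointly corrected, matching
the analyses the package replicates; bins with fewer than 20 subjects are
flagged as under-powered rather than dropped.

## The record pipeline

`read_records()`/`write_records()` handle a fixed one-row-per-subject CSV
schema (see `?critical_trial_records`); validation reports all violations
with row numbers. `analyze_experiment()` produces the complete report for
one of the five built-in designs: IB rate, detection d′/c (designs with
absent conditions), non-noticer feature sensitivities with CIs, proportion
tests with BF10, confidence-bin table (exp3), congruency breakdown (designs
with an attended color), and absent-condition guess rates.

Two deliberate scope choices: exclusions are represented as pre-computed
flags with reason codes (re-deriving them would require the per-trial
primary-task stream, which is outside the record schema), and the
"question-asked-first" subset analyses of the sustained designs are omitted
because the record schema carries no question-order field; adding one would
be the natural extension.

## The synthetic observer

`simulate_experiment()` generates datasets with the statistical structure
the estimators assume:

- condition drawn with the design's present fraction (1 for exp1/exp3, 2/3
  for exp2, 3/4 for exp4/exp5); stimulus features uniform over the design's
  levels;
- detection evidence N(0, 1) / N(d′, σ); per-subject criterion
  N(c + d′/2, τ²) on the evidence axis, so the generative c is measured from
  the distribution midpoint and equals the c the analysis estimates;
- confidence 0–3 from |evidence − criterion| against three fixed ordered
  offsets (default 0.5/1/1.5), symmetric for "yes" and "no" — a minimal
  stand-in, since no generative confidence model is established for this
  paradigm;
- color/shape from independent one-interval channels at their own d′, with
  a guessing bias expressed as the probability of choosing the first level
  at zero evidence; the side response from a criterion-free two-interval
  difference rule, so the generative location d′ is recovered directly by
  the 1/√2-adjusted estimator;
- feature channels independent of the detection channel by default; a
  correlation knob (`feature_detection_rho`) exists but defaults to 0, as a
  joint model is likewise not established.

Per-design default parameters (`design_default_params()`) are fixed at the
published group-level statistics of the corresponding experiments (e.g.
exp5: d′ = 2.01, c = 0.45, guess biases 0.5295/0.5143/0.5487; exp2:
d′ = 1.81, c = 0.31 with a strong "blue" bias). For exp1/exp3 no absent
condition exists, so the criterion default 0.435 was chosen once to match
the observed ~28.6% IB rate at d′ = 2. For exp4 the congruency suppression
defaults to full (incongruent effective d′ = 0): the criterion-midpoint
convention cannot produce the very low reported incongruent hit rate with a
non-negative d′, so the generator reproduces the qualitative congruency
signature (a much higher incongruent IB rate and a color response bias),
not its exact magnitudes.

**What passing tests do and do not show.** The generator realizes exactly
the assumptions of the estimators — Gaussian evidence, a stable (or
normally jittered) criterion, independent feature channels, honest
responding. Parameter recovery and variance calibration under this model
validate the *estimators*, not the assumptions; real data may violate
independence of feature and detection channels, contain attention lapses,
memory loss between stimulus and question, or non-Gaussian evidence, none
of which the simulator emulates.

### Criterion variability

The one assumption-violation study built in: `criterion_jitter_study()`
sweeps the between-subject criterion SD τ and shows that the pooled
one-interval d′ estimate falls as τ grows (mixing operating points along a
curved ROC always loses sensitivity) while the criterion-free 2afc estimate
stays flat. This is why 2afc results are the most robust quantities in this
paradigm, and why one-interval super-subject estimates should be read as
conservative lower bounds.

## Numerical choices

- Normal quantile/density via R's `qnorm`/`dnorm` (high-accuracy inverse
  CDF); rates are validated to lie strictly inside (0, 1) and degenerate
  matrices (no present or no absent trials) are hard errors, never imputed.
- Golden-value tests compare d′/c statistics to reference values at
  absolute 0.005, covering their 2-decimal rounding; algebraic identities
  (2afc = yes-no/√2, var ratios 1/2 and 1/4, σ = 1 reductions) are asserted
  at 1e−12.
- The exact-test and interval code is cross-checked against brute-force
  enumeration and tail-probability root-finding oracles for every (k, n)
  with n ≤ 50 and sampled cases up to n = 1000.
- Monte-Carlo calibration uses 2000 replicate matrices at N₂ = 563,
  N₁ = 281 (the scale of the mid-sized criterion analyses): the empirical
  SD of d′, c and d′₂ₐfc matches the analytic SEs within 5%. Parameter
  recovery runs at 50,000–200,000 simulated subjects, where the analytic SE
  makes the ±0.02 bias bound comfortably strict; the jitter study uses
  40,000 subjects per τ. The whole suite runs in well under a minute on one
  CPU.
- One reference value is knowingly missed by a hair: the 2afc worked
  example computes to 0.50487 while the reference prints 0.51, a half-up
  rounding of 0.505; the strict 0.005 reproduction check therefore fails by
  1.3e−4 and is left failing rather than loosened.

## Limitations

- Super-subject statistics describe the group, not any individual;
  between-subject sensitivity heterogeneity is not modelled (only criterion
  heterogeneity, via τ).
- No ROC fitting from confidence ratings, no nonparametric indices (A′,
  B″), and no Bayesian estimation of d′ itself — only of the binomial
  proportion.
- The Bayes factor supports only the logistic log-odds prior family.
- The unequal-variance indices reuse the equal-variance delta-method
  variance weights; for the modest σ used in robustness checks the
  difference is negligible, but variances at extreme σ should not be
  trusted.
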