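#' Pooled decision matrix for a yes/no (or designated-signal) task
#'
#' A decision matrix collects, over a group of subjects who each contribute a
#' single critical trial, the counts of hits ("yes" on a present trial),
#' misses, false alarms ("yes" on an absent trial) and correct rejections.
#' The pooled matrix is the raw material for the super-subject estimators:
#' each subject's one response is treated as one trial of a group-level
#' pseudo-observer.
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative integer
#'   counts of the four cells.
#' @return An object of class `decision_matrix`: a list with the four cell
#'   counts plus `n_present` (hits + misses) and `n_absent`
#'   (false alarms + correct rejections).
#' @examples
#' decision_matrix(hits = 71, misses = 29, false_alarms = 7,
#'                 correct_rejections = 93)
#' @export
decision_matrix <- function(hits, misses, false_alarms, correct_rejections) {
  cells <- c(hits = hits, misses = misses, false_alarms = false_alarms,
             correct_rejections = correct_rejections)
  if (length(cells) != 4L || anyNA(cells)) {
    stop("all four cell counts must be single non-missing numbers")
  }
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("decision matrix cells must be non-negative integers")
  }
  out <- list(
    hits = as.integer(hits),
    misses = as.integer(misses),
    false_alarms = as.integer(false_alarms),
    correct_rejections = as.integer(correct_rejections),
    n_present = as.integer(hits + misses),
    n_absent = as.integer(false_alarms + correct_rejections)
  )
  class(out) <- "decision_matrix"
  out
}

#' @export
print.decision_matrix <- function(x, ...) {
  m <- matrix(c(x$hits, x$false_alarms, x$misses, x$correct_rejections),
              nrow = 2, byrow = TRUE,
              dimnames = list(response = c("yes", "no"),
                              stimulus = c("present", "absent")))
  cat("Pooled decision matrix (N present =", x$n_present,
      ", N absent =", x$n_absent, ")\n")
  print(m)
  invisible(x)
}

#' Log-linear corrected hit and false-alarm rates
#'
#' Applies the log-linear correction — add 0.5 to every cell of the decision
#' matrix (equivalently 1 to each trial total) — before computing the hit and
#' false-alarm rates. The correction keeps both rates strictly inside (0, 1)
#' so the normal quantile transform is always finite, at the cost of shrinking
#' extreme rates slightly towards 0.5. It is applied unconditionally to every
#' matrix, including 2afc matrices.
#'
#' @param matrix A [decision_matrix()].
#' @return A `rate_pair`: corrected rates `H = (hits + 0.5) / (n_present + 1)`
#'   and `FA = (false_alarms + 0.5) / (n_absent + 1)`.
#' @examples
#' m <- decision_matrix(71, 29, 7, 93)
#' log_linear_correct(m)
#' @export
log_linear_correct <- function(matrix) {
  stopifnot(inherits(matrix, "decision_matrix"))
  if (matrix$n_present < 1L) {
    stop("cannot compute rates: the matrix has no present trials")
  }
  if (matrix$n_absent < 1L) {
    stop("cannot compute rates: the matrix has no absent trials")
  }
  rate_pair(H = (matrix$hits + 0.5) / (matrix$n_present + 1),
            FA = (matrix$false_alarms + 0.5) / (matrix$n_absent + 1),
            corrected = TRUE)
}

#' Construct a hit/false-alarm rate pair
#'
#' Rates may also be supplied directly (e.g. published corrected rates) rather
#' than derived from a matrix via [log_linear_correct()].
#'
#' @param H,FA Hit and false-alarm rates, both strictly inside (0, 1).
#' @param corrected Logical; whether the log-linear correction produced these
#'   rates.
#' @return An object of class `rate_pair`.
#' @export
rate_pair <- function(H, FA, corrected = FALSE) {
  if (!is.numeric(H) || !is.numeric(FA) || length(H) != 1L || length(FA) != 1L ||
      is.na(H) || is.na(FA)) {
    stop("H and FA must be single numeric values")
  }
  if (H <= 0 || H >= 1 || FA <= 0 || FA >= 1) {
    stop("rates must lie strictly inside (0, 1); apply the log-linear ",
         "correction to a decision matrix with extreme counts")
  }
  structure(list(H = H, FA = FA, corrected = isTRUE(corrected)),
            class = "rate_pair")
}

#' @export
print.rate_pair <- function(x, ...) {
  cat(sprintf("H = %.4f, FA = %.4f%s\n", x$H, x$FA,
              if (x$corrected) " (log-linear corrected)" else ""))
  invisible(x)
}
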