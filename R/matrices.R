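#' Detection (noticing) decision matrix
#'
#' Pools each subject's single yes/no noticing response into the
#' super-subject decision matrix: hits are "yes" on present trials, misses
#' "no" on present trials (inattentional blindness), false alarms "yes" on
#' absent trials, correct rejections "no" on absent trials.
#'
#' @param records Validated records of one experiment; excluded rows are
#'   dropped.
#' @return A [decision_matrix()].
#' @export
detection_matrix <- function(records) {
  r <- included_records(records)
  present <- r$condition == "present"
  if (!any(present)) stop("no present-condition records")
  if (!any(!present)) {
    stop("no absent-condition records: the false-alarm rate, and hence d' ",
         "and c for the noticing question, require absent trials")
  }
  yes <- r$noticed == "yes"
  decision_matrix(hits = sum(present & yes),
                  misses = sum(present & !yes),
                  false_alarms = sum(!present & yes),
                  correct_rejections = sum(!present & !yes))
}

#' 2afc decision matrix for the location question
#'
#' A 2afc question has no absent condition of its own; instead one
#' alternative is (arbitrarily) designated "present". With left designated
#' present, hits are left-stimulus trials answered "left" and false alarms
#' right-stimulus trials answered "left". d'_2afc is invariant to the
#' designation up to sign; c flips sign.
#'
#' @param records Records (typically the non-noticer subset) from present
#'   trials with side responses.
#' @param present_side Which alternative counts as "present" (`"left"` by
#'   default).
#' @return A [decision_matrix()].
#' @export
twoafc_matrix <- function(records, present_side = c("left", "right")) {
  present_side <- match.arg(present_side)
  other <- setdiff(c("left", "right"), present_side)
  r <- included_records(records)
  r <- r[r$condition == "present", , drop = FALSE]
  if (nrow(r) == 0L || any(r$stim_side == "") || any(r$side_response == "")) {
    stop("2afc matrix requires present-condition records with stim_side ",
         "and side_response filled in")
  }
  sig <- r$stim_side == present_side
  resp <- r$side_response == present_side
  decision_matrix(hits = sum(sig & resp),
                  misses = sum(sig & !resp),
                  false_alarms = sum(!sig & resp),
                  correct_rejections = sum(!sig & !resp))
}

#' One-interval decision matrix for a binary feature question
#'
#' For a one-interval forced-response question (color or shape), trials
#' whose stimulus carries `signal_level` are treated as "present" and a
#' response of `signal_level` as "yes". d' is invariant to which of the two
#' levels is called the signal; c flips sign.
#'
#' @param records Present-condition records with the feature response.
#' @param feature `"color"` or `"shape"`.
#' @param signal_level Which feature level plays the signal role; defaults to
#'   the first level in sorted order.
#' @return A [decision_matrix()].
#' @export
one_interval_matrix <- function(records, feature = c("color", "shape"),
                                signal_level = NULL) {
  feature <- match.arg(feature)
  stim_col <- paste0("stim_", feature)
  resp_col <- paste0(feature, "_response")
  r <- included_records(records)
  r <- r[r$condition == "present", , drop = FALSE]
  if (nrow(r) == 0L || any(r[[stim_col]] == "") || any(r[[resp_col]] == "")) {
    stop("one-interval matrix requires present-condition records with ",
         stim_col, " and ", resp_col, " filled in")
  }
  levels <- sort(unique(c(r[[stim_col]], r[[resp_col]])))
  if (length(levels) > 2L) {
    stop("one-interval analysis handles binary designs only; found levels: ",
         paste(levels, collapse = ", "))
  }
  if (is.null(signal_level)) signal_level <- levels[1]
  if (!signal_level %in% levels) {
    stop("signal_level '", signal_level, "' not among observed levels")
  }
  sig <- r[[stim_col]] == signal_level
  resp <- r[[resp_col]] == signal_level
  decision_matrix(hits = sum(sig & resp),
                  misses = sum(sig & !resp),
                  false_alarms = sum(!sig & resp),
                  correct_rejections = sum(!sig & !resp))
}

#' Notice rates by attended-color congruency
#'
#' For sustained designs where subjects attend to squares of one color,
#' splits the present-condition noticing rate by whether the unexpected
#' stimulus matched (congruent) or mismatched (incongruent) the attended
#' color, and tabulates the color responses by attended color (the
#' response-bias side of the congruency effect).
#'
#' @param records Records with `attended_color` filled in on present trials.
#' @return A list with `notice_rates` (data frame: congruency, n, noticed,
#'   notice_rate, ib_rate) and `response_bias` (proportion choosing each
#'   color, by attended color, among present-condition subjects).
#' @export
congruency_breakdown <- function(records) {
  r <- included_records(records)
  r <- r[r$condition == "present", , drop = FALSE]
  if (nrow(r) == 0L) stop("no present-condition records")
  if (any(r$attended_color == "")) {
    stop("congruency breakdown requires attended_color on present records")
  }
  congruent <- r$stim_color == r$attended_color
  grp <- ifelse(congruent, "congruent", "incongruent")
  tab <- lapply(split(seq_len(nrow(r)), grp), function(idx) {
    n <- length(idx)
    yes <- sum(r$noticed[idx] == "yes")
    data.frame(congruency = grp[idx[1]], n = n, noticed = yes,
               notice_rate = yes / n, ib_rate = 1 - yes / n)
  })
  notice_rates <- do.call(rbind, tab)
  rownames(notice_rates) <- NULL
  bias <- NULL
  if (all(r$color_response != "")) {
    bias <- as.data.frame(prop.table(
      table(attended = r$attended_color, response = r$color_response),
      margin = 1), responseName = "proportion")
  }
  list(notice_rates = notice_rates, response_bias = bias)
}

#' Absent-condition guess rates per feature
#'
#' Among subjects shown nothing, the proportion choosing each response
#' option of each asked feature question: the empirical guessing bias.
#'
#' @param records Validated records with an absent condition.
#' @param questions Feature questions to tabulate.
#' @return A data frame with columns `feature`, `response`, `n`,
#'   `proportion`.
#' @export
absent_guess_rates <- function(records,
                               questions = c("color", "shape", "side")) {
  r <- included_records(records)
  r <- r[r$condition == "absent", , drop = FALSE]
  if (nrow(r) == 0L) stop("no absent-condition records")
  out <- list()
  for (q in questions) {
    resp <- r[[paste0(q, "_response")]]
    resp <- resp[resp != ""]
    if (length(resp) == 0L) next
    tab <- table(resp)
    out[[q]] <- data.frame(feature = q, response = names(tab),
                           n = as.integer(tab),
                           proportion = as.numeric(tab) / length(resp))
  }
  if (length(out) == 0L) stop("no feature responses among absent records")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
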