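#' Experiment design descriptors
#'
#' Returns the descriptor of one of the five single-critical-trial designs:
#'
#' * `exp1` — brief (200 ms) stimulus, every subject shown one (no absent
#'   condition); a red line on the left or right; 2afc location question.
#' * `exp2` — as `exp1` but 2/3 of subjects in the present condition (1/3
#'   absent); line red or blue; one-interval color question.
#' * `exp3` — as `exp1` plus a 0-3 confidence rating after the yes/no
#'   noticing question.
#' * `exp4` — sustained (5 s) moving stimulus during a bounce-counting task;
#'   3/4 present; black/white circle/triangle on the left/right; attended
#'   color black or white; color, shape and location questions.
#' * `exp5` — as `exp4` with orange/green stimuli and every subject
#'   attending white.
#'
#' @param name One of `"exp1"` ... `"exp5"`.
#' @return An object of class `experiment_design`: a list with the design
#'   `name`, `present_fraction`, feature levels (`colors`, `shapes`,
#'   `sides`), `attended_colors` (or `NULL`), the `questions` asked
#'   (subset of `"color"`, `"shape"`, `"side"`) and `has_confidence`.
#' @examples
#' experiment_design("exp5")
#' @export
experiment_design <- function(name = c("exp1", "exp2", "exp3", "exp4", "exp5")) {
  name <- match.arg(name)
  d <- switch(name,
    exp1 = list(present_fraction = 1, colors = "red", shapes = NULL,
                sides = c("left", "right"), attended_colors = NULL,
                questions = "side", has_confidence = FALSE),
    exp2 = list(present_fraction = 2 / 3, colors = c("red", "blue"),
                shapes = NULL, sides = c("left", "right"),
                attended_colors = NULL, questions = "color",
                has_confidence = FALSE),
    exp3 = list(present_fraction = 1, colors = "red", shapes = NULL,
                sides = c("left", "right"), attended_colors = NULL,
                questions = "side", has_confidence = TRUE),
    exp4 = list(present_fraction = 3 / 4, colors = c("black", "white"),
                shapes = c("triangle", "circle"), sides = c("left", "right"),
                attended_colors = c("black", "white"),
                questions = c("color", "shape", "side"),
                has_confidence = FALSE),
    exp5 = list(present_fraction = 3 / 4, colors = c("orange", "green"),
                shapes = c("triangle", "circle"), sides = c("left", "right"),
                attended_colors = "white",
                questions = c("color", "shape", "side"),
                has_confidence = FALSE))
  d$name <- name
  d$has_absent <- d$present_fraction < 1
  class(d) <- "experiment_design"
  d
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("design %s: present fraction %.3g; questions: %s%s\n",
              x$name, x$present_fraction,
              paste(x$questions, collapse = ", "),
              if (x$has_confidence) "; confidence rating" else ""))
  invisible(x)
}
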