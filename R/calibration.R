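# First-order count correction.
#
# Manual annotation misses grains that are severely hidden by neighbors, so
# the ground truth the network learns from undercounts the panicle. A
# first-order line fitted between annotated and manually counted totals
# corrects the model's raw output: y = slope * x + intercept.

#' Linear calibration model
#'
#' @param slope,intercept Finite real coefficients of `y = slope * x +
#'   intercept`.
#' @param n_points Number of points the fit used (0 for a fixed model such
#'   as [default_calibration()]).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(slope, intercept, n_points = 0L) {
  if (!is.finite(slope) || !is.finite(intercept))
    pc_value_error("slope and intercept must be finite")
  structure(list(slope = slope, intercept = intercept,
                 n_points = as.integer(n_points)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> y = %.4f x + %.4f%s\n", x$slope,
              x$intercept,
              if (x$n_points > 0) sprintf(" (fit on %d points)", x$n_points)
              else " (fixed)"))
  invisible(x)
}

#' The shipped default correction for real panicle photographs
#'
#' `y = 1.0294 x + 0.6069`, the line relating annotated grain totals to
#' manual counts on the photographic dataset the model was developed with.
#' Apply to raw model counts when counting real spread-panicle photographs;
#' refit with [fit_linear_correction()] for other imagery.
#'
#' @return A [calibration_model].
#' @export
default_calibration <- function() calibration_model(1.0294, 0.6069)

#' Fit the first-order correction by ordinary least squares
#'
#' Minimizes the squared residual of `y ~ a x + b`. The conventional usage
#' fits annotated counts (`x`) against manual counts (`y`) and then applies
#' the line to model outputs; fitting predicted counts directly against
#' manual counts is equally supported — pass those as `x`.
#'
#' @param x Numeric predictor counts (>= 2 values, not all identical).
#' @param y Numeric response counts, same length.
#' @return A [calibration_model] with `n_points` recorded.
#' @export
fit_linear_correction <- function(x, y) {
  if (length(x) != length(y)) pc_value_error("x and y must have equal length")
  if (length(x) < 2) pc_value_error("need at least 2 points to fit")
  if (max(x) - min(x) < .Machine$double.eps * max(1, abs(max(x))))
    pc_stop("x values are all identical; fit is singular",
            "paniclecount_singular_fit")
  fit <- lm(y ~ x)
  calibration_model(unname(coef(fit)[2]), unname(coef(fit)[1]), length(x))
}

#' Apply the linear correction to a raw count
#'
#' @param model A [calibration_model].
#' @param raw_count Raw model output count(s).
#' @param round_output When `TRUE`, round to the nearest integer (half-up)
#'   and floor at 0 — the form reported to the user.
#' @return Corrected count(s).
#' @export
apply_correction <- function(model, raw_count, round_output = FALSE) {
  stopifnot(inherits(model, "calibration_model"))
  y <- model$slope * raw_count + model$intercept
  if (round_output) y <- pmax(0, round_half_up(y, 0))
  y
}
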