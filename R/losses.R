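# Training losses.
#
# The composite loss adds two count-level terms to the Euclidean base:
# a relative (squared ratio) term that removes the scale difference between
# sparse and dense panicles, and an absolute term that softens the influence
# of occluded/overlapping outliers. L = L_euc + alpha * L_rel + beta * L_abs
# with defaults alpha = 0.1, beta = 0.01.

#' Loss configuration
#'
#' @param alpha Non-negative weight of the relative (squared-ratio) term.
#'   Default 0.1.
#' @param beta Non-negative weight of the absolute term. Default 0.01.
#'   (Distinct from the density-kernel bandwidth factor of
#'   [kernel_params()], which reuses the same Greek letter.)
#' @param euclidean_mode `"map"`: the Euclidean term is the pixel-wise
#'   squared difference between predicted and ground-truth density grids
#'   (the density-regression training convention, default); `"count"`: it is
#'   the squared difference of the scalar counts, the literal reading of the
#'   loss formula. The relative and absolute terms always operate on counts
#'   (map masses).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.1, beta = 0.01,
                        euclidean_mode = c("map", "count")) {
  if (alpha < 0 || beta < 0) pc_value_error("alpha and beta must be >= 0")
  structure(list(alpha = alpha, beta = beta,
                 euclidean_mode = match.arg(euclidean_mode)),
            class = "loss_config")
}

#' A batch of count predictions with ground truth
#'
#' @param predicted Numeric vector of predicted counts (map masses), one per
#'   image.
#' @param truth Numeric vector of ground-truth counts, same length.
#' @param predicted_grids,truth_grids Optional lists of matrices (one per
#'   image), required for the map-mode Euclidean term.
#' @return An object of class `batch_counts` of batch size `N >= 1`.
#' @export
batch_counts <- function(predicted, truth,
                         predicted_grids = NULL, truth_grids = NULL) {
  if (length(predicted) != length(truth))
    pc_value_error("predicted and truth must have equal length")
  if (length(predicted) < 1) pc_value_error("batch must be non-empty")
  if (!is.null(predicted_grids) || !is.null(truth_grids)) {
    if (length(predicted_grids) != length(predicted) ||
        length(truth_grids) != length(predicted))
      pc_value_error("grid lists must match the batch size")
  }
  structure(list(predicted = as.numeric(predicted),
                 truth = as.numeric(truth),
                 predicted_grids = predicted_grids,
                 truth_grids = truth_grids),
            class = "batch_counts")
}

#' Euclidean loss
#'
#' Count mode: \eqn{\frac{1}{2N}\sum_i (Z_i - Z_i^{GT})^2}. Map mode: the
#' same with the squared count difference replaced by the summed squared
#' per-pixel difference of the density grids.
#'
#' @param batch A [batch_counts] object (map mode requires its grids).
#' @param mode `"count"` or `"map"`.
#' @return Non-negative scalar; 0 iff predictions equal truth.
#' @export
euclidean_loss <- function(batch, mode = c("map", "count")) {
  stopifnot(inherits(batch, "batch_counts"))
  mode <- match.arg(mode)
  n <- length(batch$predicted)
  if (mode == "count")
    return(sum((batch$predicted - batch$truth)^2) / (2 * n))
  if (is.null(batch$predicted_grids) || is.null(batch$truth_grids))
    pc_value_error("map-mode Euclidean loss needs predicted and truth grids")
  sq <- mapply(function(p, t) {
    if (!all(dim(p) == dim(t)))
      pc_value_error("predicted and truth grids must have equal shape")
    sum((p - t)^2)
  }, batch$predicted_grids, batch$truth_grids)
  sum(sq) / (2 * n)
}

#' Relative (squared-ratio) loss
#'
#' \eqn{\frac{1}{N}\sum_i ((Z_i - Z_i^{GT}) / Z_i^{GT})^2}. Invariant to a
#' joint rescaling of predictions and truth; undefined at zero truth.
#'
#' @param batch A [batch_counts] object with strictly positive truth counts.
#' @return Non-negative scalar.
#' @export
relative_loss <- function(batch) {
  stopifnot(inherits(batch, "batch_counts"))
  if (any(batch$truth <= 0))
    pc_stop("relative loss undefined for zero/negative truth counts",
            "paniclecount_division_guard")
  mean(((batch$predicted - batch$truth) / batch$truth)^2)
}

#' Absolute loss
#'
#' \eqn{\frac{1}{N}\sum_i |Z_i - Z_i^{GT}|}.
#'
#' @param batch A [batch_counts] object.
#' @return Non-negative scalar.
#' @export
absolute_loss <- function(batch) {
  stopifnot(inherits(batch, "batch_counts"))
  mean(abs(batch$predicted - batch$truth))
}

#' Composite loss
#'
#' `L = L_euclidean + alpha * L_relative + beta * L_absolute`. With
#' `alpha = beta = 0` this reduces exactly to the Euclidean baseline, which
#' is how the loss-ablation grid (baseline / +relative / +absolute / +both)
#' is expressed as configurations. Items with zero truth count are excluded
#' from the relative term (where it is undefined) but contribute to the
#' other terms.
#'
#' @param batch A [batch_counts] object.
#' @param config A [loss_config] object.
#' @return A list of class `composite_loss` with elements `total`,
#'   `euclidean`, `relative`, `absolute` (components unweighted, for
#'   logging/ablation).
#' @export
composite_loss <- function(batch, config = loss_config()) {
  stopifnot(inherits(batch, "batch_counts"), inherits(config, "loss_config"))
  e <- euclidean_loss(batch, config$euclidean_mode)
  pos <- batch$truth > 0
  r <- if (config$alpha > 0 || any(pos)) {
    if (any(pos)) {
      sub <- batch_counts(batch$predicted[pos], batch$truth[pos])
      relative_loss(sub)
    } else 0
  } else 0
  a <- absolute_loss(batch)
  structure(list(total = e + config$alpha * r + config$beta * a,
                 euclidean = e, relative = r, absolute = a),
            class = "composite_loss")
}

#' @export
print.composite_loss <- function(x, ...) {
  cat(sprintf("composite loss %.6g (euclidean %.6g, relative %.6g, absolute %.6g)\n",
              x$total, x$euclidean, x$relative, x$absolute))
  invisible(x)
}
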