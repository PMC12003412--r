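# Dataset splitting and count-error metrics.

#' Split specification
#'
#' @param ratios Numeric 3-vector of train/test/validation fractions summing
#'   to 1 (default 0.8/0.1/0.1).
#' @param seed Integer seed making the random partition reproducible.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  ratios <- as.numeric(ratios)
  if (length(ratios) != 3 || any(ratios < 0))
    pc_stop("ratios must be three non-negative numbers",
            "paniclecount_config_error")
  if (abs(sum(ratios) - 1) > 1e-9)
    pc_stop("ratios must sum to 1", "paniclecount_config_error")
  structure(list(ratios = ratios, seed = as.integer(seed)),
            class = "split_spec")
}

# floor allocation with the remainder handed out train-first
split_sizes <- function(n, ratios) {
  sizes <- floor(ratios * n)
  rem <- n - sum(sizes)
  i <- 1
  while (rem > 0) {
    sizes[i] <- sizes[i] + 1
    rem <- rem - 1
    i <- i %% 3 + 1
  }
  sizes
}

#' Randomly partition items into train/test/validation sets
#'
#' Sizes follow floor allocation of the ratios with any remainder assigned
#' train-first; the permutation is seeded, so the same spec always yields
#' the same partition. With a stratification key the ratios are applied
#' within each stratum, keeping per-stratum proportions.
#'
#' @param items Vector or list to split (non-empty).
#' @param spec A [split_spec].
#' @param stratify_by Optional vector of stratum labels, one per item
#'   (e.g. camera model).
#' @return A list with components `train`, `test`, `validation`; disjoint,
#'   union = `items`.
#' @export
split_dataset <- function(items, spec = split_spec(), stratify_by = NULL) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(items)
  if (n < 1) pc_value_error("cannot split an empty dataset")
  set.seed(spec$seed)
  take <- function(idx) {
    idx <- idx[sample(length(idx))]
    sizes <- split_sizes(length(idx), spec$ratios)
    list(train = idx[seq_len(sizes[1])],
         test = idx[seq_len(sizes[2]) + sizes[1]],
         validation = idx[seq_len(sizes[3]) + sizes[1] + sizes[2]])
  }
  if (is.null(stratify_by)) {
    parts <- take(seq_len(n))
  } else {
    if (length(stratify_by) != n)
      pc_value_error("stratify_by must have one label per item")
    parts <- list(train = integer(0), test = integer(0),
                  validation = integer(0))
    for (g in unique(stratify_by)) {
      sub <- take(which(stratify_by == g))
      parts <- Map(c, parts, sub)
    }
  }
  lapply(parts, function(idx) items[idx])
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Relative counting error
#'
#' `|predicted - truth| / truth`, as a fraction. Use
#' `100 * relative_error(...)` (rounded half-up to 2 decimals) for the
#' tabular percent style.
#'
#' @param truth Positive true count(s).
#' @param predicted Predicted count(s).
#' @return Non-negative fraction(s).
#' @export
relative_error <- function(truth, predicted) {
  if (any(truth <= 0)) pc_value_error("truth counts must be > 0")
  abs(predicted - truth) / truth
}

#' Count-error metrics for a set of predictions
#'
#' \deqn{MAE = \frac{1}{N}\sum |C_i - C_i^{GT}|, \quad
#'       MSE = \frac{1}{N}\sum (C_i - C_i^{GT})^2,}
#' \deqn{RMSE = \sqrt{MSE}, \quad
#'       MAPE = \frac{1}{N}\sum |C_i - C_i^{GT}| / C_i^{GT}.}
#' Smaller is better for all four.
#'
#' @param predicted Numeric vector of predicted counts.
#' @param truth Numeric vector of positive true counts, same length.
#' @param image_ids Optional identifiers for the per-image table.
#' @return An object of class `evaluation_report` with fields `mae`, `mse`,
#'   `rmse`, `mape` and `per_image` (data frame with columns `image_id`,
#'   `truth`, `predicted`, `relative_error` as a fraction, and
#'   `relative_error_pct` rounded half-up to 2 decimals).
#' @export
compute_metrics <- function(predicted, truth, image_ids = NULL) {
  n <- length(predicted)
  if (n < 1 || length(truth) != n)
    pc_value_error("predicted and truth must be non-empty and equal length")
  if (any(truth <= 0))
    pc_stop("MAPE requires strictly positive truth counts",
            "paniclecount_division_guard")
  if (is.null(image_ids)) image_ids <- as.character(seq_len(n))
  err <- predicted - truth
  rel <- relative_error(truth, predicted)
  structure(list(
    mae = mean(abs(err)),
    mse = mean(err^2),
    rmse = sqrt(mean(err^2)),
    mape = mean(rel),
    per_image = data.frame(
      image_id = image_ids, truth = truth, predicted = predicted,
      relative_error = rel,
      relative_error_pct = round_half_up(100 * rel, 2))
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> n=%d  MAE %.4f  MSE %.4f  RMSE %.4f  MAPE %.4f (%.2f%%)\n",
    nrow(x$per_image), x$mae, x$mse, x$rmse, x$mape,
    round_half_up(100 * x$mape, 2)))
  invisible(x)
}

#' Export an evaluation report as CSV
#'
#' One row per image (id, truth, predicted, relative error in percent) plus
#' a trailing summary row carrying the four aggregate metrics.
#'
#' @param report An [compute_metrics()] report.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  df <- report$per_image[, c("image_id", "truth", "predicted",
                             "relative_error_pct")]
  summary <- data.frame(
    image_id = "summary",
    truth = NA_real_, predicted = NA_real_,
    relative_error_pct = round_half_up(100 * report$mape, 2))
  out <- rbind(df, summary)
  out$mae <- c(rep(NA_real_, nrow(df)), report$mae)
  out$mse <- c(rep(NA_real_, nrow(df)), report$mse)
  out$rmse <- c(rep(NA_real_, nrow(df)), report$rmse)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
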