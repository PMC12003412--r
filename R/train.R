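# Gradient training of the density-regression network.
#
# Optimization is Adam on single-image batches (the density-regression
# convention). The gradient of the composite loss wrt the raw output map P
# with target map T and truth count Z, writing S = sum(P):
#   map-mode Euclidean  : d/dP [ 1/2 ||P - T||^2 ]           = P - T
#   count-mode Euclidean: d/dP [ 1/2 (S - Z)^2 ]             = (S - Z)
#   relative            : d/dP [ ((S - Z)/Z)^2 ]             = 2 (S - Z)/Z^2
#   absolute            : d/dP [ |S - Z| ]                   = sign(S - Z)
# the count-term gradients being constant over pixels.

adam_init <- function(model) {
  lapply(model$layers, function(l) {
    if (l$type == "conv")
      list(mW = matrix(0, nrow(l$W), ncol(l$W)), vW = matrix(0, nrow(l$W), ncol(l$W)),
           mb = numeric(length(l$b)), vb = numeric(length(l$b)))
    else NULL
  })
}

adam_step <- function(model, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (li in seq_along(model$layers)) {
    if (model$layers[[li]]$type != "conv") next
    g <- grads[[li]]
    s <- state[[li]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    model$layers[[li]]$W <- model$layers[[li]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    model$layers[[li]]$b <- model$layers[[li]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[li]] <- s
  }
  list(model = model, state = state)
}

#' Assemble a training item from an image and its annotations
#'
#' Normalizes the image, renders the ground-truth density map and pools it
#' to the network's output stride (mass preserved, so the target's sum is
#' the grain count).
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param ann The matching [point_annotations].
#' @param stats [normalization_stats] for standardization.
#' @param output_stride The network's output stride.
#' @param params [kernel_params] for density rendering.
#' @return A list with `image` (standardized), `target` (matrix at output
#'   stride), `truth` (count N) and `image_id`.
#' @export
make_training_item <- function(image, ann, stats, output_stride,
                               params = kernel_params()) {
  dm <- downsample_density(render_density_map(ann, params), output_stride)
  list(image = normalize_image(image, stats),
       target = dm$grid,
       truth = n_points(ann),
       image_id = ann$image_id)
}

#' Train a density-regression network
#'
#' Seeded Adam training on single-image batches with the composite loss.
#' Per-epoch means of the total loss and each unweighted component are
#' logged; when `test_items` is given, test MAE is logged per epoch and the
#' best-on-test parameters are retained and returned.
#'
#' @param model A `panicle_network` from [build_network()].
#' @param items List of training items from [make_training_item()].
#' @param config A [loss_config].
#' @param epochs Number of passes over the data (>= 1).
#' @param lr Adam learning rate. The full variant's conventional default is
#'   1e-5; tiny randomly initialized models train well at 1e-3.
#' @param seed RNG seed controlling the per-epoch shuffle.
#' @param test_items Optional held-out items for per-epoch MAE tracking.
#' @param log_file Optional CSV path; the epoch log is written there.
#' @param verbose Print one line per epoch.
#' @return A list of class `training_run`: `model` (final), `best_model`
#'   (best on test, or final when no test set), `log` (data frame).
#' @export
train_network <- function(model, items, config = loss_config(),
                          epochs = 10L, lr = 1e-3, seed = 1L,
                          test_items = NULL, log_file = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(model, "panicle_network"), inherits(config, "loss_config"))
  if (length(items) < 1) pc_value_error("no training items")
  epochs <- as.integer(epochs)
  if (epochs < 1) pc_value_error("epochs must be >= 1")
  set.seed(seed)
  state <- adam_init(model)
  t <- 0
  log <- vector("list", epochs)
  best_mae <- Inf
  best_model <- model
  for (epoch in seq_len(epochs)) {
    order <- sample(length(items))
    comp_sums <- c(total = 0, euclidean = 0, relative = 0, absolute = 0)
    for (ix in order) {
      item <- items[[ix]]
      fwd <- nn_forward(model, item$image, want_cache = TRUE)
      P <- matrix(fwd$out, dim(fwd$out)[1], dim(fwd$out)[2])
      Z <- item$truth
      S <- sum(P)
      batch <- batch_counts(S, Z,
                            predicted_grids = list(P),
                            truth_grids = list(item$target))
      cl <- composite_loss(batch, config)
      comp_sums <- comp_sums + c(cl$total, cl$euclidean, cl$relative, cl$absolute)
      dP <- if (config$euclidean_mode == "map") P - item$target
            else matrix(S - Z, nrow(P), ncol(P))
      if (Z > 0) dP <- dP + config$alpha * 2 * (S - Z) / Z^2
      dP <- dP + config$beta * sign(S - Z)
      grads <- nn_backward(model, fwd$caches, array(dP, c(dim(P), 1)))
      t <- t + 1
      upd <- adam_step(model, grads, state, t, lr)
      model <- upd$model
      state <- upd$state
    }
    comp <- comp_sums / length(items)
    test_mae <- NA_real_
    if (!is.null(test_items)) {
      preds <- vapply(test_items, function(it)
        sum(pmax(nn_forward(model, it$image)$out, 0)), numeric(1))
      truths <- vapply(test_items, `[[`, numeric(1), "truth")
      test_mae <- mean(abs(preds - truths))
      if (test_mae < best_mae) {
        best_mae <- test_mae
        best_model <- model
      }
    }
    log[[epoch]] <- data.frame(epoch = epoch, total = comp["total"],
                               euclidean = comp["euclidean"],
                               relative = comp["relative"],
                               absolute = comp["absolute"],
                               test_mae = test_mae, row.names = NULL)
    if (verbose)
      message(sprintf("epoch %3d  loss %.6g  test MAE %s", epoch,
                      comp["total"],
                      if (is.na(test_mae)) "-" else sprintf("%.3f", test_mae)))
  }
  log <- do.call(rbind, log)
  if (!is.null(log_file)) write.csv(log, log_file, row.names = FALSE)
  if (is.null(test_items)) best_model <- model
  structure(list(model = model, best_model = best_model, log = log),
            class = "training_run")
}

#' Predicted counts for a list of items
#'
#' Convenience wrapper: runs [predict_density()] over prepared items and
#' returns the raw (clamped-mass) counts.
#'
#' @param model A `panicle_network`.
#' @param items List of items from [make_training_item()].
#' @return Numeric vector of raw predicted counts.
#' @export
predict_counts <- function(model, items) {
  vapply(items, function(it)
    predict_density(model, it$image, it$image_id)$raw_count, numeric(1))
}
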