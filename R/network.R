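# Density-regression network: a convolutional encoder that maps a normalized
# RGB image to a single-channel density map at a reduced resolution
# (output_stride), whose integral is the grain count.
#
# The full variant follows the crowd-counting lineage: the first 10
# convolutional layers of VGG-16 (three 2x2 max-pools, 1/8 resolution) as
# the feature front end, then six 3x3 convolutions with dilation 2
# (channels 512-512-512-256-128-64) and a 1x1 head. The tiny variant is the
# same shape of computation at toy scale (< 100k parameters) so that
# training and evaluation are feasible on one CPU core in tests; it is
# selected explicitly via the config, never silently substituted.
#
# No deep-learning framework is available in the deployment image, so
# forward, backward and the optimizer are implemented here directly on top
# of im2col/col2im kernels (src/conv_ops.cpp) and BLAS matrix products.

#' Network configuration
#'
#' @param variant `"full"` (VGG-16 front end + dilated back end) or `"tiny"`
#'   (3 small conv blocks + 2 dilated convs + 1x1 head, < 100k parameters,
#'   for CPU-scale training).
#' @param pretrained_frontend Logical; ImageNet-initialized front end. Only
#'   meaningful for the full variant and requires a weights download, which
#'   this offline build does not perform: `TRUE` raises an error.
#' @param output_stride Downsampling factor of the density output relative
#'   to the input. Fixed at 8 for the full variant; one of 1, 2, 4 for the
#'   tiny variant (default 4).
#' @return An object of class `network_config`.
#' @export
network_config <- function(variant = c("tiny", "full"),
                           pretrained_frontend = FALSE,
                           output_stride = NULL) {
  variant <- match.arg(variant)
  if (variant == "full") {
    if (!is.null(output_stride) && output_stride != 8)
      pc_stop("full variant has output_stride 8", "paniclecount_config_error")
    output_stride <- 8L
  } else {
    if (is.null(output_stride)) output_stride <- 4L
    output_stride <- as.integer(output_stride)
    if (!output_stride %in% c(1L, 2L, 4L))
      pc_stop("tiny variant output_stride must be 1, 2 or 4",
              "paniclecount_config_error")
  }
  if (isTRUE(pretrained_frontend))
    pc_stop("pretrained front-end weights are not bundled (offline build)",
            "paniclecount_config_error")
  structure(list(variant = variant, pretrained_frontend = FALSE,
                 output_stride = output_stride),
            class = "network_config")
}

# --- layer constructors -------------------------------------------------------

nn_conv <- function(cin, cout, k = 3L, dilation = 1L, init_sd = NULL) {
  pad <- as.integer(dilation * (k - 1) / 2)  # "same" padding, stride 1
  fan_in <- k * k * cin
  if (is.null(init_sd)) init_sd <- sqrt(2 / fan_in)  # He initialization
  list(type = "conv", kh = k, kw = k, cin = cin, cout = cout,
       pad = pad, dil = as.integer(dilation),
       W = matrix(rnorm(fan_in * cout, sd = init_sd), fan_in, cout),
       b = numeric(cout))
}

nn_relu <- function() list(type = "relu")
nn_pool <- function() list(type = "pool")

# --- architecture plans -------------------------------------------------------

build_layers_full <- function() {
  front <- list(
    nn_conv(3, 64), nn_relu(), nn_conv(64, 64), nn_relu(), nn_pool(),
    nn_conv(64, 128), nn_relu(), nn_conv(128, 128), nn_relu(), nn_pool(),
    nn_conv(128, 256), nn_relu(), nn_conv(256, 256), nn_relu(),
    nn_conv(256, 256), nn_relu(), nn_pool(),
    nn_conv(256, 512), nn_relu(), nn_conv(512, 512), nn_relu(),
    nn_conv(512, 512), nn_relu()
  )
  back_channels <- c(512, 512, 512, 256, 128, 64)
  back <- list()
  cin <- 512
  for (cout in back_channels) {
    back <- c(back, list(nn_conv(cin, cout, dilation = 2L), nn_relu()))
    cin <- cout
  }
  head <- list(nn_conv(64, 1, k = 1L, init_sd = 0.01))
  c(front, back, head)
}

build_layers_tiny <- function(output_stride) {
  n_pools <- as.integer(log2(output_stride))
  layers <- list(nn_conv(3, 16), nn_relu())
  if (n_pools >= 1) layers <- c(layers, list(nn_pool()))
  layers <- c(layers, list(nn_conv(16, 32), nn_relu()))
  if (n_pools >= 2) layers <- c(layers, list(nn_pool()))
  layers <- c(layers, list(
    nn_conv(32, 32), nn_relu(),
    nn_conv(32, 32, dilation = 2L), nn_relu(),
    nn_conv(32, 16, dilation = 2L), nn_relu(),
    nn_conv(16, 1, k = 1L, init_sd = 0.01)
  ))
  layers
}

#' Build a density-regression network
#'
#' Constructs the layer stack of the configured variant with seeded,
#' reproducible weight initialization (He-scaled Gaussian; the 1x1 head uses
#' sd 0.01).
#'
#' @param config A [network_config] object.
#' @param seed Integer RNG seed; the same (config, seed) pair always yields
#'   identical parameters.
#' @return An object of class `panicle_network`.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  set.seed(seed)
  layers <- switch(config$variant,
    full = build_layers_full(),
    tiny = build_layers_tiny(config$output_stride)
  )
  structure(
    list(layers = layers, config = config, seed = as.integer(seed),
         # 3x3 dilation-2 taps need a 5-pixel support at the deepest scale
         min_input = 5L * config$output_stride),
    class = "panicle_network"
  )
}

#' @export
print.panicle_network <- function(x, ...) {
  cat(sprintf("<panicle_network> variant %s, output stride %d, %d parameters\n",
              x$config$variant, x$config$output_stride, network_num_params(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model A `panicle_network`.
#' @return Integer parameter count (weights + biases).
#' @export
network_num_params <- function(model) {
  stopifnot(inherits(model, "panicle_network"))
  sum(vapply(model$layers, function(l) {
    if (l$type == "conv") length(l$W) + length(l$b) else 0L
  }, numeric(1)))
}

# --- forward / backward -------------------------------------------------------

# x: H x W x C array. Returns list(out, caches); caches is NULL unless
# want_cache, in which case it carries what each layer's backward needs.
nn_forward <- function(model, x, want_cache = FALSE) {
  caches <- if (want_cache) vector("list", length(model$layers)) else NULL
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    d <- dim(x)
    if (l$type == "conv") {
      cols <- im2col_cpp(x, d[1], d[2], d[3], l$kh, l$kw, l$pad, l$dil)
      outmat <- cols %*% l$W
      outmat <- sweep(outmat, 2, l$b, "+")
      ho <- d[1] + 2 * l$pad - l$dil * (l$kh - 1)
      wo <- d[2] + 2 * l$pad - l$dil * (l$kw - 1)
      if (want_cache) caches[[li]] <- list(cols = cols, dims = d)
      x <- array(outmat, c(ho, wo, l$cout))
    } else if (l$type == "relu") {
      mask <- x > 0
      if (want_cache) caches[[li]] <- list(mask = mask)
      x <- x * mask
    } else if (l$type == "pool") {
      res <- maxpool2_fwd_cpp(x, d[1], d[2], d[3])
      if (want_cache) caches[[li]] <- list(argmax = res$argmax, dims = d)
      x <- res$out
    }
  }
  list(out = x, caches = caches)
}

# dout: gradient wrt network output (H' x W' x 1 array).
# Returns list(grads): per conv layer a list(dW, db); NULL for others.
nn_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    if (l$type == "conv") {
      cache <- caches[[li]]
      d <- cache$dims
      doutmat <- matrix(dout, ncol = l$cout)
      grads[[li]] <- list(dW = crossprod(cache$cols, doutmat),
                          db = colSums(doutmat))
      dcols <- doutmat %*% t(l$W)
      dout <- col2im_cpp(dcols, d[1], d[2], d[3], l$kh, l$kw, l$pad, l$dil)
    } else if (l$type == "relu") {
      dout <- dout * caches[[li]]$mask
    } else if (l$type == "pool") {
      d <- caches[[li]]$dims
      dout <- maxpool2_bwd_cpp(dout, caches[[li]]$argmax, d[1], d[2], d[3])
    }
  }
  grads
}

#' A count prediction for one image
#'
#' @param density A [density_map] (at the network's output stride) with
#'   negative activations clamped to zero.
#' @param raw_count The mass of the clamped map.
#' @param image_id Image identifier.
#' @return An object of class `count_prediction`.
#' @export
count_prediction <- function(density, raw_count, image_id = "") {
  stopifnot(inherits(density, "density_map"), raw_count >= 0)
  structure(list(density = density, raw_count = raw_count,
                 image_id = image_id),
            class = "count_prediction")
}

#' @export
print.count_prediction <- function(x, ...) {
  cat(sprintf("<count_prediction> %s: raw count %.2f\n",
              x$image_id, x$raw_count))
  invisible(x)
}

#' Predict the density map and raw count of one image
#'
#' Runs the network in inference mode. Negative output activations are
#' clamped at zero so the density map — and therefore the count, its
#' integral — is well defined.
#'
#' @param model A `panicle_network` from [build_network()].
#' @param image Standardized `H x W x 3` array (see [normalize_image()]);
#'   both sides must be at least `5 * output_stride` pixels.
#' @param image_id Identifier recorded in the prediction.
#' @return A [count_prediction].
#' @export
predict_density <- function(model, image, image_id = "") {
  stopifnot(inherits(model, "panicle_network"))
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    pc_value_error("image must be an H x W x 3 array")
  if (d[1] < model$min_input || d[2] < model$min_input)
    pc_value_error(sprintf(
      "image %dx%d below the minimum input size %d for the %s variant",
      d[1], d[2], model$min_input, model$config$variant))
  out <- nn_forward(model, image)$out
  grid <- pmax(matrix(out, dim(out)[1], dim(out)[2]), 0)
  dm <- density_map(grid, model$config$output_stride, image_id)
  count_prediction(dm, sum(grid), image_id)
}

# --- checkpoints --------------------------------------------------------------

#' Save a network checkpoint
#'
#' Serializes the model (layers, config, seed) with R's native
#' serialization, the standard checkpoint format for R models.
#'
#' @param model A `panicle_network`.
#' @param path Output `.rds` path.
#' @return The path, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "panicle_network"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a network checkpoint
#' @param path Path written by [save_checkpoint()].
#' @return A `panicle_network`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) pc_not_found(sprintf("no checkpoint at %s", path))
  model <- readRDS(path)
  if (!inherits(model, "panicle_network"))
    pc_format_error("file is not a panicle_network checkpoint")
  model
}
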