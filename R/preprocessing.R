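# Image loading and channel standardization.
#
# Images are standardized per channel, (value - mean) / std on the [0, 1]
# intensity scale, before entering the network. Statistics are dataset
# specific: the shipped defaults were measured on real panicle photographs;
# synthetic training recomputes its own.

#' Per-channel normalization statistics
#'
#' @param mean Numeric 3-vector of channel means, each in `[0, 1]`.
#' @param std Numeric 3-vector of channel standard deviations, each > 0.
#' @return An object of class `normalization_stats`.
#' @export
normalization_stats <- function(mean, std) {
  mean <- as.numeric(mean)
  std <- as.numeric(std)
  if (length(mean) != 3 || length(std) != 3)
    pc_value_error("mean and std must be 3-vectors")
  if (any(mean < 0 | mean > 1)) pc_value_error("means must lie in [0, 1]")
  if (any(std <= 0)) pc_value_error("stds must be > 0")
  structure(list(mean = mean, std = std), class = "normalization_stats")
}

#' Channel statistics measured on real panicle photographs
#'
#' The mean/std the counting model was developed with, measured over the
#' full photographic dataset of spread panicles on black background. Use for
#' inference on comparable real photographs; synthetic or new datasets
#' should recompute their own with [compute_channel_stats()].
#'
#' @return A [normalization_stats] object with
#'   mean `(0.301, 0.294, 0.274)` and std `(0.189, 0.182, 0.163)`.
#' @export
panicle_default_stats <- function() {
  normalization_stats(mean = c(0.301, 0.294, 0.274),
                      std = c(0.189, 0.182, 0.163))
}

#' Load an RGB image as an H x W x 3 array in [0, 1]
#'
#' Decodes PNG or JPEG. Grayscale images are replicated to three channels;
#' an alpha channel is dropped.
#'
#' @param path Image file path.
#' @return Numeric array of dimension `height x width x 3`, values in
#'   `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) pc_not_found(sprintf("image not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- try(switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    pc_format_error(sprintf("unsupported image extension '.%s'", ext))
  ), silent = TRUE)
  if (inherits(img, "try-error"))
    pc_io_error(sprintf("failed to decode image %s", path))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Compute dataset channel statistics by streaming accumulation
#'
#' Pixel-population mean and standard deviation per channel over all pixels
#' of all images, on intensities scaled to `[0, 1]`. Accumulates count, sum
#' and sum of squares image by image, so memory does not grow with dataset
#' size; larger images contribute proportionally more pixels. The standard
#' deviation is the population form and is floored at `1e-6` to protect
#' constant channels.
#'
#' @param image_paths Character vector of at least one readable image path.
#' @return A [normalization_stats] object.
#' @export
compute_channel_stats <- function(image_paths) {
  if (length(image_paths) < 1)
    pc_value_error("need at least one image path")
  n <- 0
  s <- numeric(3)
  ss <- numeric(3)
  for (p in image_paths) {
    img <- load_image(p)
    npix <- prod(dim(img)[1:2])
    n <- n + npix
    for (c in 1:3) {
      ch <- img[, , c]
      s[c] <- s[c] + sum(ch)
      ss[c] <- ss[c] + sum(ch^2)
    }
  }
  mu <- s / n
  v <- pmax(ss / n - mu^2, 0)
  normalization_stats(mu, pmax(sqrt(v), 1e-6))
}

#' Standardize an image with channel statistics
#'
#' `out[,,c] = (image[,,c] - mean[c]) / std[c]`. Affine and invertible:
#' `out * std + mean` recovers the input.
#'
#' @param image `H x W x 3` numeric array with values in `[0, 1]`.
#' @param stats A [normalization_stats] object.
#' @return `H x W x 3` numeric array of standardized values.
#' @export
normalize_image <- function(image, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    pc_value_error("image must be an H x W x 3 array")
  out <- image
  for (c in 1:3) out[, , c] <- (image[, , c] - stats$mean[c]) / stats$std[c]
  out
}

#' Invert [normalize_image()]
#' @param image Standardized `H x W x 3` array.
#' @param stats The [normalization_stats] used to standardize it.
#' @return The original `[0, 1]`-scale array.
#' @export
denormalize_image <- function(image, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  out <- image
  for (c in 1:3) out[, , c] <- image[, , c] * stats$std[c] + stats$mean[c]
  out
}
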