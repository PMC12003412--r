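# Geometry-adaptive Gaussian density maps.
#
# Each annotated grain contributes one unit of mass, spread by a Gaussian
# whose bandwidth sigma_i = beta * mean distance to the k nearest other
# grains, so tightly packed regions get tighter kernels. Kernels are
# truncated and discretely renormalized so the total mass of the map equals
# the grain count N regardless of borders or truncation.

#' Kernel parameters for density-map generation
#'
#' @param k Positive integer, number of nearest neighbors entering the mean
#'   distance \eqn{\bar d_i}; clamped to `N - 1` for small sets. Default 3,
#'   the usual choice in geometry-adaptive density-map pipelines.
#' @param beta Positive bandwidth factor: \eqn{\sigma_i = \beta \bar d_i}.
#'   Default 0.3, the value reported to give the best counting accuracy.
#' @param fallback_sigma Bandwidth in pixels used when an image has fewer
#'   than 2 points and no neighbor distance exists. Default 15 px.
#' @param truncation_radius Kernel support radius in units of sigma; the
#'   discrete kernel is renormalized over this support so every grain
#'   contributes mass exactly 1. Default 4.
#' @param sigma_floor Lower bound on sigma in pixels, protecting against
#'   duplicate points with zero neighbor distance. Default 0.5 px.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(k = 3L, beta = 0.3, fallback_sigma = 15,
                          truncation_radius = 4, sigma_floor = 0.5) {
  k <- as.integer(k)
  if (is.na(k) || k < 1) pc_value_error("k must be >= 1")
  if (!is.numeric(beta) || beta <= 0) pc_value_error("beta must be > 0")
  if (fallback_sigma <= 0) pc_value_error("fallback_sigma must be > 0")
  if (truncation_radius < 1) pc_value_error("truncation_radius must be >= 1")
  if (sigma_floor <= 0) pc_value_error("sigma_floor must be > 0")
  structure(list(k = k, beta = beta, fallback_sigma = fallback_sigma,
                 truncation_radius = truncation_radius,
                 sigma_floor = sigma_floor),
            class = "kernel_params")
}

#' Construct a density map
#'
#' A density map is a non-negative grid (rows = image rows) whose sum is the
#' estimated or exact grain count, together with the integer factor `scale`
#' relating its resolution to the source image (1 = full resolution).
#'
#' @param grid Numeric matrix of non-negative densities (grains per cell).
#' @param scale Positive integer downsampling factor relative to the image.
#' @param image_id Optional identifier of the source image.
#' @return An object of class `density_map`.
#' @export
density_map <- function(grid, scale = 1L, image_id = NULL) {
  if (!is.matrix(grid) || !is.numeric(grid))
    pc_value_error("grid must be a numeric matrix")
  scale <- as.integer(scale)
  if (is.na(scale) || scale < 1) pc_value_error("scale must be >= 1")
  if (any(grid < 0)) pc_value_error("density grid must be non-negative")
  structure(list(grid = grid, scale = scale, image_id = image_id),
            class = "density_map")
}

#' Total mass (count) of a density map
#' @param map A [density_map] object.
#' @return The sum of all grid cells — the count the map encodes.
#' @export
density_mass <- function(map) {
  stopifnot(inherits(map, "density_map"))
  sum(map$grid)
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %dx%d grid, scale %d, mass %.4f%s\n",
              nrow(x$grid), ncol(x$grid), x$scale, density_mass(x),
              if (is.null(x$image_id)) "" else paste0(" [", x$image_id, "]")))
  invisible(x)
}

#' Mean k-nearest-neighbor distance per point
#'
#' For every point, the mean Euclidean distance to its `k` nearest other
#' points, \eqn{\bar d_i = \frac{1}{k'}\sum_{j=1}^{k'} d_{ij}} with
#' `k' = min(k, N - 1)`. Output order matches input order.
#'
#' @param x,y Numeric coordinate vectors of equal length, `N >= 2`.
#' @param k Positive integer neighbor count.
#' @return Numeric vector of length `N` of non-negative mean distances.
#' @export
mean_knn_distance <- function(x, y, k) {
  n <- length(x)
  if (length(y) != n) pc_value_error("x and y must have equal length")
  if (n < 2)
    pc_stop("need at least 2 points for neighbor distances",
            "paniclecount_insufficient_points")
  k <- as.integer(k)
  if (is.na(k) || k < 1) pc_value_error("k must be >= 1")
  kp <- min(k, n - 1L)
  d <- as.matrix(dist(cbind(x, y)))
  diag(d) <- Inf
  unname(apply(d, 1, function(row) mean(sort(row, partial = kp)[seq_len(kp)])))
}

#' Per-point adaptive Gaussian bandwidths
#'
#' \eqn{\sigma_i = \beta \bar d_i} when at least two points exist;
#' `fallback_sigma` otherwise. Duplicate points (zero neighbor distance) are
#' floored at `sigma_floor` so every bandwidth is strictly positive.
#'
#' @param x,y Numeric coordinate vectors (any length, including 0 or 1).
#' @param params A [kernel_params] object.
#' @return Numeric vector of positive bandwidths, one per point.
#' @export
adaptive_sigmas <- function(x, y, params = kernel_params()) {
  stopifnot(inherits(params, "kernel_params"))
  n <- length(x)
  if (n == 0) return(numeric(0))
  if (n < 2) return(rep(params$fallback_sigma, n))
  dbar <- mean_knn_distance(x, y, params$k)
  pmax(params$beta * dbar, params$sigma_floor)
}

#' Render the ground-truth density map of an annotation set
#'
#' Evaluates \eqn{F = \sum_i \delta(\cdot - x_i) * G_{\sigma_i}} on the pixel
#' grid: each grain contributes a Gaussian of bandwidth \eqn{\sigma_i}
#' truncated at `truncation_radius * sigma` and renormalized over its
#' discrete support, so each grain contributes mass exactly 1 and the map
#' total equals N, including for points at the image border.
#'
#' @param ann A [point_annotations] object.
#' @param params A [kernel_params] object.
#' @return A [density_map] at full resolution (`scale = 1`) with grid shape
#'   `height x width`.
#' @export
render_density_map <- function(ann, params = kernel_params()) {
  stopifnot(inherits(ann, "point_annotations"))
  h <- ann$height
  w <- ann$width
  grid <- matrix(0, nrow = h, ncol = w)
  n <- n_points(ann)
  if (n == 0) return(density_map(grid, 1L, ann$image_id))
  xs <- ann$points$x
  ys <- ann$points$y
  sig <- adaptive_sigmas(xs, ys, params)
  for (i in seq_len(n)) {
    r <- ceiling(params$truncation_radius * sig[i])
    # pixel centers at integer coordinates, 0-based
    cx0 <- max(0, floor(xs[i] - r)); cx1 <- min(w - 1, ceiling(xs[i] + r))
    cy0 <- max(0, floor(ys[i] - r)); cy1 <- min(h - 1, ceiling(ys[i] + r))
    px <- cx0:cx1
    py <- cy0:cy1
    gx <- exp(-(px - xs[i])^2 / (2 * sig[i]^2))
    gy <- exp(-(py - ys[i])^2 / (2 * sig[i]^2))
    patch <- outer(gy, gx)
    patch <- patch / sum(patch)
    grid[py + 1, px + 1] <- grid[py + 1, px + 1] + patch
  }
  density_map(grid, 1L, ann$image_id)
}

#' Downsample a density map by block summation
#'
#' Sums `factor x factor` blocks (zero-padding the grid on the bottom/right
#' when the dimensions do not divide), so the total mass is preserved
#' exactly. Used to bring full-resolution ground truth to the network's
#' output stride.
#'
#' @param map A [density_map] object.
#' @param factor Positive integer pooling factor.
#' @return A [density_map] with `scale` multiplied by `factor`.
#' @export
downsample_density <- function(map, factor) {
  stopifnot(inherits(map, "density_map"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) pc_value_error("factor must be >= 1")
  if (factor == 1) return(map)
  g <- map$grid
  nr <- ceiling(nrow(g) / factor) * factor
  nc <- ceiling(ncol(g) / factor) * factor
  if (nr != nrow(g) || nc != ncol(g)) {
    padded <- matrix(0, nr, nc)
    padded[seq_len(nrow(g)), seq_len(ncol(g))] <- g
    g <- padded
  }
  pooled <- block_sum_pool(g, factor)
  density_map(pooled, map$scale * factor, map$image_id)
}

# factor-divisible block sum via two rowsum passes
block_sum_pool <- function(g, factor) {
  row_groups <- rep(seq_len(nrow(g) / factor), each = factor)
  col_groups <- rep(seq_len(ncol(g) / factor), each = factor)
  pooled <- t(rowsum(t(rowsum(g, row_groups)), col_groups))
  dimnames(pooled) <- NULL
  pooled
}

# --- persistence --------------------------------------------------------------

#' Write a density map to HDF5 or NPY
#'
#' HDF5 files (`.h5`/`.hdf5`) store the grid in dataset `density` with
#' attributes `scale` and `image_id`; `.npy` files store the bare grid as a
#' little-endian float64 C-order array (scale and image id are not
#' representable in NPY and are restored from arguments on read).
#'
#' @param map A [density_map] object.
#' @param path Output path ending in `.h5`, `.hdf5` or `.npy`.
#' @return The path, invisibly.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    # store transposed so row-major readers see (height, width)
    rhdf5::h5write(t(map$grid), path, "density")
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, "density")
    rhdf5::h5writeAttribute(as.integer(map$scale), did, "scale")
    rhdf5::h5writeAttribute(if (is.null(map$image_id)) "" else map$image_id,
                            did, "image_id")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  } else if (ext == "npy") {
    write_npy(map$grid, path)
  } else {
    pc_format_error(sprintf("unsupported density-map extension '.%s'", ext))
  }
  invisible(path)
}

#' Read a density map written by [write_density_map()]
#'
#' @param path `.h5`/`.hdf5` or `.npy` file.
#' @param scale,image_id Metadata used for `.npy` files, which cannot store
#'   it; ignored for HDF5, which carries its own attributes.
#' @return A [density_map] object.
#' @export
read_density_map <- function(path, scale = 1L, image_id = NULL) {
  if (!file.exists(path)) pc_not_found(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) {
    g <- t(rhdf5::h5read(path, "density"))
    attrs <- rhdf5::h5readAttributes(path, "density")
    sc <- as.integer(attrs$scale)[1]
    iid <- as.character(attrs$image_id)[1]
    if (!length(iid) || is.na(iid) || !nzchar(iid)) iid <- NULL
    density_map(g, sc, iid)
  } else if (ext == "npy") {
    density_map(read_npy(path), scale, image_id)
  } else {
    pc_format_error(sprintf("unsupported density-map extension '.%s'", ext))
  }
}

# --- minimal NPY (format 1.0, float64, C order) -------------------------------

write_npy <- function(mat, path) {
  stopifnot(is.matrix(mat))
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(mat), ncol(mat))
  # magic(6) + version(2) + header_len(2) + header must be a multiple of 64
  pad <- 64 - ((10 + nchar(header) + 1) %% 64)
  if (pad == 64) pad <- 0
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1, 0))), con)
  writeBin(zip_u16(nchar(header)), con)
  writeBin(charToRaw(header), con)
  writeBin(as.vector(t(mat)), con, size = 8, endian = "little")
  invisible(path)
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic[1:6], c(as.raw(0x93), charToRaw("NUMPY"))))
    pc_format_error("not an NPY file")
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  if (!grepl("'descr': *'<f8'", header) || grepl("'fortran_order': *True", header))
    pc_format_error("only little-endian float64 C-order NPY is supported")
  m <- regmatches(header, regexec("'shape': *\\((\\d+), *(\\d+)\\)", header))[[1]]
  if (length(m) != 3) pc_format_error("could not parse NPY shape")
  shape <- as.integer(m[2:3])
  vals <- readBin(con, "numeric", prod(shape), size = 8, endian = "little")
  matrix(vals, nrow = shape[1], ncol = shape[2], byrow = TRUE)
}
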