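# Per-image grain point annotations: one (x, y) pixel coordinate per grain,
# paired with the image by shared basename (image.jpg <-> image.xlsx/image.csv).

#' Construct a point annotation set
#'
#' A `point_annotations` object holds one (x, y) point per annotated grain for
#' a single panicle image, together with the image dimensions at which the
#' coordinates were recorded. Coordinates are 0-based pixels, `x` the column
#' and `y` the row, origin at the top-left corner; a point is in bounds when
#' `0 <= x < width` and `0 <= y < height`.
#'
#' @param image_id Non-empty string, the basename shared with the image file.
#' @param width,height Positive integer image dimensions in pixels.
#' @param x,y Numeric vectors of equal length, one entry per grain.
#' @return An object of class `point_annotations` with fields `image_id`,
#'   `width`, `height` and `points` (a data frame with columns `x`, `y` in
#'   annotation order).
#' @examples
#' ann <- point_annotations("img1", 100, 100, x = c(10, 30), y = c(20, 40))
#' n_points(ann)
#' @export
point_annotations <- function(image_id, width, height,
                              x = numeric(0), y = numeric(0)) {
  if (!is.character(image_id) || length(image_id) != 1 || !nzchar(image_id))
    pc_value_error("image_id must be a non-empty string")
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1 || height < 1)
    pc_value_error("width and height must be positive integers")
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    pc_value_error("x and y must have equal length")
  check_point_bounds(x, y, width, height)
  structure(
    list(image_id = image_id, width = width, height = height,
         points = data.frame(x = x, y = y)),
    class = "point_annotations"
  )
}

check_point_bounds <- function(x, y, width, height) {
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    pc_format_error(sprintf("non-numeric coordinate at row %d", bad[1]))
  oob <- which(x < 0 | x >= width | y < 0 | y >= height)
  if (length(oob))
    pc_bounds_error(sprintf(
      "point %d at (%g, %g) outside image bounds %dx%d",
      oob[1], x[oob[1]], y[oob[1]], width, height))
  invisible(TRUE)
}

#' Number of annotated grains
#' @param ann A `point_annotations` object.
#' @return Integer count `N`.
#' @export
n_points <- function(ann) {
  stopifnot(inherits(ann, "point_annotations"))
  nrow(ann$points)
}

#' @export
print.point_annotations <- function(x, ...) {
  cat(sprintf("<point_annotations> %s: %d points, image %dx%d px\n",
              x$image_id, n_points(x), x$width, x$height))
  invisible(x)
}

#' @export
format.point_annotations <- function(x, ...) {
  sprintf("%s (%d points)", x$image_id, n_points(x))
}

#' Read grain point annotations from a spreadsheet or CSV file
#'
#' Reads one point per row from the annotation file paired with an image.
#' `.xlsx` files are read from their first sheet, `.csv` files with a header
#' row; both must carry numeric `x` and `y` columns. Row order is preserved.
#' Out-of-bounds or non-numeric coordinates raise an error naming the
#' offending row; points are never silently dropped.
#'
#' @param path Path to a `.xlsx` or `.csv` annotation file.
#' @param width,height Image dimensions in pixels that the coordinates refer
#'   to (the native resolution of the paired image).
#' @param image_id Optional image identifier; defaults to the file basename
#'   without extension.
#' @return A [point_annotations] object.
#' @seealso [write_annotations()], [find_annotation_file()]
#' @export
read_annotations <- function(path, width, height,
                             image_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path))
    pc_not_found(sprintf("annotation file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    xlsx = {
      d <- suppressMessages(
        readxl::read_xlsx(path, sheet = 1, col_types = "text"))
      as.data.frame(d, stringsAsFactors = FALSE)
    },
    csv = read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    pc_format_error(sprintf("unsupported annotation extension '.%s'", ext))
  )
  if (!all(c("x", "y") %in% tolower(names(df))))
    pc_format_error("annotation file must have 'x' and 'y' columns")
  names(df) <- tolower(names(df))
  xs <- suppressWarnings(as.numeric(df$x))
  ys <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(xs) | is.na(ys))
  if (length(bad))
    pc_format_error(sprintf("non-numeric coordinate at data row %d of %s",
                            bad[1], basename(path)))
  neg <- which(xs < 0 | ys < 0)
  if (length(neg))
    pc_format_error(sprintf("negative coordinate at data row %d of %s",
                            neg[1], basename(path)))
  point_annotations(image_id, width, height, xs, ys)
}

#' Write grain point annotations
#'
#' Writes the point list so that [read_annotations()] recovers an equal set.
#' The format follows the file extension: `.xlsx` (single sheet, header row
#' `x`, `y`) or `.csv`. When `path` is an existing directory the file is named
#' after the annotation's `image_id` — the same-prefix convention that pairs
#' annotation files with their images.
#'
#' @param ann A [point_annotations] object.
#' @param path Output file path ending in `.xlsx` or `.csv`, or an existing
#'   directory.
#' @param format Used only when `path` is a directory: `"xlsx"` (default) or
#'   `"csv"`.
#' @return The path written, invisibly.
#' @export
write_annotations <- function(ann, path, format = c("xlsx", "csv")) {
  stopifnot(inherits(ann, "point_annotations"))
  if (dir.exists(path)) {
    format <- match.arg(format)
    path <- file.path(path, paste0(ann$image_id, ".", format))
  }
  ext <- tolower(tools::file_ext(path))
  if (!dir.exists(dirname(path)))
    pc_io_error(sprintf("directory does not exist: %s", dirname(path)))
  df <- ann$points
  res <- try(switch(ext,
    xlsx = write_minimal_xlsx(df, path),
    csv = write.csv(df, path, row.names = FALSE, quote = FALSE),
    pc_format_error(sprintf("unsupported annotation extension '.%s'", ext))
  ), silent = TRUE)
  if (inherits(res, "try-error"))
    pc_io_error(sprintf("failed to write %s: %s", path,
                        attr(res, "condition")$message))
  invisible(path)
}

#' Rescale annotations to a new image resolution
#'
#' Coordinates scale linearly with the image: `x' = x * new_width / width`,
#' `y' = y * new_height / height`. The point count and ordering are
#' unchanged. Rescaling to the source dimensions is the exact identity.
#'
#' @param ann A [point_annotations] object.
#' @param new_width,new_height Positive target dimensions in pixels.
#' @return A [point_annotations] object at the new resolution.
#' @export
rescale_annotations <- function(ann, new_width, new_height) {
  stopifnot(inherits(ann, "point_annotations"))
  new_width <- as.integer(new_width)
  new_height <- as.integer(new_height)
  if (is.na(new_width) || is.na(new_height) || new_width < 1 || new_height < 1)
    pc_value_error("target dimensions must be positive")
  if (new_width == ann$width && new_height == ann$height)
    return(ann)
  sx <- new_width / ann$width
  sy <- new_height / ann$height
  x <- ann$points$x * sx
  y <- ann$points$y * sy
  # linear scaling cannot push an in-bounds point past the open upper bound,
  # but guard against float round-up at the edge
  x <- pmin(x, new_width * (1 - .Machine$double.eps))
  y <- pmin(y, new_height * (1 - .Machine$double.eps))
  point_annotations(ann$image_id, new_width, new_height, x, y)
}

#' Locate the annotation file paired with an image
#'
#' Annotation files live next to the image with the same basename and
#' extension `.xlsx` or `.csv` (checked in that order).
#'
#' @param image_path Path to the image file.
#' @return The annotation path, or `NA_character_` when none exists.
#' @export
find_annotation_file <- function(image_path) {
  stem <- file.path(dirname(image_path),
                    tools::file_path_sans_ext(basename(image_path)))
  for (ext in c(".xlsx", ".csv")) {
    cand <- paste0(stem, ext)
    if (file.exists(cand)) return(cand)
  }
  NA_character_
}
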