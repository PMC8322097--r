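#' Grayscale image container
#'
#' A thin wrapper around a numeric matrix of pixel intensities with
#' physical-pixel-size metadata. Row index `i` runs top to bottom, column
#' index `j` left to right; intensities are stored as doubles and need not
#' be normalized (the spatial-lag model is scale invariant).
#'
#' @param pixels numeric matrix of intensities, at least 2 x 2 for any
#'   model fit. All values must be finite.
#' @param pixel_size_nm physical pixel edge length in nanometres. Metadata
#'   only; it enters area computations but never the regression.
#' @return An object of class `grayscale_image` with elements `pixels`
#'   (double matrix) and `pixel_size_nm`.
#' @examples
#' img <- grayscale_image(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
grayscale_image <- function(pixels, pixel_size_nm = 73) {
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels)
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("image contains non-finite pixel values", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm)),
    class = "grayscale_image"
  )
}

#' @export
dim.grayscale_image <- function(x) dim(x$pixels)

#' @export
print.grayscale_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<grayscale_image> %d x %d px (%.0f nm/px), range [%.4g, %.4g]\n",
    d[1], d[2], x$pixel_size_nm, min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Coerce to a grayscale image
#'
#' Accepts a `grayscale_image` (returned as is) or a numeric matrix.
#'
#' @param x object to coerce.
#' @param pixel_size_nm pixel size used when `x` is a bare matrix.
#' @return A `grayscale_image`.
#' @export
as_grayscale_image <- function(x, pixel_size_nm = 73) {
  if (inherits(x, "grayscale_image")) return(x)
  grayscale_image(x, pixel_size_nm = pixel_size_nm)
}

#' Flatten an image to a vector in column-major order
#'
#' Columns are stacked top to bottom, left to right, so element
#' `j * m + i` (0-based) of the output is pixel `(i, j)`. This is the
#' vectorization used to set up the spatial-lag regression.
#'
#' @param img a `grayscale_image` or numeric matrix.
#' @return Numeric vector of length `m * n`.
#' @examples
#' vectorize_image(matrix(1:4, 2, 2, byrow = TRUE))  # [1, 3, 2, 4]
#' @export
vectorize_image <- function(img) {
  img <- as_grayscale_image(img)
  as.vector(img$pixels)
}
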