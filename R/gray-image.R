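#' Grayscale reactor frame
#'
#' A single monochrome frame: a numeric matrix of gray levels in \[0, 255\]
#' (0 = black background, 255 = white) with a physical pixel size. This is the
#' unit all morphological measurements operate on. The default pixel size,
#' 8.2 um, is that of a macro-imaging torus reactor observing particles in
#' suspension with a telecentric lens.
#'
#' @param pixels numeric matrix of gray levels in \[0, 255\]; rows are the
#'   vertical (y) image axis, columns the horizontal (x) axis.
#' @param pixel_size_um physical side length of one pixel, in micrometers.
#' @return An object of class `gray_image`: the pixel matrix with attributes
#'   `pixel_size_um` and `bit_depth` (8).
#' @examples
#' img <- gray_image(matrix(0, 64, 64))
#' total_gray(img)
#' @export
gray_image <- function(pixels, pixel_size_um = 8.2) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("gray levels must be finite and within [0, 255]")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(pixels,
            pixel_size_um = as.numeric(pixel_size_um),
            bit_depth = 8L,
            class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.3g um/px, gray range [%g, %g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"), min(x), max(x)))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

as_gray_image <- function(pixels, like) {
  gray_image(pixels, pixel_size_um = attr(like, "pixel_size_um"))
}

pixel_size <- function(img) attr(img, "pixel_size_um")

#' Gray-level mass of an image
#'
#' Sum of all gray levels. On a tophat-preprocessed frame of bright particles
#' on a dark background this sum is the segmentation-free proxy for the total
#' number of particles: disjoint identical particles contribute additively.
#'
#' @param img a [gray_image()].
#' @return A single number, the sum of all pixel values.
#' @seealso [tophat_preprocess()], [relative_particle_number()]
#' @export
total_gray <- function(img) {
  stopifnot(is.matrix(img), is.numeric(img))
  sum(img)
}

#' Grayscale opening by a linear structuring element
#'
#' Morphological opening (erosion then dilation) of a grayscale image by a
#' 1-px-thick horizontal (0 degrees) or vertical (90 degrees) line segment of
#' `length_px` pixels. The opening removes bright structures whose extent in
#' the SE direction is smaller than the SE: it is the elementary sieve of
#' gray-level granulometry. The image border is treated as background
#' (gray level 0), consistent with dark-field imaging.
#'
#' The operator is anti-extensive (output <= input pixelwise) and idempotent
#' for any SE length, including even lengths.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param length_px SE length in pixels (>= 1).
#' @param orientation_deg 0 (horizontal, along the image x axis / matrix
#'   columns) or 90 (vertical).
#' @return The opened image, same class and pixel size as the input.
#' @export
opening_linear <- function(img, length_px, orientation_deg = 0) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (length(length_px) != 1L || length_px < 1 || length_px != round(length_px))
    stop("`length_px` must be a single integer >= 1")
  if (!orientation_deg %in% c(0, 90))
    stop("`orientation_deg` must be 0 or 90")
  out <- cpp_open_line(unclass(img), as.integer(length_px), orientation_deg == 0)
  if (is_gray_image(img)) as_gray_image(out, img) else out
}

#' Tophat background removal
#'
#' White tophat transform: the image minus its opening by a square structuring
#' element. Bright objects smaller than the SE are kept while slowly varying
#' background (illumination drift, turbidity haze) is removed. The default SE
#' side of 131 px corresponds to 1074.2 um at 8.2 um/px, just above the
#' largest particle size analyzed by the granulometry, so whole particles
#' survive while the background does not.
#'
#' @param img a [gray_image()].
#' @param se_side_px side of the square SE in pixels; must be odd and >= 1.
#' @return A [gray_image()] with non-negative values, pixelwise <= `img`.
#' @export
tophat_preprocess <- function(img, se_side_px = 131) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (length(se_side_px) != 1L || se_side_px < 1 || se_side_px != round(se_side_px))
    stop("`se_side_px` must be a single integer >= 1")
  if (se_side_px %% 2 == 0) stop("`se_side_px` must be odd")
  if (se_side_px > nrow(img) || se_side_px > ncol(img))
    stop("structuring element larger than the image")
  opened <- cpp_open_square(unclass(img), as.integer(se_side_px))
  out <- unclass(img) - opened
  if (is_gray_image(img)) as_gray_image(out, img) else out
}
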