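#' @title Image and mask containers
#'
#' @description
#' Images are plain numeric arrays of dimension `H x W x 3` (rows are image
#' rows, so `dim(x)[1]` is the pixel height). Intensities are either 8-bit
#' integers in `[0, 255]` (the on-disk representation) or unit-interval reals
#' in `[0, 1]` (the representation fed to the network). Nuclei masks are
#' `H x W` matrices that are strictly binary: every pixel is 0 or 1.
#'
#' These helpers validate the two containers and convert between the disk
#' and in-memory conventions; all other functions in the package assume
#' their inputs have passed these checks.
#'
#' @name image-containers
NULL

#' Validate an RGB image array
#'
#' @param image numeric `H x W x 3` array.
#' @param arg name used in error messages.
#' @return the image, invisibly.
#' @keywords internal
check_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    stop(sprintf("`%s` has empty spatial dimensions", arg), call. = FALSE)
  if (!is.numeric(image) || anyNA(image))
    stop(sprintf("`%s` must be numeric with no missing values", arg), call. = FALSE)
  invisible(image)
}

#' Validate a binary nuclei mask
#'
#' @param mask numeric `H x W` matrix with values in `{0, 1}`.
#' @param image optional image the mask must spatially match.
#' @return the mask, invisibly.
#' @keywords internal
check_mask <- function(mask, image = NULL) {
  if (!is.matrix(mask))
    stop("`mask` must be an H x W matrix", call. = FALSE)
  if (!all(mask == 0 | mask == 1))
    stop("`mask` must be strictly binary (values in {0, 1})", call. = FALSE)
  if (!is.null(image) && !identical(dim(mask), dim(image)[1:2]))
    stop(sprintf(
      "mask dimensions (%d x %d) do not match image (%d x %d)",
      nrow(mask), ncol(mask), dim(image)[1], dim(image)[2]
    ), call. = FALSE)
  invisible(mask)
}

#' Read an RGB image from PNG or TIFF
#'
#' Returns an `H x W x 3` array of 8-bit intensities in `[0, 255]`.
#' Grayscale files are replicated across channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return numeric `H x W x 3` array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  x <- switch(tolower(tools::file_ext(path)),
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", path, call. = FALSE)
  )
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' Write an RGB image to PNG or TIFF
#'
#' @param image `H x W x 3` array, either `[0, 255]` 8-bit or `[0, 1]` real.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_rgb_image(image)
  if (max(image) > 1) image <- image / 255
  image <- pmin(pmax(image, 0), 1)
  switch(tolower(tools::file_ext(path)),
    png  = png::writePNG(image, path),
    tif  = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = 8L),
    stop("unsupported image format: ", path, call. = FALSE)
  )
  invisible(path)
}

#' Read a binary nuclei mask from a single-channel PNG
#'
#' On disk masks use `{0, 255}`; in memory they are `{0, 1}`. Any strictly
#' positive pixel is treated as nuclei.
#'
#' @param path PNG path.
#' @return `H x W` matrix with values in `{0, 1}`.
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  m <- (x > 0.5) * 1
  check_mask(m)
  m
}

#' Write a binary mask as a single-channel PNG
#'
#' @param mask `H x W` matrix in `{0, 1}`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask, path)
  invisible(path)
}
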