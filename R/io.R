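# 8-bit raster I/O. Intensities are [0, 1] in memory; the 0-255 byte scale
# exists only on disk (and in metric reporting).

#' Read an 8-bit PNG or TIFF image
#'
#' @param path file path; format chosen by extension. Only 8-bit rasters are
#'   accepted.
#' @return matrix (grayscale) or H x W x C array on [0, 1].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8)
      stop("only 8-bit PNG images are supported: ", path, call. = FALSE)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF input", call. = FALSE)
    img <- tiff::readTIFF(path, info = TRUE)
    info <- attributes(img)
    if (!is.null(info$bits.per.sample) && info$bits.per.sample != 8)
      stop("only 8-bit TIFF images are supported: ", path, call. = FALSE)
  } else stop("unsupported image format: ", path, call. = FALSE)
  attributes(img)[setdiff(names(attributes(img)), "dim")] <- NULL
  # drop a trivial alpha channel
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  img
}

#' Write an image as an 8-bit PNG or TIFF
#'
#' Values are clipped to [0, 1] and quantized to 8 bits
#' (`round(value * 255)`), so an 8-bit round-trip is lossless.
#'
#' @param path output path (.png, .tif/.tiff).
#' @param image matrix or H x W x C array on [0, 1].
#' @export
write_image <- function(path, image) {
  image <- clip01(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF output", call. = FALSE)
    tiff::writeTIFF(image, path, bits.per.sample = 8L)
  } else stop("unsupported image format: ", path, call. = FALSE)
  invisible(path)
}

#' Read a binary mask image ({0, 255} bytes map to {0, 1})
#' @param path image path.
#' @return binary matrix.
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m > 0.5) * 1
}
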