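#' Read a field image into the package's raster convention
#'
#' Images are held as `H x W x 3` numeric arrays with channel intensities in
#' `[0, 255]`. PNG is read with \pkg{png}; JPEG/TIFF are read through
#' \pkg{EBImage} when it is installed.
#'
#' @param path path to a PNG or JPEG/TIFF file.
#' @return an `H x W x 3` numeric array, intensities in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such image file: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
    return(round(img * 255))
  }
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort(sprintf("reading .%s needs the EBImage package; PNG needs only png", ext))
  }
  img <- EBImage::imageData(EBImage::readImage(path))
  # EBImage stores x,y[,c]; transpose to row = y
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img <- aperm(img[, , 1:3, drop = FALSE], c(2, 1, 3))
  round(img * 255)
}

#' Write an image array as PNG
#'
#' @param image `H x W x 3` array, intensities in `[0, 255]`.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}
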