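#' Read a raster image as an RGB image
#'
#' Supports PNG and JPEG. Grayscale rasters are promoted to RGB by channel
#' replication; images with an alpha channel are rejected (the pipeline has
#' no transparency semantics). TIFF is not supported in this build.
#'
#' @param path file path ending in .png, .jpg or .jpeg.
#' @return an [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_data("read_image: no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    tif = ,
    tiff = stop_data("read_image: TIFF is not supported in this build; convert to PNG"),
    stop_data("read_image: unsupported image format '.%s' (use PNG or JPEG)", ext)
  )
  if (length(dim(raw)) == 2L) {
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  } else if (dim(raw)[3] == 4L) {
    stop_data("read_image: image has an alpha channel, which is not supported: %s", path)
  } else if (dim(raw)[3] == 2L) {
    stop_data("read_image: gray+alpha images are not supported: %s", path)
  }
  rgb_image(round_half_up(raw * 255))
}

#' Write an RGB image to PNG
#'
#' @param img an [rgb_image()].
#' @param path output path (.png).
#' @export
write_image <- function(img, path) {
  img <- as_rgb_image(img)
  png::writePNG(unclass(img) / 255, target = path)
  invisible(path)
}

#' Write a binary mask as an 8-bit single-channel PNG
#'
#' @param mask a `binary_mask` (values 0/255 only).
#' @param path output path (.png).
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(unclass(mask) / 255, target = path)
  invisible(path)
}

#' Read a single-channel PNG back as a binary mask
#'
#' @param path path to an 8-bit PNG containing only values 0 and 255.
#' @return a `binary_mask`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_data("read_mask: no such file: %s", path)
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  vals <- round_half_up(raw * 255)
  if (!all(vals %in% c(0, 255)))
    stop_data("read_mask: %s is not binary (found gray levels other than 0/255)", path)
  as_binary_mask(matrix(as.integer(vals), nrow = nrow(raw)))
}
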