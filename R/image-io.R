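#' Fundus image container
#'
#' A colour fundus photograph with identifier and cohort label. Pixels are an
#' `H x W x 3` array with channels in `[0, 1]`, rows top-to-bottom.
#'
#' @param pixels Numeric `H x W x 3` array in `[0, 1]` (a 2-D matrix is
#'   replicated across the three channels).
#' @param image_id Character identifier.
#' @param cohort Cohort label, e.g. a country name or `"synthetic"`.
#' @return An object of class `"fundus_image"` with fields `image_id`,
#'   `cohort`, `pixels` and `native_resolution` (`c(H, W)`).
#' @export
fundus_image <- function(pixels, image_id = "img", cohort = "unlabelled") {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  d <- dim(pixels)
  if (d[1] < 64 || d[2] < 64) {
    stop("fundus image must be at least 64 x 64 pixels")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel values must be finite and in [0, 1]")
  }
  structure(
    list(image_id = as.character(image_id), cohort = as.character(cohort),
         pixels = pixels, native_resolution = c(d[1], d[2])),
    class = "fundus_image"
  )
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf("<fundus_image> %s [%s] %d x %d px\n",
              x$image_id, x$cohort,
              x$native_resolution[1], x$native_resolution[2]))
  invisible(x)
}

#' Read a fundus photograph from file
#'
#' Supports PNG, TIFF and JPEG (8- or 16-bit); values are scaled to `[0, 1]`,
#' grayscale files are replicated across channels and any alpha channel is
#' dropped.
#'
#' @param path Image file path.
#' @param image_id Identifier; defaults to the file name without extension.
#' @param cohort Cohort label.
#' @return A [fundus_image()].
#' @export
read_fundus <- function(path, image_id = NULL,
                        cohort = "unlabelled") {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext)
  )
  if (is.matrix(px)) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 1) px <- array(rep(px, 3), dim = c(dim(px)[1:2], 3))
  px[px < 0] <- 0
  px[px > 1] <- 1
  if (is.null(image_id)) {
    image_id <- tools::file_path_sans_ext(basename(path))
  }
  fundus_image(px, image_id = image_id, cohort = cohort)
}

#' Write a fundus image to a PNG file
#'
#' @param img A [fundus_image()].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_fundus_png <- function(img, path) {
  stopifnot(inherits(img, "fundus_image"))
  png::writePNG(img$pixels, path)
  invisible(path)
}
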