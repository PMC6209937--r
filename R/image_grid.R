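#' Image grid with physical pixel spacing
#'
#' The basic container used throughout the package: a 2D matrix of
#' non-negative intensities plus the isotropic pixel spacing in mm per pixel.
#' Row 1 is the top of the image (the transducer face / shallowest depth),
#' and indices are 1-based `(row, col)` as usual in R.
#'
#' @param intensities Numeric matrix of finite, non-negative values.
#' @param pixel_spacing Pixel spacing in mm per pixel (isotropic), `> 0`.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(intensities, pixel_spacing) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix")
  if (length(intensities) == 0L)
    stop("'intensities' must be non-empty")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and >= 0")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop("'pixel_spacing' must be a single positive number")
  structure(list(intensities = intensities, pixel_spacing = pixel_spacing),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_grid> %d x %d px, %.4g mm/px, range [%.4g, %.4g]\n",
              d[1], d[2], x$pixel_spacing,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$intensities)

#' Read a grayscale image (PNG or TIFF) into an image grid
#'
#' 8/16-bit PNG and TIFF are supported; intensities are normalized to
#' `[0, 1]` by the bit-depth maximum (the `png` and `tiff` readers already
#' return this normalization). Color images are rejected unless all channels
#' are identical, in which case the first channel is used.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param pixel_spacing Pixel spacing in mm per pixel.
#' @return An [image_grid].
#' @export
read_image <- function(path, pixel_spacing) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (need png/tif/tiff)"))
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3]
    for (k in seq_len(ch)[-1]) {
      if (max(abs(arr[, , k] - arr[, , 1])) > 1e-8)
        stop("non-grayscale input: ", path)
    }
    arr <- arr[, , 1]
  }
  image_grid(arr, pixel_spacing)
}

#' Write an image grid as a 16-bit grayscale TIFF or 8-bit PNG
#'
#' Intensities are clamped to `[0, 1]` before quantization.
#'
#' @param img An [image_grid].
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image_grid"))
  m <- pmin(pmax(img$intensities, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, target = path),
    tif = ,
    tiff = tiff::writeTIFF(m, where = path, bits.per.sample = 16L),
    stop("unsupported image format '", ext, "'"))
  invisible(path)
}

#' Read a co-registered power Doppler / B-mode image pair
#'
#' @param doppler_path,bmode_path Image file paths (PNG/TIFF).
#' @param pixel_spacing Pixel spacing in mm per pixel shared by both images.
#' @return A list with elements `doppler` and `bmode`, both [image_grid]s.
#' @export
read_image_pair <- function(doppler_path, bmode_path, pixel_spacing) {
  doppler <- read_image(doppler_path, pixel_spacing)
  bmode <- read_image(bmode_path, pixel_spacing)
  if (!identical(dim(doppler$intensities), dim(bmode$intensities)))
    stop("images not co-registered: dimensions differ")
  list(doppler = doppler, bmode = bmode)
}

# bilinear interpolation of a matrix at (possibly fractional) row/col
# positions; NA outside [1, nrow] x [1, ncol]
bilinear_sample <- function(mat, rows, cols) {
  H <- nrow(mat); W <- ncol(mat)
  out <- rep(NA_real_, length(rows))
  ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
  if (!any(ok)) return(out)
  r <- rows[ok]; c <- cols[ok]
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  v <- (1 - fr) * (1 - fc) * mat[cbind(r0, c0)] +
       (1 - fr) * fc       * mat[cbind(r0, c0 + 1L)] +
       fr       * (1 - fc) * mat[cbind(r0 + 1L, c0)] +
       fr       * fc       * mat[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- v
  out
}
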