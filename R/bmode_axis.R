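#' Gabor filter parameters matched to the needle
#'
#' The filter is an oriented line detector: a 2D Gaussian envelope times a
#' complex sinusoidal plane wave. Its wavelength is set to the needle
#' diameter expressed in pixels, and the two envelope standard deviations are
#' fixed by requiring the envelope to drop to 50% of its maximum at half a
#' wavelength across the needle and at one wavelength along it:
#' `sigma_x = lambda / (2*sqrt(2*log(2)))` (across, the oscillating
#' direction) and `sigma_y = lambda / sqrt(2*log(2))` (along).
#'
#' `theta` is the angle (degrees from the horizontal image axis) of the
#' *linear structure to enhance*, i.e. the needle-axis angle; the kernel's
#' oscillating axis runs perpendicular to it.
#'
#' @param theta Orientation of the enhanced structure, degrees.
#' @param wavelength Sinusoid wavelength in pixels (= needle diameter / pixel
#'   spacing).
#' @return An object of class `gabor_params` with fields `theta`,
#'   `wavelength`, `sigma_x`, `sigma_y`.
#' @export
gabor_params <- function(theta, wavelength) {
  if (wavelength < 1)
    stop("needle thinner than one pixel: wavelength = ", wavelength)
  structure(list(theta = theta %% 180,
                 wavelength = wavelength,
                 sigma_x = wavelength / (2 * sqrt(2 * log(2))),
                 sigma_y = wavelength / sqrt(2 * log(2))),
            class = "gabor_params")
}

#' Build the complex Gabor kernel
#'
#' `kernel(x, y) = exp(-(xp^2/sigma_x^2 + yp^2/sigma_y^2)/2) *
#' exp(1i * 2*pi*xp/wavelength)`, where `(xp, yp)` are image coordinates
#' rotated so that `xp` runs across the enhanced structure and `yp` along
#' it. The support is truncated at `+/- 3` times the larger sigma (odd-sized
#' square), and the kernel value at the origin is exactly `1 + 0i`.
#'
#' @param params A [gabor_params].
#' @return A complex matrix of odd dimensions, with attribute `envelope`
#'   holding the real Gaussian envelope factor.
#' @export
build_gabor_kernel <- function(params) {
  stopifnot(inherits(params, "gabor_params"))
  half <- ceiling(3 * max(params$sigma_x, params$sigma_y))
  xs <- -half:half                       # x = column offset
  ys <- -half:half                       # y = row offset (downwards)
  # structure direction (cos t, sin t) in (x, y); xp axis perpendicular to it
  t <- params$theta * pi / 180
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  xp <- -X * sin(t) + Y * cos(t)         # across the structure
  yp <- X * cos(t) + Y * sin(t)          # along the structure
  env <- exp(-0.5 * (xp^2 / params$sigma_x^2 + yp^2 / params$sigma_y^2))
  k <- env * exp(1i * 2 * pi * xp / params$wavelength)
  attr(k, "envelope") <- env
  k
}

#' ROI-masked Gabor enhancement of the B-mode image
#'
#' The B-mode image is convolved with the complex Gabor kernel (FFT, zero
#' padding at the borders) and the response magnitude is kept inside the
#' union of the candidate-region ellipse interiors and set to zero outside.
#'
#' @param bmode B-mode [image_grid].
#' @param rois Non-empty list of [ellipse_roi]s.
#' @param params A [gabor_params] whose `theta` is the initial axis angle.
#' @return An [image_grid] of the filtered magnitudes.
#' @export
masked_gabor_filter <- function(bmode, rois, params) {
  stopifnot(inherits(bmode, "image_grid"))
  if (length(rois) == 0L) stop("no candidate regions: empty ROI list")
  k <- build_gabor_kernel(params)
  m <- bmode$intensities
  re <- EBImage::filter2(m, Re(k), boundary = 0)
  im <- EBImage::filter2(m, Im(k), boundary = 0)
  mag <- sqrt(re^2 + im^2)
  mag[!roi_union_mask(rois, dim(m))] <- 0
  image_grid(mag, bmode$pixel_spacing)
}

#' Refine the needle-axis offset at a fixed angle
#'
#' Computes the Radon projection of the filtered B-mode image at the single
#' angle of the initially estimated axis and returns the line at the offset
#' maximizing it (ties broken by the smallest offset). The angle is
#' preserved exactly; only the offset is refined at this stage.
#'
#' @param filtered Filtered B-mode [image_grid] (from [masked_gabor_filter]).
#' @param theta_init Radon angle of the initial axis, degrees.
#' @return A [line_estimate] with `theta == theta_init`.
#' @export
refine_axis <- function(filtered, theta_init) {
  m <- if (inherits(filtered, "image_grid")) filtered$intensities else filtered
  if (all(m == 0)) stop("refinement impossible: filtered image is all zero")
  rt <- radon_transform(m, theta_init)
  proj <- rt$sinogram[, 1]
  best <- which(proj == max(proj))[1]  # rho ascending: smallest-tie
  line_estimate(theta_init, rt$rho[best], dim(m))
}
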