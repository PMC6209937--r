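#' Straight line (needle axis) in image coordinates
#'
#' A line is parameterized the way the discrete Radon transform indexes it:
#' with `(x, y) = (col - cc, row - rc)` centered coordinates (image center
#' `rc = (nrow + 1)/2`, `cc = (ncol + 1)/2`; y grows downwards with the row
#' index), the line is the set `x*cos(theta) + y*sin(theta) = rho`, with
#' `theta` in degrees in `[0, 180)` and `rho` a signed offset in pixels.
#'
#' The equivalent point + direction form is stored alongside: `point` is the
#' line point closest to the image center and `direction` is the unit vector
#' `(d_row, d_col)` along the line, oriented downwards (`d_row >= 0`, and
#' `d_col > 0` when horizontal). The *line angle* `angle` is measured in
#' degrees from the horizontal image axis, in `[0, 180)`; for a needle
#' inserted from the top edge it equals the insertion angle.
#'
#' @param theta Radon integration angle in degrees, reduced to `[0, 180)`.
#' @param rho Signed offset in pixels from the image center.
#' @param shape Integer vector `c(nrow, ncol)` of the image the line lives in.
#' @return An object of class `line_estimate`.
#' @export
line_estimate <- function(theta, rho, shape) {
  stopifnot(length(theta) == 1L, length(rho) == 1L, length(shape) == 2L)
  theta <- theta %% 180
  rc <- (shape[1] + 1) / 2
  cc <- (shape[2] + 1) / 2
  th <- theta * pi / 180
  # closest point to center: (x, y) = rho * (cos, sin)
  point <- c(rc + rho * sin(th), cc + rho * cos(th))
  dir <- c(cos(th), -sin(th))               # (d_row, d_col), along the line
  dir[abs(dir) < 1e-12] <- 0
  if (dir[1] < 0 || (dir[1] == 0 && dir[2] < 0)) dir <- -dir
  angle <- (atan2(dir[1], dir[2]) * 180 / pi) %% 180
  if (180 - angle < 1e-9) angle <- 0
  structure(list(theta = theta, rho = rho, shape = as.integer(shape),
                 point = point, direction = dir, angle = angle),
            class = "line_estimate")
}

#' @export
print.line_estimate <- function(x, ...) {
  cat(sprintf(
    "<line_estimate> theta = %.2f deg, rho = %.2f px (angle %.2f deg from horizontal)\n",
    x$theta, x$rho, x$angle))
  invisible(x)
}

#' Line through two points, or with a given angle through a point
#'
#' @param p1,p2 Points `c(row, col)`.
#' @param shape Image shape `c(nrow, ncol)`.
#' @return A [line_estimate].
#' @export
line_from_points <- function(p1, p2, shape) {
  d <- c(p2[1] - p1[1], p2[2] - p1[2])
  if (sqrt(sum(d^2)) < 1e-12) stop("points coincide; line undefined")
  angle <- (atan2(d[1], d[2]) * 180 / pi) %% 180
  line_from_angle_point(angle, p1, shape)
}

#' @param angle Line angle in degrees from the horizontal image axis.
#' @param point A point `c(row, col)` on the line.
#' @rdname line_from_points
#' @export
line_from_angle_point <- function(angle, point, shape) {
  theta <- (angle + 90) %% 180
  th <- theta * pi / 180
  x <- point[2] - (shape[2] + 1) / 2
  y <- point[1] - (shape[1] + 1) / 2
  line_estimate(theta, x * cos(th) + y * sin(th), shape)
}

#' Perpendicular distance from points to a line, in pixels
#'
#' @param line A [line_estimate].
#' @param points Matrix with columns `(row, col)` (or a single `c(row, col)`).
#' @return Numeric vector of unsigned distances in pixels.
#' @export
point_line_distance <- function(line, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  th <- line$theta * pi / 180
  x <- points[, 2] - (line$shape[2] + 1) / 2
  y <- points[, 1] - (line$shape[1] + 1) / 2
  abs(x * cos(th) + y * sin(th) - line$rho)
}

# orthogonal projection of points (rows of (row, col)) onto the line
project_on_line <- function(line, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  p0 <- line$point
  d <- line$direction
  t <- (points[, 1] - p0[1]) * d[1] + (points[, 2] - p0[2]) * d[2]
  cbind(p0[1] + t * d[1], p0[2] + t * d[2])
}

#' Elliptical region of interest
#'
#' Regular-shaped stand-in for an irregular Doppler cluster, in the
#' "same second central moments" convention of standard region properties:
#' `major`/`minor` are full axis lengths (`4 * sqrt(eigenvalue)`), and
#' `orientation` is the major-axis angle in degrees from the horizontal
#' image axis (same convention as [line_estimate]'s `angle`).
#'
#' @param center Ellipse center `c(row, col)` in pixels.
#' @param major,minor Full major/minor axis lengths in pixels,
#'   `major >= minor > 0`.
#' @param orientation Major-axis angle in degrees from horizontal.
#' @return An object of class `ellipse_roi`.
#' @export
ellipse_roi <- function(center, major, minor, orientation) {
  stopifnot(length(center) == 2L)
  if (!(major >= minor && minor > 0))
    stop("need major >= minor > 0")
  structure(list(center = as.numeric(center), major = major, minor = minor,
                 orientation = orientation %% 180),
            class = "ellipse_roi")
}

#' @export
print.ellipse_roi <- function(x, ...) {
  cat(sprintf(
    "<ellipse_roi> center (%.1f, %.1f), axes %.1f x %.1f px, %.1f deg\n",
    x$center[1], x$center[2], x$major, x$minor, x$orientation))
  invisible(x)
}

# unit vectors of the ellipse axes as (d_row, d_col)
ellipse_axes_dir <- function(e) {
  a <- e$orientation * pi / 180
  list(major = c(sin(a), cos(a)), minor = c(cos(a), -sin(a)))
}

#' Test whether pixel centers lie inside an ellipse
#'
#' @param e An [ellipse_roi].
#' @param points Matrix with columns `(row, col)`.
#' @return Logical vector; boundary points (quadratic form equal 1) count as
#'   inside.
#' @export
ellipse_contains <- function(e, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  ax <- ellipse_axes_dir(e)
  dr <- points[, 1] - e$center[1]
  dc <- points[, 2] - e$center[2]
  u <- dr * ax$major[1] + dc * ax$major[2]
  v <- dr * ax$minor[1] + dc * ax$minor[2]
  (u / (e$major / 2))^2 + (v / (e$minor / 2))^2 <= 1 + 1e-12
}

# binary mask of the union of ellipse interiors over an image shape
roi_union_mask <- function(rois, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  for (e in rois) {
    a <- e$major / 2
    r0 <- max(1L, floor(e$center[1] - a)); r1 <- min(shape[1], ceiling(e$center[1] + a))
    c0 <- max(1L, floor(e$center[2] - a)); c1 <- min(shape[2], ceiling(e$center[2] + a))
    if (r0 > r1 || c0 > c1) next
    grid <- expand.grid(row = r0:r1, col = c0:c1)
    inside <- ellipse_contains(e, as.matrix(grid))
    idx <- cbind(grid$row[inside], grid$col[inside])
    mask[idx] <- TRUE
  }
  mask
}
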