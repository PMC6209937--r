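#' Iterative intermeans (Ridler-Calvard) threshold
#'
#' Starting from the global mean, iterates
#' `T <- (mean(values < T) + mean(values >= T)) / 2` until the update is
#' smaller than `tol` or `max_iter` iterations have been performed. The
#' default tolerance is half a gray level: 0.5 for images on an integer
#' (8/16-bit) scale, `0.5/255` for images normalized to `[0, 1]`.
#'
#' @param img An [image_grid] or numeric matrix/vector.
#' @param tol Convergence tolerance in intensity units.
#' @param max_iter Maximum number of iterations.
#' @return The threshold, with attribute `degenerate = TRUE` when the image
#'   is constant (the constant itself is returned in that case).
#' @export
intermeans_threshold <- function(img, tol = NULL, max_iter = 100L) {
  v <- if (inherits(img, "image_grid")) as.vector(img$intensities) else as.vector(img)
  if (length(v) == 0L) stop("empty image")
  if (is.null(tol)) tol <- if (max(v) > 1.5) 0.5 else 0.5 / 255
  if (min(v) == max(v)) {
    t <- v[1]
    attr(t, "degenerate") <- TRUE
    return(t)
  }
  t <- mean(v)
  for (i in seq_len(max_iter)) {
    lo <- v[v < t]
    hi <- v[v >= t]
    # with a non-constant image both classes are non-empty once t is strictly
    # inside the value range; guard the edge where t == min(v)
    m_lo <- if (length(lo)) mean(lo) else min(v)
    m_hi <- if (length(hi)) mean(hi) else max(v)
    t_new <- (m_lo + m_hi) / 2
    if (abs(t_new - t) < tol) {
      t <- t_new
      break
    }
    t <- t_new
  }
  t
}

#' Suppress weak Doppler responses
#'
#' Pixels strictly below the intermeans threshold are set to zero; the
#' remaining pixels are unaltered.
#'
#' @param img An [image_grid] (power Doppler image).
#' @param threshold Optional threshold; computed by [intermeans_threshold]
#'   when missing.
#' @return An [image_grid] of the same dimensions, with attribute
#'   `threshold` giving the value used.
#' @export
preprocess_doppler <- function(img, threshold = NULL) {
  stopifnot(inherits(img, "image_grid"))
  if (is.null(threshold)) threshold <- intermeans_threshold(img)
  m <- img$intensities
  m[m < as.numeric(threshold)] <- 0
  out <- image_grid(m, img$pixel_spacing)
  attr(out, "threshold") <- as.numeric(threshold)
  out
}

# CDF of box(|cos th|) convolved with box(|sin th|): the shadow profile of a
# unit square projected at angle th, as a function of the signed offset u
trapezoid_cdf <- function(u, th) {
  w1 <- abs(cos(th)); w2 <- abs(sin(th))
  if (w2 < 1e-9 || w1 < 1e-9) {      # axis-aligned: plain unit box
    return(pmin(pmax(u + 0.5, 0), 1))
  }
  a <- w1 / 2; b <- w2 / 2
  R <- function(t) pmax(t, 0)^2 / 2
  (R(u + a + b) - R(u + a - b) - R(u - a + b) + R(u - a - b)) / (w1 * w2)
}

# squared-distance <= R^2 lattice offsets (excluding the origin)
disc_offsets <- function(R) {
  r <- floor(R)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= R^2 & !(g$dr == 0 & g$dc == 0), ]
  as.matrix(g)
}

#' DBSCAN clustering of active Doppler pixels
#'
#' Groups the nonzero pixels of a preprocessed power Doppler image into
#' density-connected clusters under Euclidean pixel distance, with
#' neighborhood radius `R` and minimum neighborhood size `M` (a pixel counts
#' itself). Pixels that are neither core pixels nor within `R` of a core
#' pixel are discarded as noise. Cluster labels and the assignment of border
#' pixels shared between clusters are deterministic: cluster seeds are taken
#' in row-major order (down columns, as matrices are stored in R column-major,
#' clusters are seeded column by column) and a border pixel joins the first
#' cluster that reaches it.
#'
#' @param img An [image_grid], typically the output of [preprocess_doppler]
#'   (zeros mean inactive).
#' @param R Neighborhood radius in pixels (`> 0`). Default 6.
#' @param M Minimum number of pixels per neighborhood/cluster (`>= 1`).
#'   Default 100.
#' @return A list of `pixel_cluster` objects, each with elements `label`
#'   (integer) and `pixels` (m x 2 matrix of `(row, col)`); empty list when
#'   no cluster satisfies the parameters.
#' @export
cluster_doppler <- function(img, R = 6, M = 100) {
  stopifnot(inherits(img, "image_grid"), R > 0, M >= 1)
  m <- img$intensities
  H <- nrow(m); W <- ncol(m)
  active <- m > 0
  if (!any(active)) return(list())
  offs <- disc_offsets(R)

  # neighbor counts by exact shift-and-add of the padded activity mask
  r <- floor(R)
  pad <- matrix(0L, H + 2L * r, W + 2L * r)
  pad[(r + 1L):(r + H), (r + 1L):(r + W)] <- active
  counts <- matrix(1L, H, W)  # self-count
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1]; dc <- offs[k, 2]
    counts <- counts + pad[(r + 1L + dr):(r + H + dr), (r + 1L + dc):(r + W + dc)]
  }
  core <- active & counts >= M

  labels <- matrix(0L, H, W)
  if (!any(core)) return(list())
  core_idx <- which(core)  # column-major order, deterministic
  next_label <- 0L
  for (seed in core_idx) {
    if (labels[seed] != 0L) next
    next_label <- next_label + 1L
    labels[seed] <- next_label
    queue <- seed
    while (length(queue)) {
      p <- queue[1L]
      queue <- queue[-1L]
      pr <- ((p - 1L) %% H) + 1L
      pc <- ((p - 1L) %/% H) + 1L
      nr <- pr + offs[, 1]
      nc <- pc + offs[, 2]
      keep <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
      nidx <- (nc[keep] - 1L) * H + nr[keep]
      nidx <- nidx[active[nidx] & labels[nidx] == 0L]
      if (length(nidx)) {
        labels[nidx] <- next_label
        queue <- c(queue, nidx[core[nidx]])  # only cores expand further
      }
    }
  }

  lapply(seq_len(next_label), function(lb) {
    idx <- which(labels == lb)
    structure(list(label = lb,
                   pixels = cbind(row = ((idx - 1L) %% H) + 1L,
                                  col = ((idx - 1L) %/% H) + 1L)),
              class = "pixel_cluster")
  })
}

#' Discrete Radon transform with a square-pixel projection model
#'
#' Each pixel is treated as a unit square carrying its intensity. At
#' integration angle `theta` the square's shadow on the offset axis
#' `rho = x*cos(theta) + y*sin(theta)` (measured from the image center) is
#' the trapezoid `box(|cos theta|) * box(|sin theta|)` (a convolution of two
#' boxes), and the sinogram accumulates, per unit-spaced offset bin, the
#' exact trapezoid mass falling into the bin. This area-weighted projection
#' model is the standard square-basis discretization used in tomography; a
#' point-mass model (nearest or linear binning) is biased at lattice-aligned
#' angles (0, 45, 90, 135 degrees), where whole diagonals of pixel centers
#' project coherently onto single bins. The sinogram maxima identify the
#' strongest and longest straight structures.
#'
#' @param img An [image_grid] or numeric matrix.
#' @param angles Integration angles in degrees.
#' @return A list with `sinogram` (matrix, rows = offsets, columns = angles),
#'   `rho` (offset values of the rows) and `angles`.
#' @export
radon_transform <- function(img, angles = 0:179) {
  m <- if (inherits(img, "image_grid")) img$intensities else img
  H <- nrow(m); W <- ncol(m)
  idx <- which(m != 0)
  w <- m[idx]
  y <- ((idx - 1L) %% H) + 1L - (H + 1) / 2
  x <- ((idx - 1L) %/% H) + 1L - (W + 1) / 2
  rmax <- ceiling(sqrt(((H - 1) / 2)^2 + ((W - 1) / 2)^2)) + 1L
  rho <- (-rmax):rmax
  sino <- matrix(0, length(rho), length(angles))
  if (length(idx)) {
    for (j in seq_along(angles)) {
      th <- angles[j] * pi / 180
      p <- x * cos(th) + y * sin(th) + rmax + 1
      k0 <- round(p)
      # mass of the trapezoid centered at p inside bins k0 - 1, k0, k0 + 1
      lo <- trapezoid_cdf(k0 - 0.5 - p, th)
      hi <- trapezoid_cdf(k0 + 0.5 - p, th)
      s <- rowsum(c(w * lo, w * (hi - lo), w * (1 - hi)),
                  c(k0 - 1L, k0, k0 + 1L))
      sino[as.integer(rownames(s)), j] <- s
    }
  }
  list(sinogram = sino, rho = rho, angles = angles)
}

#' Detect the strongest and longest line by Radon-transform maximization
#'
#' Returns the `(theta, rho)` pair maximizing the discrete Radon sinogram of
#' the image over the given angles, as a [line_estimate]. Ties are broken by
#' the smallest angle, then the smallest offset.
#'
#' @inheritParams radon_transform
#' @return A [line_estimate] with attribute `score` (the maximal line
#'   integral).
#' @export
radon_line_detect <- function(img, angles = 0:179) {
  m <- if (inherits(img, "image_grid")) img$intensities else img
  if (all(m == 0)) stop("no line detectable: image has no nonzero pixel")
  rt <- radon_transform(m, angles)
  best <- which(rt$sinogram == max(rt$sinogram), arr.ind = TRUE)
  # column (angle) ascending, then row (rho) ascending
  best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
  est <- line_estimate(rt$angles[best[2]], rt$rho[best[1]], dim(m))
  attr(est, "score") <- max(rt$sinogram)
  est
}

#' Initial needle axis from Doppler clusters
#'
#' Rasterizes the cluster member pixels with their Doppler intensities
#' (everything else zero) and applies [radon_line_detect] over
#' `0..179` degrees, so that "strongest and longest" means the maximal
#' intensity line integral through the clustered Doppler responses.
#'
#' @param clusters List of clusters from [cluster_doppler].
#' @param img The (preprocessed) Doppler [image_grid] supplying intensities.
#' @param angle_step Angular increment in degrees (default 1).
#' @return A [line_estimate].
#' @export
initial_axis <- function(clusters, img, angle_step = 1) {
  if (length(clusters) == 0L) stop("no Doppler evidence: empty cluster list")
  stopifnot(inherits(img, "image_grid"))
  m <- matrix(0, nrow(img$intensities), ncol(img$intensities))
  for (cl in clusters) m[cl$pixels] <- img$intensities[cl$pixels]
  radon_line_detect(m, seq(0, 180 - angle_step, by = angle_step))
}

#' Represent a pixel cluster by its moment-equivalent ellipse
#'
#' Center is the pixel centroid; orientation and axis lengths come from the
#' eigen-decomposition of the second central moment matrix of the member
#' pixel coordinates, with full axis length `4 * sqrt(eigenvalue)` (the
#' ellipse with the same second central moments as the pixel set). A
#' degenerate (collinear) cluster gets its minor axis floored at 1 px.
#'
#' @param cluster A `pixel_cluster` from [cluster_doppler], or an m x 2
#'   matrix of `(row, col)` pixels.
#' @return An [ellipse_roi].
#' @export
fit_ellipse <- function(cluster) {
  px <- if (inherits(cluster, "pixel_cluster")) cluster$pixels else cluster
  if (nrow(px) < 1L) stop("empty cluster")
  ctr <- colMeans(px)
  dr <- px[, 1] - ctr[1]
  dc <- px[, 2] - ctr[2]
  # covariance in (col, row) = (x, y) order so orientation is from horizontal
  S <- matrix(c(mean(dc^2), mean(dc * dr),
                mean(dc * dr), mean(dr^2)), 2, 2)
  e <- eigen(S, symmetric = TRUE)
  len <- 4 * sqrt(pmax(e$values, 0))
  major <- max(len[1], 1)
  minor <- max(len[2], 1)
  v <- e$vectors[, 1]  # (x, y) components of the major axis
  orientation <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  ellipse_roi(center = ctr, major = major, minor = minor,
              orientation = orientation)
}

#' Eliminate candidate regions away from the initial needle axis
#'
#' Retains exactly the ellipses whose boundary or interior intersects the
#' infinite line of `axis`. The test is exact: the center-to-line distance is
#' compared with the ellipse's support radius along the line normal,
#' `sqrt((a*cos(g))^2 + (b*sin(g))^2)` with `a, b` the semi-axes and `g` the
#' angle between the line normal and the major axis; tangency counts as an
#' intersection.
#'
#' @param ellipses List of [ellipse_roi]s.
#' @param axis A [line_estimate].
#' @return The retained sublist (possibly empty).
#' @export
filter_rois <- function(ellipses, axis) {
  keep <- vapply(ellipses, function(e) {
    d <- point_line_distance(axis, e$center)
    th <- axis$theta * pi / 180
    n <- c(sin(th), cos(th))  # line normal as (d_row, d_col)
    ax <- ellipse_axes_dir(e)
    ca <- n[1] * ax$major[1] + n[2] * ax$major[2]
    cb <- n[1] * ax$minor[1] + n[2] * ax$minor[2]
    reff <- sqrt((e$major / 2 * ca)^2 + (e$minor / 2 * cb)^2)
    d <= reff + 1e-9
  }, logical(1))
  ellipses[keep]
}
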