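#' Entry point of the needle axis into the imaged field
#'
#' Intersects the axis with the image rectangle and returns the boundary
#' intersection with the smallest row (the shallowest point, where the
#' needle enters the field); ties are broken by the smallest column.
#'
#' @param axis A [line_estimate].
#' @param shape Image shape `c(nrow, ncol)`; defaults to the axis' own shape.
#' @return The entry point `c(row, col)` (possibly fractional).
#' @export
entry_point <- function(axis, shape = axis$shape) {
  p0 <- axis$point
  d <- axis$direction
  H <- shape[1]; W <- shape[2]
  cand <- list()
  add <- function(p) cand[[length(cand) + 1L]] <<- p
  tolr <- 1e-9
  if (abs(d[1]) > tolr) {  # crossings of row = 1 and row = H
    for (rr in c(1, H)) {
      t <- (rr - p0[1]) / d[1]
      p <- c(rr, p0[2] + t * d[2])
      if (p[2] >= 1 - tolr && p[2] <= W + tolr) add(p)
    }
  }
  if (abs(d[2]) > tolr) {  # crossings of col = 1 and col = W
    for (cc in c(1, W)) {
      t <- (cc - p0[2]) / d[2]
      p <- c(p0[1] + t * d[1], cc)
      if (p[1] >= 1 - tolr && p[1] <= H + tolr) add(p)
    }
  }
  if (length(cand) == 0L) stop("axis does not intersect the image")
  pts <- do.call(rbind, cand)
  pts[, 1] <- pmin(pmax(pts[, 1], 1), H)
  pts[, 2] <- pmin(pmax(pts[, 2], 1), W)
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  pts[1, ]
}

#' Window-averaged intensity profiles along the needle axis
#'
#' A rectangular window (length two needle diameters along the axis, width
#' one diameter across, centered on the axis) is slid one pixel at a time
#' from the entry point until the axis leaves the image. At each stop `l`
#' (0-based pixel index from the entry point) the mean power Doppler and
#' B-mode intensities inside the window are recorded. The window is sampled
#' on a fixed half-pixel sub-grid (4 samples per pixel area) with bilinear
#' interpolation; samples falling outside the image are excluded from the
#' mean.
#'
#' @param doppler,bmode Co-registered [image_grid]s of identical dimensions.
#' @param axis A [line_estimate] (the refined needle axis).
#' @param needle_diameter_px Needle diameter in pixels (`> 0`).
#' @return An object of class `axis_profile` with fields `l` (0-based
#'   indices), `positions` (L x 2 matrix of the sample pixels `(row, col)`),
#'   `ipd`, `ibm` (the two profiles), `entry`, `axis`, `window_length`
#'   (= 2 * diameter) and `window_width` (= diameter).
#' @export
compute_axis_profiles <- function(doppler, bmode, axis, needle_diameter_px) {
  stopifnot(inherits(doppler, "image_grid"), inherits(bmode, "image_grid"),
            needle_diameter_px > 0)
  if (!identical(dim(doppler$intensities), dim(bmode$intensities)))
    stop("images not co-registered: dimensions differ")
  shape <- dim(doppler$intensities)
  entry <- entry_point(axis, shape)
  d <- axis$direction
  n <- c(-d[2], d[1])  # unit normal across the axis

  # samples along the axis, unit steps from the entry point
  inside <- function(p) p[1] >= 1 && p[1] <= shape[1] && p[2] >= 1 && p[2] <= shape[2]
  L <- 0L
  repeat {
    p <- entry + L * d
    if (!inside(p)) break
    L <- L + 1L
  }
  if (L < 2L) stop("axis shorter than one window")
  l <- 0:(L - 1L)
  pos <- cbind(entry[1] + l * d[1], entry[2] + l * d[2])

  wl <- needle_diameter_px          # half-length along axis (length = 2 d)
  ww <- needle_diameter_px / 2      # half-width across (width = d)
  us <- seq(-wl, wl, by = 0.5)
  vs <- seq(-ww, ww, by = 0.5)
  offs <- expand.grid(u = us, v = vs)
  o_r <- offs$u * d[1] + offs$v * n[1]
  o_c <- offs$u * d[2] + offs$v * n[2]

  K <- length(o_r)
  rows <- rep(pos[, 1], each = K) + rep(o_r, times = L)
  cols <- rep(pos[, 2], each = K) + rep(o_c, times = L)
  grp <- rep(seq_len(L), each = K)
  vpd <- bilinear_sample(doppler$intensities, rows, cols)
  vbm <- bilinear_sample(bmode$intensities, rows, cols)
  ipd <- as.vector(tapply(vpd, grp, mean, na.rm = TRUE))
  ibm <- as.vector(tapply(vbm, grp, mean, na.rm = TRUE))

  structure(list(l = l, positions = pos, ipd = ipd, ibm = ibm,
                 entry = entry, axis = axis,
                 window_length = 2 * needle_diameter_px,
                 window_width = needle_diameter_px),
            class = "axis_profile")
}

#' Approximate (Doppler-based) tip location along the axis
#'
#' Thresholds the window-averaged Doppler profile at its own mean to get a
#' binary strong-response indicator, then finds the axis position that best
#' separates strong responses (before it) from weak ones (after it): the
#' score at `l` is the number of strong samples at positions `<= l` plus the
#' number of weak samples at positions `> l`, divided by the profile length.
#' The returned index maximizes this score; ties are broken toward the
#' largest (deepest) index.
#'
#' @param profile An [compute_axis_profiles] result, or a numeric vector
#'   taken directly as the Doppler profile.
#' @return The 0-based tip index, with attributes `spd` (the score
#'   function), `bpd` (the binary indicator) and `low_confidence` (`TRUE`
#'   when the indicator is constant, e.g. for a constant profile).
#' @export
doppler_tip_estimate <- function(profile) {
  ipd <- if (inherits(profile, "axis_profile")) profile$ipd else as.numeric(profile)
  L <- length(ipd)
  if (L < 2L) stop("profile too short")
  th <- mean(ipd)
  b <- as.integer(ipd >= th)
  spd <- spd_score(b)
  idx <- max(which(spd == max(spd)))  # deepest tie
  out <- idx - 1L
  attr(out, "spd") <- spd
  attr(out, "bpd") <- b
  attr(out, "threshold") <- th
  attr(out, "low_confidence") <- all(b == b[1])
  out
}

# separation score of a binary vector: s[i] = (#1s at <= i + #0s at > i) / L
spd_score <- function(b) {
  L <- length(b)
  cs <- cumsum(b)
  (cs + (L - seq_len(L)) - (cs[L] - cs)) / L
}

#' B-mode refinement of the tip location
#'
#' Computes the signed forward difference of the B-mode profile and, within
#' a search window of two needle diameters around the Doppler tip estimate,
#' returns the index with the most negative drop (the needle-to-background
#' transition). Ties are broken toward the largest index; when no negative
#' difference exists in the window the Doppler estimate is kept and the
#' result is flagged low-confidence.
#'
#' @param profile An `axis_profile`.
#' @param doppler_tip_index 0-based index from [doppler_tip_estimate].
#' @param needle_diameter_px Needle diameter in pixels.
#' @return An object of class `tip_result`: fields `doppler_tip_index`,
#'   `refined_tip_index` (both 0-based), `tip_pixel` (`c(row, col)`),
#'   `search_radius` (pixels) and `low_confidence`.
#' @export
bmode_tip_refine <- function(profile, doppler_tip_index, needle_diameter_px) {
  stopifnot(inherits(profile, "axis_profile"))
  ibm <- profile$ibm
  L <- length(ibm)
  tip0 <- as.integer(doppler_tip_index)
  if (tip0 < 0L || tip0 > L - 1L) stop("doppler_tip_index out of range")
  radius <- 2 * needle_diameter_px
  dd <- diff(ibm)              # dd[i] = drop between l = i-1 and l = i
  ld <- 0:(L - 2L)             # 0-based index of each difference
  in_win <- abs(ld - tip0) < radius
  low_confidence <- FALSE
  if (any(in_win) && any(dd[in_win] < 0)) {
    dw <- dd
    dw[!in_win] <- Inf
    refined <- max(ld[dw == min(dw)])
  } else {
    refined <- tip0
    low_confidence <- TRUE
  }
  structure(list(doppler_tip_index = tip0,
                 refined_tip_index = refined,
                 tip_pixel = profile$positions[refined + 1L, ],
                 search_radius = radius,
                 low_confidence = low_confidence),
            class = "tip_result")
}
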