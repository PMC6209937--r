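#' Configuration of the synthetic ultrasound phantom
#'
#' Defines a seeded synthetic power Doppler / B-mode image pair with known
#' needle geometry. Defaults emulate the imaging conditions the method is
#' designed for: a 90 x 90 mm field at 0.3 mm/px, an 18G needle (1.27 mm)
#' entering at the top edge, insertion angles between 0 and 65 degrees and
#' insertion depths of 40-80 mm. Needle brightness in the B-mode image
#' decreases linearly with the insertion angle (steep needles reflect the
#' beam away from the transducer); the Doppler image contains irregular
#' high-intensity blobs strung along the shaft, densest near the tip, plus
#' spurious off-needle blobs.
#'
#' @param image_height_px,image_width_px Image dimensions in pixels.
#' @param pixel_spacing mm per pixel (isotropic).
#' @param needle_diameter Needle diameter in mm.
#' @param insertion_angle Degrees from the horizontal image axis, in
#'   `[0, 65]`.
#' @param entry_point `c(row, col)` on the top image edge (row 1).
#' @param insertion_depth Depth along the needle in mm; the tip must stay
#'   inside the image.
#' @param needle_brightness Peak needle display amplitude on the `[0, 1]`
#'   scale, before angular attenuation.
#' @param visibility_falloff Fractional brightness loss per degree of
#'   insertion angle (linear falloff, floored at 10% of the peak).
#' @param speckle_scale Rayleigh scale of the multiplicative speckle
#'   envelope.
#' @param n_distractors Number of distractor linear reflectors (B-mode only),
#'   at least 15 degrees off the needle angle.
#' @param doppler_blob_count Number of Doppler blobs along the needle.
#' @param doppler_blob_jitter Lateral scatter of the blob centers in mm
#'   (offsets are clamped at this value).
#' @param n_spurious_blobs Off-needle Doppler blobs, placed at least 10
#'   needle diameters from the axis.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_height_px = 300L,
                           image_width_px = 300L,
                           pixel_spacing = 0.3,
                           needle_diameter = 1.27,
                           insertion_angle = 30,
                           entry_point = c(1, 20),
                           insertion_depth = 60,
                           needle_brightness = 0.8,
                           visibility_falloff = 0.009,
                           speckle_scale = 0.08,
                           n_distractors = 2L,
                           doppler_blob_count = 16L,
                           doppler_blob_jitter = 1.0,
                           n_spurious_blobs = 3L,
                           seed = 0L) {
  cfg <- structure(as.list(environment()), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (image_height_px <= 0 || image_width_px <= 0)
      stop("non-positive image dimensions")
    if (pixel_spacing <= 0) stop("pixel_spacing must be > 0")
    if (needle_diameter <= 0) stop("needle_diameter must be > 0")
    if (insertion_angle < 0 || insertion_angle > 65)
      stop("insertion_angle must be in [0, 65] degrees")
    if (insertion_depth <= 0) stop("insertion_depth must be > 0")
    if (abs(entry_point[1] - 1) > 1e-9)
      stop("entry_point must lie on the top image edge (row 1)")
    tip <- phantom_tip(cfg)
    if (tip[1] < 1 || tip[1] > image_height_px ||
        tip[2] < 1 || tip[2] > image_width_px)
      stop("needle tip outside image bounds; reduce depth or angle")
  })
  invisible(cfg)
}

phantom_tip <- function(cfg) {
  a <- cfg$insertion_angle * pi / 180
  len <- cfg$insertion_depth / cfg$pixel_spacing
  cfg$entry_point + len * c(sin(a), cos(a))
}

# Rayleigh deviates, scale sigma
rrayleigh <- function(n, sigma) sigma * sqrt(-2 * log(stats::runif(n)))

# unsigned distance of pixels (u along, v across, relative to entry) helper:
# returns list(u, v) for every pixel of an H x W grid given entry and angle
axis_coords <- function(H, W, entry, angle_deg) {
  a <- angle_deg * pi / 180
  d <- c(sin(a), cos(a))       # (row, col) along the needle
  n <- c(-d[2], d[1])          # across
  r <- matrix(seq_len(H), H, W) - entry[1]
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - entry[2]
  list(u = r * d[1] + c * d[2], v = r * n[1] + c * n[2])
}

# smooth-ended Gaussian-profile ridge of half-thickness ~ width/2
ridge_mask <- function(H, W, p0, angle_deg, len, width, amp) {
  ac <- axis_coords(H, W, p0, angle_deg)
  sigma <- width / (2 * sqrt(2 * log(2)))   # FWHM = width
  cross <- exp(-ac$v^2 / (2 * sigma^2))
  along <- pmin(pmax(ac$u + 0.5, 0), 1) * pmin(pmax(len - ac$u + 0.5, 0), 1)
  amp * cross * along
}

#' Generate a seeded synthetic power Doppler / B-mode phantom pair
#'
#' The B-mode image is log-compressed multiplicative Rayleigh speckle with
#' an added bright needle ridge (attenuated linearly with insertion angle)
#' and distractor linear reflectors. The power Doppler image is near-zero
#' background noise plus elliptical Gaussian blobs centered within
#' `doppler_blob_jitter` of the needle axis, spanning entry to tip with
#' spacing densest near the tip (the last blob sits one needle diameter
#' before the tip), plus spurious blobs at least 10 needle diameters off
#' axis. The same seed gives bit-identical output; the caller's RNG state is
#' left untouched.
#'
#' @param config A [phantom_config].
#' @return A list with elements `bmode` and `doppler` ([image_grid]s),
#'   `truth` ([needle_truth]) and `blobs` (data frame of the generated
#'   on-axis Doppler blobs: along-axis position `t`, lateral offset
#'   `offset`, center `row`/`col`, sigmas and amplitude).
#' @export
generate_phantom_pair <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  validate_phantom_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  H <- config$image_height_px
  W <- config$image_width_px
  sp <- config$pixel_spacing
  d_px <- config$needle_diameter / sp
  alpha <- config$insertion_angle
  entry <- config$entry_point
  len <- config$insertion_depth / sp
  tip <- phantom_tip(config)
  truth <- needle_truth(entry, tip, config$needle_diameter)

  ## ---- B-mode: speckle + needle ridge + distractors --------------------
  env <- rrayleigh(H * W, config$speckle_scale) / config$speckle_scale
  bg <- log1p(pmin(env, 5)) / log1p(5)
  bmode <- matrix(bg, H, W)

  amp <- config$needle_brightness * max(0.1, 1 - config$visibility_falloff * alpha)
  bmode <- bmode + ridge_mask(H, W, entry, alpha, len, d_px, amp)

  if (config$n_distractors > 0) {
    for (k in seq_len(config$n_distractors)) {
      repeat {
        dang <- stats::runif(1, 0, 180)
        if (angle_error(dang, alpha %% 180) >= 15) break
      }
      p0 <- c(stats::runif(1, 0.2 * H, 0.9 * H), stats::runif(1, 0.1 * W, 0.9 * W))
      dlen <- stats::runif(1, 30, 80)
      damp <- stats::runif(1, 0.25, 0.45)
      bmode <- bmode + ridge_mask(H, W, p0, dang, dlen, d_px, damp)
    }
  }
  bmode <- pmin(bmode, 1)

  ## ---- power Doppler: background noise + blobs -------------------------
  doppler <- matrix(rrayleigh(H * W, 0.02), H, W)

  nb <- config$doppler_blob_count
  jit_px <- config$doppler_blob_jitter / sp
  blobs <- NULL
  if (nb > 0) {
    # centers from entry to tip with spacing shrinking toward the tip; the
    # first support reaches the entry, the last blob sits one diameter
    # before the tip, and consecutive supports overlap by construction
    i <- seq_len(nb)
    t <- (len - d_px) * ((i - 0.4) / (nb - 0.4))^0.9
    if (nb > 2) {
      jit <- pmin(pmax(stats::rnorm(nb - 2, 0, 1.5), -3), 3)
      t[2:(nb - 1)] <- pmin(pmax(t[2:(nb - 1)] + jit, 0), len - d_px)
    }
    # Doppler blooming is biased to one side of the shaft within a given
    # acquisition; the common bias displaces the Doppler-only centerline
    # (why the initial axis is only approximate) while the per-blob scatter
    # stays small (the shaft is rigid). All centers stay within the jitter.
    bias <- stats::runif(1, 0.3, 0.8) * jit_px * sample(c(-1, 1), 1)
    off <- pmin(pmax(bias + stats::rnorm(nb, 0, jit_px / 4), -jit_px), jit_px)
    s_along <- d_px * stats::runif(nb, 1.3, 2.0)
    s_across <- d_px * stats::runif(nb, 1.2, 1.8)
    a_blob <- stats::runif(nb, 0.65, 1.0)
    # the excited tip is the vibration anti-node: its responses are at least
    # as strong and extended as the shaft's, terminating the trail crisply
    a_blob[nb] <- stats::runif(1, 0.85, 1.0)
    s_along[nb] <- d_px * stats::runif(1, 1.5, 2.0)
    aa <- alpha * pi / 180
    dvec <- c(sin(aa), cos(aa)); nvec <- c(-dvec[2], dvec[1])
    ctr_r <- entry[1] + t * dvec[1] + off * nvec[1]
    ctr_c <- entry[2] + t * dvec[2] + off * nvec[2]
    blobs <- data.frame(t = t, offset = off, row = ctr_r, col = ctr_c,
                        sigma_along = s_along, sigma_across = s_across,
                        amp = a_blob)
    ac <- axis_coords(H, W, entry, alpha)
    for (k in i) {
      doppler <- doppler + a_blob[k] *
        exp(-(ac$u - t[k])^2 / (2 * s_along[k]^2) -
             (ac$v - off[k])^2 / (2 * s_across[k]^2))
    }
  }

  if (config$n_spurious_blobs > 0) {
    axis_line <- line_from_angle_point(alpha %% 180, entry, c(H, W))
    min_d <- 10 * d_px
    for (k in seq_len(config$n_spurious_blobs)) {
      repeat {
        p <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
        if (point_line_distance(axis_line, p) >= min_d) break
      }
      s1 <- d_px * stats::runif(1, 0.8, 1.6)
      s2 <- d_px * stats::runif(1, 0.8, 1.6)
      a_s <- stats::runif(1, 0.3, 0.7)
      rr <- matrix(seq_len(H), H, W) - p[1]
      cc <- matrix(seq_len(W), H, W, byrow = TRUE) - p[2]
      doppler <- doppler + a_s * exp(-rr^2 / (2 * s1^2) - cc^2 / (2 * s2^2))
    }
  }
  doppler <- pmin(doppler, 1)

  list(bmode = image_grid(bmode, sp),
       doppler = image_grid(doppler, sp),
       truth = truth,
       blobs = blobs)
}

#' Write a phantom pair to disk
#'
#' Writes the two images (16-bit TIFF or PNG by extension) and the ground
#' truth as a JSON sidecar with fields `entry`, `tip`, `angle_deg`,
#' `diameter_mm` and `pixel_spacing_mm`.
#'
#' @param phantom Result of [generate_phantom_pair].
#' @param out_dir Output directory (created if needed).
#' @param basename File basename; default `"phantom"`.
#' @param format `"tiff"` (16-bit) or `"png"` (8-bit).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, out_dir, basename = "phantom",
                          format = c("tiff", "png")) {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "png"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    doppler = file.path(out_dir, paste0(basename, "_doppler.", ext)),
    bmode = file.path(out_dir, paste0(basename, "_bmode.", ext)),
    truth = file.path(out_dir, paste0(basename, "_truth.json")))
  write_image(phantom$doppler, paths[["doppler"]])
  write_image(phantom$bmode, paths[["bmode"]])
  tr <- phantom$truth
  jsonlite::write_json(
    list(entry = tr$entry, tip = tr$tip, angle_deg = tr$angle,
         diameter_mm = tr$diameter,
         pixel_spacing_mm = phantom$doppler$pixel_spacing),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a phantom ground-truth JSON sidecar
#'
#' @param path Path to a `*_truth.json` file written by [write_phantom].
#' @return A [needle_truth], with attribute `pixel_spacing`.
#' @export
read_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- needle_truth(j$entry, j$tip, j$diameter_mm)
  attr(tr, "pixel_spacing") <- j$pixel_spacing_mm
  tr
}
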