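#' Pipeline configuration
#'
#' Collects the fixed physical and algorithmic parameters of the
#' localization pipeline. Defaults are the method's shipped values: DBSCAN
#' radius 6 px and minimum cluster size 100 px, a 1-degree Radon angular
#' increment, a tip search window of two needle diameters and a 3 mm axis
#' failure threshold.
#'
#' @param pixel_spacing mm per pixel.
#' @param needle_diameter Needle diameter in mm.
#' @param dbscan_R,dbscan_M DBSCAN neighborhood radius (px) and minimum
#'   cluster size (pixels).
#' @param radon_angle_step Angular increment of the initial Radon scan,
#'   degrees.
#' @param tip_search_multiplier Tip search radius in needle diameters.
#' @param failure_threshold Axis-error failure threshold in mm.
#' @param verbose Log key stage scalars with `message()`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_spacing,
                            needle_diameter = 1.27,
                            dbscan_R = 6,
                            dbscan_M = 100,
                            radon_angle_step = 1,
                            tip_search_multiplier = 2,
                            failure_threshold = 3,
                            verbose = FALSE) {
  stopifnot(pixel_spacing > 0, needle_diameter > 0, dbscan_R > 0,
            dbscan_M >= 1, radon_angle_step > 0, tip_search_multiplier > 0,
            failure_threshold > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' The file may define any subset of the [pipeline_config] fields;
#' unspecified fields keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '", ext, "'"))
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

#' Run the full two-image needle localization pipeline
#'
#' Stage 1 analyzes the power Doppler image: intermeans thresholding,
#' DBSCAN clustering of the active responses, initial axis by Radon-
#' transform maximization over the cluster pixels, moment-equivalent
#' ellipses and elimination of ellipses missing the initial axis. Stage 2
#' enhances the B-mode image with a Gabor filter matched to the needle
#' diameter and the initial axis angle, masked to the retained regions, and
#' refines the axis offset by a fixed-angle Radon projection. Stage 3 slides
#' an oriented window along the refined axis, estimates the tip from the
#' Doppler profile's step-separation score and refines it at the strongest
#' B-mode intensity drop nearby.
#'
#' A localization that cannot proceed (e.g. no Doppler cluster survives)
#' returns a failed result with a reason rather than raising an error.
#'
#' @param doppler,bmode Co-registered [image_grid]s of identical dimensions.
#' @param config A [pipeline_config].
#' @return An object of class `localization_result`: `axis` and
#'   `initial_axis` ([line_estimate]s), `entry`, `tip` (`c(row, col)` px),
#'   `tip_result`, `flags` (character vector of low-confidence markers),
#'   `failed_hard` / `failure_reason`, and `diagnostics` (threshold, cluster
#'   and ROI counts, tip indices).
#' @export
run_pipeline <- function(doppler, bmode, config) {
  stopifnot(inherits(doppler, "image_grid"), inherits(bmode, "image_grid"),
            inherits(config, "pipeline_config"))
  if (!identical(dim(doppler$intensities), dim(bmode$intensities)))
    stop("images not co-registered: dimensions differ")
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  fail <- function(reason, diag) {
    say("localization failed: %s", reason)
    structure(list(axis = NULL, initial_axis = NULL, entry = NULL,
                   tip = NULL, tip_result = NULL, flags = character(),
                   failed_hard = TRUE, failure_reason = reason,
                   diagnostics = diag),
              class = "localization_result")
  }
  d_px <- config$needle_diameter / config$pixel_spacing
  diag <- list()

  ## stage 1: power Doppler analysis
  pre <- preprocess_doppler(doppler)
  diag$threshold <- attr(pre, "threshold")
  say("intermeans threshold: %.4g", diag$threshold)
  clusters <- cluster_doppler(pre, R = config$dbscan_R, M = config$dbscan_M)
  diag$n_clusters <- length(clusters)
  say("DBSCAN clusters: %d", diag$n_clusters)
  if (length(clusters) == 0L) return(fail("no Doppler evidence", diag))
  axis0 <- initial_axis(clusters, pre, angle_step = config$radon_angle_step)
  diag$initial_theta <- axis0$theta
  diag$initial_rho <- axis0$rho
  say("initial axis: theta %.1f deg, rho %.1f px", axis0$theta, axis0$rho)
  ellipses <- lapply(clusters, fit_ellipse)
  rois <- filter_rois(ellipses, axis0)
  diag$n_rois <- length(rois)
  say("ROIs retained: %d of %d", length(rois), length(ellipses))
  if (length(rois) == 0L) return(fail("no candidate regions", diag))

  ## stage 2: B-mode refinement
  gp <- gabor_params(theta = axis0$angle, wavelength = d_px)
  filtered <- masked_gabor_filter(bmode, rois, gp)
  if (all(filtered$intensities == 0)) return(fail("refinement impossible", diag))
  axis1 <- refine_axis(filtered, axis0$theta)
  diag$refined_rho <- axis1$rho
  say("refined axis: rho %.1f px", axis1$rho)

  ## stage 3: tip localization
  prof <- compute_axis_profiles(doppler, bmode, axis1, d_px)
  tip_pd <- doppler_tip_estimate(prof)
  # search radius = tip_search_multiplier * diameter (2 diameters by default)
  tr <- bmode_tip_refine(prof, tip_pd, d_px * config$tip_search_multiplier / 2)
  diag$doppler_tip_index <- tr$doppler_tip_index
  diag$refined_tip_index <- tr$refined_tip_index
  say("tip index: doppler %d, refined %d",
      tr$doppler_tip_index, tr$refined_tip_index)
  flags <- character()
  if (isTRUE(attr(tip_pd, "low_confidence"))) flags <- c(flags, "doppler_tip_low_confidence")
  if (tr$low_confidence) flags <- c(flags, "bmode_tip_low_confidence")

  structure(list(axis = axis1, initial_axis = axis0,
                 entry = prof$entry, tip = tr$tip_pixel,
                 tip_result = tr, profile = prof, flags = flags,
                 failed_hard = FALSE, failure_reason = NULL,
                 diagnostics = diag),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  if (isTRUE(x$failed_hard)) {
    cat("<localization_result> FAILED:", x$failure_reason, "\n")
  } else {
    cat(sprintf(
      "<localization_result> axis %.1f deg, entry (%.1f, %.1f), tip (%.1f, %.1f)%s\n",
      x$axis$angle, x$entry[1], x$entry[2], x$tip[1], x$tip[2],
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  }
  invisible(x)
}

#' Write / read a localization result as JSON
#'
#' The JSON round-trips the fields needed for scoring: the refined axis
#' (`theta_deg`, `rho_px`, shape, angle), entry and tip pixels, flags and
#' failure status.
#'
#' @param result A `localization_result`.
#' @param path Output JSON path.
#' @return `path` invisibly (write); a `localization_result` (read).
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "localization_result"))
  obj <- if (isTRUE(result$failed_hard)) {
    list(failed = TRUE, reason = result$failure_reason)
  } else {
    list(failed = FALSE,
         theta_deg = result$axis$theta, rho_px = result$axis$rho,
         shape = result$axis$shape, angle_deg = result$axis$angle,
         entry = result$entry, tip = unname(result$tip),
         flags = result$flags)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (isTRUE(j$failed)) {
    return(structure(list(axis = NULL, entry = NULL, tip = NULL,
                          flags = character(), failed_hard = TRUE,
                          failure_reason = j$reason, diagnostics = list()),
                     class = "localization_result"))
  }
  structure(list(axis = line_estimate(j$theta_deg, j$rho_px, j$shape),
                 entry = j$entry, tip = j$tip,
                 flags = as.character(j$flags %||% character()),
                 failed_hard = FALSE, failure_reason = NULL,
                 diagnostics = list()),
            class = "localization_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
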