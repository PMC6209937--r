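#' Ground-truth needle geometry
#'
#' @param entry,tip Points `c(row, col)` in pixels.
#' @param diameter Needle diameter in mm.
#' @return An object of class `needle_truth` with the angle (degrees from
#'   horizontal, in `[0, 180)`) recomputed from entry and tip.
#' @export
needle_truth <- function(entry, tip, diameter) {
  stopifnot(length(entry) == 2L, length(tip) == 2L, diameter > 0)
  d <- c(tip[1] - entry[1], tip[2] - entry[2])
  if (sqrt(sum(d^2)) < 1e-12) stop("entry and tip coincide")
  angle <- (atan2(d[1], d[2]) * 180 / pi) %% 180
  structure(list(entry = as.numeric(entry), tip = as.numeric(tip),
                 angle = angle, diameter = diameter),
            class = "needle_truth")
}

#' Needle axis error
#'
#' The ground-truth entry and tip points are orthogonally projected onto the
#' estimated axis; the axis error is the larger of the two point-to-
#' projection (i.e. point-to-line) distances, converted to mm. It is by
#' construction invariant to which endpoint is called entry and which tip.
#'
#' @param truth A [needle_truth].
#' @param axis A [line_estimate].
#' @param pixel_spacing mm per pixel.
#' @return Axis error in mm.
#' @export
axis_error <- function(truth, axis, pixel_spacing) {
  d <- point_line_distance(axis, rbind(truth$entry, truth$tip))
  max(d) * pixel_spacing
}

#' Needle angle error
#'
#' Undirected difference between the estimated and true line angles; lines
#' are 180-degree periodic, so the error is in `[0, 90]`.
#'
#' @param truth A [needle_truth] (or a numeric angle in degrees).
#' @param axis A [line_estimate] (or a numeric angle in degrees).
#' @return Angle error in degrees.
#' @export
angle_error <- function(truth, axis) {
  a1 <- if (inherits(truth, "needle_truth")) truth$angle else as.numeric(truth)
  a2 <- if (inherits(axis, "line_estimate")) axis$angle else as.numeric(axis)
  d <- abs(a1 - a2) %% 180
  min(d, 180 - d)
}

#' Needle tip error
#'
#' Euclidean distance between the estimated and true tip positions, in mm.
#'
#' @param truth A [needle_truth].
#' @param result A `localization_result` (or a point `c(row, col)`).
#' @param pixel_spacing mm per pixel.
#' @return Tip error in mm.
#' @export
tip_error <- function(truth, result, pixel_spacing) {
  tip <- if (inherits(result, "localization_result")) result$tip else as.numeric(result)
  sqrt(sum((tip - truth$tip)^2)) * pixel_spacing
}

#' Score a batch of localizations against ground truth
#'
#' Computes, per insertion-angle bin (shallow `[0, 20]`, moderate `(20, 40]`,
#' steep `(40, 65]` degrees, plus the full range), the failure rate over all
#' trials (a trial fails when the axis error is `>= failure_threshold` mm or
#' the pipeline produced no axis) and the mean and standard deviation of the
#' angle, axis and tip errors over the successful trials only. Bins without
#' trials are absent from the output.
#'
#' @param results List of `localization_result`s.
#' @param truths List of matching [needle_truth]s.
#' @param pixel_spacing mm per pixel.
#' @param angle_bins Data frame with columns `bin`, `lo`, `hi`; a trial with
#'   true angle `a` falls in a bin when `lo < a <= hi` (the first bin is
#'   closed on the left as well).
#' @param failure_threshold Axis-error failure threshold in mm (default 3).
#' @return A data frame with one row per non-empty bin: `bin`, `n`,
#'   `failure_rate_pct`, `n_success`, and `angle_mean`, `angle_sd`,
#'   `axis_mean`, `axis_sd`, `tip_mean`, `tip_sd` over successes (NA when
#'   there are no successes or a single one, for the sds).
#' @export
batch_score <- function(results, truths, pixel_spacing,
                        angle_bins = default_angle_bins(),
                        failure_threshold = 3) {
  stopifnot(length(results) == length(truths))
  n <- length(results)
  ang <- vapply(truths, function(t) t$angle, numeric(1))
  err <- data.frame(angle = rep(NA_real_, n), axis = NA_real_, tip = NA_real_)
  failed <- logical(n)
  for (i in seq_len(n)) {
    r <- results[[i]]
    if (is.null(r$axis) || isTRUE(r$failed_hard)) {
      failed[i] <- TRUE
      next
    }
    err$angle[i] <- angle_error(truths[[i]], r$axis)
    err$axis[i] <- axis_error(truths[[i]], r$axis, pixel_spacing)
    err$tip[i] <- tip_error(truths[[i]], r, pixel_spacing)
    failed[i] <- err$axis[i] >= failure_threshold
  }
  rows <- lapply(seq_len(nrow(angle_bins)), function(k) {
    lo <- angle_bins$lo[k]; hi <- angle_bins$hi[k]
    # edge membership with a small tolerance so angles recomputed from
    # entry/tip geometry (exact up to floating point) land in their bin
    tol <- 1e-9
    sel <- if (k == 1L || lo == min(angle_bins$lo)) ang >= lo - tol & ang <= hi + tol
           else ang > lo + tol & ang <= hi + tol
    if (!any(sel)) return(NULL)
    ok <- sel & !failed
    data.frame(bin = angle_bins$bin[k], n = sum(sel),
               failure_rate_pct = 100 * sum(failed[sel]) / sum(sel),
               n_success = sum(ok),
               angle_mean = mean(err$angle[ok]), angle_sd = stats::sd(err$angle[ok]),
               axis_mean = mean(err$axis[ok]), axis_sd = stats::sd(err$axis[ok]),
               tip_mean = mean(err$tip[ok]), tip_sd = stats::sd(err$tip[ok]))
  })
  do.call(rbind, rows)
}

#' Default insertion-angle bins
#'
#' Shallow `[0, 20]`, moderate `(20, 40]`, steep `(40, 65]` and the full
#' range `[0, 65]` degrees; boundary angles belong to the shallower bin.
#'
#' @return A data frame with columns `bin`, `lo`, `hi`.
#' @export
default_angle_bins <- function() {
  data.frame(bin = c("shallow", "moderate", "steep", "all"),
             lo = c(0, 20, 40, 0),
             hi = c(20, 40, 65, 65),
             stringsAsFactors = FALSE)
}
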