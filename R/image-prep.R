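# Session-frame correction, Rhodamine B calibration, caliper volumes and
# disease-stage annotation.

#' Subtract dark noise and pre-injection background from a probe frame
#'
#' Each 60-min probe frame is corrected by the scalar mean of the laser-off
#' dark-noise frame and the scalar mean of the pre-injection background
#' frame. Because the pre-injection frame itself contains dark current, its
#' dark-subtracted mean is used, so dark noise is removed exactly once:
#' \code{corrected = raw - mean(dark) - (mean(preinjection) - mean(dark))}.
#' Negative results are clamped to zero (fluorescence is non-negative and
#' downstream cutoffs assume it).
#'
#' @param bundle a \linkS4class{RawImageBundle}.
#' @return numeric matrix of corrected fluorescence, same shape as the raw
#'   frame, all values >= 0.
#' @examples
#' b <- new("RawImageBundle", raw = matrix(10, 2, 2), dark = matrix(2, 2, 2),
#'          preinjection = matrix(5, 2, 2), standardReading = 100,
#'          probe = "TMRE60", mouse = "m1", day = 0L, arm = "untreated")
#' subtractBackground(b)  # 10 - 2 - (5 - 2) = 5 everywhere
#' @export
subtractBackground <- function(bundle) {
  stopifnot(is(bundle, "RawImageBundle"))
  validObject(bundle)
  darkMean <- mean(bundle@dark)
  preMean <- mean(bundle@preinjection) - darkMean
  corrected <- bundle@raw - darkMean - preMean
  corrected[corrected < 0] <- 0
  corrected
}

#' Calibrate a corrected frame against the session Rhodamine B standard
#'
#' Daily light-source variation is removed by ratio calibration: the
#' corrected frame is multiplied by \code{referenceStandard /
#' sessionStandard}, mapping every session onto the scale of a fixed
#' reference standard reading (by convention the first session's).
#'
#' @param corrected numeric matrix from \code{\link{subtractBackground}}.
#' @param sessionStandard positive scalar, this session's Rhodamine B mean.
#' @param referenceStandard positive scalar, the reference standard reading.
#' @param probe,mouse,day,arm,stage metadata carried into the result.
#' @return a \linkS4class{CalibratedImage}.
#' @export
calibrateImage <- function(corrected, sessionStandard, referenceStandard,
                           probe, mouse = "unknown", day = 0L,
                           arm = "untreated", stage = NA_character_) {
  .assertFiniteMatrix(corrected, "corrected")
  if (!is.finite(sessionStandard) || sessionStandard <= 0)
    stop("sessionStandard must be positive")
  if (!is.finite(referenceStandard) || referenceStandard <= 0)
    stop("referenceStandard must be positive")
  vals <- corrected * (referenceStandard / sessionStandard)
  vals[vals < 0] <- 0
  new("CalibratedImage", values = vals, probe = probe, mouse = mouse,
      day = as.integer(day), arm = arm, stage = stage)
}

#' Correct and calibrate a raw bundle in one step
#'
#' Convenience wrapper: \code{\link{subtractBackground}} followed by
#' \code{\link{calibrateImage}} using the bundle's own session standard.
#'
#' @param bundle a \linkS4class{RawImageBundle}.
#' @param referenceStandard positive scalar reference standard (AU).
#' @param stage optional disease-stage annotation.
#' @return a \linkS4class{CalibratedImage}.
#' @export
preprocessBundle <- function(bundle, referenceStandard,
                             stage = NA_character_) {
  corrected <- subtractBackground(bundle)
  calibrateImage(corrected, bundle@standardReading, referenceStandard,
                 probe = bundle@probe, mouse = bundle@mouse,
                 day = bundle@day, arm = bundle@arm, stage = stage)
}

#' Tumor volume from caliper diameters
#'
#' \code{volume = short^2 x (long / 2)} in mm^3. If the recorded short
#' diameter exceeds the long diameter (hand-recorded CSVs occasionally swap
#' them), the inputs are swapped with a warning rather than rejected.
#'
#' @param short_mm,long_mm non-negative caliper diameters (mm); vectorized.
#' @return volume(s) in mm^3.
#' @examples
#' tumorVolume(2, 4)  # 8
#' @export
tumorVolume <- function(short_mm, long_mm) {
  if (any(!is.finite(short_mm)) || any(!is.finite(long_mm)) ||
      any(short_mm < 0) || any(long_mm < 0))
    stop("caliper diameters must be finite and non-negative")
  swap <- short_mm > long_mm
  if (any(swap)) {
    warning("short diameter exceeds long diameter for ",
            sum(swap), " measurement(s); swapping")
    tmp <- short_mm[swap]
    short_mm[swap] <- long_mm[swap]
    long_mm[swap] <- tmp
  }
  short_mm^2 * (long_mm / 2)
}

#' Annotate a tumor trajectory with disease stages
#'
#' Treated-arm labels follow the window-chamber stage definitions:
#' measurements at or before treatment start are \code{primary}; during
#' active treatment, \code{early_regression}; after withdrawal while volume
#' is still declining, \code{late_regression}; at/near the post-treatment
#' minimum with no active growth (relative change between consecutive
#' measurements below \code{plateauTol}), \code{residual}; sustained
#' regrowth above the minimum thereafter, \code{recurrence}. Untreated
#' trajectories are \code{untreated_growth} throughout.
#'
#' @param trajectory a \linkS4class{TumorTrajectory}.
#' @param treatmentStart,treatmentEnd treatment window (days); D0 start and
#'   a 10-day every-other-day regimen by default.
#' @param plateauTol relative-change tolerance defining "no active growth"
#'   between consecutive measurements (default 0.05).
#' @return the trajectory with its \code{stages} slot filled.
#' @export
classifyStages <- function(trajectory, treatmentStart = 0,
                           treatmentEnd = 10, plateauTol = 0.05) {
  stopifnot(is(trajectory, "TumorTrajectory"))
  days <- trajectory@days
  v <- trajectory@volumes
  n <- length(days)
  if (n == 0) stop("empty trajectory")
  if (trajectory@arm == "untreated") {
    trajectory@stages <- rep("untreated_growth", n)
    validObject(trajectory)
    return(trajectory)
  }
  if (n < 2)
    stop("slope-based stage labels need at least 2 time points")
  if (treatmentEnd < treatmentStart || treatmentStart > max(days))
    stop("treatment window must overlap the measured day range")
  stages <- character(n)
  stages[days <= treatmentStart] <- "primary"
  stages[days > treatmentStart & days <= treatmentEnd] <- "early_regression"
  post <- which(days > treatmentEnd)
  if (length(post)) {
    imin <- post[which.min(v[post])]
    for (i in post) {
      rel <- if (i == 1) 0 else (v[i] - v[i - 1]) / max(v[i - 1], .Machine$double.eps)
      if (i > imin && v[i] > v[imin] * (1 + plateauTol)) {
        stages[i] <- "recurrence"
      } else if (abs(rel) < plateauTol || i == imin) {
        stages[i] <- "residual"
      } else if (rel < 0) {
        stages[i] <- "late_regression"
      } else {
        stages[i] <- "residual"
      }
    }
  }
  trajectory@stages <- stages
  validObject(trajectory)
  trajectory
}
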