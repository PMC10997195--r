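#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assays<- colData assayNames
NULL

#' RawImageBundle: one probe acquisition for one mouse-day session
#'
#' Holds the three frames acquired per probe and session — the 60-min probe
#' frame, the laser-off dark-noise frame and the pre-injection background
#' frame — together with the session's Rhodamine B standard reading and the
#' animal metadata needed downstream.
#'
#' @slot raw numeric matrix, probe fluorescence at 60 min (AU).
#' @slot dark numeric matrix, laser-off dark-noise frame (AU).
#' @slot preinjection numeric matrix, pre-injection background frame (AU).
#' @slot standardReading positive scalar, session Rhodamine B mean (AU).
#' @slot probe one of \code{"TMRE60"}, \code{"NBDG60"}, \code{"BODIPY60"}.
#' @slot mouse,arm character identifiers.
#' @slot day integer imaging day.
#' @export
setClass("RawImageBundle",
  representation(raw = "matrix", dark = "matrix", preinjection = "matrix",
                 standardReading = "numeric", probe = "character",
                 mouse = "character", day = "integer", arm = "character"))

setValidity("RawImageBundle", function(object) {
  msgs <- character()
  dims <- list(dim(object@raw), dim(object@dark), dim(object@preinjection))
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), TRUE)))
    msgs <- c(msgs, "raw, dark and preinjection frames must share one shape")
  if (any(!is.finite(object@raw)) || any(!is.finite(object@dark)) ||
      any(!is.finite(object@preinjection)))
    msgs <- c(msgs, "frames must be finite")
  if (length(object@standardReading) != 1 || !is.finite(object@standardReading) ||
      object@standardReading <= 0)
    msgs <- c(msgs, "standardReading must be a single positive number")
  if (length(object@probe) != 1 || !object@probe %in% .PROBES)
    msgs <- c(msgs, paste("probe must be one of", paste(.PROBES, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' CalibratedImage: background-corrected, standard-calibrated probe frame
#'
#' The unit of all pixel-level analysis: a single probe frame after dark
#' noise and pre-injection subtraction and Rhodamine B calibration, clamped
#' to non-negative values, with its provenance.
#'
#' @slot values numeric matrix of calibrated fluorescence (AU, >= 0).
#' @slot probe,mouse,arm,stage character annotations (stage may be \code{NA}).
#' @slot day integer imaging day.
#' @export
setClass("CalibratedImage",
  representation(values = "matrix", probe = "character", mouse = "character",
                 day = "integer", arm = "character", stage = "character"))

setValidity("CalibratedImage", function(object) {
  msgs <- character()
  if (any(!is.finite(object@values)))
    msgs <- c(msgs, "values must be finite")
  else if (min(object@values) < 0)
    msgs <- c(msgs, "values must be non-negative (clamped)")
  if (length(object@probe) != 1 || !object@probe %in% .PROBES)
    msgs <- c(msgs, "unknown probe")
  if (length(msgs)) msgs else TRUE
})

#' PixelDistribution: pooled pixel values with per-mouse blocks
#'
#' The unit of distributional comparison: calibrated pixel values pooled
#' across images ("all pixels, all mice"), each tagged with the mouse it
#' came from. The mouse id is the block unit for permutation tests, since
#' pixels within one animal are statistically dependent.
#'
#' @slot values numeric vector of pixel fluorescence (AU, >= 0).
#' @slot blocks character vector of mouse ids, one per value.
#' @slot probe character probe label.
#' @slot label character free-form group/time-point label.
#' @export
setClass("PixelDistribution",
  representation(values = "numeric", blocks = "character",
                 probe = "character", label = "character"))

setValidity("PixelDistribution", function(object) {
  msgs <- character()
  if (length(object@values) == 0)
    msgs <- c(msgs, "empty distribution")
  if (length(object@blocks) != length(object@values))
    msgs <- c(msgs, "blocks must tag every value")
  if (any(!is.finite(object@values)) || (length(object@values) && min(object@values) < 0))
    msgs <- c(msgs, "values must be finite and non-negative")
  if (length(msgs)) msgs else TRUE
})

#' KSTestResult: blocked-permutation Kolmogorov-Smirnov test result
#'
#' @slot dObs observed KS statistic in [0, 1].
#' @slot pPerm permutation p-value.
#' @slot nPerm number of permutations (enumeration count when exact).
#' @slot scheme \code{"exchange"} (unpaired) or \code{"flip"} (paired).
#' @slot exact logical; TRUE when the null was enumerated exhaustively.
#' @slot seed integer seed used for Monte-Carlo draws (NA when exact).
#' @export
setClass("KSTestResult",
  representation(dObs = "numeric", pPerm = "numeric", nPerm = "integer",
                 scheme = "character", exact = "logical", seed = "integer"))

setValidity("KSTestResult", function(object) {
  msgs <- character()
  if (object@dObs < 0 || object@dObs > 1) msgs <- c(msgs, "dObs outside [0,1]")
  if (object@pPerm <= 0 || object@pPerm > 1) msgs <- c(msgs, "pPerm outside (0,1]")
  if (!object@scheme %in% c("exchange", "flip")) msgs <- c(msgs, "unknown scheme")
  if (length(msgs)) msgs else TRUE
})

#' CutoffPair: high/low segmentation cutoffs for the two cluster probes
#'
#' @slot cutoffNBDG,cutoffTMRE non-negative cutoffs (AU).
#' @slot method \code{"mean"} or \code{"median"} of the pooled pixel values.
#' @slot poolingScope descriptor of the pixel pool used (audit trail).
#' @export
setClass("CutoffPair",
  representation(cutoffNBDG = "numeric", cutoffTMRE = "numeric",
                 method = "character", poolingScope = "character"))

setValidity("CutoffPair", function(object) {
  if (!is.finite(object@cutoffNBDG) || !is.finite(object@cutoffTMRE) ||
      object@cutoffNBDG < 0 || object@cutoffTMRE < 0)
    return("cutoffs must be finite and non-negative")
  if (!object@method %in% c("mean", "median")) return("unknown cutoff method")
  TRUE
})

#' ClusterMask: per-pixel metabolic class labels
#'
#' Pixel-wise 2x2 classification of co-registered 2-NBDG and TMRE frames.
#' Labels are \code{"LL"}, \code{"HL"}, \code{"LH"}, \code{"HH"}; the first
#' letter is the 2-NBDG level, the second the TMRE level.
#'
#' @slot labels character matrix of class labels.
#' @slot mouse,day,cutoffs provenance of the assignment.
#' @export
setClass("ClusterMask",
  representation(labels = "matrix", mouse = "character", day = "integer",
                 cutoffs = "CutoffPair"))

setValidity("ClusterMask", function(object) {
  if (!is.character(object@labels)) return("labels must be a character matrix")
  if (!all(object@labels %in% .CLASSES))
    return("labels must all be in LL/HL/LH/HH")
  TRUE
})

#' TumorTrajectory: caliper-derived tumor volumes over time
#'
#' @slot days strictly increasing integer measurement days (D0 = treatment
#'   start for treated arms).
#' @slot volumes non-negative volumes (mm^3), computed as
#'   short^2 x (long / 2) from caliper diameters.
#' @slot arm one of \code{"untreated"}, \code{"treated_sensitive"},
#'   \code{"treated_resistant"}.
#' @slot mouse character id.
#' @slot stages per-day disease-stage labels (empty until classified).
#' @export
setClass("TumorTrajectory",
  representation(days = "integer", volumes = "numeric", arm = "character",
                 mouse = "character", stages = "character"))

setValidity("TumorTrajectory", function(object) {
  msgs <- character()
  if (length(object@days) != length(object@volumes))
    msgs <- c(msgs, "days and volumes lengths differ")
  if (length(object@days) > 1 && any(diff(object@days) <= 0))
    msgs <- c(msgs, "days must be strictly increasing")
  if (any(!is.finite(object@volumes)) ||
      (length(object@volumes) && min(object@volumes) < 0))
    msgs <- c(msgs, "volumes must be finite and non-negative")
  if (length(object@stages) &&
      (length(object@stages) != length(object@days) ||
       !all(object@stages %in% .STAGES)))
    msgs <- c(msgs, "stages must label every day with a known stage")
  if (length(msgs)) msgs else TRUE
})

#' MetaboliteSet: samples-by-metabolites abundances with processing state
#'
#' A \linkS4class{SummarizedExperiment} with metabolites as rows and samples
#' as columns. \code{colData} carries \code{sample_group} and \code{batch};
#' each normalization stage adds a named assay (\code{abundance} ->
#' \code{sumnorm} -> \code{log} -> \code{pareto}, optionally
#' \code{batchcentered}) and appends to the recorded stage flags, so the
#' processing order is enforced and auditable.
#'
#' @export
setClass("MetaboliteSet", contains = "SummarizedExperiment")

setValidity("MetaboliteSet", function(object) {
  msgs <- character()
  if (!"abundance" %in% assayNames(object))
    msgs <- c(msgs, "assay 'abundance' is required")
  else {
    a <- assay(object, "abundance")
    if (any(!is.finite(a)) || any(a <= 0))
      msgs <- c(msgs, "raw abundances must be finite and positive (no filtering, no missing values)")
  }
  cd <- colData(object)
  if (!all(c("sample_group", "batch") %in% colnames(cd)))
    msgs <- c(msgs, "colData must carry sample_group and batch")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MetaboliteSet from a samples x metabolites table
#'
#' @param abundances numeric matrix or data.frame, rows = samples,
#'   columns = metabolites, all values positive.
#' @param group character/factor of group labels, one per sample.
#' @param batch optional batch labels, one per sample (defaults to one batch).
#' @return a \linkS4class{MetaboliteSet} in the \code{raw} stage.
#' @examples
#' m <- MetaboliteSet(matrix(1:6 + 0.5, 2, 3,
#'                           dimnames = list(c("s1", "s2"), c("a", "b", "c"))),
#'                    group = c("primary", "regressing"))
#' processingStages(m)
#' @export
MetaboliteSet <- function(abundances, group, batch = NULL) {
  a <- as.matrix(abundances)
  if (is.null(rownames(a))) rownames(a) <- paste0("s", seq_len(nrow(a)))
  if (is.null(colnames(a))) colnames(a) <- paste0("m", seq_len(ncol(a)))
  if (length(group) != nrow(a))
    stop("group must label every sample (row)")
  if (is.null(batch)) batch <- rep("b1", nrow(a))
  se <- SummarizedExperiment(
    assays = list(abundance = t(a)),
    colData = DataFrame(sample_group = as.character(group),
                        batch = as.character(batch),
                        row.names = rownames(a)))
  obj <- new("MetaboliteSet", se)
  metadata(obj)$stages <- "raw"
  validObject(obj)
  obj
}
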