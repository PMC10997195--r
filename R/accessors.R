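# Accessors and show() methods for the core containers.

#' @rdname CalibratedImage-class
#' @param object,x a package object.
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))

#' @rdname CalibratedImage-class
#' @export
setMethod("imageValues", "CalibratedImage", function(x) x@values)

#' @rdname PixelDistribution-class
#' @export
setGeneric("pixelValues", function(x) standardGeneric("pixelValues"))

#' @rdname PixelDistribution-class
#' @export
setMethod("pixelValues", "PixelDistribution", function(x) x@values)

#' @rdname PixelDistribution-class
#' @export
setGeneric("pixelBlocks", function(x) standardGeneric("pixelBlocks"))

#' @rdname PixelDistribution-class
#' @export
setMethod("pixelBlocks", "PixelDistribution", function(x) x@blocks)

#' @rdname ClusterMask-class
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @rdname ClusterMask-class
#' @export
setMethod("maskLabels", "ClusterMask", function(x) x@labels)

#' @rdname TumorTrajectory-class
#' @export
setGeneric("trajectoryStages", function(x) standardGeneric("trajectoryStages"))

#' @rdname TumorTrajectory-class
#' @export
setMethod("trajectoryStages", "TumorTrajectory", function(x) x@stages)

#' @rdname TumorTrajectory-class
#' @export
setGeneric("trajectoryVolumes", function(x) standardGeneric("trajectoryVolumes"))

#' @rdname TumorTrajectory-class
#' @export
setMethod("trajectoryVolumes", "TumorTrajectory", function(x) x@volumes)

#' @rdname TumorTrajectory-class
#' @export
setGeneric("trajectoryDays", function(x) standardGeneric("trajectoryDays"))

#' @rdname TumorTrajectory-class
#' @export
setMethod("trajectoryDays", "TumorTrajectory", function(x) x@days)

#' Processing stages applied to a MetaboliteSet
#'
#' @param x a \linkS4class{MetaboliteSet}.
#' @return character vector of applied stages, starting at \code{"raw"}.
#' @export
processingStages <- function(x) {
  stopifnot(is(x, "MetaboliteSet"))
  metadata(x)$stages
}

#' @rdname RawImageBundle-class
#' @export
setMethod("show", "RawImageBundle", function(object) {
  cat("RawImageBundle:", object@probe, "| mouse", object@mouse,
      "| day", object@day, "| arm", object@arm, "\n")
  cat("  frames:", paste(dim(object@raw), collapse = " x "),
      "| Rhodamine B standard:", signif(object@standardReading, 5), "AU\n")
})

#' @rdname CalibratedImage-class
#' @export
setMethod("show", "CalibratedImage", function(object) {
  cat("CalibratedImage:", object@probe, "| mouse", object@mouse,
      "| day", object@day, "| arm", object@arm,
      if (!is.na(object@stage)) paste("| stage", object@stage) else "", "\n")
  cat("  ", paste(dim(object@values), collapse = " x "),
      "pixels, range [", signif(min(object@values), 4), ",",
      signif(max(object@values), 4), "] AU\n")
})

#' @rdname PixelDistribution-class
#' @export
setMethod("show", "PixelDistribution", function(object) {
  cat("PixelDistribution:", object@probe, "|", object@label, "\n")
  cat("  ", length(object@values), "pixels from",
      length(unique(object@blocks)), "mouse block(s); mean",
      signif(mean(object@values), 5), "AU\n")
})

#' @rdname KSTestResult-class
#' @export
setMethod("show", "KSTestResult", function(object) {
  cat("Blocked-permutation KS test (", object@scheme, " scheme, ",
      if (object@exact) "exact, " else "Monte-Carlo, ",
      object@nPerm, " permutations)\n", sep = "")
  cat("  D =", signif(object@dObs, 5), " p =", signif(object@pPerm, 5), "\n")
})

#' @rdname CutoffPair-class
#' @export
setMethod("show", "CutoffPair", function(object) {
  cat("CutoffPair (", object@method, "): 2-NBDG ",
      signif(object@cutoffNBDG, 5), " AU, TMRE ",
      signif(object@cutoffTMRE, 5), " AU [", object@poolingScope, "]\n",
      sep = "")
})

#' @rdname ClusterMask-class
#' @export
setMethod("show", "ClusterMask", function(object) {
  tab <- table(factor(object@labels, levels = .CLASSES))
  cat("ClusterMask: mouse", object@mouse, "| day", object@day, "|",
      paste(dim(object@labels), collapse = " x "), "pixels\n")
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = "  "), "\n")
})

#' @rdname TumorTrajectory-class
#' @export
setMethod("show", "TumorTrajectory", function(object) {
  cat("TumorTrajectory: mouse", object@mouse, "| arm", object@arm, "|",
      length(object@days), "measurements, D", min(object@days), "-D",
      max(object@days), "\n")
  if (length(object@stages))
    cat("  stages:", paste(rle(object@stages)$values, collapse = " -> "), "\n")
})
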