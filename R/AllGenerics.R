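# Accessors and show methods. Slot access from user code is discouraged;
# these are the supported surface.

#' @rdname ImagingStudy-class
#' @param x an object.
#' @param map one of "ncct", "cbv", "cbf", "mtt", "ttd", "tmax".
#' @export
setGeneric("studyMap", function(x, map) standardGeneric("studyMap"))

#' @rdname ImagingStudy-class
#' @export
setMethod("studyMap", "ImagingStudy", function(x, map) {
  map <- match.arg(map, c("ncct", "cbv", "cbf", "mtt", "ttd", "tmax"))
  slot(x, map)
})

#' @rdname ImagingStudy-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname ImagingStudy-class
#' @export
setMethod("voxelSpacing", "ImagingStudy", function(x) x@voxelSpacing)

#' @rdname LesionMasks-class
#' @export
setMethod("voxelSpacing", "LesionMasks", function(x) x@voxelSpacing)

#' @rdname ImagingStudy-class
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' @rdname ImagingStudy-class
#' @export
setMethod("brainMask", "ImagingStudy", function(x) x@brainMask)

#' @rdname ImagingStudy-class
#' @export
setGeneric("midlineAxis", function(x) standardGeneric("midlineAxis"))

#' @rdname ImagingStudy-class
#' @export
setMethod("midlineAxis", "ImagingStudy", function(x) x@midlineAxis)

#' @rdname LesionMasks-class
#' @export
setGeneric("ischemicArea", function(x) standardGeneric("ischemicArea"))

#' @rdname LesionMasks-class
#' @export
setMethod("ischemicArea", "LesionMasks", function(x) x@ischemicArea)

#' @rdname LesionMasks-class
#' @export
setGeneric("lesionCore", function(x) standardGeneric("lesionCore"))

#' @rdname LesionMasks-class
#' @export
setMethod("lesionCore", "LesionMasks", function(x) x@core)

#' @rdname LesionMasks-class
#' @export
setGeneric("hypoperfusion", function(x) standardGeneric("hypoperfusion"))

#' @rdname LesionMasks-class
#' @export
setMethod("hypoperfusion", "LesionMasks", function(x) x@hypoperfusion)

#' @rdname LesionMasks-class
#' @export
setGeneric("coreSource", function(x) standardGeneric("coreSource"))

#' @rdname LesionMasks-class
#' @export
setMethod("coreSource", "LesionMasks", function(x) x@coreSource)

#' @rdname LesionMasks-class
#' @export
setGeneric("volumesML", function(x) standardGeneric("volumesML"))

#' @rdname LesionMasks-class
#' @export
setMethod("volumesML", "LesionMasks", function(x) x@volumesML)

#' @rdname GroundTruth-class
#' @param x an object.
#' @export
setGeneric("trueCore", function(x) standardGeneric("trueCore"))

#' @rdname GroundTruth-class
#' @export
setMethod("trueCore", "GroundTruth", function(x) x@coreMask)

#' @rdname GroundTruth-class
#' @export
setGeneric("truePenumbra", function(x) standardGeneric("truePenumbra"))

#' @rdname GroundTruth-class
#' @export
setMethod("truePenumbra", "GroundTruth", function(x) x@penumbraMask)

#' @rdname GroundTruth-class
#' @export
setGeneric("nwuApplied", function(x) standardGeneric("nwuApplied"))

#' @rdname GroundTruth-class
#' @export
setMethod("nwuApplied", "GroundTruth", function(x) x@nwuAppliedPct)

#' @rdname HHMDecision-class
#' @param x an object.
#' @export
setGeneric("isMismatch", function(x) standardGeneric("isMismatch"))

#' @rdname HHMDecision-class
#' @export
setMethod("isMismatch", "HHMDecision", function(x) x@mismatch)

#' @rdname HHMDecision-class
#' @export
setGeneric("hypodensityReading", function(x) standardGeneric("hypodensityReading"))

#' @rdname HHMDecision-class
#' @export
setMethod("hypodensityReading", "HHMDecision", function(x) x@reading)

#' @rdname HypodensityReading-class
#' @param x an object.
#' @export
setGeneric("nwuPct", function(x) standardGeneric("nwuPct"))

#' @rdname HypodensityReading-class
#' @export
setMethod("nwuPct", "HypodensityReading", function(x) x@nwuPct)

#' @rdname HHMDecision-class
#' @export
setMethod("nwuPct", "HHMDecision", function(x) {
  if (is.null(x@reading)) NA_real_ else x@reading@nwuPct
})

#' @rdname PerfusionVolumes-class
#' @param x an object.
#' @export
setGeneric("coreML", function(x) standardGeneric("coreML"))

#' @rdname PerfusionVolumes-class
#' @export
setMethod("coreML", "PerfusionVolumes", function(x) x@coreML)

#' @rdname PerfusionVolumes-class
#' @export
setGeneric("penumbraML", function(x) standardGeneric("penumbraML"))

#' @rdname PerfusionVolumes-class
#' @export
setMethod("penumbraML", "PerfusionVolumes", function(x) x@penumbraML)

#' @rdname PerfusionVolumes-class
#' @export
setGeneric("mismatchML", function(x) standardGeneric("mismatchML"))

#' @rdname PerfusionVolumes-class
#' @export
setMethod("mismatchML", "PerfusionVolumes", function(x) x@mismatchML)

#' @rdname PerfusionVolumes-class
#' @export
setGeneric("mismatchRatio", function(x) standardGeneric("mismatchRatio"))

#' @rdname PerfusionVolumes-class
#' @export
setMethod("mismatchRatio", "PerfusionVolumes", function(x) x@mismatchRatio)

#' @rdname ConfusionTable-class
#' @param x an object.
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname ConfusionTable-class
#' @export
setMethod("confusionCounts", "ConfusionTable", function(x) {
  c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn)
})

setMethod("show", "ImagingStudy", function(object) {
  dm <- dim(object@ncct)
  cat("ImagingStudy:", paste(dm, collapse = " x "), "voxels,",
      paste(object@voxelSpacing, collapse = " x "), "mm\n")
  cat("  maps: ncct cbv cbf mtt ttd tmax | brain voxels:",
      sum(object@brainMask), "| midline axis:", object@midlineAxis, "\n")
})

setMethod("show", "LesionMasks", function(object) {
  v <- object@volumesML
  cat("LesionMasks (core source:", object@coreSource, ")\n")
  cat(sprintf("  ischemic area %.2f mL | core %.2f mL | hypoperfusion %.2f mL\n",
              v[["ischemicArea"]], v[["core"]], v[["hypoperfusion"]]))
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@gridShape, collapse = " x "), "voxels,",
      paste(object@voxelSpacing, collapse = " x "), "mm\n")
  cat(sprintf("  lesion radii %s mm (core %s mm), onset %.2f h, NWU %.2f %%/h cap %.1f %%\n",
              paste(object@lesionRadiiMM, collapse = "/"),
              paste(object@coreRadiiMM, collapse = "/"),
              object@onsetToCTHours, object@nwuRatePctPerH, object@nwuCapPct))
})

setMethod("show", "HHMDecision", function(object) {
  cat("HHMDecision: core", if (object@corePresent) "present" else "absent",
      "| hypodense:", object@hypodense,
      "| mismatch:", object@mismatch, "\n")
  if (!is.null(object@reading))
    cat(sprintf("  NWU %.2f%% (core %.2f HU vs mirror %.2f HU)\n",
                object@reading@nwuPct, object@reading@meanHUCore,
                object@reading@meanHUMirror))
})

setMethod("show", "PerfusionVolumes", function(object) {
  cat(sprintf("PerfusionVolumes: core %.1f mL, penumbra %.1f mL, mismatch %.1f mL, ratio %s\n",
              object@coreML, object@penumbraML, object@mismatchML,
              format(object@mismatchRatio, digits = 3)))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ConfusionTable", function(object) {
  cat("ConfusionTable\n")
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(c("test+", "test-"),
                              c("eligible", "not eligible")))
  print(m)
})
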