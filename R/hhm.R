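#' Net water uptake of the core region on NCCT
#'
#' NWU = (1 - mean HU over the core / mean HU over the mirrored core) x 100.
#' The mirrored core is the reflection of the core mask across the
#' midsagittal plane, i.e. the homologous healthy tissue. A negative NWU
#' (core denser than its mirror) is legal and reads as "no hypodensity".
#' Per-axial-slice values (third grid axis) support the slice-by-slice
#' reading.
#'
#' @param ncct NCCT volume, HU.
#' @param coreMask non-empty logical core mask.
#' @param brainMask logical brain mask (carried for interface symmetry; the
#'   core and its mirror are assumed to lie inside the brain).
#' @param midlineAxis left-right axis index.
#' @return list: \code{meanHUCore}, \code{meanHUMirror}, \code{nwuPct},
#'   \code{perSliceNWU} (named by slice index), \code{coreSlices}.
#' @examples
#' p <- generatePhantom(phantomSpec(huNoiseSD = 0, onsetToCTHours = 4), seed = 1)
#' computeNWU(studyMap(p$study, "ncct"), trueCore(p$truth),
#'            brainMask(p$study), 1L)$nwuPct
#' @export
computeNWU <- function(ncct, coreMask, brainMask = NULL, midlineAxis = 1L) {
  if (!any(coreMask)) stop("empty core mask: check corePresent first")
  mir <- mirrorReference(ncct, midlineAxis)
  hc <- mean(ncct[coreMask])
  hm <- mean(mir[coreMask])
  if (hm <= 0) stop("mirrored core region has non-positive mean HU")
  slices <- which(apply(coreMask, 3, any))
  psn <- vapply(slices, function(s) {
    m <- coreMask[, , s]
    100 * (1 - mean(ncct[, , s][m]) / mean(mir[, , s][m]))
  }, numeric(1))
  names(psn) <- slices
  list(meanHUCore = hc, meanHUMirror = hm,
       nwuPct = 100 * (1 - hc / hm),
       perSliceNWU = psn, coreSlices = slices)
}

#' Judge the presence of a clear hypodensity
#'
#' The human call "clear hypodensity with respect to the healthy side" is
#' operationalised as an NWU threshold \code{deltaPct}. The comparison is
#' strict: an NWU exactly at the threshold counts as doubt, and doubt is
#' rated as absence of hypodensity (the conservative reading rule). Under
#' \code{sliceRule = "all_slices"} every core-bearing axial slice must
#' individually exceed the threshold, mirroring the requirement that a
#' hypoperfusion-hypodensity match encompass all slices.
#'
#' @param nwuPct global NWU, percent.
#' @param perSliceNWU per-slice NWU values (required for "all_slices").
#' @param deltaPct hypodensity threshold, percent (default 5).
#' @param sliceRule "global" (default) or "all_slices".
#' @return logical: hypodensity present.
#' @export
judgeHypodensity <- function(nwuPct, perSliceNWU = NULL, deltaPct = 5,
                             sliceRule = c("global", "all_slices")) {
  if (deltaPct < 0) stop("'deltaPct' must be >= 0")
  sliceRule <- match.arg(sliceRule)
  if (sliceRule == "global") return(nwuPct > deltaPct)
  if (is.null(perSliceNWU) || !length(perSliceNWU))
    stop("'all_slices' rule needs per-slice NWU values")
  all(perSliceNWU > deltaPct)
}

#' Classify the hypoperfusion-hypodensity mismatch
#'
#' The tissue-clock decision: a mismatch is present when a core lesion is
#' visible on the perfusion maps but no clear hypodensity has yet developed
#' in the corresponding NCCT region -- indicating that the occlusion is
#' recent and the patient likely still within the thrombolysis window.
#' With an empty core there is nothing to mismatch and the call is negative
#' with no reading attached.
#'
#' @param study an \linkS4class{ImagingStudy}.
#' @param masks \linkS4class{LesionMasks} computed from the same study.
#' @param deltaPct hypodensity threshold, percent NWU (default 5).
#' @param sliceRule "global" or "all_slices" (see
#'   \code{\link{judgeHypodensity}}).
#' @return an \linkS4class{HHMDecision}.
#' @examples
#' p <- generatePhantom(phantomSpec(onsetToCTHours = 1), seed = 7)
#' classifyHHM(p$study, segmentStudy(p$study))
#' @export
classifyHHM <- function(study, masks, deltaPct = 5,
                        sliceRule = c("global", "all_slices")) {
  stopifnot(is(study, "ImagingStudy"), is(masks, "LesionMasks"))
  sliceRule <- match.arg(sliceRule)
  if (!identical(dim(masks@core), dim(study@ncct)))
    stop("mask grid does not match the study grid")
  if (!any(masks@core))
    return(new("HHMDecision", corePresent = FALSE, hypodense = FALSE,
               mismatch = FALSE, reading = NULL))
  r <- computeNWU(study@ncct, masks@core, study@brainMask,
                  study@midlineAxis)
  hypo <- judgeHypodensity(r$nwuPct, r$perSliceNWU, deltaPct, sliceRule)
  reading <- new("HypodensityReading",
                 meanHUCore = r$meanHUCore, meanHUMirror = r$meanHUMirror,
                 nwuPct = r$nwuPct, perSliceNWU = unname(r$perSliceNWU),
                 perSlicePresent = unname(r$perSliceNWU > deltaPct),
                 hypodense = hypo)
  new("HHMDecision", corePresent = TRUE, hypodense = hypo,
      mismatch = !hypo, reading = reading)
}
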