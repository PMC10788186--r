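#' Perfusion volumes for the automated mismatch rule
#'
#' Computes the two volumes entering the EXTEND-style criteria: the core as
#' voxels whose CBF falls below \code{coreRelFraction} (default 30\%) of the
#' contralateral mirrored CBF, and the penumbra as voxels with
#' Tmax > \code{tmaxCutS} (default 6 s), both inside the brain mask. Voxels
#' with a zero mirrored CBF cannot be judged relatively and are excluded
#' from the core. A core extending beyond the Tmax lesion makes the
#' mismatch volume negative; this is legal and flagged.
#'
#' @param study an \linkS4class{ImagingStudy}.
#' @param coreRelFraction relative CBF cut, default 0.30.
#' @param tmaxCutS penumbra Tmax cut in seconds, default 6.
#' @return a \linkS4class{PerfusionVolumes} object.
#' @examples
#' p <- generatePhantom(phantomSpec(), seed = 1)
#' perfusionVolumes(p$study)
#' @export
perfusionVolumes <- function(study, coreRelFraction = 0.30, tmaxCutS = 6) {
  stopifnot(is(study, "ImagingStudy"))
  ref <- mirrorReference(study@cbf, study@midlineAxis)
  core <- study@brainMask & ref > 0 & study@cbf < coreRelFraction * ref
  pen <- study@brainMask & study@tmax > tmaxCutS
  sp <- study@voxelSpacing
  coreML <- maskVolumeML(core, sp)
  penML <- maskVolumeML(pen, sp)
  ratio <- if (coreML > 0) penML / coreML else if (penML > 0) Inf else NaN
  flags <- character(0)
  if (penML - coreML < 0) flags <- "negative_mismatch_volume"
  new("PerfusionVolumes", coreML = coreML, penumbraML = penML,
      mismatchML = penML - coreML, mismatchRatio = ratio, flags = flags)
}

#' Automated perfusion mismatch decision
#'
#' Applies the EXTEND criteria to the measured volumes. Conjunctive logic
#' (default, the trial's reading): positive iff core < 70 mL AND absolute
#' mismatch > 10 mL AND mismatch ratio > 1.2. Disjunctive logic (the
#' literal "or" reading): positive iff core < 70 mL AND (ratio > 1.2 OR
#' mismatch > 10 mL). A zero core with non-zero penumbra has ratio infinity;
#' with both volumes zero there is nothing to salvage and the call is
#' negative, not an error.
#'
#' @param v \linkS4class{PerfusionVolumes}.
#' @param criteria \linkS4class{ExtendCriteria}.
#' @return logical: mismatch present (patient imaging-eligible).
#' @examples
#' v <- new("PerfusionVolumes", coreML = 20, penumbraML = 40,
#'          mismatchML = 20, mismatchRatio = 2, flags = character(0))
#' extendDecision(v)
#' @export
extendDecision <- function(v, criteria = extendCriteria()) {
  stopifnot(is(v, "PerfusionVolumes"), is(criteria, "ExtendCriteria"))
  if (v@penumbraML == 0 && v@coreML == 0) return(FALSE)
  capOK <- v@coreML < criteria@coreCapML
  ratioOK <- !is.nan(v@mismatchRatio) && v@mismatchRatio > criteria@ratioCut
  absOK <- v@mismatchML > criteria@absCutML
  if (criteria@logic == "conjunctive") capOK && ratioOK && absOK
  else capOK && (ratioOK || absOK)
}

#' Thrombolysis eligibility label
#'
#' A patient is eligible when imaged within 4.5 h of symptom onset, or
#' beyond 4.5 h when the automated perfusion mismatch is present. The window
#' boundary is strict: an onset-to-imaging time of exactly 4.5 h is not
#' within the window.
#'
#' @param onsetToCTHours hours from symptom onset to imaging (vectorised).
#' @param extendPositive logical automated-mismatch call(s).
#' @param windowHours thrombolysis window, default 4.5.
#' @return data.frame with columns \code{onset_to_ct_h},
#'   \code{within_window}, \code{extend_positive}, \code{eligible}.
#' @examples
#' labelEligibility(c(2, 6, 6), c(FALSE, TRUE, FALSE))$eligible
#' @export
labelEligibility <- function(onsetToCTHours, extendPositive,
                             windowHours = 4.5) {
  if (any(onsetToCTHours < 0)) stop("onset time must be >= 0")
  if (length(extendPositive) != length(onsetToCTHours))
    stop("inputs must have equal length")
  ww <- onsetToCTHours < windowHours
  data.frame(onset_to_ct_h = onsetToCTHours, within_window = ww,
             extend_positive = extendPositive,
             eligible = ww | extendPositive)
}
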