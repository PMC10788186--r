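#' @import methods
NULL

# A voxel grid is a plain 3-D double array; masks are 3-D logical arrays.
.checkGrid <- function(x, name) {
  if (!is.array(x) || length(dim(x)) != 3L)
    return(sprintf("'%s' must be a 3-D array", name))
  NULL
}

#' Co-registered multimodal CT study
#'
#' One patient's non-contrast CT (Hounsfield units) together with the five
#' perfusion parameter maps produced by CTP post-processing, all resampled to
#' one voxel grid. The contralateral ("normal side") reference used by all
#' relative thresholds is taken by reflecting across the midsagittal plane,
#' which is assumed to be the central plane of \code{midlineAxis}.
#'
#' @slot ncct NCCT volume, HU.
#' @slot cbv cerebral blood volume, mL/100 mL.
#' @slot cbf cerebral blood flow, mL/100 mL/min.
#' @slot mtt mean transit time, s.
#' @slot ttd time to drain, s.
#' @slot tmax time-to-maximum of the residue function, s.
#' @slot voxelSpacing per-axis voxel spacing in mm (length 3).
#' @slot brainMask logical array delimiting brain tissue.
#' @slot midlineAxis index (1-3) of the left-right axis.
#' @export
setClass("ImagingStudy",
  representation(
    ncct = "array", cbv = "array", cbf = "array",
    mtt = "array", ttd = "array", tmax = "array",
    voxelSpacing = "numeric", brainMask = "array",
    midlineAxis = "integer"))

setValidity("ImagingStudy", function(object) {
  maps <- list(ncct = object@ncct, cbv = object@cbv, cbf = object@cbf,
               mtt = object@mtt, ttd = object@ttd, tmax = object@tmax)
  for (nm in names(maps)) {
    msg <- .checkGrid(maps[[nm]], nm)
    if (!is.null(msg)) return(msg)
  }
  dm <- dim(object@ncct)
  for (nm in names(maps))
    if (!identical(dim(maps[[nm]]), dm))
      return(sprintf("grid mismatch: '%s' is %s but 'ncct' is %s", nm,
                     paste(dim(maps[[nm]]), collapse = "x"),
                     paste(dm, collapse = "x")))
  if (!identical(dim(object@brainMask), dm))
    return("'brainMask' does not match the map grid")
  if (!is.logical(object@brainMask))
    return("'brainMask' must be logical")
  if (!any(object@brainMask))
    return("'brainMask' is empty")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    return("'voxelSpacing' must be 3 positive values (mm)")
  if (length(object@midlineAxis) != 1L || !object@midlineAxis %in% 1:3)
    return("'midlineAxis' must be 1, 2 or 3")
  inb <- object@brainMask
  for (nm in names(maps)) {
    v <- maps[[nm]][inb]
    if (any(!is.finite(v)))
      return(sprintf("non-finite voxels in '%s' inside the brain mask", nm))
    if (any(v < 0))
      return(sprintf("negative voxels in '%s' inside the brain mask", nm))
  }
  TRUE
})

#' @describeIn ImagingStudy constructor.
#' @param ncct,cbv,cbf,mtt,ttd,tmax 3-D arrays on one grid.
#' @param voxelSpacing numeric(3), mm.
#' @param brainMask logical array; defaults to \code{ncct > 0}.
#' @param midlineAxis left-right axis index, default 1.
#' @export
imagingStudy <- function(ncct, cbv, cbf, mtt, ttd, tmax,
                         voxelSpacing, brainMask = NULL, midlineAxis = 1L) {
  if (is.null(brainMask)) brainMask <- ncct > 0
  new("ImagingStudy", ncct = ncct, cbv = cbv, cbf = cbf, mtt = mtt,
      ttd = ttd, tmax = tmax, voxelSpacing = as.numeric(voxelSpacing),
      brainMask = brainMask, midlineAxis = as.integer(midlineAxis))
}

#' Segmentation masks derived from one study
#'
#' The rater-style segmentation output: the total ischemic area (bolus-delay
#' lesion on MTT/TTD/Tmax), the core lesion found within it, and the Tmax
#' hypoperfusion mask, with volumes in mL.
#'
#' @slot ischemicArea,core,hypoperfusion logical voxel masks.
#' @slot coreSource "CBV", "CBF" or "none" -- which perfusion map defined the
#'   core ("none" iff the core is empty).
#' @slot volumesML named numeric: volumes of the three masks in mL.
#' @slot voxelSpacing mm, carried over from the study.
#' @export
setClass("LesionMasks",
  representation(
    ischemicArea = "array", core = "array", hypoperfusion = "array",
    coreSource = "character", volumesML = "numeric",
    voxelSpacing = "numeric"))

setValidity("LesionMasks", function(object) {
  dm <- dim(object@ischemicArea)
  for (nm in c("ischemicArea", "core", "hypoperfusion")) {
    m <- slot(object, nm)
    if (!is.array(m) || !is.logical(m)) return(sprintf("'%s' must be a logical array", nm))
    if (!identical(dim(m), dm)) return("mask grids differ")
  }
  if (any(object@core & !object@ischemicArea))
    return("core mask is not contained in the ischemic area")
  if (!object@coreSource %in% c("CBV", "CBF", "none"))
    return("coreSource must be 'CBV', 'CBF' or 'none'")
  if ((object@coreSource == "none") != !any(object@core))
    return("coreSource must be 'none' exactly when the core is empty")
  if (!all(c("ischemicArea", "core", "hypoperfusion") %in% names(object@volumesML)))
    return("volumesML must name all three masks")
  TRUE
})

#' Segmentation thresholds
#'
#' Thresholds of the core/penumbra segmentation rules. Defaults are the
#' published reading criteria: core on CBV below 2 mL/100 mL absolute or 30\%
#' of the contralateral value, CBF fallback below 30 mL/100 mL/min or 60\%
#' contralateral, hypoperfusion at Tmax > 6 s. The ischemic-area step
#' (a rater eyeballing "sensitive MTT or TTD maps") is operationalised as
#' relative MTT above \code{mttRelArea} times the mirrored value, OR
#' Tmax > \code{tmaxCutS}; 1.45 is a conventional penumbra threshold.
#'
#' @slot cbvAbs mL/100 mL, default 2.
#' @slot cbvRel fraction of contralateral, default 0.30.
#' @slot cbfAbs mL/100 mL/min, default 30.
#' @slot cbfRel fraction of contralateral, default 0.60.
#' @slot tmaxCutS s, default 6.
#' @slot mttRelArea relative-MTT factor for the ischemic area, default 1.45.
#' @slot minCoreVoxels a CBV core smaller than this falls back to CBF, default 1.
#' @slot cbvJoint if TRUE the absolute and relative core criteria must hold
#'   jointly (AND); default FALSE (either suffices).
#' @slot keepLargestComponent drop speckle, keeping the largest 26-connected
#'   component of the ischemic area; default TRUE.
#' @export
setClass("SegmentationThresholds",
  representation(cbvAbs = "numeric", cbvRel = "numeric",
                 cbfAbs = "numeric", cbfRel = "numeric",
                 tmaxCutS = "numeric", mttRelArea = "numeric",
                 minCoreVoxels = "integer", cbvJoint = "logical",
                 keepLargestComponent = "logical"))

setValidity("SegmentationThresholds", function(object) {
  pos <- c(cbvAbs = object@cbvAbs, cbfAbs = object@cbfAbs,
           tmaxCutS = object@tmaxCutS, mttRelArea = object@mttRelArea)
  if (any(pos <= 0)) return("all thresholds must be positive")
  if (object@cbvRel <= 0 || object@cbvRel >= 1 ||
      object@cbfRel <= 0 || object@cbfRel >= 1)
    return("relative fractions must lie in (0, 1)")
  if (object@minCoreVoxels < 1L) return("minCoreVoxels must be >= 1")
  TRUE
})

#' @describeIn SegmentationThresholds constructor with published defaults.
#' @param cbvAbs,cbvRel,cbfAbs,cbfRel,tmaxCutS,mttRelArea,minCoreVoxels,cbvJoint,keepLargestComponent see slots.
#' @export
segmentationThresholds <- function(cbvAbs = 2, cbvRel = 0.30, cbfAbs = 30,
                                   cbfRel = 0.60, tmaxCutS = 6,
                                   mttRelArea = 1.45, minCoreVoxels = 1L,
                                   cbvJoint = FALSE,
                                   keepLargestComponent = TRUE) {
  new("SegmentationThresholds", cbvAbs = cbvAbs, cbvRel = cbvRel,
      cbfAbs = cbfAbs, cbfRel = cbfRel, tmaxCutS = tmaxCutS,
      mttRelArea = mttRelArea, minCoreVoxels = as.integer(minCoreVoxels),
      cbvJoint = cbvJoint, keepLargestComponent = keepLargestComponent)
}

#' Digital head-phantom specification
#'
#' Geometry and physiology of a single synthetic patient: an ellipsoidal
#' brain with a mirror-symmetric healthy hemisphere, an ellipsoidal
#' hypoperfused (penumbra) lesion containing a concentric core, and an NCCT
#' density deficit in the core that grows with time from onset (net water
#' uptake). All lengths in mm, times in hours unless stated.
#'
#' @slot gridShape integer(3) voxel counts.
#' @slot voxelSpacing numeric(3) mm.
#' @slot brainBaselineHU healthy-tissue HU (default 33, gray matter).
#' @slot huNoiseSD additive NCCT noise SD, HU.
#' @slot baselineCBF,baselineCBV,baselineTmax,baselineMTT,baselineTTD healthy
#'   map values (50 mL/100 mL/min, 4 mL/100 mL, 0.5 s, 4.8 s, 6 s).
#' @slot lesionCenter voxel coordinates (1-based) of the lesion center.
#' @slot lesionRadiiMM,coreRadiiMM semi-axes of the penumbra and core
#'   ellipsoids; the core must fit inside the penumbra.
#' @slot coreCBFFraction CBF inside the core as a fraction of contralateral
#'   (default 0.25, below the 30\% core criterion).
#' @slot penumbraCBFFraction CBF fraction in the non-core penumbra (0.65,
#'   hypoperfused but above every core criterion).
#' @slot coreCBV absolute CBV in the core (default 1 mL/100 mL, below both
#'   the 2 mL/100 mL absolute and the 30\%-relative criterion).
#' @slot penumbraTmaxS Tmax inside the whole lesion (default 8 s > 6 s).
#' @slot penumbraMTTFactor MTT/TTD elevation factor in the lesion (default 2).
#' @slot nwuRatePctPerH,nwuCapPct linear net-water-uptake rate and its
#'   saturation value (defaults 1.3 \%/h, 12 \%).
#' @slot onsetToCTHours time from symptom onset to imaging.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSpacing = "numeric",
                 brainBaselineHU = "numeric", huNoiseSD = "numeric",
                 baselineCBF = "numeric", baselineCBV = "numeric",
                 baselineTmax = "numeric", baselineMTT = "numeric",
                 baselineTTD = "numeric", lesionCenter = "numeric",
                 lesionRadiiMM = "numeric", coreRadiiMM = "numeric",
                 coreCBFFraction = "numeric", penumbraCBFFraction = "numeric",
                 coreCBV = "numeric", penumbraTmaxS = "numeric",
                 penumbraMTTFactor = "numeric", nwuRatePctPerH = "numeric",
                 nwuCapPct = "numeric", onsetToCTHours = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
    return("gridShape must be 3 counts >= 4")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    return("voxelSpacing must be 3 positive values (mm)")
  if (any(object@coreRadiiMM > object@lesionRadiiMM))
    return("core ellipsoid must fit inside the penumbra ellipsoid")
  if (any(object@lesionRadiiMM <= 0) || any(object@coreRadiiMM <= 0))
    return("lesion radii must be positive")
  # lesion must stay in one hemisphere: the midsagittal plane is the central
  # plane of axis 1, at voxel coordinate (n+1)/2
  mid <- (object@gridShape[1] + 1) / 2
  rvox <- object@lesionRadiiMM[1] / object@voxelSpacing[1]
  x0 <- object@lesionCenter[1]
  if (!(x0 + rvox < mid || x0 - rvox > mid))
    return("lesion crosses the midsagittal plane")
  if (object@nwuRatePctPerH < 0) return("nwuRatePctPerH must be >= 0")
  if (object@nwuCapPct < 0 || object@nwuCapPct >= 100)
    return("nwuCapPct must lie in [0, 100)")
  if (object@onsetToCTHours < 0) return("onsetToCTHours must be >= 0")
  if (object@huNoiseSD < 0) return("huNoiseSD must be >= 0")
  if (object@coreCBFFraction <= 0 || object@coreCBFFraction >= 1 ||
      object@penumbraCBFFraction <= 0 || object@penumbraCBFFraction >= 1)
    return("CBF fractions must lie in (0, 1)")
  TRUE
})

#' @describeIn PhantomSpec constructor with default study conditions.
#' @param gridShape,voxelSpacing,brainBaselineHU,huNoiseSD,baselineCBF,baselineCBV,baselineTmax,baselineMTT,baselineTTD,lesionCenter,lesionRadiiMM,coreRadiiMM,coreCBFFraction,penumbraCBFFraction,coreCBV,penumbraTmaxS,penumbraMTTFactor,nwuRatePctPerH,nwuCapPct,onsetToCTHours see slots.
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 16L),
                        voxelSpacing = c(2, 2, 5),
                        brainBaselineHU = 33, huNoiseSD = 0.5,
                        baselineCBF = 50, baselineCBV = 4,
                        baselineTmax = 0.5, baselineMTT = 4.8,
                        baselineTTD = 6,
                        lesionCenter = c(16, 32, 8),
                        lesionRadiiMM = c(20, 20, 18),
                        coreRadiiMM = c(10, 10, 9),
                        coreCBFFraction = 0.25,
                        penumbraCBFFraction = 0.65,
                        coreCBV = 1, penumbraTmaxS = 8,
                        penumbraMTTFactor = 2,
                        nwuRatePctPerH = 1.3, nwuCapPct = 12,
                        onsetToCTHours = 1) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSpacing = as.numeric(voxelSpacing),
      brainBaselineHU = brainBaselineHU, huNoiseSD = huNoiseSD,
      baselineCBF = baselineCBF, baselineCBV = baselineCBV,
      baselineTmax = baselineTmax, baselineMTT = baselineMTT,
      baselineTTD = baselineTTD, lesionCenter = as.numeric(lesionCenter),
      lesionRadiiMM = as.numeric(lesionRadiiMM),
      coreRadiiMM = as.numeric(coreRadiiMM),
      coreCBFFraction = coreCBFFraction,
      penumbraCBFFraction = penumbraCBFFraction,
      coreCBV = coreCBV, penumbraTmaxS = penumbraTmaxS,
      penumbraMTTFactor = penumbraMTTFactor,
      nwuRatePctPerH = nwuRatePctPerH, nwuCapPct = nwuCapPct,
      onsetToCTHours = onsetToCTHours)
}

#' Simulation ground truth
#'
#' True lesion masks and the water-uptake actually applied when a phantom was
#' generated; used by recovery tests.
#'
#' @slot coreMask,penumbraMask logical arrays on the study grid (core inside
#'   penumbra).
#' @slot onsetToCTHours hours.
#' @slot nwuAppliedPct percent HU deficit written into the core.
#' @export
setClass("GroundTruth",
  representation(coreMask = "array", penumbraMask = "array",
                 onsetToCTHours = "numeric", nwuAppliedPct = "numeric"))

setValidity("GroundTruth", function(object) {
  if (!is.logical(object@coreMask) || !is.logical(object@penumbraMask))
    return("truth masks must be logical arrays")
  if (!identical(dim(object@coreMask), dim(object@penumbraMask)))
    return("truth masks must share one grid")
  if (any(object@coreMask & !object@penumbraMask))
    return("true core must be contained in the true penumbra")
  TRUE
})

#' Synthetic cohort specification
#'
#' Stratum sizes and onset-time distributions of a simulated cohort. The
#' three strata mirror the observed cohort structure: patients imaged within
#' 4.5 h of onset; late presenters whose perfusion profile satisfies the
#' EXTEND mismatch criteria; and late presenters who fail them (the
#' non-eligible group). Onset times are drawn from normal distributions
#' truncated at zero (eligible: mean 2.7 h, SD 2.3 h; non-eligible: mean
#' 8.27 h, SD 6.1 h) and further truncated to the stratum's side of 4.5 h.
#'
#' @slot nWithinWindow,nLateMismatch,nLateNoMismatch stratum sizes.
#' @slot onsetMeanEligibleH,onsetSDEligibleH,onsetMeanNonEligibleH,onsetSDNonEligibleH
#'   truncated-normal parameters, hours.
#' @slot extendPosRateWithinWindow fraction of within-window patients whose
#'   lesion geometry also satisfies EXTEND (default 88/197, the observed
#'   within-window detection rate of automated perfusion mismatch).
#' @slot seed RNG seed; the same spec yields a bit-identical cohort.
#' @export
setClass("CohortSpec",
  representation(nWithinWindow = "integer", nLateMismatch = "integer",
                 nLateNoMismatch = "integer",
                 onsetMeanEligibleH = "numeric", onsetSDEligibleH = "numeric",
                 onsetMeanNonEligibleH = "numeric",
                 onsetSDNonEligibleH = "numeric",
                 extendPosRateWithinWindow = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  n <- c(object@nWithinWindow, object@nLateMismatch, object@nLateNoMismatch)
  if (any(n < 0L)) return("stratum counts must be >= 0")
  if (sum(n) == 0L) return("cohort must contain at least one patient")
  if (object@onsetSDEligibleH <= 0 || object@onsetSDNonEligibleH <= 0)
    return("onset-time SDs must be positive")
  if (object@extendPosRateWithinWindow < 0 ||
      object@extendPosRateWithinWindow > 1)
    return("extendPosRateWithinWindow must lie in [0, 1]")
  TRUE
})

#' @describeIn CohortSpec constructor; defaults reproduce the observed
#'   cohort (197 within window, 22 late with mismatch, 28 late without).
#' @param nWithinWindow,nLateMismatch,nLateNoMismatch,onsetMeanEligibleH,onsetSDEligibleH,onsetMeanNonEligibleH,onsetSDNonEligibleH,extendPosRateWithinWindow,seed see slots.
#' @export
cohortSpec <- function(nWithinWindow = 197L, nLateMismatch = 22L,
                       nLateNoMismatch = 28L,
                       onsetMeanEligibleH = 2.7, onsetSDEligibleH = 2.3,
                       onsetMeanNonEligibleH = 8 + 16 / 60,
                       onsetSDNonEligibleH = 6.1,
                       extendPosRateWithinWindow = 88 / 197,
                       seed = 1L) {
  new("CohortSpec", nWithinWindow = as.integer(nWithinWindow),
      nLateMismatch = as.integer(nLateMismatch),
      nLateNoMismatch = as.integer(nLateNoMismatch),
      onsetMeanEligibleH = onsetMeanEligibleH,
      onsetSDEligibleH = onsetSDEligibleH,
      onsetMeanNonEligibleH = onsetMeanNonEligibleH,
      onsetSDNonEligibleH = onsetSDNonEligibleH,
      extendPosRateWithinWindow = extendPosRateWithinWindow,
      seed = as.integer(seed))
}

#' NCCT hypodensity reading
#'
#' Intermediate quantities of the hypodensity judgment: mean core HU, mean HU
#' of the mirrored core region, the net water uptake
#' NWU = (1 - HU_core / HU_mirror) x 100, per-axial-slice NWU values for the
#' slice-by-slice reading, and the final call.
#'
#' @slot meanHUCore,meanHUMirror HU.
#' @slot nwuPct percent (may be negative: core denser than mirror).
#' @slot perSliceNWU NWU per core-bearing axial slice.
#' @slot perSlicePresent per-slice hypodensity calls at the threshold used.
#' @slot hypodense final call.
#' @export
setClass("HypodensityReading",
  representation(meanHUCore = "numeric", meanHUMirror = "numeric",
                 nwuPct = "numeric", perSliceNWU = "numeric",
                 perSlicePresent = "logical", hypodense = "logical"))

#' Hypoperfusion-hypodensity mismatch decision
#'
#' @slot corePresent core lesion visible on the perfusion maps.
#' @slot hypodense clear NCCT hypodensity inside the core region.
#' @slot mismatch \code{corePresent && !hypodense}: the tissue-clock call
#'   that the patient is still early.
#' @slot reading the \linkS4class{HypodensityReading}, or NULL when no core.
#' @export
setClass("HHMDecision",
  representation(corePresent = "logical", hypodense = "logical",
                 mismatch = "logical", reading = "ANY"))

setValidity("HHMDecision", function(object) {
  if (!identical(object@mismatch, object@corePresent && !object@hypodense))
    return("mismatch must equal corePresent && !hypodense")
  if (object@corePresent && is.null(object@reading))
    return("reading required when a core is present")
  if (!object@corePresent && !is.null(object@reading))
    return("reading must be NULL when no core is present")
  TRUE
})

#' Perfusion mismatch volumes
#'
#' Volumes entering the automated (EXTEND-style) mismatch rule: core from
#' relative CBF below 30\% of the contralateral side, penumbra from
#' Tmax > 6 s.
#'
#' @slot coreML,penumbraML,mismatchML mL; mismatch = penumbra - core and may
#'   be negative when the core extends beyond the Tmax lesion (flagged).
#' @slot mismatchRatio penumbra/core; Inf when core is 0 and penumbra > 0;
#'   NaN when both are 0.
#' @slot flags character vector of quality flags.
#' @export
setClass("PerfusionVolumes",
  representation(coreML = "numeric", penumbraML = "numeric",
                 mismatchML = "numeric", mismatchRatio = "numeric",
                 flags = "character"))

setValidity("PerfusionVolumes", function(object) {
  if (object@coreML < 0 || object@penumbraML < 0)
    return("volumes must be >= 0")
  if (abs(object@mismatchML - (object@penumbraML - object@coreML)) > 1e-9)
    return("mismatchML must equal penumbraML - coreML")
  TRUE
})

#' EXTEND mismatch criteria
#'
#' The automated perfusion eligibility rule: mismatch ratio > 1.2 between
#' the Tmax > 6 s and CBF < 30\% lesions, absolute mismatch > 10 mL, total
#' core volume < 70 mL. Under \code{logic = "conjunctive"} (default,
#' following the trial that validated the rule) all three clauses must hold;
#' \code{"disjunctive"} implements the literal "ratio ... or absolute
#' mismatch" reading, still gated by the core cap.
#'
#' @slot ratioCut default 1.2.
#' @slot absCutML default 10 mL.
#' @slot coreCapML default 70 mL.
#' @slot logic "conjunctive" or "disjunctive".
#' @export
setClass("ExtendCriteria",
  representation(ratioCut = "numeric", absCutML = "numeric",
                 coreCapML = "numeric", logic = "character"))

setValidity("ExtendCriteria", function(object) {
  if (object@ratioCut <= 0 || object@absCutML <= 0 || object@coreCapML <= 0)
    return("all cuts must be positive")
  if (!object@logic %in% c("conjunctive", "disjunctive"))
    return("logic must be 'conjunctive' or 'disjunctive'")
  TRUE
})

#' @describeIn ExtendCriteria constructor with trial defaults.
#' @param ratioCut,absCutML,coreCapML,logic see slots.
#' @export
extendCriteria <- function(ratioCut = 1.2, absCutML = 10, coreCapML = 70,
                           logic = c("conjunctive", "disjunctive")) {
  new("ExtendCriteria", ratioCut = ratioCut, absCutML = absCutML,
      coreCapML = coreCapML, logic = match.arg(logic))
}

#' 2x2 confusion table
#'
#' Counts of a binary classifier against the eligibility label: tp = eligible
#' and test-positive, fp = non-eligible positive, fn = eligible negative,
#' tn = non-eligible negative.
#'
#' @slot tp,fp,fn,tn non-negative integer counts.
#' @export
setClass("ConfusionTable",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 tn = "integer"))

setValidity("ConfusionTable", function(object) {
  n <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(is.na(n)) || any(n < 0L)) return("counts must be non-negative")
  if (sum(n) == 0L) return("table must contain at least one observation")
  TRUE
})

#' @describeIn ConfusionTable constructor.
#' @param tp,fp,fn,tn counts.
#' @export
confusionTable <- function(tp, fp, fn, tn) {
  new("ConfusionTable", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn))
}
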