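#' Net water uptake as a function of time from onset
#'
#' Ischemic tissue takes up water after arterial occlusion, which lowers its
#' CT density; the percent density deficit relative to the healthy mirror
#' region ("net water uptake", NWU) therefore acts as a tissue clock. The
#' phantom uses a linear accrual with saturation,
#' \code{min(rate * t, cap)}: continuous, non-decreasing, and swappable for
#' any other monotone trajectory.
#'
#' @param tHours time from symptom onset, hours (vectorised).
#' @param ratePctPerHour accrual rate, percent per hour (default 1.3).
#' @param capPct saturation value, percent (default 12).
#' @return NWU in percent, same length as \code{tHours}.
#' @examples
#' nwuTimeCourse(c(0, 4.5, 20))
#' @export
nwuTimeCourse <- function(tHours, ratePctPerHour = 1.3, capPct = 12) {
  if (any(tHours < 0)) stop("time from onset must be >= 0")
  if (ratePctPerHour < 0) stop("NWU rate must be >= 0")
  if (capPct < 0 || capPct >= 100) stop("NWU cap must lie in [0, 100)")
  pmin(ratePctPerHour * tHours, capPct)
}

# voxel membership of an axis-aligned ellipsoid; center/radii in voxel units
.ellipsoidMask <- function(dm, center, radiiVox) {
  x <- ((seq_len(dm[1]) - center[1]) / radiiVox[1])^2
  y <- ((seq_len(dm[2]) - center[2]) / radiiVox[2])^2
  z <- ((seq_len(dm[3]) - center[3]) / radiiVox[3])^2
  outer(outer(x, y, "+"), z, "+") <= 1
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a single digital head phantom
#'
#' Builds a co-registered study (NCCT + five perfusion maps) on the grid of
#' \code{spec}, with a mirror-symmetric healthy brain, an ellipsoidal
#' hypoperfused lesion (Tmax and MTT/TTD elevated, CBF moderately reduced)
#' and a core subregion (CBF below the 30\% relative criterion, CBV below
#' both core criteria). The NCCT density inside the true core is reduced by
#' the net water uptake accrued at \code{spec@onsetToCTHours}; Gaussian
#' noise of SD \code{spec@huNoiseSD} is added to the NCCT inside the brain.
#' The same (spec, seed) pair always yields a bit-identical study.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed integer RNG seed; required even when the noise SD is zero.
#' @return list with elements \code{study} (\linkS4class{ImagingStudy}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' p <- generatePhantom(phantomSpec(onsetToCTHours = 1), seed = 7)
#' p$study
#' @export
generatePhantom <- function(spec, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("'seed' is required: phantom generation must be reproducible")
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  dm <- spec@gridShape
  sp <- spec@voxelSpacing
  brain <- .ellipsoidMask(dm, (dm + 1) / 2, 0.47 * dm)
  pen <- .ellipsoidMask(dm, spec@lesionCenter, spec@lesionRadiiMM / sp)
  core <- .ellipsoidMask(dm, spec@lesionCenter, spec@coreRadiiMM / sp)
  if (any(pen & !brain))
    stop("lesion extends outside the brain mask")
  nwu <- nwuTimeCourse(spec@onsetToCTHours, spec@nwuRatePctPerH,
                       spec@nwuCapPct)

  blank <- array(0, dm)
  cbf <- cbv <- tmax <- mtt <- ttd <- ncct <- blank
  cbf[brain] <- spec@baselineCBF
  cbv[brain] <- spec@baselineCBV
  tmax[brain] <- spec@baselineTmax
  mtt[brain] <- spec@baselineMTT
  ttd[brain] <- spec@baselineTTD
  ncct[brain] <- spec@brainBaselineHU

  tmax[pen] <- spec@penumbraTmaxS
  mtt[pen] <- spec@penumbraMTTFactor * spec@baselineMTT
  ttd[pen] <- spec@penumbraMTTFactor * spec@baselineTTD
  cbf[pen] <- spec@penumbraCBFFraction * spec@baselineCBF
  cbf[core] <- spec@coreCBFFraction * spec@baselineCBF
  cbv[core] <- spec@coreCBV
  ncct[core] <- spec@brainBaselineHU * (1 - nwu / 100)

  if (spec@huNoiseSD > 0) {
    noise <- .withSeed(seed, rnorm(sum(brain), 0, spec@huNoiseSD))
    ncct[brain] <- pmax(ncct[brain] + noise, 0)
  }

  study <- imagingStudy(ncct, cbv, cbf, mtt, ttd, tmax,
                        voxelSpacing = sp, brainMask = brain,
                        midlineAxis = 1L)
  truth <- new("GroundTruth", coreMask = core, penumbraMask = pen,
               onsetToCTHours = spec@onsetToCTHours, nwuAppliedPct = nwu)
  list(study = study, truth = truth)
}

# normal rejection-sampled into (lower, upper)
.rtruncnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

# Per-patient simulation plan: stratum, onset, lesion geometry, sub-seed.
# Within-window patients get EXTEND-positive geometry (distinct core inside a
# larger penumbra) with probability extendPosRateWithinWindow, otherwise a
# "matched" lesion (core == penumbra, mismatch ratio 1) that fails EXTEND;
# late-eligible patients always get mismatch geometry; the late non-eligible
# stratum always gets a matched lesion. Lesion size is jittered by a common
# radial scale in [0.85, 1.2] so volumes vary while EXTEND calls stay
# guaranteed per stratum.
.cohortPlan <- function(cs) {
  stopifnot(is(cs, "CohortSpec"))
  validObject(cs)
  .withSeed(cs@seed, {
    strat <- rep(c("within_window", "late_mismatch", "late_no_mismatch"),
                 c(cs@nWithinWindow, cs@nLateMismatch, cs@nLateNoMismatch))
    n <- length(strat)
    onset <- numeric(n)
    ww <- strat == "within_window"
    lm <- strat == "late_mismatch"
    ln <- strat == "late_no_mismatch"
    onset[ww] <- .rtruncnorm(sum(ww), cs@onsetMeanEligibleH,
                             cs@onsetSDEligibleH, 0, 4.5)
    onset[lm] <- .rtruncnorm(sum(lm), cs@onsetMeanEligibleH,
                             cs@onsetSDEligibleH, 4.5, Inf)
    onset[ln] <- .rtruncnorm(sum(ln), cs@onsetMeanNonEligibleH,
                             cs@onsetSDNonEligibleH, 4.5, Inf)
    matched <- logical(n)
    matched[ww] <- runif(sum(ww)) >= cs@extendPosRateWithinWindow
    matched[ln] <- TRUE
    scale <- runif(n, 0.85, 1.2)
    data.frame(
      patient_id = sprintf("S%04d", seq_len(n)),
      stratum = strat,
      onset_to_ct_h = onset,
      lesion_scale = scale,
      matched_lesion = matched,
      eligible_expected = strat != "late_no_mismatch",
      phantom_seed = sample.int(.Machine$integer.max, n),
      stringsAsFactors = FALSE)
  })
}

# PhantomSpec for one plan row, derived from a base spec
.planSpec <- function(base, row) {
  lr <- base@lesionRadiiMM * row$lesion_scale
  cr <- if (row$matched_lesion) lr else base@coreRadiiMM * row$lesion_scale
  sp <- base
  sp@lesionRadiiMM <- lr
  sp@coreRadiiMM <- cr
  sp@onsetToCTHours <- row$onset_to_ct_h
  validObject(sp)
  sp
}

#' Generate a synthetic cohort of phantoms
#'
#' Draws onset times and lesion geometries for the three strata of
#' \code{cs} (see \linkS4class{CohortSpec}) and builds one phantom per
#' patient. Patients in the late no-mismatch stratum receive a "matched"
#' lesion whose core fills the whole hypoperfused region, so the EXTEND rule
#' always rejects them; late-eligible patients always receive mismatch
#' geometry that satisfies it.
#'
#' @param cs a \linkS4class{CohortSpec}.
#' @param baseSpec phantom template whose geometry is jittered per patient.
#' @param keepStudies if FALSE, only the record table is returned (the
#'   pipeline regenerates phantoms on the fly to bound memory).
#' @return list with \code{records} (one row per patient: id, stratum, onset,
#'   geometry, expected eligibility, per-patient seed) and \code{studies}
#'   (named list of \code{list(study, truth)}, or NULL).
#' @examples
#' coh <- generateCohort(cohortSpec(2, 1, 1, seed = 1), keepStudies = FALSE)
#' coh$records$stratum
#' @export
generateCohort <- function(cs, baseSpec = phantomSpec(), keepStudies = TRUE) {
  plan <- .cohortPlan(cs)
  studies <- NULL
  if (keepStudies) {
    studies <- lapply(seq_len(nrow(plan)), function(i) {
      generatePhantom(.planSpec(baseSpec, plan[i, ]),
                      seed = plan$phantom_seed[i])
    })
    names(studies) <- plan$patient_id
  }
  list(records = plan, studies = studies)
}
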