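# reverse an array along one axis
.flipAxis <- function(a, axis) {
  ix <- lapply(dim(a), seq_len)
  ix[[axis]] <- rev(ix[[axis]])
  do.call(`[`, c(list(a), ix, list(drop = FALSE)))
}

#' Contralateral mirror reference
#'
#' Returns, for every voxel, the value at its reflection across the
#' midsagittal plane (the central plane of \code{midlineAxis}), i.e. the
#' "normal side" reference used by all relative perfusion thresholds.
#' Reflection is an involution: mirroring twice restores the input.
#'
#' @param map 3-D array.
#' @param midlineAxis left-right axis index (default 1).
#' @return array of mirrored values, same shape as \code{map}.
#' @export
mirrorReference <- function(map, midlineAxis = 1L) {
  if (!is.array(map) || length(dim(map)) != 3L)
    stop("'map' must be a 3-D array")
  .flipAxis(map, midlineAxis)
}

# keep the largest 26-connected component of a logical mask (first component
# wins ties); emulates a rater ignoring speckle
.largestComponent <- function(mask) {
  idx <- which(mask)
  if (length(idx) < 2L) return(mask)
  dm <- dim(mask)
  lab <- array(0L, dm)
  lab[idx] <- seq_along(idx)
  co <- arrayInd(idx, dm)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
          nb[, 2] >= 1 & nb[, 2] <= dm[2] &
          nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dm[1] + (nb[ok, 3] - 1) * dm[1] * dm[2]
    tgt <- lab[lin]
    hit <- tgt > 0L
    if (any(hit))
      edges[[r]] <- cbind(which(ok)[hit], tgt[hit])
  }
  el <- do.call(rbind, edges)
  n <- length(idx)
  g <- if (is.null(el))
    igraph::make_empty_graph(n, directed = FALSE)
  else
    igraph::make_graph(edges = as.vector(t(el)), n = n, directed = FALSE)
  comp <- igraph::components(g)
  keep <- comp$membership == which.max(comp$csize)
  out <- array(FALSE, dm)
  out[idx[keep]] <- TRUE
  out
}

#' Total ischemic area from bolus-delay maps
#'
#' Operationalises the reading of "sensitive MTT or TTD maps": a voxel
#' belongs to the ischemic area when its MTT exceeds
#' \code{thr@mttRelArea} times the contralateral (mirrored) MTT, or its
#' Tmax exceeds \code{thr@tmaxCutS}. Voxels whose mirrored MTT is zero use
#' the Tmax criterion only. By default the largest 26-connected component is
#' retained. An empty mask is a legal result.
#'
#' @param study an \linkS4class{ImagingStudy}.
#' @param thr \linkS4class{SegmentationThresholds}.
#' @return logical voxel mask.
#' @export
ischemicAreaMask <- function(study, thr = segmentationThresholds()) {
  stopifnot(is(study, "ImagingStudy"), is(thr, "SegmentationThresholds"))
  mtt <- study@mtt
  ref <- mirrorReference(mtt, study@midlineAxis)
  rel <- ref > 0 & mtt > thr@mttRelArea * ref
  mask <- study@brainMask & (rel | study@tmax > thr@tmaxCutS)
  if (thr@keepLargestComponent) mask <- .largestComponent(mask)
  mask
}

#' Core lesion within the ischemic area
#'
#' Applies the CBV rule first: voxels of \code{area} with CBV below
#' \code{thr@cbvAbs} (absolute) or below \code{thr@cbvRel} times the
#' mirrored CBV. If fewer than \code{thr@minCoreVoxels} voxels qualify ("no
#' CBV lesion present"), the CBF fallback is used instead: CBF below
#' \code{thr@cbfAbs} or below \code{thr@cbfRel} times the mirrored CBF.
#' Voxels with a zero mirrored value are judged on the absolute criterion
#' alone. With \code{thr@cbvJoint = TRUE} the absolute and relative criteria
#' must hold jointly rather than alternatively.
#'
#' @param study an \linkS4class{ImagingStudy}.
#' @param thr \linkS4class{SegmentationThresholds}.
#' @param area logical mask from \code{\link{ischemicAreaMask}}.
#' @return list with \code{mask} (logical, always a subset of \code{area})
#'   and \code{source} ("CBV", "CBF" or "none").
#' @export
coreLesionMask <- function(study, thr = segmentationThresholds(), area) {
  stopifnot(is(study, "ImagingStudy"), is(thr, "SegmentationThresholds"))
  if (!identical(dim(area), dim(study@ncct)))
    stop("'area' does not match the study grid")
  rule <- function(map, absCut, relCut) {
    ref <- mirrorReference(map, study@midlineAxis)
    absHit <- map < absCut
    relHit <- ref > 0 & map < relCut * ref
    hit <- if (thr@cbvJoint) (absHit & (relHit | ref <= 0)) else (absHit | relHit)
    area & hit
  }
  cbvCore <- rule(study@cbv, thr@cbvAbs, thr@cbvRel)
  if (sum(cbvCore) >= thr@minCoreVoxels)
    return(list(mask = cbvCore, source = "CBV"))
  cbfCore <- rule(study@cbf, thr@cbfAbs, thr@cbfRel)
  if (sum(cbfCore) >= thr@minCoreVoxels)
    return(list(mask = cbfCore, source = "CBF"))
  list(mask = array(FALSE, dim(area)), source = "none")
}

#' Mask volume in mL
#'
#' @param mask logical (or strictly 0/1 numeric) voxel mask.
#' @param voxelSpacingMM numeric(3), mm.
#' @return volume in mL: voxel count x voxel volume (mm^3) / 1000.
#' @examples
#' m <- array(FALSE, c(10, 10, 1)); m[1:100] <- TRUE
#' maskVolumeML(m, c(2, 2, 5))  # 2 mL
#' @export
maskVolumeML <- function(mask, voxelSpacingMM) {
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("'mask' must be binary")
    mask <- mask == 1
  }
  if (!is.logical(mask)) stop("'mask' must be binary")
  if (length(voxelSpacingMM) != 3L || any(voxelSpacingMM <= 0))
    stop("'voxelSpacingMM' must be 3 positive values")
  sum(mask) * prod(voxelSpacingMM) / 1000
}

#' Segment a study into lesion masks
#'
#' Runs the full reading algorithm: ischemic area on the bolus-delay maps,
#' core within it (CBV rule with CBF fallback), and the Tmax > 6 s
#' hypoperfusion mask, with volumes in mL.
#'
#' @param study an \linkS4class{ImagingStudy}.
#' @param thr \linkS4class{SegmentationThresholds}.
#' @return a \linkS4class{LesionMasks} object.
#' @examples
#' p <- generatePhantom(phantomSpec(huNoiseSD = 0), seed = 1)
#' segmentStudy(p$study)
#' @export
segmentStudy <- function(study, thr = segmentationThresholds()) {
  area <- ischemicAreaMask(study, thr)
  core <- coreLesionMask(study, thr, area)
  hypo <- study@brainMask & study@tmax > thr@tmaxCutS
  sp <- study@voxelSpacing
  new("LesionMasks",
      ischemicArea = area, core = core$mask, hypoperfusion = hypo,
      coreSource = core$source,
      volumesML = c(ischemicArea = maskVolumeML(area, sp),
                    core = maskVolumeML(core$mask, sp),
                    hypoperfusion = maskVolumeML(hypo, sp)),
      voxelSpacing = sp)
}
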