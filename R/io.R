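.mapSuffixes <- c(ncct = "_ncct", cbv = "_cbv", cbf = "_cbf",
                  mtt = "_mtt", ttd = "_ttd", tmax = "_tmax")

#' Write a study as NIfTI volumes
#'
#' One NIfTI-1 file per map (suffixes \code{_ncct}, \code{_cbv}, \code{_cbf},
#' \code{_mtt}, \code{_ttd}, \code{_tmax}), the brain mask as
#' \code{_brainmask} (uint8), and a JSON sidecar with spacing, midline axis
#' and any extra metadata (e.g. the generating spec and seed).
#'
#' @param study an \linkS4class{ImagingStudy}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, default "study".
#' @param meta named list merged into the sidecar.
#' @return invisibly, the sidecar path.
#' @export
writeStudy <- function(study, dir, prefix = "study", meta = list()) {
  stopifnot(is(study, "ImagingStudy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  put <- function(arr, suffix, datatype = "double") {
    img <- RNifti::asNifti(arr, internal = FALSE)
    RNifti::pixdim(img) <- study@voxelSpacing
    RNifti::writeNifti(img, file.path(dir, paste0(prefix, suffix, ".nii")),
                       datatype = datatype)
  }
  for (nm in names(.mapSuffixes)) put(slot(study, nm), .mapSuffixes[[nm]])
  put(array(as.integer(study@brainMask), dim(study@brainMask)),
      "_brainmask", datatype = "uint8")
  side <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(
    c(list(voxel_spacing_mm = study@voxelSpacing,
           midline_axis = study@midlineAxis,
           grid_shape = dim(study@ncct)), meta),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}

#' Read a study from NIfTI volumes
#'
#' Expects the six map files written by \code{\link{writeStudy}} (or any
#' co-registered data following the same naming). Voxel spacing is taken
#' from the NIfTI header; shapes and spacings must agree across maps. The
#' brain mask is read from \code{_brainmask} when present, otherwise derived
#' as NCCT > 0.
#'
#' @param dir directory holding the volumes.
#' @param prefix file-name prefix, default "study".
#' @return an \linkS4class{ImagingStudy}.
#' @export
readStudy <- function(dir, prefix = "study") {
  one <- function(suffix, required = TRUE) {
    f <- list.files(dir, paste0("^", prefix, suffix, "\\.nii(\\.gz)?$"),
                    full.names = TRUE)
    if (!length(f)) {
      if (required)
        stop("missing map: no '", prefix, suffix, ".nii[.gz]' in ", dir)
      return(NULL)
    }
    RNifti::readNifti(f[1])
  }
  imgs <- lapply(.mapSuffixes, one)
  dims <- lapply(imgs, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("grid mismatch between maps: ",
         paste(sprintf("%s=%s", names(dims),
                       vapply(dims, paste, "", collapse = "x")),
               collapse = ", "))
  spac <- RNifti::pixdim(imgs$ncct)[1:3]
  for (nm in names(imgs)) {
    if (max(abs(RNifti::pixdim(imgs[[nm]])[1:3] - spac)) > 1e-6)
      stop("voxel spacing differs between 'ncct' and '", nm, "'")
    if (any(!is.finite(as.array(imgs[[nm]]))))
      stop("non-finite voxels in '", nm, "'")
  }
  arrs <- lapply(imgs, function(x) {
    a <- as.array(x); attributes(a) <- list(dim = dim(x)); a
  })
  bm <- one("_brainmask", required = FALSE)
  brain <- if (is.null(bm)) arrs$ncct > 0 else {
    a <- as.array(bm) > 0; attributes(a) <- list(dim = dim(bm)); a
  }
  imagingStudy(arrs$ncct, arrs$cbv, arrs$cbf, arrs$mtt, arrs$ttd,
               arrs$tmax, voxelSpacing = spac, brainMask = brain,
               midlineAxis = 1L)
}

#' Write lesion masks as NIfTI volumes
#'
#' @param masks a \linkS4class{LesionMasks}.
#' @param dir output directory.
#' @param prefix file-name prefix, default "masks".
#' @return invisibly, the output directory.
#' @export
writeMasks <- function(masks, dir, prefix = "masks") {
  stopifnot(is(masks, "LesionMasks"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("ischemicArea", "core", "hypoperfusion")) {
    m <- slot(masks, nm)
    img <- RNifti::asNifti(array(as.integer(m), dim(m)), internal = FALSE)
    RNifti::pixdim(img) <- masks@voxelSpacing
    RNifti::writeNifti(img, file.path(dir, paste0(prefix, "_",
                                                  tolower(nm), ".nii")),
                       datatype = "uint8")
  }
  invisible(dir)
}

#' Default pipeline configuration
#'
#' All tunables of the simulate-segment-classify-evaluate pipeline in one
#' nested list: cohort composition, phantom physiology, segmentation
#' thresholds, the HHM hypodensity threshold, and the EXTEND criteria.
#' Every threshold default equals the published value where one exists.
#' Round-trips losslessly through YAML via
#' \code{\link{writePipelineConfig}} / \code{\link{readPipelineConfig}}.
#'
#' @param seed cohort RNG seed.
#' @param outDir output directory or NULL for in-memory runs.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L, outDir = NULL) {
  list(
    cohort = list(nWithinWindow = 197L, nLateMismatch = 22L,
                  nLateNoMismatch = 28L, onsetMeanEligibleH = 2.7,
                  onsetSDEligibleH = 2.3,
                  onsetMeanNonEligibleH = 8 + 16 / 60,
                  onsetSDNonEligibleH = 6.1,
                  extendPosRateWithinWindow = 88 / 197,
                  seed = as.integer(seed)),
    phantom = list(gridShape = c(64L, 64L, 16L), voxelSpacing = c(2, 2, 5),
                   brainBaselineHU = 33, huNoiseSD = 0.5, baselineCBF = 50,
                   baselineCBV = 4, baselineTmax = 0.5, baselineMTT = 4.8,
                   baselineTTD = 6, lesionCenter = c(16, 32, 8),
                   lesionRadiiMM = c(20, 20, 18),
                   coreRadiiMM = c(10, 10, 9), coreCBFFraction = 0.25,
                   penumbraCBFFraction = 0.65, coreCBV = 1,
                   penumbraTmaxS = 8, penumbraMTTFactor = 2,
                   nwuRatePctPerH = 1.3, nwuCapPct = 12),
    segmentation = list(cbvAbs = 2, cbvRel = 0.30, cbfAbs = 30,
                        cbfRel = 0.60, tmaxCutS = 6, mttRelArea = 1.45,
                        minCoreVoxels = 1L, cbvJoint = FALSE,
                        keepLargestComponent = TRUE),
    hhm = list(deltaPct = 5, sliceRule = "global"),
    extend = list(ratioCut = 1.2, absCutML = 10, coreCapML = 70,
                  logic = "conjunctive"),
    output = list(dir = outDir))
}

#' @rdname defaultPipelineConfig
#' @param config configuration list.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname defaultPipelineConfig
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
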