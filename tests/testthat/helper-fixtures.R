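# Fixtures and independent brute-force oracles used across test files.

# small noise-free phantom spec for fast loops
tinySpec <- function(...) {
  args <- list(gridShape = c(32L, 32L, 8L), voxelSpacing = c(4, 4, 10),
               lesionCenter = c(8, 16, 4), lesionRadiiMM = c(20, 20, 18),
               coreRadiiMM = c(10, 10, 9), huNoiseSD = 0)
  do.call(phantomSpec, utils::modifyList(args, list(...)))
}

# uniform study on a small grid with per-map overrides applied to a region
uniformStudy <- function(dm = c(8L, 8L, 4L), spacing = c(2, 2, 5),
                         ncct = 33, cbv = 4, cbf = 50, mtt = 4.8,
                         ttd = 6, tmax = 0.5) {
  mk <- function(v) array(v, dm)
  imagingStudy(mk(ncct), mk(cbv), mk(cbf), mk(mtt), mk(ttd), mk(tmax),
               voxelSpacing = spacing, brainMask = array(TRUE, dm),
               midlineAxis = 1L)
}

# random positive-valued study for property tests
randomStudy <- function(dm = c(8L, 8L, 4L), seed = 1) {
  set.seed(seed)
  mk <- function(lo, hi) array(runif(prod(dm), lo, hi), dm)
  imagingStudy(mk(20, 40), mk(0.5, 6), mk(10, 70), mk(2, 12), mk(3, 14),
               mk(0, 10), voxelSpacing = c(2, 2, 5),
               brainMask = array(TRUE, dm), midlineAxis = 1L)
}

# voxel-by-voxel re-evaluation of the written segmentation rules,
# independent of the package's vectorised implementation
oracleIschemicArea <- function(study, thr) {
  dm <- dim(studyMap(study, "ncct"))
  mtt <- studyMap(study, "mtt"); tmax <- studyMap(study, "tmax")
  bm <- brainMask(study)
  out <- array(FALSE, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (!bm[i, j, k]) next
    ref <- mtt[dm[1] + 1 - i, j, k]
    out[i, j, k] <- (ref > 0 && mtt[i, j, k] > thr@mttRelArea * ref) ||
      tmax[i, j, k] > thr@tmaxCutS
  }
  out
}

oracleCore <- function(study, thr, area) {
  dm <- dim(area)
  ruleMask <- function(map, absCut, relCut) {
    out <- array(FALSE, dm)
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
      if (!area[i, j, k]) next
      ref <- map[dm[1] + 1 - i, j, k]
      absHit <- map[i, j, k] < absCut
      relHit <- ref > 0 && map[i, j, k] < relCut * ref
      out[i, j, k] <- if (thr@cbvJoint) absHit && (relHit || ref <= 0)
                      else absHit || relHit
    }
    out
  }
  cbv <- ruleMask(studyMap(study, "cbv"), thr@cbvAbs, thr@cbvRel)
  if (sum(cbv) >= thr@minCoreVoxels) return(list(mask = cbv, source = "CBV"))
  cbf <- ruleMask(studyMap(study, "cbf"), thr@cbfAbs, thr@cbfRel)
  if (sum(cbf) >= thr@minCoreVoxels) return(list(mask = cbf, source = "CBF"))
  list(mask = array(FALSE, dm), source = "none")
}

# Clopper-Pearson bounds by brute-force inversion of binomial tail
# probabilities on a probability grid
cpGridOracle <- function(k, n, alpha = 0.05, by = 1e-4) {
  grid <- seq(0, 1, by = by)
  low <- if (k == 0) 0 else
    min(grid[pbinom(k - 1, n, grid, lower.tail = FALSE) >= alpha / 2])
  high <- if (k == n) 1 else
    max(grid[pbinom(k, n, grid) >= alpha / 2])
  c(low = low, high = high)
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
mwEnumOracle <- function(x, y) {
  u <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  all <- c(x, y)
  n1 <- length(x)
  combs <- combn(length(all), n1)
  us <- apply(combs, 2, function(ix) u(all[ix], all[-ix]))
  uObs <- u(x, y)
  min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}
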