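test_that("mirror reference reverses the midline axis and is an involution", {
  row <- array(c(10, 20, 30, 40), c(4, 1, 1))
  expect_equal(as.vector(mirrorReference(row, 1L)), c(40, 30, 20, 10))
  a <- randomStudy(seed = 4)
  m <- studyMap(a, "cbf")
  expect_identical(mirrorReference(mirrorReference(m, 1L), 1L), m)
  # a symmetric map is a fixed point
  sym <- m + mirrorReference(m, 1L)
  expect_identical(mirrorReference(sym, 1L), sym)
  # contralateral reference of core voxels reads the healthy baseline
  p <- generatePhantom(tinySpec(), seed = 1)
  ref <- mirrorReference(studyMap(p$study, "cbf"), 1L)
  expect_true(all(ref[trueCore(p$truth)] == 50))
  expect_error(mirrorReference(1:5), "3-D")
})

test_that("ischemic area follows the MTT/Tmax rules on degenerate inputs", {
  healthy <- uniformStudy()
  expect_false(any(ischemicAreaMask(healthy)))
  # all-zero MTT with Tmax 7 s everywhere: whole brain qualifies
  allTmax <- uniformStudy(mtt = 0, tmax = 7)
  expect_true(all(ischemicAreaMask(allTmax) == brainMask(allTmax)))
})

test_that("segmentation on a noise-free phantom recovers ground truth exactly", {
  for (onset in c(0.5, 6)) {
    p <- generatePhantom(tinySpec(onsetToCTHours = onset), seed = 9)
    m <- segmentStudy(p$study)
    expect_identical(ischemicArea(m), truePenumbra(p$truth))
    expect_identical(lesionCore(m), trueCore(p$truth))
    expect_identical(hypoperfusion(m), truePenumbra(p$truth))
    expect_identical(coreSource(m), "CBV")
  }
})

test_that("core falls back from CBV to CBF when no CBV lesion is present", {
  # CBV in the core at 3.5 mL/100 mL: neither < 2 absolute nor < 30 % of the
  # contralateral 4.0 (87.5 %); CBF at 20 % of contralateral fires both CBF
  # criteria (10 < 30 absolute, 0.20 < 0.60 relative)
  p <- generatePhantom(tinySpec(coreCBV = 3.5, coreCBFFraction = 0.2),
                       seed = 2)
  m <- segmentStudy(p$study)
  expect_identical(coreSource(m), "CBF")
  expect_identical(lesionCore(m), trueCore(p$truth))
  # healthy maps: empty core, source "none"
  healthy <- uniformStudy()
  cm <- coreLesionMask(healthy, area = ischemicAreaMask(healthy))
  expect_false(any(cm$mask))
  expect_identical(cm$source, "none")
})

test_that("mask volumes are count times voxel volume", {
  m <- array(FALSE, c(10, 10, 2)); m[1:100] <- TRUE
  expect_equal(maskVolumeML(m, c(2, 2, 5)), 2)
  expect_equal(maskVolumeML(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), 0)
  expect_error(maskVolumeML(array(0.5, c(2, 2, 2)), c(1, 1, 1)), "binary")
  # voxelised ellipsoid volume approximates the analytic one within a
  # half-voxel surface shell
  p <- generatePhantom(phantomSpec(huNoiseSD = 0), seed = 1)
  vol <- maskVolumeML(trueCore(p$truth), c(2, 2, 5))
  analytic <- 4 / 3 * pi * 10 * 10 * 9 / 1000
  rEff <- (10 * 10 * 9)^(1 / 3)
  shell <- 4 * pi * rEff^2 * max(c(2, 2, 5)) / 2 / 1000
  expect_lt(abs(vol - analytic), shell)
})

test_that("vectorised masks equal a brute-force per-voxel oracle on small grids", {
  thrNoLCC <- segmentationThresholds(keepLargestComponent = FALSE)
  for (seed in 1:5) {
    st <- randomStudy(dm = c(8L, 8L, 4L), seed = seed)
    area <- ischemicAreaMask(st, thrNoLCC)
    expect_identical(area, oracleIschemicArea(st, thrNoLCC))
    got <- coreLesionMask(st, thrNoLCC, area)
    want <- oracleCore(st, thrNoLCC, area)
    expect_identical(got$mask, want$mask)
    expect_identical(got$source, want$source)
  }
  # the joint (AND) reading also matches its oracle
  thrJoint <- segmentationThresholds(cbvJoint = TRUE,
                                     keepLargestComponent = FALSE)
  st <- randomStudy(seed = 11)
  area <- ischemicAreaMask(st, thrJoint)
  expect_identical(coreLesionMask(st, thrJoint, area)$mask,
                   oracleCore(st, thrJoint, area)$mask)
})

test_that("largest-component cleanup drops speckle but keeps the lesion", {
  p <- generatePhantom(tinySpec(), seed = 1)
  st <- p$study
  # plant an isolated hot voxel far from the lesion on the healthy side
  tm <- studyMap(st, "tmax"); tm[22, 22, 4] <- 9
  spiked <- imagingStudy(studyMap(st, "ncct"), studyMap(st, "cbv"),
                         studyMap(st, "cbf"), studyMap(st, "mtt"),
                         studyMap(st, "ttd"), tm,
                         voxelSpacing = voxelSpacing(st),
                         brainMask = brainMask(st))
  withLCC <- ischemicAreaMask(spiked)
  expect_identical(withLCC, truePenumbra(p$truth))
  noLCC <- ischemicAreaMask(spiked,
                            segmentationThresholds(keepLargestComponent = FALSE))
  expect_equal(sum(noLCC) - sum(withLCC), 1L)
})

test_that("segmentation is idempotent and thresholds act monotonically", {
  p <- generatePhantom(tinySpec(), seed = 6)
  m1 <- segmentStudy(p$study)
  m2 <- segmentStudy(p$study)
  expect_identical(lesionCore(m1), lesionCore(m2))
  expect_identical(ischemicArea(m1), ischemicArea(m2))
  st <- randomStudy(seed = 8)
  # raising the Tmax cut never grows the hypoperfusion mask
  prev <- NULL
  for (cut in c(2, 4, 6, 8)) {
    hypo <- brainMask(st) & studyMap(st, "tmax") > cut
    if (!is.null(prev)) expect_false(any(hypo & !prev))
    prev <- hypo
  }
  # raising the absolute CBV cut never shrinks the CBV core
  area <- array(TRUE, dim(brainMask(st)))
  prev <- NULL
  for (cut in c(1, 2, 4, 6)) {
    thr <- segmentationThresholds(cbvAbs = cut, keepLargestComponent = FALSE)
    core <- coreLesionMask(st, thr, area)
    if (!is.null(prev) && core$source == "CBV" && prev$source == "CBV")
      expect_false(any(prev$mask & !core$mask))
    prev <- core
  }
})
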