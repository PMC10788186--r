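test_that("net water uptake time course is linear with saturation", {
  expect_equal(nwuTimeCourse(0, 1.3, 12), 0)
  expect_equal(nwuTimeCourse(4.5, 1.3, 12), 5.85)  # 1.3 x 4.5, by hand
  expect_equal(nwuTimeCourse(20, 1.3, 12), 12)     # cap binds
  t <- seq(0, 30, by = 0.25)
  w <- nwuTimeCourse(t)
  expect_true(all(diff(w) >= 0))
  expect_true(all(w <= 12))
  expect_error(nwuTimeCourse(-1), "time")
  expect_error(nwuTimeCourse(1, ratePctPerHour = -0.5), "rate")
  expect_error(nwuTimeCourse(1, capPct = 120), "cap")
})

test_that("phantom generation is deterministic and seed-mandatory", {
  sp <- phantomSpec()
  a <- generatePhantom(sp, seed = 11)
  b <- generatePhantom(sp, seed = 11)
  for (m in c("ncct", "cbv", "cbf", "mtt", "ttd", "tmax"))
    expect_identical(studyMap(a$study, m), studyMap(b$study, m))
  c <- generatePhantom(sp, seed = 12)
  expect_false(identical(studyMap(a$study, "ncct"),
                         studyMap(c$study, "ncct")))
  expect_error(generatePhantom(sp), "seed")
})

test_that("noise-free NCCT is mirror-symmetric at onset zero and outside the lesion later", {
  p0 <- generatePhantom(tinySpec(onsetToCTHours = 0), seed = 3)
  ncct <- studyMap(p0$study, "ncct")
  expect_identical(ncct, mirrorReference(ncct, 1L))
  p1 <- generatePhantom(tinySpec(onsetToCTHours = 8), seed = 3)
  les <- truePenumbra(p1$truth)
  outside <- !(les | mirrorReference(les, 1L))
  for (m in c("ncct", "cbv", "cbf", "mtt", "ttd", "tmax")) {
    a <- studyMap(p1$study, m)
    expect_identical(a[outside], mirrorReference(a, 1L)[outside])
  }
})

test_that("lesion geometry invariants hold: containment, hemisphere, brain", {
  p <- generatePhantom(tinySpec(), seed = 5)
  core <- trueCore(p$truth); pen <- truePenumbra(p$truth)
  expect_false(any(core & !pen))
  # core is contained in the Tmax > 6 s mask
  expect_false(any(core & !(studyMap(p$study, "tmax") > 6)))
  # lesion stays on one side of the midsagittal plane
  dm <- dim(pen)
  leftCount <- sum(pen[seq_len(dm[1] / 2), , ])
  expect_identical(sum(pen), leftCount)
  # a lesion poking out of the brain is rejected
  bad <- tinySpec(lesionCenter = c(4, 4, 1))
  expect_error(generatePhantom(bad, seed = 1), "outside the brain")
  # a lesion crossing the midline is rejected at spec level
  expect_error(phantomSpec(lesionCenter = c(30, 32, 8)), "midsagittal")
})

test_that("mean core HU is non-increasing in onset time (tissue clock)", {
  onsets <- c(0, 1, 2.5, 4, 4.5, 6, 9, 12, 24)
  hu <- vapply(onsets, function(t) {
    p <- generatePhantom(tinySpec(onsetToCTHours = t), seed = 2)
    mean(studyMap(p$study, "ncct")[trueCore(p$truth)])
  }, numeric(1))
  expect_true(all(diff(hu) <= 0))
  # deficit saturates at the cap
  expect_equal(hu[length(hu)], 33 * (1 - 12 / 100))
})

test_that("phantom hypodensity crosses the default threshold between 1 h and 12 h", {
  # NWU(1 h) = 1.3 % is below delta = 5 %; NWU(12 h) = 12 % (cap) is above
  expect_lt(nwuTimeCourse(1), 5)
  p1 <- generatePhantom(phantomSpec(onsetToCTHours = 1), seed = 7)
  nw1 <- computeNWU(studyMap(p1$study, "ncct"), trueCore(p1$truth),
                    brainMask(p1$study), 1L)
  expect_lt(nw1$nwuPct, 5)
  expect_gt(nwuTimeCourse(12), 5)
  p2 <- generatePhantom(phantomSpec(onsetToCTHours = 12), seed = 7)
  nw2 <- computeNWU(studyMap(p2$study, "ncct"), trueCore(p2$truth),
                    brainMask(p2$study), 1L)
  expect_gt(nw2$nwuPct, 5)
})

test_that("cohort generation respects stratum sizes, labels and onset windows", {
  coh <- generateCohort(cohortSpec(197L, 22L, 28L, seed = 1),
                        keepStudies = FALSE)
  r <- coh$records
  expect_equal(nrow(r), 247L)
  expect_equal(sum(r$eligible_expected), 219L)
  expect_equal(as.vector(table(r$stratum)[c("within_window",
                                            "late_mismatch",
                                            "late_no_mismatch")]),
               c(197L, 22L, 28L))
  expect_true(all(r$onset_to_ct_h[r$stratum == "within_window"] < 4.5))
  expect_true(all(r$onset_to_ct_h[r$stratum != "within_window"] > 4.5))
  expect_true(all(r$onset_to_ct_h > 0))
  # determinism: identical spec gives an identical cohort
  coh2 <- generateCohort(cohortSpec(197L, 22L, 28L, seed = 1),
                         keepStudies = FALSE)
  expect_identical(r, coh2$records)

  single <- generateCohort(cohortSpec(1L, 0L, 0L, seed = 1),
                           keepStudies = FALSE)
  expect_equal(single$records$stratum, "within_window")
  expect_error(cohortSpec(0L, 0L, 0L), "at least one")
})

test_that("the late no-mismatch stratum always fails the EXTEND rule", {
  coh <- generateCohort(cohortSpec(0L, 0L, 5L, seed = 2))
  calls <- vapply(coh$studies, function(s)
    extendDecision(perfusionVolumes(s$study)), logical(1))
  expect_false(any(calls))
})
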