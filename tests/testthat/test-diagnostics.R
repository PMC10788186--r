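test_that("confusion tables from the published cohort match its printed counts", {
  ref <- referenceCohort()
  expect_equal(nrow(ref), 247L)
  expect_equal(sum(ref$eligible), 219L)
  hhm <- confusionCounts(confusionFromCohort(ref, "hhm_positive"))
  expect_equal(hhm, c(tp = 195L, fp = 8L, fn = 24L, tn = 20L))
  ext <- confusionCounts(confusionFromCohort(ref, "extend_positive"))
  expect_equal(ext, c(tp = 110L, fp = 0L, fn = 109L, tn = 28L))
  expect_error(confusionFromCohort(ref[0, ], "hhm_positive"), "empty")
  broken <- ref; broken$hhm_positive[c(2, 5)] <- NA
  expect_error(confusionFromCohort(broken, "hhm_positive"), "P002.*P005")
})

test_that("confusion counting equals brute-force recounting on random cohorts", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:60, 1)
    rec <- data.frame(patient_id = seq_len(n),
                      eligible = runif(n) < 0.7,
                      call = runif(n) < 0.5)
    ct <- confusionCounts(confusionFromCohort(rec, "call"))
    manual <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
    for (i in seq_len(n)) {
      cell <- if (rec$eligible[i] && rec$call[i]) "tp"
        else if (!rec$eligible[i] && rec$call[i]) "fp"
        else if (rec$eligible[i]) "fn" else "tn"
      manual[cell] <- manual[cell] + 1L
    }
    expect_equal(ct, manual)
    expect_equal(sum(ct), n)
  }
})

test_that("Clopper-Pearson intervals match printed values and a tail-inversion oracle", {
  ci <- clopperPearson(195, 219)
  expect_equal(round(unname(ci[1, ]), 3), c(0.841, 0.929))
  expect_equal(unname(clopperPearson(0, 28)[1, "low"]), 0)
  expect_equal(unname(clopperPearson(28, 28)[1, "high"]), 1)
  g <- cpGridOracle(20, 28)
  ci2 <- clopperPearson(20, 28)
  expect_lt(abs(ci2[1, "low"] - g[["low"]]), 2e-4)
  expect_lt(abs(ci2[1, "high"] - g[["high"]]), 2e-4)
  expect_true(ci2[1, "low"] < 20 / 28 && 20 / 28 < ci2[1, "high"])
  expect_error(clopperPearson(5, 3), "k")
})

test_that("exact intervals cover the true proportion at least nominally", {
  set.seed(2024)
  k <- rbinom(2000, 28, 0.7)
  ci <- clopperPearson(k, 28)
  coverage <- mean(ci[, "low"] <= 0.7 & 0.7 <= ci[, "high"])
  expect_gte(coverage, 0.95)
})

test_that("accuracy metrics reproduce the published table rows", {
  hhm <- accuracyMetrics(confusionTable(195, 8, 24, 20))
  est <- setNames(roundHalfUp(hhm$estimate, 1), hhm$metric)
  expect_equal(est, c(sensitivity = 89.0, specificity = 71.4, ppv = 96.1,
                      npv = 45.5, auc = 80.2))
  ext <- accuracyMetrics(confusionTable(110, 0, 109, 28))
  est2 <- setNames(roundHalfUp(ext$estimate, 1), ext$metric)
  expect_equal(est2, c(sensitivity = 50.2, specificity = 100.0, ppv = 100.0,
                       npv = 20.4, auc = 75.1))
  # each point estimate lies inside its exact CI
  for (m in list(hhm, ext)) {
    prop <- m[m$metric != "auc", ]
    expect_true(all(prop$ciLow <= prop$estimate + 1e-9 &
                      prop$estimate <= prop$ciHigh + 1e-9))
  }
  perfect <- accuracyMetrics(confusionTable(10, 0, 0, 5))
  expect_equal(perfect$estimate, rep(100, 5))
})

test_that("AUC identity and class-swap symmetry hold for arbitrary tables", {
  set.seed(7)
  for (i in 1:20) {
    cts <- as.integer(rmultinom(1, sample(20:200, 1), c(4, 1, 2, 1)))
    if (cts[1] + cts[3] == 0 || cts[2] + cts[4] == 0) next
    m <- accuracyMetrics(confusionTable(cts[1], cts[2], cts[3], cts[4]))
    est <- setNames(m$estimate, m$metric)
    expect_equal(est[["auc"]],
                 (est[["sensitivity"]] + est[["specificity"]]) / 2)
    # swapping the positive/negative class maps sens<->spec, ppv<->npv
    sw <- accuracyMetrics(confusionTable(cts[4], cts[3], cts[2], cts[1]))
    estSw <- setNames(sw$estimate, sw$metric)
    expect_equal(estSw[["sensitivity"]], est[["specificity"]])
    expect_equal(estSw[["ppv"]], est[["npv"]])
  }
})

test_that("undefined metrics are NA rather than fabricated", {
  m <- accuracyMetrics(confusionTable(0, 5, 0, 7))  # no eligible patients
  est <- setNames(m$estimate, m$metric)
  expect_true(is.na(est[["sensitivity"]]))
  expect_true(is.na(est[["auc"]]))
  expect_false(is.na(est[["specificity"]]))
})

test_that("proportion comparisons use uncorrected chi-square with Fisher fallback", {
  expect_lt(compareProportions(190, 197, 5, 22), 0.001)
  expect_lt(compareProportions(154, 198, 12, 26), 0.001)
  expect_equal(compareProportions(10, 20, 10, 20), 1.0)
  # uncorrected Pearson statistic, checked against the closed form
  p <- compareProportions(15, 40, 5, 30)
  tab <- rbind(c(15, 25), c(5, 25))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - e)^2 / e)
  expect_equal(p, pchisq(x2, 1, lower.tail = FALSE))
  expect_lt(abs(compareProportions(15, 40, 5, 30, method = "fisher") -
                  fisher.test(tab)$p.value), 1e-12)
  expect_error(compareProportions(0, 10, 0, 12), "margin")
})

test_that("continuous comparisons: hand-enumerated U test and onset-time separation", {
  x <- c(1.1, 3.2, 5.3); y <- c(2.4, 4.5, 6.6)
  expect_equal(compareContinuous(x, y, "mann_whitney"), mwEnumOracle(x, y))
  x2 <- c(1, 2, 3); y2 <- c(10, 11, 12)
  expect_equal(compareContinuous(x2, y2, "mann_whitney"),
               mwEnumOracle(x2, y2))
  expect_equal(compareContinuous(c(1, 2, 3), c(1, 2, 3), "mann_whitney"), 1.0)
  expect_error(compareContinuous(c(1, 1), c(2, 2), "t_test"), "degenerate")
  # onset-time distributions of the two groups separate at p < 0.001
  # in (at least) 99 of 100 seeded replicates
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    elig <- pmax(rnorm(200, 2.7, 2.3), 1e-3)
    non <- pmax(rnorm(28, 8 + 16 / 60, 6.1), 1e-3)
    if (compareContinuous(elig, non, "t_test") < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("cohort summary reproduces printed percentages and handles edge cases", {
  # 154 of 198 non-missing eligible hypertensives -> 77.8 %
  rec <- data.frame(
    patient_id = seq_len(247),
    eligible = rep(c(TRUE, FALSE), c(219, 28)),
    hypertension = c(rep(c(TRUE, FALSE, NA), c(154, 44, 21)),
                     rep(c(TRUE, FALSE, NA), c(12, 14, 2))))
  s <- cohortSummary(rec, "hypertension")
  expect_equal(s$eligible_summary, "154 (77.8)")
  expect_equal(s$missing_eligible, 21L)
  expect_equal(s$noneligible_summary, "12 (46.2)")
  expect_lt(s$p_value, 0.001)
  # single-record group: SD unavailable, p-value NA rather than invented
  tiny <- data.frame(patient_id = 1:3, eligible = c(TRUE, FALSE, FALSE),
                     age = c(70, 80, 60))
  s2 <- cohortSummary(tiny, "age")
  expect_match(s2$eligible_summary, "NA")
  expect_true(is.na(s2$p_value))
  # synthetic cohort records summarise with matching group sizes
  coh <- generateCohort(cohortSpec(6L, 2L, 3L, seed = 3),
                        keepStudies = FALSE)$records
  coh$eligible <- coh$eligible_expected
  s3 <- cohortSummary(coh, "onset_to_ct_h")
  expect_equal(s3$missing_eligible + s3$missing_noneligible, 0L)
})
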