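test_that("degenerate dispersion collapses draws onto the configured median", {
  cfg <- generatorConfig(cmvrSdlog = c(male = 0, female = 0),
                         baselineSdlog = 0)
  set.seed(1)
  for (k in 1:5) {
    phys <- sampleTruePhysiology(cfg, "male")
    expect_equal(phys$cmvrHyper, 680)
    expect_equal(phys$cmvrBase, 1360)
  }
  expect_equal(sampleTruePhysiology(cfg, "female")$cmvrHyper, 860)
})

test_that("large-sample medians respect the sex-specific configuration", {
  cfg <- generatorConfig()
  set.seed(99)
  males <- vapply(1:10000, function(i)
    sampleTruePhysiology(cfg, "male")$cmvrHyper, numeric(1))
  females <- vapply(1:10000, function(i)
    sampleTruePhysiology(cfg, "female")$cmvrHyper, numeric(1))
  expect_lt(abs(median(males) - 680) / 680, 0.03)
  expect_lt(abs(median(females) - 860) / 860, 0.03)
  # configured female/male median ratio 860/680 is preserved
  expect_equal(median(females) / median(males), 860 / 680, tolerance = 0.05)
  # dispersion calibration: quartile ratio close to 865/520 for males
  expect_equal(unname(quantile(males, 0.75) / quantile(males, 0.25)),
               865 / 520, tolerance = 0.05)
})

test_that("series solve is self-consistent and tends to the zero-resistance algebra", {
  # negligible epicardial resistance: Q -> 1000 Pa / CMVR, Pd -> Pa
  fat <- vesselGeometry(seq(0, 10, length.out = 11),
                        cbind(0, 0, seq(0, 10, length.out = 11)),
                        rep(5, 11))
  fwd <- forwardSeriesSolve(fat, Pa = 90, cmvrTrue = 900)
  expect_equal(fwd$Q, 100, tolerance = 1e-3)
  expect_equal(fwd$Pd, 90, tolerance = 1e-3)

  # defining identity: computeCMVR recovers the true CMVR to 1e-10
  ph <- sixtyPhantom()
  for (cmvr in c(300, 680, 1500)) {
    fwd <- forwardSeriesSolve(ph, 92, cmvr)
    expect_lt(abs(computeCMVR(fwd$Pd, fwd$Q) - cmvr) / cmvr, 1e-10)
    expect_true(fwd$Pd > 0 && fwd$Pd < 92)
  }
})

test_that("tightening the stenosis lowers both flow and distal pressure", {
  qs <- pds <- numeric(0)
  for (sev in seq(0, 90, by = 10)) {
    g <- makeStenosedPhantom(stenosisSpec(severity = sev))
    fwd <- forwardSeriesSolve(g, 92, 680)
    qs <- c(qs, fwd$Q); pds <- c(pds, fwd$Pd)
  }
  expect_true(all(diff(qs) < 0))
  expect_true(all(diff(pds) < 0))
})

test_that("cohort generation is deterministic and ordering-invariant per case", {
  cfg <- nullGenConfig(nMale = 8L, nFemale = 8L)
  c1 <- generateCohort(cfg, seed = 42)
  c2 <- generateCohort(cfg, seed = 42)
  expect_identical(cohortTruth(c1), cohortTruth(c2))
  expect_identical(proximalPressure(c1@cases[[5]]@pressures$hyperaemic),
                   proximalPressure(c2@cases[[5]]@pressures$hyperaemic))
  # per-case substreams: case k does not depend on cohort size
  c3 <- generateCohort(nullGenConfig(nMale = 4L, nFemale = 0L), seed = 42)
  expect_identical(cohortTruth(c3)$cmvr_hyper_true[3],
                   cohortTruth(c1)$cmvr_hyper_true[3])
})

test_that("requested sex counts are produced exactly", {
  co <- generateCohort(sexEffectGenConfig(nMale = 109L, nFemale = 35L),
                       seed = 1)
  sexes <- vapply(cohortCases(co), function(cs) cs@sex, "")
  expect_identical(sum(sexes == "male"), 109L)
  expect_identical(sum(sexes == "female"), 35L)
  expect_identical(cohortTruth(co)$sex, sexes)
})

test_that("baseline CMVR dominates hyperaemic when jitter is disabled", {
  cfg <- nullGenConfig(nMale = 30L, nFemale = 30L, baselineSdlog = 0)
  truth <- cohortTruth(generateCohort(cfg, seed = 13))
  expect_true(all(truth$cmvr_base_true >= truth$cmvr_hyper_true))
  expect_equal(truth$cmvr_base_true / truth$cmvr_hyper_true,
               rep(2, nrow(truth)), tolerance = 1e-12)
})

test_that("noiseless full-pipeline recovery is within 2% of hidden truth", {
  cfg <- generatorConfig(nMale = 50L, nFemale = 50L, projectionNoiseSd = 0,
                         useProjections = TRUE, nSamples = 65L)
  co <- generateCohort(cfg, seed = 31)
  run <- runCohort(co, gradientThreshold = 0)
  expect_true(all(run$results$status == "included"))
  relErr <- abs(run$results$cmvr_hyper_wu -
                  cohortTruth(co)$cmvr_hyper_true) /
    cohortTruth(co)$cmvr_hyper_true
  expect_lt(max(relErr), 0.02)
})

test_that("covariate prevalences are matched in large cohorts", {
  cfg <- nullGenConfig(nMale = 400L, nFemale = 100L)
  co <- generateCohort(cfg, seed = 77)
  run <- runCohort(co)
  prev <- cfg@covariatePrev
  for (v in c("smoker", "hypertension", "diabetes")) {
    phat <- mean(run$results[[v]])
    ci <- qbinom(c(0.0005, 0.9995), 500, prev[[v]]) / 500
    expect_gte(phat, ci[1]); expect_lte(phat, ci[2])
  }
  arteries <- table(run$results$artery)
  expect_gt(arteries[["LAD"]], arteries[["LMS"]])
})
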