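test_that("FFR is the hyperaemic distal-to-proximal pressure ratio", {
  expect_equal(computeFFR(pressureRecord(90, 72)), 0.80)
  expect_equal(computeFFR(pressureRecord(81, 64.8)), 0.80)
  expect_equal(computeFFR(pressureRecord(95, 95)), 1.0)
  expect_error(computeFFR(pressureRecord(90, 72, state = "baseline")),
               class = "coroflow_error_invalid_pressures")
})

test_that("CMVR applies hydraulic Ohm's law in Wood units", {
  expect_equal(computeCMVR(Pd = 68, Q = 100), 680)
  expect_equal(computeCMVR(Pd = 86, Q = 100), 860)
  expect_equal(computeCMVR(70, 200), computeCMVR(70, 100) / 2)
  expect_error(computeCMVR(70, 0), class = "coroflow_error_invalid_flow")
  expect_error(computeCMVR(70, -5), class = "coroflow_error_invalid_flow")
})

test_that("CFR is the hyperaemic-to-baseline flow ratio", {
  expect_equal(computeCFR(87, 52), 87 / 52)
  expect_equal(computeCFR(60, 60), 1)
  expect_equal(computeCFR(100, 50), 2)
  expect_error(computeCFR(0, 50), class = "coroflow_error_invalid_flow")
})

test_that("pressure records enforce 0 < Pd <= Pa", {
  expect_error(pressureRecord(90, 95), class = "coroflow_error_invalid_pressures")
  expect_error(pressureRecord(90, 0), class = "coroflow_error_invalid_pressures")
  expect_silent(pressureRecord(90, 90))
})

makeCase <- function(geom = NULL, projections = list(),
                     paH = 90, pdH = 72, paB = 90, pdB = 80,
                     forced = "") {
  new("CaseRecord", caseId = "C001", patientId = "P001", sex = "male",
      artery = "LAD", covariates = list(age = 60, caucasian = TRUE,
        smoker = FALSE, bmi_gt25 = FALSE, hypertension = FALSE,
        dyslipidaemia = FALSE, diabetes = FALSE, lung_disease = FALSE,
        valve_disease = FALSE, prior_mi = FALSE, lvsd = FALSE),
      spec = stenosisSpec(severity = 60), geometry = geom,
      projections = projections,
      pressures = list(baseline = pressureRecord(paB, pdB, "baseline"),
                       hyperaemic = pressureRecord(paH, pdH)),
      forcedFailure = forced)
}

test_that("runCase produces finite positive indices for a nominal case", {
  res <- runCase(makeCase(geom = sixtyPhantom()))
  expect_identical(res$status, "included")
  idx <- res$indices
  expect_true(all(is.finite(c(idx@ffr, idx@cmvrBase, idx@cmvrHyper,
                              idx@cfr, idx@qBase, idx@qHyper))))
  expect_equal(idx@ffr, 0.8)
  # CFR equals the ratio of the two flow results bit for bit
  expect_identical(idx@cfr, idx@qHyper / idx@qBase)
  # Ohm's-law identity round trip
  expect_lt(abs(computeCMVR(72, idx@qHyper) * idx@qHyper / 1000 - 72) / 72,
            1e-12)
})

test_that("runCase maps failures onto the consort taxonomy", {
  # no appreciable gradient (Pa = Pd under hyperaemia) -> inadequate_gradient
  res <- runCase(makeCase(geom = straightTube(), paH = 90, pdH = 90))
  expect_identical(res$status, "inadequate_gradient")
  expect_null(res$indices)

  # gradient below the 2 mmHg wire-drift threshold is also inadequate
  res <- runCase(makeCase(geom = straightTube(), paH = 90, pdH = 89))
  expect_identical(res$status, "inadequate_gradient")

  # views 10 degrees apart -> reconstruction_failure
  ph <- sixtyPhantom()
  res <- runCase(makeCase(projections = list(projectGeometry(ph, c(0, 0)),
                                             projectGeometry(ph, c(10, 0)))))
  expect_identical(res$status, "reconstruction_failure")

  # forced markers pass straight through
  expect_identical(runCase(makeCase(geom = ph, forced = "meshing_failure"))$status,
                   "meshing_failure")
  expect_identical(runCase(makeCase(geom = ph,
                                    forced = "convergence_failure"))$status,
                   "convergence_failure")
})

test_that("consort counts always conserve the submitted total", {
  cfg <- nullGenConfig(nMale = 20L, nFemale = 20L,
                       failureRates = consortRates())
  co <- generateCohort(cfg, seed = 7)
  run <- runCohort(co)
  expect_identical(unname(run$consort[["submitted"]]), nCases(co))
  expect_identical(sum(run$consort[exclusionCategories]),
                   run$consort[["submitted"]])
  expect_identical(nrow(run$exclusions), nCases(co))
  expect_identical(sort(run$exclusions$case_id),
                   sort(vapply(cohortCases(co), function(x) x@caseId, "")))
})

test_that("every case of a valid cohort is included once gradients are accepted", {
  co <- generateCohort(nullGenConfig(nMale = 15L, nFemale = 15L), seed = 3)
  # with the physiological 2 mmHg cut-off a few near-normal arteries drop
  # out organically (mild lesion + high microvascular resistance gives a
  # sub-threshold trans-lesional gradient) -- only ever in that category
  runDefault <- runCohort(co)
  excluded <- runDefault$results$status != "included"
  expect_true(all(runDefault$results$status[excluded] ==
                    "inadequate_gradient"))
  # accepting any positive gradient includes everything
  run <- runCohort(co, gradientThreshold = 0)
  expect_identical(unname(run$consort[["included"]]), 30L)
  expect_true(all(run$results$status == "included"))
})

test_that("injected Pa = Pd cases are excluded as inadequate gradients", {
  co <- generateCohort(nullGenConfig(nMale = 10L, nFemale = 10L), seed = 5)
  for (k in 1:3) {
    cs <- co@cases[[k]]
    cs@pressures$hyperaemic <- pressureRecord(90, 90)
    co@cases[[k]] <- cs
  }
  run <- runCohort(co, gradientThreshold = 0)
  expect_identical(unname(run$consort[["inadequate_gradient"]]), 3L)
  expect_identical(unname(run$consort[["included"]]), 17L)
})

test_that("injected failure rates are recovered within binomial tolerance", {
  rates <- consortRates()
  # moderate fixed severity and dispersion-free CMVR keep every
  # non-injected gradient above threshold, so the consort categories
  # reflect the injections alone
  cfg <- generatorConfig(nMale = 250L, nFemale = 250L,
                         failureRates = rates,
                         cmvrMedian = c(male = 680, female = 680),
                         cmvrSdlog = c(male = 0, female = 0),
                         sevRange = c(55, 65),
                         useProjections = FALSE, nSamples = 33L)
  co <- generateCohort(cfg, seed = 19)
  run <- runCohort(co)
  n <- nCases(co)
  for (cat in names(rates)) {
    k <- run$consort[[cat]]
    ci <- qbinom(c(0.0005, 0.9995), n, rates[[cat]])
    expect_gte(k, ci[1])
    expect_lte(k, ci[2])
  }
  # injected categories match the hidden truth annotations exactly
  truth <- cohortTruth(co)
  inj <- truth$injected_failure[truth$injected_failure != ""]
  expect_identical(sum(run$consort[names(rates)]), length(inj))
})

test_that("applyExclusions separates included rows and keeps the accounting", {
  cfg <- nullGenConfig(nMale = 15L, nFemale = 15L,
                       failureRates = consortRates())
  ae <- applyExclusions(generateCohort(cfg, seed = 23))
  expect_true(all(ae$included$status == "included"))
  expect_identical(nrow(ae$included),
                   unname(ae$consort[["included"]]))
  expect_identical(nrow(ae$results), unname(ae$consort[["submitted"]]))
})
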