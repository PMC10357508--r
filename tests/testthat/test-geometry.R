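test_that("stenosed phantom follows the cosine radius law", {
  # degenerate stenosis: constant radius
  tube <- straightTube()
  expect_true(all(radii(tube) == 1.5))

  # 60% diameter reduction of a 1.5 mm lumen leaves 0.6 mm at the throat
  ph <- sixtyPhantom()
  expect_equal(minRadius(ph), 0.6, tolerance = 1e-12)
  expect_equal(arclength(ph)[which.min(radii(ph))], 15)

  # area reduction identity: 1 - 0.4^2 = 84% of reference area at the throat
  aMin <- pi * minRadius(ph)^2
  aRef <- pi * 1.5^2
  expect_equal(1 - aMin / aRef, 0.84, tolerance = 1e-12)

  # radius returns to r0 outside the stenotic segment
  s <- arclength(ph)
  expect_true(all(radii(ph)[s < 10 | s > 20] == 1.5))
})

test_that("invalid stenosis specs are rejected", {
  expect_error(stenosisSpec(severity = 100), class = "coroflow_error_invalid_spec")
  expect_error(stenosisSpec(severity = -1), class = "coroflow_error_invalid_spec")
  expect_error(stenosisSpec(len = 30, L = 30), class = "coroflow_error_invalid_spec")
  expect_error(stenosisSpec(len = 40, L = 30), class = "coroflow_error_invalid_spec")
  expect_error(makeStenosedPhantom(stenosisSpec(), nSamples = 5),
               class = "coroflow_error_invalid_spec")
})

test_that("projection of an axisymmetric lumen reports true radii as half-widths", {
  ph <- sixtyPhantom()
  for (ang in list(c(0, 0), c(37, 12), c(90, 0))) {
    v <- projectGeometry(ph, ang)
    expect_equal(halfWidths(v), radii(ph))
  }
  # two different views, identical half-width profiles (axisymmetry)
  vA <- projectGeometry(ph, c(0, 0))
  vB <- projectGeometry(ph, c(60, 10))
  expect_identical(halfWidths(vA), halfWidths(vB))
})

test_that("projection noise is seeded and reproducible", {
  ph <- sixtyPhantom()
  set.seed(42); v1 <- projectGeometry(ph, c(0, 0), noiseSd = 0.05)
  set.seed(42); v2 <- projectGeometry(ph, c(0, 0), noiseSd = 0.05)
  expect_identical(halfWidths(v1), halfWidths(v2))
  expect_false(identical(halfWidths(v1), radii(ph)))
  expect_true(all(halfWidths(v1) > 0))
})

test_that("two-view reconstruction recovers a straight cylinder exactly", {
  tube <- straightTube()
  vA <- projectGeometry(tube, c(0, 0))
  vB <- projectGeometry(tube, c(90, 0))
  rec <- reconstructFromTwoViews(vA, vB)
  expect_lt(max(abs(radii(rec) - 1.5)), 1e-9)
  expect_equal(vesselLength(rec), 30, tolerance = 1e-9)
  expect_lt(reprojectionResidual(vA, vB, rec), 1e-9)
})

test_that("noiseless round trip recovers the stenotic radius profile", {
  ph <- sixtyPhantom()
  rec <- reconstructFromTwoViews(projectGeometry(ph, c(0, 0)),
                                 projectGeometry(ph, c(55, 20)))
  expect_lt(abs(minRadius(rec) - 0.6) / 0.6, 0.01)
  # full-profile recovery within 1% relative, arclength within 2%
  expect_lt(max(abs(radii(rec) - radii(ph)) / radii(ph)), 0.01)
  expect_lt(abs(vesselLength(rec) - vesselLength(ph)) / vesselLength(ph),
            0.02)
})

test_that("views closer than 30 degrees are refused", {
  ph <- sixtyPhantom()
  vA <- projectGeometry(ph, c(0, 0))
  vB <- projectGeometry(ph, c(10, 0))
  expect_error(reconstructFromTwoViews(vA, vB),
               class = "coroflow_error_insufficient_separation")
  expect_equal(viewSeparation(vA, vB), 10, tolerance = 1e-9)
  # anti-parallel folding: 170 degrees apart is effectively 10
  vC <- projectGeometry(ph, c(170, 0))
  expect_equal(viewSeparation(vA, vC), 10, tolerance = 1e-9)
})

test_that("mismatched projection extents raise a reconstruction failure", {
  ph <- sixtyPhantom()
  vA <- projectGeometry(ph, c(0, 0))
  vB <- projectGeometry(ph, c(90, 0))
  # truncate view B to the proximal 60% of the vessel
  keep <- vB@t <= 0.6
  vBt <- new("ProjectionView", id = "B", angles = viewAngles(vB),
             t = vB@t[keep], polyline = polyline(vB)[keep, ],
             halfWidth = halfWidths(vB)[keep])
  expect_error(reconstructFromTwoViews(vA, vBt),
               class = "coroflow_error_reconstruction_failure")
})

test_that("reconstruction error shrinks with projection noise, on average", {
  noiseLevels <- c(0.1, 0.05, 0)
  meanErr <- vapply(noiseLevels, function(sd) {
    errs <- vapply(1:50, function(k) {
      set.seed(1000 + k)
      sev <- runif(1, 35, 80)
      ph <- makeStenosedPhantom(stenosisSpec(severity = sev), 65L)
      rec <- reconstructFromTwoViews(projectGeometry(ph, c(0, 0), sd),
                                     projectGeometry(ph, c(90, 0), sd))
      mean(abs(radii(rec) - radii(ph)) / radii(ph))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(meanErr) < 0))
})

test_that("geometry and projection files round-trip through CSV", {
  ph <- sixtyPhantom(33L)
  gpath <- withr::local_tempfile(fileext = ".csv")
  writeGeometryCsv(ph, gpath, comment = "fixture")
  ph2 <- readGeometryCsv(gpath)
  expect_equal(radii(ph2), radii(ph), tolerance = 1e-12)
  expect_equal(arclength(ph2), arclength(ph), tolerance = 1e-12)

  v <- projectGeometry(ph, c(35, 5), noiseSd = 0)
  ppath <- withr::local_tempfile(fileext = ".csv")
  writeProjectionCsv(v, ppath)
  v2 <- readProjectionCsv(ppath)
  expect_equal(viewAngles(v2), c(35, 5))
  expect_equal(halfWidths(v2), halfWidths(v), tolerance = 1e-12)
})
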