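#' @include AllClasses.R AllGenerics.R geometry.R flow_reduced.R
NULL

#' Construct a synthetic cohort generator configuration
#'
#' See \linkS4class{GeneratorConfig} for the meaning and provenance of the
#' defaults (sex-specific lognormal hyperaemic CMVR, severity and pressure
#' distributions, covariate prevalences and artery frequencies matching the
#' emulated study population of 144 patients).
#'
#' @param nMale,nFemale patient counts
#' @param cmvrMedian hyperaemic CMVR medians (WU), named male/female
#' @param cmvrSdlog lognormal sdlog per sex; defaults calibrated so the
#'   quartile ratio matches the emulated interquartile ranges
#'   (865/520 male, 1205/650 female)
#' @param baselineRatio baseline-to-hyperaemic CMVR ratio
#' @param baselineSdlog per-case lognormal jitter of that ratio (0 disables)
#' @param paMean,paSd,paMin aortic pressure distribution (mmHg)
#' @param sevMean,sevSd,sevRange stenosis severity (percent diameter)
#' @param r0Mean,r0Sd,r0Range reference radius (mm)
#' @param vesselLength,stenosisLength segment lengths (mm)
#' @param projectionNoiseSd half-width noise sd (mm)
#' @param viewAngles list of two length-2 angle pairs (degrees)
#' @param nSamples centerline samples per geometry
#' @param failureRates named injection rates (see \code{\link{consortRates}})
#' @param arteryProbs named sampling weights over LAD/RCA/LCx/Dx/OM/LMS
#' @param covariatePrev named covariate prevalences
#' @param ageMean,ageSd age distribution (years)
#' @param useProjections whether cases carry projections (TRUE) or the
#'   geometry itself (FALSE)
#' @return a \linkS4class{GeneratorConfig}
#' @export
generatorConfig <- function(
    nMale = 109L, nFemale = 35L,
    cmvrMedian = c(male = 680, female = 860),
    cmvrSdlog = c(male = 0.377, female = 0.458),
    baselineRatio = 2.0, baselineSdlog = 0.25,
    paMean = 92, paSd = 10, paMin = 60,
    sevMean = 60, sevSd = 15, sevRange = c(35, 90),
    r0Mean = 1.5, r0Sd = 0.2, r0Range = c(1.0, 2.0),
    vesselLength = 30, stenosisLength = 10,
    projectionNoiseSd = 0, viewAngles = list(c(0, 0), c(90, 0)),
    nSamples = 129L,
    failureRates = c(inadequate_gradient = 0, reconstruction_failure = 0,
                     meshing_failure = 0, convergence_failure = 0),
    arteryProbs = c(LAD = 103, RCA = 45, LCx = 26, Dx = 17, OM = 7,
                    LMS = 5) / 203,
    covariatePrev = c(caucasian = 0.90, smoker = 0.63, bmi_gt25 = 0.64,
                      hypertension = 0.65, dyslipidaemia = 0.76,
                      diabetes = 0.26, lung_disease = 0.11,
                      valve_disease = 0.05, prior_mi = 0.25, lvsd = 0.20),
    ageMean = 65, ageSd = 10, useProjections = TRUE) {
  fr <- c(inadequate_gradient = 0, reconstruction_failure = 0,
          meshing_failure = 0, convergence_failure = 0)
  fr[names(failureRates)] <- as.numeric(failureRates)
  asNum <- function(x) stats::setNames(as.numeric(x), names(x))
  cmvrMedian <- asNum(cmvrMedian); cmvrSdlog <- asNum(cmvrSdlog)
  arteryProbs <- asNum(arteryProbs); covariatePrev <- asNum(covariatePrev)
  obj <- new("GeneratorConfig",
             nMale = as.integer(nMale), nFemale = as.integer(nFemale),
             cmvrMedian = cmvrMedian, cmvrSdlog = cmvrSdlog,
             baselineRatio = as.numeric(baselineRatio),
             baselineSdlog = as.numeric(baselineSdlog),
             paMean = as.numeric(paMean), paSd = as.numeric(paSd),
             paMin = as.numeric(paMin), sevMean = as.numeric(sevMean),
             sevSd = as.numeric(sevSd), sevRange = as.numeric(sevRange),
             r0Mean = as.numeric(r0Mean), r0Sd = as.numeric(r0Sd),
             r0Range = as.numeric(r0Range),
             vesselLength = as.numeric(vesselLength),
             stenosisLength = as.numeric(stenosisLength),
             projectionNoiseSd = as.numeric(projectionNoiseSd),
             viewAngles = viewAngles,
             nSamples = as.integer(nSamples), failureRates = fr,
             arteryProbs = arteryProbs, covariatePrev = covariatePrev,
             ageMean = as.numeric(ageMean), ageSd = as.numeric(ageSd),
             useProjections = isTRUE(useProjections))
  validObject(obj)
  obj
}

#' Failure-injection rates emulating the study-scale consort accounting
#'
#' Out of 256 submitted arterial cases the emulated workflow excluded 20 for
#' inadequate pressure gradients, 19 for inadequate angiographic views, 7
#' for meshing failure and 7 for solver non-convergence; these proportions
#' are returned as injection rates.
#'
#' @return named numeric rates
#' @export
consortRates <- function() {
  c(inadequate_gradient = 20 / 256, reconstruction_failure = 19 / 256,
    meshing_failure = 7 / 256, convergence_failure = 7 / 256)
}

## truncated normal draw via inverse-CDF on a restricted uniform; keeps the
## draw count per case fixed so substreams stay aligned
rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Draw ground-truth physiology for one case
#'
#' Hyperaemic CMVR is lognormal with the configured sex-specific median;
#' baseline CMVR is the hyperaemic value times the configured ratio times a
#' median-one lognormal per-case jitter; aortic pressure is drawn per state
#' from a truncated normal. Uses the session RNG.
#'
#' @param cfg a \linkS4class{GeneratorConfig}
#' @param sex "male" or "female"
#' @return list with \code{cmvrHyper}, \code{cmvrBase} (WU), \code{paBase},
#'   \code{paHyper} (mmHg)
#' @export
sampleTruePhysiology <- function(cfg, sex = c("male", "female")) {
  sex <- match.arg(sex)
  cmvrHyper <- stats::rlnorm(1, log(cfg@cmvrMedian[[sex]]),
                             cfg@cmvrSdlog[[sex]])
  jitter <- if (cfg@baselineSdlog > 0)
    stats::rlnorm(1, 0, cfg@baselineSdlog) else 1
  cmvrBase <- cmvrHyper * cfg@baselineRatio * jitter
  pa <- rtruncnorm1(2, cfg@paMean, cfg@paSd, lo = cfg@paMin)
  list(cmvrHyper = cmvrHyper, cmvrBase = cmvrBase,
       paBase = pa[1], paHyper = pa[2])
}

#' Self-consistent pressures and flow for a stenosis in series with a
#' microvascular bed
#'
#' Solves the series circuit: the epicardial pressure drop follows the
#' quadratic lumen model while the microvascular bed obeys Ohm's law,
#' \eqn{P_a - aQ - bQ^2 = P_d = CMVR \cdot Q / 1000}. For non-negative
#' a and b a unique positive root exists in closed form.
#'
#' @param geom a \linkS4class{VesselGeometry}
#' @param Pa aortic (inlet) pressure, mmHg
#' @param cmvrTrue microvascular resistance (WU)
#' @param fluid a \linkS4class{FluidProperties}
#' @param Ke separation-loss coefficient
#' @return list with \code{Pd} (mmHg) and \code{Q} (ml/min)
#' @export
forwardSeriesSolve <- function(geom, Pa, cmvrTrue,
                               fluid = fluidProperties(), Ke = 1.52) {
  stopifnot(Pa > 0, cmvrTrue > 0)
  a <- viscousCoefficient(geom, fluid)
  b <- expansionCoefficient(geom, fluid, Ke)
  Q <- positiveRoot(a + cmvrTrue / 1000, b, Pa)
  Pd <- cmvrTrue * Q / 1000
  stopifnot(Q > 0, Pd > 0, Pd < Pa)
  list(Pd = Pd, Q = Q)
}

## Deterministic per-case substreams: the master seed generates one
## well-scrambled sub-seed per case, so case k is invariant to cohort
## ordering (and to cohort size, for a given k). Linear seed formulas are
## avoided deliberately -- related Mersenne-Twister seeds yield correlated
## early draws, which measurably distorts cohort-level statistics.
caseSeeds <- function(seed, n) {
  set.seed(as.integer(seed %% 2147483647))
  sample.int(2147483646L, n)
}

#' Generate a synthetic cohort with hidden ground truth
#'
#' Produces \code{nMale + nFemale} virtual patients (one artery each):
#' covariates at the configured prevalences, arteries at the configured
#' frequencies, a stenosed phantom per case, ground-truth microvascular
#' resistance per state, and pressures made self-consistent with the series
#' stenosis + microvasculature circuit via
#' \code{\link{forwardSeriesSolve}}. Cases carry either two (optionally
#' noisy) projections or the geometry itself. Failure modes are injected at
#' the configured rates: minimal-disease cases for inadequate gradients
#' (severity 0 in a wide reference lumen), views 15 degrees apart for
#' reconstruction failures, and forced markers for meshing/convergence
#' failures. All randomness derives from \code{seed} through per-case
#' substreams, so the cohort is reproducible case by case.
#'
#' @param cfg a \linkS4class{GeneratorConfig}
#' @param seed integer seed
#' @return a \linkS4class{Cohort}; the hidden truth table is only for test
#'   harnesses and accuracy summaries, never for pipeline operations
#' @export
generateCohort <- function(cfg = generatorConfig(), seed = 1L) {
  nTot <- cfg@nMale + cfg@nFemale
  sexes <- rep(c("male", "female"), c(cfg@nMale, cfg@nFemale))
  cases <- vector("list", nTot)
  tr <- list(case_id = character(nTot), sex = sexes,
             cmvr_hyper_true = numeric(nTot), cmvr_base_true = numeric(nTot),
             q_hyper_true = numeric(nTot), q_base_true = numeric(nTot),
             pd_hyper_true = numeric(nTot), pd_base_true = numeric(nTot),
             injected_failure = character(nTot))
  covNames <- names(cfg@covariatePrev)
  frNames <- names(cfg@failureRates)
  cumRates <- cumsum(cfg@failureRates)
  subSeeds <- caseSeeds(seed, nTot)

  for (k in seq_len(nTot)) {
    set.seed(subSeeds[k])
    sex <- sexes[k]
    caseId <- sprintf("C%03d", k)
    patientId <- sprintf("P%03d", k)

    cov <- as.list(stats::runif(length(covNames)) < cfg@covariatePrev)
    names(cov) <- covNames
    cov$age <- round(stats::rnorm(1, cfg@ageMean, cfg@ageSd))
    artery <- sample(names(cfg@arteryProbs), 1, prob = cfg@arteryProbs)

    uFail <- stats::runif(1)
    injected <- ""
    if (any(uFail < cumRates)) injected <- frNames[which(uFail < cumRates)[1]]

    sev <- rtruncnorm1(1, cfg@sevMean, cfg@sevSd,
                       cfg@sevRange[1], cfg@sevRange[2])
    r0 <- rtruncnorm1(1, cfg@r0Mean, cfg@r0Sd,
                      cfg@r0Range[1], cfg@r0Range[2])
    if (injected == "inadequate_gradient") {
      ## minimal epicardial disease: no focal narrowing, wide reference
      ## lumen, so the trans-lesional gradient stays below wire drift
      sev <- 0; r0 <- cfg@r0Range[2]
    }
    spec <- stenosisSpec(r0 = r0, L = cfg@vesselLength,
                         len = cfg@stenosisLength,
                         severity = sev)
    geom <- makeStenosedPhantom(spec, cfg@nSamples)

    phys <- sampleTruePhysiology(cfg, sex)
    fwdB <- forwardSeriesSolve(geom, phys$paBase, phys$cmvrBase)
    fwdH <- forwardSeriesSolve(geom, phys$paHyper, phys$cmvrHyper)
    pressures <- list(
      baseline = pressureRecord(phys$paBase, fwdB$Pd, "baseline"),
      hyperaemic = pressureRecord(phys$paHyper, fwdH$Pd, "hyperaemic"))

    angles <- cfg@viewAngles
    carriesProjections <- cfg@useProjections
    if (injected == "reconstruction_failure") {
      angles <- list(c(0, 0), c(15, 0))   # below the 30 degree criterion
      carriesProjections <- TRUE
    }
    projections <- list()
    geometrySlot <- geom
    if (carriesProjections) {
      projections <- list(
        projectGeometry(geom, angles[[1]], cfg@projectionNoiseSd, "A"),
        projectGeometry(geom, angles[[2]], cfg@projectionNoiseSd, "B"))
      geometrySlot <- NULL
    }
    forced <- if (injected %in% c("meshing_failure", "convergence_failure"))
      injected else ""

    cases[[k]] <- new("CaseRecord", caseId = caseId, patientId = patientId,
                      sex = sex, artery = artery, covariates = cov,
                      spec = spec, geometry = geometrySlot,
                      projections = projections, pressures = pressures,
                      forcedFailure = forced)
    tr$case_id[k] <- caseId
    tr$cmvr_hyper_true[k] <- phys$cmvrHyper
    tr$cmvr_base_true[k] <- phys$cmvrBase
    tr$q_hyper_true[k] <- fwdH$Q; tr$q_base_true[k] <- fwdB$Q
    tr$pd_hyper_true[k] <- fwdH$Pd; tr$pd_base_true[k] <- fwdB$Pd
    tr$injected_failure[k] <- injected
  }
  new("Cohort", cases = cases, truth = as.data.frame(tr,
                                                     stringsAsFactors = FALSE),
      config = cfg, seed = as.integer(seed))
}
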