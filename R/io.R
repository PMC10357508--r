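#' @include AllClasses.R AllGenerics.R geometry.R physiology.R cohort.R stats.R
NULL

pkgVersion <- function() {
  as.character(utils::packageVersion("coroflow"))
}

## md5 of the canonical JSON serialization of a config-like list; used so
## every output artifact records which configuration produced it
configHash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

generatorConfigList <- function(cfg) {
  list(nMale = cfg@nMale, nFemale = cfg@nFemale,
       cmvrMedian = as.list(cfg@cmvrMedian),
       cmvrSdlog = as.list(cfg@cmvrSdlog),
       baselineRatio = cfg@baselineRatio, baselineSdlog = cfg@baselineSdlog,
       paMean = cfg@paMean, paSd = cfg@paSd, paMin = cfg@paMin,
       sevMean = cfg@sevMean, sevSd = cfg@sevSd, sevRange = cfg@sevRange,
       r0Mean = cfg@r0Mean, r0Sd = cfg@r0Sd, r0Range = cfg@r0Range,
       vesselLength = cfg@vesselLength, stenosisLength = cfg@stenosisLength,
       projectionNoiseSd = cfg@projectionNoiseSd,
       viewAngles = cfg@viewAngles, nSamples = cfg@nSamples,
       failureRates = as.list(cfg@failureRates),
       arteryProbs = as.list(cfg@arteryProbs),
       covariatePrev = as.list(cfg@covariatePrev),
       ageMean = cfg@ageMean, ageSd = cfg@ageSd,
       useProjections = cfg@useProjections)
}

#' Read a generator configuration from YAML
#'
#' Any subset of the \code{\link{generatorConfig}} arguments may be given;
#' missing keys keep their defaults.
#'
#' @param path YAML file
#' @return a \linkS4class{GeneratorConfig}
#' @export
readGeneratorConfigYaml <- function(path) {
  if (!file.exists(path))
    cfStop("coroflow_error_io", sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw))
    cfStop("coroflow_error_io", "generator config must be a YAML mapping")
  for (nm in c("cmvrMedian", "cmvrSdlog", "failureRates", "arteryProbs",
               "covariatePrev"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  known <- names(formals(generatorConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    cfStop("coroflow_error_io", sprintf("unknown config keys: %s",
                                        paste(unknown, collapse = ", ")))
  do.call(generatorConfig, raw)
}

#' Read a solver configuration from YAML or JSON
#'
#' Keys: \code{backend, nx, nr, tol, max_iter, K_e, mu, rho}; missing keys
#' keep defaults. \code{mu} and \code{rho} are returned as an attached
#' \linkS4class{FluidProperties}.
#'
#' @param path YAML or JSON file
#' @return list with \code{solver} (\linkS4class{SolverConfig}) and
#'   \code{fluid} (\linkS4class{FluidProperties})
#' @export
readSolverConfig <- function(path) {
  if (!file.exists(path))
    cfStop("coroflow_error_io", sprintf("config file '%s' not found", path))
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.list(raw)) cfStop("coroflow_error_io", "solver config must be a mapping")
  solver <- solverConfig(
    backend = raw$backend %||% "reduced_order",
    nx = raw$nx %||% 64L, nr = raw$nr %||% 16L,
    tol = raw$tol %||% 1e-6, maxIter = raw$max_iter %||% 10000L,
    Ke = raw$K_e %||% 1.52)
  fluid <- fluidProperties(mu = raw$mu %||% 0.0035, rho = raw$rho %||% 1056)
  list(solver = solver, fluid = fluid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

outputHeader <- function(seed, hash) {
  sprintf("coroflow %s seed=%s config_md5=%s", pkgVersion(), seed, hash)
}

#' Write a generated cohort to files
#'
#' Writes \code{cohort.csv} (one row per case: identifiers, covariates,
#' stenosis parameters and the per-state pressures), per-case projection or
#' geometry files under \code{projections/} / \code{geometries/}, and the
#' hidden ground truth to \code{truth.json} as a separate sidecar so the
#' pipeline never needs to touch it. Every file carries a header comment
#' with tool version, seed and config hash; outputs are deterministic for a
#' given cohort.
#'
#' @param cohort a \linkS4class{Cohort}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writeCohortFiles <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(generatorConfigList(cohort@config))
  hdr <- outputHeader(cohort@seed, hash)
  rows <- lapply(cohort@cases, function(cs) {
    pb <- cs@pressures$baseline; ph <- cs@pressures$hyperaemic
    data.frame(case_id = cs@caseId, patient_id = cs@patientId, sex = cs@sex,
               artery = cs@artery, age = cs@covariates$age,
               caucasian = cs@covariates$caucasian,
               smoker = cs@covariates$smoker,
               bmi_gt25 = cs@covariates$bmi_gt25,
               hypertension = cs@covariates$hypertension,
               dyslipidaemia = cs@covariates$dyslipidaemia,
               diabetes = cs@covariates$diabetes,
               lung_disease = cs@covariates$lung_disease,
               valve_disease = cs@covariates$valve_disease,
               prior_mi = cs@covariates$prior_mi, lvsd = cs@covariates$lvsd,
               r0_mm = cs@spec@r0, length_mm = cs@spec@L,
               stenosis_centre_mm = cs@spec@centre,
               stenosis_length_mm = cs@spec@len,
               stenosis_pct = cs@spec@severity,
               pa_base_mmhg = proximalPressure(pb),
               pd_base_mmhg = distalPressure(pb),
               pa_hyper_mmhg = proximalPressure(ph),
               pd_hyper_mmhg = distalPressure(ph),
               input = if (is.null(cs@geometry)) "projections" else "geometry",
               forced_failure = cs@forcedFailure, stringsAsFactors = FALSE)
  })
  writeCsvWithHeader(do.call(rbind, rows), file.path(dir, "cohort.csv"), hdr)
  for (cs in cohort@cases) {
    if (!is.null(cs@geometry)) {
      gd <- file.path(dir, "geometries")
      dir.create(gd, showWarnings = FALSE)
      writeGeometryCsv(cs@geometry, file.path(gd, paste0(cs@caseId, ".csv")),
                       hdr)
    } else {
      pd <- file.path(dir, "projections", cs@caseId)
      dir.create(pd, recursive = TRUE, showWarnings = FALSE)
      writeProjectionCsv(cs@projections[[1]], file.path(pd, "viewA.csv"), hdr)
      writeProjectionCsv(cs@projections[[2]], file.path(pd, "viewB.csv"), hdr)
    }
  }
  truth <- list(header = hdr, truth = cohort@truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfgOut <- c(list(header = hdr, seed = cohort@seed),
              generatorConfigList(cohort@config))
  jsonlite::write_json(cfgOut, file.path(dir, "generator_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort back from files
#'
#' Rebuilds \linkS4class{CaseRecord}s from \code{cohort.csv} plus the
#' per-case geometry/projection files. The hidden truth sidecar is only
#' loaded when \code{withTruth = TRUE}.
#'
#' @param dir directory written by \code{\link{writeCohortFiles}}
#' @param withTruth also load \code{truth.json}
#' @return a \linkS4class{Cohort} (config slot is NULL; the seed is read
#'   from \code{generator_config.json} when present)
#' @export
readCohortFiles <- function(dir, withTruth = FALSE) {
  cpath <- file.path(dir, "cohort.csv")
  if (!file.exists(cpath))
    cfStop("coroflow_error_io", sprintf("no cohort.csv under '%s'", dir))
  df <- utils::read.csv(cpath, comment.char = "#")
  cases <- lapply(seq_len(nrow(df)), function(k) {
    rw <- df[k, ]
    spec <- stenosisSpec(r0 = rw$r0_mm, L = rw$length_mm,
                         centre = rw$stenosis_centre_mm,
                         len = rw$stenosis_length_mm,
                         severity = rw$stenosis_pct)
    geom <- NULL; projections <- list()
    if (rw$input == "geometry") {
      geom <- readGeometryCsv(file.path(dir, "geometries",
                                        paste0(rw$case_id, ".csv")))
    } else {
      pd <- file.path(dir, "projections", rw$case_id)
      projections <- list(readProjectionCsv(file.path(pd, "viewA.csv")),
                          readProjectionCsv(file.path(pd, "viewB.csv")))
    }
    cov <- list(age = rw$age, caucasian = rw$caucasian, smoker = rw$smoker,
                bmi_gt25 = rw$bmi_gt25, hypertension = rw$hypertension,
                dyslipidaemia = rw$dyslipidaemia, diabetes = rw$diabetes,
                lung_disease = rw$lung_disease,
                valve_disease = rw$valve_disease, prior_mi = rw$prior_mi,
                lvsd = rw$lvsd)
    new("CaseRecord", caseId = rw$case_id, patientId = rw$patient_id,
        sex = rw$sex, artery = rw$artery, covariates = cov, spec = spec,
        geometry = geom, projections = projections,
        pressures = list(
          baseline = pressureRecord(rw$pa_base_mmhg, rw$pd_base_mmhg,
                                    "baseline"),
          hyperaemic = pressureRecord(rw$pa_hyper_mmhg, rw$pd_hyper_mmhg,
                                      "hyperaemic")),
        forcedFailure = if (is.na(rw$forced_failure)) ""
                        else as.character(rw$forced_failure))
  })
  truth <- data.frame()
  if (withTruth) {
    tpath <- file.path(dir, "truth.json")
    if (file.exists(tpath))
      truth <- jsonlite::read_json(tpath, simplifyVector = TRUE)$truth
  }
  seed <- 0L
  gc <- file.path(dir, "generator_config.json")
  if (file.exists(gc))
    seed <- as.integer(jsonlite::read_json(gc, simplifyVector = TRUE)$seed)
  new("Cohort", cases = cases, truth = truth, config = NULL, seed = seed)
}

#' Write pipeline results and reports
#'
#' @param results results data.frame from \code{\link{runCohort}}
#' @param path output file
#' @param seed seed recorded in the header
#' @param hash config hash recorded in the header
#' @return the path, invisibly
#' @name results-io
NULL

#' @rdname results-io
#' @export
writeResultsCsv <- function(results, path, seed = NA, hash = "none") {
  writeCsvWithHeader(results, path, outputHeader(seed, hash))
  invisible(path)
}

#' @rdname results-io
#' @export
readResultsCsv <- function(path) {
  if (!file.exists(path))
    cfStop("coroflow_error_io", sprintf("results file '%s' not found", path))
  utils::read.csv(path, comment.char = "#")
}

#' @param report data.frame from \code{\link{subgroupReport}}
#' @param csvPath,mdPath output files (either may be NULL)
#' @rdname results-io
#' @export
writeSubgroupReport <- function(report, csvPath = NULL, mdPath = NULL,
                                seed = NA, hash = "none") {
  if (!is.null(csvPath))
    writeCsvWithHeader(report, csvPath, outputHeader(seed, hash))
  if (!is.null(mdPath)) {
    fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 4,
                                                    format = "g"))
    lines <- c(
      sprintf("<!-- %s -->", outputHeader(seed, hash)),
      "| variable | group A | group B | test | statistic | p | effect size | significant |",
      "|---|---|---|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %s | %s | %s | %s | %s |",
              report$variable, report$group_a_summary,
              report$group_b_summary, report$test, fmt(report$statistic),
              fmt(report$p), fmt(report$effect_size),
              ifelse(report$significant, "yes", "no")),
      "",
      paste("Each row is tested at nominal two-tailed alpha = 0.05 with no",
            "multiplicity correction; interpret marginal p-values",
            "accordingly."))
    writeLines(lines, mdPath)
  }
  invisible(csvPath %||% mdPath)
}
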