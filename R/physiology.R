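#' @include AllClasses.R AllGenerics.R flow_reduced.R
NULL

#' Physiological indices for one artery
#'
#' Houses the two index equations: the hydraulic equivalent of Ohm's law
#' \eqn{CMVR = 1000\, P_d / Q} (Wood units; the factor 1000 converts ml/min
#' to L/min) and \eqn{CFR = Q_{hyper} / Q_{base}}, plus the standard
#' \eqn{FFR = P_d / P_a} under hyperaemia.
#'
#' @slot ffr fractional flow reserve, in (0, 1]
#' @slot cmvrBase,cmvrHyper microvascular resistance per state (WU)
#' @slot cfr coronary flow reserve
#' @slot qBase,qHyper absolute flow per state (ml/min)
#' @exportClass PhysioIndices
setClass("PhysioIndices",
  representation(ffr = "numeric", cmvrBase = "numeric", cmvrHyper = "numeric",
                 cfr = "numeric", qBase = "numeric", qHyper = "numeric"))

setValidity("PhysioIndices", function(object) {
  msg <- character()
  if (!(object@ffr > 0 && object@ffr <= 1)) msg <- c(msg, "FFR must lie in (0, 1]")
  if (object@cmvrBase <= 0 || object@cmvrHyper <= 0)
    msg <- c(msg, "CMVR must be positive")
  if (object@cfr <= 0) msg <- c(msg, "CFR must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhysioIndices", function(object) {
  cat(sprintf(
    paste0("PhysioIndices: FFR %.3f | CMVR %0.f (baseline) / %0.f ",
           "(hyperaemic) WU | CFR %.2f | Q %.1f / %.1f ml/min\n"),
    object@ffr, object@cmvrBase, object@cmvrHyper, object@cfr,
    object@qBase, object@qHyper))
})

#' Fractional flow reserve from a hyperaemic pressure pair
#'
#' @param p a hyperaemic \linkS4class{PressureRecord}
#' @return Pd/Pa, in (0, 1]
#' @examples
#' computeFFR(pressureRecord(Pa = 90, Pd = 72))  # 0.80
#' @export
computeFFR <- function(p) {
  stopifnot(is(p, "PressureRecord"))
  if (pressureState(p) != "hyperaemic")
    cfStop("coroflow_error_invalid_pressures",
           "FFR is defined under hyperaemia")
  if (proximalPressure(p) <= 0)
    cfStop("coroflow_error_invalid_pressures", "Pa must be positive")
  distalPressure(p) / proximalPressure(p)
}

#' Coronary microvascular resistance (Wood units)
#'
#' Hydraulic Ohm's law on the microvascular compartment: distal pressure
#' over absolute flow, \eqn{1000 P_d / Q}, in mmHg min/L.
#'
#' @param Pd distal pressure (mmHg)
#' @param Q absolute flow (ml/min), positive
#' @return CMVR in Wood units
#' @examples
#' computeCMVR(Pd = 68, Q = 100)  # 680 WU
#' @export
computeCMVR <- function(Pd, Q) {
  if (any(Q <= 0))
    cfStop("coroflow_error_invalid_flow", "flow must be positive")
  1000 * Pd / Q
}

#' Coronary flow reserve
#'
#' @param qHyper,qBase hyperaemic and baseline flow (ml/min), both positive
#' @return CFR = qHyper / qBase
#' @export
computeCFR <- function(qHyper, qBase) {
  if (any(qHyper <= 0) || any(qBase <= 0))
    cfStop("coroflow_error_invalid_flow", "flows must be positive")
  qHyper / qBase
}

exclusionCategories <- c("inadequate_gradient", "reconstruction_failure",
                         "meshing_failure", "convergence_failure", "included")

#' Run the full per-case workflow
#'
#' Reconstructs the lumen if the case carries projections, solves the flow
#' for both physiological states and derives the indices. Any stage failure
#' is mapped onto the consort exclusion taxonomy and returned as a log
#' entry; failures are never silently dropped. A case whose hyperaemic
#' pressure gradient is below \code{gradientThreshold} (default 2 mmHg,
#' below pressure-wire drift tolerance) is excluded as
#' \code{inadequate_gradient}, because without an epicardial gradient the
#' flow is unidentifiable.
#'
#' @param case a \linkS4class{CaseRecord}
#' @param cfg a \linkS4class{SolverConfig}
#' @param fluid a \linkS4class{FluidProperties}
#' @param gradientThreshold minimal hyperaemic Pa - Pd (mmHg) for inclusion
#' @return list with elements \code{indices} (a
#'   \linkS4class{PhysioIndices}, or NULL when excluded), \code{status}
#'   (one of the consort categories or "included"), \code{detail} and
#'   \code{log} (one-row data.frame for the exclusion log)
#' @export
runCase <- function(case, cfg = solverConfig(), fluid = fluidProperties(),
                    gradientThreshold = 2) {
  stopifnot(is(case, "CaseRecord"))
  out <- function(status, detail = "", indices = NULL)
    list(indices = indices, status = status, detail = detail,
         log = data.frame(case_id = case@caseId, category = status,
                          detail = detail, stringsAsFactors = FALSE))

  if (case@forcedFailure == "meshing_failure")
    return(out("meshing_failure", "volumetric meshing failed"))

  geom <- case@geometry
  if (is.null(geom)) {
    if (length(case@projections) != 2)
      return(out("reconstruction_failure", "case carries no usable views"))
    geom <- tryCatch(
      reconstructFromTwoViews(case@projections[[1]], case@projections[[2]]),
      coroflow_error = function(e) e)
    if (is(geom, "condition"))
      return(out("reconstruction_failure", conditionMessage(geom)))
  }

  hyper <- case@pressures[["hyperaemic"]]
  base <- case@pressures[["baseline"]]
  gradH <- proximalPressure(hyper) - distalPressure(hyper)
  gradB <- proximalPressure(base) - distalPressure(base)
  if (gradH < gradientThreshold || gradB <= 0)
    return(out("inadequate_gradient",
               sprintf("hyperaemic gradient %.2f mmHg below %.2f",
                       gradH, gradientThreshold)))

  if (case@forcedFailure == "convergence_failure")
    return(out("convergence_failure", "CFD simulation did not converge"))

  solveState <- function(p) tryCatch(
    solveFlow(geom, proximalPressure(p), distalPressure(p), fluid, cfg),
    coroflow_error = function(e) e)
  fH <- solveState(hyper)
  if (is(fH, "condition")) return(mapSolverFailure(fH, out))
  fB <- solveState(base)
  if (is(fB, "condition")) return(mapSolverFailure(fB, out))

  idx <- new("PhysioIndices",
             ffr = computeFFR(hyper),
             cmvrBase = computeCMVR(distalPressure(base), flowRate(fB)),
             cmvrHyper = computeCMVR(distalPressure(hyper), flowRate(fH)),
             cfr = computeCFR(flowRate(fH), flowRate(fB)),
             qBase = flowRate(fB), qHyper = flowRate(fH))
  vb <- validObject(idx, test = TRUE)
  if (!isTRUE(vb))
    return(out("convergence_failure", paste("implausible indices:", vb)))
  if (idx@cmvrBase < idx@cmvrHyper)
    attr(idx, "note") <- "baseline CMVR below hyperaemic (logged, not enforced)"
  out("included", "", indices = idx)
}

mapSolverFailure <- function(e, out) {
  if (inherits(e, "coroflow_error_inadequate_gradient"))
    out("inadequate_gradient", conditionMessage(e))
  else out("convergence_failure", conditionMessage(e))
}

#' Run a cohort through the pipeline with consort accounting
#'
#' Applies \code{\link{runCase}} to every case, assembles one results row
#' per submitted artery (excluded cases keep their row with NA indices and
#' their exclusion category in \code{status}) and tallies the consort
#' summary. Counts always conserve the submitted case total.
#'
#' @param cohort a \linkS4class{Cohort}
#' @param cfg a \linkS4class{SolverConfig}
#' @param fluid a \linkS4class{FluidProperties}
#' @param gradientThreshold see \code{\link{runCase}}
#' @return list with \code{results} (data.frame), \code{consort} (named
#'   counts per category plus \code{submitted}) and \code{exclusions}
#'   (the per-case log)
#' @export
runCohort <- function(cohort, cfg = solverConfig(),
                      fluid = fluidProperties(), gradientThreshold = 2) {
  stopifnot(is(cohort, "Cohort"))
  nC <- nCases(cohort)
  num <- function() rep(NA_real_, nC)
  chr <- function() character(nC)
  out <- list(case_id = chr(), patient_id = chr(), sex = chr(),
              artery = chr(), ffr = num(), stenosis_pct = num(),
              q_base_mlmin = num(), q_hyper_mlmin = num(),
              cmvr_base_wu = num(), cmvr_hyper_wu = num(), cfr = num(),
              status = chr(), age = num(), caucasian = logical(nC),
              smoker = logical(nC), bmi_gt25 = logical(nC),
              hypertension = logical(nC), dyslipidaemia = logical(nC),
              diabetes = logical(nC), lung_disease = logical(nC),
              valve_disease = logical(nC), prior_mi = logical(nC),
              lvsd = logical(nC))
  detail <- chr()
  for (k in seq_len(nC)) {
    cs <- cohort@cases[[k]]
    res <- runCase(cs, cfg, fluid, gradientThreshold)
    idx <- res$indices
    cov <- cs@covariates
    out$case_id[k] <- cs@caseId; out$patient_id[k] <- cs@patientId
    out$sex[k] <- cs@sex; out$artery[k] <- cs@artery
    out$stenosis_pct[k] <- cs@spec@severity
    out$status[k] <- res$status
    detail[k] <- res$detail
    if (!is.null(idx)) {
      out$ffr[k] <- idx@ffr; out$q_base_mlmin[k] <- idx@qBase
      out$q_hyper_mlmin[k] <- idx@qHyper
      out$cmvr_base_wu[k] <- idx@cmvrBase
      out$cmvr_hyper_wu[k] <- idx@cmvrHyper; out$cfr[k] <- idx@cfr
    }
    out$age[k] <- cov$age; out$caucasian[k] <- cov$caucasian
    out$smoker[k] <- cov$smoker; out$bmi_gt25[k] <- cov$bmi_gt25
    out$hypertension[k] <- cov$hypertension
    out$dyslipidaemia[k] <- cov$dyslipidaemia
    out$diabetes[k] <- cov$diabetes
    out$lung_disease[k] <- cov$lung_disease
    out$valve_disease[k] <- cov$valve_disease
    out$prior_mi[k] <- cov$prior_mi; out$lvsd[k] <- cov$lvsd
  }
  results <- as.data.frame(out, stringsAsFactors = FALSE)
  exclusions <- data.frame(case_id = out$case_id, category = out$status,
                           detail = detail, stringsAsFactors = FALSE)
  consort <- vapply(exclusionCategories, function(cat)
    sum(exclusions$category == cat), integer(1))
  consort <- c(submitted = nrow(exclusions), consort)
  list(results = results, consort = consort, exclusions = exclusions)
}

#' Consort filtering of a processed cohort
#'
#' Convenience wrapper around \code{\link{runCohort}} that separates the
#' included results from the exclusion accounting.
#'
#' @inheritParams runCohort
#' @return list with \code{included} (results rows of included cases),
#'   \code{consort} and \code{exclusions} as in \code{\link{runCohort}}
#' @export
applyExclusions <- function(cohort, cfg = solverConfig(),
                            fluid = fluidProperties(),
                            gradientThreshold = 2) {
  run <- runCohort(cohort, cfg, fluid, gradientThreshold)
  list(included = run$results[run$results$status == "included", , drop = FALSE],
       consort = run$consort, exclusions = run$exclusions,
       results = run$results)
}
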