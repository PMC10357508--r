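#' @import methods
NULL

## Classed conditions so that pipeline stages can map failures onto the
## consort exclusion taxonomy without string-matching messages.
cfStop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "coroflow_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' Parametric description of a single smooth stenosis
#'
#' Describes an axisymmetric vessel of reference radius \code{r0} and length
#' \code{L} carrying one cosine-shaped narrowing of length \code{len} centred
#' at \code{centre}. Severity is the percentage \emph{diameter} reduction
#' relative to the reference lumen, matching visual angiographic grading
#' (a 60\% stenosis leaves a minimal radius of 0.4 r0 and 16\% of the
#' reference cross-sectional area).
#'
#' @slot r0 reference lumen radius (mm)
#' @slot L vessel length along the centerline (mm)
#' @slot centre arclength position of the stenosis throat (mm)
#' @slot len length of the stenotic segment (mm)
#' @slot severity percentage diameter reduction, in [0, 100)
#' @exportClass StenosisSpec
setClass("StenosisSpec",
  representation(r0 = "numeric", L = "numeric", centre = "numeric",
                 len = "numeric", severity = "numeric"))

setValidity("StenosisSpec", function(object) {
  msg <- character()
  if (length(object@r0) != 1 || !is.finite(object@r0) || object@r0 <= 0)
    msg <- c(msg, "r0 must be a single positive number (mm)")
  if (length(object@L) != 1 || !is.finite(object@L) || object@L <= 0)
    msg <- c(msg, "L must be a single positive number (mm)")
  if (length(object@severity) != 1 || !is.finite(object@severity) ||
      object@severity < 0 || object@severity >= 100)
    msg <- c(msg, "severity must lie in [0, 100) percent diameter reduction")
  if (length(object@len) != 1 || !is.finite(object@len) ||
      object@len <= 0 || object@len >= object@L)
    msg <- c(msg, "stenosis length must satisfy 0 < len < L")
  if (length(object@centre) != 1 || !is.finite(object@centre) ||
      object@centre <= 0 || object@centre >= object@L)
    msg <- c(msg, "stenosis centre must lie strictly inside (0, L)")
  if (length(msg)) msg else TRUE
})

#' Construct a StenosisSpec
#'
#' @param r0 reference radius (mm)
#' @param L vessel length (mm)
#' @param centre throat position along the vessel (mm); default mid-vessel
#' @param len stenosis length (mm)
#' @param severity percentage diameter reduction in [0, 100)
#' @return a \linkS4class{StenosisSpec}
#' @examples
#' stenosisSpec(r0 = 1.5, L = 30, len = 10, severity = 60)
#' @export
stenosisSpec <- function(r0 = 1.5, L = 30, centre = L / 2, len = 10,
                         severity = 60) {
  tryCatch(
    new("StenosisSpec", r0 = as.numeric(r0), L = as.numeric(L),
        centre = as.numeric(centre), len = as.numeric(len),
        severity = as.numeric(severity)),
    error = function(e)
      cfStop("coroflow_error_invalid_spec", conditionMessage(e)))
}

#' Axisymmetric rigid lumen geometry
#'
#' The reconstruction target and flow-solver input: a 3D centerline sampled
#' at strictly increasing arclengths with one lumen radius per sample.
#' Consecutive centerline spacings must equal the arclength increments.
#'
#' @slot arclength arclength samples s_i (mm), strictly increasing from 0
#' @slot centerline n x 3 matrix of centerline points (mm)
#' @slot radius lumen radius r_i (mm), all positive
#' @exportClass VesselGeometry
setClass("VesselGeometry",
  representation(arclength = "numeric", centerline = "matrix",
                 radius = "numeric"))

setValidity("VesselGeometry", function(object) {
  s <- object@arclength; r <- object@radius; C <- object@centerline
  msg <- character()
  if (length(s) < 10) msg <- c(msg, "need at least 10 arclength samples")
  if (length(s) && s[1] != 0) msg <- c(msg, "arclength must start at 0")
  if (any(diff(s) <= 0)) msg <- c(msg, "arclength must be strictly increasing")
  if (length(r) != length(s)) msg <- c(msg, "radius and arclength differ in length")
  if (any(!is.finite(r)) || any(r <= 0)) msg <- c(msg, "all radii must be positive")
  if (!is.numeric(C) || ncol(C) != 3 || nrow(C) != length(s))
    msg <- c(msg, "centerline must be an n x 3 numeric matrix")
  if (length(s) > 1 && ncol(C) == 3 && nrow(C) == length(s)) {
    seg <- sqrt(rowSums((C[-1, , drop = FALSE] - C[-nrow(C), , drop = FALSE])^2))
    if (max(abs(seg - diff(s))) > 1e-6)
      msg <- c(msg, "centerline spacing must equal arclength increments (1e-6 mm)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VesselGeometry
#'
#' @param arclength strictly increasing arclength samples from 0 (mm)
#' @param centerline n x 3 matrix of points (mm)
#' @param radius positive lumen radii (mm)
#' @return a \linkS4class{VesselGeometry}
#' @export
vesselGeometry <- function(arclength, centerline, radius) {
  tryCatch(
    new("VesselGeometry", arclength = as.numeric(arclength),
        centerline = as.matrix(centerline), radius = as.numeric(radius)),
    error = function(e)
      cfStop("coroflow_error_invalid_geometry", conditionMessage(e)))
}

#' One angiographic projection of a lumen
#'
#' An orthographic silhouette of an axisymmetric vessel: the projected
#' centerline polyline in in-plane coordinates (u, v) plus the half-width of
#' the silhouette at each sample. The viewing direction is parameterised by
#' two rotation angles in degrees (rotation about the z axis, then elevation
#' out of the x-y plane), emulating the two gantry angles of an angiogram.
#'
#' @slot id view identifier
#' @slot angles two rotation angles (degrees) defining the view direction
#' @slot t normalized arclength parameter along the 3D centerline, in [0, 1]
#' @slot polyline n x 2 matrix of projected centerline points (mm)
#' @slot halfWidth silhouette half-widths w_i (mm), all positive
#' @exportClass ProjectionView
setClass("ProjectionView",
  representation(id = "character", angles = "numeric", t = "numeric",
                 polyline = "matrix", halfWidth = "numeric"))

setValidity("ProjectionView", function(object) {
  msg <- character()
  if (length(object@angles) != 2 || any(!is.finite(object@angles)))
    msg <- c(msg, "angles must be two finite degrees")
  n <- length(object@t)
  if (nrow(object@polyline) != n || length(object@halfWidth) != n)
    msg <- c(msg, "t, polyline and halfWidth lengths must agree")
  if (any(object@halfWidth <= 0)) msg <- c(msg, "half-widths must be positive")
  if (any(diff(object@t) <= 0)) msg <- c(msg, "t must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Blood rheology for the flow solvers
#'
#' Defaults are the standard Newtonian blood parameters used throughout:
#' dynamic viscosity 0.0035 Pa s and density 1056 kg/m^3.
#'
#' @slot mu dynamic viscosity (Pa s)
#' @slot rho density (kg/m^3)
#' @exportClass FluidProperties
setClass("FluidProperties", representation(mu = "numeric", rho = "numeric"))

setValidity("FluidProperties", function(object) {
  if (length(object@mu) != 1 || object@mu <= 0) return("mu must be positive")
  if (length(object@rho) != 1 || object@rho <= 0) return("rho must be positive")
  TRUE
})

#' @param mu dynamic viscosity (Pa s)
#' @param rho density (kg/m^3)
#' @rdname FluidProperties-class
#' @export
fluidProperties <- function(mu = 0.0035, rho = 1056) {
  obj <- new("FluidProperties", mu = as.numeric(mu), rho = as.numeric(rho))
  validObject(obj)
  obj
}

#' Flow-solver configuration
#'
#' @slot backend "reduced_order" (quadratic pressure-drop model, default) or
#'   "axisymmetric" (steady axisymmetric Navier-Stokes, the internal oracle)
#' @slot nx axial grid cells (axisymmetric backend)
#' @slot nr radial grid cells (axisymmetric backend)
#' @slot tol relative residual tolerance
#' @slot maxIter maximum outer iterations
#' @slot Ke separation-loss coefficient of the quadratic term
#' @exportClass SolverConfig
setClass("SolverConfig",
  representation(backend = "character", nx = "integer", nr = "integer",
                 tol = "numeric", maxIter = "integer", Ke = "numeric"))

setValidity("SolverConfig", function(object) {
  msg <- character()
  if (!object@backend %in% c("reduced_order", "axisymmetric"))
    msg <- c(msg, "backend must be 'reduced_order' or 'axisymmetric'")
  if (object@tol <= 0) msg <- c(msg, "tolerance must be positive")
  if (object@nx < 16L || object@nr < 8L)
    msg <- c(msg, "grid resolution must be at least 16 x 8")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be at least 1")
  if (object@Ke < 0) msg <- c(msg, "Ke must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @param backend solver backend
#' @param nx,nr axial and radial grid cells (axisymmetric backend)
#' @param tol relative residual tolerance
#' @param maxIter maximum outer iterations
#' @param Ke separation-loss coefficient
#' @rdname SolverConfig-class
#' @export
solverConfig <- function(backend = c("reduced_order", "axisymmetric"),
                         nx = 64L, nr = 16L, tol = 1e-6, maxIter = 10000L,
                         Ke = 1.52) {
  backend <- match.arg(backend)
  obj <- new("SolverConfig", backend = backend, nx = as.integer(nx),
             nr = as.integer(nr), tol = as.numeric(tol),
             maxIter = as.integer(maxIter), Ke = as.numeric(Ke))
  validObject(obj)
  obj
}

#' Result of a single steady flow computation
#'
#' @slot Q volumetric flow at the outlet (ml/min)
#' @slot backend which solver produced the result
#' @slot converged whether the solver met its residual tolerance; an
#'   unconverged result is flagged unusable downstream
#' @slot residual final relative residual
#' @slot iterations iterations used
#' @slot reynolds Reynolds number at the minimal lumen
#' @exportClass FlowResult
setClass("FlowResult",
  representation(Q = "numeric", backend = "character", converged = "logical",
                 residual = "numeric", iterations = "integer",
                 reynolds = "numeric"))

#' Invasive pressure pair for one physiological state
#'
#' @slot Pa proximal pressure (mmHg)
#' @slot Pd distal pressure (mmHg)
#' @slot state "baseline" or "hyperaemic"
#' @exportClass PressureRecord
setClass("PressureRecord",
  representation(Pa = "numeric", Pd = "numeric", state = "character"))

setValidity("PressureRecord", function(object) {
  msg <- character()
  if (!(object@state %in% c("baseline", "hyperaemic")))
    msg <- c(msg, "state must be 'baseline' or 'hyperaemic'")
  if (!(object@Pd > 0 && object@Pd <= object@Pa))
    msg <- c(msg, "pressures must satisfy 0 < Pd <= Pa")
  if (length(msg)) msg else TRUE
})

#' @param Pa proximal pressure (mmHg)
#' @param Pd distal pressure (mmHg)
#' @param state "baseline" or "hyperaemic"
#' @rdname PressureRecord-class
#' @export
pressureRecord <- function(Pa, Pd, state = c("hyperaemic", "baseline")) {
  state <- match.arg(state)
  tryCatch(
    new("PressureRecord", Pa = as.numeric(Pa), Pd = as.numeric(Pd),
        state = state),
    error = function(e)
      cfStop("coroflow_error_invalid_pressures", conditionMessage(e)))
}

#' One virtual patient-artery case
#'
#' Carries either a lumen geometry or a pair of projections, plus the
#' baseline and hyperaemic pressure records. Forced-failure markers emulate
#' pathologies (volumetric meshing failure, solver divergence) that the
#' simplified pipeline cannot produce organically.
#'
#' @slot caseId unique case identifier
#' @slot patientId patient identifier
#' @slot sex "male" or "female"
#' @slot artery one of LAD, RCA, LCx, Dx, OM, LMS
#' @slot covariates named list of demographic/comorbidity covariates
#' @slot spec the generating \linkS4class{StenosisSpec}
#' @slot geometry a \linkS4class{VesselGeometry}, or NULL when only
#'   projections are supplied
#' @slot projections list of two \linkS4class{ProjectionView}s, or empty
#' @slot pressures named list with elements "baseline" and "hyperaemic"
#' @slot forcedFailure "" or one of "meshing_failure", "convergence_failure"
#' @exportClass CaseRecord
setClass("CaseRecord",
  representation(caseId = "character", patientId = "character",
                 sex = "character", artery = "character",
                 covariates = "list", spec = "ANY", geometry = "ANY",
                 projections = "list", pressures = "list",
                 forcedFailure = "character"))

arteryLevels <- c("LAD", "RCA", "LCx", "Dx", "OM", "LMS")

setValidity("CaseRecord", function(object) {
  msg <- character()
  if (!object@sex %in% c("male", "female"))
    msg <- c(msg, "sex must be 'male' or 'female'")
  if (!object@artery %in% arteryLevels)
    msg <- c(msg, sprintf("artery must be one of %s",
                          paste(arteryLevels, collapse = ", ")))
  if (!all(c("baseline", "hyperaemic") %in% names(object@pressures)))
    msg <- c(msg, "pressures must contain 'baseline' and 'hyperaemic'")
  if (!object@forcedFailure %in% c("", "meshing_failure", "convergence_failure"))
    msg <- c(msg, "unknown forcedFailure marker")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort with hidden ground truth
#'
#' The truth table (per-case microvascular resistance and flows used to
#' generate the pressures) is carried separately so that pipeline operations
#' never read it; only test harnesses and accuracy summaries should.
#'
#' @slot cases list of \linkS4class{CaseRecord}
#' @slot truth data.frame of hidden per-case ground truth
#' @slot config the \linkS4class{GeneratorConfig} used
#' @slot seed integer seed the cohort was generated from
#' @exportClass Cohort
setClass("Cohort",
  representation(cases = "list", truth = "data.frame", config = "ANY",
                 seed = "integer"))

#' Synthetic cohort generator configuration
#'
#' Defaults emulate the observed study conditions: 109 male and 35 female
#' patients; sex-specific lognormal hyperaemic CMVR with medians 680 (male)
#' and 860 (female) Wood units and log-sd calibrated to the printed
#' interquartile ranges; baseline CMVR a factor 2 above hyperaemic; aortic
#' pressure normal(92, 10) mmHg truncated at 60; stenosis severity
#' normal(60, 15) percent truncated to [20, 90] (median 60, IQR roughly
#' 50-70). Failure-injection rates default to zero; see
#' \code{\link{consortRates}} for rates matching the study's consort
#' accounting.
#'
#' @slot nMale,nFemale patient counts per sex
#' @slot cmvrMedian named numeric, hyperaemic CMVR median per sex (WU)
#' @slot cmvrSdlog named numeric, lognormal sdlog per sex
#' @slot baselineRatio baseline-to-hyperaemic CMVR ratio (>= 1 physiologic)
#' @slot baselineSdlog per-case lognormal jitter of the baseline ratio
#'   (0 disables)
#' @slot paMean,paSd,paMin aortic pressure distribution (mmHg)
#' @slot sevMean,sevSd,sevRange stenosis severity distribution (percent)
#' @slot r0Mean,r0Sd,r0Range reference radius distribution (mm)
#' @slot vesselLength vessel length (mm)
#' @slot stenosisLength stenosis segment length (mm)
#' @slot projectionNoiseSd additive Gaussian noise sd on half-widths (mm)
#' @slot viewAngles list of two length-2 angle vectors (degrees)
#' @slot nSamples centerline samples per geometry
#' @slot failureRates named rates for injected consort failure modes
#' @slot arteryProbs sampling probabilities over the six artery labels
#' @slot covariatePrev named prevalences for binary covariates
#' @slot ageMean,ageSd age distribution (years)
#' @slot useProjections if TRUE cases carry two noisy projections (the
#'   pipeline must reconstruct); if FALSE cases carry the geometry directly
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(nMale = "integer", nFemale = "integer",
                 cmvrMedian = "numeric", cmvrSdlog = "numeric",
                 baselineRatio = "numeric", baselineSdlog = "numeric",
                 paMean = "numeric", paSd = "numeric", paMin = "numeric",
                 sevMean = "numeric", sevSd = "numeric", sevRange = "numeric",
                 r0Mean = "numeric", r0Sd = "numeric", r0Range = "numeric",
                 vesselLength = "numeric", stenosisLength = "numeric",
                 projectionNoiseSd = "numeric", viewAngles = "list",
                 nSamples = "integer", failureRates = "numeric",
                 arteryProbs = "numeric", covariatePrev = "numeric",
                 ageMean = "numeric", ageSd = "numeric",
                 useProjections = "logical"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@nMale < 0L || object@nFemale < 0L)
    msg <- c(msg, "patient counts must be non-negative")
  if (!all(c("male", "female") %in% names(object@cmvrMedian)) ||
      any(object@cmvrMedian <= 0))
    msg <- c(msg, "cmvrMedian must be positive and named male/female")
  if (!all(c("male", "female") %in% names(object@cmvrSdlog)) ||
      any(object@cmvrSdlog < 0))
    msg <- c(msg, "cmvrSdlog must be non-negative and named male/female")
  if (object@baselineRatio <= 0) msg <- c(msg, "baselineRatio must be positive")
  if (any(object@failureRates < 0) || sum(object@failureRates) > 1)
    msg <- c(msg, "failureRates must be non-negative with sum <= 1")
  if (abs(sum(object@arteryProbs) - 1) > 1e-8)
    msg <- c(msg, "arteryProbs must sum to 1")
  if (any(object@covariatePrev < 0) || any(object@covariatePrev > 1))
    msg <- c(msg, "covariate prevalences must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
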