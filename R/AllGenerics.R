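#' @include AllClasses.R
NULL

#' Accessors for coroflow objects
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param object a coroflow S4 object
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("arclength", function(object) standardGeneric("arclength"))
#' @rdname accessors
#' @export
setGeneric("centerline", function(object) standardGeneric("centerline"))
#' @rdname accessors
#' @export
setGeneric("radii", function(object) standardGeneric("radii"))
#' @rdname accessors
#' @export
setGeneric("vesselLength", function(object) standardGeneric("vesselLength"))
#' @rdname accessors
#' @export
setGeneric("minRadius", function(object) standardGeneric("minRadius"))
#' @rdname accessors
#' @export
setGeneric("viewAngles", function(object) standardGeneric("viewAngles"))
#' @rdname accessors
#' @export
setGeneric("halfWidths", function(object) standardGeneric("halfWidths"))
#' @rdname accessors
#' @export
setGeneric("polyline", function(object) standardGeneric("polyline"))
#' @rdname accessors
#' @export
setGeneric("flowRate", function(object) standardGeneric("flowRate"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("reynoldsNumber", function(object) standardGeneric("reynoldsNumber"))
#' @rdname accessors
#' @export
setGeneric("proximalPressure", function(object) standardGeneric("proximalPressure"))
#' @rdname accessors
#' @export
setGeneric("distalPressure", function(object) standardGeneric("distalPressure"))
#' @rdname accessors
#' @export
setGeneric("pressureState", function(object) standardGeneric("pressureState"))
#' @rdname accessors
#' @export
setGeneric("cohortCases", function(object) standardGeneric("cohortCases"))
#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setGeneric("nCases", function(object) standardGeneric("nCases"))

#' @rdname accessors
setMethod("arclength", "VesselGeometry", function(object) object@arclength)
#' @rdname accessors
setMethod("centerline", "VesselGeometry", function(object) object@centerline)
#' @rdname accessors
setMethod("radii", "VesselGeometry", function(object) object@radius)
#' @rdname accessors
setMethod("vesselLength", "VesselGeometry", function(object)
  object@arclength[length(object@arclength)])
#' @rdname accessors
setMethod("minRadius", "VesselGeometry", function(object) min(object@radius))

#' @rdname accessors
setMethod("viewAngles", "ProjectionView", function(object) object@angles)
#' @rdname accessors
setMethod("halfWidths", "ProjectionView", function(object) object@halfWidth)
#' @rdname accessors
setMethod("polyline", "ProjectionView", function(object) object@polyline)

#' @rdname accessors
setMethod("flowRate", "FlowResult", function(object) object@Q)
#' @rdname accessors
setMethod("isConverged", "FlowResult", function(object) object@converged)
#' @rdname accessors
setMethod("reynoldsNumber", "FlowResult", function(object) object@reynolds)

#' @rdname accessors
setMethod("proximalPressure", "PressureRecord", function(object) object@Pa)
#' @rdname accessors
setMethod("distalPressure", "PressureRecord", function(object) object@Pd)
#' @rdname accessors
setMethod("pressureState", "PressureRecord", function(object) object@state)

#' @rdname accessors
setMethod("cohortCases", "Cohort", function(object) object@cases)
#' @rdname accessors
setMethod("cohortTruth", "Cohort", function(object) object@truth)
#' @rdname accessors
setMethod("nCases", "Cohort", function(object) length(object@cases))

setMethod("show", "StenosisSpec", function(object) {
  cat(sprintf(
    "StenosisSpec: r0 %.3g mm, L %.3g mm, %.3g%% diameter stenosis (len %.3g mm at s = %.3g mm)\n",
    object@r0, object@L, object@severity, object@len, object@centre))
})

setMethod("show", "VesselGeometry", function(object) {
  cat(sprintf(
    "VesselGeometry: %d samples over %.3g mm, radius %.3g-%.3g mm (min at s = %.3g mm)\n",
    length(object@arclength), vesselLength(object), min(object@radius),
    max(object@radius), object@arclength[which.min(object@radius)]))
})

setMethod("show", "ProjectionView", function(object) {
  cat(sprintf(
    "ProjectionView '%s': angles (%.1f, %.1f) deg, %d samples, half-width %.3g-%.3g mm\n",
    object@id, object@angles[1], object@angles[2], length(object@t),
    min(object@halfWidth), max(object@halfWidth)))
})

setMethod("show", "FlowResult", function(object) {
  cat(sprintf(
    "FlowResult [%s]: Q = %.4g ml/min, Re(min lumen) = %.3g, %s (residual %.2e, %d iterations)\n",
    object@backend, object@Q, object@reynolds,
    if (object@converged) "converged" else "NOT CONVERGED",
    object@residual, object@iterations))
})

setMethod("show", "PressureRecord", function(object) {
  cat(sprintf("PressureRecord [%s]: Pa = %.4g, Pd = %.4g mmHg (Pd/Pa = %.3f)\n",
              object@state, object@Pa, object@Pd, object@Pd / object@Pa))
})

setMethod("show", "CaseRecord", function(object) {
  cat(sprintf(
    "CaseRecord %s (patient %s, %s, %s): %s; input = %s%s\n",
    object@caseId, object@patientId, object@sex, object@artery,
    sprintf("%.0f%% stenosis", object@spec@severity),
    if (!is.null(object@geometry)) "geometry" else "two projections",
    if (nzchar(object@forcedFailure))
      sprintf(" [forced %s]", object@forcedFailure) else ""))
})

setMethod("show", "Cohort", function(object) {
  sexes <- vapply(object@cases, function(cs) cs@sex, character(1))
  cat(sprintf(
    "Cohort: %d cases (%d male, %d female), seed %d; hidden truth table %d x %d\n",
    length(object@cases), sum(sexes == "male"), sum(sexes == "female"),
    object@seed, nrow(object@truth), ncol(object@truth)))
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    paste0("GeneratorConfig: %d male + %d female; hyperaemic CMVR median ",
           "%g/%g WU (M/F), sdlog %.3g/%.3g; baseline ratio %.3g; ",
           "projection noise sd %g mm; %s\n"),
    object@nMale, object@nFemale,
    object@cmvrMedian[["male"]], object@cmvrMedian[["female"]],
    object@cmvrSdlog[["male"]], object@cmvrSdlog[["female"]],
    object@baselineRatio, object@projectionNoiseSd,
    if (object@useProjections) "cases carry projections"
    else "cases carry geometries"))
})
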