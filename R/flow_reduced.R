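#' @include AllClasses.R AllGenerics.R
NULL

MMHG_PA <- 133.322        # pascals per mmHg
MLMIN_M3S <- 1e-6 / 60    # m^3/s per ml/min

#' Convert pressures between mmHg and pascals
#'
#' @param p pressure value(s)
#' @return converted pressure(s); the factor is 133.322 Pa per mmHg
#' @examples
#' mmHgToPa(1)    # 133.322
#' mmHgToPa(90)   # 11998.98
#' @export
mmHgToPa <- function(p) p * MMHG_PA

#' @rdname mmHgToPa
#' @export
paToMmHg <- function(p) p / MMHG_PA

#' Linear (viscous) pressure-drop coefficient of a lumen
#'
#' Integrates the local Poiseuille resistance along the vessel,
#' \eqn{a = \int 8\mu / (\pi r(s)^4)\, ds} (trapezoidal quadrature), and
#' converts to interface units. For a constant-radius tube this equals the
#' Poiseuille resistance exactly, so \eqn{Q = \Delta P / a} reproduces
#' \eqn{Q = \pi \Delta P r^4 / (8 \mu L)}.
#'
#' @param geom a \linkS4class{VesselGeometry}
#' @param fluid a \linkS4class{FluidProperties}
#' @return pressure-drop coefficient in mmHg per (ml/min)
#' @export
viscousCoefficient <- function(geom, fluid = fluidProperties()) {
  s <- arclength(geom) * 1e-3         # m
  r <- radii(geom) * 1e-3             # m
  integrand <- 8 * fluid@mu / (pi * r^4)   # Pa per (m^3/s) per m
  aSI <- sum(diff(s) * (integrand[-1] + integrand[-length(s)]) / 2)
  aSI * MLMIN_M3S / MMHG_PA
}

#' Quadratic (separation-loss) pressure-drop coefficient
#'
#' Young-Tsai-type expansion loss across a stenosis:
#' \eqn{b = (K_e \rho / 2) (1/A_{min} - 1/A_{out})^2} with \eqn{A_{min}} the
#' minimal and \eqn{A_{out}} the distal outlet cross-sectional area;
#' zero when the lumen does not narrow relative to the outlet.
#'
#' @param geom a \linkS4class{VesselGeometry}
#' @param fluid a \linkS4class{FluidProperties}
#' @param Ke separation-loss coefficient (classical empirical default 1.52)
#' @return coefficient in mmHg per (ml/min)^2
#' @export
expansionCoefficient <- function(geom, fluid = fluidProperties(), Ke = 1.52) {
  r <- radii(geom) * 1e-3
  aMin <- pi * min(r)^2
  aOut <- pi * r[length(r)]^2
  bSI <- (Ke * fluid@rho / 2) * (1 / aMin - 1 / aOut)^2
  bSI * MLMIN_M3S^2 / MMHG_PA
}

#' Steady flow through a lumen between prescribed pressures
#'
#' Computes the absolute volumetric flow driven by the proximal-to-distal
#' pressure difference. The default \code{reduced_order} backend solves the
#' quadratic pressure-drop relation \eqn{b Q^2 + a Q = P_a - P_d} for its
#' unique positive root, with \eqn{a} the integrated viscous coefficient and
#' \eqn{b} the separation-loss coefficient. The \code{axisymmetric} backend
#' solves the steady incompressible Newtonian momentum/continuity equations
#' on a body-fitted axisymmetric grid (see \code{\link{axisymmetricFlow}})
#' and iterates the flow until the computed pressure drop matches the
#' prescribed one. Both report the Reynolds number at the minimal lumen and
#' an explicit convergence state.
#'
#' @param geom a \linkS4class{VesselGeometry}
#' @param Pa,Pd proximal and distal pressures (mmHg); requires Pa > Pd > 0
#' @param fluid a \linkS4class{FluidProperties}
#' @param cfg a \linkS4class{SolverConfig}
#' @return a \linkS4class{FlowResult} with Q in ml/min
#' @examples
#' tube <- makeStenosedPhantom(stenosisSpec(r0 = 1.5, L = 30, severity = 0))
#' flowRate(solveFlow(tube, Pa = 90, Pd = 80))  # Poiseuille: ~1514.6 ml/min
#' @export
solveFlow <- function(geom, Pa, Pd, fluid = fluidProperties(),
                      cfg = solverConfig()) {
  stopifnot(is(geom, "VesselGeometry"))
  if (!(Pd > 0))
    cfStop("coroflow_error_inadequate_gradient", "Pd must be positive")
  if (Pa <= Pd)
    cfStop("coroflow_error_inadequate_gradient",
           sprintf("Pa (%.3g) must exceed Pd (%.3g) to drive flow", Pa, Pd))
  if (cfg@backend == "reduced_order") {
    solveFlowReduced(geom, Pa, Pd, fluid, cfg)
  } else {
    solveFlowAxisymmetric(geom, Pa, Pd, fluid, cfg)
  }
}

## unique positive root of b Q^2 + a Q = dP, numerically stable for b -> 0
positiveRoot <- function(a, b, dP) {
  if (b <= 0) return(dP / a)
  2 * dP / (a + sqrt(a^2 + 4 * b * dP))
}

solveFlowReduced <- function(geom, Pa, Pd, fluid, cfg) {
  a <- viscousCoefficient(geom, fluid)
  b <- expansionCoefficient(geom, fluid, cfg@Ke)
  dP <- Pa - Pd
  Q <- positiveRoot(a, b, dP)
  res <- abs(b * Q^2 + a * Q - dP) / dP
  new("FlowResult", Q = Q, backend = "reduced_order",
      converged = res <= max(cfg@tol, 1e-12), residual = res,
      iterations = 1L, reynolds = reynoldsAtThroat(geom, Q, fluid))
}

#' Reynolds number at the minimal lumen
#'
#' \eqn{Re = 2 \rho Q / (\pi r_{min} \mu)}, i.e. mean-velocity, diameter
#' based.
#'
#' @param geom a \linkS4class{VesselGeometry}
#' @param Q flow in ml/min
#' @param fluid a \linkS4class{FluidProperties}
#' @return dimensionless Reynolds number
#' @export
reynoldsAtThroat <- function(geom, Q, fluid = fluidProperties()) {
  rMin <- minRadius(geom) * 1e-3
  2 * fluid@rho * (Q * MLMIN_M3S) / (pi * rMin * fluid@mu)
}
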