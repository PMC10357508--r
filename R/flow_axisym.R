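#' @include AllClasses.R AllGenerics.R flow_reduced.R
NULL

## Steady axisymmetric Navier-Stokes in streamfunction-vorticity form on a
## body-fitted grid. Coordinates: xi = axial position in [0, L], eta = r/R(x)
## in [0, 1]. With Stokes streamfunction psi (u = psi_r / r, v = -psi_x / r)
## and reduced azimuthal vorticity chi = omega / r (regular at the axis):
##
##   psi_xx + psi_rr - (1/r) psi_r = -r^2 chi
##   u chi_x + v chi_r = nu (chi_xx + chi_rr + (3/r) chi_r)
##
## Mapped derivatives use m = eta R'/R:
##   F_x  = F_xi - m F_eta
##   F_xx = F_xixi - 2 m F_xieta + m^2 F_etaeta - eta (R''/R - 2R'^2/R^2) F_eta
##   F_r  = F_eta / R,  F_rr = F_etaeta / R^2
## Cross-derivative terms are lagged (treated explicitly), keeping both
## linear systems 5-point; the outer Picard iteration absorbs them.

axiIdx <- function(i, j, nxp) i + (j - 1L) * nxp

## Discrete fully-developed profile at one axial station: with chi constant
## across the section the vorticity equation is satisfied identically, and
## psi solves the radial part of the streamfunction equation. Solving the
## coupled (psi_2..psi_nr, chi) system with the same stencils as the 2D
## solver yields an inlet state that is an exact fixed point of the interior
## discretization on a straight segment, so no spurious axial adjustment
## (and hence no spurious convective pressure drop) occurs near the inlet.
fdProfile1D <- function(Rv, Rpv, Rppv, eta, he, psiW) {
  nrp <- length(eta)
  nr <- nrp - 1L
  nun <- nr          # unknowns: psi_2..psi_nr (nr - 1 of them) + chi
  A <- matrix(0, nun, nun)
  b <- numeric(nun)
  mj <- eta * Rpv / Rv
  Aee <- mj^2 + 1 / Rv^2
  Aeta <- -eta * (Rppv / Rv - 2 * Rpv^2 / Rv^2) - 1 / (eta * Rv^2)
  ## the chi unknown is rescaled (chi = sc * z) so the system is balanced:
  ## raw chi ~ 1/R^4 while psi rows carry 1/(R^2 he^2)
  sc <- 1 / (Rv^4 * he^2)
  for (j in 2:nr) {
    rIdx <- j - 1L
    cS <- Aee[j] / he^2 - Aeta[j] / (2 * he)
    cD <- -2 * Aee[j] / he^2
    cN <- Aee[j] / he^2 + Aeta[j] / (2 * he)
    if (j - 1L >= 2L) A[rIdx, j - 2L] <- cS
    A[rIdx, rIdx] <- cD
    if (j + 1L <= nr) A[rIdx, j] <- cN else b[rIdx] <- b[rIdx] - cN * psiW
    A[rIdx, nun] <- (eta[j] * Rv)^2 * sc
  }
  dn2 <- (Rv * he)^2 / (1 + Rpv^2)
  ## Jensen second-order wall vorticity: chi_w 2 r_w^2 dn^2 =
  ##   7 psi_w - 8 psi_nr + psi_{nr-1}
  A[nun, nr - 1L] <- 8
  if (nr - 2L >= 1L) A[nun, nr - 2L] <- -1
  A[nun, nun] <- 2 * Rv^2 * dn2 * sc
  b[nun] <- 7 * psiW
  z <- solve(A, b)
  list(psi = c(0, z[seq_len(nr - 1L)], psiW), chi = z[nun] * sc)
}

#' Steady axisymmetric flow field at prescribed flow rate
#'
#' Low-level driver: given the flow rate, iterates the coupled
#' streamfunction/vorticity system to the configured residual and returns the
#' pressure drop obtained by integrating the axial momentum equation along
#' the symmetry axis. \code{\link{solveFlow}} wraps this in an outer
#' iteration that matches the prescribed pressure difference.
#'
#' @param geom a \linkS4class{VesselGeometry} (straight-axis; the solver uses
#'   the radius profile r(s))
#' @param Q flow rate (ml/min)
#' @param fluid a \linkS4class{FluidProperties}
#' @param cfg a \linkS4class{SolverConfig} (grid, tolerance, max iterations)
#' @param state optional warm-start state from a previous call on the same
#'   grid
#' @param relax under-relaxation factor for the vorticity update
#' @return list with \code{dP} (mmHg), \code{converged}, \code{iterations},
#'   \code{residual}, velocity fields \code{u}, \code{v} (m/s), grid vectors
#'   and the internal state for warm starts
#' @export
axisymmetricFlow <- function(geom, Q, fluid = fluidProperties(),
                             cfg = solverConfig(backend = "axisymmetric"),
                             state = NULL, relax = 0.5) {
  nx <- cfg@nx; nr <- cfg@nr
  nxp <- nx + 1L; nrp <- nr + 1L
  n <- nxp * nrp
  nu <- fluid@mu / fluid@rho

  sM <- arclength(geom) * 1e-3
  rM <- radii(geom) * 1e-3
  L <- sM[length(sM)]
  Rf <- stats::splinefun(sM, rM, method = "natural")
  xi <- seq(0, L, length.out = nxp)
  eta <- seq(0, 1, length.out = nrp)
  hx <- xi[2] - xi[1]; he <- eta[2] - eta[1]
  R <- Rf(xi); Rp <- Rf(xi, deriv = 1); Rpp <- Rf(xi, deriv = 2)

  QSI <- Q * MLMIN_M3S
  psiW <- QSI / (2 * pi)
  ubar <- QSI / (pi * R^2)              # section-mean velocity per station

  ETA <- matrix(eta, nxp, nrp, byrow = TRUE)
  RM <- matrix(R, nxp, nrp)
  RPM <- matrix(Rp, nxp, nrp)
  RPPM <- matrix(Rpp, nxp, nrp)
  rPhys <- ETA * RM                     # physical radius at each node
  m <- ETA * RPM / RM                   # metric of the mapped x-derivative

  ## ---- constant streamfunction matrix (geometry-only) -------------------
  ii <- seq_len(nxp)
  interI <- 2:(nxp - 1L); interJ <- 2:(nrp - 1L)
  Ig <- rep(interI, times = nr - 1L)
  Jg <- rep(interJ, each = nx - 1L)
  kC <- axiIdx(Ig, Jg, nxp)
  mC <- m[cbind(Ig, Jg)]
  Aee <- mC^2 + 1 / R[Ig]^2                                  # psi_etaeta
  Aeta <- -ETA[cbind(Ig, Jg)] * (Rpp[Ig] / R[Ig] - 2 * Rp[Ig]^2 / R[Ig]^2) -
    1 / (ETA[cbind(Ig, Jg)] * R[Ig]^2)                       # psi_eta
  trip <- list(
    i = c(kC, kC, kC, kC, kC),
    j = c(kC, axiIdx(Ig - 1L, Jg, nxp), axiIdx(Ig + 1L, Jg, nxp),
          axiIdx(Ig, Jg - 1L, nxp), axiIdx(Ig, Jg + 1L, nxp)),
    x = c(-2 / hx^2 - 2 * Aee / he^2,
          rep(1 / hx^2, length(kC)), rep(1 / hx^2, length(kC)),
          Aee / he^2 - Aeta / (2 * he), Aee / he^2 + Aeta / (2 * he)))
  addRow <- function(tr, ki, kj, kx) {
    tr$i <- c(tr$i, ki); tr$j <- c(tr$j, kj); tr$x <- c(tr$x, kx); tr
  }
  ## inlet (Dirichlet), axis (psi = 0), wall (psi = psiW): identity rows.
  ## Row sets are disjoint (axis/wall start at i = 2) so no duplicate
  ## triplets are summed at domain corners.
  kIn <- axiIdx(rep(1L, nrp), seq_len(nrp), nxp)
  kAx <- axiIdx(2:nxp, rep(1L, nxp - 1L), nxp)
  kWl <- axiIdx(2:nxp, rep(nrp, nxp - 1L), nxp)
  trip <- addRow(trip, kIn, kIn, rep(1, nrp))
  trip <- addRow(trip, kAx, kAx, rep(1, nxp - 1L))
  trip <- addRow(trip, kWl, kWl, rep(1, nxp - 1L))
  ## outlet: second-order one-sided d/dxi = 0 (skip axis/wall corners)
  jOut <- 2:(nrp - 1L)
  kO <- axiIdx(rep(nxp, length(jOut)), jOut, nxp)
  trip <- addRow(trip, rep(kO, 3L),
                 c(kO, axiIdx(rep(nxp - 1L, length(jOut)), jOut, nxp),
                   axiIdx(rep(nxp - 2L, length(jOut)), jOut, nxp)),
                 c(rep(3, length(kO)), rep(-4, length(kO)),
                   rep(1, length(kO))))
  Apsi <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                               dims = c(n, n))
  ## row equilibration plus one step of iterative refinement below: the
  ## wall-vorticity formula divides O(he^2) streamfunction differences by
  ## the squared wall spacing, so the linear solve must be as clean as
  ## double precision allows
  rowScale <- 1 / apply(abs(Apsi), 1, max)
  ApsiEq <- Matrix::Diagonal(x = rowScale) %*% Apsi
  facPsi <- Matrix::lu(ApsiEq)
  solvePsi <- function(bVec) {
    bEq <- rowScale * bVec
    x <- as.numeric(Matrix::solve(facPsi, bEq))
    r <- bEq - as.numeric(ApsiEq %*% x)
    x + as.numeric(Matrix::solve(facPsi, r))
  }

  ## ---- inlet profile and initial fields ---------------------------------
  inProf <- fdProfile1D(R[1], Rp[1], Rpp[1], eta, he, psiW)
  psiIn <- inProf$psi
  chiIn <- inProf$chi
  if (!is.null(state) && identical(dim(state$psi), c(nxp, nrp))) {
    scale <- Q / state$Q
    psi <- state$psi * scale
    chi <- state$chi * scale
  } else {
    ## initialize every station with its local fully-developed profile
    ## (lubrication-style first guess; exact for a straight tube)
    psi <- matrix(0, nxp, nrp)
    chi <- matrix(0, nxp, nrp)
    for (i in seq_len(nxp)) {
      pr <- fdProfile1D(R[i], 0, 0, eta, he, psiW)
      psi[i, ] <- pr$psi
      chi[i, ] <- pr$chi
    }
  }
  chi[1, ] <- chiIn
  psi[1, ] <- psiIn

  dn2 <- (R * he / sqrt(1 + Rp^2))^2   # squared wall-normal spacing
  chiScale <- max(abs(chiIn), 4 * max(ubar) / min(R)^2)

  centralXi <- function(F) {
    Fx <- matrix(0, nxp, nrp)
    Fx[interI, ] <- (F[interI + 1L, ] - F[interI - 1L, ]) / (2 * hx)
    Fx[1, ] <- (F[2, ] - F[1, ]) / hx
    Fx[nxp, ] <- (F[nxp, ] - F[nxp - 1L, ]) / hx
    Fx
  }
  centralEta <- function(F) {
    Fe <- matrix(0, nxp, nrp)
    Fe[, interJ] <- (F[, interJ + 1L] - F[, interJ - 1L]) / (2 * he)
    Fe[, 1] <- (F[, 2] - F[, 1]) / he
    Fe[, nrp] <- (F[, nrp] - F[, nrp - 1L]) / he
    Fe
  }
  crossD <- function(F) {           # F_xieta, interior only (0 on borders)
    Fc <- matrix(0, nxp, nrp)
    Fc[interI, interJ] <-
      (F[interI + 1L, interJ + 1L] - F[interI + 1L, interJ - 1L] -
       F[interI - 1L, interJ + 1L] + F[interI - 1L, interJ - 1L]) /
      (4 * hx * he)
    Fc
  }

  psi0 <- psi; chi0 <- chi
  u <- v <- matrix(0, nxp, nrp)
  res <- Inf; iter <- 0L; totalIter <- 0L
  ## Picard iteration with a relaxation ladder: the wall-vorticity coupling
  ## destabilises the fixed point for severe narrowings, so on divergence
  ## the sweep restarts from the lubrication initial state with a smaller
  ## relaxation factor.
  for (relaxTry in unique(c(relax, relax / 3, relax / 10))) {
  psi <- psi0; chi <- chi0
  res <- Inf; iter <- 0L
  resHist <- rep(Inf, cfg@maxIter)
  while (iter < cfg@maxIter && res > cfg@tol) {
    iter <- iter + 1L

    ## 1) streamfunction solve with lagged cross-derivative
    rhs <- matrix(0, nxp, nrp)
    rhs[interI, interJ] <- (-(rPhys^2) * chi + 2 * m * crossD(psi))[interI, interJ]
    rhs[1, ] <- psiIn
    rhs[, 1] <- 0
    rhs[, nrp] <- psiW
    rhs[nxp, interJ] <- 0
    psi <- matrix(solvePsi(as.numeric(rhs)), nxp, nrp)

    ## 2) velocities from psi
    psiEta <- centralEta(psi)
    psiXi <- centralXi(psi)
    u <- matrix(0, nxp, nrp)
    u[, 2:nrp] <- psiEta[, 2:nrp] / (RM[, 2:nrp]^2 * ETA[, 2:nrp])
    u[, 1] <- (16 * psi[, 2] - psi[, 3]) / (6 * (he * R)^2)
    u[, nrp] <- 0
    v <- matrix(0, nxp, nrp)
    v[, 2:nrp] <- -(psiXi[, 2:nrp] - m[, 2:nrp] * psiEta[, 2:nrp]) /
      rPhys[, 2:nrp]

    ## 3) wall vorticity: Jensen second-order formula on the wall-normal
    ## spacing, under-relaxed (wall feedback is the stiffest coupling)
    chiWall <- (7 * psiW - 8 * psi[, nrp - 1L] + psi[, nrp - 2L]) /
      (2 * R^2 * dn2)
    chi[, nrp] <- chi[, nrp] + 0.5 * (chiWall - chi[, nrp])

    ## 4) vorticity transport solve (upwind convection, lagged cross term)
    Uc <- u
    Vc <- (v - u * ETA * RPM) / RM
    mI <- m[cbind(Ig, Jg)]
    Cee <- nu * (mI^2 + 1 / R[Ig]^2)
    Ceta <- nu * (-ETA[cbind(Ig, Jg)] *
                    (Rpp[Ig] / R[Ig] - 2 * Rp[Ig]^2 / R[Ig]^2) +
                  3 / (ETA[cbind(Ig, Jg)] * R[Ig]^2))
    UcI <- Uc[cbind(Ig, Jg)]; VcI <- Vc[cbind(Ig, Jg)]
    up <- pmax(UcI, 0); um <- pmax(-UcI, 0)
    vp <- pmax(VcI, 0); vm <- pmax(-VcI, 0)
    diag0 <- (up + um) / hx + (vp + vm) / he + 2 * nu / hx^2 + 2 * Cee / he^2
    west <- -up / hx - nu / hx^2
    east <- -um / hx - nu / hx^2
    south <- -vp / he - Cee / he^2 + Ceta / (2 * he)
    north <- -vm / he - Cee / he^2 - Ceta / (2 * he)
    tc <- list(
      i = c(kC, kC, kC, kC, kC),
      j = c(kC, axiIdx(Ig - 1L, Jg, nxp), axiIdx(Ig + 1L, Jg, nxp),
            axiIdx(Ig, Jg - 1L, nxp), axiIdx(Ig, Jg + 1L, nxp)),
      x = c(diag0, west, east, south, north))
    tc <- addRow(tc, kIn, kIn, rep(1, nrp))
    tc <- addRow(tc, kWl, kWl, rep(1, nxp - 1L))
    ## axis: second-order one-sided d/deta = 0 (i = 1 belongs to the inlet)
    kAxI <- axiIdx(2:nxp, rep(1L, nxp - 1L), nxp)
    tc <- addRow(tc, rep(kAxI, 3L),
                 c(kAxI, axiIdx(2:nxp, rep(2L, nxp - 1L), nxp),
                   axiIdx(2:nxp, rep(3L, nxp - 1L), nxp)),
                 c(rep(3, length(kAxI)), rep(-4, length(kAxI)),
                   rep(1, length(kAxI))))
    kOut <- axiIdx(rep(nxp, length(jOut)), jOut, nxp)
    tc <- addRow(tc, rep(kOut, 3L),
                 c(kOut, axiIdx(rep(nxp - 1L, length(jOut)), jOut, nxp),
                   axiIdx(rep(nxp - 2L, length(jOut)), jOut, nxp)),
                 c(rep(3, length(kOut)), rep(-4, length(kOut)),
                   rep(1, length(kOut))))
    Achi <- Matrix::sparseMatrix(i = tc$i, j = tc$j, x = tc$x, dims = c(n, n))
    ## moving the implicit terms left leaves the lagged diffusion cross
    ## term on the right: (conv - D_implicit) chi = -2 nu m chi_xieta
    rhsC <- matrix(0, nxp, nrp)
    rhsC[interI, interJ] <- (-2 * nu * m * crossD(chi))[interI, interJ]
    rhsC[, nrp] <- chi[, nrp]
    rhsC[1, ] <- chiIn
    rhsC[2:nxp, 1] <- 0
    rhsC[nxp, jOut] <- 0
    chiNew <- tryCatch(
      matrix(as.numeric(Matrix::solve(Achi, as.numeric(rhsC))), nxp, nrp),
      error = function(e) NULL)
    if (is.null(chiNew) || !all(is.finite(chiNew))) {
      res <- Inf
      break
    }
    res <- max(abs(chiNew - chi)) / chiScale
    chi <- chi + relaxTry * (chiNew - chi)
    resHist[iter] <- res
    ## stagnation at the rounding floor: no meaningful progress over the
    ## last 50 iterations means further sweeps only burn time
    if (iter >= 50L && res > 0.5 * min(resHist[seq_len(iter - 49L)])) break
  }
  totalIter <- totalIter + iter
  if (is.finite(res) && res <= cfg@tol) break
  ## a finite plateau is kept (reported unconverged); only divergence
  ## triggers a retry at smaller relaxation
  if (is.finite(res) && res < 1e-3) break
  }
  iter <- totalIter

  ## ---- pressure drop from axial momentum along the symmetry axis --------
  ## On the axis dp/dx = mu lap(u) - rho u u_x, and the axisymmetric
  ## identity lap(u) = -(1/r) d(r^2 chi)/dr gives lap(u)|axis = -2 chi,
  ## avoiding second differences of the velocity field.
  u0 <- u[, 1]
  du0 <- centralXi(matrix(u0, nxp, 1))[, 1]
  dpdx <- -fluid@rho * u0 * du0 - 2 * fluid@mu * chi[, 1]
  dPSI <- -sum((dpdx[-1] + dpdx[-nxp]) / 2 * hx)

  list(dP = paToMmHg(dPSI), converged = res <= cfg@tol, iterations = iter,
       residual = res, u = u, v = v, xi = xi, eta = eta, R = R, Q = Q,
       psi = psi, chi = chi)
}

## Outer iteration: find Q such that the axisymmetric pressure drop matches
## the prescribed Pa - Pd. Secant on Q, warm-started fields.
solveFlowAxisymmetric <- function(geom, Pa, Pd, fluid, cfg,
                                  outerTol = 1e-4, maxOuter = 15L) {
  dPT <- Pa - Pd
  a <- viscousCoefficient(geom, fluid)
  b <- expansionCoefficient(geom, fluid, cfg@Ke)
  Q0 <- positiveRoot(a, b, dPT)

  state <- NULL
  totalIter <- 0L
  allConverged <- TRUE
  evalDP <- function(Q) {
    sol <- axisymmetricFlow(geom, Q, fluid, cfg, state = state)
    state <<- sol
    totalIter <<- totalIter + sol$iterations
    allConverged <<- allConverged && sol$converged
    sol$dP
  }

  Qa <- Q0; fa <- evalDP(Qa) - dPT
  if (abs(fa) / dPT <= outerTol) {
    Q <- Qa; fb <- fa
  } else {
    Qb <- Qa * dPT / (fa + dPT); fb <- evalDP(Qb) - dPT
    k <- 0L
    while (abs(fb) / dPT > outerTol && k < maxOuter && abs(fb - fa) > 0) {
      Qn <- Qb - fb * (Qb - Qa) / (fb - fa)
      if (!is.finite(Qn) || Qn <= 0) Qn <- Qb / 2
      Qa <- Qb; fa <- fb
      Qb <- Qn; fb <- evalDP(Qb) - dPT
      k <- k + 1L
    }
    Q <- Qb
  }
  matched <- abs(fb) / dPT <= outerTol
  if (!allConverged || !matched)
    cfStop("coroflow_error_nonconvergence",
           sprintf(paste0("axisymmetric solver did not converge ",
                          "(field residual %.2e, pressure mismatch %.2e)"),
                   state$residual, abs(fb) / dPT))
  new("FlowResult", Q = Q, backend = "axisymmetric",
      converged = TRUE, residual = state$residual,
      iterations = totalIter, reynolds = reynoldsAtThroat(geom, Q, fluid))
}
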