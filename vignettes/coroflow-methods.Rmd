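---
title: "Methods: computational coronary flow, microvascular resistance and subgroup statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: computational coronary flow, microvascular resistance and subgroup statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroflow)
```

# Overview

`coroflow` implements a pressure-to-flow pipeline for stenosed coronary
arteries: an axisymmetric rigid lumen is reconstructed from two
angiographic projections, the absolute flow consistent with the measured
proximal/distal pressure pair is computed, and the physiological indices
FFR, CFR and absolute coronary microvascular resistance (CMVR, Wood
units) are derived per physiological state. Because patient-level imaging
and pressure data of this kind are generally not shareable, the package
ships a synthetic cohort generator with hidden ground truth; every claim
the package makes about accuracy is a claim its own test suite computes
on that generator, not a claim about clinical data.

# Geometry: phantoms, projection, reconstruction

A stenosed phantom is a straight-axis vessel of reference radius $r_0$
with one cosine-shaped narrowing of length $l$ centred at $s^*$:
$$r(s) = r_0 - \frac{\sigma}{100}\, r_0\, \tfrac12\!\left(1 +
\cos\frac{2\pi (s - s^*)}{l}\right), \qquad |s - s^*| < l/2,$$
so severity $\sigma$ is a percentage *diameter* reduction, matching
visual angiographic grading; a 60 % stenosis of a 1.5 mm lumen leaves a
0.6 mm throat and 16 % of the reference area.

Projection is orthographic: a view is parameterised by two gantry-style
angles, the centerline is projected onto the view plane, and the
silhouette half-width equals the local radius (an axisymmetric lumen has
no other silhouette). Optional additive Gaussian noise on half-widths
emulates contour-detection error; centerline noise is deliberately out of
scope.

Reconstruction from two views at least 30° apart — the angular criterion
used in angiographic acquisition — is a calibrated two-view orthographic
triangulation. The full projective epipolar machinery of clinical systems
is not reproducible from published descriptions, so the design keeps the
input/output contract (two views ≥ 30° → axisymmetric $r(s)$) and makes
the correspondence rule explicit: points are paired by normalised
arclength, and epipolar consistency (the least-squares reprojection
residual, `reprojectionResidual`) is exposed as a validation diagnostic
rather than used for matching. The radius is the arithmetic mean of the
two half-widths — unbiased under axisymmetry.

The reconstructed radius profile is regularised with a generalised
cross-validated smoothing spline. The reason is statistical, not
cosmetic: downstream resistances depend on $r^{-4}$ and $A_{\min}^{-2}$,
and the minimum of a noisy profile is extreme-value biased low, so raw
half-width noise produces a systematic upward bias in resistance. GCV
selects an essentially zero penalty on noise-free silhouettes (the
noiseless round trip recovers $r(s)$ to well under 1 %), while with
0.05 mm half-width noise it roughly triples recovery accuracy. Tests
cover both regimes.

# Flow: a two-backend contract

Pressures are prescribed at the reconstruction inlet and outlet and flow
is steady, laminar and Newtonian (blood: $\mu = 0.0035$ Pa·s, $\rho =
1056$ kg/m³; mmHg, ml/min and mm at the interface, SI internally,
1 mmHg = 133.322 Pa).

**Reduced-order backend (default).** The trans-stenotic drop is
$\Delta P = aQ + bQ^2$ with
$$a = \int \frac{8\mu}{\pi r(s)^4}\, ds, \qquad
  b = \frac{K_e \rho}{2}\left(\frac{1}{A_{\min}} -
  \frac{1}{A_{out}}\right)^2 .$$
$a$ is evaluated by trapezoidal quadrature and is the exact Poiseuille
resistance for a constant-radius tube; $b$ is a Young–Tsai-type
separation loss with the classical empirical coefficient $K_e = 1.52$
(configurable). The solver returns the unique positive root of
$bQ^2 + aQ = P_a - P_d$ in closed form and verifies it to $10^{-12}$
relative.

**Axisymmetric backend (internal oracle).** The steady momentum and
continuity equations are solved in streamfunction–vorticity form
($\psi$, $\chi = \omega/r$, which is regular at the axis) on a
body-fitted grid $\xi = x$, $\eta = r/R(x)$:
$$\psi_{xx} + \psi_{rr} - \tfrac1r \psi_r = -r^2\chi, \qquad
  u\chi_x + v\chi_r = \nu\left(\chi_{xx} + \chi_{rr} +
  \tfrac3r \chi_r\right).$$
Numerical choices that matter:

- Both linear systems are solved directly (sparse LU via `Matrix`); the
  streamfunction matrix depends only on the geometry and is factored
  once, with row equilibration and one step of iterative refinement
  because the wall-vorticity formula divides $O(h_\eta^2)$
  streamfunction differences by the squared wall spacing.
- Wall vorticity uses the second-order (Jensen) two-point formula; the
  first-order Thom formula leaves an $O(h_\eta)$ bias that is visible in
  the pressure drop.
- The inlet profile is the *discrete* fully developed solution of the
  radial operator (solved per station as a small dense system), not the
  analytic parabola. This makes a straight tube an exact fixed point of
  the interior discretisation, so no spurious axial adjustment — and
  hence no spurious convective pressure contribution, which scales with
  the dynamic head — occurs near the inlet. The same per-station solve
  provides the lubrication-style initial field.
- Convection is first-order upwinded; metric cross-derivatives are
  lagged (kept explicit), so both matrices stay 5-point. The outer
  Picard iteration under-relaxes the vorticity update (default 0.5) and
  restarts from the initial state with a 3× and 10× smaller factor if a
  severe narrowing destabilises the wall coupling. Divergence and
  stagnation at the rounding floor are detected; non-convergence is a
  classed, logged outcome, never a crash of a cohort run.
- The pressure drop is integrated along the symmetry axis using
  $dp/dx = \mu\,\mathrm{lap}(u) - \rho u u_x$ with the identity
  $\mathrm{lap}(u)|_{axis} = -2\chi_{axis}$, avoiding second differences
  of the velocity field.
- Prescribed-pressure solves wrap the fixed-flow solver in a secant
  iteration on $Q$ (relative pressure mismatch $10^{-4}$), warm-started
  between evaluations.

On a straight tube the backend reproduces the Poiseuille pressure drop
with monotone second-order grid convergence (0.9 %, 0.20 %, 0.05 % on
32×8, 64×16, 128×32 cells) and a parabolic profile with max/mean
velocity 2.00 within 2 %.

**Agreement between the backends** is regime-dependent and the tests
encode the measured envelope rather than a single number: in the Stokes
limit the Navier–Stokes pressure drop exceeds the lubrication integral by
only 1–3 % (any severity); at physiological gradients agreement on flow
is within 10 % for mild stenoses (~20 %), but for a smooth 60 % cosine
stenosis at throat Reynolds numbers of 100–200 the $K_e = 1.52$
sudden-expansion loss — an empirical high-Reynolds coefficient for
abrupt geometries — overestimates the separation loss, and the two
backends differ by ~20–25 % on flow (the reduced model being the
conservative one). This is a model-form difference, not a numerical
error; the reduced backend remains the pipeline default and the
axisymmetric solver the benchmark.

# Physiology and consort accounting

The index equations are
$\mathrm{FFR} = P_d/P_a$ (hyperaemic), $\mathrm{CMVR} = 1000\,P_d/Q$
(the factor 1000 converts ml/min to L/min, giving Wood units, with each
state using its own $P_d$), and $\mathrm{CFR} = Q_{hyper}/Q_{base}$. No
gravitational/hydrostatic pressure correction is applied. Baseline CMVR
below hyperaemic CMVR is logged as non-physiologic but not rejected.

Every submitted case ends in exactly one consort category:
`inadequate_gradient`, `reconstruction_failure`, `meshing_failure`,
`convergence_failure` or `included`; counts always conserve the submitted
total. The inadequate-gradient threshold — unspecified in clinical
descriptions — is hyperaemic $P_a - P_d < 2$ mmHg (configurable),
i.e. below pressure-wire drift tolerance the epicardial flow is
unidentifiable. A consequence worth stating explicitly: under realistic
defaults a few percent of synthetic cases are excluded *organically* in
this category (a mild lesion in series with a high microvascular
resistance yields a sub-threshold gradient no matter how the severity
range is chosen, because the flow is microvascular-limited). This
mirrors the exclusion structure of real workflows and is why the
"all-included" contract is expressed with `gradientThreshold = 0` in the
tests.

# The synthetic cohort generator

The generator defines the study-scale conditions and is not a tuning
knob. Defaults: 109 male and 35 female patients, one artery each;
hyperaemic CMVR lognormal with sex-specific medians 680 (male) and 860
(female) WU and log-sd 0.377 / 0.458, calibrated so the quartile ratio
matches study-scale interquartile ranges (865/520 and 1205/650); the
lognormal was chosen because CMVR is positive and right-skewed with
asymmetric IQRs. Baseline CMVR is hyperaemic × 2.0 (consistent with the
ratio of study-scale medians) × a median-one lognormal per-case jitter
(sdlog 0.25; 0 disables, and then baseline ≥ hyperaemic always). Aortic
pressure is normal(92, 10) mmHg truncated at 60, drawn per state (the
hyperaemic aortic drop is ignored); severity is normal(60, 15) %
truncated to [35, 90] (median 60, IQR ≈ [50, 70]); reference radius
normal(1.5, 0.2) mm on [1.0, 2.0]; vessel length 30 mm, stenosis length
10 mm, 129 centerline samples; covariate prevalences follow the emulated
demography (90 % white Caucasian, 63 % smokers, …) with no causal effect
on CMVR by default, so subgroup rows double as type-I-error fixtures;
artery labels are drawn at the emulated frequencies (LAD 103/203, …).

Pressures are made self-consistent by the series circuit
$P_a - aQ - bQ^2 = P_d = \mathrm{CMVR}\cdot Q/1000$, solved in closed
form (unique positive root for $a, b \ge 0$); `computeCMVR` applied to
the result returns the hidden truth to $10^{-10}$, which is the
round-trip identity the acceptance battery checks.

Failure injection is off by default; `consortRates()` provides
study-scale rates (20/19/7/7 out of 256). Injected inadequate-gradient
cases use severity 0 in a wide (2 mm) lumen so the category is
deterministic; injected reconstruction failures carry views 15° apart;
meshing/convergence failures are forced markers, since the simplified
pipeline cannot produce them organically.

All randomness flows from one seed through per-case substreams, so case
$k$ is invariant to cohort ordering and size. The substreams are drawn
with `sample.int` from the master-seeded RNG rather than derived by a
linear formula: related Mersenne–Twister seeds produce correlated early
draws across cases, which measurably distorted cohort-level rank
statistics (power 0.73 vs 0.78 expected) before this was fixed.

**What the generator does not emulate:** real angiographic imagery,
cardiac motion, contrast dynamics, centerline (as opposed to width)
noise, within-patient correlation of multiple arteries, side-branch
flow, collateral supply, or any causal covariate structure. Passing
tests therefore demonstrate the correctness of the computational chain
under the stated synthetic conditions, not clinical accuracy.

# Statistical battery

Conventions are fixed and tested: Mann–Whitney U with tie-corrected
variance *with* continuity correction (a flag disables it), exact
permutation p (twice the smaller tail, capped at 1) for pooled n ≤ 12;
tie-corrected Kruskal–Wallis H with a χ² reference; Pearson χ² without
continuity correction; Welch t by default (pooled-variance variant
available, for which F = t² holds in two-group ANOVA); Cohen's d on the
pooled SD and Hedges' g = d·J with J = 1 − 3/(4df − 1), df = n₁+n₂−2;
Pearson r with the t-transform p. Group ordering puts the reference
level (male, white Caucasian, "no") first, so Z < 0 means the comparison
group runs higher. Degenerate inputs (constant samples, empty groups,
two-group Kruskal–Wallis calls, variables that do not split the cohort)
raise classed errors rather than returning misleading numbers.

`subgroupReport` gates each binary comparison with Shapiro–Wilk per
group: mean ± SD and Welch t when normality is not rejected, median
[IQR] and rank-sum otherwise. The three-level artery comparison
(LAD+Dx vs LCx+OM vs RCA; left-main cases are not assignable to one
system and are omitted from that row) uses Kruskal–Wallis; "origin"
compares left vs right coronary cases; "age" uses correlation. No
multiplicity correction is applied across rows — matching common
reporting practice — and the markdown report carries a nominal-α caveat.

The power comparison in the acceptance battery runs the pipeline on
gradient-complete cohorts (`gradientThreshold = 0`): the 2 mmHg
exclusion rule truncates the high-CMVR tail asymmetrically by sex and
lowers power by ~6 points, which is an epidemiological selection effect;
the bracket is meant to compare the analysis chain against a direct
Monte-Carlo oracle on the same population.

# Problem sizes and tolerances used by the test battery

Chosen as the package's own balance of resolution and turnaround:
cohorts of 100 cases (50/50) for recovery checks, 33 centerline samples
and geometry-mode cases for replicated statistical simulations (the
quadrature resolution is irrelevant to rank statistics), the default 129
samples wherever geometric accuracy is probed; 1000 replicates for the
type-I rate, 500 for the power bracket; axisymmetric grids 32×8–128×32
with residual tolerance 10⁻⁶–10⁻⁸ and 10 000 iteration cap. The
acceptance script reruns the same computations from scratch under a
caller-supplied seed.

# Known limitations

- The reconstruction is orthographic with correspondence by normalised
  arclength; strongly curved or foreshortened centerlines are outside
  its validity (phantoms are straight-axis).
- The axisymmetric solver is steady and laminar; throat Reynolds numbers
  beyond a few hundred (readily produced by an 18 mmHg gradient across a
  60 % stenosis) violate the steadiness assumption physically, and the
  upwind scheme's numerical diffusion grows with cell Péclet number.
- The reduced model's separation loss uses a single empirical $K_e$;
  smooth constrictions at moderate Reynolds numbers overestimate losses
  by ~20 % relative to the Navier–Stokes benchmark.
- One artery per patient: within-patient clustering of multi-artery
  analyses is not modelled (flagged for the subgroup machinery, which
  treats arteries as independent).
- Indices inherit all assumptions above; no claim is made about
  agreement with invasive microvascular measurements.
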