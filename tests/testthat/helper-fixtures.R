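# Shared fixtures: everything is generated in code, no stored data.

straightTube <- function(r0 = 1.5, L = 30, n = 129L) {
  makeStenosedPhantom(stenosisSpec(r0 = r0, L = L, severity = 0), n)
}

sixtyPhantom <- function(n = 129L) {
  makeStenosedPhantom(stenosisSpec(r0 = 1.5, L = 30, len = 10, severity = 60),
                      n)
}

# Small, fast generator setups used across cohort/stats/pipeline tests.
# Geometry-mode cases skip projection/reconstruction; 33 centerline samples
# keep the resistance quadrature cheap without changing what the tests probe.
nullGenConfig <- function(nMale = 50L, nFemale = 50L, ...) {
  generatorConfig(nMale = nMale, nFemale = nFemale,
                  cmvrMedian = c(male = 680, female = 680),
                  cmvrSdlog = c(male = 0.377, female = 0.377),
                  useProjections = FALSE, nSamples = 33L, ...)
}

sexEffectGenConfig <- function(nMale = 109L, nFemale = 35L, ...) {
  generatorConfig(nMale = nMale, nFemale = nFemale,
                  useProjections = FALSE, nSamples = 33L, ...)
}

fastAxiConfig <- function(nx = 64L, nr = 16L, tol = 1e-6)
  solverConfig("axisymmetric", nx = nx, nr = nr, tol = tol, maxIter = 1500L)
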