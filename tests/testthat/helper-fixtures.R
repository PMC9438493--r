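# Shared fixtures, built in code. Heavyweight end-to-end results are
# computed once per session and cached here so several tests can assert
# against the same runs.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  hit <- .fixtureCache[[name]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  .fixtureCache[[name]] <- val
  val
}

# a small P1 toy crystal reused by many deterministic tests
smallToy <- function() {
  cachedFixture("smallToy", generateToyCrystal(
    cell = unitCell(24, 24, 24), nAtoms = 6L, solventFraction = 0.75,
    B = 20, resolution = 3, noiseFrac = 0, seed = 7L))
}

# the headline toy: generator defaults (40 A P1 cube, fraction 0.80,
# 3 A resolution, 2% amplitude noise)
headlineToy <- function() {
  cachedFixture("headlineToy", generateToyCrystal(seed = 3L))
}

# random symmetric density map on a given grid
randomMap <- function(dims = c(8, 8, 8), cell = unitCell(20, 20, 20),
                      sg = "P1", seed = 1) {
  set.seed(seed)
  symmetrizeMap(densityMap(array(rnorm(prod(dims)), dims), cell, sg))
}

# scaled study protocol shared by the end-to-end checks: 10 envelope runs
# of 300 iterations, 5 phase runs of 1200 iterations
scaledPipeline <- function(toy, assumedFraction, seed = 42L,
                           envRuns = 10L, envIters = 300L,
                           phaseRuns = 5L, phaseIters = 1200L) {
  envCfg <- scaleStageConfig(defaultEnvelopeConfig(), envRuns, envIters)
  phCfg <- scaleStageConfig(defaultPhaseConfig(3), phaseRuns, phaseIters)
  suppressWarnings(runTwoStage(
    toy@refl, assumedFraction, envCfg, phCfg, seed = seed,
    truth = list(phases = toy@phases, envelope = toy@envelope)))
}

pipelineBase <- function() {
  cachedFixture("pipeBase", scaledPipeline(headlineToy(), 0.80))
}

pipelineLowFraction <- function() {
  cachedFixture("pipeLow", scaledPipeline(
    cachedFixture("toy60", generateToyCrystal(seed = 3L, solventFraction = 0.60)),
    0.60))
}

pipelineUnder <- function() {
  cachedFixture("pipeUnder", scaledPipeline(headlineToy(), 0.75,
    envRuns = 6L, phaseRuns = 4L))
}

pipelineOver <- function() {
  cachedFixture("pipeOver", scaledPipeline(headlineToy(), 0.90,
    envRuns = 6L, phaseRuns = 4L))
}
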