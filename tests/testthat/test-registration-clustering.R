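# Origin/inversion registration, envelope and phase distances, DB-SCAN
# clustering and consensus construction.

test_that("envelope correlation matches exhaustive 2x2 counting", {
  dims <- c(8, 8, 8)
  cell <- unitCell(16, 16, 16)
  set.seed(1)
  m1 <- array(runif(512) < 0.3, dims)
  m2 <- array(runif(512) < 0.3, dims)
  e1 <- binaryEnvelope(m1, 0.7, cell)
  e2 <- binaryEnvelope(m2, 0.7, cell)
  n11 <- as.numeric(sum(m1 & m2)); n10 <- as.numeric(sum(m1 & !m2))
  n01 <- as.numeric(sum(!m1 & m2)); n00 <- as.numeric(sum(!m1 & !m2))
  oracle <- (n11 * n00 - n01 * n10) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  expect_equal(envelopeCC(e1, e2), oracle)

  expect_equal(envelopeCC(e1, e1), 1)
  # complement at fraction 0.5 gives exactly -1
  h <- array(c(rep(TRUE, 256), rep(FALSE, 256)), dims)
  eh <- binaryEnvelope(h, 0.5, cell)
  ehc <- binaryEnvelope(!h, 0.5, cell)
  expect_equal(envelopeCC(eh, ehc), -1)
  # independent large masks: |CC| < 0.02
  set.seed(2)
  big <- c(50, 50, 40)
  b1 <- binaryEnvelope(array(runif(1e5) < 0.25, big), 0.75, cell)
  b2 <- binaryEnvelope(array(runif(1e5) < 0.25, big), 0.75, cell)
  expect_lt(abs(envelopeCC(b1, b2)), 0.02)
  # single-class mask undefined
  expect_warning(cc <- envelopeCC(
    binaryEnvelope(array(TRUE, dims), 0.5, cell), e1), "undefined")
  expect_true(is.na(cc))
})

test_that("registration recovers planted origin shifts and inversions", {
  toy <- smallToy()
  env <- toy@envelope
  expect_equal(bestRegistration(env, env)@shift, c(0, 0, 0))
  expect_false(bestRegistration(env, env)@inverted)
  expect_equal(bestRegistration(env, env)@score, 1)

  # planted on-grid translation in P1 (continuous origins)
  dims <- dim(envelopeMask(env))
  t0 <- c(5L, 2L, 9L)
  shifted <- binaryEnvelope(dmphase:::.translateArray(envelopeMask(env), t0),
                            env@solventFraction, env@cell, env@spacegroup)
  reg <- bestRegistration(env, shifted)
  expect_equal(round(reg@shift * dims), -t0 %% dims, ignore_attr = TRUE)
  expect_equal(reg@score, 1)
  back <- applyRegistration(shifted, reg)
  expect_identical(envelopeMask(back), envelopeMask(env))

  # planted inversion (achiral group: permitted)
  inv <- binaryEnvelope(dmphase:::.invertArray(envelopeMask(env)),
                        env@solventFraction, env@cell, env@spacegroup)
  regi <- bestRegistration(env, inv)
  expect_true(regi@inverted)
  expect_equal(regi@score, 1)
  expect_identical(envelopeMask(applyRegistration(inv, regi)),
                   envelopeMask(env))

  # discrete group: planted allowed half-cell shift in P212121
  sg <- spaceGroup("P212121")
  cell <- unitCell(20, 22, 24)
  dimsD <- suggestGrid(cell, 2, sg)
  set.seed(9)
  vm <- densityMap(array(rnorm(prod(dimsD)), dimsD), cell, sg)
  vm <- symmetrizeMap(vm)
  e <- envelopeFromVariance(localVarianceMap(vm, 5), 0.7)
  tfrac <- c(0.5, 0, 0.5)
  tgrid <- as.integer(tfrac * dimsD)
  sh <- binaryEnvelope(dmphase:::.translateArray(envelopeMask(e), tgrid),
                       0.7, cell, sg)
  regD <- bestRegistration(e, sh, allowInversion = FALSE)
  expect_equal(regD@score, 1)
  expect_equal(sort(unique(abs(regD@shift))) %in% c(0, 0.5),
               rep(TRUE, length(unique(abs(regD@shift)))))
  expect_identical(envelopeMask(applyRegistration(sh, regD)),
                   envelopeMask(e))
})

test_that("envelope distance behaves as a registered pseudo-metric", {
  toy <- smallToy()
  env <- toy@envelope
  expect_equal(envelopeDistance(env, env), 0)
  set.seed(3)
  dims <- dim(envelopeMask(env))
  rnd <- binaryEnvelope(array(runif(prod(dims)) < 0.25, dims), 0.75,
                        env@cell, env@spacegroup)
  d <- envelopeDistance(env, rnd)
  expect_gt(d, 0.9)  # unrelated envelopes sit near 1
  expect_equal(envelopeDistance(rnd, env), d, tolerance = 1e-9)
})

test_that("phase distance finds planted shifts and has the right null", {
  toy <- smallToy()
  ps <- toy@phases
  expect_equal(phaseDistance(ps, ps), 0, tolerance = 1e-9)

  # planted origin shift: phases rotated by 360 h.t for an on-grid t
  dims <- dim(mapValues(toy@map))
  t0 <- c(3, 11, 6) / dims
  reg <- new("Registration", shift = t0, inverted = FALSE, score = 1)
  ps2 <- applyRegistration(ps, reg)
  expect_gt(mean(dmphase:::.absAngleDiff(phaseValues(ps2) - phaseValues(ps)),
                 na.rm = TRUE), 20)  # naive comparison is far off
  expect_lt(phaseDistance(ps, ps2), 0.01)

  # inversion alternative: negated phases register back to zero distance
  psi <- new("PhaseSet", refl = ps@refl,
             phase = dmphase:::.wrap360(-phaseValues(ps)),
             weight = ps@weight, sigma = ps@sigma)
  expect_lt(phaseDistance(ps, psi), 0.01)

  # independent uniform phases: mean absolute difference ~ 90 degrees.
  # built in P212121 (discrete origins) so registration cannot deflate the
  # null by much
  cell <- unitCell(60, 62, 64)
  sg <- spaceGroup("P212121")
  hkl <- dmphase:::.uniqueHKLtoResolution(cell, sg, 2.2)
  set.seed(10)
  refl <- reflectionData(hkl$h, hkl$k, hkl$l, runif(nrow(hkl), 1, 10),
                         cell = cell, spacegroup = sg)
  n <- nReflections(refl)
  expect_gt(n, 9000)
  pa <- phaseSet(refl, runif(n, 0, 360))
  pb <- phaseSet(refl, runif(n, 0, 360))
  expect_lt(abs(phaseDistance(pa, pb) - 90), 2)
})

test_that("weighted phase differences follow the stated formula", {
  cell <- unitCell(20, 20, 20)  # small cell: nothing below the 25 A cutoff
  refl <- reflectionData(1:5, c(0, 1, 0, 2, 1), c(0, 0, 1, 1, 2),
                         fobs = c(5, 4, 3, 2, 1), cell = cell,
                         spacegroup = "P212121", lowResCutoff = 25)
  p1 <- phaseSet(refl, c(10, 50, 100, 200, 300))
  p2 <- phaseSet(refl, c(30, 40, 140, 170, 280))
  # hand computation at zero shift: diffs 20,10,40,30,20
  expect_equal(phaseDistance(p1, p2, allowInversion = FALSE), 24,
               tolerance = 1e-9)
  # with apodization weights the value changes exactly per the formula
  sig <- 0.1
  p1w <- phaseSet(refl, c(10, 50, 100, 200, 300), sigma = sig)
  w <- apodizationWeight(reflTable(refl)$s, sig)
  d1 <- dmphase:::.absAngleDiff(phaseValues(p1w) - phaseValues(p2))
  manual <- sum(w * d1) / sum(w)
  got <- weightedMeanAbsPhaseDiff(p1w, p2, allowInversion = FALSE)
  expect_lte(got, manual + 1e-9)   # registration can only improve
  # at the identity registration the formula matches exactly
  expect_equal(dmphase:::.registerPhasePair(p1w, p2, weights = p1w@weight,
                                            allowInversion = FALSE)$mapd,
               got)
  expect_equal(weightedMeanAbsPhaseDiff(p1, p1), 0)
})

test_that("DB-SCAN on precomputed distances follows the definition", {
  # two tight groups of 6 at distance 0.01, inter-group 0.9
  n <- 12
  D <- matrix(0.9, n, n)
  D[1:6, 1:6] <- 0.01
  D[7:12, 7:12] <- 0.01
  diag(D) <- 0
  cs <- dbscanClusters(D, minPoints = 5, eps = 0.1)
  expect_equal(max(cs@labels), 2L)
  expect_equal(cs@labels[1:6], rep(1L, 6))
  expect_equal(cs@labels[7:12], rep(2L, 6))

  # all points mutually distant: everything is noise
  D2 <- matrix(1, 8, 8); diag(D2) <- 0
  expect_equal(max(dbscanClusters(D2, 3, 0.5)@labels), 0L)

  # a group of minPoints - 1 is noise by definition
  D3 <- matrix(1, 8, 8); diag(D3) <- 0
  D3[1:4, 1:4] <- 0.01; diag(D3) <- 0
  expect_equal(max(dbscanClusters(D3, 5, 0.1)@labels), 0L)
  expect_equal(max(dbscanClusters(D3, 4, 0.1)@labels), 1L)

  expect_error(dbscanClusters(matrix(c(0, NA, NA, 0), 2), 2, 1), "NA")
})

test_that("the envelope eps rule takes the 4th percentile", {
  D <- matrix(0.7, 10, 10); diag(D) <- 0
  expect_equal(chooseEpsEnvelopes(D), 0.7)
  # uniform grid of distances ~ 0.04 at the 4th percentile
  n <- 101
  vals <- seq(0, 1, length.out = n * (n - 1) / 2)
  D2 <- matrix(0, n, n)
  D2[upper.tri(D2)] <- vals
  D2 <- D2 + t(D2)
  expect_equal(chooseEpsEnvelopes(D2), 0.04, tolerance = 0.01)
  # invariant under relabeling of the inputs
  perm <- sample(n)
  expect_equal(chooseEpsEnvelopes(D2[perm, perm]), chooseEpsEnvelopes(D2))
})

test_that("consensus envelopes vote by voxel and edit connectivity", {
  toy <- smallToy()
  env <- toy@envelope
  cons <- consensusEnvelope(list(env, env, env))
  expect_gte(envelopeCC(cons, env), 0.95)

  # one member disagreeing on one voxel loses the vote
  m2 <- env; m3 <- env
  vox <- which(envelopeMask(env))[1]
  mm <- envelopeMask(m3); mm[vox] <- FALSE
  m3@mask <- mm
  cons2 <- consensusEnvelope(list(env, m2, m3), minFraction = 0)
  expect_true(envelopeMask(cons2)[vox])
  # ties count as protein
  cons3 <- consensusEnvelope(list(env, m3), minFraction = 0)
  expect_true(envelopeMask(cons3)[vox])

  # a planted 5-voxel island is erased by the connectivity edit
  mi <- envelopeMask(env)
  corner <- which(!mi)[c(1, 2)]
  # pick 5 solvent voxels in a far corner forming a line
  d <- dim(mi)
  far <- arrayInd(which(!mi), d)
  pick <- far[order(-rowSums(far)), ][1:5, ]
  lin <- pick[, 1] + d[1] * ((pick[, 2] - 1) + d[2] * (pick[, 3] - 1))
  mi[lin] <- TRUE
  planted <- binaryEnvelope(mi, env@solventFraction, env@cell, env@spacegroup)
  edited <- editConnectivity(planted, minFraction = 6 / sum(mi))
  expect_true(all(!envelopeMask(edited)[lin]))
  cn <- envelopeConnectivity(edited)
  expect_equal(cn$islandFraction, 0)

  expect_error(consensusEnvelope(list(env)), ">= 2")
})

test_that("consensus phases are circular means with circular variance", {
  toy <- smallToy()
  ps <- toy@phases
  out <- consensusPhases(list(ps, ps, ps))
  expect_equal(out$circularVariance, 0, tolerance = 1e-12)
  common <- !is.na(phaseValues(ps))
  expect_equal(phaseValues(out$phases)[common], phaseValues(ps)[common],
               tolerance = 1e-6)

  # two phases 10 and 50 average to 30
  refl <- reflectionData(1:3, c(0, 1, 1), c(0, 0, 1), c(3, 2, 1),
                         cell = unitCell(30, 30, 30),
                         spacegroup = "P212121")
  pA <- phaseSet(refl, c(10, 10, 10))
  pB <- phaseSet(refl, c(50, 50, 50))
  outAB <- consensusPhases(list(pA, pB))
  expect_equal(phaseValues(outAB$phases), rep(30, 3), tolerance = 1e-6)
  expect_equal(outAB$circularVariance, 1 - cos(pi / 9), tolerance = 1e-9)

  # antipodal pair: zero resultant, flagged undefined
  pC <- phaseSet(refl, c(190, 50, 50))
  expect_warning(outAC <- consensusPhases(list(pA, pC)), "undefined")
  expect_true(outAC$undefined[1])
  expect_true(is.na(phaseValues(outAC$phases)[1]))
})

test_that("registration scores are shift-invariant over the allowed set", {
  toy <- smallToy()
  env <- toy@envelope
  dims <- dim(envelopeMask(env))
  set.seed(21)
  rnd <- binaryEnvelope(array(runif(prod(dims)) < 0.25, dims), 0.75,
                        env@cell, env@spacegroup)
  base <- bestRegistration(env, rnd)@score
  t0 <- c(4L, 4L, 8L)
  both <- bestRegistration(
    binaryEnvelope(dmphase:::.translateArray(envelopeMask(env), t0), 0.75,
                   env@cell, env@spacegroup),
    binaryEnvelope(dmphase:::.translateArray(envelopeMask(rnd), t0), 0.75,
                   env@cell, env@spacegroup))@score
  expect_equal(both, base, tolerance = 1e-9)
})
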