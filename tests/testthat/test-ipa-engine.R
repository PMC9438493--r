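# The Difference Map and Error Reduction update rules, convergence
# behaviour on toy constraint-satisfaction problems, and run execution.

# projection onto a line a + t*u in R^n (convex, affine)
projLine <- function(a, u) {
  u <- u / sqrt(sum(u^2))
  function(x) a + sum((x - a) * u) * u
}
# projection onto a circle (non-convex)
projCircle <- function(center, r) {
  function(x) {
    d <- x - center
    nd <- sqrt(sum(d^2))
    if (nd == 0) return(center + c(r, 0))
    center + d * (r / nd)
  }
}

test_that("DM parameters are validated and default to Elser's choice", {
  p <- dmParameters(0.7)
  expect_equal(p@gammaA, -1 / 0.7)
  expect_equal(p@gammaB, 1 / 0.7)
  expect_error(dmParameters(0), "beta")
  expect_error(dmParameters(1.2), "beta")
})

test_that("ER converges on intersecting affine constraints", {
  PA <- projLine(c(0, 0), c(1, 0))     # x-axis
  PB <- projLine(c(0, 0), c(1, 1))     # diagonal; intersection = origin
  x <- c(3, -2)
  errs <- numeric(50)
  for (i in 1:50) {
    errs[i] <- sqrt(sum((PB(x) - x)^2))
    x <- erStep(x, PA, PB)
  }
  expect_lt(sqrt(sum(x^2)), 1e-6)               # reached the intersection
  expect_true(all(diff(errs) <= 1e-12))         # error non-increasing
  # a point already in the intersection is a fixed point
  expect_equal(erStep(c(0, 0), PA, PB), c(0, 0))
})

test_that("dmStep matches a hand-rolled scalar reference", {
  # two-point constraint sets {a}, {b} in 1-D
  a <- 1.5; b <- -0.5; beta <- 0.7
  PA <- function(x) rep(a, length(x))
  PB <- function(x) rep(b, length(x))
  x <- 0.2
  xr <- 0.2
  for (i in 1:100) {
    st <- dmStep(x, PA, PB, dmParameters(beta))
    x <- st$x
    # scalar reference, written out elementwise
    gA <- -1 / beta; gB <- 1 / beta
    fA <- (1 + gA) * a - gA * xr
    fB <- (1 + gB) * b - gB * xr
    estA <- a; estB <- b     # point sets project everything to the point
    xr <- xr + beta * (estA - estB)
    expect_equal(st$estA, a)
    expect_equal(st$estB, b)
  }
  expect_equal(x, xr)

  # est_A = est_B means convergence: the iterate stops moving
  PI <- function(x) x
  st <- dmStep(c(1, 2, 3), PI, PI, dmParameters(0.6))
  expect_equal(st$x, c(1, 2, 3))
})

test_that("deltaDM matches its closed forms", {
  expect_equal(deltaDM(c(1, 2), c(1, 2)), 0)
  x <- rnorm(50)
  expect_equal(deltaDM(x + 0.3, x), 0.3)
  y <- rnorm(50)
  expect_equal(deltaDM(x, y), sqrt(mean((x - y)^2)))
})

test_that("negating beta reverses the projection order", {
  PA <- projLine(c(0, 1), c(1, 0.3))
  PB <- projLine(c(1, 0), c(-0.2, 1))
  beta <- 0.45
  neg <- negateBeta(dmParameters(beta))
  expect_equal(neg@beta, -beta)
  expect_equal(neg@gammaA, 1 / beta)
  x1 <- c(2, 2); x2 <- c(2, 2)
  for (i in 1:40) {
    x1 <- dmStep(x1, PA, PB, neg)$x
    x2 <- dmStep(x2, PB, PA, dmParameters(beta))$x
  }
  expect_equal(x1, x2, tolerance = 1e-9)
  # double negation restores the original dynamics
  x3 <- c(2, 2)
  for (i in 1:40) x3 <- dmStep(x3, PA, PB, dmParameters(-(-beta)))$x
  x4 <- c(2, 2)
  for (i in 1:40) x4 <- dmStep(x4, PA, PB, dmParameters(beta))$x
  expect_equal(x3, x4)
})

test_that("DM converges on convex toys with nonempty intersection", {
  PA <- projLine(c(0, 0, 1), c(1, 0, 0))
  PB <- projLine(c(0, 0, 1), c(0, 1, 0))  # intersect at (0,0,1)
  x <- c(2, -3, 0)
  for (i in 1:300) {
    st <- dmStep(x, PA, PB, dmParameters(0.7))
    x <- st$x
  }
  expect_lt(deltaDM(st$estA, st$estB), 1e-8)
  expect_lt(sqrt(sum((st$estA - c(0, 0, 1))^2)), 1e-6)
})

test_that("ER stagnates on a non-convex two-circle toy while DM escapes", {
  # two intersecting circles; on the symmetry axis both projections stay
  # axial, so ER settles at a non-solution fixed point
  PA <- projCircle(c(0, 0), 1)
  PB <- projCircle(c(1.5, 0), 1)
  x <- c(-2, 0)
  for (i in 1:200) {
    xn <- erStep(x, PA, PB)
    stepSize <- sqrt(sum((xn - x)^2))
    x <- xn
  }
  expect_lt(stepSize, 1e-10)                       # stopped moving
  expect_gt(sqrt(sum((PB(x) - x)^2)), 1e-3)        # but violates B

  # DM from the same stagnation-prone start keeps exploring: its iterate
  # never freezes at a non-solution
  y <- c(-2, 0)
  minStep <- Inf
  for (i in 1:200) {
    st <- dmStep(y, PA, PB, dmParameters(0.7))
    minStep <- min(minStep, sqrt(sum((st$x - y)^2)))
    y <- st$x
  }
  expect_gt(minStep, 1e-6)

  # and from a generic start DM locates a point in both circles
  z <- c(-2, 0.7)
  found <- FALSE
  for (i in 1:2000) {
    st <- dmStep(z, PA, PB, dmParameters(0.7))
    z <- st$x
    if (deltaDM(st$estA, st$estB) < 1e-10) { found <- TRUE; break }
  }
  expect_true(found)
  sol <- st$estA
  expect_lt(abs(sqrt(sum(sol^2)) - 1), 1e-8)
  expect_lt(abs(sqrt(sum((sol - c(1.5, 0))^2)) - 1), 1e-8)
})

test_that("runStage executes plans reproducibly", {
  toy <- smallToy()
  refl <- toy@refl
  ref <- referenceHistogramFromToy(toy, 0.2)
  dims <- dim(mapValues(toy@map))

  plan0 <- iterationPlan(new("StageConfig", kind = "envelope", runs = 1L,
                             blocks = list(), apodPlan = list(type = "none"),
                             filterPlan = list(rStart = 8, rEnd = 8,
                                               shrinkIters = 0L),
                             lowResCutoff = 25, holdEnvelope = 0L,
                             gridSpacingFrac = 0.4,
                             effectiveResolution = 3))
  expect_equal(nrow(plan0), 0L)
  r0 <- runStage(refl, plan0, 0.75, ref, dims, seed = 5)
  expect_equal(nrow(trajectoryMetrics(r0$trajectory)), 0L)

  cfg <- scaleStageConfig(defaultEnvelopeConfig(), runs = 1, iterations = 30)
  plan <- iterationPlan(cfg, max(reflTable(refl)$s))
  res1 <- runStage(refl, plan, 0.75, function(s) referenceHistogramFromToy(toy, s),
                   dims, seed = 11)
  expect_equal(nrow(trajectoryMetrics(res1$trajectory)), 30L)
  expect_true(all(is.finite(trajectoryMetrics(res1$trajectory)$deltaDM)))
  res2 <- runStage(refl, plan, 0.75, function(s) referenceHistogramFromToy(toy, s),
                   dims, seed = 11)
  expect_identical(trajectoryMetrics(res1$trajectory),
                   trajectoryMetrics(res2$trajectory))
  # different seed gives a different trajectory
  res3 <- runStage(refl, plan, 0.75, function(s) referenceHistogramFromToy(toy, s),
                   dims, seed = 12)
  expect_false(identical(trajectoryMetrics(res1$trajectory)$deltaDM,
                         trajectoryMetrics(res3$trajectory)$deltaDM))
})

test_that("the two solution estimates satisfy their constraint sets", {
  toy <- smallToy()
  refl <- toy@refl
  cfg <- scaleStageConfig(defaultEnvelopeConfig(), runs = 1, iterations = 15)
  plan <- iterationPlan(cfg, max(reflTable(refl)$s))
  dims <- dim(mapValues(toy@map))
  # hold the supplied envelope fixed so the constraint set is static
  res <- runStage(refl, plan, 0.75,
                  function(s) referenceHistogramFromToy(toy, s), dims,
                  envelope = toy@envelope, holdEnvelope = 10^6L, seed = 21)
  # est_A satisfies the real-space constraints exactly
  expect_equal(solventVariance(res$estA, res$envelope), 0)
  # est_B reproduces the observed amplitudes exactly after scaling
  ag <- amplitudeAgreement(refl, res$estB, apod = plan$sigma[nrow(plan)])
  expect_equal(ag$cc, 1, tolerance = 1e-8)
  expect_lt(ag$r, 1e-8)
})

test_that("trajectories serialize as tab-separated text", {
  toy <- smallToy()
  cfg <- scaleStageConfig(defaultEnvelopeConfig(), runs = 1, iterations = 5)
  plan <- iterationPlan(cfg, max(reflTable(toy@refl)$s))
  res <- runStage(toy@refl, plan, 0.75,
                  function(s) referenceHistogramFromToy(toy, s),
                  dim(mapValues(toy@map)), seed = 2)
  tmp <- tempfile()
  writeTrajectory(res$trajectory, tmp)
  lines <- readLines(tmp)
  expect_match(lines[1], "^# seed 2")
  got <- read.delim(tmp, comment.char = "#")
  expect_equal(nrow(got), 5)
  expect_true(all(c("deltaDM", "solventVariance", "wasserstein", "ampCC")
                  %in% names(got)))
})
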