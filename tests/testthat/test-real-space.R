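# Solvent flattening, histogram matching, the variance-based envelope and
# the real-space agreement metrics.

test_that("the triweight kernel matches its closed form", {
  expect_equal(triweight(0, 5), 1)
  expect_equal(triweight(5, 5), 0)
  expect_equal(triweight(2.5, 5), (3 / 4)^3)  # 0.421875
  expect_equal(triweight(7, 5), 0)
  r <- seq(0, 5, by = 0.1)
  expect_true(all(diff(triweight(r, 5)) <= 0))
})

test_that("local variance agrees with a direct windowed computation", {
  cell <- unitCell(16, 16, 16)
  dims <- c(16, 16, 16)

  cst <- densityMap(array(2.7, dims), cell)
  vm <- localVarianceMap(cst, 3)
  expect_lt(max(abs(mapValues(vm))), 1e-12)

  # two-level block map: brute-force windowed oracle
  vals <- array(0, dims)
  vals[1:8, , ] <- 1
  m <- densityMap(vals, cell)
  r0 <- 3
  vm <- localVarianceMap(m, r0)

  dist <- dmphase:::.gridDistance(dims, cell)
  kv <- triweight(as.numeric(dist), r0)
  kv <- kv / sum(kv)
  karr <- array(kv, dims)
  direct <- array(NA_real_, dims)
  off <- which(karr > 0, arr.ind = TRUE) - 1L
  w <- karr[karr > 0]
  for (i in c(1, 5, 8, 9, 16)) for (j in c(1, 8)) {
    k <- 4
    src <- vals[cbind((i - 1 + off[, 1]) %% 16 + 1,
                      (j - 1 + off[, 2]) %% 16 + 1,
                      (k - 1 + off[, 3]) %% 16 + 1)]
    mu <- sum(w * src)
    direct[i, j, k] <- sum(w * src^2) - mu^2
    expect_equal(mapValues(vm)[i, j, k], direct[i, j, k], tolerance = 1e-10)
  }
  # variance peaks at the interface
  expect_gt(mapValues(vm)[8, 8, 8], mapValues(vm)[4, 8, 8])

  # shift invariance
  vm2 <- localVarianceMap(densityMap(vals + 11, cell), r0)
  expect_equal(mapValues(vm2), mapValues(vm), tolerance = 1e-9)

  expect_error(localVarianceMap(m, 0.5), "below two grid spacings")
  expect_error(localVarianceMap(m, 9), "beyond half the cell")
})

test_that("envelope thresholding realizes the requested fraction", {
  cell <- unitCell(8, 8, 8)
  set.seed(4)
  vm <- densityMap(array(runif(64), c(4, 4, 4)), cell)
  env <- envelopeFromVariance(vm, 0.75)
  expect_equal(sum(envelopeMask(env)), 16)

  # monotone field: threshold equals the fraction quantile (sort oracle)
  v <- array(seq_len(1000), c(10, 10, 10))
  envm <- envelopeFromVariance(densityMap(v, unitCell(10, 10, 10)), 0.6)
  expect_equal(sort(which(envelopeMask(envm))), 601:1000)

  # realized fraction within one grid point of target on random fields
  for (seed in 1:3) {
    set.seed(seed)
    vmr <- densityMap(array(rnorm(12^3), c(12, 12, 12)), unitCell(12, 12, 12))
    e <- envelopeFromVariance(vmr, 0.71)
    expect_lt(abs(realizedSolventFraction(e) - 0.71), 1 / 12^3 + 1e-12)
    # affine rescaling of the input leaves the envelope unchanged
    e2 <- envelopeFromVariance(densityMap(3 * mapValues(vmr) + 7,
                                          unitCell(12, 12, 12)), 0.71)
    expect_identical(envelopeMask(e), envelopeMask(e2))
  }

  expect_error(envelopeFromVariance(densityMap(array(1, c(4, 4, 4)), cell),
                                    0.75), "constant")
})

test_that("solvent flattening touches only the solvent region", {
  cell <- unitCell(6, 6, 6)
  dims <- c(6, 6, 6)
  mask <- array(FALSE, dims); mask[1:3, , ] <- TRUE
  env <- binaryEnvelope(mask, 0.5, cell)
  vals <- array(rnorm(216), dims)
  m <- densityMap(vals, cell)
  fl <- flattenSolvent(m, env)
  expect_equal(mapValues(fl)[mask], vals[mask])
  expect_equal(unique(as.numeric(mapValues(fl)[!mask])),
               mean(vals[!mask]))
  expect_equal(solventVariance(fl, env), 0)
  # idempotent
  expect_equal(mapValues(flattenSolvent(fl, env)), mapValues(fl))

  # population variance: solvent {0,2} has variance 1
  v2 <- array(0, dims); v2[!mask] <- rep(c(0, 2), length.out = sum(!mask))
  expect_equal(solventVariance(densityMap(v2, cell), env), 1)
  # direct-formula check on a random fixture
  expect_equal(solventVariance(m, env),
               mean((vals[!mask] - mean(vals[!mask]))^2))
})

test_that("histogram matching is rank-preserving and mean-correct", {
  cell <- unitCell(6, 6, 6)
  dims <- c(6, 6, 6)
  mask <- array(FALSE, dims); mask[, , 1:3] <- TRUE
  env <- binaryEnvelope(mask, 0.5, cell)
  set.seed(8)
  ref <- referenceHistogram(rnorm(5000, mean = 2, sd = 0.7))

  vals <- array(rnorm(216), dims)
  m <- densityMap(vals, cell)
  hm <- histogramMatchProtein(m, env, ref)
  pv <- mapValues(hm)[mask]
  expect_equal(order(pv), order(vals[mask]))        # monotone
  expect_equal(mean(pv), mean(ref@values))           # mean shifted to ref

  # a map already matching the reference is (nearly) unchanged
  m2 <- hm
  hm2 <- histogramMatchProtein(m2, env, ref)
  expect_lt(max(abs(mapValues(hm2)[mask] - mapValues(m2)[mask])) /
              diff(range(ref@values)), 0.02)

  # uniform protein values mapped onto a two-point reference
  ref2 <- referenceHistogram(rep(c(0, 1), each = 500))
  m3 <- densityMap(array(runif(216), dims), cell)
  hm3 <- histogramMatchProtein(m3, env, ref2)
  w1 <- wasserstein1(mapValues(hm3)[mask], ref2@values)
  expect_lt(w1, 1e-6 * 1)

  expect_error(histogramMatchProtein(m,
    binaryEnvelope(array(c(TRUE, rep(FALSE, 215)), dims), 0.9, cell), ref),
    "fewer than 10")
})

test_that("the real-space projection is idempotent and region-local", {
  toy <- smallToy()
  env <- toy@envelope
  ref <- referenceHistogramFromToy(toy)
  set.seed(12)
  m <- densityMap(array(rnorm(prod(dim(envelopeMask(env)))),
                        dim(envelopeMask(env))), toy@cell)
  p1 <- projectReal(m, env, ref)
  p2 <- projectReal(p1, env, ref)
  expect_lt(max(abs(mapValues(p2) - mapValues(p1))) /
              diff(range(mapValues(p1))), 1e-9)
  expect_equal(solventVariance(p1, env), 0)
  # protein untouched by the flattening half
  hm <- histogramMatchProtein(m, env, ref)
  expect_equal(mapValues(p1)[envelopeMask(env)],
               mapValues(hm)[envelopeMask(env)])
})

test_that("rank->quantile matching is the least-squares monotone transport", {
  # exhaustive check on a 5-point region: among all bijections of the
  # values onto the 5 reference quantiles, the rank-preserving one
  # minimizes the squared change
  v <- c(0.3, -1.2, 2.4, 0.9, 0.1)
  refq <- c(-0.5, 0.2, 0.6, 1.4, 3.0)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  costs <- apply(perms, 1, function(p) sum((refq[p] - v)^2))
  bestPerm <- perms[which.min(costs), ]
  rankPerm <- match(rank(v), 1:5)
  expect_equal(refq[bestPerm], refq[rank(v)])
})

test_that("Wasserstein-1 matches closed forms and is a metric", {
  x <- runif(400)
  expect_equal(wasserstein1(x, x), 0)
  # translated point masses
  expect_equal(wasserstein1(rep(1.3, 10), rep(1.3 + 0.25, 10)), 0.25)
  # translated uniforms, via explicit CDF tables (trapezoid rule)
  g <- seq(0, 1, by = 0.001)
  expect_equal(wassersteinCDF(g, punif(g), g + 0.2, punif(g)), 0.2,
               tolerance = 1e-3)
  set.seed(77)
  expect_lt(abs(wasserstein1(runif(4000), runif(4000) + 0.2) - 0.2), 0.02)
  # triangle inequality on random empirical triples
  for (i in 1:5) {
    a <- rnorm(300); b <- rexp(300); c <- runif(300, -1, 2)
    expect_lte(wasserstein1(a, c),
               wasserstein1(a, b) + wasserstein1(b, c) + 1e-12)
  }
})
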