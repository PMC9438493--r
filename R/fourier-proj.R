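# Fourier-space constraint machinery: the amplitude projection P_B with its
# Wilson-statistics guard on missing data, amplitude agreement metrics, and
# overall B-factor estimation.

# --- grid <-> reflection mapping -----------------------------------------

# Precompute, for a reflection set and a grid, everything the amplitude
# projection needs. Cached inside the ReflectionData object keyed by dims.
.fourierContext <- function(refl, dims) {
  key <- paste("ctx", paste(dims, collapse = "x"))
  hit <- refl@cache[[key]]
  if (!is.null(hit)) return(hit)

  sg <- refl@spacegroup
  tb <- refl@table
  mil <- .gridMiller(dims)
  hklG <- cbind(mil$h, mil$k, mil$l)
  sGrid <- scatteringMagnitude(hklG, cell = refl@cell)
  can <- canonicalHKL(hklG, sg, details = TRUE)
  keyG <- .hklKey(can$h, can$k, can$l)
  keyR <- .hklKey(tb$h, tb$k, tb$l)
  mapIdx <- match(keyG, keyR)           # NA where grid hkl not in table
  obsIdx <- which(!is.na(mapIdx) & !tb$missing[mapIdx])

  sObs <- tb$s[!tb$missing]
  sMax <- if (length(sObs)) max(sObs) else 0
  inRange <- sGrid <= sMax + 1e-12
  zeroIdx <- which(!inRange)
  missIdx <- which(inRange & (is.na(mapIdx) | tb$missing[mapIdx]))
  originIdx <- which(sGrid == 0)

  # per-grid-point classification for the Wilson guard (exact from operators;
  # unmeasured frequencies outside the table still get their true eps/centric)
  epsG <- can$epsilon
  centG <- can$centric

  # canonical grid position of each unique reflection (for phase read-out):
  # the grid point whose Miller indices equal the canonical ones
  reflGridIdx <- match(keyR, .hklKey(mil$h, mil$k, mil$l))

  # shell statistics of the observed data (static for a given reflection set)
  shells <- shellStatistics(refl)
  shellOfGrid <- pmin(pmax(findInterval(sGrid, shells$sLow), 1L), nrow(shells))

  ctx <- list(dims = dims, n = prod(dims), sGrid = sGrid,
              mapIdx = mapIdx, obsIdx = obsIdx, missIdx = missIdx,
              zeroIdx = zeroIdx, originIdx = originIdx,
              fobsGrid = tb$fobs[mapIdx],
              epsG = epsG, centricG = centG,
              conjG = can$conj, shiftG = can$phaseShiftDeg,
              reflGridIdx = reflGridIdx,
              reflFobs = tb$fobs, reflS = tb$s, reflMissing = tb$missing,
              shells = shells, shellOfGrid = shellOfGrid,
              sg = sg, cell = refl@cell)
  refl@cache[[key]] <- ctx
  ctx
}

#' Resolution-shell statistics for Wilson-based checks
#'
#' Observed reflections are partitioned into shells of (as nearly as
#' possible) equal counts; each shell records the mean normalized intensity
#' Sigma = <I/epsilon>, the mean amplitude, the count and the centric
#' fraction. These drive the Wilson guard and the overall B estimate.
#'
#' @param refl a [ReflectionData-class]
#' @param nShells target number of shells (default 20, reduced so that each
#'   shell keeps at least `minPerShell` reflections when possible)
#' @param minPerShell minimum reflections per shell (default 50)
#' @return data.frame with columns sLow, sHigh, sMid, SigmaI, meanF, count,
#'   centricFrac
#' @export
shellStatistics <- function(refl, nShells = 20, minPerShell = 50) {
  tb <- refl@table[!refl@table$missing, ]
  if (!nrow(tb)) .stopf("no observed reflections")
  nShells <- max(1L, min(nShells, nrow(tb) %/% minPerShell,
                         nrow(tb)))
  if (nShells < 1L) nShells <- 1L
  ord <- order(tb$s)
  tb <- tb[ord, ]
  grp <- ceiling(seq_along(tb$s) / (nrow(tb) / nShells))
  grp <- pmin(grp, nShells)
  ioe <- tb$fobs^2 / tb$epsilon
  agg <- function(x, f) as.numeric(tapply(x, grp, f))
  data.frame(
    sLow = agg(tb$s, min), sHigh = agg(tb$s, max),
    sMid = agg(tb$s, stats::median),
    SigmaI = agg(ioe, mean), meanF = agg(tb$fobs, mean),
    count = agg(tb$s, length),
    centricFrac = agg(tb$centric, mean))
}

#' Wilson-statistics guard on reconstructed amplitudes
#'
#' During phase retrieval the unmeasured ("missing") Fourier amplitudes
#' evolve freely and can grow without bound, distorting the density. If a
#' reconstructed amplitude is improbably large -- upper-tail probability
#' below `threshold` under the Wilson amplitude distribution for its class
#' (acentric: Rayleigh with mean square epsilon*Sigma; centric: half-normal
#' with mean square epsilon*Sigma) -- it is reset to the expected amplitude
#' for that class at the relevant resolution. The comparison is strict: a
#' tail probability exactly at the threshold leaves the amplitude unchanged.
#'
#' @param fcalc reconstructed amplitude(s)
#' @param Sigma shell mean normalized intensity <I/epsilon> (> 0)
#' @param centric logical classification
#' @param epsilon symmetry enhancement factor(s)
#' @param threshold tail-probability cutoff, default 5e-6
#' @return amplitudes with improbable values reset to the class expectation
#' @export
wilsonGuard <- function(fcalc, Sigma, centric = FALSE, epsilon = 1,
                        threshold = 5e-6) {
  if (any(Sigma <= 0)) .stopf("nonpositive shell statistic")
  n <- length(fcalc)
  Sigma <- rep_len(Sigma, n); centric <- rep_len(centric, n)
  epsilon <- rep_len(epsilon, n)
  es <- epsilon * Sigma
  # strict comparison done on the amplitude axis for numerical robustness:
  # reset iff fcalc exceeds the threshold amplitude where the tail
  # probability equals `threshold`
  fThr <- ifelse(centric, sqrt(es) * stats::qnorm(1 - threshold / 2),
                 sqrt(-es * log(threshold)))
  expF <- ifelse(centric, sqrt(2 * es / pi), sqrt(pi * es) / 2)
  ifelse(fcalc > fThr, expF, fcalc)
}

# --- the amplitude projection P_B ----------------------------------------

# vals: numeric 3-D array; returns list(vals, scale)
.projectFourierCtx <- function(vals, ctx, sigma = Inf, guard = TRUE) {
  Fc <- stats::fft(vals, inverse = TRUE) / ctx$n
  amp <- Mod(Fc)
  w <- if (is.finite(sigma)) exp(-ctx$sGrid[ctx$obsIdx]^2 / (2 * sigma^2)) else 1
  target <- w * ctx$fobsGrid[ctx$obsIdx]
  aobs <- amp[ctx$obsIdx]
  k <- sum(aobs * target) / sum(target^2)
  if (!is.finite(k) || k <= 0) k <- 1
  newAmp <- amp
  newAmp[ctx$obsIdx] <- k * target
  if (guard && length(ctx$missIdx)) {
    mi <- ctx$missIdx
    wm <- if (is.finite(sigma)) exp(-ctx$sGrid[mi]^2 / (2 * sigma^2)) else 1
    SigEff <- (k * wm)^2 * ctx$epsG[mi] *
      ctx$shells$SigmaI[ctx$shellOfGrid[mi]]
    a <- amp[mi]
    cen <- ctx$centricG[mi]
    fThr <- ifelse(cen, sqrt(SigEff) * stats::qnorm(1 - 2.5e-6),
                   sqrt(-SigEff * log(5e-6)))
    expF <- ifelse(cen, sqrt(2 * SigEff / pi), sqrt(pi * SigEff) / 2)
    newAmp[mi] <- ifelse(a > fThr, expF, a)
  }
  ratio <- ifelse(amp > 0, newAmp / amp, 0)
  Fn <- Fc * ratio
  Fn[amp == 0 & newAmp > 0] <- newAmp[amp == 0 & newAmp > 0]  # phase 0 fallback
  if (length(ctx$zeroIdx)) Fn[ctx$zeroIdx] <- 0
  out <- Re(stats::fft(array(Fn, ctx$dims)))
  out <- .symmetrizeValues(out, ctx$sg, ctx$dims)
  list(vals = array(out, ctx$dims), scale = k)
}

#' Fourier-amplitude projection P_B
#'
#' Fourier transforms the current density, replaces the amplitudes of the
#' observed reflections with the (apodized, least-squares scaled) measured
#' amplitudes while preserving the calculated phases, leaves missing
#' reflections at their calculated amplitude subject to the Wilson guard,
#' zeroes frequencies beyond the measured resolution range, and transforms
#' back. This is the Euclidean-closest map with the required amplitudes.
#'
#' @param map a [DensityMap-class]
#' @param refl a [ReflectionData-class] sharing the cell and group
#' @param apod an [Apodization-class], sigma, or `Inf` for none
#' @param guard apply the Wilson guard to missing amplitudes
#' @return a [DensityMap-class]
#' @export
projectFourier <- function(map, refl, apod = Inf, guard = TRUE) {
  sigma <- if (is(apod, "Apodization")) apod@sigma else as.numeric(apod)
  if (!any(!refl@table$missing)) .stopf("all reflections are missing")
  ctx <- .fourierContext(refl, dim(map@values))
  res <- .projectFourierCtx(map@values, ctx, sigma, guard)
  map@values <- res$vals
  map
}

# fast amplitude CC/R over unique observed reflections (trajectory metric)
.amplitudeAgreementCtx <- function(vals, ctx, sigma = Inf) {
  Fc <- stats::fft(vals, inverse = TRUE) / ctx$n
  gi <- ctx$reflGridIdx
  sel <- !ctx$reflMissing & !is.na(gi)
  fc <- Mod(Fc[gi[sel]])
  w <- if (is.finite(sigma)) exp(-ctx$reflS[sel]^2 / (2 * sigma^2)) else 1
  obs <- w * ctx$reflFobs[sel]
  k <- sum(fc * obs) / sum(obs^2)
  list(cc = suppressWarnings(stats::cor(fc, obs)),
       r = sum(abs(fc - k * obs)) / sum(k * obs), k = k)
}

#' Agreement between calculated and measured amplitudes
#'
#' Pearson correlation coefficient and R factor over the observed
#' reflections, after apodizing the measured amplitudes and applying the
#' least-squares scale k that matches the calculated amplitudes to them:
#' `R = sum |k Fcalc - w Fobs| / sum (w Fobs)`.
#'
#' @param refl a [ReflectionData-class]
#' @param calc a [DensityMap-class], or a numeric vector of calculated
#'   amplitudes in the order of `reflTable(refl)`
#' @param apod an [Apodization-class] or sigma (default none)
#' @return list with `cc`, `r` and the scale `k`; `cc` is NA (with a
#'   warning) if either amplitude set has zero variance
#' @export
amplitudeAgreement <- function(refl, calc, apod = Inf) {
  sigma <- if (is(apod, "Apodization")) apod@sigma else as.numeric(apod)
  tb <- refl@table
  if (is(calc, "DensityMap")) {
    ctx <- .fourierContext(refl, dim(calc@values))
    Fc <- stats::fft(calc@values, inverse = TRUE) / ctx$n
    gi <- ctx$reflGridIdx
    calc <- ifelse(is.na(gi), NA_real_, Mod(Fc[ifelse(is.na(gi), 1L, gi)]))
  }
  sel <- !tb$missing & !is.na(calc)
  if (sum(sel) < 2) .stopf("need at least 2 observed reflections")
  w <- if (is.finite(sigma)) apodizationWeight(tb$s[sel], sigma) else 1
  obs <- w * tb$fobs[sel]
  fc <- calc[sel]
  k <- sum(fc * obs) / sum(obs^2)
  r <- sum(abs(fc - k * obs)) / sum(k * obs)
  cc <- if (stats::sd(obs) == 0 || stats::sd(fc) == 0) {
    .warnf("zero-variance amplitude set: correlation undefined")
    NA_real_
  } else stats::cor(fc, obs)
  list(cc = cc, r = r, k = k)
}

#' Estimate the overall isotropic B factor from the amplitude data
#'
#' A Wilson-plot estimate: the log mean normalized intensity per resolution
#' shell, `ln <I/epsilon>`, is regressed (weighted by shell counts) against
#' `s^2/2`; the slope is -B. The standard error of the slope is returned,
#' and a quality warning is attached when the fit is poor (R^2 < 0.5) --
#' never silently.
#'
#' @param refl a [ReflectionData-class] (or a data.frame with columns s,
#'   fobs, epsilon, missing)
#' @param nShells shells for the fit (data must span at least 5)
#' @return list with `B` (Angstrom^2), `se`, `r.squared`
#' @export
estimateOverallB <- function(refl, nShells = 20) {
  sh <- if (is(refl, "ReflectionData")) shellStatistics(refl, nShells)
        else refl
  if (nrow(sh) < 5) .stopf("B estimation needs data spanning >= 5 resolution shells")
  x <- sh$sMid^2 / 2
  y <- log(sh$SigmaI)
  fit <- stats::lm(y ~ x, weights = sh$count)
  sm <- summary(fit)
  B <- -unname(stats::coef(fit)[2])
  out <- list(B = B, se = unname(sm$coefficients[2, 2]),
              r.squared = sm$r.squared)
  if (sm$r.squared < 0.5)
    .warnf("Wilson plot fit is poor (R^2 = %.2f); B estimate unreliable", sm$r.squared)
  out
}
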