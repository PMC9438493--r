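# Synthetic toy crystals: pseudo-atom structures in small cells with known
# density, envelope and phases, emulating the statistical structure the
# method relies on (Wilson-distributed intensities with an overall B
# factor, a generic protein-like density histogram, featureless solvent).
# Every other module is testable against these with no external data.

#' ToyCrystal: a synthetic crystal with full ground truth
#'
#' @slot cell,spacegroup the crystal frame
#' @slot atoms data.frame of pseudo-atoms: fractional x,y,z, scattering
#'   weight, isotropic B (Angstrom^2)
#' @slot map the true [DensityMap-class]
#' @slot envelope the true [BinaryEnvelope-class]
#' @slot phases the true [PhaseSet-class]
#' @slot refl [ReflectionData-class] with (optionally noisy) amplitudes
#' @slot trueAmp noise-free amplitudes per unique reflection
#' @slot f000 the (unmeasurable) zero-frequency coefficient
#' @slot solventFraction realized solvent fraction of the true envelope
#' @name ToyCrystal-class
#' @aliases ToyCrystal
#' @exportClass ToyCrystal
setClass("ToyCrystal",
  representation(cell = "UnitCell", spacegroup = "SpaceGroupSpec",
                 atoms = "data.frame", map = "DensityMap",
                 envelope = "BinaryEnvelope", phases = "PhaseSet",
                 refl = "ReflectionData", trueAmp = "numeric",
                 f000 = "numeric", solventFraction = "numeric"))

setMethod("show", "ToyCrystal", function(object) {
  cat(sprintf("ToyCrystal: %d pseudo-atoms in %s, solvent fraction %.3f, %d unique reflections\n",
              nrow(object@atoms), object@spacegroup@name,
              object@solventFraction, nrow(object@refl@table)))
})

# enumerate the symmetry-unique reflections with 0 < s <= 1/resolution
.uniqueHKLtoResolution <- function(cell, sg, resolution) {
  smax <- 1 / resolution
  lens <- cellParameters(cell)[1:3]
  hmax <- ceiling(lens * smax) + 1L
  grid <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                      l = -hmax[3]:hmax[3])
  s <- scatteringMagnitude(as.matrix(grid), cell = cell)
  keep <- s > 0 & s <= smax
  can <- canonicalHKL(as.matrix(grid[keep, ]), sg)
  uniq <- !duplicated(.hklKey(can$h, can$k, can$l))
  can[uniq, c("h", "k", "l")]
}

# structure factors of a set of Gaussian pseudo-atoms (symmetry-expanded);
# computed in chunks to bound the phase-matrix memory
.atomStructureFactors <- function(hkl, s, atoms, sg) {
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  xs <- do.call(rbind, lapply(sg@ops, function(g)
    t(g$R %*% t(pos) + g$t)))
  w <- rep(atoms$weight, length(sg@ops))
  B <- rep(atoms$B, length(sg@ops))
  Fc <- complex(length.out = nrow(hkl))
  for (chunk in split(seq_len(nrow(xs)), (seq_len(nrow(xs)) - 1) %/% 256)) {
    ph <- exp(2i * pi * (hkl %*% t(xs[chunk, , drop = FALSE])))
    fall <- exp(-outer(s^2, B[chunk]) / 4)
    Fc <- Fc + as.complex((ph * fall) %*% w[chunk])
  }
  Fc
}

#' Generate a toy crystal with known density, envelope and phases
#'
#' Pseudo-atoms (isotropic Gaussians of the given B factor) are placed as a
#' connected random cluster, so the true envelope is predominantly a single
#' component. The density is synthesized from the structure factors
#' truncated at the stated resolution; the true envelope is the set of
#' densest grid points realizing the requested solvent fraction; the stored
#' amplitudes are the transform amplitudes with optional multiplicative
#' noise `(1 + noiseFrac * N(0,1))`, floored at zero, with sigmas emitted
#' consistently. Fully reproducible from `seed`.
#'
#' @param cell a [UnitCell-class] (default 40 Angstrom cube)
#' @param spacegroup group or name (default P1)
#' @param nAtoms number of pseudo-atoms; the default (NULL) packs the
#'   protein volume at heavy-atom granularity (one pseudo-atom per 20
#'   cubic Angstrom, bond-scale walk steps), so the cluster fills its
#'   molecular footprint with continuous density the way a real protein
#'   fills its envelope. 0 gives a flat, all-solvent cell
#' @param solventFraction requested solvent fraction in (0,1)
#' @param B isotropic displacement parameter, Angstrom^2
#' @param resolution data resolution limit, Angstrom
#' @param noiseFrac multiplicative amplitude noise level (default 0.02)
#' @param seed RNG seed
#' @param lowResCutoff passed to [reflectionData()] (default 25)
#' @param gridSpacingFrac grid spacing as a fraction of the resolution
#' @param atomWeight scattering weight per pseudo-atom
#' @return a [ToyCrystal-class]
#' @export
generateToyCrystal <- function(cell = unitCell(40, 40, 40),
                               spacegroup = "P1", nAtoms = NULL,
                               solventFraction = 0.8, B = 30,
                               resolution = 3, noiseFrac = 0.02, seed = 1L,
                               lowResCutoff = 25, gridSpacingFrac = 2 / 5,
                               atomWeight = 1) {
  sg <- spaceGroup(spacegroup)
  set.seed(seed)
  ortho <- orthoMatrix(cell)
  lens <- cellParameters(cell)[1:3]
  if (is.null(nAtoms)) {
    # residue-level coarse graining: one pseudo-atom per ~135 A^3 of
    # protein volume (about one bead per residue), filling the molecular
    # region out to its surface
    protVol <- (1 - solventFraction) * cellVolume(cell) / length(sg@ops)
    nAtoms <- max(4L, as.integer(round(protVol / 135)))
  }
  nAtoms <- as.integer(nAtoms)

  if (nAtoms > 0) {
    # atoms fill a compact molecular ball uniformly out to its surface
    # (dart throwing with a bond-scale minimum separation): a single
    # connected blob whose density occupies its whole footprint, as real
    # protein does
    center <- as.numeric(ortho %*% c(0.5, 0.5, 0.5))
    rlim <- max((3 * nAtoms * 135 / (4 * pi))^(1 / 3), 6)
    rlim <- min(rlim, 0.45 * min(lens))
    minSep2 <- 3.4^2
    xyz <- matrix(NA_real_, nAtoms, 3)
    placed <- 0L
    while (placed < nAtoms) {
      cand <- stats::rnorm(3)
      cand <- center + cand / sqrt(sum(cand^2)) *
        rlim * stats::runif(1)^(1 / 3)
      if (placed > 0L) {
        d2 <- rowSums((xyz[seq_len(placed), , drop = FALSE] -
                         matrix(cand, placed, 3, byrow = TRUE))^2)
        if (min(d2) < minSep2) next
      }
      placed <- placed + 1L
      xyz[placed, ] <- cand
    }
    # secondary-structure-scale contrast: atom weights modulated by blobs
    # ~10 A apart (helix/sheet packing produces strong intermediate-
    # resolution density fluctuations that a uniform fill would lack)
    nC <- max(2L, as.integer(round(nAtoms / 8)))
    centers <- xyz[sample.int(nAtoms, nC), , drop = FALSE]
    d2min <- rep(Inf, nAtoms)
    for (ci in seq_len(nC)) {
      d2 <- rowSums((xyz - matrix(centers[ci, ], nAtoms, 3, byrow = TRUE))^2)
      d2min <- pmin(d2min, d2)
    }
    wmod <- 0.6 + 1.4 * exp(-d2min / (2 * 3.5^2))
    frac <- t(solve(ortho) %*% t(xyz)) %% 1
    atoms <- data.frame(x = frac[, 1], y = frac[, 2], z = frac[, 3],
                        weight = atomWeight * wmod, B = B)
  } else {
    atoms <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        weight = numeric(0), B = numeric(0))
  }

  uh <- .uniqueHKLtoResolution(cell, sg, resolution)
  hkl <- as.matrix(uh)
  s <- scatteringMagnitude(hkl, cell = cell)
  Fc <- if (nAtoms > 0) .atomStructureFactors(hkl, s, atoms, sg)
        else complex(length.out = nrow(hkl))
  trueAmp <- Mod(Fc)
  truePhase <- .wrap360(.rad2deg(Arg(Fc)))
  truePhase[trueAmp == 0] <- 0
  f000 <- sum(atoms$weight) * length(sg@ops)

  noise <- if (noiseFrac > 0) 1 + noiseFrac * stats::rnorm(length(trueAmp))
           else rep(1, length(trueAmp))
  fobs <- pmax(trueAmp * noise, 0)
  sigf <- noiseFrac * trueAmp
  refl <- reflectionData(hkl[, 1], hkl[, 2], hkl[, 3], fobs, sigf, cell,
                         sg, lowResCutoff)
  # align stored truth with the (re-sorted) unique table
  idx <- match(.hklKey(refl@table$h, refl@table$k, refl@table$l),
               .hklKey(hkl[, 1], hkl[, 2], hkl[, 3]))
  trueAmp <- trueAmp[idx]
  truePhase <- truePhase[idx]

  dims <- suggestGrid(cell, gridSpacingFrac * resolution, sg)
  ctx <- .fourierContext(refl, dims)
  Fg <- .expandToGrid(ctx, trueAmp, truePhase)
  Fg[1] <- f000
  vals <- Re(stats::fft(Fg))
  vals <- .symmetrizeValues(array(vals, dims), sg, dims)
  map <- densityMap(array(vals, dims), cell, sg)

  if (nAtoms > 0) {
    # true molecular envelope: the fraction-matching footprint of the
    # pseudo-atom cluster (grid points nearest to any atom, minimum-image).
    # A raw density threshold would select only the sharp peaks on top of
    # the atoms, not the molecular region the envelope concept refers to.
    idx <- .gridIndex0(dims)
    fr <- cbind(idx$i1 / dims[1], idx$i2 / dims[2], idx$i3 / dims[3])
    posAll <- do.call(rbind, lapply(sg@ops, function(g)
      t(g$R %*% t(as.matrix(atoms[, c("x", "y", "z")])) + g$t)))
    dmin <- rep(Inf, nrow(fr))
    for (j in seq_len(nrow(posAll))) {
      d <- fr - matrix(posAll[j, ] %% 1, nrow(fr), 3, byrow = TRUE)
      d <- d - round(d)
      xyz2 <- d %*% t(ortho)
      dmin <- pmin(dmin, rowSums(xyz2^2))
    }
    n <- length(vals)
    nProt <- round((1 - solventFraction) * n)
    ord <- order(dmin, seq_len(n))
    mask <- logical(n)
    mask[ord[seq_len(nProt)]] <- TRUE
    if (length(sg@ops) > 1L) {
      perms <- .opPermutations(sg, dims)
      cnt <- integer(n)
      for (p in perms) cnt <- cnt + as.integer(mask[p])
      mask <- cnt * 2L >= length(perms)
    }
    mask <- array(mask, dims)
  } else {
    mask <- array(FALSE, dims)
  }
  realized <- 1 - mean(mask)
  if (nAtoms > 0 && abs(realized - solventFraction) > 0.02)
    .stopf("requested solvent fraction %.2f not achievable (realized %.2f)",
           solventFraction, realized)
  env <- if (nAtoms > 0) binaryEnvelope(mask, solventFraction, cell, sg)
         else new("BinaryEnvelope", mask = mask, solventFraction = 0.999,
                  cell = cell, spacegroup = sg)

  new("ToyCrystal", cell = cell, spacegroup = sg, atoms = atoms, map = map,
      envelope = env, phases = phaseSet(refl, truePhase, sigma = Inf),
      refl = refl, trueAmp = trueAmp, f000 = f000,
      solventFraction = realized)
}

#' Reference histogram from a toy crystal
#'
#' The density distribution of the protein region of the toy's true map,
#' recomputed with the given apodization applied to the (noise-free)
#' structure factors -- matching the convention that the reference data are
#' apodized in the same fashion as the working data.
#'
#' @param toy a [ToyCrystal-class]
#' @param apod an [Apodization-class] or sigma (Inf for none)
#' @return a [ReferenceHistogram-class]
#' @export
referenceHistogramFromToy <- function(toy, apod = Inf) {
  sigma <- if (is(apod, "Apodization")) apod@sigma else as.numeric(apod)
  if (!any(toy@envelope@mask)) .stopf("toy has an empty protein region")
  dims <- dim(toy@map@values)
  ctx <- .fourierContext(toy@refl, dims)
  w <- if (is.finite(sigma)) apodizationWeight(toy@refl@table$s, sigma)
       else rep(1, nrow(toy@refl@table))
  Fg <- .expandToGrid(ctx, w * toy@trueAmp, toy@phases@phase)
  Fg[1] <- toy@f000
  vals <- Re(stats::fft(Fg))
  vals <- .symmetrizeValues(array(vals, dims), toy@spacegroup, dims)
  referenceHistogram(vals[toy@envelope@mask],
                     B = mean(toy@atoms$B),
                     resolution = 1 / max(toy@refl@table$s),
                     sigma = sigma)
}

#' Simulate Wilson-distributed amplitude data
#'
#' Builds a P21 pseudo-cell large enough to hold `n` unique reflections to
#' `sMax`, and draws intensities from the Wilson distributions for each
#' class -- exponential for acentric reflections, chi-squared (1 dof) for
#' centric -- with mean `epsilon * Sigma * exp(-B s^2 / 2)`. Used to test
#' the overall-B estimator and the Wilson guard. The natural centric
#' fraction of the P21 cell is used unless `centricFraction` is given, in
#' which case the class labels are resampled to that fraction (a purely
#' statistical override for estimator testing).
#'
#' @param n number of reflections
#' @param Sigma scale of the mean intensity at s = 0
#' @param B overall isotropic B factor, Angstrom^2
#' @param centricFraction optional override of the centric fraction
#' @param seed RNG seed
#' @param sMax resolution limit in reciprocal Angstrom (default 0.5)
#' @return a [ReflectionData-class] with simulated amplitudes
#' @export
simulateWilsonAmplitudes <- function(n, Sigma = 1, B = 30,
                                     centricFraction = NULL, seed = 1L,
                                     sMax = 0.5) {
  set.seed(seed)
  # a cubic P21 cell sized so the unique count comfortably exceeds n
  a <- (4 * n * 1.4 / ((4 / 3) * pi * sMax^3))^(1 / 3)
  cell <- unitCell(a, a, a)
  sg <- spaceGroup("P21")
  uh <- .uniqueHKLtoResolution(cell, sg, 1 / sMax)
  if (nrow(uh) < n) .stopf("internal sizing error: only %d reflections", nrow(uh))
  pick <- sort(sample.int(nrow(uh), n))
  hkl <- as.matrix(uh[pick, ])
  refl <- reflectionData(hkl[, 1], hkl[, 2], hkl[, 3],
                         fobs = rep(1, n), cell = cell, spacegroup = sg,
                         lowResCutoff = 1e6)  # no cutoff: keep all observed
  tb <- refl@table
  if (!is.null(centricFraction)) {
    cen <- logical(nrow(tb))
    cen[sample.int(nrow(tb), round(centricFraction * nrow(tb)))] <- TRUE
    tb$centric <- cen
  }
  meanI <- tb$epsilon * Sigma * exp(-B * tb$s^2 / 2)
  I <- ifelse(tb$centric, meanI * stats::rchisq(nrow(tb), 1),
              meanI * stats::rexp(nrow(tb)))
  tb$fobs <- sqrt(I)
  tb$missing <- FALSE
  refl@table <- tb
  refl
}
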