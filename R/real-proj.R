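# Real-space constraints: solvent flattening, histogram matching, and the
# variance-based molecular envelope with its triweight filter.

#' BinaryEnvelope: protein/solvent partition of the unit cell
#'
#' @slot mask logical array, TRUE = protein
#' @slot solventFraction target solvent volume fraction in (0,1)
#' @slot cell a [UnitCell-class]
#' @slot spacegroup a [SpaceGroupSpec-class]
#' @name BinaryEnvelope-class
#' @aliases BinaryEnvelope
#' @exportClass BinaryEnvelope
setClass("BinaryEnvelope",
  representation(mask = "array", solventFraction = "numeric",
                 cell = "UnitCell", spacegroup = "SpaceGroupSpec"))

setValidity("BinaryEnvelope", function(object) {
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3)
    return("mask must be a logical 3-D array")
  f <- object@solventFraction
  if (length(f) != 1 || is.na(f) || f <= 0 || f >= 1)
    return("solventFraction must lie in (0,1)")
  TRUE
})

#' Construct a binary envelope
#' @param mask logical 3-D array (TRUE = protein)
#' @param solventFraction target solvent fraction
#' @param cell,spacegroup context
#' @export
binaryEnvelope <- function(mask, solventFraction, cell, spacegroup = "P1") {
  new("BinaryEnvelope", mask = mask, solventFraction = solventFraction,
      cell = cell, spacegroup = spaceGroup(spacegroup))
}

#' @describeIn BinaryEnvelope-class the logical mask (TRUE = protein)
#' @param env a \code{BinaryEnvelope}
#' @export
envelopeMask <- function(env) env@mask

#' @describeIn BinaryEnvelope-class solvent fraction actually realized by
#'   the mask (may differ slightly from the target after consensus
#'   averaging)
#' @export
realizedSolventFraction <- function(env) 1 - mean(env@mask)

setMethod("show", "BinaryEnvelope", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryEnvelope %dx%dx%d: solvent fraction %.3f realized (%.3f target)\n",
              d[1], d[2], d[3], realizedSolventFraction(object),
              object@solventFraction))
})

#' Triweight filter kernel
#'
#' The compactly supported weight `(1 - (r/r0)^2)^3` for r < r0 and 0
#' beyond, used to smooth the local-variance map that defines the molecular
#' envelope.
#' @param r distance(s) in Angstrom (>= 0)
#' @param r0 kernel radius in Angstrom (> 0)
#' @export
triweight <- function(r, r0) {
  stopifnot(r0 > 0, all(r >= 0))
  ifelse(r < r0, (1 - (r / r0)^2)^3, 0)
}

.kernelCache <- new.env(parent = emptyenv())

# FFT of the normalized periodic triweight kernel
.kernelFFT <- function(dims, cell, r0) {
  key <- paste(c(dims, round(cellParameters(cell), 6), round(r0, 6)),
               collapse = "_")
  hit <- .kernelCache[[key]]
  if (!is.null(hit)) return(hit)
  dist <- .gridDistance(dims, cell)
  kv <- triweight(as.numeric(dist), r0)
  kv <- kv / sum(kv)
  kf <- stats::fft(array(kv, dims))
  # keep the cache bounded: radii shrink continuously during a run
  if (length(ls(.kernelCache)) > 64) rm(list = ls(.kernelCache), envir = .kernelCache)
  .kernelCache[[key]] <- kf
  kf
}

# periodic convolution with the normalized kernel, both as plain arrays
.kernelConvolve <- function(vals, kf) {
  Re(stats::fft(stats::fft(vals) * kf, inverse = TRUE)) / length(vals)
}

#' Triweight-filtered local variance of the density
#'
#' At each grid point the weighted local variance `K*rho^2 - (K*rho)^2`,
#' with K the unit-sum periodic triweight kernel of radius r0, computed by
#' Fourier convolution. Regions of structured (protein) density have high
#' local variance; featureless solvent has low.
#'
#' @param map a [DensityMap-class]
#' @param r0 filter radius in Angstrom; must be at least two grid spacings
#'   and less than half the shortest cell edge
#' @return a [DensityMap-class] of local variances (>= 0)
#' @export
localVarianceMap <- function(map, r0) {
  dims <- dim(map@values)
  lens <- cellParameters(map@cell)[1:3]
  spacing <- max(lens / dims)
  if (r0 < 2 * spacing)
    .stopf("filter radius %.2f A is below two grid spacings (%.2f A)", r0, 2 * spacing)
  if (r0 >= min(lens) / 2)
    .stopf("filter radius %.2f A reaches beyond half the cell", r0)
  kf <- .kernelFFT(dims, map@cell, r0)
  m1 <- .kernelConvolve(map@values, kf)
  m2 <- .kernelConvolve(map@values^2, kf)
  v <- pmax(m2 - m1^2, 0)
  map@values <- array(v, dims)
  map
}

#' Threshold a variance map into a molecular envelope
#'
#' The grid points with the highest filtered local variance are marked
#' protein, so that the protein count is `round((1 - fraction) * N)`. Ties
#' at the threshold are broken deterministically by (value, linear grid
#' index); for non-P1 groups whole symmetry orbits are kept together so the
#' mask respects the crystallographic symmetry.
#'
#' @param varmap a [DensityMap-class] of local variances
#' @param solventFraction target solvent fraction in (0,1)
#' @return a [BinaryEnvelope-class]
#' @export
envelopeFromVariance <- function(varmap, solventFraction) {
  stopifnot(solventFraction > 0, solventFraction < 1)
  v <- as.numeric(varmap@values)
  if (max(v) - min(v) <= 1e-12 * (1 + abs(max(v))))
    .stopf("variance map is constant: envelope undefined")
  n <- length(v)
  nProt <- round((1 - solventFraction) * n)
  sg <- varmap@spacegroup
  if (length(sg@ops) > 1L) {
    v <- as.numeric(.symmetrizeValues(array(v, dim(varmap@values)), sg,
                                      dim(varmap@values)))
  }
  ord <- order(v, seq_len(n), decreasing = TRUE)
  mask <- logical(n)
  mask[ord[seq_len(nProt)]] <- TRUE
  if (length(sg@ops) > 1L) {
    # keep orbits whole: a point is protein iff its whole orbit is selected
    perms <- .opPermutations(sg, dim(varmap@values))
    cnt <- integer(n)
    for (p in perms) cnt <- cnt + as.integer(mask[p])
    mask <- cnt * 2L >= length(perms)  # orbit majority (ties -> protein)
  }
  binaryEnvelope(array(mask, dim(varmap@values)), solventFraction,
                 varmap@cell, sg)
}

#' Flatten the solvent region
#'
#' Sets every solvent grid point to the pre-projection solvent mean; protein
#' points are untouched. Together with histogram matching this is the
#' real-space projection: the minimum change making the solvent featureless.
#'
#' @param map a [DensityMap-class]
#' @param env a [BinaryEnvelope-class] on the same grid
#' @export
flattenSolvent <- function(map, env) {
  stopifnot(all(dim(map@values) == dim(env@mask)))
  solv <- !env@mask
  if (!any(solv)) .stopf("empty solvent region")
  map@values[solv] <- mean(map@values[solv])
  map
}

#' Variance of the density in the solvent region
#'
#' Population variance over solvent grid points; the running measure of
#' solvent flatness (0 when perfectly flat).
#' @param map a [DensityMap-class]
#' @param env a [BinaryEnvelope-class]
#' @export
solventVariance <- function(map, env) {
  solv <- !env@mask
  if (!any(solv)) .stopf("empty solvent region")
  .popVar(as.numeric(map@values[solv]))
}

#' ReferenceHistogram: target protein density distribution
#'
#' The expected density-value distribution in the protein region, stored as
#' an empirical quantile table. Protein density histograms are generic but
#' depend on resolution, overall B factor and any apodization in force, so
#' the provenance is recorded alongside.
#'
#' @slot values sorted reference sample (the quantile table)
#' @slot provenance list with B (Angstrom^2), resolution (Angstrom) and
#'   apodization sigma used to generate the reference
#' @name ReferenceHistogram-class
#' @aliases ReferenceHistogram
#' @exportClass ReferenceHistogram
setClass("ReferenceHistogram",
  representation(values = "numeric", provenance = "list"))

setValidity("ReferenceHistogram", function(object) {
  if (length(object@values) < 2) return("reference needs >= 2 values")
  if (any(!is.finite(object@values))) return("reference values must be finite")
  if (is.unsorted(object@values)) return("quantile table must be sorted")
  TRUE
})

#' Build a reference histogram from a density sample
#' @param values density values of a reference protein region
#' @param B,resolution,sigma provenance (B factor, resolution, apodization)
#' @param maxPoints size of the stored quantile table
#' @export
referenceHistogram <- function(values, B = NA_real_, resolution = NA_real_,
                               sigma = Inf, maxPoints = 4096) {
  values <- sort(as.numeric(values[is.finite(values)]))
  if (length(values) > maxPoints) {
    p <- (seq_len(maxPoints) - 0.5) / maxPoints
    values <- as.numeric(stats::quantile(values, p, type = 7, names = FALSE))
  }
  new("ReferenceHistogram", values = values,
      provenance = list(B = B, resolution = resolution, sigma = sigma))
}

#' @describeIn ReferenceHistogram-class evaluate the reference quantile
#'   function at probabilities p
#' @param ref a \code{ReferenceHistogram}
#' @param p probabilities in [0,1]
#' @export
refQuantile <- function(ref, p) {
  n <- length(ref@values)
  stats::approx((seq_len(n) - 0.5) / n, ref@values, xout = p, rule = 2)$y
}

setMethod("show", "ReferenceHistogram", function(object) {
  pv <- object@provenance
  cat(sprintf("ReferenceHistogram: %d quantiles, mean %.4g, sd %.4g (B=%s, d=%s, sigma=%s)\n",
              length(object@values), mean(object@values),
              stats::sd(object@values),
              format(pv$B), format(pv$resolution),
              if (is.finite(pv$sigma %||% Inf)) format(pv$sigma) else "none"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Histogram matching of the protein region
#'
#' Rank-preserving transform of the protein density onto the reference
#' distribution (classical histogram specification: value of rank i maps to
#' the reference quantile at (i - 0.5)/n, equal ranks broken by grid order),
#' followed by a mean shift so the protein mean equals the reference mean.
#' With `preserve = "post"` (the default) the variance after quantile
#' mapping -- i.e. the reference variance -- is preserved by shifting only;
#' `preserve = "pre"` instead rescales to retain the protein region's
#' variance before matching.
#'
#' @param map a [DensityMap-class]
#' @param env a [BinaryEnvelope-class]
#' @param ref a [ReferenceHistogram-class]
#' @param preserve which variance the final affine adjustment preserves
#' @export
histogramMatchProtein <- function(map, env, ref, preserve = c("post", "pre")) {
  preserve <- match.arg(preserve)
  prot <- which(env@mask)
  if (length(prot) < 10) .stopf("fewer than 10 protein grid points")
  v <- map@values[prot]
  ord <- order(v, seq_along(v))
  n <- length(v)
  mapped <- numeric(n)
  mapped[ord] <- refQuantile(ref, (seq_len(n) - 0.5) / n)
  refMean <- mean(ref@values)
  if (preserve == "pre") {
    sdv <- stats::sd(v); sdm <- stats::sd(mapped)
    if (sdm > 0 && sdv > 0) mapped <- (mapped - mean(mapped)) * (sdv / sdm)
    mapped <- mapped + refMean
  } else {
    mapped <- mapped - mean(mapped) + refMean
  }
  map@values[prot] <- mapped
  map
}

#' Real-space projection P_A
#'
#' The composition of histogram matching in the protein region and solvent
#' flattening, for a fixed envelope: the minimum change to the density that
#' gives both regions their expected distributions. Idempotent; the two
#' regions are treated independently.
#'
#' @param map a [DensityMap-class]
#' @param env a [BinaryEnvelope-class]
#' @param ref a [ReferenceHistogram-class]
#' @param preserve passed to [histogramMatchProtein()]
#' @export
projectReal <- function(map, env, ref, preserve = "post") {
  flattenSolvent(histogramMatchProtein(map, env, ref, preserve), env)
}

# fast path used by the engine: vals is a plain array
.projectRealVals <- function(vals, mask, refValues, refMean) {
  solv <- !mask
  vals[solv] <- mean(vals[solv])
  prot <- which(mask)
  v <- vals[prot]
  ord <- order(v, seq_along(v))
  n <- length(v)
  m <- length(refValues)
  mapped <- numeric(n)
  mapped[ord] <- stats::approx((seq_len(m) - 0.5) / m, refValues,
                               xout = (seq_len(n) - 0.5) / n, rule = 2)$y
  vals[prot] <- mapped - mean(mapped) + refMean
  vals
}

#' First Wasserstein distance between two distributions
#'
#' `W1 = integral |F_P - F_Q|` over the value axis. For two empirical
#' samples the step-function integral is evaluated exactly on the merged
#' support; explicit CDF tables are integrated by the trapezoidal rule on
#' the merged grid (see [wassersteinCDF()]).
#'
#' @param x,y numeric samples, or [ReferenceHistogram-class] objects
#' @return the distance (same units as the values)
#' @examples
#' wasserstein1(runif(100), runif(100) + 0.2)  # ~0.2
#' @export
wasserstein1 <- function(x, y) {
  if (is(x, "ReferenceHistogram")) x <- x@values
  if (is(y, "ReferenceHistogram")) y <- y@values
  x <- sort(x); y <- sort(y)
  if (!all(is.finite(c(x, y)))) .stopf("unbounded support")
  grid <- sort(unique(c(x, y)))
  if (length(grid) < 2) return(0)
  Fx <- findInterval(grid, x) / length(x)
  Fy <- findInterval(grid, y) / length(y)
  # step CDFs are constant on [grid_i, grid_{i+1}): exact rectangle rule
  sum(abs(Fx - Fy)[-length(grid)] * diff(grid))
}

#' Wasserstein-1 distance from explicit CDF tables
#'
#' Trapezoidal evaluation of `integral |F_P - F_Q|` on the merged support
#' grid of two tabulated CDFs.
#' @param xP,FP grid and CDF values of the first distribution
#' @param xQ,FQ grid and CDF values of the second
#' @export
wassersteinCDF <- function(xP, FP, xQ, FQ) {
  if (!all(is.finite(c(xP, xQ)))) .stopf("unbounded support")
  grid <- sort(unique(c(xP, xQ)))
  fP <- stats::approx(xP, FP, xout = grid, rule = 2)$y
  fQ <- stats::approx(xQ, FQ, xout = grid, rule = 2)$y
  d <- abs(fP - fQ)
  sum((d[-1] + d[-length(d)]) / 2 * diff(grid))
}
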