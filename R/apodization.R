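#' Gaussian apodization of Fourier amplitudes
#'
#' The effective resolution of a reconstruction is controlled by multiplying
#' the amplitude data by a Gaussian weight `w(s) = exp(-s^2 / (2 sigma^2))`,
#' where s is the scattering-vector magnitude (1/resolution, in reciprocal
#' Angstrom). A Gaussian taper avoids the ringing artifacts a sharp
#' resolution cutoff would introduce. By convention the width is also
#' reported as the half width at 1/100th of maximum height, 3.03 sigma, or
#' the corresponding resolution 1/(3.03 sigma).
#'
#' @slot sigma standard deviation in reciprocal Angstrom; Inf means no
#'   apodization (w = 1 everywhere)
#' @name Apodization-class
#' @aliases Apodization
#' @exportClass Apodization
setClass("Apodization", representation(sigma = "numeric"))

setValidity("Apodization", function(object) {
  if (length(object@sigma) != 1 || is.na(object@sigma) || object@sigma <= 0)
    return("sigma must be a single positive number (Inf for none)")
  TRUE
})

#' Construct an apodization
#' @param sigma Gaussian sigma in reciprocal Angstrom, or `Inf`/"none"
#' @export
apodization <- function(sigma) {
  if (identical(sigma, "none")) sigma <- Inf
  new("Apodization", sigma = as.numeric(sigma))
}

#' Gaussian apodization weight
#' @param s scattering-vector magnitude(s), reciprocal Angstrom
#' @param sigma Gaussian sigma (reciprocal Angstrom); Inf gives weight 1
#' @return weights in (0, 1]
#' @examples
#' apodizationWeight(0, 0.1)          # 1
#' apodizationWeight(3.03 * 0.1, 0.1) # ~0.01: half width at 1/100 height
#' @export
apodizationWeight <- function(s, sigma) {
  if (is.infinite(sigma)) return(rep(1, length(s)))
  stopifnot(sigma > 0, all(s >= 0))
  exp(-s^2 / (2 * sigma^2))
}

setMethod("show", "Apodization", function(object) {
  if (is.infinite(object@sigma)) {
    cat("Apodization: none (w = 1)\n")
  } else {
    cat(sprintf("Apodization: sigma %.4g 1/A; 1/100-height half width %.4g 1/A (%.2f A resolution)\n",
                object@sigma, 3.03 * object@sigma, 1 / (3.03 * object@sigma)))
  }
})

#' @describeIn Apodization-class resolution (Angstrom) at which the weight
#'   falls to 1/100 of its maximum
#' @param apod an \code{Apodization}
#' @export
apodizationResolution <- function(apod) {
  if (is.infinite(apod@sigma)) return(NA_real_)
  1 / (3.03 * apod@sigma)
}

# area under the weight curve over [0, sMax]
.apodArea <- function(sigma, sMax) {
  if (is.infinite(sigma)) return(sMax)
  # integral of exp(-s^2/(2 sigma^2)) = sigma * sqrt(pi/2) * erf(sMax/(sqrt(2) sigma))
  sigma * sqrt(2 * pi) * (stats::pnorm(sMax / sigma) - 0.5)
}

#' ApodizationSchedule: equal-area resolution extension
#'
#' During phase determination the effective resolution is raised gradually:
#' the Gaussian sigma increases step by step so that the area under the
#' weight curve, integrated up to the full resolution of the data set,
#' grows by a constant increment, reaching the unapodized limit (w = 1,
#' area = sMax) at the final step.
#'
#' @slot sigmas strictly increasing sigma values, ending with Inf
#' @slot iterationsPerStep iterations of the update rule spent at each step
#' @slot sMax the full data resolution limit used for the areas
#' @name ApodizationSchedule-class
#' @aliases ApodizationSchedule
#' @exportClass ApodizationSchedule
setClass("ApodizationSchedule",
  representation(sigmas = "numeric", iterationsPerStep = "integer",
                 sMax = "numeric"))

setValidity("ApodizationSchedule", function(object) {
  sig <- object@sigmas
  if (length(sig) < 2) return("schedule needs at least 2 steps")
  if (any(diff(sig) <= 0)) return("sigma values must be strictly increasing")
  if (!is.infinite(sig[length(sig)])) return("final step must be unapodized")
  if (object@iterationsPerStep < 1) return("iterationsPerStep must be >= 1")
  TRUE
})

#' Build an equal-area apodization schedule
#'
#' Step 1 uses `sigma0`; intermediate sigmas are found by monotone
#' root-finding (relative tolerance 1e-6) so the areas form an arithmetic
#' progression from the step-1 area to the unapodized area `sMax`; the final
#' step applies no apodization.
#'
#' @param sigma0 starting sigma (reciprocal Angstrom)
#' @param nSteps number of steps (>= 2)
#' @param sMax full resolution limit of the data set (reciprocal Angstrom)
#' @param iterationsPerStep iterations per step (default 240)
#' @return an [ApodizationSchedule-class]
#' @export
apodizationSchedule <- function(sigma0, nSteps, sMax, iterationsPerStep = 240L) {
  stopifnot(sigma0 > 0, nSteps >= 2, sMax > 0)
  a0 <- .apodArea(sigma0, sMax)
  # finite sigma only approaches the unapodized area asymptotically; treat
  # anything within 1e-4 relative as "already unapodized"
  if (a0 >= sMax * (1 - 1e-4))
    .stopf("sigma0 = %g already gives the unapodized area: nothing to extend", sigma0)
  areas <- seq(a0, sMax, length.out = nSteps)
  sigmas <- numeric(nSteps)
  sigmas[1] <- sigma0
  sigmas[nSteps] <- Inf
  if (nSteps > 2) {
    for (i in 2:(nSteps - 1)) {
      f <- function(lsig) .apodArea(exp(lsig), sMax) - areas[i]
      lo <- log(sigma0)
      hi <- log(sigma0)
      while (f(hi) < 0) hi <- hi + 1
      sigmas[i] <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-6 * abs(lo) + 1e-10)$root)
    }
  }
  new("ApodizationSchedule", sigmas = sigmas,
      iterationsPerStep = as.integer(iterationsPerStep), sMax = sMax)
}

#' @describeIn ApodizationSchedule-class sigma values of the schedule
#' @param sched an \code{ApodizationSchedule}
#' @export
scheduleSigmas <- function(sched) sched@sigmas

#' @describeIn ApodizationSchedule-class areas under the successive weight
#'   curves (arithmetic progression by construction)
#' @export
scheduleAreas <- function(sched) {
  vapply(sched@sigmas, .apodArea, numeric(1), sMax = sched@sMax)
}

setMethod("show", "ApodizationSchedule", function(object) {
  n <- length(object@sigmas)
  cat(sprintf("ApodizationSchedule: %d steps x %d iterations; sigma %.4g -> none; sMax %.4g 1/A\n",
              n, object@iterationsPerStep, object@sigmas[1], object@sMax))
})
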