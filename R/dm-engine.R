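# The Error Reduction and Difference Map update rules, and single-run
# execution with per-iteration trajectory logging.

#' DMParameters: relaxation constants of the Difference Map
#'
#' The Difference Map update is
#' `x <- x + beta * (P_A(f_B(x)) - P_B(f_A(x)))` with relaxed projections
#' `f_A(x) = (1 + gamma_A) P_A(x) - gamma_A x` and likewise for B. The
#' defaults `gamma_A = -1/beta`, `gamma_B = +1/beta` are the standard
#' recommended choice. Changing the sign of beta effectively reverses the
#' order in which the two projections are applied.
#'
#' @slot beta adjustable parameter, -1 < beta < 1, beta != 0
#' @slot gammaA,gammaB relaxation parameters
#' @name DMParameters-class
#' @aliases DMParameters
#' @exportClass DMParameters
setClass("DMParameters",
  representation(beta = "numeric", gammaA = "numeric", gammaB = "numeric"))

setValidity("DMParameters", function(object) {
  b <- object@beta
  if (length(b) != 1 || is.na(b) || b == 0 || abs(b) >= 1)
    return("beta must satisfy -1 < beta < 1 and beta != 0")
  TRUE
})

#' Construct Difference Map parameters
#' @param beta in (-1,0) or (0,1)
#' @param gammaA,gammaB relaxation constants (defaults -1/beta, +1/beta)
#' @export
dmParameters <- function(beta, gammaA = -1 / beta, gammaB = 1 / beta) {
  new("DMParameters", beta = beta, gammaA = gammaA, gammaB = gammaB)
}

setMethod("show", "DMParameters", function(object) {
  cat(sprintf("DMParameters: beta=%.3f gammaA=%.3f gammaB=%.3f\n",
              object@beta, object@gammaA, object@gammaB))
})

#' One cycle of the Error Reduction algorithm
#'
#' Plain alternating projections: the density is adjusted to exactly satisfy
#' the Fourier-space constraint, then the real-space constraint. ER
#' converges locally but stagnates at non-solutions of non-convex problems,
#' which is why it is used only for final polishing.
#'
#' @param x numeric vector/array (the density)
#' @param PA,PB projection functions onto the real-space and Fourier-space
#'   constraint sets
#' @return the updated x = PA(PB(x))
#' @export
erStep <- function(x, PA, PB) PA(PB(x))

#' One iteration of the Difference Map algorithm
#'
#' Generates the two solution estimates `estA = P_A(f_B(x))` and
#' `estB = P_B(f_A(x))` (satisfying the real-space and Fourier-space
#' constraints respectively) and the updated iterate
#' `x + beta * (estA - estB)`. When the two estimates coincide the
#' algorithm has converged and either is a solution.
#'
#' @param x numeric vector/array
#' @param PA,PB projection functions
#' @param params a [DMParameters-class] (or a bare beta value)
#' @return list with `x`, `estA`, `estB`
#' @export
dmStep <- function(x, PA, PB, params) {
  if (is.numeric(params)) params <- dmParameters(params)
  gA <- params@gammaA; gB <- params@gammaB; beta <- params@beta
  pa <- PA(x); pb <- PB(x)
  fA <- (1 + gA) * pa - gA * x
  fB <- (1 + gB) * pb - gB * x
  estA <- PA(fB)
  estB <- PB(fA)
  list(x = x + beta * (estA - estB), estA = estA, estB = estB)
}

#' Negate the Difference Map's beta parameter
#'
#' With the default relaxations tied to beta, flipping its sign reproduces
#' the dynamics of the positive-beta iteration with the two projections
#' applied in the opposite order. The relaxation constants are re-derived
#' from the negated beta.
#' @param params a [DMParameters-class]
#' @export
negateBeta <- function(params) dmParameters(-params@beta)

#' Root-mean-square deviation between the two DM solution estimates
#'
#' The convergence indicator of the Difference Map: zero iff the two
#' estimates coincide, i.e. a point in the intersection of the constraint
#' sets has been found.
#' @param estA,estB the two solution estimates
#' @export
deltaDM <- function(estA, estB) sqrt(mean((estA - estB)^2))

#' Trajectory: per-iteration metric log of a run
#'
#' @slot metrics data.frame, one row per iteration: iter, alg, beta, sigma,
#'   r0, deltaDM, solventVariance, wasserstein, ampCC and (when ground truth
#'   was supplied) phaseDiff and envelopeCC
#' @slot seed the RNG seed of the run
#' @name Trajectory-class
#' @aliases Trajectory
#' @exportClass Trajectory
setClass("Trajectory",
  representation(metrics = "data.frame", seed = "integer"))

setMethod("show", "Trajectory", function(object) {
  m <- object@metrics
  cat(sprintf("Trajectory: %d iterations (seed %d); final deltaDM %.4g, ampCC %.3f\n",
              nrow(m), object@seed, m$deltaDM[nrow(m)], m$ampCC[nrow(m)]))
})

#' @describeIn Trajectory-class the metric table
#' @param traj a \code{Trajectory}
#' @export
trajectoryMetrics <- function(traj) traj@metrics

#' Write a trajectory as tab-separated text (one row per iteration)
#' @param traj a [Trajectory-class]
#' @param path output file
#' @export
writeTrajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed %d", traj@seed), con)
  utils::write.table(traj@metrics, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# random initial phases: uniform for acentric reflections, uniform over the
# two allowed values for centric ones
.randomPhases <- function(refl) {
  tb <- refl@table
  n <- nrow(tb)
  ph <- stats::runif(n, 0, 360)
  if (any(tb$centric)) {
    ci <- which(tb$centric)
    base <- centricPhaseRestriction(as.matrix(tb[ci, c("h", "k", "l")]),
                                    refl@spacegroup)
    ph[ci] <- base + 180 * (stats::runif(length(ci)) < 0.5)
  }
  ph[tb$missing] <- NA_real_
  .wrap360(ph)
}

# expand per-unique-reflection complex coefficients onto the FFT grid
.expandToGrid <- function(ctx, amp, phaseDeg) {
  Fg <- complex(length.out = ctx$n)
  ok <- which(!is.na(ctx$mapIdx))
  r <- ctx$mapIdx[ok]
  keep <- !is.na(phaseDeg[r]) & !is.na(amp[r])
  ok <- ok[keep]; r <- r[keep]
  phG <- ifelse(ctx$conjG[ok], -(phaseDeg[r] + ctx$shiftG[ok]),
                phaseDeg[r] + ctx$shiftG[ok])
  Fg[ok] <- amp[r] * exp(1i * .deg2rad(phG))
  array(Fg, ctx$dims)
}

# read the unique-reflection phases off a density array
.phasesFromVals <- function(vals, ctx) {
  Fc <- stats::fft(vals, inverse = TRUE) / ctx$n
  gi <- ctx$reflGridIdx
  ph <- rep(NA_real_, length(gi))
  ok <- !is.na(gi)
  ph[ok] <- .wrap360(.rad2deg(Arg(Fc[gi[ok]])))
  ph
}

#' Execute one phasing run
#'
#' Runs the iteration plan (Difference Map and Error Reduction blocks with
#' their scheduled beta, apodization sigma and filter radius), updating the
#' molecular envelope each iteration from the Fourier-constraint solution
#' estimate, and logs the convergence and agreement metrics per iteration.
#' Fully reproducible given `seed`.
#'
#' @param refl a [ReflectionData-class]
#' @param plan data.frame with one row per iteration and columns `alg`
#'   ("DM"/"ER"), `beta`, `sigma` (reciprocal Angstrom, Inf for none) and
#'   `r0` (filter radius, Angstrom); see [iterationPlan()]
#' @param solventFraction assumed solvent volume fraction
#' @param refHist a [ReferenceHistogram-class], or a function(sigma) that
#'   returns one matched to the apodization in force
#' @param dims grid dimensions (e.g. from [suggestGrid()])
#' @param envelope optional starting [BinaryEnvelope-class]
#' @param holdEnvelope keep the starting envelope fixed for this many
#'   iterations before updating it each iteration
#' @param seed RNG seed for the random starting phases
#' @param guard apply the Wilson guard to missing amplitudes
#' @param truth optional list with elements `phases` (a [PhaseSet-class])
#'   and/or `envelope` for agreement tracking
#' @param truthEvery evaluate the (more expensive) truth metrics every this
#'   many iterations
#' @return list with `trajectory` ([Trajectory-class]), `estA`, `estB`
#'   ([DensityMap-class]), `envelope` ([BinaryEnvelope-class]), `phases`
#'   ([PhaseSet-class] from the final Fourier-constraint estimate), `seed`
#' @export
runStage <- function(refl, plan, solventFraction, refHist, dims,
                     envelope = NULL, holdEnvelope = 0L, seed = 1L,
                     guard = TRUE, truth = NULL, truthEvery = 25L) {
  stopifnot(is.data.frame(plan), nrow(plan) >= 0)
  set.seed(seed)
  ctx <- .fourierContext(refl, dims)
  tb <- refl@table

  histProvider <- if (is.function(refHist)) refHist else function(sigma) refHist
  histCache <- new.env(parent = emptyenv())
  getHist <- function(sigma) {
    key <- format(sigma)
    hit <- histCache[[key]]
    if (is.null(hit)) {
      rh <- histProvider(sigma)
      hit <- list(values = rh@values, mean = mean(rh@values))
      histCache[[key]] <- hit
    }
    hit
  }

  # random-phase start at the first step's apodization
  ph0 <- .randomPhases(refl)
  sig1 <- if (nrow(plan)) plan$sigma[1] else Inf
  w0 <- if (is.finite(sig1)) apodizationWeight(tb$s, sig1) else rep(1, nrow(tb))
  Fg <- .expandToGrid(ctx, w0 * tb$fobs, ph0)
  x <- Re(stats::fft(Fg))
  x <- as.numeric(.symmetrizeValues(array(x, dims), ctx$sg, dims))
  x <- array(x, dims)

  mask <- if (!is.null(envelope)) envelope@mask else NULL
  if (is.null(mask)) {
    vm <- localVarianceMap(densityMap(x, refl@cell, refl@spacegroup),
                           if (nrow(plan)) plan$r0[1] else 8)
    mask <- envelopeFromVariance(vm, solventFraction)@mask
    holdEnvelope <- 0L
  }

  nIter <- nrow(plan)
  mcols <- c("deltaDM", "solventVariance", "wasserstein", "ampCC",
             "phaseDiff", "envelopeCC")
  M <- matrix(NA_real_, nIter, length(mcols), dimnames = list(NULL, mcols))
  estA <- estB <- x
  truePS <- truth$phases
  trueEnv <- truth$envelope

  for (i in seq_len(nIter)) {
    sigma <- plan$sigma[i]; r0 <- plan$r0[i]
    rh <- getHist(sigma)
    if (plan$alg[i] == "DM") {
      beta <- plan$beta[i]
      gA <- -1 / beta; gB <- 1 / beta
      pa <- .projectRealVals(x, mask, rh$values, rh$mean)
      pb <- .projectFourierCtx(x, ctx, sigma, guard)$vals
      fA <- (1 + gA) * pa - gA * x
      fB <- (1 + gB) * pb - gB * x
      estA <- .projectRealVals(fB, mask, rh$values, rh$mean)
      estB <- .projectFourierCtx(fA, ctx, sigma, guard)$vals
      x <- x + beta * (estA - estB)
    } else {
      estB <- .projectFourierCtx(x, ctx, sigma, guard)$vals
      estA <- .projectRealVals(estB, mask, rh$values, rh$mean)
      x <- estA
    }
    if (!all(is.finite(x)))
      .stopf("non-finite density at iteration %d: run aborted", i)

    M[i, "deltaDM"] <- sqrt(mean((estA - estB)^2))
    solv <- !mask
    M[i, "solventVariance"] <- .popVar(estB[solv])
    M[i, "wasserstein"] <- wasserstein1(estB[mask], rh$values)
    M[i, "ampCC"] <- .amplitudeAgreementCtx(estA, ctx, sigma)$cc

    # envelope update from the Fourier-space solution estimate
    if (i > holdEnvelope) {
      vm <- localVarianceMap(densityMap(array(estB, dims), refl@cell,
                                        refl@spacegroup), r0)
      mask <- envelopeFromVariance(vm, solventFraction)@mask
    }

    if (!is.null(truth) && (i %% truthEvery == 0L || i == nIter)) {
      if (!is.null(truePS)) {
        ps <- phaseSet(refl, .phasesFromVals(estB, ctx),
                       sigma = sigma)
        M[i, "phaseDiff"] <- weightedMeanAbsPhaseDiff(ps, truePS)
      }
      if (!is.null(trueEnv)) {
        e <- binaryEnvelope(mask, solventFraction, refl@cell, refl@spacegroup)
        reg <- bestRegistration(trueEnv, e)
        M[i, "envelopeCC"] <- reg@score
      }
    }
  }

  finalSigma <- if (nIter) plan$sigma[nIter] else Inf
  phases <- phaseSet(refl, .phasesFromVals(estB, ctx), sigma = finalSigma)
  metrics <- data.frame(iter = seq_len(nIter),
                        alg = if (nIter) plan$alg else character(0),
                        beta = if (nIter) plan$beta else numeric(0),
                        sigma = if (nIter) plan$sigma else numeric(0),
                        r0 = if (nIter) plan$r0 else numeric(0))
  metrics <- cbind(metrics, as.data.frame(M))
  list(trajectory = new("Trajectory", metrics = metrics,
                        seed = as.integer(seed)),
       estA = densityMap(array(estA, dims), refl@cell, refl@spacegroup),
       estB = densityMap(array(estB, dims), refl@cell, refl@spacegroup),
       envelope = binaryEnvelope(mask, solventFraction, refl@cell,
                                 refl@spacegroup),
       phases = phases, seed = as.integer(seed))
}
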