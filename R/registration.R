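# Origin and inversion registration. Solutions started from random phases
# select their crystallographic origin (and, in achiral groups, their hand)
# arbitrarily; before any comparison or averaging, maps, envelopes and phase
# sets must be brought to a common origin over the group's permitted shifts.

#' Registration: relative origin shift and hand between two solutions
#'
#' @slot shift fractional translation applied to the second object to align
#'   it with the first
#' @slot inverted was the second object inverted (hand flip)?
#' @slot score the registration quality (correlation-type score at the
#'   optimum)
#' @name Registration-class
#' @aliases Registration
#' @exportClass Registration
setClass("Registration",
  representation(shift = "numeric", inverted = "logical", score = "numeric"))

setMethod("show", "Registration", function(object) {
  cat(sprintf("Registration: shift (%.4f, %.4f, %.4f)%s, score %.4f\n",
              object@shift[1], object@shift[2], object@shift[3],
              if (object@inverted) ", inverted" else "", object@score))
})

# logical array over the t-grid marking permitted origin shifts
.allowedShiftMask <- function(sg, dims) {
  allowed <- array(FALSE, dims)
  cont <- sg@continuousAxes
  axVals <- function(a, frac) {
    if (cont[a]) return(0:(dims[a] - 1L))
    v <- round(frac * dims[a])
    if (abs(frac * dims[a] - v) > 1e-6)
      .stopf("origin shift %g not representable on a grid of %d points", frac, dims[a])
    as.integer(v %% dims[a])
  }
  for (r in seq_len(nrow(sg@originShifts))) {
    sh <- sg@originShifts[r, ]
    allowed[axVals(1, sh[1]) + 1L, axVals(2, sh[2]) + 1L,
            axVals(3, sh[3]) + 1L] <- TRUE
  }
  allowed
}

# invert an array through the origin: out(x) = v(-x)
.invertArray <- function(v) {
  d <- dim(v)
  ix <- lapply(d, function(n) c(1L, rev(seq_len(n)[-1])))
  v[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

# translate an array by t grid units: out(x) = v(x - t)
.translateArray <- function(v, t) {
  d <- dim(v)
  ix <- lapply(1:3, function(a) ((seq_len(d[a]) - 1L - t[a]) %% d[a]) + 1L)
  v[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

# cross-correlation sum C(t) = sum_x a(x) b(x - t) for all grid t
.crossCorr <- function(a, b) {
  Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) /
    length(a)
}

# pick the best allowed shift; deterministic lexicographic tie-break
.pickBest <- function(score, allowed, tol = 1e-9) {
  idx <- which(allowed)
  sc <- score[idx]
  top <- max(sc)
  cand <- idx[sc >= top - tol]
  d <- dim(score)
  ai <- arrayInd(cand, d) - 1L
  ord <- order(ai[, 1], ai[, 2], ai[, 3])
  best <- cand[ord[1]]
  list(t = arrayInd(best, d) - 1L, score = score[best])
}

#' Find the best origin shift (and hand) aligning two objects
#'
#' Evaluates the agreement score over all permitted origin shifts of the
#' space group -- by FFT-based cross-correlation (the phased translation
#' function for phase sets) when origins are continuous, by direct
#' evaluation over the finite list otherwise -- and over the inversion
#' alternative when the group permits it. For binary envelopes the score is
#' the Matthews correlation of the two masks; for density maps the Pearson
#' correlation of the values.
#'
#' @param a,b two [BinaryEnvelope-class] or two [DensityMap-class] objects
#'   on commensurate grids (for phase sets see [phaseDistance()])
#' @param allowInversion search the inverted hand too (default: the group's
#'   inversion ambiguity)
#' @return a [Registration-class]; `shift` is the fractional translation
#'   and `inverted` the hand flip to apply to `b`
#' @export
bestRegistration <- function(a, b, allowInversion = NULL) {
  isEnv <- is(a, "BinaryEnvelope")
  av <- if (isEnv) a@mask + 0 else a@values
  bv <- if (isEnv) b@mask + 0 else b@values
  if (!all(dim(av) == dim(bv))) .stopf("incompatible grids")
  sg <- a@spacegroup
  if (is.null(allowInversion)) allowInversion <- sg@inversionAmbiguous
  dims <- dim(av)
  allowed <- .allowedShiftMask(sg, dims)
  n <- length(av)
  scorer <- if (isEnv) {
    na <- sum(av); nb <- sum(bv)
    function(C) {
      f11 <- C / n; f10 <- na / n - f11; f01 <- nb / n - f11
      f00 <- 1 - f11 - f10 - f01
      num <- f11 * f00 - f01 * f10
      den <- sqrt((f11 + f10) * (f01 + f00) * (f11 + f01) * (f10 + f00))
      ifelse(den > 0, num / den, 0)
    }
  } else {
    ma <- mean(av); mb <- mean(bv)
    sda <- sqrt(.popVar(as.numeric(av))); sdb <- sqrt(.popVar(as.numeric(bv)))
    function(C) (C / n - ma * mb) / (sda * sdb)
  }
  best <- NULL
  for (inv in if (allowInversion) c(FALSE, TRUE) else FALSE) {
    b2 <- if (inv) .invertArray(bv) else bv
    sc <- scorer(.crossCorr(av, b2))
    pk <- .pickBest(sc, allowed)
    if (is.null(best) || pk$score > best@score)
      best <- new("Registration", shift = as.numeric(pk$t) / dims,
                  inverted = inv, score = pk$score)
  }
  best
}

#' Apply a registration to an object
#'
#' Brings `b` (the second argument of the registration) onto the reference:
#' maps and envelopes are inverted (if flagged) and translated; for a phase
#' set the phases become `phi' = (+/- phi) + 360 (h . t)`.
#' @param x a [BinaryEnvelope-class], [DensityMap-class] or
#'   [PhaseSet-class]
#' @param reg a [Registration-class]
#' @export
applyRegistration <- function(x, reg) {
  if (is(x, "PhaseSet")) {
    tb <- x@refl@table
    ph <- x@phase
    if (reg@inverted) ph <- -ph
    ph <- ph + 360 * as.numeric(as.matrix(tb[, c("h", "k", "l")]) %*% reg@shift)
    x@phase <- .wrap360(ph)
    return(x)
  }
  isEnv <- is(x, "BinaryEnvelope")
  v <- if (isEnv) x@mask else x@values
  if (reg@inverted) v <- .invertArray(v)
  t <- round(reg@shift * dim(v))
  if (any(abs(reg@shift * dim(v) - t) > 1e-6))
    .stopf("registration shift is off-grid for this map")
  v <- .translateArray(v, as.integer(t))
  if (isEnv) x@mask <- v else x@values <- v
  x
}

#' Correlation coefficient between two binary envelopes
#'
#' The Matthews (phi) correlation computed from the 2x2 table of matching
#' proportions: f00 and f11 are the proportions of grid points agreeing in
#' the solvent and protein regions, f01/f10 the mismatches. 1 for identical
#' masks, about 0 for statistically independent masks. No registration is
#' performed; see [envelopeDistance()] for the registered version.
#'
#' @param e1,e2 [BinaryEnvelope-class] objects on the same grid
#' @return correlation in [-1, 1]; NA with a warning for single-class masks
#' @export
envelopeCC <- function(e1, e2) {
  m1 <- e1@mask; m2 <- e2@mask
  stopifnot(all(dim(m1) == dim(m2)))
  n <- length(m1)
  f11 <- sum(m1 & m2) / n; f10 <- sum(m1 & !m2) / n
  f01 <- sum(!m1 & m2) / n; f00 <- 1 - f11 - f10 - f01
  den <- (f11 + f10) * (f01 + f00) * (f11 + f01) * (f10 + f00)
  if (den <= 0) {
    .warnf("single-class mask: envelope correlation undefined")
    return(NA_real_)
  }
  (f11 * f00 - f01 * f10) / sqrt(den)
}

#' Registered distance between two envelopes
#'
#' `d = sqrt(1 - CC^2)` with CC the best correlation over permitted origin
#' shifts and the inversion alternative: 0 for identical envelopes, about 1
#' for unrelated ones.
#' @param e1,e2 [BinaryEnvelope-class] objects
#' @param allowInversion default: the group's inversion ambiguity
#' @export
envelopeDistance <- function(e1, e2, allowInversion = NULL) {
  reg <- bestRegistration(e1, e2, allowInversion)
  sqrt(max(0, 1 - reg@score^2))
}

# --- phase-set registration ----------------------------------------------

# search grid for phase-set translation functions
.phaseSearchDims <- function(tb, sg) {
  maxH <- pmax(vapply(c("h", "k", "l"), function(cn) max(abs(tb[[cn]])), 0), 1)
  vapply(1:3, function(a) {
    div <- 1L
    if (!sg@continuousAxes[a] && nrow(sg@originShifts) > 1) {
      fr <- sg@originShifts[, a]
      fr <- fr[abs(fr) > 1e-9]
      if (length(fr)) div <- max(round(1 / min(abs(fr))))
    }
    .niceGridCount(2 * (2 * maxH[a] + 1), div)
  }, numeric(1))
}

# core of phase-set comparison: best shift/hand minimizing the weighted
# mean absolute phase difference
.registerPhasePair <- function(p1, p2, weights = NULL, allowInversion = NULL,
                               topK = 8L) {
  r1 <- p1@refl; tb <- r1@table
  sg <- r1@spacegroup
  if (is.null(allowInversion)) allowInversion <- sg@inversionAmbiguous
  sel <- which(!is.na(p1@phase) & !is.na(p2@phase) & !tb$missing)
  if (!length(sel)) .stopf("no common phased reflections")
  hkl <- as.matrix(tb[sel, c("h", "k", "l")])
  W <- if (is.null(weights)) rep(1, length(sel)) else weights[sel]
  ph1 <- p1@phase[sel]
  cont <- any(sg@continuousAxes)
  dims <- .phaseSearchDims(tb[sel, ], sg)
  mapd <- function(dphiDeg, w) sum(w * .absAngleDiff(dphiDeg)) / sum(w)
  best <- NULL
  for (inv in if (allowInversion) c(FALSE, TRUE) else FALSE) {
    ph2 <- if (inv) -p2@phase[sel] else p2@phase[sel]
    dph <- ph1 - ph2
    evalAt <- function(tfrac) mapd(dph - 360 * as.numeric(hkl %*% tfrac), W)
    cands <- list()
    if (cont) {
      # phased translation function: resultant of W exp(i dphi) over shifts
      Z <- complex(length.out = prod(dims))
      pos <- 1L + (hkl[, 1] %% dims[1]) +
        dims[1] * ((hkl[, 2] %% dims[2]) + dims[2] * (hkl[, 3] %% dims[3]))
      Z[pos] <- W * exp(1i * .deg2rad(dph))
      S <- Re(stats::fft(array(Z, dims)))
      allowed <- .allowedShiftMask(sg, dims)
      idx <- which(allowed)
      ordIdx <- idx[order(S[idx], decreasing = TRUE)]
      take <- utils::head(ordIdx, topK)
      for (li in take) {
        t0 <- (arrayInd(li, dims) - 1L) / dims
        cands[[length(cands) + 1L]] <- as.numeric(t0)
        # polish the continuous components by maximizing the resultant
        free <- which(sg@continuousAxes)
        obj <- function(par) {
          tf <- as.numeric(t0); tf[free] <- par
          -sum(W * cos(.deg2rad(dph - 360 * as.numeric(hkl %*% tf))))
        }
        op <- stats::optim(as.numeric(t0)[free], obj, method = "Nelder-Mead",
                           control = list(maxit = 200, reltol = 1e-10))
        tf <- as.numeric(t0); tf[free] <- op$par %% 1
        cands[[length(cands) + 1L]] <- tf
      }
      # always include the exact discrete rows too
      for (r in seq_len(nrow(sg@originShifts)))
        cands[[length(cands) + 1L]] <- sg@originShifts[r, ]
    } else {
      for (r in seq_len(nrow(sg@originShifts)))
        cands[[length(cands) + 1L]] <- sg@originShifts[r, ]
    }
    for (tf in cands) {
      v <- evalAt(tf)
      if (is.null(best) || v < best$mapd)
        best <- list(shift = as.numeric(tf) %% 1, inverted = inv, mapd = v)
    }
  }
  best
}

#' Mean absolute phase difference between two phase sets
#'
#' The mean over common reflections of the wrapped absolute phase
#' difference, minimized over the permitted origin shifts (each shift t
#' rotating reflection h by 360 (h.t) degrees) and, where the group allows
#' it, the inversion alternative. Two unrelated phase sets score about 90
#' degrees; this is the distance used for clustering phase sets.
#'
#' @param p1,p2 [PhaseSet-class] objects sharing a reflection set
#' @param allowInversion default: the group's inversion ambiguity
#' @return degrees in [0, 180]
#' @export
phaseDistance <- function(p1, p2, allowInversion = NULL) {
  .registerPhasePair(p1, p2, weights = NULL,
                     allowInversion = allowInversion)$mapd
}

#' Weighted mean absolute phase difference
#'
#' As [phaseDistance()], but each reflection is weighted by the apodization
#' weight of `p` (so strongly down-weighted high-resolution terms count
#' less). With all weights 1 this equals the plain phase distance.
#' @param p a [PhaseSet-class] whose apodization weights are used
#' @param model the comparison [PhaseSet-class] (e.g. ground truth)
#' @param allowInversion default: the group's inversion ambiguity
#' @return degrees in [0, 180]
#' @export
weightedMeanAbsPhaseDiff <- function(p, model, allowInversion = NULL) {
  .registerPhasePair(p, model, weights = p@weight,
                     allowInversion = allowInversion)$mapd
}

#' Registration details for a phase-set pair
#'
#' Like [phaseDistance()] but returning the full [Registration-class]
#' (shift, hand and the achieved distance as a negative score, so that
#' higher scores mean better agreement).
#' @param p1,p2 [PhaseSet-class] objects
#' @param weights optional per-reflection weights
#' @param allowInversion default: the group's inversion ambiguity
#' @export
phaseRegistration <- function(p1, p2, weights = NULL, allowInversion = NULL) {
  b <- .registerPhasePair(p1, p2, weights, allowInversion)
  new("Registration", shift = b$shift, inverted = b$inverted,
      score = -b$mapd)
}
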