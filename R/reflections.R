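#' ReflectionData: symmetry-unique indexed amplitudes
#'
#' One record per symmetry-unique reflection, with the measured amplitude
#' (or a missing flag), the scattering-vector magnitude s = 1/d, the
#' centric/acentric classification and the symmetry enhancement factor
#' epsilon derived from the operators. Records below the low-resolution
#' cutoff are retained but flagged missing: the ultra-low-resolution terms
#' are prone to systematic artifacts and omitting them aids convergence, so
#' they are left to evolve under the Wilson guard instead.
#'
#' @slot table data.frame with columns h, k, l, fobs, sigma, missing, s,
#'   centric, epsilon
#' @slot cell a [UnitCell-class]
#' @slot spacegroup a [SpaceGroupSpec-class]
#' @slot lowResCutoff low-resolution cutoff in Angstrom (reflections with
#'   d > cutoff are flagged missing); default 25
#' @slot cache internal environment for grid-mapping caches
#' @name ReflectionData-class
#' @aliases ReflectionData
#' @exportClass ReflectionData
setClass("ReflectionData",
  representation(table = "data.frame", cell = "UnitCell",
                 spacegroup = "SpaceGroupSpec", lowResCutoff = "numeric",
                 cache = "environment"))

setValidity("ReflectionData", function(object) {
  tb <- object@table
  need <- c("h", "k", "l", "fobs", "sigma", "missing", "s", "centric", "epsilon")
  if (!all(need %in% names(tb))) return("reflection table is missing columns")
  if (any(tb$h == 0 & tb$k == 0 & tb$l == 0 & !tb$missing))
    return("(0,0,0) must never be present as an observed reflection")
  if (any(!is.na(tb$fobs) & tb$fobs < 0)) return("negative amplitude")
  key <- .hklKey(tb$h, tb$k, tb$l)
  if (anyDuplicated(key)) return("duplicate reflections after symmetry reduction")
  s2 <- scatteringMagnitude(as.matrix(tb[, c("h", "k", "l")]), cell = object@cell)
  if (any(abs(s2 - tb$s) > 1e-8 * (1 + s2)))
    return("stored s values disagree with the reciprocal metric")
  TRUE
})

#' Build symmetry-unique reflection data from raw records
#'
#' Input indices are reduced to their symmetry-unique representatives.
#' Symmetry mates carrying the same amplitude (within relative tolerance
#' 1e-4) merge into a single record; mates with conflicting amplitudes are
#' reported as duplicates, naming the offending indices. Amplitudes must be
#' non-negative; reflections at resolution lower than `lowResCutoff` are
#' flagged missing.
#'
#' @param h,k,l integer Miller indices
#' @param fobs amplitudes (NA for unmeasured)
#' @param sigma optional amplitude standard deviations
#' @param cell a [UnitCell-class]
#' @param spacegroup a [SpaceGroupSpec-class] or name
#' @param lowResCutoff in Angstrom; default 25
#' @return a [ReflectionData-class]
#' @export
reflectionData <- function(h, k, l, fobs, sigma = NA_real_, cell,
                           spacegroup = "P1", lowResCutoff = 25) {
  sg <- spaceGroup(spacegroup)
  if (any(!is.na(fobs) & fobs < 0)) {
    bad <- which(!is.na(fobs) & fobs < 0)[1]
    .stopf("negative amplitude at (%d,%d,%d)", h[bad], k[bad], l[bad])
  }
  can <- canonicalHKL(cbind(h, k, l), sg)
  key <- .hklKey(can$h, can$k, can$l)
  grp <- match(key, unique(key))
  ord <- which(!duplicated(key))
  # check amplitude consistency within each orbit
  for (g in which(tabulate(grp) > 1)) {
    f <- fobs[grp == g]
    f <- f[!is.na(f)]
    if (length(f) > 1 && (max(f) - min(f)) > 1e-4 * (1 + max(f))) {
      i <- which(grp == g)
      .stopf("duplicate reflection (%s) with conflicting amplitudes: input rows %s",
             key[ord[g]], paste(i, collapse = ", "))
    }
  }
  agg <- function(x) vapply(split(x, grp), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  fobsU <- agg(fobs)
  sigmaU <- agg(rep_len(as.numeric(sigma), length(fobs)))
  hu <- can$h[ord]; ku <- can$k[ord]; lu <- can$l[ord]
  s <- scatteringMagnitude(cbind(hu, ku, lu), cell = cell)
  missing <- is.na(fobsU) | (s < 1 / lowResCutoff)
  tb <- data.frame(h = hu, k = ku, l = lu, fobs = as.numeric(fobsU),
                   sigma = as.numeric(sigmaU), missing = missing, s = s,
                   centric = can$centric[ord], epsilon = can$epsilon[ord])
  tb <- tb[order(tb$s, tb$h, tb$k, tb$l), ]
  rownames(tb) <- NULL
  new("ReflectionData", table = tb, cell = cell, spacegroup = sg,
      lowResCutoff = lowResCutoff, cache = new.env(parent = emptyenv()))
}

#' @describeIn ReflectionData-class the reflection table as a data.frame
#' @param refl a \code{ReflectionData}
#' @export
reflTable <- function(refl) refl@table

#' Number of reflections (observed, or all unique)
#' @param refl a [ReflectionData-class]
#' @param observed count only non-missing records
#' @export
nReflections <- function(refl, observed = FALSE) {
  if (observed) sum(!refl@table$missing) else nrow(refl@table)
}

setMethod("show", "ReflectionData", function(object) {
  tb <- object@table
  obs <- !tb$missing
  cat(sprintf("ReflectionData: %d unique reflections (%d observed, %d missing) in %s\n",
              nrow(tb), sum(obs), sum(!obs), object@spacegroup@name))
  if (any(obs))
    cat(sprintf("  resolution %.2f - %.2f A; %d centric; low-res cutoff %.1f A\n",
                1 / min(tb$s[obs]), 1 / max(tb$s[obs]), sum(tb$centric),
                object@lowResCutoff))
})

#' Read reflections from a text HKL file
#'
#' Whitespace-separated columns `h k l F [sigF]`; `#` starts a comment.
#' Extra columns are ignored with a warning. The records are reduced to the
#' symmetry-unique set and classified exactly as in [reflectionData()].
#'
#' @param path file path
#' @param cell a [UnitCell-class]
#' @param spacegroup a [SpaceGroupSpec-class] or name
#' @param lowResCutoff in Angstrom, default 25
#' @return a [ReflectionData-class]
#' @export
readHKL <- function(path, cell, spacegroup = "P1", lowResCutoff = 25) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) .stopf("no reflection records in '%s'", path)
  fields <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 4)) .stopf("line with fewer than 4 fields in '%s'", path)
  if (any(nf > 5))
    .warnf("ignoring extra columns beyond 'h k l F sigF' in '%s'", path)
  num <- function(i) as.numeric(vapply(fields, `[`, character(1), i))
  h <- num(1); k <- num(2); l <- num(3); f <- num(4)
  s <- if (any(nf >= 5)) {
    vapply(fields, function(x) if (length(x) >= 5) as.numeric(x[5]) else NA_real_,
           numeric(1))
  } else NA_real_
  if (any(is.na(h) | is.na(k) | is.na(l)))
    .stopf("unparseable Miller indices in '%s'", path)
  reflectionData(h, k, l, f, s, cell, spacegroup, lowResCutoff)
}

#' Write reflections in the text HKL dialect
#' @param refl a [ReflectionData-class]
#' @param path output file
#' @param sigma include the sigma column
#' @export
writeHKL <- function(refl, path, sigma = TRUE) {
  tb <- refl@table[!refl@table$missing | !is.na(refl@table$fobs), ]
  tb <- tb[!is.na(tb$fobs), ]
  con <- file(path, "w")
  on.exit(close(con))
  cp <- cellParameters(refl@cell)
  writeLines(sprintf("# cell %.4f %.4f %.4f %.3f %.3f %.3f  spacegroup %s",
                     cp[1], cp[2], cp[3], cp[4], cp[5], cp[6],
                     refl@spacegroup@name), con)
  if (sigma && any(!is.na(tb$sigma))) {
    writeLines(sprintf("%4d %4d %4d %14.6g %14.6g", tb$h, tb$k, tb$l,
                       tb$fobs, ifelse(is.na(tb$sigma), 0, tb$sigma)), con)
  } else {
    writeLines(sprintf("%4d %4d %4d %14.6g", tb$h, tb$k, tb$l, tb$fobs), con)
  }
  invisible(path)
}

#' PhaseSet: per-reflection phases with apodization weights
#'
#' The unit of clustering during phase determination. Phases are in degrees
#' on [0, 360); the weight of each reflection is the Gaussian apodization
#' weight w(s) in force when the set was produced (1 everywhere for an
#' unapodized set).
#'
#' @slot refl the paired [ReflectionData-class]
#' @slot phase numeric, degrees in [0,360); NA for missing reflections
#' @slot weight numeric in [0,1]
#' @slot sigma apodization sigma in reciprocal Angstrom (Inf = none)
#' @name PhaseSet-class
#' @aliases PhaseSet
#' @exportClass PhaseSet
setClass("PhaseSet",
  representation(refl = "ReflectionData", phase = "numeric",
                 weight = "numeric", sigma = "numeric"))

setValidity("PhaseSet", function(object) {
  n <- nrow(object@refl@table)
  if (length(object@phase) != n || length(object@weight) != n)
    return("phase/weight length must match the reflection table")
  ph <- object@phase[!is.na(object@phase)]
  if (any(ph < 0 | ph >= 360)) return("phases must lie in [0, 360)")
  if (any(object@weight < 0 | object@weight > 1 + 1e-12))
    return("weights must lie in [0, 1]")
  TRUE
})

#' Construct a phase set
#' @param refl a [ReflectionData-class]
#' @param phase degrees, one per unique reflection (NA where missing)
#' @param sigma apodization sigma that produced the set (Inf for none);
#'   weights are computed as w(s) from it
#' @export
phaseSet <- function(refl, phase, sigma = Inf) {
  w <- if (is.finite(sigma)) apodizationWeight(refl@table$s, sigma)
       else rep(1, nrow(refl@table))
  new("PhaseSet", refl = refl, phase = .wrap360(phase), weight = w,
      sigma = sigma)
}

#' @describeIn PhaseSet-class phases in degrees
#' @param ps a \code{PhaseSet}
#' @export
phaseValues <- function(ps) ps@phase

#' @describeIn PhaseSet-class apodization-derived weights
#' @export
phaseWeights <- function(ps) ps@weight

setMethod("show", "PhaseSet", function(object) {
  cat(sprintf("PhaseSet: %d phased reflections of %d; apodization sigma %s\n",
              sum(!is.na(object@phase)), length(object@phase),
              if (is.finite(object@sigma)) sprintf("%.4g 1/A", object@sigma)
              else "none"))
})

#' Write a phase set as text `h k l F phase weight`
#'
#' The header records the cell, the space group and the apodization sigma.
#' @param ps a [PhaseSet-class]
#' @param path output file
#' @export
writePhaseSet <- function(ps, path) {
  tb <- ps@refl@table
  con <- file(path, "w")
  on.exit(close(con))
  cp <- cellParameters(ps@refl@cell)
  writeLines(sprintf("# cell %.4f %.4f %.4f %.3f %.3f %.3f", cp[1], cp[2],
                     cp[3], cp[4], cp[5], cp[6]), con)
  writeLines(sprintf("# spacegroup %s", ps@refl@spacegroup@name), con)
  writeLines(sprintf("# apodization_sigma %s",
                     if (is.finite(ps@sigma)) format(ps@sigma) else "none"), con)
  sel <- !is.na(ps@phase)
  writeLines(sprintf("%4d %4d %4d %14.6g %10.4f %8.5f", tb$h[sel], tb$k[sel],
                     tb$l[sel], ifelse(is.na(tb$fobs[sel]), 0, tb$fobs[sel]),
                     ps@phase[sel], ps@weight[sel]), con)
  invisible(path)
}

#' Read a phase set written by [writePhaseSet()]
#' @param path input file
#' @param cell,spacegroup context for rebuilding the reflection table
#' @param lowResCutoff passed to [reflectionData()]
#' @export
readPhaseSet <- function(path, cell, spacegroup, lowResCutoff = 25) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  sig <- Inf
  m <- grep("apodization_sigma", hdr, value = TRUE)
  if (length(m)) {
    v <- sub(".*apodization_sigma[[:space:]]+", "", m[1])
    if (v != "none") sig <- as.numeric(v)
  }
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  fl <- strsplit(trimws(body), "[[:space:]]+")
  num <- function(i) as.numeric(vapply(fl, `[`, character(1), i))
  refl <- reflectionData(num(1), num(2), num(3), num(4), cell = cell,
                         spacegroup = spacegroup, lowResCutoff = lowResCutoff)
  # map phases onto the (re-sorted) unique table
  can <- canonicalHKL(cbind(num(1), num(2), num(3)), spaceGroup(spacegroup))
  idx <- match(.hklKey(refl@table$h, refl@table$k, refl@table$l),
               .hklKey(can$h, can$k, can$l))
  phaseSet(refl, num(5)[idx], sigma = sig)
}
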