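# Density-based clustering of envelopes and phase sets, and construction of
# consensus solutions by averaging cluster members on a common origin.
# Clustering is the device that identifies true solutions: correct results
# from independently seeded runs agree with each other, while the many
# incorrect envelopes/phase sets satisfying the constraints are mutually
# unrelated.

#' ClusterSet: result of density-based clustering
#'
#' @slot labels integer per input: cluster id (1, 2, ...) or 0 for noise
#' @slot minPoints,eps the DB-SCAN parameters used
#' @slot distances the pairwise distance matrix clustered
#' @name ClusterSet-class
#' @aliases ClusterSet
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(labels = "integer", minPoints = "integer", eps = "numeric",
                 distances = "matrix"))

setMethod("show", "ClusterSet", function(object) {
  k <- max(object@labels)
  sizes <- if (k > 0) tabulate(object@labels, k) else integer(0)
  cat(sprintf("ClusterSet: %d cluster(s) %s; %d noise of %d (minPoints=%d, eps=%.4g)\n",
              k, if (k) paste0("of sizes ", paste(sizes, collapse = ",")) else "",
              sum(object@labels == 0L), length(object@labels),
              object@minPoints, object@eps))
})

#' @describeIn ClusterSet-class member indices of each cluster
#' @param cs a \code{ClusterSet}
#' @export
clusterMembers <- function(cs) {
  k <- max(cs@labels)
  lapply(seq_len(k), function(i) which(cs@labels == i))
}

#' DB-SCAN on a precomputed distance matrix
#'
#' Standard density-based clustering: a point is a core point when at least
#' `minPoints` points (itself included) lie within `eps`; clusters are the
#' connected groups of core points plus the border points they reach.
#' Border points reachable from several clusters are assigned to the first
#' cluster that reaches them (clusters are grown in input-index order), so
#' the result is deterministic for a given input order; the core/noise
#' partition itself is order-independent.
#'
#' @param distances symmetric matrix with zero diagonal; no NAs
#' @param minPoints minimum neighbourhood size (self included)
#' @param eps neighbourhood radius
#' @return a [ClusterSet-class]
#' @export
dbscanClusters <- function(distances, minPoints, eps) {
  d <- as.matrix(distances)
  if (any(is.na(d))) .stopf("NA in distance matrix")
  if (nrow(d) != ncol(d) || any(abs(diag(d)) > 1e-12))
    .stopf("need a square distance matrix with zero diagonal")
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= minPoints
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (q in nb[[j]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  new("ClusterSet", labels = labels, minPoints = as.integer(minPoints),
      eps = eps, distances = d)
}

#' Data-driven neighbourhood radius for envelope clustering
#'
#' Because envelope correlations vary widely between data sets there is no
#' absolute distance threshold that works for all; instead eps is set to
#' the 4th percentile (linear interpolation) of the N(N-1)/2 unique
#' pairwise distances.
#' @param distances symmetric distance matrix
#' @param probs percentile, default 0.04
#' @export
chooseEpsEnvelopes <- function(distances, probs = 0.04) {
  d <- as.matrix(distances)
  as.numeric(stats::quantile(d[upper.tri(d)], probs, type = 7, names = FALSE))
}

# --- connectivity editing -------------------------------------------------

# label connected components of a logical 3-D mask under periodic
# 6-connectivity; returns integer array (0 outside the mask)
.labelComponents <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(array(0L, d))
  n <- length(mask)
  pos <- arrayInd(idx, d)
  lin <- function(a, b, cc) a + d[1] * ((b - 1L) + d[2] * (cc - 1L))
  edges <- NULL
  inMask <- logical(n); inMask[idx] <- TRUE
  for (ax in 1:3) {
    shifted <- pos
    shifted[, ax] <- (pos[, ax] %% d[ax]) + 1L  # +1 with wrap
    nb <- lin(shifted[, 1], shifted[, 2], shifted[, 3])
    keep <- inMask[nb]
    if (any(keep)) edges <- rbind(edges, cbind(idx[keep], nb[keep]))
  }
  vid <- match(seq_len(n), idx)  # vertex id within mask
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(cbind(vid[edges[, 1]], vid[edges[, 2]])))
  comp <- igraph::components(g)$membership
  out <- array(0L, d)
  out[idx] <- as.integer(comp)
  out
}

#' Connectivity statistics of an envelope's protein region
#' @param env a [BinaryEnvelope-class]
#' @return list: `nComponents`, `islandFraction` (protein voxels outside the
#'   largest component, as a fraction of all protein voxels)
#' @export
envelopeConnectivity <- function(env) {
  lab <- .labelComponents(env@mask)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes)) return(list(nComponents = 0L, islandFraction = 0))
  list(nComponents = length(sizes),
       islandFraction = 1 - max(sizes) / sum(sizes))
}

#' Edit envelope connectivity: erase small islands, fill small voids
#'
#' Consensus averaging can leave small disconnected protein islands and
#' small solvent voids enclosed in the protein region; a good molecular
#' envelope is (nearly) singly connected. Protein components smaller than
#' `minFraction` of the protein voxel count are erased, and solvent
#' components (other than the largest, the bulk solvent) smaller than the
#' same threshold are filled.
#'
#' @param env a [BinaryEnvelope-class]
#' @param minFraction size threshold as a fraction of the protein voxel
#'   count (default 0.01)
#' @export
editConnectivity <- function(env, minFraction = 0.01) {
  mask <- env@mask
  thr <- minFraction * sum(mask)
  lab <- .labelComponents(mask)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < thr)
  if (length(small)) mask[lab %in% small] <- FALSE
  lab2 <- .labelComponents(!mask)
  sizes2 <- tabulate(lab2[lab2 > 0])
  if (length(sizes2) > 1) {
    bulk <- which.max(sizes2)
    fill <- setdiff(which(sizes2 < thr), bulk)
    if (length(fill)) mask[lab2 %in% fill] <- TRUE
  }
  env@mask <- mask
  env
}

#' Consensus envelope of a cluster
#'
#' Members are brought to the origin (and hand) of the first member, a
#' per-voxel majority vote is taken (ties count as protein), and the result
#' is connectivity-edited with [editConnectivity()]. The realized solvent
#' fraction of the consensus may deviate from the target because of the
#' averaging; it is reported by [realizedSolventFraction()].
#'
#' @param members list of [BinaryEnvelope-class] objects on one grid
#' @param registrations optional precomputed list of [Registration-class]
#'   aligning each member to the first (computed if NULL)
#' @param minFraction connectivity-edit threshold (see [editConnectivity()])
#' @return a [BinaryEnvelope-class]
#' @export
consensusEnvelope <- function(members, registrations = NULL,
                              minFraction = 0.01) {
  if (length(members) < 2) .stopf("need >= 2 cluster members")
  d0 <- dim(members[[1]]@mask)
  votes <- array(0L, d0)
  for (i in seq_along(members)) {
    m <- members[[i]]
    if (!all(dim(m@mask) == d0)) .stopf("members on different grids")
    if (i > 1) {
      reg <- if (!is.null(registrations)) registrations[[i]]
             else bestRegistration(members[[1]], m)
      m <- applyRegistration(m, reg)
    }
    votes <- votes + m@mask
  }
  mask <- votes * 2L >= length(members)  # ties -> protein
  env <- binaryEnvelope(mask, members[[1]]@solventFraction,
                        members[[1]]@cell, members[[1]]@spacegroup)
  editConnectivity(env, minFraction)
}

#' Consensus phase set of a cluster
#'
#' Members are registered to the first member; for each reflection the
#' consensus phase is the argument of the mean unit phase vector across
#' members. A reflection whose mean resultant is (numerically) zero --
#' e.g. an antipodal pair -- has no defined mean direction and is flagged
#' undefined. The consistency of the cluster is summarized by the sample
#' circular variance, 1 minus the mean resultant length over defined
#' reflections: 0 for perfectly consistent phases, up to 1 for unrelated
#' ones.
#'
#' @param members list of [PhaseSet-class] objects sharing a reflection set
#' @param registrations optional list of [Registration-class] aligning each
#'   member to the first
#' @return list: `phases` (a [PhaseSet-class]; undefined phases are NA),
#'   `circularVariance`, `undefined` (logical per reflection)
#' @export
consensusPhases <- function(members, registrations = NULL) {
  if (length(members) < 2) .stopf("need >= 2 cluster members")
  refl <- members[[1]]@refl
  n <- nrow(refl@table)
  Zsum <- complex(length.out = n)
  cnt <- integer(n)
  for (i in seq_along(members)) {
    m <- members[[i]]
    if (i > 1) {
      reg <- if (!is.null(registrations)) registrations[[i]]
             else phaseRegistration(members[[1]], m)
      m <- applyRegistration(m, reg)
    }
    ok <- !is.na(m@phase)
    Zsum[ok] <- Zsum[ok] + exp(1i * .deg2rad(m@phase[ok]))
    cnt[ok] <- cnt[ok] + 1L
  }
  R <- ifelse(cnt > 0, Mod(Zsum) / pmax(cnt, 1L), NA_real_)
  undef <- !is.na(R) & R < 1e-9
  ph <- rep(NA_real_, n)
  def <- cnt > 0 & !undef
  ph[def] <- .wrap360(.rad2deg(Arg(Zsum[def])))
  circVar <- 1 - mean(R[def])
  if (any(undef))
    .warnf("%d reflection(s) with zero resultant: consensus phase undefined",
           sum(undef))
  list(phases = phaseSet(refl, ph, sigma = members[[1]]@sigma),
       circularVariance = circVar, undefined = undef)
}
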