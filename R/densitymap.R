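#' DensityMap: real-valued density on a grid over one unit cell
#'
#' Density values are stored for the full unit cell in P1-expanded form
#' (symmetry is imposed by averaging over the operators after each inverse
#' Fourier transform). Fractional coordinate (0,0,0) sits at array index
#' (1,1,1); the grid is cell-periodic.
#'
#' @slot values numeric 3-D array (nu x nv x nw), finite
#' @slot cell a [UnitCell-class]
#' @slot spacegroup a [SpaceGroupSpec-class]
#' @name DensityMap-class
#' @aliases DensityMap
#' @exportClass DensityMap
setClass("DensityMap",
  representation(values = "array", cell = "UnitCell",
                 spacegroup = "SpaceGroupSpec"))

setValidity("DensityMap", function(object) {
  d <- dim(object@values)
  if (length(d) != 3) return("values must be a 3-D array")
  if (any(d < 2)) return("grid counts must be >= 2")
  if (!all(is.finite(object@values))) return("density values must be finite")
  if (!.gridCompatible(object@spacegroup, d))
    return("grid counts are incompatible with the symmetry operators' translations")
  TRUE
})

#' Construct a density map
#' @param values numeric 3-D array
#' @param cell a [UnitCell-class]
#' @param spacegroup a [SpaceGroupSpec-class] or symbol (default P1)
#' @export
densityMap <- function(values, cell, spacegroup = "P1") {
  new("DensityMap", values = values, cell = cell,
      spacegroup = spaceGroup(spacegroup))
}

#' @describeIn DensityMap-class the raw value array
#' @param map a \code{DensityMap}
#' @export
mapValues <- function(map) map@values

#' @describeIn DensityMap-class grid dimensions (nu, nv, nw)
#' @export
gridDims <- function(map) dim(map@values)

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@values)
  v <- object@values
  cat(sprintf("DensityMap %dx%dx%d in %s; range [%.4g, %.4g], mean %.4g, sd %.4g\n",
              d[1], d[2], d[3], object@spacegroup@name,
              min(v), max(v), mean(v), stats::sd(v)))
})

#' Choose grid counts for a target spacing
#'
#' Returns the smallest FFT-friendly grid (factors 2, 3, 5) whose spacing
#' along each axis does not exceed `spacing`, compatible with the symmetry
#' operators (translation denominators divide the counts; axes mixed by a
#' rotation share a count).
#'
#' @param cell a [UnitCell-class]
#' @param spacing target grid spacing in Angstrom (e.g. 2/5 of the effective
#'   resolution)
#' @param spacegroup a [SpaceGroupSpec-class] or name
#' @return integer(3) grid counts
#' @export
suggestGrid <- function(cell, spacing, spacegroup = "P1") {
  sg <- spaceGroup(spacegroup)
  lens <- c(cell@a, cell@b, cell@c)
  # required divisor per axis from operator translations
  div <- rep(1L, 3)
  for (g in sg@ops) for (a in 1:3) {
    if (abs(g$t[a]) > 1e-9) {
      den <- round(1 / min(abs(c(g$t[a], 1 - g$t[a]))))
      div[a] <- as.integer(max(div[a], den))
    }
  }
  # axes coupled by off-diagonal rotation elements must share a count
  groupId <- 1:3
  for (g in sg@ops) for (a in 1:3) for (b in 1:3) {
    if (a != b && g$R[a, b] != 0) groupId[groupId == groupId[b]] <- groupId[a]
  }
  n <- integer(3)
  for (grp in unique(groupId)) {
    axes <- which(groupId == grp)
    need <- max(ceiling(lens[axes] / spacing))
    d <- 1L
    for (a in axes) d <- as.integer(d * div[a] / .gcd(d, div[a]))  # lcm
    n[axes] <- .niceGridCount(need, d)
  }
  n
}

.gcd <- function(x, y) if (y == 0) x else .gcd(y, x %% y)

#' Structure factors of a density map
#'
#' Discrete Fourier analysis of the cell: `F(h) = (1/N) * sum_x rho(x)
#' exp(+2 pi i h.x)`, returned as a complex array indexed like the FFT grid
#' (element (1,1,1) is F(000)). Hermitian symmetry `F(-h) = conj(F(h))`
#' holds for real maps, and [mapFromStructureFactors()] inverts the
#' transform exactly.
#'
#' @param map a [DensityMap-class] (or a numeric 3-D array)
#' @return complex array of the same dimensions
#' @export
structureFactors <- function(map) {
  vals <- if (is(map, "DensityMap")) map@values else map
  stats::fft(vals, inverse = TRUE) / length(vals)
}

#' Inverse transform: density from structure factors
#' @param sf complex array as produced by [structureFactors()]
#' @param cell a [UnitCell-class]
#' @param spacegroup group for the resulting map
#' @param symmetrize average over the symmetry operators after the transform
#' @return a [DensityMap-class]
#' @export
mapFromStructureFactors <- function(sf, cell, spacegroup = "P1",
                                    symmetrize = TRUE) {
  sg <- spaceGroup(spacegroup)
  vals <- Re(stats::fft(sf))
  vals <- array(vals, dim = dim(sf))
  if (symmetrize) vals <- .symmetrizeValues(vals, sg, dim(sf))
  densityMap(vals, cell, sg)
}

#' Impose crystallographic symmetry by group averaging
#' @param map a [DensityMap-class]
#' @export
symmetrizeMap <- function(map) {
  map@values <- .symmetrizeValues(map@values, map@spacegroup, dim(map@values))
  map
}

# Miller indices of every grid element (list of three N-vectors) and their s
.gridMiller <- function(dims) {
  h1 <- .fftFreq(dims[1]); h2 <- .fftFreq(dims[2]); h3 <- .fftFreq(dims[3])
  list(h = rep.int(h1, dims[2] * dims[3]),
       k = rep.int(rep(h2, each = dims[1]), dims[3]),
       l = rep(h3, each = dims[1] * dims[2]))
}

# minimum-image Cartesian distance from the grid origin to every grid point
.distCache <- new.env(parent = emptyenv())
.gridDistance <- function(dims, cell) {
  key <- paste(c(dims, round(cellParameters(cell), 6)), collapse = "_")
  hit <- .distCache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- .gridIndex0(dims)
  fr <- cbind(idx$i1 / dims[1], idx$i2 / dims[2], idx$i3 / dims[3])
  fr <- fr - round(fr)  # minimum image in fractional coords
  xyz <- fr %*% t(orthoMatrix(cell))
  d <- array(sqrt(rowSums(xyz^2)), dim = dims)
  .distCache[[key]] <- d
  d
}

#' Pearson correlation between two density maps
#' @param a,b [DensityMap-class] objects on the same grid
#' @export
mapCorrelation <- function(a, b) {
  stopifnot(all(dim(a@values) == dim(b@values)))
  stats::cor(as.numeric(a@values), as.numeric(b@values))
}
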