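#' UnitCell: crystallographic unit-cell geometry
#'
#' Holds the six cell parameters and provides the metric machinery used
#' throughout the package: the orthogonalization matrix (fractional to
#' Cartesian coordinates, in Angstrom), the real and reciprocal metric
#' tensors, and the cell volume.
#'
#' @slot a,b,c cell edge lengths in Angstrom (> 0)
#' @slot alpha,beta,gamma cell angles in degrees, each in (0, 180)
#' @name UnitCell-class
#' @aliases UnitCell
#' @exportClass UnitCell
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"))

setValidity("UnitCell", function(object) {
  p <- c(object@a, object@b, object@c)
  ang <- c(object@alpha, object@beta, object@gamma)
  if (any(!is.finite(p)) || any(p <= 0))
    return("cell lengths must be finite and > 0")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    return("cell angles must lie in (0, 180) degrees")
  ca <- cos(.deg2rad(object@alpha)); cb <- cos(.deg2rad(object@beta))
  cg <- cos(.deg2rad(object@gamma))
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) return("degenerate cell: metric tensor not positive definite")
  TRUE
})

#' Construct a unit cell
#'
#' @param a,b,c cell lengths in Angstrom
#' @param alpha,beta,gamma cell angles in degrees (default 90)
#' @return a [UnitCell-class] object
#' @examples
#' uc <- unitCell(40, 40, 40)
#' cellVolume(uc)
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma))
}

#' @describeIn UnitCell-class the six cell parameters as a named vector
#' @param cell a \code{UnitCell}
#' @export
cellParameters <- function(cell) {
  stopifnot(is(cell, "UnitCell"))
  c(a = cell@a, b = cell@b, c = cell@c,
    alpha = cell@alpha, beta = cell@beta, gamma = cell@gamma)
}

#' Orthogonalization matrix (fractional -> Cartesian, Angstrom)
#'
#' Standard PDB convention: a along x, b in the x-y plane.
#' @param cell a [UnitCell-class]
#' @export
orthoMatrix <- function(cell) {
  stopifnot(is(cell, "UnitCell"))
  ca <- cos(.deg2rad(cell@alpha)); cb <- cos(.deg2rad(cell@beta))
  cg <- cos(.deg2rad(cell@gamma)); sg <- sin(.deg2rad(cell@gamma))
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell@a, cell@b * cg, cell@c * cb,
           0,      cell@b * sg, cell@c * (ca - cb * cg) / sg,
           0,      0,           cell@c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' Real-space metric tensor (Angstrom^2)
#' @param cell a [UnitCell-class]
#' @export
metricTensor <- function(cell) {
  o <- orthoMatrix(cell)
  t(o) %*% o
}

#' Reciprocal metric tensor (Angstrom^-2)
#' @param cell a [UnitCell-class]
#' @export
recipMetricTensor <- function(cell) solve(metricTensor(cell))

#' Unit-cell volume in cubic Angstrom
#' @param cell a [UnitCell-class]
#' @export
cellVolume <- function(cell) {
  stopifnot(is(cell, "UnitCell"))
  sqrt(det(metricTensor(cell)))
}

#' Scattering-vector magnitude s = 1/d for Miller indices
#'
#' s is the distance from the Fourier-space origin in reciprocal Angstrom;
#' its inverse is the resolution of the reflection.
#'
#' @param h,k,l integer Miller indices (vectors of equal length), or `h` may
#'   be an n x 3 matrix with `k`, `l` missing
#' @param cell a [UnitCell-class]
#' @return numeric vector of s values (Angstrom^-1); 0 only for (0,0,0)
#' @examples
#' scatteringMagnitude(1, 0, 0, unitCell(10, 10, 10))  # 0.1
#' @export
scatteringMagnitude <- function(h, k = NULL, l = NULL, cell) {
  if (is.matrix(h)) {
    hkl <- h
  } else {
    hkl <- cbind(h, k, l)
  }
  g <- recipMetricTensor(cell)
  sqrt(pmax(rowSums((hkl %*% g) * hkl), 0))
}

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              object@a, object@b, object@c, object@alpha, object@beta,
              object@gamma, cellVolume(object)))
})
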