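# Internal helpers shared across the package.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# wrap an angular difference (degrees) into [0, 180]
.absAngleDiff <- function(x) {
  d <- abs(x) %% 360
  pmin(d, 360 - d)
}

# wrap degrees into [0, 360); NA passes through
.wrap360 <- function(x) {
  y <- x %% 360
  y[!is.na(y) & y < 0] <- y[!is.na(y) & y < 0] + 360
  y
}

# population variance: grid points are the whole population of a region
.popVar <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# smallest integer >= n whose prime factors are all in {2,3,5} and which is
# divisible by `div` (keeps FFT lengths fast and symmetry-translations on-grid)
.niceGridCount <- function(n, div = 1L) {
  n <- max(as.integer(ceiling(n)), 2L, as.integer(div))
  n <- as.integer(div * ceiling(n / div))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + as.integer(div)
  }
}

# 0-based grid index vectors for an array of dims d (linear order = R array order)
.gridIndex0 <- function(d) {
  list(
    i1 = rep.int(0:(d[1] - 1L), d[2] * d[3]),
    i2 = rep.int(rep(0:(d[2] - 1L), each = d[1]), d[3]),
    i3 = rep(0:(d[3] - 1L), each = d[1] * d[2])
  )
}

# Miller index along one axis for FFT element 0..n-1
.fftFreq <- function(n) {
  h <- 0:(n - 1L)
  h[h > n / 2] <- h[h > n / 2] - n
  h
}

# stable key for (h,k,l) triples
.hklKey <- function(h, k, l) paste(h, k, l, sep = ",")
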