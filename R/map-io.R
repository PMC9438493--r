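# CCP4/MRC map input and output (mode 2, 32-bit float, X fastest).

#' Write a density map (or envelope mask) in CCP4/MRC format
#'
#' Mode 2 (float32), axis order X fastest, cell and space-group number
#' recorded in the header; voxel statistics (min/max/mean/rms) filled in.
#' Masks are written as 0/1 values.
#'
#' @param map a [DensityMap-class] or [BinaryEnvelope-class]
#' @param path output file
#' @param ispg space-group number to record (default 1; the operators
#'   themselves are not serialized in this minimal writer)
#' @export
writeCCP4Map <- function(map, path, ispg = 1L) {
  if (is(map, "BinaryEnvelope")) {
    vals <- map@mask + 0
    cell <- map@cell
  } else {
    vals <- map@values
    cell <- map@cell
  }
  d <- dim(vals)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wInt(d)                       # NC NR NS
  wInt(2L)                      # MODE 2 = float32
  wInt(c(0L, 0L, 0L))           # start offsets
  wInt(d)                       # MX MY MZ
  cp <- cellParameters(cell)
  wFlt(cp)                      # cell
  wInt(c(1L, 2L, 3L))           # MAPC MAPR MAPS
  wFlt(c(min(vals), max(vals), mean(vals)))
  wInt(ispg)                    # ISPG
  wInt(0L)                      # NSYMBT
  wInt(rep(0L, 25L))            # extra (words 25-49)
  wFlt(c(0, 0, 0))              # origin (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)     # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # machine stamp (LE)
  wFlt(sqrt(.popVar(as.numeric(vals))))              # RMS
  wInt(1L)                      # NLABL
  lab <- sprintf("%-80s", "dmphase map")
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeChar(strrep(" ", 80 * 9), con, nchars = 720, eos = NULL)
  wFlt(as.numeric(vals))        # data, X fastest (R array order)
  invisible(path)
}

#' Read a CCP4/MRC map
#'
#' Accepts mode 0/1/2 maps with the standard axis order (MAPC,MAPR,MAPS =
#' 1,2,3) and zero start offsets; either byte order is handled via the
#' machine stamp.
#'
#' @param path input file
#' @param spacegroup group to attach to the map (default P1; the header's
#'   ISPG number is not mapped back to operators)
#' @return a [DensityMap-class]
#' @export
readCCP4Map <- function(path, spacegroup = "P1") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1024)
  if (length(hdr) < 1024) .stopf("malformed header: file shorter than 1024 bytes")
  if (rawToChar(hdr[209:212]) != "MAP ")
    .stopf("malformed header: missing 'MAP ' stamp")
  endian <- if (as.integer(hdr[213]) == 0x11) "big" else "little"
  rInt <- function(w, n = 1)
    readBin(hdr[(4 * (w - 1) + 1):(4 * (w - 1) + 4 * n)], "integer",
            n = n, size = 4, endian = endian)
  rFlt <- function(w, n = 1)
    readBin(hdr[(4 * (w - 1) + 1):(4 * (w - 1) + 4 * n)], "numeric",
            n = n, size = 4, endian = endian)
  d <- rInt(1, 3)
  mode <- rInt(4)
  starts <- rInt(5, 3)
  mxyz <- rInt(8, 3)
  cellp <- rFlt(11, 6)
  axes <- rInt(17, 3)
  nsymbt <- rInt(24)
  if (!all(axes == c(1L, 2L, 3L)))
    .stopf("unsupported axis order (%s)", paste(axes, collapse = ","))
  if (any(starts != 0L)) .stopf("nonzero start offsets not supported")
  if (!mode %in% c(0L, 1L, 2L)) .stopf("unsupported mode %d", mode)
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  n <- prod(d)
  vals <- switch(as.character(mode),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = endian),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, endian = endian)),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)))
  if (length(vals) != n) .stopf("truncated map data")
  if (!all(d == mxyz))
    .warnf("map covers %s of a %s cell grid; treating as full cell",
           paste(d, collapse = "x"), paste(mxyz, collapse = "x"))
  densityMap(array(vals, d),
             unitCell(cellp[1], cellp[2], cellp[3], cellp[4], cellp[5], cellp[6]),
             spacegroup)
}
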