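# MRC/CCP4 2014 map I/O and trilinear density interpolation.
#
# Header layout (4-byte words): 1-3 NX/NY/NZ, 4 MODE, 5-7 N*START, 8-10 M*,
# 11-13 CELLA, 14-16 CELLB, 17-19 MAPC/MAPR/MAPS, 20-22 DMIN/DMAX/DMEAN,
# 23 ISPG, 24 NSYMBT, 25-49 extra, 50-52 ORIGIN, 53 "MAP ", 54 machine
# stamp, 55 RMS, 56 NLABL, 57-256 labels.

.mrcInts <- function(raw, words, endian) {
  readBin(raw[rep((words - 1L) * 4L, each = 4L) + 1:4],
          what = "integer", n = length(words), size = 4L, endian = endian)
}

.mrcFloats <- function(raw, words, endian) {
  readBin(raw[rep((words - 1L) * 4L, each = 4L) + 1:4],
          what = "numeric", n = length(words), size = 4L, endian = endian)
}

.mrcHeaderSane <- function(raw, endian) {
  dims <- .mrcInts(raw, 1:3, endian)
  mode <- .mrcInts(raw, 4L, endian)
  all(dims >= 1L) && all(dims <= 100000L) && mode %in% c(0L, 1L, 2L, 6L)
}

#' Read an MRC/CCP4 density map
#'
#' Reads an MRC/CCP4 2014 volume into a [DensityGrid-class]. Any axis
#' permutation recorded in the MAPC/MAPR/MAPS fields is normalized to
#' canonical X, Y, Z order, so voxel `(i, j, k)` (0-based) is always at
#' world position `origin + voxelSize * c(i, j, k)`. The origin is taken
#' from the ORIGIN header record when set, otherwise from the
#' NXSTART/NYSTART/NZSTART offsets times the voxel size (the two MRC
#' dialects in circulation). Only orthogonal cells are supported.
#'
#' @param path path to an MRC/CCP4 file.
#' @param contourLevel recommended contour level to attach to the grid (the
#'   file format itself does not carry one).
#' @return A [DensityGrid-class].
#' @seealso [writeMap()], [interpolateDensity()]
#' @export
readMap <- function(path, contourLevel = NA_real_) {
  if (!file.exists(path)) stop("map file not found: ", path)
  sz <- file.size(path)
  if (is.na(sz) || sz < 1024) stop("malformed MRC file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, what = "raw", n = 1024L)

  endian <- "little"
  if (!.mrcHeaderSane(hdr, endian)) {
    endian <- "big"
    if (!.mrcHeaderSane(hdr, endian))
      stop("malformed MRC header (implausible dimensions/mode): ", path)
  }

  dims <- .mrcInts(hdr, 1:3, endian)          # along columns, rows, sections
  mode <- .mrcInts(hdr, 4L, endian)
  starts <- .mrcInts(hdr, 5:7, endian)
  m <- .mrcInts(hdr, 8:10, endian)
  cella <- .mrcFloats(hdr, 11:13, endian)
  cellb <- .mrcFloats(hdr, 14:16, endian)
  mapcrs <- .mrcInts(hdr, 17:19, endian)
  nsymbt <- .mrcInts(hdr, 24L, endian)
  orig <- .mrcFloats(hdr, 50:52, endian)

  if (any(abs(cellb - 90) > 1e-3))
    stop("unsupported geometry: non-orthogonal cell (angles ",
         paste(format(cellb, digits = 6), collapse = ", "), ")")
  if (all(mapcrs == 0L)) mapcrs <- 1:3
  if (!identical(sort(mapcrs), 1:3))
    stop("malformed MRC header: MAPC/MAPR/MAPS is not a permutation of 1:3")

  if (nsymbt > 0L) invisible(readBin(con, "raw", n = nsymbt))
  nvox <- prod(dims)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1L,
                             signed = TRUE, endian = endian)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2L,
                             signed = TRUE, endian = endian)),
    "2" = readBin(con, "numeric", n = nvox, size = 4L, endian = endian),
    "6" = as.numeric(readBin(con, "integer", n = nvox, size = 2L,
                             signed = FALSE, endian = endian)),
    stop("unsupported MRC mode: ", mode))
  if (length(vals) < nvox)
    stop("malformed MRC file (data shorter than header promises): ", path)

  a <- array(vals, dim = dims)                 # column-fastest storage
  perm <- match(1:3, mapcrs)                   # crs dim holding axis X, Y, Z
  a <- aperm(a, perm)

  mAxis <- m                                   # MX/MY/MZ are already per axis
  mAxis[mAxis <= 0L] <- dim(a)[mAxis <= 0L]
  voxel <- cella / mAxis
  if (any(!is.finite(voxel)) || any(voxel <= 0))
    voxel <- rep(1, 3)

  origin <- if (any(is.finite(orig) & orig != 0)) {
    orig
  } else {
    starts[perm] * voxel
  }

  DensityGrid(a, origin = origin, voxelSize = voxel,
              contourLevel = contourLevel)
}

#' Write a DensityGrid as an MRC/CCP4 map
#'
#' Writes MODE 2 (32-bit float) data in canonical X, Y, Z axis order with
#' the world origin stored in the ORIGIN header record. `readMap(writeMap(g))`
#' reproduces values, origin and voxel size exactly for float32-representable
#' inputs (the format stores 32-bit floats).
#'
#' @param grid a [DensityGrid-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readMap()]
#' @export
writeMap <- function(grid, path) {
  stopifnot(is(grid, "DensityGrid"))
  v <- grid@values
  d <- dim(v)
  con <- file(path, "wb")
  on.exit(close(con))

  wInt <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")

  wInt(d)                                   # NX NY NZ
  wInt(2L)                                  # MODE 2: float32
  wInt(c(0L, 0L, 0L))                       # N*START
  wInt(d)                                   # MX MY MZ
  wFlt(d * grid@voxelSize)                  # CELLA
  wFlt(c(90, 90, 90))                       # CELLB
  wInt(1:3)                                 # MAPC MAPR MAPS canonical
  wFlt(c(min(v), max(v), mean(v)))          # DMIN DMAX DMEAN
  wInt(1L)                                  # ISPG (P1 volume)
  wInt(0L)                                  # NSYMBT
  wInt(integer(25L))                        # extra
  wFlt(grid@origin)                         # ORIGIN
  writeBin(charToRaw("MAP "), con)          # format tag
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wFlt(stats::sd(v))                        # RMS
  wInt(1L)                                  # NLABL
  lab <- charToRaw(formatC("catracer density grid", width = -80))
  writeBin(c(lab, raw(800L - length(lab))), con)

  wFlt(as.numeric(v))                       # canonical order == column-fastest
  invisible(path)
}

#' Trilinear density interpolation
#'
#' Interpolates the density at arbitrary world positions inside the grid
#' bounding box from the 8 surrounding voxels. Exact at voxel centers, and
#' exact everywhere for fields that are affine in the coordinates.
#'
#' @param grid a [DensityGrid-class].
#' @param points numeric(3) or an n x 3 matrix of world positions (Angstrom).
#' @return numeric vector of interpolated densities.
#' @examples
#' g <- DensityGrid(array(seq_len(27), c(3, 3, 3)))
#' interpolateDensity(g, c(1, 1, 1)) == gridValues(g)[2, 2, 2]
#' @export
interpolateDensity <- function(grid, points) {
  stopifnot(is(grid, "DensityGrid"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  d <- dim(grid@values)
  t <- sweep(sweep(points, 2L, grid@origin, "-"), 2L, grid@voxelSize, "/")
  eps <- 1e-9
  if (any(t < -eps) || any(sweep(t, 2L, d - 1L, "-") > eps))
    stop("point outside the grid bounding box")
  t <- pmin(pmax(t, 0), matrix(d - 1L, nrow(t), 3L, byrow = TRUE))
  i0 <- pmin(floor(t), matrix(d - 2L, nrow(t), 3L, byrow = TRUE))
  i0 <- pmax(i0, 0)
  f <- t - i0

  v <- grid@values
  nx <- d[1L]; nxy <- d[1L] * d[2L]
  base <- 1 + i0[, 1L] + nx * i0[, 2L] + nxy * i0[, 3L]
  out <- numeric(nrow(t))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[, 1L] else 1 - f[, 1L]) *
         (if (dy) f[, 2L] else 1 - f[, 2L]) *
         (if (dz) f[, 3L] else 1 - f[, 3L])
    out <- out + w * v[base + dx + nx * dy + nxy * dz]
  }
  out
}

#' Read a C-alpha trace from a PDB file
#'
#' Extracts the C-alpha atoms of one chain, in file order. Alternate-location
#' duplicates of a residue keep the first occurrence (with a warning);
#' non-standard residues are dropped with a warning.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; `NULL` takes the first chain in the file.
#' @return A [CaStructure-class].
#' @seealso [writeCaModel()]
#' @export
readCaStructure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0L) stop("no C-alpha atoms in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("chain '", chain, "' not found in ", path)

  dup <- duplicated(at$resno)
  if (any(dup)) {
    warning(sum(dup), " duplicate C-alpha record(s) (altloc); keeping the first")
    at <- at[!dup, , drop = FALSE]
  }
  aa <- bio3d::aa321(at$resid)
  bad <- !(aa %in% .AA20)
  if (any(bad)) {
    warning("dropping ", sum(bad), " non-standard residue(s)")
    at <- at[!bad, , drop = FALSE]
    aa <- aa[!bad]
  }
  if (is.unsorted(at$resno, strictly = TRUE)) {
    warning("residue numbers not strictly increasing; sorting")
    o <- order(at$resno)
    at <- at[o, , drop = FALSE]
    aa <- aa[o]
    keep <- !duplicated(at$resno)
    at <- at[keep, , drop = FALSE]
    aa <- aa[keep]
  }
  CaStructure(resno = at$resno, aa = aa,
              xyz = cbind(at$x, at$y, at$z))
}

#' Write a C-alpha model (or structure) as a PDB file
#'
#' Emits standard ATOM records (C-alpha only), occupancy 1.00, with the
#' B-factor column optionally carrying a per-residue confidence score.
#' Coordinates are written at the format's 3-decimal precision.
#'
#' @param model a [CaModel-class] or [CaStructure-class].
#' @param path output file path.
#' @param bfactor optional numeric vector (recycled) written to the B-factor
#'   column, e.g. a consensus confidence profile; defaults to 0.
#' @param chain chain identifier to write.
#' @return `path`, invisibly.
#' @seealso [readCaStructure()], [confidenceProfile()]
#' @export
writeCaModel <- function(model, path, bfactor = NULL, chain = "A") {
  s <- if (is(model, "CaModel")) model@structure else model
  stopifnot(is(s, "CaStructure"))
  n <- length(s@resno)
  if (n == 0L) stop("empty structure")
  b <- if (is.null(bfactor)) rep(0, n) else rep_len(as.numeric(bfactor), n)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(s@xyz)),
                   resno = s@resno,
                   resid = bio3d::aa123(s@aa),
                   chain = rep(chain, n),
                   elety = rep("CA", n),
                   o = rep(1, n),
                   b = b)
  invisible(path)
}
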