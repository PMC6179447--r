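# Toy backbones and simulated density maps. These generators exist so the
# whole tracing pipeline can be exercised end to end without any deposited
# map or structure: an ideal alpha-helix (the feature best traced at 3-5 A),
# a beta-hairpin (a chain-reversal topology), and a Gaussian-kernel map
# simulator that realizes the same generative assumption the mean-shift
# stage inverts.

#' Ideal alpha-helix C-alpha trace
#'
#' Generates an ideal alpha-helix: radius 2.3 Angstrom, rise 1.5
#' Angstrom/residue, 100 degrees twist/residue about `axis`, giving the
#' canonical ~3.8 Angstrom consecutive C-alpha spacing.
#'
#' @param nRes number of residues (>= 2).
#' @param start world position (Angstrom) of the helix axis base point.
#' @param axis helix axis direction (normalized internally).
#' @param sequence optional one-letter sequence of length `nRes`; default
#'   poly-alanine.
#' @return A [CaStructure-class] with residues numbered from 1.
#' @examples
#' h <- makeHelix(10)
#' range(sqrt(rowSums(diff(caPositions(h))^2)))  # ~3.83 A throughout
#' @export
makeHelix <- function(nRes, start = c(0, 0, 0), axis = c(0, 0, 1),
                      sequence = NULL) {
  if (nRes < 2L) stop("nRes must be >= 2")
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame (u, v, axis)
  ref <- if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2L] * u[3L] - axis[3L] * u[2L],
         axis[3L] * u[1L] - axis[1L] * u[3L],
         axis[1L] * u[2L] - axis[2L] * u[1L])
  i <- seq_len(nRes) - 1L
  theta <- i * 100 * pi / 180
  xyz <- outer(2.3 * cos(theta), u) + outer(2.3 * sin(theta), v) +
    outer(1.5 * i, axis)
  xyz <- sweep(xyz, 2L, start, "+")
  aa <- if (is.null(sequence)) rep("A", nRes) else {
    s <- strsplit(sequence, "")[[1L]]
    if (length(s) != nRes) stop("sequence length must equal nRes")
    s
  }
  CaStructure(resno = seq_len(nRes), aa = aa, xyz = xyz)
}

#' Beta-hairpin C-alpha trace
#'
#' Two antiparallel straight strands (C-alpha spacing 3.8 Angstrom along the
#' strand, 5.0 Angstrom inter-strand gap) joined by a 2-residue turn, as a
#' fixture exercising chain-reversal topology.
#'
#' @param nRes total number of residues (even, >= 6).
#' @param start world position of the first residue.
#' @param mirror logical; reflect the hairpin through the xz-plane.
#' @param sequence optional one-letter sequence; default poly-valine.
#' @return A [CaStructure-class].
#' @export
makeHairpin <- function(nRes, start = c(0, 0, 0), mirror = FALSE,
                        sequence = NULL) {
  if (nRes < 6L || nRes %% 2L != 0L) stop("nRes must be even and >= 6")
  s <- (nRes - 2L) / 2L                      # residues per strand
  xEnd <- (s - 1L) * 3.8
  strand1 <- cbind((seq_len(s) - 1L) * 3.8, 0, 0)
  # 2-residue turn on a circle of radius 2.89 A centered between the strands,
  # chosen so all turn steps are ~3.7 A (close to the virtual C-alpha bond)
  r <- 2.89
  ang <- c(-40, 40) * pi / 180
  turn <- cbind(xEnd + 1.45 + r * cos(ang), 2.5 + r * sin(ang), 0)
  strand2 <- cbind(rev((seq_len(s) - 1L) * 3.8), 5.0, 0)
  xyz <- rbind(strand1, turn, strand2)
  if (mirror) xyz[, 2L] <- -xyz[, 2L]
  xyz <- sweep(xyz, 2L, start, "+")
  aa <- if (is.null(sequence)) rep("V", nRes) else {
    ss <- strsplit(sequence, "")[[1L]]
    if (length(ss) != nRes) stop("sequence length must equal nRes")
    ss
  }
  CaStructure(resno = seq_len(nRes), aa = aa, xyz = xyz)
}

#' Simulate a density map from a C-alpha trace
#'
#' Renders each atom as a Gaussian kernel `exp(-1.5 * d^2 / sigmaSim^2)` on
#' a regular grid covering the structure's bounding box plus `pad`; voxel
#' values are the sum over atoms. This is the generative assumption the
#' mean-shift stage inverts, so parameter-recovery tests are meaningful on
#' these maps. The attached contour level is the 60th percentile of the
#' positive voxel values (a fixed convention for fixtures; all downstream
#' thresholds are fractions of it).
#'
#' A rule of thumb: for a map of nominal resolution R Angstrom use
#' `sigmaSim = R / 2` (a "4 A map" is simulated with `sigmaSim = 2`).
#'
#' @param structure a [CaStructure-class] (used as point atoms).
#' @param voxel voxel size (Angstrom, isotropic).
#' @param sigmaSim Gaussian kernel bandwidth (Angstrom).
#' @param pad bounding-box padding (Angstrom).
#' @param weights optional per-residue amplitude, e.g. proportional to
#'   residue volume to create density contrast along the chain;
#'   default all 1.
#' @param weightByVolume logical; weight atoms by mean residue volume
#'   (normalized to mean 1 across the structure). Ignored when `weights`
#'   is given.
#' @return A [DensityGrid-class].
#' @seealso [makeHelix()], [residueVolumes()]
#' @export
simulateMap <- function(structure, voxel = 1.0, sigmaSim = 2.0, pad = 5.0,
                        weights = NULL, weightByVolume = FALSE) {
  stopifnot(is(structure, "CaStructure"))
  if (sigmaSim <= 0) stop("sigmaSim must be > 0")
  if (voxel <= 0) stop("voxel must be > 0")
  xyz <- structure@xyz
  n <- nrow(xyz)
  if (n == 0L) stop("empty structure")
  if (is.null(weights)) {
    weights <- if (weightByVolume) {
      v <- residueVolumes()[structure@aa]
      v / mean(v)
    } else rep(1, n)
  }
  weights <- rep_len(weights, n)

  lo <- apply(xyz, 2L, min) - pad
  hi <- apply(xyz, 2L, max) + pad
  dims <- pmax(floor((hi - lo) / voxel) + 1L, 2L)
  gx <- lo[1L] + (seq_len(dims[1L]) - 1L) * voxel
  gy <- lo[2L] + (seq_len(dims[2L]) - 1L) * voxel
  gz <- lo[3L] + (seq_len(dims[3L]) - 1L) * voxel

  vals <- array(0, dim = dims)
  for (a in seq_len(n)) {
    ex <- exp(-1.5 * (gx - xyz[a, 1L])^2 / sigmaSim^2)
    ey <- exp(-1.5 * (gy - xyz[a, 2L])^2 / sigmaSim^2)
    ez <- exp(-1.5 * (gz - xyz[a, 3L])^2 / sigmaSim^2)
    vals <- vals + weights[a] *
      (ex %o% ey %o% ez)
  }
  pos <- vals[vals > 0]
  contour <- if (length(pos)) as.numeric(stats::quantile(pos, 0.6)) else 0
  DensityGrid(vals, origin = lo, voxelSize = rep(voxel, 3L),
              contourLevel = contour)
}
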