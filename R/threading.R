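# Threading the target sequence onto the longest tree path.
#
# The path is resampled at a fixed arc-length step; the map density is
# interpolated at each sample, smoothed along the arc, and z-normalized
# over the path. Residue side-chain volumes (z-normalized over the 20
# standard residues) play the role of "expected density": a residue with a
# large side chain should sit where the path density is relatively high.
# A dynamic program places a contiguous block of the sequence on strictly
# advancing path points, with consecutive placements between minSpacing and
# maxSpacing of arc length (nominal 3.8 A virtual bond); larger interior
# jumps and unplaced terminal residues are charged gapOpen each.

#' Mean amino-acid residue volumes
#'
#' Side-chain-inclusive mean residue volumes in cubic Angstrom (standard
#' crystallographic table; glycine smallest at ~60, tryptophan largest at
#' ~228). The z-normalized form over the 20 residues is attached as
#' attribute `"z"`; only the relative sizes matter for threading.
#'
#' @return Named numeric vector of 20 volumes with a `"z"` attribute.
#' @export
residueVolumes <- function() {
  v <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
         Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
         L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
         S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
  z <- (v - mean(v)) / stats::sd(v)
  attr(v, "z") <- z
  v
}

#' Resample a path at fixed arc-length steps
#'
#' Arc-length parameterization of the polyline through the path's node
#' positions, sampled every `step` Angstrom (the path end is always
#' included, so the last interval may be shorter). At every sample the map
#' density is interpolated trilinearly, then smoothed along the arc with a
#' Gaussian kernel of bandwidth `smoothSigma`, and finally z-normalized
#' over the path (so the threading score is invariant to affine rescaling
#' of the raw map values).
#'
#' @param pathPositions p x 3 matrix of node positions along the path (e.g.
#'   `graph@positions[longestPath(tree), ]`).
#' @param grid the [DensityGrid-class] the path lives in.
#' @param step resampling step in Angstrom.
#' @param smoothSigma arc-length smoothing bandwidth in Angstrom (0
#'   disables smoothing).
#' @return A [PathProfile-class].
#' @seealso [threadSequence()]
#' @export
resamplePath <- function(pathPositions, grid, step = 1.0, smoothSigma = 2.0) {
  P <- as.matrix(pathPositions)
  if (nrow(P) < 2L) stop("degenerate path: need at least 2 positions")
  seg <- sqrt(rowSums(diff(P)^2))
  if (sum(seg) < step) stop("degenerate path: total length shorter than step")
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s <- seq(0, L, by = step)
  if (L - s[length(s)] > 1e-9) s <- c(s, L)

  # linear interpolation along the polyline
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  f <- (s - cum[idx]) / seg[idx]
  pts <- P[idx, , drop = FALSE] + f * (P[idx + 1L, , drop = FALSE] -
                                         P[idx, , drop = FALSE])

  raw <- interpolateDensity(grid, pts)
  sm <- raw
  if (smoothSigma > 0) {
    D <- abs(outer(s, s, "-"))
    W <- exp(-1.5 * (D / smoothSigma)^2)
    W[D > 3 * smoothSigma] <- 0
    sm <- as.numeric(W %*% raw) / rowSums(W)
  }
  # a numerically constant profile (e.g. a uniform field, where trilinear
  # weights wobble at machine precision) must z-normalize to exact zeros
  sdv <- stats::sd(sm)
  z <- if (!is.finite(sdv) || sdv <= 1e-9 * max(abs(mean(sm)), 1e-12))
    rep(0, length(sm)) else (sm - mean(sm)) / sdv
  new("PathProfile", points = pts, arc = s, densities = z,
      rawDensities = sm, step = step)
}

# Shared scoring pieces, used by both the DP and the brute-force oracle in
# the tests: match score and transition penalty.
.threadMatch <- function(zDensity, zVolume) -(zDensity - zVolume)^2

.threadStepPenalty <- function(deltaIdx, dmin, dmax, gapOpen) {
  ifelse(deltaIdx < dmin, -Inf,
         ifelse(deltaIdx <= dmax, 0,
                -gapOpen * ceiling((deltaIdx - dmax) / dmax)))
}

#' Thread a sequence onto a path profile by dynamic programming
#'
#' Finds the highest-scoring placement of a contiguous block of the target
#' sequence on strictly advancing path points. The match score of residue
#' `a` at point `p` is `-(z_density(p) - z_volume(a))^2`; consecutive
#' residues must advance between `minSpacing` and `maxSpacing` of arc
#' length at zero cost, larger interior jumps cost `gapOpen` per skipped
#' spacing window, and each unplaced terminal residue costs `gapOpen`.
#' `direction = "reverse"` threads against the reversed profile, covering
#' the possibility that the chain runs the other way along the path; the
#' pipeline always evaluates both directions and keeps both models.
#'
#' @param profile a [PathProfile-class].
#' @param sequence target protein sequence (single string or character
#'   vector of one-letter codes).
#' @param volumes residue volume table from [residueVolumes()].
#' @param gapOpen gap penalty (in squared-z units).
#' @param direction `"forward"` or `"reverse"`.
#' @param minSpacing,maxSpacing allowed consecutive-residue arc-length
#'   advance (Angstrom), bracketing the canonical 3.8 A virtual bond.
#' @param minFragment minimum number of residues that must be placed.
#' @return A [ThreadingAlignment-class].
#' @seealso [buildCaModel()]
#' @export
threadSequence <- function(profile, sequence, volumes = residueVolumes(),
                           gapOpen = 1.0, direction = c("forward", "reverse"),
                           minSpacing = 2.8, maxSpacing = 4.5,
                           minFragment = 3L) {
  direction <- match.arg(direction)
  stopifnot(is(profile, "PathProfile"))
  seqv <- if (length(sequence) == 1L && nchar(sequence[1L]) > 1L)
    strsplit(sequence, "")[[1L]] else as.character(sequence)
  if (!all(seqv %in% .AA20))
    stop("sequence contains non-standard residue codes")
  n <- length(seqv)
  zd <- profile@densities
  if (direction == "reverse") zd <- rev(zd)
  m <- length(zd)

  dmin <- max(1L, as.integer(ceiling(minSpacing / profile@step)))
  dmax <- as.integer(floor(maxSpacing / profile@step))
  if (dmax < dmin)
    stop("infeasible spacing constraints: no integer step between ",
         minSpacing, " and ", maxSpacing, " at step ", profile@step)

  zv <- attr(volumes, "z")[seqv]
  M <- outer(zv, zd, .threadMatch)              # n x m match scores

  # A[r, p]: best score of a placement whose last placed residue is r at
  # point p (terminal trimming of residues 1..r-1 charged when r starts).
  A <- sweep(M, 1L, gapOpen * (seq_len(n) - 1L), "-")  # start-of-chain option
  ptr <- matrix(0L, n, m)                       # 0 = start, else delta index
  if (n > 1L && m - 1L >= dmin) {
    deltas <- dmin:(m - 1L)
    pen <- .threadStepPenalty(deltas, dmin, dmax, gapOpen)
    for (r in 2:n) {
      startScore <- A[r, ]
      best <- rep(-Inf, m)
      arg <- integer(m)
      for (j in seq_along(deltas)) {
        dd <- deltas[j]
        if (dd >= m) break
        p <- (dd + 1L):m
        cand <- A[r - 1L, p - dd] + pen[j]
        upd <- cand > best[p] + 1e-15
        if (any(upd)) {
          best[p][upd] <- cand[upd]
          arg[p][upd] <- dd
        }
      }
      chain <- best + M[r, ]
      useStart <- startScore >= chain
      A[r, ] <- ifelse(useStart, startScore, chain)
      ptr[r, ] <- ifelse(useStart, 0L, arg)
    }
  }

  final <- sweep(A, 1L, gapOpen * (n - seq_len(n)), "-")
  bi <- which(final == max(final), arr.ind = TRUE)
  bi <- bi[order(bi[, 1L], bi[, 2L]), , drop = FALSE][1L, ]
  r <- bi[1L]; p <- bi[2L]
  score <- final[r, p]
  if (!is.finite(score)) stop("no feasible threading on this path")

  ptsIdx <- integer(0)
  resIdx <- integer(0)
  while (TRUE) {
    ptsIdx <- c(p, ptsIdx)
    resIdx <- c(r, resIdx)
    d <- ptr[r, p]
    if (d == 0L) break
    p <- p - d
    r <- r - 1L
  }
  if (length(resIdx) < minFragment)
    stop("no feasible threading: best placement covers only ",
         length(resIdx), " residue(s)")

  new("ThreadingAlignment", residues = as.integer(resIdx),
      pointIndex = as.integer(ptsIdx), direction = direction,
      score = as.numeric(score), nResidues = as.integer(n))
}

#' Build a C-alpha model from a threading alignment
#'
#' Places each assigned residue's C-alpha at its path point (in the
#' direction the alignment was threaded) and labels it with the target
#' sequence.
#'
#' @param alignment a [ThreadingAlignment-class].
#' @param profile the [PathProfile-class] the alignment refers to.
#' @param sequence the full target sequence (string or character vector).
#' @param provenance free-form parameter-set identifier stored on the
#'   model.
#' @return A [CaModel-class]; residue numbers are the target sequence
#'   positions (a contiguous block).
#' @export
buildCaModel <- function(alignment, profile, sequence, provenance = "") {
  stopifnot(is(alignment, "ThreadingAlignment"), is(profile, "PathProfile"))
  seqv <- if (length(sequence) == 1L && nchar(sequence[1L]) > 1L)
    strsplit(sequence, "")[[1L]] else as.character(sequence)
  pts <- profile@points
  if (alignment@direction == "reverse")
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  xyz <- pts[alignment@pointIndex, , drop = FALSE]
  s <- CaStructure(resno = alignment@residues,
                   aa = seqv[alignment@residues], xyz = xyz)
  new("CaModel", structure = s, threadingScore = alignment@score,
      direction = alignment@direction, provenance = provenance)
}
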