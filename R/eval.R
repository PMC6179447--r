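# Model-vs-reference C-alpha metrics: sequence-dependent RMSD and GDT-TS,
# and sequence-independent unlabeled RMSD, recall and precision. All
# defaults are frame-fixed (no superposition): models are built in the
# map's coordinate frame, the frame the reference was fitted in.

.asCa <- function(x) {
  if (is(x, "CaModel")) x@structure
  else if (is(x, "CaStructure")) x
  else stop("expected a CaModel or CaStructure")
}

.matchedPairs <- function(model, reference) {
  m <- .asCa(model); r <- .asCa(reference)
  shared <- intersect(m@resno, r@resno)
  if (length(shared) == 0L)
    stop("no residue numbers shared between model and reference")
  list(mx = m@xyz[match(shared, m@resno), , drop = FALSE],
       rx = r@xyz[match(shared, r@resno), , drop = FALSE],
       n = length(shared))
}

#' C-alpha RMSD over residue-matched pairs
#'
#' Root-mean-square deviation over C-alpha pairs matched by residue number.
#' By default computed in the fixed shared frame; `superpose = TRUE` first
#' finds the least-squares (Kabsch) superposition of the matched pairs.
#'
#' @param model,reference [CaModel-class] or [CaStructure-class] objects
#'   sharing at least one residue number.
#' @param superpose least-squares superpose before measuring.
#' @return RMSD in Angstrom.
#' @export
caRMSD <- function(model, reference, superpose = FALSE) {
  p <- .matchedPairs(model, reference)
  mx <- if (superpose) .kabschFit(p$mx, p$rx) else p$mx
  sqrt(mean(rowSums((mx - p$rx)^2)))
}

# least-squares superposition of 'mobile' onto 'fixed' via bio3d
.kabschFit <- function(mobile, fixed) {
  inds <- seq_len(3L * nrow(fixed))
  fit <- bio3d::fit.xyz(fixed = as.numeric(t(fixed)),
                        mobile = as.numeric(t(mobile)),
                        fixed.inds = inds, mobile.inds = inds)
  matrix(as.numeric(fit), ncol = 3L, byrow = TRUE)
}

#' GDT-TS over residue-matched pairs
#'
#' Mean over the cutoffs 1, 2, 4 and 8 Angstrom of the percentage of
#' reference C-alpha atoms whose residue-matched model atom lies within the
#' cutoff, in the fixed shared frame. Normalization is by the reference
#' length, so unmodeled residues count as misses (a partial-coverage model
#' cannot exceed its coverage fraction times 100).
#'
#' @inheritParams caRMSD
#' @param superpose least-squares superpose the matched pairs first.
#' @return GDT-TS score in 0..100.
#' @export
gdtTS <- function(model, reference, superpose = FALSE) {
  p <- .matchedPairs(model, reference)
  mx <- if (superpose) .kabschFit(p$mx, p$rx) else p$mx
  d <- sqrt(rowSums((mx - p$rx)^2))
  nRef <- length(.asCa(reference)@resno)
  mean(vapply(c(1, 2, 4, 8),
              function(cut) 100 * sum(d <= cut) / nRef, numeric(1)))
}

#' Unlabeled (nearest-neighbour) C-alpha RMSD
#'
#' RMSD between each model C-alpha and its nearest reference C-alpha,
#' ignoring sequence identity: a measure of trace geometry independent of
#' sequence register. Direction is model-to-reference by default;
#' `direction = "reference"` measures the other way.
#'
#' @inheritParams caRMSD
#' @param direction which set is scanned against the other.
#' @return RMSD in Angstrom.
#' @export
unlabeledRMSD <- function(model, reference,
                          direction = c("model", "reference")) {
  direction <- match.arg(direction)
  a <- .asCa(model)@xyz
  b <- .asCa(reference)@xyz
  if (direction == "reference") { tmp <- a; a <- b; b <- tmp }
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty structure")
  d2 <- .minCrossDist2(a, b)
  sqrt(mean(d2))
}

# squared distance from each row of a to its nearest row of b
.minCrossDist2 <- function(a, b) {
  cross <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  pmax(apply(cross, 1L, min), 0)
}

#' C-alpha recall and precision
#'
#' Recall: the fraction of reference C-alpha atoms closer than `threshold`
#' (strictly) to any model C-alpha. Precision: the same with the roles
#' swapped. The conventional thresholds are 2 and 3 Angstrom.
#'
#' @inheritParams caRMSD
#' @param threshold distance threshold in Angstrom.
#' @return Named numeric: `recall` and `precision`, each in `[0, 1]`.
#' @export
recallPrecision <- function(model, reference, threshold = 3.0) {
  a <- .asCa(model)@xyz
  b <- .asCa(reference)@xyz
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty structure")
  recall <- mean(sqrt(.minCrossDist2(b, a)) < threshold)
  precision <- mean(sqrt(.minCrossDist2(a, b)) < threshold)
  c(recall = recall, precision = precision)
}

#' All five model-quality metrics at once
#'
#' Aggregates [caRMSD()], [gdtTS()], [unlabeledRMSD()] and
#' [recallPrecision()] at the 2 and 3 Angstrom thresholds into an
#' [EvalReport-class], all in the fixed shared frame.
#'
#' @inheritParams caRMSD
#' @return An [EvalReport-class].
#' @export
evaluateModel <- function(model, reference) {
  m <- .asCa(model); r <- .asCa(reference)
  rp2 <- recallPrecision(model, reference, threshold = 2.0)
  rp3 <- recallPrecision(model, reference, threshold = 3.0)
  new("EvalReport",
      rmsd = caRMSD(model, reference),
      gdtTs = gdtTS(model, reference),
      unlabeledRmsd = unlabeledRMSD(model, reference),
      recall2 = unname(rp2["recall"]), recall3 = unname(rp3["recall"]),
      precision2 = unname(rp2["precision"]),
      precision3 = unname(rp3["precision"]),
      nModel = length(m@resno), nReference = length(r@resno))
}
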