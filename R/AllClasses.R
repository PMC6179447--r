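#' @import methods
NULL

#' The 20 standard amino acids, one-letter codes
#'
#' @keywords internal
#' @noRd
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' DensityGrid: a regular 3D scalar density field
#'
#' Container for a cryo-EM density map (or a simulated one): a 3D array of
#' density values on a regular orthogonal grid, with the world-coordinate
#' metadata needed to place every voxel in Angstroms. The world position of
#' 0-based voxel index (i, j, k) is `origin + voxelSize * c(i, j, k)`.
#'
#' @slot values 3D numeric array of density (map units, unscaled).
#' @slot origin numeric(3), world position (Angstrom) of voxel (0,0,0).
#' @slot voxelSize numeric(3), Angstrom per voxel along x, y, z; all > 0.
#' @slot contourLevel numeric(1), the recommended contour level in map
#'   units. Density thresholds downstream are expressed as fractions of it.
#'   May be `NA` for maps read from files that carry no such annotation.
#'
#' @seealso [readMap()], [writeMap()], [simulateMap()], [interpolateDensity()]
#' @export
setClass("DensityGrid",
         representation(values = "array",
                        origin = "numeric",
                        voxelSize = "numeric",
                        contourLevel = "numeric"))

setValidity("DensityGrid", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "'values' must be a 3D array with all dimensions >= 1")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be a finite numeric vector of length 3")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be 3 positive finite numbers")
  if (length(object@contourLevel) != 1L)
    msg <- c(msg, "'contourLevel' must be a single number (may be NA)")
  if (length(msg)) msg else TRUE
})

#' Construct a DensityGrid
#'
#' @param values 3D numeric array of density values.
#' @param origin world position (Angstrom) of voxel (0,0,0).
#' @param voxelSize Angstrom per voxel along each axis (recycled from
#'   length 1).
#' @param contourLevel recommended contour level (map units), or `NA`.
#' @return A [DensityGrid-class] object.
#' @examples
#' g <- DensityGrid(array(0, c(4, 4, 4)), origin = c(0, 0, 0), voxelSize = 1)
#' @export
DensityGrid <- function(values, origin = c(0, 0, 0), voxelSize = c(1, 1, 1),
                        contourLevel = NA_real_) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("DensityGrid", values = values, origin = as.numeric(origin),
      voxelSize = as.numeric(voxelSize),
      contourLevel = as.numeric(contourLevel))
}

#' CaStructure: an ordered C-alpha trace
#'
#' An ordered list of residues, each a 1-based residue number, a one-letter
#' amino-acid code, and a 3D position in Angstroms. Used both for reference
#' structures read from PDB files and for fixture backbones.
#'
#' @slot resno integer vector, strictly increasing residue numbers.
#' @slot aa character vector of one-letter amino-acid codes (standard 20).
#' @slot xyz n x 3 numeric matrix of C-alpha coordinates (Angstrom).
#'
#' @seealso [readCaStructure()], [writeCaModel()], [makeHelix()]
#' @export
setClass("CaStructure",
         representation(resno = "integer", aa = "character", xyz = "matrix"))

setValidity("CaStructure", function(object) {
  n <- length(object@resno)
  msg <- character()
  if (length(object@aa) != n)
    msg <- c(msg, "'aa' and 'resno' lengths differ")
  if (!is.numeric(object@xyz) || nrow(object@xyz) != n || ncol(object@xyz) != 3L)
    msg <- c(msg, "'xyz' must be an n x 3 numeric matrix matching 'resno'")
  if (n > 1L && any(diff(object@resno) <= 0L))
    msg <- c(msg, "residue numbers must be strictly increasing")
  if (n > 0L && !all(object@aa %in% .AA20))
    msg <- c(msg, "amino-acid codes must be among the 20 standard one-letter codes")
  if (length(msg)) msg else TRUE
})

#' Construct a CaStructure
#'
#' @param resno residue numbers (strictly increasing integers).
#' @param aa one-letter amino-acid codes.
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @return A [CaStructure-class] object.
#' @export
CaStructure <- function(resno, aa, xyz) {
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- NULL
  new("CaStructure", resno = as.integer(resno), aa = as.character(aa),
      xyz = xyz)
}

#' PointGraph: proximity graph over local dense points
#'
#' Undirected weighted graph whose nodes are LDPs (local dense points) and
#' whose edges connect every pair of points within `cutoff` Angstrom, with
#' the Euclidean distance as edge weight.
#'
#' @slot positions m x 3 matrix of node positions (Angstrom).
#' @slot edges e x 2 integer matrix of node index pairs (i < j).
#' @slot weights numeric vector of edge lengths (Angstrom), all > 0.
#' @slot cutoff numeric(1), the distance cutoff used to build the graph.
#'
#' @seealso [buildGraph()], [minimumSpanningTree()]
#' @export
setClass("PointGraph",
         representation(positions = "matrix", edges = "matrix",
                        weights = "numeric", cutoff = "numeric"))

setValidity("PointGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (ncol(object@positions) != 3L)
    msg <- c(msg, "'positions' must have 3 columns")
  if (nrow(e) != length(object@weights))
    msg <- c(msg, "'edges' and 'weights' lengths differ")
  if (nrow(e) > 0L) {
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    if (any(e < 1L) || any(e > nrow(object@positions)))
      msg <- c(msg, "edge endpoints out of range")
    if (any(object@weights <= 0)) msg <- c(msg, "edge weights must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' SpanningTree: a spanning tree over a PointGraph component
#'
#' A spanning tree of the largest connected component of its parent
#' [PointGraph-class], scored by the sum of the lengths of the top-K longest
#' leaf-to-leaf paths (the objective maximized by [tabuRefine()]).
#'
#' @slot graph the parent PointGraph.
#' @slot treeEdges integer vector of indices into the parent graph's edge
#'   list; exactly `length(nodes) - 1` of them, acyclic.
#' @slot nodes integer vector, node indices of the spanned component.
#' @slot score numeric(1), sum of top-K leaf-pair path lengths (Angstrom).
#' @slot topK integer(1), the K used for the score.
#' @slot history numeric vector, best-so-far score after each refinement
#'   iteration (empty for a freshly built MST).
#'
#' @seealso [minimumSpanningTree()], [tabuRefine()], [longestPath()]
#' @export
setClass("SpanningTree",
         representation(graph = "PointGraph", treeEdges = "integer",
                        nodes = "integer", score = "numeric",
                        topK = "integer", history = "numeric"))

setValidity("SpanningTree", function(object) {
  msg <- character()
  if (length(object@treeEdges) != length(object@nodes) - 1L)
    msg <- c(msg, "a spanning tree must have |nodes| - 1 edges")
  if (length(object@treeEdges) &&
      (any(object@treeEdges < 1L) ||
       any(object@treeEdges > nrow(object@graph@edges))))
    msg <- c(msg, "tree edge indices out of range")
  if (length(msg)) msg else TRUE
})

#' PathProfile: a path resampled at fixed arc-length steps
#'
#' The longest tree path, resampled every `step` Angstrom of arc length,
#' with the map density interpolated (and smoothed along the arc) at each
#' sample, z-normalized over the path.
#'
#' @slot points p x 3 matrix of sample positions (Angstrom).
#' @slot arc numeric vector of arc-length positions (Angstrom) of the
#'   samples; consecutive values are `step` apart (last may be closer).
#' @slot densities numeric vector of z-normalized densities per sample.
#' @slot rawDensities numeric vector of smoothed (pre-normalization)
#'   densities.
#' @slot step numeric(1), the resampling step (Angstrom).
#'
#' @seealso [resamplePath()], [threadSequence()]
#' @export
setClass("PathProfile",
         representation(points = "matrix", arc = "numeric",
                        densities = "numeric", rawDensities = "numeric",
                        step = "numeric"))

setValidity("PathProfile", function(object) {
  msg <- character()
  n <- nrow(object@points)
  if (length(object@arc) != n || length(object@densities) != n)
    msg <- c(msg, "'arc' and 'densities' must match the number of points")
  if (any(!is.finite(object@densities)))
    msg <- c(msg, "densities must be finite")
  if (length(msg)) msg else TRUE
})

#' ThreadingAlignment: a sequence-to-path assignment
#'
#' The result of the threading dynamic program: a contiguous block of target
#' residues assigned to strictly increasing path points, in one direction.
#'
#' @slot residues integer vector of target sequence positions placed
#'   (contiguous, increasing).
#' @slot pointIndex integer vector, for each placed residue the index of the
#'   path point it occupies (strictly increasing, in threading direction).
#' @slot direction `"forward"` or `"reverse"`.
#' @slot score numeric(1), the threading score (higher is better).
#' @slot nResidues integer(1), length of the full target sequence.
#'
#' @seealso [threadSequence()], [buildCaModel()]
#' @export
setClass("ThreadingAlignment",
         representation(residues = "integer", pointIndex = "integer",
                        direction = "character", score = "numeric",
                        nResidues = "integer"))

setValidity("ThreadingAlignment", function(object) {
  msg <- character()
  if (length(object@residues) != length(object@pointIndex))
    msg <- c(msg, "'residues' and 'pointIndex' lengths differ")
  if (length(object@residues) > 1L) {
    if (any(diff(object@residues) != 1L))
      msg <- c(msg, "placed residues must be contiguous")
    if (any(diff(object@pointIndex) <= 0L))
      msg <- c(msg, "path-point indices must be strictly increasing")
  }
  if (!object@direction %in% c("forward", "reverse"))
    msg <- c(msg, "direction must be 'forward' or 'reverse'")
  if (length(msg)) msg else TRUE
})

#' CaModel: a threaded C-alpha model
#'
#' A [CaStructure-class] labeled with the target-sequence residues it
#' covers, plus the threading score used to rank models and a provenance
#' tag recording the parameter combination that produced it.
#'
#' @slot structure the C-alpha trace as a CaStructure.
#' @slot threadingScore numeric(1), the threading DP score.
#' @slot direction `"forward"` or `"reverse"` threading direction.
#' @slot provenance character(1), parameter-set identifier.
#'
#' @seealso [buildCaModel()], [runSweep()], [writeCaModel()]
#' @export
setClass("CaModel",
         representation(structure = "CaStructure",
                        threadingScore = "numeric",
                        direction = "character",
                        provenance = "character"))

#' ModelEnsemble: ranked candidate models from a parameter sweep
#'
#' @slot models list of [CaModel-class], sorted by threading score
#'   descending (ties broken by provenance).
#' @slot config the sweep configuration list used (see [sweepConfig()]).
#'
#' @seealso [runSweep()], [confidenceProfile()]
#' @export
setClass("ModelEnsemble",
         representation(models = "list", config = "list"))

setValidity("ModelEnsemble", function(object) {
  if (!all(vapply(object@models, is, logical(1), class2 = "CaModel")))
    return("all elements of 'models' must be CaModel objects")
  sc <- vapply(object@models, function(m) m@threadingScore, numeric(1))
  if (length(sc) > 1L && any(diff(sc) > 1e-9))
    return("models must be sorted by threading score, descending")
  TRUE
})

#' EvalReport: model-vs-reference metric bundle
#'
#' The five C-alpha model quality metrics computed against a reference
#' structure in a shared coordinate frame: sequence-dependent RMSD and
#' GDT-TS, and sequence-independent unlabeled RMSD, recall and precision at
#' 2 and 3 Angstrom.
#'
#' @slot rmsd numeric(1), C-alpha RMSD over residue-matched pairs (Angstrom).
#' @slot gdtTs numeric(1), GDT-TS in 0..100.
#' @slot unlabeledRmsd numeric(1), nearest-neighbour RMSD, model to
#'   reference (Angstrom).
#' @slot recall2,recall3 fraction of reference C-alphas closer than 2/3
#'   Angstrom to any model C-alpha.
#' @slot precision2,precision3 fraction of model C-alphas closer than 2/3
#'   Angstrom to any reference C-alpha.
#' @slot nModel,nReference integer, sizes of the two C-alpha sets.
#'
#' @seealso [evaluateModel()]
#' @export
setClass("EvalReport",
         representation(rmsd = "numeric", gdtTs = "numeric",
                        unlabeledRmsd = "numeric",
                        recall2 = "numeric", recall3 = "numeric",
                        precision2 = "numeric", precision3 = "numeric",
                        nModel = "integer", nReference = "integer"))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (!is.na(object@gdtTs) && (object@gdtTs < 0 || object@gdtTs > 100))
    msg <- c(msg, "gdtTs must be in [0, 100]")
  fr <- c(object@recall2, object@recall3, object@precision2, object@precision3)
  if (any(!is.na(fr) & (fr < 0 | fr > 1)))
    msg <- c(msg, "recall/precision must be in [0, 1]")
  if (length(msg)) msg else TRUE
})
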