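#' Accessors for catracer classes
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @return `gridValues`: the 3D density array.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname accessors
#' @return `gridOrigin`: numeric(3) world origin (Angstrom).
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @return `voxelSize`: numeric(3) Angstrom per voxel.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @return `contourLevel`: the recommended contour level (map units).
#' @export
setGeneric("contourLevel", function(x) standardGeneric("contourLevel"))

#' @rdname accessors
#' @return `caPositions`: n x 3 matrix of C-alpha coordinates.
#' @export
setGeneric("caPositions", function(x) standardGeneric("caPositions"))

#' @rdname accessors
#' @return `residueNumbers`: integer vector of residue numbers.
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))

#' @rdname accessors
#' @return `caSequence`: character vector of one-letter codes.
#' @export
setGeneric("caSequence", function(x) standardGeneric("caSequence"))

#' @rdname accessors
#' @return `nResidues`: number of residues.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @return `treeScore`: the top-K path-length score of a tree.
#' @export
setGeneric("treeScore", function(x) standardGeneric("treeScore"))

#' @rdname accessors
#' @return `treeEdgeMatrix`: e x 2 matrix of node indices of tree edges.
#' @export
setGeneric("treeEdgeMatrix", function(x) standardGeneric("treeEdgeMatrix"))

#' @rdname accessors
#' @return `threadingScore`: the threading DP score of a model.
#' @export
setGeneric("threadingScore", function(x) standardGeneric("threadingScore"))

#' @rdname accessors
#' @return `provenance`: parameter-set identifier of a model.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @return `models`: list of CaModel in an ensemble.
#' @export
setGeneric("models", function(x) standardGeneric("models"))

#' @rdname accessors
#' @export
setMethod("gridValues", "DensityGrid", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("gridOrigin", "DensityGrid", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("voxelSize", "DensityGrid", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("contourLevel", "DensityGrid", function(x) x@contourLevel)

#' @rdname accessors
#' @export
setMethod("caPositions", "CaStructure", function(x) x@xyz)

#' @rdname accessors
#' @export
setMethod("caPositions", "CaModel", function(x) x@structure@xyz)

#' @rdname accessors
#' @export
setMethod("residueNumbers", "CaStructure", function(x) x@resno)

#' @rdname accessors
#' @export
setMethod("residueNumbers", "CaModel", function(x) x@structure@resno)

#' @rdname accessors
#' @export
setMethod("caSequence", "CaStructure", function(x) x@aa)

#' @rdname accessors
#' @export
setMethod("caSequence", "CaModel", function(x) x@structure@aa)

#' @rdname accessors
#' @export
setMethod("nResidues", "CaStructure", function(x) length(x@resno))

#' @rdname accessors
#' @export
setMethod("nResidues", "CaModel", function(x) length(x@structure@resno))

#' @rdname accessors
#' @export
setMethod("treeScore", "SpanningTree", function(x) x@score)

#' @rdname accessors
#' @export
setMethod("treeEdgeMatrix", "SpanningTree",
          function(x) x@graph@edges[x@treeEdges, , drop = FALSE])

#' @rdname accessors
#' @export
setMethod("threadingScore", "CaModel", function(x) x@threadingScore)

#' @rdname accessors
#' @export
setMethod("provenance", "CaModel", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("models", "ModelEnsemble", function(x) x@models)

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityGrid: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel size (A): %s\n",
              paste(format(object@voxelSize, digits = 4), collapse = " x ")))
  cat(sprintf("  origin (A):     %s\n",
              paste(format(object@origin, digits = 4), collapse = ", ")))
  cat(sprintf("  density range:  [%.4g, %.4g], contour level %.4g\n",
              min(object@values), max(object@values), object@contourLevel))
})

setMethod("show", "CaStructure", function(object) {
  n <- length(object@resno)
  cat(sprintf("CaStructure: %d residues", n))
  if (n > 0L)
    cat(sprintf(" (%d-%d)", object@resno[1L], object@resno[n]))
  cat("\n")
  if (n > 0L)
    cat("  sequence:", paste(object@aa, collapse = ""), "\n")
})

setMethod("show", "PointGraph", function(object) {
  cat(sprintf("PointGraph: %d nodes, %d edges (cutoff %.2f A)\n",
              nrow(object@positions), nrow(object@edges), object@cutoff))
})

setMethod("show", "SpanningTree", function(object) {
  cat(sprintf("SpanningTree: %d nodes, %d edges, top-%d path score %.2f A\n",
              length(object@nodes), length(object@treeEdges),
              object@topK, object@score))
})

setMethod("show", "CaModel", function(object) {
  cat(sprintf("CaModel: %d residues, %s threading, score %.4f [%s]\n",
              length(object@structure@resno), object@direction,
              object@threadingScore, object@provenance))
})

setMethod("show", "ModelEnsemble", function(object) {
  cat(sprintf("ModelEnsemble: %d models\n", length(object@models)))
  if (length(object@models)) {
    sc <- vapply(object@models, function(m) m@threadingScore, numeric(1))
    cat(sprintf("  threading scores: best %.4f, worst %.4f\n",
                sc[1L], sc[length(sc)]))
  }
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (C-alpha model vs reference)\n")
  cat(sprintf("  RMSD:           %.3f A\n", object@rmsd))
  cat(sprintf("  GDT-TS:         %.1f\n", object@gdtTs))
  cat(sprintf("  unlabeled RMSD: %.3f A\n", object@unlabeledRmsd))
  cat(sprintf("  recall    (<2 / <3 A): %.3f / %.3f\n",
              object@recall2, object@recall3))
  cat(sprintf("  precision (<2 / <3 A): %.3f / %.3f\n",
              object@precision2, object@precision3))
  cat(sprintf("  n model / reference: %d / %d\n",
              object@nModel, object@nReference))
})
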