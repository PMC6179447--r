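# Proximity graph over LDPs, minimum spanning tree, top-K longest-path tree
# score, and tabu-search refinement.
#
# A tree is scored by the sum of the lengths of its top-K longest paths
# (K = 100 by default). Paths in a tree are determined by their endpoint
# pair, and any path with an interior endpoint is a sub-path of a
# leaf-to-leaf path, so the ranking is taken over leaf pairs.

#' Tabu-search parameters
#'
#' @param nIterations number of tabu iterations.
#' @param tabuTenure number of recent moves whose edges stay forbidden.
#' @param topK number of longest paths summed into the tree score.
#' @param rngSeed integer seed controlling candidate-move sampling; the
#'   whole refinement is reproducible bit-for-bit given the seed.
#' @param moveBudget maximum number of candidate moves evaluated per
#'   iteration; larger neighbourhoods are sampled uniformly.
#' @return A validated parameter list for [tabuRefine()].
#' @export
tabuParams <- function(nIterations = 100L, tabuTenure = 20L, topK = 100L,
                       rngSeed = 1L, moveBudget = 500L) {
  stopifnot(nIterations >= 0, tabuTenure >= 1, topK >= 1, moveBudget >= 1)
  list(nIterations = as.integer(nIterations),
       tabuTenure = as.integer(tabuTenure), topK = as.integer(topK),
       rngSeed = as.integer(rngSeed), moveBudget = as.integer(moveBudget))
}

#' Build the LDP proximity graph
#'
#' Connects every pair of points within `edgeCutoff` Angstrom; edge weight
#' is the Euclidean distance. The default cutoff (5 Angstrom) sits just
#' above the canonical 3.8 Angstrom C-alpha spacing.
#'
#' @param ldps a `data.frame` from [detectLdps()] (columns `x`, `y`, `z`),
#'   or an m x 3 position matrix.
#' @param edgeCutoff distance cutoff in Angstrom.
#' @return A [PointGraph-class].
#' @seealso [minimumSpanningTree()]
#' @export
buildGraph <- function(ldps, edgeCutoff = 5.0) {
  pos <- if (is.data.frame(ldps)) as.matrix(ldps[, c("x", "y", "z")]) else as.matrix(ldps)
  dimnames(pos) <- NULL
  if (nrow(pos) < 2L) stop("need at least 2 points to build a graph")
  D <- as.matrix(stats::dist(pos))
  sel <- which(upper.tri(D) & D <= edgeCutoff & D > 0, arr.ind = TRUE)
  edges <- cbind(sel[, 1L], sel[, 2L])
  pg <- new("PointGraph", positions = pos,
            edges = matrix(as.integer(edges), ncol = 2L),
            weights = D[sel], cutoff = edgeCutoff)
  comp <- .graphComponents(pg)
  if (max(tabulate(comp)) < 2L)
    stop("fewer than 2 nodes in the largest connected component; ",
         "increase edgeCutoff")
  pg
}

.pgIgraph <- function(pg, edgeIdx = seq_len(nrow(pg@edges))) {
  g <- igraph::make_graph(t(pg@edges[edgeIdx, , drop = FALSE]),
                          n = nrow(pg@positions), directed = FALSE)
  igraph::E(g)$weight <- pg@weights[edgeIdx]
  igraph::E(g)$id <- edgeIdx
  g
}

.graphComponents <- function(pg) {
  igraph::components(.pgIgraph(pg))$membership
}

.leafPairLengths <- function(pg, treeEdges) {
  g <- .pgIgraph(pg, treeEdges)
  deg <- igraph::degree(g)
  leaves <- which(deg == 1L)
  if (length(leaves) < 2L) return(numeric(0))
  D <- igraph::distances(g, v = leaves, to = leaves)
  sort(D[upper.tri(D)], decreasing = TRUE)
}

.treeScore <- function(pg, treeEdges, k) {
  len <- .leafPairLengths(pg, treeEdges)
  sum(utils::head(len, k))
}

#' Minimum spanning tree of the largest component
#'
#' @param graph a [PointGraph-class].
#' @param topK number of longest paths summed into the tree score.
#' @return A [SpanningTree-class] spanning the largest connected component
#'   of `graph`, minimal in total edge weight.
#' @seealso [buildGraph()], [tabuRefine()], [longestPath()]
#' @export
minimumSpanningTree <- function(graph, topK = 100L) {
  stopifnot(is(graph, "PointGraph"))
  g <- .pgIgraph(graph)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  nodes <- which(comp$membership == big)
  if (length(nodes) < 2L)
    stop("largest connected component has fewer than 2 nodes")
  mstg <- igraph::mst(g, weights = igraph::E(g)$weight)
  ids <- igraph::E(mstg)$id
  ends <- graph@edges[ids, , drop = FALSE]
  keep <- ends[, 1L] %in% nodes
  treeEdges <- sort(as.integer(ids[keep]))
  new("SpanningTree", graph = graph, treeEdges = treeEdges,
      nodes = as.integer(nodes),
      score = .treeScore(graph, treeEdges, topK),
      topK = as.integer(topK), history = numeric(0))
}

#' Top-K longest path lengths in a tree
#'
#' Lengths (sums of edge weights) of the paths between every pair of leaf
#' nodes, largest first, truncated to `k`. Their sum is the tree score that
#' [tabuRefine()] maximizes.
#'
#' @param tree a [SpanningTree-class].
#' @param k number of paths to return (all, if fewer exist).
#' @return Numeric vector of path lengths, descending.
#' @export
topKPathLengths <- function(tree, k = tree@topK) {
  stopifnot(is(tree, "SpanningTree"))
  utils::head(.leafPairLengths(tree@graph, tree@treeEdges), k)
}

#' Longest path in a tree
#'
#' The leaf-to-leaf path of maximal summed edge weight (the weighted tree
#' diameter). Ties are broken toward the lexicographically smallest
#' endpoint index pair.
#'
#' @param tree a [SpanningTree-class].
#' @return Integer vector of node indices along the path; the node
#'   positions are `tree@graph@positions[result, ]`. The path length in
#'   Angstrom is attached as attribute `"length"`.
#' @seealso [resamplePath()]
#' @export
longestPath <- function(tree) {
  stopifnot(is(tree, "SpanningTree"))
  g <- .pgIgraph(tree@graph, tree@treeEdges)
  deg <- igraph::degree(g)
  leaves <- which(deg == 1L)
  if (length(leaves) < 2L) stop("tree has fewer than 2 leaves")
  D <- igraph::distances(g, v = leaves, to = leaves)
  best <- max(D[upper.tri(D)])
  idx <- which(D == best & upper.tri(D), arr.ind = TRUE)
  pair <- cbind(pmin(leaves[idx[, 1L]], leaves[idx[, 2L]]),
                pmax(leaves[idx[, 1L]], leaves[idx[, 2L]]))
  o <- order(pair[, 1L], pair[, 2L])[1L]
  from <- pair[o, 1L]; to <- pair[o, 2L]
  p <- igraph::shortest_paths(g, from = from, to = to, output = "vpath")
  path <- as.integer(p$vpath[[1L]])
  attr(path, "length") <- best
  path
}

# Membership split of the tree after removing tree edge 'dropIdx' (an index
# into treeEdges); returns logical vector over nodes: TRUE for the side
# containing the dropped edge's first endpoint.
.splitMembership <- function(pg, treeEdges, dropIdx) {
  rest <- treeEdges[-dropIdx]
  g <- .pgIgraph(pg, rest)
  memb <- igraph::components(g)$membership
  memb == memb[pg@edges[treeEdges[dropIdx], 1L]]
}

#' Tabu-search refinement of a spanning tree
#'
#' Local search over spanning trees of the parent graph's largest
#' component, maximizing the top-K path-length score. Each iteration
#' enumerates (delete tree edge, add reconnecting non-tree edge) moves,
#' evaluates up to `moveBudget` of them (sampling uniformly with the seeded
#' RNG when the neighbourhood is larger), and applies the best admissible
#' move even when it worsens the score. Edges touched by the last
#' `tabuTenure` moves are forbidden, except for moves that beat the best
#' score seen so far (aspiration). The best-scoring tree ever visited is
#' returned; its `history` slot records the best-so-far score after each
#' iteration (non-decreasing by construction).
#'
#' @param tree a [SpanningTree-class] (typically from
#'   [minimumSpanningTree()]).
#' @param params a list from [tabuParams()].
#' @return A [SpanningTree-class] with score >= the input's score.
#' @export
tabuRefine <- function(tree, params = tabuParams()) {
  stopifnot(is(tree, "SpanningTree"))
  pg <- tree@graph
  k <- params$topK
  E <- pg@edges
  inComp <- logical(nrow(pg@positions))
  inComp[tree@nodes] <- TRUE
  compEdges <- which(inComp[E[, 1L]] & inComp[E[, 2L]])
  if (params$nIterations == 0L ||
      length(compEdges) <= length(tree@treeEdges))
    return(tree)

  # seed-controlled sampling without touching the caller's RNG stream
  haveSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (haveSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (haveSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(params$rngSeed)

  T <- tree@treeEdges
  curScore <- .treeScore(pg, T, k)
  bestT <- T
  bestScore <- curScore
  tabu <- integer(0)                 # edge ids of the last 'tenure' moves
  history <- numeric(0)

  for (it in seq_len(params$nIterations)) {
    # full neighbourhood: (position in T to delete, edge id to add)
    cand <- vector("list", length(T))
    for (ti in seq_along(T)) {
      sideA <- .splitMembership(pg, T, ti)
      cross <- compEdges[xor(sideA[E[compEdges, 1L]],
                             sideA[E[compEdges, 2L]])]
      cross <- setdiff(cross, T)
      if (length(cross))
        cand[[ti]] <- cbind(ti, cross)
    }
    moves <- do.call(rbind, cand)
    if (is.null(moves) || nrow(moves) == 0L) break
    if (nrow(moves) > params$moveBudget)
      moves <- moves[sample.int(nrow(moves), params$moveBudget), , drop = FALSE]

    scores <- vapply(seq_len(nrow(moves)), function(mi) {
      Tn <- T
      Tn[moves[mi, 1L]] <- moves[mi, 2L]
      .treeScore(pg, Tn, k)
    }, numeric(1))

    isTabu <- (T[moves[, 1L]] %in% tabu) | (moves[, 2L] %in% tabu)
    admissible <- !isTabu | scores > bestScore + 1e-12
    if (!any(admissible)) admissible <- rep(TRUE, nrow(moves))

    ord <- order(-scores, T[moves[, 1L]], moves[, 2L])
    pick <- ord[admissible[ord]][1L]

    deleted <- T[moves[pick, 1L]]
    added <- moves[pick, 2L]
    T[moves[pick, 1L]] <- added
    T <- sort(T)
    curScore <- scores[pick]
    tabu <- c(tabu, deleted, added)
    if (length(tabu) > 2L * params$tabuTenure)
      tabu <- tabu[(length(tabu) - 2L * params$tabuTenure + 1L):length(tabu)]

    if (curScore > bestScore) {
      bestScore <- curScore
      bestT <- T
    }
    history <- c(history, bestScore)
  }

  new("SpanningTree", graph = pg, treeEdges = as.integer(sort(bestT)),
      nodes = tree@nodes, score = bestScore, topK = as.integer(k),
      history = history)
}
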