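# Independent oracles and small constructors shared across the tests. The
# oracles are deliberately written from first principles (exhaustive
# enumeration, direct recursion) and never call the package code paths they
# are used to check.

# ---- labelled trees via Pruefer sequences --------------------------------

pruferDecode <- function(pr, n) {
  if (n == 2L) return(matrix(c(1L, 2L), 1L, 2L))
  deg <- tabulate(pr, n) + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_along(pr)) {
    leaf <- which.max(deg == 1L)          # smallest index with degree 1
    edges[k, ] <- c(leaf, pr[k])
    deg[leaf] <- 0L
    deg[pr[k]] <- deg[pr[k]] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

.treeCache <- new.env(parent = emptyenv())

# every labelled tree on n nodes, as a list of (n-1) x 2 edge matrices
allLabelledTrees <- function(n) {
  key <- as.character(n)
  if (!is.null(.treeCache[[key]])) return(.treeCache[[key]])
  trees <- if (n == 2L) {
    list(matrix(c(1L, 2L), 1L, 2L))
  } else {
    prs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
    lapply(seq_len(nrow(prs)), function(i) pruferDecode(prs[i, ], n))
  }
  .treeCache[[key]] <- trees
  trees
}

# minimum spanning weight by exhaustive enumeration; W is a full symmetric
# weight matrix with NA marking absent edges
oracleMinSpanningWeight <- function(W) {
  n <- nrow(W)
  best <- Inf
  for (e in allLabelledTrees(n)) {
    w <- sum(W[cbind(e[, 1L], e[, 2L])])
    if (!is.na(w) && w < best) best <- w
  }
  best
}

# ---- leaf-pair path lengths by direct DFS --------------------------------

oracleLeafPathLengths <- function(edges, weights, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    adj[[i]] <- rbind(adj[[i]], c(j, weights[k]))
    adj[[j]] <- rbind(adj[[j]], c(i, weights[k]))
  }
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), integer(1))
  leaves <- which(deg == 1L)
  pathLen <- function(cur, target, prev, acc) {
    if (cur == target) return(acc)
    a <- adj[[cur]]
    for (r in seq_len(nrow(a))) {
      if (a[r, 1L] != prev) {
        res <- pathLen(a[r, 1L], target, cur, acc + a[r, 2L])
        if (!is.na(res)) return(res)
      }
    }
    NA_real_
  }
  lens <- numeric(0)
  if (length(leaves) >= 2L)
    for (i in seq_len(length(leaves) - 1L))
      for (j in (i + 1L):length(leaves))
        lens <- c(lens, pathLen(leaves[i], leaves[j], 0L, 0))
  sort(lens, decreasing = TRUE)
}

# best achievable top-k objective over all spanning trees of the graph
# whose weights are in W (NA = absent edge)
oracleBestTopK <- function(W, k) {
  n <- nrow(W)
  best <- -Inf
  for (e in allLabelledTrees(n)) {
    w <- W[cbind(e[, 1L], e[, 2L])]
    if (anyNA(w)) next
    sc <- sum(head(oracleLeafPathLengths(e, w, n), k))
    if (sc > best) best <- sc
  }
  best
}

# ---- threading score by exhaustive enumeration --------------------------

# all placements of a contiguous residue block on strictly increasing
# points; same scoring rule as the DP, written as direct recursion
oracleThreadScore <- function(zd, zv, gapOpen, dmin, dmax) {
  zv <- unname(zv)
  n <- length(zv); m <- length(zd)
  best <- -Inf
  rec <- function(r, p, acc) {
    sc <- acc - gapOpen * (n - r)
    if (sc > best) best <<- sc
    if (r < n && p + dmin <= m) {
      for (q in (p + dmin):m) {
        dd <- q - p
        pen <- if (dd <= dmax) 0 else gapOpen * ceiling((dd - dmax) / dmax)
        rec(r + 1L, q, acc - (zd[q] - zv[r + 1L])^2 - pen)
      }
    }
  }
  for (s in seq_len(n)) for (p in seq_len(m))
    rec(s, p, -(zd[p] - zv[s])^2 - gapOpen * (s - 1L))
  best
}

# ---- constructors --------------------------------------------------------

# a SpanningTree over the complete geometric graph on 'pos' whose tree
# edges are the rows of 'edges'
mkTree <- function(pos, edges, k = 100L) {
  pg <- buildGraph(pos, edgeCutoff = 1e6)
  idx <- vapply(seq_len(nrow(edges)), function(r) {
    i <- min(edges[r, ]); j <- max(edges[r, ])
    which(pg@edges[, 1L] == i & pg@edges[, 2L] == j)
  }, integer(1))
  new("SpanningTree", graph = pg, treeEdges = as.integer(sort(idx)),
      nodes = seq_len(nrow(pos)), score = 0, topK = as.integer(k),
      history = numeric(0))
}

# a PathProfile with prescribed (already normalized) densities on a
# straight line, step 1 A
mkProfile <- function(zd, step = 1) {
  m <- length(zd)
  pts <- cbind(seq_len(m) * step, 0, 0)
  new("PathProfile", points = pts, arc = (seq_len(m) - 1) * step,
      densities = zd, rawDensities = zd, step = step)
}

mkModel <- function(xyz, score = 0, resno = seq_len(nrow(xyz)),
                    aa = rep("A", nrow(xyz)), direction = "forward",
                    provenance = "test") {
  new("CaModel",
      structure = CaStructure(resno = resno, aa = aa, xyz = xyz),
      threadingScore = score, direction = direction,
      provenance = provenance)
}

mkEnsemble <- function(models) {
  sc <- vapply(models, function(m) m@threadingScore, numeric(1))
  new("ModelEnsemble", models = models[order(-sc)], config = list())
}

# float32-representable random values (8 fractional bits)
f32vals <- function(n) round(runif(n) * 256) / 256

# low-level MRC writer used to craft headers the package writer never
# produces (permuted axes, non-orthogonal cells); independent of writeMap
writeRawMrc <- function(path, valuesCrs, mapcrs, voxel, origin,
                        cellAngles = c(90, 90, 90)) {
  dcrs <- dim(valuesCrs)
  dAxis <- integer(3)
  dAxis[mapcrs] <- dcrs          # axis extents from crs extents
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(dcrs); wi(2L); wi(c(0L, 0L, 0L)); wi(dAxis)
  wf(dAxis * voxel); wf(cellAngles)
  wi(mapcrs)
  wf(c(min(valuesCrs), max(valuesCrs), mean(valuesCrs)))
  wi(1L); wi(0L); wi(integer(25L))
  wf(origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
  wf(sd(valuesCrs)); wi(0L)
  writeBin(raw(800L), con)
  wf(as.numeric(valuesCrs))
  invisible(path)
}

# hand-formatted C-alpha PDB line (for fixtures with altloc etc.)
pdbCaLine <- function(serial, resid, chain, resno, x, y, z, alt = " ",
                      occ = 1, b = 0) {
  sprintf("ATOM  %5d  CA %s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, alt, resid, chain, resno, x, y, z, occ, b)
}

# one varied 30-residue sequence used by the pipeline-level tests
helix30seq <- function() "MKTAYIAKQRQISFVKSHFSRQLEERLGLI"
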