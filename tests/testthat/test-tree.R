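# Proximity graph, MST, top-K path score, longest path, tabu refinement.

test_that("proximity graph edges follow the cutoff", {
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0))
  expect_identical(nrow(buildGraph(pts, 3)@edges), 2L)
  expect_identical(nrow(buildGraph(pts, 5)@edges), 3L)
  expect_error(buildGraph(pts[1, , drop = FALSE], 3), "at least 2")
  expect_error(buildGraph(rbind(c(0, 0, 0), c(10, 0, 0)), 3), "component")
})

test_that("graph edges equal a brute-force pair scan", {
  set.seed(13)
  pts <- matrix(runif(60, 0, 10), 20, 3)
  pg <- buildGraph(pts, 4)
  manual <- NULL
  for (i in 1:19) for (j in (i + 1):20) {
    if (sqrt(sum((pts[i, ] - pts[j, ])^2)) <= 4)
      manual <- rbind(manual, c(i, j))
  }
  expect_identical(pg@edges[order(pg@edges[, 1], pg@edges[, 2]), ],
                   matrix(as.integer(manual), ncol = 2))
})

test_that("MST keeps the short sides of a triangle and fixes trees", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(-0.125, 0.9921567, 0))
  pg <- buildGraph(pts, 10)
  mst <- minimumSpanningTree(pg)
  expect_equal(sum(pg@weights[mst@treeEdges]), 2, tolerance = 1e-6)
  # a path-shaped graph is its own MST
  path <- cbind(seq(0, 15, by = 3.8), 0, 0)
  pgp <- buildGraph(path, 4)
  mstp <- minimumSpanningTree(pgp)
  expect_identical(sort(mstp@treeEdges), seq_len(nrow(pgp@edges)))
})

test_that("MST weight equals exhaustive spanning-tree enumeration", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:7, 1)
    pts <- matrix(runif(n * 3, 0, 8), n, 3)
    pg <- buildGraph(pts, 1e6)
    W <- as.matrix(dist(pts))
    diag(W) <- NA
    mst <- minimumSpanningTree(pg)
    expect_equal(sum(pg@weights[mst@treeEdges]), oracleMinSpanningWeight(W),
                 tolerance = 1e-9)
  }
})

test_that("top-K path lengths match their defining examples", {
  # path graph a-b-c with weights 1, 2: single leaf pair, length 3
  tr <- mkTree(rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)),
               rbind(c(1, 2), c(2, 3)))
  expect_equal(topKPathLengths(tr, 1), 3)
  # star with three unit arms: all leaf pairs have length 2
  star <- mkTree(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                 rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(topKPathLengths(star, 2), c(2, 2))
  expect_identical(length(topKPathLengths(star, 100)), 3L)
})

test_that("top-K path lengths match exhaustive leaf-pair enumeration", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    pts <- matrix(runif(n * 3, 0, 30), n, 3)
    pr <- sample.int(n, n - 2, replace = TRUE)
    edges <- pruferDecode(pr, n)
    tr <- mkTree(pts, edges)
    w <- tr@graph@weights[tr@treeEdges]
    em <- treeEdgeMatrix(tr)
    oracle <- oracleLeafPathLengths(em, w, n)
    k <- sample(1:6, 1)
    expect_equal(topKPathLengths(tr, k), head(oracle, k), tolerance = 1e-9)
    # the longest path length agrees with the top-1 score
    lp <- longestPath(tr)
    expect_equal(attr(lp, "length"), oracle[1], tolerance = 1e-9)
    # and its node sequence really connects two leaves with that length
    seg <- sqrt(rowSums(diff(tr@graph@positions[lp, , drop = FALSE])^2))
    expect_equal(sum(seg), oracle[1], tolerance = 1e-9)
  }
})

test_that("longest path picks the two longest arms of a star", {
  # arms of length 1, 2, 3 from a hub: diameter 5 through arms 2 and 3
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
  star <- mkTree(pts, rbind(c(1, 2), c(1, 3), c(1, 4)))
  lp <- longestPath(star)
  expect_equal(attr(lp, "length"), 5)
  expect_identical(sort(lp), c(1L, 3L, 4L))
})

test_that("tabu refinement is a no-op at zero iterations and never regresses", {
  set.seed(23)
  pts <- matrix(runif(18, 0, 6), 6, 3)
  pg <- buildGraph(pts, 1e6)
  mst <- minimumSpanningTree(pg, topK = 3)
  expect_identical(tabuRefine(mst, tabuParams(nIterations = 0, topK = 3)),
                   mst)
  ref <- tabuRefine(mst, tabuParams(nIterations = 25, topK = 3, rngSeed = 5))
  expect_gte(treeScore(ref), treeScore(mst))
  expect_true(all(diff(ref@history) >= 0))
  # the result is still a spanning tree of the same component
  expect_identical(length(ref@treeEdges), length(ref@nodes) - 1L)
  g <- igraph::make_graph(t(treeEdgeMatrix(ref)), n = 6, directed = FALSE)
  expect_true(igraph::is_forest(g) && igraph::components(g)$no == 1L)
})

test_that("tabu refinement is reproducible under a fixed seed", {
  set.seed(29)
  pts <- matrix(runif(24, 0, 7), 8, 3)
  pg <- buildGraph(pts, 1e6)
  mst <- minimumSpanningTree(pg, topK = 2)
  p <- tabuParams(nIterations = 15, topK = 2, rngSeed = 11, moveBudget = 10)
  r1 <- tabuRefine(mst, p)
  r2 <- tabuRefine(mst, p)
  expect_identical(r1@treeEdges, r2@treeEdges)
  expect_identical(r1@history, r2@history)
})

test_that("tabu search attains the exhaustive optimum on small graphs", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 5
    pts <- matrix(runif(n * 3, 0, 6), n, 3)
    pg <- buildGraph(pts, 1e6)
    W <- as.matrix(dist(pts)); diag(W) <- NA
    k <- c(1, 3, 100)[rep]
    mst <- minimumSpanningTree(pg, topK = k)
    ref <- tabuRefine(mst, tabuParams(nIterations = 40, topK = k,
                                      rngSeed = rep))
    expect_equal(treeScore(ref), oracleBestTopK(W, k), tolerance = 1e-9)
  }
})
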