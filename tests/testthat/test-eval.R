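# The five model-vs-reference C-alpha metrics.

test_that("identical structures score perfectly on every metric", {
  h <- makeHelix(15)
  ev <- evaluateModel(h, h)
  expect_identical(ev@rmsd, 0)
  expect_identical(ev@gdtTs, 100)
  expect_identical(ev@unlabeledRmsd, 0)
  expect_identical(c(ev@recall2, ev@recall3, ev@precision2, ev@precision3),
                   rep(1, 4))
})

test_that("a rigid translation shows up frame-fixed but not superposed", {
  h <- makeHelix(10)
  t1 <- CaStructure(residueNumbers(h), caSequence(h),
                    sweep(caPositions(h), 2, c(1, 0, 0), "+"))
  expect_equal(caRMSD(t1, h), 1, tolerance = 1e-12)
  expect_equal(caRMSD(t1, h, superpose = TRUE), 0, tolerance = 1e-6)
})

test_that("RMSD matches the direct formula on random pairs", {
  set.seed(47)
  a <- CaStructure(1:5, rep("A", 5), matrix(runif(15, 0, 10), 5, 3))
  b <- CaStructure(1:5, rep("A", 5), matrix(runif(15, 0, 10), 5, 3))
  expect_equal(caRMSD(a, b),
               sqrt(mean(rowSums((caPositions(a) - caPositions(b))^2))),
               tolerance = 1e-12)
  expect_error(caRMSD(a, CaStructure(6:9, rep("A", 4),
                                     matrix(runif(12), 4, 3))),
               "shared")
})

test_that("GDT-TS counts the four cutoffs over the reference length", {
  h <- makeHelix(10)
  m3 <- CaStructure(residueNumbers(h), caSequence(h),
                    sweep(caPositions(h), 2, c(3, 0, 0), "+"))
  # every pair displaced by exactly 3 A: only the 4 and 8 A cutoffs count
  expect_equal(gdtTS(m3, h), 50)
  # perfect model covering half the reference
  half <- CaStructure(1:5, caSequence(h)[1:5], caPositions(h)[1:5, ])
  expect_equal(gdtTS(half, h), 50)
  rp <- recallPrecision(half, h, 3)
  expect_equal(unname(rp), c(0.5, 1))
})

test_that("unlabeled RMSD ignores sequence register", {
  h <- makeHelix(8)
  # same coordinates, residue numbering reversed: labeled metrics collapse,
  # the unlabeled one does not
  rev <- CaStructure(1:8, caSequence(h)[8:1], caPositions(h)[8:1, ])
  expect_identical(unlabeledRMSD(rev, h), 0)
  expect_gt(caRMSD(rev, h), 5)
  one <- CaStructure(1L, "A", matrix(c(2, 0, 0), 1))
  two <- CaStructure(1:2, c("A", "A"), rbind(c(0, 0, 0), c(9, 9, 9)))
  expect_equal(unlabeledRMSD(one, two), 2)
})

test_that("unlabeled RMSD matches a brute-force nearest scan", {
  set.seed(53)
  for (rep in 1:10) {
    na <- sample(3:20, 1); nb <- sample(3:20, 1)
    a <- CaStructure(1:na, rep("A", na), matrix(runif(na * 3, 0, 15), na, 3))
    b <- CaStructure(1:nb, rep("A", nb), matrix(runif(nb * 3, 0, 15), nb, 3))
    d2 <- vapply(seq_len(na), function(i) {
      min(rowSums(sweep(caPositions(b), 2, caPositions(a)[i, ])^2))
    }, numeric(1))
    expect_equal(unlabeledRMSD(a, b), sqrt(mean(d2)), tolerance = 1e-12)
  }
})

test_that("recall/precision use a strict threshold and are symmetric", {
  a <- CaStructure(1L, "A", matrix(c(0, 0, 0), 1))
  b <- CaStructure(1L, "A", matrix(c(2, 0, 0), 1))
  # distance exactly 2: "closer than" is strict
  expect_equal(unname(recallPrecision(a, b, 2)), c(0, 0))
  expect_equal(unname(recallPrecision(a, b, 2.0001)), c(1, 1))
  set.seed(59)
  for (rep in 1:25) {
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    a <- CaStructure(1:na, rep("A", na), matrix(runif(na * 3, 0, 12), na, 3))
    b <- CaStructure(1:nb, rep("A", nb), matrix(runif(nb * 3, 0, 12), nb, 3))
    t <- sample(c(2, 3), 1)
    ab <- recallPrecision(a, b, t)
    ba <- recallPrecision(b, a, t)
    expect_identical(ab[["recall"]], ba[["precision"]])
    expect_identical(ab[["precision"]], ba[["recall"]])
  }
})

test_that("all metrics are invariant under a joint rigid transform", {
  set.seed(61)
  h <- makeHelix(12)
  m <- CaStructure(residueNumbers(h), caSequence(h),
                   caPositions(h) + matrix(rnorm(36, sd = 1), 12, 3))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  move <- function(s) CaStructure(residueNumbers(s), caSequence(s),
                                  caPositions(s) %*% R +
                                    matrix(c(3, -1, 2), nResidues(s), 3,
                                           byrow = TRUE))
  e1 <- evaluateModel(m, h)
  e2 <- evaluateModel(move(m), move(h))
  for (sl in c("rmsd", "gdtTs", "unlabeledRmsd", "recall2", "recall3",
               "precision2", "precision3"))
    expect_equal(slot(e2, sl), slot(e1, sl), tolerance = 1e-9)
})

test_that("a hand-built four-residue toy matches hand computation", {
  # residues 40 A apart so nearest neighbours are the matched pairs;
  # displacements 0.5, 1.5, 2.5, 9 A
  ref <- CaStructure(1:4, c("A", "G", "W", "V"),
                     cbind(c(0, 40, 80, 120), 0, 0))
  off <- c(0.5, 1.5, 2.5, 9)
  mod <- CaStructure(1:4, c("A", "G", "W", "V"),
                     cbind(c(0, 40, 80, 120), off, 0))
  ev <- evaluateModel(mod, ref)
  expect_equal(ev@rmsd, sqrt(mean(off^2)), tolerance = 1e-12)
  expect_equal(ev@gdtTs, 100 * mean(c(1, 2, 3, 3) / 4))
  expect_equal(ev@unlabeledRmsd, sqrt(mean(off^2)), tolerance = 1e-12)
  # strict "closer than": 0.5 and 1.5 beat 2 A; 2.5 additionally beats 3 A
  expect_equal(unname(c(ev@recall2, ev@recall3)), c(2, 3) / 4)
  expect_equal(unname(c(ev@precision2, ev@precision3)), c(2, 3) / 4)
  # swapping the roles swaps recall and precision
  ev2 <- evaluateModel(ref, mod)
  expect_identical(ev2@recall3, ev@precision3)
  expect_identical(ev2@precision2, ev@recall2)
})
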