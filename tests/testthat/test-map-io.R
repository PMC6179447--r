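# MRC/CCP4 I/O, trilinear interpolation, and PDB C-alpha I/O.

test_that("MRC round trip reproduces values, origin and voxel size exactly", {
  # MODE 2 stores 32-bit floats, so exactness is asserted on
  # float32-representable inputs (dyadic rationals)
  set.seed(11)
  for (i in 1:5) {
    d <- sample(2:6, 3, replace = TRUE)
    g <- DensityGrid(array(f32vals(prod(d)), d),
                     origin = sample(-8:8, 3) / 4,
                     voxelSize = sample(c(0.5, 1, 1.25, 2), 3, replace = TRUE),
                     contourLevel = 0.5)
    p <- withr::local_tempfile(fileext = ".mrc")
    writeMap(g, p)
    g2 <- readMap(p, contourLevel = 0.5)
    expect_identical(dim(gridValues(g2)), dim(gridValues(g)))
    expect_identical(as.numeric(gridValues(g2)), as.numeric(gridValues(g)))
    expect_identical(gridOrigin(g2), gridOrigin(g))
    expect_identical(voxelSize(g2), voxelSize(g))
  }
})

test_that("voxel (0,0,0) sits at the stored origin", {
  g <- DensityGrid(array(f32vals(27), c(3, 3, 3)), origin = c(5, 5, 5),
                   voxelSize = 1, contourLevel = 0.5)
  p <- withr::local_tempfile(fileext = ".mrc")
  writeMap(g, p)
  g2 <- readMap(p)
  expect_identical(gridOrigin(g2), c(5, 5, 5))
  expect_equal(interpolateDensity(g2, c(5, 5, 5)), gridValues(g)[1, 1, 1])
})

test_that("permuted MAPC/MAPR/MAPS axis order is normalized at read time", {
  set.seed(7)
  A <- array(f32vals(3 * 4 * 5), c(3, 4, 5))
  origin <- c(1, -2, 0.5)
  fCanon <- withr::local_tempfile(fileext = ".mrc")
  writeRawMrc(fCanon, A, mapcrs = 1:3, voxel = 1, origin = origin)
  for (mapcrs in list(c(3L, 1L, 2L), c(2L, 1L, 3L), c(3L, 2L, 1L))) {
    # B[c, r, s] = A[x, y, z] with axis 'mapcrs[d]' along crs dimension d
    B <- aperm(A, mapcrs)
    fPerm <- withr::local_tempfile(fileext = ".mrc")
    writeRawMrc(fPerm, B, mapcrs = mapcrs, voxel = 1, origin = origin)
    gc1 <- readMap(fCanon)
    gc2 <- readMap(fPerm)
    expect_identical(gridValues(gc2), gridValues(gc1))
    expect_identical(gridOrigin(gc2), gridOrigin(gc1))
  }
})

test_that("NCSTART origin fallback and non-orthogonal rejection behave", {
  A <- array(f32vals(8), c(2, 2, 2))
  f <- withr::local_tempfile(fileext = ".mrc")
  # zero ORIGIN record: falls back to starts * voxel (starts are 0 here)
  writeRawMrc(f, A, mapcrs = 1:3, voxel = 2, origin = c(0, 0, 0))
  expect_identical(gridOrigin(readMap(f)), c(0, 0, 0))
  f2 <- withr::local_tempfile(fileext = ".mrc")
  writeRawMrc(f2, A, mapcrs = 1:3, voxel = 1, origin = c(0, 0, 0),
              cellAngles = c(90, 120, 90))
  expect_error(readMap(f2), "non-orthogonal")
  expect_error(readMap(tempfile(fileext = ".mrc")), "not found")
})

test_that("an independent MRC implementation agrees with the writer", {
  # cross-check the on-disk format against gemmi (Python), which shares no
  # code with this package
  g <- DensityGrid(array(f32vals(3 * 4 * 5), c(3, 4, 5)),
                   origin = c(1.5, -2, 3), voxelSize = c(1, 1, 1),
                   contourLevel = 0.5)
  p <- withr::local_tempfile(fileext = ".mrc")
  writeMap(g, p)
  out <- system2("python", c("-c", shQuote(paste0(
    "import gemmi, numpy as np, json;",
    "m = gemmi.read_ccp4_map('", p, "');",
    "a = np.array(m.grid, copy=False);",
    "print(json.dumps({'shape': list(a.shape),",
    " 'sum': float(a.sum()), 'v000': float(a[0,0,0]),",
    " 'v210': float(a[2,1,0]),",
    " 'origin': [m.header_float(w) for w in (50,51,52)]}))"))),
    stdout = TRUE)
  res <- jsonlite::fromJSON(out[length(out)])
  expect_identical(res$shape, c(3L, 4L, 5L))
  expect_equal(res$sum, sum(gridValues(g)), tolerance = 1e-6)
  expect_identical(res$v000, gridValues(g)[1, 1, 1])
  expect_identical(res$v210, gridValues(g)[3, 2, 1])
  expect_equal(res$origin, c(1.5, -2, 3), tolerance = 1e-6)
})

test_that("trilinear interpolation is exact at voxel centers and midpoints", {
  set.seed(3)
  v <- array(runif(4 * 4 * 4), c(4, 4, 4))
  g <- DensityGrid(v, origin = c(10, 0, -5), voxelSize = c(1, 2, 0.5))
  expect_identical(interpolateDensity(g, c(10 + 2, 0 + 2 * 2, -5 + 0.5)),
                   v[3, 3, 2])
  # midpoint of two voxel centers along x
  expect_equal(interpolateDensity(g, c(10.5, 2, -4.5)),
               (v[1, 2, 2] + v[2, 2, 2]) / 2)
  expect_error(interpolateDensity(g, c(9, 0, 0)), "outside")
})

test_that("trilinear interpolation is exact for affine fields", {
  d <- c(6, 5, 7)
  co <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  aff <- function(p) 0.3 + 2 * p[, 1] - 0.7 * p[, 2] + 0.1 * p[, 3]
  g <- DensityGrid(array(aff(as.matrix(co)), d))
  set.seed(5)
  pts <- cbind(runif(50, 0, d[1] - 1), runif(50, 0, d[2] - 1),
               runif(50, 0, d[3] - 1))
  expect_equal(interpolateDensity(g, pts), aff(pts), tolerance = 1e-12)
})

test_that("C-alpha PDB round trip holds to format precision", {
  h <- makeHelix(8, sequence = "GAVLIFWK")
  p <- withr::local_tempfile(fileext = ".pdb")
  writeCaModel(h, p, bfactor = seq(0, 0.7, 0.1))
  s <- readCaStructure(p, chain = "A")
  expect_identical(residueNumbers(s), 1:8)
  expect_identical(caSequence(s), strsplit("GAVLIFWK", "")[[1]])
  expect_equal(caPositions(s), caPositions(h), tolerance = 1e-3)
})

test_that("altloc duplicates keep the first C-alpha and chains resolve", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdbCaLine(1, "ALA", "A", 1, 11, 12, 13, alt = "A", occ = 0.5),
    pdbCaLine(2, "ALA", "A", 1, 11.5, 12, 13, alt = "B", occ = 0.5),
    pdbCaLine(3, "GLY", "A", 2, 14, 12, 13),
    pdbCaLine(4, "TRP", "A", 3, 17, 12, 13),
    pdbCaLine(5, "SER", "B", 1, 0, 0, 0),
    "END"), p)
  expect_warning(s <- readCaStructure(p, chain = "A"), "duplicate")
  expect_identical(nResidues(s), 3L)
  expect_equal(caPositions(s)[1, ], c(11, 12, 13))
  sB <- readCaStructure(p, chain = "B")
  expect_identical(caSequence(sB), "S")
  expect_error(readCaStructure(p, chain = "C"), "chain")
})
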