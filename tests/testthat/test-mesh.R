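# Geometry: mesh validity, volumes, region summaries, VTK round trips,
# voxel-map sampling.

test_that("mesh construction validates volumes and connectivity", {
  m <- unitTet()
  expect_equal(totalVolume(m), 1 / 6)
  expect_equal(nrow(m@surfaceFacets), 4L)

  # inverted element (two nodes swapped) has negative volume
  expect_error(tetMesh(m@nodes, matrix(c(1L, 3L, 2L, 4L), 1)),
               "degenerate or inverted")
  # zero-volume element (coplanar nodes)
  expect_error(tetMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                       matrix(1:4, 1)), "degenerate or inverted")
  # out-of-range connectivity
  expect_error(tetMesh(m@nodes, matrix(c(1L, 2L, 3L, 5L), 1)), "out of range")
})

test_that("region summaries are volume-weighted and additive", {
  m <- twoTets()
  v <- elementVolumes(m)
  expect_equal(v, c(1 / 6, 1 / 2))

  # uniform field: mean equals the value for any mask
  expect_equal(regionSummary(m, c(0.5, 0.5))$mean, 0.5)
  # volumes 1:3, values 0 and 1 -> volume-weighted mean 0.75
  expect_equal(regionSummary(m, c(0, 1))$mean, 0.75)
  # masked region volume + complement volume = total volume (exact)
  mask <- c(TRUE, FALSE)
  expect_identical(regionSummary(m, v * 0, mask)$volume +
                     regionSummary(m, v * 0, !mask)$volume, totalVolume(m))
  expect_error(regionSummary(m, c(0, 1), c(0, 0)), "empty mask")
  expect_error(regionSummary(m, c(0, 1), c(0.5, 1)), "binary")
})

test_that("VTK write/read round trip is exact and rejects non-tet cells", {
  m <- makeProstateMesh(c(8, 7, 9), elementSize = 4)
  f <- withr::local_tempfile(fileext = ".vtk")
  fields <- list(cellularity = runif(nElements(m)),
                 mask = rep(c(0, 1), length.out = nElements(m)))
  writeVTKMesh(m, f, fields)
  back <- readVTKMesh(f)
  expect_identical(back$mesh@nodes, m@nodes)
  expect_identical(back$mesh@tets, m@tets)
  expect_identical(back$fields$cellularity, fields$cellularity)
  expect_identical(back$fields$mask, fields$mask)

  # a hexahedron cell (type 12) must be refused
  bad <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "t", "ASCII",
               "DATASET UNSTRUCTURED_GRID", "POINTS 8 double",
               apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = " "),
               "CELLS 1 9", "8 0 1 2 3 4 5 6 7", "CELL_TYPES 1", "12"), bad)
  expect_error(readVTKMesh(bad), "unsupported element")
})

test_that("synthetic ellipsoid volume approaches the analytic value", {
  semi <- c(10, 8, 9)
  analytic <- 4 / 3 * pi * prod(semi)
  m <- makeProstateMesh(semi, elementSize = 2.5)
  expect_lt(abs(totalVolume(m) - analytic) / analytic, 0.05)
  expect_true(all(elementVolumes(m) > 0))
})

test_that("trilinear sampling reproduces affine fields at centroids", {
  m <- makeProstateMesh(c(6, 5, 5.5), elementSize = 3)
  # grid enclosing the mesh: 2 mm pitch, origin at -10
  aff <- diag(c(2, 2, 2, 1))
  aff[1:3, 4] <- -10
  dims <- c(11, 11, 11)
  idx <- as.matrix(expand.grid(i = 0:10, j = 0:10, k = 0:10))
  world <- t(aff %*% t(cbind(idx, 1)))[, 1:3]

  # constant map
  mc <- voxelMap(array(7, dims), aff)
  expect_equal(interpolateToMesh(mc, m), rep(7, nElements(m)))

  # x-coordinate ramp: trilinear interpolation is exact for degree-1 fields
  mx <- voxelMap(array(world[, 1], dims), aff)
  expect_equal(interpolateToMesh(mx, m), elementCentroids(m)[, 1],
               tolerance = 1e-10)

  # mesh translated outside the grid errors with the element id
  mOut <- tetMesh(m@nodes + 100, m@tets)
  expect_error(interpolateToMesh(mx, mOut), "outside the voxel grid")

  # nearest-neighbour keeps a binary map binary
  mb <- voxelMap(array(rep(c(0, 1), length.out = prod(dims)), dims), aff)
  nn <- interpolateToMesh(mb, m, method = "nearest")
  expect_true(all(nn %in% c(0, 1)))
})

test_that("NIfTI voxel maps round trip through disk", {
  arr <- array(rnorm(60), c(3, 4, 5))
  aff <- diag(c(1.5, 1.5, 3, 1))
  aff[1:3, 4] <- c(-20, -30, -10)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeNIfTIMap(voxelMap(arr, aff, "mm^2/s"), f)
  back <- readNIfTIMap(f, "mm^2/s")
  expect_equal(back@data, arr, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back@affine, aff, tolerance = 1e-6)
})
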