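test_that("PLY and OBJ round-trips are lossless", {
  tet <- makeTetrahedron()
  for (ext in c("ply", "obj")) {
    p <- file.path(tempdir(), paste0("tet.", ext))
    writeMesh(tet, p)
    back <- readMesh(p)
    expect_equal(nrow(meshVertices(back)), 4)
    expect_equal(nrow(meshFaces(back)), 4)
    expect_equal(meshVertices(back), meshVertices(tet), ignore_attr = TRUE)
    expect_identical(meshFaces(back), meshFaces(tet))
  }
})

test_that("PLY scalar channel round-trips", {
  tet <- makeTetrahedron()
  tet@scalars <- c(0.25, 1.5, 3.75, 5)
  p <- file.path(tempdir(), "tetq.ply")
  writeMesh(tet, p)
  expect_equal(meshScalars(readMesh(p)), tet@scalars, tolerance = 1e-12)
})

test_that("binary little-endian PLY is read", {
  tet <- makeTetrahedron()
  p <- file.path(tempdir(), "tetbin.ply")
  con <- file(p, "wb")
  hdr <- c("ply", "format binary_little_endian 1.0",
           "element vertex 4",
           "property float x", "property float y", "property float z",
           "element face 4",
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  v <- meshVertices(tet)
  writeBin(as.numeric(t(v)), con, size = 4, endian = "little")
  for (i in 1:4) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(meshFaces(tet)[i, ] - 1L), con, size = 4,
             endian = "little")
  }
  close(con)
  back <- readMesh(p)
  expect_equal(meshVertices(back), v, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(meshFaces(back), meshFaces(tet))
})

test_that("polygonal faces are fan-triangulated with a warning", {
  p <- file.path(tempdir(), "quad.ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property double x", "property double y", "property double z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), p)
  expect_warning(m <- readMesh(p), "triangulat")
  expect_equal(nrow(meshFaces(m)), 2)
})

test_that("unknown formats and unreadable files error", {
  expect_error(readMesh("nofile.xyz"), "unknown mesh format")
  expect_error(readMesh(file.path(tempdir(), "does-not-exist.ply")),
               "cannot read")
})

test_that("landmark CSV and JSON round-trips preserve coordinates", {
  cell <- meanCellLandmarks("I", "M")
  for (ext in c("csv", "json")) {
    p <- file.path(tempdir(), paste0("lms.", ext))
    writeLandmarks(cell$lms, p)
    back <- readLandmarks(p)
    expect_equal(lmCoords(back)[lmLabels(cell$lms), ],
                 lmCoords(cell$lms), tolerance = 1e-6)
  }
})

test_that("landmark validation names missing and bad labels", {
  cell <- meanCellLandmarks()
  co <- lmCoords(cell$lms)
  p <- file.path(tempdir(), "missing.csv")
  writeLandmarks(LandmarkSet(co[rownames(co) != "Pg", ]), p)
  expect_error(readLandmarks(p), "Pg")

  bad <- co
  rownames(bad)[1] <- "NotALandmark"
  expect_error(LandmarkSet(bad), "NotALandmark")

  dup <- rbind(co, co["N", , drop = FALSE])
  expect_error(LandmarkSet(dup), "duplicate")

  half <- co[rownames(co) != "Go-l", ]
  expect_error(LandmarkSet(half), "incomplete bilateral pair")
})

test_that("generator-emitted files reload to 1e-6", {
  set.seed(21)
  s <- generateSubject("II", "F")
  p <- file.path(tempdir(), "gen.csv")
  writeLandmarks(s$landmarks, p)
  expect_equal(lmCoords(readLandmarks(p)), lmCoords(s$landmarks),
               tolerance = 1e-6)

  tet <- makeTetrahedron()
  pm <- file.path(tempdir(), "gen.ply")
  set.seed(22)
  sm <- generateSubject("I", "M", mesh = TRUE, template = sharedTemplate())
  writeMesh(sm$mesh, pm)
  expect_equal(meshVertices(readMesh(pm)), meshVertices(sm$mesh),
               tolerance = 1e-6, ignore_attr = TRUE)
})
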