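test_that("the template is exactly symmetric, watertight and anchored", {
  tpl <- sharedTemplate()
  m <- templateMirror(tpl)
  v <- meshVertices(templateMesh(tpl))
  expect_identical(m[m], seq_along(m))            # involutive
  expect_identical(v[m, 1], -v[, 1])              # exact x negation
  expect_identical(v[m, 2:3], v[, 2:3])
  expect_true(craniosym:::.isWatertight(templateMesh(tpl)))
  expect_setequal(
    setdiff(names(templateAnchors(tpl)), landmarkVocabulary()),
    sprintf("Layer%d-%d", rep(1:4, each = 10), rep(0:9, 4)))
  expect_false(anyDuplicated(templateAnchors(tpl)) > 0)
})

test_that("template volume matches the analytic superellipsoid by voxels", {
  tpl0 <- buildTemplate(bumps = FALSE)
  vm <- meshVolume(templateMesh(tpl0), "mm3")
  lms <- canonicalLandmarks()
  yV <- lmPoint(lms, "V")[2]; yGn <- lmPoint(lms, "Gn")[2]
  L <- lmPoint(lms, "PRn")[3] - lmPoint(lms, "Op")[3]
  ax <- 160.98 / 2; ay <- (yV - yGn) / 2; az <- 0.40 * L
  yc <- (yV + yGn) / 2; expo <- 2.5
  h <- 2
  xs <- seq(-ax, ax, by = h); zs <- seq(-az, az, by = h)
  g <- expand.grid(x = xs, z = zs)
  cnt <- 0
  for (y in seq(yc - ay, yc + ay, by = h)) {
    s <- (abs(g$x) / ax)^expo + (abs(y - yc) / ay)^expo +
      (abs(g$z) / az)^expo
    cnt <- cnt + sum(s <= 1)
  }
  expect_equal(vm, cnt * h^3, tolerance = 0.01)
})

test_that("low resolutions are refused", {
  expect_error(buildTemplate(6, 32), ">= 8")
})

test_that("scaleTemplate recovers known stretches", {
  tpl <- sharedTemplate()
  own <- templateLandmarks(tpl)
  s1 <- scaleTemplate(tpl, own)
  expect_equal(attr(s1, "scale"), c(1, 1, 1), tolerance = 1e-9)

  co2 <- lmCoords(own) * 2
  rownames(co2) <- lmLabels(own)
  s2 <- scaleTemplate(tpl, LandmarkSet(co2))
  expect_equal(attr(s2, "scale"), c(2, 2, 2), tolerance = 1e-9)

  set.seed(20)
  sc <- stats::runif(3, 0.6, 1.7)
  co3 <- lmCoords(own) %*% diag(sc)
  rownames(co3) <- lmLabels(own)
  s3 <- scaleTemplate(tpl, LandmarkSet(co3))
  expect_equal(attr(s3, "scale"), sc, tolerance = 1e-6)
  # symmetry survives anisotropic scaling
  expect_true(validObject(s3))
})

test_that("closest-point map is exact: self-match and analytic sphere", {
  tpl <- sharedTemplate()
  corr <- closestPointMap(tpl, templateMesh(tpl))
  expect_identical(max(corrDistances(corr)), 0)
  expect_identical(corrPoints(corr), unname(meshVertices(templateMesh(tpl))))

  sph <- makeSphereTemplate(radius = 100, nr = 48, nv = 40)
  q <- HeadMesh(matrix(c(0, 0, 250), 1, 3), matrix(integer(0), 0, 3))
  corr2 <- closestPointMap(q, templateMesh(sph))
  # faceting makes the surface slightly inside the true sphere
  expect_equal(corrDistances(corr2), 150, tolerance = 5e-3)
})

test_that("pruned search equals brute force over all triangles", {
  sph <- makeSphereTemplate(radius = 80, nr = 20, nv = 14)
  mesh <- templateMesh(sph)
  set.seed(21)
  q <- matrix(stats::rnorm(300, 0, 120), 100, 3)
  queries <- HeadMesh(q, matrix(integer(0), 0, 3))
  fast <- closestPointMap(queries, mesh)
  slow <- closestPointMap(queries, mesh, bruteForce = TRUE)
  expect_identical(corrDistances(fast), corrDistances(slow))
  expect_identical(corrPoints(fast), corrPoints(slow))
  expect_identical(corrFaces(fast), corrFaces(slow))
})

test_that("closest points lie on their matched triangles", {
  sph <- makeSphereTemplate(radius = 50, nr = 16, nv = 12)
  mesh <- templateMesh(sph)
  set.seed(22)
  q <- matrix(stats::rnorm(60, 0, 70), 20, 3)
  corr <- closestPointMap(HeadMesh(q, matrix(integer(0), 0, 3)), mesh)
  v <- meshVertices(mesh); f <- meshFaces(mesh)
  for (i in 1:20) {
    tri <- f[corrFaces(corr)[i], ]
    A <- v[tri[1], ]; B <- v[tri[2], ]; C <- v[tri[3], ]
    p <- corrPoints(corr)[i, ]
    # barycentric reconstruction: p must lie in the triangle's plane hull
    M <- cbind(B - A, C - A)
    bc <- qr.solve(M, p - A)
    expect_gte(min(bc), -1e-9)
    expect_lte(sum(bc), 1 + 1e-9)
    expect_lt(max(abs(A + M %*% bc - p)), 1e-9)
    expect_equal(sqrt(sum((q[i, ] - p)^2)), corrDistances(corr)[i],
                 tolerance = 1e-12)
  }
})

test_that("template serialisation round-trips", {
  tpl <- buildTemplate(16, 12)
  p <- file.path(tempdir(), "tpl.ply")
  writeTemplate(tpl, p)
  back <- readTemplate(p)
  expect_identical(templateMirror(back), templateMirror(tpl))
  expect_identical(templateAnchors(back), templateAnchors(tpl))
  expect_equal(meshVertices(templateMesh(back)),
               meshVertices(templateMesh(tpl)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pipeline determinism: identical inputs give identical maps", {
  tpl <- buildTemplate(16, 12)
  set.seed(23)
  s <- generateSubject("I", "F", mesh = TRUE, template = tpl)
  r1 <- analyzeAsymmetry(s$mesh, s$landmarks, template = tpl)
  r2 <- analyzeAsymmetry(s$mesh, s$landmarks, template = tpl)
  expect_identical(r1@pairValues, r2@pairValues)
  expect_identical(r1@AH, r2@AH)
})
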