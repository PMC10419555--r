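# cylinder of radius R about the y axis, closed with caps
makeCylinder <- function(R = 60, y0 = -50, y1 = 150, nr = 36, ny = 20) {
  ys <- seq(y0, y1, length.out = ny)
  V <- do.call(rbind, lapply(ys, function(y) {
    a <- 2 * pi * (0:(nr - 1)) / nr
    cbind(R * sin(a), y, R * cos(a))
  }))
  idx <- function(i, j) (i - 1L) * nr + ((j) %% nr) + 1L
  F <- list()
  for (i in 1:(ny - 1)) for (j in 0:(nr - 1)) {
    F[[length(F) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    F[[length(F) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  top <- nrow(V) + 1L; bot <- nrow(V) + 2L
  V <- rbind(V, c(0, y1, 0), c(0, y0, 0))
  for (j in 0:(nr - 1)) {
    F[[length(F) + 1]] <- c(top, idx(ny, j + 1), idx(ny, j))
    F[[length(F) + 1]] <- c(bot, idx(1, j), idx(1, j + 1))
  }
  HeadMesh(V, do.call(rbind, F))
}

cylinderSpanLandmarks <- function(y0 = 0, y1 = 140) {
  LandmarkSet(rbind("OBs-r" = c(-10, y0, 0), "OBs-l" = c(10, y0, 0),
                    "V" = c(0, y1, 0)))
}

test_that("layer landmarks on a cylinder sit at the cylinder radius", {
  # nr divisible by 10 so the ray azimuths pass through vertex columns
  # (elsewhere the faceted cylinder lies slightly inside the true radius)
  cyl <- makeCylinder(R = 60, nr = 40)
  lay <- layerLandmarks(cyl, cylinderSpanLandmarks(0, 140))
  co <- lmCoords(lay)
  expect_equal(nrow(co), 40)
  radii <- sqrt(co[, 1]^2 + co[, 3]^2)
  expect_equal(unname(radii), rep(60, 40), tolerance = 1e-6)
  # heights evenly spaced strictly inside (OBs level, V)
  hs <- sort(unique(round(co[, 2], 9)))
  expect_equal(hs, 140 * (1:4) / 5, tolerance = 1e-9)
  # azimuth 0 faces +z
  expect_gt(co["Layer1-0", 3], 0)
  expect_lt(abs(co["Layer1-0", 1]), 1e-9)
})

test_that("layer landmarks are mirror-consistent on a mirrored mesh", {
  cyl <- makeCylinder(R = 45)
  lay <- lmCoords(layerLandmarks(cyl, cylinderSpanLandmarks(0, 140)))
  v <- meshVertices(cyl); v[, 1] <- -v[, 1]
  layM <- lmCoords(layerLandmarks(HeadMesh(v, meshFaces(cyl)),
                                  cylinderSpanLandmarks(0, 140)))
  for (k in 1:4) for (j in 0:9) {
    a <- lay[sprintf("Layer%d-%d", k, j), ]
    b <- layM[sprintf("Layer%d-%d", k, (10 - j) %% 10), ]
    expect_equal(unname(b), unname(c(-a[1], a[2], a[3])), tolerance = 1e-9)
  }
})

test_that("rays that miss the surface are reported with their position", {
  cyl <- makeCylinder(R = 60, y0 = -50, y1 = 100)
  expect_error(layerLandmarks(cyl, cylinderSpanLandmarks(0, 300)),
               "layer ray misses")
})

test_that("the facial region is the PRn/Gn bisector half-space", {
  prn <- c(0, 60, 80); gn <- c(0, -40, 70)
  set.seed(30)
  pts <- matrix(stats::rnorm(900, 0, 90), 300, 3)
  mask <- facialRegion(HeadMesh(pts, matrix(integer(0), 0, 3)),
                       prn = prn, gn = gn)
  # closed-form oracle: signed distance to the perpendicular bisector plane
  mid <- (prn + gn) / 2
  nrm <- (gn - prn) / sqrt(sum((gn - prn)^2))
  side <- as.vector((pts - matrix(mid, 300, 3, byrow = TRUE)) %*% nrm)
  expect_identical(mask, side <= 0)
  expect_true(facialRegion(HeadMesh(matrix(prn, 1, 3),
                                    matrix(integer(0), 0, 3)),
                           prn = prn, gn = gn))
  expect_false(facialRegion(HeadMesh(matrix(gn, 1, 3),
                                     matrix(integer(0), 0, 3)),
                            prn = prn, gn = gn))
})

test_that("region masks are mirror-consistent and conserve pairs", {
  tpl <- sharedTemplate()
  mask <- facialRegion(tpl)
  m <- templateMirror(tpl)
  expect_identical(mask, mask[m])
  corr <- closestPointMap(tpl, templateMesh(tpl))
  pw <- pointwiseAsymmetry(corr, tpl)
  fm <- mask[pw$pairIndex[, 1]]
  expect_identical(sum(fm) + sum(!fm), nrow(pw$pairIndex))
})

test_that("pointwise asymmetry is zero for a symmetric subject and
           invariant to left/right relabelling", {
  sph <- makeSphereTemplate(radius = 90, nr = 24, nv = 18)
  corr <- closestPointMap(sph, templateMesh(sph))
  pw <- pointwiseAsymmetry(corr, sph)
  expect_identical(max(pw$values), 0)

  set.seed(31)
  v <- meshVertices(templateMesh(sph))
  left <- v[, 1] > 0
  r <- sqrt(rowSums(v[left, , drop = FALSE]^2))
  v2 <- v; v2[left, ] <- v[left, ] * (r + 1.5) / r
  subj <- HeadMesh(v2, meshFaces(templateMesh(sph)))
  pwA <- pointwiseAsymmetry(closestPointMap(sph, subj), sph)
  # mirrored subject: asymmetry magnitudes are unchanged
  v3 <- v2; v3[, 1] <- -v3[, 1]
  pwB <- pointwiseAsymmetry(closestPointMap(sph,
                                            HeadMesh(v3,
                                                     meshFaces(templateMesh(sph)))),
                            sph)
  expect_equal(mean(pwA$values), mean(pwB$values), tolerance = 1e-9)
})

test_that("radial offsets are recovered within the faceting tolerance", {
  for (res in list(c(40, 32), c(64, 48))) {
    sph <- makeSphereTemplate(radius = 100, nr = res[1], nv = res[2])
    v <- meshVertices(templateMesh(sph))
    left <- v[, 1] > 0
    for (delta in c(0.5, 2)) {
      v2 <- v
      r <- sqrt(rowSums(v[left, , drop = FALSE]^2))
      v2[left, ] <- v[left, ] * (r + delta) / r
      subj <- HeadMesh(v2, meshFaces(templateMesh(sph)))
      pw <- pointwiseAsymmetry(closestPointMap(sph, subj), sph)
      expect_equal(mean(pw$values), delta, tolerance = 0.1)
    }
  }
})

test_that("summaries are regional means with guarded edge cases", {
  expect_equal(asymmetrySummary(rep(3.5, 10), rep(c(TRUE, FALSE), 5)),
               list(AH = 3.5, AF = 3.5))
  vals <- c(1, 2, 3, 4, 10)
  s <- asymmetrySummary(vals, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(s$AH, 4)
  expect_equal(s$AF, 1.5)
  expect_error(asymmetrySummary(vals, rep(FALSE, 5)), "empty facial mask")
  expect_error(asymmetrySummary(numeric(0), logical(0)), "no asymmetry")
})

test_that("head metrics: unit cube and analytic sphere", {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  cube <- HeadMesh(v, f)
  lms <- LandmarkSet(rbind(V = c(0, 1, 0), Gn = c(0, 0, 0)))
  hm <- headMetrics(cube, lms)
  expect_equal(hm$H, 1)
  expect_equal(hm$L, 1)
  expect_equal(hm$W, 1)
  expect_equal(hm$V, 0.001, tolerance = 1e-12)

  sph <- templateMesh(makeSphereTemplate(radius = 100, nr = 64, nv = 48))
  expect_equal(meshVolume(sph, "cm3"), 4 / 3 * pi * 1e6 / 1000,
               tolerance = 0.01)

  open <- HeadMesh(meshVertices(cube), meshFaces(cube)[-1, ])
  expect_error(meshVolume(open), "watertight")
})

test_that("heat maps export, round-trip and localise a known bump", {
  sph <- makeSphereTemplate(radius = 100, nr = 32, nv = 24)
  mesh <- templateMesh(sph)
  v <- meshVertices(mesh)

  # symmetric subject: uniform minimum colour
  pw0 <- pointwiseAsymmetry(closestPointMap(sph, mesh), sph)
  vals0 <- numeric(nrow(v))
  p0 <- file.path(tempdir(), "heat0.ply")
  exportHeatmap(sph, vals0, p0)
  expect_equal(meshScalars(readMesh(p0)), vals0)
  txt <- readLines(p0)
  colLines <- grep("^[-0-9]", txt, value = TRUE)[seq_len(nrow(v))]
  cols <- unique(vapply(strsplit(colLines, " "),
                        function(t) paste(utils::tail(t, 3), collapse = ","),
                        ""))
  expect_length(cols, 1)

  # bump on the left: maximum heat inside the deformed support
  centre <- c(60, 40, 40)
  d <- sqrt(rowSums((v - matrix(centre, nrow(v), 3, byrow = TRUE))^2))
  bumpMask <- d < 35
  v2 <- v
  r <- sqrt(rowSums(v^2))
  infl <- 3 * exp(-(d / 20)^2)
  v2[bumpMask, ] <- v[bumpMask, ] * ((r + infl) / r)[bumpMask]
  subj <- HeadMesh(v2, meshFaces(mesh))
  pw <- pointwiseAsymmetry(closestPointMap(sph, subj), sph)
  vals <- numeric(nrow(v))
  vals[pw$pairIndex[, 1]] <- pw$values
  vals[pw$pairIndex[, 2]] <- pw$values
  hottest <- v[which.max(vals), ]
  expect_true(sqrt(sum((abs(hottest) - abs(centre))^2)) < 40)
  p1 <- file.path(tempdir(), "heat1.ply")
  exportHeatmap(sph, vals, p1)
  expect_equal(meshScalars(readMesh(p1)), vals, tolerance = 1e-6)
})

test_that("full subject analysis recovers configured asymmetry levels", {
  tpl <- sharedTemplate()
  set.seed(33)
  drawn <- meas <- NULL
  for (k in 1:4) {
    s <- generateSubject(sample(c("I", "II"), 1), sample(c("M", "F"), 1),
                         mesh = TRUE, template = tpl)
    res <- analyzeAsymmetry(s$mesh, s$landmarks, template = tpl)
    drawn <- rbind(drawn, s$head[c("AF", "AH")])
    meas <- rbind(meas, c(asymAF(res), asymAH(res)))
  }
  expect_equal(mean(meas[, 1]) / mean(drawn[, 1]), 1, tolerance = 0.1)
})
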