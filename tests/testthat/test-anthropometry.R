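test_that("distance matches the coordinate-wise formula", {
  expect_equal(pointDistance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(pointDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(1)
  for (k in 1:50) {
    p <- stats::rnorm(3, 0, 10); q <- stats::rnorm(3, 0, 10)
    oracle <- sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2 + (p[3] - q[3])^2)
    expect_equal(pointDistance(p, q), oracle, tolerance = 1e-12)
  }
})

test_that("point-to-line distance agrees with a dense-grid minimiser", {
  expect_equal(pointLineDistance(c(0, 5, 0), c(0, 0, 0), c(0, 1, 0)), 0)
  expect_equal(pointLineDistance(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                                 signedAxis = c(1, 0, 0)), 1)
  expect_equal(pointLineDistance(c(-1, 3, 0), c(0, 0, 0), c(0, 1, 0),
                                 signedAxis = c(1, 0, 0)), -1)
  expect_error(pointLineDistance(c(1, 0, 0), c(2, 2, 2), c(2, 2, 2)),
               "degenerate line")
  set.seed(2)
  for (k in 1:100) {
    p <- stats::rnorm(3, 0, 5); a <- stats::rnorm(3, 0, 5)
    b <- a + stats::rnorm(3, 0, 5)
    # independent 1-D minimisation of |p - (a + t (b - a))| over t
    f <- function(t) sqrt(sum((p - (a + t * (b - a)))^2))
    oracle <- stats::optimize(f, c(-60, 60), tol = 1e-12)$objective
    expect_equal(pointLineDistance(p, a, b), oracle, tolerance = 1e-6)
  }
})

test_that("vertex angle matches the law-of-cosines oracle", {
  expect_equal(vertexAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(vertexAngle(c(-2, 0, 0), c(0, 0, 0), c(5, 0, 0)), 180)
  expect_error(vertexAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "degenerate")
  set.seed(3)
  for (k in 1:100) {
    a <- stats::rnorm(3); v <- stats::rnorm(3); b <- stats::rnorm(3)
    ca <- pointDistance(v, b); cb <- pointDistance(v, a)
    cc <- pointDistance(a, b)
    oracle <- acos(min(1, max(-1, (ca^2 + cb^2 - cc^2) / (2 * ca * cb)))) *
      180 / pi
    expect_equal(vertexAngle(a, v, b), oracle, tolerance = 1e-9)
  }
})

test_that("segment angle equals the vertex angle at a shared origin", {
  expect_equal(segmentAngle(c(0, 0, 0), c(1, 0, 0), c(5, 5, 5),
                            c(5, 6, 5)), 90)
  expect_equal(segmentAngle(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0),
                            c(-2, 0, 0)), 180)
  set.seed(4)
  for (k in 1:50) {
    a1 <- stats::rnorm(3); a2 <- stats::rnorm(3)
    b1 <- stats::rnorm(3); b2 <- stats::rnorm(3)
    oracle <- vertexAngle(a2 - a1, c(0, 0, 0), b2 - b1)
    expect_equal(segmentAngle(a1, a2, b1, b2), oracle, tolerance = 1e-9)
  }
})

test_that("measureSubject fills the battery with the expected geometry", {
  cell <- meanCellLandmarks("I", "M")
  rec <- measureSubject(cell$lms)
  expect_equal(unname(rec[names(cell$targets)]), unname(cell$targets),
               tolerance = 1e-9)
  # symmetric subject: per-side values agree exactly
  expect_equal(rec[["Go_Gn_r"]], rec[["Go_Gn_l"]], tolerance = 1e-9)
  expect_equal(rec[["gonial_angle_r"]], rec[["gonial_angle_l"]],
               tolerance = 1e-9)
  # missing landmark errors name the problem
  co <- lmCoords(cell$lms)
  expect_error(measureSubject(LandmarkSet(co[rownames(co) != "Sn", ])),
               "Sn")
})

test_that("distances scale linearly and angles are scale-invariant", {
  cell <- meanCellLandmarks("II", "F")
  rec <- measureSubject(cell$lms)
  lin <- c("N_Gn", "N_Sn", "Sto_Gn", "Sn_Sto", "N_Sto", "Sn_to_NPg",
           "Go_Gn", "Pg_to_NB")
  ang <- c("nasolabial_angle", "labiomental_angle",
           "lowerlip_submental_angle", "gonial_angle", "facial_convexity",
           "soft_tissue_convexity")
  set.seed(6)
  for (s in stats::runif(4, 0.5, 2)) {
    co <- lmCoords(cell$lms) * s
    rownames(co) <- lmLabels(cell$lms)
    rs <- measureSubject(LandmarkSet(co))
    expect_equal(unname(rs[lin]), unname(rec[lin]) * s, tolerance = 1e-9)
    expect_equal(unname(rs[ang]), unname(rec[ang]), tolerance = 1e-9)
  }
})

test_that("a mirrored subject yields identical parameters", {
  cell <- meanCellLandmarks("III", "F")
  co <- lmCoords(cell$lms)
  mir <- co; mir[, 1] <- -mir[, 1]
  # mirroring swaps anatomical left/right: relabel to keep pairs honest
  rn <- rownames(mir)
  rn2 <- sub("-r$", "-TMP", rn); rn2 <- sub("-l$", "-r", rn2)
  rn2 <- sub("-TMP$", "-l", rn2)
  rownames(mir) <- rn2
  rec <- measureSubject(cell$lms)
  recM <- measureSubject(LandmarkSet(mir))
  keep <- measurementLabels()$name
  expect_equal(unname(abs(recM[keep])), unname(abs(rec[keep])),
               tolerance = 1e-9)
})

test_that("the vertical chain obeys the triangle inequality", {
  set.seed(7)
  for (k in 1:30) {
    s <- generateSubject(sample(c("I", "II", "III"), 1),
                         sample(c("M", "F"), 1))
    rec <- measureSubject(s$landmarks)
    expect_lte(rec[["N_Sto"]], rec[["N_Sn"]] + rec[["Sn_Sto"]] + 1e-9)
    expect_lte(rec[["N_Sto"]], rec[["N_Gn"]] + 1e-9)
  }
})
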