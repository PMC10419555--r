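## Low-level geometric primitives shared by the correspondence and asymmetry
## machinery.  All coordinates are mm; meshes use 1-based vertex indices.

.rowNorms <- function(m) sqrt(rowSums(m * m))

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

## Closest point on each of k triangles to a single query point.
## Vectorised Voronoi-region classification (Ericson, Real-Time Collision
## Detection, 5.1.5).  A, B, C are k x 3 matrices; p length 3.
.closestOnTriangles <- function(p, A, B, C) {
  k <- nrow(A)
  ab <- B - A; ac <- C - A
  ap <- matrix(p, k, 3, byrow = TRUE) - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- matrix(p, k, 3, byrow = TRUE) - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- matrix(p, k, 3, byrow = TRUE) - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)

  out <- matrix(NA_real_, k, 3)
  unset <- rep(TRUE, k)

  take <- function(mask, value) {
    sel <- unset & mask
    if (any(sel)) out[sel, ] <<- value[sel, , drop = FALSE]
    unset <<- unset & !mask
  }

  take(d1 <= 0 & d2 <= 0, A)                       # vertex region A
  take(d3 >= 0 & d4 <= d3, B)                      # vertex region B
  vc <- d1 * d4 - d3 * d2
  vAB <- d1 / pmax(d1 - d3, .Machine$double.xmin)
  take(vc <= 0 & d1 >= 0 & d3 <= 0, A + ab * vAB)  # edge AB
  take(d6 >= 0 & d5 <= d6, C)                      # vertex region C
  vb <- d5 * d2 - d1 * d6
  wAC <- d2 / pmax(d2 - d6, .Machine$double.xmin)
  take(vb <= 0 & d2 >= 0 & d6 <= 0, A + ac * wAC)  # edge AC
  va <- d3 * d6 - d5 * d4
  wBC <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), .Machine$double.xmin)
  take(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
       B + (C - B) * wBC)                          # edge BC
  if (any(unset)) {                                # face interior
    denom <- 1 / (va + vb + vc)
    v <- vb * denom; w <- vc * denom
    inn <- A + ab * v + ac * w
    out[unset, ] <- inn[unset, , drop = FALSE]
  }
  out
}

## Precompute per-face arrays once per mesh.
.faceArrays <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  cent <- (A + B + C) / 3
  rad <- pmax(.rowNorms(A - cent), .rowNorms(B - cent), .rowNorms(C - cent))
  list(A = A, B = B, C = C, cent = cent, rad = rad, v = v)
}

## Globally nearest surface point for a batch of query points.
## exact pruning: a face can hold the minimiser only if
## |q - centroid| - rad <= current upper bound.
.closestPointsOnMesh <- function(queries, mesh, bruteForce = FALSE) {
  fa <- .faceArrays(mesh)
  nq <- nrow(queries)
  pts <- matrix(0, nq, 3)
  fidx <- integer(nq)
  dist <- numeric(nq)
  for (i in seq_len(nq)) {
    q <- queries[i, ]
    if (bruteForce) {
      cand <- seq_len(nrow(fa$A))
    } else {
      dv <- .rowNorms(fa$v - matrix(q, nrow(fa$v), 3, byrow = TRUE))
      ub <- min(dv)
      dc <- .rowNorms(fa$cent - matrix(q, nrow(fa$cent), 3, byrow = TRUE))
      cand <- which(dc - fa$rad <= ub)
    }
    cp <- .closestOnTriangles(q, fa$A[cand, , drop = FALSE],
                              fa$B[cand, , drop = FALSE],
                              fa$C[cand, , drop = FALSE])
    d <- .rowNorms(cp - matrix(q, length(cand), 3, byrow = TRUE))
    j <- which.min(d)
    pts[i, ] <- cp[j, ]
    fidx[i] <- cand[j]
    dist[i] <- d[j]
  }
  list(points = pts, faces = fidx, distances = dist)
}

## Moeller-Trumbore ray/triangle intersection of one ray against all faces.
## Returns the parameter t of every forward hit (t > eps) and the face index.
.rayMeshHits <- function(origin, dir, mesh, eps = 1e-9) {
  fa <- .faceArrays(mesh)
  e1 <- fa$B - fa$A
  e2 <- fa$C - fa$A
  k <- nrow(e1)
  dmat <- matrix(dir, k, 3, byrow = TRUE)
  pvec <- cbind(dmat[, 2] * e2[, 3] - dmat[, 3] * e2[, 2],
                dmat[, 3] * e2[, 1] - dmat[, 1] * e2[, 3],
                dmat[, 1] * e2[, 2] - dmat[, 2] * e2[, 1])
  det <- rowSums(e1 * pvec)
  ok <- abs(det) > eps
  tvec <- matrix(origin, k, 3, byrow = TRUE) - fa$A
  u <- rowSums(tvec * pvec) / det
  qvec <- cbind(tvec[, 2] * e1[, 3] - tvec[, 3] * e1[, 2],
                tvec[, 3] * e1[, 1] - tvec[, 1] * e1[, 3],
                tvec[, 1] * e1[, 2] - tvec[, 2] * e1[, 1])
  v <- rowSums(dmat * qvec) / det
  t <- rowSums(e2 * qvec) / det
  hit <- ok & u >= -eps & v >= -eps & (u + v) <= 1 + eps & t > eps
  list(t = t[hit], face = which(hit))
}

## Edge-manifold closedness: every undirected edge used by exactly 2 faces.
.isWatertight <- function(mesh) {
  f <- mesh@faces
  if (!nrow(f)) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

## Area-weighted outward vertex normals (outwardness enforced via the sign
## of the enclosed volume).
.vertexNormals <- function(mesh) {
  fa <- .faceArrays(mesh)
  e1 <- fa$B - fa$A; e2 <- fa$C - fa$A
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vol6 <- sum(rowSums(fa$A * cbind(
    fa$B[, 2] * fa$C[, 3] - fa$B[, 3] * fa$C[, 2],
    fa$B[, 3] * fa$C[, 1] - fa$B[, 1] * fa$C[, 3],
    fa$B[, 1] * fa$C[, 2] - fa$B[, 2] * fa$C[, 1])))
  if (vol6 < 0) fn <- -fn
  f <- mesh@faces
  vn <- matrix(0, nrow(mesh@vertices), 3)
  for (k in 1:3) {
    s <- rowsum(fn, f[, k])
    rows <- as.integer(rownames(s))
    vn[rows, ] <- vn[rows, ] + s
  }
  n <- .rowNorms(vn)
  n[n == 0] <- 1
  vn / n
}

#' Enclosed volume of a closed triangulated mesh
#'
#' Signed-tetrahedron (divergence theorem) summation.  The mesh must be
#' watertight; orientation is handled by taking the absolute value.
#'
#' @param mesh a [HeadMesh-class].
#' @param units \code{"mm3"} or \code{"cm3"}.
#' @return enclosed volume.
#' @export
meshVolume <- function(mesh, units = c("mm3", "cm3")) {
  units <- match.arg(units)
  if (!.isWatertight(mesh))
    stop("mesh is not watertight; enclosed volume is undefined")
  fa <- .faceArrays(mesh)
  vol6 <- rowSums(fa$A * cbind(
    fa$B[, 2] * fa$C[, 3] - fa$B[, 3] * fa$C[, 2],
    fa$B[, 3] * fa$C[, 1] - fa$B[, 1] * fa$C[, 3],
    fa$B[, 1] * fa$C[, 2] - fa$B[, 2] * fa$C[, 1]))
  v <- abs(sum(vol6)) / 6
  if (units == "cm3") v / 1000 else v
}
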