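## The exactly mirror-symmetric head template: a superellipsoid cranium
## blended with nasal and chin protrusions, triangulated as a half mesh plus
## an exact x-negated mirror copy so the symmetry invariant holds to the
## last bit.  Anchors map every anatomical landmark label (and the 40
## constructed cranial-layer labels) to a template vertex.

.superellipsoidRadius <- function(u, ax, ay, az, expo) {
  ## radius along unit direction u so that c + r*u lies on the superellipsoid
  s <- (abs(u[, 1]) / ax)^expo + (abs(u[, 2]) / ay)^expo +
       (abs(u[, 3]) / az)^expo
  s^(-1 / expo)
}

#' Build the symmetric head template
#'
#' The cranial vault is a superellipsoid sized to the canonical mean head
#' (height from V-Gn, depth from PRn-Op, width given by \code{width});
#' nasal and chin protrusions are Gaussian radial bumps centred on the
#' midline directions of PRn and Gn, so the surface passes through those
#' landmarks.  The mesh is built as a half surface plus an exact mirror
#' copy: \code{position(mirror(i))} is the x-negated \code{position(i)}
#' exactly, midline vertices are self-paired with x = 0, and the mesh is
#' watertight.
#'
#' @param radialResolution number of azimuthal steps (even, >= 8).
#' @param verticalResolution number of latitude bands (>= 8).
#' @param width template head width in mm (x extent of the superellipsoid).
#' @param exponent superellipsoid exponent (2 = ellipsoid; larger = squarer).
#' @param bumps include the nasal/chin protrusions (disable to obtain the
#'   pure analytic superellipsoid, e.g. for volume validation).
#' @return a [SymmetricTemplate-class] with all 37 anatomical + 40 layer
#'   anchors placed.
#' @export
#' @examples
#' tpl <- buildTemplate(24, 20)
#' tpl
buildTemplate <- function(radialResolution = 40, verticalResolution = 32,
                          width = 160.98, exponent = 2.5, bumps = TRUE) {
  nr <- as.integer(radialResolution)
  nv <- as.integer(verticalResolution)
  if (nr < 8 || nv < 8) stop("resolutions must be >= 8")
  if (nr %% 2L) nr <- nr + 1L   # even azimuth count => exact midline columns

  lms <- canonicalLandmarks()
  yV <- lmPoint(lms, "V")[2]; yGn <- lmPoint(lms, "Gn")[2]
  zPRn <- lmPoint(lms, "PRn")[3]; zOp <- lmPoint(lms, "Op")[3]
  H <- yV - yGn; L <- zPRn - zOp
  ax <- width / 2
  ay <- H / 2
  az <- 0.40 * L
  ## cranium centred on the canonical vertical axis (z = 0) so scalp rays
  ## from the axis always meet the surface
  center <- c(0, (yV + yGn) / 2, 0)

  ## radial bump model: surface passes through PRn and Gn
  uNose <- .unit(lmPoint(lms, "PRn") - center)
  uChin <- .unit(lmPoint(lms, "Gn") - center)
  ampNose <- sqrt(sum((lmPoint(lms, "PRn") - center)^2)) -
    .superellipsoidRadius(matrix(uNose, 1, 3), ax, ay, az, exponent)
  ampChin <- sqrt(sum((lmPoint(lms, "Gn") - center)^2)) -
    .superellipsoidRadius(matrix(uChin, 1, 3), ax, ay, az, exponent)
  radius <- function(u) {
    r <- .superellipsoidRadius(u, ax, ay, az, exponent)
    if (bumps) {
      angN <- acos(pmin(1, pmax(-1, u %*% uNose)))
      angC <- acos(pmin(1, pmax(-1, u %*% uChin)))
      r <- r + ampNose * exp(-(angN / 0.20)^2) + ampChin * exp(-(angC / 0.35)^2)
    }
    as.numeric(r)
  }

  grid <- .symmetricLatLongMesh(radius, center, nr, nv)
  mesh <- grid$mesh
  mirror <- grid$mirror

  ## anchors: anatomical landmarks -> nearest vertices, mirror-consistently
  anchors <- .placeAnchors(mesh@vertices, mirror, lms)

  ## constructed cranial-layer anchors from the template's own surface
  layers <- layerLandmarks(mesh, lms)
  lco <- lmCoords(layers)
  V <- mesh@vertices
  for (k in seq_len(nrow(lco))) {
    d <- .rowNorms(V - matrix(lco[k, ], nrow(V), 3, byrow = TRUE))
    d[anchors] <- Inf                       # keep anchors unique
    anchors[rownames(lco)[k]] <- which.min(d)
  }

  tpl <- new("SymmetricTemplate", mesh = mesh, mirror = mirror,
             anchors = anchors)
  validObject(tpl)
  tpl
}

## Exactly mirror-symmetric closed lat-long mesh around the y axis: rings
## i = 1..nv-1 at polar angle theta, azimuth j = 0..nr-1 measured from +z;
## the half j = 0..nr/2 is computed from radiusFun, the rest are exact
## x-negated copies, so mirror symmetry holds to the last bit.
.symmetricLatLongMesh <- function(radiusFun, center, nr, nv) {
  nr <- as.integer(nr); nv <- as.integer(nv)
  half <- nr %/% 2L
  nring <- nv - 1L
  nvert <- nring * nr + 2L
  V <- matrix(0, nvert, 3)
  idx <- function(i, j) (i - 1L) * nr + (j %% nr) + 2L  # 1 = top pole
  topPole <- 1L
  botPole <- nvert

  thetas <- pi * seq_len(nring) / nv
  for (i in seq_len(nring)) {
    st <- sin(thetas[i]); ct <- cos(thetas[i])
    for (j in 0:half) {
      a <- 2 * pi * j / nr
      sx <- if (j == 0L || j == half) 0 else sin(a)
      u <- matrix(c(st * sx, ct, st * cos(a)), 1, 3)
      un <- u / sqrt(sum(u * u))
      p <- center + radiusFun(un) * as.numeric(un)
      if (j == 0L || j == half) p[1] <- 0
      V[idx(i, j), ] <- p
      if (j > 0L && j < half)                       # exact mirror copy
        V[idx(i, nr - j), ] <- c(-p[1], p[2], p[3])
    }
  }
  V[topPole, ] <- center + c(0, radiusFun(matrix(c(0, 1, 0), 1, 3)), 0)
  V[botPole, ] <- center + c(0, -radiusFun(matrix(c(0, -1, 0), 1, 3)), 0)

  F <- list()
  for (j in 0:(nr - 1L))
    F[[length(F) + 1]] <- c(topPole, idx(1L, j), idx(1L, j + 1L))
  for (i in seq_len(nring - 1L)) {
    for (j in 0:(nr - 1L)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      F[[length(F) + 1]] <- c(a, cc, d)
      F[[length(F) + 1]] <- c(a, d, b)
    }
  }
  for (j in 0:(nr - 1L))
    F[[length(F) + 1]] <- c(botPole, idx(nring, j + 1L), idx(nring, j))

  mirror <- integer(nvert)
  mirror[topPole] <- topPole; mirror[botPole] <- botPole
  for (i in seq_len(nring))
    for (j in 0:(nr - 1L))
      mirror[idx(i, j)] <- idx(i, (nr - j) %% nr)

  list(mesh = HeadMesh(V, do.call(rbind, F)), mirror = mirror)
}

## nearest-vertex anchor assignment; left anchors are forced to be the exact
## mirrors of the right anchors, midline landmarks snap to midline vertices.
.placeAnchors <- function(V, mirror, lms) {
  midlineVerts <- which(mirror == seq_along(mirror))
  taken <- logical(nrow(V))
  anchors <- integer(0)
  nearestFree <- function(p, cand) {
    cand <- cand[!taken[cand]]
    if (!length(cand)) stop("resolution too low to place template anchors")
    d <- .rowNorms(V[cand, , drop = FALSE] -
                   matrix(p, length(cand), 3, byrow = TRUE))
    cand[which.min(d)]
  }
  for (lab in .midlineLabels()) {
    i <- nearestFree(lmPoint(lms, lab), midlineVerts)
    taken[i] <- TRUE
    anchors[lab] <- i
  }
  leftVerts <- which(V[, 1] > 0)
  for (stem in .bilateralStems()) {
    i <- nearestFree(lmPoint(lms, paste0(stem, "-l")), leftVerts)
    taken[i] <- TRUE; taken[mirror[i]] <- TRUE
    anchors[paste0(stem, "-l")] <- i
    anchors[paste0(stem, "-r")] <- mirror[i]
  }
  anchors
}

#' Anisotropically size the template to a subject
#'
#' Scale factors are chosen so the template's landmark extents match the
#' subject's: width from the Go-r/Go-l span, height from V-Gn, depth from
#' PRn-Op.  Scaling is applied about the canonical origin, component-wise,
#' so the exact mirror pairing is preserved.
#'
#' @param template a [SymmetricTemplate-class].
#' @param lms subject [LandmarkSet-class] in the canonical frame.
#' @return a rescaled [SymmetricTemplate-class]; scale factors in
#'   \code{attr(, "scale")}.
#' @export
scaleTemplate <- function(template, lms) {
  tl <- templateLandmarks(template)
  extents <- function(l) {
    c(w = lmPoint(l, "Go-l")[1] - lmPoint(l, "Go-r")[1],
      h = lmPoint(l, "V")[2] - lmPoint(l, "Gn")[2],
      d = lmPoint(l, "PRn")[3] - lmPoint(l, "Op")[3])
  }
  es <- extents(lms); et <- extents(tl)
  if (any(es <= 0) || any(et <= 0))
    stop("non-positive landmark extent; is the subject in the canonical frame?")
  s <- es / et
  mesh <- template@mesh
  mesh@vertices <- mesh@vertices *
    matrix(s, nrow(mesh@vertices), 3, byrow = TRUE)
  out <- new("SymmetricTemplate", mesh = mesh, mirror = template@mirror,
             anchors = template@anchors)
  attr(out, "scale") <- unname(s)
  out
}

#' Dense closest-point correspondence
#'
#' For every vertex of the (typically TPS-warped) template, the globally
#' nearest point on the subject's triangulated surface in Euclidean
#' distance, found by exact point-to-triangle projection.  The search is
#' pruned with a centroid-radius bound that cannot discard the minimiser,
#' so results equal an exhaustive scan over all triangles.
#'
#' @param x a [HeadMesh-class] or [SymmetricTemplate-class] whose vertices
#'   are the query points.
#' @param subject the subject [HeadMesh-class].
#' @param bruteForce if \code{TRUE}, scan all triangles for every query
#'   (reference path; used for validation).
#' @return a [CorrespondenceMap-class].
#' @export
closestPointMap <- function(x, subject, bruteForce = FALSE) {
  if (is(x, "SymmetricTemplate")) x <- x@mesh
  if (!nrow(subject@faces)) stop("subject mesh is empty")
  queries <- x@vertices
  res <- .closestPointsOnMesh(queries, subject, bruteForce = bruteForce)
  new("CorrespondenceMap", points = res$points,
      faces = as.integer(res$faces), distances = res$distances)
}

#' Serialise a template to PLY plus a JSON sidecar
#'
#' @param template a [SymmetricTemplate-class].
#' @param path output PLY path; the sidecar (mirror pairing and anchors,
#'   0-based) is written next to it with extension \code{.json}.
#' @return invisibly, the sidecar path.
#' @export
writeTemplate <- function(template, path) {
  writeMesh(template@mesh, path, format = "ply")
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(mirror = template@mirror - 1L,
         anchors = as.list(template@anchors - 1L)),
    side, digits = NA, auto_unbox = TRUE)
  invisible(side)
}

#' Read a template written by [writeTemplate()]
#' @param path the PLY path used at write time.
#' @return a [SymmetricTemplate-class].
#' @export
readTemplate <- function(path) {
  mesh <- readMesh(path)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  anchors <- unlist(meta$anchors) + 1L
  new("SymmetricTemplate", mesh = mesh,
      mirror = as.integer(meta$mirror) + 1L,
      anchors = anchors)
}
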