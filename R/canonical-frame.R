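## Canonical head frame: midsagittal plane = {x = 0}, +x toward the
## subject's anatomical left, +y superior, +z anterior, origin at the
## OBi midpoint projected onto the fitted plane.

.bilateralPairs <- function(lms) {
  co <- lms@coords
  stems <- .bilateralStems()
  r <- co[paste0(stems, "-r"), , drop = FALSE]
  l <- co[paste0(stems, "-l"), , drop = FALSE]
  list(right = r, left = l, diff = r - l, mid = (r + l) / 2)
}

#' Estimate the canonical head frame from landmarks
#'
#' The midsagittal plane normal is the dominant direction (leading
#' eigenvector) of the 11 unit right-minus-left bilateral difference vectors;
#' the plane is anchored at the centroid of all pair midpoints and all
#' midline landmarks.  In-plane axes: +z is the in-plane component of
#' PRn - Op (anterior), +y completes the right-handed triad; signs are
#' validated against y(V) > y(Gn) and z(PRn) > z(Op).
#'
#' @param lms a complete [LandmarkSet-class] (all 37 anatomical labels).
#' @return a [CanonicalFrame-class].
#' @export
#' @examples
#' lms <- canonicalLandmarks()
#' fr <- estimateCanonicalFrame(lms)
#' lc <- applyFrame(lms, fr)
estimateCanonicalFrame <- function(lms) {
  checkComplete(lms)
  bp <- .bilateralPairs(lms)
  nrm <- .rowNorms(bp$diff)
  if (all(nrm < 1e-9))
    stop("alignment error: all bilateral pairs are coincident")
  u <- bp$diff[nrm >= 1e-9, , drop = FALSE] / nrm[nrm >= 1e-9]
  M <- crossprod(u)                       # sum of outer products
  xhat <- eigen(M, symmetric = TRUE)$vectors[, 1]
  ## +x toward anatomical left: mean(left - right) projects positively
  if (sum(xhat * colMeans(bp$left - bp$right)) < 0) xhat <- -xhat
  xhat <- .unit(xhat)

  co <- lms@coords
  centroid <- colMeans(rbind(bp$mid, co[.midlineLabels(), , drop = FALSE]))

  w <- lmPoint(lms, "PRn") - lmPoint(lms, "Op")
  w <- w - sum(w * xhat) * xhat
  if (sqrt(sum(w * w)) < 1e-9)
    stop("alignment error: PRn and Op do not define an anterior axis")
  zhat <- .unit(w)
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])   # z x x = y

  if (sum(yhat * (lmPoint(lms, "V") - lmPoint(lms, "Gn"))) < 0)
    warning("canonical frame: V is not superior to Gn under the fitted axes")

  obiMid <- (lmPoint(lms, "OBi-r") + lmPoint(lms, "OBi-l")) / 2
  origin <- obiMid - sum((obiMid - centroid) * xhat) * xhat

  CanonicalFrame(rotation = rbind(xhat, yhat, zhat, deparse.level = 0),
                 translation = origin)
}

.transformPoints <- function(m, frame, inverse = FALSE) {
  R <- frame@rotation
  t <- frame@translation
  if (inverse)
    m %*% R + matrix(t, nrow(m), 3, byrow = TRUE)
  else
    (m - matrix(t, nrow(m), 3, byrow = TRUE)) %*% t(R)
}

#' @rdname applyFrame
setMethod("applyFrame", "matrix", function(x, frame, inverse = FALSE) {
  .transformPoints(x, frame, inverse)
})

#' @rdname applyFrame
setMethod("applyFrame", "LandmarkSet", function(x, frame, inverse = FALSE) {
  m <- .transformPoints(x@coords, frame, inverse)
  rownames(m) <- rownames(x@coords)
  LandmarkSet(m)
})

#' @rdname applyFrame
setMethod("applyFrame", "HeadMesh", function(x, frame, inverse = FALSE) {
  HeadMesh(.transformPoints(x@vertices, frame, inverse), x@faces,
           scalars = x@scalars)
})
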