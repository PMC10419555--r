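## Thin-plate-spline warp with the 3D biharmonic kernel U(r) = r.
## With lambda = 0 the warp interpolates the control pairs exactly; the
## affine part reproduces any exactly-affine control relation with zero
## kernel weights.

.pairwiseDist <- function(a, b) {
  ## |a_i - b_j| without forming cubes; a: n x 3, b: m x 3
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Fit a thin-plate-spline warp
#'
#' Solves the standard bordered linear system for the kernel weights and the
#' affine part.  \code{lambda = 0} gives exact interpolation at the controls;
#' \code{lambda > 0} trades interpolation for smoothness.
#'
#' @param sources n x 3 matrix of control source points (n >= 4,
#'   non-coplanar, no duplicates).
#' @param targets n x 3 matrix of control target points.
#' @param lambda regularisation, >= 0.
#' @return a [TPSWarp-class].
#' @export
#' @examples
#' src <- matrix(rnorm(30), 10, 3)
#' w <- fitTPS(src, src + 1)   # pure translation
#' max(abs(warpPoints(w, src) - (src + 1)))
fitTPS <- function(sources, targets, lambda = 0) {
  sources <- as.matrix(sources); targets <- as.matrix(targets)
  n <- nrow(sources)
  if (n < 4) stop("at least 4 control pairs are required")
  if (nrow(targets) != n) stop("sources and targets must pair up")
  if (lambda < 0) stop("lambda must be >= 0")

  K <- .pairwiseDist(sources, sources)
  dup <- which(K < 1e-12 & upper.tri(K), arr.ind = TRUE)
  if (nrow(dup))
    stop("singular TPS system: duplicate control sources at rows ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "))
  sv <- svd(scale(sources, center = TRUE, scale = FALSE))$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("singular TPS system: control sources are coplanar")

  P <- cbind(1, sources)
  L <- rbind(cbind(K + diag(lambda, n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(targets, matrix(0, 4, 3))
  sol <- solve(L, rhs)
  new("TPSWarp", sources = sources, targets = targets,
      affine = sol[(n + 1):(n + 4), , drop = FALSE],
      weights = sol[1:n, , drop = FALSE], lambda = lambda)
}

#' Apply a thin-plate-spline warp to points
#'
#' @param warp a [TPSWarp-class] from [fitTPS()].
#' @param pts m x 3 matrix of points (or a length-3 vector).
#' @return m x 3 matrix of warped points.
#' @export
warpPoints <- function(warp, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1, 3)
  pts <- as.matrix(pts)
  U <- .pairwiseDist(pts, warp@sources)
  cbind(1, pts) %*% warp@affine + U %*% warp@weights
}

#' Apply a thin-plate-spline warp to a mesh or template
#'
#' A warped template is in general no longer mirror-symmetric (that is the
#' point: it now follows the subject), so the result is always returned as a
#' plain [HeadMesh-class]; keep the template's mirror pairing and anchors
#' alongside it for the asymmetry stage.
#'
#' @param warp a [TPSWarp-class].
#' @param x a [HeadMesh-class] or [SymmetricTemplate-class].
#' @return a [HeadMesh-class] with warped vertices.
#' @export
warpMesh <- function(warp, x) {
  if (is(x, "SymmetricTemplate")) x <- x@mesh
  HeadMesh(warpPoints(warp, x@vertices), x@faces, scalars = x@scalars)
}

#' Bending energy of a fitted warp
#'
#' Zero exactly when the control relation is affine.
#'
#' @param warp a [TPSWarp-class].
#' @return non-negative scalar (kernel quadratic form, summed over x/y/z).
#' @export
tpsBendingEnergy <- function(warp) {
  ## U(r) = r is conditionally negative definite on the constraint subspace
  ## (zero column sums), so the energy quadratic form carries a minus sign
  K <- .pairwiseDist(warp@sources, warp@sources)
  max(0, -sum(warp@weights * (K %*% warp@weights)))
}
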