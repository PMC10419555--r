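#' @import methods
NULL

## ---------------------------------------------------------------------------
## Landmark vocabulary
## ---------------------------------------------------------------------------

#' The closed vocabulary of 37 anatomical soft-tissue landmarks
#'
#' Midline labels (15): G, N, PRn, Sn, C, Ls, Li, Sto, B, Pg, Gn, V, Op, O,
#' Cer.  Bilateral labels (11 pairs): Ala, Nb, As, Ex, En, Cph, Ch, Go, OBs,
#' OBi, L, each with a \code{-r} and \code{-l} suffix (subject's right/left).
#' Constructed cranial-layer labels of the form \code{Layer<k>-<j>} are also
#' accepted by [LandmarkSet()] but are not part of the anatomical battery.
#'
#' @return Character vector of the 37 anatomical labels.
#' @export
#' @examples
#' length(landmarkVocabulary())  # 37
landmarkVocabulary <- function() {
  c(.midlineLabels(),
    paste0(rep(.bilateralStems(), each = 2), c("-r", "-l")))
}

.midlineLabels <- function() {
  c("G", "N", "PRn", "Sn", "C", "Ls", "Li", "Sto", "B", "Pg", "Gn",
    "V", "Op", "O", "Cer")
}

.bilateralStems <- function() {
  c("Ala", "Nb", "As", "Ex", "En", "Cph", "Ch", "Go", "OBs", "OBi", "L")
}

.isLayerLabel <- function(x) grepl("^Layer[0-9]+-[0-9]+$", x)

## ---------------------------------------------------------------------------
## HeadMesh
## ---------------------------------------------------------------------------

#' Triangulated head-surface mesh
#'
#' @slot vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#' @slot scalars optional per-vertex scalar channel (length 0 or n-vertices),
#'   used e.g. for asymmetry heat maps.
#'
#' @name HeadMesh-class
#' @aliases HeadMesh-class
#' @exportClass HeadMesh
setClass("HeadMesh",
  representation(vertices = "matrix", faces = "matrix", scalars = "numeric"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3), scalars = numeric(0))
)

setValidity("HeadMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must have 3 columns")
  if (ncol(f) != 3L) return("faces must have 3 columns")
  if (length(v) && !all(is.finite(v))) return("vertex coordinates must be finite")
  if (nrow(f)) {
    if (min(f) < 1L || max(f) > nrow(v))
      return("face indices out of range")
  }
  if (length(object@scalars) && length(object@scalars) != nrow(v))
    return("scalar channel length must match vertex count")
  TRUE
})

#' Construct a HeadMesh
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param scalars optional per-vertex numeric channel.
#' @return A [HeadMesh-class] object.
#' @export
HeadMesh <- function(vertices, faces, scalars = numeric(0)) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  colnames(vertices) <- c("x", "y", "z")
  dimnames(faces) <- NULL
  new("HeadMesh", vertices = vertices, faces = faces,
      scalars = as.numeric(scalars))
}

setMethod("show", "HeadMesh", function(object) {
  cat("HeadMesh:", nrow(object@vertices), "vertices,",
      nrow(object@faces), "faces",
      if (length(object@scalars)) "(with scalar channel)" else "", "\n")
})

#' @describeIn HeadMesh-class vertex coordinate matrix
#' @param x,object a \code{HeadMesh}
#' @export
meshVertices <- function(x) x@vertices

#' @describeIn HeadMesh-class face index matrix (1-based)
#' @export
meshFaces <- function(x) x@faces

#' @describeIn HeadMesh-class per-vertex scalar channel (may be empty)
#' @export
meshScalars <- function(x) x@scalars

## ---------------------------------------------------------------------------
## LandmarkSet
## ---------------------------------------------------------------------------

#' Named 3D landmark configuration
#'
#' A mapping from landmark labels to 3D points (mm).  Labels must come from
#' the closed 37-label anatomical vocabulary ([landmarkVocabulary()]) or be
#' constructed cranial-layer labels \code{Layer<k>-<j>}.
#'
#' @slot coords numeric matrix with one labelled row per landmark.
#' @name LandmarkSet-class
#' @exportClass LandmarkSet
setClass("LandmarkSet", representation(coords = "matrix"))

setValidity("LandmarkSet", function(object) {
  m <- object@coords
  if (ncol(m) != 3L) return("coords must have 3 columns")
  lab <- rownames(m)
  if (is.null(lab)) return("coords must have row labels")
  if (anyDuplicated(lab)) {
    return(paste0("duplicate landmark label(s): ",
                  paste(unique(lab[duplicated(lab)]), collapse = ", ")))
  }
  bad <- setdiff(lab, landmarkVocabulary())
  bad <- bad[!.isLayerLabel(bad)]
  if (length(bad))
    return(paste0("label(s) outside the landmark vocabulary: ",
                  paste(bad, collapse = ", ")))
  if (length(m) && !all(is.finite(m))) return("coordinates must be finite")
  ## bilateral labels must come in complete -r/-l pairs
  for (stem in .bilateralStems()) {
    r <- paste0(stem, "-r") %in% lab
    l <- paste0(stem, "-l") %in% lab
    if (xor(r, l))
      return(paste0("incomplete bilateral pair for ", stem))
  }
  TRUE
})

#' Construct a LandmarkSet
#'
#' @param coords numeric matrix (rows = landmarks, columns = x/y/z in mm)
#'   with row names giving labels, or a named list of length-3 points.
#' @return A [LandmarkSet-class] object.
#' @export
LandmarkSet <- function(coords) {
  if (is.list(coords))
    coords <- do.call(rbind, lapply(coords, function(p) as.numeric(p)))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  new("LandmarkSet", coords = coords)
}

setMethod("show", "LandmarkSet", function(object) {
  lab <- rownames(object@coords)
  nanat <- sum(lab %in% landmarkVocabulary())
  cat("LandmarkSet:", nrow(object@coords), "landmarks (",
      nanat, "anatomical,", sum(.isLayerLabel(lab)), "layer )\n")
})

#' @describeIn LandmarkSet-class coordinate matrix with labelled rows
#' @param x a \code{LandmarkSet}
#' @export
lmCoords <- function(x) x@coords

#' @describeIn LandmarkSet-class landmark labels
#' @export
lmLabels <- function(x) rownames(x@coords)

#' Extract one landmark as a length-3 point
#' @param x a \code{LandmarkSet}
#' @param label landmark label
#' @return numeric length-3 vector (mm)
#' @export
lmPoint <- function(x, label) {
  if (!label %in% rownames(x@coords))
    stop("landmark not present: ", label)
  as.numeric(x@coords[label, ])
}

#' Check that all 37 anatomical landmarks are present
#' @param x a \code{LandmarkSet}
#' @param context character, used in the error message
#' @return invisibly \code{TRUE}; errors listing missing labels otherwise
#' @export
checkComplete <- function(x, context = "landmark set") {
  missing <- setdiff(landmarkVocabulary(), rownames(x@coords))
  if (length(missing))
    stop(context, " is missing landmark(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## CanonicalFrame
## ---------------------------------------------------------------------------

#' Canonical head coordinate frame
#'
#' Rigid transform into the frame in which the fitted midsagittal plane is
#' \{x = 0\}, +x points toward the subject's anatomical left, +y superior and
#' +z anterior; the origin is the midpoint of OBi-r/OBi-l projected onto the
#' midsagittal plane.  Canonical coordinates of a point p are
#' \code{rotation \%*\% (p - translation)}.
#'
#' @slot rotation 3 x 3 orthonormal matrix (rows = canonical axes), det +1.
#' @slot translation length-3 origin of the frame in input coordinates.
#' @name CanonicalFrame-class
#' @exportClass CanonicalFrame
setClass("CanonicalFrame",
         representation(rotation = "matrix", translation = "numeric"))

setValidity("CanonicalFrame", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthonormal to 1e-9")
  if (abs(det(R) - 1) > 1e-9) return("rotation must have det +1")
  if (length(object@translation) != 3L) return("translation must be length 3")
  TRUE
})

#' @rdname CanonicalFrame-class
#' @param rotation,translation slots, see class description
#' @export
CanonicalFrame <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("CanonicalFrame", rotation = rotation,
      translation = as.numeric(translation))
}

setMethod("show", "CanonicalFrame", function(object) {
  cat("CanonicalFrame: origin (",
      paste(sprintf("%.2f", object@translation), collapse = ", "),
      ") mm\n")
})

## ---------------------------------------------------------------------------
## SymmetricTemplate
## ---------------------------------------------------------------------------

#' Exactly mirror-symmetric head template
#'
#' @slot mesh the template [HeadMesh-class].
#' @slot mirror integer vector: \code{mirror[i]} is the vertex paired with
#'   vertex i across the midsagittal plane; midline vertices are self-paired.
#' @slot anchors named integer vector mapping landmark labels (37 anatomical
#'   + constructed layer labels) to template vertex indices.
#' @name SymmetricTemplate-class
#' @exportClass SymmetricTemplate
setClass("SymmetricTemplate",
  representation(mesh = "HeadMesh", mirror = "integer", anchors = "integer"))

setValidity("SymmetricTemplate", function(object) {
  v <- object@mesh@vertices
  m <- object@mirror
  if (length(m) != nrow(v)) return("mirror pairing length must match vertices")
  if (!identical(m[m], seq_along(m))) return("mirror pairing must be involutive")
  mid <- which(m == seq_along(m))
  if (length(mid) && any(v[mid, 1] != 0))
    return("midline (self-paired) vertices must have x = 0")
  ## exact mirror geometry: position(m(i)) = x-negated position(i)
  if (any(v[m, 1] != -v[, 1]) || any(v[m, 2] != v[, 2]) ||
      any(v[m, 3] != v[, 3]))
    return("mirror pairs must be exact x-negated copies")
  if (is.null(names(object@anchors))) return("anchors must be named")
  if (length(object@anchors) &&
      (min(object@anchors) < 1L || max(object@anchors) > nrow(v)))
    return("anchor vertex indices out of range")
  TRUE
})

setMethod("show", "SymmetricTemplate", function(object) {
  cat("SymmetricTemplate:", nrow(object@mesh@vertices), "vertices,",
      sum(object@mirror == seq_along(object@mirror)), "midline,",
      length(object@anchors), "anchors\n")
})

#' @describeIn SymmetricTemplate-class the template mesh
#' @param x a \code{SymmetricTemplate}
#' @export
templateMesh <- function(x) x@mesh

#' @describeIn SymmetricTemplate-class involutive mirror pairing
#' @export
templateMirror <- function(x) x@mirror

#' @describeIn SymmetricTemplate-class named anchor vertex indices
#' @export
templateAnchors <- function(x) x@anchors

#' Landmark positions at the template's anchor vertices
#' @param x a \code{SymmetricTemplate}
#' @return a [LandmarkSet-class] of the anchor positions
#' @export
templateLandmarks <- function(x) {
  m <- x@mesh@vertices[x@anchors, , drop = FALSE]
  rownames(m) <- names(x@anchors)
  LandmarkSet(m)
}

## ---------------------------------------------------------------------------
## TPSWarp
## ---------------------------------------------------------------------------

#' Thin-plate-spline warp in 3D
#'
#' Landmark-interpolating deformation with the 3D biharmonic kernel
#' U(r) = r: \code{f(p) = A^T [1, p] + sum_i w_i U(|p - c_i|)}.
#'
#' @slot sources n x 3 control source points.
#' @slot targets n x 3 control target points.
#' @slot affine 4 x 3 affine part (rows: intercept, x, y, z).
#' @slot weights n x 3 kernel weights.
#' @slot lambda regularisation used at fit time (0 = exact interpolation).
#' @name TPSWarp-class
#' @exportClass TPSWarp
setClass("TPSWarp",
  representation(sources = "matrix", targets = "matrix", affine = "matrix",
                 weights = "matrix", lambda = "numeric"))

setValidity("TPSWarp", function(object) {
  n <- nrow(object@sources)
  if (!all(dim(object@affine) == c(4L, 3L))) return("affine must be 4 x 3")
  if (nrow(object@weights) != n) return("one weight row per control")
  if (object@lambda < 0) return("lambda must be >= 0")
  TRUE
})

setMethod("show", "TPSWarp", function(object) {
  cat("TPSWarp:", nrow(object@sources), "controls, lambda =",
      object@lambda, "\n")
})

## ---------------------------------------------------------------------------
## CorrespondenceMap
## ---------------------------------------------------------------------------

#' Dense template-to-subject correspondence
#'
#' For every template vertex, the globally nearest point on the subject's
#' triangulated surface, the triangle carrying it, and the distance.
#'
#' @slot points n x 3 matched surface points on the subject (mm).
#' @slot faces integer vector of matched subject face indices.
#' @slot distances numeric vector of Euclidean distances (mm).
#' @name CorrespondenceMap-class
#' @exportClass CorrespondenceMap
setClass("CorrespondenceMap",
  representation(points = "matrix", faces = "integer", distances = "numeric"))

setValidity("CorrespondenceMap", function(object) {
  n <- nrow(object@points)
  if (length(object@faces) != n || length(object@distances) != n)
    return("points, faces and distances must agree in length")
  if (length(object@distances) && any(object@distances < 0))
    return("distances must be non-negative")
  TRUE
})

setMethod("show", "CorrespondenceMap", function(object) {
  cat("CorrespondenceMap:", nrow(object@points), "vertices, mean distance",
      sprintf("%.3f", mean(object@distances)), "mm\n")
})

#' @describeIn CorrespondenceMap-class matched surface points
#' @param x a \code{CorrespondenceMap}
#' @export
corrPoints <- function(x) x@points

#' @describeIn CorrespondenceMap-class matched face indices
#' @export
corrFaces <- function(x) x@faces

#' @describeIn CorrespondenceMap-class match distances (mm)
#' @export
corrDistances <- function(x) x@distances

## ---------------------------------------------------------------------------
## AsymmetryResult
## ---------------------------------------------------------------------------

#' Per-subject asymmetry summary
#'
#' @slot pairIndex p x 2 integer matrix of (left vertex, mirrored right
#'   vertex) template index pairs (left representative has x > 0).
#' @slot pairValues per-pair asymmetry (mm), |d_L - d_R| of origin distances.
#' @slot faceMask logical per pair: representative vertex inside the facial
#'   region (closer to PRn than to Gn).
#' @slot AH mean asymmetry over all pairs (whole head, mm).
#' @slot AF mean asymmetry over facial pairs (mm).
#' @slot metrics named list with head metrics H, L, W (mm) and V (cm^3),
#'   possibly empty.
#' @slot vertexValues per-template-vertex heat-map scalar (pair value on both
#'   pair members, 0 on the midline).
#' @name AsymmetryResult-class
#' @exportClass AsymmetryResult
setClass("AsymmetryResult",
  representation(pairIndex = "matrix", pairValues = "numeric",
                 faceMask = "logical", AH = "numeric", AF = "numeric",
                 metrics = "list", vertexValues = "numeric"))

setValidity("AsymmetryResult", function(object) {
  p <- nrow(object@pairIndex)
  if (length(object@pairValues) != p || length(object@faceMask) != p)
    return("pairValues and faceMask must have one entry per pair")
  if (length(object@pairValues) && any(object@pairValues < 0))
    return("asymmetry values must be non-negative")
  TRUE
})

setMethod("show", "AsymmetryResult", function(object) {
  cat(sprintf("AsymmetryResult: %d pairs, AH = %.3f mm, AF = %.3f mm\n",
              nrow(object@pairIndex), object@AH, object@AF))
})

#' @describeIn AsymmetryResult-class whole-head mean asymmetry (mm)
#' @param x an \code{AsymmetryResult}
#' @export
asymAH <- function(x) x@AH

#' @describeIn AsymmetryResult-class facial mean asymmetry (mm)
#' @export
asymAF <- function(x) x@AF

#' @describeIn AsymmetryResult-class per-pair values (mm)
#' @export
asymPairValues <- function(x) x@pairValues

#' @describeIn AsymmetryResult-class head metrics list (H, L, W, V)
#' @export
asymMetrics <- function(x) x@metrics
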