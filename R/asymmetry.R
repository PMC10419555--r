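## Left-right asymmetry scoring: constructed cranial-layer landmarks,
## facial/cranial region masks, per-mirror-pair asymmetry from origin
## distances, whole-head and facial summaries (AH, AF), head metrics
## (H, L, W, V) and heat-map export.

#' Construct the cranial-layer landmarks
#'
#' Places \code{nLayers * perLayer} constructed landmarks on the scalp:
#' layer heights are evenly spaced strictly between the OBs level (mean of
#' OBs-r/OBs-l) and the vertex V; at each height, rays are cast from the y
#' axis at azimuths \code{360 * j / perLayer} degrees (j = 0 .. perLayer-1,
#' 0 degrees = +z, anterior) and the farthest surface intersection is taken.
#'
#' @param mesh subject [HeadMesh-class] in the canonical frame.
#' @param lms subject [LandmarkSet-class] (provides the OBs and V levels).
#' @param nLayers,perLayer layer count and landmarks per layer (default
#'   4 x 10 = 40).
#' @return a [LandmarkSet-class] with labels \code{Layer<k>-<j>}.
#' @export
layerLandmarks <- function(mesh, lms, nLayers = 4, perLayer = 10) {
  yLo <- (lmPoint(lms, "OBs-r")[2] + lmPoint(lms, "OBs-l")[2]) / 2
  yHi <- lmPoint(lms, "V")[2]
  if (!(yHi > yLo))
    stop("vertical span for the cranial layers is not well-defined")
  heights <- yLo + seq_len(nLayers) * (yHi - yLo) / (nLayers + 1)
  out <- matrix(0, nLayers * perLayer, 3)
  labs <- character(nLayers * perLayer)
  r <- 0L
  for (k in seq_len(nLayers)) {
    for (j in 0:(perLayer - 1L)) {
      a <- 2 * pi * j / perLayer
      dir <- c(sin(a), 0, cos(a))
      hits <- .rayMeshHits(c(0, heights[k], 0), dir, mesh)
      if (!length(hits$t))
        stop(sprintf("layer ray misses the mesh (layer %d, azimuth %g deg)",
                     k, 360 * j / perLayer))
      t <- max(hits$t)          # farthest intersection = outer scalp surface
      r <- r + 1L
      out[r, ] <- c(0, heights[k], 0) + t * dir
      labs[r] <- sprintf("Layer%d-%d", k, j)
    }
  }
  rownames(out) <- labs
  LandmarkSet(out)
}

#' Facial region mask
#'
#' A vertex belongs to the facial region iff its distance to the pronasale
#' is less than or equal to its distance to the gnathion; the complement is
#' the cranial (skull) region.  The boundary is the perpendicular bisector
#' plane of the PRn-Gn segment.
#'
#' @param x a [HeadMesh-class] or [SymmetricTemplate-class].
#' @param prn,gn the pronasale and gnathion positions (default: the
#'   template's own anchors when \code{x} is a template).
#' @return logical vector, one entry per vertex (TRUE = facial).
#' @export
facialRegion <- function(x, prn = NULL, gn = NULL) {
  if (is(x, "SymmetricTemplate")) {
    tl <- templateLandmarks(x)
    if (is.null(prn)) prn <- lmPoint(tl, "PRn")
    if (is.null(gn)) gn <- lmPoint(tl, "Gn")
    v <- x@mesh@vertices
  } else {
    v <- x@vertices
  }
  if (is.null(prn) || is.null(gn))
    stop("prn and gn are required for a plain mesh")
  if (all(prn == gn)) stop("PRn and Gn coincide")
  dP <- .rowNorms(v - matrix(prn, nrow(v), 3, byrow = TRUE))
  dG <- .rowNorms(v - matrix(gn, nrow(v), 3, byrow = TRUE))
  dP <= dG
}

#' Per-mirror-pair asymmetry
#'
#' For each template mirror pair (i, m(i)) with left representative
#' (template x > 0), the asymmetry is the absolute difference between the
#' origin distance of the left matched subject point and that of the right
#' matched point: \code{| |p_i - o| - |p_m(i) - o| |}.  Midline vertices
#' (self-paired) are excluded.  The \code{"displacement"} alternative uses
#' the distance between the left matched point and the x-mirrored right
#' matched point instead.
#'
#' @param corr a [CorrespondenceMap-class] (template vertex -> subject
#'   surface point).
#' @param template the [SymmetricTemplate-class] that was matched (provides
#'   the mirror pairing and the left/right labelling).
#' @param origin length-3 origin (canonical frame origin by default).
#' @param method \code{"origin"} (origin-distance difference) or
#'   \code{"displacement"}.
#' @return list with \code{pairIndex} (p x 2: left, right vertex indices)
#'   and \code{values} (mm).
#' @export
pointwiseAsymmetry <- function(corr, template, origin = c(0, 0, 0),
                               method = c("origin", "displacement")) {
  method <- match.arg(method)
  mirror <- template@mirror
  if (nrow(corr@points) != length(mirror))
    stop("correspondence does not cover every template vertex")
  left <- which(template@mesh@vertices[, 1] > 0)
  pairIndex <- cbind(left = left, right = mirror[left])
  pL <- corr@points[pairIndex[, 1], , drop = FALSE]
  pR <- corr@points[pairIndex[, 2], , drop = FALSE]
  if (method == "origin") {
    o <- matrix(origin, nrow(pL), 3, byrow = TRUE)
    values <- abs(.rowNorms(pL - o) - .rowNorms(pR - o))
  } else {
    pRm <- pR; pRm[, 1] <- -pRm[, 1]
    values <- .rowNorms(pL - pRm)
  }
  list(pairIndex = pairIndex, values = values)
}

#' Summarise per-pair asymmetry into AH and AF
#'
#' @param values per-pair asymmetry values (mm).
#' @param faceMask logical per pair (left representative in the facial
#'   region).
#' @return list with \code{AH} (mean over all pairs) and \code{AF} (mean
#'   over facial pairs), both mm.
#' @export
asymmetrySummary <- function(values, faceMask) {
  if (!length(values)) stop("no asymmetry pairs")
  if (!any(faceMask)) stop("empty facial mask")
  list(AH = mean(values), AF = mean(values[faceMask]))
}

#' Head metrics H, L, W, V
#'
#' H = y(V) - y(Gn) from the landmarks; L and W are the z and x extents of
#' the mesh; V is the enclosed volume (signed-tetrahedron summation),
#' reported in cm^3.  The subject must be in the canonical frame and the
#' mesh watertight for the volume.
#'
#' @param mesh subject [HeadMesh-class].
#' @param lms subject [LandmarkSet-class].
#' @return named list H, L, W (mm) and V (cm^3).
#' @export
headMetrics <- function(mesh, lms) {
  v <- mesh@vertices
  list(H = lmPoint(lms, "V")[2] - lmPoint(lms, "Gn")[2],
       L = max(v[, 3]) - min(v[, 3]),
       W = max(v[, 1]) - min(v[, 1]),
       V = meshVolume(mesh, units = "cm3"))
}

#' Full per-subject asymmetry analysis
#'
#' Orchestrates the per-subject pipeline: canonical alignment, cranial-layer
#' construction, template sizing, thin-plate-spline warp on the paired
#' landmarks (37 anatomical + 40 layer), closest-point correspondence, and
#' asymmetry scoring.
#'
#' @param mesh subject [HeadMesh-class] (any rigid pose).
#' @param lms subject [LandmarkSet-class] (the 37 anatomical landmarks).
#' @param template a [SymmetricTemplate-class]; built at default resolution
#'   when omitted.
#' @param lambda TPS regularisation (0 = exact interpolation).
#' @param iterations closest-point passes (1 = single pass; further passes
#'   move the template onto its matched points and re-match).
#' @param method per-pair statistic, see [pointwiseAsymmetry()].
#' @return an [AsymmetryResult-class].
#' @export
analyzeAsymmetry <- function(mesh, lms, template = NULL, lambda = 0,
                             iterations = 1,
                             method = c("origin", "displacement")) {
  method <- match.arg(method)
  if (is.null(template)) template <- buildTemplate()
  frame <- estimateCanonicalFrame(lms)
  lmsC <- applyFrame(lms, frame)
  meshC <- applyFrame(mesh, frame)

  layers <- layerLandmarks(meshC, lmsC)
  scaled <- scaleTemplate(template, lmsC)

  anchors <- templateAnchors(scaled)
  targets <- rbind(lmCoords(lmsC)[landmarkVocabulary(), , drop = FALSE],
                   lmCoords(layers))
  sources <- scaled@mesh@vertices[anchors[rownames(targets)], , drop = FALSE]
  warp <- fitTPS(sources, targets, lambda = lambda)
  warped <- warpMesh(warp, scaled@mesh)

  corr <- closestPointMap(warped, meshC)
  it <- 1
  while (it < iterations) {
    warped@vertices <- corr@points
    corr <- closestPointMap(warped, meshC)
    it <- it + 1
  }

  pw <- pointwiseAsymmetry(corr, scaled, origin = c(0, 0, 0),
                           method = method)
  faceMaskV <- facialRegion(scaled)
  faceMask <- faceMaskV[pw$pairIndex[, 1]]
  s <- asymmetrySummary(pw$values, faceMask)
  metrics <- headMetrics(meshC, lmsC)

  vertexValues <- numeric(length(scaled@mirror))
  vertexValues[pw$pairIndex[, 1]] <- pw$values
  vertexValues[pw$pairIndex[, 2]] <- pw$values

  new("AsymmetryResult", pairIndex = pw$pairIndex, pairValues = pw$values,
      faceMask = faceMask, AH = s$AH, AF = s$AF, metrics = metrics,
      vertexValues = vertexValues)
}

## fixed 0-5 mm heat scale so per-group maps are comparable across subjects
.heatColors <- function(values, limits = c(0, 5)) {
  ramp <- grDevices::colorRamp(c("#00007F", "#0000FF", "#00FFFF",
                                 "#FFFF00", "#FF0000"))
  x <- pmin(pmax((values - limits[1]) / diff(limits), 0), 1)
  round(ramp(x))
}

#' Export an asymmetry heat map
#'
#' Writes the template mesh as PLY with a per-vertex scalar channel
#' (\code{quality}) holding the asymmetry value (each vertex and its mirror
#' carry the pair value; midline vertices carry 0) and an 8-bit colour ramp
#' on a fixed 0-5 mm scale (clipped).
#'
#' @param template a [SymmetricTemplate-class] (or any [HeadMesh-class]).
#' @param vertexValues per-vertex scalar, e.g.
#'   \code{asymResult@vertexValues}.
#' @param path output PLY path.
#' @param limits colour scale limits in mm.
#' @param views optional directory: if non-NULL, PNG renders of the four
#'   canonical views are written there (facial frontal, craniofacial
#'   frontal, left and right lateral).
#' @return invisibly, \code{path}.
#' @export
exportHeatmap <- function(template, vertexValues, path, limits = c(0, 5),
                          views = NULL) {
  mesh <- if (is(template, "SymmetricTemplate")) template@mesh else template
  mesh@scalars <- as.numeric(vertexValues)
  cols <- .heatColors(vertexValues, limits)
  writeMesh(mesh, path, format = "ply", colors = cols)
  if (!is.null(views)) .renderViews(mesh, cols, views)
  invisible(path)
}

## Painter's-algorithm orthographic renders of the four canonical views.
.renderViews <- function(mesh, cols, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- mesh@vertices; f <- mesh@faces
  hex <- grDevices::rgb(cols[, 1], cols[, 2], cols[, 3], maxColorValue = 255)
  views <- list(
    facial_frontal = list(ax = c(1, 2), depth = 3, flip = 1, zoom = TRUE),
    craniofacial_frontal = list(ax = c(1, 2), depth = 3, flip = 1,
                                zoom = FALSE),
    left_lateral = list(ax = c(3, 2), depth = 1, flip = 1, zoom = FALSE),
    right_lateral = list(ax = c(3, 2), depth = 1, flip = -1, zoom = FALSE)
  )
  for (nm in names(views)) {
    vw <- views[[nm]]
    px <- v[, vw$ax[1]] * vw$flip
    py <- v[, vw$ax[2]]
    depth <- rowMeans(matrix(v[t(f), vw$depth], ncol = 3, byrow = TRUE)) *
      (if (vw$depth == 1 && vw$flip == -1) -1 else 1)
    ord <- order(depth)
    fcol <- hex[f[, 1]]
    file <- file.path(dir, paste0(nm, ".png"))
    grDevices::png(file, width = 480, height = 480)
    graphics::par(mar = c(0, 0, 0, 0))
    ylim <- if (vw$zoom) {
      lo <- stats::quantile(py, 0.05); c(lo, lo + 0.6 * (max(py) - lo))
    } else range(py)
    graphics::plot(NA, xlim = range(px), ylim = ylim, asp = 1, axes = FALSE,
                   xlab = "", ylab = "")
    for (k in ord)
      graphics::polygon(px[f[k, ]], py[f[k, ]], col = fcol[k], border = NA)
    grDevices::dev.off()
  }
  invisible(dir)
}
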