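## The 14-parameter soft-tissue measurement battery: 8 linear and 6 angular
## parameters computed from the 37-landmark configuration.  Short codes
## a'-n' follow the conventional table layout; degrees and mm throughout.

#' Euclidean distance between two points
#' @param p,q length-3 points (mm).
#' @return distance in mm.
#' @export
pointDistance <- function(p, q) {
  d <- as.numeric(p) - as.numeric(q)
  sqrt(sum(d * d))
}

#' Perpendicular distance from a point to an infinite line
#'
#' Distance from \code{p} to the line through \code{a} and \code{b}.  When
#' \code{signedAxis} is given, the result is signed by the component of the
#' residual (p minus its projection onto the line) along that axis; the
#' canonical choice \code{+z} makes anterior displacements positive.
#'
#' @param p query point; \code{a}, \code{b} two distinct points on the line.
#' @param signedAxis optional length-3 direction for the sign.
#' @return distance in mm (signed if \code{signedAxis} is given).
#' @export
pointLineDistance <- function(p, a, b, signedAxis = NULL) {
  p <- as.numeric(p); a <- as.numeric(a); b <- as.numeric(b)
  d <- b - a
  len2 <- sum(d * d)
  if (len2 == 0) stop("degenerate line: a and b coincide")
  t <- sum((p - a) * d) / len2
  res <- p - (a + t * d)
  dist <- sqrt(sum(res * res))
  if (is.null(signedAxis)) return(dist)
  s <- sum(res * as.numeric(signedAxis))
  if (s < 0) -dist else dist
}

#' Angle at a vertex
#'
#' The angle between rays v->a and v->b, in degrees, in (0, 180].
#'
#' @param a,v,b length-3 points; \code{v} is the vertex.
#' @return angle in degrees.
#' @export
vertexAngle <- function(a, v, b) {
  u <- as.numeric(a) - as.numeric(v)
  w <- as.numeric(b) - as.numeric(v)
  nu <- sqrt(sum(u * u)); nw <- sqrt(sum(w * w))
  if (nu == 0 || nw == 0)
    stop("degenerate angle: a point coincides with the vertex")
  cosang <- sum(u * w) / (nu * nw)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Angle between two directed segments
#'
#' The angle between the vectors a2 - a1 and b2 - b1, in degrees (0, 180].
#'
#' @param a1,a2 endpoints of the first segment.
#' @param b1,b2 endpoints of the second segment.
#' @return angle in degrees.
#' @export
segmentAngle <- function(a1, a2, b1, b2) {
  u <- as.numeric(a2) - as.numeric(a1)
  w <- as.numeric(b2) - as.numeric(b1)
  nu <- sqrt(sum(u * u)); nw <- sqrt(sum(w * w))
  if (nu == 0 || nw == 0) stop("degenerate segment")
  cosang <- sum(u * w) / (nu * nw)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Names and short codes of the 14 measured parameters
#'
#' @return data.frame with \code{name}, \code{code} (a'-n'), \code{type}
#'   and \code{region} columns, in canonical order.
#' @export
measurementLabels <- function() {
  data.frame(
    name = c("N_Gn", "N_Sn", "Sto_Gn", "Sn_Sto", "N_Sto", "Sn_to_NPg",
             "Go_Gn", "Pg_to_NB", "nasolabial_angle", "labiomental_angle",
             "lowerlip_submental_angle", "gonial_angle",
             "facial_convexity", "soft_tissue_convexity"),
    code = c("a'", "b'", "c'", "d'", "e'", "f'", "g'", "h'", "i'", "j'",
             "k'", "l'", "m'", "n'"),
    type = c(rep("linear", 8), rep("angular", 6))[
      c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14)],
    region = c("overall", "midface", "lowerface", "midface", "midface",
               "midface", "lowerface", "lowerface", "midface", "lowerface",
               "lowerface", "lowerface", "overall", "overall"),
    stringsAsFactors = FALSE
  )
}

#' Measure the 14-parameter battery for one subject
#'
#' Linear parameters (mm): N-Gn (a'), N-Sn (b'), Sto-Gn (c'), Sn-Sto (d'),
#' N-Sto (e'), Sn to the N-Pg line (f', signed, + anterior), Go-Gn (g',
#' per side and side mean), Pg to the N-B line (h', signed, + anterior).
#' Angular parameters (degrees): nasolabial angle C-Sn-Ls (i'; the columella
#' label C stands for the columella point Cm), labiomental angle Li-B-Pg
#' (j'), lower lip to submental plane angle between B-Pg and Cer-Gn (k'),
#' gonial angle OBi-Go-Gn computed per side with ipsilateral OBi/Go (l',
#' reported per side and as the side mean), facial convexity N-Sn-Pg (m')
#' and full soft-tissue convexity N-PRn-Pg (n').
#'
#' Signed distances use the +z (anterior) axis; the landmark set should be
#' in the canonical frame (see [estimateCanonicalFrame()]) for the signs to
#' be anatomically meaningful.  Distances and angles themselves are
#' rigid-motion invariant.
#'
#' @param lms a complete [LandmarkSet-class].
#' @param signedAxis axis used for the signs of f' and h' (default +z).
#' @return named numeric vector with the 14 parameters plus per-side values
#'   \code{Go_Gn_r}, \code{Go_Gn_l}, \code{gonial_angle_r},
#'   \code{gonial_angle_l}.
#' @export
#' @examples
#' rec <- measureSubject(canonicalLandmarks())
#' rec[["Sn_Sto"]]
measureSubject <- function(lms, signedAxis = c(0, 0, 1)) {
  checkComplete(lms, "measureSubject input")
  P <- function(l) lmPoint(lms, l)
  goR <- pointDistance(P("Go-r"), P("Gn"))
  goL <- pointDistance(P("Go-l"), P("Gn"))
  gaR <- vertexAngle(P("OBi-r"), P("Go-r"), P("Gn"))
  gaL <- vertexAngle(P("OBi-l"), P("Go-l"), P("Gn"))
  out <- c(
    N_Gn   = pointDistance(P("N"), P("Gn")),
    N_Sn   = pointDistance(P("N"), P("Sn")),
    Sto_Gn = pointDistance(P("Sto"), P("Gn")),
    Sn_Sto = pointDistance(P("Sn"), P("Sto")),
    N_Sto  = pointDistance(P("N"), P("Sto")),
    Sn_to_NPg = pointLineDistance(P("Sn"), P("N"), P("Pg"), signedAxis),
    Go_Gn  = (goR + goL) / 2,
    Pg_to_NB = pointLineDistance(P("Pg"), P("N"), P("B"), signedAxis),
    nasolabial_angle = vertexAngle(P("C"), P("Sn"), P("Ls")),
    labiomental_angle = vertexAngle(P("Li"), P("B"), P("Pg")),
    lowerlip_submental_angle = segmentAngle(P("B"), P("Pg"),
                                            P("Cer"), P("Gn")),
    gonial_angle = (gaR + gaL) / 2,
    facial_convexity = vertexAngle(P("N"), P("Sn"), P("Pg")),
    soft_tissue_convexity = vertexAngle(P("N"), P("PRn"), P("Pg")),
    Go_Gn_r = goR, Go_Gn_l = goL,
    gonial_angle_r = gaR, gonial_angle_l = gaL
  )
  out
}

#' Measure a batch of landmark files
#'
#' @param paths character vector of landmark file paths.
#' @param ids subject identifiers (defaults to file base names).
#' @return data.frame, one row per subject, columns = parameters.
#' @export
measureBatch <- function(paths, ids = NULL) {
  if (is.null(ids)) ids <- tools::file_path_sans_ext(basename(paths))
  recs <- lapply(paths, function(p) {
    lms <- readLandmarks(p)
    fr <- estimateCanonicalFrame(lms)
    measureSubject(applyFrame(lms, fr))
  })
  out <- as.data.frame(do.call(rbind, recs))
  out <- cbind(id = ids, out)
  rownames(out) <- NULL
  out
}
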