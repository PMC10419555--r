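#' Apply a canonical frame transform
#'
#' Rigidly transforms an object into the canonical head frame defined by a
#' [CanonicalFrame-class].  Distances between any two points are preserved
#' (isometry).
#'
#' @param x a [HeadMesh-class], [LandmarkSet-class] or an n x 3 matrix.
#' @param frame a [CanonicalFrame-class].
#' @param inverse if \code{TRUE}, apply the inverse transform (back into the
#'   original coordinates).
#' @return an object of the same class as \code{x}.
#' @export
setGeneric("applyFrame", function(x, frame, inverse = FALSE)
  standardGeneric("applyFrame"))
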