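# Shared fixtures, all built in code.

# smallest closed triangulated solid
makeTetrahedron <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  HeadMesh(v, f)
}

# exactly mirror-symmetric sphere with pairing, wrapped as a template
makeSphereTemplate <- function(radius = 100, nr = 40, nv = 32,
                               center = c(0, 0, 0)) {
  g <- craniosym:::.symmetricLatLongMesh(function(u) radius, center, nr, nv)
  new("SymmetricTemplate", mesh = g$mesh, mirror = g$mirror,
      anchors = c(V = 1L))
}

randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rigidly transform a LandmarkSet
rigidMove <- function(lms, R, shift) {
  m <- lmCoords(lms) %*% t(R) + matrix(shift, nrow(lmCoords(lms)), 3,
                                       byrow = TRUE)
  rownames(m) <- lmLabels(lms)
  LandmarkSet(m)
}

# one template built once for the whole suite (resolution as shipped)
sharedTemplate <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- buildTemplate()
    tpl
  }
})

classSexCells <- expand.grid(class = c("I", "II", "III"), sex = c("M", "F"),
                             stringsAsFactors = FALSE)

# deterministic mean-target landmark set for a given cell
meanCellLandmarks <- function(class = "I", sex = "M") {
  norms <- referenceNorms()
  tg <- vapply(names(norms$measurements), function(p)
    norms$measurements[[p]][[class]][[sex]][1], 0)
  hd <- c(H = norms$head$H[[class]][1], L = norms$head$L[[class]][1],
          W = norms$head$W[[class]][1])
  list(targets = tg, head = hd, lms = placeLandmarks(tg, hd))
}
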