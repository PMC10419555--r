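## Mesh and landmark file IO.  PLY (ascii and binary_little_endian) and OBJ
## for meshes; CSV (label,x,y,z) and JSON (label -> [x,y,z]) for landmarks.
## All coordinates are mm.  On disk, PLY/OBJ follow their native conventions
## (0-based / 1-based face indices); in memory faces are 1-based.

#' Read a triangulated mesh
#'
#' @param path file path.
#' @param format \code{"ply"} or \code{"obj"}; guessed from the file
#'   extension when omitted.
#' @return a [HeadMesh-class]; a per-vertex \code{quality} property, if
#'   present in a PLY file, is loaded into the scalar channel.
#' @export
readMesh <- function(path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "obj"))
      stop("unknown mesh format: ", ext)
    format <- ext
  }
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  switch(format, ply = .readPLY(path), obj = .readOBJ(path))
}

#' Write a triangulated mesh
#'
#' @param mesh a [HeadMesh-class].
#' @param path output path.
#' @param format \code{"ply"} (ascii) or \code{"obj"}; guessed from the
#'   extension when omitted.
#' @param colors optional n x 3 integer matrix (0-255) of per-vertex colours
#'   (PLY only).
#' @return invisibly, \code{path}.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "ply", "obj"),
                      colors = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "obj"))
      stop("unknown mesh format: ", ext)
    format <- ext
  }
  switch(format,
         ply = .writePLY(mesh, path, colors),
         obj = .writeOBJ(mesh, path))
  invisible(path)
}

.writePLY <- function(mesh, path, colors = NULL) {
  v <- mesh@vertices
  f <- mesh@faces
  hasQ <- length(mesh@scalars) == nrow(v)
  hasC <- !is.null(colors)
  hdr <- c("ply", "format ascii 1.0",
           "comment craniosym head mesh",
           paste("element vertex", nrow(v)),
           "property double x", "property double y", "property double z")
  if (hasQ) hdr <- c(hdr, "property double quality")
  if (hasC) hdr <- c(hdr, "property uchar red", "property uchar green",
                     "property uchar blue")
  hdr <- c(hdr, paste("element face", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
  if (hasQ) vl <- paste(vl, sprintf("%.17g", mesh@scalars))
  if (hasC)
    vl <- paste(vl, colors[, 1], colors[, 2], colors[, 3])
  fl <- paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(hdr, vl, fl), path)
}

.plyTypeSize <- function(t) {
  switch(t, char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
         float = 4L, float32 = 4L, double = 8L, float64 = 8L,
         stop("unsupported PLY type: ", t))
}

.plyReadScalar <- function(con, t, n = 1L) {
  sz <- .plyTypeSize(t)
  if (t %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", n = n, size = sz, endian = "little")
  else
    readBin(con, "integer", n = n, size = sz, endian = "little",
            signed = !(t %in% c("uchar", "uint8", "ushort", "uint16")))
}

.readPLY <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  mark <- grepRaw("end_header", raw, fixed = TRUE)
  if (!length(mark)) stop("not a PLY file (no end_header): ", path)
  nl <- mark + 10L
  while (nl <= length(raw) && raw[nl] != as.raw(10L)) nl <- nl + 1L
  bodyStart <- nl + 1L
  hdr <- strsplit(rawToChar(raw[seq_len(mark - 1L)]), "\r?\n")[[1]]
  hdr <- trimws(hdr)
  if (!identical(hdr[1], "ply")) stop("not a PLY file: ", path)
  fmtLine <- grep("^format ", hdr, value = TRUE)[1]
  fmt <- strsplit(fmtLine, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  ## parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (line in hdr) {
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], list = TRUE, countType = tok[3], type = tok[4])
      else
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur

  vertices <- NULL; faces <- NULL; quality <- numeric(0)

  if (fmt == "ascii") {
    body <- strsplit(rawToChar(raw[bodyStart:length(raw)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    pos <- 1L
    for (el in elements) {
      lines <- body[seq(pos, length.out = el$count)]
      pos <- pos + el$count
      toks <- strsplit(trimws(lines), "\\s+")
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, "", "name")
        m <- do.call(rbind, lapply(toks, function(t) as.numeric(t)))
        vertices <- m[, match(c("x", "y", "z"), pn), drop = FALSE]
        if ("quality" %in% pn) quality <- m[, match("quality", pn)]
      } else if (el$name == "face") {
        faces <- do.call(rbind, lapply(toks, function(t) {
          n <- as.integer(t[1])
          as.integer(t[1 + seq_len(n)])
        }))
      }
    }
  } else {
    con <- rawConnection(raw[bodyStart:length(raw)])
    on.exit(close(con))
    for (el in elements) {
      listy <- any(vapply(el$props, `[[`, TRUE, "list"))
      if (!listy) {
        types <- vapply(el$props, `[[`, "", "type")
        pn <- vapply(el$props, `[[`, "", "name")
        if (length(unique(types)) == 1L) {      # homogeneous block: bulk read
          m <- matrix(.plyReadScalar(con, types[1], el$count * length(pn)),
                      ncol = length(pn), byrow = TRUE)
        } else {
          m <- matrix(0, el$count, length(pn))
          for (i in seq_len(el$count))
            for (j in seq_along(el$props))
              m[i, j] <- .plyReadScalar(con, types[j])
        }
        if (el$name == "vertex") {
          vertices <- m[, match(c("x", "y", "z"), pn), drop = FALSE]
          if ("quality" %in% pn) quality <- m[, match("quality", pn)]
        }
      } else {
        p <- el$props[[1]]
        rows <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          n <- .plyReadScalar(con, p$countType)
          rows[[i]] <- .plyReadScalar(con, p$type, n)
        }
        if (el$name == "face") faces <- do.call(rbind, rows)
      }
    }
  }
  if (is.null(vertices)) stop("PLY file has no vertex element: ", path)
  if (is.null(faces)) faces <- matrix(integer(0), 0, 3)
  faces <- .triangulateFaces(faces)
  HeadMesh(vertices, faces + 1L, scalars = quality)
}

.readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  vertices <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(t)
    as.numeric(t[2:4])))
  faces <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(t) {
    idx <- vapply(t[-1], function(s) as.integer(strsplit(s, "/")[[1]][1]), 0L)
    idx
  }))
  if (is.null(faces)) faces <- matrix(integer(0), 0, 3)
  faces <- .triangulateFaces(faces - 1L)
  HeadMesh(vertices, faces + 1L)
}

.writeOBJ <- function(mesh, path) {
  v <- mesh@vertices
  f <- mesh@faces
  lines <- c(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
             sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  writeLines(lines, path)
}

## Fan-triangulate polygonal faces (0-based input and output); warn once.
.triangulateFaces <- function(faces) {
  if (is.matrix(faces) && ncol(faces) == 3L) return(faces)
  rows <- if (is.matrix(faces)) asplit(faces, 1) else faces
  out <- list()
  warned <- FALSE
  for (r in rows) {
    r <- as.integer(r)
    if (length(r) == 3L) {
      out[[length(out) + 1]] <- r
    } else {
      if (!warned) {
        warning("non-triangular faces encountered; fan-triangulating")
        warned <- TRUE
      }
      for (i in 2:(length(r) - 1))
        out[[length(out) + 1]] <- c(r[1], r[i], r[i + 1])
    }
  }
  do.call(rbind, out)
}

#' Read a landmark file
#'
#' CSV files must have a header \code{label,x,y,z}; JSON files must be a
#' mapping \code{label -> [x, y, z]}.  Units are mm.  Labels are validated
#' against the closed vocabulary ([landmarkVocabulary()], plus constructed
#' \code{Layer<k>-<j>} labels).
#'
#' @param path file path (\code{.csv} or \code{.json}).
#' @param requireComplete error unless all 37 anatomical labels are present.
#' @return a [LandmarkSet-class].
#' @export
readLandmarks <- function(path, requireComplete = TRUE) {
  if (!file.exists(path)) stop("cannot read landmark file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    m <- do.call(rbind, lapply(obj, as.numeric))
    rownames(m) <- names(obj)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("label", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("landmark CSV must have columns label,x,y,z")
    m <- as.matrix(df[, c("x", "y", "z")])
    rownames(m) <- df$label
  }
  lms <- LandmarkSet(m)
  if (requireComplete) checkComplete(lms, paste0("landmark file '", path, "'"))
  lms
}

#' Write a landmark file
#'
#' @param lms a [LandmarkSet-class].
#' @param path output path (\code{.csv} or \code{.json} selects the dialect).
#' @return invisibly, \code{path}.
#' @export
writeLandmarks <- function(lms, path) {
  ext <- tolower(tools::file_ext(path))
  m <- lms@coords
  if (ext == "json") {
    obj <- lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
    names(obj) <- rownames(m)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  } else {
    df <- data.frame(label = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
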