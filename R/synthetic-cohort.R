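## Synthetic head-cohort generator.  Target values for the 14-parameter
## battery are drawn per class x sex from the calibrated normal
## distributions, then landmarks are placed constructively so that
## measureSubject() reproduces every drawn target exactly: the midline
## vertical chain first (N, Sto, Sn, Gn from the drawn distances), then the
## profile points that realise the drawn angles/offsets (Pg, PRn, C, Ls, B,
## Li), then the bilateral landmarks as exact mirror pairs (Go/OBi placed to
## realise the drawn mandibular length and gonial angle).  Head meshes are
## the symmetric template warped to the generated landmarks; bilateral
## asymmetry of configured magnitude is injected on the mesh.

.deg2rad <- function(d) d * pi / 180

## 2D helpers in the midsagittal (y, z) plane; +y superior, +z anterior.
.rot2 <- function(v, deg) {
  r <- .deg2rad(deg)
  c(cos(r) * v[1] - sin(r) * v[2], sin(r) * v[1] + cos(r) * v[2])
}
.unit2 <- function(v) v / sqrt(sum(v * v))
.to3 <- function(p) c(0, p[1], p[2])

## intersection of circles |P-c1| = r1, |P-c2| = r2; NULL when infeasible
.circleIntersect <- function(c1, r1, c2, r2) {
  d <- sqrt(sum((c2 - c1)^2))
  if (d < 1e-12) return(NULL)
  t <- (r1^2 - r2^2 + d^2) / (2 * d)
  h2 <- r1^2 - t^2
  if (h2 < 0) return(NULL)
  u <- (c2 - c1) / d
  perp <- c(-u[2], u[1])
  base <- c1 + t * u
  h <- sqrt(h2)
  list(base + h * perp, base - h * perp)
}

#' Default cohort configuration
#'
#' Calibration defaults come from [referenceNorms()]; any entry can be
#' overridden.  \code{raterNoiseSD} is the isotropic landmark perturbation
#' (mm) used by [simulateRaters()]; \code{seed} fixes all randomness of
#' [generateCohort()].
#'
#' @param norms calibration tables, see [referenceNorms()].
#' @param raterNoiseSD landmark digitisation noise SD in mm.
#' @param seed integer seed.
#' @return a config list.
#' @export
cohortConfig <- function(norms = referenceNorms(), raterNoiseSD = 0.5,
                         seed = 1L) {
  list(norms = norms, raterNoiseSD = raterNoiseSD, seed = as.integer(seed))
}

## truncated-normal draw (+- 4 SD) to avoid geometrically wild tails
.rtrunc <- function(mean, sd) {
  if (sd == 0) return(mean)
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (abs(x - mean) <= 4 * sd) return(x)
  }
}

## Draw the 14 parameter targets for one class x sex cell.  The vertical
## chain (N-Sn, Sn-Sto, Sto-Gn independent; N-Sto and N-Gn via positive
## slack variables) is drawn coherently so the triangle inequalities every
## landmark configuration must satisfy hold by construction, while all
## configured means are reproduced exactly.
.drawTargets <- function(class, sex, norms) {
  g <- function(p) norms$measurements[[p]][[class]][[sex]]
  d <- function(p) { v <- g(p); .rtrunc(v[1], v[2]) }
  ## vertex angles are only representable in (0, 180): redraw the rare
  ## tail draws outside it
  dAng <- function(p) {
    v <- g(p)
    repeat {
      x <- .rtrunc(v[1], v[2])
      if (x > 5 && x < 179.5) return(x)
    }
  }
  b <- d("N_Sn"); dd <- d("Sn_Sto"); cc <- d("Sto_Gn")
  slack1Mean <- g("N_Sn")[1] + g("Sn_Sto")[1] - g("N_Sto")[1]
  slack2Mean <- g("N_Sto")[1] + g("Sto_Gn")[1] - g("N_Gn")[1]
  if (slack1Mean <= 0 || slack2Mean <= 0)
    stop("configured vertical means violate the triangle inequality")
  det <- g("N_Sn")[2] == 0 && g("Sn_Sto")[2] == 0 && g("N_Sto")[2] == 0
  s1 <- if (det) slack1Mean else stats::rgamma(1, 4, scale = slack1Mean / 4)
  det2 <- det && g("Sto_Gn")[2] == 0 && g("N_Gn")[2] == 0
  s2 <- if (det2) slack2Mean else stats::rgamma(1, 4, scale = slack2Mean / 4)
  e <- b + dd - s1
  a <- e + cc - s2
  c(N_Gn = a, N_Sn = b, Sto_Gn = cc, Sn_Sto = dd, N_Sto = e,
    Sn_to_NPg = d("Sn_to_NPg"), Go_Gn = d("Go_Gn"), Pg_to_NB = d("Pg_to_NB"),
    nasolabial_angle = dAng("nasolabial_angle"),
    labiomental_angle = dAng("labiomental_angle"),
    lowerlip_submental_angle = dAng("lowerlip_submental_angle"),
    gonial_angle = dAng("gonial_angle"),
    facial_convexity = dAng("facial_convexity"),
    soft_tissue_convexity = dAng("soft_tissue_convexity"))
}

.drawHead <- function(class, norms) {
  h <- function(p) { v <- norms$head[[p]][[class]]; .rtrunc(v[1], v[2]) }
  out <- c(H = h("H"), L = h("L"), W = h("W"), AH = h("AH"), AF = h("AF"))
  out["AH"] <- max(out["AH"], 0)
  out["AF"] <- max(out["AF"], 0)
  out
}

## ---------------------------------------------------------------------------
## Constructive landmark placement
## ---------------------------------------------------------------------------

#' Place the 37 landmarks to realise a set of measurement targets
#'
#' Deterministic constructive placement: the returned configuration is
#' exactly mirror-symmetric (left/right pairs are x-negated copies) and
#' [measureSubject()] reproduces every target value.  The frame convention
#' is the canonical one (midline x = 0, +y superior, +z anterior) up to a
#' translation; Gn sits at the origin of the construction frame.
#'
#' @param targets named vector of the 14 parameters (see
#'   [measurementLabels()]); mm and degrees.
#' @param headDims named vector with H, L, W (mm).
#' @return a [LandmarkSet-class] with the 37 anatomical labels.
#' @export
placeLandmarks <- function(targets, headDims = c(H = 228.6, L = 181.38,
                                                 W = 160.98)) {
  t <- as.list(targets)
  W <- headDims[["W"]]; H <- headDims[["H"]]; L <- headDims[["L"]]

  ## --- midline chain in the (y, z) plane; Gn at the origin, facial axis
  ## tilted 8 degrees anterior so the profile points have room in +z.
  Gn <- c(0, 0)
  psi <- 82                     # N direction from Gn, degrees from +z axis
  N <- t$N_Gn * c(sin(.deg2rad(psi)), cos(.deg2rad(psi)))

  sto <- .circleIntersect(Gn, t$Sto_Gn, N, t$N_Sto)
  if (is.null(sto)) stop("infeasible vertical chain (Sto)")
  Sto <- if (sto[[1]][2] >= sto[[2]][2]) sto[[1]] else sto[[2]]

  sn <- .circleIntersect(N, t$N_Sn, Sto, t$Sn_Sto)
  if (is.null(sn)) stop("infeasible vertical chain (Sn)")
  Sn <- if (sn[[1]][2] >= sn[[2]][2]) sn[[1]] else sn[[2]]

  Pg <- .solvePg(N, Sn, Gn, t$facial_convexity, t$Sn_to_NPg)
  PRn <- .solvePRn(N, Sn, Pg, t$soft_tissue_convexity, t$N_Sn)
  Cer <- Gn + c(-40, -10)        # subhyoid: inferior, slightly posterior
  B <- .solveB(N, Pg, Gn, Cer, t$lowerlip_submental_angle, t$Pg_to_NB)

  ## Li from the labiomental angle at B; take the branch toward Sto
  dPgB <- .unit2(Pg - B)
  rho <- 0.45 * sqrt(sum((Sto - B)^2))
  liC <- lapply(c(-1, 1), function(s) B + rho * .rot2(dPgB, s * t$labiomental_angle))
  Li <- liC[[which.min(vapply(liC, function(p) sum((p - Sto)^2), 0))]]

  ## Ls on the Sn-Sto segment; C from the nasolabial angle (superior branch)
  Ls <- Sn + 0.35 * (Sto - Sn)
  dLs <- .unit2(Ls - Sn)
  rhoC <- 0.30 * sqrt(sum((PRn - Sn)^2))
  cC <- lapply(c(-1, 1), function(s) Sn + rhoC * .rot2(dLs, s * t$nasolabial_angle))
  Cm <- cC[[which.max(vapply(cC, `[`, 0, 1))]]

  ## --- bilateral landmarks (exact mirror pairs, left = +x)
  Gn3 <- .to3(Gn)
  uGo <- c(0.55, 0.60, -0.58); uGo <- uGo / sqrt(sum(uGo^2))
  GoL <- Gn3 + t$Go_Gn * uGo
  d1 <- (Gn3 - GoL) / sqrt(sum((Gn3 - GoL)^2))
  w <- c(0, 1, 0) - sum(c(0, 1, 0) * d1) * d1
  w <- w / sqrt(sum(w * w))
  la <- .deg2rad(t$gonial_angle)
  OBiL <- GoL + 45 * (cos(la) * d1 + sin(la) * w)

  ## --- remaining landmarks: fixed anatomical offsets (do not enter the
  ## measured battery) scaled to the drawn head dimensions
  zPRn <- PRn[2]
  Op <- c(PRn[1], zPRn - L)              # same height as PRn => level z axis
  V <- c(Gn[1] + H, zPRn - 0.55 * L)
  O <- c(PRn[1] - 30, Op[2] + 12)
  G <- c(N[1] + 12, N[2] + 2)
  OBsL <- OBiL + c(4, 28, 0)
  LbL <- OBiL + c(2, -6, 4)

  mid <- rbind(G = G, N = N, PRn = PRn, Sn = Sn, C = Cm, Ls = Ls, Li = Li,
               Sto = Sto, B = B, Pg = Pg, Gn = Gn, V = V, Op = Op, O = O,
               Cer = Cer)
  co <- matrix(0, 37, 3)
  labs <- character(37)
  for (i in seq_len(nrow(mid))) {
    co[i, ] <- .to3(mid[i, ])
    labs[i] <- rownames(mid)[i]
  }
  k <- nrow(mid)
  bil <- list(Go = GoL, OBi = OBiL, OBs = OBsL, L = LbL,
              Ala = c(0.105 * W, Sn[1] + 4, Sn[2] + 1),
              Nb = c(0.050 * W, Sn[1] + 1, Sn[2] + 3),
              As = c(0.075 * W, Sn[1] + 8, Sn[2] + 1),
              Ex = c(0.260 * W, N[1] - 0.30 * t$N_Sn, N[2] - 6),
              En = c(0.100 * W, N[1] - 0.30 * t$N_Sn, N[2] + 2),
              Cph = c(0.035 * W, Ls[1] + 1, Ls[2] - 0.5),
              Ch = c(0.150 * W, Sto[1], Sto[2] - 6))
  for (nm in names(bil)) {
    p <- bil[[nm]]
    co[k + 1, ] <- c(-p[1], p[2], p[3]); labs[k + 1] <- paste0(nm, "-r")
    co[k + 2, ] <- p; labs[k + 2] <- paste0(nm, "-l")
    k <- k + 2
  }
  rownames(co) <- labs
  LandmarkSet(co)
}

## Pg realises both the facial convexity (angle N-Sn-Pg) and the signed
## subnasale offset f' = dist(Sn, line N-Pg): Pg lies on a ray from Sn at
## the target angle from Sn->N; the ray parameter solves a quadratic in the
## offset magnitude.  Both rotation branches are tried; the branch/root
## whose signed offset matches the target sign and whose Pg is nearest the
## gnathion wins.
.solvePg <- function(N, Sn, Gn, convexity, fSigned) {
  f <- abs(fSigned)
  b <- sqrt(sum((N - Sn)^2))
  m <- .deg2rad(convexity)
  wN <- .unit2(N - Sn)
  cand <- list()
  for (sgn in c(-1, 1)) {
    dir <- .rot2(wN, sgn * convexity)
    A <- f^2 - b^2 * sin(m)^2
    Bq <- -2 * b * f^2 * cos(m)
    Cq <- f^2 * b^2
    roots <- if (abs(A) < 1e-12) {
      if (abs(Bq) < 1e-15) numeric(0) else -Cq / Bq
    } else {
      disc <- Bq^2 - 4 * A * Cq
      if (disc < 0) numeric(0)
      else (-Bq + c(1, -1) * sqrt(disc)) / (2 * A)
    }
    roots <- roots[is.finite(roots) & roots > 1e-6]
    for (s in roots) {
      Pg <- Sn + s * dir
      fm <- pointLineDistance(.to3(Sn), .to3(N), .to3(Pg),
                              signedAxis = c(0, 0, 1))
      if (abs(abs(fm) - f) > 1e-6) next
      if (f > 1e-9 && sign(fm) != sign(fSigned)) next
      if (Pg[1] >= Sn[1]) next             # Pg must be inferior to Sn
      cand[[length(cand) + 1]] <- Pg
    }
  }
  if (!length(cand)) stop("infeasible convexity/subnasale-offset combination")
  cand[[which.min(vapply(cand, function(p) sum((p - Gn)^2), 0))]]
}

## PRn sees the chord N-Pg at the full soft-tissue convexity angle
## (inscribed-angle locus); among the locus points the one at the preferred
## nasal height (anterior branch) is taken, falling back to the arc apex.
.solvePRn <- function(N, Sn, Pg, convexity, nasalHeight) {
  nR <- .deg2rad(convexity)
  chord <- Pg - N
  dch <- sqrt(sum(chord^2))
  R <- dch / (2 * sin(nR))
  mid <- (N + Pg) / 2
  perp <- .unit2(c(-chord[2], chord[1]))
  if (perp[2] < 0) perp <- -perp          # anterior side
  hoff <- sqrt(max(R^2 - (dch / 2)^2, 0))
  yT <- Sn[1] + 0.25 * nasalHeight
  cand <- list()
  for (sgn in c(-1, 1)) {
    O <- mid + sgn * hoff * perp
    dy2 <- R^2 - (yT - O[1])^2
    if (dy2 >= 0) {
      for (s2 in c(1, -1))
        cand[[length(cand) + 1]] <- c(yT, O[2] + s2 * sqrt(dy2))
    }
    cand[[length(cand) + 1]] <- O + R * perp   # arc apex fallback
  }
  ok <- Filter(function(p) {
    a <- vertexAngle(.to3(N), .to3(p), .to3(Pg))
    is.finite(a) && abs(a - convexity) < 1e-6
  }, cand)
  if (!length(ok)) stop("infeasible soft-tissue convexity")
  ok[[which.max(vapply(ok, `[`, 0, 2))]]
}

## B realises the submental-plane angle (direction of Pg - B relative to
## Cer -> Gn) and the signed pogonion offset h' = dist(Pg, line N-B).
.solveB <- function(N, Pg, Gn, Cer, submentalAngle, hSigned) {
  h <- abs(hSigned)
  vSub <- .unit2(Gn - Cer)
  cand <- list()
  for (sgn in c(-1, 1)) {
    dirB <- .rot2(vSub, sgn * submentalAngle)
    g <- function(s) {
      B <- Pg - s * dirB
      pointLineDistance(.to3(Pg), .to3(N), .to3(B)) - h
    }
    grid <- seq(0.5, 80, by = 0.5)
    gv <- vapply(grid, g, 0)
    sc <- which(diff(sign(gv)) != 0)
    for (i in sc) {
      s <- stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-12)$root
      B <- Pg - s * dirB
      hm <- pointLineDistance(.to3(Pg), .to3(N), .to3(B),
                              signedAxis = c(0, 0, 1))
      if (abs(abs(hm) - h) > 1e-6) next
      if (h > 1e-9 && sign(hm) != sign(hSigned)) next
      cand[[length(cand) + 1]] <- B
    }
  }
  if (!length(cand)) stop("infeasible pogonion offset / submental angle")
  sup <- Filter(function(B) B[1] > Pg[1], cand)   # prefer B above Pg
  if (length(sup)) sup[[1]] else cand[[1]]
}

#' Canonical mean landmark configuration
#'
#' The deterministic landmark placement for the class-I cohort means
#' (roster-weighted across sexes) and class-I head norms, expressed in the
#' canonical frame.  Used to size the symmetric template and as a convenient
#' known-truth fixture.
#'
#' @return a [LandmarkSet-class].
#' @export
canonicalLandmarks <- function() {
  norms <- referenceNorms()
  wM <- norms$roster$I$M; wF <- norms$roster$I$F
  tg <- vapply(names(norms$measurements), function(p) {
    m <- norms$measurements[[p]]$I
    (wM * m$M[1] + wF * m$F[1]) / (wM + wF)
  }, 0)
  hd <- c(H = norms$head$H$I[1], L = norms$head$L$I[1], W = norms$head$W$I[1])
  lms <- placeLandmarks(tg, hd)
  applyFrame(lms, estimateCanonicalFrame(lms))
}

## ---------------------------------------------------------------------------
## Subject and cohort generation
## ---------------------------------------------------------------------------

## layer warp targets on the cranial ellipsoid of the drawn head dimensions,
## cast from the canonical (OBi-origin) vertical axis like layerLandmarks()
.ellipsoidLayerTargets <- function(lms, headDims, nLayers = 4, perLayer = 10) {
  H <- headDims[["H"]]; L <- headDims[["L"]]; W <- headDims[["W"]]
  yGn <- lmPoint(lms, "Gn")[2]
  o <- estimateCanonicalFrame(lms)@translation
  ## cranial ellipsoid centred on the canonical vertical axis, so every
  ## layer ray cast from the axis meets it
  ax <- W / 2; ay <- H / 2; az <- 0.40 * L
  yc <- yGn + H / 2; zc <- o[3]
  yLo <- (lmPoint(lms, "OBs-r")[2] + lmPoint(lms, "OBs-l")[2]) / 2
  yHi <- yGn + H
  out <- matrix(0, nLayers * perLayer, 3)
  labs <- character(nrow(out))
  r <- 0L
  for (k in seq_len(nLayers)) {
    h <- yLo + k * (yHi - yLo) / (nLayers + 1)
    yterm <- ((h - yc) / ay)^2
    for (j in 0:(perLayer - 1L)) {
      a <- 2 * pi * j / perLayer
      dx <- sin(a); dz <- cos(a)
      ## ray (o_x=0, h, o_z) + t (dx, 0, dz) meets the ellipsoid
      A <- dx^2 / ax^2 + dz^2 / az^2
      Bq <- 2 * (dz * (o[3] - zc) / az^2)
      Cq <- (o[3] - zc)^2 / az^2 + yterm - 1
      disc <- Bq^2 - 4 * A * Cq
      if (disc < 0) stop("layer target ray misses the cranial ellipsoid")
      t <- (-Bq + sqrt(disc)) / (2 * A)
      r <- r + 1L
      out[r, ] <- c(t * dx, h, o[3] + t * dz)
      labs[r] <- sprintf("Layer%d-%d", k, j)
    }
  }
  rownames(out) <- labs
  LandmarkSet(out)
}

#' Generate one synthetic subject
#'
#' Draws the 14 parameter targets for the requested class x sex cell, places
#' landmarks constructively ([placeLandmarks()]), and optionally produces a
#' head mesh by warping the symmetric template to the generated landmarks
#' (37 anatomical + 40 cranial-layer controls on the drawn head ellipsoid).
#' Configured asymmetry (the drawn AF/AH levels) is injected on the mesh as
#' a uniform radial offset of the left facial / left cranial vertices about
#' the canonical origin; landmarks themselves stay exactly symmetric.
#'
#' Randomness uses the R session RNG: seed with \code{set.seed()} or use
#' [generateCohort()].
#'
#' @param class \code{"I"}, \code{"II"} or \code{"III"}.
#' @param sex \code{"M"} or \code{"F"}.
#' @param cfg a [cohortConfig()].
#' @param mesh generate the head mesh as well?
#' @param template a prebuilt [SymmetricTemplate-class] (recommended when
#'   generating many subjects).
#' @param maxRedraws redraw budget for geometrically infeasible target
#'   combinations.
#' @return list with \code{landmarks} ([LandmarkSet-class]), \code{targets}
#'   (the drawn 14 parameters), \code{head} (drawn H/L/W/AH/AF), and
#'   \code{mesh} ([HeadMesh-class] or \code{NULL}).
#' @export
generateSubject <- function(class = "I", sex = "M", cfg = cohortConfig(),
                            mesh = FALSE, template = NULL,
                            maxRedraws = 400) {
  norms <- cfg$norms
  targets <- .drawTargets(class, sex, norms)
  head <- .drawHead(class, norms)
  lms <- NULL
  for (att in seq_len(maxRedraws)) {
    lms <- tryCatch(placeLandmarks(targets, head),
                    error = function(e) e)
    if (!inherits(lms, "error")) break
    ## redraw only the component implicated by the failure, so the other
    ## marginals stay calibrated (full redraws would bias e.g. the
    ## convexity mean whenever its tail collides with the offset draw)
    msg <- conditionMessage(lms)
    cell <- function(p) norms$measurements[[p]][[class]][[sex]]
    if (att > maxRedraws / 2) {          # escape pathological combinations
      targets <- .drawTargets(class, sex, norms)
      head <- .drawHead(class, norms)
    } else if (grepl("subnasale-offset", msg)) {
      targets[["Sn_to_NPg"]] <- .rtrunc(cell("Sn_to_NPg")[1],
                                        cell("Sn_to_NPg")[2])
    } else if (grepl("pogonion offset", msg)) {
      targets[["Pg_to_NB"]] <- .rtrunc(cell("Pg_to_NB")[1],
                                       cell("Pg_to_NB")[2])
    } else if (grepl("soft-tissue convexity", msg)) {
      targets[["soft_tissue_convexity"]] <-
        .rtrunc(cell("soft_tissue_convexity")[1],
                cell("soft_tissue_convexity")[2])
    } else {
      targets <- .drawTargets(class, sex, norms)
      head <- .drawHead(class, norms)
    }
    lms <- NULL
  }
  if (is.null(lms) || inherits(lms, "error"))
    stop("could not draw a feasible subject in ", maxRedraws, " attempts")
  out <- list(landmarks = lms, targets = targets, head = head, mesh = NULL)
  if (mesh) {
    if (is.null(template)) template <- buildTemplate()
    sm <- .subjectMesh(lms, head, template)
    out$mesh <- sm$mesh
    out$landmarks <- sm$landmarks
  }
  out
}

## Template -> subject mesh: size, TPS-warp on 77 controls, inject the
## drawn asymmetry as radial offsets of the left-side vertices.
.subjectMesh <- function(lms, head, template) {
  frame <- estimateCanonicalFrame(lms)
  lmsC <- applyFrame(lms, frame)
  scaled <- scaleTemplate(template, lmsC)
  layerT <- .ellipsoidLayerTargets(lmsC, head)
  targets <- rbind(lmCoords(lmsC)[landmarkVocabulary(), , drop = FALSE],
                   lmCoords(layerT))
  anchors <- templateAnchors(scaled)
  sources <- scaled@mesh@vertices[anchors[rownames(targets)], , drop = FALSE]
  warped <- warpMesh(fitTPS(sources, targets), scaled@mesh)

  ## Asymmetry injection about the canonical origin (0,0,0).  The left-side
  ## surface is pushed along its outward normal by g / cos(phi), phi the
  ## normal-vs-radial obliquity, which realises an origin-distance gain of g
  ## under closest-point matching (a pure radial vertex offset would be
  ## under-read by cos^2 phi).  The gain field g is tapered to zero at the
  ## midline seam and blended across the face/skull boundary (hard steps
  ## would be under-read by queries matched near the cliff), and each
  ## region's field is normalised so the expected regional mean equals the
  ## configured level.
  AF <- head[["AF"]]; AH <- head[["AH"]]
  faceMask <- facialRegion(scaled)
  leftMask <- scaled@mesh@vertices[, 1] > 0
  wf <- mean(faceMask[leftMask])
  deltaFace <- AF
  deltaSkull <- max(0, (AH - wf * AF) / max(1 - wf, 1e-9))
  if (deltaFace > 0 || deltaSkull > 0) {
    v <- warped@vertices
    nrm <- .vertexNormals(warped)
    radial <- v / .rowNorms(v)
    cosphi <- rowSums(nrm * radial)
    tl <- templateLandmarks(scaled)
    dP <- .rowNorms(v - matrix(lmPoint(tl, "PRn"), nrow(v), 3, byrow = TRUE))
    dG <- .rowNorms(v - matrix(lmPoint(tl, "Gn"), nrow(v), 3, byrow = TRUE))
    seam <- pmin(1, pmax(0, scaled@mesh@vertices[, 1] / 60))
    wFace <- pmin(1, pmax(0, 0.5 + (dG - dP) / 80))
    g <- seam * (wFace * deltaFace + (1 - wFace) * deltaSkull)
    eff <- pmin(1, cosphi / 0.3)          # clamp attenuation at high obliquity
    for (sel in list(leftMask & faceMask, leftMask & !faceMask)) {
      target <- if (identical(sel, leftMask & faceMask)) deltaFace
                else deltaSkull
      m <- mean((g * eff)[sel])
      if (any(sel) && m > 0 && target > 0) g[sel] <- g[sel] * target / m
      else g[sel] <- 0
    }
    t <- pmin(g / pmax(cosphi, 0.3), 25)  # cap to avoid self-intersection
    v[leftMask, ] <- v[leftMask, , drop = FALSE] +
      nrm[leftMask, , drop = FALSE] * t[leftMask]
    warped@vertices <- v
  }
  ## back to the construction frame so mesh and landmarks stay aligned
  list(mesh = applyFrame(warped, frame, inverse = TRUE),
       landmarks = applyFrame(lmsC, frame, inverse = TRUE))
}

#' Generate a full synthetic cohort
#'
#' Reproducible from \code{cfg$seed}.  Roster sizes default to the reference
#' composition (74/50/15 split across classes).  When \code{outDir} is
#' given, per-subject landmark CSVs, optional meshes (PLY) and a roster CSV
#' are written there.
#'
#' @param cfg a [cohortConfig()].
#' @param mesh also generate head meshes (slower).
#' @param outDir optional output directory.
#' @param template optional prebuilt template (built once when needed).
#' @return data.frame with one row per subject: \code{id}, \code{class},
#'   \code{sex}, \code{age}, the 14 measured parameters, and the drawn head
#'   values; landmark sets in \code{attr(, "landmarks")}, meshes in
#'   \code{attr(, "meshes")}.
#' @export
generateCohort <- function(cfg = cohortConfig(), mesh = FALSE,
                           outDir = NULL, template = NULL) {
  set.seed(cfg$seed)
  roster <- cfg$norms$roster
  if (mesh && is.null(template)) template <- buildTemplate()
  rows <- list(); lmsList <- list(); meshList <- list()
  sid <- 0L
  for (cl in names(roster)) {
    for (sx in names(roster[[cl]])) {
      for (i in seq_len(roster[[cl]][[sx]])) {
        sid <- sid + 1L
        id <- sprintf("S%03d", sid)
        subj <- generateSubject(cl, sx, cfg, mesh = mesh,
                                template = template)
        meas <- measureSubject(subj$landmarks)
        age <- round(stats::runif(1, 9, 10.26), 2)   # mean ~ 9.13 years
        rows[[sid]] <- data.frame(
          id = id, class = cl, sex = sx, age = age,
          t(meas[measurementLabels()$name]),
          H = subj$head[["H"]], L = subj$head[["L"]], W = subj$head[["W"]],
          AH = subj$head[["AH"]], AF = subj$head[["AF"]],
          stringsAsFactors = FALSE)
        lmsList[[id]] <- subj$landmarks
        if (mesh) meshList[[id]] <- subj$mesh
      }
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort, file.path(outDir, "roster.csv"),
                     row.names = FALSE)
    for (id in cohort$id) {
      writeLandmarks(lmsList[[id]],
                     file.path(outDir, paste0(id, "_landmarks.csv")))
      if (mesh)
        writeMesh(meshList[[id]], file.path(outDir, paste0(id, ".ply")))
    }
  }
  attr(cohort, "landmarks") <- lmsList
  if (mesh) attr(cohort, "meshes") <- meshList
  cohort
}

## ---------------------------------------------------------------------------
## Rater simulation
## ---------------------------------------------------------------------------

#' Simulate independent raters digitising one subject
#'
#' Each rater perturbs every landmark with isotropic Gaussian noise of the
#' given SD and the 14-parameter battery is re-measured per rater.
#'
#' @param lms the subject's true [LandmarkSet-class].
#' @param nRaters number of raters.
#' @param noiseSD landmark perturbation SD in mm.
#' @return matrix raters x parameters (14 columns).
#' @export
simulateRaters <- function(lms, nRaters = 2, noiseSD = 0.5) {
  if (noiseSD < 0) stop("noiseSD must be >= 0")
  pars <- measurementLabels()$name
  out <- matrix(0, nRaters, length(pars),
                dimnames = list(NULL, pars))
  co <- lmCoords(lms)
  for (r in seq_len(nRaters)) {
    pert <- co + matrix(stats::rnorm(length(co), 0, noiseSD), nrow(co), 3)
    rownames(pert) <- rownames(co)
    out[r, ] <- measureSubject(LandmarkSet(pert))[pars]
  }
  out
}

#' Emulate the two-rater reliability study
#'
#' Draws \code{nPerClass} subjects from each occlusion class (sexes in
#' roster proportion), with true parameter values from the configured
#' class x sex distributions, and simulates each rater's measurement as the
#' true value plus Gaussian error with SD equal to \code{noiseFrac} of the
#' realised between-subject SD of the study sample.  Returns the ICC per
#' parameter over the pooled sample.
#'
#' @param classes occlusion classes included (default: all three).
#' @param nPerClass subjects sampled per class.
#' @param nRaters raters.
#' @param noiseFrac rater error as a fraction of the between-subject SD.
#' @param cfg a [cohortConfig()].
#' @param form ICC form, see [iccAgreement()].
#' @return named numeric vector of ICCs (one per parameter).
#' @export
reliabilityStudy <- function(classes = c("I", "II", "III"), nPerClass = 31,
                             nRaters = 2, noiseFrac = 0.25,
                             cfg = cohortConfig(), form = "ICC2") {
  norms <- cfg$norms
  cls <- rep(classes, each = nPerClass)
  sxs <- unlist(lapply(classes, function(cl) {
    rN <- norms$roster[[cl]]
    sample(rep(c("M", "F"), times = c(rN$M, rN$F)), nPerClass,
           replace = nPerClass > (rN$M + rN$F))
  }))
  n <- length(cls)
  pars <- names(norms$measurements)
  iccs <- numeric(length(pars)); names(iccs) <- pars
  for (p in seq_along(pars)) {
    truth <- vapply(seq_len(n), function(i) {
      cell <- norms$measurements[[pars[p]]][[cls[i]]][[sxs[i]]]
      stats::rnorm(1, cell[1], cell[2])
    }, 0)
    sdB <- stats::sd(truth)
    ratings <- vapply(seq_len(nRaters), function(j)
      truth + stats::rnorm(n, 0, noiseFrac * sdB), numeric(n))
    iccs[p] <- iccAgreement(ratings, form = form)
  }
  iccs
}
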