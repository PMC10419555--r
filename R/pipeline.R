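## End-to-end orchestration: simulate (or load) -> align -> measure ->
## correspond -> asymmetry -> statistics -> tables / heat maps, as one
## reproducible run with a provenance manifest.

#' Run the full analysis pipeline
#'
#' Stages: (1) cohort input - either a synthetic cohort generated from
#' \code{cfg} or an existing directory with \code{roster.csv} and
#' per-subject landmark files; (2) canonical alignment and the 14-parameter
#' measurement battery per subject; (3) optional dense-correspondence
#' asymmetry analysis (template + TPS + closest point) on the subjects with
#' meshes; (4) cohort statistics; (5) published-layout tables, per-class
#' mean heat maps and a provenance manifest, all written to \code{outDir}.
#'
#' Any stage error aborts the run with the stage named; outputs of completed
#' stages are retained.
#'
#' @param outDir output directory (created).
#' @param cfg a [cohortConfig()]; ignored when \code{inputDir} is given.
#' @param inputDir optional directory produced by [generateCohort()] (or
#'   following the same layout) to analyse instead of simulating.
#' @param mesh run the mesh/asymmetry stage.
#' @param asymmetrySubset optional number of subjects per class for the
#'   asymmetry stage (default: all; lower it for quick runs).
#' @param template optional prebuilt [SymmetricTemplate-class].
#' @param tTestVariant,iccForm,lambda,iterations,heatLimits analysis flags
#'   passed to the respective stages.
#' @param renderViews write PNG renders of the four canonical heat-map
#'   views.
#' @return invisibly, a list with the cohort table, group summary, class
#'   distribution, per-subject asymmetry table (if run) and the manifest.
#' @export
runPipeline <- function(outDir, cfg = cohortConfig(), inputDir = NULL,
                        mesh = FALSE, asymmetrySubset = NULL,
                        template = NULL,
                        tTestVariant = c("pooled", "welch"),
                        iccForm = "ICC2", lambda = 0, iterations = 1,
                        heatLimits = c(0, 5), renderViews = FALSE) {
  tTestVariant <- match.arg(tTestVariant)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(line, "\n", sep = "", file = logFile, append = TRUE)
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, " started")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- stage: cohort ---------------------------------------------------
  cohort <- stage("cohort", {
    if (is.null(inputDir)) {
      if (mesh && is.null(template)) template <- buildTemplate()
      generateCohort(cfg, mesh = mesh, template = template)
    } else {
      roster <- utils::read.csv(file.path(inputDir, "roster.csv"),
                                stringsAsFactors = FALSE)
      lmsList <- lapply(roster$id, function(id)
        readLandmarks(file.path(inputDir, paste0(id, "_landmarks.csv"))))
      names(lmsList) <- roster$id
      attr(roster, "landmarks") <- lmsList
      if (mesh) {
        meshes <- lapply(roster$id, function(id)
          readMesh(file.path(inputDir, paste0(id, ".ply"))))
        names(meshes) <- roster$id
        attr(roster, "meshes") <- meshes
      }
      roster
    }
  })

  ## -- stage: measure --------------------------------------------------
  measured <- stage("measure", {
    lmsList <- attr(cohort, "landmarks")
    pars <- measurementLabels()$name
    m <- t(vapply(cohort$id, function(id) {
      lms <- lmsList[[id]]
      fr <- estimateCanonicalFrame(lms)
      measureSubject(applyFrame(lms, fr))[pars]
    }, numeric(length(pars))))
    out <- cbind(cohort[c("id", "class", "sex", "age")], as.data.frame(m))
    utils::write.csv(out, file.path(outDir, "measurements.csv"),
                     row.names = FALSE)
    out
  })

  ## -- stage: asymmetry ------------------------------------------------
  asymTable <- NULL
  if (mesh) {
    asymTable <- stage("asymmetry", {
      if (is.null(template)) template <- buildTemplate()
      lmsList <- attr(cohort, "landmarks")
      meshes <- attr(cohort, "meshes")
      ids <- unlist(lapply(split(cohort$id, cohort$class), function(v)
        utils::head(v, asymmetrySubset %||% length(v))))
      rows <- list(); heat <- list()
      for (id in ids) {
        res <- analyzeAsymmetry(meshes[[id]], lmsList[[id]],
                                template = template, lambda = lambda,
                                iterations = iterations)
        cl <- cohort$class[cohort$id == id]
        rows[[id]] <- data.frame(id = id, class = cl,
                                 AH = res@AH, AF = res@AF,
                                 H = res@metrics$H, L = res@metrics$L,
                                 W = res@metrics$W, V = res@metrics$V)
        heat[[cl]] <- if (is.null(heat[[cl]])) list(res@vertexValues)
                      else c(heat[[cl]], list(res@vertexValues))
      }
      for (cl in names(heat)) {
        meanHeat <- Reduce(`+`, heat[[cl]]) / length(heat[[cl]])
        exportHeatmap(template, meanHeat,
                      file.path(outDir,
                                paste0("heatmap_class_", cl, ".ply")),
                      limits = heatLimits,
                      views = if (renderViews)
                        file.path(outDir, paste0("views_class_", cl))
                      else NULL)
      }
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      utils::write.csv(out, file.path(outDir, "asymmetry.csv"),
                       row.names = FALSE)
      out
    })
  }

  ## -- stage: statistics -----------------------------------------------
  stats <- stage("statistics", {
    summary <- summarizeCohort(measured, variant = tTestVariant)
    dist <- classDistribution(cohort)
    utils::write.csv(summary, file.path(outDir, "group_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(dist, file.path(outDir, "class_distribution.csv"),
                     row.names = FALSE)
    if (!is.null(asymTable) && all(table(asymTable$class) >= 4)) {
      asum <- summarizeCohort(cbind(asymTable,
                                    sex = cohort$sex[match(asymTable$id,
                                                           cohort$id)]),
                              parameters = c("AH", "AF", "H", "L", "W", "V"),
                              variant = tTestVariant)
      utils::write.csv(asum, file.path(outDir, "asymmetry_summary.csv"),
                       row.names = FALSE)
    }
    list(summary = summary, distribution = dist)
  })

  ## -- stage: manifest -------------------------------------------------
  manifest <- stage("manifest", {
    cfgFile <- tempfile()
    saveRDS(cfg, cfgFile)
    man <- list(
      package = "craniosym",
      version = as.character(utils::packageVersion("craniosym")),
      seed = cfg$seed,
      n_subjects = nrow(cohort),
      classes = as.list(table(cohort$class)),
      config_hash = unname(tools::md5sum(cfgFile)),
      flags = list(tTestVariant = tTestVariant, iccForm = iccForm,
                   lambda = lambda, iterations = iterations,
                   heatLimits = heatLimits),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    )
    unlink(cfgFile)
    jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    man
  })
  logmsg("run complete: ", nrow(cohort), " subjects")

  invisible(list(cohort = cohort, measured = measured,
                 summary = stats$summary, distribution = stats$distribution,
                 asymmetry = asymTable, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
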