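## Cohort statistics: unpaired two-sample t tests (pooled by default, Welch
## by flag), one-way fixed-effects ANOVA across the three occlusion classes,
## ICC(2,1) for inter-rater agreement, and group-summary tables.  No
## multiple-testing correction is applied (each comparison is reported at
## its nominal level).

#' Unpaired two-sample t test
#'
#' Accepts either raw samples (\code{x}, \code{y}) or summary statistics
#' (\code{nx, meanx, sdx} vs \code{ny, meany, sdy}), e.g. when reproducing
#' published group tables.  The pooled-variance Student test is the default;
#' Welch is available via \code{variant}.
#'
#' @param x,y numeric samples (ignored when summary statistics are given).
#' @param variant \code{"pooled"} or \code{"welch"}.
#' @param nx,meanx,sdx,ny,meany,sdy optional summary statistics.
#' @return list with \code{t}, \code{df}, \code{p} (two-sided).
#' @export
#' @examples
#' twoSampleT(nx = 38, meanx = 20.54, sdx = 1.90,
#'            ny = 36, meany = 19.15, sdy = 2.42)$p
twoSampleT <- function(x = NULL, y = NULL, variant = c("pooled", "welch"),
                       nx = NULL, meanx = NULL, sdx = NULL,
                       ny = NULL, meany = NULL, sdy = NULL) {
  variant <- match.arg(variant)
  if (is.null(nx)) {
    if (length(x) < 2 || length(y) < 2)
      stop("need at least 2 observations per group")
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      df <- length(x) + length(y) - 2
      if (mean(x) == mean(y)) return(list(t = 0, df = df, p = 1))
      return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
    }
    ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
    return(list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value))
  }
  if (nx < 2 || ny < 2) stop("need at least 2 observations per group")
  if (sdx == 0 && sdy == 0) {
    if (meanx == meany) return(list(t = 0, df = nx + ny - 2, p = 1))
    return(list(t = sign(meanx - meany) * Inf, df = nx + ny - 2, p = 0))
  }
  if (variant == "pooled") {
    sp2 <- ((nx - 1) * sdx^2 + (ny - 1) * sdy^2) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    a <- sdx^2 / nx; b <- sdy^2 / ny
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (nx - 1) + b^2 / (ny - 1))
  }
  t <- (meanx - meany) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' One-way fixed-effects ANOVA
#'
#' With exactly two groups, F equals the square of the pooled two-sample t
#' statistic.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2))
    stop("each group needs at least 2 observations")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (stats::var(values) == 0)
    return(list(F = 0, df1 = length(groups) - 1,
                df2 = length(values) - length(groups), p = 1))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p = fit$p.value)
}

#' Intraclass correlation coefficient for inter-rater agreement
#'
#' ICC(2,1): two-way random effects, absolute agreement, single measurement,
#' computed from the two-way mean-squares decomposition
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)}
#' with n subjects (rows) and k raters (columns).  ICC(3,1) (consistency,
#' raters fixed) is available via \code{form}.
#'
#' @param ratings n x k numeric matrix, subjects in rows, raters in columns;
#'   no missing cells.
#' @param form \code{"ICC2"} (default) or \code{"ICC3"}.
#' @return the ICC estimate (scalar).
#' @export
iccAgreement <- function(ratings, form = c("ICC2", "ICC3")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2) stop("need at least 2 raters")
  if (n < 5) stop("need at least 5 subjects")
  if (anyNA(ratings)) stop("missing cells are not supported")
  if (stats::var(as.vector(ratings)) == 0)
    stop("constant ratings: ICC is undefined")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  SSR <- k * sum((rowm - grand)^2)                 # subjects (rows)
  SSC <- n * sum((colm - grand)^2)                 # raters (columns)
  SSE <- sum((ratings - outer(rowm, rep(1, k)) -
              outer(rep(1, n), colm) + grand)^2)   # residual
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (form == "ICC2")
    (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  else
    (MSR - MSE) / (MSR + (k - 1) * MSE)
}

#' Class distribution of a cohort roster
#'
#' @param cohort data.frame with columns \code{class} (\code{"I"},
#'   \code{"II"}, \code{"III"}) and \code{sex} (\code{"M"}, \code{"F"}).
#' @return data.frame with counts and percentages (percent of the total,
#'   rounded to one decimal) per class, plus per-sex counts.
#' @export
classDistribution <- function(cohort) {
  stopifnot(all(c("class", "sex") %in% names(cohort)))
  total <- nrow(cohort)
  cls <- c("I", "II", "III")
  out <- data.frame(
    class = cls,
    n = vapply(cls, function(cl) sum(cohort$class == cl), 0L),
    male = vapply(cls, function(cl)
      sum(cohort$class == cl & cohort$sex == "M"), 0L),
    female = vapply(cls, function(cl)
      sum(cohort$class == cl & cohort$sex == "F"), 0L),
    row.names = NULL
  )
  out$percent <- round(100 * out$n / total, 1)
  out
}

#' Group summary tables in the published layout
#'
#' For each parameter: per-class x per-sex n/mean/SD rows, a Total row
#' computed from the raw per-subject values (never from rounded subgroup
#' summaries), the omnibus 3-class ANOVA p per sex and overall, the three
#' pairwise class contrasts (pooled t on the Totals), and the within-class
#' sex contrast.  Significance is flagged at p <= 0.05 with no
#' multiple-testing correction.
#'
#' @param cohort data.frame with \code{class}, \code{sex} and parameter
#'   columns.
#' @param parameters character vector of parameter columns (defaults to the
#'   14-parameter battery present in the table).
#' @param variant t-test variant for the pairwise contrasts.
#' @return data.frame, one row per parameter x (M, F, Total).
#' @export
summarizeCohort <- function(cohort, parameters = NULL,
                            variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (is.null(parameters))
    parameters <- intersect(measurementLabels()$name, names(cohort))
  cls <- c("I", "II", "III")
  rows <- list()
  for (par in parameters) {
    for (grp in c("M", "F", "Total")) {
      sel <- if (grp == "Total") rep(TRUE, nrow(cohort))
             else cohort$sex == grp
      vals <- lapply(cls, function(cl)
        cohort[[par]][sel & cohort$class == cl])
      ns <- vapply(vals, length, 0L)
      means <- vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
                      0)
      sds <- vapply(vals, function(v)
        if (length(v) > 1) stats::sd(v) else NA_real_, 0)
      ok <- ns >= 2
      if (sum(ok) < 2) {
        warning("empty/degenerate cells for ", par, " (", grp, ")")
        pOmni <- NA_real_
      } else {
        pOmni <- oneWayAnova(vals[ok])$p
      }
      pw <- function(i, j) {
        if (ns[i] < 2 || ns[j] < 2) return(NA_real_)
        twoSampleT(vals[[i]], vals[[j]], variant = variant)$p
      }
      pSex <- if (grp == "Total") {
        NA_real_
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        parameter = par, group = grp,
        n_I = ns[1], mean_I = round(means[1], 2), sd_I = round(sds[1], 2),
        n_II = ns[2], mean_II = round(means[2], 2), sd_II = round(sds[2], 2),
        n_III = ns[3], mean_III = round(means[3], 2),
        sd_III = round(sds[3], 2),
        p_omnibus = pOmni,
        p_I_II = if (grp == "Total") pw(1, 2) else NA_real_,
        p_I_III = if (grp == "Total") pw(1, 3) else NA_real_,
        p_II_III = if (grp == "Total") pw(2, 3) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
    ## within-class sex contrasts
    for (i in seq_along(cls)) {
      m <- cohort[[par]][cohort$sex == "M" & cohort$class == cls[i]]
      f <- cohort[[par]][cohort$sex == "F" & cohort$class == cls[i]]
      rows[[length(rows)]][[paste0("p_sex_", cls[i])]] <-
        if (length(m) >= 2 && length(f) >= 2)
          twoSampleT(m, f, variant = variant)$p else NA_real_
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    for (cc in c("p_sex_I", "p_sex_II", "p_sex_III"))
      if (is.null(r[[cc]])) r[[cc]] <- NA_real_
    r
  }))
  out$significant <- !is.na(out$p_omnibus) & out$p_omnibus <= 0.05
  rownames(out) <- NULL
  out
}
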