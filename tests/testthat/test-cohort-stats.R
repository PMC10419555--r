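test_that("two-sample t: identities, base-R agreement and summary input", {
  set.seed(40)
  x <- stats::rnorm(20, 10, 2); y <- stats::rnorm(25, 11, 3)
  expect_equal(twoSampleT(x, x)$t, 0)
  expect_equal(twoSampleT(x, x)$p, 1)

  for (variant in c("pooled", "welch")) {
    got <- twoSampleT(x, y, variant = variant)
    ref <- stats::t.test(x, y, var.equal = (variant == "pooled"))
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    # summary-statistic input reproduces the raw-data test exactly
    gs <- twoSampleT(variant = variant,
                     nx = length(x), meanx = mean(x), sdx = stats::sd(x),
                     ny = length(y), meany = mean(y), sdy = stats::sd(y))
    expect_equal(gs$t, got$t, tolerance = 1e-12)
    expect_equal(gs$p, got$p, tolerance = 1e-12)
  }
  expect_error(twoSampleT(x[1], y), "at least 2")
})

test_that("pooled t agrees with a permutation test on small samples", {
  set.seed(41)
  x <- stats::rnorm(8, 0, 1); y <- stats::rnorm(7, 1.2, 1)
  pT <- twoSampleT(x, y)$p
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  perm <- replicate(4000, {
    idx <- sample(length(pooled), length(x))
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  pPerm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(pT - pPerm), 0.02)
})

test_that("one-way ANOVA: identities and base-R agreement", {
  expect_equal(oneWayAnova(list(rep(2, 5), rep(2, 6)))$p, 1)
  set.seed(42)
  g <- list(stats::rnorm(12, 0), stats::rnorm(10, 0.5), stats::rnorm(14, 1))
  got <- oneWayAnova(g)
  df <- data.frame(v = unlist(g),
                   f = factor(rep(1:3, times = lengths(g))))
  ref <- stats::anova(stats::aov(v ~ f, data = df))
  expect_equal(got$F, ref[1, "F value"], tolerance = 1e-9)
  expect_equal(got$p, ref[1, "Pr(>F)"], tolerance = 1e-9)

  # two-group case: F = t^2 and the p values coincide
  t2 <- twoSampleT(g[[1]], g[[2]])
  a2 <- oneWayAnova(g[1:2])
  expect_equal(a2$F, t2$t^2, tolerance = 1e-9)
  expect_equal(a2$p, t2$p, tolerance = 1e-9)
  expect_error(oneWayAnova(list(1:3)), "at least 2 groups")
  expect_error(oneWayAnova(list(1:3, 2)), "at least 2 observations")
})

test_that("ICC(2,1) equals the independently fitted mean-squares oracle", {
  set.seed(43)
  for (k in 1:5) {
    n <- sample(5:40, 1); r <- sample(2:4, 1)
    ratings <- matrix(stats::rnorm(n * r, 50, 8), n, r) +
      stats::rnorm(n, 0, 4)          # subject effect
    got <- iccAgreement(ratings)
    # oracle: two-way ANOVA mean squares via stats::aov
    df <- data.frame(y = as.vector(ratings),
                     subj = factor(rep(seq_len(n), r)),
                     rater = factor(rep(seq_len(r), each = n)))
    ms <- stats::anova(stats::aov(y ~ subj + rater, data = df))
    MSR <- ms["subj", "Mean Sq"]; MSC <- ms["rater", "Mean Sq"]
    MSE <- ms["Residuals", "Mean Sq"]
    oracle <- (MSR - MSE) / (MSR + (r - 1) * MSE + r * (MSC - MSE) / n)
    expect_equal(got, oracle, tolerance = 1e-9)
    oracle3 <- (MSR - MSE) / (MSR + (r - 1) * MSE)
    expect_equal(iccAgreement(ratings, form = "ICC3"), oracle3,
                 tolerance = 1e-9)
  }
})

test_that("ICC edge cases and invariances", {
  set.seed(44)
  r1 <- stats::rnorm(12, 20, 5)
  expect_equal(iccAgreement(cbind(r1, r1)), 1, tolerance = 1e-12)
  ratings <- cbind(r1, r1 + stats::rnorm(12, 0, 1))
  base <- iccAgreement(ratings)
  expect_equal(iccAgreement(ratings + 100), base, tolerance = 1e-9)
  expect_equal(iccAgreement(ratings * 7), base, tolerance = 1e-9)
  expect_error(iccAgreement(matrix(5, 10, 2)), "constant ratings")
  expect_error(iccAgreement(ratings[1:3, ]), "at least 5 subjects")
  expect_error(iccAgreement(ratings[, 1, drop = FALSE]), "at least 2 raters")
})

test_that("class distribution reproduces the published percentages", {
  cohort <- data.frame(
    class = rep(c("I", "II", "III"), c(74, 50, 15)),
    sex = c(rep(c("M", "F"), c(38, 36)), rep(c("M", "F"), c(24, 26)),
            rep(c("M", "F"), c(4, 11))))
  cd <- classDistribution(cohort)
  expect_equal(cd$percent, c(53.2, 36.0, 10.8))
  expect_equal(cd$n, c(74L, 50L, 15L))
  expect_equal(cd$male, c(38L, 24L, 4L))
  # independent tally
  expect_equal(cd$n, unname(vapply(c("I", "II", "III"), function(cl) {
    k <- 0L
    for (i in seq_len(nrow(cohort))) if (cohort$class[i] == cl) k <- k + 1L
    k
  }, 0L)))
  one <- classDistribution(data.frame(class = rep("II", 9),
                                      sex = rep("F", 9)))
  expect_equal(one$percent, c(0, 100, 0))
})

test_that("cohort summaries: degenerate cohorts and sampling consistency", {
  # identical subjects: all p = 1, SD = 0
  flat <- data.frame(class = rep(c("I", "II", "III"), c(8, 8, 8)),
                     sex = rep(c("M", "F"), 12), N_Gn = 100)
  s <- summarizeCohort(flat, parameters = "N_Gn")
  expect_true(all(s$p_omnibus == 1))
  expect_true(all(s[s$group == "Total", c("sd_I", "sd_II", "sd_III")] == 0))

  # simulated cohort: Total means within 2 SEM of the configured means
  cohort <- generateCohort(cohortConfig(seed = 77))
  norms <- referenceNorms()
  s2 <- summarizeCohort(cohort)
  for (par in c("N_Sn", "Sn_Sto", "Go_Gn", "facial_convexity")) {
    tot <- s2[s2$parameter == par & s2$group == "Total", ]
    for (cl in c("I", "II", "III")) {
      cell <- norms$measurements[[par]][[cl]]
      nM <- norms$roster[[cl]]$M; nF <- norms$roster[[cl]]$F
      mu <- (nM * cell$M[1] + nF * cell$F[1]) / (nM + nF)
      sdP <- sqrt((nM * cell$M[2]^2 + nF * cell$F[2]^2) / (nM + nF) +
                    nM * nF * (cell$M[1] - cell$F[1])^2 / (nM + nF)^2)
      sem <- sdP / sqrt(nM + nF)
      # 3 SEM: 12 cells are checked simultaneously
      expect_lt(abs(tot[[paste0("mean_", cl)]] - mu), 3 * sem + 0.01)
    }
  }
})
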