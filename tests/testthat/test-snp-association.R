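test_that("reference allele is the control-major allele", {
  r <- assignReferenceAllele(c(0, 0, 1, 2))
  expect_equal(r, list(maf = 0.375, flipped = FALSE))
  r <- assignReferenceAllele(c(2, 2, 2, 1))
  expect_equal(r, list(maf = 0.125, flipped = TRUE))
  # tie at exactly 0.5 keeps the panel orientation
  r <- assignReferenceAllele(c(1, 1, 1, 1))
  expect_equal(r, list(maf = 0.5, flipped = FALSE))
  expect_error(assignReferenceAllele(c(NA, NA)), "no non-missing")
})

test_that("inheritance-model encodings follow the genotype contrasts", {
  expect_equal(unname(encodeModel(0:2, "allelic")[, 1]), 0:2)
  cod <- encodeModel(0:2, "codominant")
  expect_equal(unname(cod[, "het"]), c(0, 1, 0))
  expect_equal(unname(cod[, "hom"]), c(0, 0, 1))
  expect_equal(unname(encodeModel(0:2, "dominant")[, 1]), c(0, 1, 1))
})

test_that("logistic fit matches the closed-form 2x2 solution", {
  dat <- expand2x2(39, 37, 84, 176)
  fit <- logisticFit(cbind(x = dat$x), dat$y)
  cf <- closedForm2x2(39, 37, 84, 176)
  expect_equal(unname(fit$coefficients["x"]), cf$beta, tolerance = 1e-10)
  expect_equal(unname(fit$standard_errors["x"]), cf$se, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["(Intercept)"]), cf$intercept,
               tolerance = 1e-10)
  expect_true(fit$converged)

  # intercept-only: log case/control odds of the cohort
  f0 <- logisticFit(NULL, c(rep(1, 78), rep(0, 256)))
  expect_equal(unname(f0$coefficients), log(78 / 256), tolerance = 1e-10)

  expect_error(logisticFit(cbind(x = c(1, 0)), c(1, 1)), "single class")
  expect_error(logisticFit(cbind(a = c(1, 0, 1, 0), b = c(2, 0, 2, 0)),
                           c(1, 1, 0, 0)), "collinear.*b")
})

test_that("complete separation is flagged", {
  y <- c(rep(1, 20), rep(0, 20))
  x <- c(rep(1, 20), rep(0, 20))
  fit <- logisticFit(cbind(x = x + stats::rnorm(40, 0, 1e-6)), y)
  expect_true(fit$separation_flag)
})

test_that("trend test equals the Cochran-Armitage score formula", {
  same <- rbind(c(10, 20, 30), c(10, 20, 30))
  expect_equal(trendTest(same), 1)
  mono <- rbind(c(10, 20, 30), c(30, 20, 10))
  expect_equal(trendTest(mono), oracleTrend(mono), tolerance = 1e-10)
  set.seed(21)
  for (i in 1:50) {
    tab <- matrix(stats::rpois(6, 15) + 1, 2)
    expect_equal(trendTest(tab), oracleTrend(tab), tolerance = 1e-10)
  }
  expect_error(trendTest(rbind(c(0, 0, 0), c(1, 2, 3))), "degenerate")
})

test_that("trend test holds its size under the null", {
  set.seed(31)
  rej <- 0; reps <- 2000; n <- 150
  probs <- c(0.49, 0.42, 0.09)  # HWE at maf 0.3
  for (i in 1:reps) {
    tab <- cbind(stats::rmultinom(1, n, probs), stats::rmultinom(1, n, probs))
    if (trendTest(t(tab)) < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.03)
  expect_lt(rej / reps, 0.07)
})

simAssocStudy <- function(or, maf, n, seed) {
  panel <- makePanel(1, maf = maf, or = or, rsid = "rsS")
  cfg <- simConfig(nCases = n, nControls = n, panel = panel,
                   missingRate = 0, duplicateFraction = 0, seed = seed)
  simulateCohort(cfg)
}

test_that("allelic OR recovers the simulated effect and the null", {
  null <- associateSnp(simAssocStudy(1, 0.3, 5000, 17), "rsS")
  expect_gt(null$allelic_or, 0.9)
  expect_lt(null$allelic_or, 1.1)
  eff <- associateSnp(simAssocStudy(2, 0.3, 5000, 18), "rsS")
  expect_gt(eff$allelic_or, 1.85)
  expect_lt(eff$allelic_or, 2.15)
  expect_lt(eff$allelic_p, 0.05)
  expect_true(eff$significant)
})

test_that("empty homozygote cells yield undefined contrasts, not failures", {
  study <- simAssocStudy(1, 0.05, 60, 23)
  geno <- t(dosageMatrix(study))
  geno[, "rsS"][geno[, "rsS"] == 2] <- 1  # remove all minor homozygotes
  st2 <- SnpStudy(geno, snpPanel(study), subjectData(study))
  row <- associateSnp(st2, "rsS")
  expect_true(is.na(row$hom_or))
  expect_false(is.na(row$het_or))
  expect_false(is.na(row$dom_or))
})

test_that("scant complete cases are flagged instead of fit", {
  study <- simAssocStudy(1, 0.3, 8, 29)
  row <- associateSnp(study, "rsS")
  expect_true(row$insufficient_data)
  expect_true(is.na(row$allelic_or))
})

test_that("associateAll emits one row per analyzed SNP plus Bonferroni", {
  study <- simulateCohort(simConfig(seed = 5))
  qc <- runQc(study, hweExclude = FALSE)
  res <- associateAll(qc$study)
  expect_equal(nrow(res), nrow(qc$study))
  expect_true(all(res$maf_controls <= 0.5, na.rm = TRUE))
  expect_true(all(res$p_allelic_bonferroni >= res$allelic_p, na.rm = TRUE))
  ok <- !is.na(res$allelic_or)
  expect_true(all(res$allelic_ci_low[ok] <= res$allelic_or[ok] &
                    res$allelic_or[ok] <= res$allelic_ci_high[ok]))
})

test_that("the age adjustment recovers an injected age effect", {
  panel <- makePanel(1, maf = 0.3, or = 1, rsid = "rsS")
  cfg <- simConfig(nCases = 3000, nControls = 3000, panel = panel,
                   ageSd = 10, ageEffect = 0.05,
                   missingRate = 0, duplicateFraction = 0, seed = 37)
  st <- simulateCohort(cfg)
  subj <- subjectData(st)
  fit <- logisticFit(cbind(dosage = t(dosageMatrix(st))[, "rsS"],
                           age = subj$age,
                           sex = as.numeric(subj$sex == "male")),
                     as.numeric(subj$status == "case"))
  expect_equal(unname(fit$coefficients["age"]), 0.05, tolerance = 0.3)
  # genotype stays null in the adjusted model
  expect_lt(abs(fit$coefficients["dosage"]), log(1.1))
})
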