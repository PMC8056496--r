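test_that("risk-allele orientation follows the external odds ratio", {
  expect_equal(riskAlleleDosage(2, 1.5), 2)
  expect_equal(riskAlleleDosage(0, 0.8), 2)  # protective minor: flip
  expect_equal(riskAlleleDosage(1, 0.8), 1)
  expect_true(is.na(riskAlleleDosage(NA, 1.5)))
  expect_error(riskAlleleDosage(1, 0), "positive")
})

test_that("unweighted and weighted scores sum risk alleles correctly", {
  expect_equal(unweightedScore(rep(0, 23)),
               list(raw = 0, n_genotyped = 23L))
  expect_equal(unweightedScore(rep(2, 23)),
               list(raw = 46, n_genotyped = 23L))
  expect_equal(unweightedScore(c(2, 1, 0, NA)),
               list(raw = 3, n_genotyped = 3L))
  expect_true(is.na(unweightedScore(c(NA_real_, NA_real_))$raw))

  expect_equal(weightedScore(2, 2.0)$raw, 2 * log(2), tolerance = 1e-12)
  # protective SNP: heterozygote carries one (major) risk allele
  a <- riskAlleleDosage(1, 0.5)
  expect_equal(weightedScore(a, 0.5)$raw, log(2), tolerance = 1e-12)
  expect_equal(weightedScore(2, 1.0)$raw, 0)
  expect_error(weightedScore(c(1, 1), c(1.2, NA)), "missing weight")
})

test_that("unweighted equals weighted when every OR is e", {
  set.seed(44)
  a <- sample(c(0:2, NA), 30, replace = TRUE)
  u <- unweightedScore(a)
  w <- weightedScore(a, rep(exp(1), 30))
  expect_equal(u$raw, w$raw, tolerance = 1e-12)
  expect_equal(u$n_genotyped, w$n_genotyped)
})

test_that("missingness scaling is exact, homogeneous and identity at full call", {
  expect_equal(scaleScore(10, 23, 23), 10)
  expect_equal(scaleScore(10, 23, 20), 11.5)
  expect_equal(scaleScore(0, 23, 7), 0)
  expect_equal(scaleScore(3 * 4.2, 25, 18), 3 * scaleScore(4.2, 25, 18))
  expect_error(scaleScore(10, 23, 0), "no genotyped")
})

test_that("control quintiles use nearest-rank, right-closed cutpoints", {
  ctrl <- 1:10
  expect_equal(quintileAssign(7, ctrl), 4L)       # cutpoints 2,4,6,8
  expect_equal(quintileAssign(4, ctrl), 2L)       # equal to c2 stays low
  expect_equal(quintileAssign(c(-5, 2, 8.5, 100), ctrl), c(1L, 1L, 5L, 5L))
  expect_error(quintileAssign(1, rep(3, 10)), "degenerate")
  set.seed(55)
  u <- stats::runif(10000)
  q <- quintileAssign(u, u)
  expect_true(all(abs(table(q) / 10000 - 0.2) <= 0.01))
})

test_that("computePrs produces the four published score variants", {
  study <- runQc(simulateCohort(simConfig(seed = 6)),
                 hweExclude = FALSE)$study
  prs <- computePrs(study)
  # survival-GWAS loci never score; monomorphic locus already QC-dropped
  expect_equal(length(prs@snpSubset), 23L)
  expect_false(any(c("rs684559", "rs353630") %in% prs@snpSubset))
  sc <- prsScores(prs)
  expect_true(all(sc$unweighted >= 0 & sc$unweighted <= 46, na.rm = TRUE))
  full <- !is.na(sc$n_genotyped) & sc$n_genotyped == 23
  expect_equal(sc$unweighted_scaled[full], sc$unweighted[full])
  expect_equal(sc$weighted_scaled[full], sc$weighted[full])
  an <- prsAnalyses(prs)
  expect_equal(names(an),
               c("unweighted_full_callrate", "unweighted_scaled_all",
                 "weighted_full_callrate", "weighted_scaled_all"))
  for (b in an) {
    expect_equal(b$term, c(paste0("quintile", 1:5), "continuous"))
    expect_equal(b$or[1], 1)
  }
  # the full-call-rate analysis uses fewer subjects than the scaled one
  expect_lt(sum(an$unweighted_full_callrate$cases, na.rm = TRUE),
            ncol(study))
})

test_that("a 9-SNP subset score runs with the same schema", {
  ref <- referenceAssociation()
  nine <- ref$rsid[ref$significant]
  expect_length(nine, 9L)
  study <- runQc(simulateCohort(simConfig(seed = 6)),
                 hweExclude = FALSE)$study
  prs <- computePrs(study, snpSubset = nine)
  expect_equal(sort(prs@snpSubset), sort(nine))
  expect_equal(names(prsAnalyses(prs)),
               c("unweighted_full_callrate", "unweighted_scaled_all",
                 "weighted_full_callrate", "weighted_scaled_all"))
  expect_true(all(prsScores(prs)$unweighted <= 18, na.rm = TRUE))
})

test_that("aggregate simulated risk shows up as increasing quintile ORs", {
  panel <- makePanel(10, maf = 0.3, or = 1.5)
  cfg <- simConfig(nCases = 700, nControls = 700, panel = panel,
                   missingRate = 0, duplicateFraction = 0, seed = 77)
  prs <- computePrs(runQc(simulateCohort(cfg))$study)
  blk <- prsAnalyses(prs)$weighted_full_callrate
  top <- blk$or[blk$term == "quintile5"]
  cont <- blk$or[blk$term == "continuous"]
  expect_gt(top, cont)     # top-vs-bottom exceeds the per-quintile increment
  expect_gt(cont, 1)
  expect_lt(blk$p[blk$term == "continuous"], 0.05)
})

test_that("null scores give a flat continuous association", {
  # weights stay non-degenerate (panel OR 1.3) but the generative truth is null
  panel <- makePanel(10, maf = 0.3, or = 1.3)
  cfg <- simConfig(nCases = 4000, nControls = 4000, panel = panel,
                   trueOr = stats::setNames(rep(1, 10), panel$rsid),
                   missingRate = 0, duplicateFraction = 0, seed = 78)
  prs <- computePrs(runQc(simulateCohort(cfg))$study)
  cont <- prsAnalyses(prs)$unweighted_full_callrate
  or <- cont$or[cont$term == "continuous"]
  expect_gt(or, 0.95)
  expect_lt(or, 1.05)
})
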