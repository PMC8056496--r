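# Independent oracle implementations used to validate the package's
# statistical primitives. Deliberately coded by a different route than the
# implementations: log-factorial arithmetic instead of dhyper / the
# heterozygote-count recurrence / IRLS.

# Fisher exact, two-sided, by explicit log-factorial enumeration.
oracleFisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  lp <- lfactorial(r1) + lfactorial(n - r1) + lfactorial(c1) +
    lfactorial(n - c1) - lfactorial(n) -
    (lfactorial(support) + lfactorial(r1 - support) +
       lfactorial(c1 - support) + lfactorial(n - r1 - c1 + support))
  pr <- exp(lp)
  obs <- pr[match(a, support)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Fisher p-values for every table with the given margins at once.
oracleFisherAll <- function(r1, c1, n) {
  support <- max(0, r1 + c1 - n):min(r1, c1)
  lp <- lfactorial(r1) + lfactorial(n - r1) + lfactorial(c1) +
    lfactorial(n - c1) - lfactorial(n) -
    (lfactorial(support) + lfactorial(r1 - support) +
       lfactorial(c1 - support) + lfactorial(n - r1 - c1 + support))
  pr <- exp(lp)
  vapply(pr, function(o) min(1, sum(pr[pr <= o * (1 + 1e-7)])), numeric(1))
}

# Exact HWE p by the direct conditional-probability formula.
oracleHwe <- function(nMM, nMm, nmm) {
  n <- nMM + nMm + nmm
  rare <- min(2 * nMM + nMm, 2 * nmm + nMm)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    a <- (rare - h) / 2; b <- n - a - h
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp)
  obs <- pr[match(nMm, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Cochran-Armitage trend p by the direct score formula.
oracleTrend <- function(tab, score = seq_len(ncol(tab)) - 1) {
  r <- tab[1, ]; n <- colSums(tab)
  N <- sum(n); R <- sum(r); pbar <- R / N
  U <- sum(score * (r - n * R / N))
  V <- pbar * (1 - pbar) * (sum(score^2 * n) - sum(score * n)^2 / N)
  stats::pchisq(U^2 / V, df = 1, lower.tail = FALSE)
}

# Closed-form logistic solution for a single binary covariate:
# cells (a, b) = exposed/unexposed cases, (c, d) = exposed/unexposed
# controls.
closedForm2x2 <- function(a, b, c, d) {
  list(beta = log(a * d / (b * c)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d),
       intercept = log(b / d))
}

# Expand a 2x2 of counts into subject-level covariate/outcome vectors.
expand2x2 <- function(a, b, c, d) {
  list(x = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
       y = c(rep(1, a + b), rep(0, c + d)))
}

# Small simulation panel for targeted cohorts.
makePanel <- function(m, maf = 0.3, or = 1, rsid = sprintf("rs%03d", seq_len(m))) {
  data.frame(rsid = rsid, gene = "SIM",
             major = "A", minor = "G",
             gwas_or = rep(or, length.out = m),
             in_prs = TRUE,
             ref_maf_study_controls = rep(maf, length.out = m),
             stringsAsFactors = FALSE)
}

exampleFixtureDir <- function() {
  system.file("extdata", "example_cohort", package = "pancprs")
}
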