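#' Synthetic-cohort configuration
#'
#' Defaults reproduce the published study's structure: 78 cases and 256
#' controls; control genotypes in exact Hardy-Weinberg proportions at the
#' published control minor-allele frequencies (a MAF of 0 encodes a
#' monomorphic locus); case genotypes from the tilted distribution implied
#' by an additive logistic disease model at the published per-allele odds
#' ratios; ages normal with the published group means (SD 26 years,
#' back-derived from the published age comparison); sex and self-reported
#' ancestry at the published group proportions; exposures as independent
#' Bernoulli draws at the published group rates; sparse genotype missingness
#' (rate 0.005, matching the share of subjects with a perfect call rate);
#' 5\% duplicated samples for concordance QC. A fraction of subjects can be
#' given heavy missingness to exercise the 75\% call-rate filter (default
#' 0, the cohort's post-QC state).
#'
#' @param nCases,nControls group sizes.
#' @param panel SNP panel data.frame; its \code{ref_maf_study_controls} and
#'   \code{gwas_or} columns supply the default MAFs and true ORs.
#' @param controlMaf,trueOr per-SNP overrides (named or in panel order).
#' @param ageMeanCase,ageMeanControl,ageSd age model (years).
#' @param propFemaleCase,propFemaleControl sex model.
#' @param ancestryProbsCase,ancestryProbsControl named probabilities over
#'   African/European/Asian (normalised internally).
#' @param exposureRates 2-row matrix (case, control) x exposure rates.
#' @param missingRate per-genotype missingness probability.
#' @param lowCallrateFraction fraction of subjects given heavy (about 50\%)
#'   missingness.
#' @param duplicateFraction fraction of subjects re-issued as declared
#'   duplicates.
#' @param ageEffect optional log-odds-per-year effect of age on disease
#'   risk (default 0). When set, case ages are drawn from the exponentially
#'   tilted control age distribution (mean shifted by
#'   \code{ageEffect * ageSd^2}, overriding \code{ageMeanCase}), the exact
#'   case age law under a log-linear risk model; used to check that the
#'   age adjustment is wired correctly.
#' @param seed integer seed; identical seed and config give a bit-identical
#'   cohort.
#' @return validated config list of class \code{simConfig}.
#' @export
simConfig <- function(nCases = 78, nControls = 256,
                      panel = defaultPanel(),
                      controlMaf = NULL, trueOr = NULL,
                      ageMeanCase = 62.46, ageMeanControl = 56.62,
                      ageSd = 26,
                      propFemaleCase = 0.59, propFemaleControl = 0.57,
                      ancestryProbsCase = c(African = 0.32,
                                            European = 0.667,
                                            Asian = 0.013),
                      ancestryProbsControl = c(African = 0.175,
                                               European = 0.813,
                                               Asian = 0.012),
                      exposureRates = rbind(
                        case = c(tobacco = 0.5132, alcohol = 0.3158,
                                 diabetes = 0.3553, pancreatitis = 0.1053,
                                 family_history = 0.10),
                        control = c(tobacco = 0.3231, alcohol = 0.3231,
                                    diabetes = 0.0962, pancreatitis = 0.0077,
                                    family_history = 0.07)),
                      missingRate = 0.005, lowCallrateFraction = 0,
                      duplicateFraction = 0.05, ageEffect = 0, seed = 1) {
  if (is.null(controlMaf)) {
    controlMaf <- stats::setNames(panel$ref_maf_study_controls, panel$rsid)
  } else if (is.null(names(controlMaf))) {
    names(controlMaf) <- panel$rsid[seq_along(controlMaf)]
  }
  if (is.null(trueOr)) {
    trueOr <- stats::setNames(panel$gwas_or, panel$rsid)[names(controlMaf)]
  } else if (is.null(names(trueOr))) {
    if (length(trueOr) == 1L) trueOr <- rep(trueOr, length(controlMaf))
    if (length(trueOr) != length(controlMaf))
      stop("trueOr must have one value per SNP")
    names(trueOr) <- names(controlMaf)
  }
  stopifnot(nCases > 0, nControls > 0)
  if (any(is.na(controlMaf) | controlMaf < 0 | controlMaf >= 1))
    stop("control MAFs must lie in [0, 1)")
  if (any(is.na(trueOr) | trueOr <= 0)) stop("true ORs must be positive")
  if (missingRate < 0 || missingRate >= 1) stop("missingRate outside [0, 1)")
  for (p in list(propFemaleCase, propFemaleControl, lowCallrateFraction,
                 duplicateFraction, exposureRates))
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  cfg <- list(nCases = nCases, nControls = nControls,
              panel = panel[match(names(controlMaf), panel$rsid), ,
                            drop = FALSE],
              controlMaf = controlMaf, trueOr = trueOr,
              ageMeanCase = ageMeanCase, ageMeanControl = ageMeanControl,
              ageSd = ageSd, propFemaleCase = propFemaleCase,
              propFemaleControl = propFemaleControl,
              ancestryProbsCase =
                ancestryProbsCase / sum(ancestryProbsCase),
              ancestryProbsControl =
                ancestryProbsControl / sum(ancestryProbsControl),
              exposureRates = exposureRates,
              missingRate = missingRate,
              lowCallrateFraction = lowCallrateFraction,
              duplicateFraction = duplicateFraction,
              ageEffect = ageEffect, seed = seed)
  class(cfg) <- "simConfig"
  cfg
}

#' Expected case minor-allele frequency under the tilted model
#'
#' Under control-HWE genotype proportions (q^2, 2pq, p^2 with p = control
#' MAF) and an additive per-allele odds ratio, the case genotype
#' distribution is proportional to HWE(g) * OR^g, giving expected case MAF
#' (2 p^2 OR^2 + 2 p q OR) / (2 (p^2 OR^2 + 2 p q OR + q^2)).
#'
#' @param maf control minor-allele frequency.
#' @param or per-minor-allele odds ratio.
#' @return expected case MAF.
#' @export
expectedCaseMaf <- function(maf, or) {
  p <- maf; q <- 1 - maf
  num <- 2 * p^2 * or^2 + 2 * p * q * or
  den <- 2 * (p^2 * or^2 + 2 * p * q * or + q^2)
  num / den
}

## genotype draw for n subjects at one SNP: HWE tilted by or^g
draw_genotypes <- function(n, maf, or) {
  if (maf == 0) return(rep(0, n))
  p <- maf; q <- 1 - maf
  w <- c(q^2, 2 * p * q * or, p^2 * or^2)
  sample(0:2, n, replace = TRUE, prob = w / sum(w))
}

#' Simulate exposure flags
#'
#' Independent Bernoulli draws per subject and exposure at the supplied
#' rates.
#'
#' @param n number of subjects.
#' @param rates named exposure rates in [0, 1].
#' @return character matrix of \code{"yes"} / \code{"no"}, one column per
#'   exposure.
#' @export
simulateExposures <- function(n, rates) {
  if (any(rates < 0 | rates > 1)) stop("rates outside [0, 1]")
  out <- vapply(names(rates), function(v)
    ifelse(stats::runif(n) < rates[[v]], "yes", "no"),
    character(n))
  if (n == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL,
                                                            names(rates)))
  out
}

#' Simulate a case-control cohort
#'
#' Control genotypes per SNP from exact Hardy-Weinberg proportions at the
#' configured control MAF; case genotypes from the tilted distribution
#' P(g | case) proportional to HWE(g) * OR^g (independent SNPs, no linkage
#' disequilibrium). Ages are normal per group (truncated to [0, 120]), sex
#' and ancestry categorical per group, exposures independent Bernoulli.
#' Missingness is applied uniformly at \code{missingRate}, with
#' \code{lowCallrateFraction} of subjects given about 50\% missingness to
#' exercise the call-rate filter; \code{duplicateFraction} of subjects are
#' copied verbatim under fresh IDs with \code{duplicate_of} set. All
#' randomness flows from \code{config$seed}.
#'
#' @param config a [simConfig()].
#' @return a [SnpStudy-class] (duplicates and low-call-rate subjects
#'   included; run [runQc()] to filter).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  nCa <- config$nCases; nCo <- config$nControls
  n <- nCa + nCo
  rsids <- names(config$controlMaf)

  status <- c(rep("case", nCa), rep("control", nCo))
  ids <- sprintf("S%04d", seq_len(n))

  geno <- matrix(NA_real_, n, length(rsids), dimnames = list(ids, rsids))
  for (j in seq_along(rsids)) {
    maf <- config$controlMaf[j]
    geno[status == "control", j] <- draw_genotypes(nCo, maf, 1)
    geno[status == "case", j] <- draw_genotypes(nCa, maf, config$trueOr[j])
  }

  ## with a log-linear age effect on risk, case-control sampling tilts the
  ## control age density exponentially: normal again, mean + effect * sd^2
  caseAgeMean <- if (config$ageEffect != 0)
    config$ageMeanControl + config$ageEffect * config$ageSd^2
  else config$ageMeanCase
  age <- ifelse(status == "case",
                stats::rnorm(n, caseAgeMean, config$ageSd),
                stats::rnorm(n, config$ageMeanControl, config$ageSd))
  age <- round(pmin(120, pmax(0, age)), 1)
  pf <- ifelse(status == "case", config$propFemaleCase,
               config$propFemaleControl)
  sex <- ifelse(stats::runif(n) < pf, "female", "male")
  ancestry <- character(n)
  ancestry[status == "case"] <- sample(names(config$ancestryProbsCase), nCa,
                                       TRUE, config$ancestryProbsCase)
  ancestry[status == "control"] <- sample(names(config$ancestryProbsControl),
                                          nCo, TRUE,
                                          config$ancestryProbsControl)
  expo <- matrix(NA_character_, n, ncol(config$exposureRates),
                 dimnames = list(NULL, colnames(config$exposureRates)))
  expo[status == "case", ] <- simulateExposures(
    nCa, config$exposureRates["case", ])
  expo[status == "control", ] <- simulateExposures(
    nCo, config$exposureRates["control", ])

  miss_rate <- rep(config$missingRate, n)
  if (config$lowCallrateFraction > 0) {
    nLow <- ceiling(config$lowCallrateFraction * n)
    low <- sample(n, nLow)
    miss_rate[low] <- stats::runif(nLow, 0.35, 0.65)
  }
  miss <- matrix(stats::runif(n * length(rsids)), n) < miss_rate
  geno[miss] <- NA

  subjects <- data.frame(subject_id = ids, status = status, age = age,
                         sex = sex, ancestry = ancestry, expo,
                         duplicate_of = NA_character_,
                         stringsAsFactors = FALSE)

  if (config$duplicateFraction > 0) {
    nDup <- ceiling(config$duplicateFraction * n)
    src <- sample(n, nDup)
    dup_ids <- paste0(ids[src], "D")
    dgeno <- geno[src, , drop = FALSE]
    rownames(dgeno) <- dup_ids
    geno <- rbind(geno, dgeno)
    dsub <- subjects[src, , drop = FALSE]
    dsub$subject_id <- dup_ids
    dsub$duplicate_of <- ids[src]
    subjects <- rbind(subjects, dsub)
  }
  SnpStudy(geno, config$panel, subjects)
}

#' Write a cohort as the pipeline's three input files
#'
#' Emits \code{genotypes.tsv}, \code{subjects.tsv} and \code{panel.tsv}
#' consumable by [readGenotypes()], [readSubjects()] and [loadPanel()];
#' deterministic output (same cohort, same bytes).
#'
#' @param study a [SnpStudy-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the three paths.
#' @export
writeFixture <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- file.path(dir, "genotypes.tsv")
  s <- file.path(dir, "subjects.tsv")
  p <- file.path(dir, "panel.tsv")
  writeGenotypes(t(dosageMatrix(study)), g)
  writeSubjects(subjectData(study), s)
  writePanel(snpPanel(study), p)
  invisible(c(genotypes = g, subjects = s, panel = p))
}
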