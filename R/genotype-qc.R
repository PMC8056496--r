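#' Per-subject genotyping call rate
#'
#' Fraction of panel SNPs with a non-missing call for one subject. Subjects
#' below 75\% are discarded by [runQc()], mirroring standard array QC.
#'
#' @param row numeric vector of dosages (length = panel size).
#' @return call rate in [0, 1].
#' @export
callRate <- function(row) {
  if (length(row) == 0L) stop("zero-length dosage row")
  mean(!is.na(row))
}

#' Concordance between a declared duplicate pair
#'
#' Computed only over SNPs called in both members. Pairs below the
#' concordance threshold (default 0.99 in [runQc()]) are flagged; pairs with
#' no jointly called SNP get an undefined concordance and a
#' \code{"no_overlap"} flag.
#'
#' @param rowA,rowB dosage vectors of equal length.
#' @return list with \code{concordance} (NA when undefined) and
#'   \code{n_compared}.
#' @export
duplicateConcordance <- function(rowA, rowB) {
  if (length(rowA) != length(rowB)) stop("duplicate rows differ in length")
  both <- !is.na(rowA) & !is.na(rowB)
  n <- sum(both)
  if (n == 0L) return(list(concordance = NA_real_, n_compared = 0L))
  list(concordance = mean(rowA[both] == rowB[both]), n_compared = n)
}

#' Exact Hardy-Weinberg test
#'
#' Two-sided exact test on one SNP's genotype counts: conditioning on the
#' observed allele counts, every heterozygote count of matching parity is
#' enumerated and the probabilities of all configurations no more likely than
#' the observed one are summed (the standard exact HWE test). Probabilities
#' are computed by the numerically stable recurrence over heterozygote
#' counts. Monomorphic configurations have a single compatible table and
#' return 1. Intended for control subjects only.
#'
#' @param nMM,nMm,nmm non-negative genotype counts (major hom, het, minor
#'   hom).
#' @return exact two-sided p-value in (0, 1].
#' @export
hweExactP <- function(nMM, nMm, nmm) {
  if (any(c(nMM, nMm, nmm) < 0)) stop("negative genotype count")
  n <- nMM + nMm + nmm
  if (n == 0L) stop("no genotyped controls")
  rare <- min(2 * nMM + nMm, 2 * nmm + nMm)
  if (rare == 0L) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  ## unnormalised probabilities via the het-count recurrence:
  ## P(h+2)/P(h) = 4 * homR(h) * homC(h) / ((h+1)(h+2))
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    homR <- (rare - h) / 2
    homC <- n - h - homR
    lp[k] <- lp[k - 1] + log(4 * homR * homC) - log((h + 1) * (h + 2))
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(nMm, hets)]
  if (is.na(obs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

#' Detect monomorphic SNPs
#'
#' rsIDs with zero observed copies of one allele across all (QC-passed)
#' subjects: every non-missing dosage 0, every non-missing dosage 2, or no
#' calls at all. Such loci carry no association information and are excluded
#' downstream.
#'
#' @param genotypes subjects x rsIDs dosage matrix, or a [SnpStudy-class].
#' @return character vector of monomorphic rsIDs.
#' @export
detectMonomorphic <- function(genotypes) {
  if (methods::is(genotypes, "SnpStudy"))
    genotypes <- t(dosageMatrix(genotypes))
  mono <- vapply(colnames(genotypes), function(rs) {
    d <- genotypes[, rs]
    d <- d[!is.na(d)]
    length(d) == 0L || sum(d) == 0 || sum(2 - d) == 0
  }, logical(1))
  names(mono)[mono]
}

#' Run the full genotype quality-control stage
#'
#' Fixed order, idempotent: (1) declared duplicate pairs are scored for
#' concordance and collapsed, retaining the member with the higher call rate;
#' (2) subjects with call rate below \code{callRateMin} are excluded; (3) on
#' the survivors, monomorphic SNPs are excluded and the exact Hardy-Weinberg
#' test is run in controls, excluding SNPs with p <= \code{hweAlpha} (the
#' exclusion can be disabled via \code{hweExclude}; the source study reported
#' all loci in equilibrium, so nothing is lost by default).
#'
#' @param study a [SnpStudy-class].
#' @param callRateMin minimum per-subject call rate (default 0.75).
#' @param concordanceMin duplicate-pair concordance flag threshold (0.99).
#' @param hweAlpha control HWE exclusion level (0.05).
#' @param hweExclude drop SNPs failing HWE (default TRUE).
#' @return list with \code{study} (the filtered [SnpStudy-class]) and
#'   \code{report} (a [QcReport-class]).
#' @export
runQc <- function(study, callRateMin = 0.75, concordanceMin = 0.99,
                  hweAlpha = 0.05, hweExclude = TRUE) {
  geno <- t(dosageMatrix(study))
  subj <- subjectData(study)
  cr <- apply(geno, 1, callRate)
  names(cr) <- rownames(geno)

  excl_subj <- data.frame(subject_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  dup_tab <- data.frame(id_a = character(), id_b = character(),
                        concordance = numeric(), n_compared = integer(),
                        flag = character(), stringsAsFactors = FALSE)

  dup_rows <- which(!is.na(subj$duplicate_of))
  for (i in dup_rows) {
    a <- subj$duplicate_of[i]; b <- subj$subject_id[i]
    if (!a %in% rownames(geno)) next
    dc <- duplicateConcordance(geno[a, ], geno[b, ])
    flag <- if (is.na(dc$concordance)) "no_overlap"
            else if (dc$concordance < concordanceMin) "discordant"
            else "ok"
    dup_tab <- rbind(dup_tab, data.frame(
      id_a = a, id_b = b, concordance = dc$concordance,
      n_compared = dc$n_compared, flag = flag, stringsAsFactors = FALSE))
    drop <- if (cr[b] > cr[a]) a else b  # keep higher call rate; tie keeps original
    excl_subj <- rbind(excl_subj, data.frame(
      subject_id = drop, reason = "duplicate", stringsAsFactors = FALSE))
  }

  remaining <- setdiff(rownames(geno), excl_subj$subject_id)
  low <- remaining[cr[remaining] < callRateMin]
  if (length(low))
    excl_subj <- rbind(excl_subj, data.frame(
      subject_id = low, reason = "low_call_rate", stringsAsFactors = FALSE))
  remaining <- setdiff(remaining, low)

  geno_kept <- geno[remaining, , drop = FALSE]
  subj_kept <- subj[match(remaining, subj$subject_id), , drop = FALSE]

  mono <- detectMonomorphic(geno_kept)
  excl_snp <- if (length(mono))
    data.frame(rsid = mono, reason = "monomorphic", stringsAsFactors = FALSE)
  else data.frame(rsid = character(), reason = character(),
                  stringsAsFactors = FALSE)

  ctrl <- geno_kept[subj_kept$status == "control", , drop = FALSE]
  poly <- setdiff(colnames(geno_kept), mono)
  hwe <- do.call(rbind, lapply(poly, function(rs) {
    d <- ctrl[, rs]; d <- d[!is.na(d)]
    data.frame(rsid = rs, n_MM = sum(d == 0), n_Mm = sum(d == 1),
               n_mm = sum(d == 2),
               p = if (length(d)) hweExactP(sum(d == 0), sum(d == 1),
                                            sum(d == 2)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(hwe))
    hwe <- data.frame(rsid = character(), n_MM = integer(), n_Mm = integer(),
                      n_mm = integer(), p = numeric(),
                      stringsAsFactors = FALSE)
  if (hweExclude && nrow(hwe)) {
    fail <- hwe$rsid[!is.na(hwe$p) & hwe$p <= hweAlpha]
    if (length(fail))
      excl_snp <- rbind(excl_snp, data.frame(
        rsid = fail, reason = "hwe_fail", stringsAsFactors = FALSE))
  }

  keep_snps <- setdiff(colnames(geno_kept), excl_snp$rsid)
  filtered <- SnpStudy(geno_kept[, keep_snps, drop = FALSE],
                       snpPanel(study), subj_kept)
  report <- methods::new("QcReport",
    callRates = cr,
    excludedSubjects = excl_subj,
    duplicatePairs = dup_tab,
    hweControls = hwe,
    monomorphicSnps = as.character(mono),
    excludedSnps = excl_snp,
    thresholds = c(call_rate = callRateMin, concordance = concordanceMin,
                   hwe_alpha = hweAlpha))
  list(study = filtered, report = report)
}

#' Serialise a QC report
#'
#' Writes a JSON bundle and a human-readable TSV of exclusions.
#'
#' @param report a [QcReport-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeQcReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jpath <- file.path(dir, "qc_report.json")
  jsonlite::write_json(list(
    thresholds = as.list(report@thresholds),
    call_rates = as.list(report@callRates),
    excluded_subjects = report@excludedSubjects,
    duplicate_pairs = report@duplicatePairs,
    hwe_controls = report@hweControls,
    monomorphic_snps = report@monomorphicSnps,
    excluded_snps = report@excludedSnps), jpath,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tpath <- file.path(dir, "qc_exclusions.tsv")
  excl <- rbind(
    data.frame(item = report@excludedSubjects$subject_id,
               kind = "subject", reason = report@excludedSubjects$reason,
               stringsAsFactors = FALSE),
    data.frame(item = report@excludedSnps$rsid, kind = "snp",
               reason = report@excludedSnps$reason, stringsAsFactors = FALSE))
  utils::write.table(excl, tpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(jpath, tpath))
}
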