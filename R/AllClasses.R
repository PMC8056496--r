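#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

VALID_ALLELES <- c("A", "C", "G", "T")

## Panel loci defined by a survival GWAS, never part of the risk score
SURVIVAL_SNPS <- c("rs684559", "rs353630")

PANEL_COLUMNS <- c("rsid", "gene", "major", "minor", "gwas_or", "in_prs")

SUBJECT_COLUMNS <- c("subject_id", "status", "age", "sex", "ancestry",
                     "tobacco", "alcohol", "diabetes", "pancreatitis",
                     "family_history", "duplicate_of")

EXPOSURE_VARS <- c("tobacco", "alcohol", "diabetes", "pancreatitis",
                   "family_history")

#' SnpStudy: a candidate-SNP case-control study container
#'
#' Extends \linkS4class{SummarizedExperiment}. The single assay \code{"dosage"}
#' holds minor-allele dosages (0/1/2, \code{NA} = no call) with SNPs as rows
#' and subjects as columns. \code{rowData} carries the SNP panel (nearest gene,
#' major/minor alleles, external GWAS odds-ratio weight, risk-score membership,
#' reference allele frequencies); \code{colData} carries subject metadata
#' (case/control status, age, sex, self-reported ancestry, exposure flags,
#' declared duplicate links).
#'
#' Dosage counts copies of the panel's \emph{minor} allele, not the risk
#' allele; orientation to the risk allele happens inside the PRS module and
#' orientation to the control-major reference inside the association module.
#'
#' @seealso [SnpStudy()], [runQc()], [associateAll()], [computePrs()]
#' @export
setClass("SnpStudy", contains = "SummarizedExperiment")

setValidity("SnpStudy", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- !(is.na(d) | d %in% c(0, 1, 2))
    if (any(bad))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- setdiff(PANEL_COLUMNS, colnames(rd))
  if (length(need))
    msg <- c(msg, paste0("rowData lacks panel columns: ",
                         paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(rd$rsid))
      msg <- c(msg, "duplicate rsid in panel")
    if (!all(rd$major %in% VALID_ALLELES) || !all(rd$minor %in% VALID_ALLELES))
      msg <- c(msg, "alleles must be one of A, C, G, T")
    if (any(rd$major == rd$minor))
      msg <- c(msg, "major and minor allele must differ")
    if (any(!is.na(rd$gwas_or) & rd$gwas_or <= 0))
      msg <- c(msg, "gwas_or must be positive")
    if (any(rd$rsid %in% SURVIVAL_SNPS & rd$in_prs))
      msg <- c(msg, paste0("in_prs must be FALSE for ",
                           paste(SURVIVAL_SNPS, collapse = " and ")))
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("subject_id", "status") %in% colnames(cd)))
    msg <- c(msg, "colData needs subject_id and status")
  else {
    if (any(is.na(cd$status)) || !all(cd$status %in% c("case", "control")))
      msg <- c(msg, "status must be 'case' or 'control', never missing")
    if ("age" %in% colnames(cd)) {
      a <- cd$age
      if (any(!is.na(a) & (a < 0 | a > 120)))
        msg <- c(msg, "age must lie in [0, 120] when present")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SnpStudy
#'
#' @param genotypes numeric matrix of minor-allele dosages with subjects as
#'   rows and rsIDs as columns (the orientation of the genotype TSV), values
#'   0/1/2/\code{NA}. Transposed internally so SNPs become assay rows.
#' @param panel data.frame as returned by [loadPanel()]; restricted to the
#'   genotyped rsIDs, which must all be present in the panel.
#' @param subjects data.frame as returned by [readSubjects()]; row order is
#'   matched to the genotype rows by \code{subject_id}.
#' @return a [SnpStudy-class] object.
#' @examples
#' study <- simulateCohort(simConfig(nCases = 20, nControls = 40, seed = 1))
#' study
#' @export
SnpStudy <- function(genotypes, panel, subjects) {
  stopifnot(is.matrix(genotypes))
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes)))
    stop("genotype matrix needs subject row names and rsid column names")
  missing_panel <- setdiff(colnames(genotypes), panel$rsid)
  if (length(missing_panel))
    stop("rsIDs absent from panel: ", paste(missing_panel, collapse = ", "))
  panel <- panel[match(colnames(genotypes), panel$rsid), , drop = FALSE]
  idx <- match(rownames(genotypes), subjects$subject_id)
  if (anyNA(idx))
    stop("subjects absent from metadata: ",
         paste(rownames(genotypes)[is.na(idx)], collapse = ", "))
  subjects <- subjects[idx, , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(genotypes)),
    rowData = S4Vectors::DataFrame(panel, row.names = panel$rsid),
    colData = S4Vectors::DataFrame(subjects,
                                   row.names = subjects$subject_id))
  methods::new("SnpStudy", se)
}

#' @describeIn SnpStudy-class minor-allele dosage matrix (SNPs x subjects)
#' @param x a \code{SnpStudy}
#' @export
dosageMatrix <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn SnpStudy-class the SNP panel as a data.frame
#' @export
snpPanel <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @describeIn SnpStudy-class subject metadata as a data.frame
#' @export
subjectData <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn SnpStudy-class logical vector, TRUE for cases
#' @export
isCase <- function(x) subjectData(x)$status == "case"

setMethod("show", "SnpStudy", function(object) {
  st <- subjectData(object)$status
  cat("SnpStudy:", nrow(object), "SNPs x", ncol(object), "subjects (",
      sum(st == "case"), "cases /", sum(st == "control"), "controls )\n")
  d <- dosageMatrix(object)
  cat(sprintf("  overall call rate: %.3f\n", mean(!is.na(d))))
  cat("  panel genes:",
      paste(utils::head(snpPanel(object)$gene, 5), collapse = ", "),
      if (nrow(object) > 5) "..." else "", "\n")
})

#' Genotype quality-control report
#'
#' Produced by [runQc()]. Records per-subject call rates, excluded subjects
#' with reasons, duplicate-pair concordances, control Hardy-Weinberg exact
#' p-values, monomorphic loci and excluded SNPs with reasons.
#'
#' @slot callRates named numeric, per-subject call rate in [0, 1].
#' @slot excludedSubjects data.frame with columns subject_id, reason.
#' @slot duplicatePairs data.frame: id_a, id_b, concordance, n_compared, flag.
#' @slot hweControls data.frame: rsid, n_MM, n_Mm, n_mm, p.
#' @slot monomorphicSnps character, rsIDs monomorphic after subject QC.
#' @slot excludedSnps data.frame with columns rsid, reason.
#' @slot thresholds named numeric, the thresholds the run used.
#' @export
setClass("QcReport", representation(
  callRates = "numeric",
  excludedSubjects = "data.frame",
  duplicatePairs = "data.frame",
  hweControls = "data.frame",
  monomorphicSnps = "character",
  excludedSnps = "data.frame",
  thresholds = "numeric"))

setMethod("show", "QcReport", function(object) {
  cat("QcReport:", length(object@callRates), "subjects screened\n")
  cat("  excluded subjects:", nrow(object@excludedSubjects), "\n")
  cat("  duplicate pairs:", nrow(object@duplicatePairs), "\n")
  cat("  excluded SNPs:", nrow(object@excludedSnps),
      "( monomorphic:", length(object@monomorphicSnps), ")\n")
  if (nrow(object@hweControls))
    cat(sprintf("  min control HWE p: %.4g\n", min(object@hweControls$p)))
})

#' @describeIn QcReport-class subjects removed by QC, with reasons
#' @param x a \code{QcReport}
#' @export
excludedSubjects <- function(x) x@excludedSubjects

#' @describeIn QcReport-class SNPs removed by QC, with reasons
#' @export
excludedSnps <- function(x) x@excludedSnps

#' Polygenic risk score results
#'
#' Produced by [computePrs()]. Holds per-subject scores for the four score
#' variants (unweighted / ln(OR)-weighted, each raw and missingness-scaled)
#' and the four adjusted logistic analyses (quintile contrasts vs the lowest
#' control-based quintile, plus a per-quintile-increment continuous fit).
#'
#' @slot scores data.frame, one row per subject: subject_id, status,
#'   n_genotyped, unweighted, weighted, unweighted_scaled, weighted_scaled.
#' @slot analyses named list of data.frames, one per score variant, rows
#'   quintile 1..5 and "continuous" with or/ci_low/ci_high/p and counts.
#' @slot snpSubset character, rsIDs entering the score.
#' @slot weights named numeric, |ln(OR)| weight per rsID.
#' @export
setClass("PrsResult", representation(
  scores = "data.frame",
  analyses = "list",
  snpSubset = "character",
  weights = "numeric"))

setMethod("show", "PrsResult", function(object) {
  cat("PrsResult:", nrow(object@scores), "subjects,",
      length(object@snpSubset), "SNPs in score\n")
  for (nm in names(object@analyses)) {
    blk <- object@analyses[[nm]]
    cont <- blk[blk$term == "continuous", ]
    top <- blk[blk$term == "quintile5", ]
    cat(sprintf("  %-28s top-vs-bottom OR %.2f, per-quintile OR %.2f\n",
                nm,
                if (nrow(top)) top$or else NA_real_,
                if (nrow(cont)) cont$or else NA_real_))
  }
})

#' @describeIn PrsResult-class per-subject score table
#' @param x a \code{PrsResult}
#' @export
prsScores <- function(x) x@scores

#' @describeIn PrsResult-class the four quintile/continuous analysis blocks
#' @export
prsAnalyses <- function(x) x@analyses
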