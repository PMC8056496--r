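#' Load a SNP panel definition table
#'
#' The panel is a TSV with header columns \code{rsid, gene, major, minor,
#' gwas_or, in_prs} and optional reference-frequency column pairs
#' \code{ref_maf_<label>} / \code{ref_n_<label>} (e.g. the study controls and
#' dbSNP ancestry frequencies).
#'
#' @param path path to the panel TSV.
#' @return data.frame, one row per locus, validated: alleles in A/C/G/T and
#'   distinct, \code{gwas_or > 0}, no duplicate rsIDs, \code{in_prs} forced
#'   \code{FALSE} for the two survival-GWAS loci (rs684559, rs353630), all
#'   reference MAFs inside [0, 1].
#' @export
loadPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("no panel rows in ", path)
  need <- setdiff(PANEL_COLUMNS, colnames(tab))
  if (length(need))
    stop("panel lacks columns: ", paste(need, collapse = ", "))
  dup <- tab$rsid[duplicated(tab$rsid)]
  if (length(dup))
    stop("duplicate rsid in panel (row ",
         which(tab$rsid %in% dup)[2], "): ", dup[1])
  badA <- which(!(tab$major %in% VALID_ALLELES) |
                !(tab$minor %in% VALID_ALLELES) |
                tab$major == tab$minor)
  if (length(badA))
    stop("malformed alleles in panel row ", badA[1], " (", tab$rsid[badA[1]],
         "): ", tab$major[badA[1]], "/", tab$minor[badA[1]])
  badOR <- which(!is.finite(tab$gwas_or) | tab$gwas_or <= 0)
  if (length(badOR))
    stop("non-positive gwas_or in panel row ", badOR[1],
         " (", tab$rsid[badOR[1]], ")")
  tab$in_prs <- as.logical(tab$in_prs) & !(tab$rsid %in% SURVIVAL_SNPS)
  for (cl in grep("^ref_maf_", colnames(tab), value = TRUE)) {
    v <- tab[[cl]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("reference MAF outside [0,1] in column ", cl)
  }
  tab
}

#' The shipped default SNP panel
#'
#' Twenty-six candidate loci previously reported in pancreatic-cancer GWAS,
#' with major/minor alleles and the study controls' minor-allele frequencies
#' as the \code{study_controls} reference column, plus dbSNP African /
#' European / Asian frequencies for the nine loci with published ancestry
#' breakdowns. The \code{gwas_or} column ships the study's own allelic
#' odds-ratio estimates as documented placeholder PRS weights: the original
#' discovery-GWAS ORs were never tabulated at the source, so users wanting
#' externally weighted scores should substitute them. rs35226131 (monomorphic
#' in the study population, hence excluded from all published analyses)
#' carries synthetic placeholder alleles (C/T), a neutral weight of 1 and a
#' reference MAF of 0.
#'
#' @return data.frame of 26 loci (see [loadPanel()]).
#' @export
defaultPanel <- function() {
  loadPanel(system.file("extdata", "default_panel.tsv", package = "pancprs"))
}

#' Read a wide genotype TSV
#'
#' First column \code{subject_id}, remaining columns rsIDs; cells are
#' minor-allele dosages 0/1/2, with \code{NA} or an empty string meaning no
#' call. Columns not present in the panel are dropped with a warning.
#'
#' @param path path to the TSV.
#' @param panel data.frame from [loadPanel()].
#' @return numeric matrix, subjects in rows (named), panel rsIDs in columns.
#' @export
readGenotypes <- function(path, panel) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (colnames(tab)[1] != "subject_id")
    stop("first genotype column must be subject_id")
  ids <- tab$subject_id
  snp_cols <- setdiff(colnames(tab), "subject_id")
  unknown <- setdiff(snp_cols, panel$rsid)
  if (length(unknown))
    warning("dropping non-panel genotype columns: ",
            paste(unknown, collapse = ", "))
  keep <- intersect(snp_cols, panel$rsid)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = length(keep),
                dimnames = list(ids, keep))
  for (rs in keep) {
    raw <- trimws(tab[[rs]])
    raw[raw == ""] <- NA
    ok <- is.na(raw) | raw %in% c("0", "1", "2")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("invalid dosage '", raw[i], "' for subject ", ids[i],
           ", SNP ", rs)
    }
    mat[, rs] <- as.numeric(raw)
  }
  mat
}

#' Write a genotype matrix as a wide TSV
#'
#' Inverse of [readGenotypes()]: round trips byte-identically for matrices
#' read from a valid file (modulo column order, which follows the matrix).
#'
#' @param genotypes subjects x rsIDs dosage matrix.
#' @param path output path.
#' @export
writeGenotypes <- function(genotypes, path) {
  df <- data.frame(subject_id = rownames(genotypes),
                   genotypes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject metadata TSV
#'
#' Expected header: \code{subject_id, status, age, sex, ancestry, tobacco,
#' alcohol, diabetes, pancreatitis, family_history, duplicate_of}. Status must
#' be \code{case} or \code{control} and is never allowed missing; blank age,
#' sex, ancestry and exposure cells are retained as missing.
#'
#' @param path path to the TSV.
#' @return data.frame with one row per subject.
#' @export
readSubjects <- function(path) {
  if (!file.exists(path)) stop("subject file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- setdiff(SUBJECT_COLUMNS, colnames(tab))
  if (length(need))
    stop("subject file lacks columns: ", paste(need, collapse = ", "))
  blank <- function(x) { x <- trimws(x); x[x == "" | x == "NA"] <- NA; x }
  tab[] <- lapply(tab, blank)
  if (any(is.na(tab$status)))
    stop("missing status for subject ",
         tab$subject_id[which(is.na(tab$status))[1]])
  bad <- which(!tab$status %in% c("case", "control"))
  if (length(bad))
    stop("invalid status '", tab$status[bad[1]], "' for subject ",
         tab$subject_id[bad[1]])
  tab$age <- as.numeric(tab$age)
  if (any(!is.na(tab$age) & (tab$age < 0 | tab$age > 120)))
    stop("age outside [0, 120]")
  badsex <- which(!is.na(tab$sex) & !tab$sex %in% c("male", "female"))
  if (length(badsex))
    stop("invalid sex '", tab$sex[badsex[1]], "'")
  tab$ancestry[is.na(tab$ancestry)] <- "unknown"
  for (v in EXPOSURE_VARS) {
    badv <- which(!is.na(tab[[v]]) & !tab[[v]] %in% c("yes", "no"))
    if (length(badv))
      stop("invalid ", v, " value '", tab[[v]][badv[1]], "'")
  }
  tab
}

#' Write a subject metadata TSV
#' @param subjects data.frame as from [readSubjects()].
#' @param path output path.
#' @export
writeSubjects <- function(subjects, path) {
  out <- subjects[, SUBJECT_COLUMNS]
  out[] <- lapply(out, function(x) ifelse(is.na(x), "NA", as.character(x)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a panel TSV
#' @param panel data.frame as from [loadPanel()].
#' @param path output path.
#' @export
writePanel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read panel genotypes from a VCF
#'
#' Sites are matched to the panel by ID (rsID), never by position. Diploid GT
#' fields are converted to minor-allele dosage using the panel's allele
#' orientation: when VCF REF/ALT equals panel major/minor the ALT count is
#' used directly; when REF/ALT is flipped relative to the panel the dosage is
#' complemented (2 - ALT count) and a message notes the flip. Half calls and
#' \code{./.} become missing; panel rsIDs absent from the VCF yield an
#' all-missing column with a warning; a multi-allelic record at a panel site
#' is an error. Requires the optional \pkg{vcfR} package.
#'
#' @param path VCF path (plain or bgzipped).
#' @param panel data.frame from [loadPanel()].
#' @return numeric matrix, subjects x panel rsIDs present in the VCF order of
#'   the panel.
#' @export
readVcfGenotypes <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readVcfGenotypes needs the 'vcfR' package")
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(v)
  if (!is.matrix(fm))  # single-record VCFs drop to a named vector
    fm <- matrix(fm, nrow = 1, dimnames = list(NULL, names(fm)))
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!is.matrix(gt))
    gt <- matrix(gt, nrow = nrow(fix),
                 dimnames = list(NULL, colnames(v@gt)[-1]))
  samples <- colnames(gt)
  out <- matrix(NA_real_, nrow = length(samples), ncol = nrow(panel),
                dimnames = list(samples, panel$rsid))
  for (i in seq_len(nrow(panel))) {
    rs <- panel$rsid[i]
    hit <- which(fix$ID == rs)
    if (length(hit) == 0L) {
      warning("panel SNP ", rs, " absent from VCF; column set to missing")
      next
    }
    if (length(hit) > 1L || grepl(",", fix$ALT[hit]))
      stop("multi-allelic VCF record at panel SNP ", rs)
    ref <- fix$REF[hit]; alt <- fix$ALT[hit]
    g <- gt[hit, ]
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    alt_dosage <- vapply(alleles, function(a) {
      if (length(a) != 2L || any(!a %in% c("0", "1"))) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
    if (ref == panel$major[i] && alt == panel$minor[i]) {
      out[, rs] <- alt_dosage
    } else if (ref == panel$minor[i] && alt == panel$major[i]) {
      message("VCF REF/ALT flipped relative to panel at ", rs,
              "; complementing dosage")
      out[, rs] <- 2 - alt_dosage
    } else {
      stop("VCF alleles ", ref, "/", alt, " do not match panel ",
           panel$major[i], "/", panel$minor[i], " at ", rs)
    }
  }
  out
}

#' Published summary tables shipped as reference data
#'
#' Loaders for the source study's printed summary statistics, used by the
#' reconstruction-based validation suite: the per-SNP association summary
#' (control/case MAFs, allelic OR with 95\% CI and p, trend p, significance
#' flag), the ancestry-stratified MAF table (dbSNP and study frequencies with
#' printed significance flags), and the cohort epidemiology table (percentages
#' with effective denominators of 76 cases / 260 controls for the exposure
#' variables, the smallest integers reproducing every printed percentage; the
#' diabetes and pancreatitis printed p-values are upper bounds, stored as
#' 0.0001).
#'
#' @return data.frame.
#' @export
referenceAssociation <- function() {
  utils::read.delim(system.file("extdata", "study_assoc_reference.tsv",
                                package = "pancprs"),
                    stringsAsFactors = FALSE)
}

#' @rdname referenceAssociation
#' @export
referenceAncestryMaf <- function() {
  utils::read.delim(system.file("extdata", "study_ancestry_maf.tsv",
                                package = "pancprs"),
                    stringsAsFactors = FALSE)
}

#' @rdname referenceAssociation
#' @export
referenceEpidemiology <- function() {
  utils::read.delim(system.file("extdata", "study_epidemiology.tsv",
                                package = "pancprs"),
                    stringsAsFactors = FALSE)
}
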