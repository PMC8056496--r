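#' Run the full pipeline
#'
#' Executes the stages in their canonical order — quality control,
#' epidemiology table, per-SNP association, ancestry MAF comparison,
#' polygenic risk scores — and writes the four study-style TSV tables, the
#' QC report (JSON + TSV), a JSON bundle of all results and a plain-text log
#' recording every exclusion. Re-running on identical inputs produces
#' byte-identical outputs.
#'
#' @param panel path to the panel TSV, or a loaded panel data.frame.
#' @param genotypes path to the genotype TSV, or a dosage matrix.
#' @param subjects path to the subject TSV, or a subject data.frame.
#' @param outDir output directory.
#' @param callRateMin,concordanceMin,hweAlpha,alpha QC and significance
#'   thresholds (defaults 0.75, 0.99, 0.05, 0.05).
#' @param prsSubset optional rsID subset for the risk score.
#' @return invisibly, a list with \code{qc}, \code{epidemiology},
#'   \code{association}, \code{ancestry_maf}, \code{prs} and the filtered
#'   study.
#' @export
runAll <- function(panel, genotypes, subjects, outDir,
                   callRateMin = 0.75, concordanceMin = 0.99,
                   hweAlpha = 0.05, alpha = 0.05, prsSubset = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.character(panel)) panel <- stage("load_panel", loadPanel(panel))
  if (is.character(genotypes))
    genotypes <- stage("read_genotypes", readGenotypes(genotypes, panel))
  if (is.character(subjects))
    subjects <- stage("read_subjects", readSubjects(subjects))
  study <- stage("build_study", SnpStudy(genotypes, panel, subjects))

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  qc <- stage("qc", runQc(study, callRateMin = callRateMin,
                          concordanceMin = concordanceMin,
                          hweAlpha = hweAlpha))
  ex <- excludedSubjects(qc$report)
  for (i in seq_len(nrow(ex)))
    note("excluded subject ", ex$subject_id[i], ": ", ex$reason[i])
  exs <- excludedSnps(qc$report)
  for (i in seq_len(nrow(exs)))
    note("excluded SNP ", exs$rsid[i], ": ", exs$reason[i])
  writeQcReport(qc$report, outDir)

  epi <- stage("epitable", epiTable(qc$study))
  assoc <- stage("assoc", associateAll(qc$study, alpha = alpha))
  maf <- stage("mafcompare", mafCompare(qc$study, alpha = alpha))
  prs <- stage("prs", computePrs(qc$study, snpSubset = prsSubset))

  tables <- list(epidemiology = renderTable(epi, "epidemiology"),
                 association = renderTable(assoc, "association"),
                 ancestry_maf = renderTable(maf, "ancestry_maf"),
                 prs = renderTable(prs, "prs"))
  for (nm in names(tables))
    utils::write.table(tables[[nm]], file.path(outDir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(prsScores(prs),
                     file.path(outDir, "prs_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    thresholds = list(call_rate = callRateMin, concordance = concordanceMin,
                      hwe_alpha = hweAlpha, alpha = alpha),
    association = assoc, ancestry_maf = maf,
    prs = prsAnalyses(prs)), file.path(outDir, "results.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(outDir, "run.log"))

  invisible(list(qc = qc$report, study = qc$study, epidemiology = epi,
                 association = assoc, ancestry_maf = maf, prs = prs))
}

fmt_or_ci <- function(or, lo, hi) {
  ifelse(is.na(or), "-",
         sprintf("%.2f (%.2f-%.2f)", or, lo, hi))
}

fmt_p <- function(p) ifelse(is.na(p), "-", sprintf("%.4g", p))

#' Render a stage result as a publication-style table
#'
#' Mirrors the column order and block structure of the study's four result
#' tables; undefined contrasts are rendered as \code{"-"}.
#'
#' @param results the corresponding stage's output: [epiTable()],
#'   [associateAll()], [mafCompare()] or a [PrsResult-class].
#' @param style one of \code{"epidemiology"}, \code{"association"},
#'   \code{"ancestry_maf"}, \code{"prs"}.
#' @return data.frame of formatted strings, ready to write as TSV.
#' @export
renderTable <- function(results, style = c("epidemiology", "association",
                                           "ancestry_maf", "prs")) {
  style <- match.arg(style)
  if (style == "prs") {
    if (!methods::is(results, "PrsResult"))
      stop("prs style needs a PrsResult")
    blocks <- prsAnalyses(results)
    out <- do.call(rbind, lapply(names(blocks), function(nm) {
      b <- blocks[[nm]]
      data.frame(score = nm, term = b$term,
                 or = ifelse(is.na(b$or), "-", sprintf("%.2f", b$or)),
                 ci_95 = ifelse(is.na(b$ci_low), "-",
                                sprintf("%.2f-%.2f", b$ci_low, b$ci_high)),
                 p = fmt_p(b$p), stringsAsFactors = FALSE)
    }))
    out$or[out$term == "quintile1"] <- "1.00"
    out$ci_95[out$term == "quintile1"] <- "Ref"
    return(out)
  }
  if (!is.data.frame(results)) stop("expected a data.frame for ", style)
  if (nrow(results) == 0L) return(results)
  switch(style,
    epidemiology = data.frame(
      variable = results$variable, level = results$level,
      cases = sprintf("%.2f", results$cases),
      controls = sprintf("%.2f", results$controls),
      test = results$test, p = fmt_p(results$p),
      stringsAsFactors = FALSE),
    association = {
      need <- c("rsid", "maf_controls", "allelic_or", "p_trend")
      if (!all(need %in% colnames(results))) stop("schema mismatch")
      data.frame(
        rsid = results$rsid,
        maf_controls = sprintf("%.2f", results$maf_controls),
        maf_cases = sprintf("%.2f", results$maf_cases),
        allelic = fmt_or_ci(results$allelic_or, results$allelic_ci_low,
                            results$allelic_ci_high),
        allelic_p = fmt_p(results$allelic_p),
        het = fmt_or_ci(results$het_or, results$het_ci_low,
                        results$het_ci_high),
        het_p = fmt_p(results$het_p),
        hom = fmt_or_ci(results$hom_or, results$hom_ci_low,
                        results$hom_ci_high),
        hom_p = fmt_p(results$hom_p),
        p_trend = fmt_p(results$p_trend),
        dominant = fmt_or_ci(results$dom_or, results$dom_ci_low,
                             results$dom_ci_high),
        dominant_p = fmt_p(results$dom_p),
        significant = ifelse(results$significant, "*", ""),
        stringsAsFactors = FALSE)
    },
    ancestry_maf = {
      if (!all(c("rsid", "ancestry") %in% colnames(results)))
        stop("schema mismatch")
      data.frame(
        rsid = results$rsid, ancestry = results$ancestry,
        maf_cases = sprintf("%.2f", results$maf_cases),
        maf_controls = sprintf("%.2f", results$maf_controls),
        maf_reference = ifelse(is.na(results$maf_reference), "-",
                               sprintf("%.2f", results$maf_reference)),
        flags = paste0(ifelse(results$sig_case_vs_control, "*", ""),
                       ifelse(results$sig_control_vs_reference, "**", "")),
        stringsAsFactors = FALSE)
    })
}
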