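as_count_table <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.numeric(x) && length(x) == 4L)
    return(matrix(x, nrow = 2, byrow = TRUE))
  stop("expected a count matrix or a length-4 vector (a, b, c, d)")
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction (the convention the study's reconstructed tables
#' require). Works on r x c tables; df = (r-1)(c-1).
#'
#' @param x count matrix, or \code{c(a, b, c, d)} filling a 2x2 by row
#'   (rows = groups, columns = outcome levels).
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
chisqTest <- function(x) {
  tab <- as_count_table(x)
  if (any(tab < 0)) stop("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Direct hypergeometric enumeration: conditioning on the margins, the
#' probabilities of all tables no more likely than the observed one are
#' summed (with the usual 1e-7 relative tolerance absorbing floating-point
#' ties between symmetric tables, the same convention as
#' \code{stats::fisher.test}).
#'
#' @param x 2x2 count matrix or \code{c(a, b, c, d)} by row.
#' @return two-sided p-value.
#' @export
fisherExact <- function(x) {
  tab <- as_count_table(x)
  if (!all(dim(tab) == 2L)) stop("fisherExact needs a 2x2 table")
  if (any(tab < 0)) stop("negative counts")
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(support, c1, n - c1, r1)
  obs <- pr[match(a, support)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Two-sample Student t test from raw samples or summary moments
#'
#' Pooled-variance Student t by default, Welch as an option; two-sided p.
#' Either supply two raw vectors \code{x}, \code{y}, or the six summary
#' moments.
#'
#' @param x,y raw samples (optional).
#' @param mean1,sd1,n1,mean2,sd2,n2 summary moments (used when \code{x} is
#'   missing).
#' @param welch use the Welch-Satterthwaite df instead of pooling.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
twoSampleT <- function(x = NULL, y = NULL, mean1, sd1, n1, mean2, sd2, n2,
                       welch = FALSE) {
  if (!is.null(x)) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    tval <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Reconstruct an integer count from a printed percentage
#'
#' \code{round(pct/100 * denominator)} with halves rounded away from zero,
#' the convention that reproduces every verified cell of the study's printed
#' tables.
#'
#' @param pct percentage in [0, 100].
#' @param denominator positive integer group size.
#' @return integer count.
#' @export
countsFromPercent <- function(pct, denominator) {
  if (any(pct < 0 | pct > 100)) stop("percentage outside [0, 100]")
  if (any(denominator <= 0)) stop("denominator must be positive")
  k <- floor(pct / 100 * denominator + 0.5)
  if (any(k < 0 | k > denominator)) stop("count outside [0, denominator]")
  as.integer(k)
}

#' Compare two groups' allele frequencies
#'
#' Builds the 2x2 minor/major allele-count table from each group's MAF and
#' subject count (allele totals are twice the subject counts; counts are
#' reconstructed with [countsFromPercent()]) and applies a chi-square or
#' Fisher exact test.
#'
#' @param maf1,maf2 minor-allele frequencies in [0, 1].
#' @param n1,n2 subject counts per group.
#' @param method \code{"chisq"} or \code{"fisher"}.
#' @return list with \code{table} (rows = groups, columns = minor/major),
#'   \code{p} and \code{method}.
#' @export
alleleCountTest <- function(maf1, n1, maf2, n2,
                            method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (any(c(maf1, maf2) < 0 | c(maf1, maf2) > 1)) stop("MAF outside [0, 1]")
  if (n1 <= 0 || n2 <= 0) stop("subject counts must be positive")
  m1 <- countsFromPercent(100 * maf1, 2 * n1)
  m2 <- countsFromPercent(100 * maf2, 2 * n2)
  tab <- matrix(c(m1, 2 * n1 - m1, m2, 2 * n2 - m2), nrow = 2, byrow = TRUE,
                dimnames = list(c("group1", "group2"), c("minor", "major")))
  p <- if (method == "chisq") chisqTest(tab)$p else fisherExact(tab)
  list(table = tab, p = p, method = method)
}

#' Case-control epidemiology table
#'
#' Univariate comparisons of cohort descriptors: Student t for age,
#' chi-square (no continuity correction) for sex, ancestry (r x c) and the
#' binary exposures; complete cases per variable.
#'
#' @param study a [SnpStudy-class] or a subject data.frame.
#' @return data.frame: variable, level, value in cases / controls (percent,
#'   or years for age), test, statistic, p (repeated within variable).
#' @export
epiTable <- function(study) {
  subj <- if (methods::is(study, "SnpStudy")) subjectData(study) else study
  case <- subj$status == "case"
  rows <- list()
  pct <- function(x, lev) 100 * mean(x == lev, na.rm = TRUE)

  ok <- !is.na(subj$age)
  tt <- twoSampleT(subj$age[case & ok], subj$age[!case & ok])
  rows[[1]] <- data.frame(variable = "age", level = "mean",
                          cases = mean(subj$age[case & ok]),
                          controls = mean(subj$age[!case & ok]),
                          test = "t", statistic = tt$t, p = tt$p)

  catvar <- function(var, levels) {
    v <- subj[[var]]
    ok <- !is.na(v) & v %in% levels
    tab <- table(factor(subj$status[ok], c("case", "control")),
                 factor(v[ok], levels))
    res <- tryCatch(chisqTest(unclass(tab)), error = function(e) NULL)
    do.call(rbind, lapply(levels, function(lv) data.frame(
      variable = var, level = lv,
      cases = pct(v[case & ok], lv), controls = pct(v[!case & ok], lv),
      test = "chisq",
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      p = if (is.null(res)) NA_real_ else res$p)))
  }
  rows[[2]] <- catvar("sex", c("male", "female"))
  rows[[3]] <- catvar("ancestry",
                      intersect(c("African", "European", "Asian", "unknown"),
                                unique(subj$ancestry)))
  for (v in EXPOSURE_VARS) rows[[length(rows) + 1]] <- catvar(v, c("yes", "no"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ancestry-stratified MAF comparison table
#'
#' For each SNP and self-reported ancestry stratum, computes case and control
#' minor-allele frequencies from the observed dosages and tests cases vs
#' controls on the allele-count table; when the panel carries a reference MAF
#' for that ancestry, controls are also tested against the reference
#' population (counts reconstructed from the reference MAF and sample size).
#'
#' @param study a QC-passed [SnpStudy-class].
#' @param alpha significance flag level (0.05).
#' @param method test passed to [alleleCountTest()].
#' @return data.frame, one row per SNP x ancestry present in the cohort.
#' @export
mafCompare <- function(study, alpha = 0.05, method = "chisq") {
  geno <- t(dosageMatrix(study))
  subj <- subjectData(study)
  panel <- snpPanel(study)
  strata <- intersect(c("African", "European", "Asian"),
                      unique(subj$ancestry))
  maf_n <- function(rows, rs) {
    d <- geno[rows, rs]; d <- d[!is.na(d)]
    c(maf = if (length(d)) sum(d) / (2 * length(d)) else NA_real_,
      n = length(d))
  }
  out <- list()
  for (rs in colnames(geno)) for (anc in strata) {
    ca <- maf_n(subj$status == "case" & subj$ancestry == anc, rs)
    co <- maf_n(subj$status == "control" & subj$ancestry == anc, rs)
    safe_p <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    p_cc <- if (ca["n"] > 0 && co["n"] > 0)
      safe_p(alleleCountTest(ca["maf"], ca["n"], co["maf"], co["n"],
                             method = method)$p) else NA_real_
    ref_maf <- panel[[paste0("ref_maf_", tolower(anc))]]
    ref_n <- panel[[paste0("ref_n_", tolower(anc))]]
    i <- match(rs, panel$rsid)
    p_ref <- if (!is.null(ref_maf) && !is.na(ref_maf[i]) && co["n"] > 0)
      safe_p(alleleCountTest(co["maf"], co["n"], ref_maf[i], ref_n[i],
                             method = method)$p) else NA_real_
    out[[length(out) + 1]] <- data.frame(
      rsid = rs, ancestry = anc,
      maf_cases = unname(ca["maf"]), n_cases = unname(ca["n"]),
      maf_controls = unname(co["maf"]), n_controls = unname(co["n"]),
      p_case_vs_control = p_cc,
      sig_case_vs_control = !is.na(p_cc) & p_cc < alpha,
      maf_reference = if (is.null(ref_maf)) NA_real_ else ref_maf[i],
      p_control_vs_reference = p_ref,
      sig_control_vs_reference = !is.na(p_ref) & p_ref < alpha,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
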