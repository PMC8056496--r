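#' Orient a SNP to the control-major reference allele
#'
#' The reference category is the more common allele in controls: when the
#' panel minor allele has control frequency above 0.5 the dosages must be
#' complemented (2 - dosage). A tie at exactly 0.5 keeps the panel
#' orientation.
#'
#' @param controlDosages non-missing-capable dosage vector for controls.
#' @return list with \code{maf} (the control minor-allele frequency after
#'   orientation, <= 0.5) and \code{flipped}.
#' @export
assignReferenceAllele <- function(controlDosages) {
  d <- controlDosages[!is.na(controlDosages)]
  if (length(d) == 0L) stop("no non-missing control genotypes")
  f <- sum(d) / (2 * length(d))
  if (f > 0.5) list(maf = 1 - f, flipped = TRUE)
  else list(maf = f, flipped = FALSE)
}

#' Encode a dosage under an inheritance model
#'
#' Allelic: one additive column equal to the dosage. Codominant: indicator
#' columns for heterozygote and minor homozygote. Dominant: one indicator for
#' carrying at least one minor allele.
#'
#' @param dosage vector of dosages in 0/1/2.
#' @param model one of \code{"allelic"}, \code{"codominant"},
#'   \code{"dominant"}.
#' @return numeric matrix of covariate columns.
#' @export
encodeModel <- function(dosage, model = c("allelic", "codominant",
                                          "dominant")) {
  model <- match.arg(model)
  switch(model,
    allelic = cbind(dosage = dosage),
    codominant = cbind(het = as.numeric(dosage == 1),
                       hom = as.numeric(dosage == 2)),
    dominant = cbind(carrier = as.numeric(dosage >= 1)))
}

#' Maximum-likelihood logistic regression fit
#'
#' Binomial IRLS (via \code{stats::glm.fit}) with tight convergence
#' (relative deviance-change tolerance 1e-12, at most 50 iterations) and Wald standard errors from the
#' inverse observed information evaluated at the converged coefficients. An
#' intercept is prepended. (Quasi-)separation is flagged when any
#' coefficient runs beyond 15 on the log-odds scale.
#'
#' @param design covariate matrix (no intercept column), or NULL for an
#'   intercept-only fit.
#' @param outcome binary 0/1 vector (1 = case).
#' @return object of class \code{logisticFit}: coefficients,
#'   standard_errors, vcov, converged, n_iterations, separation_flag, n.
#' @export
logisticFit <- function(design, outcome) {
  y <- as.numeric(outcome)
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  X <- if (is.null(design)) matrix(nrow = length(y), ncol = 0)
       else as.matrix(design)
  if (is.null(colnames(X)) && ncol(X))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear design; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 50)))
  ## observed information evaluated at the converged coefficients
  beta <- fit$coefficients
  mu <- as.vector(1 / (1 + exp(-(X %*% beta))))
  w <- mu * (1 - mu)
  vcov <- tryCatch(chol2inv(chol(crossprod(X, w * X))),
                   error = function(e)
                     matrix(NA_real_, ncol(X), ncol(X)))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = beta,
    standard_errors = sqrt(diag(vcov)),
    vcov = vcov,
    converged = fit$converged,
    n_iterations = fit$iter,
    separation_flag = any(abs(beta) > 15, na.rm = TRUE),
    n = length(y)), class = "logisticFit")
}

#' @export
print.logisticFit <- function(x, ...) {
  cat("logisticFit (n =", x$n, ", iterations =", x$n_iterations,
      if (!x$converged) ", NOT converged" else "", ")\n")
  print(data.frame(beta = x$coefficients, se = x$standard_errors))
  invisible(x)
}

## Wald OR, 95% CI and p for one coefficient of a logisticFit
waldOr <- function(fit, term) {
  b <- fit$coefficients[term]
  se <- fit$standard_errors[term]
  z <- b / se
  c(or = exp(b), ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)))
}

#' Cochran-Armitage trend test
#'
#' Score test for a linear trend in case proportion across the three genotype
#' classes with scores 0/1/2; two-sided p from the 1-df chi-square. Genotype
#' classes with no subjects are dropped.
#'
#' @param counts 2x3 matrix of counts, rows = (case, control), columns =
#'   genotype dosage 0/1/2.
#' @return two-sided p-value.
#' @export
trendTest <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != 2L)
    stop("expected a 2 x k genotype count matrix")
  score <- seq_len(ncol(counts)) - 1
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  score <- score[keep]
  if (ncol(counts) < 2L || any(rowSums(counts) == 0))
    stop("degenerate margins for trend test")
  res <- suppressWarnings(
    stats::prop.trend.test(counts[1, ], colSums(counts), score = score))
  unname(res$p.value)
}

#' Associate one SNP with case status
#'
#' Orients the SNP to the control-major reference allele, then fits the
#' allelic, codominant and dominant logistic models, each adjusted for age
#' and sex (complete cases on genotype, age and sex), computes the
#' Cochran-Armitage trend p on the unadjusted genotype counts and an
#' unadjusted allele-count 2x2 odds ratio for cross-checking against printed
#' MAFs. When either status group has no minor homozygote the homozygote
#' contrast is undefined (reported NA) and the heterozygote contrast is fit
#' on the subjects with dosage <= 1.
#'
#' @param study a QC-passed [SnpStudy-class].
#' @param rsid the SNP to test.
#' @param minPerGroup complete-case floor per status group (default 10);
#'   below it the row is flagged \code{insufficient_data} and no model is
#'   fit.
#' @param alpha nominal significance level for the flag column.
#' @return one-row data.frame (see [associateAll()] for the columns).
#' @export
associateSnp <- function(study, rsid, minPerGroup = 10, alpha = 0.05) {
  geno <- t(dosageMatrix(study))
  if (!rsid %in% colnames(geno)) stop("unknown rsid: ", rsid)
  subj <- subjectData(study)
  sex01 <- ifelse(subj$sex == "male", 1, 0)  # female = reference
  keep <- !is.na(geno[, rsid]) & !is.na(subj$age) & !is.na(sex01)
  d <- geno[keep, rsid]
  y <- as.numeric(subj$status[keep] == "case")
  age <- subj$age[keep]
  sex <- sex01[keep]

  na4 <- c(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           p = NA_real_)
  row <- data.frame(rsid = rsid, n_complete = length(y),
                    maf_controls = NA_real_, maf_cases = NA_real_,
                    flipped = NA, t(c(
                      allelic = na4, het = na4, hom = na4, dom = na4)),
                    p_trend = NA_real_, or_allele_2x2 = NA_real_,
                    insufficient_data = FALSE, significant = FALSE,
                    stringsAsFactors = FALSE)
  names(row) <- sub("^(allelic|het|hom|dom)\\.", "\\1_", names(row))

  if (sum(y == 1) < minPerGroup || sum(y == 0) < minPerGroup) {
    row$insufficient_data <- TRUE
    return(row)
  }

  ref <- assignReferenceAllele(d[y == 0])
  if (ref$flipped) d <- 2 - d
  row$maf_controls <- ref$maf
  row$flipped <- ref$flipped
  dc <- d[y == 1]
  row$maf_cases <- sum(dc) / (2 * length(dc))

  put <- function(row, prefix, vals) {
    row[paste0(prefix, c("_or", "_ci_low", "_ci_high", "_p"))] <-
      unname(vals)
    row
  }
  fit_or <- function(cov, yy, aa, ss, term) {
    f <- logisticFit(cbind(cov, age = aa, sex = ss), yy)
    waldOr(f, term)
  }

  row <- put(row, "allelic", fit_or(cbind(dosage = d), y, age, sex,
                                    "dosage"))

  hom_by_group <- c(sum(d == 2 & y == 1), sum(d == 2 & y == 0))
  if (all(hom_by_group > 0)) {
    f <- logisticFit(cbind(encodeModel(d, "codominant"),
                           age = age, sex = sex), y)
    row <- put(row, "het", waldOr(f, "het"))
    row <- put(row, "hom", waldOr(f, "hom"))
  } else {
    sub <- d <= 1
    if (sum(y[sub] == 1) > 0 && sum(y[sub] == 0) > 0 && any(d[sub] == 1))
      row <- put(row, "het",
                 fit_or(cbind(het = as.numeric(d[sub] == 1)),
                        y[sub], age[sub], sex[sub], "het"))
  }

  carrier_by_group <- c(sum(d >= 1 & y == 1), sum(d >= 1 & y == 0))
  if (all(carrier_by_group > 0) && any(d == 0))
    row <- put(row, "dom", fit_or(encodeModel(d, "dominant"),
                                  y, age, sex, "carrier"))

  counts <- rbind(case = tabulate(d[y == 1] + 1, 3),
                  control = tabulate(d[y == 0] + 1, 3))
  row$p_trend <- tryCatch(trendTest(counts), error = function(e) NA_real_)

  a <- sum(d[y == 1]); b <- 2 * sum(y == 1) - a
  cc <- sum(d[y == 0]); dd <- 2 * sum(y == 0) - cc
  if (all(c(a, b, cc, dd) > 0)) row$or_allele_2x2 <- (a * dd) / (b * cc)

  ps <- unlist(row[c("allelic_p", "het_p", "hom_p", "dom_p")])
  row$significant <- any(!is.na(ps) & ps < alpha)
  row
}

#' Associate every SNP in a study
#'
#' Runs [associateSnp()] across all panel SNPs retained in the (QC-passed)
#' study. A Bonferroni-adjusted allelic p-value column is appended for
#' information only; the significance flag stays nominal, matching the
#' source analysis.
#'
#' @inheritParams associateSnp
#' @return data.frame, one row per SNP: control/case MAFs, orientation flag,
#'   OR / 95\% CI / p for the allelic, codominant-heterozygote,
#'   codominant-homozygote and dominant contrasts, trend p, unadjusted
#'   allele-count OR, completeness flags.
#' @export
associateAll <- function(study, minPerGroup = 10, alpha = 0.05) {
  out <- do.call(rbind, lapply(rownames(study), associateSnp,
                               study = study, minPerGroup = minPerGroup,
                               alpha = alpha))
  out$p_allelic_bonferroni <- pmin(1, out$allelic_p * nrow(out))
  rownames(out) <- NULL
  out
}
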