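#' Convert minor-allele dosage to risk-allele count
#'
#' The risk allele is the minor allele when the external GWAS odds ratio is
#' >= 1 and the major allele otherwise, so protective minor alleles are
#' flipped before counting or weighting. Missing propagates.
#'
#' @param minorDosage dosage in 0/1/2/\code{NA}.
#' @param gwasOr published per-minor-allele odds ratio (> 0).
#' @return risk-allele count in 0/1/2/\code{NA}.
#' @export
riskAlleleDosage <- function(minorDosage, gwasOr) {
  if (any(gwasOr <= 0)) stop("gwas_or must be positive")
  ifelse(gwasOr >= 1, minorDosage, 2 - minorDosage)
}

#' Unweighted polygenic score for one subject
#'
#' Sum of non-missing risk-allele counts over the score's SNPs.
#'
#' @param riskDosages risk-allele counts (0/1/2/\code{NA}) over the m SNPs.
#' @return list with \code{raw} and \code{n_genotyped}; \code{raw} is
#'   \code{NA} when no SNP is genotyped.
#' @export
unweightedScore <- function(riskDosages) {
  if (length(riskDosages) == 0L) stop("empty score panel")
  ok <- !is.na(riskDosages)
  list(raw = if (any(ok)) sum(riskDosages[ok]) else NA_real_,
       n_genotyped = sum(ok))
}

#' ln(OR)-weighted polygenic score for one subject
#'
#' Each SNP contributes risk-allele count times |ln(OR)|: 0 for no risk
#' allele, ln(OR) for one, 2 ln(OR) for two, on the risk-allele scale (the
#' absolute value makes flipped protective alleles contribute positively).
#'
#' @param riskDosages risk-allele counts over the m SNPs.
#' @param gwasOr per-SNP published odds ratios (same length; a missing
#'   weight is an error naming the SNP).
#' @return list with \code{raw} and \code{n_genotyped}.
#' @export
weightedScore <- function(riskDosages, gwasOr) {
  if (length(riskDosages) != length(gwasOr))
    stop("weights and dosages differ in length")
  bad <- which(!is.finite(gwasOr))
  if (length(bad))
    stop("missing weight for SNP ",
         if (!is.null(names(gwasOr))) names(gwasOr)[bad[1]] else bad[1])
  w <- abs(log(gwasOr))
  ok <- !is.na(riskDosages)
  list(raw = if (any(ok)) sum(riskDosages[ok] * w[ok]) else NA_real_,
       n_genotyped = sum(ok))
}

#' Scale a score for missing genotypes
#'
#' Multiplies the raw score by (total score SNPs) / (SNPs genotyped for the
#' subject), making scores comparable across call rates; the identity at
#' full call rate.
#'
#' @param raw raw score.
#' @param mTotal total SNPs in the score.
#' @param nGenotyped SNPs genotyped for the subject (>= 1).
#' @return scaled score.
#' @export
scaleScore <- function(raw, mTotal, nGenotyped) {
  if (any(nGenotyped == 0)) stop("no genotyped PRS SNPs")
  raw * mTotal / nGenotyped
}

#' Assign control-based quintiles
#'
#' Cutpoints are the nearest-rank empirical quantiles of the control scores
#' at 0.2/0.4/0.6/0.8; bins are left-open, right-closed, so a score equal to
#' a cutpoint falls in the lower quintile and the top quintile is open above.
#'
#' @param scores scores to bin.
#' @param controlScores control-group scores defining the cutpoints (at
#'   least 5 distinct values).
#' @return integer quintiles 1-5 (\code{NA} for \code{NA} scores).
#' @export
quintileAssign <- function(scores, controlScores) {
  cs <- sort(controlScores[!is.na(controlScores)])
  if (length(unique(cs)) < 5L) stop("degenerate control distribution")
  cuts <- cs[ceiling(seq_len(4) * length(cs) / 5)]
  as.integer(findInterval(scores, cuts, left.open = TRUE) + 1L)
}

#' Adjusted association between score quintiles and case status
#'
#' Two logistic fits, both adjusted for age and sex on complete cases: one
#' with quintiles 2-5 as indicator contrasts against quintile 1, one with
#' the quintile index 1-5 as a continuous covariate (so the continuous OR is
#' per one-quintile increment). A quintile with no cases or no controls
#' yields an undefined contrast.
#'
#' @param quintile integer 1-5 per subject.
#' @param status \code{"case"} / \code{"control"} per subject.
#' @param age,sex adjustment covariates (sex as \code{"male"} /
#'   \code{"female"}).
#' @return data.frame rows \code{quintile1} (reference) ... \code{quintile5}
#'   and \code{continuous}, with or/ci_low/ci_high/p and per-quintile
#'   case/control counts.
#' @export
prsAssociation <- function(quintile, status, age, sex) {
  sex01 <- ifelse(sex == "male", 1, 0)
  keep <- !is.na(quintile) & !is.na(age) & !is.na(sex01)
  q <- quintile[keep]
  y <- as.numeric(status[keep] == "case")
  age <- age[keep]; sex01 <- sex01[keep]

  counts <- t(vapply(1:5, function(k)
    c(cases = sum(y == 1 & q == k), controls = sum(y == 0 & q == k)),
    numeric(2)))
  ok_q <- which(counts[, 1] > 0 & counts[, 2] > 0)

  out <- data.frame(term = c(paste0("quintile", 1:5), "continuous"),
                    cases = c(counts[, 1], NA), controls = c(counts[, 2], NA),
                    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  out[1, c("or", "ci_low", "ci_high", "p")] <- c(1, NA, NA, NA)

  present <- intersect(2:5, unique(q))
  usable <- intersect(present, ok_q)
  if (1 %in% ok_q && length(usable)) {
    ind <- vapply(present, function(k) as.numeric(q == k),
                  numeric(length(q)))
    colnames(ind) <- paste0("quintile", present)
    fit <- logisticFit(cbind(ind, age = age, sex = sex01), y)
    for (k in usable)
      out[k, c("or", "ci_low", "ci_high", "p")] <-
        unname(waldOr(fit, paste0("quintile", k)))
  }
  fitc <- logisticFit(cbind(quintile = q, age = age, sex = sex01), y)
  out[6, c("or", "ci_low", "ci_high", "p")] <- unname(waldOr(fitc,
                                                             "quintile"))
  out
}

#' Compute the study's four polygenic risk scores and their associations
#'
#' Builds risk-allele dosages (orienting each SNP by its external weight),
#' then per-subject unweighted and |ln(OR)|-weighted sums with their
#' missingness-scaled versions, and runs the adjusted quintile and
#' continuous logistic analyses for the four published variants: unweighted
#' and weighted on the 100\%-call-rate subset (raw scores), and unweighted
#' and weighted scaled on all scoreable subjects. Quintile cutpoints come
#' from each analysis population's own controls.
#'
#' @param study a QC-passed [SnpStudy-class].
#' @param snpSubset rsIDs to score; default all panel SNPs retained in the
#'   study with \code{in_prs} TRUE (the two survival-GWAS loci are never
#'   included).
#' @param weights named per-SNP odds ratios overriding the panel
#'   \code{gwas_or} column.
#' @return a [PrsResult-class].
#' @export
computePrs <- function(study, snpSubset = NULL, weights = NULL) {
  panel <- snpPanel(study)
  if (is.null(snpSubset))
    snpSubset <- panel$rsid[panel$in_prs]
  snpSubset <- setdiff(snpSubset, SURVIVAL_SNPS)
  snpSubset <- intersect(snpSubset, rownames(study))
  if (length(snpSubset) == 0L) stop("empty PRS SNP subset")
  ors <- if (is.null(weights)) {
    stats::setNames(panel$gwas_or[match(snpSubset, panel$rsid)], snpSubset)
  } else {
    if (!all(snpSubset %in% names(weights)))
      stop("missing weight for SNP ",
           setdiff(snpSubset, names(weights))[1])
    weights[snpSubset]
  }
  geno <- t(dosageMatrix(study))[, snpSubset, drop = FALSE]
  risk <- sweep_risk(geno, ors)
  m <- length(snpSubset)
  w <- abs(log(ors))

  nGeno <- rowSums(!is.na(risk))
  unw <- rowSums(risk, na.rm = TRUE)
  unw[nGeno == 0] <- NA
  wgt <- as.vector((ifelse(is.na(risk), 0, risk) %*% w))
  wgt[nGeno == 0] <- NA

  subj <- subjectData(study)
  scores <- data.frame(
    subject_id = subj$subject_id, status = subj$status,
    n_genotyped = nGeno,
    unweighted = unw, weighted = wgt,
    unweighted_scaled = ifelse(nGeno > 0, unw * m / nGeno, NA),
    weighted_scaled = ifelse(nGeno > 0, wgt * m / nGeno, NA),
    stringsAsFactors = FALSE)

  block <- function(score, rows) {
    s <- score[rows]
    ctrl <- s[subj$status[rows] == "control"]
    qq <- quintileAssign(s, ctrl)
    prsAssociation(qq, subj$status[rows], subj$age[rows], subj$sex[rows])
  }
  full <- nGeno == m
  any_called <- nGeno > 0
  analyses <- list(
    unweighted_full_callrate = block(scores$unweighted, full),
    unweighted_scaled_all = block(scores$unweighted_scaled, any_called),
    weighted_full_callrate = block(scores$weighted, full),
    weighted_scaled_all = block(scores$weighted_scaled, any_called))

  methods::new("PrsResult", scores = scores, analyses = analyses,
               snpSubset = snpSubset, weights = w)
}

## risk-allele orientation applied column-wise to a dosage matrix
sweep_risk <- function(geno, ors) {
  flip <- ors < 1
  out <- geno
  out[, flip] <- 2 - geno[, flip, drop = FALSE]
  out
}
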