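---
title: "Methods: candidate-SNP association and polygenic risk scores"
author: "pancprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-SNP association and polygenic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancprs)
```

## The study design this package models

A candidate-SNP case–control study genotypes a fixed, rsID-keyed panel of
loci — here 26 variants previously reported in pancreatic-cancer GWAS — in
a modest cohort (the reference design: 78 cases, 256 controls), then asks
whether each locus replicates, how allele frequencies behave across
self-reported ancestry strata, and how a polygenic risk score built from
the panel separates cases from controls. All data structures follow from
that design: a `SnpStudy` extends `SummarizedExperiment` with one assay of
minor-allele dosages (SNPs × subjects), the panel in `rowData` and subject
metadata in `colData`. Dosage always counts the panel's *minor* allele at
ingest; orientation to the control-major reference (association) or to the
risk allele (scores) happens inside the respective module, so no genotype
is ever flipped twice.

## Quality control

QC runs in a fixed, idempotent order:

1. **Duplicates.** Declared duplicate pairs are scored by concordance over
   jointly called SNPs; pairs under the threshold (default 0.99) or with no
   overlap are flagged. The member with the higher call rate is retained —
   the retention rule is our choice (duplicates exist for QC only and any
   fixed rule is defensible); ties keep the original sample.
2. **Call rate.** Subjects genotyped at fewer than 75% of panel SNPs are
   excluded. The threshold is a tunable fraction (`callRateMin`), applied
   per sample only — there is deliberately no per-SNP call-rate filter,
   because the reference design states only the per-sample rule.
3. **Monomorphic loci and Hardy–Weinberg.** On the survivors, loci with
   zero observed copies of either allele are removed (they carry no
   information), and the exact HWE test is run in controls only — cases are
   expected to depart from HWE at truly associated loci, so they never
   contribute. SNPs with p ≤ 0.05 are excluded by default; the exclusion
   can be disabled (`hweExclude = FALSE`) since a nominal screen removes
   ~5% of well-behaved loci by construction.

The HWE test is the *exact* test rather than the chi-square: with dozens of
cases, genotype cells are small and the asymptotic test is unreliable,
while the exact test admits a clean enumeration oracle. Probabilities are
computed by the numerically stable recurrence over heterozygote counts
conditional on the observed allele counts; the two-sided p sums all
configurations no more likely than the observed one, with a 1e-9 relative
tolerance absorbing floating-point ties between symmetric configurations.

## Contingency-table machinery

Chi-square tests are Pearson without continuity correction — the convention
that reproduces the reference study's printed p-values from reconstructed
counts — with r×c support for the three-level ancestry comparison; Fisher's
exact test is restricted to 2×2 by design and computed by direct
hypergeometric enumeration (again with the conventional 1e-7 relative tie
tolerance). Counts are reconstructed from printed percentages by
`round(pct/100 × n)` with halves away from zero, the rule that matched
every table cell we verified; the effective denominators for the exposure
variables are 76 cases and 260 controls, the smallest integers reproducing
the printed percentages (the enrollment counts are 78/256 — the
discrepancy is surfaced in the package documentation rather than hidden).
The age comparison is the pooled-variance Student t (Welch available),
accepting either raw samples or summary moments.

## Per-SNP association

For each SNP the reference category is the more common allele in controls;
a control frequency above 0.5 complements the dosages, a tie at exactly 0.5
keeps the panel orientation. Three adjusted logistic models are fit on
complete cases (genotype, age, sex): allelic (additive dosage), codominant
(het and hom indicators) and dominant (carrier indicator), each with age
linear in years and sex coded 0 = female (the larger group). The "allelic
model" is per-subject dosage regression because the reference results are
*adjusted* allelic ORs and an allele-level 2×2 cannot carry subject-level
covariates; an unadjusted allele-count OR is also emitted for cross-checks
against printed MAFs. The trend p is the unadjusted Cochran–Armitage score
test with scores 0/1/2, kept distinct from the allelic fit because the
reference tables print different values for the two.

Fitting is binomial IRLS (`glm.fit`) with a 1e-12 relative deviance
tolerance and at most 50 iterations; Wald covariance is the inverse
observed information *re-evaluated at the converged coefficients* (the
information from the final IRLS weighting step is one iteration stale and
costs ~1e-8 of standard-error accuracy). Collinear designs are rejected
naming the offending column; quasi-separation is flagged when any
coefficient exceeds 15 on the log-odds scale. When either status group has
no minor homozygote, the homozygote contrast is undefined (rendered "–")
and the heterozygote contrast is re-fit on the dosage ≤ 1 subset so that an
empty cell cannot distort it through quasi-separation. Fits fall below a
complete-case floor (default 10 per group) are reported as
`insufficient_data` rather than fit. Significance is nominal p < 0.05 with
no multiplicity correction, matching the reference analysis; a Bonferroni
column is emitted for information only.

## Polygenic risk scores

Risk alleles are oriented per SNP by the external odds ratio: minor allele
if OR ≥ 1, major otherwise, so protective minor alleles flip before
counting and every weight |ln OR| is non-negative. The four score variants
are the unweighted sum of risk-allele counts, the |ln OR|-weighted sum, and
their missingness-scaled versions (score × m / n_genotyped, the identity at
full call rate; scaling applies to the weighted sum exactly as to the
unweighted one). The default subset is every analyzed panel SNP except the
two survival-GWAS loci; a 9-SNP subset restricted to the replicated loci
runs through the identical code path.

Quintile cutpoints are nearest-rank empirical quantiles of the *control*
scores at 0.2/0.4/0.6/0.8 with left-open/right-closed bins — deterministic,
oracle-checkable and unambiguous under ties, which the reference leaves
unspecified. The four published analyses use two distinct cutpoint sets:
raw scores on the 100%-call-rate subset use that subset's controls; scaled
scores on all subjects use all scoreable controls. Association is one
adjusted logistic fit with quintiles 2–5 as indicators against quintile 1,
and one with the integer quintile index 1–5 as a continuous covariate (the
published "continuous" unit is one quintile increment, so the index — not
the raw score — is the covariate). Fewer than five distinct control scores
is an error (degenerate distribution); an empty case or control cell in a
quintile leaves that contrast undefined.

The default panel ships the study's own allelic OR estimates as the
`gwas_or` weight column. This is a documented placeholder: the intended
weights are the discovery-GWAS ORs, which were never tabulated at the
source, so users with access to them should substitute their own via the
`weights` argument of `computePrs()`.

## The synthetic-cohort generator

The generator emulates the reference study's data structure so the whole
pipeline is testable at desk scale:

- control genotypes per SNP from exact HWE proportions (q², 2pq, p²) at the
  published control MAFs (a MAF of 0 encodes the monomorphic locus);
- case genotypes from the tilted distribution P(g|case) ∝ HWE(g)·ORᵍ — the
  exact case law under an additive logistic model with case–control
  sampling — which is fast and analytically checkable (expected case MAF
  `(2p²OR² + 2pqOR) / (2(p²OR² + 2pqOR + q²))`), rather than rejection
  sampling a population;
- ages normal per group (means 62.46 / 56.62 years; SD 26 years for both
  groups, back-derived from the published group means, sample sizes and
  age-comparison p-value, since no SD is printed), truncated to [0, 120];
- sex and ancestry categorical at the published group proportions;
  exposures independent Bernoulli at the published group rates (the family
  history rates, unpublished, default to 10%/7%, typical of pancreatic
  cancer cohorts);
- uniform genotype missingness at 0.005 per call — chosen so the share of
  subjects with a perfect call rate matches the published 100%-call-rate
  subset (≈86%) — plus an optional fraction of subjects with ~50%
  missingness to exercise the call-rate filter (default 0, the cohort's
  post-QC state), and 5% duplicated samples with fresh IDs;
- one integer seed drives everything; identical seed and config give a
  bit-identical cohort, and the committed example fixture regenerates from
  its seed.

What the generator does *not* emulate — and therefore what passing tests do
not demonstrate about real data: linkage disequilibrium between loci (the
panel's loci sit on different chromosomes or distant regions and the score
assumes additivity, so SNPs are drawn independently), population structure
beyond categorical ancestry labels, genotype–exposure dependence,
non-additive (dominance or epistatic) disease architectures, and
genotyping-intensity artifacts (genotypes arrive as hard calls). Parameter
recovery on simulated cohorts shows the estimators are wired correctly,
not that the biological effect sizes are attainable in any particular
population.

## Numerical choices and degenerate inputs

Tie and tolerance rules are fixed once: HWE and Fisher tie tolerances 1e-9
and 1e-7 relative; IRLS deviance tolerance 1e-12, 50 iterations; quintile
bins right-closed; control-MAF tie keeps panel orientation; count
reconstruction rounds half away from zero. Degenerate inputs fail loudly
with the offending item named: empty panels, out-of-range dosages (with
subject and SNP coordinates), zero-margin tables, single-class outcomes,
collinear designs, all-missing score rows, fewer than five distinct control
scores. Missing covariates are handled by complete-case exclusion per fit.
VCF ingest matches panel sites by rsID only — the loci are defined by
rsID, never position — complements dosages when REF/ALT is flipped
relative to the panel, treats half calls as missing and refuses
multi-allelic records at panel sites.

## Validation problem sizes

The test suite and the acceptance script validate at these scales, chosen
to keep a full run within a few minutes on one CPU while leaving no
meaningful Monte-Carlo slack: exhaustive oracle agreement over all 2×2
tables with total ≤ 60 (635,375 tables) and all HWE genotype triples with
n ≤ 50 (23,425 triples); closed-form logistic agreement on 100 random 2×2
expansions; allelic-OR recovery over OR ∈ {0.6, 1, 1.5, 2} × MAF ∈ {0.1,
0.25, 0.4} with 200 replicates of 2,000 cases/2,000 controls per cell;
null calibration of the chi-square and trend tests at 10,000 replicates;
quintile balance at 10,000 controls; and risk-score detection power over
200 replicates of 1,000/1,000 with ten SNPs of OR 1.3. The printed-table
reconstructions (tobacco, diabetes, pancreatitis, ancestry MAFs, direction
consistency of the nine replicated loci) are deterministic and instant.

## Known limitations

Beyond the generator's simplifications listed above: the package performs
no LD-aware or penalized score construction, no exposure×SNP interactions,
no recessive model, no survival analysis (the two survival-GWAS loci are
carried only to be excluded from scores), and no liftover or genome-build
awareness. The published per-SNP adjusted ORs and score quintile ORs of
the reference cohort are not reproducible without its raw genotypes, which
were never deposited; they anchor schemas, directions and simulation
design, not point values.
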