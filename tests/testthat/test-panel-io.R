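test_that("shipped default panel has the full candidate locus set", {
  p <- defaultPanel()
  expect_equal(nrow(p), 26L)
  expect_true(all(c("rs35226131", "rs11655237") %in% p$rsid))
  r <- p[p$rsid == "rs3790844", ]
  expect_equal(r$gene, "NR5A2")
  expect_equal(c(r$major, r$minor), c("T", "C"))
  expect_false(any(p$in_prs[p$rsid %in% c("rs684559", "rs353630")]))
  expect_true(all(p$gwas_or > 0))
})

test_that("panel validation rejects malformed input, naming the row", {
  empty <- tempfile(fileext = ".tsv")
  writeLines("rsid\tgene\tmajor\tminor\tgwas_or\tin_prs", empty)
  expect_error(loadPanel(empty), "no panel rows")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("rsid\tgene\tmajor\tminor\tgwas_or\tin_prs",
               "rs1\tG1\tA\tG\t1.2\tTRUE",
               "rs1\tG1\tA\tG\t1.2\tTRUE"), dup)
  expect_error(loadPanel(dup), "duplicate rsid.*rs1")

  badallele <- tempfile(fileext = ".tsv")
  writeLines(c("rsid\tgene\tmajor\tminor\tgwas_or\tin_prs",
               "rs9\tG1\tA\tN\t1.2\tTRUE"), badallele)
  expect_error(loadPanel(badallele), "allele.*rs9")

  bador <- tempfile(fileext = ".tsv")
  writeLines(c("rsid\tgene\tmajor\tminor\tgwas_or\tin_prs",
               "rs9\tG1\tA\tG\t-1\tTRUE"), bador)
  expect_error(loadPanel(bador), "gwas_or.*rs9")
})

test_that("genotype TSV round trips and rejects invalid dosages", {
  panel <- makePanel(2, rsid = c("rsA", "rsB"))
  m <- matrix(c(0, 1, 2, NA, 1, 1), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("rsA", "rsB")))
  f <- tempfile(fileext = ".tsv")
  writeGenotypes(m, f)
  back <- readGenotypes(f, panel)
  expect_identical(back, m)

  extra <- tempfile(fileext = ".tsv")
  writeLines(c("subject_id\trsA\trsZ", "s1\t1\t2"), extra)
  expect_warning(g <- readGenotypes(extra, panel), "rsZ")
  expect_equal(colnames(g), "rsA")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("subject_id\trsA", "s1\t3"), bad)
  expect_error(readGenotypes(bad, panel), "subject s1, SNP rsA")
})

test_that("subject TSV parsing enforces status and keeps blanks missing", {
  f <- tempfile(fileext = ".tsv")
  hdr <- paste(c("subject_id", "status", "age", "sex", "ancestry",
                 "tobacco", "alcohol", "diabetes", "pancreatitis",
                 "family_history", "duplicate_of"), collapse = "\t")
  writeLines(c(hdr,
               "s1\tcase\t\tmale\tEuropean\tyes\tno\tno\tno\tno\t",
               "s2\tcontrol\t61\tfemale\tAfrican\tno\tno\tyes\tno\tno\t"),
             f)
  s <- readSubjects(f)
  expect_equal(nrow(s), 2L)
  expect_true(is.na(s$age[1]))
  expect_equal(s$age[2], 61)

  writeLines(c(hdr,
               "s1\thealthy\t50\tmale\tEuropean\tno\tno\tno\tno\tno\t"), f)
  expect_error(readSubjects(f), "invalid status 'healthy'")

  writeLines(c(hdr, "s1\t\t50\tmale\tEuropean\tno\tno\tno\tno\tno\t"), f)
  expect_error(readSubjects(f), "missing status")
})

test_that("VCF genotypes map to panel-minor dosage with orientation fixes", {
  panel <- makePanel(3, rsid = c("rsA", "rsB", "rsC"))
  # rsB has REF = panel minor, so its ALT dosage must be complemented
  panel$major <- c("A", "G", "C"); panel$minor <- c("G", "A", "T")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "p1", "p2"), collapse = "\t"),
    "1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1",
    "1\t200\trsB\tA\tG\t.\tPASS\t.\tGT\t1/1\t./."), vcf)
  expect_warning(
    expect_message(g <- readVcfGenotypes(vcf, panel), "flipped.*rsB"),
    "rsC")
  expect_equal(unname(g[, "rsA"]), c(1, 2))
  # rsB: ALT G is the panel MAJOR allele; 1/1 = 2 major copies = dosage 0
  expect_equal(unname(g["p1", "rsB"]), 0)
  expect_true(is.na(g["p2", "rsB"]))
  expect_true(all(is.na(g[, "rsC"])))

  multi <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "p1"), collapse = "\t"),
    "1\t100\trsA\tA\tG,T\t.\tPASS\t.\tGT\t0/1"), multi)
  expect_error(suppressWarnings(readVcfGenotypes(multi, panel[1, ])),
               "multi-allelic")
})

test_that("every rsid of a constructed study resolves to one panel row", {
  study <- simulateCohort(simConfig(nCases = 15, nControls = 30, seed = 3))
  expect_true(all(rownames(study) %in% snpPanel(study)$rsid))
  expect_false(anyDuplicated(snpPanel(study)$rsid) > 0)
  expect_error(SnpStudy(matrix(1, 1, 1, dimnames = list("s1", "rsNOPE")),
                        defaultPanel(),
                        subjectData(study)),
               "absent from panel")
})
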