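# Summary-statistic I/O and allele harmonization.

test_that("well-formed tables parse and invalid rows are dropped with a message", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchrom\tpos\tea\tnea\teaf\tbeta\tse\tpval\tn",
               "rs1\t1\t100\tA\tG\t0.3\t0.1\t0.02\t5.733e-7\t5000",
               "rs2\t1\t200\tC\tT\t0.5\t-0.2\t0.05\t6.334e-5\t5000",
               "rs3\t1\t300\tG\tA\t.\t0.05\t0.04\t0.2\t5000"), path)
  tab <- read_sumstats(path, trait_id = "prot")
  expect_s3_class(tab, "sumstat_table")
  expect_equal(nrow(tab$data), 3)
  expect_true(is.na(tab$data$eaf[3]))

  # se = 0 row dropped, others kept
  writeLines(c("rsid\tchrom\tpos\tea\tnea\teaf\tbeta\tse\tpval\tn",
               "rs1\t1\t100\tA\tG\t0.3\t0.1\t0\t0.001\t5000",
               "rs2\t1\t200\tC\tT\t0.5\t-0.2\t0.05\t6.334e-5\t5000"), path)
  expect_message(tab2 <- read_sumstats(path, trait_id = "prot"),
                 "dropped 1 invalid row")
  expect_equal(tab2$data$rsid, "rs2")

  # unmappable required column is fatal; zero parseable rows is fatal
  writeLines(c("snp\tchrom\tpos\tea\tnea\teaf\tbeta\tse\tpval\tn",
               "rs1\t1\t100\tA\tG\t0.3\t0.1\t0.02\t5.733e-7\t5000"), path)
  expect_error(read_sumstats(path, trait_id = "p"), "rsid")
  expect_equal(nrow(read_sumstats(path, trait_id = "p",
                                  dialect = c(rsid = "snp"))$data), 1)
  writeLines(c("rsid\tchrom\tpos\tea\tnea\teaf\tbeta\tse\tpval\tn",
               "rs1\t1\t100\tA\tG\t0.3\t0.1\t0\t0.001\t5000"), path)
  expect_error(suppressMessages(read_sumstats(path, trait_id = "p")),
               "no parseable rows")
})

test_that("write/read round trip reproduces a 100-row table exactly", {
  tab <- random_table(100, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  back <- read_sumstats(path, trait_id = tab$trait_id)
  expect_identical(back$data, tab$data)
})

test_that("palindrome detection follows allele complementarity", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
  expect_equal(is_palindromic(c("T", "G", "AT"), c("A", "C", "A")),
               c(TRUE, TRUE, NA))
})

test_that("harmonization flips swapped alleles and applies the palindrome MAF rule", {
  ex <- make_table(c("rs1", "rs2", "rs3", "rs4"),
                   ea = c("A", "A", "A", "A"),
                   nea = c("G", "T", "T", "C"),
                   beta = c(0.10, 0.08, 0.12, 0.05),
                   se = 0.02,
                   eaf = c(0.30, 0.50, 0.10, 0.20), trait_id = "prot")
  ou <- make_table(c("rs1", "rs2", "rs3", "rs4"),
                   ea = c("G", "A", "A", "G"),
                   nea = c("A", "T", "T", "C"),
                   beta = c(0.05, 0.02, 0.03, 0.01),
                   se = 0.02,
                   eaf = c(0.70, 0.50, 0.91, 0.20),
                   trait_id = "bmi", trait_type = "outcome")
  hd <- harmonize(ex, ou)
  p <- hd$pairs

  # swapped non-palindromic alleles: beta negated, eaf complemented
  expect_equal(p$action[1], "flipped")
  expect_equal(p$beta_y[1], -0.05)
  expect_equal(p$eaf_y[1], 0.30)

  # palindromic A/T with MAF 0.50 > 0.42: excluded
  expect_true(p$excluded[2])
  expect_equal(p$exclusion_reason[2], "palindromic_intermediate_maf")

  # palindromic A/T, eaf 0.10 vs 0.91: strand inferred opposite
  expect_equal(p$action[3], "freq_inferred")
  expect_equal(p$beta_y[3], -0.03)
  expect_equal(p$eaf_y[3], 0.09)

  # irreconcilable alleles (A/C vs G/C)
  expect_true(p$excluded[4])
  expect_equal(p$exclusion_reason[4], "allele_mismatch")

  # audit trail lists exactly the excluded variants
  audit_path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonization_audit(hd, audit_path)
  audit <- read.delim(audit_path)
  expect_equal(audit$rsid, c("rs2", "rs4"))
  expect_equal(audit$reason,
               c("palindromic_intermediate_maf", "allele_mismatch"))
})

test_that("palindrome frequency-concordance matches the hand-worked truth table", {
  # four strand/orientation configurations of an A/T SNP with exposure
  # eaf 0.10 (true effect +0.1 on the A allele):
  #  same strand, same EA      -> outcome eaf 0.12, beta +0.05, no flip
  #  same strand, swapped EA   -> outcome eaf 0.88, beta -0.05, flip
  #  other strand, reported T  -> outcome eaf 0.89, beta -0.05, flip
  #  other strand, reported A  -> outcome eaf 0.11, beta +0.05, no flip
  ex <- make_table(paste0("rs", 1:4), ea = "A", nea = "T",
                   beta = 0.1, se = 0.02, eaf = 0.10, trait_id = "x")
  ou <- make_table(paste0("rs", 1:4),
                   ea = c("A", "T", "T", "A"),
                   nea = c("T", "A", "A", "T"),
                   beta = c(0.05, -0.05, -0.05, 0.05),
                   se = 0.02,
                   eaf = c(0.12, 0.88, 0.89, 0.11),
                   trait_id = "y", trait_type = "outcome")
  hd <- harmonize(ex, ou)
  expect_false(any(hd$pairs$excluded))
  expect_equal(hd$pairs$action, rep("freq_inferred", 4))
  expect_equal(hd$pairs$beta_y, rep(0.05, 4))
  expect_equal(hd$pairs$eaf_y, c(0.12, 0.12, 0.11, 0.11))
})

test_that("harmonization is involution-safe and invariant to allele relabelling", {
  tab <- random_table(60, seed = 11)
  self <- harmonize(tab, tab)
  expect_false(any(self$pairs$excluded))
  expect_equal(self$pairs$action, rep("aligned", 60))
  expect_equal(self$pairs$beta_x, self$pairs$beta_y)

  # swapping both alleles and negating beta in the outcome leaves the
  # harmonized (beta_x, beta_y) pairs unchanged
  out <- random_table(60, seed = 12, trait_id = "out", trait_type = "outcome")
  relab <- out
  relab$data$ea <- out$data$nea
  relab$data$nea <- out$data$ea
  relab$data$beta <- -out$data$beta
  relab$data$eaf <- 1 - out$data$eaf
  h1 <- harmonize(tab, out)
  h2 <- harmonize(tab, relab)
  expect_equal(h1$pairs$excluded, h2$pairs$excluded)
  k <- !h1$pairs$excluded
  expect_equal(h1$pairs$beta_y[k], h2$pairs$beta_y[k])
  expect_equal(h1$pairs$beta_x[k], h2$pairs$beta_x[k])
  expect_equal(h1$pairs$eaf_y[k], h2$pairs$eaf_y[k])

  # excluded + kept counts always partition the rsid intersection
  expect_equal(sum(h1$pairs$excluded) + nrow(mr_pairs(h1)), 60)
})

test_that("harmonization errors on an empty variant intersection", {
  a <- make_table("rs1", "A", "G", 0.1, 0.02, trait_id = "protA")
  b <- make_table("rs2", "A", "G", 0.1, 0.02, trait_id = "bmi",
                  trait_type = "outcome")
  expect_error(harmonize(a, b), "protA.*bmi")
})

test_that("palindromic variants without frequencies are excluded, others proceed", {
  ex <- make_table(c("rs1", "rs2"), ea = c("A", "A"), nea = c("T", "G"),
                   beta = 0.1, se = 0.02, eaf = c(NA, NA), trait_id = "x")
  ou <- make_table(c("rs1", "rs2"), ea = c("A", "A"), nea = c("T", "G"),
                   beta = 0.05, se = 0.02, eaf = c(0.3, 0.3),
                   trait_id = "y", trait_type = "outcome")
  hd <- harmonize(ex, ou)
  expect_true(hd$pairs$excluded[1])
  expect_equal(hd$pairs$exclusion_reason[1], "palindromic_missing_eaf")
  expect_false(hd$pairs$excluded[2])
})
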