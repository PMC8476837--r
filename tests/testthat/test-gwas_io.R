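# Reading summary statistics / LD panels and allele harmonization.

test_that("summary statistics read through, with malformed rows dropped and logged", {
  path <- write_tsv_text(c(
    "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\t1\t1000\tA\tG\t0.2\t0.10\t0.02\t5e-7\t8000",
    "rs2\t1\t2000\tC\tT\t0.4\t-0.05\t0.03\t0.09\t8000",
    "rs3\t2\t3000\tG\tA\t0.1\t0.08\t0.02\t6e-5\t8000"))
  tab <- read_summary_stats(path, trait_id = "m1", trait_role = "exposure")
  expect_s3_class(tab, "summary_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(tab$beta, c(0.10, -0.05, 0.08))

  path2 <- write_tsv_text(c(
    "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\t1\t1000\ta\tg\t0.2\t0.10\t0.02\t5e-7\t8000",
    "rs2\t1\t2000\tC\tT\t0.4\t-0.05\tNA\t0.09\t8000",
    "rs3\t2\t3000\tAT\tA\t0.1\t0.08\t0.02\t6e-5\t8000"))
  expect_message(tab2 <- read_summary_stats(path2, "m1", "exposure"),
                 "dropped 2 row")
  expect_equal(tab2$snp_id, "rs1")
  expect_equal(tab2$effect_allele, "A")  # upper-cased
  expect_equal(sum(attr(tab2, "n_dropped")), 2)
})

test_that("duplicate snp_ids and missing required columns are hard errors", {
  dup <- write_tsv_text(c(
    "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\t1\t1000\tA\tG\t0.2\t0.1\t0.02\t1e-6\t10",
    "rs1\t1\t1000\tA\tG\t0.2\t0.1\t0.02\t1e-6\t10"))
  expect_error(read_summary_stats(dup, "m", "exposure"), "rs1",
               class = "mrmetab_input_error")

  nose <- write_tsv_text(c("SNP\tCHR\tPOS\tEA\tOA\tBETA\tP",
                           "rs1\t1\t1\tA\tG\t0.1\t1e-6"))
  expect_error(read_summary_stats(nose, "m", "exposure"), "SE",
               class = "mrmetab_config_error")
})

test_that("column maps translate foreign dialects, csv included", {
  path <- write_tsv_text(c(
    "rsid,chromosome,bp,a1,a2,freq,effect,stderr,pvalue",
    "rs9,3,500,T,C,0.25,0.2,0.05,0.004"))
  map <- c(SNP = "rsid", CHR = "chromosome", POS = "bp", EA = "a1", OA = "a2",
           EAF = "freq", BETA = "effect", SE = "stderr", P = "pvalue")
  tab <- read_summary_stats(path, "m", "exposure", column_map = map)
  expect_equal(tab$snp_id, "rs9")
  expect_equal(tab$se, 0.05)
  expect_true(is.na(tab$n))
})

test_that("pairwise LD panels default missing pairs to zero and reject bad r2", {
  path <- write_tsv_text(c("SNP_A\tSNP_B\tR2", "rs1\trs2\t0.5"))
  panel <- read_ld_panel(path, "pairwise")
  expect_equal(panel_r2(panel, "rs1", "rs2"), 0.5)
  expect_equal(panel_r2(panel, "rs1", "rs1"), 1)
  expect_true(is.na(panel_r2(panel, "rs1", "rs999")))
  expect_equal(unname(ld_panel(c("a", "b"), diag(2))$r2["a", "b"]), 0)

  bad <- write_tsv_text(c("SNP_A\tSNP_B\tR2", "rs1\trs2\t1.4"))
  expect_error(read_ld_panel(bad, "pairwise"), class = "mrmetab_input_error")
})

test_that("genotype dosage panels give squared sample correlations", {
  withr::with_seed(7, {
    n <- 10000
    d1 <- rbinom(n, 2, 0.3)
    d2 <- rbinom(n, 2, 0.3)  # independent draw
    lines <- c(paste(c("SNP", "CHR", "POS", paste0("s", 1:n)), collapse = "\t"),
               paste(c("rs1", "1", "100", d1), collapse = "\t"),
               paste(c("rs2", "1", "200", d1), collapse = "\t"),  # identical
               paste(c("rs3", "1", "300", d2), collapse = "\t"))
    panel <- read_ld_panel(write_tsv_text(lines), "genotype")
    expect_equal(panel_r2(panel, "rs1", "rs2"), 1.0)
    expect_lt(panel_r2(panel, "rs1", "rs3"), 0.01)
    expect_equal(panel_r2(panel, "rs1", "rs3"), cor(d1, d2)^2, tolerance = 1e-12)
  })
})

test_that("allele swaps and strand complements are aligned, with sign flips", {
  ex <- mk_table("rs1", beta = 0.10, se = 0.02, ea = "A", oa = "G",
                 trait_id = "exp")
  ou_swap <- mk_table("rs1", beta = -0.05, se = 0.01, ea = "G", oa = "A",
                      eaf = 0.7, trait_id = "out", trait_role = "outcome")
  h <- harmonize(ex, ou_swap)
  expect_equal(h$Gamma, 0.05)
  expect_true(h$flipped)
  expect_equal(h$eaf_outcome, 0.3)

  # Same variant reported on the opposite strand (T/C is the complement of
  # A/G): orientation kept, no flip.
  ou_strand <- mk_table("rs1", beta = -0.05, se = 0.01, ea = "T", oa = "C",
                        trait_id = "out", trait_role = "outcome")
  h2 <- harmonize(ex, ou_strand)
  expect_equal(h2$Gamma, -0.05)
  expect_false(h2$flipped)

  # Unreconcilable allele pair is dropped; with nothing left this is an error.
  ou_bad <- mk_table("rs1", beta = 0.05, se = 0.01, ea = "A", oa = "C",
                     trait_id = "out", trait_role = "outcome")
  expect_error(suppressMessages(harmonize(ex, ou_bad)),
               class = "mrmetab_analysis_error")
})

test_that("palindromic SNPs are frequency-aligned or dropped as ambiguous", {
  ex <- mk_table(c("rs1", "rs2"), beta = c(0.1, 0.2), se = 0.02,
                 ea = "A", oa = "T", eaf = 0.10, trait_id = "exp")

  # Clear minor-allele frequencies on the same side of 0.5: kept, no flip.
  ou_same <- mk_table(c("rs1", "rs2"), beta = c(0.05, 0.07), se = 0.01,
                      ea = "A", oa = "T", eaf = 0.12,
                      trait_id = "out", trait_role = "outcome")
  h <- harmonize(ex, ou_same, palindromic_policy = "infer",
                 maf_infer_threshold = 0.42)
  expect_equal(nrow(h), 2)
  expect_false(any(h$flipped))
  expect_equal(h$Gamma, c(0.05, 0.07))

  # Opposite sides of 0.5: the recorded effect allele is the other strand's;
  # retained but flipped.
  ou_opp <- mk_table("rs1", beta = 0.05, se = 0.01, ea = "A", oa = "T",
                     eaf = 0.88, trait_id = "out", trait_role = "outcome")
  h2 <- harmonize(ex[ex$snp_id == "rs1", ], ou_opp)
  expect_true(h2$flipped)
  expect_equal(h2$Gamma, -0.05)
  expect_equal(h2$eaf_outcome, 0.12)

  # Near-0.5 frequency is strand-ambiguous: dropped under infer.
  ex_amb <- mk_table(c("rs1", "rs2"), beta = c(0.1, 0.2), se = 0.02,
                     ea = "A", oa = "T", eaf = c(0.49, 0.10), trait_id = "exp")
  h3 <- suppressMessages(harmonize(ex_amb, ou_same))
  expect_equal(h3$snp_id, "rs2")
  expect_equal(attr(h3, "drops")$reason, "palindromic_ambiguous")

  # policy = drop removes all palindromic SNPs outright.
  expect_error(suppressMessages(harmonize(ex, ou_same, palindromic_policy = "drop")),
               "no shared instruments")
})

test_that("harmonization is idempotent and invariant to pre-flipped input", {
  withr::with_seed(11, {
    J <- 30
    pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "G"), ncol = 2, byrow = TRUE)
    idx <- sample(4, J, replace = TRUE)
    ex <- mk_table(sprintf("rs%02d", 1:J), beta = rnorm(J, 0, 0.2), se = 0.02,
                   ea = pairs[idx, 1], oa = pairs[idx, 2],
                   eaf = runif(J, 0.05, 0.45), trait_id = "exp")
    flip <- runif(J) < 0.5
    ou <- mk_table(sprintf("rs%02d", 1:J), beta = rnorm(J, 0, 0.1), se = 0.05,
                   ea = ifelse(flip, pairs[idx, 2], pairs[idx, 1]),
                   oa = ifelse(flip, pairs[idx, 1], pairs[idx, 2]),
                   eaf = ifelse(flip, 1 - ex$eaf, ex$eaf),
                   trait_id = "out", trait_role = "outcome")
    h <- harmonize(ex, ou)
    expect_equal(h$flipped, flip[match(h$snp_id, ex$snp_id)])

    # Rebuild tables from the harmonized arrays: a second pass is a no-op.
    ex2 <- mk_table(h$snp_id, beta = h$gamma, se = h$sigma_x,
                    ea = h$effect_allele, oa = h$other_allele,
                    eaf = h$eaf_exposure, trait_id = "exp")
    ou2 <- mk_table(h$snp_id, beta = h$Gamma, se = h$sigma_y,
                    ea = h$effect_allele, oa = h$other_allele,
                    eaf = h$eaf_outcome, trait_id = "out", trait_role = "outcome")
    h2 <- harmonize(ex2, ou2)
    expect_equal(h2$gamma, h$gamma)
    expect_equal(h2$Gamma, h$Gamma)
    expect_false(any(h2$flipped))

    # Flipping both outcome alleles and negating beta changes nothing.
    ou3 <- mk_table(ou$snp_id, beta = -ou$beta, se = ou$se,
                    ea = ou$other_allele, oa = ou$effect_allele,
                    eaf = 1 - ou$eaf, trait_id = "out", trait_role = "outcome")
    h3 <- harmonize(ex, ou3)
    expect_equal(h3$gamma, h$gamma)
    expect_equal(h3$Gamma, h$Gamma)
  })
})

test_that("record counts are conserved across harmonization", {
  ex <- mk_table(c("rs1", "rs2", "rs3", "rs4"), beta = c(0.1, 0.2, 0.3, 0.4),
                 se = 0.02, ea = c("A", "A", "A", "A"), oa = c("G", "T", "G", "G"),
                 eaf = c(0.2, 0.49, 0.2, 0.2), trait_id = "exp")
  # rs1 aligned; rs2 palindromic-ambiguous; rs3 non-resolvable; rs4 absent.
  ou <- mk_table(c("rs1", "rs2", "rs3", "rs9"), beta = c(0.1, 0.1, 0.1, 0.1),
                 se = 0.05, ea = c("A", "A", "A", "A"), oa = c("G", "T", "C", "G"),
                 eaf = c(0.2, 0.45, 0.2, 0.2), trait_id = "out", trait_role = "outcome")
  h <- suppressMessages(harmonize(ex, ou))
  counts <- attr(h, "counts")
  not_shared <- nrow(ex) - counts["input"]
  expect_equal(unname(counts[["harmonized"]] + counts[["dropped"]] + not_shared),
               nrow(ex), ignore_attr = TRUE)
  expect_setequal(attr(h, "drops")$reason,
                  c("palindromic_ambiguous", "non_resolvable"))
  expect_equal(h$snp_id, "rs1")
})

test_that("empty intersection raises the no-shared-instruments error", {
  ex <- mk_table("rs1", 0.1, 0.02, trait_id = "exp")
  ou <- mk_table("rs2", 0.1, 0.02, trait_id = "out", trait_role = "outcome")
  expect_error(harmonize(ex, ou), "no shared instruments",
               class = "mrmetab_analysis_error")
})
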