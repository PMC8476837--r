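# In-code fixture builders shared across test files.

mk_table <- function(snp_id, beta, se, pval = NULL,
                     ea = "A", oa = "G", eaf = 0.3,
                     chrom = "1", pos = seq_along(snp_id) * 1e5,
                     trait_id = "trait", trait_role = "exposure") {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  summary_table(data.frame(
    snp_id = snp_id, chrom = rep_len(chrom, length(snp_id)),
    pos = rep_len(pos, length(snp_id)),
    effect_allele = rep_len(ea, length(snp_id)),
    other_allele = rep_len(oa, length(snp_id)),
    eaf = rep_len(eaf, length(snp_id)),
    beta = beta, se = rep_len(se, length(snp_id)),
    pval = pval, n = NA_real_, stringsAsFactors = FALSE),
    trait_id = trait_id, trait_role = trait_role)
}

# Random harmonized set with heterogeneous weights.
rand_hset <- function(J, seed) {
  withr::with_seed(seed, {
    gamma <- runif(J, 0.1, 1) * sample(c(-1, 1), J, replace = TRUE)
    mrmetab:::make_harmonized(
      gamma = gamma,
      sigma_x = runif(J, 0.01, 0.1),
      Gamma = 0.3 * gamma + rnorm(J, 0, 0.05),
      sigma_y = runif(J, 0.02, 0.3))
  })
}

write_tsv_text <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  writeLines(lines, path)
  path
}
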