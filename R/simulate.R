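# Synthetic two-sample GWAS generator with known ground truth. Emulates a
# quantitative-trait exposure sample (per-SD effects) and a large
# case-control outcome sample (log-odds effects) directly on the
# summary-statistic scale, plus block LD panels and multi-exposure studies
# sharing instruments.

#' Configuration for the synthetic two-sample GWAS generator
#'
#' Defaults emulate the study design the package targets at desk scale: a
#' metabolomics exposure GWAS of 7,824 individuals and a heart-failure
#' outcome meta-analysis whose effective sample size is about 180,000
#' (47,309 cases / 930,014 controls). Instrument effects default to
#' `gamma_dist = c(0.5, 0.2)` per-SD units — the strong selected metabolite
#' QTLs such screens retain (per-SNP variance explained roughly 6-10%).
#'
#' @param n_snp Number of SNPs J.
#' @param n_exposure_sample Exposure GWAS sample size n1.
#' @param n_outcome_sample Effective outcome sample size n2 (log-odds scale).
#' @param maf_range Minor-allele frequency range, `0 < low <= high < 0.5`.
#' @param true_beta Causal effect(s) in log-odds per SD; recycled over
#'   exposures.
#' @param gamma_dist `c(mean, sd)` of true SNP-exposure effects at
#'   instrument SNPs.
#' @param pleiotropy Direct-effect regime: `"none"`, `"balanced"` (mean-zero
#'   direct effects; InSIDE holds), `"directional"` (mean
#'   `pleiotropy_mean`; InSIDE holds) or `"inside_violating"` (direct
#'   effects correlated with instrument strength).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the per-SNP direct
#'   effect alpha_j among invalid instruments (log-odds scale).
#' @param invalid_fraction Share of instrument SNPs carrying a direct effect.
#' @param ld_blocks Optional list of `c(size, r)` pairs: consecutive SNPs
#'   grouped into blocks with exchangeable within-block dosage correlation
#'   `r` (panel r² = r²); SNPs beyond the listed blocks are independent.
#' @param n_exposures Number of exposures sharing the SNP panel and outcome.
#' @param n_instruments Instruments per exposure (recycled); `NULL` makes
#'   every SNP an instrument of every exposure.
#' @param shared_snp_rate Probability that an instrument slot of a later
#'   exposure reuses an earlier exposure's instrument.
#' @param seed Master seed; every exposure draws from its own derived
#'   sub-stream, so adding exposures never perturbs existing ones.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snp = 100L, n_exposure_sample = 7824L,
                       n_outcome_sample = 180000L,
                       maf_range = c(0.05, 0.45), true_beta = 0.2,
                       gamma_dist = c(mean = 0.5, sd = 0.2),
                       pleiotropy = c("none", "balanced", "directional",
                                      "inside_violating"),
                       pleiotropy_mean = 0, pleiotropy_sd = 0.05,
                       invalid_fraction = 0.3,
                       ld_blocks = NULL, n_exposures = 1L,
                       n_instruments = NULL, shared_snp_rate = 0,
                       seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] && maf_range[2] < 0.5)) {
    stop_config("maf_range must satisfy 0 < low <= high < 0.5")
  }
  if (invalid_fraction < 0 || invalid_fraction > 1) {
    stop_config("invalid_fraction must lie in [0, 1]")
  }
  if (n_exposure_sample <= 0 || n_outcome_sample <= 0) {
    stop_config("sample sizes must be positive")
  }
  structure(as.list(environment()), class = "sim_config")
}

.NONPALINDROMIC_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                                  "G", "A", "G", "T", "T", "C", "T", "G"),
                                ncol = 2, byrow = TRUE)

# Two-sided normal p-value, kept strictly positive (very strong associations
# would otherwise underflow to 0, an invalid p).
recompute_pval <- function(beta, se) {
  pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
}

# Shared study layout (positions, MAFs, alleles, LD blocks), drawn once per
# seed so exposure sub-streams see the same panel.
sim_layout <- function(config) {
  J <- config$n_snp
  with_seed(derive_seed(config$seed, 0L), {
    maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
    block_id <- integer(J)
    block_r <- numeric(0)
    nxt <- 1L
    if (!is.null(config$ld_blocks)) {
      for (b in config$ld_blocks) {
        size <- b[[1]]
        if (nxt + size - 1L > J) break
        block_id[nxt:(nxt + size - 1L)] <- length(block_r) + 1L
        block_r <- c(block_r, b[[2]])
        nxt <- nxt + size
      }
    }
    singles <- which(block_id == 0L)
    block_id[singles] <- length(block_r) + seq_along(singles)
    n_blocks <- max(block_id)
    chrom <- as.character(1L + (block_id - 1L) %% 22L)
    # Blocks on the same chromosome sit 20 Mb apart (outside any clumping
    # window); SNPs within a block are 10 kb apart.
    within <- stats::ave(seq_len(J), block_id, FUN = seq_along)
    pos <- ((block_id - 1L) %/% 22L) * 2e7 + 1e5 + (within - 1L) * 1e4
    allele_idx <- sample.int(nrow(.NONPALINDROMIC_PAIRS), J, replace = TRUE)
    r2 <- diag(J)
    for (bid in unique(block_id[block_id <= length(block_r)])) {
      members <- which(block_id == bid)
      if (length(members) > 1) {
        r2[members, members] <- block_r[bid]^2
        diag(r2)[members] <- 1
      }
    }
    list(snp_id = sprintf("rs%06d", seq_len(J)), maf = maf, chrom = chrom,
         pos = pos, ea = .NONPALINDROMIC_PAIRS[allele_idx, 1],
         oa = .NONPALINDROMIC_PAIRS[allele_idx, 2],
         r2 = r2)
  })
}

#' Simulate a two-sample GWAS study with known ground truth
#'
#' True instrument effects gamma_j are drawn from `gamma_dist`; direct
#' (pleiotropic) effects alpha_j follow the configured regime; true outcome
#' effects are `Gamma_j = sum_k beta_k gamma_jk + alpha_j`. Observed effects
#' add independent sampling noise with standard errors
#' `sigma_X = 1/sqrt(2 n1 maf (1-maf))` on the exposure side and the
#' analogous `sigma_Y` at the outcome's effective sample size; p-values come
#' from the two-sided normal approximation. The LD panel reflects the block
#' structure exactly.
#'
#' @param config A [sim_config()].
#' @return List with `exposures` (named list of [summary_table()]s),
#'   `outcome` (a [summary_table()]), `panel` (an [ld_panel()]) and `truth`
#'   (per-SNP latent effects, instrument assignments, per-exposure causal
#'   effects, SEs and the config).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_snp
  K <- config$n_exposures
  lay <- sim_layout(config)
  sigma_x <- 1 / sqrt(2 * config$n_exposure_sample * lay$maf * (1 - lay$maf))
  sigma_y <- 1 / sqrt(2 * config$n_outcome_sample * lay$maf * (1 - lay$maf))
  beta_true <- rep_len(config$true_beta, K)
  gmean <- config$gamma_dist[[1]]
  gsd <- config$gamma_dist[[2]]

  gamma_true <- matrix(0, J, K)
  alpha <- matrix(0, J, K)
  instruments <- vector("list", K)
  n_inst <- if (is.null(config$n_instruments)) rep(J, K) else
    rep_len(config$n_instruments, K)
  used <- integer(0)
  exposures <- vector("list", K)
  names(exposures) <- sprintf("EXP%02d", seq_len(K))

  for (k in seq_len(K)) {
    with_seed(derive_seed(config$seed, k), {
      if (is.null(config$n_instruments)) {
        inst <- seq_len(J)
      } else {
        inst <- integer(0)
        pool <- setdiff(seq_len(J), used)
        for (slot in seq_len(min(n_inst[k], J))) {
          reuse <- k > 1 && length(setdiff(used, inst)) > 0 &&
            stats::runif(1) < config$shared_snp_rate
          from <- if (reuse) setdiff(used, inst) else setdiff(pool, inst)
          if (length(from) == 0) from <- setdiff(seq_len(J), inst)
          inst <- c(inst, from[sample.int(length(from), 1)])
        }
      }
      instruments[[k]] <- sort(inst)
      used <- union(used, inst)
      gamma_true[inst, k] <- stats::rnorm(length(inst), gmean, gsd)
      if (config$pleiotropy != "none" && config$invalid_fraction > 0) {
        n_invalid <- round(config$invalid_fraction * length(inst))
        invalid <- inst[sample.int(length(inst), n_invalid)]
        a <- switch(config$pleiotropy,
          balanced = stats::rnorm(n_invalid, 0, config$pleiotropy_sd),
          directional = stats::rnorm(n_invalid, config$pleiotropy_mean,
                                     config$pleiotropy_sd),
          inside_violating = config$pleiotropy_mean +
            0.5 * gamma_true[invalid, k] +
            stats::rnorm(n_invalid, 0, config$pleiotropy_sd))
        alpha[invalid, k] <- a
      }
      gamma_hat <- gamma_true[, k] + stats::rnorm(J) * sigma_x
      exposures[[k]] <- summary_table(data.frame(
        snp_id = lay$snp_id, chrom = lay$chrom, pos = lay$pos,
        effect_allele = lay$ea, other_allele = lay$oa, eaf = lay$maf,
        beta = gamma_hat, se = sigma_x,
        pval = recompute_pval(gamma_hat, sigma_x),
        n = config$n_exposure_sample, stringsAsFactors = FALSE),
        trait_id = names(exposures)[k], trait_role = "exposure")
    })
  }

  Gamma_true <- drop(gamma_true %*% beta_true) + rowSums(alpha)
  outcome <- with_seed(derive_seed(config$seed, 1000000L), {
    Gamma_hat <- Gamma_true + stats::rnorm(J) * sigma_y
    summary_table(data.frame(
      snp_id = lay$snp_id, chrom = lay$chrom, pos = lay$pos,
      effect_allele = lay$ea, other_allele = lay$oa, eaf = lay$maf,
      beta = Gamma_hat, se = sigma_y,
      pval = recompute_pval(Gamma_hat, sigma_y),
      n = config$n_outcome_sample, stringsAsFactors = FALSE),
      trait_id = "OUTCOME", trait_role = "outcome")
  })

  panel <- ld_panel(lay$snp_id, lay$r2, chrom = lay$chrom, pos = lay$pos)
  truth <- list(beta_true = stats::setNames(beta_true, names(exposures)),
                gamma_true = gamma_true, alpha = alpha,
                instruments = stats::setNames(
                  lapply(instruments, function(i) lay$snp_id[i]),
                  names(exposures)),
                maf = lay$maf, sigma_x = sigma_x, sigma_y = sigma_y,
                Gamma_true = Gamma_true, config = config)
  list(exposures = exposures, outcome = outcome, panel = panel, truth = truth)
}

# Convenience: simulate a single harmonized instrument set directly (no
# selection/harmonization stages), for estimator-level simulation studies.
simulate_harmonized <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_exposures == 1L)
  sim <- simulate_two_sample(config)
  ex <- sim$exposures[[1]]
  ou <- sim$outcome
  h <- make_harmonized(ex$beta, ex$se, ou$beta, ou$se, snp_id = ex$snp_id,
                       exposure_id = trait_id(ex), outcome_id = trait_id(ou),
                       chrom = ex$chrom, pos = ex$pos)
  attr(h, "truth") <- sim$truth
  h
}

#' Write a ready-to-run synthetic batch study to disk
#'
#' Generates a complete multi-exposure study bundle in the package's file
#' dialects, with planted features exercising every pipeline stage: one
#' causal exposure (`EXP01`, true log-odds effect 0.2, with one retained
#' palindromic A/T instrument and one outcome-shifted MR-PRESSO outlier
#' instrument), one exposure left with only two instruments (`EXP02`, below
#' the count filter), a SNP instrumenting both `EXP03` and `EXP04` (removed
#' by the cross-exposure restriction), an LD pair of `EXP05` instruments at
#' r² = 0.9 (thinned by clumping), one `EXP06` instrument on the exclusion
#' list, and a subset of outcome rows recorded with swapped alleles
#' (realigned during harmonization). All remaining exposures are null.
#'
#' @param dir Output directory (created; must be writable).
#' @param scale `"small"` (20 exposures x 500 SNPs) or `"medium"`
#'   (40 exposures x 1500 SNPs).
#' @param seed Integer seed; the bundle is reproducible byte-for-byte.
#' @return List with `dir`, the written `paths`, the `planted` feature
#'   record and the generator `truth`, invisibly.
#' @export
make_fixture_study <- function(dir, scale = c("small", "medium"), seed = 1L) {
  scale <- match.arg(scale)
  J <- switch(scale, small = 500L, medium = 1500L)
  K <- switch(scale, small = 20L, medium = 40L)
  n_inst <- c(12L, 2L, rep(10L, K - 2L))
  config <- sim_config(n_snp = J, n_exposures = K, n_instruments = n_inst,
                       true_beta = c(0.2, rep(0, K - 1)),
                       pleiotropy = "none", invalid_fraction = 0,
                       shared_snp_rate = 0, seed = seed)
  sim <- simulate_two_sample(config)
  exposures <- sim$exposures
  outcome <- sim$outcome
  truth <- sim$truth
  inst <- truth$instruments

  # Planted shared instrument: the first EXP03 instrument also instruments
  # EXP04, so the cross-exposure restriction must remove it from both.
  shared_snp <- inst$EXP03[1]
  i <- match(shared_snp, exposures$EXP04$snp_id)
  exposures$EXP04$beta[i] <- 0.3
  exposures$EXP04$pval[i] <- recompute_pval(0.3, exposures$EXP04$se[i])

  # Retained palindromic instrument of EXP01: A/T with clearly minor EAF.
  pal_snp <- inst$EXP01[1]
  for (k in seq_along(exposures)) {
    i <- match(pal_snp, exposures[[k]]$snp_id)
    exposures[[k]]$effect_allele[i] <- "A"
    exposures[[k]]$other_allele[i] <- "T"
    exposures[[k]]$eaf[i] <- 0.15
  }
  i <- match(pal_snp, outcome$snp_id)
  outcome$effect_allele[i] <- "A"
  outcome$other_allele[i] <- "T"
  outcome$eaf[i] <- 0.15

  # MR-PRESSO outlier: one EXP01 instrument's outcome effect shifted by
  # +10 sigma_Y.
  outlier_snp <- inst$EXP01[2]
  i <- match(outlier_snp, outcome$snp_id)
  outcome$beta[i] <- outcome$beta[i] + 10 * outcome$se[i]
  outcome$pval[i] <- recompute_pval(outcome$beta[i], outcome$se[i])

  # LD pair among EXP05 instruments: colocated at r² = 0.9 so clumping keeps
  # only the smaller-p index SNP.
  ld_a <- inst$EXP05[1]
  ld_b <- inst$EXP05[2]
  ia <- match(ld_a, outcome$snp_id)
  ib <- match(ld_b, outcome$snp_id)
  for (k in seq_along(exposures)) {
    exposures[[k]]$chrom[ib] <- exposures[[k]]$chrom[ia]
    exposures[[k]]$pos[ib] <- exposures[[k]]$pos[ia] + 5e4
  }
  outcome$chrom[ib] <- outcome$chrom[ia]
  outcome$pos[ib] <- outcome$pos[ia] + 5e4

  # Outcome rows recorded with swapped alleles (harmonization must flip
  # them back). Every 25th SNP, skipping the palindromic plant.
  swap_idx <- setdiff(seq(5L, J, by = 25L), match(pal_snp, outcome$snp_id))
  tmp <- outcome$effect_allele[swap_idx]
  outcome$effect_allele[swap_idx] <- outcome$other_allele[swap_idx]
  outcome$other_allele[swap_idx] <- tmp
  outcome$beta[swap_idx] <- -outcome$beta[swap_idx]
  outcome$eaf[swap_idx] <- 1 - outcome$eaf[swap_idx]

  excluded_snp <- inst$EXP06[1]
  exclusion <- c(excluded_snp, "rs9999991", "rs9999992")

  dir.create(file.path(dir, "exposures"), recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (k in names(exposures)) {
    paths[[k]] <- write_summary_stats(exposures[[k]],
                                      file.path(dir, "exposures", paste0(k, ".tsv")))
  }
  paths$outcome <- write_summary_stats(outcome, file.path(dir, "outcome.tsv"))
  ld_tab <- data.frame(SNP_A = ld_a, SNP_B = ld_b, R2 = 0.9)
  paths$ld_panel <- file.path(dir, "ld_panel.tsv")
  utils::write.table(ld_tab, paths$ld_panel, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$exclusion <- file.path(dir, "exclusion.txt")
  writeLines(exclusion, paths$exclusion)
  truth_tab <- data.frame(
    exposure_id = names(exposures),
    true_beta = truth$beta_true,
    n_instruments = vapply(inst, length, 1L),
    instruments = vapply(inst, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(truth_tab, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$config <- file.path(dir, "study.yaml")
  writeLines(c(
    "exposures_dir: exposures",
    "outcome: outcome.tsv",
    "ld_panel: ld_panel.tsv",
    "exclusion: exclusion.txt",
    sprintf("seed: %d", as.integer(seed))
  ), paths$config)
  planted <- list(causal_exposure = "EXP01", true_beta = 0.2,
                  low_iv_exposure = "EXP02",
                  shared_snp = shared_snp, shared_exposures = c("EXP03", "EXP04"),
                  palindromic_snp = pal_snp, outlier_snp = outlier_snp,
                  ld_pair = c(ld_a, ld_b), ld_exposure = "EXP05",
                  excluded_snp = excluded_snp, excluded_exposure = "EXP06")
  invisible(list(dir = dir, paths = paths, planted = planted, truth = truth))
}

#' Load a study bundle written by [make_fixture_study()]
#'
#' @param dir Bundle directory.
#' @return List with `exposures`, `outcome`, `panel`, `exclusion`, ready for
#'   [run_batch()].
#' @export
load_study <- function(dir) {
  expo_files <- sort(list.files(file.path(dir, "exposures"), pattern = "\\.tsv$",
                                full.names = TRUE))
  if (length(expo_files) == 0) stop_input(sprintf("no exposure files under %s", dir))
  ids <- sub("\\.tsv$", "", basename(expo_files))
  exposures <- stats::setNames(
    lapply(seq_along(expo_files), function(i) {
      read_summary_stats(expo_files[i], trait_id = ids[i], trait_role = "exposure")
    }), ids)
  outcome <- read_summary_stats(file.path(dir, "outcome.tsv"),
                                trait_id = "OUTCOME", trait_role = "outcome")
  ld_path <- file.path(dir, "ld_panel.tsv")
  panel <- if (file.exists(ld_path)) read_ld_panel(ld_path, "pairwise") else NULL
  excl_path <- file.path(dir, "exclusion.txt")
  exclusion <- if (file.exists(excl_path)) read_exclusion_list(excl_path) else character()
  list(exposures = exposures, outcome = outcome, panel = panel,
       exclusion = exclusion)
}
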