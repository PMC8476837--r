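# Batch orchestration: instrument selection -> harmonization -> five
# estimators -> sensitivity -> significance tiers and the multi-model
# candidate decision rule, across a whole panel of exposures.

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param m_tests Number of tests (e.g. the number of exposures screened).
#' @return `alpha / m_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_tests = 1L) {
  if (!is_count(m_tests, min = 1)) stop_input("m_tests must be a count >= 1")
  alpha / m_tests
}

#' Multi-model candidate decision rule
#'
#' An exposure is a candidate causal feature when the primary IVW estimate is
#' nominally significant, at least three of the five models (necessarily
#' including IVW) have p < `alpha`, and all five effect estimates share a
#' sign ("similar estimates of causal effects" operationalized as sign
#' consistency).
#'
#' @param results An [mr_all()] table: exactly the five methods, equal
#'   `n_snp`.
#' @param alpha Nominal significance level (default 0.05).
#' @param m_tests Optional number of exposures screened; when given, the
#'   record also flags Bonferroni significance (`p_IVW < alpha / m_tests`).
#' @param min_models Minimum number of significant models (default 3).
#' @return A `decision_record` list: `n_snp`, per-method results,
#'   `bonferroni_significant`, `nominal`, `n_models_significant`,
#'   `directions_consistent`, `candidate`.
#' @export
decide_candidate <- function(results, alpha = 0.05, m_tests = NULL,
                             min_models = 3L) {
  missing_m <- setdiff(.MR_METHODS, results$method)
  if (length(missing_m) > 0) {
    stop_input(sprintf("results must contain all five methods; missing: %s",
                       paste(missing_m, collapse = ", ")))
  }
  results <- results[match(.MR_METHODS, results$method), , drop = FALSE]
  if (length(unique(results$n_snp)) != 1) {
    stop_input("all five methods must use the same instrument count")
  }
  p_ivw <- results$pval[results$method == "IVW"]
  nominal <- p_ivw < alpha
  sig <- results$pval < alpha
  n_sig <- sum(sig)
  ivw_sig <- sig[results$method == "IVW"]
  directions <- all(results$beta > 0) || all(results$beta < 0)
  candidate <- nominal && ivw_sig && n_sig >= min_models && directions
  bonf <- if (is.null(m_tests)) NA else p_ivw < bonferroni_threshold(alpha, m_tests)
  structure(list(
    exposure_id = attr(results, "exposure_id"),
    n_snp = results$n_snp[1],
    results = results,
    p_ivw = p_ivw,
    bonferroni_significant = bonf,
    nominal = nominal,
    n_models_significant = n_sig,
    directions_consistent = directions,
    candidate = candidate
  ), class = "decision_record")
}

#' @export
print.decision_record <- function(x, ...) {
  cat(sprintf("Decision for '%s' (%d SNPs): candidate = %s\n",
              x$exposure_id %||% "?", x$n_snp, x$candidate))
  cat(sprintf("  IVW p = %s; %d/5 models significant; directions consistent = %s\n",
              fmt_sci(x$p_ivw), x$n_models_significant, x$directions_consistent))
  invisible(x)
}

#' Batch analysis configuration
#'
#' Collects every tunable of [run_batch()] with the pipeline defaults:
#' instrument selection at p < 1e-5, clumping at r² = 0.001 within a
#' 10,000 kb window, removal of SNPs instrumenting >= 2 exposures,
#' instrument counts restricted to \[3, 100\], frequency-based palindromic
#' inference at MAF <= 0.42, multiplicative random-effects IVW, 1000
#' bootstrap/simulation replicates, and nominal alpha 0.05 with Bonferroni
#' over the number of exposures screened.
#'
#' @param p_threshold Instrument selection p-value threshold.
#' @param r2_cutoff,window_kb LD clumping parameters.
#' @param cross_exposure_min Minimum exposures sharing a SNP for removal.
#' @param min_iv,max_iv Inclusive instrument-count bounds per exposure.
#' @param palindromic_policy,maf_infer_threshold See [harmonize()].
#' @param alpha Nominal significance level.
#' @param bonferroni_m Tests for the Bonferroni tier; `NULL` means the
#'   number of exposures supplied to [run_batch()].
#' @param variance_model IVW variance model.
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param bandwidth_factor Mode-estimator bandwidth multiplier.
#' @param presso_n_sim,presso_alpha MR-PRESSO settings.
#' @param intercept_magnitude_cut Egger-intercept closeness cut.
#' @param seed Master seed; per-exposure sub-seeds are derived from it so
#'   results do not depend on panel ordering.
#' @return A `batch_config` list.
#' @export
batch_config <- function(p_threshold = 1e-5, r2_cutoff = 0.001, window_kb = 10000,
                         cross_exposure_min = 2L, min_iv = 3L, max_iv = 100L,
                         palindromic_policy = "infer", maf_infer_threshold = 0.42,
                         alpha = 0.05, bonferroni_m = NULL,
                         variance_model = "multiplicative_random",
                         n_boot = 1000L, bandwidth_factor = 1,
                         presso_n_sim = 1000L, presso_alpha = 0.05,
                         intercept_magnitude_cut = 0.1, seed = 1L) {
  structure(as.list(environment()), class = "batch_config")
}

#' Run the full batch MR analysis over a panel of exposures
#'
#' For every exposure: select instruments (p-value screen, LD clumping),
#' apply the cross-exposure restriction over the whole panel, remove
#' exclusion-listed SNPs, drop exposures outside the instrument-count bounds,
#' harmonize against the outcome, run the five estimators and the
#' sensitivity layers, and apply the candidate decision rule. Individual
#' exposure failures are recorded in the skip table and never abort the
#' batch. Given identical inputs and seed the output is reproducible
#' bit-for-bit.
#'
#' @param exposures Named list of exposure [summary_table()]s.
#' @param outcome The outcome [summary_table()].
#' @param panel An [ld_panel()], or `NULL` to treat all SNPs as independent.
#' @param exclusion Character vector of snp_ids to exclude.
#' @param config A [batch_config()].
#' @return An `mr_batch` list: `results` (one row per analyzed exposure,
#'   sorted by IVW p ascending), `models` (per-method detail rows for the
#'   nominally significant exposures), `sensitivity` (per-exposure
#'   diagnostics), `decisions` and `sensitivity_reports` (full objects),
#'   `skipped`, `traces` and `config`.
#' @export
run_batch <- function(exposures, outcome, panel = NULL, exclusion = character(),
                      config = batch_config()) {
  if (length(exposures) == 0) stop_input("at least one exposure is required")
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    names(exposures) <- vapply(exposures, function(e) trait_id(e) %||% "exposure",
                               "")
  }
  m_tests <- config$bonferroni_m %||% length(exposures)
  skipped <- list()
  note_skip <- function(id, stage, reason) {
    skipped[[length(skipped) + 1]] <<- data.frame(
      exposure_id = id, stage = stage, reason = reason, stringsAsFactors = FALSE)
  }

  # Stage 1-2: per-exposure p-value screen and LD clumping.
  sets <- list()
  for (id in names(exposures)) {
    sets[[id]] <- tryCatch({
      cand <- select_by_pvalue(exposures[[id]], config$p_threshold)
      ld_clump(cand, exposures[[id]], panel,
               r2_cutoff = config$r2_cutoff, window_kb = config$window_kb)
    }, error = function(e) {
      note_skip(id, "instrument_selection", conditionMessage(e))
      NULL
    })
  }
  sets <- Filter(Negate(is.null), sets)

  # Stage 3: cross-exposure restriction over the whole panel.
  sets <- restrict_cross_exposure(sets, exposures,
                                  association_threshold = config$p_threshold,
                                  min_share = config$cross_exposure_min)
  # Stage 4: exclusion list.
  sets <- lapply(sets, apply_exclusion_list, exclusion = exclusion)
  # Stage 5: instrument-count filter.
  sets <- filter_iv_count(sets, min_iv = config$min_iv, max_iv = config$max_iv)
  for (i in seq_len(nrow(attr(sets, "removed")))) {
    rem <- attr(sets, "removed")[i, ]
    note_skip(rem$exposure_id, "iv_count_filter",
              sprintf("%s (%d instruments)", rem$reason, rem$n_iv))
  }

  decisions <- list()
  sens_reports <- list()
  traces <- list()
  for (id in names(sets)) {
    traces[[id]] <- filter_trace(sets[[id]])
    res <- tryCatch({
      expo <- exposures[[id]]
      expo_sub <- expo[expo$snp_id %in% sets[[id]]$snp_ids, , drop = FALSE]
      attributes(expo_sub)[c("trait_id", "trait_role", "class")] <-
        attributes(expo)[c("trait_id", "trait_role", "class")]
      h <- harmonize(expo_sub, outcome,
                     palindromic_policy = config$palindromic_policy,
                     maf_infer_threshold = config$maf_infer_threshold)
      if (nrow(h) < config$min_iv) {
        stop_analysis(sprintf("fewer than %d instruments after harmonization (%d)",
                              config$min_iv, nrow(h)))
      }
      exposure_seed <- derive_seed(config$seed, match(id, names(exposures)))
      fits <- mr_all(h, variance_model = config$variance_model,
                     n_boot = config$n_boot,
                     bandwidth_factor = config$bandwidth_factor,
                     seed = exposure_seed)
      attr(fits, "exposure_id") <- id
      sens <- sensitivity_report(
        h, intercept_magnitude_cut = config$intercept_magnitude_cut,
        presso_n_sim = config$presso_n_sim, presso_alpha = config$presso_alpha,
        seed = derive_seed(exposure_seed, 99L),
        variance_model = config$variance_model)
      list(decision = decide_candidate(fits, alpha = config$alpha,
                                       m_tests = m_tests),
           sens = sens)
    }, error = function(e) {
      note_skip(id, "analysis", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      decisions[[id]] <- res$decision
      sens_reports[[id]] <- res$sens
    }
  }

  results <- do.call(rbind, lapply(names(decisions), function(id) {
    d <- decisions[[id]]
    s <- sens_reports[[id]]
    ivw <- d$results[d$results$method == "IVW", ]
    data.frame(
      exposure_id = id, n_snp = d$n_snp,
      beta = ivw$beta, se = ivw$se, pval = ivw$pval,
      or_ = ivw$or_, ci_low = ivw$ci_low, ci_high = ivw$ci_high,
      bonferroni_significant = d$bonferroni_significant,
      nominal = d$nominal,
      n_models_significant = d$n_models_significant,
      directions_consistent = d$directions_consistent,
      candidate = d$candidate,
      q_ivw_p = s$q_ivw$p, q_egger_p = s$q_egger$p,
      egger_intercept = s$egger_intercept$intercept,
      egger_intercept_p = s$egger_intercept$p,
      presso_global_p = if (is.null(s$presso)) NA_real_ else s$presso$global_p,
      n_presso_outliers = if (is.null(s$presso)) NA_integer_ else length(s$presso$outliers),
      heterogeneity_ok = s$heterogeneity_ok,
      pleiotropy_ok = s$pleiotropy_ok,
      loo_stable = s$loo_stable,
      stringsAsFactors = FALSE)
  }))
  if (!is.null(results)) {
    results <- results[order(results$pval, results$exposure_id), , drop = FALSE]
    rownames(results) <- NULL
  } else {
    results <- data.frame()
  }

  models <- do.call(rbind, lapply(names(decisions), function(id) {
    d <- decisions[[id]]
    if (!d$nominal) return(NULL)
    s <- sens_reports[[id]]
    r <- d$results
    data.frame(exposure_id = id, method = r$method, n_snp = r$n_snp,
               beta = r$beta, se = r$se, pval = r$pval, or_ = r$or_,
               ci_low = r$ci_low, ci_high = r$ci_high,
               p_heterogeneity = ifelse(r$method == "MR-Egger", s$q_egger$p,
                                        ifelse(r$method == "IVW", s$q_ivw$p, NA_real_)),
               p_pleiotropy = ifelse(r$method == "MR-Egger",
                                     s$egger_intercept$p, NA_real_),
               stringsAsFactors = FALSE)
  }))
  models <- models %||% data.frame()

  skipped <- if (length(skipped) > 0) do.call(rbind, skipped) else
    data.frame(exposure_id = character(), stage = character(),
               reason = character(), stringsAsFactors = FALSE)

  sens_tab <- do.call(rbind, lapply(names(sens_reports), function(id) {
    s <- sens_reports[[id]]
    data.frame(exposure_id = id,
               q_ivw = s$q_ivw$Q, q_ivw_df = s$q_ivw$df, q_ivw_p = s$q_ivw$p,
               q_egger = s$q_egger$Q, q_egger_df = s$q_egger$df,
               q_egger_p = s$q_egger$p,
               egger_intercept = s$egger_intercept$intercept,
               egger_intercept_se = s$egger_intercept$se,
               egger_intercept_p = s$egger_intercept$p,
               presso_global_p = if (is.null(s$presso)) NA_real_ else s$presso$global_p,
               presso_outliers = if (is.null(s$presso)) "" else
                 paste(s$presso$outliers, collapse = ","),
               presso_distortion_p = if (is.null(s$presso)) NA_real_ else
                 s$presso$distortion_p,
               heterogeneity_ok = s$heterogeneity_ok,
               pleiotropy_ok = s$pleiotropy_ok,
               loo_stable = s$loo_stable,
               sensitive_snps = paste(attr(s$loo, "sensitive_snps"), collapse = ","),
               stringsAsFactors = FALSE)
  })) %||% data.frame()

  structure(list(results = results, models = models, sensitivity = sens_tab,
                 decisions = decisions, sensitivity_reports = sens_reports,
                 skipped = skipped, traces = traces, config = config,
                 m_tests = m_tests),
            class = "mr_batch")
}

#' @export
print.mr_batch <- function(x, ...) {
  cat(sprintf("Batch MR analysis: %d exposure(s) analyzed, %d skipped\n",
              nrow(x$results), length(unique(x$skipped$exposure_id))))
  if (nrow(x$results) > 0) {
    cat(sprintf("  nominal (p < %g): %d; candidates: %d; Bonferroni threshold %s\n",
                x$config$alpha, sum(x$results$nominal), sum(x$results$candidate),
                fmt_sci(bonferroni_threshold(x$config$alpha, x$m_tests))))
    top <- utils::head(x$results[, c("exposure_id", "n_snp", "beta", "pval", "candidate")], 5)
    print(top)
  }
  invisible(x)
}

format_results_table <- function(results) {
  data.frame(
    Metabolite = results$exposure_id,
    nSNP = results$n_snp,
    Beta = fmt_num(results$beta),
    SE = fmt_num(results$se),
    P = fmt_sci(results$pval),
    `OR (95%CI)` = sprintf("%s (%s-%s)", fmt_num(results$or_),
                           fmt_num(results$ci_low), fmt_num(results$ci_high)),
    check.names = FALSE, stringsAsFactors = FALSE)
}

format_models_table <- function(models) {
  data.frame(
    Metabolite = models$exposure_id,
    Method = models$method,
    nSNP = models$n_snp,
    P = fmt_sci(models$pval),
    `OR (95%CI)` = sprintf("%s (%s-%s)", fmt_num(models$or_),
                           fmt_num(models$ci_low), fmt_num(models$ci_high)),
    P_Heterogeneity = ifelse(is.na(models$p_heterogeneity), "",
                             fmt_num(models$p_heterogeneity)),
    P_HorizontalPleiotropy = ifelse(is.na(models$p_pleiotropy), "",
                                    fmt_num(models$p_pleiotropy)),
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write batch results to tab-separated files
#'
#' Emits `results.tsv` (one IVW row per exposure, sorted by p),
#' `candidates.tsv` (per-method detail for nominally significant exposures),
#' `sensitivity.tsv`, `skipped.tsv` and `run_log.txt` under `dir`.
#'
#' @param batch An `mr_batch` from [run_batch()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_batch_results <- function(batch, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    tsv(format_results_table(batch$results), "results.tsv"),
    tsv(format_models_table(batch$models), "candidates.tsv"),
    tsv(batch$sensitivity, "sensitivity.tsv"),
    tsv(batch$skipped, "skipped.tsv")
  )
  log_path <- file.path(dir, "run_log.txt")
  lines <- c(
    sprintf("exposures analyzed: %d", nrow(batch$results)),
    sprintf("nominal: %d, candidates: %d", sum(batch$results$nominal),
            sum(batch$results$candidate)),
    sprintf("bonferroni threshold: %s",
            fmt_sci(bonferroni_threshold(batch$config$alpha, batch$m_tests))),
    sprintf("seed: %s", batch$config$seed),
    "filter traces:",
    vapply(names(batch$traces), function(id) {
      tr <- batch$traces[[id]]
      sprintf("  %s: %s", id,
              paste(sprintf("%s=%s", names(tr), tr), collapse = " "))
    }, "")
  )
  writeLines(lines, log_path)
  invisible(c(paths, log_path))
}
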