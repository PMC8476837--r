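# Sensitivity layers: Cochran's Q heterogeneity tests, the Egger-intercept
# horizontal-pleiotropy test, the MR-PRESSO global/outlier/distortion tests,
# and leave-one-out stability.

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_j w_j (\theta_j - \hat\theta_j)^2} with
#' \eqn{w_j = \gamma_j^2/\sigma_{Yj}^2}. Under the IVW model the fitted value
#' is the common IVW estimate (df = J - 1); under the Egger model the fitted
#' values come from the free-intercept regression on oriented data
#' (df = J - 2). The p-value is the upper chi-squared tail; `p > 0.05` is
#' read as no evidence of heterogeneity.
#'
#' @param h A `harmonized_set`.
#' @param model `"ivw"` (J >= 2) or `"egger"` (J >= 3).
#' @return List with `Q`, `df`, `p`.
#' @export
cochran_q <- function(h, model = c("ivw", "egger")) {
  model <- match.arg(model)
  J <- nrow(h)
  if (model == "ivw") {
    if (J < 2) stop_analysis("Cochran's Q (IVW) requires at least 2 instruments")
    r <- ratio_estimates(h)
    beta <- sum(r$weight * r$theta) / sum(r$weight)
    Q <- sum(r$weight * (r$theta - beta)^2)
    df <- J - 1L
  } else {
    fit <- egger_fit(h)  # errors below 3 instruments
    Q <- fit$Q
    df <- fit$df
  }
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Egger-intercept test for directional pleiotropy
#'
#' The MR-Egger intercept estimates the average direct (pleiotropic) effect
#' of the instruments on the outcome. No evidence of horizontal pleiotropy is
#' declared when the intercept is close to zero
#' (strictly `|intercept| < intercept_magnitude_cut`) *and* its p-value
#' exceeds 0.05.
#'
#' @param h A `harmonized_set`, J >= 3.
#' @param intercept_magnitude_cut Closeness-to-zero cut (default 0.1).
#' @return List with `intercept`, `se`, `p`, `pleiotropy_ok`.
#' @export
egger_intercept_test <- function(h, intercept_magnitude_cut = 0.1) {
  fit <- egger_fit(h)
  list(intercept = fit$intercept, se = fit$se_intercept, p = fit$p_intercept,
       pleiotropy_ok = abs(fit$intercept) < intercept_magnitude_cut &&
         fit$p_intercept > 0.05)
}

# IVW slope (weighted zero-intercept regression of Gamma on gamma).
ivw_slope <- function(g, G, w) sum(w * g * G) / sum(w * g^2)

#' MR-PRESSO pleiotropy residual sum of squares and outlier test
#'
#' Three stages. (1) Global test: the observed residual sum of squares
#' \eqn{RSS = \sum_j w_j (\Gamma_j - \hat\theta_{-j}\gamma_j)^2}, where
#' \eqn{\hat\theta_{-j}} is the leave-one-out IVW slope and
#' \eqn{w_j = 1/\sigma_{Yj}^2}, is compared against `n_sim` simulated
#' datasets drawn under the no-pleiotropy model
#' (\eqn{\Gamma^*_j \sim N(\hat\theta_{-j}\gamma_j, \sigma_{Yj}^2)},
#' \eqn{\gamma^*_j \sim N(\gamma_j, \sigma_{Xj}^2)}); the global p-value is
#' the empirical upper-tail probability with the (1+k)/(1+n) correction, so
#' it can never be exactly zero. (2) Outlier test: each SNP's observed
#' squared residual is compared with its own simulated distribution;
#' per-SNP p-values are Bonferroni-adjusted by J and SNPs with adjusted
#' p < `outlier_alpha` are flagged. (3) Distortion test: the change in the
#' IVW estimate after removing the flagged outliers is compared with the
#' spread of changes from `n_distortion` random same-size removals.
#'
#' @param h A `harmonized_set`, J >= 4.
#' @param n_sim Simulated datasets for the global/outlier tests
#'   (default 1000, minimum 100).
#' @param outlier_alpha Significance level on the Bonferroni-adjusted
#'   per-SNP p-values (default 0.05).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @param n_distortion Random removals for the distortion test (default 1000).
#' @return List with `global_rss`, `global_p`, `outlier_p` (adjusted, named
#'   by snp_id), `outliers`, `distortion_p` (`NA` when no outliers),
#'   `beta_all`, `beta_no_outliers`.
#' @export
mr_presso <- function(h, n_sim = 1000L, outlier_alpha = 0.05, seed = NULL,
                      n_distortion = 1000L) {
  J <- nrow(h)
  if (J < 4) stop_analysis("MR-PRESSO requires at least 4 instruments")
  if (!is_count(n_sim, min = 100)) stop_input("n_sim must be a count >= 100")
  g <- h$gamma
  G <- h$Gamma
  w <- 1 / h$sigma_y^2
  S1 <- sum(w * g * G)
  S2 <- sum(w * g^2)
  theta_loo <- (S1 - w * g * G) / (S2 - w * g^2)
  res_obs <- w * (G - theta_loo * g)^2
  rss_obs <- sum(res_obs)

  with_seed(seed, {
    gam_star <- matrix(stats::rnorm(n_sim * J, mean = rep(g, each = n_sim),
                                    sd = rep(h$sigma_x, each = n_sim)),
                       nrow = n_sim, ncol = J)
    Gam_star <- matrix(stats::rnorm(n_sim * J, mean = rep(theta_loo * g, each = n_sim),
                                    sd = rep(h$sigma_y, each = n_sim)),
                       nrow = n_sim, ncol = J)
    W <- matrix(w, n_sim, J, byrow = TRUE)
    S1s <- rowSums(W * gam_star * Gam_star)
    S2s <- rowSums(W * gam_star^2)
    theta_star <- (S1s - W * gam_star * Gam_star) / (S2s - W * gam_star^2)
    res_star <- W * (Gam_star - theta_star * gam_star)^2
    rss_star <- rowSums(res_star)
    global_p <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
    exceed <- res_star >= matrix(res_obs, n_sim, J, byrow = TRUE)
    p_raw <- (1 + colSums(exceed)) / (n_sim + 1)
    p_adj <- stats::setNames(pmin(1, p_raw * J), h$snp_id)
    outliers <- h$snp_id[p_adj < outlier_alpha]

    beta_all <- ivw_slope(g, G, w)
    beta_no <- NA_real_
    distortion_p <- NA_real_
    n_out <- length(outliers)
    if (n_out > 0 && J - n_out >= 2) {
      keep <- !(h$snp_id %in% outliers)
      beta_no <- ivw_slope(g[keep], G[keep], w[keep])
      d_obs <- beta_no - beta_all
      d_rand <- vapply(seq_len(n_distortion), function(b) {
        drop_idx <- sample.int(J, n_out)
        ivw_slope(g[-drop_idx], G[-drop_idx], w[-drop_idx]) - beta_all
      }, 1.0)
      distortion_p <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (n_distortion + 1)
    }
    structure(list(global_rss = rss_obs, global_p = global_p,
                   outlier_p = p_adj, outliers = outliers,
                   distortion_p = distortion_p,
                   beta_all = beta_all, beta_no_outliers = beta_no,
                   n_sim = n_sim),
              class = "mr_presso")
  })
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.3f, global p = %.4g\n",
              x$global_rss, x$global_p))
  if (length(x$outliers) > 0) {
    cat(sprintf("  outliers: %s (distortion p = %.4g)\n",
                paste(x$outliers, collapse = ", "), x$distortion_p))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}

#' Leave-one-out analysis
#'
#' Recomputes the IVW estimate with each instrument removed in turn. A row's
#' confidence interval `beta +/- 1.96 se` either excludes zero or not;
#' the result is called stable when every leave-one-out interval excludes
#' zero (no single SNP carries the signal).
#'
#' @param h A `harmonized_set`, J >= 3.
#' @param variance_model IVW variance model, kept consistent with the main
#'   analysis (default multiplicative random effects).
#' @return data.frame with one row per left-out SNP (`snp_id, beta, se,
#'   pval, ci_low, ci_high, ci_excludes_zero`); attributes `loo_stable`
#'   (logical) and `sensitive_snps` (snp_ids whose removal makes the interval
#'   cross zero).
#' @export
leave_one_out <- function(h, variance_model = "multiplicative_random") {
  J <- nrow(h)
  if (J < 3) stop_analysis("leave-one-out requires at least 3 instruments")
  rows <- lapply(seq_len(J), function(j) {
    fit <- mr_ivw(h[-j, , drop = FALSE], variance_model = variance_model)
    data.frame(snp_id = h$snp_id[j], beta = fit$beta, se = fit$se,
               pval = fit$pval,
               ci_low = fit$beta - 1.96 * fit$se,
               ci_high = fit$beta + 1.96 * fit$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ci_excludes_zero <- out$ci_low > 0 | out$ci_high < 0
  attr(out, "loo_stable") <- all(out$ci_excludes_zero)
  attr(out, "sensitive_snps") <- out$snp_id[!out$ci_excludes_zero]
  out
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles the Q heterogeneity tests (IVW and Egger), the Egger-intercept
#' pleiotropy test, MR-PRESSO (when J >= 4) and leave-one-out, plus the three
#' verdict flags: `heterogeneity_ok` (both Q p-values > 0.05),
#' `pleiotropy_ok` (Egger-intercept rule) and `loo_stable`.
#'
#' @param h A `harmonized_set`, J >= 3.
#' @param intercept_magnitude_cut Passed to [egger_intercept_test()].
#' @param presso_n_sim,presso_alpha,seed Passed to [mr_presso()].
#' @param variance_model Passed to [leave_one_out()].
#' @return A `sensitivity_report` list.
#' @export
sensitivity_report <- function(h, intercept_magnitude_cut = 0.1,
                               presso_n_sim = 1000L, presso_alpha = 0.05,
                               seed = NULL,
                               variance_model = "multiplicative_random") {
  q_ivw <- cochran_q(h, "ivw")
  q_egger <- cochran_q(h, "egger")
  eg <- egger_intercept_test(h, intercept_magnitude_cut)
  presso <- if (nrow(h) >= 4) {
    mr_presso(h, n_sim = presso_n_sim, outlier_alpha = presso_alpha, seed = seed)
  } else NULL
  loo <- leave_one_out(h, variance_model = variance_model)
  structure(list(
    exposure_id = attr(h, "exposure_id"),
    q_ivw = q_ivw, q_egger = q_egger,
    egger_intercept = eg,
    presso = presso,
    loo = loo,
    heterogeneity_ok = q_ivw$p > 0.05 && q_egger$p > 0.05,
    pleiotropy_ok = eg$pleiotropy_ok,
    loo_stable = attr(loo, "loo_stable")
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity report for '%s':\n", x$exposure_id %||% "?"))
  cat(sprintf("  Q (IVW):   %.3f on %d df, p = %.3g\n", x$q_ivw$Q, x$q_ivw$df, x$q_ivw$p))
  cat(sprintf("  Q (Egger): %.3f on %d df, p = %.3g\n", x$q_egger$Q, x$q_egger$df, x$q_egger$p))
  cat(sprintf("  Egger intercept: %.4f (p = %.3g) -> pleiotropy_ok = %s\n",
              x$egger_intercept$intercept, x$egger_intercept$p, x$pleiotropy_ok))
  if (!is.null(x$presso)) {
    cat(sprintf("  MR-PRESSO global p = %.3g, %d outlier(s)\n",
                x$presso$global_p, length(x$presso$outliers)))
  }
  cat(sprintf("  leave-one-out stable = %s\n", x$loo_stable))
  invisible(x)
}

#' Per-SNP data for scatter, forest and funnel displays
#'
#' Exports everything needed to redraw the standard MR panels for one pair:
#' per-SNP effects with standard errors and Wald ratios (scatter and funnel),
#' the fitted line of each of the five models (zero-intercept for all but
#' MR-Egger), and the leave-one-out forest rows.
#'
#' @param h A `harmonized_set`.
#' @param results Optional precomputed [mr_all()] table (recomputed when
#'   `NULL`; bootstrap SEs then use `seed`).
#' @param seed Seed used when recomputing `results`.
#' @return List of data.frames: `scatter` (snp_id, gamma, sigma_x, Gamma,
#'   sigma_y), `lines` (method, intercept, slope), `forest` (leave-one-out
#'   rows) and `funnel` (snp_id, theta, se, precision).
#' @export
mr_plot_data <- function(h, results = NULL, seed = NULL) {
  if (is.null(results)) results <- mr_all(h, seed = seed)
  extras <- attr(results, "extras")
  lines <- data.frame(
    method = results$method,
    intercept = vapply(results$method, function(m) {
      if (m == "MR-Egger") extras[["MR-Egger"]]$intercept else 0
    }, 1.0),
    slope = results$beta,
    stringsAsFactors = FALSE
  )
  r <- ratio_estimates(h)
  list(
    scatter = data.frame(snp_id = h$snp_id, gamma = h$gamma, sigma_x = h$sigma_x,
                         Gamma = h$Gamma, sigma_y = h$sigma_y,
                         stringsAsFactors = FALSE),
    lines = lines,
    forest = leave_one_out(h),
    funnel = data.frame(snp_id = r$snp_id, theta = r$theta, se = r$se,
                        precision = 1 / r$se, stringsAsFactors = FALSE)
  )
}

#' Minimal scatter plot of SNP effects with fitted model lines
#'
#' Base-graphics helper over [mr_plot_data()]: SNP-outcome against
#' SNP-exposure effects (oriented so gamma >= 0) with one fitted line per
#' model.
#'
#' @param h A `harmonized_set`.
#' @param results Optional precomputed [mr_all()] table.
#' @param ... Passed to [plot()].
#' @return The [mr_plot_data()] list, invisibly.
#' @export
plot_mr_scatter <- function(h, results = NULL, ...) {
  pd <- mr_plot_data(h, results)
  sgn <- ifelse(pd$scatter$gamma < 0, -1, 1)
  x <- pd$scatter$gamma * sgn
  y <- pd$scatter$Gamma * sgn
  plot(x, y, pch = 19, xlab = "SNP effect on exposure (per SD)",
       ylab = "SNP effect on outcome (log odds)", ...)
  graphics::segments(x, y - 1.96 * pd$scatter$sigma_y, x, y + 1.96 * pd$scatter$sigma_y,
                     col = "grey60")
  for (i in seq_len(nrow(pd$lines))) {
    graphics::abline(pd$lines$intercept[i], pd$lines$slope[i], col = i + 1, lty = i)
  }
  graphics::legend("topleft", legend = pd$lines$method, col = seq_len(nrow(pd$lines)) + 1,
                   lty = seq_len(nrow(pd$lines)), cex = 0.8, bty = "n")
  invisible(pd)
}
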