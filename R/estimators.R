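# The five two-sample MR causal estimators: inverse-variance weighted,
# MR-Egger regression, weighted median, and the simple/weighted mode-based
# estimators. All operate on a harmonized_set of per-SNP effects
# (gamma_j, sigma_Xj) on the exposure and (Gamma_j, sigma_Yj) on the outcome.

.MR_METHODS <- c("IVW", "MR-Egger", "WeightedMedian", "SimpleMode", "WeightedMode")

mr_result <- function(method, n_snp, beta, se, pval, extra = list()) {
  out <- data.frame(method = method, n_snp = as.integer(n_snp),
                    beta = beta, se = se, pval = pval,
                    or_ = exp(beta),
                    ci_low = exp(beta - 1.96 * se),
                    ci_high = exp(beta + 1.96 * se),
                    stringsAsFactors = FALSE)
  attr(out, "extra") <- extra
  class(out) <- c("mr_result", "data.frame")
  out
}

#' Per-SNP Wald ratio estimates
#'
#' The ratio estimate for SNP j is \eqn{\theta_j = \Gamma_j / \gamma_j} with
#' first-order standard error \eqn{\sigma_{Yj} / |\gamma_j|} and
#' inverse-variance weight \eqn{\gamma_j^2 / \sigma_{Yj}^2}.
#'
#' @param gamma,sigma_x SNP-exposure effects and standard errors
#'   (`sigma_x` is carried for downstream use; the first-order ratio SE does
#'   not involve it).
#' @param Gamma,sigma_y SNP-outcome effects and standard errors.
#' @return data.frame with columns `theta`, `se`, `weight` (vectorized).
#' @export
wald_ratio <- function(gamma, sigma_x, Gamma, sigma_y) {
  if (any(gamma == 0)) stop_input("wald_ratio undefined for gamma = 0")
  if (any(sigma_y <= 0)) stop_input("sigma_y must be > 0")
  data.frame(theta = Gamma / gamma,
             se = sigma_y / abs(gamma),
             weight = gamma^2 / sigma_y^2)
}

ratio_estimates <- function(h) {
  r <- wald_ratio(h$gamma, h$sigma_x, h$Gamma, h$sigma_y)
  r$snp_id <- h$snp_id
  r
}

#' Inverse-variance weighted estimate
#'
#' The primary estimator: the inverse-variance weighted mean of per-SNP Wald
#' ratios, \eqn{\hat\beta = \sum_j w_j \theta_j / \sum_j w_j} with
#' \eqn{w_j = \gamma_j^2/\sigma_{Yj}^2} — equivalently a zero-intercept
#' regression of \eqn{\Gamma_j} on \eqn{\gamma_j} weighted by
#' \eqn{1/\sigma_{Yj}^2}. Under the fixed-effect model the SE is
#' \eqn{(\sum_j w_j)^{-1/2}}; the multiplicative random-effects model
#' (default) inflates it by \eqn{\max(1, \hat\phi)} where
#' \eqn{\hat\phi^2 = Q/(J-1)} is the residual dispersion, so underdispersion
#' is never credited. P-values use the two-sided normal approximation.
#'
#' @param h A `harmonized_set` (see [harmonize()]), J >= 2 SNPs.
#' @param variance_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_result` row; the `"extra"` attribute carries `Q`, `df` and
#'   `phi2`.
#' @export
mr_ivw <- function(h, variance_model = c("multiplicative_random", "fixed")) {
  variance_model <- match.arg(variance_model)
  J <- nrow(h)
  if (J < 2) stop_analysis("IVW requires at least 2 instruments")
  r <- ratio_estimates(h)
  w <- r$weight
  beta <- sum(w * r$theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  Q <- sum(w * (r$theta - beta)^2)
  phi2 <- Q / (J - 1)
  se <- if (variance_model == "multiplicative_random") {
    se_fixed * max(1, sqrt(phi2))
  } else {
    se_fixed
  }
  pval <- 2 * stats::pnorm(-abs(beta / se))
  mr_result("IVW", J, beta, se, pval,
            extra = list(Q = Q, df = J - 1L, phi2 = phi2,
                         variance_model = variance_model))
}

# Weighted linear regression of Gamma on gamma with a free intercept, on
# orientation-standardized data (gamma_j >= 0). Shared by mr_egger() and the
# sensitivity diagnostics.
egger_fit <- function(h) {
  J <- nrow(h)
  if (J < 3) stop_analysis("MR-Egger requires at least 3 instruments")
  sgn <- ifelse(h$gamma < 0, -1, 1)
  g <- h$gamma * sgn
  G <- h$Gamma * sgn
  w <- 1 / h$sigma_y^2
  X <- cbind(1, g)
  A <- crossprod(X, X * w)
  b <- crossprod(X, G * w)
  coefs <- unname(drop(solve(A, b)))
  fitted <- drop(X %*% coefs)
  rss <- sum(w * (G - fitted)^2)
  phi2 <- rss / (J - 2)
  cov_fixed <- solve(A)
  se <- unname(sqrt(diag(cov_fixed))) * max(1, sqrt(phi2))
  tval <- coefs / se
  pval <- 2 * stats::pt(-abs(tval), df = J - 2)
  list(intercept = coefs[1], slope = coefs[2],
       se_intercept = se[1], se_slope = se[2],
       p_intercept = pval[1], p_slope = pval[2],
       Q = rss, df = J - 2L, phi2 = phi2)
}

#' MR-Egger regression estimate
#'
#' Weighted linear regression of the SNP-outcome effects on the SNP-exposure
#' effects with a free intercept, after orienting every SNP so that
#' \eqn{\gamma_j \ge 0} (negating \eqn{\gamma_j} and \eqn{\Gamma_j} jointly).
#' The slope estimates the causal effect under the InSIDE assumption; the
#' intercept measures average directional pleiotropy and is returned with its
#' SE and p-value in the `"extra"` attribute. Standard errors are inflated by
#' \eqn{\max(1, \hat\phi)} with \eqn{\hat\phi^2 = Q'/(J-2)}; p-values use the
#' t distribution with J - 2 degrees of freedom.
#'
#' @param h A `harmonized_set`, J >= 3 SNPs.
#' @return An `mr_result` row; `"extra"` carries `intercept`,
#'   `intercept_se`, `intercept_p`, `Q`, `df`, `phi2`.
#' @export
mr_egger <- function(h) {
  fit <- egger_fit(h)
  mr_result("MR-Egger", nrow(h), fit$slope, fit$se_slope, fit$p_slope,
            extra = list(intercept = fit$intercept,
                         intercept_se = fit$se_intercept,
                         intercept_p = fit$p_intercept,
                         Q = fit$Q, df = fit$df, phi2 = fit$phi2))
}

# Point estimate: linear interpolation of the weighted empirical distribution
# of ratio estimates at probability 1/2.
weighted_median_point <- function(theta, weight) {
  o <- order(theta)
  th <- theta[o]
  wn <- weight[o] / sum(weight)
  p <- cumsum(wn) - wn / 2
  if (0.5 <= p[1]) return(th[1])
  n <- length(th)
  if (0.5 >= p[n]) return(th[n])
  i <- findInterval(0.5, p)
  th[i] + (th[i + 1] - th[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

boot_se <- function(point_fun, theta, se_theta, n_boot, seed) {
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      point_fun(stats::rnorm(length(theta), mean = theta, sd = se_theta))
    }, 1.0)
    stats::sd(reps)
  })
}

#' Weighted median estimate
#'
#' The median of the inverse-variance weighted empirical distribution of the
#' per-SNP Wald ratios: ratios are sorted, normalized weights accumulated,
#' and the estimate interpolated at cumulative probability 1/2. Consistent
#' when at least half the weight comes from valid instruments. The SE is the
#' standard deviation of the estimate over `n_boot` parametric-bootstrap
#' replicates (each resamples \eqn{\theta_j \sim N(\theta_j, se_j)} and
#' recomputes the weighted median); the p-value is two-sided normal.
#'
#' @param h A `harmonized_set`, J >= 2 SNPs.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed making the bootstrap reproducible.
#' @return An `mr_result` row.
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed = NULL) {
  J <- nrow(h)
  if (J < 2) stop_analysis("weighted median requires at least 2 instruments")
  r <- ratio_estimates(h)
  beta <- weighted_median_point(r$theta, r$weight)
  se <- boot_se(function(th) weighted_median_point(th, r$weight),
                r$theta, r$se, n_boot, seed)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  mr_result("WeightedMedian", J, beta, se, pval,
            extra = list(n_boot = n_boot))
}

# Modified Silverman bandwidth: robust scale is the smaller of the SD and the
# (consistency-scaled) MAD. Zero when a majority of the ratios coincide
# (MAD = 0); kde_mode() then degenerates to the exact weighted mode.
mode_bandwidth <- function(theta, bandwidth_factor = 1) {
  s <- min(stats::sd(theta), stats::mad(theta))
  if (!is.finite(s) || s <= 0) return(0)
  bandwidth_factor * 1.06 * s * length(theta)^(-1 / 5)
}

# Argmax of the weighted Gaussian-kernel density over theta: 512-point grid
# on [min - 3h, max + 3h], refined locally by stats::optimize (golden-section
# with parabolic interpolation). A multi-modal plateau is broken toward the
# smallest theta with a warning. Bandwidth zero (a majority of exactly tied
# ratios) degenerates to the most heavily weighted tied value.
kde_mode <- function(theta, wn, bandwidth) {
  if (bandwidth <= 0) {
    u <- sort(unique(theta))
    tot <- vapply(u, function(v) sum(wn[theta == v]), 1.0)
    return(u[which.max(tot)])
  }
  dens <- function(x) sum(wn * stats::dnorm((x - theta) / bandwidth))
  grid <- seq(min(theta) - 3 * bandwidth, max(theta) + 3 * bandwidth,
              length.out = 512L)
  f <- as.vector(crossprod(stats::dnorm(outer(theta, grid, "-") / bandwidth), wn))
  top <- which(f >= max(f) * (1 - 1e-12))
  if (length(top) > 1 && any(diff(top) > 1)) {
    warning("multi-modal density plateau; mode taken at the smallest ratio",
            call. = FALSE)
  }
  i <- top[1]
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(512L, i + 1L)]
  stats::optimize(dens, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

mode_estimate <- function(h, weighted, bandwidth_factor, n_boot, seed, method) {
  J <- nrow(h)
  if (J < 3) stop_analysis("mode-based estimators require at least 3 instruments")
  r <- ratio_estimates(h)
  wn <- if (weighted) r$weight / sum(r$weight) else rep(1 / J, J)
  point <- function(th) kde_mode(th, wn, mode_bandwidth(th, bandwidth_factor))
  beta <- point(r$theta)
  se <- boot_se(point, r$theta, r$se, n_boot, seed)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  mr_result(method, J, beta, se, pval,
            extra = list(bandwidth = mode_bandwidth(r$theta, bandwidth_factor),
                         bandwidth_factor = bandwidth_factor, n_boot = n_boot))
}

#' Simple mode-based estimate
#'
#' Clusters the per-SNP Wald ratios by a Gaussian-kernel density with
#' bandwidth \eqn{h = \phi \cdot 1.06 \cdot s \cdot J^{-1/5}}, where `s` is
#' the smaller of the standard deviation and the scaled median absolute
#' deviation of the ratios, and takes the causal estimate at the density
#' argmax — the largest cluster of agreeing SNPs. Consistent under the
#' zero-modal-pleiotropy assumption (the most common pleiotropy value is
#' zero). SE by parametric bootstrap as in [mr_weighted_median()].
#'
#' @param h A `harmonized_set`, J >= 3 SNPs.
#' @param bandwidth_factor Multiplier \eqn{\phi} on the modified Silverman
#'   bandwidth (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @return An `mr_result` row.
#' @export
mr_simple_mode <- function(h, bandwidth_factor = 1, n_boot = 1000L, seed = NULL) {
  mode_estimate(h, weighted = FALSE, bandwidth_factor, n_boot, seed, "SimpleMode")
}

#' Weighted mode-based estimate
#'
#' As [mr_simple_mode()], but each SNP's kernel contribution is scaled by its
#' normalized inverse-variance weight, so precise SNPs dominate cluster
#' membership.
#'
#' @inheritParams mr_simple_mode
#' @return An `mr_result` row.
#' @export
mr_weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000L, seed = NULL) {
  mode_estimate(h, weighted = TRUE, bandwidth_factor, n_boot, seed, "WeightedMode")
}

#' Run all five MR estimators
#'
#' @param h A `harmonized_set` with at least 3 SNPs (the Egger and mode
#'   minimum).
#' @param variance_model IVW variance model (see [mr_ivw()]).
#' @param n_boot,bandwidth_factor,seed Passed to the bootstrap-based
#'   estimators; distinct sub-seeds are derived per method.
#' @return An `mr_result` data.frame with five rows (IVW, MR-Egger,
#'   WeightedMedian, SimpleMode, WeightedMode); the `"extras"` attribute is a
#'   named list of the per-method extra fields.
#' @export
mr_all <- function(h, variance_model = c("multiplicative_random", "fixed"),
                   n_boot = 1000L, bandwidth_factor = 1, seed = NULL) {
  variance_model <- match.arg(variance_model)
  seeds <- if (is.null(seed)) vector("list", 3) else
    lapply(1:3, function(k) derive_seed(seed, k))
  res <- list(
    mr_ivw(h, variance_model),
    mr_egger(h),
    mr_weighted_median(h, n_boot = n_boot, seed = seeds[[1]]),
    mr_simple_mode(h, bandwidth_factor = bandwidth_factor, n_boot = n_boot,
                   seed = seeds[[2]]),
    mr_weighted_mode(h, bandwidth_factor = bandwidth_factor, n_boot = n_boot,
                     seed = seeds[[3]])
  )
  out <- do.call(rbind, lapply(res, as.data.frame))
  rownames(out) <- NULL
  attr(out, "extras") <- stats::setNames(lapply(res, attr, "extra"), out$method)
  class(out) <- c("mr_result", "data.frame")
  out
}
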