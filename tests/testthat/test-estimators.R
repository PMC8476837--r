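# The five causal estimators and their shared invariants.

test_that("Wald ratios follow the first-order formula and its symmetries", {
  r <- wald_ratio(gamma = 0.20, sigma_x = 0.05, Gamma = 0.10, sigma_y = 0.05)
  expect_equal(r$theta, 0.5)
  expect_equal(r$se, 0.25)
  expect_equal(r$weight, 1 / r$se^2)
  expect_equal(wald_ratio(0.2, 0.05, 0, 0.05)$theta, 0)
  expect_equal(wald_ratio(-0.2, 0.05, -0.1, 0.05)$theta, 0.5)
  expect_error(wald_ratio(0, 0.05, 0.1, 0.05), class = "mrmetab_input_error")
})

test_that("IVW reproduces the hand-computed weighted least squares instance", {
  h <- mrmetab:::make_harmonized(gamma = c(1, 1), sigma_x = 0.1,
                                 Gamma = c(1, 3), sigma_y = 1)
  fixed <- mr_ivw(h, "fixed")
  expect_equal(fixed$beta, 2.0)
  expect_equal(fixed$se, 1 / sqrt(2))
  ex <- attr(fixed, "extra")
  expect_equal(ex$Q, 2)
  expect_equal(ex$phi2, 2)
  rand <- mr_ivw(h, "multiplicative_random")
  expect_equal(rand$beta, 2.0)
  expect_equal(rand$se, 1.0)

  # Zero dispersion: both variance models coincide and Q = 0.
  h0 <- mrmetab:::make_harmonized(gamma = c(1, 2, 4), sigma_x = 0.1,
                                  Gamma = c(0.5, 1, 2), sigma_y = 1)
  expect_equal(mr_ivw(h0, "fixed")$se, mr_ivw(h0, "multiplicative_random")$se)
  expect_equal(attr(mr_ivw(h0), "extra")$Q, 0)
  expect_equal(mr_ivw(h0)$beta, 0.5)

  expect_error(mr_ivw(h0[1, ]), class = "mrmetab_analysis_error")
})

test_that("IVW equals the closed-form weighted mean of Wald ratios", {
  for (seed in 1:50) {
    h <- rand_hset(sample(3:40, 1), seed)
    expect_equal(mr_ivw(h)$beta,
                 oracle_ivw(h$gamma, h$Gamma, h$sigma_y),
                 tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers an exact line and its intercept diagnostics", {
  h <- mrmetab:::make_harmonized(gamma = c(1, 2, 3), sigma_x = 0.1,
                                 Gamma = c(0.6, 1.1, 1.6), sigma_y = 0.3)
  fit <- mr_egger(h)
  ex <- attr(fit, "extra")
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(ex$intercept, 0.1, tolerance = 1e-10)
  expect_lt(ex$Q, 1e-20)
  expect_error(mr_egger(h[1:2, ]), class = "mrmetab_analysis_error")
})

test_that("Egger intercept tracks the mean direct effect in simulation", {
  # Balanced pleiotropy (InSIDE holds, mean 0) vs directional (mean 0.05).
  run <- function(regime, mean_a, n_rep = 200) {
    ints <- vapply(seq_len(n_rep), function(r) {
      cfg <- sim_config(n_snp = 50, n_exposure_sample = 8000,
                        n_outcome_sample = 50000,
                        pleiotropy = regime, pleiotropy_mean = mean_a,
                        pleiotropy_sd = 0.05, invalid_fraction = 1,
                        seed = 5000 + r)
      h <- mrmetab:::simulate_harmonized(cfg)
      attr(mr_egger(h), "extra")$intercept
    }, 1.0)
    c(mean = mean(ints), mcse = sd(ints) / sqrt(n_rep))
  }
  bal <- run("balanced", 0)
  expect_lt(abs(bal["mean"]), 3 * bal["mcse"])
  dir <- run("directional", 0.05)
  expect_lt(abs(dir["mean"] - 0.05), 3 * dir["mcse"])
})

test_that("weighted median interpolates the weighted ratio distribution", {
  h <- mrmetab:::make_harmonized(gamma = rep(1, 3), sigma_x = 0.1,
                                 Gamma = c(1, 2, 3), sigma_y = 1)
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 2.0)

  # A single wild ratio cannot drag the estimate beyond its neighbours.
  h4 <- mrmetab:::make_harmonized(gamma = rep(1, 4), sigma_x = 0.1,
                                  Gamma = c(1, 2, 3, 100), sigma_y = 1)
  b4 <- mr_weighted_median(h4, n_boot = 50, seed = 1)$beta
  expect_gte(b4, 2)
  expect_lte(b4, 3)

  # Nearly all weight on one SNP: the estimate is that SNP's ratio.
  h5 <- mrmetab:::make_harmonized(gamma = c(10, 0.001, 0.001), sigma_x = 0.1,
                                  Gamma = c(7, 0.002, 0.003), sigma_y = 1)
  expect_equal(mr_weighted_median(h5, n_boot = 50, seed = 1)$beta, 0.7,
               tolerance = 1e-3)

  # Matches the independent interpolation oracle on random instances.
  for (seed in 1:40) {
    h <- rand_hset(sample(2:30, 1), seed)
    r <- wald_ratio(h$gamma, h$sigma_x, h$Gamma, h$sigma_y)
    expect_equal(mr_weighted_median(h, n_boot = 10, seed = 1)$beta,
                 oracle_weighted_median(r$theta, r$weight), tolerance = 1e-12)
  }
})

test_that("mode estimators find the majority ratio cluster", {
  h <- mrmetab:::make_harmonized(gamma = rep(1, 4), sigma_x = 0.1,
                                 Gamma = c(0.5, 0.5, 0.5, 3.0), sigma_y = 0.5)
  expect_equal(mr_simple_mode(h, n_boot = 50, seed = 1)$beta, 0.5,
               tolerance = 0.05)

  h_eq <- mrmetab:::make_harmonized(gamma = rep(1, 3), sigma_x = 0.1,
                                    Gamma = rep(0.7, 3), sigma_y = 0.5)
  expect_equal(mr_simple_mode(h_eq, n_boot = 10, seed = 1)$beta, 0.7)

  # Equal weights make the weighted and simple modes identical.
  expect_equal(mr_weighted_mode(h, n_boot = 50, seed = 1)$beta,
               mr_simple_mode(h, n_boot = 50, seed = 1)$beta)

  # Dominant weight drags the weighted (not the simple) mode.
  hw <- mrmetab:::make_harmonized(gamma = c(1, 1, 1, 10), sigma_x = 0.1,
                                  Gamma = c(0.5, 0.52, 0.48, 20), sigma_y = 0.5)
  expect_equal(mr_simple_mode(hw, n_boot = 20, seed = 1)$beta, 0.5,
               tolerance = 0.1)
  expect_equal(mr_weighted_mode(hw, n_boot = 20, seed = 1)$beta, 2,
               tolerance = 0.1)
  expect_error(mr_simple_mode(h[1:2, ]), class = "mrmetab_analysis_error")
})

test_that("mode argmax matches a fine-grid density oracle, including scaled bandwidths", {
  for (seed in 1:20) {
    h <- rand_hset(sample(5:25, 1), seed)
    r <- wald_ratio(h$gamma, h$sigma_x, h$Gamma, h$sigma_y)
    for (phi in c(1, 2)) {
      bw <- mrmetab:::mode_bandwidth(r$theta, phi)
      scale <- diff(range(r$theta)) + 6 * bw
      got <- mr_simple_mode(h, bandwidth_factor = phi, n_boot = 5, seed = 1)$beta
      want <- oracle_kde_mode(r$theta, rep(1 / nrow(h), nrow(h)), bw)
      expect_equal(got, want, tolerance = 1e-3 * scale)
      gotw <- mr_weighted_mode(h, bandwidth_factor = phi, n_boot = 5, seed = 1)$beta
      wantw <- oracle_kde_mode(r$theta, r$weight / sum(r$weight), bw)
      expect_equal(gotw, wantw, tolerance = 1e-3 * scale)
    }
  }
})

test_that("estimates are orientation-invariant and scale-equivariant", {
  h <- rand_hset(20, 99)
  fits <- mr_all(h, n_boot = 50, seed = 7)

  # Jointly negating (gamma, Gamma) of arbitrary SNPs changes nothing.
  withr::with_seed(1, sgn <- sample(c(-1, 1), 20, replace = TRUE))
  h_neg <- h
  h_neg$gamma <- h$gamma * sgn
  h_neg$Gamma <- h$Gamma * sgn
  fits_neg <- mr_all(h_neg, n_boot = 50, seed = 7)
  expect_equal(fits_neg$beta, fits$beta, tolerance = 1e-9)
  expect_equal(fits_neg$se, fits$se, tolerance = 1e-6)

  # Multiplying Gamma and sigma_y by c scales every beta and SE by c.
  cc <- 2.5
  h_sc <- h
  h_sc$Gamma <- h$Gamma * cc
  h_sc$sigma_y <- h$sigma_y * cc
  fits_sc <- mr_all(h_sc, n_boot = 50, seed = 7)
  expect_equal(fits_sc$beta, fits$beta * cc, tolerance = 1e-9)
  expect_equal(fits_sc$se, fits$se * cc, tolerance = 1e-6)
})

test_that("bootstrap standard errors are reproducible under a seed", {
  h <- rand_hset(15, 3)
  a <- mr_all(h, n_boot = 200, seed = 42)
  b <- mr_all(h, n_boot = 200, seed = 42)
  expect_identical(a, b)
  c_ <- mr_weighted_median(h, n_boot = 200, seed = 43)
  expect_false(identical(a$se[a$method == "WeightedMedian"], c_$se))
})

test_that("with many valid instruments all five estimators agree", {
  cfg <- sim_config(n_snp = 200, n_exposure_sample = 50000,
                    n_outcome_sample = 200000, true_beta = 0.2,
                    pleiotropy = "none", seed = 31)
  h <- mrmetab:::simulate_harmonized(cfg)
  fits <- mr_all(h, n_boot = 200, seed = 8)
  ivw_se <- fits$se[fits$method == "IVW"]
  expect_lt(max(fits$beta) - min(fits$beta), 2 * max(fits$se))
  expect_equal(fits$beta[fits$method == "IVW"], 0.2, tolerance = 10 * ivw_se)

  # Reporting identities: OR = exp(beta), CI brackets it.
  expect_equal(fits$or_, exp(fits$beta))
  expect_true(all(fits$ci_low < fits$or_ & fits$or_ < fits$ci_high))
})
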