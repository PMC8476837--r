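# Independent brute-force oracles used to check the estimators and the
# clumping routine. Deliberately written as plain loops/grids, sharing no
# code with the package internals.

oracle_weighted_median <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]
  wn <- w[ord] / sum(w)
  p <- numeric(length(th))
  s <- 0
  for (j in seq_along(th)) {
    p[j] <- s + wn[j] / 2
    s <- s + wn[j]
  }
  if (0.5 <= p[1]) return(th[1])
  n <- length(th)
  if (0.5 >= p[n]) return(th[n])
  j <- max(which(p <= 0.5))
  th[j] + (0.5 - p[j]) * (th[j + 1] - th[j]) / (p[j + 1] - p[j])
}

# Fine-grid argmax of the weighted Gaussian kernel density.
oracle_kde_mode <- function(theta, wn, bw, n_grid = 100001L) {
  grid <- seq(min(theta) - 3 * bw, max(theta) + 3 * bw, length.out = n_grid)
  dens <- vapply(grid, function(x) sum(wn * dnorm((x - theta) / bw)), 1.0)
  grid[which.max(dens)]
}

# Greedy clumping re-implemented over an explicit candidate data.frame
# (snp_id, chrom, pos, pval) and a full r2 matrix.
oracle_clump <- function(df, r2mat, cutoff, window_bp) {
  remaining <- df[order(df$pval, df$chrom, df$pos, df$snp_id), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    index <- remaining[1, ]
    kept <- c(kept, index$snp_id)
    drop <- logical(nrow(remaining))
    drop[1] <- TRUE
    for (j in seq_len(nrow(remaining))[-1]) {
      if (remaining$chrom[j] != index$chrom) next
      if (abs(remaining$pos[j] - index$pos) > window_bp) next
      if (r2mat[index$snp_id, remaining$snp_id[j]] > cutoff) drop[j] <- TRUE
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  sort(kept)
}

# Closed-form IVW: weighted mean of Wald ratios.
oracle_ivw <- function(gamma, Gamma, sigma_y) {
  theta <- Gamma / gamma
  w <- gamma^2 / sigma_y^2
  sum(w * theta) / sum(w)
}
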