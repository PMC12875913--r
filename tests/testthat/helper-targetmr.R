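# Fixture builders and independent oracles shared across the suite.

# A minimal valid association table builder.
make_assoc <- function(rsid, chrom = "7", pos = seq_along(rsid) * 1000,
                       ea = "A", oa = "G", eaf = 0.3, beta = -0.02,
                       se = 0.004, pvalue = NULL, n = 1000) {
  if (is.null(pvalue)) pvalue <- pmax(2 * pnorm(-abs(beta / se)),
                                      .Machine$double.xmin)
  data.frame(rsid = rsid, chrom = chrom, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pvalue = pvalue, n = n, stringsAsFactors = FALSE)
}

make_sumstats <- function(...) sumstats(make_assoc(...))

# Harmonized pairs with prescribed Wald ratios theta and SEs: gamma = 1 with
# negligible exposure uncertainty, so theta_j = Gamma_j and se(theta_j) =
# se_Gamma_j exactly.
pairs_from_ratios <- function(theta, se, outcome_type = "continuous") {
  harmonized_set(
    data.frame(rsid = sprintf("rs%03d", seq_along(theta)), gamma = 1,
               se_gamma = 1e-8, Gamma = theta, se_Gamma = se,
               stringsAsFactors = FALSE),
    outcome_type = outcome_type)
}

# Independent greedy-clumping oracle: explicit set bookkeeping, no shared
# code with clump(). Returns retained rsids in retention order.
oracle_clump <- function(df, r2, r2_threshold, window) {
  remaining <- order(df$pvalue, df$pos, df$rsid)
  kept <- character(0)
  while (length(remaining) > 0) {
    idx <- remaining[1]
    kept <- c(kept, df$rsid[idx])
    remaining <- remaining[-1]
    if (length(remaining) > 0) {
      drop <- vapply(remaining, function(j) {
        df$chrom[j] == df$chrom[idx] &&
          abs(df$pos[j] - df$pos[idx]) <= window &&
          r2[df$rsid[idx], df$rsid[j]] > r2_threshold
      }, logical(1))
      remaining <- remaining[!drop]
    }
  }
  kept
}

# Weighted-regression oracle via explicit normal equations on the augmented
# design [1, gamma], weights w; returns coefficients and their unscaled
# covariance.
oracle_wls <- function(gamma, Gamma, w, intercept = TRUE) {
  X <- if (intercept) cbind(1, gamma) else cbind(gamma)
  XtWX <- t(X) %*% (w * X)
  XtWy <- t(X) %*% (w * Gamma)
  coef <- solve(XtWX, XtWy)
  list(coef = drop(coef), cov_unscaled = solve(XtWX),
       rss_w = sum(w * (Gamma - X %*% coef)^2))
}

# Random summary-stats table for property tests.
random_table <- function(n, seed) {
  set.seed(seed)
  make_sumstats(rsid = sprintf("rs%04d", sample.int(9999, n)),
                pos = sort(sample.int(5e6, n)),
                beta = rnorm(n, 0, 0.05), se = runif(n, 0.002, 0.01),
                eaf = runif(n, 0.05, 0.95))
}

# Random LD matrix over given rsids (positive r2 via squared correlations of
# random Gaussian data).
random_ld <- function(rsids, seed) {
  set.seed(seed)
  x <- matrix(rnorm(length(rsids) * 25), nrow = length(rsids))
  r2 <- cor(t(x))^2
  diag(r2) <- 1
  ld_matrix(r2, rsids)
}
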