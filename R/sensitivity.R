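#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (theta_j - theta_IVW-FE)^2` over the per-instrument Wald
#' ratios with `w_j = 1 / se(theta_j)^2`; under homogeneity Q follows a
#' chi-square distribution with `J - 1` degrees of freedom. Q also drives
#' the multiplicative dispersion factor of the random-effects IVW SE.
#'
#' @param pairs A `harmonized_set` with at least 2 instruments.
#' @return A `heterogeneity_result` list: `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(pairs) {
  pairs <- check_pairs(pairs, 2L, "Cochran's Q")
  comp <- ivw_fe_components(pairs)
  structure(list(Q = comp$Q, df = comp$J - 1L,
                 pvalue = stats::pchisq(comp$Q, df = comp$J - 1L,
                                        lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4f, df = %d, p = %.3g\n", x$Q, x$df, x$pvalue))
  invisible(x)
}

#' Egger-intercept pleiotropy decision
#'
#' Flags average directional pleiotropy when the MR-Egger intercept differs
#' from zero at level `alpha`.
#'
#' @param e An `egger_result` from [egger()].
#' @param alpha Significance level (default 0.05).
#' @return List with `p_intercept`, `alpha`, and logical `pleiotropic`.
#' @export
egger_intercept_test <- function(e, alpha = 0.05) {
  stopifnot(inherits(e, "egger_result"))
  list(p_intercept = e$p_intercept, alpha = alpha,
       pleiotropic = e$p_intercept < alpha)
}

# Leave-one-out fixed-effect IVW slopes and residual sums of squares, for a
# J-vector of exposure/outcome effects with outcome-side weights w.
# Returns list(theta_loo, ss) where ss_j = (Gamma_j - theta_(-j) gamma_j)^2.
loo_residuals <- function(gamma, Gamma, w) {
  a <- w * gamma * Gamma
  b <- w * gamma^2
  theta_loo <- (sum(a) - a) / (sum(b) - b)
  ss <- (Gamma - theta_loo * gamma)^2
  list(theta_loo = theta_loo, ss = ss)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' MR-PRESSO residual-based outlier diagnostics
#'
#' Simulation-based pleiotropy residual sum of squares and outlier test.
#' Observed residuals use leave-one-out fixed-effect IVW slopes:
#' `ss_j = (Gamma_j - theta_(-j) gamma_j)^2`, `RSS_obs = sum ss_j`. Null
#' replicates redraw `Gamma*_j ~ N(theta_(-j) gamma_j, se_Gamma_j^2)` and
#' `gamma*_j ~ N(gamma_j, se_gamma_j^2)` and are scored by the same
#' leave-one-out procedure. The global p-value is the (+1-corrected)
#' proportion of replicate RSS values at or above the observed one;
#' per-instrument outlier p-values compare each observed `ss_j` to its
#' simulated distribution and are Bonferroni-adjusted across the J
#' instruments. When outliers are flagged, an outlier-corrected
#' random-effects IVW estimate is reported together with a distortion test:
#' the observed distortion coefficient
#' `(theta_all - theta_corrected) / |theta_corrected|` is compared to its
#' null distribution obtained by removing random instrument subsets of the
#' same size.
#'
#' Instruments are processed in sorted-rsid order so results are invariant
#' to input permutation for a given seed; identical inputs and seed give
#' bit-identical output.
#'
#' @param pairs A `harmonized_set` with at least 4 instruments.
#' @param n_sim Number of simulated replicates (default 1000, minimum 100).
#' @param seed Integer seed for the simulation stream.
#' @param alpha Significance level for the outlier flags (default 0.05).
#' @return A `presso_result` list: `rss_obs`, `p_global`, `outlier_pvalues`
#'   (named, raw), `outlier_pvalues_adj` (Bonferroni), `outliers`,
#'   `p_distortion` (NULL when no outliers), `distortion_coef`, `corrected`
#'   (outlier-corrected IVW, NULL when no outliers), `n_sim`, `seed`.
#' @export
mr_presso <- function(pairs, n_sim = 1000L, seed = 1L, alpha = 0.05) {
  pairs <- check_pairs(pairs, 4L, "MR-PRESSO")
  stopifnot(n_sim >= 100L)
  ord <- order(pairs$rsid)
  df <- as.data.frame(pairs)[ord, , drop = FALSE]
  J <- nrow(df)
  w <- 1 / df$se_Gamma^2

  obs <- loo_residuals(df$gamma, df$Gamma, w)
  rss_obs <- sum(obs$ss)

  sim <- with_seed(seed, {
    gamma_star <- matrix(stats::rnorm(J * n_sim, mean = df$gamma,
                                      sd = df$se_gamma), nrow = J)
    Gamma_star <- matrix(stats::rnorm(J * n_sim,
                                      mean = obs$theta_loo * df$gamma,
                                      sd = df$se_Gamma), nrow = J)
    a <- w * gamma_star * Gamma_star
    b <- w * gamma_star^2
    theta_loo_star <- sweep(-a, 2L, colSums(a), `+`) /
      sweep(-b, 2L, colSums(b), `+`)
    ss_star <- (Gamma_star - theta_loo_star * gamma_star)^2
    list(rss = colSums(ss_star), ss = ss_star)
  })

  p_global <- (1 + sum(sim$rss >= rss_obs)) / (1 + n_sim)
  p_out <- (1 + rowSums(sim$ss >= obs$ss)) / (1 + n_sim)
  names(p_out) <- df$rsid
  p_adj <- pmin(1, p_out * J)
  outliers <- df$rsid[p_adj < alpha]

  corrected <- NULL
  p_distortion <- NULL
  distortion_coef <- NULL
  if (length(outliers) > 0 && length(outliers) < J) {
    keep <- !(df$rsid %in% outliers)
    sub <- harmonized_set(df[keep, , drop = FALSE],
                          exposure_unit = attr(pairs, "exposure_unit") %||%
                            "1% lower HbA1c",
                          outcome_type = attr(pairs, "outcome_type") %||%
                            "continuous")
    corrected <- ivw(sub, effects = "random")
    theta_all <- sum(w * df$gamma * df$Gamma) / sum(w * df$gamma^2)
    theta_cor <- sum((w * df$gamma * df$Gamma)[keep]) /
      sum((w * df$gamma^2)[keep])
    distortion_coef <- (theta_all - theta_cor) / abs(theta_cor)
    d_null <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(b) {
        drop_idx <- sample.int(J, length(outliers))
        theta_b <- sum((w * df$gamma * df$Gamma)[-drop_idx]) /
          sum((w * df$gamma^2)[-drop_idx])
        (theta_all - theta_b) / abs(theta_b)
      }, numeric(1))
    })
    p_distortion <- (1 + sum(abs(d_null) >= abs(distortion_coef))) / (1 + n_sim)
  }

  structure(list(rss_obs = rss_obs, p_global = p_global,
                 outlier_pvalues = p_out, outlier_pvalues_adj = p_adj,
                 outliers = outliers, p_distortion = p_distortion,
                 distortion_coef = distortion_coef, corrected = corrected,
                 n_sim = as.integer(n_sim), seed = as.integer(seed)),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4f, global p = %.3g (n_sim = %d, seed = %d)\n",
              x$rss_obs, x$p_global, x$n_sim, x$seed))
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$p_distortion))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}
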