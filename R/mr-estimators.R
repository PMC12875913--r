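mr_result <- function(method, beta, se, n_snps, df = Inf,
                      outcome_type = "continuous") {
  stopifnot(se > 0)
  z <- beta / se
  if (is.finite(df)) {
    pvalue <- 2 * stats::pt(-abs(z), df = df)
  } else {
    pvalue <- 2 * stats::pnorm(-abs(z))
  }
  out <- data.frame(method = method, beta = beta, se = se,
                    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                    pvalue = pvalue, n_snps = n_snps,
                    stringsAsFactors = FALSE)
  structure(out, outcome_type = outcome_type,
            class = c("mr_result", "data.frame"))
}

check_pairs <- function(pairs, min_n = 1L, what = "estimation") {
  stopifnot(is.data.frame(pairs))
  pairs <- pairs[pairs$gamma != 0, , drop = FALSE]
  if (nrow(pairs) < min_n) {
    stop("insufficient instruments for ", what, ": need >= ", min_n,
         " with nonzero exposure effect, have ", nrow(pairs), call. = FALSE)
  }
  pairs
}

#' Per-instrument Wald ratio
#'
#' The single-instrument causal estimate: outcome effect divided by exposure
#' effect, `theta_j = Gamma_j / gamma_j`, with the first-order delta-method
#' standard error `se_Gamma_j / |gamma_j|` (the uncertainty in the exposure
#' effect is ignored, which is accurate for strong instruments). The
#' second-order expansion adding the exposure-side term
#' `Gamma^2 se_gamma^2 / gamma^4` is available behind `second_order`.
#'
#' @param pair One-row `harmonized_set` (or data frame with `gamma`,
#'   `se_gamma`, `Gamma`, `se_Gamma`).
#' @param second_order Include the exposure-uncertainty term in the SE.
#' @return An `mr_result` with `method = "wald"`.
#' @export
wald_ratio <- function(pair, second_order = FALSE) {
  stopifnot(nrow(pair) == 1L)
  if (pair$gamma == 0) stop("Wald ratio undefined for gamma == 0", call. = FALSE)
  theta <- pair$Gamma / pair$gamma
  se <- pair$se_Gamma / abs(pair$gamma)
  if (second_order) {
    se <- sqrt(pair$se_Gamma^2 / pair$gamma^2 +
                 pair$Gamma^2 * pair$se_gamma^2 / pair$gamma^4)
  }
  mr_result("wald", theta, se, 1L,
            outcome_type = attr(pair, "outcome_type") %||% "continuous")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

wald_components <- function(pairs, second_order = FALSE) {
  theta <- pairs$Gamma / pairs$gamma
  se <- pairs$se_Gamma / abs(pairs$gamma)
  if (second_order) {
    se <- sqrt(pairs$se_Gamma^2 / pairs$gamma^2 +
                 pairs$Gamma^2 * pairs$se_gamma^2 / pairs$gamma^4)
  }
  list(theta = theta, w = 1 / se^2)
}

ivw_fe_components <- function(pairs, second_order = FALSE) {
  wc <- wald_components(pairs, second_order)
  theta_ivw <- sum(wc$w * wc$theta) / sum(wc$w)
  se_fe <- 1 / sqrt(sum(wc$w))
  Q <- sum(wc$w * (wc$theta - theta_ivw)^2)
  list(theta = theta_ivw, se_fe = se_fe, Q = Q, J = nrow(pairs))
}

#' Inverse-variance-weighted combination of Wald ratios
#'
#' Pools per-instrument Wald ratios with weights `w_j = 1 / se(theta_j)^2`.
#' `effects = "fixed"` uses `se = (sum w_j)^(-1/2)`; `effects = "random"`
#' (the default, matching common drug-target MR practice) applies
#' multiplicative random effects, inflating the fixed-effect SE by
#' `max(1, sqrt(Q / (J - 1)))` where `Q` is Cochran's heterogeneity
#' statistic, so the random-effects SE is never smaller than the
#' fixed-effect one. With a single instrument both reduce to the Wald ratio.
#' P-values use a normal reference.
#'
#' @param pairs A `harmonized_set`.
#' @param effects `"random"` or `"fixed"`.
#' @param second_order Passed to the Wald SE computation.
#' @return An `mr_result` with `method` `"ivw-re"` or `"ivw-fe"`.
#' @export
ivw <- function(pairs, effects = c("random", "fixed"), second_order = FALSE) {
  effects <- match.arg(effects)
  pairs <- check_pairs(pairs, 1L, "IVW")
  comp <- ivw_fe_components(pairs, second_order)
  se <- comp$se_fe
  if (effects == "random" && comp$J >= 2L) {
    se <- se * max(1, sqrt(comp$Q / (comp$J - 1L)))
  }
  mr_result(if (effects == "random") "ivw-re" else "ivw-fe",
            comp$theta, se, comp$J,
            outcome_type = attr(pairs, "outcome_type") %||% "continuous")
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' with an intercept, weights `1 / se_Gamma^2`. The slope is the causal
#' estimate under the InSIDE assumption (instrument strength independent of
#' direct effects); the intercept estimates average directional pleiotropy
#' and its test is the standard pleiotropy diagnostic. Standard errors are
#' scaled multiplicatively by `max(1, sqrt(RSS_w / (J - 2)))` and p-values
#' use a t reference with `J - 2` degrees of freedom.
#'
#' @param pairs A `harmonized_set` with at least 3 instruments.
#' @return An `egger_result` list: `slope`, `se_slope`, `p_slope`,
#'   `ci_low`, `ci_high`, `intercept`, `se_intercept`, `p_intercept`,
#'   `n_snps`, `df`.
#' @export
egger <- function(pairs) {
  pairs <- check_pairs(pairs, 3L, "MR-Egger regression")
  if (stats::var(pairs$gamma) == 0) {
    stop("exposure effects are constant; Egger regression is unidentified",
         call. = FALSE)
  }
  J <- nrow(pairs)
  w <- 1 / pairs$se_Gamma^2
  fit <- stats::lm(Gamma ~ gamma, data = as.data.frame(pairs), weights = w)
  slope <- unname(stats::coef(fit)["gamma"])
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  df <- J - 2L
  rss_w <- sum(w * stats::residuals(fit)^2)
  # unscaled covariance (X' W X)^-1, then multiplicative dispersion
  # max(1, sqrt(RSS_w / df)); computed directly so an exact fit (RSS = 0)
  # yields finite SEs rather than 0/0
  X <- cbind(1, pairs$gamma)
  V <- solve(crossprod(X, w * X))
  disp <- max(1, sqrt(rss_w / df))
  se_int <- sqrt(V[1, 1]) * disp
  se_slp <- sqrt(V[2, 2]) * disp
  structure(list(
    slope = slope, se_slope = se_slp,
    ci_low = slope - 1.96 * se_slp, ci_high = slope + 1.96 * se_slp,
    p_slope = 2 * stats::pt(-abs(slope / se_slp), df = df),
    intercept = intercept, se_intercept = se_int,
    p_intercept = 2 * stats::pt(-abs(intercept / se_int), df = df),
    n_snps = J, df = df, rss_w = rss_w),
    class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("MR-Egger (J = %d): slope %.4f (SE %.4f, p = %.3g); intercept %.4g (SE %.4g, p = %.3g)\n",
              x$n_snps, x$slope, x$se_slope, x$p_slope,
              x$intercept, x$se_intercept, x$p_intercept))
  invisible(x)
}

#' Convert an Egger fit's slope into an `mr_result` row
#'
#' @param e An `egger_result`.
#' @param outcome_type Outcome scale label.
#' @export
egger_slope_result <- function(e, outcome_type = "continuous") {
  out <- data.frame(method = "egger", beta = e$slope, se = e$se_slope,
                    ci_low = e$ci_low, ci_high = e$ci_high,
                    pvalue = e$p_slope, n_snps = e$n_snps,
                    stringsAsFactors = FALSE)
  structure(out, outcome_type = outcome_type,
            class = c("mr_result", "data.frame"))
}

#' Express a binary-outcome estimate on the odds-ratio scale
#'
#' Exponentiates the log-odds causal estimate and its confidence bounds,
#' adding `or`, `or_ci_low`, `or_ci_high` columns; the beta-scale fields are
#' untouched. For an HbA1c exposure oriented to the lowering allele these
#' are odds ratios per 1% lower HbA1c.
#'
#' @param result An `mr_result` for a binary outcome.
#' @return The augmented `mr_result`.
#' @export
to_or_scale <- function(result) {
  if (!identical(attr(result, "outcome_type"), "binary")) {
    stop("odds-ratio scale applies only to binary outcomes", call. = FALSE)
  }
  result$or <- exp(result$beta)
  result$or_ci_low <- exp(result$ci_low)
  result$or_ci_high <- exp(result$ci_high)
  result
}

#' @export
print.mr_result <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    if (!is.null(x$or) && !is.na(x$or[i])) {
      cat(sprintf("%s (J = %d): OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
                  x$method[i], x$n_snps[i], x$or[i], x$or_ci_low[i],
                  x$or_ci_high[i], x$pvalue[i]))
    } else {
      cat(sprintf("%s (J = %d): beta %.4f (95%% CI %.4f to %.4f), p = %.3g\n",
                  x$method[i], x$n_snps[i], x$beta[i], x$ci_low[i],
                  x$ci_high[i], x$pvalue[i]))
    }
  }
  invisible(x)
}
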