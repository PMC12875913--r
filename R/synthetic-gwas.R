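#' Configuration for the two-sample summary-statistics generator
#'
#' Defaults emulate the cis drug-target design the pipeline targets: 17
#' instruments (the size of a typical single-gene instrument set for a
#' glycemic exposure), an exposure GWAS of ~147k samples and an outcome GWAS
#' of ~212k samples, common variants, and per-allele exposure effects of a
#' few hundredths of a percent HbA1c, which puts single-variant F statistics
#' in the high-double-digit range seen in well-powered drug-target analyses.
#'
#' @param J Instrument count.
#' @param theta True causal effect of the exposure on the outcome, per unit
#'   *increase* of the exposure in raw trait units. The truth record also
#'   carries `theta_lowering = -theta`, the value estimated by the pipeline
#'   after orientation to the lowering allele.
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes.
#' @param gamma_scale Scale of the true per-allele exposure effects
#'   (% HbA1c per allele).
#' @param gamma_dist `"centered"` draws true exposure effects from
#'   `N(0, gamma_scale^2)` (allele coding as a GWAS reports it);
#'   `"positive"` draws them half-normal with the same scale, emulating
#'   effects already expressed in the analysis orientation (all instruments
#'   coded by the trait-lowering or -raising allele). Directional pleiotropy
#'   (`pleiotropy_mean != 0`) only means a consistent direction relative to
#'   the instruments' shared orientation, so the Egger-vs-IVW separation is
#'   exhibited under `"positive"`.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the direct
#'   (pleiotropic) effects `alpha_j`; a nonzero mean gives directional
#'   pleiotropy, a nonzero SD with zero mean gives balanced pleiotropy.
#' @param inside_violation If `TRUE`, `alpha_j` gains a component
#'   proportional to `gamma_j`, violating the InSIDE assumption.
#' @param n_outliers Number of implanted outlier variants.
#' @param outlier_magnitude Outcome-effect shift of each implanted outlier,
#'   in units of that variant's outcome SE.
#' @param binary_outcome If `TRUE`, outcome effects are labelled log-odds.
#' @param palindromic_fraction Fraction of variants given palindromic
#'   (A/T or C/G) allele pairs.
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(J = 17L, theta = 0, maf_range = c(0.05, 0.5),
                              n_exp = 146806L, n_out = 211717L,
                              gamma_scale = 0.045,
                              gamma_dist = c("centered", "positive"),
                              pleiotropy_mean = 0, pleiotropy_sd = 0,
                              inside_violation = FALSE,
                              n_outliers = 0L, outlier_magnitude = 0,
                              binary_outcome = FALSE,
                              palindromic_fraction = 0.1, seed = 1L) {
  stopifnot(J >= 1L, length(maf_range) == 2L,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_exp >= 2L, n_out >= 2L, pleiotropy_sd >= 0,
            n_outliers >= 0L, n_outliers <= J,
            palindromic_fraction >= 0, palindromic_fraction <= 1)
  gamma_dist <- match.arg(gamma_dist)
  structure(list(J = as.integer(J), theta = theta, maf_range = maf_range,
                 n_exp = as.integer(n_exp), n_out = as.integer(n_out),
                 gamma_scale = gamma_scale, gamma_dist = gamma_dist,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 inside_violation = inside_violation,
                 n_outliers = as.integer(n_outliers),
                 outlier_magnitude = outlier_magnitude,
                 binary_outcome = binary_outcome,
                 palindromic_fraction = palindromic_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# two-sided normal p, floored at the smallest positive double so extreme
# z-scores do not underflow to an invalid p of 0
norm_p <- function(beta, se) {
  pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
}

#' Simulate two-sample GWAS summary statistics
#'
#' Generates exposure and outcome association tables under the structural
#' model the MR estimators assume: per variant `j`, a true exposure effect
#' `gamma_j` (centered, SD `gamma_scale`), a direct effect
#' `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)` (plus a gamma-correlated
#' term under `inside_violation`), and a true outcome effect
#' `Gamma_j = theta * gamma_j + alpha_j`. Standard errors follow the
#' standardized-trait GWAS approximation
#' `se = (2 maf (1 - maf) n)^(-1/2)` and observed effects are drawn
#' `N(truth, se^2)`; `n_outliers` randomly chosen variants have their
#' observed outcome effect shifted by `outlier_magnitude` outcome SEs.
#' P-values use a normal reference. Variants receive non-palindromic allele
#' pairs except for a configurable palindromic fraction, and sequential
#' positions on one chromosome.
#'
#' @param cfg A [simulation_config()].
#' @return List with `exposure` and `outcome` (`sumstats` tables in the
#'   generic dialect) and `truth` (list: `theta`, `theta_lowering`,
#'   `gamma`, `alpha`, `Gamma`, `outliers` rsids, `maf`).
#' @export
simulate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    J <- cfg$J
    rsid <- sprintf("rs%05d", seq_len(J))
    pos <- 44e6 + seq_len(J) * 10000
    maf <- stats::runif(J, cfg$maf_range[1], cfg$maf_range[2])

    n_palin <- round(cfg$palindromic_fraction * J)
    palin_idx <- if (n_palin > 0) sample.int(J, n_palin) else integer(0)
    ea <- character(J); oa <- character(J)
    np_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                         "G", "A", "C", "A", "G", "T", "C", "T"),
                       ncol = 2, byrow = TRUE)
    p_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                      ncol = 2, byrow = TRUE)
    pick_np <- sample.int(nrow(np_pairs), J, replace = TRUE)
    pick_p <- sample.int(nrow(p_pairs), J, replace = TRUE)
    ea <- np_pairs[pick_np, 1]; oa <- np_pairs[pick_np, 2]
    ea[palin_idx] <- p_pairs[pick_p[palin_idx], 1]
    oa[palin_idx] <- p_pairs[pick_p[palin_idx], 2]

    gamma <- stats::rnorm(J, 0, cfg$gamma_scale)
    if (cfg$gamma_dist == "positive") gamma <- abs(gamma)
    alpha <- stats::rnorm(J, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    if (cfg$inside_violation) alpha <- alpha + 0.5 * gamma
    Gamma <- cfg$theta * gamma + alpha

    se_g <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exp)
    se_G <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_out)
    g_hat <- stats::rnorm(J, gamma, se_g)
    G_hat <- stats::rnorm(J, Gamma, se_G)

    outlier_idx <- if (cfg$n_outliers > 0) sample.int(J, cfg$n_outliers) else integer(0)
    G_hat[outlier_idx] <- G_hat[outlier_idx] +
      cfg$outlier_magnitude * se_G[outlier_idx]

    exposure <- sumstats(
      data.frame(rsid = rsid, chrom = "7", pos = pos,
                 effect_allele = ea, other_allele = oa, eaf = maf,
                 beta = g_hat, se = se_g, pvalue = norm_p(g_hat, se_g),
                 n = cfg$n_exp, stringsAsFactors = FALSE),
      trait_name = "synthetic exposure", trait_unit = "% HbA1c",
      ancestry = "synthetic", sample_size = cfg$n_exp)
    outcome <- sumstats(
      data.frame(rsid = rsid, chrom = "7", pos = pos,
                 effect_allele = ea, other_allele = oa, eaf = maf,
                 beta = G_hat, se = se_G, pvalue = norm_p(G_hat, se_G),
                 n = cfg$n_out, stringsAsFactors = FALSE),
      trait_name = "synthetic outcome",
      trait_unit = if (cfg$binary_outcome) "log-odds" else "SD",
      ancestry = "synthetic", sample_size = cfg$n_out)
    list(exposure = exposure, outcome = outcome,
         truth = list(theta = cfg$theta, theta_lowering = -cfg$theta,
                      gamma = stats::setNames(gamma, rsid),
                      alpha = stats::setNames(alpha, rsid),
                      Gamma = stats::setNames(Gamma, rsid),
                      outliers = rsid[sort(outlier_idx)], maf = maf))
  })
}

#' Build a harmonized set directly from generator output
#'
#' Convenience for estimator studies: pairs the observed exposure and
#' outcome effects of [simulate_two_sample()] without going through allele
#' orientation, so the working effects stay in raw trait units and the IVW
#' estimand is `truth$theta`.
#'
#' @param sim Output of [simulate_two_sample()].
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return A [harmonized_set()] with `exposure_unit = "raw"`.
#' @export
pairs_from_simulation <- function(sim, outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  harmonized_set(
    data.frame(rsid = sim$exposure$rsid, gamma = sim$exposure$beta,
               se_gamma = sim$exposure$se, Gamma = sim$outcome$beta,
               se_Gamma = sim$outcome$se,
               eaf_exposure = sim$exposure$eaf,
               eaf_outcome = sim$outcome$eaf, stringsAsFactors = FALSE),
    exposure_unit = "raw", outcome_type = outcome_type)
}

#' Simulate block-structured LD and a matching genotype panel
#'
#' Draws continuous allele dosages from a Gaussian factor model: variants in
#' the same block share a latent factor with loading
#' `sqrt(within_block_r2)`, so realized within-block r-squared concentrates
#' near `within_block_r2` and cross-block r-squared near zero. The returned
#' LD matrix is computed from the genotypes via
#' [compute_ld_from_genotypes()].
#'
#' @param n_variants Total variant count; must equal `sum(block_sizes)`.
#' @param block_sizes Integer vector of LD-block sizes.
#' @param within_block_r2 Target within-block r-squared in \[0, 1).
#' @param n_samples Reference-panel sample count.
#' @param seed Integer seed.
#' @param rsid Optional rsid labels (default `rs00001...`), matching
#'   [simulate_two_sample()] output so the two generators compose.
#' @return List with `ld` (an `ld_matrix`) and `genotypes` (variants x
#'   samples dosage matrix with entries in \[0, 2\]).
#' @export
simulate_ld_blocks <- function(n_variants, block_sizes, within_block_r2,
                               n_samples = 1000L, seed = 1L, rsid = NULL) {
  stopifnot(sum(block_sizes) == n_variants, within_block_r2 >= 0,
            within_block_r2 < 1, n_samples >= 2L)
  if (is.null(rsid)) rsid <- sprintf("rs%05d", seq_len(n_variants))
  stopifnot(length(rsid) == n_variants)
  with_seed(seed, {
    block <- rep(seq_along(block_sizes), block_sizes)
    load <- sqrt(sqrt(within_block_r2))  # latent corr = sqrt(r2) => r2 on dosages
    u <- matrix(stats::rnorm(length(block_sizes) * n_samples),
                nrow = length(block_sizes))
    e <- matrix(stats::rnorm(n_variants * n_samples), nrow = n_variants)
    z <- load * u[block, , drop = FALSE] + sqrt(1 - load^2) * e
    # linear map into [0, 2] dosage space preserves Pearson correlation
    geno <- pmin(pmax(1 + 0.3 * z, 0), 2)
    rownames(geno) <- rsid
    list(ld = compute_ld_from_genotypes(geno), genotypes = geno)
  })
}
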