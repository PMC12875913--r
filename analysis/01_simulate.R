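#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Emulates the two designs of a drug-target MR study of glycemic control:
#  * a cis exposure GWAS — HbA1c-associated variants concentrated in a
#    single gene region (a stand-in for GCK), with block LD so clumping has
#    work to do;
#  * a genome-wide exposure GWAS — independent HbA1c variants spread across
#    chromosomes, outside the target region.
# For each design, four outcome GWAS are built over the same variants from
# the generator's truth record: two binary (memory loss, type 2 diabetes as
# positive control; effective sample sizes reflect case/control imbalance)
# and two continuous cognition scores. True effects are chosen so the
# cognition signals are absent or attenuated under the genome-wide design
# while the glycemic positive control is shared — the pattern the
# comparison stage should recover.
#
# Outputs (results/sim/): generic-dialect summary-stats TSVs, LD r2 TSVs,
# and truth.json.

suppressPackageStartupMessages(library(targetmr))

out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed0 <- 20260922L

# effective sample size of a case/control GWAS
n_eff <- function(n_case, n_ctrl) round(4 / (1 / n_case + 1 / n_ctrl))

# outcome designs: true causal effect per 1 unit *higher* exposure, so the
# per-1%-lower estimates carry the opposite sign (protective OR < 1 for
# positive theta on a risk outcome)
outcomes <- list(
  memory_loss = list(binary = TRUE, n_out = n_eff(1384, 210333),
                     theta_cis = 1.56, theta_gw = 0.48),
  t2d = list(binary = TRUE, n_out = n_eff(38841, 451248),
             theta_cis = 1.35, theta_gw = 1.31),
  intelligence = list(binary = FALSE, n_out = 216381,
                      theta_cis = -0.18, theta_gw = 0),
  prospective_memory = list(binary = FALSE, n_out = 162335,
                            theta_cis = -0.06, theta_gw = 0.01)
)

# draw an outcome table over an existing exposure simulation's variants
make_outcome <- function(sim, theta, n_out, binary, seed) {
  set.seed(seed)
  expo <- as.data.frame(sim$exposure)
  maf <- sim$truth$maf
  se_G <- 1 / sqrt(2 * maf * (1 - maf) * n_out)
  Gamma_true <- theta * sim$truth$gamma
  G_hat <- rnorm(nrow(expo), Gamma_true, se_G)
  p <- pmax(2 * pnorm(-abs(G_hat / se_G)), .Machine$double.xmin)
  sumstats(data.frame(rsid = expo$rsid, chrom = expo$chrom, pos = expo$pos,
                      effect_allele = expo$effect_allele,
                      other_allele = expo$other_allele, eaf = expo$eaf,
                      beta = G_hat, se = se_G, pvalue = p, n = n_out),
           trait_unit = if (binary) "log-odds" else "SD",
           sample_size = n_out)
}

build_design <- function(label, J, block_sizes, within_r2, chrom_labels,
                         theta_field, seed) {
  sim <- simulate_two_sample(simulation_config(
    J = J, theta = 0, gamma_scale = 0.06, seed = seed))
  expo <- as.data.frame(sim$exposure)
  expo$chrom <- chrom_labels
  write_sumstats(sumstats(expo, trait_name = "HbA1c", trait_unit = "%"),
                 file.path(out_dir, paste0("exposure_", label, ".tsv")))

  ld <- simulate_ld_blocks(J, block_sizes, within_block_r2 = within_r2,
                           n_samples = 2000, seed = seed + 1,
                           rsid = expo$rsid)
  write_ld_matrix(ld$ld, file.path(out_dir, paste0("ld_", label, ".tsv")))

  thetas <- list()
  for (nm in names(outcomes)) {
    oc <- outcomes[[nm]]
    theta <- oc[[theta_field]]
    tab <- make_outcome(sim, theta, oc$n_out, oc$binary,
                        seed = seed + 100 + match(nm, names(outcomes)))
    df <- as.data.frame(tab)
    df$chrom <- chrom_labels
    write_sumstats(sumstats(df, trait_name = nm,
                            trait_unit = attr(tab, "trait_unit")),
                   file.path(out_dir, paste0("outcome_", nm, "_", label, ".tsv")))
    thetas[[nm]] <- theta
  }
  list(gamma = as.list(sim$truth$gamma), thetas = thetas)
}

# cis design: 40 candidate variants in the target region, LD blocks of 2
truth_cis <- build_design("cis", J = 40, block_sizes = rep(2, 20),
                          within_r2 = 0.6, chrom_labels = rep("7", 40),
                          theta_field = "theta_cis", seed = seed0)
# genome-wide design: 60 independent variants spread over chromosomes
truth_gw <- build_design("gw", J = 60, block_sizes = rep(1, 60),
                         within_r2 = 0, chrom_labels = as.character(
                           rep(1:20, each = 3)),
                         theta_field = "theta_gw", seed = seed0 + 1000)

jsonlite::write_json(list(cis = truth_cis, gw = truth_gw,
                          seed = seed0, n_eff = lapply(outcomes, `[[`, "n_out")),
                     file.path(out_dir, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat("Simulated study data written to", out_dir, "\n")
cat(" cis design: 40 variants in 20 LD blocks (r2 ~ 0.6), 4 outcomes\n")
cat(" genome-wide design: 60 independent variants, 4 outcomes\n")
cat(" true per-1%-lower effects: cognition signals absent or attenuated in\n",
    "the genome-wide design; glycemic positive control (t2d) in both\n")
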