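test_that("orientation to the lowering allele swaps raising records and is idempotent", {
  tab <- make_sumstats(c("rs1", "rs2"), ea = c("A", "C"), oa = c("G", "T"),
                       beta = c(0.02, -0.02), eaf = c(0.3, 0.4))
  out <- orient_to_lowering(tab)
  expect_equal(out$effect_allele, c("G", "C"))
  expect_equal(out$other_allele, c("A", "T"))
  expect_equal(out$beta, c(-0.02, -0.02))
  expect_equal(out$eaf, c(0.7, 0.4))
  expect_equal(as.data.frame(orient_to_lowering(out)), as.data.frame(out))
})

test_that("harmonize aligns swapped outcome alleles and negates the effect", {
  expo <- make_sumstats("rs1", ea = "G", oa = "A", beta = -0.02, eaf = 0.7)
  outc <- make_sumstats("rs1", ea = "A", oa = "G", beta = 0.1, eaf = 0.3,
                        se = 0.05)
  h <- harmonize(expo, outc)
  expect_equal(nrow(h), 1L)
  expect_equal(h$Gamma, -0.1)
  expect_true(h$flipped)
  expect_equal(h$gamma, 0.02)   # working unit: per 1% lower exposure
  expect_equal(h$eaf_outcome, 0.7)
})

test_that("an unoriented exposure is a contract error", {
  expo <- make_sumstats("rs1", beta = 0.02)
  outc <- make_sumstats("rs1", se = 0.05)
  expect_error(harmonize(expo, outc), "not oriented")
})

test_that("palindromic variants follow the frequency rule table", {
  # unambiguous concordant frequencies: retained as reported
  expo <- make_sumstats("rs1", ea = "A", oa = "T", beta = -0.02, eaf = 0.10)
  outc <- make_sumstats("rs1", ea = "A", oa = "T", beta = 0.05, eaf = 0.12,
                        se = 0.05)
  h <- harmonize(expo, outc, palindromic_eaf_limit = 0.42)
  expect_equal(h$Gamma, 0.05)
  expect_true(h$palindromic)
  expect_false(h$flipped)

  # unambiguous discordant frequencies: orientation flipped
  outc2 <- make_sumstats("rs1", ea = "A", oa = "T", beta = 0.05, eaf = 0.88,
                         se = 0.05)
  h2 <- harmonize(expo, outc2)
  expect_equal(h2$Gamma, -0.05)
  expect_true(h2$flipped)
  expect_equal(h2$eaf_outcome, 0.12)

  # ambiguous outcome frequency: dropped with reason
  outc3 <- make_sumstats("rs1", ea = "A", oa = "T", beta = 0.05, eaf = 0.50,
                         se = 0.05)
  h3 <- harmonize(expo, outc3)
  expect_equal(nrow(h3), 0L)
  expect_equal(attr(h3, "dropped")$reason, "palindromic-ambiguous")

  # missing frequency on either side: dropped
  outc4 <- make_sumstats("rs1", ea = "A", oa = "T", beta = 0.05, eaf = NA,
                         se = 0.05)
  expect_equal(attr(harmonize(expo, outc4), "dropped")$reason,
               "palindromic-ambiguous")
})

test_that("every allele configuration resolves per the harmonization rule table", {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expo_pairs <- expand.grid(ea = bases, oa = bases, stringsAsFactors = FALSE)
  expo_pairs <- expo_pairs[expo_pairs$ea != expo_pairs$oa, ]
  for (i in seq_len(nrow(expo_pairs))) {
    e_ea <- expo_pairs$ea[i]; e_oa <- expo_pairs$oa[i]
    e_palin <- comp[[e_ea]] == e_oa
    expo <- make_sumstats("rs1", ea = e_ea, oa = e_oa, beta = -0.02, eaf = 0.1)
    for (j in seq_len(nrow(expo_pairs))) {
      o_ea <- expo_pairs$ea[j]; o_oa <- expo_pairs$oa[j]
      outc <- make_sumstats("rs1", ea = o_ea, oa = o_oa, beta = 0.05,
                            eaf = 0.1, se = 0.05)
      h <- harmonize(expo, outc, palindromic_eaf_limit = 0.42)
      same <- o_ea == e_ea && o_oa == e_oa
      swap <- o_ea == e_oa && o_oa == e_ea
      csame <- comp[[o_ea]] == e_ea && comp[[o_oa]] == e_oa
      cswap <- comp[[o_ea]] == e_oa && comp[[o_oa]] == e_ea
      if (e_palin) {
        if (same || swap) {
          # frequencies 0.1 vs 0.1 are concordant: kept as reported
          expect_equal(h$Gamma, 0.05, info = paste(e_ea, e_oa, o_ea, o_oa))
        } else {
          expect_equal(attr(h, "dropped")$reason, "allele-mismatch")
        }
      } else if (same || csame) {
        expect_equal(h$Gamma, 0.05)
        expect_false(h$flipped)
      } else if (swap || cswap) {
        expect_equal(h$Gamma, -0.05)
        expect_true(h$flipped)
      } else {
        expect_equal(attr(h, "dropped")$reason, "allele-mismatch")
      }
    }
  }
})

test_that("harmonization is invariant to outcome allele-coding flips", {
  set.seed(21)
  n <- 30
  bases_np <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"),
                   c("A", "T"), c("C", "G"))
  pick <- sample(length(bases_np), n, replace = TRUE)
  ea <- vapply(bases_np[pick], `[`, "", 1)
  oa <- vapply(bases_np[pick], `[`, "", 2)
  expo <- orient_to_lowering(
    make_sumstats(sprintf("rs%02d", 1:n), ea = ea, oa = oa,
                  beta = rnorm(n, 0, 0.03), eaf = runif(n, 0.05, 0.35)))
  outc <- make_sumstats(sprintf("rs%02d", 1:n), ea = ea, oa = oa,
                        beta = rnorm(n, 0, 0.1), eaf = runif(n, 0.05, 0.35),
                        se = 0.05)
  h0 <- harmonize(expo, outc)

  flip_idx <- sample(n, 12)
  flipped <- as.data.frame(outc)
  tmp <- flipped$effect_allele[flip_idx]
  flipped$effect_allele[flip_idx] <- flipped$other_allele[flip_idx]
  flipped$other_allele[flip_idx] <- tmp
  flipped$beta[flip_idx] <- -flipped$beta[flip_idx]
  flipped$eaf[flip_idx] <- 1 - flipped$eaf[flip_idx]
  h1 <- harmonize(expo, sumstats(flipped))

  # estimate-relevant content identical; the flipped bookkeeping flag tracks
  # the input representation, so it is excluded
  cols <- c("rsid", "gamma", "se_gamma", "Gamma", "se_Gamma", "palindromic",
            "eaf_exposure", "eaf_outcome")
  expect_equal(as.data.frame(h0)[cols], as.data.frame(h1)[cols])
  expect_equal(attr(h0, "dropped"), attr(h1, "dropped"))
})

test_that("pairs plus dropped account for every shared rsid", {
  set.seed(31)
  expo <- orient_to_lowering(random_table(25, seed = 61))
  outc_df <- as.data.frame(random_table(30, seed = 62))
  outc_df$rsid[1:15] <- expo$rsid[1:15]   # overlap by construction
  outc <- sumstats(outc_df)
  h <- harmonize(expo, outc)
  shared <- intersect(expo$rsid, outc$rsid)
  dropped <- attr(h, "dropped")
  on_shared <- dropped[dropped$reason != "absent-from-outcome", ]
  expect_equal(nrow(h) + nrow(on_shared), length(shared))
  expect_equal(sort(c(h$rsid, on_shared$rsid)), sort(shared))
  # rsids absent from the outcome appear in the ledger
  expect_setequal(dropped$rsid[dropped$reason == "absent-from-outcome"],
                  setdiff(expo$rsid, outc$rsid))
})

test_that("harmonized sets export to TSV and reload numerically intact", {
  pairs <- pairs_from_ratios(c(0.5, -0.2, 0.1), c(0.1, 0.05, 0.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(pairs, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$Gamma, pairs$Gamma)
  expect_equal(back$se_Gamma, pairs$se_Gamma)
  expect_equal(back$gamma, pairs$gamma)
})
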