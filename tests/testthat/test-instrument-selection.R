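gck <- gene_region("7", 44182812, 44229038, flank = 100000)

test_that("region filtering keeps the flanked window inclusively", {
  # window is chr7:44082812-44329038 after the 100-kb flank
  tab <- make_sumstats(sprintf("rs%d", 1:6),
                       chrom = c("7", "7", "7", "7", "7", "8"),
                       pos = c(44082811, 44082812, 44200000, 44329038,
                               44329039, 44200000))
  within <- filter_by_region(tab, gck, "within")
  expect_equal(within$rsid, c("rs2", "rs3", "rs4"))
  expect_false("rs1" %in% within$rsid)  # one base outside the window
  excl <- filter_by_region(tab, gck, "exclude")
  expect_equal(excl$rsid, c("rs1", "rs5", "rs6"))
})

test_that("exclude mode equals the brute-force complement on random tables", {
  tab <- random_table(50, seed = 7)
  region <- gene_region("7", 1e6, 2e6, flank = 5e5)
  inside_oracle <- tab$chrom == "7" & tab$pos >= 5e5 & tab$pos <= 25e5
  expect_equal(filter_by_region(tab, region, "within")$rsid,
               tab$rsid[inside_oracle])
  expect_equal(filter_by_region(tab, region, "exclude")$rsid,
               tab$rsid[!inside_oracle])
})

test_that("p-value filtering has an inclusive boundary", {
  tab <- make_sumstats(c("rs1", "rs2", "rs3"),
                       pvalue = c(5e-8, 6e-8, 1e-10))
  kept <- filter_by_pvalue(tab, 5e-8)
  expect_setequal(kept$rsid, c("rs1", "rs3"))
  # brute-force count on a random mixed table
  tab2 <- random_table(20, seed = 11)
  expect_equal(nrow(filter_by_pvalue(tab2, 1e-3)),
               sum(tab2$pvalue <= 1e-3))
})

test_that("greedy clumping retains the most significant representative per cluster", {
  tab <- make_sumstats(c("rsA", "rsB", "rsC"), pos = c(1000, 2000, 3000),
                       pvalue = c(1e-12, 1e-10, 1e-9))
  r2 <- matrix(c(1, 0.5, 0.1,
                 0.5, 1, 0.2,
                 0.1, 0.2, 1), 3, 3,
               dimnames = list(c("rsA", "rsB", "rsC"), c("rsA", "rsB", "rsC")))
  out <- clump(tab, ld_matrix(r2), r2_threshold = 0.3, window_bases = 1e7)
  expect_equal(out$rsid, c("rsA", "rsC"))

  single <- clump(make_sumstats("rs1"), ld_matrix(matrix(1, 1, 1,
                    dimnames = list("rs1", "rs1"))), 0.3, 1e7)
  expect_equal(single$rsid, "rs1")

  indep <- clump(tab, ld_matrix(diag(3) + 0, c("rsA", "rsB", "rsC")), 0.3, 1e7)
  expect_equal(sort(indep$rsid), c("rsA", "rsB", "rsC"))
})

test_that("clumping matches the brute-force oracle on random instances", {
  for (i in 1:60) {
    n <- sample(2:10, 1)
    tab <- random_table(n, seed = 100 + i)
    ld <- random_ld(tab$rsid, seed = 200 + i)
    thr <- runif(1, 0.05, 0.8)
    win <- sample(c(5e5, 2e6, 1e7), 1)
    got <- clump(tab, ld, r2_threshold = thr, window_bases = win)
    expect_equal(got$rsid, oracle_clump(as.data.frame(tab), ld, thr, win))
  }
})

test_that("clumping is invariant to input row order", {
  tab <- random_table(10, seed = 33)
  ld <- random_ld(tab$rsid, seed = 34)
  base <- clump(tab, ld, 0.2, 1e7)$rsid
  for (i in 1:5) {
    set.seed(i)
    perm <- sumstats(as.data.frame(tab)[sample.int(nrow(tab)), ])
    expect_equal(clump(perm, ld, 0.2, 1e7)$rsid, base)
  }
})

test_that("no retained clump pair violates the r2/window constraint", {
  for (i in 1:20) {
    tab <- random_table(8, seed = 300 + i)
    ld <- random_ld(tab$rsid, seed = 400 + i)
    out <- clump(tab, ld, 0.25, 2e6)
    if (nrow(out) < 2) next
    combs <- combn(nrow(out), 2)
    for (k in seq_len(ncol(combs))) {
      a <- combs[1, k]; b <- combs[2, k]
      ok <- ld[out$rsid[a], out$rsid[b]] <= 0.25 ||
        abs(out$pos[a] - out$pos[b]) > 2e6 || out$chrom[a] != out$chrom[b]
      expect_true(ok)
    }
  }
})

test_that("variants absent from the LD source are dropped with a warning", {
  tab <- make_sumstats(c("rs1", "rs2"), pvalue = c(1e-10, 1e-9))
  ld <- ld_matrix(matrix(1, 1, 1, dimnames = list("rs1", "rs1")))
  expect_warning(out <- clump(tab, ld, 0.3, 1e7), "absent from the LD source")
  expect_equal(out$rsid, "rs1")
})

test_that("the F statistic is the squared z-score and mean F rises as SEs shrink", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 0.02), 0)
  tab <- random_table(12, seed = 55)
  f1 <- mean(f_statistic(tab$beta, tab$se))
  se2 <- tab$se
  se2[4] <- se2[4] / 2
  expect_gt(mean(f_statistic(tab$beta, se2)), f1)
  # explained-variance form agrees in magnitude for strong signals
  f_r2 <- f_statistic(0.1, 0.02, method = "r2", eaf = 0.3, n = 1e5)
  expect_equal(f_r2, (1e5 - 2) / 1e5 * 25, tolerance = 1e-6)
})

test_that("LD from genotypes matches the direct correlation oracle", {
  g_same <- rbind(rs1 = c(0, 1, 2, 1, 0), rs2 = c(0, 1, 2, 1, 0))
  expect_equal(unclass(compute_ld_from_genotypes(g_same))["rs1", "rs2"], 1)
  ld2 <- compute_ld_from_genotypes(rbind(rs1 = c(0, 2, 0, 2),
                                         rs2 = c(0, 0, 2, 2)))
  expect_equal(unclass(ld2)["rs1", "rs2"], 0)
  set.seed(99)
  g <- matrix(sample(0:2, 100, replace = TRUE), nrow = 5,
              dimnames = list(sprintf("rs%d", 1:5), NULL))
  ld <- compute_ld_from_genotypes(g)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    num <- cov(g[i, ], g[j, ])^2
    den <- var(g[i, ]) * var(g[j, ])
    expect_equal(unclass(ld)[i, j], num / den, tolerance = 1e-12)
  }
  g[2, ] <- 1
  expect_error(compute_ld_from_genotypes(g), "zero-variance")
})

test_that("select_instruments chains region, significance and clumping stages", {
  set.seed(5)
  tab <- make_sumstats(sprintf("rs%02d", 1:20), pos = 44100000 + 1:20 * 10000,
                       beta = rnorm(20, 0, 0.05), se = 0.004)
  ld <- random_ld(tab$rsid, seed = 6)
  inst <- select_instruments(tab, gck, mode = "cis", ld = ld)
  expect_s3_class(inst, "instrument_set")
  expect_true(all(inst$instruments$pvalue <= 5e-8))
  expect_equal(inst$mean_F, mean((inst$instruments$beta / inst$instruments$se)^2))
  expect_equal(inst$params$r2_threshold, 0.3)
  expect_lte(inst$counts["clumped"], inst$counts["significant"])
  # genome-wide mode defaults to the stricter clumping threshold
  gw <- select_instruments(tab, gene_region("9", 1, 2), mode = "genome-wide",
                           ld = ld)
  expect_equal(gw$params$r2_threshold, 0.001)
})

test_that("LD matrices round-trip through the square TSV format", {
  ld <- random_ld(sprintf("rs%d", 1:4), seed = 77)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, path)
  back <- read_ld_matrix(path)
  expect_equal(unclass(back), unclass(ld), tolerance = 1e-12)
})
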