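test_that("the Wald ratio and its delta-method SE match hand evaluation", {
  pair <- harmonized_set(data.frame(rsid = "rs1", gamma = 0.4, se_gamma = 0.01,
                                    Gamma = 0.2, se_Gamma = 0.05))
  w <- wald_ratio(pair)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.125)
  expect_equal(w$ci_low, 0.5 - 1.96 * 0.125)
  expect_equal(w$pvalue, 2 * pnorm(-4))

  zero <- harmonized_set(data.frame(rsid = "rs1", gamma = 0.4, se_gamma = 0.01,
                                    Gamma = 0, se_Gamma = 0.05))
  expect_equal(wald_ratio(zero)$beta, 0)

  neg <- harmonized_set(data.frame(rsid = "rs1", gamma = -0.4, se_gamma = 0.01,
                                   Gamma = -0.2, se_Gamma = 0.05))
  expect_equal(wald_ratio(neg)$beta, 0.5)
  expect_equal(wald_ratio(neg)$se, 0.125)

  undef <- harmonized_set(data.frame(rsid = "rs1", gamma = 0, se_gamma = 0.01,
                                     Gamma = 0.2, se_Gamma = 0.05))
  expect_error(wald_ratio(undef), "gamma == 0")
})

test_that("IVW reproduces the closed-form weighted mean and dispersion", {
  pairs <- pairs_from_ratios(theta = c(0.5, 0.25), se = c(0.1, 0.05))
  fe <- ivw(pairs, effects = "fixed")
  # weights 100 and 400: pooled (100*0.5 + 400*0.25) / 500 = 0.3
  expect_equal(fe$beta, 0.3, tolerance = 1e-10)
  expect_equal(fe$se, 1 / sqrt(500), tolerance = 1e-10)
  re <- ivw(pairs, effects = "random")
  # Q = 100*(0.2)^2 + 400*(0.05)^2 = 5; dispersion = sqrt(Q / 1)
  expect_equal(re$beta, 0.3, tolerance = 1e-10)
  expect_equal(re$se, sqrt(5) / sqrt(500), tolerance = 1e-10)
})

test_that("single-instrument IVW reduces to the Wald ratio", {
  pair <- harmonized_set(data.frame(rsid = "rs1", gamma = 0.4, se_gamma = 0.01,
                                    Gamma = 0.2, se_Gamma = 0.05))
  w <- wald_ratio(pair)
  for (eff in c("fixed", "random")) {
    est <- ivw(pair, effects = eff)
    expect_equal(est$beta, w$beta)
    expect_equal(est$se, w$se)
    expect_equal(est$pvalue, w$pvalue)
  }
})

test_that("fixed-effect IVW equals the no-intercept WLS slope of Gamma on gamma", {
  for (i in 1:10) {
    set.seed(500 + i)
    J <- sample(3:15, 1)
    pairs <- harmonized_set(data.frame(
      rsid = sprintf("rs%02d", 1:J), gamma = runif(J, 0.01, 0.08),
      se_gamma = runif(J, 0.001, 0.005), Gamma = rnorm(J, 0, 0.1),
      se_Gamma = runif(J, 0.02, 0.1)))
    wls <- oracle_wls(pairs$gamma, pairs$Gamma, 1 / pairs$se_Gamma^2,
                      intercept = FALSE)
    expect_equal(ivw(pairs, effects = "fixed")$beta, unname(wls$coef),
                 tolerance = 1e-10)
  }
})

test_that("random-effects SE never falls below the fixed-effect SE", {
  for (i in 1:20) {
    set.seed(600 + i)
    J <- sample(2:20, 1)
    pairs <- pairs_from_ratios(rnorm(J, 0.3, 0.2), runif(J, 0.05, 0.3))
    expect_gte(ivw(pairs, "random")$se, ivw(pairs, "fixed")$se)
  }
})

test_that("estimates are invariant under instrument permutation", {
  set.seed(71)
  pairs <- harmonized_set(data.frame(
    rsid = sprintf("rs%02d", 1:9), gamma = runif(9, 0.01, 0.08),
    se_gamma = runif(9, 0.001, 0.005), Gamma = rnorm(9, 0, 0.1),
    se_Gamma = runif(9, 0.02, 0.1)))
  perm <- harmonized_set(as.data.frame(pairs)[sample.int(9), ])
  expect_equal(ivw(pairs)$beta, ivw(perm)$beta)
  expect_equal(ivw(pairs)$se, ivw(perm)$se)
  e1 <- egger(pairs); e2 <- egger(perm)
  expect_equal(e1$slope, e2$slope)
  expect_equal(e1$intercept, e2$intercept)
  expect_equal(cochran_q(pairs)$Q, cochran_q(perm)$Q)
})

test_that("Egger recovers an exact linear law with zero residual", {
  gamma <- c(0.02, 0.05, 0.08)
  pairs <- harmonized_set(data.frame(
    rsid = c("rs1", "rs2", "rs3"), gamma = gamma, se_gamma = 0.001,
    Gamma = 0.1 + 0.5 * gamma, se_Gamma = 0.05))
  e <- egger(pairs)
  expect_equal(e$slope, 0.5, tolerance = 1e-10)
  expect_equal(e$intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$rss_w, 0, tolerance = 1e-16)
  expect_true(is.finite(e$se_slope) && e$se_slope > 0)
})

test_that("Egger matches the weighted normal-equations oracle", {
  for (i in 1:10) {
    set.seed(700 + i)
    J <- 8
    pairs <- harmonized_set(data.frame(
      rsid = sprintf("rs%02d", 1:J), gamma = runif(J, 0.01, 0.08),
      se_gamma = runif(J, 0.001, 0.005), Gamma = rnorm(J, 0, 0.1),
      se_Gamma = runif(J, 0.02, 0.1)))
    w <- 1 / pairs$se_Gamma^2
    o <- oracle_wls(pairs$gamma, pairs$Gamma, w, intercept = TRUE)
    e <- egger(pairs)
    expect_equal(e$intercept, unname(o$coef[1]), tolerance = 1e-10)
    expect_equal(e$slope, unname(o$coef[2]), tolerance = 1e-10)
    disp <- max(1, sqrt(o$rss_w / (J - 2)))
    expect_equal(e$se_intercept, sqrt(o$cov_unscaled[1, 1]) * disp,
                 tolerance = 1e-10)
    expect_equal(e$se_slope, sqrt(o$cov_unscaled[2, 2]) * disp,
                 tolerance = 1e-10)
    expect_equal(e$p_slope, 2 * pt(-abs(e$slope / e$se_slope), J - 2))
  }
  expect_error(egger(pairs_from_ratios(c(0.1, 0.2), c(0.1, 0.1))),
               "insufficient instruments")
})

test_that("odds-ratio transformation exponentiates the estimate and CI", {
  null_est <- ivw(pairs_from_ratios(0, 0.1, outcome_type = "binary"))
  expect_equal(to_or_scale(null_est)$or, 1)
  est <- harmonized_set(data.frame(rsid = sprintf("rs%d", 1:4), gamma = 1,
                                   se_gamma = 1e-8, Gamma = -1.56,
                                   se_Gamma = 2 * 0.746),
                        outcome_type = "binary")
  # construct an estimate with beta = -1.56 and se = 0.746
  r <- ivw(est, "fixed")
  expect_equal(r$beta, -1.56, tolerance = 1e-10)
  expect_equal(r$se, 0.746, tolerance = 1e-10)
  r_or <- to_or_scale(r)
  expect_equal(r_or$or, exp(-1.56), tolerance = 1e-10)
  expect_equal(r_or$or_ci_low, exp(-1.56 - 1.96 * 0.746), tolerance = 1e-10)
  expect_equal(r_or$or_ci_high, exp(-1.56 + 1.96 * 0.746), tolerance = 1e-10)
  # consistent with a reported protective association of ~0.21 (0.049-0.91)
  expect_equal(round(r_or$or, 2), 0.21)
  expect_lt(r_or$or_ci_low, r_or$or)
  expect_lt(r_or$or, r_or$or_ci_high)
  cont <- ivw(pairs_from_ratios(0.5, 0.1))
  expect_error(to_or_scale(cont), "binary")
})
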