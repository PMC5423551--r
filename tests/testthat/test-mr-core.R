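test_that("Wald ratios reproduce hand-computed values and limits", {
  # asthma CYP2R1 row: ln(0.99) / -0.052 with first-order delta SE
  wr <- wald_ratio(log(0.99), 0.01030875, -0.052)
  expect_equal(wr$estimate, 0.1932757, tolerance = 1e-6)
  expect_equal(wr$se, 0.1982451, tolerance = 1e-6)

  # a flat odds ratio forces an exactly null ratio
  expect_identical(wald_ratio(log(1.00), 0.02, -0.047)$estimate, 0)

  # second-order SE collapses to first-order when se_x = 0
  w1 <- wald_ratio(0.1, 0.05, 0.5)
  w2 <- wald_ratio(0.1, 0.05, 0.5, se_x = 0, method = "second_order")
  expect_equal(w2$se, w1$se)
  # and exceeds it when se_x > 0
  w3 <- wald_ratio(0.1, 0.05, 0.5, se_x = 0.1, method = "second_order")
  expect_gt(w3$se, w1$se)

  expect_error(wald_ratio(0.1, 0.05, 0), "weak instrument")
  expect_error(wald_ratio(0.1, 0.05, 0.5, method = "second_order"),
               "se_x")
  expect_error(wald_ratio(0.1, -0.05, 0.5), "positive")
})

test_that("IVW pooling: identity, symmetry, and the four asthma ratios", {
  one <- ivw_pool(0.19, 0.20)
  expect_equal(one$estimate, 0.19)
  expect_equal(one$se, 0.20)

  two <- ivw_pool(c(0.1, 0.3), c(0.2, 0.2))
  expect_equal(two$estimate, 0.2)
  expect_equal(two$se, 0.2 / sqrt(2))

  tabs <- vitd_study_tables()
  harm <- harmonize_tables(tabs$exposure, tabs$asthma)
  wr <- wald_ratio(harm$beta_y, harm$se_y, harm$beta_x)
  pooled <- ivw_pool(wr)
  expect_equal(pooled$estimate, -0.062345, tolerance = 1e-4)
  expect_equal(pooled$se, 0.126875, tolerance = 1e-4)

  expect_error(ivw_pool(numeric(0), numeric(0)), "at least one")
  expect_error(ivw_pool(c(1, 2), c(1, -1)), "positive")
})

test_that("IVW pooling equals weighted least squares through the origin", {
  set.seed(7)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    beta_x <- runif(k, 0.02, 0.3) * sample(c(-1, 1), k, replace = TRUE)
    beta_y <- rnorm(k, 0.05, 0.1)
    se_y <- runif(k, 0.005, 0.2)
    wr <- wald_ratio(beta_y, se_y, beta_x)
    pooled <- ivw_pool(wr)
    wls <- lm(beta_y ~ 0 + beta_x, weights = 1 / se_y^2)
    expect_lt(abs(pooled$estimate - unname(coef(wls))), 1e-10)
  }
})

test_that("pooling and heterogeneity agree with metafor's fixed-effects fit", {
  tabs <- vitd_study_tables()
  for (nm in c("asthma", "ige")) {
    harm <- harmonize_tables(tabs$exposure, tabs[[nm]])
    wr <- wald_ratio(harm$beta_y, harm$se_y, harm$beta_x)
    pooled <- ivw_pool(wr)
    het <- heterogeneity(wr)
    fit <- metafor::rma(yi = wr$estimate, sei = wr$se, method = "FE")
    expect_equal(pooled$estimate, unname(as.numeric(fit$beta)),
                 tolerance = 1e-10)
    expect_equal(pooled$se, unname(fit$se), tolerance = 1e-10)
    expect_equal(het$q, unname(fit$QE), tolerance = 1e-10)
  }
})

test_that("heterogeneity follows the Q/I2 formulas and their edge cases", {
  same <- heterogeneity(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.3))
  expect_equal(same$q, 0)
  expect_equal(same$i2, 0)
  expect_true(all(same$i2_ci >= 0 & same$i2_ci < 1))

  two <- heterogeneity(c(0, 2), c(1, 1))
  expect_equal(two$q, 2)
  expect_equal(two$i2, 0.5)

  # permutation invariance
  set.seed(11)
  e <- rnorm(5); s <- runif(5, 0.1, 1)
  perm <- sample(5)
  expect_equal(heterogeneity(e, s)$q, heterogeneity(e[perm], s[perm])$q)

  expect_error(heterogeneity(1, 1), "fewer than two")

  # I2 and its CI stay inside [0, 1) over random instances
  for (i in 1:30) {
    k <- sample(2:7, 1)
    h <- heterogeneity(rnorm(k, sd = 2), runif(k, 0.05, 0.8))
    expect_true(h$i2 >= 0 && h$i2 < 1)
    expect_true(all(h$i2_ci >= 0 & h$i2_ci < 1))
    expect_lte(h$i2_ci[1], h$i2_ci[2])
  }
})

test_that("per-SD rescaling reproduces the published asthma odds ratio", {
  pooled <- list(estimate = -0.062345, se = 0.126872)
  res <- per_sd_decrease(pooled, sigma = 0.47, or_scale = TRUE)
  expect_equal(round(res$or, 2), 1.03)
  expect_equal(res$p, 0.6232, tolerance = 1e-3)

  # a null per-unit effect maps to OR exactly 1 with a log-symmetric CI
  null <- per_sd_decrease(list(estimate = 0, se = 0.2))
  expect_equal(null$or, 1)
  expect_equal(log(null$or_ci[2]), -log(null$or_ci[1]))

  # decrease and increase are mirror images with identical p-values
  up <- per_sd_decrease(pooled, 0.47, direction = "increase")
  dn <- per_sd_decrease(pooled, 0.47, direction = "decrease")
  expect_equal(up$estimate, -dn$estimate)
  expect_equal(up$p, dn$p)

  expect_error(per_sd_decrease(pooled, sigma = -1), "positive")
})

test_that("two-sided p-values follow the normal tail", {
  expect_equal(two_sided_p(0, 1), 1)
  expect_equal(two_sided_p(qnorm(0.975), 1), 0.05)
  expect_equal(two_sided_p(-0.062345, 0.126872), 0.623, tolerance = 1e-3)
  expect_error(two_sided_p(1, 0), "positive")
})

test_that("per-study meta-analysis of one SNP pools by precision", {
  same <- ivw_meta_studies(c(0.1, 0.1), c(0.05, 0.05))
  expect_equal(same$beta, 0.1)
  expect_equal(same$se, 0.05 / sqrt(2))

  dom <- ivw_meta_studies(c(0.0, 1.0), c(0.01, 10))
  expect_lt(abs(dom$beta), 1e-5)
  expect_equal(dom$se, 0.01, tolerance = 1e-6)

  single <- ivw_meta_studies(0.3, 0.1)
  expect_equal(single$beta, 0.3)
  expect_equal(single$se, 0.1)
})

test_that("rescaling the exposure effects rescales per-unit but not per-SD", {
  tabs <- vitd_study_tables()
  fit <- mr_ivw(tabs$exposure, tabs$asthma, sigma = 0.47)
  for (c_ in c(2, -3, 0.5)) {
    exp2 <- tabs$exposure
    exp2$beta <- exp2$beta * c_
    exp2$se <- exp2$se * abs(c_)
    fit2 <- mr_ivw(exp2, tabs$asthma, sigma = 0.47 * abs(c_))
    expect_equal(fit2$estimate_per_unit, fit$estimate_per_unit / c_,
                 tolerance = 1e-12)
    # per-SD estimate is unchanged up to the orientation of the exposure
    expect_equal(fit2$estimate, sign(c_) * fit$estimate, tolerance = 1e-12)
    expect_equal(fit2$p, fit$p, tolerance = 1e-12)
  }
})

test_that("mr_ivw object exposes coherent accessors and subsets", {
  tabs <- vitd_study_tables()
  fit <- mr_ivw(tabs$exposure, tabs$asthma)
  expect_s3_class(fit, "mr_ivw")
  expect_equal(sum(weights(fit)), 1)
  expect_equal(unname(coef(fit)), fit$estimate)
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), c(fit$ci_lower, fit$ci_upper))
  expect_lt(ci[1, 1], ci[1, 2])

  # subset 'all' is the unrestricted analysis
  all_fit <- subset_analysis(tabs$exposure, tabs$asthma, "all")
  expect_equal(all_fit$estimate, fit$estimate)

  # rsid-based custom subset matches the equivalent named subset
  syn <- mr_ivw(tabs$exposure, tabs$asthma, subset = "synthesis_only")
  custom <- mr_ivw(tabs$exposure, tabs$asthma,
                   subset = c("rs10741657", "rs12785878"))
  expect_equal(custom$estimate, syn$estimate)
  expect_identical(custom$subset, "custom")

  expect_error(mr_ivw(tabs$exposure, tabs$asthma, subset = character(0)),
               "no instruments")
  missing_out <- tabs$asthma[1:3, ]
  attr(missing_out, "scale") <- "log_odds"
  class(missing_out) <- class(tabs$asthma)
  expect_error(harmonize_tables(tabs$exposure, missing_out),
               "rs6013897")
})
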