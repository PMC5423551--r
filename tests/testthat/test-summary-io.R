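test_that("odds-ratio and CI conversions match direct evaluation", {
  expect_identical(beta_from_or(1), 0)
  expect_equal(beta_from_or(0.99), -0.0100503359, tolerance = 1e-8)
  expect_equal(beta_from_or(1.03), 0.0295588022, tolerance = 1e-8)
  expect_error(beta_from_or(0), "positive")
  expect_error(beta_from_or(-1.2), "positive")

  expect_equal(se_from_ci(0.97, 1.01), 0.01030875, tolerance = 1e-5)
  expect_equal(se_from_ci(-0.23, 0.19, scale = "linear"),
               0.42 / (2 * qnorm(0.975)), tolerance = 1e-12)
  # narrow intervals give small but strictly positive SEs
  eps <- 10^-(4:8)
  expect_true(all(diff(se_from_ci(1, 1 + eps)) < 0))
  expect_true(all(se_from_ci(1, 1 + eps) > 0))
  expect_error(se_from_ci(1.01, 0.97), "below")
  expect_error(se_from_ci(-0.1, 0.1, scale = "log_odds"), "positive")
})

test_that("CI recovery round-trips through exp(beta +/- z*se)", {
  z <- qnorm(0.975)
  set.seed(41)
  for (i in 1:25) {
    lo <- runif(1, 0.5, 1); hi <- lo * exp(runif(1, 0.01, 0.5))
    se <- se_from_ci(lo, hi)
    beta <- (log(lo) + log(hi)) / 2
    expect_equal(exp(beta + c(-1, 1) * z * se), c(lo, hi),
                 tolerance = 1e-9)
  }
})

test_that("reader parses OR/CI tables and preserves order and metadata", {
  tab <- st(data.frame(rsid = c("rs2282679", "rs1"),
                       effect_allele = c("C", "A"),
                       or = c(1.01, 1.2), ci_lower = c(0.99, 1.1),
                       ci_upper = c(1.04, 1.31)),
            study_id = "meta", trait = "asthma")
  expect_s3_class(tab, "study_table")
  expect_identical(tab$rsid, c("rs2282679", "rs1"))
  expect_equal(tab$beta[1], log(1.01))
  expect_equal(tab$se[1], 0.01256938, tolerance = 1e-5)
  expect_identical(attr(tab, "scale"), "log_odds")
  expect_identical(attr(tab, "study_id"), "meta")
  expect_true(all(is.na(tab$p)))   # missing p tolerated
})

test_that("reader handles beta+CI on the linear scale", {
  tab <- st(data.frame(rsid = "rs10741657", beta = -0.02,
                       ci_lower = -0.23, ci_upper = 0.19),
            scale = "linear")
  expect_equal(tab$se, 0.1071448, tolerance = 1e-6)
  expect_identical(attr(tab, "scale"), "linear")
})

test_that("reader errors are specific and an empty table is not an error", {
  path <- write_tsv(data.frame(rsid = "rs1", beta = 0.1))
  expect_error(read_summary_table(path, "s", "t"), "effect columns")

  path <- write_tsv(data.frame(rsid = "rs1", beta = "x", se = 0.1))
  expect_error(read_summary_table(path, "s", "t"),
               "non-numeric value 'x' in column 'beta', row 1")

  path <- write_tsv(data.frame(rsid = c("rs1", "rs1"), beta = c(1, 2),
                               se = c(1, 1)))
  expect_error(read_summary_table(path, "s", "t"), "duplicate rsid.*rs1")

  empty <- st(data.frame(rsid = character(), beta = numeric(),
                         se = numeric()))
  expect_identical(nrow(empty), 0L)
})

test_that("beta/se columns take precedence over OR/CI with a warning", {
  path <- write_tsv(data.frame(rsid = "rs1", beta = 0.5, se = 0.1,
                               or = 1.2, ci_lower = 1.1, ci_upper = 1.31))
  expect_warning(tab <- read_summary_table(path, "s", "t"), "precedence")
  expect_equal(tab$beta, 0.5)
  expect_equal(tab$se, 0.1)
})

test_that("write/read round-trips the record collection exactly", {
  tabs <- vitd_study_tables()
  for (nm in names(tabs)) {
    path <- tempfile(fileext = ".tsv")
    write_summary_table(tabs[[nm]], path)
    back <- read_summary_table(path, attr(tabs[[nm]], "study_id"),
                               attr(tabs[[nm]], "trait"),
                               attr(tabs[[nm]], "scale"))
    expect_identical(as.data.frame(back), as.data.frame(tabs[[nm]]),
                     label = nm)
  }
})

test_that("harmonization flips, complements and is idempotent", {
  hp <- harmonize_pair(rec(ea = "C", oa = "T", beta = -0.05),
                       rec(ea = "C", oa = "T", beta = 0.1))
  expect_false(hp$flipped)
  expect_equal(hp$outcome$beta, 0.1)

  hp <- harmonize_pair(rec(ea = "C", oa = "A", beta = -0.05),
                       rec(ea = "A", oa = "C", beta = 0.1, eaf = 0.3))
  expect_true(hp$flipped)
  expect_equal(hp$outcome$beta, -0.1)
  expect_equal(hp$outcome$eaf, 0.7)
  expect_identical(hp$outcome$effect_allele, "C")

  # idempotent on its own output
  hp2 <- harmonize_pair(rec(ea = "C", oa = "A", beta = -0.05),
                        as.data.frame(hp$outcome))
  expect_false(hp2$flipped)
  expect_equal(hp2$outcome$beta, hp$outcome$beta)

  # strand (complement) match resolves for non-palindromic SNPs
  hp3 <- harmonize_pair(rec(ea = "C", oa = "T"), rec(ea = "G", oa = "A"))
  expect_false(hp3$flipped)
})

test_that("harmonization rejects ambiguous and incompatible alleles", {
  expect_error(harmonize_pair(rec(ea = "A", oa = "T", eaf = 0.5),
                              rec(ea = "A", oa = "T", eaf = 0.5)),
               "palindromic")
  # palindromic but frequency-resolvable: no error
  expect_no_error(harmonize_pair(rec(ea = "A", oa = "T", eaf = 0.19),
                                 rec(ea = "A", oa = "T", eaf = 0.2)))
  expect_error(harmonize_pair(rec(ea = "C", oa = "T"),
                              rec(ea = "A", oa = "C")),
               "incompatible")
  expect_error(harmonize_pair(rec(rsid = "rs1"), rec(rsid = "rs2")),
               "different SNPs")
})

test_that("proxy substitution re-keys, logs, enforces r2, and inverts", {
  tab <- st(data.frame(rsid = c("rs17217119", "rs2"),
                       beta = c(0.02, 0.1), se = c(0.01, 0.1)))
  out <- substitute_proxy(tab, "rs6013897", "rs17217119", r2 = 1.0)
  expect_identical(out$rsid, c("rs6013897", "rs2"))
  expect_identical(attr(out, "proxy_log")$proxy, "rs17217119")
  expect_equal(out$beta, tab$beta)

  expect_error(substitute_proxy(tab, "rs6013897", "rs17217119", r2 = 0.8),
               "below the required minimum")
  expect_error(substitute_proxy(tab, "rsX", "rs_absent", r2 = 1),
               "not present")

  # substituting back restores the original keying
  back <- substitute_proxy(out, "rs17217119", "rs6013897", r2 = 1.0)
  expect_identical(back$rsid, tab$rsid)
})
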