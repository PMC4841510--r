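test_that("probandwise concordance matches direct enumeration of affected individuals", {
  expect_equal(signif(probandwise_concordance(5, 189), 3), 5.03)
  expect_equal(probandwise_concordance(0, 10), 0)
  expect_equal(probandwise_concordance(3, 0), 100)
  expect_equal(probandwise_concordance(2, 4), 50)  # 4 of 8 cases have an affected co-twin
  expect_error(probandwise_concordance(0, 0),
               class = "twinpaf_undefined_statistic")
})

test_that("relative risk reproduces the implied individual-level 2x2 table", {
  expect_equal(signif(relative_risk(15668, 5, 189), 3), 8.28)
  # counts at exact independence for a per-twin risk of 0.1
  expect_equal(relative_risk(100, 1, 18), 1)
  # exposed risk 4/8, unexposed 4/12
  expect_equal(relative_risk(10, 2, 4), 1.5)
  expect_identical(relative_risk(100, 5, 0), Inf)
  expect_error(relative_risk(10, 10, 0), class = "twinpaf_undefined_statistic")
  expect_error(relative_risk(10, 0, 0), class = "twinpaf_undefined_statistic")
})

test_that("attributable fraction follows P*(RR-1)/RR with the degenerate conventions", {
  expect_equal(signif(population_attributable_fraction(15668, 5, 189), 3), 4.42)
  expect_equal(signif(population_attributable_fraction(4307, 3, 20), 3), 22.8)
  expect_equal(population_attributable_fraction(100, 1, 18), 0)  # RR = 1
  expect_equal(signif(population_attributable_fraction(10, 2, 4), 3), 16.7)
  expect_equal(population_attributable_fraction(50, 0, 20), 0)   # P = 0
  # RR -> Inf limit: PAF = P
  expect_equal(population_attributable_fraction(100, 5, 0),
               probandwise_concordance(5, 0))
  # RR below 1 is returned negative, with a warning
  expect_warning(neg <- population_attributable_fraction(100, 1, 40),
                 "negative")
  expect_lt(neg, 0)
})

test_that("estimate_concordance populates consistent estimates for whole tables", {
  est <- estimate_concordance(make_record(8437, 42, 505))
  expect_equal(signif(est$probandwise_concordance_pct, 3), 14.3)
  expect_equal(signif(est$relative_risk, 3), 4.60)
  expect_equal(signif(est$paf_pct, 3), 11.2)
  expect_equal(est$probandwise_concordance_pct,
               100 * est$risk_cotwin_affected)
  expect_false(est$rr_infinite)

  full <- estimate_concordance(mz_twin_cohorts())
  expect_equal(nrow(full), 28L)
  expect_true(all(full$paf_pct <= full$probandwise_concordance_pct + 1e-12))
  expect_true(all(full$paf_pct >= 0 & full$paf_pct <= 100))
  expect_true(all((full$relative_risk >= 1) == (full$paf_pct >= 0)))
})

test_that("estimator agrees with the brute-force individual-level oracle on small cohorts", {
  set.seed(42)
  for (i in 1:200) {
    nt <- sample(1:30, 1)
    nc <- sample(0:nt, 1)
    nd <- sample(0:(nt - nc), 1)
    orc <- oracle_stats(nt, nc, nd)
    if (is.null(orc)) {
      expect_error(relative_risk(nt, nc, nd),
                   class = "twinpaf_undefined_statistic")
      next
    }
    expect_equal(probandwise_concordance(nc, nd), orc$P)
    expect_equal(relative_risk(nt, nc, nd), orc$RR)
    expect_equal(suppressWarnings(population_attributable_fraction(nt, nc, nd)),
                 orc$PAF)
  }
})

test_that("statistics are invariant to scaling all counts and monotone in concordant pairs", {
  set.seed(7)
  for (i in 1:50) {
    nt <- sample(5:500, 1)
    nc <- sample(0:(nt %/% 2), 1)
    nd <- sample(1:(nt - nc), 1)
    k <- sample(2:20, 1)
    expect_equal(suppressWarnings(population_attributable_fraction(nt, nc, nd)),
                 suppressWarnings(population_attributable_fraction(k * nt, k * nc, k * nd)))
    expect_equal(probandwise_concordance(nc, nd),
                 probandwise_concordance(k * nc, k * nd))
  }
  # PAF = 100 * (exposed risk - unexposed risk) is nondecreasing in N_C
  # while affected pairs stay below a quarter of the cohort (the regime of
  # every realistic twin cohort; near saturation the unexposed risk rises
  # faster and the ordering can reverse)
  nt <- 400; nd <- 40
  pafs <- suppressWarnings(vapply(1:(nt %/% 4 - nd), function(nc)
    population_attributable_fraction(nt, nc, nd), numeric(1)))
  expect_true(all(diff(pafs) >= -1e-12))
})

test_that("bootstrap intervals are seed-reproducible and shrink with cohort size", {
  rec <- make_record(15668, 5, 189)
  a <- bootstrap_ci(rec, "PAF", n_resamples = 2000, seed = 11)
  b <- bootstrap_ci(rec, "PAF", n_resamples = 2000, seed = 11)
  expect_identical(a, b)
  expect_lte(a$lower, a$estimate)
  expect_gte(a$upper, a$estimate)
  expect_equal(a$estimate, population_attributable_fraction(15668, 5, 189))

  big <- bootstrap_ci(make_record(1566800, 500, 18900), "PAF",
                      n_resamples = 2000, seed = 11)
  expect_lt(big$upper - big$lower, a$upper - a$lower)

  # degenerate cohort: every pair concordant, no sampling variability in P
  deg <- bootstrap_ci(make_record(50, 50, 0), "P", n_resamples = 200, seed = 1)
  expect_equal(deg$lower, 100)
  expect_equal(deg$upper, 100)
})
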