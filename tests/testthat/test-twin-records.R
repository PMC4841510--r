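test_that("a valid single-row CSV round-trips through read_twin_table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "disease_name,category,country,sex_subset,n_pairs_total,n_concordant,n_discordant",
    "Bladder cancer,cancer,\"Sweden, Denmark, Finland\",both,15668,5,189"), path)
  rec <- read_twin_table(path)
  expect_s3_class(rec, "twin_cohort")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$n_pairs_total, 15668L)
  expect_equal(rec$n_concordant, 5L)
  expect_equal(rec$n_discordant, 189L)
  expect_equal(rec$country, "Sweden, Denmark, Finland")
})

test_that("invalid tables are rejected with informative conditions", {
  # counts exceeding the number of pairs
  expect_error(make_record(10, 6, 5), class = "twinpaf_validation_error")
  # missing column
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("disease_name,category,country,sex_subset,n_pairs_total,n_concordant",
               "X,other,Y,both,10,1"), path)
  expect_error(read_twin_table(path), "n_discordant",
               class = "twinpaf_format_error")
  # empty table
  writeLines("disease_name,category,country,sex_subset,n_pairs_total,n_concordant,n_discordant",
             path)
  expect_error(read_twin_table(path), "empty",
               class = "twinpaf_validation_error")
  # thousands separators
  writeLines(c("disease_name,category,country,sex_subset,n_pairs_total,n_concordant,n_discordant",
               "X,other,Y,both,\"15,668\",5,189"), path)
  expect_error(read_twin_table(path), class = "twinpaf_format_error")
  # category conflicting with the fixed map
  expect_error(make_record(100, 1, 2, disease = "Asthma", category = "cancer"),
               class = "twinpaf_validation_error")
  # bad sex subset
  expect_error(make_record(100, 1, 2, sex = "unknown"),
               class = "twinpaf_validation_error")
})

test_that("the bundled 28-disease dataset has the expected structure", {
  x <- mz_twin_cohorts()
  expect_equal(nrow(x), 28L)
  asthma <- x[x$disease_name == "Asthma", ]
  expect_equal(unlist(asthma[, c("n_pairs_total", "n_concordant", "n_discordant")],
                      use.names = FALSE), c(5084L, 257L, 447L))
  expect_equal(asthma$category, "lung")
  t1d <- x[x$disease_name == "Type 1 diabetes", ]
  expect_equal(unlist(t1d[, c("n_pairs_total", "n_concordant", "n_discordant")],
                      use.names = FALSE), c(4307L, 3L, 20L))
  expect_equal(t1d$category, "autoimmune")
  counts <- table(x$category)
  expect_equal(counts[["cancer"]], 9L)
  expect_equal(counts[["cardiovascular"]], 2L)
  expect_equal(counts[["neurological"]], 4L)
  expect_equal(counts[["lung"]], 2L)
  expect_equal(counts[["obesity-associated"]], 2L)
  expect_equal(counts[["autoimmune"]], 3L)
  expect_equal(counts[["genitourinary"]], 3L)
  expect_equal(counts[["other"]], 3L)
  # the eight sex-combined cancers share one pooled Nordic cohort
  pooled <- x[x$category == "cancer" & x$sex_subset == "both", ]
  expect_true(all(pooled$n_pairs_total == 15668L))
})

test_that("write_twin_table / read_twin_table is the identity on the fixture", {
  x <- mz_twin_cohorts()
  path <- withr::local_tempfile(fileext = ".csv")
  write_twin_table(x, path)
  y <- read_twin_table(path)
  expect_equal(as.data.frame(y), as.data.frame(x))
})

test_that("combine_twin_records sums counts and is order-independent", {
  one <- make_record(1000, 3, 10, sex = "female")
  expect_equal(as.data.frame(combine_twin_records(one)), as.data.frame(one))

  two <- twin_cohort(rbind(as.data.frame(one),
                           as.data.frame(make_record(1200, 2, 8, sex = "male"))))
  comb <- combine_twin_records(two)
  expect_equal(comb$n_pairs_total, 2200L)
  expect_equal(comb$n_concordant, 5L)
  expect_equal(comb$n_discordant, 18L)
  expect_equal(comb$sex_subset, "both")

  flipped <- combine_twin_records(two[2:1, ])
  expect_equal(flipped[, 5:7], comb[, 5:7])

  # combining then estimating equals estimating from hand-summed counts
  est_comb <- estimate_concordance(comb)
  est_direct <- estimate_concordance(make_record(1000 + 1200, 3 + 2, 10 + 8))
  expect_equal(est_comb$paf_pct, est_direct$paf_pct)
  expect_equal(est_comb$relative_risk, est_direct$relative_risk)

  expect_error(combine_twin_records(twin_cohort(rbind(
    as.data.frame(one), as.data.frame(make_record(10, 1, 2, disease = "Other name"))))),
    class = "twinpaf_validation_error")
  expect_error(combine_twin_records(twin_cohort(rbind(
    as.data.frame(one), as.data.frame(make_record(10, 1, 2, sex = "female"))))),
    "duplicate", class = "twinpaf_validation_error")
})
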