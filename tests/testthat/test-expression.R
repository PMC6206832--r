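test_that("cohort percentile follows the mid-rank tie rule", {
  expect_equal(cohort_percentile(5, rep(5, 10)), 50)
  expect_equal(cohort_percentile(99, 1:20), 100)
  expect_equal(cohort_percentile(7, 1:10), 65)
  expect_error(cohort_percentile(1, numeric(0)), "non-empty")
})

test_that("cohort percentile is monotone and near-uniform under resampling", {
  set.seed(3)
  cohort <- rnorm(50)
  values <- sort(rnorm(100))
  pct <- vapply(values, cohort_percentile, numeric(1),
                cohort_values = cohort)
  expect_true(all(diff(pct) >= 0))

  # percentiles of fresh draws from the cohort's own distribution are
  # approximately uniform on [0, 100]; the achievable deviation is bounded
  # below by the reference cohort's own sampling error, hence the large cohort
  big_cohort <- rnorm(4000)
  draws <- rnorm(1e4)
  u <- vapply(draws, cohort_percentile, numeric(1),
              cohort_values = big_cohort) / 100
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("expression status thresholds are inclusive at the boundaries", {
  expect_equal(call_expression_status(99), "overexpressed")
  expect_equal(call_expression_status(50), "normal")
  expect_equal(call_expression_status(5, lower = 5), "underexpressed")
  expect_equal(call_expression_status(95, upper = 95), "overexpressed")
  expect_error(call_expression_status(50, lower = 90, upper = 20), "lower")
})

test_that("every tumor gene yields exactly one expression call", {
  kb <- toy_kb_cached()
  tumor <- data.frame(gene = c("BRAF", "MET", "NOT_IN_COHORT"),
                      value = c(50, 200, 7))
  calls <- expression_calls(tumor, kb, "SKCM")
  expect_equal(nrow(calls), 3)
  expect_equal(calls$status[calls$gene == "NOT_IN_COHORT"], "no_cohort_data")
  expect_true(is.na(calls$percentile[calls$gene == "NOT_IN_COHORT"]))
  expect_equal(calls$status[calls$gene == "MET"], "overexpressed")

  expect_error(expression_calls(tumor, kb, "NO_SUCH_COHORT"), "cohort")
})

test_that("a tenfold unit mismatch triggers the guard warning", {
  kb <- toy_kb_cached()
  skcm_max <- max(kb$reference_cohorts$SKCM[["BRAF"]])
  tumor <- data.frame(gene = "BRAF", value = skcm_max * 11)
  expect_warning(expression_calls(tumor, kb, "SKCM"), "units")
})

test_that("CNV-expression concordance follows the support/contradiction rules", {
  lyn <- concordance(list(gene = "LYN", call = "amplification"),
                     list(status = "underexpressed"))
  expect_equal(lyn$verdict, "contradicted")
  expect_equal(concordance(list(gene = "g", call = "deletion"),
                           list(status = "underexpressed"))$verdict,
               "supported")
  expect_equal(concordance(list(gene = "g", call = "amplification"),
                           list(status = "normal"))$verdict,
               "uninformative")
  expect_error(concordance(list(gene = "g", call = "neutral"),
                           list(status = "normal")), "non-neutral")
})

test_that("concordance table covers non-neutral calls, uninformative without RNA", {
  cnv <- data.frame(gene = c("LYN", "MET", "KIT"), copy_number = c(8, 8, 2),
                    call = c("amplification", "amplification", "neutral"),
                    source = "wgs")
  expr <- data.frame(gene = c("LYN", "MET"), value = c(1, 99),
                     cohort = "SKCM", percentile = c(1, 99),
                     status = c("underexpressed", "overexpressed"))
  tab <- concordance_table(cnv, expr)
  expect_equal(nrow(tab), 2)  # neutral gene excluded
  expect_equal(tab$verdict[tab$gene == "LYN"], "contradicted")
  expect_equal(tab$verdict[tab$gene == "MET"], "supported")

  no_rna <- concordance_table(cnv, NULL)
  expect_true(all(no_rna$verdict == "uninformative"))
})

test_that("five-number summaries are produced for boxplot rendering", {
  kb <- toy_kb_cached()
  tumor <- data.frame(gene = c("BRAF", "NOT_IN_COHORT"), value = c(50, 1))
  calls <- expression_calls(tumor, kb, "SKCM")
  summ <- expression_summaries(calls, kb, "SKCM")
  expect_equal(summ$gene, "BRAF")
  vals <- kb$reference_cohorts$SKCM[["BRAF"]]
  expect_equal(summ$median, median(vals))
  expect_equal(summ$min, min(vals))
  expect_equal(summ$patient_value, 50)
})
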