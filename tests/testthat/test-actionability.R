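make_aberrations <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(kind = r$kind, gene = r$gene %||% "",
               detail = r$detail %||% "", evidence_value = r$ev %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("aberration collection counts each evidence type once", {
  vars <- do.call(rbind, lapply(1:4, function(i) {
    variant_row(pos = 100 * i, gene = paste0("G", i))
  }))
  cnv <- data.frame(gene = c("LYN", "MET", "KIT"), copy_number = c(8, 8, 2),
                    call = c("amplification", "amplification", "neutral"),
                    source = "wgs")
  expr <- data.frame(gene = "FGFR4", value = 40, cohort = "SKCM",
                     percentile = 99, status = "overexpressed")
  burden <- mutational_burden(data.frame(consequence = rep("missense", 150)))
  ab <- collect_aberrations(vars, cnv, expr, burden)
  expect_equal(nrow(ab), 8)  # 4 SNVs + 2 amplifications + 1 overexpression + burden
  expect_equal(sum(ab$kind == "burden_high"), 1)
  expect_equal(ab$gene[ab$kind == "burden_high"], "")

  expect_equal(nrow(collect_aberrations(vars[0, ], NULL, NULL, NULL)), 0)
})

test_that("expression-contradicted amplifications are excluded and rerouted", {
  cnv <- data.frame(gene = "LYN", copy_number = 8, call = "amplification",
                    source = "wgs")
  expr <- data.frame(gene = "LYN", value = 1, cohort = "SKCM",
                     percentile = 1, status = "underexpressed")
  conc <- concordance_table(cnv, expr)
  ab <- collect_aberrations(NULL, cnv, expr, NULL, conc)
  expect_false(any(ab$kind == "amplification"))
  # the underexpression call itself is still an aberration
  expect_true(any(ab$kind == "underexpression" & ab$gene == "LYN"))

  findings <- match_resistance(ab, toy_kb_cached(), "melanoma", conc)
  expect_true(all(c("bosutinib", "masitinib") %in% findings$affected_therapy))
  expect_match(findings$rationale[findings$affected_therapy == "bosutinib"],
               "not supported by expression")
})

test_that("therapy matching reproduces the BRAF V600E melanoma case", {
  kb <- toy_kb_cached()
  ab <- make_aberrations(list(kind = "snv_indel", gene = "BRAF",
                              detail = "V600E", ev = 0.45))
  recs <- match_therapies(ab, kb, "melanoma")
  expect_setequal(recs$drug, c("dabrafenib", "vemurafenib", "LTT462", "LXH254"))
  dab <- recs[recs$drug == "dabrafenib", ]
  expect_equal(dab$confidence, "A")
  expect_equal(dab$section, "cancer_type_specific")
  ltt <- recs[recs$drug == "LTT462", ]
  expect_equal(ltt$confidence, "D")
  expect_equal(ltt$section, "investigational")
  expect_equal(dab$pathway, "MAPK signaling")
  # approved drugs carry the approval bonus in their priority
  expect_gt(dab$priority, ltt$priority)
})

test_that("burden-high emits the checkpoint-inhibitor recommendation", {
  kb <- toy_kb_cached()
  ab <- make_aberrations(list(kind = "burden_high", detail = "826"))
  recs <- match_therapies(ab, kb, "melanoma")
  expect_equal(recs$drug, "ipilimumab")
  expect_equal(recs$section, "cancer_type_specific")
  expect_equal(recs$confidence, "A")

  none <- match_therapies(make_aberrations(
    list(kind = "snv_indel", gene = "GENE_WITHOUT_KB", detail = "X1Y")),
    kb, "melanoma")
  expect_equal(nrow(none), 0)
})

test_that("expression aberrations only match their dedicated scopes", {
  kb <- toy_kb_cached()
  over <- make_aberrations(list(kind = "overexpression", gene = "MET",
                                detail = "percentile 99", ev = 99))
  recs <- match_therapies(over, kb, "melanoma")
  expect_equal(recs$drug, "crizotinib")
  expect_equal(recs$section, "off_label")
  # an overexpression of BRAF must NOT trigger any_alteration interactions
  braf_over <- make_aberrations(list(kind = "overexpression", gene = "BRAF",
                                     detail = "percentile 99", ev = 99))
  expect_equal(nrow(match_therapies(braf_over, kb, "melanoma")), 0)
})

test_that("confidence assignment follows the A-D rules with best-level precedence", {
  pre <- list(evidence_stage = "preclinical")
  ph3 <- list(evidence_stage = "phase3")
  small <- list(evidence_stage = "smaller_study")
  expect_equal(assign_confidence(pre, "approved_same_indication"), "A")
  expect_equal(assign_confidence(pre, "not_approved"), "D")
  expect_equal(assign_confidence(pre, "approved_other_indication"), "C")
  expect_equal(assign_confidence(ph3, "not_approved"), "B")
  expect_equal(assign_confidence(small, "not_approved"), "C")
  expect_equal(assign_confidence(ph3, "approved_other_indication"), "B")
})

test_that("upgrading approval status never worsens the confidence level", {
  stages <- c("approved_same_indication_possible", "phase3", "smaller_study",
              "preclinical")
  chain <- c("not_approved", "approved_other_indication",
             "approved_same_indication")
  levels <- c(A = 1, B = 2, C = 3, D = 4)
  for (stage in stages) {
    ranks <- levels[vapply(chain, function(st) {
      assign_confidence(list(evidence_stage = stage), st)
    }, character(1))]
    expect_true(all(diff(ranks) <= 0),
                info = paste("stage", stage, ":",
                             paste(names(ranks), collapse = " -> ")))
  }
})

test_that("one drug matching via several interactions yields one merged row", {
  kb <- toy_kb_cached()
  # MET amplified and overexpressed: crizotinib matches twice for the
  # amplification aberration? no - one row per aberration-drug pair
  ab <- make_aberrations(
    list(kind = "amplification", gene = "MET", detail = "copy number 8", ev = 8),
    list(kind = "overexpression", gene = "MET", detail = "percentile 99", ev = 99))
  recs <- match_therapies(ab, kb, "melanoma")
  expect_equal(nrow(recs), 2)  # one per aberration
  expect_true(all(recs$drug == "crizotinib"))
})

test_that("resistance variants produce lacking-benefit findings with references", {
  kb <- toy_kb_cached()
  ab <- make_aberrations(
    list(kind = "snv_indel", gene = "TP53", detail = "V173L", ev = 0.3),
    list(kind = "snv_indel", gene = "ALK", detail = "G1202R", ev = 0.2),
    list(kind = "burden_low", detail = "30 non-synonymous variants", ev = 30))
  findings <- match_resistance(ab, kb, "ovarian carcinoma")
  expect_setequal(findings$affected_therapy,
                  c("carboplatin", "crizotinib", "ipilimumab"))
  expect_true(all(nzchar(findings$references)))
  expect_match(findings$rationale[findings$gene == "TP53"], "resistance")
  expect_match(findings$rationale[findings$kind == "burden_low"],
               "low mutational burden")

  no_res <- match_resistance(make_aberrations(
    list(kind = "snv_indel", gene = "BRAF", detail = "V600E")), kb, "melanoma")
  expect_equal(nrow(no_res), 0)
})

test_that("actionable count links aberrations to therapies or findings", {
  kb <- toy_kb_cached()
  ab <- make_aberrations(
    list(kind = "snv_indel", gene = "BRAF", detail = "V600E", ev = 0.4),
    list(kind = "snv_indel", gene = "TP53", detail = "V173L", ev = 0.3),
    list(kind = "snv_indel", gene = "NO_KB_GENE", detail = "A1B", ev = 0.2))
  recs <- match_therapies(ab, kb, "melanoma")
  findings <- match_resistance(ab, kb, "melanoma")
  expect_equal(count_actionable(ab, recs, findings), 2)
  expect_lte(count_actionable(ab, recs, findings), nrow(ab))
  expect_equal(count_actionable(ab[0, ], recs[0, ], findings[0, ]), 0)
  expect_equal(count_actionable(ab, recs[0, ], findings[0, ]), 0)
})

test_that("recommendations are stably sorted by section, confidence, priority", {
  kb <- toy_kb_cached()
  ab <- make_aberrations(
    list(kind = "snv_indel", gene = "BRAF", detail = "V600E", ev = 0.4),
    list(kind = "burden_high", detail = "826", ev = 826),
    list(kind = "overexpression", gene = "FGFR4", detail = "percentile 99",
         ev = 99))
  recs <- match_therapies(ab, kb, "melanoma")
  sec_rank <- match(recs$section, c("cancer_type_specific", "off_label",
                                    "investigational"))
  expect_true(all(diff(sec_rank) >= 0))
  within <- split(match(recs$confidence, LETTERS[1:4]), sec_rank)
  expect_true(all(vapply(within, function(x) all(diff(x) >= 0), logical(1))))
})
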