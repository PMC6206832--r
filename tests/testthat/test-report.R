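# A small but complete patient built directly from module outputs.
toy_bundle_inputs <- function() {
  kb <- toy_kb_cached()
  vars <- rbind(
    variant_row(gene = "BRAF", protein_change = "V600E", vaf = 0.45),
    variant_row(pos = 500, gene = "NO_KB_GENE", vaf = 0.1))
  vars <- annotate_variants(vars, kb)
  burden <- mutational_burden(data.frame(consequence = rep("missense", 150)))
  ab <- collect_aberrations(vars, NULL, NULL, burden)
  recs <- match_therapies(ab, kb, "melanoma")
  findings <- match_resistance(ab, kb, "melanoma")
  trials <- rank_trials(match_trials(recs, kb, ab))
  gs <- gene_status_overview(ab, kb$frequently_mutated$melanoma)
  meta <- list(patient_id = "P-001", cancer_type = "melanoma",
               sample_type = "fresh frozen", clinician = "Dr. X",
               hla_type = "HLA-A*02:01")
  list(kb = kb, meta = meta, ab = ab, recs = recs, findings = findings,
       trials = trials, gs = gs, burden = burden)
}

build_toy_level1 <- function(x = toy_bundle_inputs()) {
  build_level1_report(x$meta, x$ab, x$recs, x$findings, x$trials, x$gs,
                      burden = x$burden, timestamp = "2018-06-01T12:00:00Z")
}

test_that("gene status overview marks mutated, not-mutated and not-assessed genes", {
  ab <- data.frame(kind = "snv_indel", gene = "BRAF", detail = "V600E",
                   evidence_value = 0.4, stringsAsFactors = FALSE)
  gs <- gene_status_overview(ab, c("BRAF", "NRAS", "KIT"))
  expect_equal(gs$status, c("mutated", "not_mutated", "not_mutated"))
  expect_equal(gs$detail[1], "V600E")

  panel <- gene_status_overview(ab, c("BRAF", "NRAS", "KIT"),
                                assessed_genes = c("BRAF", "KIT"))
  expect_equal(panel$status[panel$gene == "NRAS"], "not_assessed")

  none <- gene_status_overview(ab[0, ], c("BRAF", "NRAS"))
  expect_true(all(none$status == "not_mutated"))
})

test_that("level-1 bundles are unfiltered and deterministic", {
  x <- toy_bundle_inputs()
  b1 <- build_toy_level1(x)
  counts <- unlist(b1$overview$section_counts)
  expect_equal(sum(counts), nrow(x$recs))
  expect_equal(nrow(b1$addendum), nrow(x$ab))

  b2 <- build_toy_level1(x)
  expect_identical(render_report(b1, "structured"),
                   render_report(b2, "structured"))

  expect_error(build_level1_report(x$meta, NULL, x$recs, x$findings,
                                   x$trials, x$gs),
               "aberrations")
})

test_that("level-2 derivation filters but keeps the full addendum", {
  b1 <- build_toy_level1()
  same <- build_level2_report(b1, list())
  expect_equal(same$level, "level2")
  same$level <- "level1"
  expect_equal(render_report(same, "structured"),
               render_report(b1, "structured"))

  filtered <- build_level2_report(b1, list(exclude_drugs = "LTT462"))
  drugs2 <- unlist(lapply(filtered$sections, function(s) s$drug))
  expect_false("LTT462" %in% drugs2)
  expect_equal(nrow(filtered$addendum), nrow(b1$addendum))
  # the LTT462 trial is dropped with its drug
  expect_false("NCT-LTT462-CH" %in% filtered$trials$trial_id)

  expect_error(build_level2_report(b1, list(exclude_drugs = "no_such_drug")),
               "absent from the level-1")
})

test_that("level-2 recommendations and trials are subsets of level-1", {
  b1 <- build_toy_level1()
  b2 <- build_level2_report(b1, list(exclude_drugs = c("LTT462", "LXH254")))
  l1_drugs <- unlist(lapply(b1$sections, function(s) s$drug))
  l2_drugs <- unlist(lapply(b2$sections, function(s) s$drug))
  expect_true(all(l2_drugs %in% l1_drugs))
  expect_true(all(b2$trials$trial_id %in% b1$trials$trial_id))
  expect_true(all(b2$lacking_benefit$affected_therapy %in%
                    b1$lacking_benefit$affected_therapy))
  # addendum covers every aberration cited by any section
  cited <- unique(unlist(lapply(b2$sections, function(s) {
    paste(s$kind, s$gene, s$detail, sep = "|")
  })))
  listed <- paste(b2$addendum$kind, b2$addendum$gene, b2$addendum$detail,
                  sep = "|")
  expect_true(all(cited %in% listed))
})

test_that("human-readable rendering shows frequencies as percent", {
  b1 <- build_toy_level1()
  md <- render_report(b1, "human_readable")
  expect_match(md, "45.0%", fixed = TRUE)
  expect_match(md, "Cancer type specific therapies")
  expect_match(md, "Therapies potentially lacking benefit")
  expect_match(md, "dabrafenib")
  expect_match(md, "Guide section")

  expect_error(render_report(b1, "pdf"), "arg")
})

test_that("structured rendering round-trips losslessly", {
  b1 <- build_toy_level1()
  json <- render_report(b1, "structured")
  back <- parse_report(json)
  expect_identical(render_report(back, "structured"), json)
})

test_that("a bundle with no matching trials still renders the trials section", {
  x <- toy_bundle_inputs()
  b <- build_level1_report(x$meta, x$ab, x$recs, x$findings,
                           x$trials[0, ], x$gs, burden = x$burden)
  md <- render_report(b, "human_readable")
  expect_match(md, "Clinical trial options")
  expect_match(md, "No matching recruiting trials")
})
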