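# oncoboard

Somatic variant interpretation and clinical reporting for molecular tumor
boards.

Precision-oncology programs sequence a patient's tumor (tumor/normal
WES/WGS with optional RNA-seq, or a tumor-only targeted panel) and must
turn the resulting calls into something a tumor board can discuss: which
aberrations are real, which drugs they sensitize to or confer resistance
against, how strong the evidence is, which trials are open, and what it all
looks like on paper. `oncoboard` implements that interpretation chain as a
deterministic engine for bioinformaticians supporting such a program:

* **Consensus calling** — per-caller somatic VCFs are normalized to minimal
  allele representation and only variants reported by at least
  `min_callers` of the callers (default 2 of 3) are kept; the merged VAF is
  the median across supporting callers. Tumor-only panel VCFs use the same
  path with `min_callers = 1`.
* **Gene-level copy number** — each gene takes the copy number of its
  largest-overlap segment; defaults call amplification at copy number ≥ 6
  and deletion at ≤ 1.
* **Cohort-relative expression** — a tumor value's percentile in a
  reference cohort is `100·(#{x < v} + ½·#{x = v})/n`; ≥ 95th percentile is
  overexpressed, ≤ 5th underexpressed. Amplifications contradicted by low
  expression are diverted to a "therapies potentially lacking benefit"
  section.
* **Tumor mutational burden** — the count of non-synonymous protein-coding
  consensus variants; strictly more than 100 is classified high (the
  melanoma checkpoint-blockade threshold).
* **Therapy matching and tiering** — aberrations are matched against a
  local drug–gene knowledge-base snapshot; each match is graded
  A (approved, same indication), B (well-powered clinical evidence),
  C (approved elsewhere / smaller studies) or D (preclinical), sectioned as
  cancer-type-specific / off-label / investigational, and prioritized by
  database support with regulator-approved drugs dominating.
* **Trials, reports, cohort statistics** — recruiting trials are ranked
  (variant-requiring first, then phase, then proximity), assembled into
  deterministic level-1 (automatic, unfiltered) and level-2 (curated
  subset) report bundles with a complete aberration addendum, and
  per-patient counts aggregate to median (IQR) cohort summaries using
  type-7 quantiles.

A seeded synthetic-patient generator (`generate_patient()`) produces
multi-caller VCFs, segment and expression tables over a 20-gene
mini-genome with exact ground truth, so the whole chain is testable without
any downloads.

## Worked example

```r
library(oncoboard)
kb  <- toy_knowledge_base()
sim <- generate_patient(simulation_config(seed = 7), tempdir())
res <- interpret_patient(
  sim$paths$vcfs, kb, read_gene_model(sim$paths$gene_model),
  cancer_type = "melanoma", segment_file = sim$paths$segments,
  expression_file = sim$paths$expression, cohort_name = "SKCM")

res$recommendations[, c("gene", "detail", "drug", "confidence", "section")]
#>   gene         detail        drug confidence              section
#> 1 BRAF          V600E  dabrafenib          A cancer_type_specific
#> 2 BRAF          V600E vemurafenib          A cancer_type_specific
#> 3  KIT chr1:118101A>G   sorafenib          C            off_label
#> 4  KIT chr1:118465A>G   sorafenib          C            off_label
#> 5 BRAF          V600E      LTT462          D      investigational
#> 6 BRAF          V600E      LXH254          D      investigational

res$burden
#> Tumor mutational burden: 30 non-synonymous variants (threshold 100) -> low

res$report
#> Clinical report bundle (level1) for patient anonymous
#>   therapies: 2 specific / 2 off-label / 2 investigational; 1 lacking benefit; 3 trials; 49 aberrations in addendum
```

The planted BRAF V600E driver is matched at level A to the two approved
BRAF inhibitors and at level D to two investigational compounds; two
incidental KIT variants pick up the off-label multikinase inhibitor via an
any-alteration rule; the low burden (30 < 100) generates a lacking-benefit
warning against CTLA-4 blockade rather than a recommendation.
`render_report(res$report, "human_readable")` prints the full Markdown
report; the JSON form round-trips via `parse_report()`.

Cohort summaries over the packaged pilot-study count tables:

```r
t1 <- read_patient_records(system.file("extdata", "table1_counts.tsv",
                                       package = "oncoboard"))
summarize_cohort(t1)
#> Cohort of 11 patients; 11 with >=1 actionable aberration (100%)
#>   n_actionable             median 5 (IQR 2)
#>   n_therapies_total        median 10 (IQR 4.5)
#>   n_cancer_type_specific   median 0 (IQR 2)
#>   n_off_label              median 4 (IQR 1)
#>   n_investigational        median 5 (IQR 3)
#>   n_lacking_benefit        median 2 (IQR 3.5)
```

A thin CLI wrapping the same functions ships in `inst/cli/oncoboard`
(subcommands `cohort-summary`, `simulate`, `interpret`).

## Package layout

| Path | Contents |
|------|----------|
| `R/` | consensus, annotation, expression, actionability, trials, report, cohort and simulation modules |
| `inst/extdata/toy_kb/` | toy knowledge-base snapshot (TSV + JSON manifest) |
| `inst/extdata/table*_counts.tsv` | pilot-study per-patient count tables |
| `vignettes/tumor-board-interpretation.Rmd` | methods and design notes |
| `tests/testthat/` | unit, property and acceptance suites |
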