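---
title: "From somatic variant calls to tiered therapy recommendations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From somatic variant calls to tiered therapy recommendations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoboard)
```

## The problem

Molecular tumor boards translate a tumor's genomic and transcriptomic
landscape into treatment options. Between the variant callers and the board
meeting sits a chain of interpretation steps: deciding which calls to trust,
attaching biological and regulatory context, matching aberrations to drugs,
grading the evidence, finding open trials, and condensing everything into a
report a clinician can act on. `oncoboard` implements that chain as a
deterministic, testable engine operating on local knowledge-base snapshots,
so a given set of inputs always produces the same report.

The engine covers comprehensive tumor/normal designs (WES/WGS plus optional
tumor RNA-seq) and tumor-only targeted panels. It deliberately does *not*
run variant callers, aligners or expression quantifiers; their outputs are
its inputs.

## Consensus variant calling

Somatic callers disagree substantially, and a single caller's private calls
are enriched for artifacts. The engine therefore merges per-caller VCFs and
keeps only variants reported by at least `min_callers` callers (default 2,
intended for a three-caller design such as MuTect + VarScan2 + Strelka).
Matching uses a normalized `(chrom, pos, ref, alt)` key only — annotation
fields are excluded on purpose, so caller-specific annotation differences
cannot break the match. Normalization trims the shared allele suffix, then
the shared prefix (advancing the position), leaving at least one base per
allele; this is the standard minimal-representation convention and is
idempotent.

Per merged variant the allele fraction is the *median* of the supporting
callers' values (missing values excluded). The median was chosen over the
mean because with three callers it is unaffected by one discordant
estimate. Panel VCFs flow through the same parser with `min_callers = 1`
and `origin_flag = "tumor_only"`.

A note on filtering order: PASS filtering is applied per caller *before*
consensus. The alternative (consensus first, filter later) would let two
callers' rejected calls form a consensus; we consider that undesirable, and
document it here as this package's choice rather than an upstream
convention.

## Copy number and expression

Gene-level copy number is derived from segment tables: each gene takes the
copy number of the segment with the largest overlap (ties go to the
lower-coordinate segment). The default call thresholds are copy number
\>= 6 for amplification and <= 1 for deletion; published reports print copy
numbers without universal thresholds, so these are exposed as parameters
and recorded with every call.

Tumor expression is judged against a reference cohort of the same cancer
type (for example a public melanoma cohort), because tumor-only RNA has no
matched normal. The percentile uses a mid-rank tie rule,
$100 \cdot (\#\{x < v\} + \tfrac12 \#\{x = v\})/n$, which is symmetric and
deterministic. Genes at or above the 95th percentile are called
overexpressed, at or below the 5th underexpressed; the literature rarely
quantifies "over- or underexpressed", so both thresholds are parameters and
the percentile is reported alongside each call. A guard warns when a tumor
value exceeds the cohort maximum more than tenfold, which almost always
means mismatched normalization units rather than biology.

Copy-number calls are cross-checked against expression: an amplification
with low expression is *contradicted* — the would-be targeted gene product
is not there — and is routed to the "therapies potentially lacking benefit"
section instead of generating recommendations.

## Mutational burden

The burden counts non-synonymous protein-coding consensus variants
(missense, nonsense, frameshift, in-frame indels and splice-site changes;
the qualifying set is configurable because splice-site inclusion is a
borderline judgment). A count strictly above 100 is classified high, the
threshold at which melanoma patients have shown favorable response to
CTLA-4 checkpoint blockade. No VAF cutoff is applied by default; a minimum
VAF is available as a parameter. The burden is modeled as one more
aberration so the same matching machinery produces both the high-burden
immunotherapy recommendation and the low-burden lacking-benefit warning,
via knowledge-base entries under the pseudo-gene `MUTATIONAL_BURDEN`.

## Knowledge base and matching

All annotation sources are local snapshot files (one TSV per entity plus a
JSON manifest): drug-gene interactions with the supporting source
databases, drug approvals with indications, clinical trials, per-cancer
frequently-mutated gene lists, gene-to-pathway mappings, optional curated
per-variant effects, and reference expression cohorts. Live services are
deliberately out of scope — snapshots make runs reproducible and the
curation auditable. Conflicting effect directions for the same drug-gene
pair are kept as separate rows and both are reported; the engine does not
adjudicate curation disagreements.

Matching rules per aberration kind:

* small variants match `specific_variant` interactions by exact protein
  change, and `any_alteration` interactions on the gene;
* amplifications and deletions match their dedicated scopes and
  `any_alteration`;
* expression aberrations match *only* `overexpression`/`underexpression`
  scopes — an expression change is not evidence for a DNA-level
  "any alteration" rule;
* burden aberrations match the `MUTATIONAL_BURDEN` entries.

Drug priority is the number of supporting source databases, plus a constant
bonus of 100 when the drug is regulator-approved, so any approved drug
outranks any unapproved one (interaction aggregators combine on the order
of 30 databases, so 100 is safely dominant).

## Confidence levels and report sections

Evidence grading follows the AMP/ASCO/CAP-style four-level scheme used in
tumor-board reports: **A** — approved for this indication; **B** —
well-powered clinical evidence (preferably phase 3); **C** — approved for a
different indication or smaller studies; **D** — preclinical only. When
several rules fire, the best level wins. One consequence, chosen
deliberately: a drug with phase-3 evidence that is also approved for
another indication grades B, not C, because the precedence rule always
takes the stronger claim. The curated evidence stage
`approved_same_indication_possible` is treated as phase-3-grade evidence
for grading purposes.

Report sections are a pure function of the regulatory status:
cancer-type-specific (approved, same indication), off-label (approved,
other indication), investigational (not approved). Rows are stable-sorted
by section, confidence, descending priority, gene and drug, so reports are
reproducible byte for byte.

Trials are matched on shared drugs among recruiting studies; ranking
prefers trials that explicitly require the observed variant, then higher
phase, then location (Switzerland, neighboring, elsewhere), with the
registry identifier as the final tiebreak. Phase outranks location because
a later-phase trial is the stronger clinical signal; the weighting order is
a documented choice. Eligibility beyond the variant requirement is left to
the clinician.

## Two-step reporting

The level-1 report is assembled automatically and completely — every
recommendation, warning and trial, plus an addendum of *all* identified
aberrations — so it can be delivered quickly. The level-2 report is the
curated version: a selection may only *remove* items present in level 1,
and the addendum always stays complete, so curation can narrow but never
silently invent. Timestamps are injected rather than sampled, making both
renderings deterministic; the structured JSON form is canonical and
round-trips losslessly, the Markdown form is derived and never parsed
back. Variant frequencies render as percent with one decimal.

## Cohort summaries

Per-patient counts (actionable aberrations; therapies split by section;
lacking-benefit findings) aggregate to median and IQR per column with
missing values excluded, plus the fraction of patients with at least one
actionable aberration. Quartiles interpolate order statistics at
$1 + (n-1)p$ (quantile type 7, the R default). That convention reproduces
all six published summary pairs of the pilot-study tables shipped under
`inst/extdata/`, which is why it is the default; it remains configurable.
"Actionable" is operationalized as: linked to at least one therapy
recommendation or one lacking-benefit finding — a resistance warning
without any recommendable drug still counts, which matches how the pilot
tables count a patient whose only finding was a resistance variant.

## The synthetic-data generator

`generate_patient()` emulates a comprehensive analysis on a two-contig
mini-genome with a 20-gene model (ten real cancer-gene symbols so the toy
knowledge base applies, ten fillers). Each true variant enters each
caller's VCF independently with the configured sensitivity; each caller
additionally receives its own false calls, placed in a coordinate range
disjoint from true variants and from other callers, so the expected
consensus set is exact by construction. The three callers write their
allele fractions in three different FORMAT dialects (`AF`, percent `FREQ`,
`AD` depths) to exercise the parser paths. A BRAF V600E driver is always
planted. Copy-number states and expression values are planted consistently
(amplified genes above the cohort maximum, deleted genes below the
minimum), and the expected recommendation set is derived from literal
lookup tables mirroring the toy knowledge base — not from the matching
engine being tested.

Defaults: 40 true variants of which 30 non-synonymous, per-caller
sensitivity 1.0 with zero false positives, 10% of genes amplified and 10%
deleted, reference cohort size 30. These defaults describe a clean,
fully-recoverable patient; noisier settings (sensitivity 0.9, five false
calls per caller) are exercised explicitly in the test suite over 30 seeds,
and the end-to-end exactness check runs 100 seeded patients at the clean
settings. What the generator does *not* emulate: read-level errors, FFPE
artifacts, subclonal structure, caller-specific error profiles, or
annotation disagreement between callers — so passing tests demonstrate the
correctness of the interpretation chain, not robustness to upstream calling
noise.

## Numerical and degenerate-input choices

* Allele normalization refuses variants whose alleles are equal after
  trimming (degenerate records) with an explicit error.
* A VCF without any allele-fraction field keeps its variants with `vaf =
  NA` and a warning; missing VAFs are excluded from the consensus median
  and never counted against a minimum-VAF filter.
* Empty reference cohorts produce `no_cohort_data` calls, never errors.
* Overlapping copy-number segments on one chromosome are rejected as
  invalid input rather than silently resolved.
* Filter status `.` is treated as passing, since panel exports often leave
  FILTER unset.
* Ties everywhere break deterministically (lower coordinate, alphabetical
  gene, lexicographic trial id).

## Worked example

```{r example, eval = FALSE}
kb <- toy_knowledge_base()
sim <- generate_patient(simulation_config(seed = 7), tempdir())
res <- interpret_patient(
  sim$paths$vcfs, kb, read_gene_model(sim$paths$gene_model),
  cancer_type = "melanoma", segment_file = sim$paths$segments,
  expression_file = sim$paths$expression, cohort_name = "SKCM")
res$recommendations[, c("gene", "detail", "drug", "confidence", "section")]
cat(render_report(res$report, "human_readable"))
```

## Known limitations

* Evidence stages are curated inputs; the engine does not mine literature.
* Resistance rules are matched irrespective of cancer type; indication
  awareness would require per-interaction indication fields in the
  snapshot.
* Burden interactions are not indication-filtered either: the confidence
  level and section (via the approval table) carry the indication signal.
* Fusion detection, germline assessment and HLA typing are out of scope;
  HLA type is consumed as metadata and reported verbatim.
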