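# End-to-end orchestration: consensus -> annotation -> expression ->
# actionability -> trials -> report, for one patient.

#' Run the full interpretation pipeline for one patient
#'
#' Parses the per-caller VCFs, applies the minimum-caller consensus rule,
#' assigns genes and annotations, derives gene-level copy-number calls and
#' cohort-relative expression calls when those inputs are provided, computes
#' the mutational burden, matches therapies, resistance findings and
#' clinical trials against the knowledge base, and assembles the automatic
#' level-1 report bundle.
#'
#' For tumor-only panel data pass a single VCF with \code{min_callers = 1}
#' and \code{origin_flag = "tumor_only"}; burden computation is typically
#' disabled there (\code{compute_burden = FALSE}) since small panels cannot
#' estimate genome-wide burden.
#'
#' @param vcf_files Named character vector mapping caller id to VCF path.
#' @param kb An \code{mtb_kb} object.
#' @param gene_model Gene model data frame (see [read_gene_model()]).
#' @param cancer_type Patient cancer-type label.
#' @param patient_meta List of patient metadata (see
#'   [build_level1_report()]); a minimal default is derived when omitted.
#' @param segment_file Optional copy-number segment TSV.
#' @param expression_file Optional tumor expression TSV (gene, value).
#' @param cohort_name Reference cohort name (required with
#'   \code{expression_file}).
#' @param min_callers Consensus threshold (default 2).
#' @param amp_threshold,del_threshold Copy-number call thresholds.
#' @param tmb_threshold Mutational-burden threshold.
#' @param compute_burden Whether to compute the mutational burden.
#' @param expr_lower,expr_upper Expression percentile thresholds.
#' @param origin_flag Variant origin recorded by the parser.
#' @param timestamp Injected report timestamp.
#' @return A list with elements \code{variants}, \code{cnv_calls},
#'   \code{expression_calls}, \code{concordance}, \code{burden},
#'   \code{aberrations}, \code{recommendations}, \code{findings},
#'   \code{n_actionable}, \code{trials}, \code{gene_status},
#'   \code{report} (the level-1 \code{mtb_report}).
#' @export
interpret_patient <- function(vcf_files, kb, gene_model, cancer_type,
                              patient_meta = NULL, segment_file = NULL,
                              expression_file = NULL, cohort_name = NULL,
                              min_callers = 2, amp_threshold = 6,
                              del_threshold = 1, tmb_threshold = 100,
                              compute_burden = TRUE, expr_lower = 5,
                              expr_upper = 95,
                              origin_flag = "somatic_matched",
                              timestamp = "1970-01-01T00:00:00Z") {
  stopifnot(inherits(kb, "mtb_kb"))
  if (is.null(names(vcf_files)) || any(!nzchar(names(vcf_files)))) {
    stop("vcf_files must be a named vector (caller id -> path)")
  }
  if (is.null(patient_meta)) {
    patient_meta <- list(patient_id = "anonymous", cancer_type = cancer_type,
                         sample_type = "tumor", clinician = "",
                         hla_type = "")
  }
  patient_meta$cancer_type <- cancer_type

  caller_sets <- lapply(names(vcf_files), function(id) {
    parse_caller_vcf(vcf_files[[id]], id, origin_flag = origin_flag)
  })
  names(caller_sets) <- names(vcf_files)
  variants <- consensus_merge(caller_sets, min_callers = min_callers)
  variants <- assign_genes(variants, gene_model)
  variants <- annotate_variants(variants, kb)

  cnv_calls <- NULL
  if (!is.null(segment_file)) {
    segments <- read_segments(segment_file)
    cnv_calls <- gene_copy_number(segments, gene_model,
                                  amp_threshold = amp_threshold,
                                  del_threshold = del_threshold)
  }

  expr_calls <- NULL
  expression_available <- !is.null(expression_file)
  if (expression_available) {
    if (is.null(cohort_name)) {
      stop("cohort_name is required when expression_file is given")
    }
    tumor <- utils::read.delim(expression_file, sep = "\t",
                               stringsAsFactors = FALSE)
    expr_calls <- expression_calls(tumor, kb, cohort_name,
                                   lower = expr_lower, upper = expr_upper)
  }

  conc <- NULL
  if (!is.null(cnv_calls)) conc <- concordance_table(cnv_calls, expr_calls)

  burden <- NULL
  if (compute_burden) {
    burden <- mutational_burden(variants, threshold = tmb_threshold)
  }

  aberrations <- collect_aberrations(variants, cnv_calls, expr_calls,
                                     burden, conc)
  recommendations <- match_therapies(aberrations, kb, cancer_type)
  findings <- match_resistance(aberrations, kb, cancer_type, conc)
  trials <- rank_trials(match_trials(recommendations, kb, aberrations))

  fm_genes <- kb$frequently_mutated[[cancer_type]] %||% character(0)
  gene_status <- gene_status_overview(aberrations, fm_genes)

  report <- build_level1_report(patient_meta, aberrations, recommendations,
                                findings, trials, gene_status,
                                burden = burden,
                                expression_available = expression_available,
                                timestamp = timestamp)
  list(variants = variants, cnv_calls = cnv_calls,
       expression_calls = expr_calls, concordance = conc, burden = burden,
       aberrations = aberrations, recommendations = recommendations,
       findings = findings,
       n_actionable = count_actionable(aberrations, recommendations, findings),
       trials = trials, gene_status = gene_status, report = report)
}
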