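# Expression module: cohort-relative expression calls and CNV-expression
# concordance. The tumor sample has no matched-normal RNA, so a gene's
# expression is judged against a reference cohort of the same cancer type
# (e.g. a public tumor expression release).

#' Percentile of a tumor expression value within a reference cohort
#'
#' Mid-rank convention: values strictly below count fully, ties count half,
#' so a value equal to the entire cohort sits at the 50th percentile and the
#' statistic is symmetric and deterministic.
#'
#' @param value Tumor expression value (same unit as the cohort).
#' @param cohort_values Numeric vector of reference-cohort values (non-empty).
#' @return Percentile in \code{[0, 100]}.
#' @export
#' @examples
#' cohort_percentile(7, 1:10)  # 65
cohort_percentile <- function(value, cohort_values) {
  cohort_values <- cohort_values[!is.na(cohort_values)]
  n <- length(cohort_values)
  if (n == 0) stop("cohort_values must be non-empty")
  100 * (sum(cohort_values < value) + 0.5 * sum(cohort_values == value)) / n
}

#' Call over/under/normal expression from a cohort percentile
#'
#' Boundaries are inclusive: a percentile at exactly the lower (upper)
#' threshold is called underexpressed (overexpressed).
#'
#' @param percentile Percentile in \code{[0, 100]}.
#' @param lower Percentile at or below which a gene is underexpressed.
#' @param upper Percentile at or above which a gene is overexpressed.
#' @return One of \code{"overexpressed"}, \code{"normal"},
#'   \code{"underexpressed"}.
#' @export
call_expression_status <- function(percentile, lower = 5, upper = 95) {
  if (!(lower < upper) || lower < 0 || upper > 100) {
    stop("thresholds must satisfy 0 <= lower < upper <= 100")
  }
  if (percentile >= upper) "overexpressed"
  else if (percentile <= lower) "underexpressed"
  else "normal"
}

#' Cohort-relative expression calls for a tumor expression table
#'
#' Produces exactly one call per gene in the tumor table. Genes absent from
#' the reference cohort get status \code{no_cohort_data}. A unit-mismatch
#' guard warns when a tumor value exceeds the cohort maximum more than
#' tenfold, which usually indicates differently normalized inputs.
#'
#' @param tumor Data frame with columns \code{gene}, \code{value}.
#' @param kb An \code{mtb_kb} object whose \code{reference_cohorts} contains
#'   \code{cohort_name}, or a named list of per-gene numeric vectors.
#' @param cohort_name Name of the reference cohort.
#' @param lower,upper Percentile thresholds (see [call_expression_status()]).
#' @return Data frame with columns gene, value, cohort, percentile, status.
#' @export
expression_calls <- function(tumor, kb, cohort_name, lower = 5, upper = 95) {
  cohort <- if (inherits(kb, "mtb_kb")) {
    if (!(cohort_name %in% names(kb$reference_cohorts))) {
      stop("reference cohort not in knowledge base: ", cohort_name)
    }
    kb$reference_cohorts[[cohort_name]]
  } else kb
  stopifnot(all(c("gene", "value") %in% names(tumor)))
  n <- nrow(tumor)
  percentile <- rep(NA_real_, n)
  status <- rep("no_cohort_data", n)
  for (i in seq_len(n)) {
    vals <- cohort[[tumor$gene[i]]]
    if (is.null(vals) || length(vals) == 0) next
    if (tumor$value[i] > 10 * max(vals)) {
      warning("tumor value for ", tumor$gene[i], " exceeds cohort maximum ",
              "more than 10-fold; check expression units")
    }
    percentile[i] <- cohort_percentile(tumor$value[i], vals)
    status[i] <- call_expression_status(percentile[i], lower, upper)
  }
  data.frame(gene = tumor$gene, value = tumor$value, cohort = cohort_name,
             percentile = percentile, status = status,
             stringsAsFactors = FALSE)
}

#' Five-number summaries for expression boxplot rendering
#'
#' @param expr_calls Output of [expression_calls()].
#' @param kb Knowledge base (or named list of per-gene cohort values).
#' @param cohort_name Reference cohort name.
#' @return Data frame with gene, min, q1, median, q3, max, patient value and
#'   percentile, one row per gene with cohort data.
#' @export
expression_summaries <- function(expr_calls, kb, cohort_name) {
  cohort <- if (inherits(kb, "mtb_kb")) kb$reference_cohorts[[cohort_name]] else kb
  keep <- expr_calls$status != "no_cohort_data"
  rows <- lapply(which(keep), function(i) {
    vals <- cohort[[expr_calls$gene[i]]]
    q <- stats::quantile(vals, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(gene = expr_calls$gene[i], min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5],
               patient_value = expr_calls$value[i],
               patient_percentile = expr_calls$percentile[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), min = numeric(), q1 = numeric(),
                      median = numeric(), q3 = numeric(), max = numeric(),
                      patient_value = numeric(),
                      patient_percentile = numeric())
  }
  out
}

#' Concordance between a copy-number call and an expression call
#'
#' A deletion is supported by low expression and contradicted by high
#' expression; an amplification is supported by high expression and
#' contradicted by low expression; normal or missing expression is
#' uninformative. Contradicted amplifications are routed downstream to the
#' therapies-potentially-lacking-benefit section, since a drug targeting an
#' amplified but silent gene is unlikely to help.
#'
#' @param cnv One copy-number call (one-row data frame or list with
#'   \code{gene}, \code{call}); the call must not be \code{neutral}.
#' @param expr One expression call (list/row with \code{gene},
#'   \code{status}).
#' @return A list with \code{gene}, \code{cnv_call}, \code{expression_status}
#'   and \code{verdict} (\code{supported}/\code{contradicted}/
#'   \code{uninformative}).
#' @export
concordance <- function(cnv, expr) {
  if (cnv$call == "neutral") stop("concordance is defined for non-neutral calls")
  verdict <- "uninformative"
  if (cnv$call == "deletion" && expr$status == "underexpressed") verdict <- "supported"
  if (cnv$call == "amplification" && expr$status == "overexpressed") verdict <- "supported"
  if (cnv$call == "deletion" && expr$status == "overexpressed") verdict <- "contradicted"
  if (cnv$call == "amplification" && expr$status == "underexpressed") verdict <- "contradicted"
  list(gene = cnv$gene, cnv_call = cnv$call,
       expression_status = expr$status, verdict = verdict)
}

#' Concordance table for all non-neutral copy-number calls
#'
#' @param cnv_calls Output of [gene_copy_number()].
#' @param expr_calls Output of [expression_calls()] (may be \code{NULL} when
#'   no RNA data is available, in which case every verdict is
#'   uninformative).
#' @return Data frame with gene, cnv_call, expression_status, verdict.
#' @export
concordance_table <- function(cnv_calls, expr_calls = NULL) {
  nn <- cnv_calls[cnv_calls$call != "neutral", , drop = FALSE]
  rows <- lapply(seq_len(nrow(nn)), function(i) {
    status <- "no_cohort_data"
    if (!is.null(expr_calls)) {
      j <- match(nn$gene[i], expr_calls$gene)
      if (!is.na(j)) status <- expr_calls$status[j]
    }
    as.data.frame(concordance(nn[i, ], list(status = status)),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), cnv_call = character(),
                      expression_status = character(), verdict = character(),
                      stringsAsFactors = FALSE)
  }
  out
}
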