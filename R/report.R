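# Report module: assemble level-1 (automatic, unfiltered) and level-2
# (curated) clinical report bundles, with an overview page, tiered therapy
# sections, a lacking-benefit section, a trials table and a full addendum.

#' Mutational status of frequently mutated genes
#'
#' The overview page lists genes frequently described as mutated in the
#' patient's cancer so the board can see at a glance whether the classic
#' drivers are affected. A gene is \code{mutated} when any aberration
#' touches it, \code{not_assessed} when it lies outside the assay's assessed
#' gene set (targeted panels), and \code{not_mutated} otherwise.
#'
#' @param aberrations Aberration table.
#' @param frequently_mutated_genes Character vector of genes for the
#'   patient's cancer type (from the knowledge base).
#' @param assessed_genes Genes covered by the assay; \code{NULL} means all
#'   listed genes were assessed (comprehensive sequencing).
#' @return Data frame with columns gene, status, detail.
#' @export
gene_status_overview <- function(aberrations, frequently_mutated_genes,
                                 assessed_genes = NULL) {
  rows <- lapply(frequently_mutated_genes, function(g) {
    if (!is.null(assessed_genes) && !(g %in% assessed_genes)) {
      return(data.frame(gene = g, status = "not_assessed", detail = "",
                        stringsAsFactors = FALSE))
    }
    hit <- aberrations[aberrations$gene == g, , drop = FALSE]
    if (nrow(hit) > 0) {
      data.frame(gene = g, status = "mutated",
                 detail = paste(unique(hit$detail), collapse = "; "),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g, status = "not_mutated", detail = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), status = character(),
                      detail = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Build the automatic, unfiltered level-1 report bundle
#'
#' The level-1 report is generated without manual inspection so it can reach
#' the clinician within a day of sequencing: it contains every
#' recommendation, finding and ranked trial, plus an addendum listing all
#' identified aberrations (actionable or not). Timestamps are injected, not
#' sampled, so that building twice from the same inputs yields an identical
#' bundle.
#'
#' @param patient_meta List with \code{patient_id}, \code{cancer_type},
#'   \code{sample_type}, \code{clinician}, \code{hla_type}.
#' @param aberrations Aberration table (becomes the addendum).
#' @param recommendations Recommendation table.
#' @param findings Lacking-benefit finding table.
#' @param trials Ranked trial table.
#' @param gene_status Output of [gene_status_overview()].
#' @param burden \code{mtb_burden} or \code{NULL}.
#' @param expression_available Whether RNA data entered the analysis; when
#'   \code{FALSE} the bundle is flagged so the report states the absence.
#' @param timestamp Fixed creation timestamp string.
#' @return An object of class \code{mtb_report}.
#' @export
build_level1_report <- function(patient_meta, aberrations, recommendations,
                                findings, trials, gene_status, burden = NULL,
                                expression_available = TRUE,
                                timestamp = "1970-01-01T00:00:00Z") {
  for (nm in c("patient_id", "cancer_type")) {
    if (is.null(patient_meta[[nm]])) {
      stop("patient_meta must provide '", nm, "'")
    }
  }
  if (is.null(aberrations)) stop("report build failed: missing stage 'aberrations'")
  if (is.null(recommendations)) stop("report build failed: missing stage 'recommendations'")
  if (is.null(findings)) stop("report build failed: missing stage 'findings'")
  if (is.null(trials)) stop("report build failed: missing stage 'trials'")
  if (is.null(gene_status)) stop("report build failed: missing stage 'gene_status'")

  section_counts <- stats::setNames(
    vapply(SECTION_LEVELS, function(s) sum(recommendations$section == s),
           integer(1)), SECTION_LEVELS)
  overview <- list(
    section_counts = as.list(section_counts),
    n_lacking_benefit = nrow(findings),
    burden = if (is.null(burden)) NULL else unclass(burden),
    gene_status = gene_status)
  structure(list(
    level = "level1",
    patient_meta = patient_meta,
    overview = overview,
    sections = split(recommendations,
                     factor(recommendations$section, levels = SECTION_LEVELS)),
    lacking_benefit = findings,
    trials = trials,
    addendum = aberrations,
    glossary_included = TRUE,
    expression_available = expression_available,
    created = timestamp), class = "mtb_report")
}

#' Derive a curated level-2 report from a level-1 bundle
#'
#' Level-2 reporting is the manually curated step: the selection may only
#' remove items present in the level-1 bundle (by drug and/or gene); the
#' addendum still lists every identified aberration. Trials whose matched
#' drugs are all removed are dropped as well.
#'
#' @param level1 An \code{mtb_report} with \code{level == "level1"}.
#' @param selection List with optional character elements
#'   \code{exclude_drugs} and \code{exclude_genes}; every name must occur in
#'   the level-1 recommendations.
#' @return An \code{mtb_report} with \code{level == "level2"}.
#' @export
build_level2_report <- function(level1, selection = list()) {
  stopifnot(inherits(level1, "mtb_report"), level1$level == "level1")
  recs <- do.call(rbind, level1$sections)
  rownames(recs) <- NULL
  exd <- selection$exclude_drugs %||% character(0)
  exg <- selection$exclude_genes %||% character(0)
  unknown <- c(setdiff(exd, recs$drug),
               setdiff(exg, c(recs$gene, level1$lacking_benefit$gene)))
  if (length(unknown) > 0) {
    stop("selection references item(s) absent from the level-1 report: ",
         paste(unknown, collapse = ", "))
  }
  keep <- !(recs$drug %in% exd) & !(recs$gene %in% exg)
  recs2 <- sort_recommendations(recs[keep, , drop = FALSE])
  findings2 <- level1$lacking_benefit[
    !(level1$lacking_benefit$gene %in% exg), , drop = FALSE]
  trials2 <- level1$trials
  if (nrow(trials2) > 0) {
    still_matched <- vapply(strsplit(trials2$matched_drugs, ",", fixed = TRUE),
                            function(d) any(d %in% recs2$drug), logical(1))
    trials2 <- trials2[still_matched, , drop = FALSE]
  }
  out <- build_level1_report(level1$patient_meta, level1$addendum, recs2,
                             findings2, trials2, level1$overview$gene_status,
                             burden = if (is.null(level1$overview$burden)) NULL
                                      else structure(level1$overview$burden,
                                                     class = "mtb_burden"),
                             expression_available = level1$expression_available,
                             timestamp = level1$created)
  out$level <- "level2"
  out
}

#' Render a report bundle
#'
#' The structured (JSON) rendering is the canonical artifact and round-trips
#' losslessly through [parse_report()]. The human-readable (Markdown)
#' rendering shows, per recommendation, the gene, variant, frequency (VAF as
#' percent with one decimal) or copy number, relative-expression percentile
#' when available, pathway/function, therapy, confidence level and
#' references.
#'
#' @param bundle An \code{mtb_report}.
#' @param format \code{"structured"} or \code{"human_readable"}.
#' @return A character scalar (JSON document or Markdown text).
#' @export
render_report <- function(bundle, format = c("structured", "human_readable")) {
  stopifnot(inherits(bundle, "mtb_report"))
  format <- match.arg(format)
  if (format == "structured") {
    return(as.character(jsonlite::toJSON(unclass(bundle), dataframe = "rows",
                                         auto_unbox = TRUE, digits = NA,
                                         null = "null", pretty = TRUE)))
  }
  render_markdown_report(bundle)
}

#' Parse a structured report document back into a bundle
#'
#' @param json JSON text produced by \code{render_report(format = "structured")}.
#' @return An \code{mtb_report}.
#' @export
parse_report <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  for (s in names(x$sections)) {
    x$sections[[s]] <- as_rec_df(x$sections[[s]], empty_recommendation_table())
  }
  x$lacking_benefit <- as_rec_df(x$lacking_benefit, empty_finding_table())
  x$addendum <- as_rec_df(x$addendum, empty_aberration_table())
  x$trials <- as_rec_df(x$trials, data.frame(
    trial_id = character(), title = character(), phase = integer(),
    matched_drugs = character(), location_class = character(),
    variant_match = logical(), stringsAsFactors = FALSE))
  x$overview$gene_status <- as_rec_df(x$overview$gene_status, data.frame(
    gene = character(), status = character(), detail = character(),
    stringsAsFactors = FALSE))
  structure(x, class = "mtb_report")
}

as_rec_df <- function(x, prototype) {
  if (is.null(x) || (is.list(x) && length(x) == 0)) return(prototype)
  as.data.frame(x, stringsAsFactors = FALSE)
}

format_evidence <- function(kind, value, detail) {
  if (kind == "snv_indel") {
    if (is.na(value)) "frequency n/a" else sprintf("%.1f%%", 100 * value)
  } else if (kind %in% c("amplification", "deletion")) {
    paste0("copy number ", value)
  } else if (kind %in% c("overexpression", "underexpression")) {
    sprintf("percentile %.1f", value)
  } else {
    detail
  }
}

render_markdown_report <- function(bundle) {
  m <- bundle$patient_meta
  lines <- c(
    paste0("# Molecular tumor board report (", bundle$level, ")"),
    "",
    paste0("Patient: ", m$patient_id, " | Cancer type: ", m$cancer_type,
           " | Sample: ", m$sample_type %||% "n/a"),
    paste0("Clinician: ", m$clinician %||% "n/a", " | HLA-I: ",
           m$hla_type %||% "n/a"),
    paste0("Created: ", bundle$created),
    "", "## Overview", "")
  sc <- bundle$overview$section_counts
  lines <- c(lines,
             paste0("Therapies: ", sc$cancer_type_specific,
                    " cancer-type specific, ", sc$off_label, " off-label, ",
                    sc$investigational, " investigational; ",
                    bundle$overview$n_lacking_benefit,
                    " potentially lacking benefit."))
  if (!is.null(bundle$overview$burden)) {
    b <- bundle$overview$burden
    lines <- c(lines, paste0("Mutational burden: ", b$nonsynonymous_count,
                             " non-synonymous variants (", b$classification,
                             ", threshold ", b$threshold, ")."))
  }
  if (!bundle$expression_available) {
    lines <- c(lines, "Gene expression data were not available for this analysis.")
  }
  gs <- bundle$overview$gene_status
  if (nrow(gs) > 0) {
    lines <- c(lines, "", "Frequently mutated genes:",
               paste0("- ", gs$gene, ": ", gs$status,
                      ifelse(nzchar(gs$detail), paste0(" (", gs$detail, ")"), "")))
  }
  section_titles <- c(cancer_type_specific = "Cancer type specific therapies",
                      off_label = "Non cancer type specific (off-label) therapies",
                      investigational = "Investigational therapies")
  for (s in names(section_titles)) {
    recs <- bundle$sections[[s]]
    lines <- c(lines, "", paste0("## ", section_titles[[s]]), "")
    if (is.null(recs) || nrow(recs) == 0) {
      lines <- c(lines, "No therapies in this category.")
      next
    }
    lines <- c(lines,
               "| Gene | Variant | Frequency or Copy number | Pathway/Function | Therapy | Confidence | References |",
               "|------|---------|--------------------------|------------------|---------|------------|------------|")
    for (i in seq_len(nrow(recs))) {
      r <- recs[i, ]
      lines <- c(lines, paste0(
        "| ", r$gene, " | ", r$detail, " | ",
        format_evidence(r$kind, r$evidence_value, r$detail), " | ",
        r$pathway, " | ", r$drug, " | ", r$confidence, " | ",
        r$references, " |"))
    }
  }
  lines <- c(lines, "", "## Therapies potentially lacking benefit", "")
  fb <- bundle$lacking_benefit
  if (nrow(fb) == 0) {
    lines <- c(lines, "No resistance-associated findings.")
  } else {
    for (i in seq_len(nrow(fb))) {
      lines <- c(lines, paste0("- ", fb$affected_therapy[i], ": ",
                               fb$rationale[i], " [", fb$references[i], "]"))
    }
  }
  lines <- c(lines, "", "## Clinical trial options", "")
  tr <- bundle$trials
  if (nrow(tr) == 0) {
    lines <- c(lines, "No matching recruiting trials were found.")
  } else {
    lines <- c(lines,
               "| Study title | Phase | Location | Drug(s) | Identifier |",
               "|-------------|-------|----------|---------|------------|")
    for (i in seq_len(nrow(tr))) {
      lines <- c(lines, paste0("| ", tr$title[i], " | ", tr$phase[i], " | ",
                               tr$location_class[i], " | ",
                               tr$matched_drugs[i], " | ", tr$trial_id[i],
                               " |"))
    }
  }
  lines <- c(lines, "", "## Addendum: all identified aberrations", "")
  ad <- bundle$addendum
  if (nrow(ad) == 0) {
    lines <- c(lines, "No aberrations identified.")
  } else {
    for (i in seq_len(nrow(ad))) {
      lines <- c(lines, paste0("- ", ad$kind[i], " ",
                               ifelse(nzchar(ad$gene[i]), ad$gene[i], "(genome-wide)"),
                               " ", ad$detail[i]))
    }
  }
  if (isTRUE(bundle$glossary_included)) {
    lines <- c(lines, "", "## Guide section", "",
               report_glossary_text())
  }
  paste(lines, collapse = "\n")
}

# Static glossary shipped with the package.
report_glossary_text <- function() {
  path <- system.file("extdata", "report_glossary.md", package = "oncoboard")
  if (nzchar(path) && file.exists(path)) {
    paste(readLines(path, warn = FALSE), collapse = "\n")
  } else {
    "Glossary unavailable."
  }
}

#' @export
print.mtb_report <- function(x, ...) {
  sc <- x$overview$section_counts
  cat("Clinical report bundle (", x$level, ") for patient ",
      x$patient_meta$patient_id, "\n", sep = "")
  cat("  therapies: ", sc$cancer_type_specific, " specific / ", sc$off_label,
      " off-label / ", sc$investigational, " investigational; ",
      x$overview$n_lacking_benefit, " lacking benefit; ",
      nrow(x$trials), " trials; ", nrow(x$addendum),
      " aberrations in addendum\n", sep = "")
  invisible(x)
}
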