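# Actionability module: collect aberrations, match them to drug-gene
# interactions, assign AMP/ASCO/CAP-style confidence levels (A-D), map the
# regulatory status onto report sections, and detect resistance /
# lacking-benefit findings.

CONFIDENCE_LEVELS <- c("A", "B", "C", "D")
SECTION_LEVELS <- c("cancer_type_specific", "off_label", "investigational")

empty_aberration_table <- function() {
  data.frame(kind = character(), gene = character(), detail = character(),
             evidence_value = numeric(), stringsAsFactors = FALSE)
}

empty_recommendation_table <- function() {
  data.frame(gene = character(), detail = character(), kind = character(),
             drug = character(), confidence = character(),
             section = character(), priority = numeric(),
             pathway = character(), references = character(),
             evidence_value = numeric(), stringsAsFactors = FALSE)
}

empty_finding_table <- function() {
  data.frame(gene = character(), detail = character(), kind = character(),
             affected_therapy = character(), rationale = character(),
             references = character(), stringsAsFactors = FALSE)
}

aberration_key <- function(ab) paste(ab$kind, ab$gene, ab$detail, sep = "|")

#' Collect reportable aberrations from all upstream analyses
#'
#' One aberration per small variant, per non-neutral copy-number call whose
#' amplification is not contradicted by expression, per over/underexpression
#' call, plus exactly one burden aberration when the mutational burden was
#' computed. Expression-contradicted amplifications are excluded here and
#' routed to the lacking-benefit machinery via the concordance table.
#'
#' @param annotated_variants Variant table (annotated or not).
#' @param cnv_calls Output of [gene_copy_number()] (may be \code{NULL}).
#' @param expression_calls Output of [expression_calls()] (may be
#'   \code{NULL}).
#' @param burden An \code{mtb_burden} object (may be \code{NULL} when TMB was
#'   not assessed, e.g. panel data).
#' @param concordance Output of [concordance_table()]; used to drop
#'   contradicted amplifications (may be \code{NULL}).
#' @return Aberration table with columns kind, gene, detail, evidence_value.
#' @export
collect_aberrations <- function(annotated_variants, cnv_calls = NULL,
                                expression_calls = NULL, burden = NULL,
                                concordance = NULL) {
  out <- list()
  if (!is.null(annotated_variants) && nrow(annotated_variants) > 0) {
    v <- annotated_variants
    detail <- ifelse(nzchar(v$protein_change), v$protein_change,
                     paste0(v$chrom, ":", v$pos, v$ref, ">", v$alt))
    out[[length(out) + 1L]] <- data.frame(
      kind = "snv_indel", gene = v$gene, detail = detail,
      evidence_value = v$vaf, stringsAsFactors = FALSE)
  }
  if (!is.null(cnv_calls) && nrow(cnv_calls) > 0) {
    nn <- cnv_calls[cnv_calls$call != "neutral", , drop = FALSE]
    if (!is.null(concordance) && nrow(concordance) > 0) {
      contradicted <- concordance$gene[concordance$verdict == "contradicted" &
                                         concordance$cnv_call == "amplification"]
      nn <- nn[!(nn$call == "amplification" & nn$gene %in% contradicted), ,
               drop = FALSE]
    }
    if (nrow(nn) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        kind = nn$call, gene = nn$gene,
        detail = paste0("copy number ", nn$copy_number),
        evidence_value = nn$copy_number, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(expression_calls) && nrow(expression_calls) > 0) {
    ex <- expression_calls[expression_calls$status %in%
                             c("overexpressed", "underexpressed"), ,
                           drop = FALSE]
    if (nrow(ex) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        kind = sub("expressed", "expression", ex$status), gene = ex$gene,
        detail = sprintf("percentile %.1f", ex$percentile),
        evidence_value = ex$percentile, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(burden)) {
    out[[length(out) + 1L]] <- data.frame(
      kind = paste0("burden_", burden$classification), gene = "",
      detail = paste0(burden$nonsynonymous_count, " non-synonymous variants"),
      evidence_value = burden$nonsynonymous_count, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_aberration_table())
  rownames(res) <- NULL
  res
}

# Does one interaction row match one aberration row? Expression aberrations
# only match their dedicated scopes; any_alteration covers genomic kinds on
# the gene; burden kinds match the MUTATIONAL_BURDEN pseudo-gene entries.
interaction_matches <- function(ia, ab) {
  if (ab$kind %in% c("burden_high", "burden_low")) {
    level <- sub("^burden_", "", ab$kind)
    return(ia$gene == BURDEN_GENE && ia$variant_scope == "specific_variant" &&
             ia$specific_variant == level)
  }
  if (ia$gene != ab$gene) return(FALSE)
  switch(ab$kind,
         snv_indel = ia$variant_scope == "any_alteration" ||
           (ia$variant_scope == "specific_variant" &&
              ia$specific_variant == ab$detail),
         amplification = ia$variant_scope %in% c("amplification", "any_alteration"),
         deletion = ia$variant_scope %in% c("deletion", "any_alteration"),
         overexpressed = ,
         overexpression = ia$variant_scope == "overexpression",
         underexpressed = ,
         underexpression = ia$variant_scope == "underexpression",
         FALSE)
}

#' Assign an evidence confidence level to an interaction
#'
#' Levels follow the AMP/ASCO/CAP-style grading used in tumor-board reports:
#' A for drugs regulator-approved in the patient's indication; B for drugs
#' with well-powered (preferably phase-3) clinical evidence; C for drugs
#' approved in a different indication or tested in smaller studies; D for
#' preclinical-only evidence. When several rules apply the best (earliest)
#' level wins, so upgrading a drug's approval status can never worsen its
#' level.
#'
#' @param interaction Interaction row/list with \code{evidence_stage}.
#' @param approval_status_value One of the values returned by
#'   [approval_status()].
#' @return \code{"A"}, \code{"B"}, \code{"C"} or \code{"D"}.
#' @export
assign_confidence <- function(interaction, approval_status_value) {
  candidates <- "D"
  if (approval_status_value == "approved_same_indication") {
    candidates <- c(candidates, "A")
  }
  if (approval_status_value == "approved_other_indication") {
    candidates <- c(candidates, "C")
  }
  stage <- interaction$evidence_stage
  if (stage %in% c("phase3", "approved_same_indication_possible")) {
    candidates <- c(candidates, "B")
  }
  if (stage == "smaller_study") candidates <- c(candidates, "C")
  CONFIDENCE_LEVELS[min(match(candidates, CONFIDENCE_LEVELS))]
}

section_for_status <- function(approval_status_value) {
  switch(approval_status_value,
         approved_same_indication = "cancer_type_specific",
         approved_other_indication = "off_label",
         not_approved = "investigational",
         stop("unknown approval status: ", approval_status_value))
}

#' Match aberrations to sensitizing therapies
#'
#' For each aberration, every sensitizing interaction whose variant scope
#' matches yields one recommendation, with confidence from
#' [assign_confidence()], report section from the drug's regulatory status,
#' and priority from [drug_priority()]. When one drug matches one aberration
#' through several interactions, the best confidence level is kept, the
#' highest priority retained, and references merged (one report row per
#' gene-drug pair). Output is stable-sorted by (section, confidence,
#' -priority, gene, drug).
#'
#' @param aberrations Aberration table from [collect_aberrations()].
#' @param kb An \code{mtb_kb} object.
#' @param cancer_type The patient's cancer-type label.
#' @return Recommendation table.
#' @export
match_therapies <- function(aberrations, kb, cancer_type) {
  stopifnot(inherits(kb, "mtb_kb"))
  ia_all <- kb$interactions[kb$interactions$effect_direction == "sensitizing", ,
                            drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(aberrations))) {
    ab <- aberrations[i, ]
    for (j in seq_len(nrow(ia_all))) {
      ia <- ia_all[j, ]
      if (!interaction_matches(ia, ab)) next
      status <- approval_status(kb, ia$drug, cancer_type)
      appr <- kb$approvals[kb$approvals$drug == ia$drug, ]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = ab$gene, detail = ab$detail, kind = ab$kind, drug = ia$drug,
        confidence = assign_confidence(ia, status),
        section = section_for_status(status),
        priority = drug_priority(ia, appr),
        pathway = unname(kb$gene_pathways[ia$gene] %|na|% ""),
        references = ia$references, evidence_value = ab$evidence_value,
        stringsAsFactors = FALSE)
    }
  }
  recs <- do.call(rbind, rows)
  if (is.null(recs)) return(empty_recommendation_table())

  # one row per (aberration, drug): best confidence, max priority, merged refs
  key <- paste(recs$gene, recs$detail, recs$kind, recs$drug, sep = "|")
  merged <- lapply(split(seq_len(nrow(recs)), key), function(idx) {
    grp <- recs[idx, , drop = FALSE]
    best <- grp[order(match(grp$confidence, CONFIDENCE_LEVELS)), , drop = FALSE][1, ]
    best$priority <- max(grp$priority)
    refs <- unique(unlist(strsplit(grp$references, ";", fixed = TRUE)))
    best$references <- paste(refs[nzchar(refs)], collapse = ";")
    best
  })
  recs <- do.call(rbind, merged)
  sort_recommendations(recs)
}

sort_recommendations <- function(recs) {
  ord <- order(match(recs$section, SECTION_LEVELS),
               match(recs$confidence, CONFIDENCE_LEVELS),
               -recs$priority, recs$gene, recs$drug)
  recs <- recs[ord, , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Detect therapies potentially lacking benefit
#'
#' Produces one finding per resistance-direction interaction matching an
#' observed aberration, one finding against immunotherapy when the burden is
#' low and the knowledge base declares the burden-low association, and one
#' finding per expression-contradicted amplification against the drugs that
#' would have targeted that amplification.
#'
#' @param aberrations Aberration table (including a burden aberration when
#'   computed).
#' @param kb An \code{mtb_kb} object.
#' @param cancer_type Patient cancer type (recorded; resistance rules in the
#'   snapshot are matched irrespective of indication).
#' @param concordance Output of [concordance_table()] (may be \code{NULL}).
#' @return Finding table with columns gene, detail, kind, affected_therapy,
#'   rationale, references.
#' @export
match_resistance <- function(aberrations, kb, cancer_type,
                             concordance = NULL) {
  stopifnot(inherits(kb, "mtb_kb"))
  ia_all <- kb$interactions[kb$interactions$effect_direction == "resistance", ,
                            drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(aberrations))) {
    ab <- aberrations[i, ]
    for (j in seq_len(nrow(ia_all))) {
      ia <- ia_all[j, ]
      if (!interaction_matches(ia, ab)) next
      rationale <- if (ab$kind == "burden_low") {
        "low mutational burden indicates limited benefit of this therapy"
      } else {
        paste0(ab$gene, " ", ab$detail,
               " is associated with resistance to this therapy")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = ab$gene, detail = ab$detail, kind = ab$kind,
        affected_therapy = ia$drug, rationale = rationale,
        references = ia$references, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(concordance) && nrow(concordance) > 0) {
    contra <- concordance[concordance$verdict == "contradicted" &
                            concordance$cnv_call == "amplification", ,
                          drop = FALSE]
    for (i in seq_len(nrow(contra))) {
      gene <- contra$gene[i]
      targets <- kb$interactions[kb$interactions$gene == gene &
                                   kb$interactions$effect_direction == "sensitizing" &
                                   kb$interactions$variant_scope %in%
                                     c("amplification", "any_alteration"), ,
                                 drop = FALSE]
      for (j in seq_len(nrow(targets))) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, detail = "amplification", kind = "amplification",
          affected_therapy = targets$drug[j],
          rationale = paste0(gene, " amplification is not supported by ",
                             "expression; targeting it likely lacks benefit"),
          references = targets$references[j], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_finding_table())
  out <- out[order(out$gene, out$affected_therapy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count actionable aberrations
#'
#' An aberration is actionable when it is linked to at least one therapy
#' recommendation or one lacking-benefit finding.
#'
#' @param aberrations Aberration table.
#' @param recommendations Recommendation table.
#' @param findings Finding table.
#' @return Integer count of distinct actionable aberrations.
#' @export
count_actionable <- function(aberrations, recommendations, findings) {
  if (nrow(aberrations) == 0) return(0L)
  keys <- aberration_key(aberrations)
  linked <- character(0)
  if (nrow(recommendations) > 0) {
    linked <- c(linked, aberration_key(recommendations))
  }
  if (nrow(findings) > 0) {
    linked <- c(linked, aberration_key(findings))
  }
  sum(unique(keys) %in% linked)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
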