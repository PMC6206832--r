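# Trials module: match recommended drugs to recruiting clinical trials and
# rank them for the report.

LOCATION_ORDER <- c("switzerland", "neighboring", "other")

#' Match recommended drugs to clinical-trial records
#'
#' A trial matches when it is recruiting and shares at least one drug with
#' the recommendations. A trial that explicitly requires the observed
#' variant (\code{required_variant_key} equal to an observed
#' \code{"GENE PCHANGE"} aberration key) is flagged, since such trials are of
#' particular interest for eligibility.
#'
#' @param recommendations Recommendation table from [match_therapies()].
#' @param kb An \code{mtb_kb} object.
#' @param aberrations Aberration table, used to evaluate variant
#'   requirements (optional).
#' @return Data frame of matched trials with columns trial_id, title, phase,
#'   matched_drugs (comma-joined), location_class, variant_match.
#' @export
match_trials <- function(recommendations, kb, aberrations = NULL) {
  stopifnot(inherits(kb, "mtb_kb"))
  drugs <- unique(recommendations$drug)
  observed_keys <- character(0)
  if (!is.null(aberrations) && nrow(aberrations) > 0) {
    snv <- aberrations[aberrations$kind == "snv_indel", , drop = FALSE]
    observed_keys <- paste(snv$gene, snv$detail)
  }
  rows <- list()
  for (i in seq_len(nrow(kb$trials))) {
    tr <- kb$trials[i, ]
    if (tr$status != "recruiting") next
    trial_drugs <- strsplit(tr$drugs, ",", fixed = TRUE)[[1]]
    matched <- intersect(trial_drugs, drugs)
    if (length(matched) == 0) next
    vm <- isTRUE(tr$requires_variant) &&
      tr$required_variant_key %in% observed_keys
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = tr$trial_id, title = tr$title, phase = tr$phase,
      matched_drugs = paste(sort(matched), collapse = ","),
      location_class = tr$location_class, variant_match = vm,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(trial_id = character(), title = character(),
                      phase = integer(), matched_drugs = character(),
                      location_class = character(),
                      variant_match = logical(), stringsAsFactors = FALSE)
  }
  out
}

#' Rank matched trials for the report
#'
#' Ordering preference: trials explicitly requiring the observed variant
#' first, then higher phase, then location (Switzerland before neighboring
#' countries before elsewhere), with the registry identifier as a final
#' deterministic tiebreak. Phase outranks location.
#'
#' @param matched Output of [match_trials()].
#' @return The same rows, ranked; a permutation of the input.
#' @export
rank_trials <- function(matched) {
  if (nrow(matched) == 0) return(matched)
  ord <- order(-as.integer(matched$variant_match), -matched$phase,
               match(matched$location_class, LOCATION_ORDER),
               matched$trial_id)
  out <- matched[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
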