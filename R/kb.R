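# Enumerations shared across the package. Kept as plain character vectors:
# validation happens at the module boundaries, not via factor levels.
VARIANT_SCOPES <- c("any_alteration", "specific_variant", "amplification",
                    "deletion", "overexpression", "underexpression")
EFFECT_DIRECTIONS <- c("sensitizing", "resistance")
EVIDENCE_STAGES <- c("approved_same_indication_possible", "phase3",
                     "smaller_study", "preclinical")
LOCATION_CLASSES <- c("switzerland", "neighboring", "other")
TRIAL_STATUSES <- c("recruiting", "other")

# Pseudo-gene under which burden-linked interactions are stored in the
# snapshot: variant_scope = specific_variant, specific_variant in {high, low}.
BURDEN_GENE <- "MUTATIONAL_BURDEN"

#' Load a knowledge-base snapshot
#'
#' Reads a directory of TSV/JSON snapshot files standing in for the live
#' annotation services used in molecular tumor boards (drug-gene interaction
#' aggregators such as DGIdb, the Swiss drug regulator Swissmedic, trial
#' registries, curated gene lists) and returns a validated knowledge base.
#'
#' The snapshot layout is one TSV per entity plus a JSON manifest:
#' \describe{
#'   \item{interactions.tsv}{gene, drug, variant_scope, specific_variant,
#'     effect_direction, databases (comma-joined), evidence_stage, references}
#'   \item{approvals.tsv}{drug, approved_indications (semicolon-joined),
#'     swissmedic_approved (TRUE/FALSE)}
#'   \item{trials.tsv}{trial_id, title, phase, drugs (comma-joined),
#'     location_class, requires_variant, required_variant_key, status}
#'   \item{frequently_mutated.tsv}{cancer_type, rank, gene}
#'   \item{pathways.tsv}{gene, pathway}
#'   \item{variant_effects.tsv}{optional; gene, protein_change, known_effect,
#'     functional_impact, databases, identifiers}
#'   \item{cohort_<name>.tsv}{gene, value1..valueN reference expression values}
#'   \item{manifest.json}{snapshot_date, databases}
#' }
#'
#' Burden-linked interactions (e.g. high mutational burden sensitizing to
#' checkpoint blockade) are stored under the pseudo-gene
#' \code{MUTATIONAL_BURDEN} with \code{variant_scope = "specific_variant"} and
#' \code{specific_variant} \code{"high"} or \code{"low"}.
#'
#' @param directory_path Directory containing the snapshot files.
#' @return An object of class \code{mtb_kb}: a list with elements
#'   \code{interactions}, \code{approvals}, \code{trials},
#'   \code{frequently_mutated} (named list of gene vectors),
#'   \code{gene_pathways} (named character), \code{variant_effects},
#'   \code{reference_cohorts} (named list of per-gene value lists) and
#'   \code{manifest}.
#' @export
#' @examples
#' kb <- load_knowledge_base(system.file("extdata/toy_kb", package = "oncoboard"))
#' nrow(kb$interactions)
load_knowledge_base <- function(directory_path) {
  if (!dir.exists(directory_path)) {
    stop("knowledge-base directory not found: ", directory_path)
  }
  need <- c("interactions.tsv", "approvals.tsv", "trials.tsv",
            "frequently_mutated.tsv", "pathways.tsv", "manifest.json")
  missing <- need[!file.exists(file.path(directory_path, need))]
  if (length(missing) > 0) {
    stop("knowledge-base snapshot is missing required file(s): ",
         paste(missing, collapse = ", "))
  }

  read_tsv <- function(f) {
    utils::read.delim(file.path(directory_path, f), sep = "\t",
                      stringsAsFactors = FALSE, colClasses = "character",
                      na.strings = NULL)
  }

  interactions <- read_tsv("interactions.tsv")
  approvals <- read_tsv("approvals.tsv")
  approvals$swissmedic_approved <- as.logical(approvals$swissmedic_approved)
  trials <- read_tsv("trials.tsv")
  trials$phase <- as.integer(trials$phase)
  trials$requires_variant <- as.logical(trials$requires_variant)

  fm <- read_tsv("frequently_mutated.tsv")
  fm$rank <- as.integer(fm$rank)
  fm <- fm[order(fm$cancer_type, fm$rank), , drop = FALSE]
  frequently_mutated <- split(fm$gene, fm$cancer_type)

  pw <- read_tsv("pathways.tsv")
  gene_pathways <- stats::setNames(pw$pathway, pw$gene)

  variant_effects <- NULL
  if (file.exists(file.path(directory_path, "variant_effects.tsv"))) {
    variant_effects <- read_tsv("variant_effects.tsv")
  }

  cohort_files <- list.files(directory_path, pattern = "^cohort_.*\\.tsv$")
  reference_cohorts <- list()
  for (f in cohort_files) {
    nm <- sub("^cohort_(.*)\\.tsv$", "\\1", f)
    tab <- utils::read.delim(file.path(directory_path, f), sep = "\t",
                             stringsAsFactors = FALSE)
    vals <- lapply(seq_len(nrow(tab)), function(i) {
      v <- suppressWarnings(as.numeric(tab[i, -1]))
      v[!is.na(v)]
    })
    reference_cohorts[[nm]] <- stats::setNames(vals, tab[[1]])
  }

  manifest <- jsonlite::read_json(file.path(directory_path, "manifest.json"),
                                  simplifyVector = TRUE)

  kb <- structure(
    list(interactions = interactions, approvals = approvals, trials = trials,
         frequently_mutated = frequently_mutated,
         gene_pathways = gene_pathways, variant_effects = variant_effects,
         reference_cohorts = reference_cohorts, manifest = manifest),
    class = "mtb_kb")
  validate_kb(kb)
  kb
}

#' Validate knowledge-base cross-references and invariants
#'
#' @param kb An \code{mtb_kb} object.
#' @return \code{kb}, invisibly; stops with a validation error otherwise.
#' @keywords internal
validate_kb <- function(kb) {
  ia <- kb$interactions
  required_cols <- c("gene", "drug", "variant_scope", "specific_variant",
                     "effect_direction", "databases", "evidence_stage",
                     "references")
  miss <- setdiff(required_cols, names(ia))
  if (length(miss) > 0) {
    stop("interactions table lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad_scope <- setdiff(unique(ia$variant_scope), VARIANT_SCOPES)
  if (length(bad_scope) > 0) {
    stop("unknown variant_scope value(s): ", paste(bad_scope, collapse = ", "))
  }
  bad_dir <- setdiff(unique(ia$effect_direction), EFFECT_DIRECTIONS)
  if (length(bad_dir) > 0) {
    stop("unknown effect_direction value(s): ", paste(bad_dir, collapse = ", "))
  }
  bad_stage <- setdiff(unique(ia$evidence_stage), EVIDENCE_STAGES)
  if (length(bad_stage) > 0) {
    stop("unknown evidence_stage value(s): ", paste(bad_stage, collapse = ", "))
  }
  if (any(!nzchar(ia$databases))) {
    stop("every interaction must cite at least one supporting database")
  }
  # specific_variant non-empty iff scope is specific_variant
  sv <- ia$variant_scope == "specific_variant"
  if (any(sv & !nzchar(ia$specific_variant)) ||
      any(!sv & nzchar(ia$specific_variant))) {
    stop("specific_variant must be set exactly when variant_scope is ",
         "'specific_variant'")
  }

  dangling <- setdiff(unique(ia$drug), kb$approvals$drug)
  if (length(dangling) > 0) {
    stop("interaction drug(s) missing from approvals: ",
         paste(sort(dangling), collapse = ", "))
  }
  unapproved <- !kb$approvals$swissmedic_approved
  if (any(unapproved & nzchar(kb$approvals$approved_indications))) {
    stop("drugs with swissmedic_approved = FALSE must have empty ",
         "approved_indications")
  }

  rv <- kb$trials$requires_variant
  if (any(rv & !nzchar(kb$trials$required_variant_key))) {
    stop("trials with requires_variant = TRUE must name required_variant_key")
  }
  bad_loc <- setdiff(unique(kb$trials$location_class), LOCATION_CLASSES)
  if (length(bad_loc) > 0) {
    stop("unknown location_class value(s): ", paste(bad_loc, collapse = ", "))
  }

  fm_genes <- unique(unlist(kb$frequently_mutated, use.names = FALSE))
  no_pathway <- setdiff(fm_genes, names(kb$gene_pathways))
  if (length(no_pathway) > 0) {
    stop("frequently-mutated gene(s) lack a pathway entry: ",
         paste(sort(no_pathway), collapse = ", "))
  }
  invisible(kb)
}

#' Serialize a knowledge base back to a snapshot directory
#'
#' Writes the same TSV/JSON layout read by [load_knowledge_base()], so that
#' load -> write -> load round-trips.
#'
#' @param kb An \code{mtb_kb} object.
#' @param directory_path Output directory (created if absent).
#' @return \code{directory_path}, invisibly.
#' @export
write_knowledge_base <- function(kb, directory_path) {
  stopifnot(inherits(kb, "mtb_kb"))
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) {
    utils::write.table(df, file.path(directory_path, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(kb$interactions, "interactions.tsv")
  wr(kb$approvals, "approvals.tsv")
  wr(kb$trials, "trials.tsv")
  fm <- do.call(rbind, lapply(names(kb$frequently_mutated), function(ct) {
    genes <- kb$frequently_mutated[[ct]]
    data.frame(cancer_type = ct, rank = seq_along(genes), gene = genes,
               stringsAsFactors = FALSE)
  }))
  wr(fm, "frequently_mutated.tsv")
  wr(data.frame(gene = names(kb$gene_pathways),
                pathway = unname(kb$gene_pathways),
                stringsAsFactors = FALSE), "pathways.tsv")
  if (!is.null(kb$variant_effects)) wr(kb$variant_effects, "variant_effects.tsv")
  for (nm in names(kb$reference_cohorts)) {
    coh <- kb$reference_cohorts[[nm]]
    width <- max(lengths(coh))
    mat <- t(vapply(coh, function(v) c(v, rep(NA_real_, width - length(v))),
                    numeric(width)))
    df <- data.frame(gene = names(coh), mat, stringsAsFactors = FALSE)
    names(df) <- c("gene", paste0("value", seq_len(width)))
    wr(df, paste0("cohort_", nm, ".tsv"))
  }
  jsonlite::write_json(kb$manifest, file.path(directory_path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(directory_path)
}

#' Regulatory approval status of a drug for a cancer type
#'
#' Classifies a drug relative to the patient's indication: approved for this
#' cancer type, approved but for a different indication (off-label candidate),
#' or not approved at all (investigational).
#'
#' @param kb An \code{mtb_kb} object.
#' @param drug Drug name; must exist in the approvals table.
#' @param cancer_type Cancer-type label of the patient.
#' @return One of \code{"approved_same_indication"},
#'   \code{"approved_other_indication"}, \code{"not_approved"}.
#' @export
#' @examples
#' kb <- toy_knowledge_base()
#' approval_status(kb, "dabrafenib", "melanoma")
approval_status <- function(kb, drug, cancer_type) {
  stopifnot(inherits(kb, "mtb_kb"))
  i <- match(drug, kb$approvals$drug)
  if (is.na(i)) stop("drug not present in approvals table: ", drug)
  if (!kb$approvals$swissmedic_approved[i]) return("not_approved")
  indications <- strsplit(kb$approvals$approved_indications[i], ";",
                          fixed = TRUE)[[1]]
  if (cancer_type %in% indications) "approved_same_indication"
  else "approved_other_indication"
}

#' Priority score of a drug-gene interaction
#'
#' The more source databases support an interaction, the higher the priority;
#' regulator-approved drugs outrank all unapproved drugs regardless of
#' database support. The score is the number of supporting databases plus a
#' constant \code{approved_bonus} added for approved drugs; the default bonus
#' (100) exceeds the roughly 30 databases aggregated by interaction resources,
#' so the approved/unapproved dominance holds for any realistic count.
#'
#' @param interaction One interaction: a one-row data frame or list with a
#'   \code{databases} field (comma-joined string or character vector).
#' @param approval The drug's approval entry: a one-row data frame or list
#'   with logical \code{swissmedic_approved}.
#' @param approved_bonus Constant added for regulator-approved drugs.
#' @return Numeric priority score.
#' @export
drug_priority <- function(interaction, approval, approved_bonus = 100) {
  dbs <- interaction$databases
  if (length(dbs) == 1 && is.character(dbs)) {
    dbs <- strsplit(dbs, ",", fixed = TRUE)[[1]]
  }
  n_db <- sum(nzchar(trimws(dbs)))
  n_db + if (isTRUE(as.logical(approval$swissmedic_approved))) approved_bonus else 0
}

#' @export
print.mtb_kb <- function(x, ...) {
  cat("Molecular tumor board knowledge base (snapshot ",
      x$manifest$snapshot_date %||% "unknown", ")\n", sep = "")
  cat("  interactions: ", nrow(x$interactions),
      " | drugs: ", nrow(x$approvals),
      " | trials: ", nrow(x$trials), "\n", sep = "")
  cat("  cancer types with gene lists: ",
      paste(names(x$frequently_mutated), collapse = ", "), "\n", sep = "")
  cat("  reference cohorts: ",
      paste(names(x$reference_cohorts), collapse = ", "), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
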