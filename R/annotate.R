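# Annotation module: attach knowledge-base context to consensus variants and
# compute the tumor mutational burden biomarker.

# Consequence classes counted as non-synonymous protein-coding; splice-site
# changes are included by default as protein-affecting.
NONSYNONYMOUS_CLASSES <- c("missense", "nonsense", "frameshift",
                           "inframe_indel", "splice_site")

#' Annotate consensus variants with knowledge-base information
#'
#' Best-effort annotation: every input variant appears exactly once in the
#' output; variants in genes the knowledge base does not know receive empty
#' annotations but are never dropped. Pathway comes from the gene-pathway
#' map; known effect (gain/loss of function), functional impact and database
#' identifiers come from the per-variant effect table when the (gene,
#' protein change) pair is curated there.
#'
#' @param variants Variant table (with \code{gene} filled in).
#' @param kb An \code{mtb_kb} object.
#' @return The variant table with added columns \code{pathway},
#'   \code{functional_impact}, \code{known_effect}, \code{database_hits}
#'   (comma-joined \code{db:id} pairs).
#' @export
#' @examples
#' kb <- toy_knowledge_base()
#' v <- data.frame(chrom = "chr1", pos = 1000L, ref = "T", alt = "A",
#'                 gene = "BRAF", protein_change = "V600E", vaf = 0.45,
#'                 callers = "mutect", consequence = "missense",
#'                 origin_flag = "somatic_matched")
#' annotate_variants(v, kb)[, c("gene", "pathway", "known_effect")]
annotate_variants <- function(variants, kb) {
  stopifnot(inherits(kb, "mtb_kb"))
  n <- nrow(variants)
  variants$pathway <- rep("", n)
  variants$functional_impact <- rep("unknown", n)
  variants$known_effect <- rep("unknown", n)
  variants$database_hits <- rep("", n)
  if (n == 0) return(variants)

  known <- variants$gene %in% names(kb$gene_pathways)
  variants$pathway[known] <- unname(kb$gene_pathways[variants$gene[known]])

  ve <- kb$variant_effects
  if (!is.null(ve) && nrow(ve) > 0) {
    key <- paste(variants$gene, variants$protein_change)
    idx <- match(key, paste(ve$gene, ve$protein_change))
    hit <- !is.na(idx) & nzchar(variants$protein_change)
    variants$known_effect[hit] <- ve$known_effect[idx[hit]]
    variants$functional_impact[hit] <- ve$functional_impact[idx[hit]]
    dbs <- strsplit(ve$databases[idx[hit]], ",", fixed = TRUE)
    ids <- strsplit(ve$identifiers[idx[hit]], ",", fixed = TRUE)
    variants$database_hits[hit] <- mapply(function(d, i) {
      paste(paste0(d, ":", i), collapse = ",")
    }, dbs, ids)
    declared <- kb$manifest$databases
    if (!is.null(declared)) {
      used <- unique(unlist(dbs, use.names = FALSE))
      undecl <- setdiff(used, declared)
      if (length(undecl) > 0) {
        stop("variant_effects cites database(s) absent from the manifest: ",
             paste(undecl, collapse = ", "))
      }
    }
  }
  variants
}

#' Tumor mutational burden
#'
#' Counts non-synonymous protein-coding variants (missense, nonsense,
#' frameshift, in-frame indel and, by default, splice-site changes) and
#' classifies the burden as high when the count strictly exceeds the
#' threshold. A burden above 100 such mutations has been associated with
#' response to CTLA-4 checkpoint blockade in melanoma, which is why the
#' default threshold is 100; a burden at or below it flags limited expected
#' benefit of that immunotherapy.
#'
#' @param variants Variant table with a \code{consequence} column.
#' @param threshold Count strictly above which the burden is high.
#' @param min_vaf Optional minimum allele fraction for a variant to count
#'   (default 0, i.e. no VAF filter); variants with missing VAF always count.
#' @param qualifying Consequence classes counted as non-synonymous.
#' @return A list of class \code{mtb_burden}: \code{nonsynonymous_count},
#'   \code{threshold}, \code{classification} (\code{"high"}/\code{"low"}).
#' @export
#' @examples
#' v <- data.frame(consequence = rep(c("missense", "synonymous"), c(180, 120)))
#' mutational_burden(v)$nonsynonymous_count  # 180
mutational_burden <- function(variants, threshold = 100, min_vaf = 0,
                              qualifying = NONSYNONYMOUS_CLASSES) {
  stopifnot(threshold >= 1)
  keep <- variants$consequence %in% qualifying
  if (min_vaf > 0 && "vaf" %in% names(variants)) {
    keep <- keep & (is.na(variants$vaf) | variants$vaf >= min_vaf)
  }
  count <- sum(keep)
  structure(list(nonsynonymous_count = count, threshold = threshold,
                 classification = if (count > threshold) "high" else "low"),
            class = "mtb_burden")
}

#' @export
print.mtb_burden <- function(x, ...) {
  cat("Tumor mutational burden: ", x$nonsynonymous_count,
      " non-synonymous variants (threshold ", x$threshold, ") -> ",
      x$classification, "\n", sep = "")
  invisible(x)
}
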