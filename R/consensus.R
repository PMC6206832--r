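# Consensus module: per-caller VCF ingestion, allele normalization, the
# minimum-caller consensus rule, and gene-level copy-number calls.

CONSEQUENCES <- c("missense", "nonsense", "splice_site", "synonymous",
                  "frameshift", "inframe_indel", "other")

# SnpEff/VEP-style effect terms mapped onto the coarse consequence enum.
CONSEQUENCE_MAP <- c(
  missense_variant = "missense", missense = "missense",
  stop_gained = "nonsense", nonsense = "nonsense",
  splice_acceptor_variant = "splice_site", splice_donor_variant = "splice_site",
  splice_region_variant = "splice_site", splice_site = "splice_site",
  synonymous_variant = "synonymous", synonymous = "synonymous",
  frameshift_variant = "frameshift", frameshift = "frameshift",
  inframe_insertion = "inframe_indel", inframe_deletion = "inframe_indel",
  inframe_indel = "inframe_indel")

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(),
             protein_change = character(), vaf = numeric(),
             callers = character(), consequence = character(),
             origin_flag = character(), stringsAsFactors = FALSE)
}

#' Normalize a variant representation
#'
#' Trims alleles to their minimal representation so that the same event
#' reported differently by different callers matches on one key: the shared
#' suffix is removed first, then the shared prefix (advancing the position),
#' always leaving at least one base in each allele. The operation is
#' idempotent.
#'
#' @param chrom Contig name.
#' @param pos 1-based position.
#' @param ref,alt Allele strings (non-empty, no commas).
#' @return A list with elements \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @export
#' @examples
#' normalize_variant("1", 100, "CA", "CG")  # -> pos 101, A>G
normalize_variant <- function(chrom, pos, ref, alt) {
  if (!nzchar(ref) || !nzchar(alt)) stop("ref and alt must be non-empty")
  if (ref == alt) stop("degenerate variant: ref equals alt after input")
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  # shared suffix
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # shared prefix, advancing pos
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  ref2 <- paste(r, collapse = "")
  alt2 <- paste(a, collapse = "")
  if (ref2 == alt2) stop("degenerate variant: ref equals alt after trimming")
  list(chrom = chrom, pos = as.integer(pos), ref = ref2, alt = alt2)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

normalize_variant_table <- function(df) {
  if (nrow(df) == 0) return(df)
  for (i in seq_len(nrow(df))) {
    nv <- normalize_variant(df$chrom[i], df$pos[i], df$ref[i], df$alt[i])
    df$pos[i] <- nv$pos
    df$ref[i] <- nv$ref
    df$alt[i] <- nv$alt
  }
  df
}

#' Parse one caller's somatic VCF
#'
#' Reads a VCF 4.x file, keeps passing records (FILTER \code{PASS} or
#' \code{.}), decomposes multi-allelic records, normalizes each allele pair,
#' and derives the tumor variant allele fraction from, in order of
#' preference, FORMAT \code{AF}, FORMAT \code{FREQ} (percent strings as
#' written by VarScan), or FORMAT \code{AD} (alt depth over total depth).
#' When no such field is present the variant is retained with \code{vaf = NA}
#' and a warning is emitted.
#'
#' Gene symbol, consequence and protein change are read from the INFO keys
#' \code{GENE}, \code{EFFECT} and \code{PCHANGE} when the upstream annotation
#' wrote them (SnpEff/VEP effect terms are mapped onto the coarse consequence
#' classes); otherwise they are left empty for downstream annotation.
#'
#' @param file Path to a VCF file.
#' @param caller_id Identifier recorded in the \code{callers} field.
#' @param tumor_sample Sample name holding the tumor genotype; defaults to
#'   the sample named \code{TUMOR} if present, else the last sample column.
#' @param origin_flag \code{"somatic_matched"} for tumor/normal callers,
#'   \code{"tumor_only"} for single-sample panel VCFs.
#' @return A variant table (data frame) with one row per decomposed variant:
#'   chrom, pos, ref, alt, gene, protein_change, vaf, callers, consequence,
#'   origin_flag.
#' @export
parse_caller_vcf <- function(file, caller_id, tumor_sample = NULL,
                             origin_flag = "somatic_matched") {
  if (!file.exists(file)) stop("VCF file not found: ", file)
  check_vcf_lines(file)
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) return(empty_variant_table())

  gene <- info_field(vcf, "GENE")
  effect <- info_field(vcf, "EFFECT")
  pchange <- info_field(vcf, "PCHANGE")

  samples <- colnames(vcf@gt)[-1]
  if (is.null(tumor_sample)) {
    tumor_sample <- if ("TUMOR" %in% samples) "TUMOR" else samples[length(samples)]
  }
  af <- gt_field(vcf, "AF", tumor_sample)
  freq <- gt_field(vcf, "FREQ", tumor_sample)
  ad <- gt_field(vcf, "AD", tumor_sample)

  rows <- list()
  missing_vaf <- FALSE
  for (i in seq_len(n)) {
    filt <- fix[i, "FILTER"]
    if (!is.na(filt) && !(filt %in% c("PASS", "."))) next
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      vaf <- allele_fraction(af[i], freq[i], ad[i], allele_index = k)
      if (is.na(vaf)) missing_vaf <- TRUE
      nv <- normalize_variant(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                              fix[i, "REF"], alts[k])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = nv$chrom, pos = nv$pos, ref = nv$ref, alt = nv$alt,
        gene = gene[i], protein_change = pchange[i], vaf = vaf,
        callers = caller_id, consequence = map_consequence(effect[i]),
        origin_flag = origin_flag, stringsAsFactors = FALSE)
    }
  }
  if (missing_vaf) {
    warning("no allele-fraction field (AF/FREQ/AD) for one or more records ",
            "in ", basename(file), "; vaf recorded as NA")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_variant_table())
  rownames(out) <- NULL
  out
}

# Cheap structural validation so malformed files fail with a line number
# rather than an opaque parser error.
check_vcf_lines <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (!any(startsWith(lines, "#CHROM"))) {
    stop("not a VCF (no #CHROM header line): ", file)
  }
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) < 8) {
      stop("malformed VCF record at line ", i, " of ", file,
           " (fewer than 8 tab-separated fields)")
    }
  }
  invisible(TRUE)
}

info_field <- function(vcf, key) {
  out <- suppressWarnings(vcfR::extract.info(vcf, element = key))
  if (is.null(out)) out <- rep(NA_character_, nrow(vcf@fix))
  out[is.na(out)] <- ""
  out
}

gt_field <- function(vcf, key, sample) {
  if (ncol(vcf@gt) < 2) return(rep(NA_character_, nrow(vcf@fix)))
  m <- tryCatch(vcfR::extract.gt(vcf, element = key),
                error = function(e) NULL)
  if (is.null(m) || !(sample %in% colnames(m))) {
    return(rep(NA_character_, nrow(vcf@fix)))
  }
  m[, sample]
}

allele_fraction <- function(af, freq, ad, allele_index = 1) {
  if (!is.na(af) && nzchar(af)) {
    parts <- suppressWarnings(as.numeric(strsplit(af, ",", fixed = TRUE)[[1]]))
    v <- parts[min(allele_index, length(parts))]
    if (!is.na(v)) return(v)
  }
  if (!is.na(freq) && nzchar(freq)) {
    parts <- strsplit(freq, ",", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(sub("%", "", parts[min(allele_index, length(parts))],
                                         fixed = TRUE)))
    if (!is.na(v)) return(v / 100)
  }
  if (!is.na(ad) && nzchar(ad)) {
    depths <- suppressWarnings(as.numeric(strsplit(ad, ",", fixed = TRUE)[[1]]))
    if (length(depths) >= allele_index + 1 && !anyNA(depths) && sum(depths) > 0) {
      return(depths[allele_index + 1] / sum(depths))
    }
  }
  NA_real_
}

map_consequence <- function(effect) {
  if (is.na(effect) || !nzchar(effect)) return("other")
  out <- CONSEQUENCE_MAP[[effect]]
  if (is.null(out)) "other" else out
}

#' Merge per-caller variant sets with a minimum-caller consensus rule
#'
#' Retains exactly the variants whose normalized (chrom, pos, ref, alt) key
#' is reported by at least \code{min_callers} callers; requiring support from
#' two of three independent somatic callers suppresses caller-specific false
#' positives. The merged record carries the union of supporting callers and
#' the median of their non-missing allele fractions; annotation fields take
#' the first non-empty value. For single-caller panel data use
#' \code{min_callers = 1}, which returns the input set unchanged.
#'
#' @param caller_sets Named list mapping caller id to a variant table as
#'   returned by [parse_caller_vcf()].
#' @param min_callers Minimum number of supporting callers (default 2).
#' @return A merged variant table ordered by (chrom, pos, ref, alt).
#' @export
consensus_merge <- function(caller_sets, min_callers = 2) {
  if (min_callers < 1) stop("min_callers must be >= 1")
  if (length(caller_sets) == 0) stop("at least one caller set is required")
  if (is.null(names(caller_sets)) || any(!nzchar(names(caller_sets)))) {
    stop("caller_sets must be a named list")
  }
  combined <- do.call(rbind, lapply(names(caller_sets), function(id) {
    df <- caller_sets[[id]]
    if (nrow(df) == 0) return(NULL)
    df <- normalize_variant_table(df)
    df$callers <- id
    df
  }))
  if (is.null(combined) || nrow(combined) == 0) return(empty_variant_table())

  key <- variant_key(combined$chrom, combined$pos, combined$ref, combined$alt)
  merged <- lapply(split(seq_len(nrow(combined)), key), function(idx) {
    grp <- combined[idx, , drop = FALSE]
    support <- unique(grp$callers)
    if (length(support) < min_callers) return(NULL)
    vafs <- grp$vaf[!is.na(grp$vaf)]
    first_nonempty <- function(x) {
      x <- x[!is.na(x) & nzchar(x)]
      if (length(x) > 0) x[1] else ""
    }
    data.frame(
      chrom = grp$chrom[1], pos = grp$pos[1], ref = grp$ref[1],
      alt = grp$alt[1], gene = first_nonempty(grp$gene),
      protein_change = first_nonempty(grp$protein_change),
      vaf = if (length(vafs) > 0) stats::median(vafs) else NA_real_,
      callers = paste(sort(support), collapse = ","),
      consequence = {
        cons <- grp$consequence[grp$consequence != "other"]
        if (length(cons) > 0) cons[1] else "other"
      },
      origin_flag = grp$origin_flag[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  if (is.null(out)) return(empty_variant_table())
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene model table
#'
#' @param file TSV with columns gene, chrom, start, end (1-based inclusive).
#' @return Data frame with those columns.
#' @export
read_gene_model <- function(file) {
  gm <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gm)))
  if (anyDuplicated(gm$gene)) stop("gene symbols in the gene model must be unique")
  if (any(gm$start > gm$end)) stop("gene model intervals must have start <= end")
  gm
}

gene_model_granges <- function(model) {
  GenomicRanges::GRanges(model$chrom,
                         IRanges::IRanges(model$start, model$end),
                         gene = model$gene)
}

#' Assign gene symbols to variants from a gene model
#'
#' Variants falling outside every modeled gene keep an empty symbol.
#' Overlapping genes are resolved to the alphabetically first symbol for
#' determinism.
#'
#' @param variants Variant table.
#' @param model Gene model data frame (see [read_gene_model()]).
#' @return The variant table with \code{gene} filled in.
#' @export
assign_genes <- function(variants, model) {
  if (nrow(variants) == 0) return(variants)
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  gr <- gene_model_granges(model)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vr, gr))
  if (length(hits) > 0) {
    df <- data.frame(q = S4Vectors::queryHits(hits),
                     gene = gr$gene[S4Vectors::subjectHits(hits)],
                     stringsAsFactors = FALSE)
    df <- df[order(df$q, df$gene), , drop = FALSE]
    df <- df[!duplicated(df$q), , drop = FALSE]
    variants$gene[df$q] <- df$gene
  }
  variants
}

#' Read copy-number segments
#'
#' @param file TSV/BED-like file with columns chrom, start, end, copy_number.
#' @param zero_based Set \code{TRUE} for BED-dialect 0-based half-open
#'   coordinates; the default expects 1-based inclusive coordinates.
#' @return Data frame with 1-based inclusive coordinates.
#' @export
read_segments <- function(file, zero_based = FALSE) {
  seg <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "copy_number") %in% names(seg)))
  if (zero_based) seg$start <- seg$start + 1L
  seg
}

#' Gene-level copy-number calls from segments
#'
#' Each gene takes the copy number of the overlapping segment with the
#' largest overlap (ties broken toward the lower-coordinate segment) and is
#' called amplified or deleted against the thresholds. Genes with no
#' overlapping segment are omitted; overlapping segments on one chromosome
#' are rejected as invalid input.
#'
#' @param segments Data frame with chrom, start, end, copy_number (1-based
#'   inclusive; see [read_segments()]).
#' @param model Gene model data frame.
#' @param amp_threshold Copy number at or above which a gene is called
#'   amplified (default 6).
#' @param del_threshold Copy number at or below which a gene is called
#'   deleted (default 1).
#' @param source \code{"wgs"} or \code{"wes"}, recorded per call.
#' @return Data frame with columns gene, copy_number, call
#'   (amplification/deletion/neutral), source.
#' @export
gene_copy_number <- function(segments, model, amp_threshold = 6,
                             del_threshold = 1, source = "wgs") {
  if (!(amp_threshold > del_threshold) || del_threshold < 0) {
    stop("thresholds must satisfy amp_threshold > del_threshold >= 0")
  }
  for (chr in unique(segments$chrom)) {
    s <- segments[segments$chrom == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("overlapping segments on chromosome ", chr)
    }
  }
  gr_seg <- GenomicRanges::GRanges(segments$chrom,
                                   IRanges::IRanges(segments$start, segments$end))
  gr_gene <- gene_model_granges(model)
  # segments on contigs without modeled genes are valid input
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_gene, gr_seg))
  if (length(hits) == 0) {
    return(data.frame(gene = character(), copy_number = numeric(),
                      call = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(gr_gene[qh], gr_seg[sh]))
  pick <- data.frame(gene_i = qh, seg_i = sh, overlap = ov,
                     seg_start = segments$start[sh])
  pick <- pick[order(pick$gene_i, -pick$overlap, pick$seg_start), , drop = FALSE]
  pick <- pick[!duplicated(pick$gene_i), , drop = FALSE]
  cn <- segments$copy_number[pick$seg_i]
  call <- ifelse(cn >= amp_threshold, "amplification",
                 ifelse(cn <= del_threshold, "deletion", "neutral"))
  out <- data.frame(gene = model$gene[pick$gene_i], copy_number = cn,
                    call = call, source = source, stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}

#' Write a merged variant table as TSV
#'
#' @param variants Merged variant table.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_variant_table <- function(variants, file) {
  utils::write.table(variants, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a merged variant set as a minimal VCF with a CALLERS INFO tag
#'
#' @param variants Merged variant table.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_consensus_vcf <- function(variants, file) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Supporting callers\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Median tumor allele fraction\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  body <- character(0)
  if (nrow(variants) > 0) {
    info <- paste0("CALLERS=", variants$callers,
                   ifelse(is.na(variants$vaf), "",
                          sprintf(";VAF=%.4f", variants$vaf)),
                   ifelse(nzchar(variants$gene),
                          paste0(";GENE=", variants$gene), ""))
    body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                  variants$alt, ".", "PASS", info, sep = "\t")
  }
  writeLines(c(header, body), file)
  invisible(file)
}
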