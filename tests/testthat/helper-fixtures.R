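# Shared fixture builders and independent oracles.

variant_row <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "C",
                        gene = "", protein_change = "", vaf = 0.3,
                        callers = "c1", consequence = "missense",
                        origin_flag = "somatic_matched") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             gene = gene, protein_change = protein_change, vaf = vaf,
             callers = callers, consequence = consequence,
             origin_flag = origin_flag, stringsAsFactors = FALSE)
}

# Write a small VCF from body lines; the FORMAT columns are optional.
write_test_vcf <- function(body, file = tempfile(fileext = ".vcf"),
                           format_ids = c("AF")) {
  fmt <- c(
    AF = "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
    FREQ = "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"FREQ\">",
    AD = "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    GT = "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"gene\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"effect\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"pchange\">",
    unname(fmt[c("GT", format_ids)]),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "NORMAL", "TUMOR", sep = "\t"))
  writeLines(c(header, body), file)
  file
}

# Independent normalization oracle: longest-common-affix arithmetic rather
# than the iterative trim used by the implementation.
oracle_normalize <- function(chrom, pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  common_suffix <- 0
  while (common_suffix < min(length(r), length(a)) &&
         r[length(r) - common_suffix] == a[length(a) - common_suffix]) {
    common_suffix <- common_suffix + 1
  }
  cut <- min(common_suffix, length(r) - 1, length(a) - 1)
  r <- r[seq_len(length(r) - cut)]
  a <- a[seq_len(length(a) - cut)]
  common_prefix <- 0
  while (common_prefix < min(length(r), length(a)) &&
         r[common_prefix + 1] == a[common_prefix + 1]) {
    common_prefix <- common_prefix + 1
  }
  cut <- min(common_prefix, length(r) - 1, length(a) - 1)
  if (cut > 0) {
    r <- r[-seq_len(cut)]
    a <- a[-seq_len(cut)]
  }
  list(chrom = chrom, pos = as.integer(pos + cut),
       ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# Independent quantile oracle: explicit sorted-order-statistic interpolation
# at position 1 + (n - 1) p.
oracle_median_iqr <- function(values) {
  values <- sort(values[!is.na(values)])
  n <- length(values)
  at <- function(p) {
    h <- 1 + (n - 1) * p
    lo <- floor(h)
    hi <- ceiling(h)
    values[lo] + (h - lo) * (values[hi] - values[lo])
  }
  c(median = at(0.5), iqr = at(0.75) - at(0.25))
}

# Brute-force consensus oracle over key sets.
oracle_consensus_keys <- function(key_sets, min_callers = 2) {
  counts <- table(unlist(lapply(key_sets, unique)))
  sort(names(counts)[counts >= min_callers])
}

random_indel_pair <- function() {
  bases <- c("A", "C", "G", "T")
  len_r <- sample(1:6, 1)
  len_a <- sample(1:6, 1)
  ref <- paste(sample(bases, len_r, replace = TRUE), collapse = "")
  alt <- paste(sample(bases, len_a, replace = TRUE), collapse = "")
  if (ref == alt) return(NULL)
  list(ref = ref, alt = alt)
}

toy_kb_cached <- local({
  kb <- NULL
  function() {
    if (is.null(kb)) kb <<- toy_knowledge_base()
    kb
  }
})
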