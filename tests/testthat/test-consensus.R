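test_that("VCF parsing filters non-PASS records and decomposes multi-allelics", {
  f <- write_test_vcf(c(
    "chr1\t100\t.\tA\tC\t.\tPASS\tGENE=BRAF;EFFECT=missense_variant\tGT:AF\t0/0:0.0\t0/1:0.40",
    "chr1\t200\t.\tG\tT\t.\tlowqual\tGENE=TP53\tGT:AF\t0/0:0.0\t0/1:0.10",
    "chr1\t300\t.\tA\tC,T\t.\tPASS\t.\tGT:AF\t0/0:0.0\t0/1:0.25,0.05"))
  v <- parse_caller_vcf(f, "mutect")
  expect_equal(nrow(v), 3)  # 1 PASS SNV + 2 alleles; non-PASS dropped
  expect_setequal(v$pos[v$chrom == "chr1"], c(100L, 300L, 300L))
  expect_equal(sort(v$alt[v$pos == 300]), c("C", "T"))
  expect_equal(v$vaf[v$pos == 300 & v$alt == "T"], 0.05)
  expect_equal(v$gene[v$pos == 100], "BRAF")
  expect_equal(v$consequence[v$pos == 100], "missense")
  expect_true(all(v$callers == "mutect"))
})

test_that("allele fraction falls back from AF to FREQ to AD, else NA with warning", {
  f_freq <- write_test_vcf(
    "chr1\t100\t.\tA\tC\t.\tPASS\t.\tGT:FREQ\t0/0:0.0%\t0/1:20%",
    format_ids = "FREQ")
  expect_equal(parse_caller_vcf(f_freq, "varscan")$vaf, 0.20)

  f_ad <- write_test_vcf(
    "chr1\t100\t.\tA\tC\t.\tPASS\t.\tGT:AD\t0/0:100,0\t0/1:80,20",
    format_ids = "AD")
  expect_equal(parse_caller_vcf(f_ad, "strelka")$vaf, 0.20)

  f_none <- write_test_vcf(
    "chr1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1",
    format_ids = character(0))
  expect_warning(v <- parse_caller_vcf(f_none, "x"), "allele-fraction")
  expect_true(is.na(v$vaf))
})

test_that("malformed VCF input fails with a line number", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               "chr1\t100\tonly-three-fields"), bad)
  expect_error(parse_caller_vcf(bad, "x"), "line 3")
  notvcf <- tempfile(fileext = ".vcf")
  writeLines("gene\tvalue", notvcf)
  expect_error(parse_caller_vcf(notvcf, "x"), "#CHROM")
})

test_that("variant normalization trims shared affixes and is idempotent", {
  expect_equal(normalize_variant("1", 100, "CA", "CG"),
               list(chrom = "1", pos = 101L, ref = "A", alt = "G"))
  expect_equal(normalize_variant("1", 100, "A", "G"),
               list(chrom = "1", pos = 100L, ref = "A", alt = "G"))
  expect_equal(normalize_variant("1", 100, "ATT", "AT"),
               list(chrom = "1", pos = 100L, ref = "AT", alt = "A"))
  expect_error(normalize_variant("1", 100, "AA", "AA"), "degenerate")

  set.seed(42)
  checked <- 0
  while (checked < 20) {
    pair <- random_indel_pair()
    if (is.null(pair)) next
    got <- tryCatch(normalize_variant("2", 500, pair$ref, pair$alt),
                    error = function(e) "degenerate")
    want <- oracle_normalize("2", 500, pair$ref, pair$alt)
    if (identical(got, "degenerate")) {
      expect_equal(want$ref, want$alt)  # oracle agrees it collapses
    } else {
      expect_equal(got, want)
      # idempotence
      expect_equal(normalize_variant(got$chrom, got$pos, got$ref, got$alt), got)
    }
    checked <- checked + 1
  }
})

test_that("consensus keeps variants supported by at least min_callers callers", {
  v1 <- variant_row(pos = 100)
  v2 <- variant_row(pos = 200, vaf = 0.5)
  v3 <- variant_row(pos = 300)
  sets <- list(A = rbind(v1, v2), B = rbind(v2, v3), C = v2)
  merged <- consensus_merge(sets, min_callers = 2)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$pos, 200L)
  expect_equal(merged$callers, "A,B,C")

  # three identical sets come back unchanged
  s <- rbind(v1, v2, v3)
  same <- consensus_merge(list(a = s, b = s, c = s), min_callers = 2)
  expect_setequal(same$pos, s$pos)

  # panel path: single caller with min_callers = 1 returns the input set
  panel <- consensus_merge(list(panel = s), min_callers = 1)
  expect_setequal(panel$pos, s$pos)
  expect_equal(panel$vaf[order(panel$pos)], s$vaf[order(s$pos)])

  expect_error(consensus_merge(sets, min_callers = 0), "min_callers")
})

test_that("consensus vaf is the median of supporting callers, missing excluded", {
  mk <- function(vaf, caller) variant_row(pos = 100, vaf = vaf, callers = caller)
  merged <- consensus_merge(list(a = mk(0.1, "a"), b = mk(0.5, "b"),
                                 c = mk(0.3, "c")))
  expect_equal(merged$vaf, 0.3)
  merged2 <- consensus_merge(list(a = mk(0.1, "a"), b = mk(NA, "b")))
  expect_equal(merged2$vaf, 0.1)
})

test_that("consensus equals the brute-force counting oracle and is order independent", {
  set.seed(7)
  for (rep in 1:25) {
    pool <- sample(50:400, 12)
    key_sets <- lapply(1:3, function(k) sample(pool, sample(3:10, 1)))
    sets <- lapply(key_sets, function(keys) {
      do.call(rbind, lapply(keys, function(p) variant_row(pos = p)))
    })
    names(sets) <- c("a", "b", "c")
    merged <- consensus_merge(sets, min_callers = 2)
    expect_equal(sort(as.character(merged$pos)),
                 oracle_consensus_keys(lapply(key_sets, as.character)))
    # permuting the caller enumeration changes nothing
    merged_rev <- consensus_merge(rev(sets), min_callers = 2)
    expect_equal(merged, merged_rev)
    # output is a subset of the union with enough supporters each
    expect_true(all(lengths(strsplit(merged$callers, ",")) >= 2))
  }
})

test_that("gene copy number uses thresholds and the largest-overlap rule", {
  model <- data.frame(gene = c("G1", "G2", "G3"), chrom = "chr1",
                      start = c(100, 1000, 5000), end = c(199, 1999, 5999))
  segments <- data.frame(chrom = "chr1", start = c(50, 900, 5000, 5600),
                         end = c(500, 2500, 5599, 5999),
                         copy_number = c(8, 2, 1, 2))
  calls <- gene_copy_number(segments, model, amp_threshold = 6,
                            del_threshold = 1)
  expect_equal(calls$call[calls$gene == "G1"], "amplification")
  expect_equal(calls$call[calls$gene == "G2"], "neutral")
  # G3: 60% of the gene in the CN-1 segment, 40% in CN-2 -> deletion
  expect_equal(calls$call[calls$gene == "G3"], "deletion")

  overlapping <- data.frame(chrom = "chr1", start = c(100, 150),
                            end = c(200, 300), copy_number = c(2, 2))
  expect_error(gene_copy_number(overlapping, model), "overlapping segments")

  no_hit <- gene_copy_number(data.frame(chrom = "chr9", start = 1, end = 10,
                                        copy_number = 4), model)
  expect_equal(nrow(no_hit), 0)  # genes without segments are omitted
})

test_that("consensus output can be written as TSV and tagged VCF", {
  v <- rbind(variant_row(pos = 100, gene = "BRAF", vaf = 0.4,
                         callers = "a,b"),
             variant_row(pos = 200, callers = "a,c"))
  tsv <- tempfile(fileext = ".tsv")
  write_variant_table(v, tsv)
  expect_equal(nrow(read.delim(tsv)), 2)
  vcf <- tempfile(fileext = ".vcf")
  write_consensus_vcf(v, vcf)
  lines <- readLines(vcf)
  expect_true(any(grepl("^#CHROM", lines)))
  expect_true(any(grepl("CALLERS=a,b", lines)))
})
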