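# Fixtures module: a deterministic toy knowledge base encoding well-known
# drug-gene relations, a synthetic two-contig mini-genome with a 20-gene
# model, and a seeded generator producing multi-caller VCFs, copy-number
# segments and expression tables with exact ground truth.

SIM_GENES <- c("BRAF", "NRAS", "KIT", "TP53", "ALK", "GNA11", "MET", "LYN",
               "FGFR4", "CDKN2A", paste0("OB", sprintf("%02d", 11:20)))

#' Synthetic mini-genome gene model
#'
#' Twenty genes on two synthetic contigs (ten per contig), each 10 kb wide
#' and well separated, so interval logic can be exercised without a
#' reference genome. The first ten symbols are real cancer genes so the toy
#' knowledge base applies to them.
#'
#' @return Gene model data frame (gene, chrom, start, end).
#' @export
mini_gene_model <- function() {
  n <- length(SIM_GENES)
  chrom <- rep(c("chr1", "chr2"), each = n / 2)
  start <- rep(50000 + (seq_len(n / 2) - 1) * 30000, 2)
  data.frame(gene = SIM_GENES, chrom = chrom, start = start,
             end = start + 9999, stringsAsFactors = FALSE)
}

#' Deterministic toy knowledge base
#'
#' Encodes well-described drug-gene relations used throughout the package's
#' integration tests: BRAF V600E sensitizing to BRAF inhibitors (dabrafenib,
#' vemurafenib) and the investigational compounds LTT462/LXH254; NRAS Q61K
#' to the MEK inhibitor trametinib; GNA11 Q209L to sorafenib; TP53 V173L
#' conferring platinum resistance; ALK G1202R conferring ALK-inhibitor
#' resistance; high mutational burden sensitizing to (and low burden arguing
#' against) CTLA-4 checkpoint blockade; LYN amplification to
#' bosutinib/masitinib; FGFR4/MET overexpression to ponatinib/crizotinib;
#' CDKN2A loss to palbociclib. Reference expression cohorts cover all
#' mini-genome genes with deterministic values.
#'
#' @return An \code{mtb_kb} object.
#' @export
toy_knowledge_base <- function() {
  ia <- function(gene, drug, scope, sv, dir, dbs, stage, refs) {
    data.frame(gene = gene, drug = drug, variant_scope = scope,
               specific_variant = sv, effect_direction = dir,
               databases = dbs, evidence_stage = stage, references = refs,
               stringsAsFactors = FALSE)
  }
  interactions <- rbind(
    ia("BRAF", "dabrafenib", "specific_variant", "V600E", "sensitizing",
       "DGIdb,MyCancerGenome,CIViC,OncoKB", "approved_same_indication_possible",
       "PMID:22608338"),
    ia("BRAF", "vemurafenib", "specific_variant", "V600E", "sensitizing",
       "DGIdb,MyCancerGenome,CIViC", "approved_same_indication_possible",
       "PMID:21639808"),
    ia("BRAF", "LTT462", "any_alteration", "", "sensitizing",
       "DGIdb", "preclinical", "NCT02711345"),
    ia("BRAF", "LXH254", "any_alteration", "", "sensitizing",
       "DGIdb", "preclinical", "NCT02607813"),
    ia("NRAS", "trametinib", "specific_variant", "Q61K", "sensitizing",
       "DGIdb,MyCancerGenome", "phase3", "PMID:22663011"),
    ia("GNA11", "sorafenib", "specific_variant", "Q209L", "sensitizing",
       "DGIdb", "smaller_study", "PMID:21083380"),
    ia("KIT", "sorafenib", "any_alteration", "", "sensitizing",
       "DGIdb,MyCancerGenome", "smaller_study", "PMID:18488160"),
    ia("TP53", "carboplatin", "specific_variant", "V173L", "resistance",
       "COSMIC", "smaller_study", "PMID:21941004"),
    ia("ALK", "crizotinib", "specific_variant", "G1202R", "resistance",
       "COSMIC,MyCancerGenome", "smaller_study", "PMID:27432227"),
    ia(BURDEN_GENE, "ipilimumab", "specific_variant", "high", "sensitizing",
       "MyCancerGenome", "phase3", "PMID:25409260"),
    ia(BURDEN_GENE, "ipilimumab", "specific_variant", "low", "resistance",
       "MyCancerGenome", "phase3", "PMID:25409260"),
    ia("LYN", "bosutinib", "amplification", "", "sensitizing",
       "DGIdb", "preclinical", "PMID:22089421"),
    ia("LYN", "masitinib", "amplification", "", "sensitizing",
       "DGIdb", "preclinical", "PMID:25061177"),
    ia("FGFR4", "ponatinib", "overexpression", "", "sensitizing",
       "DGIdb", "smaller_study", "PMID:23139194"),
    ia("MET", "crizotinib", "overexpression", "", "sensitizing",
       "DGIdb,MyCancerGenome", "smaller_study", "PMID:26637283"),
    ia("MET", "crizotinib", "amplification", "", "sensitizing",
       "DGIdb,MyCancerGenome", "smaller_study", "PMID:26637283"),
    ia("CDKN2A", "palbociclib", "specific_variant", "R80*", "sensitizing",
       "DGIdb", "smaller_study", "PMID:26030518"))

  ap <- function(drug, ind, ok) {
    data.frame(drug = drug, approved_indications = ind,
               swissmedic_approved = ok, stringsAsFactors = FALSE)
  }
  approvals <- rbind(
    ap("dabrafenib", "melanoma", TRUE),
    ap("vemurafenib", "melanoma", TRUE),
    ap("trametinib", "melanoma", TRUE),
    ap("ipilimumab", "melanoma", TRUE),
    ap("LTT462", "", FALSE),
    ap("LXH254", "", FALSE),
    ap("masitinib", "", FALSE),
    ap("sorafenib", "renal cell carcinoma;hepatocellular carcinoma", TRUE),
    ap("carboplatin", "ovarian carcinoma;lung adenocarcinoma", TRUE),
    ap("crizotinib", "lung adenocarcinoma", TRUE),
    ap("bosutinib", "chronic myeloid leukemia", TRUE),
    ap("ponatinib", "chronic myeloid leukemia", TRUE),
    ap("palbociclib", "breast cancer", TRUE))

  tr <- function(id, title, phase, drugs, loc, reqv, key, status) {
    data.frame(trial_id = id, title = title, phase = phase, drugs = drugs,
               location_class = loc, requires_variant = reqv,
               required_variant_key = key, status = status,
               stringsAsFactors = FALSE)
  }
  trials <- rbind(
    tr("NCT-LTT462-CH", "ERK1/2 inhibitor LTT462 in advanced solid tumors",
       1L, "LTT462", "switzerland", FALSE, "", "recruiting"),
    tr("NCT-LXH254-CH", "RAF inhibitor LXH254 in advanced solid tumors",
       1L, "LXH254", "switzerland", FALSE, "", "recruiting"),
    tr("NCT-DABRA-V600E", "Dabrafenib combination in BRAF V600E tumors",
       2L, "dabrafenib,trametinib", "switzerland", TRUE, "BRAF V600E",
       "recruiting"),
    tr("NCT-IPI-3", "Checkpoint blockade in high-burden melanoma",
       3L, "ipilimumab", "other", FALSE, "", "recruiting"),
    tr("NCT-PONA-2", "Pan-FGFR inhibition in FGFR-aberrant cancers",
       2L, "ponatinib", "neighboring", FALSE, "", "recruiting"),
    tr("NCT-CRIZ-CLOSED", "Crizotinib in MET-driven tumors",
       2L, "crizotinib", "other", FALSE, "", "other"))

  frequently_mutated <- list(
    melanoma = c("BRAF", "NRAS", "KIT"),
    `uveal melanoma` = c("GNA11", "GNAQ"),
    `lung adenocarcinoma` = c("EGFR", "ALK", "KRAS"))

  rtk <- "Receptor tyrosine kinase signaling"
  gene_pathways <- c(
    BRAF = "MAPK signaling", NRAS = "MAPK signaling",
    KRAS = "MAPK signaling", KIT = rtk, ALK = rtk, MET = rtk, EGFR = rtk,
    FGFR4 = "FGFR signaling", LYN = "Src family kinase signaling",
    TP53 = "Genome integrity / DNA damage response",
    GNA11 = "G-protein signaling", GNAQ = "G-protein signaling",
    CDKN2A = "Cell cycle regulation")
  gene_pathways[BURDEN_GENE] <- "Immune response biomarker"

  variant_effects <- data.frame(
    gene = c("BRAF", "NRAS", "TP53", "ALK", "CDKN2A"),
    protein_change = c("V600E", "Q61K", "V173L", "G1202R", "R80*"),
    known_effect = c("gain_of_function", "gain_of_function",
                     "loss_of_function", "gain_of_function",
                     "loss_of_function"),
    functional_impact = c("damaging", "damaging", "damaging", "damaging",
                          "damaging"),
    databases = c("COSMIC,ClinVar", "COSMIC", "COSMIC", "COSMIC", "COSMIC"),
    identifiers = c("COSM476,VCV000013961", "COSM580", "COSM10717",
                    "COSM5677632", "COSM12475"),
    stringsAsFactors = FALSE)

  # Deterministic reference cohorts over all mini-genome genes (no RNG).
  cohort_values <- function(offset, n = 30) {
    lapply(seq_along(SIM_GENES), function(i) {
      round(50 + 8 * sin(seq_len(n) * 0.7 + i + offset) +
              2 * cos(seq_len(n) * 1.3 + i), 3)
    })
  }
  reference_cohorts <- list(
    SKCM = stats::setNames(cohort_values(0), SIM_GENES),
    UVM = stats::setNames(cohort_values(3), SIM_GENES))

  kb <- structure(
    list(interactions = interactions, approvals = approvals, trials = trials,
         frequently_mutated = frequently_mutated,
         gene_pathways = gene_pathways, variant_effects = variant_effects,
         reference_cohorts = reference_cohorts,
         manifest = list(snapshot_date = "2018-06-01",
                         databases = c("DGIdb", "MyCancerGenome", "CIViC",
                                       "OncoKB", "COSMIC", "ClinVar",
                                       "dbSNP"))),
    class = "mtb_kb")
  validate_kb(kb)
  kb
}

# Mirror of the toy knowledge base used to derive ground-truth expectations
# in the generator, kept as literal lookup tables so the expectation side
# does not run the matching engine it is meant to check.
TOY_SPECIFIC_SENSITIZING <- list(
  "BRAF V600E" = c("dabrafenib", "vemurafenib"),
  "NRAS Q61K" = "trametinib",
  "GNA11 Q209L" = "sorafenib",
  "CDKN2A R80*" = "palbociclib")
TOY_ANY_ALTERATION <- list(BRAF = c("LTT462", "LXH254"), KIT = "sorafenib")
TOY_AMPLIFICATION <- list(LYN = c("bosutinib", "masitinib"), MET = "crizotinib")
TOY_OVEREXPRESSION <- list(FGFR4 = "ponatinib", MET = "crizotinib")
TOY_BURDEN_HIGH <- "ipilimumab"

#' Simulation configuration
#'
#' @param seed Integer RNG seed.
#' @param n_true_variants Number of true somatic variants (including the
#'   planted BRAF V600E driver).
#' @param per_caller_sensitivity Probability that each caller reports each
#'   true variant, in \code{(0, 1]}.
#' @param per_caller_false_positive_count Unique false calls added per
#'   caller (disjoint across callers by construction).
#' @param n_genes Number of genes from the mini-genome used (2..20).
#' @param cohort_size Reference-cohort size for expression (>= 2).
#' @param fraction_amplified,fraction_deleted Fractions of genes given copy
#'   number 8 / 0 in the segment table.
#' @param burden_target Number of true variants given a non-synonymous
#'   consequence (caps at \code{n_true_variants}).
#' @return A validated list of class \code{sim_config}.
#' @export
simulation_config <- function(seed, n_true_variants = 40,
                              per_caller_sensitivity = 1.0,
                              per_caller_false_positive_count = 0,
                              n_genes = 20, cohort_size = 30,
                              fraction_amplified = 0.1,
                              fraction_deleted = 0.1,
                              burden_target = 30) {
  if (per_caller_sensitivity <= 0 || per_caller_sensitivity > 1) {
    stop("per_caller_sensitivity must be in (0, 1]")
  }
  if (fraction_amplified < 0 || fraction_amplified > 1 ||
      fraction_deleted < 0 || fraction_deleted > 1 ||
      fraction_amplified + fraction_deleted > 1) {
    stop("amplified/deleted fractions must be in [0, 1] and sum to <= 1")
  }
  if (cohort_size < 2) stop("cohort_size must be >= 2")
  if (n_genes < 2 || n_genes > length(SIM_GENES)) {
    stop("n_genes must be between 2 and ", length(SIM_GENES))
  }
  if (n_true_variants < 1) stop("n_true_variants must be >= 1")
  structure(list(seed = as.integer(seed), n_true_variants = n_true_variants,
                 per_caller_sensitivity = per_caller_sensitivity,
                 per_caller_false_positive_count = per_caller_false_positive_count,
                 n_genes = n_genes, cohort_size = cohort_size,
                 fraction_amplified = fraction_amplified,
                 fraction_deleted = fraction_deleted,
                 burden_target = min(burden_target, n_true_variants)),
            class = "sim_config")
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

write_sim_vcf <- function(df, file, style = c("af", "freq", "ad")) {
  style <- match.arg(style)
  fmt_header <- switch(style,
    af = "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    freq = "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"Variant allele frequency\">",
    ad = "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    fmt_header,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "NORMAL", "TUMOR", sep = "\t"))
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  body <- vapply(seq_len(nrow(df)), function(i) {
    info <- paste0("GENE=", df$gene[i], ";EFFECT=", df$consequence[i],
                   ifelse(nzchar(df$protein_change[i]),
                          paste0(";PCHANGE=", df$protein_change[i]), ""))
    depth <- 100L
    alt_reads <- round(df$vaf[i] * depth)
    tumor <- switch(style,
      af = paste0("0/1:", sprintf("%.4f", df$vaf[i])),
      freq = paste0("0/1:", sprintf("%.2f%%", 100 * df$vaf[i])),
      ad = paste0("0/1:", depth - alt_reads, ",", alt_reads))
    normal <- switch(style, af = "0/0:0.0000", freq = "0/0:0.00%",
                     ad = "0/0:100,0")
    fmt <- switch(style, af = "GT:AF", freq = "GT:FREQ", ad = "GT:AD")
    paste(df$chrom[i], df$pos[i], ".", df$ref[i], df$alt[i], ".", "PASS",
          info, fmt, normal, tumor, sep = "\t")
  }, character(1))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Generate a synthetic patient with known ground truth
#'
#' Emulates the inputs of a comprehensive (tumor/normal WES + WGS + RNA)
#' analysis: three caller VCFs over a synthetic two-contig genome, in which
#' each true variant appears in each caller's file independently with the
#' configured sensitivity and each caller receives its own disjoint false
#' calls; a per-gene copy-number segment table; a tumor expression table
#' against the toy SKCM reference cohort. A BRAF V600E driver is always
#' among the true variants. The returned ground truth records which variant
#' keys have enough caller support, the expected per-gene calls, and the
#' expected (gene, drug) recommendation set derived from literal lookup
#' tables mirroring the toy knowledge base.
#'
#' @param config A \code{sim_config} from [simulation_config()].
#' @param out_dir Directory to write the input files into.
#' @return List with \code{paths} (vcfs, segments, expression, gene_model),
#'   \code{truth} (true_variants, expected_consensus, expected_calls,
#'   expected_recommendations, expected_burden) and \code{config}.
#' @export
generate_patient <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  model <- mini_gene_model()[seq_len(config$n_genes), , drop = FALSE]
  callers <- c("mutect", "varscan", "strelka")

  # --- true variants: driver + random SNVs inside genes ------------------
  n <- config$n_true_variants
  gene_idx <- sample(seq_len(nrow(model)), n, replace = TRUE)
  offset <- sample(0:9999, n, replace = TRUE)
  pos <- model$start[gene_idx] + offset
  alleles <- random_alleles(n)
  n_nonsyn <- config$burden_target
  consequence <- c(rep("missense", min(n_nonsyn, n)),
                   rep("synonymous", max(0, n - n_nonsyn)))
  truth_df <- data.frame(
    chrom = model$chrom[gene_idx], pos = pos, ref = alleles$ref,
    alt = alleles$alt, gene = model$gene[gene_idx], protein_change = "",
    vaf = round(stats::runif(n, 0.05, 0.95), 4), consequence = consequence,
    stringsAsFactors = FALSE)
  # planted driver: overwrite variant 1
  braf <- model[model$gene == "BRAF", ]
  if (nrow(braf) == 1) {
    truth_df$chrom[1] <- braf$chrom
    truth_df$pos[1] <- braf$start + 1798L
    truth_df$ref[1] <- "T"
    truth_df$alt[1] <- "A"
    truth_df$gene[1] <- "BRAF"
    truth_df$protein_change[1] <- "V600E"
    truth_df$consequence[1] <- "missense"
  }
  truth_df <- truth_df[!duplicated(variant_key(truth_df$chrom, truth_df$pos,
                                               truth_df$ref, truth_df$alt)), ,
                       drop = FALSE]
  n <- nrow(truth_df)

  # --- per-caller inclusion and disjoint false positives -----------------
  included <- matrix(stats::runif(n * 3) <= config$per_caller_sensitivity,
                     nrow = n, ncol = 3)
  support <- rowSums(included)
  fp_sets <- list()
  n_fp <- config$per_caller_false_positive_count
  if (n_fp > 0) {
    fp_pos_all <- sample(seq(2e6, 3e6), 3 * n_fp)  # off-gene, off-truth range
    for (k in 1:3) {
      fp_alleles <- random_alleles(n_fp)
      fp_sets[[k]] <- data.frame(
        chrom = "chr1", pos = fp_pos_all[((k - 1) * n_fp + 1):(k * n_fp)],
        ref = fp_alleles$ref, alt = fp_alleles$alt, gene = "",
        protein_change = "", vaf = round(stats::runif(n_fp, 0.02, 0.2), 4),
        consequence = "missense", stringsAsFactors = FALSE)
    }
  }

  vcf_paths <- stats::setNames(
    file.path(out_dir, paste0(callers, ".vcf")), callers)
  styles <- c("af", "freq", "ad")
  for (k in 1:3) {
    df <- truth_df[included[, k], , drop = FALSE]
    if (n_fp > 0) df <- rbind(df, fp_sets[[k]])
    write_sim_vcf(df, vcf_paths[k], style = styles[k])
  }

  # --- copy-number segments: one segment per gene ------------------------
  n_amp <- round(config$fraction_amplified * nrow(model))
  n_del <- round(config$fraction_deleted * nrow(model))
  cn_state <- sample(c(rep("amp", n_amp), rep("del", n_del),
                       rep("neutral", nrow(model) - n_amp - n_del)))
  copy_number <- ifelse(cn_state == "amp", 8L, ifelse(cn_state == "del", 0L, 2L))
  segments <- data.frame(chrom = model$chrom, start = model$start,
                         end = model$end, copy_number = copy_number,
                         stringsAsFactors = FALSE)
  seg_path <- file.path(out_dir, "segments.tsv")
  utils::write.table(segments, seg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- expression: amplified genes high, deleted genes low, rest median --
  kb <- toy_knowledge_base()
  cohort <- kb$reference_cohorts$SKCM[model$gene]
  expr_value <- vapply(seq_len(nrow(model)), function(i) {
    vals <- cohort[[i]]
    switch(cn_state[i],
           amp = max(vals) * 1.5,
           del = min(vals) * 0.5,
           stats::median(vals))
  }, numeric(1))
  expression <- data.frame(gene = model$gene, value = round(expr_value, 3),
                           stringsAsFactors = FALSE)
  expr_path <- file.path(out_dir, "expression.tsv")
  utils::write.table(expression, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  model_path <- file.path(out_dir, "gene_model.tsv")
  utils::write.table(model, model_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- ground truth ------------------------------------------------------
  keys <- variant_key(truth_df$chrom, truth_df$pos, truth_df$ref, truth_df$alt)
  consensus_idx <- which(support >= 2)
  amp_genes <- model$gene[cn_state == "amp"]
  del_genes <- model$gene[cn_state == "del"]
  over_genes <- amp_genes    # expression planted above the cohort maximum
  under_genes <- del_genes   # expression planted below the cohort minimum

  expected <- character(0)
  for (i in consensus_idx) {
    g <- truth_df$gene[i]
    pc <- truth_df$protein_change[i]
    if (nzchar(pc)) {
      for (d in TOY_SPECIFIC_SENSITIZING[[paste(g, pc)]]) {
        expected <- c(expected, paste(g, d, sep = "|"))
      }
    }
    for (d in TOY_ANY_ALTERATION[[g]]) {
      expected <- c(expected, paste(g, d, sep = "|"))
    }
  }
  for (g in amp_genes) {
    for (d in TOY_AMPLIFICATION[[g]]) expected <- c(expected, paste(g, d, sep = "|"))
  }
  # any-alteration interactions also cover genomic copy-number aberrations
  for (g in c(amp_genes, del_genes)) {
    for (d in TOY_ANY_ALTERATION[[g]]) expected <- c(expected, paste(g, d, sep = "|"))
  }
  for (g in over_genes) {
    for (d in TOY_OVEREXPRESSION[[g]]) expected <- c(expected, paste(g, d, sep = "|"))
  }
  n_nonsyn_consensus <- sum(truth_df$consequence[consensus_idx] %in%
                              NONSYNONYMOUS_CLASSES)
  burden_high <- n_nonsyn_consensus > 100
  if (burden_high) expected <- c(expected, paste("", TOY_BURDEN_HIGH, sep = "|"))

  truth <- list(
    true_variants = keys,
    expected_consensus = keys[consensus_idx],
    expected_calls = c(
      stats::setNames(rep("amplification", length(amp_genes)), amp_genes),
      stats::setNames(rep("deletion", length(del_genes)), del_genes),
      stats::setNames(rep("overexpressed", length(over_genes)), over_genes),
      stats::setNames(rep("underexpressed", length(under_genes)), under_genes)),
    expected_recommendations = sort(unique(expected)),
    expected_burden = list(count = n_nonsyn_consensus,
                           classification = if (burden_high) "high" else "low"))

  list(paths = list(vcfs = vcf_paths, segments = seg_path,
                    expression = expr_path, gene_model = model_path),
       truth = truth, config = config)
}
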