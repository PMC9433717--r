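# Shared fixtures, built in code at test time.

# Minimal two-tool registry: one probability-scaled tool and one
# lower-is-pathogenic tool on an open scale.
toy_registry <- function() {
  load_tool_registry(list(
    ToolA = list(field = "ToolA", direction = "higher_is_pathogenic",
                 reference_threshold = 0.5),
    ToolB = list(field = "ToolB", direction = "lower_is_pathogenic",
                 reference_threshold = -4.14)
  ))
}

# Hand-written annotated VCF: 3 variants, 2 CSQ tools, one blank score.
write_toy_vcf <- function(path, extra_lines = character()) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS>",
    "##INFO=<ID=LABEL,Number=1,Type=String,Description=\"label\">",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations. Format: Allele|SYMBOL|Consequence|CCDS|CANONICAL|",
           "BIOTYPE|ToolA|ToolB\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chrS\t10\t.\tA\tG\t.\tPASS\tLABEL=pathogenic;",
           "CSQ=G|GENEA|missense_variant|CCDS1.1|YES|protein_coding|0.9|-5.2"),
    paste0("chrS\t20\t.\tC\tT\t.\tPASS\tLABEL=benign;",
           "CSQ=T|GENEB|missense_variant|CCDS2.1|YES|protein_coding|0.2|"),
    paste0("chrS\t30\t.\tG\tA\t.\tPASS\tLABEL=benign;",
           "CSQ=A|GENEC|missense_variant|CCDS3.1|YES|protein_coding|0.4|-1.0"),
    extra_lines
  ), path)
  path
}

# ClinVar-style record table: 6 hand-enumerated records covering the filter
# chain (2 ontology-matching P/LP, 1 matching B/LB, 1 zero-star, 1
# conflicting, 1 wrong phenotype).
clinvar_toy_records <- function() {
  tibble::tibble(
    chrom = "chrS", pos = 1:6 * 10L, ref = "A", alt = "G",
    gene = c("GENEA", "GENEA", "GENEB", "GENEA", "GENEB", "GENEC"),
    consequence = "missense_variant",
    review_stars = c(2L, 1L, 2L, 0L, 1L, 2L),
    significance = c("Pathogenic", "Likely_pathogenic", "Benign",
                     "Pathogenic", "Conflicting_interpretations_of_pathogenicity",
                     "Pathogenic"),
    ontology_ids = list("MedGen:C0001", "MedGen:C0001", "MedGen:C0001",
                        "MedGen:C0001", "MedGen:C0001", "MedGen:C9999")
  )
}

toy_disease_rules <- function(...) {
  filter_rule_set(ontology_ids = "MedGen:C0001", ...)
}

# Population F-beta-optimal threshold for two normal class distributions at
# equal prevalence, by direct numeric maximization of the population F-beta.
population_fbeta_optimum <- function(mean_path, mean_ben, sd = 1, beta = 1) {
  t <- seq(min(mean_path, mean_ben) - 4 * sd,
           max(mean_path, mean_ben) + 4 * sd, length.out = 20001)
  recall <- 1 - pnorm(t, mean_path, sd)
  fpr <- 1 - pnorm(t, mean_ben, sd)
  precision <- recall / (recall + fpr)
  fb <- (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
  t[which.max(fb)]
}

# gnomAD-style benign candidates: hand-enumerated 20-record fixture.
#  - 4 rare (AF <= 0.001, one exactly at the strict cut)
#  - 2 outside the gene panel
#  - 3 non-missense
#  - 2 in the excluded TTN gene
#  - 1 key in the exclusion set
#  - 8 survivors
gnomad_toy_records <- function() {
  tibble::tibble(
    chrom = "chrS", pos = 1:20 * 10L, ref = "A", alt = "C",
    gene = c(rep("GENEA", 6), rep("GENEB", 6), "OFFPANEL", "OFFPANEL",
             "TTN", "TTN", rep("GENEA", 4)),
    consequence = c(rep("missense_variant", 9),
                    "synonymous_variant", "intron_variant", "stop_gained",
                    rep("missense_variant", 8)),
    allele_frequency = c(0.0005, 0.0008, 0.001, 0.00099,
                         rep(0.01, 16))
  )
}

gnomad_toy_rules <- function() {
  filter_rule_set(
    maf_threshold = 0.001,
    gene_panel = c("GENEA", "GENEB", "TTN"),
    excluded_genes = "TTN",
    exclusion_variant_sets = list("chrS:170:A:C")
  )
}

# Overlapping-score fixture for calibration: 20 points, fixed by hand.
overlap_fixture <- function() {
  list(
    scores = c(0.15, 0.22, 0.35, 0.41, 0.48, 0.52, 0.58, 0.63, 0.71, 0.84,
               0.05, 0.12, 0.19, 0.28, 0.33, 0.44, 0.51, 0.57, 0.66, 0.77),
    labels = rep(c("pathogenic", "benign"), each = 10)
  )
}

sep_fixture <- function() {
  list(
    scores = c(0.8, 0.85, 0.9, 0.95, 1.0, 0.0, 0.05, 0.1, 0.15, 0.2),
    labels = rep(c("pathogenic", "benign"), each = 5)
  )
}

# Brute-force Mann-Whitney probability: P(path > benign) + 0.5 P(tie).
pairwise_auroc <- function(scores, labels) {
  ok <- !is.na(scores)
  sp <- scores[ok & labels == "pathogenic"]
  sb <- scores[ok & labels == "benign"]
  cmp <- outer(sp, sb, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Reference F-beta grid evaluation through the general confusion path,
# independent of the vectorised fast path used by best_threshold().
fbeta_grid_oracle <- function(scores, labels, comparator, beta, grid) {
  vapply(grid, function(th) {
    cs <- confusion_at_threshold(scores, labels, th, comparator)
    f_beta(cs$precision, cs$sensitivity, beta)
  }, numeric(1))
}
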