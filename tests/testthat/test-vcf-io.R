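test_that("a hand-built VCF parses into the enumerated score matrix", {
  path <- write_toy_vcf(tempfile(fileext = ".vcf"))
  out <- parse_annotated_vcf(path, toy_registry())
  expect_equal(nrow(out$records), 3)
  expect_equal(out$records$label, c("pathogenic", "benign", "benign"))
  expect_equal(out$records$gene, c("GENEA", "GENEB", "GENEC"))

  sm <- out$scores
  expect_equal(sm$ToolA, c(0.9, 0.2, 0.4))
  expect_equal(sm$ToolB, c(-5.2, NA, -1.0))
  expect_equal(sum(is.na(sm[c("ToolA", "ToolB")])), 1)
})

test_that("multi-allelic records decompose into one record per alt", {
  path <- tempfile(fileext = ".vcf")
  write_toy_vcf(path, extra_lines = paste0(
    "chrS\t40\t.\tA\tC,T\t.\tPASS\tLABEL=benign;",
    "CSQ=C|GENEA|missense_variant|CCDS1.1|YES|protein_coding|0.1|-1.0,",
    "T|GENEA|missense_variant|CCDS1.1|YES|protein_coding|0.7|-2.0"
  ))
  out <- parse_annotated_vcf(path, toy_registry())
  # decomposition conserves count: 3 single-alt + 2 alts = 5 records
  expect_equal(nrow(out$records), 5)
  dec <- out$records[out$records$pos == 40, ]
  expect_equal(nrow(dec), 2)
  expect_equal(dec$chrom, rep("chrS", 2))
  expect_equal(dec$ref, rep("A", 2))
  expect_setequal(dec$alt, c("C", "T"))
  # per-allele CSQ matching gives each alt its own score
  sm <- out$scores
  expect_equal(sm$ToolA[sm$pos == 40 & sm$alt == "C"], 0.1)
  expect_equal(sm$ToolA[sm$pos == 40 & sm$alt == "T"], 0.7)
})

test_that("empty VCF gives empty records and a 0-row score matrix", {
  path <- write_toy_vcf(tempfile(fileext = ".vcf"))
  lines <- readLines(path)
  writeLines(lines[!grepl("^chrS", lines)], path)
  out <- suppressWarnings(parse_annotated_vcf(path, toy_registry()))
  expect_equal(nrow(out$records), 0)
  expect_equal(nrow(out$scores), 0)
  expect_true(all(c("ToolA", "ToolB") %in% names(out$scores)))
})

test_that("a registry field absent from the CSQ header is an error naming it", {
  path <- write_toy_vcf(tempfile(fileext = ".vcf"))
  reg <- load_tool_registry(list(
    Ghost = list(field = "GhostField", direction = "higher_is_pathogenic",
                 reference_threshold = 0.5)
  ))
  expect_error(parse_annotated_vcf(path, reg), "GhostField")
})

test_that("malformed numeric scores degrade to missing with a warning", {
  path <- tempfile(fileext = ".vcf")
  write_toy_vcf(path, extra_lines = paste0(
    "chrS\t50\t.\tT\tA\t.\tPASS\tLABEL=benign;",
    "CSQ=A|GENEA|missense_variant|CCDS1.1|YES|protein_coding|not_a_number|-1.0"
  ))
  expect_warning(out <- parse_annotated_vcf(path, toy_registry()),
                 "malformed")
  expect_true(is.na(out$scores$ToolA[out$scores$pos == 50]))
  expect_equal(out$scores$ToolB[out$scores$pos == 50], -1.0)
})

test_that("transcript pick order prefers ccds, then canonical, then biotype", {
  path <- tempfile(fileext = ".vcf")
  # three transcripts for one variant: scores differ so the pick is visible
  write_toy_vcf(path, extra_lines = paste0(
    "chrS\t60\t.\tG\tT\t.\tPASS\tLABEL=benign;",
    "CSQ=T|GENEA|missense_variant|||processed_transcript|0.1|,",
    "T|GENEA|missense_variant||YES|protein_coding|0.2|,",
    "T|GENEA|missense_variant|CCDS9.1||protein_coding|0.3|"
  ))
  out <- parse_annotated_vcf(path, toy_registry())
  expect_equal(out$scores$ToolA[out$scores$pos == 60], 0.3) # CCDS wins
  out2 <- parse_annotated_vcf(path, toy_registry(),
                              pick_policy = c("canonical", "ccds", "biotype", "rank"))
  expect_equal(out2$scores$ToolA[out2$scores$pos == 60], 0.2)
})

test_that("write/parse round trip reproduces the score matrix cell-for-cell", {
  profs <- list(
    sim_tool_profile("GoodTool"),
    sim_tool_profile("Sparse", missingness = c(0.3, 0.1)),
    sim_tool_profile("Inv", direction = "lower_is_pathogenic",
                     pathogenic = score_dist("normal", mean = -2, sd = 1),
                     benign = score_dist("normal", mean = 0, sd = 1),
                     reference_threshold = -1)
  )
  sim <- simulate_cohort(sim_cohort_spec(25, 25, 10, seed = 42), profs)
  path <- tempfile(fileext = ".vcf")
  write_annotated_vcf(sim$records, sim$scores, sim$registry, path)
  back <- parse_annotated_vcf(path, sim$registry)
  expect_equal(as.data.frame(back$scores), as.data.frame(sim$scores))
  expect_equal(back$records$label, sim$records$label)
  expect_equal(back$records$gene, sim$records$gene)

  # TSV export: one column per tool, "." as the undefined-marker
  tsv <- tempfile(fileext = ".tsv")
  write_scored_tsv(sim$records, sim$scores, tsv)
  tab <- readr::read_tsv(tsv, na = ".", show_col_types = FALSE)
  expect_equal(names(tab)[1:8], c("chrom", "pos", "ref", "alt", "gene",
                                  "consequence", "label", "source"))
  expect_equal(sum(is.na(tab$Sparse)), sum(is.na(sim$scores$Sparse)))
})

test_that("negating a tool's scores and flipping its direction leaves metrics unchanged", {
  sim <- simulate_cohort(sim_cohort_spec(40, 40, 0, seed = 11),
                         list(sim_tool_profile("T1")))
  cohort <- new_cohort_dataset("sim", sim$records)
  reg_flip <- load_tool_registry(list(
    T1 = list(field = "T1", direction = "lower_is_pathogenic",
              reference_threshold = -0.5)
  ))
  scores_flip <- sim$scores
  scores_flip$T1 <- -scores_flip$T1

  fixed <- evaluate_fixed(cohort, sim$scores, sim$registry)
  fixed_flip <- evaluate_fixed(cohort, scores_flip, reg_flip)
  expect_equal(fixed_flip$weighted_norm_mcc, fixed$weighted_norm_mcc)
  expect_equal(fixed_flip$tp, fixed$tp)

  roc <- evaluate_roc(cohort, sim$scores, sim$registry)
  roc_flip <- evaluate_roc(cohort, scores_flip, reg_flip)
  expect_equal(roc_flip$auroc, roc$auroc)
})

test_that("categorical CSQ labels are mapped and VUS classifications stay missing", {
  reg <- load_tool_registry(list(
    Cat = list(field = "Cat", direction = "higher_is_pathogenic",
               reference_threshold = 0.5, excluded_from_multithreshold = TRUE,
               categorical_map = list(Benign = 0, Likely_benign = 0.25,
                                      Likely_pathogenic = 0.75, Pathogenic = 1))
  ))
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS>",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"x ",
           "Format: Allele|SYMBOL|Consequence|CCDS|CANONICAL|BIOTYPE|Cat\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrS\t10\t.\tA\tG\t.\tPASS\tCSQ=G|X|missense_variant||||Likely_pathogenic",
    "chrS\t20\t.\tA\tG\t.\tPASS\tCSQ=G|X|missense_variant||||VUS",
    "chrS\t30\t.\tA\tG\t.\tPASS\tCSQ=G|X|missense_variant||||Benign"
  ), path)
  out <- parse_annotated_vcf(path, reg)
  expect_equal(out$scores$Cat, c(0.75, NA, 0))
})

test_that("INFO-located scores pick per-allele values or the worst value", {
  reg <- load_tool_registry(list(
    InfoTool = list(field = "ITS", location = "info",
                    direction = "higher_is_pathogenic",
                    reference_threshold = 0.5)
  ))
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS>",
    "##INFO=<ID=ITS,Number=.,Type=Float,Description=\"score\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrS\t10\t.\tA\tC,T\t.\tPASS\tITS=0.2,0.8",     # per-allele
    "chrS\t20\t.\tA\tG\t.\tPASS\tITS=0.3,0.9"        # worst-of for one alt
  ), path)
  out <- parse_annotated_vcf(path, reg)
  expect_equal(out$scores$InfoTool[out$scores$alt == "C"], 0.2)
  expect_equal(out$scores$InfoTool[out$scores$alt == "T"], 0.8)
  expect_equal(out$scores$InfoTool[out$scores$pos == 20], 0.9)
})
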