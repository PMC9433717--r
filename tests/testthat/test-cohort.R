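test_that("ClinVar filter chain keeps the hand-enumerated survivors", {
  cohort <- filter_clinvar(clinvar_toy_records(), toy_disease_rules())
  g <- glance(cohort)
  expect_equal(g$n, 3)
  expect_equal(g$n_pathogenic, 2)
  expect_equal(g$n_benign, 1)

  kept <- tidy(cohort)
  expect_false(any(kept$review_stars == 0))                  # zero-star gone
  expect_false(any(grepl("Uncertain|Conflicting", kept$significance)))
  expect_false("MedGen:C9999" %in% unlist(kept$ontology_ids)) # wrong phenotype

  # audit telescopes: each step's kept count feeds the next step
  a <- cohort$audit
  expect_equal(a$n_kept[-nrow(a)], a$n_in[-1])
  expect_equal(a$n_in[1], 6)
  expect_equal(a$n_kept[nrow(a)], 3)
})

test_that("ClinVar filter is idempotent and errors on missing metadata", {
  rules <- toy_disease_rules()
  once <- filter_clinvar(clinvar_toy_records(), rules)
  twice <- filter_clinvar(tidy(once), rules)
  expect_equal(tidy(twice), tidy(once))

  bad <- clinvar_toy_records()
  bad$review_stars <- NULL
  expect_error(filter_clinvar(bad, rules), "review_stars")
})

test_that("review-star minimum is a parameter (benchmark 1 vs summary 2)", {
  strict <- filter_clinvar(clinvar_toy_records(),
                           toy_disease_rules(min_review_stars = 2))
  expect_equal(glance(strict)$n, 2) # the 1-star Likely_pathogenic drops out
})

test_that("missense selection is a substring match on the consequence term", {
  rec <- tibble::tibble(
    chrom = "chrS", pos = 1:3 * 10L, ref = "A", alt = "G",
    consequence = c("missense_variant", "synonymous_variant",
                    "missense_variant&splice_region_variant")
  )
  kept <- select_missense(rec)
  expect_equal(kept$pos, c(10L, 30L))
  expect_equal(select_missense(kept), kept) # idempotent
})

test_that("gnomAD benign chain matches hand enumeration step by step", {
  res <- suppressMessages(
    build_gnomad_benign(gnomad_toy_records(), gnomad_toy_rules(),
                        split_sizes = c(4, 4), seed = 5)
  )
  a <- res$cohort$audit
  expect_equal(a$step[1:5], c("af>0.001", "gene_panel", "missense",
                              "excluded_genes", "exclusion_set_1"))
  # 20 -> 16 common (AF strictly > 0.001 removes 4, incl. the boundary value)
  expect_equal(a$n_in[1], 20); expect_equal(a$n_kept[1], 16)
  # panel removes the 2 OFFPANEL records
  expect_equal(a$n_kept[2], 14)
  # missense removes the 3 other consequences
  expect_equal(a$n_kept[3], 11)
  # TTN exclusion removes 2
  expect_equal(a$n_kept[4], 9)
  # explicit exclusion key removes 1 -> 8 survivors
  expect_equal(a$n_kept[5], 8)
  expect_equal(glance(res$cohort)$n_benign, 8)

  # seeded split: disjoint sets of the requested sizes, reproducible
  k1 <- variant_key(tidy(res$splits[[1]]))
  k2 <- variant_key(tidy(res$splits[[2]]))
  expect_equal(length(k1), 4); expect_equal(length(k2), 4)
  expect_length(intersect(k1, k2), 0)
  res2 <- suppressMessages(
    build_gnomad_benign(gnomad_toy_records(), gnomad_toy_rules(),
                        split_sizes = c(4, 4), seed = 5)
  )
  expect_identical(tidy(res2$splits[[1]]), tidy(res$splits[[1]]))

  expect_error(
    suppressMessages(build_gnomad_benign(gnomad_toy_records(),
                                         gnomad_toy_rules(),
                                         split_sizes = c(6, 6), seed = 5)),
    "split sizes"
  )
})

test_that("conjunctive gnomAD filters commute: reordering does not change the set", {
  rules <- gnomad_toy_rules()
  res_a <- suppressMessages(build_gnomad_benign(gnomad_toy_records(), rules))
  # apply the same predicates by hand in a different order
  rec <- gnomad_toy_records()
  rec <- select_missense(rec)
  rec <- rec[rec$gene %in% rules$gene_panel, ]
  rec <- rec[rec$allele_frequency > rules$maf_threshold, ]
  rec <- rec[!(rec$gene %in% rules$excluded_genes), ]
  rec <- rec[!(variant_key(rec) %in% rules$exclusion_variant_sets[[1]]), ]
  expect_setequal(variant_key(tidy(res_a$cohort)), variant_key(rec))
})

test_that("external clinical lists import with exclusion and mismatch rules", {
  rows <- tibble::tibble(
    chrom = "chrS", pos = 1:5 * 10L, ref = "A", alt = "T",
    gene = "GENEA",
    assignment = c("Pathogenic", "Likely_pathogenic", "Benign",
                   "Pathogenic", "Pathogenic"),
    consequence = c(rep("missense_variant", 4), "splice_donor_variant"),
    allele_mismatch = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  cohort <- import_external_list(rows, exclusion_keys = "chrS:10:A:T")
  # row1 excluded (already claimed), row3 not whitelisted, row4 mismatch,
  # row5 not missense -> only row2 survives, labelled pathogenic
  expect_equal(tidy(cohort)$pos, 20L)
  expect_equal(tidy(cohort)$label, "pathogenic")
  a <- cohort$audit
  expect_equal(a$n_kept[-nrow(a)], a$n_in[-1])

  empty <- import_external_list(rows[0, ])
  expect_equal(glance(empty)$n, 0)
  expect_true(all(empty$audit$n_in == 0))

  expect_error(import_external_list(dplyr::select(rows, -"alt")), "alt")
})

test_that("merge_cohorts unions by key with first-cohort priority", {
  mk <- function(name, pos, label) {
    new_cohort_dataset(name, tibble::tibble(
      chrom = "chrS", pos = pos, ref = "A", alt = "G", label = label
    ))
  }
  a <- mk("a", c(10L, 20L, 30L), "pathogenic")
  b <- mk("b", c(40L, 50L, 60L, 70L), "benign")
  m <- merge_cohorts(list(a, b))
  expect_equal(glance(m)$n, 7)

  self <- suppressMessages(merge_cohorts(list(a, a)))
  expect_equal(tidy(self)[c("chrom", "pos", "ref", "alt")],
               tidy(a)[c("chrom", "pos", "ref", "alt")])

  c1 <- mk("c1", c(10L, 20L, 30L), "pathogenic")
  c2 <- mk("c2", c(20L, 30L, 40L, 50L), "pathogenic")
  m2 <- suppressMessages(merge_cohorts(list(c1, c2)))
  expect_equal(glance(m2)$n, 3 + 4 - 2)

  conflict <- mk("c3", c(20L), "benign")
  expect_error(suppressMessages(merge_cohorts(list(c1, conflict),
                                              dedupe = FALSE)),
               "conflicting labels")
  # with dedupe the first cohort's label wins
  m3 <- suppressMessages(merge_cohorts(list(c1, conflict)))
  expect_equal(tidy(m3)$label[tidy(m3)$pos == 20], "pathogenic")
})

test_that("distribution summary pools rare genes and generalizes categories", {
  rec <- tibble::tibble(
    chrom = "chrS", pos = 1:12 * 10L, ref = "A", alt = "G",
    gene = c(rep("BIGGENE", 7), rep("SMALL", 4), "TINY"),
    consequence = c(rep("missense_variant", 6), "inframe_insertion",
                    "inframe_deletion", "intron_variant",
                    "splice_donor_variant", "missense_variant", "stop_gained"),
    molecular_consequence = NA_character_
  )
  s <- summarize_distribution(rec, min_gene_count = 5)
  expect_setequal(s$gene_table$gene, c("BIGGENE", "Other"))
  expect_equal(s$gene_table$n[s$gene_table$gene == "Other"], 5)
  expect_equal(sum(s$gene_table$proportion), 1, tolerance = 1e-12)

  ct <- s$category_table
  expect_equal(ct$n[ct$category == "Inframe indel"], 2)
  expect_equal(ct$n[ct$category == "Splice site/Intron"], 2)
  expect_equal(sum(ct$proportion), 1, tolerance = 1e-12)

  # molecular-consequence field takes precedence when populated
  rec$molecular_consequence <- c("nonsense", rep(NA_character_, 11))
  s2 <- summarize_distribution(rec, min_gene_count = 5)
  expect_true("nonsense" %in% s2$category_table$category)

  expect_true("BIGGENE" %in% names(s$per_gene_category_tables))
  expect_false("Other" %in% names(s$per_gene_category_tables))
})

test_that("training-set exclusion removes the union and audits per tool", {
  rec <- tibble::tibble(chrom = "chrS", pos = 1:10 * 10L, ref = "A",
                        alt = "G", label = "pathogenic")
  cohort <- new_cohort_dataset("c", rec)
  sets <- list(
    tool1 = c("chrS:10:A:G", "chrS:20:A:G"),
    tool2 = c("chrS:20:A:G", "chrS:30:A:G") # one key shared
  )
  out <- exclude_training_overlap(cohort, sets)
  expect_equal(glance(out)$n, 7)
  steps <- out$audit$step
  expect_true(all(c("training_overlap:tool1", "training_overlap:tool2",
                    "training_overlap:union") %in% steps))
  # union step removes nothing extra after sequential per-tool removal
  last <- out$audit[nrow(out$audit), ]
  expect_equal(last$n_in, last$n_kept)

  ident <- exclude_training_overlap(cohort, list())
  expect_equal(tidy(ident), tidy(cohort))
  # idempotent
  again <- exclude_training_overlap(out, sets)
  expect_equal(tidy(again), tidy(out))
})

test_that("recency filter uses a strict date cutoff and drops undated records", {
  rec <- tibble::tibble(
    chrom = "chrS", pos = 1:6 * 10L, ref = "A", alt = "G", label = "pathogenic",
    first_reported = as.Date(c("2020-01-01", "2020-06-15", "2020-06-16",
                               "2021-01-01", "2019-12-31", NA))
  )
  cutoff <- as.Date("2020-06-15")
  out <- suppressMessages(filter_recent(rec, cutoff))
  expect_equal(tidy(out)$pos, c(30L, 40L)) # strictly after only
  a <- out$audit
  expect_equal(a$n_in[1], 6)
  expect_equal(a$n_kept[1], 5) # one undated dropped first
  expect_equal(a$n_kept[2], 2)
})
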