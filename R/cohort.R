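#' Labelled benchmark cohorts
#'
#' A `cohort_dataset` bundles a normalized variant table with the audit trail
#' of the filter chain that produced it: one row per filter step with the
#' number of records entering and kept, telescoping so that each step's kept
#' count is the next step's input count. `tidy()` returns the record table,
#' `glance()` the label counts.
#'
#' @param name Cohort name.
#' @param records Variant table (tibble with at least the key columns and
#'   `label`).
#' @param audit Audit-trail tibble (`step`, `n_in`, `n_kept`); built up by
#'   the filter functions.
#' @return A `cohort_dataset` object.
#' @export
new_cohort_dataset <- function(name, records, audit = empty_audit()) {
  if (anyDuplicated(variant_key(records)) > 0) {
    abort("cohort contains duplicate variant keys")
  }
  structure(list(name = name, records = tibble::as_tibble(records),
                 audit = audit),
            class = "cohort_dataset")
}

empty_audit <- function() {
  tibble::tibble(step = character(), n_in = integer(), n_kept = integer())
}

add_audit <- function(audit, step, n_in, n_kept) {
  dplyr::bind_rows(audit, tibble::tibble(
    step = step, n_in = as.integer(n_in), n_kept = as.integer(n_kept)
  ))
}

#' @export
print.cohort_dataset <- function(x, ...) {
  g <- glance(x)
  cat("<cohort_dataset> '", x$name, "': ", nrow(x$records), " variants (",
      g$n_pathogenic, " pathogenic, ", g$n_benign, " benign, ",
      g$n_vus, " VUS); ", nrow(x$audit), " filter steps\n", sep = "")
  invisible(x)
}

#' @export
tidy.cohort_dataset <- function(x, ...) x$records

#' @export
glance.cohort_dataset <- function(x, ...) {
  lab <- x$records$label
  tibble::tibble(
    name = x$name,
    n = nrow(x$records),
    n_pathogenic = sum(lab == "pathogenic"),
    n_benign = sum(lab == "benign"),
    n_vus = sum(lab == "vus")
  )
}

#' Filter rule set for cohort construction
#'
#' Bundles the knobs of the ClinVar/gnomAD filter chains. Defaults reflect a
#' benchmark-grade cohort: review status of at least one star (zero-star
#' assertions excluded), uncertain or conflicting interpretations excluded,
#' a strict minor-allele-frequency cut of 0.001 (frequency must exceed it),
#' and TTN excluded from benign panels to avoid one gene dominating the
#' missense pool. Empty sets disable the corresponding rule.
#'
#' @param ontology_ids Disease-ontology identifiers (MedGen/OMIM/Mondo); a
#'   record matches when any of its ids is in this set.
#' @param min_review_stars Minimum review stars (1 for benchmark cohorts; use
#'   2 for summary-figure style selections of > 1 star).
#' @param excluded_significances Significance strings to exclude.
#' @param require_consequence Consequence terms kept by missense selection.
#' @param maf_threshold Strict lower bound on allele frequency for "common"
#'   benign candidates, in \[0, 1\].
#' @param gene_panel Gene symbols to restrict to (empty = no restriction).
#' @param excluded_genes Gene symbols removed after panel restriction.
#' @param exclusion_variant_sets List of character vectors of variant keys
#'   (`chrom:pos:ref:alt`) to exclude (e.g. keys already in other cohorts).
#' @return A `filter_rule_set` list.
#' @export
filter_rule_set <- function(ontology_ids = character(),
                            min_review_stars = 1,
                            excluded_significances = c(
                              "Uncertain_significance",
                              "Conflicting_interpretations_of_pathogenicity"
                            ),
                            require_consequence = "missense_variant",
                            maf_threshold = 0.001,
                            gene_panel = character(),
                            excluded_genes = "TTN",
                            exclusion_variant_sets = list()) {
  stopifnot(maf_threshold >= 0, maf_threshold <= 1)
  structure(list(
    ontology_ids = ontology_ids, min_review_stars = min_review_stars,
    excluded_significances = excluded_significances,
    require_consequence = require_consequence, maf_threshold = maf_threshold,
    gene_panel = gene_panel, excluded_genes = excluded_genes,
    exclusion_variant_sets = exclusion_variant_sets
  ), class = "filter_rule_set")
}

require_fields <- function(records, fields, op) {
  missing_f <- setdiff(fields, names(records))
  if (length(missing_f) > 0) {
    abort(paste0(op, ": records lack required field(s): ",
                 paste(missing_f, collapse = ", ")))
  }
}

#' Build a labelled cohort from ClinVar-style records
#'
#' Applies the disease-specific ClinVar filter chain: keep records matching
#' at least one disease-ontology identifier, drop assertions below the
#' review-star minimum (zero-star records go first), drop excluded
#' significances (uncertain and conflicting interpretations), then label the
#' survivors pathogenic (P/LP) or benign (B/LB) from their significance,
#' dropping anything that maps to neither. Every step is recorded in the
#' audit trail.
#'
#' @param records Variant table carrying `review_stars`, `significance` and
#'   `ontology_ids`.
#' @param rules A [filter_rule_set()].
#' @param name Cohort name (default `"clinvar"`).
#' @return A `cohort_dataset` with pathogenic/benign labels.
#' @export
filter_clinvar <- function(records, rules, name = "clinvar") {
  require_fields(records, c("review_stars", "significance", "ontology_ids"),
                 "filter_clinvar")
  audit <- empty_audit()
  cur <- tibble::as_tibble(records)

  if (length(rules$ontology_ids) > 0) {
    keep <- purrr::map_lgl(cur$ontology_ids,
                           ~ length(intersect(.x, rules$ontology_ids)) > 0)
    audit <- add_audit(audit, "ontology_match", nrow(cur), sum(keep))
    cur <- cur[keep, ]
  }
  keep <- !is.na(cur$review_stars) & cur$review_stars >= rules$min_review_stars
  audit <- add_audit(audit, paste0("review_stars>=", rules$min_review_stars),
                     nrow(cur), sum(keep))
  cur <- cur[keep, ]
  keep <- is.na(cur$significance) |
    !(cur$significance %in% rules$excluded_significances)
  audit <- add_audit(audit, "excluded_significances", nrow(cur), sum(keep))
  cur <- cur[keep, ]
  lab <- vapply(cur$significance, function(s) derive_label(NA_character_, s),
                character(1))
  keep <- lab %in% c("pathogenic", "benign")
  audit <- add_audit(audit, "assignable_significance", nrow(cur), sum(keep))
  cur <- cur[keep, ]
  cur$label <- lab[keep]
  new_cohort_dataset(name, cur, audit)
}

#' Select missense variants
#'
#' Keeps records whose picked consequence contains `missense_variant`
#' (substring match, so compound terms such as
#' `missense_variant&splice_region_variant` are retained). Order preserved.
#'
#' @param records Variant table with a `consequence` column.
#' @return Filtered variant table.
#' @export
select_missense <- function(records) {
  require_fields(records, "consequence", "select_missense")
  records[!is.na(records$consequence) &
            grepl("missense_variant", records$consequence, fixed = TRUE), ]
}

#' Build a benign cohort from population (gnomAD-style) records
#'
#' Filter chain, in order: allele frequency strictly above the MAF threshold
#' (common variants); gene within the disease gene panel; missense
#' consequence; gene not in the excluded set (e.g. TTN, which would dominate
#' the missense pool); variant key absent from every exclusion set (known
#' pathogenic/uncertain keys from other sources). Survivors are labelled
#' benign and then split at random — without replacement, seeded — into the
#' requested disjoint subsets; leftover variants stay in the parent cohort
#' but belong to no split, and their count is logged in the audit trail.
#'
#' @param records Variant table carrying `allele_frequency` and `gene`.
#' @param rules A [filter_rule_set()].
#' @param split_sizes Integer sizes of the disjoint random subsets.
#' @param seed Integer seed for the split.
#' @param name Cohort name.
#' @return List with `cohort` (all survivors) and `splits` (list of
#'   `cohort_dataset`, one per requested size).
#' @export
build_gnomad_benign <- function(records, rules, split_sizes = integer(),
                                seed = 1, name = "gnomad_benign") {
  require_fields(records, c("allele_frequency", "gene"), "build_gnomad_benign")
  audit <- empty_audit()
  cur <- tibble::as_tibble(records)

  keep <- !is.na(cur$allele_frequency) &
    cur$allele_frequency > rules$maf_threshold
  audit <- add_audit(audit, paste0("af>", rules$maf_threshold),
                     nrow(cur), sum(keep))
  cur <- cur[keep, ]
  if (length(rules$gene_panel) > 0) {
    keep <- cur$gene %in% rules$gene_panel
    audit <- add_audit(audit, "gene_panel", nrow(cur), sum(keep))
    cur <- cur[keep, ]
  }
  n_in <- nrow(cur)
  cur <- select_missense(cur)
  audit <- add_audit(audit, "missense", n_in, nrow(cur))
  if (length(rules$excluded_genes) > 0) {
    keep <- !(cur$gene %in% rules$excluded_genes)
    audit <- add_audit(audit, "excluded_genes", nrow(cur), sum(keep))
    cur <- cur[keep, ]
  }
  for (i in seq_along(rules$exclusion_variant_sets)) {
    keep <- !(variant_key(cur) %in% rules$exclusion_variant_sets[[i]])
    audit <- add_audit(audit, paste0("exclusion_set_", i), nrow(cur), sum(keep))
    cur <- cur[keep, ]
  }
  cur$label <- "benign"
  cohort <- new_cohort_dataset(name, cur, audit)

  splits <- list()
  if (length(split_sizes) > 0) {
    if (sum(split_sizes) > nrow(cur)) {
      abort(paste0("build_gnomad_benign: split sizes sum to ",
                   sum(split_sizes), " but only ", nrow(cur),
                   " survivors are available"))
    }
    perm <- withr_seed(seed, sample.int(nrow(cur)))
    offset <- 0L
    splits <- purrr::imap(as.integer(split_sizes), function(sz, i) {
      idx <- perm[seq_len(sz) + offset]
      offset <<- offset + sz
      new_cohort_dataset(
        paste0(name, "_set", i), cur[sort(idx), ],
        add_audit(empty_audit(), "random_split", nrow(cur), sz)
      )
    })
    n_rest <- nrow(cur) - sum(split_sizes)
    if (n_rest > 0) {
      inform(paste0("build_gnomad_benign: ", n_rest,
                    " survivors left unassigned by the split"))
    }
  }
  list(cohort = cohort, splits = splits)
}

#' Import an external clinical variant list as a pathogenic cohort
#'
#' For registry-style lists (e.g. a curated patient registry export): keeps
#' rows with a whitelisted assignment, drops keys already present in other
#' cohorts, drops rows flagged as allele mismatches against the reference
#' annotation, then selects missense variants. Survivors are labelled
#' pathogenic.
#'
#' @param rows Tabular list with columns `chrom`, `pos`, `ref`, `alt`,
#'   `assignment`, `consequence` and logical `allele_mismatch`.
#' @param exclusion_keys Character vector of variant keys already claimed by
#'   other cohorts.
#' @param significance_whitelist Assignments to keep (default P/LP).
#' @param name Cohort name.
#' @return A `cohort_dataset` labelled pathogenic.
#' @export
import_external_list <- function(rows, exclusion_keys = character(),
                                 significance_whitelist = c(
                                   "Pathogenic", "Likely_pathogenic",
                                   "Pathogenic/Likely_pathogenic"
                                 ),
                                 name = "external") {
  require_fields(rows, c(.key_cols, "assignment"), "import_external_list")
  audit <- empty_audit()
  cur <- tibble::as_tibble(rows)

  keep <- cur$assignment %in% significance_whitelist
  audit <- add_audit(audit, "assignment_whitelist", nrow(cur), sum(keep))
  cur <- cur[keep, ]
  keep <- !(variant_key(cur) %in% exclusion_keys)
  audit <- add_audit(audit, "absent_from_exclusion", nrow(cur), sum(keep))
  cur <- cur[keep, ]
  if ("allele_mismatch" %in% names(cur)) {
    keep <- !isTRUE_vec(cur$allele_mismatch)
    audit <- add_audit(audit, "allele_match", nrow(cur), sum(keep))
    cur <- cur[keep, ]
  }
  n_in <- nrow(cur)
  cur <- select_missense(cur)
  audit <- add_audit(audit, "missense", n_in, nrow(cur))
  cur$label <- "pathogenic"
  new_cohort_dataset(name, cur, audit)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Merge labelled cohorts
#'
#' Union keyed by `(chrom, pos, ref, alt)`. With `dedupe = TRUE` the
#' first-listed cohort wins on key collision (its metadata is kept) and the
#' collision count is logged; with `dedupe = FALSE` a key carried by two
#' cohorts with conflicting labels is an error listing the offending keys.
#'
#' @param cohorts List of `cohort_dataset` objects, in priority order.
#' @param dedupe Resolve key collisions by first-cohort priority?
#' @param name Name for the merged cohort.
#' @return A `cohort_dataset`.
#' @export
merge_cohorts <- function(cohorts, dedupe = TRUE, name = "merged") {
  stopifnot(length(cohorts) > 0)
  all_rec <- purrr::map(cohorts, ~ dplyr::mutate(tidy(.x), .cohort = .x$name))
  combined <- dplyr::bind_rows(all_rec)
  keys <- variant_key(combined)
  dup <- duplicated(keys)
  if (any(dup)) {
    if (!dedupe) {
      conflict <- tapply(combined$label, keys, function(l) length(unique(l)) > 1)
      bad <- names(conflict)[conflict]
      if (length(bad) > 0) {
        abort(paste0("merge_cohorts: conflicting labels for key(s): ",
                     paste(bad, collapse = ", ")))
      }
    }
    inform(paste0("merge_cohorts: ", sum(dup),
                  " duplicate key(s) resolved by cohort priority"))
  }
  kept <- combined[!dup, setdiff(names(combined), ".cohort")]
  audit <- add_audit(empty_audit(), "merge_union", nrow(combined), nrow(kept))
  new_cohort_dataset(name, kept, audit)
}

#' Summarize variant distribution by gene and category
#'
#' Produces the per-gene and per-category composition of a cohort. Genes with
#' fewer than `min_gene_count` variants are pooled as `"Other"`. Categories
#' come from the molecular-consequence field, falling back to the picked VEP
#' consequence when empty; `inframe_deletion`/`inframe_insertion` are
#' generalized to `"Inframe indel"` and splice-site/intron terms are combined
#' into `"Splice site/Intron"`. Proportions sum to 1 in each table.
#'
#' @param records Variant table with `gene` and consequence fields.
#' @param min_gene_count Minimum per-gene count to escape pooling (default 5).
#' @return List with `gene_table`, `category_table` and
#'   `per_gene_category_tables` (named list, one category table per
#'   non-pooled gene).
#' @export
summarize_distribution <- function(records, min_gene_count = 5) {
  require_fields(records, c("gene", "consequence"), "summarize_distribution")
  records <- tibble::as_tibble(records)
  mc <- if ("molecular_consequence" %in% names(records)) {
    records$molecular_consequence
  } else {
    rep(NA_character_, nrow(records))
  }
  category <- generalize_category(ifelse(is.na(mc) | !nzchar(mc),
                                         records$consequence, mc))
  gene_counts <- dplyr::count(records, .data$gene, name = "n")
  pooled <- ifelse(
    records$gene %in% gene_counts$gene[gene_counts$n < min_gene_count],
    "Other", records$gene
  )
  gene_table <- dplyr::arrange(
    dplyr::count(tibble::tibble(gene = pooled), .data$gene, name = "n"),
    dplyr::desc(.data$n)
  )
  gene_table$proportion <- gene_table$n / sum(gene_table$n)
  category_table <- dplyr::arrange(
    dplyr::count(tibble::tibble(category = category), .data$category, name = "n"),
    dplyr::desc(.data$n)
  )
  category_table$proportion <- category_table$n / sum(category_table$n)
  per_gene <- purrr::map(
    setNames(nm = setdiff(gene_table$gene, "Other")),
    function(g) {
      tab <- dplyr::count(tibble::tibble(category = category[pooled == g]),
                          .data$category, name = "n")
      tab$proportion <- tab$n / sum(tab$n)
      dplyr::arrange(tab, dplyr::desc(.data$n))
    }
  )
  list(gene_table = gene_table, category_table = category_table,
       per_gene_category_tables = per_gene)
}

generalize_category <- function(x) {
  dplyr::case_when(
    grepl("inframe_(deletion|insertion)", x) ~ "Inframe indel",
    grepl("splice|intron_variant", x) ~ "Splice site/Intron",
    TRUE ~ x
  )
}

#' Exclude variants that appear in predictor training sets
#'
#' Type-I circularity control: removes from a cohort every variant whose key
#' appears in any of the supplied per-tool training-set key collections. The
#' audit trail gains one step per tool set (applied sequentially) plus a
#' final union step, so the per-tool attrition is visible.
#'
#' @param cohort A `cohort_dataset`.
#' @param training_sets Named list, tool -> character vector of variant keys.
#' @return A `cohort_dataset` with the overlapping records removed.
#' @export
exclude_training_overlap <- function(cohort, training_sets) {
  cur <- tidy(cohort)
  audit <- cohort$audit
  for (tool in names(training_sets)) {
    keep <- !(variant_key(cur) %in% training_sets[[tool]])
    audit <- add_audit(audit, paste0("training_overlap:", tool),
                       nrow(cur), sum(keep))
    cur <- cur[keep, ]
  }
  union_keys <- unique(unlist(training_sets, use.names = FALSE))
  keep <- !(variant_key(cur) %in% union_keys)
  audit <- add_audit(audit, "training_overlap:union", nrow(cur), sum(keep))
  cur <- cur[keep, ]
  new_cohort_dataset(paste0(cohort$name, "_excluded_training"), cur, audit)
}

#' Keep variants first reported strictly after a cutoff date
#'
#' Circularity control by recency: a variant reported only after the
#' assessed predictors were trained cannot have leaked into their training
#' data. Records lacking a `first_reported` date are dropped (recency cannot
#' be proven) and their count is logged as its own audit step.
#'
#' @param records Variant table with a `first_reported` date column.
#' @param cutoff A `Date` (or string coercible to one); strict inequality,
#'   so a record dated exactly at the cutoff is removed.
#' @param name Cohort name.
#' @return A `cohort_dataset`.
#' @export
filter_recent <- function(records, cutoff, name = "recent") {
  require_fields(records, "first_reported", "filter_recent")
  cutoff <- as.Date(cutoff)
  cur <- tibble::as_tibble(records)
  audit <- empty_audit()
  keep <- !is.na(cur$first_reported)
  audit <- add_audit(audit, "has_first_reported", nrow(cur), sum(keep))
  if (any(!keep)) {
    inform(paste0("filter_recent: ", sum(!keep), " undated record(s) dropped"))
  }
  cur <- cur[keep, ]
  keep <- cur$first_reported > cutoff
  audit <- add_audit(audit, paste0("first_reported>", format(cutoff)),
                     nrow(cur), sum(keep))
  cur <- cur[keep, ]
  new_cohort_dataset(name, cur, audit)
}

#' Write a cohort's records and audit trail to TSV
#'
#' @param cohort A `cohort_dataset`.
#' @param path_prefix Output prefix; writes `<prefix>_records.tsv` and
#'   `<prefix>_audit.tsv`.
#' @return The two paths, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path_prefix) {
  rec <- tidy(cohort)
  rec$ontology_ids <- NULL
  p1 <- paste0(path_prefix, "_records.tsv")
  p2 <- paste0(path_prefix, "_audit.tsv")
  write_report_tsv(rec, p1)
  write_report_tsv(cohort$audit, p2)
  invisible(c(p1, p2))
}
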