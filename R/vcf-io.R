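#' Parse a predictor-annotated VCF into a variant table and score matrix
#'
#' Reads a VCF 4.x file (plain or bgzipped) whose INFO field and/or VEP-style
#' CSQ block carry per-tool prediction scores, and normalizes it into (i) a
#' variant table with one row per `(chrom, pos, ref, alt)` after multi-allelic
#' decomposition, and (ii) a variants-by-tools score matrix with explicit
#' missingness (`NA`). No allele normalization beyond splitting
#' multi-allelics is performed (no left-alignment): inputs are assumed to be
#' consistently annotated upstream.
#'
#' Per variant, exactly one transcript annotation is chosen from the CSQ
#' block by `pick_policy` (default mimics the pick order
#' ccds, canonical, biotype, rank: prefer transcripts with a CCDS id, then
#' canonical ones, then protein-coding biotype, then the first listed). A
#' tool whose CSQ sub-field is blank or unparseable for the picked transcript
#' is recorded as missing (with a warning for malformed numerics, never a
#' crash). INFO-located tools with several comma-separated values take the
#' per-allele value when the count matches the ALT count, otherwise the most
#' deleterious value under the tool's direction.
#'
#' Clinical metadata are read from configurable INFO keys (`info_fields`):
#' significance, review status (either a star count or a ClinVar-style
#' review-status string), disease-ontology ids, allele frequency, first
#' reported date, label and source. When no explicit label key is present the
#' label is derived from the significance text (P/LP -> pathogenic, B/LB ->
#' benign, Uncertain_significance -> vus, otherwise unlabeled).
#'
#' @param vcf_source Path to the VCF file.
#' @param registry A `tool_registry`; every tool contributes one score column.
#' @param pick_policy Character vector ordering the transcript-pick criteria;
#'   any subset/permutation of `c("ccds", "canonical", "biotype", "rank")`.
#' @param info_fields Named list mapping record metadata to INFO keys; see
#'   Details. Defaults cover ClinVar-style files plus this package's own
#'   output.
#' @param csq_tag INFO key of the VEP consequence block (default `"CSQ"`).
#' @return List with `records` (tibble of variant records) and `scores` (a
#'   `score_matrix` tibble: key columns `chrom`, `pos`, `ref`, `alt`, then one
#'   numeric column per registry tool).
#' @export
parse_annotated_vcf <- function(vcf_source, registry,
                                pick_policy = c("ccds", "canonical", "biotype", "rank"),
                                info_fields = default_info_fields(),
                                csq_tag = "CSQ") {
  vcf <- vcfR::read.vcfR(vcf_source, verbose = FALSE)
  fix <- vcf@fix
  meta <- vcf@meta
  csq_fields <- csq_format_fields(meta, csq_tag)
  needed <- registry$field[registry$location == "csq"]
  if (nrow(registry) > 0 && length(needed) > 0) {
    if (is.null(csq_fields)) {
      abort(paste0("VCF header declares no ", csq_tag,
                   " INFO field but the registry references CSQ sub-fields"))
    }
    missing_fields <- setdiff(needed, csq_fields)
    if (length(missing_fields) > 0) {
      abort(paste0("CSQ sub-field(s) absent from VCF header: ",
                   paste(missing_fields, collapse = ", ")))
    }
  }
  if (nrow(fix) == 0) {
    return(list(records = empty_records_tbl(),
                scores = new_score_matrix(empty_scores_tbl(registry$name))))
  }

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    decompose_record(fix[i, ], registry, csq_fields, pick_policy,
                     info_fields, csq_tag)
  })
  records <- dplyr::bind_rows(purrr::map(rows, "record"))
  scores <- dplyr::bind_rows(purrr::map(rows, "scores"))
  scores <- dplyr::bind_cols(records[.key_cols], scores)
  list(records = records, scores = new_score_matrix(scores))
}

#' @rdname parse_annotated_vcf
#' @export
default_info_fields <- function() {
  list(
    label = "LABEL", source = "SOURCE", significance = "CLNSIG",
    review = "CLNREVSTAT", ontology = "CLNDISDB", af = "AF",
    first_reported = "FIRST_REPORTED", gene = "GENEINFO", mc = "MC"
  )
}

csq_format_fields <- function(meta, csq_tag) {
  line <- grep(paste0("^##INFO=<ID=", csq_tag, ","), meta, value = TRUE)
  if (length(line) == 0) return(NULL)
  m <- stringr::str_match(line[1], "Format: ([^\"]+)")
  if (is.na(m[1, 2])) return(NULL)
  strsplit(trimws(m[1, 2]), "\\|")[[1]]
}

info_value <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))
  m[, 2]
}

# decompose one VCF row into per-alt records and score rows
decompose_record <- function(fixrow, registry, csq_fields, pick_policy,
                             info_fields, csq_tag) {
  alts <- strsplit(fixrow[["ALT"]], ",", fixed = TRUE)[[1]]
  info <- fixrow[["INFO"]]
  csq_raw <- info_value(info, csq_tag)
  csq_entries <- if (!is.na(csq_raw) && !is.null(csq_fields)) {
    purrr::map(strsplit(csq_raw, ",", fixed = TRUE)[[1]], function(e) {
      v <- strsplit(e, "|", fixed = TRUE)[[1]]
      length(v) <- length(csq_fields)
      setNames(ifelse(is.na(v), "", v), csq_fields)
    })
  } else list()

  out <- purrr::map(seq_along(alts), function(ai) {
    alt <- alts[ai]
    picked <- pick_transcript(csq_entries, alt, pick_policy)
    record <- build_record(fixrow, alt, ai, length(alts), picked, info, info_fields)
    scores <- extract_scores(registry, picked, info, ai, length(alts))
    list(record = record, scores = scores)
  })
  list(record = dplyr::bind_rows(purrr::map(out, "record")),
       scores = dplyr::bind_rows(purrr::map(out, "scores")))
}

pick_transcript <- function(entries, alt, pick_policy) {
  if (length(entries) == 0) return(NULL)
  if (!is.null(entries[[1]]) && "Allele" %in% names(entries[[1]])) {
    hits <- purrr::keep(entries, ~ .x[["Allele"]] == alt)
    if (length(hits) > 0) entries <- hits
  }
  if (length(entries) == 1) return(entries[[1]])
  keyfun <- list(
    ccds = function(e) !nzchar(e["CCDS"] %||% ""),        # FALSE sorts first
    canonical = function(e) !identical(unname(e["CANONICAL"]), "YES"),
    biotype = function(e) !identical(unname(e["BIOTYPE"]), "protein_coding"),
    rank = function(e) 0
  )
  ord <- do.call(order, c(
    purrr::map(pick_policy, function(p) {
      vapply(entries, function(e) as.numeric(isTRUE(keyfun[[p]](e))), numeric(1))
    }),
    list(seq_along(entries))
  ))
  entries[[ord[1]]]
}

csq_get <- function(picked, field) {
  if (is.null(picked) || !(field %in% names(picked))) return(NA_character_)
  v <- picked[[field]]
  if (!nzchar(v)) NA_character_ else v
}

build_record <- function(fixrow, alt, ai, n_alt, picked, info, info_fields) {
  sig <- info_value(info, info_fields$significance)
  label_raw <- info_value(info, info_fields$label)
  gene <- csq_get(picked, "SYMBOL")
  if (is.na(gene)) {
    gi <- info_value(info, info_fields$gene)
    gene <- if (!is.na(gi)) strsplit(gi, "[:|]")[[1]][1] else NA_character_
  }
  af_raw <- info_value(info, info_fields$af)
  af <- NA_real_
  if (!is.na(af_raw)) {
    vals <- suppressWarnings(as.numeric(strsplit(af_raw, ",", fixed = TRUE)[[1]]))
    af <- if (length(vals) == n_alt) vals[ai] else vals[1]
  }
  ont_raw <- info_value(info, info_fields$ontology)
  ont <- if (is.na(ont_raw)) character(0) else strsplit(ont_raw, "[|,]")[[1]]
  dt_raw <- info_value(info, info_fields$first_reported)
  mc_raw <- info_value(info, info_fields$mc)
  tibble::tibble(
    chrom = fixrow[["CHROM"]],
    pos = as.integer(fixrow[["POS"]]),
    ref = fixrow[["REF"]],
    alt = alt,
    gene = gene,
    consequence = csq_get(picked, "Consequence"),
    molecular_consequence = if (is.na(mc_raw)) NA_character_ else mc_raw,
    label = derive_label(label_raw, sig),
    source = info_value(info, info_fields$source) %|NA|% "user",
    review_stars = parse_review_stars(info_value(info, info_fields$review)),
    significance = sig,
    ontology_ids = list(ont),
    first_reported = if (is.na(dt_raw)) as.Date(NA) else as.Date(dt_raw),
    allele_frequency = af
  )
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

derive_label <- function(label_raw, sig) {
  if (!is.na(label_raw)) {
    lab <- tolower(label_raw)
    if (lab %in% c("pathogenic", "benign", "vus", "unlabeled")) return(lab)
  }
  if (is.na(sig)) return("unlabeled")
  if (grepl("^(Pathogenic|Likely_pathogenic|Pathogenic/Likely_pathogenic)$", sig)) {
    return("pathogenic")
  }
  if (grepl("^(Benign|Likely_benign|Benign/Likely_benign)$", sig)) return("benign")
  if (grepl("Uncertain_significance", sig)) return("vus")
  "unlabeled"
}

# ClinVar-style review status -> star count; plain integers pass through
parse_review_stars <- function(x) {
  if (is.na(x)) return(NA_integer_)
  n <- suppressWarnings(as.integer(x))
  if (!is.na(n)) return(n)
  dplyr::case_when(
    grepl("practice_guideline", x) ~ 4L,
    grepl("reviewed_by_expert_panel", x) ~ 3L,
    grepl("multiple_submitters", x) & !grepl("conflicting", x) ~ 2L,
    grepl("conflicting", x) ~ 1L,
    grepl("single_submitter", x) ~ 1L,
    TRUE ~ 0L
  )
}

extract_scores <- function(registry, picked, info, ai, n_alt) {
  if (nrow(registry) == 0) return(tibble::tibble(.rows = 1))
  vals <- purrr::pmap_dbl(
    list(registry$name, registry$field, registry$location,
         registry$direction, seq_len(nrow(registry))),
    function(name, field, location, direction, i) {
      raw <- if (location == "csq") {
        csq_get(picked, field)
      } else {
        info_value(info, field)
      }
      if (is.na(raw)) return(NA_real_)
      cmap <- registry$categorical_map[[i]]
      if (!is.null(cmap)) {
        v <- suppressMessages(map_categorical_score(raw, registry[i, ]))
        return(v %||% NA_real_)
      }
      parts <- strsplit(raw, ",", fixed = TRUE)[[1]]
      nums <- suppressWarnings(as.numeric(parts))
      if (all(is.na(nums))) {
        if (any(nzchar(parts))) {
          warn(paste0("tool '", name, "': malformed score '", raw,
                      "' recorded as missing"))
        }
        return(NA_real_)
      }
      if (length(nums) == n_alt && n_alt > 1) return(nums[ai])
      if (length(nums) == 1) return(nums[1])
      # several values for one allele: take the most deleterious
      if (direction == "higher_is_pathogenic") max(nums, na.rm = TRUE)
      else min(nums, na.rm = TRUE)
    }
  )
  tibble::as_tibble(as.list(setNames(vals, registry$name)))
}

empty_records_tbl <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    gene = character(), consequence = character(),
    molecular_consequence = character(), label = character(),
    source = character(), review_stars = integer(), significance = character(),
    ontology_ids = list(), first_reported = as.Date(character()),
    allele_frequency = numeric()
  )
}

empty_scores_tbl <- function(tools) {
  base <- tibble::tibble(chrom = character(), pos = integer(),
                         ref = character(), alt = character())
  for (t in tools) base[[t]] <- numeric()
  base
}

new_score_matrix <- function(tbl) {
  structure(tbl, class = unique(c("score_matrix", class(tibble::as_tibble(tbl)))))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> ", nrow(x), " variants x ",
      ncol(x) - length(.key_cols), " tools; ",
      sum(is.na(as.matrix(x[setdiff(names(x), .key_cols)]))),
      " missing cells\n", sep = "")
  NextMethod()
}

#' Write a normalized variant table and score matrix back to VCF
#'
#' Serializes records (one per decomposed alt allele) with their clinical
#' metadata in INFO keys and per-tool scores in a single-transcript CSQ
#' block. Numeric scores are printed with 17 significant digits so a
#' write/re-parse round trip reproduces the score matrix cell-for-cell,
#' including missingness. Categorical tools are written back as their label
#' (inverse of the categorical map).
#'
#' @param records Variant table as returned by [parse_annotated_vcf()] or
#'   [simulate_cohort()].
#' @param scores Matching `score_matrix`.
#' @param registry The `tool_registry` whose tools populate the CSQ block.
#' @param path Output path (plain-text VCF).
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(records, scores, registry, path) {
  stopifnot(nrow(records) == nrow(scores))
  tools <- registry$name
  csq_fields <- c("Allele", "SYMBOL", "Consequence", "CCDS", "CANONICAL",
                  "BIOTYPE", tools)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(records$chrom), ">"),
    "##INFO=<ID=LABEL,Number=1,Type=String,Description=\"Benchmark label\">",
    "##INFO=<ID=SOURCE,Number=1,Type=String,Description=\"Record provenance\">",
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"Clinical significance\">",
    "##INFO=<ID=CLNREVSTAT,Number=1,Type=String,Description=\"Review status\">",
    "##INFO=<ID=CLNDISDB,Number=1,Type=String,Description=\"Disease ontology ids\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=FIRST_REPORTED,Number=1,Type=String,Description=\"First report date\">",
    "##INFO=<ID=MC,Number=1,Type=String,Description=\"Molecular consequence\">",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations. Format: ", paste(csq_fields, collapse = "|"), "\">"),
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO"), collapse = "\t"))
  )
  fmt_score <- function(tool, v) {
    i <- match(tool, registry$name)
    cmap <- registry$categorical_map[[i]]
    if (!is.null(cmap)) {
      ifelse(is.na(v), "", names(cmap)[match(v, cmap)])
    } else {
      ifelse(is.na(v), "", sprintf("%.17g", v))
    }
  }
  score_strs <- purrr::map(tools, ~ fmt_score(.x, scores[[.x]]))
  names(score_strs) <- tools
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    csq <- paste(c(
      r$alt, r$gene %|NA|% "", r$consequence %|NA|% "", "CCDS0001.1", "YES",
      "protein_coding",
      vapply(tools, function(t) score_strs[[t]][i], character(1))
    ), collapse = "|")
    info <- c(
      paste0("LABEL=", r$label),
      paste0("SOURCE=", r$source),
      if (!is.na(r$significance)) paste0("CLNSIG=", r$significance),
      if (!is.na(r$review_stars)) paste0("CLNREVSTAT=", r$review_stars),
      if (length(r$ontology_ids[[1]]) > 0) {
        paste0("CLNDISDB=", paste(r$ontology_ids[[1]], collapse = "|"))
      },
      if (!is.na(r$allele_frequency)) {
        paste0("AF=", sprintf("%.17g", r$allele_frequency))
      },
      if (!is.na(r$first_reported)) {
        paste0("FIRST_REPORTED=", format(r$first_reported))
      },
      if (!is.na(r$molecular_consequence %||% NA)) {
        paste0("MC=", r$molecular_consequence)
      },
      paste0("CSQ=", csq)
    )
    paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS",
          paste(info, collapse = ";"), sep = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Export the normalized variant table with scores as TSV
#'
#' Columns: chrom, pos, ref, alt, gene, consequence, label, source, then one
#' column per tool. Missing scores are written as ".".
#'
#' @inheritParams write_annotated_vcf
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scored_tsv <- function(records, scores, path) {
  out <- dplyr::bind_cols(
    records[c("chrom", "pos", "ref", "alt", "gene", "consequence",
              "label", "source")],
    scores[setdiff(names(scores), .key_cols)]
  )
  write_report_tsv(out, path)
}
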