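#' Wide calibration report mirroring the per-beta layout
#'
#' One row per tool: reference threshold, then per beta a
#' `"best (q025, q975)"` column and the outside-interval flag.
#'
#' @param result A `calibration_result`.
#' @param digits Display digits for the threshold strings.
#' @return A wide tibble.
#' @export
format_calibration_wide <- function(result, digits = 3) {
  fmt <- function(b, lo, hi) {
    sprintf("%s (%s, %s)", round(b, digits), round(lo, digits), round(hi, digits))
  }
  long <- dplyr::mutate(
    tibble::as_tibble(result),
    cell = fmt(.data$best_threshold, .data$bootstrap_q025, .data$bootstrap_q975)
  )
  wide <- tidyr::pivot_wider(
    long[c("tool", "reference_threshold", "beta", "cell",
           "reference_outside_interval")],
    names_from = "beta",
    values_from = c("cell", "reference_outside_interval"),
    names_glue = "{.value}_beta_{beta}"
  )
  dplyr::rename_with(wide, ~ sub("^cell_", "threshold_", .x))
}

config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  unname(tools::md5sum(tmp))
}

file_digests <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

write_manifest <- function(out_dir, command, config, inputs, seed) {
  jsonlite::write_json(list(
    command = command,
    config_digest = config_digest(config),
    input_digests = file_digests(inputs),
    seed = seed,
    tool_registry_version = as.character(utils::packageVersion("predbench")),
    timestamp = format(Sys.time(), tz = "UTC")
  ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
}

config_profiles <- function(cfg_profiles) {
  purrr::map(cfg_profiles, function(p) {
    mk_dist <- function(d) do.call(score_dist, c(list(family = d$family),
                                                 d[setdiff(names(d), "family")]))
    sim_tool_profile(
      name = p$name,
      direction = p$direction %||% "higher_is_pathogenic",
      pathogenic = if (!is.null(p$pathogenic)) mk_dist(p$pathogenic) else
        score_dist("beta", shape1 = 8, shape2 = 2),
      benign = if (!is.null(p$benign)) mk_dist(p$benign) else
        score_dist("beta", shape1 = 2, shape2 = 8),
      missingness = unlist(p$missingness %||% c(0, 0)),
      reference_threshold = p$reference_threshold %||% 0.5
    )
  })
}

load_registry_arg <- function(registry) {
  if (is.null(registry) || identical(registry, "default")) default_registry()
  else if (inherits(registry, "tool_registry")) registry
  else load_tool_registry(registry)
}

#' Run one pipeline stage end-to-end
#'
#' Uniform front end over the package: validates a structured config,
#' executes the requested stage, writes TSV reports plus a JSON run manifest
#' (config and input digests, seed, package version, timestamp) into the
#' output directory, and cleans up partial outputs on error. All randomness
#' flows from the config-level `seed`; per-stage sub-seeds are derived from
#' it deterministically, so two runs with the same config and inputs produce
#' identical report files.
#'
#' Commands and their main config keys:
#' \describe{
#'   \item{simulate}{`spec` (class sizes, seed), `profiles`; writes
#'     `cohort.vcf`, `truth.tsv`, `provenance.json`.}
#'   \item{build-cohort}{`vcf`, optional `rules`; writes cohort records and
#'     audit TSVs.}
#'   \item{benchmark}{`vcf`, `registry`, optional `mode` (`fixed`/`roc`),
#'     optional `thresholds` override map; writes `ranking_<mode>.tsv`.}
#'   \item{calibrate}{`vcf`, `registry`, `betas`, `n_boot`; writes
#'     `calibration.tsv` (long) and `calibration_wide.tsv`.}
#'   \item{rank}{`vcf`, `registry`, `k`, optional `weights`; ranks by both
#'     metrics and writes `top_tools.tsv`.}
#'   \item{prioritize}{`vcf`, `registry`, `tools`, optional `thresholds`;
#'     writes `prioritization.tsv`.}
#' }
#'
#' @param command One of `"simulate"`, `"build-cohort"`, `"benchmark"`,
#'   `"calibrate"`, `"rank"`, `"prioritize"`.
#' @param config Named list, or path to a YAML file with the stage's keys;
#'   must contain `out_dir`.
#' @return Named character vector of output paths, invisibly.
#' @export
run_pipeline <- function(command, config) {
  command <- match.arg(command, c("simulate", "build-cohort", "benchmark",
                                  "calibrate", "rank", "prioritize"))
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) abort("config error at 'out_dir': required")
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  inputs <- purrr::keep(list(config$vcf, config$registry),
                        ~ is.character(.x) && length(.x) == 1)
  inputs <- purrr::keep(as.character(inputs), file.exists)

  paths <- tryCatch(
    switch(command,
      "simulate" = pipeline_simulate(config, out_dir, seed),
      "build-cohort" = pipeline_build_cohort(config, out_dir),
      "benchmark" = pipeline_benchmark(config, out_dir),
      "calibrate" = pipeline_calibrate(config, out_dir, seed),
      "rank" = pipeline_rank(config, out_dir, seed),
      "prioritize" = pipeline_prioritize(config, out_dir)
    ),
    error = function(e) {
      if (created) unlink(out_dir, recursive = TRUE)
      abort(paste0("pipeline '", command, "' failed: ", conditionMessage(e)))
    }
  )
  write_manifest(out_dir, command, config, inputs, seed)
  invisible(c(paths, manifest = file.path(out_dir, "manifest.json")))
}

pipeline_simulate <- function(config, out_dir, seed) {
  if (is.null(config$profiles)) abort("config error at 'profiles': required")
  sp <- config$spec %||% list()
  spec <- sim_cohort_spec(
    n_pathogenic = sp$n_pathogenic %||% 100,
    n_benign = sp$n_benign %||% 100,
    n_vus = sp$n_vus %||% 0,
    seed = sp$seed %||% seed
  )
  sim <- simulate_cohort(spec, config_profiles(config$profiles), dir = out_dir)
  sim$paths
}

pipeline_build_cohort <- function(config, out_dir) {
  if (is.null(config$vcf)) abort("config error at 'vcf': required")
  if (!file.exists(config$vcf)) abort(paste0("input not found: ", config$vcf))
  registry <- load_registry_arg(config$registry)
  parsed <- parse_annotated_vcf(config$vcf, registry)
  r <- config$rules %||% list()
  rules <- filter_rule_set(
    ontology_ids = unlist(r$ontology_ids %||% character(0)),
    min_review_stars = r$min_review_stars %||% 1
  )
  cohort <- filter_clinvar(parsed$records, rules,
                           name = config$name %||% "cohort")
  mis <- select_missense(tidy(cohort))
  cohort2 <- new_cohort_dataset(cohort$name, mis,
                                add_audit(cohort$audit, "missense",
                                          nrow(tidy(cohort)), nrow(mis)))
  write_cohort_tsv(cohort2, file.path(out_dir, cohort2$name))
  setNames(file.path(out_dir, paste0(cohort2$name,
                                     c("_records.tsv", "_audit.tsv"))),
           c("records", "audit"))
}

parse_labelled_input <- function(config) {
  if (is.null(config$vcf)) abort("config error at 'vcf': required")
  if (!file.exists(config$vcf)) abort(paste0("input not found: ", config$vcf))
  registry <- load_registry_arg(config$registry)
  parsed <- parse_annotated_vcf(config$vcf, registry)
  list(registry = registry, records = parsed$records, scores = parsed$scores)
}

labelled_cohort <- function(records, name = "dataset") {
  keep <- records$label %in% c("pathogenic", "benign")
  new_cohort_dataset(name, records[keep, ],
                     add_audit(empty_audit(), "labelled", nrow(records),
                               sum(keep)))
}

pipeline_benchmark <- function(config, out_dir) {
  inp <- parse_labelled_input(config)
  mode <- match.arg(config$mode %||% "fixed", c("fixed", "roc"))
  cohort <- labelled_cohort(inp$records)
  tbl <- if (mode == "fixed") {
    evaluate_fixed(cohort, inp$scores, inp$registry,
                   threshold_override = config$thresholds)
  } else {
    evaluate_roc(cohort, inp$scores, inp$registry,
                 min_coverage = config$min_coverage %||% 0.5)
  }
  p <- file.path(out_dir, paste0("ranking_", mode, ".tsv"))
  write_report_tsv(tbl, p)
  c(ranking = p)
}

pipeline_calibrate <- function(config, out_dir, seed) {
  inp <- parse_labelled_input(config)
  betas <- unlist(config$betas %||% c(0.5, 1, 1.5))
  if (any(betas <= 0)) abort("config error at 'betas': must be positive")
  cohort <- labelled_cohort(inp$records)
  data <- scores_with_labels(cohort, inp$scores)
  cal <- calibrate_thresholds(data, inp$registry, betas = betas,
                              n_boot = config$n_boot %||% 1000, seed = seed)
  p1 <- file.path(out_dir, "calibration.tsv")
  p2 <- file.path(out_dir, "calibration_wide.tsv")
  write_report_tsv(cal, p1)
  readr::write_tsv(format_calibration_wide(cal), p2, progress = FALSE)
  c(calibration = p1, calibration_wide = p2)
}

pipeline_rank <- function(config, out_dir, seed) {
  inp <- parse_labelled_input(config)
  cohort <- labelled_cohort(inp$records)
  t_fixed <- evaluate_fixed(cohort, inp$scores, inp$registry)
  t_roc <- evaluate_roc(cohort, inp$scores, inp$registry,
                        min_coverage = config$min_coverage %||% 0.5)
  k <- config$k %||% 5
  sel <- average_rank_select(list(t_fixed, t_roc), k = k,
                             weights = unlist(config$weights %||% NULL))
  p <- file.path(out_dir, "top_tools.tsv")
  write_report_tsv(sel, p)
  c(top_tools = p)
}

pipeline_prioritize <- function(config, out_dir) {
  inp <- parse_labelled_input(config)
  tools <- unlist(config$tools %||% inp$registry$name)
  top <- inp$registry[inp$registry$name %in% tools, ]
  thresholds <- config$thresholds %||%
    setNames(as.list(top$reference_threshold), top$name)
  vus <- inp$scores[inp$records$label == "vus", ]
  vus$gene <- inp$records$gene[inp$records$label == "vus"]
  rep <- prioritize_vus(vus, top, thresholds,
                        majority = config$majority %||% 0.5)
  p <- file.path(out_dir, "prioritization.tsv")
  write_report_tsv(rep, p)
  c(prioritization = p)
}
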