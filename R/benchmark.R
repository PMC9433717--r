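#' Join cohort labels onto a score matrix
#'
#' Inner-joins a labelled cohort with a score matrix on the variant key,
#' returning one row per labelled variant with its label and one score
#' column per tool — the shape every evaluation function consumes.
#'
#' @param cohort A `cohort_dataset` (or a variant table with a `label`
#'   column).
#' @param scores A `score_matrix`.
#' @return Tibble with key columns, `label`, and the tool columns.
#' @export
scores_with_labels <- function(cohort, scores) {
  rec <- if (inherits(cohort, "cohort_dataset")) tidy(cohort) else cohort
  dplyr::inner_join(rec[c(.key_cols, "label")], tibble::as_tibble(scores),
                    by = .key_cols)
}

rank_rows <- function(tbl, metric) {
  # undefined metric values rank below all defined ones; ties broken by
  # higher coverage, then tool name
  cov <- tbl$coverage %||% rep(0, nrow(tbl))
  ord <- order(is.na(tbl[[metric]]), -ifelse(is.na(tbl[[metric]]), -Inf,
                                             tbl[[metric]]),
               -cov, tbl$tool)
  out <- tbl[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

new_ranking_table <- function(tbl, dataset, metric) {
  structure(tbl, class = c("ranking_table", class(tbl)),
            dataset = dataset, ranking_metric = metric)
}

#' @export
print.ranking_table <- function(x, ...) {
  cat("<ranking_table> dataset '", attr(x, "dataset"), "', ranked by ",
      attr(x, "ranking_metric"), "\n", sep = "")
  NextMethod()
}

#' @export
glance.ranking_table <- function(x, ...) {
  tibble::tibble(
    dataset = attr(x, "dataset"),
    ranking_metric = attr(x, "ranking_metric"),
    n_tools = nrow(x),
    top_tool = x$tool[1]
  )
}

#' Fixed-threshold evaluation and coverage-weighted MCC ranking
#'
#' Evaluates every registry tool on a labelled cohort at its published
#' reference threshold (or a per-tool override, e.g. a calibrated
#' threshold), and ranks tools by the coverage-weighted normalized MCC.
#' Tools whose metrics are undefined rank below all defined ones; metric
#' ties break by higher coverage, then tool name.
#'
#' @param cohort A `cohort_dataset` with both classes present.
#' @param scores A `score_matrix` covering the cohort.
#' @param registry A `tool_registry`.
#' @param threshold_override Optional named numeric vector/list,
#'   tool -> replacement threshold; every name must exist in the registry.
#' @return A `ranking_table` tibble: `tool`, `rank`, `threshold`, and all
#'   [confusion_at_threshold()] columns.
#' @export
evaluate_fixed <- function(cohort, scores, registry, threshold_override = NULL) {
  data <- scores_with_labels(cohort, scores)
  check_two_classes(data)
  if (!is.null(threshold_override)) {
    unknown <- setdiff(names(threshold_override), registry$name)
    if (length(unknown) > 0) {
      abort(paste0("threshold_override names absent from registry: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  tools <- intersect(registry$name, names(data))
  rows <- purrr::map(tools, function(tool) {
    spec <- registry_spec(registry, tool)
    thr <- threshold_override[[tool]] %||% spec$reference_threshold
    cs <- confusion_at_threshold(data[[tool]], data$label, thr, spec$comparator)
    dplyr::bind_cols(tibble::tibble(tool = tool, threshold = thr), cs)
  })
  tbl <- rank_rows(dplyr::bind_rows(rows), "weighted_norm_mcc")
  name <- if (inherits(cohort, "cohort_dataset")) cohort$name else "dataset"
  new_ranking_table(tbl, name, "weighted_norm_mcc")
}

check_two_classes <- function(data) {
  if (length(unique(data$label[data$label %in% c("pathogenic", "benign")])) < 2 ||
      !all(data$label %in% c("pathogenic", "benign"))) {
    abort("evaluation requires a cohort labelled pathogenic/benign with both classes")
  }
}

#' Multi-threshold (ROC) evaluation and auROC ranking
#'
#' Rank-transforms each tool's scores (inverting lower-is-pathogenic tools),
#' builds ROC curves on scored variants only, and ranks tools by auROC.
#' Tools scoring fewer than `min_coverage` of the cohort are excluded from
#' the ranking and listed separately, as are categorical tools flagged
#' `excluded_from_multithreshold` (their artificial numeric scale has no
#' meaningful threshold sweep).
#'
#' @inheritParams evaluate_fixed
#' @param min_coverage Minimum fraction of scored variants (default 0.5).
#' @return A `ranking_table` (`tool`, `rank`, `auroc`, `coverage`,
#'   `n_scored`, `n_pos`, `n_neg`) with the excluded tools in
#'   `attr(, "excluded")`.
#' @export
evaluate_roc <- function(cohort, scores, registry, min_coverage = 0.5) {
  data <- scores_with_labels(cohort, scores)
  check_two_classes(data)
  tools <- intersect(registry$name, names(data))
  excluded <- tibble::tibble(tool = character(), reason = character())
  rows <- purrr::map(tools, function(tool) {
    spec <- registry_spec(registry, tool)
    if (spec$excluded_from_multithreshold) {
      excluded <<- dplyr::bind_rows(excluded,
                                    tibble::tibble(tool = tool,
                                                   reason = "categorical"))
      return(NULL)
    }
    s <- data[[tool]]
    coverage <- mean(!is.na(s))
    if (coverage < min_coverage) {
      excluded <<- dplyr::bind_rows(excluded,
                                    tibble::tibble(tool = tool,
                                                   reason = "low_coverage"))
      return(NULL)
    }
    rt <- rank_transform(s, spec$direction)
    roc <- roc_and_auroc(rt, data$label)
    tibble::tibble(tool = tool, auroc = roc$auroc, coverage = coverage,
                   n_scored = roc$n_scored, n_pos = roc$n_pos,
                   n_neg = roc$n_neg)
  })
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) == 0) abort("evaluate_roc: all tools excluded")
  tbl <- rank_rows(tbl, "auroc")
  name <- if (inherits(cohort, "cohort_dataset")) cohort$name else "dataset"
  out <- new_ranking_table(tbl, name, "auroc")
  attr(out, "excluded") <- excluded
  out
}

#' Select top tools by average rank across datasets
#'
#' Averages each tool's rank across several ranking tables (optionally
#' weighted, e.g. by dataset size so larger cohorts count for more) and
#' returns the `k` tools with the lowest average rank. A tool missing from a
#' table (e.g. excluded by the coverage rule) receives that table's worst
#' rank plus one, so exclusion is penalized but not disqualifying. Ties in
#' average rank break by tool name.
#'
#' @param tables List of `ranking_table` objects.
#' @param k Number of tools to select.
#' @param weights Optional per-table positive weights (default uniform).
#' @return Tibble of the selected tools: `tool`, `avg_rank`, ordered best
#'   first.
#' @export
average_rank_select <- function(tables, k, weights = NULL) {
  stopifnot(length(tables) > 0)
  if (is.null(weights)) weights <- rep(1, length(tables))
  stopifnot(length(weights) == length(tables), all(weights > 0))
  universe <- unique(unlist(purrr::map(tables, "tool")))
  if (k > length(universe)) {
    abort(paste0("average_rank_select: k = ", k, " exceeds the ",
                 length(universe), " tools available"))
  }
  rank_mat <- purrr::map(tables, function(tb) {
    worst <- max(tb$rank) + 1
    r <- tb$rank[match(universe, tb$tool)]
    miss <- is.na(r)
    if (any(miss)) {
      inform(paste0("average_rank_select: ", sum(miss), " tool(s) missing ",
                    "from table '", attr(tb, "dataset"),
                    "' assigned worst rank + 1"))
    }
    ifelse(miss, worst, r)
  })
  avg <- Reduce(`+`, purrr::map2(rank_mat, weights, `*`)) / sum(weights)
  out <- tibble::tibble(tool = universe, avg_rank = avg)
  out <- out[order(out$avg_rank, out$tool), ]
  head(out, k)
}

#' Prioritize VUS by top-tool ensemble agreement
#'
#' Classifies each variant of unknown significance against every
#' top-performing tool that scored it, and tiers the variants by agreement:
#' `unanimous_pathogenic` when every scoring tool calls it pathogenic,
#' `majority_pathogenic` when strictly more than `majority` of scoring tools
#' do, `majority_benign` otherwise. The denominator is the number of tools
#' that scored the variant (not the nominal panel size) unless
#' `denominator = "panel"`. Variants scored by no tool are tiered
#' `"unscored"` and excluded from percentage summaries.
#'
#' @param vus_scores A `score_matrix` of VUS (key columns + tool columns);
#'   extra metadata columns such as `gene` are carried through.
#' @param top_tools A `tool_registry` slice of the selected tools.
#' @param thresholds Named numeric, tool -> decision threshold (reference or
#'   calibrated); must cover `top_tools`.
#' @param majority Strict agreement cut (default 0.5).
#' @param denominator `"scored"` (default) or `"panel"`.
#' @return A `prioritization_report` tibble: key columns, `gene` (if
#'   present), `n_tools_scored`, `n_tools_pathogenic`, `agreement_fraction`,
#'   `tier`.
#' @export
prioritize_vus <- function(vus_scores, top_tools, thresholds, majority = 0.5,
                           denominator = c("scored", "panel")) {
  denominator <- match.arg(denominator)
  if (nrow(top_tools) == 0) abort("prioritize_vus: top_tools is empty")
  missing_thr <- setdiff(top_tools$name, names(thresholds))
  if (length(missing_thr) > 0) {
    abort(paste0("prioritize_vus: no threshold for tool(s): ",
                 paste(missing_thr, collapse = ", ")))
  }
  vus <- tibble::as_tibble(vus_scores)
  calls <- purrr::map(top_tools$name, function(tool) {
    spec <- registry_spec(top_tools, tool)
    classify_calls(vus[[tool]], thresholds[[tool]], spec$comparator)
  })
  call_mat <- do.call(cbind, calls)
  n_scored <- rowSums(!is.na(call_mat))
  n_path <- rowSums(call_mat, na.rm = TRUE)
  denom <- if (denominator == "panel") rep(nrow(top_tools), nrow(vus)) else n_scored
  frac <- ifelse(denom > 0, n_path / denom, NA_real_)
  tier <- dplyr::case_when(
    n_scored == 0 ~ "unscored",
    n_path == n_scored & n_scored > 0 & denominator == "scored" ~ "unanimous_pathogenic",
    n_path == denom & denominator == "panel" ~ "unanimous_pathogenic",
    frac > majority ~ "majority_pathogenic",
    TRUE ~ "majority_benign"
  )
  if (any(tier == "unscored")) {
    inform(paste0("prioritize_vus: ", sum(tier == "unscored"),
                  " variant(s) scored by zero tools"))
  }
  keep_meta <- intersect(c(.key_cols, "gene"), names(vus))
  out <- dplyr::bind_cols(
    vus[keep_meta],
    tibble::tibble(n_tools_scored = n_scored, n_tools_pathogenic = n_path,
                   agreement_fraction = frac, tier = tier)
  )
  structure(out, class = c("prioritization_report", class(out)),
            majority = majority, denominator = denominator)
}

#' @export
glance.prioritization_report <- function(x, ...) {
  scored <- x[x$tier != "unscored", ]
  tibble::tibble(
    n_variants = nrow(x),
    n_scored = nrow(scored),
    n_unanimous_pathogenic = sum(scored$tier == "unanimous_pathogenic"),
    frac_majority_pathogenic = mean(
      scored$tier %in% c("unanimous_pathogenic", "majority_pathogenic")
    ),
    frac_majority_benign = mean(scored$tier == "majority_benign")
  )
}

#' Bar chart of a tool ranking
#'
#' @param x A `ranking_table`.
#' @return A ggplot object.
#' @export
plot_ranking <- function(x) {
  metric <- attr(x, "ranking_metric")
  ggplot2::ggplot(x, ggplot2::aes(
    x = .data[[metric]], y = stats::reorder(.data$tool, -.data$rank)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = metric, y = NULL,
                  title = paste0("Tool ranking (", attr(x, "dataset"), ")")) +
    ggplot2::theme_minimal()
}
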