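#' Uniform threshold grid over the observed score range
#'
#' @param scores Non-missing numeric scores (NAs are dropped).
#' @param n_points Number of grid points (default 100), endpoints included.
#' @return Ordered numeric vector of length `n_points` spanning
#'   `[min(scores), max(scores)]`.
#' @export
#' @examples
#' threshold_grid(c(-10, 0, 10), n_points = 5) # -10 -5 0 5 10
threshold_grid <- function(scores, n_points = 100) {
  scores <- scores[!is.na(scores)]
  if (length(unique(scores)) < 2) {
    abort("threshold_grid: need at least 2 distinct scores (degenerate range)")
  }
  seq(min(scores), max(scores), length.out = n_points)
}

# F-beta at every grid point, via sorted-score counting: for each threshold,
# tp/fp follow from how many class scores lie strictly beyond it. Equivalent
# to calling confusion_at_threshold() per grid point (property-tested), but
# O((n + G) log n) instead of O(n G).
fbeta_on_grid <- function(scores, labels, comparator, beta, grid) {
  ok <- !is.na(scores)
  sp <- sort(scores[ok & labels == "pathogenic"])
  sb <- sort(scores[ok & labels == "benign"])
  n_pos <- length(sp)
  if (comparator == "strict_greater") {
    tp <- n_pos - findInterval(grid, sp)            # pathogenic scores > th
    fp <- length(sb) - findInterval(grid, sb)
  } else {
    tp <- findInterval(grid, sp, left.open = TRUE)  # pathogenic scores < th
    fp <- findInterval(grid, sb, left.open = TRUE)
  }
  fn <- n_pos - tp
  precision <- ifelse(tp + fp == 0, NA_real_, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, NA_real_, tp / (tp + fn))
  f_beta(precision, recall, beta)
}

#' Best decision threshold by F-beta grid search
#'
#' Evaluates the confusion matrix at each of `n_points` thresholds uniformly
#' spaced over the observed score range and returns the threshold maximizing
#' the F-beta score. Ties are broken towards the most stringent threshold
#' (the one calling fewest variants pathogenic): the largest tied threshold
#' for `strict_greater` tools, the smallest for `strict_less` — a
#' conservative clinical default that is also deterministic.
#'
#' @inheritParams confusion_at_threshold
#' @param beta Positive F-beta weight; beta < 1 favours precision, beta > 1
#'   favours recall.
#' @param grid Optional pre-computed threshold grid (used by the bootstrap so
#'   that all replicates share one scale); defaults to
#'   `threshold_grid(scores, n_points)`.
#' @param n_points Grid size when `grid` is not supplied.
#' @return One-row tibble: `threshold`, `fbeta`.
#' @export
best_threshold <- function(scores, labels, comparator = "strict_greater",
                           beta = 1, grid = NULL, n_points = 100) {
  labels <- as.character(labels)
  ok <- !is.na(scores)
  if (length(unique(labels[ok])) < 2) {
    abort("best_threshold: both classes must be present among scored variants")
  }
  if (is.null(grid)) grid <- threshold_grid(scores, n_points)
  fb <- fbeta_on_grid(scores, labels, comparator, beta, grid)
  best <- which(fb == max(fb))
  # most stringent tied threshold: fewest pathogenic calls
  i <- if (comparator == "strict_less") min(best) else max(best)
  tibble::tibble(threshold = grid[i], fbeta = fb[i])
}

#' Bootstrap stability of the calibrated threshold
#'
#' Draws `n_boot` stratified bootstrap samples — resampling with replacement
#' within each class so every replicate has exactly the original
#' pathogenic/benign counts — recomputes the best F-beta threshold on each,
#' and returns the empirical 0.025/0.975 quantiles of the replicate
#' thresholds. All replicates are evaluated on the threshold grid of the
#' original sample, so interval endpoints live on a common scale. Fully
#' reproducible for a given `seed`.
#'
#' @inheritParams best_threshold
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @return List with `q025`, `q975` and the full numeric vector
#'   `sample_thresholds` (length `n_boot`) for diagnostics.
#' @export
bootstrap_threshold <- function(scores, labels, comparator = "strict_greater",
                                beta = 1, n_boot = 1000, seed = 1,
                                grid = NULL, n_points = 100) {
  if (n_boot < 2) abort("bootstrap_threshold: n_boot must be at least 2")
  labels <- as.character(labels)
  ok <- !is.na(scores)
  s <- scores[ok]
  l <- labels[ok]
  idx_pos <- which(l == "pathogenic")
  idx_neg <- which(l == "benign")
  if (length(idx_pos) == 0 || length(idx_neg) == 0) {
    abort("bootstrap_threshold: both classes must be present among scored variants")
  }
  if (is.null(grid)) grid <- threshold_grid(s, n_points)
  thr <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- c(sample(idx_pos, replace = TRUE), sample(idx_neg, replace = TRUE))
      best_threshold(s[take], l[take], comparator, beta, grid = grid)$threshold
    }, numeric(1))
  })
  qs <- unname(quantile(thr, c(0.025, 0.975), type = 7))
  list(q025 = qs[1], q975 = qs[2], sample_thresholds = thr)
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Calibrate disease-specific thresholds for every tool
#'
#' Runs the F-beta grid optimization plus bootstrap for each numeric tool in
#' the registry and each beta value, flagging tools whose published reference
#' threshold falls outside the bootstrap 95% interval (the tell-tale of a
#' threshold that is suboptimal for the disease cohort at hand). Categorical
#' tools marked `excluded_from_multithreshold` are skipped.
#'
#' @param data A labelled variant table joined with scores (one column per
#'   tool), e.g. `scores_with_labels(cohort, matrix)`.
#' @param registry A `tool_registry`.
#' @param betas Numeric vector of beta values (default `c(0.5, 1, 1.5)`).
#' @param n_boot Bootstrap replicates per tool/beta.
#' @param seed Integer seed; per-tool/beta sub-seeds are derived
#'   deterministically from it.
#' @param n_points Threshold-grid size.
#' @return A `calibration_result` tibble: one row per tool and beta with
#'   columns `tool`, `beta`, `reference_threshold`, `best_threshold`,
#'   `best_fbeta`, `bootstrap_q025`, `bootstrap_q975`, `n_bootstrap`,
#'   `reference_outside_interval`.
#' @export
calibrate_thresholds <- function(data, registry, betas = c(0.5, 1, 1.5),
                                 n_boot = 1000, seed = 1, n_points = 100) {
  stopifnot(all(betas > 0))
  tools <- registry$name[!registry$excluded_from_multithreshold]
  tools <- intersect(tools, names(data))
  combos <- tidyr::expand_grid(tool = tools, beta = betas)
  rows <- purrr::pmap(combos, function(tool, beta) {
    spec <- registry_spec(registry, tool)
    s <- data[[tool]]
    l <- data$label
    ok <- !is.na(s)
    if (length(unique(l[ok])) < 2 || length(unique(s[ok])) < 2) {
      return(NULL) # tool unusable on this cohort; dropped from the report
    }
    grid <- threshold_grid(s, n_points)
    bt <- best_threshold(s, l, spec$comparator, beta, grid = grid)
    sub_seed <- derive_seed(seed, paste(tool, beta))
    bs <- bootstrap_threshold(s, l, spec$comparator, beta, n_boot = n_boot,
                              seed = sub_seed, grid = grid)
    tibble::tibble(
      tool = tool, beta = beta,
      reference_threshold = spec$reference_threshold,
      best_threshold = bt$threshold, best_fbeta = bt$fbeta,
      bootstrap_q025 = bs$q025, bootstrap_q975 = bs$q975,
      n_bootstrap = n_boot,
      reference_outside_interval =
        spec$reference_threshold < bs$q025 | spec$reference_threshold > bs$q975
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("calibration_result", class(out)), seed = seed)
}

# deterministic 31-bit sub-seed from a master seed and a stage label
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

#' Is the published reference threshold outside the bootstrap interval?
#'
#' TRUE iff the reference threshold lies strictly below the 0.025 quantile or
#' strictly above the 0.975 quantile of the bootstrap threshold distribution
#' (the interval is closed: a reference exactly at an endpoint is inside).
#'
#' @param result A `calibration_result` tibble (or compatible data frame with
#'   `reference_threshold`, `bootstrap_q025`, `bootstrap_q975`).
#' @return Logical vector, one per row.
#' @export
#' @examples
#' assess_reference(data.frame(reference_threshold = 0.5,
#'                             bootstrap_q025 = 0.366, bootstrap_q975 = 0.832))
assess_reference <- function(result) {
  result$reference_threshold < result$bootstrap_q025 |
    result$reference_threshold > result$bootstrap_q975
}

#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(
    n_tools = dplyr::n_distinct(x$tool),
    n_betas = dplyr::n_distinct(x$beta),
    n_reference_outside = sum(x$reference_outside_interval),
    seed = attr(x, "seed") %||% NA_integer_
  )
}

#' Plot calibrated thresholds with bootstrap intervals
#'
#' One panel per beta: point = calibrated threshold, segment = bootstrap 95%
#' interval, cross = published reference threshold.
#'
#' @param x A `calibration_result`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(y = .data$tool)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$bootstrap_q025,
                                       xend = .data$bootstrap_q975,
                                       yend = .data$tool),
                          colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(x = .data$best_threshold)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$reference_threshold),
                        shape = 4, colour = "red") +
    ggplot2::facet_wrap(~beta, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "threshold (tool-native scale)", y = NULL) +
    ggplot2::theme_minimal()
}
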