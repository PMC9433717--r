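#' Predictor tool registry
#'
#' A tool registry declares, for every pathogenicity predictor to benchmark,
#' where its score lives in an annotated VCF, which side of its decision
#' threshold is pathogenic, and the published reference threshold on the
#' tool's native scale. The package ships a default registry of 39 predictors
#' spanning protein-level, conservation, consequence-agnostic and
#' disease-specific methods.
#'
#' Comparators are strict throughout: a score strictly greater than the
#' threshold (or strictly less, for lower-is-pathogenic tools such as SIFT,
#' FATHMM, PROVEAN, MTR and CDTS) is called pathogenic; a score exactly at the
#' threshold is classified benign.
#'
#' @param config_source Path to a YAML registry file (one entry per tool), or
#'   a named list with the same structure.
#' @return A `tool_registry` tibble with one row per tool and columns `name`,
#'   `field`, `location`, `direction`, `comparator`, `reference_threshold`,
#'   `scope`, `excluded_from_multithreshold`, `categorical_map` (list-column),
#'   `range_min`, `range_max`. Tools appear in declaration order.
#' @export
#' @examples
#' reg <- default_registry()
#' nrow(reg) # 39
#' reg[reg$name == "FATHMM", c("comparator", "reference_threshold")]
load_tool_registry <- function(config_source) {
  cfg <- if (is.character(config_source)) {
    if (!file.exists(config_source)) {
      abort(paste0("registry config not found: ", config_source))
    }
    yaml::read_yaml(config_source)
  } else if (is.list(config_source)) {
    config_source
  } else {
    abort("config_source must be a file path or a named list")
  }
  if (length(cfg) == 0) {
    return(new_tool_registry(empty_registry_tbl()))
  }
  nms <- names(cfg)
  if (is.null(nms) || any(nms == "")) {
    abort("registry config must be a named map, one entry per tool")
  }
  if (anyDuplicated(nms)) {
    abort(paste0(
      "duplicate tool name(s) in registry: ",
      paste(unique(nms[duplicated(nms)]), collapse = ", ")
    ))
  }
  rows <- purrr::imap(cfg, parse_tool_entry)
  reg <- dplyr::bind_rows(rows)
  new_tool_registry(reg)
}

allowed_registry_keys <- c(
  "field", "location", "direction", "reference_threshold", "scope",
  "excluded_from_multithreshold", "categorical_map", "range_min", "range_max"
)

parse_tool_entry <- function(entry, name) {
  if (!is.list(entry)) abort(paste0("tool '", name, "': entry must be a map"))
  unknown <- setdiff(names(entry), allowed_registry_keys)
  if (length(unknown) > 0) {
    abort(paste0(
      "tool '", name, "': unknown registry key(s): ",
      paste(unknown, collapse = ", ")
    ))
  }
  for (key in c("field", "direction", "reference_threshold")) {
    if (is.null(entry[[key]])) {
      abort(paste0("tool '", name, "': missing mandatory registry key '", key, "'"))
    }
  }
  direction <- match.arg(entry$direction,
                         c("higher_is_pathogenic", "lower_is_pathogenic"))
  thr <- as.numeric(entry$reference_threshold)
  if (!is.finite(thr)) {
    abort(paste0("tool '", name, "': reference_threshold must be finite"))
  }
  cmap <- entry$categorical_map
  if (!is.null(cmap)) {
    cmap <- unlist(cmap)
    if (anyDuplicated(cmap)) {
      abort(paste0("tool '", name, "': categorical_map must be injective"))
    }
    if (any(cmap < 0 | cmap > 1)) {
      abort(paste0("tool '", name, "': categorical_map values must lie in [0,1]"))
    }
  }
  tibble::tibble(
    name = name,
    field = as.character(entry$field),
    location = match.arg(entry$location %||% "csq", c("csq", "info")),
    direction = direction,
    # strict comparators mirror the ">" / "<" of the published thresholds
    comparator = if (direction == "higher_is_pathogenic") "strict_greater" else "strict_less",
    reference_threshold = thr,
    scope = match.arg(
      entry$scope %||% "protein",
      c("protein", "conservation", "consequence_agnostic", "disease_specific")
    ),
    excluded_from_multithreshold = isTRUE(entry$excluded_from_multithreshold),
    categorical_map = list(cmap),
    range_min = as.numeric(entry$range_min %||% NA_real_),
    range_max = as.numeric(entry$range_max %||% NA_real_)
  )
}

empty_registry_tbl <- function() {
  tibble::tibble(
    name = character(), field = character(), location = character(),
    direction = character(), comparator = character(),
    reference_threshold = numeric(), scope = character(),
    excluded_from_multithreshold = logical(), categorical_map = list(),
    range_min = numeric(), range_max = numeric()
  )
}

new_tool_registry <- function(tbl) {
  structure(tbl, class = c("tool_registry", class(tibble::as_tibble(tbl))))
}

#' @rdname load_tool_registry
#' @export
default_registry <- function() {
  path <- system.file("extdata", "default_registry.yaml", package = "predbench")
  load_tool_registry(path)
}

#' @export
print.tool_registry <- function(x, ...) {
  cat("<tool_registry> ", nrow(x), " tools (",
      sum(x$excluded_from_multithreshold), " fixed-threshold only)\n", sep = "")
  NextMethod()
}

registry_spec <- function(registry, tool) {
  i <- match(tool, registry$name)
  if (is.na(i)) abort(paste0("tool '", tool, "' not present in registry"))
  dplyr::slice(tibble::as_tibble(registry), i)
}

#' Map a categorical prediction label to a numeric score
#'
#' Categorical predictors (e.g. a clinical-significance classifier emitting
#' "Pathogenic"/"Likely_benign" labels) are mapped to artificial numeric
#' scores so they can enter fixed-threshold evaluation: Benign 0,
#' Likely_benign 0.25, Likely_pathogenic 0.75, Pathogenic 1 in the default
#' registry. Labels outside the map — including "VUS" — become missing
#' (`NA`); such tools never enter multi-threshold analysis.
#'
#' @param label Character vector of categorical labels.
#' @param spec One-row slice of a `tool_registry` whose `categorical_map` is
#'   present.
#' @return Numeric vector; unmapped labels are `NA`.
#' @export
#' @examples
#' reg <- default_registry()
#' map_categorical_score(c("Likely_pathogenic", "VUS"), reg[reg$name == "cVEP", ])
map_categorical_score <- function(label, spec) {
  cmap <- spec$categorical_map[[1]]
  if (is.null(cmap)) abort("spec has no categorical_map")
  out <- unname(cmap[label])
  unknown <- setdiff(unique(label[!is.na(label) & !(label %in% names(cmap))]), NA)
  if (length(unknown) > 0) {
    inform(paste0(
      "unmapped categorical label(s) treated as missing: ",
      paste(unknown, collapse = ", ")
    ))
  }
  out
}
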