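#' Parametric score distribution
#'
#' Small helper describing a class-conditional score distribution for the
#' synthetic cohort generator: `"normal"` (mean, sd), `"beta"` (shape1,
#' shape2), or `"mixture"` of two such components with weights.
#'
#' @param family `"normal"`, `"beta"` or `"mixture"`.
#' @param ... Parameters: `mean`/`sd` for normal, `shape1`/`shape2` for
#'   beta, `components` (list of `score_dist`) and `weights` for mixture.
#' @return A `score_dist` list.
#' @export
score_dist <- function(family = c("normal", "beta", "mixture"), ...) {
  family <- match.arg(family)
  args <- list(...)
  if (family == "mixture") {
    stopifnot(length(args$components) == length(args$weights),
              abs(sum(args$weights) - 1) < 1e-12)
  }
  structure(list(family = family, args = args), class = "score_dist")
}

dist_density <- function(d) {
  switch(d$family,
    normal = function(x) dnorm(x, d$args$mean, d$args$sd),
    beta = function(x) dbeta(x, d$args$shape1, d$args$shape2),
    mixture = function(x) {
      Reduce(`+`, purrr::map2(d$args$components, d$args$weights,
                              function(cmp, w) w * dist_density(cmp)(x)))
    }
  )
}

dist_sample <- function(d, n) {
  switch(d$family,
    normal = rnorm(n, d$args$mean, d$args$sd),
    beta = rbeta(n, d$args$shape1, d$args$shape2),
    mixture = {
      comp <- sample.int(length(d$args$components), n, replace = TRUE,
                         prob = d$args$weights)
      out <- numeric(n)
      for (i in seq_along(d$args$components)) {
        idx <- comp == i
        out[idx] <- dist_sample(d$args$components[[i]], sum(idx))
      }
      out
    }
  )
}

dist_support <- function(d) {
  switch(d$family,
    normal = d$args$mean + c(-8, 8) * d$args$sd,
    beta = c(1e-9, 1 - 1e-9),
    mixture = range(unlist(purrr::map(d$args$components, dist_support)))
  )
}

#' Synthetic predictor profile
#'
#' Describes one simulated pathogenicity predictor: its score direction,
#' class-conditional score distributions, per-class missingness, and the
#' reference threshold it would publish. The default pair —
#' Beta(8, 2) scores for pathogenic variants vs Beta(2, 8) for benign —
#' emulates a well-performing probability-scaled tool with heavy but
#' incomplete class overlap.
#'
#' @param name Tool name.
#' @param direction Score direction.
#' @param pathogenic,benign `score_dist` objects for each class.
#' @param missingness Length-2 numeric `c(pathogenic, benign)` missingness
#'   probabilities in \[0, 1\).
#' @param reference_threshold Published decision threshold for the simulated
#'   tool (default 0.5).
#' @return A `sim_tool_profile` list.
#' @export
sim_tool_profile <- function(name,
                             direction = "higher_is_pathogenic",
                             pathogenic = score_dist("beta", shape1 = 8, shape2 = 2),
                             benign = score_dist("beta", shape1 = 2, shape2 = 8),
                             missingness = c(0, 0),
                             reference_threshold = 0.5) {
  direction <- match.arg(direction,
                         c("higher_is_pathogenic", "lower_is_pathogenic"))
  stopifnot(length(missingness) == 2, all(missingness >= 0),
            any(missingness < 1))
  structure(list(
    name = name, direction = direction, pathogenic = pathogenic,
    benign = benign, missingness = missingness,
    reference_threshold = reference_threshold
  ), class = "sim_tool_profile")
}

#' Registry for simulated tools
#'
#' @param profiles List of `sim_tool_profile` objects.
#' @return A `tool_registry` covering the simulated tools (CSQ-located,
#'   numeric, included in multi-threshold analysis).
#' @export
profiles_registry <- function(profiles) {
  cfg <- setNames(purrr::map(profiles, function(p) {
    list(field = p$name, direction = p$direction,
         reference_threshold = p$reference_threshold, scope = "protein")
  }), purrr::map_chr(profiles, "name"))
  load_tool_registry(cfg)
}

#' Synthetic cohort specification
#'
#' Class sizes, gene pool and seed for [simulate_cohort()]. The default gene
#' pool is deliberately skewed — most pathogenic weight on one gene — to
#' emulate the over-representation of pathogenic missense variants in a
#' single disease gene that real cardiomyopathy cohorts show, while benign
#' variants spread more uniformly across the panel.
#'
#' @param n_pathogenic,n_benign,n_vus Class sizes.
#' @param gene_pool Character vector of gene symbols.
#' @param gene_weights_pathogenic,gene_weights_benign Sampling weights over
#'   `gene_pool` for each class (normalized internally).
#' @param seed Integer seed.
#' @return A `sim_cohort_spec` list.
#' @export
sim_cohort_spec <- function(n_pathogenic = 100, n_benign = 100, n_vus = 0,
                            gene_pool = c("GENEA", "GENEB", "GENEC", "GENED"),
                            gene_weights_pathogenic = c(0.6, 0.2, 0.1, 0.1),
                            gene_weights_benign = rep(1 / length(gene_pool),
                                                      length(gene_pool)),
                            seed = 1) {
  stopifnot(n_pathogenic >= 0, n_benign >= 0, n_vus >= 0,
            length(gene_weights_pathogenic) == length(gene_pool),
            length(gene_weights_benign) == length(gene_pool))
  structure(list(
    n_pathogenic = n_pathogenic, n_benign = n_benign, n_vus = n_vus,
    gene_pool = gene_pool,
    gene_weights_pathogenic = gene_weights_pathogenic / sum(gene_weights_pathogenic),
    gene_weights_benign = gene_weights_benign / sum(gene_weights_benign),
    seed = seed
  ), class = "sim_cohort_spec")
}

#' Simulate a scored, labelled variant cohort
#'
#' Generates a fully synthetic annotated cohort: fictional coordinates on
#' contig `"chrS"` with sequential positions (no resemblance to real loci),
#' random ref/alt bases, genes sampled from the spec's weighted pool,
#' missense consequences, ground-truth labels, and per-tool scores drawn
#' from each profile's class-conditional distribution with the stated
#' missingness. VUS rows draw their latent class with probability
#' `vus_pathogenic_fraction` but keep the label `"vus"`, so the ensemble
#' prioritization path is testable end-to-end. Fully reproducible under the
#' spec's seed; when `dir` is given, writes the annotated VCF, a truth TSV
#' and a provenance JSON embedding the seed.
#'
#' @param spec A [sim_cohort_spec()].
#' @param profiles List of [sim_tool_profile()] objects (at least one).
#' @param dir Optional output directory.
#' @param vus_pathogenic_fraction Probability a VUS row's latent scores are
#'   drawn from the pathogenic distribution (default 0.5).
#' @return List with `records`, `scores` (a `score_matrix`), `truth`
#'   (records plus latent class), `registry`, and (when `dir` is given)
#'   `paths`.
#' @export
simulate_cohort <- function(spec, profiles, dir = NULL,
                            vus_pathogenic_fraction = 0.5) {
  stopifnot(inherits(spec, "sim_cohort_spec"), length(profiles) >= 1)
  n <- spec$n_pathogenic + spec$n_benign + spec$n_vus
  if (n == 0) abort("simulate_cohort: zero total variants")
  registry <- profiles_registry(profiles)

  sim <- withr_seed(spec$seed, {
    label <- c(rep("pathogenic", spec$n_pathogenic),
               rep("benign", spec$n_benign), rep("vus", spec$n_vus))
    latent <- label
    if (spec$n_vus > 0) {
      latent[label == "vus"] <- ifelse(
        runif(spec$n_vus) < vus_pathogenic_fraction, "pathogenic", "benign"
      )
    }
    gene <- character(n)
    for (cls in c("pathogenic", "benign")) {
      idx <- latent == cls
      w <- if (cls == "pathogenic") spec$gene_weights_pathogenic else spec$gene_weights_benign
      gene[idx] <- sample(spec$gene_pool, sum(idx), replace = TRUE, prob = w)
    }
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1))
    records <- tibble::tibble(
      chrom = "chrS", pos = seq_len(n) * 10L, ref = ref, alt = alt,
      gene = gene, consequence = "missense_variant",
      molecular_consequence = "missense_variant",
      label = label, source = "user",
      review_stars = NA_integer_, significance = NA_character_,
      ontology_ids = replicate(n, character(0), simplify = FALSE),
      first_reported = as.Date(NA), allele_frequency = NA_real_
    )
    scores <- records[.key_cols]
    for (p in profiles) {
      s <- numeric(n)
      is_path <- latent == "pathogenic"
      s[is_path] <- dist_sample(p$pathogenic, sum(is_path))
      s[!is_path] <- dist_sample(p$benign, sum(!is_path))
      miss_p <- ifelse(is_path, p$missingness[1], p$missingness[2])
      s[runif(n) < miss_p] <- NA_real_
      scores[[p$name]] <- s
    }
    list(records = records, scores = scores, latent = latent)
  })

  truth <- dplyr::mutate(sim$records[c(.key_cols, "gene", "label")],
                         latent_class = sim$latent)
  out <- list(records = sim$records, scores = new_score_matrix(sim$scores),
              truth = truth, registry = registry)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    vcf_path <- file.path(dir, "cohort.vcf")
    truth_path <- file.path(dir, "truth.tsv")
    prov_path <- file.path(dir, "provenance.json")
    write_annotated_vcf(sim$records, out$scores, registry, vcf_path)
    write_report_tsv(truth, truth_path)
    jsonlite::write_json(list(
      seed = spec$seed,
      n_pathogenic = spec$n_pathogenic, n_benign = spec$n_benign,
      n_vus = spec$n_vus,
      tools = purrr::map(profiles, function(p) list(
        name = p$name, direction = p$direction,
        missingness = p$missingness,
        reference_threshold = p$reference_threshold
      ))
    ), prov_path, auto_unbox = TRUE, digits = NA)
    out$paths <- c(vcf = vcf_path, truth = truth_path, provenance = prov_path)
  }
  out
}

#' Analytic optimal threshold for a simulated tool
#'
#' Returns the score at which the prevalence-weighted class-conditional
#' densities cross — the point a correctly calibrated balanced (beta = 1)
#' threshold search should recover on large samples. Found by scanning the
#' common support for a sign change of
#' `prevalence * f_path(x) - (1 - prevalence) * f_benign(x)` and root-finding
#' within the bracketing interval.
#'
#' @param profile A `sim_tool_profile` with closed-form densities.
#' @param prevalence Pathogenic class prevalence (default 0.5).
#' @return The crossing score.
#' @export
#' @examples
#' p <- sim_tool_profile("t",
#'   pathogenic = score_dist("normal", mean = 2, sd = 1),
#'   benign = score_dist("normal", mean = 0, sd = 1))
#' analytic_optimum(p) # 1
analytic_optimum <- function(profile, prevalence = 0.5) {
  stopifnot(prevalence > 0, prevalence < 1)
  dp <- dist_density(profile$pathogenic)
  db <- dist_density(profile$benign)
  f <- function(x) prevalence * dp(x) - (1 - prevalence) * db(x)
  supp <- range(dist_support(profile$pathogenic),
                dist_support(profile$benign))
  xs <- seq(supp[1], supp[2], length.out = 4096)
  fx <- f(xs)
  sgn <- sign(fx)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flips) == 0) {
    abort("analytic_optimum: densities do not cross in the support")
  }
  # crossing inside the region where both densities carry mass
  mass <- dp(xs) + db(xs)
  flips <- flips[order(-mass[flips])]
  uniroot(f, c(xs[flips[1]], xs[flips[1] + 1]), tol = 1e-10)$root
}
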