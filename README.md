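# predbench

Benchmarking of computational pathogenicity predictors for missense
variants, from annotated VCF files.

## The problem

Clinical genetics pipelines routinely annotate rare missense variants with
scores from dozens of in-silico pathogenicity predictors (SIFT, REVEL,
ClinPred, CADD, conservation scores, disease-specific classifiers, ...).
Which tool should a diagnostic lab trust for a *specific* disease, and at
what decision threshold? Published reference thresholds were tuned on
disease-agnostic data and can be far from optimal for a particular cohort;
benchmarks that ignore missing predictions flatter tools that only score
easy variants; and tools evaluated on variants they were trained on look
better than they are (type-I circularity).

`predbench` is for bioinformaticians and clinical-genetics researchers who
want to run this kind of benchmark themselves: it takes VCFs whose INFO /
VEP-CSQ annotations already carry predictor scores (it never runs any
predictor), builds labelled pathogenic/benign cohorts with auditable filter
chains, ranks tools, recalibrates their thresholds for the disease at hand,
and prioritizes variants of unknown significance (VUS) by top-tool
agreement.

## The statistics at its core

For a tool with confusion counts TP, TN, FP, FN on the variants it scored,
the headline ranking metric is the **coverage-weighted normalized Matthews
correlation coefficient**:

```
MCC           = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))
normalizedMCC = (MCC + 1) / 2                      ∈ [0, 1]
weighted norm MCC = coverage · normalizedMCC
```

where `coverage` is the fraction of presented variants the tool scored —
missingness is a first-class penalty, not an excuse. Tools are also ranked
by **auROC** on rank-transformed scores (computed from scored variants
only; equal to the Mann–Whitney probability that a random pathogenic
variant outscores a random benign one, ties half-counted).

Disease-specific thresholds are recalibrated by maximizing the
**F-beta score**

```
Fβ = (1 + β²) · P · R / (β² · P + R)        β ∈ {0.5, 1, 1.5} by default
```

over a 100-point grid spanning the observed score range; β < 1 favours
precision, β > 1 recall. Stability is quantified with a stratified
bootstrap (class counts preserved exactly; 0.025/0.975 quantiles of the
replicate thresholds), and a published reference threshold falling outside
that interval is flagged as suboptimal for the cohort.

All decision comparators are strict (`score > threshold` pathogenic, or
`<` for lower-is-pathogenic tools such as SIFT and FATHMM); a score exactly
at the threshold is classified benign. A bundled registry of 39 predictors
records each tool's annotation field, direction, scope and published
threshold; a YAML config adds custom tools.

## Worked example

Everything below is synthetic — the package ships a generator with known
class-conditional score distributions, so the whole pipeline runs offline.

```r
library(predbench)

profiles <- list(
  sim_tool_profile("AlphaScore"),                        # Beta(8,2) vs Beta(2,8)
  sim_tool_profile("BetaScore", missingness = c(0.25, 0.25)),
  sim_tool_profile("GammaScore", direction = "lower_is_pathogenic",
                   pathogenic = score_dist("normal", mean = -2, sd = 1),
                   benign     = score_dist("normal", mean =  0, sd = 1),
                   reference_threshold = -1)
)
sim    <- simulate_cohort(sim_cohort_spec(150, 150, 40, seed = 2024), profiles)
cohort <- new_cohort_dataset("demo", sim$records[sim$records$label != "vus", ])

evaluate_fixed(cohort, sim$scores, sim$registry)
#>   tool        rank coverage sensitivity specificity   mcc weighted_norm_mcc
#> 1 AlphaScore     1    1           0.98        0.973 0.953             0.977
#> 2 GammaScore     2    1           0.833       0.82  0.653             0.827
#> 3 BetaScore      3    0.727       0.991       0.991 0.982             0.72
```

`BetaScore` separates classes almost perfectly (MCC 0.98) but skips a
quarter of the variants, so coverage weighting drops it below `GammaScore`.
The multi-threshold view inverts that verdict — auROC is computed on scored
variants only:

```r
evaluate_roc(cohort, sim$scores, sim$registry)
#>   tool       auroc coverage n_scored n_pos n_neg  rank
#> 1 BetaScore  0.999    0.727      218   109   109     1
#> 2 AlphaScore 0.998    1          300   150   150     2
#> 3 GammaScore 0.912    1          300   150   150     3
```

Threshold recalibration with bootstrap intervals (most reference
thresholds sit outside the interval and get flagged):

```r
cal <- calibrate_thresholds(scores_with_labels(cohort, sim$scores),
                            sim$registry, n_boot = 200, seed = 99)
format_calibration_wide(cal)
#>   tool       reference_threshold threshold_beta_0.5      threshold_beta_1        ...
#> 1 AlphaScore                 0.5 0.591 (0.572, 0.621)    0.572 (0.572, 0.621)
#> 2 BetaScore                  0.5 0.527 (0.527, 0.547)    0.527 (0.527, 0.547)
#> 3 GammaScore                -1   -1.605 (-1.609, -1.175) -0.602 (-1.175, -0.602)
```

VUS prioritization by ensemble agreement of the tools:

```r
vus <- sim$scores[sim$records$label == "vus", ]
glance(prioritize_vus(vus, sim$registry,
       setNames(as.list(sim$registry$reference_threshold), sim$registry$name)))
#>   n_variants n_scored n_unanimous_pathogenic frac_majority_pathogenic
#> 1         40       40                     18                    0.475
```

18 of the 40 VUS are called pathogenic by every tool that scored them —
those are the variants to follow up first.

Real data enters through `parse_annotated_vcf()` (VEP-CSQ or INFO-key
scores, multi-allelic decomposition, transcript picking), the ClinVar /
population-database filter chains (`filter_clinvar()`,
`build_gnomad_benign()`, `import_external_list()`), and circularity
controls (`exclude_training_overlap()`, `filter_recent()`). A thin CLI over
`run_pipeline()` lives in `inst/cli/predbench`.

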