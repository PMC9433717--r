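---
title: "Benchmarking variant pathogenicity predictors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking variant pathogenicity predictors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predbench)
```

`predbench` evaluates in-silico missense pathogenicity predictors against
labelled variant cohorts. This vignette is the package's account of the
statistics it implements, the knobs that matter, and the choices made where
the design was genuinely open.

## The evaluation model

A benchmark run starts from a table of variants keyed by
`(chrom, pos, ref, alt)` (multi-allelic sites decomposed, no further allele
normalization — inputs are assumed consistently annotated upstream), each
labelled `pathogenic` or `benign`, and a score matrix with one column per
tool and explicit missing cells. Three complementary views are computed.

**Fixed-threshold view.** Each tool's scores are dichotomized at its
decision threshold with a *strict* comparator: `score > t` is pathogenic
for higher-is-pathogenic tools, `score < t` for the minority whose scale
runs the other way (SIFT, FATHMM, PROVEAN, MTR, CDTS in the bundled
registry). A score exactly at the threshold is therefore benign — this
matches how the published cut-offs are stated and is deliberately
conservative. From TP/TN/FP/FN we derive sensitivity, specificity,
precision and the Matthews correlation coefficient, then rank tools by

$$\text{weighted norm MCC} = \text{coverage} \cdot \frac{\text{MCC}+1}{2},$$

where coverage is the scored fraction of *presented* variants. The
rationale: a predictor that abstains on hard variants should not outrank
one that commits everywhere, because in diagnostics an absent prediction is
a real cost. A perfect tool scoring half the cohort lands at 0.5 — exactly
chance level for a full-coverage tool.

**Multi-threshold view.** Scores are rank-transformed to $[0,1]$ (mean rank
for ties, sign inverted for lower-is-pathogenic tools) and summarized by
the area under the ROC curve, computed over all distinct cutpoints with the
trapezoidal rule on scored variants only. This auROC equals the
Mann–Whitney probability $P(S_\text{path} > S_\text{benign}) + \tfrac12
P(\text{tie})$ and is invariant under monotone transforms, which the test
suite verifies against a brute-force pairwise oracle and against `pROC`.
Tools scoring less than half the cohort are excluded from this ranking
(their curve says little about their deployable behaviour) but keep their
place in the coverage-weighted ranking, where the missingness penalty is
the point. Categorical classifiers mapped onto an artificial numeric scale
(e.g. `Benign = 0 … Pathogenic = 1`) participate only in fixed-threshold
evaluation: a threshold sweep over four artificial values is not a ROC
analysis.

**Threshold recalibration.** For each tool, $F_\beta = (1+\beta^2)PR /
(\beta^2 P + R)$ is evaluated at 100 thresholds uniformly spanning the
observed score range, for $\beta \in \{0.5, 1, 1.5\}$: $\beta<1$ buys
precision (fewer false positives), $\beta>1$ buys recall. Stability comes
from a stratified bootstrap — resampling with replacement within each class
so every replicate keeps the original class counts exactly — and the
0.025/0.975 quantiles of the replicate thresholds. A published reference
threshold outside that closed interval is flagged: the tool's generic
cut-off is probably wrong for this cohort.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| grid size | 100 points over the observed range | fine enough that the grid step, not the sample, limits resolution on cohorts of hundreds of variants |
| $\beta$ values | 0.5, 1, 1.5 | one precision-leaning, one balanced, one recall-leaning threshold per tool |
| bootstrap replicates | 1000 | stable 2.5/97.5 percentiles; smaller values (50–200) are used in tests where only reproducibility is asserted |
| ROC coverage floor | 0.5 | below half coverage an ROC ranking compares tools on disjoint easy subsets |
| minimum review stars | 1 (benchmark), 2 (summary tables) | zero-star assertions carry no review; summaries of curated knowledge warrant a stricter floor |
| MAF cut for benign candidates | strictly $> 0.001$ | variants common in population databases are incompatible with a rare, penetrant disease allele |
| majority cut for VUS agreement | strictly $> 0.5$ of *scoring* tools | the panel's tools have near-complete coverage; a scored-tool denominator degrades gracefully when one abstains (a `panel` denominator is available) |

## Numerical conventions

* **MCC with a zero marginal** (no predicted positives, a single-class
  column, …) is defined as 0, chance level. This keeps the
  coverage-weighted score defined for degenerate tools instead of
  propagating `NaN` into rankings.
* **Undefined ratio metrics** (precision with `TP+FP = 0`) stay `NA` in R
  and are written as `"."` in every TSV report — never silently 0. Ranking
  places undefined metrics below all defined ones, then breaks ties by
  higher coverage, then tool name, so orderings are total and
  deterministic.
* **Grid ties** in $F_\beta$ resolve to the most stringent threshold (the
  fewest pathogenic calls): the largest tied grid point for
  higher-is-pathogenic tools, the smallest for the inverted ones. A
  conservative clinical default that is also reproducible. One visible
  consequence: on perfectly separable data a bootstrap replicate that
  happens to omit the weakest pathogenic score selects a threshold just
  below *its own* smallest pathogenic score, which can exceed the full
  sample's — replicate thresholds are guaranteed to clear every benign
  score, not to stay below the original class gap.
* **Bootstrap replicates reuse the grid of the original sample** rather
  than recomputing one per replicate. The alternative changes each
  replicate's scale with its min/max draw; a fixed grid keeps the replicate
  thresholds commensurable, which is what quantiles of their distribution
  assume.
* **Bootstrap intervals are closed**: a reference threshold exactly at a
  quantile endpoint is *inside*.
* **Rank transform of a single score** maps to 0.5; the degenerate case
  never arises on real cohorts but should not crash a pipeline.
* All randomness flows from one seed; pipeline stages derive sub-seeds
  deterministically, and every manifest records the seed, so identical
  configs and inputs give byte-identical reports.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws per-tool scores from class-conditional
distributions (normal, beta, or two-component mixtures), with per-class
missingness and an optional inverted direction. The default profile —
Beta(8,2) for pathogenic vs Beta(2,8) for benign — mimics a
well-performing probability-scaled predictor with real overlap (closed-form
pair probability ≈ 0.966). Gene symbols are sampled with a deliberately
skewed pathogenic pool (default 60% of weight on one gene) against a
uniform benign pool, mirroring the single-gene over-representation that
disease cohorts show for pathogenic missense variation. Coordinates live on
a fictional contig `chrS` with sequential positions, so nothing resembles a
real locus; VUS rows carry scores under a latent class (default 50:50) so
the agreement analysis is exercised end-to-end.

What it does **not** model: linkage between tools (simulated scores are
conditionally independent given the class, whereas real meta-predictors are
strongly correlated), realistic mutational spectra or allele frequencies,
transcript-level annotation ambiguity, and label noise. Passing tests
therefore demonstrate that the machinery is correct on data with known
truth — not that any particular tool ranking on real cohorts is right.

## Calibration recovery: which target is recoverable?

For two class-conditional densities crossing at $t^\*$ (equal prevalence),
`analytic_optimum()` returns the crossing — the Bayes/accuracy-optimal
cut. It is tempting to expect the $\beta=1$ grid search to recover $t^\*$,
but the $F_1$-optimal threshold is a *different* population quantity: at
the optimum the posterior probability of pathogenicity equals $F^\*/2$
(not $1/2$), so for Normal(0,1) vs Normal(2,1) the $F_1$ optimum sits at
$t = 1 + \tfrac12\operatorname{logit}(F^\*/2) \approx 0.843$, a third of a
standard deviation below the crossing at 1. The two coincide only for
sharply separated, mirror-symmetric profiles (for Beta(8,2) vs Beta(2,8)
the $F_1$ optimum is numerically ≈ 0.4985 vs a crossing of 0.5). The
package's recovery tests therefore target the population $F_\beta$ optimum
computed by direct numeric maximization, and — because the argmax of a
flat objective is noisy (empirical sd ≈ 0.09 at 1000 variants per class) —
assert recovery of the *mean* estimate over five independent cohorts to
within two grid steps, rather than a single-cohort draw.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data:
1000 random confusion matrices and 500 random score/label sets for the
metric oracles; 1000 variants per class (five replicate cohorts) for
calibration recovery; 2000 per class for auROC recovery; 500 per class
plus 100 VUS for the benchmark/prioritization conditions; 200 bootstrap
replicates where intervals are reported. These sizes put Monte-Carlo noise
well below the asserted tolerances while keeping a full run in seconds.

## Known limitations

* Only the fate of decomposed SNV-style records is tested extensively;
  indel normalization (left-alignment) is out of scope by design.
* The circularity controls need per-tool training-set variant keys or
  first-report dates; neither can be conjured when a tool's training data
  were never disclosed — the same gap the underlying benchmark literature
  reports.
* Per-transcript score multiplicity is resolved by the picked transcript
  (then worst-case for per-variant comma lists); other conventions exist
  and would change a small minority of cells.
* Combining top tools into a trained meta-predictor is deliberately not
  implemented; the package reports agreement, not a fitted ensemble.
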