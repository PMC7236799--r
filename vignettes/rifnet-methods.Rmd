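---
title: "Differential-network regulator ranking: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential-network regulator ranking: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rifnet)
```

## The problem

A two-condition expression study (treated S versus control C) is usually
summarised gene by gene: means, fold changes, p-values. That view is blind
to *differential connectivity* — a gene whose mean never moves but whose
correlations with the rest of the transcriptome change between conditions,
which is the expression-level signature of a regulator whose activity is
modulated post-transcriptionally (ligand binding, localisation,
phosphorylation). The regulatory impact factor (RIF) statistics target that
signature directly.

## Model and assumptions

The unit of input is an `ExpressionStudy`: a gene-by-sample matrix of
normalized, log-scale values with a sample-to-condition assignment. The
package assumes the values are already preprocessed — it performs no
background correction, normalization or transformation, and the loader
rejects missing values by default because every downstream score is a sum
over targets and silent NA propagation would corrupt whole columns of the
analysis (an explicit `missing = "drop_genes"` switch drops offending genes
and reports the count).

Three quantities per DE target *j* — its overall mean `x_j`, condition
means `x_jS`, `x_jC`, and `d_j = x_jS − x_jC` — and the condition-wise
correlations `r_rjS`, `r_rjC` of each regulator *r* to each target define
everything else:

* `RIF1_r = mean_j( x_j · d_j · DC_rj² )` with `DC_rj = r_rjS − r_rjC`;
* `RIF2_r = mean_j( (x_jS · r_rjS)² − (x_jC · r_rjC)² )`;
* `PIF_j = x_j · d_j`, and the target product `PIF_j · |DC_rj|` for a focal
  regulator.

Raw RIF values carry the (arbitrary) scale of squared log abundances, so
they are z-scored across the regulator universe before combination; the
combined score is `|z1| + |z2|`. The combined magnitudes of roughly 3–6 that
practitioners report for top hits arise naturally on this standardized
scale. An option (`combine = "mean_abs"`) halves the sum for workflows that
prefer an average of absolute scores; ranking is unaffected since the two
rules are monotone transforms of each other.

Correlation is Pearson on the log scale (Spearman by option), matching the
usual practice for variance-stabilized array intensities. Differential
co-expression is the raw difference of correlations, which is how the
statistic is defined; a Fisher-z variant is available but off by default,
because the raw difference bounded in [−2, 2] is the published definition
and is what the squared term in RIF1 expects.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `de_pvalue_threshold` | 0.001 | probability | strict `p <` threshold for the target set; raw, not FDR-adjusted |
| `de_test` | Welch t | — | the field's screens vary; any `f(s, c) → p` can be plugged in |
| `correlation_method` | pearson | — | log-scale intensities are approximately Gaussian |
| `combine` | sum_abs | — | combined = |z1|+|z2|; `mean_abs` divides by 2 |
| `pif_variant` | overall_mean | — | PIF uses `x_j`; `half_sum` uses `(x_jS + x_jC)/2`, which differs only under unequal group sizes |
| `min_samples_per_condition` | 3 | samples | correlation is undefined below 3 |

The DE test choice deserves a note: a raw threshold on an unnamed test is
common in this literature, and the Welch t on log expression is the simplest
defensible default — it does not assume equal variances and degrades
gracefully when one group is nearly constant. Genes constant in *both*
groups carry no evidence and are assigned p = 1 and flagged rather than
erroring, so a study with dead probes still processes.

## Design choices where the design was open

* **Regulator universe.** All expressed genes are candidate regulators,
  *including* the DE targets themselves. Excluding them would change the
  standardization population and hence every z-score; including them costs
  only the self-links, which are defined as r = 1 on both sides and DC = 0,
  contributing nothing to RIF1 and an `x_jS² − x_jC²` term to RIF2.
* **Zero variance within one condition.** The correlation on that side is
  defined as 0 and the link flagged, keeping the regulator in the
  standardization population; silently dropping it would shift every other
  gene's z-score.
* **Tie-breaking.** Ranking sorts by combined score descending and breaks
  exact ties lexically by gene id, so outputs are byte-reproducible.
* **Enrichment.** The ranked-list enrichment scans prefix cutoffs
  `step, 2·step, …, N/2` (default step `N/100`) and reports the minimum
  hypergeometric upper tail with BH correction *across sets, not cutoffs*.
  This minimum-over-cutoffs p is deliberately anti-conservative — the exact
  minimum-hypergeometric (mHG) correction used by dedicated web tools is not
  reproduced — and the test suite demonstrates the inflation under the null.
  For honest per-set inference use `n_permutations`, which recomputes the
  scan on shuffled rankings and returns an empirical p.
* **Role assignment.** RIF2 and `d_j` flip sign when the condition roles
  are exchanged, so the treated/control mapping is explicit; when labels are
  not the canonical S/C and no mapping is given, the loader falls back to
  lexical order and says so, making a silent misassignment impossible. The
  full condition-swap behaviour (raw scores negate, combined scores and
  ranks invariant) is asserted property-style in the tests.

## What the simulator emulates — and what it does not

`simulate_study()` generates log-scale Gaussian expression: baselines drawn
uniformly from `baseline_mean_range` (default 6–12, the realistic range of
log2 microarray intensities), residual SD `noise_sd` (default 0.5), DE
targets shifted by `de_effect` residual SDs in the treated samples (default
2, a detectable but not extreme effect at n = 20 + 20), and planted
regulators that are pure noise in their own profile — non-DE by
construction — but coupled to a disjoint block of DE targets through a
shared within-condition latent profile with strength `coupling_S` in S and
`coupling_C` in C (defaults 0.8 and 0). Coupling through one latent variable
implies target–target correlations of about `coupling²` inside a block,
which the block-level tests account for. The default scale (2000 genes,
500-gene regulator universe in the self-tests) keeps the full suite in
seconds; `sim_config_full_scale()` provides the 7350-gene, 1279-target,
23 + 23-sample geometry of a full array study for slower integration runs.

Deliberately *not* modelled: probe effects, batch structure, amplification
chemistry, heavy-tailed noise, and correlated null genes. Passing the
recovery tests therefore shows the statistics and their implementation are
correct under the stated generative model — it does not certify performance
on real arrays, where correlated nulls in particular can crowd the top
ranks.

## Numerical choices

Group means and variances are computed by vectorized row operations and the
Welch p by the textbook formula; the tests pin them to `stats::t.test` and
to an independently coded oracle at 1e-12. Correlation matrices come from
`stats::cor` on condition-sliced transposes; RIF sums are matrix products
over the link matrices, pinned to naive term-by-term loops at 1e-10 across
100 random studies. Hypergeometric tails use `stats::phyper`, pinned to
direct pmf summation at 1e-12 for all universe sizes up to 200. All
stochastic steps flow from a single integer seed; identical seed and config
give bit-identical simulations and byte-identical result tables.

## Problem sizes in the self-tests

The packaged tests run 2000-gene studies with 20 + 20 samples and a 500-gene
regulator universe (20 seeds for the recovery property, 10 for null
calibration), 100 random 200-gene studies for the oracle-equivalence sweep,
and one 7350 × 46 round-trip of the IO layer. These sizes were chosen so the
whole suite exercises every property at full strength in well under a
minute of numeric work.

## Known limitations

* RIF scores are relative to their universe: changing the universe changes
  the z-scores, so combined scores are comparable only within one run.
* The DE screen is unadjusted by design; the target set is a working set,
  not an inference set.
* Correlation estimates at the minimum group size (3–5 samples) are very
  noisy; the statistics remain defined but rankings from such studies
  should be treated as exploratory.
* The enrichment minimum-p is a screening statistic, not a calibrated
  p-value, unless the permutation option is used.
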