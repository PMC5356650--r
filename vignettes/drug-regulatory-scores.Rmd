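---
title: "Drug regulatory scores: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug regulatory scores: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drscore)
```

## The problem

Small-molecule inhibitors of a signalling pathway leave a transcriptomic
fingerprint: treating a reference cell line and profiling expression before
and after gives a per-gene record of what "pathway switched off" looks like.
If a tumor's expression pattern resembles that fingerprint, its pathway is
plausibly quiet; if it looks like the mirror image, the pathway is plausibly
hyperactive. `drscore` turns that idea into a quantitative per-sample score
— the drug regulatory score (DRS) — and supplies the downstream statistics
a study built on such scores needs: survival stratification, group
comparisons, drug-sensitivity screens and response classification.

A **positive DRS** means the sample resembles the drug-treated (inhibited)
state; a **negative DRS** means the sample expresses the program the drug
suppresses, i.e. high pathway activity. Every directional test downstream
inherits this convention.

## From treated/control arrays to a signature

`build_profile()` converts one treated/control pair of log2 expression
vectors into a per-gene signed score in five steps:

1. log2 ratio, computed as `treated - control` (inputs are already log2);
2. genes with positive ratios form the up-regulated group, negative the
   down-regulated group — the grouping is carried by the sign throughout;
3. ratios are z-transformed across all genes jointly;
4. two-sided normal tail p-values are `-log10`-transformed;
5. the transformed values are trimmed to `[-20, 20]` and re-signed.

Replicates are averaged on the final trimmed scores
(`average_replicates()`), after restricting to the profiles at the highest
treatment concentration (`select_highest_concentration()`), on the
expectation that expression changes saturate with dose.

Choices worth stating explicitly, since the procedure admits variants:

* **Population standard deviation** in the z-transform. At genome scale the
  population/sample distinction is negligible, but it must be fixed for
  reproducibility; we use the population form throughout, including in the
  frozen test oracles.
* **Two-sided p-values.** Sidedness is not identifiable from the procedure
  itself because the sign is restored from the ratio afterwards; two-sided
  tails keep the score symmetric in up- and down-regulation.
* **Z across all genes jointly**, not within the up/down groups separately.
  Group-wise standardization would decouple the two halves of the signature
  and make scores incomparable across profiles whose group sizes differ.
* Duplicate gene rows (multiple probes per symbol) are collapsed by mean
  before step 1 (`read_matrix()`), and rows with missing values are dropped
  with a logged count.

## The running-sum score

Scoring asks: are the signature's up-weighted genes concentrated near the
top of a sample's expression ranking, and the down-weighted genes near the
bottom? With the sample's cohort-standardized expression sorted descending,
$g_1 \ge g_2 \ge \dots \ge g_n$, and signature weights $d_j \in [0,1]$
aligned to that order, the foreground and background cumulative fractions
are

$$f(i) = \frac{\sum_{j \le i} |g_j d_j|}{\sum_{j \le n} |g_j d_j|}, \qquad
  b(i) = \frac{\sum_{j \le i} |g_j (1-d_j)|}{\sum_{j \le n} |g_j (1-d_j)|},$$

and the pre-DRS is the dominant excursion of $f - b$:

$$\mathrm{pDRS}^{+} = \max\!\big[f(i_{\max}) - b(i_{\max}),\, 0\big], \qquad
  \mathrm{pDRS}^{-} = \min\!\big[f(i_{\min}) - b(i_{\min}),\, 0\big],$$

returning $\mathrm{pDRS}^{+}$ when it strictly exceeds
$|\mathrm{pDRS}^{-}|$ and $\mathrm{pDRS}^{-}$ otherwise. Both excursions
live in $[-1, 1]$ by construction, and positive rescaling of $g$ cancels in
the ratios.

The signed trimmed profile scores are mapped to weights by
`d_up = max(score, 0)/20`, `d_dn = max(-score, 0)/20` — a linear map that
preserves relative magnitudes and saturates exactly at the trim bound. The
statistic is computed twice per sample, once with the up-group weights and
once with the down-group weights.

### Permutation normalization

Raw excursions depend on signature size and weight distribution, so each
pre-DRS is normalized against a null built by permuting the genes of the
sample profile (`n_perm = 1000` by default; tests use smaller values). The
observed value is divided by the **mean absolute null value**; the final
score is `DRS = DRS_up - DRS_dn`.

Numerical and design notes:

* Permuting the expression vector and re-sorting is equivalent to permuting
  the weight vector against the fixed sorted expression, which is what the
  implementation does — the running-sum denominators are recomputed for
  every permutation because $\sum_j |g_j d_{\pi(j)}|$ is
  permutation-dependent.
* The divisor aggregates the null sign-agnostically (mean of $|$null$|$).
  A sign-matched alternative (positive observed values divided by the mean
  positive null) is available via `null_mode = "sign_matched"`; with the
  roughly symmetric nulls we observe, the two differ by a near-constant
  factor and do not change any downstream ordering-based analysis.
* Expression is standardized **gene-wise across the cohort** before
  scoring: "highly expressed" is only meaningful relative to other samples,
  and raw within-sample values would conflate gene-specific baselines.
* Ties in expression are broken by gene identifier (stable sort) so results
  do not depend on input order.
* Per-sample permutation seeds are derived from the root seed plus a hash
  of the sample's expression values. This makes cohort scoring
  deterministic, invariant to column order, and gives identical samples
  identical scores — at the cost that two *different* cohorts containing
  the same sample values reuse the same permutation stream, which is
  intended.
* A sample whose intersection with the signature universe falls below
  `min_overlap` (default 50 genes), or whose foreground/background sums
  degenerate (e.g. an all-zero profile), is flagged in the output table
  rather than dropped.

One property that might be assumed of such a statistic is monotone
concordance under single swaps — moving one up-weighted gene higher in the
ranking never decreasing $\mathrm{pDRS}^{+}$. It is **false** for the
weighted, normalized form: the swap changes the foreground total and
thereby renormalizes every other gene's contribution, and counterexamples
are easy to generate. The property does hold when a single gene carries all
the weight, and the test suite asserts exactly that version.

## The synthetic study generator

`sim_config()` fixes the conditions of the simulated study; all tests and
the acceptance script run at these conditions (scaled cohort counts are
noted below).

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | genes in the universe |
| `n_signature_up` / `n_signature_dn` | 100 / 100 | pathway program sizes |
| `n_samples` | 200 | cohort size |
| `activity_sd` | 1 | sd of the latent per-sample pathway activity |
| `effect_size` | 1 | log2 expression shift per unit activity |
| `noise_sd` | 1 | sd of expression noise (log2 units) |
| `hazard_coef` | 0.8 | log-hazard per unit activity |
| `baseline_hazard` | 0.1 | baseline exponential event rate |
| `censor_rate` | 0.2 | independent censoring fraction |
| `ic50_coef` | 1 | log-IC50 shift per unit activity (planted drug) |
| `burden_coef` | 1.5 | log-odds of high burden per unit activity |

The generator encodes one latent variable per sample and three readouts.
The *drug experiment* (`simulate_drug_experiment()`) suppresses the
pathway-up program and induces the pathway-down program in treated
replicates. The *cohort* (`simulate_cohort()`) moves the same programs with
per-sample activity, in the direction opposite to the inhibitor — so DRS is
expected to **anti-correlate** with activity. The *outcomes*
(`simulate_outcomes()`) give exponential survival with a log-linear hazard
in activity (the simplest generator consistent with a proportional-hazards
analysis), a logistic burden label, and an IC50 table with one planted
activity-linked drug among pure-noise drugs. Censoring is independent:
a censored sample is observed at a uniform fraction of its event time.

What the generator deliberately does **not** emulate: probe-level array
artifacts, batch effects, correlated gene-gene noise, mutation/copy-number
co-occurrence structure, or non-proportional hazards. Passing tests
therefore demonstrate that the pipeline recovers planted signal under clean
conditions, not that it is robust to every failure mode of real cohorts. An
optional second latent variable (`confounder_sd > 0`) adds a correlated
nuisance program and a matching clinical covariate for median-split
stratified analyses.

At the default conditions the scoring statistic saturates quickly: the
DRS–activity correlation is already near its ceiling at `effect_size`
0.5, so the effect-size monotonicity test asserts nondecreasing magnitude
with a small sampling tolerance rather than strict growth.

## Downstream stages

* `compare_groups()` — Wilcoxon rank-sum for two groups (exact for small
  tie-free samples, normal approximation with continuity correction
  otherwise), one-way ANOVA for three or more.
* `phospho_total_ratio()` — protein-array tables arrive log10-transformed,
  so the phospho/total "ratio" is the difference of log10 columns; a raw
  mode exists behind `log_input = FALSE`.
* `stratify_at_zero()` — groups are defined by strict inequalities, so
  samples at exactly 0 belong to neither and are excluded with a logged
  count. `split_at_median()` sends ties at the median to the low group,
  also logged.
* `km_logrank()` / `cox_univariate()` / `cox_batch()` — Kaplan-Meier
  estimators with the log-rank test and univariate Cox fits (Wald p-values,
  Benjamini-Hochberg adjustment across batched fits), via the survival
  package.
* `drug_screen()` — per-drug Spearman (or Pearson) correlation of DRS with
  IC50, BH adjustment across drugs, selection at adjusted p < 0.05 split
  into positive and negative lists; under-populated drugs are reported as
  skipped.
* `classify_rcb()` — random forest (ecosystem-default hyperparameters,
  recorded seed) with stratified 10-fold cross-validation; out-of-fold
  class probabilities are pooled into one ROC/AUC. The AUC is the
  rank-based Mann-Whitney form, cross-checked in the tests against an
  independent ROC library. A single DRS feature is the default use;
  a feature matrix is accepted.

## Reproducibility and problem sizes

Every randomized operation consumes a seed derived from one root seed, so a
`run_config()` fully determines all pipeline outputs; `run_pipeline()`
writes a manifest of md5 hashes and rerunning a configuration reproduces it
byte for byte.

The test suite exercises the pipeline at reduced sizes chosen to keep a
full run in a few minutes on one core while leaving the planted effects
detectable: null calibration uses 50 cohorts of 100 samples x 2000 genes
with 200 permutations; signal and survival recovery use 1000-gene cohorts
of 100-150 samples with 50-100 permutations; the brute-force oracle runs
200 random instances of at most 12 genes. The acceptance script runs the
full default study (200 samples, 2000 genes, 200 permutations) once.

## Known limitations

* The permutation null treats genes as exchangeable; correlated gene
  blocks in real data make the null anti-conservative, and per-cohort
  exceedance rates are visibly overdispersed even in simulation because
  all samples share one signature.
* DRS magnitude saturates for strong signals, compressing dynamic range at
  the top; rank-based downstream analyses are unaffected, but linear
  correlations against a strong latent signal plateau.
* Gene identifiers are matched case-sensitively after whitespace
  stripping; no symbol/probe translation is attempted.
* The survival stage fits univariate models only; multivariable adjustment
  is out of scope.
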