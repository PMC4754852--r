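---
title: "Methods: differential DNA methylation and hormone-receptor status across two array platforms"
author: "methscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential DNA methylation and hormone-receptor status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscan)
```

## The scientific question

Breast tumors split clinically into hormone-receptor-positive disease
(estrogen and/or progesterone receptor positive, ER/PR-positive) and the
more aggressive ER/PR-negative disease. Promoter CpG methylation — a
fraction between 0 (unmethylated) and 1 (fully methylated), the "beta
value" reported by methylation arrays — differs systematically between
the two groups, with coordinate promoter hypermethylation repeatedly
reported in receptor-positive tumors. `methscan` implements a complete
analysis of that question for the two-platform study design: a compact
training panel (~1505 CpG probes over ~807 gene promoters, ~75 tumors)
and a larger validation platform (tens of thousands of probes, ~306
tumors), with expression data on the validation cohort.

The package covers five analysis stages, each usable on its own:

1. **Aggregation** (`aggregate_to_genes`): probe beta values annotated to
   the same gene are averaged per sample; a gene-sample cell is missing
   only if every contributing probe is missing.
2. **Association scan** (`scan_all_genes`, `bootstrap_direction_ci`): one
   logistic regression per gene of ER/PR-positive status on the gene's
   mean beta, adjusting for age (continuous) and race/ethnicity (dummy
   variables against a non-Hispanic White referent). Coefficient signs
   are dichotomized into positive vs inverse associations; the fraction
   positive and the positive:inverse ratio are summarized with
   bias-corrected percentile bootstrap intervals over patient resamples.
3. **SAM** (`run_sam`): a from-scratch two-class significance analysis of
   microarrays — moderated d statistic with fudge factor s0, permutation
   expected order statistics, asymmetric delta cutoffs, FDR as the median
   permuted exceedance count over the number of calls, preceded by
   K-nearest-neighbour imputation.
4. **Cross-platform validation** (`validate_predictors`): predictor genes
   found on the training platform are matched by gene symbol to the
   validation platform, re-tested there (Welch t-test on gene mean beta,
   SAM d of the highest-|d| probe), and tallied for direction concordance
   and t-test confirmation.
5. **Expression correlation** (`correlate_methylation_expression`):
   per-gene Pearson correlation between gene methylation and expression,
   overall and within each receptor stratum, with significance counts
   split by sign.

A seeded synthetic-data generator emulating both platform designs makes
every stage testable end to end without any external download.

## Models and statistics

### Per-gene logistic scan

For gene $g$ with mean beta $m_{gi}$ in sample $i$,

$$\operatorname{logit} P(Y_i = 1) = \beta_0 + \beta_1 m_{gi} +
  \gamma^\top z_i,$$

where $Y_i = 1$ for ER/PR-positive tumors and $z_i$ holds age in years
and race/ethnicity dummies. Fitting is maximum likelihood by iteratively
reweighted least squares (compiled, since the bootstrap refits hundreds
of thousands of models); two-sided Wald p-values are reported for
$\beta_1$. Results are verified against `stats::glm` in the test suite.

*Degenerate fits.* A gene is `excluded` — not counted in direction
summaries — when the predictor is constant, a class has fewer than two
usable samples, or the MLE does not exist (complete or quasi-complete
separation, detected as IRLS divergence). Exclusion deliberately does
**not** trigger on coefficient magnitude: beta values often occupy a
narrow sub-interval of [0,1], so legitimate log-odds coefficients per
unit beta can run into the hundreds with perfectly informative Wald
tests.

*Direction summary.* At threshold $p^\*$, converged genes with
$p \le p^\*$ are counted by coefficient sign; `prop_positive`
$= n_+/(n_+ + n_-)$ and the ratio $n_+/n_-$. Values are held at full
precision and rounded only for presentation (two decimals for the
proportion, one for the ratio, whole percent). Thresholds 1.0, 0.20,
0.05 reproduce the conventional three-row summary table; no multiplicity
adjustment is applied in this module (FDR control lives in the SAM
stage).

*Bootstrap.* Patients are resampled with replacement, unstratified; each
replicate reruns the full scan and summary. Replicate $b$ draws its
resample from seed $+ b$, so individual replicates can be reproduced in
isolation. The interval is the bias-corrected (BC) percentile interval
without acceleration:
$z_0 = \Phi^{-1}(\#\{\theta^*_b < \hat\theta\}/B)$ (ties counted half),
bounds at the $\Phi(2 z_0 \pm 1.96)$ percentiles of the bootstrap
distribution. Replicates where a statistic is undefined (no inverse
associations for the ratio) are excluded from that statistic's interval
and counted. Both the raw ratio and the bootstrap-median ratio are
retained, since rounded published ratios can reflect either.

### SAM

For feature $i$ with group means $\bar x_{1i}$ (ER/PR-positive) and
$\bar x_{2i}$,

$$d_i = \frac{\bar x_{1i} - \bar x_{2i}}{s_i + s_0}, \qquad
  s_i = \sqrt{\left(\tfrac1{n_1}+\tfrac1{n_2}\right)
  \frac{SS_{1i} + SS_{2i}}{n_1+n_2-2}},$$

so $d_i > 0$ means higher methylation in receptor-positive disease. The
fudge factor $s_0$ damps inflated $d$ at low-scatter features; it is
selected from $\{0\} \cup$ {5th..95th percentiles of $s_i$} by minimizing
the coefficient of variation of the median absolute deviation of $d$
across scatter-quantile bins (100 bins; on small matrices the bin count
drops to $\max(5, n/5)$ so each bin keeps several members — a numerical
guard, since single-member bins make every MAD zero and the criterion
undefined). Ties go to the smallest candidate, so homoscedastic data
yield $s_0 = 0$.

Significance is judged against permutation expected order statistics:
balanced label relabelings drawn uniformly (enumerated exhaustively when
$\binom{n}{n_1}$ does not exceed the permutation budget), $d$ recomputed
and sorted under each, and averaged rank by rank. At threshold
$\Delta$, the upper cut is the smallest observed $d$ exceeding its
expected value by more than $\Delta$, the lower cut the largest falling
more than $\Delta$ below — asymmetric, side-specific cuts. The FDR
estimate is the median (configurable quantile) across permutations of
the count of permuted $d$ beyond the cuts, divided by the number called;
no correction for the proportion of true nulls is applied. Missing
values are imputed first with the K-nearest-neighbour rule (k = 10 by
default): neighbours ranked by Euclidean distance over shared observed
samples scaled by the number of shared samples, skipping neighbours
unobserved at the target cell. Imputation is used only for the SAM
stage, never for the logistic scan, which simply drops missing samples
per gene.

Feature granularity follows the platform: the training run operates on
gene-mean beta; the validation run on probes, with a per-gene rollup
reporting the probe with the highest |d|.

### Validation and concordance

Predictors are matched across platforms by exact, whitespace-trimmed,
case-sensitive gene symbol — no synonym rescue, mirroring how
cross-platform matching is typically done at symbol level. Per
predictor: gene mean beta on the validation cohort is compared between
receptor groups by Welch's two-sided t-test (chosen over the pooled
t-test for robustness to the markedly unequal group sizes), and the
validation d is the highest-|d| probe's SAM score. Status: `absent`
(no probe), `not_associated` (d = 0), otherwise the sign of the group
mean difference, downgraded to `non_significant` when the reported probe
falls outside SAM's called set at the configured delta — "significant in
validation" is thus membership in the delta cut, which is the reading
most consistent with published tables where a mid-sized d can be flagged
non-significant while a smaller one on another dataset is not.
Concordance requires an undowngraded status equal to the training
direction; confirmation additionally requires the t-test p at or below
alpha (default 0.05, configurable — the confirmation threshold is not
uniquely determined by published figures).

### Expression correlation

Pearson's rho between gene mean beta and expression, pairwise-complete,
with two-sided p from the t transform
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, $df = n - 2$; undefined (flagged NA)
when fewer than 3 pairs or either variable is constant. Correlations are
computed overall and within each receptor stratum; gene counts
significant at alpha are split by sign. Expression enters on whatever
(typically log) scale it is supplied; Pearson's rho is invariant to
positive affine rescaling, so the choice affects only interpretation of
slopes, not the reported correlations. `subsample_correlations`
re-estimates per-gene rho on repeated random subsets (say 75 of 306
samples) to emulate small-cohort replication.

## The synthetic-data generator

The generator plants effects on the logit scale of beta so group shifts
respect [0,1]:

$$\beta_{\text{probe},i} = \operatorname{logit}^{-1}\!\big(
 \operatorname{logit}(b_g) + o_p + e_g\,[i \in \text{pos}] +
 \varepsilon_{pi}\big),$$

with gene baseline $b_g \sim \text{Beta}(2,2)$ (a symmetric choice on
(0,1); the real platforms' baseline distributions are not published),
fixed probe offset $o_p \sim N(0, 0.5)$, planted group effect $e_g$
(default +1 logit for 5 % of genes, −1 for 1 %, matching the roughly
5:1 hyper:hypo structure of the published association table), and
per-cell noise $\varepsilon \sim N(0, 0.5)$. Values are clamped to
$[10^{-6}, 1-10^{-6}]$ and a small fraction of cells (2 % training
platform, 1 % validation) is blanked at random, never a whole probe row.
Probe counts per gene follow the training panel's published design
weights (28.6 / 57.3 / 14.1 % for 1 / 2 / 3+ probes, "3+" uniform on
3..5). Expression is linear in gene mean beta,
$8 + \text{slope}_g \cdot \bar\beta_{gi} + N(0,1)$, with slope −5 for
85 % of genes (inverse coupling, the typical repressive promoter effect)
and +5 for the rest. Cohorts fix the ER/PR-positive count exactly at
`round(n * prevalence)` (53/75 and 239/306 at the two presets); among
positives the ER/PR combination is drawn as both/ER-only/PR-only with
probabilities 0.65/0.20/0.15 (receptor-combination frequencies are not
published for these cohorts; clinically most ER-positive tumors are also
PR-positive). Ages are uniform on 30–80; race/ethnicity follows each
cohort's published composition.

What the generator does **not** emulate: batch effects, tumor purity,
copy-number interference, allele-specific methylation, beta-value
heteroscedasticity near the range ends, and probe-to-probe correlation
beyond the shared gene baseline. Passing tests on this generator
therefore demonstrate correctness of the statistical machinery under a
clean generative model, not robustness to those real-data artifacts.

Every stochastic function takes an explicit seed and restores the
caller's RNG state; sub-stage seeds derive deterministically from the
master seed by stage name, so adding a stage never shifts another
stage's stream and identical configurations give byte-identical outputs.

## Numerical choices and edge cases

- IRLS: coefficient-change convergence at relative 1e-10, at most 100
  iterations; linear predictors clamped at ±30 and a converged solution
  sitting on that clamp is treated as a diverging (separated) fit.
- Two-group tests with both groups constant and equal return t = 0 and
  p = 1 rather than erroring; the Wilcoxon test uses the normal
  approximation with tie correction; chi-square without continuity
  correction.
- Bootstrap intervals use type-7 quantiles; a degenerate bootstrap
  distribution equal to the observed value collapses the interval to a
  point, and zero estimated bias reduces BC to the plain percentile
  interval.
- s0 tie-breaking: candidates within 1e-9 relative of the minimum CV are
  tied and the smallest wins; an everywhere-undefined criterion returns 0.
- Gene symbols are trimmed and matched case-sensitively everywhere.
- Delimited text is written at 6 significant digits; write-then-read is
  the identity at that precision.

## Study sizes used by the shipped tests and acceptance script

The test suite exercises the machinery at the sizes the design questions
demand rather than at full published scale: panel-scale scans (807 genes
× 75 samples), a 2000-gene × 306-sample validation platform, 200-seed ×
200-replicate bootstrap calibration on 200-gene null cohorts, 25-seed
recovery and concordance studies, and exhaustive permutation oracles on
2-vs-2 and 3-vs-3 toys. The acceptance script runs one full simulated
two-platform study (1000 bootstrap replicates, 1000 permutations) and
reports the quantities it computes.

## Known limitations

- **BC bootstrap of a sign fraction under a global null.** When no gene
  carries a real effect, every coefficient sign is borderline, and
  patient resampling shrinks the positive fraction toward 0.5 whatever
  the observed value. The BC step reads that conditional shrinkage as
  estimator bias and shifts the interval *away* from 0.5, so the
  nominal-95 % interval covers the true 0.5 in only ~70 % of null
  simulations (the plain percentile interval overcovers at ~100 % under
  the same conditions). With real effects present — the regime the
  procedure is actually used in — most signs are stable under resampling
  and the pathology is mild. The package implements the documented BC
  formula as is; users wanting conservative null behavior can read the
  percentile interval off the bootstrap medians also reported.
- **Separated genes cannot reach Wald significance.** The strongest
  planted effects occasionally separate the two groups perfectly at
  n = 75 (particularly genes averaging 3–5 probes); their logistic MLE
  does not exist and they are excluded from direction counts. SAM has no
  such failure mode and recovers them, which is one practical argument
  for running both analyses, and plausibly why a published scan of 807
  genes can report 806 coefficients.
- The SAM FDR is the classic permutation estimate without a true-null
  proportion correction and can exceed 1 in pathological cases; it is
  reported as computed.
- KNN imputation builds a full feature-distance matrix; fine up to a few
  thousand features, quadratic beyond.
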