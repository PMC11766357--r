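---
title: "Methods: plasma-EV small-RNA biomarker discovery"
author: "evsmallrna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma-EV small-RNA biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evsmallrna)
```

# The problem

Eosinophilic esophagitis (EoE) is diagnosed and monitored by endoscopy with
biopsies; a blood-based readout would spare patients repeated invasive
procedures. Small RNAs carried by plasma extracellular vesicles (EVs) are a
candidate liquid-biopsy substrate: their cargo shifts with esophageal
inflammation and can be profiled by small-RNA sequencing and validated by
RT-qPCR. This package implements the full downstream analysis for such a
study — from a feature-by-sample count matrix to differential-expression
candidates, per-marker diagnostic profiles, cross-validated two-marker
panels, a stability-selected qPCR normalizer, and relative-quantification
statistics — together with a seeded synthetic-data generator that emulates
the cohort structure the analysis assumes, so every stage is testable
against a known ground truth.

The cohort design mirrored throughout is: unpaired disease-free controls;
subjects sampled twice (active disease at baseline, again after
anti-inflammatory treatment), giving a paired contrast; and a few low-depth
technical negative controls used for quality control.

# Synthetic cohort generator

Counts for feature $i$ in sample $j$ are negative binomial with mean

$$\mu_{ij} = m_i \cdot 2^{\beta_{i,c(j)}} \cdot 2^{u_{s(j)}} \cdot s_j$$

and variance $\mu + \alpha\mu^2$, where $m_i$ is the log-normal baseline
abundance, $\beta_{i,c}$ the planted condition effect (log2), $u_s$ a
subject effect shared by a subject's two samples, and $s_j$ the sample size
factor. Defaults are the study design: 16 controls, 26 subject pairs, 3
negative controls, 800 features, 4% of features planted per contrast
(mirroring the ~32 of ~757 detected species reported regulated in such
data), planted |log2 FC| = 2 (mid-range of reported candidate fold changes,
which span about 1.3- to 13-fold), dispersion $\alpha = 0.2$ (typical for
small-RNA counts at these depths; the true per-cohort value is unknown and
deliberately a free parameter), baseline log2 means $\mathcal{N}(5, 2^2)$,
size-factor log2 SD 0.4, subject-effect SD 0.5 log2 units, and negative
controls drawn from a flat (structureless) NB at 2% of the median real
library size.

Design choices worth flagging:

* **Planted effects are fixed-magnitude, alternating sign.** Up/down
  assignment is deterministic given the seed, so recovery tests can condition
  on direction.
* **The designated reference feature** emulates a let-7a-like housekeeper:
  baseline abundance three SD above the mean (the most abundant miRNAs in
  plasma EV data are typically members of a few dominant families) with a
  tenfold-reduced dispersion, and zero fold change in both contrasts.
* **Subject effects are common-mode**: one multiplier applies to all
  features of a sample pair. This induces the within-subject correlation the
  paired test exploits, and it also means a panel combining an up- and a
  down-regulated marker can cancel subject-level noise — a structural reason
  two-marker panels outperform single markers here.
* **Ct tables** are derived from the same ground truth: each replicate is
  $Ct = (35 - \log_2(m_i + 1)) - \log_2(\text{relative abundance}) +
  \mathcal{N}(0, \sigma_{ct})$, in triplicate by default.

What the generator does *not* emulate: zero inflation, batch effects,
adapter/UMI artifacts, compositional coupling between features, and
heavy-tailed outlier samples. Passing recovery tests therefore demonstrates
internal correctness of the pipeline under its stated model, not performance
on any real cohort.

# Quality control

The study-style QC excluded samples that clustered with technical negative
controls in a Pearson-correlation dendrogram and PCA. Visual exclusion is
not reproducible, so the package defines a deterministic surrogate: on
log2-CPM (pseudocount 1), a real sample is excluded iff its maximum Pearson
correlation to any negative control exceeds its maximum correlation to any
other real sample, or its library size falls below 10% of the median real
library. Negative controls are always excluded from analysis. PCA
coordinates (centered, unscaled, via SVD) are reported for plotting only and
never enter the rule, which keeps the exclusion criterion single-sourced.
On well-separated synthetic data this rule attains sensitivity and
specificity 1 across seeds; the thresholds are conventions, not fitted
values.

# Differential expression

The screen is deliberately a *simplified* NB analysis, not a DESeq2
re-implementation: downstream selection consumes only baseMean, fold-change
sign/magnitude and p, and all of its operating characteristics are validated
by simulation.

* **Normalization** is median-of-ratios over features expressed in every
  sample, rescaled to geometric mean 1 (verified against DESeq2's
  implementation in the test suite); library-size ratios are the fallback
  when no feature is shared.
* **Dispersion** is a within-group method-of-moments estimate
  $\hat\alpha = \max(0, (\bar v - \bar m)/\bar m^2)$ shrunk toward the
  across-feature mean with weight $w = 4/(4+n)$ — an intentionally ad-hoc
  weight; it stabilizes small-sample estimates without a trend fit.
* **Unpaired contrast**: Wald test on
  $\widehat{\mathrm{lfc}} = \log_2\!\big((\bar x_1 + pc)/(\bar x_0 + pc)\big)$
  with a delta-method SE evaluated at the same pseudocount-regularized means
  ($pc = 0.5$) that enter the ratio. Evaluating the variance at the raw
  plug-in means makes the test mildly anticonservative; the regularized
  form is calibrated at the study design sizes — the acceptance suite
  checks the empirical type-I error over 5000 null feature-tests against
  the 99% binomial band around the nominal 0.05. At smaller cohorts
  (e.g. 18 vs 12) a residual inflation of a fraction of a percent remains —
  a known limitation of plug-in Wald tests.
* **Paired contrast**: per-subject log-ratios tested with the exact
  Wilcoxon signed-rank (dynamic programming over doubled midranks, exact to
  25 pairs even with ties, continuity-corrected normal approximation
  beyond). The study does not state how pairing entered its model; the
  log-ratio + exact-test route is assumption-light and fully testable by
  enumeration.
* **No multiple-testing correction** enters selection — candidates are
  filtered on raw p < 0.05, matching the published criteria; a
  Benjamini–Hochberg column is emitted for information only.

Signed fold changes follow the reporting convention $+2^{\mathrm{lfc}}$ for
up, $-2^{-\mathrm{lfc}}$ for down, so $|FC| \ge 1$ always.

# Diagnostics and candidate selection

Per-feature scores are $\log_2(\text{normalized count} + 0.5)$; AUC is the
midrank Mann–Whitney statistic and is reported oriented (≥ 0.5, with the
direction recorded). The operating point is Youden's J over midpoints
between adjacent distinct scores — the publication's threshold rule is
unstated, so the confusion-matrix consistency of its printed tables (SN/SP
plus group sizes reproducing PPV/NPV exactly) is the verifiable surface,
and the package provides `reconstruct_confusion()` for exactly that check.
Candidates require AUC > 0.75, baseMean > 10 and p < 0.05, all strict.

# Pairwise panels

Every unordered candidate pair is scored by leave-one-out cross-validation
of a linear soft-margin SVM (C = 1; the publication states no
hyperparameters). Standardization is refit within each training fold —
the held-out sample never influences its own score. The solver is a
deterministic dual coordinate descent (zero start, tolerance $10^{-8}$,
regularized bias via an augmented constant feature), validated against a
brute-force active-set QP oracle.

The pooled score for the held-out sample is the fold's **linear component**
$w \cdot \tilde x$ *without the intercept*. With the intercept included,
pooled LOOCV scores of pure-noise pairs are systematically pessimistic
(mean AUC well below 0.5, a known artifact of pooled leave-one-out scores
regardless of solver): each training fold is short one sample of the
held-out class, and the intercept absorbs exactly that imbalance, shifting
every held-out score against its own class. The intercept is constant
within a fold, so dropping it leaves within-fold ranking untouched; the
null-pair mean AUC then sits within 0.5 ± 0.06 (checked over 100 seeds by
the acceptance suite) and informative-pair power is unchanged.
One cross-validated ROC is computed from the pooled scores (per-fold AUC is
undefined with single-sample folds); 95% CIs are seeded stratified
bootstraps (2000 resamples). SVM-RFE ranks features by iteratively
eliminating the smallest |weight| (ties: lexicographically smaller id
first). Whether the published pair AUCs came from exhaustive pairing or
RFE-guided search is ambiguous, so both are provided.

# Reference selection

Candidates for the qPCR normalizer are features with signed fold change
strictly inside ±1.2 — interpreted as |lfc| < log2(1.2), the only reading
consistent with a signed-FC scale that has no values in (−1, 1). In-window
features are ranked by highest mean, lowest SD, and lowest CV, combined as
an unweighted mean rank (the publication gives no weighting). The
statistics are computed on $\log_2(\text{normalized} + 1)$: on the raw
count scale SD grows mechanically with the mean, so no abundant housekeeper
could ever rank well on it and the published account — a single abundant
feature ranking best on all three criteria — would be unsatisfiable;
log-scale stability is also what geNorm/NormFinder-class tools use. Under
this rule the planted housekeeper is recovered in ≥ 95/100 seeds.

# Relative quantification

Triplicates are aggregated by dropping undetermined wells, then replicates
more than 0.5 cycles from the replicate median (no replicate-handling rule
is published; 0.5 cycles is a common bench convention). ΔCt is target minus
reference within a sample, relative expression $2^{-\Delta Ct}$, and RQ is
$2^{-\Delta\Delta Ct}$ against the calibrator-group mean ΔCt. Group
comparisons use the in-house exact Mann–Whitney U (unpaired) and exact
Wilcoxon signed-rank (paired) on $\log_2$ relative expression; rank tests
are invariant to the ΔCt-vs-RQ scale question, which the publication leaves
open. Exactness conventions: midranks for ties, zeros dropped, two-sided
p = 2·min(tails) capped at 1, exact distributions by subset-sum dynamic
programming over doubled midranks (combined n ≤ 30 unpaired, n ≤ 25
paired), continuity- and tie-corrected normal approximations beyond.

# Orchestration and determinism

`run_pipeline()` chains simulate → QC → both DE contrasts → diagnostics →
pair search → reference selection → simulated qPCR validation, writing every
stage table, a `summary.json`, and a log of seeds and parameters. A single
root seed spawns per-stage sub-seeds, so stages are individually
reproducible and a rerun with the same configuration is byte-identical
(logs deliberately contain no timestamps). A stage failure writes a
`FAILED` marker and preserves earlier outputs.

# Problem sizes used by the tests

The test and acceptance suites run at deliberately desk-scale sizes chosen
to keep Monte-Carlo error well below the tested margins: 5000 null features
for type-I calibration; 1000 planted features (10 seeds × 2000-feature
matrices at 18 vs 12, baseline mean 100, $\alpha = 0.1$) for fold-change
recovery; 600 planted features per effect size for the power curve; 100
seeds for each recovery rate (strongest pair, reference selection,
null-pair AUC). The pair-recovery experiment plants its strong pair as the
most abundant up- and most abundant down-regulated features at low
dispersion (α = 0.05), the regime in which a two-marker panel is clearly
separated from its single markers; at saturating effect sizes the argmax
over near-tied pairs is not a stable target for any method.

# Known limitations

* Cohort-level published values (fold changes, p-values, AUCs of the real
  data) are not reproducible without the deposited sequencing data; the
  package validates procedure, calibration and internal consistency instead.
* The Wald screen keeps slight small-sample type-I inflation below ~30
  samples per contrast; the paired exact test is conversely a little
  conservative at small pair counts due to discreteness.
* The LOOCV intercept-free scoring makes pooled null AUCs nearly unbiased
  but is still a pooled-LOOCV heuristic; leave-pair-out CV would be the
  rigorous alternative at higher cost.
* The exclusion rule is a surrogate for a visual QC decision; its
  thresholds (correlation dominance, 10% library floor) are conventions.
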