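---
title: "Models and methods behind stresswaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stresswaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresswaves)
```

stresswaves analyses acute-stress time courses across molecular layers:
bulk RNA-seq split into nascent (unspliced) and processed (spliced)
transcript signal, phosphoproteomic intensity matrices, single-nucleus
pseudo-bulks, transcription-factor regulons, and temporal logFC profiles.
This vignette explains the models, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The two-compartment transcript model

Every simulated gene follows the standard kinetic model of mRNA metabolism:

$$\frac{du}{dt} = \alpha(t) - \beta u, \qquad
  \frac{ds}{dt} = \beta u - \gamma s,$$

where $u$ is unprocessed (intron-containing) and $s$ processed (mature)
transcript abundance, $\alpha(t)$ the transcription rate, $\beta$ the
processing rate and $\gamma = \ln 2 / t_{1/2}$ the first-order decay rate.
$\alpha(t)$ is piecewise constant: baseline outside a pulse window,
`alpha_baseline * alpha_pulse` inside it. `alpha_pulse > 1` is stress
induction; `alpha_pulse = 0` is transcriptional shutdown (rerouting of the
machinery to induced genes); `gamma_pulse > 1` models active, stress-induced
degradation — the mechanistic alternative to passive decay. The system
starts at the pre-stress steady state $u^* = \alpha_0/\beta$,
$s^* = \alpha_0/\gamma$.

Because the forcing is piecewise constant the system is solved *exactly*,
segment by segment, with the analytic two-exponential solution (the
$\beta = \gamma$ degeneracy uses its $t e^{-\gamma t}$ limit). The test
suite verifies agreement with an adaptive Runge–Kutta oracle to far better
than $10^{-6}$ relative error, so downstream consistency tests inherit no
integration error.

Key parameter defaults and why:

* `half_life`: drawn log-normal with median 4.5 h and $\sigma = 0.8$ on the
  natural-log scale in `make_kinetics_panel()`. 4.5 h is the median
  half-life of downregulated genes as estimated in fibroblast decay assays;
  the log-normal spread covers the observed range from tens of minutes
  (immediate early genes) to a day.
* `beta = 20`/h (pre-mRNA half-life about 2 min). In vivo processing
  timescales are not well constrained; any $\beta \gg \gamma$ preserves the
  property the analyses rely on — nascent dynamics lead mature dynamics —
  so $\beta$ is exposed but its exact value is immaterial to the tested
  limits.
* Course design: 45/90/120/180/240 min sampling in two hippocampal regions
  (dHC, vHC), 7 replicates per group, 20M expected counts,
  negative-binomial dispersion 0.05 — typical bulk RNA-seq conditions for
  this kind of study. Timepoint-0 samples are the unstressed controls.

## Nascent vs processed quantification

Reads are classified under three schemes sharing the filters *primary
alignment*, *strand concordance*, at most 3 feature-unmatched bases, and at
least 90% overlap with the feature: (i) exon features, split reads allowed —
the processed count; (ii) exon features, non-split only; (iii) transcript
bodies, non-split only. The unprocessed count is (iii) − (ii): non-split
reads on the gene body that are *not* explainable by mature mRNA.
Negative differences (possible through the overlap thresholds) are clamped
to zero and flagged. Reads overlapping several genes are resolved to the
largest overlap; exact ties are left unassigned rather than double-counted.

The read simulator places mature-origin reads uniformly on the spliced
transcript (junction-spanning where they cross exon boundaries) and
nascent-origin reads uniformly on the unspliced span. Reads are drawn per
(gene, origin) proportional to abundance and are **not** length-weighted — a
deliberate simplification that makes the expected intronic read fraction
analytic (nascent share × intron length share). Records carry coordinates
and overlap fractions, not base strings.

## Passive decay consistency

If downregulation after stress is passive — transcription is rerouted and
existing mRNA simply decays — the remaining fraction after time $t$ is
$2^{-t/t_{1/2}}$: 45 min at the 4.5 h median half-life predicts
$100(1 - 2^{-0.75/4.5}) \approx 11\%$ downregulation.
`decay_consistency()` compares this expectation (at the median half-life of
the downregulated genes) with the observed downregulation
($100(1-2^{\mathrm{median\ logFC}})$ by default; the median of per-gene
percent changes is available via `observed_method`) and declares
consistency within a configurable tolerance, default 5 percentage points —
the analysis is a qualitative plausibility check, and the tolerance is
deliberately exposed rather than hidden.

One subtlety drives where the mechanism discrimination is run. For
$t \ll t_{1/2}$, shutdown ($s/s_0 = e^{-\gamma t}$) and doubled decay
($s/s_0 = \tfrac12(1 + e^{-2\gamma t})$) agree to first order in
$\gamma t$: at 45 min they predict 10.9% vs 10.3% — indistinguishable under
any sensible tolerance. By 4 h the curves have diverged (46% vs 35% at the
median half-life), so the shutdown-vs-active-degradation discrimination is
performed at the final timepoint of the course, where it is reliable across
simulation seeds; the 45-min comparison is reported only as the
expected-vs-observed consistency check. Half-life binning defaults to
quartiles since the grouped-distribution display has no canonical edges.

## Phosphoproteomic differential analysis

* **Filtering**: a peptide is kept if in at least one condition it has at
  most `thr = 2` missing values — the interpretation under which a
  condition-wise comparison remains possible after imputation.
* **MinProb imputation**: missingness in label-free proteomics is
  predominantly left-censored, so each missing cell is drawn from a normal
  centred at that sample's $q = 0.01$ quantile of observed log2
  intensities, with spread `sigma_scale` × the median per-sample observed
  SD. Centre and spread are exposed because only the method and $q$ are
  canonical.
* **Moderated test**: per-peptide residual variances are shrunken toward a
  pooled prior $(d_0, s_0^2)$ estimated by moment matching on
  $\log s^2$ (trigamma inversion), and the t statistic uses
  $\mathrm{df} + d_0$ degrees of freedom. `moderate = FALSE` recovers the
  ordinary two-sample t-test exactly; the test suite also cross-checks the
  moderated path against an independent shrinkage implementation. An
  optional blocking factor is absorbed as additive covariates.
* **Two-way ANOVA** (`interaction_anova`): ordinary least squares per
  peptide for stress × sex designs, reporting interaction and main-effect
  p-values.
* **Enrichment**: the 2×2 phospho × significant table is tested with
  Fisher's exact test; reported fractions are integer percent,
  round-half-up, which reproduces printed values exactly from their
  numerator/denominator pairs.

The phospho generator plants a transient wave: peptide effects follow a
log-normal pulse peaking at `wave_peak_time` (default 0.1 h, i.e. directly
after a 6-min stressor) and decaying to 1% of peak by `wave_decay_time`
(default 0.5 h) — so effects are large immediately, reduced at 15 min, and
essentially absent from 30 min on. Missingness is logistic in intensity
(steepness `censoring_strength`), with the threshold solved numerically to
hit the requested overall missing rate; `censoring_strength = 0` gives
missingness completely at random.

## TF activity from weighted regulons

Regulons arrive as TF → (target, confidence category A–E, mode ±1) tables.
Category E (lowest confidence) is discarded; categories A–D receive weights
1.0/0.8/0.6/0.4 by default. The published benchmark behind these categories
reports only approximate AUCs, so the default preserves the *ordering* —
which is all the downstream score uses — and the map is configurable.

The activity score is a transparent weighted mean: with expression
row-standardized to z-scores,
$$A(\mathrm{tf}, j) = \frac{\sum_i w_i m_i z_{ij}}{\sum_i w_i},$$
with $w_i$ the confidence weight and $m_i = \pm 1$ the mode of action.
This replaces the pleiotropy-corrected rank-enrichment statistic of the
established regulon tool with a statistic whose permutation null is
analytic ($\mathrm{sd} = \sqrt{\sum w_i^2}/\sum w_i$), which the tests
verify. Pleiotropy handling is reduced to down-weighting targets shared by
more than `p_max = 10` regulons by the number of regulons containing them.
This is a documented departure, not an emulation.

Differential activity fits `activity ~ region + timepoint` per TF and tests
dropping the timepoint terms with a variance-moderated F-test; a TF is
called only if it passes FDR < 0.005, maximum absolute activity change >
0.2 (activity scores are log-scale-like, so mean differences play the role
of logFCs), and its own transcript averages log-CPM ≥ 2. For co-clustering,
the gene × TF matrix (weight × mode, z-scored per TF over its nonzero
support so that non-targets stay exactly zero) is concatenated with the
genes' temporal logFC columns and partitioned around 9 medoids
(`cluster::pam`, deterministic through its build step).

## Cell-type assignment of bulk DEGs

For each bulk DEG, the per-cell-type pseudo-bulk stress−control difference
$\Delta_c$ is weighted by statistical support, $w_c = |\Delta_c|(1 - p_c)$,
and the gene goes to the top-weighted cell type among those whose
difference shares the bulk direction. If the top weight is less than twice
the second-largest weight over *all* cell types the call is AMBIGUOUS; if
no cell type is direction-concordant, NO_CONCORDANT. The weighting phrase
behind this rule admits two readings; the multiplicative one is the
default and the exponent form $|\Delta_c|^{(1-p_c)}$ sits behind
`weight_mode = "power"`. Both are monotone in $|\Delta|$ and in $1 - p$,
which is all the rule requires. Taking the ambiguity comparison over all
cell types (not only concordant ones) is the stricter, more conservative
choice. Missing p-values count as $p = 1$ (no support), with a message.

The generator plants each responsive gene in one cell type, gives every
(gene, type) a log-normal baseline factor, and produces replicate-level
noise, per-type t-test p-values, and the bulk as the exact
abundance-weighted mixture of the noise-free type means — so the mixture
identity is testable exactly and recovery of planted origins is measurable.

## Temporal waves and meta-analysis

`kmeans_profiles` clusters feature × (region, timepoint) logFC matrices
with Euclidean k-means, 50 random restarts (best inertia kept), and
reports per-cluster per-column mean, SEM and SD. Clusters below
`min_size = 15` are excluded from the report but remain assigned — never
silently dropped. The number of centers is a *required* user input (5 for
the phospho course, 25 for the transcriptome course are the documented
defaults of the emulated analyses): automatic selection indices rarely
agree, so `elbow_report` provides inertia and silhouette diagnostics and
never chooses. Degenerate inputs with fewer distinct rows than centers are
split by row identity with zero inertia rather than erroring.

`estimate_svs` captures hidden batch structure orthogonal to the protected
design: log-CPM (pseudocount 0.5 — a transparent, dependency-free variance
stabilization) is regressed on the protected design and the residuals
decomposed by SVD. The number of surrogate variables is chosen by parallel
analysis: a component is kept while its share of residual variance exceeds
the 95th percentile of nulls built by permuting the matrix within genes and
re-residualizing. Comparing variance *fractions* rather than raw singular
values matters: re-residualizing a permuted matrix removes a rank-$p$ slice
of its variance, so raw null singular values sit systematically below the
observed ones and a raw-value rule inflates the SV count on pure noise
(verifiable by simulation); fractions of matrices with equal rank are
exchangeable under the null and calibrate correctly. Retained right
singular vectors are orthogonal to the design by construction (correlation
below $10^{-8}$, asserted).

`meta_fit` pools datasets on log-CPM with per-gene ordinary least squares:
additive mode fits `~ SVs + condition` and tests the shared condition
effect; interactive mode fits `~ SVs + condition * dataset` and
additionally tests the interaction terms, BH-adjusted per test family.
Ordinary (unmoderated) tests are used here so that with one dataset and no
SVs the fit reduces *exactly* to the per-gene linear model; confounded
condition/dataset layouts abort with a diagnostic rather than silently
aliasing.

## What the generator does and does not emulate

Emulated: the 5-timepoint two-region course with controls; gene-wise
transcription pulses, processing and first-order decay with log-normal
half-lives; transcriptional shutdown and active-degradation alternatives;
negative-binomial count noise scaled to library size; cell-type-specific
response amplitudes over a neurons/astrocytes/vascular/oligodendrocytes/
microglia panel; TF regulons driving induction; a transient phosphorylation
wave with left-censored missingness.

Not emulated: read base strings and alignment artifacts (records carry
overlap geometry only); droplet chemistry, ambient RNA and doublets;
isoform structure beyond one transcript per gene; length-weighted read
sampling; region-specific response differences (regions share kinetics and
differ only in noise). Green tests therefore demonstrate correctness of
the *computations* under a faithful error model, not robustness to every
artifact of real data.

## Problem sizes used in the checks

The packaged checks run shutdown/active-degradation discrimination on 250
genes × 4 replicates over 100 seeds, TF recovery with 10 active among 200
TFs (10 targets each, 2000 genes, 18 samples) over 50 seeds, null FDR
calibration over 500 (moderated test) and 100 (meta-analysis) replicates,
and counting-oracle equivalence on 50,000 reads over 200 genes — sizes at
which every Monte-Carlo margin in the assertions is comfortable while the
whole suite stays fast.

## Known limitations

* The activity score is linear; strongly non-additive regulation (e.g.
  cooperative TF pairs) is summarized, not modelled.
* `meta_fit`'s Gaussian OLS on log-CPM is approximate for very low counts;
  at the library sizes simulated here its null is calibrated (asserted),
  but count-level GLMs would be preferable near zero.
* Half-lives are treated as known inputs; estimating them from the time
  course itself is out of scope.
* The decay consistency check compares medians; it is a population-level
  plausibility test, not a per-gene decay fit.
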