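---
title: "Progressive disease markers from label-free proteomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progressive disease markers from label-free proteomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progmarker)
```

## The analysis problem

`progmarker` implements an end-to-end analysis of label-free quantification
(LFQ) proteomics for ordered disease cohorts. The motivating design is a
gynaecological tissue panel — clear cell carcinoma (CC), endometrioid
carcinoma (EC), endometriosis (EMT) and benign endometrium (END), with the
unbalanced sizes 6/7/3/5 — where endometriosis is the presumed precursor
lesion of both carcinoma subtypes. The scientific target is the set of
proteins whose abundance rises along the trajectory END → EMT → carcinoma:
such proteins are candidate disease markers and candidate participants in
malignant transformation.

The pipeline input is a MaxQuant-style `proteinGroups.txt` table: one row
per protein group, one `LFQ intensity <sample>` column per sample, zeros
meaning "not quantified". Everything upstream (spectral acquisition,
database search, MaxLFQ normalisation) is out of scope; everything
downstream of the quantification matrix is implemented and tested here.

## Preprocessing

**Filtering.** Groups identified by fewer than `min_unique_peptides = 2`
unique peptides, decoy ("Reverse") entries and potential contaminants are
removed. Two unique peptides is the conventional identification floor;
the filter report records what each criterion removed.

**Log transform and missingness.** Intensities are log2-transformed; zeros
become missing cells with provenance tracked per cell. In LFQ data
missingness is predominantly *missing not at random*: low-abundance signals
fall below the detection limit. The imputation model therefore draws each
missing cell, per sample column, from

\[ N(\mu_j - d\,\sigma_j,\; (w\,\sigma_j)^2), \]

where \(\mu_j, \sigma_j\) are the observed mean and SD of column \(j\),
with down-shift \(d = 1.0\) SDs and width \(w = 0.3\) as defaults. These
defaults mirror the configuration used by the tool of record for this kind
of analysis (Perseus exposes the same two parameters; its shipped default
down-shift is larger at 1.8 — both are exposed as arguments). Imputation is
column-wise because per-run sensitivity differs between LC-MS/MS runs; μ
and σ use observed cells only, with the sample (n−1) SD. Imputation
consumes a dedicated, named RNG substream derived from the pipeline seed,
so inserting or removing other stochastic stages never changes imputed
values.

**Z-scoring.** Row (protein) standardisation ahead of Euclidean-distance
clustering divides by the population (1/n) SD by default — the convention
of common heatmap tooling; the sample convention is available via
`sd_type`. The choice rescales every row by the same factor and is
invisible to clustering topology.

## Quality control

Pairwise Pearson correlation between samples is computed either on the
imputed complete matrix (default; matches how post-processing heatmaps are
made) or on cells observed in both samples of a pair
(`observed_pairwise`), which is deterministic because it ignores imputation
noise. A sample is flagged as a cohort outlier when its *best* within-cohort
correlation falls strictly below the threshold (default 0.75). The default
sits between the ≈0.80 within-cohort floor a clean tissue cohort shows and
the ≈0.72 ceiling of a genuinely atypical sample, so a single histological
mismatch is flagged without tuning; singleton cohorts are never flagged and
exclusion of flagged samples is opt-in (`exclude_outliers`), since removing
a patient is a judgement call. Housekeeping stability is reported as the
linear-scale coefficient of variation and the log2 SD per protein.

## Multivariate structure

PCA runs on samples-as-observations over the complete log2 matrix,
column-centred, not scaled, via singular value decomposition; component
signs are fixed by making each component's largest-magnitude loading
positive, so results are reproducible to the bit. Hierarchical clustering
uses Euclidean distance with average linkage (UPGMA) by default — the
tool-of-record convention when only the distance is prescribed — with
single, complete and Ward linkage available. Cluster/label agreement is
quantified by the adjusted Rand index.

## Differential screens

The cohort-level screen is a per-protein one-way fixed-effects ANOVA with
Benjamini–Hochberg adjustment (default flag level 0.01). Proteins constant
across all samples take the degenerate convention F = 0, p = 1. For
two-group contrasts the package computes empirical-Bayes moderated t
statistics: per-protein pooled variances \(s^2\) on \(d\) residual degrees
of freedom are shrunk toward a prior,

\[ \tilde s^2 = \frac{d_0 s_0^2 + d\,s^2}{d_0 + d}, \qquad
   t = \frac{\Delta}{\tilde s\sqrt{1/n_1 + 1/n_2}} \sim t_{d_0 + d}, \]

with \((d_0, s_0^2)\) estimated from all proteins by the moment equations
on log variances (the trigamma equation inverted by Newton iteration;
\(d_0 = \infty\) when the observed dispersion does not exceed its sampling
expectation). The estimation is delegated to `limma::fitFDist()`, the
reference implementation of exactly this estimator; the statistics
themselves are computed in-package because the marker procedure needs a
non-standard variant (below), and they are cross-checked against
`limma::eBayes()` in the test suite.

The volcano significance rule adds a fudge factor to the denominator,
\(t_{s0} = \Delta/(\mathrm{se} + s_0)\) with defaults FDR = 0.05 and
\(s_0 = 1\), referred to the unmodified degrees of freedom and BH-adjusted.
This is the deterministic, analytic form of the rule; permutation-based
FDR is out of scope.

## The marker procedure

For each adjacent transition of the ordered cohorts (END→EMT,
EMT→carcinoma; the two carcinoma subtypes are analysed separately, each
against the same precursor cohorts):

1. **One-sided moderated test with a conservative control variance.** The
   screen looks for *elevation* only, so p-values are one-sided. Protein
   levels in the control (earlier) cohort are modelled as normal with a
   deliberately pessimistic variance: the upper bound of a \((1-\gamma)\)
   chi-square confidence interval (default \(\gamma = 0.25\)). The
   group-level form of this bound, \((n-1)s^2/\chi^2_\gamma(n-1)\), is
   exposed as `conservative_control_fit()`. Inside
   `transition_posteriors()` the bound is instead applied to the moderated
   variance at its effective degrees of freedom — the inflation factor is
   \(\nu/\chi^2_\gamma(\nu)\) with \(\nu = d_0 + d\). This was a genuinely
   open design point; the package applies the bound to the variance
   estimate the test actually uses because inflating the raw \(n-1\)-df
   group variance would double-count uncertainty the prior has already
   absorbed, and would deflate null z-scores far from the N(0, 1) reference
   the two-group model's default null assumes. As the prior becomes certain
   the factor tends to 1; with weak priors and small control groups it is
   substantial (e.g. ≈1.48 at \(\nu = 10\), \(\gamma = 0.25\)).

2. **Null proportion.** One-sided p-values feed the right-boundary
   estimator of the true-null proportion: on a 20-bin histogram of p, scan
   left to right and stop at the first bin whose height does not exceed the
   tail estimate \(\#\{p > r\}/(m(1-r))\) computed at the bin's right
   boundary \(r\); \(\pi_0\) is that tail estimate, clipped to [0, 1]. On
   an equal-width histogram the tail estimate equals the mean height of the
   bins to the right, so the rule finds the point where the histogram has
   flattened to its null plateau. Twenty bins give the candidate boundaries
   0.05, 0.10, …, 0.95.

3. **Two-group model.** z-scores \(z = \Phi^{-1}(1-p)\); marginal density
   \(\hat f\) by a Gaussian kernel estimate with Silverman's rule-of-thumb
   bandwidth on a 1024-point grid; local false discovery rate
   \(\mathrm{lfdr}(z) = \pi_0 f_0(z)/\hat f(z)\), clipped to [0, 1]. The
   null density \(f_0\) is the theoretical standard normal by default — the
   moderated one-sided p-values are calibrated under the null, so the
   theoretical choice is the simpler and better-grounded default — with an
   empirical option (normal with the median and IQR/1.349 of z) for data
   whose null is visibly shifted or deflated. The posterior probability of
   elevation is \(1 - \mathrm{lfdr}\) for \(z > 0\), else 0.

4. **Pattern classification.** At posterior threshold \(\tau = 0.9\):
   pattern **A** if both transitions are elevated, **B** if only END→EMT,
   **C** if only EMT→carcinoma, `none` otherwise; the marker set is
   A ∪ B ∪ C. No published cutoff exists for this posterior; 0.9 is the
   conventional high-confidence level and is exposed as `tau` everywhere.

p-values of exactly 0 or 1 (possible after clamping in degenerate inputs)
are moved to \(1/(m+1)\) and \(m/(m+1)\) with a warning before the z
transform.

## The synthetic-data generator

`generate_lfq_dataset()` emulates the statistical regime the analysis
assumes, with known ground truth: 21 samples in the 6/7/3/5 cohort design;
per-protein log2 baselines \(b_i \sim N(25, 2^2)\) (typical MaxLFQ log2
scale); within-cohort residual SD 0.7 log2 units (a realistic tissue-LFQ
replicate spread); progressive patterns A/B/C at 2% each by default with a
2.0 log2-unit step per perturbed transition (pattern A gains one step at
EMT and a second in carcinoma; B and C gain a single step each — the size
of pattern C's single carcinoma step is the package's choice, mirroring
B); 50
dedicated housekeeping proteins with equal means everywhere; and
missing-not-at-random dropout acting on the *realized* noisy value,
\(P(\text{missing}) = \mathrm{logit}^{-1}(\alpha - \beta x)\) with defaults
\(\alpha = 10.4, \beta = 0.5\) (≈25% dropout one baseline-SD below the
mean, ≈11% at the mean — chosen once as a realistic deep-proteome rate;
the underlying study does not report its missing-value fraction).
Intensities are exported on the raw \(2^x\) scale with zeros for missing
cells, in the same proteinGroups dialect the reader consumes, so simulated
data exercise the identical code path as real files.

What the generator does *not* emulate: peptide-level evidence, batch
effects beyond an optional annotation column, correlated proteins
(co-regulation), heavy-tailed noise, and abundance-dependent variance.
Passing tests on synthetic data therefore certify the statistical machinery
under the stated model, not robustness to those real-data features.

## Numerical choices and problem sizes

- Ties in distances and all RNG-dependent stages are made deterministic by
  fixed seeds and named substreams; identical config + seed reproduces
  byte-identical outputs.
- The test suite and `scripts/acceptance.R` size their simulations for
  desk-scale runs: 10⁵ imputation draws; 20 000 variances for prior
  recovery; 100 replicates of 1000 p-values for \(\pi_0\); 200 effect-free
  datasets of 300 proteins × 21 samples for null calibration; 25 replicates
  of 2000 proteins for marker recovery; 10 replicates for the
  signature-discrimination indices (the adjusted Rand index of a 2-cut over
  8 samples is intrinsically high-variance, so the replicate mean is the
  meaningful quantity). These sizes are the package's validation choices;
  all scale linearly if larger certification runs are wanted.
- Degenerate inputs: constant proteins yield F = 0/p = 1 in the ANOVA and
  an explicit error in z-scoring; control groups with zero variance are
  flagged `degenerate` in the conservative fit; columns with fewer than two
  observed values abort imputation with the column named.

## Known limitations

- The marker procedure's operating characteristics at \(\tau = 0.9\) are
  conservative by construction: with small precursor cohorts (three EMT
  samples) and a 2 log2-unit effect, the local-fdr boundary sits around
  z ≈ 3.3 while true effects centre near z ≈ 3.9–4.0, so single-transition
  patterns are detected at roughly 70–75% sensitivity, and essentially all
  calls are correct (the acceptance script reports both numbers). Higher
  sensitivity requires a lower τ, larger cohorts or stronger effects —
  a trade the τ parameter exposes but the default deliberately does not
  take.
- Exact reproduction of marker *counts* from any particular study is not
  guaranteed: the posterior cutoff, the conservative-estimation rule and
  the π₀ binning are configuration, and published analyses rarely state
  them completely.
- No network resources are consulted: annotation and pathway membership
  come from user-supplied GMT files; web-service statistics (PANTHER,
  ConsensusPathDB, Reactome) are out of scope.
- No batch-effect correction, no permutation FDR, no alternative imputation
  schemes (kNN, minimum-value): the down-shift model is the single,
  explicit assumption about missingness.
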