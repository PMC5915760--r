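# progmarker

Label-free quantitative (LFQ) proteomics of disease-progression cohorts,
from a MaxQuant-style `proteinGroups.txt` table to a ranked set of
progressive disease markers.

The package targets the study design of endometriosis-associated ovarian
carcinoma: four unbalanced tissue cohorts — clear cell carcinoma (CC),
endometrioid carcinoma (EC), endometriosis (EMT) and benign endometrium
(END) — profiled by label-free LC-MS/MS, where the biological question is
which proteins rise along the presumed disease trajectory
END → EMT → carcinoma. It is aimed at proteomics analysts who have a
protein-group quantification matrix and a sample annotation and want a
reproducible, seeded path from raw intensities to marker calls, plus a
synthetic-data generator with ground truth so every stage can be validated
without any external download.

## The model

**Preprocessing.** Protein groups with fewer than 2 unique peptides, decoy
hits and contaminants are removed; intensities are log2-transformed with
zeros treated as missing. Missing values are imputed Perseus-style per
sample column: draws from N(μ − 1.0·σ, (0.3·σ)²), where μ and σ are the
observed mean and SD of the column — emulating signals below the detection
limit (missing-not-at-random).

**QC and structure.** Pairwise Pearson correlation between samples (with an
outlier rule that flags a sample whose best within-cohort correlation falls
below a threshold), housekeeping-protein stability, PCA by SVD on the log2
matrix, and average-linkage hierarchical clustering under Euclidean distance
on z-scored rows.

**Differential screens.** Per-protein one-way ANOVA across cohorts with
Benjamini–Hochberg control; empirical-Bayes moderated t statistics
(`s̃² = (d₀s₀² + d·s²)/(d₀ + d)`, prior `(d₀, s₀²)` estimated from all
proteins); and the S0-volcano rule `t_s0 = Δ/(se + s0)` that de-prioritises
tiny fold changes.

**Marker procedure.** For each adjacent transition (END→EMT, EMT→cancer):
a one-sided moderated test of elevation with a conservatively inflated
control variance (chi-square upper confidence bound at level γ), one-sided
p-values mapped to z = Φ⁻¹(1 − p), the true-null proportion π₀ estimated by
the right-boundary histogram rule, and the two-group model
`lfdr(z) = π₀ f₀(z) / f̂(z)` with a kernel estimate of the marginal density
f̂. Each protein gets a posterior probability of elevation `1 − lfdr` per
transition; at threshold τ, proteins are classified into progressive
patterns **A** (elevated at both transitions), **B** (END→EMT only),
**C** (EMT→cancer only); the union A ∪ B ∪ C is the disease-marker set.

**Signatures and enrichment.** Directional gene signatures are checked for
sign concordance against proteomic fold changes, tested for cohort
discrimination via clustering + adjusted Rand index, and arbitrary GMT gene
sets are scored by hypergeometric over-representation.

## Worked example

```r
library(progmarker)

cfg <- sim_config(n_proteins = 3000, seed = 42)   # 21 samples: CC 6, EC 7, EMT 3, END 5
sim <- generate_lfq_dataset(cfg)

pg <- filter_protein_groups(sim$protein_groups)
attr(pg, "filter_report")
#> # A tibble: 4 × 2
#>   criterion         removed
#>   <chr>               <int>
#> 1 reverse                 0
#> 2 contaminant             0
#> 3 unique_peptides<2     141
#> 4 total                 141

em <- impute_downshift(to_log2(pg), seed = 42)
em
#> <expr_matrix> 2859 proteins x 21 samples; 8447 cells not measured (8447 imputed)

correlation_report(em)
#> <correlation_report> 21 samples (imputed_complete); off-diagonal PCC range [0.728, 0.825]

post  <- transition_posteriors(em, sim$annotation, c("END", "EMT", "CC"))
calls <- classify_patterns(post, tau = 0.9)
calls
#> <marker_call> 2859 proteins at tau = 0.90: A=0 B=17 C=25 none=2817 (42 markers)

glance(attr(post, "fit_1"))
#> # A tibble: 1 × 6
#>       m   pi0 null        null_mean null_sd bandwidth
#>   <int> <dbl> <chr>           <dbl>   <dbl>     <dbl>
#> 1  2859 0.982 theoretical         0       1     0.189
```

The filter report says 141 of 3000 simulated groups fell below the
2-unique-peptide rule. After imputation the 21 samples correlate between
0.73 and 0.83 — the within-cohort range a clean tissue cohort shows. The
first-transition two-group fit estimates that 98% of proteins are null for
the END→EMT elevation; 42 proteins pass the τ = 0.9 posterior threshold in
at least one transition and form the marker set, each labelled with its
progressive pattern. With a ground-truth simulation, `sim$truth$pattern`
lets you score these calls directly.

Whole-pipeline runs (reading real files or simulating, through QC, PCA,
clustering, ANOVA, volcano, markers, signatures and enrichment, with a JSON
manifest) go through `run_pipeline()`, driven by an R list or a YAML
configuration. Result objects have `tidy()`/`glance()` methods and
`autoplot()`/`plot_volcano()` graphics.

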