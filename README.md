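# immunodyn

Analysis toolkit for **longitudinal tumor immune dynamics** in serial-biopsy
cohorts: patients biopsied before treatment (T1), on-treatment (T2), and at
surgery (T3), with bulk RNA expression, clinical covariates, and H&E-style
histology. The package implements the full analysis chain used to ask how
cytotoxic treatment reshapes the tumor immune microenvironment and whether
that response predicts pathologic complete response (pCR):

* **Mixed-model differential expression.** Per feature, a random-intercept
  linear mixed model
  `y_i = β0 + β1·purity_i + β2·subtype_i + β3·time_i + b_patient + ε_i`
  fit by one-dimensional profiled (restricted) maximum likelihood over the
  variance ratio σ²_b/σ²_e, with the treatment-time term tested by a
  likelihood-ratio χ² on ML fits. Genes are selected at p < 0.01 and
  |log2 FC| > 1, then grouped by k-means consensus clustering on
  per-time-point mean profiles.
* **Signature scoring.** Single-sample gene-set scores via a Gaussian
  kernel-ECDF rank statistic and a weighted Kolmogorov–Smirnov-like random
  walk; cytolytic activity (CYT) as the geometric mean of GZMA and PRF1;
  hypergeometric cluster–pathway enrichment.
* **Immune cell deconvolution.** nu-support-vector regression (linear
  kernel, ν ∈ {0.25, 0.5, 0.75} chosen by fit RMSE) of bulk mixtures on a
  13-cell-type signature matrix, with non-negativity and sum-to-one
  normalization, plus 13→10 group aggregation.
* **Immune states.** Integrative latent-variable (EM) clustering of
  signature scores and cell fractions into cold/warm/hot states, rank
  selected by BIC, with transition tables and percentages between time
  points.
* **Virtual microdissection.** Non-negative matrix factorization with
  Kullback–Leibler multiplicative updates (30-run best-of restarts),
  cophenetic-coefficient rank selection, entropy-based exemplar genes
  (score > median + 3·MAD and max contribution above the median), and
  factor-to-compartment attribution with composite tumor/normal factors.
* **TIL quantification.** Otsu segmentation with minShape/maxShape/
  failure-region size filters and watershed splitting, a fixed 36-feature
  vector per nucleus, a radial-kernel probability SVM, the 0.97 / 0.1
  score cutoffs and 60–150 px size gate, 2050-px tiling with global
  coordinate reconstruction, and TIL density as count per tissue area.
* **Outcome association.** Covariate-adjusted logistic/linear regression
  per immune feature and elastic-net bootstrap variable usage (selection
  frequency over resampled fits with cross-validated penalty).
* **Synthetic cohort generator.** Every input above can be simulated with
  retained ground truth — longitudinal expression with known fixed and
  random effects, Dirichlet cell mixtures, and histology-like images with
  planted nuclei — so the whole pipeline is testable without
  controlled-access patient data.

## Worked example

```r
library(immunodyn)

cfg <- simulation_config(n_patients = 60, n_genes = 400,
                         signature_blocks = c(immune = 50),
                         effect_sizes = list(immune = list(
                           purity = -2, time = c(T2 = 1, T3 = -0.5))),
                         seed = 11)
cohort <- simulate_cohort(cfg)
de <- run_de(log_transform(cohort$expression), cohort$clinical)
head(subset(de, comparison == "T1-T2" & fdr < 0.05), 3)
#>   feature   group comparison  estimate t_statistic lrt_chisq      p_value          fdr
#> 1   G0001 overall      T1-T2 1.0173830    8.820316  56.00883 7.214641e-14 1.154343e-12
#> 2   G0002 overall      T1-T2 0.8303531    7.643724  45.63610 1.423931e-11 1.324587e-10
#> 3   G0003 overall      T1-T2 0.9454513    8.376323  51.75923 6.274120e-13 6.782833e-12
```

The `estimate` column is the log2 fold change of the on-treatment (T2)
samples over baseline after adjusting for tumor purity, subtype, and the
patient random intercept — here recovering the planted +1 log2 shift of the
immune block; `p_value` comes from the likelihood-ratio test of the time
term and `fdr` is its Benjamini–Hochberg adjustment within the comparison.

A full synthetic run of every stage (scores, DE, clustering, deconvolution,
immune states and transitions, NMF, TIL imaging, outcome ranking):

```r
summary <- pipeline_demo(seed = 42)
summary$pcr_percent      # consort bookkeeping: 33 (% of patients with pCR)
summary$til_count        # 60 lymphocytes detected (60 were planted)
summary$til_density      # 166.7 lymphocytes per mm^2 of tissue
```

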