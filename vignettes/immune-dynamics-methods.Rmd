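---
title: "Methods: longitudinal tumor immune dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal tumor immune dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and setting

`immunodyn` analyzes serial tumor biopsy cohorts in which each patient is
sampled at up to three treatment time points — baseline (T1), on-treatment
(T2), and surgery (T3) — with bulk expression (TPM), clinical covariates
(subtype, tumor purity, pathologic response), and histology images.
Patients who achieve pathologic complete response (pCR) have no residual
tumor at surgery, so the T3 sample exists only for residual-disease
patients; every model in the package has to live with this structurally
missing, outcome-dependent third time point. This vignette records the
modeling choices, defaults, and the reasoning behind the places where the
design was genuinely open.

# The mixed model for longitudinal differential expression

Feature values (log2 expression, signature scores, cell fractions) are
modeled per feature as

$$y_i = \beta_0 + \beta_1\,\mathrm{purity}_i + \beta_2\,\mathrm{subtype}_i
+ \beta_3\,\mathrm{time}_i + b_{d(i)} + \varepsilon_i,$$

with a Gaussian random intercept $b_d \sim N(0, \sigma_b^2)$ per patient
and residuals $\varepsilon \sim N(0, \sigma_e^2)$. Tumor purity enters as
a covariate because treatment changes tumor cellularity, which otherwise
masquerades as expression change; subtype enters in the overall cohort but
is dropped in subtype-restricted runs where it is constant or nearly so.

For a single random intercept the likelihood profiles down to one
dimension: given the variance ratio $\lambda = \sigma_b^2/\sigma_e^2$,
generalized least squares is ordinary least squares on partially
group-centered data ($y - \theta_d\,\bar y_d$ with
$\theta_d = 1 - 1/\sqrt{1 + n_d\lambda}$) and $\sigma_e^2$ has a closed
form. `fit_lmm()` optimizes the profiled (restricted) deviance over
$\log\lambda$ on $[\log 10^{-8}, \log 10^{8}]$, explicitly compares the
boundary $\lambda = 0$, and treats ratios below $10^{-7}$ as the boundary,
where the fit collapses to OLS as it should. The test suite verifies
agreement with `lme4` to five decimals on both ML and REML paths.

Treatment-time effects are tested by a likelihood-ratio $\chi^2$ on ML
fits (REML likelihoods are not comparable across fixed-effect structures),
with the statistic floored at zero; degrees of freedom equal the
difference in fixed-effect counts. Time is categorical, not linear,
because immune features travel up–down trajectories (rise at T2, fall at
T3) that a linear trend would null out. Differential analysis runs
separately per pairwise comparison (T1–T2, T2–T3, T1–T3) on the samples at
those two time points, and FDR is Benjamini–Hochberg within each
comparison × sample-group stratum — pooling across comparisons is a
defensible alternative; we expose the per-stratum choice because the three
comparisons answer different questions and are reported separately.

Gene selection takes the union over comparisons and groups of
`p < 0.01` and absolute fold change > 2, i.e. $|\beta_3| > 1$ on the log2
scale on which the model operates. Selected genes are clustered by k-means
consensus: each of 100 resamples draws 80% of samples, recomputes per-time
mean profiles of row-z-scored expression (so temporal *shape*, not
amplitude, is the signal), and runs k-means with 10 restarts; the
consensus matrix of co-assignment frequencies is cut by average-linkage
hierarchical clustering into k = 3 groups. The resample count and
subsample fraction are package defaults chosen for stability at cohort
sizes of tens to hundreds of samples.

# Single-sample gene-set scores

Scores use the kernel-ECDF random-walk construction: per gene, a Gaussian
kernel smoothed ECDF across samples (bandwidth $\mathrm{sd}/4$; constant
genes score 0.5 everywhere), per sample a ranking of genes by that
statistic, and per gene set a weighted KS-like walk over the ranking with
weight exponent $\tau = 1$ and the max-deviation-difference score. These
defaults are the reference algorithm's; both are exposed. One numerical
choice is ours: the rank weight is $|r - (p+1)/2|$, symmetric about the
middle rank, so that reversing a ranking exactly negates the walk — the
tests rely on this antisymmetry, and the suite pins the whole construction
to an independently written brute-force implementation at $10^{-9}$.

The cytolytic activity score is the geometric mean of GZMA and PRF1
expression with a small offset (default 0.01, the convention of the
cytolytic-index literature) so zero expression stays defined. Cluster ×
pathway enrichment is an upper-tail hypergeometric test whose universe is
the genes in the filtered expression matrix — not the genome — because
that is the population selection actually operated on. A pathway is mapped
to a cluster when enrichment FDR < 20% and its own score is differentially
distributed over time at FDR < 5% in the same sample group.

# Immune cell deconvolution

`nusvr_deconvolve()` regresses each mixture on the signature matrix with
nu-SVR (linear kernel), per the published support-vector deconvolution
method: restrict to shared genes on the linear TPM scale, z-score the
signature columns and the mixture, fit at $\nu \in \{0.25, 0.5, 0.75\}$,
keep the $\nu$ with the lowest RMSE between fitted and observed mixture,
zero negative coefficients, and renormalize to the simplex. Deconvolution
is invariant to positive rescaling of the mixture (z-scoring absorbs it)
and equivariant under signature column permutation. The shipped signature
is synthetic — 13 archetypal cell types with block markers — standing in
for proprietary leukocyte references; the 13→10 aggregation (naive CD4
with Treg, naive with memory B, monocytes with M0) is a documented,
configurable convention, since no published enumeration exists to copy.

# Immune states

Cold/warm/hot states come from a shared Gaussian latent-variable model
across feature blocks (signature scores, cell fractions): $x_i = W z_i +
e_i$ with $k-1$ latent dimensions, diagonal noise, EM from a principal
component initialization (seed 17). We deliberately run EM to convergence
*without* penalty and apply the lasso-type soft threshold once to the
converged loadings, scaled per latent dimension by its strongest loading
(default penalty 0.2; penalty ≥ 1 zeroes everything and is flagged
degenerate). Thresholding inside every M-step makes a zeroed latent
column an absorbing state and biases all loadings toward a shrunken fixed
point, which flattens the likelihood across k and defeats BIC-based rank
selection; the one-shot proximal step keeps the sparsity semantics while
leaving the likelihood informative. Cluster assignments are k-means (25
restarts) on the posterior latent means; `select_k_bic()` minimizes
$-2\ell + (\#\{W \ne 0\} + p)\log n$ with ties broken toward smaller k.

With k = 3, clusters are ordered into C/W/H by the mean of a per-sample
immune intensity summary; we use z-scored cytolytic score (plus a
TIL-factor score when available) because the states are phenotypically
defined by immune infiltration but no canonical ordering statistic exists.
Exact ties are refused rather than silently broken. Transitions between
paired time points are counted with conserved margins, and edge
percentages use half-away-from-zero rounding — the convention that
reproduces printed cohort percentages such as 20/26 → 77% and 10/11 → 91%
exactly (banker's rounding does not).

# Virtual microdissection

`nmf_brunet()` implements KL-divergence multiplicative updates from random
non-negative initializations. A run stops when the sample connectivity
vector (argmax factor per sample) is unchanged for 40 consecutive checks
at a 10-iteration check interval, or at `max_iter`; the best of 30 runs by
KL error is kept. Rank selection computes, per candidate k, the consensus
matrix of sample co-clustering across runs and the cophenetic correlation
between 1 − consensus and its average-linkage dendrogram distances;
degenerate perfectly-stable consensus scores 1 and is flagged. On real
compendium-scale data the optimal rank lands in the teens; on the planted
three-block synthetic matrices used for validation the selector must — and
does — return 3.

Exemplar genes per factor use the entropy specificity score
$1 + \frac{1}{\log_2 k}\sum_f p_f \log_2 p_f$ with $p_f$ the
row-normalized gene weights: 1 for a single-factor gene, 0 for a uniform
one. Selection requires score > median + 3·MAD **and** a maximum raw
contribution above the median of all W entries; the MAD is unscaled
(median absolute deviation, no 1.4826 normality factor), following the
cited extraction convention, and the contribution threshold uses raw
entries — both are documented and tested against brute-force
recomputation. Factor–compartment attribution is rule-based (dominant
sample group with a 1.2× margin over the runner-up, optionally confirmed
by exemplar enrichment); composite tumor and normal factors are plain sums
of member factor weights.

# TIL quantification from histology-like images

Segmentation inverts intensity (nuclei are dark), takes a global Otsu
threshold, and labels connected components with the published size
filters: components < 50 px are discarded, > 2000 px discarded as
segmentation failures, and components in (800, 2000] are split by
watershed on the distance transform with pieces re-filtered. A guard
rejects Otsu splits with < 0.1 mean foreground/background contrast so
blank tissue yields zero candidates instead of thresholded noise.

Each candidate gets a fixed, documented 36-feature vector: 10 shape
features from the mask alone (area is exactly the pixel count; brightness
changes cannot touch these), 14 intensity statistics on inverted gray
within the mask, and 12 texture/context features (border contrast,
gradients, local background, histogram entropy/energy). The classifier is
a radial-kernel C-classification SVM with probability output. The
published filters are applied verbatim: lymphocyte iff probability ≥ 0.97
and area ∈ [60, 150]; non-lymphocyte iff probability ≤ 0.1; large cell iff
not classed lymphocyte and area ≥ Q3 of areas among cells > 200 px. Large
images are processed in 2050-px tiles with a 40-px overlap margin;
detections belong to the tile containing their centroid, which resolves
border duplicates (the choice is ours — the tiling convention is silent on
boundary cells). Tissue area counts pixels darker than a near-white
cutoff, converted to mm² at 0.5 µm/px (20× convention, configurable), and
density is count over area.

The synthetic image generator plants small round dark nuclei (area
60–150 px) and larger irregular paler blobs on lightly textured tissue.
It is a single-stain caricature: the detector operates on intensity and
shape, which exercises every stated filter, but passing tests say nothing
about color deconvolution of real stains, overlapping nuclei crowds, or
scanner artifacts. The shipped classifier is likewise trained on synthetic
nuclei; on real slides it must be retrained on pathologist-marked cells.

# Outcome association

Per-feature association with pCR adjusts for the clinical covariates
(subtype flags, stages, purities) via logistic regression for binary
features and linear regression otherwise; perfect separation is detected
(non-convergence, boundary fitted probabilities, or runaway coefficients)
and refit with a light ridge penalty. Feature ranking bootstraps patients
with replacement; each iteration fits an elastic-net logistic path
(mixing α = 0.5 — unstated in the source convention, exposed as a
parameter; equal penalty factors on every variable) with the penalty
chosen by 5-fold cross-validated deviance, and records nonzero
coefficients. Usage is the selection percentage; ranks break ties by mean
absolute coefficient. The reference setting is 10,000 iterations; the
validation suite runs 500 (and smaller unit checks at 100–200), which is
sufficient to order a planted strong on-treatment predictor above pure
noise and to separate signal and noise feature groups by rank-sum test.

# The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the
study conditions: 146 patients; subtype mix 22/20/20/38% across
ER+/HER2−, ER+/HER2+, HER2+/ER−, TN; pCR rate 38%, with pCR patients
never contributing T3; baseline purity Beta(5, 2) with the on-treatment
mean lowered by 0.15 (on-treatment biopsies carry relatively more
non-tumor tissue; the magnitude is a free parameter, chosen once);
expression built on the log2 scale from the mixed model above and
exponentiated to TPM, so OLS inverts it exactly when all noise terms are
zero. Validation cohorts use 200 patients with σ_b = σ_e = 0.5 (log2
units) and a 100-gene immune block carrying a +1 log2 on-treatment effect
that relaxes to −0.5 at surgery — the up–down trajectory characteristic of
treatment-induced immune infiltration. What the generator does not
emulate: negative-binomial count dispersion (expression is lognormal
around the linear predictor), gene–gene correlation beyond block
structure, and missing-at-random dropout beyond the pCR rule; tests
passing on it validate the estimators' contracts, not distributional
robustness on real RNA-seq.

# Problem sizes and numerical conventions

The test and acceptance runs use: 200 patients × 600 genes for
mixed-model recovery and null calibration (500 null genes); 25 noise-free
Dirichlet mixtures over 13 cell types; a 300-gene × 45-sample planted
three-block matrix for NMF (15 runs per candidate rank, 2–6); twenty
2050² images with 50–200 planted lymphocytes; 60 samples in three planted
states for integrative clustering; 120 patients × 15 features × 500
bootstrap iterations for the elastic net. Percentages round half away
from zero. The likelihood-ratio statistic is floored at 0; as is typical
for mixed-model likelihood-ratio tests, the χ² reference is mildly liberal
in finite samples (empirical size near 0.06 at nominal 0.05 for cohorts of
200 patients), which the calibration checks' tolerance band
acknowledges. Variance
ratios below 10⁻⁷ collapse to the OLS boundary. Zero-variance rows
z-scale to zeros with a warning; empty gene-set overlaps score `NA` with
a warning rather than erroring, so one bad set cannot abort a scoring
run.

# Known limitations

The GSVA-flavor score is implemented only for continuous (log-scale)
inputs, not the Poisson-kernel count variant. The integrative clustering
is the original Gaussian EM with a single penalty, not the Bayesian or
multi-penalty successors. The deconvolution has no absolute mode and no
permutation p-values. The elastic-net bootstrap treats patients as
exchangeable and does not stratify resamples by subtype. Histology
handling is single-channel; whole-slide pyramid formats are out of scope.
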