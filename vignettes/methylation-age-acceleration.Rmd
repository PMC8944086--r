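---
title: "Methods: DNAm age acceleration, methylation entropy and outcome in GBM-style cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNAm age acceleration, methylation entropy and outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `methage`, the assumptions they
make, the parameters that matter, and the design decisions taken where the
design was genuinely open. It states no empirical result that the test
suite or the analysis drivers do not themselves compute.

# The data model

A methylation data set is a probes × samples matrix of beta values
(methylated fraction in [0, 1]) or M-values (log2 odds,
`M = log2(β/(1−β))`), tagged with its scale, plus a probe annotation
modelled on the Illumina 450k manifest: chromosome and 1-based position
(hg19 labels carried as metadata only — no liftover), CpG-island relation
(Island, N/S shore, N/S shelf, open sea), gene and signed TSS distance,
promoter status (|TSS distance| ≤ 1500 bp), and SNP/sex-chromosome flags.
Linear modelling is done on M-values, whose variance is more nearly
constant across the beta range; entropy and purity work on betas, whose
[0, 1] scale the formulas assume.

Probe filtering removes probes failing detection (p > 0.01), on sex
chromosomes, or overlapping SNPs. Whether a single failing sample should
remove a probe is not a settled convention; the default here is the
strictest reading (any failing sample removes the probe), with
`max_fail_frac` exposing the tolerated fraction. Filtering is idempotent
and order-preserving, and reports counts per rule.

Cross-study aggregation uses parametric empirical-Bayes location/scale
adjustment (ComBat, via `sva`) on M-values, protecting age as a
biological covariate. One consequence worth stating plainly: because the
per-probe batch effects are shrunk toward an empirical prior, batch means
are equalized only up to a shrinkage residual of order
σ²/(n·τ²) — exact post-hoc equality of batch means is not a property of
the real procedure, and the tests assert near-removal (>98% of a planted
shift) rather than exact equality. The non-parametric ComBat variant is
out of scope.

# The epigenetic clock

DNAm age is `F⁻¹(intercept + Σ w_j β_j)` over clock probes, with the
piecewise age transform `F(a) = log(a+1) − log(adult+1)` for `a ≤ adult`
and `(a − adult)/(adult+1)` above, continuous at the knot
(`adult_age = 20` years unless configured). Age acceleration is
`DNAm age − age`, exactly.

Decisions:

- **Missing clock probes** (typically lost to filtering) are dropped from
  the linear predictor without re-normalization, with a warning and a
  count; mean-imputation (β = 0.5) is available behind a flag. Dropping
  mirrors how published clocks are applied to filtered arrays.
- **Calibration** (`calibrate_betas()`) is a per-probe quantile-range
  match to a reference profile — a monotone linear map that preserves
  within-probe sample ranking. It is a generic stand-in for array-specific
  calibration recipes and is off by default, because the synthetic
  generator emits data already on the model scale.
- **Training** (`train_clock()`) fits an elastic net (`glmnet`,
  α = 0.5 by default) on transformed ages with a seeded fold assignment,
  so refits are bit-identical. The penalty is selected at the minimum of
  the cross-validation curve.

# Methylation entropy

The marker-level entropy treats each CpG as a two-state source
(methylated `p`, unmethylated `1−p`):
`HME = Σ_i [p_u log p_u + p_m log p_m] / (N log ½)`.
Natural logs are used; the normalization makes the base cancel. Betas of
exactly 0 or 1 are handled by the `0·log 0 = 0` convention rather than
clipping, so the fully-methylated profile gives exactly 0. The statistic
is symmetric under `p → 1−p`, maximal (1) when every marker sits at 0.5,
and additive: the HME of a concatenation is the length-weighted mean of
the parts — which is why the global HME equals the probe-count-weighted
mean of the 12 stratum HMEs. Empty strata are reported as missing, never
as zero.

A second, read-level formulation is included as a reference oracle:
`H = −(1/n_cpgs) Σ_k f_k log2 f_k` over methylation-haplotype
frequencies, in base 2 so that a 4-CpG locus covered by two pure alleles
at 50/50 gives exactly 0.25. The two formulations answer different
questions (marginal disorder vs. allele-pattern disorder) and are not
interchangeable.

# Association scans

DMP detection compares, per probe, the linear model with the variable of
interest against the intercept-only null by F-test, with Bonferroni
adjustment across probes and a DMP threshold of q < 0.1. The adjusted
p-value is reported as the q-value — no FDR procedure is substituted. The
scan accepts a numeric covariate or a factor (so the same machinery runs
`CpG ~ age`, `CpG ~ Accel` and `CpG ~ subtype`), is invariant to affine
rescaling of the covariate, and returns `F = 0, p = 1` for constant
probes while rejecting constant covariates. Covariate-adjusted DMP models
(e.g. adding purity or study) are deliberately not the default: the bare
model is the stated procedure, and adjustments change the question being
asked.

Functional methylation tests each promoter CpG (±1500 bp of the TSS)
against its annotated gene's expression by Spearman correlation,
t-approximation for n ≥ 10 and the exact distribution below, average
ranks on ties. A probe annotated to several genes is tested once per
gene. The adjustment for this scan is not pinned down by convention, so
the default is Benjamini–Hochberg with a flag for Bonferroni; the
functional call requires both q < 0.05 and ρ ≤ −0.3 (boundary
inclusive — a measure-zero choice for continuous data, documented for
determinism).

Gene-set enrichment is the upper-tail hypergeometric test per set with
Bonferroni adjustment across sets (significant at adjusted p ≤ 0.1).
Real curated collections are out of scope; the analysis drivers build
seeded synthetic collections (random sets plus a spiked set) so the
machinery is exercised with a known answer.

# Sample-level molecular state

- **Copy number.** Per-probe log2 of combined methylated + unmethylated
  intensity over a reference total, median-centered per sample (the exact
  within-sample normalization of array intensities is not standardized;
  median-centering is the default here). Segmentation is circular binary
  segmentation written for this package: the candidate change is the arc
  maximizing the normalized mean difference between arc and complement,
  accepted when its permutation p (probes shuffled within the segment,
  `(1+b)/(1+B)` estimator) falls below α = 0.01, recursing into
  subsegments; defaults n_perm = 1000, min_width = 3; segmentation never
  crosses chromosomes and segments tile the probes exactly. No hybrid
  p-value speed-ups are used.
- **CDKN2A homozygous deletion.** A Gaussian mixture on per-sample mean
  log-ratios of CDKN2A probes. BIC chooses between one and two
  components under a common variance — the equal-variance model avoids
  the degenerate spike components the unequal-variance fit produces at
  cohort-scale n — and the call degenerates to "no HD" when one component
  is preferred or the means are separated by less than one component
  standard deviation. HD = posterior > 0.5 for the lower component.
- **Purity.** Least-squares mixing weight of the observed profile between
  tumor and normal reference profiles, over informative probes
  (reference difference > 0.3, at least 50 of them), clipped to [0, 1].
  The reference profiles are explicit inputs; re-deriving them from
  external consortia is out of scope.
- **MGMT-STP27.** The two-probe logistic model with the published cutoff
  0.358 (boundary classifies methylated). The model coefficients are a
  required input — they are not printed in the source literature and are
  not re-estimated here; the synthetic generator emits its own generating
  coefficients in the truth record.
- **Clustering.** G-CIMP via Ward (ward.D2) on Euclidean distances, cut
  at k = 2, flagging the cluster with the higher mean methylation over
  the most variable probes. Subtype assignment is a nearest-centroid
  surrogate for external random-forest classifiers, with ties resolved to
  the first centroid in column order (tolerance-aware, so exact
  equidistance is deterministic).

# Outcome statistics

- **ADONIS** delegates to `vegan::adonis2` on Euclidean distances with
  free label permutation and a seeded stream; on univariate data the R²
  reduces exactly to one-way ANOVA R², which the tests assert to 1e-10.
- **Variation partitioning** fits the 7 redundancy models (A, B, C, AB,
  AC, BC, ABC) on the multivariate response by least squares and applies
  inclusion–exclusion. Raw-R² fractions sum exactly to the joint R²
  (asserted to 1e-10); Ezekiel-adjusted fractions are reported alongside
  and are the better summary when block ranks differ — the raw/adjusted
  pair is always reported together. Shared fractions may be negative
  under suppression or collinearity; they are reported, not clipped.
- **HC3 Wald tests** use the sandwich covariance
  `(XᵀX)⁻¹ Xᵀ diag(e²/(1−h)²) X (XᵀX)⁻¹` and an F reference on
  (q, n−p) df. Saturated design points (leverage 1) are an error, not a
  silent NaN. The analysis drivers follow the model-comparison
  convention: main terms are tested in the additive two-way model and the
  interaction in the full model — testing a main effect in the presence
  of its interaction would only measure the reference-cell contrast.
- **Cox models** contain exactly treatment, MGMT, one covariate and
  treatment × MGMT, fit by maximum partial likelihood with Efron tie
  handling (the tie method is not dictated by the outcome model itself;
  Efron is the less biased default). MGMT enters with the unmethylated
  state as reference so the reported hazard ratios describe the
  methylated modality.
- **CMH** is the Mantel–Haenszel chi-squared on 2×2×K tables, continuity
  correction off by default, closed form for K = 1; zero-margin strata
  carry no information and are dropped with a warning.

# The synthetic cohort generator

The generator is first-class, tested code: its defaults describe the
cohort the analysis targets — an adult IDHwt GBM trial population, ages
27–85, acceleration averaging 36.81 years (sd 23.99) with
subtype-dependent shifts (highest in RTK II), subtypes ~31/20/49%
MES/RTK I/RTK II, four study batches, purity 0.45–0.99, a protective
acceleration effect of log-HR −0.0147 per year and a treatment × MGMT
interaction of log-HR −1.3 on an exponential baseline (0.55/year,
censoring 0.15/year, times reported in months). Each logical block
(annotation, subjects, clock, DMPs, expression, noise, batch, CNV,
survival) draws from its own stream derived from the master seed, so
enlarging one block never perturbs another and identical seeds give
bit-identical cohorts.

Structural choices:

- **Clock probes** are `β_j = b_j + c_j·F(age + accel)` with weights
  `w = c/Σc²`, so the generating clock inverts exactly on noiseless data.
  This makes the clock-probe block rank-2 by construction: the generating
  coefficients are *not* identifiable from noiseless training data (any
  weights with `Σ w c = 1` predict perfectly), which is why the
  clock-training recovery test builds an independent random design
  instead of using the cohort's clock probes.
- **Noise** is specified as a beta-scale sd but applied on the logit
  scale via the delta method (`sd_logit = sd/(μ(1−μ))`), keeping betas in
  (0, 1) without truncation and preserving the monotone age signal.
- **Probe-class baselines** make promoter-island betas bimodal (ordered)
  and open-sea betas intermediate (disordered), which is what drives the
  stratified entropy contrast the entropy tests assert.
- **Purity** mixes each tumor profile linearly with one fixed synthetic
  normal-brain profile. At clock probes the normal profile is set to the
  clock's own value at the mid-cohort age — normal tissue shows no
  acceleration — so impurity dilutes the acceleration signal toward zero
  rather than randomizing it. Observed cohort-mean acceleration is
  therefore *attenuated* relative to the planted truth (≈26 vs ≈37 years
  on the default seed); the truth record keeps the planted values for
  exact comparisons.
- **MGMT probes** are driven by the true MGMT state through generating
  STP27 coefficients stored in the truth record; the normal-brain profile
  is fixed unmethylated at these probes so purity mixing cannot flip
  calls.
- **CNV** is planted in the intensity pair (chr7 gain, chr10 loss,
  CDKN2A at ×2^−3.32 for the HD subset), not in the betas.

What the generator does **not** emulate: co-methylation/LD structure
beyond the planted blocks, realistic genomic probe spacing, array
chemistry artifacts (noob/dye/RUV are out of scope — data enter already
normalized), cellular heterogeneity beyond a single normal profile, and
non-proportional hazards. Passing tests therefore demonstrate that the
statistical machinery recovers what was planted under the stated noise
model — not that it would be robust to every artifact of real arrays.

# Problem sizes and tolerances

The analysis drivers run at 10,000 probes × 200 samples with 353 clock
probes — large enough for every stage to behave asymptotically while the
whole workflow completes in minutes. The test suite uses smaller cohorts
(600–5,200 probes, 25–300 samples) chosen per property: exact identities
are asserted at 1e-8–1e-12; calibration bands for null simulations follow
binomial Monte-Carlo widths at the stated replicate counts; recovery
thresholds (recall ≥ 0.8, accuracy ≥ 95/98%) sit well below the power the
planted effect sizes imply. Permutation p-values always use the
`(1+b)/(1+B)` estimator so a permutation test can never report zero.

# Known limitations

- The CBS permutation test is O(m²) per segment per permutation;
  chromosomes with many thousands of probes would need the established
  hybrid approximations, which are deliberately not implemented.
- Variation partitioning is least-squares redundancy analysis on the raw
  response; distance-based variants are not provided.
- The functional scan tests promoter CpGs only; gene-body or enhancer
  methylation–expression coupling is out of scope.
- `wald_hc3` fits by OLS; generalized linear responses are not supported.
- The nearest-centroid subtype surrogate requires centroids on the
  matrix's probes; it does not re-derive centroids from reference data.
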