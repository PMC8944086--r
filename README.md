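# methage

DNA methylation age acceleration, entropy and outcome analysis for
IDH-wild-type glioblastoma-style 450k cohorts.

## The problem

IDH-wild-type glioblastoma (GBM) affects adults across a wide age range,
and treatment choices — particularly for elderly patients — hinge on
biological rather than chronological age and on the MGMT promoter
methylation status. The tumor methylome carries several layers of
age-related and tumor-biology signal that can be quantified from a single
450k-style array:

- **DNAm age and age acceleration.** An epigenetic clock predicts an age
  from the betas of a fixed set of clock CpGs through a penalized linear
  model on a transformed age scale
  (`F(a) = log(a+1) − log(adult+1)` below the adult knot, linear above).
  *Age acceleration* is `Accel = DNAm age − age` in years; in GBM it
  averages decades, and higher acceleration associates with better outcome.
- **Methylation entropy (HME).** Per sample, over N CpGs with methylated
  fraction `p_i`:
  `HME = Σ_i [p_u log p_u + p_m log p_m] / (N log ½)`, with `p_m = p_i`,
  `p_u = 1 − p_i` and `0·log 0 = 0` — 0 for fully ordered profiles, 1 at
  maximal disorder. Computed globally and within the 12 strata formed by
  CpG-island relation (Island, shores, shelves, open sea) × promoter status.
- **Differential and functional methylation.** Probe-wise linear-model
  F-tests (`CpG ~ age`, `CpG ~ Accel`) with Bonferroni adjustment (DMP at
  q < 0.1); promoter CpGs (±1500 bp of the TSS) negatively rank-correlated
  with their gene's expression (q < 0.05 and Spearman ρ ≤ −0.3) are
  *functional*; hypergeometric gene-set enrichment with Bonferroni ≤ 0.1.
- **Sample-level molecular state.** MGMT-STP27 (two-probe logistic model on
  the M-values of cg12434587/cg12981137, methylated at probability
  ≥ 0.358), methylation-based purity (least-squares tumor/normal mixing
  weight), copy-number log-ratios from combined probe intensities with
  circular binary segmentation, CDKN2A homozygous-deletion calls by a
  Gaussian mixture, Ward/Euclidean G-CIMP clustering, and a
  nearest-centroid subtype surrogate (MES / RTK I / RTK II).
- **Outcome statistics.** PCA, permutation MANOVA (ADONIS) on Euclidean
  distances, three-block variation partitioning of the entropy table,
  Wald F-tests with HC3 sandwich covariance, Cox models with a
  treatment × MGMT interaction, and the Cochran–Mantel–Haenszel test.

Because the cohorts such analyses target are controlled-access or
large downloads, the package ships a seeded **synthetic cohort generator**
that plants every structure listed above together with a ground-truth
record, so the full workflow — and its tests — run anywhere in minutes.

## Worked example

```r
library(methage)

cfg <- cohort_config(n_samples = 200, n_probes = 10000,
                     n_clock_probes = 353, seed = 1234)
co  <- generate_cohort(cfg)

betas <- filter_probes(co$betas, co$annotation,
                       detection_p = co$detection_p, p_thresh = 0.01)
M     <- combat_adjust(beta_to_m(betas), co$sample_sheet$batch,
                       covariates = data.frame(age = co$sample_sheet$age))

dnam  <- predict_dnam_age(m_to_beta(M), co$truth$clock)
accel <- age_acceleration(dnam, co$sample_sheet$age)
mean(accel)   # observed acceleration, attenuated by tumor purity
#> [1] 25.92

res <- dmp_scan(M, accel)
sum(res$is_dmp)          # CpGs associated with acceleration at q < 0.1
hme(rep(1, 100))         # fully methylated profile: exactly 0
#> [1] 0
read_haplotype_entropy(c(0.5, 0.5), 4)  # two pure 4-CpG alleles at 50/50
#> [1] 0.25
```

The full analysis is organised as numbered drivers under `analysis/`
(run them in order from the repository root):

```sh
Rscript analysis/01_simulate.R       # cohort + ground truth fixtures
Rscript analysis/02_preprocess.R     # filtering, M-values, ComBat
Rscript analysis/03_clock_accel.R    # DNAm age, acceleration, baseline table
Rscript analysis/04_entropy.R        # HME strata + variation partitioning
Rscript analysis/05_association.R    # DMP / functional / enrichment scans
Rscript analysis/06_genomic_state.R  # MGMT, purity, CNV, subtype
Rscript analysis/07_outcome.R        # HC3 Wald tests, Cox models, CMH
```

Each driver narrates what it finds and writes its tables under `results/`.
On the default seed the workflow reports, among others: batch R² collapsing
from 0.053 to 0.0011 (p = 1.00) after ComBat while the subtype R² (0.108,
p = 0.01) survives; 50/50 planted acceleration-DMPs recovered at q < 0.1;
an acceleration hazard ratio of 0.990 per year (p = 0.037) with a
treatment × MGMT interaction HR of 0.296 (p = 0.0012); and 100%
agreement of the CDKN2A homozygous-deletion and subtype calls with the
planted truth.

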