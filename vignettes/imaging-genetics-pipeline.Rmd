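---
title: "Discovery, refinement and validation of SNP-imaging association with weighted RV tests and bootstrap-enhanced sparse CCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovery, refinement and validation of SNP-imaging association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvscca)
```

## The problem

Imaging-genetics studies of Alzheimer's disease ask whether common genetic
variation is associated with the *rate* at which brain structure
deteriorates. Two features make this statistically awkward. First, the
genomic block is very high-dimensional relative to the sample (tens of
thousands of SNPs, a few hundred subjects), with weak, diffuse effects and
strong local correlation (linkage disequilibrium). Second, cohorts such as
ADNI are case-control by design: mildly impaired and demented subjects are
heavily oversampled relative to their population frequency, so unweighted
sample covariances do not estimate population associations.

`rvscca` implements a three-stage answer:

1. **Discovery.** A single global test of linear association between the
   adjusted minor-allele-count matrix $X$ ($n \times p$) and the adjusted
   atrophy-rate matrix $Y$ ($n \times q$), using a weighted RV coefficient
   with a permutation null.
2. **Refinement.** Bootstrap-enhanced sparse canonical correlation
   analysis: soft-thresholded rank-1 approximation of the weighted
   cross-correlation matrix, refit across stratified bootstrap resamples,
   yielding a variable importance probability (VIP) per SNP and liberal /
   stringent refined sets (VIP ≥ 0.5 and ≥ 0.9).
3. **Validation.** The refined SNP sets are tested again with the RV
   permutation test in an independent sample, and the statistic is
   decomposed into per-SNP scores.

## Endophenotypes: rates of change from mixed models

Each region of interest (ROI) $j$ is modelled longitudinally:

$$Y_{ijt} = \beta_{0j} + \beta_{1j}\,\mathrm{MCI}_i + \beta_{2j}\,\mathrm{AD}_i
  + \beta_{3j} t + \beta_{4j}\,\mathrm{MCI}_i\, t + \beta_{5j}\,\mathrm{AD}_i\, t
  + \gamma_{1ij} + \gamma_{2ij} t + \varepsilon_{ijt},$$

with $t$ in months, CN as reference group, a bivariate Gaussian random
intercept/slope pair with unstructured covariance, and independent
Gaussian noise. Fits use REML via `lme4` (`fit_roi_lmm()`); the subject's
predicted rate of change is the group slope plus the conditional mode
(empirical BLUP) of the slope deviation,
$\hat\beta_{3j} + \hat\beta_{4j}\mathrm{MCI}_i + \hat\beta_{5j}\mathrm{AD}_i
+ \hat\gamma_{2ij}$ (`predict_rates()`). A non-convergent REML fit falls
back to ML and then to a random-intercept-only model, flagged; singular
fits are flagged but retained — the conditional modes remain usable and
excluding those subjects would bias the later multivariate stage.

## Sampling weights and confounder adjustment

With assumed population prevalences $p_D$ and sampled group counts $n_D$,
each subject in group $D$ receives weight $w_D \propto p_D / n_D$,
standardized so the weights sum to $n$ (`compute_weights()`). The AD
prevalence itself is derived from census-style inputs and rounded to the
nearest half percent, ties away from zero (`derive_prevalence_ad()`);
the rounding rule matters only in knife-edge cases and is documented
rather than load-bearing.

Population structure is proxied by classical (Torgerson) MDS on the
identity-by-state distance matrix (`ibs_distance()`, `mds_coordinates()`;
10 coordinates by default, following the common ten-axes convention for
stratification adjustment). Both data blocks are residualized on an
intercept, the coordinates, and APOE genotype dummies by weighted OLS
(`weighted_residualize()`); APOE is adjusted even though the MDS
coordinates are present because it can carry stratification signal over
and above them, and it is the dominant genetic risk factor. The reference
APOE category is the most frequent genotype — the coding is arbitrary and
this choice keeps dummies sparse. Residual columns are then standardized
to weighted mean 0 / variance 1 (`adjust_cohort()`), so the SCCA stage
operates on a weighted cross-*correlation* matrix. Standardizing after
(not before) residualization keeps the columns exactly weighted-centered;
the alternative order differs only by column scalings and is not
separately exposed.

## The weighted RV test

With weights standardized to sum to $n$, the weighted cross-covariance is

$$S_{X_k Y_l} = \frac{1}{n}\sum_i w_i\,(x_{ik}-\bar x_k^w)(y_{il}-\bar y_l^w),$$

which reduces exactly to the divisor-$n$ sample covariance at unit
weights, and

$$RV = \frac{\sum_{k,l} S_{X_kY_l}^2}
 {\sqrt{\sum_{k,l} S_{X_kX_l}^2\; \sum_{k,l} S_{Y_kY_l}^2}} \in [0,1].$$

The permutation null permutes the rows of $Y$ *together with their
weights* against fixed $X$ rows (`rv_test()`). How the two weightings
should combine inside one covariance is genuinely underdetermined; this
package uses one coherent weighting per permuted dataset — the permuted
weights define the weighted means and covariances of both blocks — which
keeps every permuted statistic a valid weighted RV of a relabelled
dataset. The p-value uses the add-one estimator
$(1 + \#\{RV^{(b)} \ge RV_{obs}\})/(1+P)$, which cannot be zero.
Internally the statistic is computed from $n \times n$ weighted Gram
matrices, making $P = 10^4$ permutations tractable when $p \gg n$; the
Gram route is tested against the explicit covariance-block formula.

Per-SNP contributions to the RV numerator, $\sum_j S_{ij}^2$, normalized
to mean 1, rank the SNPs driving a validation association
(`snp_scores()`).

## Sparse CCA, penalty choice, bootstrap VIPs

`scca_fit()` alternates $a \leftarrow \mathcal{S}(Kb, \lambda_u)/\|\cdot\|_2$
and $b \leftarrow \mathcal{S}(K^\top a, \lambda_v)/\|\cdot\|_2$, where
$\mathcal{S}$ is soft-thresholding; with both penalties zero this is
power iteration for the leading singular pair of $K$. Defaults:
$\lambda_v = 0$ (a sparse SNP combination against a non-sparse imaging
combination), `tol = 1e-6` on the maximum coefficient change,
`max_iter = 1000`, $b$ initialized at the leading right singular vector,
sign fixed so the largest $|a_k|$ is positive. A fully thresholded model
is returned flagged empty, not as an error, because bootstrap replicates
may legitimately produce it. The alternating updates ascend the
*penalized* objective $a^\top K b - \lambda_u\|a\|_1 - \lambda_v\|b\|_1$;
the unpenalized correlation can decrease slightly as the solution
sparsifies, which is why the monotonicity check is stated on the
penalized form.

Cross-validated penalty selection (`cv_select_penalty()`, grid
$\{0\} \cup \{10^{-4} + 0.0005k\} \le 0.1$, ties to the smaller penalty)
is provided mainly to demonstrate its failure mode: with diffuse weak
signal the prediction criterion retains essentially all variables. The
operational choice is therefore `calibrate_penalty_to_fraction()`, which
bisects $\lambda_u$ until about 10% of SNPs carry nonzero coefficients —
the fraction of markers plausibly associated in a targeted region — and
`bootstrap_vip()` then resamples subjects with replacement *within each
diagnostic group* (preserving the biased design), recomputes the weighted
cross-correlation, refits at the fixed penalty, and reports
$VIP_k$ = selection frequency. Resampled-monomorphic SNP columns are
zeroed for that replicate. The priority (VIP ≥ 0.5) and top-hit
(VIP ≥ 0.9) sets use inclusive thresholds (`select_refined_sets()`).

## Gene-set stage

Per-SNP exclusion probabilities $VEP = 1 - VIP$ play the role of
p-values. The gene score is the *second-smallest* VEP among a gene's SNPs
(20 kb padding), guarding against long genes; single-SNP genes fall back
to their only VEP and are flagged. Scores are mapped to z-scores via
$-\Phi^{-1}(VEP)$ after clipping to $[1/2B, 1-1/2B]$ — the upstream
tool's internal transform is not public, so the probit map is the
package's own documented choice. The set statistic is the
Efron–Tibshirani maxmean, restandardized against random same-size gene
sets by default (an all-genes asymptotic reference is available behind a
flag, since the canonical reference distribution is ambiguous).
Significance comes from re-running the refinement under Y-permutation
with a scaled-down bootstrap count, with Benjamini–Hochberg adjustment
and a deliberately liberal FDR threshold (0.8) because this stage is a
screen, not a confirmatory test.

## The synthetic cohort generator

`simulate_cohort()` generates the structure the analysis assumes: three
diagnostic groups sampled with bias (defaults 179/296/157 CN/MCI/AD
against prevalences 0.875/0.05/0.075), 56 ROI trajectories at months
0/6/12/18/24 following the mixed model above, a sparse causal SNP subset
shifting atrophy slopes, APOE genotypes tilted toward ε4 in impaired
groups, and a latent ancestry coordinate that shifts both allele
frequencies and ROI baselines — so the MDS + APOE adjustment has genuine
confounding to remove. Genotype missingness is completely at random
(the real mechanism of sporadic genotyping failure is not modelled), and
phenotype dropout never removes a subject's last follow-up, preserving
the longitudinal table's invariant.

**LD model.** Within a block, each SNP copies a shared founder genotype
(drawn from the Hardy–Weinberg law at the block's MAF) per subject with
probability $\rho^{1/4}$, and otherwise redraws independently from the
same law. This gives pairwise within-block genotype $r^2 \approx \rho$
directly and exact independence at $\rho = 0$. A latent-Gaussian
threshold copula was considered first, but thresholding attenuates the
genotype correlation well below the latent one (to $r^2 \le$ ~0.7 even
at latent correlation 0.95, worse at low MAF), which makes the
correlation parameter an indirect dial; the copying model keeps the
knob's meaning honest. Within-block SNPs share one MAF, as tightly linked
real variants essentially do. Default $\rho = 0.85$ in blocks of 10.

Default effect and variance scales are chosen to look like
cortical-thickness trajectories: baselines near 2.5 mm, CN/MCI/AD group
slopes near −0.002/−0.005/−0.009 mm/month, random-intercept variance
0.04, random-slope variance $10^{-5}$, noise variance 0.0025, causal
effect −0.0015 mm/month per minor allele. One integer seed drives all
sub-generators through a documented splitting scheme
(`seed + 1000003 k`).

What passing tests on this generator do **not** show: robustness to
non-Gaussian random effects, informative dropout, genotyping batch
effects, fine-scale ancestry, or LD patterns beyond exchangeable blocks.
The generator is a stand-in — the real genotype-generating process is
unknowable — and every distributional choice above is labelled as such.

## Numerical and scale choices

* HWE quality control uses the conditional exact test (enumeration of
  heterozygote counts given allele counts, two-sided by probability
  ordering), the behaviour class of standard GWAS tooling; tested in all
  retained subjects by default, configurable to controls only.
* QC order is fixed: sex chromosomes → call rate (≥ 95%) → MAF (≥ 5%) →
  HWE ($p \ge 10^{-6}$); filters are idempotent.
* Missing genotypes after QC are filled with the SNP's rounded mean
  count; the package deliberately has no reference-panel imputation, and
  downstream treats filled genotypes as known.
* Region restriction uses closed Mb intervals and 1-based positions; the
  published Alzheimer's-disease linkage-region table ships in
  `extdata/alzgene_linkage_regions.csv`.
* LD blocks are grown greedily from the left-most unassigned SNP, adding
  a SNP only if its $r^2$ with *all* current members exceeds 0.7 —
  deterministic, and equivalent to the all-pairs description on the
  configurations tested against brute force.
* MDS eigenvector signs are fixed by making the largest-magnitude
  loading positive; requesting more dimensions than the configuration's
  rank pads with zero columns and warns.
* Test and example problem sizes are deliberately desk-scale: cohorts of
  100–630 subjects, 20–300 SNPs, 1–6 ROIs, $P$ of 99–199 permutations and
  $B$ of 200–500 bootstrap replicates. These sizes are where the checked
  properties (type-I error, VIP separation, calibration) are already
  stable; production analyses should scale $P$ and $B$ up (the study
  design behind this package used $P = 10^4$ and $B = 10^5$).

## Known limitations

The bootstrap resamples already-adjusted rows rather than redoing the
confounder regression inside each replicate (configurable in principle,
one order of magnitude cheaper, slightly anticonservative for the VIPs).
The gene-set stage's restandardization reference is a package choice, not
a reproduction of the upstream tool's internals. Subject-level QC
(relatedness, sex checks, outlier removal) is accepted as an input
exclusion list rather than implemented. Binary PLINK `.bed` is not
parsed; use `.ped`/`.map` text or a delimited count matrix.
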