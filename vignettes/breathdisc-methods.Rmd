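---
title: "Methods: breath VOC discrimination from GC-tof-MS chromatograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath VOC discrimination from GC-tof-MS chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathdisc)
```

## The problem

Exhaled breath carries hundreds of volatile organic compounds (VOCs) whose
relative abundances shift with pulmonary disease. Untargeted breathomics
measures them by thermal desorption GC-tof-MS: each subject yields a
chromatogram — a scan-time × m/z intensity matrix (nominal masses m/z
35–350, 5 scans/s). `breathdisc` implements a complete analysis for
three-group studies of this kind (healthy controls and two interstitial
lung disease phenotypes, an IPF-like and a CTD-ILD-like group): chromatogram
conditioning, peak quantification, Random-Forest discrimination with
deterministic Duplex validation, hierarchical fusion of the three binary
classifiers, confounder testing by regularized MANOVA, and canonical
correlation of the discriminatory VOCs against lung-function parameters.

Because raw clinical breath data are rarely shareable, the package is built
around a synthetic-cohort generator with a complete ground-truth ledger.
Every claim the test suite makes about the pipeline is a parameter-recovery
or calibration statement against that ledger.

## The synthetic cohort model

One subject's chromatogram is rendered as

```
intensity(t, mz) = baseline(t, mz)
                 + sum_k  a_k * N(t; apex_k + jitter, width_k) * s_k(mz)
```

then multiplied by `max(1 + noise_cv * eps, 0)` (heteroscedastic,
multiplicative noise, `eps ~ N(0,1)`) and by a per-sample dilution factor
`exp(N(0, dilution_sd))`. Compound `k` has a Gaussian elution profile (area
equals its abundance `a_k` at unit scan spacing) and a unit-sum mass
spectrum `s_k` with 5–15 nominal-mass lines; lines are shared between
compounds with probability 0.2 so spectral-correlation peak merging faces
genuinely confusable spectra. Retention apexes keep a guaranteed minimum
spacing; widths are drawn U(3, 6) scans, i.e. FWHM 1.4–2.8 s at 5 scans/s —
typical capillary-GC peak widths — which also keeps more than half of the
trace peak-free so that the MAD-based noise scale used in peak picking
behaves sensibly on clean data.

Log abundances are `base_k + sigma_b * e`, with `sigma_b = 0.4`
(between-subject SD on the natural-log scale, i.e. roughly ±50% abundance
variation between subjects — a realistic magnitude for breath VOCs).
Discriminatory compounds receive mean shifts of `effect_size * sigma_b`
with random signs: a set for control↔A, a set for control↔B, and a set for
A↔B (carried by group A; overlaps between sets are allowed, as shared
discriminators occur in practice). The A↔B set is additionally coupled,
with correlation `clinical_coupling` (default 0.7), to a latent severity
variable that also loads on two clinical columns (total lung capacity and
six-minute walk distance by default). Clinical tables carry age, sex,
smoking and eight lung-function columns with group-typical means and SDs;
lung function is absent (NA) for controls, as in referral-based control
groups without pulmonary work-up.

Default cohort sizes are 51/53/51 (controls / IPF-like / CTD-like). The
default acquisition is 3300 scans (an 11-minute equivalent of the
instrument's 33-minute run, preserving peak density); `run_seconds = 1980`
gives the full 9900-scan geometry. The generator is fully deterministic
given `(config, seed)`, per-sample render streams are derived from the
master seed, and `synthetic_truth` records everything that was planted.

The generator emulates the statistical structure the analysis assumes —
multiplicative noise, smooth drift, dilution, retention jitter, planted
group effects, latent clinical coupling. It does not emulate co-eluting
isomers, detector saturation, column bleed chemistry, or batch drift across
measurement days; passing tests therefore demonstrate correctness of the
algorithms under the stated model, not robustness to every artifact of real
instruments.

## Preprocessing chain

Stages run in a fixed, stage-checked order; each run carries a `stage`
marker and calling a stage out of order is an error.

1. **Log transform** `ln(1 + x)`. Multiplicative detector noise becomes
   approximately homoscedastic, which is what the wavelet thresholding and
   least-squares smoothing downstream assume. `1 + x` because chromatograms
   contain exact zeros.
2. **Wavelet denoising.** Each channel trace is decomposed with a
   periodized orthonormal Daubechies wavelet (db4, 2 levels by default);
   detail coefficients are soft-thresholded at the universal threshold
   `sigma_hat * sqrt(2 log n)` with `sigma_hat = MAD(finest details)/0.6745`.
   The DWT is implemented in the package (hard-coded db2/db4/db8 filters,
   perfect reconstruction tested to machine precision).
3. **Baseline correction** by asymmetric least squares: per channel,
   minimize `sum w_i (y_i - z_i)^2 + lambda * sum (d2 z)^2` with weights
   `p` where `y > z` and `1 - p` otherwise (defaults `lambda = 1e5`,
   `p = 0.001`, 10 iterations). At these grid sizes the dense-knot B-spline
   formulation and the discrete second-difference penalty are numerically
   equivalent; the pentadiagonal system is solved by a banded LDLᵀ in
   compiled code. Corrected signal is clipped at zero.
4. **Alignment.** The scan-wise median TIC is the reference; each run's TIC
   is cut into 100-scan segments, the integer shift in ±25 scans maximizing
   Pearson correlation with the reference is found per segment (ties prefer
   the smaller shift, so flat segments stay put), shifts are linearly
   interpolated between segment centres and applied to every channel by
   linear interpolation. Shifts at the search bound are capped with a
   warning.
5. **Probabilistic quotient normalization.** Dilution acts multiplicatively
   on measured intensities, so the aligned runs are first returned to the
   intensity scale (`expm1`); the reference is the scan-wise median TIC
   restricted to scans above its 25th percentile, each run's median
   run/reference quotient is its dilution estimate, and the run is divided
   by it. Re-normalizing against the same stored reference is exactly a
   no-op. Downstream areas are therefore dilution-corrected intensities —
   physical quantities, not areas of a log signal.
6. **Peak picking** on the cohort-mean TIC: local maxima with topographic
   prominence at least `5 * sigma_hat` (`sigma_hat` from the MAD of the
   first-differenced trace), bounds at the flanking TIC minima, shared by
   all samples so the participants × peaks matrix is rectangular.
   Per-sample areas are trapezoidal integrals of that sample's TIC over the
   shared bounds; the consensus spectrum is the TIC-weighted mean spectrum
   at apex ± 1 scan.
7. **Peak merging.** Peaks whose consensus spectra correlate at ≥ 0.95 with
   apexes within 15 scans merge greedily in descending correlation order
   (ties to the earlier apex); areas add, spectra combine area-weighted.

A deliberate accuracy note: PQN estimates dilution from the median
compound-abundance ratio, so when compositions genuinely vary between
subjects the quotient of an undiluted sample deviates from 1 by roughly
`sigma_b / sqrt(n_compounds)` (2–3% at 50 compounds). This per-sample
scalar bounds the achievable per-compound rank fidelity of recovered areas:
noiseless recovery is essentially perfect (median per-compound correlation
with truth > 0.99, areas within ~1% of truth) but literal rank identity
across all samples is not a property any faithful PQN implementation can
deliver. The acceptance suite asserts the > 0.99 recovery bar together with
exact feature-count recovery.

## Discrimination

- **Duplex split** (per class, Euclidean distance on z-scored features):
  the two mutually farthest samples seed TRAIN, the two farthest remaining
  seed TEST, then the sets alternately (TRAIN first, the original
  ordering of the method) receive the unassigned sample farthest from
  them until TEST holds `round_half_up(0.2 * n_class)`; the remainder
  trains. Ties break to the smaller sample index, so the split is fully
  deterministic — 53/51 groups give 42+41 train and 11+10 test.
- **Forest.** 1000 trees, `mtry = floor(sqrt(p))`, mandatory seed.
  OOB error is the internal validation error (accuracy = 1 − error);
  importance is unscaled permutation importance (mean decrease in OOB
  accuracy). Proximity — the fraction of trees in which two samples share a
  terminal node — is computed over all samples of the split, with the
  train–train block restricted to trees where both samples were out of
  bag. The OOB restriction matters: fitted-tree proximities between
  training samples encode the memorized labels, so even a label-shuffled
  cohort would look separated in the proximity-PCA; OOB proximities stay
  flat under the null, which the calibration tests verify.
- **VOC selection.** The importance cut-off that practitioners draw by eye
  below the visibly dominant VOCs is made reproducible as the largest
  consecutive gap of the
  *log*-importance ranking within the top 50, restricted to cut positions
  keeping only features ≥ 10% of the top importance, with values clamped at
  max/1000 (permutation importances may be ≤ 0 in the noise tail).
  Importance spectra decay multiplicatively, so the signal/noise boundary
  is a fold-change break; the largest *absolute* drop usually sits between
  ranks 1 and 2 and would select almost nothing. If no gap exceeds twice
  the median log-gap the ranking has no elbow and a fixed count is taken
  with a warning; all-nonpositive importances are an error.
- **Validation.** The final forest is refit on TRAIN restricted to the
  selected VOCs and applied once to the Duplex TEST set: accuracy,
  sensitivity, specificity at vote threshold 0.5 (positive class = the
  disease class, or the first of the pair for the disease–disease model),
  ROC over all vote thresholds, trapezoidal AUC (equal to the Mann–Whitney
  form, tested against exhaustive pair counting). Both OOB and test
  metrics are reported side by side, since studies of this design are
  often ambiguous about which one headline numbers refer to.
- **Proximity PCA.** Classical scaling of `D = 1 - proximity`
  (`B = -1/2 J D² J`, eigendecomposition, scores = eigenvectors ×
  √eigenvalues; negative eigenvalues truncated at zero with a logged
  count). Out-of-sample points enter by the Gower extension
  `score_k = -(d² - rowmeans(D²)) · v_k / (2 sqrt(lambda_k))`, which
  exactly reproduces the embedding coordinates of held-out model samples.
  One wording note: descriptions of RF proximity occasionally invert the
  convention; here, as in the standard formulation, *large* proximity
  means *similar*.

## Fusion

Each of the three binary models contributes its first `k = 2`
proximity-PCA coordinates for every cohort sample (training scores for its
own samples, Gower projections for the rest); the concatenated 6-dim scores
get a final PCA whose first three components are the three-group view. The
mean silhouette width of the group labels in that view is the separation
summary. A direct multi-class forest is deliberately out of scope — the
fusion of validated binary models is the design point. The exact
construction of fused scores (components per model, rescaling) is an
interpretation; concatenate-then-PCA is the package's documented choice.

## Inference statistics

- **CCA.** Both blocks are `ln(1+x)`-transformed and column-standardized;
  canonical directions solve the generalized eigenproblem with ridge
  `1e-3 · I` on both within-block correlation matrices; `rho1` is the
  correlation of the first canonical variate pair (unit-variance variates
  are the two plot axes). Significance is a permutation test (rows of the
  clinical block permuted; `p = (1 + #{perm ≥ obs}) / (B + 1)`), chosen
  because it is distribution-free and consistent with the pipeline's
  resampling style.
- **Clinical subset selection** is greedy forward selection over the eight
  lung-function columns. Candidates are ranked by permutation-corrected
  `rho1` (observed minus mean permuted), where the inner null is
  *conditional*: only the candidate column is permuted, already-selected
  columns keep their pairing — this prices exactly what an uninformative
  column would add and does not mask a second genuinely coupled column. A
  step is admitted only if its `rho1` exceeds the `1 - 0.05/m` conditional
  permutation quantile (`m` = candidates examined that step); without the
  admission test the maximum over candidates admits a spurious column in
  most unrelated datasets, and without the Bonferroni share a third column
  rides along in about a third of coupled datasets.
- **Regularized MANOVA** for confounders: shrinkage Wilks ratio
  `det(W + gamma I) / det(T + gamma I)` with `gamma` from a
  Ledoit–Wolf-style rule on the pooled within-group covariance (estimated
  once on the observed grouping and reused across permutations so the
  statistic is comparable); significance by permutation of the factor
  labels; continuous factors are dichotomized at the median (logged). At
  small dimension and vanishing shrinkage the permutation p-value agrees
  with a permutation Hotelling T², which the tests check. Type-I error is
  verified at 0.05 ± 0.03 over 200 null replicates.
- **Univariate battery**: Welch t-tests (a pooled-variance switch exists)
  with Benjamini–Hochberg adjustment across the battery and a Lilliefors
  normality flag per group (via the `nortest` implementation, whose
  calibration the tests verify directly; the test needs n ≥ 5 per group).
  Zero-variance variables are flagged and excluded from the FDR battery.

## Numerical and design choices

- Problem sizes in tests and the acceptance script are scaled: 30-subject
  cohorts at the default 3300-scan geometry for end-to-end recovery,
  40–100 subjects at the feature level for forest/fusion/CCA studies, 200
  null replicates for calibration, 20 seeds for stability medians. The
  methods are size-agnostic; the sizes were chosen to make the full suite
  a matter of minutes.
- Seeds are explicit everywhere (config field, function arguments); there
  is no hidden RNG state, and identical inputs reproduce identical outputs
  bit for bit.
- Degenerate inputs fail loudly: dimension mismatches, NaNs, non-monotone
  scan axes, out-of-order stages, single-class training sets, constant CCA
  columns, single-level factors, empty score vectors.
- YAML is the configuration format (`sim.yaml`); chromatograms travel
  either as mzML (read via `mzR`, centroids binned to nearest integer
  channel, x.5 rounding up, out-of-range masses counted and logged) or as
  the package's plain `matrix_csv` dialect (header row = m/z axis, first
  column = scan time) so cohorts remain inspectable as text.

## Known limitations

- Duplex-based validation is not exchangeable: because each class's test
  samples are picked deterministically (and centrally) from that class,
  the null distribution of test AUC is centred slightly above 0.5
  (empirically ≈ 0.54 at n = 40+40 against 0.50 for random splits). This
  is a property of the validation design itself and should be kept in mind
  when reading small-test-set metrics from any study using Duplex splits.
- The post-selection permutation p of the chosen clinical subset is
  computed on the same data that chose the subset and is therefore
  optimistic; the admission test controls how often anything is selected
  under the null, but the final p is descriptive, not a fresh test.
- PQN's compositional bias (above) bounds rank-exact abundance recovery.
- The importance cut-off reproduces a by-eye procedure with a stated rule;
  different reasonable rules select slightly different VOC counts.
- Clinical covariates are independent across columns given the latent
  severity; real lung-function panels are mutually correlated beyond one
  latent factor.
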