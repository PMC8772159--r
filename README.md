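# breathdisc

Discrimination of interstitial lung disease phenotypes from exhaled-breath
volatile organic compounds (VOCs), measured by thermal-desorption GC-tof-MS.

Untargeted breathomics yields one chromatogram per subject — a scan-time ×
m/z intensity matrix (nominal masses m/z 35–350 at 5 scans/s). `breathdisc`
implements the full analysis for a three-group design (healthy controls, an
IPF-like group, a CTD-ILD-like group):

- **Preprocessing**: `ln(1+x)` transform → Daubechies wavelet denoising
  (universal soft threshold) → asymmetric-least-squares baseline
  (min Σ wᵢ(yᵢ−zᵢ)² + λ Σ(Δ²z)², weights p where y>z else 1−p) →
  segment-wise retention-time alignment against the median TIC →
  probabilistic quotient normalization (sample ÷ median ratio to the
  reference spectrum) → peak picking on the cohort-mean TIC → merging of
  peaks with spectral correlation ≥ 0.95, giving the participants × peaks
  area matrix.
- **Discrimination** (per group pair): deterministic Duplex 80/20
  train/test split; Random Forest (1000 trees, permutation importance);
  VOC selection at the dominant importance gap; refit + held-out
  validation (accuracy, sensitivity, specificity, ROC with Mann–Whitney
  AUC = P(score⁺ > score⁻) + ½P(tie)); classical scaling of the RF
  proximity matrix (B = −½ J D² J, D = 1 − proximity) for the score plots.
- **Fusion**: every sample projected into each binary model's
  proximity-PCA space (Gower out-of-sample extension), coordinates
  concatenated, final PCA for the three-group view with a silhouette
  summary.
- **Inference**: regularized MANOVA (shrinkage Wilks ratio
  det(W+γI)/det(T+γI), permutation p) for confounders; canonical
  correlation analysis of discriminatory VOCs vs lung-function parameters
  with greedy permutation-guarded subset selection and a permutation
  p-value; Welch-t / FDR / Lilliefors univariate battery.
- **Synthetic cohorts**: a generator that renders chromatograms from a
  fully recorded ground truth (planted compounds, group effects,
  heteroscedastic noise, baseline drift, dilution, retention jitter, and a
  latent severity coupling VOCs to clinical columns), so every pipeline
  stage is testable as a parameter-recovery problem.

See `vignettes/breathdisc-methods.Rmd` for models, assumptions, parameter
defaults and known limitations.

## Worked example

Feature-level simulation (50/50/50 subjects, 200 compounds, 10 VOCs planted
at 1.5 between-subject SD for the IPF-like vs control contrast):

```r
library(breathdisc)
cfg <- sim_config(n_per_group = c(50L, 50L, 50L), n_compounds = 200L,
                  n_disc_A = 10L, n_disc_B = 10L, n_disc_AB = 0L, seed = 7)
sim <- simulate_feature_matrix(cfg)

split <- duplex_split(sim$fm, c("IPF-like", "control"))
#> <split_plan> IPF-like vs control: train 40+40 / test 10+10 (Duplex, euclidean on z-scored features)

full  <- train_forest(sim$fm, c("IPF-like", "control"), split, seed = 7)
vocs  <- select_discriminatory_vocs(full)
length(intersect(vocs, sim$truth$catalog$compound[sim$truth$disc$A$compound]))
#> 10        # all 10 planted discriminatory VOCs recovered

model <- refit_and_validate(sim$fm, c("IPF-like", "control"), split, vocs,
                            seed = 7)
model
#> <binary_rf> IPF-like vs control: 1000 trees, mtry 3, OOB accuracy 0.963
#>   test: accuracy 0.950, sensitivity 1.000, specificity 0.900, AUC 0.985
```

OOB accuracy is the forest's internal estimate (1 − out-of-bag error); the
test line is the held-out Duplex 20% at vote threshold 0.5, plus the
trapezoidal ROC AUC. With a cohort whose A↔B discriminatory VOCs are
coupled (ρ = 0.7) to a latent severity loading on total lung capacity (TLC)
and six-minute walk distance (6MWD), the CCA step recovers exactly that
clinical pair:

```r
cfg <- sim_config(n_per_group = c(50L, 50L, 50L), n_compounds = 200L,
                  n_disc_A = 10L, n_disc_B = 10L, n_disc_AB = 8L, seed = 7)
sim <- simulate_feature_matrix(cfg)
pat  <- sim$clinical$group != "control"
vocs <- sim$truth$catalog$compound[unique(sim$truth$disc$AB$compound)]
lung <- c("VC","TLC","FRC","FEV1","DLCO","PaO2","PaCO2","SixMWD")
cca  <- cca_subset_select(sim$fm$areas[pat, vocs],
                          as.matrix(sim$clinical[pat, lung]), seed = 7)
cca
#> <cca_result> rho1 = 0.7681 over 8 VOC x 2 clinical columns, permutation p = 0.001
cca$selected
#> [1] "TLC"    "SixMWD"
```

`rho1` is the first canonical correlation between the VOC block and the
selected lung-function columns; the p-value is a row-permutation test
(B = 999 by default). The full chromatogram-level chain is
`generate_cohort()` → `build_feature_matrix()` (log → denoise → baseline →
align → PQN → pick → merge) and is exercised end to end by the test suite
and the command line:

```sh
inst/cli/breathdisc simulate     --config sim.yaml --out cohort/ --seed 11
inst/cli/breathdisc preprocess   --in cohort/ --clinical cohort/clinical.csv --out features.csv
inst/cli/breathdisc discriminate --features features.csv --pair IPF-like,control --out m1.json
inst/cli/breathdisc fuse         --models m1.rds,m2.rds,m3.rds --features features.csv --out fused.csv
inst/cli/breathdisc correlate    --features features.csv --clinical cohort/clinical.csv --vocs C001,C002 --out cca.json
inst/cli/breathdisc confounders  --features features.csv --clinical cohort/clinical.csv --vocs C001,C002 --out confounders.csv
```

## File formats

- **matrix_csv chromatograms**: header row `scan_time,<mz1>,<mz2>,...`
  (ascending integer m/z), first column scan times in seconds, one row per
  scan — inspectable with any text tool. mzML (centroided) is read through
  `mzR`; fractional masses are binned to the nearest integer channel (x.5
  rounds up) and out-of-range masses are counted and logged.
- **feature matrix CSV**: header of peak ids; columns 1–2 are `sample_id`
  and `group`; full double precision round-trip.
- **clinical CSV**: `sample_id`, `group`, `age`, `sex`, `smoking`, and the
  lung-function columns `VC, TLC, FRC, FEV1, DLCO, PaO2, PaCO2, SixMWD`
  (percent predicted; PaO2/PaCO2 in mm Hg; may be NA for controls).
- **simulation config**: YAML with the fields of `sim_config()`.

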