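test_that("log transform has the stated closed forms and stabilizes variance", {
  run <- gaussian_run(height = exp(1) - 1, sigma = 3, n_mz = 1)
  lg <- log_transform(run)
  expect_identical(lg$stage, "logged")
  apex <- which.max(run$intensities[, 1])
  expect_equal(lg$intensities[apex, 1], 1)          # ln(1 + (e - 1)) = 1
  expect_equal(lg$intensities[1, 1], log1p(run$intensities[1, 1]))
  zero <- chrom_run("z", 1:4, 35L, matrix(0, 4, 1))
  expect_equal(log_transform(zero)$intensities, matrix(0, 4, 1))

  # multiplicative noise: raw SD scales ~100x across a 100x intensity range,
  # log-scale SD varies far less at high intensity
  set.seed(1)
  mus <- c(1e2, 1e3, 1e4)
  reps <- vapply(mus, function(mu) {
    x <- mu * (1 + 0.1 * rnorm(500))
    c(raw = sd(x), logged = sd(log1p(x)))
  }, numeric(2))
  expect_gt(reps["raw", 3] / reps["raw", 1], 30)
  expect_lt(max(reps["logged", ]) / min(reps["logged", ]), 3)
})

test_that("negative intensities and stage violations are rejected", {
  bad <- gaussian_run()
  bad$intensities[5, 1] <- -1
  expect_error(log_transform(bad), "negative")
  expect_error(log_transform(at_stage(gaussian_run(), "logged")), "stage",
               class = "breathdisc_validation_error")
  expect_error(wavelet_denoise(gaussian_run()), "stage")
  expect_error(baseline_correct(at_stage(gaussian_run(), "logged")), "stage")
  expect_error(align_runs(list(gaussian_run())), "stage")
  expect_error(pqn_normalize(list(gaussian_run())), "stage")
  expect_error(pick_peaks(list(gaussian_run())), "stage")
})

test_that("the periodized Daubechies transform reconstructs perfectly", {
  set.seed(2)
  for (ord in c(2, 4, 8)) {
    x <- matrix(rnorm(128 * 3), 128, 3)
    dec <- breathdisc:::dwt_periodized(x, order = ord, levels = 2)
    expect_equal(breathdisc:::idwt_periodized(dec), x, tolerance = 1e-10)
  }
  # odd lengths are padded and cropped back
  x <- matrix(rnorm(101), 101, 1)
  dec <- breathdisc:::dwt_periodized(x, order = 4, levels = 2)
  expect_equal(breathdisc:::idwt_periodized(dec), x, tolerance = 1e-10)
})

test_that("wavelet denoising preserves flat traces exactly", {
  zero <- at_stage(chrom_run("z", 1:64, 35:36, matrix(0, 64, 2)), "logged")
  expect_equal(wavelet_denoise(zero)$intensities, matrix(0, 64, 2))
  const <- at_stage(chrom_run("c", 1:64, 35:36, matrix(3.7, 64, 2)), "logged")
  dec <- breathdisc:::dwt_periodized(const$intensities, 4, 2)
  expect_equal(max(abs(dec$details[[1]])), 0, tolerance = 1e-12)
  expect_equal(max(abs(dec$details[[2]])), 0, tolerance = 1e-12)
  expect_equal(wavelet_denoise(const)$intensities, matrix(3.7, 64, 2),
               tolerance = 1e-12)
})

test_that("wavelet denoising reduces RMSE against the known clean signal", {
  scans <- 1:256
  clean <- 10 * exp(-0.5 * ((scans - 128) / 6)^2)
  wins <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- clean + rnorm(256, 0, 2)   # SNR 5 at the apex
    run <- at_stage(chrom_run("n", scans, 35L,
                              matrix(pmax(noisy, -10), ncol = 1)), "logged")
    den <- wavelet_denoise(run)$intensities[, 1]
    sqrt(mean((den - clean)^2)) < sqrt(mean((noisy - clean)^2))
  }, logical(1))
  expect_gte(sum(wins), 95)
})

test_that("ALS baseline tracks peak-free signal and preserves peak height", {
  # pure linear ramp: corrected residual is negligible
  ramp <- at_stage(chrom_run("r", 1:400, 35L,
                             matrix(seq(0, 10, length.out = 400), ncol = 1)),
                   "denoised")
  res <- baseline_correct(ramp)
  expect_lt(max(abs(res$run$intensities)), 1e-3 * 10)
  expect_identical(res$run$stage, "baseline_corrected")

  # gaussian peak on a constant offset: apex recovered within 5%
  h <- 8
  pk <- gaussian_run(height = h, apex = 200, sigma = 4, offset = 3, n_mz = 1)
  pk <- at_stage(pk, "denoised")
  res2 <- baseline_correct(pk)
  expect_lt(abs(max(res2$run$intensities[, 1]) - h) / h, 0.05)
  expect_true(all(res2$run$intensities >= 0))   # clipping contract
  expect_equal(dim(res2$baseline), dim(pk$intensities))

  expect_error(baseline_correct(pk, lambda_smooth = -1), "lambda",
               class = "breathdisc_config_error")
  expect_error(baseline_correct(pk, p_asym = 2), "p_asym")
})

test_that("alignment is the identity on identical runs and recovers planted shifts", {
  coh <- noiseless_cohort()
  runs <- lapply(coh$runs[1:4], function(r) {
    at_stage(log_transform(r), "baseline_corrected")
  })
  same <- align_runs(rep(runs[1], 3))
  expect_true(all(vapply(same, function(r) all(attr(r, "shifts") == 0),
                         logical(1))))
  expect_equal(same[[2]]$intensities, runs[[1]]$intensities, tolerance = 1e-12)

  # translate one run by +5 scans; its apexes must come back within 1 scan
  shifted <- runs[[1]]
  n <- nrow(shifted$intensities)
  shifted$intensities <- shifted$intensities[c(rep(1, 5), 1:(n - 5)), ]
  aligned <- align_runs(c(runs[1], runs[2:4], list(shifted)))
  ref_apex <- which.max(tic(runs[[1]]))
  back_apex <- which.max(tic(aligned[[5]]))
  expect_lte(abs(back_apex - ref_apex), 1)
  mid <- attr(aligned[[5]], "shifts")
  expect_true(median(abs(mid)) <= 6 && median(abs(mid)) >= 4)

  # alignment hardly changes the total ion count
  expect_lt(abs(sum(aligned[[5]]$intensities) - sum(shifted$intensities)) /
              sum(shifted$intensities), 0.005)
})

test_that("shifts beyond the search bound are capped with a warning", {
  coh <- noiseless_cohort()
  base <- at_stage(log_transform(coh$runs[[1]]), "baseline_corrected")
  n <- nrow(base$intensities)
  shifted <- base
  shifted$intensities <- base$intensities[c(rep(1, 40), 1:(n - 40)), ]
  expect_warning(
    aligned <- align_runs(c(rep(list(base), 3), list(shifted)),
                          segment_len = 100, max_shift = 25),
    "capped")
  expect_true(all(abs(attr(aligned[[4]], "shifts")) <= 25))
  expect_error(align_runs(rep(list(base), 2), segment_len = 10, max_shift = 25),
               "segment_len", class = "breathdisc_config_error")
})

test_that("PQN recovers exact dilutions and is idempotent", {
  coh <- noiseless_cohort()
  runs <- lapply(coh$runs[1:4], function(r) at_stage(log_transform(r), "aligned"))
  # make run 3 exactly 3x the consensus on the intensity scale
  runs[[3]]$intensities <- log1p(3 * expm1(runs[[1]]$intensities))
  runs[[4]]$intensities <- runs[[1]]$intensities
  runs[[2]]$intensities <- runs[[1]]$intensities
  res <- pqn_normalize(runs)
  expect_equal(unname(res$quotients[3]), 3, tolerance = 1e-9)
  expect_equal(unname(res$quotients[1]), 1, tolerance = 1e-9)
  expect_equal(res$cohort[[3]]$intensities, res$cohort[[1]]$intensities,
               tolerance = 1e-9)
  # re-normalizing against the same reference is a no-op
  res2 <- pqn_normalize(res$cohort, reference = res$reference)
  expect_equal(unname(res2$quotients), rep(1, 4), tolerance = 1e-12)
  expect_lt(max(abs(res2$cohort[[2]]$intensities -
                      res$cohort[[2]]$intensities)), 1e-6)
})

test_that("PQN quotients track planted dilution factors", {
  # enough compounds that the median quotient averages out composition noise
  cfg <- quick_cfg(n_compounds = 40L, run_seconds = 300,
                   dilution_sd = 0.3, noise_cv = 0.05, rt_jitter_sd = 0,
                   baseline_amp = 0, seed = 31)
  coh <- generate_cohort(cfg)
  runs <- lapply(coh$runs, function(r) at_stage(log_transform(r), "aligned"))
  res <- pqn_normalize(runs)
  expect_gt(cor(res$quotients, coh$truth$samples$dilution), 0.95)
})

test_that("peak picking finds planted gaussians with analytic areas", {
  flat <- at_stage(chrom_run("f", 1:300, 35:36, matrix(0, 300, 2)), "normalized")
  expect_equal(length(pick_peaks(list(flat))), 0)

  one <- at_stage(gaussian_run(height = 100, apex = 150, sigma = 2,
                               n_scans = 300, n_mz = 2), "normalized")
  feats <- pick_peaks(list(one))
  expect_equal(length(feats), 1)
  expect_lte(abs(feats[[1]]$apex_scan - 150), 1)
  area_truth <- 100 * 2 * sqrt(2 * pi)
  expect_lt(abs(feats[[1]]$areas[1] - area_truth) / area_truth, 0.05)
  expect_equal(sum(feats[[1]]$consensus_spectrum), 1, tolerance = 1e-9)
  expect_true(feats[[1]]$left_bound <= feats[[1]]$apex_scan)
  expect_true(feats[[1]]$apex_scan < feats[[1]]$right_bound)

  # two gaussians 10 sigma apart resolve into exactly two peaks
  scans <- 1:300
  tr <- 100 * exp(-0.5 * ((scans - 100) / 3)^2) +
    80 * exp(-0.5 * ((scans - 130) / 3)^2)
  two <- at_stage(chrom_run("t", scans, 35L, matrix(tr, ncol = 1)), "normalized")
  expect_equal(length(pick_peaks(list(two))), 2)
})

test_that("peak merging follows the spectral-correlation rule", {
  mk_peak <- function(apex, spec, area) {
    structure(list(peak_id = sprintf("P%04d", apex), apex_scan = apex,
                   left_bound = apex - 5L, right_bound = apex + 5L,
                   consensus_spectrum = spec / sum(spec),
                   areas = area, member_peaks = sprintf("P%04d", apex)),
              class = "peak_feature")
  }
  s1 <- c(5, 1, 0, 2, 0.5); s2 <- c(0.2, 3, 4, 0, 1)
  same <- list(mk_peak(100, s1, c(a = 2)), mk_peak(105, s1, c(a = 3)))
  merged <- merge_peaks(same)
  expect_equal(length(merged), 1)
  expect_equal(unname(merged[[1]]$areas), 5)   # summed member areas
  expect_equal(length(merged[[1]]$member_peaks), 2)

  # low spectral correlation: never merged
  diff_spec <- list(mk_peak(100, s1, c(a = 2)), mk_peak(105, s2, c(a = 3)))
  expect_lt(cor(s1, s2), 0.5)
  expect_equal(length(merge_peaks(diff_spec)), 2)

  # identical spectra but outside the retention window: not merged
  far <- list(mk_peak(100, s1, c(a = 2)), mk_peak(200, s1, c(a = 3)))
  expect_equal(length(merge_peaks(far)), 2)
})

test_that("a compound split by a noise dip merges back to one feature", {
  # same spectrum, adjacent apexes (as a dip in one elution profile makes)
  scans <- 1:300
  spec <- c(4, 1, 3)
  tr <- 100 * exp(-0.5 * ((scans - 145) / 4)^2) +
    90 * exp(-0.5 * ((scans - 158) / 4)^2)
  X <- outer(tr, spec / sum(spec))
  run <- at_stage(chrom_run("d", scans, 35:37, X), "normalized")
  picked <- pick_peaks(list(run))
  expect_equal(length(picked), 2)
  merged <- merge_peaks(picked)
  expect_equal(length(merged), 1)
})

test_that("build_feature_matrix is deterministic and validates the join", {
  coh <- noiseless_cohort()
  sub <- coh$runs[1:4]
  cl <- coh$clinical[1:4, ]
  fm1 <- build_feature_matrix(sub, cl)
  fm2 <- build_feature_matrix(sub, cl)
  expect_identical(fm1$areas, fm2$areas)
  expect_identical(as.character(fm1$groups),
                   as.character(cl$group[match(fm1$sample_ids, cl$sample_id)]))
  expect_error(build_feature_matrix(sub, cl[-2, ]),
               coh$runs[[2]]$sample_id,
               class = "breathdisc_validation_error")
})
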