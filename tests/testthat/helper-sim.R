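# Shared fixtures: small, fast simulation configs. Chromatogram-level tests
# use a short run and a narrow m/z window so each run stays small; tests that
# assert the full instrument geometry construct it explicitly.

options(breathdisc.verbose = FALSE)

quick_cfg <- function(...) {
  args <- modifyList(
    list(n_per_group = c(4L, 3L, 3L), n_compounds = 12L,
         n_disc_A = 2L, n_disc_B = 2L, n_disc_AB = 2L,
         mz_min = 35L, mz_max = 84L, run_seconds = 120,
         seed = 101L),
    list(...))
  do.call(sim_config, args)
}

# one noiseless mini-cohort, built once per test run
noiseless_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- quick_cfg(noise_cv = 0, baseline_amp = 0, rt_jitter_sd = 0,
                       dilution_sd = 0)
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})

# a single synthetic gaussian-peak run for unit tests of individual stages
gaussian_run <- function(height = 100, apex = 200, sigma = 2, n_scans = 400,
                         n_mz = 5, offset = 0, stage = "raw",
                         sample_id = "g1") {
  scans <- seq_len(n_scans)
  trace <- height * exp(-0.5 * ((scans - apex) / sigma)^2) + offset
  X <- matrix(rep(trace / n_mz, n_mz), ncol = n_mz)
  chrom_run(sample_id, scans / 5, seq(35L, length.out = n_mz), X,
            stage = stage)
}

# advance a run to a given pipeline stage without altering the data (for
# stage-contract tests that need a run "at" some stage)
at_stage <- function(run, stage) {
  run$stage <- stage
  run
}

# feature matrix with planted two-group separation on chosen columns
toy_fm <- function(n_per_class = 10, p = 6, shift_cols = 1, shift = 3,
                   classes = c("control", "IPF-like"), seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(exp(rnorm(n * p)), n, p,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("V%02d", seq_len(p))))
  g <- rep(classes, each = n_per_class)
  if (length(shift_cols)) {
    X[g == classes[2], shift_cols] <-
      X[g == classes[2], shift_cols] * exp(shift)
  }
  feature_matrix(X, groups = g)
}
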