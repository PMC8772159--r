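#' Simulation configuration for synthetic breath cohorts
#'
#' Defines the statistical and instrumental conditions a synthetic cohort is
#' generated under. Defaults mirror the study design the pipeline targets:
#' three groups (healthy controls, an IPF-like disease group, a CTD-ILD-like
#' disease group) of sizes 51/53/51, a nominal-mass axis m/z 35-350 (316 unit
#' channels), a 5 scans/sec time-of-flight acquisition, and discriminatory
#' compounds planted as mean log-abundance shifts between groups.
#'
#' The default acquisition length is 660 s (3300 scans), a time-scaled stand-in
#' for the instrument's full 33-min run that preserves peak density; pass
#' `run_seconds = 1980` for the full 9900-scan geometry.
#'
#' @param n_per_group named integer vector `c(control=, groupA=, groupB=)`;
#'   groupA plays the IPF-like role, groupB the CTD-ILD-like role.
#' @param n_compounds total number of planted compounds.
#' @param n_disc_A,n_disc_B,n_disc_AB numbers of compounds whose abundance
#'   differs control vs A, control vs B, and A vs B respectively (sets may
#'   overlap; a compound can discriminate in two contrasts).
#' @param effect_size mean log-abundance shift of a discriminatory compound,
#'   in units of the between-subject log-abundance SD.
#' @param mz_min,mz_max integer m/z bounds of the nominal-mass axis.
#' @param scan_rate scans per second.
#' @param run_seconds acquisition length in seconds.
#' @param noise_cv coefficient of variation of the multiplicative
#'   (heteroscedastic) intensity noise.
#' @param baseline_amp amplitude of the smooth baseline drift relative to the
#'   median TIC peak height.
#' @param rt_jitter_sd SD of per-sample retention-time jitter, in scans.
#' @param dilution_sd SD of the per-sample log dilution factor.
#' @param clinical_coupling correlation between the latent severity variable,
#'   the A-vs-B discriminatory compounds, and the coupled clinical columns.
#' @param coupled_clinical clinical columns tied to the latent severity
#'   (defaults to total lung capacity and six-minute walk distance).
#' @param between_subject_sd SD of between-subject log-abundance variation.
#' @param seed integer RNG seed; the same `sim_config` always regenerates a
#'   byte-identical cohort.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_per_group = c(control = 51L, groupA = 53L, groupB = 51L),
                       n_compounds = 200L,
                       n_disc_A = 10L, n_disc_B = 10L, n_disc_AB = 10L,
                       effect_size = 1.5,
                       mz_min = 35L, mz_max = 350L,
                       scan_rate = 5, run_seconds = 660,
                       noise_cv = 0.1,
                       baseline_amp = 0.1,
                       rt_jitter_sd = 2,
                       dilution_sd = 0.3,
                       clinical_coupling = 0.7,
                       coupled_clinical = c("TLC", "SixMWD"),
                       between_subject_sd = 0.4,
                       seed = 1L) {
  cfg <- structure(
    list(n_per_group = setNames(as.integer(n_per_group),
                                c("control", "groupA", "groupB")),
         n_compounds = as.integer(n_compounds),
         n_disc_A = as.integer(n_disc_A),
         n_disc_B = as.integer(n_disc_B),
         n_disc_AB = as.integer(n_disc_AB),
         effect_size = effect_size,
         mz_min = as.integer(mz_min), mz_max = as.integer(mz_max),
         scan_rate = scan_rate, run_seconds = run_seconds,
         noise_cv = noise_cv, baseline_amp = baseline_amp,
         rt_jitter_sd = rt_jitter_sd, dilution_sd = dilution_sd,
         clinical_coupling = clinical_coupling,
         coupled_clinical = coupled_clinical,
         between_subject_sd = between_subject_sd,
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) bd_config_error(sprintf("invalid sim_config field '%s': %s", field, why))
  }
  chk(length(cfg$n_per_group) == 3 && all(cfg$n_per_group > 0),
      "n_per_group", "all three group counts must be > 0")
  chk(cfg$n_compounds > 0, "n_compounds", "must be > 0")
  for (f in c("n_disc_A", "n_disc_B", "n_disc_AB")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= cfg$n_compounds, f,
        sprintf("must be in [0, n_compounds=%d]", cfg$n_compounds))
  }
  chk(cfg$mz_min < cfg$mz_max, "mz_min", "mz_min must be < mz_max")
  chk(cfg$scan_rate > 0, "scan_rate", "must be > 0")
  chk(cfg$run_seconds > 0, "run_seconds", "must be > 0")
  chk(cfg$effect_size >= 0, "effect_size", "must be >= 0")
  chk(cfg$noise_cv >= 0, "noise_cv", "must be >= 0")
  chk(cfg$baseline_amp >= 0, "baseline_amp", "must be >= 0")
  chk(cfg$rt_jitter_sd >= 0, "rt_jitter_sd", "must be >= 0")
  chk(cfg$dilution_sd >= 0, "dilution_sd", "must be >= 0")
  chk(abs(cfg$clinical_coupling) <= 1, "clinical_coupling", "must be in [-1, 1]")
  chk(cfg$between_subject_sd > 0, "between_subject_sd", "must be > 0")
  chk(all(cfg$coupled_clinical %in% clinical_lung_columns()),
      "coupled_clinical",
      paste("must be among", paste(clinical_lung_columns(), collapse = ", ")))
  chk(is.finite(cfg$seed), "seed", "must be a finite integer")
  invisible(cfg)
}

n_scans <- function(cfg) as.integer(round(cfg$scan_rate * cfg$run_seconds))
n_channels <- function(cfg) cfg$mz_max - cfg$mz_min + 1L

clinical_lung_columns <- function() {
  c("VC", "TLC", "FRC", "FEV1", "DLCO", "PaO2", "PaCO2", "SixMWD")
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields of [sim_config()] may be overridden in the file; omitted
#' fields keep their defaults. `n_per_group` is given as a mapping with keys
#' `control`, `groupA`, `groupB`.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) bd_config_error("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    bd_config_error("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(raw$n_per_group)) raw$n_per_group <- unlist(raw$n_per_group)
  do.call(sim_config, raw)
}
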