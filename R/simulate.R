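#' Synthetic breath-cohort generator
#'
#' Generates cohorts of GC-tof-MS chromatograms and matching clinical tables
#' with the statistical structure the downstream analysis assumes, together
#' with a complete ground-truth ledger (`synthetic_truth`) so that every
#' pipeline stage can be tested as a parameter-recovery problem.
#'
#' The signal model for one subject is
#' `intensity(scan, mz) = baseline(scan, mz) +
#'    sum_compounds abundance * GaussianRT(scan; apex + jitter, width) * spectrum(mz)`
#' followed by multiplicative heteroscedastic noise
#' `* max(1 + noise_cv * eps, 0)` and a per-sample dilution factor.
#' Discriminatory compounds receive group-specific mean log-abundance shifts
#' of `effect_size` between-subject SDs; the A-vs-B discriminatory compounds
#' are additionally coupled (with correlation `clinical_coupling`) to a latent
#' severity variable that also loads on the configured clinical columns.
#'
#' @param config a [sim_config()].
#' @return `generate_cohort()` returns a list with elements `runs` (list of
#'   [chrom_run()] objects, one per subject, stage `"raw"`), `clinical`
#'   (data.frame of per-subject covariates), and `truth` (the
#'   `synthetic_truth` ledger).
#' @seealso [render_run()], [simulate_feature_matrix()]
#' @export
generate_cohort <- function(config) {
  truth <- build_truth(config)
  runs <- lapply(seq_len(nrow(truth$samples)), function(i) render_run(truth, i))
  bd_log(sprintf("generated cohort: %d runs (%d scans x %d channels), %d compounds",
                 length(runs), n_scans(config), n_channels(config),
                 config$n_compounds))
  list(runs = runs, clinical = truth$clinical, truth = truth)
}

#' Simulate a feature matrix directly from the abundance model
#'
#' Draws the same per-subject compound abundances and clinical covariates as
#' [generate_cohort()] but skips chromatographic rendering, yielding the
#' feature matrix an ideal preprocessing of that cohort would recover (peak
#' areas equal to compound abundances, dilution removed). Used for studies of
#' the statistical machinery (forests, fusion, CCA, confounders) where the
#' chromatographic layer is not under test.
#'
#' @param config a [sim_config()].
#' @return list with `fm` (a [feature_matrix()]), `clinical`, and `truth`.
#' @export
simulate_feature_matrix <- function(config) {
  truth <- build_truth(config)
  areas <- exp(truth$log_abund)
  colnames(areas) <- truth$catalog$compound
  rownames(areas) <- truth$samples$sample_id
  fm <- feature_matrix(areas, groups = truth$samples$group)
  list(fm = fm, clinical = truth$clinical, truth = truth)
}

# derive a per-sample seed from the master seed (kept inside 32-bit range)
derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 7919 + idx * 104729) %% 2147483647)
}

#' Build the ground-truth ledger of a synthetic cohort
#'
#' Draws everything the cohort's chromatograms are rendered from: the peak
#' catalog (retention apex, width, unit-sum mass spectrum and base log
#' abundance per compound), the three discriminatory contrast sets with
#' signed effects, per-subject realized abundances, dilution factors,
#' retention shifts and latent severity scores, and the clinical table with
#' its configured severity coupling. [render_run()] turns one row of the
#' ledger into a chromatogram.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_truth`.
#' @export
build_truth <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  S <- n_scans(config)
  C <- n_channels(config)
  K <- config$n_compounds

  # --- retention apexes: sorted with a guaranteed minimum gap, so that peak
  # density stays realistic at any configured compound count
  margin <- 80L
  span <- S - 2L * margin
  if (span <= K) bd_config_error("run too short for n_compounds: ",
                                 K, " compounds in ", S, " scans")
  gap_min <- max(4, min(60, floor(span / K * 0.75)))
  slack <- span - (K - 1) * gap_min
  if (slack <= 0) {
    gap_min <- max(1, floor(span / K * 0.5))
    slack <- span - (K - 1) * gap_min
  }
  apexes <- margin + round(sort(runif(K)) * slack + (seq_len(K) - 1) * gap_min)
  widths <- runif(K, 3, 6)
  base_log <- runif(K, log(2e4), log(6e4))

  # --- mass spectra: 5-15 nonzero unit-mass lines, Dirichlet weights; lines
  # are re-used across compounds with probability 0.2 so that
  # spectral-correlation merging has genuinely confusable neighbours
  spectra <- matrix(0, K, C)
  used_lines <- integer(0)
  for (i in seq_len(K)) {
    nl <- sample(5:15, 1)
    lines <- integer(nl)
    for (j in seq_len(nl)) {
      lines[j] <- if (length(used_lines) && runif(1) < 0.2) {
        sample(used_lines, 1)
      } else sample.int(C, 1)
    }
    lines <- unique(lines)
    used_lines <- unique(c(used_lines, lines))
    w <- -log(runif(length(lines)))   # Dirichlet(1,...,1)
    spectra[i, lines] <- w / sum(w)
  }

  # --- discriminatory contrasts (independent draws; overlap allowed)
  draw_set <- function(n) {
    if (n == 0) return(data.frame(compound = integer(0), sign = numeric(0)))
    idx <- sort(sample.int(K, n))
    data.frame(compound = idx, sign = sample(c(-1, 1), n, replace = TRUE))
  }
  disc <- list(A = draw_set(config$n_disc_A),
               B = draw_set(config$n_disc_B),
               AB = draw_set(config$n_disc_AB))

  # --- subjects
  groups <- factor(rep(c("control", "IPF-like", "CTD-like"), config$n_per_group),
                   levels = c("control", "IPF-like", "CTD-like"))
  n <- length(groups)
  sample_ids <- sprintf("S%03d", seq_len(n))
  severity <- rnorm(n)
  dilution <- exp(rnorm(n, 0, config$dilution_sd))
  rt_shift <- rnorm(n, 0, config$rt_jitter_sd)

  # --- realized log abundances
  sb <- config$between_subject_sd
  rho <- config$clinical_coupling
  delta <- config$effect_size * sb
  eps <- matrix(rnorm(n * K), n, K)
  coupled <- disc$AB$compound
  if (length(coupled)) {
    eps[, coupled] <- rho * severity +
      sqrt(1 - rho^2) * eps[, coupled, drop = FALSE]
  }
  log_abund <- matrix(base_log, n, K, byrow = TRUE) + sb * eps
  shift_rows <- function(set, grp) {
    if (!nrow(set)) return()
    rows <- which(groups == grp)
    for (r in seq_len(nrow(set))) {
      log_abund[rows, set$compound[r]] <<-
        log_abund[rows, set$compound[r]] + set$sign[r] * delta
    }
  }
  shift_rows(disc$A, "IPF-like")
  shift_rows(disc$B, "CTD-like")
  shift_rows(disc$AB, "IPF-like")   # A-vs-B difference carried by group A

  samples <- data.frame(sample_id = sample_ids, group = groups,
                        dilution = dilution, severity = severity,
                        rt_shift = rt_shift, stringsAsFactors = FALSE)
  clinical <- simulate_clinical(samples, config)

  structure(
    list(config = config,
         catalog = data.frame(compound = sprintf("C%03d", seq_len(K)),
                              apex_scan = apexes, width = widths,
                              base_log_abund = base_log,
                              stringsAsFactors = FALSE),
         spectra = spectra,
         disc = disc,
         samples = samples,
         log_abund = log_abund,
         clinical = clinical,
         clinical_loadings = list(columns = config$coupled_clinical,
                                  rho = config$clinical_coupling)),
    class = "synthetic_truth")
}

# Per-subject covariates with group-typical distributions; lung-function
# columns exist for patients only (controls carry NA, as in routine referral
# cohorts where controls get no pulmonary work-up). Coupled columns share the
# latent severity of the abundance model with loading `clinical_coupling`.
simulate_clinical <- function(samples, config) {
  n <- nrow(samples)
  g <- as.integer(samples$group)   # 1 control, 2 IPF-like, 3 CTD-like
  age_mu <- c(53, 69, 57)[g]; age_sd <- c(10, 9, 12)[g]
  p_male <- c(0.68, 0.75, 0.26)[g]
  smoke_p <- rbind(c(0.49, 0.35, 0.16),   # never / ex / current
                   c(0.40, 0.60, 0.00),
                   c(0.72, 0.24, 0.04))
  smoking <- character(n); sex <- character(n)
  for (i in seq_len(n)) {
    sex[i] <- if (runif(1) < p_male[i]) "male" else "female"
    smoking[i] <- sample(c("never", "ex", "current"), 1, prob = smoke_p[g[i], ])
  }
  cl <- data.frame(sample_id = samples$sample_id,
                   group = samples$group,
                   age = pmax(round(rnorm(n, age_mu, age_sd)), 20),
                   sex = sex, smoking = smoking,
                   stringsAsFactors = FALSE)
  # mean (SD) per patient group, percent predicted (PaO2/PaCO2 in mm Hg)
  lung_mu <- list(VC = c(77, 78), TLC = c(71, 76), FRC = c(74, 78),
                  FEV1 = c(80, 78), DLCO = c(49, 49), PaO2 = c(75, 80),
                  PaCO2 = c(41, 39), SixMWD = c(88, 78))
  lung_sd <- list(VC = c(22, 23), TLC = c(15, 15), FRC = c(17, 15),
                  FEV1 = c(22, 25), DLCO = c(17, 17), PaO2 = c(9, 12),
                  PaCO2 = c(4, 4), SixMWD = c(20, 20))
  rho <- config$clinical_coupling
  patient <- g > 1
  for (col in clinical_lung_columns()) {
    v <- rep(NA_real_, n)
    idx <- which(patient)
    mu <- lung_mu[[col]][g[idx] - 1]; sdv <- lung_sd[[col]][g[idx] - 1]
    e <- rnorm(length(idx))
    if (col %in% config$coupled_clinical) {
      e <- rho * samples$severity[idx] + sqrt(1 - rho^2) * e
    }
    v[idx] <- pmax(round(mu + sdv * e, 1), 5)
    cl[[col]] <- v
  }
  cl
}

#' Render one subject's chromatogram from the truth ledger
#'
#' Deterministic given `(truth, sample_index)`: the per-sample noise stream is
#' seeded from the master seed and the sample index, so individual runs can be
#' re-rendered in any order and always reproduce the cohort of
#' [generate_cohort()].
#'
#' @param truth a `synthetic_truth` from [build_truth()]/[generate_cohort()].
#' @param sample_index subject row in `truth$samples`.
#' @return a raw-stage [chrom_run()].
#' @export
render_run <- function(truth, sample_index) {
  cfg <- truth$config
  if (sample_index < 1 || sample_index > nrow(truth$samples)) {
    bd_stop("sample_index out of range: ", sample_index)
  }
  set.seed(derive_seed(cfg$seed, sample_index))
  S <- n_scans(cfg); C <- n_channels(cfg)
  scans <- seq_len(S)
  smp <- truth$samples[sample_index, ]

  abund <- exp(truth$log_abund[sample_index, ])
  apex <- truth$catalog$apex_scan + smp$rt_shift
  width <- truth$catalog$width
  # Gaussian retention profiles; at unit scan spacing each column has area
  # equal to its abundance
  G <- vapply(seq_along(abund), function(i) {
    abund[i] * exp(-0.5 * ((scans - apex[i]) / width[i])^2) /
      (width[i] * sqrt(2 * pi))
  }, numeric(S))
  X <- G %*% truth$spectra

  if (cfg$baseline_amp > 0) {
    peak_h <- exp(truth$catalog$base_log_abund) / (width * sqrt(2 * pi))
    H <- median(peak_h)
    t01 <- (scans - 1) / (S - 1)
    drift <- rowSums(vapply(1:3, function(k) {
      runif(1, 0.3, 1) * cos(pi * k * t01 + runif(1, 0, 2 * pi))
    }, numeric(S)))
    drift <- (drift - min(drift)) / max(drift - min(drift) + 1e-12)
    w <- -log(runif(C)); w <- w / sum(w)
    X <- X + (cfg$baseline_amp * H) * outer(drift, w)
  }

  if (cfg$noise_cv > 0) {
    X <- X * pmax(1 + cfg$noise_cv * matrix(rnorm(S * C), S, C), 0)
  }
  X <- X * smp$dilution

  chrom_run(sample_id = smp$sample_id,
            scan_times = scans / cfg$scan_rate,
            mz_axis = seq(cfg$mz_min, cfg$mz_max),
            intensities = X, stage = "raw")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d subjects (%s), %d compounds, disc A/B/AB = %d/%d/%d\n",
              nrow(x$samples),
              paste(table(x$samples$group), collapse = "/"),
              nrow(x$catalog), nrow(x$disc$A), nrow(x$disc$B), nrow(x$disc$AB)))
  invisible(x)
}
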