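#' Log transform of a chromatogram
#'
#' Applies `ln(1 + x)` to every intensity. GC-MS intensity noise is
#' predominantly multiplicative (SD proportional to signal); the log converts
#' it to approximately constant variance so that the later smoothing,
#' thresholding and least-squares stages see homoscedastic errors. `1 + x`
#' rather than `x` because chromatograms contain exact zeros.
#'
#' @param run a raw-stage [chrom_run()].
#' @return the run with transformed intensities, stage `"logged"`.
#' @export
log_transform <- function(run) {
  check_stage(run, "raw")
  if (any(run$intensities < 0)) {
    bd_validation_error("negative intensities in sample '", run$sample_id, "'")
  }
  run$intensities <- log1p(run$intensities)
  run$stage <- "logged"
  run
}

#' Wavelet denoising of a chromatogram
#'
#' Each m/z channel trace is decomposed with a periodized orthonormal
#' Daubechies wavelet to `levels` detail levels; detail coefficients are
#' soft-thresholded at the universal threshold `sigma * sqrt(2 log n)`, with
#' `sigma` estimated as `MAD(finest details) / 0.6745`, then the trace is
#' reconstructed. Approximation coefficients are untouched, so smooth
#' structure (peaks, baseline) passes through while white noise is removed.
#'
#' @param run a logged-stage [chrom_run()].
#' @param wavelet_order Daubechies order (2, 4 or 8 vanishing moments).
#' @param levels number of decomposition levels.
#' @return the denoised run, stage `"denoised"`.
#' @export
wavelet_denoise <- function(run, wavelet_order = 4, levels = 2) {
  check_stage(run, "logged")
  if (levels < 1) bd_config_error("levels must be >= 1")
  dec <- dwt_periodized(run$intensities, order = wavelet_order, levels = levels)
  n <- nrow(run$intensities)
  fine <- dec$details[[1]]
  # per-channel noise scale from the finest detail coefficients
  sigma <- apply(fine, 2, function(d) mad(d, center = 0, constant = 1)) / 0.6745
  thr <- sigma * sqrt(2 * log(n))
  for (lev in seq_along(dec$details)) {
    dec$details[[lev]] <- soft_threshold(
      dec$details[[lev]], matrix(thr, nrow(dec$details[[lev]]),
                                 length(thr), byrow = TRUE))
  }
  run$intensities <- idwt_periodized(dec)
  run$stage <- "denoised"
  run
}

#' Asymmetric-least-squares baseline correction
#'
#' Per channel, estimates a slowly varying baseline `z` by iteratively
#' reweighted penalized least squares: minimize
#' `sum_i w_i (y_i - z_i)^2 + lambda * sum (second difference of z)^2`
#' with asymmetric weights (`p_asym` where `y > z`, `1 - p_asym` elsewhere),
#' so the smoother hugs the troughs under the peaks. The corrected signal is
#' `y - z`, clipped at zero.
#'
#' @param run a denoised-stage [chrom_run()].
#' @param lambda_smooth smoothness penalty (larger = stiffer baseline).
#' @param p_asym asymmetry weight in (0, 1); small values let peaks float
#'   above the baseline.
#' @param n_iter number of reweighting iterations.
#' @return list with `run` (stage `"baseline_corrected"`) and `baseline`
#'   (the subtracted matrix, for inspection).
#' @export
baseline_correct <- function(run, lambda_smooth = 1e5, p_asym = 0.001,
                             n_iter = 10) {
  check_stage(run, "denoised")
  if (lambda_smooth <= 0) bd_config_error("lambda_smooth must be > 0")
  if (p_asym <= 0 || p_asym >= 1) bd_config_error("p_asym must be in (0, 1)")
  z <- als_baseline_mat(run$intensities, lambda_smooth, p_asym, as.integer(n_iter))
  run$intensities <- pmax(run$intensities - z, 0)
  run$stage <- "baseline_corrected"
  list(run = run, baseline = z)
}

#' Retention-time alignment of a cohort
#'
#' The cohort's scan-wise median total ion current is the alignment
#' reference. Each run's TIC is cut into segments of `segment_len` scans; per
#' segment the integer shift in `[-max_shift, max_shift]` maximizing the
#' Pearson correlation with the reference segment is found, shifts are
#' interpolated linearly between segment centres, and every channel is warped
#' by linear interpolation along the scan axis. Shifts hitting the search
#' bound are capped with a warning.
#'
#' @param cohort list of baseline-corrected [chrom_run()]s sharing axes.
#' @param segment_len segment length in scans.
#' @param max_shift maximum absolute shift in scans.
#' @return list of aligned runs (stage `"aligned"`), with the per-segment
#'   shifts of each run attached as attribute `"shifts"`.
#' @export
align_runs <- function(cohort, segment_len = 100, max_shift = 25) {
  if (!length(cohort)) bd_stop("empty cohort")
  lapply(cohort, check_stage, expected = "baseline_corrected")
  if (segment_len < 2 * max_shift) {
    bd_config_error("segment_len must be >= 2 * max_shift")
  }
  tics <- vapply(cohort, tic, numeric(nrow(cohort[[1]]$intensities)))
  ref <- apply(tics, 1, median)
  S <- length(ref)
  starts <- seq(1, S, by = segment_len)
  centers <- pmin(starts + segment_len / 2, S)
  lapply(seq_along(cohort), function(ri) {
    run <- cohort[[ri]]
    y <- tics[, ri]
    seg_shift <- vapply(starts, function(s0) {
      idx <- s0:min(s0 + segment_len - 1, S)
      best <- 0L; best_r <- -Inf
      cand <- -max_shift:max_shift
      cand <- cand[order(abs(cand), cand)]   # prefer the smallest shift on ties
      for (sh in cand) {
        src <- idx + sh
        ok <- src >= 1 & src <= S
        if (sum(ok) < max(4, length(idx) / 2)) next
        a <- y[src[ok]]; b <- ref[idx[ok]]
        if (sd(a) == 0 || sd(b) == 0) {
          r <- if (sd(a) == 0 && sd(b) == 0) 1 else 0
        } else r <- cor(a, b)
        if (r > best_r + 1e-12) { best_r <- r; best <- sh }
      }
      best
    }, numeric(1))
    if (any(abs(seg_shift) >= max_shift)) {
      warning(sprintf("sample '%s': %d segment shift(s) at the +/-%d search bound (capped)",
                      run$sample_id, sum(abs(seg_shift) >= max_shift), max_shift))
    }
    shift_t <- approx(centers, seg_shift, xout = seq_len(S), rule = 2)$y
    src <- seq_len(S) + shift_t
    src <- pmin(pmax(src, 1), S)
    lo <- floor(src); hi <- pmin(lo + 1, S); fr <- src - lo
    run$intensities <- run$intensities[lo, , drop = FALSE] * (1 - fr) +
      run$intensities[hi, , drop = FALSE] * fr
    run$stage <- "aligned"
    attr(run, "shifts") <- seg_shift
    run
  })
}

#' Probabilistic quotient normalization of a cohort
#'
#' Removes per-sample dilution. Sample dilution acts multiplicatively on the
#' measured intensities, so the aligned runs are first returned from the log
#' scale (the smoothing stages' working scale) to the intensity scale with
#' `expm1`. The reference is the scan-wise median TIC vector over all runs,
#' restricted to scans where the reference exceeds its 25th percentile
#' (avoiding near-zero bins); each run's quotient vector is its TIC over the
#' reference on those bins, and the whole run is divided by the median
#' quotient — its dilution estimate. Downstream peak areas are therefore on
#' the (dilution-corrected) intensity scale.
#'
#' Re-normalizing a normalized cohort against the same `reference` is a
#' no-op: all median quotients come out exactly 1.
#'
#' @param cohort list of aligned [chrom_run()]s (an already-normalized
#'   cohort is accepted for re-normalization against a fixed reference).
#' @param reference optional fixed reference TIC vector (as returned in
#'   `$reference`); computed from the cohort when `NULL`.
#' @return list with `cohort` (normalized runs, intensity scale),
#'   `quotients` (named vector of per-run median quotients, the dilution
#'   estimates), and `reference`.
#' @export
pqn_normalize <- function(cohort, reference = NULL) {
  if (!length(cohort)) bd_stop("empty cohort")
  stages <- vapply(cohort, `[[`, character(1), "stage")
  if (!all(stages %in% c("aligned", "normalized"))) {
    lapply(cohort, check_stage, expected = "aligned")
  }
  cohort <- lapply(cohort, function(run) {
    if (run$stage == "aligned") run$intensities <- expm1(run$intensities)
    run
  })
  tics <- vapply(cohort, tic, numeric(nrow(cohort[[1]]$intensities)))
  ref <- if (is.null(reference)) apply(tics, 1, median) else reference
  if (all(ref == 0)) bd_stop("all-zero PQN reference")
  bins <- which(ref > quantile(ref, 0.25))
  quotients <- vapply(seq_along(cohort), function(i) {
    median(tics[bins, i] / ref[bins])
  }, numeric(1))
  names(quotients) <- vapply(cohort, `[[`, character(1), "sample_id")
  cohort <- lapply(seq_along(cohort), function(i) {
    run <- cohort[[i]]
    run$intensities <- run$intensities / quotients[i]
    run$stage <- "normalized"
    run
  })
  list(cohort = cohort, quotients = quotients, reference = ref)
}

#' Peak picking on the cohort-mean TIC
#'
#' Candidate peaks are local maxima of the cohort-mean total ion current
#' whose topographic prominence exceeds `k_sigma` times the noise scale
#' (median absolute deviation of the first-differenced trace / 0.6745). Peak
#' bounds are the TIC minima flanking each apex (half-open `[left, right)`),
#' shared by all samples so the feature matrix is rectangular; each sample's
#' area is the trapezoidal integral of its own TIC over the shared bounds.
#' The consensus mass spectrum is the TIC-weighted mean of the cohort-mean
#' spectra at apex +/- 1 scan, unit-normalized.
#'
#' @param cohort list of normalized [chrom_run()]s.
#' @param k_sigma prominence threshold in noise-SD units.
#' @return list of `peak_feature` records, each carrying `areas` (one value
#'   per sample).
#' @export
pick_peaks <- function(cohort, k_sigma = 5) {
  if (!length(cohort)) bd_stop("empty cohort")
  lapply(cohort, check_stage, expected = "normalized")
  X_mean <- Reduce(`+`, lapply(cohort, `[[`, "intensities")) / length(cohort)
  mtic <- rowSums(X_mean)
  S <- length(mtic)
  sigma <- mad(diff(mtic), center = 0, constant = 1) / 0.6745
  apexes <- which(diff(c(-Inf, mtic)) > 0 & diff(c(mtic, Inf)) <= 0)
  apexes <- apexes[mtic[apexes] > 0]
  prom <- vapply(apexes, function(a) peak_prominence(mtic, a), numeric(1))
  keep <- prom >= k_sigma * sigma & prom > 1e-12
  apexes <- apexes[keep]
  if (!length(apexes)) return(list())
  # bounds: TIC argmin between consecutive retained apexes
  bounds <- integer(length(apexes) + 1)
  bounds[1] <- which.min(mtic[1:apexes[1]])
  for (i in seq_len(length(apexes) - 1)) {
    seg <- apexes[i]:apexes[i + 1]
    bounds[i + 1] <- seg[which.min(mtic[seg])]
  }
  bounds[length(bounds)] <- apexes[length(apexes)] +
    which.min(mtic[apexes[length(apexes)]:S]) - 1L
  tic_mat <- vapply(cohort, tic, numeric(S))
  lapply(seq_along(apexes), function(i) {
    a <- apexes[i]
    left <- bounds[i]; right <- max(bounds[i + 1], a + 1L)
    rows <- max(a - 1L, 1L):min(a + 1L, S)
    w <- mtic[rows]
    spec <- colSums(X_mean[rows, , drop = FALSE] * w) / sum(w)
    if (sum(spec) > 0) spec <- spec / sum(spec)
    areas <- apply(tic_mat[left:right, , drop = FALSE], 2, trapz_unit)
    structure(list(peak_id = sprintf("P%04d", a), apex_scan = a,
                   left_bound = left, right_bound = right,
                   consensus_spectrum = spec, areas = areas,
                   member_peaks = sprintf("P%04d", a)),
              class = "peak_feature")
  })
}

# topographic prominence: height above the higher of the two key saddles
peak_prominence <- function(y, a) {
  h <- y[a]
  left_min <- h; i <- a
  while (i > 1) {
    i <- i - 1
    if (y[i] > h) break
    left_min <- min(left_min, y[i])
  }
  if (i == 1 && y[1] <= h) left_min <- min(left_min, min(y[1:a]))
  right_min <- h; i <- a
  n <- length(y)
  while (i < n) {
    i <- i + 1
    if (y[i] > h) break
    right_min <- min(right_min, y[i])
  }
  if (i == n && y[n] <= h) right_min <- min(right_min, min(y[a:n]))
  h - max(left_min, right_min)
}

trapz_unit <- function(y) {
  n <- length(y)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2)
}

#' Merge picked peaks belonging to the same compound
#'
#' A compound fragmenting into several picked peaks (e.g. a noise dip
#' splitting one elution profile) leaves near-identical mass spectra at
#' nearby retention times. Peak pairs with consensus-spectrum Pearson
#' correlation `>= corr_threshold` and apexes within `rt_window` scans are
#' merged greedily in descending correlation order (ties broken by the
#' earlier apex); a merged feature sums the member areas and carries the
#' area-weighted mean spectrum.
#'
#' @param features output of [pick_peaks()].
#' @param corr_threshold minimum spectral correlation for a merge.
#' @param rt_window maximum apex separation in scans.
#' @return list of merged `peak_feature` records.
#' @export
merge_peaks <- function(features, corr_threshold = 0.95, rt_window = 15) {
  if (length(features) < 2) return(features)
  repeat {
    n <- length(features)
    best <- NULL; best_r <- -Inf
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(features[[i]]$apex_scan - features[[j]]$apex_scan) > rt_window) next
        si <- features[[i]]$consensus_spectrum
        sj <- features[[j]]$consensus_spectrum
        if (sd(si) == 0 || sd(sj) == 0) next
        r <- cor(si, sj)
        if (r >= corr_threshold &&
            (r > best_r + 1e-12 ||
             (abs(r - best_r) <= 1e-12 && !is.null(best) &&
              min(features[[i]]$apex_scan, features[[j]]$apex_scan) <
              min(features[[best[1]]]$apex_scan, features[[best[2]]]$apex_scan)))) {
          best_r <- r; best <- c(i, j)
        }
      }
    }
    if (is.null(best)) break
    fi <- features[[best[1]]]; fj <- features[[best[2]]]
    wi <- sum(fi$areas); wj <- sum(fj$areas)
    if (wi + wj == 0) { wi <- 1; wj <- 1 }
    spec <- (wi * fi$consensus_spectrum + wj * fj$consensus_spectrum) / (wi + wj)
    if (sum(spec) > 0) spec <- spec / sum(spec)
    lead <- if (wi >= wj) fi else fj
    merged <- structure(list(
      peak_id = lead$peak_id,
      apex_scan = lead$apex_scan,
      left_bound = min(fi$left_bound, fj$left_bound),
      right_bound = max(fi$right_bound, fj$right_bound),
      consensus_spectrum = spec,
      areas = fi$areas + fj$areas,
      member_peaks = c(fi$member_peaks, fj$member_peaks)),
      class = "peak_feature")
    features[[best[1]]] <- merged
    features[[best[2]]] <- NULL
  }
  features
}

#' Feature matrix container
#'
#' One row per participant and one column per quantified peak, plus group
#' labels and (optionally) the merged peak features the columns came from.
#'
#' @param areas numeric matrix (samples x peaks) with dimnames; non-negative,
#'   no missing entries.
#' @param groups factor or character of group labels, one per row.
#' @param features optional list of `peak_feature` records, one per column.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(areas, groups, features = NULL) {
  if (anyNA(areas)) bd_validation_error("feature matrix contains missing entries")
  if (is.null(rownames(areas)) || (ncol(areas) > 0 && is.null(colnames(areas)))) {
    bd_validation_error("areas must carry sample ids (rownames) and peak ids (colnames)")
  }
  if (anyDuplicated(rownames(areas))) {
    bd_validation_error("duplicate sample id: ",
                        rownames(areas)[duplicated(rownames(areas))][1])
  }
  if (length(groups) != nrow(areas)) {
    bd_validation_error("group labels do not match the number of samples")
  }
  structure(list(sample_ids = rownames(areas),
                 areas = areas,
                 groups = factor(groups),
                 features = features),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d peaks; groups: %s\n",
              nrow(x$areas), ncol(x$areas),
              paste(sprintf("%s=%d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Run the full preprocessing chain on a cohort
#'
#' Applies, in fixed order, log transform, wavelet denoising, baseline
#' correction, retention-time alignment, probabilistic quotient
#' normalization, peak picking, and spectral-correlation peak merging, then
#' joins the clinical group labels to form the participants x peaks matrix.
#'
#' @param cohort list of raw [chrom_run()]s, or a directory containing
#'   `matrix_csv` chromatograms (see [read_chromatogram()]).
#' @param clinical clinical table (data.frame with `sample_id` and `group`,
#'   or a CSV path for [read_clinical()]).
#' @param params named list overriding stage parameters: `wavelet_order`,
#'   `levels`, `lambda_smooth`, `p_asym`, `n_iter`, `segment_len`,
#'   `max_shift`, `k_sigma`, `corr_threshold`, `rt_window`.
#' @return a [feature_matrix()].
#' @export
build_feature_matrix <- function(cohort, clinical, params = list()) {
  p <- modifyList(list(wavelet_order = 4, levels = 2, lambda_smooth = 1e5,
                       p_asym = 0.001, n_iter = 10, segment_len = 100,
                       max_shift = 25, k_sigma = 5, corr_threshold = 0.95,
                       rt_window = 15), params)
  if (is.character(cohort)) cohort <- read_cohort_dir(cohort)
  if (is.character(clinical)) clinical <- read_clinical(clinical)
  ids <- vapply(cohort, `[[`, character(1), "sample_id")
  missing_ids <- setdiff(ids, clinical$sample_id)
  if (length(missing_ids)) {
    bd_validation_error("clinical table is missing sample id(s): ",
                        paste(missing_ids, collapse = ", "))
  }
  bd_log("preprocess: log transform (", length(cohort), " runs)")
  cohort <- lapply(cohort, log_transform)
  bd_log("preprocess: wavelet denoise (db", p$wavelet_order, ", ",
         p$levels, " levels)")
  cohort <- lapply(cohort, wavelet_denoise,
                   wavelet_order = p$wavelet_order, levels = p$levels)
  bd_log("preprocess: ALS baseline (lambda=", format(p$lambda_smooth),
         ", p=", format(p$p_asym), ")")
  cohort <- lapply(cohort, function(r) {
    baseline_correct(r, p$lambda_smooth, p$p_asym, p$n_iter)$run
  })
  bd_log("preprocess: alignment")
  cohort <- align_runs(cohort, p$segment_len, p$max_shift)
  bd_log("preprocess: PQN normalization")
  cohort <- pqn_normalize(cohort)$cohort
  bd_log("preprocess: peak picking")
  feats <- pick_peaks(cohort, p$k_sigma)
  bd_log("preprocess: picked ", length(feats), " peaks; merging")
  feats <- merge_peaks(feats, p$corr_threshold, p$rt_window)
  bd_log("preprocess: ", length(feats), " features after merging")
  if (!length(feats)) bd_stop("no peaks found in cohort")
  areas <- vapply(feats, `[[`, numeric(length(cohort)), "areas")
  if (is.null(dim(areas))) areas <- matrix(areas, nrow = length(cohort))
  rownames(areas) <- ids
  colnames(areas) <- vapply(feats, `[[`, character(1), "peak_id")
  groups <- clinical$group[match(ids, clinical$sample_id)]
  feature_matrix(areas, groups = groups, features = feats)
}
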