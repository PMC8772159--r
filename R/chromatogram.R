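#' Chromatogram run container
#'
#' A `chrom_run` holds one subject's GC-tof-MS acquisition as a dense
#' scan-time x m/z intensity matrix together with its axes and a processing
#' `stage` marker. Stages advance in the fixed pipeline order
#' `raw -> logged -> denoised -> baseline_corrected -> aligned -> normalized`;
#' every preprocessing stage checks that its input is at the preceding stage,
#' so a chain assembled out of order fails loudly instead of silently
#' producing a differently-scaled matrix.
#'
#' @param sample_id character scalar identifying the subject.
#' @param scan_times numeric vector of acquisition times in seconds, strictly
#'   increasing with uniform spacing `1/scan_rate`.
#' @param mz_axis integer vector of nominal (unit-binned) m/z channels,
#'   ascending.
#' @param intensities numeric matrix, `length(scan_times)` rows x
#'   `length(mz_axis)` columns, non-negative, no missing values.
#' @param stage processing stage label (see above).
#' @return An object of class `chrom_run`.
#' @export
chrom_run <- function(sample_id, scan_times, mz_axis, intensities,
                      stage = "raw") {
  run <- structure(
    list(sample_id = as.character(sample_id),
         scan_times = as.numeric(scan_times),
         mz_axis = as.integer(mz_axis),
         intensities = intensities,
         stage = match.arg(stage, chrom_stages())),
    class = "chrom_run")
  validate_chrom_run(run)
  run
}

chrom_stages <- function() {
  c("raw", "logged", "denoised", "baseline_corrected", "aligned", "normalized")
}

validate_chrom_run <- function(run) {
  if (!is.matrix(run$intensities)) {
    bd_validation_error("intensities must be a matrix")
  }
  if (nrow(run$intensities) != length(run$scan_times) ||
      ncol(run$intensities) != length(run$mz_axis)) {
    bd_validation_error(sprintf(
      "dimension mismatch for sample '%s': %d x %d intensities vs %d scans, %d channels",
      run$sample_id, nrow(run$intensities), ncol(run$intensities),
      length(run$scan_times), length(run$mz_axis)))
  }
  if (anyNA(run$intensities) || any(!is.finite(run$intensities))) {
    bd_validation_error("intensities contain missing or non-finite values")
  }
  if (length(run$scan_times) > 1 && any(diff(run$scan_times) <= 0)) {
    bd_validation_error("scan times must be strictly increasing")
  }
  if (is.unsorted(run$mz_axis)) {
    bd_validation_error("m/z axis must be ascending")
  }
  invisible(run)
}

# guard used by every preprocessing stage
check_stage <- function(run, expected) {
  if (!identical(run$stage, expected)) {
    bd_validation_error(sprintf(
      "sample '%s' is at stage '%s' but stage '%s' input is required (pipeline order: %s)",
      run$sample_id, run$stage, expected,
      paste(chrom_stages(), collapse = " -> ")))
  }
  invisible(run)
}

#' @export
print.chrom_run <- function(x, ...) {
  cat(sprintf("<chrom_run '%s'> %d scans x %d m/z channels, stage '%s'\n",
              x$sample_id, nrow(x$intensities), ncol(x$intensities), x$stage))
  invisible(x)
}

#' Total ion current of a run
#'
#' Per-scan sum of intensities across all m/z channels.
#'
#' @param run a `chrom_run`.
#' @return numeric vector, one value per scan.
#' @export
tic <- function(run) rowSums(run$intensities)
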