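#' Read a chromatogram from disk
#'
#' Two formats are supported. `matrix_csv` is this package's plain-text
#' dialect: row 1 is a header `scan_time, <mz1>, <mz2>, ...` and column 1
#' holds the scan times in seconds, so a cohort can be inspected with any
#' spreadsheet tool. `mzml` reads centroided mzML via the `mzR` package;
#' fractional m/z values are binned to the nearest integer channel
#' (ties at .5 round up) within `[mz_min, mz_max]`, summing intensities that
#' fall into the same channel and counting (and logging) discarded
#' out-of-range masses.
#'
#' @param path file path.
#' @param format `"matrix_csv"` or `"mzml"`.
#' @param mz_min,mz_max integer channel bounds used when binning mzML input.
#' @param sample_id sample identifier; defaults to the file stem.
#' @return a raw-stage [chrom_run()]; for mzML input the number of discarded
#'   data points is attached as attribute `"dropped"`.
#' @export
read_chromatogram <- function(path, format = c("matrix_csv", "mzml"),
                              mz_min = 35L, mz_max = 350L,
                              sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) bd_validation_error("file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]+$", "", basename(path))
  }
  if (format == "matrix_csv") {
    df <- tryCatch(read.csv(path, check.names = FALSE),
                   error = function(e) bd_validation_error(
                     "malformed matrix_csv '", path, "': ", conditionMessage(e)))
    if (ncol(df) < 2 || names(df)[1] != "scan_time") {
      bd_validation_error("malformed matrix_csv '", path,
                          "': first column must be 'scan_time'")
    }
    mz <- suppressWarnings(as.numeric(names(df)[-1]))
    if (anyNA(mz)) bd_validation_error("malformed matrix_csv '", path,
                                       "': non-numeric m/z header")
    X <- as.matrix(df[, -1, drop = FALSE])
    if (anyNA(X)) bd_validation_error("matrix_csv '", path, "' contains NA")
    return(chrom_run(sample_id, df$scan_time, as.integer(mz), unname(X)))
  }
  # mzML
  if (!requireNamespace("mzR", quietly = TRUE)) {
    bd_stop("reading mzML requires the 'mzR' package")
  }
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  scan_times <- hdr$retentionTime
  if (any(diff(scan_times) <= 0)) {
    bd_validation_error("mzML '", path, "': non-monotone scan times")
  }
  channels <- seq(as.integer(mz_min), as.integer(mz_max))
  X <- matrix(0, length(pk), length(channels))
  dropped <- 0L
  for (i in seq_along(pk)) {
    m <- pk[[i]]
    if (!nrow(m)) next
    ch <- floor(m[, 1] + 0.5)            # nearest integer, .5 rounds up
    inr <- ch >= mz_min & ch <= mz_max
    dropped <- dropped + sum(!inr)
    if (any(inr)) {
      agg <- tapply(m[inr, 2], ch[inr], sum)
      X[i, as.integer(names(agg)) - as.integer(mz_min) + 1L] <-
        X[i, as.integer(names(agg)) - as.integer(mz_min) + 1L] + agg
    }
  }
  if (dropped > 0) bd_log("mzML '", basename(path), "': dropped ", dropped,
                          " out-of-range data point(s)")
  run <- chrom_run(sample_id, scan_times, channels, X)
  attr(run, "dropped") <- dropped
  run
}

#' Write a chromatogram in the matrix_csv dialect
#'
#' @param run a [chrom_run()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(run, path) {
  df <- data.frame(scan_time = run$scan_times, run$intensities,
                   check.names = FALSE)
  names(df) <- c("scan_time", run$mz_axis)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write and read a cohort directory
#'
#' One `<sample_id>.csv` chromatogram per subject (matrix_csv dialect) plus
#' `clinical.csv`; [write_cohort()] also stores the ground-truth ledger as
#' `truth.json` when given one.
#'
#' @param cohort output of [generate_cohort()] (or a list with `runs` and
#'   `clinical`).
#' @param dir cohort directory.
#' @return `dir` / list of runs, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (run in cohort$runs) {
    write_chromatogram(run, file.path(dir, paste0(run$sample_id, ".csv")))
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(catalog = tr$catalog, disc = tr$disc,
           samples = tr$samples, clinical_loadings = tr$clinical_loadings),
      file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "clinical.csv"]
  if (!length(files)) bd_validation_error("no chromatogram CSVs in ", dir)
  lapply(files, read_chromatogram, format = "matrix_csv")
}

#' Read a clinical table
#'
#' CSV with at least `sample_id` and `group` columns; lung-function columns
#' may be missing (NA) for controls.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    bd_validation_error("clinical table must have 'sample_id' and 'group' columns")
  }
  if (anyNA(df$group)) bd_validation_error("clinical table has missing group labels")
  if (anyDuplicated(df$sample_id)) {
    bd_validation_error("duplicate sample id in clinical table: ",
                        df$sample_id[duplicated(df$sample_id)][1])
  }
  df
}

#' Write / read a feature matrix as CSV
#'
#' Header row of peak ids; first column `sample_id`, second column `group`;
#' lossless round-trip at full double precision.
#'
#' @param fm a [feature_matrix()].
#' @param path CSV path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns a [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(sample_id = fm$sample_ids,
                   group = as.character(fm$groups),
                   fm$areas, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", "group", colnames(fm$areas)),
                   collapse = ","), con)
  for (i in seq_len(nrow(df))) {
    writeLines(paste(c(df$sample_id[i], df$group[i],
                       format(fm$areas[i, ], digits = 17, scientific = TRUE,
                              trim = TRUE)),
                     collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || !identical(names(df)[1:2], c("sample_id", "group"))) {
    bd_validation_error("feature-matrix CSV must start with sample_id,group columns")
  }
  if (anyDuplicated(df$sample_id)) {
    bd_validation_error("duplicate sample id: ",
                        df$sample_id[duplicated(df$sample_id)][1])
  }
  areas <- as.matrix(df[, -(1:2), drop = FALSE])
  if (is.character(areas)) mode(areas) <- "numeric"
  if (nrow(df) && ncol(areas) && anyNA(areas)) {
    bd_validation_error("feature-matrix CSV contains NA areas")
  }
  rownames(areas) <- df$sample_id
  feature_matrix(areas, groups = df$group)
}
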