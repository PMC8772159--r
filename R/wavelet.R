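# Periodized orthonormal Daubechies discrete wavelet transform.
#
# Implemented here because the analysis needs only a 1-D periodized DWT with
# soft thresholding, applied column-wise to large scan x channel matrices.
# The analysis operator is orthogonal, so the synthesis step is its transpose
# and perfect reconstruction holds to machine precision.

# Daubechies extremal-phase decomposition low-pass filters (orthonormal,
# sum = sqrt(2)); dbN has N vanishing moments and 2N taps.
db_filter <- function(order) {
  filters <- list(
    "2" = c(0.482962913144690, 0.836516303737469,
            0.224143868041857, -0.129409522550921),
    "4" = c(0.230377813308897, 0.714846570552916, 0.630880767929859,
            -0.027983769416860, -0.187034811719093, 0.030841381835561,
            0.032883011666885, -0.010597401785069),
    "8" = c(0.054415842243082, 0.312871590914466, 0.675630736298013,
            0.585354683654869, -0.015829105256024, -0.284015542962428,
            0.000472484573998, 0.128747426620186, -0.017369301002022,
            -0.044088253931065, 0.013981027917016, 0.008746094047016,
            -0.004870352993452, -0.000391740372996, 0.000675449405999,
            -0.000117476784003))
  h <- filters[[as.character(order)]]
  if (is.null(h)) bd_config_error("unsupported Daubechies order: ", order,
                                  " (available: 2, 4, 8)")
  h
}

# quadrature-mirror high-pass from the low-pass
qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

# one analysis level, column-wise on a matrix with an even number of rows
dwt_step <- function(x, h) {
  n <- nrow(x)
  g <- qmf(h)
  L <- length(h)
  half <- n / 2L
  a <- matrix(0, half, ncol(x))
  d <- matrix(0, half, ncol(x))
  base <- 2L * (seq_len(half) - 1L)            # 0-based start of each window
  for (j in seq_len(L)) {
    idx <- (base + (j - 1L)) %% n + 1L
    a <- a + h[j] * x[idx, , drop = FALSE]
    d <- d + g[j] * x[idx, , drop = FALSE]
  }
  list(a = a, d = d)
}

# transpose (= inverse) of dwt_step
idwt_step <- function(a, d, h) {
  n <- 2L * nrow(a)
  g <- qmf(h)
  L <- length(h)
  x <- matrix(0, n, ncol(a))
  base <- 2L * (seq_len(nrow(a)) - 1L)
  for (j in seq_len(L)) {
    idx <- (base + (j - 1L)) %% n + 1L
    contrib <- h[j] * a + g[j] * d
    # accumulate: rows may repeat when the filter wraps, so add per tap
    x[idx, ] <- x[idx, , drop = FALSE] + contrib
  }
  x
}

# Multi-level periodized DWT of the columns of x (rows padded by edge
# reflection to a multiple of 2^levels, cropped after reconstruction).
dwt_periodized <- function(x, order = 4, levels = 2) {
  h <- db_filter(order)
  n0 <- nrow(x)
  block <- 2L^levels
  pad <- (block - n0 %% block) %% block
  if (n0 < length(h)) {
    bd_stop("trace of length ", n0, " is shorter than the db", order,
            " filter support (", length(h), ")")
  }
  if (pad > 0) x <- rbind(x, x[n0 - seq_len(pad) + 1L, , drop = FALSE])
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    st <- dwt_step(a, h)
    a <- st$a
    details[[lev]] <- st$d
  }
  list(approx = a, details = details, order = order, n0 = n0, pad = pad)
}

idwt_periodized <- function(decomp) {
  h <- db_filter(decomp$order)
  a <- decomp$approx
  for (lev in rev(seq_along(decomp$details))) {
    a <- idwt_step(a, decomp$details[[lev]], h)
  }
  a[seq_len(decomp$n0), , drop = FALSE]
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)
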