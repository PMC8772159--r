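#' First canonical correlation between a VOC block and a clinical block
#'
#' Canonical correlation analysis finds paired linear combinations of two
#' variable blocks with maximal correlation; it extends the pairwise Pearson
#' correlation to whole variable sets. Both blocks are `ln(1 + x)`
#' transformed (the measurement scales are multiplicative) and column-
#' standardized; canonical directions come from the standard generalized
#' eigenproblem with a ridge term `ridge * I` added to both within-block
#' covariances to keep the problem well-posed when columns are collinear.
#'
#' @param X numeric matrix, the VOC block (complete cases only).
#' @param Y numeric matrix, the clinical block.
#' @param ridge ridge added to both within-block correlation matrices.
#' @param log_transform apply `ln(1 + x)` to both blocks first.
#' @return object of class `cca_result`: canonical weights `wx`, `wy`, the
#'   first canonical correlation `rho1`, and the unit-variance canonical
#'   variates `u`, `v` (one pair of per-sample scores).
#' @export
cca_first <- function(X, Y, ridge = 1e-3, log_transform = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (anyNA(X) || anyNA(Y)) bd_validation_error("CCA blocks must be complete cases")
  if (nrow(X) != nrow(Y)) bd_validation_error("blocks have different sample counts")
  if (nrow(X) <= max(ncol(X), ncol(Y))) {
    bd_validation_error("need more samples than columns in each block")
  }
  if (log_transform) {
    if (any(X < 0) || any(Y < 0)) {
      bd_validation_error("log transform requires non-negative blocks")
    }
    X <- log1p(X); Y <- log1p(Y)
  }
  for (blk in list(X = X, Y = Y)) {
    sds <- apply(blk, 2, sd)
    if (any(sds == 0)) {
      nm <- colnames(blk)[which(sds == 0)[1]]
      bd_validation_error("constant column in CCA block: ",
                          if (is.null(nm)) which(sds == 0)[1] else nm)
    }
  }
  Xs <- scale(X); Ys <- scale(Y)
  n <- nrow(Xs)
  Cxx <- crossprod(Xs) / (n - 1) + ridge * diag(ncol(Xs))
  Cyy <- crossprod(Ys) / (n - 1) + ridge * diag(ncol(Ys))
  Cxy <- crossprod(Xs, Ys) / (n - 1)
  ex <- eigen(Cxx, symmetric = TRUE)
  ey <- eigen(Cyy, symmetric = TRUE)
  Sxi <- ex$vectors %*% diag(1 / sqrt(pmax(ex$values, 1e-12)),
                             ncol(Xs)) %*% t(ex$vectors)
  Syi <- ey$vectors %*% diag(1 / sqrt(pmax(ey$values, 1e-12)),
                             ncol(Ys)) %*% t(ey$vectors)
  sv <- svd(Sxi %*% Cxy %*% Syi)
  wx <- drop(Sxi %*% sv$u[, 1]); wy <- drop(Syi %*% sv$v[, 1])
  u <- drop(Xs %*% wx); v <- drop(Ys %*% wy)
  rho1 <- abs(cor(u, v))
  if (cor(u, v) < 0) { wy <- -wy; v <- -v }
  u <- u / sd(u); v <- v / sd(v)
  names(wx) <- colnames(X); names(wy) <- colnames(Y)
  structure(list(wx = wx, wy = wy, rho1 = rho1, u = u, v = v,
                 ridge = ridge, log_transform = log_transform,
                 selected = colnames(Y), perm_p = NA_real_),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> rho1 = %.4f over %d VOC x %d clinical columns",
              x$rho1, length(x$wx), length(x$wy)))
  if (!is.na(x$perm_p)) cat(sprintf(", permutation p = %.4g", x$perm_p))
  cat("\n")
  invisible(x)
}

#' Permutation p-value for the first canonical correlation
#'
#' Rows of `Y` are permuted `B` times, breaking the X-Y link while keeping
#' both within-block structures; `p = (1 + #{rho1_perm >= rho1_obs}) / (B + 1)`.
#'
#' @inheritParams cca_first
#' @param B number of permutations.
#' @param seed RNG seed.
#' @return the permutation p-value (in `[1/(B+1), 1]`).
#' @export
cca_permutation_p <- function(X, Y, B = 9999, ridge = 1e-3,
                              log_transform = TRUE, seed = 1L) {
  if (B < 1) bd_stop("B must be >= 1")
  obs <- cca_first(X, Y, ridge, log_transform)$rho1
  Y <- as.matrix(Y)
  set.seed(seed)
  n <- nrow(Y)
  exceed <- 0L
  for (b in seq_len(B)) {
    rho_b <- cca_first(X, Y[sample.int(n), , drop = FALSE],
                       ridge, log_transform)$rho1
    if (rho_b >= obs) exceed <- exceed + 1L
  }
  (1 + exceed) / (B + 1)
}

#' Greedy subset selection of clinical parameters for CCA
#'
#' Adds clinical columns one at a time, at each step taking the candidate
#' whose addition maximizes the permutation-corrected first canonical
#' correlation: `rho1` of the enlarged model minus the mean of `rho1` over
#' `B_inner` conditional permutations in which only the candidate column is
#' row-permuted (already-selected columns keep their pairing with the VOC
#' block). The conditional null prices exactly what an uninformative column
#' of the same marginal distribution would add, so the criterion penalizes
#' the optimistic growth of `rho1` with block size without masking a second
#' genuinely coupled column. A step is admitted only when its `rho1` also
#' exceeds the `1 - admit_alpha` conditional-permutation quantile (without
#' this test the maximum over candidates admits a spurious column in most
#' unrelated datasets; the level is Bonferroni-shared across the candidates
#' examined in a step). Selection stops when no admissible addition remains
#' or at `max_params`; the final model is refit on the selected subset with
#' a fresh `B_final`-permutation p-value.
#'
#' @param X the VOC block.
#' @param Y_full matrix of all candidate clinical columns (named).
#' @param max_params maximum number of clinical columns.
#' @param B_inner permutations per candidate evaluation.
#' @param B_final permutations for the final p-value.
#' @param admit_alpha per-step admission level (see above).
#' @inheritParams cca_first
#' @param seed RNG seed.
#' @return a `cca_result` for the selected subset, with `selected` and
#'   `perm_p` filled in, and the selection `path` attached.
#' @export
cca_subset_select <- function(X, Y_full, max_params = 8, B_inner = 100,
                              B_final = 999, ridge = 1e-3,
                              log_transform = TRUE, admit_alpha = 0.05,
                              seed = 1L) {
  Y_full <- as.matrix(Y_full)
  if (is.null(colnames(Y_full))) colnames(Y_full) <- paste0("Y", seq_len(ncol(Y_full)))
  set.seed(seed)
  step_alpha <- admit_alpha   # rescaled per step by the candidate count
  corrected_rho <- function(cols, cand_col) {
    Y <- Y_full[, cols, drop = FALSE]
    rho <- cca_first(X, Y, ridge, log_transform)$rho1
    n <- nrow(Y)
    perm <- vapply(seq_len(B_inner), function(b) {
      Yp <- Y
      Yp[, cand_col] <- Yp[sample.int(n), cand_col]
      cca_first(X, Yp, ridge, log_transform)$rho1
    }, numeric(1))
    c(rho = rho, corrected = rho - mean(perm),
      admit = unname(quantile(perm, 1 - step_alpha)))
  }
  selected <- character(0)
  path <- list()
  while (length(selected) < max_params) {
    remaining <- setdiff(colnames(Y_full), selected)
    if (!length(remaining)) break
    step_alpha <- admit_alpha / length(remaining)
    cand <- vapply(remaining,
                   function(col) corrected_rho(c(selected, col), col),
                   numeric(3))
    pick <- which.max(cand["corrected", ])
    if (cand["corrected", pick] <= 1e-12 ||
        cand["rho", pick] <= cand["admit", pick]) break
    selected <- c(selected, remaining[pick])
    path[[length(path) + 1]] <- list(added = remaining[pick],
                                     rho = cand["rho", pick],
                                     corrected = cand["corrected", pick])
    bd_log(sprintf("CCA subset selection: + %s (rho1 %.3f, corrected %.3f)",
                   remaining[pick], cand["rho", pick],
                   cand["corrected", pick]))
  }
  if (!length(selected)) {
    bd_log("CCA subset selection: no clinical column improves on the null")
    res <- structure(list(wx = NULL, wy = NULL, rho1 = NA_real_,
                          u = NULL, v = NULL, ridge = ridge,
                          log_transform = log_transform,
                          selected = character(0), perm_p = NA_real_),
                     class = "cca_result")
    attr(res, "path") <- path
    return(res)
  }
  res <- cca_first(X, Y_full[, selected, drop = FALSE], ridge, log_transform)
  res$selected <- selected
  res$perm_p <- cca_permutation_p(X, Y_full[, selected, drop = FALSE],
                                  B = B_final, ridge = ridge,
                                  log_transform = log_transform,
                                  seed = seed + 1L)
  attr(res, "path") <- path
  res
}

#' Regularized MANOVA test for a confounder
#'
#' Tests whether a study parameter (age, sex, smoking, ...) structures the
#' selected discriminatory VOC block. The statistic is a shrinkage Wilks
#' ratio `det(W + gamma I) / det(T + gamma I)` (within vs total scatter of
#' the VOC block across the factor's levels), with `gamma` set by a
#' Ledoit-Wolf-style rule on the pooled within-group covariance so the test
#' remains usable when variables approach the sample count. Significance is
#' assessed by permuting the factor labels. Continuous factors are
#' dichotomized at the median (logged).
#'
#' @param X numeric matrix of the discriminatory VOC block (samples x VOCs).
#' @param factor_values categorical (factor/character) or numeric confounder.
#' @param B number of permutations.
#' @param factor_name label used in reporting.
#' @param seed RNG seed.
#' @return object of class `rmanova_result`: `statistic` (shrinkage Wilks
#'   ratio, small = strong effect), `gamma`, `p_value`, `factor_name`.
#' @export
rmanova_confounder <- function(X, factor_values, B = 999,
                               factor_name = deparse(substitute(factor_values)),
                               seed = 1L) {
  X <- as.matrix(X)
  if (is.numeric(factor_values) && length(unique(factor_values)) > 2) {
    bd_log("rMANOVA: dichotomizing continuous factor '", factor_name,
           "' at the median")
    factor_values <- factor(factor_values > median(factor_values),
                            labels = c("low", "high"))
  }
  f <- factor(factor_values)
  f <- droplevels(f)
  if (nlevels(f) < 2) bd_stop("factor '", factor_name, "' has a single level")
  if (any(table(f) < 2)) bd_stop("factor '", factor_name,
                                 "' has a level with fewer than 2 samples")
  stat <- rmanova_statistic(X, f)
  set.seed(seed)
  n <- nrow(X)
  exceed <- 0L
  for (b in seq_len(B)) {
    s_b <- rmanova_statistic(X, f[sample.int(n)], gamma = stat["gamma"])
    if (s_b["lambda"] <= stat["lambda"]) exceed <- exceed + 1L
  }
  structure(list(factor_name = factor_name,
                 levels = levels(f),
                 statistic = unname(stat["lambda"]),
                 gamma = unname(stat["gamma"]),
                 B = B,
                 p_value = (1 + exceed) / (B + 1)),
            class = "rmanova_result")
}

# shrinkage Wilks ratio; gamma estimated once on the observed grouping and
# reused for permutations so the statistic is comparable across relabelings
rmanova_statistic <- function(X, f, gamma = NULL) {
  n <- nrow(X); p <- ncol(X)
  Xc_tot <- scale(X, center = TRUE, scale = FALSE)
  T_ <- crossprod(Xc_tot)
  W <- matrix(0, p, p)
  for (lv in levels(f)) {
    rows <- f == lv
    Xg <- scale(X[rows, , drop = FALSE], center = TRUE, scale = FALSE)
    W <- W + crossprod(Xg)
  }
  if (is.null(gamma)) {
    S <- W / (n - nlevels(f))
    gamma <- ledoit_wolf_gamma(X, f, S) * (n - nlevels(f))
  }
  lam <- det_ratio(W + diag(gamma, p), T_ + diag(gamma, p))
  c(lambda = lam, gamma = gamma)
}

# ratio of determinants via log-determinants (avoids overflow for large p)
det_ratio <- function(A, B) {
  exp(determinant(A, logarithm = TRUE)$modulus -
        determinant(B, logarithm = TRUE)$modulus)[1]
}

# Ledoit-Wolf-style shrinkage intensity toward mu*I on the pooled
# within-group covariance; returns lambda* x mu (the additive ridge)
ledoit_wolf_gamma <- function(X, f, S) {
  p <- ncol(S)
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, p))^2)
  if (d2 < 1e-300) return(1e-8 * max(mu, 1))
  # dispersion of per-observation outer products around S, pooled over groups
  b2 <- 0; n_eff <- 0
  for (lv in levels(f)) {
    Xg <- scale(X[f == lv, , drop = FALSE], center = TRUE, scale = FALSE)
    ng <- nrow(Xg)
    for (i in seq_len(ng)) {
      b2 <- b2 + sum((tcrossprod(Xg[i, ]) - S)^2)
    }
    n_eff <- n_eff + ng
  }
  b2 <- min(b2 / n_eff^2, d2)
  shrink <- b2 / d2
  max(shrink * mu, 1e-8 * max(mu, 1))
}

#' @export
print.rmanova_result <- function(x, ...) {
  cat(sprintf("<rmanova> %s (%s): Wilks-type %.4f (gamma %.3g), permutation p = %.4g\n",
              x$factor_name, paste(x$levels, collapse = "/"),
              x$statistic, x$gamma, x$p_value))
  invisible(x)
}

#' Confounder report across factors and group comparisons
#'
#' Runs [rmanova_confounder()] for every (factor, comparison) pair, testing
#' whether the confounder structures the discriminatory VOC block within the
#' samples of that comparison.
#'
#' @param fm a [feature_matrix()] (typically restricted to selected VOCs).
#' @param clinical clinical table with the factor columns.
#' @param factors character vector of clinical column names to test.
#' @param comparisons list of group-label pairs.
#' @param B permutations per test.
#' @param seed RNG seed.
#' @return data.frame with one row per (factor, comparison): statistic,
#'   gamma, p_value.
#' @export
confounder_report <- function(fm, clinical, factors = c("age", "sex", "smoking"),
                              comparisons = list(c("control", "IPF-like"),
                                                 c("control", "CTD-like"),
                                                 c("IPF-like", "CTD-like")),
                              B = 999, seed = 1L) {
  rows <- list()
  for (fac in factors) {
    if (!fac %in% names(clinical)) bd_stop("unknown clinical column: ", fac)
    for (cmp in comparisons) {
      keep_ids <- clinical$sample_id[clinical$group %in% cmp]
      idx <- fm$sample_ids %in% keep_ids
      vals <- clinical[[fac]][match(fm$sample_ids[idx], clinical$sample_id)]
      res <- tryCatch(
        rmanova_confounder(fm$areas[idx, , drop = FALSE], vals, B = B,
                           factor_name = fac, seed = seed),
        breathdisc_error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        factor = fac, comparison = paste(cmp, collapse = " vs "),
        statistic = if (is.null(res)) NA_real_ else res$statistic,
        gamma = if (is.null(res)) NA_real_ else res$gamma,
        p_value = if (is.null(res)) NA_real_ else res$p_value)
    }
  }
  do.call(rbind, rows)
}

#' Univariate group-comparison battery
#'
#' For every variable: a two-sample t-test (Welch by default) between the
#' two groups, Benjamini-Hochberg FDR adjustment across the whole battery,
#' and a Lilliefors normality check (Kolmogorov-Smirnov against the normal
#' with estimated parameters) per group. Zero-variance variables are flagged
#' and excluded from the FDR battery.
#'
#' @param data data.frame or matrix of variables (columns) by samples (rows).
#' @param grouping factor with two levels.
#' @param welch use Welch's unequal-variance t-test (pooled-variance
#'   Student's t when `FALSE`).
#' @return data.frame with one row per variable: `t`, `p_raw`, `p_fdr`,
#'   `lilliefors_pass` (both groups consistent with normality at alpha 0.05),
#'   `excluded` flag.
#' @export
univariate_table <- function(data, grouping, welch = TRUE) {
  data <- as.data.frame(data)
  g <- factor(grouping)
  if (nlevels(g) != 2) bd_stop("grouping must have exactly two levels")
  out <- lapply(names(data), function(v) {
    x <- data[[v]]
    ok <- !is.na(x)
    x1 <- x[ok & g == levels(g)[1]]
    x2 <- x[ok & g == levels(g)[2]]
    if (length(x1) < 2 || length(x2) < 2 || (sd(x1) == 0 && sd(x2) == 0)) {
      return(data.frame(variable = v, t = NA_real_, p_raw = NA_real_,
                        lilliefors_pass = NA, excluded = TRUE))
    }
    tt <- t.test(x1, x2, var.equal = !welch)
    lil_ok <- all(vapply(list(x1, x2), function(z) {
      if (length(z) < 5 || sd(z) == 0) return(NA)  # Lilliefors needs n >= 5
      nortest::lillie.test(z)$p.value >= 0.05
    }, logical(1)), na.rm = TRUE)
    data.frame(variable = v, t = unname(tt$statistic),
               p_raw = tt$p.value, lilliefors_pass = lil_ok, excluded = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_fdr <- NA_real_
  inb <- !out$excluded
  out$p_fdr[inb] <- p.adjust(out$p_raw[inb], method = "BH")
  out
}
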