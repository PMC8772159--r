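#' Duplex train/test split
#'
#' Deterministic, distance-based sample partitioning. Per class, on z-scored
#' features with Euclidean distance: the two mutually farthest samples seed
#' the TRAIN set; the two farthest among the remaining samples seed the TEST
#' set; thereafter the sets alternately (TRAIN first) receive the unassigned
#' sample maximizing its minimum distance to the receiving set, until TEST
#' reaches its quota of `round(test_frac * n_class)` (half-up); all remaining
#' samples go to TRAIN. Ties are broken by the smaller sample index, so the
#' split is identical on every call.
#'
#' @param fm a [feature_matrix()].
#' @param classes character vector of the two group labels to split.
#' @param test_frac fraction of each class reserved for the test set.
#' @return an object of class `split_plan` with `train_ids`, `test_ids`,
#'   per-class counts, and the assignment trace.
#' @export
duplex_split <- function(fm, classes, test_frac = 0.2) {
  if (length(classes) != 2) bd_stop("classes must name exactly two groups")
  absent <- setdiff(classes, levels(fm$groups))
  if (length(absent)) bd_stop("class not present in data: ",
                              paste(absent, collapse = ", "))
  keep <- fm$groups %in% classes
  X <- fm$areas[keep, , drop = FALSE]
  grp <- droplevels(fm$groups[keep])
  sds <- apply(X, 2, sd)
  Xz <- scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  train_ids <- character(0); test_ids <- character(0)
  trace <- list()
  for (cl in classes) {
    idx <- which(grp == cl)
    n_cl <- length(idx)
    if (n_cl < 5) bd_stop("class '", cl, "' has fewer than 5 samples")
    quota <- round_half_up(test_frac * n_cl)
    if (quota < 1) bd_stop("test quota is 0 for class '", cl, "'")
    D <- as.matrix(dist(Xz[idx, , drop = FALSE]))
    ids <- rownames(X)[idx]
    unassigned <- seq_len(n_cl)
    farthest_pair <- function(avail) {
      sub <- D[avail, avail, drop = FALSE]
      best <- c(1L, 2L); bestd <- -Inf
      for (a in seq_along(avail)) {
        for (b in seq_along(avail)) {
          if (b <= a) next
          if (sub[a, b] > bestd + 1e-12) { bestd <- sub[a, b]; best <- c(a, b) }
        }
      }
      sort(avail[best])
    }
    tr <- farthest_pair(unassigned)
    unassigned <- setdiff(unassigned, tr)
    te <- if (quota >= 2) farthest_pair(unassigned) else {
      # quota of one: take the sample farthest from the TRAIN seeds
      unassigned[which.max(apply(D[unassigned, tr, drop = FALSE], 1, min))][1]
    }
    te <- te[seq_len(min(length(te), quota))]
    unassigned <- setdiff(unassigned, te)
    next_for <- function(set) {
      dmin <- apply(D[unassigned, set, drop = FALSE], 1, min)
      unassigned[which.max(dmin)]       # which.max takes the first (smallest index) tie
    }
    turn <- "train"
    while (length(unassigned) && length(te) < quota) {
      if (turn == "train") {
        pick <- next_for(tr); tr <- c(tr, pick); turn <- "test"
      } else {
        pick <- next_for(te); te <- c(te, pick); turn <- "train"
      }
      unassigned <- setdiff(unassigned, pick)
    }
    tr <- c(tr, unassigned)
    train_ids <- c(train_ids, ids[tr])
    test_ids <- c(test_ids, ids[te])
    trace[[cl]] <- list(train = ids[tr], test = ids[te], quota = quota)
  }
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 classes = classes, test_frac = test_frac,
                 counts = vapply(trace, function(t) {
                   c(train = length(t$train), test = length(t$test))
                 }, numeric(2)),
                 metric = "euclidean on z-scored features",
                 trace = trace),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s: train %s / test %s (Duplex, %s)\n",
              paste(x$classes, collapse = " vs "),
              paste(x$counts["train", ], collapse = "+"),
              paste(x$counts["test", ], collapse = "+"), x$metric))
  invisible(x)
}

#' Train a binary Random-Forest discrimination model
#'
#' Fits a forest on the TRAIN samples of the split only. The out-of-bag
#' (OOB) error is the forest's internal generalization error (each sample
#' judged only by trees that never saw it); model accuracy is `1 - error`.
#' Variable importance is the Breiman permutation importance (mean decrease
#' in OOB accuracy when a feature is permuted, unscaled). The proximity of
#' two samples is the fraction of trees in which they land in the same
#' terminal node, computed over all samples of the split (train and test) —
#' large proximity means similar VOC profiles, and `1 - proximity` is the
#' learned distance. For pairs of training samples the count is restricted
#' to trees in which both were out of bag: proximities read off the fitted
#' trees directly would reflect the memorized training labels rather than
#' the VOC structure (a label-shuffled cohort would still look separated),
#' while OOB proximities stay flat under the null.
#'
#' @param fm a [feature_matrix()].
#' @param classes the pair of group labels (the first non-control label, or
#'   the first of the pair, is the positive class for sensitivity).
#' @param split a `split_plan` from [duplex_split()].
#' @param n_trees number of trees.
#' @param mtry features tried per node split; default `floor(sqrt(p))`.
#' @param seed RNG seed for the forest (mandatory; no hidden RNG state).
#' @param features optional character vector restricting the model to a
#'   subset of peak columns.
#' @return an object of class `binary_rf`.
#' @export
train_forest <- function(fm, classes, split, n_trees = 1000, mtry = NULL,
                         seed = 1L, features = NULL) {
  X <- fm$areas
  if (!is.null(features)) {
    missing_f <- setdiff(features, colnames(X))
    if (length(missing_f)) bd_stop("unknown feature(s): ",
                                   paste(missing_f, collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  all_ids <- c(split$train_ids, split$test_ids)
  y <- factor(as.character(fm$groups[match(all_ids, fm$sample_ids)]),
              levels = classes)
  X <- X[match(all_ids, rownames(X)), , drop = FALSE]
  is_test <- all_ids %in% split$test_ids
  y_train <- y[!is_test]
  if (length(unique(y_train)) < 2) {
    bd_stop("degenerate split: training set contains a single class")
  }
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(X))))
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = as.data.frame(X[!is_test, , drop = FALSE]), y = y_train,
    ntree = n_trees, mtry = mtry, importance = TRUE, keep.forest = TRUE,
    proximity = TRUE, oob.prox = TRUE)
  oob_pred <- rf$predicted
  oob_error <- mean(oob_pred != y_train)
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  prox <- predict(rf, as.data.frame(X), proximity = TRUE)$proximity
  dimnames(prox) <- list(all_ids, all_ids)
  # train-train block from OOB co-occupancy (honest similarity)
  prox[!is_test, !is_test] <- rf$proximity
  structure(list(class_pair = classes, n_trees = n_trees, mtry = mtry,
                 seed = seed, rf = rf,
                 feature_names = colnames(X),
                 sample_ids = all_ids, is_test = is_test, y = y,
                 training_features = X,
                 oob_error = oob_error, oob_accuracy = 1 - oob_error,
                 importance = imp,
                 proximity = prox,
                 selected_vocs = NULL, test_metrics = NULL, roc = NULL,
                 embedding = NULL),
            class = "binary_rf")
}

#' @export
print.binary_rf <- function(x, ...) {
  cat(sprintf("<binary_rf> %s: %d trees, mtry %d, OOB accuracy %.3f\n",
              paste(x$class_pair, collapse = " vs "), x$n_trees, x$mtry,
              x$oob_accuracy))
  if (!is.null(x$test_metrics)) {
    cat(sprintf("  test: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
                x$test_metrics["accuracy"], x$test_metrics["sensitivity"],
                x$test_metrics["specificity"], x$roc$auc))
  }
  invisible(x)
}

#' Select discriminatory VOCs from the importance ranking
#'
#' Reproducible surrogate for an importance cut-off drawn by eye: the
#' visibly dominant VOCs are separated from the noise shelf
#' at the largest consecutive gap of the descending importance ranking,
#' measured on the log scale (importance spectra decay multiplicatively, so
#' the signal/noise boundary is a fold-change break, not the largest
#' absolute drop — that is usually between ranks 1 and 2). Within the top
#' `max_considered`, candidate cut positions are restricted to features with
#' at least 10% of the top importance (a cut must keep only standouts), and
#' values are clamped at `max importance / 1000` so near-zero permutation
#' importances in the tail cannot produce spurious fold changes. If the
#' largest log-gap does not exceed twice the median log-gap the ranking has
#' no natural elbow, and a configured fixed count is taken instead (with a
#' warning).
#'
#' @param model a `binary_rf` from [train_forest()].
#' @param max_considered ranking depth searched for the gap.
#' @param fallback_count number of top features selected when no dominant
#'   gap exists.
#' @return character vector of selected feature names.
#' @export
select_discriminatory_vocs <- function(model, max_considered = 50,
                                       fallback_count = 10) {
  imp <- sort(model$importance, decreasing = TRUE)
  if (all(imp <= 0)) bd_stop("no discriminatory signal: all importances <= 0")
  m <- min(max_considered, length(imp))
  top <- imp[seq_len(m)]
  eps <- max(top) * 1e-3
  clamped <- pmax(top, eps)
  gaps <- diff(-log(clamped))            # log fold-change between neighbours
  cand <- which(top[-m] >= 0.1 * top[1]) # cut must keep only standouts
  cut <- cand[which.max(gaps[cand])]
  if (max(gaps[cand]) <= 2 * median(gaps)) {
    warning(sprintf("no dominant importance gap (max log-gap %.3g <= 2 x median %.3g); falling back to top %d",
                    max(gaps[cand]), median(gaps), fallback_count))
    cut <- min(fallback_count, m)
  }
  names(top)[seq_len(cut)]
}

#' Refit on the selected VOCs and validate on the test set
#'
#' The final model is refit on the TRAIN samples restricted to the selected
#' features, then applied once to the held-out Duplex TEST samples: accuracy,
#' sensitivity and specificity at vote threshold 0.5 (positive class = the
#' disease class, or the first of the pair for disease-disease contrasts),
#' a full ROC over vote-fraction thresholds with trapezoidal AUC, and the
#' proximity embedding of the refit forest.
#'
#' @inheritParams train_forest
#' @param selected_vocs feature names from [select_discriminatory_vocs()].
#' @param n_components embedding dimensions retained.
#' @return a `binary_rf` with `selected_vocs`, `test_metrics`, `oob` and
#'   `roc` filled in and the proximity embedding attached.
#' @export
refit_and_validate <- function(fm, classes, split, selected_vocs,
                               n_trees = 1000, mtry = NULL, seed = 1L,
                               n_components = 3) {
  if (!length(selected_vocs)) bd_stop("selected_vocs is empty")
  model <- train_forest(fm, classes, split, n_trees = n_trees, mtry = mtry,
                        seed = seed, features = selected_vocs)
  model$selected_vocs <- selected_vocs
  pos <- positive_class(classes)
  votes <- predict(model$rf,
                   as.data.frame(fm$areas[match(split$test_ids, fm$sample_ids),
                                          selected_vocs, drop = FALSE]),
                   type = "vote")[, pos]
  y_test <- factor(as.character(fm$groups[match(split$test_ids, fm$sample_ids)]),
                   levels = classes)
  truth_pos <- y_test == pos
  pred_pos <- votes >= 0.5
  model$test_metrics <- c(
    accuracy = mean(pred_pos == truth_pos),
    sensitivity = mean(pred_pos[truth_pos]),
    specificity = mean(!pred_pos[!truth_pos]))
  model$test_error <- 1 - model$test_metrics[["accuracy"]]
  model$roc <- roc_curve(votes[truth_pos], votes[!truth_pos])
  model$positive_class <- pos
  model$embedding <- proximity_embed(model, n_components = n_components)
  model
}

positive_class <- function(classes) {
  non_ctrl <- classes[!grepl("control", classes, ignore.case = TRUE)]
  if (length(non_ctrl) == 1) non_ctrl else classes[1]
}

#' ROC curve over vote-fraction thresholds
#'
#' @param scores_pos,scores_neg classifier scores (e.g. vote fractions for
#'   the positive class) of truly positive / truly negative samples.
#' @return an object of class `roc_curve`: descending `thresholds`,
#'   `sensitivity`, `specificity`, and trapezoidal `auc`.
#' @export
roc_curve <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg)) {
    bd_stop("both score lists must be non-empty")
  }
  thr <- sort(unique(c(scores_pos, scores_neg, -Inf, Inf)), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores_pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores_neg < t), numeric(1))
  fpr <- 1 - spec
  auc_trap <- sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc_trap),
            class = "roc_curve")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive scores above a random negative,
#' ties counting one half: the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg)) {
    bd_stop("both score lists must be non-empty")
  }
  r <- rank(c(scores_pos, scores_neg))   # mean ranks handle ties as 1/2
  n1 <- length(scores_pos)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(scores_neg))
}

#' Classical-scaling embedding of the RF proximity matrix
#'
#' The learned distance is `D = 1 - proximity`. Classical scaling double-
#' centers the squared distances, `B = -1/2 J D^2 J`, and eigendecomposes
#' `B`; scores are eigenvectors scaled by the square roots of their
#' eigenvalues. Negative eigenvalues (the proximity distance need not be
#' Euclidean) are truncated at zero with a logged count. This is the "PCA on
#' RF proximities" view of a binary model.
#'
#' @param model a `binary_rf` with a proximity matrix.
#' @param n_components number of leading components to keep.
#' @return object of class `prox_embedding`: `scores` (samples x components),
#'   `eigenvalues`, `vectors`, and the row means of `D^2` needed for
#'   out-of-sample projection.
#' @export
proximity_embed <- function(model, n_components = 3) {
  P <- model$proximity
  D2 <- (1 - P)^2
  n <- nrow(D2)
  rm_ <- rowMeans(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(D2))
  eg <- eigen(B, symmetric = TRUE)
  ev <- eg$values
  n_neg <- sum(ev < -1e-10)
  if (n_neg > 0) bd_log("proximity embedding: truncated ", n_neg,
                        " negative eigenvalue(s) at 0")
  ev <- pmax(ev, 0)
  n_pos <- sum(ev > 1e-12)
  if (n_components > n_pos) {
    warning(sprintf("only %d positive eigenvalues; reducing n_components from %d",
                    n_pos, n_components))
    n_components <- max(n_pos, 1L)
  }
  k <- seq_len(n_components)
  scores <- sweep(eg$vectors[, k, drop = FALSE], 2, sqrt(ev[k]), `*`)
  rownames(scores) <- rownames(P)
  structure(list(scores = scores, eigenvalues = ev[k],
                 vectors = eg$vectors[, k, drop = FALSE],
                 d2_row_means = rm_, n = n),
            class = "prox_embedding")
}

#' Project new samples into a model's proximity-PCA space
#'
#' A sample outside a binary model's data is passed through the fitted
#' forest; its proximity to each model sample (fraction of shared terminal
#' nodes) gives squared distances `d^2`, and the Gower out-of-sample
#' extension `score_k = -(d^2 - rowmeans(D^2)) . v_k / (2 sqrt(lambda_k))`
#' places it in the training embedding. Projecting a sample already in the
#' model reproduces its embedding coordinates (exactly for held-out model
#' samples; approximately for training samples, whose stored proximities are
#' the OOB-restricted ones).
#'
#' @param model an embedded `binary_rf` (see [refit_and_validate()]).
#' @param sample_features numeric matrix (samples x features) containing the
#'   model's selected features (by name), or a single named vector.
#' @return matrix of projected scores (samples x components).
#' @export
project_sample <- function(model, sample_features) {
  if (is.null(model$embedding)) bd_stop("model has no embedding; run refit_and_validate")
  if (is.null(dim(sample_features))) {
    sample_features <- matrix(sample_features, nrow = 1,
                              dimnames = list("new", names(sample_features)))
  }
  missing_f <- setdiff(model$feature_names, colnames(sample_features))
  if (length(missing_f)) bd_stop("sample lacks model feature(s): ",
                                 paste(missing_f, collapse = ", "))
  Xn <- sample_features[, model$feature_names, drop = FALSE]
  Xm <- model$training_features
  if (is.null(Xm)) bd_stop("model lacks stored features for projection")
  combined <- rbind(Xm, Xn)
  prox <- predict(model$rf, as.data.frame(combined), proximity = TRUE)$proximity
  n <- nrow(Xm)
  cross <- prox[seq_len(n), n + seq_len(nrow(Xn)), drop = FALSE]
  emb <- model$embedding
  d2 <- (1 - cross)^2                     # n x n_new
  centered <- d2 - emb$d2_row_means       # recycled by column
  scores <- t(centered) %*% emb$vectors
  denom <- -2 * sqrt(emb$eigenvalues)
  scores <- sweep(scores, 2, ifelse(abs(denom) > 1e-12, denom, Inf), `/`)
  rownames(scores) <- rownames(Xn)
  scores
}
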