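#' Hierarchical fusion of the three binary models
#'
#' A direct multi-class forest is harder to optimize and interpret than a
#' set of well-validated binary models, so the three pairwise models are
#' combined instead: every cohort sample is placed into each binary model's
#' proximity-PCA space (its own training scores when the sample belongs to
#' that model, the Gower out-of-sample projection otherwise), the first `k`
#' coordinates from each model are concatenated into a fused score vector,
#' and a final PCA of the concatenation gives a 3-D view of all three groups
#' at once. The silhouette of the group labels in that 3-D view is computed
#' and logged as a separation summary.
#'
#' @param models list of three embedded `binary_rf` models covering the
#'   three pairwise contrasts (see [refit_and_validate()]).
#' @param fm the full-cohort [feature_matrix()].
#' @param k components taken from each binary model.
#' @return an object of class `fusion_scores`: data.frame `scores` with
#'   sample id, group, the `3 * k` fused coordinates and the 3-D projection
#'   (`PC1..PC3`), plus `silhouette` (mean silhouette width by group) and
#'   the `prcomp` rotation used for the view.
#' @export
fuse_models <- function(models, fm, k = 2) {
  if (length(models) != 3 || any(!vapply(models, inherits, logical(1), "binary_rf"))) {
    bd_stop("fusion needs exactly three fitted binary_rf models")
  }
  for (m in models) {
    if (is.null(m$embedding)) bd_stop("model ", paste(m$class_pair, collapse = "/"),
                                      " has no embedding")
  }
  ids <- fm$sample_ids
  blocks <- lapply(models, function(m) {
    kk <- min(k, ncol(m$embedding$scores))
    out <- matrix(NA_real_, length(ids), kk)
    rownames(out) <- ids
    inside <- ids %in% m$sample_ids
    if (any(inside)) {
      out[inside, ] <- m$embedding$scores[match(ids[inside], m$sample_ids),
                                          seq_len(kk), drop = FALSE]
    }
    if (any(!inside)) {
      proj <- project_sample(m, fm$areas[match(ids[!inside], fm$sample_ids), ,
                                         drop = FALSE][, m$feature_names,
                                                       drop = FALSE])
      out[!inside, ] <- proj[, seq_len(kk), drop = FALSE]
    }
    colnames(out) <- sprintf("%s_c%d",
                             paste(abbreviate(m$class_pair, 4), collapse = "."),
                             seq_len(kk))
    out
  })
  fused <- do.call(cbind, blocks)
  pc <- prcomp(fused, center = TRUE, scale. = FALSE)
  n3 <- min(3, ncol(pc$x))
  view <- pc$x[, seq_len(n3), drop = FALSE]
  colnames(view) <- paste0("PC", seq_len(n3))
  sil <- silhouette_mean(view, fm$groups)
  bd_log(sprintf("fusion: %d-dim fused scores, 3-D group silhouette %.3f",
                 ncol(fused), sil))
  structure(list(scores = data.frame(sample_id = ids,
                                     group = fm$groups,
                                     fused, view, check.names = FALSE),
                 k = k, silhouette = sil, rotation = pc$rotation),
            class = "fusion_scores")
}

# mean silhouette width of labels in a Euclidean score space
silhouette_mean <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(as.integer(droplevels(labels)), dist(scores))
  mean(sil[, "sil_width"])
}

#' @export
print.fusion_scores <- function(x, ...) {
  cat(sprintf("<fusion_scores> %d samples, %d fused dims + 3-D view, group silhouette %.3f\n",
              nrow(x$scores), 3 * x$k, x$silhouette))
  invisible(x)
}
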