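test_that("Duplex splitting is deterministic with the half-up 20% quota", {
  fm <- toy_fm(n_per_class = 10, p = 4, shift_cols = NULL)
  sp1 <- duplex_split(fm, c("control", "IPF-like"))
  sp2 <- duplex_split(fm, c("control", "IPF-like"))
  expect_identical(sp1$train_ids, sp2$train_ids)
  expect_identical(sp1$test_ids, sp2$test_ids)
  expect_equal(unname(sp1$counts["train", ]), c(8, 8))
  expect_equal(unname(sp1$counts["test", ]), c(2, 2))
  expect_length(intersect(sp1$train_ids, sp1$test_ids), 0)
  expect_setequal(c(sp1$train_ids, sp1$test_ids), fm$sample_ids)
})

test_that("Duplex quotas reproduce the study's 53/51 split arithmetic", {
  set.seed(8)
  X <- matrix(exp(rnorm(104 * 5)), 104, 5,
              dimnames = list(sprintf("S%03d", 1:104), sprintf("V%d", 1:5)))
  fm <- feature_matrix(X, groups = rep(c("IPF-like", "control"), c(53, 51)))
  sp <- duplex_split(fm, c("IPF-like", "control"), test_frac = 0.2)
  expect_equal(unname(sp$counts[, 1]), c(42, 11))  # round-half-up(10.6)
  expect_equal(unname(sp$counts[, 2]), c(41, 10))  # round-half-up(10.2)
})

test_that("Duplex reproduces the hand-traced 1-D assignment", {
  # points 0..9 in one class: TRAIN seeds = the two mutually farthest {0,9},
  # TEST seeds = farthest of the rest {1,8}; quota 2 is then already filled
  X <- cbind(v = 0:9, w = rep(1, 10))
  rownames(X) <- sprintf("x%d", 0:9)
  # a second class far away so the pairwise split is well defined
  Y <- cbind(v = 100:106, w = rep(1, 7))
  rownames(Y) <- sprintf("y%d", 0:6)
  fm <- feature_matrix(rbind(X, Y), groups = rep(c("a", "b"), c(10, 7)))
  sp <- duplex_split(fm, c("a", "b"), test_frac = 0.2)
  expect_setequal(sp$trace[["a"]]$test, c("x1", "x8"))
  expect_true(all(c("x0", "x9") %in% sp$trace[["a"]]$train))
})

test_that("Duplex rejects degenerate requests", {
  fm <- toy_fm(n_per_class = 10, p = 3, shift_cols = NULL)
  expect_error(duplex_split(fm, c("control", "absent")), "absent")
  expect_error(duplex_split(fm, c("control", "IPF-like"), test_frac = 0.01),
               "quota")
})

test_that("a label-equal feature dominates a forest and its importance", {
  set.seed(5)
  n <- 40
  g <- rep(c("control", "IPF-like"), each = n / 2)
  X <- matrix(exp(rnorm(n * 10)), n, 10,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("V%02d", 1:10)))
  X[, 1] <- ifelse(g == "IPF-like", 1, 0)   # feature equals the label
  fm <- feature_matrix(X, groups = g)
  sp <- duplex_split(fm, c("IPF-like", "control"))
  m <- train_forest(fm, c("IPF-like", "control"), sp, n_trees = 500, seed = 2)
  expect_gte(m$oob_accuracy, 0.98)
  expect_identical(names(which.max(m$importance)), "V01")
  expect_equal(m$oob_accuracy + m$oob_error, 1)     # exact complement
})

test_that("proximities are a valid similarity with duplicates co-landing", {
  fm <- toy_fm(n_per_class = 10, p = 5, shift_cols = 1:2, shift = 2, seed = 9)
  # duplicate one sample under a new id
  X <- rbind(fm$areas, dup = fm$areas[1, ])
  rownames(X)[nrow(X)] <- "Sdup"
  fm2 <- feature_matrix(X, groups = c(as.character(fm$groups),
                                      as.character(fm$groups[1])))
  sp <- duplex_split(fm2, c("control", "IPF-like"))
  m <- train_forest(fm2, c("control", "IPF-like"), sp, n_trees = 500, seed = 3)
  P <- m$proximity
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(P, t(P))
  expect_equal(unname(diag(P)), rep(1, nrow(P)))
  expect_gt(P["S01", "Sdup"], 0.95)
})

test_that("null labels give chance-level OOB accuracy", {
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 40
    X <- matrix(exp(rnorm(n * 20)), n, 20,
                dimnames = list(sprintf("S%02d", 1:n), sprintf("V%02d", 1:20)))
    fm <- feature_matrix(X, groups = sample(rep(c("control", "IPF-like"),
                                                each = n / 2)))
    sp <- duplex_split(fm, c("control", "IPF-like"))
    m <- train_forest(fm, c("control", "IPF-like"), sp, n_trees = 300,
                      seed = s)
    m$oob_accuracy
  }, numeric(1))
  # binomial SE at n_train = 32 is ~0.088; individual runs stay within ~2 SE
  expect_gte(mean(abs(accs - 0.5) <= 0.25), 0.9)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("importance-gap selection isolates dominant features", {
  model <- structure(list(importance = c(a = 10, b = 9.5, c = 0.1, d = 0.05,
                                         e = 0.04, f = 0.03)),
                     class = "binary_rf")
  expect_identical(select_discriminatory_vocs(model), c("a", "b"))
  flat <- structure(list(importance = setNames(rep(1, 30), paste0("v", 1:30))),
                    class = "binary_rf")
  expect_warning(sel <- select_discriminatory_vocs(flat), "fall")
  expect_length(sel, 10)
  none <- structure(list(importance = c(a = 0, b = -1)), class = "binary_rf")
  expect_error(select_discriminatory_vocs(none), "no discriminatory signal")
})

test_that("selection recovers planted discriminatory VOCs", {
  hits <- vapply(1:5, function(s) {
    cfg <- sim_config(n_per_group = c(50L, 50L, 5L), n_compounds = 200L,
                      n_disc_A = 10L, n_disc_B = 0L, n_disc_AB = 0L,
                      effect_size = 1.5, seed = 500 + s)
    sim <- simulate_feature_matrix(cfg)
    sp <- duplex_split(sim$fm, c("IPF-like", "control"))
    m <- train_forest(sim$fm, c("IPF-like", "control"), sp, seed = s)
    sel <- select_discriminatory_vocs(m)
    planted <- sim$truth$catalog$compound[sim$truth$disc$A$compound]
    length(intersect(sel, planted))
  }, numeric(1))
  expect_gte(median(hits), 8)
})

test_that("refit on a separable pair is perfect; accuracy + error = 1", {
  fm <- toy_fm(n_per_class = 10, p = 6, shift_cols = 1:3, shift = 6, seed = 2)
  sp <- duplex_split(fm, c("IPF-like", "control"))
  full <- train_forest(fm, c("IPF-like", "control"), sp, n_trees = 500, seed = 1)
  sel <- select_discriminatory_vocs(full)
  m <- refit_and_validate(fm, c("IPF-like", "control"), sp, sel,
                          n_trees = 500, seed = 1)
  expect_equal(unname(m$test_metrics["accuracy"]), 1)
  expect_equal(m$roc$auc, 1)
  expect_equal(unname(m$test_metrics["accuracy"]) + m$test_error, 1)
  expect_identical(m$positive_class, "IPF-like")
  expect_true(all(diff(m$roc$sensitivity) >= 0))   # sens grows as thr drops
})

test_that("AUC follows the Mann-Whitney convention", {
  expect_equal(auc(c(0.9, 0.8, 0.4), c(0.7, 0.3, 0.2)), 8 / 9)
  expect_equal(auc(rep(0.5, 4), rep(0.5, 6)), 0.5)       # all tied
  expect_equal(auc(c(3, 4), c(1, 2)), 1)
  expect_error(auc(numeric(0), 1), "non-empty")
})

test_that("AUC equals brute-force pair counting on random instances", {
  brute_auc <- function(p, n) {
    s <- 0
    for (a in p) for (b in n) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(p) * length(n))
  }
  set.seed(12)
  for (i in 1:100) {
    n1 <- sample(1:25, 1); n2 <- sample(1:25, 1)
    p <- sample(seq(0, 1, 0.05), n1, replace = TRUE)  # ties likely
    n <- sample(seq(0, 1, 0.05), n2, replace = TRUE)
    expect_equal(auc(p, n), brute_auc(p, n))
  }
  # trapezoidal ROC AUC agrees with the rank form
  set.seed(13)
  for (i in 1:20) {
    p <- runif(8); n <- runif(11)
    expect_equal(roc_curve(p, n)$auc, auc(p, n), tolerance = 1e-12)
  }
})

test_that("proximity embedding matches closed forms and cmdscale", {
  # all-identical samples: proximity 1 everywhere -> every score at origin
  same <- structure(list(proximity = matrix(1, 4, 4,
                                            dimnames = list(letters[1:4],
                                                            letters[1:4]))),
                    class = "binary_rf")
  expect_warning(emb <- proximity_embed(same, 3), "positive eigenvalues")
  expect_equal(max(abs(emb$scores)), 0, tolerance = 1e-10)

  # two tight blocks at proximity 0 from each other: the two-point classical
  # scaling solution puts them 1 apart (at +/- 0.5 on component 1)
  P <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 3)),
             cbind(matrix(0, 3, 3), matrix(1, 3, 3)))
  dimnames(P) <- list(letters[1:6], letters[1:6])
  blocks <- structure(list(proximity = P), class = "binary_rf")
  emb2 <- suppressWarnings(proximity_embed(blocks, 1))
  c1 <- emb2$scores[, 1]
  expect_equal(sort(unique(round(abs(c1), 10))), 0.5)
  expect_equal(abs(mean(c1[1:3]) - mean(c1[4:6])), 1)

  # general agreement with stats::cmdscale as the independent implementation
  set.seed(3)
  fm <- toy_fm(n_per_class = 8, p = 5, shift_cols = 1:2, shift = 2, seed = 3)
  sp <- duplex_split(fm, c("control", "IPF-like"))
  m <- train_forest(fm, c("control", "IPF-like"), sp, n_trees = 300, seed = 4)
  emb3 <- proximity_embed(m, 2)
  ref <- stats::cmdscale(as.dist(1 - m$proximity), k = 2)
  for (k in 1:2) {
    expect_equal(abs(cor(emb3$scores[, k], ref[, k])), 1, tolerance = 1e-6)
  }
})

test_that("planted effects separate groups in the embedded scores", {
  cfg <- sim_config(n_per_group = c(25L, 25L, 5L), n_compounds = 50L,
                    n_disc_A = 8L, n_disc_B = 0L, n_disc_AB = 0L,
                    effect_size = 2, seed = 77)
  sim <- simulate_feature_matrix(cfg)
  sp <- duplex_split(sim$fm, c("IPF-like", "control"))
  full <- train_forest(sim$fm, c("IPF-like", "control"), sp, seed = 7)
  sel <- select_discriminatory_vocs(full)
  m <- refit_and_validate(sim$fm, c("IPF-like", "control"), sp, sel, seed = 7)
  sc <- m$embedding$scores
  labs <- sim$fm$groups[match(rownames(sc), sim$fm$sample_ids)]
  expect_gt(breathdisc:::silhouette_mean(sc, labs), 0)
})

test_that("out-of-sample projection extends the embedding consistently", {
  fm <- toy_fm(n_per_class = 10, p = 5, shift_cols = 1:2, shift = 3, seed = 6)
  sp <- duplex_split(fm, c("control", "IPF-like"))
  full <- train_forest(fm, c("control", "IPF-like"), sp, n_trees = 500, seed = 5)
  sel <- names(sort(full$importance, decreasing = TRUE))[1:3]
  m <- refit_and_validate(fm, c("control", "IPF-like"), sp, sel,
                          n_trees = 500, seed = 5)
  # projecting a model sample reproduces its own embedding coordinates
  sid <- m$sample_ids[m$is_test][1]
  proj <- project_sample(m, fm$areas[sid, m$feature_names])
  expect_equal(unname(proj[1, ]), unname(m$embedding$scores[sid, ]),
               tolerance = 1e-6)
  # a near-duplicate lands near the original
  nd <- fm$areas[sid, m$feature_names] * 1.0001
  proj2 <- project_sample(m, nd)
  rng <- apply(m$embedding$scores, 2, function(x) diff(range(x)))
  expect_true(all(abs(proj2[1, ] - m$embedding$scores[sid, ]) <= 0.05 * rng +
                    1e-9))
  expect_error(project_sample(m, c(bad = 1)), "lacks")
})
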