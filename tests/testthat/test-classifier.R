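test_that("Gini impurity matches closed forms", {
  expect_equal(gini_impurity(c(10, 0, 0, 0)), 0)
  expect_equal(gini_impurity(c(5, 5, 0, 0)), 0.5)
  expect_equal(gini_impurity(c(25, 20, 20, 20)), 1 - 1825 / 7225,
               tolerance = 1e-12)
  expect_error(gini_impurity(c(0, 0)), "positive sum")
})

test_that("perfectly separable 1-D data splits at the midpoint", {
  x <- data.frame(f = c(1, 2, 3, 10, 11, 12))
  y <- rep(c("control", "ataxia"), each = 3)
  fit <- train_coarse_tree(x, y)
  expect_equal(fit$n_splits, 1L)
  expect_equal(fit$splits[[1]]$threshold, 6.5)
  expect_identical(predict_signature(fit, x), y)
})

test_that("the greedy fit matches the exhaustive-search oracle", {
  # fixed 8-point, 3-feature, 4-class toy set
  X <- data.frame(a = c(1, 2, 9, 10, 1, 2, 9, 10),
                  b = c(1, 1, 1, 1, 8, 8, 8, 8),
                  c = c(5, 6, 5, 7, 6, 5, 7, 5))
  y <- c("control", "control", "ataxia", "ataxia",
         "dystonia", "dystonia", "tremor", "tremor")
  fit <- train_coarse_tree(X, y)
  orc <- oracle_tree(X, y)
  expect_equal(length(fit$splits), length(orc))
  for (k in seq_along(orc)) {
    expect_equal(fit$splits[[k]]$feature, orc[[k]]$feature)
    expect_equal(fit$splits[[k]]$threshold, orc[[k]]$threshold)
    expect_equal(fit$splits[[k]]$path, orc[[k]]$path)
  }

  # random small datasets (<= 12 points x 3 features)
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(5:12, 1)
    X <- data.frame(a = round(runif(n, 0, 10), 1),
                    b = round(rnorm(n, 5, 3), 1),
                    c = sample(1:6, n, replace = TRUE) + 0.5)
    y <- sample(signature_levels(), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    fit <- train_coarse_tree(X, y)
    orc <- oracle_tree(X, y)
    expect_equal(length(fit$splits), length(orc), info = paste("seed", seed))
    for (k in seq_along(orc)) {
      expect_equal(fit$splits[[k]]$feature, orc[[k]]$feature,
                   info = paste("seed", seed, "split", k))
      expect_equal(fit$splits[[k]]$threshold, orc[[k]]$threshold,
                   tolerance = 1e-12, info = paste("seed", seed))
    }
  }
})

test_that("training is invariant to row order", {
  ref <- fit_reference_tree()
  f <- ref$features
  set.seed(3)
  perm <- sample(nrow(f))
  fit2 <- train_coarse_tree(f[perm, feature_names()], f$group_label[perm])
  expect_equal(lapply(fit2$splits, `[`, c("feature", "threshold", "path")),
               lapply(ref$tree$splits, `[`, c("feature", "threshold", "path")))
})

test_that("prediction descends thresholds deterministically", {
  ref <- fit_reference_tree()
  tree <- ref$tree
  # value exactly at a threshold goes right
  x <- data.frame(f = c(1, 2, 10, 11))
  y <- c("control", "control", "tremor", "tremor")
  small <- train_coarse_tree(x, y)
  thr <- small$splits[[1]]$threshold
  expect_identical(predict_signature(small, data.frame(f = thr)), "tremor")
  expect_identical(predict_signature(small, data.frame(f = thr - 1e-9)),
                   "control")

  # 100 random vectors agree with an independent manual walk
  set.seed(14)
  rnd <- ref$features[sample(nrow(ref$features), 100, replace = TRUE),
                      feature_names()]
  rnd[] <- lapply(rnd, function(v) v * runif(100, 0.5, 1.5))
  pred <- predict_signature(tree, rnd)
  manual <- vapply(seq_len(nrow(rnd)), function(i)
    oracle_walk(tree, rnd[i, ]), "")
  expect_identical(pred, manual)

  expect_error(predict_signature(tree, data.frame(firing_rate = 50)),
               "no surrogate splits")
})

test_that("trees never exceed 3 splits and warn when growth stalls", {
  ref <- fit_reference_tree()
  expect_lte(ref$tree$n_splits, 3L)
  expect_equal(ref$tree$n_splits, 3L)  # 4 separable classes use all splits
  # constant feature with multi-class labels: no split possible
  expect_warning(
    fit <- train_coarse_tree(data.frame(f = rep(1, 6)),
                             rep(c("control", "ataxia"), 3)),
    "no further impurity-reducing split")
  expect_equal(fit$n_splits, 0L)
})

test_that("leaf-label ties resolve by training prior then class order", {
  # leaf with a 1-1 tie between control (larger prior) and tremor
  X <- data.frame(f = c(1, 2, 3, 10, 11))
  y <- c("control", "control", "tremor", "tremor", "control")
  fit <- train_coarse_tree(X, y, max_splits = 1)
  leaf_labels <- c(oracle_walk(fit, data.frame(f = 0)),
                   oracle_walk(fit, data.frame(f = 100)))
  expect_true("control" %in% leaf_labels)
})

test_that("model selection runs 12 stratified splits and applies tie rules", {
  co <- generate_archetypal_cohort(c(control = 33, ataxia = 24,
                                     dystonia = 24, tremor = 24), seed = 60)
  f <- featurize_cohort(co$cohort)
  rep <- run_model_selection(f, seed = 9)
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep$summary), 12L)
  expect_true(all(rep$summary$accuracy >= 0 & rep$summary$accuracy <= 1))
  sel <- rep$summary[rep$selected, ]
  best <- max(rep$summary$accuracy)
  expect_equal(sel$accuracy, best)
  cands <- rep$summary[rep$summary$accuracy == best, ]
  cands <- cands[cands$n_features == min(cands$n_features), ]
  expect_equal(rep$selected, min(cands$split_id))  # lowest id among ties
  # train/validation sets are disjoint by construction; accuracy is high on
  # clean synthetic cohorts
  expect_gte(best, 0.9)

  expect_error(run_model_selection(f[1:40, ], seed = 1), "insufficient")
  small <- generate_archetypal_cohort(c(control = 16, ataxia = 12,
                                        dystonia = 12, tremor = 12),
                                      seed = 61)
  fs <- featurize_cohort(small$cohort)
  scaled <- run_model_selection(fs, seed = 2, allow_scaled = TRUE,
                                n_splits = 3)
  expect_s3_class(scaled, "validation_report")
})

test_that("classify_cohort tabulates origin against signature", {
  ref <- fit_reference_tree()
  one <- classify_cohort(ref$tree, ref$features[1, ])
  expect_equal(sum(one$counts), 1)

  # classifying the training set reproduces at least training accuracy
  cs <- classify_cohort(ref$tree, ref$features)
  diag_acc <- sum(diag(cs$counts[signature_levels(), signature_levels()])) /
    sum(cs$counts)
  expect_gte(diag_acc, 0.9)
  pr <- proportion_table(cs)
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-12)

  expect_error(classify_cohort(ref$tree, ref$features[0, ]), "empty cohort")
})
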