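test_that("assemble_features emits one 443-column row per pair", {
  ds <- balanced_synthetic_dataset(seed = 5L)
  f <- assemble_features(ds)
  expect_identical(ncol(f$x), 443L)
  expect_identical(nrow(f$x), nrow(ds$pairs))
  expect_identical(colnames(f$x),
                   c(descriptor_names(), paste0("maccs_", 1:166)))
  expect_identical(f$y, as.integer(ds$pairs$label == "positive"))
  expect_identical(sum(f$y), sum(1L - f$y))  # balanced by construction
})

test_that("split_train_test stratifies, is deterministic and rounds by class", {
  y <- rep(c(0L, 1L), each = 50L)
  sp <- split_train_test(y, seed = 3L)
  expect_identical(length(sp$train), 50L)
  expect_identical(sum(y[sp$train]), 25L)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  expect_identical(sp, split_train_test(y, seed = 3L))
  expect_false(identical(sp, split_train_test(y, seed = 4L)))

  odd <- c(rep(0L, 7L), rep(1L, 9L))
  sp2 <- split_train_test(odd, seed = 1L)
  expect_identical(sum(odd[sp2$train] == 0L), 4L)  # ceiling(7/2)
  expect_identical(sum(odd[sp2$train] == 1L), 5L)  # ceiling(9/2)
  expect_error(split_train_test(rep(1L, 10L)), "both classes")
})

test_that("cross_validate reports 5-fold means/SDs and breaks ties low", {
  d <- separable_xy(n = 100L, p = 10L, gap = 3, seed = 6L)
  cv <- cross_validate(d$x, d$y, "knn", grid = c(3L, 5L, 7L), seed = 2L)
  expect_identical(names(cv$report),
                   c("Model", "param", "ROC", "Sens", "Spec", "ROCSD",
                     "SensSD", "SpecSD"))
  expect_true(all(cv$grid_table$ROC >= 0 & cv$grid_table$ROC <= 1))
  expect_true(all(cv$grid_table$ROCSD >= 0))
  # perfectly separable: every k reaches AUC 1, so the tie-break picks
  # the smallest hyperparameter
  expect_true(all(cv$grid_table$ROC == 1))
  expect_identical(cv$best_param, 3L)
  expect_error(cross_validate(d$x[1:6, ], d$y[1:6], "knn", grid = 3L),
               "single-class")
})

test_that("auc_rank matches hand examples and null behaviour", {
  expect_equal(auc_rank(c(.9, .8, .7, .6, .5, .4), c(1, 1, 0, 1, 0, 0)),
               8 / 9)
  expect_equal(auc_rank(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  withr::with_seed(10, {
    null_auc <- auc_rank(runif(4000), rep(c(0, 1), 2000))
    expect_lt(abs(null_auc - 0.5), 0.05)
  })
})

test_that("auc_rank equals concordant-pair counting on small score sets", {
  # exhaustive over discretized scores for n <= 5, random draws for 6..8
  alphabet <- c(0.2, 0.5, 0.8)
  for (n in 2:5) {
    grids <- expand.grid(rep(list(alphabet), n))
    labels <- expand.grid(rep(list(c(0L, 1L)), n))
    keep <- rowSums(labels) %in% seq_len(n - 1L)
    labels <- labels[keep, , drop = FALSE]
    withr::with_seed(n, {
      li <- sample(nrow(labels), min(10L, nrow(labels)))
      for (g in sample(nrow(grids), min(40L, nrow(grids)))) {
        s <- as.numeric(grids[g, ])
        for (l in li) {
          y <- as.integer(labels[l, ])
          expect_equal(auc_rank(s, y), auc_pairs_oracle(s, y),
                       tolerance = 1e-12)
        }
      }
    })
  }
  withr::with_seed(99, {
    for (rep in seq_len(300L)) {
      n <- sample(6:8, 1L)
      s <- sample(alphabet, n, replace = TRUE)
      y <- c(0L, 1L, sample(c(0L, 1L), n - 2L, replace = TRUE))
      expect_equal(auc_rank(s, y), auc_pairs_oracle(s, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("roc_points runs from (0,0) to (1,1) monotonically", {
  withr::with_seed(12, {
    s <- round(runif(50), 2)
    y <- rbinom(50, 1, 0.5)
    y[1:2] <- c(0L, 1L)
    r <- roc_points(s, y)
    expect_equal(r$fpr[1L], 0)
    expect_equal(r$tpr[1L], 0)
    expect_equal(r$fpr[nrow(r)], 1)
    expect_equal(r$tpr[nrow(r)], 1)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  })
})

test_that("select_threshold honours the grid oracle and the low tie-break", {
  # separable scores: F1 = 1 from 0.11 upward, so the lowest grid value
  # attaining the maximum is 0.11
  s <- c(0.9, 0.9, 0.1, 0.1)
  y <- c(1L, 1L, 0L, 0L)
  expect_equal(select_threshold(s, y)$threshold, 0.11)
  expect_equal(select_threshold(s, y)$f1, 1)

  brute <- function(s, y, grid) {
    f1s <- sapply(grid, function(t) {
      tp <- sum(s >= t & y == 1L)
      fp <- sum(s >= t & y == 0L)
      fn <- sum(s < t & y == 1L)
      if (tp == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
    })
    list(threshold = grid[which.max(f1s)], f1 = max(f1s))
  }
  grid <- seq(0, 1, by = 0.01)
  withr::with_seed(31, {
    for (rep in seq_len(100L)) {
      n <- sample(10:40, 1L)
      s <- round(runif(n), 3)
      y <- c(0L, 1L, sample(c(0L, 1L), n - 2L, replace = TRUE))
      got <- select_threshold(s, y, grid)
      want <- brute(s, y, grid)
      expect_equal(got$f1, want$f1, tolerance = 1e-12)
      expect_equal(got$threshold, want$threshold)
    }
  })
  expect_error(select_threshold(c(0.2, 0.3), c(0L, 1L), grid = 0.9),
               "no grid threshold")
})

test_that("evaluate_test requires both classes and reports rank AUC", {
  d <- separable_xy(n = 60L, p = 10L, seed = 4L)
  fit <- fit_learner("glm", d$x[1:40, ], d$y[1:40])
  ev <- evaluate_test(fit, d$x[41:60, ], d$y[41:60])
  expect_gte(ev$auc, 0.9)
  expect_s3_class(ev$roc, "data.frame")
  expect_error(evaluate_test(fit, d$x[41:44, ], rep(1L, 4L)),
               "both classes")
})

test_that("train_model produces a complete, serializable bundle", {
  ds <- balanced_synthetic_dataset(seed = 6L)
  bundle <- train_model(ds, algorithm = "rf", seed = 4L, grid = 21L,
                        ntree = 60L)
  expect_s3_class(bundle, "smireg_bundle")
  expect_identical(bundle$direction, "up")
  expect_identical(bundle$feature_names,
                   c(descriptor_names(), paste0("maccs_", 1:166)))
  expect_true(bundle$threshold > 0 && bundle$threshold < 1)
  expect_true(bundle$test_auc > 0.5)
  expect_identical(nrow(bundle$cv_report), 1L)

  # serialization round-trip: identical probabilities on a 50-row fixture
  f <- assemble_features(ds)
  fixture <- f$x[seq_len(50L), , drop = FALSE]
  dir <- withr::local_tempdir()
  save_bundle(bundle, dir)
  expect_true(file.exists(file.path(dir, "metadata.json")))
  back <- load_bundle(dir)
  expect_identical(predict_prob(back$fit, fixture),
                   predict_prob(bundle$fit, fixture))
})

test_that("train/test rows are disjoint and cover the dataset", {
  ds <- balanced_synthetic_dataset(seed = 7L)
  f <- assemble_features(ds)
  sp <- split_train_test(f$y, seed = 11L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(f$y))
})
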