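# Feature assembly, train/test splitting, cross-validated tuning,
# held-out evaluation and threshold calibration.
#
# Each (molecule, miRNA) pair becomes one row of 443 features: the 277
# sequence-composition descriptors followed by the 166 MACCS keys. The
# balanced dataset is split 50/50 stratified by label; the single tuned
# hyperparameter of each classifier family is chosen by the mean AUC over
# 5 stratified CV folds of the training half; the final model is refit on
# the full training half, evaluated by AUC on the held-out half, and its
# decision threshold ("suggestion rate") is set to the F1-maximizing grid
# value on the held-out predictions.

#' Assemble the 443-column feature matrix of a dataset
#'
#' @param ds A `regulation_dataset` (typically balanced, after negative
#'   augmentation).
#' @return List with `x` (numeric matrix, one row per pair, 443 named
#'   columns), `y` (integer 0/1; positive = 1) and `keys` (data frame of
#'   `sm_id`, `mirna_id`).
#' @export
assemble_features <- function(ds) {
  stopifnot(inherits(ds, "regulation_dataset"))
  desc <- descriptor_matrix(ds$sequences)
  x <- cbind(desc[ds$pairs$mirna_id, , drop = FALSE],
             ds$fingerprints[ds$pairs$sm_id, , drop = FALSE])
  rownames(x) <- NULL
  colnames(x) <- c(descriptor_names(), maccs_colnames())
  list(x = x,
       y = as.integer(ds$pairs$label == "positive"),
       keys = ds$pairs[, c("sm_id", "mirna_id")])
}

#' Stratified train/test split
#'
#' Splits row indices into a training and a testing part, stratified by
#' label, deterministic under `seed`. With odd class counts the training
#' side receives the extra row.
#'
#' @param y 0/1 labels.
#' @param fraction Training fraction (default 0.5, an even split).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(y, fraction = 0.5, seed = 1L) {
  y <- check_binary_labels(y)
  stopifnot(fraction > 0, fraction < 1)
  if (min(table(y)) < 2L) {
    stop("need at least 2 rows per class to split", call. = FALSE)
  }
  train <- local_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(y == cl)
      idx[sample.int(length(idx), ceiling(length(idx) * fraction))]
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

make_folds <- function(y, folds, seed) {
  assign_fold <- function(idx) {
    f <- rep_len(seq_len(folds), length(idx))
    stats::setNames(f, idx[sample.int(length(idx))])
  }
  fold_of <- local_seed(seed, {
    c(assign_fold(which(y == 0L)), assign_fold(which(y == 1L)))
  })
  out <- integer(length(y))
  out[as.integer(names(fold_of))] <- fold_of
  out
}

#' Cross-validated tuning of one classifier family
#'
#' For each grid value, fits on 4 of 5 stratified folds and scores the
#' held-out fold; reports the mean and SD over folds of AUC, sensitivity
#' and specificity (the latter two at the 0.5 probability cutoff) and
#' selects the grid value with the highest mean AUC, breaking ties toward
#' the smaller value.
#'
#' @param x Feature matrix.
#' @param y 0/1 labels.
#' @param algorithm One of `"glm"`, `"knn"`, `"svm"`, `"ann"`, `"rf"`.
#' @param grid Hyperparameter grid; `NULL` uses the family default.
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for fold assignment and stochastic learners.
#' @param ntree Random-forest tree count.
#' @return List with `algorithm`, `best_param`, `report` (one row: the
#'   Table-style columns Model, ROC, Sens, Spec, ROCSD, SensSD, SpecSD at
#'   the selected value) and `grid_table` (all grid rows).
#' @export
cross_validate <- function(x, y, algorithm, grid = NULL, folds = 5L,
                           seed = 1L, ntree = 500L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  y <- check_binary_labels(y)
  if (is.null(grid)) grid <- default_grid(algorithm, ncol(x))
  stopifnot(length(grid) > 0L)
  fold_id <- make_folds(y, folds, seed)
  for (f in seq_len(folds)) {
    if (length(unique(y[fold_id == f])) < 2L) {
      stop(sprintf("fold %d is single-class; too few rows per class", f),
           call. = FALSE)
    }
  }
  rows <- lapply(grid, function(par) {
    m <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- fit_learner(algorithm, x[tr, , drop = FALSE], y[tr],
                         param = par, seed = seed + f, ntree = ntree)
      pr <- predict_prob(fit, x[!tr, , drop = FALSE])
      c(auc = auc_rank(pr, y[!tr]), sens_spec(pr, y[!tr]))
    }, numeric(3L))
    data.frame(param = par,
               ROC = mean(m["auc", ]), Sens = mean(m["sens", ]),
               Spec = mean(m["spec", ]),
               ROCSD = stats::sd(m["auc", ]),
               SensSD = stats::sd(m["sens", ]),
               SpecSD = stats::sd(m["spec", ]))
  })
  grid_table <- do.call(rbind, rows)
  # highest mean AUC; ties toward the smaller hyperparameter value
  best <- order(-grid_table$ROC, grid_table$param)[1L]
  report <- cbind(Model = algorithm, grid_table[best, , drop = FALSE])
  rownames(report) <- NULL
  list(algorithm = algorithm, best_param = grid_table$param[best],
       report = report, grid_table = grid_table)
}

#' Held-out evaluation of a fitted learner
#'
#' @param fit A `smireg_learner`.
#' @param x Test feature matrix.
#' @param y Test 0/1 labels (both classes present).
#' @return List with `auc` (rank-based, midrank ties) and `roc` (curve
#'   points from [roc_points()]).
#' @export
evaluate_test <- function(fit, x, y) {
  y <- check_binary_labels(y)
  pr <- predict_prob(fit, x)
  list(auc = auc_rank(pr, y), roc = roc_points(pr, y), probabilities = pr)
}

#' Train, tune, evaluate and calibrate one direction model
#'
#' Runs the full modeling pipeline on a balanced dataset: 50/50 stratified
#' split, 5-fold CV tuning by AUC on the training half, final refit,
#' held-out AUC, and F1 threshold calibration on the held-out predictions.
#'
#' @param ds A balanced `regulation_dataset`.
#' @param algorithm Classifier family (default `"rf"`, the best performer).
#' @param seed Master seed; the split, folds and learner seeds derive
#'   from it and are recorded in the bundle.
#' @param grid Hyperparameter grid (`NULL` = family default).
#' @param folds CV folds (default 5).
#' @param fraction Training fraction (default 0.5).
#' @param ntree Random-forest tree count (default 500).
#' @return A `smireg_bundle`: fitted model, tuned hyperparameter, frozen
#'   feature ordering, calibrated threshold, CV report and test AUC.
#' @export
train_model <- function(ds, algorithm = "rf", seed = 1L, grid = NULL,
                        folds = 5L, fraction = 0.5, ntree = 500L) {
  stopifnot(inherits(ds, "regulation_dataset"))
  feats <- assemble_features(ds)
  split <- split_train_test(feats$y, fraction = fraction, seed = seed)
  xtr <- feats$x[split$train, , drop = FALSE]
  ytr <- feats$y[split$train]
  cv <- cross_validate(xtr, ytr, algorithm, grid = grid, folds = folds,
                       seed = seed, ntree = ntree)
  fit <- fit_learner(algorithm, xtr, ytr, param = cv$best_param,
                     seed = seed, ntree = ntree)
  test <- evaluate_test(fit, feats$x[split$test, , drop = FALSE],
                        feats$y[split$test])
  thr <- select_threshold(test$probabilities, feats$y[split$test])
  structure(list(
    direction = ds$direction,
    algorithm = algorithm,
    fit = fit,
    param = cv$best_param,
    feature_names = colnames(feats$x),
    threshold = thr$threshold,
    f1 = thr$f1,
    test_auc = test$auc,
    roc = test$roc,
    cv_report = cv$report,
    cv_grid = cv$grid_table,
    seed = seed,
    split = split,
    meta = list(package = "smiReg",
                version = as.character(utils::packageVersion("smiReg")),
                r_version = paste(R.version$major, R.version$minor,
                                  sep = "."),
                ntree = ntree, folds = folds, fraction = fraction)
  ), class = "smireg_bundle")
}

#' @export
print.smireg_bundle <- function(x, ...) {
  cat(sprintf(
    "<smireg_bundle: %s-regulation, %s (param = %s)>\n  test AUC %.3f, suggestion rate %.2f (F1 %.3f)\n",
    x$direction, x$algorithm, format(x$param), x$test_auc, x$threshold,
    x$f1))
  invisible(x)
}

#' Serialize a model bundle to a directory
#'
#' Writes `bundle.rds` plus a human-readable `metadata.json` sidecar
#' (direction, algorithm, tuned value, threshold, test AUC, seeds,
#' versions) and the CV report as `cv_report.tsv`.
#'
#' @param bundle A `smireg_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "smireg_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(bundle, file.path(dir, "bundle.rds"), version = 3L)
  meta <- c(bundle$meta,
            list(direction = bundle$direction,
                 algorithm = bundle$algorithm,
                 param = bundle$param,
                 threshold = bundle$threshold,
                 f1 = bundle$f1,
                 test_auc = bundle$test_auc,
                 seed = bundle$seed))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.table(bundle$cv_report, file.path(dir, "cv_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a serialized model bundle
#'
#' @param dir Directory written by [save_bundle()].
#' @return A `smireg_bundle`.
#' @export
load_bundle <- function(dir) {
  path <- file.path(dir, "bundle.rds")
  if (!file.exists(path)) {
    stop(sprintf("no bundle.rds under %s", dir), call. = FALSE)
  }
  bundle <- readRDS(path)
  stopifnot(inherits(bundle, "smireg_bundle"))
  bundle
}
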