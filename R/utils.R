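# Shared numeric utilities: scoped RNG, rank-based AUC, ROC curves,
# sensitivity/specificity and F1 threshold selection.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded internals never perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_binary_labels <- function(labels) {
  stopifnot(length(labels) > 0L)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  labels
}

#' Area under the ROC curve (rank formulation)
#'
#' Mann-Whitney statistic with midrank tie handling: the probability that
#' a random positive outranks a random negative, counting ties as one
#' half.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct score threshold, from (0, 0) to
#' (1, 1), with predicted positive defined as `score >= threshold`.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  n1 <- sum(l)
  n0 <- length(l) - n1
  # cumulative counts at each distinct threshold (all ties included)
  keep <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l)[keep]
  fp <- cumsum(1L - l)[keep]
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp / n0),
             tpr = c(0, tp / n1))
}

#' Sensitivity and specificity at a probability cutoff
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels.
#' @param cutoff Predicted positive iff `score >= cutoff` (default 0.5).
#' @return Named numeric vector `c(sens, spec)`.
#' @export
sens_spec <- function(scores, labels, cutoff = 0.5) {
  labels <- check_binary_labels(labels)
  pred <- scores >= cutoff
  c(sens = sum(pred & labels == 1L) / sum(labels == 1L),
    spec = sum(!pred & labels == 0L) / sum(labels == 0L))
}

#' F1 score at a fixed threshold
#'
#' `F1 = 2 * precision * recall / (precision + recall)` with predicted
#' positive defined as `score >= threshold`; zero when nothing is
#' predicted positive or nothing predicted positive is correct.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  if (tp == 0L) return(0)
  precision <- tp / sum(pred)
  recall <- tp / sum(labels == 1L)
  2 * precision * recall / (precision + recall)
}

#' F1-maximizing decision threshold (the suggestion rate)
#'
#' Sweeps the threshold grid, computes F1 at each value, and returns the
#' lowest grid value attaining the maximum F1 — the calibrated
#' "suggestion rate" above which a predicted pair is deemed worth
#' experimental follow-up.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels, both classes present.
#' @param grid Candidate thresholds (default 0.00 to 1.00 in steps of
#'   0.01).
#' @return List with `threshold` and `f1` (the maximum).
#' @export
select_threshold <- function(scores, labels, grid = seq(0, 1, by = 0.01)) {
  labels <- check_binary_labels(labels)
  stopifnot(length(grid) > 0L)
  if (!any(scores >= min(grid))) {
    stop("no grid threshold yields any predicted positive", call. = FALSE)
  }
  f1 <- vapply(grid, function(t) f1_score(scores, labels, t), numeric(1L))
  best <- which(f1 >= max(f1) - 1e-15)[1L]  # lowest threshold wins ties
  list(threshold = grid[best], f1 = f1[best])
}
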