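# Similarity-propagated mining of negative regulation pairs.
#
# The corpus records only positive (known) regulations, so negatives must
# be mined. The regulation score of a candidate (molecule D, miRNA m) in a
# direction is the mean Tanimoto similarity between D's fingerprint and
# the fingerprints of m's known regulators in that direction: structurally
# dissimilar molecules are unlikely to share a regulation. Candidates
# scoring strictly below a threshold (default 0.1) form the negative pool,
# from which as many pairs as there are positives are drawn uniformly at
# random under an explicit seed, yielding a balanced dataset.

#' Regulation score of a candidate molecule for one miRNA
#'
#' Arithmetic mean of the Tanimoto similarities between the candidate's
#' fingerprint and each known regulator's fingerprint. Undefined (an
#' error) when the miRNA has no known regulator in the direction under
#' consideration.
#'
#' @param candidate_fp Binary fingerprint vector (length 166).
#' @param regulator_fps Binary matrix of known-regulator fingerprints, one
#'   per row; must have at least one row.
#' @return Score in `[0, 1]`.
#' @export
regulation_score <- function(candidate_fp, regulator_fps) {
  if (is.vector(regulator_fps)) {
    regulator_fps <- matrix(regulator_fps, nrow = 1L)
  }
  if (nrow(regulator_fps) == 0L) {
    stop("regulation score undefined: no known regulators", call. = FALSE)
  }
  mean(tanimoto_vec(candidate_fp, regulator_fps))
}

#' Enumerate negative-candidate pairs for a dataset
#'
#' The candidate universe is the Cartesian product of the dataset's own
#' molecules and miRNAs, minus its positive pairs, minus (optionally)
#' pairs known positive in the opposite direction, minus pairs whose miRNA
#' has no known regulator in this direction (their score is undefined).
#'
#' @param ds A `regulation_dataset` containing only positive pairs.
#' @param other_positives Optional data frame (columns `sm_id`,
#'   `mirna_id`) of opposite-direction positives to exclude; `NULL`
#'   disables cross-direction exclusion.
#' @return Data frame with columns `sm_id`, `mirna_id`.
#' @export
enumerate_candidates <- function(ds, other_positives = NULL) {
  stopifnot(inherits(ds, "regulation_dataset"))
  pos <- ds$pairs[ds$pairs$label == "positive", ]
  if (nrow(pos) != nrow(ds$pairs)) {
    stop("candidate enumeration expects a positives-only dataset",
         call. = FALSE)
  }
  with_regulator <- unique(pos$mirna_id)
  cand <- expand.grid(sm_id = rownames(ds$fingerprints),
                      mirna_id = with_regulator,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$sm_id, d$mirna_id, sep = "\r")
  drop <- key(cand) %in% key(pos)
  if (!is.null(other_positives)) {
    stopifnot(all(c("sm_id", "mirna_id") %in% names(other_positives)))
    drop <- drop | key(cand) %in% key(other_positives)
  }
  cand[!drop, , drop = FALSE]
}

#' Score candidate pairs
#'
#' @param ds A positives-only `regulation_dataset`.
#' @param candidates Data frame from [enumerate_candidates()].
#' @return `candidates` with an added `score` column.
#' @export
score_candidates <- function(ds, candidates) {
  pos <- ds$pairs[ds$pairs$label == "positive", ]
  regulators <- split(pos$sm_id, pos$mirna_id)
  scores <- numeric(nrow(candidates))
  # group by miRNA so each regulator fingerprint block is built once
  for (mir in unique(candidates$mirna_id)) {
    regs <- regulators[[mir]]
    if (is.null(regs)) {
      stop(sprintf("miRNA '%s' has no known regulator in this direction",
                   mir), call. = FALSE)
    }
    reg_fp <- ds$fingerprints[regs, , drop = FALSE]
    idx <- which(candidates$mirna_id == mir)
    cand_fp <- ds$fingerprints[candidates$sm_id[idx], , drop = FALSE]
    # mean over regulators of Tanimoto(candidate, regulator)
    m <- cand_fp != 0
    r <- reg_fp != 0
    inter <- m %*% t(r)
    union <- outer(rowSums(m), rowSums(r), `+`) - inter
    tani <- ifelse(union == 0, 0, inter / union)
    scores[idx] <- rowMeans(tani)
  }
  candidates$score <- scores
  candidates
}

#' Mine and attach balanced negative pairs
#'
#' Scores every candidate pair, keeps those with regulation score strictly
#' below `threshold`, draws `n` of them uniformly at random without
#' replacement under `seed`, labels them negative and returns the
#' augmented dataset (positives unchanged, `count(negative) ==
#' count(positive)` by default).
#'
#' @param ds A positives-only `regulation_dataset`.
#' @param other_positives Opposite-direction positives to exclude from the
#'   candidate universe (cross-direction exclusion; `NULL` to disable).
#' @param threshold Score cutoff; strict inequality (`score < threshold`).
#' @param n Number of negatives to draw; defaults to the positive count.
#' @param seed Integer seed for the uniform draw (recorded in the result).
#' @return The augmented `regulation_dataset`, with the full audit table
#'   (`sm_id`, `mirna_id`, `score`, `kept`) attached as attribute
#'   `scores` and the seed as attribute `seed`.
#' @export
sample_negatives <- function(ds, other_positives = NULL, threshold = 0.1,
                             n = NULL, seed = 1L) {
  stopifnot(inherits(ds, "regulation_dataset"))
  n_pos <- sum(ds$pairs$label == "positive")
  if (is.null(n)) n <- n_pos
  cand <- enumerate_candidates(ds, other_positives)
  cand <- score_candidates(ds, cand)
  pool <- which(cand$score < threshold)
  if (length(pool) < n) {
    stop(sprintf(
      paste0("negative pool too small: %d candidates score below %.3g but ",
             "%d are requested; consider relaxing the threshold"),
      length(pool), threshold, n), call. = FALSE)
  }
  take <- local_seed(seed, sample(pool, n))
  cand$kept <- FALSE
  cand$kept[take] <- TRUE
  neg <- data.frame(sm_id = cand$sm_id[take],
                    mirna_id = cand$mirna_id[take],
                    direction = ds$direction,
                    label = "negative",
                    stringsAsFactors = FALSE)
  aug <- regulation_dataset(ds$direction, rbind(ds$pairs, neg),
                            ds$fingerprints, ds$sequences,
                            smiles = ds$smiles)
  attr(aug, "scores") <- cand[, c("sm_id", "mirna_id", "score", "kept")]
  attr(aug, "seed") <- seed
  aug
}
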