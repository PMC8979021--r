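# Batch prediction: the four query modes of the server workflow —
# rank candidate molecules for a miRNA, or candidate miRNAs for a
# molecule, under the up- or the down-regulation model.

featurize_pair <- function(bundle, fingerprint, sequence) {
  x <- matrix(c(build_descriptor(sequence), as.numeric(fingerprint)),
              nrow = 1L)
  colnames(x) <- c(descriptor_names(), maccs_colnames())
  if (!identical(colnames(x), bundle$feature_names)) {
    stop("feature layout does not match the model bundle", call. = FALSE)
  }
  x
}

prediction_frame <- function(bundle, sm_id, mirna_id, probability) {
  data.frame(sm_id = sm_id, mirna_id = mirna_id,
             direction = bundle$direction,
             probability = probability,
             call = ifelse(probability >= bundle$threshold,
                           "worth-studying", "below-threshold"),
             stringsAsFactors = FALSE)
}

#' Predict the regulation probability of one molecule-miRNA pair
#'
#' Featurizes the pair (277 sequence descriptors + 166 MACCS keys), scores
#' it with the bundle's fitted model and compares the probability with the
#' bundle's calibrated suggestion rate: a pair at or above the rate is
#' called `"worth-studying"`.
#'
#' @param bundle A `smireg_bundle`.
#' @param fingerprint Molecule MACCS fingerprint (length-166 binary
#'   vector), or a SMILES string to be featurized with RDKit.
#' @param sequence miRNA sequence (character scalar).
#' @param sm_id,mirna_id Identifiers used in the result.
#' @return One-row data frame: `sm_id`, `mirna_id`, `direction`,
#'   `probability`, `call`.
#' @export
predict_pair <- function(bundle, fingerprint, sequence, sm_id = "query_sm",
                         mirna_id = "query_mirna") {
  stopifnot(inherits(bundle, "smireg_bundle"))
  if (is.character(fingerprint)) {
    fingerprint <- maccs_fingerprint(fingerprint, id = sm_id)
  }
  if (length(fingerprint) != MACCS_BITS) {
    stop(sprintf("fingerprint must have %d bits", MACCS_BITS),
         call. = FALSE)
  }
  x <- featurize_pair(bundle, fingerprint, sequence)
  prediction_frame(bundle, sm_id, mirna_id, predict_prob(bundle$fit, x))
}

#' Rank a candidate library against one query
#'
#' The two molecule-side modes score a query miRNA against a library of
#' molecule fingerprints; the two miRNA-side modes score a query molecule
#' against a library of miRNA sequences. Results are sorted by
#' probability (descending), ties broken by entity id (ascending), and
#' truncated to `top_n`.
#'
#' @param bundle A `smireg_bundle` (its direction selects up- vs
#'   down-regulation).
#' @param query For `mode = "mirna-to-sm"`, the query miRNA sequence (a
#'   character scalar, optionally named with its id); for
#'   `mode = "sm-to-mirna"`, the query molecule as a length-166
#'   fingerprint or a SMILES string.
#' @param library For `"mirna-to-sm"`, a fingerprint matrix (rows =
#'   candidate molecules); for `"sm-to-mirna"`, a named character vector
#'   of candidate miRNA sequences.
#' @param mode `"mirna-to-sm"` or `"sm-to-mirna"`.
#' @param top_n Number of top-ranked results to return (default: all).
#' @return Data frame with columns `rank`, `sm_id`, `mirna_id`,
#'   `direction`, `probability`, `call`, ordered by decreasing
#'   probability.
#' @export
rank_candidates <- function(bundle, query, library,
                            mode = c("mirna-to-sm", "sm-to-mirna"),
                            top_n = NULL) {
  stopifnot(inherits(bundle, "smireg_bundle"))
  mode <- match.arg(mode)
  if (mode == "mirna-to-sm") {
    stopifnot(is.character(query), length(query) == 1L)
    if (!is.matrix(library) || nrow(library) == 0L) {
      stop("library must be a non-empty fingerprint matrix", call. = FALSE)
    }
    mirna_id <- if (!is.null(names(query))) names(query) else "query_mirna"
    desc <- build_descriptor(query)
    x <- cbind(matrix(desc, nrow(library), length(desc), byrow = TRUE),
               library)
    colnames(x) <- c(descriptor_names(), maccs_colnames())
    res <- prediction_frame(bundle, rownames(library), mirna_id,
                            predict_prob(bundle$fit, x))
    ord <- order(-res$probability, res$sm_id)
  } else {
    if (is.character(query) && length(query) == 1L) {
      query <- maccs_fingerprint(query)
    }
    if (length(library) == 0L) stop("library is empty", call. = FALSE)
    stopifnot(is.character(library), !is.null(names(library)))
    desc <- descriptor_matrix(library)
    x <- cbind(desc, matrix(as.numeric(query), length(library),
                            MACCS_BITS, byrow = TRUE))
    colnames(x) <- c(descriptor_names(), maccs_colnames())
    res <- prediction_frame(bundle, "query_sm", names(library),
                            predict_prob(bundle$fit, x))
    ord <- order(-res$probability, res$mirna_id)
  }
  res <- res[ord, , drop = FALSE]
  if (!is.null(top_n)) res <- utils::head(res, top_n)
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}
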