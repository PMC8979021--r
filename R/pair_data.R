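# Loading, validation and direction-wise splitting of the regulation-pair
# corpus.
#
# The input corpus is a 4-column TSV (sm_id, smiles, mirna_id, direction)
# in the style of an SM2miR export plus a mature-miRNA FASTA. Pairs whose
# miRNA has no sequence are dropped (and logged); duplicates on
# (sm_id, mirna_id, direction) are collapsed; retained pairs are labeled
# positive and partitioned by regulation direction into one dataset per
# direction. Identity matching between the pair table and the FASTA is by
# exact id token — no fuzzy name resolution, which is a classic source of
# label leakage.

PAIR_COLUMNS <- c("sm_id", "smiles", "mirna_id", "direction")
DIRECTIONS <- c("up", "down")

#' Construct a regulation dataset
#'
#' A regulation dataset holds all pairs of one regulation direction
#' together with the featurized entities they reference: a fingerprint per
#' molecule and a sequence per miRNA.
#'
#' @param direction `"up"` or `"down"`.
#' @param pairs Data frame with columns `sm_id`, `mirna_id`, `direction`,
#'   `label` (`"positive"`/`"negative"`).
#' @param fingerprints Integer matrix (rows = molecules, 166 MACCS
#'   columns) covering every `sm_id` in `pairs`.
#' @param sequences Named character vector covering every `mirna_id`.
#' @param smiles Optional named character vector of SMILES per molecule
#'   (kept for export; may be `NA` for fingerprint-level corpora).
#' @return Object of class `regulation_dataset`.
#' @export
regulation_dataset <- function(direction, pairs, fingerprints, sequences,
                               smiles = NULL) {
  direction <- match.arg(direction, DIRECTIONS)
  stopifnot(is.data.frame(pairs),
            all(c("sm_id", "mirna_id", "direction", "label") %in%
                  names(pairs)))
  if (nrow(pairs) == 0L) {
    stop(sprintf("empty %s-regulation dataset", direction), call. = FALSE)
  }
  if (!all(pairs$direction == direction)) {
    stop("all pairs must share the dataset direction", call. = FALSE)
  }
  if (!all(pairs$label %in% c("positive", "negative"))) {
    stop("pair labels must be 'positive' or 'negative'", call. = FALSE)
  }
  key <- paste(pairs$sm_id, pairs$mirna_id, pairs$direction)
  if (anyDuplicated(key)) {
    stop("duplicate (sm_id, mirna_id, direction) in pairs", call. = FALSE)
  }
  missing_fp <- setdiff(unique(pairs$sm_id), rownames(fingerprints))
  if (length(missing_fp) > 0L) {
    stop(sprintf("no fingerprint for molecule(s): %s",
                 paste(utils::head(missing_fp, 5L), collapse = ", ")),
         call. = FALSE)
  }
  missing_seq <- setdiff(unique(pairs$mirna_id), names(sequences))
  if (length(missing_seq) > 0L) {
    stop(sprintf("no sequence for miRNA(s): %s",
                 paste(utils::head(missing_seq, 5L), collapse = ", ")),
         call. = FALSE)
  }
  mols <- sort(unique(pairs$sm_id))
  mirs <- sort(unique(pairs$mirna_id))
  structure(list(
    direction = direction,
    pairs = pairs[, c("sm_id", "mirna_id", "direction", "label")],
    fingerprints = fingerprints[mols, , drop = FALSE],
    sequences = sequences[mirs],
    smiles = if (!is.null(smiles)) smiles[mols] else NULL
  ), class = "regulation_dataset")
}

#' @export
print.regulation_dataset <- function(x, ...) {
  s <- dataset_summary(x)
  cat(sprintf(
    "<regulation_dataset: %s> %d pairs (%d positive / %d negative), %d molecules, %d miRNAs\n",
    x$direction, s$n_pairs, s$n_positive, s$n_negative, s$n_molecules,
    s$n_mirnas))
  invisible(x)
}

#' Summary counts of a regulation dataset
#'
#' @param ds A `regulation_dataset`.
#' @return List with `direction`, `n_pairs`, `n_positive`, `n_negative`,
#'   `n_molecules`, `n_mirnas`.
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "regulation_dataset"))
  list(direction = ds$direction,
       n_pairs = nrow(ds$pairs),
       n_positive = sum(ds$pairs$label == "positive"),
       n_negative = sum(ds$pairs$label == "negative"),
       n_molecules = nrow(ds$fingerprints),
       n_mirnas = length(ds$sequences))
}

#' Load a regulation-pair corpus and split it by direction
#'
#' Reads the 4-column pair TSV and the miRNA FASTA, drops pairs whose
#' miRNA id has no sequence (each drop is logged), collapses duplicates on
#' (sm_id, mirna_id, direction), labels every retained pair positive and
#' returns one dataset per direction.
#'
#' Molecule fingerprints are taken from `fingerprints` when supplied
#' (precomputed, e.g. by the synthetic-corpus generator) and otherwise
#' computed from the SMILES column with RDKit; in the latter case
#' duplicate molecules are detected by canonical-SMILES equality and
#' conflicting duplicate ids are an error.
#'
#' @param pair_table Path to the pair TSV (columns `sm_id`, `smiles`,
#'   `mirna_id`, `direction`).
#' @param sequences Path to the miRNA FASTA, or a named character vector
#'   of sequences.
#' @param fingerprints Optional precomputed fingerprint matrix or path to
#'   a fingerprint TSV (see [read_fingerprints()]).
#' @param species_prefix Optional id prefix filter (e.g. `"hsa-"`) applied
#'   to miRNA ids before anything else.
#' @return List with elements `up` and `down` (each a
#'   `regulation_dataset`, or `NULL` when that direction has no retained
#'   pairs — at least one is non-`NULL`) and `dropped` (data frame of
#'   discarded rows with a `reason` column).
#' @export
load_pairs <- function(pair_table, sequences, fingerprints = NULL,
                       species_prefix = NULL) {
  pairs <- if (is.data.frame(pair_table)) pair_table else {
    if (!file.exists(pair_table)) {
      stop(sprintf("pair table not found: %s", pair_table), call. = FALSE)
    }
    utils::read.delim(pair_table, stringsAsFactors = FALSE,
                      check.names = FALSE)
  }
  missing <- setdiff(PAIR_COLUMNS, names(pairs))
  if (length(missing) > 0L) {
    stop(sprintf("pair table lacks required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad_dir <- !pairs$direction %in% DIRECTIONS
  if (any(bad_dir)) {
    stop(sprintf("invalid direction '%s' (expected up/down)",
                 pairs$direction[bad_dir][1L]), call. = FALSE)
  }
  seqs <- if (is.character(sequences) && length(sequences) == 1L &&
                file.exists(sequences)) read_mirna_fasta(sequences)
          else sequences
  stopifnot(!is.null(names(seqs)))

  dropped <- pairs[0, ]
  dropped$reason <- character(0L)
  if (!is.null(species_prefix)) {
    off <- !startsWith(pairs$mirna_id, species_prefix)
    if (any(off)) {
      d <- pairs[off, ]; d$reason <- "species filter"
      dropped <- rbind(dropped, d)
      pairs <- pairs[!off, ]
    }
  }
  no_seq <- !pairs$mirna_id %in% names(seqs)
  if (any(no_seq)) {
    d <- pairs[no_seq, ]; d$reason <- "missing miRNA sequence"
    dropped <- rbind(dropped, d)
    message(sprintf("dropped %d pair(s) with no sequence for: %s",
                    sum(no_seq),
                    paste(utils::head(unique(pairs$mirna_id[no_seq]), 5L),
                          collapse = ", ")))
    pairs <- pairs[!no_seq, ]
  }
  dup <- duplicated(pairs[, c("sm_id", "mirna_id", "direction")])
  if (any(dup)) {
    d <- pairs[dup, ]; d$reason <- "duplicate pair"
    dropped <- rbind(dropped, d)
    pairs <- pairs[!dup, ]
  }
  if (nrow(pairs) == 0L) {
    stop("no pairs retained after filtering", call. = FALSE)
  }
  pairs$label <- "positive"

  # molecule featurization (shared across directions)
  first <- !duplicated(pairs$sm_id)
  mol_ids <- pairs$sm_id[first]
  mol_smiles <- stats::setNames(pairs$smiles[first], mol_ids)
  if (is.null(fingerprints)) {
    fp <- maccs_fingerprints(unname(mol_smiles), ids = mol_ids)
  } else {
    fp <- if (is.matrix(fingerprints)) fingerprints
          else read_fingerprints(fingerprints)
  }

  out <- list(up = NULL, down = NULL, dropped = dropped)
  for (dir in DIRECTIONS) {
    sub <- pairs[pairs$direction == dir, ]
    if (nrow(sub) > 0L) {
      out[[dir]] <- regulation_dataset(dir, sub, fp, seqs,
                                       smiles = mol_smiles)
    }
  }
  out
}

#' Export a validated dataset directory
#'
#' Writes `pairs.tsv`, `molecules.tsv` (id, smiles), `fingerprints.tsv`,
#' `mirnas.fasta` and `summary.json` under `dir`.
#'
#' @param ds A `regulation_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "regulation_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(ds$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mols <- data.frame(
    id = rownames(ds$fingerprints),
    smiles = if (!is.null(ds$smiles)) unname(ds$smiles) else NA_character_,
    stringsAsFactors = FALSE)
  utils::write.table(mols, file.path(dir, "molecules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fingerprints(ds$fingerprints, file.path(dir, "fingerprints.tsv"))
  write_mirna_fasta(ds$sequences, file.path(dir, "mirnas.fasta"))
  jsonlite::write_json(dataset_summary(ds),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a dataset directory written by [export_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `regulation_dataset`.
#' @export
load_dataset <- function(dir) {
  pairs <- utils::read.delim(file.path(dir, "pairs.tsv"),
                             stringsAsFactors = FALSE)
  fp <- read_fingerprints(file.path(dir, "fingerprints.tsv"))
  seqs <- read_mirna_fasta(file.path(dir, "mirnas.fasta"))
  mols_path <- file.path(dir, "molecules.tsv")
  smiles <- NULL
  if (file.exists(mols_path)) {
    mols <- utils::read.delim(mols_path, stringsAsFactors = FALSE)
    if (!all(is.na(mols$smiles))) {
      smiles <- stats::setNames(mols$smiles, mols$id)
    }
  }
  regulation_dataset(pairs$direction[1L], pairs, fp, seqs, smiles = smiles)
}
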