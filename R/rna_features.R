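# Sequence-composition descriptors for mature miRNAs.
#
# A mature miRNA is encoded as a 277-dimensional numeric vector:
#   [1]       sequence length (nt)
#   [2..5]    mononucleotide ratios A, C, G, U
#   [6..21]   2-mer frequencies, lexicographic over A < C < G < U
#   [22..277] 4-mer frequencies, lexicographic
# k-mer frequency = overlapping-window count / (L - k + 1), so each k-block
# is a probability vector. The ordering is frozen: trained models depend on
# the column layout.

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalize a raw miRNA sequence
#'
#' Uppercases the input and maps the DNA alphabet to RNA (`T` -> `U`).
#' Any character outside `A/C/G/U/T` (either case) is a hard error naming
#' the offending character and its position; IUPAC ambiguity codes are not
#' silently accepted.
#'
#' @param raw Character scalar, the sequence as read from input.
#' @return Character scalar over the alphabet `A`, `C`, `G`, `U`.
#' @examples
#' normalize_sequence("guuccu")   # "GUUCCU"
#' normalize_sequence("GTTCCT")   # "GUUCCU"
#' @export
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is.na(raw) || !nzchar(raw)) {
    stop("sequence is empty", call. = FALSE)
  }
  up <- chartr("acgut", "ACGUT", raw)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(RNA_ALPHABET, "T"))
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid character '%s' at position %d (allowed: A/C/G/U/T, any case)",
      chars[bad[1L]], bad[1L]
    ), call. = FALSE)
  }
  chartr("T", "U", up)
}

#' All k-mers over the RNA alphabet in lexicographic order
#'
#' @param k Word length.
#' @return Character vector of length `4^k`, ordered with A < C < G < U.
#' @export
kmer_universe <- function(k) {
  stopifnot(k >= 1L)
  out <- RNA_ALPHABET
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      out <- as.vector(t(outer(out, RNA_ALPHABET, paste0)))
    }
  }
  out
}

#' Overlapping k-mer frequencies of a normalized sequence
#'
#' Counts every overlapping window of length `k` and divides by the number
#' of windows, `L - k + 1`, so the returned vector sums to one. All `4^k`
#' k-mers are reported (absent ones as zero) in lexicographic order.
#'
#' @param seq Normalized sequence (see [normalize_sequence()]).
#' @param k Word length, `>= 1`; the sequence must be at least `k` long.
#' @return Named numeric vector of length `4^k`.
#' @examples
#' kmer_frequencies("ACGU", 2)  # AC, CG, GU each 1/3
#' @export
kmer_frequencies <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1L)
  n <- nchar(seq)
  if (n < k) {
    stop(sprintf("sequence length %d is shorter than k = %d", n, k),
         call. = FALSE)
  }
  universe <- kmer_universe(k)
  windows <- substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  counts <- table(factor(windows, levels = universe))
  out <- as.numeric(counts) / (n - k + 1L)
  names(out) <- universe
  out
}

#' Descriptor column names (length, ratios, 2-mers, 4-mers)
#'
#' @return Character vector of the 277 descriptor column names, in the
#'   frozen order used by [build_descriptor()].
#' @export
descriptor_names <- function() {
  c("len",
    paste0("ratio_", RNA_ALPHABET),
    paste0("f_", kmer_universe(2L)),
    paste0("f_", kmer_universe(4L)))
}

#' Build the 277-dimensional miRNA descriptor
#'
#' Layout: sequence length (1), mononucleotide ratios (4), 2-mer
#' frequencies (16), 4-mer frequencies (256). Sequences shorter than 4 nt
#' are rejected (the 4-mer block would be undefined). The input is
#' normalized first, so DNA-alphabet and lowercase input are accepted.
#'
#' @param sequence miRNA sequence (character scalar).
#' @return Named numeric vector of length 277.
#' @examples
#' d <- build_descriptor("GUUCCUGCUGAACUGAGCCAG")
#' d[["len"]]      # 21
#' d[["ratio_A"]]  # 4/21
#' @export
build_descriptor <- function(sequence) {
  seq <- normalize_sequence(sequence)
  if (nchar(seq) < 4L) {
    stop(sprintf("sequence length %d < 4; 4-mer frequencies are undefined",
                 nchar(seq)), call. = FALSE)
  }
  out <- c(nchar(seq),
           kmer_frequencies(seq, 1L),
           kmer_frequencies(seq, 2L),
           kmer_frequencies(seq, 4L))
  names(out) <- descriptor_names()
  out
}

#' Read mature miRNA sequences from a FASTA file
#'
#' Multi-record FASTA with wrapped lines is supported; the id is the header
#' token up to the first whitespace. Sequences are normalized (uppercase,
#' `T` mapped to `U`) and validated.
#'
#' @param path FASTA file path.
#' @return Named character vector of normalized sequences; names are ids.
#' @export
read_mirna_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop(sprintf("no records in FASTA file: %s", path), call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated miRNA id in FASTA: %s",
                 ids[duplicated(ids)][1L]), call. = FALSE)
  }
  seqs <- as.character(set)
  out <- vapply(seq_along(seqs), function(i) {
    tryCatch(normalize_sequence(seqs[[i]]),
             error = function(e) stop(sprintf("record '%s': %s",
                                              ids[i], conditionMessage(e)),
                                      call. = FALSE))
  }, character(1L))
  names(out) <- ids
  out
}

#' Write miRNA sequences to a FASTA file
#'
#' @param sequences Named character vector (ids as names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirna_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  lines <- as.vector(rbind(paste0(">", names(sequences)),
                           unname(sequences)))
  writeLines(lines, path)
  invisible(path)
}

#' Descriptor matrix for a set of miRNAs
#'
#' @param sequences Named character vector of sequences.
#' @return Numeric matrix, one row per miRNA, 277 named columns.
#' @export
descriptor_matrix <- function(sequences) {
  stopifnot(length(sequences) > 0L, !is.null(names(sequences)))
  mat <- t(vapply(sequences, build_descriptor,
                  numeric(length(descriptor_names()))))
  rownames(mat) <- names(sequences)
  mat
}

#' Export a descriptor matrix as TSV
#'
#' One row per miRNA: an `id` column followed by the 277 named descriptor
#' columns.
#'
#' @param sequences Named character vector of sequences.
#' @param path Output TSV path.
#' @return The data frame written, invisibly.
#' @export
export_descriptors <- function(sequences, path) {
  mat <- descriptor_matrix(sequences)
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
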