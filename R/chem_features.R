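# Small-molecule featurization: 166-key MACCS structural fingerprints and
# Tanimoto similarity.
#
# Fingerprints are computed by RDKit through the bundled helper script
# (inst/python/maccs_fp.py), run under the `python` found on the PATH.
# RDKit's 167-bit MACCS convention reserves bit 0, which is always unset;
# we drop it so exactly the 166 public keys remain, key i at position i.
# Absolute bit patterns are backend-dependent (MACCS SMARTS definitions
# differ slightly between toolkits); the pipeline logic does not depend on
# any particular pattern, only on fingerprints being fixed-length binary
# vectors.

MACCS_BITS <- 166L

maccs_colnames <- function() paste0("maccs_", seq_len(MACCS_BITS))

find_python <- function(python = getOption("smiReg.python", "python")) {
  path <- Sys.which(python)
  if (!nzchar(path)) {
    stop(sprintf(
      "no '%s' executable on the PATH; SMILES featurization needs Python with RDKit",
      python), call. = FALSE)
  }
  path
}

maccs_script <- function() {
  p <- system.file("python", "maccs_fp.py", package = "smiReg")
  if (!nzchar(p)) stop("bundled maccs_fp.py not found", call. = FALSE)
  p
}

#' MACCS fingerprints for a set of SMILES strings
#'
#' Parses each SMILES with RDKit (via the `python` on the PATH) and returns
#' the 166-key MACCS fingerprint. Input SMILES need not be canonical: the
#' fingerprint is computed from the parsed molecule, and the canonical form
#' is returned so duplicates can be detected by structure rather than by
#' string.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Molecule identifiers; defaults to `names(smiles)` or
#'   `mol1 ... molN`.
#' @param on_error `"stop"` (default) fails on the first unparseable
#'   SMILES, naming the id and string; `"skip"` drops offenders and lists
#'   them in the `skipped` attribute of the result.
#' @return Integer matrix (`n x 166`, values 0/1) with molecule ids as row
#'   names and `maccs_1 ... maccs_166` as column names. The canonical
#'   SMILES are attached as attribute `canonical_smiles`; skipped rows (if
#'   any) as attribute `skipped` (data frame of id, smiles, message).
#' @export
maccs_fingerprints <- function(smiles, ids = NULL,
                               on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles), length(smiles) > 0L)
  if (is.null(ids)) {
    ids <- if (!is.null(names(smiles))) names(smiles)
           else paste0("mol", seq_along(smiles))
  }
  stopifnot(length(ids) == length(smiles))
  if (any(!nzchar(smiles) | is.na(smiles))) {
    stop("empty SMILES for id(s): ",
         paste(ids[!nzchar(smiles) | is.na(smiles)], collapse = ", "),
         call. = FALSE)
  }
  py <- find_python()
  input <- paste(ids, smiles, sep = "\t")
  out <- suppressWarnings(
    system2(py, shQuote(maccs_script()), input = input, stdout = TRUE,
            stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("MACCS helper failed (is RDKit importable under 'python'?)",
         call. = FALSE)
  }
  fields <- strsplit(out, "\t", fixed = TRUE)
  if (length(fields) != length(smiles)) {
    stop("MACCS helper returned an unexpected number of rows", call. = FALSE)
  }
  ok <- vapply(fields, `[[`, character(1L), 2L) == "ok"
  if (any(!ok)) {
    bad <- which(!ok)
    msgs <- vapply(fields[bad], `[[`, character(1L), 3L)
    if (on_error == "stop") {
      stop(sprintf("molecule '%s': %s", ids[bad[1L]], msgs[1L]),
           call. = FALSE)
    }
    skipped <- data.frame(id = ids[bad], smiles = smiles[bad],
                          message = msgs, stringsAsFactors = FALSE)
  } else {
    skipped <- NULL
  }
  keep <- which(ok)
  if (length(keep) == 0L) {
    stop("no SMILES could be parsed", call. = FALSE)
  }
  bits <- t(vapply(fields[keep], function(f) {
    as.integer(strsplit(f[[4L]], "", fixed = TRUE)[[1L]])
  }, integer(MACCS_BITS)))
  rownames(bits) <- ids[keep]
  colnames(bits) <- maccs_colnames()
  attr(bits, "canonical_smiles") <-
    stats::setNames(vapply(fields[keep], `[[`, character(1L), 3L), ids[keep])
  if (!is.null(skipped)) attr(bits, "skipped") <- skipped
  bits
}

#' MACCS fingerprint of a single molecule
#'
#' @param smiles SMILES string.
#' @param id Molecule id used in error messages.
#' @return Integer vector of length 166 (0/1).
#' @export
maccs_fingerprint <- function(smiles, id = "query") {
  drop(maccs_fingerprints(smiles, ids = id)[1L, ])
}

#' Tanimoto similarity between two binary fingerprints
#'
#' `|on in both| / |on in either|`. Two all-zero fingerprints have
#' similarity 0 (featureless molecules are not declared similar).
#'
#' @param a,b Binary vectors of equal length (0/1 or logical).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("fingerprint length mismatch: %d vs %d",
                 length(a), length(b)), call. = FALSE)
  }
  a <- as.logical(a)
  b <- as.logical(b)
  union <- sum(a | b)
  if (union == 0L) return(0)
  sum(a & b) / union
}

#' Tanimoto similarities of one fingerprint against a fingerprint matrix
#'
#' Vectorized counterpart of [tanimoto()] for scoring one molecule against
#' many.
#'
#' @param x Binary vector of length equal to `ncol(mat)`.
#' @param mat Binary matrix, one fingerprint per row.
#' @return Numeric vector, one similarity per row of `mat`.
#' @export
tanimoto_vec <- function(x, mat) {
  stopifnot(is.matrix(mat), length(x) == ncol(mat))
  x <- as.numeric(as.logical(x))
  m <- mat != 0
  inter <- as.vector(m %*% x)
  union <- rowSums(m) + sum(x) - inter
  ifelse(union == 0, 0, inter / union)
}

#' Read molecules from a SMILES table
#'
#' Accepts either a headered TSV with columns `id` and `smiles`, or a
#' headerless one-SMILES-per-line file (ids are generated as
#' `mol1 ... molN`).
#'
#' @param path Input file path.
#' @return Data frame with columns `id` and `smiles`.
#' @export
read_smiles_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("SMILES file not found: %s", path), call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    missing <- setdiff(c("id", "smiles"), names(df))
    if (length(missing) > 0L) {
      stop(sprintf("SMILES TSV %s lacks column(s): %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    df[, c("id", "smiles")]
  } else {
    smiles <- readLines(path)
    smiles <- smiles[nzchar(smiles)]
    data.frame(id = paste0("mol", seq_along(smiles)), smiles = smiles,
               stringsAsFactors = FALSE)
  }
}

#' Write a fingerprint matrix as TSV
#'
#' One row per molecule: `id` column plus 166 columns `maccs_1 ...
#' maccs_166` of 0/1. The format round-trips through
#' [read_fingerprints()], which is also the import path for precomputed
#' fingerprints (as emitted by the synthetic-corpus generator).
#'
#' @param fp Integer matrix as returned by [maccs_fingerprints()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fp, path) {
  stopifnot(is.matrix(fp), ncol(fp) == MACCS_BITS, !is.null(rownames(fp)))
  df <- data.frame(id = rownames(fp), fp, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fingerprint matrix from TSV
#'
#' @param path TSV written by [write_fingerprints()].
#' @return Integer matrix (`n x 166`, 0/1), molecule ids as row names.
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("fingerprint file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("id", maccs_colnames()), names(df))
  if (length(missing) > 0L) {
    stop(sprintf("fingerprint TSV %s lacks %d expected column(s), e.g. %s",
                 path, length(missing), missing[1L]), call. = FALSE)
  }
  mat <- as.matrix(df[, maccs_colnames()])
  if (!all(mat %in% c(0L, 1L))) {
    stop("fingerprint TSV contains values other than 0/1", call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$id
  mat
}
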