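# Synthetic SM2miR-like corpora with planted, recoverable structure.
#
# The generator emulates the shape of a curated regulation corpus without
# any download: molecules fall into structural families (each family owns
# a disjoint block of MACCS keys; members are the family prototype with
# independent bit flips), each family is assigned a unique sequence motif
# (a 4-mer by default), miRNA sequences are uniform random with the
# family motif planted in the subset that family regulates, and every
# (family member, motif-bearing miRNA) pair is emitted as a positive pair
# with the family's regulation direction. A fraction of emitted labels is
# corrupted; the uncorrupted rule is recorded in a ground-truth table so
# recovery tests can score against it.
#
# Molecules are emitted at fingerprint level (sampling chemically valid
# SMILES with controlled similarity is out of scope); the SMILES code
# path is exercised by a small fixture of real drug SMILES shipped under
# inst/extdata.

#' Synthetic corpus configuration
#'
#' @param n_families Number of molecule families (each owns a disjoint
#'   block of MACCS keys and one sequence motif).
#' @param molecules_per_family Members per family.
#' @param n_mirnas Total miRNAs; each family regulates
#'   `floor(n_mirnas / (2 * n_families))` of them, the remainder carry no
#'   motif.
#' @param motif_length Planted motif length (default 4, so the signal
#'   lives in the descriptor's 4-mer block).
#' @param fingerprint_noise Per-key bit-flip probability when deriving a
#'   member from its family prototype (default 0.05).
#' @param label_noise Probability that an emitted pair's direction is
#'   corrupted (default 0.05).
#' @param directions Direction per family, recycled (default alternates
#'   up/down).
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the configuration.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_families = 10L, molecules_per_family = 10L,
                             n_mirnas = 200L, motif_length = 4L,
                             fingerprint_noise = 0.05, label_noise = 0.05,
                             directions = c("up", "down"), seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              molecules_per_family = as.integer(molecules_per_family),
              n_mirnas = as.integer(n_mirnas),
              motif_length = as.integer(motif_length),
              fingerprint_noise = fingerprint_noise,
              label_noise = label_noise,
              directions = match.arg(directions, DIRECTIONS,
                                     several.ok = TRUE),
              seed = as.integer(seed))
  stopifnot(cfg$n_families >= 1L, cfg$molecules_per_family >= 1L,
            cfg$n_mirnas >= cfg$n_families, cfg$motif_length >= 1L,
            cfg$fingerprint_noise >= 0, cfg$fingerprint_noise <= 1,
            cfg$label_noise >= 0, cfg$label_noise <= 1)
  if (cfg$n_families > MACCS_BITS %/% 4L) {
    stop("too many families: each needs a block of at least 4 MACCS keys",
         call. = FALSE)
  }
  if (cfg$n_families > 4^cfg$motif_length %/% 2L) {
    stop("too many families for distinct motifs of this length",
         call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

random_rna <- function(n, min_len = 18L, max_len = 25L) {
  vapply(seq_len(n), function(i) {
    len <- sample.int(max_len - min_len + 1L, 1L) + min_len - 1L
    paste(sample(RNA_ALPHABET, len, replace = TRUE), collapse = "")
  }, character(1L))
}

plant_motif <- function(seq, motif) {
  len <- nchar(seq)
  k <- nchar(motif)
  pos <- sample.int(len - k + 1L, 1L)
  paste0(substr(seq, 1L, pos - 1L), motif, substr(seq, pos + k, len))
}

#' Generate a synthetic regulation corpus
#'
#' See the file header for the generative model. All randomness flows
#' from `cfg$seed`; the same configuration always produces an identical
#' corpus.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `pairs` (data frame: `sm_id`, `smiles` (`NA`),
#'   `mirna_id`, `direction`), `fingerprints` (0/1 matrix, molecules x
#'   166), `sequences` (named character vector), `truth` (data frame:
#'   `sm_id`, `mirna_id`, `true_direction` (`"none"` for non-regulating
#'   combinations actually emitted), `family`, `corrupted`) and `config`.
#' @export
generate_corpus <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  local_seed(cfg$seed, {
    nf <- cfg$n_families
    # disjoint key blocks; prototype = every key of its block
    block <- floor(MACCS_BITS / nf)
    proto <- matrix(0L, nf, MACCS_BITS)
    for (f in seq_len(nf)) {
      proto[f, ((f - 1L) * block + 1L):(f * block)] <- 1L
    }
    # one unique motif per family (sampled without replacement, and
    # regenerated as a whole on the rare collision with a reverse pick)
    motifs <- character(0L)
    repeat {
      motifs <- vapply(seq_len(nf), function(f) {
        paste(sample(RNA_ALPHABET, cfg$motif_length, replace = TRUE),
              collapse = "")
      }, character(1L))
      if (!anyDuplicated(motifs)) break
      message("motif collision across families; regenerating")
    }
    fam_dir <- rep_len(cfg$directions, nf)

    # molecules: family prototypes with independent bit flips
    n_mol <- nf * cfg$molecules_per_family
    fp <- matrix(0L, n_mol, MACCS_BITS,
                 dimnames = list(sprintf("SM%03d", seq_len(n_mol)),
                                 maccs_colnames()))
    mol_family <- rep(seq_len(nf), each = cfg$molecules_per_family)
    for (i in seq_len(n_mol)) {
      bits <- proto[mol_family[i], ]
      flip <- stats::runif(MACCS_BITS) < cfg$fingerprint_noise
      fp[i, ] <- ifelse(flip, 1L - bits, bits)
    }

    # miRNAs: uniform sequences with the family motif planted in the
    # regulated set. Sequences are rejection-sampled so that no miRNA
    # carries a motif by chance: motif presence is then equivalent to
    # regulation by that family, making the planted rule exactly
    # recoverable from the descriptors.
    per_fam <- max(1L, cfg$n_mirnas %/% (2L * nf))
    mir_family <- rep(NA_integer_, cfg$n_mirnas)
    slot <- 0L
    for (f in seq_len(nf)) {
      idx <- slot + seq_len(per_fam)
      if (max(idx) > cfg$n_mirnas) break
      mir_family[idx] <- f
      slot <- slot + per_fam
    }
    draw_mirna <- function(fam) {
      repeat {
        s <- random_rna(1L)
        if (!is.na(fam)) s <- plant_motif(s, motifs[fam])
        banned <- if (is.na(fam)) motifs else motifs[-fam]
        if (!any(vapply(banned, grepl, logical(1L), x = s,
                        fixed = TRUE))) return(s)
      }
    }
    seqs <- vapply(mir_family, draw_mirna, character(1L))
    names(seqs) <- sprintf("syn-miR-%03d", seq_len(cfg$n_mirnas))

    # positive pairs: every family member x every miRNA the family regulates
    pair_list <- lapply(seq_len(nf), function(f) {
      mols <- rownames(fp)[mol_family == f]
      mirs <- names(seqs)[!is.na(mir_family) & mir_family == f]
      if (length(mirs) == 0L) return(NULL)
      expand.grid(sm_id = mols, mirna_id = mirs,
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    })
    fam_of_pair <- rep(seq_len(nf),
                       vapply(pair_list, function(d) if (is.null(d)) 0L
                              else nrow(d), integer(1L)))
    pairs <- do.call(rbind, pair_list)
    if (is.null(pairs) || nrow(pairs) == 0L) {
      stop("impossible configuration: no positive pairs emitted",
           call. = FALSE)
    }
    true_dir <- fam_dir[fam_of_pair]
    corrupt <- stats::runif(nrow(pairs)) < cfg$label_noise
    flip_dir <- function(d) ifelse(d == "up", "down", "up")
    emitted <- ifelse(corrupt, flip_dir(true_dir), true_dir)

    list(pairs = data.frame(sm_id = pairs$sm_id, smiles = NA_character_,
                            mirna_id = pairs$mirna_id,
                            direction = emitted,
                            stringsAsFactors = FALSE),
         fingerprints = fp,
         sequences = seqs,
         truth = data.frame(sm_id = pairs$sm_id,
                            mirna_id = pairs$mirna_id,
                            true_direction = true_dir,
                            family = fam_of_pair,
                            corrupted = corrupt,
                            stringsAsFactors = FALSE),
         motifs = motifs,
         config = cfg)
  })
}

#' Write a synthetic corpus to disk
#'
#' Emits `pairs.tsv`, `fingerprints.tsv` and `mirnas.fasta` in exactly
#' the formats the corpus loader consumes, plus `truth.tsv` and
#' `config.json`.
#'
#' @param corpus Result of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(corpus$pairs, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fingerprints(corpus$fingerprints,
                     file.path(dir, "fingerprints.tsv"))
  write_mirna_fasta(corpus$sequences, file.path(dir, "mirnas.fasta"))
  utils::write.table(corpus$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(corpus$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
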