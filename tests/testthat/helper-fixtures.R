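# Shared fixture builders. Everything is generated in code; nothing is
# read from outside the package.

# fingerprint with the given on-bit indices
fp_bits <- function(on, n = 166L) {
  v <- integer(n)
  v[on] <- 1L
  v
}

# random 0/1 fingerprint matrix with row names
random_fp_matrix <- function(n, density = 0.2, seed = 1L, nbits = 166L) {
  withr::with_seed(seed, {
    m <- matrix(as.integer(runif(n * nbits) < density), n, nbits,
                dimnames = list(sprintf("SM%03d", seq_len(n)),
                                paste0("maccs_", seq_len(nbits))))
    m
  })
}

# linearly separable two-class problem for learner tests:
# class means differ along the first 20 of p features
separable_xy <- function(n = 120L, p = 40L, gap = 2, seed = 1L) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * p), n, p)
    shift <- seq_len(min(20L, p))
    x[, shift] <- x[, shift] + gap * y
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, y = y)
  })
}

# small planted-structure corpus -> balanced up-direction dataset
balanced_synthetic_dataset <- function(seed = 5L, n_families = 6L,
                                       molecules_per_family = 6L,
                                       n_mirnas = 72L, ...) {
  corpus <- generate_corpus(synthetic_config(
    n_families = n_families, molecules_per_family = molecules_per_family,
    n_mirnas = n_mirnas, seed = seed, ...))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_corpus(corpus, dir)
  res <- load_pairs(file.path(dir, "pairs.tsv"),
                    file.path(dir, "mirnas.fasta"),
                    fingerprints = file.path(dir, "fingerprints.tsv"))
  sample_negatives(res$up, other_positives = res$down$pairs,
                   seed = seed + 1L)
}

# brute-force AUC: mean over (positive, negative) pairs of the indicator
# that the positive outscores the negative, ties counting one half
auc_pairs_oracle <- function(scores, labels) {
  sp <- scores[labels == 1L]
  sn <- scores[labels == 0L]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

random_rna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
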