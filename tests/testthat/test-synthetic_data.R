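test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(n_families = 60L), "too many families")
  expect_error(synthetic_config(fingerprint_noise = 1.5), "fingerprint_noise")
  expect_error(synthetic_config(n_families = 10L, motif_length = 1L),
               "distinct motifs")
})

test_that("the corpus is a deterministic function of the configuration", {
  cfg <- synthetic_config(n_families = 4L, molecules_per_family = 4L,
                          n_mirnas = 40L, seed = 33L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_corpus(generate_corpus(cfg), d1)
  write_corpus(generate_corpus(cfg), d2)
  for (f in c("pairs.tsv", "fingerprints.tsv", "mirnas.fasta",
              "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # a different seed generically changes the corpus
  d3 <- withr::local_tempdir()
  write_corpus(generate_corpus(synthetic_config(
    n_families = 4L, molecules_per_family = 4L, n_mirnas = 40L,
    seed = 34L)), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "pairs.tsv"))),
                         unname(tools::md5sum(file.path(d3, "pairs.tsv")))))
})

test_that("emitted files parse cleanly through the corpus loader", {
  dir <- withr::local_tempdir()
  write_corpus(generate_corpus(synthetic_config(seed = 3L)), dir)
  expect_no_warning(
    res <- load_pairs(file.path(dir, "pairs.tsv"),
                      file.path(dir, "mirnas.fasta"),
                      fingerprints = file.path(dir, "fingerprints.tsv")))
  expect_s3_class(res$up, "regulation_dataset")
  expect_s3_class(res$down, "regulation_dataset")
})

test_that("planted structure: family similarity and motif placement", {
  corpus <- generate_corpus(synthetic_config(seed = 17L))
  fam <- corpus$truth$family[match(rownames(corpus$fingerprints),
                                   corpus$truth$sm_id)]
  keep <- !is.na(fam)
  fam <- fam[keep]
  fp <- corpus$fingerprints[keep, ]
  # within-family mean Tanimoto exceeds between-family mean at noise 0.05
  withr::with_seed(1, {
    n <- nrow(fp)
    within <- c(); between <- c()
    for (rep in seq_len(400L)) {
      ij <- sample(n, 2L)
      t <- tanimoto(fp[ij[1L], ], fp[ij[2L], ])
      if (fam[ij[1L]] == fam[ij[2L]]) within <- c(within, t)
      else between <- c(between, t)
    }
    expect_gt(mean(within), mean(between))
    expect_lt(mean(between), 0.1)  # cross-family pairs can be mined as negatives
  })
  # every positive pair's miRNA carries its family motif
  motif_of <- corpus$motifs[corpus$truth$family]
  hit <- mapply(grepl, motif_of,
                corpus$sequences[corpus$truth$mirna_id], fixed = TRUE)
  expect_true(all(hit))
})

test_that("a noise-free corpus is perfectly separable and learnable", {
  cfg <- synthetic_config(n_families = 4L, molecules_per_family = 6L,
                          n_mirnas = 64L, fingerprint_noise = 0,
                          label_noise = 0, directions = "up", seed = 8L)
  corpus <- generate_corpus(cfg)
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  res <- load_pairs(file.path(dir, "pairs.tsv"),
                    file.path(dir, "mirnas.fasta"),
                    fingerprints = file.path(dir, "fingerprints.tsv"))
  aug <- sample_negatives(res$up, seed = 1L)

  # rule-based oracle: a pair is positive iff the miRNA carries the
  # molecule's family motif -> classes are separable by construction
  fam_of_mol <- corpus$truth$family[match(aug$pairs$sm_id,
                                          corpus$truth$sm_id)]
  rule_hit <- mapply(function(f, mir) {
    grepl(corpus$motifs[f], corpus$sequences[[mir]], fixed = TRUE)
  }, fam_of_mol, aug$pairs$mirna_id)
  expect_identical(unname(rule_hit), aug$pairs$label == "positive")

  f <- assemble_features(aug)
  sp <- split_train_test(f$y, seed = 2L)
  fit <- fit_learner("rf", f$x[sp$train, ], f$y[sp$train], param = 50L,
                     seed = 3L, ntree = 150L)
  auc <- auc_rank(predict_prob(fit, f$x[sp$test, ]), f$y[sp$test])
  expect_gte(auc, 0.99)
})

test_that("mined negatives have a lower true-regulation rate than positives", {
  corpus <- generate_corpus(synthetic_config(seed = 21L))
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  res <- load_pairs(file.path(dir, "pairs.tsv"),
                    file.path(dir, "mirnas.fasta"),
                    fingerprints = file.path(dir, "fingerprints.tsv"))
  aug <- sample_negatives(res$up, other_positives = res$down$pairs,
                          seed = 4L)
  truth_key <- paste(corpus$truth$sm_id, corpus$truth$mirna_id)
  truly_up <- truth_key[corpus$truth$true_direction == "up"]
  rate <- function(label) {
    p <- aug$pairs[aug$pairs$label == label, ]
    mean(paste(p$sm_id, p$mirna_id) %in% truly_up)
  }
  expect_gt(rate("positive"), rate("negative"))
  expect_lt(rate("negative"), 0.05)
})
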