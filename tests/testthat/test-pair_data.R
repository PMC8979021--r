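make_toy_inputs <- function(dir) {
  fp <- rbind(SM1 = fp_bits(1:10), SM2 = fp_bits(5:14),
              SM3 = fp_bits(100:110))
  colnames(fp) <- paste0("maccs_", 1:166)
  pairs <- data.frame(
    sm_id = c("SM1", "SM2", "SM1", "SM3", "SM2"),
    smiles = NA_character_,
    mirna_id = c("mirA", "mirA", "mirB", "mirC", "mir-unknown"),
    direction = c("up", "up", "down", "up", "up"),
    stringsAsFactors = FALSE)
  write.table(pairs, file.path(dir, "pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_mirna_fasta(c(mirA = "GUUCCUGCUG", mirB = "ACGUACGUAC",
                      mirC = "UUUUCCCCGG"),
                    file.path(dir, "mirnas.fasta"))
  write_fingerprints(fp, file.path(dir, "fingerprints.tsv"))
  dir
}

test_that("load_pairs drops missing-sequence rows, dedupes and partitions", {
  dir <- withr::local_tempdir()
  make_toy_inputs(dir)
  expect_message(
    res <- load_pairs(file.path(dir, "pairs.tsv"),
                      file.path(dir, "mirnas.fasta"),
                      fingerprints = file.path(dir, "fingerprints.tsv")),
    "mir-unknown")
  expect_identical(res$dropped$reason, "missing miRNA sequence")
  s_up <- dataset_summary(res$up)
  s_down <- dataset_summary(res$down)
  expect_identical(s_up$n_pairs, 3L)
  expect_identical(s_down$n_pairs, 1L)
  expect_identical(s_up$n_positive, 3L)
  # direction partition is exhaustive and disjoint over retained rows
  key <- function(d) paste(d$sm_id, d$mirna_id, d$direction)
  expect_length(intersect(key(res$up$pairs), key(res$down$pairs)), 0L)
  expect_identical(nrow(res$up$pairs) + nrow(res$down$pairs), 4L)
  expect_true(all(res$up$pairs$label == "positive"))
})

test_that("duplicate pairs are collapsed and logged", {
  dir <- withr::local_tempdir()
  make_toy_inputs(dir)
  tab <- read.delim(file.path(dir, "pairs.tsv"))
  tab <- rbind(tab, tab[1L, ])
  res <- suppressMessages(
    load_pairs(tab, file.path(dir, "mirnas.fasta"),
               fingerprints = file.path(dir, "fingerprints.tsv")))
  expect_identical(sum(res$dropped$reason == "duplicate pair"), 1L)
  expect_identical(nrow(res$up$pairs), 3L)
})

test_that("schema violations and empty results are errors", {
  dir <- withr::local_tempdir()
  make_toy_inputs(dir)
  tab <- read.delim(file.path(dir, "pairs.tsv"))
  expect_error(load_pairs(tab[, -1L], file.path(dir, "mirnas.fasta")),
               "sm_id")
  bad <- tab
  bad$direction[1L] <- "sideways"
  expect_error(load_pairs(bad, file.path(dir, "mirnas.fasta")),
               "sideways")
  none <- tab
  none$mirna_id <- "absent"
  expect_error(suppressMessages(
    load_pairs(none, file.path(dir, "mirnas.fasta"),
               fingerprints = file.path(dir, "fingerprints.tsv"))),
    "no pairs retained")
})

test_that("species prefix filter drops foreign ids", {
  dir <- withr::local_tempdir()
  make_toy_inputs(dir)
  tab <- read.delim(file.path(dir, "pairs.tsv"))
  tab$mirna_id <- sub("^mirA$", "hsa-mirA", tab$mirna_id)
  seqs <- c(`hsa-mirA` = "GUUCCUGCUG", mirB = "ACGUACGUAC",
            mirC = "UUUUCCCCGG")
  res <- suppressMessages(
    load_pairs(tab, seqs,
               fingerprints = file.path(dir, "fingerprints.tsv"),
               species_prefix = "hsa-"))
  expect_identical(unique(res$up$pairs$mirna_id), "hsa-mirA")
  expect_true(all(c("species filter") %in% res$dropped$reason))
})

test_that("dataset export/load round-trips to an identical dataset", {
  dir <- withr::local_tempdir()
  make_toy_inputs(dir)
  res <- suppressMessages(
    load_pairs(file.path(dir, "pairs.tsv"), file.path(dir, "mirnas.fasta"),
               fingerprints = file.path(dir, "fingerprints.tsv")))
  out <- withr::local_tempdir()
  export_dataset(res$up, out)
  expect_true(all(file.exists(file.path(out,
    c("pairs.tsv", "molecules.tsv", "fingerprints.tsv", "mirnas.fasta",
      "summary.json")))))
  back <- load_dataset(out)
  expect_identical(back$pairs, res$up$pairs, ignore_attr = TRUE)
  expect_identical(back$fingerprints, res$up$fingerprints)
  expect_identical(back$sequences, res$up$sequences)
})

test_that("the SMILES-path corpus loader featurizes molecules with RDKit", {
  res <- suppressMessages(load_pairs(
    system.file("extdata", "toy_pairs.tsv", package = "smiReg"),
    system.file("extdata", "mirnas_fixture.fasta", package = "smiReg")))
  expect_identical(ncol(res$up$fingerprints), 166L)
  expect_identical(ncol(res$down$fingerprints), 166L)
  expect_identical(dataset_summary(res$down)$n_pairs, 4L)
})
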