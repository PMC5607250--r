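test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_reads = c(E = 0L, L = 10L)), "configuration")
  expect_error(sim_config(adapter = "ACGT"), "configuration")
  expect_error(sim_config(contaminant_fractions = c(mRNA = 0.9),
                          no_adapter_fraction = 0.2), "configuration")
  expect_error(sim_config(contaminant_fractions = c(banana = 0.1)),
               "configuration")
})

test_that("reference counts follow the configuration", {
  cfg <- sim_config(seed = 1, n_mirnas = 20, n_novel = 5,
                    n_reads = c(E = 1000L, L = 1000L))
  scn <- gen_references(cfg)
  expect_equal(nrow(scn$truth), 25)                 # 25 planted hairpins
  known_seqs <- scn$truth$mature_seq[!scn$truth$is_novel]
  novel_seqs <- scn$truth$mature_seq[scn$truth$is_novel]
  mature_set <- as.character(scn$bundle$mature_mirna)
  expect_true(all(known_seqs %in% mature_set))      # 20 in the mature set
  expect_false(any(novel_seqs %in% mature_set))     # 5 absent (novel truth)
  expect_setequal(unique(duomir:::species_of(names(scn$bundle$mature_mirna))),
                  c("chi", "bta"))
  for (cat in duomir:::contaminant_categories()) {
    expect_gt(length(scn$bundle[[cat]]), 0)
  }
})

test_that("generation and simulation are deterministic given the seed", {
  cfg <- sim_config(seed = 3, n_mirnas = 5, n_novel = 2,
                    n_reads = c(E = 2000L, L = 2000L))
  s1 <- gen_references(cfg)
  s2 <- gen_references(cfg)
  d1 <- file.path(tempdir(), "bundle1"); d2 <- file.path(tempdir(), "bundle2")
  write_bundle(s1$bundle, d1); write_bundle(s2$bundle, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  l1 <- simulate_library(s1, "E"); l2 <- simulate_library(s2, "E")
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$categories, l2$categories)
})

test_that("a bundle written to disk reads back equal", {
  scn <- gen_references(sim_config(seed = 8, n_mirnas = 4, n_novel = 1,
                                   n_reads = c(E = 1000L, L = 1000L)))
  d <- file.path(tempdir(), "bundle_rt")
  write_bundle(scn$bundle, d)
  b2 <- read_bundle(d)
  expect_identical(as.character(b2$mature_mirna),
                   as.character(scn$bundle$mature_mirna))
  expect_identical(b2$mature_to_pre, scn$bundle$mature_to_pre)
  expect_identical(as.character(b2$genome), as.character(scn$bundle$genome))
})

test_that("planted hairpins pass the criteria engine (recall ceiling 100%)", {
  for (sd in c(1, 2)) {
    scn <- gen_references(sim_config(seed = sd, n_mirnas = 15, n_novel = 5,
                                     n_reads = c(E = 1000L, L = 1000L)))
    pass <- vapply(scn$truth$precursor_seq, function(p) {
      criteria_pass(evaluate_criteria(
        structure_features(fold_hairpin(p), c(1, 22))))
    }, logical(1))
    expect_true(all(pass))
  }
})

test_that("per-read categories are conserved in the emitted library", {
  cfg <- sim_config(seed = 10, n_reads = c(E = 5000L, L = 5000L),
                    n_mirnas = 10, n_novel = 2)
  scn <- gen_references(cfg)
  lib <- simulate_library(scn, "E")
  expect_equal(length(lib$reads), length(lib$categories))
  expect_equal(sum(lib$category_counts), length(lib$reads))
  # miRNA-derived reads match the realized counts
  expect_equal(sum(lib$mirna_counts),
               sum(lib$categories %in% c("mirna", "novel_mirna")))
})

test_that("null counts concentrate near a ratio of one", {
  cfg <- sim_config(seed = 12, n_reads = c(E = 50000L, L = 50000L),
                    n_mirnas = 40, n_novel = 0, de_fraction = 0)
  scn <- simulate_libraries(gen_references(cfg))
  tr <- scn$truth
  big <- tr$count_E >= 100 & tr$count_L >= 100
  lr <- log2(tr$count_L[big] / tr$count_E[big])
  expect_lt(median(abs(lr)), 0.5)
})

test_that("a planted +5 log2 fold change puts L above E in most seeds", {
  cfg <- sim_config(seed = 20, n_reads = c(E = 4000L, L = 4000L),
                    n_mirnas = 10, n_novel = 0, de_fraction = 0.1,
                    log2fc_range = c(5, 5))
  scn <- gen_references(cfg)
  i <- which(scn$truth$is_de)
  expect_length(i, 1)
  up <- if (scn$truth$log2fc_true[i] > 0) "L" else "E"
  dn <- setdiff(c("E", "L"), up)
  wins <- 0L
  for (s in 1:100) {
    cfg2 <- scn$config; cfg2$seed <- 1000L + s
    hi <- simulate_library(scn, up, config = cfg2)$mirna_counts[i]
    lo <- simulate_library(scn, dn, config = cfg2)$mirna_counts[i]
    wins <- wins + (hi > lo)
  }
  expect_gte(wins, 95)
})

test_that("an empty category with positive demand is a configuration error", {
  cfg <- sim_config(seed = 1, n_mirnas = 4, n_novel = 0,
                    n_reads = c(E = 1000L, L = 1000L))
  scn <- gen_references(cfg)
  scn$bundle$mRNA <- Biostrings::DNAStringSet()
  expect_error(simulate_library(scn, "E"), "configuration error")
})

test_that("library FASTQ and truth TSV round-trip through files", {
  cfg <- sim_config(seed = 14, n_reads = c(E = 500L, L = 500L),
                    n_mirnas = 4, n_novel = 1)
  scn <- simulate_libraries(gen_references(cfg))
  fq <- tempfile(fileext = ".fastq")
  write_library_fastq(scn$libs$E, fq)
  back <- read_reads(fq)
  expect_equal(unname(back), scn$libs$E$reads)
  expect_equal(names(back), scn$libs$E$read_ids)
  tsv <- tempfile(fileext = ".tsv")
  write_truth_tsv(scn$truth, tsv)
  tr <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(tr$id, scn$truth$id)
  expect_equal(tr$count_E, scn$truth$count_E)
})

test_that("novel-candidate outputs are written as text artifacts", {
  cfg <- sim_config(seed = 15, n_reads = c(E = 4000L, L = 4000L),
                    n_mirnas = 5, n_novel = 2)
  scn <- simulate_libraries(gen_references(cfg))
  res <- run_pipeline(scn$libs$E$reads, scn$libs$L$reads, scn$bundle,
                      adapter = cfg$adapter)
  d <- file.path(tempdir(), "novel_out")
  write_novel(res$novel, d)
  expect_true(file.exists(file.path(d, "novel_precursors.fa")))
  crit <- read.table(file.path(d, "novel_criteria.tsv"), header = TRUE,
                     sep = "\t")
  expect_equal(nrow(crit), nrow(res$novel$candidates))
  expect_true(all(crit$overall))
  struct <- readLines(file.path(d, "novel_structures.txt"))
  expect_equal(length(struct), 3 * nrow(res$novel$candidates))
})
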