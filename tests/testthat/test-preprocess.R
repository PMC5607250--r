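test_that("adapter trimming returns the insert before the leftmost match", {
  expect_equal(
    trim_adapter3("ACGTACGTACGTACGTACGTTGGAATTC", "TGGAATTC",
                  min_overlap = 6, max_mismatch = 0),
    "ACGTACGTACGTACGTACGT")
  # no adapter substring -> 3ADT null
  expect_true(is.na(trim_adapter3("ACGTACGTACGTACGTACGTACGTAC", "TGGAATTC",
                                  min_overlap = 6, max_mismatch = 0)))
  # one mismatch tolerated
  expect_equal(
    trim_adapter3("ACGTACGTACGTTGGACTTC", "TGGAATTC",
                  min_overlap = 6, max_mismatch = 1),
    "ACGTACGTACGT")
  # partial adapter at the very end still found if >= min_overlap
  expect_equal(
    trim_adapter3("ACGTACGTACGTACGTTGGAAT", "TGGAATTC",
                  min_overlap = 6, max_mismatch = 0),
    "ACGTACGTACGTACGT")
  # non-nucleotide characters: junk, not an exception
  expect_true(is.na(trim_adapter3("ACGTNNACGTTGGAATTC", "TGGAATTC")))
})

test_that("junk detection flags low-complexity reads of any length", {
  expect_true(all(is_junk(c(strrep("A", 17), strrep("A", 18)))))
  expect_true(is_junk("ACGTACGTNACGTACGTACGT"))           # contains N
  expect_true(is_junk(paste0(strrep("T", 12), "ACGTACG"))) # homopolymer run
  expect_true(is_junk(strrep("AC", 11)))                   # dinucleotide repeat
  expect_false(is_junk("TGAGGTAGTAGGTTGTATAGTT"))
})

test_that("collapse keeps per-sequence counts and U/case normalization", {
  reads <- c(rep("ugagguaguagguuguauaguu", 3), "TACCCTGTAGAACCGAATTTGT")
  r <- filter_and_collapse(reads, "E")
  expect_equal(nrow(r$tags), 2)
  expect_equal(r$tags$count[r$tags$sequence == "TGAGGTAGTAGGTTGTATAGTT"], 3)
  expect_equal(r$tags$count[r$tags$sequence == "TACCCTGTAGAACCGAATTTGT"], 1)
})

test_that("the ledger partitions every read exactly once", {
  adapter <- "TGGAATTCTCGG"
  reads <- c(
    paste0("TGAGGTAGTAGGTTGTATAGTT", adapter),  # valid 22-mer
    paste0("TGAGGTAGTAGGTTGTATAGTT", adapter),
    paste0("ACGTACGTACGTACGT", adapter),        # 16-mer -> too short
    strrep("A", 40),                            # junk (and no adapter)
    paste0("ACGTACGTACGTACGTACGTACGTACGTACGT")  # no adapter -> 3ADT
  )
  r <- filter_and_collapse(reads, "E", adapter = adapter)
  lg <- r$ledger
  get <- function(d) lg$reads[lg$disposition == d]
  expect_equal(get("raw"), 5)
  expect_equal(get("junk"), 1)
  expect_equal(get("adt3_or_length"), 2)
  expect_equal(get("valid"), 2)
  expect_equal(get("raw"), get("junk") + get("adt3_or_length") + get("valid"))
})

test_that("tags and ledger are independent of read order", {
  set.seed(3)
  adapter <- "TGGAATTCTCGG"
  inserts <- replicate(50, random_seq(sample(16:28, 1)))
  reads <- paste0(sample(inserts, 300, replace = TRUE), adapter)
  a <- filter_and_collapse(reads, "E", adapter = adapter)
  b <- filter_and_collapse(rev(reads), "E", adapter = adapter)
  expect_identical(a$tags, b$tags)
  expect_identical(a$ledger, b$ledger)
})

test_that("collapse round-trip recovers the filtered insert multiset", {
  adapter <- "TGGAATTCTCGG"
  set.seed(4)
  inserts <- replicate(20, random_seq(22))
  reads <- paste0(sample(inserts, 200, replace = TRUE), adapter)
  r <- filter_and_collapse(reads, "E", adapter = adapter)
  expanded <- rep(r$tags$sequence, r$tags$count)
  expect_equal(sort(expanded), sort(substr(reads, 1, 22)))
})

test_that("3ADT ledger count equals the planted no-adapter truth", {
  cfg <- sim_config(seed = 5, n_reads = c(E = 1000L, L = 1000L),
                    n_mirnas = 10, n_novel = 2,
                    contaminant_fractions = c(mRNA = 0),
                    no_adapter_fraction = 0.05, junk_fraction = 0,
                    read_error_rate = 0)
  scn <- gen_references(cfg)
  lib <- simulate_library(scn, "E")
  planted <- sum(lib$categories == "no_adapter")
  r <- filter_and_collapse(lib$reads, "E", adapter = cfg$adapter)
  expect_equal(r$ledger$reads[r$ledger$disposition == "adt3_or_length"],
               planted)
})

test_that("length distribution is normalized and tracks the tag mix", {
  tg <- tag_table(c("TGAGGTAGTAGGTTGTATAGTT",     # 22
                    "TACCCTGTAGAACCGAATTTGT",     # 22
                    "TAGCAGCACGTAAATATTGG"),      # 20
                  count_E = c(10, 5, 1), count_L = c(2, 2, 2))
  ld <- length_distribution(tg)
  expect_equal(ld$reads_E[ld$length == 22], 15)
  expect_equal(ld$unique_E[ld$length == 22], 2)
  expect_equal(sum(ld$read_frac_E), 1, tolerance = 1e-12)
  expect_equal(sum(ld$unique_frac_L), 1, tolerance = 1e-12)
  # single tag -> 100% at its length
  one <- length_distribution(tag_table("TGAGGTAGTAGGTTGTATAGTT", 10, 0))
  expect_equal(one$read_frac_E[one$length == 22], 1)
})
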