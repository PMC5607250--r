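#' Configuration for the synthetic two-library small RNA experiment
#'
#' Builds the parameter set for [gen_references()] and [simulate_library()].
#' Defaults describe a scaled-down two-library (early/late, "E"/"L") design:
#' two libraries of 2e5 reads, 100 known miRNAs drawn from two species, 10
#' novel hairpins, 10% contaminant reads spread over the seven reference
#' categories, 5% reads with no detectable 3' adapter, a trace of junk
#' reads, and 20% of known miRNAs differentially expressed at
#' |log2 fold change| between 3 and 5.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_reads Named integer pair, reads per library (names `E`, `L`).
#' @param n_mirnas Number of known mature miRNAs to plant.
#' @param n_novel Number of novel (absent from the mature set) hairpins.
#' @param contaminant_fractions Named fractions per contaminant category;
#'   together with `no_adapter_fraction` and `junk_fraction` they must sum
#'   to at most 1 (the remainder is miRNA-derived reads).
#' @param no_adapter_fraction Fraction of reads carrying no 3' adapter.
#' @param junk_fraction Fraction of low-complexity junk reads.
#' @param de_fraction Fraction of known miRNAs differentially expressed.
#' @param log2fc_range Interval from which DE |log2 fold changes| are drawn.
#' @param dispersion Negative-binomial dispersion of per-miRNA counts
#'   (`0` gives Poisson counts).
#' @param adapter 3' adapter sequence (length >= 6).
#' @param read_error_rate Per-base substitution probability, applied as at
#'   most one substitution per read at rate `read_length * read_error_rate`.
#' @param read_length Fixed sequencer read length.
#' @param isomir_probs Probabilities of 3' isomiR offsets -2..+2.
#' @param conserved_fraction Fraction of known miRNAs present identically in
#'   both species' mature sets (the rest belong to the other species only).
#' @param genome_length Length of the single toy genome contig.
#' @param n_contam_refs,contam_ref_length Contaminant reference set sizes.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_reads = c(E = 200000L, L = 200000L),
                       n_mirnas = 100L,
                       n_novel = 10L,
                       contaminant_fractions = c(
                         mRNA = 0.03, rRNA = 0.025, tRNA = 0.015,
                         snoRNA = 0.01, snRNA = 0.005, other_ncRNA = 0.005,
                         "repeat" = 0.01),
                       no_adapter_fraction = 0.05,
                       junk_fraction = 0.001,
                       de_fraction = 0.2,
                       log2fc_range = c(3, 5),
                       dispersion = 0.1,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_error_rate = 0.001,
                       read_length = 50L,
                       isomir_probs = c("-2" = 0.05, "-1" = 0.10, "0" = 0.70,
                                        "1" = 0.10, "2" = 0.05),
                       conserved_fraction = 0.5,
                       genome_length = 100000L,
                       n_contam_refs = 5L,
                       contam_ref_length = 300L) {
  cfg <- as.list(environment())
  if (any(is.na(n_reads)) || any(n_reads <= 0)) {
    stop("configuration error: n_reads must be positive")
  }
  if (is.null(names(n_reads)) || !all(c("E", "L") %in% names(n_reads))) {
    names(cfg$n_reads) <- c("E", "L")
  }
  bad <- setdiff(names(contaminant_fractions), contaminant_categories())
  if (length(bad)) stop("configuration error: unknown category ", bad[1])
  fr <- c(contaminant_fractions, no_adapter_fraction, junk_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("configuration error: fractions must lie in [0,1] and sum to <= 1")
  }
  if (nchar(adapter) < 6) stop("configuration error: adapter shorter than 6 nt")
  if (n_mirnas < 1) stop("configuration error: n_mirnas must be >= 1")
  if (dispersion < 0) stop("configuration error: dispersion must be >= 0")
  if (abs(sum(isomir_probs) - 1) > 1e-8 || length(isomir_probs) != 5) {
    stop("configuration error: isomir_probs must be 5 values summing to 1")
  }
  need <- 2000 + (n_mirnas + n_novel) * 600
  if (genome_length < need) {
    stop("configuration error: genome too short for the requested hairpins")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Species tag of a miRBase-style identifier ("chi-miR-12a-5p" -> "chi").
#' @noRd
species_of <- function(id) stringi::stri_extract_first_regex(id, "^[a-z]{2,4}")

#' Generate the reference bundle and ground-truth table
#'
#' Plants `n_mirnas + n_novel` perfect-stem hairpin precursors (22-nt mature
#' arm, 8-nt loop, reverse-complement 3' arm; 52 nt total) on the plus strand
#' of a single random contig, at least 500 nt apart. Mature records carry
#' miRBase-style identifiers whose prefix is the species tag; a configurable
#' fraction is present identically in both the focal species (`chi`) and a
#' second mammal (`bta`), the rest in `bta` only, so that both Group 1a and
#' Group 1b are reachable. Novel hairpins get loci and expression but no
#' mature or precursor record. Contaminant categories each receive a set of
#' random reference sequences. All planted sequences are screened against
#' the adapter seed and low-complexity content so the preprocessing filters
#' can be benchmarked exactly.
#'
#' Per-miRNA expected expression weights, DE flags and true log2 fold
#' changes are decided here (deterministically given the seed) so that the
#' two libraries simulated later share one truth.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"sim_scenario"` with elements `bundle`
#'   (class `"ref_bundle"`), `truth` (data frame; loci are 0-based
#'   half-open), and `config`.
#' @export
gen_references <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seed6 <- substr(norm_seq(config$adapter), 1, 6)
  avoid <- unique(c(seed6, revcomp(seed6)))

  n_known <- config$n_mirnas
  n_novel <- config$n_novel
  n_all <- n_known + n_novel
  matures <- random_dna(n_all, 22, avoid = avoid, screen_low_complexity = TRUE)
  while (anyDuplicated(matures)) {
    dup <- duplicated(matures)
    matures[dup] <- random_dna(sum(dup), 22, avoid = avoid,
                               screen_low_complexity = TRUE)
  }
  # Loops over {A, C} only: such loops cannot pair internally (or with the
  # adapter-screened arms), so each planted precursor folds to its designed
  # perfect stem and passes the structural criteria by construction.
  loops <- random_dna(n_all, 8, avoid = avoid, alphabet = c("A", "C"))
  precursors <- paste0(matures, loops, revcomp(matures))

  # Identifiers: paralog pairs share a family stem (miR-<k>a / miR-<k>b).
  fam_idx <- ((seq_len(n_known) - 1) %/% 2) + 1
  letter <- c("a", "b")[((seq_len(n_known) - 1) %% 2) + 1]
  base_name <- paste0("miR-", fam_idx, letter)
  n_cons <- round(n_known * config$conserved_fraction)
  is_cons <- seq_len(n_known) <= n_cons
  focal_id <- ifelse(is_cons, paste0("chi-", base_name, "-5p"),
                     paste0("bta-", base_name, "-5p"))

  mature_ids <- character(0); mature_seqs <- character(0)
  pre_ids <- character(0); pre_seqs <- character(0)
  mature_to_pre <- character(0)
  for (i in seq_len(n_known)) {
    sps <- if (is_cons[i]) c("chi", "bta") else "bta"
    for (sp in sps) {
      mid <- paste0(sp, "-", base_name[i], "-5p")
      pid <- paste0(sp, "-mir-", fam_idx[i], letter[i])
      mature_ids <- c(mature_ids, mid)
      mature_seqs <- c(mature_seqs, matures[i])
      pre_ids <- c(pre_ids, pid)
      pre_seqs <- c(pre_seqs, precursors[i])
      mature_to_pre[mid] <- pid
    }
  }

  # Toy genome with planted hairpins, >= 500 nt apart on the plus strand.
  glen <- config$genome_length
  genome <- random_dna(1, glen)
  spacing <- max(560L, floor((glen - 2000L) / n_all))
  starts1 <- 1000L + (seq_len(n_all) - 1L) * spacing # 1-based
  for (i in seq_len(n_all)) {
    stringi::stri_sub(genome, starts1[i], starts1[i] + 51L) <- precursors[i]
  }

  contam <- lapply(contaminant_categories(), function(cat) {
    s <- random_dna(config$n_contam_refs, config$contam_ref_length,
                    avoid = seed6, screen_low_complexity = TRUE)
    Biostrings::DNAStringSet(stats::setNames(s, paste0(cat, "_", seq_along(s))))
  })
  names(contam) <- contaminant_categories()

  bundle <- c(list(
    genome = Biostrings::DNAStringSet(c(ctg1 = genome)),
    mature_mirna = Biostrings::DNAStringSet(stats::setNames(mature_seqs, mature_ids)),
    pre_mirna = Biostrings::DNAStringSet(stats::setNames(
      pre_seqs[!duplicated(pre_ids)], pre_ids[!duplicated(pre_ids)])),
    mature_to_pre = mature_to_pre,
    focal_species = "chi",
    species = c("chi", "bta")), contam)
  class(bundle) <- "ref_bundle"

  # Expression truth.
  w <- pmax(stats::rlnorm(n_all, 0, 1), 0.25)
  is_de <- rep(FALSE, n_all)
  de_pick <- sample(n_known, round(config$de_fraction * n_known))
  is_de[de_pick] <- TRUE
  lfc <- numeric(n_all)
  lfc[de_pick] <- sample(c(-1, 1), length(de_pick), replace = TRUE) *
    stats::runif(length(de_pick), config$log2fc_range[1], config$log2fc_range[2])

  truth <- data.frame(
    id = c(focal_id, sprintf("novel-m%d", seq_len(n_novel))),
    category = c(rep("known_mirna", n_known), rep("novel_mirna", n_novel)),
    family = c(paste0("miR-", fam_idx), rep(NA_character_, n_novel)),
    species = c(ifelse(is_cons, "chi,bta", "bta"), rep(NA_character_, n_novel)),
    contig = "ctg1",
    start = starts1 - 1L,        # 0-based half-open
    end = starts1 + 51L,
    strand = "+",
    mature_seq = matures,
    precursor_seq = precursors,
    is_novel = c(rep(FALSE, n_known), rep(TRUE, n_novel)),
    is_de = is_de,
    log2fc_true = lfc,
    weight = w,
    stringsAsFactors = FALSE)

  out <- list(bundle = bundle, truth = truth, config = config)
  class(out) <- "sim_scenario"
  out
}

# Read-length mix for contaminant inserts (18..26 nt, peaked at 22).
#' @noRd
contam_length_probs <- function() {
  p <- c(0.02, 0.05, 0.08, 0.12, 0.40, 0.14, 0.09, 0.06, 0.04)
  p / sum(p)
}

#' Simulate one adapter-ligated small RNA library
#'
#' Emits fixed-length reads for one library: miRNA reads are a mature
#' sequence (with a 3' isomiR offset of up to +/-2 nt) followed by the 3'
#' adapter and adapter-derived filler, truncated to the read length;
#' contaminant reads are random 18-26-nt windows of the category's
#' references, adapter-ligated the same way; a configured fraction of reads
#' carries no adapter at all, and another is low-complexity junk. Per-miRNA
#' counts are negative-binomial around the expected count implied by the
#' truth table's weights and true fold changes (Poisson when `dispersion`
#' is 0). Each read carries at most one sequencing substitution, at rate
#' `read_length * read_error_rate`.
#'
#' @param scenario A `"sim_scenario"` from [gen_references()].
#' @param library_id `"E"` or `"L"`.
#' @param config Configuration; defaults to the scenario's own.
#' @return A list of class `"sim_library"`: `library_id`, `reads` (character
#'   vector), `read_ids`, `categories` (per-read source category),
#'   `mirna_counts` (named realized counts per planted miRNA), and
#'   `category_counts`.
#' @export
simulate_library <- function(scenario, library_id = c("E", "L"),
                             config = scenario$config) {
  stopifnot(inherits(scenario, "sim_scenario"))
  library_id <- match.arg(library_id)
  lib_index <- match(library_id, c("E", "L"))
  set.seed((config$seed %% 2000000000L) + 7919L * lib_index)

  n_total <- as.integer(config$n_reads[[library_id]])
  truth <- scenario$truth
  bundle <- scenario$bundle

  mirna_frac <- 1 - config$junk_fraction - config$no_adapter_fraction -
    sum(config$contaminant_fractions)
  n_mirna_pool <- round(mirna_frac * n_total)

  # Realized per-miRNA counts.
  sgn <- if (library_id == "L") 1 else -1
  mu <- n_mirna_pool * (truth$weight / sum(truth$weight)) *
    2^(sgn * truth$log2fc_true / 2)
  counts <- if (config$dispersion == 0) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  names(counts) <- truth$id

  # Non-miRNA reads are sized against the realized miRNA pool so that the
  # emitted per-category composition matches the configured fractions even
  # when the negative-binomial draw moves the library total.
  n_total_real <- if (mirna_frac > 0) round(sum(counts) / mirna_frac) else n_total
  n_junk <- round(config$junk_fraction * n_total_real)
  n_noad <- round(config$no_adapter_fraction * n_total_real)
  n_cat <- round(config$contaminant_fractions * n_total_real)
  for (cat in names(n_cat)) {
    if (n_cat[[cat]] > 0 && length(bundle[[cat]]) == 0) {
      stop("configuration error: positive fraction for empty category ", cat)
    }
  }

  # miRNA inserts with 3' isomiR offsets.
  offsets <- as.integer(names(config$isomir_probs))
  ins_acc <- list(); cat_acc <- list()
  for (i in seq_len(nrow(truth))) {
    if (counts[i] == 0) next
    k <- as.vector(stats::rmultinom(1, counts[i], config$isomir_probs))
    mat <- truth$mature_seq[i]
    loop <- substr(truth$precursor_seq[i], 23, 30)
    variants <- vapply(offsets, function(off) {
      if (off < 0) substr(mat, 1, 22 + off)
      else if (off == 0) mat
      else paste0(mat, substr(loop, 1, off))
    }, character(1))
    ins_acc[[length(ins_acc) + 1]] <- rep(variants, k)
    cat_acc[[length(cat_acc) + 1]] <-
      rep(if (truth$is_novel[i]) "novel_mirna" else "mirna", counts[i])
  }

  # Contaminant inserts: random windows of the category references.
  lenp <- contam_length_probs()
  for (cat in names(n_cat)) {
    nc <- n_cat[[cat]]
    if (nc == 0) next
    refs <- as.character(bundle[[cat]])
    idx <- sample(length(refs), nc, replace = TRUE)
    len <- sample(18:26, nc, replace = TRUE, prob = lenp)
    maxs <- nchar(refs)[idx] - len + 1
    st <- floor(stats::runif(nc) * maxs) + 1
    ins_acc[[length(ins_acc) + 1]] <- stringi::stri_sub(refs[idx], st, st + len - 1)
    cat_acc[[length(cat_acc) + 1]] <- rep(cat, nc)
  }
  inserts <- unlist(ins_acc, use.names = FALSE) %||% character(0)
  categories <- unlist(cat_acc, use.names = FALSE) %||% character(0)

  adapter <- norm_seq(config$adapter)
  filler <- strrep(adapter, ceiling(config$read_length / nchar(adapter)) + 1)
  reads <- stringi::stri_sub(paste0(inserts, filler), 1, config$read_length)

  if (n_noad > 0) {
    reads <- c(reads, random_dna(n_noad, config$read_length,
                                 avoid = substr(adapter, 1, 6)))
    categories <- c(categories, rep("no_adapter", n_noad))
  }
  if (n_junk > 0) {
    reads <- c(reads, strrep(sample(c("A", "C", "G", "T"), n_junk,
                                    replace = TRUE), config$read_length))
    categories <- c(categories, rep("junk", n_junk))
  }

  # At most one substitution per read.
  n <- length(reads)
  hit <- which(stats::runif(n) < config$read_error_rate * config$read_length)
  if (length(hit)) {
    pos <- sample.int(config$read_length, length(hit), replace = TRUE)
    old <- substr(reads[hit], pos, pos)
    sub <- vapply(old, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1), USE.NAMES = FALSE)
    stringi::stri_sub(reads[hit], pos, pos) <- sub
  }

  ord <- sample.int(n)
  out <- list(library_id = library_id,
              reads = reads[ord],
              read_ids = sprintf("%s_read_%07d", library_id, seq_len(n)),
              categories = categories[ord],
              mirna_counts = counts,
              category_counts = c(table(categories)))
  class(out) <- "sim_library"
  out
}

#' Simulate both libraries and record realized counts in the truth table
#'
#' @param scenario A `"sim_scenario"` from [gen_references()].
#' @return The scenario with `libs` (list of `"sim_library"` objects `E` and
#'   `L`) added and `truth` gaining realized `count_E` / `count_L` columns.
#' @export
simulate_libraries <- function(scenario) {
  libs <- list(E = simulate_library(scenario, "E"),
               L = simulate_library(scenario, "L"))
  scenario$truth$count_E <- as.integer(libs$E$mirna_counts[scenario$truth$id])
  scenario$truth$count_L <- as.integer(libs$L$mirna_counts[scenario$truth$id])
  scenario$libs <- libs
  scenario
}

#' Write a simulated library as FASTQ (constant quality)
#'
#' @param lib A `"sim_library"` object.
#' @param path Output path (plain text FASTQ).
#' @export
write_library_fastq <- function(lib, path) {
  qual <- strrep("I", nchar(lib$reads))
  writeLines(paste0("@", lib$read_ids, "\n", lib$reads, "\n+\n", qual), path)
  invisible(path)
}

#' Read a FASTA or FASTQ file as a character vector of reads
#'
#' @param path Input path; format detected from the first character.
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  first <- substr(readLines(path, n = 1), 1, 1)
  fmt <- if (first == "@") "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(x), names(x))
}

#' Write the reference bundle as a directory of FASTA files plus manifest
#'
#' @param bundle A `"ref_bundle"`.
#' @param dir Output directory (created if missing).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets <- c("genome", "mature_mirna", "pre_mirna", contaminant_categories())
  for (s in sets) {
    if (!is.null(bundle[[s]]) && length(bundle[[s]]) > 0) {
      Biostrings::writeXStringSet(bundle[[s]], file.path(dir, paste0(s, ".fa")))
    }
  }
  yaml::write_yaml(list(focal_species = bundle$focal_species,
                        species = bundle$species,
                        mature_to_pre = as.list(bundle$mature_to_pre)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a reference bundle written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return A `"ref_bundle"` list.
#' @export
read_bundle <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  sets <- c("genome", "mature_mirna", "pre_mirna", contaminant_categories())
  bundle <- list()
  for (s in sets) {
    f <- file.path(dir, paste0(s, ".fa"))
    bundle[[s]] <- if (file.exists(f)) Biostrings::readDNAStringSet(f)
                   else Biostrings::DNAStringSet()
  }
  bundle$focal_species <- man$focal_species
  bundle$species <- unlist(man$species)
  bundle$mature_to_pre <- unlist(man$mature_to_pre)
  class(bundle) <- "ref_bundle"
  bundle
}

#' Write the ground-truth table as TSV
#'
#' Columns: id, category, contig, start, end (0-based half-open), strand,
#' count_E, count_L, log2fc_true, is_de, is_novel.
#'
#' @param truth Truth data frame from [simulate_libraries()].
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  cols <- c("id", "category", "contig", "start", "end", "strand",
            "count_E", "count_L", "log2fc_true", "is_de", "is_novel")
  cols <- intersect(cols, names(truth))
  utils::write.table(truth[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
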