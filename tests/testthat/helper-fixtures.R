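# Constructed hairpin fixtures. Structures are supplied as dot-bracket
# strings (the folder is bypassed), so each fixture isolates exactly one
# criterion; sequences are arbitrary.

db <- function(...) paste0(...)
dots <- function(n) strrep(".", n)
opens <- function(n) strrep("(", n)
closes <- function(n) strrep(")", n)

fixture_hairpin <- function(structure, mature_span, energy = -30) {
  seq <- strrep("A", nchar(structure))
  h <- fold_hairpin(seq, structure = structure, energy = energy)
  structure_features(h, mature_span)
}

# A hairpin passing all eleven criteria: perfect 22-bp stem, 8-nt loop.
template_fixture <- function(energy = -30) {
  fixture_hairpin(db(opens(22), dots(8), closes(22)), c(1, 22), energy)
}

# One fixture per criterion, each failing that criterion alone.
criterion_fixtures <- function() {
  list(
    # 13-nt bulge in the stem, outside the mature region.
    c1 = fixture_hairpin(db(opens(22), dots(8), closes(12), dots(13),
                            closes(10)), c(1, 22)),
    # 14-bp stem: 6 + 8 pairs split by a symmetric 4/4 mature bulge.
    c2 = fixture_hairpin(db(opens(6), dots(4), opens(8), dots(14), closes(8),
                            dots(4), closes(6)), c(1, 18)),
    # energy just above the cutoff.
    c3 = template_fixture(energy = -14.9),
    # 48-nt hairpin (20-bp stem, 8-nt loop).
    c4 = fixture_hairpin(db(opens(20), dots(8), closes(20)), c(1, 20)),
    # 22-nt terminal loop.
    c5 = fixture_hairpin(db(opens(22), dots(22), closes(22)), c(1, 22)),
    # 5-nt mature-region bulge (4 on the mature strand, 5 opposite).
    c6 = fixture_hairpin(db(opens(18), dots(4), opens(4), dots(8), closes(4),
                            dots(5), closes(18)), c(1, 22)),
    # biased mature bulge: 4 on the mature strand vs 1 opposite (bias 3).
    c7 = fixture_hairpin(db(opens(18), dots(4), opens(4), dots(8), closes(4),
                            dots(1), closes(18)), c(1, 22)),
    # three biased mature bulges (runs 1, 1, 2 on the mature strand).
    c8 = fixture_hairpin(db(opens(5), dots(1), opens(5), dots(1), opens(5),
                            dots(2), opens(6), dots(8), closes(21)),
                         c(1, 22)),
    # five mature errors across two bulges (4/2 and 1/0).
    c9 = fixture_hairpin(db(opens(8), dots(4), opens(5), dots(1), opens(7),
                            dots(8), closes(12), dots(2), closes(8)),
                         c(1, 22)),
    # 11 mature base pairs: 3 nt outside the stem, 11 paired, 4 in a bulge.
    c10 = fixture_hairpin(db(dots(3), opens(11), dots(4), opens(8), dots(8),
                             closes(8), dots(2), closes(11)), c(1, 18)),
    # mature overlaps the terminal loop by 5 of 22 nt (77.3% in stem).
    c11 = fixture_hairpin(db(opens(8), opens(17), dots(8), closes(17),
                             closes(8)), c(9, 30))
  )
}

# Small hand-built reference bundle exercising every branch of the
# classification cascade.
tiny_bundle <- function() {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  m1 <- "TGAGGTAGTAGGTTGTATAGTT" # chi, precursor on genome -> 1a
  m2 <- "TACCCTGTAGAACCGAATTTGT" # bta, precursor on genome -> 1b
  m3 <- "TCCCTGAGACCCTAACTTGTGA" # hsa, precursor off genome, hairpin -> 2a
  m4 <- "TAGCAGCACGTAAATATTGGCG" # hsa, off genome, no hairpin context -> 2b
  m5 <- "TGGCTCAGTTCAGCAGGAACAG" # hsa, neither on genome -> 3
  loop <- "ACCAAACA"
  hp <- function(m) paste0(m, loop, rc(m))
  ac <- function(n) strrep("AC", ceiling(n / 2)) |> substr(1, n)
  genome <- paste0(ac(100), hp(m1), ac(60), hp(m2), ac(60), hp(m3),
                   ac(60), m4, ac(100))
  mature <- Biostrings::DNAStringSet(c(
    "chi-miR-101-5p" = m1, "bta-miR-102-5p" = m2, "hsa-miR-103-5p" = m3,
    "hsa-miR-104-5p" = m4, "hsa-miR-105-5p" = m5))
  pre <- Biostrings::DNAStringSet(c(
    "chi-mir-101" = hp(m1), "bta-mir-102" = hp(m2),
    "hsa-mir-103" = paste0(m3, loop, ac(22)),  # decoy: not on genome
    "hsa-mir-104" = paste0(m4, loop, ac(22)),
    "hsa-mir-105" = hp(m5)))
  bundle <- list(
    genome = Biostrings::DNAStringSet(c(ctgA = genome)),
    mature_mirna = mature,
    pre_mirna = pre,
    mature_to_pre = c("chi-miR-101-5p" = "chi-mir-101",
                      "bta-miR-102-5p" = "bta-mir-102",
                      "hsa-miR-103-5p" = "hsa-mir-103",
                      "hsa-miR-104-5p" = "hsa-mir-104",
                      "hsa-miR-105-5p" = "hsa-mir-105"),
    focal_species = "chi",
    species = c("chi", "bta", "hsa"),
    mirnas = c(m1 = m1, m2 = m2, m3 = m3, m4 = m4, m5 = m5))
  class(bundle) <- "ref_bundle"
  bundle
}

tag_table <- function(seqs, count_E, count_L = count_E) {
  data.frame(sequence = seqs, count_E = count_E, count_L = count_L,
             stringsAsFactors = FALSE)
}
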