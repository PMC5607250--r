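test_that("the cascade assigns each reachable group", {
  b <- tiny_bundle()
  m <- b$mirnas
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  tg <- tag_table(
    c(m[["m1"]], m[["m2"]], m[["m3"]], m[["m4"]], m[["m5"]],
      rc(m[["m1"]]),                      # opposite arm of the chi precursor
      "GACTGACTGACTGACTGACTGA"),          # matches nothing
    count_E = c(10, 10, 10, 10, 10, 10, 10))
  a <- map_known(tg, b)
  grp <- stats::setNames(a$group, a$sequence)
  expect_equal(unname(grp[m[["m1"]]]), "1a")
  expect_equal(unname(grp[m[["m2"]]]), "1b")
  expect_equal(unname(grp[m[["m3"]]]), "2a")
  expect_equal(unname(grp[m[["m4"]]]), "2b")
  expect_equal(unname(grp[m[["m5"]]]), "3")
  expect_equal(unname(grp["GACTGACTGACTGACTGACTGA"]), "unassigned")
  # cascade exclusivity: exactly one group per tag
  expect_equal(anyDuplicated(a$sequence), 0)
  # other-arm detection
  oa <- a[a$sequence == rc(m[["m1"]]), ]
  expect_true(oa$other_arm)
  expect_equal(oa$group, "1a")
  expect_equal(oa$arm, "3p")
})

test_that("isomiR variants still match within tolerance", {
  b <- tiny_bundle()
  m1 <- b$mirnas[["m1"]]
  tg <- tag_table(c(substr(m1, 1, 20),            # -2 truncation
                    paste0(m1, "AC"),             # +2 extension
                    sub("^(.{10}).", "\\1A", m1)),# one internal substitution
                  count_E = c(5, 5, 5))
  a <- map_known(tg, b)
  expect_true(all(a$group == "1a"))
})

test_that("tags below the evidence threshold are never assigned", {
  b <- tiny_bundle()
  tg <- tag_table(c(b$mirnas[["m1"]], b$mirnas[["m2"]]), count_E = c(3, 4),
                  count_L = c(0, 0))
  a <- map_known(tg, b, min_reads = 3)     # "> 3" by default
  expect_equal(a$group[a$sequence == b$mirnas[["m1"]]], "unassigned")
  expect_equal(a$group[a$sequence == b$mirnas[["m2"]]], "1b")
  a2 <- map_known(tg, b, min_reads = 3, count_gt = FALSE)  # ">= 3" variant
  expect_equal(a2$group[a2$sequence == b$mirnas[["m1"]]], "1a")
})

test_that("removing the focal species demotes 1a to 1b, never to novel", {
  cfg <- sim_config(seed = 2, n_reads = c(E = 5000L, L = 5000L),
                    n_mirnas = 12, n_novel = 2, conserved_fraction = 1)
  scn <- gen_references(cfg)
  tg <- tag_table(scn$truth$mature_seq[!scn$truth$is_novel], count_E = 10)
  a1 <- map_known(tg, scn$bundle)
  expect_true(all(a1$group == "1a"))
  b2 <- scn$bundle
  keep_m <- !startsWith(names(b2$mature_mirna), "chi-")
  keep_p <- !startsWith(names(b2$pre_mirna), "chi-")
  b2$mature_mirna <- b2$mature_mirna[keep_m]
  b2$pre_mirna <- b2$pre_mirna[keep_p]
  b2$mature_to_pre <- b2$mature_to_pre[keep_m]
  b2$species <- "bta"
  a2 <- map_known(tg, b2)
  expect_true(all(a2$group == "1b"))
})

test_that("arm assignment splits at the loop midpoint with a 5p tie", {
  h <- fold_hairpin(strrep("A", 80),
                    structure = db(opens(30), dots(10), closes(30), dots(10)),
                    energy = -40)
  expect_equal(arm_of(c(1, 22), h), "5p")
  expect_equal(arm_of(c(48, 69), h), "3p")
  # loop spans 31..40, midpoint 35.5; mature 25..46 is centered on it
  expect_equal(arm_of(c(25, 46), h), "5p")
})

test_that("family stems strip species, paralog and arm decorations", {
  a <- data.frame(
    sequence = NA_character_,
    mirna_id = c("chi-miR-30a-5p", "bta-miR-30f", "hsa-miR-30e",
                 "chi-let-7a", "chi-let-7f", "hsa-miR-2284x"),
    group = "1a", stringsAsFactors = FALSE)
  fs <- family_summary(a)
  expect_equal(fs$n_members[fs$family == "miR-30"], 3)
  expect_equal(fs$n_members[fs$family == "let-7"], 2)
  expect_equal(fs$n_members[fs$family == "miR-2284"], 1)
  expect_equal(nrow(fs), 3)
})

test_that("planted family count is recovered from a clean simulation", {
  cfg <- sim_config(seed = 4, n_reads = c(E = 5000L, L = 5000L),
                    n_mirnas = 10, n_novel = 2)
  scn <- gen_references(cfg)
  tg <- tag_table(scn$truth$mature_seq[!scn$truth$is_novel], count_E = 10)
  a <- map_known(tg, scn$bundle)
  fs <- family_summary(a)
  expect_equal(nrow(fs), length(unique(scn$truth$family[!scn$truth$is_novel])))
})

test_that("conservation profile counts species occurrences", {
  cfg <- sim_config(seed = 6, n_reads = c(E = 5000L, L = 5000L),
                    n_mirnas = 8, n_novel = 2, conserved_fraction = 1)
  scn <- gen_references(cfg)
  tg <- tag_table(scn$truth$mature_seq[!scn$truth$is_novel], count_E = 10)
  a <- map_known(tg, scn$bundle)
  cp <- conservation_profile(a, scn$bundle)
  # every planted miRNA is present identically in both species
  expect_equal(cp$per_species$n_mirnas[cp$per_species$species == "chi"], 8)
  expect_equal(cp$per_species$n_mirnas[cp$per_species$species == "bta"], 8)
  expect_equal(cp$conservation$n_tags[cp$conservation$min_species == 2], 8)
  # empty assignments give an all-zero profile
  cp0 <- conservation_profile(a[0, ], scn$bundle)
  expect_true(all(cp0$per_species$n_mirnas == 0))
})
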