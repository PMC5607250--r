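#' Matching tolerance for tag-to-mature alignment
#'
#' Known-miRNA matching allows a bounded number of internal substitutions
#' and a bounded 5'/3' truncation or extension of the tag relative to the
#' reference mature, which accommodates sequencing variants and 3' isomiRs
#' while keeping false matches rare for 18-26-mers.
#'
#' @param max_sub Maximum internal substitutions.
#' @param max_end Maximum truncation/extension at each end, in nt.
#' @return List of class `"map_tolerance"`.
#' @export
map_tolerance <- function(max_sub = 2L, max_end = 2L) {
  stopifnot(max_sub >= 0, max_end >= 0)
  structure(list(max_sub = as.integer(max_sub), max_end = as.integer(max_end)),
            class = "map_tolerance")
}

# Precompute a character matrix of mature reference sequences (rows padded
# with NA) for vectorized mismatch counting.
#' @noRd
mature_matrix <- function(matures) {
  seqs <- norm_seq(as.character(matures))
  ids <- names(matures)
  lens <- nchar(seqs)
  maxlen <- max(lens)
  M <- matrix(NA_character_, nrow = length(seqs), ncol = maxlen)
  for (i in seq_along(seqs)) {
    M[i, seq_len(lens[i])] <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
  }
  list(ids = ids, species = species_of(ids), lens = lens, M = M,
       maxlen = maxlen)
}

# All matures matching a tag within tolerance. For each 5' offset d
# (tag start aligned to reference position 1 + d), mismatches are counted
# over the overlap and end overhangs are bounded by max_end per end.
#' @noRd
match_matures <- function(tagseq, mm, tol) {
  tlen <- nchar(tagseq)
  tch <- strsplit(tagseq, "", fixed = TRUE)[[1]]
  best_mm <- rep(Inf, length(mm$ids))
  best_d <- rep(NA_integer_, length(mm$ids))
  for (d in seq(-tol$max_end, tol$max_end)) {
    tpos <- seq_len(tlen)
    rcol <- tpos + d
    sel <- rcol >= 1 & rcol <= mm$maxlen
    if (!any(sel)) next
    cmp <- mm$M[, rcol[sel], drop = FALSE] !=
      matrix(tch[tpos[sel]], nrow = nrow(mm$M), ncol = sum(sel), byrow = TRUE)
    mism <- rowSums(cmp, na.rm = TRUE)
    right <- (tlen + d) - mm$lens # >0: tag 3' extension; <0: 3' truncation
    ok <- mism <= tol$max_sub & abs(right) <= tol$max_end
    upd <- ok & mism < best_mm
    best_mm[upd] <- mism[upd]
    best_d[upd] <- d
  }
  hit <- is.finite(best_mm)
  data.frame(mirna_id = mm$ids[hit], species = mm$species[hit],
             mismatches = best_mm[hit], offset = best_d[hit],
             stringsAsFactors = FALSE)
}

# Deterministic best match: focal species first, then fewest mismatches,
# then lexicographic reference id.
#' @noRd
best_mature <- function(matches, focal) {
  if (nrow(matches) == 0) return(NULL)
  ord <- order(matches$species != focal, matches$mismatches, matches$mirna_id)
  matches[ord[1], , drop = FALSE]
}

# Plain-character genome accessors -------------------------------------------

#' @noRd
genome_text <- function(bundle) {
  g <- bundle$genome
  list(names = names(g), fwd = as.character(g))
}

# All exact genomic loci of a sequence, both strands; 1-based inclusive.
#' @noRd
genome_loci <- function(seq, gt) {
  out <- list()
  rc <- revcomp(seq)
  for (k in seq_along(gt$fwd)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seq else rc
      loc <- stringi::stri_locate_all_fixed(gt$fwd[k], pat)[[1]]
      if (!is.na(loc[1, 1])) {
        out[[length(out) + 1]] <- data.frame(
          contig = gt$names[k], start = loc[, 1], end = loc[, 2],
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(contig = character(0), start = integer(0), end = integer(0),
                  strand = character(0), stringsAsFactors = FALSE)
}

#' @noRd
genome_has <- function(seq, gt) {
  rc <- revcomp(seq)
  any(stringi::stri_detect_fixed(gt$fwd, seq)) ||
    any(stringi::stri_detect_fixed(gt$fwd, rc))
}

# The three flanking windows around a genomic tag locus, in the tag's own
# orientation: tag at the 5' arm (downstream context only), centered, and
# tag at the 3' arm (upstream context only). Coordinates 1-based inclusive.
#' @noRd
flank_windows <- function(gt, contig, start, end, strand, flank = 80L) {
  k <- match(contig, gt$names)
  glen <- nchar(gt$fwd[k])
  spans <- if (strand == "+") {
    list(c(start, min(glen, end + flank)),
         c(max(1, start - flank), min(glen, end + flank)),
         c(max(1, start - flank), end))
  } else {
    list(c(max(1, start - flank), end),
         c(max(1, start - flank), min(glen, end + flank)),
         c(start, min(glen, end + flank)))
  }
  lapply(seq_along(spans), function(a) {
    sp <- spans[[a]]
    w <- substr(gt$fwd[k], sp[1], sp[2])
    if (strand == "+") {
      m <- c(start - sp[1] + 1, end - sp[1] + 1)
    } else {
      w <- revcomp(w)
      m <- c(sp[2] - end + 1, sp[2] - start + 1)
    }
    list(seq = w, mature_span = m, anchor = c("5p", "center", "3p")[a],
         window = sp)
  })
}

# First window whose folded structure passes all criteria; NULL otherwise.
#' @noRd
hairpin_at_locus <- function(gt, contig, start, end, strand, flank = 80L,
                             thresholds = criteria_thresholds()) {
  for (w in flank_windows(gt, contig, start, end, strand, flank)) {
    n <- nchar(w$seq)
    if (n < 50 || n > 300) next
    h <- fold_hairpin(w$seq)
    rep <- evaluate_criteria(structure_features(h, w$mature_span), thresholds)
    if (criteria_pass(rep)) {
      return(list(hairpin = h, report = rep, window = w))
    }
  }
  NULL
}

#' Classify valid tags into the six known/novel miRNA groups
#'
#' Runs the decision cascade for each tag with sufficient read support:
#' a tag matching a focal-species mature miRNA whose precursor maps to the
#' genome is Group 1a; matching another mammal's mature with a
#' genome-mapped precursor is 1b; a mature match whose precursor does not
#' map but whose own genomic flank folds into a qualifying hairpin is 2a
#' (2b without the hairpin); a mature match with neither precursor nor tag
#' on the genome is 3; tags matching no mature are left `unassigned` and are
#' the input to [call_novel()]. Tags matching a precursor only (at the
#' opposite arm of a known mature) are recorded as arm-derived known miRNAs
#' (`other_arm = TRUE`) and grouped through the same cascade.
#'
#' @param tags Tag table (`sequence` plus `count_*` columns), typically the
#'   `valid` element of [partition_valid()].
#' @param bundle A `"ref_bundle"` containing `mature_mirna`, `pre_mirna`,
#'   `mature_to_pre` and `genome`.
#' @param tolerance A [map_tolerance()] object.
#' @param min_reads Read-evidence threshold; tags at or below it (strictly
#'   greater is required by default) are never assigned.
#' @param count_gt If `TRUE` (default) the threshold is `total > min_reads`;
#'   if `FALSE`, `total >= min_reads`.
#' @param flank Flanking context, nt on each side, for the Group 2a hairpin
#'   check.
#' @return A data frame of class `"group_assignments"`: one row per
#'   considered tag with `sequence`, per-library counts, `total`, `group`
#'   (`1a`, `1b`, `2a`, `2b`, `3`, `unassigned`), `mirna_id`, `species`,
#'   `precursor_id`, `arm` (`5p`/`3p`/`unknown`), `other_arm`, `mismatches`,
#'   and the first genomic locus (`contig`, `start`, `end` 0-based
#'   half-open, `strand`) when the tag maps.
#' @export
map_known <- function(tags, bundle, tolerance = map_tolerance(),
                      min_reads = 3L, count_gt = TRUE, flank = 80L) {
  tg <- if (!is.null(tags$tags)) tags$tags else tags
  if (is.character(tg)) tg <- data.frame(sequence = tg, count = 1L,
                                         stringsAsFactors = FALSE)
  ccols <- grep("^count", names(tg), value = TRUE)
  total <- if (length(ccols)) Reduce(`+`, tg[ccols]) else rep(1L, nrow(tg))
  eligible <- if (count_gt) total > min_reads else total >= min_reads

  has_genome <- !is.null(bundle$genome) && length(bundle$genome) > 0
  if (!has_genome) {
    warning("bundle has no genome: groups 1a/1b/2a/2b/4 are unreachable")
  }
  gt <- if (has_genome) genome_text(bundle) else NULL
  mm <- if (length(bundle$mature_mirna)) mature_matrix(bundle$mature_mirna)
        else NULL
  pre <- norm_seq(as.character(bundle$pre_mirna))
  pre_ids <- names(bundle$pre_mirna)
  focal <- bundle$focal_species %||% ""

  pre_maps <- if (has_genome && length(pre)) {
    stats::setNames(vapply(pre, genome_has, logical(1), gt = gt), pre_ids)
  } else stats::setNames(logical(length(pre)), pre_ids)
  pre_fold <- new.env(parent = emptyenv())

  arm_for <- function(pid, mature_seq) {
    pseq <- pre[match(pid, pre_ids)]
    if (is.na(pseq)) return("unknown")
    at <- stringi::stri_locate_first_fixed(pseq, mature_seq)
    if (is.na(at[1, 1])) return("unknown")
    h <- tryCatch({
      if (!is.null(pre_fold[[pid]])) pre_fold[[pid]]
      else pre_fold[[pid]] <- fold_hairpin(pseq)
    }, error = function(e) NULL)
    if (is.null(h)) return("unknown")
    arm_of(c(at[1, 1], at[1, 2]), h)
  }

  n <- nrow(tg)
  res <- data.frame(
    sequence = tg$sequence, total = total,
    group = rep("unassigned", n), mirna_id = NA_character_,
    species = NA_character_, precursor_id = NA_character_,
    arm = "unknown", other_arm = FALSE, mismatches = NA_integer_,
    contig = NA_character_, start = NA_integer_, end = NA_integer_,
    strand = NA_character_, stringsAsFactors = FALSE)
  for (cc in ccols) res[[cc]] <- tg[[cc]]

  for (i in which(eligible)) {
    s <- tg$sequence[i]
    hit <- NULL; other_arm <- FALSE
    if (!is.null(mm)) {
      m <- match_matures(s, mm, tolerance)
      hit <- best_mature(m, focal)
    }
    mature_seq <- s
    if (is.null(hit) && length(pre)) {
      # Opposite-arm match against a known precursor.
      contain <- stringi::stri_detect_fixed(pre, s)
      if (!any(contain) && tolerance$max_sub > 0) {
        cnts <- Biostrings::vcountPattern(
          s, Biostrings::DNAStringSet(pre), max.mismatch = tolerance$max_sub)
        contain <- cnts > 0
      }
      if (any(contain)) {
        cand <- data.frame(mirna_id = pre_ids[contain],
                           species = species_of(pre_ids[contain]),
                           mismatches = 0L, offset = 0L,
                           stringsAsFactors = FALSE)
        hit <- best_mature(cand, focal)
        other_arm <- TRUE
      }
    }
    if (is.null(hit)) next

    res$mirna_id[i] <- hit$mirna_id
    res$species[i] <- hit$species
    res$other_arm[i] <- other_arm
    res$mismatches[i] <- hit$mismatches
    pid <- if (other_arm) hit$mirna_id
           else unname(bundle$mature_to_pre[hit$mirna_id])
    if (!is.null(pid) && !is.na(pid)) res$precursor_id[i] <- pid

    loci <- if (has_genome) genome_loci(s, gt) else NULL
    if (!is.null(loci) && nrow(loci)) {
      res$contig[i] <- loci$contig[1]
      res$start[i] <- loci$start[1] - 1L
      res$end[i] <- loci$end[1]
      res$strand[i] <- loci$strand[1]
    }

    pre_on_genome <- !is.null(pid) && !is.na(pid) &&
      pid %in% names(pre_maps) && isTRUE(pre_maps[[pid]])
    if (pre_on_genome) {
      res$group[i] <- if (hit$species == focal) "1a" else "1b"
      if (other_arm) {
        at <- stringi::stri_locate_first_fixed(pre[match(pid, pre_ids)], s)
        res$arm[i] <- if (!is.na(at[1, 1]))
          arm_for(pid, s) else "unknown"
      } else {
        mseq <- norm_seq(as.character(bundle$mature_mirna[[hit$mirna_id]]))
        res$arm[i] <- arm_for(pid, mseq)
      }
    } else if (!is.null(loci) && nrow(loci) > 0) {
      hp <- hairpin_at_locus(gt, loci$contig[1], loci$start[1], loci$end[1],
                             loci$strand[1], flank)
      res$group[i] <- if (!is.null(hp)) "2a" else "2b"
      if (!is.null(hp)) {
        res$arm[i] <- arm_of(hp$window$mature_span, hp$hairpin)
      }
    } else {
      res$group[i] <- "3"
    }
  }
  class(res) <- c("group_assignments", "data.frame")
  res
}

#' Arm of a mature span within a hairpin precursor
#'
#' The mature sequence is 5p-derived when its midpoint lies 5' of the
#' hairpin-loop midpoint, 3p-derived otherwise; an exact tie is broken to
#' 5p. Returns `"unknown"` when the structure has no hairpin loop.
#'
#' @param mature_span Integer pair, 1-based inclusive span in the precursor.
#' @param precursor A `"hairpin"` object (see [fold_hairpin()]).
#' @return `"5p"`, `"3p"`, or `"unknown"`.
#' @export
arm_of <- function(mature_span, precursor) {
  f <- tryCatch(structure_features(precursor, mature_span),
                error = function(e) NULL)
  if (is.null(f) || !isTRUE(f$valid)) return("unknown")
  loop_mid <- mean(f$loop_span)
  mature_mid <- mean(mature_span)
  if (mature_mid <= loop_mid) "5p" else "3p"
}

#' Summarize miRNA families from group assignments
#'
#' The family of a miRNA name is its case-insensitive stem: the leading
#' `miR`/`let`/`lin` token plus the first number, dropping the species
#' prefix, paralog suffix letters and `-5p`/`-3p` arm suffixes
#' (`chi-miR-30a-5p`, `bta-miR-30f` and `hsa-miR-30e` all belong to family
#' `miR-30`). As a consistency check, the seed region (nt 2-8) of member
#' tags is compared within each family and disagreements are reported in
#' the `seed_disagreements` attribute.
#'
#' @param assignments A `"group_assignments"` data frame (rows with a
#'   `mirna_id` are used).
#' @return Data frame with `family`, `n_members` (distinct miRNA ids),
#'   `members` (comma-joined) and `n_species`.
#' @export
family_summary <- function(assignments) {
  a <- assignments[!is.na(assignments$mirna_id), , drop = FALSE]
  ids <- unique(a$mirna_id)
  fam <- mirna_family(ids)
  keep <- !is.na(fam)
  df <- data.frame(id = ids[keep], family = fam[keep], stringsAsFactors = FALSE)
  sp <- species_of(df$id)
  out <- do.call(rbind, lapply(split(seq_len(nrow(df)), df$family), function(ix) {
    data.frame(family = df$family[ix[1]], n_members = length(ix),
               members = paste(sort(df$id[ix]), collapse = ","),
               n_species = length(unique(sp[ix])), stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_members, out$family), , drop = FALSE]
  rownames(out) <- NULL
  # Seed consistency: members of one family should share the nt 2-8 seed.
  if (!is.null(assignments$sequence)) {
    seedtab <- tapply(substr(assignments$sequence, 2, 8)[!is.na(assignments$mirna_id)],
                      mirna_family(assignments$mirna_id[!is.na(assignments$mirna_id)]),
                      function(x) length(unique(x)))
    attr(out, "seed_disagreements") <- names(seedtab)[seedtab > 1]
  }
  out
}

#' Family stem of miRNA identifiers
#'
#' @param ids Character vector of miRBase-style names.
#' @return Character vector of family stems (`NA` when no stem is found).
#' @export
mirna_family <- function(ids) {
  x <- stringi::stri_replace_first_regex(ids, "^[a-z]{2,4}-", "")
  m <- stringi::stri_match_first_regex(tolower(x), "^(mir|let|lin)-?(\\d+)")
  tok <- c(mir = "miR", let = "let", lin = "lin")[m[, 2]]
  ifelse(is.na(m[, 1]), NA_character_, paste0(tok, "-", m[, 3]))
}

#' Cross-species conservation profile of identified miRNAs
#'
#' For each species in the bundle, counts the distinct mature miRNAs of
#' that species matched by the identified tags (a tag matching homologs in
#' several species is counted once per species), and tabulates how many
#' tags are conserved among at least *n* species.
#'
#' @param assignments A `"group_assignments"` data frame; tags with a
#'   mature match (groups 1a-3) are profiled.
#' @param bundle A `"ref_bundle"`.
#' @param tolerance A [map_tolerance()] object.
#' @return List with `per_species` (data frame `species`, `n_mirnas`) and
#'   `conservation` (data frame `min_species`, `n_tags`).
#' @export
conservation_profile <- function(assignments, bundle,
                                 tolerance = map_tolerance()) {
  a <- assignments[assignments$group %in% c("1a", "1b", "2a", "2b", "3"), ,
                   drop = FALSE]
  species <- bundle$species %||% unique(species_of(names(bundle$mature_mirna)))
  if (nrow(a) == 0 || length(bundle$mature_mirna) == 0) {
    return(list(per_species = data.frame(species = species, n_mirnas = 0),
                conservation = data.frame(min_species = seq_along(species),
                                          n_tags = 0)))
  }
  mm <- mature_matrix(bundle$mature_mirna)
  per_tag_species <- lapply(unique(a$sequence), function(s) {
    unique(match_matures(s, mm, tolerance)$species)
  })
  ids_by_species <- lapply(species, function(sp) {
    hit <- unlist(lapply(unique(a$sequence), function(s) {
      m <- match_matures(s, mm, tolerance)
      m$mirna_id[m$species == sp]
    }))
    unique(hit)
  })
  per_species <- data.frame(species = species,
                            n_mirnas = lengths(ids_by_species))
  nsp <- lengths(per_tag_species)
  conservation <- data.frame(
    min_species = seq_len(max(1, length(species))),
    n_tags = vapply(seq_len(max(1, length(species))),
                    function(k) sum(nsp >= k), numeric(1)))
  list(per_species = per_species, conservation = conservation)
}
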