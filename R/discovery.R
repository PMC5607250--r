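#' Call novel miRNA candidates (Group 4) from unmatched tags
#'
#' For each genome-mapped tag that matched no mature or precursor reference,
#' extracts up to three windows of genomic context (80 nt of flank on each
#' side: tag at the 5' arm, centered, tag at the 3' arm), folds each window,
#' and evaluates the eleven secondary-structure criteria with the tag as the
#' mature span. Any window passing all criteria makes the tag a Group 4
#' novel candidate; minus-strand loci are reverse-complemented before
#' folding. Tags mapping to more than `max_loci` genomic sites are discarded
#' as repetitive, and tags at or below the read-evidence threshold are never
#' called. Candidates are deduplicated by locus (overlapping windows on one
#' contig are one candidate; the highest-count tag represents it).
#'
#' @param assignments A `"group_assignments"` data frame (its `unassigned`
#'   rows are evaluated), or a tag table with `sequence`/`count_*` columns.
#' @param bundle A `"ref_bundle"` with a genome.
#' @param min_reads Read-evidence threshold (strictly greater than, by
#'   default, matching [map_known()]).
#' @param count_gt See [map_known()].
#' @param flank Flanking context in nt on each side.
#' @param max_loci Maximum genomic loci before a tag is set aside as
#'   repetitive.
#' @param thresholds Criteria thresholds, see [criteria_thresholds()].
#' @param structures Optional named list (by tag sequence) of lists with
#'   `structure` (dot-bracket) and optionally `energy`, used verbatim
#'   instead of the bundled folder for that tag's precursor window.
#' @return A list with `candidates` (data frame: `candidate_id`, `sequence`,
#'   `total`, `contig`, `start`, `end` of the precursor window (0-based
#'   half-open), `strand`, `arm`, `energy`, `precursor_seq`, `dot_bracket`),
#'   `reports` (list of criteria reports per candidate), and `repetitive`
#'   (tags discarded for multi-mapping).
#' @export
call_novel <- function(assignments, bundle, min_reads = 3L, count_gt = TRUE,
                       flank = 80L, max_loci = 5L,
                       thresholds = criteria_thresholds(),
                       structures = NULL) {
  tg <- assignments
  if (inherits(tg, "group_assignments")) {
    tg <- tg[tg$group == "unassigned", , drop = FALSE]
  }
  ccols <- grep("^count", names(tg), value = TRUE)
  total <- if (!is.null(tg$total)) tg$total
           else if (length(ccols)) Reduce(`+`, tg[ccols])
           else rep(1L, nrow(tg))
  eligible <- if (count_gt) total > min_reads else total >= min_reads
  tg <- tg[eligible, , drop = FALSE]
  total <- total[eligible]

  gt <- genome_text(bundle)
  cand <- list(); reports <- list(); repetitive <- character(0)
  if (nrow(tg)) {
    ord <- order(-total, tg$sequence)
    tg <- tg[ord, , drop = FALSE]
    total <- total[ord]
  }
  for (i in seq_len(nrow(tg))) {
    s <- tg$sequence[i]
    loci <- genome_loci(s, gt)
    if (nrow(loci) == 0) next
    if (nrow(loci) > max_loci) {
      repetitive <- c(repetitive, s)
      next
    }
    for (r in seq_len(nrow(loci))) {
      found <- NULL
      ext <- if (!is.null(structures) && !is.null(structures[[s]])) {
        structures[[s]]
      } else NULL
      if (!is.null(ext)) {
        ws <- flank_windows(gt, loci$contig[r], loci$start[r], loci$end[r],
                            loci$strand[r], flank)
        for (w in ws) {
          if (nchar(w$seq) != nchar(ext$structure)) next
          h <- fold_hairpin(w$seq, structure = ext$structure,
                            energy = ext$energy)
          repx <- evaluate_criteria(structure_features(h, w$mature_span),
                                    thresholds)
          if (criteria_pass(repx)) { found <- list(hairpin = h, report = repx,
                                                   window = w); break }
        }
      } else {
        found <- hairpin_at_locus(gt, loci$contig[r], loci$start[r],
                                  loci$end[r], loci$strand[r], flank,
                                  thresholds)
      }
      if (is.null(found)) next
      cand[[length(cand) + 1]] <- list(
        sequence = s, total = total[i], contig = loci$contig[r],
        wstart = found$window$window[1], wend = found$window$window[2],
        strand = loci$strand[r], found = found)
      reports[[length(reports) + 1]] <- found$report
      break # one candidate per tag
    }
  }

  # Deduplicate by overlapping precursor windows per contig; candidates are
  # already in decreasing read-support order, so the first in a cluster is
  # its representative.
  keep <- rep(TRUE, length(cand))
  if (length(cand) > 1) {
    for (a in seq_along(cand)) {
      if (!keep[a]) next
      for (b in seq_along(cand)) {
        if (b <= a || !keep[b]) next
        if (cand[[a]]$contig == cand[[b]]$contig &&
            cand[[a]]$wstart <= cand[[b]]$wend &&
            cand[[b]]$wstart <= cand[[a]]$wend) {
          keep[b] <- FALSE
        }
      }
    }
  }
  cand <- cand[keep]; reports <- reports[keep]

  if (length(cand)) {
    candidates <- do.call(rbind, lapply(seq_along(cand), function(k) {
      x <- cand[[k]]
      data.frame(
        candidate_id = sprintf("novel-cand-%02d", k),
        sequence = x$sequence, total = x$total, contig = x$contig,
        start = x$wstart - 1L, end = x$wend, strand = x$strand,
        arm = arm_of(x$found$window$mature_span, x$found$hairpin),
        energy = x$found$hairpin$energy,
        precursor_seq = x$found$hairpin$seq,
        dot_bracket = x$found$hairpin$dot_bracket,
        stringsAsFactors = FALSE)
    }))
  } else {
    candidates <- data.frame(candidate_id = character(0))
  }
  names(reports) <- candidates$candidate_id
  list(candidates = candidates, reports = reports, repetitive = repetitive)
}

#' Write novel-candidate outputs
#'
#' Emits the precursor FASTA, a criteria TSV (one column per criterion's
#' measured value plus pass flags), and a Vienna-style plain-text structure
#' file (id, sequence, dot-bracket with energy).
#'
#' @param novel Result of [call_novel()].
#' @param dir Output directory.
#' @export
write_novel <- function(novel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cd <- novel$candidates
  if (nrow(cd)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(cd$precursor_seq, cd$candidate_id)),
      file.path(dir, "novel_precursors.fa"))
    crit <- do.call(rbind, lapply(names(novel$reports), function(id) {
      r <- novel$reports[[id]]
      row <- as.data.frame(as.list(stats::setNames(r$measured, r$criterion)))
      row$candidate_id <- id
      row$overall <- criteria_pass(r)
      row
    }))
    utils::write.table(crit, file.path(dir, "novel_criteria.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(paste0(">", cd$candidate_id, "\n", cd$precursor_seq, "\n",
                      cd$dot_bracket, " (", sprintf("%.2f", cd$energy), ")"),
               file.path(dir, "novel_structures.txt"))
  }
  invisible(dir)
}

#' Run the full two-library pipeline
#'
#' Orchestrates preprocessing, contaminant partitioning, six-group
#' classification, novel-candidate calling and differential expression for
#' two read sets, returning every intermediate table.
#'
#' @param reads_E,reads_L Character vectors of raw reads.
#' @param bundle A `"ref_bundle"`.
#' @param adapter 3' adapter sequence.
#' @param min_reads Read-evidence threshold for classification.
#' @param de_th A [de_thresholds()] object.
#' @param flank Flanking context for hairpin evaluation, nt per side.
#' @param max_mismatch_contaminant Substitutions tolerated in contaminant
#'   containment matching.
#' @return A list with `ledgers`, `tags`, `length_dist`, `partition`
#'   (contaminant stats and valid tags), `assignments`, `novel`,
#'   `mirna_counts` (per-miRNA aggregated counts), and `de` (the
#'   differential-expression table).
#' @export
run_pipeline <- function(reads_E, reads_L, bundle,
                         adapter = "TGGAATTCTCGGGTGCCAAGG",
                         min_reads = 3L, de_th = de_thresholds(),
                         flank = 80L, max_mismatch_contaminant = 1L) {
  fE <- filter_and_collapse(reads_E, "E", adapter = adapter)
  fL <- filter_and_collapse(reads_L, "L", adapter = adapter)
  merged <- collapse_libraries(fE, fL)
  raw <- stats::setNames(
    merged$ledgers$reads[merged$ledgers$disposition == "raw"], c("E", "L"))
  rawu <- stats::setNames(
    merged$ledgers$unique[merged$ledgers$disposition == "raw"], c("E", "L"))
  part <- partition_valid(merged$tags, bundle, raw_totals = raw,
                          raw_unique = rawu,
                          max_mismatch = max_mismatch_contaminant)
  assignments <- map_known(part$valid, bundle, min_reads = min_reads,
                           flank = flank)
  novel <- call_novel(assignments, bundle, min_reads = min_reads,
                      flank = flank)

  # Aggregate known-miRNA counts over their assigned tags.
  known <- assignments[assignments$group %in% c("1a", "1b", "2a", "2b", "3"), ,
                       drop = FALSE]
  x <- tapply(known$count_E, known$mirna_id, sum)
  y <- tapply(known$count_L, known$mirna_id, sum)
  ids <- sort(unique(known$mirna_id))
  counts <- data.frame(id = ids,
                       x = as.integer(x[ids]), y = as.integer(y[ids]),
                       stringsAsFactors = FALSE)
  valid_totals <- c(
    E = sum(part$stats$reads_E[part$stats$category == "valid"]),
    L = sum(part$stats$reads_L[part$stats$category == "valid"]))
  de <- if (nrow(counts)) {
    de_table(counts, totals = valid_totals, th = de_th)
  } else NULL

  list(ledgers = merged$ledgers, tags = merged$tags,
       length_dist = length_distribution(merged$tags),
       partition = part, assignments = assignments, novel = novel,
       mirna_counts = counts, valid_totals = valid_totals, de = de)
}
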