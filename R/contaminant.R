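#' Match one tag against the contaminant reference categories
#'
#' Returns the first category, in the priority order repeat, rRNA, tRNA,
#' snoRNA, snRNA, other ncRNA, mRNA, in which the tag is contained as a
#' substring of any reference (on either strand), allowing up to
#' `max_mismatch` substitutions. Empty categories are skipped silently.
#'
#' @param tag A single tag sequence (18-26 nt).
#' @param bundle A `"ref_bundle"`.
#' @param max_mismatch Substitutions tolerated (0 or more).
#' @return The category name, or `NA_character_` when the tag hits nothing
#'   (it stays a valid tag).
#' @export
match_category <- function(tag, bundle, max_mismatch = 1L) {
  stopifnot(length(tag) == 1)
  s <- norm_seq(tag)
  for (cat in contaminant_categories()) {
    refs <- bundle[[cat]]
    if (is.null(refs) || length(refs) == 0) next
    both <- c(as.character(refs), as.character(Biostrings::reverseComplement(refs)))
    if (any(stringi::stri_detect_fixed(both, s))) return(cat)
    if (max_mismatch > 0) {
      hits <- Biostrings::vcountPattern(s, Biostrings::DNAStringSet(both),
                                        max.mismatch = max_mismatch)
      if (any(hits > 0)) return(cat)
    }
  }
  NA_character_
}

# Vectorized category assignment. Exact containment is checked first against
# per-category concatenated reference text (both strands); only tags with no
# exact hit anywhere go through the mismatch-tolerant scan.
#' @noRd
classify_contaminants <- function(seqs, bundle, max_mismatch = 1L) {
  out <- rep(NA_character_, length(seqs))
  cats <- contaminant_categories()
  texts <- list(); sets <- list()
  for (cat in cats) {
    refs <- bundle[[cat]]
    if (is.null(refs) || length(refs) == 0) next
    both <- c(as.character(refs), as.character(Biostrings::reverseComplement(refs)))
    texts[[cat]] <- stringi::stri_join(both, collapse = "\n")
    sets[[cat]] <- Biostrings::DNAStringSet(both)
  }
  todo <- seq_along(seqs)
  for (cat in names(texts)) {
    if (!length(todo)) break
    hit <- stringi::stri_detect_fixed(texts[[cat]], seqs[todo])
    out[todo[hit]] <- cat
    todo <- todo[!hit]
  }
  if (max_mismatch > 0 && length(todo)) {
    for (i in todo) {
      s <- seqs[i]
      for (cat in names(sets)) {
        if (any(Biostrings::vcountPattern(s, sets[[cat]],
                                          max.mismatch = max_mismatch) > 0)) {
          out[i] <- cat
          break
        }
      }
    }
  }
  out
}

#' Partition unique tags into contaminant categories versus valid tags
#'
#' Every tag is assigned exactly one category or stays valid. The statistics
#' table reports, per library, total-read and unique-tag counts for each
#' category, an Rfam supercategory (the sum of rRNA, tRNA, snoRNA, snRNA and
#' other ncRNA), and the valid remainder, with percentages of the raw
#' totals carried in the filter ledger, rounded half-up to two decimals.
#'
#' @param tags Tag table with `sequence` and per-library `count_*` columns
#'   (or the list returned by [collapse_libraries()]).
#' @param bundle A `"ref_bundle"`.
#' @param raw_totals Named numeric, raw read totals per library (ledger
#'   `raw` rows); required for percentages.
#' @param raw_unique Optional named numeric, raw unique-sequence totals per
#'   library, for unique-tag percentages.
#' @param max_mismatch Substitutions tolerated in containment matching.
#' @return A list with `valid` (tag table subset), `assignments` (per-tag
#'   category or NA), and `stats` (accounting data frame).
#' @export
partition_valid <- function(tags, bundle, raw_totals, raw_unique = NULL,
                            max_mismatch = 1L) {
  tg <- if (!is.null(tags$tags)) tags$tags else tags
  if (missing(raw_totals) || is.null(raw_totals)) {
    stop("raw_totals is required: percentages are undefined without it")
  }
  ccols <- grep("^count_", names(tg), value = TRUE)
  libs <- sub("^count_", "", ccols)
  stopifnot(all(libs %in% names(raw_totals)))

  assign <- classify_contaminants(tg$sequence, bundle, max_mismatch)
  cats <- contaminant_categories()
  rows <- c(cats, "Rfam", "valid")
  stats <- data.frame(category = rows, stringsAsFactors = FALSE)
  for (k in seq_along(libs)) {
    cnt <- tg[[ccols[k]]]
    reads <- vapply(cats, function(cc) sum(cnt[!is.na(assign) & assign == cc]),
                    numeric(1))
    uniq <- vapply(cats, function(cc) sum(!is.na(assign) & assign == cc & cnt > 0),
                   numeric(1))
    reads <- c(reads, Rfam = sum(reads[rfam_subclasses()]),
               valid = sum(cnt[is.na(assign)]))
    uniq <- c(uniq, Rfam = sum(uniq[rfam_subclasses()]),
              valid = sum(is.na(assign) & cnt > 0))
    stats[[paste0("reads_", libs[k])]] <- reads
    stats[[paste0("pct_reads_", libs[k])]] <-
      percent_of_raw(reads, raw_totals[[libs[k]]])
    stats[[paste0("unique_", libs[k])]] <- uniq
    if (!is.null(raw_unique)) {
      stats[[paste0("pct_unique_", libs[k])]] <-
        percent_of_raw(uniq, raw_unique[[libs[k]]])
    }
  }
  valid <- tg[is.na(assign), , drop = FALSE]
  rownames(valid) <- NULL
  list(valid = valid, assignments = assign, stats = stats)
}

#' Format a category accounting row set in Table style
#'
#' Given per-category read counts and the raw total, recomputes each
#' category's percentage of the raw total (two decimals, half-up). This is
#' the formatter behind the `pct_*` columns of [partition_valid()].
#'
#' @param counts Named numeric vector of category read counts.
#' @param raw_total Raw read total of the library.
#' @return Data frame with `category`, `reads`, `pct`.
#' @export
#' @examples
#' format_accounting(c(mRNA = 85700, Rfam = 314821), raw_total = 18908954)
format_accounting <- function(counts, raw_total) {
  data.frame(category = names(counts), reads = as.numeric(counts),
             pct = percent_of_raw(as.numeric(counts), raw_total),
             stringsAsFactors = FALSE, row.names = NULL)
}
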