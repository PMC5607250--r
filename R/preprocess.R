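#' Flag junk (low-complexity) reads
#'
#' A read is junk when it contains an ambiguous base (N or any
#' non-nucleotide character), any single base makes up at least
#' `max_base_frac` of its length, it contains a homopolymer run of at least
#' `min_homopolymer` bases, or a dinucleotide repeat covers at least
#' `max_dinuc_frac` of its length. These thresholds follow common
#' vendor-pipeline heuristics and are configurable.
#'
#' @param seqs Character vector of read sequences.
#' @param max_base_frac Single-base fraction threshold.
#' @param min_homopolymer Homopolymer run threshold.
#' @param max_dinuc_frac Dinucleotide-repeat coverage threshold.
#' @return Logical vector.
#' @export
is_junk <- function(seqs, max_base_frac = 0.8, min_homopolymer = 10,
                    max_dinuc_frac = 0.9) {
  s <- norm_seq(seqs)
  n <- nchar(s)
  bad <- stringi::stri_detect_regex(s, "[^ACGT]") | n == 0
  ok <- !bad & n > 0
  if (any(ok)) {
    for (b in c("A", "C", "G", "T")) {
      frac <- stringi::stri_count_fixed(s[ok], b) / n[ok]
      bad[ok] <- bad[ok] | frac >= max_base_frac
    }
    hp <- sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}", min_homopolymer,
                  min_homopolymer, min_homopolymer, min_homopolymer)
    bad[ok] <- bad[ok] | stringi::stri_detect_regex(s[ok], hp)
    dins <- c("AC", "AG", "AT", "CA", "CG", "CT",
              "GA", "GC", "GT", "TA", "TC", "TG")
    idx <- which(ok & !bad)
    if (length(idx)) {
      for (d in dins) {
        hits <- stringi::stri_locate_all_regex(s[idx], paste0("(?:", d, ")+"))
        run <- vapply(hits, function(m) {
          if (is.na(m[1, 1])) 0L else max(m[, 2] - m[, 1] + 1L)
        }, integer(1))
        bad[idx] <- bad[idx] | (run / n[idx] >= max_dinuc_frac)
        idx <- idx[run / n[idx] < max_dinuc_frac]
        if (!length(idx)) break
      }
    }
  }
  bad
}

#' Trim the 3' adapter from a single read
#'
#' Scans the read left to right for the first position where a prefix of the
#' adapter of length at least `min_overlap` matches with at most
#' `max_mismatch` substitutions, and returns the insert 5' of that position.
#' Returns `NA` when no such match exists (a "3ADT"-null read) or when the
#' read contains non-nucleotide characters (such reads are junk, not an
#' error).
#'
#' @param read A single read sequence.
#' @param adapter 3' adapter sequence.
#' @param min_overlap Minimum adapter prefix length to accept (>= 4).
#' @param max_mismatch Maximum substitutions tolerated in the match.
#' @return The insert sequence (possibly empty), or `NA_character_`.
#' @export
#' @examples
#' trim_adapter3("ACGTACGTACGTACGTACGTTGGAATTC", "TGGAATTC",
#'               min_overlap = 6, max_mismatch = 0)
trim_adapter3 <- function(read, adapter, min_overlap = 6L, max_mismatch = 1L) {
  stopifnot(length(read) == 1, nchar(adapter) >= min_overlap, min_overlap >= 4)
  r <- norm_seq(read)
  a <- norm_seq(adapter)
  if (stringi::stri_detect_regex(r, "[^ACGT]")) return(NA_character_)
  L <- nchar(r); alen <- nchar(a)
  rint <- utf8ToInt(r); aint <- utf8ToInt(a)
  for (p in seq_len(max(0, L - min_overlap + 1))) {
    len <- min(alen, L - p + 1)
    mism <- sum(rint[p:(p + len - 1)] != aint[seq_len(len)])
    if (mism <= max_mismatch) return(substr(r, 1, p - 1))
  }
  NA_character_
}

# Vectorized batch trimming. Fast path: leftmost exact occurrence of the
# adapter seed (its first min_overlap bases); reads without an exact seed
# fall back to the mismatch-tolerant single-read scan.
#' @noRd
trim_adapters <- function(reads, adapter, min_overlap = 6L, max_mismatch = 1L) {
  r <- norm_seq(reads)
  a <- norm_seq(adapter)
  seed <- substr(a, 1, min_overlap)
  pos <- stringi::stri_locate_first_fixed(r, seed)[, 1]
  out <- ifelse(is.na(pos), NA_character_, substr(r, 1, pos - 1))
  if (max_mismatch > 0) {
    miss <- which(is.na(pos))
    if (length(miss)) {
      out[miss] <- vapply(r[miss], function(x) {
        if (stringi::stri_detect_regex(x, "[^ACGT]")) NA_character_
        else trim_adapter3(x, a, min_overlap, max_mismatch)
      }, character(1), USE.NAMES = FALSE)
    }
  }
  out
}

#' Filter reads and collapse them into unique tags
#'
#' Applies the read filters in accounting order -- junk first, then 3'
#' adapter detection (when `adapter` is given; reads with no detectable
#' adapter are "3ADT"), then insert length -- and collapses the surviving
#' inserts case-insensitively with U normalized to T. When `adapter` is
#' `NULL` the input is taken to be already-trimmed inserts. Reads failing
#' several filters are ledgered under the first. The 3ADT and length
#' dispositions share one ledger row, mirroring the usual accounting-table
#' layout.
#'
#' @param reads Character vector of reads (or a `DNAStringSet`).
#' @param library_id Library label, e.g. `"E"`.
#' @param adapter Optional 3' adapter to trim.
#' @param min_len,max_len Insert length bounds retained (inclusive).
#' @param min_overlap,max_mismatch Adapter-matching parameters.
#' @param junk_opts Named list overriding [is_junk()] thresholds.
#' @return A list with `tags` (data frame: `sequence`, `count`; sorted by
#'   sequence) and `ledger` (class `"filter_ledger"`: per-disposition read
#'   and unique-sequence tallies partitioning the input exactly).
#' @export
filter_and_collapse <- function(reads, library_id, adapter = NULL,
                                min_len = 18L, max_len = 26L,
                                min_overlap = 6L, max_mismatch = 1L,
                                junk_opts = list()) {
  r <- norm_seq(as.character(reads))
  n_raw <- length(r)
  junk <- do.call(is_junk, c(list(seqs = r), junk_opts))
  inserts <- rep(NA_character_, n_raw)
  keep <- !junk
  if (!is.null(adapter)) {
    inserts[keep] <- trim_adapters(r[keep], adapter, min_overlap, max_mismatch)
  } else {
    inserts[keep] <- r[keep]
  }
  adt3 <- keep & is.na(inserts)
  len <- nchar(inserts)
  badlen <- keep & !adt3 & (len < min_len | len > max_len)
  valid <- keep & !adt3 & !badlen

  uniq <- function(x) length(unique(x))
  ledger <- data.frame(
    library = library_id,
    disposition = c("raw", "junk", "adt3_or_length", "valid"),
    reads = c(n_raw, sum(junk), sum(adt3) + sum(badlen), sum(valid)),
    unique = c(uniq(r), uniq(r[junk]), uniq(r[adt3 | badlen]),
               uniq(inserts[valid])),
    stringsAsFactors = FALSE)
  class(ledger) <- c("filter_ledger", "data.frame")

  tab <- table(inserts[valid])
  tags <- data.frame(sequence = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  tags <- tags[order(tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL
  list(tags = tags, ledger = ledger)
}

#' Merge per-library collapsed tags into one tag table
#'
#' @param ... Results of [filter_and_collapse()], one per library, or a
#'   single list of them. Library labels are taken from the ledgers.
#' @return A list with `tags` (data frame: `sequence` plus one `count_<lib>`
#'   column per library) and `ledgers` (row-bound filter ledgers).
#' @export
collapse_libraries <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(args[[1]]$tags)) args <- args[[1]]
  libs <- vapply(args, function(a) a$ledger$library[1], character(1))
  seqs <- sort(unique(unlist(lapply(args, function(a) a$tags$sequence))))
  tags <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (k in seq_along(args)) {
    cnt <- stats::setNames(args[[k]]$tags$count, args[[k]]$tags$sequence)
    v <- as.integer(cnt[seqs])
    v[is.na(v)] <- 0L
    tags[[paste0("count_", libs[k])]] <- v
  }
  list(tags = tags, ledgers = do.call(rbind, lapply(args, `[[`, "ledger")))
}

#' Length distribution of unique tags
#'
#' @param tags Tag table (from [collapse_libraries()] or
#'   [filter_and_collapse()]).
#' @param lengths Lengths to tabulate.
#' @return Data frame with one row per length and, per library, read counts,
#'   read fractions, unique-tag counts and unique fractions. Fractions sum
#'   to 1 per library.
#' @export
length_distribution <- function(tags, lengths = 18:26) {
  tg <- if (!is.null(tags$tags)) tags$tags else tags
  len <- nchar(tg$sequence)
  ccols <- grep("^count", names(tg), value = TRUE)
  out <- data.frame(length = lengths)
  for (cc in ccols) {
    lib <- sub("^count_?", "", cc)
    suffix <- if (nzchar(lib)) paste0("_", lib) else ""
    reads <- vapply(lengths, function(l) sum(tg[[cc]][len == l]), numeric(1))
    uniq <- vapply(lengths, function(l) sum(len == l & tg[[cc]] > 0), numeric(1))
    out[[paste0("reads", suffix)]] <- reads
    out[[paste0("read_frac", suffix)]] <- if (sum(reads) > 0) reads / sum(reads) else reads
    out[[paste0("unique", suffix)]] <- uniq
    out[[paste0("unique_frac", suffix)]] <- if (sum(uniq) > 0) uniq / sum(uniq) else uniq
  }
  out
}
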