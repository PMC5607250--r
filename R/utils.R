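#' Round half away from zero
#'
#' Fixed-precision rounding with halves rounded up, matching the arithmetic
#' used in sequencing accounting tables (e.g. 0.455 -> 0.46), unlike base
#' [round()]'s banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a raw total, formatted to two decimals
#'
#' Computes `100 * count / raw_total` rounded half-up to two decimal places,
#' the convention used throughout library accounting tables.
#'
#' @param count Numeric vector of category counts.
#' @param raw_total Positive scalar, the raw read (or unique-sequence) total.
#' @return Numeric vector of two-decimal percentages.
#' @export
#' @examples
#' percent_of_raw(85700, 18908954)
percent_of_raw <- function(count, raw_total) {
  stopifnot(length(raw_total) == 1, raw_total > 0)
  round_half_up(100 * count / raw_total, 2)
}

# Normalize nucleotide text: upper case, RNA -> DNA alphabet.
#' @noRd
norm_seq <- function(x) {
  stringi::stri_replace_all_fixed(toupper(x), "U", "T")
}

# Reverse complement for plain character vectors (DNA alphabet).
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA sequences screened against forbidden substrings and, optionally,
# against low-complexity content (homopolymer runs >= 8). Resamples offending
# sequences until clean; used by the generator so that planted sequences can
# never collide with the adapter seed or trip the junk filter.
#' @noRd
random_dna <- function(n, len, avoid = character(), screen_low_complexity = FALSE,
                       alphabet = c("A", "C", "G", "T"), max_iter = 200L) {
  if (n == 0) return(character())
  draw <- function(k) {
    vapply(seq_len(k), function(i) {
      paste(sample(alphabet, len, replace = TRUE), collapse = "")
    }, character(1))
  }
  out <- draw(n)
  for (iter in seq_len(max_iter)) {
    bad <- rep(FALSE, n)
    for (pat in avoid) {
      bad <- bad | stringi::stri_detect_fixed(out, pat)
    }
    if (screen_low_complexity) {
      bad <- bad | stringi::stri_detect_regex(out, "A{8,}|C{8,}|G{8,}|T{8,}")
    }
    if (!any(bad)) return(out)
    out[bad] <- draw(sum(bad))
  }
  stop("could not generate sequences avoiding the requested substrings")
}

# Contaminant categories in matching priority (and reporting) order.
#' @noRd
contaminant_categories <- function() {
  c("repeat", "rRNA", "tRNA", "snoRNA", "snRNA", "other_ncRNA", "mRNA")
}

#' @noRd
rfam_subclasses <- function() {
  c("rRNA", "tRNA", "snoRNA", "snRNA", "other_ncRNA")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
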