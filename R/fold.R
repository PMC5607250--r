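#' Fold a candidate precursor into a hairpin structure
#'
#' Computes the maximum-scoring non-crossing base pairing (Watson-Crick plus
#' GU wobble, minimum loop length 3) by dynamic programming with a stacking
#' bonus, and attaches a calibrated free-energy estimate. When a dot-bracket
#' `structure` is supplied (e.g. from an external thermodynamic folder) it is
#' used verbatim and the bundled folder is bypassed; a supplied `energy`
#' likewise takes precedence over the estimate.
#'
#' The energy estimate is `-1.6` kcal/mol per stacked pair, with stacks that
#' involve a GU pair weighted by one half. It is a crude calibration intended
#' to place well-formed hairpins in a realistic minimum-free-energy range and
#' is only meaningful relative to the default energy criterion; supplied
#' energies should be preferred when available.
#'
#' @param seq Nucleotide string (A/C/G/T/U, case-insensitive). Length must be
#'   in `[50, 300]` unless `structure` is supplied.
#' @param structure Optional dot-bracket string of the same length as `seq`.
#' @param energy Optional free energy in kcal/mol (<= 0).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @return An object of class `"hairpin"`: a list with elements `seq`
#'   (normalized to the DNA alphabet), `dot_bracket`, `pairs` (two-column
#'   matrix of 1-based paired positions, 5' position first), `score` (DP
#'   score; `NA` for supplied structures), and `energy` (kcal/mol).
#' @seealso [structure_features()], [evaluate_criteria()]
#' @export
#' @examples
#' h <- fold_hairpin(paste0(
#'   "GCGCGCGCGCGCGCGCGCAGCAGAAAAGCTGCTGCGCGCGCGCGCGCGCGC"))
#' h$dot_bracket
fold_hairpin <- function(seq, structure = NULL, energy = NULL, min_loop = 3L) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- norm_seq(seq)
  if (stringi::stri_detect_regex(s, "[^ACGT]")) {
    stop("sequence contains non-ACGU(T) characters")
  }
  n <- nchar(s)
  if (is.null(structure)) {
    if (n < 50 || n > 300) {
      stop("sequence length must be in [50, 300] for de novo folding")
    }
    dp <- fold_pairing(s, min_loop = min_loop)
    dot_bracket <- dp$dot_bracket
    pairs <- dp$pairs
    score <- dp$score
  } else {
    if (nchar(structure) != n) stop("structure length must match sequence")
    pairs <- parse_dotbracket(structure)
    dot_bracket <- structure
    score <- NA_integer_
  }
  if (is.null(energy)) energy <- hairpin_energy(s, pairs)
  out <- list(seq = s, dot_bracket = dot_bracket, pairs = pairs,
              score = score, energy = energy)
  class(out) <- "hairpin"
  out
}

#' Maximum-scoring non-crossing pairing of a nucleotide sequence
#'
#' The dynamic program underlying [fold_hairpin()], exposed without the
#' precursor length bounds. Pair scores are 3 (GC), 2 (AU), 1 (GU) plus a
#' bonus of 1 for each stacked pair; hairpin loops must hold at least
#' `min_loop` unpaired bases. Traceback is deterministic.
#'
#' @param seq Nucleotide string (A/C/G/T/U).
#' @param min_loop Minimum hairpin-loop length.
#' @return List with `score`, `dot_bracket`, and `pairs` (two-column
#'   1-based matrix).
#' @export
#' @examples
#' fold_pairing("GGGGGGGGGGAAAACCCCCCCCCC")$dot_bracket
fold_pairing <- function(seq, min_loop = 3L) {
  s <- norm_seq(seq)
  if (stringi::stri_detect_regex(s, "[^ACGT]")) {
    stop("sequence contains non-ACGU(T) characters")
  }
  n <- nchar(s)
  dp <- .fold_dp(s, min_loop = as.integer(min_loop), stack_bonus = 1L)
  mate <- dp$mate + 1L # to 1-based; unpaired = 0
  mate[mate == 0L] <- NA_integer_
  db <- rep(".", n)
  paired5 <- which(!is.na(mate) & seq_len(n) < mate)
  db[paired5] <- "("
  db[mate[paired5]] <- ")"
  pairs <- if (length(paired5)) cbind(i = paired5, j = mate[paired5])
           else matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  list(score = dp$score, dot_bracket = paste(db, collapse = ""), pairs = pairs)
}

#' Parse a dot-bracket string into a pair table
#'
#' @param structure Dot-bracket string over `"().",` without pseudoknots.
#' @return Two-column integer matrix of 1-based paired positions (5' first).
#' @export
parse_dotbracket <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("(", ")", "."))) stop("invalid dot-bracket character")
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  res_i <- integer(0); res_j <- integer(0)
  for (p in seq_along(ch)) {
    if (ch[p] == "(") {
      open <- c(open, p)
    } else if (ch[p] == ")") {
      if (length(open) == 0) stop("unbalanced dot-bracket string")
      res_i <- c(res_i, open[length(open)])
      res_j <- c(res_j, p)
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0) stop("unbalanced dot-bracket string")
  if (length(res_i)) {
    ord <- order(res_i)
    pairs <- cbind(i = res_i[ord], j = res_j[ord])
  }
  pairs
}

# Energy estimate: -1.6 kcal/mol per stack, GU-containing stacks half weight.
#' @noRd
hairpin_energy <- function(seq, pairs, per_stack = 1.6) {
  if (nrow(pairs) == 0) return(0)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  mate <- rep(NA_integer_, nchar(seq))
  mate[pairs[, 1]] <- pairs[, 2]
  mate[pairs[, 2]] <- pairs[, 1]
  is_gu <- function(i, j) {
    (ch[i] == "G" && ch[j] == "T") || (ch[i] == "T" && ch[j] == "G")
  }
  w <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!is.na(mate[i + 1]) && mate[i + 1] == j - 1) {
      gu <- is_gu(i, j) || is_gu(i + 1, j - 1)
      w <- w + if (gu) 0.5 else 1
    }
  }
  -per_stack * w
}

#' @export
print.hairpin <- function(x, ...) {
  cat(sprintf("hairpin: %d nt, %d pairs, energy %.1f kcal/mol\n",
              nchar(x$seq), nrow(x$pairs), x$energy))
  cat(x$seq, "\n", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Measure secondary-structure features of a hairpin around a mature span
#'
#' Locates the hairpin loop nearest the mature span, walks its stem (the
#' pairs that enclose that loop and no other), and measures the quantities
#' the eleven-criterion filter is built on.
#'
#' Definitions for quantities the field's vendor pipelines leave informal:
#' a *bulge* is the pair of (possibly empty) unpaired runs between two
#' consecutive stem pairs, sized by its larger run; a mature-region *error*
#' is an unpaired mature nucleotide lying within the stem (terminal-loop
#' overlap is measured by the percent-in-stem feature instead); a bulge is
#' *biased* when its two runs differ in length, and its bias is that
#' difference. A bulge belongs to the mature region when either of its runs
#' touches the mature span.
#'
#' @param h A `"hairpin"` object from [fold_hairpin()].
#' @param mature_span Integer pair, 1-based inclusive span of the candidate
#'   mature sequence within the precursor; length must be in `[18, 26]`.
#' @return A list of feature measurements: `stem_pairs`, `hairpin_len`,
#'   `loop_len`, `loop_span`, `largest_bulge`, `mature_bulge_max`,
#'   `mature_bulge_bias_max`, `mature_biased_bulges`, `mature_errors`,
#'   `mature_pairs`, `mature_in_stem_pct`, `energy`, and `valid` (FALSE when
#'   no hairpin loop exists).
#' @export
structure_features <- function(h, mature_span) {
  stopifnot(inherits(h, "hairpin"), length(mature_span) == 2)
  m1 <- mature_span[1]; m2 <- mature_span[2]
  n <- nchar(h$seq)
  mlen <- m2 - m1 + 1
  if (m1 < 1 || m2 > n || mlen < 18 || mlen > 26) {
    stop("mature span must lie within the precursor and be 18-26 nt")
  }
  empty <- list(valid = FALSE, stem_pairs = 0L, hairpin_len = 0L,
                loop_len = NA_integer_, loop_span = c(NA_integer_, NA_integer_),
                largest_bulge = NA_integer_, mature_bulge_max = NA_integer_,
                mature_bulge_bias_max = NA_integer_,
                mature_biased_bulges = NA_integer_, mature_errors = NA_integer_,
                mature_pairs = 0L, mature_in_stem_pct = 0,
                energy = h$energy, mature_span = c(m1, m2))
  P <- h$pairs
  if (nrow(P) == 0) return(empty)
  paired <- rep(FALSE, n)
  paired[c(P[, 1], P[, 2])] <- TRUE

  # Hairpin loops: pairs with no paired position strictly inside.
  is_loop <- vapply(seq_len(nrow(P)), function(r) {
    i <- P[r, 1]; j <- P[r, 2]
    j - i - 1 > 0 && !any(paired[(i + 1):(j - 1)])
  }, logical(1))
  loops <- P[is_loop, , drop = FALSE]
  if (nrow(loops) == 0) return(empty)

  # Choose the loop nearest the mature span (0 when they overlap).
  loop_dist <- vapply(seq_len(nrow(loops)), function(r) {
    li <- loops[r, 1] + 1; lj <- loops[r, 2] - 1
    if (lj < li) { li <- loops[r, 1]; lj <- loops[r, 2] }
    max(0, li - m2, m1 - lj)
  }, numeric(1))
  L <- loops[which.min(loop_dist), ]

  # Stem: pairs enclosing this loop and no other.
  encloses <- P[, 1] <= L[1] & P[, 2] >= L[2]
  other_loops <- loops[!(loops[, 1] == L[1] & loops[, 2] == L[2]), , drop = FALSE]
  clean <- vapply(seq_len(nrow(P)), function(r) {
    if (!encloses[r]) return(FALSE)
    if (nrow(other_loops) == 0) return(TRUE)
    !any(other_loops[, 1] > P[r, 1] & other_loops[, 2] < P[r, 2])
  }, logical(1))
  S <- P[clean, , drop = FALSE]
  S <- S[order(S[, 1]), , drop = FALSE]

  first <- S[1, 1]; last <- S[1, 2]
  loop_i <- S[nrow(S), 1]; loop_j <- S[nrow(S), 2]
  loop_len <- loop_j - loop_i - 1
  loop_span <- c(loop_i + 1, loop_j - 1)
  hairpin_len <- last - first + 1

  # Bulges between consecutive stem pairs.
  bulges <- list()
  if (nrow(S) > 1) {
    for (t in seq_len(nrow(S) - 1)) {
      g5 <- S[t + 1, 1] - S[t, 1] - 1
      g3 <- S[t, 2] - S[t + 1, 2] - 1
      if (g5 > 0 || g3 > 0) {
        run5 <- if (g5 > 0) (S[t, 1] + 1):(S[t + 1, 1] - 1) else integer(0)
        run3 <- if (g3 > 0) (S[t + 1, 2] + 1):(S[t, 2] - 1) else integer(0)
        bulges[[length(bulges) + 1]] <-
          list(g5 = g5, g3 = g3, size = max(g5, g3), bias = abs(g5 - g3),
               pos = c(run5, run3))
      }
    }
  }
  largest_bulge <- if (length(bulges)) max(vapply(bulges, `[[`, 0, "size")) else 0L

  mpos <- m1:m2
  stem_region <- c(first:loop_i, loop_j:last)
  in_stem <- mpos %in% stem_region
  mature_in_stem_pct <- 100 * sum(in_stem) / mlen
  mature_errors <- sum(in_stem & !paired[mpos])
  mature_pairs <- sum(paired[mpos])

  mb <- Filter(function(b) any(b$pos %in% mpos), bulges)
  mature_bulge_max <- if (length(mb)) max(vapply(mb, `[[`, 0, "size")) else 0L
  mature_bulge_bias_max <- if (length(mb)) max(vapply(mb, `[[`, 0, "bias")) else 0L
  mature_biased_bulges <- sum(vapply(mb, function(b) b$bias > 0, logical(1)))

  list(valid = TRUE, stem_pairs = nrow(S), hairpin_len = unname(hairpin_len),
       loop_len = unname(loop_len), loop_span = unname(loop_span),
       largest_bulge = largest_bulge, mature_bulge_max = mature_bulge_max,
       mature_bulge_bias_max = mature_bulge_bias_max,
       mature_biased_bulges = mature_biased_bulges,
       mature_errors = mature_errors, mature_pairs = mature_pairs,
       mature_in_stem_pct = mature_in_stem_pct, energy = h$energy,
       mature_span = c(m1, m2))
}

#' Default thresholds of the eleven-criterion hairpin filter
#'
#' All comparisons are inclusive. The criteria are: (1) nucleotides in one
#' stem bulge <= 12; (2) stem base pairs >= 16; (3) free energy <= -15
#' kcal/mol; (4) hairpin length (up and down stem plus terminal loop) >= 50;
#' (5) terminal loop length <= 20; (6) nucleotides in one mature-region
#' bulge <= 4; (7) biased errors in one mature-region bulge <= 2; (8) biased
#' bulges in the mature region <= 2; (9) errors in the mature region <= 4;
#' (10) base pairs in the mature region >= 12; (11) percentage of the mature
#' region lying in the stem >= 80.
#'
#' @return Named list of the eleven thresholds.
#' @export
criteria_thresholds <- function() {
  list(c1_max_bulge = 12, c2_min_stem_pairs = 16, c3_max_energy = -15,
       c4_min_hairpin_len = 50, c5_max_loop_len = 20, c6_max_mature_bulge = 4,
       c7_max_mature_bulge_bias = 2, c8_max_mature_biased_bulges = 2,
       c9_max_mature_errors = 4, c10_min_mature_pairs = 12,
       c11_min_mature_in_stem_pct = 80)
}

#' Evaluate the eleven hairpin criteria on measured features
#'
#' @param features Feature list from [structure_features()].
#' @param thresholds Threshold list as produced by [criteria_thresholds()];
#'   individual entries may be relaxed or tightened.
#' @return A data frame with one row per criterion (`criterion`, `measured`,
#'   `threshold`, `pass`) and an attribute `overall` equal to the conjunction
#'   of the eleven flags. A structure with no hairpin loop fails all flags.
#' @export
evaluate_criteria <- function(features, thresholds = criteria_thresholds()) {
  th <- utils::modifyList(criteria_thresholds(), as.list(thresholds))
  f <- features
  measured <- c(f$largest_bulge, f$stem_pairs, f$energy, f$hairpin_len,
                f$loop_len, f$mature_bulge_max, f$mature_bulge_bias_max,
                f$mature_biased_bulges, f$mature_errors, f$mature_pairs,
                f$mature_in_stem_pct)
  lims <- c(th$c1_max_bulge, th$c2_min_stem_pairs, th$c3_max_energy,
            th$c4_min_hairpin_len, th$c5_max_loop_len, th$c6_max_mature_bulge,
            th$c7_max_mature_bulge_bias, th$c8_max_mature_biased_bulges,
            th$c9_max_mature_errors, th$c10_min_mature_pairs,
            th$c11_min_mature_in_stem_pct)
  dir <- c("<=", ">=", "<=", ">=", "<=", "<=", "<=", "<=", "<=", ">=", ">=")
  if (isTRUE(f$valid)) {
    pass <- ifelse(dir == "<=", measured <= lims, measured >= lims)
    pass[is.na(pass)] <- FALSE
  } else {
    pass <- rep(FALSE, 11)
  }
  out <- data.frame(criterion = paste0("c", 1:11), measured = as.numeric(measured),
                    threshold = lims, direction = dir, pass = pass,
                    stringsAsFactors = FALSE)
  attr(out, "overall") <- all(pass)
  out
}

#' @rdname evaluate_criteria
#' @param report A criteria report from [evaluate_criteria()].
#' @export
criteria_pass <- function(report) isTRUE(attr(report, "overall"))
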