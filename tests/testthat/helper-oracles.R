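# Independent oracles used by the tests. Deliberately naive implementations
# that share no code with the package internals.

# All non-crossing pairings of positions i..j (1-based) with a minimum
# hairpin loop of `min_loop` unpaired bases, as lists of 2-column matrices.
enumerate_pairings <- function(n, min_loop = 3) {
  rec <- function(i, j) {
    if (j - i < min_loop + 1) {
      return(list(matrix(integer(0), ncol = 2)))
    }
    out <- lapply(rec(i + 1, j), identity) # i unpaired
    for (k in (i + min_loop + 1):j) {
      inner <- rec(i + 1, k - 1)
      outer <- rec(k + 1, j)
      for (a in inner) for (b in outer) {
        out[[length(out) + 1]] <- rbind(c(i, k), a, b)
      }
    }
    out
  }
  rec(1, n)
}

# Score a pairing the way the bundled folder defines it: GC 3, AU 2, GU 1,
# +1 for each stacked pair; incompatible base pairs score -Inf.
score_pairing <- function(seq, pairs) {
  if (nrow(pairs) == 0) return(0)
  ch <- strsplit(toupper(gsub("U", "T", seq)), "")[[1]]
  ps <- function(a, b) {
    key <- paste0(sort(c(a, b)), collapse = "")
    switch(key, "CG" = 3, "AT" = 2, "GT" = 1, -Inf)
  }
  total <- sum(apply(pairs, 1, function(p) ps(ch[p[1]], ch[p[2]])))
  key <- paste(pairs[, 1], pairs[, 2])
  stacks <- sum(paste(pairs[, 1] + 1, pairs[, 2] - 1) %in% key)
  total + stacks
}

# Brute-force optimum over all pairings.
brute_force_fold_score <- function(seq, min_loop = 3) {
  max(vapply(enumerate_pairings(nchar(seq), min_loop),
             function(p) score_pairing(seq, p), numeric(1)))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
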