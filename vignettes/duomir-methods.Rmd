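---
title: "Methods: two-library small RNA-seq miRNA discovery and differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small RNA-seq miRNA discovery and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duomir)
```

## The analysis problem

`duomir` analyses a classic two-condition small RNA sequencing design in
which each condition is a single pooled library (for example, early and
late lactation of a mammary gland, pooled over animals). There are no
replicates: all inference is count-based and per-library. The pipeline
mirrors the stages a vendor small-RNA pipeline performs:

1. **Preprocessing** — junk/low-complexity removal, 3' adapter detection
   (reads with no detectable adapter, "3ADT", are removed), an 18–26 nt
   insert-length filter, and collapse of identical inserts into unique tags
   with per-library counts. Every read lands in exactly one ledger bin, so
   the accounting always sums to the raw total.
2. **Contaminant partitioning** — tags contained (either strand, up to one
   substitution by default) in mRNA, rRNA, tRNA, snoRNA, snRNA, other
   ncRNA, or repeat references are removed, with priority repeat → rRNA →
   tRNA → snoRNA → snRNA → other ncRNA → mRNA when a tag hits several
   databases. The Rfam supercategory is the sum of the five ncRNA classes.
   Percentages are reported against raw totals, rounded half-up to two
   decimals.
3. **Six-group classification** — valid tags are compared to mature and
   precursor miRNA references (species encoded in the miRBase-style id
   prefix) and to the genome. Group 1a: focal-species mature match whose
   precursor maps to the genome; 1b: other-mammal mature match with a
   genome-mapped precursor; 2a: mature match, precursor unmapped, but the
   tag's own genomic flank folds into a qualifying hairpin; 2b: as 2a
   without the hairpin; 3: mature match with nothing on the genome; tags
   matching only the opposite arm of a known precursor are kept as
   arm-derived known miRNAs. Everything else is a Group 4 candidate.
4. **Novel miRNA calling** — each genome locus of an unmatched tag is
   evaluated in three windows (tag at the 5' arm, centered, tag at the 3'
   arm, with 80 nt of flank per side), folded, and passed through the
   eleven-criterion filter below with the tag as the mature span.
5. **Differential expression** — reads-per-million normalization against
   each library's valid-read total, a count-ratio exact test with Fisher
   and chi-square companions, and DE flags at configurable thresholds.
6. **Network export** — miRNA–gene and gene–pathway edge tables (target
   prediction itself is out of scope and consumed as input) become typed
   bipartite/tripartite networks with hub summaries and SIF/GraphML/TSV
   round-trip export.

## Hairpin folding and the eleven criteria

The bundled folder computes the maximum-scoring non-crossing pairing
(Watson–Crick plus GU wobble; minimum hairpin loop 3 nt) by dynamic
programming with a stacking bonus: pair scores 3 (GC), 2 (AU), 1 (GU),
plus 1 per stacked pair, with deterministic traceback (helix continuation
preferred on ties, then leftmost bifurcation). This is a score-maximizing
folder, not a thermodynamic one; externally computed dot-bracket
structures and energies can be supplied verbatim and take precedence.

The free-energy *estimate* attached to de-novo folds is
`-1.6 kcal/mol × (stack count)`, with stacks involving a GU pair at half
weight. It is a linear calibration that places well-formed miRNA hairpins
in a realistic MFE range (a perfect 22-bp stem scores −33.6 kcal/mol); the
energy criterion is only meaningful with this documented estimate or with
supplied energies.

Candidate precursors must pass all eleven criteria (inclusive
comparisons): stem bulge ≤ 12 nt; stem pairs ≥ 16; energy ≤ −15 kcal/mol;
hairpin length (up stem + down stem + terminal loop) ≥ 50; terminal loop
≤ 20; mature-region bulge ≤ 4; biased errors in one mature bulge ≤ 2;
biased mature bulges ≤ 2; mature errors ≤ 4; mature pairs ≥ 12; mature
region ≥ 80% in the stem.

Because the field leaves several of these terms informal, the package
fixes them as: a *bulge* is the pair of unpaired runs between two
consecutive stem pairs, sized by its larger run; a mature *error* is an
unpaired mature nucleotide inside the stem (terminal-loop overlap is
instead captured by the percent-in-stem criterion); a bulge is *biased*
when its two runs differ, with bias equal to the difference; a bulge
belongs to the mature region when either run touches the mature span. The
stem itself is the chain of pairs enclosing the hairpin loop nearest the
mature span and no other loop, which makes the features well defined even
when the optimal pairing of an extended genomic window contains additional
stray helices.

Anchoring matters here: the 5'-arm window starts exactly at the tag and
the 3'-arm window ends exactly at it, so a genuine hairpin on the
appropriate side is evaluated without upstream context that the
score-maximizing folder could otherwise pair around the stem.

## The exact test

For counts `x` and `y` in libraries of sizes `N1` and `N2`, the test uses
the conditional distribution

p(y|x) = (N2/N1)^y (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) ),

computed in log space via `lgamma` with ascending, deterministic
summation. The lower tail is `C = Σ_{k≤y} p(k|x)`, the upper tail
`D = Σ_{k≥y} p(k|x)` (computed as `1 − C(y−1)` with clamping), and the
two-sided p-value is `min(1, 2·min(C, D))`. Useful facts the test suite
pins down: `p(0|0) = 1/2` at equal totals; `p(1|5) = 6!/(5!·1!·2^7) =
0.046875`; the masses sum to one; and the count/total swap obeys
`p(y|x; N1, N2) = (N1/N2)·p(x|y; N2, N1)` — exact symmetry holds exactly
when `N1 = N2`. The distribution conditions on the first library's count,
so the two-sided p-value is not literally library-exchangeable at unequal
totals; this is a property of the test itself, not of the implementation.

DE flags require, jointly: summed raw reads > 10, exact-test p < 0.05 and
|log2 fold change| ≥ 1.5 on normalized values. Reported fold changes use
the low-expression rules: records under 1 RPM in *both* libraries are
removed before testing, and a zero RPM is replaced by 0.01 before the
ratio is formed. The 1.5 threshold is the stricter of the two cutoffs in
circulation for this design (|log2 ratio| ≥ 1 being the other); both are
exposed via `de_thresholds()`. No multiple-testing correction gates the
flags — a Benjamini–Hochberg column is emitted for reference only —
matching how single-library pipelines of this type report DE. The
evidence threshold for classification reads the "more than 3 reads" rule
literally as `count > 3`; `count_gt = FALSE` switches to `≥ 3`.

## What the generator emulates (and what it does not)

`gen_references()` + `simulate_library()` produce a complete study with
known truth:

* a single 100-kb contig with planted 52-nt precursors (22-nt mature arm,
  8-nt loop, reverse-complement 3' arm) at least 500 nt apart on the plus
  strand — minus-strand handling elsewhere is exercised by fixtures;
* 100 known miRNAs by default, half present identically in two species
  (`chi` focal, `bta` other) so Groups 1a and 1b are both populated, and
  10 novel hairpins absent from the mature set;
* two libraries of 200,000 reads: miRNA reads are mature ± a 3' isomiR
  offset of up to 2 nt (probabilities 0.05/0.10/0.70/0.10/0.05), ligated
  to the TruSeq-style 3' adapter and truncated to 50 nt; 10% contaminant
  reads drawn as 18–26-nt windows (peaked at 22 nt) of the category
  references; 5% reads with no adapter; 0.1% junk;
* per-miRNA counts negative-binomial (dispersion 0.1; Poisson at 0)
  around expected counts implied by log-normal abundance weights, with
  20% of known miRNAs differentially expressed at |log2FC| uniform in
  [3, 5], balanced in sign at random.

Three constructive guarantees make truth recovery exact rather than
probabilistic: planted sequences are screened against the adapter seed
(so trimming can never fire inside an insert), mature arms are screened
for low-complexity runs (so the junk filter cannot eat a planted miRNA),
and loops are drawn from the {A, C} alphabet so they cannot pair
internally — every planted precursor therefore folds to its designed stem
and passes all eleven criteria, making the pipeline's recall ceiling 100%
on clean data. Non-miRNA read counts are sized against the *realized*
miRNA pool, so the emitted per-category composition matches the
configured fractions even when the negative-binomial draw moves the
library total.

Deliberate simplifications: no per-cycle error profiles (each read
carries at most one substitution, at rate `read_length × error_rate`), no
5' isomiRs or RNA editing, constant FASTQ quality, a single contig, and
exactly two libraries. Passing tests on this generator demonstrates that
the pipeline's logic is correct under its own assumptions; it does not
certify performance on real libraries, where adapter chemistry, repeat
content and mapping ambiguity are harsher.

## Numerical and design choices

* Accounting percentages round half away from zero at two decimals
  (`round_half_up`), matching how sequencing summary tables are printed.
* Coordinates are 1-based inclusive inside R and 0-based half-open in
  exported loci tables.
* Mature-to-precursor links are explicit (`mature_to_pre` in the bundle)
  rather than inferred from names.
* Tag-to-mature tolerance defaults to ≤ 2 internal substitutions and ≤ 2
  nt of 5'/3' truncation/extension — wide enough for the simulated
  isomiRs and the known-miRNA variant classes this design reports, narrow
  enough that random 22-mers essentially never match.
* Multi-hit ties are broken deterministically: focal species first, then
  fewest mismatches, then lexicographic id. Arm ties (mature centered on
  the loop midpoint) resolve to 5p.
* Tags mapping to more than 5 genomic loci are set aside as repetitive
  during novel calling.
* Batch adapter trimming uses a leftmost-exact-seed fast path with a
  mismatch-tolerant per-read fallback; `trim_adapter3()` documents the
  reference semantics.
* The end-to-end suite runs at 2 × 200k reads with 100 + 10 planted
  miRNAs — large enough for stable percentages and power, small enough to
  run in about two minutes.

## Known limitations

The folder is a score maximizer: its energies are calibrated estimates,
and criterion 3 should be interpreted against them or against supplied
thermodynamic energies. Classification matches by containment and bounded
mismatches, not by spliced or gapped alignment. The exact test treats
each library as one pooled observation; with biological replicates a
count model with replicate variance would be preferred. Family assignment
is name-stem based, with the seed (nt 2–8) check only logged, not
enforced.
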