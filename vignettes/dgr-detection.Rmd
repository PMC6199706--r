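---
title: "Detecting diversity-generating retroelements in phage genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diversity-generating retroelements in phage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgrscan)
```

## The biology being modelled

Diversity-generating retroelements (DGRs) are genetic cassettes that
hypermutate a short window of a target gene. The cassette carries a reverse
transcriptase (RT), an invariant *template repeat* (TR), and a *variable
repeat* (VR) inside the target gene. During mutagenic retrohoming the RT
produces an error-prone cDNA of the TR and that cDNA replaces the VR; the
errors occur essentially only where the TR has an adenine. The diagnostic
signature of a DGR is therefore a pair of near-identical repeats near an RT
gene whose differences sit almost exclusively at adenine positions of one
copy — that copy is the TR, and the diversified copy inside a protein-coding
gene is the VR. The canonical example is the *Bordetella* phage BPP-1
cassette, where a 134 bp VR diversifies the tail-fiber gene; the gut-phage
cassette this package's synthetic validation genome emulates has two
adjacent 117 bp repeats differing at 14 adenine positions, with the VR at
the C terminus of a very large target ORF.

`dgrscan` implements this detection logic plus the downstream analyses
that usually accompany it: prophage-activity classification from virome
read coverage, a lifestyle-confidence rule with a chi-square enrichment
test, cross-variant diversification analysis, fractional-abundance
estimation, and a retrohoming simulator that generates ground-truth data
for all of the above.

## Detection model

Candidate repeat pairs are found by seed-and-extend within a window of
`rt_window` (default 20 kb) on each side of each RT ORF:

1. **Seeding.** All exact shared k-mers (`seed_k = 11`) anchor candidate
   pairs. If no 11-mer pairs up, a second pass runs at k = 7: a 117 bp
   repeat with 14 scattered mismatches must contain a clean stretch of at
   least ⌈(117 − 14)/15⌉ ≈ 7 bp by pigeonhole, so the fallback guarantees a
   seed in the densest plausible cassette even when 11 fails. Seeds whose
   k-mer occurs more than 50 times in the window are skipped as
   low-complexity noise; a genuine two-copy repeat is unaffected.
2. **Extension.** Each seed is extended greedily right, then left, while
   the cumulative mismatch fraction of the growing gapless alignment stays
   at or below `max_mismatch_fraction = 0.25`. After the rightward pass the
   end is trimmed back to a matching column and the mismatch count is
   re-tallied before extending left — otherwise mismatches accumulated
   while coasting into divergent flanking sequence would prevent the left
   end of the repeat from being reached at all.
3. **Trimming.** Both termini are trimmed to matching (non-N) columns.
   Interior mismatches, including ones close to the edges, are kept: DGR
   repeats genuinely carry mismatches within a few bases of their ends.
4. **Filtering.** Pairs shorter than `min_repeat_len = 40` bp, with copies
   overlapping, or separated by more than `max_copy_separation = 5 kb` are
   dropped; duplicate and nested seed products collapse to one maximal
   pair.

The repeat model is gapless: observed TR/VR alignments have no indels, and
an indel-tolerant extension would blur the per-column mismatch bookkeeping
the adenine criteria depend on. A consequence worth knowing: when the
sequence flanking one copy happens to resemble the flank of the other, the
reported boundary can slip by a few bases onto chance matches. Downstream
consumers should treat boundaries as accurate to about ±3 bp; the
adenine-mismatch columns themselves are exact.

### Orientation and strand

For each mismatched column we ask which copy owns the adenine. The copy
with more adenines at mismatch columns is the TR. Because a cassette on the
reverse strand shows the same signal as *thymine* ownership on the forward
strand, both bases are counted and the better of the two determines the
cassette strand; scoring then happens on the cassette's own strand. Ties
are broken by CDS evidence (the copy inside an annotated ORF is the VR,
since the diversified copy sits in its target gene); if that is also
uninformative the first copy is declared TR and an ambiguity flag is set —
the package never silently guesses.

### Calling thresholds

A pair becomes a cassette when the TR carries at least `A_min = 10`
adenines and at least `S_min = 7` mismatch columns are adenines in the TR.
These are the published screen defaults. The screen's own description uses
"minimum 7" while a results summary elsewhere says "> 7"; we adopt ≥ 7 (the
stated tool setting) and expose `S_min` so either convention is one flag
away. Cassettes are ranked by proximity to their RT (rank 1 = closest), and
a pair reachable from several RT windows is reported once, under the
closest RT.

### Adenine-bias p-value

`adenine_bias()` reports a one-sided binomial tail
P(X ≥ a | n = total mismatches, p = f_A), where f_A is the adenine fraction
of the TR itself. Using the TR's own composition as the null makes the
number comparable across cassettes with different base content. It is
purely descriptive — one cassette per report row, no multiplicity
correction applies.

## Coverage and activity

`coverage_from_sam()` re-implements per-base depth from SAM text: depth is
added over reference-consuming `M/=/X` columns, deletions advance the
reference without depth, and unmapped/secondary/supplementary records are
ignored. Identity is `(aligned_cols − NM)/aligned_cols` — reproducible from
the SAM alone, unlike gap-compressed variants. The activity rule is strict:
a region is `active` only when mean fold coverage exceeds the threshold
(default 10); exactly 10.0× is `inactive`. Reads are counted wherever they
align, with no deduplication — read dereplication belongs to upstream QC.

`naive_map()` is test plumbing, not a production mapper: a read is placed
only where its first 31-mer matches the reference exactly and uniquely
(either strand), which is enough to close the simulate–map–cover loop on
clean simulated data and keeps the package free of an aligner dependency.

## Lifestyle statistics

A lifestyle call is confident when the mean replicate score minus its
standard deviation clears 0.5, applied symmetrically to both lifestyles; a
margin of exactly 0.5 is not confident. The standard deviation is the
sample (n−1) form by default — the convention is not fixed by the original
description, so a population-sd option exists. The enrichment test is a
plain Pearson goodness-of-fit of observed class counts against background
proportions with df = classes − 1 and no continuity correction; the exact
inputs behind published enrichment P-values are typically not recoverable,
so the test is exposed as a calculator rather than tied to any constant.

## Diversification analysis

Variant sets are compared gaplessly, column by column; a length mismatch is
an error rather than a silent alignment, which removes an external MSA
dependency without changing results for equal-length repeats. Variable
positions are counted at the nucleotide level, and the explorable sequence
space is reported as exactly 4^n. Past n = 26 that exceeds double
precision, so the package computes it in base-10 bignum arithmetic and
returns a digit string (`pow4_exact()`); for the documented 21-position VR
this is 4,398,046,511,104 ≈ 4.4 × 10^12, consistent with the
order-of-magnitude claim of ~10^12 variants.

## Abundance

Fractional abundance is recruited primary alignments (identity-filtered at
97% by default) divided by total reads — the simplest defensible
definition, with an optional per-kilobase normalization for comparisons
across references of different length. The global virion calculator is a
deliberate three-factor product (prevalence × virions per carrier ×
population) with all inputs exposed, because no fixed parameterization of
that back-of-envelope estimate is authoritative.

## The simulator and what it does (not) show

`plant_cassette()` builds a random genome with an RT ORF (carrying the
catalytic YxDD motif), an invariant TR, and a VR embedded in frame near the
3′ end of a synthetic target ORF. Defaults mirror the observed gut-phage
anatomy: a 117 bp TR with 30 adenines and exactly 14 adenine substitutions
in the VR. Two layouts are available (`rt_first`, `target_first`); the
latter keeps TR and VR adjacent when the VR sits deep inside a very long
ORF. Design points:

* **Substitutions draw from the three non-identical bases**, so
  `mutation_prob` equals the realized per-adenine mismatch probability and
  tests can use exact binomial expectations. Real retrohoming also permits
  silent A→A incorporation; that distinction does not affect any statistic
  computed here.
* **Clean flanks.** The single-copy flanking context of each repeat is
  rewritten to diverge columnwise from the other copy's context for 45 bp —
  more than the ⌊(0.25·117)/0.75⌋ + 1 columns the extension rule could ever
  coast — so planted boundaries are exactly recoverable and recovery tests
  can assert equality rather than tolerance.
* **Rejection sampling** guarantees no in-frame stops in the planted ORFs
  and no accidental ≥ 40 bp duplication outside the planted pair.
* **Reproducibility.** Every output is a pure function of the parameters
  including the seed; the RNG state of the caller is saved and restored.

`synth_reads()` draws uniform reads at a chosen fold coverage with
independent substitution errors and constant qualities. Real viromes have
coverage biases, indels, quality gradients and duplicated reads; passing
tests on simulated data therefore demonstrates the *bookkeeping* (depth
conservation, identity filtering, threshold boundaries), not robustness to
real sequencing artifacts.

The synthetic validation genomes (`synthetic_hankyphage()`,
`synthetic_bpp1()`) are deterministic stand-ins built to the published
anatomy of the two best-described cassettes (42,831 bp / 45 CDS with a
117 bp, 14-adenine-mismatch cassette targeting residues 2188–2226 of a
large ORF; a 134 bp VR in a tail-fiber gene). They let the full pipeline be
validated offline and bit-reproducibly; they are labelled synthetic
everywhere and are not the real sequences.

## Numerical and testing choices

* Internal coordinates are 0-based half-open; all human-facing output is
  1-based inclusive. The conversion is a bijection and is property-tested.
* Columns containing N never count as matches, mismatches or adenines.
* The binomial and chi-square tails come from `stats::pbinom`/`pchisq`;
  the test suite checks them against an exact Pascal-triangle enumeration
  and an independent series/continued-fraction incomplete-gamma
  implementation to 10^-10.
* Test problem sizes are deliberately modest — 3 kb planted genomes for the
  100-seed recovery sweeps, 2–2.5 kb regions for coverage round-trips,
  10^4 replicates for retrohoming moments — chosen so the whole suite runs
  in well under a minute while every assertion stays exact or within
  pre-stated Monte-Carlo bounds.

## Known limitations

* Inverted-repeat DGRs and multi-VR cascades are not modelled (direct
  repeats only; additional pairs appear as rank ≥ 2, not as cascades).
* No indel tolerance between TR and VR.
* Repeat boundaries can slip onto chance flank matches by a few bases (see
  above); adenine-mismatch columns are exact.
* The HMM search for RT domains is consumed (domtblout) rather than run;
  the built-in motif fallback (`[YFLIVM].DD`, ≥ 200 aa) is a coarse filter
  that will miss divergent RTs and pass occasional false anchors — harmless
  for cassette calling, since anchors without repeat pairs produce nothing.
* SAM text only (the declared subset); BAM belongs to external tooling.
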