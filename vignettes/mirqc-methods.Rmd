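---
title: "Methods: read-pattern confidence classification and literature mining"
author: "mirqc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-pattern confidence classification and literature mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirqc)
```

# Scope and model

mirqc assesses microRNA hairpin annotations against the read-mapping
signature left by canonical Drosha/Dicer processing, and mines article
text for microRNA functional information. This vignette records the
model, the tunable parameters, the design decisions taken where the
published rules leave room, and the limits of what the test suite
demonstrates.

## The processing signature

Drosha cleaves the primary transcript at the hairpin base and Dicer at
the loop side, excising a ~22-nt duplex whose two strands become the
5p and 3p mature microRNAs. Both enzymes are RNase III family and leave
2-nt 3′ overhangs, and 5′-end selection is precise because the seed is
anchored there. In deep small-RNA data a genuine locus therefore shows
reads on both arms, duplex geometry with short 3′ overhangs, and
strongly modal 5′ read starts on each arm.

A locus is **high confidence** when all of the following hold
(`qc_params()` defaults, each a parameter):

| rule | default | parameter |
|---|---|---|
| mature annotations on both arms | — | — |
| duplex 3′ overhangs within window, both ends | [0, 4] nt | `min_overhang`, `max_overhang`, `overhang_mode` |
| assigned reads per arm | ≥ 20 | `min_reads` |
| modal 5′ fraction per arm | ≥ 0.50 | `min_frac` |

and **low confidence** when both of:

| rule | default | parameter |
|---|---|---|
| total mapped reads | > 100 (strict) | `low_min_reads` |
| dominant-arm modal 5′ fraction | < 0.30 (strict) | `low_max_frac` |

High precedes low; everything else is *undetermined*. The asymmetry is
deliberate: lack of data must not condemn an annotation, so the low
flag requires abundant reads that actively contradict precise
processing. Inclusive versus strict comparisons follow the printed
rules exactly (≥ 20, ≥ 50%, > 100, < 30%, overhang inclusive [0, 4]),
and the boundary behaviour is pinned by sweep tests (pass at 20 reads
and 50%, fail at 19 and 49.9%; flagged at 101 reads and 29.9%, not at
100 or 30.0%).

## Duplex overhang geometry

With a pair table `pt` over the hairpin and matures `5p = [s5, e5]`,
`3p = [s3, e3]` (1-based inclusive), the Drosha-end overhang is
`(e3 − pt[i]) − (i − s5)` where `i` is the first paired position at or
after `s5` within a `scan_window` (default 5 nt); the Dicer-end
overhang is the mirror image anchored at `s3`. The `(i − s5)`
compensation makes the measure exact whenever the duplex is locally
helical around the anchor, so a mature whose terminal bases are
unpaired is still measured correctly. If no paired base exists within
the window the end is *undefined*, and an undefined end fails the
criterion: high confidence should not rest on unmeasurable geometry.
Negative (recessed) overhangs fail the [0, 4] window, 0 being the
printed lower bound.

The overhang rule is enforced at **both** duplex ends by default
(`overhang_mode = "both"`), since Drosha and Dicer each leave one; the
published wording does not specify an end, so `"either"` is available
for the laxer reading.

## Read-to-arm assignment and 5′ homogeneity

The published depth rule counts "overlapping reads" without defining
overlap. mirqc assigns a read to the arm whose mature interval,
extended by `arm_extension = 2` nt on each side, covers at least
`min_read_overlap = 50%` of the read's length; of two qualifying arms
the larger overlap wins and exact ties are unassigned. The 2-nt
extension tolerates templated 3′ trimming/tailing isomiRs while the
50% rule excludes loop-spanning fragments.

5′ homogeneity compares reads to each other, not to the annotation:
the statistic is the fraction of an arm's reads sharing the *modal*
observed 5′ start. This lets the measure critique a mis-annotated
mature whose reads are perfectly processed at a shifted position. Ties
on the mode do not change the fraction (the smallest position is
reported as the mode). Counts are weighted by collapse counts, not
distinct sequences, because the criteria are depth thresholds; reads
pooled across datasets are treated as one population.

## The synthetic-locus generator

`make_locus()` builds a perfect-stem hairpin — 3p stem arm the reverse
complement of the 5p arm, analytically written pair table, unpaired
loop (default 8 nt) and unpaired 10-nt flanks mirroring precursor
context — with matures placed to realise requested overhangs exactly
(the construction inverts the measurement formulas, which is what makes
the requested == measured round-trip a meaningful property test).
`simulate_reads()` draws, per arm, `depth` reads whose 5′ start is
canonical with probability `homogeneity` and otherwise uniformly
shifted within ±`shift_range` (never 0), with 3′ length jitter within
±`trim_range`; reads are exact hairpin substrings and the stack is
reproducible from `seed`. Defaults (24-nt arms, 1000 reads per arm,
homogeneity 0.9, shifts ≤ 3 nt, jitter ≤ 2 nt, 2-nt overhangs)
describe a well-covered, well-processed mammalian-style locus —
dominant-isomiR fractions near 0.9 and a few-nt isomiR spread are
typical of abundant microRNAs in real data.

The uniform non-zero shift is the simplest null that exercises the
homogeneity statistic; the published material gives no empirical
5′-error model. The generator deliberately does **not** emulate
sequencing error, non-templated tailing, cross-mapping between
paralogous hairpins, imperfect stems with bulges, or realistic
expression distributions across loci. Passing tests therefore show
that the classifier implements its rules exactly and behaves correctly
at every decision boundary; they do not show robustness to alignment
artefacts or folding errors in real data, where structure quality and
mapping policy dominate.

## Mining pipeline decisions

*Sentence splitting.* A deterministic rule-based splitter: boundaries
at `.`/`!`/`?` followed by whitespace and a capital/digit/opening
bracket, with protected abbreviation and initial handling; decimals
survive because the next character is a digit. The splitter is a
pluggable contract — any `text -> character vector` function can stand
in.

*Name recognition.* Case-insensitive patterns for
`miR/mir/miRNA/microRNA` + separator + number with optional letter,
paralogue and `-5p/-3p` suffixes, matched leftmost-longest, plus an
exceptional-name lexicon (`let-7[a-z]?`, `lin-4`, `bantam`, `lsy-6`,
`iab-4`, `iab-8`; configurable, since any fixed list of exceptions is
best-effort). Unicode hyphen variants and space separators are
normalised before matching; names normalise to a canonical lower-case
`mir-` form with the arm suffix split off, so `MicroRNA-21`,
`miRNA-21` and `miR-21` are one name.

*Table filtering.* A sentence is eliminated iff it has > 25 distinct
normalised names or > 200 whitespace words. The name count is taken
*before* family expansion — the filter targets typography (tables and
reference lists), so it should see what was literally written. Words
are whitespace tokens; no published definition exists.

*Species assignment.* If a sentence names a subset of the article's
species, only those are assigned; if it names none, all article
species are (the mention cannot be attributed). A sentence naming only
species absent from the article's list also receives all article
species: foreign names alone do not veto when no listed species is
named. Where a sentence names both listed and unlisted species, the
listed ones win — this precedence is an interpretation, flagged here.

*Family expansion.* Exact gene name → that gene; lettered group
(`let-7a`) → all `let-7a-N`; bare family key → all members for the
species. The packaged family table (`families_synthetic.tsv`) follows
real family structure — including the 11 human let-7 genes — but its
accessions are synthetic placeholders.

*Scoring.* `score = positive-stem hits − negative-stem hits`, each
token hit counting once per lexicon, so scores add over concatenation.
Stems match at word-prefix boundaries. The shipped lexicons contain
the canonical positives (expression, target, regulate, inhibit) and
curated extensions, and a negative list of measurement/procedure terms;
both are plain-text configuration intended to be refined.

*Term frequencies.* Tokens are lower-case alphanumeric-plus-hyphen
runs; tokens under 3 characters, without letters, or on the English
(snowball) or curated scientific stop lists are dropped. Tokenisation
is this package's choice; the rendered image is optional and untested
— the frequency table is the contract, since images are not
assertable.

## Numerical and degenerate-input choices

Coordinates are 1-based inclusive everywhere (R/IRanges idiom and the
community file convention), so no off-by-one translation exists
between memory and disk. Zero-read arms give an undefined (`NA`) modal
fraction that fails the homogeneity criterion and, on the dominant
arm, blocks the low flag. Duplicate collapsed rows are summed;
entry order never affects a profile; rejected alignment rows
(sequence mismatch, unknown hairpin, non-positive count, reverse
strand) are tallied per reason rather than silently dropped. The
modal-start tie-break (smallest position) only affects reporting,
never the fraction. Seeded RNG state is restored after simulation, so
library calls do not perturb a caller's random stream.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated
data: boundary sweeps use one fixture locus with exact histograms
(up to 1000 reads per arm, 40–101 sweep points per threshold),
property suites use the 0..6 overhang grid plus 100 seeded loci and
depth-1000/2000 recovery runs, and the mining checks use the bundled
three-article corpus and the printed-name list. The whole suite
completes in well under a minute on one CPU; sizes were chosen as the
smallest that make the binomial 99% recovery bounds and the boundary
sweeps meaningful.

## Known limitations

The classifier consumes provided structures; a wrong fold silently
yields wrong geometry (the optional Nussinov-style folder is for
fixtures only and maximises pairing, not free energy). Exact-match
read validation rejects mismatched alignments rather than re-aligning.
Multi-mapping across hairpins is taken per-hairpin as given, with no
cross-locus reassignment. The mining pipeline does not resolve
ambiguous gene symbols outside the microRNA nomenclature, relies on
the caller for article–species associations, and its keyword scoring
is a transparent count, not a trained model.
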