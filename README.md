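# mirqc

Read-pattern confidence classification and literature mining for
microRNA annotations.

## The problem

Most microRNAs are discovered by small RNA deep sequencing, and the
stringency of annotation varies widely between submitting groups, so
genuine microRNAs sit in public catalogues next to mis-annotated
fragments of other RNA species. Canonical biogenesis leaves a
distinctive fingerprint in sequencing data that can be checked *post
hoc*: Drosha and Dicer excise a ~22-nt duplex from the hairpin
precursor, so reads should stack on **both arms**, the two mature
products should form a duplex with short **3′ overhangs**, and the
**5′ ends** of the reads on each arm should be nearly invariant,
because target recognition depends on the seed sequence anchored at the
5′ end.

mirqc implements this check for annotation curators and small-RNA
analysts, together with a text-mining pipeline that recovers functional
information about microRNAs from the literature.

## The classifiers

A hairpin with mature annotations, a secondary structure and a stack of
collapsed read alignments is called **high confidence** iff all of:

1. mature microRNAs are annotated on both arms of the hairpin;
2. the mature duplex exhibits a 3′ overhang of 0–4 nt (both the
   Drosha-side and Dicer-side ends, by default);
3. each mature microRNA has ≥ 20 overlapping reads;
4. ≥ 50% of the reads on each arm share the same (modal) 5′ end.

A deeply covered locus whose read pattern *contradicts* precise
processing is flagged **low confidence** iff both of:

1. more than 100 reads map across the hairpin locus (strict);
2. < 30% of reads on the more abundant arm share the same 5′ end
   (strict).

Everything else — typically loci that simply lack data — is
**undetermined**: absence of reads is never taken as evidence against
an annotation. The overhang at the hairpin-base (Drosha) end is
measured as `end3′(3p) − partner(start(5p))` on the pair table, and
symmetrically at the loop (Dicer) end; unpaired mature termini are
compensated within a 5-nt scan window, and ends with no paired base in
the window are conservatively treated as failing.

All thresholds are parameters (`qc_params()`) with the defaults above.

## The mining pipeline

`mine_corpus()` takes full-text articles (abstract, introduction,
results, discussion as labelled plain text), splits them into
sentences, recognises microRNA gene names (`miR-#`, `miRNA-#`,
`microRNA-#` styles plus exceptional names such as `let-7`, `lin-4`
and `bantam`), eliminates table-like sentences (> 25 distinct names or
> 200 words), assigns sentences to species (a sentence naming a subset
of the article's species is assigned only to those), expands
family-level mentions to all member genes (`let-7` in a human paper
reaches all 11 human let-7 genes), and scores sentences by functional
keyword content (positive stems such as `target`/`regulat`/`inhibit`
minus negative, procedure-related stems such as `measur`/`qpcr`).
Articles are ranked per gene by summed sentence score, and
`term_frequencies()` turns a gene's sentences into stop-word-filtered
word-cloud counts (shown only for genes with ≥ 10 sentences).

## Worked example

Simulate a canonically processed locus and classify it:

```r
library(mirqc)
params <- sim_preset("high", seed = 42)
locus  <- make_locus(params)
stack  <- simulate_reads(locus, params)
classify(locus$hairpin, locus$annotations, locus$structure, stack)
#> <confidence_report> SYN-syn-mir-1: high
#>   criteria: both_arms_annotated=T overhang_ok=T depth_ok_5p=T depth_ok_3p=T
#>             homogeneity_ok_5p=T homogeneity_ok_3p=T
#>             low_total_reads_gt_threshold=T low_homogeneity_lt_threshold=F
#>   depth 5p/3p: 1000/1000; modal fraction 5p/3p: 0.89/0.89; overhangs: 2/2; total 2000
```

1000 reads per arm (well over the 20-read minimum), 89% of them
sharing the modal 5′ start (over the 50% minimum), and a 2-nt 3′
overhang at both duplex ends (inside the 0–4 window) make the locus
high confidence. The same objects work from the shell:
`mirqc simulate --preset high --seed 42 --out-prefix sim` then
`mirqc confidence --hairpins sim.fa --structures sim.str --matures
sim.mature.tsv --alignments sim.aln.tsv --out report.tsv`.

Mine the bundled example corpus and summarise mir-21:

```r
corpus <- read_corpus_jsonl(system.file("extdata", "corpus_example.jsonl",
                                        package = "mirqc"))
lex <- read_species_lexicon(system.file("extdata", "species_lexicon.tsv",
                                        package = "mirqc"))
fam <- read_family_table(system.file("extdata", "families_synthetic.tsv",
                                     package = "mirqc"))
res <- mine_corpus(corpus, lex, fam)
res$ranking[res$ranking$gene_accession == "SYNMI00012", ]
#>    gene_accession article_id total_score n_sentences
#> 12     SYNMI00012     900001           7           3
term_frequencies(res$sentences$text[res$sentences$gene_accession ==
                                      "SYNMI00012"])
#> <term_frequency_table> (unnamed): 14 terms from 3 sentences
#>   mir-21: 2
#>   proliferation: 2
#>   apoptosis: 1
#>   ...
```

Three sentences mention mir-21 in article 900001; their summed
functional score is 7 (hits such as *governs*, *targets*, *regulates*,
*inhibited*, minus procedure words like *measured* and *normalized*),
and the surviving word-cloud terms are the functional vocabulary —
*proliferation*, *apoptosis* — rather than boilerplate.

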