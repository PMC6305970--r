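---
title: "Harmonizing genome annotations against a gold standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing genome annotations against a gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txharmonize)
```

## The problem

Genome annotations within a phylogeny are uneven: one heavily curated
species (for *Drosophila*, the *D. melanogaster* reference) coexists with
relatives whose gene models were derived largely from conserved ORFs and
therefore lack UTRs, isoforms and noncoding genes. Deep stranded RNA-seq
across sexed adult tissues makes it possible to rebuild those annotations
de novo — but transcript assemblers are noisy, and their output depends
strongly on tuning. `txharmonize` implements the harmonization strategy of
tuning everything on the gold-standard species and lifting the tuned
settings over to its relatives: evaluate an annotation against read
evidence, tune an assembler by grid search against the gold standard,
filter assembled gene models with an SVM trained on that standard, merge
survivors into the reference annotation, rediscover 1:1 orthologs with a
two-stage SVM, and validate the result against full-length cDNAs.

All coordinates inside the package are Bioconductor-native `GRanges`
(1-based, closed). GTF/GFF3 files therefore need no coordinate conversion
on input or output; interval arithmetic is delegated to
`IRanges`/`GenomicRanges` throughout, which removes the usual off-by-one
hazards by construction.

## The similarity objective

Every optimization and labeling step rests on one statistic: the Jaccard
index over genomic bases,

$$ J(A, B) = \frac{|A \cap B|}{|A \cup B|}, $$

computed on the *unique exon* base sets of two annotations
(`exon_jaccard()`), on two transcripts' exonic blocks
(`transcript_jaccard()`), or on arbitrary interval sets
(`jaccard_bases()`). Duplicate exon coordinates across isoforms collapse
before the union, so the statistic measures the annotated exonic
footprint, not isoform redundancy. Jaccard is computed stranded by default
because the supported library protocol is stranded; an unstranded mode
reproduces the BEDTools default for cross-checks. Maximizing $J$ against
the gold standard simultaneously rewards covered reference bases and
penalizes assembler-only bases — which is what makes it usable as a single
tuning objective.

```{r jaccard}
a <- GenomicRanges::GRanges("2L:1-100:+")
b <- GenomicRanges::GRanges("2L:51-150:+")
jaccard_bases(a, b)
```

## Annotation evaluation

Two complementary completeness metrics
(`unannotated_read_fraction()`, `unannotated_region_fraction()`): the
fraction of uniquely mapped reads touching no annotated gene region, and
the fraction of unannotated genomic bases covered by at least one read.
The first is sensitive to a few highly expressed unannotated loci; the
second is not, which is why both are reported. "Annotated region"
defaults to the transcript span (introns included), so pre-mRNA reads do
not masquerade as novel transcription; an exon-only mode is available. A
spliced read counts as annotated if *any* block overlaps *any* gene
region by one base — conservative with respect to calling novel
transcription.

## Multi-level comparison

`compare_annotations()` reports sensitivity and precision at six levels
(base, exon, intron, intron chain, transcript, gene). Exact coordinate
identity defines matches at the exon/intron/chain levels; a multi-exon
transcript matches when its full ordered intron chain is identical to a
reference transcript's. Mono-exonic transcripts have no chain, so they
match by exonic Jaccard at a threshold of 0.6 — the same cutoff used to
label gene models for the filter — rather than emulating any external
tool's internal mono-exon rule; matching is greedy one-to-one by
descending Jaccard so that TP counts are well defined. Genes match when
they share at least one matched transcript.

## Assembler tuning

`run_sweep()` evaluates a `parameter_grid()` exhaustively, scoring each
combination by exon-level Jaccard of the assembler output against the
gold standard; `refine_grid()` then brackets the incumbent at finer
spacing and `run_refinement_schedule()` iterates the process. Two details
matter:

* The incumbent combination is always a point of the refined grid (it is
  the bracket center) and objectives are memoized across rounds, so the
  best objective is non-decreasing by construction — an optimum lying
  between coarse grid points (as happens in practice) is caught by the
  next round without ever regressing.
* A failed combination is recorded as `NA` and the sweep continues; only
  an entirely failed sweep is an error.

The real assembler is reached through a one-argument contract
(`(reads, params) -> AnnotationSet`); `stringtie_assembler()` shows the
subprocess template for an external binary, and all tests run against
`make_synthetic_assembler()`, which plants a known optimum (see below).
The published protocol fixes the minimum transcript length at 30 bp (the
shortest gene in the gold-standard annotation) and stranded mode; those
are fixed settings of the adapter, not sweep parameters. Merging
sample-level assemblies into a species-level annotation is itself tuned
(`optimize_merge_params()`) over the merge thresholds F (minimum FPKM),
T (minimum TPM) and g (merge gap).

## Gene-model filtering and merging

Assembler output at the tuned optimum still contains spurious short
mono-exonic models. `label_training_set()` marks a predicted gene positive
iff its best-match reference gene exceeds Jaccard 0.6 (strictly);
`extract_features()` builds the 8-feature representation — isoform
number, mean unique-exon length, exon GC, mean unique-intron length,
intron GC, counts of canonical GT-AG and non-canonical introns (donor and
acceptor dinucleotides read on the coding strand), and the median
normalized expression in the 14 sexed tissues (terminalia excluded).
`train_filter()` then grid-searches an SVM (kernels rbf/sigmoid/linear,
C and $\gamma$ over $10^{-3}..10^3$; the rbf incumbent C = 10,
$\gamma$ = 0.1 is always a grid point) by stratified 5-fold
cross-validated ROC AUC.

Three design choices here were genuinely open and are package decisions:
per-gene scalar features are *means* over the unique exon/intron sets
(median and total are selectable); expression features are
$\log(x + 1)$-transformed and all features z-standardized with training
statistics, which rbf kernels effectively require; and cross-validation
is stratified 5-fold with a caller-supplied seed.

`merge_with_reference()` keeps every reference gene model. A filtered
transcript whose intron chain equals a reference transcript's (same
strand) is unified with it by exon base-union — extending terminal exons,
i.e. recovering UTRs, while preserving every junction. Mono-exonic
transcripts merge only when they overlap on the same strand: an empty
intron chain alone is deliberately *not* treated as "the same structure
for all introns", since that reading would merge all mono-exonic genes
genome-wide. Unmatched transcripts enter as novel, and gene membership is
recomputed as connected components of same-strand exonic overlap, which
is what lets a junction-bridging novel transcript merge two legacy genes
and lets isolated novel transcripts found new genes. The operation is
idempotent and never loses a reference intron chain. Final annotations
can be re-identified with the harmonized `YOgn<CODE>NNNNN` /
`YOtr<CODE>NNNNN` scheme (`assign_yo_ids()`), numbered deterministically
in (contig, start) order.

## Ortholog discovery

`find_orthologs()` searches for 1:1 orthologs missed by protein-level
reciprocal-best-hit (RBH) tables — noncoding genes in particular — in two
SVM stages, trained on the known 1:1 set against seeded random gene
pairs:

1. **Structure and expression** (rbf, C = 1000, $\gamma$ = 0.001):
   synteny, tissue-expression Spearman correlation over the 14 sexed
   tissues, and the intron ratio
   $(\mathrm{introns}_{query} + 1) / (\mathrm{introns}_{ref} + 1)$.
2. **Sequence** (rbf, C = 1000, $\gamma$ = 0.01): global alignment of the
   two longest transcripts (match +1, mismatch −1, gap open −2, gap
   extend −0.5) summarized as alignable/total and identical/alignable
   column fractions.

The synteny feature summarizes the ±10-gene window as the fraction of the
query's up-to-20 flanking genes whose RBH partner falls within ±10 ranks
of the candidate reference gene; flanks without a partner stay in the
denominator. This scalar form, the alignment-ratio denominators (total =
alignment columns including gaps), and the blocking of the candidate
universe (pairs linked by an RBH hit or reachable through a flank
partner's neighborhood — an all-vs-all scan is intractable and
pointless) are package decisions where the method description leaves the
scalarization open. Reference genes with several stage-2 survivors are
one-to-many and excluded; the final table is a partial bijection by
construction.

## cDNA validation

Full-length cDNA alignments (BED12) provide isoform-level validation
independent of the short reads that built the annotation.
`cdna_jaccard()` scores each cDNA against its best-matching transcript;
`classify_ends()` buckets termini (within / 5′-extended / 3′-extended /
both / intergenic) against the best-match transcript span — isoform
resolved and strict (slack defaults to 0 bp, configurable);
`classify_junctions()` buckets intron-containing cDNAs as: all junctions
present (the cDNA's chain is a contiguous sub-chain of one transcript),
called junctions annotated (every junction known, but no single
transcript carries the chain), partially unannotated, all unannotated, or
antisense (the junction set matches the opposite strand only — a
reverse-transcription artifact signature). The nested distinction between
the first two categories is a package decision: they are the two natural
readings of "junctions compatible with the annotation", and the chosen
rule makes them mutually exclusive and exhaustive.

## The synthetic-data module

Every input the toolkit consumes can be generated with planted ground
truth (`simulate_genome_and_annotation()`, `perturb_annotation()`,
`simulate_reads()`, `simulate_expression_matrix()`,
`simulate_ortholog_pair_species()`, `simulate_cdnas()`,
`make_synthetic_assembler()`), deterministically per (config, seed); each
generator draws from its own fixed-offset stream so adding one does not
reshuffle another. Defaults describe a compact fly-like genome: 42% GC,
log-normal exons around 300 bp and *short* introns around 80 bp (the
hallmark of dipteran gene structure), 1 + Poisson(3) exons per
transcript, 1 + Poisson(1) isoforms per gene built by exon skipping /
intron retention / alternative 5′ starts, 90% canonical GT-AG junctions,
stranded 76 bp reads, and the 16 sexed-tissue × 4 replicate expression
design with log-normal baselines and multiplicative tissue bias.
Perturbation rates emulate the deficits of legacy annotations (truncated
UTRs, split genes, dropped genes/isoforms, spurious short mono-exonic
calls); the ortholog generator plants a 1:1 bijection with i.i.d.
substitutions, gene-order rearrangement, RBH dropout and a withheld
fraction to rediscover.

The synthetic assembler reconstructs the truth annotation degraded
monotonically in the normalized distance between its parameters and a
planted optimum — dropped transcripts (in a fixed nested order),
truncated terminal exons, spurious fragments. Monotonicity is exact, not
statistical, so sweep-recovery tests are sharp.

What the generators deliberately do **not** model: sequencing error,
coverage gaps within transcripts, alignment artifacts, paralogy and
gene-family turnover, indel evolution, and realistic expression
covariance across tissues. Passing tests therefore demonstrate
correctness of the statistics, classifiers and merge logic under the
stated generative assumptions — not end-to-end performance on real
libraries, which additionally depends on the external mapper and
assembler.

## Numerical choices and problem sizes

Ties in `best_match_table()` break by higher shared-junction count, then
lexicographic id; argmax ties in sweeps break by enumeration order; both
for determinism. Division-by-zero cases are errors (both-empty Jaccard,
zero reads, annotation covering the whole genome) or `NA` (comparison
levels with empty denominators, constant expression vectors in Spearman),
never silent zeros. Strand `"*"` is rejected at parse time: the protocol
this package models is stranded, and an unstranded transcript would
poison every stranded statistic downstream.

The test and acceptance workloads run on toy genomes of 25–50 genes on
one or two 80–100 kb contigs, 10,000–50,000 reads, and 10,000-cDNA
cohorts; these sizes exercise every code path while keeping a full run in
minutes on a laptop. The grid-enumeration checks use the full published
refinement grids (89,100 and 152,460 combinations) since enumeration is
cheap; note that the published *first*-round grid implies
5·5·5·6·5·5 = 18,750 combinations, and `enumerate_grid()` reports that
true product.

## Known limitations

* `compare_annotations()` documents its own matching rules; external
  comparison tools differ in mono-exon handling and locus clustering, so
  absolute percentages are comparable only within this package.
* `merge_with_reference()` recomputes gene membership by overlap closure;
  reference genes that already overlap on the same strand will be fused,
  which is intended for assembler output but can surprise on unusual
  references.
* The internal global aligner is exact but quadratic; for very long
  transcripts an external aligner can be substituted upstream and its
  aligned fractions fed to `train_stage2()` directly.
* The CLI's `sweep` and `orthologs` subcommands demonstrate the
  respective pipelines against the packaged synthetic assembler and
  generators; driving an external assembler or homology table is done
  through the R API.
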