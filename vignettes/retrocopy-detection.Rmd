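---
title: "Detecting retrotransposed genes from exome read pairs: methods"
author: "retroexome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting retrotransposed genes from exome read pairs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroexome)
```

## The evidence model

A retrotransposition event copies a spliced mRNA back into the genome. The
new copy lacks introns, and — crucially for short-read detection — it is
absent from the reference assembly, so every read derived from it aligns to
the exons of its **source gene**. Detection therefore never sees the
insertion site; it sees an excess of read pairs over the source exons whose
geometry is impossible for ordinary genomic fragments.

Consider a sequencing fragment of length $f$ drawn from the retrocopy. Its
two reads map into exons of the source gene, and the reference-coordinate
span of the pair (the *ostensible template length*) is

$$\mathrm{tlen} \;=\; f \;+\; \sum_{i \in \text{introns between the mates}} \ell_i ,$$

because every intron between the mates' exons was spliced out of the
template but is present in the reference. With exome inserts of
$300 \pm 50$ bp and human-scale introns, pairs bridging an exon junction
exceed 1000 bp of span while concordant background pairs essentially never
do (1000 bp is a 14-standard-deviation event for the insert distribution).

A gene is called as a retrocopy candidate in a sample when:

1. pairs pass the filters — **both** mates with MAPQ ≥ `min_mapq` (20) and
   span ≥ `min_tlen` (1000 bp);
2. **both** mates of a contributing pair overlap exons of the gene (all
   retrocopy-derived sequence is exonic, so one mate in an intron is
   evidence against the retrocopy origin of a pair);
3. at least `min_supported_exons` (3) discrete exons each carry at least
   `min_reads_per_exon` (2) read ends from passing pairs;
4. the gene bears introns (≥ 2 exons) — an intronless gene cannot lose
   introns, and its retrocopy would be indistinguishable from segmental
   duplication.

Genes incorporated into the reference as processed pseudogenes are invisible
to this method by design: their reads map to the pseudogene locus, not to
the source exons.

### Interpretation choices behind the thresholds

The threshold phrasing the defaults encode ("more than 1 read per exon",
"spanning more than 2 discrete exons") admits several readings; the package
fixes one and exposes the rest as parameters:

* *Read ends, not pairs, per exon.* An exon counts as supported when ≥ 2
  read ends of passing pairs overlap it. A pair whose mates land in two
  exons contributes one read end to each. Counting pairs instead is one
  parameter change (`min_reads_per_exon`).
* *Aggregate spanning.* "More than 2 discrete exons" is evaluated over the
  gene's supported-exon set, not per pair — a single pair has only two
  reads and cannot individually touch three exons.
* *MAPQ on both mates.* A uniquely mapped read paired with a multi-mapper
  fabricates long spans; requiring both mates ≥ 20 removes that failure
  mode.
* *No orientation filter.* Insertion context can perturb pair orientation,
  and the span filter does the discriminative work, so forward–reverse
  orientation is recorded but not required.
* *Exon union per gene symbol.* Transcript isoforms are collapsed to the
  union of their exons: the method detects retrocopies of genes, and the
  union is the most permissive assignment of a read to "an exon".

### Cohort analyses

Per-sample candidate lists are assembled into a genes × samples logical
matrix (a `SummarizedExperiment` subclass). A gene detected in **every**
sample of a cohort (`recurrence_fraction = 1`) is flagged a *reference
relic*: the parsimonious explanation is an intronless paralog missing from
the reference assembly — the same signal in every individual — rather than
independent somatic events. Relics are kept in the matrix but excluded from
event counting (exclusive-gene counts, per-chromosome counts,
iPSC-minus-parent differences). Chromosome counts are by **source**
chromosome, the only locus observable from source-locus evidence.

Samples are clustered on their boolean profiles with Jaccard distance
(base `dist(method = "binary")`) and average linkage. Nothing downstream
depends on the dendrogram; the presence matrix is the analysed object, and
both distance and linkage are arguments.

The iPSC-minus-parent difference is the designed signal of the study
layout: one retrotransposition happens in one cell, so events in a
fibroblast culture sit at tiny allele fractions and are undetectable in
bulk, while an iPSC line — a single-cell clone — carries its founder cell's
events at full allele fraction. Positive differences are expected; negative
values are allowed and reported.

## Mutational signatures

Somatic single-nucleotide variants are defined by set difference: calls
present in the iPSC VCF and absent (same chromosome, position, alternate)
from the parental VCF. Homozygous iPSC-private calls are retained — a
somatic mutation followed by gene conversion presents as homozygous.
Filters: FILTER must be PASS/`.` (optional), site depth DP in the iPSC
sample ≥ `min_depth` (8, inclusive; depth is site coverage, not the
alternate-allele count — an alternate-count mode would be a one-line
parameterisation), and position outside every structural-mutation region
(deletions, copy-number gains, copy-neutral LOH, supplied as BED), where
genotypes are unreliable.

Each variant is assigned to one of 96 classes: the substitution expressed
on the pyrimidine strand (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the
two flanking reference bases. Purine-reference variants are
reverse-complemented before labeling, which makes the count vector
invariant under reverse-complement rewriting of the input — a property the
tests assert directly. The *dipyrimidine fraction* is the fraction of
classifiable variants whose 5' or 3' neighbor on the pyrimidine strand is
also a pyrimidine — the substrate geometry of UV lesions such as
cyclobutane dimers. The definition uses either flanking neighbor because
the lesion chemistry requires only an adjacent pyrimidine on one side;
under a uniform distribution over the 96 classes its expectation is
$3/4$ (72 of the 96 labels have a pyrimidine flank), which the test suite
confirms by enumeration.

## Read-backed phasing

Two heterozygous variants close enough to be spanned by one fragment are
phased directly from read evidence. Every fragment informative at both loci
is classified: alternate allele at the first locus only, at the second
only, at both, or at neither. The verdict is

* **trans** — ≥ `min_fragments` fragments in each single-alternate class
  and **zero** dual-alternate fragments;
* **cis** — ≥ `min_fragments` dual-alternate fragments and zero
  single-alternate ones;
* **ambiguous** otherwise.

The zero is strict because the compound-heterozygosity conclusion rests on
the *absence* of dual-variant fragments; `min_fragments` (default 3)
guards against calling from one or two chance observations. A deletion
allele is observed when a read's alignment shows a deletion operation
covering the interval; the reference allele when the read aligns across
the whole interval without one; anything else is uninformative. For the
worked coordinate pair shipped in the examples (an SNV at 45,352,351 and a
23-bp deletion at 45,352,505–45,352,527, 1-based inclusive), the package
reports the exact inter-variant distance implied by the coordinates rather
than a rounded figure.

## What the simulator emulates — and what it does not

The generator's defaults are the study conditions the analysis assumes:
101-bp paired-end reads (101-cycle Illumina chemistry), fragment length
$\mathcal{N}(300, 50^2)$ bp, exonic coverage 100×, genes of 2–8 exons with
120–400 bp exons and 1200–3000 bp introns on one synthetic chromosome.
Intron lengths are chosen so that a retrocopy pair bridging adjacent exons
always clears the 1000-bp span threshold while background pairs never
approach it; exon lengths are short enough that exome-scale genes stay
desk-sized. `retrocopy_fraction` models clonality: 1 for an iPSC-like
clone, small values for a heterogeneous parental bulk.

Retrocopy reads are written as mapped to the source locus directly — the
evidence model *is* source-locus mapping, so simulating an aligner adds
nothing testable. A mate crossing an exon junction is truncated to its
largest genomic block with the remainder soft-clipped, mimicking a DNA
read mapper that does not produce spliced alignments. Consequently the
span identity is stated on the **aligned** cDNA interval: `tlen` equals
the aligned span plus the introns strictly between the aligned footprints;
for unclipped pairs the aligned span is the fragment length and the
identity reduces to the displayed equation. The tests verify this per pair
against an independent base-by-base cDNA→genome position map.

Background pairs are contiguous genomic fragments anchored on exons. The
pair count is calibrated by a pilot draw so that `exonic_coverage` means
mean per-base read depth over the exon union (captured fragments spill
into flanking introns, so an uncalibrated count would undershoot).

The variant simulator plants somatic SNVs at reference sites whose
trinucleotide matches a class drawn from a 96-class profile, realized on
either strand with equal probability, plus shared germline variants and
two kinds of decoys (depth below threshold; inside exclusion regions) that
the filters must remove. The default profile is UV-like and chosen on
biological grounds: 60% of mass on C>T classes with a 5' pyrimidine, 25%
on other C>T classes, 15% uniform over C>A and T>C — a C>T-dominated
spectrum of the kind nucleotide-excision-repair-deficient lines accumulate.
Its support spans 48 classes, so zero-mass classes double as exact
negative controls in recovery tests.

Deliberately not modeled: quality-score realism, PCR duplicates, GC bias,
real capture-kit target sets, sequencing error beyond a uniform
substitution rate (applied to phasing reads, whose base calls matter).
Passing tests therefore demonstrate the correctness of the detection
arithmetic and filter logic under the stated geometry, not robustness to
alignment artifacts, mapping ambiguity in paralogous families, or coverage
nonuniformity in real capture data.

## Numerical and convention choices

* All in-memory coordinates are 1-based closed (`GRanges` convention);
  0-based formats (BED) are converted only inside readers/writers, giving
  a single conversion point. SAM/VCF are natively 1-based.
* `tlen` is recomputed from mate reference spans, never trusted from the
  SAM TLEN column.
* Exon indices in reports are 1-based positions within the sorted exon
  union.
* Candidate ordering: descending supporting pairs, ties by gene symbol —
  deterministic output for fixed input.
* Degenerate inputs: empty candidate lists propagate as 0-row tables; a
  0-gene cohort matrix warns; two all-absent profiles cluster at distance
  0; zero classifiable variants make the dipyrimidine fraction `NA` with a
  warning; unknown VCF depth fails the depth filter rather than passing.
* Secondary/supplementary alignments are ignored (primary-alignment
  semantics of the MAPQ filter); unmatched mates and cross-chromosome
  pairs are dropped with counters.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on simulated data:
20-gene genomes (~250 kb) at 100× exonic coverage for detection checks
(~25,000 background pairs), 10,000 retrocopy pairs for the span-identity
oracle, 1000 planted SNVs (+40 decoys, +30 germline) for signature
recovery, 30 fragments for phasing, and a 6-sample (3 donors ×
parental/iPSC) cohort at 30× for the conservation checks. These sizes were
chosen so every property is exercised with comfortable statistical margins
while a full run stays in the minutes range on one core.

## Known limitations

* Source-locus evidence cannot localize the insertion site, distinguish
  multiple independent insertions of the same gene, or detect retrocopies
  already assembled into the reference.
* Paralogous gene families (the reference-relic signature) are flagged by
  recurrence, not resolved; a true somatic event in a relic-flagged gene
  would be discounted.
* The somatic set difference inherits the sensitivity of the upstream
  caller in the parental sample: a variant undercalled in the parent
  appears somatic.
* Split-read (soft-clip junction) evidence is deliberately unused; pairs
  are the unit of evidence throughout.
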