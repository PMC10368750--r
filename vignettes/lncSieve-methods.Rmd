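---
title: "lncSieve: methods and design notes"
author: "lncSieve authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncSieve: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncSieve)
```

## The problem

The Mexican tetra *Astyanax mexicanus* exists as a sighted surface
morphotype and several blind cave morphotypes, making its eye
transcriptome a natural system for asking which long non-coding RNAs
(lncRNAs) accompany eye development and eye loss. Starting from de novo
transcriptome assemblies of the two morphotypes, a lncRNA catalogue is
inferred in stages: candidate selection by coding-potential consensus
and filtering, genomic mapping and positional classification against
protein-coding genes, cross-morphotype sharing by reciprocal best hits,
EST-based validation, tiered conservation annotation and candidate-gene
interaction reporting. lncSieve implements that inference layer as
reusable, tested functions. Upstream steps — read trimming, assembly,
abundance estimation, protein/ncRNA annotation, spliced alignment and
the coding-potential tools themselves — are consumed as tables, not
reimplemented.

Because the full analysis needs large external inputs, every stage here
is exercised on synthetic data with planted ground truth: the
synthetic-data module is first-class code that generates genomes, gene
models, mapped transcripts of every positional geometry, tool votes,
expression values, ortholog pairs, ESTs and decoys, all deterministic
under a seed.

## Coding-potential consensus

Each transcript carries exactly five binary verdicts (coding /
noncoding), one per coding-potential tool. The consensus rule is
4-of-5: at least four noncoding verdicts call the transcript noncoding,
at least four coding verdicts call it coding, and the only remaining
configuration — a 3–2 split — is *undetermined*. Over the 32 possible
verdict vectors this yields exactly 6 noncoding, 6 coding and 20
undetermined outcomes (`choose(5,4) + choose(5,5)` per side), which the
test suite asserts by enumeration. Records with missing or extra
verdicts are rejected rather than guessed: the upstream tools always
report, so a malformed row indicates a data-handling error, not tool
failure. The coding and undetermined sets are retained in a side
channel — undetermined transcripts are candidates for bi-functional
RNAs, not noise.

## The candidate filter cascade

`runCascade()` applies, in order:

1. **Length**: keep transcripts of at least 200 nt (boundary kept).
2. **Consensus**: keep the noncoding class only.
3. **Annotation**: drop transcripts with a protein annotation or an
   ncRNA family label; a transcript with no flag row counts as
   unannotated.
4. **Redundancy**: identity-1.0 clustering (below).
5. **Expression**: keep FPKM ≥ 1 (boundary kept); a missing value is
   treated as 0 with a warning, a negative value is an error.

Stage counts telescope — each stage's output count is the next stage's
input count — so a transcript failing several filters is counted once,
at the first applicable stage. The cascade is idempotent on its own
output.

Two open points were settled as follows. The redundancy step runs
*before* the expression step (the pipeline's order of record), which
means an expression value attached to a collapsed member is discarded
with it; we keep the representative's own FPKM rather than summing
cluster members, since each member's FPKM already estimates its own
abundance. And FPKM is a single per-transcript value; per-replicate
expression handling is out of scope.

### The identity-1.0 dedup contract

Redundancy removal at similarity threshold 1.0 has exact semantics: a
sequence is collapsed into a representative iff it is identical to, or
an exact substring of, that representative, on either strand. At
threshold 1.0 the greedy word-indexed clustering heuristic and this
contract coincide, so `dedupIdentity()` implements the contract
directly: sequences are processed longest-first (ties by smallest id,
which fixes the representative choice deterministically) and checked by
exact substring containment against current representatives and their
reverse complements. The cluster map is a total function from input ids
to representative ids, and the test suite checks it against a naive
all-pairs oracle.

## Positional classification

Mapped lncRNAs are classified against protein-coding gene models into
16 classes over four axes — type, direction, location, subtype:

* **type**: *genic* iff the genomic spans overlap by ≥ 1 bp, else
  *intergenic* (within a window, default 100,000 bp).
* **direction**: *sense* iff the strands agree.
* **location** (genic): *exonic* iff any lncRNA exon overlaps any gene
  exon, else *intronic*. Defining location by exon–exon overlap is what
  makes a gene sitting wholly inside a lncRNA's intron "intronic
  containing" even though the gene lies inside the lncRNA's genomic
  span — the SOX2-OT-like geometry.
* **subtype** (genic): *containing* iff the lncRNA span contains the
  gene span (equal spans included — a deliberate tie-break), *nested*
  iff the gene span strictly contains the lncRNA, else *overlapping*.
* **location** (intergenic): *upstream* iff the lncRNA lies on the
  partner gene's 5′ side; **subtype** is *same_strand* for sense pairs,
  and for antisense pairs *divergent* when upstream (transcription away
  from each other) and *convergent* when downstream (toward each
  other).

That gives 12 genic classes (2 × 2 × 3) and 4 intergenic ones. The
six-way GENCODE-style summary collapses genic classes to
exonic/intronic/overlapping (the *overlapping* subtype wins over
location) and intergenic classes to their subtype.

Design choices worth recording:

* **Coordinates** are 1-based closed `GRanges`/`IRanges` throughout —
  the native convention of the containers this package is built on —
  and GTF/GFF3 need no conversion on either side.
* **Intergenic distance** is counted between nearest span ends such
  that adjacent features have distance 1; this keeps the invariant
  "intergenic implies distance ≥ 1" exact, with genic pairs at
  distance 0.
* **Frame**: whether upstream/downstream is measured in the partner
  gene's frame or the lncRNA's is genuinely underdetermined; the
  reference frame is an argument (`frame = "gene"` default,
  `"lncrna"` alternative). Antisense geometry is frame-independent;
  same-strand pairs flip location between frames.
* **Best partner**: any genic partner outranks any intergenic one;
  among genic partners larger span overlap wins, among intergenic
  smaller distance wins, and remaining ties go to the smallest gene id
  — a documented total order, so `isBest` is always unique. How the
  original classifier tool breaks such ties is unpublished; this order
  is our substitute.
* **Window**: 100,000 bp default, configurable; lncRNAs with no gene
  in range are reported as partnerless rather than dropped.
* Genes with undefined strand are skipped with a warning; overlapping
  genes all compete as partners and the ranking decides.
* Gene span is min(start)–max(end) of the gene's exons.

Alignment intake excludes chimeras (blocks of one alignment spanning
more than one chromosome or strand), drops alignments to
non-whitelisted sequences (the unplaced-scaffold exclusion), and when a
transcript has several colinear alignments keeps the one covering the
largest fraction of the transcript, flagging the record.

## Homology: thresholds, RBH, validation, conservation

The semantic core operates on BLAST-outfmt6-style hit tables (with a
`qcovs` column, union-of-segments per query); the internal aligner
exists so the synthetic tests need no external binary. The shipped,
versioned profile configuration (`thresholdProfiles()`):

| profile        | e-value  | identity | coverage | extra      |
|----------------|----------|----------|----------|------------|
| rbh            | —        | ≥ 70     | ≥ 70     |            |
| est            | ≤ 1e-5   | ≥ 95     | ≥ 95     |            |
| own_lnc        | ≤ 1e-5   | ≥ 70     | ≥ 70     | top 3 hits |
| zebrafish_lnc  | ≤ 1e-5   | ≥ 50     | ≥ 50     |            |
| human_lnc      | ≤ 1e-5   | ≥ 50     | ≥ 25     |            |
| fish_screen    | ≤ 1e-3   | —        | ≥ 60     |            |

All comparisons are inclusive — a hit exactly at a floor is retained —
and `filterHits()` is monotone: raising any threshold never grows the
retained set. The tier identities/coverages step down with phylogenetic
distance deliberately: lncRNA primary sequence conserves poorly, so the
human tier asks only for a well-conserved quarter of the query. The
fish screen's e-value bound is read as ≤ 1e-3, consistent with every
other cutoff in the family (the alternative reading — keeping only
hits *worse* than 1e-3 — would invert the screen's purpose).

* **Best-hit key**: (bit score desc, e-value asc, identity desc,
  subject id asc) — a total order, fixed and config-locked.
* **RBH**: both tables are profile-filtered first; (a, b) is a pair iff
  each is the other's unique best. The result is a partial matching —
  no id appears twice — and defines the shared-lncRNA set between
  morphotypes.
* **EST validation**: a candidate is validated iff ≥ 1 hit passes the
  95/95 profile against the deduplicated EST library. The hit-table
  direction is explicit (`candidateSide`): with synthetic ESTs that are
  mutated subsequences of their parents, the EST is the query (its
  coverage of the parent is what the 95% floor should measure); tables
  from querying candidates against an EST database use the other side.
* **Tiered annotation**: known iff any tier retains a hit; the
  Venn-style exclusive-region counts partition the known set, and
  known + novel equals the candidate total by construction — both are
  asserted on every synthetic run.
* **Fish screen**: round one drops species with no passing hit; round
  two refilters the merged surviving panel with the same floors and
  reports per-species conserved counts and per-lncRNA species lists.

### The internal aligner

`localAlign()` computes an optimal Smith–Waterman local alignment
(match +2, mismatch −3, gap open −5, gap extend −2 per position —
megablast-like scoring) via Biostrings, trying both query strands.
Percent identity is identities over alignment columns; query coverage
is the aligned query span over query length. `N` never matches
anything, itself included. Bit scores use Karlin–Altschul defaults
(λ = 0.625, K = 0.41) and e-values are therefore approximate; no
threshold decision on synthetic data rests on them — the synthetic
fixtures are designed so that identity and coverage carry the
decisions. `alignSets()` adds a shared-word prefilter (default word 14:
long enough that unrelated random sequences essentially never share a
seed, short enough that homologs at 10% divergence always do). The test
suite checks the aligner's optimality against an independently written
quadratic-space affine-gap dynamic program on hundreds of random pairs.

## The synthetic-data module

The generators emulate, with planted truth: gene models on chromosomes
(non-overlapping multi-exon genes; overlapping-gene ambiguity is left
to the classifier's documented ranking), mapped transcripts realising
any of the 16 geometries with their host gene guaranteed to be the best
partner, five-tool votes with an independent per-tool error rate,
expression tables with an exactly-planted below-floor fraction
(`round(n × fraction)` uniform in [0, 1), the rest shifted log-normal
≥ 1), ortholog pairs by point substitution, ESTs as mutated contiguous
subsequences (lengths uniform in [100, min(parent, 800)] — typical EST
scale), and uniform-composition decoys, which minimise accidental
homology at the stated thresholds. Every generator is byte-deterministic
under a fixed seed.

Defaults were chosen once as realistic study conditions: gene exons
400–600 bp with introns 800–2,000 bp (large enough that every intronic
geometry can be planted on any gene), intergenic gaps 15–30 kb (so a
planted intergenic transcript at ≤ 5 kb is always nearest its host),
5% ortholog divergence (comfortably above the 70% RBH identity floor,
far from trivial identity), 2% EST mutation against the 95% validation
floor, and cascade defect fractions 25/10/10/25/5% (short / coding /
annotated / low-FPKM / duplicate) planted as *disjoint* groups so each
stage's removal count is exactly known. No distributional description
of real transcript lengths or abundances was available to copy, so
lengths and the log-normal FPKM parameters are exposed configuration
with placeholder defaults.

What the synthetic data does *not* emulate — and hence what passing
tests do not show about real data: read-level error and assembly
artefacts, splice-aware alignment ambiguity, the actual feature
computations of the coding-potential tools (votes are simulated
verdicts), biased base composition, paralogy and repeat families
(decoys are uniform-random), or realistic lncRNA length/expression
distributions. The tests demonstrate that the inference logic is
correct given its inputs, not that upstream tools produce those inputs
faithfully.

## Problem sizes and numerical choices

The shipped test and acceptance runs use: 160 planted transcripts
(10 per class) on a 40-gene, 4-chromosome genome for classifier
recovery; 400 transcripts for the cascade; 200 ortholog pairs plus 50
decoys (sequences 400–900 nt) for RBH; 500 random pairs ≤ 80 nt for
the aligner-versus-oracle check; and 200 sequences for the dedup
oracle check — sizes chosen to exercise every code path while keeping
a full run in minutes on one core. Degenerate inputs are defined
behaviour throughout: empty transcript sets flow through every stage,
empty hit tables yield empty (not missing) results, and zero-length
sequences are validation errors.

## Known limitations

* E-values from the internal aligner are approximate; quantitative
  e-value work should use external alignment output.
* Multi-isoform gene models are flattened to one exon chain per gene.
* Expression is one value per transcript; replicate-aware or
  differential analyses are out of scope.
* The 16-class taxonomy assigns one class per (lncRNA, gene) pair; a
  lncRNA's non-best partners are reported but carry no aggregate
  summary.
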