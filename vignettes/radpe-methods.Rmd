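---
title: "Local assembly of RAD paired-end libraries: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local assembly of RAD paired-end libraries: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpe)
```

## The method

Restriction-site associated DNA (RAD) paired-end sequencing reads each DNA
fragment from both ends: read 1 starts at the restriction cut site (the
*RAD tag*, invariant for all fragments sharing that site), read 2 at the
randomly sheared other end.  Since all pairs sharing one tag come from one
small neighbourhood of the genome, their sheared-end reads can be
assembled *locally*, one tag at a time, into a contig that is several-fold
longer than the reads.  The contigs then serve as a per-locus reference
for SNP discovery between samples, and — where a polymorphism falls inside
the tag itself — for haplotype-resolved contig pairs.

Three library geometries are supported:

* **SNP discovery** — complete digest with a rare cutter (SbfI), shear
  selection around 300–800 bp; contigs per tag, threshold genotyping.
* **Partial digest** — incomplete digestion with frequent 4-cutters
  (NlaIII, Sau3AI) produces overlapping multi-kb fragments whose tag-side
  contigs tile a whole genome redundantly.
* **Long insert** — double circularization places sequence 1–6 kb from
  the cut site at the far end of a short sequencable fragment; a two-pass
  assembly turns the resulting spread of read-2 distances into multi-kb
  contigs.

The pipeline stages are: quality filtering and (optional) barcode
demultiplexing → binning by tag → count thresholds and repetitive-tag
removal → per-bin coverage cap → per-bin assembly → read-back alignment,
pileup and threshold calling → reports (contig FASTA, two-line SNP
report, VCF, TSV).

## Read filters and binning

* A pair is dropped when either read has **more than 25** bases at phred
  ≤ 11 (the score of `'K'` under the phred64, Illumina-1.5 encoding).
  The filter is applied per read but the pair is dropped as a unit: an
  orphaned mate cannot be binned consistently.  Both `max_poor` and the
  poor-score cutoff are arguments of `quality_filter()`.
* The tag is the first 39 bases of (trimmed) read 1 by default; the tag
  length is configurable (`bin_filter_config(tag_length = )`).
* Bins are kept when `min_count <= n < max_count`, with counts pooled
  over all samples, because the contigs are assembled from the pooled
  reads.  Mode presets: 30/1000 (SNP discovery), 25/500 (partial-digest
  whole genome), 1000/unbounded (long insert).  Tags at Hamming distance
  1 from a removed repetitive tag are removed with it: at repetitive-tag
  read counts, single sequencing errors create derivative tags with
  enough reads to pass the minimum filter.
* Oversequenced bins are truncated to a coverage cap (default 30×)
  measured as read-2 bases over the estimated region length — by
  convention the upper bound of the shear size-selection window.  The
  truncation keeps pairs in input order rather than subsampling at
  random, so reruns are bit-reproducible.

## The per-bin assembler

Each bin's **read-2 sequences only** are assembled (read 1 is the
invariant tag, not assembly substrate) in a canonical k-mer de Bruijn
graph: k-mers are stored as the lexicographic minimum of themselves and
their reverse complement, k is odd so no k-mer is self-complementary, and
k-mers containing N are skipped.  Simplification repeats to a fixpoint:

* **tips** — dead-end unbranched paths shorter than `tip_max_length`
  (default `2k`) attached at a branch are clipped;
* **bubbles** — two unbranched arms sharing both endpoints with sequence
  identity ≥ `bubble_identity` (default 0.9) are merged, keeping the
  higher-coverage arm (ties keep the lexicographically smaller spelled
  sequence, for determinism);
* **coverage cutoff** — k-mers with multiplicity below `cov_cutoff` are
  dropped first.

`cov_cutoff` defaults to 2 in `assembly_params()`: at 30–60× pooled bin
depth, almost all error k-mers are singletons and removing them cleans
the graph before tip/bubble passes.  The **partial-digest pipeline preset
uses `cov_cutoff = 1`**: in that geometry the per-tag sheared-end depth
is only ~3× and tapers toward the contig tail, so singleton k-mers are
real sequence and a cutoff of 2 would truncate every contig.

Contigs are maximal unbranched paths, reported in canonical orientation
(minimum of sequence and reverse complement) and sorted by decreasing
length — two properties that make assembly output strand-invariant and
byte-reproducible.  Mean k-mer coverage is the mean node multiplicity
along the path.  Contigs shorter than `min_contig_length` (default
100 bp) are dropped.

### Word-length selection

Per bin, three word lengths are tried: a fixed low k (21), the
coverage-predicted k, and a fixed high k (31), and the trial with the
largest **total assembled length** wins; ties go to the larger N50, then
the smaller k.  The depth→k map is a monotone step function (below 10× →
21; below 30× → 25; below 100× → 29; else 31): sparse bins need short
words so reads still overlap by k, deep bins afford long words that
bridge short repeats.  The three trial values and the map are package
defaults spanning the word lengths classic short-read de Bruijn
assemblers used; all are configurable.

### Long-insert two-pass assembly

Pass 1 assembles at a long word length (41; word lengths up to 63 are
supported natively).  Pass 2 re-assembles at the coverage-predicted k
with the pass-1 contigs added to the input set (each threaded through
the graph with weight 1), and finally uses the pass-1 contigs as
*templates*: pass-2 contigs whose terminal 40-mers place uniquely and in
compatible order on one pass-1 contig are stitched together, gaps filled
from the template.  In a purely count-based de Bruijn graph, adding long
sequences cannot by itself separate repeats shorter than the read but
longer than k; the template-guided merge is what lets the long first-pass
contigs bridge such repeats, which is their purpose here.

## Alignment and variant calling

Reads are aligned back to their bin's contigs by seed-and-extend: exact
17-mer seeds from the read start, middle and end are located on both
contig strands, and each candidate is extended by a banded (half-width
10) affine-gap alignment with match +1, mismatch −2, gap open −4, gap
extend −1, accepted at score ≥ 0.6 × read length.  A read scoring equally
well on two contigs of the bin is discarded as ambiguous.  These scoring
constants are package choices.

Pileups count, per contig position and sample, base observations with
phred ≥ 20 ("high-quality nucleotides"); insertions are counted at the
anchoring base before them and deletions at the first deleted position.
Genotypes are called by thresholding: an allele *passes* at **≥ 4
observations** in a sample; no passing allele is a no-call (`-`), one is
a homozygote (the same ≥4 rule applies to the single allele), two are a
heterozygote `[X/Y]` with the contig (reference) allele first, three or
more a no-call flagged multi-allelic.  A record is emitted at every
position where some sample's call contains an allele differing from the
contig consensus; indels pass under the same threshold.  Positions are
1-based on the contig.

Bi-allelic tags: two kept tags at Hamming distance exactly 1 with pooled
count ratio inside [1/3, 3] and no other candidate partner are paired as
the two alleles of one locus; their contigs are phased by construction
and their sequence differences reported as phased variants.  The ratio
bound (a package choice) excludes error-derived partner tags, which are
far rarer than their source tag.

## The simulator

The simulator generates i.i.d.-base genomes (linear or circular — the
circular option avoids edge effects in whole-genome coverage studies),
plants SNPs/indels at ≥10 bp spacing with a full truth table, digests
molecules site-by-site (each site cut with probability `partial_cut_prob`
per molecule copy; coinciding cut coordinates of adjacent sites are cut
once), size-selects fragments, shears, and emits read pairs whose read 1
starts inside the recognition site at the enzyme's tag offset (SbfI tags
begin `TGCAGG`, NlaIII `CATG`, Sau3AI `GATC`) and whose read 2 is the
reverse complement of the sheared end.  Substitution errors get quality
15, correct bases quality 40 — a two-level model that keeps the
high-quality pileup filter meaningful without modelling quality decay by
cycle.

Two modelling choices deserve note.  First, the **kept sheared-piece
length is drawn uniformly over the shear window** (conditioned on the
fragment length): gel extraction, not the shear process, dominates what
is retained, and this matches the near-uniform distribution of
sheared-end distances the contig-length profile depends on.  Second, the
partial-digest run digests each enzyme in its **own library** (as the
two-enzyme bench protocol does) and emits a target number of pairs per
surviving tag (default 40), resampling shear lengths across that tag's
fragment instances — sequencing depth is set by the sequencer, not by
the digest copy number.  In the long-insert geometry the read-2 distance
is `L − y` with insert length `L` uniform over the size selection and
second-shear offset `y` uniform over `(0, shear_mean − read2_len)`; the
junction position per final fragment is recorded.  The simulator does
not model PCR/GC bias, adapter chimeras, re-ligated concatemers, or
quality-by-cycle profiles — so passing tests demonstrate algorithmic
correctness on idealized libraries, not robustness to every real-data
artifact.

## Numerical and reporting conventions

* Coordinates are 0-based half-open inside the simulator, 1-based in all
  reports (contig positions, VCF, FASTA placements).
* N50 is the smallest length L such that contigs ≥ L sum to at least
  half the total; it is reported both over all contigs and over each
  tag's longest contig.
* Truth-genome coverage counts distinct *contig placements* overlapping
  a base, not read depth.
* Contig FASTA headers follow
  `<tagIndex>_<tagSequence>_NODE_<n>_length_<L>_cov_<c>` with coverage
  printed to six decimals; the SNP report uses the two-line dialect
  (header line, then `pos ref sample1 gt1 sample2 gt2`).
* All randomness flows through explicit `seed` arguments; a fixed seed
  reproduces every output file byte-identically.

## Problem sizes used by the test suite

The suite exercises: single-bin assemblies of 300–800 bp regions at
20–30×; a whole-genome partial-digest run on a circular 100 kb genome
(two 4-cutter libraries of 50 molecule copies, ~1,200 kept tags, ~46,000
pairs) checked against the ≥99.9 % (≥1 contig) and ≥91 % (≥5 contigs)
coverage profile; 200-bin oracle-equivalence and planted-variant
recovery studies (2 heterozygous SNPs per 300–800 bp locus, 30× per
sample, 0.5 % error rate, sensitivity ≥ 0.90 with zero false positives);
and a long-insert study on 3–5 kb regions including an engineered 34 bp
repeat that the two-pass strategy must bridge.  These sizes keep each
study well-powered for its bound while completing quickly on one CPU.

## Known limitations

* The assembler is deliberately compact: its cleanup thresholds are
  analogues of, not clones of, any particular production assembler's, so
  absolute contig counts on real libraries will differ between tools
  even when the coverage profile reproduces.
* Paired-end insert-size constraints are not used during assembly;
  within one bin all reads already share a locus, so pairing adds little.
* No scaffolding across bins and no merging of per-bin contigs into a
  genome-wide assembly.
* The caller is exactly the threshold rule — no genotype likelihoods, no
  population-genetic statistics.
* Barcode matching is exact; there is no 1-mismatch rescue.
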