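---
title: "svsigcall: model, parameters and design notes"
author: "svsigcall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svsigcall: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svsigcall)
```

# The problem and the model

Structural variants — deletions, insertions, duplications, inversions and
translocations of roughly 50 bp and above — are poorly captured by short
reads but are frequently contained entirely within a single long read.
`svsigcall` therefore treats the *alignment* of each read as the primary
observation. Two alignment features carry SV information:

* **Intra-alignment indels.** Aligners encode mid-read deletions and
  insertions as `D`/`I` CIGAR operations. Operations of at least
  `min_size` bp (default 30) become per-read signatures
  `(position, length, read)`. Around real SVs, aligners often shatter one
  long event into several smaller operations; two same-kind signatures of
  one read are re-merged when they are close — for insertions when the
  start distance is at most `Sig_dis`, for deletions when the gap between
  the end of the first and the start of the second is at most `Sig_dis`.
  The merged record keeps the first start and the summed length, so total
  inserted/deleted bases per read are conserved.
* **Split alignments.** When a read cannot be represented by one gapped
  alignment, it is reported as a primary plus supplementary records. Each
  record becomes a segment on the coordinates of the full, clip-inclusive
  read (soft *and* hard clips count, so the offsets agree across records;
  reverse-strand records are flipped onto the original read orientation
  using the implied read length). For two segments adjacent on the read on
  one chromosome and strand, with
  `diff_dis = (ref2_start − ref1_end) − (read2_start − read1_end)` and
  `diff_olp = ref1_end − ref2_start`, the pair indicates a deletion
  (`diff_olp < 30`, `diff_dis ≥ 30`; breakpoint at `ref1_end`, size
  `diff_dis`), an insertion (`diff_olp < 30`, `diff_dis ≤ −30`; at the
  floored midpoint of `ref1_end` and `ref2_start`), or a tandem
  duplication (`diff_olp ≥ 30`; the overlap `[ref2_start, ref1_end]`).
  Opposite strands give an inversion junction — head-to-head (from the
  segment ends) when the first segment is forward, tail-to-tail (from the
  starts) otherwise. Different chromosomes with a read gap under 100 bp
  give a breakend; of the eight strand combinations, a forward segment
  contributes its reference end when it is first (start when second), a
  reverse segment the opposite, and the alphabetically smaller chromosome
  is stored first. A dedicated three-segment detector handles a mobile
  sequence inserted between two duplicated copies (A, X, A′): the A/A′
  pair has duplication geometry while X maps elsewhere, yielding DUP, BND
  and INS signatures together.

A subtlety worth recording: a reverse-complement read presents a same-strand
segment pair in *mirrored* order, so the deletion/insertion/duplication
geometry is always evaluated on the canonical forward orientation of the
pair. Without this, a duplication read sequenced on the minus strand would
be classified as spanning the union rather than the overlap of its
segments. The breakend case needs no such correction — the eight strand
cases are already mirror-consistent.

# Clustering and allele refinement

Signatures of one type (and chromosome, or chromosome pair for breakends)
are grouped by position: signatures `i` and `j` are linked when
`|pos_i − pos_j| ≤ TH` **or** `|(pos_i+len_i) − (pos_j+len_j)| ≤ TH`.
`svsigcall` computes the connected components of this linkage. Because both
conditions are interval conditions on a single coordinate, the components
are obtained exactly by union-find over consecutive gaps in the
position-sorted and the end-sorted orders (if two signatures are within
`TH`, every intermediate signature in that order is too), which makes the
clustering independent of scan direction and equal to the brute-force
predicate graph — a property the test suite verifies against an
igraph-based oracle. Clusters with fewer than two supporting reads are
discarded before refinement.

Per-type defaults for `TH` are 200 bp (DEL, INS), 500 bp (DUP, INV) and
50 bp (BND), all exposed as `max_cluster_bias_*` configuration keys.

**Deletion/insertion refinement.** A cluster may mix two alleles of a
heterozygous locus. Members are sorted by size (largest first) and split by
the chained-gap rule: a signature joins the open sub-cluster iff its size
differs from the *last added* signature by less than
`Bias_L = α · mean(length)`. α defaults to 0.2 for insertions with
high-error reads (CLR/ONT), 0.65 for CCS, and 0.3 for deletions regardless
of platform. The sub-cluster with the most distinct supporting reads (SR)
is the major allele when `SR ≥ SR_min` and `SR > μ·|Group|`
(μ: insertions 0.6 CLR/ONT / 0.65 CCS; deletions 0.7 / 0.35); remaining
sub-clusters with at least `SR_min` signatures are minor alleles. When no
major allele exists, the two largest sub-clusters are both admitted iff
`SR_min ≤ SR_first ≤ μ|Group|`, `0.4|Group| ≤ SR_second ≤ SR_min` and
`SR_first + SR_second ≥ 0.95|Group|` — i.e. nearly all evidence supports
exactly two alleles. The upper bound on `SR_second` is implemented exactly
as stated; note it makes the rescue fire only when
`SR_min ≥ 0.4|Group|`, so balanced dual-allele loci with 10 reads per
allele are recovered at the default `SR_min = 10` but not at very
permissive support thresholds. This also means the number of reported
alleles is not globally monotone in `SR_min`; monotonicity holds on the
major-allele path and is tested there.

**Duplication/inversion refinement** groups members so the total breakpoint
discrepancy of a sub-cluster — the spread of the first breakpoints plus the
spread of the second — stays within 500 bp, then selects alleles with
`μ = 1/3`. (A per-coordinate reading of "breakpoints within 500 bp" would
be strictly weaker; the summed form is what separates, e.g., junction pairs
(6000, 6950) and (6400, 7300).) **Breakend refinement** keeps
orientation classes and chromosome pairs apart, uses a 50-bp rule on both
mates, `μ = 0.6`, and halves `SR_min` (rounded up), reflecting that
translocation evidence is diluted over chromosome/orientation combinations.

Support (SR) always counts distinct read names, not signatures: one read
may contribute several merged fragments but is one molecule of evidence.
Ties between sub-clusters of equal support are broken by larger mean
length, then smaller position, for determinism.

# Calling and genotyping

Each allele sub-cluster becomes a call at the arithmetic mean of its
members' positions and sizes (each read counted once; means are rounded to
integers). Calls under 30 bp are removed. Deletions are written with
negative `SVLEN`, insertions/duplications positive, per VCF convention.

Genotyping uses a bi-allelic diploid model. `SR_ALT` is the allele's
support; `SR_Ref` counts distinct reads with an alignment record fully
spanning `[pos − F, pos + F]` (flank `F = 500` bp) that are not among the
supporting reads. With a flat 1/3 prior and a constant per-read
mis-assignment probability ε (default 0.1):

$$L(0/0) = \tfrac13 (1-\varepsilon)^{SR_{Ref}}\,\varepsilon^{SR_{ALT}},\quad
  L(0/1) = \tfrac13 \left(\tfrac12\right)^{SR_{Ref}+SR_{ALT}},\quad
  L(1/1) = \tfrac13 (1-\varepsilon)^{SR_{ALT}}\,\varepsilon^{SR_{Ref}}.$$

All computation is in log space and normalized by log-sum-exp, so
posteriors sum to one exactly and no underflow occurs at any depth. The
genotype is the posterior argmax; GL are log10 posteriors, GQ is the phred
gap between best and second-best capped at 100, QUAL is the phred-scaled
posterior of hom-ref (for a hom-ref call, of its complement), and PL are
min-normalized phred likelihoods. At a multi-allelic site every alternative
allele is genotyped independently under the bi-allelic model and written as
its own VCF record. With `sr_ref = sr_alt = 0` the genotype is `./.`;
genotyping can be skipped entirely (`genotype = FALSE`), in which case all
genotypes are `./.` and only DV is filled.

# Block-parallel execution

The genome is partitioned into 10-Mbp blocks. Each read group is *owned* by
the block containing its primary alignment start, but a block *processes*
every read group with any alignment record inside its range padded by
50 kbp — more than a read length plus twice the largest clustering
threshold — so clusters near a cut are always seen whole, and breakend
evidence is visible from both partner chromosomes. A call is emitted only
by the block containing its position, which removes duplicates
deterministically. Blocks are processed with `parallel::mclapply` and
concatenated in genomic order, so the output VCF is byte-identical for any
thread count; the test suite asserts this for 1/2/8 workers.

# The synthetic-alignment generator

The generator emulates what an aligner *reports* around each implanted SV,
not the sequencing process itself. Reads are laid uniformly over each
contig at the requested coverage (default 20×) with Gaussian length
variation around 10 kbp. For a variant-haplotype read crossing an implant
with at least 200 bp of anchor on each side: indels below 1 kbp appear as a
single record with a `D`/`I` operation (in *fragmented* mode, as two
sub-threshold-spaced operations the extractor must re-merge); larger indels
and all duplication/inversion/breakend implants appear as primary +
supplementary pairs with consistent SA tags and exactly the split geometry
the classifier expects — including three-segment chains for reads spanning
a whole inversion. Reads overlapping a breakpoint with insufficient anchor
are soft-clipped at the breakpoint, as an aligner would report them, which
keeps them out of both the variant and the reference evidence. An optional
jitter knob perturbs per-read breakpoints and sizes to exercise the
clustering tolerances; it is off by default.

Heterozygous implants live on one of two haplotypes. By default reads
alternate haplotypes in position order ("alternate" mode), which realizes
the half-coverage-per-haplotype design of standard simulation pipelines
*exactly* at every locus; a Bernoulli(0.5) "random" mode is available. The
deterministic mode was chosen because per-locus binomial depth fluctuation
is a property of sampling noise, not of the caller: with ~18 spanning reads
a random 50/50 draw lands outside the het/hom decision boundary of the
likelihood model in roughly 1–2 % of loci, which would make genotype
concordance a coin flip over hundreds of loci rather than a statement about
the method.

What the generator does **not** model, and what passing tests therefore do
not show: base-level sequencing errors and quality strings (SEQ is `*`),
mapping ambiguity and mapping-quality variation (all records are MAPQ 60),
repeat-induced misalignment, coverage biases, and reverse-strand sequencing
of the molecule (segment geometry is emitted in forward orientation; strand
handling of the classifier is covered by dedicated unit tests instead).
Duplication implants default to 100–450 bp, below the genotyping flank: for
tandem duplications longer than the flank, spanning-read genotyping is
intrinsically uninformative — both haplotypes retain reference-spanning
copies — and zygosity would require depth-based evidence, which this model
(like the underlying method) does not use. Breakend implants follow
reciprocal-translocation geometry, so all variant reads crossing the
breakpoint are split and reference coverage elsewhere is unchanged.

# Evaluation statistics

A prediction matches a truth record of the same class when the prediction
interval padded by 1 kbp intersects the truth interval and the size ratio
`min(L)/max(L)` is at least 0.7 (insertions use `end = start + length`;
zero sizes never match). Breakends match at *breakpoint* level when both
breakpoints are within 1 kbp on the same chromosome pair, and at
*breakend* level when the strand-connectivity class also agrees.
Assignment is greedy one-to-one in position order with ties broken by
breakpoint distance, so `TP + FP = |calls|` and `TP + FN = |truth|` hold
exactly. Precision, recall and F1 follow the usual ratios with 0/0 defined
as 0; genotype-aware variants re-count a matched call with a discordant
genotype against the statistics. Trio recall is the fraction of homozygous
parental SVs re-identified in the offspring (parental records without
genotypes are excluded from the denominator); the Mendelian discordance
rate is the fraction of offspring calls found in neither parent. An
optional preprocessing step rewrites duplications as insertions for truth
sets using that convention (off by default).

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; conversion to
  1-based happens once, at VCF serialization.
* The insertion midpoint `(ref1_end + ref2_start)/2` is floored; call
  positions and sizes are rounded means.
* "Weighted average" of cluster members is implemented as the unweighted
  arithmetic mean with each read counted once; no alternative weights are
  defined by the model.
* The 30-bp constants of the split-pair geometry follow `min_size`
  downwards (`min(30, min_size)`) so a smaller `--min_size` relaxes both
  extractors consistently.
* Records with MAPQ below 20 and secondary alignments are ignored;
  supplementary records are grouped by read name, with SA-tag
  reconstruction only as a fallback when supplementary records are absent.
  `N` CIGAR operations advance the reference but never produce deletion
  signatures (they encode splicing in SAM semantics).
* Malformed CIGARs drop the record with a warning; reads with inconsistent
  implied lengths across records, or without a primary record, are skipped
  with a warning. Empty inputs produce a header-only, parseable VCF.
* Likelihood ties in genotyping are broken toward the later genotype in
  (0/0, 0/1, 1/1) order; they can only occur at `sr_ref = sr_alt`, where
  the heterozygous likelihood strictly dominates for ε < 0.5.

# Problem sizes used in the test suite

The standard end-to-end study is a 10-Mbp two-contig genome with 200
implants (60 DEL, 60 INS, 30 DUP, 30 INV, 20 BND; half heterozygous) at
20× clean coverage, called with `min_support = 3` (the support threshold
appropriate for clean simulated data; the package default of 10 reflects
real-data practice). The dual-allele refinement study uses two loci
(108 + 36 bp insertions; 123 + 37 bp deletions) with exactly 10 reads per
allele, run at the default `SR_min = 10` — the regime in which the
two-allele rescue rule is designed to fire. These sizes keep the full
suite fast while exercising every code path: clustering oracles run on 500
random signature sets, and genotype properties on a 10,000-point sweep.

# Known limitations

* Genotyping is strictly diploid; multi-allelic sites are genotyped one
  alternative allele at a time under the bi-allelic model.
* Duplication zygosity beyond flank-sized events is not identifiable from
  spanning reads (see above); no depth model is implemented.
* Inversion calls report the majority junction class of their cluster;
  complex nested rearrangements beyond the single duplication-with-
  insertion pattern are not resolved.
* The evaluation module implements the package's own matching rules, not
  any external benchmarking tool's semantics.
* CRAM input and within-alignment base-level re-examination are out of
  scope.
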