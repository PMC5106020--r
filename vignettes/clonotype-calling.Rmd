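---
title: "Clonotype calling by spaced seeds and junction windows: methods and design"
author: "vdjcluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonotype calling by spaced seeds and junction windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjcluster)
```

## The problem

V(D)J recombination assembles each lymphocyte's antigen receptor locus
from germline V, (D,) and J genes, trimming the recombined gene ends and
inserting untemplated N nucleotides. The junction is therefore a
near-unique clone identifier, and deep sequencing of rearranged loci
(RepSeq) makes it possible to quantify a lymphocyte population — to
profile an immune response, or to track a leukemic clone across follow-up
samples at frequencies far below what flow cytometry resolves.

Aligning every read against full germline databases is needlessly
expensive when the goal is to *count clones*: reads of the same clone
share the same junction. `vdjcluster` therefore separates a cheap,
alignment-free detection/clustering phase from a detailed designation
phase that runs once per clonotype.

## Phase one: spaced-seed detection and windowed clustering

**Index.** For every configured recombination system ("germline set": a
locus label, 5′ gene list, 3′ gene list), every spaced k-mer of every
gene on both strands is recorded under its `(locus, side, strand)` label.
A spaced seed is a pattern like `#####-#####-###` over match (`#`) and
don't-care (`-`) positions; the lookup key keeps only the characters under
`#`, which buys tolerance to isolated substitutions at the cost of a
longer span. The bundled defaults are a contiguous weight-10 seed, with
the weight-13 spaced seed above available per set; seed weights in the
9–13 range are the practical sweet spot between sensitivity and chance
matches for genes of this length. A k-mer observed under two or more
distinct labels becomes AMBIGUOUS and contributes no evidence — abstention
is cheaper than arbitration at this stage.

**Detection.** Each read is affected position-wise. Among `(locus,
strand)` pairs the one with the most (unambiguous) affects wins; if the
runner-up has at least 90% of the winner's affects, the read is called
`AMBIGUOUS_LOCUS` instead — for MRD use a mis-assigned read is worse than
an abstained one. A detected read needs at least `minAffects` (default 5)
5′-side and `minAffects` 3′-side affects of the winning pair, with the 5′
evidence upstream of the 3′ evidence on the forward-oriented read. The
default of 5 suppresses chance single-k-mer hits while costing little
sensitivity: a germline remnant of length ℓ carries about ℓ − span + 1
seeds, so any remnant ≳ 15 nt clears the bar.

**Junction window.** With *j_l* the end of the last 5′ seed and *j_r* the
start of the first 3′ seed, the window is the `w` nucleotides centred on
`⌊(j_l + j_r)/2⌋` (default `w = 50`, even, ≥ 20). Because the spaced-seed
extremes can interleave slightly, an overlap of the two evidence blocks up
to one seed span is tolerated; a larger inversion demotes the weaker side
(`NO_FIVE_PRIME`/`NO_THREE_PRIME`). Reads whose window would cross a read
border are `TOO_SHORT` unless truncated windows are explicitly enabled;
truncated windows cluster separately, because reproducibility of the
clonotype key across samples matters more than squeezing in short reads.

One consequence worth knowing: when the first (or last) N base happens to
equal the base the recombination deleted, the germline k-mer match extends
one position into the junction, and the window shifts by one relative to a
window computed from the true recombination breakpoints. This is harmless
— the shift is a deterministic function of the sequence, so all reads of a
clone shift identically and the clonotype key remains stable — but it
means window *strings* should be compared between runs of the caller, not
against breakpoint-derived coordinates.

**Clustering** is exact on `(locus, window)`. No mismatch tolerance is
applied here; similarity-based merging is a separate, later operation (see
below), keeping phase one deterministic and order-independent. The
representative of a clonotype is the longest read carrying the window
(ties: lexicographically smallest), maximizing context for phase two. The
per-status read accounting (`DETECTED`, `NO_FIVE_PRIME`, `NO_THREE_PRIME`,
`NO_AFFECTS`, `AMBIGUOUS_LOCUS`, `TOO_SHORT`) is total: every input read
lands in exactly one bin.

## Phase two: designation, CDR3, productivity

**Gene designation.** The representative is aligned against each candidate
5′ gene with a semi-global dynamic program: the aligned region of the read
is a prefix of the read (the read may begin inside the gene, so the gene
start is free), and both ends are free (the gene's 3′ end is deleted by
recombination). The 3′ gene alignment is the mirror image. Scoring is
linear-gap with match +2, mismatch −3, gap −7: V(D)J junction variation is
substitution-dominated, so indels are penalized strongly; the DP is exact
and is verified in the test suite against an exhaustive recursion on small
instances. A designation is accepted when both best scores reach 30
(≈ 15 matched nucleotides); below that the clonotype is `UNSEGMENTED`.
Ties between alleles resolve to the lexicographically smallest name, with
the tie list recorded. All tie-breaks (smallest end on the read, then on
the gene) are deterministic, so results are reproducible bit-for-bit.

**Multi-D junctions.** The middle segment between the two alignments is
scanned for up to `maxD` D genes (TRδ rearrangements can carry two or even
three). Placement is greedy by best local-alignment score, splitting the
remaining segments after each accepted D; a D is accepted at score ≥ 16
and aligned length ≥ 8, reflecting how short D genes are (8–37 bp). Greedy
placement can in principle miss a jointly-better combination of
overlapping D candidates; a joint DP over D combinations was deliberately
left out of this version, and the recovery rates on simulated VDDJ/VDDDJ
junctions (≥ 95% with D remnants ≥ 12 nt) did not justify the complexity.
Unexplained middle segments become the N regions, read directly off the
representative, so the designated span always reconstructs exactly
whenever the gene alignments are substitution-free. When junction
micro-homology lets a gene alignment extend into the N region, the
deletion/N split shifts accordingly — this ambiguity is intrinsic to the
sequence, not resolvable by any caller, and does not affect gene identity.

**CDR3 and productivity.** The junction runs from the Cys104 codon to the
Phe/Trp118 codon (IMGT conventions). Anchors are resolved per gene, in
order of preference: an explicit anchor from the configuration; for 5′
genes, the ungapped position of the base at the conventional gapped
nucleotide offset of codon 104 (a configurable constant, default 310); for
3′ genes, the first Phe/Trp-Gly-X-Gly motif. The V anchor is mapped onto
the representative through the *left* end of the V alignment and the J
anchor through the *right* end of the J alignment — each through the end
that lies in true germline — so a chance indel where an alignment extends
into the junction cannot shift the mapping. An anchor falling in a deleted
gene region gives `NO_ANCHOR`; incomplete systems have no anchors and no
CDR3 by construction. Productivity is defined as: junction length
divisible by 3 **and** no stop codon in the junction reading frame; the
CDR3 amino-acid string is the junction translation minus its two anchor
residues. Whether productivity should also consider the frame upstream of
the junction is left out of scope — the junction-local definition is
recorded here and in the JSON output.

Designation and CDR3 run only for the top `designateTop` clonotypes
(default 100) — the long tail of singleton clonotypes is rarely worth
aligning, and this is exactly what keeps throughput linear in read count.

## Diversity, merging, normalization

Diversity is computed on the clonotype abundance vector: Shannon *H* in
natural log units, equitability *E* = *H*/ln *S* (undefined at *S* = 1,
reported missing), and Simpson's *Ds* in the unbiased Gini–Simpson form
1 − Σc(c−1)/(N(N−1)). Both conventions (log base, Simpson form) are
recorded in the output metadata because several incompatible "Simpson"
conventions circulate.

`autoMerge` absorbs technical satellites: an edge joins two clonotypes of
the same locus when their windows are within Levenshtein distance `eps`
(default 1) and the smaller total count is at most `ratio` (default 0.1)
times the larger; connected components collapse into their largest member.
This is the ε-graph connected-component core of DBSCAN with `minPts` = 1 —
at clonotype scale a density threshold adds nothing, since the count-ratio
condition already encodes "satellite of". The defaults are conservative on
purpose: PCR/sequencing satellites sit at distance 1 with tiny ratios,
while two genuine clones of comparable size are never merged. Note that
components are transitive: a satellite sitting between two real clones can
bridge them, which is why `ratio` < 1 matters. Both merge operations
conserve total read counts and record absorbed windows.

`normalizeAbundances` rescales a sample so a spiked control clonotype of
known concentration takes exactly its expected fraction, redistributing
the remaining mass proportionally (result sums to 1) — the standard
spike-in quantification used for MRD.

## The simulator, and what the tests do and do not show

The simulator is first-class, tested code. It generates germline sets
(random genes with a pairwise edit-distance floor, default 10, so gene
identity is recoverable; Cys codons with consistent gapped sequences on 5′
genes; Phe/Trp-Gly-X-Gly motifs on 3′ genes; D genes in the 8–37 nt
range), and repertoires: clone = 5′ remnant + N (+ D remnant + N)… + 3′
remnant, with per-end deletions, reads drawn under a uniform or geometric
abundance law (default geometric, ratio 0.7, giving the major/minor clone
structure typical of a leukemic diagnosis sample), per-base substitution
errors, and strand flips. Every clone carries full truth: genes,
deletions, N strings, junction coordinates (when both anchors survive the
deletions), productivity by direct frame/stop arithmetic, and the expected
junction window.

Problem sizes used by the checks (chosen as comfortable desk-scale
conditions): clustering exactness and read conservation on 10,000
error-free reads over 50 clones across three systems, including an
incomplete D-D system with 40-nt neighbor pads, under a uniform abundance
law so that every simulated clone is actually represented among the reads;
designation recovery on 500 rearrangements with remnants ≥ 40 nt (100% V/J
identity error-free, ≥ 95% at 1% substitution error); 200 VDDJ junctions;
200 CDR3 cases; DP-versus-recursion equality on 100 random instances up to
length 20.

What passing these tests shows: the machinery is exact under its own
model — substitution errors, clean recombination structure, genes with a
healthy distance floor. What they do not show: behaviour under somatic
hypermutation hotspots (IGH in mature B-cell malignancies), PCR chimeras,
indel-heavy sequencing (e.g. raw nanopore), highly similar real allele
families, or capture/RNA-seq libraries where recombined reads are a tiny
fraction. Real germline databases are license-restricted and deliberately
not bundled; the configuration format accepts any gene FASTA, gapped or
not, so real data plugs in without code changes.

## Degenerate inputs and numerical corner cases

Empty read files produce a valid empty result (with a complete accounting
of zero reads). Reads shorter than the seed span are `TOO_SHORT`. Windows
containing N never match the index. A gene shorter than the seed span
contributes no k-mers and is reported in the index warnings — neighbor
pads are the remedy. The empty alignment (score 0) is a legal DP optimum,
so unrelated sequences never produce negative-score designations, they
fall below the acceptance threshold instead. All simulator parameters are
ranges with safe degenerate behaviour (zero deletions, zero N, single
clone), which the tests exercise.

## Known limitations

- Greedy (not joint) multi-D placement, as discussed above.
- One global seed span per index: per-set seed patterns are configured,
  but one index is built per run with a single pattern.
- The locus arbitration is joint across all systems in a single pass; an
  alternative is one sequential pass per system. Joint arbitration plus
  the 10% abstention band was chosen to keep per-read accounting total and
  order-independent.
- The JSON result dialect is this package's own documented schema; it is
  deliberately versioned (`vdjcluster-1.0`) and not byte-compatible with
  any other tool's format.
- The representative is a real read, not a consensus; at high error rates
  the designated deletions/N regions reflect that read's errors even when
  gene identity is robust.
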