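---
title: "Methods: homology-based spliced-alignment gene calling"
author: "splicecall developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based spliced-alignment gene calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Eukaryotic protein-coding genes are split into exons, and splicing
signals diverge too fast for model-based gene finders to transfer across
distant clades. `splicecall` therefore makes no assumption about splice
sites. Instead it asks a purely homology-based question: which set of
genomic segments, read in some frame and strand, concatenates into a
protein that looks like a known one?

The pipeline has five stages:

1. **Six-frame fragment extraction.** Every contig is translated in all
   six frames; maximal stop-free stretches of at least 20 codons
   (`min_fragment_aa`) become *fragments*. Stretches abutting contig
   ends, which lack a bounding stop codon, are kept: on short
   metagenomic contigs real exons frequently run off the edge.
2. **Local search.** Each fragment is aligned (Smith-Waterman, BLOSUM62,
   affine gaps 11/1) against each reference protein. The aligned part of
   a fragment against a target $T$ is a *putative exon* with four
   coordinates: target start/end $P^{ST}, P^{ET}$ (amino acids,
   inclusive) and contig start/end $P^{SC}, P^{EC}$ (nucleotides of the
   translation start/end, always expressed on the plus strand). A match
   of at least 10 aa is required. Per-exon significance is deliberately
   lenient ($E \le 100$): sub-significant exons can combine into highly
   significant multi-exon calls.
3. **Spliced join.** Putative exons of one (contig, strand, target)
   group are chained by dynamic programming under pairwise compatibility
   constraints (below), maximising a composite bit-score.
4. **Redundancy reduction.** Homologous targets call the same locus many
   times; calls that share an exon are clustered greedily and the
   best-scoring member of each cluster survives as the *prediction*.
5. **Overlap resolution.** Same-strand predictions that overlap on the
   contig are resolved in favour of the better E-value.

## Compatibility and scoring

Exons $P_i, P_j$ with $P_i^{ST} < P_j^{ST}$ are compatible on the plus
strand iff their contig order matches their target order
($P_i^{SC} < P_j^{SC}$), the contig gap can hold an intron
($15 \le P_j^{SC}-P_i^{EC} \le 10000$ nt), and their target ranges do
not overlap by more than 10 aa ($P_j^{ST}-P_i^{ET} \ge -10$). On the
minus strand the contig conditions flip sign.

A compatible chain of $k$ exons scores

$$S(P_{set},T)=\sum_{i=1}^{k} S(P_i,T)+\sum_{i=1}^{k-1}C(l_i)+\log_2(k!)$$

where $S(P_i,T)$ is the per-exon Karlin-Altschul bit-score
($(\lambda r - \ln K)/\ln 2$ with the BLAST gapped constants
$\lambda = 0.267$, $K = 0.041$), $l_i = P_{i+1}^{ST}-P_i^{ET}$ counts
unmatched (or, negative, overlapping) target residues between
consecutive exons, and $C(l)=0$ for $l=1$, otherwise $-|l|$. Because
target coordinates are stored inclusive, perfect adjacency gives
$l = 1$, which reconciles the "number of unmatched residues" reading
with the $C(1)=0$ exemption. Only target-side gaps are penalised;
intron length is constrained but not scored. The $\log_2(k!)$ term
rewards consistent ordering. The gene-call E-value is
$E = 2 \cdot D \cdot 2^{-S}$, with $D$ the total amino-acid count of
the reference database and the factor 2 for the two searched strands.

## The chaining recursion

Exons are sorted in translation order along the contig (ties: target
end, then exon id). The textbook single-state recursion — keep the best
(score, count) pair per exon — is *not* exact here: the ordering reward
depends on the chain length, so a chain with slightly lower score but
more exons can overtake after a later extension collects
$\log_2(k+1)$. We therefore layer the state over the chain length:
$S[j][k]$ is the best score of a chain of exactly $k$ exons ending at
exon $j$. This makes the recursion provably equal to exhaustive
enumeration over compatible subsets (the acceptance suite verifies
equality on 1000 random instances against an independent oracle).
Chain length is capped at 64, far beyond any real gene architecture at
these scales. A two-pointer window over the sorted starts prunes
predecessors that can never satisfy the intron upper bound, so typical
groups run near-linearly.

Determinism: equal scores prefer the earlier predecessor; the global
optimum prefers the chain whose first exon comes earliest in
translation order.

## Why the search has a k-mer prefilter

The lenient per-exon cutoff ($E \le 100$) is calibrated to a *staged*
search: in the fast search tools this method builds on, a k-mer
prefilter discards the vast majority of random fragment-target pairs
before any E-value is computed. Against a desk-scale reference (tens of
kilo-residues), a raw exhaustive Smith-Waterman with $E \le 100$ admits
roughly half of *all* random pairs, and the chaining stage then
assembles arbitrarily long all-noise exon chains whose summed bit-scores
pass every downstream filter — the inverted-fragment null model produces
hundreds of false positives instead of none. Leniency and prefilter are
a matched pair, so `search_fragments()` requires candidate pairs to
share one exact amino-acid 5-mer (`prefilter_kmer = 5`; set 0 for the
exhaustive mode). At 70–90% sequence identity the probability that a
30+ aa exon shares no 5-mer with its target is negligible, while random
pairs pass at $\approx m \cdot n/20^5 \sim 10^{-3}$.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `min_fragment_aa` | 20 (40 in the `large_metagenome` preset) | minimal stop-free fragment, codons |
| `min_exon_aa` | 10 (20 in the preset) | minimal aligned exon, aa |
| `max_exon_evalue` | 100 | per-exon E-value against the reference |
| `max_call_evalue` | 1e-4 | gene-call E-value after joining |
| `min_tcov` | 0.6 | predicted-protein / target length ratio |
| `min_intron`, `max_intron` | 15, 10000 nt | joinable contig gap |
| `max_target_overlap` | 10 aa | tolerated target-side overlap |
| matrix / gaps / $\lambda$, $K$ | BLOSUM62, 11/1, 0.267/0.041 | blastp-compatible statistics |
| `prefilter_kmer` | 5 | shared-k-mer search prefilter |

## The synthetic world

`synth_config()` describes the fixture world: 200 multi-exon genes
(2–5 exons of 30–150 aa each, uniform) over ~1 Mbp on 5 contigs,
introns uniform on 20–500 nt (inside the joinable window), strands
even, reference targets derived from the true proteins by per-site
substitution (BLOSUM-weighted replacements) at a chosen divergence,
plus 20 unrelated decoys. Exons sit on codon boundaries, so each intron
carries an implanted in-frame stop in the frame continuing the upstream
exon — without it, multi-exon genes whose introns happen to be
stop-free would surface as single fragments and never exercise the
joiner.

What the generator does *not* emulate: codon-usage and GC bias,
sequencing error, chimeric contigs, overlapping or nested genes,
phase-split codons at exon boundaries, paralogous gene families, and
profile (rather than sequence) references. A green end-to-end test
therefore establishes that the machinery recovers genes under
controlled divergence with realistic intron/exon geometry — not that
real-genome sensitivity figures are reproduced. The acceptance criteria
are accordingly property-based (oracle equality, boundary exactness,
partition/overlap invariants, recovery and null-model bounds at stated
scales).

Known stochastic edge: a local alignment occasionally extends a
marginally net-positive stretch of intron translation, widening the
claimed target range past the 10-aa overlap allowance and dropping one
true exon from the chain; at 10–20% divergence this costs a percent or
two of genes (a sensitivity, not a redundancy, effect). The same
behaviour is reproduced by an independent aligner, i.e. it is a
property of lenient local alignment, not an implementation artifact.

## Numerical and design choices

* Internal coordinates are 0-based half-open on the plus strand; GFF3
  output is 1-based inclusive. Minus-strand exons keep
  $P^{SC} > P^{EC}$ in plus coordinates, and the minus-strand
  compatibility conditions are applied directly rather than by
  remapping through reverse complements.
* One best local alignment is kept per (fragment, target) pair;
  sub-optimal alternate alignments of the same pair are not considered
  as additional exon candidates.
* Clustering uses the *first* (seeding) call of a cluster both for the
  share-an-exon test and for the scan horizon $m$, even though the
  final representative may be a different, higher-scoring member; the
  scan examines calls starting strictly before $m$.
* "Overlap" in overlap resolution means sharing at least one
  nucleotide; ties on E-value break by bit-score, then span start, then
  target id.
* Codons containing non-ACGT bases translate to `X`, which scores via
  the matrix's X column; trailing partial codons are discarded.
* Identity is counted over alignment columns (matches / alignment
  length), including the identity thresholds of the evaluation module
  and the taxonomy rank cutoffs (which are strict, as printed:
  identity 0.95 exactly is genus, not species).
* The benchmark mapping aligns proteins end-gap-free; mismatch columns
  are aligned non-identical residue pairs, gaps are free of mismatch
  charge but count in the column total.
* Lineages missing trailing ranks truncate to the deepest present rank.

## Limitations

Splice-site boundaries are approximate by design (the method recovers
protein-coding parts, not exact intron edges). Pseudogenes with
retained similarity can be reported. Genes spanning several contigs
yield partial, possibly split predictions. The built-in search is meant
for desk-scale references; for large databases, import externally
computed hits in BLAST tabular format via `import_hits_m8()`.
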