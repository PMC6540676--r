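---
title: "aflpcap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aflpcap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aflpcap)
```

# Scope

`aflpcap` models the computational side of AFLP-based sequence capture:
predicting the bait set a double-digest / selective-PCR protocol would
produce from a genome, and converting capture assemblies into
phylogenomic supermatrices and SNP matrices. Wet-lab chemistry (bead
cleanups, hybridization), read processing, de novo assembly, read
mapping, variant calling and tree inference are out of scope: the
package consumes assembled contigs and VCFs and emits matrices for
external phylogenetics tools.

# The in silico AFLP model

## Digestion

Each enzyme is an exact recognition site plus a 0-based top-strand cut
offset (MluI `A^CGCGT`, offset 1; SbfI `CCTGCA^GG`, offset 6). Cut
positions are `site start + offset` for every exact occurrence; windows
containing `N` never match; cuts falling on a sequence end are ignored
(they would create empty fragments). Fragments are the intervals
between consecutive cuts, with ends labeled by the cutting enzyme or
`"terminal"` at the extremities, so fragment sequences always
concatenate back to the input and fragment count equals cut count + 1.

Two modelling choices matter here. First, overhangs are not modeled: a
single top-strand coordinate defines each cut, because only fragment
identity matters downstream (bait capture is sequence-level, and the
4-nt stagger of both default enzymes is far below bait-length scale).
A consequence verified in the tests is that digesting a reverse
complement reproduces the cut set only after a per-enzyme stagger
correction of `site length − 2·offset`. Second, both default sites are
palindromic, so a single top-strand scan finds every site; the enzyme
constructor accepts arbitrary sites, but non-palindromic enzymes would
additionally need a bottom-strand scan, which is not implemented.

## Amplifiability, size selection, selective PCR

Y-adapter chemistry amplifies only fragments with one MluI and one SbfI
end; `adapter_compatible()` is that exact rule. Size selection keeps
lengths in an inclusive window (default 500–2,000 bp; the protocol
literature states the bounds without edge handling, and we chose
inclusivity as the less surprising convention).

Selective amplification normalizes each fragment so its MluI end is
leftmost (reverse-complementing when needed), then tests two positions:

* the sense-strand base immediately 3′ of the MluI remnant
  (`site length − offset` = 5 bases into the fragment), against the
  forward primer's selective base;
* the antisense-strand base immediately 3′ of the SbfI remnant
  (`offset` = 6 bases from the right end, complemented), against the
  reverse primer's selective base.

This is the primer-extension direction on each strand. The protocol
descriptions do not spell out the chemistry at base level; this
convention is the one under which a single-base pair of selective
primers retains 1/16 of compatible fragments with uniform insert
bases, which is the stated theoretical expectation. `N` at a tested
position never matches. Fragments shorter than both remnants plus two
bases cannot expose both tested positions and are rejected into a
`too_short_to_test` tally rather than silently dropped.

`pool_baits()` unions the per-combination products, deduplicated by
source coordinates, and warns when the count leaves the recommended
500–5,000 window. The theoretical fractions (1/16 per combination, 1/4
for the {A,T}×{C,G} pool) are defined over *amplifiable* fragments;
because the phrase "of the total digestion fragments" is ambiguous,
`design_baits()` reports the selective fraction against both
denominators (all digestion fragments, and adapter-compatible ones).

# Similarity search

The built-in aligner is a word-seeded Smith–Waterman: two sequences
with no shared exact k-mer (default k = 11, either strand) produce no
hit, otherwise an affine-gap optimal local alignment is computed by an
Rcpp Gotoh kernel and checked in the test suite against
`Biostrings::pairwiseAlignment` as an independent exhaustive oracle.
Scoring defaults are megablast-like: match +2, mismatch −3, gap open 5,
gap extend 2 (a gap of length *g* costs `5 + 2g`). Bit scores use the
Karlin–Altschul form with λ = 0.625 and K = 0.41, the published gapped
parameters for exactly this scoring system, and e-values are
`m·n·2^(−bits)` with the search space taken as query length × total
subject length. The intent is not to reproduce an external search
program's numbers bit-for-bit but to provide a self-contained engine
whose e-value ceiling (default 1e-10) filters comparably; externally
produced 12-column tabular files can be imported and are
interchangeable downstream.

Best-hit selection is a pure function of the hit table: maximal
bitscore, ties broken by lower e-value, longer alignment, then
lexicographically smallest subject id, so results never depend on row
order. Minus-strand hits keep the tabular convention `send < sstart`
and are only normalized at projection time, keeping imported tables
bit-faithful.

# Contig QC, redundancy, orthology

QC keeps contigs with length ≥ 200 bp and mean depth ≥ 5× (both
inclusive, both configurable); a missing depth under a positive
threshold is an input error naming the contig. Depths come from a
two-column TSV or assembler-style `cov_<float>` headers.

Redundancy reduction is greedy and longest-first: a contig joins an
existing representative when the best local hit's identical positions
amount to at least 95% of the shorter sequence, else it founds a new
cluster. Dedicated clustering tools use a global-identity definition;
with local hits the identities-over-shorter-length ratio is the closest
analogue, and the cutoff is exposed. The pipeline applies QC before
redundancy reduction; the reverse order is available by calling the two
steps directly.

Orthology follows the mutual-best-hit rule: sample contig *c* joins the
group anchored on reference contig *r* iff `best(c → ref) = r` and
`best(ref → sample) = c`, with both search directions actually executed
at the e-value ceiling. Each reference contig anchors at most one
group, each member belongs to at most one group, and samples without a
mutual pair are simply absent from that group. The reference (bait
sample) contributes each group's anchor sequence and participates in
trimming and alignment as an ordinary row.

# Optimal aligning region and matrices

Projection treats each member's linking hit as ungapped: a single
offset `(sstart − 1) − (qstart − 1)` places the whole member on
reference coordinates (minus-strand members are reverse-complemented
first, with their hit coordinates recomputed). This mirrors the use of
hit positions alone to determine relative positions; indels inside the
hit shift the projection by at most the hit's gap length, which the
subsequent multiple alignment absorbs.

With coverage `cov(p)` = number of member spans containing reference
column `p` and `k = ⌈threshold · n⌉`, the trim window is
`[min F, max F + 1)` over the feasible set `F = {p : cov(p) ≥ k}`. Both
boundary columns meet the threshold by construction; interior dips
below `k` are allowed because the rule constrains only the boundaries.
This is the widest window with feasible boundaries — no strictly wider
window can have both boundary columns feasible, which the tests verify
against a brute-force column scan. An empty feasible set rejects the
group with a distinct status rather than an error in batch runs.
Members whose span misses the window are dropped and logged; survivors
are cropped by interval intersection mapped back to member-local
coordinates.

The built-in multiple aligner is progressive center-star: the center is
the sequence with the highest summed global-alignment score to the
rest, remaining rows join in decreasing similarity to the center, and
pairwise gaps merge under once-a-gap-always-a-gap. This is adequate for
the short, high-identity rows the pipeline produces; for
publication-grade alignments any external aligner can be substituted
as a command template (e.g. `"mafft --auto {in} > {out}"`), and errors
from the external command are propagated with its diagnostics.

Row filtering computes pairwise similarity as identical characters over
columns where both rows are non-gap (0 when no columns are shared),
removes rows whose mean similarity to the others is strictly below 30%
in one pass over the original alignment, and realigns the survivors
exactly once — matching the single-pass description of the procedure
being modeled. A row at exactly the cutoff is kept.

The supermatrix keeps alignments with at least `min_taxa` rows. The
source descriptions disagree between "more than six taxa" and "at
least six species"; the default is the inclusive reading
(`min_taxa = 6`, kept at exactly six) with a `strict` flag for the
other. Loci concatenate in sorted og-id order, missing species are
gap-filled with `-`, partitions are 1-based inclusive and tile the
matrix exactly. Completeness by locus and species is filled cells over
species × loci; completeness by characters is non-gap characters over
species × total length — so flank-induced internal gaps lower only the
second statistic.

# SNP matrices

Site quality is the VCF `QUAL` column (a `GQ` option exists, using the
site's minimum per-sample genotype quality); the rule is strict
(`> 30`), following the wording "higher than 30". Filters tally in the
order quality → biallelic SNP → zero missing, and the tallies sum to
input minus output. Multi-allelic sites and indels are dropped rather
than split: the downstream matrix needs one column per site, and
dropping is the conservative choice. Heterozygotes become two-base
IUPAC codes (R, Y, S, W, K, M), phased and unphased separators are
equivalent, and missing calls use `?` by default. Zero-missing output
therefore contains no missing symbol at all, which the tests assert.

# Synthetic data: what it emulates and what it does not

The generators are seeded and deterministic (per-stage seeds derived
from a master seed, kept below 2³¹). `simulate_genome` draws i.i.d.
bases at a chosen GC fraction. `evolve_family` applies the Jukes–Cantor
substitution process at branch length *d*: each site mutates with
probability `(3/4)(1 − e^(−4d/3))` to a uniformly chosen different
base, so realized p-distances concentrate on the closed form (verified
in tests at 3 binomial standard errors). `simulate_contigs` adds
independent random flanks (uniform 0..`flank_length` per end) —
reproducing the staggered extents the boundary search exists to
handle — plus per-species dropout and log-normal depths
(`meanlog = log 20`, `sdlog = 0.5`, a typical capture-depth spread).
`simulate_vcf` plants exact counts of passing, low-quality,
multi-allelic and missing-genotype sites with QUAL values straddling
30.

What the synthetic regime deliberately lacks: indels (families evolve
without them by default, so alignments are trivially correct at the
substitution level), rate heterogeneity across sites, paralogy,
chimeric assembly, sequencing error, and base-composition drift
between species. Passing tests on this regime demonstrates the
*bookkeeping* is right — projections, windows, filters, matrices,
truth recovery — not that the pipeline is robust to assembly artifacts
in real data.

Default study conditions used by the test suite: ortholog families of
250–800 bp, 4–6 species, per-species divergences 0.05–0.30, flanks up
to 80 bp; amplification fractions are checked on 100,000 simulated
compatible fragments against 3 binomial standard errors; recovery and
contamination are checked at divergence ≤ 0.10 (where ≥ 90% of families
must be recovered with zero cross-family assignments), and mean
recovery must be non-increasing across divergences
{0.05, 0.10, 0.20, 0.30} by majority vote over five seeds — the
qualitative divergence–efficiency relationship observed in real
capture data.

# Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; hit tables are
  1-based inclusive (tabular dialect); partitions are 1-based
  inclusive (phylogenetics convention). Every writer documents its
  convention.
* Ties: best-hit ties break by e-value, length, then subject id;
  center-star center ties break lexicographically; equal cut positions
  from two enzymes keep the first enzyme's label.
* Degenerate inputs: empty fragment sets pass through every AFLP
  operation; a group losing all (or all but one) rows raises a typed
  `aflpcap_group_rejected` condition that batch drivers convert into a
  per-group rejection record; an empty SNP matrix cannot be written.
* The acceptance script derives its generator seeds from the
  command-line seed; both reported quantities are rule-bound minima
  (boundary coverage ≥ the 50% threshold by construction; retained-row
  similarity ≥ the 30% cutoff with wide margin at the simulated
  divergence), so they are stable across seeds.

# Known limitations

* The seed-and-extend aligner computes one best local alignment per
  pair; multiple HSPs, translated searches and low-complexity masking
  are not modeled.
* Center-star alignment is O(n²) in rows and less accurate than
  profile aligners on divergent or indel-rich data; use the external
  backend for such cases.
* Non-palindromic enzymes, ambiguity codes in recognition sites, PCR
  efficiency bias, incomplete digestion and methylation sensitivity
  are not modeled.
* Orthology is strictly 1:1; paralog families yield at most one member
  per sample and may drop loci entirely (the paralog-trap behaviour is
  tested).
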