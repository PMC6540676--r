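# aflpcap

In silico AFLP bait design and capture-data phylogenomics for R.

## The problem

AFLP-based sequence capture is a reduced-representation method for
non-model organisms: genomic DNA is digested with two restriction
enzymes (MluI, `A^CGCGT`, and SbfI, `CCTGCA^GG`), Y-adapters are
ligated so that only fragments carrying *both* adapter types amplify,
fragments are size-selected (500–2,000 bp), and selective PCR primers —
each carrying one extra 3′ nucleotide — amplify a predictable subset of
fragments that becomes the biotinylated bait pool. A primer pair with
one selective base per side amplifies 1/16 of the amplifiable
fragments in expectation; pooling the four combinations {A,T}×{C,G}
yields 1/4. A practical bait pool holds roughly 500–5,000 fragments.

`aflpcap` predicts that bait set from any genome sequence, and
implements the downstream analysis that turns capture assemblies into
phylogenomic matrices:

* **Contig QC** — keep contigs with length ≥ 200 bp and mean depth ≥ 5×;
  greedy longest-first redundancy reduction at 95% identity.
* **Orthology** — 1:1 orthology groups by mutual best hit (MBH) between
  each sample and the bait-sample reference, e-value ≤ 1e-10. The
  built-in aligner is a k-mer-seeded Smith–Waterman with
  Karlin–Altschul e-values; externally produced 12-column tabular hit
  files can be imported instead.
* **Optimal aligning region** — each member contig is projected onto
  reference coordinates through its linking hit; the trim window
  `[min F, max F + 1)` is taken over the feasible set
  `F = {p : cov(p) ≥ ⌈t·n⌉}` so that both boundary columns are covered
  by at least a fraction *t* (default 50%) of members.
* **Alignment filters and supermatrix** — progressive alignment
  (center-star, or an external aligner command), removal of rows whose
  mean pairwise similarity falls strictly below 30%, one realignment,
  a minimum-taxa rule (default 6), concatenation with partition records,
  and two completeness statistics: filled cells over species × loci, and
  non-gap characters over total matrix characters.
* **SNP matrices** — VCF sites filtered by quality (strictly > 30),
  biallelic-SNP and zero-missing rules, genotypes coded as IUPAC
  ambiguity characters, written as NEXUS / relaxed PHYLIP / FASTA.
* **Synthetic data** — seeded generators for random genomes,
  Jukes–Cantor ortholog families at chosen divergences, per-sample
  contigs with staggered flanks, dropout and simulated depths, and toy
  VCFs with planted filter classes, so every stage is testable with
  known truth.

## Worked example

```r
library(aflpcap)

ds <- simulate_capture_dataset(n_families = 8, n_species = 6,
                               divergence = 0.05, flank_length = 60,
                               seed = 42)
res <- run_capture_pipeline(ds$reference, ds$samples,
                            min_len = 0, min_depth = 0, min_taxa = 5)
print(res$groups)
print(res$supermatrix)
```

```
orthology_groups: 8 group(s)
  og0001 <- sp01_c001: 5 member(s)
  og0002 <- sp01_c002: 5 member(s)
  ...
supermatrix: 6 species x 5461 bp (8 loci)
  100.0% complete by locus and species, 93.0% by characters
```

Eight synthetic ortholog families were simulated for six species at
per-species branch length 0.05; all eight are recovered as MBH groups
with one member per non-reference sample, and the trimmed, filtered
alignments concatenate into a 5,461 bp supermatrix. Completeness by
characters (93%) is below completeness by locus (100%) because the
staggered flanks leave gap-filled margins inside loci.

SNP matrix from a toy VCF with planted filter classes:

```r
sim <- simulate_vcf(5, c(pass = 12, low_qual = 6, multi_allelic = 2,
                         with_missing = 3), seed = 42)
v <- filter_sites(read_vcf_sites(sim$path), min_qual = 30)
str(attr(v, "tally"))
```

```
List of 5
 $ n_input              : int 23
 $ removed_qual         : int 6
 $ removed_not_biallelic: int 2
 $ removed_missing      : int 3
 $ n_output             : int 12
```

The 12 surviving sites are exactly the planted "pass" class;
`build_snp_matrix()` then yields a 5-sample × 12-site IUPAC matrix and
`write_snp_matrix()` emits it as NEXUS.

Bait design runs directly on a genome FASTA:

```r
baits <- design_baits("genome.fa")        # digest -> adapters -> size -> PCR
write_bait_fasta(baits, "baits.fa")
```

A command-line wrapper with `digest`, `search`, `orthology`, `matrix`,
`snps` and `simulate` subcommands is installed at
`inst/cli/aflpcap.R`.

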