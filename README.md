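# svforge

Simulation of next-generation sequencing data with embedded structural
variants (SVs), for developing and benchmarking SV callers and tumour
heterogeneity methods. Deletions, insertions, tandem and inverted
duplications, inversions, translocations, compound events and foreign
(e.g. viral) insertions are spiked into haploid template sequences at
exact breakpoints, with per-variant ploidy and cell fraction — the
features needed to mimic germline, somatic and clonally structured
cancer genomes. Outputs are altered contigs (FASTA), paired-end reads
(FASTQ) and ground truth (BED), plus optional alignments through
external `bwa`/`samtools`.

## The model

**Clonal fractions from a phylogeny.** A clonal-evolution scenario is a
strictly binary tree whose internal nodes are bifurcation events: node
*j* carries variant label *V<sub>j</sub>* and the conditional fraction
*f(V<sub>j</sub>) ∈ [0,1]* of the parental population that gains it.
Each leaf *C<sub>i</sub>* is a terminal genotype described by a tertiary
path vector *c<sub>i,j</sub>* ∈ {0,1,2} (off path / on path without the
variant / on path carrying it). The final subpopulation frequency is

&nbsp;&nbsp;&nbsp;&nbsp;F(C<sub>i</sub>) = ∏<sub>j: c<sub>i,j</sub>&gt;0</sub> [(c<sub>i,j</sub>−1)·f(V<sub>j</sub>) + (2−c<sub>i,j</sub>)·(1−f(V<sub>j</sub>))]

and the marginal carrier fraction of each variant is

&nbsp;&nbsp;&nbsp;&nbsp;F(V<sub>j</sub>) = Σ<sub>i</sub> I(c<sub>i,j</sub>=2) F(C<sub>i</sub>).

`tree2var()` rewrites the allele-fraction column of a VAR file with
these marginal frequencies.

**Divide-and-conquer simulation.** The genome is tiled per chromosome
into *N* equal blocks B<sub>k</sub> = [G(k−1)/N + 1, Gk/N], with
ligation regions of length *l* straddling each interior boundary,
L<sub>k</sub> = [Gk/N − l/2 + 1, Gk/N + l/2]. Every variant becomes one
task over the block run it impacts; the gaps become size-capped no-op
tasks. Each task loads its block run plus half a ligation region on
each side, forges the altered contig per haplotype, and samples
paired-end reads — from the altered contig with weight equal to the
cell fraction and from the original with the complementary weight,
coverage split across the P haplotypes. Fragments lying entirely within
a flagged ligation zone are sampled at half rate, so merged coverage is
uniform across block boundaries. Every task carries a pre-assigned
seed, making the output a pure function of (inputs, master seed)
regardless of worker count.

## Worked example

```r
library(svforge)
set.seed(1)
template <- Biostrings::DNAStringSet(c(chr1 = randomDna(50000)))
vars <- SVVariantSet(
  vid      = c("del1", "dup1", "ins1"),
  fraction = c(0.5, 1.0, 0.3),
  ploidy   = c("2/1", "2/1,2", "2/2"),
  chrom    = "chr1",
  pos      = c(12000L, 30000L, 44000L),
  del_len  = c(2000L, 1500L, 0L),
  ins_seq  = c("", "", randomDna(400)),
  svtype   = c("DEL", "DUP", "INS"))
lib <- SVLibrarySet(insert_mean = 300, insert_sd = 30,
                    read_len = 100, coverage = 30)
man <- mutforge(template, var = vars, par = lib, out_dir = "demo",
                level = "read", plan_size = 5000, ligation = 1000,
                seed = 7)
man$tasks
#>   ordinal n_contigs n_pairs
#> 1       1         1    1484
#> 2       2         2     718
#> 3       3         1    1525
#> 4       4         3    1789
#> 5       5         1     829
#> 6       6         2     770
#> 7       7         1     790
```

Seven tasks tile the 50 kb template: three variant tasks (one per
event) and four no-op tasks. The heterozygous deletion task (ordinal 2)
contributes its original contig plus one altered haplotype; the
homozygous duplication task (ordinal 4) contributes two altered
haplotypes. The 7,905 read pairs land in `demo/sim.read1.fq` /
`demo/sim.read2.fq`, the contigs in `demo/sim.contigs.fa`, and the
ground truth — BED3 intervals followed by the full VAR columns — in
`demo/sim.truth.bed`, all listed with checksums in
`demo/sim.manifest.tsv`.

Rewriting fractions from the example clonal tree:

```r
tree <- readClonalTree(system.file("extdata", "example_clonal_tree.nwk",
                                   package = "svforge"))
round(variantFrequencies(tree), 3)
#>   V1   V5   V2   V4   V3
#> 0.50 0.40 0.30 0.24 0.18
```

The root event is carried by half of all cells; downstream events on a
carrying lineage always have lower frequency.

Command-line wrappers for batch use live in `inst/cli/`
(`mutforge.R`, `tree2var.R`).

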