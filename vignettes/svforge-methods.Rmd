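---
title: "Simulating structural variants with clonal allele fractions: methods and design"
author: "svforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating structural variants with clonal allele fractions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svforge)
```

# What the package simulates

svforge spikes structural variants into haploid template sequences and
simulates Illumina-like paired-end reads from the result. Its purpose
is to produce sequencing data whose read-mapping signatures (coverage
changes, insert-size shifts, clipped/split and hanging read pairs) are
faithful to the embedded events, together with exact ground truth, so
that variant callers and tumour-heterogeneity estimators can be
benchmarked against a known answer. Three properties distinguish the
design: per-variant control of breakpoint, ploidy and cell fraction;
clonal structure expressed as a phylogeny and converted to allele
fractions; and a divide-and-conquer execution scheme whose output is a
pure function of the inputs and one master seed, at any worker count.

# The clonal-frequency model

A clonal scenario is a strictly binary tree. Each internal node $j$ is
a bifurcation: a fraction $f(V_j) \in [0,1]$ of the parental population
gains variant $V_j$, the rest do not. Leaves are terminal genotypes.
For leaf $i$ and node $j$ the tertiary path code $c_{i,j}$ is 0 when
node $j$ is not on the root-to-leaf path, 1 when it is on the path but
the lineage did not gain $V_j$, and 2 when it did. The final
subpopulation frequency is the product over on-path nodes

$$F(C_i) = \prod_{j:\,c_{i,j}>0}
  \left[(c_{i,j}-1)\,f(V_j) + (2-c_{i,j})\,(1-f(V_j))\right],$$

i.e. $f$ where the lineage carries the variant and $1-f$ where it does
not, and the marginal carrier fraction of a variant is the sum over
carrying leaves,

$$F(V_j) = \sum_i I(c_{i,j}=2)\, F(C_i).$$

Two structural consequences follow and are enforced as property tests:
$\sum_i F(C_i) = 1$ for any tree and fractions, and on a carrying
lineage an upstream event's $F$ is never smaller than a downstream
event's. A leaf can reach $F = 0$ (a deceased population) whenever a
fraction on its path is 0 or 1.

**Which child gains.** NEWICK encodes the tree with internal-node
labels and fractions as branch weights, e.g.

```
((C1, C2) V5: 0.8, ((C3, C4) V4:0.8, (C5, C6) V3: 0.9) V2:0.6) V1:0.5
```

but it does not say which of the two children is the gaining
subpopulation. svforge adopts the convention that the *first-listed*
child gains, and exposes `gaining = "second"` on `readClonalTree()` for
the mirrored reading. Under the default convention the example tree
gives

```{r}
tree <- readClonalTree(system.file("extdata", "example_clonal_tree.nwk",
                                   package = "svforge"))
round(leafFrequencies(tree), 3)
round(variantFrequencies(tree), 3)
```

The root's marginal frequency equals its conditional fraction under
either convention; the distribution of the downstream values depends on
the convention, which is why it is explicit and configurable. The test
suite cross-checks every closed-form value against an independent
Monte-Carlo oracle that pushes $10^6$ cells through the bifurcation
cascade with binomial splits and counts carriers.

**Multiclonal origins.** The reserved internal label `-` denotes an
empty event: its fraction shapes the split but rewrites no VAR record.
A two-clonal-origin tumour is encoded as an empty root whose two child
events carry conditional fraction 1.0, making each subclone fully
clonal within its lineage partition.

**Leaf weights.** NEWICK leaf weights are accepted as informational
annotation only; `tree2var()` warns when they disagree with the
computed $F(C_i)$ and always uses the computed values.

# Control-file dialects

Three tab-delimited, `#`-headed dialects drive a run. Column orders
are fixed by this package (the field inventories are standard, an
authoritative column order is not), and all readers reject violations
with line-addressed diagnostics.

* **VAR** — exact variants:
  `vid pid fraction ploidy chrom pos del_len ins_seq [svtype]`.
  Coordinates are 1-based inclusive. `ploidy` is `P/h1,h2,...` (total
  haploid count and altered haplotype indices) with shorthands `hom`
  (all haplotypes) and `het` (haplotype 1). `ins_seq` is literal
  sequence, a template-segment reference `seg:chrom:start-end:strand`
  (the insertion arm of a translocation; `-` strand means reverse
  complement), or a foreign reference `fasta:record:strand` (e.g. a
  viral genome; `*` selects the first record). `svtype` is optional on
  input and inferred from the edit fields when absent.
* **META** — variant distributions:
  `svtype count size_dist fraction_dist ploidy_dist [foreign_source]`.
  Distribution tokens are `family:params` with families `fixed:v`,
  `uniform:a,b`, `normal:mu,sd` (sizes truncated to $\ge 1$),
  `bernoulli:p` (zygosity: success = homozygous), plus the `hom`/`het`
  shorthands.
* **PAR** — sequencing libraries:
  `insert_mean insert_sd read_len coverage base_error [snv_rate indel_rate]`,
  one library per line. Multiple lines form a normal mixture (total
  coverage is the sum), the intended way to model irregular multi-modal
  insert-size distributions.

Ground truth is BED3 — 0-based, half-open, sorted by (chrom, start) —
with the full VAR columns appended, so it round-trips to the input
specification. A pure insertion is reported as `[pos-1, pos)`, the base
before the insertion point, because BED requires nonzero width.
Compound events keep their group label (`pid`); a group must have at
least two member rows or name another record, and members must agree on
fraction and ploidy.

# Editing semantics

All edits reduce to one splice per variant, applied in slice-local
coordinates (genome-to-slice conversion happens once, at task
construction, so the off-by-one audit lives in one place):

* `DEL` removes `[pos, pos+del_len-1]`;
* `INS` inserts `ins_seq` before `pos`;
* `DUP` inserts a copy of the segment immediately after itself (copy
  number 2; higher copy numbers are expressed as repeated `INS` rows
  sharing a `pid`);
* `IDUP` inserts the reverse-complemented copy after the segment;
* `INV` replaces the segment with its reverse complement;
* translocations are two coordinated rows — a deletion arm at the
  source and an insertion arm at the destination whose payload is the
  source segment, extracted once from the *unaltered* template by
  `resolveCompound()` before task dispatch. Omitting the deletion arm
  leaves the source intact (a duplicated translocation); the `-` strand
  inverts the inserted copy.

The reverse complement is IUPAC-aware and case-preserving at the string
level; contigs are however stored and emitted through Biostrings
containers, which normalise case, so soft-masking does not survive into
products. Haplotype handling is by construction isolating: the edit is
applied to the haplotypes named in the ploidy code and the original
sequence serves all others. The forge path is validated against an
independently written naive string-edit oracle on $10^4$ randomized
cases, plus involution checks (double inversion, delete-after-insert)
and exact length accounting.

# Block grid, tasks and reproducibility

Each chromosome of length $G$ is tiled with $N$ equal blocks
$B_k = [G(k-1)/N + 1,\, Gk/N]$ of `plan_size` bp (chromosome-end blocks
may be shorter), and ligation regions
$L_k = [Gk/N - l/2 + 1,\, Gk/N + l/2]$ of length $l$ straddle interior
boundaries. A variant claims the run of blocks overlapped by its impact
region — $[pos, pos+del\_len-1]$ for deleting events, $[pos-1, pos]$
for pure insertions — padded by one ligation length. The guard keeps
every breakpoint out of every ligation region (the forge refuses
otherwise), so the attenuated zones at contig ends are always identical
sequence between the original and altered contig. Two variants claiming
the same block are refused with a re-plan diagnostic rather than
silently merged: one variant per task is the contract that keeps tasks
independent. Unclaimed gaps become no-op tasks capped at `trunk_size`
blocks (default 10).

Each task loads its block run extended by $l/2$ into each neighbouring
block and carries a seed derived deterministically from (master seed,
task ordinal), fixed at planning time. Workers therefore commute:
serial execution and a fork pool of any size produce byte-identical
FASTA/FASTQ/BED, which the test suite verifies by checksum at 1 versus
4 workers. Merged outputs are ordered by task ordinal, never by
completion order.

META expansion draws each event's size, fraction and zygosity from the
stated distributions and places it uniformly at random over the space
that can still accommodate it (target regions minus mask, if given).
After each placement the claimed block run plus a one-ligation guard is
removed from the available space — slightly greedier than removing the
impact region alone, but it guarantees the one-variant-per-block-run
contract holds for every expansion. Placement failure names the META
line and the remaining space. A chi-square test over 1,000 seeded
expansions confirms uniformity of placed starts at $\alpha = 0.001$.

# Read sampling and the ligation rule

For each (library, haplotype, source contig) the expected pair count is
$w \cdot (c/P) \cdot L/(2R)$ — weight, per-haplotype coverage, contig
length, read length — where an altered haplotype draws from the altered
contig with weight equal to the cell fraction and from the original
with the complement, so a large deletion automatically yields
proportionally fewer pairs. Realised counts are Poisson; fragment
starts are uniform; insert sizes are normal per library, resampled
while shorter than $2R$ or longer than the contig; mates face inward
(FR) with read 1 on a fair-coin strand. Qualities are constant at
Phred $\mathrm{round}(-10\log_{10}\max(\texttt{base\_error}, 10^{-4}))$;
substitution errors hit each base independently; `snv_rate` and
`indel_rate` plant small variants once per contig *before* sampling, so
overlapping reads agree on the planted allele. `base_error` defaults
to 0 so benchmarks stay deterministic unless errors are requested.

**The half-rate rule.** A ligation region is simulated twice — once
with each adjacent contig. To compensate, fragments are retained with
probability 0.5 when they lie *entirely inside* a flagged zone. The
containment predicate (isolated in one function) was a deliberate
design choice over the simpler "fragment start inside the zone" rule:
a fragment wholly inside the overlap can be generated by both
neighbouring contigs, so halving each side restores the exact rate,
while a fragment that only partially overlaps the zone can be generated
by exactly one contig and must keep its full rate. The start rule
attenuates, at the far edge of the overlap, fragments whose twin the
other contig cannot generate at all, leaving an insert-sized coverage
trough after merging; the containment rule makes the merged expectation
exactly uniform, which the test suite checks as a step-free profile
across a block boundary. Per contig, deep inside a 1 kb zone with a
300 bp insert, the sampled rate is 50% of the interior rate, with
insert-sized transition bands at the zone edges whose deficit and
excess roughly cancel in the zone mean (measured 47–52% over seeds).

The default ligation length is $2(\mu + 3\sigma)$ over the configured
libraries, so no valid fragment spans more than one zone; it must stay
below `plan_size` (default 1 Mb).

# Mapping-feature expectations

`alteredToRefMap()`/`refFrameDepth()` fold sampled reads back onto
template coordinates the way an aligner would: reads inside a deletion
vanish (depth $\approx 0$ at cell fraction 1, half the flank at 0.5),
a tandem duplication's copies stack ($(1+f)\times$ flank depth at
fraction $f$), and pairs straddling a deletion imply a reference-frame
insert of the library mean plus the deleted length. The acceptance
tests verify all three on a 100 kb toy genome at 60x within three
Poisson/binomial standard errors, allowing for the length-biased
selection of straddling fragments ($+\sigma^2/(\mu - 2R + 1)$ bp).

# Synthetic templates, problem sizes and what the tests show

Templates are uniform-composition random DNA (`randomDna()`), which
exercises every code path but lacks repeats, GC bias, homopolymers and
low-complexity tracts; the simulator likewise models no platform error
profile (flat qualities, no quality ramps or homopolymer indels) and no
microhomology or untemplated insertions at breakpoints. Passing tests
therefore demonstrate correctness of the coordinate arithmetic,
frequency model, sampling weights and determinism contract — not
realism of base-level error structure. Test and acceptance problem
sizes were chosen as the smallest that leave the stochastic checks
well-powered: 10–100 kb templates, 15–60x coverage, $10^6$ Monte-Carlo
cells, 1,000 random trees, $10^4$ forge cases.

# Numerical and degenerate-input choices

* Floating comparisons in the frequency model use absolute tolerance
  $10^{-9}$ ($10^{-12}$ for the normalisation identity).
* Fraction distributions are resampled into $[0,1]$; sizes are rounded
  and truncated to $\ge 1$ bp.
* A chromosome shorter than `plan_size` is a single block with no
  ligation regions; a contig shorter than the minimum insert yields
  zero pairs with a warning; a zero-coverage library yields an empty
  stream; an empty variant set produces valid, header-only ground
  truth.
* Insert-size resampling falls back to the clamped mean after 1,000
  failed rounds (pathological parameter combinations only).
* Per-task seeds come from an integer hash of (master seed, ordinal),
  kept below $2^{31}$; identical inputs and seed give identical bytes.

# Known limitations

Copy-number control beyond one extra tandem copy requires explicit
repeated rows; ground truth is BED-based (no VCF emission); alignment
output delegates entirely to external `bwa mem`/`samtools` and is
exercised only when those executables are present; long-read platforms
are out of scope. The dialects' column orders are this package's own
convention and are documented above precisely because no external
standard fixes them.
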