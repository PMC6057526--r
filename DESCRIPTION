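Package: svforge
Title: Structural Variant Spike-In Simulation with Clonal Allele Fractions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates next-generation sequencing data with embedded
    structural variants. Deletions, insertions, tandem and inverted
    duplications, inversions, translocations and compound events are
    spiked into haploid template sequences at user-controlled
    breakpoints, ploidies and cell fractions, optionally structured by
    a clonal-evolution phylogeny whose bifurcation fractions are
    converted into per-variant allele fractions. A divide-and-conquer
    block/ligation-region scheme partitions the genome into independent
    tasks so simulation parallelises without changing the output:
    paired-end reads are sampled from original and altered contigs in
    proportion to allele fraction and contig length, with half-rate
    sampling inside ligation overlaps so merged coverage stays uniform.
    Outputs are altered contigs (FASTA), read pairs (FASTQ) and
    ground-truth records (BED), driven by tab-delimited VAR/META/PAR
    control files and NEWICK clonal trees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Software, Sequencing, StructuralVariation, DataImport
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'formats-var.R'
    'clonal-tree.R'
    'formats-output.R'
    'planner.R'
    'forge.R'
    'readsim.R'
    'engine.R'
    'cli.R'
    'formats-meta-par.R'
    'measure.R'
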