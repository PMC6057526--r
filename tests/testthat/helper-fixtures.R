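# Shared fixtures, generated in code.

# the worked clonal-evolution example tree
EXAMPLE_NEWICK <-
    "((C1, C2) V5: 0.8, ((C3, C4) V4:0.8, (C5, C6) V3: 0.9) V2:0.6) V1:0.5"

# frozen closed-form frequencies for the example tree under the
# first-listed-child-gains convention (verified against the Monte-Carlo
# population oracle in test-clonal-tree.R)
EXAMPLE_LEAF_F <- c(C1 = 0.40, C2 = 0.10, C3 = 0.24, C4 = 0.06,
                    C5 = 0.18, C6 = 0.02)
EXAMPLE_VAR_F <- c(V1 = 0.50, V2 = 0.30, V3 = 0.18, V4 = 0.24, V5 = 0.40)

exampleTree <- function(...) readClonalTree(text = EXAMPLE_NEWICK, ...)

writeTempLines <- function(lines, ext = ".txt") {
    path <- withr::local_tempfile(fileext = ext,
                                  .local_envir = parent.frame())
    writeLines(lines, path)
    path
}

# a small VAR file with one heterozygous deletion
simpleVarLines <- function() {
    c("#vid\tpid\tfraction\tploidy\tchrom\tpos\tdel_len\tins_seq",
      "v1\t.\t0.5\t2/1\tchr1\t1001\t500\t.")
}

templateSet <- function(lengths, seed = 99) {
    withr::with_seed(seed,
        Biostrings::DNAStringSet(vapply(lengths, randomDna, character(1))))
}

stdLib <- function(coverage = 60, read_len = 100, insert_mean = 300,
                   insert_sd = 30, ...) {
    SVLibrarySet(insert_mean = insert_mean, insert_sd = insert_sd,
                 read_len = read_len, coverage = coverage, ...)
}

# random strictly binary clonal tree over `labels`, random fractions;
# uses the current RNG state
randomNewick <- function(labels) {
    counter <- new.env()
    assign("i", 0L, counter)
    build <- function(tips) {
        if (length(tips) == 1L) return(tips)
        k <- sample(length(tips) - 1L, 1L)
        i <- get("i", counter) + 1L
        assign("i", i, counter)
        sprintf("(%s,%s)X%d:%g", build(tips[seq_len(k)]),
                build(tips[-seq_len(k)]), i, round(runif(1), 4))
    }
    build(labels)
}
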