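#' @import methods
#' @importFrom S4Vectors isConstant
NULL

setOldClass("phylo")

## Column inventory of the VAR dialect, in file order.  `svtype` is optional
## on input (inferred from the edit fields) but always present internally.
.VAR_COLUMNS <- c("vid", "pid", "fraction", "ploidy", "chrom", "pos",
                  "del_len", "ins_seq", "svtype")

.META_COLUMNS <- c("svtype", "count", "size_dist", "fraction_dist",
                   "ploidy_dist", "foreign_source")

.PAR_COLUMNS <- c("insert_mean", "insert_sd", "read_len", "coverage",
                  "base_error", "snv_rate", "indel_rate")

.SVTYPES <- c("DEL", "INS", "DUP", "IDUP", "INV", "TRA", "ITRA")

#' Set of structural variant specifications
#'
#' An \code{SVVariantSet} holds one row per spike-in event: identifier,
#' optional compound-group label (\code{pid}), cell fraction, ploidy code
#' (\code{"P/h1,h2"}, or the shorthands \code{"hom"}/\code{"het"}), template
#' chromosome, 1-based start, deleted length, inserted sequence (literal,
#' \code{"seg:chrom:start-end:strand"} template-segment reference, or
#' \code{"fasta:record:strand"} foreign reference) and the symbolic variant
#' type used for ground-truth reporting.
#'
#' @slot variants data.frame with the VAR columns.
#' @export
setClass("SVVariantSet", representation(variants = "data.frame"))

setValidity("SVVariantSet", function(object) {
    v <- object@variants
    if (!identical(colnames(v), .VAR_COLUMNS))
        return(sprintf("variants must have columns %s",
                       paste(.VAR_COLUMNS, collapse = ", ")))
    if (nrow(v) == 0L)
        return(TRUE)
    msg <- character()
    if (anyDuplicated(v$vid))
        msg <- c(msg, sprintf("duplicate variant id(s): %s",
                 paste(unique(v$vid[duplicated(v$vid)]), collapse = ", ")))
    bad <- which(!is.finite(v$fraction) | v$fraction < 0 | v$fraction > 1)
    if (length(bad))
        msg <- c(msg, sprintf("fraction outside [0,1] at record %d", bad[1L]))
    bad <- which(v$pos < 1L)
    if (length(bad))
        msg <- c(msg, sprintf("pos < 1 at record %d", bad[1L]))
    bad <- which(v$del_len < 0L)
    if (length(bad))
        msg <- c(msg, sprintf("del_len < 0 at record %d", bad[1L]))
    ## events that neither delete nor insert are vacuous; segment/foreign
    ## references count as insertions even before resolution
    vac <- which(v$del_len == 0L & !nzchar(v$ins_seq) &
                 !(v$svtype %in% c("DUP", "IDUP", "INV", "TRA", "ITRA")))
    if (length(vac))
        msg <- c(msg, sprintf("record %d has del_len 0 and empty ins_seq",
                              vac[1L]))
    pl <- lapply(v$ploidy, .parsePloidy)
    bad <- which(vapply(pl, function(p) is.null(p), logical(1)))
    if (length(bad))
        msg <- c(msg, sprintf("unparsable ploidy code '%s' at record %d",
                              v$ploidy[bad[1L]], bad[1L]))
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Set of variant meta-distributions
#'
#' One row per variant class to generate: type, event count, and the
#' size / fraction / ploidy distributions as \code{family:params} tokens
#' (families \code{fixed}, \code{uniform}, \code{normal}, \code{bernoulli},
#' plus the ploidy shorthands \code{hom} and \code{het}).
#'
#' @slot meta data.frame with the META columns.
#' @export
setClass("SVMetaSet", representation(meta = "data.frame"))

setValidity("SVMetaSet", function(object) {
    m <- object@meta
    if (!identical(colnames(m), .META_COLUMNS))
        return(sprintf("meta must have columns %s",
                       paste(.META_COLUMNS, collapse = ", ")))
    if (nrow(m) == 0L)
        return(TRUE)
    if (any(m$count < 0L))
        return("count must be >= 0")
    for (i in seq_len(nrow(m))) {
        for (col in c("size_dist", "fraction_dist", "ploidy_dist")) {
            d <- tryCatch(.parseDist(m[[col]][i]), error = function(e) e)
            if (inherits(d, "error"))
                return(sprintf("row %d, %s: %s", i, col,
                               conditionMessage(d)))
        }
    }
    TRUE
})

#' Set of sequencing-library specifications
#'
#' One row per library: insert-size mean and standard deviation (bp), read
#' length (bp), haploid-genome fold coverage contributed by the library,
#' per-base substitution error rate, and optional contig-level SNV and
#' indel planting rates.
#'
#' @slot libraries data.frame with the PAR columns.
#' @export
setClass("SVLibrarySet", representation(libraries = "data.frame"))

setValidity("SVLibrarySet", function(object) {
    p <- object@libraries
    if (!identical(colnames(p), .PAR_COLUMNS))
        return(sprintf("libraries must have columns %s",
                       paste(.PAR_COLUMNS, collapse = ", ")))
    if (nrow(p) == 0L)
        return(TRUE)
    if (any(p$insert_mean <= 0)) return("insert_mean must be > 0")
    if (any(p$insert_sd < 0)) return("insert_sd must be >= 0")
    if (any(p$read_len < 1)) return("read_len must be >= 1")
    if (any(p$coverage < 0)) return("coverage must be >= 0")
    for (col in c("base_error", "snv_rate", "indel_rate"))
        if (any(p[[col]] < 0 | p[[col]] > 1))
            return(sprintf("%s must lie in [0,1]", col))
    TRUE
})

#' Clonal-evolution binary tree
#'
#' A strictly binary phylogeny of tumour subpopulations.  Each internal
#' node carries the label of the structural variant gained at that
#' bifurcation and the conditional fraction \eqn{f(V)} of the parental
#' population that gains it; leaves are terminal genotypes.  Which child
#' subtree gains the variant is a convention (\code{gaining}), defaulting
#' to the first-listed child of the NEWICK string.
#'
#' @slot phylo an \code{ape} \code{phylo} object (cladewise, input order).
#' @slot fractions numeric, conditional fraction per internal node, indexed
#'   by internal node number minus the tip count; names are variant labels.
#' @slot gaining \code{"first"} or \code{"second"}.
#' @export
setClass("ClonalTree",
         representation(phylo = "phylo", fractions = "numeric",
                        gaining = "character"))

setValidity("ClonalTree", function(object) {
    phy <- object@phylo
    m <- phy$Nnode
    n <- length(phy$tip.label)
    if (n != m + 1L)
        return("tree is not strictly binary (need n leaves = m + 1)")
    kids <- tabulate(phy$edge[, 1L], nbins = n + m)
    if (any(kids[(n + 1L):(n + m)] != 2L))
        return("every internal node must have exactly two children")
    if (length(object@fractions) != m)
        return("need one conditional fraction per internal node")
    f <- object@fractions
    if (any(!is.finite(f) | f < 0 | f > 1))
        return("conditional fractions must lie in [0,1]")
    labs <- names(f)
    real <- labs[labs != "-"]
    if (anyDuplicated(real))
        return("internal variant labels must be unique")
    if (anyDuplicated(phy$tip.label))
        return("leaf genotype labels must be unique")
    if (!object@gaining %in% c("first", "second"))
        return("gaining must be 'first' or 'second'")
    TRUE
})

#' Block/ligation partition of a template genome
#'
#' Each chromosome is tiled independently with non-overlapping blocks of
#' (at most) \code{plan_size} bp; chromosome-end blocks may be shorter.
#' A ligation region of length \code{ligation} straddles every interior
#' block boundary symmetrically and buffers the hand-off between the
#' per-task simulations.
#'
#' @slot blocks GRanges of the blocks, with per-chromosome \code{block}
#'   indices in \code{mcols}.
#' @slot ligations GRanges of the ligation regions.
#' @slot plan_size numeric, the planned block size in bp.
#' @slot ligation numeric, the ligation-region length in bp (even).
#' @slot seqlengths named integer vector of chromosome lengths.
#' @export
setClass("BlockGrid",
         representation(blocks = "GRanges", ligations = "GRanges",
                        plan_size = "numeric", ligation = "numeric",
                        seqlengths = "integer"))

setValidity("BlockGrid", function(object) {
    if (object@plan_size <= object@ligation)
        return("plan_size must exceed the ligation length")
    if (object@ligation < 0 || object@ligation %% 2 != 0)
        return("ligation length must be a non-negative even number")
    bl <- object@blocks
    for (chr in names(object@seqlengths)) {
        b <- bl[as.character(GenomicRanges::seqnames(bl)) == chr]
        if (length(b) == 0L)
            return(sprintf("chromosome %s has no blocks", chr))
        b <- b[order(GenomicRanges::start(b))]
        if (GenomicRanges::start(b)[1L] != 1L ||
            GenomicRanges::end(b)[length(b)] != object@seqlengths[[chr]])
            return(sprintf("blocks do not span chromosome %s", chr))
        if (length(b) > 1L &&
            any(GenomicRanges::start(b)[-1L] !=
                GenomicRanges::end(b)[-length(b)] + 1L))
            return(sprintf("blocks do not tile chromosome %s", chr))
    }
    TRUE
})

#' Task plan for a simulation run
#'
#' Ordered list of contiguous block runs, each carrying either one variant
#' payload or a no-op instruction, plus the per-task load interval
#' (block run extended by half a ligation length on each side), the
#' ligation flags for its two ends and a pre-assigned task seed.
#'
#' @slot tasks data.frame, one row per task in dispatch (ordinal) order.
#' @slot variants SVVariantSet holding the payload records.
#' @slot grid the BlockGrid the plan was built on.
#' @export
setClass("TaskPlan",
         representation(tasks = "data.frame", variants = "SVVariantSet",
                        grid = "BlockGrid"))

#' Original/altered contig pair produced by forging
#'
#' @slot chrom template sequence name.
#' @slot offset genome coordinate of the slice start (1-based).
#' @slot original DNAString, the unedited template slice.
#' @slot altered DNAStringSet, one edited sequence per altered haplotype
#'   (possibly empty for no-op contigs).
#' @slot altered_haps integer indices of the altered haplotypes.
#' @slot ploidy total haploid count P.
#' @slot breakpoints data.frame of altered-contig breakpoint coordinates.
#' @export
setClass("ContigPair",
         representation(chrom = "character", offset = "numeric",
                        original = "DNAString", altered = "DNAStringSet",
                        altered_haps = "integer", ploidy = "integer",
                        breakpoints = "data.frame"))

setValidity("ContigPair", function(object) {
    if (length(object@altered) != length(object@altered_haps))
        return("one altered sequence per altered haplotype required")
    if (length(object@altered_haps) &&
        (any(object@altered_haps < 1L) ||
         any(object@altered_haps > object@ploidy)))
        return("altered haplotype indices must lie in 1..P")
    TRUE
})
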