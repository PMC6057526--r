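#' @include formats-var.R
#' @importFrom Biostrings DNAString DNAStringSet writeXStringSet
#'   readDNAStringSet reverseComplement QualityScaledDNAStringSet
#'   PhredQuality writeQualityScaledXStringSet
#' @importFrom GenomicRanges GRanges start end seqnames reduce setdiff
#' @importFrom IRanges IRanges coverage
NULL

#' Write simulated contigs to FASTA
#'
#' @param contigs a named \code{DNAStringSet} (or named character vector)
#'   of original and altered contigs.
#' @param path output FASTA file.
#' @return Invisibly, \code{path}.
#' @export
writeSimFasta <- function(contigs, path) {
    if (!is(contigs, "DNAStringSet"))
        contigs <- DNAStringSet(contigs)
    writeXStringSet(contigs, path)
    invisible(path)
}

#' Write a read-pair set to two FASTQ files
#'
#' Record k of the read-1 file and record k of the read-2 file share one
#' name stem (\code{"contig:ordinal"}), suffixed \code{/1} and \code{/2}.
#' Qualities are Sanger Phred+33.
#'
#' @param pairs a data.frame of read pairs as produced by
#'   \code{\link{samplePairs}} (columns \code{name}, \code{seq1},
#'   \code{seq2}, \code{qual1}, \code{qual2}).
#' @param path1,path2 output FASTQ files for read 1 and read 2.
#' @return Invisibly, \code{c(path1, path2)}.
#' @export
writeFastqPair <- function(pairs, path1, path2) {
    if (length(pairs$seq1) != length(pairs$seq2))
        stop("internal consistency error: read-1/read-2 counts differ")
    .writeFastq(pairs$seq1, pairs$qual1, paste0(pairs$name, "/1"), path1)
    .writeFastq(pairs$seq2, pairs$qual2, paste0(pairs$name, "/2"), path2)
    invisible(c(path1, path2))
}

.writeFastq <- function(seqs, quals, names, path) {
    if (length(seqs) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    x <- QualityScaledDNAStringSet(DNAStringSet(setNames(seqs, names)),
                                   PhredQuality(quals))
    writeQualityScaledXStringSet(x, path)
    invisible(path)
}

#' Read a FASTQ file into sequences and qualities
#'
#' @param path FASTQ file.
#' @return A \code{QualityScaledDNAStringSet}.
#' @export
readFastq <- function(path) {
    ## metadata-column drop warning from the quality pairing is noise here
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}

## 1-based inclusive variant interval -> 0-based half-open BED interval.
## Pure insertions get [pos-1, pos), the base before the insertion point,
## since BED requires nonzero width.
.bedInterval <- function(pos, del_len) {
    start0 <- ifelse(del_len > 0L, pos - 1L, pos - 1L)
    end0 <- ifelse(del_len > 0L, pos - 1L + del_len, pos)
    cbind(start = start0, end = end0)
}

#' Write the ground-truth BED file
#'
#' BED3 intervals of every spiked-in variant, sorted by (chrom, start),
#' with the full VAR columns appended after the third column so the file
#' round-trips to the input specification.
#'
#' @param variants an \linkS4class{SVVariantSet}.
#' @param path output BED file.
#' @return Invisibly, \code{path}.
#' @export
writeGroundTruthBed <- function(variants, path) {
    stopifnot(is(variants, "SVVariantSet"))
    v <- variants@variants
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#chrom\tstart\tend\t",
                      paste(.VAR_COLUMNS, collapse = "\t")), con)
    if (nrow(v)) {
        iv <- .bedInterval(v$pos, v$del_len)
        ord <- order(v$chrom, iv[, "start"])
        v <- v[ord, , drop = FALSE]
        iv <- iv[ord, , drop = FALSE]
        out <- cbind(v$chrom, iv[, "start"], iv[, "end"],
                     v$vid, .emptyToDot(v$pid),
                     format(v$fraction, digits = 15), v$ploidy, v$chrom,
                     v$pos, v$del_len, .emptyToDot(v$ins_seq), v$svtype)
        writeLines(apply(out, 1L, paste, collapse = "\t"), con)
    }
    invisible(path)
}

#' Read a ground-truth BED file back into variant specifications
#'
#' @param path a BED file written by \code{\link{writeGroundTruthBed}}.
#' @return An \linkS4class{SVVariantSet} (sorted by chrom, start).
#' @export
readGroundTruthBed <- function(path) {
    raw <- .readControlFile(path, 12L, 12L, "ground-truth BED")
    if (length(raw$fields) == 0L)
        return(SVVariantSet())
    m <- t(vapply(raw$fields, identity, character(12)))
    vs <- SVVariantSet(vid = m[, 4L], pid = .dotToEmpty(m[, 5L]),
                       fraction = .numField(m[, 6L], raw$lineno, "BED",
                                            "fraction"),
                       ploidy = m[, 7L], chrom = m[, 8L],
                       pos = as.integer(m[, 9L]),
                       del_len = as.integer(m[, 10L]),
                       ins_seq = .dotToEmpty(m[, 11L]), svtype = m[, 12L])
    validObject(vs)
    vs
}

#' Read mask/target regions from a BED3 file
#'
#' @param path BED file of regions (mask or target).
#' @return A \code{GRanges} (1-based, as used internally), or \code{NULL}
#'   when \code{path} is \code{NULL}.
#' @export
readBedRegions <- function(path) {
    if (is.null(path))
        return(NULL)
    gr <- rtracklayer::import(path, format = "BED")
    GenomicRanges::granges(gr)
}
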