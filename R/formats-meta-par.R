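#' @include utils.R
NULL

#' Construct a set of variant meta-distributions
#'
#' @param svtype variant classes (DEL, INS, DUP, IDUP, INV).
#' @param count events to generate per class.
#' @param size_dist,fraction_dist,ploidy_dist distribution tokens
#'   (\code{family:params}; families \code{fixed}, \code{uniform},
#'   \code{normal}, \code{bernoulli}, and the ploidy shorthands
#'   \code{hom}/\code{het}).
#' @param foreign_source optional FASTA path for foreign insertions ("").
#' @return An \linkS4class{SVMetaSet}.
#' @export
SVMetaSet <- function(svtype = character(), count = integer(),
                      size_dist = character(), fraction_dist = character(),
                      ploidy_dist = "bernoulli:0.5", foreign_source = "") {
    n <- length(svtype)
    m <- data.frame(svtype = as.character(svtype),
                    count = rep_len(as.integer(count), n),
                    size_dist = rep_len(as.character(size_dist), n),
                    fraction_dist = rep_len(as.character(fraction_dist), n),
                    ploidy_dist = rep_len(as.character(ploidy_dist), n),
                    foreign_source = rep_len(as.character(foreign_source), n),
                    stringsAsFactors = FALSE)
    new("SVMetaSet", meta = m)
}

#' Read a META file
#'
#' The META dialect gives higher-level control than VAR: one line per
#' variant class with the number of events and the size, allele-fraction
#' and ploidy distributions, e.g.
#' \code{DEL<tab>100<tab>uniform:100,10000<tab>uniform:0,1<tab>bernoulli:0.5}
#' for 100 deletions of 100 bp-10 kb with uniform allelic fraction and a
#' fair homo/heterozygosity coin.
#'
#' @param path file to read.
#' @return An \linkS4class{SVMetaSet}.
#' @seealso \code{\link{expandMeta}} to draw concrete variants.
#' @export
readMeta <- function(path) {
    raw <- .readControlFile(path, 5L, 6L, "META")
    if (length(raw$fields) == 0L)
        return(SVMetaSet())
    m <- t(vapply(raw$fields, function(f) c(f, rep("", 6L - length(f)))[1:6],
                  character(6)))
    count <- .numField(m[, 2L], raw$lineno, "META", "count")
    bad <- which(count < 0)
    if (length(bad))
        stop(sprintf("META validation error at line %d: negative count",
                     raw$lineno[bad[1L]]))
    ms <- SVMetaSet(svtype = m[, 1L], count = as.integer(count),
                    size_dist = m[, 3L], fraction_dist = m[, 4L],
                    ploidy_dist = m[, 5L],
                    foreign_source = .dotToEmpty(m[, 6L]))
    validObject(ms)
    ms
}

#' Write a META file
#'
#' @param meta an \linkS4class{SVMetaSet}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeMeta <- function(meta, path) {
    stopifnot(is(meta, "SVMetaSet"))
    m <- meta@meta
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", paste(.META_COLUMNS, collapse = "\t")), con)
    if (nrow(m))
        writeLines(apply(cbind(m$svtype, m$count, m$size_dist,
                               m$fraction_dist, m$ploidy_dist,
                               .emptyToDot(m$foreign_source)),
                         1L, paste, collapse = "\t"), con)
    invisible(path)
}

#' @rdname accessors
#' @export
setMethod("metaTable", "SVMetaSet", function(x) x@meta)

#' @export
setMethod("length", "SVMetaSet", function(x) nrow(x@meta))

setMethod("show", "SVMetaSet", function(object) {
    cat(sprintf("SVMetaSet with %d distribution line(s), %d event(s) total\n",
                nrow(object@meta), sum(object@meta$count)))
    if (nrow(object@meta))
        print(object@meta, row.names = FALSE)
})

#' Construct a set of sequencing-library specifications
#'
#' @param insert_mean mean template insert size (bp).
#' @param insert_sd insert-size standard deviation (bp).
#' @param read_len read length (bp).
#' @param coverage haploid-genome fold coverage contributed by the library.
#' @param base_error per-base substitution error rate.
#' @param snv_rate,indel_rate optional contig-level small-variant rates.
#' @return An \linkS4class{SVLibrarySet}.
#' @export
SVLibrarySet <- function(insert_mean = numeric(), insert_sd = 0,
                         read_len = integer(), coverage = numeric(),
                         base_error = 0, snv_rate = 0, indel_rate = 0) {
    n <- length(insert_mean)
    p <- data.frame(insert_mean = as.numeric(insert_mean),
                    insert_sd = rep_len(as.numeric(insert_sd), n),
                    read_len = rep_len(as.integer(read_len), n),
                    coverage = rep_len(as.numeric(coverage), n),
                    base_error = rep_len(as.numeric(base_error), n),
                    snv_rate = rep_len(as.numeric(snv_rate), n),
                    indel_rate = rep_len(as.numeric(indel_rate), n),
                    stringsAsFactors = FALSE)
    obj <- new("SVLibrarySet", libraries = p)
    short <- p$insert_mean < 2 * p$read_len
    if (any(short))
        warning(sprintf("library %d: insert_mean < 2*read_len; fragments will be resampled aggressively",
                        which(short)[1L]))
    obj
}

#' Read a PAR file
#'
#' One sequencing library per line:
#' \code{insert_mean insert_sd read_len coverage base_error [snv_rate indel_rate]}.
#' Multiple lines describe a normal mixture of libraries (e.g. short- and
#' long-insert preparations); total coverage is the sum over lines.
#'
#' @param path file to read.
#' @return An \linkS4class{SVLibrarySet}.
#' @export
readPar <- function(path) {
    raw <- .readControlFile(path, 5L, 7L, "PAR")
    if (length(raw$fields) == 0L)
        return(SVLibrarySet())
    m <- t(vapply(raw$fields, function(f) c(f, rep("0", 7L - length(f)))[1:7],
                  character(7)))
    num <- lapply(seq_len(7L), function(j)
        .numField(m[, j], raw$lineno, "PAR", .PAR_COLUMNS[j]))
    if (any(num[[2L]] < 0))
        stop(sprintf("PAR validation error at line %d: negative insert_sd",
                     raw$lineno[which(num[[2L]] < 0)[1L]]))
    ps <- SVLibrarySet(insert_mean = num[[1L]], insert_sd = num[[2L]],
                       read_len = as.integer(num[[3L]]), coverage = num[[4L]],
                       base_error = num[[5L]], snv_rate = num[[6L]],
                       indel_rate = num[[7L]])
    validObject(ps)
    ps
}

#' Write a PAR file
#'
#' @param libraries an \linkS4class{SVLibrarySet}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writePar <- function(libraries, path) {
    stopifnot(is(libraries, "SVLibrarySet"))
    p <- libraries@libraries
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", paste(.PAR_COLUMNS, collapse = "\t")), con)
    if (nrow(p))
        writeLines(apply(format(p, digits = 15, trim = TRUE), 1L,
                         paste, collapse = "\t"), con)
    invisible(path)
}

#' @rdname accessors
#' @export
setMethod("libraryTable", "SVLibrarySet", function(x) x@libraries)

#' @export
setMethod("length", "SVLibrarySet", function(x) nrow(x@libraries))

setMethod("show", "SVLibrarySet", function(object) {
    p <- object@libraries
    cat(sprintf("SVLibrarySet with %d librar%s, %.1fx total coverage\n",
                nrow(p), if (nrow(p) == 1L) "y" else "ies",
                sum(p$coverage)))
    if (nrow(p))
        print(p, row.names = FALSE)
})
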