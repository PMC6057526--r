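#' @include utils.R
NULL

#' Construct a set of variant specifications
#'
#' @param vid unique variant identifiers.
#' @param pid compound-group labels ("" for simple events).
#' @param fraction cell fractions in [0,1].
#' @param ploidy ploidy codes ("P/h1,h2", "hom", "het").
#' @param chrom template sequence names.
#' @param pos 1-based start positions.
#' @param del_len deleted lengths (segment lengths for DUP/IDUP/INV).
#' @param ins_seq inserted sequences, "" for none; may be a
#'   \code{"seg:chrom:start-end:strand"} or \code{"fasta:record:strand"}
#'   reference until resolved by \code{\link{resolveCompound}}.
#' @param svtype symbolic types (one of DEL, INS, DUP, IDUP, INV, TRA,
#'   ITRA); inferred from the edit fields when \code{NA}.
#' @return An \linkS4class{SVVariantSet}.
#' @examples
#' SVVariantSet(vid = "v1", fraction = 0.5, ploidy = "2/1",
#'              chrom = "chr1", pos = 1001, del_len = 500)
#' @export
SVVariantSet <- function(vid = character(), pid = "", fraction = numeric(),
                         ploidy = "2/1", chrom = character(),
                         pos = integer(), del_len = 0L, ins_seq = "",
                         svtype = NA_character_) {
    n <- length(vid)
    v <- data.frame(vid = as.character(vid),
                    pid = rep_len(as.character(pid), n),
                    fraction = rep_len(as.numeric(fraction), n),
                    ploidy = rep_len(as.character(ploidy), n),
                    chrom = rep_len(as.character(chrom), n),
                    pos = rep_len(as.integer(pos), n),
                    del_len = rep_len(as.integer(del_len), n),
                    ins_seq = rep_len(as.character(ins_seq), n),
                    svtype = rep_len(as.character(svtype), n),
                    stringsAsFactors = FALSE)
    v$svtype <- ifelse(is.na(v$svtype) | v$svtype == "",
                       .inferSvtype(v$del_len, v$ins_seq), v$svtype)
    new("SVVariantSet", variants = v)
}

.inferSvtype <- function(del_len, ins_seq) {
    ifelse(del_len > 0L & !nzchar(ins_seq), "DEL",
    ifelse(del_len == 0L & nzchar(ins_seq), "INS", "INS"))
}

#' Read a VAR file
#'
#' The VAR dialect is a tab-delimited, \code{#}-headed table specifying
#' exact per-variant information, one event per line, with columns
#' \code{vid pid fraction ploidy chrom pos del_len ins_seq [svtype]}.
#' \code{"."} denotes an empty field.  Record order is preserved.
#'
#' @param path file to read.
#' @return An \linkS4class{SVVariantSet}.
#' @seealso \code{\link{writeVar}} for the lossless inverse.
#' @export
readVar <- function(path) {
    raw <- .readControlFile(path, 8L, 9L, "VAR")
    if (length(raw$fields) == 0L)
        return(SVVariantSet())
    m <- t(vapply(raw$fields, function(f) c(f, rep("", 9L - length(f)))[1:9],
                  character(9)))
    fraction <- .numField(m[, 3L], raw$lineno, "VAR", "fraction")
    bad <- which(fraction < 0 | fraction > 1)
    if (length(bad))
        stop(sprintf("VAR validation error at line %d: fraction %g outside [0,1]",
                     raw$lineno[bad[1L]], fraction[bad[1L]]))
    pos <- as.integer(.numField(m[, 6L], raw$lineno, "VAR", "pos"))
    del_len <- as.integer(.numField(m[, 7L], raw$lineno, "VAR", "del_len"))
    vs <- SVVariantSet(vid = m[, 1L], pid = .dotToEmpty(m[, 2L]),
                       fraction = fraction, ploidy = m[, 4L],
                       chrom = m[, 5L], pos = pos, del_len = del_len,
                       ins_seq = .dotToEmpty(m[, 8L]),
                       svtype = ifelse(nzchar(.dotToEmpty(m[, 9L])),
                                       m[, 9L], NA_character_))
    validObject(vs)
    vs
}

#' Write a VAR file
#'
#' Writes all nine VAR columns so that \code{readVar(writeVar(x))} is the
#' identity, including verbatim foreign/segment insertion references.
#'
#' @param variants an \linkS4class{SVVariantSet}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeVar <- function(variants, path) {
    stopifnot(is(variants, "SVVariantSet"))
    v <- variants@variants
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", paste(.VAR_COLUMNS, collapse = "\t")), con)
    if (nrow(v)) {
        out <- cbind(v$vid, .emptyToDot(v$pid), format(v$fraction, digits = 15),
                     v$ploidy, v$chrom, v$pos, v$del_len,
                     .emptyToDot(v$ins_seq), v$svtype)
        writeLines(apply(out, 1L, paste, collapse = "\t"), con)
    }
    invisible(path)
}

#' @rdname accessors
#' @export
setMethod("variantTable", "SVVariantSet", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("variantIds", "SVVariantSet", function(x) x@variants$vid)

#' @rdname accessors
#' @export
setMethod("fractions", "SVVariantSet",
          function(x) setNames(x@variants$fraction, x@variants$vid))

#' @rdname accessors
#' @export
setReplaceMethod("fractions", "SVVariantSet", function(x, value) {
    if (!is.null(names(value))) {
        idx <- match(names(value), x@variants$vid)
        if (anyNA(idx))
            stop(sprintf("unknown variant id(s): %s",
                         paste(names(value)[is.na(idx)], collapse = ", ")))
        x@variants$fraction[idx] <- unname(value)
    } else {
        x@variants$fraction <- rep_len(value, nrow(x@variants))
    }
    validObject(x)
    x
})

#' @export
setMethod("length", "SVVariantSet", function(x) nrow(x@variants))

setMethod("show", "SVVariantSet", function(object) {
    v <- object@variants
    cat(sprintf("SVVariantSet with %d variant(s)\n", nrow(v)))
    if (nrow(v)) {
        tab <- table(v$svtype)
        cat("  types:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = " "), "\n")
        print(head(v, 5L), row.names = FALSE)
        if (nrow(v) > 5L)
            cat(sprintf("  ... and %d more\n", nrow(v) - 5L))
    }
})
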