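#' @include planner.R
NULL

## Effective single-string edit realised by a variant row, in slice-local
## 1-based coordinates.  Every supported class reduces to "delete
## `del` bases at `at`, then insert `ins` before what remains at `at`".
## DUP/IDUP/INV derive their inserted sequence from the template segment.
.effectiveEdit <- function(seq, pos_local, del_len, ins_seq, svtype) {
    L <- nchar(seq)
    seg <- if (del_len > 0L) substr(seq, pos_local, pos_local + del_len - 1L)
           else ""
    switch(svtype,
        DUP = list(at = pos_local + del_len, del = 0L, ins = seg,
                   bp_label = "dup_copy"),
        IDUP = list(at = pos_local + del_len, del = 0L,
                    ins = .revcompChar(seg), bp_label = "dup_copy"),
        INV = list(at = pos_local, del = del_len, ins = .revcompChar(seg),
                   bp_label = "inverted_segment"),
        list(at = pos_local, del = del_len, ins = ins_seq,
             bp_label = if (del_len > 0L && !nzchar(ins_seq)) "del_junction"
                        else "inserted_segment"))
}

.applyEdit <- function(seq, edit) {
    L <- nchar(seq)
    if (edit$at < 1L || edit$at + edit$del - 1L > L)
        stop("edit exceeds the loaded slice")
    paste0(substr(seq, 1L, edit$at - 1L), edit$ins,
           substr(seq, edit$at + edit$del, L))
}

#' Apply one variant to a template slice
#'
#' Produces the altered contig for every haplotype carrying the variant,
#' at exact base-pair breakpoints.  Semantics by \code{svtype}: DEL
#' removes \code{[pos, pos+del_len-1]}; INS inserts \code{ins_seq} before
#' \code{pos}; DUP inserts a tandem copy of the segment immediately after
#' itself; IDUP inserts its reverse complement after the segment; INV
#' replaces the segment with its reverse complement; TRA/ITRA rows carry
#' either a deletion arm or an insertion arm of a translocation (resolved
#' to literal sequence by \code{\link{resolveCompound}}).  Reverse
#' complement is IUPAC-aware; output contigs are normalised to uppercase
#' by the \code{DNAString} container.
#'
#' @param original the loaded template slice (\code{DNAString} or
#'   character scalar) covering the task's load interval.
#' @param variant one row of an \linkS4class{SVVariantSet} (a one-row
#'   data.frame or a length-one set), with resolved literal \code{ins_seq};
#'   \code{NULL} for a no-op contig.
#' @param offset genome coordinate of the slice start (1-based);
#'   \code{variant$pos} is converted to slice-local coordinates here, the
#'   only place genome and slice coordinates meet.
#' @param chrom template sequence name for the pair.
#' @param lig_left,lig_right lengths (bp) of the ligation buffers at the
#'   slice ends; breakpoints falling inside them violate the planning
#'   contract and raise an error.
#' @param default_ploidy ploidy used to resolve hom/het shorthand codes.
#' @return A \linkS4class{ContigPair}.
#' @examples
#' cp <- forgeContig("ACGTACGT",
#'   variantTable(SVVariantSet(vid = "d", fraction = 1, ploidy = "1/1",
#'     chrom = "c", pos = 3, del_len = 2)), offset = 1, chrom = "c")
#' as.character(alteredContigs(cp)[[1]])   # "ACACGT"
#' @export
forgeContig <- function(original, variant = NULL, offset = 1L,
                        chrom = "chr", lig_left = 0L, lig_right = 0L,
                        default_ploidy = 2L) {
    seq <- if (is(original, "DNAString") || is(original, "DNAStringSet"))
        as.character(original) else as.character(original)
    if (is(variant, "SVVariantSet"))
        variant <- variantTable(variant)
    if (is.null(variant) || nrow(variant) == 0L)
        return(new("ContigPair", chrom = chrom, offset = as.numeric(offset),
                   original = DNAString(seq), altered = DNAStringSet(),
                   altered_haps = integer(),
                   ploidy = as.integer(default_ploidy),
                   breakpoints = data.frame(label = character(),
                                            start_alt = integer(),
                                            end_alt = integer())))
    if (nrow(variant) != 1L)
        stop("forgeContig applies exactly one variant per task")
    pl <- .parsePloidy(variant$ploidy, default_ploidy)
    if (is.null(pl))
        stop(sprintf("unparsable ploidy code '%s'", variant$ploidy))
    p_local <- as.integer(variant$pos - offset + 1L)
    L <- nchar(seq)
    if (p_local < 1L || p_local + max(variant$del_len - 1L, 0L) > L)
        stop(sprintf("variant %s impact region outside the loaded slice",
                     variant$vid))
    ins <- variant$ins_seq
    if (grepl(":", ins, fixed = TRUE))
        stop(sprintf(
            "variant %s carries an unresolved insertion reference '%s'; run resolveCompound() first",
            variant$vid, ins))
    edit <- .effectiveEdit(seq, p_local, as.integer(variant$del_len),
                           ins, variant$svtype)
    imp <- .impactRegion(p_local, as.integer(variant$del_len))
    if ((lig_left > 0L && imp[1L] <= lig_left) ||
        (lig_right > 0L && imp[2L] > L - lig_right))
        stop(sprintf(
            "planning-contract violation: breakpoint of %s inside a ligation buffer",
            variant$vid))
    altered <- .applyEdit(seq, edit)
    bp <- data.frame(label = paste0(variant$vid, ":", edit$bp_label),
                     start_alt = edit$at,
                     end_alt = edit$at + max(nchar(edit$ins), 1L) - 1L,
                     stringsAsFactors = FALSE)
    haps <- pl$haps
    alt_set <- DNAStringSet(setNames(rep(altered, length(haps)),
                                     sprintf("h%d", haps)))
    new("ContigPair", chrom = chrom, offset = as.numeric(offset),
        original = DNAString(seq), altered = alt_set,
        altered_haps = as.integer(haps), ploidy = pl$P, breakpoints = bp)
}

#' @rdname accessors
#' @export
setMethod("alteredContigs", "ContigPair", function(x) x@altered)

#' @rdname accessors
#' @export
setMethod("originalContig", "ContigPair", function(x) x@original)

setMethod("show", "ContigPair", function(object) {
    cat(sprintf(
        "ContigPair on %s @%g: original %d bp, %d altered haplotype(s)%s\n",
        object@chrom, object@offset, length(object@original),
        length(object@altered_haps),
        if (length(object@altered))
            sprintf(" of %d bp", Biostrings::width(object@altered)[1L])
        else ""))
})

## ins_seq reference grammar:
##   "seg:<chrom>:<start>-<end>:<strand>"  template segment (translocations)
##   "<fasta>:<record>:<strand>"           foreign FASTA record ("*" = first)
## anything without ":" is literal sequence.
.isReference <- function(ins_seq) grepl(":", ins_seq, fixed = TRUE)

.resolveReference <- function(token, template, foreign = NULL) {
    parts <- strsplit(token, ":", fixed = TRUE)[[1L]]
    if (parts[1L] == "seg") {
        if (length(parts) != 4L || !grepl("^[0-9]+-[0-9]+$", parts[3L]))
            stop(sprintf("malformed segment reference '%s'", token))
        chrom <- parts[2L]
        se <- as.integer(strsplit(parts[3L], "-", fixed = TRUE)[[1L]])
        if (!chrom %in% names(template))
            stop(sprintf("segment reference '%s': unknown chromosome", token))
        if (se[1L] < 1L || se[2L] > length(template[[chrom]]) ||
            se[2L] < se[1L])
            stop(sprintf("segment reference '%s' out of bounds", token))
        seq <- as.character(Biostrings::subseq(template[[chrom]],
                                               se[1L], se[2L]))
        strand <- parts[4L]
    } else {
        if (length(parts) != 3L)
            stop(sprintf("malformed foreign reference '%s'", token))
        src <- parts[1L]
        path <- if (!is.null(foreign) && src %in% names(foreign))
            foreign[[src]] else src
        if (!file.exists(path))
            stop(sprintf("foreign FASTA '%s' not found for reference '%s'",
                         path, token))
        fa <- readDNAStringSet(path)
        names(fa) <- sub("\\s.*$", "", names(fa))
        rec <- parts[2L]
        if (rec == "*")
            rec <- names(fa)[1L]
        if (!rec %in% names(fa))
            stop(sprintf("record '%s' not in foreign FASTA '%s'", rec, path))
        seq <- as.character(fa[[rec]])
        strand <- parts[3L]
    }
    if (!strand %in% c("+", "-"))
        stop(sprintf("reference '%s': strand must be '+' or '-'", token))
    if (strand == "-") .revcompChar(seq) else seq
}

#' Resolve compound events and insertion references
#'
#' Validates compound groups (rows sharing a non-empty \code{pid}) and
#' materialises every insertion reference into literal sequence before
#' task dispatch: template-segment references (\code{seg:chrom:start-end:strand},
#' the insertion arms of translocations; \code{-} strand means reverse
#' complement) are extracted from the unaltered template once, and
#' foreign references (\code{fasta:record:strand}, e.g. a viral genome)
#' are read from their FASTA.  Group members must agree on fraction and
#' ploidy; a singleton group (dangling pid) or a pid naming its own row
#' (cycle) is rejected.
#'
#' @param variants an \linkS4class{SVVariantSet}.
#' @param template named \code{DNAStringSet} of the template genome.
#' @param foreign optional named list/vector mapping foreign source names
#'   to FASTA paths (an unmapped name is tried as a path itself).
#' @return The \linkS4class{SVVariantSet} with all \code{ins_seq} literal.
#' @export
resolveCompound <- function(variants, template, foreign = NULL) {
    stopifnot(is(variants, "SVVariantSet"))
    v <- variants@variants
    grp <- v$pid[nzchar(v$pid)]
    if (length(grp)) {
        cyc <- which(nzchar(v$pid) & v$pid == v$vid)
        if (length(cyc))
            stop(sprintf("pid cycle: record %s names itself as parent",
                         v$vid[cyc[1L]]))
        tab <- table(grp)
        dang <- names(tab)[tab < 2L]
        ## a singleton member may legitimately point at another record
        dang <- dang[!dang %in% v$vid]
        if (length(dang))
            stop(sprintf("dangling pid(s): %s", paste(dang, collapse = ", ")))
        for (g in unique(grp)) {
            rows <- v[v$pid == g, , drop = FALSE]
            if (length(unique(rows$fraction)) > 1L)
                stop(sprintf("fraction mismatch within compound group '%s'",
                             g))
            if (length(unique(rows$ploidy)) > 1L)
                stop(sprintf("ploidy mismatch within compound group '%s'", g))
        }
    }
    refs <- which(.isReference(v$ins_seq))
    for (i in refs)
        v$ins_seq[i] <- .resolveReference(v$ins_seq[i], template, foreign)
    variants@variants <- v
    validObject(variants)
    variants
}
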