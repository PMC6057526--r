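#' @include readsim.R
NULL

#' Map altered-contig coordinates back to the reference frame
#'
#' For an altered contig produced by a single edit, gives the reference
#' (original-slice) coordinate of every altered base: bases of a tandem
#' duplication's extra copy fold back onto the duplicated segment,
#' inverted bases map to their mirrored positions, bases downstream of a
#' deletion shift right, and inserted bases map to \code{NA} (they have
#' no reference position).
#'
#' @param alt_len length of the altered contig.
#' @param pos slice-local 1-based variant start.
#' @param del_len deleted/segment length.
#' @param svtype variant class (DEL, INS, DUP, IDUP, INV).
#' @param ins_len inserted length (INS only).
#' @return Integer vector of length \code{alt_len}; reference coordinate
#'   per altered base, \code{NA} for novel sequence.
#' @export
alteredToRefMap <- function(alt_len, pos, del_len, svtype, ins_len = 0L) {
    i <- seq_len(alt_len)
    switch(svtype,
        DEL = ifelse(i < pos, i, i + del_len),
        INS = ifelse(i < pos, i,
              ifelse(i < pos + ins_len, NA_integer_, i - ins_len)),
        DUP = ifelse(i < pos + del_len, i, i - del_len),
        IDUP = ifelse(i < pos + del_len, i,
               ifelse(i < pos + 2L * del_len,
                      2L * pos + 2L * del_len - 1L - i,   # mirrored copy
                      i - del_len)),
        INV = ifelse(i >= pos & i < pos + del_len,
                     2L * pos + del_len - 1L - i, i),
        stop(sprintf("no reference-frame map for svtype '%s'", svtype)))
}

#' Reference-frame read depth of a sampled pair set
#'
#' Computes per-base depth on the source contig and accumulates it onto
#' reference coordinates through a coordinate map, emulating what an
#' aligner would report: reads inside a deletion vanish from the
#' reference, a tandem duplication's two copies stack up, and so on.
#'
#' @param pairs read pairs from \code{\link{samplePairs}} (one contig).
#' @param map integer map from \code{\link{alteredToRefMap}} (use
#'   \code{seq_len(len)} for an unaltered contig).
#' @param ref_len reference length to report over.
#' @return Numeric depth vector of length \code{ref_len}.
#' @export
refFrameDepth <- function(pairs, map, ref_len) {
    cov <- pairCoverage(pairs, length(map))
    keep <- !is.na(map)
    depth <- numeric(ref_len)
    acc <- tapply(cov[keep], map[keep], sum)
    idx <- as.integer(names(acc))
    ok <- idx >= 1L & idx <= ref_len
    depth[idx[ok]] <- acc[ok]
    depth
}
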