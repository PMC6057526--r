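#' @include formats-output.R
NULL

#' Partition a template genome into blocks and ligation regions
#'
#' Each chromosome is tiled independently with non-overlapping blocks of
#' \code{plan_size} bp (the final block of a chromosome may be shorter);
#' a ligation region of \code{ligation} bp straddles every interior block
#' boundary symmetrically (\code{ligation/2} bp on each side).  Ligation
#' regions never span chromosome boundaries.  A chromosome shorter than
#' the planned block size becomes a single block with no ligation regions.
#'
#' @param genome named integer vector of chromosome lengths, or a
#'   \code{DNAStringSet} template.
#' @param plan_size planned block size in bp (default 1 Mb).
#' @param ligation ligation-region length in bp; rounded up to an even
#'   number; must be smaller than \code{plan_size}.
#' @return A \linkS4class{BlockGrid}.
#' @examples
#' grid <- planBlocks(c(chr1 = 1000L), plan_size = 100, ligation = 20)
#' blocks(grid)[1:2]
#' ligationRegions(grid)[1]
#' @export
planBlocks <- function(genome, plan_size = 1e6, ligation = 1000) {
    if (is(genome, "DNAStringSet"))
        genome <- setNames(Biostrings::width(genome), names(genome))
    seqlens <- as.integer(genome)
    names(seqlens) <- names(genome)
    if (is.null(names(seqlens)) || any(!nzchar(names(seqlens))))
        stop("chromosome lengths must be named")
    ligation <- as.integer(ceiling(ligation / 2) * 2)
    if (plan_size <= ligation)
        stop("plan_size must exceed the ligation length")
    bl <- list(); lg <- list()
    for (chr in names(seqlens)) {
        L <- seqlens[[chr]]
        N <- max(1L, as.integer(ceiling(L / plan_size)))
        st <- as.integer((seq_len(N) - 1L) * plan_size + 1L)
        en <- as.integer(pmin(seq_len(N) * plan_size, L))
        bl[[chr]] <- data.frame(chrom = chr, start = st, end = en,
                                idx = seq_len(N))
        if (N > 1L) {
            bnd <- en[-N]                 # interior block boundaries
            lg[[chr]] <- data.frame(chrom = chr,
                start = pmax(1L, bnd - ligation %/% 2L + 1L),
                end = pmin(L, bnd + ligation %/% 2L),
                idx = seq_len(N - 1L))
        }
    }
    bl <- do.call(rbind, bl)
    blocks <- GRanges(bl$chrom, IRanges(bl$start, bl$end), block = bl$idx,
                      seqlengths = seqlens)
    ligs <- if (length(lg)) {
        lg <- do.call(rbind, lg)
        GRanges(lg$chrom, IRanges(lg$start, lg$end), boundary = lg$idx,
                seqlengths = seqlens)
    } else GRanges(boundary = integer())
    new("BlockGrid", blocks = blocks, ligations = ligs,
        plan_size = as.numeric(plan_size), ligation = as.numeric(ligation),
        seqlengths = seqlens)
}

#' @rdname accessors
#' @export
setMethod("blocks", "BlockGrid", function(x) x@blocks)

#' @rdname accessors
#' @export
setMethod("ligationRegions", "BlockGrid", function(x) x@ligations)

setMethod("show", "BlockGrid", function(object) {
    cat(sprintf(
        "BlockGrid: %d chromosome(s), %d block(s) (plan %g bp), %d ligation region(s) (%g bp)\n",
        length(object@seqlengths), length(object@blocks),
        object@plan_size, length(object@ligations), object@ligation))
})

## impact region of one variant row on the template, 1-based inclusive
.impactRegion <- function(pos, del_len) {
    if (del_len > 0L) c(pos, pos + del_len - 1L) else c(max(1L, pos - 1L), pos)
}

#' Expand variant meta-distributions into concrete variants
#'
#' Draws \code{count} events per META line with sizes, fractions and
#' zygosities from the stated distributions, placing each event uniformly
#' at random among the template positions that can still accommodate it.
#' After each placement the impacted block run, padded by one ligation
#' length, is removed from the available space, so placed events map to
#' pairwise disjoint block runs (the planner's one-variant-per-task
#' contract) and breakpoints stay clear of ligation regions.
#'
#' @param meta an \linkS4class{SVMetaSet}.
#' @param grid a \linkS4class{BlockGrid} for the target template.
#' @param mask optional \code{GRanges} of regions to avoid.
#' @param target optional \code{GRanges} restricting placement (default:
#'   the whole genome).
#' @param ploidy total haploid count used to resolve hom/het draws.
#' @param foreign optional named list mapping META \code{foreign_source}
#'   names to FASTA paths (referenced, not loaded, at expansion time).
#' @return An \linkS4class{SVVariantSet} in generation order.  Uses the
#'   current RNG state; seed it for reproducible expansions.
#' @export
expandMeta <- function(meta, grid, mask = NULL, target = NULL,
                       ploidy = 2L, foreign = NULL) {
    stopifnot(is(meta, "SVMetaSet"), is(grid, "BlockGrid"))
    genome <- GRanges(names(grid@seqlengths),
                      IRanges(1L, unname(grid@seqlengths)))
    avail <- if (is.null(target)) genome else
        GenomicRanges::intersect(reduce(target), genome,
                                 ignore.strand = TRUE)
    if (!is.null(mask))
        avail <- GenomicRanges::setdiff(avail, reduce(mask),
                                        ignore.strand = TRUE)
    m <- meta@meta
    out <- list()
    type_counter <- integer()
    lig <- as.integer(grid@ligation)
    for (i in seq_len(nrow(m))) {
        sdist <- .parseDist(m$size_dist[i])
        fdist <- .parseDist(m$fraction_dist[i])
        pdist <- .parseDist(m$ploidy_dist[i])
        svtype <- m$svtype[i]
        for (k in seq_len(m$count[i])) {
            size <- max(1L, as.integer(round(.drawDist(sdist))))
            frac <- .drawFraction(fdist)
            pl <- .drawPloidy(pdist, ploidy)
            span <- if (svtype == "INS") 2L else size
            pos <- .placeEvent(avail, span)
            if (is.na(pos))
                stop(sprintf(
                    "placement failure for META line %d (%s, event %d of %d): %d bp of eligible space left for a %d bp event",
                    i, svtype, k, m$count[i],
                    sum(GenomicRanges::width(avail)), span))
            type_counter[svtype] <-
                (if (is.na(type_counter[svtype])) 0L
                 else type_counter[svtype]) + 1L
            ins <- ""
            del <- size
            if (svtype == "INS") {
                pos <- pos + 1L           # span was [pos-1, pos]
                del <- 0L
                ins <- if (nzchar(m$foreign_source[i]))
                    sprintf("%s:*:+", m$foreign_source[i])
                else randomDna(size)
            }
            out[[length(out) + 1L]] <- data.frame(
                vid = sprintf("%s%d", svtype, type_counter[svtype]),
                pid = "", fraction = frac, ploidy = pl,
                chrom = as.character(seqnames(avail))[
                    .containingRange(avail, pos)],
                pos = pos, del_len = del, ins_seq = ins, svtype = svtype,
                stringsAsFactors = FALSE)
            rec <- out[[length(out)]]
            imp <- .impactRegion(rec$pos, rec$del_len)
            claimed <- .claimedRun(grid, rec$chrom, imp, lig)
            avail <- GenomicRanges::setdiff(avail,
                GRanges(rec$chrom, IRanges(max(1L, claimed$start - lig),
                                           claimed$end + lig)),
                ignore.strand = TRUE)
        }
    }
    if (length(out) == 0L)
        return(SVVariantSet())
    v <- do.call(rbind, out)
    vs <- SVVariantSet(vid = v$vid, pid = v$pid, fraction = v$fraction,
                       ploidy = v$ploidy, chrom = v$chrom, pos = v$pos,
                       del_len = v$del_len, ins_seq = v$ins_seq,
                       svtype = v$svtype)
    validObject(vs)
    vs
}

.drawFraction <- function(fdist) {
    for (i in 1:1000) {
        x <- .drawDist(fdist)
        if (x >= 0 && x <= 1)
            return(x)
    }
    stop(sprintf("fraction distribution '%s' keeps drawing outside [0,1]",
                 fdist$family))
}

.drawPloidy <- function(pdist, ploidy) {
    hom <- switch(pdist$family,
        hom = TRUE, het = FALSE,
        bernoulli = .drawDist(pdist) == 1,
        stop(sprintf("ploidy distribution family '%s' not supported",
                     pdist$family)))
    if (hom) .formatPloidy(ploidy, seq_len(ploidy))
    else .formatPloidy(ploidy, 1L)
}

## uniform draw of a start position such that [pos, pos+span-1] fits in
## one remaining available range; NA when no range can take the event
.placeEvent <- function(avail, span) {
    w <- GenomicRanges::width(avail)
    eligible <- pmax(0L, w - span + 1L)
    total <- sum(as.numeric(eligible))
    if (total <= 0)
        return(NA_integer_)
    u <- ceiling(runif(1L) * total)
    idx <- which(cumsum(as.numeric(eligible)) >= u)[1L]
    offset <- u - c(0, cumsum(as.numeric(eligible)))[idx]
    as.integer(GenomicRanges::start(avail)[idx] + offset - 1L)
}

.containingRange <- function(gr, pos) {
    hit <- which(GenomicRanges::start(gr) <= pos &
                 GenomicRanges::end(gr) >= pos)
    if (length(hit) == 0L)
        stop("internal error: placed position escaped the available space")
    hit[1L]
}

## block run (first/last block index plus bp extent) claimed by an impact
## interval extended by the guard margin
.claimedRun <- function(grid, chrom, impact, guard) {
    b <- grid@blocks[as.character(seqnames(grid@blocks)) == chrom]
    L <- grid@seqlengths[[chrom]]
    lo <- max(1L, impact[1L] - guard)
    hi <- min(L, impact[2L] + guard)
    k <- which(GenomicRanges::end(b) >= lo & GenomicRanges::start(b) <= hi)
    list(first = min(k), last = max(k),
         start = GenomicRanges::start(b)[min(k)],
         end = GenomicRanges::end(b)[max(k)])
}

#' Assign variant and no-op tasks to block runs
#'
#' Each variant claims the run of blocks overlapped by its impact region
#' plus a one-ligation-length guard margin (keeping breakpoints out of
#' every ligation region); the gaps between variant runs become no-op
#' tasks capped at \code{trunk_size} blocks.  Together the task runs tile
#' the grid exactly.  Every task gets a load interval (its run extended
#' by half a ligation length into each neighbouring block) and a
#' deterministic seed derived from \code{master_seed} and the task
#' ordinal, fixed before dispatch.
#'
#' @param grid a \linkS4class{BlockGrid}.
#' @param variants an \linkS4class{SVVariantSet} (resolved; see
#'   \code{\link{resolveCompound}}).
#' @param trunk_size no-op run cap, in blocks.
#' @param master_seed integer master seed for per-task seed derivation.
#' @return A \linkS4class{TaskPlan}.
#' @export
assignTasks <- function(grid, variants, trunk_size = 10L, master_seed = 1L) {
    stopifnot(is(grid, "BlockGrid"), is(variants, "SVVariantSet"))
    v <- variants@variants
    lig <- as.integer(grid@ligation)
    half <- lig %/% 2L
    if (nrow(v)) {
        v <- v[order(v$chrom, v$pos), , drop = FALSE]
        miss <- setdiff(v$chrom, names(grid@seqlengths))
        if (length(miss))
            stop(sprintf("variant chromosome(s) not in template: %s",
                         paste(miss, collapse = ", ")))
        ends <- v$pos + pmax(v$del_len - 1L, 0L)
        over <- which(ends > grid@seqlengths[v$chrom] | v$pos < 1L)
        if (length(over))
            stop(sprintf("variant %s spans beyond chromosome %s",
                         v$vid[over[1L]], v$chrom[over[1L]]))
    }
    rows <- list()
    for (chr in names(grid@seqlengths)) {
        b <- grid@blocks[as.character(seqnames(grid@blocks)) == chr]
        N <- length(b)
        claim <- rep(NA_character_, N)
        vc <- v[v$chrom == chr, , drop = FALSE]
        runs <- list()
        for (i in seq_len(nrow(vc))) {
            imp <- .impactRegion(vc$pos[i], vc$del_len[i])
            run <- .claimedRun(grid, chr, imp, lig)
            k <- run$first:run$last
            taken <- which(!is.na(claim[k]))
            if (length(taken))
                stop(sprintf(
                    "variants %s and %s claim overlapping block runs on %s; re-plan with a smaller plan_size",
                    claim[k[taken[1L]]], vc$vid[i], chr))
            claim[k] <- vc$vid[i]
            runs[[vc$vid[i]]] <- run
        }
        ## walk blocks left to right, emitting variant runs and capped
        ## no-op runs for the gaps
        k <- 1L
        while (k <= N) {
            if (!is.na(claim[k])) {
                vid <- claim[k]
                run <- runs[[vid]]
                rows[[length(rows) + 1L]] <- list(
                    kind = "variant", chrom = chr, block_first = run$first,
                    block_last = run$last, vid = vid)
                k <- run$last + 1L
            } else {
                gap_end <- k
                while (gap_end < N && is.na(claim[gap_end + 1L]))
                    gap_end <- gap_end + 1L
                for (s in seq(k, gap_end, by = trunk_size)) {
                    e <- min(s + trunk_size - 1L, gap_end)
                    rows[[length(rows) + 1L]] <- list(
                        kind = "noop", chrom = chr, block_first = s,
                        block_last = e, vid = NA_character_)
                }
                k <- gap_end + 1L
            }
        }
    }
    tk <- do.call(rbind, lapply(rows, as.data.frame,
                                stringsAsFactors = FALSE))
    if (is.null(tk))
        tk <- data.frame(kind = character(), chrom = character(),
                         block_first = integer(), block_last = integer(),
                         vid = character(), stringsAsFactors = FALSE)
    n <- nrow(tk)
    tk$ordinal <- seq_len(n)
    bstart <- integer(n); bend <- integer(n)
    for (i in seq_len(n)) {
        b <- grid@blocks[as.character(seqnames(grid@blocks)) == tk$chrom[i]]
        bstart[i] <- GenomicRanges::start(b)[tk$block_first[i]]
        bend[i] <- GenomicRanges::end(b)[tk$block_last[i]]
    }
    L <- unname(grid@seqlengths[tk$chrom])
    tk$run_start <- bstart
    tk$run_end <- bend
    tk$load_start <- pmax(1L, bstart - half)
    tk$load_end <- pmin(L, bend + half)
    ## a flagged end means the contig shares a ligation region with its
    ## neighbour task; chromosome ends are unflagged
    tk$lig_left <- ifelse(bstart > 1L, as.integer(grid@ligation), 0L)
    tk$lig_right <- ifelse(bend < L, as.integer(grid@ligation), 0L)
    tk$seed <- vapply(tk$ordinal, function(o) .taskSeed(master_seed, o),
                      integer(1))
    tk <- tk[, c("ordinal", "kind", "chrom", "block_first", "block_last",
                 "run_start", "run_end", "load_start", "load_end",
                 "lig_left", "lig_right", "vid", "seed")]
    new("TaskPlan", tasks = tk, variants = variants, grid = grid)
}

#' @rdname accessors
#' @export
setMethod("taskTable", "TaskPlan", function(x) x@tasks)

#' @export
setMethod("length", "TaskPlan", function(x) nrow(x@tasks))

setMethod("show", "TaskPlan", function(object) {
    tk <- object@tasks
    cat(sprintf("TaskPlan: %d task(s) (%d variant, %d no-op)\n",
                nrow(tk), sum(tk$kind == "variant"),
                sum(tk$kind == "noop")))
})
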