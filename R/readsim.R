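#' @include forge.R
NULL

## Constant Sanger quality character for a per-base error rate; capped at
## Q40 so error-free libraries still carry a realistic quality.
.qualChar <- function(base_error) {
    q <- round(-10 * log10(max(base_error, 1e-4)))
    rawToChar(as.raw(33L + as.integer(q)))
}

.revcompVec <- function(x) {
    if (length(x) == 0L)
        return(character())
    as.character(Biostrings::reverseComplement(DNAStringSet(x)))
}

#' Build the sampling plan for one contig pair
#'
#' One row per (library, haplotype, source contig): an altered haplotype
#' draws pairs from the altered contig with weight \code{fraction} and
#' from the original with weight \code{1 - fraction}; unaltered
#' haplotypes draw only from the original.  Per-haplotype coverage is the
#' library coverage divided by the ploidy P, and the expected pair count
#' scales with each contig's own length:
#' \code{weight * (coverage/P) * length / (2 * read_len)}, so e.g. a large
#' deletion yields proportionally fewer pairs from its altered contig.
#'
#' @param pair a \linkS4class{ContigPair}.
#' @param libraries an \linkS4class{SVLibrarySet}.
#' @param fraction cell fraction carrying the variant (0 for no-op).
#' @param lig_left,lig_right flagged ligation-zone lengths (bp) at the
#'   contig ends (0 = chromosome end, unflagged).
#' @param task_id identifier woven into contig/read names.
#' @return data.frame sampling plan (one row per sampled contig).
#' @export
buildSamplingPlan <- function(pair, libraries, fraction = 0,
                              lig_left = 0L, lig_right = 0L,
                              task_id = "t1") {
    stopifnot(is(pair, "ContigPair"), is(libraries, "SVLibrarySet"),
              fraction >= 0, fraction <= 1)
    libs <- libraries@libraries
    P <- pair@ploidy
    len_org <- length(pair@original)
    rows <- list()
    for (li in seq_len(nrow(libs))) {
        cov_h <- libs$coverage[li] / P
        for (h in seq_len(P)) {
            ai <- match(h, pair@altered_haps)
            if (!is.na(ai)) {
                len_alt <- Biostrings::width(pair@altered)[ai]
                rows[[length(rows) + 1L]] <- data.frame(
                    lib = li, hap = h, source = "alt",
                    contig = sprintf("%s_%s_h%d_alt", pair@chrom, task_id, h),
                    contig_len = len_alt, weight = fraction,
                    expected = fraction * cov_h * len_alt /
                        (2 * libs$read_len[li]),
                    stringsAsFactors = FALSE)
                w_org <- 1 - fraction
            } else {
                w_org <- 1
            }
            rows[[length(rows) + 1L]] <- data.frame(
                lib = li, hap = h, source = "org",
                contig = sprintf("%s_%s_h%d_org", pair@chrom, task_id, h),
                contig_len = len_org, weight = w_org,
                expected = w_org * cov_h * len_org / (2 * libs$read_len[li]),
                stringsAsFactors = FALSE)
        }
    }
    plan <- do.call(rbind, rows)
    plan$lig_left <- as.integer(lig_left)
    plan$lig_right <- as.integer(lig_right)
    plan
}

## Attenuation predicate: a fragment is sampled at half rate iff it lies
## ENTIRELY inside a flagged ligation zone.  Such fragments are exactly
## the ones the neighbouring task's contig can also generate, so halving
## them (and only them) makes merged coverage continuous everywhere.
.inLigationZone <- function(start, insert, contig_len, lig_left, lig_right) {
    end <- start + insert - 1L
    (lig_left > 0L & end <= lig_left) |
        (lig_right > 0L & start >= contig_len - lig_right + 1L)
}

## Sample read pairs from one contig sequence.  Uses the current RNG.
.emptyPairs <- function() {
    data.frame(name = character(), contig = character(),
               start = integer(), insert = integer(),
               strand1 = character(), seq1 = character(),
               seq2 = character(), qual1 = character(),
               qual2 = character(), stringsAsFactors = FALSE)
}

.sampleFromContig <- function(seq, n_expected, read_len, insert_mean,
                              insert_sd, lig_left, lig_right, contig,
                              qual_char) {
    empty <- .emptyPairs()
    L <- nchar(seq)
    min_ins <- 2L * read_len
    if (L < min_ins) {
        warning(sprintf("contig %s (%d bp) shorter than the minimum insert; no pairs simulated",
                        contig, L))
        return(empty)
    }
    n <- rpois(1L, n_expected)
    if (n == 0L)
        return(empty)
    ins <- as.integer(round(rnorm(n, insert_mean, insert_sd)))
    bad <- which(ins < min_ins | ins > L)
    guard <- 0L
    while (length(bad)) {                 # truncated-normal resampling
        ins[bad] <- as.integer(round(rnorm(length(bad), insert_mean,
                                           insert_sd)))
        bad <- bad[ins[bad] < min_ins | ins[bad] > L]
        guard <- guard + 1L
        if (guard > 1000L) {
            ins[bad] <- pmin(pmax(min_ins, as.integer(insert_mean)), L)
            break
        }
    }
    start <- as.integer(floor(runif(n) * (L - ins + 1))) + 1L
    keep <- rep(TRUE, n)
    zone <- .inLigationZone(start, ins, L, lig_left, lig_right)
    if (any(zone))
        keep[zone] <- runif(sum(zone)) < 0.5
    start <- start[keep]; ins <- ins[keep]
    n <- length(start)
    if (n == 0L)
        return(empty)
    left <- substring(seq, start, start + read_len - 1L)
    right <- substring(seq, start + ins - read_len, start + ins - 1L)
    ## FR orientation, read-1 strand a fair coin: forward read 1 reads the
    ## left end of the fragment, reverse read 1 reads the right end
    fwd1 <- runif(n) < 0.5
    seq1 <- ifelse(fwd1, left, .revcompVec(right))
    seq2 <- ifelse(fwd1, .revcompVec(right), left)
    data.frame(name = sprintf("%s:%d", contig, seq_len(n)),
               contig = contig, start = start, insert = ins,
               strand1 = ifelse(fwd1, "+", "-"),
               seq1 = toupper(seq1), seq2 = toupper(seq2),
               qual1 = strrep(qual_char, read_len),
               qual2 = strrep(qual_char, read_len),
               stringsAsFactors = FALSE)
}

#' Sample read pairs according to a sampling plan
#'
#' Realised pair counts are Poisson with the plan's expectation; fragment
#' starts are uniform over valid positions; insert sizes are normal per
#' library, resampled while shorter than twice the read length or longer
#' than the contig.  Fragments lying entirely inside a flagged ligation
#' zone are retained with probability 0.5, so that, after merging with
#' the neighbouring task's reads, coverage across block boundaries is
#' uniform.  Contig-level SNV/indel planting and per-base read errors are
#' applied when the library requests them.
#'
#' @param plan a sampling plan from \code{\link{buildSamplingPlan}}.
#' @param pair the \linkS4class{ContigPair} the plan was built for.
#' @param libraries the \linkS4class{SVLibrarySet}.
#' @param seed optional integer; when given, seeds the RNG first.
#' @return data.frame of read pairs (one row per pair) with columns
#'   \code{name, contig, start, insert, strand1, seq1, seq2, qual1, qual2}.
#' @export
samplePairs <- function(plan, pair, libraries, seed = NULL) {
    stopifnot(is(pair, "ContigPair"), is(libraries, "SVLibrarySet"))
    if (!is.null(seed))
        set.seed(seed)
    libs <- libraries@libraries
    out <- list()
    for (r in seq_len(nrow(plan))) {
        row <- plan[r, ]
        lib <- libs[row$lib, ]
        if (row$expected <= 0)
            next
        seq <- if (row$source == "org") as.character(pair@original)
               else as.character(pair@altered[[match(row$hap,
                                                     pair@altered_haps)]])
        if (lib$snv_rate > 0 || lib$indel_rate > 0)
            seq <- mutateContig(seq, lib$snv_rate, lib$indel_rate)$seq
        pr <- .sampleFromContig(seq, row$expected, lib$read_len,
                                lib$insert_mean, lib$insert_sd,
                                row$lig_left, row$lig_right,
                                sprintf("%s:L%d", row$contig, row$lib),
                                .qualChar(lib$base_error))
        if (lib$base_error > 0)
            pr <- applyErrors(pr, lib$base_error)
        out[[length(out) + 1L]] <- pr
    }
    if (length(out) == 0L)
        return(.emptyPairs())
    do.call(rbind, out)
}

#' Apply per-base substitution errors to sampled read pairs
#'
#' Each base is substituted independently with probability
#' \code{base_error} to a uniformly random different base.  Qualities are
#' already constant at Phred \code{round(-10*log10(max(base_error, 1e-4)))}.
#'
#' @param pairs a read-pair data.frame from \code{\link{samplePairs}}.
#' @param base_error substitution probability per base.
#' @return The data.frame with mutated \code{seq1}/\code{seq2}.
#' @export
applyErrors <- function(pairs, base_error) {
    if (base_error <= 0 || nrow(pairs) == 0L)
        return(pairs)
    pairs$seq1 <- .substituteBases(pairs$seq1, base_error)
    pairs$seq2 <- .substituteBases(pairs$seq2, base_error)
    pairs
}

.BASES <- c("A", "C", "G", "T")

.substituteBases <- function(seqs, rate) {
    joined <- paste(seqs, collapse = "")
    v <- strsplit(joined, "", fixed = TRUE)[[1L]]
    hit <- which(runif(length(v)) < rate)
    if (length(hit)) {
        ## uniformly random *different* base: shift by 1-3 in base order
        cur <- match(v[hit], .BASES)
        cur[is.na(cur)] <- 1L
        v[hit] <- .BASES[((cur - 1L + sample(1:3, length(hit),
                                             replace = TRUE)) %% 4L) + 1L]
    }
    joined <- paste(v, collapse = "")
    ends <- cumsum(nchar(seqs))
    substring(joined, c(1L, head(ends, -1L) + 1L), ends)
}

#' Plant random SNVs and small indels on a contig
#'
#' Small variants are embedded once per contig before read sampling, so
#' overlapping reads share the same planted allele.
#'
#' @param seq contig sequence (character scalar).
#' @param snv_rate per-base substitution planting rate.
#' @param indel_rate per-base indel planting rate (length 1-3, insertion
#'   or deletion with equal probability).
#' @return list with the mutated \code{seq} and an \code{events}
#'   data.frame (pos, type, detail).
#' @export
mutateContig <- function(seq, snv_rate = 0, indel_rate = 0) {
    L <- nchar(seq)
    events <- list()
    if (snv_rate > 0 && L > 0L) {
        m <- rbinom(1L, L, snv_rate)
        if (m > 0L) {
            pos <- sort(sample.int(L, m))
            v <- strsplit(seq, "", fixed = TRUE)[[1L]]
            cur <- match(toupper(v[pos]), .BASES)
            cur[is.na(cur)] <- 1L
            alt <- .BASES[((cur - 1L + sample(1:3, m, replace = TRUE))
                           %% 4L) + 1L]
            v[pos] <- alt
            seq <- paste(v, collapse = "")
            events[[length(events) + 1L]] <-
                data.frame(pos = pos, type = "SNV", detail = alt,
                           stringsAsFactors = FALSE)
        }
    }
    if (indel_rate > 0 && L > 3L) {
        m <- rbinom(1L, L, indel_rate)
        if (m > 0L) {
            pos <- sort(sample.int(L - 3L, m), decreasing = TRUE)
            for (p in pos) {              # right-to-left keeps coords valid
                len <- sample(1:3, 1L)
                if (runif(1L) < 0.5) {
                    ins <- randomDna(len)
                    seq <- paste0(substr(seq, 1L, p), ins,
                                  substr(seq, p + 1L, nchar(seq)))
                    events[[length(events) + 1L]] <-
                        data.frame(pos = p, type = "INS", detail = ins,
                                   stringsAsFactors = FALSE)
                } else {
                    seq <- paste0(substr(seq, 1L, p),
                                  substr(seq, p + len + 1L, nchar(seq)))
                    events[[length(events) + 1L]] <-
                        data.frame(pos = p, type = "DEL",
                                   detail = as.character(len),
                                   stringsAsFactors = FALSE)
                }
            }
        }
    }
    list(seq = seq,
         events = if (length(events)) do.call(rbind, events)
                  else data.frame(pos = integer(), type = character(),
                                  detail = character()))
}

#' Per-base read depth of a sampled pair set
#'
#' Depth is computed from the recorded fragment geometry (both mates of
#' every pair), in the coordinates of the source contig.
#'
#' @param pairs a read-pair data.frame from \code{\link{samplePairs}}.
#' @param contig_len length of the source contig.
#' @return Numeric vector of per-base depth, length \code{contig_len}.
#' @export
pairCoverage <- function(pairs, contig_len) {
    if (nrow(pairs) == 0L)
        return(numeric(contig_len))
    rl <- nchar(pairs$seq1[1L])
    ir <- IRanges(c(pairs$start, pairs$start + pairs$insert - rl),
                  width = rl)
    as.numeric(IRanges::coverage(ir, width = contig_len))
}
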