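#' @include readsim.R
#' @importFrom parallel mclapply
#' @importFrom tools md5sum
NULL

.loadTemplate <- function(fasta) {
    if (is(fasta, "DNAStringSet")) {
        tpl <- fasta
    } else {
        if (!file.exists(fasta))
            stop(sprintf("template FASTA '%s' not found", fasta))
        tpl <- readDNAStringSet(fasta)
    }
    names(tpl) <- sub("\\s.*$", "", names(tpl))
    tpl
}

## default ligation length: generous enough that no valid fragment spans
## more than one flagged zone boundary
.defaultLigation <- function(libraries) {
    if (is.null(libraries) || length(libraries) == 0L)
        return(1000)
    p <- libraries@libraries
    ceiling(max(2 * (p$insert_mean + 3 * p$insert_sd)) / 2) * 2
}

## One simulation task: load the slice, forge, sample.  Pure function of
## (template, task row, payload, libraries); seeds its own RNG so results
## are identical under any executor.
.runTask <- function(task, template, variants, libraries, level,
                     default_ploidy) {
    set.seed(task$seed)
    chrom <- task$chrom
    slice <- as.character(Biostrings::subseq(template[[chrom]],
                                             task$load_start,
                                             task$load_end))
    vrow <- NULL
    fraction <- 0
    if (task$kind == "variant") {
        vrow <- variants@variants[variants@variants$vid == task$vid, ,
                                  drop = FALSE]
        fraction <- vrow$fraction
    }
    pair <- forgeContig(slice, vrow, offset = task$load_start,
                        chrom = chrom,
                        lig_left = task$lig_left, lig_right = task$lig_right,
                        default_ploidy = default_ploidy)
    tid <- sprintf("t%d", task$ordinal)
    contigs <- setNames(as.character(pair@original),
                        sprintf("%s_%s_org", chrom, tid))
    if (length(pair@altered)) {
        alt <- as.character(pair@altered)
        names(alt) <- sprintf("%s_%s_h%d_alt_%s", chrom, tid,
                              pair@altered_haps, task$vid)
        contigs <- c(contigs, alt)
    }
    pairs <- .emptyPairs()
    if (level %in% c("read", "alignment") && length(libraries) > 0L) {
        plan <- buildSamplingPlan(pair, libraries, fraction,
                                  lig_left = task$lig_left,
                                  lig_right = task$lig_right,
                                  task_id = tid)
        pairs <- samplePairs(plan, pair, libraries)
    }
    list(ordinal = task$ordinal, contigs = contigs, pairs = pairs)
}

#' Merge per-task products into the final deliverables
#'
#' Concatenates contigs and read pairs in task-ordinal order (never
#' completion order), writes the all-contig FASTA, the paired FASTQ files
#' (read level only) and the ground-truth BED, and records every product
#' with its MD5 checksum plus per-task realised pair counts in a
#' tab-delimited manifest.
#'
#' @param results list of per-task products (from the internal worker),
#'   in any order; missing ordinals abort.
#' @param variants the \linkS4class{SVVariantSet} for ground truth (with
#'   original, unresolved insertion references).
#' @param out_dir output directory.
#' @param prefix file-name prefix for all products.
#' @param level output level, \code{"contig"} or \code{"read"}.
#' @return Invisibly, a list with \code{products} and \code{tasks}
#'   data.frames (the manifest) and the output paths.
#' @export
mergeOutputs <- function(results, variants, out_dir, prefix = "sim",
                         level = "contig") {
    ords <- vapply(results, `[[`, integer(1), "ordinal")
    if (!setequal(ords, seq_along(results)))
        stop(sprintf("missing task product(s): %s",
                     paste(setdiff(seq_along(results), ords),
                           collapse = ", ")))
    results <- results[order(ords)]
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- function(ext) file.path(out_dir, paste0(prefix, ext))
    contigs <- unlist(lapply(results, `[[`, "contigs"))
    writeSimFasta(DNAStringSet(contigs), path(".contigs.fa"))
    writeGroundTruthBed(variants, path(".truth.bed"))
    files <- c(contigs = path(".contigs.fa"), truth = path(".truth.bed"))
    n_pairs_task <- vapply(results, function(r) nrow(r$pairs), integer(1))
    if (level %in% c("read", "alignment")) {
        pairs <- do.call(rbind, lapply(results, `[[`, "pairs"))
        writeFastqPair(pairs, path(".read1.fq"), path(".read2.fq"))
        files <- c(files, read1 = path(".read1.fq"),
                   read2 = path(".read2.fq"))
    }
    products <- data.frame(product = names(files), path = unname(files),
                           md5 = unname(md5sum(unname(files))),
                           stringsAsFactors = FALSE)
    tasks <- data.frame(ordinal = seq_along(results),
                        n_contigs = vapply(results, function(r)
                            length(r$contigs), integer(1)),
                        n_pairs = n_pairs_task)
    manifest_path <- path(".manifest.tsv")
    con <- file(manifest_path, "w")
    writeLines("#product\tpath\tmd5", con)
    writeLines(apply(products, 1L, paste, collapse = "\t"), con)
    writeLines("#task\tn_contigs\tn_pairs", con)
    writeLines(apply(tasks, 1L, paste, collapse = "\t"), con)
    close(con)
    invisible(list(products = products, tasks = tasks, files = files,
                   manifest = manifest_path))
}

#' Run a full spike-in simulation
#'
#' The end-to-end driver: reads the template and control files, expands
#' META distributions if given, resolves compound events, partitions the
#' genome into the block/ligation grid, assigns one task per variant plus
#' capped no-op tasks, executes all tasks (serially or on a fork pool --
#' identical products either way, since every task carries its own
#' pre-assigned seed), and merges the products.  Output levels:
#' \code{"contig"} writes the all-contig FASTA and ground-truth BED only;
#' \code{"read"} adds the paired FASTQ files; \code{"alignment"}
#' additionally maps the reads with external \code{bwa}/\code{samtools}
#' when available (degrading to \code{"read"} with a warning otherwise).
#'
#' @param fasta template FASTA path or \code{DNAStringSet}.
#' @param var VAR path or \linkS4class{SVVariantSet} (exact variants).
#' @param meta META path or \linkS4class{SVMetaSet} (alternative to
#'   \code{var}; expanded to a VAR set first).
#' @param par PAR path or \linkS4class{SVLibrarySet}; required for read
#'   and alignment levels.
#' @param out_dir output directory.
#' @param level \code{"contig"}, \code{"read"} or \code{"alignment"}.
#' @param plan_size planned block size (bp).
#' @param ligation ligation-region length (bp); default
#'   \code{2*(insert_mean + 3*insert_sd)} maximised over libraries.
#' @param trunk_size no-op block-run cap.
#' @param seed master seed; all randomness derives from it.
#' @param workers fork-pool size (1 = serial, the default).
#' @param mask,target optional BED paths or \code{GRanges} restricting
#'   META placement.
#' @param foreign optional named list of foreign FASTA paths.
#' @param ploidy template ploidy P (haploid copies per cell).
#' @param dry_run stop after planning: write the expanded VAR and the
#'   task plan, simulate nothing.
#' @param prefix output file prefix.
#' @return Invisibly, the run manifest (see \code{\link{mergeOutputs}});
#'   for dry runs, the paths of the VAR and plan files.
#' @export
mutforge <- function(fasta, var = NULL, meta = NULL, par = NULL,
                     out_dir = ".", level = c("contig", "read", "alignment"),
                     plan_size = 1e6, ligation = NULL, trunk_size = 10L,
                     seed = 1L, workers = 1L, mask = NULL, target = NULL,
                     foreign = NULL, ploidy = 2L, dry_run = FALSE,
                     prefix = "sim") {
    level <- match.arg(level)
    template <- .loadTemplate(fasta)
    libraries <- if (is.null(par)) NULL
                 else if (is(par, "SVLibrarySet")) par else readPar(par)
    if (level %in% c("read", "alignment") &&
        (is.null(libraries) || length(libraries) == 0L))
        stop(sprintf("output level '%s' requires a PAR file with at least one library",
                     level))
    if (is.null(ligation))
        ligation <- .defaultLigation(libraries)
    grid <- planBlocks(template, plan_size = plan_size, ligation = ligation)
    if (is.null(var) && is.null(meta))
        stop("either a VAR or a META input is required")
    set.seed(seed)
    if (!is.null(var)) {
        variants <- if (is(var, "SVVariantSet")) var else readVar(var)
    } else {
        metaset <- if (is(meta, "SVMetaSet")) meta else readMeta(meta)
        variants <- expandMeta(metaset, grid,
                               mask = if (is.character(mask))
                                   readBedRegions(mask) else mask,
                               target = if (is.character(target))
                                   readBedRegions(target) else target,
                               ploidy = ploidy, foreign = foreign)
    }
    resolved <- resolveCompound(variants, template, foreign)
    plan <- assignTasks(grid, resolved, trunk_size = trunk_size,
                        master_seed = seed)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (dry_run) {
        var_path <- file.path(out_dir, paste0(prefix, ".var"))
        plan_path <- file.path(out_dir, paste0(prefix, ".plan.tsv"))
        writeVar(variants, var_path)
        write.table(taskTable(plan), plan_path, sep = "\t",
                    quote = FALSE, row.names = FALSE)
        message(sprintf("dry run: %d variant(s), %d task(s) planned",
                        length(variants), length(plan)))
        return(invisible(list(var = var_path, plan = plan_path,
                              variants = variants, tasks = plan)))
    }
    tk <- taskTable(plan)
    task_rows <- split(tk, tk$ordinal)
    run_one <- function(task)
        .runTask(task, template, resolved, libraries, level, ploidy)
    results <- if (workers > 1L)
        mclapply(task_rows, run_one, mc.cores = workers)
    else lapply(task_rows, run_one)
    failed <- which(vapply(results, inherits, logical(1), "try-error") |
                    vapply(results, is.null, logical(1)))
    if (length(failed))
        stop(sprintf("task %d (seed %d) failed; rerun it alone to replay",
                     failed[1L], tk$seed[failed[1L]]))
    manifest <- mergeOutputs(results, variants, out_dir, prefix = prefix,
                             level = level)
    if (level == "alignment") {
        ref_path <- if (is.character(fasta)) fasta
                    else file.path(out_dir, paste0(prefix, ".ref.fa"))
        if (!is.character(fasta))
            writeSimFasta(template, ref_path)
        bam <- alignWrapper(manifest$files[["read1"]],
                            manifest$files[["read2"]], ref_path,
                            file.path(out_dir, prefix))
        if (!is.null(bam))
            manifest$files <- c(manifest$files, alignment = bam)
    }
    invisible(manifest)
}

#' Align simulated reads with external bwa/samtools
#'
#' Thin subprocess wrapper producing a coordinate-sorted, indexed BAM.
#' When the executables are absent the output level degrades to read
#' level with a warning; a nonzero exit of either tool is surfaced.
#'
#' @param fq1,fq2 FASTQ paths (read 1 / read 2).
#' @param reference reference FASTA path.
#' @param out_prefix output path prefix (writes \code{<prefix>.bam}).
#' @return The BAM path, or \code{NULL} when alignment was skipped.
#' @export
alignWrapper <- function(fq1, fq2, reference, out_prefix) {
    bwa <- Sys.which("bwa"); st <- Sys.which("samtools")
    if (!nzchar(bwa) || !nzchar(st)) {
        warning("bwa/samtools not found on PATH; degrading to read-level output")
        return(NULL)
    }
    bam <- paste0(out_prefix, ".bam")
    sam <- paste0(out_prefix, ".sam")
    status <- system2(bwa, c("index", shQuote(reference)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0)
        stop(sprintf("bwa index exited with status %d", status))
    status <- system2(bwa, c("mem", shQuote(reference), shQuote(fq1),
                             shQuote(fq2)), stdout = sam, stderr = FALSE)
    if (status != 0)
        stop(sprintf("bwa mem exited with status %d", status))
    status <- system2(st, c("sort", "-o", shQuote(bam), shQuote(sam)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0)
        stop(sprintf("samtools sort exited with status %d", status))
    unlink(sam)
    status <- system2(st, c("index", shQuote(bam)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0)
        stop(sprintf("samtools index exited with status %d", status))
    bam
}
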