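engineFixture <- function() {
    list(tpl = templateSet(c(chrA = 30000L), seed = 31),
         vs = SVVariantSet(vid = c("del1", "dup1"),
                           fraction = c(0.5, 1), ploidy = c("2/1", "2/1,2"),
                           chrom = "chrA", pos = c(8000L, 22000L),
                           del_len = c(1500L, 1000L),
                           svtype = c("DEL", "DUP")),
         lib = stdLib(coverage = 15))
}

test_that("contig-level runs produce the FASTA and ground-truth products", {
    fx <- engineFixture()
    out <- withr::local_tempdir()
    man <- mutforge(fx$tpl, var = fx$vs, out_dir = out, level = "contig",
                    plan_size = 5000, ligation = 1000, seed = 42)
    expect_true(all(file.exists(man$products$path)))
    expect_false("read1" %in% man$products$product)
    fa <- Biostrings::readDNAStringSet(man$files[["contigs"]])
    # record count = per task (1 original + altered haplotypes)
    expect_equal(length(fa), sum(man$tasks$n_contigs))
    # het deletion contributes 1 altered record, hom duplication 2
    expect_equal(sum(grepl("_alt_del1$", names(fa))), 1L)
    expect_equal(sum(grepl("_alt_dup1$", names(fa))), 2L)
    # every ground-truth vid appears in an altered contig header
    truth <- readGroundTruthBed(man$files[["truth"]])
    for (vid in variantIds(truth))
        expect_true(any(grepl(vid, names(fa), fixed = TRUE)))
    # ground truth round trips to the input specification
    expect_equal(variantTable(truth)[order(variantTable(truth)$vid), ],
                 variantTable(fx$vs)[order(variantIds(fx$vs)), ],
                 ignore_attr = TRUE)
})

test_that("read-level runs conserve pair counts through the merge", {
    fx <- engineFixture()
    out <- withr::local_tempdir()
    man <- mutforge(fx$tpl, var = fx$vs, par = fx$lib, out_dir = out,
                    level = "read", plan_size = 5000, ligation = 1000,
                    seed = 42)
    r1 <- readFastq(man$files[["read1"]])
    r2 <- readFastq(man$files[["read2"]])
    expect_equal(length(r1), length(r2))
    expect_equal(length(r1), sum(man$tasks$n_pairs))
    expect_equal(sub("/1$", "", names(r1)), sub("/2$", "", names(r2)))
    # read level without a PAR file is a configuration error
    expect_error(mutforge(fx$tpl, var = fx$vs, out_dir = out,
                          level = "read", plan_size = 5000, seed = 1),
                 "requires a PAR")
})

test_that("identical seeds give byte-identical products for 1 vs 4 workers", {
    fx <- engineFixture()
    d1 <- withr::local_tempdir(); d4 <- withr::local_tempdir()
    m1 <- mutforge(fx$tpl, var = fx$vs, par = fx$lib, out_dir = d1,
                   level = "read", plan_size = 5000, ligation = 1000,
                   seed = 99, workers = 1)
    m4 <- mutforge(fx$tpl, var = fx$vs, par = fx$lib, out_dir = d4,
                   level = "read", plan_size = 5000, ligation = 1000,
                   seed = 99, workers = 4)
    expect_identical(m1$products$md5, m4$products$md5)
    # a different seed changes the reads
    m2 <- mutforge(fx$tpl, var = fx$vs, par = fx$lib, out_dir = d1,
                   level = "read", plan_size = 5000, ligation = 1000,
                   seed = 100, workers = 1)
    expect_false(identical(m1$products$md5[m1$products$product == "read1"],
                           m2$products$md5[m2$products$product == "read1"]))
})

test_that("dry runs stop at planning and emit the expanded VAR and plan", {
    tpl <- templateSet(c(chrA = 50000L), seed = 33)
    meta <- SVMetaSet(svtype = "DEL", count = 4L,
                      size_dist = "uniform:200,800",
                      fraction_dist = "uniform:0,1",
                      ploidy_dist = "bernoulli:0.5")
    out <- withr::local_tempdir()
    res <- suppressMessages(
        mutforge(tpl, meta = meta, out_dir = out, level = "contig",
                 plan_size = 5000, ligation = 600, seed = 7,
                 dry_run = TRUE))
    expect_true(file.exists(res$var))
    expect_true(file.exists(res$plan))
    expect_equal(length(readVar(res$var)), 4L)
    expect_false(file.exists(file.path(out, "sim.contigs.fa")))
    # the dry-run VAR replayed as input reproduces the same plan
    res2 <- suppressMessages(
        mutforge(tpl, var = res$var, out_dir = out, level = "contig",
                 plan_size = 5000, ligation = 600, seed = 7,
                 dry_run = TRUE, prefix = "replay"))
    expect_equal(taskTable(res2$tasks)[, c("kind", "chrom", "block_first",
                                           "block_last", "vid")],
                 taskTable(res$tasks)[, c("kind", "chrom", "block_first",
                                          "block_last", "vid")])
})

test_that("the merged deliverables are empty-but-valid for a variant-free run", {
    tpl <- templateSet(c(chrA = 6000L), seed = 35)
    out <- withr::local_tempdir()
    man <- mutforge(tpl, var = SVVariantSet(), par = stdLib(coverage = 5),
                    out_dir = out, level = "read", plan_size = 3000,
                    ligation = 800, seed = 3)
    truth <- readLines(man$files[["truth"]])
    expect_equal(length(truth), 1L)          # header only
    fa <- Biostrings::readDNAStringSet(man$files[["contigs"]])
    expect_equal(length(fa), length(man$tasks$ordinal))
    expect_gt(length(readFastq(man$files[["read1"]])), 0L)
})

test_that("command-line entry points drive the same machinery", {
    tpl_path <- withr::local_tempfile(fileext = ".fa")
    writeSimFasta(templateSet(c(chrA = 20000L), seed = 37), tpl_path)
    var_path <- withr::local_tempfile(fileext = ".var")
    writeVar(SVVariantSet(vid = "d1", fraction = 1, ploidy = "2/1,2",
                          chrom = "chrA", pos = 9000L, del_len = 800L),
             var_path)
    par_path <- withr::local_tempfile(fileext = ".par")
    writePar(stdLib(coverage = 8), par_path)
    out <- withr::local_tempdir()
    suppressMessages(mutforgeCli(c("--fasta", tpl_path, "--var", var_path,
                                   "--par", par_path, "--out", out,
                                   "--level", "read", "--plan-size", "4000",
                                   "--ligation", "1000", "--seed", "5")))
    expect_true(file.exists(file.path(out, "sim.read1.fq")))

    # tree2var CLI rewrites fractions through the clonal-tree machinery
    nwk <- withr::local_tempfile(fileext = ".nwk")
    writeLines(paste0(EXAMPLE_NEWICK, ";"), nwk)
    var5 <- withr::local_tempfile(fileext = ".var")
    writeVar(SVVariantSet(vid = paste0("V", 1:5), fraction = 0,
                          ploidy = "2/1", chrom = "chrA",
                          pos = c(1, 3, 5, 7, 9) * 1000L, del_len = 100L),
             var5)
    out_var <- withr::local_tempfile(fileext = ".var")
    suppressMessages(tree2varCli(c("--tree", nwk, "--var", var5,
                                   "--out", out_var)))
    got <- fractions(readVar(out_var))
    expect_equal(unname(got[paste0("V", 1:5)]),
                 unname(EXAMPLE_VAR_F[paste0("V", 1:5)]))
})

test_that("alignment level degrades gracefully without the external tools", {
    fx <- engineFixture()
    out <- withr::local_tempdir()
    if (nzchar(Sys.which("bwa")) && nzchar(Sys.which("samtools"))) {
        tpl_path <- file.path(out, "ref.fa")
        writeSimFasta(fx$tpl, tpl_path)
        man <- mutforge(tpl_path, var = fx$vs, par = fx$lib, out_dir = out,
                        level = "alignment", plan_size = 5000,
                        ligation = 1000, seed = 12)
        expect_true(file.exists(man$files[["alignment"]]))
    } else {
        expect_warning(
            mutforge(fx$tpl, var = fx$vs, par = fx$lib, out_dir = out,
                     level = "alignment", plan_size = 5000,
                     ligation = 1000, seed = 12),
            "degrading")
    }
})
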