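oneVar <- function(...) variantTable(SVVariantSet(...))

test_that("each variant class realises its edit at exact breakpoints", {
    del <- forgeContig("ACGTACGT",
        oneVar(vid = "d", fraction = 1, ploidy = "1/1", chrom = "c",
               pos = 3L, del_len = 2L), 1, "c", default_ploidy = 1)
    expect_equal(as.character(alteredContigs(del)[[1]]), "ACACGT")

    inv <- forgeContig("ACGTAC",
        oneVar(vid = "i", fraction = 1, ploidy = "1/1", chrom = "c",
               pos = 2L, del_len = 3L, svtype = "INV"), 1, "c")
    expect_equal(as.character(alteredContigs(inv)[[1]]), "AACGAC")

    dup <- forgeContig("ACGT",
        oneVar(vid = "u", fraction = 1, ploidy = "1/1", chrom = "c",
               pos = 2L, del_len = 2L, svtype = "DUP"), 1, "c")
    expect_equal(as.character(alteredContigs(dup)[[1]]), "ACGCGT")

    ins <- forgeContig("AAAA",
        oneVar(vid = "n", fraction = 1, ploidy = "1/1", chrom = "c",
               pos = 3L, del_len = 0L, ins_seq = "TT"), 1, "c")
    expect_equal(as.character(alteredContigs(ins)[[1]]), "AATTAA")

    idup <- forgeContig("AACGTT",
        oneVar(vid = "v", fraction = 1, ploidy = "1/1", chrom = "c",
               pos = 3L, del_len = 2L, svtype = "IDUP"), 1, "c")
    expect_equal(as.character(alteredContigs(idup)[[1]]), "AACGCGTT")

    # genome offset converts to slice-local coordinates once
    shifted <- forgeContig("ACGTACGT",
        oneVar(vid = "d", fraction = 1, ploidy = "1/1", chrom = "c",
               pos = 1003L, del_len = 2L), offset = 1001, chrom = "c")
    expect_equal(as.character(alteredContigs(shifted)[[1]]), "ACACGT")
})

test_that("heterozygous edits leave the other haplotypes untouched", {
    het <- forgeContig("ACGTACGT",
        oneVar(vid = "d", fraction = 0.5, ploidy = "2/1", chrom = "c",
               pos = 3L, del_len = 2L), 1, "c", default_ploidy = 2)
    expect_equal(het@altered_haps, 1L)
    expect_equal(length(alteredContigs(het)), 1L)
    expect_equal(as.character(originalContig(het)), "ACGTACGT")
    hom <- forgeContig("ACGTACGT",
        oneVar(vid = "d", fraction = 1, ploidy = "2/1,2", chrom = "c",
               pos = 3L, del_len = 2L), 1, "c")
    expect_equal(hom@altered_haps, c(1L, 2L))
    expect_equal(as.character(alteredContigs(hom)[[1]]),
                 as.character(alteredContigs(hom)[[2]]))
})

test_that("forge matches the naive string-edit oracle on random cases", {
    withr::local_seed(77)
    for (i in 1:500) {
        L <- sample(20:120, 1)
        seq <- randomDna(L)
        svtype <- sample(c("DEL", "INS", "DUP", "IDUP", "INV"), 1)
        len <- if (svtype == "INS") 0L else sample.int(min(10L, L - 2L), 1)
        pos <- sample.int(L - max(len, 1L), 1)
        ins <- if (svtype == "INS") randomDna(sample.int(12L, 1)) else ""
        got <- forgeContig(seq,
            oneVar(vid = "x", fraction = 1, ploidy = "1/1", chrom = "c",
                   pos = pos, del_len = len, ins_seq = ins,
                   svtype = svtype), 1, "c")
        expect_equal(as.character(alteredContigs(got)[[1]]),
                     naiveEdit(seq, svtype, pos, len, ins),
                     label = sprintf("%s pos=%d len=%d L=%d", svtype,
                                     pos, len, L))
    }
})

test_that("length accounting and involutions hold", {
    withr::local_seed(8)
    seq <- randomDna(200)
    # net length change equals insertions minus deletions, exactly
    cases <- list(list("DEL", 30L, ""), list("INS", 0L, randomDna(17)),
                  list("DUP", 25L, ""), list("INV", 40L, ""))
    for (cs in cases) {
        got <- forgeContig(seq, oneVar(vid = "x", fraction = 1,
            ploidy = "1/1", chrom = "c", pos = 50L, del_len = cs[[2]],
            ins_seq = cs[[3]], svtype = cs[[1]]), 1, "c")
        expected_delta <- switch(cs[[1]], DEL = -cs[[2]],
                                 INS = nchar(cs[[3]]), DUP = cs[[2]],
                                 INV = 0L)
        expect_equal(length(alteredContigs(got)[[1]]) - nchar(seq),
                     expected_delta)
    }
    # INV applied twice restores the original
    once <- as.character(alteredContigs(forgeContig(seq,
        oneVar(vid = "x", fraction = 1, ploidy = "1/1", chrom = "c",
               pos = 31L, del_len = 60L, svtype = "INV"), 1, "c"))[[1]])
    twice <- as.character(alteredContigs(forgeContig(once,
        oneVar(vid = "x", fraction = 1, ploidy = "1/1", chrom = "c",
               pos = 31L, del_len = 60L, svtype = "INV"), 1, "c"))[[1]])
    expect_equal(twice, seq)
    # deleting an inserted segment restores the original
    ins <- randomDna(12)
    with_ins <- as.character(alteredContigs(forgeContig(seq,
        oneVar(vid = "x", fraction = 1, ploidy = "1/1", chrom = "c",
               pos = 90L, del_len = 0L, ins_seq = ins), 1, "c"))[[1]])
    back <- as.character(alteredContigs(forgeContig(with_ins,
        oneVar(vid = "x", fraction = 1, ploidy = "1/1", chrom = "c",
               pos = 90L, del_len = 12L), 1, "c"))[[1]])
    expect_equal(back, seq)
})

test_that("reverse complement honours IUPAC codes and preserves case", {
    # the string-level reverse complement keeps soft-masking case
    expect_equal(svforge:::.revcompChar("AArsWn"), "nWsyTT")
    got <- forgeContig("AArsWn", oneVar(vid = "x", fraction = 1,
        ploidy = "1/1", chrom = "c", pos = 3L, del_len = 4L,
        svtype = "INV"), 1, "c")
    # contigs are normalised to uppercase in the DNAString container
    expect_equal(as.character(alteredContigs(got)[[1]]), "AANWSY")
    expect_error(forgeContig("AXGTAC", oneVar(vid = "x", fraction = 1,
        ploidy = "1/1", chrom = "c", pos = 1L, del_len = 6L,
        svtype = "INV"), 1, "c"), "non-IUPAC")
})

test_that("breakpoints inside ligation buffers violate the planning contract", {
    seq <- randomDna(1000)
    expect_error(forgeContig(seq, oneVar(vid = "x", fraction = 1,
        ploidy = "1/1", chrom = "c", pos = 50L, del_len = 10L), 1, "c",
        lig_left = 100L), "planning-contract")
    expect_error(forgeContig(seq, oneVar(vid = "x", fraction = 1,
        ploidy = "1/1", chrom = "c", pos = 950L, del_len = 10L), 1, "c",
        lig_right = 100L), "planning-contract")
    # the same edit away from the buffers is fine
    expect_s4_class(forgeContig(seq, oneVar(vid = "x", fraction = 1,
        ploidy = "1/1", chrom = "c", pos = 500L, del_len = 10L), 1, "c",
        lig_left = 100L, lig_right = 100L), "ContigPair")
})

test_that("compound groups validate and resolve to coordinated edits", {
    tpl <- templateSet(c(chrA = 3000L, chrB = 3000L))
    seg <- as.character(Biostrings::subseq(tpl[["chrA"]], 1000, 1499))
    # balanced translocation: deletion arm at the source, insertion arm
    # (segment reference) at the destination
    vs <- SVVariantSet(vid = c("t1a", "t1b"), pid = "t1",
                       fraction = 0.5, ploidy = "2/1",
                       chrom = c("chrA", "chrB"), pos = c(1000L, 2000L),
                       del_len = c(500L, 0L),
                       ins_seq = c("", "seg:chrA:1000-1499:+"),
                       svtype = "TRA")
    res <- resolveCompound(vs, tpl)
    v <- variantTable(res)
    expect_equal(v$ins_seq[2], seg)
    # inverted arm resolves to the reverse complement
    inv <- SVVariantSet(vid = c("t1a", "t1b"), pid = "t1", fraction = 0.5,
                        ploidy = "2/1", chrom = c("chrA", "chrB"),
                        pos = c(1000L, 2000L), del_len = c(500L, 0L),
                        ins_seq = c("", "seg:chrA:1000-1499:-"),
                        svtype = "ITRA")
    vres <- variantTable(resolveCompound(inv, tpl))
    expect_equal(Biostrings::DNAString(vres$ins_seq[2]),
                 Biostrings::reverseComplement(Biostrings::DNAString(seg)))

    # duplicated translocation: source retained, destination gains 500 bp
    dup <- SVVariantSet(vid = "t2", fraction = 0.5, ploidy = "2/1",
                        chrom = "chrB", pos = 2500L, del_len = 0L,
                        ins_seq = "seg:chrA:1000-1499:+", svtype = "TRA")
    dres <- resolveCompound(dup, tpl)
    cp <- forgeContig(as.character(tpl[["chrB"]]),
                      variantTable(dres), 1, "chrB")
    expect_equal(length(alteredContigs(cp)[[1]]), 3500L)

    # dangling pid (singleton group naming no record) is an error
    dang <- SVVariantSet(vid = "x", pid = "ghost", fraction = 1,
                         ploidy = "2/1", chrom = "chrA", pos = 100L,
                         del_len = 10L)
    expect_error(resolveCompound(dang, tpl), "dangling")
    # a pid naming the record itself is a cycle
    cyc <- SVVariantSet(vid = "x", pid = "x", fraction = 1,
                        ploidy = "2/1", chrom = "chrA", pos = 100L,
                        del_len = 10L)
    expect_error(resolveCompound(cyc, tpl), "cycle")
    # fraction mismatch within a group
    mis <- SVVariantSet(vid = c("a", "b"), pid = "g", fraction = c(0.5, 0.6),
                        ploidy = "2/1", chrom = "chrA",
                        pos = c(100L, 300L), del_len = 10L)
    expect_error(resolveCompound(mis, tpl), "fraction mismatch")
})

test_that("foreign insertions resolve from their FASTA with orientation", {
    tpl <- templateSet(c(chrA = 1000L))
    viral <- withr::with_seed(3, randomDna(120))
    fa <- withr::local_tempfile(fileext = ".fa")
    writeSimFasta(Biostrings::DNAStringSet(c(hpv16 = viral)), fa)
    vs <- SVVariantSet(vid = "f1", fraction = 1, ploidy = "2/1,2",
                       chrom = "chrA", pos = 500L, del_len = 0L,
                       ins_seq = sprintf("%s:hpv16:-", fa), svtype = "INS")
    res <- resolveCompound(vs, tpl)
    expect_equal(Biostrings::DNAString(variantTable(res)$ins_seq),
                 Biostrings::reverseComplement(Biostrings::DNAString(viral)))
    # named mapping works too, and "*" picks the first record
    vs2 <- SVVariantSet(vid = "f1", fraction = 1, ploidy = "2/1",
                        chrom = "chrA", pos = 500L, del_len = 0L,
                        ins_seq = "virus:*:+", svtype = "INS")
    res2 <- resolveCompound(vs2, tpl, foreign = list(virus = fa))
    expect_equal(variantTable(res2)$ins_seq, viral)
    expect_error(resolveCompound(
        SVVariantSet(vid = "f1", fraction = 1, ploidy = "2/1",
                     chrom = "chrA", pos = 500L, del_len = 0L,
                     ins_seq = "virus:missing:+", svtype = "INS"),
        tpl, foreign = list(virus = fa)), "not in foreign FASTA")
})
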