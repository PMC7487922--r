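test_that("editing levels follow the G/(A+G) rule with coverage guards", {
    bundle <- toyBundle()
    bundle <- withBases(bundle, 150, "A")
    site <- GRanges("chrT", IRanges(150, width = 1), strand = "+")

    lv <- siteEditingLevel(toyEvidence(150, "A", "G", 16, 4), site)
    expect_equal(unname(lv), 0.20)

    # fewer than three edited reads: undefined
    lv2 <- siteEditingLevel(toyEvidence(150, "A", "G", 18, 2), site)
    expect_true(is.na(lv2))

    # coverage below ten A+G reads: undefined
    lv3 <- siteEditingLevel(toyEvidence(150, "A", "G", 3, 5), site)
    expect_true(is.na(lv3))

    # minus-strand site counts genomic T/C reads
    bundle <- withBases(bundle, 1150, "T")
    siteM <- GRanges("chrT", IRanges(1150, width = 1), strand = "-")
    lv4 <- siteEditingLevel(toyEvidence(1150, "T", "C", 12, 4,
                                        strand = "-"), siteM)
    expect_equal(unname(lv4), 0.25)
})

test_that("overall rate pools reads and equals the weighted per-site mean", {
    bundle <- toyBundle()
    bundle <- withBases(bundle, c(150, 160), c("A", "A"))
    sites <- GRanges("chrT", IRanges(c(150, 160), width = 1),
                     strand = "+")
    ev <- rbind(toyEvidence(150, "A", "G", 9, 1),
                toyEvidence(160, "A", "G", 7, 3))
    design <- data.frame(sample_id = "S1_r1", stage = "S1",
                         replicate = 1L)
    r <- overallEditingRate(ev, sites, design)
    expect_equal(unname(r$perSample), 4 / 20)

    # a site with zero edited reads contributes zero
    ev0 <- toyEvidence(150, "A", "G", 10, 0)
    expect_equal(unname(overallEditingRate(ev0, sites[1],
                                           design)$perSample), 0)

    # algebraic identity: pooled ratio == coverage-weighted mean of
    # per-site ratios, on random fixtures
    set.seed(5)
    for (i in 1:5) {
        nA <- sample(5:30, 4); nG <- sample(0:10, 4)
        pos <- c(150, 160, 170, 180)
        bundle <- withBases(bundle, pos, rep("A", 4))
        ev <- do.call(rbind, lapply(1:4, function(k)
            toyEvidence(pos[k], "A", "G", nA[k], nG[k])))
        ss <- GRanges("chrT", IRanges(pos, width = 1), strand = "+")
        r <- overallEditingRate(ev, ss, design)
        w <- (nA + nG) / sum(nA + nG)
        expect_equal(unname(r$perSample),
                     sum(w * nG / (nA + nG)), tolerance = 1e-12)
    }
})

test_that("feature annotation is a partition with CDS precedence", {
    bundle <- toyBundle()
    # 131 CDS of gP; 300 intron; 700 intergenic; 1050 3'UTR of gM
    sites <- GRanges("chrT", IRanges(c(131, 300, 700, 1050), width = 1),
                     strand = c("+", "+", "+", "-"))
    ann <- annotateFeature(sites, geneModels(bundle))
    expect_equal(as.character(ann$feature),
                 c("CDS", "intron", "intergenic", "3UTR"))
    expect_equal(ann$host_gene[1], "gP")
    expect_true(all(!is.na(ann$feature)))

    # overlapping transcripts: CDS wins over intron
    extra <- geneModels(bundle)
    tx2 <- GRanges("chrT", IRanges(c(250, 250, 290), c(350, 350, 310)),
                   strand = "+", type = c("transcript", "exon", "CDS"),
                   gene_id = "gX", transcript_id = "gX.t1",
                   biotype = "protein_coding")
    ann2 <- annotateFeature(GRanges("chrT", IRanges(300, width = 1),
                                    strand = "+"), c(extra, tx2))
    expect_equal(as.character(ann2$feature), "CDS")

    # lncRNA exons are their own category with the host gene recorded
    lnc <- GRanges("chrT", IRanges(c(1600, 1600, 1600), c(1700, 1700, 1700)),
                   strand = "+", type = c("gene", "transcript", "exon"),
                   gene_id = "lnc1", transcript_id = "lnc1.t1",
                   biotype = "lincRNA")
    ann3 <- annotateFeature(GRanges("chrT", IRanges(1650, width = 1),
                                    strand = "+"),
                            c(geneModels(bundle), lnc))
    expect_equal(as.character(ann3$feature), "ncRNA_exon")
    expect_equal(ann3$host_gene, "lnc1")
})

test_that("recoding annotation translates edited codons", {
    bundle <- toyBundle()
    # codon 1 of the plus-strand CDS occupies 131-133; plant AAT
    ch <- strsplit(as.character(genomeSeq(bundle)[[1]]), "")[[1]]
    ch[131:133] <- c("A", "A", "T")
    ch[134:136] <- c("G", "C", "A")
    bundle2 <- toyBundle(ch)
    genes <- geneModels(bundle2)

    # edit at codon position 2: AAT -> AGT, Asn -> Ser
    s1 <- GRanges("chrT", IRanges(132, width = 1), strand = "+")
    r1 <- annotateRecoding(s1, genes, genomeSeq(bundle2))
    expect_equal(r1$refCodon, "AAT"); expect_equal(r1$altCodon, "AGT")
    expect_equal(r1$refAA, "Asn"); expect_equal(r1$altAA, "Ser")
    expect_equal(r1$consequence, "nonsynonymous")

    # GCA edited at codon position 3 -> GCG, Ala -> Ala, synonymous
    s2 <- GRanges("chrT", IRanges(136, width = 1), strand = "+")
    r2 <- annotateRecoding(s2, genes, genomeSeq(bundle2))
    expect_equal(r2$altCodon, "GCG")
    expect_equal(r2$consequence, "synonymous")
})

test_that("minus-strand recoding mirrors the plus-strand result", {
    bundle <- toyBundle()
    ch <- strsplit(as.character(genomeSeq(bundle)[[1]]), "")[[1]]
    # minus CDS first codon occupies genomic 1468-1470 (transcribed
    # 5'->3' reads 1470,1469,1468); plant complement of AAT = ATT
    ch[1468:1470] <- c("A", "T", "T")
    bundle2 <- toyBundle(ch)
    # transcribed codon pos 2 = genomic 1469 (a T, complement A)
    s <- GRanges("chrT", IRanges(1469, width = 1), strand = "-")
    r <- annotateRecoding(s, geneModels(bundle2), genomeSeq(bundle2))
    expect_equal(r$refCodon, "AAT")
    expect_equal(r$refAA, "Asn"); expect_equal(r$altAA, "Ser")
    expect_equal(r$consequence, "nonsynonymous")
})

test_that("repeat annotation reports distributions and handles empties", {
    st <- sharedStudy()
    sites <- truthSites(st$truth)
    ann <- annotateRepeats(sites, repeatRanges(st$bundle))
    expect_equal(ann$fractionInRepeats, mean(sites$inRepeat),
                 tolerance = 1e-12)
    expect_gte(ann$fractionInRepeats, 0.8 - 1e-9)
    expect_true(all(ann$sites$repeat_family[sites$inRepeat] ==
                    "SINE/tRNA"))
    expect_true(all(ann$sites$repeat_subfamily[sites$inRepeat] ==
                    "Pre0_SS"))

    empty <- annotateRepeats(sites, GRanges())
    expect_true(all(empty$sites$repeat_family == "none"))
    expect_equal(empty$fractionInRepeats, 0)
})

test_that("neighbor preference respects strand and normalizes columns", {
    ch <- rep("C", 2000)
    ch[c(150, 160)] <- "A"; ch[c(151, 161)] <- "G"; ch[c(149, 159)] <- "T"
    bundle <- toyBundle(ch)
    sites <- GRanges("chrT", IRanges(c(150, 160), width = 1),
                     strand = "+")
    np <- neighborPreference(sites, genomeSeq(bundle))
    expect_equal(np["G", "+1"], 1)
    expect_equal(np["T", "-1"], 1)
    expect_equal(unname(colSums(np)), c(1, 1), tolerance = 1e-9)

    # minus-strand: -1 neighbor is the complement of the genomic +1 base
    ch2 <- rep("C", 2000)
    ch2[1150] <- "T"; ch2[1151] <- "A"; ch2[1149] <- "G"
    bundle2 <- toyBundle(ch2)
    sm <- GRanges("chrT", IRanges(1150, width = 1), strand = "-")
    np2 <- neighborPreference(sm, genomeSeq(bundle2))
    expect_equal(np2["T", "-1"], 1)  # complement of genomic A at +1
    expect_equal(np2["C", "+1"], 1)  # complement of genomic G at -1
})

test_that("RPKM follows the exon-model normalization", {
    expect_equal(rpkm(10, 1000, 1e6), 10)
    expect_equal(rpkm(0, 1000, 1e6), 0)
    expect_equal(rpkm(10, 1000, 2e6), 5)
    expect_equal(rpkm(10, 2000, 1e6), 5)
    expect_error(rpkm(10, 0, 1e6), "length")
    expect_error(rpkm(10, 1000, 0), "mapped")
})

test_that("level estimation is unbiased at high coverage", {
    cfg <- simConfig(nTrueSites = 200L, nDiffSites = 0L,
                     coverageMean = 1000, baseErrorRate = 0,
                     replicateSd = 0, nHetSnps = 0L, nKnownOnlySnps = 0L,
                     nArtifactsPerClass = c(read_end = 0L,
                                            homopolymer = 0L, mismap = 0L),
                     nBackgroundSites = 0L, seed = 31L)
    ref <- generateReference(cfg)
    truth <- plantTruth(ref, cfg)
    ev <- simulateRnaEvidence(ref, truth, cfg)
    sites <- truthSites(truth)
    ee <- editingLevelMatrix(ev, sites)
    est <- rowMeans(editingLevels(ee), na.rm = TRUE)
    true <- rowMeans(S4Vectors::mcols(sites)$stageLevel)
    expect_lt(abs(mean(est - true)), 0.01)
    expect_true(all(editingLevels(ee) >= 0 & editingLevels(ee) <= 1,
                    na.rm = TRUE))
})
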