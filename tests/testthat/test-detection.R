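test_that("candidate calling applies quality, allele-type and support rules", {
    bundle <- toyBundle()
    bundle <- withBases(bundle, c(150, 160, 170), c("A", "A", "A"))

    # 12 ref + 4 alt good-quality reads: a candidate
    ev <- toyEvidence(150, "A", "G", 12, 4)
    calls <- callCandidates(ev, bundle)
    expect_length(calls, 1L)
    expect_equal(calls$ref, "A"); expect_equal(calls$alt, "G")
    expect_equal(calls$refCount, 12L); expect_equal(calls$altCount, 4L)

    # alternative support below three reads: no candidate
    expect_length(callCandidates(toyEvidence(150, "A", "G", 12, 2),
                                 bundle), 0L)

    # three allele types with >= 3 reads each: rejected
    ev3 <- rbind(toyEvidence(150, "A", "G", 10, 3),
                 toyEvidence(150, "A", "C", 0, 3))
    expect_length(callCandidates(ev3, bundle), 0L)

    # low-quality alternative reads are not counted
    evq <- rbind(toyEvidence(150, "A", "G", 12, 0),
                 toyEvidence(150, "A", "G", 0, 4, qual = 20L))
    expect_length(callCandidates(evq, bundle), 0L)

    # reference disagreement with the genome is a data-integrity error
    evb <- toyEvidence(150, "C", "G", 12, 4)
    expect_error(callCandidates(evb, bundle), "disagrees with genome")
})

test_that("genomic SNP filter flags WGS het/hom-alt and catalogued positions", {
    bundle <- toyBundle()
    bundle <- withBases(bundle, c(150, 160, 170, 180), rep("A", 4))
    wgs <- GRanges("chrT", IRanges(c(150, 160), width = 1),
                   ref = c("A", "A"), alt = c("G", "G"),
                   genotype = c("het", "hom_alt"),
                   multiallelic = c(FALSE, FALSE))
    ks <- GRanges("chrT", IRanges(170, width = 1))
    bundle2 <- referenceBundle(genomeSeq(bundle), geneModels(bundle),
                               repeatRanges(bundle), ks, wgs)
    ev <- rbind(toyEvidence(150, "A", "G", 10, 5),
                toyEvidence(160, "A", "G", 10, 5),
                toyEvidence(170, "A", "G", 10, 5),
                toyEvidence(180, "A", "G", 10, 5))
    calls <- filterGenomicSnps(callCandidates(ev, bundle2), bundle2)
    expect_equal(calls$flag_wgs_snp, c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(calls$flag_known_snp, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("splice filter removes only near-junction intronic sites", {
    bundle <- toyBundle()
    # intron of the plus gene spans 221-420
    pos <- c(222, 225, 320, 219)   # distances 2, 5, deep intron, exonic
    bundle <- withBases(bundle, pos, rep("A", 4))
    ev <- do.call(rbind, lapply(pos, function(p)
        toyEvidence(p, "A", "G", 10, 5)))
    calls <- filterSpliceProximal(callCandidates(ev, bundle),
                                  geneModels(bundle))
    flags <- calls$flag_splice_proximal[match(pos, start(calls))]
    expect_equal(flags, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("homopolymer filter matches a maximal-run oracle", {
    # constructed runs: AAAAA flagged, AAAA not, first base of 6-run flagged
    ch <- rep(c("C", "T"), length.out = 2000)
    ch[300:304] <- "A"   # run 5
    ch[400:403] <- "A"   # run 4
    ch[500:505] <- "A"   # run 6
    bundle <- toyBundle(ch)
    pos <- c(302, 401, 500)
    ev <- do.call(rbind, lapply(pos, function(p)
        toyEvidence(p, "A", "G", 10, 5)))
    calls <- filterHomopolymer(callCandidates(ev, bundle),
                               genomeSeq(bundle))
    expect_equal(calls$flag_homopolymer[match(pos, start(calls))],
                 c(TRUE, FALSE, TRUE))

    # property: agreement with an independent rle-based oracle on random
    # genomes
    set.seed(9)
    for (rep in 1:5) {
        ch <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE,
                     prob = c(0.4, 0.1, 0.1, 0.4))
        bundle <- toyBundle(ch)
        pos <- sample(100:1900, 25)
        ev <- do.call(rbind, lapply(pos, function(p)
            toyEvidence(p, ch[p], if (ch[p] == "G") "A" else "G", 10, 5)))
        calls <- filterHomopolymer(callCandidates(ev, bundle),
                                   genomeSeq(bundle))
        r <- rle(ch)
        runLen <- rep(r$lengths, r$lengths)
        expect_equal(calls$flag_homopolymer,
                     runLen[start(calls)] >= 5L)
    }
})

test_that("read-end filter recounts alternative support away from read ends", {
    bundle <- toyBundle()
    bundle <- withBases(bundle, c(150, 160), c("A", "A"))
    # alt offsets: 3 from 5' end, 5 from 3' end (offset5 = 146), internal
    ev <- rbind(toyEvidence(150, "A", "G", 12, 0),
                toyEvidence(150, "A", "G", 0, 1, off5Alt = 3L),
                toyEvidence(150, "A", "G", 0, 1, off5Alt = 146L),
                toyEvidence(150, "A", "G", 0, 1, off5Alt = 40L))
    calls <- callCandidates(ev, bundle)
    calls <- filterReadEnd(calls, ev)
    expect_equal(calls$altCountEndFiltered, 1L)
    expect_true(calls$flag_read_end)

    ev2 <- rbind(toyEvidence(160, "A", "G", 12, 3, off5Alt = 40L))
    calls2 <- filterReadEnd(callCandidates(ev2, bundle), ev2)
    expect_equal(calls2$altCountEndFiltered, 3L)
    expect_false(calls2$flag_read_end)

    # degenerate margin 0 is a no-op
    cfg0 <- detectionConfig(readEndMargin = 0L)
    calls3 <- filterReadEnd(callCandidates(ev, bundle, cfg0), ev, cfg0)
    expect_equal(calls3$altCountEndFiltered, 3L)
    expect_false(calls3$flag_read_end)
})

test_that("multimap filter flags duplicated windows on both methods", {
    st <- sharedStudy()
    bundle <- st$bundle
    arts <- truthArtifacts(st$truth)
    mm <- arts[arts$class == "mismap"]
    ev <- st$evidence
    calls <- callCandidates(ev, bundle)
    m1 <- filterMultimap(calls, genomeSeq(bundle))
    m2 <- filterMultimap(calls, genomeSeq(bundle), method = "alignment")
    expect_equal(m1$flag_multimap, m2$flag_multimap)
    expect_true(all(start(mm) %in% start(m1)[m1$flag_multimap]))
    # true sites (unique sequence or diverged repeats) are never flagged
    expect_false(any(start(truthSites(st$truth)) %in%
                     start(m1)[m1$flag_multimap]))
})

test_that("a score ratio of 1 flags only exact duplicates", {
    ch <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
    ch[301:400] <- ch[1001:1100]   # plant one exact 100 bp duplicate
    ch[350] <- "A"; ch[1050] <- "A"
    ch[600] <- "A"
    bundle <- toyBundle(ch)
    cfg <- detectionConfig(multimapScoreRatio = 1.0)
    ev <- rbind(toyEvidence(350, "A", "G", 10, 5),
                toyEvidence(600, "A", "G", 10, 5))
    calls <- filterMultimap(callCandidates(ev, bundle, cfg),
                            genomeSeq(bundle), cfg)
    expect_equal(calls$flag_multimap[match(c(350, 600), start(calls))],
                 c(TRUE, FALSE))
})

test_that("strand and mismatch type resolve on the transcribed strand", {
    bundle <- toyBundle()
    # genomic T>C inside the minus-strand gene is A-to-G on the transcript
    bundle <- withBases(bundle, c(1150, 150), c("T", "A"))
    ev <- rbind(toyEvidence(1150, "T", "C", 10, 5, strand = "-"),
                toyEvidence(150, "A", "G", 10, 5))
    calls <- resolveStrandType(callCandidates(ev, bundle),
                               geneModels(bundle), ev)
    expect_equal(as.character(strand(calls))[match(1150, start(calls))],
                 "-")
    expect_equal(calls$mismatchType[match(1150, start(calls))], "A-to-G")
    expect_equal(calls$mismatchType[match(150, start(calls))], "A-to-G")

    # intergenic site: majority library strand; ties stay unresolved
    bundle <- withBases(bundle, c(700, 750), c("A", "A"))
    ev2 <- rbind(toyEvidence(700, "A", "G", 6, 4, strand = "+"),
                 toyEvidence(700, "A", "G", 2, 1, strand = "-"),
                 toyEvidence(750, "A", "G", 5, 3, strand = "+"),
                 toyEvidence(750, "A", "G", 5, 3, strand = "-"))
    calls2 <- resolveStrandType(callCandidates(ev2, bundle),
                                geneModels(bundle), ev2)
    expect_equal(as.character(strand(calls2))[match(700, start(calls2))],
                 "+")
    expect_equal(as.character(strand(calls2))[match(750, start(calls2))],
                 "*")
    expect_true(is.na(calls2$mismatchType[match(750, start(calls2))]))
})

test_that("type tally conserves counts and selects the A-to-I subset", {
    res <- sharedDetection()
    counts <- mismatchTypeCounts(res)
    calls <- editingCalls(res)
    survStrand <- surviving(res)
    survStrand <- survStrand[!is.na(survStrand$mismatchType)]
    expect_equal(sum(counts), length(survStrand))
    expect_equal(length(editingSites(res)),
                 unname(counts[["A-to-G"]]))
    # conservation: candidates = surviving + flagged (multi-flag once)
    flagged <- vapply(callFilterFlags(calls), length, 1L) > 0L
    expect_equal(length(calls), sum(flagged) + length(surviving(res)))
})

test_that("filters commute: any application order gives the same set", {
    st <- sharedStudy()
    cfg <- detectionConfig()
    bundle <- st$bundle
    base <- callCandidates(st$evidence, bundle, cfg)
    o1 <- filterMultimap(filterReadEnd(filterHomopolymer(
        filterSpliceProximal(filterGenomicSnps(base, bundle),
                             geneModels(bundle), cfg),
        genomeSeq(bundle), cfg), st$evidence, cfg), genomeSeq(bundle), cfg)
    o2 <- filterGenomicSnps(filterSpliceProximal(filterHomopolymer(
        filterReadEnd(filterMultimap(base, genomeSeq(bundle), cfg),
                      st$evidence, cfg), genomeSeq(bundle), cfg),
        geneModels(bundle), cfg), bundle)
    f1 <- as.data.frame(S4Vectors::mcols(o1)[, startsWith(
        colnames(S4Vectors::mcols(o1)), "flag_")])
    f2 <- as.data.frame(S4Vectors::mcols(o2)[, startsWith(
        colnames(S4Vectors::mcols(o2)), "flag_")])
    expect_equal(f1, f2)
})

test_that("planted truth is recovered and artifacts are excluded", {
    st <- sharedStudy()
    res <- sharedDetection()
    siteKeys <- paste0(seqnames(editingSites(res)), ":",
                       start(editingSites(res)))
    truth <- st$truth
    truthKeys <- paste0(seqnames(truthSites(truth)), ":",
                        start(truthSites(truth)))
    lvl <- rowMeans(S4Vectors::mcols(truthSites(truth))$stageLevel)
    expect_gte(mean(truthKeys[lvl >= 0.2] %in% siteKeys), 0.95)
    badKeys <- c(paste0(seqnames(truthArtifacts(truth)), ":",
                        start(truthArtifacts(truth))),
                 paste0(seqnames(truthHetSnps(truth)), ":",
                        start(truthHetSnps(truth))))
    expect_length(intersect(badKeys, siteKeys), 0L)
    # no false positives beyond the planted truth
    expect_true(all(siteKeys %in% truthKeys))
})

test_that("detection is symmetric under reverse-complementing the study", {
    st <- sharedStudy()
    res <- sharedDetection()
    rcs <- reverseComplementStudy(st)
    res2 <- detectEditingSites(rcs$evidence, rcs$bundle)
    L <- width(genomeSeq(st$bundle))[[1]]
    mapped <- L - start(editingSites(res2)) + 1L
    expect_setequal(mapped, start(editingSites(res)))
    # strand flips, type stays A-to-G
    expect_true(all(editingSites(res2)$mismatchType == "A-to-G"))
})
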