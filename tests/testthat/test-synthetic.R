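test_that("generator is deterministic and refuses infeasible configs", {
    cfg <- smallConfig(seed = 7L)
    r1 <- generateReference(cfg)
    r2 <- generateReference(cfg)
    expect_identical(as.character(genomeSeq(r1)), as.character(genomeSeq(r2)))
    s1 <- simulateStudy(cfg); s2 <- simulateStudy(cfg)
    expect_identical(s1$evidence, s2$evidence)
    expect_identical(as.character(s1$mirnas), as.character(s2$mirnas))

    expect_error(generateReference(smallConfig(nGenes = 0L)), "gene")
    expect_error(generateReference(smallConfig(genomeLength = 5000L)),
                 "genomeLength")
    expect_error(simConfig(stageLevels = c(Y30 = 1.5)), "0,1")
    expect_error(simConfig(readLength = 5L), "readLength")
})

test_that("the duplicated segment pair is >= 95% identical (alignment oracle)", {
    ref <- generateReference(smallConfig(seed = 5L, dupMutations = 4L))
    dup <- S4Vectors::metadata(geneModels(ref))$duplication
    genome <- genomeSeq(ref)[[1]]
    a <- subseq(genome, start(dup)[1], end(dup)[1])
    b <- subseq(genome, start(dup)[2], end(dup)[2])
    aln <- pairwiseAlignment(a, b, type = "global")
    expect_gte(Biostrings::pid(aln), 95)
})

test_that("true sites sit on transcribed-strand adenosines, mostly in repeats", {
    st <- sharedStudy()
    sites <- truthSites(st$truth)
    ch <- strsplit(as.character(genomeSeq(st$bundle)[[1]]), "")[[1]]
    plus <- as.character(strand(sites)) == "+"
    expect_true(all(ch[start(sites)[plus]] == "A"))
    expect_true(all(ch[start(sites)[!plus]] == "T"))
    inRep <- countOverlaps(sites, repeatRanges(st$bundle),
                           ignore.strand = TRUE) > 0L
    expect_gte(mean(inRep), 0.8 - 1e-9)
    expect_identical(unname(inRep), sites$inRepeat)
})

test_that("per-stage means of planted levels match the configured targets", {
    cfg <- simConfig(nTrueSites = 500L, nDiffSites = 0L,
                     stageLevels = c(S1 = 0.15, S2 = 0.25, S3 = 0.18),
                     seed = 12L)
    ref <- generateReference(cfg)
    truth <- plantTruth(ref, cfg)
    lvl <- S4Vectors::mcols(truthSites(truth))$stageLevel
    expect_equal(unname(colMeans(lvl)), c(0.15, 0.25, 0.18),
                 tolerance = 0.02 / 0.2)  # +/- 0.02 absolute
    for (s in colnames(lvl))
        expect_lt(abs(mean(lvl[, s]) - cfg@stageLevels[[s]]), 0.02)
})

test_that("empty truth is valid and positions never collide", {
    cfg <- smallConfig(nTrueSites = 0L, nDiffSites = 0L)
    truth <- plantTruth(generateReference(cfg), cfg)
    expect_length(truthSites(truth), 0L)
    expect_true(validObject(truth))

    st <- sharedStudy()
    tr <- st$truth
    pos <- c(start(truthSites(tr)), start(truthHetSnps(tr)),
             start(tr@knownOnlySnps), start(truthArtifacts(tr)))
    expect_false(anyDuplicated(pos) > 0L)
})

test_that("artifact classes are built to violate exactly their filter", {
    st <- sharedStudy()
    arts <- truthArtifacts(st$truth)
    ch <- strsplit(as.character(genomeSeq(st$bundle)[[1]]), "")[[1]]
    runLen <- homopolymerRunLengths(paste(ch, collapse = ""))
    homo <- arts[arts$class == "homopolymer"]
    expect_true(all(runLen[start(homo)] >= 5L))
    dup <- st$truth@duplication
    mm <- arts[arts$class == "mismap"]
    expect_true(all(start(mm) >= start(dup)[1] &
                    start(mm) <= end(dup)[1]))
    # read-end artifacts: no alternative read internal at both ends
    re <- arts[arts$class == "read_end"]
    ev <- st$evidence[pos %in% start(re)]
    altBase <- ifelse(as.character(strand(re))[match(ev$pos, start(re))] ==
                      "+", "G", "C")
    alt <- ev[ev$base == altBase]
    expect_true(all(pmin(alt$offset_from_5p, alt$offset_from_3p) <= 6L))
})

test_that("WGS genotypes are het records that avoid editing sites and round-trip", {
    st <- sharedStudy()
    wgs <- wgsGenotypeRanges(st$bundle)
    expect_length(wgs, 10L)
    expect_true(all(wgs$genotype == "het"))
    expect_length(intersect(start(wgs), start(truthSites(st$truth))), 0L)

    path <- tempfile(fileext = ".vcf")
    writeSimpleVcf(wgs, path)
    back <- readVcfPositions(path, "genotype")
    expect_equal(start(back), start(wgs))
    expect_equal(back$genotype, wgs$genotype)
    expect_equal(back$ref, wgs$ref)
    expect_equal(back$alt, wgs$alt)
})

test_that("binomial sampling concentrates at the planted editing level", {
    cfg <- simConfig(nTrueSites = 1L, nDiffSites = 0L,
                     stageLevels = c(S1 = 0.5), nReplicates = 1L,
                     coverageMean = 10000, baseErrorRate = 0,
                     siteLevelSd = 0, replicateSd = 0,
                     nHetSnps = 0L, nKnownOnlySnps = 0L,
                     nArtifactsPerClass = c(read_end = 0L,
                                            homopolymer = 0L, mismap = 0L),
                     nBackgroundSites = 0L, seed = 3L)
    ref <- generateReference(cfg)
    truth <- plantTruth(ref, cfg)
    ev <- simulateRnaEvidence(ref, truth, cfg)
    site <- truthSites(truth)
    gB <- if (as.character(strand(site)) == "+") "G" else "C"
    aB <- if (as.character(strand(site)) == "+") "A" else "T"
    nG <- sum(ev$base == gB); nA <- sum(ev$base == aB)
    expect_gte(nG / (nA + nG), 0.48)
    expect_lte(nG / (nA + nG), 0.52)
})

test_that("level zero with zero error rate yields no edited reads", {
    cfg <- simConfig(nTrueSites = 5L, nDiffSites = 0L,
                     stageLevels = c(S1 = 0), nReplicates = 2L,
                     baseErrorRate = 0, siteLevelSd = 0, replicateSd = 0,
                     nHetSnps = 0L, nKnownOnlySnps = 0L,
                     nArtifactsPerClass = c(read_end = 0L,
                                            homopolymer = 0L, mismap = 0L),
                     nBackgroundSites = 0L, seed = 4L)
    ref <- generateReference(cfg)
    truth <- plantTruth(ref, cfg)
    ev <- simulateRnaEvidence(ref, truth, cfg)
    expect_true(all(ev$base == ev$ref_base))
})

test_that("true sites at usable levels always carry enough edited reads", {
    # separability: error-free coverage >= 30 leaves >= 3 edited reads at
    # every site with level >= 0.2 (binomial tail over pooled samples)
    for (seed in c(21L, 22L, 23L)) {
        cfg <- smallConfig(seed = seed, coverageMean = 30)
        study <- simulateStudy(cfg)
        sites <- truthSites(study$truth)
        lvl <- rowMeans(S4Vectors::mcols(sites)$stageLevel)
        hi <- sites[lvl >= 0.2]
        ev <- study$evidence[pos %in% start(hi)]
        gB <- ifelse(as.character(strand(hi)) == "+", "G", "C")
        nG <- vapply(seq_along(hi), function(i)
            sum(ev$pos == start(hi)[i] & ev$base == gB[i]), 1L)
        expect_true(all(nG >= 3L))
    }
})
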