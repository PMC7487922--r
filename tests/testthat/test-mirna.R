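revcompRna <- function(dna) {
    comp <- c(A = "U", C = "G", G = "C", T = "A")
    paste(rev(unname(comp[strsplit(dna, "")[[1]]])), collapse = "")
}

test_that("a perfect complement scores the hand-computed maximum", {
    set.seed(1)
    flank <- paste(sample(c("A", "C", "G", "T"), 101, replace = TRUE),
                   collapse = "")
    target22 <- substr(flank, 40, 61)
    mir <- Biostrings::RNAStringSet(setNames(revcompRna(target22), "m1"))
    hits <- scanTargets(flank, mir)
    expect_equal(nrow(hits), 1L)
    # 7 seed positions at 2*5 plus 15 at 5
    expect_equal(hits$score, 7 * 10 + 15 * 5)
    expect_equal(c(hits$tStart, hits$tEnd), c(40, 61))
    expect_equal(hits$nPairs, 22L)
    expect_lte(hits$energy, -7)
})

test_that("score thresholds behave monotonically and reject random pairs", {
    set.seed(2)
    flank <- paste(sample(c("A", "C", "G", "T"), 101, replace = TRUE),
                   collapse = "")
    mirs <- Biostrings::RNAStringSet(setNames(
        vapply(1:5, function(i) paste(sample(c("A", "C", "G", "U"), 22,
                                             replace = TRUE),
                                      collapse = ""), ""),
        paste0("r", 1:5)))
    strict <- scanTargets(flank, mirs, mirandaParams())
    expect_equal(nrow(strict), 0L)

    counts <- vapply(c(140, 100, 60, 0), function(th)
        nrow(scanTargets(flank, mirs,
                         mirandaParams(scoreThreshold = th,
                                       energyThreshold = 1e6))), 1L)
    expect_true(all(diff(counts) >= 0))
})

test_that("duplex energies follow the nearest-neighbor stack model", {
    p <- mirandaParams(scoreThreshold = 0, energyThreshold = 1e6)
    # G:C-only duplex vs A:U-only duplex of the same length
    gc <- paste(rep("G", 20), collapse = "")
    au <- paste(rep("A", 20), collapse = "")
    hGc <- scanTargets(gc, Biostrings::RNAStringSet(c(m = revcompRna(gc))),
                       p)
    hAu <- scanTargets(au, Biostrings::RNAStringSet(c(m = revcompRna(au))),
                       p)
    expect_equal(hGc$energy[1], -3.3 * 19, tolerance = 1e-9)
    expect_equal(hAu$energy[1], -1.1 * 19, tolerance = 1e-9)
    expect_lt(hGc$energy[1], hAu$energy[1])

    # single pair only: no stack, zero energy
    pr <- data.frame(targetPos = 5L, mirnaPos = 3L, class = 2L)
    expect_equal(duplexEnergy(pr, strsplit("AAAAG", "")[[1]],
                              strsplit("CUU", "")[[1]]), 0)

    # mismatches weaken a duplex relative to its perfect version
    set.seed(4)
    t22 <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                 collapse = "")
    perfect <- scanTargets(t22, Biostrings::RNAStringSet(
        c(m = revcompRna(t22))), p)
    ch <- strsplit(t22, "")[[1]]
    ch[c(8, 12, 16)] <- c("A", "A", "A")  # disrupt three pairs
    mut <- paste(ch, collapse = "")
    worse <- scanTargets(mut, Biostrings::RNAStringSet(
        c(m = revcompRna(t22))), p)
    expect_lt(perfect$energy[1], worse$energy[1])
})

test_that("flank pairs are strand-aware and truncate at transcript ends", {
    st <- sharedStudy()
    res <- sharedDetection()
    sites <- annotateSites(editingSites(res), st$bundle)
    u3 <- sites[as.character(sites$feature) == "3UTR"]
    plus <- u3[as.character(strand(u3)) == "+"][1]
    fp <- extractFlankPair(plus, st$bundle)
    expect_equal(fp@editIndex, 51L)
    expect_equal(substr(fp@refSeq, 51, 51), "A")
    expect_equal(substr(fp@editSeq, 51, 51), "G")
    expect_true(validObject(fp))

    minus <- u3[as.character(strand(u3)) == "-"][1]
    fpM <- extractFlankPair(minus, st$bundle)
    ch <- strsplit(as.character(genomeSeq(st$bundle)[[1]]), "")[[1]]
    expect_equal(ch[start(minus)], "T")
    expect_equal(substr(fpM@refSeq, fpM@editIndex, fpM@editIndex), "A")

    # a site close to the transcript boundary records its truncation
    genes <- geneModels(st$bundle)
    tx <- genes[genes$type == "transcript" &
                genes$gene_id == plus$host_gene][1]
    nearEnd <- GRanges(seqnames(plus), IRanges(end(tx) - 10L, width = 1L),
                       strand = "+", feature = factor("3UTR"))
    ch2 <- ch[start(nearEnd)]
    if (ch2 == "A") {
        fpE <- extractFlankPair(nearEnd, st$bundle)
        expect_equal(fpE@truncated3, 39L)
        expect_equal(nchar(fpE@refSeq), 62L)
    }
    intronic <- sites[as.character(sites$feature) == "intron"][1]
    expect_error(extractFlankPair(intronic, st$bundle), "3'-UTR")
})

test_that("editing gains, destroys or retunes binding sites as constructed", {
    set.seed(6)
    flankCh <- sample(c("A", "C", "G", "T"), 101, replace = TRUE)
    flankCh[51] <- "A"
    ref <- paste(flankCh, collapse = "")
    editCh <- flankCh; editCh[51] <- "G"
    edit <- paste(editCh, collapse = "")

    # miRNA designed against the EDITED window, edited base in the seed
    gainTarget <- substr(edit, 33, 54)   # position 51 = miRNA pos 4
    lossTarget <- substr(ref, 33, 54)
    mirs <- Biostrings::RNAStringSet(c(gain = revcompRna(gainTarget),
                                       loss = revcompRna(lossTarget)))
    hr <- scanTargets(ref, mirs)
    he <- scanTargets(edit, mirs)
    eff <- classifyEffects(hr, he)
    expect_equal(eff$class[eff$mirna == "gain"], "gained")
    expect_equal(eff$class[eff$mirna == "loss"], "lost")

    # swapping reference and edited scans is antisymmetric
    effSwap <- classifyEffects(he, hr)
    expect_equal(effSwap$class[effSwap$mirna == "gain"], "lost")
    expect_equal(effSwap$class[effSwap$mirna == "loss"], "gained")

    # a hit away from the edited base is bit-identical in both scans
    awayTarget <- substr(ref, 5, 26)    # never covers position 51
    mirA <- Biostrings::RNAStringSet(c(away = revcompRna(awayTarget)))
    ha <- scanTargets(ref, mirA); hb <- scanTargets(edit, mirA)
    expect_identical(ha$score, hb$score)
    expect_identical(ha$tStart, hb$tStart)
    expect_identical(ha$energy, hb$energy)
    effA <- classifyEffects(ha, hb)
    expect_equal(effA$class, "unchanged")
    expect_equal(effA$deltaE, 0)
})

test_that("hits that do not cover the edited base never change class", {
    st <- sharedStudy()
    res <- sharedDetection()
    sites <- annotateSites(editingSites(res), st$bundle)
    u3 <- sites[as.character(sites$feature) == "3UTR"]
    me <- mirnaEffects(u3[seq_len(min(6, length(u3)))], st$bundle,
                       st$mirnas)
    eff <- me$effects
    expect_true(all(eff$class %in% c("gained", "lost", "energy_changed",
                                     "unchanged")))
    gained <- eff[eff$class == "gained", ]
    expect_true(all(is.na(gained$energyRef) & !is.na(gained$energyEdit)))
    lost <- eff[eff$class == "lost", ]
    expect_true(all(!is.na(lost$energyRef) & is.na(lost$energyEdit)))
})

test_that("energy-distribution comparison detects shifts and symmetry", {
    set.seed(8)
    ref <- -runif(40, 5, 7)
    edit <- ref - 2
    r <- compareEnergyDistributions(ref, edit)
    expect_lt(r$p, 0.01)
    expect_equal(r$medianDiff, -2, tolerance = 1e-9)

    same <- compareEnergyDistributions(ref, ref)
    expect_equal(same$p, 1, tolerance = 1e-9)
    expect_equal(same$medianDiff, 0)

    sw <- compareEnergyDistributions(edit, ref)
    expect_equal(sw$p, r$p, tolerance = 1e-6)
    expect_equal(sw$medianDiff, 2, tolerance = 1e-9)

    expect_equal(compareEnergyDistributions(rep(-5, 5), rep(-5, 4))$p, 1)
    expect_error(compareEnergyDistributions(c(-1, -2), c(-3, -4, -5)),
                 "three")
})
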