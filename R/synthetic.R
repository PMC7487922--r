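#' @importFrom Biostrings reverseComplement DNAString readDNAStringSet
#'   writeXStringSet subseq
#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps strand<-
#' @importFrom data.table data.table rbindlist setorder := .N
NULL

SYN_CONTIG <- "chrS"

# gene cassette geometry (bp), in transcribed order
GENE_BLOCKS <- list(
    e1 = 150L,  # 90 bp 5'UTR + 60 bp CDS
    i1 = 600L,  # hosts a SINE copy at offset 25
    e2 = 300L,  # CDS
    i2 = 600L,  # homopolymer run at offset 50; gene 1: duplication source
    e3 = 600L)  # 120 bp CDS + 480 bp 3'UTR (SINE at 3'UTR+100, run at +370)
GENE_LEN <- sum(unlist(GENE_BLOCKS))
GENE_GAP <- 1000L
GENOME_MARGIN <- 500L
REPEAT_LEN <- 250L
REPEAT_MUT_RATE <- 0.12
HOMOPOL_INTRON_RUN <- 10L
HOMOPOL_UTR_RUN <- 8L
HOMOPOL_FILTER_RUN <- 5L   # run length the downstream filter removes
PLACEMENT_JUNCTION_MARGIN <- 6L  # keep true sites clear of splice filters
PLACEMENT_DUP_MARGIN <- 30L      # keep true sites clear of the duplication

randomDna <- function(n, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
    sample(names(probs), n, replace = TRUE, prob = probs)
}

mutateSeq <- function(ch, rate) {
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
    ch
}

revcompChars <- function(ch) rev(unname(COMPLEMENT[ch]))

#' Generate a synthetic reference bundle
#'
#' Builds a single-contig genome carrying \code{nGenes} gene cassettes on
#' alternating strands (each with 5'-UTR, split CDS, introns and a long
#' 3'-UTR; the last two genes are annotated as lncRNAs when
#' \code{nGenes >= 4}), an A-rich SINE family ("SINE/tRNA:Pre0_SS") planted
#' in introns and 3'-UTRs, homopolymer runs inside transcribed regions, and
#' one intronic segment duplicated into intergenic space (the multi-mapping
#' trap).  Deterministic for a given \code{config}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{ReferenceBundle}; the duplication and planted
#'   homopolymer runs are recorded in \code{metadata(geneModels(ref))}.
#' @export
generateReference <- function(config) {
    validObject(config)
    if (config@nGenes < 1L)
        stop("infeasible config: at least one gene is required")
    set.seed(subSeed(config@seed, 1L))
    nG <- config@nGenes
    lastGeneEnd <- GENOME_MARGIN + nG * GENE_LEN + (nG - 1L) * GENE_GAP
    needed <- lastGeneEnd + 300L + config@dupLength + 100L
    if (config@genomeLength < needed)
        stop(sprintf(paste0("infeasible config: genomeLength %d < %d bp ",
                            "needed for %d genes plus the duplicated ",
                            "segment"), config@genomeLength, needed, nG))

    seqCh <- randomDna(config@genomeLength)
    strands <- rep(c("+", "-"), length.out = nG)
    biotypes <- rep("protein_coding", nG)
    if (nG >= 4L) biotypes[c(nG - 1L, nG)] <- c("lincRNA", "novel_lncRNA")

    feats <- list(); reps <- list(); homos <- list()
    consensus <- randomDna(REPEAT_LEN,
                           c(A = 0.45, C = 0.15, G = 0.12, T = 0.28))
    dupSource <- NULL

    for (g in seq_len(nG)) {
        gStart <- GENOME_MARGIN + (g - 1L) * (GENE_LEN + GENE_GAP) + 1L
        gEnd <- gStart + GENE_LEN - 1L
        strand <- strands[g]
        gid <- sprintf("geneS%02d", g)
        tid <- paste0(gid, ".t1")

        # genomic intervals of the transcribed-order blocks
        widths <- unlist(GENE_BLOCKS)
        ord <- if (strand == "+") seq_along(widths) else rev(seq_along(widths))
        gw <- widths[ord]
        gs <- gStart + cumsum(c(0L, gw[-length(gw)]))
        ge <- gs + gw - 1L
        blocks <- data.frame(name = names(gw), start = gs, end = ge)
        b <- function(nm) blocks[blocks$name == nm, , drop = FALSE]
        # sub-interval of a block measured in transcribed coordinates
        sub <- function(nm, from, to) {
            bk <- b(nm)
            if (strand == "+") c(bk$start + from - 1L, bk$start + to - 1L)
            else c(bk$end - to + 1L, bk$end - from + 1L)
        }
        add <- function(type, s, e) {
            feats[[length(feats) + 1L]] <<- data.frame(
                start = s, end = e, strand = strand, type = type,
                gene_id = gid, transcript_id = tid, biotype = biotypes[g])
        }
        add("gene", gStart, gEnd); add("transcript", gStart, gEnd)
        for (nm in c("e1", "e2", "e3")) add("exon", b(nm)$start, b(nm)$end)
        for (nm in c("i1", "i2")) add("intron", b(nm)$start, b(nm)$end)
        if (biotypes[g] == "protein_coding") {
            u5 <- sub("e1", 1L, 90L); c1 <- sub("e1", 91L, 150L)
            c3 <- sub("e3", 1L, 120L); u3 <- sub("e3", 121L, 600L)
            add("five_prime_utr", u5[1], u5[2])
            add("CDS", c1[1], c1[2])
            add("CDS", b("e2")$start, b("e2")$end)
            add("CDS", c3[1], c3[2])
            add("three_prime_utr", u3[1], u3[2])
        }

        plantRepeat <- function(s) {
            ch <- mutateSeq(consensus, REPEAT_MUT_RATE)
            if (strand == "-") ch <- revcompChars(ch)
            seqCh[s:(s + REPEAT_LEN - 1L)] <<- ch
            reps[[length(reps) + 1L]] <<- data.frame(
                start = s, end = s + REPEAT_LEN - 1L, strand = strand)
        }
        r1 <- sub("i1", 26L, 25L + REPEAT_LEN)
        plantRepeat(min(r1))
        r2 <- sub("e3", 221L, 220L + REPEAT_LEN)  # inside the 3'UTR
        plantRepeat(min(r2))

        plantRun <- function(s, len) {
            base <- if (strand == "+") "A" else "T"
            seqCh[s:(s + len - 1L)] <<- base
            homos[[length(homos) + 1L]] <<- data.frame(
                start = s, end = s + len - 1L, strand = strand)
        }
        h1 <- sub("i2", 51L, 50L + HOMOPOL_INTRON_RUN)
        plantRun(min(h1), HOMOPOL_INTRON_RUN)
        h2 <- sub("e3", 491L, 490L + HOMOPOL_UTR_RUN)
        plantRun(min(h2), HOMOPOL_UTR_RUN)

        if (g == 1L) {
            d <- sub("i2", 121L, 120L + config@dupLength)
            dupSource <- c(min(d), max(d))
        }
    }

    # duplicate the source segment into intergenic space past the last gene
    copyStart <- lastGeneEnd + 300L
    srcCh <- seqCh[dupSource[1]:dupSource[2]]
    copyCh <- if (config@dupMutations > 0L) {
        idx <- sample(length(srcCh), min(config@dupMutations, length(srcCh)))
        tmp <- srcCh
        for (i in idx) tmp[i] <- sample(setdiff(BASES, tmp[i]), 1L)
        tmp
    } else srcCh
    seqCh[copyStart:(copyStart + config@dupLength - 1L)] <- copyCh

    genome <- DNAStringSet(setNames(paste(seqCh, collapse = ""), SYN_CONTIG))
    featDf <- do.call(rbind, feats)
    genes <- GRanges(SYN_CONTIG, IRanges(featDf$start, featDf$end),
                     strand = featDf$strand, type = featDf$type,
                     gene_id = featDf$gene_id,
                     transcript_id = featDf$transcript_id,
                     biotype = featDf$biotype)
    GenomeInfoDb::seqlengths(genes) <- setNames(config@genomeLength,
                                                SYN_CONTIG)
    repDf <- do.call(rbind, reps)
    repeats <- GRanges(SYN_CONTIG, IRanges(repDf$start, repDf$end),
                       strand = repDf$strand,
                       family = "SINE/tRNA", subfamily = "Pre0_SS")
    homoDf <- do.call(rbind, homos)
    metadata(genes)$homopolymers <- GRanges(
        SYN_CONTIG, IRanges(homoDf$start, homoDf$end), strand = homoDf$strand)
    metadata(genes)$duplication <- GRanges(
        SYN_CONTIG,
        IRanges(c(dupSource[1], copyStart),
                c(dupSource[2], copyStart + config@dupLength - 1L)),
        role = c("source", "copy"))
    referenceBundle(genome, genes, repeats)
}

# integer positions of transcribed-strand adenosines within gene bodies,
# with exclusion of homopolymers, splice-junction margins and the
# duplicated segment
.placementPool <- function(ref, config) {
    genes <- geneModels(ref)
    seqCh <- strsplit(as.character(genomeSeq(ref)[[SYN_CONTIG]]), "")[[1]]
    runLen <- homopolymerRunLengths(paste(seqCh, collapse = ""))
    gene <- genes[genes$type == "gene"]
    introns <- genes[genes$type == "intron"]
    dup <- metadata(genes)$duplication
    excl <- rep(FALSE, length(seqCh))
    excl[runLen >= HOMOPOL_FILTER_RUN] <- TRUE
    for (i in seq_along(introns)) {
        s <- start(introns)[i]; e <- end(introns)[i]
        m <- PLACEMENT_JUNCTION_MARGIN
        excl[s:min(e, s + m - 1L)] <- TRUE
        excl[max(s, e - m + 1L):e] <- TRUE
    }
    ds <- max(1L, start(dup)[1] - PLACEMENT_DUP_MARGIN)
    de <- min(length(seqCh), end(dup)[1] + PLACEMENT_DUP_MARGIN)
    excl[ds:de] <- TRUE
    excl[start(dup)[2]:end(dup)[2]] <- TRUE
    excl[c(1L, 2L, length(seqCh) - 1L, length(seqCh))] <- TRUE

    pool <- list()
    for (i in seq_along(gene)) {
        s <- start(gene)[i]; e <- end(gene)[i]
        st <- as.character(strand(gene))[i]
        want <- if (st == "+") "A" else "T"
        pos <- (s:e)[seqCh[s:e] == want & !excl[s:e]]
        pool[[i]] <- data.frame(pos = pos, strand = st,
                                gene_id = gene$gene_id[i])
    }
    do.call(rbind, pool)
}

#' Plant the synthetic editing truth
#'
#' Places true A-to-I sites on transcribed-strand adenosines (about 80%
#' inside the SINE repeats, emulating the strong repeat enrichment of real
#' editomes), assigns per-site, per-stage true editing levels around the
#' configured stage means (with \code{nDiffSites} sites shifted by
#' \code{diffDelta} in one stage), and plants heterozygous SNPs,
#' catalogue-only SNPs and three artifact classes, each of which violates
#' exactly one downstream filter.
#'
#' @param ref a \linkS4class{ReferenceBundle} from
#'   \code{\link{generateReference}}.
#' @param config the same \linkS4class{SimConfig}.
#' @return a \linkS4class{SyntheticTruth}.
#' @export
plantTruth <- function(ref, config) {
    set.seed(subSeed(config@seed, 2L))
    pool <- .placementPool(ref, config)
    genes <- geneModels(ref)
    dup <- metadata(genes)$duplication
    homos <- metadata(genes)$homopolymers
    inRepeat <- countOverlaps(GRanges(SYN_CONTIG, IRanges(pool$pos,
                                                          width = 1L)),
                              repeatRanges(ref), ignore.strand = TRUE) > 0L

    takeFrom <- function(df, n, what) {
        if (nrow(df) < n)
            stop(sprintf("not enough adenosines to place %d %s sites",
                         n, what))
        df[sample.int(nrow(df), n), , drop = FALSE]
    }
    used <- integer()
    stages <- names(config@stageLevels)

    nRep <- round(0.8 * config@nTrueSites)
    repPick <- takeFrom(pool[inRepeat, ], nRep, "repeat true")
    nonPick <- takeFrom(pool[!inRepeat, ], config@nTrueSites - nRep,
                        "non-repeat true")
    truePick <- rbind(repPick, nonPick)
    used <- c(used, truePick$pos)

    nT <- nrow(truePick)
    lvl <- matrix(NA_real_, nT, length(stages),
                  dimnames = list(NULL, stages))
    if (nT > 0L) {
        offset <- stats::rnorm(nT, 0, config@siteLevelSd)
        for (s in stages)
            lvl[, s] <- pmin(1, pmax(0, config@stageLevels[[s]] +
                                        offset))
        differential <- rep(FALSE, nT)
        diffStage <- rep(NA_character_, nT)
        if (config@nDiffSites > 0L) {
            dIdx <- sample.int(nT, min(config@nDiffSites, nT))
            differential[dIdx] <- TRUE
            diffStage[dIdx] <- sample(stages, length(dIdx), replace = TRUE)
            for (i in dIdx)
                lvl[i, diffStage[i]] <- min(1, lvl[i, diffStage[i]] +
                                            config@diffDelta)
        }
    } else {
        differential <- logical(); diffStage <- character()
    }
    sites <- GRanges(rep(SYN_CONTIG, nrow(truePick)),
                     IRanges(truePick$pos, width = 1L),
                     strand = truePick$strand,
                     gene_id = truePick$gene_id,
                     inRepeat = c(rep(TRUE, nrow(repPick)),
                                  rep(FALSE, nrow(nonPick))),
                     differential = differential, diffStage = diffStage)
    mcols(sites)$stageLevel <- lvl

    rest <- pool[!(pool$pos %in% used), ]
    seqCh <- strsplit(as.character(genomeSeq(ref)[[SYN_CONTIG]]), "")[[1]]

    # heterozygous genomic SNPs, ~50% alternative allele in RNA
    hetPick <- takeFrom(rest, config@nHetSnps, "het SNP")
    used <- c(used, hetPick$pos)
    hetAlt <- vapply(seqCh[hetPick$pos],
                     function(b) sample(setdiff(BASES, b), 1L), "")
    hetSnps <- GRanges(rep(SYN_CONTIG, nrow(hetPick)),
                       IRanges(hetPick$pos, width = 1L),
                       strand = hetPick$strand,
                       ref = seqCh[hetPick$pos], alt = unname(hetAlt),
                       inDbsnp = seq_len(max(0L, nrow(hetPick))) %%
                           2L == 1L)

    rest <- pool[!(pool$pos %in% used), ]
    koPick <- takeFrom(rest, config@nKnownOnlySnps, "catalogue-only SNP")
    used <- c(used, koPick$pos)
    koAlt <- vapply(seqCh[koPick$pos],
                    function(b) sample(setdiff(BASES, b), 1L), "")
    knownOnly <- GRanges(rep(SYN_CONTIG, nrow(koPick)),
                         IRanges(koPick$pos, width = 1L),
                         strand = koPick$strand,
                         ref = seqCh[koPick$pos], alt = unname(koAlt))

    # artifact classes: each violates exactly one filter
    rest <- pool[!(pool$pos %in% used), ]
    nArt <- config@nArtifactsPerClass
    rePick <- takeFrom(rest[!(rest$pos %in% used), ], nArt[["read_end"]],
                       "read-end artifact")
    used <- c(used, rePick$pos)

    homoPos <- list()
    for (i in seq_along(homos)) {
        s <- start(homos)[i]; e <- end(homos)[i]
        st <- as.character(strand(homos))[i]
        homoPos[[i]] <- data.frame(pos = s:e, strand = st,
                                   gene_id = NA_character_)
    }
    homoPos <- do.call(rbind, homoPos)
    gene <- genes[genes$type == "gene"]
    ov <- findOverlaps(GRanges(SYN_CONTIG, IRanges(homoPos$pos, width = 1L)),
                       gene, ignore.strand = TRUE)
    homoPos$gene_id[S4Vectors::queryHits(ov)] <-
        gene$gene_id[S4Vectors::subjectHits(ov)]
    homoPick <- takeFrom(homoPos, nArt[["homopolymer"]],
                         "homopolymer artifact")
    used <- c(used, homoPick$pos)

    dupS <- start(dup)[1]; dupE <- end(dup)[1]
    dupStrand <- as.character(strand(gene))[1]
    want <- if (dupStrand == "+") "A" else "T"
    runLen <- homopolymerRunLengths(paste(seqCh, collapse = ""))
    dupInner <- (dupS + PLACEMENT_DUP_MARGIN):(dupE - PLACEMENT_DUP_MARGIN)
    dupOk <- dupInner[seqCh[dupInner] == want &
                      runLen[dupInner] < HOMOPOL_FILTER_RUN]
    mmPick <- takeFrom(data.frame(pos = dupOk, strand = dupStrand,
                                  gene_id = gene$gene_id[1]),
                       nArt[["mismap"]], "mismap artifact")
    used <- c(used, mmPick$pos)

    withClass <- function(df, cls) {
        df$class <- rep(cls, nrow(df))
        df
    }
    artDf <- rbind(withClass(rePick, "read_end"),
                   withClass(homoPick, "homopolymer"),
                   withClass(mmPick, "mismap"))
    artifacts <- GRanges(rep(SYN_CONTIG, nrow(artDf)),
                         IRanges(artDf$pos, width = 1L),
                         strand = artDf$strand, class = artDf$class,
                         gene_id = artDf$gene_id)

    rest <- pool[!(pool$pos %in% used), ]
    bgPick <- takeFrom(rest, config@nBackgroundSites, "background")
    bg <- GRanges(rep(SYN_CONTIG, nrow(bgPick)),
                  IRanges(bgPick$pos, width = 1L),
                  strand = bgPick$strand, gene_id = bgPick$gene_id)
    truth <- new("SyntheticTruth", sites = sites, hetSnps = hetSnps,
                 knownOnlySnps = knownOnly, artifacts = artifacts,
                 duplication = dup, homopolymers = homos)
    metadata(truth@sites)$background <- bg
    truth
}

#' Simulate the WGS genotype call set
#'
#' Heterozygous records at the planted SNP positions; everywhere else the
#' genome is homozygous reference (no record).  True editing sites never
#' receive a record: editing is an RNA-only phenomenon.
#'
#' @param ref a \linkS4class{ReferenceBundle}.
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param config the \linkS4class{SimConfig}.
#' @return a \code{GRanges} with columns \code{ref}, \code{alt},
#'   \code{genotype}, \code{multiallelic}.
#' @export
simulateWgsGenotypes <- function(ref, truth, config) {
    het <- truth@hetSnps
    gr <- GRanges(seqnames(het), IRanges(start(het), width = 1L),
                  ref = het$ref, alt = het$alt,
                  genotype = rep("het", length(het)),
                  multiallelic = rep(FALSE, length(het)))
    sort(gr)
}

#' Known-SNP catalogue of the synthetic study
#'
#' Positions of catalogued SNPs: the planted heterozygous SNPs flagged as
#' catalogued plus the catalogue-only positions (which carry RNA variation
#' but no WGS genotype record, so only the catalogue filter can remove
#' them).
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @return a \code{GRanges} with columns \code{ref}, \code{alt}.
#' @export
knownSnpCatalog <- function(truth) {
    het <- truth@hetSnps[truth@hetSnps$inDbsnp]
    a <- GRanges(seqnames(het), IRanges(start(het), width = 1L),
                 ref = het$ref, alt = het$alt)
    ko <- truth@knownOnlySnps
    b <- GRanges(seqnames(ko), IRanges(start(ko), width = 1L),
                 ref = ko$ref, alt = ko$alt)
    sort(c(a, b))
}

#' Sample sheet of a simulated design
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a data.frame with \code{sample_id}, \code{stage},
#'   \code{replicate}, one row per sample, stages in configured order.
#' @export
studyDesign <- function(config) .sampleSheet(config)

.sampleSheet <- function(config) {
    stages <- names(config@stageLevels)
    data.frame(
        sample_id = as.vector(vapply(stages, function(s)
            paste0(s, "_r", seq_len(config@nReplicates)),
            character(config@nReplicates))),
        stage = rep(stages, each = config@nReplicates),
        replicate = rep(seq_len(config@nReplicates), length(stages)),
        stringsAsFactors = FALSE)
}

#' Simulate per-sample RNA-seq site evidence
#'
#' For each sample and each interesting position (true sites, SNPs,
#' artifacts and monomorphic background adenosines), draws a Poisson
#' coverage (floor 1) and a binomial count of alternative reads at the
#' position's per-sample true level (stage level plus replicate noise for
#' true sites; ~0.5 for heterozygous SNPs; a fixed fraction for artifacts).
#' Read-end artifacts carry all their alternative reads within
#' \code{artifactEndMargin} bp of a read end; all other reads place the
#' site uniformly along the read.  Base-call errors replace the observed
#' base with a random other base at \code{baseErrorRate}.  The library
#' strand of every read equals the transcribed strand (dUTP-style
#' strand-specific protocol).
#'
#' @param ref a \linkS4class{ReferenceBundle}.
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param config the \linkS4class{SimConfig}.
#' @return a \code{data.table} with columns \code{chrom}, \code{pos},
#'   \code{ref_base}, \code{sample_id}, \code{read_id}, \code{base},
#'   \code{base_qual}, \code{offset_from_5p}, \code{offset_from_3p},
#'   \code{library_strand}.
#' @export
simulateRnaEvidence <- function(ref, truth, config) {
    set.seed(subSeed(config@seed, 3L))
    seqCh <- strsplit(as.character(genomeSeq(ref)[[SYN_CONTIG]]), "")[[1]]
    sheet <- .sampleSheet(config)
    stages <- names(config@stageLevels)

    altFor <- function(strand) ifelse(strand == "+", "G", "C")
    sites <- truth@sites
    bg <- metadata(truth@sites)$background
    siteDf <- rbind(
        if (length(sites)) data.frame(
            pos = start(sites), strand = as.character(strand(sites)),
            alt = altFor(as.character(strand(sites))), kind = "true",
            idx = seq_along(sites)) else NULL,
        if (length(truth@hetSnps)) data.frame(
            pos = start(truth@hetSnps),
            strand = as.character(strand(truth@hetSnps)),
            alt = truth@hetSnps$alt, kind = "het",
            idx = seq_along(truth@hetSnps)) else NULL,
        if (length(truth@knownOnlySnps)) data.frame(
            pos = start(truth@knownOnlySnps),
            strand = as.character(strand(truth@knownOnlySnps)),
            alt = truth@knownOnlySnps$alt, kind = "known_only",
            idx = seq_along(truth@knownOnlySnps)) else NULL,
        if (length(truth@artifacts)) data.frame(
            pos = start(truth@artifacts),
            strand = as.character(strand(truth@artifacts)),
            alt = altFor(as.character(strand(truth@artifacts))),
            kind = paste0("artifact_", truth@artifacts$class),
            idx = seq_along(truth@artifacts)) else NULL,
        if (length(bg)) data.frame(
            pos = start(bg), strand = as.character(strand(bg)),
            alt = altFor(as.character(strand(bg))), kind = "background",
            idx = seq_along(bg)) else NULL)
    if (is.null(siteDf) || nrow(siteDf) == 0L)
        return(data.table(chrom = character(), pos = integer(),
                          ref_base = character(), sample_id = character(),
                          read_id = character(), base = character(),
                          base_qual = integer(), offset_from_5p = integer(),
                          offset_from_3p = integer(),
                          library_strand = character()))
    nS <- nrow(siteDf)
    rl <- config@readLength
    m <- config@artifactEndMargin
    stageLvl <- if (length(sites)) mcols(sites)$stageLevel else NULL

    out <- vector("list", nrow(sheet))
    for (k in seq_len(nrow(sheet))) {
        stage <- sheet$stage[k]
        lvl <- numeric(nS)
        isTrue <- siteDf$kind == "true"
        if (any(isTrue))
            lvl[isTrue] <- pmin(1, pmax(0,
                stageLvl[siteDf$idx[isTrue], stage] +
                stats::rnorm(sum(isTrue), 0, config@replicateSd)))
        lvl[siteDf$kind == "het"] <- 0.5
        lvl[grepl("^artifact_", siteDf$kind) |
            siteDf$kind == "known_only"] <- config@artifactLevel
        cov <- pmax(1L, stats::rpois(nS, config@coverageMean))
        nAlt <- stats::rbinom(nS, cov, lvl)

        sIdx <- rep.int(seq_len(nS), cov)
        isAlt <- sequence(cov) <= rep.int(nAlt, cov)
        n <- length(sIdx)
        base <- ifelse(isAlt, siteDf$alt[sIdx], seqCh[siteDf$pos[sIdx]])
        if (config@baseErrorRate > 0) {
            err <- which(stats::runif(n) < config@baseErrorRate)
            if (length(err)) {
                shift <- sample.int(3L, length(err), replace = TRUE)
                base[err] <- vapply(seq_along(err), function(j)
                    setdiff(BASES, base[err[j]])[shift[j]], "")
            }
        }
        qual <- as.integer(pmin(41, pmax(2, round(
            stats::rnorm(n, config@qualMean, config@qualSd)))))
        p5 <- sample.int(rl, n, replace = TRUE)
        endArt <- isAlt & siteDf$kind[sIdx] == "artifact_read_end"
        if (any(endArt)) {
            ne <- sum(endArt)
            off <- sample.int(m, ne, replace = TRUE)
            atFive <- stats::runif(ne) < 0.5
            p5[endArt] <- ifelse(atFive, off, rl + 1L - off)
        }
        p3 <- rl + 1L - p5
        out[[k]] <- data.table(
            chrom = SYN_CONTIG, pos = siteDf$pos[sIdx],
            ref_base = seqCh[siteDf$pos[sIdx]],
            sample_id = sheet$sample_id[k],
            read_id = paste0(sheet$sample_id[k], "_", seq_len(n)),
            base = base, base_qual = qual,
            offset_from_5p = p5, offset_from_3p = p3,
            library_strand = siteDf$strand[sIdx])
    }
    ev <- rbindlist(out)
    setorder(ev, chrom, pos, sample_id)
    ev[]
}

#' Simulate mature miRNA sequences targeting 3'-UTR editing flanks
#'
#' Roughly a third of the miRNAs are perfect reverse complements of an
#' edited 3'-UTR flank (so editing creates their site), a third match the
#' unedited flank (so editing destroys their site) and the remainder are
#' random 22-mers.  The edited position always falls inside the seed
#' (position 4 from the miRNA 5' end), making the single A/G difference
#' decisive for target calls.
#'
#' @param ref a \linkS4class{ReferenceBundle}.
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param config the \linkS4class{SimConfig}; \code{nMirnas} controls the
#'   count via \code{floor(n/3)} gain-directed and loss-directed designs.
#' @param n number of miRNAs to generate.
#' @return a named \link[Biostrings]{RNAStringSet}.
#' @export
simulateMirnas <- function(ref, truth, config, n = 9L) {
    set.seed(subSeed(config@seed, 4L))
    genes <- geneModels(ref)
    utr3 <- genes[genes$type == "three_prime_utr"]
    sites <- truth@sites
    inU3 <- countOverlaps(sites, utr3, ignore.strand = TRUE) > 0L
    u3sites <- sites[inU3]
    nGain <- min(floor(n / 3), length(u3sites))
    nLoss <- min(floor(n / 3), max(0L, length(u3sites) - nGain))
    seqCh <- strsplit(as.character(genomeSeq(ref)[[SYN_CONTIG]]), "")[[1]]
    mirLen <- 22L; seedPos <- 4L

    mkTarget <- function(site, edited) {
        pos <- start(site); st <- as.character(strand(site))
        if (st == "+") {
            win <- seqCh[(pos - (mirLen - seedPos)):(pos + seedPos - 1L)]
            if (edited) win[mirLen - seedPos + 1L] <- "G"
        } else {
            gwin <- seqCh[(pos - seedPos + 1L):(pos + (mirLen - seedPos))]
            win <- revcompChars(gwin)
            if (edited) win[mirLen - seedPos + 1L] <- "G"
        }
        win
    }
    toMirna <- function(targetWin) {
        ch <- revcompChars(targetWin)
        paste(gsub("T", "U", ch), collapse = "")
    }
    seqs <- character(); nms <- character()
    if (nGain > 0L) {
        pick <- u3sites[sample.int(length(u3sites), nGain)]
        for (i in seq_len(nGain)) {
            seqs <- c(seqs, toMirna(mkTarget(pick[i], edited = TRUE)))
            nms <- c(nms, sprintf("syn-miR-gain-%d", i))
        }
        remaining <- u3sites[!(start(u3sites) %in% start(pick))]
    } else remaining <- u3sites
    if (nLoss > 0L && length(remaining) >= nLoss) {
        pick <- remaining[sample.int(length(remaining), nLoss)]
        for (i in seq_len(nLoss)) {
            seqs <- c(seqs, toMirna(mkTarget(pick[i], edited = FALSE)))
            nms <- c(nms, sprintf("syn-miR-loss-%d", i))
        }
    }
    nRand <- n - length(seqs)
    for (i in seq_len(nRand)) {
        seqs <- c(seqs, paste(sample(c("A", "C", "G", "U"), mirLen,
                                     replace = TRUE), collapse = ""))
        nms <- c(nms, sprintf("syn-miR-rand-%d", i))
    }
    RNAStringSet(setNames(seqs, nms))
}

#' Simulate the complete synthetic study
#'
#' Convenience wrapper: reference, truth, WGS genotypes, known-SNP
#' catalogue, RNA evidence and miRNAs, plus the sample sheet.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a list with elements \code{bundle} (reference with genotypes and
#'   catalogue attached), \code{truth}, \code{evidence}, \code{mirnas},
#'   \code{design}, \code{config}.
#' @examples
#' study <- simulateStudy(simConfig(nTrueSites = 20L, nHetSnps = 5L,
#'     nKnownOnlySnps = 2L, nArtifactsPerClass = c(read_end = 2L,
#'     homopolymer = 2L, mismap = 2L), nBackgroundSites = 10L))
#' @export
simulateStudy <- function(config = simConfig()) {
    ref <- generateReference(config)
    truth <- plantTruth(ref, config)
    wgs <- simulateWgsGenotypes(ref, truth, config)
    dbsnp <- knownSnpCatalog(truth)
    bundle <- referenceBundle(genomeSeq(ref), geneModels(ref),
                              repeatRanges(ref), dbsnp, wgs)
    evidence <- simulateRnaEvidence(ref, truth, config)
    mirnas <- simulateMirnas(ref, truth, config)
    list(bundle = bundle, truth = truth, evidence = evidence,
         mirnas = mirnas, design = .sampleSheet(config), config = config)
}

.mapPos <- function(pos, L) L - pos + 1L

.revRanges <- function(gr, L) {
    if (length(gr) == 0L) return(gr)
    newStart <- .mapPos(end(gr), L)
    newEnd <- .mapPos(start(gr), L)
    out <- GRanges(seqnames(gr), IRanges(newStart, newEnd),
                   strand = chartr("+-", "-+", as.character(strand(gr))))
    mcols(out) <- mcols(gr)
    md <- metadata(gr)
    metadata(out) <- md
    out
}

#' Reverse-complement an entire synthetic study
#'
#' Maps the genome, every annotation track and the read evidence onto the
#' reverse-complement coordinate system (position p becomes L - p + 1,
#' strands flip, observed bases complement; read-end offsets are properties
#' of the reads and stay put).  Editing detection is strand-symmetric, so
#' the A-to-I site set of the transformed study maps exactly onto the
#' original one.
#'
#' @param study a list as returned by \code{\link{simulateStudy}}.
#' @return a study list in the mirrored coordinate system.
#' @export
reverseComplementStudy <- function(study) {
    bundle <- study$bundle
    L <- width(genomeSeq(bundle))[[1]]
    genome <- DNAStringSet(setNames(
        as.character(reverseComplement(genomeSeq(bundle)[[1]])), SYN_CONTIG))
    genes <- .revRanges(geneModels(bundle), L)
    md <- metadata(geneModels(bundle))
    metadata(genes)$homopolymers <- .revRanges(md$homopolymers, L)
    metadata(genes)$duplication <- .revRanges(md$duplication, L)
    GenomeInfoDb::seqlengths(genes) <- setNames(L, SYN_CONTIG)
    repeats <- .revRanges(repeatRanges(bundle), L)
    comp <- function(b) unname(COMPLEMENT[b])
    ks <- .revRanges(knownSnpRanges(bundle), L)
    if (length(ks)) { ks$ref <- comp(ks$ref); ks$alt <- comp(ks$alt) }
    wgs <- .revRanges(wgsGenotypeRanges(bundle), L)
    if (length(wgs)) { wgs$ref <- comp(wgs$ref); wgs$alt <- comp(wgs$alt) }
    newBundle <- referenceBundle(genome, genes, repeats, ks, wgs)

    ev <- data.table::copy(study$evidence)
    ev[, `:=`(pos = .mapPos(pos, L), ref_base = comp(ref_base),
              base = comp(base),
              library_strand = chartr("+-", "-+", library_strand))]
    setorder(ev, chrom, pos, sample_id)

    truth <- study$truth
    newTruth <- new("SyntheticTruth",
                    sites = .revRanges(truth@sites, L),
                    hetSnps = .revRanges(truth@hetSnps, L),
                    knownOnlySnps = .revRanges(truth@knownOnlySnps, L),
                    artifacts = .revRanges(truth@artifacts, L),
                    duplication = .revRanges(truth@duplication, L),
                    homopolymers = .revRanges(truth@homopolymers, L))
    list(bundle = newBundle, truth = newTruth, evidence = ev,
         mirnas = study$mirnas, design = study$design,
         config = study$config)
}
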