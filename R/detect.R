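#' @importFrom Biostrings matchPattern pairwiseAlignment score
#'   nucleotideSubstitutionMatrix
NULL

FILTER_NAMES <- c("wgs_snp", "known_snp", "splice_proximal", "homopolymer",
                  "read_end", "multimap")

.flagCols <- paste0("flag_", FILTER_NAMES)

#' Call candidate RNA-DNA differences from site evidence
#'
#' Pools quality-passing reads (phred >= \code{minBaseQual}, base not N)
#' across samples at every covered position.  Allele types are bases
#' supported by at least \code{minAltReads} reads plus the reference base;
#' a candidate is emitted when there is exactly one non-reference allele
#' type and no more than \code{maxAlleleTypes} allele types in total.  The
#' reference base of the evidence must match the genome.
#'
#' @param evidence a site-evidence \code{data.table}.
#' @param ref a \linkS4class{ReferenceBundle}.
#' @param cfg a \linkS4class{DetectionConfig}.
#' @return a \code{GRanges} of candidate calls with \code{ref}, \code{alt},
#'   pooled \code{refCount}/\code{altCount}, per-sample count matrices
#'   \code{refMat}/\code{altMat} and all filter flags initialised to
#'   \code{FALSE}.
#' @export
callCandidates <- function(evidence, ref, cfg = detectionConfig()) {
    base_qual <- base <- NULL  # data.table NSE
    ev <- evidence[base_qual >= cfg@minBaseQual & base != "N"]
    if (nrow(ev) == 0L) return(.emptyCalls())
    genome <- genomeSeq(ref)
    refCheck <- unique(ev[, c("chrom", "pos", "ref_base")])
    for (ct in unique(refCheck$chrom)) {
        sel <- refCheck[refCheck$chrom == ct, ]
        gbase <- as.character(Biostrings::extractAt(
            genome[[ct]], IRanges(sel$pos, width = 1L)))
        bad <- gbase != sel$ref_base
        if (any(bad))
            stop(sprintf(paste0("evidence reference base disagrees with ",
                                "genome at %s:%d (evidence %s, genome %s)"),
                         ct, sel$pos[which(bad)[1]],
                         sel$ref_base[which(bad)[1]],
                         gbase[which(bad)[1]]))
    }
    counts <- ev[, .N, by = c("chrom", "pos", "ref_base", "base")]
    wide <- data.table::dcast(counts, chrom + pos + ref_base ~ base,
                              value.var = "N", fill = 0L)
    for (b in BASES) if (!b %in% names(wide)) wide[[b] ] <- 0L
    cmat <- as.matrix(wide[, BASES, with = FALSE])
    refIdx <- match(wide$ref_base, BASES)
    refCount <- cmat[cbind(seq_len(nrow(cmat)), refIdx)]
    altOk <- cmat >= cfg@minAltReads
    altOk[cbind(seq_len(nrow(cmat)), refIdx)] <- FALSE
    nAlleles <- rowSums(altOk) + 1L  # reference is always an allele type
    oneAlt <- rowSums(altOk) == 1L & nAlleles <= cfg@maxAlleleTypes
    if (!any(oneAlt)) return(.emptyCalls())
    sel <- which(oneAlt)
    altIdx <- apply(altOk[sel, , drop = FALSE], 1L, which)
    altBase <- BASES[altIdx]
    altCount <- cmat[cbind(sel, altIdx)]

    keyAll <- posKey(wide$chrom[sel], wide$pos[sel])
    samples <- sort(unique(evidence$sample_id))
    perS <- ev[, .N, by = c("chrom", "pos", "sample_id", "base")]
    perS$key <- posKey(perS$chrom, perS$pos)
    perS <- perS[perS$key %in% keyAll]
    mkMat <- function(bases) {
        m <- matrix(0L, length(sel), length(samples),
                    dimnames = list(NULL, samples))
        hit <- perS[perS$base == bases[match(perS$key, keyAll)]]
        if (nrow(hit)) {
            i <- match(hit$key, keyAll)
            j <- match(hit$sample_id, samples)
            m[cbind(i, j)] <- hit$N
        }
        m
    }
    refMat <- mkMat(setNames(wide$ref_base[sel], keyAll))
    altMat <- mkMat(setNames(altBase, keyAll))

    calls <- GRanges(wide$chrom[sel], IRanges(wide$pos[sel], width = 1L),
                     ref = wide$ref_base[sel], alt = altBase,
                     refCount = unname(refCount[sel]),
                     altCount = unname(altCount))
    mcols(calls)$refMat <- refMat
    mcols(calls)$altMat <- altMat
    for (fc in .flagCols) mcols(calls)[[fc]] <- rep(FALSE, length(calls))
    mcols(calls)$altCountEndFiltered <- mcols(calls)$altCount
    mcols(calls)$mismatchType <- rep(NA_character_, length(calls))
    sort(calls, ignore.strand = TRUE)
}

.emptyCalls <- function() {
    g <- GRanges()
    mcols(g) <- DataFrame(ref = character(), alt = character(),
                          refCount = integer(), altCount = integer())
    for (fc in .flagCols) mcols(g)[[fc]] <- logical()
    mcols(g)$altCountEndFiltered <- integer()
    mcols(g)$mismatchType <- character()
    g
}

#' Filter 1: genomic SNP exclusion
#'
#' Flags calls whose position is genotyped heterozygous (or homozygous
#' alternative, a reference error masquerading as full editing) in the WGS
#' call set, and calls at positions present in the known-SNP catalogue.
#'
#' @param calls candidate calls from \code{\link{callCandidates}}.
#' @param ref a \linkS4class{ReferenceBundle} carrying \code{wgsGenotypes}
#'   and \code{knownSnps}.
#' @return calls with \code{flag_wgs_snp} / \code{flag_known_snp} updated.
#' @export
filterGenomicSnps <- function(calls, ref) {
    wgs <- wgsGenotypeRanges(ref)
    if (length(wgs)) {
        bad <- wgs[wgs$genotype %in% c("het", "hom_alt")]
        calls$flag_wgs_snp <- calls$flag_wgs_snp |
            countOverlaps(calls, bad, ignore.strand = TRUE) > 0L
    }
    ks <- knownSnpRanges(ref)
    if (length(ks))
        calls$flag_known_snp <- calls$flag_known_snp |
            countOverlaps(calls, ks, ignore.strand = TRUE) > 0L
    calls
}

#' Filter 2: splice-junction proximity
#'
#' Flags intronic calls within \code{spliceWindow} bp of an exon-intron
#' boundary (the first intronic base counts as distance 1).  Calls falling
#' in any exon are never flagged by this filter.
#'
#' @param calls candidate calls.
#' @param genes gene-model \code{GRanges}.
#' @param cfg a \linkS4class{DetectionConfig}.
#' @return calls with \code{flag_splice_proximal} updated.
#' @export
filterSpliceProximal <- function(calls, genes, cfg = detectionConfig()) {
    if (length(calls) == 0L) return(calls)
    exons <- genes[genes$type %in% c("exon", "five_prime_utr",
                                     "three_prime_utr", "CDS")]
    introns <- genes[genes$type == "intron"]
    inExon <- countOverlaps(calls, exons, ignore.strand = TRUE) > 0L
    ov <- findOverlaps(calls, introns, ignore.strand = TRUE)
    near <- rep(FALSE, length(calls))
    if (length(ov)) {
        pos <- start(calls)[S4Vectors::queryHits(ov)]
        iS <- start(introns)[S4Vectors::subjectHits(ov)]
        iE <- end(introns)[S4Vectors::subjectHits(ov)]
        d <- pmin(pos - iS + 1L, iE - pos + 1L)
        hit <- tapply(d, S4Vectors::queryHits(ov), min) <= cfg@spliceWindow
        near[as.integer(names(hit))] <- unname(hit)
    }
    calls$flag_splice_proximal <- calls$flag_splice_proximal |
        (near & !inExon)
    calls
}

#' Filter 3: homopolymer runs
#'
#' Flags calls lying within a maximal run of \code{homopolymerMinRun} or
#' more identical reference bases.
#'
#' @param calls candidate calls.
#' @param genome a \code{DNAStringSet}.
#' @param cfg a \linkS4class{DetectionConfig}.
#' @return calls with \code{flag_homopolymer} updated.
#' @export
filterHomopolymer <- function(calls, genome, cfg = detectionConfig()) {
    if (length(calls) == 0L) return(calls)
    flag <- rep(FALSE, length(calls))
    for (ct in unique(as.character(seqnames(calls)))) {
        runLen <- homopolymerRunLengths(as.character(genome[[ct]]))
        sel <- as.character(seqnames(calls)) == ct
        flag[sel] <- runLen[start(calls)[sel]] >= cfg@homopolymerMinRun
    }
    calls$flag_homopolymer <- calls$flag_homopolymer | flag
    calls
}

#' Filter 4: read-end position
#'
#' Discards alternative-supporting reads whose edited base lies within
#' \code{readEndMargin} bp of either read end (where sequencing errors
#' concentrate), recomputes the alternative read count, and flags calls
#' whose surviving support drops below \code{minAltReads}.
#'
#' @param calls candidate calls.
#' @param evidence the site-evidence \code{data.table}.
#' @param cfg a \linkS4class{DetectionConfig}.
#' @return calls with \code{altCountEndFiltered} and \code{flag_read_end}
#'   updated.
#' @export
filterReadEnd <- function(calls, evidence, cfg = detectionConfig()) {
    if (length(calls) == 0L) return(calls)
    base_qual <- NULL
    ev <- evidence[base_qual >= cfg@minBaseQual]
    ev <- ev[posKey(ev$chrom, ev$pos) %in% grKey(calls)]
    key <- grKey(calls)
    idx <- match(posKey(ev$chrom, ev$pos), key)
    isAlt <- ev$base == calls$alt[idx]
    internal <- pmin(ev$offset_from_5p, ev$offset_from_3p) >
        cfg@readEndMargin
    surv <- tapply(isAlt & internal, idx, sum)
    counts <- integer(length(calls))
    counts[as.integer(names(surv))] <- as.integer(surv)
    calls$altCountEndFiltered <- counts
    calls$flag_read_end <- calls$flag_read_end |
        counts < cfg@minAltReads
    calls
}

#' Filter 5: multi-mapping regions
#'
#' Extracts the window of \code{multimapFlank} bp around each call and
#' asks whether any other genomic locus (either strand) aligns it with at
#' least \code{multimapScoreRatio} of the perfect score.  The default
#' \code{"mismatch"} method searches for near-exact occurrences with at
#' most \code{floor(width * (1 - ratio) / 2)} mismatches, which is
#' equivalent to the score-ratio rule under unit match/mismatch scores
#' with gap penalties that make gapped alignments unprofitable; the
#' \code{"alignment"} method runs explicit local alignments against the
#' self-masked genome and its reverse complement.
#'
#' @param calls candidate calls.
#' @param genome a \code{DNAStringSet}.
#' @param cfg a \linkS4class{DetectionConfig}.
#' @param method \code{"mismatch"} (fast) or \code{"alignment"}.
#' @return calls with \code{flag_multimap} updated.
#' @export
filterMultimap <- function(calls, genome, cfg = detectionConfig(),
                           method = c("mismatch", "alignment")) {
    method <- match.arg(method)
    if (length(calls) == 0L) return(calls)
    flag <- rep(FALSE, length(calls))
    for (ct in unique(as.character(seqnames(calls)))) {
        subject <- genome[[ct]]
        L <- length(subject)
        sel <- which(as.character(seqnames(calls)) == ct)
        # k-mers that recur on the forward strand or occur on the
        # reverse strand; chunks outside this set cannot be part of a
        # near-exact duplicate
        kmerScreen <- local({
            cache <- list()
            s <- as.character(subject)
            sRev <- as.character(reverseComplement(subject))
            function(len) {
                key <- as.character(len)
                if (is.null(cache[[key]])) {
                    st <- seq_len(L - len + 1L)
                    fwd <- substring(s, st, st + len - 1L)
                    rev <- substring(sRev, st, st + len - 1L)
                    cache[[key]] <<- union(fwd[duplicated(fwd)],
                                           intersect(fwd, rev))
                }
                cache[[key]]
            }
        })
        subjChar <- as.character(subject)
        for (i in sel) {
            pos <- start(calls)[i]
            wS <- max(1L, pos - cfg@multimapFlank)
            wE <- min(L, pos + cfg@multimapFlank)
            w <- wE - wS + 1L
            if (method == "mismatch") {
                maxMM <- floor(w * (1 - cfg@multimapScoreRatio) / 2)
                # pigeonhole prescreen: a <= maxMM-mismatch copy of the
                # window must contain one of maxMM+1 disjoint chunks
                # exactly; only windows passing the prescreen are aligned
                cl <- w %/% (maxMM + 1L)
                screen <- kmerScreen(cl)
                chunkStarts <- wS + (seq_len(maxMM + 1L) - 1L) * cl
                chunks <- substring(subjChar, chunkStarts,
                                    chunkStarts + cl - 1L)
                if (!any(chunks %in% screen)) { flag[i] <- FALSE; next }
                window <- subseq(subject, wS, wE)
                fwd <- matchPattern(window, subject, max.mismatch = maxMM)
                other <- sum(start(fwd) != wS)
                if (other == 0L) {
                    rev <- matchPattern(reverseComplement(window), subject,
                                        max.mismatch = maxMM)
                    other <- length(rev)
                }
                flag[i] <- other > 0L
            } else {
                window <- subseq(subject, wS, wE)
                masked <- Biostrings::replaceAt(
                    subject, IRanges(wS, wE),
                    paste(rep("N", w), collapse = ""))
                mat <- nucleotideSubstitutionMatrix(match = 1,
                                                    mismatch = -1)
                mat["N", ] <- -10; mat[, "N"] <- -10
                sc1 <- score(pairwiseAlignment(window, masked,
                    type = "local", substitutionMatrix = mat,
                    gapOpening = 5, gapExtension = 2))
                sc2 <- score(pairwiseAlignment(window,
                    reverseComplement(masked),
                    type = "local", substitutionMatrix = mat,
                    gapOpening = 5, gapExtension = 2))
                flag[i] <- max(sc1, sc2) >= cfg@multimapScoreRatio * w
            }
        }
    }
    calls$flag_multimap <- calls$flag_multimap | flag
    calls
}

#' Resolve the transcribed strand and mismatch type
#'
#' The transcribed strand is the gene strand when the call lies within
#' genes of a single strand; outside genes it is the majority library
#' strand of the covering reads (strand-specific protocol), with ties and
#' opposite-strand gene overlaps left unresolved.  The mismatch type is
#' reported on the transcribed strand, so a genomic T-to-C change inside a
#' minus-strand gene is an A-to-G event.
#'
#' @param calls candidate calls.
#' @param genes gene-model \code{GRanges}.
#' @param evidence the site-evidence \code{data.table}.
#' @return calls with \code{strand} set (\code{*} when unresolved) and
#'   \code{mismatchType} filled.
#' @export
resolveStrandType <- function(calls, genes, evidence) {
    if (length(calls) == 0L) return(calls)
    geneSpans <- genes[genes$type == "gene"]
    ov <- findOverlaps(calls, geneSpans, ignore.strand = TRUE)
    res <- rep("*", length(calls))
    if (length(ov)) {
        st <- as.character(strand(geneSpans))[S4Vectors::subjectHits(ov)]
        byCall <- split(st, S4Vectors::queryHits(ov))
        uni <- vapply(byCall, function(s) {
            u <- unique(s)
            if (length(u) == 1L) u else "*"
        }, "")
        res[as.integer(names(uni))] <- uni
    }
    need <- which(res == "*" &
                  countOverlaps(calls, geneSpans, ignore.strand = TRUE) ==
                  0L)
    if (length(need)) {
        key <- grKey(calls)[need]
        evKey <- posKey(evidence$chrom, evidence$pos)
        for (j in seq_along(need)) {
            ls <- evidence$library_strand[evKey == key[j]]
            nPlus <- sum(ls == "+"); nMinus <- sum(ls == "-")
            if (nPlus > nMinus) res[need[j]] <- "+"
            else if (nMinus > nPlus) res[need[j]] <- "-"
        }
    }
    strand(calls) <- res
    typed <- res != "*"
    refT <- ifelse(res == "-", unname(COMPLEMENT[calls$ref]), calls$ref)
    altT <- ifelse(res == "-", unname(COMPLEMENT[calls$alt]), calls$alt)
    calls$mismatchType <- ifelse(typed, paste0(refT, "-to-", altT),
                                 NA_character_)
    calls
}

#' Select surviving editing sites and tally mismatch types
#'
#' Retains calls with no filter flag, tallies the twelve strand-resolved
#' mismatch types over the strand-resolved survivors, and returns the
#' A-to-G (A-to-I) subset as the editing-site set.
#'
#' @param calls fully filtered, strand-resolved calls.
#' @return a list with \code{sites} (A-to-I \code{GRanges}),
#'   \code{typeCounts} and \code{typePercent}.
#' @export
selectEditingSites <- function(calls) {
    flagMat <- as.matrix(as.data.frame(mcols(calls)[, .flagCols]))
    flagged <- if (length(calls)) rowSums(flagMat) > 0L else logical()
    surv <- calls[!flagged]
    typed <- surv[!is.na(surv$mismatchType)]
    typeCounts <- setNames(integer(12L), mismatchTypes())
    tab <- table(typed$mismatchType)
    typeCounts[names(tab)] <- as.integer(tab)
    if (length(typed) == 0L) {
        warning("no surviving strand-resolved calls")
        typePercent <- setNames(rep(NA_real_, 12L), mismatchTypes())
    } else typePercent <- countPercentages(typeCounts)
    sites <- typed[typed$mismatchType == "A-to-G"]
    list(sites = sites, typeCounts = typeCounts,
         typePercent = typePercent)
}

#' Run the full editing-site detection cascade
#'
#' Candidate calling followed by the five filters (genomic SNPs,
#' splice-junction proximity, homopolymers, read-end position,
#' multi-mapping), strand/type resolution and A-to-I selection.  The
#' filters are pure predicates on the candidate set, so their order does
#' not change the surviving sites.
#'
#' @param evidence a site-evidence \code{data.table}.
#' @param bundle a \linkS4class{ReferenceBundle} with WGS genotypes and
#'   known SNPs attached.
#' @param cfg a \linkS4class{DetectionConfig}.
#' @param multimapMethod passed to \code{\link{filterMultimap}}.
#' @return an \linkS4class{EditingCallSet}.
#' @examples
#' study <- simulateStudy(simConfig(nTrueSites = 20L, nHetSnps = 4L,
#'     nKnownOnlySnps = 2L, nArtifactsPerClass = c(read_end = 2L,
#'     homopolymer = 2L, mismap = 2L), nBackgroundSites = 5L,
#'     baseErrorRate = 0))
#' res <- detectEditingSites(study$evidence, study$bundle)
#' @export
detectEditingSites <- function(evidence, bundle, cfg = detectionConfig(),
                               multimapMethod = "mismatch") {
    calls <- callCandidates(evidence, bundle, cfg)
    calls <- filterGenomicSnps(calls, bundle)
    calls <- filterSpliceProximal(calls, geneModels(bundle), cfg)
    calls <- filterHomopolymer(calls, genomeSeq(bundle), cfg)
    calls <- filterReadEnd(calls, evidence, cfg)
    calls <- filterMultimap(calls, genomeSeq(bundle), cfg,
                            method = multimapMethod)
    calls <- resolveStrandType(calls, geneModels(bundle), evidence)
    selection <- selectEditingSites(calls)
    attrition <- vapply(.flagCols, function(fc) sum(mcols(calls)[[fc]]),
                        integer(1))
    names(attrition) <- FILTER_NAMES
    new("EditingCallSet", calls = calls,
        typeCounts = selection$typeCounts,
        typePercent = selection$typePercent,
        sites = selection$sites, attrition = attrition, config = cfg)
}

#' Failed-filter labels per call
#'
#' @param calls a call \code{GRanges} with flag columns.
#' @return a \code{CharacterList}, one element of failed-filter names per
#'   call.
#' @export
callFilterFlags <- function(calls) {
    flagMat <- as.matrix(as.data.frame(mcols(calls)[, .flagCols]))
    colnames(flagMat) <- FILTER_NAMES
    IRanges::CharacterList(apply(flagMat, 1L, function(r)
        names(r)[r], simplify = FALSE))
}
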