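#' Parameters for the miRNA target scanner
#'
#' Complementarity scoring in the style of classic miRNA target finders:
#' Watson-Crick match +5, G:U wobble +1, mismatch -3, gap open -9, gap
#' extend -4, with pair scores at miRNA positions 2-8 from the 5' end (the
#' seed) doubled.  A hit is reported when the alignment score reaches
#' \code{scoreThreshold} and the duplex energy is at most
#' \code{energyThreshold} kcal/mol.
#'
#' @param match,wobble,mismatch,gapOpen,gapExtend alignment scores.
#' @param seedStart,seedEnd seed positions from the miRNA 5' end.
#' @param seedScale pair-score multiplier within the seed.
#' @param scoreThreshold minimum alignment score of a reported hit.
#' @param energyThreshold maximum duplex energy (kcal/mol) of a hit.
#' @param maxHitsPerMirna maximum non-overlapping hits per miRNA and
#'   sequence.
#' @return a parameter list.
#' @export
mirandaParams <- function(match = 5, wobble = 1, mismatch = -3,
                          gapOpen = -9, gapExtend = -4,
                          seedStart = 2L, seedEnd = 8L, seedScale = 2,
                          scoreThreshold = 140, energyThreshold = -7,
                          maxHitsPerMirna = 4L) {
    list(match = match, wobble = wobble, mismatch = mismatch,
         gapOpen = gapOpen, gapExtend = gapExtend,
         seedStart = as.integer(seedStart), seedEnd = as.integer(seedEnd),
         seedScale = seedScale, scoreThreshold = scoreThreshold,
         energyThreshold = energyThreshold,
         maxHitsPerMirna = as.integer(maxHitsPerMirna))
}

# pair class of target (DNA) vs miRNA (RNA) base: 2 = Watson-Crick,
# 1 = G:U wobble, 0 = mismatch
.pairClass <- function(tBase, mBase) {
    wc <- (tBase == "A" & mBase == "U") | (tBase == "C" & mBase == "G") |
          (tBase == "G" & mBase == "C") | (tBase == "T" & mBase == "A")
    gu <- (tBase == "G" & mBase == "U") | (tBase == "T" & mBase == "G")
    ifelse(wc, 2L, ifelse(gu, 1L, 0L))
}

# Smith-Waterman of the reversed miRNA against the target with affine
# gaps and seed weighting; returns the single best local alignment
.swDuplex <- function(tChars, mChars, params) {
    n <- length(tChars); q <- length(mChars)
    rm <- rev(mChars)                       # rm[i] is miRNA position q-i+1
    mirPos <- q - seq_len(q) + 1L
    weight <- ifelse(mirPos >= params$seedStart &
                     mirPos <= params$seedEnd, params$seedScale, 1)
    H <- matrix(0, q + 1L, n + 1L)
    E <- matrix(-Inf, q + 1L, n + 1L)
    F <- matrix(-Inf, q + 1L, n + 1L)
    ptr <- matrix(0L, q + 1L, n + 1L)       # 1 diag, 2 left(E), 3 up(F)
    best <- 0; bi <- 0L; bj <- 0L
    for (i in seq_len(q)) {
        cls <- .pairClass(tChars, rep(rm[i], n))
        sc <- ifelse(cls == 2L, params$match,
                     ifelse(cls == 1L, params$wobble, params$mismatch))
        sc <- ifelse(tChars == "#", -1e6, sc)   # masked positions
        sc <- sc * weight[i]
        for (j in seq_len(n)) {
            E[i + 1L, j + 1L] <- max(H[i + 1L, j] + params$gapOpen,
                                     E[i + 1L, j] + params$gapExtend)
            F[i + 1L, j + 1L] <- max(H[i, j + 1L] + params$gapOpen,
                                     F[i, j + 1L] + params$gapExtend)
            diag <- H[i, j] + sc[j]
            h <- max(0, diag, E[i + 1L, j + 1L], F[i + 1L, j + 1L])
            H[i + 1L, j + 1L] <- h
            ptr[i + 1L, j + 1L] <-
                if (h == 0) 0L
                else if (h == diag) 1L
                else if (h == E[i + 1L, j + 1L]) 2L else 3L
            if (h > best) { best <- h; bi <- i; bj <- j }
        }
    }
    if (best <= 0) return(NULL)
    # traceback with an explicit H/E/F state machine
    i <- bi; j <- bj; state <- "H"
    tPos <- integer(); mPos <- integer(); cls <- integer()
    while (i > 0L && j > 0L) {
        if (state == "H") {
            mv <- ptr[i + 1L, j + 1L]
            if (mv == 0L) break
            if (mv == 1L) {
                tPos <- c(j, tPos); mPos <- c(mirPos[i], mPos)
                cls <- c(.pairClass(tChars[j], rm[i]), cls)
                i <- i - 1L; j <- j - 1L
            } else if (mv == 2L) state <- "E" else state <- "F"
        } else if (state == "E") {
            fromH <- H[i + 1L, j] + params$gapOpen
            if (E[i + 1L, j + 1L] == fromH) state <- "H"
            j <- j - 1L   # target base j unpaired (gap in miRNA)
        } else {
            fromH <- H[i, j + 1L] + params$gapOpen
            if (F[i + 1L, j + 1L] == fromH) state <- "H"
            i <- i - 1L   # miRNA base unpaired (gap in target)
        }
    }
    if (length(tPos) == 0L) return(NULL)
    list(score = best, tStart = min(tPos), tEnd = max(tPos),
         pairs = data.frame(targetPos = tPos, mirnaPos = mPos,
                            class = cls))
}

#' Nearest-neighbor duplex energy of an alignment
#'
#' Sums constant stack terms over consecutive paired positions: G:C on
#' G:C stacks -3.3, A:U on A:U -1.1, mixed Watson-Crick -2.1, any stack
#' containing a G:U wobble -0.5 kcal/mol; every interior unpaired stretch
#' (mismatch or gap) costs +4.1.  A single base pair has no stack and
#' energy 0.
#'
#' @param pairs a data.frame with \code{targetPos}, \code{mirnaPos},
#'   \code{class} (2 Watson-Crick, 1 wobble, 0 mismatch) as produced by
#'   the scanner, and the aligned sequences' bases via \code{tBase}.
#' @param tChars,mChars character vectors of target (DNA) and miRNA (RNA)
#'   sequences the positions index into.
#' @return energy in kcal/mol (0 when fewer than two paired positions).
#' @export
duplexEnergy <- function(pairs, tChars, mChars) {
    paired <- pairs[pairs$class > 0L, , drop = FALSE]
    if (nrow(paired) < 1L) return(NA_real_)
    if (nrow(paired) == 1L) return(0)
    kind <- function(k) {
        t <- tChars[paired$targetPos[k]]
        if (paired$class[k] == 1L) return("GU")
        if (t %in% c("C", "G")) "GC" else "AU"
    }
    kinds <- vapply(seq_len(nrow(paired)), kind, "")
    e <- 0
    nStretch <- 0L
    for (k in 2L:nrow(paired)) {
        dT <- paired$targetPos[k] - paired$targetPos[k - 1L]
        dM <- paired$mirnaPos[k - 1L] - paired$mirnaPos[k]
        if (dT == 1L && dM == 1L) {
            a <- kinds[k - 1L]; b <- kinds[k]
            e <- e + if (a == "GU" || b == "GU") -0.5
                     else if (a == "GC" && b == "GC") -3.3
                     else if (a == "AU" && b == "AU") -1.1
                     else -2.1
        } else {
            nStretch <- nStretch + 1L
        }
    }
    e + 4.1 * nStretch
}

#' Scan a sequence for miRNA target sites
#'
#' Aligns each miRNA (3' to 5') against the target with the seed-weighted
#' complementarity scoring of \code{\link{mirandaParams}}.  Up to
#' \code{maxHitsPerMirna} non-overlapping hits per miRNA are recovered by
#' masking each accepted hit and rescanning; overlapping candidate hits
#' therefore resolve to the best-scoring one (leftmost on ties, by the
#' deterministic traceback).
#'
#' @param seq target sequence (character or \code{DNAString}), 5' to 3'.
#' @param mirnas named \code{RNAStringSet} (or named character) of mature
#'   miRNAs, 18-25 nt.
#' @param params from \code{\link{mirandaParams}}.
#' @return a data.frame of hits: \code{mirna}, \code{tStart}, \code{tEnd},
#'   \code{score}, \code{energy}, \code{nPairs}; the paired positions are
#'   attached as a list column \code{pairs}.
#' @export
scanTargets <- function(seq, mirnas, params = mirandaParams()) {
    tChars <- strsplit(toupper(as.character(seq)), "")[[1]]
    mirnaSeqs <- as.character(mirnas)
    hits <- list()
    for (nm in names(mirnaSeqs)) {
        mChars <- strsplit(toupper(mirnaSeqs[[nm]]), "")[[1]]
        masked <- tChars
        for (h in seq_len(params$maxHitsPerMirna)) {
            aln <- .swDuplex(masked, mChars, params)
            if (is.null(aln) || aln$score < params$scoreThreshold) break
            en <- duplexEnergy(aln$pairs, tChars, mChars)
            if (!is.na(en) && en <= params$energyThreshold)
                hits[[length(hits) + 1L]] <- data.frame(
                    mirna = nm, tStart = aln$tStart, tEnd = aln$tEnd,
                    score = aln$score, energy = en,
                    nPairs = sum(aln$pairs$class > 0L),
                    pairs = I(list(aln$pairs)))
            masked[aln$tStart:aln$tEnd] <- "#"
        }
    }
    if (length(hits) == 0L)
        return(data.frame(mirna = character(), tStart = integer(),
                          tEnd = integer(), score = numeric(),
                          energy = numeric(), nPairs = integer(),
                          pairs = I(list())))
    do.call(rbind, hits)
}

#' Extract the reference/edited flank pair of a 3'-UTR editing site
#'
#' Takes \code{flank} bp on each side of the site on the transcribed
#' strand (reverse-complemented genomic context for minus-strand sites),
#' truncated at transcript and contig boundaries with the lost lengths
#' recorded, and substitutes A with G at the edited position to build the
#' edited sequence.
#'
#' @param site a length-1 site \code{GRanges} with a \code{feature}
#'   column equal to \code{"3UTR"} (see \code{\link{annotateFeature}}).
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @param flank bp of context on each side.
#' @return a \linkS4class{FlankPair}.
#' @export
extractFlankPair <- function(site, bundle, flank = 50L) {
    stopifnot(length(site) == 1L)
    if (is.null(site$feature) || as.character(site$feature) != "3UTR")
        stop("flank pairs are defined for 3'-UTR editing sites only")
    genes <- geneModels(bundle)
    genome <- genomeSeq(bundle)
    ct <- as.character(seqnames(site)); pos <- start(site)
    st <- as.character(strand(site))
    L <- width(genome)[[match(ct, names(genome))]]
    tx <- genes[genes$type == "transcript"]
    ovr <- findOverlaps(site, tx, ignore.strand = TRUE)
    lo <- 1L; hi <- L
    if (length(ovr)) {
        t1 <- tx[S4Vectors::subjectHits(ovr)[1]]
        lo <- start(t1); hi <- end(t1)
    }
    wS <- max(lo, pos - flank); wE <- min(hi, pos + flank)
    seq <- as.character(subseq(genome[[ct]], wS, wE))
    if (st == "-") {
        seq <- as.character(reverseComplement(DNAString(seq)))
        idx <- wE - pos + 1L
        t5 <- flank - (wE - pos); t3 <- flank - (pos - wS)
    } else {
        idx <- pos - wS + 1L
        t5 <- flank - (pos - wS); t3 <- flank - (wE - pos)
    }
    ch <- strsplit(seq, "")[[1]]
    if (ch[idx] != "A")
        stop(sprintf("site %s:%d is not an adenosine on the %s strand",
                     ct, pos, st))
    edit <- ch; edit[idx] <- "G"
    new("FlankPair", site = site, refSeq = seq,
        editSeq = paste(edit, collapse = ""), editIndex = as.integer(idx),
        truncated5 = as.integer(t5), truncated3 = as.integer(t3))
}

#' Classify the miRNA-binding effect of an editing site
#'
#' Scans the reference and edited flanks with identical parameters, keeps
#' the best hit per miRNA on each sequence, and classifies each
#' miRNA-site pair: \code{gained} (hit on the edited sequence only),
#' \code{lost} (reference only), \code{energy_changed} (hit on both with
#' a different duplex energy) or \code{unchanged}.
#'
#' @param refHits,editHits hit data.frames from \code{\link{scanTargets}}
#'   on the reference and edited sequence.
#' @return a data.frame with \code{mirna}, \code{class}, \code{energyRef},
#'   \code{energyEdit}, \code{deltaE}.
#' @export
classifyEffects <- function(refHits, editHits) {
    bestPer <- function(h) {
        if (nrow(h) == 0L) return(h)
        h <- h[order(h$mirna, -h$score, h$tStart), , drop = FALSE]
        h[!duplicated(h$mirna), , drop = FALSE]
    }
    r <- bestPer(refHits); e <- bestPer(editHits)
    mirnas <- sort(union(r$mirna, e$mirna))
    if (length(mirnas) == 0L)
        return(data.frame(mirna = character(), class = character(),
                          energyRef = numeric(), energyEdit = numeric(),
                          deltaE = numeric()))
    out <- lapply(mirnas, function(nm) {
        er <- r$energy[r$mirna == nm]; ee <- e$energy[e$mirna == nm]
        inR <- length(er) > 0L; inE <- length(ee) > 0L
        cls <- if (inE && !inR) "gained"
               else if (inR && !inE) "lost"
               else if (ee != er) "energy_changed" else "unchanged"
        data.frame(mirna = nm, class = cls,
                   energyRef = if (inR) er else NA_real_,
                   energyEdit = if (inE) ee else NA_real_,
                   deltaE = if (inR && inE) ee - er else NA_real_)
    })
    do.call(rbind, out)
}

#' miRNA-binding consequences for a set of 3'-UTR editing sites
#'
#' @param sites annotated A-to-I sites (feature column present).
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @param mirnas a named \code{RNAStringSet}.
#' @param params from \code{\link{mirandaParams}}.
#' @param flank flank width in bp.
#' @return a list with \code{effects} (per site and miRNA),
#'   \code{summary} (pair and site counts per class) and \code{energies}
#'   (all hit energies on reference and edited flanks).
#' @export
mirnaEffects <- function(sites, bundle, mirnas, params = mirandaParams(),
                         flank = 50L) {
    u3 <- sites[as.character(sites$feature) == "3UTR"]
    effects <- list(); eRef <- numeric(); eEdit <- numeric()
    for (i in seq_along(u3)) {
        fp <- extractFlankPair(u3[i], bundle, flank)
        hr <- scanTargets(fp@refSeq, mirnas, params)
        he <- scanTargets(fp@editSeq, mirnas, params)
        eRef <- c(eRef, hr$energy); eEdit <- c(eEdit, he$energy)
        eff <- classifyEffects(hr, he)
        if (nrow(eff)) {
            eff$site <- grKey(u3[i])
            effects[[length(effects) + 1L]] <- eff
        }
    }
    effects <- if (length(effects)) do.call(rbind, effects)
               else data.frame(mirna = character(), class = character(),
                               energyRef = numeric(),
                               energyEdit = numeric(), deltaE = numeric(),
                               site = character())
    affected <- effects[effects$class != "unchanged", , drop = FALSE]
    summary <- list(
        pairsAffected = nrow(affected),
        pairsGained = sum(effects$class == "gained"),
        pairsLost = sum(effects$class == "lost"),
        pairsEnergyChanged = sum(effects$class == "energy_changed"),
        sitesGained = length(unique(effects$site[effects$class ==
                                                 "gained"])),
        sitesLost = length(unique(effects$site[effects$class == "lost"])),
        sitesEnergyChanged = length(unique(
            effects$site[effects$class == "energy_changed"])))
    list(effects = effects, summary = summary,
         energies = list(ref = eRef, edit = eEdit))
}

#' Compare duplex-energy distributions
#'
#' Two-sided Wilcoxon rank-sum test between two energy samples (for
#' example edited versus reference flanks, or DES versus non-DES sites),
#' with medians and their difference.
#'
#' @param energiesRef,energiesEdit numeric vectors.
#' @return a list with \code{p}, \code{statistic}, \code{medianRef},
#'   \code{medianEdit}, \code{medianDiff} (edit minus ref).
#' @export
compareEnergyDistributions <- function(energiesRef, energiesEdit) {
    if (length(energiesRef) < 3L || length(energiesEdit) < 3L)
        stop("need at least three energies per group")
    if (all(c(energiesRef, energiesEdit) ==
            c(energiesRef, energiesEdit)[1]))
        return(list(p = 1, statistic = NA_real_,
                    medianRef = stats::median(energiesRef),
                    medianEdit = stats::median(energiesEdit),
                    medianDiff = 0))
    w <- suppressWarnings(stats::wilcox.test(energiesEdit, energiesRef,
                                             exact = FALSE))
    list(p = w$p.value, statistic = unname(w$statistic),
         medianRef = stats::median(energiesRef),
         medianEdit = stats::median(energiesEdit),
         medianDiff = stats::median(energiesEdit) -
             stats::median(energiesRef))
}
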