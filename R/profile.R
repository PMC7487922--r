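#' @importFrom Biostrings GENETIC_CODE extractAt
NULL

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Stop")

# per-site x per-sample counts of transcribed-strand A and G reads
.editCounts <- function(evidence, sites, minQual, samples = NULL) {
    if (is.null(samples)) samples <- sort(unique(evidence$sample_id))
    nS <- length(sites)
    edited <- matrix(0L, nS, length(samples),
                     dimnames = list(NULL, samples))
    editable <- edited
    if (nS == 0L || nrow(evidence) == 0L)
        return(list(edited = edited, editable = editable))
    base_qual <- NULL
    ev <- evidence[base_qual >= minQual]
    key <- grKey(sites)
    idx <- match(posKey(ev$chrom, ev$pos), key)
    keep <- !is.na(idx)
    ev <- ev[keep]; idx <- idx[keep]
    st <- as.character(strand(sites))[idx]
    aBase <- ifelse(st == "-", "T", "A")
    gBase <- ifelse(st == "-", "C", "G")
    j <- match(ev$sample_id, samples)
    isG <- ev$base == gBase
    isA <- ev$base == aBase
    lin <- (j - 1L) * nS + idx
    nCell <- nS * length(samples)
    edited[] <- tabulate(lin[isG], nbins = nCell)
    editable[] <- tabulate(lin[isG | isA], nbins = nCell)
    list(edited = edited, editable = editable)
}

#' Per-site, per-sample editing levels
#'
#' The editing level is the number of G reads over the number of A plus G
#' reads covering the site, computed on the transcribed strand (genomic
#' T/C for minus-strand sites) over reads with quality at least
#' \code{minQual}.  The level is undefined (NA) when fewer than
#' \code{minCoverage} A+G reads cover the site or fewer than
#' \code{minEditReads} reads support the edited form.
#'
#' @param evidence a site-evidence \code{data.table}.
#' @param sites an A-to-I site \code{GRanges} (strand = transcribed).
#' @param design a data.frame with \code{sample_id}, \code{stage},
#'   \code{replicate}; defaults to parsing ids like \code{"Y30_r1"}.
#' @param qcfg a \linkS4class{QuantConfig}.
#' @return an \linkS4class{EditingExperiment}.
#' @export
editingLevelMatrix <- function(evidence, sites, design = NULL,
                               qcfg = quantConfig()) {
    if (is.null(design)) {
        ids <- sort(unique(evidence$sample_id))
        design <- data.frame(sample_id = ids,
                             stage = sub("_r[0-9]+$", "", ids),
                             replicate = as.integer(sub("^.*_r", "", ids)))
    }
    cn <- .editCounts(evidence, sites, qcfg@minQual, design$sample_id)
    level <- cn$edited / cn$editable
    undef <- cn$editable < qcfg@minCoverage | cn$edited < qcfg@minEditReads
    level[undef] <- NA_real_
    level[is.nan(level)] <- NA_real_
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(level = level, edited = cn$edited,
                      editable = cn$editable),
        rowRanges = sites,
        colData = S4Vectors::DataFrame(design, row.names = design$sample_id))
    new("EditingExperiment", se)
}

#' Editing level of a single site
#'
#' @param evidence a site-evidence \code{data.table}.
#' @param site a length-1 \code{GRanges}.
#' @param qcfg a \linkS4class{QuantConfig}.
#' @return named numeric of per-sample levels (NA where undefined).
#' @examples
#' # 16 A reads and 4 G reads with good quality give level 0.20
#' @export
siteEditingLevel <- function(evidence, site, qcfg = quantConfig()) {
    ee <- editingLevelMatrix(evidence, site, qcfg = qcfg)
    setNames(as.numeric(editingLevels(ee)[1L, ]), colnames(ee))
}

#' Overall editing rate per sample and stage
#'
#' The overall rate of a sample is the pooled ratio of G reads to A+G
#' reads across all A-to-I editing positions, with no per-site coverage
#' requirement (only the base-quality cut).  The stage value is the
#' unweighted mean over its replicates; the read-pooled stage ratio is
#' also reported.
#'
#' @param evidence a site-evidence \code{data.table}.
#' @param sites the A-to-I site \code{GRanges}.
#' @param design sample sheet as in \code{\link{editingLevelMatrix}}.
#' @param minQual minimum base quality.
#' @return a list with \code{perSample}, \code{perStage} (replicate means)
#'   and \code{perStagePooled} (read-pooled ratios).
#' @export
overallEditingRate <- function(evidence, sites, design = NULL,
                               minQual = 25) {
    if (length(sites) == 0L) stop("no A-to-I sites supplied")
    if (is.null(design)) {
        ids <- sort(unique(evidence$sample_id))
        design <- data.frame(sample_id = ids,
                             stage = sub("_r[0-9]+$", "", ids),
                             replicate = as.integer(sub("^.*_r", "", ids)))
    }
    cn <- .editCounts(evidence, sites, minQual, design$sample_id)
    num <- colSums(cn$edited); den <- colSums(cn$editable)
    if (all(den == 0)) {
        warning("no A/G reads cover any site")
        perSample <- setNames(rep(NA_real_, length(den)), names(den))
    } else perSample <- num / den
    stages <- unique(design$stage)
    perStage <- vapply(stages, function(s)
        mean(perSample[design$sample_id[design$stage == s]]), numeric(1))
    perStagePooled <- vapply(stages, function(s) {
        ids <- design$sample_id[design$stage == s]
        sum(num[ids]) / sum(den[ids])
    }, numeric(1))
    list(perSample = perSample, perStage = perStage,
         perStagePooled = perStagePooled)
}

#' Genomic feature of each editing site
#'
#' Assigns exactly one feature per site with precedence CDS > 3'-UTR >
#' 5'-UTR > ncRNA exon > intron > intergenic when transcripts overlap, and
#' records the host gene id(s).
#'
#' @param sites a site \code{GRanges}.
#' @param genes gene-model \code{GRanges}.
#' @return \code{sites} with \code{feature} and \code{host_gene} columns.
#' @export
annotateFeature <- function(sites, genes) {
    prec <- c("CDS", "3UTR", "5UTR", "ncRNA_exon", "intron", "intergenic")
    feat <- rep("intergenic", length(sites))
    host <- rep(NA_character_, length(sites))
    coding <- genes$biotype == "protein_coding"
    pick <- function(sel, label) {
        ov <- findOverlaps(sites, genes[sel], ignore.strand = TRUE)
        hit <- unique(S4Vectors::queryHits(ov))
        better <- match(label, prec) < match(feat[hit], prec)
        hit <- hit[better]
        feat[hit] <<- label
        g <- tapply(genes$gene_id[sel][S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov),
                    function(x) paste(unique(x), collapse = ","))
        host[as.integer(names(g))[as.integer(names(g)) %in% hit]] <<-
            unname(g[as.integer(names(g)) %in% hit])
    }
    # apply lowest precedence first so higher labels overwrite
    pick(genes$type == "intron", "intron")
    pick(genes$type == "exon" & !coding, "ncRNA_exon")
    pick(genes$type == "five_prime_utr", "5UTR")
    pick(genes$type == "three_prime_utr", "3UTR")
    pick(genes$type == "CDS", "CDS")
    sites$feature <- factor(feat, levels = prec)
    sites$host_gene <- host
    sites
}

#' Recoding consequence of CDS editing sites
#'
#' Builds the codon on the transcribed strand, substitutes A with G at the
#' edited position, translates both and reports the amino-acid pair.  A
#' classic example is an AAT codon edited at its second position: AGT,
#' Asn to Ser, nonsynonymous.
#'
#' @param sites a site \code{GRanges}; only entries with
#'   \code{feature == "CDS"} (annotate first) or overlapping a CDS are
#'   processed.
#' @param genes gene-model \code{GRanges}.
#' @param genome a \code{DNAStringSet}.
#' @return a \code{DataFrame} aligned with \code{sites}: columns
#'   \code{transcript_id}, \code{refCodon}, \code{altCodon}, \code{refAA},
#'   \code{altAA}, \code{consequence} (NA outside CDS).
#' @export
annotateRecoding <- function(sites, genes, genome) {
    n <- length(sites)
    out <- DataFrame(transcript_id = rep(NA_character_, n),
                     refCodon = rep(NA_character_, n),
                     altCodon = rep(NA_character_, n),
                     refAA = rep(NA_character_, n),
                     altAA = rep(NA_character_, n),
                     consequence = rep(NA_character_, n))
    cds <- genes[genes$type == "CDS"]
    if (length(cds) == 0L || n == 0L) return(out)
    ov <- findOverlaps(sites, cds, ignore.strand = TRUE)
    for (q in unique(S4Vectors::queryHits(ov))) {
        tx <- cds$transcript_id[
            S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == q][1]]
        chunks <- cds[cds$transcript_id == tx]
        chunks <- chunks[order(start(chunks))]
        st <- as.character(strand(chunks))[1]
        ct <- as.character(seqnames(chunks))[1]
        if (sum(width(chunks)) %% 3L != 0L)
            stop(sprintf("CDS phase of %s inconsistent (length %d)",
                         tx, sum(width(chunks))))
        seqs <- as.character(extractAt(genome[[ct]],
                                       IRanges(start(chunks),
                                               end(chunks))))
        cdsSeq <- paste(seqs, collapse = "")
        if (st == "-")
            cdsSeq <- as.character(reverseComplement(DNAString(cdsSeq)))
        pos <- start(sites)[q]
        cum <- cumsum(c(0L, width(chunks)))
        k <- which(pos >= start(chunks) & pos <= end(chunks))[1]
        cdsPos <- if (st == "+") cum[k] + (pos - start(chunks)[k] + 1L)
                  else sum(width(chunks)) -
                      (cum[k] + (pos - start(chunks)[k] + 1L)) + 1L
        ci <- ceiling(cdsPos / 3); cp <- cdsPos - (ci - 1L) * 3L
        codon <- substring(cdsSeq, (ci - 1L) * 3L + 1L, ci * 3L)
        if (substring(codon, cp, cp) != "A") next  # not an A on this frame
        altCodon <- codon
        substring(altCodon, cp, cp) <- "G"
        refAA <- GENETIC_CODE[[codon]]
        altAA <- GENETIC_CODE[[altCodon]]
        out$transcript_id[q] <- tx
        out$refCodon[q] <- codon; out$altCodon[q] <- altCodon
        out$refAA[q] <- unname(AA3[refAA]); out$altAA[q] <- unname(AA3[altAA])
        out$consequence[q] <- if (refAA == altAA) "synonymous"
                              else "nonsynonymous"
    }
    out
}

#' Repeat overlap of editing sites
#'
#' @param sites a site \code{GRanges}.
#' @param repeats repeat \code{GRanges} with \code{family},
#'   \code{subfamily}.
#' @return a list: \code{sites} (with \code{repeat_family},
#'   \code{repeat_subfamily}, \code{"none"} where outside repeats),
#'   \code{familyCounts}, \code{subfamilyCounts}, \code{fractionInRepeats}.
#' @export
annotateRepeats <- function(sites, repeats) {
    fam <- rep("none", length(sites))
    subf <- rep("none", length(sites))
    if (length(repeats) && length(sites)) {
        ov <- findOverlaps(sites, repeats, ignore.strand = TRUE)
        q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
        first <- !duplicated(q)
        fam[q[first]] <- repeats$family[s[first]]
        subf[q[first]] <- repeats$subfamily[s[first]]
    }
    sites$repeat_family <- fam
    sites$repeat_subfamily <- subf
    inRep <- fam != "none"
    list(sites = sites,
         familyCounts = table(fam[inRep]),
         subfamilyCounts = table(paste0(fam[inRep], ":", subf[inRep])),
         fractionInRepeats = if (length(sites)) mean(inRep) else NA_real_)
}

#' Neighbor-nucleotide preference around editing sites
#'
#' Frequencies of A/C/G/T at the positions immediately 5' (-1) and 3' (+1)
#' of the edited adenosine, on the edited (transcribed) strand.  Sites at
#' contig edges are skipped for the affected column.  Each column sums
#' to 1.
#'
#' @param sites a strand-resolved site \code{GRanges}.
#' @param genome a \code{DNAStringSet}.
#' @return a 4 x 2 matrix (rows A, C, G, T; columns \code{"-1"},
#'   \code{"+1"}).
#' @export
neighborPreference <- function(sites, genome) {
    m <- matrix(0, 4L, 2L, dimnames = list(BASES, c("-1", "+1")))
    if (length(sites) == 0L) return(m)
    for (ct in unique(as.character(seqnames(sites)))) {
        seqCh <- strsplit(as.character(genome[[ct]]), "")[[1]]
        L <- length(seqCh)
        sel <- sites[as.character(seqnames(sites)) == ct]
        pos <- start(sel); st <- as.character(strand(sel))
        for (i in seq_along(sel)) {
            gm <- pos[i] - 1L; gp <- pos[i] + 1L
            if (st[i] == "+") {
                if (gm >= 1L) m[seqCh[gm], "-1"] <- m[seqCh[gm], "-1"] + 1
                if (gp <= L) m[seqCh[gp], "+1"] <- m[seqCh[gp], "+1"] + 1
            } else {
                if (gp <= L) {
                    b <- COMPLEMENT[seqCh[gp]]
                    m[b, "-1"] <- m[b, "-1"] + 1
                }
                if (gm >= 1L) {
                    b <- COMPLEMENT[seqCh[gm]]
                    m[b, "+1"] <- m[b, "+1"] + 1
                }
            }
        }
    }
    sweep(m, 2L, pmax(colSums(m), 1L), "/")
}

#' Annotate editing sites with features, repeats and neighbors
#'
#' @param sites the A-to-I site \code{GRanges}.
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @return the sites with \code{feature}, \code{host_gene},
#'   \code{repeat_family}, \code{repeat_subfamily} columns.
#' @export
annotateSites <- function(sites, bundle) {
    sites <- annotateFeature(sites, geneModels(bundle))
    annotateRepeats(sites, repeatRanges(bundle))$sites
}

#' Per-gene expression matrix in RPKM from site evidence
#'
#' Counts evidence reads falling in the exons of each gene, per sample,
#' and normalizes by exon-model length and per-sample read totals.  This
#' is an evidence-based expression proxy for the simulated designs.
#'
#' @param evidence a site-evidence \code{data.table}.
#' @param genes gene-model \code{GRanges}.
#' @return a genes x samples RPKM matrix.
#' @export
geneRpkmMatrix <- function(evidence, genes) {
    exons <- genes[genes$type == "exon"]
    gids <- unique(genes$gene_id[genes$type == "gene"])
    samples <- sort(unique(evidence$sample_id))
    lens <- vapply(gids, function(g) sum(width(GenomicRanges::reduce(
        exons[exons$gene_id == g], ignore.strand = TRUE))), numeric(1))
    totals <- table(factor(evidence$sample_id, levels = samples))
    gr <- GRanges(evidence$chrom, IRanges(evidence$pos, width = 1L))
    out <- matrix(0, length(gids), length(samples),
                  dimnames = list(gids, samples))
    for (g in seq_along(gids)) {
        sel <- countOverlaps(gr, exons[exons$gene_id == gids[g]],
                             ignore.strand = TRUE) > 0L
        cnt <- table(factor(evidence$sample_id[sel], levels = samples))
        out[g, ] <- rpkm(as.numeric(cnt), lens[g], as.numeric(totals))
    }
    out
}
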