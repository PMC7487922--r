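suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
    library(data.table)
    library(SummarizedExperiment)
})

# small but complete synthetic study shared across test files (error-free
# reads so the truth table is exactly recoverable)
smallConfig <- function(seed = 101L, ...) {
    args <- list(nTrueSites = 60L, nDiffSites = 10L, nHetSnps = 10L,
                 nKnownOnlySnps = 5L,
                 nArtifactsPerClass = c(read_end = 5L, homopolymer = 5L,
                                        mismap = 5L),
                 nBackgroundSites = 20L, baseErrorRate = 0, seed = seed)
    do.call(simConfig, utils::modifyList(args, list(...)))
}

sharedStudy <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- simulateStudy(smallConfig())
        cache
    }
})

sharedDetection <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            st <- sharedStudy()
            cache <<- detectEditingSites(st$evidence, st$bundle)
        }
        cache
    }
})

# hand-built toy reference: one plus-strand and one minus-strand coding
# gene on a 2000 bp contig with fully controlled sequence content
toyBundle <- function(seqChars = NULL) {
    set.seed(42)
    ch <- if (is.null(seqChars))
        sample(c("A", "C", "G", "T"), 2000, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3)) else seqChars
    genome <- DNAStringSet(setNames(paste(ch, collapse = ""), "chrT"))
    mk <- function(s, e, strand, type, gid, tid, bt)
        GRanges("chrT", IRanges(s, e), strand = strand, type = type,
                gene_id = gid, transcript_id = tid, biotype = bt)
    # plus gene: exon 101-220 (5U 101-130, CDS 131-220), intron 221-420,
    # exon 421-600 (CDS 421-510, 3U 511-600); CDS length 90+90=180
    gp <- c(mk(101, 600, "+", "gene", "gP", "gP.t1", "protein_coding"),
            mk(101, 600, "+", "transcript", "gP", "gP.t1",
               "protein_coding"),
            mk(101, 220, "+", "exon", "gP", "gP.t1", "protein_coding"),
            mk(421, 600, "+", "exon", "gP", "gP.t1", "protein_coding"),
            mk(221, 420, "+", "intron", "gP", "gP.t1", "protein_coding"),
            mk(101, 130, "+", "five_prime_utr", "gP", "gP.t1",
               "protein_coding"),
            mk(131, 220, "+", "CDS", "gP", "gP.t1", "protein_coding"),
            mk(421, 510, "+", "CDS", "gP", "gP.t1", "protein_coding"),
            mk(511, 600, "+", "three_prime_utr", "gP", "gP.t1",
               "protein_coding"))
    # minus gene: genomic 1001-1500; exons 1001-1200 / 1301-1500;
    # transcribed 5'UTR at high coordinates (1471-1500)
    gm <- c(mk(1001, 1500, "-", "gene", "gM", "gM.t1", "protein_coding"),
            mk(1001, 1500, "-", "transcript", "gM", "gM.t1",
               "protein_coding"),
            mk(1001, 1200, "-", "exon", "gM", "gM.t1", "protein_coding"),
            mk(1301, 1500, "-", "exon", "gM", "gM.t1", "protein_coding"),
            mk(1201, 1300, "-", "intron", "gM", "gM.t1", "protein_coding"),
            mk(1471, 1500, "-", "five_prime_utr", "gM", "gM.t1",
               "protein_coding"),
            mk(1301, 1470, "-", "CDS", "gM", "gM.t1", "protein_coding"),
            mk(1101, 1200, "-", "CDS", "gM", "gM.t1", "protein_coding"),
            mk(1001, 1100, "-", "three_prime_utr", "gM", "gM.t1",
               "protein_coding"))
    genes <- sort(c(gp, gm), ignore.strand = TRUE)
    GenomeInfoDb::seqlengths(genes) <- c(chrT = 2000L)
    referenceBundle(genome, genes)
}

# evidence rows for one site: nRef + nAlt reads, all internal and
# high-quality unless overridden
toyEvidence <- function(pos, refBase, altBase, nRef, nAlt,
                        sample = "S1_r1", qual = 30L,
                        off5Ref = 75L, off5Alt = 75L, strand = "+",
                        chrom = "chrT", readLen = 150L) {
    n <- nRef + nAlt
    data.table(
        chrom = chrom, pos = as.integer(pos), ref_base = refBase,
        sample_id = sample,
        read_id = paste0(sample, "_", pos, "_", seq_len(n)),
        base = c(rep(refBase, nRef), rep(altBase, nAlt)),
        base_qual = as.integer(rep(qual, length.out = n)),
        offset_from_5p = as.integer(c(rep(off5Ref, nRef),
                                      rep(off5Alt, length.out = nAlt))),
        offset_from_3p = as.integer(readLen + 1L -
            c(rep(off5Ref, nRef), rep(off5Alt, length.out = nAlt))),
        library_strand = strand)
}

# force the reference base of the toy genome at given positions
withBases <- function(bundle, pos, bases) {
    ch <- strsplit(as.character(genomeSeq(bundle)[[1]]), "")[[1]]
    ch[pos] <- bases
    genome <- DNAStringSet(setNames(paste(ch, collapse = ""),
                                    names(genomeSeq(bundle))))
    referenceBundle(genome, geneModels(bundle), repeatRanges(bundle),
                    knownSnpRanges(bundle), wgsGenotypeRanges(bundle))
}

surviving <- function(callSet) {
    calls <- editingCalls(callSet)
    flags <- vapply(callFilterFlags(calls), length, 1L) > 0L
    calls[!flags]
}
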