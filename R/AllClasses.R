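#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- Rle
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges start end width strand seqnames
#' @importFrom GenomeInfoDb seqlengths seqlevels
#' @importFrom Biostrings DNAStringSet RNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Simulation configuration for the synthetic editing study
#'
#' Holds every knob of the synthetic-data generator: genome geometry, the
#' 3-stage x n-replicate design, per-stage mean editing levels, coverage and
#' error models, and the number of planted heterozygous SNPs and artifact
#' sites per class.  Identical configurations (including \code{seed}) yield
#' byte-identical outputs.
#'
#' @slot genomeLength contig length in bp.
#' @slot nGenes number of genes (alternating strands; includes two lncRNAs
#'   when \code{nGenes >= 4}).
#' @slot nTrueSites number of planted A-to-I editing sites.
#' @slot nDiffSites number of true sites given a stage-specific level shift
#'   of \code{diffDelta} (differentially edited truth).
#' @slot diffDelta level shift applied to one stage of each differential site.
#' @slot stageLevels named numeric, mean editing level per stage in [0,1].
#' @slot nReplicates biological replicates per stage.
#' @slot coverageMean mean read depth per site and sample (Poisson, floor 1).
#' @slot baseErrorRate per-read probability of a random base-call error.
#' @slot nHetSnps planted heterozygous genomic SNPs (seen at ~50% in RNA).
#' @slot nKnownOnlySnps planted RNA variants present only in the known-SNP
#'   catalogue (not in the WGS genotypes).
#' @slot nArtifactsPerClass named integer: planted artifact sites per class
#'   (\code{read_end}, \code{homopolymer}, \code{mismap}).
#' @slot nBackgroundSites monomorphic transcribed adenosines with evidence
#'   but no variation.
#' @slot artifactLevel alternative-allele fraction used for artifact sites.
#' @slot readLength simulated read length in bp.
#' @slot artifactEndMargin read-end window (bp) used when constructing
#'   read-end artifacts.
#' @slot replicateSd standard deviation of per-replicate level noise.
#' @slot siteLevelSd standard deviation of per-site level offsets around the
#'   stage mean.
#' @slot dupLength length (bp) of the duplicated (multi-mapping) segment.
#' @slot dupMutations point mutations introduced into the duplicate copy.
#' @slot qualMean,qualSd mean and sd of simulated phred base qualities.
#' @slot seed integer random seed.
#' @export
setClass("SimConfig", representation(
    genomeLength = "integer", nGenes = "integer",
    nTrueSites = "integer", nDiffSites = "integer", diffDelta = "numeric",
    stageLevels = "numeric", nReplicates = "integer",
    coverageMean = "numeric", baseErrorRate = "numeric",
    nHetSnps = "integer", nKnownOnlySnps = "integer",
    nArtifactsPerClass = "integer", nBackgroundSites = "integer",
    artifactLevel = "numeric", readLength = "integer",
    artifactEndMargin = "integer", replicateSd = "numeric",
    siteLevelSd = "numeric", dupLength = "integer", dupMutations = "integer",
    qualMean = "numeric", qualSd = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    probs <- c(object@baseErrorRate, object@stageLevels, object@artifactLevel)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "probabilities and levels must lie in [0,1]")
    counts <- c(object@genomeLength, object@nGenes, object@nTrueSites,
                object@nDiffSites, object@nHetSnps, object@nKnownOnlySnps,
                object@nArtifactsPerClass, object@nBackgroundSites,
                object@nReplicates)
    if (any(counts < 0)) msg <- c(msg, "counts must be >= 0")
    if (object@readLength < 2L * object@artifactEndMargin + 1L)
        msg <- c(msg, "readLength must be >= 2*artifactEndMargin + 1")
    if (is.null(names(object@stageLevels)) || any(names(object@stageLevels) == ""))
        msg <- c(msg, "stageLevels must be a named vector (stage -> level)")
    need <- c("read_end", "homopolymer", "mismap")
    if (!all(need %in% names(object@nArtifactsPerClass)))
        msg <- c(msg, "nArtifactsPerClass needs read_end, homopolymer, mismap")
    if (length(msg)) msg else TRUE
})

#' Detection thresholds for the editing-site filter cascade
#'
#' Collects the quality thresholds and the per-filter parameters of the
#' five-filter cascade in one auditable object.
#'
#' @slot minBaseQual minimum phred base quality for a read to be counted.
#' @slot maxAlleleTypes maximum number of allele types at a site.
#' @slot minAltReads minimum reads supporting the minor (alternative) allele.
#' @slot spliceWindow intronic sites within this many bp of a splice
#'   junction are removed.
#' @slot readEndMargin alternative reads within this many bp of either read
#'   end are discarded.
#' @slot homopolymerMinRun minimum length of a homopolymer run that
#'   disqualifies a site.
#' @slot multimapFlank half-width of the window aligned genome-wide for the
#'   uniqueness filter.
#' @slot multimapScoreRatio a site is discarded when a second locus aligns
#'   its window with at least this fraction of the perfect score.
#' @export
setClass("DetectionConfig", representation(
    minBaseQual = "numeric", maxAlleleTypes = "integer",
    minAltReads = "integer", spliceWindow = "integer",
    readEndMargin = "integer", homopolymerMinRun = "integer",
    multimapFlank = "integer", multimapScoreRatio = "numeric"))

setValidity("DetectionConfig", function(object) {
    msg <- character()
    if (any(c(object@minBaseQual, object@maxAlleleTypes, object@minAltReads,
              object@spliceWindow, object@readEndMargin,
              object@homopolymerMinRun, object@multimapFlank) < 0))
        msg <- c(msg, "all thresholds must be >= 0")
    if (object@multimapScoreRatio <= 0 || object@multimapScoreRatio > 1)
        msg <- c(msg, "multimapScoreRatio must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Quantification thresholds for per-site editing levels
#'
#' @slot minCoverage minimum A+G read coverage for a defined level.
#' @slot minQual minimum phred base quality for a read to be counted.
#' @slot minEditReads minimum G (edited) reads for a defined level.
#' @export
setClass("QuantConfig", representation(
    minCoverage = "integer", minQual = "numeric", minEditReads = "integer"))

setValidity("QuantConfig", function(object) {
    if (any(c(object@minCoverage, object@minQual, object@minEditReads) < 0))
        "all thresholds must be >= 0" else TRUE
})

#' Reference bundle: genome, gene models, repeats and genomic variation
#'
#' One coordinate system (1-based, as in \pkg{GenomicRanges}) holding the
#' genome sequence, flattened gene models (gene/transcript/exon/CDS/UTR/
#' intron features), repeat annotation, the known-SNP catalogue and the
#' WGS genotype calls.
#'
#' @slot genome a \link[Biostrings]{DNAStringSet}, one entry per contig.
#' @slot genes a \link[GenomicRanges]{GRanges} of gene-model features with
#'   metadata columns \code{type} (gene, transcript, exon, CDS,
#'   five_prime_utr, three_prime_utr, intron), \code{gene_id},
#'   \code{transcript_id} and \code{biotype}.
#' @slot repeats a \code{GRanges} with columns \code{family} and
#'   \code{subfamily}.
#' @slot knownSnps a \code{GRanges} of catalogued SNP positions.
#' @slot wgsGenotypes a \code{GRanges} with columns \code{genotype}
#'   (\code{hom_ref}, \code{het}, \code{hom_alt}), \code{ref}, \code{alt}
#'   and \code{multiallelic}.
#' @export
setClass("ReferenceBundle", representation(
    genome = "DNAStringSet", genes = "GRanges", repeats = "GRanges",
    knownSnps = "GRanges", wgsGenotypes = "GRanges"))

setValidity("ReferenceBundle", function(object) {
    msg <- character()
    lens <- setNames(width(object@genome), names(object@genome))
    chk <- function(gr, what) {
        if (length(gr) == 0L) return(character())
        bad <- !(as.character(seqnames(gr)) %in% names(lens))
        if (any(bad)) return(sprintf("%s on unknown contig", what))
        if (any(start(gr) < 1L) ||
            any(end(gr) > lens[as.character(seqnames(gr))]))
            return(sprintf("%s outside contig bounds", what))
        character()
    }
    msg <- c(msg, chk(object@genes, "gene features"),
             chk(object@repeats, "repeats"),
             chk(object@knownSnps, "known SNPs"),
             chk(object@wgsGenotypes, "WGS genotypes"))
    if (length(object@genes) &&
        !all(c("type", "gene_id", "transcript_id", "biotype") %in%
             colnames(mcols(object@genes))))
        msg <- c(msg, "genes must carry type, gene_id, transcript_id, biotype")
    if (length(msg)) msg else TRUE
})

#' Planted truth of a synthetic editing study
#'
#' @slot sites \code{GRanges} of true A-to-I sites (strand = transcribed
#'   strand) with a per-stage true-level matrix \code{stageLevel}, a
#'   \code{differential} flag and \code{inRepeat}.
#' @slot hetSnps \code{GRanges} of heterozygous genomic SNPs (\code{ref},
#'   \code{alt}, \code{inDbsnp}).
#' @slot knownOnlySnps \code{GRanges} of catalogue-only SNP positions that
#'   carry an RNA variant.
#' @slot artifacts \code{GRanges} of planted artifact sites with column
#'   \code{class} (\code{read_end}, \code{homopolymer}, \code{mismap}).
#' @slot duplication \code{GRanges} of length 2 (\code{role} = source, copy).
#' @slot homopolymers \code{GRanges} of planted homopolymer runs.
#' @export
setClass("SyntheticTruth", representation(
    sites = "GRanges", hetSnps = "GRanges", knownOnlySnps = "GRanges",
    artifacts = "GRanges", duplication = "GRanges", homopolymers = "GRanges"))

setValidity("SyntheticTruth", function(object) {
    pos <- function(gr) {
        if (length(gr) == 0L) return(character())
        paste0(as.character(seqnames(gr)), ":", start(gr))
    }
    all3 <- c(pos(object@sites), pos(object@hetSnps),
              pos(object@knownOnlySnps), pos(object@artifacts))
    if (anyDuplicated(all3))
        "true sites, SNPs and artifacts must be pairwise disjoint" else TRUE
})

#' Result container for the editing-site filter cascade
#'
#' @slot calls \code{GRanges} of candidate RNA-DNA differences with
#'   reference/alternative alleles, pooled and per-sample read counts,
#'   strand-resolved mismatch type and accumulated \code{filterFlags}.
#' @slot typeCounts named integer, surviving calls per mismatch type.
#' @slot typePercent named numeric, the same as percentages.
#' @slot sites \code{GRanges}, the surviving A-to-I subset.
#' @slot attrition named integer, calls flagged per filter.
#' @slot config the \linkS4class{DetectionConfig} used.
#' @export
setClass("EditingCallSet", representation(
    calls = "GRanges", typeCounts = "integer", typePercent = "numeric",
    sites = "GRanges", attrition = "integer", config = "DetectionConfig"))

#' Editing-level matrix as a RangedSummarizedExperiment
#'
#' Rows are A-to-I editing sites (with their annotations in
#' \code{rowRanges}), columns are samples with \code{stage} and
#' \code{replicate} in \code{colData}.  Assays: \code{level} (G/(A+G), NA
#' where undefined), \code{edited} (G reads) and \code{editable} (A+G
#' reads).
#' @export
setClass("EditingExperiment", contains = "RangedSummarizedExperiment")

setValidity("EditingExperiment", function(object) {
    msg <- character()
    if (!all(c("level", "edited", "editable") %in%
             SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assays level, edited, editable are required")
    else {
        lv <- SummarizedExperiment::assay(object, "level")
        if (any(lv < 0 | lv > 1, na.rm = TRUE))
            msg <- c(msg, "levels must lie in [0,1] or be NA")
    }
    if (!all(c("stage", "replicate") %in%
             colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData needs stage and replicate")
    if (length(msg)) msg else TRUE
})

#' Reference/edited flank pair around a 3'-UTR editing site
#'
#' Sequences are reported on the transcribed strand; the edited position is
#' \code{editIndex} (1-based within the flank), an A in \code{refSeq} and a
#' G in \code{editSeq}.
#'
#' @slot site the \code{GRanges} of the editing site.
#' @slot refSeq,editSeq character flank sequences (DNA alphabet).
#' @slot editIndex 1-based index of the edited base within the flanks.
#' @slot truncated5,truncated3 bp lost to contig edges on the 5'/3' side
#'   (transcribed-strand orientation).
#' @export
setClass("FlankPair", representation(
    site = "GRanges", refSeq = "character", editSeq = "character",
    editIndex = "integer", truncated5 = "integer", truncated3 = "integer"))

setValidity("FlankPair", function(object) {
    r <- strsplit(object@refSeq, "")[[1]]
    e <- strsplit(object@editSeq, "")[[1]]
    if (length(r) != length(e)) return("flank sequences differ in length")
    d <- which(r != e)
    if (!identical(d, object@editIndex))
        return("sequences must differ exactly at editIndex")
    if (r[object@editIndex] != "A" || e[object@editIndex] != "G")
        return("edited base must be A (reference) -> G (edited)")
    TRUE
})
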