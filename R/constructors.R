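#' Create a simulation configuration
#'
#' Defaults encode the emulated study design: three postnatal stages (Y30,
#' Y180, Y300) with three biological replicates each, 150 bp reads, and
#' per-stage mean editing levels matching the overall rates observed across
#' pineal-gland development (16.63%, 20.87%, 18.86%).
#'
#' @param genomeLength contig length in bp.
#' @param nGenes number of genes.
#' @param nTrueSites planted A-to-I sites.
#' @param nDiffSites sites given a stage-specific shift of \code{diffDelta}.
#' @param diffDelta stage-specific level shift for differential sites.
#' @param stageLevels named numeric of per-stage mean levels.
#' @param nReplicates replicates per stage.
#' @param coverageMean mean per-site, per-sample coverage.
#' @param baseErrorRate per-read base-call error probability.
#' @param nHetSnps planted heterozygous SNPs.
#' @param nKnownOnlySnps planted catalogue-only SNPs with RNA variation.
#' @param nArtifactsPerClass named integer (read_end, homopolymer, mismap).
#' @param nBackgroundSites monomorphic covered adenosines.
#' @param artifactLevel alternative-allele fraction at artifact sites.
#' @param readLength read length in bp.
#' @param artifactEndMargin read-end window for read-end artifacts.
#' @param replicateSd per-replicate level noise sd.
#' @param siteLevelSd per-site level offset sd.
#' @param dupLength duplicated-segment length in bp.
#' @param dupMutations point mutations in the duplicate copy (0 = exact).
#' @param qualMean,qualSd base-quality distribution parameters.
#' @param seed integer random seed.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nTrueSites = 50L, seed = 7L)
#' @export
simConfig <- function(genomeLength = 60000L, nGenes = 6L,
                      nTrueSites = 500L, nDiffSites = 60L, diffDelta = 0.3,
                      stageLevels = c(Y30 = 0.1663, Y180 = 0.2087,
                                      Y300 = 0.1886),
                      nReplicates = 3L, coverageMean = 50,
                      baseErrorRate = 0.001, nHetSnps = 50L,
                      nKnownOnlySnps = 20L,
                      nArtifactsPerClass = c(read_end = 50L,
                                             homopolymer = 50L,
                                             mismap = 50L),
                      nBackgroundSites = 200L, artifactLevel = 0.3,
                      readLength = 150L, artifactEndMargin = 6L,
                      replicateSd = 0.02, siteLevelSd = 0.05,
                      dupLength = 400L, dupMutations = 0L,
                      qualMean = 36, qualSd = 4, seed = 1L) {
    new("SimConfig", genomeLength = as.integer(genomeLength),
        nGenes = as.integer(nGenes), nTrueSites = as.integer(nTrueSites),
        nDiffSites = as.integer(nDiffSites), diffDelta = diffDelta,
        stageLevels = stageLevels, nReplicates = as.integer(nReplicates),
        coverageMean = coverageMean, baseErrorRate = baseErrorRate,
        nHetSnps = as.integer(nHetSnps),
        nKnownOnlySnps = as.integer(nKnownOnlySnps),
        nArtifactsPerClass = vapply(nArtifactsPerClass, as.integer,
                                    integer(1)),
        nBackgroundSites = as.integer(nBackgroundSites),
        artifactLevel = artifactLevel, readLength = as.integer(readLength),
        artifactEndMargin = as.integer(artifactEndMargin),
        replicateSd = replicateSd, siteLevelSd = siteLevelSd,
        dupLength = as.integer(dupLength),
        dupMutations = as.integer(dupMutations),
        qualMean = qualMean, qualSd = qualSd, seed = as.integer(seed))
}

#' Create a detection configuration
#'
#' Defaults are the thresholds of the high-confidence editing pipeline:
#' base quality >= 25, at most two allele types, minor allele supported by
#' at least three reads, intronic sites within 4 bp of splice junctions
#' removed, variants within 6 bp of a read end discarded, homopolymer runs
#' of 5+ bases excluded, and a 0.95 second-best/best alignment-score ratio
#' for the multi-mapping filter over +/- 25 bp windows.
#'
#' @param minBaseQual,maxAlleleTypes,minAltReads,spliceWindow,readEndMargin
#'   see \linkS4class{DetectionConfig}.
#' @param homopolymerMinRun,multimapFlank,multimapScoreRatio see
#'   \linkS4class{DetectionConfig}.
#' @return a validated \linkS4class{DetectionConfig}.
#' @examples
#' detectionConfig(minAltReads = 2L)
#' @export
detectionConfig <- function(minBaseQual = 25, maxAlleleTypes = 2L,
                            minAltReads = 3L, spliceWindow = 4L,
                            readEndMargin = 6L, homopolymerMinRun = 5L,
                            multimapFlank = 25L, multimapScoreRatio = 0.95) {
    new("DetectionConfig", minBaseQual = minBaseQual,
        maxAlleleTypes = as.integer(maxAlleleTypes),
        minAltReads = as.integer(minAltReads),
        spliceWindow = as.integer(spliceWindow),
        readEndMargin = as.integer(readEndMargin),
        homopolymerMinRun = as.integer(homopolymerMinRun),
        multimapFlank = as.integer(multimapFlank),
        multimapScoreRatio = multimapScoreRatio)
}

#' Create a quantification configuration
#'
#' Defaults: a defined editing level needs at least 10 high-quality
#' (phred >= 25) A+G reads and at least 3 reads supporting the edited (G)
#' form.
#'
#' @param minCoverage,minQual,minEditReads see \linkS4class{QuantConfig}.
#' @return a validated \linkS4class{QuantConfig}.
#' @export
quantConfig <- function(minCoverage = 10L, minQual = 25, minEditReads = 3L) {
    new("QuantConfig", minCoverage = as.integer(minCoverage),
        minQual = minQual, minEditReads = as.integer(minEditReads))
}

#' Assemble a reference bundle
#'
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param genes gene-model features (\code{GRanges}).
#' @param repeats repeat annotation (\code{GRanges}); may be empty.
#' @param knownSnps known-SNP positions (\code{GRanges}); may be empty.
#' @param wgsGenotypes WGS genotype calls (\code{GRanges}); may be empty.
#' @return a validated \linkS4class{ReferenceBundle}.
#' @export
referenceBundle <- function(genome, genes,
                            repeats = GRanges(), knownSnps = GRanges(),
                            wgsGenotypes = GRanges()) {
    new("ReferenceBundle", genome = genome, genes = genes,
        repeats = repeats, knownSnps = knownSnps,
        wgsGenotypes = wgsGenotypes)
}
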