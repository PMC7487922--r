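#' Write detected sites as TSV
#'
#' @param callSet an \linkS4class{EditingCallSet}.
#' @param path output file.
#' @export
writeSitesTsv <- function(callSet, path) {
    calls <- editingCalls(callSet)
    flags <- callFilterFlags(calls)
    df <- data.frame(
        chrom = as.character(seqnames(calls)), pos_1based = start(calls),
        strand = as.character(strand(calls)), ref = calls$ref,
        alt = calls$alt, mismatch_type = calls$mismatchType,
        ref_reads = calls$refCount, alt_reads = calls$altCount,
        alt_reads_end_filtered = calls$altCountEndFiltered,
        filter_flags = vapply(flags, function(f)
            if (length(f)) paste(f, collapse = ",") else "PASS", ""))
    altMat <- mcols(calls)$altMat
    if (!is.null(altMat)) {
        colnames(altMat) <- paste0("alt_", colnames(altMat))
        df <- cbind(df, as.data.frame(altMat))
    }
    fwrite(df, path, sep = "\t")
    invisible(path)
}

.defaultPipelineConfig <- function() {
    list(detection = list(), quant = list(),
         des = list(minDelta = 0.1, maxFdr = 0.05),
         mirna = list(flank = 50L), seed = 1L)
}

#' Read a pipeline configuration from YAML
#'
#' Keys: \code{outDir}; either \code{simulate} (arguments of
#' \code{\link{simConfig}}) or \code{inputs} (paths: \code{genome},
#' \code{gtf}, \code{repeats}, \code{wgsVcf}, \code{dbsnpVcf},
#' \code{evidence}, \code{mirnas}, optional \code{deg}); optional
#' \code{detection}, \code{quant}, \code{des}, \code{mirna} threshold
#' overrides and a global \code{seed}.
#'
#' @param path YAML file.
#' @return a validated configuration list.
#' @export
readPipelineConfig <- function(path) {
    cfg <- utils::modifyList(.defaultPipelineConfig(),
                             yaml::read_yaml(path))
    validatePipelineConfig(cfg)
    cfg
}

#' Validate a pipeline configuration
#'
#' Checks threshold ranges and that every referenced input file exists,
#' before any computation starts.
#'
#' @param cfg a configuration list.
#' @return the configuration, invisibly; errors on problems.
#' @export
validatePipelineConfig <- function(cfg) {
    if (is.null(cfg$outDir)) stop("config error: outDir is required")
    if (is.null(cfg$inputs) && is.null(cfg$simulate))
        stop("config error: either inputs or simulate must be given")
    if (!is.null(cfg$inputs)) {
        need <- c("genome", "gtf", "evidence")
        for (k in need)
            if (is.null(cfg$inputs[[k]]))
                stop(sprintf("config error: inputs$%s is required", k))
        for (k in names(cfg$inputs)) {
            paths <- cfg$inputs[[k]]
            missing <- paths[!file.exists(paths)]
            if (length(missing))
                stop(sprintf("config error: inputs$%s not found: %s",
                             k, paste(missing, collapse = ", ")))
        }
    }
    des <- cfg$des
    if (!is.null(des$minDelta) && (des$minDelta < 0 || des$minDelta > 1))
        stop("config error: des$minDelta must be in [0,1]")
    if (!is.null(des$maxFdr) && (des$maxFdr <= 0 || des$maxFdr > 1))
        stop("config error: des$maxFdr must be in (0,1]")
    invisible(cfg)
}

.stageLog <- function(stage, ...) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste0(...)))
}

#' Run the full editing-analysis pipeline
#'
#' Orchestrates simulate (or load) -> detect -> profile -> differential
#' -> miRNA from one configuration, writing every stage output plus a
#' machine-readable JSON run report into \code{outDir}.  Deterministic
#' under a fixed configuration and seed.
#'
#' @param config a configuration list (see
#'   \code{\link{readPipelineConfig}}) or the path to a YAML file.
#' @return the run report, invisibly.
#' @examples
#' \donttest{
#' cfg <- list(outDir = tempfile("run"),
#'             simulate = list(nTrueSites = 30L, nHetSnps = 5L,
#'                             nKnownOnlySnps = 2L, nBackgroundSites = 10L,
#'                             nArtifactsPerClass = c(read_end = 3L,
#'                                 homopolymer = 3L, mismap = 3L)),
#'             seed = 1L)
#' report <- runPipeline(cfg)
#' }
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readPipelineConfig(config)
    config <- utils::modifyList(.defaultPipelineConfig(), config)
    validatePipelineConfig(config)
    outDir <- config$outDir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    report <- list(seed = config$seed)

    if (!is.null(config$inputs)) {
        .stageLog("load", "reading inputs")
        ins <- config$inputs
        genome <- readGenomeFasta(ins$genome)
        genes <- readGeneModels(ins$gtf)
        repeats <- if (!is.null(ins$repeats)) readRepeats(ins$repeats)
                   else GRanges()
        knownSnps <- if (!is.null(ins$dbsnpVcf))
            readVcfPositions(ins$dbsnpVcf, "known_snp") else GRanges()
        wgs <- if (!is.null(ins$wgsVcf))
            readVcfPositions(ins$wgsVcf, "genotype") else GRanges()
        bundle <- referenceBundle(genome, genes, repeats, knownSnps, wgs)
        evidence <- rbindlist(lapply(ins$evidence, readSiteEvidence))
        setorder(evidence, chrom, pos, sample_id)
        mirnas <- if (!is.null(ins$mirnas)) readMirnaFasta(ins$mirnas)
                  else RNAStringSet()
        degList <- if (!is.null(ins$deg))
            utils::read.table(ins$deg, header = FALSE,
                              stringsAsFactors = FALSE)$V1 else NULL
        design <- if (!is.null(ins$design))
            utils::read.table(ins$design, header = TRUE,
                              stringsAsFactors = FALSE) else NULL
        truth <- NULL
    } else {
        .stageLog("simulate", "generating synthetic study")
        simArgs <- config$simulate
        if (!is.null(config$seed)) simArgs$seed <- config$seed
        if (!is.null(simArgs$nArtifactsPerClass))
            simArgs$nArtifactsPerClass <-
                unlist(simArgs$nArtifactsPerClass)
        if (!is.null(simArgs$stageLevels))
            simArgs$stageLevels <- unlist(simArgs$stageLevels)
        scfg <- do.call(simConfig, simArgs)
        study <- simulateStudy(scfg)
        bundle <- study$bundle; evidence <- study$evidence
        mirnas <- study$mirnas; truth <- study$truth
        degList <- NULL
        design <- study$design
        writeGenomeFasta(genomeSeq(bundle), file.path(outDir, "genome.fa"))
        writeGtf(geneModels(bundle), file.path(outDir, "genes.gtf"))
        writeRepeatsBed(repeatRanges(bundle),
                        file.path(outDir, "repeats.bed"))
        ks <- knownSnpRanges(bundle)
        writeSimpleVcf(ks, file.path(outDir, "dbsnp.vcf"),
                       genotypes = FALSE)
        writeSimpleVcf(wgsGenotypeRanges(bundle),
                       file.path(outDir, "wgs.vcf"))
        writeSiteEvidence(evidence, file.path(outDir, "evidence.tsv"))
        writeMirnaFasta(mirnas, file.path(outDir, "mirnas.fa"))
        writeTruthTsv(truth, file.path(outDir, "truth.tsv"))
        report$simulated <- list(nTrueSites = length(truthSites(truth)),
                                 nHetSnps = length(truthHetSnps(truth)),
                                 nArtifacts =
                                     length(truthArtifacts(truth)))
    }

    .stageLog("detect", "calling and filtering variants")
    dcfg <- do.call(detectionConfig, config$detection)
    callSet <- detectEditingSites(evidence, bundle, dcfg)
    writeSitesTsv(callSet, file.path(outDir, "sites.tsv"))
    report$detection <- list(
        candidates = length(editingCalls(callSet)),
        surviving = sum(rowSums(as.matrix(as.data.frame(
            mcols(editingCalls(callSet))[, .flagCols]))) == 0L),
        aToISites = length(editingSites(callSet)),
        attrition = as.list(filterAttrition(callSet)),
        typeCounts = as.list(mismatchTypeCounts(callSet)))

    .stageLog("profile", "quantifying and annotating")
    qcfg <- do.call(quantConfig, config$quant)
    sites <- annotateSites(editingSites(callSet), bundle)
    ee <- editingLevelMatrix(evidence, sites, design = design,
                             qcfg = qcfg)
    lv <- editingLevels(ee)
    rownames(lv) <- grKey(sites)
    fwrite(data.frame(site = rownames(lv), lv, check.names = FALSE),
           file.path(outDir, "levels.tsv"), sep = "\t")
    rates <- overallEditingRate(evidence, sites,
        design = as.data.frame(SummarizedExperiment::colData(ee)))
    fwrite(data.frame(sample = names(rates$perSample),
                      rate = rates$perSample),
           file.path(outDir, "rates_per_sample.tsv"), sep = "\t")
    np <- neighborPreference(sites, genomeSeq(bundle))
    fwrite(data.frame(base = rownames(np), np, check.names = FALSE),
           file.path(outDir, "neighbor_freq.tsv"), sep = "\t")
    repAnn <- annotateRepeats(sites, repeatRanges(bundle))
    fwrite(data.frame(family = names(repAnn$familyCounts),
                      count = as.integer(repAnn$familyCounts)),
           file.path(outDir, "repeat_distribution.tsv"), sep = "\t")
    rpkmMat <- geneRpkmMatrix(evidence, geneModels(bundle))
    fwrite(data.frame(gene = rownames(rpkmMat), rpkmMat,
                      check.names = FALSE),
           file.path(outDir, "rpkm.tsv"), sep = "\t")
    report$profile <- list(
        featureCounts = as.list(table(sites$feature)),
        fractionInRepeats = repAnn$fractionInRepeats,
        overallRatePerStage = as.list(rates$perStage))

    .stageLog("differential", "testing stage comparisons")
    desLists <- testAllComparisons(ee,
        minDelta = config$des$minDelta, maxFdr = config$des$maxFdr)
    for (nm in names(desLists))
        fwrite(desLists[[nm]],
               file.path(outDir, paste0("des_", nm, ".tsv")), sep = "\t")
    desSummary <- summarizeComparisons(desLists)
    fwrite(desSummary$perComparison,
           file.path(outDir, "des_summary.tsv"), sep = "\t")
    cl <- tryCatch(clusterSamples(ee), error = function(e) NULL)
    if (!is.null(cl))
        writeLines(cl$newick, file.path(outDir, "sample_clustering.nwk"))
    report$differential <- list(
        perComparison = desSummary$perComparison,
        unionCount = desSummary$unionCount,
        intersectionCount = desSummary$intersectionCount)
    if (!is.null(degList)) {
        desGenes <- unique(unlist(lapply(desLists, function(d) {
            key <- d$site[d$des]
            sites$host_gene[match(key, grKey(sites))]
        })))
        report$degOverlap <- overlapGenes(desGenes[!is.na(desGenes)],
                                          degList)
    }

    if (length(mirnas)) {
        .stageLog("mirna", "scanning 3'-UTR flanks")
        mparams <- do.call(mirandaParams,
                           config$mirna[setdiff(names(config$mirna),
                                                "flank")])
        flank <- if (!is.null(config$mirna$flank)) config$mirna$flank
                 else 50L
        desKeys <- unique(unlist(lapply(desLists,
                                        function(d) d$site[d$des])))
        mset <- sites[grKey(sites) %in% desKeys]
        if (length(mset) == 0L) mset <- sites
        me <- mirnaEffects(mset, bundle, mirnas, mparams, flank)
        fwrite(me$effects[, setdiff(names(me$effects), "pairs")],
               file.path(outDir, "mirna_effects.tsv"), sep = "\t")
        report$mirna <- me$summary
    }

    report$reconciliation <- list(
        featureTotal = sum(unlist(report$profile$featureCounts)),
        aToISites = report$detection$aToISites)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .stageLog("done", "report written to ",
              file.path(outDir, "report.json"))
    invisible(report)
}
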