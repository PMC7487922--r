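#' @rdname ReferenceBundle-class
#' @param x a \linkS4class{ReferenceBundle}.
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname ReferenceBundle-class
#' @export
setMethod("genomeSeq", "ReferenceBundle", function(x) x@genome)

#' @rdname ReferenceBundle-class
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname ReferenceBundle-class
#' @export
setMethod("geneModels", "ReferenceBundle", function(x) x@genes)

#' @rdname ReferenceBundle-class
#' @export
setGeneric("repeatRanges", function(x) standardGeneric("repeatRanges"))

#' @rdname ReferenceBundle-class
#' @export
setMethod("repeatRanges", "ReferenceBundle", function(x) x@repeats)

#' @rdname ReferenceBundle-class
#' @export
setGeneric("knownSnpRanges", function(x) standardGeneric("knownSnpRanges"))

#' @rdname ReferenceBundle-class
#' @export
setMethod("knownSnpRanges", "ReferenceBundle", function(x) x@knownSnps)

#' @rdname ReferenceBundle-class
#' @export
setGeneric("wgsGenotypeRanges",
           function(x) standardGeneric("wgsGenotypeRanges"))

#' @rdname ReferenceBundle-class
#' @export
setMethod("wgsGenotypeRanges", "ReferenceBundle", function(x) x@wgsGenotypes)

#' @rdname SyntheticTruth-class
#' @param x a \linkS4class{SyntheticTruth}.
#' @export
setGeneric("truthSites", function(x) standardGeneric("truthSites"))

#' @rdname SyntheticTruth-class
#' @export
setMethod("truthSites", "SyntheticTruth", function(x) x@sites)

#' @rdname SyntheticTruth-class
#' @export
setGeneric("truthArtifacts", function(x) standardGeneric("truthArtifacts"))

#' @rdname SyntheticTruth-class
#' @export
setMethod("truthArtifacts", "SyntheticTruth", function(x) x@artifacts)

#' @rdname SyntheticTruth-class
#' @export
setGeneric("truthHetSnps", function(x) standardGeneric("truthHetSnps"))

#' @rdname SyntheticTruth-class
#' @export
setMethod("truthHetSnps", "SyntheticTruth", function(x) x@hetSnps)

#' @rdname EditingCallSet-class
#' @param x an \linkS4class{EditingCallSet}.
#' @export
setGeneric("editingCalls", function(x) standardGeneric("editingCalls"))

#' @rdname EditingCallSet-class
#' @export
setMethod("editingCalls", "EditingCallSet", function(x) x@calls)

#' @rdname EditingCallSet-class
#' @export
setGeneric("editingSites", function(x) standardGeneric("editingSites"))

#' @rdname EditingCallSet-class
#' @export
setMethod("editingSites", "EditingCallSet", function(x) x@sites)

#' @rdname EditingCallSet-class
#' @export
setGeneric("mismatchTypeCounts",
           function(x) standardGeneric("mismatchTypeCounts"))

#' @rdname EditingCallSet-class
#' @export
setMethod("mismatchTypeCounts", "EditingCallSet", function(x) x@typeCounts)

#' @rdname EditingCallSet-class
#' @export
setGeneric("filterAttrition", function(x) standardGeneric("filterAttrition"))

#' @rdname EditingCallSet-class
#' @export
setMethod("filterAttrition", "EditingCallSet", function(x) x@attrition)

#' @rdname EditingExperiment-class
#' @param x an \linkS4class{EditingExperiment}.
#' @export
setGeneric("editingLevels", function(x) standardGeneric("editingLevels"))

#' @rdname EditingExperiment-class
#' @export
setMethod("editingLevels", "EditingExperiment",
          function(x) SummarizedExperiment::assay(x, "level"))

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@genomeLength, "bp genome,", object@nGenes,
        "genes,", object@nTrueSites, "true sites (",
        object@nDiffSites, "differential ), stages:",
        paste(sprintf("%s=%.3f", names(object@stageLevels),
                      object@stageLevels), collapse = " "),
        "x", object@nReplicates, "replicates, seed", object@seed, "\n")
})

setMethod("show", "ReferenceBundle", function(object) {
    cat("ReferenceBundle:", length(object@genome), "contig(s),",
        sum(width(object@genome)), "bp;",
        length(unique(object@genes$gene_id[object@genes$type == "gene"])),
        "genes;", length(object@repeats), "repeat intervals;",
        length(object@knownSnps), "known SNPs;",
        length(object@wgsGenotypes), "WGS genotype records\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@sites), "true sites;",
        length(object@hetSnps), "het SNPs;",
        length(object@knownOnlySnps), "catalogue-only SNPs;",
        length(object@artifacts), "artifact sites (",
        paste(names(table(object@artifacts$class)),
              table(object@artifacts$class), collapse = ", "), ")\n")
})

setMethod("show", "EditingCallSet", function(object) {
    cat("EditingCallSet:", length(object@calls), "candidate calls,",
        length(object@sites), "surviving A-to-I sites\n")
    if (length(object@attrition)) {
        cat("  flagged per filter:\n")
        for (f in names(object@attrition))
            cat(sprintf("    %-14s %d\n", f, object@attrition[[f]]))
    }
})

setMethod("show", "FlankPair", function(object) {
    cat("FlankPair:", nchar(object@refSeq), "nt, edited base at index",
        object@editIndex, sprintf("(truncated 5'/3': %d/%d)\n",
                                  object@truncated5, object@truncated3))
})
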