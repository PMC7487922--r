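#' @importFrom data.table fread fwrite
NULL

#' Read a genome FASTA
#'
#' Contig names are the first whitespace-delimited token of each header;
#' bases are upper-cased.  Duplicate contig names are a format error.
#'
#' @param path FASTA file.
#' @return a \link[Biostrings]{DNAStringSet}.
#' @export
readGenomeFasta <- function(path) {
    x <- readDNAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        stop("duplicate contig names in FASTA: ",
             paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
    DNAStringSet(toupper(x))
}

#' Write a genome FASTA
#' @param genome a \code{DNAStringSet}.
#' @param path output file.
#' @export
writeGenomeFasta <- function(genome, path) {
    writeXStringSet(genome, path)
    invisible(path)
}

#' Write gene models as GTF
#'
#' Emits gene, transcript, exon, CDS and UTR records (introns are implied
#' by the exon structure) with \code{gene_id}, \code{transcript_id} and
#' \code{gene_biotype} attributes, 1-based closed coordinates.
#'
#' @param genes a gene-model \code{GRanges} (see
#'   \linkS4class{ReferenceBundle}).
#' @param path output file.
#' @export
writeGtf <- function(genes, path) {
    keep <- genes[genes$type %in% c("gene", "transcript", "exon", "CDS",
                                    "five_prime_utr", "three_prime_utr")]
    attrs <- ifelse(keep$type == "gene",
        sprintf('gene_id "%s"; gene_biotype "%s";',
                keep$gene_id, keep$biotype),
        sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                keep$gene_id, keep$transcript_id, keep$biotype))
    lines <- sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     as.character(seqnames(keep)), keep$type,
                     start(keep), end(keep),
                     as.character(strand(keep)), attrs)
    writeLines(lines, path)
    invisible(path)
}

# split exon-minus-CDS pieces into 5'/3' UTRs relative to the CDS span
.deriveUtrs <- function(exons, cds, strand) {
    utr <- GenomicRanges::setdiff(exons, cds, ignore.strand = TRUE)
    if (length(utr) == 0L) return(GRanges())
    cdsStart <- min(start(cds)); cdsEnd <- max(end(cds))
    left <- utr[end(utr) < cdsStart]
    right <- utr[start(utr) > cdsEnd]
    if (strand == "+") {
        if (length(left)) left$type <- "five_prime_utr"
        if (length(right)) right$type <- "three_prime_utr"
    } else {
        if (length(left)) left$type <- "three_prime_utr"
        if (length(right)) right$type <- "five_prime_utr"
    }
    c(left, right)
}

#' Read gene models from a GTF file
#'
#' Ensembl-dialect GTF.  Introns are derived per transcript from the exon
#' structure; when a coding transcript lacks explicit UTR records they are
#' derived as exon-minus-CDS, with the 5'/3' assignment following the
#' transcribed strand.  A CDS whose total length is not divisible by three,
#' or a CDS without a parent transcript, is a format error.
#'
#' @param path GTF file.
#' @return a gene-model \code{GRanges} with columns \code{type},
#'   \code{gene_id}, \code{transcript_id}, \code{biotype}.
#' @export
readGeneModels <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    if (is.null(gr$gene_id)) stop("GTF lacks gene_id attributes")
    bio <- if (!is.null(gr$gene_biotype)) gr$gene_biotype
           else rep("protein_coding", length(gr))
    feats <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                     strand = strand(gr),
                     type = as.character(gr$type), gene_id = gr$gene_id,
                     transcript_id = if (!is.null(gr$transcript_id))
                         gr$transcript_id else NA_character_,
                     biotype = bio)
    txIds <- unique(feats$transcript_id[feats$type == "transcript"])
    cdsTx <- unique(feats$transcript_id[feats$type == "CDS"])
    orphan <- setdiff(cdsTx, txIds)
    if (length(orphan))
        stop("CDS without parent transcript: ",
             paste(orphan, collapse = ", "))
    out <- list(feats)
    for (tx in txIds) {
        sel <- feats[!is.na(feats$transcript_id) &
                     feats$transcript_id == tx]
        exons <- sel[sel$type == "exon"]
        if (length(exons) == 0L) next
        st <- as.character(strand(exons))[1]
        gid <- exons$gene_id[1]; bt <- exons$biotype[1]
        exonsR <- sort(GenomicRanges::reduce(exons, ignore.strand = TRUE))
        txSpan <- range(exonsR)
        introns <- GenomicRanges::setdiff(txSpan, exonsR,
                                          ignore.strand = TRUE)
        mk <- function(gr0, type) {
            if (length(gr0) == 0L) return(NULL)
            GRanges(seqnames(gr0), IRanges(start(gr0), end(gr0)),
                    strand = st, type = type, gene_id = gid,
                    transcript_id = tx, biotype = bt)
        }
        out[[length(out) + 1L]] <- mk(introns, "intron")
        cds <- sel[sel$type == "CDS"]
        if (length(cds)) {
            if (sum(width(cds)) %% 3L != 0L)
                stop(sprintf("CDS of %s has length %d, not divisible by 3",
                             tx, sum(width(cds))))
            if (!any(sel$type %in% c("five_prime_utr", "three_prime_utr",
                                     "UTR"))) {
                utr <- .deriveUtrs(sort(GenomicRanges::reduce(
                    exons, ignore.strand = TRUE)),
                    sort(GenomicRanges::reduce(cds, ignore.strand = TRUE)),
                    st)
                if (length(utr)) {
                    u <- mk(utr, "x"); u$type <- utr$type
                    out[[length(out) + 1L]] <- u
                }
            }
        }
    }
    res <- sort(do.call(c, out[!vapply(out, is.null, TRUE)]),
                ignore.strand = TRUE)
    res
}

#' Write repeat annotation as BED6
#'
#' BED name encodes the family as \code{"class/family:subfamily"}
#' (e.g. \code{"SINE/tRNA:Pre0_SS"}); coordinates follow the BED 0-based
#' half-open convention.
#'
#' @param repeats a repeat \code{GRanges} with \code{family},
#'   \code{subfamily}.
#' @param path output file.
#' @export
writeRepeatsBed <- function(repeats, path) {
    lines <- sprintf("%s\t%d\t%d\t%s:%s\t0\t%s",
                     as.character(seqnames(repeats)), start(repeats) - 1L,
                     end(repeats), repeats$family, repeats$subfamily,
                     as.character(strand(repeats)))
    writeLines(lines, path)
    invisible(path)
}

#' Read repeat annotation (BED6 or RepeatMasker .out)
#'
#' @param path input file; format detected from content unless given.
#' @param format \code{"bed"} or \code{"out"}.
#' @return a repeat \code{GRanges} with \code{family} and \code{subfamily}.
#' @export
readRepeats <- function(path, format = c("auto", "bed", "out")) {
    format <- match.arg(format)
    if (format == "auto") {
        first <- readLines(path, n = 1L)
        format <- if (grepl("^\\s*SW|^\\s*score", first)) "out" else "bed"
    }
    if (format == "bed") {
        bed <- utils::read.table(path, sep = "\t",
                                 stringsAsFactors = FALSE)
        fam <- sub(":.*$", "", bed$V4)
        sub <- ifelse(grepl(":", bed$V4), sub("^[^:]*:", "", bed$V4), "")
        GRanges(bed$V1, IRanges(bed$V2 + 1L, bed$V3),
                strand = if (ncol(bed) >= 6) bed$V6 else "*",
                family = fam, subfamily = sub)
    } else {
        lines <- readLines(path)
        lines <- lines[-seq_len(min(3L, length(lines)))]
        lines <- lines[nzchar(trimws(lines))]
        f <- strsplit(trimws(lines), "\\s+")
        GRanges(vapply(f, `[`, "", 5L),
                IRanges(as.integer(vapply(f, `[`, "", 6L)),
                        as.integer(vapply(f, `[`, "", 7L))),
                strand = ifelse(vapply(f, `[`, "", 9L) == "C", "-", "+"),
                family = vapply(f, `[`, "", 11L),
                subfamily = vapply(f, `[`, "", 10L))
    }
}

#' Write a minimal VCF 4.2 file
#'
#' @param gr a \code{GRanges} with \code{ref} and \code{alt} columns; when
#'   \code{genotypes = TRUE} also \code{genotype} (\code{hom_ref},
#'   \code{het}, \code{hom_alt}) written as a single-sample GT field.
#' @param path output file.
#' @param genotypes write a FORMAT/GT sample column.
#' @param sampleName sample column header.
#' @export
writeSimpleVcf <- function(gr, path, genotypes = TRUE,
                           sampleName = "WGS") {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=editomeR-synthetic",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
    cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
    if (genotypes) cols <- c(cols, "FORMAT", sampleName)
    body <- character(length(gr))
    gtMap <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
    for (i in seq_along(gr)) {
        fields <- c(as.character(seqnames(gr))[i], start(gr)[i], ".",
                    gr$ref[i], gr$alt[i], ".", "PASS", ".")
        if (genotypes) fields <- c(fields, "GT",
                                   unname(gtMap[gr$genotype[i]]))
        body[i] <- paste(fields, collapse = "\t")
    }
    writeLines(c(hdr[seq_len(if (genotypes) 3L else 2L)],
                 paste(cols, collapse = "\t"), body), path)
    invisible(path)
}

#' Read SNP positions or genotypes from a VCF
#'
#' In \code{"genotype"} mode, GT 0/0, 0/1 (or 1/0) and 1/1 map to
#' \code{hom_ref}, \code{het}, \code{hom_alt}; a missing GT field is a
#' format error.  Records with more than one ALT allele are retained but
#' flagged \code{multiallelic} (downstream calling rejects sites with more
#' than two allele types).  In \code{"known_snp"} mode only positions are
#' collected.
#'
#' @param path a VCF 4.x file.
#' @param mode \code{"known_snp"} or \code{"genotype"}.
#' @return a \code{GRanges}; genotype mode adds \code{genotype},
#'   \code{ref}, \code{alt}, \code{multiallelic}.
#' @export
readVcfPositions <- function(path, mode = c("known_snp", "genotype")) {
    mode <- match.arg(mode)
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    pos <- GRanges(seqnames(rr), IRanges(start(rr), width = 1L))
    if (mode == "known_snp") {
        mcols(pos) <- NULL
        return(pos)
    }
    gtMat <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gtMat) || ncol(gtMat) == 0L)
        stop("VCF has no GT field; cannot read genotypes")
    gt <- gtMat[, 1L]
    if (any(is.na(gt) | gt %in% c(".", "./.")))
        stop("missing GT values in genotype VCF")
    cls <- ifelse(gt %in% c("0/0", "0|0"), "hom_ref",
           ifelse(gt %in% c("0/1", "1/0", "0|1", "1|0"), "het",
           ifelse(gt %in% c("1/1", "1|1"), "hom_alt", NA)))
    if (any(is.na(cls)))
        stop("unsupported GT values: ",
             paste(unique(gt[is.na(cls)]), collapse = ", "))
    alt <- VariantAnnotation::alt(vcf)
    pos$genotype <- unname(cls)
    pos$ref <- as.character(VariantAnnotation::ref(vcf))
    pos$alt <- vapply(as(alt, "CharacterList"),
                      function(a) paste(a, collapse = ","), "")
    pos$multiallelic <- S4Vectors::elementNROWS(alt) > 1L
    pos
}

EVIDENCE_COLS <- c("chrom", "pos_1based", "ref_base", "sample_id",
                   "read_id", "base", "base_qual_phred", "offset_from_5p",
                   "offset_from_3p", "library_strand")

#' Write site evidence as TSV
#'
#' @param evidence a site-evidence \code{data.table} (see
#'   \code{\link{simulateRnaEvidence}}).
#' @param path output file.
#' @export
writeSiteEvidence <- function(evidence, path) {
    out <- data.table(
        chrom = evidence$chrom, pos_1based = evidence$pos,
        ref_base = evidence$ref_base, sample_id = evidence$sample_id,
        read_id = evidence$read_id, base = evidence$base,
        base_qual_phred = evidence$base_qual,
        offset_from_5p = evidence$offset_from_5p,
        offset_from_3p = evidence$offset_from_3p,
        library_strand = evidence$library_strand)
    fwrite(out, path, sep = "\t")
    invisible(path)
}

#' Read site evidence from TSV
#'
#' @param path a TSV written by \code{\link{writeSiteEvidence}} (or any
#'   file in the same dialect).
#' @return a site-evidence \code{data.table}.
#' @export
readSiteEvidence <- function(path) {
    ev <- fread(path, sep = "\t", colClasses = list(
        character = c("chrom", "ref_base", "sample_id", "read_id", "base",
                      "library_strand")))
    missing <- setdiff(EVIDENCE_COLS, names(ev))
    if (length(missing))
        stop("evidence TSV lacks columns: ",
             paste(missing, collapse = ", "))
    if (nrow(ev)) {
        if (any(ev$offset_from_5p < 1L | ev$offset_from_3p < 1L))
            stop("read-end offsets must be >= 1")
        if (!all(ev$base %in% c("A", "C", "G", "T", "N")))
            stop("observed bases must be one of A, C, G, T, N")
        if (any(ev$base_qual_phred < 0L))
            stop("base qualities must be >= 0")
    }
    out <- data.table(
        chrom = ev$chrom, pos = as.integer(ev$pos_1based),
        ref_base = ev$ref_base, sample_id = ev$sample_id,
        read_id = ev$read_id, base = ev$base,
        base_qual = as.integer(ev$base_qual_phred),
        offset_from_5p = as.integer(ev$offset_from_5p),
        offset_from_3p = as.integer(ev$offset_from_3p),
        library_strand = ev$library_strand)
    setorder(out, chrom, pos, sample_id)
    out[]
}

#' Read mature miRNA sequences
#'
#' miRBase-style FASTA; T is accepted and converted to U; names are the
#' first header token.
#'
#' @param path FASTA file.
#' @return a named \link[Biostrings]{RNAStringSet}.
#' @export
readMirnaFasta <- function(path) {
    x <- Biostrings::readBStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    RNAStringSet(gsub("T", "U", toupper(as.character(x))))
}

#' Write miRNA sequences as FASTA
#' @param mirnas an \code{RNAStringSet}.
#' @param path output file.
#' @export
writeMirnaFasta <- function(mirnas, path) {
    writeXStringSet(mirnas, path)
    invisible(path)
}

#' Write the planted truth as TSV
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path output file.
#' @export
writeTruthTsv <- function(truth, path) {
    s <- truth@sites
    lvl <- mcols(s)$stageLevel
    df <- data.frame(chrom = as.character(seqnames(s)), pos_1based = start(s),
                     strand = as.character(strand(s)), kind = "true_site",
                     class = ifelse(s$differential, "differential",
                                    "stable"))
    if (!is.null(lvl)) df <- cbind(df, as.data.frame(lvl))
    extras <- rbind(
        data.frame(chrom = as.character(seqnames(truth@hetSnps)),
                   pos_1based = start(truth@hetSnps),
                   strand = as.character(strand(truth@hetSnps)),
                   kind = "het_snp", class = ""),
        data.frame(chrom = as.character(seqnames(truth@artifacts)),
                   pos_1based = start(truth@artifacts),
                   strand = as.character(strand(truth@artifacts)),
                   kind = "artifact", class = truth@artifacts$class))
    if (nrow(extras) && !is.null(lvl)) {
        pad <- matrix(NA_real_, nrow(extras), ncol(lvl),
                      dimnames = list(NULL, colnames(lvl)))
        extras <- cbind(extras, as.data.frame(pad))
    }
    fwrite(rbind(df, extras), path, sep = "\t")
    invisible(path)
}
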