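BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

complementBase <- function(b) unname(COMPLEMENT[b])

#' All twelve strand-resolved mismatch types
#' @return character vector, e.g. \code{"A-to-G"}.
#' @export
mismatchTypes <- function() {
    out <- character()
    for (r in BASES) for (a in setdiff(BASES, r))
        out <- c(out, paste0(r, "-to-", a))
    out
}

posKey <- function(chrom, pos) {
    if (length(pos) == 0L) return(character())   # paste0() would give ":"
    paste0(chrom, ":", pos)
}

grKey <- function(gr) posKey(as.character(seqnames(gr)), start(gr))

#' Per-base maximal homopolymer run lengths
#'
#' For every position of a nucleotide sequence, the length of the maximal
#' run of identical bases containing it.
#'
#' @param seq a character scalar or \code{DNAString}.
#' @return integer vector of the same length as the sequence.
#' @examples
#' homopolymerRunLengths("GAAAAAC")
#' @export
homopolymerRunLengths <- function(seq) {
    ch <- strsplit(as.character(seq), "")[[1]]
    r <- rle(ch)
    rep.int(r$lengths, r$lengths)
}

# percentage vector over named counts, e.g. mismatch-type tallies
#' Percentages of a named count vector
#'
#' Turns a tally (for example mismatch-type counts) into percentages of the
#' total.
#'
#' @param counts named non-negative numeric vector.
#' @return named numeric vector summing to 100.
#' @examples
#' countPercentages(c(`A-to-G` = 44267, other = 3017))
#' @export
countPercentages <- function(counts) {
    if (sum(counts) == 0) stop("total count is zero")
    100 * counts / sum(counts)
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' @param readCount reads assigned to the gene.
#' @param exonModelLength total exon-model length in bp (> 0).
#' @param totalMappedReads library size in mapped reads (> 0).
#' @return numeric RPKM values.
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(readCount, exonModelLength, totalMappedReads) {
    if (any(exonModelLength <= 0)) stop("exon model length must be > 0")
    if (any(totalMappedReads <= 0)) stop("total mapped reads must be > 0")
    readCount / (exonModelLength / 1000) / (totalMappedReads / 1e6)
}

# truncated normal on [lo, hi] by clamping (mass at bounds is negligible at
# the sds used by the generator)
clampNorm <- function(n, mean, sd, lo = 0, hi = 1) {
    pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

# derive a stream-specific seed from the master seed, kept below 2^31
subSeed <- function(seed, k) (as.integer(seed) %% 20000000L) * 100L + k
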