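#' Benjamini-Hochberg false discovery rates
#'
#' The textbook step-up ladder: with ordered p-values p_(1) <= ... <=
#' p_(n), q_(i) = min over j >= i of p_(j) * n / j, clipped at 1.  Order
#' preserving and monotone in the p-value rank.
#'
#' @param p numeric vector of p-values in [0,1].
#' @return q-values in the input order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(p) {
    if (length(p) == 0L) return(numeric())
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0,1]")
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(n)
    out[o] <- q
    out
}

# vectorized equal-variance two-sample t over matrix rows
.rowTTest <- function(a, b) {
    nA <- rowSums(!is.na(a)); nB <- rowSums(!is.na(b))
    mA <- rowMeans(a, na.rm = TRUE); mB <- rowMeans(b, na.rm = TRUE)
    vA <- apply(a, 1L, stats::var, na.rm = TRUE)
    vB <- apply(b, 1L, stats::var, na.rm = TRUE)
    df <- nA + nB - 2L
    sp2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / df
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    t <- (mB - mA) / se
    p <- 2 * stats::pt(-abs(t), df)
    # zero variance in both groups: equal means give p = 1, not NaN
    degenerate <- is.nan(t)
    t[degenerate] <- 0; p[degenerate] <- 1
    list(t = t, p = p, meanA = mA, meanB = mB, df = df)
}

#' Test for differentially edited sites between two groups
#'
#' Per site, a two-sided Student's t-test (equal variance; Welch optional)
#' on the editing levels of group B versus group A.  Only sites with at
#' least two defined levels in each group are tested; q-values are
#' Benjamini-Hochberg across the tested sites of this comparison.  A site
#' is differentially edited (DES) when q <= \code{maxFdr} and
#' |mean(B) - mean(A)| >= \code{minDelta}; direction is the sign of the
#' delta (up = higher in group B).
#'
#' @param levels sites x samples matrix of editing levels (NA =
#'   undefined), or an \linkS4class{EditingExperiment}.
#' @param groupA,groupB column names of the two groups (e.g. replicates of
#'   two stages); the comparison is labelled B-A.
#' @param minDelta minimum absolute editing difference.
#' @param maxFdr FDR threshold.
#' @param varEqual use the pooled-variance Student statistic (default) or
#'   Welch.
#' @param siteIds optional site labels (defaults to rownames or
#'   coordinates).
#' @return a data.frame with one row per tested site: \code{site},
#'   \code{comparison}, \code{meanA}, \code{meanB}, \code{delta},
#'   \code{t}, \code{p}, \code{q}, \code{des}, \code{direction}.
#' @export
testDES <- function(levels, groupA, groupB, minDelta = 0.1, maxFdr = 0.05,
                    varEqual = TRUE, siteIds = NULL) {
    if (is(levels, "EditingExperiment")) {
        if (is.null(siteIds))
            siteIds <- grKey(SummarizedExperiment::rowRanges(levels))
        levels <- editingLevels(levels)
    }
    if (is.null(siteIds))
        siteIds <- if (!is.null(rownames(levels))) rownames(levels)
                   else as.character(seq_len(nrow(levels)))
    stopifnot(all(c(groupA, groupB) %in% colnames(levels)))
    a <- levels[, groupA, drop = FALSE]
    b <- levels[, groupB, drop = FALSE]
    eligible <- rowSums(!is.na(a)) >= 2L & rowSums(!is.na(b)) >= 2L
    a <- a[eligible, , drop = FALSE]; b <- b[eligible, , drop = FALSE]
    if (nrow(a) == 0L)
        return(data.frame(site = character(), comparison = character(),
                          meanA = numeric(), meanB = numeric(),
                          delta = numeric(), t = numeric(), p = numeric(),
                          q = numeric(), des = logical(),
                          direction = character()))
    if (varEqual) {
        tt <- .rowTTest(a, b)
    } else {
        tt <- list(t = numeric(nrow(a)), p = numeric(nrow(a)),
                   meanA = rowMeans(a, na.rm = TRUE),
                   meanB = rowMeans(b, na.rm = TRUE))
        for (i in seq_len(nrow(a))) {
            w <- stats::t.test(b[i, ], a[i, ], var.equal = FALSE)
            tt$t[i] <- unname(w$statistic); tt$p[i] <- w$p.value
        }
        degenerate <- is.nan(tt$t)
        tt$t[degenerate] <- 0; tt$p[degenerate] <- 1
    }
    delta <- tt$meanB - tt$meanA
    q <- bhFdr(tt$p)
    data.frame(site = siteIds[eligible],
               comparison = rep("B-A", sum(eligible)),
               meanA = unname(tt$meanA), meanB = unname(tt$meanB),
               delta = unname(delta), t = unname(tt$t), p = unname(tt$p),
               q = q, des = q <= maxFdr & abs(delta) >= minDelta,
               direction = ifelse(delta > 0, "up",
                                  ifelse(delta < 0, "down", "none")))
}

#' Pairwise DES tests across all stage comparisons
#'
#' Runs \code{\link{testDES}} for every later-minus-earlier stage pair
#' (labels like \code{"Y180-Y30"}).
#'
#' @param ee an \linkS4class{EditingExperiment}.
#' @param minDelta,maxFdr,varEqual passed to \code{\link{testDES}}.
#' @return a named list of per-comparison data.frames.
#' @export
testAllComparisons <- function(ee, minDelta = 0.1, maxFdr = 0.05,
                               varEqual = TRUE) {
    cd <- SummarizedExperiment::colData(ee)
    stages <- unique(as.character(cd$stage))
    out <- list()
    for (i in seq_along(stages)) for (j in seq_len(i - 1L)) {
        later <- stages[i]; earlier <- stages[j]
        label <- paste0(later, "-", earlier)
        res <- testDES(ee,
                       groupA = rownames(cd)[cd$stage == earlier],
                       groupB = rownames(cd)[cd$stage == later],
                       minDelta = minDelta, maxFdr = maxFdr,
                       varEqual = varEqual)
        res$comparison <- label
        out[[label]] <- res
    }
    out
}

#' Summarize DES comparisons
#'
#' Per comparison: up/down/total counts (total = up + down); across
#' comparisons: the number of distinct DESs and the size of the all-way
#' intersection.
#'
#' @param desLists a named list of \code{\link{testDES}} results.
#' @return a list with \code{perComparison} (data.frame),
#'   \code{unionCount} and \code{intersectionCount}.
#' @export
summarizeComparisons <- function(desLists) {
    perComp <- do.call(rbind, lapply(names(desLists), function(nm) {
        d <- desLists[[nm]]
        des <- d[d$des, , drop = FALSE]
        data.frame(comparison = nm,
                   up = sum(des$direction == "up"),
                   down = sum(des$direction == "down"),
                   total = nrow(des))
    }))
    sets <- lapply(desLists, function(d) unique(d$site[d$des]))
    unionCount <- length(unique(unlist(sets)))
    interCount <- if (length(sets))
        length(Reduce(intersect, sets)) else 0L
    list(perComparison = perComp, unionCount = unionCount,
         intersectionCount = interCount)
}

#' Hierarchical clustering of samples by editing profile
#'
#' Restricts the matrix to sites defined in every sample, computes
#' 1 - Pearson correlation between sample level vectors and clusters with
#' average linkage.  Columns are ordered by sample name beforehand, so the
#' result is invariant to the input sample order; ties in the correlation
#' structure resolve deterministically by name.
#'
#' @param levels sites x samples level matrix (or an
#'   \linkS4class{EditingExperiment}).
#' @return a list with \code{hclust}, \code{order} (leaf labels) and
#'   \code{newick} (the tree in Newick text).
#' @export
clusterSamples <- function(levels) {
    if (is(levels, "EditingExperiment")) levels <- editingLevels(levels)
    if (ncol(levels) < 2L) stop("need at least two samples")
    levels <- levels[, order(colnames(levels)), drop = FALSE]
    complete <- levels[stats::complete.cases(levels), , drop = FALSE]
    if (nrow(complete) < 2L)
        stop("fewer than two sites are defined in all samples")
    d <- stats::as.dist(1 - stats::cor(complete))
    hc <- stats::hclust(d, method = "average")
    phy <- ape::as.phylo(hc)
    list(hclust = hc, order = hc$labels[hc$order],
         newick = ape::write.tree(phy))
}

#' Overlap differentially edited genes with an expression DEG list
#'
#' A gene is differentially edited when it contains at least one DES.
#' Duplicate ids collapse before counting.
#'
#' @param desGenes character vector of genes containing DESs.
#' @param degList character vector of differentially expressed genes.
#' @return a list with \code{genes} (the intersection) and \code{count}.
#' @export
overlapGenes <- function(desGenes, degList) {
    genes <- sort(intersect(unique(desGenes), unique(degList)))
    list(genes = genes, count = length(genes))
}

#' Hypergeometric over-representation test per functional term
#'
#' For each term, p = P(X >= k) where k is the overlap between the gene
#' set and the term, under sampling |set| genes from the universe.  Term
#' genes outside the universe are pruned with a warning; q-values are
#' Benjamini-Hochberg across terms.
#'
#' @param geneSet character vector, a subset of \code{universe}.
#' @param universe character vector of all eligible genes.
#' @param termGenes named list of character vectors (term -> genes).
#' @return a data.frame with \code{term}, \code{termSize}, \code{overlap},
#'   \code{p}, \code{q}.
#' @export
enrichmentTest <- function(geneSet, universe, termGenes) {
    universe <- unique(universe)
    geneSet <- unique(geneSet)
    if (!all(geneSet %in% universe))
        stop("geneSet must be a subset of the universe")
    N <- length(universe); n <- length(geneSet)
    res <- lapply(names(termGenes), function(term) {
        tg <- unique(termGenes[[term]])
        outside <- setdiff(tg, universe)
        if (length(outside)) {
            warning(sprintf("term %s: %d gene(s) outside universe pruned",
                            term, length(outside)))
            tg <- intersect(tg, universe)
        }
        K <- length(tg)
        k <- length(intersect(geneSet, tg))
        p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(term = term, termSize = K, overlap = k, p = p)
    })
    out <- do.call(rbind, res)
    out$q <- bhFdr(out$p)
    out
}
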