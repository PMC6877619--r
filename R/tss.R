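#' Assign gene TSSs to their nearest domain boundary
#'
#' Each gene's TSS is matched to its nearest boundary junction; pairs at
#' distance >= \code{maxDist} are dropped; when several genes share a
#' nearest boundary only the closest is kept. Genes flagged inactive are
#' removed only after the nearest-neighbour competition, so they can still
#' displace an active gene from a boundary (avoiding spurious
#' active-gene/boundary associations) without appearing in the result.
#'
#' @param tss data.frame with columns \code{chrom}, \code{pos} (0-based
#'   TSS coordinate), \code{gene}, \code{active} (logical).
#' @param b a \code{\link{BoundarySet}}.
#' @param maxDist maximum TSS-boundary distance in bp (default 10000).
#' @return data.frame of unique (boundary, gene) pairs with columns
#'   \code{bin}, \code{chrom}, \code{gene}, \code{distance}.
#' @export
assignTssToBoundaries <- function(tss, b, maxDist = 10000) {
    g <- b@genome
    bt <- binTable(g)
    ends <- boundaryBins(b)
    if (!length(ends) || !nrow(tss))
        return(data.frame(bin = integer(), chrom = character(),
                          gene = character(), distance = numeric()))
    junction <- bt$end[ends + 1L]       # bp coordinate of each junction
    bGr <- GenomicRanges::GRanges(bt$chrom[ends + 1L],
        IRanges::IRanges(junction, width = 1))
    tGr <- GenomicRanges::GRanges(tss$chrom,
        IRanges::IRanges(tss$pos + 1, width = 1))
    hits <- GenomicRanges::distanceToNearest(tGr, bGr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    dist <- S4Vectors::mcols(hits)$distance
    keep <- dist < maxDist
    df <- data.frame(gene = tss$gene[qh], active = tss$active[qh],
                     bin = ends[sh], chrom = bt$chrom[ends[sh] + 1L],
                     distance = dist)[keep, , drop = FALSE]
    if (!nrow(df))
        return(data.frame(bin = integer(), chrom = character(),
                          gene = character(), distance = numeric()))
    df <- df[order(df$bin, df$distance), , drop = FALSE]
    df <- df[!duplicated(df$bin), , drop = FALSE]   # closest gene wins
    df <- df[df$active, , drop = FALSE]             # drop inactive afterwards
    rownames(df) <- NULL
    df[c("bin", "chrom", "gene", "distance")]
}
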