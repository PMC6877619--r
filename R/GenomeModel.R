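#' Construct a GenomeModel
#'
#' @param chromosomes data.frame with columns \code{name}, \code{length}
#'   (bp) and optionally \code{copyNumber} (default 2, i.e. a paired
#'   autosome); or a named numeric vector of lengths.
#' @param binSize bin width in bp.
#' @return A \code{\link{GenomeModel}}.
#' @examples
#' g <- genomeModel(c(chr2L = 1e6, chrX = 5e5), binSize = 25000)
#' nBins(g)
#' @export
genomeModel <- function(chromosomes, binSize) {
    if (is.numeric(chromosomes) && !is.null(names(chromosomes)))
        chromosomes <- data.frame(name = names(chromosomes),
                                  length = as.numeric(chromosomes))
    if (is.null(chromosomes$copyNumber)) chromosomes$copyNumber <- 2L
    chromosomes$name <- as.character(chromosomes$name)
    chromosomes$copyNumber <- as.integer(chromosomes$copyNumber)
    binSize <- as.integer(binSize)
    bins <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
        len <- chromosomes$length[i]
        starts <- seq(0, len - 1, by = binSize)
        data.frame(chrom = chromosomes$name[i], start = starts,
                   end = pmin(starts + binSize, len))
    }))
    bins$bin_id <- seq_len(nrow(bins)) - 1L
    rownames(bins) <- NULL
    new("GenomeModel", chroms = chromosomes, binSize = binSize, bins = bins)
}

#' @rdname genomeModel
#' @param g a \code{GenomeModel}.
#' @export
nBins <- function(g) nrow(g@bins)

#' @rdname genomeModel
#' @export
chromNames <- function(g) g@chroms$name

#' @rdname genomeModel
#' @export
chromLengths <- function(g) setNames(g@chroms$length, g@chroms$name)

#' @rdname genomeModel
#' @export
copyNumbers <- function(g) setNames(g@chroms$copyNumber, g@chroms$name)

#' @rdname genomeModel
#' @export
binSize <- function(g) g@binSize

#' @rdname genomeModel
#' @export
binTable <- function(g) g@bins

#' Number of bins per chromosome
#' @param g a \code{GenomeModel}.
#' @return Named integer vector, chromosome order preserved.
#' @export
chromNBins <- function(g) {
    tab <- table(factor(g@bins$chrom, levels = chromNames(g)))
    setNames(as.integer(tab), chromNames(g))
}

#' First global bin_id of each chromosome
#' @param g a \code{GenomeModel}.
#' @return Named integer vector of 0-based offsets.
#' @export
chromOffsets <- function(g) {
    nb <- chromNBins(g)
    setNames(as.integer(cumsum(c(0, nb[-length(nb)]))), names(nb))
}

#' Chromosome of each global bin
#' @param g a \code{GenomeModel}.
#' @return Character vector of length \code{nBins(g)}.
#' @export
binChrom <- function(g) g@bins$chrom

#' Bin table as a GRanges
#' @param g a \code{GenomeModel}.
#' @return A \code{GRanges} with 1-based ranges and a \code{bin_id} column.
#' @export
binsGRanges <- function(g) {
    GenomicRanges::GRanges(g@bins$chrom,
        IRanges::IRanges(g@bins$start + 1L, g@bins$end),
        bin_id = g@bins$bin_id)
}

#' Global bin_id containing a genomic position
#'
#' @param g a \code{GenomeModel}.
#' @param chrom character vector of chromosome names.
#' @param pos numeric vector of 0-based positions (bp).
#' @return Integer vector of global bin_ids.
#' @export
binOfPosition <- function(g, chrom, pos) {
    off <- chromOffsets(g)
    nb <- chromNBins(g)
    if (!all(chrom %in% names(off))) stop("unknown chromosome in position query")
    local <- pmin(as.integer(pos %/% binSize(g)), nb[chrom] - 1L)
    if (any(pos < 0) || any(pos >= chromLengths(g)[chrom]))
        stop("position outside chromosome bounds")
    as.integer(off[chrom] + local)
}

setMethod("show", "GenomeModel", function(object) {
    cat(sprintf("GenomeModel: %d chromosome(s), bin size %d bp, %d bins\n",
                nrow(object@chroms), object@binSize, nBins(object)))
    for (i in seq_len(nrow(object@chroms)))
        cat(sprintf("  %s  %.0f bp  copy %d\n", object@chroms$name[i],
                    object@chroms$length[i], object@chroms$copyNumber[i]))
})
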