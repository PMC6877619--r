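#' Read a binned contact matrix from triplet + bin-table files
#'
#' The triplet file is whitespace-delimited \code{bin1_id bin2_id value};
#' the bins file is BED4-like: \code{chrom start end bin_id} (0-based
#' half-open, dense bin_ids in row order). Lower-triangle records are
#' mirrored into the upper triangle and summed with duplicates.
#'
#' @param path triplet TSV path.
#' @param binsPath bin-table path.
#' @param copyNumber optional named integer vector of chromosome copy
#'   numbers (default 2 everywhere).
#' @param kind kind of the stored values: \code{"raw"} (default),
#'   \code{"balanced"} or \code{"frequency"}. Non-finite balanced values
#'   are set to 0 on reading.
#' @return A \code{\link{ContactMatrix}} of the requested kind.
#' @export
readContacts <- function(path, binsPath, copyNumber = NULL, kind = "raw") {
    g <- readBins(binsPath, copyNumber)
    trip <- read.table(path, header = FALSE,
                       col.names = c("bin1", "bin2", "value"))
    if (kind == "raw" && nrow(trip) && any(trip$value < 0))
        stop("negative count in triplet file at row ",
             which(trip$value < 0)[1])
    if (kind != "raw") trip$value[!is.finite(trip$value)] <- 0
    n <- nBins(g)
    bad <- which(trip$bin1 < 0 | trip$bin1 >= n | trip$bin2 < 0 | trip$bin2 >= n)
    if (length(bad))
        stop(sprintf("triplet row %d references bin_id outside the bin table: (%d, %d)",
                     bad[1], trip$bin1[bad[1]], trip$bin2[bad[1]]))
    contactMatrix(g, trip$bin1, trip$bin2, trip$value, kind = kind)
}

#' @rdname readContacts
#' @export
readBins <- function(binsPath, copyNumber = NULL) {
    bins <- read.table(binsPath, header = FALSE,
                       col.names = c("chrom", "start", "end", "bin_id"))
    bins$chrom <- as.character(bins$chrom)
    lens <- tapply(bins$end, bins$chrom, max)
    cn <- unique(bins$chrom)          # keep file order, not alphabetical
    chroms <- data.frame(name = cn, length = as.numeric(lens[cn]))
    if (!is.null(copyNumber)) {
        if (!all(cn %in% names(copyNumber)))
            stop("copyNumber must name every chromosome in the bin table")
        chroms$copyNumber <- as.integer(copyNumber[cn])
    }
    g <- genomeModel(chroms, binSize = max(bins$end - bins$start))
    if (!all(binTable(g)$start == bins$start) ||
        !all(binTable(g)$bin_id == bins$bin_id))
        stop("bin table is not a dense 0-based tiling")
    g
}

#' Write a ContactMatrix as triplet + bin-table files
#'
#' @param m a \code{\link{ContactMatrix}}.
#' @param path triplet TSV path.
#' @param binsPath optional bin-table path.
#' @return Invisibly, \code{path}.
#' @export
writeContacts <- function(m, path, binsPath = NULL) {
    write.table(m@entries, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    if (!is.null(binsPath))
        write.table(binTable(m@genome), binsPath, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read / write per-bin bias vectors
#'
#' Bias files are TSV \code{bin_id bias}; bins absent from the file get NA.
#'
#' @param path file path.
#' @param g a \code{\link{GenomeModel}}.
#' @return \code{readBias}: numeric vector of length \code{nBins(g)}.
#' @export
readBias <- function(path, g) {
    tab <- read.table(path, header = FALSE, col.names = c("bin_id", "bias"))
    b <- rep(NA_real_, nBins(g))
    b[tab$bin_id + 1L] <- tab$bias
    b
}

#' @rdname readBias
#' @param bias numeric bias vector.
#' @export
writeBias <- function(bias, path) {
    keep <- !is.na(bias)
    write.table(data.frame(bin_id = which(keep) - 1L, bias = bias[keep]),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read point features from a BED file
#'
#' Imports a BED track and reduces each record to its midpoint, the
#' convention used for binding-site positions throughout the package.
#'
#' @param path BED file path.
#' @return data.frame with columns \code{chrom}, \code{mid} (0-based bp) and,
#'   when present in the BED, \code{name} and \code{score}.
#' @export
readFeatureBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    out <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        mid = floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2))
    if (!is.null(gr$name)) out$name <- gr$name
    if (!is.null(gr$score)) out$score <- gr$score
    out
}

#' Read a signal track (bedGraph or wig)
#'
#' @param path file path.
#' @param format \code{"bedGraph"} or \code{"wig"} (guessed from the
#'   extension when NULL).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and \code{value}.
#' @export
readSignalTrack <- function(path, format = NULL) {
    if (is.null(format)) {
        format <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "WIG"
                  else "bedGraph"
    }
    gr <- rtracklayer::import(path, format = format)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               value = gr$score)
}

#' Write a per-bin track as bedGraph
#'
#' @param g a \code{\link{GenomeModel}}.
#' @param values numeric, one value per bin (NA bins skipped).
#' @param path output path.
#' @export
writeBedGraph <- function(g, values, path) {
    b <- binTable(g)
    keep <- !is.na(values)
    write.table(data.frame(b$chrom[keep], b$start[keep], b$end[keep],
                           values[keep]),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
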