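#' Construct a ContactMatrix from triplets
#'
#' Entries below the diagonal are mirrored into the upper triangle and summed
#' with any duplicate of the same cell.
#'
#' @param genome a \code{\link{GenomeModel}}.
#' @param bin1,bin2 integer bin_ids.
#' @param value numeric values.
#' @param kind matrix kind: \code{"raw"}, \code{"balanced"} or
#'   \code{"frequency"}.
#' @param bias optional per-bin bias vector.
#' @param maskedBins optional integer vector of masked bin_ids.
#' @param metadata optional list.
#' @return A \code{\link{ContactMatrix}}.
#' @export
contactMatrix <- function(genome, bin1 = integer(), bin2 = integer(),
                          value = numeric(), kind = "raw", bias = numeric(),
                          maskedBins = integer(), metadata = list()) {
    n <- nBins(genome)
    bad <- which(bin1 < 0 | bin1 >= n | bin2 < 0 | bin2 >= n)
    if (length(bad))
        stop(sprintf("entry %d references bin_id outside the bin table (%d, %d)",
                     bad[1], bin1[bad[1]], bin2[bad[1]]))
    lo <- pmin(bin1, bin2); hi <- pmax(bin1, bin2)
    key <- lo * n + hi
    agg <- rowsum(as.numeric(value), key)
    ukey <- as.numeric(rownames(agg))
    e <- data.frame(bin1 = as.integer(ukey %/% n), bin2 = as.integer(ukey %% n),
                    value = as.numeric(agg[, 1]))
    e <- e[order(e$bin1, e$bin2), , drop = FALSE]
    e <- e[e$value != 0, , drop = FALSE]
    rownames(e) <- NULL
    new("ContactMatrix", genome = genome, entries = e, kind = kind,
        bias = bias, maskedBins = as.integer(maskedBins), metadata = metadata)
}

#' @rdname contactMatrix
#' @param m a \code{ContactMatrix}.
#' @export
contactEntries <- function(m) m@entries

#' @rdname contactMatrix
#' @export
contactKind <- function(m) m@kind

#' @rdname contactMatrix
#' @export
contactGenome <- function(m) m@genome

#' @rdname contactMatrix
#' @export
contactBias <- function(m) m@bias

#' @rdname contactMatrix
#' @export
maskedBins <- function(m) m@maskedBins

#' Dense cis block of one chromosome
#'
#' Materializes the symmetric contact sub-matrix of a chromosome with
#' chromosome-local indices. Absent cells are 0.
#'
#' @param m a \code{ContactMatrix}.
#' @param chrom chromosome name.
#' @return A dense symmetric numeric matrix (nb x nb).
#' @export
cisBlock <- function(m, chrom) {
    g <- m@genome
    off <- chromOffsets(g)[[chrom]]
    nb <- chromNBins(g)[[chrom]]
    e <- m@entries
    sel <- e$bin1 >= off & e$bin1 < off + nb & e$bin2 >= off & e$bin2 < off + nb
    e <- e[sel, , drop = FALSE]
    mat <- matrix(0, nb, nb)
    if (nrow(e)) {
        i <- e$bin1 - off + 1L; j <- e$bin2 - off + 1L
        mat[cbind(i, j)] <- e$value
        mat[cbind(j, i)] <- e$value
    }
    mat
}

#' Replace the cis block of one chromosome
#'
#' @param m a \code{ContactMatrix}.
#' @param chrom chromosome name.
#' @param block dense symmetric matrix (upper triangle is stored).
#' @return A \code{ContactMatrix} with that chromosome's cis entries replaced.
#' @keywords internal
setCisBlock <- function(m, chrom, block) {
    g <- m@genome
    off <- chromOffsets(g)[[chrom]]
    nb <- chromNBins(g)[[chrom]]
    e <- m@entries
    drop <- e$bin1 >= off & e$bin1 < off + nb & e$bin2 >= off & e$bin2 < off + nb
    keep <- e[!drop, , drop = FALSE]
    idx <- which(upper.tri(block, diag = TRUE) & block != 0, arr.ind = TRUE)
    add <- data.frame(bin1 = off + idx[, 1] - 1L, bin2 = off + idx[, 2] - 1L,
                      value = block[idx])
    e2 <- rbind(keep, add)
    e2 <- e2[order(e2$bin1, e2$bin2), , drop = FALSE]
    rownames(e2) <- NULL
    initialize(m, entries = e2)
}

#' Look up contact values for (i, j) queries
#'
#' Symmetric lookup: \code{contactValue(m, i, j) == contactValue(m, j, i)}.
#'
#' @param m a \code{ContactMatrix}.
#' @param i,j integer bin_ids (vectorized).
#' @return Numeric vector; 0 for absent cells.
#' @export
contactValue <- function(m, i, j) {
    n <- nBins(m@genome)
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- lo * n + hi
    ekey <- m@entries$bin1 * n + m@entries$bin2
    v <- m@entries$value[match(key, ekey)]
    v[is.na(v)] <- 0
    v
}

#' Total cis counts per chromosome
#' @param m a \code{ContactMatrix}.
#' @return Named numeric vector.
#' @export
cisTotals <- function(m) {
    g <- m@genome
    chrom <- binChrom(g)
    e <- m@entries
    c1 <- chrom[e$bin1 + 1L]; c2 <- chrom[e$bin2 + 1L]
    cis <- e[c1 == c2, , drop = FALSE]
    tot <- setNames(numeric(length(chromNames(g))), chromNames(g))
    if (nrow(cis)) {
        s <- tapply(cis$value, chrom[cis$bin1 + 1L], sum)
        tot[names(s)] <- s
    }
    tot
}

setMethod("show", "ContactMatrix", function(object) {
    cat(sprintf("ContactMatrix (%s): %d entries on %d bins (%d chromosomes)\n",
                object@kind, nrow(object@entries), nBins(object@genome),
                nrow(object@genome@chroms)))
    if (length(object@maskedBins))
        cat(sprintf("  %d masked bins\n", length(object@maskedBins)))
})
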