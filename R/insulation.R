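#' Crane-style insulation score
#'
#' For each bin, the mean balanced signal in a window x window square just
#' up- and downstream of the bin (rows i-window..i-1, columns
#' i+1..i+window), sliding along the main diagonal. The first two diagonals
#' (distances 0 and 1) never intersect this square and the first and last
#' \code{window} bins of every chromosome are skipped. Raw scores are
#' normalized by the chromosome mean; a boundary's score is the mean of the
#' normalized scores of the two bins adjacent to its junction.
#'
#' @param m a balanced \code{\link{ContactMatrix}}.
#' @param window square window size in bins (default 10 = 35 kb at 3.5-kb
#'   bins).
#' @return list with \code{raw} and \code{normalized} named lists of
#'   per-chromosome per-bin vectors (NA where skipped).
#' @export
insulationScore <- function(m, window = 10L) {
    stopifnot(contactKind(m) %in% c("balanced", "frequency"))
    g <- contactGenome(m)
    raw <- list(); norm <- list()
    for (cn in chromNames(g)) {
        mat <- cisBlock(m, cn)
        nb <- nrow(mat)
        sc <- rep(NA_real_, nb)
        if (nb < 2 * window + 1) {
            warning(sprintf("%s shorter than 2*window+1 bins; no insulation scores",
                            cn))
            raw[[cn]] <- sc; norm[[cn]] <- sc
            next
        }
        for (i in (window + 1):(nb - window))
            sc[i] <- mean(mat[(i - window):(i - 1), (i + 1):(i + window)])
        raw[[cn]] <- sc
        mu <- mean(sc, na.rm = TRUE)
        norm[[cn]] <- if (is.finite(mu) && mu > 0) sc / mu else sc * NA_real_
    }
    list(raw = raw, normalized = norm, window = window)
}

#' Per-boundary insulation scores
#'
#' Assigns each boundary (junction between end bin e and e+1) the mean of
#' the normalized insulation scores of bins e and e+1.
#'
#' @param b a \code{\link{BoundarySet}}.
#' @param ins an insulation result from \code{\link{insulationScore}}
#'   computed on the matching matrix.
#' @return The \code{BoundarySet} with its \code{insulation} slot filled
#'   (parallel to \code{boundaryBins(b)}).
#' @export
boundaryInsulation <- function(b, ins) {
    g <- b@genome
    off <- chromOffsets(g)
    nbv <- chromNBins(g)
    ends <- boundaryBins(b)
    chrom <- binChrom(g)[ends + 1L]
    score <- vapply(seq_along(ends), function(k) {
        cn <- chrom[k]
        loc <- ends[k] - off[[cn]] + 1L     # 1-based local index of end bin
        v <- ins$normalized[[cn]]
        nxt <- if (loc + 1L <= nbv[[cn]]) v[loc + 1L] else NA_real_
        mean(c(v[loc], nxt), na.rm = TRUE)
    }, numeric(1))
    b@insulation <- score
    b
}
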