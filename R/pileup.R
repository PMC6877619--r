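#' Aggregate pairwise contact pile-up around anchor pairs
#'
#' For every ordered anchor pair (i, j) on one chromosome passing the
#' non-overlap filters 1+n <= i <= D-n and i+2n < j <= D-n (D the
#' chromosome dimension in bins), a (2n+1) x (2n+1) window of the contact
#' matrix centred on (i, j) is divided by the mean of the slightly larger
#' (2(n+1)+1) x (2(n+1)+1) local-background window, log2-transformed, and
#' the windows are averaged over all retained pairs. Non-finite values are
#' set to 0 both before normalization and after the log transform.
#'
#' @param m a balanced \code{\link{ContactMatrix}}.
#' @param anchors integer vector of global bin_ids (e.g. top-scoring loci
#'   or binding-site bins).
#' @param n window half-width in bins (default 20, i.e. +-70 kb at 3.5-kb
#'   bins).
#' @param bgExtra background half-width extension (default 1, the
#'   literal n+1 background).
#' @return list with \code{profile} ((2n+1) x (2n+1) mean log2 matrix),
#'   \code{nPairs}, \code{nFiltered}.
#' @export
aggregatePairwiseProfile <- function(m, anchors, n = 20L, bgExtra = 1L) {
    g <- contactGenome(m)
    off <- chromOffsets(g)
    nbv <- chromNBins(g)
    chrom <- binChrom(g)[anchors + 1L]
    acc <- matrix(0, 2 * n + 1, 2 * n + 1)
    nPairs <- 0L
    nFiltered <- 0L
    nb2 <- n + bgExtra
    for (cn in unique(chrom)) {
        a <- sort(anchors[chrom == cn]) - off[[cn]] + 1L   # local 1-based
        D <- nbv[[cn]]
        if (length(a) < 2) next
        mat <- NULL
        cmb <- utils::combn(a, 2)
        for (k in seq_len(ncol(cmb))) {
            i <- cmb[1, k]; j <- cmb[2, k]
            ok <- i >= 1 + n && i <= D - n && j > i + 2 * n && j <= D - n &&
                  i - nb2 >= 1 && j + nb2 <= D
            if (!ok) { nFiltered <- nFiltered + 1L; next }
            if (is.null(mat)) mat <- cisBlock(m, cn)
            win <- mat[(i - n):(i + n), (j - n):(j + n)]
            bg <- mat[(i - nb2):(i + nb2), (j - nb2):(j + nb2)]
            win[!is.finite(win)] <- 0
            bg[!is.finite(bg)] <- 0
            mu <- mean(bg)
            if (mu <= 0) { nFiltered <- nFiltered + 1L; next }
            lg <- log2(win / mu)
            lg[!is.finite(lg)] <- 0
            acc <- acc + lg
            nPairs <- nPairs + 1L
        }
    }
    if (nPairs == 0)
        stop(sprintf("no anchor pair survives the filters (%d filtered out)",
                     nFiltered))
    list(profile = acc / nPairs, nPairs = nPairs, nFiltered = nFiltered)
}
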