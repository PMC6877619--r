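#' Select top-scoring interactions per diagonal
#'
#' Non-parametric selection: within each cis diagonal of a chromosome
#' (distances >= 2 bins), cells whose balanced value is strictly greater
#' than the diagonal's \code{pct}-th percentile are selected. The percentile
#' is computed over the full diagonal, counting absent sparse cells as 0,
#' with the linear-interpolation quantile convention. Strict inequality
#' means a constant diagonal selects nothing.
#'
#' @param m a balanced \code{\link{ContactMatrix}}.
#' @param pct percentile threshold in (0, 100); default 95 (top 5%).
#' @param maxDist optional maximum interaction distance in bp.
#' @return data.frame with columns \code{chrom}, \code{bin1}, \code{bin2}
#'   (global bin_ids, bin1 < bin2), \code{value}.
#' @export
selectTopInteractions <- function(m, pct = 95, maxDist = NULL) {
    stopifnot(contactKind(m) %in% c("balanced", "frequency"))
    if (pct <= 0 || pct >= 100) stop("pct must lie in (0, 100)")
    g <- contactGenome(m)
    nb <- chromNBins(g)
    chrom <- binChrom(g)
    e <- contactEntries(m)
    same <- chrom[e$bin1 + 1L] == chrom[e$bin2 + 1L]
    e <- e[same, , drop = FALSE]
    d <- e$bin2 - e$bin1
    maxD <- if (is.null(maxDist)) Inf else floor(maxDist / binSize(g))
    keep <- d >= 2L & d <= maxD
    e <- e[keep, , drop = FALSE]
    d <- d[keep]
    ch <- chrom[e$bin1 + 1L]
    out <- list()
    for (cn in chromNames(g)) {
        sel <- ch == cn
        ee <- e[sel, , drop = FALSE]
        dd <- d[sel]
        picked <- logical(nrow(ee))
        for (k in unique(dd)) {
            at <- dd == k
            vals <- ee$value[at]
            len <- nb[[cn]] - k
            thr <- quantile(c(vals, numeric(max(len - length(vals), 0))),
                            pct / 100, names = FALSE, type = 7)
            picked[at] <- vals > thr
        }
        if (any(picked))
            out[[cn]] <- data.frame(chrom = cn,
                                    bin1 = ee$bin1[picked],
                                    bin2 = ee$bin2[picked],
                                    value = ee$value[picked])
    }
    res <- if (length(out)) do.call(rbind, out)
           else data.frame(chrom = character(), bin1 = integer(),
                           bin2 = integer(), value = numeric())
    rownames(res) <- NULL
    attr(res, "binSize") <- binSize(g)
    res
}

#' Cluster top-scoring interactions by Euclidean proximity
#'
#' Single-linkage connected components in contact-map coordinate space:
#' two points are linked when
#' D = sqrt((i_x - j_x)^2 + (i_y - j_y)^2) * binSize <= linkDist.
#' With the defaults (25-kb bins, 25-kb link distance) this links only
#' immediate neighbours.
#'
#' @param points data.frame from \code{\link{selectTopInteractions}}.
#' @param linkDist linkage distance in bp (default 25000).
#' @param binSize bin size in bp; taken from the points attribute when NULL.
#' @return The input with a \code{cluster} column (ids unique within
#'   chromosome) and a \code{clusterSize} column.
#' @export
clusterInteractions <- function(points, linkDist = 25000, binSize = NULL) {
    if (is.null(binSize)) binSize <- attr(points, "binSize")
    if (is.null(binSize)) stop("binSize not given and absent from points")
    points$cluster <- NA_integer_
    points$clusterSize <- NA_integer_
    if (!nrow(points)) return(points)
    maxBins <- linkDist / binSize
    for (cn in unique(points$chrom)) {
        idx <- which(points$chrom == cn)
        x <- points$bin1[idx]; y <- points$bin2[idx]
        npt <- length(idx)
        # candidate pairs within maxBins on both axes, then Euclidean gate
        ord <- order(x, y)
        pairs <- list()
        for (a in seq_len(npt - 1)) {
            ia <- ord[a]
            b <- a + 1L
            while (b <= npt && x[ord[b]] - x[ia] <= maxBins) {
                ib <- ord[b]
                if (abs(y[ib] - y[ia]) <= maxBins &&
                    sqrt((x[ib] - x[ia])^2 + (y[ib] - y[ia])^2) <= maxBins)
                    pairs[[length(pairs) + 1L]] <- c(ia, ib)
                b <- b + 1L
            }
        }
        gr <- igraph::make_empty_graph(npt, directed = FALSE)
        if (length(pairs))
            gr <- igraph::add_edges(gr, unlist(pairs))
        comp <- igraph::components(gr)
        points$cluster[idx] <- comp$membership
        points$clusterSize[idx] <- comp$csize[comp$membership]
    }
    points
}

#' Fraction of clustered top-scoring interactions
#'
#' A point is clustered when its cluster has size >= 2.
#'
#' @param points clustered points from \code{\link{clusterInteractions}}.
#' @return Named numeric vector: per-chromosome clustered fraction.
#' @export
clusteredFraction <- function(points) {
    if (!nrow(points)) stop("empty point set")
    vapply(split(points, points$chrom),
           function(p) mean(p$clusterSize >= 2), numeric(1))
}

#' Difference in clustered fractions between two samples
#'
#' @param a,b clustered point sets (e.g. female and male) produced with
#'   identical selection and clustering parameters.
#' @return Named numeric vector, fraction(a) - fraction(b) per chromosome
#'   common to both.
#' @export
clusteredFractionDifference <- function(a, b) {
    fa <- clusteredFraction(a)
    fb <- clusteredFraction(b)
    common <- intersect(names(fa), names(fb))
    fa[common] - fb[common]
}
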