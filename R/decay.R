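#' Interaction-frequency decay curve
#'
#' For each chromosome, computes the median signal at every cis distance in
#' \code{[minDist, maxDist]} bins. The median runs over the full diagonal:
#' bin pairs absent from the sparse store count as 0, extending the
#' convention that non-finite normalized values are set to 0.
#'
#' @param m a balanced or frequency \code{\link{ContactMatrix}}.
#' @param minDist,maxDist distance range in bins (defaults 2 and 100).
#' @return data.frame with columns \code{chrom}, \code{dist} (bins),
#'   \code{distBp}, \code{median}, \code{scale}.
#' @export
decayCurve <- function(m, minDist = 2L, maxDist = 100L) {
    stopifnot(contactKind(m) %in% c("balanced", "frequency"))
    g <- contactGenome(m)
    nb <- chromNBins(g)
    bs <- binSize(g)
    chrom <- binChrom(g)
    e <- contactEntries(m)
    same <- chrom[e$bin1 + 1L] == chrom[e$bin2 + 1L]
    e <- e[same, , drop = FALSE]
    ch <- chrom[e$bin1 + 1L]
    d <- e$bin2 - e$bin1
    out <- list()
    for (cn in chromNames(g)) {
        hi <- maxDist
        if (nb[[cn]] < maxDist + 1L) {
            hi <- nb[[cn]] - 1L
            warning(sprintf("%s shorter than maxDist + 1 bins; range truncated at %d",
                            cn, hi))
        }
        dd <- seq.int(minDist, max(hi, minDist))
        med <- vapply(dd, function(k) {
            .diagMedian(e$value[ch == cn & d == k], nb[[cn]] - k)
        }, numeric(1))
        med[!is.finite(med)] <- 0
        out[[cn]] <- data.frame(chrom = cn, dist = dd, distBp = dd * bs,
                                median = med)
    }
    res <- do.call(rbind, out)
    res$scale <- if (contactKind(m) == "frequency") "frequency" else "signal"
    rownames(res) <- NULL
    res
}

#' Fit the log-log decay slope
#'
#' Ordinary least squares of log10(median) on log10(distance in bp) over the
#' near-linear fit range (2 to 15 bins by default). Zero medians are dropped
#' from the fit with a warning.
#'
#' @param curve a decay curve (one chromosome) from \code{\link{decayCurve}}.
#' @param fitMin,fitMax fit range in bins (defaults 2 and 15).
#' @return data.frame with \code{chrom}, \code{slope}, \code{intercept},
#'   \code{fitMinBp}, \code{fitMaxBp}, \code{nPoints}.
#' @export
fitDecaySlope <- function(curve, fitMin = 2L, fitMax = 15L) {
    stopifnot(length(unique(curve$chrom)) == 1)
    sel <- curve[curve$dist >= fitMin & curve$dist <= fitMax, , drop = FALSE]
    zero <- sel$median <= 0
    if (any(zero)) {
        warning(sprintf("%s: %d zero medians dropped from the slope fit",
                        sel$chrom[1], sum(zero)))
        sel <- sel[!zero, , drop = FALSE]
    }
    if (nrow(sel) < 3)
        stop(sprintf("fewer than 3 usable points in the fit range on %s",
                     curve$chrom[1]))
    fit <- lm(log10(median) ~ log10(distBp), data = sel)
    data.frame(chrom = sel$chrom[1], slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               fitMinBp = min(sel$distBp), fitMaxBp = max(sel$distBp),
               nPoints = nrow(sel))
}

#' Decay slopes for every chromosome of a matrix
#'
#' @param m a balanced or frequency \code{\link{ContactMatrix}}.
#' @param minDist,maxDist distance range in bins for the curve.
#' @param fitMin,fitMax fit range in bins.
#' @return data.frame of per-chromosome slope fits.
#' @export
decaySlopes <- function(m, minDist = 2L, maxDist = 100L, fitMin = 2L,
                        fitMax = 15L) {
    curves <- decayCurve(m, minDist, maxDist)
    do.call(rbind, lapply(split(curves, curves$chrom)[unique(curves$chrom)],
        fitDecaySlope, fitMin = fitMin, fitMax = fitMax))
}

#' Pairwise slope deltas
#'
#' Antisymmetric table of slope differences between chromosomes,
#' delta(a, b) = slope_a - slope_b.
#'
#' @param fits data.frame with columns \code{chrom} and \code{slope}.
#' @return Square numeric matrix with chromosome dimnames.
#' @export
slopeDeltas <- function(fits) {
    if (anyDuplicated(fits$chrom)) stop("duplicate chromosome names")
    if (nrow(fits) < 2) stop("need at least 2 chromosomes")
    s <- setNames(fits$slope, fits$chrom)
    outer(s, s, "-")
}

#' Decay CDF over the distance grid
#'
#' Cumulative sum of the median contact frequencies, divided by its maximum
#' so the last value is exactly 1.
#'
#' @param curve a frequency-scale decay curve (one chromosome).
#' @return data.frame with \code{chrom}, \code{dist}, \code{distBp},
#'   \code{cdf}.
#' @export
decayCdf <- function(curve) {
    stopifnot(length(unique(curve$chrom)) == 1)
    if (!all(curve$scale == "frequency"))
        stopifnot(all(curve$median >= 0))
    cs <- cumsum(curve$median)
    if (cs[length(cs)] <= 0) stop("all-zero decay curve; CDF undefined")
    data.frame(chrom = curve$chrom[1], dist = curve$dist,
               distBp = curve$distBp, cdf = cs / cs[length(cs)])
}

#' Kuiper statistic between two decay CDFs
#'
#' V = max(cdf_a - cdf_b) + max(cdf_b - cdf_a), each maximum floored at 0
#' so one-sided dominance yields the single largest gap.
#'
#' @param a,b CDFs from \code{\link{decayCdf}} on identical distance grids.
#' @return The Kuiper statistic (a number in [0, 2]).
#' @export
kuiperStatistic <- function(a, b) {
    if (!identical(a$dist, b$dist)) stop("CDF distance grids differ")
    diff <- a$cdf - b$cdf
    max(c(diff, 0)) + max(c(-diff, 0))
}

#' Compare chrX slope deltas against autosome-pair deltas
#'
#' Two-sample Wilcoxon rank-sum test of the chrX-vs-autosome slope deltas
#' against the deltas between unordered autosome pairs.
#'
#' @param deltas square delta matrix from \code{\link{slopeDeltas}}.
#' @param chrxName name of the X chromosome row.
#' @return list with \code{statistic}, \code{p.value}, \code{xDeltas},
#'   \code{autoDeltas}.
#' @export
compareXvsAutosomes <- function(deltas, chrxName) {
    cn <- rownames(deltas)
    if (!chrxName %in% cn) stop("chrX row not found in delta table")
    autos <- setdiff(cn, chrxName)
    if (length(autos) < 2) stop("need at least 2 autosomes")
    xd <- deltas[chrxName, autos]
    pairs <- utils::combn(autos, 2)
    ad <- deltas[cbind(pairs[1, ], pairs[2, ])]
    if (length(xd) < 2 || length(ad) < 2)
        stop(sprintf("too few deltas (chrX: %d, autosomes: %d)",
                     length(xd), length(ad)))
    useExact <- length(xd) < 50 && length(ad) < 50 &&
        !anyDuplicated(c(xd, ad))
    wt <- wilcox.test(xd, ad, exact = useExact)
    list(statistic = unname(wt$statistic), p.value = wt$p.value,
         xDeltas = xd, autoDeltas = setNames(ad, apply(pairs, 2, paste,
                                                       collapse = "-")))
}
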