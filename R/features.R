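#' Flanking windows around boundaries, split at shared territory
#'
#' Each boundary (junction after end bin e) gets a window of up to
#' \code{half} bins on both sides (bins e-half+1 .. e+half). When the
#' windows of two neighbouring boundaries would overlap, the intervening
#' bins are assigned equally to both (the downstream boundary takes the
#' extra bin when their number is odd, so even directly adjacent
#' boundaries keep their own end bin), and windows of one set are always
#' disjoint. Windows are clipped at chromosome ends.
#'
#' @param b a \code{\link{BoundarySet}}.
#' @param half window half-width in bins (default 15, i.e. 52.5 kb at
#'   3.5-kb bins).
#' @return data.frame with columns \code{chrom}, \code{end_bin},
#'   \code{lo}, \code{hi} (global bin_id range, inclusive), \code{nBins}.
#' @export
boundaryWindows <- function(b, half = 15L) {
    g <- b@genome
    off <- chromOffsets(g)
    nbv <- chromNBins(g)
    ends <- boundaryBins(b)
    chrom <- binChrom(g)[ends + 1L]
    out <- list()
    for (cn in unique(chrom)) {
        e <- ends[chrom == cn]
        lo <- e - half + 1L
        hi <- e + half
        if (length(e) > 1) {
            gap <- e[-1] - e[-length(e)]           # intervening bin counts
            lshare <- as.integer(floor(gap / 2))   # upstream boundary's share
            hi[-length(e)] <- pmin(hi[-length(e)], e[-length(e)] + lshare)
            lo[-1] <- pmax(lo[-1], e[-length(e)] + lshare + 1L)
        }
        lo <- pmax(lo, off[[cn]])
        hi <- pmin(hi, off[[cn]] + nbv[[cn]] - 1L)
        out[[cn]] <- data.frame(chrom = cn, end_bin = e, lo = lo, hi = hi,
                                nBins = hi - lo + 1L)
    }
    res <- if (length(out)) do.call(rbind, out)
           else data.frame(chrom = character(), end_bin = integer(),
                           lo = integer(), hi = integer(), nBins = integer())
    rownames(res) <- NULL
    res
}

#' Point-feature enrichment in boundary windows vs a uniform null
#'
#' The expected site density is N_m / L: total sites divided by chromosome
#' length in bins, assuming uniform placement. The observed density is the
#' number of site midpoints falling into the windows divided by the total
#' window length in bins. Returns log2(observed / expected).
#'
#' @param windows a window set from \code{\link{boundaryWindows}}.
#' @param features data.frame (\code{chrom}, \code{mid}) of site midpoints.
#' @param g a \code{\link{GenomeModel}}.
#' @return list with \code{log2ratio}, \code{observedDensity},
#'   \code{expectedDensity}, \code{nInWindows}, \code{windowBins}.
#' @export
featureEnrichment <- function(windows, features, g) {
    if (!nrow(windows) || sum(windows$nBins) == 0)
        stop("window set has zero total length")
    chroms <- unique(windows$chrom)
    f <- features[features$chrom %in% chroms, , drop = FALSE]
    N <- nrow(f)
    L <- sum(chromNBins(g)[chroms])
    expected <- N / L
    if (N) {
        bins <- binOfPosition(g, f$chrom, f$mid)
        inWin <- vapply(bins, function(bb)
            any(bb >= windows$lo & bb <= windows$hi), logical(1))
        nIn <- sum(inWin)
    } else nIn <- 0L
    W <- sum(windows$nBins)
    observed <- nIn / W
    list(log2ratio = log2(observed / expected),
         observedDensity = observed, expectedDensity = expected,
         nInWindows = nIn, windowBins = W)
}

#' Permutation null for feature enrichment
#'
#' Re-places the same number of sites uniformly over the window set's
#' chromosomes \code{nPerm} times and recomputes the enrichment, giving an
#' empirical null distribution of log2 ratios.
#'
#' @param windows a window set from \code{\link{boundaryWindows}}.
#' @param nSites number of sites per shuffle.
#' @param g a \code{\link{GenomeModel}}.
#' @param nPerm number of shuffles (default 200).
#' @param seed integer seed.
#' @return Numeric vector of \code{nPerm} log2 ratios (may contain -Inf
#'   when a shuffle hits no window).
#' @export
featureEnrichmentPermutation <- function(windows, nSites, g, nPerm = 200L,
                                         seed = 1L) {
    set.seed(seed)
    chroms <- unique(windows$chrom)
    lens <- chromLengths(g)[chroms]
    vapply(seq_len(nPerm), function(k) {
        ch <- sample(chroms, nSites, replace = TRUE, prob = lens / sum(lens))
        sites <- data.frame(chrom = ch, mid = floor(runif(nSites, 0, lens[ch])))
        featureEnrichment(windows, sites, g)$log2ratio
    }, numeric(1))
}

#' Scale a signal track by its 99th percentile
#'
#' @param track data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{value}).
#' @return The track with \code{value} divided by its 99th percentile.
#' @export
scaleSignal99 <- function(track) {
    q <- quantile(track$value, 0.99, names = FALSE, type = 7)
    if (!is.finite(q) || q <= 0) stop("99th percentile not positive")
    track$value <- track$value / q
    track
}

#' Insulator summit per boundary region
#'
#' The summit is the maximum signal of the track within each boundary
#' region (one-bin-wide window centred on the junction); NA when no signal
#' interval overlaps the region.
#'
#' @param b a \code{\link{BoundarySet}} with regions built
#'   (\code{\link{makeBoundaryRegions}}).
#' @param track signal data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{value}), typically 99th-percentile-scaled.
#' @return Numeric vector parallel to \code{boundaryBins(b)}.
#' @export
boundarySummits <- function(b, track) {
    if (!nrow(b@regions)) stop("boundary regions not built; run makeBoundaryRegions")
    reg <- GenomicRanges::GRanges(b@regions$chrom,
        IRanges::IRanges(b@regions$start + 1, b@regions$end))
    sig <- GenomicRanges::GRanges(track$chrom,
        IRanges::IRanges(track$start + 1, track$end))
    hits <- GenomicRanges::findOverlaps(reg, sig)
    out <- rep(NA_real_, length(reg))
    if (length(hits)) {
        mx <- tapply(track$value[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits), max)
        out[as.integer(names(mx))] <- as.numeric(mx)
    }
    out
}

#' Classify boundaries by combinatorial insulator presence
#'
#' Using 99th-percentile-scaled summits and a high/low cutoff (default 0.5,
#' the midpoint between the modes of the bimodal summit distributions):
#' class "BEAF+ and CP/CH+" has high BEAF-32 and high CP190 or Chromator;
#' "BEAF+ or CP/CH+" has exactly one of the two conditions (including
#' BEAF-32 low with both CP190 and Chromator high); "BEAF- and CP/CH-" has
#' all low. When male and female tracks are both given, each boundary uses
#' the maximum of the two summits.
#'
#' @param b a \code{\link{BoundarySet}} with regions built.
#' @param beaf,cp190,chromator scaled signal tracks, or lists of two tracks
#'   (e.g. \code{list(male, female)}) combined by per-boundary maximum.
#' @param cutoff scaled-signal threshold between high and low (default
#'   0.5).
#' @return data.frame with per-boundary summits and the \code{class}
#'   column.
#' @export
classifyInsulatorBoundaries <- function(b, beaf, cp190, chromator,
                                        cutoff = 0.5) {
    tracks <- list(beaf = beaf, cp190 = cp190, chromator = chromator)
    for (nm in names(tracks))
        if (is.null(tracks[[nm]])) stop("missing insulator track: ", nm)
    summit <- lapply(tracks, function(tr) {
        if (is.data.frame(tr)) return(boundarySummits(b, tr))
        do.call(pmax, c(lapply(tr, function(x) boundarySummits(b, x)),
                        list(na.rm = TRUE)))
    })
    hb <- !is.na(summit$beaf) & summit$beaf >= cutoff
    hc <- (!is.na(summit$cp190) & summit$cp190 >= cutoff) |
          (!is.na(summit$chromator) & summit$chromator >= cutoff)
    class <- ifelse(hb & hc, "BEAF+ and CP/CH+",
             ifelse(hb | hc, "BEAF+ or CP/CH+", "BEAF- and CP/CH-"))
    data.frame(bin = boundaryBins(b), chrom = b@regions$chrom,
               beaf = summit$beaf, cp190 = summit$cp190,
               chromator = summit$chromator, class = class)
}
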