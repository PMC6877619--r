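#' Directionality index (DI) track
#'
#' Per-bin contrast of upstream vs downstream contact sums over a
#' \code{windowN}-bin window (Dixon-style). With A the summed signal from
#' the bin to its \code{windowN} upstream bins, B the downstream sum and
#' E = (A + B) / 2:
#' DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E),
#' 0 when A = B, and NA when E = 0 or the window exits the chromosome.
#'
#' @param m a balanced \code{\link{ContactMatrix}} (cis blocks are used).
#' @param windowN window size in bins (default 10, i.e. 35 kb at 3.5-kb
#'   bins).
#' @return Named list per chromosome of numeric DI vectors (one value per
#'   bin, NA where undefined).
#' @export
directionalityIndex <- function(m, windowN = 10L) {
    if (windowN < 1) stop("windowN must be >= 1")
    stopifnot(contactKind(m) %in% c("balanced", "frequency"))
    g <- contactGenome(m)
    out <- list()
    for (cn in chromNames(g)) {
        mat <- cisBlock(m, cn)
        nb <- nrow(mat)
        di <- rep(NA_real_, nb)
        for (i in seq_len(nb)) {
            if (i - windowN < 1 || i + windowN > nb) next
            A <- sum(mat[i, (i - windowN):(i - 1)])
            B <- sum(mat[i, (i + 1):(i + windowN)])
            E <- (A + B) / 2
            if (E == 0) next
            di[i] <- if (A == B) 0 else
                sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
        }
        out[[cn]] <- di
    }
    attr(out, "windowN") <- windowN
    out
}

#' Forward and backward first differences of a DI track
#'
#' forward_i = DI_i - DI_{i+1}; backward_i = DI_i - DI_{i-1}. Defined only
#' where both DIs are finite.
#'
#' @param di a DI track from \code{\link{directionalityIndex}} (one
#'   chromosome's numeric vector).
#' @return list with \code{forward} and \code{backward} numeric vectors.
#' @export
deltaDI <- function(di) {
    n <- length(di)
    fw <- c(di[-n] - di[-1], NA_real_)
    bw <- c(NA_real_, di[-1] - di[-n])
    list(forward = fw, backward = bw)
}

# Tukey fences of x within a +-localM window around position i
.localFences <- function(x, i, localM) {
    lo <- max(1L, i - localM); hi <- min(length(x), i + localM)
    w <- x[lo:hi]
    w <- w[is.finite(w)]
    if (length(w) < 2) return(c(lower = NA_real_, upper = NA_real_))
    q <- quantile(w, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
}

#' Call structural-domain boundaries with the Local Score Differentiator
#'
#' Domain starts and ends are local outliers of the first differences of
#' the directionality index, detected with Tukey fences computed in a
#' sliding window of \code{localM} bins up- and downstream:
#' Fence_forward = Q25(dDI_fw) - 1.5 IQR, Fence_backward = Q75(dDI_bw) +
#' 1.5 IQR. A domain start requires finite DI, dDI_forward <= Fence_forward
#' and dDI_forward <= DI; a domain end requires finite DI, dDI_backward >=
#' Fence_backward and dDI_backward >= DI. On top of the fence rule a call
#' must have strictly negative dDI_forward (starts) or strictly positive
#' dDI_backward (ends), so perfectly flat tracks - where the fences
#' degenerate to the quartiles - never emit boundaries. \code{strict}
#' additionally requires DI <= 0 at starts and DI >= 0 at ends;
#' \code{fillGaps} closes gaps between consecutive domains by extending
#' each domain end to the bin before the next start. Both default FALSE.
#'
#' @param m a balanced \code{\link{ContactMatrix}}.
#' @param windowN DI window in bins (default 10).
#' @param localM fence window half-width in bins (default 25); truncated at
#'   chromosome ends.
#' @param strict require DI sign agreement (default FALSE).
#' @param fillGaps connect consecutive domains (default FALSE).
#' @return A \code{\link{BoundarySet}}.
#' @export
callDomains <- function(m, windowN = 10L, localM = 25L, strict = FALSE,
                        fillGaps = FALSE) {
    g <- contactGenome(m)
    di <- directionalityIndex(m, windowN)
    off <- chromOffsets(g)
    starts <- integer(); ends <- integer()
    for (cn in chromNames(g)) {
        dv <- di[[cn]]
        dd <- deltaDI(dv)
        nb <- length(dv)
        isStart <- logical(nb); isEnd <- logical(nb)
        for (i in seq_len(nb)) {
            if (!is.finite(dv[i])) next
            if (is.finite(dd$forward[i]) && dd$forward[i] < 0) {
                fen <- .localFences(dd$forward, i, localM)
                if (is.finite(fen["lower"]) &&
                    dd$forward[i] <= fen["lower"] &&
                    dd$forward[i] <= dv[i] &&
                    (!strict || dv[i] <= 0))
                    isStart[i] <- TRUE
            }
            if (is.finite(dd$backward[i]) && dd$backward[i] > 0) {
                fen <- .localFences(dd$backward, i, localM)
                if (is.finite(fen["upper"]) &&
                    dd$backward[i] >= fen["upper"] &&
                    dd$backward[i] >= dv[i] &&
                    (!strict || dv[i] >= 0))
                    isEnd[i] <- TRUE
            }
        }
        sIdx <- which(isStart); eIdx <- which(isEnd)
        if (fillGaps && length(sIdx) && length(eIdx)) {
            # extend each domain end to meet the next domain start
            for (k in seq_along(eIdx)) {
                nxt <- sIdx[sIdx > eIdx[k]]
                if (length(nxt) && nxt[1] > eIdx[k] + 1L)
                    eIdx[k] <- nxt[1] - 1L
            }
            eIdx <- sort(unique(eIdx))
        }
        starts <- c(starts, off[[cn]] + sIdx - 1L)
        ends <- c(ends, off[[cn]] + eIdx - 1L)
    }
    new("BoundarySet", genome = g, starts = sort(starts), ends = sort(ends),
        regions = data.frame(chrom = character(), start = numeric(),
                             end = numeric(), end_bin = integer()),
        insulation = numeric(), boundaryClass = character())
}

#' @rdname callDomains
#' @param b a \code{BoundarySet}.
#' @export
domainStarts <- function(b) b@starts

#' @rdname callDomains
#' @export
domainEnds <- function(b) b@ends

#' Build one-bin-wide boundary regions from domain ends
#'
#' Each unique domain-end bin e defines a boundary at the junction between
#' e and e + 1; the region is the junction coordinate extended by half a
#' bin on each side, i.e. a bin-size-wide interval spanning the adjacent
#' halves of the end and start bins. Regions at the final chromosome bin
#' are clipped to the chromosome end and flagged.
#'
#' @param b a \code{\link{BoundarySet}}.
#' @return The \code{BoundarySet} with its \code{regions} slot filled
#'   (columns \code{chrom}, \code{start}, \code{end}, \code{end_bin},
#'   \code{clipped}).
#' @export
makeBoundaryRegions <- function(b) {
    g <- b@genome
    bs <- binSize(g)
    bt <- binTable(g)
    ends <- sort(unique(b@ends))
    if (!length(ends)) {
        b@regions <- data.frame(chrom = character(), start = numeric(),
                                end = numeric(), end_bin = integer(),
                                clipped = logical())
        return(b)
    }
    chrom <- bt$chrom[ends + 1L]
    lens <- chromLengths(g)[chrom]
    junction <- bt$end[ends + 1L]       # coordinate between bin e and e+1
    start <- pmax(junction - bs / 2, 0)
    end <- pmin(junction + bs / 2, lens)
    clipped <- end - start < bs
    b@regions <- data.frame(chrom = chrom, start = start, end = end,
                            end_bin = ends, clipped = clipped)
    rownames(b@regions) <- NULL
    b
}

#' Boundary junction bins of a BoundarySet
#'
#' The identity of a boundary for comparisons: the bin index of its domain
#' end (the junction lies between this bin and the next).
#'
#' @param b a \code{\link{BoundarySet}}.
#' @return Sorted unique integer vector of global bin_ids.
#' @export
boundaryBins <- function(b) sort(unique(b@ends))

#' Compare two boundary sets by exact bin match
#'
#' Boundaries present in both sets (identical junction bin) are "same";
#' present only in the second (male) set, "appearing"; only in the first
#' (female) set, "disappearing". The classes partition the union.
#'
#' @param female,male \code{\link{BoundarySet}}s called on identically
#'   binned matrices.
#' @return list with \code{classes} (data.frame \code{bin}, \code{chrom},
#'   \code{class}), \code{nonMatchingFraction} = 1 - |same| / |union|, and
#'   the three bin vectors.
#' @export
compareBoundarySets <- function(female, male) {
    if (binSize(female@genome) != binSize(male@genome))
        stop("bin-size mismatch between boundary sets")
    f <- boundaryBins(female); mb <- boundaryBins(male)
    same <- intersect(f, mb)
    disappearing <- setdiff(f, mb)
    appearing <- setdiff(mb, f)
    un <- sort(union(f, mb))
    cls <- data.frame(bin = un,
                      chrom = binChrom(female@genome)[un + 1L],
                      class = ifelse(un %in% same, "same",
                              ifelse(un %in% appearing, "appearing",
                                     "disappearing")))
    list(classes = cls,
         nonMatchingFraction = if (length(un)) 1 - length(same) / length(un)
                               else 0,
         same = same, appearing = appearing, disappearing = disappearing)
}
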