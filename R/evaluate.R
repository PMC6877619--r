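#' Boundary-recovery metrics against simulation ground truth
#'
#' Matches called boundary junctions to the ground-truth junctions of a
#' \code{\link{SimTruth}} within a bin tolerance and reports the true
#' positive rate and false discovery rate. A called end bin e corresponds
#' to the junction before local bin e + 1; a true boundary is recorded as
#' the local index of the first bin of its downstream TAD.
#'
#' @param called a \code{\link{BoundarySet}}.
#' @param truth a \code{\link{SimTruth}}.
#' @param tolBins matching tolerance in bins (default 1).
#' @return list with \code{tpr}, \code{fdr}, \code{nTrue}, \code{nCalled},
#'   \code{nMatchedTrue}.
#' @export
boundaryRecovery <- function(called, truth, tolBins = 1L) {
    g <- called@genome
    off <- chromOffsets(g)
    chrom <- binChrom(g)
    ends <- boundaryBins(called)
    nTrue <- 0L; nMatchedTrue <- 0L; nCalled <- length(ends)
    nMatchedCalled <- 0L
    for (cn in chromNames(g)) {
        tj <- truth@boundaries[[cn]]
        cj <- ends[chrom[ends + 1L] == cn] - off[[cn]] + 1L  # called junctions
        nTrue <- nTrue + length(tj)
        if (length(tj) && length(cj)) {
            nMatchedTrue <- nMatchedTrue +
                sum(vapply(tj, function(t) any(abs(cj - t) <= tolBins),
                           logical(1)))
            nMatchedCalled <- nMatchedCalled +
                sum(vapply(cj, function(cc) any(abs(tj - cc) <= tolBins),
                           logical(1)))
        }
    }
    list(tpr = if (nTrue) nMatchedTrue / nTrue else NA_real_,
         fdr = if (nCalled) 1 - nMatchedCalled / nCalled else NA_real_,
         nTrue = nTrue, nCalled = nCalled, nMatchedTrue = nMatchedTrue)
}
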