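#' @import methods
#' @importFrom stats median quantile rbinom rpois runif wilcox.test setNames
#'   aggregate lm coef
#' @importFrom utils read.table write.table head tail
NULL

#' GenomeModel: binned genome with chromosome lengths and copy numbers
#'
#' Describes the genome underlying a binned contact matrix: an ordered set of
#' chromosomes (or chromosome arms, e.g. 2L/2R/3L/3R/X in \emph{Drosophila}),
#' their lengths in bp, their expected copy numbers (2 for paired autosomes,
#' 1 for the single male X), the bin size, and the derived global bin table.
#'
#' Bin intervals are 0-based half-open and tile each chromosome; the last bin
#' of a chromosome may be shorter than \code{binSize}. \code{bin_id} is dense
#' and global (0-based), ordered by chromosome then position.
#'
#' @slot chroms data.frame with columns \code{name}, \code{length} (bp),
#'   \code{copyNumber} (integer >= 1).
#' @slot binSize integer, bin width in bp.
#' @slot bins data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{bin_id}.
#' @exportClass GenomeModel
setClass("GenomeModel",
    slots = c(chroms = "data.frame", binSize = "integer", bins = "data.frame"))

setValidity("GenomeModel", function(object) {
    ch <- object@chroms
    if (!all(c("name", "length", "copyNumber") %in% names(ch)))
        return("chroms must have columns name, length, copyNumber")
    if (anyDuplicated(ch$name)) return("duplicate chromosome names")
    if (any(ch$length <= 0)) return("chromosome lengths must be positive")
    if (any(ch$copyNumber < 1)) return("copy numbers must be >= 1")
    if (length(object@binSize) != 1L || object@binSize < 1L)
        return("binSize must be a single positive integer")
    b <- object@bins
    if (!all(c("chrom", "start", "end", "bin_id") %in% names(b)))
        return("bins must have columns chrom, start, end, bin_id")
    if (!identical(b$bin_id, seq_len(nrow(b)) - 1L))
        return("bin_id must be dense and 0-based in row order")
    for (i in seq_len(nrow(ch))) {
        bb <- b[b$chrom == ch$name[i], , drop = FALSE]
        exp_n <- ceiling(ch$length[i] / object@binSize)
        if (nrow(bb) != exp_n)
            return(sprintf("chromosome %s: expected %d bins, found %d",
                           ch$name[i], exp_n, nrow(bb)))
        if (bb$start[1] != 0 || bb$end[nrow(bb)] != ch$length[i] ||
            (nrow(bb) > 1 && !all(bb$start[-1] == bb$end[-nrow(bb)])))
            return(sprintf("bins do not tile chromosome %s", ch$name[i]))
    }
    TRUE
})

#' ContactMatrix: sparse symmetric binned contact map
#'
#' Stores the upper triangle (\code{bin1 <= bin2}) of a genome-wide symmetric
#' contact matrix as triplets, together with its \code{\link{GenomeModel}},
#' the matrix kind, and (after balancing) the per-bin bias vector and the set
#' of masked (low-coverage) bins.
#'
#' @slot genome a \code{GenomeModel}.
#' @slot entries data.frame with columns \code{bin1}, \code{bin2},
#'   \code{value}; \code{bin1 <= bin2}; absent cells are zero.
#' @slot kind one of \code{"raw"}, \code{"balanced"}, \code{"frequency"}.
#' @slot bias numeric per-bin bias (balanced = raw / (bias_i * bias_j));
#'   NA for masked or never-balanced bins; length 0 before balancing.
#' @slot maskedBins integer vector of bin_ids excluded from balancing.
#' @slot metadata list of processing details (convergence metric, spreads).
#' @exportClass ContactMatrix
setClass("ContactMatrix",
    slots = c(genome = "GenomeModel", entries = "data.frame",
              kind = "character", bias = "numeric", maskedBins = "integer",
              metadata = "list"))

setValidity("ContactMatrix", function(object) {
    e <- object@entries
    if (!all(c("bin1", "bin2", "value") %in% names(e)))
        return("entries must have columns bin1, bin2, value")
    if (!object@kind %in% c("raw", "balanced", "frequency"))
        return("kind must be raw, balanced or frequency")
    n <- nBins(object@genome)
    if (nrow(e)) {
        if (any(e$bin1 > e$bin2)) return("entries must satisfy bin1 <= bin2")
        if (min(e$bin1) < 0 || max(e$bin2) >= n)
            return("entries reference bin_ids outside the bin table")
        if (anyDuplicated(e$bin1 * n + e$bin2))
            return("duplicate (bin1, bin2) entries")
        if (object@kind == "raw" &&
            (any(e$value < 0) || any(e$value != round(e$value))))
            return("raw counts must be non-negative integers")
        if (object@kind != "raw" && (any(!is.finite(e$value)) || any(e$value < 0)))
            return("balanced/frequency values must be finite and non-negative")
    }
    if (length(object@bias) && length(object@bias) != n)
        return("bias length must equal the number of bins")
    TRUE
})

#' BoundarySet: called domain boundaries on one binned genome
#'
#' Domain starts and ends are 0-based bin indices (global bin_ids). A
#' boundary is identified by its junction: the gap between a domain-end bin
#' \code{e} and the following bin \code{e + 1}. Boundary regions are
#' one-bin-wide intervals centred on the junction coordinate.
#'
#' @slot genome a \code{GenomeModel}.
#' @slot starts integer vector of domain-start bin_ids.
#' @slot ends integer vector of domain-end bin_ids.
#' @slot regions data.frame (chrom, start, end, end_bin) of boundary regions;
#'   zero rows until \code{makeBoundaryRegions} is called.
#' @slot insulation numeric per-boundary insulation score (parallel to the
#'   unique junctions of \code{regions}); length 0 until computed.
#' @slot boundaryClass character per-boundary class ("same", "appearing",
#'   "disappearing"); length 0 until a comparison assigns it.
#' @exportClass BoundarySet
setClass("BoundarySet",
    slots = c(genome = "GenomeModel", starts = "integer", ends = "integer",
              regions = "data.frame", insulation = "numeric",
              boundaryClass = "character"))

setValidity("BoundarySet", function(object) {
    if (is.unsorted(object@starts) || is.unsorted(object@ends))
        return("starts and ends must be sorted")
    n <- nBins(object@genome)
    idx <- c(object@starts, object@ends)
    if (length(idx) && (min(idx) < 0 || max(idx) >= n))
        return("boundary bins outside the bin table")
    TRUE
})

#' SimSpec: parameters of a synthetic contact-map study
#'
#' Ground-truth description of a simulated Hi-C experiment: power-law
#' distance decay per chromosome, TAD-block structure with per-boundary
#' insulation strengths, per-chromosome cis coverage under copy-number
#' scaling, and a uniform trans-contact fraction.
#'
#' @slot genome a \code{GenomeModel}.
#' @slot decayExponent named numeric, log-log decay slope per chromosome
#'   (negative).
#' @slot tadBoundaries named list; per chromosome a data.frame
#'   (\code{bin}, \code{strength}) giving the junction position (first bin of
#'   the downstream TAD, chromosome-local, 0-based) and insulation strength
#'   in [0, 1].
#' @slot intraTadBoost multiplicative contact enrichment inside TADs (>= 1).
#' @slot coverage named numeric, expected cis read pairs per chromosome for
#'   a two-copy chromosome; a copy-number-c chromosome receives c/2 of it.
#' @slot transFraction proportion of read pairs that are trans.
#' @slot seed integer random seed.
#' @exportClass SimSpec
setClass("SimSpec",
    slots = c(genome = "GenomeModel", decayExponent = "numeric",
              tadBoundaries = "list", intraTadBoost = "numeric",
              coverage = "numeric", transFraction = "numeric",
              seed = "integer"))

setValidity("SimSpec", function(object) {
    cn <- chromNames(object@genome)
    if (!all(cn %in% names(object@decayExponent)))
        return("decayExponent must name every chromosome")
    if (any(object@decayExponent >= 0))
        return("decay exponents must be negative")
    if (!all(cn %in% names(object@coverage)))
        return("coverage must name every chromosome")
    if (object@intraTadBoost < 1) return("intraTadBoost must be >= 1")
    if (object@transFraction < 0 || object@transFraction >= 1)
        return("transFraction must be in [0, 1)")
    nb <- table(factor(object@genome@bins$chrom, levels = cn))
    for (ch in names(object@tadBoundaries)) {
        tb <- object@tadBoundaries[[ch]]
        if (!nrow(tb)) next
        if (any(tb$bin < 1) || any(tb$bin >= nb[[ch]]))
            return(sprintf("boundary position outside chromosome %s", ch))
        if (any(tb$strength < 0) || any(tb$strength > 1))
            return("insulation strengths must lie in [0, 1]")
    }
    TRUE
})

#' SimTruth: realized ground truth of a simulated contact map
#'
#' @slot spec the generating \code{SimSpec}.
#' @slot boundaries named list of integer vectors: per chromosome the
#'   ground-truth boundary junction positions (chromosome-local, 0-based
#'   index of the first bin of the downstream TAD).
#' @slot featureSites data.frame (chrom, mid) of realized feature-site
#'   midpoints; zero rows until \code{simulateFeatureTrack} fills it.
#' @exportClass SimTruth
setClass("SimTruth",
    slots = c(spec = "SimSpec", boundaries = "list",
              featureSites = "data.frame"))
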