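#' Merge and binarize 4C replicate counts per fragment
#'
#' A fragment gets value 1 when any replicate has one or more overlapping
#' reads, 0 otherwise.
#'
#' @param frags data.frame with \code{chrom}, \code{mid} and one or more
#'   replicate count columns.
#' @param countCols names of the replicate count columns (default: all
#'   columns except chrom/mid).
#' @return data.frame (\code{chrom}, \code{mid}, \code{v}).
#' @export
binarizeFourc <- function(frags, countCols = NULL) {
    if (is.null(countCols))
        countCols <- setdiff(names(frags), c("chrom", "mid"))
    v <- as.integer(rowSums(as.matrix(frags[countCols]) > 0) > 0)
    data.frame(chrom = frags$chrom, mid = frags$mid, v = v)
}

#' Replicate / cross-sample depth QC for 4C probes
#'
#' Discards a probe when its two replicates differ by
#' \code{replicateFoldMax}-fold or more in total sequenced reads, and,
#' for a pairwise sample comparison, keeps a probe only when its totals
#' differ by at most \code{sampleFoldMax}-fold across the compared samples.
#'
#' @param manifest data.frame with columns \code{probe}, \code{sample},
#'   \code{replicate}, \code{reads}.
#' @param replicateFoldMax within-sample replicate fold threshold
#'   (default 2).
#' @param sampleFoldMax cross-sample fold threshold (default 1.5).
#' @return Character vector of retained probe names.
#' @export
filterFourcProbes <- function(manifest, replicateFoldMax = 2,
                              sampleFoldMax = 1.5) {
    keep <- character()
    for (pr in unique(manifest$probe)) {
        sub <- manifest[manifest$probe == pr, , drop = FALSE]
        repOk <- all(vapply(split(sub$reads, sub$sample), function(r) {
            length(r) < 2 || max(r) / min(r) < replicateFoldMax
        }, logical(1)))
        tot <- tapply(sub$reads, sub$sample, sum)
        sampOk <- length(tot) < 2 || max(tot) / min(tot) <= sampleFoldMax
        if (repOk && sampOk) keep <- c(keep, pr)
    }
    keep
}

#' 4C fragment enrichment track
#'
#' At each fragment midpoint m, the sum of binarized values in a small
#' window (+- wSmall) is divided by the sum in a large background window
#' (+- wBig) and log10-transformed with a pseudocount of 1:
#' E_m = log10(sum_small / sum_big + 1). Fragments closer than wBig to a
#' chromosome end are excluded; fragments whose background sum is zero get
#' NA and are flagged.
#'
#' @param frags binarized fragments (\code{chrom}, \code{mid}, \code{v}).
#' @param g a \code{\link{GenomeModel}} (for chromosome lengths).
#' @param wSmall small window half-width in bp (default 20000).
#' @param wBig background window half-width in bp (default 600000).
#' @return The fragments with added columns \code{enrichment},
#'   \code{inDomain}, \code{zeroBackground}.
#' @export
fourcEnrichment <- function(frags, g, wSmall = 20000, wBig = 600000) {
    lens <- chromLengths(g)
    frags$enrichment <- NA_real_
    frags$inDomain <- FALSE
    frags$zeroBackground <- FALSE
    for (cn in unique(frags$chrom)) {
        idx <- which(frags$chrom == cn)
        ord <- idx[order(frags$mid[idx])]
        mids <- frags$mid[ord]
        vals <- frags$v[ord]
        cs0 <- c(0, cumsum(vals))
        wsum <- function(m, w) {
            lo <- findInterval(m - w, mids, left.open = TRUE)  # mids < m-w
            hi <- findInterval(m + w, mids)                    # mids <= m+w
            cs0[hi + 1L] - cs0[lo + 1L]
        }
        small <- wsum(mids, wSmall)
        big <- wsum(mids, wBig)
        dom <- mids >= wBig & mids <= lens[[cn]] - wBig
        zero <- dom & big == 0
        en <- ifelse(dom & big > 0, log10(small / big + 1), NA_real_)
        frags$enrichment[ord] <- en
        frags$inDomain[ord] <- dom
        frags$zeroBackground[ord] <- zero
    }
    frags
}

#' Mean 4C enrichment around boundary classes
#'
#' Fragments are mapped to contact-map bins (bin value = mean enrichment
#' over its fragments); bins are re-indexed by their offset from each
#' boundary's junction bin and averaged per offset across all boundaries
#' of a class. The scalar per-class summary is the mean over offsets
#' within +- \code{half} bp.
#'
#' @param frags an enrichment track from \code{\link{fourcEnrichment}}.
#' @param b a \code{\link{BoundarySet}} with regions built.
#' @param classes optional data.frame (\code{bin}, \code{class}) as from
#'   \code{compareBoundarySets(...)$classes}; when NULL all boundaries form
#'   one class "all".
#' @param half metaprofile half-width in bp (default 35000; use 7000 for
#'   the close-range variant).
#' @return list with \code{profile} (data.frame class, offset, meanE, n)
#'   and \code{summary} (named per-class mean over the +-half window).
#' @export
fourcBoundarySummary <- function(frags, b, classes = NULL, half = 35000) {
    g <- b@genome
    bs <- binSize(g)
    halfBins <- as.integer(floor(half / bs))
    ok <- frags$inDomain & !is.na(frags$enrichment)
    fr <- frags[ok, , drop = FALSE]
    if (!nrow(fr)) stop("no usable fragments")
    fbin <- binOfPosition(g, fr$chrom, fr$mid)
    binE <- tapply(fr$enrichment, fbin, mean)
    ends <- boundaryBins(b)
    if (is.null(classes))
        classes <- data.frame(bin = ends, class = "all")
    nbv <- chromNBins(g); off <- chromOffsets(g)
    chrom <- binChrom(g)
    rows <- list()
    for (k in seq_along(ends)) {
        e <- ends[k]
        cls <- classes$class[match(e, classes$bin)]
        if (is.na(cls)) next
        bBin <- e + 1L                       # bin containing the junction
        cn <- chrom[bBin + 1L]
        offs <- (-halfBins):halfBins
        bins <- bBin + offs
        valid <- bins >= off[[cn]] & bins < off[[cn]] + nbv[[cn]]
        vals <- binE[as.character(bins)]
        rows[[length(rows) + 1L]] <- data.frame(class = cls, offset = offs,
                                                E = as.numeric(vals),
                                                valid = valid)
    }
    if (!length(rows)) stop("no boundary carries a class label")
    all <- do.call(rbind, rows)
    all <- all[all$valid & !is.na(all$E), , drop = FALSE]
    if (!nrow(all)) {
        warning("no class has 4C coverage near its boundaries")
        return(list(profile = data.frame(), summary = numeric()))
    }
    prof <- aggregate(E ~ class + offset, all, mean)
    names(prof)[3] <- "meanE"
    cnt <- aggregate(E ~ class + offset, all, length)
    prof$n <- cnt$E
    summ <- tapply(all$E, all$class, mean)
    list(profile = prof[order(prof$class, prof$offset), ],
         summary = setNames(as.numeric(summ), names(summ)))
}
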