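#' Iterative-correction (ICE) balancing of a contact matrix
#'
#' Equalizes per-bin marginals under a factorizable-bias model, either
#' chromosome by chromosome on the cis blocks only, or once on the full
#' genome-wide matrix including trans contacts. Before balancing, cis cells
#' at distances 0 and 1 bins (the first \code{ignoreDiags} diagonals) are
#' removed as non-informative, and bins whose remaining marginal is below
#' \code{minMarginal} read counts are masked out. Iteration stops when the
#' relative spread (max - min) / mean of the unmasked marginals drops to
#' \code{tol}.
#'
#' The returned matrix stores balanced values raw / (bias_i * bias_j); the
#' ignored diagonals and all entries of masked bins are dropped, so
#' downstream analyses see zeros there, matching the convention of setting
#' non-informative cells to 0.
#'
#' @param m a raw-counts \code{\link{ContactMatrix}}.
#' @param scope \code{"chromosome"} (cis blocks independently) or
#'   \code{"genome"} (one genome-wide correction including trans).
#' @param minMarginal minimum marginal read count for a bin to enter
#'   balancing (default 40).
#' @param ignoreDiags number of leading cis diagonals removed (default 2:
#'   distances 0 and 1).
#' @param tol convergence tolerance on the relative marginal spread
#'   (default 1e-2).
#' @param maxIter iteration cap (default 1000).
#' @return A balanced \code{\link{ContactMatrix}} with \code{bias} filled in
#'   (NA at masked bins) and convergence details in \code{metadata}.
#' @export
iceBalance <- function(m, scope = c("chromosome", "genome"),
                       minMarginal = 40, ignoreDiags = 2, tol = 1e-2,
                       maxIter = 1000L) {
    scope <- match.arg(scope)
    stopifnot(contactKind(m) == "raw")
    g <- contactGenome(m)
    n <- nBins(g)
    chrom <- binChrom(g)
    e <- contactEntries(m)
    # drop ignored cis diagonals once, globally
    same <- chrom[e$bin1 + 1L] == chrom[e$bin2 + 1L]
    e <- e[!(same & (e$bin2 - e$bin1) < ignoreDiags), , drop = FALSE]

    bias <- rep(NA_real_, n)
    masked <- integer()
    spreads <- list()
    groups <- if (scope == "chromosome") chromNames(g) else list(chromNames(g))
    outEntries <- list()
    for (grp in groups) {
        ids <- which(chrom %in% grp) - 1L
        sel <- e$bin1 %in% ids & e$bin2 %in% ids
        if (scope == "chromosome") {
            sub <- e[sel, , drop = FALSE]
        } else {
            sub <- e       # genome-wide: everything, including trans
        }
        res <- .iceCore(sub, ids, minMarginal, tol, maxIter,
                        label = paste(grp, collapse = "+"))
        bias[res$unmasked + 1L] <- res$bias
        masked <- c(masked, res$masked)
        spreads[[paste(grp, collapse = "+")]] <- res$spread
        outEntries[[length(outEntries) + 1L]] <- res$entries
        if (scope == "genome") break
    }
    ee <- do.call(rbind, outEntries)
    if (scope == "chromosome") {
        # trans entries are untouched by chromosome-wise balancing; drop them
        # from the balanced output (cis-only procedure)
        ee <- ee[order(ee$bin1, ee$bin2), , drop = FALSE]
    }
    rownames(ee) <- NULL
    new("ContactMatrix", genome = g, entries = ee, kind = "balanced",
        bias = bias, maskedBins = sort(unique(masked)),
        metadata = list(scope = scope, tol = tol,
                        convergence = "relative spread (max-min)/mean of unmasked marginals",
                        ignoreDiags = ignoreDiags, minMarginal = minMarginal,
                        finalSpread = spreads))
}

# core ICE on one entry set restricted to bin set `ids`
.iceCore <- function(entries, ids, minMarginal, tol, maxIter, label) {
    marg <- .marginals(entries, ids)
    lowIdx <- ids[marg < minMarginal]
    keep <- setdiff(ids, lowIdx)
    if (!length(keep) || all(marg[match(keep, ids)] == 0)) {
        warning(sprintf("all bins masked on %s; empty balanced block", label))
        return(list(entries = entries[0, , drop = FALSE], unmasked = integer(),
                    bias = numeric(), masked = ids, spread = NA_real_))
    }
    e <- entries[entries$bin1 %in% keep & entries$bin2 %in% keep, , drop = FALSE]
    b <- rep(1, length(keep))
    pos <- function(x) match(x, keep)
    w <- e$value
    spread <- Inf
    for (it in seq_len(maxIter)) {
        s <- numeric(length(keep))
        if (nrow(e)) {
            add <- rowsum(c(w, w[e$bin1 != e$bin2]),
                          c(pos(e$bin1), pos(e$bin2)[e$bin1 != e$bin2]))
            s[as.integer(rownames(add))] <- add[, 1]
        }
        zero <- s == 0
        sm <- s[!zero]
        spread <- if (length(sm)) (max(sm) - min(sm)) / mean(sm) else 0
        if (spread <= tol) break
        if (it == maxIter)
            stop(sprintf("ICE did not converge on %s after %d iterations (spread %.3g)",
                         label, maxIter, spread))
        # square-root damped multiplicative update: same fixed point as the
        # plain divide-by-marginal iteration, but free of the 2-cycle
        # oscillation it shows on strongly block-structured matrices
        scal <- sqrt(s / mean(sm))
        scal[zero] <- 1
        b <- b * scal
        w <- e$value / (b[pos(e$bin1)] * b[pos(e$bin2)])
    }
    e$value <- w
    e <- e[e$value != 0, , drop = FALSE]
    list(entries = e, unmasked = keep, bias = b, masked = lowIdx,
         spread = spread)
}

# marginals of a symmetric triplet set over bin set ids (diagonal counted once)
.marginals <- function(entries, ids) {
    s <- setNames(numeric(length(ids)), ids)
    e <- entries[entries$bin1 %in% ids | entries$bin2 %in% ids, , drop = FALSE]
    if (nrow(e)) {
        v <- c(e$value, e$value[e$bin1 != e$bin2])
        b <- c(e$bin1, e$bin2[e$bin1 != e$bin2])
        sel <- b %in% ids
        add <- rowsum(v[sel], b[sel])
        s[as.character(as.integer(rownames(add)))] <- add[, 1]
    }
    unname(s)
}

#' Transform a balanced matrix to contact frequencies
#'
#' Divides every cis value of a chromosome by that chromosome's median
#' balanced signal at the first informative diagonal (distance exactly
#' 2 bins), so the contact frequency of neighbouring informative loci has
#' median 1. The median is taken over the full diagonal, counting absent
#' cells as 0.
#'
#' @param m a balanced \code{\link{ContactMatrix}}.
#' @param capped use the alternative per-cell probabilistic transform:
#'   every value divided by the chromosome's \emph{mean} signal at distance
#'   2, capped at 1 (default FALSE, the median-based transform).
#' @return A \code{ContactMatrix} of kind \code{"frequency"} (cis entries
#'   only).
#' @export
toContactFrequency <- function(m, capped = FALSE) {
    stopifnot(contactKind(m) == "balanced")
    g <- contactGenome(m)
    chrom <- binChrom(g)
    nb <- chromNBins(g)
    off <- chromOffsets(g)
    e <- contactEntries(m)
    same <- chrom[e$bin1 + 1L] == chrom[e$bin2 + 1L]
    e <- e[same, , drop = FALSE]
    ch <- chrom[e$bin1 + 1L]
    out <- e
    for (cn in chromNames(g)) {
        d2 <- e$value[ch == cn & (e$bin2 - e$bin1) == 2L]
        len <- nb[[cn]] - 2L
        ref <- if (capped) {
            if (len <= 0) NA_real_ else sum(d2) / len
        } else .diagMedian(d2, len)
        if (!is.finite(ref) || ref <= 0)
            stop(sprintf("distance-2 %s undefined or zero on %s",
                         if (capped) "mean" else "median", cn))
        v <- e$value[ch == cn] / ref
        if (capped) v <- pmin(v, 1)
        out$value[ch == cn] <- v
    }
    out <- out[out$value != 0, , drop = FALSE]
    rownames(out) <- NULL
    new("ContactMatrix", genome = g, entries = out, kind = "frequency",
        bias = m@bias, maskedBins = m@maskedBins,
        metadata = c(m@metadata, list(frequencyNorm = "per-chromosome distance-2 median")))
}

# median of a diagonal of full length `len` of which only `vals` are stored
.diagMedian <- function(vals, len) {
    if (len <= 0) return(NA_real_)
    nzero <- len - length(vals)
    if (nzero < 0) stop("more stored values than diagonal cells")
    median(c(vals, numeric(nzero)))
}
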