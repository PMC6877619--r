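#' Specify a synthetic Hi-C study
#'
#' Builds a \code{\link{SimSpec}} describing contact maps with power-law
#' distance decay, TAD-block structure with tunable boundary insulation,
#' copy-number-scaled coverage and a uniform trans fraction. The defaults
#' are the package's reference study conditions: decay exponent -1 (the
#' fractal-globule-like regime reported for metazoan chromatin), a 2.5-fold
#' intra-TAD contact enrichment, strong boundaries (insulation strength
#' 0.85), one million cis read pairs per two-copy chromosome and a 10%
#' trans fraction.
#'
#' @param genome a \code{\link{GenomeModel}}.
#' @param decayExponent negative scalar or named vector per chromosome.
#' @param tadBoundaries named list; per chromosome either an integer vector
#'   of junction positions (first bin of the downstream TAD, local 0-based)
#'   or a data.frame (\code{bin}, \code{strength}).
#' @param insulationStrength default strength for boundaries given without
#'   one.
#' @param intraTadBoost multiplicative intra-TAD enrichment (>= 1).
#' @param coverage expected cis read pairs per two-copy chromosome; scalar
#'   or named vector. A chromosome with copy number c receives c/2 of it.
#' @param transFraction proportion of read pairs that are trans.
#' @param seed integer seed.
#' @return A \code{SimSpec}.
#' @export
simSpec <- function(genome, decayExponent = -1, tadBoundaries = list(),
                    insulationStrength = 0.85, intraTadBoost = 2.5,
                    coverage = 1e6, transFraction = 0.1, seed = 1L) {
    cn <- chromNames(genome)
    if (is.null(names(decayExponent)))
        decayExponent <- setNames(rep(decayExponent, length(cn)), cn)
    if (is.null(names(coverage)) || length(coverage) == 1L)
        coverage <- setNames(rep(unname(coverage), length(cn)), cn)
    tb <- lapply(tadBoundaries, function(x) {
        if (is.data.frame(x)) x
        else data.frame(bin = as.integer(x),
                        strength = rep(insulationStrength, length(x)))
    })
    new("SimSpec", genome = genome, decayExponent = decayExponent,
        tadBoundaries = tb, intraTadBoost = intraTadBoost,
        coverage = coverage, transFraction = transFraction,
        seed = as.integer(seed))
}

# expected cis intensity matrix for one chromosome (local bins)
.cisLambda <- function(nb, exponent, tb, boost, total) {
    idx <- which(upper.tri(matrix(0, nb, nb)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    d <- j - i
    lam <- ifelse(d >= 2, d^exponent, 0)
    if (nrow(tb)) {
        bnd <- sort(tb$bin)
        str <- tb$strength[order(tb$bin)]
        tad_i <- findInterval(i - 1L, bnd)   # local 0-based bins
        tad_j <- findInterval(j - 1L, bnd)
        samet <- tad_i == tad_j
        lam[samet] <- lam[samet] * boost
        cross <- which(!samet)
        if (length(cross)) {
            # product of (1 - strength) over boundaries strictly between bins
            latt <- log(pmax(1 - str, 0))
            cl <- cumsum(latt)
            att <- exp(cl[tad_j[cross]] - ifelse(tad_i[cross] > 0,
                                                 cl[tad_i[cross]], 0))
            lam[cross] <- lam[cross] * att
        }
    }
    s <- sum(lam)
    if (s > 0) lam <- lam * (total / s)
    list(i = i, j = j, lambda = lam)
}

#' Simulate a contact map with known ground truth
#'
#' Expected cis intensity is proportional to d^exponent for distances
#' d >= 2 bins (0 at distances 0 and 1, mirroring the analysis-side
#' exclusion of the first two diagonals), multiplied by
#' \code{intraTadBoost} for bin pairs inside one TAD and attenuated by
#' (1 - strength) for every boundary crossed. Counts are Poisson with the
#' chromosome total scaled to the copy-number-adjusted coverage; trans
#' counts are Poisson-uniform over trans bin pairs at the requested
#' fraction.
#'
#' @param spec a \code{\link{SimSpec}}.
#' @param seed optional seed overriding \code{spec@seed}.
#' @return \code{list(map = ContactMatrix, truth = SimTruth)}.
#' @export
simulateContactMap <- function(spec, seed = NULL) {
    g <- spec@genome
    if (is.null(seed)) seed <- spec@seed
    set.seed(seed)
    nb <- chromNBins(g)
    off <- chromOffsets(g)
    cnum <- copyNumbers(g)
    ent <- list()
    cisTotal <- 0
    for (ch in chromNames(g)) {
        tb <- spec@tadBoundaries[[ch]]
        if (is.null(tb)) tb <- data.frame(bin = integer(), strength = numeric())
        total <- spec@coverage[[ch]] * cnum[[ch]] / 2
        cisTotal <- cisTotal + total
        lam <- .cisLambda(nb[[ch]], spec@decayExponent[[ch]], tb,
                          spec@intraTadBoost, total)
        cnt <- rpois(length(lam$lambda), lam$lambda)
        keep <- cnt > 0
        ent[[ch]] <- data.frame(bin1 = off[[ch]] + lam$i[keep] - 1L,
                                bin2 = off[[ch]] + lam$j[keep] - 1L,
                                value = cnt[keep])
    }
    f <- spec@transFraction
    if (f > 0 && length(chromNames(g)) > 1) {
        tTotal <- rpois(1, cisTotal * f / (1 - f))
        if (tTotal > 0) {
            chrom <- binChrom(g)
            n <- nBins(g)
            got <- 0L; b1 <- integer(); b2 <- integer()
            while (got < tTotal) {
                need <- (tTotal - got) * 2L + 10L
                i <- sample.int(n, need, replace = TRUE) - 1L
                j <- sample.int(n, need, replace = TRUE) - 1L
                ok <- chrom[i + 1L] != chrom[j + 1L]
                take <- min(sum(ok), tTotal - got)
                b1 <- c(b1, i[ok][seq_len(take)])
                b2 <- c(b2, j[ok][seq_len(take)])
                got <- got + take
            }
            ent[["trans"]] <- data.frame(bin1 = pmin(b1, b2),
                                         bin2 = pmax(b1, b2), value = 1)
        }
    }
    ee <- do.call(rbind, ent)
    map <- contactMatrix(g, ee$bin1, ee$bin2, ee$value, kind = "raw")
    truth <- new("SimTruth", spec = spec,
                 boundaries = lapply(spec@tadBoundaries,
                                     function(x) sort(as.integer(x$bin))),
                 featureSites = data.frame(chrom = character(),
                                           mid = numeric()))
    list(map = map, truth = truth)
}

#' Simulate a point-feature track, optionally co-located with boundaries
#'
#' @param truth a \code{\link{SimTruth}} carrying the ground-truth boundary
#'   junctions.
#' @param nSites number of sites to place.
#' @param nearBoundaryFraction proportion of sites placed within
#'   \code{maxOffset} bp of a randomly chosen ground-truth boundary; the
#'   remainder are uniform over the genome.
#' @param maxOffset maximum distance (bp) of a co-located site from its
#'   boundary junction.
#' @param seed integer seed.
#' @return data.frame (\code{chrom}, \code{mid}, \code{near}) of site
#'   midpoints.
#' @export
simulateFeatureTrack <- function(truth, nSites, nearBoundaryFraction = 0,
                                 maxOffset = 0, seed = 1L) {
    if (maxOffset < 0) stop("maxOffset must be >= 0")
    stopifnot(nSites >= 0, nearBoundaryFraction >= 0, nearBoundaryFraction <= 1)
    g <- truth@spec@genome
    set.seed(seed)
    bs <- binSize(g)
    junc <- do.call(rbind, lapply(names(truth@boundaries), function(ch) {
        b <- truth@boundaries[[ch]]
        if (!length(b)) return(NULL)
        data.frame(chrom = ch, pos = b * bs)
    }))
    nNear <- round(nSites * nearBoundaryFraction)
    if (nNear > 0 && (is.null(junc) || !nrow(junc)))
        stop("co-located sites requested but the truth has no boundaries")
    out <- list()
    if (nNear > 0) {
        k <- sample.int(nrow(junc), nNear, replace = TRUE)
        lens <- chromLengths(g)[junc$chrom[k]]
        mid <- junc$pos[k] +
            if (maxOffset > 0) round(runif(nNear, -maxOffset, maxOffset)) else 0
        out$near <- data.frame(chrom = junc$chrom[k],
                               mid = pmin(pmax(mid, 0), lens - 1),
                               near = TRUE)
    }
    nUnif <- nSites - nNear
    if (nUnif > 0) {
        lens <- chromLengths(g)
        ch <- sample(chromNames(g), nUnif, replace = TRUE,
                     prob = lens / sum(lens))
        out$unif <- data.frame(chrom = ch,
                               mid = floor(runif(nUnif, 0, lens[ch])),
                               near = FALSE)
    }
    sites <- if (length(out)) do.call(rbind, out)
             else data.frame(chrom = character(), mid = numeric(),
                             near = logical())
    rownames(sites) <- NULL
    sites
}

# name of the X chromosome in a genome ("X" or "chrX"), error if absent
.findChrX <- function(g, chrxName = NULL) {
    if (!is.null(chrxName)) return(chrxName)
    cand <- grep("^(chr)?X$", chromNames(g), value = TRUE)
    if (length(cand) != 1) stop("cannot identify a unique X chromosome")
    cand
}

#' Simulate a male/female contact-map pair
#'
#' The male map derives from the female spec with chrX copy number 1, the
#' chrX decay exponent shifted by \code{deltaExponent} (less negative,
#' emulating the slower male-X interaction decay), and the insulation
#' strength of the selected chrX boundaries set to 0 (disappearing
#' boundaries). Autosomes are statistically identical between sexes.
#'
#' @param specFemale a \code{\link{SimSpec}} with chrX at copy number 2.
#' @param weakened integer indices (1-based) into the chrX boundary list to
#'   open fully in the male map.
#' @param deltaExponent shift added to the male chrX decay exponent.
#' @param seed integer seed; female and male maps use derived sub-seeds.
#' @param chrxName chrX name override.
#' @return \code{list(female = list(map, truth), male = list(map, truth))}.
#' @export
simulateSexPair <- function(specFemale, weakened = integer(),
                            deltaExponent = 0, seed = 1L, chrxName = NULL) {
    g <- specFemale@genome
    chrx <- .findChrX(g, chrxName)
    if (specFemale@decayExponent[[chrx]] + deltaExponent >= 0)
        stop("deltaExponent would make the chrX exponent non-negative")
    tbx <- specFemale@tadBoundaries[[chrx]]
    if (length(weakened) &&
        (is.null(tbx) || any(weakened < 1) || any(weakened > nrow(tbx))))
        stop("weakened indices outside the chrX boundary list")
    male <- specFemale
    ch <- male@genome@chroms
    ch$copyNumber[ch$name == chrx] <- 1L
    male@genome <- initialize(male@genome, chroms = ch)
    male@decayExponent[[chrx]] <- male@decayExponent[[chrx]] + deltaExponent
    if (length(weakened))
        male@tadBoundaries[[chrx]]$strength[weakened] <- 0
    list(female = simulateContactMap(specFemale, seed = seed),
         male = simulateContactMap(male, seed = seed + 1L))
}
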