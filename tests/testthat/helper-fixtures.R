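# Shared fixtures and independent oracles for the test suite.

toyGenome <- function(nbins, binSize = 1000, name = "c1") {
    lens <- setNames(nbins * binSize, name)
    genomeModel(lens, binSize = binSize)
}

# ContactMatrix from a dense symmetric single-chromosome matrix
denseToCM <- function(g, mat, kind = "balanced") {
    idx <- which(upper.tri(mat, diag = TRUE) & mat != 0, arr.ind = TRUE)
    contactMatrix(g, idx[, 1] - 1L, idx[, 2] - 1L, mat[idx], kind = kind)
}

# dense symmetric matrix from a ContactMatrix (all chromosomes cis-blocked)
cmToDense <- function(m, chrom) cisBlock(m, chrom)

# --- brute-force iterative correction: alternate divide-by-marginal ---------
# Zeroes the first `ignoreDiags` diagonals, then repeatedly divides by the
# outer product of marginals (rescaled to preserve the mean marginal) until
# the relative spread of marginals reaches tol. Returns the balanced dense
# matrix normalised to unit mean marginal.
bruteIce <- function(M, tol = 1e-12, ignoreDiags = 2, maxIter = 10000) {
    W <- M
    W[abs(row(W) - col(W)) < ignoreDiags] <- 0
    for (it in seq_len(maxIter)) {
        s <- rowSums(W)
        sm <- s[s > 0]
        spread <- (max(sm) - min(sm)) / mean(sm)
        if (spread <= tol) break
        sc <- s / mean(sm)
        sc[s == 0] <- 1
        W <- W / outer(sc, sc)
    }
    s <- rowSums(W)
    W / mean(s[s > 0])
}

# normalise a dense balanced matrix to unit mean marginal (scale convention)
normUnitMarginal <- function(W) {
    s <- rowSums(W)
    W / mean(s[s > 0])
}

# --- plain union-find for clustering oracle ---------------------------------
ufFind <- function(parent, i) {
    while (parent[i] != i) i <- parent[i]
    i
}

# single-linkage components by exhaustive pairwise distances
bruteCluster <- function(x, y, maxBins) {
    n <- length(x)
    parent <- seq_len(n)
    if (n > 1) {
        D <- as.matrix(dist(cbind(x, y)))
        edges <- which(upper.tri(D) & D <= maxBins, arr.ind = TRUE)
        for (k in seq_len(nrow(edges))) {
            ra <- ufFind(parent, edges[k, 1])
            rb <- ufFind(parent, edges[k, 2])
            if (ra != rb) parent[rb] <- ra
        }
    }
    roots <- vapply(seq_len(n), function(i) ufFind(parent, i), integer(1))
    match(roots, unique(roots))
}

# --- dense decay-curve oracle ------------------------------------------------
denseDecayMedians <- function(mat, minDist, maxDist) {
    nb <- nrow(mat)
    vapply(minDist:maxDist, function(d) {
        if (d >= nb) return(0)
        median(mat[cbind(seq_len(nb - d), seq_len(nb - d) + d)])
    }, numeric(1))
}

# --- synthetic TAD fixture used by several suites ---------------------------
tadFixture <- function(seed, nbins = 400, nBoundaries = 10, readsPerBin = 300,
                       strength = 0.85, boost = 2.5, binSize = 3500) {
    g <- genomeModel(setNames(nbins * binSize, "chrX"), binSize = binSize)
    bnd <- round(seq(35, nbins - 35, length.out = nBoundaries))
    sp <- simSpec(g, decayExponent = -1,
                  tadBoundaries = list(chrX = bnd),
                  insulationStrength = strength, intraTadBoost = boost,
                  coverage = nbins * readsPerBin, transFraction = 0,
                  seed = seed)
    simulateContactMap(sp)
}
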