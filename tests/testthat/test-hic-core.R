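test_that("triplet reading mirrors the lower triangle and validates bin ids", {
    g <- toyGenome(10)
    dir <- withr::local_tempdir()
    bins <- file.path(dir, "bins.tsv")
    write.table(binTable(g), bins, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)

    trip <- file.path(dir, "m.tsv")
    writeLines(c("0\t1\t5", "1\t0\t3"), trip)
    m <- readContacts(trip, bins)
    expect_equal(contactEntries(m),
                 data.frame(bin1 = 0L, bin2 = 1L, value = 8))
    expect_equal(contactValue(m, 1, 0), contactValue(m, 0, 1))

    writeLines(character(), trip)
    m0 <- readContacts(trip, bins)
    expect_identical(nrow(contactEntries(m0)), 0L)
    expect_identical(nBins(contactGenome(m0)), 10L)

    writeLines("0\t999\t10", trip)
    expect_error(readContacts(trip, bins), "999")
    writeLines("0\t1\t-4", trip)
    expect_error(readContacts(trip, bins), "negative")
})

test_that("contact matrices round-trip through triplet files with bias", {
    g <- toyGenome(8)
    set.seed(11)
    mat <- matrix(0, 8, 8)
    mat[upper.tri(mat)] <- rpois(28, 20)
    mat <- mat + t(mat)
    m <- denseToCM(g, mat, kind = "raw")
    dir <- withr::local_tempdir()
    writeContacts(m, file.path(dir, "t.tsv"), file.path(dir, "b.tsv"))
    m2 <- readContacts(file.path(dir, "t.tsv"), file.path(dir, "b.tsv"))
    expect_equal(contactEntries(m2), contactEntries(m))

    bias <- c(runif(6, 0.5, 2), NA, NA)
    writeBias(bias, file.path(dir, "bias.tsv"))
    expect_equal(readBias(file.path(dir, "bias.tsv"), g), bias)
})

test_that("ICE equalizes marginals and matches the divide-by-marginal oracle", {
    set.seed(42)
    for (rep in 1:20) {
        mat <- matrix(0, 8, 8)
        mat[upper.tri(mat, diag = TRUE)] <- sample(50:200, 36, replace = TRUE)
        mat <- mat + t(mat) - diag(diag(mat))
        g <- toyGenome(8)
        m <- denseToCM(g, mat, kind = "raw")

        bal <- iceBalance(m, tol = 1e-12, maxIter = 10000)
        got <- normUnitMarginal(cisBlock(bal, "c1"))
        want <- bruteIce(mat, tol = 1e-12)
        expect_equal(got, want, tolerance = 1e-6)

        # the default tolerance leaves marginals within 1e-2 relative spread
        def <- iceBalance(m)
        W <- cisBlock(def, "c1")
        s <- rowSums(W)
        expect_lte((max(s) - min(s)) / mean(s), 1e-2)
    }
})

test_that("constant matrices balance to themselves (biases equal)", {
    g <- toyGenome(6)
    mat <- matrix(4, 6, 6)
    m <- denseToCM(g, mat, kind = "raw")
    bal <- iceBalance(m, ignoreDiags = 0, minMarginal = 1)
    expect_true(all(abs(contactBias(bal) - contactBias(bal)[1]) < 1e-12))
    vals <- contactEntries(bal)$value
    expect_true(all(abs(vals - vals[1]) < 1e-9))
})

test_that("low-coverage bins are masked and dropped from the balanced output", {
    g <- toyGenome(6)
    mat <- matrix(0, 6, 6)
    mat[upper.tri(mat)] <- 30
    mat <- mat + t(mat)
    mat[3, ] <- mat[, 3] <- c(0, 0, 0, 2, 3, 5)   # marginal 10 < 40
    m <- denseToCM(g, mat, kind = "raw")
    bal <- iceBalance(m)
    expect_true(2L %in% maskedBins(bal))
    e <- contactEntries(bal)
    expect_false(any(e$bin1 == 2L | e$bin2 == 2L))
    expect_true(is.na(contactBias(bal)[3]))
})

test_that("balancing an already-balanced matrix is a no-op up to tol", {
    g <- toyGenome(6)
    mat <- matrix(7, 6, 6)        # equal marginals: fixed point
    m <- denseToCM(g, mat, kind = "raw")
    bal <- iceBalance(m, ignoreDiags = 0, minMarginal = 1, tol = 1e-2)
    before <- cisBlock(m, "c1")
    after <- cisBlock(bal, "c1")
    expect_true(all(abs(after - before) / before <= 1e-2))
})

test_that("contact-frequency transform scales each chromosome by its own distance-2 median", {
    g <- genomeModel(c(a = 8000, b = 8000), binSize = 1000)
    matA <- matrix(0, 8, 8); matB <- matrix(0, 8, 8)
    for (d in 2:7) {
        for (i in seq_len(8 - d)) {
            matA[i, i + d] <- 10
            matB[i, i + d] <- 4
        }
    }
    ents <- rbind(
        data.frame(which(upper.tri(matA) & matA != 0, arr.ind = TRUE) - 1L,
                   value = matA[upper.tri(matA) & matA != 0]),
        data.frame(which(upper.tri(matB) & matB != 0, arr.ind = TRUE) + 7L,
                   value = matB[upper.tri(matB) & matB != 0]))
    m <- contactMatrix(g, ents$row, ents$col, ents$value, kind = "balanced")
    fr <- toContactFrequency(m)
    expect_identical(contactKind(fr), "frequency")
    dA <- cisBlock(fr, "a"); dB <- cisBlock(fr, "b")
    expect_equal(unique(dA[dA > 0]), 1)       # 10 / 10
    expect_equal(unique(dB[dB > 0]), 1)       # 4 / 4, own median
    # entry value 5 on a chromosome whose distance-2 median is 10 -> 0.5
    matA2 <- matA; matA2[1, 3] <- 5
    # median over the 6-cell diagonal of (5,10,10,10,10,10) is still 10
    mA <- denseToCM(genomeModel(c(a = 8000), 1000), matA2, "balanced")
    frA <- toContactFrequency(mA)
    expect_equal(cisBlock(frA, "a")[1, 3], 0.5)
})

test_that("frequency transform fails when the distance-2 median is zero", {
    g <- toyGenome(8)
    mat <- matrix(0, 8, 8)
    mat[1, 4] <- 3; mat[4, 1] <- 3      # only distance-3 signal
    m <- denseToCM(g, mat, "balanced")
    expect_error(toContactFrequency(m), "distance-2 median")
})

test_that("binomial downsampling is seeded, bounded and unbiased", {
    g <- toyGenome(150)
    set.seed(5)
    n <- 10000
    b1 <- sample(0:148, n, replace = TRUE)
    b2 <- pmin(b1 + sample(1:40, n, replace = TRUE), 149L)
    m <- contactMatrix(g, b1, b2, rep(100, n), kind = "raw")
    tot <- sum(contactEntries(m)$value)

    d1 <- downsampleBinomial(m, p = 0.5, seed = 3)
    d2 <- downsampleBinomial(m, p = 0.5, seed = 3)
    expect_identical(contactEntries(d1), contactEntries(d2))

    sdTot <- sqrt(tot * 0.5 * 0.5)
    expect_lt(abs(sum(contactEntries(d1)$value) - tot / 2), 3 * sdTot)

    expect_identical(contactEntries(downsampleBinomial(m, p = 1, seed = 1)),
                     contactEntries(m))
    expect_error(downsampleBinomial(m, p = 0), "p must")
    z <- contactMatrix(g, 0L, 5L, 0L, kind = "raw")
    expect_identical(nrow(contactEntries(downsampleBinomial(z, 0.5, 1))), 0L)
})

test_that("matched-cis downsampling thins each chromosome to the reference total", {
    g <- genomeModel(c(a = 50000, b = 50000), binSize = 1000)
    set.seed(8)
    mk <- function(total) {
        b1 <- sample(0:48, total / 10, replace = TRUE)
        d <- sample(2:20, total / 10, replace = TRUE)
        contactMatrix(g, c(b1, b1 + 50L), c(pmin(b1 + d, 49L), pmin(b1 + d, 49L) + 50L),
                      rep(10, length(b1) * 2), kind = "raw")
    }
    target <- mk(1000)
    reference <- mk(500)
    thinned <- downsampleMatchedCis(target, reference, seed = 2)
    tT <- cisTotals(target); tR <- cisTotals(reference); tD <- cisTotals(thinned)
    for (cn in c("a", "b")) {
        p <- tR[[cn]] / tT[[cn]]
        expect_lt(abs(tD[[cn]] - tR[[cn]]), 3 * sqrt(tT[[cn]] * p * (1 - p)) + 1)
    }
    # reference >= target leaves the chromosome unchanged
    same <- downsampleMatchedCis(reference, target, seed = 2)
    expect_identical(contactEntries(same), contactEntries(reference))
    # zero reference empties the chromosome
    empty <- contactMatrix(g, integer(), integer(), numeric(), kind = "raw")
    gone <- downsampleMatchedCis(target, empty, seed = 2)
    expect_identical(sum(contactEntries(gone)$value), 0)
    # missing chromosome errors
    g1 <- genomeModel(c(a = 50000), binSize = 1000)
    ref1 <- contactMatrix(g1, 0L, 3L, 5L, kind = "raw")
    expect_error(downsampleMatchedCis(target, ref1, seed = 1), "missing")
})

test_that("the capped per-cell frequency transform divides by the mean and caps at 1", {
    g <- toyGenome(8)
    mat <- matrix(0, 8, 8)
    d2 <- c(1, 2, 3, 4, 5, 9)                 # mean = 4
    for (i in 1:6) mat[i, i + 2] <- d2[i]
    mat <- mat + t(mat)
    m <- denseToCM(g, mat, "balanced")
    fr <- toContactFrequency(m, capped = TRUE)
    got <- cisBlock(fr, "c1")[cbind(1:6, 3:8)]
    expect_equal(got, pmin(d2 / 4, 1))
})
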