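test_that("the directionality index follows the chi-square-style contrast", {
    g <- toyGenome(30)
    set.seed(1)
    mat <- matrix(runif(900, 1, 2), 30, 30)
    mat <- (mat + t(mat)) / 2
    # plant a bin with known window sums: A = 10, B = 20 at windowN = 2
    i <- 15
    mat[i, (i - 2):(i - 1)] <- c(4, 6);  mat[(i - 2):(i - 1), i] <- c(4, 6)
    mat[i, (i + 1):(i + 2)] <- c(9, 11); mat[(i + 1):(i + 2), i] <- c(9, 11)
    di <- directionalityIndex(denseToCM(g, mat, "balanced"), windowN = 2)$c1
    expect_equal(di[i], 10 / 3)            # ((10-15)^2 + (20-15)^2) / 15

    # A = B gives exactly 0
    mat[i, (i + 1):(i + 2)] <- c(4, 6); mat[(i + 1):(i + 2), i] <- c(4, 6)
    di0 <- directionalityIndex(denseToCM(g, mat, "balanced"), windowN = 2)$c1
    expect_identical(di0[i], 0)

    # mirror image negates the track
    rev <- mat[30:1, 30:1]
    diR <- directionalityIndex(denseToCM(g, rev, "balanced"), windowN = 2)$c1
    diF <- directionalityIndex(denseToCM(g, mat, "balanced"), windowN = 2)$c1
    expect_equal(diR, -diF[30:1])

    # ends are undefined
    expect_true(all(is.na(diF[c(1, 2, 29, 30)])))
    expect_error(directionalityIndex(denseToCM(g, mat, "balanced"), 0),
                 "windowN")
})

test_that("DI first differences satisfy their defining identities", {
    di <- c(NA, 0, 5, 0, -2, NA)
    dd <- deltaDI(di)
    expect_equal(dd$forward[3], 5)       # DI_3 - DI_4
    expect_equal(dd$backward[3], 5)      # DI_3 - DI_2
    ok <- !is.na(dd$forward[-length(di)]) & !is.na(dd$backward[-1])
    expect_equal(dd$forward[-length(di)][ok], -dd$backward[-1][ok])
    const <- deltaDI(rep(2, 10))
    expect_true(all(const$forward[1:9] == 0) && all(const$backward[2:10] == 0))
})

test_that("fence gating matches a per-bin reimplementation of the caller", {
    sim <- tadFixture(seed = 31, nbins = 200, nBoundaries = 5,
                      readsPerBin = 250)
    bal <- iceBalance(sim$map)
    called <- callDomains(bal, windowN = 10, localM = 25)

    di <- directionalityIndex(bal, 10)$chrX
    dd <- deltaDI(di)
    nb <- length(di)
    wantStart <- integer(); wantEnd <- integer()
    for (i in seq_len(nb)) {
        if (!is.finite(di[i])) next
        win <- max(1, i - 25):min(nb, i + 25)
        fw <- dd$forward[win]; fw <- fw[is.finite(fw)]
        bw <- dd$backward[win]; bw <- bw[is.finite(bw)]
        if (is.finite(dd$forward[i]) && dd$forward[i] < 0 && length(fw) >= 2) {
            q <- quantile(fw, c(0.25, 0.75), type = 7)
            if (dd$forward[i] <= q[1] - 1.5 * (q[2] - q[1]) &&
                dd$forward[i] <= di[i])
                wantStart <- c(wantStart, i - 1L)
        }
        if (is.finite(dd$backward[i]) && dd$backward[i] > 0 && length(bw) >= 2) {
            q <- quantile(bw, c(0.25, 0.75), type = 7)
            if (dd$backward[i] >= q[2] + 1.5 * (q[2] - q[1]) &&
                dd$backward[i] >= di[i])
                wantEnd <- c(wantEnd, i - 1L)
        }
    }
    expect_identical(domainStarts(called), wantStart)
    expect_identical(domainEnds(called), wantEnd)
})

test_that("uniform matrices produce no boundary calls", {
    g <- toyGenome(80)
    m <- denseToCM(g, matrix(1, 80, 80), "balanced")
    b <- callDomains(m)
    expect_identical(length(domainStarts(b)), 0L)
    expect_identical(length(domainEnds(b)), 0L)
})

test_that("a strong two-block boundary is called within one bin", {
    g <- toyGenome(120)
    k <- 60                                    # junction after bin 59 (0-based)
    mat <- matrix(0, 120, 120)
    for (d in 2:119) for (i in seq_len(120 - d)) {
        same <- (i <= k) == (i + d <= k)
        mat[i, i + d] <- d^-1 * ifelse(same, 2.5, 0.05)
    }
    mat <- mat + t(mat)
    b <- callDomains(denseToCM(g, mat, "balanced"))
    ends <- domainEnds(b); starts <- domainStarts(b)
    expect_true(any(abs(ends - (k - 1)) <= 1))      # an end at or near bin 59
    expect_true(any(abs(starts - k) <= 1))          # a start at or near bin 60
})

test_that("call output is invariant to global matrix rescaling", {
    sim <- tadFixture(seed = 17, nbins = 150, nBoundaries = 4,
                      readsPerBin = 250)
    bal <- iceBalance(sim$map)
    e <- contactEntries(bal)
    scaled <- contactMatrix(contactGenome(bal), e$bin1, e$bin2,
                            e$value * 0.013, kind = "balanced")
    b1 <- callDomains(bal); b2 <- callDomains(scaled)
    expect_identical(domainStarts(b1), domainStarts(b2))
    expect_identical(domainEnds(b1), domainEnds(b2))
})

test_that("boundary regions are bin-wide windows centred on the junction", {
    g <- toyGenome(100, binSize = 3500)
    b <- new("BoundarySet", genome = g, starts = integer(),
             ends = c(40L, 40L, 99L), regions = data.frame(),
             insulation = numeric(), boundaryClass = character())
    b <- makeBoundaryRegions(b)
    r <- b@regions
    expect_identical(nrow(r), 2L)               # duplicate 40 collapsed
    expect_equal(r$start[1], 41 * 3500 - 1750)  # centred on coordinate 41*3500
    expect_equal(r$end[1], 41 * 3500 + 1750)
    expect_true(r$clipped[2])                   # final bin: clipped at chr end
    empty <- new("BoundarySet", genome = g, starts = integer(),
                 ends = integer(), regions = data.frame(),
                 insulation = numeric(), boundaryClass = character())
    expect_identical(nrow(makeBoundaryRegions(empty)@regions), 0L)
})

test_that("boundary-set comparison classifies and partitions exactly", {
    g <- toyGenome(200)
    mk <- function(ends) new("BoundarySet", genome = g, starts = integer(),
                             ends = as.integer(ends), regions = data.frame(),
                             insulation = numeric(),
                             boundaryClass = character())
    res <- compareBoundarySets(mk(c(10, 50, 90)), mk(c(10, 90, 120)))
    expect_setequal(res$same, c(10, 90))
    expect_setequal(res$disappearing, 50)
    expect_setequal(res$appearing, 120)
    expect_equal(res$nonMatchingFraction, 0.5)
    # classes partition the union
    expect_setequal(res$classes$bin,
                    c(res$same, res$appearing, res$disappearing))
    expect_identical(anyDuplicated(res$classes$bin), 0L)

    same <- compareBoundarySets(mk(c(5, 7)), mk(c(5, 7)))
    expect_equal(same$nonMatchingFraction, 0)
    disj <- compareBoundarySets(mk(c(5, 7)), mk(c(20, 30)))
    expect_equal(disj$nonMatchingFraction, 1)

    g2 <- toyGenome(200, binSize = 2000)
    b2 <- new("BoundarySet", genome = g2, starts = integer(), ends = 5L,
              regions = data.frame(), insulation = numeric(),
              boundaryClass = character())
    expect_error(compareBoundarySets(mk(5), b2), "bin-size")
})

test_that("insulation scores equal dense window means and dip at boundaries", {
    g <- toyGenome(50)
    set.seed(4)
    mat <- matrix(runif(2500, 0.5, 1.5), 50, 50)
    mat <- (mat + t(mat)) / 2
    m <- denseToCM(g, mat, "balanced")
    ins <- insulationScore(m, window = 10)
    w <- 10
    for (i in c(11, 25, 40)) {
        want <- mean(mat[(i - w):(i - 1), (i + 1):(i + w)])
        expect_equal(ins$raw$c1[i], want, tolerance = 1e-9)
    }
    expect_true(all(is.na(ins$raw$c1[c(1:10, 41:50)])))

    # uniform matrix: normalized score is exactly 1 wherever defined
    u <- insulationScore(denseToCM(g, matrix(2, 50, 50), "balanced"), 10)
    expect_true(all(abs(u$normalized$c1[11:40] - 1) < 1e-12))

    # planted boundary: normalized minimum at the junction
    sim <- tadFixture(seed = 23, nbins = 200, nBoundaries = 3,
                      readsPerBin = 300)
    bal <- iceBalance(sim$map)
    insX <- insulationScore(bal, 10)$normalized$chrX
    for (bnd in sim$truth@boundaries$chrX) {
        loc <- which.min(insX[(bnd - 5):(bnd + 5)]) + bnd - 6
        expect_lte(abs(loc - bnd), 2)
    }

    short <- toyGenome(15)
    expect_warning(insulationScore(denseToCM(short, matrix(1, 15, 15),
                                             "balanced"), 10), "shorter")
})

test_that("boundary insulation averages the two junction-adjacent bins", {
    sim <- tadFixture(seed = 41, nbins = 150, nBoundaries = 3,
                      readsPerBin = 300)
    bal <- iceBalance(sim$map)
    b <- makeBoundaryRegions(callDomains(bal))
    ins <- insulationScore(bal, 10)
    b <- boundaryInsulation(b, ins)
    ends <- boundaryBins(b)
    v <- ins$normalized$chrX
    want <- vapply(ends, function(e) mean(v[c(e + 1, e + 2)], na.rm = TRUE),
                   numeric(1))
    expect_equal(b@insulation, want)
})
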