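mkBounds <- function(g, ends) {
    makeBoundaryRegions(new("BoundarySet", genome = g, starts = integer(),
                            ends = as.integer(ends), regions = data.frame(),
                            insulation = numeric(),
                            boundaryClass = character()))
}

test_that("boundary windows are disjoint and split shared territory equally", {
    g <- toyGenome(200, binSize = 3500)
    # isolated boundary: full +-15 bins
    w1 <- boundaryWindows(mkBounds(g, 100), half = 15)
    expect_equal(w1$lo, 100 - 14)
    expect_equal(w1$hi, 100 + 15)
    expect_equal(w1$nBins, 30L)

    # two boundaries 10 bins apart: each receives 5 intervening bins
    w2 <- boundaryWindows(mkBounds(g, c(100, 110)), half = 15)
    expect_equal(w2$hi[1], 105)          # 100 + 5
    expect_equal(w2$lo[2], 106)          # junction territory split equally
    expect_identical(sum(w2$lo[2] <= w2$hi[1]), 0L)

    # boundary 3 bins from the chromosome start: clipped at bin 0
    w3 <- boundaryWindows(mkBounds(g, 3), half = 15)
    expect_equal(w3$lo, 0)

    # dense random boundary sets always yield a disjoint cover
    set.seed(2)
    ends <- sort(sample(20:180, 25))
    w <- boundaryWindows(mkBounds(g, ends), half = 15)
    covered <- unlist(mapply(seq, w$lo, w$hi, SIMPLIFY = FALSE))
    expect_identical(anyDuplicated(covered), 0L)
    # each window still contains its own boundary bin
    expect_true(all(w$lo <= w$end_bin & w$end_bin <= w$hi))
})

test_that("feature enrichment reports log2 observed over uniform expectation", {
    g <- toyGenome(1000, binSize = 3500)
    w <- boundaryWindows(mkBounds(g, c(200, 500, 800)), half = 15)
    # 100 sites on a 1000-bin chromosome: expected density 0.1 per bin
    set.seed(8)
    sites <- data.frame(chrom = "c1",
                        mid = floor(runif(100, 0, 1000 * 3500)))
    fe <- featureEnrichment(w, sites, g)
    expect_equal(fe$expectedDensity, 0.1)
    # doubling the in-window density moves the ratio to exactly +1
    expect_equal(log2(0.2 / 0.1), 1)
    expect_equal(fe$log2ratio,
                 log2(fe$observedDensity / fe$expectedDensity))
    expect_error(featureEnrichment(w[0, ], sites, g), "zero total")
})

test_that("uniform sites sit inside the permutation envelope, planted sites outside", {
    nb <- 1200
    g <- genomeModel(c(chrX = nb * 3500), binSize = 3500)
    bnd <- c(250, 500, 750)
    sp <- simSpec(g, tadBoundaries = list(chrX = bnd), coverage = 1e4,
                  transFraction = 0, seed = 3)
    truth <- simulateContactMap(sp)$truth
    w <- boundaryWindows(mkBounds(g, bnd - 1L), half = 15)

    unif <- simulateFeatureTrack(truth, 150, 0, 0, seed = 5)
    feU <- featureEnrichment(w, unif, g)
    null <- featureEnrichmentPermutation(w, 150, g, nPerm = 200, seed = 6)
    env <- quantile(null[is.finite(null)], c(0.025, 0.975))
    expect_gte(feU$log2ratio, env[[1]])
    expect_lte(feU$log2ratio, env[[2]])

    # windows cover 90/1200 bins; placing 30% of sites there is a 4x
    # co-location and must clear log2 >= 1.5
    planted <- simulateFeatureTrack(truth, 200, 0.3, 15000, seed = 7)
    feP <- featureEnrichment(w, planted, g)
    expect_gte(feP$log2ratio, 1.5)
})

test_that("insulator summits drive the three combinatorial classes", {
    g <- toyGenome(300, binSize = 3500)
    b <- mkBounds(g, c(50, 150, 250))
    mkTrack <- function(v) {
        bt <- binTable(g)
        data.frame(chrom = bt$chrom, start = bt$start, end = bt$end,
                   value = rep(v, length.out = nrow(bt)))
    }
    classify1 <- function(beaf, cp, ch)
        classifyInsulatorBoundaries(b, mkTrack(beaf), mkTrack(cp),
                                    mkTrack(ch))$class[1]
    expect_identical(classify1(0.9, 0.7, 0.1), "BEAF+ and CP/CH+")
    expect_identical(classify1(0.9, 0.2, 0.2), "BEAF+ or CP/CH+")
    expect_identical(classify1(0.2, 0.2, 0.2), "BEAF- and CP/CH-")
    # low BEAF with both partners high is still class (ii)
    expect_identical(classify1(0.2, 0.8, 0.9), "BEAF+ or CP/CH+")
    expect_error(classifyInsulatorBoundaries(b, NULL, mkTrack(1), mkTrack(1)),
                 "beaf")

    # male/female pairs are combined by per-boundary maximum
    two <- classifyInsulatorBoundaries(b, list(mkTrack(0.2), mkTrack(0.9)),
                                       mkTrack(0.7), mkTrack(0.1))
    expect_identical(two$class[1], "BEAF+ and CP/CH+")
})

test_that("signal scaling divides by the 99th percentile", {
    set.seed(1)
    tr <- data.frame(chrom = "c1", start = 0:999 * 100, end = 1:1000 * 100,
                     value = rexp(1000))
    sc <- scaleSignal99(tr)
    expect_equal(quantile(sc$value, 0.99, names = FALSE), 1)
    expect_equal(sc$value, tr$value / quantile(tr$value, 0.99, names = FALSE))
})

test_that("TSS assignment keeps the closest active gene per boundary", {
    g <- toyGenome(400, binSize = 3500)
    b <- mkBounds(g, c(100, 300))
    j1 <- 101 * 3500                      # junction coordinates
    j2 <- 301 * 3500
    tss <- data.frame(
        chrom = "c1",
        pos = c(j1 + 5000, j1 + 2000, j2 + 12000, j2 - 6000, j2 - 1000),
        gene = c("g5kb", "g2kb", "gfar", "g6kb", "ginactive"),
        active = c(TRUE, TRUE, TRUE, TRUE, FALSE))
    res <- assignTssToBoundaries(tss, b, maxDist = 10000)
    # boundary 100: the 2-kb gene beats the 5-kb gene
    expect_identical(res$gene[res$bin == 100], "g2kb")
    # boundary 300: the inactive gene wins the competition then is removed,
    # so the active 6-kb gene must NOT be attached to it
    expect_false(300 %in% res$bin)
    # a 12-kb TSS can never pair
    expect_false("gfar" %in% res$gene)
})
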