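smallParams <- function(...) {
    simParams(nChroms = 2L, chromLength = 100000L, ...)
}

test_that("generators are pure functions of (params, seed)", {
    p <- smallParams()
    s1 <- simulateGenome(p, 5)
    s2 <- simulateGenome(p, 5)
    expect_identical(s1$annotation@genes, s2$annotation@genes)
    expect_identical(s1$truth$regions, s2$truth$regions)
    s3 <- simulateGenome(p, 6)
    expect_false(identical(start(genes(s1$annotation)),
                           start(genes(s3$annotation))))

    t1 <- simulateAxisTrack(s1$annotation, s1$truth, p, 11)
    t2 <- simulateAxisTrack(s1$annotation, s1$truth, p, 11)
    expect_identical(t1, t2)

    e1 <- simulateExpression(s1$annotation, s1$truth, p, 12)
    e2 <- simulateExpression(s1$annotation, s1$truth, p, 12)
    expect_identical(e1, e2)

    m1 <- simulateMnase(s1$annotation, s1$truth, p, 13)
    m2 <- simulateMnase(s1$annotation, s1$truth, p, 13)
    expect_identical(m1, m2)

    # drawing from the generator does not disturb the session RNG
    set.seed(123); before <- get(".Random.seed", envir = globalenv())
    invisible(simulateGenome(p, 99))
    expect_identical(get(".Random.seed", envir = globalenv()), before)
})

test_that("simulated genomes respect their own structural invariants", {
    p <- smallParams()
    sim <- simulateGenome(p, 17)
    g <- genes(sim$annotation)
    expect_true(methods::validObject(sim$annotation))
    expect_gt(length(g), 50)
    # genes do not overlap: reducing loses no width
    red <- GenomicRanges::reduce(g, ignore.strand = TRUE)
    expect_identical(sum(width(red)), sum(width(g)))

    # truth regions tile each chromosome with alternating labels
    tr <- sim$truth$regions
    for (chr in seqlevels(tr)) {
        sub <- tr[as.character(seqnames(tr)) == chr]
        expect_identical(start(sub)[1], 1L)
        expect_identical(end(sub)[length(sub)], 100000L)
        if (length(sub) > 1) {
            expect_true(all(start(sub)[-1] == end(sub)[-length(sub)] + 1L))
            labs <- as.character(sub$label)
            expect_true(all(labs[-1] != labs[-length(labs)]))
        }
    }
    # per-gene truth labels match the interval truth
    isl <- sim$truth$islands
    mids <- GRanges(seqnames(g), IRanges(floor((start(g) - 1 + end(g)) / 2)
                                         + 1, width = 1))
    inIsland <- overlapsAny(mids, isl)
    expect_identical(unname(sim$truth$geneRegions == "island"), inIsland)

    # impossible parameters rejected up front
    expect_error(simulateGenome(simParams(geneMedianIsland = 50000,
                                          islandBlockLen = 10000), 1),
                 "exceed region block")
})

test_that("axis track: deterministic two-pathway structure", {
    # no peaks, no noise: the track is exactly the region baseline step
    p0 <- smallParams(peakAmplitude = 0, noiseCV = 0)
    sim <- simulateGenome(p0, 23)
    tr <- simulateAxisTrack(sim$annotation, sim$truth, p0, 24)
    reg <- sim$truth$regions
    for (i in sample(length(reg), 10)) {
        chr <- as.character(seqnames(reg))[i]
        expected <- if (reg$label[i] == "island") 1.5 else 1.0
        vals <- as.numeric(tr[[chr]])[start(reg)[i]:end(reg)[i]]
        expect_true(all(vals == expected))
    }

    # a single peak of amplitude A tops out at baseline + A at the 3' end
    p1 <- smallParams(peakAmplitude = 2, noiseCV = 0)
    si <- seqinfoFor(c(chrS = 20000L))
    lone <- GRanges("chrS", IRanges(5001, 6200), strand = "+", seqinfo = si)
    names(lone) <- "solo"
    ann1 <- annotationFromGRanges(lone)
    truth1 <- list(regions = GRanges("chrS", IRanges(1, 20000),
                                     label = factor("desert",
                                         levels = c("island", "desert")),
                                     seqinfo = si),
                   islands = GRanges(seqinfo = si),
                   geneRegions = c(solo = factor("desert",
                       levels = c("island", "desert"))))
    tr1 <- simulateAxisTrack(ann1, truth1, p1, 25)
    v <- as.numeric(tr1$chrS)
    expect_equal(v[6200], 1.0 + 2, tolerance = 1e-12)
    expect_equal(which.max(v), 6200L)
    expect_equal(v[1000], 1.0, tolerance = 1e-9)

    # island/desert mean signal ratio tracks the configured baselines
    p <- simParams()
    simD <- simulateGenome(p, 29)
    trD <- simulateAxisTrack(simD$annotation, simD$truth, p, 30)
    regD <- simD$truth$regions
    meanOver <- function(lab) {
        tot <- 0; n <- 0
        sel <- regD[regD$label == lab]
        for (i in seq_along(sel)) {
            chr <- as.character(seqnames(sel))[i]
            v <- as.numeric(trD[[chr]])[start(sel)[i]:end(sel)[i]]
            tot <- tot + sum(v); n <- n + length(v)
        }
        tot / n
    }
    ratio <- meanOver("island") / meanOver("desert")
    expect_equal(ratio, 1.5, tolerance = 0.075)
})

test_that("expression uplift behaves under null and default settings", {
    p0 <- simParams(exprDesertUplift = 0)   # ~500 genes on the 1 Mb default
    sim <- simulateGenome(p0, 31)
    e0 <- simulateExpression(sim$annotation, sim$truth, p0, 32)
    # null uplift: group means indistinguishable (log-scale Welch test)
    tt <- stats::t.test(log(e0$expression[e0$region == "desert"]),
                        log(e0$expression[e0$region == "island"]))
    expect_gt(tt$p.value, 0.01)
    r0 <- mean(e0$expression[e0$region == "desert"]) /
        mean(e0$expression[e0$region == "island"])
    expect_equal(r0, 1, tolerance = 0.2)
    expect_identical(e0$gene_id, names(genes(sim$annotation)))
})

test_that("nucleosome track is a phased, region-damped oscillation", {
    # undamped, noiseless: the ATG-aligned profile is exactly the cosine
    p <- smallParams(phasingDecayIsland = 1, phasingDecayDesert = 1,
                     noiseCV = 0, mnaseAmplitude = 0.5, nucPeriod = 165)
    sim <- simulateGenome(p, 41)
    mn <- simulateMnase(sim$annotation, sim$truth, p, 42)
    g <- genes(sim$annotation)
    # plus-strand genes only: the asymmetric [-flank, flank) window makes
    # reversed minus-strand rows sit one bp off the ATG by construction
    keep <- width(g) >= 400 & as.character(strand(g)) == "+"
    atg <- GenomicRanges::resize(g[keep], width = 1, fix = "start")
    pm <- anchorMatrix(mn, atg, flank = 200)
    prof <- colMeans(profileMatrix(pm))
    d <- 0:199  # downstream half of the window: inside every gene body
    expected <- 1 + 0.5 * cos(2 * pi * d / 165)
    expect_equal(unname(prof[201:400]), expected, tolerance = 1e-9)

    # slower island decay -> larger third oscillation in islands
    p2 <- smallParams(noiseCV = 0)
    sim2 <- simulateGenome(p2, 43)
    mn2 <- simulateMnase(sim2$annotation, sim2$truth, p2, 44)
    g2 <- genes(sim2$annotation)
    reg <- as.character(sim2$truth$geneRegions[names(g2)])
    long <- width(g2) >= 600
    ampAt3 <- function(sel) {
        atg <- GenomicRanges::resize(g2[sel], width = 1, fix = "start")
        pm <- anchorMatrix(mn2, atg, flank = 500)
        prof <- colMeans(profileMatrix(pm))
        # third nucleosome sits around +2 periods from the ATG
        pos <- 501 + round(2 * 165)
        prof[pos] - 1
    }
    expect_gt(ampAt3(long & reg == "island"), ampAt3(long & reg == "desert"))
})

test_that("simulated datasets round-trip through their standard formats", {
    p <- smallParams()
    sim <- simulateGenome(p, 51)
    tr <- simulateAxisTrack(sim$annotation, sim$truth, p, 52)
    ex <- simulateExpression(sim$annotation, sim$truth, p, 53)
    d <- tempfile()
    files <- writeSimulatedData(sim, tr, ex, d)
    ann <- readAnnotation(files[["genes"]], files[["sizes"]])
    expect_identical(start(genes(ann)), start(genes(sim$annotation)))
    expect_identical(names(genes(ann)), names(genes(sim$annotation)))
    back <- readTrack(files[["track"]], files[["sizes"]])
    expect_identical(as.numeric(back$chr01), as.numeric(tr$chr01))
    exBack <- read.delim(files[["expression"]])
    expect_equal(exBack$expression, ex$expression)
})
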