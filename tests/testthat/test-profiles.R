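test_that("anchor windows honour bounds, strand and midpoints", {
    tr <- trackFromVectors(list(chrI = as.numeric(1:5)))
    # anchor at the 3rd bp, flank 1: window holds bp 2..3; minus strand
    # reverses the row
    aPlus <- GRanges("chrI", IRanges(3, 3), strand = "+")
    aMinus <- GRanges("chrI", IRanges(3, 3), strand = "-")
    expect_equal(as.numeric(profileMatrix(anchorMatrix(tr, aPlus, 1))),
                 c(2, 3))
    expect_equal(as.numeric(profileMatrix(anchorMatrix(tr, aMinus, 1))),
                 c(3, 2))

    # constant track -> constant rows, any strand
    trc <- trackFromVectors(list(chrI = rep(4.5, 100)))
    anc <- GRanges("chrI", IRanges(c(20, 50, 80), width = 1),
                   strand = c("+", "-", "*"))
    pm <- anchorMatrix(trc, anc, 10)
    expect_true(all(profileMatrix(pm) == 4.5))
    expect_identical(droppedAnchors(pm), 0L)

    # out-of-bounds window dropped and counted
    near <- GRanges("chrI", IRanges(c(3, 50), width = 1))
    pm2 <- anchorMatrix(trc, near, 10)
    expect_identical(nrow(profileMatrix(pm2)), 1L)
    expect_identical(droppedAnchors(pm2), 1L)
    expect_error(anchorMatrix(trc, GRanges("chrI", IRanges(1, 1)), 200),
                 "no anchor window")

    # interval anchors are taken at their midpoint
    tr2 <- trackFromVectors(list(chrI = as.numeric(1:100)))
    iv <- GRanges("chrI", IRanges(40, 59))  # midpoint bp 50
    expect_equal(as.numeric(profileMatrix(anchorMatrix(tr2, iv, 2))),
                 c(48, 49, 50, 51))
})

test_that("unstranded anchors ignore the strand_aware flag", {
    set.seed(41)
    tr <- trackFromVectors(list(chrI = runif(500)))
    anc <- GRanges("chrI", IRanges(sample(50:450, 20), width = 1))
    m1 <- profileMatrix(anchorMatrix(tr, anc, 30, strandAware = TRUE))
    m2 <- profileMatrix(anchorMatrix(tr, anc, 30, strandAware = FALSE))
    expect_identical(m1, m2)
})

test_that("gene-scaled profiles average equal body sub-intervals", {
    tr <- trackFromVectors(list(chrI = as.numeric(0:9)))
    gPlus <- GRanges("chrI", IRanges(1, 10), strand = "+",
                     seqinfo = seqinfoFor(c(chrI = 10L)))
    names(gPlus) <- "gA"
    pm <- geneScaledMatrix(tr, annotationFromGRanges(gPlus), bodyBins = 2)
    expect_equal(as.numeric(profileMatrix(pm)), c(2, 7))

    gMinus <- gPlus
    strand(gMinus) <- "-"
    pmM <- geneScaledMatrix(tr, annotationFromGRanges(gMinus), bodyBins = 2)
    expect_equal(as.numeric(profileMatrix(pmM)), c(7, 2))

    # constant track: flat profile whatever the gene lengths
    trc <- trackFromVectors(list(chrI = rep(2.5, 2000)))
    gr <- GRanges("chrI", IRanges(c(11, 501, 1001), c(110, 850, 1900)),
                  strand = c("+", "-", "+"),
                  seqinfo = seqinfoFor(c(chrI = 2000L)))
    names(gr) <- c("a", "b", "c")
    pmc <- geneScaledMatrix(trc, annotationFromGRanges(gr), bodyBins = 10,
                            flank = 5)
    expect_true(all(profileMatrix(pmc) == 2.5))
    expect_identical(ncol(profileMatrix(pmc)), 20L)

    # a gene shorter than bodyBins bp is dropped with a count
    short <- GRanges("chrI", IRanges(c(11, 301), c(15, 800)),
                     strand = "+", seqinfo = seqinfoFor(c(chrI = 2000L)))
    names(short) <- c("tiny", "ok")
    pms <- geneScaledMatrix(trc, annotationFromGRanges(short), bodyBins = 10)
    expect_identical(nrow(profileMatrix(pms)), 1L)
    expect_identical(droppedAnchors(pms), 1L)
})

test_that("bootstrap confidence bands behave like percentile intervals", {
    # identical rows: zero-width interval equal to the mean
    mat <- matrix(rep(c(1, 2, 3, 4), each = 6), nrow = 6)
    pm <- methods::new("ProfileMatrix", mat = mat,
                       positions = as.numeric(1:4),
                       rowMeta = S4Vectors::DataFrame(id = letters[1:6]),
                       dropped = 0L, kind = "test")
    ci <- meanProfileCI(pm, nBoot = 200, seed = 3)
    expect_equal(ci$lower, ci$mean)
    expect_equal(ci$upper, ci$mean)
    expect_equal(ci$mean, c(1, 2, 3, 4))

    # two rows 0 and 2: percentile interval is [0, 2] with near certainty
    pm2 <- methods::new("ProfileMatrix", mat = matrix(c(0, 2), ncol = 1),
                        positions = 0,
                        rowMeta = S4Vectors::DataFrame(id = c("a", "b")),
                        dropped = 0L, kind = "test")
    ci2 <- meanProfileCI(pm2, nBoot = 1000, seed = 5)
    expect_equal(ci2$mean, 1)
    expect_equal(ci2$lower, 0)
    expect_equal(ci2$upper, 2)

    # deterministic given the seed; seed-to-seed wobble within 3 MC SEs
    set.seed(42)
    mat3 <- matrix(rnorm(50 * 8), nrow = 50)
    pm3 <- methods::new("ProfileMatrix", mat = mat3,
                        positions = as.numeric(1:8),
                        rowMeta = S4Vectors::DataFrame(
                            id = sprintf("r%02d", 1:50)),
                        dropped = 0L, kind = "test")
    ciA <- meanProfileCI(pm3, nBoot = 1000, seed = 7)
    ciA2 <- meanProfileCI(pm3, nBoot = 1000, seed = 7)
    expect_identical(ciA, ciA2)
    ciB <- meanProfileCI(pm3, nBoot = 1000, seed = 8)
    expect_identical(ciA$mean, ciB$mean)
    sdMean <- apply(mat3, 2, sd) / sqrt(nrow(mat3))
    mcSE <- sdMean * sqrt(0.025 * 0.975 / 1000) / dnorm(qnorm(0.975))
    expect_true(all(abs(ciA$lower - ciB$lower) < 3 * mcSE + 1e-12))
    expect_true(all(abs(ciA$upper - ciB$upper) < 3 * mcSE + 1e-12))

    expect_warning(ci1 <- meanProfileCI(methods::new("ProfileMatrix",
        mat = matrix(1:3, nrow = 1), positions = as.numeric(1:3),
        rowMeta = S4Vectors::DataFrame(id = "only"), dropped = 0L,
        kind = "test"), nBoot = 50, seed = 1), "single-row")
    expect_equal(ci1$lower, ci1$mean)
})

test_that("hotspot statistics: totals, densities and region medians", {
    v <- rep(0, 1000); v[101:200] <- 0.1; v[501:700] <- 0.05
    tr <- trackFromVectors(list(chrI = v))
    hs <- GRanges("chrI", IRanges(c(101, 501), c(200, 700)))
    names(hs) <- c("h1", "h2")
    st <- hotspotStats(tr, hs)
    expect_equal(st$hotspots$width, c(100L, 200L))
    expect_equal(st$hotspots$total, c(10, 10))
    expect_equal(st$hotspots$density, c(0.1, 0.05))

    zero <- hotspotStats(tr, GRanges("chrI", IRanges(900, 950)))
    expect_equal(zero$hotspots$total, 0)
    expect_equal(zero$hotspots$density, 0)

    set.seed(51)
    for (rep in 1:10) {
        vv <- runif(2000)
        trr <- trackFromVectors(list(chrI = vv))
        s <- sample(1:1500, 5); e <- s + sample(10:400, 5)
        hh <- GRanges("chrI", IRanges(s, pmin(e, 2000)))
        got <- hotspotStats(trr, hh)$hotspots$total
        want <- vapply(seq_along(hh), function(i)
            sum(vv[start(hh)[i]:end(hh)[i]]), numeric(1))
        expect_equal(got, want)
    }

    expect_error(hotspotStats(tr, GRanges("chrI", IRanges(990, 1200))),
                 "outside the genome")
})

test_that("width sorting is ascending with lexicographic id ties", {
    mat <- matrix(1:6, nrow = 3)
    pm <- methods::new("ProfileMatrix", mat = mat, positions = c(0, 1),
                       rowMeta = S4Vectors::DataFrame(
                           id = c("b", "c", "a"),
                           width = c(300L, 100L, 200L)),
                       dropped = 0L, kind = "hotspot")
    srt <- sortRowsByWidth(pm)
    expect_identical(rowMeta(srt)$width, c(100L, 200L, 300L))
    expect_identical(rowMeta(srt)$id, c("c", "a", "b"))

    ties <- methods::new("ProfileMatrix", mat = mat, positions = c(0, 1),
                         rowMeta = S4Vectors::DataFrame(
                             id = c("z", "x", "y"),
                             width = c(100L, 100L, 100L)),
                         dropped = 0L, kind = "hotspot")
    expect_identical(rowMeta(sortRowsByWidth(ties))$id, c("x", "y", "z"))

    one <- methods::new("ProfileMatrix", mat = mat[1, , drop = FALSE],
                        positions = c(0, 1),
                        rowMeta = S4Vectors::DataFrame(id = "a",
                                                       width = 5L),
                        dropped = 0L, kind = "hotspot")
    expect_identical(rowMeta(sortRowsByWidth(one))$id, "a")

    noW <- methods::new("ProfileMatrix", mat = mat, positions = c(0, 1),
                        rowMeta = S4Vectors::DataFrame(
                            id = c("a", "b", "c")),
                        dropped = 0L, kind = "hotspot")
    expect_error(sortRowsByWidth(noW), "width")
})
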