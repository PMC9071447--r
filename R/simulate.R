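#' Construct synthetic-data generator parameters
#'
#' Defaults emulate the budding-yeast island/desert architecture: region
#' blocks with exponential lengths whose medians are ~15 kb (islands) and
#' ~22.5 kb (deserts) giving an island fraction of 0.4; log-normal ORF
#' lengths with medians 1433 bp (islands) and 1218 bp (deserts);
#' intergenic sizes per pair class with desert medians exceeding island
#' medians by ~279 bp (divergent), ~124 bp (tandem) and ~55 bp
#' (convergent); a two-pathway axis signal (broad baseline 1.5 in islands
#' vs 1.0 in deserts, plus 200-bp-FWHM Gaussian peaks at gene 3' ends)
#' under multiplicative gamma noise with CV 0.3; desert expression 16.1%
#' above islands on the mean; and nucleosome phasing that decays more
#' slowly in islands than in deserts. The baseline ratio and peak
#' amplitude are free parameters of the generator, not measured values.
#'
#' @param nChroms,chromLength Number and length (bp) of chromosomes
#'   (defaults 4 x 250 kb = 1 Mb).
#' @param islandFraction Expected island fraction of the genome.
#' @param islandBlockLen Mean island block length, bp (exponential).
#' @param geneMedianIsland,geneMedianDesert Median ORF lengths, bp.
#' @param geneSdlog sdlog of the ORF-length log-normals.
#' @param intergenicMedianIsland,intergenicMedianDesert Named
#'   (convergent/tandem/divergent) median intergenic sizes, bp.
#' @param intergenicSdlog sdlog of the intergenic log-normals.
#' @param baselineIsland,baselineDesert Region baseline fold-enrichment.
#' @param peakAmplitude,peakWidth Gene 3'-end peak height and FWHM (bp).
#' @param noiseCV CV of the per-bp multiplicative gamma noise.
#' @param exprMeanlog,exprSdlog Island expression log-normal parameters.
#' @param exprDesertUplift Desert mean uplift (0.161 = +16.1%).
#' @param nucPeriod Nucleosome repeat length, bp.
#' @param phasingDecayIsland,phasingDecayDesert Per-nucleosome amplitude
#'   retention of the phased MNase signal.
#' @param mnaseAmplitude First-nucleosome oscillation amplitude.
#' @return A validated [SimParams-class].
#' @export
simParams <- function(nChroms = 4L, chromLength = 250000L,
                      islandFraction = 0.4,
                      islandBlockLen = 15000 / log(2),
                      geneMedianIsland = 1433, geneMedianDesert = 1218,
                      geneSdlog = 0.5,
                      intergenicMedianIsland = c(convergent = 187,
                                                 tandem = 315,
                                                 divergent = 326),
                      intergenicMedianDesert = c(convergent = 242,
                                                 tandem = 439,
                                                 divergent = 605),
                      intergenicSdlog = 0.6,
                      baselineIsland = 1.5, baselineDesert = 1.0,
                      peakAmplitude = 1.0, peakWidth = 200,
                      noiseCV = 0.3,
                      exprMeanlog = log(10), exprSdlog = 0.8,
                      exprDesertUplift = 0.161,
                      nucPeriod = 165,
                      phasingDecayIsland = 0.85,
                      phasingDecayDesert = 0.6,
                      mnaseAmplitude = 0.5) {
    methods::new("SimParams", nChroms = as.integer(nChroms),
                 chromLength = as.integer(chromLength),
                 islandFraction = islandFraction,
                 islandBlockLen = islandBlockLen,
                 geneMedianIsland = geneMedianIsland,
                 geneMedianDesert = geneMedianDesert,
                 geneSdlog = geneSdlog,
                 intergenicMedianIsland = intergenicMedianIsland,
                 intergenicMedianDesert = intergenicMedianDesert,
                 intergenicSdlog = intergenicSdlog,
                 baselineIsland = baselineIsland,
                 baselineDesert = baselineDesert,
                 peakAmplitude = peakAmplitude, peakWidth = peakWidth,
                 noiseCV = noiseCV,
                 exprMeanlog = exprMeanlog, exprSdlog = exprSdlog,
                 exprDesertUplift = exprDesertUplift,
                 nucPeriod = nucPeriod,
                 phasingDecayIsland = phasingDecayIsland,
                 phasingDecayDesert = phasingDecayDesert,
                 mnaseAmplitude = mnaseAmplitude)
}

setMethod("show", "SimParams", function(object) {
    cat(sprintf(paste0("SimParams: %d x %.0f kb chromosomes, island ",
                       "fraction %.2f\n  gene medians %d/%d bp, baselines ",
                       "%.2f/%.2f, peak A = %.2f, noise CV = %.2f\n"),
                object@nChroms, object@chromLength / 1000,
                object@islandFraction,
                round(object@geneMedianIsland),
                round(object@geneMedianDesert),
                object@baselineIsland, object@baselineDesert,
                object@peakAmplitude, object@noiseCV))
})

# Alternating island/desert blocks along one chromosome.
simBlocks <- function(params, L) {
    f <- params@islandFraction
    meanIsland <- params@islandBlockLen
    meanDesert <- meanIsland * (1 - f) / f
    state <- stats::rbinom(1L, 1L, f) == 1L  # TRUE = island
    starts <- integer(); ends <- integer(); labs <- character()
    cur <- 1L
    while (cur <= L) {
        len <- max(2000L, as.integer(round(stats::rexp(
            1L, 1 / if (state) meanIsland else meanDesert))))
        e <- min(cur + len - 1L, L)
        starts <- c(starts, cur); ends <- c(ends, e)
        labs <- c(labs, if (state) "island" else "desert")
        cur <- e + 1L
        state <- !state
    }
    data.frame(start = starts, end = ends, label = labs,
               stringsAsFactors = FALSE)
}

classifyPair <- function(leftStrand, rightStrand) {
    if (leftStrand == "+" && rightStrand == "-") "convergent"
    else if (leftStrand == "-" && rightStrand == "+") "divergent"
    else "tandem"
}

#' Simulate a genome annotation with planted island/desert truth
#'
#' Lays alternating island/desert blocks along each chromosome
#' (exponential lengths around the configured means) and places genes
#' left to right: each gene draws its length from the log-normal of the
#' region under the cursor, each gap draws from the log-normal of its
#' pair class (determined by the flanking strands, i.i.d. +/-) and
#' region. The result reproduces the island signature of longer genes,
#' shorter intergenic regions and higher coding density.
#'
#' @param params A [SimParams-class].
#' @param seed Integer seed; the generator is a pure function of
#'   (params, seed).
#' @return \code{list(annotation = GenomeAnnotation, truth = list(
#'   regions = labelled GRanges, islands = GRanges, geneRegions = named
#'   factor, params = params))}.
#' @export
simulateGenome <- function(params, seed) {
    stopifnot(methods::is(params, "SimParams"))
    methods::validObject(params)
    meanDesertBlock <- params@islandBlockLen *
        (1 - params@islandFraction) / params@islandFraction
    if (params@geneMedianIsland >= params@islandBlockLen ||
        params@geneMedianDesert >= meanDesertBlock)
        stop("gene lengths exceed region block lengths; adjust parameters")
    withSeed(seed, {
        chromNames <- sprintf("chr%02d", seq_len(params@nChroms))
        si <- Seqinfo(chromNames,
                      rep(params@chromLength, params@nChroms))
        regionList <- list(); geneList <- list()
        for (chr in chromNames) {
            L <- params@chromLength
            blocks <- simBlocks(params, L)
            regionList[[chr]] <- GRanges(chr, IRanges(blocks$start,
                                                      blocks$end),
                                         label = blocks$label,
                                         seqinfo = si)
            regionAt <- function(p) blocks$label[
                findInterval(p, blocks$start)]
            starts <- integer(); ends <- integer(); strs <- character()
            prevStrand <- sample(c("+", "-"), 1L)
            cur <- 1L + as.integer(round(stats::rlnorm(
                1L, log(params@intergenicMedianIsland[["tandem"]]),
                params@intergenicSdlog)) / 2)
            repeat {
                reg <- regionAt(min(cur, L))
                med <- if (reg == "island") params@geneMedianIsland
                       else params@geneMedianDesert
                len <- max(60L, as.integer(round(stats::rlnorm(
                    1L, log(med), params@geneSdlog))))
                if (cur + len - 1L > L) break
                starts <- c(starts, cur); ends <- c(ends, cur + len - 1L)
                strs <- c(strs, prevStrand)
                nextStrand <- sample(c("+", "-"), 1L)
                cls <- classifyPair(prevStrand, nextStrand)
                gapMed <- if (regionAt(min(cur + len, L)) == "island")
                    params@intergenicMedianIsland[[cls]]
                else params@intergenicMedianDesert[[cls]]
                gap <- max(1L, as.integer(round(stats::rlnorm(
                    1L, log(gapMed), params@intergenicSdlog))))
                cur <- cur + len + gap
                prevStrand <- nextStrand
                if (cur > L) break
            }
            if (length(starts))
                geneList[[chr]] <- GRanges(chr, IRanges(starts, ends),
                                           strand = strs, seqinfo = si)
        }
        genesGR <- unlist(methods::as(geneList, "GRangesList"),
                          use.names = FALSE)
        names(genesGR) <- sprintf("gene_%05d", seq_along(genesGR))
        regionsGR <- unlist(methods::as(regionList, "GRangesList"),
                            use.names = FALSE)
        mcols(regionsGR)$label <- factor(mcols(regionsGR)$label,
                                         levels = c("island", "desert"))
        islands <- regionsGR[mcols(regionsGR)$label == "island"]
        mids <- GRanges(seqnames(genesGR),
                        IRanges(midpointPos(genesGR), width = 1L))
        hit <- GenomicRanges::findOverlaps(mids, regionsGR)
        geneRegions <- mcols(regionsGR)$label[S4Vectors::subjectHits(hit)]
        names(geneRegions) <- names(genesGR)
        ann <- methods::new("GenomeAnnotation", genes = genesGR)
        list(annotation = ann,
             truth = list(regions = regionsGR,
                          islands = GenomicRanges::granges(islands),
                          geneRegions = geneRegions, params = params))
    })
}

# Per-chromosome numeric baseline from truth regions.
truthBaseline <- function(truth, params, chr, L) {
    v <- rep(params@baselineDesert, L)
    reg <- truth$regions
    isl <- reg[as.character(seqnames(reg)) == chr &
               mcols(reg)$label == "island"]
    for (i in seq_along(isl)) v[start(isl)[i]:end(isl)[i]] <-
        params@baselineIsland
    v
}

applyGammaNoise <- function(v, cv) {
    if (cv == 0) return(v)
    shape <- 1 / cv^2
    v * stats::rgamma(length(v), shape = shape, rate = shape)
}

#' Simulate an axis-protein fold-enrichment track
#'
#' The expected signal is the sum of the two recruitment pathways: a
#' broad region-level baseline (elevated across islands) and Gaussian
#' peaks at every gene 3' end (the gene-end pathway), multiplied by
#' per-bp gamma noise with mean 1 and the configured CV. With
#' \code{noiseCV = 0} the deterministic sum is returned exactly.
#'
#' @param annotation A [GenomeAnnotation-class] from [simulateGenome()].
#' @param truth The matching truth list.
#' @param params A [SimParams-class].
#' @param seed Integer seed.
#' @return An \code{RleList} coverage track.
#' @export
simulateAxisTrack <- function(annotation, truth, params, seed) {
    g <- genes(annotation)
    sl <- seqlengths(g)
    sdp <- params@peakWidth / (2 * sqrt(2 * log(2)))  # FWHM -> sd
    halfSupport <- as.integer(ceiling(4 * sdp))
    withSeed(seed, {
        out <- lapply(names(sl), function(chr) {
            L <- sl[[chr]]
            v <- truthBaseline(truth, params, chr, L)
            gg <- g[as.character(seqnames(g)) == chr]
            p3 <- ifelse(as.character(strand(gg)) == "+", end(gg),
                         start(gg))
            for (p in p3) {
                lo <- max(1L, p - halfSupport)
                hi <- min(L, p + halfSupport)
                d <- (lo:hi) - p
                v[lo:hi] <- v[lo:hi] +
                    params@peakAmplitude * exp(-0.5 * (d / sdp)^2)
            }
            S4Vectors::Rle(applyGammaNoise(v, params@noiseCV))
        })
        names(out) <- names(sl)
        methods::as(out, "RleList")
    })
}

#' Simulate per-gene expression with a desert uplift
#'
#' Log-normal expression per gene with a common sdlog; desert genes have
#' their meanlog shifted by \code{log(1 + uplift)} so the desert group
#' mean exceeds the island mean by the configured fraction (16.1% at the
#' default).
#'
#' @inheritParams simulateAxisTrack
#' @return data.frame \code{gene_id}, \code{region}, \code{expression}.
#' @export
simulateExpression <- function(annotation, truth, params, seed) {
    g <- genes(annotation)
    reg <- as.character(truth$geneRegions[names(g)])
    withSeed(seed, {
        meanlog <- ifelse(reg == "desert",
                          params@exprMeanlog +
                              log(1 + params@exprDesertUplift),
                          params@exprMeanlog)
        data.frame(gene_id = names(g), region = reg,
                   expression = stats::rlnorm(length(g), meanlog,
                                              params@exprSdlog),
                   stringsAsFactors = FALSE)
    })
}

#' Simulate an MNase-like nucleosome occupancy track
#'
#' Inside each gene, occupancy oscillates from the ATG with the
#' configured nucleosome period; the oscillation amplitude is damped by
#' the region-specific per-nucleosome decay factor (islands decay more
#' slowly, i.e. are better phased). Background occupancy is 1, and
#' multiplicative gamma noise is applied as for the axis track.
#'
#' @inheritParams simulateAxisTrack
#' @return An \code{RleList} coverage track.
#' @export
simulateMnase <- function(annotation, truth, params, seed) {
    g <- genes(annotation)
    sl <- seqlengths(g)
    reg <- as.character(truth$geneRegions[names(g)])
    withSeed(seed, {
        out <- lapply(names(sl), function(chr) {
            L <- sl[[chr]]
            v <- rep(1, L)
            sel <- which(as.character(seqnames(g)) == chr)
            for (i in sel) {
                w <- width(g)[i]
                d <- seq_len(w) - 1  # distance from the ATG into the body
                decay <- if (reg[i] == "island") params@phasingDecayIsland
                         else params@phasingDecayDesert
                osc <- params@mnaseAmplitude * decay^(d / params@nucPeriod) *
                    cos(2 * pi * d / params@nucPeriod)
                if (as.character(strand(g)[i]) == "+")
                    v[start(g)[i]:end(g)[i]] <- 1 + osc
                else
                    v[end(g)[i]:start(g)[i]] <- 1 + osc
            }
            S4Vectors::Rle(applyGammaNoise(v, params@noiseCV))
        })
        names(out) <- names(sl)
        methods::as(out, "RleList")
    })
}

#' Write a simulated dataset in standard pipeline input formats
#'
#' Emits the genes as BED6, the chromosome sizes, the planted truth as
#' BED (label in the name field), the axis track as bedGraph, and the
#' expression table as TSV — the same formats the analysis stages read.
#'
#' @param sim Output of [simulateGenome()].
#' @param track Optional \code{RleList} axis track.
#' @param expression Optional expression data.frame.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the files written.
#' @export
writeSimulatedData <- function(sim, track = NULL, expression = NULL, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    g <- genes(sim$annotation)
    files <- c(genes = file.path(dir, "genes.bed"),
               sizes = file.path(dir, "genome.chrom.sizes"),
               truth = file.path(dir, "truth_regions.bed"))
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                       as.character(seqnames(g)), start(g) - 1L, end(g),
                       names(g), as.character(strand(g))),
               files[["genes"]])
    writeChromSizes(seqinfo(g), files[["sizes"]])
    tr <- sim$truth$regions
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.",
                       as.character(seqnames(tr)), start(tr) - 1L, end(tr),
                       as.character(mcols(tr)$label)),
               files[["truth"]])
    if (!is.null(track)) {
        files[["track"]] <- file.path(dir, "axis_track.bedgraph")
        writeTrack(track, files[["track"]])
    }
    if (!is.null(expression)) {
        files[["expression"]] <- file.path(dir, "expression.tsv")
        utils::write.table(expression, files[["expression"]], sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    invisible(files)
}
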