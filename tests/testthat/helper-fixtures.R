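suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
    library(GenomeInfoDb)
})

seqinfoFor <- function(lens) Seqinfo(names(lens), unname(lens))

# Build a GenomeAnnotation from a compact description: list of
# (start, end, strand) entries.
annFor <- function(genes, lens, ids = NULL) {
    if (is.null(ids)) ids <- sprintf("g%02d", seq_along(genes))
    gr <- GRanges(vapply(genes, function(g) g$chrom %||% names(lens)[1],
                         character(1)),
                  IRanges(vapply(genes, function(g) g$start, numeric(1)),
                          vapply(genes, function(g) g$end, numeric(1))),
                  strand = vapply(genes, function(g) g$strand, character(1)),
                  seqinfo = seqinfoFor(lens))
    names(gr) <- ids
    annotationFromGRanges(gr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tmpChromSizes <- function(lens) {
    f <- tempfile(fileext = ".sizes")
    writeLines(sprintf("%s\t%d", names(lens), as.integer(lens)), f)
    f
}

# ---- independent oracles -------------------------------------------------

# Per-bp membership scan for coding density.
bruteCodingDensity <- function(geneDf, binStart, binEnd) {
    covered <- logical(binEnd - binStart + 1)
    for (i in seq_len(nrow(geneDf))) {
        s <- max(geneDf$start[i], binStart)
        e <- min(geneDf$end[i], binEnd)
        if (s <= e) covered[(s:e) - binStart + 1] <- TRUE
    }
    mean(covered)
}

# Independent island caller: population-SD threshold, run scan per chrom.
bruteCallIslands <- function(scoresByChrom, binBoundsByChrom, k = 1.75) {
    allScores <- unlist(scoresByChrom, use.names = FALSE)
    thr <- k * sqrt(mean((allScores - mean(allScores))^2))
    out <- list()
    for (chr in names(scoresByChrom)) {
        sc <- scoresByChrom[[chr]]
        bb <- binBoundsByChrom[[chr]]  # data.frame(start, end)
        enr <- sc >= thr
        lab <- character(0); st <- integer(0); en <- integer(0)
        i <- 1L
        while (i <= length(sc)) {
            j <- i
            while (j < length(sc) && enr[j + 1L] == enr[i]) j <- j + 1L
            lab <- c(lab, if (enr[i]) "island" else "desert")
            st <- c(st, bb$start[i]); en <- c(en, bb$end[j])
            i <- j + 1L
        }
        out[[chr]] <- data.frame(chrom = chr, start = st, end = en,
                                 label = lab, stringsAsFactors = FALSE)
    }
    list(threshold = thr, regions = do.call(rbind, out))
}

# Exhaustive Mann-Whitney via midrank sums (distinct algorithm from the
# package's doubled-U comparison count).
oracleMannWhitneyP <- function(a, b) {
    pool <- c(a, b)
    n <- length(pool); n1 <- length(a)
    r <- rank(pool)  # midranks
    centre <- n1 * (n - n1) / 2
    uFromIdx <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
    obs <- abs(uFromIdx(seq_len(n1)) - centre)
    devs <- combn(n, n1, function(idx) abs(uFromIdx(idx) - centre))
    mean(devs >= obs - 1e-9)
}

# AUC as the Mann-Whitney pair-concordance statistic (ties count 1/2).
concordanceAUC <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
}

# Bin-level Jaccard of called vs true island labels.
binJaccard <- function(binned, partition, truthRegions) {
    called <- assignRegions(binned, partition)
    mids <- GRanges(seqnames(binned),
                    IRanges(floor((start(binned) - 1 + end(binned)) / 2) + 1,
                            width = 1))
    hit <- findOverlaps(mids, truthRegions)
    trueLab <- truthRegions$label[subjectHits(hit)]
    inter <- sum(called == "island" & trueLab == "island")
    uni <- sum(called == "island" | trueLab == "island")
    if (uni == 0) return(NA_real_)
    inter / uni
}
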