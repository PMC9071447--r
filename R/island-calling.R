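#' Segment a binned signal into islands and deserts
#'
#' Classifies a bin as enriched when its score is greater than or equal to
#' \code{k} times the standard deviation of the signal across the genome
#' (default \code{k = 1.75}); maximal runs of enriched bins within a
#' chromosome are joined into islands and the remainder of each chromosome
#' becomes deserts. Joining never crosses a chromosome boundary, ties at
#' the threshold count as enriched, and a single enriched bin is an
#' island.
#'
#' The threshold is literally \code{k x SD} with no mean offset; an
#' alternative \code{mean + k x SD} mode is available via \code{mode}.
#' The SD is by default the population SD of the per-bin scores; sample
#' SD and per-bp SD (computed from \code{track}) are exposed because the
#' choice is a genuine analysis knob.
#'
#' @param binned Binned signal from [binSignal()] (a \code{GRanges} with
#'   \code{score}).
#' @param k Threshold multiplier (default 1.75).
#' @param mode \code{"sd"} (threshold = k x SD) or \code{"mean_plus_sd"}
#'   (threshold = mean + k x SD).
#' @param sdMethod \code{"population"} (divide by n) or \code{"sample"}
#'   (divide by n - 1).
#' @param sdScope \code{"bins"} (SD of bin scores, the default unit of
#'   classification) or \code{"bp"} (SD of the per-bp track, which must
#'   then be supplied as \code{track}).
#' @param track Per-bp \code{RleList}; required when \code{sdScope="bp"}.
#' @return A [RegionPartition-class].
#' @examples
#' ## bin scores c(0.5, 2, 2.2, 0.4) at k = 1.75: population SD 0.8288,
#' ## threshold 1.4504, one island spanning the middle two bins
#' @export
callIslands <- function(binned, k = 1.75, mode = c("sd", "mean_plus_sd"),
                        sdMethod = c("population", "sample"),
                        sdScope = c("bins", "bp"), track = NULL) {
    mode <- match.arg(mode)
    sdMethod <- match.arg(sdMethod)
    sdScope <- match.arg(sdScope)
    stopifnot(methods::is(binned, "GRanges"))
    scores <- mcols(binned)$score
    if (is.null(scores) || length(scores) < 2L)
        stop("need a binned signal with at least 2 bins")
    if (any(!is.finite(scores))) stop("non-finite bin score")
    if (sdScope == "bins") {
        n <- length(scores)
        mu <- mean(scores)
        ss <- sum((scores - mu)^2)
        sdev <- sqrt(ss / if (sdMethod == "population") n else n - 1L)
    } else {
        if (is.null(track)) stop("sdScope='bp' requires the per-bp track")
        m <- rleMoments(track)
        mu <- m$mean
        sdev <- sqrt(m$var * if (sdMethod == "population") 1
                     else m$n / (m$n - 1))
    }
    threshold <- k * sdev + if (mode == "mean_plus_sd") mu else 0
    enriched <- scores >= threshold
    if (sdev == 0)
        warning("signal SD is zero; segmentation is degenerate")
    else if (all(enriched))
        warning("threshold below every bin score; every bin is enriched")
    else if (!any(enriched))
        warning("threshold above every bin score; no islands called")
    # run-scan per chromosome: maximal runs of equal enrichment state
    chrVec <- as.character(seqnames(binned))
    bStart <- start(binned); bEnd <- end(binned)
    outChr <- character(); outS <- integer(); outE <- integer()
    outLab <- character()
    for (chr in seqlevels(binned)) {
        idx <- which(chrVec == chr)
        if (!length(idx)) next
        r <- rle(enriched[idx])
        last <- cumsum(r$lengths)
        first <- c(1L, utils::head(last, -1L) + 1L)
        outChr <- c(outChr, rep(chr, length(last)))
        outS <- c(outS, bStart[idx][first])
        outE <- c(outE, bEnd[idx][last])
        outLab <- c(outLab, ifelse(r$values, "island", "desert"))
    }
    regions <- GRanges(outChr, IRanges(outS, outE),
                       label = factor(outLab,
                                      levels = c("island", "desert")),
                       seqinfo = seqinfo(binned))
    bs <- metadata(binned)$bin_size
    if (is.null(bs)) bs <- max(width(binned))
    methods::new("RegionPartition", regions = regions,
                 binSize = as.numeric(bs), k = k,
                 threshold = as.numeric(threshold), mode = mode)
}

#' @rdname RegionPartition-class
#' @param x,object A \code{RegionPartition}.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname RegionPartition-class
#' @export
setMethod("regions", "RegionPartition", function(x) x@regions)

#' @rdname RegionPartition-class
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname RegionPartition-class
#' @export
setMethod("threshold", "RegionPartition", function(x) x@threshold)

setMethod("show", "RegionPartition", function(object) {
    lab <- mcols(object@regions)$label
    w <- width(object@regions)
    cat(sprintf(paste0("RegionPartition: %d islands (%.3f Mb), ",
                       "%d deserts (%.3f Mb)\n  bin %d bp, k = %.3g, ",
                       "threshold = %.4g (%s)\n"),
                sum(lab == "island"),
                sum(as.numeric(w[lab == "island"])) / 1e6,
                sum(lab == "desert"),
                sum(as.numeric(w[lab == "desert"])) / 1e6,
                as.integer(object@binSize), object@k, object@threshold,
                object@mode))
})

#' Assign features to islands or deserts by midpoint
#'
#' A feature takes the label of the region containing its midpoint
#' (half-open convention: the midpoint of [start0, end0) is
#' floor((start0 + end0) / 2)), so a feature straddling a boundary is
#' assigned deterministically.
#'
#' @param features \code{GRanges} of features within the genome.
#' @param partition A [RegionPartition-class].
#' @return Factor of labels (\code{island}/\code{desert}), one per feature.
#' @export
assignRegions <- function(features, partition) {
    stopifnot(methods::is(features, "GRanges"),
              methods::is(partition, "RegionPartition"))
    if (!length(features))
        return(factor(character(), levels = c("island", "desert")))
    mids <- GRanges(seqnames(features),
                    IRanges(midpointPos(features), width = 1L))
    hits <- GenomicRanges::findOverlaps(mids, regions(partition),
                                        ignore.strand = TRUE)
    if (length(hits) != length(features))
        stop("feature midpoint outside the partitioned genome")
    mcols(regions(partition))$label[S4Vectors::subjectHits(hits)]
}

#' Region-level summary statistics
#'
#' Per-region mean signal and/or feature density, plus island-vs-desert
#' group summaries (median and quartiles). Features are counted in the
#' region holding their midpoint, matching [assignRegions()].
#'
#' @param partition A [RegionPartition-class].
#' @param track Optional \code{RleList} signal track.
#' @param features Optional \code{GRanges} of features (e.g. hotspots).
#' @return A list of class \code{"RegionStats"}: \code{$regions}, a
#'   data.frame with one row per region (label, length, mean signal,
#'   feature count, features per kb), and \code{$groups}, per-label
#'   summaries; empty groups yield NA summaries and are flagged in
#'   \code{$undefined_groups}.
#' @export
regionSummary <- function(partition, track = NULL, features = NULL) {
    stopifnot(methods::is(partition, "RegionPartition"))
    reg <- regions(partition)
    df <- data.frame(chrom = as.character(seqnames(reg)),
                     start = start(reg), end = end(reg),
                     label = mcols(reg)$label,
                     length = width(reg),
                     stringsAsFactors = FALSE)
    if (!is.null(track)) {
        checkTrack(track)
        scored <- binnedAverage(GenomicRanges::granges(reg),
                                methods::as(track, "RleList"), "mean_signal")
        df$mean_signal <- mcols(scored)$mean_signal
    }
    if (!is.null(features)) {
        mids <- GRanges(seqnames(features),
                        IRanges(midpointPos(features), width = 1L))
        hits <- GenomicRanges::findOverlaps(mids, reg, ignore.strand = TRUE)
        cnt <- tabulate(S4Vectors::subjectHits(hits), nbins = length(reg))
        df$n_features <- cnt
        df$features_per_kb <- cnt / (df$length / 1000)
    }
    qsum <- function(v) {
        if (!length(v) || all(is.na(v)))
            return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
        c(median = unname(q[2L]), q1 = unname(q[1L]), q3 = unname(q[3L]))
    }
    groups <- lapply(c(island = "island", desert = "desert"), function(lb) {
        sub <- df[df$label == lb, , drop = FALSE]
        out <- list(n = nrow(sub), total_bp = sum(as.numeric(sub$length)))
        if (!is.null(df$mean_signal))
            out$mean_signal <- qsum(sub$mean_signal)
        if (!is.null(df$features_per_kb)) {
            out$features_per_kb <- qsum(sub$features_per_kb)
            out$n_features <- sum(sub$n_features)
        }
        out
    })
    structure(list(regions = df, groups = groups,
                   undefined_groups = names(groups)[
                       vapply(groups, function(g) g$n == 0L, TRUE)]),
              class = "RegionStats")
}

#' @export
print.RegionStats <- function(x, ...) {
    cat("RegionStats:", nrow(x$regions), "regions\n")
    for (lb in names(x$groups)) {
        g <- x$groups[[lb]]
        cat(sprintf("  %s: n = %d, %.3f Mb", lb, g$n, g$total_bp / 1e6))
        if (!is.null(g$mean_signal))
            cat(sprintf(", median signal = %.4g", g$mean_signal[["median"]]))
        cat("\n")
    }
    if (length(x$undefined_groups))
        cat("  undefined groups:", paste(x$undefined_groups, collapse = ", "),
            "\n")
    invisible(x)
}

#' Two-group comparison: Mann-Whitney or Welch t
#'
#' \code{mann_whitney}: two-sided Mann-Whitney-Wilcoxon test; for
#' \code{n1 + n2 <= 12} the p-value is computed by exhaustive enumeration
#' of all group labelings of the pooled values (ties contribute 1/2 to U,
#' and the p-value is the probability of a U at least as far from its null
#' mean \code{n1 n2 / 2} as observed), otherwise by the tie-corrected
#' normal approximation of \code{stats::wilcox.test}.
#' \code{welch_t}: Welch's unequal-variance t-test via
#' \code{stats::t.test}; the zero-variance degenerate case returns p = 1
#' (equal means) or p = 0 with a warning rather than an error.
#'
#' @param a,b Numeric vectors (group sizes >= 1; >= 2 for welch_t).
#' @param test \code{"mann_whitney"} or \code{"welch_t"}.
#' @return A list of class \code{"TestResult"}: \code{test},
#'   \code{statistic}, \code{p.value}, \code{n1}, \code{n2}, \code{exact}.
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))$p.value  # exact two-sided 0.1
#' @export
compareGroups <- function(a, b, test = c("mann_whitney", "welch_t")) {
    test <- match.arg(test)
    a <- as.numeric(a); b <- as.numeric(b)
    n1 <- length(a); n2 <- length(b)
    if (test == "mann_whitney") {
        stopifnot(n1 >= 1L, n2 >= 1L)
        u <- uStatistic(a, b)
        if (length(unique(c(a, b))) == 1L) {
            warning("all values identical in both groups; p = 1")
            return(testResult(test, u, 1, n1, n2, exact = TRUE))
        }
        if (n1 + n2 <= 12L) {
            p <- exactMannWhitneyP(a, b)
            return(testResult(test, u, p, n1, n2, exact = TRUE))
        }
        wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                  correct = TRUE))
        testResult(test, u, wt$p.value, n1, n2, exact = FALSE)
    } else {
        stopifnot(n1 >= 2L, n2 >= 2L)
        if (stats::var(a) == 0 && stats::var(b) == 0) {
            warning("zero variance in both groups; degenerate Welch test")
            same <- isTRUE(all.equal(mean(a), mean(b)))
            return(testResult(test, if (same) 0 else Inf,
                              if (same) 1 else 0, n1, n2, exact = FALSE))
        }
        tt <- stats::t.test(a, b, var.equal = FALSE)
        testResult(test, unname(tt$statistic), tt$p.value, n1, n2,
                   exact = FALSE)
    }
}

testResult <- function(test, statistic, p, n1, n2, exact) {
    structure(list(test = test, statistic = statistic,
                   p.value = min(max(p, 0), 1), n1 = n1, n2 = n2,
                   exact = exact),
              class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
    cat(sprintf("%s: statistic = %.6g, p = %.4g (n1 = %d, n2 = %d%s)\n",
                x$test, x$statistic, x$p.value, x$n1, x$n2,
                if (x$exact) ", exact" else ""))
    invisible(x)
}

# Mann-Whitney U of group a over group b, ties counting 1/2.
uStatistic <- function(a, b) {
    sum(vapply(a, function(x) sum(x > b) + 0.5 * sum(x == b), numeric(1L)))
}

# Exhaustive two-sided p over all C(n1+n2, n1) labelings of the pooled
# values. Works with ties; uses doubled-U integers for exact comparison.
exactMannWhitneyP <- function(a, b) {
    pool <- c(a, b)
    n <- length(pool); n1 <- length(a)
    u2obs <- round(2 * uStatistic(a, b))
    centre2 <- n1 * (n - n1)  # 2 * n1*n2/2
    devObs <- abs(u2obs - centre2)
    combos <- utils::combn(n, n1)
    devs <- apply(combos, 2L, function(idx) {
        abs(round(2 * uStatistic(pool[idx], pool[-idx])) - centre2)
    })
    mean(devs >= devObs)
}

#' Export a region partition as BED6
#'
#' One record per region, label in the name field and the region mean
#' signal (when a track is given) in the score field.
#'
#' @param partition A [RegionPartition-class].
#' @param path Output BED path.
#' @param track Optional \code{RleList} used to fill the score column.
#' @return Invisibly, \code{path}.
#' @export
writeRegionsBed <- function(partition, path, track = NULL) {
    reg <- regions(partition)
    score <- rep(0, length(reg))
    if (!is.null(track)) {
        scored <- binnedAverage(GenomicRanges::granges(reg),
                                methods::as(track, "RleList"), "s")
        score <- mcols(scored)$s
    }
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t.",
                       as.character(seqnames(reg)), start(reg) - 1L,
                       end(reg), as.character(mcols(reg)$label),
                       sprintf("%.8g", score)),
               path)
    invisible(path)
}

#' Read a region partition from a BED file written by [writeRegionsBed()]
#'
#' @param path BED path (name field = island/desert label).
#' @param chromSizes chrom.sizes TSV path or \code{Seqinfo}.
#' @param binSize Bin size to record on the partition (default 5000).
#' @return A [RegionPartition-class].
#' @export
readRegionsBed <- function(path, chromSizes, binSize = 5000) {
    si <- if (methods::is(chromSizes, "Seqinfo")) chromSizes
          else readChromSizes(chromSizes)
    gr <- rtracklayer::import(path, format = "bed")
    lab <- factor(gr$name, levels = c("island", "desert"))
    if (anyNA(lab)) stop("region name field must be 'island' or 'desert'")
    mcols(gr) <- DataFrame(label = lab)
    seqlevels(gr) <- seqlevels(si)
    seqinfo(gr) <- si
    methods::new("RegionPartition",
                 regions = sort(gr, ignore.strand = TRUE),
                 binSize = as.numeric(binSize), k = NA_real_,
                 threshold = NA_real_, mode = "sd")
}
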