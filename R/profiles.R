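#' Anchor-centered signal matrix
#'
#' Extracts a window of per-bp signal around each anchor: for an anchor at
#' position p the row covers offsets \code{-flank .. flank-1} relative to
#' p. Anchors of width > 1 (e.g. hotspot intervals) are represented by
#' their midpoint. With \code{strandAware = TRUE}, rows of minus-strand
#' anchors are reversed so that all rows read 5' to 3'. Windows running
#' off a chromosome end are dropped and counted, keeping every column at
#' the same sample size for the bootstrap.
#'
#' @param track An \code{RleList} coverage track.
#' @param anchors \code{GRanges} of anchors; names become row ids, mcols
#'   (e.g. \code{width}, \code{label}) are carried into the row metadata.
#' @param flank Half-window size in bp (>= 1).
#' @param strandAware Reverse minus-strand rows (default TRUE).
#' @param kind Label recorded on the matrix (default "anchor").
#' @return A [ProfileMatrix-class].
#' @export
anchorMatrix <- function(track, anchors, flank, strandAware = TRUE,
                         kind = "anchor") {
    checkTrack(track)
    stopifnot(methods::is(anchors, "GRanges"), flank >= 1)
    flank <- as.integer(flank)
    sl <- trackSeqlengths(track)
    chrs <- as.character(seqnames(anchors))
    bad <- setdiff(unique(chrs), names(sl))
    if (length(bad)) stop("anchor on unknown chromosome: ",
                          paste(bad, collapse = ", "))
    pos <- midpointPos(anchors)
    ids <- if (!is.null(names(anchors))) names(anchors)
           else sprintf("anchor_%04d", seq_along(anchors))
    keep <- pos - flank >= 1L & pos + flank - 1L <= sl[chrs]
    dropped <- sum(!keep)
    if (!any(keep)) stop("no anchor window fits inside the genome")
    anchors <- anchors[keep]; pos <- pos[keep]; chrs <- chrs[keep]
    ids <- ids[keep]
    offs <- seq.int(-flank, flank - 1L)
    mat <- matrix(NA_real_, nrow = length(anchors), ncol = 2L * flank)
    for (chr in unique(chrs)) {
        i <- which(chrs == chr)
        vals <- as.numeric(track[[chr]])
        idx <- outer(pos[i], offs, `+`)
        mat[i, ] <- vals[idx]
    }
    str <- as.character(strand(anchors))
    if (strandAware) {
        neg <- which(str == "-")
        if (length(neg)) mat[neg, ] <- mat[neg, ncol(mat):1L, drop = FALSE]
    }
    rownames(mat) <- ids
    meta <- DataFrame(id = ids, chrom = chrs, pos = pos, strand = str)
    extra <- mcols(anchors)
    if (ncol(extra)) meta <- cbind(meta, extra)
    methods::new("ProfileMatrix", mat = mat, positions = as.numeric(offs),
                 rowMeta = meta, dropped = as.integer(dropped), kind = kind)
}

#' Gene-scaled (metagene) signal matrix
#'
#' Each gene body is rescaled to \code{bodyBins} positions (the mean
#' signal over \code{bodyBins} equal sub-intervals of the body), with
#' optional fixed-bp flanks on either side; minus-strand genes are
#' reversed so rows run 5' to 3'. Genes shorter than \code{bodyBins} bp,
#' or whose flanks leave the chromosome, are dropped and counted.
#'
#' @param track An \code{RleList} coverage track.
#' @param annotation A [GenomeAnnotation-class] (or a stranded, named
#'   \code{GRanges} of genes).
#' @param bodyBins Number of scaled body positions (>= 2; default 50).
#' @param flank Flank size in real bp on each side (default 0).
#' @return A [ProfileMatrix-class]; columns are \code{-flank..-1}, scaled
#'   body positions \code{1..bodyBins}, then \code{bodyBins+1..bodyBins+flank}.
#' @export
geneScaledMatrix <- function(track, annotation, bodyBins = 50, flank = 0) {
    checkTrack(track)
    stopifnot(bodyBins >= 2)
    g <- if (methods::is(annotation, "GenomeAnnotation")) genes(annotation)
         else annotation
    bodyBins <- as.integer(bodyBins); flank <- as.integer(flank)
    sl <- trackSeqlengths(track)
    chrs <- as.character(seqnames(g))
    keep <- width(g) >= bodyBins &
        start(g) - flank >= 1L & end(g) + flank <= sl[chrs]
    dropped <- sum(!keep)
    if (!any(keep)) stop("no gene usable for the scaled profile")
    g <- g[keep]; chrs <- chrs[keep]
    ids <- if (!is.null(names(g))) names(g) else sprintf("gene_%04d", seq_along(g))
    ncolTot <- 2L * flank + bodyBins
    mat <- matrix(NA_real_, nrow = length(g), ncol = ncolTot)
    cache <- new.env(parent = emptyenv())
    for (r in seq_along(g)) {
        chr <- chrs[r]
        if (is.null(cache[[chr]])) cache[[chr]] <- as.numeric(track[[chr]])
        vals <- cache[[chr]]
        s <- start(g)[r]; e <- end(g)[r]; L <- e - s + 1L
        bnd <- s + floor(L * (0:bodyBins) / bodyBins)  # sub-interval bounds
        body <- vapply(seq_len(bodyBins), function(j)
            mean(vals[bnd[j]:(bnd[j + 1L] - 1L)]), numeric(1L))
        row <- c(if (flank > 0L) vals[(s - flank):(s - 1L)], body,
                 if (flank > 0L) vals[(e + 1L):(e + flank)])
        if (as.character(strand(g)[r]) == "-") row <- rev(row)
        mat[r, ] <- row
    }
    rownames(mat) <- ids
    positions <- c(if (flank > 0L) seq.int(-flank, -1L), seq_len(bodyBins),
                   if (flank > 0L) bodyBins + seq_len(flank))
    meta <- DataFrame(id = ids, chrom = chrs, pos = start(g),
                      strand = as.character(strand(g)), width = width(g))
    methods::new("ProfileMatrix", mat = mat, positions = as.numeric(positions),
                 rowMeta = meta, dropped = as.integer(dropped),
                 kind = "gene_scaled")
}

#' @rdname ProfileMatrix-class
#' @param x,object A \code{ProfileMatrix}.
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname ProfileMatrix-class
#' @export
setMethod("profileMatrix", "ProfileMatrix", function(x) x@mat)

#' @rdname ProfileMatrix-class
#' @export
setGeneric("rowMeta", function(x) standardGeneric("rowMeta"))

#' @rdname ProfileMatrix-class
#' @export
setMethod("rowMeta", "ProfileMatrix", function(x) x@rowMeta)

#' @rdname ProfileMatrix-class
#' @export
setGeneric("droppedAnchors", function(x) standardGeneric("droppedAnchors"))

#' @rdname ProfileMatrix-class
#' @export
setMethod("droppedAnchors", "ProfileMatrix", function(x) x@dropped)

setMethod("show", "ProfileMatrix", function(object) {
    cat(sprintf("ProfileMatrix (%s): %d anchors x %d positions (%d dropped)\n",
                object@kind, nrow(object@mat), ncol(object@mat),
                object@dropped))
})

#' Mean profile with percentile-bootstrap confidence band
#'
#' Column means of a profile matrix with a pointwise bootstrap confidence
#' interval: rows (anchors) are resampled with replacement \code{nBoot}
#' times (default 1000) and the interval is the percentile band of the
#' resampled column means (2.5% and 97.5% for \code{level = 0.95}).
#' Deterministic given \code{seed}.
#'
#' @param pm A [ProfileMatrix-class].
#' @param nBoot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @return A data.frame with columns \code{position}, \code{mean},
#'   \code{lower}, \code{upper}; attributes \code{nBoot}, \code{level},
#'   \code{seed}, \code{n}.
#' @export
meanProfileCI <- function(pm, nBoot = 1000, level = 0.95, seed = 1L) {
    stopifnot(methods::is(pm, "ProfileMatrix"), nBoot >= 1, level > 0,
              level < 1)
    mat <- pm@mat
    n <- nrow(mat)
    if (n < 1L) stop("profile matrix has no rows")
    mu <- colMeans(mat)
    if (n == 1L) {
        warning("single-row profile matrix; CI collapses to the row")
        lo <- hi <- mu
    } else {
        alpha <- (1 - level) / 2
        bootMeans <- withSeed(seed, {
            bm <- matrix(0, nrow = nBoot, ncol = ncol(mat))
            for (b in seq_len(nBoot)) {
                i <- sample.int(n, n, replace = TRUE)
                bm[b, ] <- colMeans(mat[i, , drop = FALSE])
            }
            bm
        })
        qs <- apply(bootMeans, 2L, stats::quantile,
                    probs = c(alpha, 1 - alpha), names = FALSE)
        lo <- qs[1L, ]; hi <- qs[2L, ]
    }
    structure(data.frame(position = pm@positions, mean = mu,
                         lower = lo, upper = hi),
              nBoot = as.integer(nBoot), level = level,
              seed = as.integer(seed), n = n)
}

#' Hotspot-level signal statistics
#'
#' Total signal, width, and per-bp signal density for each hotspot
#' interval, labelled island or desert by midpoint, with per-group
#' medians.
#'
#' @param track An \code{RleList} coverage track.
#' @param hotspots \code{GRanges} of hotspot intervals within the genome.
#' @param partition Optional [RegionPartition-class] for region labels.
#' @return A list of class \code{"HotspotStats"}: \code{$hotspots}
#'   (per-hotspot data.frame) and \code{$groups} (per-label medians of
#'   width, total and density; NULL without a partition).
#' @export
hotspotStats <- function(track, hotspots, partition = NULL) {
    checkTrack(track)
    stopifnot(methods::is(hotspots, "GRanges"))
    sl <- trackSeqlengths(track)
    chrs <- as.character(seqnames(hotspots))
    if (any(start(hotspots) < 1L) || any(end(hotspots) > sl[chrs]))
        stop("hotspot outside the genome")
    ids <- if (!is.null(names(hotspots))) names(hotspots)
           else sprintf("hotspot_%04d", seq_along(hotspots))
    totals <- numeric(length(hotspots))
    for (chr in unique(chrs)) {
        i <- which(chrs == chr)
        v <- Views(track[[chr]], start = start(hotspots)[i],
                   end = end(hotspots)[i])
        totals[i] <- viewSums(v)
    }
    df <- data.frame(id = ids, chrom = chrs,
                     start = start(hotspots), end = end(hotspots),
                     width = width(hotspots), total = totals,
                     density = totals / width(hotspots),
                     stringsAsFactors = FALSE)
    groups <- NULL
    if (!is.null(partition)) {
        df$label <- assignRegions(hotspots, partition)
        groups <- do.call(rbind, lapply(levels(df$label), function(lb) {
            sub <- df[df$label == lb, , drop = FALSE]
            data.frame(label = lb, n = nrow(sub),
                       median_width = stats::median(sub$width),
                       median_total = stats::median(sub$total),
                       median_density = stats::median(sub$density))
        }))
    }
    structure(list(hotspots = df, groups = groups), class = "HotspotStats")
}

#' @export
print.HotspotStats <- function(x, ...) {
    cat("HotspotStats:", nrow(x$hotspots), "hotspots\n")
    if (!is.null(x$groups)) print(x$groups)
    invisible(x)
}

#' Sort profile rows by anchor width
#'
#' Ascending width, ties broken lexicographically by anchor id — the
#' ordering used for width-sorted hotspot heatmaps.
#'
#' @param pm A [ProfileMatrix-class] whose row metadata includes
#'   \code{width}.
#' @return The reordered [ProfileMatrix-class].
#' @export
sortRowsByWidth <- function(pm) {
    stopifnot(methods::is(pm, "ProfileMatrix"))
    w <- pm@rowMeta$width
    if (is.null(w) || anyNA(w))
        stop("row metadata has no complete 'width' column")
    o <- order(w, pm@rowMeta$id)
    methods::new("ProfileMatrix", mat = pm@mat[o, , drop = FALSE],
                 positions = pm@positions,
                 rowMeta = pm@rowMeta[o, , drop = FALSE],
                 dropped = pm@dropped, kind = pm@kind)
}

#' Write a profile matrix (and row metadata sidecar) as TSV
#' @param pm A [ProfileMatrix-class].
#' @param path Output TSV; the sidecar goes to \code{<path>.meta.tsv}.
#' @return Invisibly, \code{path}.
#' @export
writeProfileMatrix <- function(pm, path) {
    m <- as.data.frame(pm@mat)
    colnames(m) <- as.character(pm@positions)
    utils::write.table(cbind(id = pm@rowMeta$id, m), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(pm@rowMeta),
                       paste0(path, ".meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
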