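#' Read a per-bp coverage track from bedGraph or wiggle
#'
#' Builds a dense per-bp coverage track (an \code{RleList}, one run-length
#' encoded vector per chromosome) from a 4-column bedGraph or a
#' fixedStep/variableStep wiggle file. Positions not covered by any record
#' are filled with 0, so the track always spans every chromosome end to
#' end.
#'
#' @param path bedGraph (\code{.bedgraph}/\code{.bdg}) or wiggle
#'   (\code{.wig}) file.
#' @param chromSizes chrom.sizes TSV path or a \code{Seqinfo}.
#' @param format \code{"auto"}, \code{"bedGraph"} or \code{"wig"}.
#' @return An \code{RleList} whose element lengths equal the chromosome
#'   lengths; all values finite and non-negative.
#' @export
readTrack <- function(path, chromSizes, format = c("auto", "bedGraph", "wig")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("track file not found: ", path)
    si <- if (methods::is(chromSizes, "Seqinfo")) chromSizes
          else readChromSizes(chromSizes)
    if (format == "auto") {
        format <- if (grepl("\\.(bedgraph|bdg)$", path, ignore.case = TRUE))
            "bedGraph"
        else if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig"
        else stop("cannot infer track format from ", path, "; pass format=")
    }
    gr <- tryCatch(rtracklayer::import(path, format = format),
                   error = function(e) stop("malformed track file ", path,
                                            ": ", conditionMessage(e)))
    trackFromGRanges(gr, si)
}

# Shared assembly/validation path for scored interval -> RleList.
trackFromGRanges <- function(gr, si) {
    bad <- setdiff(unique(as.character(seqnames(gr))), seqlevels(si))
    if (length(bad))
        stop("track record on unknown chromosome: ",
             paste(bad, collapse = ", "))
    if (length(gr)) {
        sc <- mcols(gr)$score
        if (is.null(sc)) stop("track records carry no score")
        if (any(!is.finite(sc))) stop("non-finite track value")
        if (any(sc < 0)) stop("negative track value")
        if (!IRanges::isDisjoint(GenomicRanges::granges(gr),
                                 ignore.strand = TRUE))
            stop("overlapping track records")
        if (any(end(gr) > seqlengths(si)[as.character(seqnames(gr))]))
            stop("track record beyond chromosome end")
    }
    seqlevels(gr) <- seqlevels(si)
    seqinfo(gr) <- si
    if (length(gr)) coverage(gr, weight = "score")
    else coverage(gr) * 0.0
}

#' Write a coverage track as sorted bedGraph
#'
#' Emits runs of equal value as single records (zero runs omitted; readers
#' refill them), with scores printed at full double precision so that
#' \code{readTrack(writeTrack(x))} reproduces \code{x} bit for bit.
#'
#' @param track An \code{RleList} coverage track.
#' @param path Output bedGraph path.
#' @return Invisibly, \code{path}.
#' @export
writeTrack <- function(track, path) {
    checkTrack(track)
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (chr in names(track)) {
        r <- track[[chr]]
        v <- S4Vectors::runValue(r)
        l <- S4Vectors::runLength(r)
        e <- cumsum(as.numeric(l))
        s <- e - l  # 0-based starts
        keep <- v != 0
        if (!any(keep)) next
        writeLines(sprintf("%s\t%d\t%d\t%.17g", chr, as.integer(s[keep]),
                           as.integer(e[keep]), v[keep]), con)
    }
    invisible(path)
}

#' Write a chrom.sizes file for a track or Seqinfo
#' @param x An \code{RleList} track or \code{Seqinfo}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeChromSizes <- function(x, path) {
    sl <- if (methods::is(x, "Seqinfo")) seqlengths(x) else trackSeqlengths(x)
    writeLines(sprintf("%s\t%d", names(sl), as.integer(sl)), path)
    invisible(path)
}

#' Bin a coverage track into fixed-width tiles
#'
#' Partitions every chromosome into consecutive \code{binSize}-bp bins
#' (the terminal bin may be shorter) and scores each bin with the
#' arithmetic mean of its per-bp values, the unit on which islands are
#' defined.
#'
#' @param track An \code{RleList} coverage track.
#' @param binSize Bin width in bp (default 5000).
#' @return A \code{GRanges} tiling the genome, with mcols column
#'   \code{score}; \code{metadata(.)$bin_size} records the bin size.
#' @examples
#' ## a 10-bp chromosome with values 0..9 and binSize 5 scores c(2, 7)
#' @export
binSignal <- function(track, binSize = 5000) {
    checkTrack(track)
    stopifnot(binSize >= 1)
    sl <- trackSeqlengths(track)
    bins <- tileGenome(sl, tilewidth = binSize,
                       cut.last.tile.in.chrom = TRUE)
    bins <- binnedAverage(bins, methods::as(track, "RleList"), "score")
    metadata(bins)$bin_size <- as.integer(binSize)
    bins
}

#' Scale a coverage track by a positive factor
#'
#' Multiplies every per-bp value, e.g. to apply a precomputed spike-in
#' scaling factor before between-sample comparison.
#'
#' @param track An \code{RleList} coverage track.
#' @param factor Positive scalar.
#' @return The scaled \code{RleList}.
#' @export
scaleTrack <- function(track, factor) {
    checkTrack(track)
    if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
        factor <= 0)
        stop("scaling factor must be a positive finite scalar")
    track * factor
}

#' Per-bp ratio of two coverage tracks
#'
#' Computes (numerator + pseudocount) / (denominator + pseudocount) at
#' every base pair, the fold-enrichment of a ChIP track over an input (or
#' no-tag) control. The default pseudocount is 0 and division by zero is a
#' hard error: adding a pseudocount shifts fold-enrichment and must be an
#' explicit choice.
#'
#' @param numerator,denominator \code{RleList} tracks on the same genome.
#' @param pseudocount Non-negative scalar added to both tracks.
#' @return The ratio \code{RleList}.
#' @export
ratioTrack <- function(numerator, denominator, pseudocount = 0) {
    checkTrack(numerator, "numerator"); checkTrack(denominator, "denominator")
    if (!sameGenome(numerator, denominator))
        stop("numerator and denominator are on different genomes")
    if (pseudocount < 0) stop("pseudocount must be >= 0")
    if (pseudocount == 0 &&
        any(vapply(as.list(denominator),
                   function(r) any(S4Vectors::runValue(r) == 0), TRUE)))
        stop("zero in denominator; supply a positive pseudocount")
    (numerator + pseudocount) / (denominator + pseudocount)
}

#' Construct a coverage track from per-chromosome numeric vectors
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @return An \code{RleList}.
#' @export
trackFromVectors <- function(values) {
    stopifnot(is.list(values), !is.null(names(values)))
    methods::as(lapply(values, S4Vectors::Rle), "RleList")
}
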