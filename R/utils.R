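# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators behave as pure functions of (inputs, seed).
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# Deterministic 32-bit sub-seed for a named pipeline stage, so adding a
# stage never perturbs another stage's random stream.
#' Derive a stage-specific sub-seed from a global seed
#'
#' Stable polynomial hash of the stage name folded into the global seed,
#' reduced modulo 2^31 - 1. Deterministic across sessions and platforms.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed in [0, 2^31 - 2].
#' @export
stageSeed <- function(seed, stage) {
    stopifnot(is.character(stage), length(stage) == 1L)
    m <- 2147483647
    h <- 0
    for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
    as.integer((as.numeric(seed) %% m + h * 2654435.0) %% m)
}

# chrom.sizes reader: two-column TSV (chrom, length) -> Seqinfo.
readChromSizes <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "integer"))
    if (nrow(tab) == 0L) stop("empty chrom.sizes file: ", path)
    if (anyDuplicated(tab$chrom)) stop("duplicate chromosome in ", path)
    if (any(tab$length <= 0L)) stop("non-positive chromosome length in ", path)
    Seqinfo(seqnames = tab$chrom, seqlengths = tab$length)
}

# Exact first and second moments of an Rle-valued track (per-bp).
rleMoments <- function(rlelist) {
    tot <- 0; tot2 <- 0; n <- 0
    for (r in as.list(rlelist)) {
        v <- S4Vectors::runValue(r); l <- S4Vectors::runLength(r)
        tot <- tot + sum(v * l)
        tot2 <- tot2 + sum(v * v * l)
        n <- n + sum(l)
    }
    mu <- tot / n
    list(mean = mu, var = tot2 / n - mu * mu, n = n)
}

# Midpoint position (1-based) under the half-open midpoint convention
# floor((start0 + end0) / 2): for a 1-based closed [s, e] this is
# floor((s - 1 + e) / 2) + 1.
midpointPos <- function(gr) {
    as.integer(floor((start(gr) - 1 + end(gr)) / 2) + 1L)
}

checkTrack <- function(track, what = "track") {
    if (!methods::is(track, "RleList"))
        stop(what, " must be an RleList coverage track")
    invisible(track)
}

# Do two tracks live on the same genome?
sameGenome <- function(a, b) {
    identical(names(a), names(b)) &&
        identical(unname(S4Vectors::elementNROWS(a)),
                  unname(S4Vectors::elementNROWS(b)))
}

trackSeqlengths <- function(track) {
    structure(S4Vectors::elementNROWS(track), names = names(track))
}
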