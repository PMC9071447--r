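#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- isSorted
#' @importFrom BiocGenerics start end width strand
#' @importFrom IRanges IRanges Views viewSums viewMeans coverage
#' @importFrom GenomicRanges GRanges tileGenome binnedAverage seqnames
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
#'   seqlevels<- seqinfo<-
NULL

#' GenomeAnnotation: chromosome lengths plus strand-aware gene intervals
#'
#' Container for a gene-level genome annotation: a \code{GRanges} of genes
#' (1-based, closed intervals; every gene on \code{+} or \code{-}) whose
#' \code{seqinfo} carries the chromosome lengths. Gene identifiers are the
#' names of the ranges and must be unique. Genes are kept sorted by
#' (chromosome, start).
#'
#' @slot genes A named, sorted \code{GRanges} with strand in \code{+}/\code{-}.
#' @seealso [readAnnotation()], [genePairs()], [codingDensity()]
#' @export
setClass("GenomeAnnotation", slots = c(genes = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
    g <- object@genes
    msg <- character()
    sl <- seqlengths(g)
    if (any(is.na(sl)))
        msg <- c(msg, "all chromosome lengths must be known")
    if (length(g)) {
        if (is.null(names(g)) || anyNA(names(g)))
            msg <- c(msg, "every gene must have an identifier")
        else if (anyDuplicated(names(g)))
            msg <- c(msg, sprintf("duplicate gene id: %s",
                                  names(g)[duplicated(names(g))][1L]))
        if (any(strand(g) == "*"))
            msg <- c(msg, "genes must be stranded (+ or -)")
        if (any(start(g) < 1L) ||
            any(end(g) > sl[as.character(seqnames(g))]))
            msg <- c(msg, "gene outside chromosome bounds")
        o <- order(as.integer(seqnames(g)), start(g))
        if (!identical(o, seq_along(g)))
            msg <- c(msg, "genes must be sorted by (chrom, start)")
    }
    if (length(msg)) msg else TRUE
})

#' RegionPartition: exhaustive island/desert labelling of a genome
#'
#' The result of [callIslands()]: disjoint, sorted regions labelled
#' \code{"island"} or \code{"desert"} that tile every chromosome exactly,
#' with adjacent regions on a chromosome always carrying different labels.
#' Every island is a union of consecutive enriched bins.
#'
#' @slot regions \code{GRanges} with an mcols column \code{label}
#'   (factor, levels \code{island}, \code{desert}).
#' @slot binSize Bin size (bp) of the binned signal the partition came from.
#' @slot k Threshold multiplier applied to the signal standard deviation.
#' @slot threshold The threshold value actually used (signal units).
#' @slot mode Threshold mode, \code{"sd"} (k x SD) or
#'   \code{"mean_plus_sd"} (mean + k x SD).
#' @export
setClass("RegionPartition",
         slots = c(regions = "GRanges", binSize = "numeric", k = "numeric",
                   threshold = "numeric", mode = "character"))

setValidity("RegionPartition", function(object) {
    r <- object@regions
    msg <- character()
    if (!"label" %in% colnames(mcols(r)))
        return("regions must carry a 'label' mcols column")
    lab <- mcols(r)$label
    if (!all(lab %in% c("island", "desert")))
        msg <- c(msg, "labels must be 'island' or 'desert'")
    sl <- seqlengths(r)
    if (any(is.na(sl)))
        msg <- c(msg, "partition requires known chromosome lengths")
    for (chr in seqlevels(r)) {
        idx <- which(as.character(seqnames(r)) == chr)
        if (!length(idx)) {
            msg <- c(msg, sprintf("chromosome %s not covered", chr))
            next
        }
        s <- start(r)[idx]; e <- end(r)[idx]; l <- as.character(lab[idx])
        if (s[1L] != 1L || e[length(e)] != sl[[chr]] ||
            (length(s) > 1L && any(s[-1L] != e[-length(e)] + 1L)))
            msg <- c(msg, sprintf("regions do not tile chromosome %s", chr))
        if (length(l) > 1L && any(l[-1L] == l[-length(l)]))
            msg <- c(msg, sprintf("adjacent regions share a label on %s", chr))
    }
    if (length(msg)) msg else TRUE
})

#' ProfileMatrix: anchors x relative-position signal windows
#'
#' Per-anchor signal windows extracted from a coverage track, one row per
#' retained anchor and one column per relative position. Anchors whose
#' window ran off a chromosome end are excluded; their number is kept in
#' \code{dropped}.
#'
#' @slot mat Numeric matrix, rows = anchors, columns = positions.
#' @slot positions Relative coordinate of each column (bp offsets for
#'   anchor-aligned windows; scaled-bin indices for gene-scaled profiles).
#' @slot rowMeta \code{DataFrame} of per-row metadata (id, chrom, pos,
#'   strand, and any anchor columns such as \code{width} or \code{label}).
#' @slot dropped Number of anchors excluded for running out of bounds.
#' @slot kind Free-form label of the anchor type.
#' @export
setClass("ProfileMatrix",
         slots = c(mat = "matrix", positions = "numeric",
                   rowMeta = "DataFrame", dropped = "integer",
                   kind = "character"))

setValidity("ProfileMatrix", function(object) {
    msg <- character()
    if (ncol(object@mat) != length(object@positions))
        msg <- c(msg, "positions must match matrix columns")
    if (nrow(object@mat) != nrow(object@rowMeta))
        msg <- c(msg, "rowMeta must match matrix rows")
    if (length(msg)) msg else TRUE
})

#' LogisticModel: island-vs-desert logistic regression on coding density
#'
#' A two-parameter logistic model P(island) = plogis(b0 + b1 * x) fit by
#' iteratively reweighted least squares, with convergence diagnostics and
#' a Wald test for the coding-density coefficient.
#'
#' @slot intercept,slope Fitted coefficients (b0, b1).
#' @slot converged Whether the log-likelihood converged within tolerance.
#' @slot nIter IRLS iterations used.
#' @slot se Standard errors of (intercept, slope).
#' @slot waldP Two-sided Wald p-value for the slope.
#' @slot logLik Log-likelihood at the estimate.
#' @slot n Number of training records.
#' @slot ridge Ridge penalty applied to the slope (0 = plain MLE).
#' @export
setClass("LogisticModel",
         slots = c(intercept = "numeric", slope = "numeric",
                   converged = "logical", nIter = "integer", se = "numeric",
                   waldP = "numeric", logLik = "numeric", n = "integer",
                   ridge = "numeric"))

#' SimParams: parameters of the synthetic island/desert generator
#'
#' Defaults describe a budding-yeast-like genome: region blocks with median
#' sizes ~15 kb (islands) and ~22.5 kb (deserts), log-normal ORF lengths
#' with medians 1433 bp (islands) and 1218 bp (deserts), intergenic medians
#' per pair class chosen so deserts exceed islands by ~279/124/55 bp for
#' divergent/tandem/convergent pairs, a two-pathway axis signal (broad
#' island-level baseline elevation plus Gaussian peaks at gene 3' ends),
#' multiplicative gamma noise, desert expression uplift of 16.1%, and
#' region-dependent nucleosome phasing decay.
#'
#' @slot nChroms,chromLength Number and length (bp) of chromosomes.
#' @slot islandFraction Expected fraction of the genome in islands.
#' @slot islandBlockLen Mean island block length (bp; exponential draws).
#' @slot geneMedianIsland,geneMedianDesert Median ORF length (bp) per region.
#' @slot geneSdlog Log-scale SD of the log-normal ORF-length distributions.
#' @slot intergenicMedianIsland,intergenicMedianDesert Named numeric
#'   (convergent, tandem, divergent): median intergenic size (bp).
#' @slot intergenicSdlog Log-scale SD of intergenic size distributions.
#' @slot baselineIsland,baselineDesert Region baseline fold-enrichment.
#' @slot peakAmplitude,peakWidth Gene 3'-end peak height and FWHM (bp).
#' @slot noiseCV Coefficient of variation of per-bp multiplicative gamma noise.
#' @slot exprMeanlog,exprSdlog Island expression log-normal parameters.
#' @slot exprDesertUplift Desert mean expression uplift (0.161 = +16.1%).
#' @slot nucPeriod Nucleosome repeat length (bp).
#' @slot phasingDecayIsland,phasingDecayDesert Per-nucleosome amplitude
#'   retention of the phased signal (island > desert = better ordered).
#' @slot mnaseAmplitude Amplitude of the first nucleosome oscillation.
#' @export
setClass("SimParams",
         slots = c(nChroms = "integer", chromLength = "integer",
                   islandFraction = "numeric", islandBlockLen = "numeric",
                   geneMedianIsland = "numeric", geneMedianDesert = "numeric",
                   geneSdlog = "numeric",
                   intergenicMedianIsland = "numeric",
                   intergenicMedianDesert = "numeric",
                   intergenicSdlog = "numeric",
                   baselineIsland = "numeric", baselineDesert = "numeric",
                   peakAmplitude = "numeric", peakWidth = "numeric",
                   noiseCV = "numeric",
                   exprMeanlog = "numeric", exprSdlog = "numeric",
                   exprDesertUplift = "numeric",
                   nucPeriod = "numeric",
                   phasingDecayIsland = "numeric",
                   phasingDecayDesert = "numeric",
                   mnaseAmplitude = "numeric"))

setValidity("SimParams", function(object) {
    msg <- character()
    pos <- c(chromLength = object@chromLength, nChroms = object@nChroms,
             islandBlockLen = object@islandBlockLen,
             geneMedianIsland = object@geneMedianIsland,
             geneMedianDesert = object@geneMedianDesert,
             nucPeriod = object@nucPeriod, peakWidth = object@peakWidth,
             object@intergenicMedianIsland, object@intergenicMedianDesert)
    if (any(pos <= 0)) msg <- c(msg, "lengths and medians must be positive")
    if (object@islandFraction <= 0 || object@islandFraction >= 1)
        msg <- c(msg, "islandFraction must lie in (0,1)")
    if (object@noiseCV < 0) msg <- c(msg, "noiseCV must be >= 0")
    cls <- c("convergent", "tandem", "divergent")
    if (!identical(sort(names(object@intergenicMedianIsland)), sort(cls)) ||
        !identical(sort(names(object@intergenicMedianDesert)), sort(cls)))
        msg <- c(msg, "intergenic medians must be named convergent/tandem/divergent")
    if (length(msg)) msg else TRUE
})
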