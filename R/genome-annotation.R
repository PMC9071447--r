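#' Read a gene annotation from GFF3 or BED
#'
#' Parses a GFF3 or BED6 gene annotation against a chrom.sizes file and
#' returns a validated [GenomeAnnotation-class]. GFF3 coordinates (1-based,
#' inclusive) and BED coordinates (0-based, half-open) both map onto the
#' internal 1-based closed convention, so a GFF3 record \code{start=1001,
#' end=2000} and a BED record \code{1000 2000} describe the same 1000-bp
#' gene. For GFF3, only records whose type is in \code{featureType} are
#' retained and the \code{ID} (falling back to \code{Name}) attribute is the
#' gene id; for BED the name field is the id.
#'
#' @param path GFF3 (\code{.gff}/\code{.gff3}) or BED (\code{.bed}) file.
#' @param chromSizes Two-column TSV of chromosome name and length, or a
#'   \code{Seqinfo} object.
#' @param featureType GFF3 feature types to keep (default \code{"gene"};
#'   use e.g. \code{c("gene","ORF")} for ORF-style annotations).
#' @param format \code{"auto"} (by extension), \code{"gff3"} or \code{"bed"}.
#' @return A [GenomeAnnotation-class].
#' @examples
#' sizes <- tempfile(); writeLines("chrI\t10000", sizes)
#' bed <- tempfile()
#' writeLines("chrI\t1000\t2000\tgeneA\t0\t-", bed)
#' ann <- readAnnotation(bed, sizes, format = "bed")
#' width(genes(ann))  # 1000
#' @export
readAnnotation <- function(path, chromSizes, featureType = "gene",
                           format = c("auto", "gff3", "bed")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("annotation file not found: ", path)
    si <- if (methods::is(chromSizes, "Seqinfo")) chromSizes
          else readChromSizes(chromSizes)
    if (format == "auto") {
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
                  else if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
                  else stop("cannot infer annotation format from ", path,
                            "; pass format=")
    }
    gr <- tryCatch(
        rtracklayer::import(path, format = if (format == "bed") "bed" else "gff3"),
        error = function(e) stop("malformed annotation file ", path, ": ",
                                 conditionMessage(e)))
    if (format == "gff3" && length(gr)) {
        keep <- as.character(gr$type) %in% featureType
        gr <- gr[keep]
        ids <- as.character(gr$ID)
        if (length(gr) && (is.null(gr$ID) || anyNA(ids)))
            ids <- ifelse(is.na(ids) | ids == "", as.character(gr$Name), ids)
        names(gr) <- ids
    } else if (length(gr)) {
        names(gr) <- gr$name
    }
    bad <- setdiff(unique(as.character(seqnames(gr))), seqlevels(si))
    if (length(bad))
        stop("annotation record on unknown chromosome: ",
             paste(bad, collapse = ", "))
    if (length(gr)) {
        if (is.null(names(gr)) || anyNA(names(gr)) || any(names(gr) == ""))
            stop("every gene record needs an id (GFF3 ID/Name or BED name)")
        if (anyDuplicated(names(gr)))
            stop("duplicate gene id: ", names(gr)[duplicated(names(gr))][1L])
        if (any(strand(gr) == "*"))
            stop("unstranded gene record: ",
                 names(gr)[as.logical(strand(gr) == "*")][1L])
    }
    mcols(gr) <- NULL
    if (length(gr) &&
        any(end(gr) > seqlengths(si)[as.character(seqnames(gr))]))
        stop("gene beyond chromosome end")
    seqlevels(gr) <- seqlevels(si)
    seqinfo(gr) <- si
    gr <- gr[order(as.integer(seqnames(gr)), start(gr))]
    methods::new("GenomeAnnotation", genes = gr)
}

#' @describeIn readAnnotation Build a GenomeAnnotation directly from a
#'   named, stranded \code{GRanges} with known seqlengths.
#' @param granges A \code{GRanges} of genes.
#' @export
annotationFromGRanges <- function(granges) {
    mcols(granges) <- NULL
    granges <- granges[order(as.integer(seqnames(granges)), start(granges))]
    methods::new("GenomeAnnotation", genes = granges)
}

#' @rdname GenomeAnnotation-class
#' @param object,x A \code{GenomeAnnotation}.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname GenomeAnnotation-class
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeAnnotation-class
#' @export
setMethod("chromLengths", "GenomeAnnotation",
          function(x) seqlengths(x@genes))

setMethod("show", "GenomeAnnotation", function(object) {
    cat(sprintf("GenomeAnnotation: %d genes on %d chromosome(s), %.3f Mb\n",
                length(object@genes), length(seqlevels(object@genes)),
                sum(as.numeric(seqlengths(object@genes))) / 1e6))
})

#' Classify adjacent gene pairs and their intergenic regions
#'
#' Walks consecutive genes (by start order) on each chromosome and
#' classifies each pair by strand orientation: \code{(+,-)} convergent,
#' \code{(-,+)} divergent, \code{(+,+)} or \code{(-,-)} tandem. The
#' intergenic region is the gap between the two genes; pairs whose genes
#' touch or overlap are retained with a zero-length intergenic interval
#' and \code{intergenic_empty = TRUE} (and are excluded from intergenic
#' size statistics downstream).
#'
#' @param annotation A [GenomeAnnotation-class].
#' @return A data.frame with one row per adjacent pair: \code{chrom},
#'   \code{left_id}, \code{right_id}, \code{left_strand},
#'   \code{right_strand}, \code{pair_class}, \code{intergenic_start},
#'   \code{intergenic_end} (1-based closed, NA when empty),
#'   \code{intergenic_length}, \code{intergenic_empty}.
#' @export
genePairs <- function(annotation) {
    stopifnot(methods::is(annotation, "GenomeAnnotation"))
    g <- genes(annotation)
    out <- list()
    for (chr in seqlevels(g)) {
        idx <- which(as.character(seqnames(g)) == chr)
        if (length(idx) < 2L) next
        li <- idx[-length(idx)]; ri <- idx[-1L]
        ls <- as.character(strand(g)[li]); rs <- as.character(strand(g)[ri])
        cls <- ifelse(ls == "+" & rs == "-", "convergent",
               ifelse(ls == "-" & rs == "+", "divergent", "tandem"))
        istart <- end(g)[li] + 1L
        iend <- start(g)[ri] - 1L
        empty <- istart > iend
        out[[chr]] <- data.frame(
            chrom = chr,
            left_id = names(g)[li], right_id = names(g)[ri],
            left_strand = ls, right_strand = rs,
            pair_class = factor(cls, levels = c("convergent", "tandem",
                                                "divergent")),
            intergenic_start = ifelse(empty, NA_integer_, istart),
            intergenic_end = ifelse(empty, NA_integer_, iend),
            intergenic_length = pmax(iend - istart + 1L, 0L),
            intergenic_empty = empty,
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(chrom = character(), left_id = character(),
                          right_id = character(), left_strand = character(),
                          right_strand = character(),
                          pair_class = factor(character(),
                              levels = c("convergent", "tandem", "divergent")),
                          intergenic_start = integer(),
                          intergenic_end = integer(),
                          intergenic_length = integer(),
                          intergenic_empty = logical()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Coding density of genomic bins
#'
#' Fraction of base pairs in each bin covered by the union of gene
#' intervals (overlapping genes counted once), the predictor used by the
#' island logistic model.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param bins \code{GRanges} of query bins (within chromosome bounds).
#' @return Numeric vector in [0, 1], one value per bin.
#' @examples
#' ## a 2000-bp gene in a 5000-bp bin has coding density 0.4
#' @export
codingDensity <- function(annotation, bins) {
    stopifnot(methods::is(annotation, "GenomeAnnotation"),
              methods::is(bins, "GRanges"))
    g <- genes(annotation)
    sl <- seqlengths(g)
    bad <- setdiff(unique(as.character(seqnames(bins))), names(sl))
    if (length(bad))
        stop("bin on unknown chromosome: ", paste(bad, collapse = ", "))
    if (any(start(bins) < 1L) ||
        any(end(bins) > sl[as.character(seqnames(bins))]))
        stop("bin outside chromosome bounds")
    red <- GenomicRanges::reduce(g, ignore.strand = TRUE)
    cov <- coverage(red)  # 0/1 per bp
    dens <- numeric(length(bins))
    for (chr in unique(as.character(seqnames(bins)))) {
        i <- which(as.character(seqnames(bins)) == chr)
        v <- Views(cov[[chr]], start = start(bins)[i], end = end(bins)[i])
        dens[i] <- viewSums(v) / width(bins)[i]
    }
    dens
}

#' GC content of genomic regions
#'
#' (G + C) / (A + C + G + T) per region, case-insensitive; ambiguous bases
#' are excluded from the denominator. Returns NaN for a region with no
#' unambiguous base.
#'
#' @param sequence A \code{DNAStringSet} (e.g. from
#'   \code{Biostrings::readDNAStringSet}) or a FASTA file path, with one
#'   entry per chromosome.
#' @param regions \code{GRanges} of query regions.
#' @return Numeric vector in [0, 1] (or NaN), one value per region.
#' @export
gcContent <- function(sequence, regions) {
    if (is.character(sequence))
        sequence <- Biostrings::readDNAStringSet(sequence)
    stopifnot(methods::is(sequence, "DNAStringSet"),
              methods::is(regions, "GRanges"))
    names(sequence) <- sub("\\s.*$", "", names(sequence))
    chrs <- as.character(seqnames(regions))
    bad <- setdiff(unique(chrs), names(sequence))
    if (length(bad))
        stop("region on chromosome absent from sequence: ",
             paste(bad, collapse = ", "))
    if (any(end(regions) > Biostrings::width(sequence)[match(chrs, names(sequence))]))
        stop("region beyond sequence length")
    sub <- Biostrings::DNAStringSet(sequence[match(chrs, names(sequence))],
                                    start = start(regions),
                                    end = end(regions))
    freq <- Biostrings::letterFrequency(sub, c("A", "C", "G", "T"))
    gc <- freq[, "G"] + freq[, "C"]
    tot <- rowSums(freq)
    unname(gc / tot)
}
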