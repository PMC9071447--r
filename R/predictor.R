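#' Tile a genome into fixed-width bins
#'
#' @param chromLengths Named vector of chromosome lengths, a
#'   \code{Seqinfo}, or an \code{RleList} track.
#' @param binSize Bin width in bp (default 5000).
#' @return A \code{GRanges} tiling the genome (last bin per chromosome may
#'   be short).
#' @export
genomeBins <- function(chromLengths, binSize = 5000) {
    sl <- if (methods::is(chromLengths, "Seqinfo")) seqlengths(chromLengths)
          else if (methods::is(chromLengths, "RleList"))
              trackSeqlengths(chromLengths)
          else chromLengths
    tileGenome(sl, tilewidth = binSize, cut.last.tile.in.chrom = TRUE)
}

#' Label genome bins with island/desert identity and coding density
#'
#' Builds the record set the logistic predictor trains on: one row per
#' genome bin with its coding density and the island/desert label of the
#' region containing the bin midpoint.
#'
#' @param partition A [RegionPartition-class].
#' @param bins \code{GRanges} of bins (same binning as the partition;
#'   default: regenerated from the partition's bin size).
#' @param density Per-bin coding density (same length as \code{bins});
#'   computed from \code{annotation} when omitted.
#' @param annotation Optional [GenomeAnnotation-class] used to compute
#'   \code{density}.
#' @return A data.frame: \code{chrom}, \code{start}, \code{end},
#'   \code{coding_density}, \code{label} (factor island/desert).
#' @export
labelBins <- function(partition, bins = NULL, density = NULL,
                      annotation = NULL) {
    stopifnot(methods::is(partition, "RegionPartition"))
    if (is.null(bins))
        bins <- genomeBins(seqlengths(regions(partition)),
                           partition@binSize)
    if (is.null(density)) {
        if (is.null(annotation))
            stop("supply either per-bin density or an annotation")
        density <- codingDensity(annotation, bins)
    }
    if (length(density) != length(bins))
        stop("bin count mismatch: ", length(bins), " bins vs ",
             length(density), " density values")
    data.frame(chrom = as.character(seqnames(bins)),
               start = start(bins), end = end(bins),
               coding_density = as.numeric(density),
               label = assignRegions(bins, partition),
               stringsAsFactors = FALSE)
}

#' Split labelled bins into training and test sets
#'
#' Random, disjoint, exhaustive 80/20 split (by default), stratified so
#' that island/desert proportions are preserved within rounding.
#' Deterministic given \code{seed}.
#'
#' @param data Labelled bins from [labelBins()].
#' @param trainFraction Fraction of records in the training set.
#' @param seed Integer seed.
#' @param stratified Stratify by label (default TRUE).
#' @return \code{list(train = , test = )} of data.frames.
#' @export
splitBins <- function(data, trainFraction = 0.8, seed = 1L,
                      stratified = TRUE) {
    stopifnot(is.data.frame(data), nrow(data) >= 5L,
              trainFraction > 0, trainFraction < 1)
    if (stratified) {
        tab <- table(data$label)
        if (any(tab[c("island", "desert")] == 0L) || anyNA(tab))
            stop("stratified split requires both classes present")
    }
    idx <- withSeed(seed, {
        if (stratified) {
            unlist(lapply(levels(data$label), function(lb) {
                i <- which(data$label == lb)
                nTrain <- min(max(round(length(i) * trainFraction), 1L),
                              length(i) - 1L)
                sample(i, nTrain)
            }), use.names = FALSE)
        } else {
            sample(nrow(data), round(nrow(data) * trainFraction))
        }
    })
    list(train = data[sort(idx), , drop = FALSE],
         test = data[setdiff(seq_len(nrow(data)), idx), , drop = FALSE])
}

log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Fit the island-vs-desert logistic regression on coding density
#'
#' Maximum-likelihood logistic regression of island identity (1) versus
#' desert (0) on per-bin coding density, fit by iteratively reweighted
#' least squares with step halving. Convergence is declared when the
#' (penalized) log-likelihood changes by less than \code{tol}. Under
#' perfect separation the slope diverges; iteration stops at
#' \code{maxIter} (or when a coefficient exceeds an internal cap of 500)
#' with \code{converged = FALSE} and a warning. An optional ridge penalty
#' on the slope (default 0) is available for separated data. Significance
#' of the slope is assessed with a two-sided Wald test.
#'
#' @param train Labelled bins (data.frame with \code{coding_density} and
#'   \code{label}), e.g. from [splitBins()].
#' @param maxIter Maximum IRLS iterations (default 100).
#' @param tol Log-likelihood convergence tolerance (default 1e-8).
#' @param ridge Ridge penalty on the slope (default 0 = plain MLE).
#' @return A [LogisticModel-class].
#' @export
fitLogistic <- function(train, maxIter = 100, tol = 1e-8, ridge = 0) {
    x <- as.numeric(train$coding_density)
    y <- as.integer(train$label == "island")
    if (length(unique(y)) < 2L)
        stop("training data contain a single class")
    X <- cbind(1, x)
    beta <- c(0, 0)
    pen <- diag(c(0, ridge))
    loglik <- function(b) {
        eta <- drop(X %*% b)
        sum(y * eta - log1pexp(eta)) - 0.5 * ridge * b[2L]^2
    }
    ll <- loglik(beta)
    converged <- FALSE
    iter <- 0L
    H <- NULL
    while (iter < maxIter) {
        iter <- iter + 1L
        eta <- drop(X %*% beta)
        p <- stats::plogis(eta)
        w <- pmax(p * (1 - p), 1e-12)
        H <- crossprod(X, X * w) + pen
        grad <- drop(crossprod(X, y - p)) - c(0, ridge * beta[2L])
        step <- solve(H, grad)
        newBeta <- beta + step
        newLL <- loglik(newBeta)
        halvings <- 0L
        while (newLL < ll && halvings < 30L) {  # step halving
            step <- step / 2
            newBeta <- beta + step
            newLL <- loglik(newBeta)
            halvings <- halvings + 1L
        }
        done <- abs(newLL - ll) < tol
        beta <- newBeta
        ll <- newLL
        if (max(abs(beta)) > 500) break  # separation cap
        if (done) { converged <- TRUE; break }
    }
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    if (converged && all(abs(y - p) < 1e-4)) {
        # perfect separation: the likelihood has no finite maximiser and
        # the apparent convergence is the plateau of a diverging slope
        converged <- FALSE
    }
    if (!converged)
        warning("logistic fit did not converge (perfect separation?); ",
                "coefficients reported at the iteration plateau")
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X, X * w) + pen
    se <- sqrt(diag(solve(H)))
    waldP <- 2 * stats::pnorm(-abs(beta[2L] / se[2L]))
    methods::new("LogisticModel", intercept = unname(beta[1L]),
                 slope = unname(beta[2L]),
                 converged = converged, nIter = iter, se = unname(se),
                 waldP = unname(waldP), logLik = ll,
                 n = length(y), ridge = ridge)
}

#' @rdname LogisticModel-class
#' @param object,model A \code{LogisticModel}.
#' @export
setGeneric("coefficients")

#' @rdname LogisticModel-class
#' @export
setMethod("coefficients", "LogisticModel", function(object)
    c(intercept = object@intercept, slope = object@slope))

#' Predicted island probability at given coding densities
#' @param model A [LogisticModel-class].
#' @param x Coding densities.
#' @return Probabilities in (0, 1).
#' @export
predictProb <- function(model, x) {
    stats::plogis(model@intercept + model@slope * as.numeric(x))
}

setMethod("show", "LogisticModel", function(object) {
    cat(sprintf(paste0("LogisticModel: logit P(island) = %.4g + %.4g x ",
                       "density\n  n = %d, converged = %s (%d iter), ",
                       "se(slope) = %.3g, Wald p = %.3g\n"),
                object@intercept, object@slope, object@n,
                object@converged, object@nIter, object@se[2L],
                object@waldP))
})

#' Evaluate a logistic island predictor on held-out bins
#'
#' Accuracy at a probability cutoff (predicted island iff probability >=
#' \code{probThreshold}), the ROC curve obtained by sweeping the cutoff
#' over all distinct scores, and the trapezoidal AUC (equal to the
#' pair-concordance statistic, ties counting 1/2). With a single class in
#' the test set the accuracy is still defined but the ROC/AUC are flagged
#' undefined.
#'
#' @param model A [LogisticModel-class].
#' @param test Labelled bins (data.frame).
#' @param probThreshold Probability cutoff for the accuracy (default 0.5).
#' @return A list of class \code{"EvalReport"}: \code{accuracy},
#'   \code{auc}, \code{roc} (data.frame fpr/tpr), \code{n_test},
#'   \code{threshold}, \code{note}.
#' @export
evaluateModel <- function(model, test, probThreshold = 0.5) {
    stopifnot(nrow(test) >= 1L)
    y <- as.integer(test$label == "island")
    scores <- predictProb(model, test$coding_density)
    pred <- as.integer(scores >= probThreshold)
    accuracy <- mean(pred == y)
    if (length(unique(y)) < 2L) {
        return(structure(list(accuracy = accuracy, auc = NA_real_,
                              roc = NULL, n_test = length(y),
                              threshold = probThreshold,
                              note = "single class in test set; AUC undefined"),
                         class = "EvalReport"))
    }
    roc <- rocCurve(scores, y)
    structure(list(accuracy = accuracy, auc = attr(roc, "auc"), roc = roc,
                   n_test = length(y), threshold = probThreshold,
                   note = NA_character_),
              class = "EvalReport")
}

#' ROC curve and trapezoidal AUC from scores and binary labels
#'
#' Thresholds sweep the distinct scores from high to low; tied scores move
#' as one block, producing diagonal ROC segments whose trapezoids count
#' tied pairs 1/2 — so the AUC equals the Mann-Whitney pair-concordance
#' statistic.
#'
#' @param scores Numeric scores (higher = more island-like).
#' @param labels Binary labels (1 = island/positive).
#' @return data.frame \code{fpr}, \code{tpr} from (0,0) to (1,1), with
#'   attribute \code{auc}.
#' @export
rocCurve <- function(scores, labels) {
    stopifnot(length(scores) == length(labels))
    y <- as.integer(labels)
    P <- sum(y == 1L); N <- sum(y == 0L)
    if (P == 0L || N == 0L) stop("both classes required for a ROC curve")
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; yo <- y[o]
    ends <- cumsum(rle(s)$lengths)  # tied scores move as one block
    tpr <- c(0, cumsum(yo == 1L)[ends] / P)
    fpr <- c(0, cumsum(yo == 0L)[ends] / N)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    structure(data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' @export
print.EvalReport <- function(x, ...) {
    cat(sprintf("EvalReport: accuracy = %.1f%% (cutoff %.2g), AUC = %s, n = %d\n",
                100 * x$accuracy, x$threshold,
                if (is.na(x$auc)) "undefined" else sprintf("%.3f", x$auc),
                x$n_test))
    if (!is.na(x$note)) cat(" ", x$note, "\n")
    invisible(x)
}

#' Write labelled bins / model / evaluation report to disk
#'
#' @param bins Labelled bins data.frame.
#' @param model A [LogisticModel-class].
#' @param report An \code{EvalReport}.
#' @param dir Output directory.
#' @param prefix File-name prefix (default "predict").
#' @return Invisibly, the named vector of files written.
#' @export
writePredictorOutputs <- function(bins, model, report, dir,
                                  prefix = "predict") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(bins = file.path(dir, paste0(prefix, "_bins.tsv")),
               model = file.path(dir, paste0(prefix, "_model.json")),
               roc = file.path(dir, paste0(prefix, "_roc.tsv")),
               report = file.path(dir, paste0(prefix, "_report.json")))
    utils::write.table(bins, files[["bins"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(list(intercept = model@intercept,
                              slope = model@slope,
                              converged = model@converged,
                              n_iter = model@nIter, se = model@se,
                              wald_p = model@waldP, log_lik = model@logLik,
                              n = model@n, ridge = model@ridge),
                         files[["model"]], auto_unbox = TRUE, digits = NA)
    if (!is.null(report$roc))
        utils::write.table(report$roc, files[["roc"]], sep = "\t",
                           quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(accuracy = report$accuracy, auc = report$auc,
                              n_test = report$n_test,
                              threshold = report$threshold),
                         files[["report"]], auto_unbox = TRUE, digits = NA)
    invisible(files)
}
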