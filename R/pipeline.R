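#' Build and validate a pipeline configuration
#'
#' A configuration is a plain named list (or a YAML file with the same
#' keys): input paths, the analysis parameters with their standard
#' defaults (5-kb bins, k = 1.75, 1000 bootstrap resamples, 80/20 split),
#' a global seed, an optional chromosome exclusion list, and stage
#' toggles. Validation happens up front: numeric parameters must lie in
#' range and every referenced file must exist, so a bad configuration
#' fails before any stage runs.
#'
#' @param config Path to a YAML file or a named list.
#' @param ... Overrides applied on top of \code{config}.
#' @return A validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(config = list(), ...) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    defaults <- list(track = NULL, chrom_sizes = NULL, annotation = NULL,
                     anchors = NULL, out_dir = "axisland_out",
                     bin_size = 5000, k = 1.75, threshold_mode = "sd",
                     n_boot = 1000,
                     flank = 2000, train_fraction = 0.8, seed = 1L,
                     exclude_chroms = character(),
                     stages = c("simulate", "call_islands", "region_stats",
                                "profiles", "predict"))
    over <- list(...)
    cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])
    cfg <- utils::modifyList(cfg, over[!vapply(over, is.null, TRUE)])
    if (!is.numeric(cfg$k) || cfg$k <= 0) stop("k must be > 0")
    if (cfg$bin_size < 1) stop("bin_size must be >= 1")
    if (cfg$n_boot < 1) stop("n_boot must be >= 1")
    if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
        stop("train_fraction must lie in (0, 1)")
    known <- c("simulate", "call_islands", "region_stats", "profiles",
               "predict")
    if (length(setdiff(cfg$stages, known)))
        stop("unknown stage(s): ",
             paste(setdiff(cfg$stages, known), collapse = ", "))
    if (!("simulate" %in% cfg$stages))
        for (f in c("track", "chrom_sizes", "annotation"))
            if (length(cfg$stages) && !is.null(cfg[[f]]) &&
                !file.exists(cfg[[f]]))
                stop("configured ", f, " file does not exist: ", cfg[[f]])
    structure(cfg, class = "PipelineConfig")
}

#' Run the island/desert analysis pipeline
#'
#' Executes the enabled stages in order — simulate (synthetic inputs),
#' call_islands, region_stats, profiles (ATG-anchored metagene with
#' bootstrap CI), predict (coding-density logistic model) — writing every
#' output under \code{out_dir} and finishing with a \code{manifest.json}
#' that lists each file with its MD5 checksum, the parameters and the
#' seed. Each stochastic stage uses a sub-seed derived from the global
#' seed and the stage name via [stageSeed()], so enabling or disabling
#' one stage never changes another stage's stream. Any stage failure
#' aborts with an error naming the stage.
#'
#' @param config A \code{PipelineConfig} (or list / YAML path accepted by
#'   [pipelineConfig()]).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "PipelineConfig")) config <- pipelineConfig(config)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(seed = config$seed,
                     parameters = config[c("bin_size", "k", "n_boot",
                                           "flank", "train_fraction")],
                     stages = as.list(config$stages), files = list())
    addFile <- function(name, path) {
        manifest$files[[name]] <<- list(path = path,
                                        md5 = unname(tools::md5sum(path)))
    }
    state <- list()
    runStage <- function(stage, body) {
        message("[axisland] stage: ", stage)
        tryCatch(body(), error = function(e)
            stop("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    if ("simulate" %in% config$stages) runStage("simulate", function() {
        sd0 <- stageSeed(config$seed, "simulate")
        params <- simParams()
        sim <- simulateGenome(params, sd0)
        track <- simulateAxisTrack(sim$annotation, sim$truth, params,
                                   stageSeed(config$seed, "simulate_track"))
        expr <- simulateExpression(sim$annotation, sim$truth, params,
                                   stageSeed(config$seed, "simulate_expr"))
        files <- writeSimulatedData(sim, track, expr,
                                    file.path(config$out_dir, "simulated"))
        for (nm in names(files)) addFile(paste0("simulate_", nm), files[[nm]])
        state$annotation <<- sim$annotation
        state$truth <<- sim$truth
        state$track <<- track
    })
    if (is.null(state$track) && !is.null(config$track))
        state$track <- readTrack(config$track, config$chrom_sizes)
    if (is.null(state$annotation) && !is.null(config$annotation))
        state$annotation <- readAnnotation(config$annotation,
                                           config$chrom_sizes)
    dropChroms <- function(track) {
        keep <- setdiff(names(track), config$exclude_chroms)
        track[keep]
    }
    if ("call_islands" %in% config$stages) runStage("call_islands", function() {
        if (is.null(state$track)) stop("no track available")
        binned <- binSignal(dropChroms(state$track), config$bin_size)
        part <- callIslands(binned, k = config$k,
                            mode = config$threshold_mode)
        state$partition <<- part
        path <- file.path(config$out_dir, "regions.bed")
        writeRegionsBed(part, path, track = state$track)
        addFile("regions", path)
    })
    if ("region_stats" %in% config$stages) runStage("region_stats", function() {
        if (is.null(state$partition)) stop("call_islands must run first")
        stats <- regionSummary(state$partition, track = state$track)
        path <- file.path(config$out_dir, "region_stats.tsv")
        utils::write.table(stats$regions, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        addFile("region_stats", path)
    })
    if ("profiles" %in% config$stages) runStage("profiles", function() {
        if (is.null(state$track)) stop("no track available")
        anchors <- if (!is.null(config$anchors))
            rtracklayer::import(config$anchors, format = "bed")
        else if (!is.null(state$annotation)) {
            g <- genes(state$annotation)
            GenomicRanges::resize(g, width = 1L, fix = "start")
        } else stop("no anchors or annotation available")
        pm <- anchorMatrix(state$track, anchors, flank = config$flank)
        ci <- meanProfileCI(pm, nBoot = config$n_boot,
                            seed = stageSeed(config$seed, "profiles"))
        path <- file.path(config$out_dir, "profile_ci.tsv")
        utils::write.table(ci, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        addFile("profile_ci", path)
    })
    if ("predict" %in% config$stages) runStage("predict", function() {
        if (is.null(state$partition) || is.null(state$annotation))
            stop("call_islands and an annotation are required")
        bins <- labelBins(state$partition, annotation = state$annotation)
        split <- splitBins(bins, trainFraction = config$train_fraction,
                           seed = stageSeed(config$seed, "predict"))
        model <- fitLogistic(split$train)
        report <- evaluateModel(model, split$test)
        files <- writePredictorOutputs(bins, model, report, config$out_dir)
        for (nm in names(files)) addFile(paste0("predict_", nm), files[[nm]])
    })
    manifestPath <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(manifest)
}
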