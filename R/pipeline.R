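# Config-driven orchestration of the full chain: outlier screening on the
# raw spectra, then for every grid cell (preprocessing method x selection
# method) preprocessing, wavelength selection, SPXY splitting, PLS fitting
# and evaluation, reported in one comparison table.

.methodFamily <- c(none = "None", fd = "Baseline correction",
                   sd = "Baseline correction", msc = "Scattering correction",
                   snv = "Scattering correction", mas = "Smoothing",
                   sgs = "Smoothing", norm = "Scaling", auto = "Scaling")

#' Build a pipeline configuration
#'
#' Collects every stage's settings into one validated, serializable list.
#' Input is either a CSV path (`input`) or a [generatorConfig()]
#' (`generator`); exactly one must be given.
#'
#' @param generator a [generatorConfig()], or `NULL` when reading from file.
#' @param input path to a spectra CSV (see [readSpectraCsv()]), or `NULL`.
#' @param outlier list: `method` (`"both"`, `"mc"`, `"pca"`, `"none"`),
#'   `mode` (`"union"`/`"intersection"`), `nIterations`, `calFraction`,
#'   `nLatent`, `k`, `nComponents`, `alpha`.
#' @param preprocess character vector of preprocessing method tags to run
#'   (see [preprocessSpectra()]).
#' @param select character vector of selection methods among `"none"`,
#'   `"uve"`, `"spa"`.
#' @param split list: `calFraction` (default 0.75) and optional `calSize`.
#' @param model list: `maxLatent` (default 8), `folds` (`NULL` = LOO).
#' @param selectParams list of parameter lists for the selectors, e.g.
#'   `list(uve = list(nLatent = 3), spa = list(maxVars = 5))`.
#' @param seed master seed for the stochastic stages.
#' @param outputDir directory for run artifacts (`NULL` = keep in memory).
#' @param strictNesting if `TRUE`, the split is drawn first and
#'   preprocessing state and wavelength selection are computed on
#'   calibration rows only (leak-free estimates); default `FALSE` follows
#'   the conventional ordering (selection on the full set before the split).
#' @return a validated `pipelineConfig` list.
#' @export
pipelineConfig <- function(generator = generatorConfig(), input = NULL,
                           outlier = list(), preprocess = "none",
                           select = "none", split = list(),
                           model = list(), selectParams = list(),
                           seed = 1, outputDir = NULL,
                           strictNesting = FALSE) {
    if (is.null(generator) && is.null(input))
        stop("provide either 'generator' or 'input'")
    outlier <- utils::modifyList(
        list(method = "both", mode = "union", nIterations = 1000,
             calFraction = 0.8, nLatent = NULL, k = 2.5,
             nComponents = 2, alpha = 0.05), outlier)
    stopifnot(outlier$method %in% c("both", "mc", "pca", "none"),
              outlier$mode %in% c("union", "intersection"))
    bad <- setdiff(preprocess, names(.methodFamily))
    if (length(bad))
        stop("unknown preprocessing method(s): ", paste(bad, collapse = ", "))
    bad <- setdiff(select, c("none", "uve", "spa"))
    if (length(bad))
        stop("unknown selection method(s): ", paste(bad, collapse = ", "))
    split <- utils::modifyList(list(calFraction = 0.75, calSize = NULL),
                               split)
    model <- utils::modifyList(list(maxLatent = 8, folds = NULL), model)
    selectParams <- utils::modifyList(
        list(uve = list(nLatent = 3, noiseCount = NULL, noiseScale = 1e-10,
                        cutoffMultiplier = 1),
             spa = list(maxVars = 5, validationFraction = 0.25)),
        selectParams)
    structure(list(generator = generator, input = input, outlier = outlier,
                   preprocess = preprocess, select = select, split = split,
                   model = model, selectParams = selectParams, seed = seed,
                   outputDir = outputDir, strictNesting = strictNesting),
              class = "pipelineConfig")
}

# One grid cell: preprocess -> select -> split -> choose LV -> fit -> report.
.runCell <- function(x, preMethod, selMethod, config) {
    sp_cfg <- config$split
    mdl <- config$model
    selp <- config$selectParams
    sel_idx <- NULL
    if (!config$strictNesting) {
        pre <- preprocessSpectra(x, preMethod)
        xt <- pre@transformed
        if (selMethod == "uve") {
            sel_idx <- do.call(uveSelect, c(list(xt), selp$uve,
                                            list(seed = config$seed)))$selected
        } else if (selMethod == "spa") {
            sel_idx <- do.call(spaSelect, c(list(xt), selp$spa))$selected
        }
        if (!is.null(sel_idx) && !length(sel_idx))
            stop("selection returned no variables for cell ",
                 preMethod, "/", selMethod)
        xr <- if (is.null(sel_idx)) xt else restrictBands(xt, sel_idx)
        split <- spxySplit(xr, calFraction = sp_cfg$calFraction,
                           calSize = sp_cfg$calSize)
        xcal <- xr[, split$calibrationIds]
    } else {
        split <- spxySplit(x, calFraction = sp_cfg$calFraction,
                           calSize = sp_cfg$calSize)
        pre <- preprocessSpectra(x[, split$calibrationIds], preMethod)
        xt_cal <- pre@transformed
        xt_val <- applyPreprocess(pre, x[, split$validationIds])
        if (selMethod == "uve") {
            sel_idx <- do.call(uveSelect, c(list(xt_cal), selp$uve,
                                            list(seed = config$seed)))$selected
        } else if (selMethod == "spa") {
            sel_idx <- do.call(spaSelect, c(list(xt_cal), selp$spa))$selected
        }
        if (!is.null(sel_idx) && !length(sel_idx))
            stop("selection returned no variables for cell ",
                 preMethod, "/", selMethod)
        if (!is.null(sel_idx)) {
            xt_cal <- restrictBands(xt_cal, sel_idx)
            xt_val <- restrictBands(xt_val, sel_idx)
        }
        xr <- cbind(xt_cal, xt_val)
        xcal <- xt_cal
    }
    nlv <- chooseNLatent(xcal, maxLatent = mdl$maxLatent,
                         folds = mdl$folds, seed = config$seed)
    fit <- plsFit(xcal, nLatent = as.integer(nlv))
    rep <- evaluateFit(fit, split, xr,
                       provenance = list(preprocess = preMethod,
                                         selection = selMethod,
                                         nSelected = length(sel_idx)))
    wl_sel <- if (is.null(sel_idx)) wavelengths(xr)
              else wavelengths(xr)
    data.frame(family = unname(.methodFamily[preMethod]),
               preprocess = preMethod, selection = selMethod,
               n_bands = nBands(xr),
               selected_nm = paste(wl_sel, collapse = " "),
               n_latent = rep@nLatent,
               rc2 = rep@rc2, rmsec = rep@rmsec,
               rv2 = rep@rv2, rmsev = rep@rmsev,
               n_cal = length(split$calibrationIds),
               n_val = length(split$validationIds))
}

#' Run the full data-optimization and calibration pipeline
#'
#' Executes the stages in the conventional order: outlier screening on the
#' raw spectra, outlier removal, then for every combination of configured
#' preprocessing and selection methods: preprocessing, wavelength selection,
#' SPXY splitting, latent-variable choice by cross-validation, PLS fitting,
#' and evaluation. Results are collected in one comparison table (one row
#' per grid cell); artifacts are written under `config$outputDir` when set.
#'
#' @param config a [pipelineConfig()].
#' @return list with `table` (the comparison `data.frame`), `outliers` (an
#'   [OutlierReport] or `NULL`), `data` (the cleaned [SpectraSet]), and
#'   `log` (character vector of stage messages).
#' @examples
#' cfg <- pipelineConfig(generator = generatorConfig(nSamples = 40, seed = 7),
#'                       outlier = list(method = "none"),
#'                       preprocess = c("none", "sgs"),
#'                       model = list(folds = 5))
#' res <- runPipeline(cfg)
#' res$table[, c("preprocess", "rv2", "rmsev")]
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipelineConfig"))
    log <- character(0)
    note <- function(...) {
        msg <- sprintf(...)
        log <<- c(log, msg)
        msg
    }
    x <- if (!is.null(config$input)) readSpectraCsv(config$input)
         else generateDataset(config$generator)
    note("input: %d samples x %d bands", nSamples(x), nBands(x))
    report <- NULL
    if (config$outlier$method != "none") {
        oc <- config$outlier
        report <- detectOutliers(x, method = oc$method, mode = oc$mode,
                                 nIterations = oc$nIterations,
                                 calFraction = oc$calFraction,
                                 nLatent = oc$nLatent, k = oc$k,
                                 seed = config$seed,
                                 nComponents = oc$nComponents,
                                 alpha = oc$alpha)
        x <- removeOutliers(x, report)
        note("outliers (%s, %s): removed %d, whole set now %d",
             oc$method, oc$mode, length(report@combinedIds), nSamples(x))
    }
    rows <- list()
    for (pre in config$preprocess)
        for (sel in config$select) {
            t0 <- proc.time()["elapsed"]
            cell <- tryCatch(.runCell(x, pre, sel, config),
                             error = function(e)
                                 stop("stage failure in cell ", pre, "/",
                                      sel, ": ", conditionMessage(e),
                                      call. = FALSE))
            note("cell %s/%s: RV2 = %.3f (%.2fs)", pre, sel, cell$rv2,
                 proc.time()["elapsed"] - t0)
            rows[[paste(pre, sel, sep = "/")]] <- cell
        }
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (!is.null(config$outputDir)) {
        dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
        write.csv(tab, file.path(config$outputDir, "comparison.csv"),
                  row.names = FALSE)
        if (!is.null(report)) writeOutlierReport(report, config$outputDir)
        writePipelineConfig(config,
                            file.path(config$outputDir, "config.yaml"))
        writeLines(log, file.path(config$outputDir, "run.log"))
    }
    list(table = tab, outliers = report, data = x, log = log)
}

#' Render a comparison table
#'
#' Writes the pipeline comparison table as CSV or Markdown with the
#' conventional column layout (preprocess family and method, RC2, RMSEC,
#' RV2, RMSEV), rows grouped by preprocessing family.
#'
#' @param table the comparison `data.frame` from [runPipeline()].
#' @param format `"csv"` or `"markdown"`.
#' @param path output file; `NULL` returns the rendered lines.
#' @return the rendered lines, invisibly when written to `path`.
#' @export
reportTable <- function(table, format = c("csv", "markdown"), path = NULL) {
    if (!is.character(format) || !all(format %in% c("csv", "markdown")))
        stop("unsupported format; supported formats: csv, markdown")
    format <- match.arg(format)
    if (is.null(table) || !nrow(table)) stop("comparison table is empty")
    fam_order <- c("None", "Baseline correction", "Scattering correction",
                   "Smoothing", "Scaling")
    table <- table[order(match(table$family, fam_order)), , drop = FALSE]
    if (format == "csv") {
        out <- c("Preprocess Type,Method,Selection,RC2,RMSEC,RV2,RMSEV",
                 sprintf("%s,%s,%s,%.3f,%.3f,%.3f,%.3f", table$family,
                         table$preprocess, table$selection, table$rc2,
                         table$rmsec, table$rv2, table$rmsev))
    } else {
        out <- c("| Preprocess Type | Method | Selection | RC2 | RMSEC | RV2 | RMSEV |",
                 "|---|---|---|---|---|---|---|",
                 sprintf("| %s | %s | %s | %.3f | %.3f | %.3f | %.3f |",
                         table$family, table$preprocess, table$selection,
                         table$rc2, table$rmsec, table$rv2, table$rmsev))
    }
    if (is.null(path)) return(out)
    writeLines(out, path)
    invisible(out)
}

#' Serialize and restore pipeline configurations
#'
#' Round-trips a [pipelineConfig()] through YAML so a run's configuration
#' can be archived next to its outputs and re-run later.
#'
#' @param config a `pipelineConfig`.
#' @param path YAML file path.
#' @return `writePipelineConfig`: `path`, invisibly;
#'   `readPipelineConfig`: a `pipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
    lst <- unclass(config)
    if (!is.null(lst$generator)) {
        g <- unclass(lst$generator)
        g$schema <- NULL
        lst$generator <- g
    }
    yaml::write_yaml(lst, path)
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    lst <- yaml::read_yaml(path)
    gen <- if (!is.null(lst$generator))
        do.call(generatorConfig, lst$generator)
    pipelineConfig(generator = gen, input = lst$input,
                   outlier = lst$outlier, preprocess = lst$preprocess,
                   select = lst$select, split = lst$split,
                   model = lst$model, selectParams = lst$selectParams,
                   seed = lst$seed, outputDir = lst$outputDir,
                   strictNesting = isTRUE(lst$strictNesting))
}
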