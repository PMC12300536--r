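#' @rdname spectraMatrix
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname bandSchema
#' @export
setGeneric("bandSchema", function(x) standardGeneric("bandSchema"))

#' @rdname bandSchema
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname ssc
#' @export
setGeneric("ssc", function(x) standardGeneric("ssc"))

#' @rdname ssc
#' @export
setGeneric("ssc<-", function(x, value) standardGeneric("ssc<-"))

#' @rdname sampleIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname sampleIds
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname applyPreprocess
#' @export
setGeneric("applyPreprocess", function(object, newdata)
    standardGeneric("applyPreprocess"))

#' SpectraSet: banded reflectance spectra with optional SSC reference values
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' set of multispectral reflectance measurements. Bands (channels) are rows,
#' samples are columns; the single assay `"reflectance"` stores dimensionless
#' reflectance. `rowData` carries the band schema (`wavelength_nm`,
#' `fwhm_nm`); `colData` carries per-sample metadata, in particular
#' `ssc_brix`, the refractometric soluble solids content in degrees Brix
#' (`NA` when no reference measurement exists).
#'
#' All standard `SummarizedExperiment` operations (subsetting with `[`,
#' `colData`, `metadata`, ...) work unchanged; `x[, ids]` subsets samples and
#' `x[i, ]` subsets bands.
#'
#' @param reflectance numeric matrix, samples x bands, of calibrated
#'   reflectance values (finite; nominally in \[0, ~1.2\]).
#' @param ids character vector of unique sample identifiers; defaults to the
#'   row names of `reflectance` or `S1..Sn`.
#' @param ssc optional numeric vector of SSC reference values in degrees
#'   Brix, aligned with `ids`; `NA` allowed.
#' @param schema band schema `data.frame` as returned by
#'   [defaultBandSchema()], with one row per column of `reflectance`.
#' @param timestamps optional character vector of ISO-8601 acquisition
#'   timestamps.
#'
#' @return A `SpectraSet` object.
#' @examples
#' sch <- defaultBandSchema()
#' m <- matrix(runif(3 * 18, 0.2, 0.8), nrow = 3)
#' x <- SpectraSet(m, ids = c("a", "b", "c"), ssc = c(21.5, 22.0, 23.1))
#' x
#' spectraMatrix(x)[1, 1:4]
#' @aliases SpectraSet-class
#' @exportClass SpectraSet
#' @export
SpectraSet <- function(reflectance, ids = NULL, ssc = NULL,
                       schema = defaultBandSchema(), timestamps = NULL) {
    reflectance <- as.matrix(reflectance)
    if (!is.numeric(reflectance))
        stop("'reflectance' must be a numeric matrix (samples x bands)")
    n <- nrow(reflectance)
    if (is.null(ids)) {
        ids <- rownames(reflectance)
        if (is.null(ids)) ids <- sprintf("S%d", seq_len(n))
    }
    ids <- as.character(ids)
    if (length(ids) != n)
        stop("'ids' must have one entry per row of 'reflectance'")
    if (ncol(reflectance) != nrow(schema))
        stop("'reflectance' has ", ncol(reflectance),
             " columns but the schema defines ", nrow(schema), " bands")
    cd <- DataFrame(row.names = ids)
    if (!is.null(ssc)) {
        if (length(ssc) != n)
            stop("'ssc' must have one value per sample")
        cd$ssc_brix <- as.numeric(ssc)
    } else {
        cd$ssc_brix <- rep(NA_real_, n)
    }
    if (!is.null(timestamps)) {
        if (length(timestamps) != n)
            stop("'timestamps' must have one value per sample")
        cd$timestamp <- as.character(timestamps)
    }
    rd <- DataFrame(wavelength_nm = schema$wavelength_nm,
                    fwhm_nm = schema$fwhm_nm,
                    row.names = sprintf("r%g", schema$wavelength_nm))
    assay <- t(reflectance)
    dimnames(assay) <- list(rownames(rd), ids)
    se <- SummarizedExperiment(assays = list(reflectance = assay),
                               rowData = rd, colData = cd)
    new("SpectraSet", se)
}

setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
    msg <- NULL
    rd <- rowData(object)
    if (!all(c("wavelength_nm", "fwhm_nm") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'wavelength_nm' and 'fwhm_nm'")
    else {
        wl <- rd$wavelength_nm
        if (length(wl) && any(diff(wl) <= 0))
            msg <- c(msg, "band wavelengths must be strictly increasing")
        if (any(rd$fwhm_nm <= 0))
            msg <- c(msg, "band FWHM must be positive")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (!"reflectance" %in% assayNames(object))
        msg <- c(msg, "assay 'reflectance' is required")
    else if (!all(is.finite(assay(object, "reflectance"))))
        msg <- c(msg, "reflectance values must all be finite")
    if (is.null(msg)) TRUE else msg
})

#' Extract the reflectance matrix of a SpectraSet
#'
#' Returns the spectra in the user-facing orientation, samples x bands, with
#' sample ids as row names and `r<wavelength>` column names.
#'
#' @param x a [SpectraSet].
#' @return numeric matrix, samples x bands.
#' @export
setMethod("spectraMatrix", "SpectraSet", function(x)
    t(assay(x, "reflectance")))

#' Band schema accessors
#'
#' `bandSchema` returns the band definition table (`wavelength_nm`,
#' `fwhm_nm`); `wavelengths` returns just the center wavelengths in nm.
#'
#' @param x a [SpectraSet].
#' @return `bandSchema`: a `data.frame`; `wavelengths`: a numeric vector (nm).
#' @export
setMethod("bandSchema", "SpectraSet", function(x)
    data.frame(wavelength_nm = rowData(x)$wavelength_nm,
               fwhm_nm = rowData(x)$fwhm_nm))

#' @rdname bandSchema
#' @export
setMethod("wavelengths", "SpectraSet", function(x)
    rowData(x)$wavelength_nm)

#' Soluble solids content accessors
#'
#' Get or set the per-sample SSC reference values (degrees Brix) stored in
#' `colData(x)$ssc_brix`.
#'
#' @param x a [SpectraSet].
#' @param value numeric vector of SSC values, one per sample.
#' @return `ssc`: named numeric vector in degrees Brix (`NA` where absent).
#' @export
setMethod("ssc", "SpectraSet", function(x) {
    out <- colData(x)$ssc_brix
    names(out) <- colnames(x)
    out
})

#' @rdname ssc
#' @export
setMethod("ssc<-", "SpectraSet", function(x, value) {
    if (length(value) != ncol(x))
        stop("'value' must have one SSC value per sample")
    colData(x)$ssc_brix <- as.numeric(value)
    x
})

#' Sample and band counts
#'
#' @param x a [SpectraSet].
#' @return `sampleIds`: character vector; `nSamples`, `nBands`: integers.
#' @export
setMethod("sampleIds", "SpectraSet", function(x) colnames(x))

#' @rdname sampleIds
#' @export
setMethod("nSamples", "SpectraSet", function(x) ncol(x))

#' @rdname sampleIds
#' @export
setMethod("nBands", "SpectraSet", function(x) nrow(x))

setMethod("show", "SpectraSet", function(object) {
    wl <- wavelengths(object)
    cat("SpectraSet with", ncol(object), "samples and", nrow(object),
        "bands\n")
    if (length(wl))
        cat("  wavelengths:", wl[1], "-", wl[length(wl)], "nm\n")
    s <- ssc(object)
    n_ssc <- sum(!is.na(s))
    if (n_ssc > 0)
        cat(sprintf("  SSC: %d/%d samples, %.2f-%.2f degrees Brix\n",
                    n_ssc, ncol(object),
                    min(s, na.rm = TRUE), max(s, na.rm = TRUE)))
    else cat("  SSC: none recorded\n")
    invisible(NULL)
})

#' PreprocessResult: a fitted spectral preprocessing transform
#'
#' Returned by [preprocessSpectra()] and the individual preprocessing
#' functions. Holds the transformed spectra, the method tag, and any fitted
#' state needed to transform new data with the calibration-set parameters
#' (the MSC reference spectrum; autoscaling column means/sds). Derivative
#' methods shrink the band axis; `transformed` carries the midpoint schema.
#'
#' @slot transformed a [SpectraSet] of transformed spectra.
#' @slot method character method tag (`"fd"`, `"sd"`, `"msc"`, `"snv"`,
#'   `"mas"`, `"sgs"`, `"norm"`, `"auto"`, `"none"`).
#' @slot fitted list of fitted parameters (empty for stateless methods).
#' @aliases PreprocessResult
#' @export
setClass("PreprocessResult",
         representation(transformed = "SpectraSet",
                        method = "character",
                        fitted = "list"))

setMethod("show", "PreprocessResult", function(object) {
    cat("PreprocessResult: method '", object@method, "'\n", sep = "")
    cat("  ", ncol(object@transformed), " samples x ",
        nrow(object@transformed), " bands",
        if (length(object@fitted)) "; fitted parameters stored" else "",
        "\n", sep = "")
    invisible(NULL)
})

#' PLSModel: a NIPALS partial least squares regression model
#'
#' Fitted by [plsFit()]. Predictors are column-mean centered (no scaling);
#' the composed coefficient vector `coefficients` plus `intercept` reproduce
#' the latent-variable prediction path exactly.
#'
#' @slot nLatent number of latent variables retained.
#' @slot xMeans,yMean centering state.
#' @slot weights,xLoadings p x k weight and loading matrices.
#' @slot yLoadings length-k response loadings.
#' @slot scores n x k calibration score matrix.
#' @slot coefficients regression coefficients in original variable space.
#' @slot intercept scalar intercept.
#' @slot bandNames names of the predictor variables.
#' @aliases PLSModel
#' @export
setClass("PLSModel",
         representation(nLatent = "integer", xMeans = "numeric",
                        yMean = "numeric", weights = "matrix",
                        xLoadings = "matrix", yLoadings = "numeric",
                        scores = "matrix", coefficients = "numeric",
                        intercept = "numeric", bandNames = "character"))

setMethod("show", "PLSModel", function(object) {
    cat("PLSModel:", object@nLatent, "latent variable(s),",
        length(object@coefficients), "predictors\n")
    invisible(NULL)
})

#' OutlierReport: combined Monte-Carlo and PCA outlier screening results
#'
#' Produced by [detectOutliers()] / [combineOutliers()].
#'
#' @slot mc per-sample Monte-Carlo residual statistics and flags
#'   (see [mcOutlierDetect()]); zero-row data.frame when MC was not run.
#' @slot pca per-sample Hotelling \eqn{T^2} statistics and flags
#'   (see [pcaHotellingDetect()]); zero-row data.frame when PCA was not run.
#' @slot combinedIds sample ids flagged for removal.
#' @slot mode `"union"` or `"intersection"`.
#' @aliases OutlierReport
#' @export
setClass("OutlierReport",
         representation(mc = "data.frame", pca = "data.frame",
                        combinedIds = "character", mode = "character"))

setMethod("show", "OutlierReport", function(object) {
    cat("OutlierReport (mode:", object@mode, ")\n")
    if (nrow(object@mc))
        cat("  MC flagged:",
            paste(object@mc$sample_id[object@mc$flag], collapse = ", "),
            "\n")
    if (nrow(object@pca))
        cat("  PCA flagged:",
            paste(object@pca$sample_id[object@pca$flag], collapse = ", "),
            "\n")
    cat("  combined (", length(object@combinedIds), "): ",
        paste(object@combinedIds, collapse = ", "), "\n", sep = "")
    invisible(NULL)
})

#' FitReport: calibration/validation performance of a PLS model
#'
#' Produced by [evaluateFit()]. Carries the coefficient of determination and
#' root-mean-square error for the calibration set (RC2, RMSEC) and the
#' validation set (RV2, RMSEV), both in the units of the response
#' (degrees Brix for SSC models), plus run provenance.
#'
#' @slot rc2,rv2 coefficients of determination (1 - SSres/SStot).
#' @slot rmsec,rmsev root-mean-square errors, degrees Brix.
#' @slot nLatent latent variables used.
#' @slot provenance list describing preprocessing, selection and split.
#' @aliases FitReport
#' @export
setClass("FitReport",
         representation(rc2 = "numeric", rmsec = "numeric",
                        rv2 = "numeric", rmsev = "numeric",
                        nLatent = "integer", provenance = "list"))

setMethod("show", "FitReport", function(object) {
    cat(sprintf(
        "FitReport: RC2 = %.3f, RMSEC = %.3f, RV2 = %.3f, RMSEV = %.3f (%d LV)\n",
        object@rc2, object@rmsec, object@rv2, object@rmsev, object@nLatent))
    invisible(NULL)
})
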