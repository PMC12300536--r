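# Eight spectral preprocessing methods, each SpectraSet -> PreprocessResult.
# Four families: baseline correction (fd, sd), scatter correction (msc, snv),
# smoothing (mas, sgs), scaling (norm, auto). Derivatives shrink the band
# axis; downstream stages consume the output schema.

.newResult <- function(x, mat, method, fitted = list(),
                       schema = bandSchema(x)) {
    new("PreprocessResult",
        transformed = .rebuildSpectra(x, mat, schema = schema),
        method = method, fitted = fitted)
}

.derivMat <- function(mat, wl) {
    dl <- diff(wl)
    t(apply(mat, 1L, function(r) diff(r) / dl))
}

#' Spectral derivatives on the wavelength grid
#'
#' First and second derivatives remove additive (FD) and linear (SD)
#' baseline drift. Because the channel spacing is non-uniform (25-50 nm),
#' derivatives are divided differences over the wavelength grid, not raw
#' index differences: `FD_i = (x[i+1] - x[i]) / (wl[i+1] - wl[i])`,
#' assigned to the midpoint wavelengths. The band axis shrinks by one per
#' derivative order; the result's schema carries the midpoint centers.
#'
#' @param x a [SpectraSet].
#' @return a [PreprocessResult].
#' @examples
#' x <- generateDataset(generatorConfig(nSamples = 5, seed = 1))
#' nBands(firstDerivative(x)@transformed)   # 17
#' @export
firstDerivative <- function(x) {
    wl <- wavelengths(x)
    if (length(wl) < 2) stop("first derivative needs at least 2 channels")
    mat <- .derivMat(spectraMatrix(x), wl)
    sch <- data.frame(wavelength_nm = (wl[-1] + wl[-length(wl)]) / 2,
                      fwhm_nm = bandSchema(x)$fwhm_nm[-1])
    .newResult(x, mat, "fd", schema = sch)
}

#' @rdname firstDerivative
#' @export
secondDerivative <- function(x) {
    if (nBands(x) < 3) stop("second derivative needs at least 3 channels")
    r1 <- firstDerivative(x)
    r2 <- firstDerivative(r1@transformed)
    new("PreprocessResult", transformed = r2@transformed, method = "sd",
        fitted = list())
}

#' Multiplicative scatter correction (MSC)
#'
#' Each spectrum is regressed by ordinary least squares on a reference
#' spectrum (`row = a + b * reference`); the corrected spectrum is
#' `(row - a) / b`, removing per-sample multiplicative and additive scatter.
#' The reference defaults to the column-mean spectrum of `x` and is stored
#' in `fitted`, so validation data can be corrected against calibration
#' state via [applyPreprocess()].
#'
#' @param x a [SpectraSet] (at least 2 samples when `reference` is omitted).
#' @param reference optional numeric reference spectrum (one value per band).
#' @return a [PreprocessResult] with `fitted$reference`.
#' @export
msc <- function(x, reference = NULL) {
    mat <- spectraMatrix(x)
    if (is.null(reference)) {
        if (nrow(mat) < 2)
            stop("MSC needs at least 2 samples to form a reference spectrum")
        reference <- colMeans(mat)
    }
    if (length(reference) != ncol(mat))
        stop("'reference' length must match the number of bands")
    if (var(reference) == 0) stop("MSC reference spectrum has zero variance")
    out <- .mscApply(mat, reference)
    .newResult(x, out, "msc", fitted = list(reference = reference))
}

.mscApply <- function(mat, reference) {
    rc <- reference - mean(reference)
    vref <- sum(rc^2)
    out <- mat
    for (i in seq_len(nrow(mat))) {
        b <- sum((mat[i, ] - mean(mat[i, ])) * rc) / vref
        if (abs(b) < 1e-12) {
            warning("MSC slope ~0 for sample ", rownames(mat)[i],
                    "; row returned unchanged")
            next
        }
        a <- mean(mat[i, ]) - b * mean(reference)
        out[i, ] <- (mat[i, ] - a) / b
    }
    out
}

#' Standard normal variate (SNV)
#'
#' Per-spectrum standardization: subtract the row mean, divide by the row
#' standard deviation (n-1 denominator). Removes per-sample multiplicative
#' and additive scatter without a reference spectrum.
#'
#' @param x a [SpectraSet]; every row must be non-constant.
#' @return a [PreprocessResult].
#' @export
snv <- function(x) {
    mat <- spectraMatrix(x)
    sds <- apply(mat, 1L, sd)
    if (any(sds == 0))
        stop("SNV undefined for constant spectra: sample(s) ",
             paste(rownames(mat)[sds == 0], collapse = ", "))
    .newResult(x, (mat - rowMeans(mat)) / sds, "snv")
}

.reflectPad <- function(v, h) {
    n <- length(v)
    c(v[(h + 1):2], v, v[(n - 1):(n - h)])
}

#' Moving average smoothing (MAS)
#'
#' Centered moving mean with an odd window; output length equals input
#' length, with edges handled by reflection padding. Smoothing lowers and
#' broadens spectral peaks in exchange for noise reduction.
#'
#' @param x a [SpectraSet].
#' @param window odd integer window width, `3 <= window <= nBands(x)`.
#' @return a [PreprocessResult].
#' @export
movingAverage <- function(x, window = 3) {
    p <- nBands(x)
    if (window %% 2 != 1 || window < 3 || window > p)
        stop("'window' must be odd and within [3, ", p, "]")
    h <- (window - 1) / 2
    mat <- t(apply(spectraMatrix(x), 1L, function(r) {
        rp <- .reflectPad(r, h)
        vapply(seq_len(p), function(i) mean(rp[i:(i + 2 * h)]), 0)
    }))
    .newResult(x, mat, "mas")
}

#' Savitzky-Golay smoothing (SGS)
#'
#' Local least-squares polynomial smoothing; preserves peak shape better
#' than a plain moving average and reproduces polynomial trends of degree
#' up to `polyorder` exactly. Edge values come from the polynomial fitted to
#' the first/last full window, the standard Savitzky-Golay edge treatment.
#'
#' @param x a [SpectraSet].
#' @param window odd integer window width, `polyorder < window <= nBands(x)`.
#' @param polyorder polynomial order; default window 5, order 2, the
#'   smallest sensible smoother for an 18-point spectrum.
#' @return a [PreprocessResult].
#' @export
savitzkyGolay <- function(x, window = 5, polyorder = 2) {
    p <- nBands(x)
    if (window %% 2 != 1 || window > p || polyorder >= window ||
        polyorder < 0)
        stop("need odd 'window' <= ", p, " and 0 <= 'polyorder' < window")
    mat <- t(apply(spectraMatrix(x), 1L, signal::sgolayfilt,
                   p = polyorder, n = window))
    .newResult(x, mat, "sgs")
}

#' Min-max normalization
#'
#' Per-spectrum affine rescaling to the range \[0, 1\]:
#' `(x - min) / (max - min)` row by row.
#'
#' @param x a [SpectraSet]; every row must be non-constant.
#' @return a [PreprocessResult].
#' @export
normalizeMinMax <- function(x) {
    mat <- spectraMatrix(x)
    rng <- apply(mat, 1L, range)
    span <- rng[2, ] - rng[1, ]
    if (any(span == 0))
        stop("min-max normalization undefined for constant spectra: ",
             paste(rownames(mat)[span == 0], collapse = ", "))
    .newResult(x, (mat - rng[1, ]) / span, "norm")
}

#' Autoscaling (column z-scores)
#'
#' Per-variable standardization: each band (column) is centered to mean 0
#' and scaled to unit sample standard deviation across samples. Column
#' means/sds are stored in `fitted` so validation data can be scaled with
#' calibration statistics via [applyPreprocess()].
#'
#' @param x a [SpectraSet] with at least 2 samples; every column must be
#'   non-constant.
#' @return a [PreprocessResult] with `fitted$means` and `fitted$sds`.
#' @export
autoscale <- function(x) {
    mat <- spectraMatrix(x)
    if (nrow(mat) < 2) stop("autoscaling needs at least 2 samples")
    mu <- colMeans(mat)
    sds <- apply(mat, 2L, sd)
    if (any(sds == 0))
        stop("autoscaling undefined for constant band(s) at ",
             paste(wavelengths(x)[sds == 0], collapse = ", "), " nm")
    out <- sweep(sweep(mat, 2L, mu, "-"), 2L, sds, "/")
    .newResult(x, out, "auto", fitted = list(means = mu, sds = sds))
}

#' Apply a spectral preprocessing method by name
#'
#' Dispatcher over the eight preprocessing methods (plus `"none"`), using
#' the method tags accepted throughout the package: `fd`, `sd`, `msc`,
#' `snv`, `mas`, `sgs`, `norm`, `auto`, `none`.
#'
#' @param x a [SpectraSet].
#' @param method method tag.
#' @param ... method parameters (`window`, `polyorder`, `reference`).
#' @return a [PreprocessResult].
#' @examples
#' x <- generateDataset(generatorConfig(nSamples = 10, seed = 1))
#' res <- preprocessSpectra(x, "snv")
#' rowMeans(spectraMatrix(res@transformed))[1:3]   # ~0
#' @export
preprocessSpectra <- function(x, method = c("none", "fd", "sd", "msc", "snv",
                                            "mas", "sgs", "norm", "auto"),
                              ...) {
    method <- match.arg(method)
    switch(method,
           none = .newResult(x, spectraMatrix(x), "none"),
           fd = firstDerivative(x),
           sd = secondDerivative(x),
           msc = msc(x, ...),
           snv = snv(x),
           mas = movingAverage(x, ...),
           sgs = savitzkyGolay(x, ...),
           norm = normalizeMinMax(x),
           auto = autoscale(x))
}

#' Transform new spectra with a fitted preprocessing state
#'
#' Applies the transform captured in a [PreprocessResult] to new data. For
#' MSC the stored calibration reference spectrum is used; for autoscaling
#' the stored calibration column means/sds. Stateless methods are simply
#' re-applied. This keeps validation data corrected against calibration
#' state only (no information leak).
#'
#' @param object a [PreprocessResult].
#' @param newdata a [SpectraSet] on the same input band schema.
#' @return a [SpectraSet] of transformed spectra.
#' @export
setMethod("applyPreprocess", "PreprocessResult", function(object, newdata) {
    m <- object@method
    if (m == "msc") {
        mat <- .mscApply(spectraMatrix(newdata), object@fitted$reference)
        return(.rebuildSpectra(newdata, mat))
    }
    if (m == "auto") {
        mat <- sweep(sweep(spectraMatrix(newdata), 2L,
                           object@fitted$means, "-"),
                     2L, object@fitted$sds, "/")
        return(.rebuildSpectra(newdata, mat))
    }
    preprocessSpectra(newdata, m)@transformed
})
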