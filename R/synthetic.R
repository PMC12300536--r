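# Statistical generator of SSC-linked grape reflectance spectra. The base
# shape reproduces the qualitative features of red-grape Vis/NIR reflectance:
# an anthocyanin absorption dip near 500 nm, a chlorophyll dip near 680 nm
# with the reflectance trough around 705 nm, and a gradual rise through the
# NIR (C-H / O-H overtone region). The generator is statistical, not a
# radiative-transfer model of grape tissue.

.baseShape <- function(wl) {
    0.50 -
        0.18 * exp(-((wl - 500) / 40)^2) -
        0.24 * exp(-((wl - 693) / 42)^2) +
        0.20 * stats::plogis((wl - 790) / 50) +
        0.05 * exp(-((wl - 590) / 55)^2)
}

#' Configuration of the synthetic spectra generator
#'
#' Defines the study conditions the generator emulates: a batch of grape
#' samples whose SSC follows a truncated normal distribution (defaults match
#' a typical harvest-ripe Cabernet Sauvignon batch: mean 22.03, sd 0.86,
#' range 20.00-24.60 degrees Brix), with reflectance linked linearly to SSC
#' at a small set of informative bands and degraded by per-sample
#' multiplicative scatter, baseline offset, and additive channel noise.
#'
#' @param nSamples number of samples (>= 4); default 120, one day's harvest
#'   batch.
#' @param seed integer RNG seed; the dataset is bit-reproducible from it.
#' @param sscMean,sscStd mean and sd of SSC, degrees Brix.
#' @param sscRange truncation range of SSC, degrees Brix.
#' @param informativeBands wavelengths (nm, subset of the schema centers)
#'   whose reflectance responds to SSC.
#' @param effectSize reflectance change per degree Brix at the informative
#'   bands; default 0.02 (about 2% reflectance per Brix, a realistic
#'   pigment/absorption-linked response for a low-cost sensor).
#' @param scatterSlopeStd sd of the per-sample multiplicative scatter slope
#'   (spectrum is multiplied by `1 + slope`); default 0.05.
#' @param scatterOffsetStd sd of the per-sample additive baseline offset;
#'   default 0.02 reflectance units.
#' @param noiseStd sd of additive channel noise; default 0.01 reflectance
#'   units (roughly 2% of mid-scale signal, typical of a low-cost filter
#'   photometer).
#' @param schema band schema; defaults to [defaultBandSchema()].
#' @return a validated `generatorConfig` list.
#' @examples
#' cfg <- generatorConfig(nSamples = 30, seed = 7)
#' x <- generateDataset(cfg)
#' x
#' @export
generatorConfig <- function(nSamples = 120, seed = 1,
                            sscMean = 22.03, sscStd = 0.86,
                            sscRange = c(20.00, 24.60),
                            informativeBands = c(410, 610, 900),
                            effectSize = 0.02,
                            scatterSlopeStd = 0.05,
                            scatterOffsetStd = 0.02,
                            noiseStd = 0.01,
                            schema = defaultBandSchema()) {
    if (nSamples < 4) stop("'nSamples' must be at least 4")
    if (sscStd <= 0) stop("'sscStd' must be positive")
    if (length(sscRange) != 2 || sscRange[1] >= sscRange[2])
        stop("'sscRange' must be an increasing [min, max] pair")
    if (!all(informativeBands %in% schema$wavelength_nm))
        stop("'informativeBands' must be a subset of the schema centers")
    if (any(c(scatterSlopeStd, scatterOffsetStd, noiseStd) < 0))
        stop("dispersions must be non-negative")
    structure(list(nSamples = as.integer(nSamples), seed = seed,
                   sscMean = sscMean, sscStd = sscStd, sscRange = sscRange,
                   informativeBands = informativeBands,
                   effectSize = effectSize,
                   scatterSlopeStd = scatterSlopeStd,
                   scatterOffsetStd = scatterOffsetStd,
                   noiseStd = noiseStd, schema = schema),
              class = "generatorConfig")
}

# Truncated-normal draws by rejection; vectorized and cheap at these scales.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
    out <- numeric(0)
    while (length(out) < n) {
        draw <- rnorm(2L * (n - length(out)) + 8L, mean, sd)
        out <- c(out, draw[draw >= lower & draw <= upper])
    }
    out[seq_len(n)]
}

#' Generate a synthetic grape spectra dataset
#'
#' Draws SSC values from the configured truncated normal, builds each clean
#' spectrum as the smooth base shape plus `effectSize * (SSC - sscMean)` at
#' the informative bands, then applies per-sample multiplicative scatter
#' (`(1 + slope) * x + offset`) and additive channel noise. Fully
#' reproducible from `config$seed`; the config is archived in
#' `metadata(x)$generator`.
#'
#' @param config a [generatorConfig()].
#' @return a [SpectraSet] with SSC values set.
#' @export
generateDataset <- function(config) {
    stopifnot(inherits(config, "generatorConfig"))
    sch <- config$schema
    wl <- sch$wavelength_nm
    n <- config$nSamples
    p <- length(wl)
    .withSeed(config$seed, {
        sscv <- .rtruncnorm(n, config$sscMean, config$sscStd,
                            config$sscRange[1], config$sscRange[2])
        base <- .baseShape(wl)
        eff <- as.numeric(wl %in% config$informativeBands) * config$effectSize
        clean <- matrix(base, n, p, byrow = TRUE) +
            outer(sscv - config$sscMean, eff)
        slope <- rnorm(n, 0, config$scatterSlopeStd)
        offset <- rnorm(n, 0, config$scatterOffsetStd)
        noise <- matrix(rnorm(n * p, 0, config$noiseStd), n, p)
        mat <- clean * (1 + slope) + offset + noise
        ids <- sprintf("S%03d", seq_len(n))
        out <- SpectraSet(mat, ids = ids, ssc = sscv, schema = sch)
        metadata(out)$generator <- config
        out
    })
}

#' Inject known outliers into a dataset
#'
#' Adds ground-truth abnormal samples for recovery testing. `"spectral"`
#' outliers get extra channel noise with sd `magnitude * noiseStd`
#' (an inflated-noise acquisition, e.g. stray light or contact loss);
#' `"chemical"` outliers get their SSC reference shifted by
#' `magnitude * sscStd` (a corrupted refractometer reading); `"both"`
#' applies both corruptions.
#'
#' @param x a [SpectraSet] with SSC values.
#' @param kind `"spectral"`, `"chemical"` or `"both"`.
#' @param n number of samples to corrupt (`0` is a no-op).
#' @param magnitude multiplier on the relevant dispersion (> 1).
#' @param seed RNG seed governing which samples are hit and the noise drawn.
#' @param noiseStd,sscStd dispersions the magnitudes multiply; default from
#'   `metadata(x)$generator` when the dataset came from [generateDataset()].
#' @return list with elements `dataset` (the corrupted [SpectraSet]) and
#'   `ids` (character vector of injected sample ids).
#' @export
injectOutliers <- function(x, kind = c("spectral", "chemical", "both"),
                           n = 3, magnitude = 8, seed = 1,
                           noiseStd = NULL, sscStd = NULL) {
    kind <- match.arg(kind)
    stopifnot(is(x, "SpectraSet"))
    if (n > ncol(x)) stop("'n' exceeds the number of samples")
    if (n == 0) return(list(dataset = x, ids = character(0)))
    if (magnitude <= 1) stop("'magnitude' must exceed 1")
    gen <- metadata(x)$generator
    if (is.null(noiseStd))
        noiseStd <- if (!is.null(gen)) gen$noiseStd else
            stop("'noiseStd' required when the dataset has no generator config")
    if (is.null(sscStd))
        sscStd <- if (!is.null(gen)) gen$sscStd else
            stop("'sscStd' required when the dataset has no generator config")
    .withSeed(seed, {
        hit <- sort(sample(ncol(x), n))
        mat <- spectraMatrix(x)
        s <- ssc(x)
        if (kind %in% c("spectral", "both"))
            mat[hit, ] <- mat[hit, , drop = FALSE] +
                matrix(rnorm(n * ncol(mat), 0, magnitude * noiseStd),
                       n, ncol(mat))
        if (kind %in% c("chemical", "both"))
            s[hit] <- s[hit] + magnitude * sscStd
        out <- .rebuildSpectra(x, mat)
        ssc(out) <- s
        list(dataset = out, ids = sampleIds(x)[hit])
    })
}
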