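#' Canonical 18-band schema of the multispectral sensor
#'
#' The triad multispectral sensor used for grape SSC work measures 18
#' channels with center wavelengths from 410 nm to 940 nm, each with a
#' full-width-at-half-maximum of 20 nm. This schema defines the channel
#' semantics every [SpectraSet] refers to.
#'
#' @return `data.frame` with columns `wavelength_nm` (strictly increasing
#'   centers) and `fwhm_nm` (uniform bandwidth, nm).
#' @examples
#' sch <- defaultBandSchema()
#' nrow(sch)          # 18
#' range(sch$wavelength_nm)
#' @export
defaultBandSchema <- function() {
    data.frame(
        wavelength_nm = c(410, 435, 460, 485, 510, 535, 560, 585, 610,
                          645, 680, 705, 730, 760, 810, 860, 900, 940),
        fwhm_nm = 20)
}

#' Convert raw sensor counts to reflectance
#'
#' Applies the standard two-point (dark/white) reflectance calibration:
#' `(raw - dark) / (white - dark)`, channel by channel. The dark reference is
#' acquired fully light-shielded, the white reference against a standard
#' white panel. Output is dimensionless reflectance; values slightly above 1
#' are legal (glossy fruit surfaces) and are deliberately not clipped,
#' because clipping would destroy information used by outlier screening.
#'
#' @param raw,dark,white numeric vectors of equal length: sample counts,
#'   dark-reference counts, white-reference counts.
#' @return numeric reflectance vector, same length as `raw`.
#' @examples
#' calibrateReflectance(c(55, 60), dark = c(10, 20), white = c(100, 100))
#' @export
calibrateReflectance <- function(raw, dark, white) {
    if (length(raw) != length(dark) || length(raw) != length(white))
        stop("'raw', 'dark' and 'white' must have equal length")
    denom <- white - dark
    bad <- which(denom <= 0)
    if (length(bad))
        stop("calibration failure: white <= dark at channel(s) ",
             paste(bad, collapse = ", "))
    (raw - dark) / denom
}

#' Average replicate spectral acquisitions
#'
#' Each sample is typically measured three times and the channel-wise mean
#' reflectance is used as its representative spectrum. No replicate-outlier
#' rejection is applied: the average is the plain arithmetic mean.
#'
#' @param replicates numeric matrix (replicates x channels) or a list of
#'   equal-length numeric vectors.
#' @param ids optional vector of sample ids, one per replicate; if given,
#'   all must be identical (replicates of one sample).
#' @return numeric vector: the channel-wise mean spectrum.
#' @examples
#' averageReplicates(rbind(c(0.2, 0.3), c(0.4, 0.5), c(0.6, 0.7)))
#' @export
averageReplicates <- function(replicates, ids = NULL) {
    if (is.list(replicates) && !is.data.frame(replicates)) {
        len <- unique(lengths(replicates))
        if (length(len) != 1)
            stop("replicate spectra must have identical length")
        replicates <- do.call(rbind, replicates)
    }
    replicates <- as.matrix(replicates)
    if (nrow(replicates) < 1) stop("at least one replicate is required")
    if (!is.null(ids) && length(unique(ids)) != 1)
        stop("replicates belong to different samples: ",
             paste(unique(ids), collapse = ", "))
    colMeans(replicates)
}

#' Brix conversions
#'
#' `brixToSugar` converts an SSC reading in degrees Brix to an approximate
#' sugar concentration in g/L; `brixToPotentialAlcohol` converts it to
#' percent potential alcohol. Both are linear with per-degree coefficients
#' exposed as parameters; the defaults (10 g/L and 1.8% per degree Brix)
#' follow the rule-of-thumb conversions used in the wine-grape SSC
#' literature. Note that the 1.8%/degree alcohol coefficient is high
#' relative to oenological convention (~0.55-0.6%); it is a configurable
#' coefficient precisely because conventions differ.
#'
#' @param brix SSC in degrees Brix (non-negative).
#' @param gPerLPerBrix,pctPerBrix per-degree conversion coefficients.
#' @return numeric: sugar in g/L, or potential alcohol in percent.
#' @examples
#' brixToSugar(22.03)            # 220.3 g/L
#' brixToPotentialAlcohol(1.0)   # 1.8 %
#' @export
brixToSugar <- function(brix, gPerLPerBrix = 10) {
    if (any(brix < 0)) stop("'brix' must be non-negative")
    gPerLPerBrix * brix
}

#' @rdname brixToSugar
#' @export
brixToPotentialAlcohol <- function(brix, pctPerBrix = 1.8) {
    if (any(brix < 0)) stop("'brix' must be non-negative")
    pctPerBrix * brix
}

# --- device SD-card text dialect ------------------------------------------
# One record per line: ISO-8601 timestamp, sample id, 18 reflectance values,
# comma-separated; '#'-prefixed comment lines allowed; values printed at 6
# significant digits, UTF-8, '.' decimal separator.

#' Read and write the device SD-card text dialect
#'
#' The handheld logger writes one record per line: an ISO-8601 timestamp, a
#' sample id, then one reflectance value per band, comma-separated;
#' `#`-prefixed comment lines are skipped. Values are stored at 6
#' significant digits, so `readDeviceTxt(writeDeviceTxt(x))` round-trips
#' exactly for data already at that precision.
#'
#' @param path file path.
#' @param schema band schema the file is expected to follow; defaults to
#'   [defaultBandSchema()].
#' @param x a [SpectraSet] to write.
#' @return `readDeviceTxt`: a [SpectraSet] (no SSC; timestamps in
#'   `colData`). `writeDeviceTxt`: `path`, invisibly.
#' @export
readDeviceTxt <- function(path, schema = defaultBandSchema()) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    p <- nrow(schema)
    if (!length(keep))
        return(SpectraSet(matrix(numeric(0), 0, p), ids = character(0),
                          schema = schema))
    ids <- character(length(keep))
    stamps <- character(length(keep))
    mat <- matrix(NA_real_, length(keep), p)
    for (i in seq_along(keep)) {
        ln <- keep[i]
        fields <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
        if (length(fields) != p + 2L)
            stop("parse error at line ", ln, ": expected ", p + 2L,
                 " fields, found ", length(fields))
        vals <- suppressWarnings(as.numeric(fields[-(1:2)]))
        if (anyNA(vals))
            stop("parse error at line ", ln, ": non-numeric reflectance value")
        stamps[i] <- fields[1]
        ids[i] <- fields[2]
        mat[i, ] <- vals
    }
    SpectraSet(mat, ids = ids, schema = schema, timestamps = stamps)
}

#' @rdname readDeviceTxt
#' @export
writeDeviceTxt <- function(x, path) {
    stopifnot(is(x, "SpectraSet"))
    m <- spectraMatrix(x)
    stamps <- colData(x)$timestamp
    if (is.null(stamps)) stamps <- rep("1970-01-01T00:00:00Z", nrow(m))
    lines <- c("# multispectral device log",
               sprintf("# bands_nm: %s",
                       paste(wavelengths(x), collapse = " ")))
    recs <- vapply(seq_len(nrow(m)), function(i) {
        paste(c(stamps[i], sampleIds(x)[i], sprintf("%.6g", m[i, ])),
              collapse = ",")
    }, "")
    writeLines(c(lines, recs), path, useBytes = TRUE)
    invisible(path)
}

#' Read and write spectra as CSV
#'
#' CSV layout: header `sample_id,ssc_brix,r410,...,r940` (one `r<nm>` column
#' per band of the schema), UTF-8, `.` decimal separator. `ssc_brix` may be
#' empty for samples without a reference measurement. Values are written at
#' 10 significant digits.
#'
#' @param path file path.
#' @param schema expected band schema; defaults to [defaultBandSchema()].
#' @param x a [SpectraSet] to write.
#' @return `readSpectraCsv`: a [SpectraSet]; `writeSpectraCsv`: `path`,
#'   invisibly.
#' @export
readSpectraCsv <- function(path, schema = defaultBandSchema()) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.csv(path, check.names = FALSE,
                   colClasses = c(sample_id = "character"))
    want <- c("sample_id", "ssc_brix", sprintf("r%g", schema$wavelength_nm))
    if (!identical(colnames(df), want))
        stop("CSV header does not match the band schema; expected: ",
             paste(want, collapse = ","))
    mat <- as.matrix(df[, -(1:2), drop = FALSE])
    SpectraSet(mat, ids = df$sample_id, ssc = df$ssc_brix, schema = schema)
}

#' @rdname readSpectraCsv
#' @export
writeSpectraCsv <- function(x, path) {
    stopifnot(is(x, "SpectraSet"))
    m <- spectraMatrix(x)
    s <- ssc(x)
    header <- paste(c("sample_id", "ssc_brix",
                      sprintf("r%g", wavelengths(x))), collapse = ",")
    recs <- vapply(seq_len(nrow(m)), function(i) {
        paste(c(sampleIds(x)[i],
                if (is.na(s[i])) "" else sprintf("%.10g", s[i]),
                sprintf("%.10g", m[i, ])), collapse = ",")
    }, "")
    writeLines(c(header, recs), path, useBytes = TRUE)
    invisible(path)
}
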