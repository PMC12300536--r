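# Characteristic-wavelength selection: uninformative variable elimination
# (UVE) and the successive projections algorithm (SPA). Variable indices are
# 1-based into the band schema; outputs also carry wavelengths in nm.

#' Uninformative variable elimination (UVE)
#'
#' Appends `noiseCount` uniform-random columns (scaled far below the real
#' signal) to the spectra, then fits one PLS model per leave-one-out fold
#' and records its regression-coefficient vector. The stability of a
#' variable is `mean/sd` of its coefficient across folds. Real variables
#' whose absolute stability exceeds
#' `cutoffMultiplier * max(|noise stability|)` carry information above the
#' noise floor and are selected; the noise columns themselves are excluded
#' from the selection by construction.
#'
#' @param x a [SpectraSet] with SSC values, or a matrix plus `y`.
#' @param y response when `x` is a matrix.
#' @param nLatent PLS components per fold (must be `< n - 1`).
#' @param noiseCount number of random columns; default = number of real
#'   variables.
#' @param noiseScale noise columns are `runif(n)` times `noiseScale` times
#'   the smallest real-column sd; default `1e-10`.
#' @param cutoffMultiplier multiplier on the maximal absolute noise
#'   stability; default 1.
#' @param seed RNG seed for the noise columns.
#' @return list with `stabilityReal` (named by wavelength when available),
#'   `stabilityNoise`, `cutoff`, `selected` (1-based indices, ascending),
#'   `selectedWavelengths` (nm, when `x` is a `SpectraSet`).
#' @examples
#' x <- generateDataset(generatorConfig(nSamples = 40, seed = 4,
#'                                      noiseStd = 0.002))
#' sel <- uveSelect(x, nLatent = 3, seed = 1)
#' sel$selectedWavelengths
#' @export
uveSelect <- function(x, y = NULL, nLatent = 2, noiseCount = NULL,
                      noiseScale = 1e-10, cutoffMultiplier = 1, seed = 1) {
    X <- .xMatrix(x)
    yv <- .yVector(x, y)
    n <- nrow(X); p <- ncol(X)
    if (is.null(noiseCount)) noiseCount <- p
    if (nLatent >= n - 1) stop("'nLatent' must be below n - 1")
    scale_unit <- noiseScale * min(apply(X, 2L, sd))
    Xa <- .withSeed(seed,
        cbind(X, matrix(runif(n * noiseCount), n, noiseCount) * scale_unit))
    ptot <- ncol(Xa)
    coefs <- matrix(0, n, ptot)
    for (i in seq_len(n)) {
        fit <- .plsCoefs(Xa[-i, , drop = FALSE], yv[-i], nLatent)
        coefs[i, ] <- fit$b
    }
    mu <- colMeans(coefs)
    sds <- apply(coefs, 2L, sd)
    stab <- ifelse(sds > 0, mu / sds,
                   ifelse(mu == 0, 0, sign(mu) * Inf))
    stabReal <- stab[seq_len(p)]
    stabNoise <- stab[-seq_len(p)]
    cutoff <- cutoffMultiplier * max(abs(stabNoise))
    selected <- which(abs(stabReal) > cutoff)
    wl <- if (is(x, "SpectraSet")) wavelengths(x) else NULL
    if (!is.null(wl)) names(stabReal) <- sprintf("r%g", wl)
    list(stabilityReal = stabReal, stabilityNoise = stabNoise,
         cutoff = cutoff, selected = selected,
         selectedWavelengths = if (!is.null(wl)) wl[selected] else NULL)
}

# Grow one SPA chain from a start column on an (autoscaled) matrix: at each
# step pick the unselected column with maximal residual norm after
# projection onto the orthogonal complement of the chosen span. Truncates
# when all projections vanish (collinear degenerate input).
.spaChain <- function(Xs, start, maxVars) {
    p <- ncol(Xs)
    chain <- start
    U <- Xs[, start, drop = FALSE]
    U <- U / sqrt(sum(U^2))
    while (length(chain) < maxVars) {
        rest <- setdiff(seq_len(p), chain)
        norms <- vapply(rest, function(j) {
            v <- Xs[, j]
            r <- v - U %*% crossprod(U, v)
            sqrt(sum(r^2))
        }, 0)
        if (max(norms) < 1e-10) break
        pick <- rest[which.max(norms)]
        v <- Xs[, pick]
        r <- v - U %*% crossprod(U, v)
        U <- cbind(U, r / sqrt(sum(r^2)))
        chain <- c(chain, pick)
    }
    chain
}

#' Successive projections algorithm (SPA)
#'
#' Greedy selection of minimally collinear variables: starting from every
#' candidate variable, a chain grows by repeatedly adding the column with
#' the largest projection norm onto the orthogonal complement of the span of
#' the columns already chosen (columns are autoscaled first). Every
#' `(start, length)` chain prefix is then scored by the RMSE of an ordinary
#' least squares model fitted on an SPXY calibration subset and evaluated on
#' the held-out validation subset; the global minimizer wins. Ties go to the
#' shorter chain, then the lower start index. The procedure is fully
#' deterministic.
#'
#' @param x a [SpectraSet] with SSC values, or a matrix plus `y`.
#' @param y response when `x` is a matrix.
#' @param maxVars maximal chain length (default 5).
#' @param validationFraction held-out fraction for prefix scoring
#'   (default 0.25).
#' @return list with `selected` (winning 1-based indices, ascending),
#'   `selectedWavelengths` (nm, when available), `chain` (winning chain in
#'   pick order), `scores` (`data.frame` of start, length, rmse).
#' @export
spaSelect <- function(x, y = NULL, maxVars = 5, validationFraction = 0.25) {
    X <- .xMatrix(x)
    yv <- .yVector(x, y)
    n <- nrow(X); p <- ncol(X)
    if (maxVars < 1 || maxVars > p) stop("'maxVars' must be in [1, p]")
    if (n < maxVars + 2) stop("need at least maxVars + 2 samples")
    ids <- rownames(X)
    if (is.null(ids)) { ids <- sprintf("S%d", seq_len(n)); rownames(X) <- ids }
    sp <- spxySplit(X, calFraction = 1 - validationFraction, y = yv)
    cal <- match(sp$calibrationIds, ids)
    val <- match(sp$validationIds, ids)
    Xcal <- X[cal, , drop = FALSE]
    mu <- colMeans(Xcal)
    sds <- apply(Xcal, 2L, sd)
    sds[sds == 0] <- 1
    Xs <- sweep(sweep(Xcal, 2L, mu, "-"), 2L, sds, "/")
    scores <- NULL
    best <- list(rmse = Inf, chain = integer(0))
    for (start in seq_len(p)) {
        chain <- .spaChain(Xs, start, maxVars)
        for (len in seq_along(chain)) {
            sub <- chain[seq_len(len)]
            fit <- lm.fit(cbind(1, Xcal[, sub, drop = FALSE]), yv[cal])
            pred <- drop(cbind(1, X[val, sub, drop = FALSE]) %*% fit$coefficients)
            rmse <- sqrt(mean((pred - yv[val])^2))
            scores <- rbind(scores,
                            data.frame(start = start, length = len,
                                       rmse = rmse))
            better <- rmse < best$rmse - 1e-12 ||
                (abs(rmse - best$rmse) <= 1e-12 &&
                 (len < length(best$chain) ||
                  (len == length(best$chain) && start < best$chain[1])))
            if (better) best <- list(rmse = rmse, chain = sub)
        }
    }
    wl <- if (is(x, "SpectraSet")) wavelengths(x) else NULL
    selected <- sort(best$chain)
    list(selected = selected,
         selectedWavelengths = if (!is.null(wl)) wl[selected] else NULL,
         chain = best$chain, rmse = best$rmse, scores = scores)
}

#' Restrict a dataset to selected bands
#'
#' Keeps only the selected spectral variables (1-based indices into the band
#' schema); the schema is subset accordingly and SSC values are untouched.
#'
#' @param x a [SpectraSet].
#' @param selected integer indices of bands to keep (non-empty).
#' @return the restricted [SpectraSet].
#' @examples
#' x <- generateDataset(generatorConfig(nSamples = 5, seed = 1))
#' wavelengths(restrictBands(x, c(1, 5, 8, 9, 17)))
#' @export
restrictBands <- function(x, selected) {
    stopifnot(is(x, "SpectraSet"))
    selected <- sort(unique(as.integer(selected)))
    if (!length(selected)) stop("'selected' must not be empty")
    if (any(selected < 1 | selected > nBands(x)))
        stop("band indices out of range [1, ", nBands(x), "]")
    x[selected, ]
}
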