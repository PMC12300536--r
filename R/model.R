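# SPXY partitioning, NIPALS-PLS regression, latent-variable selection, and
# the RC2/RMSEC/RV2/RMSEV metric suite.

#' SPXY calibration/validation partitioning
#'
#' Sample-set partitioning based on joint X-Y distances: pairwise Euclidean
#' distances on the spectra and absolute response differences are each
#' normalized by their maximum and summed, `d = dx/max(dx) + dy/max(dy)`.
#' The two mutually farthest samples seed the calibration set; the sample
#' whose minimum distance to the current calibration set is largest joins it
#' repeatedly until the calibration size is reached; the remainder forms the
#' validation set. Ties are broken toward the lower sample id, making the
#' split invariant to row order.
#'
#' @param x a [SpectraSet] with SSC, or a numeric matrix.
#' @param calFraction target calibration fraction; default 0.75. The
#'   calibration size is `round(calFraction * n)` (round-half-even).
#' @param calSize explicit calibration count overriding `calFraction` (lets
#'   a 113-sample set be split 83/30 exactly).
#' @param y response vector when `x` is a matrix.
#' @return list with `calibrationIds`, `validationIds`, `calFraction`.
#' @examples
#' x <- generateDataset(generatorConfig(nSamples = 20, seed = 3))
#' sp <- spxySplit(x)
#' length(sp$calibrationIds)   # 15
#' @export
spxySplit <- function(x, calFraction = 0.75, calSize = NULL, y = NULL) {
    X <- .xMatrix(x)
    yv <- .yVector(x, y)
    n <- nrow(X)
    if (n < 4) stop("SPXY needs at least 4 samples")
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("S%d", seq_len(n))
    if (is.null(calSize)) calSize <- as.integer(round(calFraction * n))
    if (calSize < 2 || calSize >= n)
        stop("calibration size must be in [2, n-1]")
    dx <- as.matrix(dist(X))
    dy <- abs(outer(yv, yv, "-"))
    mx <- max(dx); my <- max(dy)
    if (mx == 0 && my == 0)
        stop("all samples identical in X and y: no metric structure")
    if (my == 0) {
        warning("constant response: SPXY reduces to Kennard-Stone on X")
        d <- dx / mx
    } else if (mx == 0) {
        d <- dy / my
    } else {
        d <- dx / mx + dy / my
    }
    # seed pair: maximal joint distance, ties toward lexicographically
    # smallest id pair
    ord <- order(ids)
    d_o <- d[ord, ord]
    ids_o <- ids[ord]
    best <- which(d_o == max(d_o), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    cal <- c(best[1, 1], best[1, 2])
    remaining <- setdiff(seq_len(n), cal)
    while (length(cal) < calSize) {
        mind <- vapply(remaining,
                       function(i) min(d_o[i, cal]), 0)
        pick <- remaining[which.max(mind)]   # ids_o sorted: first max = low id
        cal <- c(cal, pick)
        remaining <- setdiff(remaining, pick)
    }
    list(calibrationIds = ids_o[sort(cal)],
         validationIds = ids_o[sort(remaining)],
         calFraction = calSize / n)
}

# NIPALS returning coefficients for every component count 1..kmax (nested).
.plsCoefPath <- function(X, y, kmax) {
    xm <- colMeans(X); ym <- mean(y)
    Xd <- sweep(X, 2L, xm, "-"); yc <- y - ym
    p <- ncol(X)
    W <- matrix(0, p, kmax); P <- matrix(0, p, kmax); Q <- numeric(kmax)
    B <- matrix(0, p, kmax); b0 <- numeric(kmax)
    a <- 0L
    for (i in seq_len(kmax)) {
        w <- crossprod(Xd, yc)
        nw <- sqrt(sum(w * w))
        if (nw < 1e-12) break
        w <- w / nw
        tt <- Xd %*% w
        t2 <- sum(tt * tt)
        if (t2 < 1e-24) break
        pa <- crossprod(Xd, tt) / t2
        Q[i] <- sum(yc * tt) / t2
        Xd <- Xd - tcrossprod(tt, pa)
        W[, i] <- w; P[, i] <- pa
        a <- i
        Wk <- W[, seq_len(a), drop = FALSE]
        Pk <- P[, seq_len(a), drop = FALSE]
        B[, i] <- Wk %*% solve(crossprod(Pk, Wk), Q[seq_len(a)])
        b0[i] <- ym - sum(xm * B[, i])
    }
    if (a < kmax && a > 0L)
        for (i in seq((a + 1L), kmax)) { B[, i] <- B[, a]; b0[i] <- b0[a] }
    list(B = B, b0 = b0, rank = a)
}

#' Fit a PLS regression model by NIPALS
#'
#' PLS1 regression with column-mean centering and no scaling (scaling is a
#' preprocessing choice, keeping the eight preprocessing methods
#' comparable). Components are extracted by NIPALS with deflation of X; the
#' regression coefficients in original variable space are composed so that
#' prediction does not need the latent path.
#'
#' @param x predictor [SpectraSet] or numeric matrix (samples x variables).
#' @param y response vector (degrees Brix); taken from `ssc(x)` when `x` is
#'   a `SpectraSet` and `y` is `NULL`.
#' @param nLatent number of latent variables,
#'   `1 <= nLatent <= min(n - 1, p)`. Requests beyond the effective rank are
#'   truncated with a warning.
#' @return a [PLSModel].
#' @examples
#' x <- generateDataset(generatorConfig(nSamples = 30, seed = 2))
#' m <- plsFit(x, nLatent = 3)
#' head(plsPredict(m, x))
#' @export
plsFit <- function(x, y = NULL, nLatent = 2) {
    X <- .xMatrix(x)
    yv <- .yVector(x, y)
    n <- nrow(X); p <- ncol(X)
    if (length(yv) != n) stop("'y' length must match the number of samples")
    if (var(yv) == 0) stop("response has zero variance")
    if (nLatent < 1 || nLatent > min(n - 1, p))
        stop("'nLatent' must be in [1, min(n-1, p)] = [1, ",
             min(n - 1, p), "]")
    xm <- colMeans(X); ym <- mean(yv)
    Xd <- sweep(X, 2L, xm, "-"); yc <- yv - ym
    W <- matrix(0, p, nLatent); P <- matrix(0, p, nLatent)
    Q <- numeric(nLatent); Tm <- matrix(0, n, nLatent)
    a <- 0L
    for (i in seq_len(nLatent)) {
        w <- crossprod(Xd, yc)
        nw <- sqrt(sum(w * w))
        if (nw < 1e-12) break
        w <- w / nw
        tt <- Xd %*% w
        t2 <- sum(tt * tt)
        if (t2 < 1e-24) break
        pa <- crossprod(Xd, tt) / t2
        Q[i] <- sum(yc * tt) / t2
        Xd <- Xd - tcrossprod(tt, pa)
        W[, i] <- w; P[, i] <- pa; Tm[, i] <- tt
        a <- i
    }
    if (a == 0L) stop("predictors have zero variance: no PLS component")
    if (a < nLatent) {
        warning("requested ", nLatent, " components but effective rank is ",
                a, "; truncating")
        W <- W[, seq_len(a), drop = FALSE]
        P <- P[, seq_len(a), drop = FALSE]
        Tm <- Tm[, seq_len(a), drop = FALSE]
        Q <- Q[seq_len(a)]
    }
    b <- drop(W %*% solve(crossprod(P, W), Q))
    bn <- colnames(X)
    if (is.null(bn)) bn <- sprintf("V%d", seq_len(p))
    new("PLSModel", nLatent = a, xMeans = xm, yMean = ym,
        weights = W, xLoadings = P, yLoadings = Q, scores = Tm,
        coefficients = b, intercept = ym - sum(xm * b), bandNames = bn)
}

#' Predict from a fitted PLS model
#'
#' @param model a [PLSModel].
#' @param x new predictors: [SpectraSet] or matrix with the same variables
#'   the model was trained on.
#' @return numeric vector of predictions (degrees Brix for SSC models).
#' @export
plsPredict <- function(model, x) {
    X <- .xMatrix(x)
    if (ncol(X) != length(model@coefficients))
        stop("new data has ", ncol(X), " variables; model expects ",
             length(model@coefficients))
    drop(X %*% model@coefficients) + model@intercept
}

#' Choose the number of latent variables by cross-validation
#'
#' k-fold (default leave-one-out) cross-validated RMSE is computed for every
#' candidate count `1..maxLatent`; the smallest candidate whose RMSE is
#' within 2% of the global minimum wins (parsimony rule). Fold assignment is
#' seeded and keyed by sample id, so the choice is reproducible across row
#' orders.
#'
#' @param x predictor [SpectraSet] or matrix.
#' @param y response; from `ssc(x)` when omitted.
#' @param maxLatent largest candidate, `<= min(n - 1, p)`.
#' @param folds number of CV folds; `NULL` (default) = leave-one-out.
#' @param seed seed for the fold permutation.
#' @return integer: chosen number of latent variables. The per-candidate CV
#'   RMSE is attached as attribute `"cvRmse"`.
#' @export
chooseNLatent <- function(x, y = NULL, maxLatent = 8, folds = NULL,
                          seed = 1) {
    X <- .xMatrix(x)
    yv <- .yVector(x, y)
    n <- nrow(X)
    maxLatent <- min(maxLatent, n - 2L, ncol(X))
    if (maxLatent < 1) stop("too few samples to cross-validate")
    if (is.null(folds)) folds <- n
    if (folds > n) stop("'folds' cannot exceed the number of samples")
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("S%d", seq_len(n))
    ord <- order(ids)
    fold_of <- integer(n)
    fold_of[ord] <- .withSeed(seed,
        sample(rep_len(seq_len(folds), n)))
    press <- numeric(maxLatent)
    for (f in seq_len(folds)) {
        hold <- which(fold_of == f)
        if (!length(hold)) next
        path <- .plsCoefPath(X[-hold, , drop = FALSE], yv[-hold], maxLatent)
        pred <- X[hold, , drop = FALSE] %*% path$B +
            matrix(path$b0, length(hold), maxLatent, byrow = TRUE)
        press <- press + colSums((pred - yv[hold])^2)
    }
    rmse <- sqrt(press / n)
    best <- min(rmse)
    k <- which(rmse <= 1.02 * best)[1]
    structure(as.integer(k), cvRmse = rmse)
}

#' Evaluate a PLS model on a calibration/validation split
#'
#' Computes the standard chemometric metric suite: coefficient of
#' determination and root-mean-square error on the calibration set (RC2,
#' RMSEC) and validation set (RV2, RMSEV). R-squared is the coefficient of
#' determination `1 - SSres/SStot`, with SStot taken about each set's own
#' mean (not a squared Pearson correlation).
#'
#' @param model a [PLSModel] trained on the split's calibration rows only.
#' @param split a split from [spxySplit()].
#' @param x the full dataset ([SpectraSet] or matrix with rownames).
#' @param y response; from `ssc(x)` when omitted.
#' @param provenance list recording preprocessing/selection/outlier
#'   provenance for the report.
#' @return a [FitReport].
#' @examples
#' x <- generateDataset(generatorConfig(nSamples = 40, seed = 5))
#' sp <- spxySplit(x)
#' m <- plsFit(x[, sp$calibrationIds], nLatent = 3)
#' evaluateFit(m, sp, x)
#' @export
evaluateFit <- function(model, split, x, y = NULL, provenance = list()) {
    X <- .xMatrix(x)
    yv <- .yVector(x, y)
    ids <- rownames(X)
    if (is.null(ids)) stop("'x' must carry sample ids as row names")
    names(yv) <- ids
    if (length(split$validationIds) < 2)
        stop("validation set must contain at least 2 samples")
    one <- function(which_ids) {
        pred <- plsPredict(model, X[which_ids, , drop = FALSE])
        ref <- yv[which_ids]
        ssres <- sum((ref - pred)^2)
        sstot <- sum((ref - mean(ref))^2)
        c(r2 = 1 - ssres / sstot, rmse = sqrt(mean((ref - pred)^2)))
    }
    calm <- one(split$calibrationIds)
    valm <- one(split$validationIds)
    new("FitReport", rc2 = unname(calm["r2"]), rmsec = unname(calm["rmse"]),
        rv2 = unname(valm["r2"]), rmsev = unname(valm["rmse"]),
        nLatent = model@nLatent, provenance = provenance)
}
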