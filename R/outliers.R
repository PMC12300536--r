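# Outlier screening: Monte-Carlo resampling of PLS prediction residuals and
# PCA with Hotelling T2 limits, plus their union/intersection combination.

#' Monte-Carlo resampling outlier detection
#'
#' Repeatedly splits the samples at random into a calibration subset and a
#' held-out remainder, fits a PLS model on the calibration subset and
#' predicts the held-out samples. Across iterations every sample accumulates
#' prediction residuals (`predicted - reference`); a sample whose residual
#' mean is unusually large in magnitude is a chemical (reference-value)
#' outlier, one whose residual standard deviation is unusually large is a
#' spectral outlier, and one with both is abnormal in both senses.
#'
#' Thresholds follow a k-sigma rule on the population of per-sample
#' statistics: `mean(stat) + k * sd(stat)`, applied to `|residual mean|` and
#' to the residual sd. The signed residual means are reported; flagging uses
#' the magnitude so that reference errors of either sign are caught.
#'
#' @param x a [SpectraSet] with SSC values (or matrix plus `y`).
#' @param nIterations number of random splits (>= 100; default 1000).
#' @param calFraction fraction of samples in each calibration subset
#'   (`0.5 <= calFraction < 1`; default 0.8).
#' @param nLatent PLS components per iteration; default `NULL` chooses once
#'   by 5-fold cross-validation on the full set.
#' @param k threshold multiplier (default 2.5).
#' @param seed RNG seed; sampling is keyed by sorted sample id, so flags are
#'   invariant to row order.
#' @param y response when `x` is a matrix.
#' @return `data.frame` with one row per sample: `sample_id`,
#'   `residual_mean`, `residual_std` (degrees Brix), `n_validation`,
#'   `high_mean`, `high_std`, `flag`, `mean_threshold`, `std_threshold`.
#' @examples
#' x <- generateDataset(generatorConfig(nSamples = 40, seed = 2))
#' st <- mcOutlierDetect(x, nIterations = 200, nLatent = 2, seed = 9)
#' table(st$flag)
#' @export
mcOutlierDetect <- function(x, nIterations = 1000, calFraction = 0.8,
                            nLatent = NULL, k = 2.5, seed = 1, y = NULL) {
    if (nIterations < 100) stop("'nIterations' must be at least 100")
    if (calFraction < 0.5 || calFraction >= 1)
        stop("'calFraction' must be in [0.5, 1)")
    X <- .xMatrix(x)
    yv <- .yVector(x, y)
    n <- nrow(X)
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("S%d", seq_len(n))
    ord <- order(ids)
    Xo <- X[ord, , drop = FALSE]
    yo <- yv[ord]
    ids_o <- ids[ord]
    calSize <- floor(calFraction * n)
    if (is.null(nLatent))
        nLatent <- as.integer(chooseNLatent(Xo, yo, maxLatent = 8,
                                            folds = 5, seed = seed))
    if (nLatent >= min(calSize, ncol(X) + 1))
        stop("'nLatent' must be below the rank of the calibration matrix")
    rs <- numeric(n); rs2 <- numeric(n); cnt <- integer(n)
    .withSeed(seed, {
        for (it in seq_len(nIterations)) {
            cal <- sample.int(n, calSize)
            fit <- .plsCoefs(Xo[cal, , drop = FALSE], yo[cal], nLatent)
            hold <- setdiff(seq_len(n), cal)
            res <- drop(Xo[hold, , drop = FALSE] %*% fit$b) + fit$b0 -
                yo[hold]
            rs[hold] <- rs[hold] + res
            rs2[hold] <- rs2[hold] + res^2
            cnt[hold] <- cnt[hold] + 1L
        }
    })
    if (any(cnt < 2))
        stop("sample(s) ", paste(ids_o[cnt < 2], collapse = ", "),
             " held out fewer than twice; increase 'nIterations'")
    m <- rs / cnt
    s <- sqrt(pmax(rs2 / cnt - m^2, 0) * cnt / (cnt - 1))
    # clamp float-epsilon residual statistics so a perfectly linear dataset
    # yields no flags under the relative k-sigma rule
    m[abs(m) < 1e-8] <- 0
    s[s < 1e-8] <- 0
    meanThr <- mean(abs(m)) + k * sd(abs(m))
    stdThr <- mean(s) + k * sd(s)
    out <- data.frame(sample_id = ids_o,
                      residual_mean = m, residual_std = s,
                      n_validation = cnt,
                      high_mean = abs(m) > meanThr,
                      high_std = s > stdThr,
                      mean_threshold = meanThr, std_threshold = stdThr,
                      row.names = NULL)
    out$flag <- out$high_mean | out$high_std
    # report in the original row order of x
    out[match(ids, out$sample_id), , drop = FALSE]
}

#' PCA outlier detection with Hotelling T-squared limits
#'
#' Column-mean-centered spectra are decomposed by principal component
#' analysis; each sample's Hotelling statistic over the first `nComponents`
#' scores, \eqn{T^2_i = \sum_k t_{ik}^2/\lambda_k}, is compared with the
#' small-sample F-based critical value
#' \eqn{[k(n-1)(n+1)/(n(n-k))] F_{1-\alpha}(k, n-k)}, the boundary of the
#' \eqn{(1-\alpha)} confidence ellipse in score space. Samples outside the
#' ellipse are flagged.
#'
#' @param x a [SpectraSet] or numeric matrix (samples x variables).
#' @param nComponents number of principal components (default 2).
#' @param alpha significance level (default 0.05, the 95% ellipse).
#' @return `data.frame` with `sample_id`, score columns `PC1..PCk`,
#'   `t_squared`, `limit`, `flag`.
#' @export
pcaHotellingDetect <- function(x, nComponents = 2, alpha = 0.05) {
    X <- .xMatrix(x)
    n <- nrow(X)
    k <- nComponents
    if (n <= k + 1) stop("need more than nComponents + 1 samples")
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("S%d", seq_len(n))
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    lam <- pc$sdev^2
    if (length(lam) < k || lam[k] < 1e-12 * lam[1])
        stop("degenerate covariance: zero eigenvalue among the first ",
             k, " components")
    sc <- pc$x[, seq_len(k), drop = FALSE]
    t2 <- rowSums(sweep(sc^2, 2L, lam[seq_len(k)], "/"))
    lim <- k * (n - 1) * (n + 1) / (n * (n - k)) * qf(1 - alpha, k, n - k)
    out <- data.frame(sample_id = ids, sc, t_squared = t2, limit = lim,
                      flag = t2 > lim, row.names = NULL)
    out
}

#' Combine Monte-Carlo and PCA outlier flags
#'
#' Combines the two screening results into a single removal list, by union
#' (default) or intersection of the flagged samples.
#'
#' @param mc,pca either the statistics `data.frame`s from
#'   [mcOutlierDetect()] / [pcaHotellingDetect()] (columns `sample_id`,
#'   `flag`) or plain character vectors of flagged sample ids.
#' @param mode `"union"` or `"intersection"`.
#' @param ids optional full id universe used to sanity-check vector input.
#' @return an [OutlierReport].
#' @examples
#' rep <- combineOutliers(c("92", "95", "115"),
#'                        c("81", "95", "108", "115", "117", "120"))
#' rep@combinedIds          # 7 ids
#' @export
combineOutliers <- function(mc, pca, mode = c("union", "intersection"),
                            ids = NULL) {
    mode <- match.arg(mode)
    pull <- function(obj) {
        if (is.data.frame(obj)) {
            stopifnot(all(c("sample_id", "flag") %in% colnames(obj)))
            list(tab = obj, flagged = obj$sample_id[obj$flag])
        } else {
            list(tab = data.frame(), flagged = as.character(obj))
        }
    }
    m <- pull(mc); p <- pull(pca)
    if (nrow(m$tab) && nrow(p$tab) &&
        !setequal(m$tab$sample_id, p$tab$sample_id))
        stop("MC and PCA tables cover different sample id sets")
    if (!is.null(ids)) {
        extra <- setdiff(c(m$flagged, p$flagged), ids)
        if (length(extra))
            stop("flagged ids not in the dataset: ",
                 paste(extra, collapse = ", "))
    }
    combined <- switch(mode,
                       union = union(m$flagged, p$flagged),
                       intersection = intersect(m$flagged, p$flagged))
    new("OutlierReport", mc = m$tab, pca = p$tab,
        combinedIds = as.character(sort(combined)), mode = mode)
}

#' Classify Monte-Carlo outliers by quadrant
#'
#' In the residual mean/standard-deviation plane, the threshold lines split
#' samples into four quadrants: unusually large `|mean|` only indicates a
#' chemical (reference-value) outlier; unusually large residual sd only
#' indicates a spectral outlier; both together indicate a sample abnormal in
#' both its spectrum and its reference value.
#'
#' @param stats the `data.frame` from [mcOutlierDetect()].
#' @return character vector (one per sample) in
#'   `{"normal", "chemical", "spectral", "both"}`, named by sample id.
#' @export
quadrantClassify <- function(stats) {
    stopifnot(all(c("high_mean", "high_std") %in% colnames(stats)))
    lab <- ifelse(stats$high_mean & stats$high_std, "both",
           ifelse(stats$high_mean, "chemical",
           ifelse(stats$high_std, "spectral", "normal")))
    names(lab) <- stats$sample_id
    lab
}

#' Run the full outlier screen on a dataset
#'
#' Convenience wrapper running [mcOutlierDetect()] and/or
#' [pcaHotellingDetect()] on the raw spectra and combining the flags.
#'
#' @param x a [SpectraSet] with SSC values.
#' @param method `"both"`, `"mc"` or `"pca"`.
#' @param mode combination mode, `"union"` (default) or `"intersection"`.
#' @param nIterations,calFraction,nLatent,k,seed passed to
#'   [mcOutlierDetect()].
#' @param nComponents,alpha passed to [pcaHotellingDetect()].
#' @return an [OutlierReport].
#' @export
detectOutliers <- function(x, method = c("both", "mc", "pca"),
                           mode = c("union", "intersection"),
                           nIterations = 1000, calFraction = 0.8,
                           nLatent = NULL, k = 2.5, seed = 1,
                           nComponents = 2, alpha = 0.05) {
    method <- match.arg(method)
    mode <- match.arg(mode)
    mc <- if (method %in% c("both", "mc"))
        mcOutlierDetect(x, nIterations, calFraction, nLatent, k, seed)
    else character(0)
    pca <- if (method %in% c("both", "pca"))
        pcaHotellingDetect(x, nComponents, alpha)
    else character(0)
    combineOutliers(mc, pca, mode, ids = sampleIds(x))
}

#' Remove flagged outliers from a dataset
#'
#' @param x a [SpectraSet].
#' @param report an [OutlierReport] (or character vector of ids to drop).
#' @return the [SpectraSet] without the flagged samples.
#' @export
removeOutliers <- function(x, report) {
    drop_ids <- if (is(report, "OutlierReport")) report@combinedIds
                else as.character(report)
    keep <- setdiff(sampleIds(x), drop_ids)
    x[, keep]
}

#' Serialize an outlier report
#'
#' Writes the per-sample MC and PCA statistics tables as CSV and a JSON
#' summary (mode, flagged ids per method, combined removal list).
#'
#' @param report an [OutlierReport].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeOutlierReport <- function(report, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    if (nrow(report@mc)) {
        pth <- file.path(dir, "outliers_mc.csv")
        write.csv(report@mc, pth, row.names = FALSE)
        paths <- c(paths, pth)
    }
    if (nrow(report@pca)) {
        pth <- file.path(dir, "outliers_pca.csv")
        write.csv(report@pca, pth, row.names = FALSE)
        paths <- c(paths, pth)
    }
    summ <- list(mode = report@mode,
                 mc_flagged = if (nrow(report@mc))
                     report@mc$sample_id[report@mc$flag] else character(0),
                 pca_flagged = if (nrow(report@pca))
                     report@pca$sample_id[report@pca$flag] else character(0),
                 combined = report@combinedIds)
    jp <- file.path(dir, "outliers_summary.json")
    jsonlite::write_json(summ, jp, auto_unbox = FALSE, pretty = TRUE)
    invisible(c(paths, jp))
}
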