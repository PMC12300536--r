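# Internal helpers shared across modules.

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

# Accept a SpectraSet or a plain matrix as predictor input.
.xMatrix <- function(x) {
    if (is(x, "SpectraSet")) spectraMatrix(x)
    else as.matrix(x)
}

# Response vector for model-facing ops: explicit y wins, else SSC.
.yVector <- function(x, y) {
    if (!is.null(y)) return(as.numeric(y))
    if (is(x, "SpectraSet")) {
        s <- ssc(x)
        if (anyNA(s))
            stop("SSC values are missing for some samples; supply 'y'")
        return(as.numeric(s))
    }
    stop("no response: supply 'y' or a SpectraSet with SSC values")
}

# Lean NIPALS core used in resampling loops: centered PLS1, returns the
# composed coefficients only. k is truncated silently at the effective rank.
.plsCoefs <- function(X, y, k) {
    xm <- colMeans(X)
    ym <- mean(y)
    Xd <- sweep(X, 2L, xm, "-")
    yc <- y - ym
    p <- ncol(X)
    W <- matrix(0, p, k)
    P <- matrix(0, p, k)
    Q <- numeric(k)
    a <- 0L
    for (i in seq_len(k)) {
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
        W[, i] <- w
        P[, i] <- pa
        a <- i
    }
    if (a == 0L) return(list(b = numeric(p), b0 = ym, k = 0L))
    Wk <- W[, seq_len(a), drop = FALSE]
    Pk <- P[, seq_len(a), drop = FALSE]
    b <- drop(Wk %*% solve(crossprod(Pk, Wk), Q[seq_len(a)]))
    list(b = b, b0 = ym - sum(xm * b), k = a)
}

# Rebuild a SpectraSet around a new samples x bands matrix, keeping sample
# metadata; optionally with a new band schema.
.rebuildSpectra <- function(x, mat, schema = bandSchema(x)) {
    out <- SpectraSet(mat, ids = sampleIds(x), schema = schema)
    colData(out) <- colData(x)
    metadata(out) <- metadata(x)
    out
}
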