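# Shared fixtures and independent oracles, all built in code.

# Small synthetic dataset with study-condition defaults unless overridden.
smallSpectra <- function(n = 40, seed = 1, ...) {
    generateDataset(generatorConfig(nSamples = n, seed = seed, ...))
}

# Independent brute-force greedy SPXY re-implementation (plain loops, no
# shared code with spxySplit); returns the sorted calibration ids.
spxyOracle <- function(X, y, calSize) {
    n <- nrow(X)
    ids <- rownames(X)
    dx <- as.matrix(dist(X))
    dy <- abs(outer(y, y, "-"))
    d <- dx / max(dx) + dy / max(dy)
    o <- order(ids)
    d <- d[o, o]
    ids <- ids[o]
    best <- c(1, 2)
    bv <- -1
    for (i in 1:(n - 1))
        for (j in (i + 1):n)
            if (d[i, j] > bv + 1e-12) {
                bv <- d[i, j]
                best <- c(i, j)
            }
    cal <- best
    while (length(cal) < calSize) {
        rem <- setdiff(seq_len(n), cal)
        mind <- vapply(rem, function(i) min(d[i, cal]), 0)
        cal <- c(cal, rem[which.max(mind)])
    }
    sort(ids[cal])
}

# Validation RMSE of an OLS model on a fixed calibration/validation index
# split; the scoring rule shared by the SPA exhaustive-search oracle.
olsValRmse <- function(X, y, cal, val, sub) {
    fit <- lm.fit(cbind(1, X[cal, sub, drop = FALSE]), y[cal])
    pred <- drop(cbind(1, X[val, sub, drop = FALSE]) %*% fit$coefficients)
    sqrt(mean((pred - y[val])^2))
}
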