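test_that("SPXY follows the greedy max-min rule on a hand-run case", {
    # four colinear points at 0, 1, 2, 9 with y = position: the seed pair is
    # {0, 9}; the third pick maximizes the min distance -> the point at 2
    X <- matrix(c(0, 1, 2, 9), 4, 1)
    rownames(X) <- c("a", "b", "c", "d")
    sp <- spxySplit(X, calFraction = 0.75, y = c(0, 1, 2, 9))
    expect_setequal(sp$calibrationIds, c("a", "c", "d"))
    expect_identical(sp$validationIds, "b")
})

test_that("SPXY keeps the two mutually farthest samples in calibration", {
    for (s in 1:8) {
        x <- smallSpectra(n = 20, seed = 50 + s)
        sp <- spxySplit(x)
        X <- spectraMatrix(x)
        y <- unname(ssc(x))
        dx <- as.matrix(dist(X))
        d <- dx / max(dx) + abs(outer(y, y, "-")) / max(abs(outer(y, y, "-")))
        far <- which(d == max(d), arr.ind = TRUE)[1, ]
        expect_true(all(sampleIds(x)[far] %in% sp$calibrationIds))
    }
})

test_that("SPXY agrees with a brute-force greedy oracle on small sets", {
    for (s in 1:15) {
        set.seed(s)
        n <- sample(6:12, 1)
        X <- matrix(rnorm(n * 4), n)
        rownames(X) <- sprintf("S%02d", seq_len(n))
        y <- rnorm(n)
        cs <- sample(3:(n - 2), 1)
        sp <- spxySplit(X, calSize = cs, y = y)
        expect_identical(sort(sp$calibrationIds), spxyOracle(X, y, cs))
    }
    # constant response degrades to Kennard-Stone with a warning
    set.seed(1)
    X <- matrix(rnorm(24), 8); rownames(X) <- letters[1:8]
    expect_warning(sp <- spxySplit(X, y = rep(5, 8)), "Kennard-Stone")
    expect_length(sp$calibrationIds, 6)
})

test_that("PLS attains the perfect-fit limit on rank-1 noiseless data", {
    set.seed(60)
    t <- rnorm(20)
    X <- outer(t, c(1, 2, 3, 4)) + 0.5
    rownames(X) <- sprintf("S%02d", 1:20)
    y <- 2 * t + 22
    m <- plsFit(X, y, nLatent = 1)
    expect_equal(unname(plsPredict(m, X)), y)
    sp <- list(calibrationIds = rownames(X)[1:15],
               validationIds = rownames(X)[16:20])
    rep <- evaluateFit(plsFit(X[1:15, ], y[1:15], 1), sp, X, y)
    expect_equal(rep@rc2, 1)
    expect_equal(rep@rmsec, 0)
})

test_that("full-component PLS equals the least-squares solution", {
    for (s in 1:5) {
        set.seed(s)
        X <- matrix(rnorm(30 * 6), 30)
        y <- rnorm(30)
        m <- plsFit(X, y, nLatent = 6)
        ols <- qr.solve(cbind(1, X), y)
        expect_equal(m@coefficients, unname(ols[-1]), tolerance = 1e-8)
        expect_equal(m@intercept, unname(ols[1]), tolerance = 1e-8)
    }
})

test_that("PLS internals satisfy the latent-path identities", {
    x <- smallSpectra(n = 30, seed = 61)
    m <- plsFit(x, nLatent = 4)
    # successive score vectors are mutually orthogonal
    G <- crossprod(m@scores)
    offdiag <- G[upper.tri(G)]
    expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
    # prediction via scores equals prediction via composed coefficients
    Xc <- sweep(spectraMatrix(x), 2, m@xMeans)
    predScores <- drop(Xc %*% m@weights %*%
                       solve(crossprod(m@xLoadings, m@weights), m@yLoadings)) +
        m@yMean
    expect_equal(plsPredict(m, x), predScores, tolerance = 1e-10)
    # centering: adding a constant to all predictors leaves predictions put
    shifted <- spectraMatrix(x) + 0.37
    expect_equal(unname(plsPredict(plsFit(shifted, unname(ssc(x)), 4),
                                   shifted)),
                 unname(plsPredict(m, x)))
    # predicting the calibration mean spectrum returns the mean response
    expect_equal(unname(plsPredict(m, matrix(m@xMeans, 1))), m@yMean)
})

test_that("PLS matches an independent reference implementation", {
    set.seed(62)
    X <- matrix(rnorm(30 * 8), 30, dimnames = list(NULL, paste0("V", 1:8)))
    y <- rnorm(30)
    m1 <- plsFit(X, y, nLatent = 3)
    m2 <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
    p2 <- predict(m2, X)$predict[, 1, 3]
    expect_equal(unname(plsPredict(m1, X)), unname(p2), tolerance = 1e-10)
})

test_that("PLS guards its preconditions and truncates at rank", {
    set.seed(63)
    X <- matrix(rnorm(40), 10)
    expect_error(plsFit(X, rep(1, 10), 2), "zero variance")
    expect_error(plsFit(X, rnorm(10), 5), "nLatent")
    Xr <- outer(rnorm(10), c(1, 2, 3, 4))
    expect_warning(m <- plsFit(Xr, drop(Xr %*% c(1, 0, 0, 0)) + rnorm(10, 0, 1e-6), 3),
                   "truncating")
    expect_equal(m@nLatent, 1L)
})

test_that("cross-validated latent-variable choice recovers the true
           dimension and stays parsimonious under noise", {
    rec <- sum(vapply(1:100, function(s) {
        set.seed(s)
        n <- 40; p <- 10
        T2 <- matrix(rnorm(n * 2), n)
        L <- matrix(rnorm(2 * p), 2)
        X <- T2 %*% L + matrix(rnorm(n * p, 0, 0.05), n)
        y <- drop(T2 %*% c(1, -0.5)) + rnorm(n, 0, 0.05)
        chooseNLatent(X, y, maxLatent = 6) == 2
    }, NA))
    expect_gte(rec, 90)
    nul <- sum(vapply(1:100, function(s) {
        set.seed(200 + s)
        X <- matrix(rnorm(40 * 10), 40)
        chooseNLatent(X, rnorm(40), maxLatent = 6) == 1
    }, NA))
    expect_gt(nul, 50)
    # deterministic given data and fold scheme
    x <- smallSpectra(n = 30, seed = 64)
    expect_identical(chooseNLatent(x, maxLatent = 5, folds = 5, seed = 2),
                     chooseNLatent(x, maxLatent = 5, folds = 5, seed = 2))
})

test_that("fit metrics follow their definitions", {
    X <- matrix(rnorm(18 * 6), 6)
    rownames(X) <- letters[1:6]
    # hand-computable validation block: refs (20,22,24), preds (21,22,23)
    m <- new("PLSModel", nLatent = 1L, xMeans = rep(0, 18), yMean = 0,
             weights = matrix(0, 18, 1), xLoadings = matrix(0, 18, 1),
             yLoadings = 0, scores = matrix(0, 6, 1),
             coefficients = rep(0, 18), intercept = 0,
             bandNames = sprintf("V%d", 1:18))
    fakePred <- c(a = 1, b = 2, c = 3, d = 21, e = 22, f = 23)
    local_mocked_bindings(plsPredict = function(model, x)
        fakePred[rownames(grapeSpec:::.xMatrix(x))], .package = "grapeSpec")
    sp <- list(calibrationIds = c("a", "b", "c"),
               validationIds = c("d", "e", "f"))
    rep <- evaluateFit(m, sp, X, y = c(1, 2, 3, 20, 22, 24))
    expect_equal(rep@rc2, 1)
    expect_equal(rep@rmsec, 0)
    expect_equal(rep@rv2, 0.75)
    expect_equal(rep@rmsev, sqrt(2 / 3), tolerance = 1e-6)
    # r2 = 0 when predicting the set mean everywhere
    fakePred[c("d", "e", "f")] <- 22
    expect_equal(evaluateFit(m, sp, X, y = c(1, 2, 3, 20, 22, 24))@rv2, 0)
    expect_error(evaluateFit(m, list(calibrationIds = c("a", "b", "c", "d", "e"),
                                     validationIds = "f"),
                             X, y = 1:6), "at least 2")
})
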