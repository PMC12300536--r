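test_that("MC screening is silent on noiseless exactly-linear data", {
    x <- generateDataset(generatorConfig(nSamples = 50, seed = 1,
                                         noiseStd = 0,
                                         scatterSlopeStd = 0,
                                         scatterOffsetStd = 0))
    st <- mcOutlierDetect(x, nIterations = 200, nLatent = 1, seed = 4)
    expect_equal(st$residual_mean, rep(0, 50))
    expect_equal(st$residual_std, rep(0, 50))
    expect_false(any(st$flag))
})

test_that("MC screening recovers injected outliers and their quadrants", {
    x <- smallSpectra(n = 60, seed = 2)
    injb <- injectOutliers(x, "both", n = 3, magnitude = 8, seed = 5)
    st <- mcOutlierDetect(injb$dataset, nIterations = 400, nLatent = 3,
                          seed = 6)
    flagged <- st$sample_id[st$flag]
    expect_true(all(injb$ids %in% flagged))
    lab <- quadrantClassify(st)
    expect_true(all(lab[injb$ids] != "normal"))
    # chemical-only corruption shows up through the residual-mean axis
    injc <- injectOutliers(x, "chemical", n = 2, magnitude = 8, seed = 7)
    stc <- mcOutlierDetect(injc$dataset, nIterations = 400, nLatent = 3,
                           seed = 8)
    expect_true(all(stc$high_mean[stc$sample_id %in% injc$ids]))
})

test_that("MC screening is deterministic and row-order invariant", {
    x <- smallSpectra(n = 30, seed = 3)
    st1 <- mcOutlierDetect(x, nIterations = 150, nLatent = 2, seed = 11)
    st2 <- mcOutlierDetect(x, nIterations = 150, nLatent = 2, seed = 11)
    expect_identical(st1, st2)
    xr <- x[, rev(sampleIds(x))]
    st3 <- mcOutlierDetect(xr, nIterations = 150, nLatent = 2, seed = 11)
    expect_setequal(st1$sample_id[st1$flag], st3$sample_id[st3$flag])
    ord <- match(st1$sample_id, st3$sample_id)
    expect_equal(st3$residual_mean[ord], st1$residual_mean)
    expect_error(mcOutlierDetect(x, nIterations = 50), "at least 100")
})

test_that("Hotelling screening flags a far-displaced sample exactly", {
    set.seed(20)
    X <- matrix(rnorm(30 * 5, sd = 0.2), 30)
    X[, 1] <- rnorm(30)                     # dominant first eigendirection
    rownames(X) <- sprintf("S%02d", 1:30)
    X[7, 1] <- X[7, 1] + 25
    res <- pcaHotellingDetect(X, nComponents = 2, alpha = 0.05)
    expect_identical(res$sample_id[res$flag], "S07")
    expect_true(all(res$t_squared >= 0))
    expect_equal(res$flag, res$t_squared > res$limit)
})

test_that("Hotelling limit behaves at the alpha extremes and under
           centering shifts", {
    set.seed(21)
    X <- matrix(rnorm(40 * 6), 40)
    rownames(X) <- sprintf("S%02d", 1:40)
    loose <- pcaHotellingDetect(X, 2, alpha = 0.9999)
    expect_true(all(loose$flag[loose$t_squared > 0]))
    r1 <- pcaHotellingDetect(X, 2, 0.05)
    r2 <- pcaHotellingDetect(sweep(X, 2, rep(-3.7, 6), "-"), 2, 0.05)
    expect_equal(r2$t_squared, r1$t_squared)
    # rank-deficient data: zero eigenvalue among the first components
    Xr <- outer(rnorm(20), rnorm(6))
    rownames(Xr) <- sprintf("S%02d", 1:20)
    expect_error(pcaHotellingDetect(Xr, 2), "degenerate")
})

test_that("flag combination supports union and intersection semantics", {
    mc <- c("92", "95", "115")
    pca <- c("81", "95", "108", "115", "117", "120")
    ids <- as.character(1:120)
    u <- combineOutliers(mc, pca, "union", ids = ids)
    expect_length(u@combinedIds, 7)
    i <- combineOutliers(mc, pca, "intersection", ids = ids)
    expect_identical(i@combinedIds, c("115", "95"))
    e <- combineOutliers(character(0), character(0))
    expect_length(e@combinedIds, 0)
    expect_error(combineOutliers(mc, pca, ids = as.character(1:100)),
                 "not in the dataset")
    # union never removes fewer than either method alone
    expect_gte(length(u@combinedIds), length(mc))
    expect_gte(length(u@combinedIds), length(pca))
})

test_that("quadrant labels follow the mean/std threshold semantics", {
    st <- data.frame(sample_id = c("a", "b", "c", "d"),
                     high_mean = c(TRUE, FALSE, TRUE, FALSE),
                     high_std = c(FALSE, TRUE, TRUE, FALSE))
    expect_identical(unname(quadrantClassify(st)),
                     c("chemical", "spectral", "both", "normal"))
})

test_that("removal keeps all unflagged samples intact", {
    x <- smallSpectra(n = 20, seed = 4)
    rep <- combineOutliers(sampleIds(x)[c(2, 5)], sampleIds(x)[c(5, 9)])
    y <- removeOutliers(x, rep)
    expect_equal(nSamples(y), 17)
    keep <- setdiff(sampleIds(x), rep@combinedIds)
    expect_identical(spectraMatrix(y), spectraMatrix(x)[keep, ])
})

test_that("outlier reports serialize to CSV and JSON", {
    x <- smallSpectra(n = 25, seed = 6)
    rep <- detectOutliers(x, method = "both", nIterations = 150,
                          nLatent = 2, seed = 13)
    dir <- withr::local_tempdir()
    paths <- writeOutlierReport(rep, dir)
    expect_true(all(file.exists(paths)))
    summ <- jsonlite::read_json(file.path(dir, "outliers_summary.json"),
                                simplifyVector = TRUE)
    expect_identical(summ$mode, "union")
    expect_setequal(summ$combined, rep@combinedIds)
})
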