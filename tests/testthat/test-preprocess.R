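test_that("derivatives are divided differences on the wavelength grid", {
    sch <- defaultBandSchema()
    const <- SpectraSet(matrix(0.7, 2, 18), ids = c("a", "b"))
    expect_equal(unname(spectraMatrix(firstDerivative(const)@transformed)),
                 matrix(0, 2, 17))
    # spectrum linear in wavelength: constant FD, zero SD
    lin <- SpectraSet(matrix(0.001 * sch$wavelength_nm, 1, byrow = TRUE),
                      ids = "a")
    fd <- spectraMatrix(firstDerivative(lin)@transformed)
    expect_equal(unname(fd), matrix(0.001, 1, 17))
    sd2 <- spectraMatrix(secondDerivative(lin)@transformed)
    expect_equal(unname(sd2), matrix(0, 1, 16))
    # hand case on two channels: (0.2 - 0.1) / (435 - 410) = 0.004 per nm
    two <- SpectraSet(matrix(c(0.1, 0.2), 1), ids = "a",
                      schema = data.frame(wavelength_nm = c(410, 435),
                                          fwhm_nm = 20))
    r <- firstDerivative(two)
    expect_equal(unname(spectraMatrix(r@transformed)[1, 1]), 0.004)
    expect_equal(wavelengths(r@transformed), 422.5)
    # band axis shrinks by one per derivative order, midpoint centers
    x <- smallSpectra(n = 4, seed = 1)
    expect_equal(nBands(firstDerivative(x)@transformed), 17)
    expect_equal(nBands(secondDerivative(x)@transformed), 16)
    expect_equal(wavelengths(firstDerivative(x)@transformed)[1], 422.5)
    expect_error(firstDerivative(two[1, ]), "at least 2")
})

test_that("MSC maps affine copies of the reference onto the reference", {
    x <- smallSpectra(n = 8, seed = 2)
    ref <- colMeans(spectraMatrix(x))
    m <- rbind(ref, 2 * ref + 1, 0.5 * ref - 0.3)
    xs <- SpectraSet(m, ids = c("a", "b", "c"))
    out <- spectraMatrix(msc(xs, reference = ref)@transformed)
    for (i in 1:3) expect_equal(unname(out[i, ]), unname(ref))
    expect_error(msc(xs, reference = rep(1, 18)), "zero variance")
    # a constant row has zero slope against any reference: flagged, unchanged
    xc <- SpectraSet(rbind(ref, rep(0.4, 18)), ids = c("a", "b"))
    expect_warning(res <- msc(xc, reference = ref), "slope")
    expect_equal(unname(spectraMatrix(res@transformed)[2, ]), rep(0.4, 18))
})

test_that("SNV standardizes every spectrum to mean 0, sd 1", {
    xs <- SpectraSet(matrix(c(1, 2, 3), 1),
                     ids = "a",
                     schema = data.frame(wavelength_nm = c(410, 435, 460),
                                         fwhm_nm = 20))
    expect_equal(unname(spectraMatrix(snv(xs)@transformed)[1, ]),
                 c(-1, 0, 1))
    x <- smallSpectra(n = 10, seed = 3)
    out <- spectraMatrix(snv(x)@transformed)
    expect_equal(unname(rowMeans(out)), rep(0, 10))
    expect_equal(unname(apply(out, 1, sd)), rep(1, 10))
    # idempotence
    expect_equal(spectraMatrix(snv(snv(x)@transformed)@transformed), out)
    xc <- SpectraSet(matrix(0.5, 1, 18), ids = "flatS")
    expect_error(snv(xc), "flatS")
})

test_that("scatter-correction methods are row-affine invariant and remove
           the generator's scatter", {
    x <- smallSpectra(n = 12, seed = 4)
    m <- spectraMatrix(x)
    slopes <- runif(12, 0.5, 2)
    offs <- runif(12, -0.3, 0.3)
    xa <- SpectraSet(m * slopes + offs, ids = sampleIds(x))
    expect_equal(spectraMatrix(snv(xa)@transformed),
                 spectraMatrix(snv(x)@transformed))
    expect_equal(spectraMatrix(normalizeMinMax(xa)@transformed),
                 spectraMatrix(normalizeMinMax(x)@transformed))
    # scatter-only data (no noise, no SSC effect): MSC and SNV collapse
    # between-sample variance below 1% of its pre-transform level
    xs <- generateDataset(generatorConfig(nSamples = 30, seed = 6,
                                          effectSize = 0, noiseStd = 0))
    pre <- apply(spectraMatrix(xs), 2, var)
    for (meth in c("msc", "snv")) {
        post <- apply(spectraMatrix(
            preprocessSpectra(xs, meth)@transformed), 2, var)
        expect_true(all(post < 0.01 * pre))
    }
})

test_that("moving average smooths with reflection edges", {
    const <- SpectraSet(matrix(0.3, 1, 18), ids = "a")
    expect_equal(spectraMatrix(movingAverage(const, 3)@transformed),
                 spectraMatrix(const))
    sch5 <- data.frame(wavelength_nm = seq(410, 510, 25), fwhm_nm = 20)
    xs <- SpectraSet(matrix(c(0, 3, 0, 3, 0), 1), ids = "a", schema = sch5)
    out <- spectraMatrix(movingAverage(xs, 3)@transformed)
    # reflection padding: (3,0,3,0,3,0,3) -> means (2,1,2,1,2)
    expect_equal(unname(out[1, ]), c(2, 1, 2, 1, 2))
    expect_lt(max(out), max(spectraMatrix(xs)))
    expect_error(movingAverage(const, 4), "odd")
    expect_error(movingAverage(const, 19), "odd")
})

test_that("Savitzky-Golay reproduces low-order polynomials and reduces
           noise variance", {
    idx <- 1:18
    poly <- 2 + 0.3 * idx - 0.01 * idx^2
    xs <- SpectraSet(rbind(poly, rep(1, 18)), ids = c("a", "b"))
    out <- spectraMatrix(savitzkyGolay(xs, 5, 2)@transformed)
    expect_equal(unname(out[1, ]), unname(poly))
    expect_equal(unname(out[2, ]), rep(1, 18))
    # variance reduction on white-noise spectra, 200 seeded draws
    set.seed(99)
    noise <- matrix(rnorm(200 * 18, 0.5, 0.05), 200)
    xn <- SpectraSet(noise, ids = sprintf("N%03d", 1:200))
    sm <- spectraMatrix(savitzkyGolay(xn, 5, 2)@transformed)
    expect_lt(mean(apply(sm, 2, var)), mean(apply(noise, 2, var)))
    expect_error(savitzkyGolay(xs, 5, 5), "polyorder")
})

test_that("min-max normalization rescales each spectrum to [0, 1]", {
    xs <- SpectraSet(matrix(c(2, 4, 6), 1), ids = "a",
                     schema = data.frame(wavelength_nm = c(410, 435, 460),
                                         fwhm_nm = 20))
    expect_equal(unname(spectraMatrix(normalizeMinMax(xs)@transformed)[1, ]),
                 c(0, 0.5, 1))
    x <- smallSpectra(n = 9, seed = 5)
    out <- spectraMatrix(normalizeMinMax(x)@transformed)
    expect_equal(unname(apply(out, 1, min)), rep(0, 9))
    expect_equal(unname(apply(out, 1, max)), rep(1, 9))
    again <- spectraMatrix(
        normalizeMinMax(normalizeMinMax(x)@transformed)@transformed)
    expect_equal(again, out)
})

test_that("autoscaling gives unit-variance columns and reusable state", {
    x <- smallSpectra(n = 10, seed = 7)
    res <- autoscale(x)
    out <- spectraMatrix(res@transformed)
    expect_equal(unname(colMeans(out)), rep(0, 18))
    expect_equal(unname(apply(out, 2, sd)), rep(1, 18))
    # two samples: all entries +-1/sqrt(2)
    x2 <- x[, 1:2]
    out2 <- spectraMatrix(autoscale(x2)@transformed)
    expect_equal(abs(unname(out2)), matrix(1 / sqrt(2), 2, 18),
                 tolerance = 1e-12)
    # applying stored params to the training set reproduces the transform
    expect_equal(spectraMatrix(applyPreprocess(res, x)), out)
    # applying to new data uses calibration statistics, not refit ones
    xnew <- smallSpectra(n = 6, seed = 8)
    applied <- spectraMatrix(applyPreprocess(res, xnew))
    manual <- sweep(sweep(spectraMatrix(xnew), 2, res@fitted$means),
                    2, res@fitted$sds, "/")
    expect_equal(applied, manual)
})

test_that("fitted MSC state corrects new spectra against the calibration
           reference", {
    xcal <- smallSpectra(n = 15, seed = 9)
    res <- msc(xcal)
    xval <- smallSpectra(n = 5, seed = 10)
    out <- spectraMatrix(applyPreprocess(res, xval))
    manual <- grapeSpec:::.mscApply(spectraMatrix(xval),
                                    res@fitted$reference)
    expect_equal(out, manual)
})

test_that("transforms preserve sample order and ids", {
    x <- smallSpectra(n = 7, seed = 11)
    for (meth in c("fd", "sd", "msc", "snv", "mas", "sgs", "norm", "auto"))
        expect_identical(
            sampleIds(preprocessSpectra(x, meth)@transformed),
            sampleIds(x))
})
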