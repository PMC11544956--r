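## Independent oracle for Savitzky-Golay weights: explicit polynomial
## least-squares fit over the window, derivative of the fitted polynomial
## at the centre, extracted one unit vector at a time.
sgOracle <- function(window, polyOrder, order) {
    h <- (window - 1) / 2
    xs <- seq(-h, h)
    vapply(seq_len(window), function(k) {
        yk <- numeric(window); yk[k] <- 1
        cf <- coef(lm(yk ~ poly(xs, polyOrder, raw = TRUE)))
        factorial(order) * unname(cf[order + 1])
    }, numeric(1))
}

test_that("5-point quadratic SG weights match the least-squares oracle", {
    expect_equal(sgFilterWeights(5, 2, 1), c(-2, -1, 0, 1, 2) / 10,
                 tolerance = 1e-12)
    expect_equal(sgFilterWeights(5, 2, 2), c(2, -1, -2, -1, 2) / 7,
                 tolerance = 1e-12)
    for (cfg in list(c(5, 2, 1), c(5, 2, 2), c(7, 2, 1), c(7, 3, 2))) {
        expect_equal(sgFilterWeights(cfg[1], cfg[2], cfg[3]),
                     sgOracle(cfg[1], cfg[2], cfg[3]),
                     tolerance = 1e-10)
    }
})

test_that("SG weights agree with the signal package's sgolay filters", {
    skip_if_not_installed("signal")
    for (m in 1:2) {
        S <- signal::sgolay(p = 2, n = 5, m = m)
        expect_equal(sgFilterWeights(5, 2, m), unclass(S)[3, ],
                     ignore_attr = TRUE, tolerance = 1e-10)
    }
})

test_that("SG derivative reproduces polynomial derivatives and drops edges", {
    p <- 12L
    x <- makePairedSet(nDays = 1L, p = p, seed = 1L)
    i <- seq_len(p)
    quad <- rbind(3 + 2 * i + 0.5 * i^2, 1 - i + 2 * i^2)
    xq <- SpectrumSet(quad, seq(908, 1676, length.out = p),
                      sampleInfo(x)[, 1:5], analysisDay(x))
    d1 <- sgDerivative(xq, order = 1L)
    expect_equal(ncol(spectra(d1)), p - 4L)
    keep <- 3:(p - 2)
    expect_equal(unname(spectra(d1)),
                 rbind(2 + 1 * keep, -1 + 4 * keep), tolerance = 1e-10)
    d2 <- sgDerivative(xq, order = 2L)
    expect_equal(unname(spectra(d2)),
                 rbind(rep(1, p - 4), rep(4, p - 4)), tolerance = 1e-10)
    ## errors: too few points, non-uniform grid
    expect_error(sgDerivative(makePairedSet(p = 4L)), "at least 5")
    bad <- SpectrumSet(quad[, 1:6], c(908, 910, 930, 1000, 1200, 1676),
                       sampleInfo(x)[, 1:5], analysisDay(x))
    expect_error(sgDerivative(bad), "non-uniform")
})

test_that("SG derivative is linear in its input", {
    set.seed(21)
    base <- makePairedSet(nDays = 3L, nRep = 1L, p = 15L, seed = 21L)
    a <- spectra(base)
    b <- matrix(rnorm(length(a)), nrow(a))
    mk <- function(m) SpectrumSet(m, wavelengths(base),
                                  sampleInfo(base)[, 1:5],
                                  analysisDay(base))
    lhs <- spectra(sgDerivative(mk(2.5 * a - 1.5 * b), order = 2L))
    rhs <- 2.5 * spectra(sgDerivative(mk(a), order = 2L)) -
           1.5 * spectra(sgDerivative(mk(b), order = 2L))
    expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("SNV standardises every row and is idempotent", {
    x <- makePairedSet(nDays = 3L, nRep = 2L, p = 30L, seed = 2L)
    ## symmetric 3-point case, n-1 denominator
    x3 <- SpectrumSet(matrix(c(1, 2, 3), 1L, 3L),
                      c(1000, 1100, 1200),
                      data.frame(site = "E", fish = 1L, group = "C",
                                 term_hours = 3L, replicate = 1L),
                      day = 1L)
    expect_equal(unname(spectra(snv(x3))[1, ]), c(-1, 0, 1))
    s <- spectra(snv(x))
    expect_lt(max(abs(rowMeans(s))), 1e-12)
    expect_equal(unname(apply(s, 1, sd)), rep(1, nrow(s)),
                 tolerance = 1e-12)
    expect_equal(spectra(snv(snv(x))), s, tolerance = 1e-12)
    ## constant row -> error identifying the row
    bad <- SpectrumSet(matrix(5, 1L, 3L), c(1000, 1100, 1200),
                       data.frame(site = "E", fish = 1L, group = "C",
                                  term_hours = 3L, replicate = 1L),
                       day = 1L)
    expect_error(snv(bad), "zero row variance")
})

test_that("pair centering zeroes each day and ignores class identity", {
    x <- makePairedSet(nDays = 2L, nRep = 1L, p = 5L, seed = 4L)
    pc <- pairCenter(x)
    m <- spectra(pc)
    day <- analysisDay(pc)
    for (d in unique(day))
        expect_lt(max(abs(colSums(m[day == d, , drop = FALSE]))), 1e-10)
    ## two rows per day: outputs are +/- half the difference
    raw <- spectra(x)
    expect_equal(m[1, ], (raw[1, ] - raw[2, ]) / 2, ignore_attr = TRUE)
    expect_equal(m[2, ], -m[1, ])
    ## metadata untouched
    expect_equal(sampleInfo(pc), sampleInfo(x))
    ## additive per-day offset removed exactly
    shifted <- raw
    shifted[day == 1, ] <- sweep(shifted[day == 1, , drop = FALSE], 2,
                                 rnorm(5), `+`)
    xs <- SpectrumSet(shifted, wavelengths(x), sampleInfo(x)[, 1:5],
                      day)
    expect_equal(spectra(pairCenter(xs)), m, tolerance = 1e-10)
    ## unpaired day -> error listing the day
    solo <- filterSpectra(x, group = "C")
    expect_error(pairCenter(solo), "day 1")
})

test_that("autoscaling freezes training parameters and round-trips", {
    x <- makePairedSet(nDays = 4L, nRep = 2L, p = 7L, seed = 6L)
    mat <- spectra(x)
    params <- autoscaleFit(mat)
    z <- autoscaleApply(mat, params)
    expect_lt(max(abs(colMeans(z))), 1e-12)
    expect_equal(apply(z, 2, sd), rep(1, ncol(z)), ignore_attr = TRUE,
                 tolerance = 1e-12)
    ## held-out data uses the training parameters, not its own
    held <- mat[1:4, ] + 3
    zh <- autoscaleApply(held, params)
    expect_equal(zh, z[1:4, ] + 3 / rep(params$scale,
                                        each = 4), tolerance = 1e-12)
    ## serialization round-trip
    path <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(center = params$center, scale = params$scale),
              path, row.names = FALSE)
    back <- read.csv(path)
    expect_equal(back$center, unname(params$center), tolerance = 1e-12)
    expect_equal(back$scale, unname(params$scale), tolerance = 1e-12)
    ## constant training column -> error naming the variable
    mat2 <- mat; mat2[, 3] <- 1
    colnames(mat2) <- sprintf("%.6g", wavelengths(x))
    expect_error(autoscaleFit(mat2), "constant training column")
})
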