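test_that("the same seed reproduces the study bit for bit", {
    a <- simulateStudy(syntheticPreset("weak", seed = 17L))
    b <- simulateStudy(syntheticPreset("weak", seed = 17L))
    expect_identical(spectra(a$spectra), spectra(b$spectra))
    expect_identical(sampleInfo(a$spectra), sampleInfo(b$spectra))
    c <- simulateStudy(syntheticPreset("weak", seed = 18L))
    expect_false(identical(spectra(a$spectra), spectra(c$spectra)))
})

test_that("the default design matches the paired study layout", {
    sim <- simulateStudy(SyntheticStudyConfig(seed = 2L))
    x <- sim$spectra
    info <- sampleInfo(x)
    ## 4 matrices x 12 days x 2 fish x 3 replicates
    expect_equal(ncol(x), 4L * 12L * 2L * 3L)
    expect_equal(nrow(x), 125L)
    expect_equal(range(wavelengths(x)), c(908, 1676))
    ## per matrix and term: 36 rows across 6 days, one C + one T fish
    for (m in c("E", "G", "M", "S")) for (te in c(3L, 24L)) {
        sub <- info[info$site == m & info$term_hours == te, ]
        expect_equal(nrow(sub), 36L)
        expect_length(unique(sub$day), 6L)
        byDay <- split(sub, sub$day)
        for (d in byDay) {
            expect_setequal(as.character(unique(d$group)), c("C", "T"))
            expect_length(unique(d$fish), 2L)
            expect_equal(unname(table(d$replicate)), rep(2L, 3L),
                         ignore_attr = TRUE)
        }
    }
    ## labels are valid codes
    expect_silent(parseSampleLabel(sampleLabels(x)))
})

test_that("variance-component defaults keep biology above treatment", {
    cfg <- SyntheticStudyConfig()
    expect_gt(cfg@fishSd, max(abs(c(cfg@deltaBandsShort,
                                    cfg@deltaBandsLong))))
    ## short- and long-term deltas have opposite signs on at least half
    ## of the affected bands
    aff <- which(cfg@deltaBandsShort != 0 | cfg@deltaBandsLong != 0)
    opp <- sum(cfg@deltaBandsShort[aff] * cfg@deltaBandsLong[aff] < 0)
    expect_gte(opp, length(aff) / 2)
})

test_that("presets expose null, weak and strong regimes", {
    nul <- syntheticPreset("null")
    expect_true(all(nul@deltaBandsShort == 0) &&
                all(nul@deltaBandsLong == 0))
    expect_length(informativeWavelengths(nul, 3L), 0L)
    wk <- syntheticPreset("weak")
    expect_equal(max(abs(wk@deltaBandsShort)), wk@fishSd)
    st <- syntheticPreset("strong")
    expect_length(informativeWavelengths(st, 3L), 10L)
    expect_length(informativeWavelengths(st, 24L), 10L)
    ## sign flip on at least half of the informative wavelengths
    i <- informativeWavelengths(st, 3L)
    flip <- sum(st@deltaSpectrumShort[i] * st@deltaSpectrumLong[i] < 0)
    expect_gte(flip, 5L)
    expect_error(syntheticPreset("bogus"))
})

test_that("null class means coincide as the design grows", {
    cfg <- SyntheticStudyConfig(nDays = 200L, matrices = "M",
                                deltaBandsShort = rep(0, 4L),
                                deltaBandsLong = rep(0, 4L),
                                seed = 19L)
    sim <- simulateStudy(cfg)
    x <- filterSpectra(sim$spectra, term = 3L)
    mat <- spectra(x)
    g <- sampleInfo(x)$group
    d <- colMeans(mat[g == "C", ]) - colMeans(mat[g == "T", ])
    se <- sqrt(apply(mat[g == "C", ], 2, var) / sum(g == "C") +
               apply(mat[g == "T", ], 2, var) / sum(g == "T"))
    ## every wavelength within sampling error of zero difference;
    ## the bound is Bonferroni-adjusted for the p simultaneous z-scores
    expect_lt(max(abs(d / se)),
              qnorm(1 - 0.01 / (2 * length(d))))
    expect_lt(mean(abs(d / se)), 1.5)
})

test_that("SNV cancels the simulated scatter effects", {
    cfg <- syntheticPreset("weak", seed = 20L)
    noScatter <- cfg
    noScatter@scatterSd <- 0
    noScatter@offsetSd <- 0
    a <- snv(simulateStudy(cfg)$spectra)
    b <- snv(simulateStudy(noScatter)$spectra)
    ## same underlying draws (shared stream), scatter removed by SNV up
    ## to the replicate-noise rescaling
    expect_equal(spectra(a), spectra(b), tolerance = 0.05)
    expect_gt(max(abs(spectra(simulateStudy(cfg)$spectra) -
                      spectra(simulateStudy(noScatter)$spectra))), 0.05)
})

test_that("zero-delta wavelengths show no class difference after
           pair centering", {
    cfg <- syntheticPreset("strong", seed = 21L)
    sim <- simulateStudy(cfg)
    x <- pairCenter(filterSpectra(sim$spectra, site = "M", term = 3L))
    mat <- spectra(x)
    g <- sampleInfo(x)$group
    diffs <- colMeans(mat[g == "T", ]) - colMeans(mat[g == "C", ])
    inf <- sim$truth$informative$short
    ## informative wavelengths carry the delta; the rest are noise-level
    expect_gt(min(abs(diffs[inf])), 10 * median(abs(diffs[-inf])))
})

test_that("the weak preset separates detectably but imperfectly", {
    accs <- vapply(seq_len(20), function(s) {
        x <- presetSubset("weak", seed = 2000L + s)
        cvEvaluate(x, ncomp = 2, scheme = buildDayGroups(x),
                   pretreatment = "snv")$accuracy
    }, numeric(1))
    pooled <- mean(accs)
    ## strictly above the pooled chance band, strictly below perfect
    upper <- qbinom(0.995, 36L * 20L, 0.5) / (36 * 20) * 100
    expect_gt(pooled, upper)
    expect_lt(pooled, 100)
})

test_that("invalid configurations are rejected", {
    expect_error(SyntheticStudyConfig(matrices = character(0)),
                 "matrix")
    expect_error(SyntheticStudyConfig(nDays = 7L), "nDays")
    expect_error(SyntheticStudyConfig(noiseSd = -1), "variance")
    expect_error(SyntheticStudyConfig(deltaSpectrumShort = 1:3),
                 "deltaSpectrumShort")
})
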