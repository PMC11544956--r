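## Shared in-code fixtures for the test suite.

## A tiny paired-design SpectrumSet built by hand: `nDays` days, one
## control + one treated fish per day, `nRep` replicates, `p` wavelengths
## on the instrument grid. Intensities are seeded white noise plus an
## optional class effect added to the treated rows.
makePairedSet <- function(nDays = 2L, nRep = 1L, p = 6L, seed = 42L,
                          effect = 0, site = "E", term = 3L) {
    set.seed(seed)
    wl <- seq(908, 1676, length.out = p)
    info <- expand.grid(replicate = seq_len(nRep), group = c("C", "T"),
                        dayIdx = seq_len(nDays),
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    info$site <- site
    info$term_hours <- term
    info$fish <- 2L * (info$dayIdx - 1L) + ifelse(info$group == "C", 1L, 2L)
    n <- nrow(info)
    mat <- matrix(rnorm(n * p), n, p)
    mat[info$group == "T", ] <- mat[info$group == "T", ] + effect
    SpectrumSet(mat, wl,
                info[, c("site", "fish", "group", "term_hours",
                         "replicate")],
                day = info$dayIdx)
}

## Random valid label fields for round-trip property checks.
randomLabelInfo <- function(n, seed = 1L) {
    set.seed(seed)
    data.frame(
        site = sample(c("E", "G", "M", "S"), n, replace = TRUE),
        fish = sample(1:99, n, replace = TRUE),
        group = sample(c("C", "T"), n, replace = TRUE),
        term_hours = sample(c(3L, 24L), n, replace = TRUE),
        replicate = sample(1:9, n, replace = TRUE),
        stringsAsFactors = FALSE)
}

## Study-design subset used by most CV tests: one matrix, one term from a
## simulated preset (36 rows, 6 days).
presetSubset <- function(preset = "null", seed = 1L, site = "M",
                         term = 3L) {
    sim <- simulateStudy(syntheticPreset(preset, seed = seed))
    filterSpectra(sim$spectra, site = site, term = term)
}
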