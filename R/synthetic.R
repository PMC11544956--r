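.defaultBands <- function() {
    ## Gaussian absorbance bands; per-matrix base amplitudes follow the
    ## qualitative NIR picture for fish tissue: dominant water first
    ## overtone ~1400 nm, weak ~1000 nm water band, lipid C-H second
    ## overtone 1150-1200 nm (muscle > eye ~ gills > skin), and a
    ## ~1350 nm C-H combination shoulder.
    data.frame(
        name = c("water1000", "lipid1180", "shoulder1350", "water1400"),
        center = c(1000, 1180, 1350, 1400),
        sigma = c(30, 25, 30, 40),
        E = c(0.12, 0.08, 0.20, 1.00),
        G = c(0.12, 0.08, 0.20, 1.00),
        M = c(0.12, 0.15, 0.20, 1.00),
        S = c(0.12, 0.02, 0.20, 1.00),
        stringsAsFactors = FALSE)
}

#' Construct a synthetic study configuration
#'
#' Defaults emulate the paired study design this workflow targets: 12
#' analysis days (first six short-term 3 h, last six long-term 24 h), one
#' control and one treated fish per day, 3 replicate spectra per fish and
#' matrix, a 125-point grid over the 908--1676 nm instrument range, and
#' fish-level variability (`fishSd`) exceeding the treatment effect, so
#' classification genuinely needs the paired-day structure.
#'
#' @param nDays,nReplicates,matrices,wavelengths,bands,fishSd,noiseSd,scatterSd,offsetSd
#'   see [SyntheticStudyConfig-class].
#' @param deltaBandsShort,deltaBandsLong per-band treatment amplitude
#'   deltas (default: modest water-band increase / lipid decrease at the
#'   short term, partly sign-flipped at the long term).
#' @param deltaSpectrumShort,deltaSpectrumLong optional explicit
#'   per-wavelength additive treatment profiles.
#' @param seed integer seed of the generator's single random stream.
#' @return a [SyntheticStudyConfig-class].
#' @export
SyntheticStudyConfig <- function(nDays = 12L, nReplicates = 3L,
        matrices = c("E", "G", "M", "S"),
        wavelengths = seq(908, 1676, length.out = 125L),
        bands = .defaultBands(),
        fishSd = 0.04, noiseSd = 0.005, scatterSd = 0.05,
        offsetSd = 0.02,
        deltaBandsShort = c(0, -0.02, 0.01, 0.02),
        deltaBandsLong = c(0, 0.02, 0.01, -0.02),
        deltaSpectrumShort = numeric(0),
        deltaSpectrumLong = numeric(0),
        seed = 1L) {
    new("SyntheticStudyConfig",
        nDays = as.integer(nDays), nReplicates = as.integer(nReplicates),
        matrices = matrices, wavelengths = wavelengths, bands = bands,
        fishSd = fishSd, noiseSd = noiseSd, scatterSd = scatterSd,
        offsetSd = offsetSd,
        deltaBandsShort = deltaBandsShort,
        deltaBandsLong = deltaBandsLong,
        deltaSpectrumShort = deltaSpectrumShort,
        deltaSpectrumLong = deltaSpectrumLong,
        seed = as.integer(seed))
}

#' Named synthetic study presets
#'
#' * `"null"` — no treatment effect at all (every delta zero); the
#'   negative control for calibrating the cross-validation error rate.
#' * `"weak"` — band-amplitude deltas of the same magnitude as the
#'   fish-effect sd, the regime the real study operates in: detectable
#'   through paired-day centering but far from trivially separable.
#' * `"strong"` — a 100-point grid with 10 informative wavelengths
#'   carrying large (0.5 absorbance) narrow additive deltas, sign-flipped
#'   for the long term on 6 of 10; ground truth for variable-selection
#'   recovery, calibrated once so the full BE pipeline reaches perfect
#'   cross-validated classification at the shipped seed.
#'
#' @param name one of `"null"`, `"weak"`, `"strong"`.
#' @param seed seed stored in the returned config.
#' @return a [SyntheticStudyConfig-class].
#' @export
syntheticPreset <- function(name = c("null", "weak", "strong"),
                            seed = 1L) {
    name <- match.arg(name)
    switch(name,
        null = SyntheticStudyConfig(
            deltaBandsShort = rep(0, 4L), deltaBandsLong = rep(0, 4L),
            seed = seed),
        weak = SyntheticStudyConfig(
            deltaBandsShort = c(0, -0.04, 0.04, 0.04),
            deltaBandsLong = c(0, 0.04, 0.04, -0.04),
            seed = seed),
        strong = {
            p <- 100L
            wl <- seq(908, 1676, length.out = p)
            idx <- seq(10L, 100L, by = 10L)
            dS <- numeric(p); dS[idx] <- 0.5
            dL <- numeric(p)
            dL[idx] <- rep(c(-0.5, 0.5), c(6L, 4L))
            SyntheticStudyConfig(
                wavelengths = wl,
                deltaBandsShort = rep(0, 4L),
                deltaBandsLong = rep(0, 4L),
                deltaSpectrumShort = dS, deltaSpectrumLong = dL,
                seed = seed)
        })
}

## Treatment difference profile (treated minus control mean) for a term,
## in absorbance units on the config grid.
.deltaProfile <- function(config, term, matrix = NULL) {
    wl <- config@wavelengths
    bands <- config@bands
    d <- if (term == 3L) config@deltaBandsShort else config@deltaBandsLong
    prof <- numeric(length(wl))
    for (b in seq_len(nrow(bands)))
        prof <- prof + d[b] *
            exp(-0.5 * ((wl - bands$center[b]) / bands$sigma[b])^2)
    extra <- if (term == 3L) config@deltaSpectrumShort
             else config@deltaSpectrumLong
    if (length(extra)) prof <- prof + extra
    prof
}

#' Ground-truth informative wavelengths of a configuration
#'
#' Wavelength indices whose treatment difference profile exceeds 1% of
#' its maximal absolute value (empty under the null).
#'
#' @param config a [SyntheticStudyConfig-class].
#' @param term 3 or 24.
#' @return integer vector of indices into `config@wavelengths`.
#' @export
informativeWavelengths <- function(config, term) {
    prof <- .deltaProfile(config, as.integer(term))
    m <- max(abs(prof))
    if (m == 0) return(integer(0))
    which(abs(prof) > 0.01 * m)
}

#' Simulate a paired-design NIR study
#'
#' Generates spectra day by day from a single seeded random stream: for
#' each analysis day one control and one treated fish are drawn; each
#' fish receives per-band amplitude perturbations (sd `fishSd`) shared by
#' all its replicates; each replicate spectrum is the band sum times a
#' multiplicative scatter factor, plus an additive offset and white
#' noise. Treated fish additionally receive the term-specific treatment
#' deltas. Fish effects are drawn before replicate noise, so the
#' replicate structure is exactly nested. Random draws are made
#' unconditionally (then scaled by the respective sd), so two
#' configurations differing only in variance components share the same
#' underlying draws at the same seed.
#'
#' @param config a [SyntheticStudyConfig-class].
#' @return list with `spectra` (a [SpectrumSet-class] over all requested
#'   matrices and both terms) and `truth` (informative wavelength indices
#'   and difference profiles per term, per-fish band effects, and the
#'   config).
#' @export
simulateStudy <- function(config) {
    validObject(config)
    set.seed(config@seed)
    wl <- config@wavelengths
    p <- length(wl)
    bands <- config@bands
    nb <- nrow(bands)
    shapes <- vapply(seq_len(nb), function(b)
        exp(-0.5 * ((wl - bands$center[b]) / bands$sigma[b])^2),
        numeric(p))                          # p x nb
    terms <- rep(c(3L, 24L), each = config@nDays %/% 2L)
    rows <- list(); labs <- list(); dayv <- integer(0)
    fishEffects <- list()
    for (m in config@matrices) {
        baseAmp <- bands[[m]]
        for (d in seq_len(config@nDays)) {
            term <- terms[d]
            delta <- .deltaProfile(config, term)
            for (g in c("C", "T")) {
                fish <- 2L * (d - 1L) + ifelse(g == "C", 1L, 2L)
                eff <- rnorm(nb) * config@fishSd
                fishEffects[[paste(m, fish, sep = ".")]] <- eff
                mean_ <- drop(shapes %*% (baseAmp + eff)) +
                    if (g == "T") delta else 0
                for (r in seq_len(config@nReplicates)) {
                    mult <- 1 + rnorm(1L) * config@scatterSd
                    off <- rnorm(1L) * config@offsetSd
                    noise <- rnorm(p) * config@noiseSd
                    rows[[length(rows) + 1L]] <- mean_ * mult + off + noise
                    labs[[length(labs) + 1L]] <- data.frame(
                        site = m, fish = fish, group = g,
                        term_hours = term, replicate = r,
                        stringsAsFactors = FALSE)
                    dayv <- c(dayv, d)
                }
            }
        }
    }
    info <- do.call(rbind, labs)
    info$site <- factor(info$site, levels = c("E", "G", "M", "S"))
    info$group <- factor(info$group, levels = c("C", "T"))
    x <- SpectrumSet(do.call(rbind, rows), wl, info, dayv)
    list(spectra = x,
         truth = list(
             informative = list(
                 short = informativeWavelengths(config, 3L),
                 long = informativeWavelengths(config, 24L)),
             delta = list(short = .deltaProfile(config, 3L),
                          long = .deltaProfile(config, 24L)),
             fishEffects = fishEffects,
             config = config))
}

setMethod("show", "SyntheticStudyConfig", function(object) {
    cat("SyntheticStudyConfig:", object@nDays, "days x 2 fish x",
        object@nReplicates, "replicates |",
        length(object@wavelengths), "wavelengths |",
        "matrices:", paste(object@matrices, collapse = ""), "\n")
    cat(sprintf(
        "  fishSd %.3g, noiseSd %.3g, scatterSd %.3g, offsetSd %.3g, seed %d\n",
        object@fishSd, object@noiseSd, object@scatterSd,
        object@offsetSd, object@seed))
    invisible(object)
})
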