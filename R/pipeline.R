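#' Run the full BE-PLS-DA analysis
#'
#' For every combination of sample matrix, exposure term and pretreatment:
#' filters the spectra, builds paired-day cancellation groups, runs
#' VIP-driven backward elimination around cross-validated PLS-DA
#' ([bePLSDA()]), and collects one report record with the selected
#' variable count, number of latent variables, and calibration /
#' cross-validation accuracy and non-error rate. The best model per
#' (matrix, term) — maximal CV accuracy, ties to higher calibration
#' accuracy then fewer variables — is kept for latent-variable score and
#' coefficient exports. The run is fully deterministic given the input
#' (or the synthetic seed).
#'
#' @param spectra a [SpectrumSet-class], or `NULL` to simulate.
#' @param preset synthetic preset name (see [syntheticPreset()]) used
#'   when `spectra` is `NULL`.
#' @param seed seed for the synthetic study (preset runs only).
#' @param matrices sample matrices to analyse (default: all present).
#' @param terms exposure terms to analyse (subset of 3, 24).
#' @param pretreatments pretreatments to compare; each is one
#'   [preprocessSpectra()] step or a chained character vector inside a
#'   list.
#' @param aMax,fraction,pMin,pairCentering passed to [bePLSDA()].
#' @param outDir if non-`NULL`, write `report.csv`, per-(matrix, term)
#'   score / coefficient / CV-prediction CSVs and per-run BE traces there.
#' @param verbose logical; one line per BE cycle.
#' @return list with `report` (data.frame, one row per matrix x term x
#'   pretreatment), `results` (named list of [BEResult-class]), `best`
#'   (named list, best result per matrix x term) and `spectra`.
#' @export
runAnalysis <- function(spectra = NULL, preset = NULL, seed = 1L,
                        matrices = NULL, terms = c(3L, 24L),
                        pretreatments = list("snv", "der1", "der2"),
                        aMax = 5L, fraction = 0.06, pMin = aMax + 1L,
                        pairCentering = TRUE, outDir = NULL,
                        verbose = FALSE) {
    if (is.null(spectra)) {
        if (is.null(preset))
            stop("supply either spectra or a synthetic preset name")
        config <- syntheticPreset(preset, seed = seed)
        spectra <- simulateStudy(config)$spectra
    }
    if (!is.list(pretreatments)) pretreatments <- as.list(pretreatments)
    info <- sampleInfo(spectra)
    if (is.null(matrices))
        matrices <- as.character(sort(unique(info$site)))
    terms <- as.integer(terms)
    termName <- c(`3` = "Short-term", `24` = "Long-term")
    report <- list(); results <- list(); best <- list()
    for (m in matrices) {
        for (te in terms) {
            sub <- filterSpectra(spectra, site = m, term = te)
            for (pre in pretreatments) {
                key <- paste(m, te, paste(pre, collapse = "+"),
                             sep = ".")
                res <- bePLSDA(sub, pretreatment = pre, aMax = aMax,
                               fraction = fraction, pMin = pMin,
                               pairCentering = pairCentering,
                               verbose = verbose)
                results[[key]] <- res
                rec <- cbind(
                    data.frame(SampleMatrix = m,
                               Effect = termName[as.character(te)],
                               stringsAsFactors = FALSE),
                    beSummary(res))
                report[[key]] <- rec
                bkey <- paste(m, te, sep = ".")
                if (is.null(best[[bkey]]) ||
                    .betterResult(res, best[[bkey]]))
                    best[[bkey]] <- res
            }
        }
    }
    report <- do.call(rbind, report)
    rownames(report) <- NULL
    out <- list(report = report, results = results, best = best,
                spectra = spectra)
    if (!is.null(outDir)) .writeArtifacts(out, outDir)
    invisible(out)
}

.betterResult <- function(a, b) {
    sa <- beSummary(a); sb <- beSummary(b)
    if (sa$AccCV != sb$AccCV) return(sa$AccCV > sb$AccCV)
    if (sa$AccCal != sb$AccCal) return(sa$AccCal > sb$AccCal)
    sa$NVariables < sb$NVariables
}

.writeArtifacts <- function(out, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeReport(out$report, file.path(outDir, "report.csv"))
    for (bkey in names(out$best)) {
        res <- out$best[[bkey]]
        model <- finalModel(res)
        sc <- data.frame(label = res@cvPredictions$label,
                         day = res@cvPredictions$day,
                         class = res@cvPredictions$truth,
                         model@scores, check.names = FALSE)
        colnames(sc) <- c("label", "day", "class",
                          paste0("LV", seq_len(model@ncomp)))
        utils::write.csv(sc,
            file.path(outDir, paste0("scores_", bkey, ".csv")),
            row.names = FALSE)
        cf <- data.frame(wavelength_nm = selectedWavelengths(res),
                         coefficient = unname(coef(model)))
        utils::write.csv(cf,
            file.path(outDir, paste0("coefficients_", bkey, ".csv")),
            row.names = FALSE)
        utils::write.csv(res@cvPredictions,
            file.path(outDir, paste0("cv_predictions_", bkey, ".csv")),
            row.names = FALSE)
    }
    for (key in names(out$results))
        utils::write.csv(beTrace(out$results[[key]]),
            file.path(outDir, paste0("be_trace_", key, ".csv")),
            row.names = FALSE)
    invisible(outDir)
}

#' Compare coefficient signs between exposure terms
#'
#' Restricted to the wavelengths selected by both models, reports the
#' fraction with opposite coefficient signs — the workflow's summary of
#' whether the short-term effect (fresh vs treated) acts on the spectrum
#' in part opposite to the long-term effect (iced vs treated).
#'
#' @param short,long fitted [PLSDAModel-class] or [BEResult-class] objects
#'   for the short- and long-term models of one sample matrix.
#' @return list with `fraction` (opposite-sign fraction in `[0, 1]`,
#'   `NA` on empty intersection), `n` (shared wavelengths) and `table`
#'   (per-wavelength coefficients and sign relation).
#' @export
compareTerms <- function(short, long) {
    getWl <- function(x)
        if (is(x, "BEResult")) selectedWavelengths(x)
        else as.numeric(x@variables)
    getB <- function(x)
        if (is(x, "BEResult")) coef(finalModel(x)) else coef(x)
    wlS <- getWl(short); wlL <- getWl(long)
    bS <- getB(short); bL <- getB(long)
    shared <- intersect(wlS, wlL)
    if (!length(shared)) {
        warning("no shared wavelengths between the two models")
        return(list(fraction = NA_real_, n = 0L,
                    table = data.frame()))
    }
    cS <- bS[match(shared, wlS)]
    cL <- bL[match(shared, wlL)]
    opp <- sign(cS) * sign(cL) < 0
    tab <- data.frame(wavelength_nm = shared, coef_short = unname(cS),
                      coef_long = unname(cL), opposite = opp)
    list(fraction = mean(opp), n = length(shared), table = tab)
}
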