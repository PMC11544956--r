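#' Read a wide spectra table from CSV
#'
#' Expects a comma-separated UTF-8 table with one row per measurement,
#' numeric wavelength column headers in nm, one column of 9-character
#' sample codes and (optionally) an integer analysis-day column. If the
#' day column is absent a `fishDay` map (fish number -> day) must be
#' supplied, because the label code does not encode the analysis day and
#' the paired-day cross-validation scheme needs it.
#'
#' @param path file to read.
#' @param labelColumn name of the sample-code column (default `"label"`).
#' @param dayColumn name of the analysis-day column, or `NULL` if absent.
#' @param fishDay optional named vector mapping fish number (as names) to
#'   day, used when `dayColumn` is `NULL`.
#' @return a [SpectrumSet-class], wavelength columns sorted ascending.
#' @seealso [writeSpectraTable()]
#' @export
readSpectraTable <- function(path, labelColumn = "label",
                             dayColumn = "day", fishDay = NULL) {
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (!labelColumn %in% names(tab))
        stop("label column '", labelColumn, "' not found in ", path)
    labels <- as.character(tab[[labelColumn]])
    hasDay <- !is.null(dayColumn) && dayColumn %in% names(tab)
    wlCols <- setdiff(names(tab), c(labelColumn,
                                    if (hasDay) dayColumn))
    wl <- suppressWarnings(as.numeric(wlCols))
    if (anyNA(wl))
        stop("non-numeric wavelength header(s): ",
             paste(utils::head(wlCols[is.na(wl)], 3L), collapse = ", "))
    if (anyDuplicated(wl))
        stop("duplicate wavelength header: ", wl[anyDuplicated(wl)])
    mat <- as.matrix(tab[, wlCols, drop = FALSE])
    if (!is.numeric(mat) || anyNA(mat)) {
        bad <- which(is.na(suppressWarnings(
            matrix(as.numeric(mat), nrow(mat)))), arr.ind = TRUE)[1L, ]
        stop("non-numeric intensity at row ", bad[1L],
             ", wavelength column '", wlCols[bad[2L]], "'")
    }
    if (hasDay) {
        day <- as.integer(tab[[dayColumn]])
    } else {
        if (is.null(fishDay))
            stop("no day column '", dayColumn,
                 "' and no fishDay map supplied")
        info <- parseSampleLabel(labels)
        day <- as.integer(fishDay[as.character(info$fish)])
        if (anyNA(day))
            stop("fishDay map missing day for fish ",
                 info$fish[which(is.na(day))[1L]])
    }
    SpectrumSet(mat, wl, labels, day)
}

#' Write a SpectrumSet as a wide CSV table
#'
#' Inverse of [readSpectraTable()]: one row per measurement, wavelength
#' headers in nm, a `label` column of 9-character codes and a `day` column.
#'
#' @param x a [SpectrumSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpectraTable <- function(x, path) {
    mat <- spectra(x)
    tab <- data.frame(label = sampleLabels(x), day = analysisDay(x),
                      mat, check.names = FALSE)
    colnames(tab) <- c("label", "day", sprintf("%.6g", wavelengths(x)))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write the classification report table
#'
#' One row per (sample matrix, exposure term, pretreatment) with the
#' selected variable count, number of latent variables, and calibration /
#' cross-validation accuracy and non-error rate, mirroring the layout in
#' which such studies tabulate BE-PLS-DA results. Percentages are
#' formatted to two decimals (one misclassification out of 36 prints as
#' 97.22).
#'
#' @param results data.frame with columns `SampleMatrix`, `Effect`,
#'   `PreTreatment`, `NVariables`, `NLV`, `AccCal`, `AccCV`, `NERCal`,
#'   `NERCV` (as produced by [runAnalysis()]), possibly empty.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
writeReport <- function(results, path) {
    headers <- c("SampleMatrix", "Effect", "Pre-Treatment", "N Variables",
                 "N LV", "Acc% cal", "Acc% cv", "NER% cal", "NER% cv")
    if (NROW(results) == 0L) {
        writeLines(paste(headers, collapse = ","), path)
        return(invisible(path))
    }
    need <- c("SampleMatrix", "Effect", "PreTreatment", "NVariables",
              "NLV", "AccCal", "AccCV", "NERCal", "NERCV")
    miss <- setdiff(need, names(results))
    if (length(miss))
        stop("report records missing column(s): ",
             paste(miss, collapse = ", "))
    out <- data.frame(
        results$SampleMatrix, results$Effect, results$PreTreatment,
        results$NVariables, results$NLV,
        sprintf("%.2f", results$AccCal), sprintf("%.2f", results$AccCV),
        sprintf("%.2f", results$NERCal), sprintf("%.2f", results$NERCV),
        check.names = FALSE, stringsAsFactors = FALSE)
    colnames(out) <- headers
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
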