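#' Construct a SpectrumSet
#'
#' @param intensities numeric matrix, one row per measurement, one column
#'   per wavelength (the usual wide orientation of chemometric tables).
#'   Stored internally transposed, wavelengths-by-measurements.
#' @param wavelengths numeric vector of wavelengths in nm, one per column
#'   of `intensities`; need not be sorted (columns are reordered).
#' @param labels character vector of 9-character sample codes (see
#'   [parseSampleLabel()]) or a data.frame of parsed fields.
#' @param day integer vector assigning each measurement to its analysis
#'   day; required by the paired-day cross-validation scheme because the
#'   label code itself does not encode the day.
#' @return A [SpectrumSet-class] object.
#' @examples
#' wl <- seq(908, 1676, length.out = 10)
#' x <- SpectrumSet(matrix(rnorm(20), 2, 10), wl,
#'                  c("EF01C03_1", "EF02T03_1"), day = c(1L, 1L))
#' wavelengths(x)
#' @rdname SpectrumSet
#' @export
SpectrumSet <- function(intensities, wavelengths, labels, day) {
    intensities <- as.matrix(intensities)
    if (length(wavelengths) != ncol(intensities))
        stop("length(wavelengths) must equal ncol(intensities)")
    if (anyDuplicated(wavelengths))
        stop("duplicate wavelength: ",
             wavelengths[anyDuplicated(wavelengths)])
    n <- nrow(intensities)
    if (is.data.frame(labels)) info <- labels
    else info <- parseSampleLabel(labels)
    if (nrow(info) != n)
        stop("number of labels (", nrow(info),
             ") must equal number of measurement rows (", n, ")")
    day <- as.integer(day)
    if (length(day) != n)
        stop("length(day) (", length(day),
             ") must equal number of measurement rows (", n, ")")
    ord <- order(wavelengths)
    wavelengths <- wavelengths[ord]
    intensities <- intensities[, ord, drop = FALSE]
    codes <- .labelCodes(info)
    cd <- S4Vectors::DataFrame(info, day = day, row.names = make.unique(codes))
    a <- t(intensities)
    dimnames(a) <- list(
        sprintf("%.6g", wavelengths), rownames(cd))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = a),
        rowData = S4Vectors::DataFrame(wavelength_nm = wavelengths),
        colData = cd)
    new("SpectrumSet", se)
}

#' @rdname SpectrumSet
#' @export
setMethod("wavelengths", "SpectrumSet", function(x)
    SummarizedExperiment::rowData(x)$wavelength_nm)

#' @rdname SpectrumSet
#' @export
setMethod("spectra", "SpectrumSet", function(x)
    t(SummarizedExperiment::assay(x, "intensity")))

#' @rdname SpectrumSet
#' @export
setMethod("sampleLabels", "SpectrumSet", function(x)
    .labelCodes(sampleInfo(x)))

## 9-character display codes; the two-digit fish field recycles past 99
## (large simulated designs), true fish ids stay in colData.
.labelCodes <- function(info) {
    info$fish <- (as.integer(info$fish) - 1L) %% 99L + 1L
    formatSampleLabel(info)
}

#' @rdname SpectrumSet
#' @export
setMethod("sampleInfo", "SpectrumSet", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname SpectrumSet
#' @export
setMethod("analysisDay", "SpectrumSet", function(x)
    SummarizedExperiment::colData(x)$day)

#' @describeIn SpectrumSet number of measurements (columns of the
#'   internal assay).
#' @export
nSpectra <- function(x) ncol(x)

setMethod("show", "SpectrumSet", function(object) {
    wl <- wavelengths(object)
    cd <- SummarizedExperiment::colData(object)
    cat("SpectrumSet:", ncol(object), "spectra x", nrow(object),
        "wavelengths\n")
    if (length(wl))
        cat(sprintf("  grid: %.1f-%.1f nm\n", min(wl), max(wl)))
    cat("  sites:", paste(levels(droplevels(factor(cd$site))),
                          collapse = ", "),
        "| terms:", paste(sort(unique(cd$term_hours)), collapse = ", "),
        "h | days:", length(unique(cd$day)), "\n")
    invisible(object)
})

#' Subset a SpectrumSet by sample matrix and exposure term
#'
#' Convenience filter used when analysing each sample matrix and term
#' separately, as the classification workflow requires.
#'
#' @param x a [SpectrumSet-class].
#' @param site optional site code(s) to keep (E, G, M, S).
#' @param term optional exposure term(s) in hours to keep (3, 24).
#' @param group optional group code(s) to keep (C, T).
#' @return the filtered `SpectrumSet`.
#' @export
filterSpectra <- function(x, site = NULL, term = NULL, group = NULL) {
    cd <- SummarizedExperiment::colData(x)
    keep <- rep(TRUE, ncol(x))
    if (!is.null(site)) keep <- keep & cd$site %in% site
    if (!is.null(term)) keep <- keep & cd$term_hours %in% term
    if (!is.null(group)) keep <- keep & cd$group %in% group
    if (!any(keep))
        stop("no measurements left after filtering")
    x[, keep]
}

## Rebuild a SpectrumSet around a new measurements-by-wavelengths matrix,
## keeping column metadata. Used by the pretreatment operators.
.replaceSpectra <- function(x, mat, wavelengths = NULL) {
    if (is.null(wavelengths)) wavelengths <- wavelengths(x)
    SpectrumSet(mat, wavelengths,
                labels = sampleInfo(x)[, c("site", "fish", "group",
                                           "term_hours", "replicate")],
                day = analysisDay(x))
}
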