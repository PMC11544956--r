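#' VIP-driven backward elimination around cross-validated PLS-DA
#'
#' Iterative variable selection: at each cycle every latent-variable count
#' A in `1..aMax` is scored by grouped cross-validation ([cvEvaluate()]),
#' the best A is kept (ties to the smaller A), the variables are ranked by
#' the cross-validated mean VIP of the fold models at that A, and the
#' `max(1, floor(fraction * p))` smallest-VIP variables are eliminated
#' (at most 6% of the current variables per cycle by default). The loop
#' runs down to `pMin` variables; afterwards the cycle attaining the
#' maximal CV accuracy is selected (ties: fewer variables, then fewer
#' LVs, then the earlier cycle) and its model refitted on all rows. The
#' procedure is fully deterministic given data, scheme and parameters;
#' equal-VIP ties during removal are broken by ascending VIP then
#' ascending variable index.
#'
#' @param x a [SpectrumSet-class], rows filtered to one sample matrix and
#'   one exposure term.
#' @param scheme a [CVScheme-class]; built from `x` if `NULL`.
#' @param pretreatment pretreatment step(s) (see [preprocessSpectra()])
#'   applied once before the elimination loop.
#' @param aMax maximal number of latent variables tried per cycle.
#' @param fraction maximal fraction of current variables removed per
#'   cycle (default 0.06).
#' @param pMin smallest variable count evaluated (default `aMax + 1`).
#' @param pairCentering logical, see [preprocessSpectra()].
#' @param reoptimizeA logical; re-select A every cycle (default) or keep
#'   the first cycle's A for the whole trace.
#' @param verbose logical; print one line per cycle.
#' @return a [BEResult-class].
#' @export
bePLSDA <- function(x, scheme = NULL, pretreatment = "snv", aMax = 5L,
                    fraction = 0.06, pMin = aMax + 1L,
                    pairCentering = TRUE, reoptimizeA = TRUE,
                    verbose = FALSE) {
    aMax <- as.integer(aMax)
    if (aMax < 1L) stop("aMax must be >= 1")
    if (fraction <= 0 || fraction >= 1)
        stop("fraction must be in (0, 1)")
    pMin <- as.integer(pMin)
    if (pMin < aMax + 1L)
        stop("pMin must be at least aMax + 1")
    xp <- preprocessSpectra(x, pretreatment, pairCentering)
    if (is.null(scheme)) scheme <- buildDayGroups(xp)
    wl <- wavelengths(xp)
    p0 <- length(wl)
    if (pMin >= p0)
        stop("pMin (", pMin, ") must be smaller than the initial ",
             "variable count (", p0, ")")
    mat <- spectra(xp)
    colnames(mat) <- sprintf("%.6g", wl)
    info <- sampleInfo(xp)
    labels <- sampleLabels(xp)
    y <- as.character(info$group)
    groups <- cvGroups(scheme)
    retained <- seq_len(p0)
    trace <- list(); details <- list(); cycle <- 0L
    fixedA <- NA_integer_
    while (length(retained) >= pMin) {
        cycle <- cycle + 1L
        cvByA <- .cvGrid(mat[, retained, drop = FALSE], y, labels,
                         info$day, groups, aMax)
        aGrid <- if (reoptimizeA || is.na(fixedA)) seq_len(aMax)
                 else fixedA
        accByA <- vapply(cvByA[aGrid], `[[`, numeric(1L), "accuracy")
        best <- which.max(accByA)          # ties -> smaller A
        bestA <- aGrid[best]
        if (is.na(fixedA)) fixedA <- bestA
        cvBest <- cvByA[[bestA]]
        calFit <- fitPLSDA(mat[, retained, drop = FALSE], y,
                           ncomp = bestA, classes = c("C", "T"))
        calPred <- ifelse(calFit@fitted >= calFit@threshold, "T", "C")
        calMet <- classificationMetrics(y, calPred)
        k <- max(1L, floor(fraction * length(retained)))
        ## rank by cross-validated mean VIP; stable ascending-VIP,
        ## ascending-index order for determinism
        ord <- order(cvBest$vip, seq_along(retained))
        drop_ <- ord[seq_len(min(k, length(retained) - 1L))]
        trace[[cycle]] <- data.frame(
            cycle = cycle, p = length(retained), ncomp = bestA,
            acc_cal = calMet$accuracy, ner_cal = calMet$ner,
            acc_cv = cvBest$accuracy, ner_cv = cvBest$ner,
            n_removed = length(drop_))
        details[[cycle]] <- list(
            retained = retained, wavelengths = wl[retained],
            accByA = setNames(accByA, paste0("A", aGrid)),
            vip = cvBest$vip, removed = wl[retained[drop_]],
            predictions = cvBest$predictions)
        if (verbose)
            message(sprintf(
                "cycle %d: p=%d A=%d Acc%%cv=%.2f", cycle,
                length(retained), bestA, cvBest$accuracy))
        retained <- retained[-drop_]
    }
    trace <- do.call(rbind, trace)
    ## best cycle: max CV accuracy; ties -> fewer variables, fewer LVs,
    ## earlier cycle
    ordSel <- order(-trace$acc_cv, trace$p, trace$ncomp, trace$cycle)
    sel <- ordSel[1L]
    selIdx <- details[[sel]]$retained
    model <- fitPLSDA(mat[, selIdx, drop = FALSE], y,
                      ncomp = trace$ncomp[sel], classes = c("C", "T"))
    new("BEResult",
        trace = trace, details = details, selected = as.integer(sel),
        wavelengths = wl[selIdx], finalModel = model,
        cvPredictions = details[[sel]]$predictions,
        pretreatment = paste(pretreatment, collapse = "+"))
}

#' @rdname BEResult
#' @param object a `BEResult`.
#' @export
setMethod("beTrace", "BEResult", function(object) object@trace)

#' @rdname BEResult
#' @export
setMethod("selectedWavelengths", "BEResult",
    function(object) object@wavelengths)

#' @rdname BEResult
#' @export
setMethod("finalModel", "BEResult", function(object) object@finalModel)

#' @describeIn BEResult selected-cycle summary: variable count, LV count
#'   and calibration/CV accuracy and NER, as one data.frame row.
#' @param result a `BEResult`.
#' @export
beSummary <- function(result) {
    tr <- result@trace[result@selected, , drop = FALSE]
    data.frame(PreTreatment = result@pretreatment,
               NVariables = tr$p, NLV = tr$ncomp,
               AccCal = tr$acc_cal, AccCV = tr$acc_cv,
               NERCal = tr$ner_cal, NERCV = tr$ner_cv,
               row.names = NULL)
}

setMethod("show", "BEResult", function(object) {
    tr <- object@trace[object@selected, ]
    cat("BEResult (", object@pretreatment, "): ",
        nrow(object@trace), " cycle(s); selected cycle ",
        object@selected, "\n", sep = "")
    cat(sprintf(
        "  %d variables, %d LV | Acc%%cal %.2f, Acc%%cv %.2f, NER%%cv %.2f\n",
        tr$p, tr$ncomp, tr$acc_cal, tr$acc_cv, tr$ner_cv))
    invisible(object)
})
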