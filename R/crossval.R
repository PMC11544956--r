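#' Build paired-day cancellation groups
#'
#' Partitions the measurements of one sample matrix and one exposure term
#' into leave-more-out cancellation groups, one per analysis day: every
#' replicate of every fish analysed that day is held out together. Checks
#' the paired design: a fish's replicates must not span days, and every
#' day must contain both a control and a treated fish.
#'
#' @param x a [SpectrumSet-class] already filtered to one sample matrix
#'   and one exposure term (see [filterSpectra()]).
#' @param term optional term (3 or 24) asserted to be the only one present.
#' @return a [CVScheme-class].
#' @export
buildDayGroups <- function(x, term = NULL) {
    info <- sampleInfo(x)
    if (length(unique(info$site)) > 1L)
        stop("measurements span several sample matrices (",
             paste(unique(info$site), collapse = ", "),
             "); filter to one before building groups")
    if (length(unique(info$term_hours)) > 1L)
        stop("measurements span both exposure terms; filter to one")
    if (!is.null(term) && !all(info$term_hours == term))
        stop("measurements are not all at term ", term, " h")
    byFish <- split(info$day, info$fish)
    multi <- names(byFish)[vapply(byFish, function(d)
        length(unique(d)) > 1L, logical(1L))]
    if (length(multi))
        stop("replicates of fish ", multi[1L], " span several days")
    days <- sort(unique(info$day))
    groups <- lapply(days, function(d) which(info$day == d))
    names(groups) <- paste0("day", days)
    for (i in seq_along(days)) {
        g <- unique(info$group[groups[[i]]])
        if (length(g) < 2L)
            stop("day ", days[i], " lacks one class (only '",
                 as.character(g), "' present)")
    }
    info2 <- data.frame(
        day = days,
        fish = vapply(groups, function(i)
            paste(sort(unique(info$fish[i])), collapse = "+"),
            character(1L)),
        n = lengths(groups))
    new("CVScheme", groups = groups, info = info2)
}

#' @rdname CVScheme
#' @param x a `CVScheme`.
#' @export
setMethod("cvGroups", "CVScheme", function(x) x@groups)

setMethod("show", "CVScheme", function(object) {
    cat("CVScheme:", length(object@groups), "cancellation group(s),",
        sum(lengths(object@groups)), "measurements\n")
    print(object@info, row.names = FALSE)
    invisible(object)
})

#' Grouped cross-validation of a PLS-DA model
#'
#' For every cancellation group: autoscaling parameters and the PLS-DA
#' model are fitted on the remaining groups only, the held-out group is
#' pretreated with the frozen training parameters and predicted; the
#' pooled predictions (each measurement predicted exactly once) give the
#' cross-validated accuracy and non-error rate. VIP scores are averaged
#' over the fold models. Row-local pretreatments (SNV, derivatives) and
#' paired-day centering are applied before splitting via
#' [preprocessSpectra()]; both use only within-row / within-day structure,
#' so no information crosses folds.
#'
#' @param x a [SpectrumSet-class].
#' @param ncomp number of latent variables.
#' @param scheme a [CVScheme-class] from [buildDayGroups()].
#' @param pretreatment pretreatment step(s) passed to
#'   [preprocessSpectra()], or `NULL` if `x` is already pretreated.
#' @param pairCentering logical, see [preprocessSpectra()].
#' @return list with `accuracy`, `ner` (percent), `vip` (mean over fold
#'   models), `predictions` (data.frame: index, label, day, truth,
#'   response, predicted) and `folds` (per-fold indices and frozen
#'   autoscaling parameters).
#' @export
cvEvaluate <- function(x, ncomp, scheme, pretreatment = NULL,
                       pairCentering = TRUE) {
    if (!is.null(pretreatment))
        x <- preprocessSpectra(x, pretreatment, pairCentering)
    mat <- spectra(x)
    colnames(mat) <- sprintf("%.6g", wavelengths(x))
    info <- sampleInfo(x)
    y <- as.character(info$group)
    groups <- cvGroups(scheme)
    idx <- sort(unlist(groups, use.names = FALSE))
    if (!identical(idx, seq_len(nrow(mat))))
        stop("scheme does not partition the ", nrow(mat), " measurements")
    n <- nrow(mat)
    response <- numeric(n); predicted <- character(n)
    vip <- 0; folds <- vector("list", length(groups))
    for (k in seq_along(groups)) {
        hold <- groups[[k]]
        train <- setdiff(seq_len(n), hold)
        if (length(train) == 0L) train <- hold  # degenerate single group
        ytr <- y[train]
        if (length(unique(ytr)) < 2L)
            stop("training fold for group ", names(groups)[k],
                 " contains a single class")
        if (ncomp > min(length(train) - 1L, ncol(mat)))
            stop("ncomp = ", ncomp, " exceeds training fold capacity")
        fit <- fitPLSDA(mat[train, , drop = FALSE], ytr, ncomp = ncomp,
                        classes = c("C", "T"))
        pr <- predict(fit, mat[hold, , drop = FALSE])
        response[hold] <- pr$response
        predicted[hold] <- pr$class
        vip <- vip + vipScores(fit)
        folds[[k]] <- list(holdout = hold,
                           center = fit@center, scale = fit@scale)
    }
    vip <- vip / length(groups)
    met <- classificationMetrics(y, predicted)
    list(accuracy = met$accuracy, ner = met$ner, vip = vip,
         predictions = data.frame(
             index = seq_len(n), label = sampleLabels(x),
             day = info$day, truth = y, response = response,
             predicted = predicted, stringsAsFactors = FALSE),
         folds = folds, confusion = met$confusion)
}

## Evaluate all component counts 1..aMax in one CV pass, exploiting the
## nestedness of NIPALS components (one fold fit at aMax serves every A).
## Returns per-A pooled metrics, predictions and mean fold VIPs.
.cvGrid <- function(mat, y, labels, days, groups, aMax) {
    n <- nrow(mat)
    response <- matrix(0, n, aMax)
    vip <- matrix(0, ncol(mat), aMax)
    for (k in seq_along(groups)) {
        hold <- groups[[k]]
        train <- setdiff(seq_len(n), hold)
        if (length(train) == 0L) train <- hold
        ytr <- .codeClasses(y[train], c("C", "T"))$y
        if (length(unique(ytr)) < 2L)
            stop("training fold for group ", names(groups)[k],
                 " contains a single class")
        if (aMax > min(length(train) - 1L, ncol(mat)))
            stop("ncomp = ", aMax, " exceeds training fold capacity")
        params <- autoscaleFit(mat[train, , drop = FALSE])
        Xs <- autoscaleApply(mat[train, , drop = FALSE], params)
        core <- .plsCore(Xs, ytr, aMax)
        Hs <- autoscaleApply(mat[hold, , drop = FALSE], params)
        for (A in seq_len(aMax)) {
            cb <- .plsCollapse(core, A)
            response[hold, A] <- drop(cb$intercept + Hs %*% cb$b)
            vip[, A] <- vip[, A] + .plsVip(core, A)
        }
    }
    vip <- vip / length(groups)
    perA <- lapply(seq_len(aMax), function(A) {
        predicted <- ifelse(response[, A] >= 0.5, "T", "C")
        met <- classificationMetrics(y, predicted)
        list(accuracy = met$accuracy, ner = met$ner, vip = vip[, A],
             predictions = data.frame(
                 index = seq_len(n), label = labels, day = days,
                 truth = y, response = response[, A],
                 predicted = predicted, stringsAsFactors = FALSE))
    })
    perA
}
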