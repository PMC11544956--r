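#' Fit a two-class PLS-DA model
#'
#' Partial least squares discriminant analysis for a binary class: the
#' class membership is coded control = 0, treated = 1 and regressed on the
#' (autoscaled) spectral variables by PLS1. Latent variables are extracted
#' by the classical NIPALS iteration: each X-weight vector maximises the
#' covariance of the X-score with the current response residual, X is
#' deflated by its rank-one score/loading reconstruction and the response
#' by its fitted part. With the number of components equal to the rank of
#' X the fitted values coincide with ordinary least squares.
#'
#' @param x numeric matrix (measurements x variables) or a
#'   [SpectrumSet-class] (variables named by wavelength; the class is
#'   taken from the sample metadata `group`).
#' @param y class vector (factor/character with the control level first,
#'   or 0/1 numeric); ignored when `x` is a `SpectrumSet`.
#' @param ncomp number of latent variables A, `1 <= A <= min(n-1, p)`.
#' @param autoscale logical; standardise columns to zero mean / unit sd
#'   with parameters stored in the model (the workflow's convention). Set
#'   `FALSE` if `x` is already scaled (parameters are then identity).
#' @param classes length-2 character giving the control and treated codes
#'   (defaults `c("C","T")`, or the factor levels of `y`).
#' @return a [PLSDAModel-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 12, 5)
#' y <- rep(c("C", "T"), each = 6)
#' m <- fitPLSDA(X, y, ncomp = 2)
#' vipScores(m)
#' @export
fitPLSDA <- function(x, y = NULL, ncomp, autoscale = TRUE,
                     classes = NULL) {
    if (is(x, "SpectrumSet")) {
        if (is.null(y)) y <- sampleInfo(x)$group
        vars <- sprintf("%.6g", wavelengths(x))
        x <- spectra(x)
        colnames(x) <- vars
    }
    x <- as.matrix(x)
    n <- nrow(x); p <- ncol(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
    yc <- .codeClasses(y, classes)
    y01 <- yc$y; classes <- yc$classes
    if (length(y01) != n)
        stop("length of class vector (", length(y01),
             ") does not match rows of x (", n, ")")
    if (length(unique(y01)) < 2L)
        stop("both classes must be present to fit PLS-DA")
    ncomp <- as.integer(ncomp)
    if (ncomp < 1L || ncomp > min(n - 1L, p))
        stop("ncomp must be in 1..min(n-1, p) = ", min(n - 1L, p))
    if (autoscale) {
        params <- autoscaleFit(x)
        Xs <- autoscaleApply(x, params)
    } else {
        params <- list(center = setNames(rep(0, p), colnames(x)),
                       scale = setNames(rep(1, p), colnames(x)))
        Xs <- x
    }
    core <- .plsCore(Xs, y01, ncomp)
    W <- core$W; P <- core$P; Tm <- core$Tm; q <- core$q
    cb <- .plsCollapse(core, ncomp)
    b <- cb$b; intercept <- cb$intercept
    fitted <- drop(intercept + Xs %*% b)
    rownames(W) <- rownames(P) <- colnames(x)
    model <- new("PLSDAModel",
        ncomp = ncomp, weights = W, loadings = P, yloadings = q,
        scores = Tm, coefficients = setNames(b, colnames(x)),
        intercept = intercept,
        center = setNames(unname(params$center), colnames(x)),
        scale = setNames(unname(params$scale), colnames(x)),
        variables = colnames(x), classes = classes, threshold = 0.5,
        fitted = fitted, y = y01)
    validObject(model)
    model
}

## NIPALS PLS1 core on a (possibly autoscaled) predictor matrix. The
## extracted components are nested: the first A columns of (W, P, q) are
## exactly the A-component model, which .plsCollapse exploits.
.plsCore <- function(Xs, y01, ncomp) {
    n <- nrow(Xs); p <- ncol(Xs)
    xsMeans <- colMeans(Xs)
    Xd <- sweep(Xs, 2L, xsMeans)
    ymean <- mean(y01)
    yd <- y01 - ymean
    W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
    Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
    for (a in seq_len(ncomp)) {
        w <- crossprod(Xd, yd)
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12)
            stop("X fully deflated before component ", a,
                 ": reduce ncomp")
        w <- w / nw
        tt <- drop(Xd %*% w)
        t2 <- sum(tt^2)
        if (t2 < 1e-12)
            stop("degenerate score at component ", a, ": reduce ncomp")
        pl <- drop(crossprod(Xd, tt)) / t2
        qa <- sum(yd * tt) / t2
        Xd <- Xd - tcrossprod(tt, pl)
        yd <- yd - qa * tt
        W[, a] <- w; P[, a] <- pl; Tm[, a] <- tt; q[a] <- qa
    }
    list(W = W, P = P, Tm = Tm, q = q, ymean = ymean,
         xsMeans = xsMeans)
}

## Collapse the first A components into one regression vector (b,
## intercept) in the space .plsCore was given.
.plsCollapse <- function(core, A) {
    W <- core$W[, seq_len(A), drop = FALSE]
    P <- core$P[, seq_len(A), drop = FALSE]
    q <- core$q[seq_len(A)]
    b <- drop(W %*% solve(crossprod(P, W), q))
    list(b = b, intercept = core$ymean - sum(core$xsMeans * b))
}

## VIP scores of the first A components of a .plsCore fit.
.plsVip <- function(core, A) {
    W <- core$W[, seq_len(A), drop = FALSE]
    ssy <- core$q[seq_len(A)]^2 *
        colSums(core$Tm[, seq_len(A), drop = FALSE]^2)
    sqrt(nrow(W) * drop(W^2 %*% ssy) / sum(ssy))
}

## Map a class vector to 0/1 coding with the control class first.
.codeClasses <- function(y, classes = NULL) {
    if (is.numeric(y) && all(y %in% c(0, 1))) {
        if (is.null(classes)) classes <- c("C", "T")
        return(list(y = as.numeric(y), classes = classes))
    }
    y <- as.factor(y)
    lev <- levels(droplevels(y))
    if (length(lev) != 2L)
        stop("exactly two classes required, got: ",
             paste(lev, collapse = ", "))
    if (is.null(classes)) classes <- lev
    if (!all(y %in% classes))
        stop("unknown class label")
    list(y = as.numeric(y == classes[2L]), classes = classes)
}

#' Predict from a fitted PLS-DA model
#'
#' Applies the stored autoscaling and regression vector to new spectra and
#' thresholds the continuous response at the model threshold (default
#' 0.5). A response exactly at the threshold is classified treated.
#'
#' @param object a [PLSDAModel-class].
#' @param newdata matrix (measurements x variables, same p as the model)
#'   or [SpectrumSet-class].
#' @return list with `response` (continuous), `class` (predicted codes).
#' @export
setMethod("predict", "PLSDAModel", function(object, newdata) {
    mat <- if (is(newdata, "SpectrumSet")) spectra(newdata)
           else as.matrix(newdata)
    p <- length(object@coefficients)
    if (ncol(mat) != p)
        stop("newdata has ", ncol(mat), " columns; model expects ", p)
    Xs <- sweep(sweep(mat, 2L, object@center), 2L, object@scale, `/`)
    yhat <- drop(object@intercept + Xs %*% object@coefficients)
    cls <- ifelse(yhat >= object@threshold,
                  object@classes[2L], object@classes[1L])
    list(response = yhat, class = cls)
})

#' Variable importance in projection (VIP) scores
#'
#' For component a with unit weight vector w_a, score t_a and Y-loading
#' q_a, the explained response sum of squares is SSY_a = q_a^2 t_a' t_a
#' and VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a ). The squared
#' scores average to 1 over variables, so VIP = 1 is the
#' "average importance" reference line.
#'
#' @param object a fitted [PLSDAModel-class].
#' @return named non-negative vector of length p, mean squared value 1.
#' @rdname vipScores
#' @export
setMethod("vipScores", "PLSDAModel", function(object) {
    W <- object@weights
    p <- nrow(W)
    ssy <- object@yloadings^2 * colSums(object@scores^2)
    wn2 <- colSums(W^2)             # unit by construction; guard anyway
    contrib <- sweep(W^2, 2L, wn2, `/`)
    v <- sqrt(p * drop(contrib %*% ssy) / sum(ssy))
    setNames(v, object@variables)
})

#' @describeIn fitPLSDA collapsed regression coefficients in
#'   pretreated-autoscaled space (used for short- vs long-term coefficient
#'   sign comparison).
#' @param object a fitted `PLSDAModel`.
#' @param ... unused.
#' @export
setMethod("coef", "PLSDAModel", function(object, ...) object@coefficients)

setMethod("show", "PLSDAModel", function(object) {
    cat("PLSDAModel:", length(object@coefficients), "variables,",
        object@ncomp, "latent variable(s)\n")
    cat("  classes:", paste(object@classes, collapse = " vs "),
        "| threshold:", object@threshold, "\n")
    acc <- classificationMetrics(
        ifelse(object@y == 1, object@classes[2L], object@classes[1L]),
        ifelse(object@fitted >= object@threshold,
               object@classes[2L], object@classes[1L]))
    cat(sprintf("  calibration accuracy: %.2f%%\n", acc$accuracy))
    invisible(object)
})

#' Classification accuracy and non-error rate
#'
#' Accuracy is the percentage of correct predictions; the non-error rate
#' (NER%) is the arithmetic mean of the per-class sensitivities, in
#' percent. The two coincide for balanced classes with balanced errors.
#'
#' @param truth,predicted equal-length class vectors (two classes).
#' @return list with `accuracy`, `ner` (both in percent) and the 2x2
#'   `confusion` table (rows = truth).
#' @examples
#' classificationMetrics(rep(c("C", "T"), each = 18),
#'                       c(rep("C", 17), "T", rep("T", 18)))
#' @export
classificationMetrics <- function(truth, predicted) {
    truth <- as.character(truth); predicted <- as.character(predicted)
    if (length(truth) != length(predicted))
        stop("truth and predicted must have equal length")
    classes <- sort(unique(truth))
    if (length(classes) > 2L)
        stop("more than two classes in truth")
    if (!all(predicted %in% classes))
        stop("unknown label in predictions: ",
             setdiff(predicted, classes)[1L])
    conf <- table(factor(truth, classes), factor(predicted, classes))
    accuracy <- 100 * sum(diag(conf)) / sum(conf)
    sens <- diag(conf) / rowSums(conf)
    list(accuracy = accuracy, ner = 100 * mean(sens),
         confusion = conf)
}
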