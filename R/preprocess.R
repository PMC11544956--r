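#' Standard normal variate (SNV) scatter correction
#'
#' Centres and scales each spectrum (row) to mean 0 and unit standard
#' deviation (n-1 denominator), removing additive offsets and
#' multiplicative scatter effects. SNV is idempotent up to floating-point
#' tolerance.
#'
#' @param x a [SpectrumSet-class].
#' @return the transformed `SpectrumSet`.
#' @rdname snv
#' @export
setMethod("snv", "SpectrumSet", function(x) {
    mat <- spectra(x)
    m <- rowMeans(mat)
    s <- apply(mat, 1L, stats::sd)
    zero <- which(s == 0 | !is.finite(s))
    if (length(zero))
        stop("zero row variance: cannot SNV-transform measurement ",
             zero[1L], " ('", sampleLabels(x)[zero[1L]], "')")
    .replaceSpectra(x, (mat - m) / s)
})

#' Savitzky-Golay derivative filter weights
#'
#' Closed-form convolution weights of the moving polynomial least-squares
#' derivative: a polynomial of degree `polyOrder` is fitted to each
#' `window`-point segment and its `order`-th derivative evaluated at the
#' centre, in index (grid-step) units. For the default 5-point quadratic,
#' the first-derivative weights are (-2,-1,0,1,2)/10 and the
#' second-derivative weights (2,-1,-2,-1,2)/7.
#'
#' @param window odd filter width (number of points).
#' @param polyOrder polynomial degree (> `order` - 1).
#' @param order derivative order.
#' @return numeric vector of `window` convolution weights.
#' @export
sgFilterWeights <- function(window = 5L, polyOrder = 2L, order = 1L) {
    window <- as.integer(window)
    if (window < 3L || window %% 2L == 0L)
        stop("window must be odd and >= 3")
    if (polyOrder < order)
        stop("polyOrder must be >= derivative order")
    if (polyOrder >= window)
        stop("polyOrder must be < window")
    h <- (window - 1L) %/% 2L
    G <- outer(seq(-h, h), 0:polyOrder, `^`)
    ## row (order+1) of the pseudoinverse gives the centred polynomial
    ## coefficient of x^order; times order! it is the derivative at 0
    pinv <- solve(crossprod(G), t(G))
    factorial(order) * pinv[order + 1L, ]
}

#' Savitzky-Golay derivative of spectra
#'
#' Applies the moving 5-point, second-order-polynomial least-squares
#' derivative along the wavelength axis of each spectrum. Edges are
#' truncated (no padding): the output drops `(window-1)/2` wavelengths at
#' each end, so the default 5-point filter maps p wavelengths to p - 4.
#' The wavelength grid is treated as uniform in index units; the
#' derivative is scaled per grid step, a global factor that classification
#' after autoscaling is invariant to.
#'
#' @param x a [SpectrumSet-class] with at least `window` wavelengths on a
#'   (near-)uniform grid.
#' @param order derivative order, 1 or 2.
#' @param window odd filter width (default 5).
#' @param polyOrder fitted polynomial degree (default 2).
#' @return a `SpectrumSet` on the truncated wavelength grid.
#' @rdname sgDerivative
#' @export
setMethod("sgDerivative", "SpectrumSet",
    function(x, order = 1L, window = 5L, polyOrder = 2L) {
        if (!order %in% c(1L, 2L))
            stop("derivative order must be 1 or 2")
        wl <- wavelengths(x)
        p <- length(wl)
        if (p < window)
            stop("need at least ", window, " wavelengths, got ", p)
        d <- diff(wl)
        if (max(d) - min(d) > 1e-6 * mean(d))
            stop("non-uniform wavelength grid (spacing varies by more ",
                 "than tolerance); resample before differentiation")
        w <- sgFilterWeights(window, polyOrder, order)
        h <- (as.integer(window) - 1L) %/% 2L
        mat <- spectra(x)
        keep <- seq.int(h + 1L, p - h)
        out <- matrix(0, nrow(mat), length(keep))
        for (k in seq_len(window))
            out <- out + w[k] * mat[, keep + (k - 1L) - h, drop = FALSE]
        .replaceSpectra(x, out, wavelengths = wl[keep])
    })

#' Paired-day centering
#'
#' Subtracts from every spectrum the mean spectrum of all measurements
#' sharing its analysis day, so each control/treated pair of fish is
#' expressed relative to its own average. This removes fish- and day-level
#' additive variability, which in this study design is larger than the
#' treatment effect itself. The operation uses only the day structure,
#' never class identity, so it can be applied identically to training and
#' held-out days without information leakage.
#'
#' @param x a [SpectrumSet-class]; every day present must contain both a
#'   control and a treated fish.
#' @return the day-centred `SpectrumSet` (per-day mean spectrum zero).
#' @rdname pairCenter
#' @export
setMethod("pairCenter", "SpectrumSet", function(x) {
    info <- sampleInfo(x)
    day <- info$day
    for (d in unique(day)) {
        g <- unique(info$group[day == d])
        if (length(g) < 2L)
            stop("unpaired day ", d, ": only group '", as.character(g),
                 "' present")
    }
    mat <- spectra(x)
    centred <- mat
    for (d in unique(day)) {
        i <- which(day == d)
        centred[i, ] <- sweep(mat[i, , drop = FALSE], 2L,
                              colMeans(mat[i, , drop = FALSE]))
    }
    .replaceSpectra(x, centred)
})

#' Fit and apply per-wavelength autoscaling
#'
#' `autoscaleFit` computes per-wavelength training means and standard
#' deviations (n-1 denominator); `autoscaleApply` standardises any
#' spectra matrix with those frozen parameters. In cross-validation the
#' parameters are always fitted on the training folds only.
#'
#' @param x numeric matrix (measurements x wavelengths) or
#'   [SpectrumSet-class] (its [spectra()] matrix is used).
#' @return `autoscaleFit`: list with `center`, `scale` (named by
#'   variable); `autoscaleApply`: the standardised matrix.
#' @export
autoscaleFit <- function(x) {
    mat <- if (is(x, "SpectrumSet")) spectra(x) else as.matrix(x)
    if (nrow(mat) < 2L)
        stop("need at least 2 training rows to autoscale")
    ctr <- colMeans(mat)
    scl <- apply(mat, 2L, stats::sd)
    zero <- which(scl == 0 | !is.finite(scl))
    if (length(zero))
        stop("constant training column: variable '",
             colnames(mat)[zero[1L]] %||% zero[1L],
             "' has zero variance")
    list(center = ctr, scale = scl)
}

#' @param params parameters from `autoscaleFit`.
#' @rdname autoscaleFit
#' @export
autoscaleApply <- function(x, params) {
    mat <- if (is(x, "SpectrumSet")) spectra(x) else as.matrix(x)
    if (ncol(mat) != length(params$center))
        stop("column count (", ncol(mat),
             ") does not match autoscaling parameters (",
             length(params$center), ")")
    sweep(sweep(mat, 2L, params$center), 2L, params$scale, `/`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a named pretreatment pipeline
#'
#' The pretreatments compared by the workflow are alternatives: each model
#' uses exactly one of SNV (`"snv"`), first derivative (`"der1"`) or
#' second derivative (`"der2"`) before autoscaling; `"none"` passes the
#' spectra through. A character vector chains several steps in order
#' (e.g. `c("snv", "der1")`) for workflows that read the pretreatments as
#' a sequence. Paired-day centering, when enabled, is applied after the
#' spectral pretreatment and before autoscaling.
#'
#' @param x a [SpectrumSet-class].
#' @param method character vector of steps among `"none"`, `"snv"`,
#'   `"der1"`, `"der2"`.
#' @param pairCentering logical; apply [pairCenter()] after the steps.
#' @return the pretreated `SpectrumSet`.
#' @export
preprocessSpectra <- function(x, method = "snv", pairCentering = TRUE) {
    for (m in method) {
        x <- switch(match.arg(m, c("none", "snv", "der1", "der2")),
            none = x,
            snv = snv(x),
            der1 = sgDerivative(x, order = 1L),
            der2 = sgDerivative(x, order = 2L))
    }
    if (pairCentering) x <- pairCenter(x)
    x
}
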