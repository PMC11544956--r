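#' @import methods
#' @importFrom stats predict rnorm sd setNames
#' @importFrom utils read.csv write.csv head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
NULL

#' SpectrumSet: NIR spectra with sample metadata
#'
#' `SpectrumSet` extends [SummarizedExperiment::SummarizedExperiment] and
#' stores one NIR absorbance spectrum per measurement. Following
#' Bioconductor convention, features (wavelengths) are rows and measurements
#' are columns of the `"intensity"` assay; the user-facing accessor
#' [spectra()] returns the transposed measurements-by-wavelengths matrix
#' that chemometric code operates on.
#'
#' Column metadata holds the parsed sample label fields (`site`, `fish`,
#' `group`, `term_hours`, `replicate`, see [parseSampleLabel()]) plus the
#' analysis `day` used to build paired cross-validation groups. The handheld
#' instrument this workflow targets acquires over 908--1676 nm; the class
#' itself only requires a strictly increasing finite grid so that
#' derivative-truncated and toy grids remain representable.
#'
#' @slot (inherited) see `SummarizedExperiment`.
#' @seealso [SpectrumSet()], [readSpectraTable()], [simulateStudy()]
#' @export
setClass("SpectrumSet", contains = "SummarizedExperiment")

setValidity("SpectrumSet", function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    rd <- SummarizedExperiment::rowData(object)
    if (!"wavelength_nm" %in% colnames(rd)) {
        msg <- c(msg, "rowData column 'wavelength_nm' is required")
    } else {
        wl <- rd$wavelength_nm
        if (!is.numeric(wl) || anyNA(wl))
            msg <- c(msg, "'wavelength_nm' must be numeric without NA")
        else if (length(wl) > 1L && any(diff(wl) <= 0))
            msg <- c(msg, "'wavelength_nm' must be strictly increasing")
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("site", "fish", "group", "term_hours", "replicate", "day")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData column(s) missing: ",
                             paste(miss, collapse = ", ")))
    if ("intensity" %in% SummarizedExperiment::assayNames(object)) {
        a <- SummarizedExperiment::assay(object, "intensity")
        if (!all(is.finite(a)))
            msg <- c(msg, "all intensities must be finite")
    }
    if (length(msg)) msg else TRUE
})

#' PLSDAModel: fitted two-class PLS-DA model
#'
#' A PLS1 regression of a 0/1 class coding (control = 0, treated = 1) on
#' autoscaled spectral variables, fitted by NIPALS. Stores the weight,
#' loading and score matrices of the latent variables, the collapsed
#' regression coefficient vector, the training autoscaling parameters, and
#' the 0.5 decision threshold (ties classified treated).
#'
#' @slot ncomp number of latent variables (LVs).
#' @slot weights p x A matrix W of X-weights (unit columns).
#' @slot loadings p x A matrix P of X-loadings.
#' @slot yloadings length-A vector q of Y-loadings.
#' @slot scores n x A matrix T of X-scores (mutually orthogonal columns).
#' @slot coefficients length-p collapsed regression vector b in
#'   autoscaled space.
#' @slot intercept response intercept (training class-coding mean).
#' @slot center,scale training per-variable autoscaling mean and sd.
#' @slot variables variable (wavelength) names, length p.
#' @slot classes class codes, control first (default `c("C","T")`).
#' @slot threshold decision threshold on the continuous response.
#' @slot fitted fitted continuous responses on the training set.
#' @slot y training 0/1 coded response.
#' @export
setClass("PLSDAModel",
    representation(
        ncomp = "integer",
        weights = "matrix",
        loadings = "matrix",
        yloadings = "numeric",
        scores = "matrix",
        coefficients = "numeric",
        intercept = "numeric",
        center = "numeric",
        scale = "numeric",
        variables = "character",
        classes = "character",
        threshold = "numeric",
        fitted = "numeric",
        y = "numeric"
    )
)

setValidity("PLSDAModel", function(object) {
    msg <- character()
    p <- length(object@coefficients)
    A <- object@ncomp
    if (nrow(object@weights) != p || ncol(object@weights) != A)
        msg <- c(msg, "weights must be p x ncomp")
    if (length(object@yloadings) != A)
        msg <- c(msg, "yloadings must have length ncomp")
    if (length(object@classes) != 2L)
        msg <- c(msg, "exactly two classes required")
    ## latent-variable scores must be mutually orthogonal
    if (ncol(object@scores) >= 2L) {
        G <- crossprod(object@scores)
        off <- max(abs(G[upper.tri(G)]))
        nrm <- max(diag(G))
        if (off > 1e-8 * max(1, nrm))
            msg <- c(msg, "score vectors are not mutually orthogonal")
    }
    if (length(msg)) msg else TRUE
})

#' CVScheme: cancellation groups for paired-day cross-validation
#'
#' A partition of measurement indices into cancellation groups, one per
#' analysis day: all replicate spectra of the fish analysed on the same day
#' are held out together ("leave-more-out"). For the study design this
#' workflow targets (6 days per exposure term, one control + one treated
#' fish per day, 3 replicates) that gives 6 groups of 6 rows.
#'
#' @slot groups named list of integer index vectors, disjoint, covering
#'   all rows.
#' @slot info one data.frame row per group: day, fish ids, row count.
#' @export
setClass("CVScheme",
    representation(groups = "list", info = "data.frame"))

setValidity("CVScheme", function(object) {
    idx <- unlist(object@groups, use.names = FALSE)
    if (anyDuplicated(idx))
        return("cancellation groups must be disjoint")
    if (length(object@groups) != nrow(object@info))
        return("info must have one row per group")
    TRUE
})

#' BEResult: backward-elimination trace and selected model
#'
#' Result of VIP-driven backward elimination around cross-validated PLS-DA.
#' The trace records, for every elimination cycle, the retained variable
#' count, the per-cycle best number of latent variables, and calibration /
#' cross-validation accuracy and non-error rate; the selected cycle is the
#' one attaining maximal CV accuracy (ties: fewer variables, then fewer
#' LVs, then the earlier cycle).
#'
#' @slot trace data.frame: cycle, p, ncomp, acc_cal, ner_cal, acc_cv,
#'   ner_cv, n_removed.
#' @slot details per-cycle list: retained indices/wavelengths, per-A CV
#'   accuracy, mean cross-validated VIP, removed wavelengths.
#' @slot selected index of the selected cycle in the trace.
#' @slot wavelengths selected wavelengths (nm) of the final model.
#' @slot finalModel [PLSDAModel-class] refitted on all rows with the
#'   selected variables and LV count.
#' @slot cvPredictions pooled CV predictions of the selected cycle.
#' @slot pretreatment character description of the pretreatment applied.
#' @export
setClass("BEResult",
    representation(
        trace = "data.frame",
        details = "list",
        selected = "integer",
        wavelengths = "numeric",
        finalModel = "PLSDAModel",
        cvPredictions = "data.frame",
        pretreatment = "character"
    )
)

#' SyntheticStudyConfig: paired-design NIR study simulator settings
#'
#' Parameters of the synthetic spectra generator. Spectra are sums of
#' Gaussian absorbance bands (water first overtone ~1400 nm dominant, weak
#' ~1000 nm water band, lipid C-H band 1150--1200 nm with matrix-dependent
#' amplitude, ~1350 nm shoulder) with nested random effects: per-fish band
#' amplitude perturbations shared by that fish's replicates, multiplicative
#' scatter and additive offset per replicate, plus white replicate noise.
#' Treated fish receive term-specific band amplitude deltas
#' (`deltaBandsShort`/`deltaBandsLong`) and/or explicit per-wavelength
#' additive profiles (`deltaSpectrumShort`/`deltaSpectrumLong`). In the
#' default configuration the fish-effect sd exceeds the largest treatment
#' delta (biological variability dominates) and the short- and long-term
#' deltas have opposite signs on at least half the affected bands.
#'
#' @slot nDays total analysis days (split evenly: first half short-term
#'   3 h, second half long-term 24 h).
#' @slot nReplicates replicate spectra per fish and matrix.
#' @slot matrices sample matrices to simulate, subset of E, G, M, S.
#' @slot wavelengths wavelength grid in nm.
#' @slot bands data.frame: center, sigma (nm) and per-matrix base
#'   amplitudes E, G, M, S (absorbance units).
#' @slot fishSd sd of per-fish band-amplitude perturbations.
#' @slot noiseSd sd of white replicate noise.
#' @slot scatterSd sd of the per-replicate multiplicative scatter factor.
#' @slot offsetSd sd of the per-replicate additive offset.
#' @slot deltaBandsShort,deltaBandsLong per-band treatment amplitude deltas.
#' @slot deltaSpectrumShort,deltaSpectrumLong explicit per-wavelength
#'   additive treatment profiles (length of `wavelengths`, or length 0).
#' @slot seed integer seed for the single pseudorandom stream.
#' @seealso [syntheticPreset()], [simulateStudy()]
#' @export
setClass("SyntheticStudyConfig",
    representation(
        nDays = "integer",
        nReplicates = "integer",
        matrices = "character",
        wavelengths = "numeric",
        bands = "data.frame",
        fishSd = "numeric",
        noiseSd = "numeric",
        scatterSd = "numeric",
        offsetSd = "numeric",
        deltaBandsShort = "numeric",
        deltaBandsLong = "numeric",
        deltaSpectrumShort = "numeric",
        deltaSpectrumLong = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticStudyConfig", function(object) {
    msg <- character()
    if (length(object@matrices) == 0L)
        msg <- c(msg, "at least one sample matrix required")
    if (!all(object@matrices %in% c("E", "G", "M", "S")))
        msg <- c(msg, "matrices must be a subset of E, G, M, S")
    if (object@nDays < 2L || object@nDays %% 2L != 0L)
        msg <- c(msg, "nDays must be even and >= 2 (paired split over terms)")
    if (any(c(object@fishSd, object@noiseSd,
              object@scatterSd, object@offsetSd) < 0))
        msg <- c(msg, "variance components must be non-negative")
    nb <- nrow(object@bands)
    if (length(object@deltaBandsShort) != nb ||
        length(object@deltaBandsLong) != nb)
        msg <- c(msg, "band delta vectors must match the number of bands")
    p <- length(object@wavelengths)
    for (s in c("deltaSpectrumShort", "deltaSpectrumLong")) {
        v <- slot(object, s)
        if (length(v) != 0L && length(v) != p)
            msg <- c(msg, paste0(s, " must be empty or length(wavelengths)"))
    }
    if (length(msg)) msg else TRUE
})
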