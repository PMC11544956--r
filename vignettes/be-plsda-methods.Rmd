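---
title: "Paired-design BE-PLS-DA for NIR treatment detection: methods and design choices"
author: "bePLSDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-design BE-PLS-DA: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the data model

The package classifies fish measurements as control or treated from
near-infrared absorbance spectra acquired with a handheld instrument
(908–1676 nm). The experimental layout it is built around is *paired*:
on each analysis day exactly one control and one treated fish are
measured, on four sample matrices (eye, gill, muscle, skin), at two
exposure terms (3 h and 24 h), with three replicate spectra per fish and
matrix. Twelve days split over the two terms give, per matrix and term,
36 measurements in 6 day-pairs.

Spectra live in a `SpectrumSet`, a `SummarizedExperiment` with
wavelengths as rows and measurements as columns; column metadata stores
the parsed 9-character sample code (site, fish, group, term, replicate)
and the analysis day. The day is *not* encoded in the label code, so it
must be supplied explicitly (a `day` column, or a fish-to-day map in
`readSpectraTable()`); the cross-validation scheme cannot be built
without it, which is why the reader refuses to guess.

A central feature of such data is that **fish-to-fish biological
variability exceeds the treatment effect**. The paired design exists to
cancel it: `pairCenter()` subtracts each day's mean spectrum, expressing
each control/treated pair relative to its own average. The operation
uses only day structure — never class labels — so it can be applied
identically to training and held-out days without leaking information
across cross-validation folds.

# Pretreatments

Three pretreatments are compared as *alternatives* (each model uses
exactly one before autoscaling): SNV, first derivative, second
derivative. The wording "SNV and first or second derivative" could also
be read as a chain; `preprocessSpectra()` accepts a step sequence
(e.g. `c("snv", "der1")`) for that reading, but the default treats them
as competing rows of the final report, which is how the results of such
workflows are tabulated.

* **SNV** standardises each spectrum to mean 0 / sd 1 (n−1 denominator
  throughout the package), removing additive offsets and multiplicative
  scatter. It is idempotent; a constant spectrum is an error naming the
  offending row.
* **Savitzky–Golay derivatives** use a 5-point window and 2nd-order
  polynomial. The closed-form weights are (−2,−1,0,1,2)/10 for the first
  and (2,−1,−2,−1,2)/7 for the second derivative. Edges are truncated
  (no padding), so *p* wavelengths become *p* − 4; plotting ranges of
  published derivative spectra being slightly narrower than acquisition
  ranges is consistent with this choice. The grid is treated as uniform
  in index units and the derivative is scaled per grid step — a global
  factor that autoscaled classification is invariant to. A grid whose
  spacing varies by more than 10⁻⁶ relative is rejected rather than
  silently differentiated.
* **Autoscaling** standardises each wavelength with means and standard
  deviations *of the training rows only*; the frozen parameters are
  applied to held-out data. A constant training column is an error
  naming the wavelength.

# PLS-DA, VIP, and metrics

The classifier is PLS1 regression of the class coding (control = 0,
treated = 1) on the pretreated, autoscaled spectra, extracted with the
classical NIPALS iteration: each weight vector maximises covariance
between its X-score and the current response residual, then X is
deflated by its rank-one reconstruction. Components are nested, score
vectors are mutually orthogonal (enforced by the class validity check),
and the model collapses to a single coefficient vector
b = W(PᵀW)⁻¹q used for prediction; with as many components as the rank
of X the fitted values equal ordinary least squares, which the tests use
as an independent oracle. Predictions threshold the continuous response
at 0.5; a response exactly at the threshold is classified treated (a
documented tie rule — with balanced classes the choice is arbitrary but
must be fixed).

Variable importance in projection follows the canonical definition
VIPⱼ = √(p Σₐ SSYₐ (wⱼₐ/‖wₐ‖)² / Σₐ SSYₐ), SSYₐ = qₐ² tₐᵀtₐ, whose
squared values average to one.

Two performance measures are reported: accuracy (% correct) and
non-error rate (NER%, the arithmetic mean of per-class sensitivities).
They coincide under balanced designs with symmetric errors — which is
why published tables of such analyses often show a single accuracy
column — but both are computed and exported. On a 36-row design every
attainable CV accuracy is a multiple of 100/36 (97.22, 94.44, 91.67, …),
a useful integrity check on any reported value.

# Cross-validation

Leave-more-out cross-validation respects the paired structure: one
cancellation group per analysis day, containing all replicates of both
fish measured that day (6 groups of 6 for the target design). Anything
fitted to data — autoscaling parameters and the PLS-DA model — is
re-estimated inside each fold on the training days only; the tests
verify the frozen parameters are bit-identical when a held-out fold is
perturbed. Row-local pretreatments (SNV, derivatives) and paired-day
centering act before splitting: the former use only the row itself, the
latter only within-day structure, so neither can leak class information
across folds. Whether the original workflow also refitted autoscaling
inside folds is not documented; always refitting is the
stricter-or-equal choice and is what this package does.

# Backward elimination

Each cycle: (i) every latent-variable count A in 1..`aMax` is scored by
the grouped CV (ties toward smaller A); (ii) variables are ranked by the
*cross-validated* mean VIP of the fold models at the cycle's best A —
the most direct reading of eliminating the "smallest VIP in
cross-validation"; (iii) the `max(1, floor(0.06 p))` lowest-VIP
variables are removed (ties broken by ascending VIP then ascending
wavelength index, for determinism). The loop runs down to `pMin`
(default `aMax + 1`) and afterwards selects the cycle with maximal CV
accuracy — a global-best rule rather than stop-at-first-deterioration,
which reproduces "best predictive ability" without inventing a stopping
threshold. Ties select fewer variables, then fewer latent variables,
then the earlier cycle. A is re-optimised every cycle by default
(`reoptimizeA = FALSE` freezes the first cycle's choice); published
selections showing different LV counts per model imply per-model
optimisation. `aMax` defaults to 5, the largest LV count such reports
use. The whole loop is deterministic given data, scheme and parameters.

Two properties of this estimator deserve emphasis:

* **Selection optimism.** The selected cycle's CV accuracy maximises
  over the trace, and selection shares the same CV folds as evaluation,
  so under the null it is biased upward — the acceptance script
  measures this directly (`cv_accuracy_null_be` versus
  `cv_accuracy_null`). Calibration claims about the procedure must
  therefore be made with the plain (non-selected) grouped CV, which the
  null-preset checks use.
* **Recovery protocol.** On strongly separated data the CV accuracy is
  100% along essentially the whole trace, and the fewer-variables tie
  rule then legitimately slims the model to `pMin` variables. Measuring
  *support recovery* (does the VIP ranking protect the truly informative
  wavelengths?) is therefore done by running the elimination down to the
  known support size (`pMin = 10` for the strong preset's 10 informative
  wavelengths) and counting how many survive. This is a property of the
  ranking, deliberately decoupled from the model-size selection.

# The synthetic study generator

`simulateStudy()` emulates the paired design with known ground truth.
A spectrum is a sum of Gaussian absorbance bands reflecting the standard
NIR picture for fish tissue: the dominant water first-overtone band near
1400 nm (amplitude 1.0, σ 40 nm), a weak ~1000 nm water band (0.12), a
lipid C–H second-overtone band near 1180 nm whose amplitude is
matrix-dependent (muscle 0.15 > eye ≈ gill 0.08 > skin 0.02), and a
~1350 nm C–H combination shoulder (0.20). These amplitudes are
calibration constants of the simulator chosen to reproduce the
qualitative band ordering, not measurements. On top of the bands:

* per-fish band-amplitude perturbations (`fishSd` = 0.04), drawn once
  per fish and shared by its replicates — the nested random effect that
  makes biology dominate treatment (`fishSd` exceeds every default
  treatment delta);
* per-replicate multiplicative scatter (sd 0.05) and additive offset
  (sd 0.02), the effects SNV is designed to remove;
* white replicate noise (sd 0.005 absorbance).

Treated fish receive term-specific band-amplitude deltas (default:
lipid −0.02 / shoulder +0.01 / water +0.02 at 3 h, partly sign-flipped
at 24 h, mirroring the observation that short-term effects — fresh vs
treated — act partly opposite to long-term ones — iced vs treated),
and/or explicit per-wavelength profiles. Random draws are made
unconditionally and scaled by their sd, so two configurations differing
only in a variance component share the remaining draws at the same seed;
this is what lets a test compare SNV outputs with and without scatter.
The default grid is 125 points over 908–1676 nm — a plausible grid for
that range; the true variable count of the original acquisitions is not
published, and it is a property of the data, not of the algorithm.

Presets: `"null"` (all deltas zero), `"weak"` (band deltas of magnitude
equal to `fishSd`, the regime the real problem lives in), and
`"strong"` (a 100-point grid with 10 single-wavelength additive deltas
of 0.5 absorbance, sign-flipped for the long term on 6 of 10; calibrated
once and frozen). What the generator does *not* model: inter-matrix
correlation of the same fish (matrices are simulated independently, as
each is analysed separately), wavelength-dependent noise, instrument
drift, and any nonlinear reflectance physics. Consequently, passing
tests demonstrate the correctness and calibration of the *procedure*
under the stated design — not that any particular real dataset will
classify perfectly.

# Numerical and degenerate-input choices

* Standard deviations use the n−1 denominator everywhere.
* NIPALS stops with an error if X deflates to numerical zero before the
  requested component (`ncomp` out of range is rejected up front).
* Zero-variance spectra (SNV), constant training columns (autoscaling),
  unpaired days (centering), single-class folds and fish whose
  replicates span days (scheme building) are all hard errors naming the
  offending row, wavelength, day or fish — silent repair would corrupt
  the paired CV.
* Equal-VIP removal ties and equal-accuracy cycle/LV ties are broken
  deterministically as described above.
* Report percentages are printed with two decimals.

# Problem sizes used in the checks

The shipped tests and the acceptance script work at the study's own
scale: 36 rows per matrix × term, 100–125 wavelengths, `aMax` 5, 20
simulated studies for the null and weak calibration checks, a 200-day
design for the law-of-large-numbers check on the generator, and a full
4 × 2 × 3 pipeline run for the report layout. The null calibration is
judged on the accuracy pooled across the 20 studies against the central
99% band of Binomial(36, ½)/36: per-study accuracies are day-correlated
and far more dispersed than a binomial draw, so the pooled mean is the
statistic that actually speaks to systematic optimism.

# Known limitations

* Two-class PLS1 only; no multi-class variant, no probabilistic
  thresholds.
* The BE selected-cycle CV accuracy is optimistic (see above); an outer
  validation layer would be required for an unbiased error estimate of
  the *selected* model, and is out of scope here as it was in the
  original workflow.
* The derivative assumes an (approximately) uniform wavelength grid.
* Matrices are analysed independently; no pooled multi-matrix model.
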