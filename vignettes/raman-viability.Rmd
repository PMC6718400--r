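---
title: "Methods: from single-cell Raman spectra to a viability assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-cell Raman spectra to a viability assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `ramanviability`. The package turns matrices of
single-cell Raman spectra from a drug-treatment series into per-condition
viability percentages and an IC50, and ships a synthetic-data generator that
emulates such experiments so that every stage can be tested against ground
truth.

## The measurement model

A measured single-cell spectrum is modelled as

$$ y = g \left( \sum_i w_i \, s_i + a_\mathrm{fl} \, s_\mathrm{fl}
   + a_\mathrm{w} \, s_\mathrm{w} \right) + \varepsilon + \text{spikes}, $$

where the $s_i$ are unit-area pure-component spectra of the macromolecular
pools (protein, lipid, nucleic acid) plus intracellular drug, $s_\mathrm{fl}$
and $s_\mathrm{w}$ are broadband fluorescence and water backgrounds, $g$ is a
per-spectrum multiplicative gain (laser-intensity fluctuation), and
$\varepsilon$ is additive detector noise. Viable and non-viable cells differ
in their composition weights $w$; the fluorescence amplitude grows with drug
dose (the drug absorbs and fluoresces strongly at the excitation
wavelength); and a fraction of acquisitions are *empty detections* that
contain only the background terms — the cell-localization step of an
automated platform occasionally triggers on debris or nothing, at a rate of
roughly one in ten.

The analysis chain inverts this model stage by stage:

1. **Calibration.** The detector records pixels, not wavenumbers. Band
   positions of a paracetamol reference are detected in the pixel domain
   (local maxima above 5% relative prominence, centers refined by 3-point
   parabolic interpolation) and matched in order to their known positions;
   a least-squares polynomial (degree 3 by default — degree 1 would ignore
   grating nonlinearity, higher degrees fit refinement noise) maps pixel to
   cm⁻¹. The intensity response is the Savitzky–Golay-smoothed ratio of a
   measured calibration-lamp spectrum to its certified irradiance, rescaled
   to unit mean; spectra are divided by it and linearly interpolated onto a
   common target axis. Linear interpolation is chosen for monotone,
   non-overshooting behaviour; its error is bounded by the local second
   derivative times the squared channel spacing, which is why the
   calibration round-trip test uses a finely sampled detector geometry.
2. **Cosmic-spike removal.** Channels whose residual against a running
   median (window 7) exceeds 8 robust standard deviations (MAD) *and*
   exceeds five times the residual of both immediate neighbours are
   replaced by the local median. The isolation criterion is essential:
   cosmic hits are single-channel events with neighbour ratios of 50 or
   more, whereas genuine narrow Raman bands leave a smooth residual hump
   under the running median whose peak-to-neighbour ratio stays below ~4 —
   without the criterion, band tops at 760/813/830 cm⁻¹ are clipped at
   realistic signal-to-noise ratios.
3. **EMSC.** Each spectrum is regressed by ordinary least squares on a
   design matrix containing a pure-cell reference spectrum, water and
   fluorescence interferents, and polynomial baseline terms up to order 3
   in the rescaled wavenumber. The corrected spectrum is
   $(y - \text{interferent and baseline parts}) / b_\mathrm{ref}$, which
   simultaneously removes background and normalizes the multiplicative
   scale. Rows with $b_\mathrm{ref} \le 10^{-6}$ carry no cell signal and
   are flagged. In practice the reference is estimated from a control well:
   the mean control spectrum minus its own OLS projection onto the
   interferent + baseline part of the design.
4. **Smoothing, normalization, region selection.** Savitzky–Golay with
   window 9 and order 3 (exactly polynomial-preserving, including edges);
   area normalization divides each row by the trapezoidal integral of its
   absolute value over the analysis windows; then channels outside the
   fingerprint (615–1800 cm⁻¹) and high-wavenumber (2790–3010 cm⁻¹)
   windows are dropped. Normalization is computed *over the analysis
   windows* but applied before cropping, so the band-poor silent region
   never influences the norm — the ordering of normalization and region
   selection is otherwise ambiguous, and this convention fixes it.
5. **Empty-spectrum rejection.** Rows flagged by EMSC, rows with
   $b_\mathrm{ref}$ below 5% of their well's median $b_\mathrm{ref}$
   (anchored per well, so dose-dependent intensity shifts do not inflate
   rejections), and rows below an absolute floor of 0.02 are removed. The
   absolute floor exists because the well-relative rule alone cannot
   recognise a well that is empty throughout (its median is itself
   background-level).
6. **PCA–SVM.** Mean-centered SVD of the training conditions; loading signs
   are fixed so each loading's largest-magnitude element is positive (ties
   broken by the first such element), making scores deterministic across
   platforms. A linear soft-margin SVM (box constraint $C = 1$) on the
   first two PC scores separates viable from non-viable cells, with the
   sign convention $f(z) > 0 \Rightarrow$ viable. Because the PC scores of
   area-normalized spectra carry arbitrary small units ($\sim 10^{-2}$), a
   fixed $C$ is only meaningful on a fixed feature scale: the solver
   standardizes each score dimension internally and folds the
   transformation back into the weights and bias, so the stored model
   remains an exact linear function of the raw scores. The training labels
   are condition-level (control → viable, highest dose → non-viable),
   accepting the label noise of the underlying populations, exactly as the
   assay protocol does. The classifier's "alpha value of 0.5" appearing in
   some solver environments is an initialization parameter of the dual
   variables; it is carried as metadata (`alpha_init`) and does not define
   behaviour — any convergent soft-margin solver yields the same model, and
   the test suite checks the solution against an independent SMO solve of
   the dual to $10^{-4}$.
7. **Cross-validated cost.** Stratified 10-fold cross-validation with a
   seeded shuffle; the pooled (not per-fold-averaged) misclassification
   rate is reported.
8. **Dose–response.** Predicted per-condition percentages are pooled across
   batches, the per-batch control wells averaged into one zero-dose anchor
   per batch, and a four-parameter log-logistic
   $v(d) = \ell + (u - \ell)/(1 + (d/\mathrm{IC50})^h)$ is fitted to the
   positive-dose points with the upper asymptote $u$ anchored to the mean
   control viability (a log-dose model cannot take $d = 0$ as a fitted
   point) and the lower asymptote bounded in $[0, 30]$ percentage points.
   Slope and IC50 are fitted by Levenberg–Marquardt from a deterministic
   multi-start grid (slopes 0.5/1/2/4, log-spaced IC50 grid across the dose
   range, two lower-asymptote starts); the best residual sum of squares
   wins, so the fit is reproducible. A fitted non-positive slope flags a
   non-inhibitory relationship; an IC50 outside a tenfold margin of the
   dose range is flagged extrapolated. The bounds are expressed in the
   units of the input (percent or fraction), which makes the fit invariant
   to that rescaling.

## Generator defaults and what they represent

| Parameter | Default | Meaning |
|---|---|---|
| `empty_rate` | 0.1 | empty detections, about one in ten acquisitions |
| `noise_sd` | 1e-4 | detector noise; peak-band SNR ≈ 40 at 0.25 s integration |
| `gain_cv` | 0.1 | laser-intensity fluctuation between cells (log-normal, mean 1) |
| `weight_jitter_sd` | 0.02 | biological cell-to-cell composition variability |
| `spike_rate` | 0.03 | cosmic hits per spectrum (Poisson; amplitude 5–50× local signal) |
| `fluorescence_scale` | 0.5 + 5·dose | dose-proportional fluorescence background |
| compositions | viable 45/25/30, non-viable 50/35/15 (protein/lipid/nucleic acid, %) | non-viable cells: lipid up, nucleic acid down |
| dose shifts | viable: lipid +0.03, nucleic −0.03 per µM; non-viable: protein +0.04, nucleic −0.04 per µM | gradual macromolecular drift with dose |

Band positions are literature marker bands (783, 813, 830, 1096 cm⁻¹
nucleic acids; 760, 1004, 1263, 1660 cm⁻¹ proteins; 1303, 1441, 1740,
2851 cm⁻¹ lipids; 1086, 1215, 1247 cm⁻¹ drug); shapes are Lorentzian by
convention with FWHM 10–30 cm⁻¹. The default axis is 1400 channels at
2 cm⁻¹ spacing (300–3098 cm⁻¹), covering both analysis regions and the
silent region between them. The noise level was fixed once, when the
generator was built, so that the first two principal components concentrate
the bulk (>80%) of the spectral variance and the two classes separate at
default settings — the regime the classification stage is designed for.

**What the generator does not emulate.** Instrument drift between wells,
detector etaloning and wavelength-dependent noise, photobleaching kinetics
(fluorescence is a static amplitude per condition), cell-cycle and
morphological heterogeneity beyond i.i.d. composition jitter, multi-channel
cosmic events, and saturation of the detector. Passing the recovery tests
therefore shows the chain is correct under its stated model, not that it is
robust to every artefact of real instruments.

A consequence worth knowing: because the classifier is trained on control
(dose 0) versus highest-dose conditions, dose-driven composition drift is
partially confounded with viability. Viable cells at high dose drift toward
the decision boundary, and conditions where many viable cells remain at
high dose are undercounted — the two-batch emulation in
`analysis/04_classify.R` shows exactly this at 1 µM in the batch whose true
viability stays near 50%. The same confound is inherent to the assay design
being emulated, not an artefact of this implementation.

## Numerical conventions

- Region windows are half-open `[low, high)` in cm⁻¹, compared on axis
  values directly.
- The EMSC design uses the wavenumber axis rescaled to $[-1, 1]$ for its
  polynomial terms (conditioning); full column rank is checked at basis
  construction.
- PCA explained-variance ratios are $d_k^2 / \sum_j d_j^2$ from the SVD of
  the centered matrix.
- All stochastic steps (generator, CV folds) take explicit integer seeds;
  identical inputs and seeds reproduce results bit-identically, and each
  processed data set carries a replayable provenance log.
- Problem sizes in the tests and acceptance script — 1000 cells per
  condition, 10 seeds for the recovery experiments, 2000 cells for the
  rejection-rate experiment — were chosen as the smallest sizes at which
  the binomial sampling error of a percentage (±3 points at $n = 1000$,
  3 SD) is comfortably below the 5-point recovery band being verified.

## Known limitations

- The spike detector assumes single-channel cosmic events; a hit spanning
  several channels is attenuated but may not be fully removed.
- The IC50 fit form (asymptote anchoring, lower bound, pooling convention)
  is one defensible choice among several; with only four positive dose
  levels the estimate is sensitive to it, which is why the package reports
  the fit flags and residuals alongside the point estimate.
- `read_spectra()` supports the package's TSV + JSON sidecar format only;
  binary instrument formats are out of scope.
- The EMSC reference estimated from a control well inherits that well's
  composition; a drifted or contaminated control propagates into the
  corrected spectra.
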