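---
title: "Single-EV Raman profiling: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-EV Raman profiling: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`evraman` implements a complete chemometric workflow for single-particle
Raman spectroscopy of extracellular vesicles (EVs): optically trapped
vesicles yield one fingerprint spectrum (~600–1800 cm⁻¹) per particle,
and the package turns ensembles of such spectra into (i) binned heatmap
visualizations, (ii) supervised cancer/noncancer classification, and
(iii) reference-free biomolecular decompositions with per-vesicle
compositional profiles. Because no public single-EV spectral repository
exists at the required scale, the package ships a first-class synthetic
generator that emulates the statistical structure such data exhibit;
every analysis stage is exercised and tested against it.

## The generative model

A single-EV spectrum is modeled as

$$ y = R \cdot \big( A\, \textstyle\sum_j w_j s_j + b + g \big) +
   \varepsilon + \text{spikes}, $$

where $s_j$ are four unit-norm, non-negative pure component spectra
(protein, nucleic acid, phosphatidylcholine-like and
sphingomyelin-like lipid), $w \sim \mathrm{Dirichlet}(\kappa\,\bar w)$
is the per-vesicle composition around the class mean $\bar w$, $A$ is
the peak signal amplitude in CCD counts, $b$ a smooth random quadratic
baseline, $g$ the PBS/water background (broad 1640 cm⁻¹ water bending
mode plus a slow hump), $R$ the instrument's relative spectral response
(whose reciprocal is the correction curve used in preprocessing), and
$\varepsilon$ zero-mean Gaussian noise whose variance is affine in the
total signal, approximating shot noise on CCD counts at 10–20 s
integrations. Cosmic spikes arrive with Poisson count per spectrum and
amplitudes of at least 20 local noise standard deviations.

Component band positions follow the standard compendium assignments for
EV constituents (see `raman_band_table()`): e.g. phenylalanine at
1004 cm⁻¹ and amide-III structure for protein; DNA ring-breathing at
723 cm⁻¹ and the PO₂⁻ backbone at 1084 cm⁻¹ for nucleic acid; C–C/CH₂
modes at 1064, 1295 and the strong CH₂ bend at 1442 cm⁻¹ for the lipid
species, with 989 cm⁻¹ distinguishing the sphingomyelin-like species.
Band shapes are pseudo-Voigt (50% Lorentzian) with a 12 cm⁻¹ FWHM,
typical of condensed-phase Raman lines. Relative heights were chosen so
that each component is dominated by its signature band, as in measured
reference spectra of proteins, nucleic acids, and phospholipids; this
dominance matters for band-target entropy minimization (below).

Defaults define the study conditions and are not tuned per analysis:

| parameter | default | unit | rationale |
|---|---|---|---|
| channels | 1024 | – | typical CCD width; mildly quadratic pixel→cm⁻¹ map so bins hold varying channel counts |
| range | 600–1800 | cm⁻¹ | fingerprint region spanning all reference bands |
| amplitude $A$ | 400 | counts | trapped-particle signal at 10 s |
| peak SNR | 60 | – | high-quality trapped-EV acquisitions; the regime in which both the classification and the unmixing analyses of such studies operate |
| $\kappa$ (weight dispersion) | 1000 | – | tight within-population compositional regulation; consistent with the observation that ~2-percentage-point mean differences sit at the PLSDA separability boundary |
| baseline | 40 | counts | slow drift at ~10% of signal |
| PBS background | 60 | counts | buffer contribution before 95% subtraction |
| spike rate | 0.05 | /spectrum | occasional cosmic events |

The default class profiles encode the compositional contrast between
EV populations: noncancer (protein .35, nucleic acid .30, PC .25, SM
.10) versus cancer (protein .30, nucleic acid .15, PC .40, SM .15) —
noncancer EVs carry markedly more nucleic acid, cancer EVs markedly
more total lipid.

What the generator does *not* emulate: vesicle size distributions and
trapping physics, wavenumber calibration error, detector dark current,
multi-particle trapping events beyond what the max-intensity threshold
filter models, and between-batch instrument drift (batches differ only
by seed). Tests passing on synthetic data therefore demonstrate the
correctness and statistical behavior of the algorithms under the
assumed data model, not instrument-specific robustness.

## Preprocessing chain

`preprocess_pipeline()` applies, in order: cosmic-spike removal,
response correction, min/max post-thresholding, subtraction of 95% of
the mean PBS reference, fingerprint crop, Whittaker baseline removal,
first-order Savitzky–Golay smoothing (frame 7), and normalization by
the area under the curve. Numerical choices:

* **Spike removal** flags channels where both the deviation from a
  9-channel running median and the second difference exceed 8 robust
  (MAD) standard deviations, then bridges flagged channels by linear
  interpolation. Requiring both criteria protects genuine narrow bands;
  thresholds are configuration, not auto-chosen. The MAD noise scale
  presumes shot-noise-limited data: on strictly noise-free synthetic
  input it collapses and band tips can be flagged, so the stage should
  be disabled for such idealized inputs.
* **Whittaker baseline**: asymmetric least squares with a
  second-difference penalty, weights $p = 10^{-4}$ above /
  $1-p$ below the baseline, iterated to weight convergence (mean
  absolute weight change < 1e-6, at most 50 iterations — in practice
  the binary weight pattern freezes within ~10–30). $\lambda = 10^4$ is
  used for both the main chain and the unmixing branch. Larger
  $\lambda$ drives the baseline's second differences to zero
  (straight-line limit); $\lambda \to 0$ reproduces the signal.
* **Savitzky–Golay**: value at the window center of the least-squares
  polynomial over the frame. At the edges the window shrinks
  symmetrically (with the order capped by the window size) rather than
  padding, so constant signals pass through unchanged everywhere.
* **Area normalization** integrates by the trapezoid rule over the
  wavenumber axis, not the channel index, because the CCD axis is
  nonuniform in cm⁻¹.
* The PBS reference set is despiked and response-corrected identically
  before averaging, then the matched fraction is subtracted.

## DRA heatmaps

`build_dra()` bins mean intensities into fixed-width wavenumber blocks
(default 50 cm⁻¹). Bins are half-open, anchored at the range low edge,
with the final partial bin closed at the upper edge so coverage is
total; channels are assigned by wavenumber value, and per-bin channel
counts are reported since the axis is nonuniform. A bin containing no
channels becomes `NA` — never zero, which would corrupt the min–max
color scale. Class rows average over spectra first, then over channels,
giving every spectrum equal weight. Rendering accepts only perceptually
uniform colormaps (viridis family) unless explicitly overridden,
because the color scale spans the cell minimum to maximum and a
"rainbow" gradient misrepresents relative differences. Subrange DRAs
recompute the scale from the subrange so that the strong CH₂ bend at
1442 cm⁻¹ does not dominate.

## PLS discriminant analysis

`fit_plsda()` regresses mean-centered spectra on mean-centered one-hot
class indicators with the SIMPLS algorithm; channels are not variance
scaled (peak intensities carry meaning). Classes are assigned by argmax
of the predicted indicators. Defaults: 3 latent variables for the
two-class problem, venetian-blinds cross-validation with 10 interleaved
folds in dataset order (a seeded pre-shuffle is available but off by
default; folds are not stratified within pooled classes).
Sensitivity and specificity are one-vs-rest, pooled over folds.

Outlier exclusion follows the conservative two-statistic rule: a
spectrum is removed only when both its Q residual (squared distance off
the LV subspace) and its Hotelling T² (leverage within it) exceed 95%
reference limits (Jackson–Mudholkar and F-distribution limits
respectively, with an empirical-quantile fallback). Requiring both
keeps the excluded fraction well below 1% on the default conditions;
either statistic alone would discard far more.

## Band-target entropy minimization

The unmixing branch pools all classes, applies the standard chain
without area normalization, and decomposes the matrix by SVD
(`btem_decompose()`; sign fixed so each loading vector's
largest-magnitude element is positive). For a band target (window plus
vector count $k$: 10 for protein and the lipids, 25 for nucleic acids),
`recover_component()` searches rotation coefficients $t$ of
$\hat s = V_k t$ minimizing the Shannon entropy of the normalized
absolute first derivative of $\hat s$ (scaled so its maximum inside the
window is 1), plus a quadratic negativity penalty and a large constant
penalty whenever the global maximum leaves the window. Minimum-entropy
spectra are those with few, sharp features — which is also why the
generator's components must be dominated by their signature bands: the
functional rewards derivative concentration.

Two design choices deserve explanation:

* **Negativity penalty weight (default 3).** The true pure spectra are
  never exactly representable in a truncated, noise-contaminated SVD
  basis; their best rotations carry small-amplitude negative ripples.
  A very large weight (say 10⁴) makes those ripples cost orders of
  magnitude more than the entropy scale, so the minimizer abandons the
  pure components for ripple-free blends of data rows (in the worst
  case, a class mean). The default keeps ripple-scale negativity
  (|ŝ| ≲ 2% of the window maximum) at a cost of order 0.1 entropy
  units while genuinely negative candidates remain prohibitive. The
  penalty applies during the search; the reported spectrum is clipped
  at zero and unit-normalized.
* **Search schedule.** Each of the 10 restarts runs seeded simulated
  annealing (initial temperature from the objective spread over 50
  random coefficient draws, initial state the best of those draws,
  exponential cooling 0.95 per epoch, Gaussian proposals annealed with
  the square root of relative temperature) followed by a Nelder–Mead
  polish of the best state; the restart with the lowest objective is
  reported. Without the polish the annealer parks at penalty-scale
  temperatures and never resolves entropy-scale differences. The
  default effort scales with the rotation dimension
  (`epochs = max(200, 20k)`, `moves = max(50, 4k)`, polish `200k`
  iterations): a flat schedule that converges at k = 10 is an order of
  magnitude short at k = 25, where it returns visibly contaminated
  nucleic-acid recoveries.

Recovery quality is noise-floor limited: with the default conditions a
pooled matrix of ~4000 spectra (the scale of the pooled first-isolation
matrices in practice) puts all four component recoveries above 0.95
cosine against their generating truths and keeps the mutual
contamination of the two lipid species small enough for downstream
abundance estimation; at only a few hundred pooled spectra the weakest
contrast directions sink into the noise floor of the basis and blends
can undercut the protein truth.

## Convex-mixing abundances

Components and spectra are unit-normalized and per-spectrum weights are
estimated by non-negative, sum-to-one least squares. Two formulations
are provided. The strict fixed-scale problem
($\min \lVert s - Cw\rVert^2$, $w \ge 0$, $\sum w = 1$) is solved by a
warm-started exact active-set method and is verified against an
exhaustive grid in the two-component case. The default, however, is the
scale-free formulation — plain NNLS followed by normalization of the
weights, equivalent to the constrained fit with a free intensity scale —
because the Euclidean norm of a convex mixture depends on its
composition: after unit-length normalization a residual
composition-dependent scale factor remains, and at fixed scale it
biases the weights by several percentage points even on noise-free
mixtures. The scale-free estimator is exact there, and on the default
noisy conditions recovers per-vesicle weights with RMSE below 0.01
against branch-processed generating components and below 0.05 with
BTEM-recovered components. Fit residuals are reported but never used to
reject spectra. Class summaries provide mean compositions (pie charts)
and median/IQR distributions (violins, 1.5×IQR whiskers).

## Problem sizes used in the checks

The shipped test-suite and the acceptance script run entirely on
synthetic data: 300 spectra per class per batch for classification
(two batches: model on isolation I, independent prediction of isolation
II), a pooled 4000-spectrum matrix for entropy minimization and
abundances, 2000 draws for the null-AUC check, and a reduced
256-channel axis for the cheaper unit tests. These sizes were chosen as
the smallest at which the statistical claims are comfortably inside
their operating regime.

## Known limitations

* The entropy-minimization landscape is explored stochastically;
  pathological seeds can in principle return a local minimum, which is
  why the lowest of 10 restarts is reported and the restart log kept.
* Q/T² reference limits assume approximately Gaussian residual
  structure; on strongly non-Gaussian ensembles the empirical-quantile
  fallback governs.
* The venetian-blinds scheme assumes dataset order carries no class
  structure at the fold period; the optional seeded shuffle covers
  pathological orderings.
* Abundances are interpretable relative to the supplied component set;
  rank-deficient component sets produce non-unique weights (a warning
  is emitted, the minimum-norm active-set solution returned).
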