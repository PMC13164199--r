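---
title: "Methods: GC-IMS-guided NIRS calibration of storage deterioration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GC-IMS-guided NIRS calibration of storage deterioration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coixcal)
```

## Overview

`coixcal` implements a two-instrument calibration strategy for storage
quality of processed coix seeds. GC-IMS supplies compound-resolved volatile
profiles from which composite quality indices are distilled; NIRS supplies
fast, non-destructive spectra that are calibrated against those indices by
partial least squares regression (PLSR). Once calibrated, routine monitoring
needs only the spectrometer. This vignette records the models, their
assumptions, the tunable parameters, and the design decisions taken where
the methodology was genuinely open.

## The measurement model behind the synthetic generator

No public dataset of this design exists, so the package generates one with
the statistical structure the analysis assumes. The generator is tested,
first-class code: every property the pipeline relies on is asserted against
it.

### Spectra

Absorbance is a Beer-Lambert-style mixture: for wavelength grid
$\lambda$ (900-1700 nm with 228 points, or 1300-2500 nm with 257 points),

$$a(\lambda) = \sum_k c_k(m)\, \sum_b A_{kb}\,
  e^{-(\lambda - \mu_{kb})^2 / 2\sigma_{kb}^2},$$

with latent components $k$: a carbohydrate/protein background and water
(constant in storage months $m$), an intact lipid substrate (slow
exponential decay, $e^{-m/400}$ -- only a few percent of the lipid pool
oxidizes, so substrate bands shrink slowly), lipid oxidation products
(logistic rise $0.15 + 0.85/(1+e^{-(m-18)/9})$, zero in the raw sample),
and roasting products created by processing ($e^{-m/200}$, zero in the raw
sample). Oxidation bands are planted at 1410 nm and 1880 nm -- inside the
1300-1500 and 1800-2000 nm windows where lipid-oxidation combination bands
fall -- so the long-wave grid sees both bands while the short-wave grid
sees only the first. The long-wave range is therefore more informative for
deterioration *by construction*, which turns the qualitative "long-wave
superior" expectation into a testable property.

Each recorded spectrum is distorted by a multiplicative scatter slope
$(1+s)$, an additive offset $o$ and white noise, with defaults
$\mathrm{sd}(s) = 0.02$, $\mathrm{sd}(o) = 0.01$, noise sd $0.002$
absorbance units -- typical magnitudes for diffuse reflectance of packed
granular samples on portable instruments. The acquisition layout is 5
subsamples $\times$ 10 scans = 50 spectra per sample. The within-sample
variance split between subsample and scan is not separately parameterized
(nothing in the downstream analysis distinguishes them); both are covered
by the per-spectrum scatter and noise terms.

### Volatiles

74 compounds are split into 8 classes (19 aldehydes, 18 alcohols, 13
ketones, 9 esters, 6 acids, 3 pyrazines, 2 furans, 4 other), each class
following a smooth parametric storage trend: logistic **rise** (aldehydes),
late logistic rise (acids, esters), exponential **fall** (alcohols),
Gaussian **dip-then-rebound** (ketones), **processing pulse** (pyrazines,
furans -- Maillard products created by roasting, fading slowly), flat
(other). Per-compound jitter varies the shape parameters within a class
without breaking monotonicity. A configurable fraction (default 0.4) of
compounds is emitted as monomer + dimer pairs sharing one trend up to a
fixed per-compound ratio, mirroring ion clustering in the drift tube.
Replicates (3 per sample) carry one shared log-normal injection factor
(sd 0.10) applied to *all* compounds including the spiked internal
standard, plus per-compound replicate noise (CV 0.05). Internal-standard
division therefore cancels the injection factor exactly -- an invariant the
tests assert at zero replicate noise.

What the generator does **not** emulate: drift-tube physics, retention
indices, compound identification, Maillard reaction kinetics, moisture
confounding, instrument transfer effects, or batch-to-batch raw-material
variation. Passing tests demonstrate that the pipeline's statistics behave
correctly on data with the assumed structure; they say nothing about
robustness to effects the generator omits.

## Preprocessing

Seven correction pipelines are compared: RAW, SG (Savitzky-Golay
smoothing), MSC, SNV, and the first-derivative compositions SGFD, MSCFD,
SNVFD. Numerical conventions:

* `log(1/R)` is read as $\log_{10}(1/R)$, the universal NIRS absorbance
  convention.
* SG defaults: window 11 points, polynomial order 2 -- common choices for
  3-5 nm point spacing; both are exposed. Derivatives are computed *within*
  the SG filter (one local fit, scaled per nm), not as a difference of a
  smoothed signal; SGFD is thus a single derivative filter, and MSCFD/SNVFD
  apply scatter correction first, then the SG derivative with the same
  window. The alternative derivative-first ordering is not implemented; the
  scatter-correction-first order matches how the composed method names are
  usually read.
* MSC regresses each spectrum on the mean *training* spectrum and inverts
  the fitted affine distortion; the reference is stored in the fitted state
  so held-out spectra are corrected against the training reference.
* Min-Max scaling is per wavelength with training minima/maxima and is
  applied **last** (after any derivative); per-spectrum scaling was
  rejected because it would duplicate SNV. Held-out values may leave
  [0, 1]; constant wavelengths map to 0 with a warning.

All data-dependent statistics live in a `fitted_state` learned on training
rows only; the tests assert that the state is bit-identical no matter which
held-out rows are later transformed.

## PLS core

PLS1 is fit by NIPALS deflation on centered data (deterministic -- no random
initialization). Spectra are centered only, since derivative magnitudes are
meaningful; marker matrices are centered and autoscaled because peak
volumes span decades. Coefficients are returned in original units via
$B = W(P'W)^{-1}q$; score orthogonality and coefficient/score prediction
equivalence are asserted to 1e-8/1e-10, and the full-rank model is checked
against the least-squares oracle.

Cross-validated latent-variable selection maximizes $R^2_{cv}$ computed
from **pooled** out-of-fold predictions rather than a mean of per-fold
$R^2$ values -- with 5 folds of modest size the pooled statistic is far
less noisy. Ties break toward fewer components. Folds are stratified by
storage class.

VIP follows the standard definition
$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a (w_{ja}/\|w_a\|)^2 /
\sum_a \mathrm{SSY}_a}$, so $\overline{\mathrm{VIP}^2} = 1$ always.

## OPLS-DA

The two-class model removes y-orthogonal variation iteratively (each
orthogonal weight is the X-loading minus its projection on the predictive
direction) and fits one predictive component on the filtered matrix; at
zero orthogonal components it reduces exactly to PLS1 on the 0/1-coded
class. The orthogonal-component count is selected by incrementing while
cross-validated Q2 improves by more than 0.01, capped at 3 -- standard
practice that prevents overfitting at the 6-21 observations typical here.
Classification accuracy uses the 0.5 midpoint cutoff. When replicate
injections of physical samples are present and more than one sample exists
per class, folds keep a sample's replicates together to avoid leakage; the
two-sample screening contrasts (3 + 3 replicates) necessarily fold at the
replicate level, stratified by class, since leave-sample-out would empty a
class.

VIP is computed from the predictive component only: orthogonal components
are by construction unrelated to the class contrast and would dilute the
marker ranking.

## Composite indices

The deterioration index is the first latent-variable score of a PLS1 model
of autoscaled, replicate-averaged marker volumes against storage months,
fit on the six processed samples only (the raw sample never enters this
index); the flavor index uses the 0/1 processing stage across all seven
samples. One latent score is used -- the point of the index is a *single*
continuous metric, and one component suffices for a monotone contrast --
with the sign oriented so the index increases with the response. Months
enter on their natural scale (no transform is prescribed by the protocol
the index emulates). Markers come from the OPLS-DA screen and are
re-weighted by the PLSR fit; selection by PLSR-VIP alone would conflate
screening and index construction in one model, so the two-stage route is
the default. The per-sample index is attached to all 50 spectra of that
sample for NIRS calibration (3 GC-IMS replicates cannot pair with 50
spectra individually).

## Calibration, splitting, validation

The 80/20 split is stratified by storage class at the spectrum level,
reproducing the acquisition-protocol convention in which all spectra are
pooled before splitting. Spectra of one physical sample therefore appear
in both partitions, which makes the held-out metrics an *internal*
validation; a sample-grouped mode exists for honest generalization
estimates but cannot stratify this design (one physical sample per class)
and errors accordingly.

The classification screen (SVM / KNN / random forest over preprocessing
methods) uses 10-fold stratified CV within the training partition, while
PLSR uses 5-fold CV -- the two stages follow different conventions and the
package mirrors each.

The permutation test shuffles the response 200 times, refits at the
**fixed** latent-variable count of the calibrated model (no re-selection --
the null must reflect the model actually deployed), records training R2
and pooled 5-fold cross-validated Q2 per permutation, and fits straight
lines of both metrics against the absolute correlation between permuted
and original responses, the unpermuted model included at correlation 1.
A Q2 intercept below 0.05 passes. Under an exchangeable null the permuted
Q2 values are negative in expectation, so genuine-signal models yield
clearly negative intercepts.

## Interpretation of coefficient profiles

High-contribution wavelength regions are contiguous runs of the
|coefficient| profile above its 90th percentile. Interpretation uses a
parsimonious 2-component model: coefficient vectors of high-rank PLS fits
are dominated by noise directions (later components fit measurement noise,
and their coefficient spikes outweigh the smooth chemical signal), making
them unreadable regardless of smoothing. With two components the top
region recovers the planted oxidation bands reliably, which the acceptance
suite checks over 20 seeded replicates.

## Problem sizes and numerical tolerances

The test suite exercises the full study layout (7 samples x 50 spectra,
257-point long-wave grid, 74 compounds x 3 replicates, 200 permutation
iterations for all four final models) plus reduced layouts (2 subsamples x
5 scans) for operator-level tests. Tolerances: exact linear-algebra
identities at 1e-8 to 1e-12; the SG sinusoid-derivative oracle at 0.05
(noise amplification through a 17-point derivative window plus quadratic
truncation); simulation-based recovery checks at fixed seeds. The
planted-marker recovery simulation uses 10 observations per group: at 3
replicates per group the expected number of chance compounds passing
VIP > 1 (~4-5 of 28 null compounds, from the null distribution of
correlations at n = 6) exceeds the false-positive budget for *any*
correlation-based screen, so a smaller design would measure small-sample
correlation noise rather than the screening method.

## Known limitations

* The synthetic generator's trends are smooth and monotone by family;
  real volatile trajectories are noisier and can cross families.
* Spectrum-level splitting overstates generalization to new samples, as
  discussed above; the paper-mirroring protocol is retained deliberately.
* The OPLS-DA screening contrasts have 3 replicates per group; their Q2
  and accuracy are near-saturated and should be read as qualitative
  separation evidence, not performance estimates.
* No moisture, temperature or instrument-transfer effects are modeled;
  calibrations built here do not transfer to real instruments.
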