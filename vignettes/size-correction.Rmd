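---
title: "Diameter correction of fruit NIR transmission spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diameter correction of fruit NIR transmission spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsize)
```

## The problem

In transmission-mode NIR sensing of intact fruit, light crosses the whole
flesh, so the detected intensity depends on the optical path length — in
practice, on the fruit's equatorial diameter. Two fruit with identical
soluble solids content (SSC) but different diameters produce systematically
different spectra, and a partial least squares (PLS) calibration built on
one size class degrades badly when applied to another. `nirsize` implements
a physics-motivated fix: model the attenuation as Beer–Lambert decay,
estimate an average per-wavelength extinction coefficient from the cohort,
and rescale every spectrum to a common reference diameter before modelling.

## The attenuation model and the correction

The working assumption is exponential attenuation over the path length
$d$ (mm):

$$ I(\lambda) = I_0(\lambda)\, e^{-u_e(\lambda)\, d}, $$

with $I_0$ the source intensity reaching the fruit and $u_e$ the effective
extinction coefficient of the flesh (1/mm). In log space the law is linear,
$\ln I = \ln I_0 - u_e d$, which `diameterAttenuationFit()` checks on data
by regressing $\ln I$ on $d$ at a chosen wavelength.

Given a reference spectrum $I_R$ at reference diameter $d_R$, each sample
$i$ supplies a per-wavelength quotient
$(\ln I_R - \ln I_i)/(d_R - d_i)$, an estimate of $-u_e$. Averaging over
samples and negating gives the cohort's average extinction curve
(`estimateExtinction()`), and each spectrum is then mapped to the reference
diameter (`applyCorrection()`):

$$ I_i^{*}(\lambda) = \exp\!\big(-u_e(\lambda)\,(d_R - d_i) +
   \ln I_i(\lambda)\big). $$

When the data follow the attenuation law exactly and the reference is the
true spectrum at $d_R$, the quotient is identical for every sample and the
correction collapses all spectra of equal composition onto one curve; the
test suite asserts both properties at numerical precision. With a positive
extinction curve, fruit smaller than the reference are attenuated and
larger fruit amplified, so the vertical spacing between size-group mean
spectra shrinks — the qualitative signature of a successful correction.

### Choices behind the correction

* **$u_e$ is a curve, not a scalar.** The log-intensity gap is
  spectrum-valued and absorption bands make the attenuation strongly
  wavelength-dependent; a scalar average is available via
  `scalarExtinction = TRUE` for users who want the cruder variant.
* **$d_i$ is each sample's own diameter.** A group-average variant
  (`diameterMode = "group-mean"`) is provided, but per-sample diameters use
  strictly more information and reduce to the group-average answer when
  diameters are unmeasured within a group.
* **`minGap` (default 1 mm).** The quotient divides by $d_R - d_i$;
  samples within 1 mm of the reference diameter contribute enormous
  variance for essentially no signal and are excluded from the *average*
  (they are still corrected — the forward map is stable everywhere).
* **Which samples feed the average.** The estimation uses spectra and
  diameters only, never SSC labels, so the pipeline averages over every
  calibration sample of every size group: the outer groups' wide diameter
  gaps (up to ±15 mm) dominate the quotients and stabilise the curve.
  Estimating from the reference group alone is possible but ill-advised —
  its gaps never exceed half the group width, and chance sampling
  correlation between SSC and diameter then leaks a multiple of the SSC
  absorption signature into $u_e$, biasing cross-size predictions.
* **Correction acts on raw positive intensities.** SNV/MSC outputs can be
  negative or dimensionless, so the correction (which takes logarithms) runs
  before any pretreatment; pretreatments are applied to the corrected
  spectra.

## The surrounding pipeline

* **Wavelength restriction** (`restrictWavelengths()`): closed interval,
  default 350–850 nm — outside it the detector signal is weak and mostly
  noise. Closed endpoints are the least surprising reading of a stated
  range. Spectra are kept at their native grid; nothing is interpolated.
* **Kennard–Stone splitting** (`kennardStone()`): deterministic max–min
  selection over Euclidean distances between intensity rows, seeded with
  the most-distant pair; ties go to the smallest sample index so a split is
  bit-reproducible. Distances are computed after wavelength restriction but
  before pretreatment, so the split does not depend on which pretreatment
  is later compared. Default 120 of 160 fruit per group to calibration.
* **Pretreatments**: SNV (per-spectrum centering/scaling, $n-1$ standard
  deviation — the standard chemometrics convention), MSC (per-spectrum
  affine regression on a reference; the calibration-set mean is the
  reference and is reused unchanged for prediction samples, preventing
  leakage), and Savitzky–Golay smoothing (default window 11 points,
  polynomial order 2 — mild smoothing that preserves the ~15–40 nm wide
  bands on a 1 nm grid). S–G uses `signal::sgolayfilt`, which fits the
  first/last full window at the edges rather than padding.
* **PLS1 by NIPALS** (`fitPLS()`): mean-centering of X and y, weights from
  the response vector, deflation of X only. With a univariate response the
  NIPALS inner loop converges in a single step, so there is no iteration
  tolerance to tune; components whose score norm falls below $10^{-12}$ of
  the first component's are dropped with a warning (this happens exactly
  beyond the rank of noiseless data). Full-rank fits reproduce ordinary
  least squares, and fixed-component predictions agree with an independent
  established implementation to $10^{-6}$ — both are asserted in the tests.
* **Latent-variable selection** (`selectLatentVariables()`):
  contiguous-block cross-validation (default 10 blocks) on the calibration
  set only, over 1–20 components; ties prefer fewer components. The
  prediction set never influences model complexity.
* **Metrics**: $R$ is Pearson's correlation between measured and predicted
  SSC; a residual-based variant $1 - \mathrm{SS}_{res}/\mathrm{SS}_{tot}$
  is reported alongside as `r_squared_alt` because part of the literature
  prints that formula under the correlation's name — it is not a
  correlation and can be negative under biased transfer. RMSE uses the
  $n-1$ divisor by convention here; divisor $n$ is an option
  (`rmseMetric(divisor = "n")`).

### Evaluation cells

`runExperiment()` evaluates three kinds of cells. *Per-group*: each size
group modelled and predicted within itself, per pretreatment. *Mixed*: the
concatenation of the per-group calibration sets (360 fruit) predicts the
concatenated prediction sets — the splits are reused, not redrawn.
*Cross-size*: the reference (medium) group's calibration set predicts each
other group in full, once uncorrected and once after size correction. The
predicted cohort is the other group's complete 160 samples: none of them
ever touches training, and the larger evaluation set makes the stochastic
comparison of corrected vs. uncorrected models stabler than a 40-sample
subset would. The default stage order is split → estimate $u_e$ on
calibration samples → correct → pretreat → model, which keeps the
evaluation free of any information flow from prediction samples.

## What the synthetic generator emulates

Real cohorts of this kind are rarely deposited, so the package ships a
generator (`generateCohort()`) that produces the statistical structure the
method assumes, with exact ground truth:

* three diameter groups — 65–75, 75–85, 85–95 mm, 160 fruit each,
  diameters uniform within the group;
* per-group SSC from truncated normal distributions (means 13.8, 13.2,
  13.3 °Brix; SDs 1.62, 1.60, 1.73; truncation at each group's observed
  min/max), matching the descriptive statistics typical of commercial
  apple cohorts of these sizes;
* intensities $I_0(\lambda) e^{-(u_{base}(\lambda) + k(\lambda)\,s)\,d}$
  with a smooth halogen-lamp-like source envelope, a baseline extinction
  around 0.08–0.09 /mm with Gaussian structure placing transmission maxima
  near 645, 710 and 810 nm and absorption bands near 675 (chlorophyll),
  758 (O–H) and 830 nm (N–H), and an SSC coupling $k$ concentrated at the
  sugar-related bands (peak $2.2\times10^{-4}$ /(mm·°Brix));
* multiplicative log-normal noise (default $\sigma = 0.01$ in log units,
  i.e. ~1% intensity noise), consistent with the log-linear model and
  guaranteeing positive intensities.

The coupling amplitude gives an SSC-driven log-intensity spread of roughly
0.03 at the strongest band across a group — large enough that a per-group
PLS model succeeds, small enough that the diameter effect (about 0.8 log
units between group centres) dominates the raw spectra, which is exactly
the regime the correction targets.

What the generator does **not** emulate: scattering anisotropy and
geometry-dependent path lengths (real transmission paths are not exactly
the equatorial diameter), skin pigmentation differences, detector
nonlinearity, temperature drift, and wavelength-correlated noise. Passing
tests therefore demonstrate that the algorithms are correct under the
stated attenuation model and robustly beneficial under its noisy
perturbation — not that any particular accuracy will be attained on a
physical instrument.

```{r example, eval = FALSE}
cohort <- generateCohort(syntheticConfig(seed = 1))
plan <- experimentPlan(cohort$set, cells = "cross-size")
report <- runExperiment(plan)
compareCorrection(report)
```

## Problem sizes and numerical tolerances

The default study conditions — 480 fruit, 501 wavelengths, 120/40 splits,
20-component searches with 10-fold cross-validation — run the full
evaluation grid in a few seconds, so tests and the acceptance script use
them unscaled (smaller cohorts appear in unit tests purely to keep
closed-form fixtures readable). Exactness checks use tolerances of
$10^{-9}$–$10^{-12}$ relative, reflecting double-precision arithmetic
through logarithms and exponentials; stochastic checks fix their seeds and
use 3-standard-error bounds.

## Known limitations

* The correction assumes one effective path length equal to the equatorial
  diameter; fruit measured off-axis or highly aspherical fruit violate it.
* $u_e$ is averaged over the cohort; composition-dependent extinction
  (e.g. the SSC coupling itself) is deliberately retained in the corrected
  spectra — it *is* the signal — but strong pigment variation between
  samples would also survive and may need a pretreatment afterwards.
* The estimation degrades when diameter spread is small; with `minGap`
  excluding everything, it fails loudly rather than extrapolating.
* Predictions transfer between size groups, not between instruments;
  calibration-transfer methods are out of scope.
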