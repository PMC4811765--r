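---
title: "Quantifying macromolecular mobility and crowding: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macromolecular mobility and crowding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptcrowd)
```

## Scope

`sptcrowd` quantifies how glucose starvation confines macromolecular mobility
in budding yeast. The measured objects are fluorescently labelled chromosomal
loci (LacO/LacI-GFP arrays) and cytoplasmic mRNP particles (PP7-tagged
transcripts), imaged as diffraction-limited spots at 0.5 s intervals for 60 s
(two-locus experiments: 1.5 s for 150 s). Because the raw movies of such
studies are rarely deposited, the package pairs every analysis stage with a
synthetic generator whose ground truth is known exactly; the generators are
first-class, tested code, and the analysis stack makes no assumption that its
input came from them.

## Diffusion models in the generator

Three motion models cover the regimes such data display:

**Brownian motion.** Parameterized directly by the slope of the 2D ensemble
MSD, because that slope — not a per-axis diffusion constant — is the
convention for the effective diffusion coefficient K here: per-axis increments
are i.i.d. Gaussian with variance `msd_slope * dt / 2`, giving
E[MSD] = `msd_slope * tau` with no factor-of-4 bookkeeping. Anyone comparing
against the usual `MSD = 4 D tau` should read `K = 4 D`.

**Fractional Brownian motion** for subdiffusion with constant anomalous
exponent `alpha` (Hurst `H = alpha/2`). Observed exponents for chromatin and
mRNPs span roughly 0.3–0.9, so the sampler must be exact across that range:
increments are synthesized by Davies–Harte circulant embedding of the
fractional-Gaussian-noise covariance
`gamma(k) = (sigma^2/2)(|k+1|^{2H} + |k-1|^{2H} - 2|k|^{2H})`.
When the circulant eigenvalues are not all nonnegative (possible at
pathological lengths), the sampler falls back to an exact Cholesky
factorization of the increment covariance — the same exact-covariance draw,
chosen over recursive (Hosking) conditioning because it is shorter to audit
and the trajectory lengths here (~10²) make its cost irrelevant. If both
paths fail the error is loud; the sampler never truncates covariance
silently.

**Confined (Ornstein–Uhlenbeck) motion** for tethered chromatin: exact
discretization with mean-reversion time `tau_c` and stationary variance
`D * tau_c` per axis, started at stationarity, so
E[MSD] = `4 D tau_c (1 - exp(-tau/tau_c))` exactly at every lag.

Static localization error is modelled as i.i.d. Gaussian position noise,
which adds a flat `4 sigma_loc^2` to the 2D MSD at every lag ≥ 1. The
paired-locus generator places two independent Brownian walkers a fixed
separation apart and adds an identical per-frame rigid translation to both,
emulating whole-nucleus motion that the two-locus distance cancels exactly.

Defaults mirror the acquisition they emulate: `dt = 0.5` s and 121 frames
(60 s inclusive of t = 0); two-locus `dt = 1.5` s and 101 frames. The movie
renderer draws isotropic Gaussian PSFs (integrated intensity
`amplitude * 2 pi psf_sigma^2`) with optional Poisson or Gaussian noise.
Published protocols do not state localization precision or spot SNR, so the
fixture defaults (`psf_sigma` 1.5 px, amplitude 100 on background 10, i.e.
peak SNR ≈ 10 under Poisson noise) are free parameters chosen as typical for
yeast spot imaging at 60–100x, not measured values.

## Tracking

Detection re-implements the classic centroid scheme for diffraction-limited
spots: a bandpass of Gaussian smoothing (sd `noise_scale`, default 1 px)
minus a boxcar background (width `feature_diameter`, default 9 px), local
maxima above a percentile threshold (default: 70th percentile of filtered
nonzero pixels) separated by at least `mask_radius` (default 4 px), then
intensity-weighted centroid refinement with mass, radius of gyration and
eccentricity from the same circular mask. Linking is globally optimal
frame-to-frame assignment: among pairings within `max_displacement` (default
5 px) that maximize the number of links, the total squared displacement is
minimized, found by exact enumeration inside connected components of the
candidate graph (ties broken deterministically by track id). There is no gap
closing: the targets are bright, stable puncta at 2 Hz, and memory-0 linking
keeps behaviour auditable. Components larger than an internal cap abort
rather than degrade to a greedy pairing. None of the detection/linking
defaults are published values; all are exposed as arguments.

## MSD and parameter estimation conventions

- Time averaging uses all overlapping start-time pairs within a trajectory;
  ensemble averaging weighs each trajectory equally (not each displacement
  pair), and the per-lag SEM is computed across trajectories. Trajectories
  shorter than a lag drop out of that lag; nothing is zero-padded. The
  alternative pair-weighted average is deliberately not offered as a hidden
  default anywhere.
- `fit_K` is OLS of MSD against `tau` over lag indices 1–10 inclusive with a
  free intercept, so static localization error (a constant offset) does not
  bias K; `through_origin = TRUE` gives the constrained alternative for
  sensitivity checks.
- `fit_alpha` is unweighted OLS of log MSD against log tau over the first 40
  lags — the standard reading of "slope of the log-log MSD". Localization
  noise flattens the short-lag end of the log-log curve, so added noise
  biases the fitted alpha downward while leaving free-intercept K within a
  few percent; the test suite asserts both directions of that behaviour.
- The two-locus MSD is the MSD of the scalar distance `d(t)` between the two
  loci. For well-separated loci each moving with MSD slope K, the distance
  MSD has slope ≈ K: the relative displacement has slope 2K and projection
  onto the separation axis halves it.

## Biophysical calculators

**Accessible cytoplasmic volume.** `A = C - V - N` per condition, with the
starved cell volume `C_S = (1 - shrink) C_NS` and vacuole volumes expressed
as fractions of the same-condition cell volume. The default inputs are the
published measurements (median cell volume 101.6 fL, 15% shrinkage, vacuole
fractions 0.25 → 0.40, nuclear volumes 4.60 → 4.12 fL), which evaluate to a
33.4% reduction in accessible cytoplasm — reported alongside the rounded
"~30%" headline rather than replacing it, since both the exact and rounded
figures follow from the same printed inputs. The identity `A + V + N = C`
holds to machine precision and the reduction is monotone in both the
shrinkage and the starved vacuole fraction.

**Volume distributions.** Median and SD are plain sample statistics. The
modal volume uses the Coulter-counter convention for right-skewed size data:
a log-spaced histogram (Freedman–Diaconis bin count on log-volumes) converted
to a density by dividing each bin count by its width in fL — without that
correction the raw count maximum estimates the median of a log-normal, not
its mode — with the peak refined to sub-bin precision by the vertex of a
local quadratic fit around the highest smoothed bin, because the raw argmax
of a fine histogram carries several bins of counting noise on flat peaks. On
log-normal populations of 10^5 cells this lands within one bin width of the
analytic mode `exp(mu - sigma^2)`.

**Dry-mass crowding.** Density = dry mass per accessible volume (pg/fL);
percent changes are reported separately for masses and densities because the
scientific claim is precisely a density rise at constant mass.

**AFM stiffness.** Per compression cycle, the OLS slope of force versus
cantilever height over approach-phase samples with force in the inclusive
3–7 nN window, sign-normalized, averaged over cycles (8 by default). Cycles
with fewer than 5 in-window samples are skipped with a warning; zero usable
cycles is an error.

**pH calibration.** A shape-preserving monotone piecewise-cubic (Hyman)
interpolant between buffer pH (5.0–8.0) and emission ratio, invertible in
both orientations. A monotone interpolant was chosen over a parametric
sigmoid because the calibration's functional form is not established;
out-of-range ratios raise an error rather than extrapolate.

**ATP standardization.** Linear OLS on the standards, concentration from the
inverted line floored at zero with a flag, OD600 correction by division, and
normalization to the pre-treatment control (pre-treatment value is 1 by
construction).

## Reproducibility machinery

All generators take a `seed` and restore the caller's RNG state, so identical
inputs give bit-identical output without perturbing the session.
`run_pipeline()` consumes a YAML/list config, writes per-condition trajectory
and MSD CSVs plus fit JSONs, a comparison table of K, alpha and
fold-changes against a declared reference condition, an optional log-log
overlay figure with a slope-one guide line, and a manifest holding the seed,
a config hash and per-file checksums; deterministic stages are
bit-reproducible across runs and stochastic ones given the seed.

## Problem sizes and what the tests show

The test and acceptance simulations use 500–1200 trajectories of 61–121
frames, chosen to match the scale of the emulated experiments (n = 183–1172
trajectories per condition) while keeping estimator standard errors a factor
of a few below the tolerances being asserted. Passing parameter-recovery
tests demonstrate that the estimators are calibrated on data generated by
their own motion models with Gaussian localization noise; they do not
demonstrate robustness to features real movies have and the generator omits:
motion blur, photobleaching, out-of-focus excursions, heterogeneous particle
populations within one condition, or drift beyond rigid per-frame
translation. The tracker's accuracy figures (recall ≥ 0.95, RMSE ≤ 0.2 px at
peak SNR ≈ 10) are likewise statements about well-separated Gaussian spots
under Poisson noise.

## Known limitations

- No gap closing or merge/split handling; crossing particles closer than
  `max_displacement` can swap identities (the exact assignment minimizes,
  but cannot eliminate, such errors).
- `fit_alpha` assumes a single power law over the fitted window; confined
  motion fitted this way yields an effective, window-dependent exponent.
- The quiescence-like regime of nearly static spots (apparent alpha ≈ 0.3
  from noise-dominated MSDs) is reachable through the confined generator but
  no attempt is made to reproduce the published quiescent estimates.
- The volume budget treats vacuole and nucleus as the only excluded
  compartments and ignores organelles it has no inputs for.
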