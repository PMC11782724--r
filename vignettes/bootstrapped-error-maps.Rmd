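---
title: "Bootstrapped residual error maps for functional lung imaging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrapped residual error maps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungboot)
```

## The signal model

Self-gated functional lung MRI delivers, per 2D slice, two cine series: a
respiratory cycle and a cardiac cycle of `N = 20` phase images each.  The
voxel signal over a cycle is modelled by its temporal discrete Fourier
series truncated after the first harmonic,

$$ s(t) \approx a_0 + |C_1|\cos\!\left(\tfrac{2\pi t}{N} + \arg C_1\right),
   \qquad t = 0,\dots,N-1 , $$

with the normalisation $a_0 = \tfrac1N\sum_t s(t)$ and
$C_1 = \tfrac2N\sum_t s(t)\,e^{-i2\pi t/N}$, chosen so that $|C_1|$ is the
physical cosine amplitude.  The DC term is the static tissue signal; the
first harmonic carries the ventilation- or perfusion-related modulation;
all higher-frequency content — noise, artifacts, model error — is the
*residual*.  Phase 0 of the respiratory cycle is expiration, where lung
parenchyma is densest and the signal maximal, so the signed ventilation
signal of a voxel is $v = \operatorname{Re} C_1$.

Three maps follow (`ventilation_map()`, `perfusion_amplitude_map()`,
`perfusion_timing_map()`):

* $V_\mathrm{abs} = (S_\mathrm{exp}-S_\mathrm{ins})/S_\mathrm{exp}
  = 2v/(a_0+v)$, in mL air per mL lung parenchyma;
* perfusion amplitude $|C_1|/S_\mathrm{ref}$, with $S_\mathrm{ref}$ the
  mean DC signal of a completely blood-filled aorta ROI;
* perfusion timing
  $\operatorname{wrap}(\arg C_1 - \varphi_\mathrm{ref})\,T_{RR}/2\pi$ in
  ms, with the reference phase taken as the argument of the complex mean
  of $C_1$ over the ROI.

## The bootstrap

The statistical error of each map is estimated from the single scan by
bootstrapping the residuals:

1. fit the first harmonic per voxel;
2. residuals $r(t) = s(t) - \hat s(t)$;
3. randomly permute each voxel's residuals along the phase axis and add
   them back to the model;
4. recompute the functional map from the synthetic series.

Steps 3–4 are repeated `B = 2000` times; the per-voxel sample SD over the
replicate stack is the error map.  To quantify how reproducible that
error estimate itself is, the error map can be recomputed `R = 1000`
times with fresh permutations and the per-voxel width of the 95% CI of
the error reported (`error_map_ci()`).

The method's core assumption is that the residuals at different phases are
exchangeable — valid when they are dominated by independent noise in
independently reconstructed phase images, and increasingly doubtful when
structured artifacts or model misspecification dominate.  Because a
permutation preserves the per-voxel mean, every synthetic series has
exactly the original $a_0$; all replicate variation enters through the
first harmonic.  A useful consequence of removing three real degrees of
freedom (bins 0 and 1) from $N = 20$ samples is that permuted residuals
carry slightly less first-harmonic power than fresh noise —
$\sqrt{(N-3)/(N-1)} \approx 0.95$ — so the bootstrap error is expected to
sit a few percent below the fresh-noise truth, comfortably inside the 15%
calibration band the validation suite enforces.

### Choices the procedure leaves open

* **Shuffle scope** — nothing in the procedure dictates whether each voxel
  gets its own permutation or one permutation is shared by the whole
  image.  The default is per-voxel (independent exchangeability is the
  stated assumption); `shuffle_mode = "shared"` is available and preserves
  spatial noise correlation.
* **Sampling** — "shuffling" is permutation without replacement (the
  default, multiset-preserving); classical resampling with replacement is
  available via `sampling = "with-replacement"`, in which case the DC term
  is perturbed too and the reference level of the perfusion normalisation
  is recomputed per replicate.
* **SD degrees of freedom** — sample SD (`sd_ddof = 1`) by default;
  immaterial at `B = 2000`.
* **Engine** — the fit is linear, so adding shuffled residuals to the
  model shifts the coefficients by exactly the residuals' DFT; the default
  engine updates $(a_0, C_1)$ per replicate and accumulates mean/SD in
  streaming form (Welford) without storing the stack.  A reference engine
  that materialises each synthetic series and refits is kept and tested to
  agree to float tolerance.
* **Sub-seeding** — every replicate, simulated scan and CI recomputation
  gets its own seed derived from the master seed (`derive_seeds()`); the
  shuffle kernel expands each sub-seed with splitmix64 into xoshiro256++
  state, making draws reproducible and platform-independent.

### Conventions fixed by the implementation

* Ventilation uses the signed real part of $C_1$; a magnitude mode exists
  for data whose expiration alignment is unknown.  Values are not clamped
  to $[0,1]$ — implausible values are diagnostic.  Voxels with
  $S_\mathrm{exp}\le 0$ are masked invalid rather than zeroed.
* Perfusion amplitude normalises by the ROI's *DC* level, reading the
  blood-filled ROI as the 100%-blood signal reference; normalising by the
  ROI's harmonic amplitude is a config option.  The published magnitude
  (~0.028) does not disambiguate the two.
* Timing wraps into $[-T_{RR}/2, T_{RR}/2)$, half-open at the positive
  end; a tie at exactly $\pi$ maps to $-\pi$.  Positive timing = voxel
  peak later than the reference.  The sign convention is declared, not
  derivable from published summaries.
* The reference phase is the argument of the ROI's complex mean (robust to
  wrapping inside the ROI); it is rejected as undefined when the ROI
  harmonics cancel or are at numerical-noise level relative to the ROI DC
  signal.

## The digital phantom

`make_phantom()` builds a 2D coronal slice: two half-elliptical lungs and
a small circular aorta ROI inside a body ellipse, with smooth random
ground-truth fields.  Defaults are calibrated to healthy-volunteer
magnitudes: median ventilation 0.22 mL/mL and median perfusion amplitude
0.028 over the lung; DC levels 40 (lung), 100 (body), 200 (blood)
arbitrary units; respiratory cycle 4000 ms (~15 breaths/min), cardiac
cycle 857 ms (~70 bpm); `noise_sigma = 2.5` (SD of one un-averaged
sample), chosen so that at six averages the median ventilation error is
on the order of 5% of the parameter — the regime reported for
well-averaged acquisitions.  The generator inverts the estimators
exactly: the respiratory modulation for target ventilation $v$ is
$m = v/(2-v)$, and the cardiac amplitude for target perfusion $p$ is
$p\,S_\mathrm{ref}$, so in the noiseless limit the full pipeline returns
the ground truth to float tolerance (a tested invariant).

Averaging is emulated by dividing the noise variance by `n_avg` rather
than storing replicates — statistically equivalent and cheaper.  Noise is
additive white Gaussian on magnitude images, the high-SNR approximation
of Rician noise and the simplest model consistent with treating noise as
the dominant independent residual source.  The phantom does *not* emulate
k-space undersampling, coil sensitivities, gating/binning errors, motion
or registration artifacts, or spatially correlated ("colored") noise —
so passing calibration tests shows the engine propagates independent
noise correctly, not that it captures artifact-dominated errors in real
data.

**Breathing depth.**  `depth_scale` is a dimensionless multiplier of the
phantom's nominal fractional lung-area change (`depth_nominal = 0.243`);
`depth_scale = 1` reproduces `vent_true` exactly, and the measured depth
of a simulated scan is `100 · depth_scale · depth_nominal` percent.  The
repeated-scan generator draws per-scan depth scales from a Gaussian
truncated at zero with mean 1 and relative SD 5.6/24.3, reproducing the
free-breathing study condition of measured depths 24.3% ± 5.6%.  Scans
with depths strictly outside the closed interval mean ± SD are excluded
from the gold-standard error (`select_scans()`), with the expiration
(maximal) area as the depth denominator — the published summaries do not
say whether expiration, inspiration or their mean was used.

## Validation design and problem sizes

The test suite validates the engine at these sizes, chosen to give
Monte-Carlo error well below the tolerance bands while keeping a full run
on one CPU in a couple of minutes:

* **Exhaustive oracle** — one voxel, `N = 4` (residuals reduce to the
  Nyquist pattern $(a,-a,a,-a)$): engine SD at `B = 20000` vs the SD over
  all 24 permutations, within 3%.
* **Calibration** — 64×64 phantom, `B = 2000`, `n_avg ∈ {6,3,1}`, all
  three map kinds: median bootstrap error over the lung within 15% of the
  per-voxel SD over 200 fresh noise realisations; and the 6→1 error ratio
  within 20% of $\sqrt 6$.
* **Gold standard** — ten simulated scans differing by noise only:
  single-scan median bootstrap error within 15% of the median
  repeated-scan SD, for every kind and averaging level, with error
  medians strictly increasing as averaging is reduced.  Depth-matched
  scans are used deliberately: with variable breathing depth the
  ventilation maps scale with the realised depth, so the repeated-scan SD
  contains a physiological repeatability component that a single-scan
  *statistical* error estimate cannot and should not reproduce.  The
  exclusion rule mitigates but does not remove that component; the
  variable-depth design is exercised separately by `run_experiment()`.
* **Reproducibility CI** — 32×32 phantom, `R = 100`: CI widths finite on
  the lung and the median width halving (±0.1) when `B` goes 500 → 2000.

Summary metrics use Tukey-hinge quartiles (medians of the sorted halves,
the overall median belonging to both halves for odd n).  This is the one
common convention that simultaneously reproduces all three published
precision-of-the-median values from the corresponding published per-scan
medians; linear-interpolation quantile rules do not.  Report rounding
follows the published table granularity (three decimals for ventilation
and perfusion amplitude, integer ms for timing medians, two decimals for
timing IQRs; half away from zero); computation is always full precision.

## Known limitations

* White-noise residuals only: artifact- or motion-dominated residuals
  violate exchangeability, and the error maps then measure the wrong
  thing (this is a property of the method, not only of the phantom).
* Only the first harmonic is modelled by default (`n_harmonics` is a
  config option); a richer pulse-wave shape in large vessels leaks into
  the residuals and inflates apparent perfusion errors there.
* No image registration is implemented; repeated real scans must be
  registered upstream, and phantom scans are aligned by construction.
* Timing is undefined where the first harmonic vanishes; such voxels are
  flagged by the map mask but their values are numerically arbitrary.
* The ventilation denominator makes errors blow up where
  $S_\mathrm{exp}\to 0$ (e.g. background); summaries should always be
  taken over a lung mask.
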