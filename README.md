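# lungboot

Voxel-wise statistical error maps for quantitative functional lung MRI,
from a single scan.

## The problem

Phase-resolved ("cine") functional lung MRI reconstructs one pseudo-breath
and one pseudo-heartbeat — typically 20 respiratory and 20 cardiac phase
images — from a free-breathing, self-gated acquisition.  Per voxel, the
signal over the cycle is modelled by its temporal first Fourier harmonic,

    S(t) = a0 + |C1| · cos(2πt/N + arg C1),

where the DC term `a0` is the static tissue signal and the first harmonic
`C1` carries the functional modulation.  Three quantitative maps follow:

* **Ventilation** `V_abs = (S_exp − S_ins) / S_exp` in mL air / mL lung
  parenchyma, with `S_exp = a0 + Re C1` (expiration, signal maximum) and
  `S_ins = a0 − Re C1`;
* **Perfusion amplitude** `|C1| / S_ref`, normalised to a blood-filled
  reference ROI in the descending aorta (dimensionless);
* **Perfusion timing** `wrap(arg C1 − φ_ref) / 2π · T_RR` in ms, the
  first-harmonic phase shift of each voxel against the aorta reference.

These maps come from a *single* reconstruction, so the classical
repeated-measurement estimate of their per-voxel error is unavailable in
routine use.  `lungboot` estimates it anyway, by **bootstrapping the model
residuals**: the deviations of the data from the first-harmonic model are
randomly permuted along the phase axis, added back to the model, and the
maps recomputed — 2000 times by default.  The per-voxel standard deviation
over the replicate stack is the error map.  The per-voxel width of the 95%
CI of that error over repeated recomputations (1000 by default) quantifies
the reproducibility of the error estimate itself.

For validation without access to raw scanner data, the package ships a
digital cine phantom with known ground-truth fields, a simulated
repeated-scan design with variable breathing depth, the repeated-scan
gold-standard error (per-voxel SD across scans) with a mean ± SD
breathing-depth exclusion rule, and the summary metrics used in
repeatability studies (lung medians and Tukey-hinge IQRs, cumulative error
distributions, precision and accuracy of the median error).

## Worked example

```r
library(lungboot)
ph   <- make_phantom(c(64, 64), seed = 1)       # ground truth known
rs   <- simulate_cine(ph, "respiratory", n_avg = 6, seed = 2)
card <- simulate_cine(ph, "cardiac",     n_avg = 6, seed = 3)

vent <- ventilation_map(fit_first_harmonic(rs))
amp  <- perfusion_amplitude_map(fit_first_harmonic(card), ph$aorta_roi)
err  <- bootstrap_error_map(rs, "ventilation",
                            cfg = boot_config(B = 2000, seed = 4))

unlist(masked_median_iqr(vent, ph$lung_mask))
#>     median        iqr
#> 0.21605761 0.07169011
unlist(masked_median_iqr(amp, ph$lung_mask))
#>      median         iqr
#> 0.028240952 0.004999104
unlist(masked_median_iqr(err, ph$lung_mask))
#>      median         iqr
#> 0.011790579 0.003020314
```

The measured lung medians (ventilation 0.216 mL/mL, perfusion amplitude
0.0282) recover the phantom's calibrated ground truth (0.22 and 0.028)
from noisy data at six averages, and the bootstrap error map reports a
median single-scan ventilation uncertainty of 0.012 mL/mL — about 5% of
the parameter value, the regime expected for a well-averaged acquisition.
`run_experiment()` wraps the full repeated-scan study (maps, error maps,
breathing-depth exclusion, gold-standard error, precision/accuracy) in one
deterministic call, and `exec/lungboot` exposes `simulate`, `maps`,
`bootstrap`, `gse` and `experiment` subcommands with NIfTI input/output
for shell use.

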