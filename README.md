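# dephasr

Slice-profile aware modeling and correction of through-slice signal
dephasing in 2D spoiled multi-gradient-echo (mGRE) MRI, for quantitative
R2\* and myelin-water-fraction (MWF) mapping.

## The problem

In 2D mGRE relaxometry the slice is much thicker than the in-plane voxel,
so macroscopic field perturbations dephase spins *across the slice* and the
measured decay is faster than the tissue decay: R2\* is overestimated
(severely where the through-slice field gradient G_z is strong) and the
short-T2\* myelin water signal is biased or lost. With a locally linear
field, the measured signal factorizes as

    S(t) = S0 · exp(−R2*·t) · F(t),
    F(t) = ∫ M_xy(z) · exp(i·γ·G_z·z·t) dz / ∫ M_xy(z) dz

where `M_xy(z) = |M_xy| e^{iφ_xy}` is the complex slice profile excited by
the RF pulse. dephasr computes `F(t)` from first principles — a hard-pulse
Bloch simulation of the slice profile for arbitrary pulse shapes and flip
angles — and divides it back out of the fit. Crucially, at flip angles
above ~60° the *phase* φ_xy(z) of the profile matters: it inverts with the
slice-select gradient polarity, making the decay polarity-dependent, which
magnitude-only corrections cannot capture.

Four nested signal models are provided: **S1** (no correction), **S2**
(magnitude-only profile), **S3** (complex profile), **S4** (complex profile
with per-voxel transmit-field scale ξ and slice scaling
λ = G_slice/(G_slice+G_z)), plus a T1-aware steady-state variant for short
TR. Supporting tools cover slice-gradient calibration, field-offset and
G_z maps from multi-echo phase, B1 normalization, navigator-echo phase
correction of raw k-space lines, NNLS MWF spectra with a 25 ms cutoff, and
a fully synthetic ground-truthed phantom generator.

## Worked example

```r
library(dephasr)

# calibrate the slice-select gradient for a 4 mm slice (sinc-Hanning pulse,
# 2 ms, BWT 2.7, 30 degrees), then excite at 90 degrees
pulse <- rf_sinc_hanning(t_pulse = 2e-3, bwt = 2.7)
g <- calibrate_slice_gradient(pulse, alpha = 30 * pi / 180, target_fwhm = 4e-3)
#> G_slice: 8.35 mT/m; achieved FWHM: 4.004 mm

prof <- simulate_profile(rf_scale_to_flip(pulse, pi / 2), g_slice = 8.29)
profile_fwhm(prof) * 1e3
#> 4.62  (the 90-degree slice is broader than the 30-degree calibration)

# dephasing factor for a 100 uT/m through-slice gradient, 32 echoes
te <- acquisition_te_grid()          # 4:5:159 ms
f3 <- dephasing_factor(prof, gz = 100, te = te, model = "F3")
round(Mod(f3$f[c(1, 9, 21)]), 3)     # |F| at TE = 4, 44, 104 ms
#> 0.964 0.015 0.007

# the factor is the difference between a ruined and an exact R2* fit:
y  <- 100 * exp(-20 * te) * Mod(f3$f)         # "measured" decay, true R2* = 20
fit_r2star(echo_series(te, y), "S1")$r2star   # uncorrected
#> 61.27
fit_r2star(echo_series(te, y), "S3", gz = 100, profile_source = prof)$r2star
#> 20.000
```

The uncorrected fit reads 61 s⁻¹ from a 20 s⁻¹ decay — that factor-3
inflation is exactly what strong through-slice gradients do to R2\* maps,
and what the S3/S4 models remove. `autoplot()` methods exist for profiles,
factors and MWF spectra; `tidy()`/`glance()` for fits; `fit_r2star_map()`
and `fit_mwf_map()` run voxel-wise over volumes with per-voxel (G_z, ξ)
maps; `sensitivity_sweep()` tabulates how much each model ingredient
(profile phase, B1 scale, slice scaling, T1 saturation) matters.

A full synthetic experiment — phantom generation, S4 fitting, recovery
against ground truth — runs from one config:

```r
run_pipeline(list(
  seed = 1, stages = c("phantom", "r2star"), model = "S4",
  output_dir = "out",
  phantom = list(nx = 64, ny = 64, nslices = 25, snr = 100),
  protocol = list(
    pulse = list(shape = "sinc_hanning", t_pulse = 2e-3, bwt = 2.7, dt = 2e-6),
    alpha_deg = 90, g_slice = 8.29, te_ms = seq(4, 159, by = 5))))
```

or from the shell via the thin CLI at `inst/cli/dephasr`
(`simulate-profile`, `dephasing`, `sensitivity`, `gzmap`, `b1norm`,
`navcorrect`, `fit-r2star`, `fit-mwf`, `make-phantom`, `run`).

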