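---
title: "Modeling through-slice dephasing in 2D multi-gradient-echo relaxometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling through-slice dephasing in 2D multi-gradient-echo relaxometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(dephasr)
```

## The problem

A 2D spoiled multi-gradient-echo (mGRE) acquisition samples the free
induction decay of each slice at a train of echo times. Quantities derived
from that decay — the effective transverse relaxation rate R2\* and the
myelin water fraction (MWF) from the multi-exponential part of the decay —
assume the decay reflects tissue. Macroscopic field perturbations (air/tissue
interfaces, imperfect shim) add a slowly varying field across the slice. With
slice thicknesses of 3–4 mm against in-plane voxels of ~1 mm, the dominant
corruption is *through-slice* dephasing: spins across the slice precess at
different rates, their vector sum decays faster than tissue alone, and R2\*
is overestimated — by up to an order of magnitude where the through-slice
gradient is strong — while the fast-decaying myelin water signal becomes
unrecoverable or biased.

If the field across the slice is locally linear,
$\Delta\omega(z) = \Delta\omega_0 + \gamma G_z z$, the measured signal
factorizes as

$$S(t) = S_\mathrm{tissue}(t)\, F(t), \qquad
F(t) = \frac{\int M_{xy}(z)\, e^{i\gamma G_z z t}\, dz}
            {\int M_{xy}(z)\, dz},$$

where $M_{xy}(z) = |M_{xy}(z)| e^{i\varphi_{xy}(z)}$ is the complex
transverse magnetization excited across the slice. For an ideal rectangular
slice $F$ is a sinc in $t$; for a real RF pulse at a large flip angle it is
not, and — the central point of this package — the *phase* $\varphi_{xy}(z)$
of the slice profile matters: it flips sign with the polarity of the
slice-select gradient, so the decay under $+G_z$ differs between the two
polarities, an effect invisible to magnitude-only models.

The package computes $F(t)$ numerically for arbitrary pulses and flip
angles and uses it to de-bias R2\* and MWF estimates. Four nested signal
models are exposed, mirroring increasing physical completeness:

* **S1** — no correction ($F \equiv 1$);
* **S2** — magnitude-only slice profile ($\varphi_{xy}$ dropped);
* **S3** — full complex profile at the nominal flip angle;
* **S4** — complex profile at the locally scaled flip angle $\alpha\xi$
  (transmit-field map $\xi$) with slice scaling $\lambda$;

plus a T1-aware variant **F_T1** that replaces the relaxation-free profile
with the spoiled steady-state solution.

## The Bloch slice-profile solver

`simulate_profile()` integrates the Bloch equations in the hard-pulse
approximation: the sampled RF envelope is treated as piecewise constant over
each inter-sample interval, and for every position $z$ the magnetization is
rotated about the instantaneous effective field $(B_1, 0, G_\mathrm{slice}
z)$ by the exact rotation for that interval (Rodrigues composition, midpoint
amplitude per interval — so the on-resonance rotation equals the trapezoid
flip integral exactly). Relaxation during the 1–2 ms pulse is neglected
(T1, T2 are two to three orders of magnitude longer). After the pulse a
rephasing phase ramp $e^{-i\gamma G_\mathrm{slice} z\, \kappa T_p}$ models
the rephasing gradient lobe; the default $\kappa = 0.5$ cancels the phase
accrued from the centre (isodelay point) of a symmetric pulse to its end and
produces the near-flat small-flip phase profile expected of a well-rephased
excitation. $\kappa$ is exposed because vendor lobe areas differ slightly.

Discretization defaults, chosen so that the refinement oracles in the test
suite bound the error:

| parameter | default | note |
|---|---|---|
| RF sampling `dt` | 2 µs | halving it changes the profile by < 1e-4 |
| z grid | 2501 points, 80 µm | ±10 cm; 10× refinement changes F by < 1e-4 |
| rephasing fraction | 0.5 | symmetric-pulse isodelay |
| $\gamma$ | 2.6752e8 rad s⁻¹ T⁻¹ | $\gamma/2\pi \approx 42.577$ MHz/T |

Two pulse families are built in. The sinc envelope uses
$\sin(\pi\,\mathrm{BWT}\,\tau/T_p)/(\pi\,\mathrm{BWT}\,\tau/T_p)$ with
$\tau = t - T_p/2$ under a Hanning window spanning the full duration, i.e.
BWT counts total bandwidth × duration — the convention that reproduces the
vendor gradient calibrations (8.29 mT/m → 4 mm and 11.05 mT/m → 3 mm at
BWT 2.7, 2 ms, 30°) from first principles. The truncated Gaussian is
$\exp(-(t-T_p/2)^2/(2\sigma^2))$: the standard Gaussian form, which is the
one consistent with the printed calibration 10.56 mT/m → 3 mm for
$\sigma = 280$ µs (the variant without the factor 2 in the denominator
yields a 4.3 mm slice at that gradient and can be ruled out). Slice
thickness is defined operationally as the FWHM of $|M_{xy}(z)|$, measured
by linear interpolation of the half-maximum crossings, and
`calibrate_slice_gradient()` finds the gradient for a target thickness by
bisection (the FWHM is monotone in the gradient amplitude; the search stops
at 0.2% relative, comfortably inside the 0.5% contract).

A sign convention note: transverse phase evolves as
$e^{+i\gamma B_z t}$ during excitation, in the rephasing ramp, and in the
readout kernel alike. Only this *relative* consistency is physical; it fixes
which slice-gradient polarity decays faster for a given $G_z$ sign, and the
package's "positive polarity" follows the convention in which the negative
polarity shows the larger phase-neglect error.

## Steady state and the Ernst angle

For finite TR the longitudinal magnetization saturates; with perfect
spoiling the per-position steady-state transverse magnitude is

$$|M_{xy}(z)| = \frac{\sin\alpha_\mathrm{eff}(z)\,(1-E_1)}
{1-\cos\alpha_\mathrm{eff}(z)\,E_1}, \qquad E_1 = e^{-TR/T_1},$$

applied by `steady_state_profile()` on top of a relaxation-free simulation,
with $\alpha_\mathrm{eff}(z) = \mathrm{atan2}(|M_{xy}|, M_z)$ — the rotation
angle the excitation actually delivered at $z$ (on resonance it reduces to
the nominal flip). The transverse phase is retained: saturation scales the
magnitude of each isochromat but does not rotate it. The Ernst angle is the
closed form $\alpha_E = \arccos E_1$; at $TR/T_1 = 2$ this gives 82.2°. (A
value of 77° is sometimes quoted for that ratio; it is inconsistent with
the closed form, which this package follows.)

## Transmit field and slice scaling

Local transmit (B1+) variation scales the flip angle, $\alpha \to
\alpha\xi$, with $\xi$ from a normalized B1 map. Because the slice profile
is needed per voxel, `xi_profile_grid()` simulates profiles on a coarse
$\Delta\xi = 0.05$ grid and interpolates the complex profiles linearly to a
0.005 refinement — the standard acceleration for voxel-wise evaluation; the
interpolation error against a direct simulation is below 1e-3 in the
profile and far below that in $F$.

The background gradient also superimposes on the slice-select gradient
during excitation, scaling the excited slice by
$\lambda = G_\mathrm{slice}/(G_\mathrm{slice}+G_z)$ (signed). Scaling the
sampling coordinates by $\lambda$ is, after substitution, exactly
equivalent to evaluating the unscaled factor at $t/\lambda$, and the
implementation uses that closed form — no interpolation enters, and the
$\lambda \to 1$ limit is exact. Voxels where $G_\mathrm{slice} + G_z
\approx 0$ are singular (the slice collapses); they are flagged and masked
rather than fit.

## Dephasing factors and the sensitivity analysis

`dephasing_factor()` evaluates the normalized integral above by trapezoidal
quadrature on the simulated profile support (±10 cm, far wider than the
slice; truncation and quadrature error are bounded by the 10× refinement
oracle at < 1e-4). $F(0) = 1$ by construction, so $S_0$ in the fit absorbs
the profile integral and the models S1–S4 are nested. The centre-frequency
offset $\Delta\omega_0$ contributes a global phase only and is tracked as
metadata; all fitting uses $|F|$.

`sensitivity_sweep()` quantifies how much each model ingredient matters as
the RMS difference (in percent) between two factors over a common time
grid. The package's comparison grid is 1–200 ms in 1 ms steps: a dense grid
covering the full decay and rebound structure of $F$ at the simulated
gradient strengths (at $G_z = 100$ µT/m and a 4 mm slice the first null of
$F$ falls near 45 ms and the factor keeps oscillating well past 150 ms).
The sweeps cover the flip-angle dependence of phase neglect (per polarity),
the transmit-scale dependence ($\xi$ from 0.6 to 1.4), the slice scaling
(both as a free $\lambda$ sweep from 0.8 to 1.2 and as the physically
reachable $\lambda(G_z)$ against $\lambda = 1$), and T1 neglect over
$TR/T_1$ with the flip angle tied to the Ernst angle. A caveat recorded
here deliberately: under this construction the transmit-scale panel — with
the $\xi$-profiles re-simulated at $\alpha\xi$ exactly as documented above
— produces RMS errors about 2.5× larger than some published figures for
the same nominal settings, while its internal structure (the 90° error
being 3× the 60° error, and the 30° error staying below about 0.75%)
is reproduced; the other panels agree closely. The acceptance suite states
these values as computed.

## Field-map inputs

The per-voxel inputs are standard and kept deliberately simple:

* `fit_delta_omega0()` — per-voxel OLS slope of the (temporally unwrapped)
  phase over the first 6 echoes, in rad/s; a two-echo variant
  $(\varphi_3-\varphi_1)/(TE_3-TE_1)$ is provided for protocols that prefer
  it. The 6-echo fit is the default; the choice is protocol-dependent and
  both are exposed. Spatial unwrapping is out of scope — inputs are
  declared spatially unwrapped and only ±2π jumps along echoes are removed.
* `gz_map_from_fieldmap()` — central difference along the slice axis
  (single-sided at the stack ends), converted by $\gamma$ to µT/m. Field
  maps are carried in rad/s internally so unit ambiguity cannot propagate.
* `normalize_b1()` — ratio to nominal, clipped to the simulated
  $\xi$-grid range with a logged count.
* `navigator_correct()` — each phase-encoding line is multiplied by
  $e^{-i(\varphi_n-\varphi_1)\,TE/TE_\mathrm{navi}}$ per channel and echo;
  the navigator phase is the angle of the complex sum over the central 25%
  of the navigator readout. The correction is an isometry per line and
  forms a group under composition, which the tests assert.

## Fitting

R2\* fitting minimizes $\sum_t (S(t) - S_0 e^{-R_2^* t} |F(t)|)^2$. Since
$S_0$ enters linearly it is profiled out analytically and the residual is
minimized over $R_2^* \in [0, 2000]$ s⁻¹ by Brent search (variable
projection — the same minimizer as a joint two-parameter nonlinear
least-squares, without derivatives), seeded by a log-linear fit of the
first six echoes. Ties on flat residual landscapes resolve toward smaller
R2\* through the bound snap at zero; fits ending on a bound are flagged.
Voxel-wise mapping evaluates $|F|$ from a complex lookup table over the
$(\xi, G_z)$ plane — linear in $\xi$ over the 0.05 nodes (identical to
interpolating the profile, since $F$ is linear in $M_{xy}$) and linear in
$G_z$ over 5 µT/m nodes, where $|F|$ is smooth to ~1e-4. The phantom
forward model uses the same engine, so forward–inverse consistency is exact
by construction and the engine itself is validated independently by the
quadrature oracles.

MWF fitting expands the F-corrected magnitude decay $S(t)/|F(t)|$ onto
$M = 200$ decaying exponentials, log-spaced in $T_2^*$ from 1.5 to 300 ms,
by unregularized nonnegative least squares; the MWF is the spectral weight
below the 25 ms cutoff. Division by $|F|$ near its nulls amplifies noise
without bound, so echoes with $|F| < 0.05$ are excluded (and counted); if
fewer than three echoes survive the voxel is flagged rather than fit.
Magnitude (not complex) signal is divided by $|F|$ — with magnitude-only
inputs the global phase is gone anyway, and the choice is recorded here
because it is not forced by the model.

Two regimes are worth knowing about, and the tests pin both: at
white-matter-like gradients (10–60 µT/m) the *uncorrected* MWF is biased
low — the slow extra decay of $|F|$ masquerades as less short-$T_2^*$
signal — while beyond roughly 80 µT/m (90° flip, 27 echoes to 60 ms) the
uncorrected spectrum collapses to nonsense because the measured decay dies
at the first null of $F$. The corrected fit recovers the true fraction in
both regimes.

## The synthetic phantom

`phantom_spec()` + `forward_signal()` generate fully synthetic,
ground-truthed volumes so every stage is testable without data downloads.
The default emulates a cylindrical gel phantom in a 64×64×25 matrix at 4 mm
slice spacing — small enough that the full end-to-end recovery runs in a
few minutes on one CPU — with:

* a smooth radial R2\* distribution, 15–45 s⁻¹;
* a through-slice gradient built from a 0→60 µT/m ramp across slices plus
  a narrow in-plane hotspot peaking near 300 µT/m, so the volume-wide
  gradient statistics (mean |G_z| ≈ 40 µT/m with localized extremes) match
  what 3 T field maps of brain and phantom show, rather than making extreme
  gradients volume-filling;
* a smooth bowl-shaped transmit field spanning ≈ 0.7–1.3;
* Rician magnitude noise (the correct statistics for coil-combined
  magnitude data), with SNR defined at the first echo on the noise-free
  foreground mean, default 100; the generator seed is recorded in the spec
  and output manifest.

What the phantom does *not* emulate — and what passing tests therefore do
not establish about real data: anatomy and susceptibility source geometry
(the field maps are smooth by construction, so field-map estimation error
is not stressed), coil sensitivities and combination, in-plane dephasing,
flow/motion, and imperfect spoiling. `forward_kspace_with_drift()`
additionally produces line-by-line k-space with a per-line phase drift and
matching navigator phases — the exact inverse scenario of the navigator
correction — for testing the k-space path.

## Reproducibility surface

`run_pipeline()` executes phantom generation, field-map derivation, and
R2\*/MWF fitting from a single validated YAML config (unknown keys are
rejected by name before any compute); outputs are NIfTI volumes written
uncompressed so reruns are byte-identical, each with a provenance JSON
carrying the config hash and seed. The `inst/cli/dephasr` script is a thin
Rscript wrapper exposing the same operations as subcommands. The
`scripts/acceptance.R` script recomputes the headline simulation quantities
(gradient calibrations and sensitivity RMSEs) from scratch against the
installed package.

## Known limitations

Linear through-slice fields only (a quadratic model would slot into the
same quadrature but is not implemented); no imperfect-spoiling or
diffusion simulation; no in-plane voxel-spread correction; no z-shim
moment modeling; spatial phase unwrapping is upstream; adiabatic/SLR/
multiband pulses are out of scope. The transmit-scale sensitivity caveat
above stands: the package reports what its documented construction
computes.
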