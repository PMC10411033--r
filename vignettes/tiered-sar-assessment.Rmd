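---
title: "Tiered SAR safety assessment: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered SAR safety assessment: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilsafe)
```

## The model

Local 10-g-averaged SAR cannot be measured during an in vivo examination;
it is estimated from electromagnetic simulations of the coil array on human
body models, scaled by the monitored input power. The estimate carries
three uncorrelated relative uncertainties: the **modeling uncertainty**
(how well the simulation reproduces phantom measurements), **intersubject
variation** (the scanned subject is never the simulated model), and the
**power-monitoring uncertainty** of the directional couplers. Writing each
as a fraction $u_i$, uncorrelated errors propagate in quadrature,

$$u_\text{total} = \sqrt{u_\text{model}^2 + u_\text{inter}^2 + u_\text{power}^2},
\qquad \text{SF} = 1 + u_\text{total},$$

and the simulated peak SAR is inflated to
$\mathrm{pSAR}_\text{corr} = \mathrm{pSAR}_\text{sim}\cdot\text{SF}$
before power limits are derived:
$P_\text{total} = \mathrm{SAR}_\text{limit}/\mathrm{pSAR}_\text{corr}\cdot
P_\text{ref}$, divided equally over channels. The alternative,
multiplying per-source factors $\prod_i(1+u_i)$, ignores the stochastic
independence of the sources and is always at least as conservative
(`multiplicative_safety_factor()` reports it alongside for comparison;
the inequality is property-tested over 10^4 random budgets).

Three validation tiers trade effort against conservatism:

* **tier 1** — no simulation. All RF power is assumed dissipated in one
  10-g averaging mass: at $n$ channels and 1 W/channel the implied SAR is
  $n/0.010$ W/kg, so the admissible total power is
  $\mathrm{SAR}_\text{limit}\times 0.010\ \mathrm{kg}$ (0.2 W at the
  20 W/kg first-level-controlled limit). No safety factor applies.
* **tier 2** — simulation validated by B1+ maps only. Because the
  controlled quantity (SAR/temperature) is not itself validated, the
  safety factor is multiplied by a **buffer** (default 2; deliberately a
  site/regulatory configuration, not a constant).
* **tier 3** — validated by B1+ maps *and* thermometry-derived SAR maps;
  the worst case over all shims and both modalities becomes the modeling
  uncertainty, and no buffer applies. A budget whose modeling term comes
  from B1 alone is refused at tier 3.

## The modeling-uncertainty statistic

Measured and simulated maps are compared voxel-wise after resampling the
simulation to the (coarser) measurement grid, normalizing by the simulated
in-mask **peak** — peak SAR sets the operating limits, so errors are
expressed relative to the quantity that matters:

$$\mathrm{SAR}_\text{diff}(x) =
\frac{\mathrm{SAR}_\text{meas}(x) - \mathrm{SAR}_\text{sim}(x)}
     {\max_x \mathrm{SAR}_\text{sim}},$$

with the squared-magnitude analogue for B1+ (SAR is quadratic in B1; the
linear convention is retained for magnitude-difference figures). The
modeling uncertainty is the **positive error not exceeded in 99.9% of
voxels** — the nearest-rank quantile (value at index
$\lceil 0.999N \rceil$ of the ascending sort). The maximum over voxels is
deliberately not used: the far tail is under-sampled and contaminated by
edge artifacts (which is also why masks can be eroded by a configurable
depth before comparison).

Numerical choices, made once:

* **Quantile estimator**: nearest rank, no interpolation (type 1 in R's
  `quantile()`), verified in the tests against an independent sort-and-index
  oracle. Reproducible integer-rank semantics; no estimator was named in
  the original description of the statistic.
* **Negative quantiles** (simulation over-predicts everywhere) clamp to 0
  in the budget — a negative "uncertainty" would shrink the RSS below the
  other terms — while the raw signed value is kept as an attribute and in
  reports.
* **Pooling**: one quantile per shim-and-modality comparison, then the
  maximum over comparisons (`worst_case_uncertainty()`), matching per-shim
  validation practice; not a single pooled quantile across shims.

## Thermometry

Early-phase RF heating is linear: $T(x,t) = T_0 + \mathrm{SAR}(x)\,t/C_p$
while conduction is negligible, so the per-voxel ordinary-least-squares
slope over the first minute, times $C_p$ (4000 J/(kg·K) for a PVP
phantom), recovers SAR. The OLS slope rather than a two-point $\Delta T$
is used — robust to frame noise and identical for noiseless data. Each
frame is first smoothed with a mask-aware 3×3 Gaussian kernel
(σ = 0.8 voxels, a standard choice for a 3×3 support; the support size is
stated practice, the σ is this package's recorded default). Mask-aware
means the kernel is renormalized over in-mask neighbors, so phantom-edge
voxels are not dragged toward the background; whether the original
processing was mask-aware at edges is unknown, so this choice is flagged
in reports. `linearity_check()` returns the per-voxel $R^2$ to verify the
window sits in the linear regime; its null distribution for pure noise
(Beta(1/2, (n−2)/2)) is used as a test oracle. The fit window defaults to
the first 60 s from the first frame, with time 0 taken as RF-on; the
offset is configurable because acquisition conventions differ.

## Intersubject variation

pSAR samples over body models and RF shims are fitted with a
two-parameter gamma distribution (location 0): maximum likelihood via
Newton iteration on the shape profile likelihood, Minka's closed-form
initialisation, with method-of-moments as fallback and a flag when the two
disagree by more than 5%. The intersubject variation is
$\mathrm{pSAR}_{99}/\overline{\mathrm{pSAR}} - 1$, where
$\mathrm{pSAR}_{99}$ is the fitted 0.999 quantile and the mean is the
**sample** mean (both means are reported). For small model databases the
conservative $\max/\min - 1$ estimator is provided instead; note that on
a printed four-model example (2.6, 3.0, 2.4, 2.8 W/kg) this definition
gives 25% where 27% was reported from unrounded values — the formula was
never printed, so `max/min − 1` is this package's documented definition
and 27% is treated as a budget input, not a computable check.

## Rounding modes

Published worked examples carry report precision through the arithmetic
(safety factor and corrected pSAR rounded to one decimal before being used
downstream: 2.3 × 1.8 × 2 = 8.3 W/kg, then 20/8.3 × 8 ≈ 19.3 W).
`rounding_mode = "paper"` reproduces exactly this chain;
`"full_precision"` carries doubles end to end. Both chains are always
computed and stored in the assessment audit trail, and the suite checks
they never differ by more than 5% on the reference scenarios. The
transmit-chain efficiency factor on the reference power defaults to 1.0
(no number is available for the losses it would model) and is exposed as
configuration.

## The synthetic world

The generators emulate the statistical structure the pipeline assumes, not
the physics. `synth_channel_fields()` places n channels around an
elliptical phantom; each contributes a complex field with exponential
magnitude decay into the phantom and a smooth propagation phase — a
geometric surrogate, not an EM solution. Shims combine channels coherently
(`combine_shim()`), so superposition, √power scaling and global-phase
invariance hold by construction and are tested. "Measurements" are the
simulation times (1 + scale error) plus a correlated Gaussian random field
(white noise Gaussian-smoothed to the stated correlation length, rescaled
to unit in-mask variance) with σ relative to the in-mask peak — the
simplest controllable correlated-noise model. Heating curves are linear
ramps SAR/C_p·t plus i.i.d. frame noise, with an optional saturation time
constant for testing window selection. pSAR populations are i.i.d. gamma
draws (defaults shape 4, scale 0.575: mean 2.3 W/kg, mimicking a published
prostate-shim population).

What a green test does **not** establish: agreement with real scanner
data. The surrogate fields have no standing-wave structure, no coupling
between channels, no registration error, no B0 drift in the thermometry,
and the noise model is stationary. The tests establish that the
*statistics* — quantiles, fits, propagation, limits — do what they claim
on data whose ground truth is known.

One metric required a definition the sources leave open: "thermometry
recovers a synthetic SAR map within 10% RMS" is asserted as RMSE divided
by the in-mask **peak** SAR, consistent with the peak normalization used
by every difference map in the package. Voxel-wise relative error is not
achievable at low SAR (the OLS noise floor
$C_p\,\sigma_\text{eff}/\sqrt{S_{tt}} \approx 1.2$ W/kg at σ_T = 0.05 K
with 13 frames over 60 s dwarfs a 2 W/kg voxel), and smoothing is part of
the asserted pipeline because the reference workflow smooths frames before
fitting.

## Degenerate inputs and tie-breaks

* NaN voxels are masked at read time and never enter statistics.
* A SAR/B1 map with negative in-mask values is rejected at construction;
  thermometry *fits* may produce small negatives in unheated voxels and
  are exempt (screen with `linearity_check()`).
* Erosion treats out-of-grid voxels as background; depth 0 is the
  identity; an empty result is allowed.
* Block-average resampling requires integer factors dividing the grid;
  anything else falls back to linear interpolation at target voxel
  centers with border clamping. Upsampling is refused outright.
* Quantile ties break by sort stability (nearest rank on the sorted
  vector).
* `fit_gamma()` rejects fewer than 10 samples, non-positive samples and
  zero-variance samples; non-convergence raises an error carrying the
  last iterate and gradient.
* Phase-offset grid search takes the first maximizer on the grid; offsets
  are reported modulo 360°.

## Phase alignment objective

Matching simulated to measured per-channel transmit phases uses a grid
search over a constant offset. The similarity objective defaults to the
mean cosine of the wrapped phase difference — continuous across the ±180°
branch cut and maximized exactly at the circular mean offset. A global
structural-similarity (SSIM) objective is available as an option, but SSIM
on wrapped phase maps is discontinuous at the branch cut, and published
descriptions of this step are ambiguous about even the sign of the
objective ("until the structural similarity was minimal"); the package
therefore treats the objective as configuration and documents the default.

## Known limitations

* No image registration: maps are assumed pre-registered; resampling is a
  pure grid reduction (voxel-centered, shared field-of-view origin).
* No VOP compression, S-parameter co-simulation, or EM solving — inputs
  are exported field/SAR maps and pSAR tables.
* The NIfTI-1 reader/writer is minimal: little-endian single-file
  volumes, common scalar datatypes, `scl_slope`/`scl_inter` honoured;
  no orientation handling beyond voxel spacing (registration is out of
  scope anyway).
* Tier-2 buffer and SAR limits are configuration, not physics; the
  defaults (2 and 20 W/kg) mirror common practice for
  first-level-controlled head/trunk imaging.
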