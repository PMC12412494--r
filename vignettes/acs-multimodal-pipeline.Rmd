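---
title: "Multimodal compartment-syndrome monitoring: models, defaults and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal compartment-syndrome monitoring: models, defaults and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsprobe)
```

## The problem

Acute compartment syndrome arises when pressure inside a closed osteofascial
muscle compartment rises high enough to throttle perfusion. The established
surgical criterion works on the perfusion pressure differential
ΔP = DBP − ICP (diastolic blood pressure minus intracompartmental pressure):
when ΔP stays below 30 mmHg for more than two hours, fasciotomy is indicated.
Pressure alone is a noisy proxy for ischemia, so the probe modeled here
measures three co-located quantities — ICP, tissue oxygen saturation (StO₂)
and local blood flow — and this package implements the computation from raw
sensor streams to those physiological quantities and the decision rule.

Because no deposited recordings exist for this device, the package ships a
first-class synthetic episode generator that emulates the in-vivo validation
protocol (a balloon catheter stepping compartment pressure 0 → 50 → 100 →
150 mmHg with ~1 min ramps, plus a multi-hour hold), so that every inversion
stage can be checked against exact ground truth.

## Thermal-anemometry flow model

The flow sensor is a resistive heater with four NTC thermistors at
increasing distances. The steady temperature excess at distance $r$ is

$$\Delta T(r) = \frac{qR/\lambda}{1 + 0.76\, s\, u R/\alpha_{fluid}}\; F(r/R),
\qquad
F(\rho) = \int_0^\infty J_0(\gamma \rho R)\, J_1(\gamma R)\,
\frac{d\gamma}{\gamma}.$$

**Grouping of the model.** The source formula is typeset with the fraction
collapsed, leaving the grouping of the printed tokens ambiguous. The grouping
above is the only one that is (a) strictly decreasing in $u$ — physically
required, since convection can only cool the probe — and (b) reduces to the
pure-conduction solution $(qR/\lambda)F(r/R)$ at $u = 0$. The grouping is
isolated in one internal function so it can be swapped if the upstream
derivation is reconciled differently.

**Shape-factor numerics.** $F$ is an oscillatory Hankel-type integral. The
default path integrates between consecutive zeros of the Bessel factors with
12-point Gauss–Legendre panels and sums the strictly alternating segment
series with repeated-averaging (Euler-type) acceleration. Three regimes are
distinguished by $\rho = r/R$:

* $\rho \le 0.5$ — segments paced by $J_1$ zeros; $J_0(\rho x)$ is a smooth
  slow modulation and acceleration converges geometrically.
* $\rho \ge 2$ — symmetric, paced by the zeros of $J_0(\rho x)$.
* $0.5 < \rho < 2$ — the two frequencies beat at $|1-\rho|$, which defeats
  naive acceleration. The integral is summed exactly on $[0, X]$ with
  $X = \min(\max(1500,\, 40/|1-\rho|),\, 4\cdot10^4)$ and the tail is added
  analytically from the leading large-argument asymptotics of the product,
  which reduces to two single-frequency integrals
  $\int_X^\infty \sin(ax)/x^2\,dx$ and $\int_X^\infty \cos(bx)/x^2\,dx$
  evaluated by the same panel-plus-acceleration machinery. The neglected
  $O(x^{-3})$ asymptotic corrections are oscillatory with the same
  frequencies; with the $X$ rule above their contribution is bounded well
  below the $10^{-8}$ absolute target for every $\rho$.

$F$ also has an exact closed form via the Weber–Schafheitlin integral:
$F = \tfrac{2}{\pi}E(\rho^2)$ for $\rho \le 1$ and
$F = \tfrac{2\rho}{\pi}\left[E(1/\rho^2) - (1-1/\rho^2)K(1/\rho^2)\right]$
for $\rho > 1$, with $K, E$ complete elliptic integrals computed by the
arithmetic–geometric mean. This is deliberately implemented as a *second
method* (`method = "elliptic"`), not the default: the tests compare the two
routes pointwise (agreement ~$10^{-9}$) and additionally compare the default
route against a brute-force fine-grid trapezoid oracle that shares no code
with either.

**Inversion.** The residual sum of squares over the four channels is linear
in $g = 1/(1 + 0.76 s u R/\alpha)$, so the bounded least-squares problem in
$u \ge 0$ has a closed-form optimum; `invert_flow()` uses it to bracket
`stats::optimize` (the contracted path) and `invert_flow_series()` applies
the closed form vectorised over long traces. $g^* \ge 1$ maps to $u = 0$;
$g^*$ at or below the value at `u_max` is flagged as a boundary solution.
The first 60 s after heater switch-on are treated as thermal equilibration
and excluded from inversion by default.

**Default constants** (all configurable; none are published for the deployed
device, so outputs are documented as relative flow trends):

| parameter | default | rationale |
|---|---|---|
| `q_heat` | 870 W/m² | ~11 mW (1 kΩ heater at 3.3 V) over a 2 mm-radius spreader |
| `big_r` | 2 mm | spreader on a 3–4 mm-wide probe |
| `k_tissue` | 0.5 W/(m·K) | skeletal muscle literature value |
| `alpha_fluid` | 1.35·10⁻⁷ m²/s | thermal diffusivity of blood |
| `s_blood` | 0.05 | resting muscle blood volume fraction |
| `r_list` | 0.5, 6.5, 7.25, 8 mm | thermistor offsets 16/22.5/23.25/24 mm from the oximeter with the heater behind the first; the first distance floored at 0.5 mm to stay out of the $r \to 0$ near field |

With these values ΔT at zero flow is ≈3.9 K at the nearest thermistor and
≈0.5 K at the farthest, and flow in the physiological 0–20 mm/s range
modulates ΔT by factors of 1–10 — consistent with a few-Kelvin bench
response.

## Oximetry model

Optical densities $OD(\lambda,t) = -\ln(I_t/I_0)$ are computed per
wavelength with $I_0$ estimated as the per-channel mean over the first 30 s
(the source defines no reference window; the episode's initial zero-pressure
plateau makes this exact in simulation). The signal is split at 0.1 Hz into
DC and AC with a zero-phase 4th-order Butterworth filter, and the *DC branch*
feeds the inversion — the stated purpose of the low-pass step is to remove
the cardiac AC component before computing concentration changes; this choice
is flagged as an open reconciliation point. The 2×2 modified Beer–Lambert
system is then solved exactly, and

$$StO_2(t) = \frac{HbO_{2,0} + \Delta HbO_2(t)}
{HbO_{2,0} + \Delta HbO_2(t) + Hb_0 + \Delta Hb(t)}$$

clamped to $[0,1]$, with the baseline pools splitting total hemoglobin
(150 g/L ÷ 64 500 g/mol) by a nominal baseline saturation of 0.70. The
denominator's second change term is read as $\Delta Hb(t)$ (the source
prints a subscript that can only be a typo). Nonpositive intensities or
denominators are masked as `NA` rather than raised, so isolated corrupt
samples propagate as missing data.

Defaults: extinction coefficients from the standard tabulated hemoglobin
compilation (Prahl/OMLC) at 660 nm (HbO₂ 319.6, Hb 3226.56 L mol⁻¹cm⁻¹) and
880 nm (HbO₂ 1214.0, Hb 726.44); DPF = 1 per wavelength (unpublished —
affects only the scale of the concentration changes, never the sign or trend
of StO₂); LED–photodiode distance 0.25 cm (datasheet-scale geometry of the
integrated module, configurable).

**Filter realisation.** The Butterworth sections are designed by bilinear
transform as cascaded biquads; forward–backward application gives zero phase.
Initial conditions are set to the DC steady state of the first sample so a
constant passes through exactly, and the signal is padded by odd reflection
over ~12 settling lengths of the slowest pole. At the default 0.1 Hz cutoff
the filter needs roughly 60 s on *each side* of a pressure step to settle to
below $10^{-6}$; tests therefore evaluate closure on samples at least 60 s
from any ramp ("interior samples").

**Pulse metrics.** Rate comes from the dominant periodogram peak in
0.5–4 Hz with parabolic interpolation; variability is the SD of successive
peak-to-peak intervals with peak times refined by quadratic interpolation.
A peak less than 20× the band's median power raises an undefined-rate
condition (`acs_no_pulse`) instead of returning a number.

## Pressure channel

`icp = gain·raw − offset − temp_coeff·(t_dev − t_ref)`. The barometer's
internal second-order compensation is out of scope; the linear coefficient
compensates residual drift only, and elastomer pressure transmission is
taken as ideal. `fit_hydrostatic()` regresses raw readings on
$\rho g h$ (converted at 133.322387415 Pa/mmHg) and returns the
gain/offset that map readings back onto the reference column.

## Decision layer

`fasciotomy_flag()` uses strict-run semantics: a single sample at or above
threshold resets the clock, and a sampling gap longer than twice the median
interval breaks a run (the source assumes continuous monitoring and does not
define dropout or excursion semantics; strictness is the conservative
reading and is what the run-length oracle in the tests implements
independently). A run qualifies when its duration is ≥ `min_duration`
(default 7200 s), and the earliest flag time is the first qualifying run's
start plus that duration.

`correlate_modalities()` defaults to plateau-mean regression: reference
plateaus are detected where the ±5 s central slope of the 5 s-smoothed
reference stays below 0.05 mmHg/s for at least 30 s, the first half of each
plateau is discarded so lagged channels settle, and OLS slope/intercept and
Pearson r are computed across the plateau means. Per-sample regression is
available (`method = "sample"`) but conflates the flow lag with the
coupling.

## The synthetic world

`episode_config()` states the simulated experiment explicitly. Defaults:
900 s at 20 Hz; plateaus 0/50/100/150 mmHg with 60 s ramps ("one minute"
per the protocol); DBP 70 mmHg; heart rate 80 bpm (anesthetised swine);
couplings −0.0015 StO₂-fraction/mmHg and −0.03 mm/s/mmHg, chosen so the
150 mmHg plateau drives StO₂ from 0.70 to ~0.475 and flow from 5 mm/s to
~0.5 mm/s — a strong but not saturating ischemic response; additive Gaussian
noise of 0.3 mmHg (pressure), 10⁻³ intensity units (PPG) and 0.01 K
(thermistors); a 2%-of-DC pulsatile sinusoid on the PPG; and a raw-pressure
artifact model (offset 5 mmHg, 0.2 mmHg/K residual coefficient, 0.5 K
sinusoidal device-temperature drift) to exercise the calibration.

The flow response is modeled as a pure transport delay (`flow_delay`,
default 15 s) followed by a first-order lag (`flow_lag_tau`, default 20 s).
The source reports only *that* flow lags pressure, attributing it to thermal
equilibration timescales, and quantifies neither constant; the two-parameter
split exists because a first-order lag alone has no sample-exact
cross-correlation lag, while a dead time does — the lag acceptance check
runs an episode with `flow_lag_tau = 0` so "the configured lag" is well
defined, and the 63.2%-at-τ property tests the first-order part separately.

What the generator does *not* emulate: arterial waveform shape beyond a
sinusoid, motion artifacts, balloon–tissue mechanics, probe drift, or any
hemodynamic feedback between flow and oxygenation beyond the static linear
couplings. A green episode-level test therefore establishes that the
*inversion chain* is correct and sign-faithful under the stated couplings —
not that the couplings themselves are physiological truth.

## Numerical choices and degenerate inputs

* Shape-factor quadrature targets ~10⁻⁸ absolute; non-finite results raise
  `acs_numerical_error` rather than returning garbage.
* Flow inversion tolerance 10⁻¹² on the optimizer; all-channel dropout is
  `acs_missing_data`; bound-hitting solutions are flagged, not silently
  clamped.
* `separate_dc` refuses traces shorter than the filter warm-up
  (`acs_length_error`); sample rate must exceed twice the cutoff.
* StO₂ and OD mask invalid samples as `NA`; the extinction matrix is
  conditioning-checked at construction.
* The simulator is bit-deterministic under a fixed seed: each forward
  model draws from its own derived seed (`seed + k`) and restores the
  caller's RNG state.
* mmHg conversions use 133.322387415 Pa/mmHg.

## Known limitations

* Absolute flow and StO₂ values inherit unpublished device constants; only
  relative trends are meaningful, matching the device's stated use.
* The thermal model is the steady-state spreader solution; heater switch-on
  transients are handled by exclusion (60 s warm-up), not modeled.
* Beer–Lambert inversion with DPF = 1 understates pathlength in scattering
  tissue; StO₂ trends are unaffected but Δ-concentration magnitudes are
  scale-ambiguous.
* The decision layer implements the ΔP rule only; no probabilistic
  decision-support model is included.
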