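# acsprobe

Signal-processing pipeline for a multimodal intracompartmental probe used to
monitor **acute compartment syndrome (ACS)** — the limb-threatening condition
in which rising pressure inside a closed osteofascial muscle compartment
chokes off perfusion. The probe measures three co-located quantities inside
the compartment: intracompartmental pressure (ICP), tissue oxygen saturation
(StO₂) and local blood flow. This package implements the full
sensor-to-physiology computation for all three channels plus the clinical
decision layer, driven by a seeded synthetic episode generator that emulates
a stepped balloon-inflation animal experiment so that every stage is testable
against known ground truth without any external data.

## What it computes

**Thermal-anemometry flow.** Four NTC thermistors (β = 3380 K, 10 kΩ) sit
downstream of a resistive heater. The steady temperature excess at distance
*r* from the heater follows

    ΔT(r) = (q R / λ) · F(r/R) / (1 + 0.76 s u R / α_fluid)

with heater flux *q*, spreader radius *R*, tissue conductivity λ, blood
diffusivity α_fluid, blood content *s* and flow velocity *u*. The shape
factor is the Hankel-type integral

    F(ρ) = ∫₀^∞ J₀(γρR) J₁(γR) dγ/γ ,

evaluated by oscillation-aware quadrature between Bessel zeros with
alternating-series acceleration (an exact closed form in complete elliptic
integrals is provided as an independent cross-check). Flow is recovered by
bounded least squares across the four ΔT channels; because absolute device
constants are unpublished, outputs are interpreted as relative flow trends.

**Reflection-mode StO₂.** Dual-wavelength (660/880 nm) PPG intensities are
converted to optical densities OD(λ,t) = −ln(I_t/I₀), split into DC and
pulsatile components with a zero-phase 0.1 Hz low-pass filter, and inverted
through the modified Beer–Lambert law

    (Δ[HbO₂], Δ[Hb])ᵀ = (1/q) · M⁻¹ · (OD(λ₁), OD(λ₂))ᵀ ,
    StO₂ = (HbO₂₀ + ΔHbO₂) / (HbO₂₀ + ΔHbO₂ + Hb₀ + ΔHb) ,

where M holds the extinction coefficients × DPF per wavelength and the
baseline pools split total hemoglobin by a nominal baseline saturation.
Pulse rate and variability come from the AC band.

**Pressure and the decision rule.** The raw barometer channel is calibrated
with gain/offset and a residual temperature coefficient (hydrostatic
water-column fitting included). The clinical output is the perfusion
pressure differential ΔP = DBP − ICP: a maximal run with **ΔP < 30 mmHg
sustained for ≥ 2 h** raises the fasciotomy flag.

## Worked example

```r
library(acsprobe)
cfg <- episode_config(seed = 42)   # 900 s at 20 Hz, plateaus 0/50/100/150 mmHg
res <- run_pipeline(config = cfg)
print(res)
```

```
<acs_pipeline_result>
  samples: 18001 at 20 Hz
  modality summaries (plateau means vs reference pressure):
 modality        slope    intercept  pearson_r n
 pressure  1.000000000 8.327075e-15  1.0000000 4
     sto2 -0.001499625 6.999756e-01 -1.0000000 4
     flow -0.029949175 4.996866e+00 -0.9999983 4
<alert_report> rule: delta_p < 30 mmHg for >= 7200 s
  no fasciotomy indication
```

Reading the numbers: the calibrated pressure tracks the reference with slope
1 across the four plateaus; StO₂ falls by 0.0015 per mmHg of ICP and flow by
0.030 mm/s per mmHg — the inverse couplings configured in the episode,
recovered through the full raw-sensor forward/inverse chain (r < 0 for both).
No fasciotomy flag is raised because this 15-minute episode cannot satisfy
the 2-hour sustained-ΔP criterion. The pulse metrics from the PPG AC band
report 80.0 bpm from 1200 detected beats, matching the configured heart
rate, and the battery model gives 88 h endurance in 1 Hz low-power mode
(370 mAh / 4.2 mA, floored) and 26.4 h at the full 20 Hz draw.

## Command line

```sh
Rscript inst/cli/acsprobe.R simulate --config cfg.json --out ep/
Rscript inst/cli/acsprobe.R process  --in ep/ --out out/
Rscript inst/cli/acsprobe.R diagnose --in out/ [--rule rule.json]
Rscript inst/cli/acsprobe.R report   --in out/
```

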