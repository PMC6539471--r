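# hpldh

Quantifying lactate dehydrogenase (LDH) activity in viable, perfused tissue
slices from hyperpolarized [1-13C]pyruvate NMR time series.

Dissolution-DNP hyperpolarization makes the conversion of
[1-13C]pyruvate to [1-13C]lactate observable in real time, but the
polarization decays with T1 and is partly consumed by every RF excitation,
so raw peak intensities are not concentrations. This package implements the
full analysis chain that turns intensity time series into enzymatic rates,
for three acquisition designs, together with synthetic-data generators that
emulate each design with known ground truth so the whole chain is testable
without any instrument data.

## What it computes

**Two-pool kinetic model** (arrested perfusion, non-selective pulses):

    dP/dt = -P/T1p                    P -> P cos(theta) at each pulse
    dL/dt = k_1st P - L/T1l           L -> L cos(theta) at each pulse

with signals sin(theta) * P, sin(theta) * L read at each excitation
(`simulate_two_pool`, exact inter-pulse propagation; `fit_two_pool`,
bounded Levenberg-Marquardt), and the closed-form amount extrapolation
A_lac = Pyr (1 - exp(-k_1st t)) (`extrapolate_amount`).

**Selective-excitation chain** (arrested or continuous flow): precursor T1
from the pulsed decay M(t) = M0 exp(-t/T1) cos^(t/TR)(theta)
(`fit_t1_eq1`); decay correction by division with that envelope
(`correct_precursor_eq2`); constant-concentration window as the contiguous
points within 10% of the first maximum of the corrected series
(`select_constant_window`); and per-excitation rates

    v = (S_lac / S_pyr) * rho * [Pyr] V_medium / (TR * n_ATP)    [per min]

(`rate_eq3`, `aggregate_rates`), where rho — the precursor/product response
ratio of the selective pulse — comes from a Bloch simulation of the shaped
pulse (`simulate_pulse`, `response_ratio`) or from a measured scalar.

**Support**: 31P gamma-ATP quantification against an external standard with
Ernst-formula saturation correction (`saturation_factor`, `quantify_atp`),
per-mass conversion at 0.86 umole ATP/g tissue (`per_mass_rate`), and dDNP
detectability arithmetic (`signal_equivalence`). `run_pipeline()` executes
the design-appropriate chain from a config list or YAML file.

## Worked example

```r
library(hpldh)

truth  <- kinetic_params(k_1st = 1.55e-4, T1_precursor = 64.5,
                         T1_product = 20.0, M0 = 1)
scheme <- acquisition_scheme(TR = 5, nutation_precursor = 12, n_samples = 66)
fit <- fit_two_pool(simulate_two_pool(truth, scheme), scheme)
fit
#> <kinetic_fit_result> (sequential fit)
#>   k_1st        = 0.000155 1/s
#>   T1 precursor = 64.5 s   (R2 = 1.0000)
#>   T1 product   = 20 s   (R2 = 1.0000)
#>   M0           = 1 a.u.
```

The fitted rate constant feeds the downstream arithmetic. At the
study-average k = 1.67e-4 /s with 7000 nmole of probe-visible pyruvate
(14 mM in 0.5 mL):

```r
amount <- extrapolate_amount(1.67e-4, 14 * 0.5 * 1000, 60)  # 69.79 nmole
amount / 11.4                  # 6.12 nmole/min per nmole tissue ATP
per_mass_rate(6.1)             # 5.246 umole lactate / g tissue / min
signal_equivalence(5.2)        # 52 M signal-equivalent after dDNP enhancement
```

i.e. about 0.07 umole of lactate per minute, ~6.1 nmole/min/nmole ATP, an
LDH activity of ~5.2 umole/g/min, whose concentration-equivalent signal
after 10,000-fold enhancement is that of a 52 M solution — the basis for
arguing such production is detectable in vivo.

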