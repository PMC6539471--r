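---
title: "Quantifying LDH activity from hyperpolarized [1-13C]pyruvate time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LDH activity from hyperpolarized [1-13C]pyruvate time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpldh)
```

# The measurement

Dissolution dynamic nuclear polarization (dDNP) boosts the \(^{13}\)C NMR
signal of [1-\(^{13}\)C]pyruvate roughly 10,000-fold, enough to watch its
enzymatic conversion to [1-\(^{13}\)C]lactate by lactate dehydrogenase (LDH)
in real time in viable, perfused tissue slices. The polarization is
non-renewable: it decays with the longitudinal relaxation time \(T_1\) and
every radio-frequency (RF) excitation of nutation angle \(\theta\) consumes a
fraction \(1 - \cos\theta\) of it while emitting signal proportional to
\(\sin\theta\). All quantitative analysis in this package revolves around
undoing those two losses.

Three acquisition designs are supported, mirrored by three synthetic
generators with known ground truth:

1. **Arrested perfusion, non-selective pulses** (small equal angles on both
   resonances, reference scheme \(\theta = 12^\circ\), TR = 5 s): the full
   kinetic time course is observed and fitted with a two-pool model.
2. **Arrested perfusion, selective pulses**: a shaped pulse reads the lactate
   pool at \(\sim 90^\circ\) each TR (8–16 s), nulling it, so each sample
   measures only newly produced lactate and no kinetic model is needed.
3. **Continuous flow**: as 2, but with ongoing delivery of hyperpolarized
   medium, requiring a decay correction and a data-driven selection of the
   time window where the precursor concentration is constant.

# The two-pool kinetic model

For non-selective acquisition the longitudinal magnetizations \(P\)
(pyruvate) and \(L\) (lactate) evolve between pulses as

\[
\frac{dP}{dt} = -\frac{P}{T_{1,P}}, \qquad
\frac{dL}{dt} = k_{1st}\,P - \frac{L}{T_{1,L}},
\]

with discrete losses \(P \to P\cos\theta_P\), \(L \to L\cos\theta_L\) at each
excitation and signals \(\sin\theta_P\,P\), \(\sin\theta_L\,L\) read just
before each pulse. Consumption of pyruvate by the reaction is **neglected**
in the precursor equation: the metabolized fraction over an experiment is
\(\sim k_{1st} t \lesssim 1\%\), far below the precursor's own decay. A
consequence worth knowing: total magnetization is *not* conserved even with
relaxation and RF switched off — it drifts by exactly \(M_0 k_{1st} t\),
and the test suite asserts that drift law rather than a conservation it
cannot have.

`simulate_two_pool()` propagates this system *exactly*: between pulses the
product equation has the closed-form solution

\[
L(\tau) = L_0 e^{-\tau/T_{1,L}} + k_{1st} P_0\,
  \frac{e^{-\tau/T_{1,P}} - e^{-\tau/T_{1,L}}}{1/T_{1,L} - 1/T_{1,P}},
\]

(with the confluent limit \(\tau e^{-\tau/T_{1,P}}\) when the two \(T_1\)s
coincide). The tests verify it against an independent fine-grid Euler
integration (1 ms steps) to \(10^{-4}\) relative.

`fit_two_pool()` estimates \((M_0, T_{1,P}, k_{1st}, T_{1,L})\) by bounded
Levenberg–Marquardt. The default is **sequential**: the precursor channel,
which does not depend on \(k_{1st}\), determines \(M_0\) and \(T_{1,P}\);
the product channel then determines \(k_{1st}\) and \(T_{1,L}\) with the
precursor fixed. A joint fit over the pooled residuals is available
(`method = "joint"`); on noiseless data both recover all parameters to
better than \(10^{-4}\) relative. \(R^2\) is reported per channel, never
pooled, because the two channels have vastly different scales — the product
maximum is \(\sim 0.16\%\) of the precursor maximum at the reference
parameters.

Defaults that matter:

* starting values \(T_{1,P} = 55\) s, \(T_{1,L} = 20\) s,
  \(k_{1st} = 10^{-4}\,\mathrm{s^{-1}}\), \(M_0\) from the precursor maximum;
  lower bounds \(10^{-12}\) on all parameters (positivity, nothing more);
* the first sample is dropped (`drop_first = TRUE`) because the injection is
  typically still ongoing at the first spectrum;
* non-convergence raises a `fit-failure` error carrying the last iterate.
  The Levenberg–Marquardt core is used directly (`minpack.lm::nls.lm`)
  because wrapper-level model re-linearization can reject noise-degenerate
  but converged fits.

The closed-form amount extrapolation
\(A_{lac} = \mathrm{Pyr}\,(1 - e^{-k_{1st} t})\)
(`extrapolate_amount()`) turns a fitted rate constant into a produced amount;
with the probe-visible pyruvate pool of 14 mM \(\times\) 0.5 mL = 7000 nmole
and the study-scale rate constant it predicts on the order of 70 nmole
(0.07 µmole) of lactate per minute, which normalizes to \(\sim\)6
nmole/min per nmole of tissue ATP.

# Selective excitation: pulse physics and \(\rho\)

`simulate_pulse()` integrates the Bloch rotations of a hard or sinc envelope,
discretized into piecewise-constant steps (default 2000; doubling the count
moves responses by \(< 10^{-4}\)). Relaxation during the pulse is neglected
(2.5 ms against \(T_1\)s of tens of seconds, error \(< 0.02\%\)). The
envelope amplitude is calibrated so the on-resonance rotation equals the
stated angle exactly at the chosen discretization, making the on-resonance
response \(\sin(\theta_{cal})\) by construction. Properties held by the
tests: evenness in offset, linear small-tip scaling, agreement with the
Fourier transform of the envelope within 2% in the small-tip limit, and
agreement with an independent \(10^5\)-step rotation-matrix integration at
the working offsets.

The per-excitation rate formula needs \(\rho\), the factor converting the
observed lactate/pyruvate *signal* ratio into a *magnetization* ratio. Since
each signal is (response) × (longitudinal magnetization), that factor is

\[
\rho = \frac{\text{precursor response}}{\text{product response}},
\]

which is what `response_ratio(product_offset, precursor_offset, shape)`
returns; it equals 1 for any non-selective pulse and is \(\le 1\) for a
product-centered selective readout. We note the convention explicitly
because the opposite ratio circulates in verbal descriptions ("relative
response of lactate and pyruvate"); only the convention above maps a
constant-concentration experiment onto a constant inferred ratio, and the
synthetic end-to-end tests would fail by a factor \(\sim 1/\sin^2\theta_P\)
under the other reading.

A caveat the package surfaces rather than hides: for the stated selective
pulse (2.5 ms sinc, \(\sim 90^\circ\), 3 side-lobe pairs — the side-lobe
count is not specified by the acquisition description and 3 is a common
spectrometer default, configurable) the simulated excitation band is roughly
\(\pm 1600\) Hz, so a resonance 214 Hz away is *almost fully excited* and
the simulated \(\rho\) is close to 1. Strong selectivity at 214 Hz would
require a longer or lower-lobe pulse. Because shaped-pulse implementations
differ between spectrometers, every rate entry point also accepts a measured
scalar \(\rho\), which overrides the simulation.

# The selective analysis chain

**T1 under arrest** (`fit_t1_eq1()`): with constant precursor concentration
the pulsed signal obeys
\(M(t) = M_0\, e^{-t/T_1} \cos^{t/TR}(\theta)\);
\(T_1\) and \(M_0\) are fitted with \(\theta\), TR known. A \(90^\circ\)
precursor angle is refused as degenerate (the signal is nulled after one
pulse). The decay attributable to RF alone is separable: with the \(T_1\)
term removed the fit drives \(T_1\) to effectively infinity, which the tests
check.

**Decay correction** (`correct_precursor_eq2()`): divides the precursor
series by its decay envelope
\(e^{-t/T_1} \cos^{t/TR}(\theta_P)\), so truly constant concentration maps to
a constant. Note the direction: the correction *divides by* (equivalently,
multiplies by the inverse of) the envelope; applying the envelope a second
time would deepen the decay and could not produce the flat plateaus the
windowing step relies on. The RF term can be disabled
(`include_rf = FALSE`) for a strictly-\(T_1\) correction. Far into the decay
the correction mostly amplifies noise, so points whose correction factor
exceeds `amplification_ceiling` (default 20×) are flagged unreliable.

**Constant-concentration window** (`select_constant_window()`): the first
maximum of the corrected series is the first running maximum not exceeded by
more than `tie_tol` (default 2%) within the next `guard` (default 2)
samples; the window is the contiguous run from that maximum of points within
10% of it, stopping at the first violation. The guard absorbs noise spikes;
the tie tolerance additionally handles the *noiseless* well-mixed build-up,
which approaches its plateau monotonically and would otherwise push the
"first maximum" to the end of the plateau. The rule is idempotent
(re-selecting on the windowed subset returns the same set), and on an
arrested-design series (which starts at its maximum) it degenerates to
"first point, then walk forward".

**Per-excitation rates** (`rate_eq3()`): for each windowed excitation

\[
v = \frac{S_{lac}}{S_{pyr}} \cdot \rho \cdot
    \frac{[\mathrm{Pyr}]\, V_{medium}}{TR \cdot n_{ATP}} \times 60,
\]

in nmole · min\(^{-1}\) · (nmole ATP)\(^{-1}\), with
\([\mathrm{Pyr}] = 14\) mM and \(V_{medium} = 0.5\) mL as defaults
(mM × mL = µmole, ×1000 = nmole; computed per second, reported per minute).
Points with precursor at or below the noise floor are excluded with a
message, never silently used. `aggregate_rates()` implements the
maximal-rate convention: per-point rates rise while delivery stabilizes, so
the reported mean ± SD covers the contiguous run of points around the
maximum within `stabilization_tol` (default 15%, configurable — no numeric
criterion exists in the field for this, so the choice is exposed and
logged). Because the product pool relaxes during each repetition interval,
the per-excitation readout sits somewhat below the instantaneous
\(k\)-implied rate (about 8% at TR = 12 s, \(T_{1,L}\) = 30 s); this is a
property of the method, not a bug, and the recovery tests therefore compare
against the generator's own magnetization ratios rather than the naive
\(k \cdot [\mathrm{Pyr}] V\) rate.

# ATP quantification and unit conversions

Tissue viability and normalization use the thermal-equilibrium \(^{31}\)P
γ-ATP integral against an external standard (111 mM ATP by default).
`saturation_factor()` is the Ernst steady-state expression
\(\sin\theta\,(1-E)/(1-E\cos\theta)\), \(E = e^{-TR/T_1}\), verified against
a \(10^4\)-pulse recursion on a 20×20 grid to \(10^{-6}\).
`quantify_atp()` compares per-scan, saturation-corrected integrals; it is
deterministic, linear, and invariant to common rescaling. The \(^{31}\)P
\(T_1\) of each measurement is **mandatory input** — the package refuses to
assume one silently, because the correction can be large (the factor for the
tissue scheme, \(50^\circ\)/TR 1.1 s at \(T_1\) = 1 s, is ~0.65).

`per_mass_rate()` converts per-ATP rates to per-mass rates with a literature
tissue ATP content (default 0.86 µmole/g), and `signal_equivalence()` is the
detectability arithmetic (concentration × 10,000-fold dDNP enhancement,
expressed in molar).

# The synthetic generators

Each generator emits a truth record with every parameter it used, and every
pipeline stage has a recovery test against such truth.

* `generate_arrest_nonselective()`: the two-pool simulation plus additive
  Gaussian noise; at \(\sigma = 0\) it *is* the simulation.
* `generate_arrest_selective()`: product pool reset at each \(90^\circ\)
  readout and re-accumulated over each interval (closed form); an initial
  quench block (default 4 pulses at TR 2 s) discards product accumulated
  since injection, and omitting it demonstrably inflates the first analysis
  sample. Quench samples carry a mask and are excluded from rate analysis —
  they measure nothing, they only reset the product polarization.
* `generate_continuous_flow()`: inlet concentration ramps up
  (defaults: arrival 10 s, ramp 50 s), holds steady (180 s, the
  hyperpolarized volume over the flow rate: 12 mL at 4 mL/min), and shuts
  off; the probe volume responds as a **single well-mixed compartment**
  (exchange rate flow/\(V_{total}\) = (4/60)/1.4 s\(^{-1}\) by default) —
  the simplest model consistent with a smooth build-up/plateau/wash-out.
  The truth record reports the plateau level and the time the probe
  concentration reaches 90% of it. An optional `spike` reproduces the small
  post-plateau rise from less-depolarized material left in the line, for
  stress-testing the window rule; default off.
* `generate_p31_pair()`: integral pair with relative Gaussian noise;
  noiseless round trips are exact and 5% noise over 100 seeds biases
  recovery by well under 2%.

**What the generators do not emulate:** spectral baselines and phasing
(inputs are already-integrated intensities), pyruvate-hydrate exchange,
reverse lactate→pyruvate flux, alanine/bicarbonate channels, B1
inhomogeneity, spatially resolved perfusion, and inflow of polarized but
unpulsed material (beyond the optional spike). Passing tests demonstrate
the correctness of the analysis chain under the stated model, not the
model's completeness for any particular tissue preparation.

**Noise conventions.** Additive series noise is quoted relative to the
signal being quantified. This matters: at the reference kinetic parameters
the lactate signal maximum is ~0.16% of the pyruvate maximum, so "0.5% of
the precursor maximum" would mean a lactate channel that is pure noise
(\(R^2 \approx 0\)) — inconsistent with the \(R^2 \approx 0.9\) product
fits this analysis is designed around, and no estimator recovers a median
rate constant from it. The recovery studies therefore set \(\sigma\) as
(product-channel reference level)/SNR, with SNR 50 for the Monte-Carlo
study; in the flow design the reference level is the windowed product mean,
since hyperpolarized decay makes the early-series maximum irrelevant to the
analyzed points.

# Problem sizes and reproducibility

The shipped studies use 66-sample series (TR 5 s, ~5.5 min of acquisition)
for the non-selective design, 12–30 samples for the selective designs, 100
seeds for Monte-Carlo recovery, 2000-step pulse discretization with
\(10^5\)-step oracles, and 1 ms Euler grids — sizes chosen to match the
experiments they emulate while keeping any single study in the seconds-to-
a-minute range. All stochastic steps take explicit integer seeds;
`run_pipeline()` logs every default it applies and labels every reported
number with its units.
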