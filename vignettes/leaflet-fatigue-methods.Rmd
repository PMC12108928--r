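---
title: "Fatigue life and tear growth of bioprosthetic valve leaflets: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fatigue life and tear growth of bioprosthetic valve leaflets: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvefatigue)
```

## The problem

Tissue leaflets of transcatheter bioprosthetic valves fail by fatigue: the
leaflet opens and closes once per heart beat, roughly 4 × 10⁷ times a year,
and the stress concentrations that the implanted geometry imposes — folds at
the leaflet base, sharp creases left by an incomplete expansion — accumulate
damage until the tissue tears. `valvefatigue` estimates how long that takes.
Its input is the stress time-history at the worst (maximum-stress)
integration point of the leaflet surface, typically extracted from a
fluid–structure-interaction simulation; its outputs are an expected life in
cardiac cycles and calendar time, and a predicted growth trajectory for an
elliptical tear seeded at the same location.

The intended users are engineers and researchers running in silico
durability studies of valve implant configurations, who have per-patient
stress histories and need a transparent, testable post-processing chain from
signal to life estimate.

## The fatigue model

The chain is classical high-cycle fatigue analysis, specialised to the
cardiac setting where one *load spectrum* (one cardiac cycle of stress) is
assumed to repeat unchanged for the life of the device:

1. **Turning points and peak averaging.** The sampled signal is reduced to
   its alternating local extrema. Peaks of the same kind whose values differ
   pairwise by at most `rel_tolerance` × max|S| (default 0.05) are replaced
   by their mean: successive systolic peaks from a stabilised simulation
   differ only by numerical noise, and averaging them keeps the counted
   spectrum small. At `rel_tolerance = 0` this step is the identity.
2. **Rainflow counting** (`rainflow_count()`) decomposes the extrema into
   closed stress cycles and residual half-cycles by the four-point rule:
   an inner excursion enclosed by its neighbours on both sides is extracted
   as one full cycle (count 1.0); whatever remains unclosed is counted as
   half-cycles (0.5 each), and two matched half-cycles merge into a full
   cycle. Twice the summed counts always equals the number of excursions in
   the signal, which the tests assert for random sequences. Counting is done
   on the full multi-cycle signal and divided by the number of cardiac
   cycles, which is exact under the repeated-spectrum assumption.
3. **Gerber mean-stress correction** (`gerber_equivalent_stress()`) maps
   each counted cycle, with amplitude `Sa = (Smax − Smin)/2` and mean
   `Sm = (Smax + Smin)/2`, onto the pulsatile (R = 0) reference curve:
   `SNf = Sa / (1 − (Sm/Su)²)`. The squared term makes the correction
   sign-symmetric, so a compressive mean is as damaging as a tensile one —
   deliberate here, because the outer leaflet surface is compression-
   dominated and compressive loading is a recognised driver of leaflet
   fatigue. A `clamp_negative_mean` switch zeroes compressive means for
   sensitivity studies.
4. **Basquin life** (`basquin_life()`): `SNf = σf (2Nf)^β` inverted to
   `Nf = ½ (SNf/σf)^{1/β}`, with `σf` the single-cycle fatigue strength and
   `β < 0` the S-N slope, both calibrated on pulsatile tests of the leaflet
   tissue. Stresses at or above `σf` (including means beyond `Su`) clamp to
   `Nf = 0.5` — failure within one half-cycle — with a machine-readable
   warning, since the power law would otherwise return lives below a
   countable cycle.
5. **Miner accumulation** (`spectrum_damage()`, `total_life()`): damage per
   cardiac cycle is `D = Σ nⱼ/Nfⱼ` over the counted sub-cycles and the
   expected life is `L = 1/D` cycles; `cycles_to_duration()` converts to
   days and years at a heart rate (default 70 bpm, 365-day years). Zero
   damage is reported as an explicit infinite-life flag rather than an
   overflow.

There is no endurance limit by default (damage accrues at every amplitude);
an optional threshold amplitude can be supplied.

## The tear-growth model

A hypothesised initial tear at the maximum-stress site is an ellipse with
semi-axes `a ≥ b`. Per cardiac cycle and per counted sub-cycle:

* the **stress concentration factor** of the current geometry is
  `Kt = 1 + 2b/a`. This is the form adopted throughout; note that the
  classical elliptical-hole factor under tension normal to the major axis
  is `1 + 2a/b`, and `stress_concentration_factor(..., convention =
  "classical")` exposes that alternative so users can probe the sensitivity
  of the prediction to the convention;
* the **local elastic–plastic stress** at the crack is obtained from the
  nominal extremes by the strain-energy-density (Glinka) balance
  `σ²/E + (2σ/(e+1)) (σ/K)^{1/e} = (Kt S)²/E`, with `E` the elastic
  modulus and `(K, e)` the cyclic Ramberg–Osgood strength coefficient and
  hardening exponent. The left side is strictly increasing in `σ > 0` and
  the right side lies between its values at 0 and `Kt·S`, so the root is
  unique and bracketed; it is found by bisection to a residual below
  10⁻¹⁰ of the elastic energy term, and the tests compare it against an
  independent dense-bisection oracle over a parameter grid. Negative
  (compressive) stresses are solved on the magnitude and the sign restored;
* the **stress intensity range** is `ΔK = (σmax − σmin)√(πα)` with no shape
  factor (Y = 1), and the axis-swap rule sets the length parameter: growth
  *along the major axis* uses `b`, growth along the minor axis uses `a`;
* the **Paris law** `dα/dN = C ΔK^m` gives the per-cycle increments, which
  are superposed, weighted by each sub-cycle's fractional count
  (half-cycles contribute 0.5; a switch restricts growth to full cycles
  only).

Geometry — and with it `Kt` and `ΔK` — is refreshed after each block of
`block_size` cardiac cycles. The default `block_size = 1` refreshes every
cycle and is the limit that the superposition of per-cycle increments
approximates; larger blocks trade accuracy for speed, and a
Richardson-style test checks that halving the block changes the outcome
negligibly on the packaged spectra. For a circular crack under constant
amplitude the trajectory must follow the closed-form Paris integral
`a(N) = [a₀^{1−m/2} + (1−m/2) C (Δσ√π)^m N]^{2/(2−m)}`; the tests hold the
simulation to within 1% of it for m ∈ {2.5, 3, 4}. A configurable
`max_axis_mm` threshold stops the run with a `"tear-through"` status when
either axis outgrows the leaflet.

## Material parameters

| Parameter | Units | Meaning | Demo value |
|---|---|---|---|
| `su` | MPa | nominal ultimate tensile strength | 10 |
| `sigma_f` | MPa | single-cycle fatigue strength (pulsatile) | 7 |
| `beta` | — | S-N slope, negative | −0.09 |
| `e_modulus` | MPa | elastic modulus | 2 |
| `hardening_exp` | — | cyclic hardening exponent `e` | 0.3 |
| `strength_coeff` | MPa | cyclic strength coefficient `K` | 15 |
| `paris_c` | mm/cycle/(MPa·√mm)^m | Paris coefficient | 10⁻⁷ |
| `paris_m` | — | Paris exponent | 3 |

The packaged demo card (`demo_material_path()`) holds **synthetic
placeholder values** of plausible magnitude for glutaraldehyde-fixed bovine
pericardium. The fitted constants behind published leaflet life tables come
from proprietary ultra-high-cycle pulsatile tests and are not public, so
absolute lives computed with the demo card are illustrative only; orderings
and sensitivities are meaningful. `sigma_f` and `beta` must be calibrated at
stress ratio R = 0 — the Gerber correction maps every cycle onto that
reference curve, and parameters fitted at another ratio would bias every
life estimate. `paris_c` must be supplied in mm/MPa·√mm units; no automatic
unit conversion is attempted.

The neo-Hookean helpers (`neo_hookean_params()`, `neo_hookean_energy()`)
document the leaflet's hyperelastic material card (`C10 = μ0/2`,
`D1 = 3(1−2ν)/(μ0(ν+1))`, `U = C10(I1−3) + (1/D1)(Jel−1)²`). They are
deliberately not consumed by the fatigue pipeline: the simulation that needs
them (the fluid–structure interaction producing the stress histories) is
upstream of this package.

## The synthetic spectrum generator

`generate_cardiac_spectrum()` emulates the qualitative structure of
FSI-derived leaflet load spectra so that every pipeline stage is testable
without simulation output: one dominant systolic extremum per cycle with a
prescribed peak magnitude, a secondary diastolic feature of opposite sign,
a compression- or tension-dominant sign profile per surface, period set by
heart rate, smooth half-sine-power bumps, optional seeded Gaussian noise,
and bitwise-identical cycles when noise is off.

The packaged `patient_template()`s encode the published peak magnitudes of
three virtual TAVI patients (0.659, 0.632 and 1.676 MPa) and their surface
descriptions. The published waveforms themselves are available only as
figures, so two generator choices are package design decisions, made once:

* `systole_fraction = 0.35` of the period, the usual physiological split;
* diastolic load shares of 0.15, 0.30 and 0.90 of the peak for patients A,
  B and C. The published lives order A > B although A's peak (0.659 MPa)
  slightly exceeds B's (0.632 MPa), so the peak alone cannot carry the
  severity ordering; the diastolic share encodes what the study reports
  qualitatively — B's post-dilatation cusp fold sustains load through
  diastole, and C's non-recoverable sharp fold keeps both surfaces loaded
  through the whole cycle.

What the templates do **not** emulate: measured waveform shapes, beat-to-beat
variability, multiaxiality, shear stress, and any coupling between damage
and the load (the spectrum is stationary by assumption). Tests passing on
these templates therefore validate the *processing chain* — counting,
correction, accumulation, growth — not the fidelity of any particular
patient's loading.

## Numerical choices and degenerate inputs

* Rainflow merging of identical cycles uses an absolute tolerance of
  10⁻⁶ MPa so floating-point-identical cycles merge; counts are multiples
  of 0.5 by construction.
* A constant signal has no turning points and yields zero cycles, zero
  damage and the infinite-life flag — not an error.
* Zero-amplitude sub-cycles contribute zero damage and zero growth.
* The Glinka bisection runs to a relative residual of 10⁻¹⁰ with a
  200-iteration budget and reports solver diagnostics on failure (the
  bracket guarantees convergence in well-posed inputs).
* Problem sizes in the tests and the reproduction script are kept small —
  five-cycle generated histories, 2000-cycle crack runs, 200 random
  sequences per property suite — which is ample for the closed-form and
  oracle comparisons they make.

## Known limitations

* Uniaxial scalar stress only; no multiaxial counting, no shear.
* Linear (Miner) accumulation; no load-sequence effects, no crack closure,
  no endurance limit unless configured.
* The Paris model starts from an assumed initial flaw; crack initiation is
  not modelled (the fatigue-life pipeline covers total life to failure
  separately).
* Absolute life predictions are only as good as the S-N constants supplied;
  the packaged demo constants are placeholders.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from the installed package alone: the
calendar durations of the three published governing lives at 70 bpm, the
demo-pipeline lives and ordering for the three templates, and the
oracle-agreement metrics (rainflow re-count, Glinka residual, Paris
closed-form error, S-N refit error). See the README for invocation.
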