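---
title: "Transmission-line modelling of ultrasonic vagus nerve stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission-line modelling of ultrasonic vagus nerve stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoline)
```

## The model

`sonoline` simulates 1-D longitudinal ultrasound propagation through layered
and branched tissue using the electro-acoustic transmission-line analogy:
acoustic pressure maps to voltage through a hydrophone calibration constant
(`p = V / M`, default `M` = 70 nV/Pa), and each tissue layer becomes an
ideal lossless transmission line whose characteristic impedance is the
tissue's acoustic impedance (`Z = rho c`) and whose delay is its transit
time (`t = d / c`). Two anatomical models are built in:

* **cervical vagus stimulation** — a rooted tree of 18 segments: the skin
  stack at the neck, the vagus trunk, a branch to the left recurrent
  laryngeal nerve, a branch to the cardiac plexus, and a three-way split at
  the esophageal plexus into hepatic, gastric and celiac/splenic pathways
  (five measured terminals);
* **site-focused splenic stimulation** — a linear chain of 8 segments from
  the abdominal skin through intercostal muscle, diaphragm, spleen capsule
  and spleen to the splenic nerve (one terminal).

Each leaf carries a resistive termination equal to the impedance of its
upstream segment, so terminals are reflectionless; internal interfaces and
branch points are *not* matched, and their impedance mismatches generate
the reflections that shape the A-scan echo trains.

### The traveling-wave engine

Every segment holds a forward and a backward delay line (delay rounded to
an integer number of samples). At each step the voltage at a node with
incident port waves `a_i` on impedances `Z_i` (plus shunt conductances of
any terminations) is

    V = 2 * sum(a_i / Z_i) / (sum(1 / Z_i) + sum(1 / R))

and the wave launched back into port `i` is `V - a_i`. For a single
incident wave this reduces to the textbook reflection coefficient
`Gamma = (Z_load - Z_in) / (Z_load + Z_in)` with `Z_load` the parallel
combination of the downstream impedances, the form exposed directly as
`junction_scatter()`. Power balance
`Gamma^2 + (1 + Gamma)^2 Z_in / Z_load = 1` holds identically and is
asserted to below `1e-12` relative error in the test suite.

The source node is an **ideal voltage source**: its node voltage is clamped
to the pulse waveform, so waves returning to the origin re-reflect there
(coefficient -1 when the source is quiescent), exactly as a pulsed voltage
source behaves in a circuit simulator. A non-reflecting source option
(`source_reflects = FALSE`) launches the waveform and absorbs returns; it
exists for clean analytic comparisons.

Correctness of the engine is established against an independent oracle,
`analytic_cascade_response()`: a depth-first enumeration of every
reflection path through a short linear cascade, summing products of
interface transmission/reflection coefficients. On randomized chains of up
to four segments the two agree to better than `1e-9` of the source
amplitude (observed deviations are at machine precision, ~`1e-14`).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| hydrophone sensitivity `M` | 70e-9 | V/Pa | calibration of the reference transducer; 0.25 / 0.83 MPa map to 17.5 / 58.1 mV |
| pulse period | 500e-6 | s | repetition period of the pulsed therapeutic source |
| pulse width | 1e-6 | s | not prescribed by the original circuit description; exposed, defaulted, logged. Amplitude-normalised outputs (attenuation dB, arrival times) are insensitive to it |
| pulse shape | rectangular | — | ideal pulsed-source analogue; a 1.1 MHz tone-burst option matches the physical transducer frequency |
| time step | 1e-8 | s | bounds per-segment delay-rounding error by 5 ns, two orders below the 0.01 us reporting precision |
| simulated duration | 800e-6 / 100e-6 | s | cervical / site-focused: slightly longer than the longest first arrival |
| noise floor | 1e-6 x source | V | peak-detection threshold |
| safety thresholds | 0.1, 3, 35 | W/cm^2 | action-potential minimum, FDA therapeutic ceiling, thermal-burn bound |

Dosimetry chains the core relations per terminal: first-peak voltage ->
mechanical pressure (`p = V/M`) -> intensity `I = p^2 / (2 rho c)` evaluated
with the **terminal tissue's own** impedance (the intensity as if the
transducer sat directly on that tissue) -> attenuation
`20 log10(v_terminal / v_incident)`.

## The synthetic tissue table

The quantitative per-tissue inputs (density, speed of sound, segment
length) are deliberately kept in an editable CSV, not in code. The shipped
table is **synthetic**:

* the nerve-tissue impedance (rho = 1075 kg/m^3, c = 1630 m/s, Z =
  1.752e6 rayl) and the epidermis impedance (rho = 1109, c = 1513, Z =
  1.678e6 rayl) are pinned by inverting `I = p^2/(2 rho c)` against
  published terminal pressure/intensity pairs — every printed terminal
  intensity cell is reproduced to two decimals by these two impedances;
* all other densities and speeds are literature-typical values for skin,
  fat, muscle, connective tissue and spleen;
* segment lengths are plausible human-anatomy choices made once.

Because the lengths are synthetic, simulated **arrival times and terminal
voltages are not expected to reproduce the published voltage/time columns**
(those require the original study's unpublished per-segment lengths);
everything that is amplitude- or calibration-normalised — the dB
attenuation columns recomputed from printed voltages, the pressure and
intensity cells, the safety classification, and all structural claims
(five cervical terminals vs one site-focused terminal) — is reproduced
exactly. Passing tests therefore demonstrate the correctness of the wave
engine and the dosimetry chain, not the anatomical fidelity of the shipped
lengths. Replacing the table with measured properties upgrades the
simulation without touching code.

The simulation also idealises real tissue: no frequency-dependent
absorption, no dispersion, no nonlinearity, no beam geometry or focusing,
and no thermal effects — the model is 1-D and lossless except for
impedance-mismatch scattering, so real in-body amplitudes will be lower
than simulated ones.

## Numerical choices

* **Delay rounding.** Segment delays are rounded to the nearest integer
  number of samples; a segment whose delay falls below one time step is an
  error (the fix is a smaller step), never silently dropped.
* **Peak convention.** A "peak" is a sample-level local maximum of
  `|voltage|` with plateau handling: a flat-topped rectangular pulse counts
  once and its arrival time is the plateau onset. The reported amplitude is
  the signed voltage; detection uses the absolute value (whether published
  A-scan readings used signed or absolute maxima is unstated; absolute is
  the convention here).
* **First-peak window.** Terminal peaks are measured on
  `[0, min(duration, period)]` so a second source emission can never
  contaminate first arrivals.
* **Rounding.** Internally everything is full-precision SI. Reports round
  half away from zero to two decimals, matching printed-table conventions.
  Attenuation offers two conventions: `full` (dB from full-precision
  voltages — the physically consistent choice, under which dB columns are
  exactly independent of source amplitude) and `rounded_first` (voltages
  rounded to 0.01 mV before the ratio — the arithmetic needed to reproduce
  printed two-decimal cells). The published tables' slight dB differences
  between the 0.25 and 0.83 MPa studies (e.g. -11.93 vs -12.89 for the
  cervical splenic terminal) are consistent with voltage-first rounding,
  since the underlying linear model predicts identical dB; two 0.25 MPa
  cells (hepatic -11.54, gastric -11.88) differ by 0.01 dB from any
  recomputation off their printed voltages and are treated as published
  rounding artifacts.
* **Intensity.** The plane-wave temporal-peak form `p^2/(2 rho c)` is used
  as the spatial-peak temporal-average intensity without a duty-cycle
  factor, following the source study's usage literally.

## Problem sizes

The default cervical run is 80,001 steps over ~40 delay-line buffers
(~0.5 s on one core); the site-focused run is 10,001 steps. Unit tests use
toy chains (2-4 segments, 0.1 us steps, tens of microseconds) so the whole
suite runs in a few seconds; oracle-equivalence checks use 25-30 randomized
cascades under a fixed seed.

## Worked example

```{r example}
tab <- load_tissue_table(sonoline_example("tissue_properties_synthetic.csv"))
report <- run_study(0.25, "site_focused", tab,
                    config = sim_config(100e-6, time_step = 5e-8))
report
```

```{r ascan, fig.width = 6, fig.height = 3.5}
plot(attr(report, "traces")[["T8:B+"]])
```

## Known limitations

* Lossless lines: attenuation arises only from branching and impedance
  mismatch, so absolute delivered amplitudes are optimistic.
* 1-D: no diffraction, focusing gain or beam width; "site-focused" is
  represented purely by its shorter, unbranched path.
* The analytic oracle is exponential in echo count and restricted to
  chains of at most four segments; branched networks are verified through
  junction-level closed forms and conservation laws instead.
* Biological endpoints (TNF-alpha suppression, heart-rate changes) are out
  of scope: the package stops at acoustic dosimetry and threshold
  classification.
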