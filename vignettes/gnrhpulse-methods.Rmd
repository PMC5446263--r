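---
title: "gnrhpulse: models, methods and calibration rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gnrhpulse: models, methods and calibration rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnrhpulse)
```

GnRH (gonadotropin-releasing hormone) is secreted in pulses, and pituitary
gonadotropes respond maximally at intermediate pulse frequency. This package
provides the pieces needed to explore how such frequency decoding can arise:
exact square-wave stimulus protocols, a minimal pulse-decoding enzyme
cascade, a receptor-network ODE model in which agonist-induced receptor
internalization is the only upstream negative feedback, transcriptional
logic gates, scan analyses and single-cell mutual-information estimation.
This vignette documents the equations, the numerical methods, and the
reasoning behind the shipped default parameters.

## 1. Pulse protocols

`pulse_protocol(amplitude, width, period, horizon, baseline)` describes a
square wave: pulses of the given amplitude and width starting at
`t = 0, period, 2*period, ...`, at the baseline concentration otherwise.
`signal_at()` evaluates the wave, `input_integral()` returns the exact
closed-form time integral (including partial trailing pulses and the
baseline contribution), and `compensated_family()` builds a set of
protocols sharing one duty fraction, so that the integrated input is equal
across frequencies. For a fixed-width (non-compensated) family the input
integral is directly proportional to pulse frequency — the key confound when
interpreting frequency-response curves, and the reason compensated families
exist.

Simulators integrate segment-wise between pulse edges with a stiff-capable
adaptive solver (`deSolve::lsoda`, relative tolerance `1e-8`, absolute
`1e-12`), so the discontinuous input is handled exactly; output lands on a
uniform grid of at most 0.1 min and areas under curves (AUCs) use
trapezoidal quadrature.

## 2. The minimal cascade

The minimal model asks how little machinery suffices to read pulse
frequency. A stimulus-activated effector E1 activates two targets:
a fast one (E3) and a slow one (E2). Each conversion follows
Michaelis–Menten kinetics; for effector $i$ with active fraction $E_i^*$,

$$\frac{dE_i^*}{dt} = a_i\,k_{act,i}\frac{(T_i - E_i^*)}{K_{act,i} + (T_i - E_i^*)}
 - V_{inact,i}\frac{E_i^*}{K_{inact,i} + E_i^*},$$

where the drive $a_i$ is the binary stimulus for E1 and $E_1^*$ for E2 and
E3. The effective relaxation times $K_{inact}/V_{inact}$ are well under a
minute for E1 and E3 and more than ten-fold longer for E2 (the constructor
`minimal_params()` enforces the separation).

The fast effectors track each pulse and reset between pulses, so their
960-min AUCs are essentially proportional to pulse frequency — they read the
cumulative input, not its temporal pattern. The slow effector integrates
across pulses, and its saturating activation makes it respond
sub-linearly to frequency: under a *compensated* family (equal total input)
E1 and E3 AUCs are flat while the E2 AUC still rises with frequency, i.e.
only the slow branch genuinely decodes frequency. Frequent short pulses are
also more *efficient* (more E2 activity per unit input than rare long
pulses) and more *specific* (higher E2:E3 ratio).

### Calibration caveat: the shape of the E2 response

Defaults were chosen (by a Latin-hypercube search maximizing the worst-case
margin across all of the behavioral properties above) so that E1/E3 AUC
versus frequency is proportional ($R^2$ through the origin $> 0.98$) while
the E2 AUC is strictly increasing but clearly non-proportional
($R^2 < 0.98$). A strictly *convex* E2 frequency response (every interior
point below the chord) is incompatible, in this model family, with the E2
AUC also increasing under compensated stimulation: convexity needs
near-zero-order inactivation, whereas the compensated increase needs
saturating activation with near-first-order decay. The package therefore
operationalizes "non-linear E2 response" as strict increase plus departure
from proportionality, not as convexity.

## 3. The receptor network

`simulate_network()` integrates twelve states: free surface receptor,
hormone-bound receptor (HR) and internalized receptor; active PLC;
cytoplasmic Ca²⁺; cytoplasmic and nuclear ppERK; a four-state NFAT cycle
(cytoplasmic/nuclear × phosphorylated/dephosphorylated); and nuclear Egr1.
Binding is mass-action (`kon`, `koff`); HR internalizes at
`int_mult * kint_base` and internalized receptor recycles at
`rec_mult * krec_base` — the two multipliers are the experiment knobs.
HR activates PLC; PLC drives Ca²⁺ release (Hill); PLC and Ca²⁺ jointly
activate ERK, whose nuclear pool drives Egr1 synthesis; Ca²⁺-activated
calcineurin dephosphorylates NFAT, which then shuttles into the nucleus.
Receptor and NFAT totals are conserved exactly by construction, and the
fast upstream / slow downstream time-scale split (PLC and Ca²⁺ half-times
under 10 min; NFAT and Egr1 over 20 min) is part of the calibrated behavior.

The defaults were calibrated against qualitative targets rather than fitted
to data:

* under constant 1e-7 M GnRH, PLC spikes within minutes and relaxes to a
  plateau (receptor internalization depletes the surface pool); with
  negligible internalization the rise is sustained;
* pulsatility mitigates internalization: the relative difference between
  outputs at 1× and at negligible internalization shrinks as the pulse
  period grows, becoming small at 2-h periods;
* the Ca²⁺-AUC-optimal period among {15, 30, 60} min moves from 15 min at
  1× internalization to 30 min at 8× and 60 min at 16×;
* on a doubling ladder of internalization multipliers, the Ca²⁺ frequency
  response turns bell-shaped from 4× upward, while integrated PLC stays
  monotonic in frequency throughout.

`frequency_scan()`, `dose_scan()` and `internalization_scan()` wrap these
experiments; `optimal_period()` (ties broken toward the longer period at
0.1% relative tolerance) and `classify_shape()` (bell if an interior point
exceeds both endpoints by more than 5%, with bell taking precedence over
monotone) reduce scans to headline results.

## 4. Transcriptional gates

`gate_spec()` defines five ways to turn nuclear ppERK ($E$) and the NFAT
nuclear fraction ($N$) into reporter transcription: single-input Hill gates
(`ERK_DT`, `NFAT_DT`), their product (`AND`), a probabilistic `OR`, and a
sequential co-operative promoter (`COOP`). For the Hill gates the rate is a
static monotone function of $(E, N)$, so their frequency responses simply
inherit the (monotone) behavior of the inputs — no static monotone gate can
create a bell shape on its own.

The `COOP` promoter can. It cycles through empty → NFAT-primed →
transcribing states: NFAT binds the empty promoter (rate $b_1 N$, off-rate
$u_1$), the ERK-induced factor converts the primed promoter into the
transcribing complex (rate $b_2 E$), and resolution of that complex
($u_2$) evicts both factors. In addition, on the NFAT-*free* promoter the
ERK-induced factor can occupy its element non-productively, occluding NFAT
recruitment; this occlusion is co-operative in $E$ and treated as a fast
equilibrium, scaling the priming rate by the unoccluded fraction
$1 - E^{h}/(K_{block}^{h} + E^{h})$. At high pulse frequency nuclear ppERK
is persistently high, the empty promoter is mostly occluded, and priming
stalls; at low frequency there are too few activation windows. The result
is a bell-shaped reporter frequency response even when receptor
internalization is negligible — frequency decoding by promoter logic rather
than by receptor feedback — and a non-monotonic dose–response under
constant stimulation at low internalization multipliers (0.5× and 0.001×).

*Caveat:* because occlusion acts on a signal (nuclear ppERK) that is nearly
saturated between 1e-7 and 1e-6 M GnRH under these defaults, the COOP
dose–response at 1× internalization is also mildly non-monotonic. The
package asserts the dose–response contrast only at the reduced
internalization multipliers above.

`simulate_reporter()` integrates the promoter occupancy (classical RK4 on
the dense output grid) and the linear reporter equation (exactly, by an
exponential step per grid interval) along any simulated time course.

## 5. Single-cell variability and mutual information

`population_spec()` + `simulate_population()` draw per-cell log-normal
scalings (median 1, coefficient of variation `cv`, default 0.3) of
designated parameters — by default the receptor and ERK totals — then run
the network (or a user-supplied response function) under constant
stimulation per stimulus level and record a single-time-point readout plus
optional additive Gaussian noise. All randomness is drawn up front from one
seed, so samples are reproducible.

`estimate_mi()` quantifies how well the single-cell response identifies the
stimulus level: responses are quantile-binned (default 16 bins), mutual
information is computed by the plug-in estimator, a jackknife bias
correction is applied (leave-one-out over distinct contingency cells,
weighted by cell counts), the corrected value is clamped to
$[0, H(\text{input})]$, and a stratified percentile bootstrap over cells
gives a confidence interval. A Kraskov-style nearest-neighbour estimator
for discrete stimulus / one-dimensional continuous response is available
via `method = "knn"`. With eight equally probable stimulus levels the input
entropy is exactly 3 bits; snapshot readouts of a noisy pathway transmit
far less, and because MI is invariant under monotone rescaling of the
response, adaptation that scales responses and spread together preserves
information, whereas adaptation that scales responses against a fixed noise
floor destroys it.

## 6. Provenance and configuration

`load_config()`/`validate_config()` accept YAML or JSON run configurations
(model choice, parameter overrides, protocol, gate, population, seed) with
strict unknown-key rejection, and attach an MD5 hash of the normalised
configuration. `write_timecourse()`/`write_scan()` emit CSVs with a
commented provenance header (package version, config hash, seed, solver
tolerances) that `read_prov_csv()` reads back. A thin command-line
interface (`inst/cli/gnrhpulse.R`) and annotated example configurations
(`inst/experiments/`) wrap the same functions.

## A worked scan

```{r example, eval = FALSE}
scan <- frequency_scan(network_params(int_mult = 16),
                       periods = c(5, 15, 30, 60, 120, 240, 480))
classify_shape(scan, "ca_auc")   # "bell_shaped"
optimal_period(scan, "ca_auc")
ggplot2::autoplot(scan)
```
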