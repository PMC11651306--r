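---
title: "Models and methods behind drgephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind drgephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`drgephys` implements the quantitative analysis used in whole-cell
patch-clamp studies of intrinsic adaptive plasticity in small-diameter
dorsal root ganglion (DRG) sensory neurons: action-potential (AP) waveform
metrology, rheobase and suprathreshold excitability, rule-based firing-
pattern classification, voltage-clamp current isolation, optogenetic
firing fidelity, and the supporting cohort statistics, including the
RNA-seq TPM filtering rules used for companion expression data. Because
real recordings from such experiments are not generally deposited, the
package ships a conductance-based neuron simulator whose cohorts — with
known ground truth — exercise every analysis stage.

## Measurement definitions

All measurements operate on a `sweep`: a recorded trace paired with its
command waveform at a fixed sampling rate (50 kHz by default). Units are
fixed at mV, pA, ms and pF throughout; sample 0 is protocol time 0 and
stimulus segments are half-open `[t_start, t_end)` intervals.

* **AP detection.** An AP is an upward crossing of a rate-of-rise
  criterion (default 10 mV/ms) followed by a voltage peak above 0 mV, with
  a 2 ms refractory period. The criterion value is not quantified in the
  experimental literature this package follows; the default is documented
  and configurable, and a curvature-maximum alternative
  (`method = "d2v"`) is provided. The threshold time is sub-sample
  interpolated on the dV/dt trace. Events are attributed to the stimulus
  epoch by their *peak* time, so an onset spike whose interpolated
  threshold lands a fraction of a sample before stimulus onset still
  counts.
* **Waveform metrics.** Amplitude is threshold-to-peak, overshoot is
  0 mV-to-peak; rise and fall are 10–90% times of the rising and falling
  phases and the half-width spans the two 50% crossings. All level
  crossings are linearly interpolated, and the 10/50/90% levels are
  referenced to amplitude on both phases (a symmetric convention, since
  only the rising-phase reference is pinned by the field's definitions).
  The falling-phase *shoulder* — the inflection carried by slow sodium
  current — is scored as the fraction of the 90-10% falling segment spent
  below a quarter of its peak repolarization rate (0 for a linear fall);
  the score is exploratory, while fall time and half-width are the
  quantitative surface.
* **Rheobase.** The peak command amplitude of the first sweep (ascending
  10 pA mouse / 100 pA human grid) with at least one detected AP in the
  stimulus epoch. Cells silent up to the cap (1 nA mouse, 10 nA human)
  are non-responders and carry the cap as their rheobase, alongside an
  explicit responder flag, so both the all-cells and responders-only
  summaries can be formed. For ramps, the instantaneous injected current
  at the threshold crossing is recorded as an auxiliary value.
* **Suprathreshold counts.** AP counts at 1–4× rheobase, with multiples
  snapped *down* to the discrete amplitude grid; a multiple beyond the
  cap is flagged absent rather than scored 0.
* **Firing subtypes.** `delayed` if the first AP at rheobase arrives
  ≥ 100 ms after stimulus onset; otherwise `single` if every available
  suprathreshold sweep carries exactly one AP inside the onset window;
  otherwise `repeated` if the suprathreshold sweeps fire within the onset
  window and any sweep fires ≥ 2 APs. The onset window defaults to
  100 ms, symmetric with the delayed rule — the experimental definition
  of "at the start of current injection" is not quantified, so the
  delayed rule's constant is reused.
* **Passive properties.** Resting potential is the mean over a 1 s
  zero-injection epoch, with the inclusion window −75…−40 mV applied
  before any group statistic. Input resistance is ΔV/I from a
  hyperpolarizing step, ΔV measured over the last 20% of the step with a
  residual-slope plateau check. Capacitance — measured with amplifier
  circuitry in the experiments — is estimated here from a
  mono-exponential fit to the charging transient, `C_m = tau / R_in`.
* **Optogenetic fidelity.** The fraction of light pulses followed by an
  AP threshold within 25 ms of pulse onset; "reliable" means exactly 1.0.

## Voltage-clamp stage

The leak is a linear fit of current against command voltage over a
subthreshold window (default −100…−80 mV on the ramp foot; −85…−55 mV for
the step family, where the −50 mV step already carries detectable sodium
window current). Samples after the stimulus epoch are excluded from the
fit because tail currents deactivating after the return to holding are
not leak. A nonlinearity check rejects contaminated windows. Peaks use
the raw corrected trace at full bandwidth (minimum-sample convention); a
deflection below 3 SD of the pre-stimulus baseline is reported as zero
with a flag. A-type current is isolated by prepulse subtraction — the
+40 mV test current after a −80 mV prepulse minus the current after a
+10 mV prepulse — and reported positive outward; read literally, the
source protocol sentence yields the negative of the A-current, so the
sign convention is fixed here and documented. The "brief" prepulse
defaults to 150 ms, long enough to fully inactivate the simulated
A-conductance at +10 mV (checked in the tests).

## The neuron model

No model equations are available from the experimental source, so the
simulator is this package's own single-compartment Hodgkin–Huxley-style
design, frozen in compiled code and pinned by regression tests; its
acceptance is behavioural (the calibration windows below), not kinetic.

\[
C_m \dot V = -\big(I_{NaF} + I_{NaS} + I_{Kdr} + I_{KA} + I_{leakK}
 + I_{leakNS} + I_{ChR2}\big) + I_{inj}(t) + \xi(t)
\]

with `I = g · (gates) · (V − E)` for each branch:

* `I_NaF = g_NaF · s · m³h · (V − E_Na)` — fast sodium with fast
  inactivation `h` (steep, half-inactivation −52 mV, floor 0.007 giving a
  small persistent component) and slow inactivation `s` (fast entry when
  depolarized, ~400 ms recovery near rest). `s` carries accommodation and
  the use-dependent failure at high stimulation rates.
* `I_NaS = g_NaS · m³h · (V − E_Na)` — slower sodium activating above
  −15 mV with a non-inactivating floor (`h` floor 0.16): its deactivation
  tail shapes the falling-phase shoulder and its window current carries
  the depolarized steady state under high bath potassium.
* `I_Kdr = g_Kdr · n⁴ · (V − E_K)` — high-threshold delayed rectifier
  with slow deactivation, producing the fast repolarization and the
  after-spike hyperpolarization that sustains repetitive firing.
* `I_KA = g_KA · a·b · (V − E_K)` — A-type current with slow activation
  (so it cannot reshape the ~1 ms spike itself), inactivation `b` with a
  small non-inactivating floor that provides sustained inter-spike
  outward current.
* Two leaks: K-selective (`E_K` from Nernst) and non-selective
  (`E = 0 mV`); `E_K = (RT/F)·ln(K_out/K_in)` is recomputed from the
  concentrations on every call with `RT/F = 25.7` mV (room temperature)
  and `K_in = 140` mM from the recording-pipette solution (120 mM
  K-gluconate plus KOH titration, documented as an approximation).
* `I_ChR2 = g_ChR2 · light(t) · V` — a square-pulse light-gated
  conductance with 0 mV reversal; no photocycle kinetics.

Integration is exponential Euler on the membrane and on every gate
(unconditionally stable for the conductance form), at 4 substeps per
50 kHz sample; membrane noise is additive, `sigma·sqrt(dt)` per substep
(default sigma 0.12 mV·ms^−1/2, about 0.2 mV RMS), current clamp only.
Before recording, each sweep is settled at its pre-stimulus condition:
stimulus families are held at −60 mV by an automatically computed bias
current (the experimenter's bias), zero-injection sweeps settle freely to
the model's own resting potential. A non-finite state raises an error
rather than emitting garbage. Voltage clamp is ideal — the membrane
follows the command exactly, with no series-resistance error and no
capacitive transient — and the recorded current is the sum of the
channels selected by a mask emulating the pharmacological isolation baths
(sodium-isolating: potassium channels off; potassium-isolating: sodium
channels off).

### Phenotypes and treatments

* `repeated` is the baseline cell: onset spike followed by sustained
  firing carried by the A-current floor and Kdr after-spike dynamics.
* `single` strengthens slow sodium inactivation (low floor, fast entry,
  more hyperpolarized midpoint): one onset spike, then accommodation at
  every suprathreshold amplitude.
* `delayed` multiplies the A-conductance by 9 and slows its
  inactivation: spike onset at rheobase is pushed well past 100 ms.
* `kcl24h` scales both sodium conductances by `s_Na = 0.45` (the
  homeostatic response to 24 h sustained depolarization; the measured
  effect is a sodium-current reduction) with an optional mild A-type
  increase (`s_A = 1.15`, reflecting a non-significant trend);
  `recovery` restores both scales to 1. `acute_kcl` changes only the
  bath potassium to 30 mM — depolarization purely via Nernst, with the
  persistent sodium window tuned so the steady potential sits near
  −18 mV without AP firing (the measured acute values are −15 ± 0.5 mV at
  5 min and −18 ± 1.3 mV after 24 h). `dark`/`hz1` add the ChR2
  conductance (0.8 nS default, deliberately near threshold: at 1 Hz
  every pulse fires, while at 10 Hz accumulated slow sodium inactivation
  causes failures, the model's account of frequency-limited firing
  fidelity).

### Cohorts and ground truth

A cohort draws per-cell base parameters (log-normal jitter, CV 0.15 on
conductances and 0.10 on capacitance) indexed by *cell position only*, so
treatment groups are matched — the same culture split across conditions —
and treatment scalings are applied on top. Phenotypes are drawn from a
configurable mixture (default 55% repeated, 30% single, 15% delayed).
Acquisition is adaptive, as an experimenter would run it: ramp and step
families ascend until the first responding sweep (or the cap), and the
step family then adds the snapped 2–4× rheobase sweeps.

Membrane-noise streams are seeded per `(cell, protocol family,
amplitude)`. Because the seed depends on the amplitude and not on the
sweep's position in a family, the sweep at, say, 250 pA is bit-identical
between the 10 pA acquisition grid and the 1 pA ground-truth search —
which makes the "pipeline rheobase never below the fine-grid truth"
property structural rather than statistical. The ground-truth search
itself first locates the lowest firing 10 pA decade by an ascending scan
(firing is not monotone at strong drive: depolarization block), then
bisects at 1 pA inside that decade.

The human preset scales capacitance to ~120 pF with all conductances
scaled proportionally — preserving the voltage dynamics and phenotypes
while moving rheobase onto the human 100 pA / 10 nA grid — and reuses the
mouse kinetics, since no species-specific kinetics are available.

## Calibration

The baseline parameters were calibrated, before any acceptance test was
written, against the study's stated operating points: control resting
potential near −57 mV (inside the −75…−40 mV inclusion window), acute
30 mM KCl steady potential inside −20…−10 mV, mouse rheobase in the tens
of pA on the 10 pA grid, each phenotype recovering its own label from the
classifier in ≥ 90% of jittered cells, the KCl-vs-control directions
(higher ramp rheobase, fewer responders, fewer 3–4× APs, more single
spikers, faster AP fall and narrower half-width, all reversed by
recovery), and the voltage-clamp behaviours (step-IV peak between −20 and
0 mV, linear conductance read-out, prepulse subtraction recovering the
analytic A-current). These are the conditions the synthetic cohorts
emulate; the tests then verify them at study scale (n = 30 per group for
the current-clamp contrasts, n = 20 per group for voltage clamp, 200
sweeps for detector-oracle agreement).

## What the synthetic data does and does not show

The generator emulates sweep-level structure (noise, adaptive families,
jittered cell populations, matched treatment groups) but not several
features of real recordings: electrode/access artefacts, capacitive
transients, seal leak, slow drift, calcium currents and
calcium-activated potassium currents (the real shoulder is partly
calcium-borne), channel noise, or temperature variation. Passing tests
therefore demonstrate that the *analysis* is correct and directionally
faithful on data with known ground truth — not that the model is a
validated biophysical account of DRG neurons. Group-level means from the
experiments (absolute rheobase values, AP counts and so on) come from
real mouse and human neurons and are not reproduction targets; the two
exactly recomputable published statistics (the responder-table exact
test, p = 0.0033, and the 63.2% non-responder share among single
spikers) are recomputed from the printed counts.

## Numerical choices and degenerate inputs

* Tolerances: leak-fit nonlinearity 5 pA; inward-peak noise floor 3 SD of
  baseline; capacitance fit fails (flagged, not guessed) when the
  deflection is under 5 noise SD or 0.5 mV, or when the exponential fit
  does not converge.
* Ties and boundaries: suprathreshold multiples snap down; a rheobase so
  high that 2–4× exceeds the cap yields absent counts; `density_at`
  requires an exact grid voltage; degenerate contingency tables (an
  empty margin) return p = 1 with a flag.
* The two-sided exact test is the conditional hypergeometric rule —
  summing all tables with point probability at most the observed one —
  the convention that reproduces the published p-value on the responder
  table; it is delegated to `stats::fisher.test` and verified against an
  independent enumeration oracle for every table with total ≤ 40.
* Benjamini–Hochberg adjustment delegates to `stats::p.adjust`;
  `log2(TPM + 0.2)` is used for the offset log transform (the base is
  this package's choice; the offset is the stated detection level).
* Protein-coding renormalization rescales each sample's protein-coding
  TPMs to sum to one million before the expression filter.

## Known limitations

* The simulator's kinetics are a design, not an inference; only its
  behaviours are calibrated. The split of sodium current into fast and
  slow branches is a modelling convenience, not a claim about channel
  subtypes.
* Ideal voltage clamp overstates what a real amplifier resolves; series
  resistance and space-clamp errors are absent by construction.
* The A-type/delayed-rectifier separation by prepulse subtraction leaves
  a small early delayed-rectifier onset transient in the difference trace
  when both channels are present; it is common-mode across treatment
  groups and does not affect group contrasts.
* Very strong drive produces depolarization block (single onset spike or
  silence); real cells do this too, but it means step families are not
  monotone in firing, which the ground-truth search accounts for.
* File-based exchange uses the plain-text bundle layout only (JSON
  metadata plus per-sweep CSV); binary acquisition formats are not read
  in this environment.
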