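---
title: "Methods: I_Kur variant modelling from channel to tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: I_Kur variant modelling from channel to tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, protocols and numerical choices behind
`ikursim`. It is the package's reference for *why* things are computed the
way they are; the README shows *how* to run them.

## The channel model

The ultra-rapid delayed rectifier K+ current I_Kur (Kv1.5, gene *KCNA5*) is
modelled with two Hodgkin–Huxley gates, an activation gate $a$ and a slow
inactivation gate $i$, and a voltage-dependent maximal conductance:

$$I_{Kur} = 0.64\,\Big(4.51 + \frac{1.90}{1+e^{(V-20.52)/-8.27}}\Big)\; a \, i \,(V-E_K).$$

Wild-type steady-state activation is the product of two Boltzmann factors
(half-voltages −17.67 and −8.45 mV, slopes −5.75 and −11.51 mV); steady-state
inactivation is a Boltzmann with amplitude 0.52, half-voltage 15.11 mV,
slope 7.57 mV and a floor of 0.46 — the *minimum availability* (MA), the
fraction of channels that never inactivate. Activation and inactivation time
constants are voltage-dependent sigmoid expressions divided by a Q10 factor
of 3.52, correcting room-temperature kinetics to body temperature. Because
the clamp data that constrain the activation kinetics show both fast- and
slow-activating cells, the time constants represent a weighted mean of the
two phenotypes; the synthetic-data generator can re-expand this into an
explicit fast/slow mixture (below).

**Units.** In the standalone clamp functions the conductance expression is
used as printed, so simulated clamp currents are consistent but arbitrary in
absolute scale; inside the cell models the same expression is interpreted as
a whole-cell conductance in nS and divided by the 100 pF membrane
capacitance, which puts peak I_Kur at a few pA/pF during an AP, in line with
the native I_Kur magnitudes of both cell models.

### The six variants

Six naturally occurring *KCNA5* variants are built in
(`kcna5_variants()`): three gain-of-function (D332H, E48G, A305T) and three
loss-of-function (Y155C, D469E, P488S). Each is described *relative to WT*
by additive half-voltage shifts, multiplicative slope-factor changes, an
additive MA change and a multiplicative conductance factor; kinetics (time
constants) are unchanged. `"D322H"` is accepted as an alias for D332H — both
spellings circulate; the table's canonical label is used and the ambiguity
is surfaced in the documentation rather than silently resolved.

Three representation choices deserve explanation:

* **Single-Boltzmann baseline for variant activation.** Variant changes are
  expressed against single-Boltzmann fits, but WT activation is a
  two-Boltzmann product. `apply_mutant()` therefore shifts the
  *WT-equivalent* single Boltzmann — the least-squares fit of the product
  over −60..+60 mV (the clamp range), computed once and cached
  (`wt_equivalent_activation()`). The WT model itself keeps the exact
  product.
* **Availability ceiling.** WT availability saturates at
  0.52 + 0.46 = 0.98, not 1. When a variant shifts the MA floor, the
  hyperpolarised ceiling (0.98) is preserved and the amplitude absorbs the
  change: the floor is a property of depolarised inactivation, not of
  resting availability. The fitting module correspondingly offers the
  unnormalised 4-parameter form alongside the conventional normalised
  (amplitude = 1 − MA) form.
* **Slope factors multiply k.** The Boltzmann form places $k$ in the
  exponent denominator; the tabulated "× factor" entries are taken as
  multiplying $k$ itself (a factor < 1 steepens the curve).

MA is clipped into [0, 1): for D469E and P488S applied to a gate with no
native floor (the Grandi-lineage native I_Kur), the negative MA change
clips to zero.

## Simulated voltage clamp and synthetic data

At a fixed clamp voltage both gates relax mono-exponentially, so clamp
traces are computed in closed form (no integration error). Protocol
defaults are conventional Kv1.5 settings: holding −80 mV, 1500 ms steps from
−40 to +60 mV in 10 mV increments for activation; a conditioning pulse
followed by a 500 ms test pulse to +60 mV for availability. The protocol in
the source experiments is not tabulated, so these defaults are explicit,
editable parameters. The I–V summary uses end-of-step current by default
(I_Kur inactivates slowly); a peak-current mode is available.

`generate_traces()` adds the features of real recordings that matter for
fitting: i.i.d. Gaussian noise per sample (no 1/f noise or capacitive
transients — out of scope), an optional linear leak, and an optional
fast/slow activation mixture `w·I_fast + (1−w)·I_slow` (defaults ×0.5 and
×2.0 with w = 0.5; the true underlying values are not published, so these
are explicitly arbitrary). Generation is bit-reproducible per seed. Because
the generator is analytic, passing fits on synthetic data demonstrate
correctness of the *fitting stage*, not robustness to artefacts absent from
the noise model.

`steady_state_points()` has two extraction modes. `"none"` mimics the
experimental analysis (end-of-step conductance normalised to its maximum;
test-pulse peak normalised to the maximal test pulse) and inherits its
biases — slow inactivation during the step and the voltage dependence of
the maximal conductance contaminate the activation estimate exactly as they
do in real recordings. `"truth"` divides out the known generating model's
conductance shape and the other gate's closed-form time course, yielding
exact gate values; parameter-recovery tests use it so that fitting error is
isolated from extraction bias.

## Curve fitting

Boltzmann and mono-exponential fits use bounded Levenberg–Marquardt least
squares (via `minpack.lm`) with five starts from a coarse slope grid and
tolerances of 1e−15, so exact synthetic inputs are recovered to near machine
precision; sigmoid fits from single starts are vulnerable to local minima.
Flat availability data yield the floor with `v_half`/`slope_k` flagged
unidentifiable as a warning (not an error) so batch fits proceed. The
activation-phase window for time-constant fits defaults to 5–95% of the
current rise, avoiding the stimulus edge and slow-inactivation
contamination. `derive_relative_changes()` is the exact algebraic inverse
of `apply_mutant()` on fitted parameters.

## Cell models

Two human atrial lineages are implemented in compiled code:

* `courtemanche` — the classic 21-state human atrial myocyte model, with
  its native I_Kur; `courtemanche_newIKur` replaces that current with the
  formulation above (this stands in for the updated-model lineage whose
  full regional/Ca modifications are published only in supplementary
  material and are not reproduced here).
* `grandi` — a 39-state compartmental model (junctional/subsarcolemmal/
  cytosolic spaces, GHK L-type Ca current, RyR release with luminal
  regulation, explicit Na and Ca buffering), reconstructed from its
  original publication lineage. Bulk K+ is held constant, as in the
  original.

Variant I_Kur parameters enter the Courtemanche lineage either through the
new formulation (`courtemanche_newIKur`) or as shifts to the native I_Kur
gate Boltzmanns; the Grandi lineage always uses its native I_Kur kinetics
with the WT-relative shifts applied to the gate steady states and
conductance.

### Regional, chronic-AF and beta-adrenergic variants

These parameter sets live in supplementary material of the source
literature that is not available here; the package ships editable,
explicitly **provisional** sets:

* **Regions** (`regional_scalings()`): relative to RA, the crista
  terminalis (CT) carries more L-type Ca current and less transient
  outward current (prominent dome, longer APD, higher EAD susceptibility);
  the pectinate muscles (PM) the opposite. The CT I_CaL factor (1.32) was
  chosen as the largest value on a 0.02 grid for which the CT half of an
  isoprenaline-treated heterogeneous strand still repolarises within one
  500 ms S1 cycle — i.e. the strongest CT phenotype that keeps the tissue
  in the physiologically documented regime of EAD-prolonged but
  *terminating* action potentials. Larger values tip the reconstructed CT
  into sustained plateau oscillation, which the source observations rule
  out.
* **Chronic AF**: the Grandi lineage has a native remodelling flag (I_to
  −70%, I_Kur −50%, I_K1 +100%, I_CaL −50%, NCX +40%, among others); the
  Courtemanche lineage uses the standard remodelling set (I_CaL and I_to to
  35%, I_Kur halved, I_K1 doubled).
* **Isoprenaline (1 uM)**: implemented natively in the Grandi lineage
  (I_CaL permeability ×1.5 with a −3 mV activation shift, I_Ks ×3 with a
  −40 mV shift, I_Kur ×3, Na/K-pump Na affinity +33%, SERCA Kmf halved,
  troponin koff ×1.5) and transferred to the Courtemanche lineage as the
  same fractional changes to the homologous currents. A speculative RyR
  sensitisation term was considered and dropped: it pushed even the WT
  model into steady-state EADs, contradicting the documented behaviour of
  this model lineage (no EADs without I_Kur loss).

**ISO application is acute.** Pacing a cell chronically with ISO drifts
slowly (Na loading over tens of seconds). Experiments apply ISO as a
wash-in; the package does the same: `ead_scan()` and the S1S2 machinery
precondition without ISO and then switch the ISO parameter set on
(`acute_iso = TRUE`).

### AP metrics and EAD detection

The upstroke is the first rising −40 mV crossing after a stimulus; APD_x
runs from the upstroke to x% repolarisation between the AP peak and the
pre-stimulus diastolic voltage (a rate-robust diastolic reference). Traces
are sampled at 0.5 ms, comfortably within the 1 ms accuracy used for APD
reporting. An EAD is a local voltage minimum followed by a local maximum
with ≥ 2 mV prominence, between the AP peak and the terminal −40 mV
crossing; the *first* post-peak pair is excluded by default because it is
the physiological phase-1 notch/dome, not an EAD (`skip_dome = FALSE`
restores the raw count). The prominence threshold and window are detector
choices — no standard definition exists.

## Tissue simulation

Excitation spreads by the monodomain reaction–diffusion equation
$\partial_t V_m = \nabla\!\cdot\!(D \nabla V_m) - I_{ion}/C_m$, discretised
with explicit finite differences: harmonic-mean face diffusion coefficients
(the conservative choice at heterogeneous interfaces), no-flux boundaries
by mirrored ghost nodes, and cell dynamics advanced in lock-step at the
same dt (Rush–Larsen exponential updates for voltage gates over per-run
lookup tables at 0.02 mV resolution; forward Euler elsewhere). With D = 0
every node reproduces the isolated cell bit-for-bit, which the tests use as
a coupling-off oracle. Default steps are 0.01 ms (Courtemanche lineage) and
0.005 ms (Grandi lineage); halving dt changes APD90 by < 1 ms. The
measured spatial-discretisation sensitivity of conduction velocity at the
default 0.25 mm spacing is about 5% per dx halving, so every CV comparison
(calibration, scaling laws) is made at one fixed spacing. The dt must satisfy the diffusion stability
bound dx²/(2 max D) in 1D (dx²/4D in 2D); `solve_cable()` enforces it.

* **Strands** default to 50 mm at dx = 0.25 mm (200 nodes) — strand length
  and spacing are not stated in the source literature, so they are
  declared defaults. The scalar D is calibrated by bisection against a
  fibre-direction conduction velocity of 1.3 m/s, measured between the 25%
  and 75% positions from rising −40 mV crossings.
* **The CT/PM junction** is a half-CT/half-PM strand. The S1S2 protocol
  applies 7 S1 at 500 ms then an S2 to a 3.3 mm-radius segment at the
  junction; stimulus amplitude is twice the *measured* diastolic threshold
  at the site (2 ms pulses), since a fixed nominal amplitude can
  under-drive a site whose neighbourhood is an electrotonic sink. The
  post-S1 state is cached once; each S2 trial resumes from it. The
  vulnerability window (VW) is the S2 range classified unidirectional
  (wave reaches one strand end but not the other), located by a coarse
  scan plus bisection of both boundaries to 1 ms; non-contiguous coarse
  outcomes raise a warning. Strand-end classification is used (sensor
  depth in the source geometry is unstated).
* **The SAN surrogate** is a periodic suprathreshold stimulus train
  (default 750 ms cycle length) on a central segment of a
  PM–CT–SAN–CT–PM strand; a detailed sinoatrial node model is out of
  scope, and the node serves only as a sinus-rhythm driving force. Beats
  are labelled conducted/blocked per direction by whether each wavefront
  reaches the strand ends.
* **2D sheets** replace anatomical geometry at desk scale (default
  160×160 nodes at 0.25 mm = 40 mm square; geometry effects are
  acknowledged as lost). Re-entry is initiated by the phase-distribution
  method: full-state snapshots across one paced AP cycle
  (`build_phase_library()`, ≥ 32 snapshots recommended) are distributed
  over the sheet by a linear or Archimedean-spiral phase layout; a uniform
  layout is the no-wave control. The diffusion scale (100% control down to
  40%, severe remodelling) models gap-junction/structural remodelling.
  Dominant frequency (DF) is the peak of the mean-removed, Hann-tapered
  periodogram above 0.5 Hz over an analysis window ≥ 2 s (resolution
  1/window); re-entry is *sustained* if activity persists into the final
  250 ms, and *lifetime* is the last activation anywhere in the field.
  The sheet's base diffusion is deliberately lower than the fibre-direction
  calibration: an isotropic sheet uses an effective mean diffusivity, and
  the excitation wavelength must fit the desk-scale domain for re-entry to
  be studied at all.

## Reproducibility and problem sizes

Every simulation is deterministic; only the synthetic-clamp generator
consumes randomness, through an explicit seed. Tests and the acceptance
script use 200-node strands, 100-node-scale sheets, and conditioning trains
of 20–100 beats; these sizes were chosen as the smallest at which the
measured quantities are converged (dt/dx halving criteria above), and the
vignette states them so results can be reproduced exactly.

## Known limitations

* The Grandi-lineage model is a reconstruction from its publication
  lineage; regional/ISO/cAF sets are provisional where the original
  supplements are unavailable. One documented consequence: D469E with ISO
  produces EADs in the reconstructed RA cell, where the source
  observations report them only in CT — the RA distinction between D469E
  (conductance ×0.546) and Y155C (×0.475 with kinetic shifts) is a
  knife-edge a few percent of plateau I_Kur wide, inside the uncertainty
  of the reconstruction. The sensitivity of EAD production to the CT
  I_CaL scaling is similarly steep (the regime boundary sits between
  scalings of 1.32 and 1.34).
* **Vulnerability-window sensitivity.** The D469E-plus-ISO CT/PM window is
  the quantity most sensitive to the provisional parameters. Across the CT
  I_CaL scalings 1.20–1.32 and the protocol-conditioning variants explored
  during development, the upper window boundary ranged from roughly 380 to
  690 ms. A window whose upper boundary sits near 690 ms with a width of
  several hundred milliseconds requires CT refractoriness prolonged by
  EADs while the CT remains paceable and free of spontaneous firing; in
  this reconstruction those two regimes overlap only marginally — CT
  scalings large enough for strong EAD prolongation also support
  spontaneous CT activity, which invalidates the S1S2 classification at
  long coupling intervals. The shipped defaults therefore yield a smaller,
  earlier window than the source observations, and the acceptance script
  reports whatever the frozen configuration produces rather than a tuned
  value.
* In the new-I_Kur (Courtemanche-lineage) cell, all three loss-of-function
  variants slightly shorten APD90 (~285–289 ms vs 311 ms WT at 1 Hz) even
  though they raise APD30 and the plateau; terminal-repolarisation
  interactions with I_Kr/I_Ks make the APD90 direction model-dependent, so
  the loss-of-function shift of the vulnerable S2 range toward longer
  coupling intervals is not reproduced in that lineage.
* No fibre anisotropy, fibrosis, atrial dilation or 3D anatomy; no
  spontaneous Ca-release (delayed-after-depolarisation) mechanisms; no
  Markov channel models or state-dependent drug block.
* Temperature enters only through the single Q10 factor of the new I_Kur
  formulation.
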