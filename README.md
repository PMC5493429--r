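# ikursim

Multi-scale in-silico analysis of the atrial ultra-rapid delayed rectifier
potassium current **I_Kur** (Kv1.5, gene *KCNA5*) and six naturally occurring
gain- and loss-of-function variants, for cardiac electrophysiologists and
modellers studying atrial-fibrillation substrates.

The package spans four scales:

1. **Channel** — a Hodgkin–Huxley formulation of I_Kur with a
   voltage-dependent maximal conductance,

   I_Kur = 0.64 · (4.51 + 1.90 / (1 + e^((V−20.52)/−8.27))) · a · i · (V − E_K),

   two-Boltzmann steady-state activation, inactivation with a
   minimum-availability floor, and Q10-corrected (×3.52) time constants.
   The six variants (D332H, E48G, A305T gain-of-function; Y155C, D469E,
   P488S loss-of-function) are WT-relative parameter changes: half-voltage
   shifts, slope-factor and conductance factors, and a minimum-availability
   change.
2. **Voltage clamp** — closed-form simulated clamp protocols, a synthetic
   clamp-data generator with known ground truth (noise, leak, fast/slow
   activation mixtures), and Boltzmann / mono-exponential fitting that
   recovers the variant table by a generate–fit–difference round trip.
3. **Cell** — two human atrial action-potential models (Courtemanche-lineage,
   21 states, optionally carrying the new I_Kur; Grandi-lineage, 39 states)
   with regional (RA/CT/PM), chronic-AF and 1 µM isoprenaline variants;
   pacing, APD/restitution metrics and early-after-depolarisation (EAD)
   detection.
4. **Tissue** — explicit monodomain solvers in 1D and 2D: conduction-velocity
   calibration, S1S2 vulnerability windows at the crista-terminalis /
   pectinate-muscle junction, sinus-driven conduction patterns, and
   phase-distribution-initiated re-entry with dominant-frequency analysis.

See `vignettes/ikursim-methods.Rmd` for the models, protocols, numerical
choices, and known limitations (the regional/ISO/chronic-AF parameter sets
are explicitly provisional reconstructions).

## Worked example

Recover the D469E variant's WT-relative changes from synthetic clamp data,
then measure its cellular effect:

```r
library(ikursim)

wt  <- fit_channel_variant("WT")
mut <- fit_channel_variant("D469E")
unlist(derive_relative_changes(wt, mut))
#>    d_vhalf_act   k_act_factor  d_vhalf_inact k_inact_factor           d_ma
#>  -4.440892e-15   1.000000e+00   4.545000e+00   8.420000e-01  -9.300000e-02
#>       g_factor
#>   5.460000e-01
```

The recovered record is the built-in D469E row (inactivation half-voltage
+4.545 mV, slope ×0.842, minimum availability −0.093, conductance ×0.546)
to machine precision; with noisy traces the errors grow with the noise level (see the
parameter-recovery tests).

```r
cell <- build_cell("courtemanche_newIKur", mutation = "WT")
tr   <- pace(precondition(cell, 20, 1000), pacing_protocol(n_s1 = 1))
measure_ap(tr, 1)[, c("rmp", "peak_v", "apd90")]
#> # A tibble: 1 × 3
#>     rmp peak_v apd90
#>   <dbl>  <dbl> <dbl>
#> 1 -81.0   30.4   311
```

A 1 Hz action potential with resting potential −81 mV and APD90 ≈ 311 ms —
the expected Courtemanche-lineage morphology with the new I_Kur. Calibrating
a 50 mm strand to the physiological fibre-direction conduction velocity:

```r
cfg <- cable_config(cell, n_nodes = 200, dx = 0.25)
cal <- calibrate_diffusion(cfg, target_cv = 1.3, tolerance = 0.01)
c(D = cal$D, cv = cal$cv)
#>        D       cv
#> 0.713750 1.298701
```

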