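# fibrilsite

Amyloid fibrils of α-synuclein and other aggregation-prone proteins carry
long tubular cavities running along the stacked cross-β layers of each
protofilament. Small planar compounds such as the diaryl-pyrazole
anle138b can bind *inside* these cavities, where they translate along the
fibril axis in discrete steps and form polar contacts with the exposed
backbone ladder. `fibrilsite` implements the post-processing that
characterizes such internal binding from molecular-dynamics trajectories
and from solid-state NMR peak lists, for structural biologists and
simulators studying fibril–ligand interactions:

- **Contact maps** — per-residue contact probabilities under the
  heavy-atom (≤ 0.4 nm) and pyrazole-nitrogen/backbone (≤ 0.5 nm) rules,
  averaged over time and then over independent trajectories, with the
  edge β-strands excluded.
- **Polar bonds** — geometric hydrogen-bond detection
  (d(D···A) ≤ 0.35 nm, ∠D–H···A ≥ 150°) and halogen-bond detection
  (d(Br···O) ≤ 0.36 nm, ∠C–Br···O ≥ 150°).
- **Binding modes** — per-frame heuristic classification: I unbound,
  II partially bound (< half of the 21 ligand heavy atoms in contact),
  III bound without polar bonds, IV polar interactions (sub-typed IVa
  pyrazole HB, IVb benzodioxole HB, IVc bromophenyl XB).
- **Free-energy profiles** — Boltzmann inversion of the insertion-depth
  occupancy, *G(x) = −RT ln p(x)* at *T* = 300 K, with the profile
  minimum at zero, empty bins masked, and SEM across trajectories.
- **Dwell-time kinetics** — hysteresis-based detection of committed hops
  between β-strand registration sites and cumulative dwell-time
  statistics, with censored first/last dwells flagged.
- **RMSF contrasts** — per-residue root-mean-square fluctuations with
  optional core-backbone superposition, averaged per strand class
  (ligand-contacting vs. distant rungs), excluding edge strands.
- **NMR perturbation** — per-residue chemical-shift perturbation (mean
  |Δδ| over HN, N, Cα, Cβ), bound/free intensity ratios (a vanished
  bound peak counts as 0), and a 2-residue moving average.

A first-class synthetic-data module (`build_toy_fibril()`,
`simulate_hopping()`, `sample_boltzmann_depths()`,
`generate_peak_tables()`) generates toy fibrils, continuous-time
Markov-jump ligand trajectories and paired peak tables with *exactly
known* ground truth, so the whole chain is testable without any
external download.

## Worked example

Simulate a ligand hopping through a 12-layer toy fibril, then recover
its thermodynamics and kinetics:

```r
library(fibrilsite)

fib <- build_toy_fibril(n_layers = 12, residues_per_layer = 6)
lig <- anle138b_topology()
spec <- hopping_spec(n_sites = 10, site_spacing = 0.48,
                     rate_up = 0.25, rate_down = 0.25,
                     jitter_sigma = 0.048, n_frames = 5000, seed = 1)
hop <- simulate_hopping(spec, lig, fib)
ens <- discard_equilibration(hop$ensemble, 0.25)   # keep the last 75 %

d <- depth_series(ens, lig, fib)
free_energy_profile(d, bin_width = 0.05)
#> free_energy_profile: 66 occupied / 93 bins, G range 0 - 14.44 kJ/mol (T = 300 K)

ax <- depth_series(ens, lig, fib, projection = TRUE)
ev <- detect_dwell_events(ax, site_spacing = 0.48, origin = 0.48)
sm <- dwell_time_summary(ev)
#> mean dwell 2.30 +/- 0.17 ns over 163 events

mode_populations(classify_frames(ens, lig, fib))
#>           mode fraction sem
#> 1    I_unbound    0.000  NA
#> 2   II_partial    0.000  NA
#> 3 III_no_polar    0.396  NA
#> 4     IV_polar    0.604  NA
```

The input rates (0.25/ns up and down, i.e. a 0.5/ns total exit rate)
imply a 2 ns mean dwell; the detected 2.30 ± 0.17 ns reflects the
longer dwells at the reflecting end sites and the merging of hops
shorter than the 0.1 ns frame spacing. The deep minima of the profile
are the β-strand registration sites of the jitter-broadened occupancy.
The ligand, placed inside the cavity, is classified III or IV in every
frame, IV whenever a pyrazole hydrogen bond or bromophenyl halogen bond
to the channel-lining backbone is present.

The NMR branch works the same way on paired peak tables:

```r
pk <- generate_peak_tables(20,
        perturbation_spec(c(68:70, 74), attenuation_factor = 0.5, seed = 2),
        residue_start = 60, glycine_residues = c(67, 68))
pt <- perturbation_table(pk$free, pk$bound)
pt[pt$residue %in% 66:71, c("residue", "csp_ppm", "intensity_ratio")]
#>    residue csp_ppm intensity_ratio
#> 7       66   0.000             1.0
#> 8       67   0.000             1.0
#> 9       68   0.107             0.5
#> 10      69   0.100             0.5
#> 11      70   0.100             0.5
#> 12      71   0.000             1.0
```

Perturbed residues recover the configured attenuation (0.5) exactly and
a CSP equal to the mean of the per-nucleus offsets (0.1 ppm over four
nuclei; 0.107 ppm at the glycine-like residue 68, which has no Cβ).

Whole runs can also be driven from a single YAML config via
`run_pipeline()` (or `inst/scripts/fibrilsite.R` from a shell), which
writes every stage's CSV plus a manifest with the seed and config
checksum.

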