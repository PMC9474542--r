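---
title: "Methods: quantifying ligand binding inside fibril cavities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ligand binding inside fibril cavities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilsite)
```

`fibrilsite` analyzes how a small planar compound behaves inside the
tubular cavity of an amyloid protofilament: where it sits, which polar
contacts hold it, how it hops between β-strand rungs, and how its
presence shows up in solid-state NMR observables. This vignette explains
the models and conventions behind each stage, the tunable parameters,
and what the synthetic generators do and do not emulate.

## Coordinates, layers and the protofilament axis

All internal coordinates are **nm** (the natural unit for the contact
cutoffs used throughout); PDB and XYZ I/O converts from/to Å. Residue
numbering is taken verbatim from the input and never rewritten, so
α-synuclein-style numbering is preserved.

A protofilament is a stack of β-strand copies ("layers" or rungs) at
~0.48 nm spacing. `assign_layers()` maps chains (or explicit residue
blocks) to layers and renumbers them 0…L−1 by centroid position along
the stack's leading principal component, so layer order is geometric,
not file order. `protofilament_axis()` builds the axis direction as the
normalized mean of backbone N→H unit vectors of every 2nd residue
(default start residue 36, span 36–56): in a cross-β sheet those amide
vectors point along the inter-rung hydrogen bonds, and the stride of 2
keeps only the alternating set that faces one side of the strand. The
exact span of the folded N-terminal region is a free choice; we default
to the contiguous N-terminal β-region and expose it in
`axis_definition()`. The sign is oriented from layer 0 toward the last
layer, so reversing the layer order flips the axis.

**Insertion depth** *x* is the distance between the mass-weighted
centroid of the ligand's pyrazole ring and the mass-weighted centroid
of the tip (edge) layer. Whether the original analyses used mass or
geometric weighting is not determinable from the reported methods;
mass weighting is the default and `mass_weighted = FALSE` gives the
alternative (for a near-symmetric aromatic ring the difference is well
below the bin width). Which edge is "the tip" is likewise
configurable; profiles from either choice are mirror images.

## Equilibration trimming

`discard_equilibration()` removes the first ⌊fraction·n⌋ frames of each
trajectory independently; the default fraction 0.25 keeps the last 75 %
of the data, the usual guard against initial relaxation. With very
short series the floor convention retains everything (3 frames at 0.25
→ 0 discarded).

## Contacts and polar bonds

Two contact definitions are implemented exactly as stated quantities:

* **heavy-atom contact**: any non-hydrogen ligand atom within 0.4 nm of
  any non-hydrogen atom of a residue. Hydrogen is identified by
  element, not by atom name.
* **nitrogen/backbone contact**: either pyrazole ring nitrogen within
  0.5 nm of a backbone carbon or nitrogen. Whether Cα counts as a
  "backbone carbon" is ambiguous; it is included by default
  (`include_ca = FALSE` restricts to the carbonyl carbon and N).

Detection uses a cell-list neighbor search (cells of edge = cutoff, 27
neighboring cells inspected) with distances compared as exact squared
values, so it is bit-identical to an all-pairs scan — the test suite
enforces this equivalence on random frames.

Hydrogen bonds are decided geometrically: donor–acceptor heavy-atom
distance ≤ 0.35 nm and D–H···A angle ≥ 150° (180° = linear). Halogen
bonds: Br···O distance ≤ 0.36 nm and C–Br···O angle at the bromine
≥ 150° — the angle convention in which a perfectly linear arrangement
is 180°, the only reading under which a ≥150° threshold is meaningful.
The literature formula originally used for hydrogen-bond *energies* is
not reproducible from the reported methods; since only bond *presence*
enters the binding-mode classification, energies are reported through a
pluggable model (`polar_bond_criteria(hb_energy_model=)`) whose default
(`hb_energy_default()`, an exponential-distance × cos² angle form) is
explicitly a non-canonical surrogate for ranking, not a calibrated
energy.

Ligand donor/acceptor inventory: the pyrazole N–H donates; the pyrazole
nitrogens and benzodioxole oxygens accept from backbone amides; the
bromine bonds to backbone carbonyl oxygens. Protein sidechain O/N
acceptors are included by default and separable by flag. Edge-strand
layers are excluded from all contact reporting by default, because
partially frayed end rungs are not representative of the lattice
environment. Analyses assume whole (unwrapped, centered) molecules; no
minimum-image convention is applied.

**Contact maps** average the per-residue contact indicator over frames
first, then over independent trajectories, so each trajectory carries
equal weight regardless of length; SEM is across trajectories.

## Binding modes

Each frame is classified from its heavy-atom contact count *n* (of the
21 ligand heavy atoms) and its polar bonds: I unbound (*n* = 0), II
partially bound (*n* < 10.5), III no-polar (*n* ≥ 10.5, no HB/XB), IV
polar (≥ 1 HB or XB), with sub-labels per moiety (IVa pyrazole HB, IVb
benzodioxole HB, IVc bromophenyl XB). When a polar bond coexists with a
low contact count the polar definition wins (the mode list defines IV
by bond presence with no contact qualifier), so the major modes always
partition the frames. Populations are trajectory-means of
per-trajectory frame fractions.

## Free-energy profile by Boltzmann inversion

Depth samples pooled over trajectories are histogrammed into bins of
width 0.05 nm (a free choice: roughly a tenth of the layer spacing, so
per-rung minima are resolved; configurable). Each bin's occupancy
probability *p* gives *G = −RT ln p* with *T* = 300 K
(RT = 2.494 kJ/mol). The profile is a *relative* free energy: it is
shifted so the minimum over occupied bins is zero, and bins with zero
counts are masked as missing rather than set to zero (zero occupancy is
absence of evidence, not infinite energy). The SEM per bin is computed
across per-trajectory profiles, each aligned to zero minimum —
block-averaging within one long trajectory would also be defensible;
cross-trajectory scatter was chosen because the intended inputs are
sets of independent simulations.

The generator–analyzer pair is self-inverse: depths drawn by
`sample_boltzmann_depths()` (inverse-CDF sampling on a 4096-point grid
of a piecewise-linear potential) and analyzed by
`free_energy_profile()` recover the input potential. With 2×10⁵ samples
over a 6 kJ/mol barrier the RMS mismatch on bins with *p* > 0.01 is
≈ 0.05–0.08 kJ/mol (the acceptance script recomputes this), and an
800/200 two-bin split reproduces ΔG = RT ln 4 = 3.458 kJ/mol to
printed precision.

## Dwell-time kinetics

Hops between β-strand registration sites are read off the axial
displacement of the pyrazole centroid. Sites sit at
`origin + k·spacing`; a transition is *committed* only when the signal
enters the inner half of the new site's cell (`core_fraction = 0.5`)
and stays assigned there for `min_residence_frames` (default 1). This
hysteresis suppresses jitter-induced recrossing counts without
smoothing the signal. Dwell time is the time between committed
transitions; the first and last dwell of every series are flagged
censored and excluded from means by default (they are cut off by the
observation window and bias the mean downward; a flag includes them).

Resolution limits are inherent: dwells shorter than the 0.1 ns frame
spacing can never be observed, which removes ~2.5 % of exponential
2 ns dwells and up to twice that fraction of transitions (a missed
intermediate visit hides two hops). The recovered mean dwell is
correspondingly a few percent high. The detector with
`core_fraction = 1` and zero jitter reproduces the simulated ground
truth event-for-event, up to one frame interval per boundary.

The axial projection is the default coordinate for site detection; the
scalar centroid distance (the same series used for the free-energy
profile) can be substituted where strict parity with a scalar-depth
convention is wanted.

## RMSF

Per-atom RMSF is √⟨|r − ⟨r⟩|²⟩ over frames, after optional least-squares
(Kabsch) superposition of the core-layer backbone onto the trajectory's
first retained frame. Per-residue values average the backbone heavy
atoms (N, Cα, C′, O); strand-class profiles (ligand-contacting vs.
distant rungs) average over the core rungs of each class, excluding the
two edge layers, whose fraying would dominate. SEM is across
trajectories. Under isotropic per-coordinate jitter σ the per-atom RMSF
is σ√3, which the tests verify at σ = 0.05 nm to within 3 %;
superposition can only reduce RMSF for rigid-body noise.

## NMR perturbation mapping

CSP per residue is the unweighted mean of |Δδ| over the nuclei shared
by both tables among HN, N, Cα, Cβ — deliberately without
nucleus-specific scaling, following the plain-average convention; a
weighted variant can be layered on top by rescaling the input shifts.
Absolute differences are used (the sign of a shift change carries no
magnitude information for this map). Intensity ratios are bound/free
per matched peak, averaged over nuclei; a bound peak absent while the
free peak exists contributes ratio 0, encoding "attenuated beyond
detection" — the interpretation that disappearing signals reflect
increased local dynamics. The 2-residue moving average is trailing
(window [i, i+1], reported at i; alignment is a convention choice) and
missing-aware.

## The synthetic generators — what they emulate

* `build_toy_fibril()` builds an idealized lattice: identical rungs
  translated along +z at a 0.48 nm rise (the canonical cross-β
  stacking distance; configurable), six atoms per residue (five backbone
  atoms + one sidechain pseudo-atom), all N–H vectors along +z and all
  carbonyl oxygens at a fixed cavity radius. It reproduces the
  *bookkeeping* structure real fibrils impose (layers, backbone roles,
  a polar-lined channel), not β-sheet stereochemistry, twist, or
  sidechain packing.
* `simulate_hopping()` realizes the discrete translational motion as a
  continuous-time Markov jump process (Gillespie-sampled exponential
  waiting times, reflecting ends), discretized at the frame interval,
  with isotropic Gaussian jitter added *after* discretization so the
  ground-truth event list is exact by construction. At the reflecting
  end sites the outward rate is simply absent, which keeps the
  symmetric-rate stationary occupancy exactly uniform; the price is
  that end-site dwells are longer (their total exit rate is halved),
  so kinetics checks use enough interior sites to keep that
  contribution small. Censored dwells are flagged, never silently
  dropped.
* `generate_peak_tables()` draws realistic backbone shifts
  (HN 8.3 ± 0.4, N 119 ± 4, Cα 58 ± 3, Cβ 35 ± 6 ppm) and lognormal
  intensities, then applies the configured shift offsets, attenuation
  factor and noise to the bound state of the perturbed residues;
  glycine-like residues omit Cβ.

Passing tests on these generators show that the *analysis chain* is
correct and self-consistent; they do not validate force fields,
sampling convergence, or spectral fitting, which are upstream of this
package. All generators are bit-reproducible under a fixed seed.

## Numerical choices and degenerate inputs

* Distance thresholds compare exact squared distances (boundary
  counts as inside); no epsilon is added, so neighbor-search and
  brute-force routes agree bit-for-bit.
* A single-frame trajectory yields RMSF 0 with a warning; an all-NA
  smoothing window stays missing; zero free intensity is skipped with
  a warning rather than producing an infinite ratio.
* A profile whose samples fall in one bin is defined on that bin with
  G = 0. Doubling the bin width can only merge, never unmask, empty
  regions.
* Problem sizes used by the tests and the acceptance script — 2×10⁵
  Boltzmann samples, 25 000-frame hopping runs (~1 200 dwell events),
  10⁴-frame jitter ensembles — were chosen so statistical errors sit
  well below the assertion tolerances.

## Known limitations

* No periodic-boundary handling: trajectories must be whole and
  centered before analysis.
* The HB energy scale is a labeled surrogate; only bond presence is
  calibrated against stated criteria.
* Dwell detection cannot see sub-frame events (see above); transition
  counts are accordingly ~4–5 % low at a 2 ns mean dwell and 0.1 ns
  sampling.
* The toy fibril has no twist, no sequence, and no sidechain
  chemistry; contact maps on synthetic data exercise the machinery,
  not biology.
* GROMACS binary trajectory formats and mmCIF are not read; convert to
  multi-model PDB or XYZ first.
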