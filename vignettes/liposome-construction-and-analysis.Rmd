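---
title: "Building and analysing coarse-grained spherical liposomes"
author: "vesica"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analysing coarse-grained spherical liposomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesica)
```

# Scope and model

`vesica` constructs whole spherical coarse-grained liposomes of DPPC,
DOPC or POPC and prepares the complete input set for portion-selective
heating simulations in a GROMACS-compatible molecular-dynamics engine:
a structure file (GRO), an index file (NDX) whose three groups — the
inner water core, the lipid bilayer and the outside water — are the
temperature-coupling groups (`tc-grps`), a topology (TOP referencing a
packaged ITP parameter file) and run-parameter files (MDP).  It also
implements the analyses used to characterise how the vesicle responds
when one portion is heated: molecular radial distributions, vesicle
area per lipid (APL), mean-square displacement and diffusion
coefficients, group–group nonbonded energies, tail kink angles,
end-to-end tail distances, and spherical pore (notch) detection.

The package does **not** integrate equations of motion.  Energy
minimisation, equilibration and the long heated production runs are
delegated to the external engine; `vesica` emits their exact inputs and
consumes their outputs.

## The coarse-grained lipid model

Each phosphatidylcholine lipid is a 12-bead chain in the MARTINI 2.x
style: bead 1 is the choline head (+1 e), bead 2 the phosphate (−1 e),
beads 3–4 the glycerol linkers, beads 5–8 tail A and beads 9–12 tail B,
so the two tail *end beads* are beads 8 and 12.  One water bead stands
for four water molecules and is uncharged — which is why every
lipid–water Coulomb energy in this toolkit is *exactly* zero, a useful
structural zero that the test-suite asserts on every built system.

Bonded terms are harmonic bonds (default `b0` = 0.47 nm,
`k` = 1250 kJ/mol/nm²) and cosine-harmonic angles
(`U = k/2 (cos θ − cos θ₀)²`).  Saturated angle triples use θ₀ = 180°,
`k` = 25 kJ/mol; the triple centred on a *cis*-unsaturated bead (the
"C3 kink", bead 7 and/or 11, the third bead of each tail) uses
θ₀ = 120°, `k` = 45 kJ/mol.  DPPC is fully saturated, DOPC carries the
kink on both tails, POPC on tail B only — placed on the sn-2 chain by
the chemistry of POPC; the mapping drawings this choice would be read
from are not available to us, so the placement is a documented package
decision rather than a transcription.  Nonbonded parameters (pairwise
σ/ε, relative dielectric ε_r = 15, cutoff 1.2 nm for both LJ and
Coulomb) ship as a plain-text ITP file under `inst/extdata/`, written
by us following the published MARTINI 2.x interaction-level scheme.
Parameters are data, not code: point the readers at a different file to
substitute a force-field revision.

# Vesicle construction

## Leaflet populations from the area per lipid

A leaflet holding `N` lipids on a sphere of radius `r` at area per
lipid `APL` satisfies `N = round(4 π r² / APL)`.  The defaults are a
30 nm outer-diameter vesicle at `APL` = 0.46 nm² in a 40 nm cubic box;
the leaflet reference radii (13.701 nm outer, 11.540 nm inner) are
obtained by inverting the formula at the target populations — 5128
outer-leaflet and 3638 inner-leaflet lipids — because the diameter
alone does not determine the two counting surfaces.  For other
diameters the same fixed offsets are applied
(`r_out = D/2 − 1.299 nm`, `r_in = r_out − 2.161 nm`), and both radii
remain user-settable.

A deliberate geometric choice: the reference sphere anchors the
**phosphate bead** (bead 2) of each lipid.  The APL analysis defines
each leaflet's radius as the mean radial distance of the phosphate
beads, so with phosphate anchors the builder and the analysis are
mutually consistent by construction — `vesicleApl()` on a fresh build
returns the input APL to well within 2% (the residual is the rounding
of `N` to an integer).  It also keeps the choline head bead outermost
(outer leaflet) / innermost (inner leaflet), which gives the clean
radial ordering *inner water < inner heads ≤ lipid shell < outer
water* that the tests assert bead-wise.

## Anchor placement and lipid conformation

Anchors are laid out on each reference sphere by a Fibonacci
(golden-spiral) lattice, rotated by a seed-controlled random global
rotation.  The lattice is deterministic and nearly areally uniform: on
the default build the coefficient of variation of nearest-neighbour
anchor distances is under 15% on both leaflets (asserted in the
tests).  Each lipid starts as a straight chain along its local radial
axis with template bond lengths; the two tails run parallel, offset
laterally by 0.25 nm — which is why the end-to-end distance between
beads 8 and 12 of a freshly built lipid is exactly 0.25 nm.  Straight
radial chains from the two leaflets interpenetrate where the leaflet
gap is narrower than a chain; this is intentional — removing residual
overlap is precisely what the engine-side steepest-descent energy
minimisation is for, and the emitted equilibration inputs follow.

The builder refuses genuinely impossible geometry: an inner leaflet
whose chains would reach the vesicle centre, or an outer leaflet whose
head beads would leave the box.

## Solvation

Water beads go on a simple-cubic lattice (default spacing 0.415 nm)
with a small per-axis uniform jitter (default 0.01 nm), restricted to
the core region inside the inner exclusion sphere and the box region
outside the outer exclusion sphere.  The exclusion radii are the
extreme lipid-bead radii offset by `minSeparation` (default 0.40 nm)
plus the jitter envelope, so *no water bead can come closer than
`minSeparation` to any lipid bead* — a guarantee the tests verify by
brute force on a miniature vesicle.  The spacing default is chosen so
the packaged default counts fit: the reference composition places
67,522 beads in the ~10.6 nm-radius core, a density a 0.47 nm lattice
cannot reach; 0.415 nm leaves ≈5% headroom.  Requested counts are
honoured exactly by trimming the candidate sites closest to the
exclusion shells (deterministic tie-break by lattice order); requests
beyond lattice capacity raise a capacity error that reports the
maximum.  The default counts themselves (67,522 inner / 334,358 outer)
are configuration, not derivation: no single water-bead volume
reproduces both printed numbers, so the packaged YAML records them
verbatim and any other build fills the lattice (`NA` counts) or takes
user overrides.

## Determinism

`(spec, seed)` fixes everything: two builds with the same seed are
bitwise identical, including the emitted file bytes.  All randomness —
the global rotation of each leaflet lattice and the solvent jitter —
draws from a locally seeded RNG that leaves the caller's random stream
untouched.

# Emitted simulation inputs

`emitSimulationInputs()` writes the structure, the index file (three
canonical groups in the fixed order `INNER_WATER BILAYER OUTER_WATER`,
plus auxiliary per-leaflet groups for analysis), the topology, a
300 ps / 10 fs equilibration MDP with every group at 300 K, and one
production MDP per portion in which only that portion's reference
temperature is raised (default 390 K for 230 ns).  Protocol constants
follow the study design they implement: leap-frog integrator, Verlet
cutoff scheme with 1.2 nm LJ/Coulomb cutoffs, v-rescale thermostat,
Parrinello–Rahman barostat with `tau_p` = 13 ps at 1 bar.  Pressure
coupling is emitted as *semi-isotropic* — faithful to the protocol
being reproduced even though the system is spherical in a cubic box —
with an isotropic switch available in `thermalProtocol()`.  The
coupling constant is interpreted as a time constant in ps, the only
reading the engine's vocabulary admits.

# Trajectory handling

Analyses read either a single structure or a trajectory.  The
trajectory carrier is the *multi-frame GRO* text format (concatenated
GRO blocks with `t=` stamps): the installed R stack has no XTC/TRR
reader, and a text carrier keeps fixtures and tests fully
self-contained; converting an engine trajectory is a one-liner
(`gmx trjconv -f traj.xtc -o traj.gro`).  `openTrajectory()` validates
bead counts against the structure, drops a truncated trailing frame
with a warning, and streams frames on demand so memory use is
independent of trajectory length.

# The analyses

**Molecular radial distribution.**  The distance between two molecules
is the *minimum over all inter-bead pairs* (minimum-image convention).
For each reference lipid, target molecules are histogrammed in 0.01 nm
bins — the bin centred at `r` counts molecules in
`[r − 0.005, r + 0.005)` — and averaged over references and frames.
Values are raw average neighbour counts (their sum is the mean
neighbour count within range), not a density-normalised g(r); the
normalised variant sits behind `normalized = TRUE`.  Trajectory
averages default to the final 10% of frames, where a heated system is
closest to its new steady state; the window is an argument
(`frames = "all"` or explicit indices).

**Vesicle APL.**  Leaflets are assigned per lipid by the sign of the
dot product between the head→tail-midpoint vector and the radial
direction at the lipid's centre of geometry; each leaflet's radius is
the mean phosphate radial distance, `APL = 4 π R² / N`, and the
combined value is the area-weighted mean of the two leaflets.
Per-leaflet values are always reported alongside the combined one,
since a per-leaflet versus combined convention materially changes the
number on a strongly curved vesicle.

**MSD and diffusion.**  One marker bead per molecule (the phosphate
for lipids), per-frame centre-of-geometry drift removed, squared
displacements averaged over particles and *all* time origins (computed
with the FFT autocorrelation identity, so a 10³-particle × 10³-frame
fixture takes seconds).  A line is fitted over a configurable lag
window (default the central 10–80% of the lag range) and
`D = slope / dFit`: divisor 4 is the lateral, quasi-two-dimensional
convention appropriate for lipids diffusing on a shell and is the
default; divisor 6 is the 3-D convention that the Brownian fixtures
use.  Units: with lags in ps and MSD in nm², `D` is reported in
10⁻⁵ cm²/s.  On synthetic Brownian motion with known
`D = σ²/(2Δt)` the fit lands within 5% at the fixture size above.

**Group–group energies.**  Shifted-potential sums over intermolecular
bead pairs within the 1.2 nm cutoff:
`V_LJ = Σ 4ε[(σ/r)¹² − (σ/r)⁶] − V(r_c)` and
`V_C = Σ f q_i q_j/(ε_r r) − shift`, `f` = 138.935 kJ·nm/(mol·e²).
Intramolecular pairs are excluded entirely; identical groups switch to
intra-group mode (each unordered pair once); overlapping distinct
groups are refused.  The production path is a cell list in C++ with a
brute-force fallback for boxes under three cells per edge; both paths
are held to an all-pairs R oracle at 10⁻⁹ relative tolerance in the
tests.  Absolute agreement with an engine's energy file is *not*
promised (long-range treatment differs); trends across conditions and
the exact lipid–water Coulomb zero are.

**Kink angles and end-to-end distances.**  The kink operator measures
the angle at each triple centred on an unsaturated bead; on saturated
species it reports saturated-triple statistics and says so.  The
end-to-end operator measures the bead-8–bead-12 distance.  Both are
validated against Boltzmann-sampled conformer fixtures: the sampled
kink-angle mean must sit within three standard errors of the
deterministic quadrature mean of the same density, and end-to-end
means are cross-checked against an independently coded Monte-Carlo
chain builder.  The quadrature itself (`equilibriumAngleMean()`) is a
midpoint rule over the cosine-harmonic Boltzmann density *including
the sin θ Jacobian*; for the kink parameters at 390 K it gives
120.3°, a few degrees above a naive θ₀ read-off and consistent with
the ~122° observed in heated membranes.

**Pore detection.**  Lipid beads are projected onto the mid-radius
sphere and binned on a near-equal-area band grid (default 0.5 nm
linear resolution).  Maximal connected patches of empty cells are
pores; a patch's equivalent angular radius α comes from its solid
angle, and the estimated diameter is `2 R_mid α` plus a half-cell rim
correction (a boundary cell containing any bead counts as occupied,
which otherwise shrinks every patch by about half a cell per side).
Patches below three grid cells in diameter are suppressed — they are
ordinary packing vacancies between discrete lipids, and with the
suppression a pristine build reports exactly zero pores.  Asking for a
grid finer than twice the mean projected bead spacing is an error, in
whichever direction one words it: such a grid cannot distinguish pores
from discreteness.  Ground truth comes from `punchHole()`, which
removes all lipids whose head-bead direction falls in a cone; detected
diameters track `2 R α` within 20% down to miniature vesicles.

# Synthetic fixtures and what passing tests mean

The fixture module generates the three ground-truth-known inputs the
analyses are tested against: Brownian random walks (known `D`, known
MSD line), Boltzmann-sampled lipid conformers (fixed bonds, exact
rejection-sampled angles — rejection was chosen over inverse-CDF
because it is exact and acceptance is high in the parameter range —
free dihedrals), and punched-hole vesicles (known pore direction and
angular radius, spherical-cap removal statistics).  Fixtures carry no
nonbonded physics: passing tests demonstrate that the *operators* are
correct, not that a fixture resembles a heated membrane.  Conclusions
about real vesicle behaviour still require the external engine's
trajectories; the package's role there is to have emitted the exact
inputs and to measure the outputs with operators whose correctness was
established on the fixtures.

# Problem sizes used in the checks

The packaged default build (507,072 beads) is constructed in a couple
of seconds and is exercised directly in the tests and the acceptance
script.  Oracle comparisons run on ≤50-molecule systems where an
O(N²·B²) reference is exact and instant; statistical recoveries use
10³ particles × 10³ frames (diffusion), 4–5·10³ conformers (angles,
goodness-of-fit at p > 0.01), and a 20 nm vesicle (pores).  These
sizes make every standard error small enough that the 3-SE and 5%
bands are meaningful, while keeping the whole suite under a minute.

# Known limitations

* Single-species vesicles only; no mixed leaflets, cholesterol, or
  MARTINI 3 mappings.
* The builder's straight-chain initial conformation is intentionally
  unrelaxed; built structures are inputs to minimisation, not
  equilibrium ensembles, and their instantaneous intra-bilayer
  energies are meaningless until minimised.
* MSD assumes unwrapped (whole) trajectories; no unwrapping is
  performed.
* Energies use plain cutoff + potential shift; no long-range
  corrections, so engine energy-file values are reproduced in trend,
  not to the kJ.
* The water counts of the packaged default are recorded configuration
  (see above), and the exact counting surfaces behind the reference
  leaflet populations are a reconstruction that reproduces them
  exactly but is not uniquely determined by the printed numbers.

# A minimal session

```{r example, eval = FALSE}
library(vesica)

spec <- vesicleSpec(species = "DPPC", outerDiameter = 20, boxEdge = 26,
                    seed = 7)
sys <- buildVesicle(spec)
vesicleApl(sys)                                  # ~0.46 nm^2 by construction
emitSimulationInputs(sys, "dppc20")              # gro/ndx/top/mdp set

groupInteractionEnergy(sys, "BILAYER", "OUTER_WATER")  # Coulomb exactly 0

holed <- punchHole(sys, direction = c(0, 0, 1), halfAngle = 0.3)
detectPores(holed)                               # one pore, d ~ 2 R alpha
```
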