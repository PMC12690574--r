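---
title: "Methods: multicopy fragment GaMD preparation and descriptor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicopy fragment GaMD preparation and descriptor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamdfrag)
```

# The approach

Fragment screening by simulation solvates a target protein with many copies
of one small fragment and lets molecular dynamics discover where the copies
bind. Two ingredients make this practical. First, a purely repulsive
Lennard-Jones term between one designated *central atom* per copy (retyped
`C99`/`N99`/`O99`/`S99` by element) prevents the copies from aggregating
with each other while leaving every other interaction untouched. Second, a
Gaussian accelerated MD (GaMD) boost smooths the potential-energy surface
so copies escape shallow, spurious minima and settle into genuine sites
within affordable simulation time.

`gamdfrag` implements everything around the MD engine: building the
multicopy system, the boost mathematics and its equilibration schedule, and
the complete per-ligand descriptor analysis that turns four replicate
trajectories into a ranked list of binding sites.

# The GaMD boost

When the system potential $U$ falls below a threshold $E$, a harmonic boost
is added:

$$\Delta U = \tfrac12\,k\,(E - U)^2 \quad (U < E), \qquad
  k = \frac{k_0}{U_{\max} - U_{\min}},\; k_0 \in [0,1],$$

and the dynamics run on $U' = U + \Delta U$. $U_{\max}$ and $U_{\min}$ are
the running extrema collected during an unboosted preparation phase;
$k_0 = 1$ gives the maximal boost. We default the threshold to the *lower
bound* convention $E = U_{\max}$, the common choice in the GaMD literature;
it is exposed as configuration. Under $E \le U_{\min} + 1/k$ the smoothed
landscape is non-decreasing in $U$, which the tests verify on a dense grid.
No $k_0$ update formula is invented: $k_0$ is a user constant, capped at 1.

Because boosted ensembles are biased, observables computed on them would
need reweighting before quantitative use; the descriptor analysis here
ranks sites *within* one protocol, and reweighting is deliberately out of
scope.

The equilibration schedule ties the potential-statistics bookkeeping to
system size: `ntave = 4 * n_atoms` steps for the running-average window,
`ntcmdprep = ntebprep = 2 * ntave` and `ntcmd = 5 * ntave`
(`gamd_equilibration_schedule()`), integer arithmetic throughout.

A toy demonstrator (`langevin_double_well_demo()`) runs overdamped
Euler–Maruyama dynamics on $U(x) = h(x^2-1)^2$. The step size defaults to
$0.08/h$ time units, which keeps the explicit scheme stable against the
quartic's curvature ($8h$ at the minima) for any barrier height; barrier
crossings are counted with a $\pm 0.25$ hysteresis band so thermal
recrossing noise at $x = 0$ is not double-counted. With the barrier at
8 kcal/mol and $kT = 0.6$, the unboosted barrier is ~13 kT and essentially
never crossed, while the $k_0 = 1$ boost lowers the effective barrier
enough for regular transitions — the package's acceptance checks assert the
strict inequality of mean crossing counts over ten seeds, not a specific
count.

# System preparation

Receptor and ligand template are each rotated onto their principal axes
(eigenvectors of the mass-weighted gyration tensor; right-handed frame,
largest extent along x), which minimises the bounding box and therefore the
water count. Near-degenerate eigenvalue pairs (relative gap < 1e-8) are
resolved deterministically by fixing each axis's largest-magnitude
component positive; truly collinear inputs are an error.

The solvated-ligand template box is replicated on the minimal lattice
covering the receptor extent plus a 20 Å shell per axis
(`ceiling((extent + 2*shell)/box_length)` tiles, lattice centred on the
receptor's centre of mass — the tiling origin and the handling of partial
edge boxes are not pinned down by the protocol, so both are package
choices, applied deterministically). Pruning is *molecule-atomic*: any
template molecule (ligand copy or water) with an atom strictly closer than
1 Å to a receptor atom is removed whole, as is any molecule entirely
outside the shell region. The report counts placements and removals, and
clash pruning is order-independent by construction (each molecule is tested
against the receptor only).

# Descriptors

All analyses run on *stripped* trajectories: waters and ions removed, one
ligand copy paired with the receptor per trajectory.

**Residence time (RT).** A stability descriptor, not a kinetic unbinding
time: the duration of the longest window *ending at the final frame* in
which at least 90% of frames have the central atom within 5 Å of the
receptor; RT is 0 if the final frame is unbound. The window is anchored at
the end because the protocol's own screen discards trajectories whose
final frame is unbound (strictly greater than 5 Å), and "remains stably
bound" refers to the simulation's end state; an option scans all windows
for sensitivity checks. Trajectories with RT ≥ 50 ns are *reactive* and
enter the descriptor battery (the cutoff is configurable; 20 ns is the
documented relaxed choice for weakly bound probes). Frame times are
physical: PDB input carries no clock, so a frame interval in ns is required
wherever RT is requested.

**Energies.** $E_\mathrm{inter} = E_\mathrm{vdW} + E_\mathrm{elec}$ over
all receptor–ligand pairs: AMBER-convention Lennard-Jones
($\varepsilon$, $r_\mathrm{min}/2$, Lorentz–Berthelot combination) plus
Coulomb with 332.0637 kcal·Å/(mol·e²), no cutoff, dielectric 1. The
MM/GBSA estimate adds solvation under the one-trajectory approximation —
receptor and ligand are evaluated on their coordinates within the same
complex frame, so intramolecular terms cancel *exactly* (the estimator has
no bonded-energy code path) and the entropy term is omitted as a declared
constant:

$$\Delta G_\mathrm{bind} = E_\mathrm{inter}
 + [G_\mathrm{GB}^\mathrm{cplx} - G_\mathrm{GB}^\mathrm{rec} - G_\mathrm{GB}^\mathrm{lig}]
 + \gamma\,[\mathrm{SASA}^\mathrm{cplx} - \mathrm{SASA}^\mathrm{rec} - \mathrm{SASA}^\mathrm{lig}].$$

The polar term uses HCT pairwise-descreening effective Born radii with
Still's interpolation, interior dielectric 1, solvent 78.5, element-based
intrinsic radii, and *no* dielectric offset — so a lone ion reproduces the
Born formula with its intrinsic radius exactly, which (with long-range
additivity and $q^2$ scaling) is the numerical contract; parity with any
particular MD package's GB flavour is a non-goal. The nonpolar term is
$\gamma = 0.0072$ kcal/(mol·Å²) with zero offset. SASA is Shrake–Rupley on
a deterministic golden-spiral grid (default 960 points for reference
calculations, within 2% of the analytic sphere; 240 points inside the
pipeline where only differences and ratios matter).

**Windows.** Energy and SASA averages are reported over the residence
window and over the last 20 ns. Within the residence window, only *bound*
frames enter the averages and the stability filter: the 90% occupancy rule
deliberately tolerates brief unbound excursions, and a frame with the
ligand 30 Å away contributes a near-zero binding energy that would only
dilute the estimate — and would dominate the block statistics below. For
long windows the energy evaluation takes a uniform stride capping the
frame count at 60 per trajectory; the last-20 ns frames are always
included.

**Stability filter.** The per-frame $\Delta G$ series is averaged in 10 ns
blocks; a trajectory is discarded when any block mean deviates from the
mean of block means by strictly more than 2 × SD(block means). Two
properties are worth knowing. A constant series is kept (deviations 0 are
not > 0). And the rule is sensitive to the *correlation structure* of the
series: for ~28 statistically independent block means the expected maximum
|z| exceeds 2, so a white-noise series would be rejected more often than
not — the filter implicitly assumes the strong autocorrelation that real
binding-energy series have, and flags genuine level shifts (a 10·SD block
shift is always caught). Series spanning fewer than two blocks are kept
with a warning.

**Solvent exposure.** Ligand SASA in the complex as a percentage of the
free SASA of the same conformation (both emitted at the last snapshot and
averaged over the residence window, since the protocol prose does not pin
which defines the reported value when the window is short).

**Hydrogen bonds.** Donor–hydrogen pairs are inferred from covalent
geometry (H within 1.25 Å of N/O/S); over the last 20 ns each
intermolecular donor/acceptor combination is tested per frame against a
3.0 Å heavy-atom distance and a 135° D–H···A angle; pairs with occupancy
strictly above 45% are retained.

# Sites and the consensus vote

The contact set of a reactive trajectory is the receptor residues with any
atom strictly within 4.5 Å of any ligand atom in the final frame
(consistent with the end-anchored window; a mode averaging over the
residence window is available). Sets are clustered greedily in
(replicate, copy) order: a set joins the existing site with the highest
Jaccard index against the site's canonical residue set if that index
strictly exceeds 0.35, else it founds a new site; the canonical set is the
running union. Greedy-with-union is a deterministic choice — the protocol
prose evaluates "all similarities" without fixing an algorithm — and input
order is fixed, so results are reproducible; a different order could in
principle cluster differently.

Per site, descriptors aggregate across replicates: `n_reactive` counts
*distinct replicates* contributing a reactive trajectory (maximum = number
of replicates), best values are the most favorable over members, and
averages are the sum over member values divided by the *number of
replicates* — explicitly not by member count, so a site found in one of
four replicates is penalised. Nine columns vote: n_reactive, best RT,
best and averaged E_inter (residence window), best and averaged MM/GBSA
(residence window), averaged MM/GBSA (last 20 ns), best % exposed SASA
(last snapshot), and maximum H-bond count. Each column awards one vote to
the site holding its most favorable value (exact column ties share the
vote); the most-voted site is selected, with exact vote ties broken by the
lower averaged MM/GBSA, then the lower averaged E_inter, and flagged.

# Synthetic fixtures

The generator builds what the analysis needs to be tested end to end with
known truth, not a physical simulation:

- **Receptor**: 40 residues, two beads each (backbone + sidechain), on a
  spherical shell of radius 11 Å. Pocket residues' sidechain beads are
  rearranged into a concave cup around a site point 4 Å above the surface:
  one acceptor bead at the cup bottom (2.85 Å below the site point for the
  dominant pocket, 3.4 Å for the secondary) and a surrounding ring at
  3.3 Å, so a ligand at the site point genuinely contacts the whole pocket
  list within 4.5 Å. Cup charges are acidic, strongest in the dominant
  pocket (−0.45 bottom / −0.25 ring vs −0.15 / −0.08).
- **Ligand**: a rigid 4-atom protonated-amine-like probe (net +0.6) whose
  N–H points at the cup-bottom acceptor, giving a ~2.85 Å, near-linear
  hydrogen bond at the dominant site only (3.4 Å > 3.0 Å cutoff at the
  secondary site).
- **Trajectories** are kinematic: each copy follows a programmed event
  schedule (bound to a named pocket / unbound beyond 12 Å), with a
  tangential pose offset drawn once per event (±0.25 Å) and thermal motion
  emulated as a *single* smooth low-frequency oscillation mode per event
  (0.06–0.12 Å, 50–130 ns period). Real bound-ligand coordinates are
  strongly autocorrelated; white per-frame jitter would (correctly,
  per the block-statistics argument above) be rejected wholesale by the
  stability filter, which is a property of the filter, not of binding.
  A single mode keeps the block-mean crest factor near $\sqrt2$.
- **Defaults mirror the study conditions**: 4 replicates × 400 ns × 4
  copies, 4 ns frame interval (the saving interval of production runs is
  not specified anywhere, so analyses are expressed per-time and 4 ns is
  the package's choice balancing window resolution against test runtime).
  The default schedule programs the dominant pocket to hold reactive
  trajectories in every replicate (staggered 250–280 ns residence times),
  the secondary pocket two shorter ones, one copy that never binds and one
  that unbinds before the end (exercising the end screen).
- **Ground truth** is derived from the schedule alone: per-copy residence
  times via an independent exhaustive window scan over the programmed
  bound mask, contact truth from the pocket lists, and the dominant site
  from the reactive tally. Everything is a pure function of (spec, seed).

What passing the end-to-end recovery shows — and what it does not: the
pipeline's screens, windows, clustering and vote do recover programmed
dominant sites and residence times exactly under controlled, well-separated
conditions; it says nothing about force-field accuracy, sampling
convergence, or the behaviour of marginal sites whose descriptors overlap,
all of which require real simulations.

# Numerical choices and degenerate inputs

- Units fixed package-wide: Å, kcal/mol, elementary charges, amu; Coulomb
  constant 332.0637.
- Boundary semantics are literal: "greater than 5 Å" discards strictly
  greater (5.0 is kept); "at least 50 ns" keeps ≥; J exactly 0.35 founds a
  new site; H-bond occupancy exactly 0.45 is not retained.
- Overlapping atoms (r < 1e-6 Å) raise a singularity error naming the
  pair; effective Born radii are clamped at 30 Å; `J(∅,∅) = 0`; the
  degenerate zero-free-SASA ligand is an error rather than a NaN.
- Problem sizes in the shipped tests (40-residue receptors, 101-frame
  trajectories, ≤ 50-atom oracle systems, 960-point reference SASA) were
  chosen so each brute-force oracle comparison stays exact and the whole
  suite runs in minutes on one core.

# Limitations

No MD engine, no reweighting of boosted observables, no dihedral-specific
boosts on molecular topologies, no entropy estimates, no pose-RMSD mode
clustering, and no claim of numeric parity with any particular MM/GBSA
implementation — the closed-form limits are the contract. Binary trajectory
formats are supported only through external readers adapting into the
package's trajectory container; the native format is multi-model PDB.
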