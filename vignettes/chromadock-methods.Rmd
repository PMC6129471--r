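---
title: "Brownian-dynamics docking of linker histones on nucleosomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brownian-dynamics docking of linker histones on nucleosomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

The chromatosome — a nucleosome core particle plus one bound linker
histone (LH) and the flanking linker DNA — is a basic unit of chromatin
structure, and how the conserved winged-helix globular domain (GD) of the
LH sits on the nucleosome (on the dyad, or displaced onto one linker arm)
is sequence-dependent and functionally consequential. `chromadock`
implements a rigid-body Brownian-dynamics (BD) docking protocol for this
problem: the LH GD diffuses as a rigid body in the screened electrostatic
field of a fixed nucleosome, diffusional encounter complexes are recorded
into an energy-ranked archive, the archive is clustered, and each
cluster representative is classified by which DNA grooves its structural
elements (the α3 helix, the β1 wing and the l1 loop) contact. Point
mutations and posttranslational modifications (PTMs) of the LH are
represented as parameter-level charge/radius edits, so their effect on
the docked configuration ensemble can be scanned cheaply.

Everything runs end-to-end on synthetic idealized structures generated by
the package itself; real structures can be supplied as PQR files with
optional externally computed OpenDX potential grids through exactly the
same interfaces.

## Electrostatic model

Potentials are screened-Coulomb (Debye–Hückel) superpositions over the
charged atoms,

$$\phi(\mathbf r) \;=\; \frac{C}{\epsilon_s}\sum_i
  \frac{q_i\,e^{-\kappa(|\mathbf r-\mathbf r_i|-a_i)}}
       {(1+\kappa a_i)\,|\mathbf r-\mathbf r_i|},$$

with $C = e^2/4\pi\varepsilon_0 k_BT$ in kT Å/e² units, solvent
dielectric constant 78.54, 100 mM 1:1 ionic strength (Debye length
9.6 Å) and 298.15 K by default. The uniform-dielectric model replaces a
nonlinear Poisson–Boltzmann solve with a dielectric boundary; it admits
an exact analytic oracle (the package tests grid values against the
closed form to 0.5 %), and grids from an external PB solver can be
imported via `read_dx_grid()` with an identical downstream interface.
Potentials are tabulated on a regular grid (1 Å spacing by default, the
protocol value) and evaluated by trilinear interpolation with an
analytic screened-monopole continuation outside the box; interaction
forces are the analytic gradient of the interpolant. Beyond about 14
Debye lengths the screened interaction (≲10⁻⁴ kT) is treated as zero.

Effective charges are fitted by least squares so that a reduced site set
(charged-residue side-chain centroids plus termini for proteins, P atoms
for DNA) reproduces the grid potential over a shell of sample points
3–6 Å outside the atom-radius surface (2000 quasi-uniform points drawn
with a fixed private seed, so the fit is deterministic). For bead models
whose charges are already point charges, `formal_effective_charges()`
bypasses the fit.

By default the docking engine propagates with one-sided energies and
forces — the LH effective charges interpolated in the nucleosome grid.
The symmetrized variant (the average of the two one-sided evaluations,
which is exactly symmetric under solute exchange) is implemented
throughout and is the default of `interaction_energy()`; one-sided
propagation was chosen for the engine because it needs ~25 grid
interpolations per time step instead of ~360, and the nucleosome is by
far the larger, more highly charged solute, so its grid dominates the
interaction.

## Brownian dynamics

The propagator is the overdamped Ermak–McCammon update: displacement
$\Delta\mathbf r = (D_t/k_BT)\mathbf F\,\Delta t + \mathbf R$ with
$\langle R_\alpha^2\rangle = 2D_t\Delta t$, and an angular increment
$\Delta\boldsymbol\varphi = (D_r/k_BT)\mathbf T\,\Delta t +
\mathbf R_r$ applied as a quaternion increment and renormalized. The
time step is 1 ps. Diffusion coefficients default to Stokes–Einstein
values from an effective hydrodynamic radius $R_h = 1.29\,R_g$ of the
mobile LH (water viscosity 0.89 mPa s), with all relative diffusion
assigned to the LH; for the toy GD this gives
$D_t \approx 0.018$ Å²/ps and $D_r \approx 7\times10^{-5}$ rad²/ps.
These choices affect kinetics, not the Boltzmann-weighted pose
distribution, which is what the recorded ensemble samples; the package
verifies the Einstein relation and Boltzmann sampling in a harmonic
field against closed forms.

Excluded volume uses a 0.5 Å probe margin on a boolean occupancy grid
(a cell is occupied when its center lies within atom radius + margin of
any nucleosome atom; a pose overlaps when any LH atom center falls in an
occupied cell). Overlapping trial moves are rejected and redrawn with
fresh noise, which preserves the equilibrium distribution to the order
of the time step. The occupancy box is made symmetric about the y/z
origin planes so that an exactly dyad-symmetric model receives exactly
dyad-symmetric occupancy.

Trajectories start with the LH center uniformly distributed on a sphere
of radius 185 Å around the nucleosome center with uniform random
orientation, and stop at 204 Å. With auto-scaling (used for the smaller
synthetic system) the same offsets are kept relative to the system size:
start = nucleosome bounding radius + 30 Å, stop = start + 19 Å. An
encounter complex is any time step with center-to-center distance
< 98 Å *and* LH-center-to-dyad-point distance < 40 Å. Each trajectory is
capped at 2.5×10⁵ steps (0.25 µs) by default: the screened attraction
of the +11 e domain to the −366 e synthetic polyanion forms wells deep
enough that a surface-bound LH effectively never escapes on the
simulated time scale, and the cap bounds the recording time spent per
bound trajectory (a hard 10⁸-step validation limit is retained).
Per-trajectory seeds are derived deterministically from the master seed,
so runs are bit-reproducible and trajectory merging is
order-deterministic.

## The recorded encounter archive

Encounter poses are archived under the protocol's three rules, applied
per time step: a pose farther than 1 Å RMSD from every record is added
if its energy is within the 5000 most favorable (evicting the current
worst when full); a pose within 1 Å of a lower-energy record adds to
that record's occurrence count (the closest such record); a pose with
lower energy than all of its ≤1 Å neighbours substitutes the closest
one, inheriting its count plus one. RMSD between rigid poses of the same
body needs no coordinate expansion: with both poses in the fixed
nucleosome frame,

$$\mathrm{RMSD}^2 = \tfrac{2}{N}\!\left(\operatorname{tr}M -
 \operatorname{tr}(R_1 M R_2^{\mathsf T})\right)
 + 2\,\mathbf d\cdot(R_1-R_2)\bar{\mathbf y} + |\mathbf d|^2,$$

where $M=\sum_i \mathbf y_i\mathbf y_i^{\mathsf T}$ and $\bar{\mathbf y}$
are the second moment and centroid of the Cα (bead) coordinates and
$\mathbf d$ the difference of the translations. Neighbour queries use a
spatial hash on the translations (RMSD ≤ 1 Å implies the translations
differ by at most 1 Å + 2|ȳ|). The archive maintained by the C++ engine
is tested for exact equality against a literal quadratic-time R
implementation of the quoted rules. One subtlety is inherent to the
rules themselves: a substitution moves a record by up to the
deduplication RMSD, so the pairwise-separation property of the archive
can be transiently violated by that amount; the package keeps the rules
literal rather than re-deduplicating.

Clustering of the archive is average-linkage hierarchical clustering on
the pose-RMSD matrix cut to 10 groups, ranked by occurrence-weighted
size (ties broken by lower representative energy); the representative of
a cluster is its lowest-energy member. Records enter the clustering in
energy order, which makes the result invariant to event-arrival
permutations.

## Groove labeling and configuration classification

With the dyad axis perpendicular to the viewing plane, the minor groove
at the dyad is labeled 0, the dyad-adjacent major grooves of the
nucleosomal DNA are ±1, and the successive major grooves along each
linker arm (attachment to end, one per helical turn of 10.4 bp) are ±2,
±3, …; negative indices belong to the L-DNA1 side and positive to
L-DNA2. Because the ~1.65-turn superhelical wrap brings the arm attached
at the negative base-pair end around to the positive side of the dyad,
the ±1 side assignment is geometric (whichever dyad-adjacent groove is
nearer the L-DNA1 arm is −1), not a contour sign. For 26 bp arms this
scheme yields labels out to ±4, matching the published labeling of the
longer-linker system. A site's member phosphates are the P atoms of both
strands within a quarter turn of the site's base-pair position.

An element contacts groove *k* when any of its atoms lies within 5 Å of
any member phosphate of site *k* (the cutoff is a package default chosen
so the worked reference geometries are reproducible on the fixture; both
it and the helical repeat are configurable). The α3 direction symbol is
the N→C vector projected into the viewing plane and quantized to eight
compass arrows (reference direction: dyad → L-DNA2 arm, counterclockwise
viewed down the dyad axis), with "X" when the vector is within 30° of
the dyad axis. A configuration is on-dyad iff groove 0 is contacted;
otherwise off-dyad toward whichever arm carries all contacted indices
("mixed" when both signs occur without 0, "none" when no labeled groove
is contacted — neither occurs in the published figures but both must be
representable). Variant-versus-reference comparison uses the published
match categories: identical (all three element lists equal), partial
(one or two equal), different (none).

## Hydrogen bonds

H-bonds between the LH (N/O side-chain and backbone atoms; the
designated polar pseudo-atoms of the bead model) and the DNA phosphate
backbone (phosphate oxygens, O3′/O5′, or bare P pseudo-atoms of
coarse-grained models) are counted with a closed 3.2–3.6 Å heavy-atom
distance window, both bounds enforced as the protocol states; because
the lower bound is unusual, a conventional 0–3.6 Å mode is provided
behind `mode = "max_only"`. No angular criterion is applied. Counts are
aggregated per residue over runs and the two largest clusters, flagging
residues that make more than one bond in a single pose.

## Synthetic fixtures

The generator emulates the study inputs with idealized structures so
that every stage runs with no downloads:

* **Nucleosome**: one P pseudo-atom per strand per base pair (charge
  −1 e, radius 2.1 Å, no counterion-condensation scaling) on a
  left-handed superhelix of radius 41.9 Å and pitch 25.9 Å (~1.65 turns
  per 147 bp, 10.4 bp per turn — standard nucleosome geometry values,
  not from a specific structure), with the two strands offset by a 139°
  phase around a 9 Å helix; a neutral core sphere of packed pseudo-atoms
  provides excluded volume. The closed-reference linker arms are
  straight B-DNA segments aimed so they converge toward a stem near the
  dyad axis, as in closed chromatosome conformations; the opening angles
  rotate each arm outward from that reference, and the negative side of
  the model is constructed as the exact twofold image of the positive
  side, so equal opening angles give an exactly dyad-symmetric model.
  The default arm length is 18 bp per arm so that each arm carries the
  two groove sites (±2, ±3) that the worked reference configurations
  occupy (a 10 bp arm carries only one labeled groove site).

* **Toy LH GD**: 80 beads (one per residue, radius 3 Å) arranged as
  three idealized helices, an l1 loop and a β-hairpin wing with the
  binding face toward −x, numbered 30–109 so the named mutable sites
  carry their conventional identities (V80/K82/K85/V87 on the wing,
  K102/I104/K107/K109 on α3, the PTM sites K58/S66/S67/K72 on α1/α2).
  Thirteen +1 e and two −1 e sites realize the +11 e net charge; charged
  beads carry polar pseudo-atom names (NZ/NH1/OE1) so the H-bond stage
  has donors. The fold is a caricature: it reproduces the size, charge
  and element topology of a winged-helix GD, not its atomic structure.

* **Reference poses**: `place_reference_pose()` constructs the worked
  binding modes — on-dyad "(−3↑, 0, +3)" and the all-negative off-dyad
  configuration on L-DNA1 (contact pattern α3: −1, β1: −1 −2, l1: −2),
  plus the mirror mode on L-DNA2 — by superposing element anchor beads
  onto groove-site anchor points (Kabsch), followed by a deterministic
  hill-climb on a continuous score (contact mismatches with
  distance-to-cutoff guidance, plus excluded-volume penetration depth).
  An off-dyad search that stalls on one arm is solved on the other arm
  and mapped back through the nucleosome's exact twofold. The pose is
  verified by `classify()`; unreachable targets are an error.

What passing the synthetic tests does **not** show: fidelity to real
atomic structures, real charge distributions (AMBER partial charges,
dielectric-boundary electrostatics), hydrophobic or induced-fit
contributions, or the published per-system numbers, all of which depend
on real structure inputs and full-scale runs.

## Numerical and design choices

* Grid spacing 1 Å (protocol value); trilinear interpolation error is
  the reason the analytic-oracle comparisons are made at grid nodes.
  Grid points falling inside an atom are clamped at the atom radius.
* The effective-charge fit solves the normal equations by QR with a
  ridge fallback (warning) when they are singular.
* Hierarchical clustering ties and hclust chaining are controlled by
  presenting records in energy order; average linkage was chosen for
  robustness on loose encounter ensembles.
* Degenerate inputs: zero-length α3 vectors, empty site lists, empty
  sampling shells, 0-atom solutes and contradictory configurations are
  errors, not warnings.
* Scale of the shipped study: the acceptance-scale docking runs 500
  trajectories (and a 250-trajectory half run for the stability
  comparison) of the toy GD against the closed synthetic nucleosome,
  with start/stop spheres auto-scaled to the fixture. At this scale and
  with the exactly dyad-symmetric fixture, the two largest clusters are
  mirror-degenerate off-dyad stem modes whose rank order fluctuates
  between runs; the stability claim the package tests is therefore that
  the half-run's top configuration matches one of the full run's two
  largest clusters at least partially, up to the dyad mirror — the
  scaled analogue of the published 10,000-versus-20,000-trajectory
  "similar cluster configurations" check, stated at the resolution the
  synthetic conditions support.

## Known limitations

Rigid bodies only (no induced fit, no flexible loops or tails); no
hydrodynamic interactions; uniform-dielectric screened electrostatics as
the built-in field (import PB grids for fidelity); short-range
(hydrophobic, desolvation) terms deliberately absent; the bead-model
H-bond counts are contact counts between pseudo-atoms, not chemical
hydrogen bonds; the coarse PTM/mutation model edits parameters at one
site and cannot capture conformational responses to modification.
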