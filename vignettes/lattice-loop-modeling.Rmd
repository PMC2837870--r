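---
title: "Coarse-grained lattice loop modeling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained lattice loop modeling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticeloop)
```

## The problem

Comparative protein modeling routinely produces scaffolds whose loop
regions are missing or unreliable. `latticeloop` rebuilds such loops *de
novo* in a coarse-grained representation: the loop is excised from the
scaffold, re-inserted at random, and sampled by annealed replica-exchange
Monte Carlo (REMC) under distance restraints read from the fixed part of
the structure (or, in hybrid mode, from a consensus over several external
template models that *do* include loop conformations). The blindly
selected model is the medoid of the collated sampling trajectories;
benchmarking utilities compute the loop-only C&alpha; cRMSD after
superposing the scaffolds.

## Reduced representation

Each residue is represented by four pseudo-atoms: the C&alpha;, the
C&beta;, the side-chain geometric center, and the midpoint of the virtual
C&alpha;&ndash;C&alpha; bond. C&alpha; positions are confined to a cubic
lattice of spacing 0.61 &Aring;. A virtual bond between consecutive
C&alpha; is any integer vector with squared length between 29 and 49
lattice units, i.e. bond lengths of 3.28&ndash;4.27 &Aring; fluctuating
around the canonical 3.78 &Aring;. This window was found by brute-force
enumeration as the window centered on $(3.78/0.61)^2 \approx 38.4$ whose
vector count is exactly 800; the count, not the window itself, is the
anchoring property of the representation. With 800 admissible bond
orientations, lattice anisotropy artifacts are negligible, and a real
C&alpha; trace projects onto the lattice with an RMSD of roughly
0.25&ndash;0.3 &Aring; (the acceptance suite requires a mean of at most
0.35 &Aring; over 50 synthetic chains).

### Projection

No unique prescription exists for fitting a trace to the lattice, so the
package uses a documented heuristic: a grid search over $5^3$ sub-lattice
rigid offsets of the input, each followed by anchoring residue 1 at its
nearest vertex and assigning every subsequent bond greedily to the
admissible vector minimizing the cumulative squared error, with a one-bond
lookahead evaluated over the eight best immediate candidates. The offset
with the lowest total error wins; the fitted offset is stored with the
conformation so that lifting back to Cartesian coordinates
(`ca * spacing + origin`) is exact. The same anchored greedy machinery
re-projects displaced fragments during large Monte Carlo moves. The
approach trades optimality for an $O(N \cdot 800)$ cost per offset; in
practice it reaches the accuracy target without dynamic programming over
the full bond graph.

### Pseudo-atom geometry

The positions of C&beta; and of the side-chain center are functions of the
two virtual bonds flanking a residue plus the residue type, exposed as a
lookup table keyed by the pair of bond ids. The shipped table is
*idealized and closed-form* rather than derived from structural
statistics: C&beta; is placed 1.53 &Aring; from C&alpha; along the unit
combination of the bond bisector (pointing away from the local chain
direction change) and the bond-pair normal, whose fixed out-of-plane
component encodes L-amino-acid chirality; the side-chain center lies
further along the same direction at a per-residue-type canonical distance
(0 for glycine, up to 4.1 &Aring; for arginine). Because entries are a
pure function of `(id1, id2, restype)`, the table is generated on demand
and cached; `write_geometry_table()` serializes any subset to the
six-column text format. Terminal residues copy the nearest interior
residue's local frame.

## Energy model

The force field keeps the canonical coarse-grained *term structure* while
shipping documented surrogate parameters (editable via
`write_energy_model()` / `--ff`); reproducing any published
parameterization numerically is a non-goal. Energies are in reduced units
with $k_B = 1$; temperatures are quoted in the same units.

* **Hard-core excluded volume** — `+Inf` when any non-bonded
  C&alpha;&ndash;C&alpha; pair is closer than 3.3 &Aring; or any
  C&beta;&ndash;C&beta; pair closer than 2.5 &Aring;.
* **Side-chain contacts** — a square well on side-chain-center pairs with
  sequence separation &ge; 3: repulsion (+2.0) inside 3.0 &Aring;,
  attraction in 4.0&ndash;6.5 &Aring; with a depth set by the residue-class
  pair (hydrophobic&ndash;hydrophobic 0.5, salt bridge 0.4, mixed
  0.1&ndash;0.15, like-charge 0).
* **Cooperative hydrogen bonds** — a C&alpha; pair (separation &ge; 3) is
  bonded when its distance falls in 4.6&ndash;5.4 &Aring; and the
  connecting direction is near-perpendicular (|cos| &le; 0.5) to both local
  chain tangents; each bond contributes &minus;1.0 and each pair of bonds
  adjacent in both partners an extra &minus;0.5, rewarding extended
  H-bond networks.
* **Short-range bias** — binned tables over the $r_{13}$ distance and the
  chirality-signed $r_{14}$ distance of 3- and 4-residue windows. The
  generic table favors the helix and strand bands (&minus;0.5) and
  penalizes the mirror (left-handed) helix band (+0.3); a
  sequence-dependent table adds &minus;0.5 in the band matching the
  central residue's secondary-structure propensity class (H/E/C, a
  Chou&ndash;Fasman-style three-class scale).
* **Restraints** — flat-bottom harmonic, see below.

The surrogate depths were balanced once, at design time, against the
restraint term (next section): template-derived distance information must
dominate any single generic interaction, which is the operating regime of
restraint-based comparative modeling. With the shipped values, a
restraint violation of ~0.45 &Aring; at the default loop-restraint weight
costs about one hydrogen bond.

## Restraints

A restraint on residues $(i, j)$ with target $d_0$, tolerance $t$ and
weight $w$ contributes $0$ when $|d - d_0| \le t$ and
$w\,(|d - d_0| - t)^2$ otherwise. The flat-bottom harmonic form is the
field's standard for template-derived restraints; no specific functional
form is canonical, so this choice is documented rather than inherited.

*Single-template mode* reads restraints from scaffold&ndash;scaffold pairs
with sequence separation &ge; 5 and observed distance &le; 12 &Aring;
($d_0$ = observed, $t$ = 0.5 &Aring;), subsampled to at most 500 with the
run seed. On compact scaffolds of benchmark size this yields several
hundred restraints. *Hybrid mode* takes $d_0$ as the mean and $t$ as
$\max(0.5, \mathrm{sd})$ over &ge; 2 templates, drops pairs with spread
above 3 &Aring;, and — crucially — includes pairs touching the loop,
which single-template mode cannot provide.

Three open choices were resolved as follows and are exposed as arguments:

* **Scaffold mobility.** Scaffold residues move during sampling but under
  strong restraints (weight 10&times; the loop default), rather than being
  frozen; evaluation superposes on the scaffold regardless.
* **Weight scale.** The loop-restraint weight defaults to 5 (scaffold 50),
  chosen once so that restraint information dominates single-interaction
  energy gains (see above).
* **Near-anchor pairs.** For pairs touching the loop the minimum sequence
  separation drops to 3: the templates' loop fragments carry exactly the
  short-range signal that places a loop relative to its anchors, and
  discarding it would leave a 4-residue loop essentially unrestrained.

## Sampling

The move set mixes single-C&alpha; displacements, rigid shifts of 2&ndash;4
residue fragments (proposal weights 0.40/0.20/0.15/0.15), and small
Gaussian rigid displacements (&sigma; = 0.8 &Aring;, weight 0.10) of
random 4&ndash;22 residue fragments re-projected onto the lattice through
the anchored greedy fit; any proposal breaking the chain connectivity or
the closure bond is rejected outright, and hard-core violations are
rejected through the energy sentinel. Acceptance follows the classic
Metropolis rule $\min(1, e^{-\Delta E/T})$.

Twenty replicas (default) start from one shared random-loop conformation
on an equally spaced temperature ladder, 1.0&ndash;2.5 reduced units.
Sampling proceeds in macro-cycles of 100 sweeps; adjacent replicas attempt
swaps every 5 sweeps with the standard criterion
$\min(1, e^{(1/T_i - 1/T_j)(E_i - E_j)})$, alternating even/odd pairings.
After each macro-cycle the whole ladder is scaled by the anneal factor —
geometric annealing preserves the constant temperature spacing — and one
snapshot of the lowest-temperature replica is appended to the
pseudo-trajectory. Each simulation is repeated (default three times) with
repeat seeds spread multiplicatively from the master seed so that distinct
master seeds never share a stream; every run is bit-reproducible from its
seed because the sampler uses its own per-replica xoshiro256** generators.

Two presets bundle the schedule: `paper` (20 replicas, 100 macro-cycles,
anneal 0.98, final ladder scale 0.13) and `quick` (5 replicas, 20
macro-cycles, anneal 0.90 — chosen so that $0.90^{20} \approx 0.12$, i.e.
the quick preset cools to the same final temperature scale as the full
schedule in a fifth of the cycles). The loop is inserted by biased random
growth: admissible bond vectors are drawn with a Gaussian bias toward
straight-line closure onto the downstream anchor, clash-checked against
all placed atoms (including the rebuilt C&beta;), with two relaxation
levels (wider bias, then unbiased) before giving up; the final residue is
placed only at positions from which the closure bond is itself admissible.

## Model selection

All repeats are collated and the **top** (blind) model is the global
medoid — the snapshot minimizing the summed pairwise RMSD to all others.
The metric operates on loop coordinates after superposing the non-loop
scaffold: scaffolds are nearly identical across snapshots, and whole-chain
RMSD would wash out loop diversity (`cluster_on = "full"` switches to
whole-chain coordinates). K-means clustering (default $k = 5$, seeded,
features = superposed coordinates in the global-medoid frame) is reported
diagnostically; medoid ties resolve to the lowest snapshot index. The
**best** model — the snapshot closest to the native loop — requires native
coordinates and exists only for benchmarking; the top-model selector never
consults them.

## Evaluation

Loop accuracy is the C&alpha; cRMSD over loop residues after a Kabsch
superposition on all non-loop residues (anchors count as loop, and the
superposition uses the full scaffold; restricting it to a neighborhood is
a documented alternative the package does not take). Benchmark records
aggregate into the three loop-length bins 4&ndash;6, 7&ndash;12 and
16&ndash;25; lengths 13&ndash;15, absent from the benchmark set, fall in
no bin and are dropped with a warning. Two methods are compared with the
classic two-sample paired t-test on per-case cRMSD (zero-variance
differences are flagged as undefined rather than silently returning 0).

## Synthetic fixtures

The fixture generator builds idealized single-domain folds —
helix-loop-helix, &beta;-hairpin, three-helix — from ideal elements (helix:
rise 1.5 &Aring;, radius 2.3 &Aring;, 100&deg;/residue; strand: pleated
zigzag with 3.8 &Aring; bonds) joined by circular-arc connectors relaxed
to protein-like bond lengths, with seeded sub-&Aring;ngstr&ouml;m jitter.
Sequences are poly-alanine with leucine at crudely amphipathic positions
and glycine/serine in loops — enough to exercise every energy term. What
fixtures deliberately lack: real side-chain packing, irregular secondary
structure, solvent effects and crystallographic noise; passing the
recovery test therefore demonstrates protocol correctness (restraint
satisfaction, closure, annealing, medoid selection), not prediction
accuracy on real proteins, whose headline benchmarks additionally depend
on experimental structures and external modelers.

## Numerical choices and problem sizes

* Degenerate inputs: single-residue and two-residue chains evaluate only
  the terms their window counts allow; descriptors outside the short-range
  tables clamp to the edge bins; collinear bond pairs fall back to a fixed
  perpendicular frame direction.
* Energy invariance is asserted under lattice-preserving rigid motions
  (the 24 proper cube rotations and integer translations) — the subgroup
  of rigid motions representable in the model; improper elements flip the
  $r_{14}$ chirality sign by design.
* The test suite runs the sampler at deliberately small schedules (2-3
  replicas, 4-12 macro-cycles) for contract checks, and at the quick
  preset (5 replicas, 20 macro-cycles, 3 repeats, 3 master seeds) for the
  4-residue loop-recovery check on the 34-residue helix-loop-helix
  fixture; projection accuracy is averaged over 50 traces of 20-80
  residues. These sizes are the package's test-scale defaults; production
  modeling uses the `paper` preset.

## Known limitations

* Force-field parameters are surrogates: term structure and protocol are
  faithful, absolute energies are not comparable to any published model.
* The projection heuristic is greedy; pathological traces near the 2.5 or
  4.8 &Aring; precondition bounds may project poorly.
* Isothermal loop-dynamics analysis, all-atom reconstruction and
  energy-based re-ranking are out of scope.
* Multi-chain structures are modeled one chain at a time; insertion-coded
  loop ranges are not supported inside loop specifications.
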