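---
title: "Models and methods behind knotfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind knotfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(knotfold)
```

knotfold studies how a polypeptide chain ties itself into a knot while it
folds.  This vignette is the package's own account of the models it
implements, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the built-in synthetic systems
can and cannot tell you about real proteins.

## The coarse-grained model

Each amino acid is a single bead at its C-alpha position.  The potential
is native-centric (Gō-type): the experimentally known native structure
defines the minimum of every term, so the landscape is funnelled toward
the native state by construction.

* **Bonds** — harmonic, `k_bond * (r - r0)^2`, with rest lengths taken
  from the native trace (`k_bond = 100` in units of the native-contact
  depth per Å²).
* **Angles** — harmonic in the virtual bead angle (`k_angle = 20` per
  rad²).
* **Dihedrals** — periodic 1- and 3-fold terms
  `k1 (1 - cos(phi - phi0)) + k3 (1 - cos 3(phi - phi0))` with
  `k1 = 1`, `k3 = 0.5`.  The dihedral terms are what break mirror
  symmetry: without them a chain could fold into the topological mirror
  image of its target, which matters more for knotted proteins than for
  any other class, since the mirror fold carries the opposite knot
  chirality.
* **Native contacts** — one 12-10 well per native pair,
  `eps [5 (r0/r)^12 - 6 (r0/r)^10]`, minimum `-eps` at the native
  distance.  `eps = 1` defines the energy unit; temperatures are quoted
  as `kBT` in the same unit.
* **Excluded volume** — `(sigma_rep / r)^12` with `sigma_rep = 4` Å on
  every non-native pair at sequence separation of at least 3.

A native contact is a pair of residues at sequence separation of at
least 3 whose C-alpha distance is at most 7.5 Å.  Both numbers are
conventions of the C-alpha Gō literature, not values recovered from any
specific study, and both are arguments of `build_contact_map()`.

### The non-native (quasi-chemical) term

The optional second force field adds, on exactly the pairs that are
*not* native contacts,

```
lambda_nn * B[a(i), a(j)] * s(r),    s(r) = 1 / (1 + exp((r - rc)/w))
```

where `B` is a symmetric 20 x 20 matrix of amino-acid pair energies,
`rc = 8.5` Å and `w = 0.5` Å.  `lambda_nn = 0` recovers the pure
native-centric model bit for bit.  The switching centre is a little
larger than the native-contact cutoff because side chains extend beyond
the C-alpha positions that carry the beads.

The matrix shipped with the package
(`inst/extdata/qc_contact_energies_synthetic.csv`) is a **synthetic
surrogate**: `e_ab = -(h_a + h_b)/2` from the Kyte-Doolittle hydropathy
scale, shifted to zero mean over the 210 unique pairs.  It has the
structure of a quasi-chemical statistical potential — symmetric,
zero-mean, dominated by hydrophobicity — but it is not derived from
contact counts in solved structures; any matrix in the same CSV format
can be substituted through `go_model(qc_matrix = ...)`.  By default only
the attractive (negative) shifted entries act
(`attractive_only = TRUE`), because the role the term plays here is an
overall attraction of residues that are not rewarded by the native map;
the switch is exposed for users who want the repulsive entries too.

## Samplers

### Metropolis Monte Carlo

The MC engine proposes local crankshaft rotations (an interior segment
of 2–8 beads rigidly rotated about the axis joining its flanking beads)
and single-bead displacements, accepted with the Metropolis rule.
Because all moves are local, the sweep axis (n proposals per sweep) is a
sensible proxy for overdamped dynamics, and it is the time unit used in
knotting-probability curves.  Default amplitudes (0.4 rad, 0.25 Å) were
set so that acceptance sits in the 30–50 % band at folding temperature;
the acceptance rate of every run is logged in the trajectory metadata.

The compiled engine recomputes only the energy terms touched by each
proposal and refreshes the full sums every 50 sweeps so that incremental
rounding cannot accumulate; a test asserts the logged energy of the
final frame equals a fresh evaluation.

### Overdamped Langevin

The discrete propagator is

```
x_{i+1} = x_i + dt * D / kBT * F(x_i) + sqrt(2 D dt) * eta_i
```

with unit-variance Gaussian noise.  The action prefactor (below) is
written with an effective friction; the two are linked by the Einstein
relation `D = kBT / Gamma` with `Gamma = m_eff * gamma`, and
`langevin_params()` refuses inconsistent combinations rather than
silently picking one.  A stability guard requires
`dt * D * k_max / kBT < 0.1` for the stiffest curvature in the model (a
hard configuration error, not a warning), and the harmonic-well tests pin
the stationary variance `kBT/k` and the autocorrelation
`exp(-D k t / kBT)` to within 5 %.

## Ratchet-and-pawl biasing and dominant pathways

The reaction coordinate is the fraction of native contacts Q: a native
pair counts as formed when its distance is below 1.2 times its native
distance (the tolerance factor is config-exposed).  The bias is a
one-sided harmonic on the running record of Q:

```
E_bias = 0.5 * k_ratchet * (q_record - Q)^2   if Q < q_record, else 0
```

The chain evolves freely whenever it progresses; only regression is
penalized.  Two engineering notes:

* the sharp count has zero gradient almost everywhere, so the Monte
  Carlo engine (which only needs energies) uses it directly, while the
  Langevin engine derives the bias force from a sigmoid-smoothed
  per-pair indicator of width 0.2 Å;
* the record is updated at proposal resolution, so at frame resolution
  the logged record can be momentarily ahead of the logged Q — the
  running-maximum identity is exact at the resolution the pawl operates.

The Onsager–Machlup action of a stored path,

```
S = Gamma / (4 kBT dt) * sum_i | x_{i+1} - x_i - F(x_i) dt / Gamma |^2
```

is always evaluated with the **unbiased** force, also for trajectories
generated under the ratchet: the action scores how probable each path
would have been under the unbiased dynamics, and the trial with the
lowest action is the dominant (least biased) pathway among those sharing
an initial state.  Actions are only comparable within one initial state,
so `select_dominant()` ranks within a `path_ensemble` and never across
ensembles.  Evaluation requires frames stored at the integration stride
(stride 1); coarser strides are refused instead of rescaled, because a
subsampled path has a different action, not a rescaled one.  For an
unbiased run the expected action is exactly one half per step per degree
of freedom (each summand reduces to the squared noise), which the suite
asserts within 5 % — a calibration that catches prefactor and unit
errors in one number.

## Knot detection on open chains

A protein chain is open, so its knot state is made well-defined by
closure: both termini are extended radially away from the centroid onto
a sphere of 10 gyration radii and joined by a great-circle arc.  The
closure is deterministic; when a chain vertex lies essentially on a
closure ray (which would make the topology ill-defined), the rays are
tilted by a small deterministic escalating angle until they clear the
chain.  Stochastic multi-closure voting was deliberately not made the
default — reproducibility of every downstream label was judged more
valuable than robustness in borderline shallow-knot cases, which are
surfaced instead by the deterministic tilt escalation.

The closed polygon is simplified by KMT triangle elimination (a vertex
is deleted whenever the triangle it spans with its neighbours is not
pierced by any other segment; ambiguous intersections conservatively
block deletion), then projected along a deterministic sequence of
"generic" directions until no degenerate crossings remain.  From the
crossing diagram the package computes:

* the **Alexander determinant** |Δ(-1)| — 1 for the unknot, 3 for
  trefoils, 5 for the figure-eight class — via the underpass
  presentation of the Alexander matrix evaluated at t = -1;
* **trefoil chirality** from the sign of the summed crossing signs; the
  sign convention was anchored against the Gauss linking integral
  (projection-free), and the test suite carries that oracle;
* the **knotted core** by bidirectional trimming with re-closure,
  alternating the N and C side, in chunks with single-residue fallback;
* **slipknots** by scanning subchain intervals on a coarse grid
  (shorter intervals first);
* an independent cross-check: Fox p-colorings of the same diagram
  (|Δ(-1)| is divisible by p exactly when non-trivial p-colorings
  exist), computed by brute-force enumeration in the tests.

The determinant cannot distinguish knots with equal |Δ(-1)| (e.g. 4_1
vs 5_1, both labelled `det5`), and composite knots are out of scope;
for trefoil-forming systems, which is what this package targets, the
labels are unambiguous.

## Knotting events and mechanisms

A trajectory's first knotting event is the earliest frame that starts a
run of `persistence` consecutive knotted frames (default 10 saved
frames; transient knots that untie earlier are ignored, since reversible
knotting is common).  The mechanism classifier applies ordered rules
over a pre-event window:

1. **slipknotting** — some pre-event frame contains a slipknot while
   the threading terminus is backward-bent (end-segment bend angle
   above 90°);
2. **direct threading** — the knot core abuts a terminus (within 10
   residues) and that terminus stays straight throughout the window;
3. **mousetrapping** — the loop residues (core minus the threading
   terminal segment) move more than twice as much per frame as the
   terminal residues;
4. otherwise unclassified.

The 90° bend, the 10-residue terminal zone and the 2x displacement
ratio are heuristics that operationalize qualitative descriptions of
the three mechanisms; all are exposed as arguments.  Two boundary
behaviours are worth knowing.  A mousetrap closing slowly over a
*hooked* terminus genuinely passes through slipknot-like intermediate
states and is then labelled slipknotting by rule order; the scripted
mousetrap fixture therefore snaps shut in one step, which is also the
natural reading of the metaphor.  And a mousetrap closing over a
perfectly *straight* terminus is indistinguishable from direct
threading by these rules — relative motion enters only at rule 3.

## Synthetic fixtures: what they do and do not show

All tests run on synthetic systems built by the package itself:
parametric knots (torus-knot curves, with the left/right assignment
anchored by the Gauss writhe), ideal-geometry mini-folds
(`helix_hairpin`, `beta_hairpin_pair`), a knotted mini-fold
(`shallow_trefoil`, 40 beads whose trefoil core excludes a straight
6-bead C-terminal tail, with a hydrophobic threading terminus), and
kinematic scripts for the three mechanisms.  The shallow-trefoil
fixture gives its last 16 residues Ile/Leu identities so that the
quasi-chemical term produces the terminus-to-body attraction the
knotting mechanism relies on — mirroring natively-knotted proteins
whose threading C-terminal helix is hydrophobic.

These fixtures exercise every code path with known ground truth, and
the folding experiments on them demonstrate the *mechanisms* —
ratchet acceleration, late knotting, the knot-promoting effect of
non-native attraction — at desk scale.  They do not emulate real
protein energetics: sequence effects enter only through one synthetic
matrix; solvent, side-chain packing and dimerization are absent.
Passing tests therefore validate the machinery and the qualitative
phenomenology, not quantitative rates or probabilities for any real
protein.  Reproducing published coarse-grained numbers for real
systems requires their PDB structures as input, which the package can
consume (`load_ca_trace()`) but does not ship.

## Problem sizes and study conditions

The built-in experiments were sized once, as the package's study
conditions, and the tests and the acceptance script use the same
numbers:

* folding recovery: `helix_hairpin` (20 beads), 20 seeds, MC at
  `kBT = 0.45`, up to 1.5e5 sweeps, success = final RMSD below 1 Å;
* ratchet acceleration: same fold at `kBT = 0.8` (near the folding
  midpoint, where unbiased first passage is slow and the pawl has the
  most to contribute), 20 paired seeds, budget 8e4 sweeps,
  `k_ratchet = 1000`, one-sided sign test on sweeps-to-Q ≥ 0.9;
* non-native contrast (`knotting_contrast()`): `shallow_trefoil`
  (40 beads), 20 paired starts generated by unfolding at high
  temperature until Q < 0.1 and unknotted, then unbiased evolution for
  2.4e4 sweeps at `kBT = 1.0` — just above the native-only melting
  midpoint (~0.9), where the purely native-centric chain stays expanded
  while the quasi-chemical attraction keeps it compact — with
  `lambda_nn = 0` versus `0.5`; success = a knotted frame among the
  last 8 saved frames.  The contrast is measured in this early-folding
  regime because ratchet-driven completion to the knotted native state
  is a few-percent event for *both* force fields at these sizes (and
  productive biased trajectories are rare in general), leaving no
  statistical power at desk scale; the spontaneous knotting propensity
  of the compact partially-folded chain is where the non-native effect
  is thermodynamically driven, and it is the same readout as a
  knotting-probability-versus-time curve;
* sampler calibrations: 2e5-step harmonic-well runs, 6e4-proposal
  double-well occupancy runs.

`k_ratchet` defaults to roughly `2 kBT K^2` with K the number of native
contacts, so that losing a single formed contact below the record costs
on the order of `kBT` — strong enough to engage the pawl, weak enough
not to freeze the chain.

## Known limitations

* The determinant-based detector misses knots with |Δ(-1)| = 1 and
  conflates knot types with equal determinants.
* Radial closure can shift a shallow knot's core boundary by a few
  residues; core positions should be read with that tolerance.
* The MC engine's time axis is a proxy for dynamics; mechanism
  statistics from MC trajectories inherit that approximation.
* The Onsager-Machlup ranking applies to Langevin stride-1 trajectories;
  for MC trials the protocol keeps the first productive trajectory per
  start instead (the action is not defined for Metropolis paths).
* The quasi-chemical matrix is a documented hydropathy surrogate;
  conclusions that depend on specific pair energies (rather than the
  generic hydrophobic attraction) should be re-run with a real
  statistical potential supplied by the user.
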