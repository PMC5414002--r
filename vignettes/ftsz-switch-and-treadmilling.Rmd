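---
title: "The FtsZ open/closed switch and treadmilling of single-stranded filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The FtsZ open/closed switch and treadmilling of single-stranded filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

FtsZ is the tubulin-homolog GTPase that assembles the bacterial cytokinetic
Z ring from single-stranded protofilaments. Two long-standing puzzles follow
from that single-strandedness. First, FtsZ assembly is cooperative — it has
a critical concentration and a lag phase — which a one-dimensional polymer of
rigid subunits cannot produce (isodesmic assembly has neither). Second, FtsZ
filaments treadmill: they grow at one end while shrinking at the other, which
requires the two structurally distinct ends to also be kinetically distinct,
something rigid subunits in a single strand cannot arrange either.

Both puzzles dissolve if the subunit has two conformations — a *closed* form
adopted by free monomers and an *open* form adopted by polymerized subunits —
with the closed-to-open switch paid for by the free energy of forming a
longitudinal interface. This package implements, as reusable and tested code,
the two halves of that argument:

1. **Structural analyses** that classify FtsZ coordinate models as open or
   closed, measure the interdomain rotation that separates the two states,
   compute all-versus-all RMSD matrices, landmark-atom displacements,
   longitudinal-interface burial and filament axial repeats.
2. **A stochastic kinetic model** of a single-stranded, tubulin-like filament
   with (or without) a polymerization-associated conformational switch,
   simulated exactly with the Gillespie algorithm, that reproduces
   cooperativity, breakage suppression and treadmilling.

A synthetic-structure generator makes every structural operation testable
without downloading coordinates.

# Structural analyses

## The coordinate model

`read_structure()` parses PDB and mmCIF files (via bio3d) into a plain atom
table with author residue numbering, keeping HETATM records (nucleotides form
a large part of the longitudinal interface) and the unit cell when present.
Alternate locations are resolved to the highest-occupancy conformer, ties to
altloc "A"; insertion-coded residues are distinct residues ordered after the
base number. Symmetry mates are *not* expanded from the space group: a
protofilament neighbor is built from one explicit operator with
`build_filament()`, which is all the analyses ever need.

## Superposition and its rejection rule

Residues are paired by global sequence alignment (Needleman–Wunsch, BLOSUM62,
affine gaps 11/1 — the conventional choice, recorded in the output) on the
one-letter sequences of Cα records; residues without a Cα are dropped, never
interpolated. `kabsch()` solves the weighted least-squares rotation with SVD
and corrects reflections, so the transform is always a proper rotation.

`superpose()` then iterates up to `cycles` rejection rounds (default 5):
after each fit, pairs whose deviation exceeds `cutoff` (default 2.0) times
the current RMS deviation are discarded and the fit repeated. This mirrors
the semantics of the interactive tools used to quote pairwise RMSDs in the
structural literature. Published pairwise values are reproduced with
rejection *on*; all-versus-all matrices (`rmsd_matrix()`) default to zero
cycles so every sequence-matched residue contributes. Because the rejection
threshold is a multiple (>1) of the RMS itself, the reported RMSD is
non-increasing from cycle to cycle; iteration also stops once the RMS reaches
numerical zero.

## Interdomain rotation and the open/closed call

FtsZ's two domains — the N-terminal GTP-binding domain (NTD) and the
C-terminal GTPase-activation domain (CTD), joined by helix H-7 — move as
near-rigid bodies. `interdomain_rotation()` therefore uses fixed, named
domain intervals rather than automatic dynamic-domain detection: the NTD of
one structure is superposed on the other's (with rejection), and a Kabsch fit
of the CTD pairs in that frame yields the rotation. The angle is
`acos((trace − 1)/2)`; the axis is the rotation's fixed eigenvector with its
sign set so the screw translation is non-negative. The H-7 register shift
that accompanies opening is not computed separately; it is absorbed into the
screw translation.

Published NTD windows differ slightly between analyses (residues 13–165 in
one figure, 12–176 in another), so three presets ship
(`ftsz_domains("standard"/"narrow"/"extended")`, default NTD 12–165) and the
interval is an ordinary argument.

`classify_conformation()` labels a structure *open* when its angle against a
closed reference is at least `threshold` degrees. The default threshold of
15° is the midpoint between the two observed clusters (near 0° and near 27°);
because the census is strongly bimodal, the call is insensitive to the exact
value. Landmark displacements (`landmark_displacement()`, e.g. the R29
guanidinium carbon or the R191 Cα) are Euclidean distances after NTD
alignment; presets identify residues by author number only, since published
residue naming is not always consistent.

## Surface burial and filament geometry

`sasa()` is a Shrake–Rupley implementation with a deterministic
golden-section sphere point set (no RNG, bit-reproducible; 960 points per
atom by default — doubling changes totals by well under 1%), Chothia-style
van der Waals radii and a 1.4 Å probe. `interface_bsa()` reports the SASA
lost on complex formation both as the half-sum (the PISA "interface area")
and as the total, because published burial figures of ~700 vs ~1200 Å² do not
state the convention; the convention used is always recorded in the report.
Contact residues are those losing more than 0.1 Å².

`filament_repeat()` superposes two sequence-identical subunits and returns
the translation component along the screw axis — for the crystal filaments in
question, a near-pure ~44 Å translation (open form) or ~45 Å (closed
pseudofilaments).

# The kinetic model

## Reactions and energies

The simulator (`sim_params()`, `build_rates()`, `run_ssa()`) works in reduced
units: energies in kT, concentrations in units of a reference `c0`, times in
units of `1/(k_on c0)`. A filament is a string of subunits ordered from the
minus end (bottom face exposed) to the plus end (top face exposed); the
nucleotide of subunit *i* sits on its top face and forms interface *i*
(tubulin-like geometry), so the plus-terminal nucleotide is solvent exposed.

The elementary rates, all detailed-balance consistent:

| reaction | rate |
|---|---|
| association at an end | `k_on · c` (× `end_asymmetry` at the asymmetric end) |
| end dissociation over interface X | `k_on · c0 · exp(dG_X + dG_switch)` |
| internal breakage of interface X | `k_on · c0 · exp(dG_X)` |
| dimer nucleation (ordered pair) | `k_on · c · exp(−dG_switch)` |
| dimer dissolution | `k_on · c0 · exp(dG_X + dG_switch)` |
| hydrolysis per buried NTP interface | `k_hyd` |
| exchange per exposed NDP | `k_exch` |
| annealing per ordered filament pair | `k_on / Ω` (off by default) |

The switch enters in exactly three places. A departing end subunit relaxes to
the closed monomer form and cashes in `dG_switch`, which makes end loss
`exp(dG_switch)`-fold faster than breakage of the same interface inside the
filament — the two halves of a broken filament stay polymerized and cannot
switch. Dimer nucleation pays two switches for one interface, so
`K_dimer = exp(−dG_X − 2·dG_switch)/c0` while elongation pays one,
`K_elong = exp(−dG_X − dG_switch)/c0`: nucleation is disfavoured by
`exp(−dG_switch)` relative to elongation, which is precisely what makes
assembly cooperative with critical concentration
`c_crit = c0 · exp(dG_interface_T + dG_switch)`. The *rigid* variant forces
`dG_switch = 0` and `end_asymmetry = 1`: isodesmic assembly, breakage
identical to end loss, no coupling of structural and kinetic polarity.

Two modelling points were genuinely open and are decided as follows.
**Where the end asymmetry acts:** adding a subunit at either end has the same
net energy change but proceeds through stereochemically different pathways,
so `end_asymmetry` is a kinetic prefactor that by default multiplies
association *and* dissociation at the asymmetric end (`asymmetry_on =
"both"`), leaving every equilibrium constant untouched; applying it to
association only (also available) would make the two ends thermodynamically
different, which the model does not claim. **Terminal nucleotide exchange:**
whether the exposed terminal NDP of a filament exchanges is switchable
(`exchange_in_filament`, default on, consistent with fast solution exchange
of exposed NDP). "Plus" and "minus" are structural labels only; the package
deliberately makes no claim about which biological end is the kinetic plus
end, and `mirror_params()` produces the exact head-to-tail mirror process
(realized by relabelling the ends of the canonical simulation, which is the
mirrored chain exactly — every end-resolved observable changes sign
bit-exactly for the same seed).

## Exactness and its oracles

`run_ssa()` is the direct Gillespie method — exponential waiting times from
the total propensity, categorical selection of the next reaction — rather
than an approximate leap scheme, because the test suite checks it against
exact references: `exact_stationary_small()` enumerates the full state space
of a closed system of up to 8 subunits and solves the stationary distribution
linearly; `isodesmic_equilibrium()` and `critical_concentration()` provide
the closed-form equilibria; waiting times are tested against the exponential
law. Identical parameters and seed give bit-identical event logs.

Default parameters are the package's own choice of a clearly treadmilling
regime (the underlying schema is qualitative and publishes no rates):
`dG_T = −13`, `dG_D = −9`, `dG_switch = 8`, `end_asymmetry = 5`,
`k_hyd = 0.02`, `k_exch = 10`, `c_free = 0.07`. The reasoning is elementary
rate algebra: the plus end gains `5 × 0.07 = 0.35` subunits/s against a
T-interface loss of `5·exp(−5) ≈ 0.03`; hydrolysis at 0.02/s leaves a cap of
roughly 15 NTP interfaces, so the minus end exposes NDP interfaces and loses
`exp(−1) ≈ 0.37` subunits/s against a gain of 0.07; breakage at `exp(−9)` per
internal NDP interface leaves a mean filament lifetime of a few hundred time
units. Raising `k_hyd` toward the growth rate destroys the cap and the
filament with it — a real feature of the model, not a numerical artifact.

## Measurements

`measure_treadmilling()` defines velocity as (net additions at the plus end −
net additions at the minus end)/2 per unit surviving time of a tracked
filament, with a block-bootstrap confidence interval; a filament treadmilling
steadily at *v* gains *vt* at one end and loses *vt* at the other, so the
estimator returns *v* with its sign tied to the structural polarity.
`breakage_vs_endloss()` compares per-interface event rates (events divided by
interface-time integrals accumulated during the run) with an exact
conditional Poisson interval; by construction the ratio is
`exp(−dG_switch)`. `mass_curve()` scans closed systems over a concentration
grid, reporting equilibrated polymer mass fractions (flagging drift between
the third and fourth quarters of the run), the time to half-plateau as a lag
proxy, and — through `estimate_c_crit()` — the pinned free-monomer
concentration above the onset.

Two statistical subtleties matter when comparing simulation to the oracles.
Time-series snapshots are autocorrelated, so χ² comparisons use fast-mixing
parameter regimes and snapshot spacings near the relaxation time, and the
two-state dimer test uses the analytic time-average variance
`p(1−p)·2τ/T`. And with breakage enabled but annealing off, fragmentation is
irreversible, so the stationary state is not the Boltzmann equilibrium;
equilibrium comparisons (isodesmic closed form, critical concentration)
therefore enable annealing, whose rate (`k_on` per ordered pair) is fixed by
detailed balance against breakage. In a clamped supercritical monomer bath a
rigid filament with breakage fragments and grows without bound — correct
isodesmic physics — so rigid-variant equilibrium runs use subcritical
concentrations.

The rigid-variant zero-velocity check is run at equilibrium (`k_hyd = 0`,
all-NTP): there the mean velocity is exactly zero by detailed balance. With
hydrolysis on, the tubulin-like nucleotide geometry is not microscopically
end-symmetric even for rigid subunits (only the plus-terminal nucleotide is
exposed and exchangeable), so no symmetry argument pins the mean velocity,
and the package does not assert one.

# The synthetic-structure generator

`make_two_domain_structure()` builds a Cα-only chain — a compact
pseudo-globular "NTD" (154 residues, numbered 12–165), a straight H-7-like
segment (27 residues, 169–195) and a "CTD" blob (121 residues, 196–316) —
deterministically from a seed. `perturb_conformation()` applies a known
interdomain rotation about a chosen axis through the domain hinge, a helix
shift along its own axis, and isotropic Gaussian noise; `make_filament_crystal()`
stacks chains with a fixed axial repeat and optional twist. This emulates
exactly the geometric content the structural operations consume: known
rotations are recovered to 0.1° (noise-free) and 0.5° (noise 0.3 Å), the
classifier is perfect more than 3° from threshold, and generated filaments
return their repeat to machine precision.

What the generator does *not* emulate: real backbone geometry, side chains,
packed domain interfaces, nucleotides, or crystallographic disorder. Cα-only
chains make BSA values physically meaningless at protein-like radii, so
interface tests inflate the radii (`uniform_radius = 3`) to create measurable
contacts; synthetic BSA magnitudes are therefore *not* comparable with the
~700/~1200 Å² figures from full-atom deposited structures. Passing the
synthetic suite demonstrates the correctness of the geometry and kinetics
machinery, not agreement with any particular crystal form; validation against
the deposited entries runs whenever those files are placed where the
acceptance tests look for them (see `tests/testthat/test-acceptance.R` —
the package never downloads).

# Problem sizes and runtime

The shipped tests and the acceptance script use: 302-residue synthetic
chains; 10–20 perturbation specs per recovery loop; closed systems of 2–5
subunits for exact-oracle comparisons (10,000 time units, snapshots every
10); 300-subunit decaying filaments for breakage/end-loss ratios; 100-subunit
closed systems over 2–4 concentrations and ~2,000–2,500 time units for the
assembly curves; and 250–5,000 time units of treadmilling. These sizes give
stable statistics at interactive runtimes (the full suite in roughly two
minutes, the acceptance script in under one).

# Known limitations

- Two-domain motion with *named* domains; no automatic dynamic-domain
  detection, normal modes, or morphing.
- No space-group expansion; lattice neighbors require an explicit operator.
- The kinetic model is zero-dimensional (well-mixed), single-stranded, with
  no membrane anchoring, bending mechanics or FtsA co-polymerization, and its
  rates are reduced-unit choices, not fits to measured FtsZ kinetics.
- Annealing is implemented but off by default; breakage/annealing dynamics
  beyond detailed-balance bookkeeping (e.g. length-dependent rates) are out
  of scope.
- SASA treats all atoms as spheres with fixed radii; no solvation energetics.
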