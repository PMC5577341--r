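---
title: "Methods: conformational-landscape analysis of REMD peptide ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational-landscape analysis of REMD peptide ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remscape)
```

## Scope and model system

`remscape` analyses conformational ensembles of intrinsically disordered
peptides sampled by temperature replica-exchange (REMD). Its reference
system is the amyloid-beta 42-mer
(`DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA`) alone or bound to one of
three N-terminal hexapeptides (`DAEFRH`, `DVEFRH`, `DTEFRH` — wild type and
the A2V/A2T familial variants). All regional analyses use the standard
four-range scheme on the 42-mer: NTR (1–16), CHC (17–21), turn (22–29) and
CTR (30–42), with preCHC (11–16) as a derived sub-range. The biology in
one line: transient CHC–CTR beta-hairpins and the D23–K28 salt bridge are
aggregation-relevant features of the monomer ensemble, and hexapeptide
binding shifts their populations; this package provides the machinery to
quantify such shifts.

Because all-atom explicit-solvent REMD is out of desk-scale reach, the
package ships a first-class synthetic-data module: a toy coarse-grained
REMD sampler and a state-mixture generator with planted populations. Every
analysis is validated end to end against these generators, whose ground
truth is known by construction.

## Containers

A `topology` (chains, residues, atoms with element, partial charge, LJ
sigma/epsilon, intrinsic Born radius, hydrophobic flag) is built from a
one-letter sequence by `build_topology()`. Residue templates carry the
standard PDB heavy atoms plus a backbone amide H used only by the
secondary-structure module; side-chain hydrogens are never modelled because
every analysis here (contacts, SASA, energetics) is defined on heavy atoms.
Charges are simplified element/group defaults normalised to integer residue
net charges (ASP/GLU −1, LYS/ARG +1, HIS and termini neutral — the
protonation of the three histidines is a configuration choice, exposed
through the TSV parameter table rather than hard-coded). They are adequate
for the synthetic energetics the package performs and are fully
replaceable via `read_parameters()`.

An `ensemble` stores frames (nm) with per-frame time/replica/temperature
metadata. Interchange format is multi-model PDB (read through `bio3d`,
written by the package so that TER/MODEL bookkeeping is explicit); a
plain-text internal store round-trips metadata exactly.
`select_production()` implements the production-window convention used
throughout: the window `(start, end]` is half-open so that a 60–200 ns
window at 50 ps stride gives exactly 2,800 frames per replica and 33,600
over twelve replicas.

## Secondary structure

`assign_ss()` is a hydrogen-bond-pattern assignment in the
Kabsch–Sander/DSSP family. The electrostatic bond energy is
`27.888 (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol (distances in
Angstrom; bond when E < −0.5; any distance below 0.5 Angstrom returns +Inf
as a clash guard). Helices come from consecutive i→i+4 (ALPHA) or i→i+3
(THREE10) turn starts; strands from parallel/antiparallel bridge patterns
grouped into ladders with beta-bulge merging (gaps of at most one residue
on one strand and four on the other); hydrogen-bonded turns and bends
(Calpha kink > 70 degrees) map to TURN; everything else, including the
rare pi-helix, is COIL. This five-class folding (H→ALPHA, G→THREE10,
E/B→STRAND, T/S→TURN, rest→COIL) is the scheme used for all propensity
profiles; folding the bend class into TURN is deliberate, since disordered
Abeta ensembles report turn fractions that are only reachable with bends
included.

Two conventions matter for reproducibility:

* The amide H is always reconstructed at 1.0 Angstrom from N along the
  previous residue's C=O direction, the convention of the reference DSSP
  implementations; stored H coordinates never influence the assignment.
  We adopted this (rather than an N–C(prev) bisector placement) so that the
  package's labels are directly comparable to mdtraj/DSSP output; the test
  suite holds the five-class agreement on ideal helices, the calibrated
  hairpin and toy-REMD frames at or above 95%.
* Each donor keeps only its two lowest-energy acceptors, as in DSSP, which
  suppresses spurious bifurcated bonds in crowded geometries.

Propensity profiles (`ss_propensity()`) report per-residue class
percentages with block standard errors: the frame sequence is cut into
`n_blocks` contiguous equal segments (four by default, mirroring the four
35 ns blocks of a 140 ns production window) and SE = sd(block means)/sqrt(n).
The frame count must divide evenly; the pipeline trims accordingly.

## Geometry, contacts, reaction coordinates

Rg is mass-weighted; RMSD uses the Kabsch superposition with the proper
rotation branch enforced (determinant correction), cross-checked in the
tests against an independent quaternion oracle and `bio3d`. Contact maps
count a residue pair in contact when the Calpha–Calpha distance
(default cutoff 0.65 nm, the field-standard Calpha definition) or the
minimum heavy-atom distance (default 0.4 nm) is below cutoff; intra-chain
maps zero pairs with |i−j| < 3 so that only non-sequential contacts are
reported. Difference maps subtract bound minus free and mask entries with
|delta| at or below 0.06, the probability-difference threshold used for
tertiary-contact interpretation. Salt bridges use the minimum side-chain
N–O distance below 0.4 nm. SASA is Shrake–Rupley quadrature on a
deterministic golden-spiral grid (default 240 points; 960 reproduces an
isolated sphere's closed-form area within 1 Angstrom^2); the hydrophobic
subset sums carbon and sulfur contributions.

The two reaction coordinates of the hairpin landscape are
`nbeta` — the fraction of the 18 CHC+CTR residues assigned STRAND — and
`ncontact` — the number of CHC–CTR Calpha contacts divided by
`norm_pairs = 65` (the 5×13 theoretical maximum of CHC×CTR pairs) and
clipped to [0, 1]. The normalisation constant is explicit configuration:
"normalised to one" admits several conventions, and the theoretical
maximum is the one that needs no empirical calibration. Under it the
observed `ncontact` values stay well below 1, which only compresses the
landscape's x-axis; state rectangles are configuration too, so nothing
downstream depends on the choice.

## Landscape and states

`pmf2d()` histograms the coordinate pairs on a 20×20 grid over [0,1]^2
(binning is display resolution only) and reports
`W = −kB T ln(P/P_max)` at 300 K by default; replica temperatures of a
pooled 276–308 K production ensemble bracket this value and the choice
only scales the surface. Occupied minima are exactly zero; empty bins are
NA, never zero. State populations are computed on the raw coordinates —
never on PMF bins — over pairwise-disjoint rectangles (closed-left,
open-right, final edge closed), with an `Others` complement so the table
always sums to 100%. The bundled `default_state_rectangles()` layout
places S6 in the high-`nbeta`/high-`ncontact` corner (the hairpin-rich
region) and tiles S1–S5 over the low-order part of the plane; it is a
validation layout for synthetic data, not a claim about any particular
simulated system, and users supply their own rectangles for real analyses.
`hairpin_subset()` applies the strict `nbeta > 0.6` filter that isolates
frames with a formed CHC–CTR hairpin.

## Clustering

`gromos_cluster()` is the greedy maximum-neighbour algorithm: the frame
with most neighbours below the cutoff (strictly; 0.3 nm pairwise
Calpha-RMSD in the production protocol) seeds a cluster, members are
removed, and the procedure repeats. Ties break to the lowest frame index,
making results deterministic; the cluster center (the max-neighbour frame)
is the representative structure. Sub-population clustering reuses the same
operation on state-filtered ensembles with the 42-mer Calpha selection.

## Binding energetics

`mmgbsa_binding()` is a single-trajectory end-state decomposition:
interchain Coulomb (`ke = 332.0636` kcal Angstrom/mol/e^2, no cutoff) and
Lennard-Jones (Lorentz–Berthelot) molecular-mechanics terms, a
generalized-Born polar solvation change (Still pairwise `f_GB` with
Hawkins–Cramer–Truhlar pairwise-descreening effective radii, recomputed
per species), and a surface-area nonpolar term
(gamma = 0.00542 kcal/mol/Angstrom^2; the constant offset b = 0.92 kcal/mol
cancels in the complex-minus-chains difference and is therefore excluded).
Intra-chain MM terms cancel exactly in the single-trajectory
approximation, 1–4 exclusions never arise (only interchain pairs enter),
and no configurational-entropy term is estimated. The GB model was chosen
over a finite-difference Poisson–Boltzmann solver deliberately: it is
desk-scale, and its single-ion limit is the Born closed form
(−81.98 kcal/mol at q = 1e, R = 2 Angstrom, eps 1/80), which anchors the
implementation analytically. The report schema (dE_vdw, dE_elec, dG_polar,
dG_nonpolar, dG_bind, each mean ± block SE) is solver-agnostic, so a PB
backend can be slotted in without interface changes.

## Synthetic data: what it emulates, and what it does not

`geometric_ladder()` reproduces exponential temperature spacing (endpoints
exact; the emulated production protocol spans 276.0–592.3 K over 64
replicas, i.e. 64 × 200 ns = 12.8 microseconds aggregate).
`swap_acceptance()` is the Metropolis exchange rule. `run_toy_remd()`
samples either a Cartesian bead chain (harmonic bonds, optional square
Go wells; used for equipartition and temperature-dependence checks — a
stiff spring at its rest length carries kT/2 mean potential energy) or a
torsion-space backbone chain with Gaussian basins at the helix/strand
minima, whose frames carry complete backbones and are therefore
assignable. Replicas start from a compact ring (Cartesian) or an extended
chain (torsion); pseudo-time advances 1 ps per MC step so the
production-window logic is exercised unchanged.

`sample_mixture_ensemble()` plants state populations directly: each frame
draws a state, hairpin frames chain a calibrated CHC–CTR beta-hairpin
backbone template (ideal strand dihedrals at 17–21/30–34; the eight turn
dihedrals were optimised once, against the package's own hydrogen-bond
energy, so the antiparallel registry pairs (17,34), (19,32), (21,30) form
proper Kabsch–Sander bonds, and are frozen as constants), open frames
chain helix/coil dihedrals, and the D23–K28 bridge is planted per frame by
positioning the lysine amine. Gaussian coordinate noise (default 0.002 nm)
is added last. The generator returns its ground truth: per-frame state
labels and per-state reference label vectors (the assignment of each
noise-free template, with planted STRAND confined to the paired core and
planted ALPHA to the helix instructions). Freely drawn coil segments can
form incidental strands or helices in individual frames — a few percent
per residue at most in practice; this background is real structure in the
generated coordinates, not plant, which is why recovery tests compare
planted residues only.

What the generator does **not** emulate: force-field physics, solvent,
realistic side-chain rotamers (side chains extend along a deterministic
zigzag; functional-group geometry is only positioned meaningfully where an
analysis reads it, as for the salt bridge), within-state conformational
diversity beyond coil redraws and noise, and any of the published ensemble
averages of real Abeta simulations. Passing the validation suite therefore
demonstrates that the analysis machinery is correct and self-consistent —
not that it would reproduce any particular published trajectory's numbers.

## Numerical choices and degenerate inputs

* kB = 0.0019872 kcal/mol/K everywhere.
* Contact/SASA/GB distance work is done in double precision with exact
  thresholds (`<` for contacts and neighbour tests); coincident duplicate
  atoms in SASA are counted once.
* `pmf2d` with all frames in one bin yields a single 0 bin; zero frames is
  an error. Block protocols truncate remainders except `ss_propensity` and
  `contact_map`, which demand even splits (the pipeline trims for them).
* Kabsch superposition of degenerate (collinear) selections still returns
  a proper rotation via the determinant correction.
* Moving averages are centered and truncated at the series edges.
* All stochastic operations take explicit integer seeds; a single root
  seed drives the pipeline.

## Problem sizes in the validation suite

The shipped tests run the generators at deliberately modest sizes chosen
to exercise every code path with tight statistics: mixtures of 8–4,000
frames (4,000 for population/propensity recovery, where a planted 47%
hairpin state, planted per-residue strand/helix propensities and a planted
13% salt bridge are all recovered within three block standard errors),
toy-REMD runs of 10^3–10^5 Monte Carlo steps, clustering on ensembles of
5–60 frames, and energetics on complexes of a few hundred atoms over 2–10
frames. Oracle-equivalence checks (brute-force contact maps, quaternion
RMSD, pair-sum MM energies, exhaustive gromos clustering) run on fixtures
of at most 20 frames, where exhaustive recomputation is exact.

## Known limitations

* The secondary-structure module targets the five-class scheme; pi-helix
  and polyproline-II are not distinguished, and residual disagreement with
  reference DSSP (a few percent on strand-rich frames) is concentrated at
  ladder edges and beta-bulges.
* The GB/SA energetics is a schema-compatible surrogate for PB-based
  decomposition, with simplified charges; its numbers are meaningful for
  designed fixtures and trend tests, not for comparison with published
  binding energies.
* No periodic-boundary handling: ensembles must contain whole molecules.
* The toy REMD sampler reproduces the statistical structure of
  replica-exchange data (multi-replica, time-correlated, temperature
  dependent), not peptide physics.
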