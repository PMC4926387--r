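---
title: "Mapping protein-excipient interaction hotspots by blind docking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein-excipient interaction hotspots by blind docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excidock)
```

## Why blind docking for formulation work

Most protein-ligand docking assumes a known binding site. Excipient
screening inverts the question: for a sugar, amino acid, polyol or
surfactant, *where* on the protein surface does it prefer to sit, and do
those preferred surfaces coincide with the patches through which two
protein molecules associate and eventually aggregate? `excidock` therefore
searches the entire surface with no site prior, reports *hotspots* —
surface regions where one or several excipients dock repeatedly and
favourably — and compares them with predicted protein-protein interfaces.
An excipient whose hotspots cover an aggregation-prone patch is a rational
candidate for a stabilising formulation.

This vignette is the package's methods account: the two energy models, the
search algorithms, every tunable that matters, what the synthetic
generators do and do not emulate, and the numerical decisions taken where
the design was genuinely open.

## The empirical flexible-docking score

A pose of a flexible excipient against a rigid receptor is scored as

$$E_{tot} = E_{bind} + E_{pharma} + E_{ligpre}, \qquad
  E_{bind} = E_{inter} + E_{intra} + E_{penal}.$$

`E_inter` sums typed pair energies over all receptor-ligand heavy-atom
pairs within 6 Å; `E_intra` does the same over ligand atom pairs at bond
path separation ≥ 4 (so torsion moves are penalised for self-clashes but
1-2/1-3 geometry is not double counted). Hydrogens never enter the
geometry; donor/acceptor typing encodes hydrogen-bearing capacity instead
(`assign_atom_types()`, template-driven for the 20 amino acids,
element-driven for ligands).

Pair energies are piecewise-linear wells (all knots in `score_params()`,
distances in Å, energies in kcal/mol):

| pair type | shape |
|---|---|
| donor–acceptor | +5 below 1.5, 0 at 2.0, −2.5 on [2.3, 3.1], 0 at 3.6 |
| all other pairs | +5 below 2.0, 0 at 3.3, −0.4 on [3.6, 4.5], 0 at 6.0 |
| both charged | screened Coulomb $332.0636\,q_iq_j/(4r\cdot r)$ added |

The hydrogen-bond well is roughly six times the steric depth, reflecting
the dominance of polar contacts for small hydrophilic excipients; a clash
arm below 2.0 Å keeps donor–acceptor pairs from overlapping for free and
keeps the function continuous. `E_penal` is a fixed 10 000 whenever any
ligand atom leaves the search box, which removes escaped poses without
destroying gradient information inside the box. `E_ligpre` charges +5 for
each unsatisfied ligand preference: a formally charged ligand with no
opposite charge within 4 Å, and a ligand with ≥ 3 donors/acceptors forming
no hydrogen bond. `E_pharma`, a per-atom pharmacophore bonus, is
implemented (`pharmacophore_spec()`) but disabled by default — the method
is deliberately blind, and a pharmacophore is a site prior.

Two numerical decisions deserve emphasis:

* **Charge model.** Formal integer charges only (Asp/Glu −1, Lys/Arg +1,
  His neutral), with a distance-dependent dielectric $\varepsilon(r) = 4r$.
  Arginine's delocalised cation is carried on both terminal guanidinium
  nitrogens, which flags all guanidinium nitrogens as charged donors at
  the cost of overweighting Arg-carboxylate electrostatics; this is a
  typed empirical term, not a force field.
* **Short-range Coulomb clamp.** $\varepsilon(r) = 4r$ has no meaning
  below contact separation, and an unclamped $r^{-2}$ attraction would let
  opposite charges collapse into fused, unphysical poses that the ±100
  kcal/mol reporting bound then silently discards. Pair energies therefore
  evaluate the Coulomb term at $\max(r, 2.9\,\text{Å})$ (`elec_min_r`),
  capping a +1/−1 salt bridge near −9.9 kcal/mol — comparable to, but
  stronger than, a neutral hydrogen bond.

## The genetic algorithm

A chromosome is (translation, orientation quaternion, torsion angles);
torsions rotate the subtree on the far side of each active rotatable bond
(root = atom 1), then the rigid placement is applied about the ligand
centroid. Rotatable bonds are single, acyclic (bridge) bonds between
non-terminal heavy atoms; when more exist than the cap (default 5), the
bonds moving the most atoms are kept.

Defaults (`ga_config()`): population 800, 10 generations, tournament
selection of size 2, arithmetic crossover on translation with spherical
interpolation on orientation (rate 0.7), per-gene Gaussian mutation
(1 Å / 15° / 30°, rate 0.1), elitism 2. The search box is the receptor
bounding box + 5 Å. Half the initial population is placed uniformly in the
box and half on a 3–6 Å shell around random surface atoms — still blind,
but concentrated where contacts are possible, as whole-surface engines do.
After the last generation each reported solution undergoes a bounded
deterministic coordinate descent (≤ 120 sweeps over translation steps
1/0.5/0.25 Å, rotations 20/10/5°, torsions ±30/15°); refinement can only
lower energies. Finally poses with $|E_{tot}| > 100$ kcal/mol are
discarded as unphysical (the bound is a magnitude cap: observed pose
energies lie in the tens), poses are thinned to distinct binding sites at
2 Å heavy-atom RMSD, at most 100 sites are kept and the best 10 returned.

One seeded private RNG stream drives each `ga_dock()` call, so a run is
bit-reproducible from its seed and never perturbs the caller's RNG.
`dock_panel()` derives per-ligand seeds as `seed + index`.

## Softened Lennard-Jones rigid docking

Protein-protein docking scores a placed pair with

$$V(r) = \frac{1}{\alpha\sigma^6 + r^6}
  \left(\frac{4\varepsilon\sigma^{12}}{\alpha\sigma^6 + r^6}
  - 4\varepsilon\sigma^6\right)$$

summed over intermolecular heavy-atom pairs within 8 Å, plus a
small-weight (0.1) screened Coulomb term for charged pairs. With
$\alpha = 0.4$, $\sigma = 0.33$ nm, $\varepsilon = 0.5$ — the typical
unbound-protein calibration — the potential is finite everywhere
($V(0) = 4\varepsilon(1-\alpha)/\alpha^2 = 7.5$), which lets a coarse
search tolerate clashes that local refinement later resolves. $\sigma$ is
stored in the unit of the coordinates (3.3 Å). The implementation
evaluates $V$ as $4\varepsilon(x^2 - x)$ with
$x = \sigma^6/(\alpha\sigma^6 + r^6)$, which reduces *exactly* (to the
last bit) to the textbook 12-6 form at $\alpha = 0$.

The search is a direct scan, not FFT correlation: the receptor becomes a
probe-potential grid (1 Å spacing, box + 10 Å margin) holding the summed
soft-LJ field and, separately, the Coulomb field per unit charge (clamped
at 0.5 Å inside the clash core). For each orientation of a quasi-uniform
rotation set, every lattice translation of the ligand centroid is scored
by summing the fields at the nearest-node ligand atom positions — a few
array shifts per atom. The best candidates (3 × `n_keep`) are re-scored
with the exact pairwise sum, the top 100 kept and refined by coordinate
descent (translation steps halving 1 → 0.125 Å, rotations 10 → 1.25°).
Ties break towards the lower orientation index, then lexicographic
translation.

Orientation sets: for n = 1, 12, 24, 60 the exact rotation groups
(identity, tetrahedral, octahedral, icosahedral) are used — a group is the
optimal uniform arrangement, and at n = 60 the minimum pairwise geodesic
separation is exactly 72°. Other n are served by greedy farthest-point
subsampling of a super-Fibonacci quaternion pool, seeded at the identity,
deterministic across runs.

Solutions are clustered greedily in energy order at 3 Å ligand-Cα RMSD in
the common receptor frame (all heavy atoms for ligands without Cα); the
leader of each of the first 10 clusters is reported.

## Hotspot construction

* `contact_residues()`: a residue is in contact when any of its heavy
  atoms lies within **4.0 Å** of any probe atom. All cutoffs in the
  package are closed (≤): the boundary case is included, one convention
  applied everywhere.
* `interaction_map()` (3.5 Å): oppositely charged pairs are typed
  *electrostatic* first — a salt bridge outranks its hydrogen-bond reading
  — then donor–acceptor pairs at 2.0–3.5 Å are *hbond*, the rest
  *hydrophobic*; one entry per (residue, type) at the minimum distance.
  Map entries are always a subset of the 4 Å contact set.
* `assign_spots()`: poses connect when they share a contact residue **or**
  their centroids are within 8 Å; spots are the connected components,
  labelled by best member energy. The same rule merges spots across
  excipients into hotspots (`consolidate_hotspots()`), which makes
  consolidation idempotent and guarantees every pose lands in exactly one
  hotspot. The 8 Å default is the approximate diameter of a small-molecule
  binding footprint; it is a parameter, not a constant.
* Reporting compresses residue numbers per chain into maximal runs
  bridging gaps of ≤ 1 (`"Lys43-Trp47"`), the conventional table format.

`overlap_report()` counts residues shared between each hotspot and the
receptor-side interface of each protein-protein solution; a hotspot
matches at ≥ 1 shared residue (the qualitative criterion), and the
fraction count/|hotspot| is reported so stricter thresholds can be applied
downstream. Chains are compared by residue count, not atom contacts.

## Trajectory validation and the Tm correlation

Trajectories are multi-model PDB snapshots. `contact_persistence()` is the
fraction of frames with minimum residue-ligand heavy-atom distance ≤ 4 Å;
1.0 is the "contact maintained throughout" criterion. `rmsd_series()`
superposes each frame onto the reference by the Kabsch least-squares fit
(reflections disallowed) before computing RMSD; `rmsf()` measures each
residue's Cα fluctuation about its trajectory-mean position without
superposition, so feed pre-aligned frames when internal fluctuations are
wanted.

`mean_binding()` averages per-pose energies and reports at two decimals,
rounding halves away from zero. `fit_linear()` is ordinary least squares
of Tm on mean binding energy; exclusions are named flags
(default `"arginine"`, a detergent-like negative control that lowers Tm
despite binding strongly) rather than hard-coded drops. The bundled
reference tables (`fab_a33_binding_energies()`, `fab_a33_tm()`) ship as
plain CSVs; the acceptance script recomputes the eight reported means and
the regression from them at run time.

## What the synthetic generators emulate

`make_toy_receptor()` builds a jittered α-helical Cα trace with
hydrophobic Cβ pseudo-atoms and carves one concave polar pocket: lining
tip atoms (donors, acceptors, optionally charged) on a 2.5 Å ring around
the pocket centre — inside the flat hydrogen-bond well for a centred probe
— plus a hydrophobic rim crown that blocks sideways approaches. The
default lining (2 donors, 2 acceptors, 1 carboxylate) emulates the acidic,
hydrogen-bond-rich surface sites that charged amino-acid excipients select
on real proteins. Because the ring diameter is below the 4 Å contact
cutoff, any pocket-occupying pose contacts the entire lining, and because
the remaining surface is purely hydrophobic, the pocket is the global
optimum for a polar probe *by construction* (the test suite verifies this
against an exhaustive grid scan).

`make_ligand()` provides four idealised excipient classes (arginine-like,
disaccharide-like, polyol-like, surfactant-like) with the class's hallmark
typing and rotatable-bond counts. `make_ppi_pair()` builds a two-strand
groove receptor (chains H and L) and a shorter strand ligand planted at
the half-register, knobs-into-holes pose where every contact sits at the
soft-LJ optimum — the global docking optimum by construction, with the
planted 4 Å interface sets returned as ground truth. `make_trajectory()`
adds Gaussian noise per frame and either rescales the ligand onto the
contact (persistence 1.0) or drives it beyond the cutoff for the second
half of the frames (persistence exactly ⌈n/2⌉/n).

What passing tests on these fixtures demonstrate: the search finds planted
global optima, the bookkeeping (contacts, spots, interfaces, persistence)
is exact, and the pipeline is deterministic. What they do not demonstrate:
force-field realism, side-chain flexibility, solvation or concentration
effects on real proteins — the fixtures use pseudo-atom chemistry on
purpose, and results on real systems inherit all the usual limitations of
rigid-receptor empirical docking.

## Problem sizes and runtime choices

The reference study conditions use GA population 800 × 10 generations per
excipient and 100 recorded rigid solutions from 60 orientations on a 1 Å
lattice. The packaged test systems are sized so a full run is interactive:
a 30-residue receptor (65 heavy atoms), 8-18-atom ligands, a 26-residue
protein pair, 10-20-frame trajectories. One `ga_dock()` run at reference
settings takes a few seconds; the ten-seed pocket-recovery study runs in
about two minutes; `rigid_dock()` at defaults in a few seconds. The demo
(`run_demo()`) shrinks the GA to population 150 × 5 generations, which is
ample for the demo receptor's single pocket.

## Degenerate inputs and error policy

Empty probe sets yield empty contact sets (not an error); a negative
cutoff, an empty structure, an unsorted solution list passed to
clustering, a selection matching no heavy atoms, fewer than two usable
correlation records or zero variance in the predictor all raise immediate,
stage-named errors. Malformed PDB coordinates report the offending line
number. Pipeline stages wrap their errors with the stage name and abort;
the absence of a Tm table or of any surviving pose degrades gracefully
with a warning.

## Known limitations

* The receptor is rigid everywhere; induced fit is out of scope.
* The empirical well knots are calibrated for contrast, not fitted to
  affinity data; absolute energies are ranking scores, not free energies.
* The formal-charge electrostatics overweights multi-nitrogen cations
  (see the arginine note) and ignores partial charges and desolvation.
* Hotspot connectivity depends on the 8 Å merge distance; very shallow,
  adjacent sites can merge or split near that threshold.
* The Tm correlation is a screening-level association across excipients
  at fixed concentrations, not a thermodynamic model; its R² is
  recomputed from the bundled data by `scripts/acceptance.R` rather than
  asserted as a constant.
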