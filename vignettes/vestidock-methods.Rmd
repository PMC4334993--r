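---
title: "Methods: limited homology modelling and desk-scale docking of peptide toxins on Kir channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: limited homology modelling and desk-scale docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Inwardly rectifying potassium (Kir) channels are homo- or hetero-tetramers
whose extracellular "outer vestibule" — the roughly 50-residue loop between
the two transmembrane helices, containing the hyper-variable turret and the
pore loop — is the binding surface for pore-blocking peptide toxins such as
tertiapin (TPN), a 21-residue bee-venom peptide with two disulfide bridges
and a highly basic C-terminal tail. Which channel isoforms a toxin blocks is
largely decided by a handful of vestibule residues. `vestidock` is a
desk-scale toolkit for asking that question *in silico*: swap a vestibule
sequence onto a fixed crystal-template backbone, reassemble the tetramer,
rigid-body dock a toxin conformer ensemble, compare ranked score profiles
between channel variants, and map hotspot residues by re-docking mutants.

Every stage is testable offline: a deterministic generator builds a
synthetic C4 channel with named contact rings and a tunable charged pocket,
plus a TPN-like basic peptide.

## Limited homology modelling (`thread_chimera`)

The chimera builder performs *fixed-backbone threading*: residues whose
identity is unchanged are copied verbatim; substituted residues keep their
template backbone (N, CA, C, O) bit-identically and receive an idealized
side chain. This "limited" guarantee — zero backbone displacement — is the
point of the method: it isolates the effect of vestibule chemistry from
backbone remodelling artefacts, and it is machine-checkable
(`max |Delta backbone| == 0` is an acceptance gate).

Side chains are built from internal coordinates (standard bond lengths and
angles, NeRF chain extension) over a coarse rotamer grid: chi1 in
{-60, 180, 60}, chi2 in {180, -60, 60, 90, -90}, chi3+ trans. The rotamer
with the fewest heavy-atom contacts under 2.4 Å to other residues
(excluding the covalently adjacent backbone, whose 1-3/1-4 distances are
bonded geometry) wins (ties:
smaller summed overlap, then grid order). There is no global minimization by
design; irreparable clashes are recorded in the build report, never silently
fixed. Equal-length substitution only (tolerance 0): the vestibules this
workflow targets align without indels, and rejecting length changes keeps the
backbone guarantee honest. Non-standard residues map to `X` in sequences and
are refused as threading targets.

Ramachandran classes use rectangular boxes (A: phi [-160,-20], psi [-120,50];
B: phi [-180,-20], psi [50,180] or [-180,-170]; L: phi [20,160],
psi [-60,90]). The named favored regions have no canonical published
boundaries; the boxes are a stated approximation, adequate for the ~90%%
favored sanity check they serve.

## Tetramer assembly (`derive_operators`, `assemble_oligomer`)

Operators are derived by least-squares superposition of chain A onto each
chain of a template tetramer and returned in cyclic order about the pore
axis, defined as the direction of least variance of the four chain
centroids (exactly the C4 axis for ideal input). Assembly accepts one
subunit (homotetramer) or four (heterotetramer in cyclic order), emits
chains A-D deterministically, and reports inter-chain backbone contacts
under 2.0 Å rather than failing.

## Docking model (`dock_rigid`)

The receptor is rasterized once at `spacing` (default 1.2 Å) into three
layers: `core` (voxel centers inside van der Waals radii), `surface` (a
shell of `surface_thickness`, default 1.5 Å, outside the core) and `charge`
(formal pH-7 charges, trilinearly splatted). For each rotation of a
deterministic Euler lattice the ligand is rasterized the same way and the
translational scan is a circular FFT cross-correlation:

    grid_score(d) = w_shape * [ S_R . S_L(d)  -  p * C_R . C_L(d) ]
                  + w_elec  * [ -(Phi_R . Q_L(d)) ]

with `p = core_penalty` (default 9) and `Phi_R` the receptor Coulomb
potential — the charge layer convolved once with a truncated
`332 / max(r, spacing)` kernel (cutoff 10 Å, no screening). Correlating a
potential with ligand charges rather than two sparse charge grids is what
makes electrostatics numerically meaningful at 1.2 Å spacing; the sign is
chosen so complementary charge pairs score positively. Per rotation the top
`candidates_per_rotation` (default 10) displacements enter a pool that is
rescored with a coarse element-typed contact potential (step function
within 4.5 Å), and

    score_total = w_shape*shape + w_elec*elec + w_contact*contact

with default weights (1, 0.5, 1), declared arbitrary: all downstream use is
within-run ranking, never absolute values, matching how initial-stage
docking scores are used in practice. Ties break by (score, rotation index,
lexicographic translation), making the whole path deterministic with no
randomness to seed.

The rotation set steps the polar angle uniformly (default 30°), scales the
azimuth count by sin(beta), and steps the spin uniformly; the identity is
always element 1. The 30° default is a deliberate desk-scale setting: a
single dock of the synthetic system costs ~1 min in pure R on one CPU, and
the sampling density is a single config knob for anyone with more budget.
Production engines sample orders of magnitude more finely; this toolkit
reproduces the *workflow* and its relative comparisons, not any external
engine's scores.

## Score profiles and comparisons (`score_profile`, `compare_profiles`)

A docking run is summarized by its descending top-N score profile (default
N = 2000) and by top-k means (default k = 5) per conformer. "Channel A docks
better than channel B" has no canonical test, so two scale-free statistics
are reported side by side: the rank-wise dominance fraction (share of
shared ranks where A beats B; ties 0.5) and a two-sided Mann-Whitney U test
on the score vectors. Dominance 1.0 over the top 50 ranks is the packaged
synthetic analogue of a sensitive/insensitive channel pair.

## Pose clustering (`greedy_cluster`)

Top-M poses (default 1000) are clustered greedily by ligand C-alpha RMSD in
the receptor frame (no re-superposition, so RMSD is a plain Euclidean
distance between transformed coordinate vectors): repeatedly take the
unassigned pose with the most unassigned neighbors within `radius` (default
9 Å) as a center and absorb its neighborhood. Neighbor-count ties go to the
higher-scoring pose, then the lower index — the greedy refinement stage's
center definition is not published anywhere authoritative, so this package
fixes one reproducibly. Cluster sizes are provably non-increasing in
creation order under this tie-break.

## Interface analysis

SASA is Shrake-Rupley on a golden-spiral lattice (default 960 points, probe
1.4 Å, Bondi-style radii, 1.8 Å fallback). Footprint classes per receptor
residue: `interfacing` if buried area (free minus complexed SASA) exceeds
1 Å², `inaccessible` if free SASA is under 5 Å², `bonded-link` for
interfacing residues that appear in a detected contact, else
`solvent-accessible`. H-bonds use heavy-atom geometry only — donor-acceptor
distance <= 3.5 Å and antecedent-donor-acceptor angle >= 120°, a proxy for
an idealized hydrogen pointing at the acceptor (input hydrogens are dropped
on read because depositions are inconsistent about them). Salt bridges:
opposite-sign charged-group heavy atoms within 4.0 Å. Backbone carbonyl
oxygens always count as acceptors so selectivity-filter carbonyl contacts
(the K+ channel "pore ring") are detectable. All thresholds are config.

Contact rings are named residue/atom sets collected across chains of a
z-aligned tetramer; the diameter is the mean distance between opposing
chain pairs, which equals twice the radial placement for exact C4 input —
an analytic identity the synthetic channel is built to satisfy.

## Mutagenesis screen (`mutation_scan`, `hotspot_rank`)

Variants are all subsets (size <= `combine_up_to`) of the supplied single
mutations; each is threaded, assembled and docked with identical settings.
The hotspot metric is the gain in top-5 mean over the base channel — the
curve-level comparisons are reported too, but ranking needs a scalar and
this one is stable and cheap. Failed variants are recorded and skipped, so
a large combinatorial sweep never aborts. Synergy (gain(A+B) >
gain(A)+gain(B)) is directly readable from the scan table.

## What the synthetic data does and does not establish

`make_toy_channel` builds a palisade of antiparallel ideal beta-strands on
a cylinder (wall radius 9.5 Å), joined by analytically solved turn residues
(all backbone bonds within 1.2-1.6 Å), copied fourfold about z. Three rings
(turret Asp at r = 8 Å, mid Glu pocket at r = 6 Å, pore Tyr at r = 3.5 Å)
have their tip atoms placed at *exactly* the requested radius, giving
ring-diameter math an analytic ground truth. The pocket chemistry is
switchable: acidic (`negative`, toxin-sensitive analogue), charge-reversed
(`positive`) or neutral amide (`none`). `make_toy_peptide` is a compact
helix with a C-terminal oligo-lysine tail pointing down; the multi-model
variant jitters only the tail, emulating an NMR bundle with a mobile basic
tail.

A green test on this world establishes: the engine recovers a planted
electrostatic/steric optimum; profile dominance tracks pocket chemistry;
the scan ranks a planted charge-reversal first; clustering, SASA, contacts
and ring geometry agree with independent oracles. It does **not** establish
agreement with any external docking engine's scores, transferability to
real channel/toxin structures, binding free energies, or the behaviour of
flexible side chains — real vestibules are concave, solvated and flexible
in ways a rigid palisade is not.

## Numerical choices and degenerate inputs

- FFT correlations are circular; displacements that would push the ligand's
  occupied voxels outside the grid are masked, and the Coulomb kernel is
  truncated below the grid margin so periodic images cannot reach valid
  displacements.
- Grid dimensions are padded to 5-smooth sizes for `stats::fft` speed.
- Collinear point sets in superposition warn and return the least-squares
  answer; chain termini are excluded from Ramachandran statistics; residues
  with missing backbone atoms are reported `unevaluable`, never guessed.
- The pH-7 formal charge scheme puts +1/-1 on whole groups split evenly
  over their terminal atoms (NH1/NH2, carboxylate O pairs); histidine is
  neutral by default and configurable; unknown residues get zero charge
  with a warning.
- Net-charge-vs-pH uses a conventional textbook pKa set (documented in
  `charge_params`); the classic toxin value +4.9 at pH 7 is reproduced to
  within the pKa-set-dependent tolerance +-0.3.
- Altloc resolution keeps the highest occupancy (first on ties); hydrogens
  and deuteriums are dropped on read; waters are stripped, monatomic ions
  kept, both configurable.

## Known limitations

Rigid-body only; no refinement or minimization; initial-stage scoring with
unscreened truncated electrostatics; coarse contact types (four elements);
the per-rotation candidate beam makes the global top-N exact only within
`candidates_per_rotation * n_rotations` candidates; proline ring closure in
the side-chain builder is approximate; absolute score scales are
meaningless outside a run.
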