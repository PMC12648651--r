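---
title: "Methods: conformer ensemble sampling and CCS focusing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformer ensemble sampling and CCS focusing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confocus)
```

## The problem

An ion-mobility mass spectrometry (IM-MS) experiment measures a collision
cross-section (CCS) for an ionized molecule, but not its structure.
Turning the CCS into a structural assignment requires candidate gas-phase
geometries of the right charge state, and the quantum-chemical refinement
that ultimately validates candidates is far too expensive to run on every
protomer and every conformer. `confocus` automates the pre-quantum
stages: charge-site assignment, conformer generation, CCS-based
screening, and redundancy reduction, so that only a small, focused,
non-redundant ensemble reaches the expensive step.

The package assumes singly charged adducts ([M+H]⁺ or [M−H]⁻) of neutral
small molecules, with protonation/deprotonation restricted to nitrogen
and oxygen — the overwhelmingly dominant titratable sites in small-molecule
IM-MS. Multiply charged ions, metal adducts and tautomer enumeration are
out of scope.

## Charge models and the two-tier ranking

Every titratable site defines a charge model sharing the parent geometry
except at the site itself. Titratability is a valence rule: an N (bond
order sum < 4) or O (< 3) can be protonated — which excludes
valence-saturated cases such as nitro-group nitrogens — and any N or O
bearing a hydrogen can be deprotonated. The added proton is planted at
the standard bond length (N–H 1.01 Å, O–H 0.96 Å) along the
least-crowded direction, chosen deterministically as the direction (from
a 194-point Fibonacci sphere) maximizing the minimum distance to every
other atom. Removal takes the lowest-index bonded hydrogen. Both rules
are deliberately the simplest deterministic ones: sibling models must
differ *only* at the charge site so that their scores are comparable.

Ranking is a two-tier contract. A primary scorer orders all models
cheaply; a secondary scorer — which may also refine the geometry —
re-scores the top `top_k` (default: all), and its ordering supersedes the
primary ordering within that block. This mirrors the common pattern of a
fast learned ranker followed by a physics-based re-ranker, while keeping
both tiers pluggable. With `secondary = primary` the supersession is a
no-op by construction. Scorer failures drop the affected model with a
warning rather than aborting the run; only total failure errors out.

The built-in surrogate scorer is a fixed affinity table by site element
and hybridization (sp³ N < sp² N < sp³ O < sp² O for protonation;
carboxylate-type O < other O < N for deprotonation) plus the clash score
of the geometry. It is a deterministic stand-in encoding coarse basicity
and acidity trends, not a trained model, and is documented as such;
anything smarter enters through the contract.

Mole fractions use x_i = exp(−ΔE_i/RT)/Σ_j exp(−ΔE_j/RT) at a default
298.15 K (standard temperature; the weighting is exact for whatever
energy model supplied the ΔE values). R = 1.98720425864×10⁻³
kcal mol⁻¹ K⁻¹.

## Conformer generation and the diversity filter

The built-in generator drives every rotatable bond over a torsion grid
(default spacing 120°, i.e. three settings per bond), rotating the
smaller fragment about the bond axis. Rotatable bonds are acyclic single
bonds between non-terminal heavy atoms; amide C–N bonds count. The
convention matters only as a monotone flexibility measure (it sets the
normal-walk step count), and terminal-group torsions that generate no
distinct heavy-atom geometry are excluded.

Grids larger than the conformer target are subsampled by a seeded uniform
draw of torsion combinations, keeping generation deterministic for a
fixed seed. Each geometry is scored by a purely repulsive clash model:

E = Σ_pairs 100 · max(0, 0.8·(r_i + r_j) − d_ij)² kcal/mol,

over nonbonded pairs with Bondi van der Waals radii. Pairs that are
bonded (1–2) or share a neighbor (1–3) are excluded, since their
distances are fixed by bond lengths and angles rather than torsions and
would otherwise contribute a conformation-independent constant. The model
has no attractive, torsional or electrostatic terms — it exists to order
clashed against open geometries cheaply and deterministically; real
energy models plug in through the generator and scorer contracts.

The diversity filter first applies an energy window (default 50 kcal/mol
above the pool minimum — generous, because the clash score is a lower
bound on strain, not a potential energy), then keeps conformers greedily
in ascending energy order, rejecting any within the RMSD cutoff (default
0.5 Å superposed RMSD, a standard duplicate threshold for small
molecules) of an already-kept member, and truncates at the target count
(default 1000). The global minimum is kept by construction. Falling short
of the target is normal and explicitly not an error: the downstream
stages prune further anyway.

## CCS prediction and focusing

The built-in predictor is the projection approximation: the CCS of a
geometry is estimated as its orientation-averaged projected area, using
disks of radius r_vdW + 1.55 Å (nitrogen buffer gas probe). The average
is Monte-Carlo: 64 seeded uniform random orientations (quaternion
sampling), each projected area estimated by rejection sampling with 4096
points over the bounding box (≈1% standard error on small molecules; the
cross-orientation standard error ships as an attribute). The projection
approximation systematically underestimates CCS for large concave ions
but is accurate at small-molecule sizes, cheap, and fully deterministic
for a fixed seed — the properties this stage needs. Learned or
trajectory-method predictors enter through the `ccs_predictor` contract,
which carries the predictor's fractional accuracy as metadata.

The focus filter keeps conformers with |CCS_pred − CCS_ref| ≤
w·CCS_ref. The window half-width w defaults to the predictor's accuracy
(built-in: 0.03, aligning the window with the ~3% reproducibility scale
of experimental CCS measurements). The exact functional form mapping
predictor accuracy to window width is a design choice of this package; a
symmetric relative window is the simplest defensible one. An empty focus
result returns an empty ensemble with a structured advisory to regenerate
with a much larger conformer target — it never crashes the pipeline,
because an empty window is actionable information, not a failure.

## The normal walk

Oversized focus ensembles (> 50 conformers, the final-output rule) are
reduced by walking their RMSD distribution. Every member's Kabsch/SVD
superposition RMSD to the reference conformer (the energy minimum; ties
to the lowest index) is computed; the distribution's mean and population
SD are reported, and the range [min, max] is traversed from trailing to
leading tail in `steps = 20 × ROT` positions (floored at 1 for rigid
systems). The implementation partitions the range into `steps`
equal-width intervals and keeps exactly one representative per occupied
interval — its lowest-energy member, ties to the lowest index — plus the
reference. Everything else falls below the walk's similarity score at its
position and is removed.

The prose description of a walk "across a normal distribution" admits
several readings; the equal-width binning is the default here because it
is deterministic, honors the tail-to-tail direction, and makes the
survivor count provably ≤ steps + 1. A quantile variant (interval edges
at N(mean, sd) quantiles, concentrating walk positions where the
distribution is dense) ships behind `variant = "quantile"`. A degenerate
distribution (min = max, e.g. all-identical conformers) keeps the
reference plus one representative and warns. RMSDs are reference-based,
not all-pairs, and use all atoms, since ensemble members share a full
atom ordering.

## Evaluation

Each final ensemble is summarized by its Boltzmann-weighted CCS,
Σ x_i·CCS_i with weights from the conformer energies at the pipeline
temperature, and the percent error against the reference. Error ≤ 3%
(boundary inclusive) flags the ensemble as experimentally viable. The
weighting is energy-source-agnostic: with the built-in clash score, many
open conformers tie at zero energy and the weighting degrades gracefully
to an unweighted mean over them; with refined energies the same code
produces the physically meaningful average. As T → ∞ the weighted CCS
approaches the arithmetic mean, and as T → 0⁺ the minimum-energy
conformer's CCS; both limits are verified numerically in the tests.

Evaluation requires a reference CCS; without one the pipeline stops after
generation and reports sizes only.

## Determinism and numerical choices

Every stochastic stage (embedding, grid subsampling, orientation
sampling, synthetic fixtures) consumes an explicit integer seed, and
repeated runs with one seed produce byte-identical output trees — XYZ
files are written at fixed 6-decimal precision and the zip archiver pins
timestamps. SMILES input is embedded by a seeded distance-geometry
method (RDKit's ETKDG via the system Python), chosen precisely because it
is deterministic for a fixed seed; geometry quality upstream of torsion
driving is otherwise uncritical. XYZ input gets its connectivity from
Open Babel's geometric bond perception, with the file's own coordinates
retained.

Tie-breaks are uniform throughout: ascending score, then ascending
index. The Kabsch rotation applies the usual determinant sign correction
so reflections are never counted as superpositions. Mole-fraction sums
are exact to 1e-12 by normalization after shifting energies by their
minimum (which also prevents overflow at low temperature).

## What the synthetic fixtures do and do not show

`synth_ensemble()` builds test ensembles as a base geometry plus i.i.d.
Gaussian coordinate noise, followed by a random rigid transform, with
clash-score energies. This gives a known ground truth for superposition
RMSD (the rigid transform must be invisible), for the diversity filter
(expected survivor counts at a given noise level), and for normal-walk
invariants (subset, survivor cap, reference retention, determinism). It
does **not** emulate real conformational variation — torsional moves,
correlated displacements, energy-RMSD correlation — so passing these
suites demonstrates the algorithms' contracts, not chemical accuracy on
real ensembles. The test suite sizes these fixtures at 50–500 members
across ROT 1–6, enough to occupy many walk intervals while keeping the
whole suite under a minute of RMSD arithmetic.

## Known limitations

- The built-in scorer, generator, energy model and CCS predictor are
  deterministic surrogates encoding coarse trends; quantitative charge
  state assignment and CCS accuracy require trained or physics-based
  replacements through the published contracts.
- Ring conformations are not sampled (torsion driving only rotates
  acyclic bonds), and stereochemistry is taken as embedded.
- The projection approximation underestimates CCS for large, concave
  ions; its 3% default accuracy is a scale assumption, not a validated
  error model.
- Site enumeration is valence-based; it does not consult pKa, resonance
  (beyond the carboxylate motif in the surrogate scorer), or gas-phase
  basicity data.
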