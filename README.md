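# confocus

Autonomous gas-phase conformer ensemble sampling and collision
cross-section (CCS) focusing for ion-mobility mass spectrometry (IM-MS).

Assigning a 3-D structure to an ion observed in IM-MS requires a chain of
modeling steps before any quantum-chemical refinement can start: deciding
*where* the charge sits on a singly protonated [M+H]⁺ or deprotonated
[M−H]⁻ adduct, sampling a diverse low-energy conformer ensemble for each
candidate charge site, discarding conformers whose predicted CCS is
incompatible with the measured one, and pruning what remains so the
downstream (expensive) quantum step sees as few redundant structures as
possible. `confocus` runs that whole chain from a single call, with every
stage behind a pluggable contract so trained charge-state rankers,
external conformer generators, or learned CCS predictors can replace the
deterministic built-ins.

The package is aimed at IM-MS practitioners and modelers who have a
measured CCS (drift-tube or traveling-wave, nitrogen buffer gas) for a
small-molecule ion and want a focused, non-redundant candidate ensemble.

## Method

For a neutral molecule M and an adduct type, the pipeline:

1. **Enumerates titratable sites** — every N or O that can accept a proton
   (lone pair available) for [M+H]⁺, or donate one (bears an H) for
   [M−H]⁻. Each site defines a *charge model*: the same geometry ± one
   proton at that site.
2. **Ranks charge models** with a two-tier scorer chain: a primary scorer
   over all models, then a secondary (optionally geometry-refining) scorer
   over the top *k* whose ordering supersedes the primary one. Relative
   energies ΔE_i and gas-phase mole fractions
   x_i = exp(−ΔE_i/RT) / Σ_j exp(−ΔE_j/RT) are reported per rank
   (R = 1.98720425864×10⁻³ kcal mol⁻¹ K⁻¹).
3. **Generates conformers** per ranked model (default target: 1000 unique
   low-energy conformers) with a deterministic torsion-grid generator, and
   distills the pool with a similarity + energy filter (superposed-RMSD
   cutoff 0.5 Å, energy window 50 kcal/mol).
4. **Focuses the ensemble** on the user's reference CCS: each conformer's
   CCS is predicted (built-in: Monte-Carlo projection approximation,
   orientation-averaged projected area of van der Waals disks inflated by
   a 1.55 Å N₂ probe) and only conformers with
   |CCS_pred − CCS_ref| ≤ w·CCS_ref survive, where w defaults to the
   predictor's relative accuracy (0.03).
5. **Reduces redundancy** with the *normal walk*: member-to-reference
   Kabsch/SVD RMSDs are summarized as a distribution and traversed from
   the trailing tail (minimum RMSD) to the leading tail (maximum) in
   `steps = 20 × ROT` walk positions (ROT = rotatable-bond count), keeping
   one lowest-energy representative per occupied position. Ensembles of
   ≤ 50 conformers are already a final output and bypass the walk.
6. **Evaluates** each final ensemble by its Boltzmann-weighted CCS,
   Σ x_i·CCS_i, against the reference: a weighted CCS error ≤ 3% counts
   as experimentally viable (the 3% reflects the reproducibility of
   IM-MS-derived CCS values).

Output lands in `Completed_Job/[molecule name]/`: one
`opt_Rank[n]_[site].xyz` per charge model,
`Conformer/opt_Rank[n]_ensemble/` and `Conformer/opt_Rank[n]_focus/`
folders of per-conformer XYZ files, a `results_sum.log` summary, and a
zip of the final focus ensembles.

## Worked example

```r
library(confocus)

gly <- parse_smiles("NCC(=O)O", name = "glycine", seed = 1)
rotatable_bond_count(gly)
#> [1] 1

# self-consistent reference CCS: the projection-approximation estimate of
# the embedded input geometry
ref <- pa_ccs(conformer("seed", gly$coords), gly$elements, seed = 1)
sprintf("reference CCS: %.2f", ref)
#> [1] "reference CCS: 60.25"

cfg <- pipeline_config("glycine", "[M-H]-", ccs_ref = as.numeric(ref),
                       seed = 1)
report <- run_pipeline("NCC(=O)O", cfg)
print(report)
#> <evaluation_report> glycine [M-H]-, 2 charge model(s)
#>   rank 1 O5: gen 3, focus 3, final 3, CCS err 1.97% (viable)
#>   rank 2 N1: gen 3, focus 3, final 3, CCS err 0.60% (viable)
```

Glycine [M−H]⁻ has two titratable sites. The carboxyl-oxygen deprotomer
ranks first (the surrogate scorer encodes that carboxylates are the more
stable anions); its single rotatable bond gives a 3-point torsion grid, so
3 conformers are generated, all of which fall inside the 3% focus window
around the reference. The Boltzmann-weighted CCS of the rank-1 ensemble
deviates from the reference by 1.97% — below the 3% bound, so the
ensemble is flagged experimentally viable. `results_sum.log` carries the
same numbers per rank (relative energy, mole fraction, stage-by-stage
ensemble sizes, weighted CCS, error, viability).

A command-line front end with `run`, `reduce` (normal walk over a folder
of XYZ files) and `ccs` (single-geometry CCS estimate) subcommands ships
in `inst/cli/confocus`.

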