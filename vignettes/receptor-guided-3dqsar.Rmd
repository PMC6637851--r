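---
title: "Receptor-guided field QSAR on docked ligand series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-guided field QSAR on docked ligand series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldsar)
```

## The problem

A congeneric ligand series docked into one receptor yields a set of 3D
poses in a common frame, a docking score per pose, and — from
experiment — an affinity per compound (Ki, converted to
pKi = −log₁₀(Ki·10⁻⁶ M)). Three questions follow. Do the analogs bind
the way the reference compound does? Which residues do they actually
touch, and how? And which spatial features of the series explain the
spread in affinity? `fieldsar` answers them with common-graph pose
metrics, interaction fingerprints, and a field-based PLS model whose
alignment comes from the docking itself (receptor-guided alignment)
rather than from an atom-matching superposition.

Everything downstream assumes the poses share one coordinate frame.
That assumption is what lets the pose RMSD skip superposition and what
makes grid fields comparable across compounds; nothing in the package
re-aligns molecules.

## Common-graph pose metrics

Analogs differ chemically from the reference, so pose RMSD is defined
on the maximum common substructure (MCS): the largest **connected**
induced subgraph over heavy atoms in which paired atoms agree in
element and aromaticity and — unless `ring_relaxed = TRUE` — in the
size of the smallest ring containing them, and paired bonds agree in
order (aromatic matches aromatic). The search is a McGregor-style
branch and bound: mappings grow pair by pair along the molecular graph,
a branch that cannot reach the best size so far is cut using a
reachability bound, and an exclusion branch removes each frontier atom
so all maximal mappings are visited exactly once. Ordering is
deterministic and the search carries a time budget (default 30 s, ample
at drug-like sizes); among tied maximum mappings the one with the
smallest in-place RMSD is kept, so each pair of poses gets one
reproducible number.

RMSD is the root mean square of the distances between mapped atoms in
the shared frame — deliberately *not* fitted: a fitted RMSD would hide
exactly the rigid displacement the metric is supposed to expose.
Coverage is reported as %RefMatch (MCS size over the reference's heavy
atoms) and %MolMatch (over the probe's); a small RMSD is only
meaningful alongside high coverage. Hydrogens are excluded throughout —
their docked positions are mostly noise and their inclusion would
distort both the percentages and the RMSD.

## Pose filtering and interaction fingerprints

For cationic amine ligands of an anionic site the binding-competent
pose must form the salt bridge between the charged nitrogen and the
anchor glutamate's side-chain carboxylate. `select_pose()` implements
the corresponding rule: the best-scoring pose *among those satisfying
all essential-interaction predicates*; if none complies, the overall
best-scoring pose is returned flagged non-compliant (compounds are
never silently dropped). `detect_salt_bridge()` is the canonical
predicate, true when any cationic N lies within 4.5 Å of a carboxylate
oxygen.

`compute_ifp()` types each residue–ligand contact with nine bits.
All cutoffs live in `ifp_config()` and are deliberately conventional
structural-bioinformatics values, not fitted:

| bit | meaning | rule (defaults) |
|-----|---------|-----------------|
| C | contact | any residue heavy atom ≤ 4.5 Å of any ligand heavy atom |
| B / S | backbone / side-chain contact | the contacting residue atoms partition by backbone flag |
| P | polar | residue N/O ≤ 4.0 Å of ligand N/O or charged atom |
| H | hydrophobic | residue C/S ≤ 4.5 Å of ligand C/S |
| A | H-bond, residue acceptor | acceptor–donor heavy atoms ≤ 3.5 Å; D–H⋯A angle ≥ 120° when an explicit H exists on the donor |
| D | H-bond, residue donor | symmetric, distance-only (protein H rarely present) |
| Ar | aromatic | ring-centroid distance ≤ 5.0 Å, or centroid–cation ≤ 4.5 Å (π-cation) |
| Ch | charged | oppositely charged groups ≤ 4.5 Å |

After the geometric evaluation the logical implications are closed
explicitly (A or D set P; any chemotyped bit sets C), so the published
invariants hold even in edge geometries — for example a ring centroid
inside the aromatic cutoff while every ring atom sits just outside the
contact cutoff. Occurrence profiles are plain percentages of complexes
with a bit set, over the same complex set for every residue.

Cationic atoms are those with formal charge > 0; neutral amines are
treated as protonated only when `protonate_amines = TRUE`, because
protonation is a modelling decision the caller should own.

## The field model

Steric and electrostatic fields are evaluated at every node of an
axis-aligned grid (default spacing 1.0 Å, padding 5.0 Å around the
whole series — padding smaller than ~4 Å clips the asymptotic tail of
the steric field next to surface atoms):

* steric: Lennard-Jones 6–12 against an uncharged sp³-carbon probe,
  E = Σᵢ εᵢ[(Rᵢ/rᵢ)¹² − 2(Rᵢ/rᵢ)⁶], with Rᵢ = rmin(atom) + rmin(probe)
  and εᵢ = √(ε(atom)·ε(probe)) from a compact per-element table
  documented in the source (`.vdw_table`); at the pair-minimum distance
  the pair energy is exactly −εᵢ, which the tests exploit as a closed
  form.
* electrostatic: Coulomb against a +1 probe with distance-dependent
  dielectric ε(r) = r, E = Σᵢ 332.0637·qᵢ/rᵢ², over bond-charge-increment
  partial charges (or charges supplied in the SDF, which take
  precedence).

Pretreatment then caps energies at +30 kcal/mol (electrostatic also
floored at −30; buried nodes are evaluated and capped rather than
masked), zeroes magnitudes below 0.05 kcal/mol, and kills *n*-level
variables (≤ 4 distinct values across compounds) and zero-variance
columns. Block Unscaled Weighting multiplies each field block by
1/√(total column variance of the block): blocks enter the regression
with equal total variance while the relative scale of variables inside
a block — the spatial structure of the field — is preserved. Smart
Region Definition is available behind `srd = TRUE`: seeds are the
alive variables with the largest pilot-model coefficients (default 10%
of the block, capped at 200), variables within 2.0 Å join their nearest
seed, adjacent regions with profile correlation ≥ 0.8 merge, orphans
are dropped. We stop at grouping and orphan-dropping; no fractional
factorial variable selection is layered on top.

`comfa_pls()` fits NIPALS PLS1 on the centred, prepared matrix. For a
single response the NIPALS weights need no iteration, components are
deflated in sequence, and the regression vector is
β = W(PᵀW)⁻¹q. The test suite pins this implementation to an
algorithm-independent oracle — the Krylov-subspace closed form of PLS1 —
to 10⁻⁶ on fifty random problems.

Cross-validation is leave-one-out with re-centring per fold, but the
pretreatment, the alive-variable set and the block weights are frozen
from the full training matrix. Re-deriving them per fold is the
stricter variant; freezing is the standard field-QSAR practice and
keeps the variable set identical across folds, which is what the
reported Q² refers to. Model selection scans field sets {S, E, SE} and
1–8 components and takes the highest Q², breaking ties toward fewer
components, then fewer fields. Eight components is deliberately above
the five often quoted as a rule of thumb: reference models of this kind
are reported with up to eight, and the LOO criterion, not the scan
ceiling, is what guards against overfitting.

Reported statistics: R² = 1 − SSres/SStot on training;
S = √(SSres/(n − NC − 1)) — a residual SD penalised by model size; the
convention is documented here because published tables rarely state
it (on the packaged series it gives 0.159 against a printed 0.15);
Q² and S_LOO = √(PRESS/n); externally Rtest² as *squared Pearson
correlation* (the predictive 1 − PRESS/SS variant is systematically
slightly lower — on the packaged series 0.60 vs 0.61) and
S_test = √(Σ(ŷ−y)²/n_test). Field contributions split each component's
share of modelled response variance (q_a²‖t_a‖²) over blocks by the
squared PLS weights; contributions sum to one. Contour maps export
coefficient × column-SD per node as OpenDX, with iso-levels suggested
at the 85th percentile of nonzero absolute values — a display choice,
not part of the model.

## The train/test split

`split_dataset()` draws the external set stratified on activity: rows
ranked by pKi are partitioned into `n_test` equal-rank bins and one
test compound is drawn per bin with a seeded generator. This guarantees
the test set spans the activity range (the suite asserts ≥ 80% range
coverage), which a uniform random draw does not. The packaged
80-compound series ships with its published 64/16 membership, so
statistics computed on it do not depend on the seed.

## What the synthetic generator emulates — and what it does not

`generate_series()` builds a desk-scale stand-in for a docked
congeneric series (default 40 compounds): a rigid arylalkylamine
scaffold (phenyl ring, branched chain, protonated amine with explicit
H) fixed in one frame, a para alkyl substituent of 0–4 carbons, and a
meta substituent from {H, OH, OMe, F, NH₂}. Activities follow the
planted rule

> pKi = 6 + 0.4 · (heavy atoms in the steric region)
>       + 4 · (−q on the meta heteroatom) + N(0, 0.2²)

with the steric region a 2.2 Å sphere over the para site. The five
meta chemotypes are essential, not decorative: with a binary meta
substituent every electrostatic column takes two values and the
n-level filter removes the entire block; five chemotypes give five
distinct local charges (0 to −0.17 e) and the block survives
pretreatment the way real data would. Substituent geometry is
template-based (idealised bond lengths, no minimisation) — fields need
plausible, reproducible occupancy, not physical accuracy. The noise is
Gaussian on the pKi scale, the modelled scale.

`generate_pocket()` places a glutamate whose carboxylate faces every
compound's ammonium at ~3 Å, a phenylalanine stacked 3.6 Å over the
scaffold ring, and two leucines lining the para site — enough to make
every fingerprint bit and the salt-bridge filter exercisable with known
expected outcomes.

What passing these tests shows: the pipeline recovers planted linear
field effects (Q² ≥ 0.5 on every calibration seed; the top steric
coefficient lands in or adjacent to the planted region in ≥ 8/10
seeds with the correct sign) and reports no signal on pure noise
(mean Q² ≈ −0.45 over ten seeds). What it does not show: robustness to
pose uncertainty, conformational flexibility, protonation ambiguity,
activity cliffs, or the correlated substituent patterns of real
medicinal-chemistry series — the synthetic scaffold is rigid and its
substituent draws are independent.

## Numerical choices and degenerate inputs

* Energies at nodes inside atoms are evaluated at a 10⁻⁶ Å floor and
  capped downstream, with a warning for exact coincidences.
* NIPALS stops early (with the component count recorded) if the
  residual weight norm falls below 10⁻¹²; requesting more components
  than min(n−1, p) is an error, as is a constant response.
* LOO folds reduce the component count when a fold would exceed its
  rank.
* MCS ties are broken by minimal in-place RMSD, then deterministic
  search order; `rmsd_table()` converts per-pair failures (no common
  atom) into flagged rows instead of aborting a series.
* SRD seed ties are broken toward the lowest variable index; region
  merging uses union-find so the result is order-independent.
* The generator restores the caller's RNG state (`with_seed`), so
  seeded pipelines do not perturb session-level randomness, and equal
  seeds yield byte-identical SDF/CSV output.

## Problem sizes used by the shipped tests

The suite runs the full synthetic pipeline at 40 compounds on a ~9,000
variable grid for the recovery and noise experiments (ten seeds each),
50 random PLS problems against the Krylov oracle, and brute-force MCS
enumeration on molecules of up to ten heavy atoms; the complete suite
finishes in well under a minute of CPU plus ~30 s for the acceptance
experiments. These sizes were chosen as the smallest at which the
statistical claims are stable across seeds.

## Known limitations

* Aromaticity perception covers explicit aromatic bond orders and
  Kekulé six-rings of C/N — adequate for the chemistry the package
  generates and for typical prepared SDF input, but not a general
  Hückel treatment (fused heteroaromatics should carry aromatic bond
  orders in the input).
* Bond-charge-increment charges are a one-table approximation;
  workflows with better charges should supply them via the SDF charge
  property, which always wins.
* The MCS is exact but exponential in the worst case; the time budget
  makes pathological inputs return the best mapping found, with a
  warning, rather than hanging.
* Interaction fingerprints ignore water-mediated contacts and halogen
  bonds, and the donor-angle criterion degrades to distance-only
  without explicit hydrogens.
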