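---
title: "Methods: the vsfunnel screening workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the vsfunnel screening workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsfunnel)
```

`vsfunnel` implements a multi-target virtual-screening funnel for
broad-spectrum MMP inhibitors: a cheap fingerprint classifier first, a
geometric pharmacophore filter second, an electrostatic similarity
filter last, then cross-target consensus and a structural-novelty
selection. This vignette documents the models behind each stage, the
tunable parameters with their defaults and rationale, the numerical
choices, and what the synthetic fixtures do and do not demonstrate.

## Compound handling

Compounds are held as plain data frames (`molecule_records`): id,
canonical SMILES, molecular weight (Da), role (`library`, `active`,
`decoy`), optional pX = −log10(IC50 or Ki in molar), and a provenance
tag. Canonicalization and masses come from OpenBabel via
ChemmineR/ChemmineOB. Input charge and tautomer states are trusted
as given: protonation enumeration at assay pH is out of scope, so a
carboxylate should be supplied deprotonated if that is the relevant
species. Curated actives are expected to carry pX in the 1–13 range.

The screening window keeps compounds with 300 ≤ MW ≤ 600 Da. Both
bounds are inclusive — a 300.0 Da compound passes — a deliberate
reading since nothing in the workflow's definition hinges on strictness
at the boundary.

Weight-matched decoys (`select_mw_decoys`) are drawn without
replacement within ±25 Da of each active at a 1:1 ratio by default,
mirroring the near-1:1 active/decoy balance used throughout the
validation sets; the seed is a required argument, and a per-active
audit reports shortfalls instead of failing silently.

## Morgan fingerprints

No installed R package computes extended-connectivity (Morgan)
fingerprints, so the package implements them on the OpenBabel-parsed
molecular graph. Atom invariants are element, heavy-atom degree,
hydrogen count, formal charge and ring membership; identifiers are
iteratively rehashed with sorted (bond order, neighbour identifier)
pairs up to radius 2 and folded into 2048 bits (the radius matches the
workflow's descriptor definition; the bit length is the field's common
default, left configurable). Environments that cover no new bonds are
not re-emitted, and environments covering an already-seen bond set are
deduplicated — hence a single-heavy-atom molecule such as methane sets
exactly one bit. Hashing is a fixed polynomial over the Mersenne prime
2³¹−1, exact in double arithmetic and identical across platforms. The
fingerprints are deterministic for a given canonical structure but are
not bit-compatible with any other toolkit's ECFP variant; within this
package they only feed the classifier and the Jaccard clustering, both
of which are self-consistent.

## The calibrated bioactivity filter

A probability forest (`ranger`, 100 trees, single-threaded, seeded) is
trained on fingerprint bits of actives vs decoys. Vote fractions are
then calibrated with Platt's sigmoid `p = 1/(1+exp(Af+B))`, fitted by
maximum likelihood with Platt's soft targets `(N₊+1)/(N₊+2)` and
`1/(N₋+2)`, which keeps the fit finite on perfectly separated scores.
The held-out scores for the calibration are the forest's out-of-bag
votes: each tree's OOB prediction is an honest estimate for the
compounds it never saw, which gives Platt scaling a held-out sample
without an inner cross-validation layer.

Validation uses stratified k-fold cross-validation (default 5 folds,
i.e. 80/20 splits; fold assignment seeded per class), reporting the
nine confusion-matrix statistics (sensitivity through Matthews
correlation) as fold means. Ratios with zero denominators are reported
as `NaN`, never silently zero, so degenerate folds stay visible.

Applied to a library, the filter keeps compounds with calibrated
probability ≥ 0.20: the workflow discards compounds with a
*less-than-20%* probability of activity, so the boundary value
survives. The low threshold is intentional — this stage is a cheap
pre-filter ahead of more specific 3D stages, tuned to lose as few
actives as possible.

## Pharmacophore generation and screening

Feature perception is rule-based on the molecular graph (donor N/O–H;
acceptor N/O excluding amide, quaternary and aromatic N–H nitrogens;
negative: deprotonated oxo-acid groups at the group centroid,
tetrazolate at the ring centroid; positive charges; aromatic rings at
ring centroids; hydrophobic clusters of ≥ 3 contiguous apolar
non-aromatic carbons at the cluster centroid). A SMARTS-catalogue
formulation was considered, but the available R SMARTS engine returns
match counts rather than matched atom indices, which positioned
features require; the rule functions encode the same chemistry
explicitly and deterministically. PAINS flagging, which needs only
counts, does use a bundled, user-overridable SMARTS catalogue (a
curated subset of the widely used alert list).

Fragment-derived (e-pharmacophore style) hypotheses pool the features
of scored docked fragment poses, cluster them kind-wise (complete
linkage, never merging beyond a 2 Å radius, at most 15 clusters
total allocated across kinds by feature count), score each cluster by
the summed docking scores of its contributors — any per-pose scalar
score is accepted in place of a proprietary per-site energy — and
place sites at score-weighted centroids. One hypothesis is emitted per
site count up to 8.

Ligand-based hypotheses (for targets screened without docking)
enumerate 3–5-feature arrangements from a reference active and keep
those matching at least 50% of actives under flexible screening with
up to 10 conformers per ligand. Conformer generation itself is
external: the package takes conformers as input.

Matching semantics: a pose satisfies a hypothesis iff every *required*
(`+`) site is assigned a distinct feature of the same kind within the
site's tolerance, and at least `min_optional_matches` optional (`-`)
sites are also satisfied. `min_optional_matches` defaults to 0 —
optional sites never reject a pose — the adopted reading of the
compact `KIND(±)` hypothesis notation, whose published legend does not
pin down a partial-match quota. The default site tolerance is 2.0 Å, a
conventional pharmacophore sphere radius; it is a per-site field.
In-place screening uses docked coordinates as-is (poses and hypothesis
must share a receptor frame). Flexible screening enumerates candidate
assignments and accepts on post-Kabsch distances, with proper rotations
only (det R = +1), so mirror images of a chiral arrangement do not
match; the lowest-RMSD conformer is reported per compound. The matcher
is exact — it is tested for equivalence against an exhaustive
assignment oracle — and hypothesis selection is lexicographic:
sensitivity first (the workflow's stated priority: losing actives is
worse than passing decoys), then specificity, then fewer sites.

## Electrostatic similarity

The published workflow scores poses with a Poisson–Boltzmann-based
electrostatic Tanimoto; the solver behind it is proprietary. The
package's field model is a screened Coulomb potential
`V(r) = Σ qᵢ/(ε(dᵢ)dᵢ)` with distance-dependent dielectric
`ε(d) = 4d` (configurable to vacuum or constant ε), sampled on a
regular grid of 0.5 Å spacing with 4 Å padding around the union
bounding box of the compared pair, with points inside either molecule's
Bondi vdW envelope masked out to remove the near-singular interior.
This preserves the comparison layer's full algebraic contract — the
continuous Tanimoto `T = Σab/(Σa²+Σb²−Σab)` over common unmasked
points is symmetric, bounded in [−⅓, 1], equals 1 at self-identity,
−⅓ at exact charge negation, and follows `T(a,λa) = λ/(1+λ²−λ)` — but
absolute values are not claimed to reproduce a Poisson–Boltzmann
implementation's numbers; the potential layer is pluggable for a true
PB field. Grid-refinement stability (0.5 → 0.25 Å changing T by
< 0.02 on fixtures) is part of the test suite.

Per compound, the single docked pose with the highest Tanimoto across
all references jointly is kept. References are triaged by whether
potent actives separate from decoys against them: the two-sample
Kolmogorov–Smirnov statistic between the pX > 7 actives' and the
decoys' score distributions must reach 0.25 — a concrete
quantification of the qualitative rule that references with "very
similar" distributions are useless for cutoffs (0.25 is a moderate
effect size: well above same-distribution noise at the validation-set
sizes involved, well below demanding perfect separation).

The cutoff itself is calibrated per target from pX-stratified
histograms (bins of 0.05 over [−⅓, 1]; strata pX < 4, 4–7, > 7):
candidates are midpoints between adjacent observed values and the one
maximizing Youden's J for pX > 7 actives vs decoys wins (ties: higher
specificity, then lower cutoff). A calibration with maximal J below
0.2 is flagged non-discriminating rather than silently used. A manual
override (provenance `"manual"`) supports reading a cutoff off a
published histogram. Compounds at exactly the cutoff pass.

## Consensus, clustering, selection

Per-target funnels are stage-function pipelines recording every
survivor set; survivor counts are non-increasing by construction and
each run aborts naming the failing stage. Targets without
docking/electrostatics stages (the ligand-based branch) simply
configure fewer stages. Consensus keeps compounds surviving the final
stage of ≥ 2 funnels (≥ 3 reproduces the stricter inspection tier).

For novelty selection, hits and known actives are clustered by
single-linkage hierarchical clustering over Jaccard distance on
fingerprints, cut at distance 0.6 (Tanimoto 0.4). A density-based
hierarchical method (HDBSCAN) would be the closest published analogue;
no R implementation is available in the package's dependency
environment, and single-linkage at a fixed cut preserves the operative
contract — near-duplicates chain into one cluster, isolated compounds
do not — with one interpretable parameter. Clusters smaller than
`min_cluster_size = 2` are noise: each member becomes an eligible
singleton, because a structurally isolated hit is precisely what a
novelty selection wants to keep. Selection excludes clusters containing
a known active, takes at most one compound per cluster, ranks by the
number of funnels survived and breaks ties by compound id (the
published workflow chose by visual inspection; an id tie-break makes
the selection reproducible), and flags PAINS alerts on the report.

## Dose-response mathematics

Percent inhibition is `100(1 − vi/vo)`; the binding model is
`vi/vo = 1/(1 + [I]/IC50)`, so `[I] = IC50` gives exactly 50%
inhibition. `fit_ic50` performs a Levenberg–Marquardt least-squares fit
of the single parameter, demanding at least five distinct
concentrations whose *measured* inhibition lies in the 10–90% window
(the window is checked against the data, not the fitted curve, matching
how assay points are chosen in practice); the initial guess is the
concentration nearest 50% inhibition. The reported SD is the fit
uncertainty from the linearized covariance at the optimum — clearly
labelled as such, since published tables typically report SD across
independent experiments, a different (usually larger) quantity.

## Synthetic fixtures and what the tests show

Every test input comes from seeded generator functions; identical
specs give identical output, and the generators restore the caller's
RNG state. The classification fixture builds scaffold-sharing
sulfonamide actives (300–600 Da, pX strata 20%/40%/40% over <4, 4–7,
>7) against branched-alkane decoys weight-matched within 25 Da —
separable by construction. Passing the classifier benchmark
(sensitivity and specificity ≥ 0.95 at 500/500) therefore demonstrates
the pipeline's mechanics (fingerprinting, fold stratification,
calibration, thresholding), *not* performance on real actives, where
class overlap is the hard part; the permuted-label control (|MCC| ≈ 0)
shows the metrics are honest. Similarly, planted pose sets assume
hypothesis sites separated by more than twice the tolerance (warned
otherwise) so their labels are unambiguous; electrostatic validation
fixtures draw et_pb scores directly from truncated normals rather than
from docked geometries. Real-data effects deliberately not emulated:
docking pose noise, conformer strain, tautomer ambiguity, correlated
activity cliffs, and assay artifacts beyond the PAINS catalogue.

## Numerical choices and limitations

Grid potentials use a 10⁻⁶ Å distance floor (unreachable outside the
vdW mask) against division by zero; a Tanimoto of two identically zero
fields is an error, not 0/0 → NaN; two empty fingerprints define
Tanimoto 0. Platt fitting is BFGS on the stable log1p-form of the
negative log-likelihood. Kabsch superposition enforces det +1 via SVD
sign correction. Aromaticity is perceived from kekulized orders on
5–7-rings (cycle-basis rings), which covers common aromatics but not
exotic fused or charged π-systems; feature perception trusts input
protonation states. The funnel operates on one conformer/pose set per
compound as given — docking, conformer generation, and receptor
preparation are upstream of this package by design.

Problem sizes used in the shipped tests (500/500 compounds for the
classifier benchmark, 10 × 200 consensus matrices, 1000-instance
matcher equivalence, 100 simulated dose-response curves) were chosen as
the smallest sets at which the checked properties are stable, keeping
the full suite comfortably fast on a laptop.
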