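---
title: "Dual-target pharmacophore screening: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-target pharmacophore screening: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualphore)
```

## The screening problem

Dual-target inhibitor discovery asks for small molecules that bind two
unrelated enzymes at once — here the model system is an arginine
methyltransferase (CARM1) and a histone deacetylase (HDAC2), two epigenetic
targets whose simultaneous inhibition is a strategy against heterogeneous
cancers. `dualphore` implements the computational funnel such a campaign
runs before any compound is synthesised:

1. **Pharmacophore screen** — keep molecules whose 3D feature arrangement
   (hydrogen-bond donor, aromatic centres, hydrophobic centroid) matches a
   query model derived from the first target's active site.
2. **Enrichment validation** — quantify, on an activity-labelled decoy
   library, how well that query separates actives from inactives
   (Güner–Henry statistics).
3. **Docking-energy cascade** — among pharmacophore hits, keep compounds
   whose docking binding free energy beats a per-target cutoff for *both*
   targets, and rank the intersection.
4. **Post-hoc stability and assay arithmetic** — RMSD/RMSF trajectory
   metrics for candidate complexes, and dose–response arithmetic (percent
   inhibition, IC50 fits, potency ratios, xenograft tumour volume).

Docking itself, conformer generation and MD simulation are deliberately out
of scope: scores and trajectories are *inputs*, in plain formats (CSV,
multi-model PDB, XYZ), because the engines that produce them are external
tools. The package owns everything that turns those inputs into decisions.

## Feature perception

Annotation points are derived from a `molecule3d` by three deterministic,
format-driven rules (`perceive_features()`):

* **Donor** — every N or O atom bearing at least one explicit hydrogen,
  with the point placed on the heavy atom. Placement on the heavy atom
  rather than the hydrogen, with no directionality, is the simplest
  convention that is still testable; it makes the donor count exactly equal
  to the number of N/O atoms with an H neighbour, a property the test
  suite checks directly. Molecules without explicit hydrogens are processed
  with a warning since no donor can be perceived.
* **Aromatic** — the centroid of each ring of size 5–7 from the smallest
  set of smallest rings whose bonds all carry the SDF aromatic flag. When a
  ring carries no flags at all, a geometric fallback accepts it if its
  atoms fit a least-squares plane within 0.10 Å. There is no electronic
  aromaticity model: the input format is the authority, geometry the
  fallback.
* **Hydrophobic** — the centroid of each maximal connected cluster of at
  least 3 carbon/halogen atoms, excluding atoms bonded to N, O or a
  formally charged atom. Maximality makes clusters disjoint, so no two
  hydrophobic points share a source atom.

Commercial modelling suites use richer, unpublished typing schemes; these
rules are a documented approximation, which is why library-scale hit counts
from such suites are never treated as reproducible quantities here. All
three rules are configurable through `perception_rules()` (minimum cluster
size, planarity tolerance, ring-size range).

Ring perception is a minimum cycle basis: the shortest cycle through every
bond is found by breadth-first search and a GF(2)-independent subset of
size $m - n + c$ is kept. On fused bicyclics this yields the two
six-membered rings, never the perimeter cycle — verified in the tests
against exhaustive cycle enumeration.

## Pharmacophore matching

A query (`pharmacophore_query`) is an ordered list of typed tolerance
spheres. `match_query()` enumerates every injective, type-compatible
assignment of annotation points to features and scores each one:

* in **superpose** mode (default) by the RMSD after the optimal
  least-squares rigid superposition of the mapped points onto the feature
  centers;
* in **in_place** mode on the raw coordinates, for poses already in the
  query frame.

A compound matches when its best assignment satisfies both the RMSD cutoff
and per-feature sphere containment; *all* features are required, partial
matches never count. Ties between equal-RMSD assignments break by the
lexicographically smallest mapping, making results deterministic.
Superposition is restricted to proper rotations (determinant $+1$):
a mirror image is never matched by reflection, so chirality is preserved.
Both conventions exist because pre-aligned and flexibly-placed inputs are
both legitimate; superpose is the default as the more permissive reading.

The defaults — feature radius 1.0 Å and RMSD cutoff 1.0 Å — are stated
conventions, not reconstructions of any commercial tool's tolerances; every
quantitative test pins them explicitly. Enumeration is guarded: above a
configurable assignment-count ceiling (default $10^6$) the matcher raises a
typed capacity error, and `screen_library()` logs and counts such molecules
rather than aborting a screen.

The packaged example query (`example_query()`, also shipped as JSON) has
the four-feature typing of the CARM1-style model — donor, two aromatics,
one hydrophobic — arranged as a near-tetrahedron with 4–8 Å edges. The
coordinates are illustrative: no feature coordinates are available for the
original model, so the fixture is a synthetic stand-in, not a
reconstruction.

## Güner–Henry validation

For a labelled library of $D$ molecules with $A$ actives, a screen
returning $H_t$ hits of which $H_a$ are active is summarised by

$$GH = \frac{H_a\,(3A + H_t)}{4\,H_t\,A}\,
       \left(1 - \frac{H_t - H_a}{D - A}\right),$$

together with percent yield ($100\,H_a/H_t$), percent ratio of actives
($100\,H_a/A$), the enrichment factor $E = H_a D / (H_t A)$, and the false
negative/positive counts. $GH$ is 0 for a null model and 1 exactly at
perfect retrieval ($H_t = H_a = A$); scores of 0.7 and above are
conventionally read as an excellent model, a label the package reports but
never enforces. `gh_statistics()` keeps full-precision values and mirrors
the conventional presentation rounding (GH to two decimals, $E$ and the
percentages to integers) — e.g. counts (1500, 16, 19, 16) give
$E = 78.95 \to 79$ and $GH = 0.8798 \to 0.88$.

Admissibility is validated, including the easily-forgotten constraint
$H_t - H_a \le D - A$ (inactive hits cannot outnumber inactives), which is
exactly what confines $GH$ to $[0, 1]$.

## The cascade

`apply_threshold()` filters a score table (kcal/mol binding free energies,
more negative = stronger) per target; `run_cascade()` intersects the
per-target survivor lists with the pharmacophore hit list and ranks the
intersection ascending by summed binding energy (ties by compound id).
Comparisons are strict (`<`) by default: on the packaged worked-example
table a compound at −11.32 kcal/mol passes a −11.3 cutoff, which is the
reading consistent with the worked example's seven-compound intersection. Both
strictness and the ranking key (`sum_energy` vs `per_target`) are
configurable. Cutoff relaxation can only grow survivor sets — a
monotonicity property the suite checks on random score tables.

## Trajectory metrics

`kabsch_superpose()` is the closed-form SVD solution restricted to proper
rotations. `rmsd_series()` reports per-frame RMSD against a reference frame
on an atom selection (α-carbons by default), optionally after superposition
on that selection; values are reported in Å and nm, since MD plots
conventionally quote nm. `rmsf_per_residue()` superposes every frame onto
the selection's mean structure — the mean is refined by two superposition
iterations so the arbitrary initial reference does not bias it, a fixed and
documented choice — and reports per-residue root-mean-square fluctuation
about the time-average positions.

Reproducing a specific experiment's RMSD plateau would require the original
multi-nanosecond trajectories, which are not distributable; the package's
claims are therefore structural: superposed RMSD never exceeds in-place
RMSD, rigid motion of all frames changes nothing, and isotropic Gaussian
jitter of scale $\sigma$ per coordinate yields mean RMSD and RMSF of
$\sigma\sqrt{3}$ — closed forms the tests verify to 5–10%.

## Assay arithmetic

`inhibition_rate()` is the plate formula
$100\,(1 - (\text{test} - \text{blank})/(\text{control} - \text{blank}))$,
affine-invariant in the signals, with the blank exposed explicitly because
reported percent-inhibition tables do not always state whether it was
subtracted. `fit_sigmoid()` fits the four-parameter logistic
$y = b + (t - b)/(1 + (\mathrm{IC}_{50}/c)^{h})$ on log-concentration via
Levenberg–Marquardt (`minpack.lm`), with multi-start initialisation
(IC50 seeded at the concentration nearest half-maximum; Hill slope started
at 0.5, 1 and 2) and an honest `converged` flag — constant responses are
reported as unidentifiable, not silently "fit". The four-parameter logistic
is the standard reading of a "sigmoidal dose–response equation"; plateaus
can be constrained (e.g. 100/0) when the assay design warrants it.
`potency_ratio()` and `tumour_volume()` ($c^2 d / 2$ from calliper
diameters, erroring when the diameters are swapped) complete the readout
arithmetic.

## What the synthetic generators emulate — and what they do not

All generators hang off one `generator_spec()` and are pure functions of
the seed (byte-identical outputs, caller RNG state restored).

* `gen_labeled_library()` emulates a decoy-set validation library. Actives
  are geometric constructs: a hydroxyl, benzene hexagons (C–C 1.39 Å, with
  ring hydrogens) and a three-carbon cluster (1.54 Å spacing) planted at
  the query feature centers plus Gaussian jitter, joined into one molecule
  through a carbon–oxygen hub whose carbon is excluded from hydrophobic
  clusters by the perception rules themselves — so at zero jitter every
  planted centroid sits exactly on its feature center. Decoys omit all
  fragments of one required kind (dropping the hydrophobic cluster also
  drops the rings, whose carbons would otherwise supply hydrophobic
  points), so they can never satisfy the full query. The default scale —
  10 actives, 100 decoys, 0.2 Å jitter — keeps the reference validation run
  fast while preserving the ~1:100 active:decoy shape of a full-scale
  validation set (~1500 molecules), which is one configuration change away.
* `gen_score_table()` plants per-target passers strictly below the cutoffs
  (default −11.3 / −11.7 kcal/mol with 0.05 kcal/mol clearance), so the
  cascade's intersection is known by construction.
* `gen_dose_response()` samples the four-parameter logistic (default IC50
  10 nM, Hill 1, plateaus 100/0, eight concentrations spanning
  0.1–1000 nM) in triplicate wells with Gaussian noise scaled to 2% of the
  dynamic range — triplicates matching standard dose–response practice
  (readouts reported as mean ± SD of n = 3).
* `gen_trajectory()` produces one α-carbon per residue along a helical
  curve plus isotropic Gaussian jitter (default σ = 0.15 Å per coordinate,
  100 frames at 10 ps), with the five residues at each terminus jittered
  5× harder — a rigid core with floppy ends, the qualitative signature the
  RMSF metric must resolve.

These constructs are *not* realistic chemistry or dynamics: no force
field, no conformational coupling, no property-matched decoys, bond
lengths only locally sensible. Passing tests therefore demonstrate that the
algorithms are correct on inputs whose ground truth is known exactly — they
do not certify performance on real screening libraries, where feature
perception differences and conformational flexibility dominate.

## Numerical choices and degenerate inputs

* Superposition tolerances: rigid-motion invariance is asserted to
  $10^{-6}$ Å; sphere containment uses a $10^{-9}$ Å slack so exact-boundary
  constructions are stable.
* Kabsch requires ≥ 3 non-collinear points (collinearity detected via the
  second singular value); inside the matcher smaller feature sets fall back
  to the same closed form, whose optimum is still attained.
* `gh_statistics()` refuses $H_t = 0$ (undefined yield/E/GH) and $D = A$
  (zero denominator) rather than returning NaN.
* SDF parsing is fixed-column V2000 with record-numbered errors; writing
  rounds coordinates to 4 decimals, which bounds the round-trip error at
  $5\times10^{-5}$ Å.
* Problem sizes in the reference test run: 1000 matcher-oracle instances,
  $10^4$ GH tuples, 100 random cascade tables, a 200-atom × 100-frame
  trajectory and 50 seeded dose–response fits — sizes chosen so the whole
  property suite completes in about a minute on one core while keeping
  Monte-Carlo tolerances (5–10%) comfortably resolvable.

## Worked example

```{r}
query <- example_query()
lib <- gen_labeled_library(query, generator_spec(seed = 1))
validate_query(query, lib)

scores <- read_score_table(dualphore_example("dual_docking_scores.csv"))
run_cascade(sprintf("CH-%d", 1:7), scores,
            list(threshold_rule("CARM1", -11.3),
                 threshold_rule("HDAC2", -11.7)))
```

## Known limitations

* Feature typing is a transparent approximation; hit lists will differ
  from commercial pharmacophore engines on real molecules.
* One conformer per record: multi-conformer input must be supplied as
  multiple records, and no embedding or minimisation is performed.
* The matcher's exhaustive enumeration is exact but exponential in feature
  multiplicity; the capacity guard trades completeness for an explicit
  error on pathological inputs.
* Enrichment reporting stops at the Güner–Henry family; ROC/AUC-style
  metrics and property-matched decoy generation are intentionally absent.
* Significance testing for in-vivo growth curves is out of scope; the
  tumour-volume formula is arithmetic, not inference.
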