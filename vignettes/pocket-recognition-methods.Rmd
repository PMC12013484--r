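---
title: "Methods: point-cloud recognition of protein binding pockets"
author: "procv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point-cloud recognition of protein binding pockets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procv)
```

## The recognition model

procv treats a protein structure as an unordered 3D point cloud of
heavy-atom coordinates (Å) and a binding pocket — the protein atoms
within a 5 Å shell of a bound ligand, boundary inclusive — as a rigid
partial view of that cloud. Recognition asks: does a given pocket occur,
up to a rigid motion, inside a given structure, and with how many
consistently placed atoms? The answer is produced by the classic
correspondence-grouping chain: keypoints, local descriptors,
nearest-neighbour matching, and Hough-space pose clustering with a
least-squares rigid fit.

The underlying assumptions are that (i) pocket geometry is approximately
rigid between the query and the database structure, (ii) local atomic
neighbourhoods are distinctive enough for retrieval, and (iii) a correct
placement is supported by many atoms voting for the same pose while
incorrect matches scatter. Conformational change, alternate rotamers and
partial occupancy all violate (i) to some degree; the noise model below
quantifies tolerance to such perturbations.

### Keypoints: grid-centroid uniform sampling

Each axis of the cloud's tight bounding box is divided into ε
closed-front/open-back intervals (the axis maximum joins the last
interval; a zero-extent axis collapses to one interval with a warning).
A cell's mass is its point count; a cell is *dense* when its mass
reaches half the mean occupied-cell mass, `mass ≥ n/GridNum × 0.5`
(inclusive). Face-adjacent dense cells (index triples differing by one
in exactly one coordinate — diagonal contact does not connect) are
merged into components, and each component emits one keypoint: the
mass-weighted centroid of its member cells.

Two details were genuinely open and are resolved as follows.
*Interval openness*: the interval formula and the accompanying prose
disagree (closed-front/open-back vs open-front/closed-back); the
formula is implemented, and the conflict is noted here.
*Cell representative*: a component centroid can weight either the
cells' geometric midpoints or the mass-weighted means of the member
points. The midpoint reading is the conventional one and is the
default of `component_centroid()`/`sample_keypoints()`. The matching
pipeline, however, uses the member-point mean (`centroid = "points"`):
cell midpoints are tied to the grid axes and are therefore not
equivariant under rotation, which would make exact transform recovery
impossible even on noiseless data, while point means are exactly
equivariant whenever the cell decomposition is (guaranteed at cell
edges below the minimum interatomic distance).

### Local features

Per-point normals are the smallest-eigenvalue eigenvectors of the
neighbourhood covariance, oriented away from the cloud's centre of
mass (a rigidly covariant sign rule; any consistent orientation works
for invariance). Points with fewer than 3 neighbours get an undefined
normal.

Local reference frames at keypoints come from the eigen-decomposition
of the distance-weighted neighbourhood covariance (weights
`r − distance`). The two leading axes are oriented so the *weighted*
projection sum of neighbour displacements is nonnegative — a head-count
majority rule ties too often on small neighbourhoods and then flips
between two samplings of the same geometry — and the third axis is
their cross product, so frames are always proper. Frames with under 5
neighbours or a collinear neighbourhood are flagged degenerate; nearly
isotropic neighbourhoods (λ₂/λ₁ > 0.9) are flagged low-confidence.

The descriptor is a normalized histogram of the point-feature
quadruplet: for each (keypoint, neighbour) pair, the Darboux-frame
angles α, φ, θ and the pair distance d, each in 11 uniform bins,
concatenated to 44 bins and normalized to sum 1. All four features are
rigid-invariant given covariant normals. The distance feature is kept
(rather than the 33-bin angles-only layout common for fast point
feature histograms) because the short supports used here contain few
pairs, and the angular features alone leave too many identical
histograms to rank matches.

### Matching and grouping

A hand-implemented k-d tree (cyclic splitting dimension `depth mod k`,
median splits, distance ties to the lowest index) answers
nearest-neighbour queries identically to a linear scan; it serves both
3-dimensional coordinate queries and descriptor-space queries.

`match_descriptors()` keeps, per query keypoint, its nearest target
descriptor below the squared-distance acceptance threshold (0.25 by
default). The end-to-end matcher instead requests `corr_k = 10`
candidates per pocket keypoint, keeping every candidate tied with the
k-th best. The reason is structural: a pocket is a partial view, so
the support neighbourhood of a boundary pocket atom differs between
the excised pocket cloud and the full structure, and its single
nearest descriptor is frequently wrong. Generating several candidates
and letting geometric consistency decide is the standard remedy; the
incorrect candidates scatter in Hough space and are removed by the
consensus stages below.

The candidate ordering also exploits the partial-view structure
(`corr_rank = "containment"`). Every (keypoint, neighbour) pair
present in the pocket cloud exists with identical geometry around the
keypoint's true counterpart in the full structure, so the pocket
keypoint's raw bin counts are componentwise dominated by the
counterpart's. Candidates are therefore ranked first by the
containment violation `sum(pmax(0, counts_pocket - counts_protein))` -
exactly zero for the true counterpart, up to normal-induced bin
shifts - and only then by Euclidean descriptor distance.

Each candidate correspondence votes for the scene position of the
pocket's reference point (the pocket centroid — a small lever arm keeps
frame noise from amplifying), expressed through the matched keypoints'
local frames. Votes are binned at `cg_size_`; face-adjacent occupied
bins merge, but only bins holding at least two votes can bridge a
merge (single-vote bins attach to the heaviest adjacent cluster), so
sparse background votes cannot chain unrelated clusters together.
Clusters with at least `cg_thresh_ = 5` votes become match groups.

Each group's transform is seeded by a Kabsch fit (SVD with reflection
guard) over its densest single bin, then refined by trimmed least
squares: all candidate pairs within half a bin of reprojection are
selected (at most one per pocket keypoint, smallest residual first),
the fit is recomputed, and the selection is iterated to stability.
Re-admission spans the full candidate set, so correct pairs whose votes
were scattered by contaminated frames — or that could not vote at all
because a frame was degenerate — still support the hypothesis. Groups
that converge to the same correspondence set are reported once.
Finally, hypothesis verification keeps a group only if more than
`min_inlier_fraction` of transformed pocket points have a scene
neighbour within `hv_inlier_th_`; the full occlusion/clutter
global-verification machinery is intentionally not implemented, and its
parameters are parsed for configuration compatibility only.

### Evaluation metrics

For a predicted pocket against a reference pocket at matching
threshold δ (default 2.0 Å — the scale of a heavy-atom contact; the
threshold is configurable and reported with every result):

* POS is the fraction of *reference* points covered within δ, so it is
  always in [0, 1] even when the clouds differ in size.
* Confusion counts classify every predicted point exactly once, in
  precedence order: within δ of a reference point → TP; outside the
  reference bounding box → TN; otherwise → FP. FN counts uncovered
  reference points. The bounding-box rule makes TN meaningful for
  unbounded outside space but degenerates for perfect predictions
  (no negatives exist, and MCC is 0 by the zero-denominator
  convention).
* F1 and MCC use the conventional formulas with zero denominators
  mapped to 0, and MCC is clamped to [−1, 1] against floating-point
  overshoot.
* RMSE is the root mean squared nearest-neighbour distance from
  predicted to reference points (several conventions exist; this
  definition is documented and frozen).
* A correspondence count strictly above 10 is a *strong* similarity
  match, otherwise *weak*.

Metric distance computations form differences before squaring, so
identical clouds give exact zeros rather than cancellation residue.

### The noise model

Noise level is defined as δ, the arithmetic mean (not root-mean-square)
of per-atom Euclidean displacements. The displacement distribution is
not fixed by the definition, so the generator offers two shapes and
calibrates both so the expected displacement equals the target:
isotropic Gaussian per coordinate with σ = δ·√(π/8) (the mean of a
χ₃-distributed magnitude is σ·2√(2/π)), and uniform-in-ball with radius
4δ/3 (the mean draw is 3/4 of the radius). The Gaussian is the default;
Monte-Carlo checks at n = 10⁴ confirm the calibration within 5%.

## Configurations

`procv_config()` carries the reference parameter set in normalized
units (clouds jointly rescaled by the reciprocal of the scene
bounding-box diagonal): sampling radii 0.005/0.01, reference-frame
radius 0.015, descriptor radius 0.02, Hough bin 0.05, vote threshold 5,
and the verification parameters. These values suit densely sampled
surface scans, where the sampling radius sits far above the point
spacing and descriptor supports hold dozens of points. On atomic
clouds the same ratios fail: after diagonal normalization of a ~50 Å
protein, a 0.02 descriptor radius is ~1 Å and contains no neighbouring
atom at all.

`atomic_config()` — the working default of `match_pocket()` — therefore
states the same parameters in Å, chosen from atomic geometry before
any benchmarking and then frozen:

| parameter | value | rationale |
|---|---|---|
| `ligand_ss_`, `protein_ss_` | 0.4 / 0.5 Å | below the minimum interatomic distance, so sampling preserves every atom and is exactly rigid-equivariant |
| `descr_rad_` | 3.0 Å | the covalently bonded shell; the only context shared verbatim between a pocket excerpt and the full structure |
| `rf_rad_`, `hv_rad_normals_` | 4.0 Å | first coordination shell, enough neighbours for stable covariance |
| `cg_size_` | 2.0 Å | pose-error scale of contaminated frames; refinement tolerance is half of it, below interatomic spacing |
| `cg_thresh_` | 5 | counts are integral, read as ≥ 5 |
| `hv_inlier_th_`, `min_inlier_fraction` | 1.0 Å, 0.8 | strict enough that a pocket misplaced inside a dense atom cloud fails verification |
| `max_descr_dist` | 0.25 | loose gate on squared descriptor distance; consistency filtering happens downstream |
| `corr_k`, `corr_rank` | 10, containment | candidates per pocket keypoint handed to Hough consensus, ranked by containment violation then distance |
| `delta_metric` | 2.0 Å | heavy-atom contact resolution for POS/confusion |
| `similarity_threshold` | 10 | strong/weak cut, strict inequality |

## The synthetic study conditions

`make_structure()` emulates what the matching stages actually consume —
protein-like atom geometry — without any physical realism: a Cα trace
built as a persistent self-avoiding random walk with exact 3.8 Å steps
and a weak pull towards the fold centre; 1–4 side-chain pseudo-atoms
per residue at 1.5 Å bonds; and a ligand blob seated in the most
enclosed admissible surface position with ≥ 2.3 Å clearance. Defaults:
56 residues (a small domain, ~200 heavy atoms) and a 16-atom
drug-sized ligand, giving 5 Å pockets of roughly 20–45 atoms. All
placements enforce a 1.3 Å minimum interatomic separation; this is what
guarantees that sub-voxel sampling assigns one atom per grid cell on
both sides of a match, the precondition for exact transform recovery.

What the generator does *not* emulate — chemistry, element diversity,
secondary-structure regularity, crystallographic artefacts, genuinely
flexible pockets — bounds what green tests mean: they demonstrate the
geometric machinery (sampling, retrieval, consensus, verification,
metrics) under controlled rigid and noisy perturbations, not
performance on real structural databases.

Standard problem sizes, chosen to exercise every stage while keeping
the full suite in minutes: oracle equivalence on 100 random clouds
(n ≤ 500), 10⁴ k-d tree queries in 3 and 33 dimensions, 20-replicate
one-to-many recognition over 5 structures, and a 4-level × 20-seed
noise ladder at δ ∈ {0, 0.5, 1.0, 1.5} Å.

## Numerical choices and degenerate inputs

* Ties: nearest-neighbour distance ties go to the lowest index;
  component and group orderings are lexicographic/by-count, so all
  outputs are deterministic for a fixed seed.
* The Kabsch fit refuses groups whose correspondences are collinear
  (second singular value ≤ 10⁻¹² of the first) and guards against
  reflections via the sign of det(VUᵀ).
* Degenerate frames skip voting but their correspondences remain
  eligible for transform-based re-admission.
* An empty pocket at radius 0, an empty group list ("no match"), and
  per-pair failures inside `similarity_matrix()` are warnings or
  recorded missing values, never hard errors.
* PCD files are written with six decimals (round trip ≤ 10⁻⁶ Å); PDB
  coordinates round trip at the format's 10⁻³ Å column precision.

## Known limitations

* The noise ladder degrades steeply: at δ = 0.5 Å the short-range
  descriptors (3 Å support, 0.27 Å distance bins) already scramble, so
  verified similarity counts typically fall from full to near zero
  rather than tapering gently. The counts remain monotone
  non-increasing, which is the property the noise experiment checks.
* MCC is uninformative (0 by convention) exactly when a prediction is
  perfect, because the bounding-box rule then produces no negatives.
* Recognition robustness is tuned to atom-scale clouds; for surface
  scans use `procv_config()` and normalized units.
* Hypothesis verification is the simplified inlier-fraction test, not
  a global occlusion/clutter optimization.
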