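---
title: "radionet: methods, modeling choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radionet: methods, modeling choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`radionet` analyzes a stack of N co-registered scalar feature volumes (for
example multimodal MRI-derived maps) as a weighted network over voxel
clusters.

**Voxel domain.** Every masked voxel carries the feature vector
$v_{xyz} = (f_1, \dots, f_N)_{xyz}$. Voxels with similar feature vectors are
presumed to contain similar tissue, so the first step is clustering in
feature space. Because the features carry mixed units (intensities, mm²/s,
ml/100g/min, seconds), each feature column is z-scored (population sd)
before clustering; the cluster *statistics* are computed on the raw values.

**Cluster profiles.** Each cluster $i$ is summarized by
$C_i = [\dots, f_{j,\mathrm{mean}}, f_{j,\mathrm{std}},
f_{j,\mathrm{kurtosis}}, f_{j,\mathrm{skewness}}, f_{j,\mathrm{min}},
f_{j,\mathrm{max}}, \dots]$, a 6N-vector of the intra-cluster distribution
of every feature. Conventions (the method's description names none):
population standard deviation, Fisher moment skewness, *excess* kurtosis
(normal → 0). Singleton or zero-variance clusters get std = 0 and
skewness = kurtosis = 0 and are flagged rather than dropped, keeping the
node set stable.

**Adjacency.** Entry (i, j) is the Pearson correlation between $C_i$ and
$C_j$ after z-scoring each statistic *across clusters* — without this, the
large-magnitude statistics (min/max of high-intensity features) dominate
and every pair correlates near 1. Negative values are clipped to 0, giving
the stated [0, 1] range with the semantics "no correlation → no edge"
(an absolute value would instead turn strong anti-correlation into a strong
edge). Two clusters with bitwise-identical profiles are defined to have
COR = 1. A cluster whose z-scored profile is constant (it sits exactly at
the per-statistic mean) has no defined correlation and is reported by id as
an error.

**Graph.** Edge iff COR > threshold; weight = COR, length D = 1 − COR.
The default threshold is 0.5; `edge_threshold = "auto"` instead picks the
threshold reaching a target edge density (default 0.20, a typical sparsity
for tissue networks: roughly one in five node pairs connected). Disconnected graphs are
legal everywhere downstream.

**Node metrics and taxonomy.** Degree is weighted strength; the local
clustering coefficient is computed on the unweighted thresholded graph;
betweenness uses shortest paths under the lengths D, is divided by
(n−1)(n−2)/2 and min–max normalized; degree is min–max normalized too.
Min–max is the only normalization under which the default role cutoffs
(betweenness > 0.80, degree < 0.20, CC > 0.75) are meaningful as relative
values. Roles, with precedence bridge > hub > authority > cluster member:

| role           | rule (defaults)                         | provenance |
|----------------|------------------------------------------|------------|
| bridge         | betweenness > 0.80 and degree < 0.20     | core definition |
| hub            | degree > 0.80                            | extrapolated |
| authority      | degree above the 75th percentile         | extrapolated |
| cluster member | CC > 0.75                                | core definition |

The hub/authority cutoffs are extrapolations from the pictorial taxonomy
(it fixes no numbers for them) and are configurable. Whether "low degree"
means strength or edge count is unstated; strength is used.

**Subnetworks and back-projection.** Bridges are removed; connected
components of the remainder with ≥ `min_size` (default 3) nodes are major
subnetworks, numbered by descending size; smaller components are satellite
groups. Every voxel then inherits its cluster's node label, yielding a
label volume at the original resolution (legend: subnetworks 1..S, bridge
S+1, satellite S+2, unassigned S+3; hierarchy groups 10+g). Anatomical
identity (tumor vs healthy) is *never* inferred from topology: it is
assigned by majority overlap with a reference labeling (phantom ground
truth, or a user-supplied mask), with interface-labeled reference voxels
excluded from the vote.

**Intra-tumor hierarchy.** Nodes of one subnetwork are split into 4 groups
by degree rank (ties broken by node id, so groups are non-empty whenever
enough nodes exist); all-equal degrees collapse to one group with a
warning.

**Cluster-number sweep.** The number of clusters k is not known a priori.
Past the informative resolution, edges stop reflecting tissue structure and
behave like a random graph's. The operational criterion (invented here, and
labeled as such) scores each k two ways:

* `randomness_score = C_ER / max(C_obs, 1e-6)`, where `C_obs` is the mean
  local clustering coefficient and `C_ER` = edge density is the
  Erdős–Rényi expectation at the same size and density. Structured
  networks score ≪ 1; random ones ≈ 1; a complete graph scores exactly 1.
  A graph with edges but no triangles scores very large — tree-like wiring
  at low density is itself maximally unstructured relative to its density.
* `stability`: mean edge-set Jaccard similarity between the reference
  network and 5 reseeded clusterings, with clusters matched greedily by
  voxel overlap. Structure that only exists for one k-means seed is not
  structure.

The flagged onset is the smallest k with randomness ≥ 0.8 or stability
< 0.5. The sweep uses the *fixed* default threshold (0.5): a
density-targeting threshold would hold `C_ER` constant by construction and
mask the diagnostic.

## The phantom: a stated world

No patient data are distributed, so a synthetic phantom provides
ground-truthed input. The default (`default_phantom_spec()`):

| parameter | value | rationale |
|-----------|-------|-----------|
| grid | 64 × 64 × 8 voxels at 0.37 × 0.37 × 5.5 mm | a realistic re-sliced multimodal MRI voxel dimension; a thin slab cropped around the lesion |
| features | 21 | a full anatomical + diffusion + perfusion MRI stack |
| healthy background | means 100 + 2(j−1), sd 8 | arbitrary intensity units; per-feature offsets avoid identical columns |
| tumor ellipsoid | radii 22 × 22 × 3 voxels (~20 % of the slab), contrast 5–24 units (0.6–3 healthy sd, alternating sign), sd 14 | a large occipital mass on a cropped field of view; features differ in discriminative power, as real multimodal features do; the larger within-class sd encodes intratumor heterogeneity |
| interface | 1-voxel shell grown (6-connectivity) from tumor into background; mean = midpoint of the two class means, sd = their average | partial-volume tissue; intermediate feature values are the simplest mechanism by which interface voxels can mediate between tissue profiles |
| noise | global sd 3 per feature | scanner noise on top of biological variability |
| seed | 42 | fixed |

Voxel values are drawn independently per feature as class mean +
N(0, √(class sd² + noise sd²)); identical spec + seed is bit-reproducible.
"Zero-noise" means both sds zero, in which case every voxel equals its
class mean exactly.

What the phantom does **not** emulate: MR physics, bias fields, spatial
noise correlation, partial-volume mixing beyond the one interface shell,
motion, and — critically — the rich multi-tissue covariance structure of a
real brain (CSF, white/gray matter, edema, necrosis). A green test on the
phantom establishes that the pipeline recovers the structure the phantom
contains, not that it would segment a real ependymoma.

### A structural limitation the phantom exposes

On real patient networks, *bridge* nodes connect the tumor and healthy
subnetworks and back-project onto the tumor–healthy interface.
The three-class default phantom cannot reproduce this, for a reason worth
recording. The interface class mean is exactly the midpoint of the healthy
and tumor means, so the three class centroids are collinear in profile
space; per-statistic z-scoring is an affine map per column and preserves
that collinearity. With healthy clusters in the majority, the cross-cluster
column mean sits between the healthy position and the midpoint, so
interface profiles always fall on the tumor side of the center:
COR(interface, tumor) > 0 but COR(interface, healthy) < 0 — clipped to 0.
No edge can ever join the two sides, the graph splits into two components
with the interface clusters isolated (they surface as the `satellite`
label), and no node can satisfy the bridge definition. Real bridges arise
only when the feature space is at least two-dimensional across tissues —
i.e., when different feature subsets differentiate different tissue pairs,
as in real multimodal data with more than two tissue types. The
tissue-recovery acceptance criterion therefore passes its
subnetwork/purity clauses but honestly fails its bridge-localization
clause on this phantom; widening the phantom (or weakening the criterion)
to force a pass would defeat its purpose.

## Numerical and design choices

* **Coordinates.** Voxel tables store 1-based (x, y, z) indices in
  x-fastest order (idiomatic R); the NIfTI affine maps (index − 1) to world
  mm, so world coordinates follow the NIfTI convention exactly.
* **NIfTI I/O** is implemented in-package (single-file NIfTI-1, sform
  affine, int32/float32/float64, transparent gzip): no R NIfTI reader was
  available in the target environment. Two-file (.hdr/.img) NIfTI is not
  supported.
* **Config and spec files are JSON** (round-trip lossless) rather than
  YAML, for the same environment reason.
* **Resampling** is trilinear for features, nearest-neighbor for labels,
  voxel-center aligned with border clamping; resampling to the current
  spacing is the identity. Registration is upstream: only grid resampling
  is provided.
* **NaN policy**: any voxel holding a non-finite value in any feature is
  excluded from the mask. Imputation is deliberately not offered — the
  higher cluster moments (kurtosis, skewness) are fragile under imputed
  values.
* **k-means** uses 10 restarts under a local seed (the caller's RNG state
  is untouched); when the table has at most k distinct feature vectors,
  those vectors are used as centers directly, making the degenerate case
  deterministic. Ward (`ward.D2`) agglomeration is available for small
  tables (O(n²) distance matrix, capped at 20 000 voxels).
* **Empty clusters** are compacted with a warning, so cluster ids stay
  contiguous 1..k.
* **Auto edge threshold** places the cut between the m-th and (m+1)-th
  largest off-diagonal correlation (m = target density × pairs), erring
  dense under ties; with clipped-negative adjacencies the achievable
  density is capped by the fraction of positive pairs.
* **Min–max normalization** maps an all-equal metric vector to all zeros:
  no spread should never manufacture a high-scoring node.
* **Determinism.** Every random stage derives its seed from the config
  seed (secondary streams via a fixed integer hash kept below 2³¹), so a
  run is reproducible byte-for-byte from its run record.

## Known limitations

* The sweep's stability score depends on k-means seed variability; for
  very large k the greedy cluster matching becomes loose, which biases
  stability downward (conservative: it flags overfitting earlier).
* The correlation adjacency treats cluster profiles as exchangeable
  statistic vectors; an alternative reading ("cross-correlation" between
  voxel-level samples of two clusters) is ill-defined for unequal cluster
  sizes and was not adopted.
* Rendering/overlay visualization is out of scope; outputs are label
  volumes and tables intended for external viewers.
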