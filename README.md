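# radionet

Correlation-network analysis of multimodal radiomic feature volumes.

## The problem

Multimodal MRI of a brain tumor yields many co-registered scalar feature maps
per patient — anatomical contrasts, diffusion maps (FA, trace, ADC), and
perfusion maps (CBF, CBV, MTT, TTP) — typically N = 21 features on one voxel
grid. Each voxel *v* at coordinates (x, y, z) carries a feature vector

    v_xyz = (f_1, f_2, …, f_N)_xyz

`radionet` turns such a stack into an interpretable *network* over voxel
clusters and projects the network's topology back onto the image:

1. **Voxel clustering.** Masked voxels are grouped into k clusters by feature
   similarity (k-means on z-scored features, or Ward agglomerative). Each
   cluster i is summarized by the statistic vector

       C_i = [f1_mean, f1_std, f1_kurtosis, f1_skewness, f1_min, f1_max, …,
              fN_mean, …, fN_max]   (6N entries)

2. **Network construction.** The adjacency entry (i, j) is the
   cross-correlation COR between the statistic vectors of clusters i and j
   (z-scored per statistic across clusters, negatives clipped to 0, so
   COR ∈ [0, 1]). Edges exist where COR exceeds a threshold; edge weight =
   COR and edge length D = 1 − COR, so geodesic (shortest-path) distances
   capture indirect interactions.

3. **Node taxonomy.** After min–max normalization of the metrics, nodes are
   classified with precedence bridge > hub > authority > cluster member:
   *bridges* have high betweenness (> 0.80) and low degree (< 0.20) and
   connect subnetworks; *cluster members* have high clustering coefficient
   (> 0.75).

4. **Segmentation by back-projection.** Removing bridges splits the network
   into subnetworks; every voxel inherits its cluster's label, producing a
   tissue segmentation (e.g. tumor vs healthy brain, with bridges at their
   interface) at the original spatial resolution. Within a subnetwork, nodes
   are stratified into four degree groups — an intra-tumor heterogeneity
   hierarchy.

5. **Model selection.** A cluster-number sweep tracks when the network stops
   being structured: past the informative resolution, edges behave like an
   Erdős–Rényi random graph (`randomness_score = density / mean CC → 1`) and
   become irreproducible across reseeded clusterings.

Because no patient data ship with the method, a **synthetic phantom** module
generates multi-feature volumes with ground-truth tissue labels (healthy
background, tumor ellipsoid, partial-volume interface shell, optional
satellite spots), making every stage testable end to end.

## Worked example

```r
library(radionet)

cfg <- pipeline_config(
  phantom_spec = default_phantom_spec(seed = 42),
  k = 20, seed = 42, edge_threshold = "auto",
  hierarchy_subnetwork = "tumor",
  output_dir = "phantom_run"
)
res <- run_pipeline(cfg)
res
#> <pipeline_result> 20 nodes, 38 edges, 2 major subnetworks; outputs in phantom_run
res$identity
#>   segment_label segment_name identity    purity n_voxels
#> 1             1 subnetwork_1  healthy 0.9999141    23646
#> 2             2 subnetwork_2    tumor 1.0000000     5763
#> 3             4    satellite    tumor 0.8899457     3359
```

The 20 voxel clusters become a 20-node network with 38 edges at the
density-targeted correlation threshold (0.457). Removing no bridges — this
phantom's two tissues anticorrelate so strongly that the subnetworks are
already separate components — leaves 2 major subnetworks: `subnetwork_1`
back-projects onto healthy brain and `subnetwork_2` onto the tumor ellipsoid
(purity ≈ 100 % each against the ground truth, interface voxels excluded
from the vote). The interface-dominated clusters land in the
low-correlation `satellite` group straddling both tissues.
`segmentation.nii` holds the
tissue labels, `hierarchy.nii` the four degree groups inside the tumor
subnetwork, and `run_record.json` everything needed to reproduce the run.

The cluster-number diagnostic:

```r
tab <- build_voxel_table(generate_phantom(default_phantom_spec(seed = 42))$volume)
k_sweep(tab, c(3, 10, 20, 40, 80), seed = 42)
#>    k n_nodes edge_count    density   mean_cc randomness_score stability
#> 1  3       3          0 0.00000000 0.0000000     0.000000e+00 1.0000000
#> 2 10      10          4 0.08888889 0.0000000     8.888889e+04 0.1579365
#> 3 20      20         10 0.05263158 0.1500000     3.508772e-01 0.1282456
#> 4 40      40         58 0.07435897 0.2857143     2.602564e-01 0.1843274
#> 5 80      80        180 0.05696203 0.2034682     2.799555e-01 0.2380542
```

Randomness is lowest at the tissue-resolving scale and rises (and edge sets
stop being reproducible, `stability` < 0.5) once clusters out-resolve the
information in the features — the basis for choosing a stopping k.

## Command line

```sh
Rscript inst/cli/radionet phantom --out phantom_dir            # write the default phantom
Rscript inst/cli/radionet run    --config cfg.json             # full pipeline
Rscript inst/cli/radionet sweep  --config cfg.json --k 10:100:10
```

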