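# ugfc — brain lesion detection by unified gravitational fuzzy clustering

`ugfc` detects hyperintense lesions (tumors, enhancing or FLAIR-bright
pathology) in single-slice grayscale MR images with minimal user
intervention. It is aimed at researchers in quantitative neuroimaging who
need an automatic, fast, fully deterministic baseline segmentation together
with standard overlap metrics, and at method developers who want each stage
of the cascade available as a tested library function.

The detection cascade has three stages:

1. **Fuzzy rule-based contrast enhancement.** A three-rule Mamdani system —
   *IF a pixel is dark THEN make it darker; IF gray THEN keep it gray; IF
   bright THEN make it brighter* — evaluated by min implication, max
   aggregation and centroid defuzzification,

   y₀ = Σᵧ y·Q(y) / Σᵧ Q(y),  Q(y) = maxᵣ min( μₛ(z₀), μᵣ(y) ),

   which induces a monotone, range-expanding intensity lookup table.

2. **Unified gravitational fuzzy clustering (UGFC).** Cluster centroids are
   seeded at the modes of a Gaussian kernel estimate of the histogram at the
   *critical bandwidth* (the smallest h giving exactly c modes). Pixels whose
   fuzzy C-means membership

   μᵢⱼ = [ Σₖ (dᵢⱼ/dₖⱼ)^(2/(w−1)) ]⁻¹

   is confident (≥ θ) are hard-clustered; ambiguous pixels can further be
   captured by a cluster whose Newtonian pull F = 2·mᵢ/d² (cluster mass =
   hard pixel count, d = planar distance to the cluster core) dominates all
   others. Centroids alternate with assignments, monitored by the product
   objective J_GFC = J_GC · J_CM. The brightest cluster becomes the candidate
   lesion ROI.

3. **Reinitialization-free level-set refinement.** The ROI boundary evolves
   under ∂ϕ/∂t = β(Δϕ − div(∇ϕ/|∇ϕ|)) + λ δ(ϕ) div(g∇ϕ/|∇ϕ|) + ν g δ(ϕ)
   with edge indicator g = 1/(1 + |∇(G_σ∗I)|²); the internal β-term keeps ϕ
   an approximate signed distance function so the field never needs
   reinitialization, and contours split or merge freely.

Results are scored with Dice, Jaccard, sensitivity and specificity. A seeded
phantom generator (tissue ellipses, lesion disks, polynomial bias field,
Gaussian/Rician noise) provides ground-truth data so the whole package is
testable offline.

## Worked example

```r
library(ugfc)

ph  <- make_phantom(phantom_spec(seed = 1))      # image + lesion ground truth
res <- run_pipeline(ph$image, pipeline_config(), truth = ph$truth)
res
#> lesion detection: final mask 230 px (ROI 253 px), 870 level-set iterations
#> Dice 0.9524 | Jaccard 0.9091 | Se 0.9091 | Sp 1.0000
#> TP 230  FP 0  FN 23  TN 16131
```

The clustering ROI matches the 253-pixel lesion exactly; the refined contour
settles just inside the lesion edge, leaving 230 true positives and no false
positives — a Dice overlap of 0.95, with specificity at 1 because the
background dominates the 128×128 slice. `res$report` records per-stage
timings, the J_GC/J_CM/J_GFC trace and every effective parameter;
`res$state` holds centroids, masses and memberships. Individual stages are
plain functions (`enhance_image()`, `ugfc_cluster()`, `extract_roi()`,
`edge_indicator()`, `evolve()`, `overlap_metrics()`) that can be composed
freely.

A command-line interface wraps the same functions:

```sh
ugfc phantom -o img.png --truth truth.png --seed 3
ugfc detect img.png -o mask.png
ugfc eval truth.png mask.png -o metrics.json
```

(after installation the script lives at `system.file("exec", "ugfc",
package = "ugfc")`).

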