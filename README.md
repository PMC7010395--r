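# finid

Contour-based photo-identification of individual shark fins.

Field biologists catalogue great white sharks by the shape of the dorsal
fin: the trailing edge carries a persistent, individually distinctive
pattern of notches and serrations. `finid` implements a fully automated
pipeline from an above-water photograph to a ranked list of known
individuals:

1. **Detection.** A hierarchical segmentation rarely isolates the fin as a
   closed region (fin and body merge where their boundary is smooth), so
   candidates are generated as *contour strokes*: open arcs of region
   boundaries between salient keypoints. Keypoints are local maxima —
   ranked by prominence — of the difference-of-Gaussian corner response
   `D(u,σ) = [G(u,mσ)*x − G(u,σ)*x]² + [G(u,mσ)*y − G(u,σ)*y]²`
   of the boundary. With `n = 7` keypoints per boundary and `k = 12`
   regions, `(n² − n)k = 504` candidates are produced per image, scored by
   a random-forest regressor over a 180-dimensional feature (a 20-word
   opponent-colour bag of visual words plus a 20×8 histogram of boundary
   normals), and filtered by non-maximum suppression.
2. **Encoding.** The detected fin contour (1024 samples) is subdivided by
   its 50 most prominent keypoints into `C(50,2) = 1225` subsections, each
   resampled to 256 samples and described at filter scales
   `S = {1,2,4,8}` by two L2-normalised descriptors: the rotation-invariant
   DoG-norm, and chord-aligned boundary normals.
3. **Identification.** A local naive Bayes nearest-neighbour (LNBNN) score
   `f(d,c) = max(0, δ(NN_other) − δ(NN_c))` accumulates evidence per
   individual across descriptors and scales (one-shot: a single labelled
   reference per animal suffices). Optionally, scores are sum-pooled into a
   550-bin "fin space" (2 types × 55 spatial partition-runs × 5 scale
   bins) and a random forest — trained with two-fold by-individual
   cross-validation — maps each query-class scoring vector to a match
   probability.

The real survey corpus for this problem is private, so the package ships a
seeded synthetic generator: fin-shaped individuals with persistent notch
and multi-scale roughness signatures, sightings under rotation, scale,
shear, bending, contour jitter, waterline occlusion and splash, with
ground-truth contours, tips and region-hierarchy fixtures.

## Worked example

Simulate a small labelled population, encode references (both directions)
and queries (one direction), and identify by multi-scale LNBNN:

```r
library(finid)

ds <- make_dataset(n_individuals = 8, sightings_per_individual = 3,
                   preset = "standard", seed = 42)
#> <synthetic_dataset: 8 individuals, 24 images (standard preset, seed 42)>

refs    <- encode_dataset(ds, "reference", types = "dogn", n_keypoints = 12)
queries <- encode_dataset(ds, "query",     types = "dogn", n_keypoints = 12)
catalog <- build_catalog(refs)
#> <individual_catalog: 8 individuals, strata: dogn_1, dogn_2, dogn_4, dogn_8>

preds <- identify_queries(queries, catalog)
head(preds, 4)
#> # A tibble: 4 × 4
#>   query_id   class   score  rank
#>   <chr>      <chr>   <dbl> <int>
#> 1 ind001_s02 ind001 85.5       1
#> 2 ind001_s02 ind002  1.12      2
#> 3 ind001_s02 ind008  0.853     3
#> 4 ind001_s02 ind003  0.371     4

truth <- dplyr::rename(ds$labels[ds$labels$role == "query",
                                 c("image_id", "individual")],
                       query_id = image_id)
evaluate_identification(preds, truth)
#> <identification_evaluation: 16 queries, AP = 1.0000, mAP = 1.0000, top-1 = 1.000>
```

The score column is the summed LNBNN evidence: the true individual
(`ind001`, 85.5) dominates its nearest impostor (1.12) by two orders of
magnitude; over all 16 queries every first-ranked identity is correct. AP
pools all query–class scores; mAP averages per-individual APs so
frequently-sighted animals do not dominate.

`autoplot()` methods draw PR curves for identification and detection
results, `plot_bin_distinctiveness()` heat-maps where on the fin
individuality concentrates, and `tidy()`/`glance()` return fitted-model
summaries as tibbles. A thin command-line wrapper with
`simulate` / `detect` / `identify` / `evaluate` subcommands lives at
`inst/cli/finid.R`.

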