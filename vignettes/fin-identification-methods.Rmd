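---
title: "Contour-based fin photo-identification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour-based fin photo-identification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`finid` identifies individual sharks from above-water photographs of their
dorsal fins. The fin's outline — a smooth leading edge and an individually
jagged trailing edge — is a biometric: notches and serrations persist over
years. The package implements the full chain from pixels to identity:
detection of the fin outline as an *open contour stroke*, a multi-scale
biometric encoding of that contour, and two identification models over the
encoding. This vignette explains each model, its assumptions and tunable
parameters, what the synthetic benchmark generator does and does not
emulate, and where genuinely open design questions were settled.

## 1. Curve scale space and keypoints

Every shape in the pipeline is a planar curve $C(u) = (x(u), y(u))$,
resampled uniformly in arc length so that "scale in samples" is
geometrically meaningful. The corner-saliency signal is the squared
evolution difference of two Gaussian smoothings,

$$D(u,\sigma) = [G(u, m\sigma) * x - G(u,\sigma) * x]^2 +
               [G(u, m\sigma) * y - G(u,\sigma) * y]^2,$$

a band-pass filter on contour shape: $\sigma$ fixes localisation, $m$ the
bandwidth. Keypoints are local maxima of $D$ ranked by *prominence* — the
peak height above the larger of the two flanking-interval minima, an
interval that reaches an open signal's end contributing zero. Closed curves
are treated circularly (a loop has no ends). Ties in prominence go to the
lower vertex index, for determinism.

Numerical choices worth knowing:

* Kernels are truncated at $4\sigma$ and renormalised to unit mass.
* Closed curves use circular convolution. Open curves use *odd* (i.e.
  anti-symmetric, linearly extrapolating) reflection about the end samples.
  Plain symmetric reflection folds a straight curve into a tent and
  manufactures corner responses at the cut ends of occluded fins; odd
  reflection reproduces linear segments exactly, so a straight subsection
  has an identically zero response.
* `m = 1` makes $D \equiv 0$ and raises a warning rather than an error.

Defaults by stage (all configurable through `fin_config()`):

| stage                    | resampling | $\sigma$ | $m$ | keypoints |
|--------------------------|-----------:|---------:|----:|----------:|
| stroke candidates        | 128        | 1        | 4   | 7         |
| fin subsection keypoints | 1024       | 2        | 8   | 50        |
| descriptor filters       | 256        | 1,2,4,8  | 2   | —         |
| fin-tip localisation     | 1024       | 16       | 2   | 1         |

## 2. Fin detection as contour strokes

Fins photographed at the surface rarely form closed segmentation regions:
where fin meets body smoothly, hierarchical segmentation merges the two.
The detector therefore works on the *boundaries* of regions. A pluggable
backend produces a region hierarchy (levels in $[0,1]$, children nested in
parents); the built-in fallback runs a watershed on the gradient magnitude
of the blurred luminance, snaps basin boundaries to the best-matching
luminance side, and merges basins greedily by mean boundary gradient. The
hierarchy is descended to a pool of unique regions; regions smaller than
0.1% of the image or with mask IoU above 0.95 against an already-kept
region are rejected (the rejection thresholds are declared defaults — the
established practice of dropping "too small" and "too similar" candidates
— and both are configurable); the top `k = 12` survive.

Each surviving boundary is resampled to 128 samples for keypointing
($\sigma = 1, m = 4$, 7 keypoints), and one stroke candidate is taken per
*ordered* keypoint pair — the boundary arc between them, at the boundary's
full resolution. With $n$ keypoints and $k$ regions this yields
$(n^2-n)k = 504$ candidates, the two complementary arcs of each pair
counted once each and encoding direction not duplicated.

Candidates are scored by a 180-dimensional feature vector: a 20-word
bag-of-visual-words over dense opponent-colour patch descriptors (patch
sizes 16/24/32/40, every pixel within 4 px of the stroke), and a
20-spatial x 8-orientation histogram of boundary normals; both components
are L2-normalised before concatenation. The appearance bag depends only on
the stroke's pixel set and is direction-independent; the normals histogram
rotates by $\pi$ under reversal and is direction-dependent. A random
forest regresses the stroke's true quality — its boundary-matching
F-measure against the labelled fin contour — and greedy non-maximum
suppression removes strokes overlapping a better one by more than 0.2,
overlap measured as matched boundary pixels (2 px tolerance, one-to-one)
over the smaller stroke. The final detection threshold on predicted
quality defaults to 0.5.

Two open points were settled here: NMS overlap is a matched-pixel
fraction (robust to length asymmetry), not an F-measure; and the
quality-F-measure tolerance defaults to 0.0075 x image diagonal, the
conventional boundary-benchmark setting.

Evaluation sweeps a grid of quality thresholds $t$: a detection is a true
positive at $t$ if its ground-truth quality reaches $t$ and it is the
best-scored such candidate for its fin (one per truth). The area under the
pooled precision–recall curve gives $\mathrm{AP}^t$, and the trapezoidal
mean over the grid the volume under the PR surface, which equals 1 exactly
when every fin is found perfectly and nothing else is returned. F-measures
use maximum bipartite matching between rasterised curves; rasterisation
produces thin 8-connected digital curves (Chebyshev stepping plus chain
thinning) so that a noisy polyline and a clean boundary trace have
comparable pixel densities — without this, one-to-one matching caps recall
at the density ratio.

## 3. Biometric encoding

A detected fin contour is resampled to 1024 vertices; an edge-refinement
hook (default: identity) may sharpen it against the image first. Keypoints
($\sigma = 2, m = 8$, up to 50) subdivide the contour into
$\binom{50}{2} = 1225$ subsections — the single arc between each unordered
keypoint pair — each resampled to 256 samples so that filter scales are
length-normalised. Reference images are encoded in both directions, query
images in one, so matching never compares direction flags.

Two descriptor types are computed at scales $S = \{1,2,4,8\}$:

* **DoG-norm**: the per-vertex $D(u,\sigma)$ with $m = 2$, L2-normalised —
  rotation- and translation-invariant by construction. Straight
  subsections give a zero response; they are flagged and excluded from
  matching rather than normalised.
* **Chord-aligned normals**: the subsection is rigidly moved so its
  start-to-end chord lies on the +x axis, smoothed at $\sigma$, and the
  unit normals' two components concatenated (512 values), L2-normalised.
  Chord alignment leaves a reflection ambiguity; it is resolved by
  requiring non-negative net turn (mirroring about the chord when needed).
  The literal formulation that concatenates the smoothed coordinates
  themselves is available behind `variant = "smoothed_coords"`; the
  unit-normal reading is the default because the descriptor is named for
  boundary normals and unit normals make its scale interpretation uniform
  across subsection lengths.

## 4. Identification

**LNBNN baseline.** For each query descriptor $d$ and individual $c$, with
$\delta(\cdot)$ the squared distance to the nearest reference descriptor,
the local match score is
$f(d,c) = \max\{0,\ \delta(NN_{\bar C}) - \delta(NN_c)\}$: evidence only
when $c$'s nearest reference beats the rest of the population. Scores are
summed per (descriptor type, scale) stratum and combined with equal
weights; the argmax is the predicted identity, ties broken by class id.
Nearest-neighbour search is exact dense matrix algebra; an approximate
index can be substituted behind the same catalog interface, but every test
pins the exact path.

**Fin space.** Descriptors are indexed by type, spatial extent and global
scale: the tip (coarse-curvature maximum, overridable by ground truth)
splits the contour into leading and trailing edges; each edge is divided
into 5 equal arc-length partitions; a subsection occupies a partition when
it covers strictly more than half of it, and its occupied set — a
contiguous run among the 55 possible runs of the 10 partitions — is its
spatial bin. The global filter scale $\sigma^g = \sigma / 256 \cdot p$
($p$ = subsection length as a fraction of the contour) falls into one of 5
scale bins, giving $2 \times 55 \times 5 = 550$ bins. Scale-bin edges are
never prescribed anywhere in the method's description, so the package uses
5 logarithmically spaced half-open intervals spanning the attainable
$\sigma^g$ range (descriptor scales are geometric); values at the range
ends are clamped into the outer bins. Descriptors that occupy no partition
are excluded from fin-space matching.

Instead of collapsing a query-class comparison to a scalar, each local
match score is added at the *matched reference's* bin, yielding a 550-long
scoring vector whose sum equals the LNBNN class score over the same binned
catalog (a conservation property the tests assert to 1e-9). A random
forest maps scoring vectors to the probability of "query is this
individual", trained with two-fold cross-validation split *by individual*
— folds partition individuals, never queries, so the learned
species-level distinctiveness pattern cannot memorise individuals.
Negative pairs are down-sampled to 5 per positive (seeded); the deployed
model is refit on all rows. Per-bin distinctiveness (the subsection-level
identification AP of each bin) is available for heat-mapping where on the
fin individuality concentrates.

Evaluation reports AP over all pooled (query, class) scores and mAP, the
unweighted mean of per-individual APs, which removes bias toward
frequently-sighted animals; AP is the area under the PR step curve with
tied scores collapsed into one threshold group, so results never depend on
row order.

## 5. The synthetic benchmark generator

The real photo-identification corpus for this problem is private, so the
package ships a seeded generator that emulates its statistical structure
rather than its pixels. Each individual draws once: a leading-edge bow, an
apex position and aspect ratio, 5–12 trailing-edge notches (positions
uniform, depths log-normal around 2% of fin height, widths 1.2–3% of the
edge), and a 12-harmonic roughness spectrum (frequencies 8–48 cycles along
the trailing edge, amplitudes $\propto f^{-3/4}$). The roughness term
matters: with notches alone, individual information would exist at a
single characteristic scale and the finest descriptor scale would be pure
noise — real trailing edges are serrated across scales, and the reported
per-scale identification results require the finest filter band to be
informative. Signatures are redrawn until pairwise RMS profile distances
clear a floor, so no two individuals are near-duplicates.

Sightings apply nuisances drawn per image from a preset: in-plane rotation,
scale, an out-of-plane shear proxy, smooth bending, per-vertex contour
jitter (re-smoothed at 1 px), waterline occlusion (cropping the lower
fraction of the fin, capped at 0.75 so at least a quarter of the trailing
edge stays visible), and splash speckle. The presets are `easy` (±5°,
≤10% occlusion, 0.1 px jitter), `standard` (±20°, scale 0.8–1.25, ≤45%
occlusion, 0.15 px jitter, splash) and `hard` (±40°, ≤75% occlusion,
0.5 px jitter). Rendered scenes place the fin (180 px tall at unit scale)
on a 480x640 canvas with an underwater body silhouette that merges with
the fin into a single region — by construction the fin is never a closed
region on its own, which is precisely the situation the contour-stroke
detector exists for. Ground truth (fin contour above the waterline, tip
position, region-hierarchy fixture with exact levels) is emitted with
every image, so segmentation-backend quality never gates identification
tests. The first sighting of each individual is the clean, unoccluded
reference (one-shot learning); the rest are queries.

What the generator does **not** emulate: photographic texture and colour
of real sharks and sea state (the appearance channel sees synthetic
shading only), calibration drift between cameras, misidentified labels,
and population-scale class imbalance. Passing benchmarks on this generator
demonstrates that the geometry pipeline — detection, encoding, matching,
fin-space learning — recovers individuality under controlled nuisances; it
does not certify field accuracy, and the real open-water problem (85
individuals, thousands of heterogeneous images) is substantially harder
than the 20-individual emulation, which the pipeline saturates.

## 6. Problem sizes and benchmark configuration

The standard benchmark runs (used by the acceptance tests and reported in
the README) are: identification on 20 individuals x 6 sightings (one
reference each, 100 queries), encoded with 12 fin keypoints — 66
subsections per direction — at all four scales; and detection on 50
standard-preset renders with emitted hierarchy fixtures. Twelve keypoints
rather than 50 keeps the descriptor count per image at desk scale while
preserving the combinatorial structure; the 50-keypoint/1225-subsection
encoding is exercised separately by the counting tests. The fin-space
classifier uses 300 trees in the benchmark (500 by default elsewhere).

## 7. Known limitations

* The fallback hierarchy builder is a stand-in honouring the adapter
  contract, not a state-of-the-art boundary detector; on real imagery a
  stronger backend should be plugged in.
* Edge refinement is an identity hook; fine trailing-edge detail below the
  segmentation's resolution is not recovered.
* The appearance dictionary is trained on synthetic renders in the test
  suite; for real data it must be retrained.
* `stroke_nms` and the bipartite F-measure are exact but quadratic in
  pixel counts; very long boundaries may warrant a coarser match
  tolerance or striding.
* Prominence of end-reaching peaks uses the zero-reference convention, so
  absolute prominences (not the selected maxima) shift if a constant is
  added to an open signal; corner responses are non-negative by
  construction, so this arises only in synthetic edge cases.
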