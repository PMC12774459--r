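---
title: "Quantifying epiretinal membrane and its association with retinal thickening"
author: "ermquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epiretinal membrane and its association with retinal thickening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ermquant)
```

## The problem

An epiretinal membrane (ERM) is a fibrocellular sheet on the inner retinal
surface whose traction thickens and distorts the retina. Spectral-domain OCT
(SD-OCT) images the retina as a raster of cross-sectional B-scans — here 25
horizontal and 25 vertical 768 × 496 pixel scans per eye — so the membrane is
only ever seen one slice at a time. A detector (for example a YOLO-family
model) marks the lateral span of the ERM on each B-scan as a bounding box.
`ermquant` takes those per-scan boxes and answers three clinical questions:

1. *Where is the membrane?* Each detection's lateral extent is projected onto
   the 496 × 496 en face frame and the projections are merged into a binary
   **epiretinal projection image (EPI)**.
2. *How big is it?* Pixel counts convert to physical area (μm²) and to the
   percentage of the en face frame covered.
3. *Is it what is thickening the retina?* The retinal thickness map is cut
   into nine severity classes over the clinically scrutinised 220–500 μm
   window, and a weighted cumulative intersection-over-union (IoU) score
   summarises how well the ERM colocates with the thickened retina.

A fourth module computes the observer-study statistics used to validate such
a pipeline against expert judgment (correlations, quadratic weighted κ,
ICC(2,1), Bland–Altman limits of agreement, and acceptability indices on a
5-point Likert scale).

## Projection model

A lateral B-scan coordinate maps linearly to the en face axis,

$$x_{\mathrm{enface}} = \frac{x_{\mathrm{Bscan}}}{W_{\mathrm{Bscan}}} \times W_{\mathrm{enface}},$$

with $W_{\mathrm{Bscan}} = 768$ and $W_{\mathrm{enface}} = 496$ by default;
vertical scans land on the y-axis instead. Each scan line owns a band of the
frame perpendicular to its direction. The acquisition geometry does not state
how tall a projected rectangle should be, so the package makes the one choice
that keeps union areas well defined and reproducible: band $k$ of $n$ spans
the half-open interval $[\lfloor kS \rfloor, \lfloor (k+1)S \rfloor)$ with
$S = 496/25 = 19.84$, tiling the frame exactly — no gaps, no overlaps. All
coordinates are 0-based and half-open throughout, so pixel counting is
unambiguous.

Discretization of the along-scan extent is conservative: floor at the start,
ceiling at the end, so a detection never loses sub-pixel extent. A snapping
tolerance of 10⁻⁹ pixels is applied before floor/ceiling so that coordinates
which are mathematically integral but inexact in binary (for instance
inverse-mapped synthetic detections, $x_e \cdot 768/496$) land back on their
integer. That tolerance is far below the precision of any detector output.

Detections below a confidence cutoff (default 0.25, configurable) are
dropped before projection; multiple boxes on one scan are all projected and
unioned. The EPI records per-pixel coverage counts alongside the binary
union, but all downstream quantities treat the ERM as a pixel *set*.

## Area and ratio conventions

The default calibration follows devices where 10 en face pixels span 200 μm:
20 μm per pixel edge, 400 μm² per pixel. Area is pixel count × 400 μm²; the
ratio is area over the full 496 × 496 frame. Ratios are **truncated**, not
rounded, to two decimals — the convention that matches device report output
(a raw 14.3697…% prints as 14.36%). The raw value is kept alongside the
truncated one in all JSON reports.

## Thickness discretization

Ophthalmologists concentrate on the 220–500 μm window of a thickness map.
That window is split into nine equal bands of 280/9 ≈ 31.11 μm. Class 1 is
the **thickest** band; the index grows as thickness falls. This direction is
the one that makes the severity weighting (below) decrease with the index.
Conventions at the edges:

* intervals are closed at their lower bound, open at their upper bound;
* 500 μm itself belongs to class 1;
* pixels below 220 μm or above 500 μm are left unassigned. Thickness above
  500 μm is clinically severe but outside the stated window, and no rule is
  given for it, so such pixels are excluded rather than silently clamped;
* unmeasured pixels (NA in CSV, 0 in the 16-bit TIFF encoding) never enter
  any class.

Class membership is computed against the same edge vector that
`classBounds()` reports, so a fixture placed exactly on an edge behaves
identically in both.

## The association score

For masks $A$ and $B$, $\mathrm{IoU}(A,B) = |A \cap B| / |A \cup B|$, defined
as 0 when both are empty. With $A_{\mathrm{ERM}}$ the EPI pixel set and
$A_j$ the class-$j$ thickness mask, the score is

$$\mathrm{ASS} = \frac{1}{9} \sum_{i=1}^{9} W_i \cdot
  \mathrm{IoU}\!\left(A_{\mathrm{ERM}}, \bigcup_{j \le i} A_j\right),
\qquad W_i = -0.01 i^2 - 0.07 i + 1.666 .$$

The cumulative union means the thickest retina participates in every term,
while thinner bands only dilute it progressively — the intended clinical
emphasis. The weights are used exactly as the quadratic states. Note that
$\sum_i W_i = 8.994$, not 1 (the quadratic is sometimes described as
normalised, but its printed coefficients are not), so the attainable maximum
is $8.994/9 = 0.99933\ldots$, reached exactly when the ERM coincides with a
lone class-1 region. The package does not renormalise — fidelity to the
stated formula wins — and every pipeline report carries the weight sum so
the convention is visible downstream.

```{r score-demo}
grid <- matrix(180, 496, 496)
grid[1:19, 101:300] <- 490 # a lone class-1 island
classes <- discretizeThickness(ThicknessMap(grid))
erm <- classMasks(classes)[[1]]
associationScore(erm, classes)
```

## Observer-study statistics

Ratings are a complete case × rater matrix of Likert scores in 1–5, with 4
("agree") the default acceptance threshold. Choices worth stating:

* **Quadratic weighted κ** uses weights $1 - (i-j)^2/(k-1)^2$ on the fixed
  five-category scale, expected agreement from marginal products; two raters
  stuck on the same single category give κ = 1 by convention.
* **ICC(2,1)** is the two-way random-effects, absolute-agreement,
  single-measure coefficient from the mean-squares decomposition; the 95% CI
  uses the standard F-distribution method with Satterthwaite degrees of
  freedom. An all-constant matrix is flagged as undefined rather than NaN.
* **Bland–Altman** differences are rater 1 − rater 2 (stated in the report
  metadata, since the sign is otherwise ambiguous); limits of agreement are
  mean ± 1.96 sd.
* **Acceptability**: AAS is the mean rating; AR the percentage of ratings at
  or above the threshold; NAS counts a rating ≤ 2 as a rejection and a
  neutral 3 as neither, so NAS ∈ [−1, 1]. Pooled AR is computed over *all*
  ratings rather than averaging per-rater percentages — the principled choice
  when raters could contribute unequal numbers, and the one consistent with
  pooling 25/30 and 26/30 acceptances into 85.0%.

## The synthetic generator

No patient data ship with the package; every pipeline stage is exercised on
synthetic scenarios with known ground truth. A `ScenarioSpec` defines an ERM
region *in en face coordinates* (rectangle or ellipse) which is
inverse-projected through the linear coordinate map into per-B-scan
detections — so the projection round-trip is exactly checkable, which real
data cannot offer. The thickness map is a smooth elliptic paraboloid blob,
`background + (peak − background) · max(0, 1 − d²)`, evaluated at pixel
centres, with optional seeded Gaussian noise.

Default conditions, chosen once to mirror a plausible single-eye study:

* geometry 768 × 496 B-scans, 25 + 25 scans, 496 × 496 en face frame, 20
  μm/pixel;
* ERM ellipse of 70 × 60 pixel radii (≈ 5.4% of the frame, inside the span
  of reported patient ratios of 6–47%);
* blob peaking at 480 μm over a 200 μm background. The background sits just
  below the 220 μm window on purpose: it makes the "thickened retina"
  region exactly the blob core, so a programmed ERM/thickening overlap
  fraction is meaningful and the full 0–1 overlap range is attainable
  inside the frame;
* rating model: case quality latent ~ N(4.48, 0.8), rater shifts (0, 0.03),
  per-rating noise sd 0.2, matching the scale and near-identical rater means
  of a 30-case two-expert acceptability study.

When `overlapTarget` is set, the ERM shape is translated along x by binary
search until the requested fraction of it lies on in-range thickened retina.
The generator emulates geometry and statistics, not OCT physics: no speckle,
no vasculature, no curved or multilayered membranes, and ERM regions are
convex. Passing tests therefore demonstrate correctness of the projection,
quantification and scoring arithmetic — not detector accuracy on real eyes.

## A full run

```{r pipeline}
dir <- file.path(tempdir(), "demo-eye")
sc <- simulateScenario(ScenarioSpec(seed = 7), dir)
res <- runPipeline(runConfig(
    detectionsPath = sc$paths$manifest, dialect = "json",
    thicknessPath = sc$paths$thicknessCsv,
    ratingsPath = sc$paths$ratings
))
res$area$ermAreaUm2
res$area$ermRatioPct
res$association@score
print(res$agreement)
```

## Numerical choices and test scale

* Band arithmetic uses integer division, so tiling is exact for any frame
  size and scan count.
* Ratio truncation applies a 10⁻⁶-of-a-cent rounding guard first, so a
  mathematically exact percentage never loses its last cent to binary
  representation.
* Oracle tests run projection against per-pixel brute force on hundreds of
  random small geometries (≤ 32 × 32 frames, ≤ 4 scans) and the association
  score against a naive reimplementation on hundreds of random ≤ 16 × 16
  mask sets; simulation-behaviour checks for the rating model average 100
  seeds of 30-case studies. These sizes make the full suite run in well
  under a minute while keeping the brute-force oracles genuinely
  exhaustive per case.

## Limitations

* Bounding boxes underestimate curved or folded membranes; a
  segmentation-refined extent is out of scope here.
* Projection fidelity is bounded by the inter-scan spacing (≈ 19.8 pixels ≈
  0.4 mm): anything between scan lines is interpolated by the band model.
* Decoding vendor colour-coded thickness images into μm values is not
  attempted; the package consumes numeric maps (CSV or 16-bit TIFF).
* Agreement metrics are implemented for the two-rater design; multi-rater
  generalisations of κ are not provided (ICC accepts any number of raters).
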