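---
title: "Global Ki-67 quantification: models, parameters and design notes"
author: "Ki67Global"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global Ki-67 quantification: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Ki67Global)
```

## The problem

Ki-67 is a nuclear protein expressed in proliferating cells; in canine mast
cell tumours (and many human cancers) its immunohistochemical signal is an
established prognostic marker. The traditional readout counts
Ki-67-positive cells by eye in a single small "hotspot" of fixed area
(0.3125 mm², dichotomised at 23 cells), which is fast but poorly
reproducible. This package implements the alternative *global* readout: the
entire tumour section is segmented, every nucleus inside a pathologist-drawn
region of interest (ROI) is detected and graded by DAB staining intensity,
and the slide is summarised by proliferation index, H-score and nuclear
densities, alongside an automated hotspot search for backwards
comparability. A cohort statistics layer (rank tests, Spearman correlation,
median-dichotomised Kaplan-Meier, univariable Cox) connects the imaging
metrics to grading and outcome data.

Because no image cohort ships with the package, a synthetic slide generator
with fully known ground truth is a first-class module: every stage of the
pipeline is tested against planted truth rather than against itself.

## Stain model

Brightfield H-DAB images are unmixed in optical-density (OD) space.
Transmitted intensity follows Beer-Lambert, so per channel

$$\mathrm{OD}_c = -\log_{10}\frac{I_c + 1}{I^{0}_c + 1},$$

with $I^{0}$ the white reference (default 255 per channel). The +1 offset
bounds the OD at pixel value 0 without special-casing; it costs at most
0.002 OD at white. Each pixel's OD 3-vector is decomposed by least squares
onto a stain basis (hematoxylin, DAB, residual); negative coefficients are
clamped to zero. The default basis is the Ruifrok–Johansen H-DAB pair with
the standard per-channel complement as residual; it is configurable because
scanners and staining protocols shift the true vectors. Per-slide adaptive
basis estimation is deliberately out of scope.

DAB amount is reported on a 0–255 *pseudo-intensity* scale,
$255\cdot10^{-\mathrm{OD}}$, where 255 is unstained white and OD 1 maps to
25.5 — the "dark brown" floor of the convention. The mapping is kept
real-valued until per-nucleus averaging. A linear alternative was rejected
because it cannot reproduce both published endpoints (255 white, ≈25 dark
brown) simultaneously.

## Nucleus detection and classification

The detector is a classical segmentation chain standing in for a
proprietary deep-learning application while honouring the same output
contract: combined nuclear OD (hematoxylin + DAB) → Gaussian smoothing
(σ = 0.5 µm) → threshold (OD 0.15) → hole filling → distance-transform
watershed to split touching nuclei → area filter (8–150 µm²). All four
parameters live in the pipeline configuration; the defaults were chosen
once for 0.23 µm/pixel scans and are documented rather than hidden. No
neoplastic/non-neoplastic discrimination is attempted: all nuclei in the
ROI are counted, which mirrors the workflow this package reimplements and
is the reason the quality rubric tracks inflammation.

The watershed is applied per connected component on cropped masks. This is
an implementation detail, not a semantic one: watershed basins of a
distance map never cross background, so the per-component result equals the
whole-image watershed at a fraction of the cost on large sections.

Each object's mean DAB pseudo-intensity is measured over its **central
25–75 % pixels**: pixels are ranked by Euclidean distance to the object
boundary and the middle half of the ranking is kept. The outermost quartile
carries edge artefacts and background bleed; the innermost quartile is also
dropped (chromatin-clearing highlights). The published description does not
state whether the central band is a distance annulus or an intensity trim;
the distance-rank reading was chosen because the stated purpose is edge
artefact suppression, which is a geometric notion. Objects of ≤ 4 pixels
are kept whole. Ties in distance rank are broken by pixel index, making the
selection deterministic.

Classification uses the published pseudo-intensity bands. Two printed
boundaries are ambiguous (120 appears in both weak and moderate, 170 in
weak and ">170" negative); the package uses one consistent
half-open-from-below convention honouring the strict inequalities that are
printed for strong and negative:

| class    | band            |
|----------|-----------------|
| strong   | [0, 70)         |
| moderate | [70, 120)       |
| weak     | [120, 170]      |
| negative | (170, 255]      |

A separately published calibration sentence (mean nuclear values 89/65/39
for weak/moderate/strong) is inconsistent with these bands (89 falls in
moderate, 65 in strong); the bands are treated as normative and the
calibration means are not implemented.

## ROI handling

Annotations are GeoJSON FeatureCollections of pixel-space polygons with a
`role` property (`tumour` / `exclusion`, the latter optionally categorised
as adnexa, vessel, adipose, lymphoid, artefact or ulcer). Coordinates are
0-based, x rightward, y downward. Rasterisation uses the even-odd rule
evaluated at pixel centers; tumour polygons are unioned, exclusions are
unioned and subtracted (so nested or overlapping exclusions subtract
exactly once), and the assessed area is the true-pixel count times the
squared pixel pitch. Self-intersecting rings are rejected by name.
A nucleus belongs to the ROI iff the mask is true at the pixel containing
its centroid — a deliberate decision (the source workflow does not state
how boundary-straddling nuclei were counted); the centroid rule is
order-independent and matches per-mm² count semantics.

## Slide metrics and quality rubric

With class counts $n_{neg}, n_w, n_m, n_s$ over assessed nuclei:

* proliferation index $PI = 100\,(n_w+n_m+n_s)/n_{tot}$,
* H-score $= 1\cdot\%w + 2\cdot\%m + 3\cdot\%s$ with percentages over
  *all* assessed nuclei (range 0–300, so $PI \le H \le 3\,PI$ always),
* positive and strong densities are counts per mm² of assessed tissue.

An empty slide (no assessed nuclei) yields PI = H = 0 with a warning
rather than an error, so degenerate ROIs do not abort a batch. Exported
TSV rows round PI, H and densities to one decimal (a repository
convention; the source workflow states no rounding rule).

The quality rubric scores three axes 0–2: tissue completeness (2 above
90 % assessable, 1 for 50–90 %, 0 below 50 %), inflammation (2 below 1 %,
1 for 1–10 %, 0 above 10 %) and segmentation (same bands on the fraction
of unlabelled nuclei). Boundary fractions (exactly 1 %, 10 %, 50 %, 90 %)
belong to the middle score because the outer categories are printed with
strict inequalities.

## Hotspot analysis

The hotspot is the axis-aligned square window of area 0.3125 mm² (side
559.02 µm) maximising the count of positive-nucleus centroids, with the
half-open membership rule $x\in[x_0, x_0+s)$, $y\in[y_0, y_0+s)$. Only the
*area* is fixed by the manual convention; the square shape is this
package's choice (the literature is explicitly confused about the original
geometry). For half-open windows a maximiser always exists among windows
anchored at nucleus coordinates, so the search over those anchors (plus an
optional stride grid) is exact; an independent brute-force enumeration is
the test oracle. Ties are broken by the lexicographically smallest
$(y_0, x_0)$. The Webster dichotomisation calls ≤ 23 positives "low" and
> 23 "high"; hotspot density is count / 0.3125.

The **proliferation factor** relates the hotspot to the whole section. The
published description is self-contradictory about orientation ("ratio of
global to hotspot density" yet "twice … as high in the hotspot"); the
package computes hotspot density / global *strong* density, so factors
≥ 1 match the narrative direction. Strong-only density is the global
comparator because weak/moderate staining is frequently non-neoplastic.
A zero strong density flags the factor as undefined (NA) rather than
raising.

## Synthetic slides: what is emulated, and what is not

`generateSlide()` composites images in OD space: white background, one
disk per nucleus carrying hematoxylin OD (uniform 0.45–0.65) plus the DAB
OD corresponding to its planted pseudo-intensity. Design choices:

* **Exact class quotas** by largest-remainder apportionment instead of
  multinomial draws, so planted counts are sharp test oracles.
* **Default quotas (0.86, 0.06, 0.04, 0.04)** reproduce the cohort-level
  means the pipeline is meant to operate around: planted PI 14 % and
  H-score 26.
* **Intensity bands strictly inside the classification bands**
  (strong [30, 60], moderate [80, 110], weak [130, 160], negative
  [185, 245]) so the planted class is recoverable; the `SlideSpec`
  validity method enforces this.
* **Nucleus radii 4–6 µm** (8–12 µm diameter). The 4 µm floor is the
  geometric condition under which the blur-dilated segmentation rim stays
  outside the central 25–75 % distance band: with σ = 0.5 µm smoothing and
  an OD threshold at 0.15 of a strong-nucleus plateau, the mask dilates by
  ≈ 2.7 px, and the central band of a disk of radius $R$ only clears that
  rim when $R \gtrsim 6.5$ times the dilation — i.e. $R \ge 4$ µm at
  0.23 µm/px. Below that, rim pixels (pseudo-intensity 255) would leak
  into the central mean and break plant/recover closure.
* **Per-pixel texture dithering**: each disk's DAB OD varies per pixel by
  ± 1.5 pseudo-intensity units around the planted mean. Without it, 8-bit
  quantisation is a *systematic* per-nucleus bias of up to ≈ 2.7 units;
  with it, quantisation averages out of the central mean, which the
  generator contract then guarantees to ± 2 units.
* **Non-overlap by rejection sampling** (grid-hashed, 2 µm edge-to-edge
  separation, 100 retries per nucleus, largest-first placement order);
  failure raises an error naming the density limit rather than silently
  thinning.
* **Inflammation stand-ins**: granulocyte-like extra nuclei of radius
  2.8–3.4 µm with weak-band intensities and an `inflammatory` flag
  (granulocytes mostly stain weakly or not at all); the default fraction
  is 5 % of all nuclei, a "mild" (score 1) slide. They count as assessed
  weak nuclei, exactly as a non-discriminating detector would see them.
* **One private random stream per slide** seeded from the `SlideSpec`; the
  caller's RNG state is untouched and identical specs are bit-identical.

`plantHotspot()` adds a guaranteed-maximal positive cluster inside one
window and verifies, on the planted truth, that no disjoint window ties it.
`generateCohort()` plants a proportional-hazards structure: a standard
normal Ki-67 metric, exponential survival with hazard
$h_0\exp(\beta\,\mathrm{metric})$ and administrative censoring, so a true
hazard ratio of $e^\beta$ per metric unit is known exactly.

What the generator does **not** emulate: real chromatin texture, stain
gradients and scanner noise; nuclear pleomorphism and touching/overlapping
clusters beyond the deliberate watershed cases; ulceration morphology; and
genuinely ambiguous tumour boundaries. Passing the plant/recover suites
therefore demonstrates that the pipeline's arithmetic and geometry are
correct and self-consistent — not that the default detector parameters are
optimal on real, messy tissue, where the deep-learning detector this one
stands in for would be expected to outperform it.

## Cohort statistics

* Two-group comparisons use the Wilcoxon rank-sum test: full enumeration
  of all group assignments when both groups have ≤ 8 observations (valid
  under ties through average ranks, conditioning on the observed tie
  pattern), otherwise the tie-corrected normal approximation. Three groups
  use Kruskal–Wallis. p-values are two-sided.
* Spearman correlation uses average ranks; constant inputs flag rho as
  undefined instead of returning a number.
* Cox regressions are univariable with Efron tie handling (survival times
  have day granularity, so ties are expected), Wald 95 % intervals, and
  two censoring rules — all deaths as events, or tumour-related deaths
  only — because the survival data this layer consumes report both
  conventions and the source analysis does not say which one fed the
  published models. The default is all-deaths (overall survival).
* Kaplan–Meier curves dichotomise each metric at its median; values equal
  to the median go to the *low* group so "Ki-67-high" means strictly above
  the median. Degenerate splits are flagged, not fatal.
* Integer percentages round half away from zero; signed fold changes
  after inflammation exclusion report max/min of the two means to two
  decimals, negative when the excluded-subset mean is lower.
* No multiple-testing correction is applied by default (the p-values are
  exploratory by design); Benjamini–Hochberg is available as `adjustP()`.

## Problem sizes used by the test suite

The plant/recover property runs ten slides of 5,000 nuclei each at
0.23 µm/pixel on 5600² px sections (1.66 mm², ≈ 3,200 nuclei/mm²) — large
enough that apportionment, packing, segmentation and classification are
all exercised at realistic density, while a full suite completes on a
single CPU in well under half an hour. The hotspot search is verified
against brute force on fifty random slides of up to 500 positives; Cox
recovery uses 200 replicates of n = 200 cohorts with a planted hazard
ratio of 2. These sizes are the package's own trade-off between statistical
sharpness and turnaround.

## Known limitations

* The classical detector is a contract-equivalent stand-in, not a clone,
  of the commercial deep-learning detector; absolute counts on real tissue
  will differ even where the synthetic suites are exact.
* Stain vectors are fixed per run; slides with atypical staining would
  need a manually supplied basis.
* The hotspot window is square; published manual hotspots may have used
  other shapes of the same area.
* Grading systems, signalment and follow-up are consumed as tabular
  labels; nothing in the package re-derives them.
* Whole-slide pyramids are not streamed; images are processed as single
  in-memory tiles (desk-scale sections).
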