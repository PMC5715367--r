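---
title: "Methods: plate-based seedling phenotyping for abiotic-stress screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate-based seedling phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Reverse-genetic stress screens sow dozens of *Arabidopsis thaliana*
T-DNA insertion lines on agar plates, stress them (high salt, arsenate,
freezing, phosphate limitation), photograph every plate, and ask for
each line whether its seedlings respond differently from wild-type
(Col-0). At the scale of a hundred lines and tens of thousands of
seedlings, manual scoring is impractical and subjective; the pipeline in
this package replaces it with rule-based segmentation, per-seedling
morpho-colorimetric profiles, clustering-based state calls and a
statistical screen with false-discovery-rate control.

The pipeline has three stages (per assay):

1. **image analysis** — segment each plate photograph into "digital
   plants" (the pixel set of one seedling) using assay-specific pixel
   rules and object filters;
2. **data mining** — reduce each digital plant to features: eight
   morpho-colorimetric descriptors, a hue-class colour profile, and
   assay-specific phenotype proxies (yellowing fraction for freezing,
   merged-plant major axis for phosphate);
3. **statistics** — call seedling states by clustering colour profiles,
   test each line against wild-type (Fisher's exact test on state
   counts, or one-way ANOVA on the root-length proxy), adjust p-values
   with Benjamini–Hochberg, and triage genes on the adjusted results.

# Segmentation rules

All colour thresholds operate on 8-bit channels. Hue, saturation and
brightness (HSB) are rescaled to integers in `[0, 255]`; printed
thresholds such as 49, 74 or 138 are interpreted on that scale (they
exceed 100, so they cannot be percentages). All comparisons are strict,
exactly as configured; interval filters are closed at their endpoints.

| assay | modality | foreground rule | object filter |
|---|---|---|---|
| salt | VIS | `S > 49` (stress) / `S > 74` (standard), gray in `[0,140] ∪ [150,255]` | area > 40 px, dist < 130 px |
| salt | FLUO | `S > 20` | area > 20 px |
| arsenic | VIS | `R < 254 & G < 246 & B < 254` | area > 10, circ > 0.099, dist < 130 |
| arsenic | FLUO | `S > 50` | area > 20 px |
| freezing | VIS | `B < 127 & (R−B)/(R+B) > 0.20` | 10000 < area < 40000 px |
| phosphate (root) | VIS | local mean threshold (r = 15, offset 10) | area > 109, circ < 0.70, dist < 145 |
| phosphate (shoot) | VIS | `23 < Bri < 138` | area > 10, circ > 0.099, dist < 130 |

Grayscale is the unweighted channel mean by default (Rec. 601 luma
optional); the salt gray-band filter excludes the mid-gray band
141–149 that belongs to the embossed plate grid. The freezing rule uses
the normalised red–blue difference, a vegetation index that exploits the
low blue reflectance of leaf tissue; note that it mathematically
requires `R > B`, i.e. a hue strictly below 120°.

Foreground masks are partitioned into connected components with a
compiled flood-fill labeler (8-connectivity by default, the convention
of contour-tracing labelers; 4-connectivity available). Component
labels are assigned in raster-scan order, which fixes all downstream
tie-breaks.

On vertical phosphate plates the embossed grid is removed from the
local-threshold mask before object extraction: horizontal foreground
runs longer than 50 px and vertical runs longer than 240 px are
cleared by run-length scanning (the most literal and exactly testable
reading of "lines longer than N px removed"), one pass of 3×3 binary
erosion strips halo pixels, and the top/bottom border bands
(rows 50–260 and 1698–1798, 0-based inclusive) are blanked. The shoot
mask is then subtracted from the root mask before labeling: the dark
shoot also falls below the local mean, and without the subtraction it
fuses with its root into a single object whose topmost pixel lies above
the shoot centroid, defeating the shoot-anchored merge below.

`local_mean_threshold()` itself defaults to radius 15 px and offset 0;
the phosphate assay config raises the offset to 10 intensity levels
(the camera noise floor) so that background texture cannot percolate
into foreground.

# Digital plants and features

Per grid cell, only the largest surviving component is kept (ties go to
the lowest label), so each seedling is represented by exactly one
object. On phosphate plates, each shoot is paired with at most one root
in the same grid column — the candidate whose topmost pixel is nearest
below the shoot centroid — and the merged pixel set is the digital
plant; shoots without roots stay shoot-only, orphan roots are dropped.

The eight features:

* **area** — pixel count;
* **perimeter** — polygonal length of the Moore-traced outer contour
  (axis steps 1, diagonal steps √2; holes ignored; for a disconnected
  merged plant, the contour of its topmost part);
* **circularity** — `4πA/P²`, the normalised isoperimetric ratio (disk
  = 1, elongated → 0). The raw ratio `P²/A` is also emitted. The
  normalised form is the only one under which the configured root cut
  ("circularity lower than 0.70" for elongated roots) is meaningful;
* **compactness** — `A/P`;
* **major/minor axis** — full axis lengths `4√λ` of the equivalent
  ellipse from the second central moments of the pixel set (the axis
  about which the body is easiest to rotate). Each pixel contributes
  its own unit-square moment (`+1/12`), so the minor axis is strictly
  positive even for one-pixel-wide objects and a 20×10 rectangle has
  eccentricity exactly 2;
* **eccentricity** — major/minor, always ≥ 1;
* **hisgreypeak** — the modal grayscale intensity of the plant pixels
  (lowest value on ties).

Under the moment convention, a uniform rod of drawn length `L` has
major axis `4L/√12 ≈ 1.155 L`; the phosphate "root length" is therefore
a *proxy* on a consistent scale, not a ruler measurement — which is all
the line-versus-wild-type ANOVA needs.

Colour profiles divide the hue channel into `K` classes
(`floor(H·K/256)`; K = 16 for salt/arsenic, 32 for freezing) and record
the per-class pixel fractions, which sum to 1 per modality. Achromatic
pixels carry hue 0 and are counted (an exclusion flag exists). For
salt/arsenic the VIS and FLUO profiles are concatenated into a joined
32-vector; a seedling missed in one modality keeps a zero-filled,
flagged half so all vectors have equal length. The freezing damage
index is the fraction of pixels in the five lowest of 32 hue classes —
hue in `[0, 40)`, the red-through-yellow tones of bleached tissue; a
seedling is "damaged" iff that fraction strictly exceeds 0.5.

# Statistics

**State calls.** Records of one condition are clustered on the
Euclidean distance matrix of their joined colour profiles
(agglomerative, average linkage by default) and the tree is cut into
exactly two groups; the group with more mass in the green hue band
(hue 64–128, i.e. 90°–180°) is labeled alive (salt) or germinated
(arsenic). This automates what a manual scorer would do by eye. If all
profiles are identical the clustering is degenerate and no test is run.

**Line tests.** Fisher's exact test (two-sided, by summing
hypergeometric probabilities not exceeding that of the observed table,
with a 1e-7 relative tie tolerance) compares each line's 2×2 state
counts against wild-type; the phosphate assay uses the classical
two-group one-way ANOVA on the major-axis proxy instead, because root
length is quantitative. Within each condition, p-values are adjusted
across all tested lines by the Benjamini–Hochberg step-up procedure,
and a line has a phenotype iff its adjusted p-value is below 0.05.

**Multi-trait view.** Plants are z-scored on the eight features within
a condition (constant features dropped with a warning), clustered with
Ward linkage, and the tree is cut into five groups C1–C5 (the count is
a presentation convention; the cut level is the tree's 5-cluster
level). Each line is summarised by its density over the five groups
(rows sum to 1) and lines are clustered on those densities with average
linkage, giving the dendrogram-plus-heatmap view in which lines with
similar multi-trait phenotypes sit together.

# Gene-level triage

Lines map to genes (loci); triage aggregates line results per gene.

* **Categories.** A decision tree assigns each gene with at least one
  significant line: ≥ 2 distinct lines significant in the *same* stress
  → Category 6; else ≥ 2 alleles significant somewhere → Category 5;
  else significant in > 1 condition → Category 3; else Category 1.
  Multi-condition and multi-allele states are also reported as flags
  (Categories 2 and 4 of the flowchart). Bench-side allele-suitability
  knowledge can override the tree per gene via metadata; the bundled
  screen summary contains two such rows, which the package carries as
  printed metadata rather than silently forcing the tree.
* **Stringent filter.** A gene has a strong, stress-specific response
  iff some stress has ≥ 2 distinct significant lines *and* the minimum
  adjusted p-value within that stress is below 0.01. Freezing runs from
  different years count as one stress for both clauses.
* **Reports.** Stringent passers go to the multi-line summary table;
  genes with exactly one usable line and any significance go to the
  single-line candidate table. On the bundled screen summary the
  worked-example counts (25 stringent passers; 12 genes strong in ≥ 2
  stresses; 0 single-line passers) are recomputed by the test suite and
  the acceptance script.

# The synthetic-plate generator

Real screen images are not distributable, so every stage is validated
on generated plates with known ground truth. The generator emulates the
screen's designs: 6×6-grid square plates with 36 seedlings per plate
and 3 replicates (salt, arsenic), round plates with 60 large seedlings
and 3 replicates (freezing), and vertical 6-seed plates with 2
replicates (phosphate); one line per plate, 1800×1800 px images (the
phosphate border bands at rows 1698–1798 must exist to be exercised).

Backgrounds are constructed to produce zero foreground under the
matching rules: achromatic agar for salt (saturation 0), near-white
backlight for arsenic (`R ≥ 254` everywhere), a pale achromatic field
for freezing, and a bright backlit field with embossed grid lines for
phosphate. Tissue is sampled per pixel in HSB and converted to RGB:

* alive rosettes: hue ~ N(85, 8) (green, 120°), saturation ~ N(190, 25);
* dead/bleached tissue: hue ~ N(22, 6) (yellow-brown);
* seeds: hue ~ N(15, 5) on small ellipses (brown);
* fluorescence: hue ~ N(5, 3), high saturation, for alive/germinated
  seedlings only — dead tissue does not fluoresce, which is exactly the
  signal the joined profile clustering uses;
* freezing green tissue: hue ~ N(68, 5) truncated to [56, 76] with
  saturation ≥ 200. The lower hue band is deliberate: the red–blue
  index rule requires `R > B`, which no hue at or above 120° can
  satisfy; real leaves reflect markedly more red than blue, and the
  rendering follows that reflectance asymmetry;
* phosphate: a dark shoot blob (brightness 60–130, inside the shoot
  band) and a wavy 5-px-wide root polyline of Gaussian-drawn vertical
  extent (default 250 ± 25 px), rendered pale gray (142–168) — backlit
  roots transmit light — so roots are found by the local threshold but
  stay out of the shoot band. The sine wobble (amplitude 8 px, period
  110 px) keeps every per-column run under the 240-px vertical-line
  limit, as real curved roots do. The 250-px default was chosen from
  the moment geometry (shoot disk + rod) so the wild-type proxy lands
  on the screen's reference scale of ≈ 345 px.

Freezing damage is rendered as a contiguous yellow angular sector
covering a sampled fraction of the rosette (0.55–0.95 for damaged
seedlings, 0.02–0.35 for undamaged), so the true damage fraction is
known exactly per seedling. Per-line effects are binary survival /
germination / heavy-damage probabilities and the Gaussian root length;
wild-type defaults are the screen's reference levels (66% salt
survival, 64% arsenic germination, 50% freezing damage).

Each plate draws from its own RNG stream seeded from the experiment
seed and the plate index, so plates are reproducible individually and
experiments are bit-identical for a fixed seed. `generate_experiment()`
also computes, per line, the *expected* significance call by running
the assay's test on the true states — the oracle the image pipeline is
compared against end-to-end.

The phosphate generator embosses full-height vertical grid lines (the
merge's column reference) but places horizontal embossed lines only in
the top/bottom border bands that the cleanup step blanks anyway. A
mid-plate horizontal line would slice each root into several objects,
whereas the merge contract pairs one root per shoot; horizontal-run
removal is exercised by the border lines and by dedicated unit
fixtures.

# Numerical choices and degenerate inputs

* All printed comparisons strict; boundary values excluded.
* Component labels, and hence all tie-breaks (largest-per-cell,
  contour start pixel), follow raster-scan order.
* `hisgreypeak` ties resolve to the lowest intensity.
* Plants with < 4 pixels are flagged degenerate, never an error;
  perimeter may be 0, making circularity/compactness `NA`.
* Fisher tables with a zero margin return p = 1 with a warning; ANOVA
  with zero within-group variance returns p = 1 for identical constant
  groups and p = 0 with a degeneracy flag otherwise.
* The BH family is all lines of one condition run.
* Hue of achromatic pixels is 0; they are counted in histograms unless
  excluded.
* The layout's `dist_centers` lets distance filters measure to the
  embossed fine grid on phosphate plates (where roots span several grid
  cells) while cell assignment always uses the seed positions.

# Problem sizes in the test suite

Unit tests run on small plates (500–900 px) where geometry allows;
study-condition plates (1800×1800, 36/60/6 seedlings) are used for the
per-assay recovery checks, a three-replicate wild-type salt run
(n = 108) for clustering agreement, and count-level simulations (200
null lines; 100 seeded effect screens at survival 0.15 vs 0.65,
n = 108) for screen calibration. These sizes keep the full suite and
the acceptance script within a few minutes on one CPU while preserving
the screen's per-line sample sizes where they matter statistically.

# Limitations

The generator validates the pipeline's logic, not its robustness to
photographic reality: there is no occlusion or touching of neighbouring
seedlings, no condensation, reflections, uneven illumination or colour
cast, and tissue hue distributions are cleanly separated. Passing
synthetic tests therefore shows that the rules, features, clustering
and statistics are implemented correctly and recover known truth under
the stated imaging model — not that the printed thresholds would
segment any particular camera's images. Thresholds are configuration,
not constants, for exactly that reason. The blind manual re-scoring
used to validate the original screen is out of scope; its 90%-agreement
standard is retained as the property bar for the clustering tests.
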