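---
title: "Quantifying the foveal microvasculature on en-face OCTA: methods and design"
author: "octaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the foveal microvasculature on en-face OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaquant)
```

## The measurement problem

Optical coherence tomography angiography (OCTA) renders the perfused
retinal capillaries of a 3 x 3 mm macular field as an en-face grayscale
image, here 232 x 232 pixels (12.93 µm/px), separately for the
superficial (SCP) and deep (DCP) capillary plexus. In sickle cell
disease the deep plexus rarefies early: the foveal avascular zone (FAZ)
enlarges, branch points thin out, and perfused density falls. The
package implements the quantitative chain used to measure those
changes — pre-smoothing, binarization, skeletonization, FAZ
delineation — plus the group statistics, and pairs it with a synthetic
angiogram generator that supplies ground-truthed inputs, since patient
scans for this kind of study are not publicly deposited.

Four per-eye, per-plexus metrics are produced:

* **FAZ area** (mm²): primary outcome; manual polygon tracings are
  first-class inputs (`polygon_area_mm2()`, `read_faz_annotations()`),
  and an automated flood-fill stand-in (`segment_faz()`) substitutes on
  synthetic data.
* **Branching-point density** (junctions/mm²): merged skeleton
  junctions over the full 9 mm² field.
* **Total vessel length** (mm): skeleton path length.
* **Vessel density** (0-1): foreground fraction of the binarized
  image over the whole scan.

## The two binarization routes

The measurement chain deliberately keeps two parallel binarization
routes, mirroring the two toolchains such studies use:

1. **Global route** (ImageJ-style): Gaussian pre-smoothing at sigma
   1 px, then the IsoData iterative-intermeans threshold
   (`global_threshold()`). The skeleton metrics (branch points, total
   length) and the automated FAZ segmentation run on this mask: a
   global threshold separates the vessel class from the background
   floor, which is what skeleton topology needs.
2. **Local route** (adaptive): the Bradley-variant rule — a pixel is
   vessel iff its intensity strictly exceeds `(1 - c)` times the mean
   of the window centered on it — with `c = 0.3` on a 0-1 scale and
   the window side derived from the image size as
   `T = 2 (size / 16) + 1` (`window_size()`, 30 at size 232, odd-adjusted
   to 31 because a centered window needs a middle pixel; the raw
   formula value is available with `adjust = FALSE`). Vessel density is
   the literal foreground fraction of this mask.

The local rule has a structural property worth stating plainly: in a
window of constant positive intensity, `I = mu > mu (1 - c)`, so
featureless bright regions classify as foreground wholesale. On real
en-face angiograms, whose background carries a diffuse signal floor,
this inflates the adaptive-route vessel density — consistent with
published SCP densities near 0.8 that are implausible as a raw
perfused-area fraction. The package reports the literal fraction and
leaves the interpretation to the analyst. The windowed means use an
integral image over 16-bit-quantized intensities, so the fast path is
bit-identical to a brute-force windowed mean (the tests assert this).

Intensities are always normalized by the dtype maximum, never by the
per-image maximum, so thresholds are comparable across eyes. Borders
are replicate-padded for local means and reflected for the Gaussian;
both choices avoid dark-frame artifacts next to the image edge.

## Skeleton metrics

`skeletonize()` is Zhang-Suen two-subiteration thinning: 8-connected,
unit width, component-preserving. `classify_pixels()` classifies by
crossing number — the count of distinct branches leaving a pixel,
measured as 0-to-1 transitions around its 8-neighbour ring — rather
than by the raw neighbour count, which misreads staircase pixels on
shallow diagonals as junctions. Adjacent junction pixels are merged
into one junction (8-connected clustering), mimicking how standard
skeleton analyzers count branch points rather than junction voxels.

`total_length()` sums adjacent skeleton pairs at 1 (orthogonal) or
sqrt(2) (diagonal) pixel units, excluding diagonal pairs that share an
orthogonal skeleton neighbour: such a pair is a shortcut across a
right-angle corner, and charging it alongside the two orthogonal steps
would overstate length at every corner (about +27% on realistic
meshes). Thinning has a slight directional bias, so skeleton length is
reproducible under rotation only to a fraction of a percent; counts
(junctions, endpoints, density) are exactly invariant.

## FAZ measurement

Manual tracings (the reference method) enter as CSV vertex lists in mm
and are evaluated with the shoelace formula after a
simple-polygon check. The automated stand-in closes the vessel mask
with a disk (default radius 4 px, ~52 µm — larger than inter-capillary
gaps, far below the FAZ scale), flood-fills the background
4-connectedly from the image center (or a supplied seed), and converts
the pixel count at `(scale/1000)^2` mm² per pixel. The closing radius
is the one tunable that matters: area is non-increasing in it, and the
default was chosen once from the gap-vs-FAZ scale argument above. A
degenerate result (region = whole image, e.g. an empty mask) is
returned flagged, not silently.

Reproducibility of repeated measurements is summarized with the
intraclass correlation for two measures: two-way random effects,
consistency, average of k = 2 (`icc_consistency()`), i.e.
`ICC(C,2) = (MS_subjects - MS_error) / MS_subjects`. Consistency ICC
ignores a constant offset between raters by construction.

## The synthetic angiogram generator

`grow_network()` builds a ground-truthed planar capillary network in a
parameterized field (`plexus_params()`): a border chain and a planted
perifoveal arcade ring (a closed polygon whose chords stay tangent to
the avascular disk, so no segment enters the FAZ interior and the
avascular area is bounded by vessels at exactly the planted radius),
then space-colonization growth toward uniformly sampled attractors.
Growth enforces three geometric disciplines so that the ground truth
remains *measurable* at raster scale:

* **branch clearance**: a new tip keeps about (mean width + 2.5 px) of
  distance from all structure except its parent, so distinct branches
  do not fuse into spurious raster junctions;
* **branch-point separation**: two branch points closer than about
  `0.7 / sqrt(target density)` mm would merge into one blob after
  smoothing and thresholding, so branching is spaced;
* **twig pruning with regrowth**: side branches shorter than three
  segments are invisible to the smoothing + thresholding chain, so
  they are pruned from the truth; growth then resumes (with chains
  extending past the target so young branches mature) until the pruned
  junction count stands.

Because capillary plexuses are looped meshes, a loop-closing
(anastomosis) phase connects nearby low-degree nodes — directly or
T-wise into a split segment — until the degree-3 node count reaches
`target density x (field area - FAZ area)`; each connection adds a
junction pair without crowding the field. For junction targets near
the packing limit of resolvable branch points (the SCP preset at
95/mm²), a random mesh saturates short of the target, and the
generator instead builds a perturbed honeycomb trimmed down to the
target by deleting scattered walls — the open-cell geometry that both
admits such densities and resembles a dense superficial plexus en
face. An infeasible target (cells narrower than the vessels) fails
explicitly.

`rasterize()` draws each segment at its stated width: the boolean
ground-truth mask contains every pixel whose center lies within half
a width of the segment, and the grayscale image renders a pixel at
full brightness once it is at least half covered, with a linear
anti-aliased falloff — en-face flow signal saturates, and a plain
coverage ramp would leave sub-pixel capillaries below threshold after
sigma-1 smoothing. `add_noise()` applies, in order, a point-spread
Gaussian blur (default sigma 0.7 px), multiplicative speckle
`pixel (1 + noise_level * N(0,1))` (default 0.15), an additive
background haze (default 0.15, the diffuse signal floor of en-face
angiograms), and a clip to [0, 1]. With zero noise, blur and haze the
image passes through unchanged. All generator outputs are pure
functions of the parameters and one integer seed; per-eye seeds are
derived deterministically from the cohort master seed.

Preset defaults follow the two plexus morphologies: SCP — wider
vessels (2-4 px), 95 junctions/mm², FAZ radius 0.37 mm (~0.43 mm²);
DCP — fine vessels (1-2 px), 30 junctions/mm², FAZ radius 0.45 mm
(~0.64 mm²). FAZ-area and branching-density scales match the published
group means these presets emulate.

What the generator does **not** emulate: projection and motion
artifacts, vessel-caliber pulsatility, signal falloff with depth,
segmentation (slab) errors, and the correlated speckle texture of real
OCTA. Passing recovery tests on synthetic eyes therefore demonstrates
that the measurement chain is internally consistent against known
truth under this noise model — not that it is unbiased on device
images.

```{r one-eye, eval = FALSE}
pp <- plexus_params("DCP", seed = 1)
sim <- simulate_enface(pp)           # network + clean/degraded images
metrics <- process_enface(sim$image) # smooth, both thresholds, skeleton, FAZ
metrics
sim$network$true_junction_count / 9  # generating truth, per mm2
```

## The cohort simulator and reporting layer

`cohort_spec()` holds per-genotype-group (HbSS, HbSC, control) eye
counts and per-plexus generating distributions for FAZ area, branching
density and vessel density, plus Goldberg-stage distributions, central
retinal thickness, and qualitative lesion-flag probabilities. The
defaults reproduce the published cohort structure: 27/19/16 eyes, deep
FAZ means 0.84/0.86/0.57 mm² (SD 0.30/0.28/0.09), stage distributions
from the demographic table, and lesion rates such as 20/27 and 16/19
rarefied-capillary eyes. `make_cohort()` draws per-eye truths
(truncated normals) and, when `render = TRUE`, simulates both plexus
images per eye; `render = FALSE` supplies records only, which is what
the statistical simulation harness uses.

`process_cohort()` measures every rendered eye; `compare_groups()`
builds one comparison row per metric and plexus — per-group
descriptives (mean, n-1 SD, range, median) plus the three pairwise
Mann-Whitney contrasts (each disease group vs control, disease vs
disease) with a significance flag at p < 0.05 and no multiplicity
correction, mirroring the analysis style this replicates (the report
records how many tests were run). `stage_distribution()`,
`mean_stage()`, `qualitative_summary()` and `by_stage()` reproduce the
demographic, lesion and per-stage table structures;
`crossfoot_check()` verifies counts against totals and surfaces
printed-vs-implied mean-stage conflicts as warnings rather than
forcing either value. Eyes, not patients, are the statistical unit,
as in the tables this mirrors; inter-eye correlation is ignored and
this is a known limitation.

## Statistics

All tests are authored in the package and validated in the test suite
against independent oracles (full enumeration, `wilcox.test`,
`kruskal.test`, `aov`):

* `mann_whitney_u()`: midranks; exact two-sided p by full enumeration
  when n + m <= 14 and tie-free, else the normal approximation with
  tie-corrected variance and 0.5 continuity correction. Two-sided
  throughout.
* `kruskal_wallis()`: tie-corrected H, chi-square reference with g - 1
  degrees of freedom; identical values give H = 0, p = 1 rather than
  an error.
* `icc_consistency()`: two-way ANOVA without interaction, average-
  measures consistency; undefined (and an explicit error) at zero
  between-subject variance.
* `describe()`: mean, n-1 SD, range, median, n; the single-value SD is
  reported as 0 and flagged.

## Numerical choices and degenerate inputs

* Window sizes are forced odd (round half-up, bump even values by
  one, floor 3); the formula's printed value at size 232 is even, so
  the implementation uses 31 and keeps the raw value accessible.
* Bradley comparisons are strict (`>`): zero-signal flat windows stay
  background; the 16-bit quantization grid makes the integral image
  exact.
* IsoData iterates from the image mean on a 256-bin histogram and
  refuses constant images with an explicit error.
* Flood fill refuses a seed that lands on a vessel after closing, with
  guidance to supply one; two seeds in one cavity give identical
  regions.
* Empty masks: empty skeleton, zero length, zero density; degenerate
  FAZ flagged.
* The generator declares an unreachable junction target explicitly
  (accepting a realized count down to 85% of target, the documented
  ±15% construction tolerance) rather than returning a short network.

## Problem sizes used by the validation suite

The test suite validates parameter recovery on 20 seeded eyes per
plexus preset at noise 0.15 (median absolute relative errors must stay
within 15% for branching density, 10% for total length, 5% for FAZ
area), Mann-Whitney operating characteristics on 2,000 null
simulations at the published group sizes, the planted deep-FAZ group
effect on 100 simulated cohorts, and ICC reproducibility on 50
replicates of 27 eyes — sizes chosen so the whole suite runs in a few
minutes on one core while keeping Monte-Carlo error well inside the
asserted margins.

## Known limitations

* Synthetic speckle is i.i.d. Gaussian and multiplicative; real OCTA
  speckle is spatially correlated and signal-dependent.
* The honeycomb path used for packing-limit junction densities is
  quasi-regular; its cell-size dispersion is narrower than a real
  superficial plexus.
* Skeleton length inherits the small directional bias of Zhang-Suen
  thinning (sub-percent under rotation).
* The adaptive-route vessel density is a literal foreground fraction
  with the flat-region property discussed above; cross-study
  comparability of that number depends on background signal levels.
* Eyes are treated as independent; repeated eyes per patient are not
  modelled.
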