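---
title: "Methods: whole-organ islet and innervation quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-organ islet and innervation quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`islet3d` quantifies multi-channel 3D volumes of cleared pancreas: an
insulin channel marking β cells, a pan-neuronal or pathway-specific channel
(NF200, TH, VAChT) marking fibers and intrapancreatic ganglia, and
optionally glucagon marking α cells. This vignette records the model behind
each operator, the parameters that matter, what the synthetic phantoms do
and do not emulate, and the numerical choices a maintainer would want
written down.

## Conventions

Arrays are `(z, y, x)`; all physical quantities are µm and µm³; densities
per mm³ use 1 mm³ = 10⁹ µm³. Magnification tags carry the acquisition
pitches: 5×5×5 µm at 1.3×, 1.63×1.63×5 µm (xy, z) at 4×,
0.602×0.602×2 µm at 12×, 1.67×1.67×5 µm for confocal 10×. Voxel centers sit
at `(i − 0.5) · pitch`; all distances are voxel-center to voxel-center, so
discretization error is bounded by one voxel pitch. I/O is 32-bit-float
TIFF with an OME-XML companion carrying pitches and channel names; embedded
OME descriptions are honoured on read.

## Surface-style segmentation

Commercial "surface" detection exposes two dials: a *smoothing factor*
(surface detail grain) and a *threshold factor* for local-contrast
background subtraction. We realize them as explicit image operators:

1. Gaussian pre-smoothing with full width at half maximum equal to the
   smoothing factor, per axis in physical units (islets: 10 µm at 1.3×,
   3.25 µm at 4×; nerves: 3.25 µm).
2. A baseline estimated by Gaussian blur with standard deviation equal to
   half the threshold factor — structures wider than the stated diameter
   are suppressed, matching the documented intent of local contrast.
   Islets use the largest expected islet diameter (default 250 µm, a
   per-dataset setting because the original workflow set it per sample);
   nerves use 12.2 µm; ganglion detection uses 150 µm so that ~30 µm cell
   body clusters survive subtraction intact.
3. Subtraction, clamped at zero, then thresholding. The default is Otsu's
   between-class-variance maximum on a 256-bin histogram; an absolute
   threshold can be supplied. Because genuine structures occupy well under
   1 % of these volumes, a plain Otsu split can land inside the noise bulk
   on noisy input; the automatic threshold is therefore floored at
   `noise_floor_k` (default 4.5) robust standard deviations of the
   subtracted image, estimated as 1.4826 × MAD on a deterministic strided
   subsample of ≤ 2²⁰ voxels *before* clamping. The floor is exactly inert
   on noise-free data.
4. 3D connected components (default 26-connectivity — filamentous
   structures fragment under 6-connectivity) with a minimum object volume
   (islets 250 µm³ ≈ one β cell, nerves 100 µm³; speck suppression).
   Objects touching the volume border are flagged and included by default.

Conservation (Σ object voxel counts = foreground voxel count before the
minimum-volume filter) and threshold monotonicity are asserted in tests.

For sympathetic (TH) staining, occasional TH⁺ β cells are excluded by a
codified rule replacing the original manual curation: remove a nerve object
iff its volume is below 120 µm³, the majority of its voxels lie inside an
insulin⁺ islet, and it overlaps insulin foreground by at least one voxel.
The filter can, by construction, never remove an object at or above
120 µm³ nor one outside islets.

## Distance geometry

`distance_field()` computes the exact Euclidean distance transform with
anisotropic spacing by the separable lower-envelope (parabola) algorithm on
squared distances; it is tested against an exhaustive all-pairs oracle on
every grid up to 16³.

An islet is **innervated** iff its minimum distance to nerve foreground is
0, i.e. islet and nerve share a voxel ("touching"); face adjacency without
overlap yields one voxel pitch. Because autonomic neurotransmission acts
over 1–2 µm, a secondary **near-nerve** cutoff (< 1.6 µm, about one xy
voxel at 4×) is computed side by side — at 5 µm pitch the two coincide,
at 4× they differ, and both are reported because the classification used
for figure-level counts is ambiguous between them.

**Ganglia** were delineated manually in the original workflow; here an
NF200⁺ component is classified as a ganglion when its volume lies in
[20,000, 400,000] µm³ and its voxelized sphericity
`π^{1/3}(6V)^{2/3}/A ≥ 0.4` (a voxelized surface overestimates the true
area ~1.5×, so an ideal ball scores ≈ 0.67 and tubes score far lower; both
bounds are configurable), with an escape hatch for externally supplied
ganglion label grids. Density is count per mm³ of tissue; per-ganglion
distance is the minimum over its voxels of the islet distance field.

**Cell contacts** at high resolution: cells are thresholded, then split by
a depth-map watershed — seeds are 26-neighbourhood maxima of the distance
to background, pruned to a minimum separation of 8 µm (approximately one
endocrine cell diameter), and foreground voxels are assigned to their
geodesically nearest seed (multi-source Dijkstra with anisotropic edge
weights). Adjacent cells that cannot be split count as one, mirroring the
acknowledged limitation of the original analysis. A cell contacts a nerve
iff it shares a voxel with nerve foreground; contacts per cell are
deliberately not counted.

## Summary metrics and statistics

Per region (whole volume, duodenal, splenic — the anatomical split is a
sidecar mask, since real pancreata are divided before imaging):
β-cell volume percent, islets/mm³, mean/median islet volume, the
closed-open volume bins [0, 10³), [10³, 5·10⁴), [5·10⁴, 5·10⁵), [5·10⁵, ∞)
µm³, normalized insulin intensity (mean intensity over islet voxels divided
by a reference — the whole-tissue mean by default, or an explicit control
reference for cross-group comparisons), endocrine nerve density
(nerve∩islet / islet volume) versus exocrine nerve density (nerve outside
islets / non-islet tissue), the innervated/non-innervated comparison
(mean-volume ratio and innervated share of summed islet volume), and
equivalent sphere diameter `d = 2(3V/4π)^{1/3}` (1,000 µm³ ↦ 12 µm,
500,000 µm³ ↦ 98 µm). Endocrine plus exocrine nerve volume must equal total
nerve volume; bin percentages must sum to 100 — both are asserted at run
time.

Group comparisons follow a normality gate: Shapiro-Wilk per group at
α = 0.05; all normal → unpaired two-tailed Student t (2 groups) or one-way
ANOVA with Tukey HSD (≥ 3); otherwise Mann-Whitney (exact where possible)
or Kruskal-Wallis with Dunn's post hoc (rank-sum z with tie correction,
Bonferroni family adjustment — implemented here because no installed
package provides it, and cross-checked against the omnibus Kruskal-Wallis).
"Unpaired two-way t test" in the source methods is read as the standard
unpaired two-tailed Student t test. Median 95 % CIs use the exact binomial
order-statistic construction. Correlations are Pearson when both margins
pass the gate, Spearman otherwise. No correction is applied across metrics,
only within post-hoc families. Per-sample (per-animal) tables are the
default statistical unit; pooled per-islet records can be passed instead,
and which one is used is visible in the emitted tables.

## The synthetic phantom

The phantom is a statistical emulation, not an anatomical simulation:
islets are random ellipsoids, nerves are capsule-swept polylines, ganglia
are ellipsoids, cells are spheres. That is sufficient to exercise every
operator and to carry known ground truth; it does not reproduce real islet
shapes, fiber branching topology, staining gradients, immune infiltration,
or vasculature, so passing recovery tests demonstrates correctness of the
measurement chain, not performance on real microscopes' artifacts.

Default geometry is 512×512×128 voxels at 5 µm (the 1.3× pitch), an
elliptical-cylinder tissue slab (~2.6 mm³, ~62 % of the box) split into
duodenal/splenic halves. This size keeps a full simulate→segment→quantify
cycle under ~2 minutes on one CPU while holding ~100 islets and ~50
ganglia. Calibration anchors of the `mouse_c57_default` preset (other
presets override them; values are the published whole-pancreas study
conditions):

| parameter | value |
|---|---|
| β-cell volume fraction | 1.31 % of tissue |
| islet volume bin weights | 3.13 / 39.29 / 36.58 / 20.0 % (renormalized — the printed values sum to 99) |
| innervated islet fraction (count) | 6.1 % |
| innervated share of islet volume | 43 % |
| endocrine:exocrine nerve density ratio | 7 generative (published condition: > 6; capsule end-caps at polyline joints erode the realized ratio slightly) |
| ganglion density / mean volume / islet gap | 21.5 mm⁻³ / 83,467 µm³ / 47.3 µm |
| β-cell (α-cell) contact fraction | 9.4 % (45 %) |
| nerve tube radius | 2–3.5 µm |
| intensities (bg / islet / nerve) | 100 / 1000 / 800 |
| noise | Poisson(scale 1) then Gaussian σ 15, optional |

Mechanics worth recording:

- **Volume mixture.** One truncated lognormal component per volume bin
  (log-mean at the bin's log-midpoint, log-sd a quarter of the bin's
  log-width, support 300 µm³ — about one β cell — to 8.18·10⁶ µm³, the
  volume of the default largest-islet diameter). Mixture weights equal the
  bin targets, so expected bin occupancy reproduces them exactly; this is
  the deterministic calibration routine, with closed-form truncated
  moments used for count planning.
- **Hitting the total volume.** Volumes are drawn sequentially until the
  target total (fraction × tissue) is crossed; the last islet is shrunk to
  land exactly, or dropped if that would leave a sub-minimal fragment.
  Without this the heavy upper tail makes the realized β-volume fraction
  fluctuate by ±20 % at ~100 islets.
- **Two-population innervation calibration.** With count fraction `f` and
  volume share `s`, `k = max(1, floor(f·n))` islets are selected by a
  size-biased draw refined by deterministic swap search toward the share
  target; hitting both implies a mean-volume ratio
  `r = s(1−f)/(f(1−s)) ≈ 11.6`. The floor (rather than nearest) rounding is
  deliberate: count granularity at ~100 islets plus partial detection of
  sub-resolution islets inflate the realized count fraction, and
  conservative rounding keeps the implied ratio safely on the
  order-of-magnitude side reported for innervated islets.
- **Nerve routing.** Innervated islets receive straight fiber chords
  through their interior (guaranteeing voxel contact), each verified to
  stay ≥ 20 µm clear of every *other* islet so non-designated islets are
  never touched — after segmentation dilates boundaries by a voxel, the
  margin still holds. Exocrine fibers are tortuous random polylines with
  the same clearance; their total volume is budgeted from the configured
  endocrine:exocrine density ratio. Three straight chords per innervated
  islet is the default — real per-islet nerve volume distributions are not
  published, so the simplest geometry that yields enough intra-islet volume
  to budget against was chosen once (configurable down to a single tube).
- **Ganglia** are placed just outside a randomly chosen anchor islet of at
  least 2,000 µm³ (anchoring next to sub-voxel insulin specks would tie
  the distance metric to objects segmentation cannot resolve), at a
  surface gap drawn from a gamma distribution (mean 47.3, sd 20 µm,
  minimum 8 µm), with rejection against islet, ganglion and boundary
  overlap. Ganglia are rendered in a dedicated channel: under the nerve
  preset's 12.2 µm background window a ~30 µm blob is hollowed to a shell,
  which would corrupt both ganglion volumes and exocrine fiber volumes if
  the two object classes shared a channel. On real data, where they do
  share the pan-neuronal channel, `detect_ganglia()` runs the same
  classification on that channel.
- **Cell mode** renders a single islet at confocal 10× pitch
  (32×120×120 voxels): spheres of diameter 8 µm packed by dart throwing at
  8.8 µm minimum separation (cells stay individually resolvable; the
  sub-voxel gaps mirror partially separable real cells), a designated
  fraction per type receives an in-plane nerve terminal threading from the
  cell interior outward, clipped so it never enters another cell, with the
  terminal's z snapped to a voxel plane so a thin capsule always crosses
  voxel centers. Truth contact flags are recomputed from the rasterized
  grids, so the truth table is voxel-exact by construction.
- **Determinism.** One `set.seed()` at generation; identical config + seed
  give bit-identical volumes. Truth tables are recomputed from the truth
  label grids, never from the analytic specs.

Diabetic presets scale these anchors: `nod_diabetic` keeps 10 % of the
nondiabetic β volume with a small-islet-shifted mixture and farther,
slightly smaller ganglia; `stz_d15` keeps 40 % of control with ~30 % smaller
ganglia; `stz_d5` is the intermediate time point (60 %, a chosen value —
the day-5 fraction is not printed); human presets use mid-range donor
β fractions, much sparser innervated islets and larger ganglia. Where a
preset parameter has no published value, the choice is stated here and in
`phantom_preset()`, made once, and not revisited.

## Numerical choices

- Gaussian blur uses an exact truncated kernel (3σ) for σ ≤ 4 voxels and
  three variance-matched iterated box filters above; the switch keeps the
  250 µm background window at ~2 s per channel on the default grid versus
  minutes for the direct kernel, with deviation a fraction of a percent of
  the dynamic range at the crossover. Boundary handling is reflection
  (kernel) / replication (box).
- Otsu uses 256 bins with double-precision accumulators; constant input
  returns the constant so a strict `>` yields an empty mask (uniform
  volumes segment to nothing by construction).
- Connected-component labeling is an iterative flood fill (explicit stack);
  label statistics (counts, intensity sums, minima, centroids, exposed-face
  surface areas, border flags) are single-pass compiled accumulators.
- The watershed is seeded region growth by geodesic distance, not gradient
  flooding — adequate for convex cells and deterministic.
- Empty nerve masks yield `NA` distances (undefined, never an infinite
  sentinel) with `innervated = FALSE`; empty islet tables yield zero-islet
  summaries with `NA` medians rather than errors.
- Ties in the swap-refinement and watershed seed pruning are broken by
  deterministic ordering under the run seed.

## Problem sizes

The default test and acceptance protocol uses: one reference run and five
pooled runs at 512×512×128 (5 µm), the 10,000-draw size sampler, and five
cell-mode phantoms (~380–400 β cells each, ~1,900 pooled). These sizes were
chosen so that each phantom experiment completes in well under five minutes
on a single CPU and the whole suite in well under half an hour.

## Known limitations

- Measured distances are voxel-center based; at 5 µm pitch an islet one
  voxel away from a fiber reports 5 µm, not its meshed surface distance.
- Otsu-with-floor is a global threshold; strong staining gradients in real
  data would need per-region absolute thresholds (supported but manual).
- The phantom's nerve tree has no branching hierarchy or varicosities, and
  its intensity model is two-level; intensity-based metrics on phantoms
  (normalized insulin intensity, NF200 intensity per islet volume) exercise
  bookkeeping, not biology.
- Islets nested in animals are pooled, as in the source analyses; no
  mixed-effects modeling.
- Counts of contacts per endocrine cell are out of scope by design.
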