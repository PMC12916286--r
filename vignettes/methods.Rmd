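---
title: "Measurement models and design choices in neuroquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models and design choices in neuroquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroquant)
```

# Scope

neuroquant quantifies fluorescence-derived phenotypes of cultured
neurons: per-image pathology metrics from multi-channel
immunofluorescence (C9orf72 intensity, TDP-43 cytosol-to-nucleus ratio,
p62/SQSTM1 vesicles, γH2A.X DNA-damage foci, repeat-RNA FISH foci),
nuclear morphometry with micronucleus detection, dendritic-spine
classification on calibrated 3D stacks, ΔF/F0 calcium responses, and the
statistics ladder used to compare experimental groups. Every operator is
deterministic, takes calibrated inputs (µm per pixel is mandatory — none
of the µm-denominated gates can be applied without it), and is validated
against synthetic fixtures with known ground truth.

# Image primitives

**Thresholding.** All automatic thresholds (Li minimum cross-entropy,
Otsu between-class variance, Rényi entropy, Kapur max-entropy) operate on
the image's native dynamic range quantized to 256 bins, reproducing the
`histogram = 256` convention of interactive image analysis. The method
returns the last background bin; foreground is strictly above every
background intensity. The Rényi criterion is implemented as single-order
entropy-sum maximization with order α = 2 (α → 1 recovers the
max-entropy criterion); interactive tools combine several orders through
an ad hoc weighting that we deliberately avoid because it is neither
published with the recipes nor needed for their behavior. Degenerate
(constant) images raise an error rather than returning an arbitrary
split. For masked recipes (p62 vesicles, γH2A.X foci) the histogram is
computed over the remaining signal — the pixels inside the mask — since
"thresholding the remaining signal" is the operation the recipes
describe; including the zeroed exterior would let an arbitrarily large
empty area dictate the threshold.

**Connectivity and particle gates.** Foreground components use
8-connectivity and holes 4-connectivity (the common interactive default);
labeling is implemented in compiled code. "Radius" of an irregular
particle means its equivalent-circle radius `sqrt(area/π)`. Removal
comparisons are strict (`<`, a particle exactly at the gate survives)
except where a recipe says "≤ 5 µm", which is exposed as
`inclusive = TRUE`. Hole filling fills only enclosed background up to the
stated ceiling; border-touching background is never a hole. Both
operations are idempotent and monotone (removal never adds foreground,
filling never removes it), and these properties are tested.

**Region measurement.** Areas are pixel counts times the squared
calibration — exactly, so that area totals are conserved across
relabelings. Ellipse axes come from the second-moment (covariance)
ellipse with a 1/12 unit-square pixel correction, which keeps single-pixel
objects well-defined; eccentricity is `sqrt(a² − b²)/a`. On rasterized
ellipses with ≥ 100 px major axis the eccentricity error is below 2% (in
practice below 0.5%).

**Nuclear preprocessing.** The DAPI enhancement chain is unsharp mask
(Gaussian radius 1 px, weight 0.60), CLAHE (tile 127 px, 256 bins, clip
slope 3) and a median filter (radius 3 px), in that order. CLAHE is the
standard tile-interpolated variant: per-tile histograms are clipped at
the slope limit, the excess is redistributed, and pixels are mapped
through bilinearly interpolated tile CDFs. One recipe quotes a CLAHE
maximum of 3.10 rather than 3; both appear verbatim as the defaults of
their respective recipes and are exposed as parameters rather than
unified, since there is no principled way to decide which the instrument
operator "meant". A flat field passes through the whole chain unchanged.

# Pathology recipes

Each assay is a fixed operator chain; thresholds chosen at run time and
all normalizing areas are recorded in a qc block.

* **C9orf72**: MAP2 mask (Li → remove < 2 µm² → fill holes ≤ 4 µm²),
  nuclear mask (Otsu → remove radius < 5 µm); metric = summed C9orf72
  signal over the union of both masks, divided by the MAP2-positive area.
* **TDP-43**: MAP2 mask (CLAHE 3.10 → Otsu → remove radius < 5 µm → fill
  holes ≤ 4 µm² → watershed), nuclei (Rényi → fill holes), nuclei
  retained iff their centroid lies inside the MAP2 mask (the recipes say
  only "nuclei of MAP2-positive cells"; the centroid rule is our
  concrete reading). The ratio divides the cytosolic intensity density
  `(S_cell − S_nuc)/(A_cell − A_nuc)` by the nuclear density
  `S_nuc/A_nuc`. It is invariant under global scaling of the TDP-43
  channel; zero cytosolic signal gives 0; missing cytosolic area or zero
  nuclear signal are errors.
* **p62**: MAP2 mask (Li → remove radius ≤ 5 µm → watershed); vesicles
  from the Rényi threshold of the in-mask p62 signal, admitted in the
  0.01–1 µm² window; metrics are count per MAP2 area, mean vesicle area
  and mean integrated density.
* **γH2A.X**: nuclear mask from the preprocessing chain (binarized with
  Otsu — the recipe says only "converted to binary" — then radius < 5 µm
  removal), total nuclear area over regions ≥ 1.5 µm²; signal outside
  the mask is removed; foci from the max-entropy threshold of the
  remaining signal, area > 10⁻⁵ µm²; metrics are sum intensity and focus
  count per nuclear area and mean focus area.
* **RNA FISH**: nuclei via the Otsu + ≥ 5 µm chain (the sturdiest of the
  three nuclear recipes; none is stated for FISH), puncta via
  max-entropy with a 0.05–2 µm² admission window (a configuration
  default — no window is published), assigned to the nucleus containing
  the punctum centroid, so a focus straddling a boundary is counted
  once. `foci_summary` reports the percentage of foci-positive nuclei
  and the mean and range over positive nuclei only; 297 positive among
  1767 gives 16.8%.

When a recipe's mask chain yields zero objects the recipe raises a
stage-tagged error rather than scoring the image as zero, mirroring how
such images are excluded (not averaged in) during manual analysis.

# Nuclear morphometry

`segment_nuclei` is a classical chain (preprocess → Otsu → debris removal
→ watershed). Learned segmenters can be substituted by passing their
label raster through `labels=`; the probability/overlap parameters of
such tools are recorded in provenance for parity but do not steer the
classical chain. The debris-removal radius defaults to 0.5 µm so that
micronuclei (well below primary-nucleus size) survive segmentation.

Micronuclei are objects of at most 20 µm² whose boundary lies within
10 µm of a larger object; the nearest such object becomes the parent.
Both numbers are configuration defaults — there is no accepted
quantitative definition — and per-image counts are reported with
per-nucleus detail available in the record table.

`kmeans_area_split` implements exact 1-D 2-means: the optimal 2-partition
of sorted reals is contiguous, so scanning the n − 1 split points finds
the global within-cluster-SS optimum. We chose this over Lloyd's
iteration (with min/max initialization) because exactness makes the
order-invariance and optimality properties provable and testable; for
two clusters in one dimension the exact scan is also cheaper. Identical
values raise a "degenerate clustering" error.

# Spine morphometry

The classifier is the standard three-way decision tree: a neck exists
iff the head/neck diameter ratio is at least 1.1; a necked spine with
head ≥ 0.35 µm is a mushroom; otherwise a length/head ratio ≥ 2.5 makes
it thin; otherwise stubby. All comparisons use ≥, so geometries exactly
at a boundary take the "larger" class; the tree is verified against an
independent rule-table implementation over a dense grid (~16,000 points)
including every boundary.

The volumetric detector deliberately simplifies commercial ray-casting
measurement: the stack is binarized (Otsu), the largest 26-connected
component is the dendrite, the shaft axis comes from the principal
components of the voxel cloud, and the centerline/radius are per-slab
medians refined by two trimmed passes (large protrusions would otherwise
bias their slab's center). Protrusions are clusters of voxels beyond the
shaft surface plus a margin; their cross-sections are radial shells,
whose diameter is measured as the extent along the shaft direction — the
best-sampled axis, important because axial (z) sampling is ~6× coarser
than lateral. Head = widest shell of the distal third; neck = narrowest
shell between base and head, reported only when the neck rule holds.
Admission enforces heights 0.2–5.0 µm and width ≤ 3 µm. The voxel-count
gates quoted with the original settings (max stubby 10 voxels, min
non-stubby 5 voxels at voxel size 0.066 × 0.066 × 0.390 µm) have
tool-internal semantics that are not published; we apply the only
reading that keeps all three classes reachable — a protrusion smaller
than the non-stubby floor is classified stubby outright, and the stubby
ceiling is recorded in parameters/provenance without binding the
volumetric path (a realistic stubby spine already exceeds it). The
"attach ratio" and "discretization ratio" dendrite settings likewise
have no defined meaning outside their original tool and are carried in
configuration for provenance only.

The spine generator plants class-prototypical geometries (e.g. mushroom:
head 0.6 µm, neck 0.25 µm, length 1.5 µm; stubby: 0.45/—/0.7; thin:
0.2/0.15/1.2) at the reference voxel size, protruding laterally where
sampling is finest. On such stacks detection recall and precision are
1.0 and every class is recovered; that validates the measurement logic,
not performance on noisy in-vivo-like morphology (curved dendrites,
overlapping spines and z-oriented protrusions are out of scope).

# Calcium

ΔF/F0 = (F − F0)/F0 pointwise, with F0 the mean fluorescence over the
baseline window; the default window is the 30 s preceding the first
stimulus ("resting conditions"). Amplitudes are window maxima of ΔF/F0
within 30 s of each onset — the stimuli are 2-s applications separated by
2-min washouts, so with decay constants ≤ ~15 s the windows are
independent (cross-talk < 5%, tested). Cells are gated by their KCl
response (neuron iff peak ΔF/F0 ≥ 0.1 — KCl depolarizes neurons but not
glia) after an ionomycin viability gate (non-viable iff peak < 0.2 —
ionomycin floods any intact cell with calcium). Both thresholds are
configuration defaults; none are published. Group summaries are means ±
SEM over classified neurons only. Because per-batch counts and per-cell
counts are both legitimate units of analysis in such experiments, the
profile table retains per-cell rows so either summary can be formed.

# Statistics ladder

Shapiro-Wilk within each group gates parametric vs nonparametric
branches at α = 0.05; groups smaller than 3 or degenerate force the
nonparametric branch with a warning. Two groups: Student's t (equal
variances, the convention of the source software) or Mann-Whitney U.
More than two: one-way ANOVA with Tukey's HSD or Šidák-adjusted pairwise
t tests (both exposed; the choice between them is the analyst's, as no
rule is published), or Kruskal-Wallis with Dunn's test on the pooled
ranking (tie-corrected, Bonferroni-adjusted — the common convention when
no adjustment is named). Grouped two-factor designs use two-way ANOVA
with Tukey. The chi-square test is Pearson's without continuity
correction. Reports annotate significance at 0.05/0.01/0.001/0.0001.

The outlier screen approximates the proprietary ROUT procedure with
reproducible components: robust standardization by median and
normal-consistent MAD, two-sided normal tail p-values, and
Benjamini-Hochberg flagging at the stated Q (default 1%). The output
labels itself as this approximation. On clean normal samples (n = 50) it
flags at most one point in ≥ 95% of seeds; a gross outlier (value 100
among 1–10) is always flagged.

# Synthetic fixtures: what they emulate, and what they do not

`gen_if_image` draws anti-aliased somata (disks), nuclei (rotated
ellipses with semi-axes 5–7.5 µm, giving ~95–140 µm² areas), optional
micronuclei, and an assay channel per plan, on a 512 × 512 frame at
0.1 µm/px by default — sized so every µm-denominated gate in the recipes
is non-trivially exercised. Planted objects are pairwise separated; a
manifest records every object. Determinism is a contract: the seed fully
determines the output, and the caller's RNG state is restored.

The noise model is Poisson shot noise (calibrated so the requested SNR
holds at the brightest planted intensity) plus optional Gaussian read
noise, followed by a Gaussian smoothing of σ = 0.9 px representing the
effective point-spread function of processed microscope output —
detector noise in processed confocal or widefield data is spatially
correlated, not per-pixel speckle. p62 fixtures use 0.05 µm/px: the
0.01 µm² vesicle-admission floor can only act as a noise filter when the
pixel area is below it, so coarser sampling would contradict the recipe
it exercises.

Two systematic limits of threshold-based measurement are worth stating
because the fixtures expose them. First, entropy-based thresholds sit
just above the background mode, so object areas include the partial-
coverage rim; noise-free this adds a few percent (tests allow 10%), but
at SNR 5 the PSF-widened rim inflates threshold-defined *size* metrics
by ~40–50% even though counts, sum intensities and intensity ratios
remain accurate — counts are recovered exactly or within 10% at SNR 5,
and those are what the recovery guarantees cover. Second, the constant
background enters both compartments of the TDP-43 ratio, biasing it
toward 1 by a few percent at the default background level; recovery is
within 10% noise-free and within 20% at SNR 5 across planted ratios
0.25–2. Passing fixtures therefore demonstrates correctness of the
operator chains and their gates, not robustness to un-modeled realities
of patient-derived images (uneven illumination, autofluorescence,
overlapping cells, chromatin texture).

Problem sizes used by the test-suite and the acceptance script — 20
noise-free plus 8 noisy TDP-43 fixtures, 3 fixtures per counting assay
and condition, a ~16,000-point classifier grid, 33 exhaustive 2-means
instances, 1000 null ANOVA replicates at n = 10 per group — were chosen
as the smallest sets that still pin each guarantee down; all complete in
about a minute.

# Known limitations

* Segmentation is classical; heavily touching or textured nuclei are
  better served by a learned segmenter, whose labels can be passed into
  `segment_nuclei(labels = )` without losing the downstream morphometry.
* The spine detector assumes a single, roughly straight dendrite per
  stack and laterally protruding spines; it does not trace branch points
  or track spines over time.
* Threshold-defined size metrics inherit the rim systematics described
  above; comparisons between groups processed identically remain valid,
  absolute sizes should be interpreted with the threshold in view (it is
  recorded in every qc block).
* The ROUT approximation matches the intent (FDR-controlled outlier
  flagging) but not the exact robust-regression internals of the
  original.
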