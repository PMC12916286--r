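# neuroquant

Quantification of fluorescence imaging and live-recording assays in
cultured (iPSC-derived) neurons. The package re-implements, as tested and
reusable R functions, the image- and signal-derived measurements used to
characterize frontotemporal-dementia neuron models: neuropathology
readouts from multi-channel immunofluorescence, nuclear morphometry,
dendritic-spine classification from 3D stacks, calcium transient
responses, and the accompanying statistics ladder. Every stage is
validated end to end on synthetic fixtures with known ground truth, so no
proprietary imaging software or patient data is required.

## Who it is for

Cell biologists and image analysts who quantify neurodegeneration
phenotypes in neuronal cultures — TDP-43 mislocalization, p62/SQSTM1
vesicle changes, DNA-damage foci, repeat-RNA foci, nuclear shape change,
spine loss, and blunted stimulus responses — and want those recipes as
scripted, deterministic functions instead of interactive Fiji sessions.

## What it computes

**Image primitives** (`auto_threshold`, `remove_small_by_radius`,
`fill_holes_max_area`, `watershed_split`, `measure_regions`,
`preprocess_nuclear`): calibrated masks and region measurements. All
physical gates are specified in µm/µm² and converted through the mandatory
pixel calibration. Thresholds (Li, Otsu, Rényi entropy, max-entropy) are
computed on 256-bin histograms of the native dynamic range.

**Pathology recipes** (`c9orf72_intensity`, `tdp43_cyto_nuclear_ratio`,
`p62_vesicle_metrics`, `gh2ax_metrics`, `rna_foci_per_nucleus`,
`foci_summary`): fixed operator chains per assay. The central TDP-43
statistic is the per-image cytosol-to-nucleus ratio

    ratio = [ (S_cell − S_nuc) / (A_cell − A_nuc) ] / [ S_nuc / A_nuc ]

with S the summed TDP-43 fluorescence and A the area of the MAP2-positive
cell-body and retained-nuclei compartments (a nucleus is retained iff its
centroid lies in the MAP2 mask).

**Nuclear morphometry** (`segment_nuclei`, `eccentricity_of`,
`detect_micronuclei`, `kmeans_area_split`): eccentricity
`sqrt(a² − b²)/a` from second-moment ellipse axes, micronucleus flagging
by size and proximity, and the exact two-group 1-D K-means split of
per-image mean nuclear areas.

**Spine morphometry** (`detect_spines`, `classify_spine`,
`spine_summary`): protrusion detection on voxel-calibrated 3D stacks and
the mushroom/stubby/thin decision tree at the standard thresholds
(head/neck ratio ≥ 1.1, length/head ratio ≥ 2.5, mushroom head ≥ 0.35 µm,
heights 0.2–5 µm, width ≤ 3 µm).

**Calcium** (`compute_dff`, `stimulus_amplitudes`, `classify_cell`,
`group_summary`): ΔF/F0 = (F − F0)/F0 on 1-Hz traces, per-stimulus peak
amplitudes, KCl-based neuron/glia gating and ionomycin-based viability
gating, group means ± SEM.

**Statistics** (`normality_gate`, `compare_groups`, `chi_square`,
`rout_outliers`): Shapiro-Wilk-gated test selection (t-test/ANOVA + Tukey
or Šidák vs Mann-Whitney/Kruskal-Wallis + Dunn), Pearson chi-square, and a
robust median/MAD + FDR outlier screen.

**Synthetic data** (`gen_if_image`, `gen_spine_stack`,
`gen_calcium_traces`, `gen_group_measurements`): seeded ground-truth
generators for all of the above, with manifests recording every planted
object.

## Worked example

Simulate a confocal field with a planted cytosol:nucleus TDP-43 ratio of
0.5, then run the full quantification recipe:

```r
library(neuroquant)
fx <- gen_if_image(seed = 42, assay = list(type = "tdp43", cyto_ratio = 0.5))
r  <- tdp43_cyto_nuclear_ratio(fx$map2, fx$dapi, fx$assay, image_id = "demo")
r
#> <assay_result> tdp43_ratio  image=demo
#>   cyto_nuclear_ratio           0.516618
```

The recipe recovers the planted ratio within ~3%: the residual bias comes
from the constant background (5 AU) entering both compartments and the
rasterized mask edges. The qc block records all four terms
(`S_cell = 17,703,985`, `S_nuc = 7,144,870`, `A_cell = 1357 µm²`,
`A_nuc = 352 µm²`, 3 of 3 nuclei retained).

Counting repeat-RNA foci across a cohort where 297 of 1767 nuclei contain
at least one focus:

```r
foci_summary(data.frame(foci_count = c(rep(0, 1470), rep(1, 297))))$fraction_positive
#> [1] 16.80815   # i.e. ~17% foci-positive neurons
```

Classify planted spines on a synthetic dendrite stack (voxels
0.066 × 0.066 × 0.390 µm):

```r
sp <- data.frame(class = rep(c("mushroom", "stubby", "thin"), 2),
                 position_um = seq(2, 17, by = 3),
                 head_d = rep(c(0.6, 0.45, 0.2), 2),
                 neck_d = rep(c(0.25, NA, 0.15), 2),
                 length = rep(c(1.5, 0.7, 1.2), 2))
det <- detect_spines(gen_spine_stack(seed = 7, spines = sp)$stack)
det[, c("length", "head_diameter", "neck_diameter", "spine_class")]
#>   length head_diameter neck_diameter spine_class
#> 1  1.431         0.594         0.264    mushroom
#> 2  0.639         0.462            NA      stubby
#> 3  1.101         0.198         0.132        thin
#> ...
spine_summary(det, attr(det, "dendrite_length_um"))$type_fractions
#> mushroom   stubby     thin
#> 33.33333 33.33333 33.33333
```

All six planted spines are detected, measured within one voxel-ish of
their planted geometry, and classified correctly.

## Vignette

`vignettes/methods.Rmd` describes the measurement models, the parameter
defaults and their provenance, what the synthetic fixtures do and do not
emulate, and the package's numerical and design choices.
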