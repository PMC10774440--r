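---
title: "The centrosomal cohesion assay: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The centrosomal cohesion assay: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay

Centriole/centrosome (C/C) cohesion keeps the two centrioles of an
interphase cell — or the two duplicated centrosomes in S/G2 — close
together. In blood-derived cells from Parkinson's disease patients carrying
hyperactive LRRK2, this cohesion is impaired: the two pericentrin-positive
dots of a cell sit farther apart than in healthy controls, and the
phenotype reverts within hours of LRRK2 kinase inhibition with MLi2. The
assay quantifies this as a per-sample percentage:

* a cell with exactly two scorable centrosomal structures is **split** when
  the Euclidean distance between the structure centroids on the maximum
  projection exceeds **1.3 µm** (strictly; a tie is not split);
* a sample's **percent splitting** is the percentage of split cells among
  the cells with exactly two structures;
* a sample has a **cohesion deficit** when percent splitting is **≥ 20 %**
  (inclusive).

Two scoring modes mirror the two staining designs. In
`dual_marker_duplicated` mode a structure is scorable only when a
pericentrin and a γ-tubulin spot colocalize (a bona fide duplicated
centrosome); healthy cells sit near 90 % non-split in this mode. In
`single_marker_cc` mode every pericentrin dot counts, so the distance also
measures centriolar cohesion in G1; healthy cells show a mean inter-dot
distance around 1.2 µm and roughly 25 % of cells beyond 1.3 µm. The
threshold, the deficit cut-off and the two-dot denominators are fixed
properties of the assay, not free parameters; `scoring_config()` exposes
them for sensitivity analyses only.

The per-cell exclusion rules are applied in this order: mitotic cells
(condensed DAPI), border-touching nuclei, over-sized nuclei in PBMC mode
(lymphocytes are gated at nuclear equivalent diameter < 10 µm; monocytes
are larger), cells with no scorable structure ("only cells with clear
centrosomal staining"), and cells with more than two scorable structures.
For the last group the assay is silent in its source material; we exclude
them (`ambiguous_count`) because any choice of a pair among ≥3 dots is
arbitrary, and expose `ambiguous_policy = "two_brightest"` as the
alternative. One-dot cells contribute to the percent-two-dot denominator
only.

## The imaging stage

`analyze_stack()` chains five operations, each also exported on its own:

1. **Maximum projection** over z (`max_project()`), matching the 2D
   analysis convention of the assay.
2. **Nucleus segmentation** (`segment_nuclei()`): Gaussian smoothing, Otsu
   thresholding, hole filling, a small opening, connected components, then
   per-region features. The equivalent diameter is that of the circle with
   the region's area. A guard refuses to segment fields whose Otsu
   threshold does not clear the background by five robust standard
   deviations — on a background-only field Otsu would otherwise bisect the
   noise. The mitotic flag is relative brightness: condensed chromatin
   packs the same DNA into a fraction of the area, so a mitotic region's
   mean DAPI intensity exceeds ~3× the field's median *nucleus* intensity,
   while interphase staining varies only modestly; we flag regions above
   `mitotic_k = 2.5`. (A size-based clause is unreliable here because a
   condensed monocyte nucleus can match an interphase lymphocyte in area.)
3. **Spot detection** (`detect_spots()`): difference-of-Gaussians band-pass
   at the expected dot sigma (default 0.15 µm, the confocal PSF at a
   63×/1.4 NA objective), local maxima above
   `max(8 × MAD(response), 0.1 × max(response))`, and per-axis parabolic
   interpolation of the peak for subpixel localization. On noiseless
   renders the localization error is below 0.03 µm (a third of a pixel),
   and well below the 0.1 µm pixel at realistic noise.
4. **Marker pairing** (`pair_markers()`): mutual nearest neighbours within
   0.5 µm. Pericentrin and γ-tubulin decorate the *same* centrosome, so a
   genuine duplicated centrosome yields two spots essentially coincident;
   0.5 µm is far above the localization error and far below the 1.3 µm
   scale of interest. Mutual nearest neighbour makes the pairing symmetric
   in channel order. Unpaired spots survive as single-positive structures
   and are excluded from dual-marker scoring.
5. **Cell assembly** (`assemble_cells()`): each structure goes to the
   nucleus with the nearest boundary (distance 0 inside a nucleus), capped
   at 5 µm — centrosomes sit adjacent to the nucleus in these round
   suspension cells. Exact ties go to the lower label and are logged;
   farther structures are dropped and counted.

All coordinates are pixel-centre positions in µm with 0-based pixel
indices; every distance the package reports is computed from subpixel
centroids on the projection.

## The synthetic-data generator

Real patient images cannot ship with the package, so the generator is the
test bed: it renders fields whose ground truth is known exactly, with the
statistical structure the assay assumes.

* **Nuclei**: soft-edged ellipses with mild eccentricity (axis ratio
  0.85–1). Nuclear equivalent diameters are class-specific —
  lymphocyte-like N(8, 0.8) µm, monocyte-like N(12, 1.2) µm — so the PBMC
  diameter gate at 10 µm has signal on both sides. Mitotic cells
  (default 4 % of cells) are rendered as condensed blobs: 0.55× the
  diameter, 4× the DAPI intensity, two widely separated dots standing in
  for spindle poles.
* **Dots**: isotropic Gaussians of sigma `psf_sigma_um` (default 0.15 µm).
  Each non-mitotic cell carries one or two dots
  (`two_dot_fraction`, default 0.6 to match the observed two-dot regime);
  pair distances are drawn from N(`distance_mean_um`, `distance_sd_um`)
  truncated at zero by resampling, the pair orientation is uniform in the
  plane, and the pair midpoint is jittered around the nucleus centre.
* **Dual-marker mode** adds a γ-tubulin channel with dots exactly
  co-located with the pericentrin dots, plus Poisson(0.1)/cell *decoy*
  single-channel dots per channel, so colocalization gating has something
  to reject.
* **Geometry**: cells are placed by dart throwing with a minimum
  centre-to-centre spacing of twice the largest plausible nuclear diameter,
  so nuclei never overlap; the population spills over as many fields as the
  spacing requires. The scene is replicated over a thin z-range (default 3
  planes, off-focus planes at 60 % intensity) because the assay analyses
  maximum projections; 3D PSFs are out of scope.
* **Noise**: signal-dependent camera noise, implemented as the Gaussian
  approximation N(µ, µ + σ_read²) of Poisson shot noise plus read noise.
  At the default background (20 counts) and dot amplitude (400 counts) the
  Poisson-to-Gaussian approximation error is negligible, and a single
  vectorized draw per pixel keeps 2000-cell simulations to minutes.

Identical config + seed gives bit-identical images and ground truth
(`withr::with_seed` around the whole generation). The ground-truth split
label is defined as distance strictly greater than the configured
threshold, so re-thresholding the true distances reproduces the labels for
any threshold — a property the tests exercise.

What the generator does **not** emulate: cell crowding and overlap,
spectral bleed-through, 3D PSF structure, camera-specific fixed-pattern
noise, debris and dead cells of real PBMC preparations. Passing tests
therefore demonstrate that the measurement chain is unbiased and correctly
calibrated on well-behaved fields, not that segmentation survives heavily
degraded clinical material.

The cohort generator (`simulate_cohort_scores()`) works at the
subject level: per group it draws a true vehicle and MLi2 percent-splitting
value from stated normal distributions truncated to [0, 100], then
binomially resamples each at `cells_per_sample` (default 175, the centre of
the 150–200 cells/sample the assay targets) so per-sample noise matches an
n-cell count. The default group table mirrors the study design — 10
controls, 12 R1441G-PD, 9 R1441G-NMC, 7 G2019S-PD, 6 G2019S-NMC, 4
idiopathic-PD — with control splitting around 10 %, mutation carriers
elevated (means 20–35 %), and MLi2 restoring all groups to the control
range; within-group SDs (3–10 points) are our choice of a realistic
between-subject spread, as the source reports only group summaries.

## Western-blot ratios

`normalize_lanes()` computes the six multiplexed ratios (LRRK2/tubulin,
pS935/tubulin, pS935/LRRK2, Rab10/tubulin, pT73-Rab10/tubulin,
pT73-Rab10/Rab10) within each lane, then divides by the same ratio in that
gel's internal-standard lane — the same control sample run on every gel —
making values comparable across gels and exactly invariant to per-gel
imaging gain. Replicate lanes are averaged *after* normalization, since
normalization removes the gel effect first. Lanes with a zero denominator
band are flagged and dropped with a warning; a gel without its standard
lane is an error naming the gel. The LLOMe response
(`llome_response()`) is the percent increase of pT73-Rab10/Rab10 from
basal to LLOMe, and analogously under MLi2; we use the within-lane (not
standard-relative) ratio because it is internally controlled, and flag
non-responders (increase ≤ 0). A `ps106_rab12` column is carried through
untouched when present but no statistic is computed on it.

## Cohort statistics

`compare_groups()` reports per-group descriptives with Shapiro-Wilk
normality p-values, one-way ANOVA, and Tukey HSD over all group pairs
(via `aov()`/`TukeyHSD()`, i.e. the studentized range at the pooled error
df). Normality failures warn but never switch the test — the assay's
statistics are parametric throughout. `paired_condition_test()` is the
classical paired t on per-subject vehicle-minus-MLi2 deltas, with the
degenerate all-zero-delta case defined as t = 0, p = 1.
`correlate_scores()` is Spearman's rank correlation with average ranks for
ties and an asymptotic two-sided p. `roc_cstat()` is the Mann–Whitney
c-statistic: the probability that a random case outscores a random
control, ties weighted ½, computed from average ranks and verified in the
tests against exhaustive pair counting up to n = 50 and against an
independent library implementation. No multiple-testing correction is
applied across the report, matching the source analysis. Test–retest
stability of the phenotype is assessed as the absolute percent-splitting
difference between replicate samples; no ICC is computed since none is
described for the assay.

## Numerical choices and problem sizes

* Strict inequality at the split threshold, inclusive at the deficit
  threshold (both quoted conventions).
* The percent-split denominator is two-structure cells, the only cells for
  which the distance exists; a config switch would be needed to change
  this, deliberately not provided.
* End-to-end validation runs 2000 cells per regime (≈170 fields of
  1024×1024 px at 0.1 µm/px), which recovers the truncated-normal tail
  probabilities to well within two percentage points; distributional
  checks on the generator use 5000 cells without rendering; the type-I
  error calibration uses 1000 null replicates. These sizes hold Monte
  Carlo error comfortably below the assay's tolerances while keeping a
  full validation run to a few minutes on one CPU.
* MLi2 condition metadata (50 nM / 2 h for LCLs, 200 nM / 30 min for
  PBMCs) is annotation only and never alters computation.

## Known limitations

Assignment of structures to cells uses the segmented nucleus boundary, not
a cell boundary; in crowded fields a centrosome between two nuclei could be
attributed to the wrong cell, which is why the generator enforces
non-overlapping placement and real crowded fields should be treated with
caution. The distance is 2D (projection), so true 3D separations are
underestimated by the cosine of the polar angle — consistent with the
assay's own convention. TIFF output carries its OME metadata in a
companion XML file next to the image (the R `tiff` writer cannot embed an
ImageDescription tag); readers that expect embedded OME-XML should be
pointed at the companion file, and `load_stack()` reads either.
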