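---
title: "Models and methods behind lysomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lysomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysomorph)
```

lysomorph implements two analysis tracks that meet in studies of lysosomal
dysfunction in early-onset Parkinsonism: a knowledge-driven prioritization
score for rare variants from whole-exome sequencing, and the fluorescence
morphometry used to phenotype patient fibroblasts (colocalization, lysosome
size and network porosity, Golgi fragmentation, p62 aggregates, LysoSensor
acidity), with the group-statistics layer on top. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The KDA variant score

After filtering (caller support strictly greater than 2, gnomAD
non-Finnish-European frequency strictly below 0.01 with "not found"
passing, CADD PHRED strictly above 15, panel membership; benign/likely
benign variants polymorphic above 1% in any population excluded), each
variant receives eleven integer component scores whose sum is the total
`T`. The component rubrics live in a `KDARubric` object; every cut-point
is configurable and the rubric serializes to YAML.

The default rubric is a reconstruction: the original cut-point table is
not public, so the defaults were fitted to be consistent with every row of
the published score table and are verified against it in the test suite:

* ACMG class: B/LB = 1, VUS = 2, LP/P = 3.
* CADD PHRED: (15, 30] = 1, above 30 = 2 (values at or below 15 score 0 —
  such variants are normally removed by filtering).
* gnomAD NFE frequency: above 1e-3 = 1, [5e-6, 1e-3) = 2, below 5e-6 = 3,
  and "not found" is treated as the rarest tier (3). The boundaries are
  the coarsest cut-points consistent with all printed (frequency, score)
  pairs.
* MutationTaster, PolyPhen-2, SIFT, FATHMM-MKL, SpliceAI: the binary
  deleterious call, 0/1; missing calls score 0 (the published table prints
  0 for several predictor cells of otherwise-scored variants).
* GERP: conservation above 2 (a standard GERP++ constraint cut) scores 1;
  inputs already binarized pass through.
* Constraint: missense Z at or above 3.09 or pLI at or above 0.9 scores 1.
  How the published analysis combined Z and pLI is not documented; an OR
  over the two standard thresholds is used and both are configurable.
* Brain expression: a 0/1 flag. How expression was binarized from the
  source atlas is not documented; the flag is consumed as-is.

Totals map to an ordinal color scale from green (3) to deep red (15). The
published description fixes the anchors but not the number of bins; we use
the 13 integer steps between the anchors, clamping outside totals, which
makes the bin a deterministic, monotone function of the total.

Ranking sorts scorecards by lysosomal-pathway membership, then ACMG
severity, then total, preserving input order on ties. That key order is an
interpretation of the prose description ("lysosomal signaling pathway,
clinical significance, and overall KDA score") and is configurable via the
`keys` argument.

## Image model and morphometry operators

A `CellImage` holds named channels on the raw 8-bit scale with one pixel
size; all measurements run on maximum-intensity projections (the source
acquisitions are 15-section z-stacks, and whether sizing used single
planes is not documented — projections are assumed). Coordinates are
0-based (row, col) and every physical output converts through the pixel
size once, at the end.

**Segmentation.** Otsu thresholding on the projected channel, removal of
objects below `minObjectPx` (default 4; 12 for lysosome fields, discarding
sub-resolution specks), and connected-component labeling. The default
connectivity is 4-neighbour and is exposed because fragment counts depend
on it.

**Colocalization.** Manders M1 — the fraction of reference-channel
intensity inside the second channel's Otsu mask — is the reported value;
the intensity-weighted overlap coefficient is computed alongside. The
underlying description names the "overall overlap coefficient" but defines
the M1-style proportion, so the quoted definition governs and both are
available. `colocalize()` first subtracts a robust per-channel background
(mean + 2 SD of the dimmest 80% of pixels, clamped at zero): without it,
clipped camera noise accumulates over the many background pixels of a
sparse image and dilutes the denominator by several percent.

**Lysosome diameter.** The membrane marker outlines organelles, so a line
profile through an object shows two rim peaks; the diameter is the
distance between the outermost prominent peaks. The profile runs through
the object centroid along its principal axis, sampled bilinearly at most
one pixel apart; it is smoothed with a 3-sample moving mean; peaks need a
prominence of at least 10% of the profile range; and peak positions are
refined by parabolic interpolation, which brings the noiseless bias well
under 0.1 px. Single-peak (unresolved) objects return the FWHM with a flag
and are excluded from size summaries by default.

**Network porosity.** The network region is the morphological closure of
the lysosome mask (disc radius 25 px by default); 50 × 50-px tiles are
laid on a grid anchored at the region bounding box; tiles not entirely
inside the region are dropped; porosity is the percentage of tile pixels
not covered by lysosome signal. Porosity is computed relative to the whole
tile (not the network area within it), following the region-of-interest
phrasing of the source description. For rim-stained images the mask is
hole-filled first, since an organelle's lumen belongs to the organelle.

**Golgi morphology.** The fragment count is the number of connected
components of the Golgi mask. The distance readout locates the Golgi pixel
farthest from the nucleus centroid and reports the distance from that
extremity to the nearest nucleus pixel. The fragmented-or-beehive class is
never defined operationally in the source; the package's rule — fragment
count above 5, or nucleus distance above twice the nucleus equivalent
radius — was calibrated on the presets and both thresholds are exposed.
With the default fibroblast nucleus (equivalent radius about 6 um) the
distance clause fires rarely for compact Golgi, so the count clause
dominates.

**p62 aggregates.** An aggregate is an above-Otsu connected component
inside the cell mask with area between 0.05 and 5 um^2; density is count
per cell area. **LysoSensor.** Per-cell mean intensity over the segmented
signal, normalized replicate-wise to the control group so the control
grand mean is about 1. **Densitometry.** Ordinary least squares of known
mass on band intensity; unknowns are interpolated and flagged when outside
the standard range.

## Group statistics

Normality is gated per group by Shapiro-Wilk at alpha = 0.05 (the gate is
documented in the source methods; the alpha is not, so it is a package
default); all groups must pass for the parametric branch. Two groups give
a t-test or Mann-Whitney; more give one-way ANOVA with Tukey HSD or
Kruskal-Wallis with Dunn post hoc z-tests (Bonferroni adjustment by
default; Holm or none available); 2 × 2 proportions use Pearson's
chi-squared without continuity correction (toggleable). The Mann-Whitney
p value is exact by complete enumeration of group assignments when the
pooled sample size is at most 14 — valid under ties, and verified against
an independent implementation in the tests — and otherwise uses the
tie-corrected normal approximation. All tests are two-sided; stars follow
the `* < 0.05, ** < 0.01, *** < 0.001` convention.

## The synthetic-data generator

Each study group (CT, PD-302, PD-216, PD-212, PD-088) has a versioned
`GeneratorPreset` whose targets are the published group means; the
generator's purpose is closure: the morphometry operators, run blind on
generated images at the study's replicate structure (3 replicates; at
least 80 lysosomes, 100 Golgi cells, or 30 colocalization cells per
replicate), recover those targets within sampling error. Ground truth is
recorded before noise, and a given (preset, seed) is bit-reproducible.

Rendering choices that matter:

* **Lysosomes are annuli**, because the membrane marker stains the rim and
  the peak-distance diameter is meaningless on filled discs. The rim is a
  radial Gaussian (sigma 1 px) whose rendered radius is offset outward by
  `(sigma_PSF^2 + sigma_rim^2/2) / (2 r)` — the inward ridge shift that
  isotropic blurring imposes on a curved rim, calibrated on noiseless
  rings — so the post-blur peak sits at the true radius. Diameters are
  drawn from the group's normal distribution truncated above 100 nm;
  placement uses a parent-offspring (Thomas-style) cluster process with a
  minimum edge-to-edge gap of 7 px so that the PSF cannot merge adjacent
  objects, and falls back to uniform proposals when a cluster saturates so
  that placement failure is never correlated with object size.
* **Golgi images** draw the cell's class (fragmented or not) first, with
  the group's prevalence; fragment counts are class-conditional
  (unfragmented 1-5, fragmented 6 and up with the group's overall mean),
  which keeps the published group means as targets while making the
  classes operationally separable — the misclassification observed across
  seeds is a few percent, from segmentation rather than class overlap.
  Nucleus-to-extremity distances are likewise class-conditional, chosen so
  the group mixture reproduces the published group mean.
* **Colocalization images** plant an exact fraction of enzyme-channel
  intensity inside the trans-Golgi region. The planted region uses the
  same operational definition as the measurement (Otsu foreground of the
  clean channel), the enzyme concentrates toward the blob cores and the
  region is eroded by 2 px so the PSF cannot carry planted intensity
  across the measured boundary, and the channel is rescaled globally
  rather than clipped per pixel, which would distort the planted fraction.
* **Noise**: Gaussian PSF (sigma 1.2 px), Poisson shot noise (gain 1) and
  Gaussian read noise (SD 2 on the 8-bit scale), chosen so that per-object
  measurement scatter is realistic; all exposed in the preset.

Problem sizes in the shipped tests and acceptance script follow the study
design (3 replicates of at least 80/100/30 cells; 10 seeds for the
recovery checks; 2000 replicates for the type-I calibration), which keeps
a full run in the minutes range on one core.

**What the generator does not emulate.** Real fibroblast fields contain
touching and partially out-of-focus organelles, spatially varying
background, chromatic misregistration and deconvolution artifacts; the
generator replaces deconvolution with a Gaussian PSF so the operators face
realistic peak broadening, but recovery on these images demonstrates
operator correctness and calibration, not robustness to every real-world
artifact. Two known limits:

* **Porosity is calibrated ordinally, not to the printed means.** With
  rim-stained rendering, hole-filled Otsu masks and a no-overlap placement,
  the achievable tile coverage is bounded: measured porosity cannot drop
  much below ~55% even at the tightest packing that still keeps objects
  resolvable for the diameter assay. The dispersion parameters therefore
  preserve the published group ordering (CT lowest, PD-216 highest) and
  the monotone dispersion-porosity relationship is property-tested, but
  the printed control mean (12.8%) itself is not reproduced. Reaching it
  would require overlapping, filled organelle footprints — which would
  destroy the peak-distance diameter assay sharing the channel.
* **Printed group SDs** conflate biological and measurement variance; the
  generator makes no attempt to decompose them, so SD matching is
  best-effort.

The published per-patient fibroblast results themselves are not
recomputable (no raw images or genomes are deposited); calibrated
synthetic recovery is the substitute, and it is stated as such wherever
the package reports those numbers.

## Module shape

The assays are generated (and measured) per acquisition type at their own
magnification — 40 nm/px lysosome fields, 150 nm/px whole-cell Golgi
fields, 100 nm/px colocalization crops — because a single frame cannot
carry all channels at one pixel size honestly; `makeCellImage()` therefore
takes an `assay` argument. File-coupled pipeline stages (simulate,
morphometry, stats, prioritize) hand off through TIFF/CSV/JSON with a
manifest (seed, parameters, output checksums) so each stage is testable in
isolation and a rerun is byte-identical.
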