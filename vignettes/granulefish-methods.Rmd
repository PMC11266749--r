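---
title: "Methods: smFISH quantification of germ-granule mRNA localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smFISH quantification of germ-granule mRNA localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulefish)
```

# The measurement problem

In early *C. elegans* embryos, maternal mRNAs concentrate in germ granules
— RNA–protein condensates segregated into the P lineage (P1 through P4,
the germline founder). Single-molecule FISH makes each mRNA visible as a
diffraction-limited spot (~150 nm) whose integrated fluorescence is
proportional to the number of molecules in the spot. granulefish implements
the full quantification chain for such experiments:

1. **Spot detection and localization** — rolling-ball background
   subtraction, 3D local-maximum candidate detection, and iterative
   Gaussian-mask fitting for sub-pixel position and integrated intensity.
2. **Single-molecule calibration** — somatic blastomeres degrade maternal
   mRNA and carry almost exclusively single transcripts, so the median
   somatic spot intensity defines the intensity of one molecule.
3. **Molecule binning and cluster calling** — each spot's intensity is
   divided by the unit and rounded to a copy number; spots with ≥ 4
   molecules are "clusters".
4. **Granule segmentation** — the marker channel (e.g. MEG-3::GFP) is
   background-subtracted, blurred (σ = 1 px, per slice), thresholded by
   Kapur's maximum-entropy rule, split by a per-slice distance-transform
   watershed and linked into 3D components.
5. **Colocalization** — a spot belongs to a granule when its centre falls
   in the granule's padded bounding cube (full x/y extent
   (minor radius + 2) × 2 px, z extent major radius × 2 slices); clusters
   of two RNA species colocalize when within 2 px in x and y and 2 slices
   in z on *every* axis, matched one-to-one by distance.
6. **Concentration enrichment** — per-cell concentration on the
   mid-nucleus slice, [P] = (intensity/area of cell) − (intensity/area of
   nucleus), and enrichment [P4] / mean([P1]) over a ≥ 3-cell P1 cohort.
7. **Screen classification** — transcripts with smFISH foci in any P
   blastomere are Group I (with the PGC maintenance pattern) or Group II
   (without); transcripts never in foci are Group III. Fisher's exact
   test (implemented from the hypergeometric distribution) serves the
   sterility contingency comparisons.

Every stage is validated against a synthetic-embryo generator whose latent
variables (molecule positions, copy numbers, granule geometry, lineage
partitioning) are returned as ground truth.

# The synthetic embryo model

`sim_params()` / `generate_embryo()` emulate one blastomere:

* **Geometry.** An ellipsoidal cell (semi-axes 0.40–0.42 of the stack
  extent) with a concentric ellipsoidal nucleus at 0.35 of the cell's
  semi-axes. Geometry metadata defaults to 65 nm pixels and 300 nm slices,
  so a ~150 nm-FWHM PSF corresponds to σ ≈ 1 px laterally; axially we use
  σ = 1.1 slices. Distances and tolerances are always expressed in pixels
  (x, y) and slices (z), matching the mixed-unit protocol constants; nm
  values are carried but never used for thresholds.
* **Foci.** Total molecules are partitioned into foci with cluster sizes
  from a truncated geometric distribution (configurable mean, cap 35 —
  the largest observed copy number). Each focus is granule-associated with
  probability `p_granule` and placed uniformly inside a granule or in the
  cytoplasm. Each focus is rendered as a pixel-integrated 3D Gaussian of
  integrated intensity `n_molecules × unit_intensity` (8000 counts per
  molecule by default).
* **Granules.** Axis-aligned ellipsoids with the long axis in z (granules
  are tallest in height), rendered in a second channel at 300 counts over
  a 20-count background and smoothed with a σ = 0.8 px optical blur.
* **Noise.** Poisson shot noise on signal + background (default background
  100 counts with an optional linear ramp), plus Gaussian read noise
  (sd 3) rounded to integer ADU and clipped at zero — a standard camera
  model; the default peak SNR for a single molecule is ≈ 40.
* **Lineage.** `generate_lineage_series()` simulates P1→P4: at each
  division the P daughter keeps `inherit_fraction` of granule-associated
  molecules and a binomial volume share of cytoplasmic ones, while the
  cell shrinks by `volume_ratio` (granule radii scale with the cell so the
  granule volume fraction is conserved). With full granule localization,
  all-granule inheritance and volume halving, concentration doubles per
  division — eightfold from P1 to P4.

What the generator does *not* emulate: realistic PSF side lobes or
aberrations, photobleaching, probe-hybridization chemistry, autofluorescent
structures, cell-cell contact geometry, or the diffuse interfacial
distribution of granule proteins. Passing the recovery tests therefore
demonstrates correctness of the measurement chain under the stated noise
model, not performance on arbitrary real microscopy data.

# Numerical choices

* **Background subtraction** is a grayscale opening with a disc element per
  z-slice (radius 50 px by default, the protocol value), subtracted and
  clipped at zero; the image is scaled through [0, 1] around the opening
  since morphology there is scale-equivariant. The radius must fit the
  image plane (2r + 1 ≤ plane side).
* **Detection threshold**: the original protocol sets thresholds
  interactively; the package uses an explicit config value or, by default,
  median + 8 × MAD of the background-subtracted stack. Candidates are 3D
  (26-neighbour) maxima, non-maximum-suppressed within 2 px (Chebyshev),
  ordered by descending intensity then lexicographic position.
* **Gaussian-mask fitting** iterates an intensity-weighted centroid under a
  pixel-integrated Gaussian mask with fixed σ (from calibration/config)
  until the shift is < 0.01 px or 100 iterations; intensity is the
  least-squares amplitude `Σ I·g / Σ g²` after subtracting the window-rim
  median background. Non-converged fits keep the seed position with
  `residual = Inf`; windows at the stack border are truncated and flagged
  `edge`. Duplicate fits closer than 1 px keep the brighter record.
* **Molecule binning** is `max(1, round(intensity / unit))` with half-up
  ties (an equivalent formulation: n ≥ k when I > (k − 0.5) × unit). No
  upper cap is imposed.
* **Kapur thresholding** maximizes the summed background/foreground Shannon
  entropies over all 256-bin splits, ties to the lower split. A
  degenerate-input guard refuses to call granules when the threshold does
  not clear the image median by 5 robust deviations (structureless,
  noise-only channels); the deterministic fallback chain is Kapur →
  configured manual threshold → error.
* **Watershed** runs per slice on the distance transform of the binary
  mask (mirroring the 2D Fiji operation), and slice labels are linked into
  3D components by mask overlap between adjacent slices; a full-3D
  watershed is available behind `watershed_3d`. Components below 4 voxels
  are discarded — an automatic stand-in for the protocol's manual ROI
  curation. The segmentation blur is applied in-plane only: 1 px ≈ 65 nm
  laterally while 1 slice ≈ 300 nm, so blurring across slices would
  artificially dilate granule heights.
* **Granule radii**: the minor radius is the equivalent-circle radius of
  the largest-area z-slice; the major radius is the largest of the z
  half-extent, the half-length of the longest principal axis, and the
  minor radius (the type guarantees major ≥ minor).
* **Membership cubes** use inclusive (≤) boundary tests on 0-based
  coordinates; a spot in several cubes goes to the nearest centroid (ties
  to the lower granule id). Cluster pairing accepts candidate pairs in
  order of increasing Euclidean distance (ties by id) while both partners
  are free, which makes the unordered pair set symmetric in the two
  species.
* **Mid-nucleus slice**: the z-slice maximizing nucleus area. Raw (not
  background-subtracted) slices feed the concentration formula — the
  nuclear term is the background control and cancels any offset shared by
  cytoplasm and nucleus.
* **Reported percentages** round half-up to integers; full precision is
  retained in CSV/JSON outputs.

# Design decisions on open points

* **One axis convention everywhere.** Arrays are (z, y, x), 0-based,
  fractional pixel/slice coordinates; no stage ever swaps x and y.
* **Stacks on disk** are standard 16-bit unsigned-integer multi-page TIFFs
  (integer camera counts), which round-trip exactly; the simulator
  produces integer ADU by construction.
* **Calibration scope.** `calibrate_unit_intensity()` takes whatever spot
  table it is given — pool all somatic fields of view for one transcript
  and imaging day, mirroring the per-(transcript, batch) calibration of
  the protocol. A dispersion warning fires when MAD/median > 0.5.
* **Enrichment-above-baseline.** The membership region of a granule is its
  padded bounding *cube*, whose volume exceeds the ellipsoid it bounds by
  roughly 2–5×. For an RNA with no granule affinity the expected
  percentage of molecules "in granules" therefore equals the fraction of
  cytoplasm covered by the cubes (`granule_occupancy_fraction()`), not the
  granule volume fraction (`cytoplasm_fraction()`). Both are reported;
  enrichment above baseline uses the occupancy figure.
* **The idealized lineage check** uses the generator's exact
  concentrations (molecules per cytoplasmic voxel). The single-slice image
  measurement inherits large granule-configuration sampling noise — the
  mid-nucleus plane intersects only a handful of granules, so per-embryo
  image-based enrichment scatters by tens of percent even with 10^4
  molecules, as the per-embryo scatter in real data also shows. The
  image route is validated by its monotone response to the granule
  localization probability instead.

# Known limitations

* **Maximum-entropy masks dilate small objects.** On blurred-edge granules
  of minor radius 3–6 px, the Kapur threshold consistently lands at
  ~15–20% of the plateau intensity, i.e. about 1 px outside the half-max
  edge (verified against an independent reference implementation of the
  same algorithm). Segmentation-based granule *volumes* run ~1.7–2.2×
  voxel-truth, and minor radii ~1.2 px large, while one-to-one matching,
  centroids and counts are accurate. Comparisons built on the same masks
  (occupancy baselines, content summaries, colocalization) are internally
  consistent; absolute volume fractions are overestimated.
* **Crowding.** Foci closer than ~2.5 px are optically one spot; the
  fitter returns a single record whose intensity approximates the summed
  molecules. Molecule-weighted percentages remain nearly unbiased, but
  focus-level recall degrades in densely packed granules.
* Automatic cell/nucleus segmentation is out of scope: ROIs are inputs
  (drawn, or simulator-provided).

# Problem sizes used in the validation suite

The test-suite and acceptance-script scenarios use 96–144 px planes with
12–24 slices, 100–400 molecules per embryo (10^4 for the lineage model,
where channels are not rendered), 8–20 granules, 20-seed calibration
replicates, 50 random colocalization scenes and 100 random
histograms/tables for the threshold and Fisher oracles; the full suite
runs in a few minutes on one core.
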