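# granulefish

Quantification of single-molecule FISH (smFISH) images of early
*C. elegans* embryos: where do maternal mRNAs sit relative to germ
granules, how many molecules per focus, and how strongly do they
concentrate into the germline founder cell P4?

In these experiments each mRNA molecule appears as a diffraction-limited
(~150 nm) spot whose integrated fluorescence is proportional to its copy
number. granulefish re-implements the full measurement chain as a tested,
scriptable pipeline:

* **3D spot detection and sub-pixel fitting** — rolling-ball background
  subtraction, 3D local-maximum seeds, iterative Gaussian-mask
  localization with integrated-intensity estimation.
* **Single-molecule calibration** — the median integrated intensity of
  spots in somatic blastomeres (where nearly all spots are single
  transcripts) defines the unit intensity; spots are binned to copy
  numbers `n = max(1, round(I / unit))`, and spots with `n >= 4` are
  called **clusters**.
* **Germ-granule segmentation** — maximum-entropy (Kapur) thresholding of
  the blurred marker channel, per-slice distance-transform watershed, 3D
  linking, and the minor/major radii that define each granule's
  **membership cube**: full x/y extent `(minor + 2) * 2` px, z extent
  `major * 2` slices.
* **Colocalization** — % of molecules inside granule cubes
  (molecule-weighted), cluster–cluster colocalization between two RNA
  species (within 2 px in x and y *and* 2 slices in z, matched
  one-to-one), and granule content summaries (A-only / B-only / both /
  neither).
* **Concentration enrichment** — per-cell concentration on the
  mid-nucleus slice, `[P] = intensity/area(cell) − intensity/area(nucleus)`,
  and enrichment `[P4] / mean([P1])` over a three-cell P1 cohort. Under
  the idealized model (all molecules granule-bound, granules fully
  inherited, volume halving per division) the concentration doubles per
  division — eightfold from P1 to P4.
* **Screen classification** — Groups I/II/III from per-stage foci flags
  and the PGC maintenance pattern, tally percentages, and a
  first-principles Fisher's exact test for sterility tables.
* **Synthetic embryos with ground truth** — ellipsoidal cell/nucleus,
  granules, multi-molecule foci rendered as pixel-integrated 3D Gaussians,
  Poisson + read noise, and asymmetric P1→P4 lineage partitioning; every
  latent variable is returned so each stage can be validated.

## Worked example

```r
library(granulefish)

# one simulated P2 blastomere: 300 molecules, 60% granule-associated
p   <- sim_params(rng_seed = 7, n_molecules = 300, p_granule = 0.6,
                  dim = c(20L, 128L, 128L))
emb <- generate_embryo(p)
cfg <- pipeline_config()

spots <- detect_spots(emb$rna, cfg, roi = emb$roi)
seg   <- segment_granules(emb$granule, cfg)
cubes <- granule_bounding_cube(seg$granules, cfg$cube_pad_px)

# calibrate from a granule-free somatic field and count molecules
som <- generate_embryo(sim_params(rng_seed = 8, n_molecules = 170,
                                  p_granule = 0, n_granules = 0,
                                  cluster_size_mean = 1, lineage = "somatic",
                                  granule_channel = FALSE,
                                  dim = c(20L, 128L, 128L),
                                  foci_min_separation_px = 4))
cal <- calibrate_unit_intensity(detect_spots(som$rna, cfg, roi = som$roi))
cal
#> single-molecule intensity: 7907 (MAD 130, n = 170 spots)

spots <- assign_molecule_counts(spots, cal, cfg$cluster_min_molecules)
pct_molecules_in_granules(spots, cubes)
#> [1] 47.26368
granule_occupancy_fraction(cubes, emb$roi)   # no-affinity baseline
#> [1] 9.567565
```

The calibrated unit is within ~1% of the simulated 8000 counts/molecule.
47% of the detected molecules sit in granule cubes against a 9.6% baseline
expected for an RNA with no granule affinity — a strong granule
enrichment. The simulated truth is 59% in granules; the shortfall is the
crowding limitation discussed in the methods vignette (foci packed closer
than ~2.5 px inside granules fuse into single spots, and focus-level
losses at this density are not fully recovered by intensity summation).

The screen tally, run on a synthetic annotation table with the published
group composition:

```r
tally_screen(generate_screen_table(487, rng_seed = 1))
#> screen tally: 487 transcripts
#>   foci-positive: 441/487 (91%)
#>   Group I:  131/441 of foci-positive (30%)
#>   Group II: 310/441 of foci-positive (70%)
#>   Group III: 46/487 of all (9%)
```

A one-shot composite run (simulate → detect → calibrate → segment →
colocalize, with a reproducibility manifest) is available via
`run_pipeline()`, and a thin command-line wrapper lives at
`inst/cli/granulefish.R`.

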