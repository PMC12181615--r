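# cmhq — cerebral microhemorrhage quantification in stained serial brain sections

Cerebral microhemorrhages (CMHs) are small focal brain bleeds from ruptured
microvessels, a histological hallmark of hypertensive and aging-related
small-vessel disease. In brightfield histology they appear as dark brown
DAB (diaminobenzidine) precipitates inside blue hematoxylin-stained coronal
sections. Quantifying them across the ~1000 serial sections of a whole
mouse brain by expert manual counting is accurate but prohibitively slow,
so `cmhq` implements the automated alternatives as a tested R package, for
researchers screening cerebromicrovascular protective interventions:

* **Stain math** — Beer–Lambert optical density
  `OD_c = −log10(max(I_c,1)/I0_c)` and linear HDAB color deconvolution
  `C = OD · M⁻¹` with the Ruifrok–Johnston stain matrix (rows H, DAB,
  residual; unit-norm), plus the exact forward model `I = I0 · 10^(−C·M)`.
* **Three segmentation tracks** — (1) deconvolution: DAB channel →
  difference-of-Gaussians bandpass (50/2 px) → Otsu → fill holes;
  (2) YIQ: NTSC chrominance, thresholding the orange–blue I channel
  (`[Y I Q]ᵀ = M_NTSC·[R G B]ᵀ`); (3) a LABKIT-style random-forest pixel
  classifier (background / tissue / bleed, codes 0/1/2) trained on sparse
  annotations with bleed-biased class balancing.
* **Serial registration** — rigid (rotation + translation) MSE registration
  over an image pyramid, applied in batches of 10 new sections with 2
  frozen reference sections carried between batches, plus a reverse
  refinement pass.
* **3D reconstruction** — factor-5 majority-vote downscaling (ties favour
  bleeds), a smoothed largest-component brain-surface mask, voxelwise
  minimum overlay to remove extratissular noise, and volume assembly at
  20 µm z-spacing (8 µm sections, 2-of-5 retention).
* **Burden metrics** — per-section and whole-brain CMH count, area
  fraction (% of tissue cross-section), and density (objects per mm²
  tissue).
* **Evaluation harness** — per-section ratios to a reference standard,
  one-way ANOVA with Dunnett many-to-one contrasts across methods, and
  Kruskal–Wallis with Dunn follow-up across treatment groups.
* **A synthetic slide generator** — serial hematoxylin/DAB phantoms with
  pixel-exact ground truth (tissue silhouette with ventricle, planted
  elliptical bleeds in the 2:1 small/large training mix, achromatic debris
  artifacts, staining jitter, sensor noise, bounded rigid misalignment),
  rendered through the same Beer–Lambert model the deconvolution inverts.
  No slide data ships with the package; every validation runs against this
  generator's ground truth.

See `vignettes/cmhq-methods.Rmd` for the full model description, parameter
rationale, and limitations.

## Worked example

Generate a 16-section synthetic brain with 14 planted bleeds, segment with
the YIQ track, align and reconstruct, and compare methods against ground
truth:

```r
library(cmhq)

cfg   <- pipeline_config(sim = slide_sim_config(n_sections = 16,
                                                n_bleeds_total = 14,
                                                rng_seed = 21))
brain <- generate_stack(do.call(slide_sim_config, cfg$sim))
seg   <- run_segment(cfg, stack = brain, method = "yiq")
rec   <- run_align_reconstruct(cfg, seg$labels)

round(rec$drift, 2)
#> before  after
#>  10.67   0.06
rec$quant
#> CMH burden: 14 objects over 4.69 mm2 tissue (1.5517% area, 2.98 /mm2)
rec$volume
#> Brain volume: 16 x 84 x 112 voxels (20.0 x 8.62 x 8.62 um), depth 0.32 mm
```

The alignment reduced the mean consecutive-section centroid drift from
10.7 px to 0.06 px; the YIQ track recovered all 14 planted bleeds, and the
burden metrics (area fraction 1.55 % of tissue, density 2.98 CMH/mm²) refer
to the aligned full-resolution stack. Comparing the YIQ and deconvolution
tracks against the ground-truth reference:

```r
ref <- truth_summary(brain)
hd  <- run_segment(cfg, stack = brain, method = "hdab")
run_compare(cfg, list(yiq = seg$summary, hdab = hd$summary), ref)
#> == count ratio vs reference (ANOVA F = 20.040, p = 1.14e-06) ==
#>   reference      n= 16  ratio 1.000 +/- 0.000
#>   yiq            n= 16  ratio 1.000 +/- 0.000  (Dunnett p = 1)
#>   hdab           n=  9  ratio 2.667 +/- 0.507  (Dunnett p = 2.64e-06)
#> == area ratio vs reference (ANOVA F = 3.730, p = 0.0332) ==
#>   reference      n= 16  ratio 1.000 +/- 0.000
#>   yiq            n= 16  ratio 1.033 +/- 0.008  (Dunnett p = 0.159)
#>   hdab           n=  9  ratio 1.059 +/- 0.036  (Dunnett p = 0.0227)
```

The YIQ track matches the reference (count ratio 1.0, not significant),
while raw deconvolution over-counts 2.7-fold on this artifact-bearing stack
and is flagged by the Dunnett contrast. The deconvolution track reports
n = 9: on 7 sections it found objects where the reference has none; those
infinite ratios are excluded from the means and the exclusion is reported.

A thin command-line wrapper over the same functions is installed at
`inst/cli/cmhq` (`cmhq generate|train|segment|align|quantify|compare
--config config.yaml`).

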