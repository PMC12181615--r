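---
title: "Methods: microhemorrhage quantification in stained serial sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microhemorrhage quantification in stained serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cerebral microhemorrhages (CMHs) are focal bleeds from ruptured brain
microvessels. In histology they are detected on serial coronal sections
stained with hematoxylin (blue tissue counterstain) and DAB
(diaminobenzidine, a dark brown precipitate where red-blood-cell peroxidases
are present). A single brain yields on the order of a thousand sections, so
manual expert counting — the accuracy gold standard — is the throughput
bottleneck. `cmhq` implements the automated alternatives end to end:
per-section segmentation of DAB-positive objects, serial rigid alignment,
3D reconstruction, and whole-brain burden metrics, plus the statistical
harness to compare each automated method against a reference standard.

Because the underlying slide data are not publicly deposited, the package
ships a synthetic slide generator with exact ground truth. Every stage of
the pipeline is validated against that ground truth; nothing in the test
suite or acceptance script depends on external data.

## The optical model

Brightfield staining follows Beer–Lambert absorption. For channel
$c \in \{R,G,B\}$ with incident intensity $I_{0,c}$,

$$\mathrm{OD}_c = -\log_{10}\frac{\max(I_c, 1)}{I_{0,c}},
\qquad \mathrm{OD} = C \cdot M,$$

where $M$ is the stain matrix (rows = unit-norm OD vectors of hematoxylin,
DAB, and a residual direction) and $C$ the per-pixel stain concentrations.
Color deconvolution inverts this linearly: $C = \mathrm{OD} \cdot M^{-1}$.
The package defaults to the Ruifrok–Johnston HDAB vectors
(H ≈ (0.650, 0.704, 0.286), DAB ≈ (0.269, 0.568, 0.778)) with the residual
row as their normalized cross product; the matrix is configurable because
published presets name the vectors but implementations differ in digits.
Intensities are clipped to ≥ 1 DN before the logarithm, matching common
deconvolution implementations, so fully extinguished pixels stay finite.

The synthetic generator renders sections through exactly this forward model.
That choice is deliberate: it makes deconvolution *exactly* invertible in
the noise-free limit, which turns the unmixing stage into a hard round-trip
test (RMS error at machine precision) rather than a visual judgement.

## The three segmentation tracks

**HDAB deconvolution track.** OD → unmix → DAB channel → difference-of-
Gaussians bandpass (sizes 50/2 px, $\sigma = \text{size}/2$) → Otsu
threshold (bright polarity) → fill holes. The bandpass sizes are interpreted
in processed-image pixels (the images are analysed at their working
resolution throughout; there is no re-upscaling). The published FFT bandpass
filter this emulates has no closed-form definition, so a
difference-of-Gaussians with $\sigma = \text{size}/2$ was chosen for
testability; its pass band covers the same structure scales. This track is
stain-aware but threshold-naive: dense achromatic debris has a large
positive DAB component after unmixing (gray OD decomposes into
H + DAB + residual with DAB ≈ 1.2 per unit OD), so artifact-rich material is
systematically over-counted. The package reproduces this failure mode
deliberately — it is the reason the other two tracks exist.

**YIQ chrominance track.** The NTSC transform maps RGB to luma $Y$ and
chrominance $(I, Q)$; the in-phase axis $I$ runs orange (+) to blue (−), so
brown DAB and blue hematoxylin separate by sign. Two numerical choices were
genuinely open and are resolved as follows:

* *Tissue restriction (default on).* White slide background sits at
  $I = 0$, i.e. **between** the blue tissue mode ($I \approx -20$) and the
  orange bleed mode ($I \approx +30$). An Otsu threshold over the full frame
  therefore latches onto the tissue/background boundary and segments the
  background, not the bleeds. The default computes the threshold over
  tissue pixels only (tissue = pixels darker than the Otsu threshold of the
  luma channel); `tissue_restrict = FALSE` restores the raw behaviour.
* *Achromatic noise floor (default on).* DAB is by construction on the
  positive side of the achromatic axis, so the threshold is floored at
  $3 \times \mathrm{MAD}$ (normal-consistent) of $I$ over background
  pixels. For noise-free input the floor is exactly 0; with sensor noise it
  keeps near-achromatic debris and background fluctuation below threshold.
  Without the floor, gray specks whose noisy $I$ straddles zero fragment
  into spurious objects.

**Random-forest pixel classifier.** Three classes (0 = background,
1 = tissue, 2 = bleed), trained on sparse point annotations. The default
feature stack per RGB channel is: raw intensity, Gaussian blurs
($\sigma \in \{1,2,4,8\}$ px), gradient magnitude, Laplacian, and
min/max/variance in a radius-2 window (30 features total). The forest uses
100 trees, unlimited depth, $\sqrt{p}$ features per split, and a fixed seed
recorded in the model metadata; the interactive tool this emulates does not
publish its settings, so these defaults are explicit stand-ins. Class
balancing keeps *all* bleed annotations and subsamples background/tissue to
at most 5× the bleed count — the operational form of biasing training
toward small, easily-swamped bleeds. Predictions are deterministic given a
serialized model (the prediction seed is pinned from the model metadata).
Simulated expert annotations are drawn from ground truth: bleed strokes
from 1-px-eroded bleed interiors (a conservative stroke that avoids the
partially stained rim — which also reproduces the classifier's known slight
*under*-estimation of bleed area), background/tissue points half near the
tissue boundary and ventricle gaps, and every debris pixel labeled with its
true underlying class.

## Shared post-processing

Otsu's threshold is computed on a 256-bin histogram over the channel's
[min, max] (float channels are binned, not truncated), maximizing
$\omega_0\omega_1(\mu_0-\mu_1)^2$ with ties broken toward the lowest
threshold; a constant channel (range below $10^{-9}$ relative) is a
degenerate-input error. Hole filling converts background components not
connected to the image border to foreground (4-connected background against
8-connected foreground). Particle analysis labels connected components
(default 8-connectivity, the common particle-counting convention;
4-connectivity available) and drops objects below `min_area_um2 = 10` µm²
(≈ 1–4 px at the default calibration) to remove single-pixel noise — a
documented deviation, since the emulated workflow states no size cut.

## Registration and 3D reconstruction

Sections are padded onto a common canvas (max height × max width, centered,
background 0) and aligned by intensity-based rigid registration: the
transform (rotation about the canvas center, then translation) minimizing
mean squared intensity difference over a 3-level pyramid, initialized by a
coarse grid over ±22 px and ±11° — twice the generator's per-section
misalignment bounds, i.e. the worst relative displacement between
consecutive sections — and refined by Nelder–Mead at each level. Label maps
are registered at display scaling (codes × 127.5) and resampled with
nearest-neighbour interpolation only, so class codes never blend.

Long stacks are aligned in batches: the first 10 sections sequentially, then
groups of 2 carried references + 10 new sections (group size 12), with the
references frozen so drift cannot re-enter at batch boundaries; a short tail
merges with the reference pair. A reverse pass re-runs batched alignment on
the reversed stack and keeps the result only if the mean consecutive-section
centroid drift does not increase.

For 3D work the label stacks are reduced by factor 5 using per-block
majority vote with ties resolved toward the higher code — chosen over
mean-and-threshold precisely so single-voxel bleeds survive the reduction.
The brain surface mask (a stand-in for interactive surface segmentation,
whose parameters are unpublished) is the largest 6-connected 3D component of
the 0.5-thresholded, σ = 2-voxel Gaussian-smoothed occupancy field; the
minimum overlay zeroes all codes outside it. Voxel z-spacing defaults to
20 µm: 8-µm sections with 2-of-5 retention give a mean spacing of
8 × 5/2 µm.

Burden metrics: per-section tissue area (tissue + bleed pixels, mm²), bleed
area fraction (% of tissue area — tissue, not whole-frame, is the
denominator, consistent with density being normalized per mm² of brain),
and density (2D object count per mm² tissue; per-section 2D counts match
per-section histological counting, with 3D-merged counts reported
separately). Aggregates pool pixels and counts, i.e. tissue-area-weighted
means. Quantification runs on the full-resolution aligned stack; the
factor-5 volume is for rendering and 3D statistics.

## Method comparison and statistics

Each method's per-section count and area are expressed as ratios to the
reference (the generator's ground truth, standing in for expert manual
counts; an external manual-count table is accepted). Sections where both
method and reference are zero get ratio 1; reference-zero/method-positive
sections are flagged infinite and excluded from means, with the exclusion
count reported — exclusion avoids a handful of infinite ratios dominating
the mean. Methods are compared by one-way ANOVA with Dunnett many-to-one
contrasts against the reference (via `multcomp`, seeded for bit
reproducibility), with Shapiro–Wilk and Brown–Forsythe diagnostics
reported. Group-level burden uses Kruskal–Wallis with Dunn's rank-based
many-to-one follow-up (Holm-adjusted): pairing a rank test with a
normal-theory Dunnett contrast set would be statistically incoherent, so
the nonparametric analogue is used and the naming difference documented
here.

## What the generator emulates — and what it does not

Each synthetic section is a smooth brain-like silhouette (ellipse modulated
by low-order polar harmonics, with a fixed first-harmonic dorsoventral
asymmetry that breaks the rotational near-symmetry of a plain ellipse, as a
real coronal profile does) containing a ventricle-like interior hole,
rendered via the Beer–Lambert model above with multiplicative staining
texture and per-section/per-object lognormal intensity jitter (CV 0.1).
Bleeds are hard ellipses with a 1-px feathered rim (the ground-truth
boundary sits at half stain coverage); debris artifacts are near-black
achromatic specks near the tissue boundary. Consecutive sections advance by
0.002 of the rostro-caudal extent (20 µm of a ~10 mm axis), so
cross-section shape changes as slowly as in real serial histology. Each
section is displaced by a bounded random rigid transform, applied
analytically to the geometry so ground-truth masks are pixel-exact;
Gaussian sensor noise (σ = 2 DN) is added last, after the ground truth is
fixed.

Defaults represent the study conditions: 420 × 560 px sections at
1.725 µm/px (a 0.345 µm/px 40× scan downscaled to 20%; the true scan
resolution is unstated, so this is a flagged assumption), 40 sections, 30
bleeds in a 2:1 small (< 50 µm) : large (> 100 µm) mix, ~2 artifacts per
section, misalignment up to 10 px / 5°. A minimum bleed separation of 12 px
(twice the 3D downscale factor) keeps distinct planted objects resolvable
after reduction. Placement is rejection sampling, largest objects first.

The generator does **not** model: anatomical atlas geometry, vascular
trees, scanner shading or focus artifacts, stain bleed-through beyond the
linear model, partial-volume effects across section thickness, or touching/
overlapping bleeds (watershed splitting is out of scope). Passing tests
therefore demonstrate correctness of the algorithms under the stated
optical model and noise, not segmentation accuracy on real tissue, where
stain variability and morphology are far richer.

## Problem sizes used in validation

The test suite and the acceptance script size their simulations for a
single-CPU desk run: stain round trips on 100 random 8 × 8 fields; 200
Otsu histograms and 100 particle masks against brute-force oracles; 20
registration pairs plus one 40-section stack for drift; the full
segment–align–reconstruct–quantify chain on the default 40-section brain
(YIQ track); classifier recall over five 8-section held-out stacks (the
model is trained once on an 8-section training stack — one model per study,
as in the emulated workflow); five 4-section artifact-rich stacks for the
method-ordering comparison; and 1000 Kruskal–Wallis null simulations. Power
checks at the study's n = 3 brains per group use summary-level lognormal
burden draws rather than full image simulation.

## Known limitations

* MSE rigid registration assumes mostly overlapping, similar silhouettes;
  it has no safeguard against gross shape change (e.g. torn sections).
* The YIQ noise floor assumes some true background is visible in the frame;
  a frame fully covered by tissue falls back to the unfloored threshold.
* The HDAB track's over-counting is intrinsic (and intentional here); its
  outputs should not be used unreviewed.
* Density uses per-section 2D counts; a bleed spanning several sections is
  counted once per section it appears in (the 3D-merged count is available
  from the assembled volume).
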