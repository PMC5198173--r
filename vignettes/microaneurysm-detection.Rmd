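---
title: "Detecting microaneurysms in fundus photographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microaneurysms in fundus photographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusMA)
```

## The screening problem

Microaneurysms (MAs) — saccular outpouchings of retinal capillaries, tens of
microns across — are the earliest lesion of diabetic retinopathy (DR) visible
in a fundus photograph. Most patients attending DR screening have no
retinopathy, so an automated system that can reliably confirm the *absence*
of MAs lets human graders concentrate on the images that need them. The
difficulty is that the background an MA must be detected against varies
enormously: retinal pigmentation differs across individuals and racial
groups, illumination is uneven, media opacity and camera settings differ,
and vessel calibre itself varies. `fundusMA` implements a detection pipeline
designed around that variability, together with a synthetic image generator
and the screening statistics used to evaluate such systems.

The pipeline has three stages, each with a deliberately different
sensitivity/specificity balance:

1. **Preprocessing** standardizes geometry and removes background structure.
2. **Candidate extraction** finds every dark blob that could be an MA — high
   sensitivity, low specificity.
3. **Symmetry classification** keeps only candidates whose cross-sectional
   intensity profiles are rotationally symmetric — restoring specificity.

An image with at least one confirmed MA is called DR-positive; an image with
none is considered free of DR.

## Stage 1: preprocessing

**Field of view.** Fundus photographs show the illuminated retina as a
bright disc on a dark surround. The mask is the largest connected region
above an intensity threshold (default 0.1 on the RGB mean), and its circle
fit uses the region centroid with the area-equivalent radius
$r = \sqrt{A/\pi}$ — for near-circular masks this is as accurate as a true
enclosing-circle fit and considerably more robust to a few stray bright
pixels. Frames where the bright region covers less than 20% or more than
95% of the frame are rejected as having no usable field.

**Quality gate.** An image is gradable when the vasculature is resolvable,
the field fills a plausible fraction of the frame (0.2–0.95), and the field
centre sits within 15% of the frame diagonal of the frame centre (a proxy
for correct fovea centring; true disc/fovea localization is out of scope).
Vessel visibility is scored as 100 times the 95th percentile of the gradient
magnitude of the green channel after Gaussian smoothing with $\sigma = 2$
px, measured inside the field away from its rim. The smoothing matters:
pixel noise inflates a mean-gradient statistic to the point where it cannot
distinguish a vessel-free disc from a normal retina, whereas after smoothing
the statistic separates the two by more than a factor of five. The default
threshold (0.35) was calibrated on synthetic fixtures: vessel-bearing scenes
score above 0.6 at every pigmentation level, vessel-free or hundredfold
attenuated scenes below 0.2. These heuristics are explicit stand-ins for a
clinical gradability assessment, which is stated only verbally in screening
practice.

**Standardization.** All pixel sizes in the pipeline are meaningful only at
a fixed scale. Images are cropped to the field bounding box plus a 16-px
margin and rescaled (bilinear) so the field-of-view diameter is 768 px — at
this scale a typical MA is about 7 px across, and the two tuned sizes below
(7-px lesions, 31-px scanning region) are fixed in canonical pixels. Camera
resolutions from 768×576 up to 3888×2592 map onto this one scale. When the
measured scale factor is within $10^{-3}$ of 1 the resampling is skipped, so
already-canonical images pass through bit-identically. The crop offset and
scale factor are recorded so detections can be reported in native
coordinates.

**Red-free filter and shade correction.** The green channel is the standard
red-free view: haemoglobin absorbs green light, so vessels, MAs and
haemorrhages appear dark with maximal contrast. The background is estimated
by a running median over a 65-px square window — a median, not a mean, so
that lesions themselves do not bias the estimate — and the *darkness map*
is `max(background − intensity, 0)`. The clipping is what suppresses bright
lesions: exudates and cotton-wool spots lie above the background and clip
to zero, and the narrow gap between two adjacent bright lesions cannot
exceed the candidate depth threshold because the median background there is
still the ordinary retina. Outside the field, pixels are filled by radially
extending the rim intensity before filtering; filling with a global
constant instead leaves spurious darkness of order 0.07 at the rim whenever
there is an illumination gradient. Frame edges are mirrored. A global
illumination offset added to the whole image shifts intensity and
background equally, leaving darkness unchanged.

**Enhancement.** The darkness map is smoothed with a Gaussian
($\sigma = 1$ px, kernel truncated at $4\sigma$, normalized, symmetric
boundary), matched to the few-pixel scale of MAs: it raises their contrast
against pixel noise while preserving the total mass of interior structures.

## Stage 2: multilayered dark-object filtering

The enhanced darkness map is cut into $K = 6$ nested binary layers at
thresholds evenly spaced from the depth floor $\tau_d = 0.02$ up to the
99.9th percentile of the map inside the field. Because the thresholds
increase, layer $t+1 \subseteq$ layer $t$ by construction; a lesion appears
in every layer its depth reaches, so deep lesions are seen many times at
successively tighter supports. In each layer, 8-connected components are
kept as candidates when they look like MAs:

* equivalent diameter $2\sqrt{A/\pi}$ between 3 and 11 px (centred on the
  nominal 7-px lesion; larger blobs are haemorrhages, smaller ones noise),
* circularity $4\pi A / P^2 \ge 0.55$, where the perimeter $P$ counts
  exposed 4-neighbour pixel edges — under this counting a digital 7-px disc
  scores about 0.59 and a 3×40 vessel-like bar about 0.20, so the threshold
  cleanly rejects vessel segments while keeping discs,
* mean enhanced darkness at least $\tau_d$,
* centroid at least 16 px inside the field rim (so the later 31-px scanning
  disc fits). For the circular field this erosion is computed analytically
  from the circle fit rather than morphologically — equivalent for discs
  and much cheaper.

Centroids are intensity-weighted, which locates a symmetric lesion to well
under a pixel. The same lesion found in several layers is merged: within a
3-px radius only one representative survives, chosen greedily from the
deepest layer, ties broken by larger depth and then lexicographic centroid.
This stage is deliberately permissive — its contract is that essentially
every true MA yields a candidate; false candidates are the next stage's
problem. The defaults ($K$, size band, circularity, $\tau_d$, merge radius)
were calibrated on synthetic fixtures.

## Stage 3: SSA rotational-symmetry classification

An MA is a small round dark dot: a 1-D intensity profile through its centre
looks the same at every orientation. Vessels, vessel crossings and
haemorrhages are elongated, so their profiles change shape with
orientation. For each candidate, 12 profiles are sampled (bilinear, 1-px
spacing) along diameter lines of a 31-px scanning region at 15° steps over
[0°, 180°), from the shade-corrected intensity `1 − darkness` — sampling
the corrected map rather than the raw green channel means an illumination
gradient cannot break the symmetry.

Each profile is smoothed by singular spectrum analysis: the profile is
embedded in its Hankel trajectory matrix with window $w = 8$, decomposed by
SVD, and reconstructed from the leading $k = 2$ elementary matrices by
diagonal averaging. With $k = w$ the transform is exactly the identity; with
$k = 2$ it keeps the local mean and the dominant dip shape while stripping
pixel noise, which would otherwise dominate pairwise correlations of
31-sample profiles. $w = 8$ places the window at about a quarter of the
profile length, comfortably above the 7-px lesion scale; the grouping rule
(leading components) is the standard low-rank choice.

Similarity is the Pearson correlation over all 66 orientation pairs of
reconstructed profiles, and the decision statistic is the **minimum** over
pairs — "similar at all orientations" is a worst-case claim, and using the
minimum is what rejects a crossing, where profiles along the two vessels
agree with each other but not with the oblique ones. Zero-variance
(constant) profiles are assigned correlation 0: a flat region is not a
lesion. A candidate is confirmed when the minimum pairwise correlation
reaches $\theta_{sym} = 0.7$ (calibrated on synthetic fixtures; lowering
the threshold can only confirm more candidates, never fewer) *and* every
orientation shows a central dip. The dip guard — the central sample must
attain the minimum of the central third of the profile, within 2% of the
profile range — keeps flat or bright-centred regions from passing on
correlation alone; the small relative tolerance is there so a sub-pixel
centroid offset on a sampled grid cannot flip the flag. Candidates whose
scanning disc would cross the image boundary are kept but classified
negative with a border flag.

## The synthetic generator

No public image set accompanies this pipeline, so the package ships a
generator whose scenes exercise every failure mode the pipeline is designed
for. Scenes are rendered at the canonical scale (default 808×808 frame,
384-px field radius, so standardization is the identity) in a fixed order:

* **Background**: the green level is `0.25 + 0.5 * pigment_level` — an
  explicit, crude linear proxy for pigmentation; a linear illumination
  gradient (default amplitude 0.15) in a seed-chosen direction is applied
  multiplicatively.
* **Vessels**: 7 random-walk vessels radiate from the centre with widths
  tapering from 3–7 px and green-channel depth 0.08–0.14, then a light
  $\sigma = 0.8$ blur softens their edges. Overlaps combine by maximum, so
  crossings are not artificially darker than their branches.
* **Haemorrhages**: flat-topped supergaussian elliptical blots
  ($e^{-q^2/2}$ in the ellipse coordinate $q$), semi-major 6–12 px, aspect
  ratio 3–4.5, depth 0.10–0.18. The flat top matters: smooth anisotropic
  Gaussian dips of different widths still correlate ~0.8 across
  orientations and would defeat the symmetry test's design, whereas
  flat-topped blots (like real blot haemorrhages, which have fairly uniform
  density and defined edges) give near-constant major-axis profiles and
  correlate ~0.5–0.65.
* **Exudates**: bright supergaussian discs, radius 4–10 px, amplitude
  0.10–0.20.
* **MAs**: isotropic Gaussian dips, diameter 5–9 px ($\sigma =$
  diameter/4), depth 0.08–0.18, placed at least 20 px from vessels and all
  other lesions so that ground-truth matching within a 3-px radius is
  unambiguous.
* **Noise**: i.i.d. Gaussian pixel noise, $\sigma = 0.01$.

Scenes are bit-reproducible given the seed, and the caller's RNG state is
untouched. Cohorts realize their MA prevalence as the exact deterministic
count `round(n × prevalence)` rather than binomial sampling, so cohort-level
statistics carry no Monte-Carlo noise. The six-cohort preset (Kenya,
Botswana, Norway, Mongolia, China, UK) uses the prevalences reported for
those screening datasets (9.2%, 30.4%, 9.6%, 11.3%, 8.2%, 11.7%) and six
pigmentation levels spanning [0.2, 0.8].

What the generator does **not** emulate: optic disc and fovea, laser scars,
drusen, media haze, vessel reflexes, camera vignetting beyond a linear
gradient, compression artefacts, and irregular lesion shapes. Passing the
synthetic end-to-end tests therefore demonstrates that the implementation
realizes the intended algorithm under controlled conditions — not clinical
performance on real photographs.

## Screening statistics

Per-image decisions against ground truth give the usual confusion counts;
sensitivity and specificity are per cohort. Evaluation is per image
throughout (one image per patient). Cross-cohort dispersion is the
**population** standard deviation (divisor $n$): the cohorts studied are the
whole population of interest, not a sample from a larger one, and this is
the form under which the reference dispersion values (1.3 and 1.5
percentage points) are reproduced from the reference sensitivities and
specificities. Predictive values are standardized to an assumed population
prevalence rather than the study case mix:

$$\mathrm{PPV} = \frac{s\,p}{s\,p + (1-c)(1-p)}, \qquad
  \mathrm{NPV} = \frac{c\,(1-p)}{c\,(1-p) + (1-s)\,p}$$

with sensitivity $s$, specificity $c$ and prevalence $p$ (27% for China and
Mongolia, 56% for Kenya and Botswana, 47% for Norway and the UK). Reporting
follows screening convention: sensitivity/specificity and their SDs to one
decimal, predictive values to the whole percent.

```{r reference}
reproduce_reference_report()
```

## Numerical choices and problem sizes

* Median filter: Huang's sliding-histogram algorithm over 16-bit quantized
  intensities (two-level 256×256 histogram with a running median). The
  quantization error is below $2 \times 10^{-5}$, negligible against the
  0.02 depth threshold.
* Gaussian blur: separable, kernel truncated at $4\sigma$ and renormalized,
  symmetric (mirror) boundary; it matches a direct 2-D convolution oracle
  to $10^{-9}$.
* Connected components: 8-connectivity, two-pass union-find; labels in
  first-encounter order.
* Ties in candidate merging break by layer, then depth, then lexicographic
  centroid, making the merge deterministic.
* Degenerate inputs: an identically-zero enhanced map yields empty layers
  and no candidates; constant profiles score correlation 0; a frame without
  a plausible bright disc raises a "no field of view" error; quality-gate
  rejections carry machine-readable reasons.
* Desk-scale problem sizes used by the test suite: end-to-end cohort
  evaluation runs the six-cohort preset at 100 images per cohort at full
  canonical scale; oracle-equivalence checks run on ≤64×64 fixtures where
  exhaustive brute-force computation is exact and fast.

## Known limitations

The quality gate is a pair of scalar heuristics, not a clinical gradability
model. The shade-correction window (65 px) assumes lesions are small
relative to the window; large confluent haemorrhages would bias the local
background. The symmetry test assumes an approximately isotropic lesion;
an MA overlapping a vessel within the scanning region inherits the vessel's
anisotropy and may be missed. Pigmentation is modelled only as a global
background level, not as texture. Real-image performance must be
established on real, expert-graded photographs.
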