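# fundusMA

Automated microaneurysm (MA) detection in colour digital fundus photographs,
for diabetic retinopathy (DR) screening. Microaneurysms are the earliest
visible DR lesion — small round dark dots in the red-free (green-channel)
view of the retina — and most patients attending screening have none, so a
system that reliably confirms their *absence* can remove a large share of
the human grading workload. `fundusMA` is aimed at researchers studying
automated DR screening: it provides the detection pipeline, a synthetic
fundus-image generator with ground truth for controlled evaluation, and the
screening statistics used to report such systems.

## The method

Detection is a three-stage pipeline:

1. **Preprocessing.** The circular field of view is detected; images failing
   a quality gate (vasculature not resolvable, field badly placed) are
   excluded. Gradable images are cropped and rescaled so the field diameter
   is 768 px, passed through the red-free filter (green channel), and shade
   corrected: a 65-px running-median background *B* is subtracted and
   clipped, giving the darkness map *D* = max(*B* − *I*, 0), which removes
   pigmentation and illumination structure and suppresses bright lesions
   (exudates, cotton-wool spots). A Gaussian filter (σ = 1 px) then enhances
   small dark structures.
2. **Candidate extraction.** A multilayered dark-object filter cuts the
   enhanced map into nested threshold layers and keeps 8-connected
   components tuned to lesions ≈7 px in diameter (equivalent diameter
   3–11 px, circularity 4πA/P² ≥ 0.55, depth ≥ 0.02), merging duplicates
   across layers. High sensitivity, low specificity by design.
3. **Symmetry classification.** For each candidate, 12 cross-sectional
   intensity profiles are sampled through its centre (31-px scanning region,
   15° steps), smoothed by singular spectrum analysis (Hankel embedding,
   window 8, leading 2 components, diagonal averaging), and compared by
   Pearson correlation over all orientation pairs. A candidate is a
   confirmed MA when the *minimum* pairwise correlation reaches θ = 0.7 and
   every orientation dips at the centre — true MAs are rotationally
   symmetric; vessels, crossings and haemorrhages are not.

An image with at least one confirmed MA is DR-positive. Cohort-level
performance is summarized by sensitivity/specificity, their cross-cohort
population standard deviations, and prevalence-standardized predictive
values PPV = s·p / (s·p + (1−c)(1−p)) and NPV = c·(1−p) / (c·(1−p) + (1−s)·p).

See `vignettes/microaneurysm-detection.Rmd` for the full model description,
parameter choices and limitations.

## Worked example

Generate a synthetic scene with five microaneurysms plus vessels,
haemorrhages and an exudate, and run the full detector:

```r
library(fundusMA)

sc  <- generate_scene(scene_params(seed = 42, n_ma = 5, n_haem = 2, n_exudate = 1))
res <- detect_image(sc$image)
res$decision
#>       image_id gradable n_mas dr_positive truth_positive
#> 1 synthetic_42     TRUE     5        TRUE             NA

res$candidates[res$candidates$is_ma,
               c("row", "col", "equivalent_diameter", "depth", "min_pair_corr")]
#>      row     col equivalent_diameter depth min_pair_corr
#>  556.990 668.207               3.568 0.123         0.993
#>   87.270 448.540               4.222 0.083         0.988
#>  251.186 426.009               3.568 0.076         0.978
#>  444.861 652.196               6.676 0.042         0.983
#>  377.914 286.818               4.918 0.034         0.972
```

All five planted MAs are confirmed (centroids in 0-based canonical
coordinates; `min_pair_corr` is the worst-case profile correlation, well
above the 0.7 threshold), and the image is correctly flagged DR-positive.
The scene's haemorrhages and vessel crossings produce no confirmed MAs.

Cohort-scale simulation and evaluation:

```r
specs <- six_cohort_preset(n_images = 100)   # Kenya ... UK, reference prevalences
run_simulate(specs[[1]], "out/sim")          # PNGs + truth.csv
run_detect("out/sim", "out/det")             # per-image JSON + summary.csv
```

A thin command-line wrapper over these functions is installed at
`inst/cli/fundusma.R` (subcommands `detect`, `simulate`, `evaluate`,
`reproduce`).

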