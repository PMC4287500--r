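# tendonseg

Automatic segmentation of the supraspinatus (SSP) tendon in B-mode
musculoskeletal ultrasound.

On a longitudinal shoulder view the SSP tendon is a convex, hypoechoic band
compressed between two hyperechoic curvilinear structures — the subacromial
bursa above and the humeral cortex below. Reading its texture for tears and
tendinosis is highly operator-dependent; an automatic, reproducible
delineation of the tendon region (which, by radiologist convention,
*includes* bursa and cortex) is the first step toward quantitative
diagnosis. This package implements a full segmentation pipeline around
those three anatomical invariants, plus a synthetic phantom generator with
known ground truth so every stage is testable without clinical data.

## Method

For an image $I \in [0,1]^{m\times n}$, `segment_tendon()` runs:

1. **Rayleigh adaptive contrast enhancement** — histogram matching to a
   Rayleigh($\sigma{=}0.4$) target through the inverse CDF
   $y = \sigma\sqrt{-2\ln(1-c)}$, followed by 10 iterations of
   Perona–Malik anisotropic diffusion
   $I \leftarrow I + \lambda\sum_d g(|\nabla_d I|)\nabla_d I$,
   $g(s)=e^{-(s/\kappa)^2}$, which despeckles homogeneous tissue while the
   edge-stopping conductance preserves the band boundaries.
2. **Directional feature extraction** — a real-valued fast discrete
   curvelet transform via spectrum wrapping (an exact tight frame,
   implemented from scratch: round-trip error ~1e-14, Parseval exact),
   decomposed at scale 2 with 16 orientations; only the largest 6.5% of
   coefficients are kept and the image is reconstructed from them,
   concentrating the bright curvilinear structures.
3. **Mask generation** — rescale to 256 gray levels; threshold at
   $T=\mu+\alpha\sigma$ ($\alpha{=}0.5$); 8-connected component analysis;
   area filter (~5000 px at the canonical 421×580 size, scaling with pixel
   count); geodesic morphological cleanup (closing and opening by
   reconstruction with a 17×6 elliptical disc) and a final area filter.
4. **Boundary smoothing** — two least-squares quadratics through the upper
   and lower envelopes of the candidate mask; the final mask fills between
   the curves across the full lateral extent, bridging any gaps and
   enclosing bursa, tendon and cortex in one smooth region.

Segmentations are scored with area-overlap metrics
(TPR $=|A_a\cap A_m|/|A_m|$, FPR $=|A_a\setminus A_m|/|A_a|$, pixel
accuracy, Dice), and case-level pathology counts aggregate to sensitivity
and specificity. See the methods vignette
(`vignettes/tendon-segmentation.Rmd`) for the full model, parameter table
and design rationale.

## Worked example

```r
library(tendonseg)

ph <- generate_phantom(phantom_spec(rng_seed = 7))
ph
#> <phantom 421x580> tendon width 70.0 px, truth area 50854 px, 2155 outlier px

res <- segment_tendon(ph$image)
res
#> <segmentation_result> success, final mask 66037 px
#> # A tibble: 4 × 3
#>   stage    seconds note
#>   <chr>      <dbl> <chr>
#> 1 enhance    0.28  sigma=0.4, 10 diffusion iterations
#> 2 curvelet   0.539 scale 2/16 orientations, 6.5% coefficients, energy ratio 0.5…
#> 3 maskgen    2.52  threshold 0.3721, 2578 component(s) before area filter, 2 kep…
#> 4 boundary   0.022 0 clipped column(s), area 66037 px

overlap_metrics(res$final_mask, ph$truth_mask)[, c("tpr", "fpr", "acc", "dice")]
#> # A tibble: 1 × 4
#>     tpr   fpr   acc  dice
#>   <dbl> <dbl> <dbl> <dbl>
#> 1     1 0.230 0.938 0.870
```

Every ground-truth pixel is recovered (TPR 1). The FPR of 0.23 is mostly
structural: the final mask encloses the full thickness of the bursa and
cortex bands while the truth convention stops at their midlines. The fitted
boundary model is available as `tidy(res$boundary)`; `plot(res)` overlays
the mask.

A full synthetic study — generate a cohort with varied tendon width,
position, intensity and curvature; segment; score — is one call:

```r
ev <- evaluate_phantom_cohort(n = 20, seed = 42)
ev$report$summary   # mean tpr/fpr/acc/dice over the cohort
```

The command-line front end (`inst/cli/tendonseg`) wraps the same functions:
`tendonseg phantom --n 20 --seed 42 --out DIR`,
`tendonseg segment --input img.png --out DIR --dump`,
`tendonseg cohort --images DIR --truths DIR --out report.csv`,
`tendonseg energy-scan --image img.png --out table.csv`.

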