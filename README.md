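# mmfscope

Desk-scale simulation of transmission-matrix imaging through a
multimode-fiber (MMF) biopsy needle, plus the downstream texture /
statistics / clustering pipeline that discriminates tumor from normal
tissue along a puncture path.

A hair-thin MMF inside a biopsy needle scrambles light, but the scrambling
is linear: once the fiber's complex **transmission matrix** `T` is
calibrated (here: simulated off-axis interferometry), setting the input
phases to the conjugate of one row of `T` focuses the output to a single
spot, and raster-scanning that spot forms a fluorescence image at the
needle tip. For phase-only control of `N` modes the focus enhancement over
the speckle background is

    eta = 1 + (pi/4) (N - 1),

and the diffraction-limited resolution is the Rayleigh radius
`0.61 lambda / NA` (about 1.3 µm for an NA 0.37 probe at 785 nm). During a
puncture the focal plane is re-locked by maximizing the Brenner sharpness
`B = sum [I(x+2,y) - I(x,y)]^2 + sum [I(x,y+2) - I(x,y)]^2` (normalized,
mask-restricted) across candidate planes.

Downstream, each image is reduced to six texture metrics — GLCM contrast
and homogeneity; average magnitude spectrum (AMS); high-frequency energy
(HFE); spectral frequency contrast `ln(r95/r50)`; spectral frequency
variance `log10(Var[E]/Mean[E]^2)` of the radial spectral-energy profile —
compared between groups with assumption-routed tests (Shapiro–Wilk +
Levene → Student / Welch / Mann–Whitney), Benjamini–Hochberg FDR across
the six metrics (q = 0.05), and Cliff's delta effect sizes. Unsupervised
discrimination clusters two feature views (gray-level histograms; Canny /
Sobel edge summaries) with PCA + K-means (k = 2) and combines them with an
or-toward-tumor rule that can only raise sensitivity.

No real in vivo data are available; the package ships synthetic phantom
generators (alveolar lattice for normal lung, disordered heterogeneous
blob fields for tumor, line-pair and two-point optical targets) so every
stage is testable offline. See the methods vignette
(`vignettes/mmf-needle-simulation.Rmd`) for the models, defaults, and what
a green test does and does not establish.

## Worked example

```r
library(mmfscope)

ch  <- cohort(100, seed = 1)     # 100 normal + 100 tumor phantoms
tab <- feature_table(ch)         # six metrics per image
res <- compare_groups(tab)       # routed tests + BH-FDR + Cliff's delta
res[, c("metric", "test", "q", "significant", "delta", "direction")]
#>        metric           test        q significant  delta direction
#> 1    contrast        welch_t 2.28e-18        TRUE  0.699         1
#> 2 homogeneity mann_whitney_u 5.12e-34        TRUE -1.000        -1
#> 3         ams mann_whitney_u 5.12e-34        TRUE  1.000         1
#> 4         hfe        welch_t 4.56e-68        TRUE  1.000         1
#> 5         sfc mann_whitney_u 2.47e-16        TRUE  0.671         1
#> 6         sfv mann_whitney_u 1.36e-18        TRUE  0.724         1

discriminate_cohort(cohort(c(194, 193), seed = 2), seed = 0)
#> <cluster_result> intensity acc 0.995 | edge acc 1.000 |
#>   combined acc 1.000 sens 1.000 spec 1.000 (or_tumor)
```

All six metrics pass BH-FDR with the expected directions (tumor: contrast
up, homogeneity down, all four spectral metrics up), with moderate to very
large Cliff's deltas; on the 387-image cohort both clustering views exceed
0.85 aligned accuracy and the or-rule combination never lowers
sensitivity.

The optical layer:

```r
cfg <- optical_config(0.785, 0.37, core_diameter_um = 125)
mode_count_estimate(cfg)        # ~ 17130 guided modes
tm  <- generate_tm(cfg, n_modes = 256, seed = 1)
est <- simulate_offaxis_calibration(tm, noise_sd = 0)
est$fidelity                    # 1 (noiseless recovery is exact)
```

## Command line

```sh
Rscript exec/mmfscope simulate-tm --na 0.37 --wavelength-um 0.785 \
    --core-um 125 --modes 256 --seed 1 --out tm_dir
Rscript exec/mmfscope phantom --kind cohort --n 20 --seed 1 --out imgs
Rscript exec/mmfscope metrics --images imgs --out metrics.csv
Rscript exec/mmfscope stats --metrics metrics.csv --out results.csv
Rscript exec/mmfscope cluster --images imgs --seed 0 --out clusters
```
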