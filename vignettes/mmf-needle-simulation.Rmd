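---
title: "Simulating a multimode-fiber biopsy needle: models, phantoms, and the tumor/normal discrimination pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a multimode-fiber biopsy needle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmfscope)
```

## The problem

A multimode fiber (MMF) threaded through a biopsy needle can act as a
hair-thin microscope: light sent into the fiber emerges scrambled, but the
scrambling is linear and, once characterized by a *transmission matrix*
(TM), it can be undone. Shaping the input wavefront to the phase conjugate
of one TM row focuses the light to a single spot on the fiber facet;
raster-scanning that spot and recording the returned fluorescence builds an
image pixel by pixel. Combined with an intravascular dye (ICG), this gives
diffraction-limited fluorescence images of tissue *at the needle tip*
during a puncture, and the images carry enough texture to separate tumor
from normal parenchyma.

`mmfscope` reimplements this system as a desk-scale simulation plus the
full downstream analysis: TM generation, focusing, binary Lee hologram
encoding (how a DMD displays a phase map), off-axis interferometric
calibration, angular-spectrum propagation, Brenner-function autofocus,
point-scan image formation, synthetic tissue phantoms, six texture
metrics, assumption-driven group statistics with BH-FDR and Cliff's delta,
and dual-view PCA/K-means discrimination. No real data ships with the
package; everything downstream is exercised on phantoms whose statistical
structure mimics how these tissues present in ICG-enhanced fluorescence
microendoscopy.

## Optical model and its assumptions

**Transmission matrix.** The fiber is treated as a fully scrambling linear
map: i.i.d. circular-complex Gaussian entries, each column (input mode)
normalized to unit mean square so every mode carries equal energy. No
fiber eigenmode physics, polarization, bending dynamics, or
mode-dependent loss: the discrimination pipeline needs realistic speckle
statistics, not modal physics. The guided-mode count helper uses the
standard estimate $(\pi d\,\mathrm{NA}/\lambda)^2/2$.

**Focusing.** `focus_mask()` sets the input phases to the negated argument
of the target pixel's TM row. For phase-only control of $N$ i.i.d.
Gaussian modes the expected intensity enhancement over the mean speckle
background is $1 + \frac{\pi}{4}(N-1)$; `focus_enhancement()` measures it
with the background evaluated as the exact expectation over random input
phases, $\sum_k |t_k|^2 / N$.

**Lee holograms.** A DMD is binary and amplitude-only; a phase map
$\varphi$ is displayed by thresholding $\cos(2\pi x/T + \varphi) \ge 0$
on a carrier of period $T$ pixels and reading out the first diffraction
order. Decoding mirrors the physical readout: a circular Fourier window of
radius half the carrier frequency, followed by exact carrier removal.
Binarization on a pixel grid is *not* benign: harmonics of order
$k \equiv \pm 1 \pmod T$ alias exactly onto the carrier with amplitude
$1/k$, and sharp fringe edges contribute broadband quantization noise of
which the window captures an area-proportional share. Two consequences
drove the defaults: odd carrier periods push the aliased harmonic orders
to $2T\pm1$ (even-order harmonics of a square wave vanish), and the
residual floor depends on the commensurability of $T$ with the device
grid. The default $T = 17$ on a $256^2$ device gives a round-trip phase
RMS error of about 0.05 rad for smooth masks (contract: < 0.1 rad);
small or commensurate grids can be several times worse.

**Off-axis calibration.** Each probe mode's output field is interfered
with a tilted plane-wave reference and recovered from one intensity
image by Fourier-filtering the off-axis sideband. For a full-band speckle
field this only works if the camera oversamples the field: at the field's
own Nyquist rate the sideband, its conjugate, and the autocorrelation term
necessarily overlap. The camera model therefore oversamples 5x, places
the carrier at $(3/8, 3/8)$ cycles per camera pixel, and demodulates with
a square window exactly matching the object band; all four hologram terms
are then disjoint *including circular wrap-around*, and noiseless
recovery is exact (fidelity 1 up to the global phase, which is fixed by
making the first entry real-positive). A 4x camera still suffers a
single-bin wrap collision of the conjugate sideband (fidelity ~0.998).
Camera noise is additive Gaussian, parameterized as a fraction of the mean
hologram intensity.

**Propagation.** Angular-spectrum method with evanescent components set to
zero: unitary on the propagating band, hence exactly invertible by
propagating $-z$. 3-D TM stacks compose the facet matrix with these
propagators.

**Image formation.** A single-bucket (non-descanned) detector means the
effective PSF is the illumination focus intensity. `"ideal_psf"` mode
convolves the phantom with the Airy intensity pattern whose first zero is
at the Rayleigh radius $0.61\lambda/\mathrm{NA}$ (~1.3 µm for the
NA 0.37 probe at 785 nm); `"speckle"` mode forms each pixel from the
actual phase-conjugate focus, speckle background included. Convolution
pads by edge replication — tissue extends beyond the frame, and zero
padding would vignette the border and corrupt border-sensitive texture
statistics. Poisson noise is parameterized by the expected photon count at
the brightest pixel (default 500 when imaging through the fiber).

**Autofocus.** The Brenner measure is the shift-2 squared difference
summed over both axes (rotation robustness), restricted to pixel pairs
inside the circular field of view and normalized by the pair count, so
values are comparable across mask sizes. Out-of-focus planes are modeled
geometrically: a slice at axial distance $\Delta z$ is blurred with a
Gaussian of $\sigma = \tfrac12\,\mathrm{NA}\,\Delta z$ before the
in-focus PSF applies. Ties in the plane search break toward the smallest
$|z|$ (the facet is the mechanically locked reference). The number of planes and their spacing are free arguments: no single
choice is canonical for a real instrument.

## What the phantoms emulate — and what they do not

Normal lung at the terminal alveoli: *regularly shaped, similarly sized
round-to-oval dark voids bordered by bright septa*. `alveolar_phantom()`
paints a jittered hexagonal lattice of dark ellipses (aspect ≤ 1.3) with
bright sinusoidal-profile rims on a moderate background, a gentle
illumination field, and fine detector noise smoothed by the optical blur.
Defaults: 256×256 at 0.4 µm/pixel (a hundred-micrometer-scale field),
mean void radius 8 µm (an order-of-magnitude choice for terminal
alveoli at this field size — configurable, not measured), radius CV 0.15, jitter 0.3.

Tumor tissue: *disorganized, heterogeneous, rich in fine-scale content,
with a higher proportion of bright pixels*. `tumor_phantom()` blends
(i) spectrally shaped $1/f^{\beta}$ blob noise with $\beta = 2.5 - 1.5\,
d$ falling as `disorder` $d$ rises, (ii) sharp-edged bright clumps (a
logistic threshold of the blob field — the "stacked" cell masses),
(iii) per-pixel fine grain scaled by $d$, and (iv) multiplicative
lognormal patchiness (`heterogeneity`) at a ~14 µm scale, on a brighter
mean than normal tissue. At $d = 0$ the alveolar generator is returned
unchanged (continuity limit). The blend weight is $(1-d)$ alveolar
$+\,d$ tumor field.

These choices were made *to produce the expected direction of every
metric simultaneously* (tumor: contrast up, homogeneity down, all four
spectral metrics up) and then frozen: the patchiness concentrates
spectral energy at low radius (raising the spectral-frequency variance and
pulling $r_{50}$ down, hence raising the spectral-frequency contrast),
while the fine grain and clump edges supply high-frequency energy, GLCM
contrast, and reduced homogeneity. A green acceptance run therefore
establishes that the *pipeline* orders, tests, and separates cohorts
correctly when the stated contrasts are present — it does not validate
the generators against real tissue, and the phantoms make no claim of
anatomical fidelity (no bronchioles, vessels, septal continuity, motion,
or depth-dependent scattering).

## The six metrics and their conventions

GLCM contrast and homogeneity use 32 gray levels quantized inside the
field-of-view mask, symmetric co-occurrence averaged over the four
distance-1 offsets — all standard defaults in texture analysis, chosen
once and exposed as arguments. Spectral metrics mask-fill with the masked mean,
subtract the mean (DC vanishes), and bin $|F|^2$ by integer frequency
radius. `ams` is the mean non-DC $|F|$; `hfe` the energy fraction beyond
0.25 of the Nyquist radius (cutoff exposed); `sfc` is
$\ln(r_{95}/r_{50})$ of the cumulative radial profile (natural log — the
source says only "log ratio"); `sfv` is $\log_{10}$ of the
variance-to-mean-squared ratio of the profile with an $10^{-12}$ guard.
The spectral-frequency contrast is sometimes described as a
spectral-centroid variant; this package commits to the cumulative-
quantile definition above. Spatial metrics are
min–max normalized over the pooled groups before testing, spectral
metrics tested raw.

## Statistics

Test routing: Shapiro–Wilk on each group and median-centred
(Brown–Forsythe) Levene at $\alpha = 0.05$ → Student's t / Welch's t /
two-sided Mann–Whitney U (exact below $n = 20$ without ties, otherwise
normal approximation with continuity and tie correction). BH step-up is
applied across exactly the six metrics at $q = 0.05$; effect sizes are
Cliff's delta with ties counting zero. Note that with $\alpha = 0.05$
screening, two truly Gaussian equal-variance samples route to Student's t
only ~86% of the time — the screening tests themselves have a 5% false
alarm rate each; the test suite checks the routing *rule*, not an
inflated selection frequency. Cohort rows are treated as exchangeable
images; nothing in the pipeline models within-animal correlation.

## Discrimination

The intensity view is a 64-bin gray histogram inside the mask with bin
edges shared across the cohort (absolute brightness is a discriminative
feature). The edge view concatenates overall Canny edge density, densities
in 8 radial annuli, and a 16-bin Sobel gradient-magnitude histogram;
Canny thresholds derive from the gradient distribution (high = 90th
percentile, low = 0.4·high, σ = 1). Images are
resized to 128×128 first. Each view is standardized, PCA-reduced (10
components), and clustered by K-means with $k = 2$ and 20 restarts under
a fixed seed; cluster indices are aligned to truth by the
accuracy-maximizing permutation. The dual-view combination defaults to
*or-toward-tumor*: an image is called tumor if either view says so. On
aligned labels this can only add true (and false) positives, so combined
sensitivity is mathematically ≥ each view's — the operational form of
the two views' complementarity; an and-rule is exposed as an option. t-SNE is provided (`embed_2d()`, a compact exact implementation)
strictly as a seeded visualization with no numeric contract.

The acceptance run generates the 387-image cohort once, extracts both
feature views once, and varies the clustering seed 20 times on top —
re-generating 20 cohorts would multiply runtime without changing what the
check establishes (K-means seed stability).

## Numerical choices and degenerate inputs

* Constant image: GLCM contrast 0, homogeneity 1; zero-energy spectrum
  returns flagged sentinels (`sfv` = $\log_{10}\epsilon$).
* Constant metric column: min–max normalization refuses (degenerate).
* Lee carrier below 4 pixels, reference tilt below the
  sideband-separation bound, zero reference amplitude: errors, not
  silent degradation.
* Impulse placement in the two-point target uses nearest-pixel rounding
  of centre ± separation/2 — resolution tests depend on this rule.
* Line-pair duty cycle is exactly 1/2 only when the period is an even
  integer number of pixels; the Lee encoder samples at pixel centres so
  its duty cycle is robust to floating-point sign flips at zero
  crossings.
* Random generators consume one integer seed each and are bit-for-bit
  reproducible; cohort images derive per-image seeds from the master
  seed.

## Known limitations

Hardware is out of scope (DMD timing, PMT noise spectra, needle
mechanics, coatings), as are deep denoisers and CNN classification; the
denoise stage is a 3×3 median. The speckle-mode scanner is exact but
$O(\text{pixels}^2 \cdot \text{modes})$ — use it at small grid sizes;
the ideal-PSF mode is the fast path. Phantom realism is statistical only.
Clustering acceptance uses synthetic-cohort thresholds (accuracy ≥ 0.85
per view) rather than reproduction of an in vivo number: no deposited in
vivo image set exists to reproduce.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
ch  <- cohort(100, seed = 1)              # 100 normal + 100 tumor phantoms
tab <- feature_table(ch)                  # six metrics per image
res <- compare_groups(tab)                # routed tests + BH + Cliff's delta
res[, c("metric", "test", "q", "significant", "delta", "direction")]

cl <- discriminate_cohort(cohort(c(194, 193), seed = 2), seed = 0)
cl                                        # per-view and combined scores
```
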