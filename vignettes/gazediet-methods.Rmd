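---
title: "Gaze sampling, the spectral diet of foveal cones, and local von Kries adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze sampling, the spectral diet of foveal cones, and local von Kries adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazediet)
```

## The scientific question

A single foveal cone never sees a whole scene at once. What it experiences
over time — its *spectral diet* — is set by where the eyes point, and eye
movements are strongly non-uniform. Two questions follow. First, does the
accumulated history of excitations at one retinal location nonetheless come
to resemble the statistics of the whole scene? Second, if each retinal
location rescales its own signal by the reciprocal of its locally
accumulated input (von Kries adaptation applied *locally*), how closely
does that discount a global illuminant change compared with the textbook
*global* rescaling by the scene mean?

`gazediet` implements the full computational pipeline: hyperspectral scene
input, cone-excitation rendering, eccentricity-dependent retinal sampling
under recorded or simulated gaze, the histogram-correlation convergence
statistic, and the local-versus-global diagonal-correction comparison in
CAM16-UCS. A seeded synthetic-data module generates scenes, daylight
illuminants and gaze traces with the relevant statistical structure, so
every stage is testable without external downloads.

## Rendering scenes to cone excitations

Scenes are wavelength-sampled cubes (`spectral_image`), radiance or
effective reflectance, on the canonical grid 400–720 nm in 10 nm steps (33
bands). Effective reflectance is radiance divided pixelwise by the
direct-illumination spectrum (`radiance_to_reflectance`); relighting
multiplies a reflectance cube pointwise by an illuminant
(`apply_illuminant`). Cone excitations are the numeric integrals

$$q_i = \sum_\lambda L(\lambda)\, S_i(\lambda)\, \Delta\lambda,
\qquad i \in \{L, M, S\},\ \Delta\lambda = 10\ \mathrm{nm}.$$

The package ships its colorimetric tables as plain CSV under
`inst/extdata`: the CIE 1931 2° color-matching functions (10 nm), the CIE
daylight components S0/S1/S2, and a cone-fundamentals table derived from
the CMFs by the Hunt–Pointer–Estévez transform (each channel scaled to
unit peak). The derivation script is `data-raw/make_tables.R`. Any other
corneal fundamentals — for instance a Stockman–Sharpe 2° tabulation — can
be supplied as a CSV via `cone_fundamentals(path = ...)`; none of the
package's qualitative results depend on this choice, because every
statistic compares local and global quantities rendered through the same
fundamentals.

Daylight illuminants of a given correlated color temperature come from the
standard daylight-locus chromaticity polynomial and the S0/S1/S2 basis
(`daylight_spd`), clipped at zero (the basis reconstruction can go
slightly negative) and normalized to luminance integral Y = 100. That
normalization means an illuminant swap changes chromaticity but not the
overall luminance scale — color differences between renderings isolate the
chromatic effect of the illuminant. `cct_of` inverts the pipeline by
nearest-Planckian-locus search in CIE 1960 (u, v), refined over reciprocal
temperature; daylight SPDs round-trip within ±50 K across 4000–10000 K.

## Retinal sampling

At each gaze sample the retinal input is the 5°-diameter patch centered on
fixation. The scene is padded with its own mirror image so every fixation
yields a complete, equally sized patch. Acuity falloff is modelled by a
Gaussian blur whose standard deviation is `sigma0_px` (1 px, about 1
arcmin at the study's 336-px resolution) at the patch center and grows as
the reciprocal of relative cone density with eccentricity. The default
density profile is the smooth stand-in $d(e)/d(0) = (1 + e/e_h)^{-2}$ with
$e_h = 1°$; tabulated profiles load via `density_profile_from_csv`. The
blur sigma is capped at 8 px at the rim for tractability.

Numerically, the spatially varying blur is realised by blurring the padded
field at a small set of sigma levels (geometric between `sigma0_px` and
the cap) and blending adjacent levels linearly in sigma per patch pixel.
Each 1-d blur operator is a truncated (4 sigma) Gaussian band matrix with
rows renormalized to sum to one, so the blur has exactly unit DC gain at
every location — a constant field stays constant to machine precision, and
with a flat density profile the machinery reduces exactly to a fixed-sigma
normalized convolution (this is tested against a brute-force kernel
oracle). The foveal sample is the blurred value at the fixation pixel;
pixel centers sit at half-integer angular coordinates and gaze maps to the
nearest pixel center. Retinal image inversion is ignored — it is a
relabeling that affects no statistic.

## Gaze: recorded-like and model observers

Traces are uniformly sampled at 50 Hz (20 ms). Speeds are per-interval
angular displacements divided by the interval; samples whose incoming
speed exceeds 5 deg/s are excluded from accumulation (attributed to the
later sample of the pair, dropped rather than interpolated; `vmax = Inf`
reproduces the no-exclusion robustness variant). The exclusion is meant
for human-like traces; the random-gaze model teleports at essentially
every frame, so model observers are analyzed with the exclusion disabled.

Three model observers are provided: `simulate_random_gaze` (i.i.d. uniform
positions — the upper-limit control), `simulate_random_walk` (fixed step
length `step_speed * interval` in a uniformly random direction, redrawn
until the step stays in bounds, so the step length is exactly constant;
2.3 deg/s is the recorded modal speed, with 0.77 and 6.9 as one-third and
three times the mode), and `simulate_local_feature` (a walk at 0.77 deg/s
confined to a 0.5°-diameter disc centered on the 5×5-pixel window with the
highest mean CIELAB chroma; ties break to the first window in row-major
order, and the C* white defaults to the scene mean scaled to Y = 100). All
models draw their first position from the shared seed so variants start at
the same frame.

The synthetic human-like generator (`make_gaze`) mixes a slow drift state
(folded normal around 2.3 deg/s, truncated below the 5 deg/s threshold)
with saccades (lognormal around 60 deg/s) at a rate set by
`slow_fraction`, emulating the recorded cumulative speed distribution in
which roughly 80% of shifts fall below 5 deg/s.

## The spectral-diet statistic

For an end frame $n$ the local sample is the set of log10 foveal
excitations of frames 1..n; the global sample is the log10 excitation of
every pixel of the scene's cone image. The bin count comes from the
Freedman–Diaconis rule on the local sample (bin width $2\,\mathrm{IQR}\,
n^{-1/3}$, type-7 quartiles, one bin when degenerate); the same number of
equal-width bins spans the union of the two ranges so both histograms
share edges, and the statistic is the Pearson correlation of the two
relative-frequency vectors. With the default grid (end frames 50 to
15,000 in steps of 1) this yields 14,951 coefficients per cone class.
Excitations are floored at $10^{-6}$ of the global per-class maximum
before the log (real radiances are positive; exact zeros arise only in
synthetic degenerate inputs). Zero-variance histograms give an undefined
correlation, recorded as `NA` and excluded from averaging — never coerced
to zero.

Internally the curve is computed from a growing sorted prefix with
binary-search binning; a test verifies it is identical (to 1e-12) to
binning each end frame from scratch. Note a structural property of the
statistic: the FD bin count grows like $n^{1/3}$, so after the histogram
has converged the continuing bin refinement can slightly *erode* r. The
curve therefore rises steeply and then plateaus with a mild drift rather
than increasing monotonically; tests assert the substantive rise
(early-window r far below late-window r) rather than strict monotonicity.

## Local versus global von Kries adaptation

The scene (as effective reflectance) is relit with a 4000 K daylight
illuminant. Each retinal frame is converted per pixel to CIE XYZ and then
to CAM16 cone-like RGB through the fixed matrix M16 (first row 0.401,
0.650, −0.0515). The local adaptation state at frame $n$ is the
exponentially weighted sum of the blurred RGB retinal history (weights
$\propto e^{-(t_n - t_k)/\tau}$, the most recent frame heaviest; time
constants 1 s and 10 s), and the local correction multiplies the *next*
frame (at $t_{n+1}$) by the per-pixel reciprocal gains, floored at
$10^{-6}$ of the channel maximum. The global correction instead uses the
reciprocal global spatial means of the relit image — one diagonal
transform for the whole field, the classic global von Kries scaling. The
degree-of-adaptation factor of appearance models is fixed at complete
adaptation throughout.

Color differences between the two corrected images are Euclidean distances
in CAM16-UCS. The CAM16 chromatic-adaptation stage (CAT16) is deliberately
skipped — adaptation has already been applied explicitly — so corrected
RGB enters the model at its post-adaptation stage directly. Viewing
conditions default to average surround, adapting luminance 20 cd/m²,
background relative luminance 20, and a neutral reference white (1, 1, 1),
which is exactly where the global correction maps the scene mean; all are
configurable. The scale mapping stimulus to the model's 0–100 range is a
single achromatic factor (100 / mean of the white RGB) — never a
per-channel gain, which would smuggle in a second adaptation. The
post-adaptation stage reproduces the classic published worked example of
the full model (entered after its own adaptation transform) to four
significant figures.

The per-pixel color-difference map is summarized by its median over the 5°
disc (robust to outlier pixels), evaluated at six frames spaced
geometrically from $t_3$ to $t_{n-1}$ — an early start, since even tens of
milliseconds of exposure can influence subsequent perceived color, and the
correction target is the frame after the last history frame. The
`uncorrected_delta_e` baseline compares the scene under its original
illuminant against the 4000 K rendering with no correction at all,
interpreting "uncorrected" as original-versus-test (the alternative —
against a corrected reference — is available by passing explicit viewing
conditions). A CIELAB just-noticeable difference of about 2.2 transforms
to roughly 2.46 in CAM16-UCS; 2.46 is carried as a configured reference
constant on results, not recomputed.

## What the synthetic generators emulate — and what they do not

`make_scene` produces Voronoi mosaics of piecewise-smooth reflectances:
each region is a gray base plus a random combination of six raised-cosine
spectral bumps (centers 420–700 nm), clipped to [0, 1], with
`chroma_spread` scaling chromatic variance, times a smooth low-frequency
shading field (amplitude 0.2 by default) that supplies the continuous
within-region variation real scenes have. `chroma_spread = 0` yields an
exactly uniform gray scene (shading off) for degenerate-case tests.
Scenes span ≈6.9° horizontally, the study's camera geometry. The
generators target *structure* — regions, chromatic variance, speed
distributions — not the full statistics of natural hyperspectral
databases: no 1/f spatial spectra, no specularities, no mutual
illumination. Passing tests therefore demonstrate correctness of the
machinery and the direction of the modelled effects, not quantitative
agreement with the human-observer curves, which require the deposited
scene and gaze recordings (replayable through `read_cube`/`read_gaze`).

Test problem sizes: fixtures run at 96×72 px spanning 6.9° (at coarser
grids one pixel of foveal blur covers several times the intended visual
angle and depresses the local–global correlation artificially), with
traces of 60–120 s for the stochastic properties and a full 300-s,
15,000-frame trace for the counting checks.

## Numerical choices and degenerate inputs

* Quartiles for the FD rule: linear interpolation (type 7), fixed so the
  independent formula oracle is exact.
* Histogram bins are left-closed, right-open, last bin closed; the
  sorted-prefix fast path is proven equal to direct binning in tests.
* The exponential history is accumulated by a one-pass recursion
  (multiply by $e^{-\Delta t/\tau}$, add the new frame), so the cost is
  independent of the number of evaluation times; the decay to the
  correction time rescales all weights equally and cancels in the
  normalization.
* Mirror padding uses symmetric (edge-including) reflection; pads larger
  than the image tile the reflection with a warning. Because the 5° patch
  is nearly as large as the scene, reflected padding re-weights pixels
  near the borders; under uniform gaze the accumulated state therefore
  converges to the global mean exactly only for spatially stationary
  scenes (fine-grain mosaics), and retains a small deterministic residual
  on coarse ones. This is inherent to the padding scheme, affects local
  and global corrections alike, and sets the floor of the
  local-versus-global difference for ideal samplers.
* Reciprocal gains are floored; zero global means are an error.
* Degenerate histograms (uniform scenes) propagate `NA` correlations with
  a warning-free, non-failing pipeline.

## Known limitations

Optics (point-spread, macular pigment), individual cone mosaics, temporal
filtering beyond the exponential kernel, photoreceptor noise, and
post-receptoral pooling are all out of scope, as is reproducing the
human-observer figure values without the deposited data. The ANOVA on
minimum color differences is a stock `aov` call on the package's outputs
rather than an implementation target.

## A short worked run

```{r example, eval = FALSE}
fx <- make_fixture_set(seed = 3, duration_s = 60, height = 72, width = 96)
diet <- spectral_diet(fx$scenes$high_var, fx$traces$random,
                      illuminant = fx$illuminants$ref, vmax_degps = Inf)
print(diet)
course <- adaptation_timecourse(fx$scenes$high_var,
                                filter_speed(fx$traces$human_like),
                                illuminant_cct = 4000, tau_s = 10)
print(course)
```
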