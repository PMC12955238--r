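# gazediet

Eye movements decide what a photoreceptor gets to see. `gazediet` simulates
the cone-excitation input that single foveal cones receive while gaze roams
a hyperspectral natural scene, and asks two questions about it:

1. **Spectral diet.** Does the accumulating history of L, M, S cone
   excitations at the foveal center come to match the statistics of the
   whole scene, despite gaze being strongly non-uniform? The statistic is
   the Pearson correlation between local and global histograms of log10
   cone excitations, with Freedman–Diaconis binning from the local sample
   (bin width `2·IQR·n^(-1/3)`), recomputed at every end frame from 50 to
   15,000 at 50 Hz.

2. **Local von Kries adaptation.** If each retinal point rescales its
   cone-like signal by the reciprocal of its own exponentially weighted
   stimulus history (time constants 1 s and 10 s), how well does that
   discount a global 4000 K daylight illuminant change compared with the
   classic global scaling by the scene mean? Corrections are diagonal
   transforms in CAM16 RGB (`RGB = M16 · XYZ`), compared pointwise in
   CAM16-UCS, summarized by the median color difference ΔE over the
   5°-diameter, eccentricity-blurred retinal patch.

The package provides the colorimetric primitives (cone excitations, CIE
daylight illuminants, CAM16 cone-like responses entered after the
adaptation stage, UCS color differences, CCT, CIELAB chroma), hyperspectral
cube I/O with block-downsampling, gaze-speed analysis and filtering, three
simulated observers (uniform random gaze, fixed-step random walk, and a
chroma-seeking local-feature walk), and seeded synthetic generators for
scenes, illuminants and gaze traces so the entire pipeline runs and is
tested without external data. Recorded data can be replayed through
`read_cube()` / `read_gaze()`.

## Worked example

```r
library(gazediet)

fx <- make_fixture_set(seed = 3, duration_s = 60, height = 72, width = 96)

diet <- spectral_diet(fx$scenes$high_var, fx$traces$random,
                      illuminant = fx$illuminants$ref, vmax_degps = Inf)
print(diet)
#> <spectral_diet> 3000 valid frames, 2951 end frames
#> asymptotic local-global correlation (median of last 100 frames):
#>     L     M     S
#> 0.984 0.986 0.985
```

Under uniform random gaze the foveal diet converges to the scene's global
histogram within seconds — correlations near 1 for all three cone classes.
A walk confined to the most chromatic region (`fx$traces$feature`) stays
far below that, showing how much natural gaze shifts matter for sampling a
scene.

```r
course <- adaptation_timecourse(fx$scenes$high_var,
                                filter_speed(fx$traces$human_like),
                                illuminant_cct = 4000, tau_s = 10)
print(course)
#> <adaptation_course> tau = 10 s, illuminant 4000 K
#>  frame time_s median_dE
#>      3   0.06     31.80
#>     12   0.24     29.91
#>     48   0.96     23.68
#>    189   3.78     21.17
#>    753  15.06     12.59
#>   2999  59.98     12.10
#> reference jnd: 2.46 (min dE = 12.1 = 4.9 jnd)
```

The median color difference between locally and globally corrected retinal
images falls steadily with viewing time as local adaptation accumulates
scene history; the slower time constant (10 s) ends closer to the global
correction than the fast one (1 s). Each value is in CAM16-UCS units and
the printed reference threshold (2.46, the UCS equivalent of a CIELAB jnd
of about 2.2) puts the numbers on a perceptual scale.

`run_diet_experiment()` and `run_adaptation_experiment()` orchestrate
scene × gaze × time-constant grids from a YAML or list configuration and
write deterministic CSV/JSON outputs; a thin command-line front end lives
at `inst/cli/gazediet.R`. The methods vignette
(`vignettes/gazediet-methods.Rmd`) documents the model, parameter
conventions, numerical choices, and what the synthetic generators do and
do not emulate.

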