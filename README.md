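# specloc

Bayesian spectral-cue modelling of human sound-elevation perception.

## The problem

Listeners locate a sound's elevation from the direction-dependent
spectral filtering of the pinna — the head-related transfer function
(HRTF) — most prominently a spectral notch in the 6–9 kHz band whose
center frequency rises with source elevation. The task is ill-posed: on
the cochlea's logarithmic intensity scale the eardrum spectrum is
`S(f) = H(f; ε*) + X(f)` (dB), the sum of the unknown elevation filter
and the unknown source spectrum. `specloc` is for auditory
neuroscientists and psychophysicists who want to simulate, and probe
with spectral-contrast stimuli, an observer that solves this problem by
template matching under prior assumptions.

## The model

The observer weights frequency bands by cue reliability with a skewed
beta-shaped function

```
w(f) = a (f − f_min)^α1 (f_max − f)^α2 ,   α1 = 4.5, α2 = 1.5, [f_min, f_max] = [3.5, 12] kHz
```

correlates the weighted eardrum spectrum against stored HRTF templates
over 3–12 kHz (a weighted Pearson correlation, invariant to overall
sound level), rectifies the correlation into a likelihood
`L(ε|ε*) = max(C, 0)`, multiplies with a spatial prior `P(ε*)`
(near-uniform by default), and reads out the posterior
`R(ε*|ε) ∝ L·P` by its maximum (MAP) or by sampling. Around the model
sit a canonical HRTF generator, the 5 × 5 notch-band/outer-band
stimulus matrix (band levels 29–65 dB, spectral contrast −36…+36 dB),
a 1200-trial virtual localization experiment with a spectral noise
model, and per-condition regressions `ε_R = g·ε_T + b` fitted by
minimizing mean absolute error.

## Worked example

```r
library(specloc)

hrtfs <- make_canonical_hrtfs()
hrtfs
#> HRTF set: 59 elevations (-60 to 85 deg) x 342 frequencies (0.5 to 20 kHz)
#> gain range: -11.11 to 12.00 dB

x <- make_stimulus(65, 29)            # notch band 65 dB, outer bands 29 dB
spectral_contrast(x)
#> [1] 36
localize(x, true_elevation = -30, hrtfs)
#> [1] 82.5
localize(make_stimulus(47, 47), -30, hrtfs)
#> [1] -30
```

A +36 dB contrast stimulus superimposes a peak on the notch band, so
even a source 30° below the horizon is perceived far upward (+82.5°),
while flat noise is localized veridically. The full virtual study:

```r
d  <- build_design(seed = 1)          # 25 stimuli x 48 directions = 1200 trials
tr <- run_experiment(d, hrtfs, model_config(), noise_model(rng_seed = 2))
summarize_conditions(tr)
#> Condition summary: 25 conditions (0 flagged)
#> contrast profile:
#>  contrast_db         g       b    r2
#>          -36  1.85e-01  5.8333 0.893
#>          -27  1.92e-01  8.7012 0.875
#>          -18  3.60e-01  6.0359 0.901
#>           -9  5.28e-01 -0.4349 0.949
#>            0  9.95e-01 -0.0854 0.987
#>            9  1.52e+00  2.7699 0.873
#>           18  4.75e-01 59.9375 0.451
#>           27 -9.91e-18 82.5000 0.000
#>           36  6.08e-17 82.5000 0.000
```

Read the profile as the signature of reliability-weighted template
matching: localization gain `g` and precision `r²` are maximal near
zero contrast and fall off asymmetrically (negative contrasts retain
usable gain from the surviving outer-band cues; high positive contrasts
drive gain to zero), while the bias `b` jumps to a large upward offset
once the notch-band peak dominates. At moderate positive contrast
(~+12 dB) single trials flip between veridical and upward percepts —
up-down confusions (`two_cluster_gap()` detects them).

`run_pipeline(pipeline_config(seed = 1), "out/")` runs
generator → stimuli → simulation → analysis in one call and writes
every table (HRTF set, stimuli, trials, condition summary, profiles)
as CSV with a manifest; `scripts/run_pipeline.R` wraps it for the
shell. See `vignette("elevation-model")` for the model's assumptions,
parameter meanings, and design choices.

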