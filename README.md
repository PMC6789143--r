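# cardiodyn

Linear and nonlinear dynamical analysis of cardiomyocyte contraction motion.

Cultured cardiomyocytes — in particular clusters derived from human induced
pluripotent stem cells (hiPSC-CMs) — beat spontaneously, and the physical
motion of a beating culture can be captured with nothing more than
bright-field video. `cardiodyn` turns such videos into quantitative
contractile phenotypes for researchers studying tissue maturation, drug
response or pacing:

1. **Motion tracking** (`compute_motion_fields`, `track_video`): exhaustive
   block matching between consecutive frames (sum-of-absolute-differences
   over macroblocks, exact for integer-pixel rigid motion) yields per-frame
   displacement fields, collapsed into a *contraction-motion waveform*
   `S(t)` = mean tissue speed in µm/s. Each beat appears as a pair of speed
   peaks: the contraction stroke followed by the relaxation stroke.
2. **Linear beat metrics** (`detect_peaks`, `beat_metrics`): beat rate
   (BPM), peak-to-peak (PP) interval, contraction and relaxation velocities,
   each as mean ± sd, from prominence-filtered peak detection.
3. **Nonlinear dimensional analysis** (`variogram`, `capacity_dimension`,
   `acf_lag`, `fnn_embedding_dim`, `embed_series`, `correlation_integral`,
   `correlation_dimension`): two fractal measures of signal complexity that
   discriminate samples whose *linear* metrics are indistinguishable.

## The two dimensions

**Capacity dimension** of the waveform graph, by the variogram (variation
estimator) method: with

γ(τ) = 1/(2(N−τ)) · Σᵢ (S_{i+τ} − S_i)²,

the log–log slope *P* of γ(τ) against τ over the scaling range gives

D_capacity = 2 − P/2,

which reproduces D = 2 − H on fractional Brownian motion with Hurst
exponent H.

**Correlation dimension**, by phase-space reconstruction and the
Grassberger–Procaccia method: the series is delay-embedded
(x_j = (S_j, S_{j+τ}, …, S_{j+(m−1)τ}), Takens) with the delay τ chosen as
the 1/e decay lag of the autocorrelation function and the embedding
dimension m screened by false nearest neighbours. The correlation integral

C_m(r) = 2/(N′(N′−1)) · #{(i, j), i > j : ‖x_i − x_j‖ ≤ r}

is accumulated on 32 log-spaced bins between the smallest and largest
pairwise distance; D_correlation(m) is the slope of log C_m(r) vs log r
over an automatically selected scaling region, and the plateau of
D_correlation(m) over m is the *steady correlation dimension* D_steady.
Saturation indicates deterministic dynamics; for stochastic signals D(m)
grows without bound and the package flags the absent plateau.

Because real recordings are rarely shareable, the package ships seeded
generators with exact ground truth: twin-peak contraction waveforms with
arrhythmia-like aberrations (`simulate_waveform`), fractional Brownian
motion by circulant embedding (`simulate_fbm`), Lorenz trajectories
(`simulate_lorenz`) and rendered beating videos with known pixel motion
(`render_video`, `simulate_beat_video`).

## Worked example

```r
library(cardiodyn)

# a 20 s, 100 fps synthetic cluster beating at 60 BPM with measurement noise
sim <- simulate_waveform(beat_sim_spec(bpm = 60, duration_s = 20, fps = 100,
                                       noise_sd = 0.5, seed = 42))
w <- sim$waveform
beat_metrics(w)
#> <beat_metrics>
#>   beat rate (BPM):       60.000 +/- 0.000
#>   PP interval (s):       1.000 +/- 0.000
#>   contraction v (um/s):  20.137 +/- 0.450
#>   relaxation v (um/s):   15.113 +/- 0.397

capacity_dimension(variogram(w))
#> <variogram_result> 500 lags
#>   slope P = 1.433, D_capacity = 1.283, mean D(tau) = 1.436 [clipped]

correlation_dimension(w, m_values = 2:8)
#> <correlation_result> tau = 5, m = 2-8
#>   D(m): 0.89 1.29 1.66 2.02 2.36 2.74 3.22
#>   D_steady = 3.216 (plateau: FALSE)
```

The beat metrics recover the generator settings exactly (60 BPM, 1 s PP,
20/15 µm/s strokes, jittered by the noise). The variogram slope P ≈ 1.43
gives a mean capacity dimension ≈ 1.4, typical of a rough periodic
waveform. The correlation dimension reports *no plateau*: additive white
noise dominates the fine scales of this synthetic signal, so D(m) keeps
growing — exactly the stochastic signature the method is designed to flag.
On a deterministic chaotic oracle the plateau appears:

```r
correlation_dimension(simulate_lorenz(20000, dt = 0.02), m_values = 2:8)
#> <correlation_result> tau = 15, m = 2-8
#>   D(m): 1.88 2.07 2.08 2.07 2.10 1.96 1.95
#>   D_steady = 2.078 (plateau: TRUE)
```

2.08 is the textbook correlation dimension of the Lorenz attractor
(≈ 2.05), recovered from the x-coordinate alone.

## Command line

```sh
Rscript inst/cli/cardiodyn.R simulate waveform --bpm 60 --duration 20 \
    --seed 1 --out waveform.csv
Rscript inst/cli/cardiodyn.R metrics --waveform waveform.csv --out metrics.json
Rscript inst/cli/cardiodyn.R nonlin --waveform waveform.csv --out nonlin.json
Rscript inst/cli/cardiodyn.R track --input frames_dir/ --fps 100 \
    --um-per-px 0.25 --out waveform.csv
Rscript inst/cli/cardiodyn.R run --manifest manifest.tsv --out report/
```

(After installation the launcher is also at
`system.file("cli", "cardiodyn.R", package = "cardiodyn")`.)

## Vignette

`vignettes/cardiodyn-methods.Rmd` documents the model and estimator
choices: variogram fit range, correlation-integral binning and scaling
region, FNN thresholds, degenerate-input policy, and what the synthetic
generators do and do not emulate.
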