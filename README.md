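# tspeckle

Temporal laser speckle contrast with inter-frame correlation: closed-form
models, a quadrature oracle, a dynamic-speckle simulator, and the
measurement pipeline.

## The problem

Laser speckle contrast imaging (LSCI) infers the dynamics of a scattering
sample — blood flow, bacterial colonies, drying paint — from the contrast
`K = σ/⟨I⟩` of time-integrated speckle. The *temporal* algorithm computes
`K` per pixel over `L` consecutive frames, preserving spatial resolution.
Classic models tie `K` to the dimensionless exposure `x = T/τc` (exposure
over decorrelation time) under the assumption of statistically independent
frames. For slow dynamics (`x ≪ 1`) consecutive frames are strongly
correlated: the measured temporal contrast collapses toward zero while the
independent-frame models predict `K ≈ 1`.

`tspeckle` implements a correlation-aware temporal contrast model. Frame
pairs separated by `ψ` intervals contribute exposure-averaged correlation
factors

    1/ν_ψ = (1/T²) ∫₀ᵀ ∫_{ψ(T+δ)}^{(ψ+1)T+ψδ} g₁²(t−t′) dt′ dt,

and the expected squared contrast of an `L`-frame window with `S`
correlated intervals is

    K_t²(x, L, S) = 1/ν₀ − (2 / (L(L−1))) Σ_{ψ=1}^{S} (L−ψ) / ν_ψ,

with closed forms for Gaussian (`g₁ = exp(−πτ²/2τc²)`, ordered motion) and
Lorentzian (`g₁ = exp(−|τ|/τc)`, Brownian motion) field correlations, both
Mandel-normalized (`∫|g₁|²dτ = τc`). `S = 0` recovers the classic
independent-frame expressions. The separable spatio-temporal extension
`K² = α·Ks²(M, n, p)·K_t²(x, L, S) + Cn` covers finite pixel size (`M` =
pixel-to-grain area ratio) and correlated `n × n` sliding windows, and
reproduces the published `β^(1/2)` calibration table at the
Nyquist-Shannon ratio `M = 0.5`.

Every closed form is validated against a brute-force adaptive-quadrature
oracle (`nu_inv_quadrature()`), and the theory is closed against a
synthetic-speckle simulator (`simulate_stack()`) with exact temporal
statistics (Ornstein-Uhlenbeck updates for the Lorentzian family, full
covariance factorization for the Gaussian).

## Worked example

Theory — contrast of a 30-frame window with a realistic camera dead time
(`Δ = 0.347`), Lorentzian dynamics:

```r
library(tspeckle)
sqrt(temporal_contrast_sq(c(0.002, 0.02, 0.2, 2), L = 30,
                          delta_ratio = 0.347, family = "lorentzian"))
#> [1] 0.2283936 0.6126587 0.8882241 0.6134190
```

At `x = 0.002` (frames acquired well inside the decorrelation time) the
correlated model gives `K = 0.23` where independent-frame models would
report nearly 1; the curve rises to a single interior maximum and then
falls along the classic motion-blur branch.

Spatial calibration factors `β^(1/2)` for correlated sliding windows at
`M = 0.5`:

```r
table1()
#>   n p     family beta_half
#> 1 3 1   gaussian 0.7385305
#> 3 5 2   gaussian 0.7752470
#> 5 7 3   gaussian 0.7874820
#> 7 9 4   gaussian 0.7928973
#> 2 3 1 lorentzian 0.5925282
#> 4 5 2 lorentzian 0.6246337
#> 6 7 3 lorentzian 0.6384599
#> 8 9 4 lorentzian 0.6452080
```

Closed loop — simulate a slow sample (`τc = 100 s`, `T = 1 s`,
`δ = 0.347 s`, so `x = 0.01`), recover its decorrelation time from the
frame-correlation curve, and compare measured against predicted contrast:

```r
cfg <- simulation_config(tau_c = 100, exposure = 1, delta = 0.347,
                         L = 200, height = 128, width = 128,
                         family = "lorentzian", substeps = 8, seed = 42)
st  <- simulate_stack(cfg)
fit_correlation_time(frame_correlation_curve(st), "lorentzian")
#> tau_c = 102.156 s (lorentzian, Siegert |g1|^2 fit; rss = 0.01026 over 199 points)

roi_contrast_ensemble(st, L_window = 30)                      # measured
#> [1] 0.4703238
sqrt(temporal_contrast_sq(0.01, 30, 29, 0.347, "lorentzian"))  # model
#> [1] 0.4727203
```

The ground-truth `τc = 100 s` is recovered within ~2%, and the measured
ROI contrast agrees with the model within 0.5%. The pipeline also
provides exposure binning (`bin_frames()`,
`contrast_vs_x_experiment()`), THSP images (`thsp()`), per-pixel maps
(`temporal_contrast_map()`), contrast-model fitting
(`fit_contrast_model()`), and TIFF + JSON stack I/O
(`write_stack()`/`read_stack()`). A command-line wrapper lives at
`inst/scripts/tspeckle` (subcommands `theory`, `table1`, `simulate`,
`contrast`, `curve`, `fit-tau`, `thsp`).

See `vignettes/temporal-speckle-contrast.Rmd` for the model derivation
sketch, estimator choices, simulator design and numerical details.

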