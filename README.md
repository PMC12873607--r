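# sptkin

Simulation and kinetic analysis of fast live-cell single-particle tracking
(SPT) experiments on nuclear proteins — the kind of data produced by
imaging HaloTag-labeled factors such as DNMT1 at ~100 frames/s under HiLo
illumination, tracking single molecules for a few frames each, and asking
what fraction of the protein is chromatin-bound versus slowly or freely
diffusing.

## The model

Displacements ("jumps") of single molecules between observations separated
by a time gap Δτ are pooled into histograms at Δτ = kΔt, k = 1…7
(Δt = 10 ms, 0.01 µm bins, at most 4 jumps per trajectory per gap). For a
state with diffusion coefficient D and per-axis localization error σ the
jump length is Rayleigh:

    p(r | D, σ, Δτ) = r / (2(DΔτ + σ²)) · exp( −r² / (4(DΔτ + σ²)) )

and the data are fitted with a two- or three-state static mixture
(bound / slow / fast; three-state bounds D_bound ∈ [1e-4, 0.05],
D_free1 ∈ [0.05, 1], D_free2 ∈ [1, 10] µm²/s) by bounded least squares
simultaneously over all gaps. Fast molecules leave the axial detection
slice (dz = 0.7 µm) between frames; the fit re-weights each state at each
gap by the absorbing-slab survival probability

    S(D, t) = Σ_{n odd} 8/(n²π²) · exp( −n²π² D t / dz² ),

averaged over the admissible jump start ages (see the methods vignette,
`vignettes/spt-kinetics.Rmd`). The package also provides the upstream
stages — ground-truth Brownian simulation with axial censoring, movie
rendering, matched-filter spot detection with subpixel Gaussian
refinement, gated Hungarian trajectory linking with gap closing — and the
downstream per-cell statistics (Student/Welch t tests, Gaussian-mixture
bimodality assessment) plus small quantifications (D vs MW^(−1/3)
scaling regression, molecule counting against a fluorescence standard,
chromatin/nucleoplasm fractionation ratios).

Because raw imaging data of this kind are generally not deposited, the
simulator is a first-class, tested module and all validation is parameter
recovery against known ground truth.

## Worked example

Simulate one cell's worth of trajectories from the default ground truth
(10% bound, 18% slow at 0.35 µm²/s, 72% fast at 2.3 µm²/s, σ = 0.035 µm,
dz = 0.7 µm), compile jump histograms, and fit the three-state model:

```r
library(sptkin)

model <- ground_truth_model()      # F = (0.10, 0.18, 0.72), D = (0.005, 0.35, 2.3)
acq   <- acquisition_config()      # 10 ms frames, 0.16 um px, dz = 0.7 um
cfg   <- fit_config()              # 7 gaps, 0.01 um bins, 4 jumps/track/gap

d <- simulate_trajectories(model, acq, n_trajectories = 6000, seed = 1)
h <- compile_jump_histograms(d$trajectories, cfg)
fit_kinetic_model(h, cfg)
#> 3-state jump-length kinetic fit (21899 jumps)
#>   fractions: bound=0.120  free1=0.181  free2=0.699
#>   D [um^2/s]: bound=0.005286  free1=0.336  free2=2.34
#>   sigma = 0.0354 um, residual = 30.36, converged = TRUE
```

The fit recovers the simulated partition and mobilities: the bound
fraction within ~0.02, the fast diffusion coefficient within ~2%, and the
localization error almost exactly. `select_model()` on the same data
prefers three states over two by information criterion, mirroring the
observation that two states underfit this kind of data.

The `analysis/` directory holds the numbered workflow the package was
built around — each script is a thin narrative driver over the package
functions and writes its tables under `results/`:

1. `01_simulate.R` — reference trajectory dataset + rendered TIFF movie
2. `02_localize_track.R` — detection, subpixel refinement, linking, and
   comparison against simulator truth
3. `03_fit_kinetics.R` — histograms, 2- vs 3-state fits, defocalization
   oracle table
4. `04_cell_statistics.R` — two-condition per-cell contrast (two-tailed
   Student t test) and bimodality phenotype
5. `05_quantification.R` — scaling regression, molecule counting,
   fractionation ratios

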