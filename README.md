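# memnano

Quantitative analysis of membrane-protein nanoscale organisation and
dynamics, for researchers studying how lipid-anchored signalling proteins
(the motivating case is K-Ras on the inner plasma-membrane leaflet, where
it forms nanoclusters of ~4–6 proteins) respond to membrane-targeted
perturbations. The package covers four experiment families behind one
consistent set of R functions, plus a synthetic-data generator with
exported ground truth so the whole pipeline is testable without
instrument data.

## What it computes

**Nanoclustering from immunogold EM.** For gold-particle coordinates on a
plasma-membrane sheet of area *A*, the edge-corrected univariate Ripley
K-function

K̂(r) = A / (n(n−1)) · ΣᵢΣ_{j≠i} w_ij · 1(‖x_i − x_j‖ ≤ r)

with analytic isotropic edge weights w_ij (inverse in-region circumference
fraction), linearised as L(r) − r = √(K(r)/π) − r. Curves are normalised
by a pointwise Monte-Carlo 99% CSR envelope so the confidence limit sits
at 1; the maximum of the normalised curve, L_max, summarises the extent
of nanoclustering. Conditions are compared by a pooled-resampling
bootstrap on per-sheet L_max and a one-way ANOVA on labelling density.

**Single-particle tracking.** GLRT matched-filter spot detection
(default sensitivity 30, PSF 1.3 px) with sub-pixel Gaussian refinement;
greedy nearest-neighbour linking (max jump 5 px, one-frame blinking,
tracks ≥ 6 frames); pooled MSD; D = slope/4 from the first lags, with the
intercept estimating 4σ²_loc.

**NMR metrics.** CSP (ppm) = √((ΔN²/25 + ΔH²)/2); PRE
tagged/untagged intensity ratios normalised to a maximum of 1; TRACT
α/β exponential decay fits whose rate difference ΔR is inverted through
the rigid-rotor ¹⁵N CSA/dipole cross-correlation relation to the
rotational correlation time τ_c.

**Assay curves.** DSF melting temperature (maximum of the smoothed first
derivative of the normalised melt curve, parabolically refined); DLS
critical aggregation concentration (continuous two-segment breakpoint fit
in log₁₀ concentration); FLIM lifetime (single-exponential tail fit).

See `vignettes/memnano-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

Simulate one PM sheet with 50 nanoclusters of 4–6 gold particles
(cluster SD 20 nm) on 1 µm², build a matched CSR envelope, and read off
L_max:

```r
library(memnano)

reg   <- region(1000, 1000)                 # 1 um^2 sheet, nm units
radii <- radius_grid(rmax = 240, by = 2)

sim <- gen_cluster_pattern(cluster_model(50, c(4, 6), 20, reg), seed = 42)
env <- csr_envelope(sim$pattern$n, reg, radii, n_sims = 500, seed = 42)
analyze_sheet(sim$pattern, envelope = env)
#> normalised L(r) - r: L_max = 11.105 at r = 58 (1 = CSR confidence limit)

analyze_sheet(gen_csr_pattern(sim$pattern$n, reg, seed = 99), envelope = env)
#> normalised L(r) - r: L_max = 0.607 at r = 58 (1 = CSR confidence limit)
```

The clustered sheet sits far above the CSR confidence limit of 1
(strong nanoclustering at ~60 nm); the random pattern stays below it.
Diffusion and the localisation-noise floor are recovered from simulated
tracks (true D = 0.5 µm²/s, σ_loc = 30 nm, so the expected intercept is
4σ² = 0.0036 µm²):

```r
tracks <- gen_brownian_tracks(
  diffusion_model(0.5, localization_sd = 0.030, n_frames = 200), 200, seed = 1)
fit_diffusion(compute_msd(tracks$observed, max_lag = 6), n_lags = 4)
#> diffusion fit over 4 lags: D = 0.4973 +/- 0.00042 um^2/s, intercept = 0.00361 um^2
```

The assay fits on synthetic inputs with known truth:

```r
dl <- tract_delays()
fit_tract(gen_curve("tract", list(I0 = 1, R = 15), grid = dl$alpha, noise_sd = 0.01, seed = 2),
          gen_curve("tract", list(I0 = 1, R = 45), grid = dl$beta,  noise_sd = 0.01, seed = 3))
#> TRACT at 900 MHz: R_alpha = 14.89, R_beta = 44.74, delta_R = 29.84 1/s
#>   rotational correlation time tau_c = 9.48 ns

fit_tm(gen_curve("melt", list(Tm = 55, width = 2), noise_sd = 0.01, seed = 4))
#> DSF melting temperature: Tm = 55.35 degC (peak dF/dT = 0.113)

fit_cac(gen_curve("dls", list(cac = 80), noise_sd = 0.02, seed = 5))
#> DLS aggregation onset: CAC = 80 nM (slopes 0.188 -> 5.09 per log10 unit)

fit_lifetime(gen_curve("flim", list(I0 = 1e4, tau = 2.6, offset = 20),
                       noise_sd = 0.01, seed = 6), tail_start = 0.2)
#> fluorescence lifetime tail fit: tau = 2.591 ns (offset 20.8, 249 points)
```

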