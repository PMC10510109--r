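---
title: "Methods: nanoclustering statistics, single-particle tracking and assay-curve fits"
author: "memnano"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoclustering statistics, single-particle tracking and assay-curve fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memnano)
```

# Scope

Lipid-anchored signalling proteins such as K-Ras organise the inner leaflet
of the plasma membrane into transient nanoclusters of roughly 4--6
proteins, and drugs that perturb the membrane anchor change both that
spatial organisation and the protein's lateral mobility. `memnano`
implements the quantitative battery used to characterise such
perturbations:

* **Spatial statistics** on immunogold coordinates from plasma-membrane
  (PM) sheets: the edge-corrected univariate Ripley K-function, its
  `L(r) - r` linearisation, Monte-Carlo normalisation against complete
  spatial randomness (CSR), the `L_max` summary, a bootstrap group test
  and a labelling-density ANOVA.
* **Single-particle tracking**: GLRT-style spot detection with Gaussian
  refinement, gap-tolerant nearest-neighbour linking, pooled mean-square
  displacement (MSD) and diffusion-coefficient fits.
* **NMR-derived metrics**: combined ^1^H/^15^N chemical-shift
  perturbations (CSP), normalised paramagnetic relaxation enhancement
  (PRE) intensity ratios, and TRACT relaxation fits inverted to a
  rotational correlation time.
* **Assay curves**: DSF melting temperature, DLS critical aggregation
  concentration (CAC) and FLIM fluorescence-lifetime tail fits.

A synthetic-data generator with exported ground truth stands in for the
instrument data, so every stage is testable end to end.

# Spatial nanoclustering statistics

## The K-function and its estimator

For a point pattern of `n` gold particles on a rectangular sheet of area
`A`, the package estimates Ripley's univariate K-function with the
standard unbiased isotropic-corrected estimator

$$\hat K(r) = \frac{A}{n(n-1)} \sum_{i} \sum_{j \neq i} w_{ij}\,
  \mathbf{1}\!\left(\lVert x_i - x_j \rVert \le r\right),$$

where $w_{ij}$ is the inverse of the fraction of the circumference of the
circle centred at $x_i$ with radius $\lVert x_i - x_j\rVert$ that lies
inside the sheet. The weight is computed analytically from arc geometry
(per-edge exterior arcs with inclusion--exclusion at the corners), never
by sampling; a point on an edge gives weight 2, on a corner weight 4.
The $n(n-1)$ pair normalisation makes $\mathbb E[\hat K(r)] = \pi r^2$
exact under CSR, which the test suite verifies to within 3 Monte-Carlo
standard errors over 500 simulations, and which an $n^2$ normalisation
would miss by a factor $(n-1)/n$ — a bias of several standard errors at
$n = 300$. The uncorrected estimator (`correction = "none"`) is provided
only to demonstrate the boundary bias it suffers at large radii.

Radii default to 1--240 nm in 1 nm steps on a 1 µm² sheet: nanoclusters
live at tens of nanometres, and 240 nm keeps every correction circle's
inside fraction well defined (a warning fires beyond half the shorter
sheet side). Coincident points are legal (two gold particles can project
together); their pair contributes weight 1 each at every radius.

## Normalisation and L_max

`L(r) - r = sqrt(K(r)/pi) - r` is zero in expectation under CSR.
Significance is judged against a **pointwise** Monte-Carlo envelope: the
99th percentile of `L(r) - r` over (by default) 1000 CSR simulations at
the same `n` and sheet geometry, per radius. Dividing the observed curve
by the envelope puts the CSR confidence limit at 1, so the maximum of the
normalised curve, `L_max`, exceeds 1 exactly when the pattern clusters
beyond what CSR produces at that scale. The envelope is pointwise rather
than simultaneous because the statistic is normalised per length scale;
radii where the envelope percentile is not positive are excluded from the
curve and the `L_max` search (dividing by a non-positive confidence limit
is meaningless), and ties in the arg-max go to the smallest radius.

The acceptance script verifies the normalisation contract from scratch:
fresh CSR patterns normalised by an independent envelope have an
empirical pointwise 99th percentile of 1 (binomial error at 2000
patterns).

## Group comparison

Per-sheet `L_max` values (conditions are typically 15 or more sheets) are
compared by a bootstrap test: the observed statistic is the difference of
group means; the null pools both groups and resamples two groups of the
original sizes with replacement; the two-sided p-value
`(1 + #{|boot| >= |obs|}) / (n_boot + 1)` is never smaller than
`1/(n_boot + 1)`. The construction (difference of means under a pooled
null) is a package choice — the test family is standard but its exact
form is not dictated by the data format — and alternatives can be swapped
in at the call site. Calibration and power are part of the test suite:
same-distribution groups reject at the nominal 5% rate within binomial
error, and a 5-pooled-SD mean separation at 15 vs 15 sheets rejects in
over 95% of replicates.

Gold labelling density (points per µm² per sheet) is compared across
conditions with a standard one-way ANOVA (`stats::lm`/`anova`); the
degenerate all-equal case is reported as F = 0, p = 1.

# Single-particle tracking

## Detection

Spots are found by a matched-filter GLRT against a flat-background null:
in a window of $N$ pixels (half-width `ceiling(3*psf_sigma)`), the image
is regressed on a centred Gaussian template of width `psf_sigma`
(default 1.3 px) and the statistic $T = -N \log(1 - \rho^2)$ (template
correlation $\rho$, positive amplitudes only) is thresholded at
`sensitivity` (default 30). This emulates the behaviour of
localisation-microscopy spot finders whose published parameters are a
GLRT sensitivity and a PSF width; the exact internal scale of commercial
implementations is not public, so the threshold is calibrated here by its
false-positive behaviour: at the default threshold a pure-noise
100x100 px frame yields zero detections in at least 99% of frames.
Supra-threshold pixels are merged by 8-way adjacency into one candidate
per connected component and refined by least squares with a symmetric 2D
Gaussian (PSF width held fixed), giving sub-pixel positions with mean
bias below 0.05 px at high SNR. Detections within one PSF width of the
frame border are dropped.

## Linking

Linking is greedy and distance-sorted, frame by frame: candidate pairs of
(open track end, new localisation) are accepted in increasing distance
order subject to a maximum jump of 5 px, with single-frame gap closing
(`max_gap = 1`) so a fluorophore that blinks off for one frame keeps its
identity; distance ties go to the earlier track id, which makes the
result invariant to input row order. Global-optimal assignment was
deliberately not used: at the sparse labelling densities this pipeline
targets (tens of pM), assignment conflicts are rare and greedy matching
reproduces ground-truth partitions exactly in the test movies. Tracks
with fewer than `min_length = 6` localisations are discarded; the
acquisition convention "persisted for more than 6 frames" is ambiguous
between >= 6 and >= 7, and the package reads it as >= 6 with the
threshold configurable.

## MSD and diffusion

The MSD is time-and-ensemble pooled: squared displacements over every
admissible observation pair at frame lag $\ell$ are averaged across all
tracks (per-track MSDs averaged afterwards would weight short tracks
differently; pooling matches the convention of combining all tracks into
one file before analysis). Pairs spanning a blink gap contribute to their
true lag. For 2D Brownian motion $\mathrm{MSD}(t) = 4Dt + 4\sigma_{loc}^2$,
so an ordinary least-squares line over the first `n_lags = 4` lags gives
`D = slope/4` and an intercept that estimates four times the squared
localisation noise; a negative fitted D is reported but flagged. Pixel
data are converted at 0.16 µm/px (a 100 px field spanning 16 µm) when no
pixel size is supplied.

# NMR metrics

**CSP.** `CSP (ppm) = sqrt((dN^2/25 + dH^2)/2)`: the conventional
combined amide shift difference, ^15^N down-weighted by its larger ppm
dispersion. It depends only on $|\Delta H|, |\Delta N|$, hence is
invariant to which state is called the reference.

**PRE ratios.** Tagged/untagged peak-intensity ratios normalised so the
least-attenuated residue is exactly 1 ("normalised to 1" is read as
division by the maximum raw ratio; division by the mean of a user-named
unaffected-residue set is available via `method = "reference"` since the
convention is not unique). The output is invariant to rescaling either
spectrum, so receiver-gain or dilution differences between the tagged and
untagged samples cancel as long as they are uniform across residues.

**TRACT.** The TROSY (slow, $\alpha$) and anti-TROSY (fast, $\beta$) 1D
decay series are each fit to $I(t) = I_0 e^{-Rt}$ by nonlinear least
squares initialised from a log-linear fit (an additive offset is
optional). The rate difference $\Delta R = R_\beta - R_\alpha$ equals
twice the transverse ^15^N CSA / ^1^H--^15^N dipole cross-correlated
relaxation rate; the package inverts the rigid-rotor relation

$$\Delta R = 2\,p\,\delta_N\,(3\cos^2\theta - 1)\left[4J(0) + 3J(\omega_N)\right],
\qquad J(\omega) = \frac{2}{5}\frac{\tau_c}{1 + (\omega\tau_c)^2}$$

numerically (`uniroot`) for $\tau_c$, with $r_{NH} = 1.02$ Å,
$\Delta\sigma_N = 160$ ppm and $\theta = 17^\circ$. This conversion
formula comes from the TRACT literature, not from any single data set,
and the relation is strictly increasing in $\tau_c$, which both
guarantees a unique inversion and encodes the physics: a protein held at
a membrane surface tumbles more slowly and shows the larger
$\Delta R$. The default acquisition grids are the 14-point schedules
0--240 ms ($\alpha$) and 0--70 ms ($\beta$).

# Assay curves

**DSF.** The melt trace is normalised to its maximum, differentiated by
central differences on the 0.5 °C grid, and `Tm` is the derivative
maximum. Two numerical choices matter. First, the derivative is smoothed
with a centred running mean (default 5 grid points = 2 °C) before
peak-picking: realistic fluorescence noise otherwise dominates the
point-to-point derivative and the arg-max jitters across the transition;
the symmetric kernel leaves the noiseless peak position unchanged.
Second, the peak is refined by parabolic interpolation through its two
neighbours, since the acquisition grid would otherwise quantise `Tm` to
0.5 °C. A curve whose derivative never rises triggers a "no melting
transition" error; additional local derivative maxima (multi-domain
unfolding) are listed in the diagnostics while the global maximum is
reported.

**DLS/CAC.** The "origin of slope" on a scattering-versus-log
concentration series is operationalised as a continuous two-segment
linear fit `y = a + b x + c (x - bp)+` with the breakpoint searched
exhaustively over interior grid positions (at least two points per side);
`CAC = 10^bp`. The aggregation branch must be steeper (`c > 0`) and the
two-segment model must beat a single line by an F-ratio (default 10), or
a "no aggregation onset" error is raised — a perfectly straight series is
an error, not a CAC of convenience. The grid search equals a brute-force
oracle by construction and is exact when the true breakpoint lies on the
sampling grid.

**FLIM.** Lifetimes come from a single-exponential tail fit
$I(t) = I_0 e^{-t/\tau} + c$ restricted to `t >= tail_start`, initialised
log-linearly. All three curve fits are invariant under positive rescaling
of the signal.

# The synthetic-data generator

The generator reproduces the statistical structure each analysis assumes,
with ground truth returned beside the observables:

* **CSR patterns** — uniform points on the sheet; the Monte-Carlo null.
* **Clustered patterns** — a Thomas-type process: uniform parents, a
  discrete-uniform 4--6 offspring per parent (the reported nanocluster
  occupancy), isotropic Gaussian dispersion. The cluster radius is not
  constrained by published data; `cluster_sd = 20 nm` is an
  artifact-chosen default, selected once so clusters sit well below the
  length scales the K-function probes. Offspring landing outside the
  sheet are re-drawn until inside — not clipped or torus-wrapped — which
  preserves the intended count and mirrors how PM sheets are cropped.
* **Brownian tracks** — per-axis step variance `2 D dt` (10 ms frames by
  default), Gaussian localisation noise on reported positions, and
  blinking restricted to single-frame gaps so the one-frame gap-closing
  rule can in principle recover every track.
* **Frames** — localisations rendered as integrated 2D Gaussians
  (total intensity `photons`) on uniform background with Poisson noise;
  100x100 px at 0.16 µm/px by default. No bleaching, no dye
  photophysics beyond the single-frame blink.
* **NMR tables** — amide shifts in realistic ppm windows; perturbed
  residues get exact stated offsets; tagged intensities attenuated by
  `1 - pre_effect` with multiplicative noise.
* **Curves** — mono-exponential TRACT decays on the acquisition delay
  grids, sigmoidal melts on the 25--95 °C / 0.5 °C grid, two-segment DLS
  series in log10 concentration (default onset 80 nM, the order of
  magnitude where long-lipid-tail drug conjugates begin to aggregate),
  and exponential FLIM decays.

Each generator consumes one integer seed feeding a single pseudo-random
stream per call (sub-streams are derived deterministically), and restores
the caller's RNG state. What the generator does **not** emulate bounds
what green tests can claim about real data: there is no fixation or
labelling artefact in the point patterns, no anomalous diffusion or
motion blur in the tracks, no baseline drift or peak overlap in the NMR
tables, and no instrument-specific noise in the curves. Passing tests
demonstrate that the estimators recover known truth under the stated
statistical models at the stated noise levels — not that any biological
conclusion is reproduced.

# Problem sizes and numerical tolerances

The test suite runs the analyses at the scales the methods are designed
for while staying desk-sized: envelopes from 1000 CSR simulations where
the envelope itself is under test (199 where one envelope is reused
across 100 power replicates); 500 CSR simulations for the unbiasedness
check; 2000 fresh patterns for the normalisation contract; 500 tracks of
200 frames for diffusion recovery; 100 seeded replicates for each
curve-fit recovery claim; 1000 replicates for bootstrap calibration.
Monte-Carlo assertions use 3-sigma bands around their closed-form
expectations. Nonlinear fits use `minpack.lm::nlsLM`
(Levenberg--Marquardt) with log-linear initialisation; the TRACT
inversion brackets `uniroot` on (1e-4, 1000) ns.

# Known limitations

* Sheets are axis-aligned rectangles; non-rectangular masks and
  inhomogeneous-intensity K-functions are out of scope, as are bivariate
  (cross-type) K-functions.
* The edge correction's corner inclusion--exclusion is exact for radii up
  to half the shorter sheet side; the default grid stays well inside
  that.
* The detector assumes a symmetric Gaussian PSF and flat local
  background; the linker is greedy and has no motion model, so it is not
  suitable for dense fields or highly mobile crossing particles.
* The TRACT inversion assumes rigid isotropic tumbling with fixed CSA,
  bond length and CSA/bond angle; anisotropic diffusion or internal
  motion biases `tau_c`.
* The DLS breakpoint is constrained to the sampling grid; resolution is
  set by the titration spacing.
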