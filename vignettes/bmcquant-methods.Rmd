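---
title: "Models and methods behind bmcquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bmcquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmcquant)
```

bmcquant quantifies three live-cell measurements of bacterial
microcompartment (BMC) biogenesis: FRAP-based internal protein mobility,
dual-channel colocalization, and the temporal order of shell/cargo assembly
events. This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data validation
does and does not demonstrate.

## The FRAP diffusion model

A confocal line bleach removes fluorescence from a ~0.3 μm stripe across an
elongated intracellular structure, and recovery is imaged at fixed
intervals (by default one 512 × 512 frame per minute for an hour — the
acquisition cadence the generator emulates). Analysis happens on the 1D
axial profile: per frame, masked intensities are summed across the short
axis along the long axis of the Otsu-segmented cell, on the pixel grid.

Three modelling assumptions define the estimator:

1. **Two populations.** The first post-bleach profile `C_post` splits into
   an immobile component `(1 − M)·C_post` that keeps the bleach scar
   indefinitely, and a mobile component `M·C_post` that relaxes by free
   Fickian diffusion. This decomposition is the unique one whose long-time
   centre value reproduces the recovery plateau
   `M·C_pre + (1 − M)·C_post` implied by the mobile-fraction equation.
2. **Pure diffusion, no binding kinetics.** Recovery is matched with
   `∂C/∂t = D ∂²C/∂X²`; reaction-dominant FRAP regimes are out of scope.
3. **Closed cell.** The envelope retains fluorophores, so the simulation
   uses reflecting (no-flux) boundaries. Total fluorescence is conserved
   exactly by the scheme.

### Discretization

The engine uses explicit Euler on the profile's own pixel grid, treating
pixels as cells with centres at `(index + 0.5)·pixel_size`. The Laplacian
of interior pixel *i* is `(C[i−1] − 2C[i] + C[i+1])/dx²`; at the ends the
reflecting ghost cell mirrors the boundary cell itself, giving
`(C[2] − C[1])/dx²`. We chose the cell-centred reflection (rather than a
node-centred mirror with a factor 2) because it is the form that conserves
the plain sum of the profile exactly — the discrete counterpart of a closed
cell — and it matches the pixel-centre coordinate convention used
throughout. Steps honour the stability bound `D·dt/dx² ≤ 0.25`;
`evolve_profile()` subdivides each inter-frame interval accordingly, so
the scheme is stable and deterministic for any requested times. The
stepping loop is compiled (Rcpp) because the D search below evolves the
profile millions of steps per cell; a pure-R reference step is exported and
tested for exact agreement with the compiled path.

Accuracy is checked against two independent closed forms: free-space
Gaussian spreading (`σ²(t) = σ₀² + 2Dt`, matched within 2%) and the
cosine-series solution of the no-flux heat equation on a 64-point grid
(matched to < 0.5% maximum error out to `t = L²/D`). The semigroup property
(evolving to `t₁` then `t₂` equals evolving to `t₁ + t₂`) holds exactly
when the sample times are commensurate with the stability step; for
incommensurate times the per-segment step rounding introduces differences
of order `dt`, inherent to explicit Euler.

### Estimation

The per-cell chain is: extract axial profiles → normalize every frame to
the pre-bleach total (compensating acquisition photobleaching) → find the
bleach centre as the minimum of the (post − pre) difference profile (ties
resolve toward the cell centre, then the lower index) → build the recovery
curve as the centre-window mean (half-width 1 px) divided by its pre-bleach
value → fit `A(1 − e^(−τt))` to the rise above the post-bleach level →
report `M`, `τ½ = ln 0.5/(−τ)` and `D`.

The single-exponential fit uses Levenberg–Marquardt with analytic
residuals, parameter tolerance 1e-10, and perturbed-τ restarts. When
recovery is much faster than the frame interval, τ is only weakly
identified (any sufficiently fast rate fits); the amplitude `A`, which is
what the mobile fraction uses, remains well determined. A constant curve is
flagged degenerate with `A = 0` rather than fitted.

**Mobile fraction and D.** The textbook two-stage procedure estimates M
first — "final fluorescence" taken as the fitted plateau `post + A` (or
the last-k-frame mean via `final_mode = "last_k"`) — and then searches D
conditional on that M. Its weakness is structural: diffusive recovery is
not single-exponential, and whenever recovery is incomplete within the
imaging window the fitted plateau extrapolates with a bias that propagates
directly into D. Because the predicted observable is *linear* in M
(`observable = M·evolve(C_post) + (1 − M)·C_post`), the least-squares M for
any candidate D has a closed form, so the default estimator profiles M out
and minimizes over D alone, returning the joint least-squares pair. On
noiseless synthetic series this recovers the generating `(M, D)` to within
the search tolerance across `D ∈ [1e-4, 4e-3] μm² s⁻¹ × M ∈ [0.25, 1]`;
the two-stage path remains available (`estimator = "two_stage"`) and the
plateau-based raw M is always reported for QC (estimates with raw M
outside `[−0.05, 1.05]` are flagged rather than silently clipped).

The D search scans a log grid (25 points per decade, default range
`[1e-6, 1e-1] μm² s⁻¹` — bracketing the observed shell and cargo mobilities
by two orders of magnitude each way) and refines by golden section to a
relative tolerance of 1e-3. It is fully deterministic: no stochastic
optimizer, identical results on every run. A flat objective (no recovery
information, e.g. full immobility) is an error, not a number.

## Colocalization

Pearson's R is computed over all pixels of a whole-cell mask (Otsu
threshold on the summed channels, largest connected component, holes
filled) — no Costes thresholding, no puncta ROIs, matching whole-cell
usage; Manders coefficients and Costes randomization are out of scope.
Scatter pairs are returned in row-major order for the conventional
channel-1 vs channel-2 scatterplot. R is invariant to affine rescaling of
either channel (verified to 1e-12); background subtraction is available
but off by default since it does not change R. When several cells appear
in the field only the largest is analysed — a documented limitation of the
per-cell design.

## Assembly events

The study scored focus appearance by eye; bmcquant substitutes the
simplest auditable criterion: a focus is a connected region above
`mean + k·σ` of masked intensities (k = 3) with area ≥ 4 px, and a cell's
event is the first frame whose detection persists ≥ 2 consecutive frames
(single-frame flickers are ignored). A shell/cargo pair is labelled
`shell_first` or `cargo_first` when one precedes the other by more than the
concomitance window, else `concomitant`; the window defaults to 0 frames
because the measurement distinguishes events at its 1-frame resolution.
Focus positions are intensity-weighted centroids projected on the mask's
major axis, folded about mid-cell onto `[0, 0.5]` (0 = pole), and the
polar bias is summarized as the fraction of folded positions ≤ 0.25. All
thresholds are surfaced in `run_config()`.

## The synthetic-data generator

`generate_frap_series()` emulates the FRAP experiment end to end: a
uniform elongated structure (defaults: 3 × 1 μm at 0.05 μm/px — within the
2–4 μm rod-cell range and convenient for a mid-cell line bleach), an
instantaneous multiplicative bleach (width 0.3 μm, depth 0.8 — the actual
bleach-line geometry is unpublished, so these are fixture conventions),
two-population recovery at the configured `(D, M)`, rendering across the
rod cross-section, and Gaussian detection noise of 2% of the pre-bleach
level (Poisson shot noise optional). The `cargo_like` and `shell_like`
presets carry the reported group means (M = 0.83, D = 4.02e-4; M = 0.06,
D = 0.28e-4 μm² s⁻¹). One seed drives named substreams per stage, so the
ground-truth schedule is seed-invariant while noise realizations differ;
identical seeds reproduce bit-identical stacks.

Two features of real data are deliberately not emulated: optical
sectioning beyond a Gaussian point spread, and cell growth or division
during the series. Recovery tests therefore demonstrate estimator
correctness under the stated model — not robustness to out-of-model
effects such as membrane-proximal geometry, bleaching during acquisition
beyond the global normalization, or structure movement.

Because the FRAP ground truth flows through the same diffusion engine the
estimator inverts, round-trip tests alone would be circular. The generator
therefore also offers `engine = "analytic"`, producing profiles from the
cosine-series solution of the no-flux heat equation; recovering the
parameters of those fixtures shows the engine solves the PDE, not merely
its own discretization.

The colocalization generator places Gaussian foci at 2× cytosolic contrast
(typical of fluorescent-protein puncta over their cytosolic pool, and the
regime in which Otsu finds the cell rather than the puncta); a programmed
fraction ρ of channel-2 foci shares channel-1 centroids and the rest are
kept disjoint, so R increases strictly with ρ. The time-lapse generator
ramps a focus from 0 to full intensity over two frames at a scheduled
frame and axial position; `sample_folded_positions()` draws schedules with
a configurable pole-to-quarter probability (default 0.704, the observed
polar bias of initial assembly events).

## Problem sizes and determinism

The validation suite runs at the study's acquisition cadence but modest
spatial scale: 60-pixel profiles, 31–61 frames, 16-setting noiseless
recovery grids, 20 noisy replicates per preset, 50 scheduled time-lapses
and 500-event schedules — sizes at which every oracle is exercised while a
full run completes in about a minute. All stochastic stages consume
explicit seeds; reruns are bit-reproducible on the same platform.

## Known limitations

- 1D analysis presumes an elongated structure; compact or branched BMC
  morphologies violate the profile model.
- The immobile component is assumed strictly frozen; slow exchange between
  populations would bias M upward and D downward.
- Mean shell-like D estimates under noise are biased slightly upward
  (median error ~15–20%): with M ≈ 0.06 the recovery amplitude is close to
  the noise floor and the log-scale search asymmetrically favours faster
  candidates. The median, reported alongside, is the more robust summary.
- Focus detection assumes one dominant focus per cell (the first-assembly
  question); multi-BMC tracking and lineage analysis are out of scope.
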