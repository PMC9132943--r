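# bmcquant

Quantitative image analysis of bacterial microcompartment (BMC) biogenesis
from confocal fluorescence microscopy. The package targets the three
measurements that characterize how Pdu metabolosomes assemble in
*Salmonella*: the internal mobility of shell and cargo proteins by
fluorescence recovery after photobleaching (FRAP), the spatial association
of shell and cargo by Pearson colocalization, and the temporal order of de
novo assembly ("Shell first" vs "Cargo first") from dual-channel
time-lapses. A seeded synthetic-data generator emulates each experiment so
every stage is validated by parameter recovery against known ground truth.

## The FRAP model

A line is bleached across an elongated intracellular structure and the
fluorescence profile C(X, t) along the long axis is followed over time.
Profiles are normalized to the pre-bleach total fluorescence (compensating
acquisition photobleaching), and the recovery at the bleach centre is
summarized by three quantities:

- **Mobile fraction** — the proportion of fluorophores free to exchange into
  the bleached region,

      M = (F_final − F_post) / (F_pre − F_post),

  evaluated at the bleach centre on the normalized scale.

- **Half-time** — from the single-exponential description of the recovery
  curve f(t) = A (1 − e^(−τt)), with τ½ = ln 0.5 / (−τ).

- **Diffusion coefficient** — by matching a finite-difference simulation of
  the 1D diffusion equation ∂C/∂t = D ∂²C/∂X² to the observed recovery. The
  first post-bleach profile is split into an immobile part (1 − M)·C_post,
  which keeps the bleach scar, and a mobile part M·C_post, which relaxes by
  free diffusion with reflecting (no-flux) boundaries at the cell envelope.
  Candidate D values are scanned on a log grid and refined by golden
  section; because the predicted curve is linear in M, the best M for each
  candidate D has a closed form and the default estimator returns the joint
  least-squares pair (M, D).

Colocalization is the product-moment correlation of the two channels' pixel
intensities within an Otsu-derived whole-cell mask. Assembly events are the
first frame at which a focus (connected region above mean + 3 SD, ≥ 4 px)
persists for ≥ 2 frames in each channel; cells are labelled shell-first,
cargo-first or concomitant, and focus positions are folded onto the
pole-to-midcell axis (0 = pole, 0.5 = mid-cell).

## Worked example

Simulate a cargo-like FRAP experiment (mobile fraction 0.83, D = 4.02 ×
10⁻⁴ μm² s⁻¹, 2% detection noise, one 60 s frame per minute for an hour)
and analyse it:

```r
library(bmcquant)

params <- frap_preset("cargo_like", seed = 7)
sim <- generate_frap_series(params)
est <- analyze_frap_series(sim$series)
est[, c("M", "A", "half_time", "D")]
#>         M        A half_time            D
#> 1 0.82952 0.634373  73.08808 0.0003987744
```

The estimated mobile fraction (0.830) and diffusion coefficient
(3.99 × 10⁻⁴ μm² s⁻¹) recover the generator's ground truth; `A` is the
fitted recovery amplitude above the post-bleach level and `half_time` the
exponential half-time in seconds. Group summaries reproduce the reporting
style mean ± SD (n):

```r
s <- summarize_frap(rbind(cargo_estimates, shell_estimates),
                    group = rep(c("cargo", "shell"), c(20, 20)))
s$D_fold_ratio   # ratio of mean diffusion coefficients
```

A thin command-line wrapper is installed at `inst/cli/bmcquant.R`:

```sh
Rscript inst/cli/bmcquant.R simulate --preset cargo_like --seed 7 --output-dir out/
Rscript inst/cli/bmcquant.R frap --input out/cargo_like_frap.tif --pixel-size 0.05 --interval 60
```

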