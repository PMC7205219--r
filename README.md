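# bayesdiff

Bayesian estimation of diffusion coefficients from single-particle
tracking (SPT) trajectories, and prediction of how distinguishable two
diffusivity estimates really are.

## The problem

In SPT experiments a live cell is imaged over time, punctate objects are
linked into trajectories, and the local diffusion coefficient *D*
(μm²/s) is inferred from each trajectory's frame-to-frame steps. Two
features of real data make this hard:

* trajectories are finite, so each one offers limited evidence about a
  stochastic process, and
* every localization carries static error, which inflates the apparent
  step sizes.

Plotting per-trajectory MSD lines and comparing their intercepts gives a
point estimate with no uncertainty statement, and easily suggests
heterogeneous diffusivity where there is only sampling noise. This
package instead returns a full posterior distribution per trajectory and
a quantitative answer to "are these two trajectories sampling different
diffusivities, or the same one?"

## The model

For homogeneous isotropic diffusion, each per-axis frame-to-frame step
is a draw from N(0, σ²) with σ² = 2 D Δt per axis (so the total MSD over
*d* axes at lag Δt is 2 d D Δt). The conjugate prior for the variance of
a zero-mean Gaussian is the inverse-gamma distribution

IG(x; a, b) = b^a / Γ(a) · x^-(a+1) · e^(-b/x),

so with the uninformative limit (a₀, b₀) → (0, 0), the N pooled step
components with sum of squares S give the closed-form posterior

σ² | data ~ IG(N/2, S/2),   D | data ~ IG(N/2, S/(4Δt)),

whose mode b/(a+1) is the point estimate of D. Distinguishability of two
posteriors IG(a, b) and IG(â, b̂) is the symmetrized Kullback–Leibler
divergence, computed in closed form with the digamma function Ψ:

KL(p‖q) = (a − â) Ψ(a) + ln Γ(â) − ln Γ(a) + â (ln b − ln b̂) + a (b̂ − b)/b.

The inverse of the divergence is the number of observations you could
draw from one posterior in place of the other before significant
information loss: KL = 0.01 means ~100 substitutable measurements (the
diffusivities are practically the same); KL ≥ 1 means one or fewer (they
are distinct).

The package also simulates Brownian and fractional Brownian (Hurst
H ≠ 0.5) trajectories with static localization error, and builds
Monte-Carlo look-up tables — estimation error over (trajectory length ×
localization error), and mean symmetrized KL over (length × diffusivity
ratio) — for planning experiments before collecting data.

## Worked example

```r
library(bayesdiff)
set.seed(20)

cfg  <- sim_config(diffusivity = 0.1, n_steps = 200, n_dim = 2,
                   loc_error_sd = 0.05)
traj <- simulate_brownian(cfg)
post <- estimate_diffusivity(traj)
post
#> Inverse-gamma posterior over diffusivity: a = 200, b = 20.6094 um^2/s
#>   mode = 0.102534, 90% credible interval [0.0920819, 0.116227] um^2/s
```

The 200-step track recovers the true D = 0.1 μm²/s to within ~2.5%, and
the credible interval quantifies the residual uncertainty. Comparing it
with a track diffusing three times faster:

```r
post2 <- estimate_diffusivity(simulate_brownian(
  sim_config(diffusivity = 0.3, n_steps = 200, n_dim = 2,
             loc_error_sd = 0.05)))
symmetric_kl(post, post2)
#> [1] 100.1349
substitutable_observations(symmetric_kl(post, post2))$interpretation
#> [1] "distinct"
```

A divergence of ~100 nats (far above 1) flags the two tracks as having
genuinely different diffusivities. An experiment-design look-up table:

```r
tab <- error_table(error_table_spec(diffusivity = 0.1,
                                    lengths = c(10, 50, 100, 1000),
                                    loc_errors = c(0, 0.05, 0.1),
                                    n_replicates = 500, master_seed = 1))
tab
#>          0  0.05   0.1
#> 10   24.05 23.95 24.84
#> 50   11.35 11.49 12.86
#> 100   7.87  8.02 11.22
#> 1000  2.47  3.12  9.67
predict_error(tab, 50, 0.1)
#> [1] 12.85791
```

Each cell is the mean |% error| of the posterior-mode estimate: ~50-frame
tracks with 0.1 μm localization error carry roughly 13–15% estimation
error, and no amount of length rescues a track whose localization error
variance (σ_loc²/Δt = 0.01 μm²/s here) is a sizable fraction of D — the
mode converges to D + σ_loc²/Δt, a 10% bias floor at these settings.

## Command line

```sh
alias bayesdiff="Rscript $(Rscript -e 'cat(system.file("cli", "bayesdiff.R", package = "bayesdiff"))')"
bayesdiff simulate --d 0.1 --steps 200 --n-tracks 5 --loc-error 0.05 --seed 1 --out tracks.csv
bayesdiff estimate --in tracks.csv --out posteriors.csv
bayesdiff compare  --in posteriors.csv --out pairs.csv
bayesdiff table    --kind kl --ratios 1,2,5 --lengths 10,100,1000 --replicates 500 --seed 1 --out kl.csv
```

Trajectory files are plain CSV (`track_id, frame, t_sec, x_um, y_um[,
z_um]`), matching common tracker exports; every run writes a
`<out>.config.txt` sidecar with its fully resolved parameters so any
output is reproducible from the sidecar and seed alone.

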