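# Shared fixtures and independent oracles.

# Step sample built directly from components (bypasses trajectories).
make_step_sample <- function(components, dt = 1, n_dim = 1) {
  structure(list(components = components,
                 n_components = length(components),
                 sum_sq = sum(components^2),
                 dt = dt, n_dim = n_dim),
            class = "step_sample")
}

# Trajectory built from a position matrix (frames x dims).
make_trajectory <- function(positions, dt = 1) {
  positions <- as.matrix(positions)
  structure(list(times = (seq_len(nrow(positions)) - 1) * dt,
                 positions_true = positions,
                 positions_observed = positions,
                 config = NULL),
            class = "spt_trajectory")
}

# Quadrature oracle for the directed inverse-gamma KL divergence,
# independent of the closed form under test.
kl_quadrature <- function(a, b, ah, bh) {
  ld <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
  stats::integrate(function(x) exp(ld(x, a, b)) *
                     (ld(x, a, b) - ld(x, ah, bh)),
                   0, Inf, rel.tol = 1e-10)$value
}

# Mean percent-error magnitude of the posterior-mode estimate over
# n_rep simulated trajectories (the pipeline the look-up tables run).
mean_abs_pct_error <- function(n_rep, d_true, n_steps, loc_sd = 0,
                               dt = 1, n_dim = 2, hurst = 0.5) {
  cfg <- sim_config(diffusivity = d_true, n_steps = n_steps, dt = dt,
                    n_dim = n_dim, loc_error_sd = loc_sd, hurst = hurst)
  mean(replicate(n_rep, {
    traj <- if (hurst == 0.5) simulate_brownian(cfg)
            else simulate_fbm_trajectory(cfg)
    percent_error(posterior_mode(estimate_diffusivity(traj)), d_true)
  }))
}
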