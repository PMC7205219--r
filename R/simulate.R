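#' Simulation settings for a synthetic particle trajectory
#'
#' Bundles the physical and sampling parameters of a single-particle
#' tracking simulation: the true diffusion coefficient, the number of
#' frame-to-frame steps, the frame interval, the spatial dimensionality,
#' the static localization error, and (for fractional Brownian motion)
#' the Hurst coefficient.
#'
#' @param diffusivity true diffusion coefficient D in um^2/s, >= 0.
#'   Zero gives a stationary particle (useful for pure-noise studies).
#' @param n_steps number of frame-to-frame steps T (the trajectory has
#'   T + 1 frames), positive integer.
#' @param dt frame interval in seconds, > 0.
#' @param n_dim spatial dimensionality, 1, 2 or 3.
#' @param loc_error_sd static localization error SD per axis, in um, >= 0.
#'   Applied as independent Gaussian noise to every frame of every axis.
#' @param hurst Hurst coefficient H in (0, 1); 0.5 means pure Brownian
#'   motion, H < 0.5 anti-correlated (sub-diffusive) increments.
#' @param seed optional integer RNG seed for reproducible trajectories.
#' @return An object of class \code{"sim_config"}.
#' @seealso [simulate_brownian()], [simulate_fbm_trajectory()]
#' @export
sim_config <- function(diffusivity = 0.1, n_steps = 100, dt = 1,
                       n_dim = 2, loc_error_sd = 0, hurst = 0.5,
                       seed = NULL) {
  if (!is.numeric(diffusivity) || length(diffusivity) != 1 ||
      is.na(diffusivity) || diffusivity < 0)
    stop("'diffusivity' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(n_steps) || length(n_steps) != 1 || is.na(n_steps) ||
      n_steps < 1 || n_steps != round(n_steps))
    stop("'n_steps' must be a positive integer", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1 || is.na(dt) || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  if (!n_dim %in% c(1, 2, 3))
    stop("'n_dim' must be 1, 2 or 3", call. = FALSE)
  if (!is.numeric(loc_error_sd) || length(loc_error_sd) != 1 ||
      is.na(loc_error_sd) || loc_error_sd < 0)
    stop("'loc_error_sd' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(hurst) || length(hurst) != 1 || is.na(hurst) ||
      hurst <= 0 || hurst >= 1)
    stop("'hurst' must lie strictly between 0 and 1", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(diffusivity = diffusivity, n_steps = as.integer(n_steps),
                 dt = dt, n_dim = as.integer(n_dim),
                 loc_error_sd = loc_error_sd, hurst = hurst, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Trajectory simulation config\n")
  cat(sprintf("  D = %g um^2/s, %d steps, dt = %g s, %dD\n",
              x$diffusivity, x$n_steps, x$dt, x$n_dim))
  cat(sprintf("  localization error SD = %g um, Hurst H = %g\n",
              x$loc_error_sd, x$hurst))
  invisible(x)
}

new_trajectory <- function(times, positions_true, positions_observed,
                           config = NULL) {
  stopifnot(identical(dim(positions_true), dim(positions_observed)),
            length(times) == nrow(positions_true))
  structure(list(times = times,
                 positions_true = positions_true,
                 positions_observed = positions_observed,
                 config = config),
            class = "spt_trajectory")
}

#' @export
print.spt_trajectory <- function(x, ...) {
  cat(sprintf("Single-particle trajectory: %d frames, %d spatial dim, dt = %g s\n",
              nrow(x$positions_true), ncol(x$positions_true),
              trajectory_dt(x)))
  invisible(x)
}

# Uniform frame interval of a trajectory; errors if spacing is not constant.
trajectory_dt <- function(traj, tol = 1e-9) {
  dts <- diff(traj$times)
  dt <- dts[1]
  if (any(abs(dts - dt) > tol * max(dt, 1)))
    stop("trajectory frames are not uniformly spaced", call. = FALSE)
  dt
}

#' Simulate a pure Brownian trajectory
#'
#' Draws each per-axis frame-to-frame displacement independently from a
#' zero-mean Gaussian with variance \code{2 * D * dt} (the Einstein
#' relation per spatial axis, so that the total mean squared displacement
#' over \code{d} axes at lag \code{dt} is \code{2 * d * D * dt}), then
#' accumulates displacements from the origin. Static localization error,
#' if requested in the config, is applied to every frame afterwards via
#' [apply_localization_error()].
#'
#' @param config a [sim_config()] with \code{hurst = 0.5}.
#' @return An object of class \code{"spt_trajectory"} with elements
#'   \code{times} (seconds), \code{positions_true} and
#'   \code{positions_observed} ((T+1) x d matrices, um) and \code{config}.
#' @examples
#' traj <- simulate_brownian(sim_config(diffusivity = 0.1, n_steps = 50,
#'                                      loc_error_sd = 0.1, seed = 1))
#' traj
#' @export
simulate_brownian <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$hurst != 0.5)
    stop("simulate_brownian() requires hurst = 0.5; use simulate_fbm_trajectory()",
         call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  T_ <- config$n_steps
  d <- config$n_dim
  sd_step <- sqrt(2 * config$diffusivity * config$dt)
  steps <- matrix(stats::rnorm(T_ * d, mean = 0, sd = sd_step), T_, d)
  pos <- matrix(0, T_ + 1, d)
  pos[-1, ] <- apply(steps, 2, cumsum)
  times <- seq(0, by = config$dt, length.out = T_ + 1)
  traj <- new_trajectory(times, pos, pos, config)
  apply_localization_error(traj, config$loc_error_sd)
}

#' Add static localization error to a trajectory
#'
#' Perturbs every frame of every axis (including the first frame) with
#' independent zero-mean Gaussian noise of standard deviation
#' \code{loc_error_sd}, mimicking the finite spatial resolution of
#' localization microscopy. The noise-free positions are retained in
#' \code{positions_true}; only \code{positions_observed} changes.
#'
#' @param traj an \code{"spt_trajectory"}.
#' @param loc_error_sd per-axis localization error SD in um, >= 0.
#' @return The trajectory with noisy \code{positions_observed}.
#' @export
apply_localization_error <- function(traj, loc_error_sd) {
  stopifnot(inherits(traj, "spt_trajectory"))
  if (!is.numeric(loc_error_sd) || length(loc_error_sd) != 1 ||
      is.na(loc_error_sd) || loc_error_sd < 0)
    stop("'loc_error_sd' must be a single non-negative number", call. = FALSE)
  if (loc_error_sd == 0) {
    traj$positions_observed <- traj$positions_true
    return(traj)
  }
  noise <- matrix(stats::rnorm(length(traj$positions_true),
                               sd = loc_error_sd),
                  nrow(traj$positions_true), ncol(traj$positions_true))
  traj$positions_observed <- traj$positions_true + noise
  traj
}

# Autocovariance of fractional Gaussian noise at integer lags k for
# per-step SD sigma: (sigma^2 / 2) (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}).
fgn_acvf <- function(k, hurst, sigma = 1) {
  h2 <- 2 * hurst
  (sigma^2 / 2) * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}

#' Simulate fractional Gaussian noise
#'
#' Generates a stationary sequence of \code{n} fractional Gaussian noise
#' increments with Hurst coefficient \code{hurst} and per-step standard
#' deviation \code{sigma}, using circulant embedding (Davies-Harte): the
#' target autocovariance sequence is embedded in a circulant matrix whose
#' eigenvalues are obtained by FFT, so the generated sequence has exactly
#' the closed-form autocovariance
#' \deqn{\gamma(k) = \frac{\sigma^2}{2}\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right).}
#' At \code{hurst = 0.5} the increments are i.i.d. Gaussian. Falls back to
#' a Cholesky factorization of the covariance matrix in the (rare) event
#' the embedding is not non-negative definite.
#'
#' @param n number of increments, >= 1.
#' @param hurst Hurst coefficient in (0, 1).
#' @param sigma per-step standard deviation (units of the increments).
#' @return Numeric vector of \code{n} increments.
#' @examples
#' x <- simulate_fgn(1000, hurst = 0.375)
#' cor(x[-1], x[-1000])  # anti-correlated for H < 0.5
#' @export
simulate_fgn <- function(n, hurst, sigma = 1) {
  if (!is.numeric(hurst) || length(hurst) != 1 || is.na(hurst) ||
      hurst <= 0 || hurst >= 1)
    stop("'hurst' must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  if (hurst == 0.5) return(stats::rnorm(n, sd = sigma))
  if (n == 1) return(stats::rnorm(1, sd = sigma))
  ev <- fgn_embedding_eigenvalues(n, hurst)
  if (any(ev < 0)) {
    # Cholesky fallback: exact but O(n^3)
    Sigma <- fgn_covariance(n, hurst, sigma)
    L <- chol(Sigma)
    return(drop(crossprod(L, stats::rnorm(n))))
  }
  m <- length(ev)                       # 2 (n - 1)
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  # the real part of F diag(sqrt(ev/m)) z has exactly the Toeplitz
  # covariance embedded in the circulant
  w <- stats::fft(sqrt(ev / m) * z)
  sigma * Re(w[seq_len(n)])
}

# Eigenvalues of the circulant embedding of the FGN covariance (unit
# sigma): FFT of the even sequence r(0), ..., r(M/2), r(M/2 - 1), ...,
# r(1), with M the next power of two >= 2(n - 1) so the FFT stays
# O(M log M) for every n (the autocovariance is defined at all lags, so
# padding the embedding only enlarges the circulant).
fgn_embedding_eigenvalues <- function(n, hurst) {
  half <- max(n - 1, 1)
  half <- 2^ceiling(log2(half))
  r <- fgn_acvf(0:half, hurst)
  Re(stats::fft(c(r, r[half:2])))
}

# Dense FGN covariance matrix (Toeplitz of the closed-form autocovariance).
fgn_covariance <- function(n, hurst, sigma = 1) {
  r <- fgn_acvf(0:(n - 1), hurst, sigma)
  stats::toeplitz(r)
}

#' Simulate a fractional Brownian motion trajectory
#'
#' Generates per-axis displacements as fractional Gaussian noise with the
#' configured Hurst coefficient, calibrated so that the effective
#' diffusion coefficient at the reference lag \code{tau_ref} equals the
#' configured diffusivity: the per-axis mean squared displacement at lag
#' \code{tau_ref} is \code{2 * D * tau_ref}, which fixes the per-step
#' variance at \code{2 * D * tau_ref^(1 - 2H) * dt^(2H)}. Sub-diffusive
#' motion (\code{hurst < 0.5}) therefore has no single diffusivity: D is
#' meaningful only at the reference lag. At \code{hurst = 0.5} the output
#' is statistically identical to [simulate_brownian()]. Localization
#' error is applied as in the Brownian case.
#'
#' @param config a [sim_config()]; \code{hurst} may differ from 0.5.
#' @param tau_ref reference lag in seconds at which the effective
#'   diffusivity is defined (default 1 s).
#' @return An \code{"spt_trajectory"}.
#' @examples
#' traj <- simulate_fbm_trajectory(sim_config(diffusivity = 0.1,
#'                                            n_steps = 100, hurst = 0.375,
#'                                            seed = 1))
#' @export
simulate_fbm_trajectory <- function(config, tau_ref = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(tau_ref) || length(tau_ref) != 1 || tau_ref <= 0)
    stop("'tau_ref' must be a single positive number", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  T_ <- config$n_steps
  d <- config$n_dim
  H <- config$hurst
  sigma_step <- sqrt(2 * config$diffusivity * tau_ref^(1 - 2 * H) *
                       config$dt^(2 * H))
  steps <- vapply(seq_len(d),
                  function(i) simulate_fgn(T_, H, sigma_step),
                  numeric(T_))
  steps <- matrix(steps, T_, d)
  pos <- matrix(0, T_ + 1, d)
  pos[-1, ] <- apply(steps, 2, cumsum)
  times <- seq(0, by = config$dt, length.out = T_ + 1)
  traj <- new_trajectory(times, pos, pos, config)
  apply_localization_error(traj, config$loc_error_sd)
}
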