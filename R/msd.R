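#' Mean squared displacement curve of a trajectory
#'
#' For each lag tau = k * dt, k = 1..max_lag, averages the squared
#' Euclidean displacement over all overlapping frame pairs k frames
#' apart. For homogeneous isotropic diffusion the curve follows
#' MSD(tau) = 2 * d * D * tau^alpha with alpha = 1; sub-diffusive motion
#' has alpha < 1.
#'
#' @param traj an \code{"spt_trajectory"}.
#' @param max_lag largest lag in frames; must be smaller than the number
#'   of frames. Default: a quarter of the available steps (at least 1),
#'   the usual guard against the noisy long-lag tail.
#' @param use_observed use observed (TRUE, default) or true positions.
#' @return A data.frame with columns \code{lag_frames}, \code{lag_time}
#'   (s), \code{msd} (um^2) and \code{n_pairs}.
#' @export
msd_curve <- function(traj, max_lag = NULL, use_observed = TRUE) {
  stopifnot(inherits(traj, "spt_trajectory"))
  pos <- if (use_observed) traj$positions_observed else traj$positions_true
  n_frames <- nrow(pos)
  dt <- trajectory_dt(traj)
  if (is.null(max_lag)) max_lag <- max(1L, (n_frames - 1L) %/% 4L)
  if (max_lag >= n_frames || max_lag < 1)
    stop("'max_lag' must be between 1 and the number of steps", call. = FALSE)
  msd <- numeric(max_lag)
  n_pairs <- integer(max_lag)
  for (k in seq_len(max_lag)) {
    d2 <- rowSums((pos[(k + 1):n_frames, , drop = FALSE] -
                     pos[1:(n_frames - k), , drop = FALSE])^2)
    msd[k] <- mean(d2)
    n_pairs[k] <- length(d2)
  }
  data.frame(lag_frames = seq_len(max_lag),
             lag_time = seq_len(max_lag) * dt,
             msd = msd, n_pairs = n_pairs)
}

#' Diffusivity and scaling exponent from an MSD curve
#'
#' Unweighted least-squares fit of log(MSD) against log(tau): the slope
#' is the anomalous scaling exponent alpha, and the intercept gives the
#' (effective) diffusion coefficient via MSD = 2 * d * D * tau^alpha.
#' This is the conventional log-log MSD estimator the Bayesian posterior
#' is compared against; it yields a point estimate only, with no
#' uncertainty statement.
#'
#' @param curve a data.frame with columns \code{lag_time} and \code{msd}
#'   (as returned by [msd_curve()], possibly ensemble-averaged).
#' @param n_dim spatial dimensionality d of the underlying trajectory.
#' @return A list with \code{diffusivity} (um^2/s, effective at tau = 1 s
#'   when alpha != 1) and \code{alpha}.
#' @examples
#' curve <- data.frame(lag_time = 1:10, msd = 4 * 0.1 * (1:10))
#' msd_fit(curve, n_dim = 2)  # D = 0.1, alpha = 1
#' @export
msd_fit <- function(curve, n_dim) {
  stopifnot(is.data.frame(curve),
            all(c("lag_time", "msd") %in% names(curve)))
  if (!n_dim %in% c(1, 2, 3))
    stop("'n_dim' must be 1, 2 or 3", call. = FALSE)
  usable <- curve$msd > 0 & curve$lag_time > 0
  if (any(!usable))
    warning(sum(!usable), " non-positive MSD point(s) excluded from the log-log fit")
  if (sum(usable) < 2)
    stop("need at least 2 positive MSD points for the log-log fit",
         call. = FALSE)
  fit <- stats::lm(log(msd) ~ log(lag_time), data = curve[usable, ])
  alpha <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  list(diffusivity = exp(intercept) / (2 * n_dim), alpha = alpha)
}
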