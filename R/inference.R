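#' Extract per-axis frame-to-frame steps from a trajectory
#'
#' Splits a trajectory into its per-axis frame-to-frame displacements and
#' records the sufficient statistics for variance inference. Under
#' isotropic diffusion every axis shares one step variance, so the d
#' per-axis components of each of the T displacement vectors are pooled
#' into a single sample of N = T * d scalar draws.
#'
#' @param traj an \code{"spt_trajectory"} (simulated or read from file).
#' @param use_observed if TRUE (default) steps are taken from
#'   \code{positions_observed}, i.e. including localization error, as a
#'   tracking experiment would see; FALSE uses the noise-free positions.
#' @return An object of class \code{"step_sample"}: \code{components}
#'   (all per-axis displacements, um), \code{n_components}, \code{sum_sq}
#'   (um^2), \code{dt} (s) and \code{n_dim}.
#' @export
extract_steps <- function(traj, use_observed = TRUE) {
  stopifnot(inherits(traj, "spt_trajectory"))
  pos <- if (use_observed) traj$positions_observed else traj$positions_true
  if (nrow(pos) < 2)
    stop("trajectory must have at least 2 frames to extract steps",
         call. = FALSE)
  dt <- trajectory_dt(traj)
  disp <- diff(pos)                 # T x d matrix of displacements
  components <- as.vector(t(disp))  # frame-major order
  structure(list(components = components,
                 n_components = length(components),
                 sum_sq = sum(components^2),
                 dt = dt,
                 n_dim = ncol(pos)),
            class = "step_sample")
}

#' @export
print.step_sample <- function(x, ...) {
  cat(sprintf("Step sample: N = %d per-axis components (%dD, dt = %g s), sum of squares = %g um^2\n",
              x$n_components, x$n_dim, x$dt, x$sum_sq))
  invisible(x)
}

#' Prior for the step-variance / diffusivity posterior
#'
#' Inverse-gamma prior hyperparameters for the conjugate update. The
#' default \code{(0, 0)} is the uninformative (improper) limit in which
#' every order of magnitude of the variance is a priori equally likely;
#' it becomes proper as soon as one nonzero step is observed.
#'
#' @param a0 prior shape, >= 0.
#' @param b0 prior scale, >= 0 (um^2 when the variable is a step variance).
#' @return An object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(a0 = 0, b0 = 0) {
  if (!is.numeric(a0) || length(a0) != 1 || is.na(a0) || a0 < 0 ||
      !is.finite(a0))
    stop("'a0' must be a single finite non-negative number", call. = FALSE)
  if (!is.numeric(b0) || length(b0) != 1 || is.na(b0) || b0 < 0 ||
      !is.finite(b0))
    stop("'b0' must be a single finite non-negative number", call. = FALSE)
  structure(list(a0 = a0, b0 = b0), class = "prior_spec")
}

new_invgamma_posterior <- function(shape_a, scale_b, variable, dt, n_dim) {
  stopifnot(shape_a > 0, scale_b > 0,
            variable %in% c("step_variance", "diffusivity"))
  structure(list(shape_a = shape_a, scale_b = scale_b,
                 variable = variable, dt = dt, n_dim = n_dim),
            class = "invgamma_posterior")
}

#' @export
print.invgamma_posterior <- function(x, ...) {
  units <- if (x$variable == "diffusivity") "um^2/s" else "um^2"
  cat(sprintf("Inverse-gamma posterior over %s: a = %g, b = %g %s\n",
              x$variable, x$shape_a, x$scale_b, units))
  cat(sprintf("  mode = %g, 90%% credible interval [%g, %g] %s\n",
              posterior_mode(x),
              qinvgamma(0.05, x$shape_a, x$scale_b),
              qinvgamma(0.95, x$shape_a, x$scale_b), units))
  invisible(x)
}

#' Conjugate posterior over the per-axis step variance
#'
#' Bayesian update for the variance of a zero-mean Gaussian with known
#' mean: with an inverse-gamma prior IG(a0, b0) and N observed step
#' components with sum of squares S, the posterior is
#' IG(a0 + N/2, b0 + S/2). With the uninformative prior (0, 0) this is
#' IG(N/2, S/2).
#'
#' @param steps a \code{"step_sample"} from [extract_steps()].
#' @param prior a [prior_spec()]; default uninformative.
#' @return An \code{"invgamma_posterior"} with \code{variable =
#'   "step_variance"}.
#' @seealso [to_diffusivity_posterior()] for the rescaling to diffusivity.
#' @export
fit_variance_posterior <- function(steps, prior = prior_spec()) {
  stopifnot(inherits(steps, "step_sample"), inherits(prior, "prior_spec"))
  if (steps$n_components < 1)
    stop("at least one step component is required", call. = FALSE)
  b <- prior$b0 + steps$sum_sq / 2
  if (b <= 0)
    stop("degenerate posterior: all steps are zero and the prior is improper",
         call. = FALSE)
  new_invgamma_posterior(shape_a = prior$a0 + steps$n_components / 2,
                         scale_b = b,
                         variable = "step_variance",
                         dt = steps$dt, n_dim = steps$n_dim)
}

#' Rescale a step-variance posterior to a diffusivity posterior
#'
#' Uses the per-axis Einstein relation sigma^2 = 2 * D * dt: dividing an
#' inverse-gamma variate by the constant 2 * dt leaves the shape unchanged
#' and divides the scale, so IG(a, b) over sigma^2 becomes
#' IG(a, b / (2 * dt)) over D.
#'
#' @param post an \code{"invgamma_posterior"} over the step variance.
#' @return The posterior over the diffusivity (um^2/s).
#' @export
to_diffusivity_posterior <- function(post) {
  stopifnot(inherits(post, "invgamma_posterior"))
  if (post$variable == "diffusivity")
    stop("posterior is already over diffusivity (double transform?)",
         call. = FALSE)
  new_invgamma_posterior(shape_a = post$shape_a,
                         scale_b = post$scale_b / (2 * post$dt),
                         variable = "diffusivity",
                         dt = post$dt, n_dim = post$n_dim)
}

#' Point and interval summaries of an inverse-gamma posterior
#'
#' \code{posterior_mode} returns the density argmax \code{b / (a + 1)},
#' the point estimate used throughout; \code{posterior_mean} returns
#' \code{b / (a - 1)} (defined for \code{a > 1});
#' \code{posterior_interval} returns a central credible interval.
#'
#' @param post an \code{"invgamma_posterior"}.
#' @param level credible level for the central interval (default 0.9).
#' @return A single value (mode/mean) or a two-element named vector
#'   (interval), in the posterior's units.
#' @export
posterior_mode <- function(post) {
  stopifnot(inherits(post, "invgamma_posterior"))
  post$scale_b / (post$shape_a + 1)
}

#' @rdname posterior_mode
#' @export
posterior_mean <- function(post) {
  stopifnot(inherits(post, "invgamma_posterior"))
  if (post$shape_a <= 1)
    stop("posterior mean is undefined for shape <= 1", call. = FALSE)
  post$scale_b / (post$shape_a - 1)
}

#' @rdname posterior_mode
#' @export
posterior_interval <- function(post, level = 0.9) {
  stopifnot(inherits(post, "invgamma_posterior"),
            level > 0, level < 1)
  alpha <- (1 - level) / 2
  c(lower = qinvgamma(alpha, post$shape_a, post$scale_b),
    upper = qinvgamma(1 - alpha, post$shape_a, post$scale_b))
}

#' Magnitude of the percent estimation error
#'
#' \code{|100 * (estimate - true_d) / true_d|}, the figure of merit used
#' by the estimation-error look-up tables.
#'
#' @param estimate estimated diffusivity (or variance).
#' @param true_d true value, > 0.
#' @return Non-negative percent error (vectorized over \code{estimate}).
#' @export
percent_error <- function(estimate, true_d) {
  if (!is.numeric(true_d) || any(true_d <= 0))
    stop("'true_d' must be positive", call. = FALSE)
  abs(100 * (estimate - true_d) / true_d)
}

#' Full inference pipeline for one trajectory
#'
#' Convenience wrapper: extract steps, fit the conjugate step-variance
#' posterior and rescale it to diffusivity.
#'
#' @inheritParams extract_steps
#' @inheritParams fit_variance_posterior
#' @return An \code{"invgamma_posterior"} over the diffusivity.
#' @examples
#' traj <- simulate_brownian(sim_config(diffusivity = 0.1, n_steps = 200,
#'                                      seed = 7))
#' estimate_diffusivity(traj)
#' @export
estimate_diffusivity <- function(traj, prior = prior_spec(),
                                 use_observed = TRUE) {
  steps <- extract_steps(traj, use_observed = use_observed)
  to_diffusivity_posterior(fit_variance_posterior(steps, prior))
}
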