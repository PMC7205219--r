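#' Kullback-Leibler divergence between two inverse-gamma posteriors
#'
#' Closed-form directed KL divergence, in nats, between p = IG(a, b) and
#' q = IG(a_hat, b_hat):
#' \deqn{KL(p \| q) = (a - \hat a)\,\Psi(a) + \log\Gamma(\hat a) -
#'   \log\Gamma(a) + \hat a (\log b - \log \hat b) + a\,\frac{\hat b - b}{b},}
#' where \eqn{\Psi} is the digamma function. The divergence is
#' non-negative, zero iff the parameter pairs coincide, asymmetric in its
#' arguments, and invariant to rescaling both scale parameters by the
#' same constant (so converting variance posteriors to diffusivity
#' posteriors never changes distinguishability).
#'
#' @param p,q objects of class \code{"invgamma_posterior"} over the same
#'   variable, or bare lists/vectors with elements \code{shape_a} and
#'   \code{scale_b}.
#' @return Directed divergence in nats, >= 0.
#' @seealso [symmetric_kl()] for the symmetrized version used to compare
#'   trajectories.
#' @export
kl_inverse_gamma <- function(p, q) {
  pp <- as_ig_params(p)
  qq <- as_ig_params(q)
  check_same_variable(p, q)
  a <- pp$a; b <- pp$b
  ah <- qq$a; bh <- qq$b
  (a - ah) * digamma(a) + lgamma(ah) - lgamma(a) +
    ah * (log(b) - log(bh)) + a * (bh - b) / b
}

#' Symmetrized KL divergence between two posteriors
#'
#' The average of the two directed divergences,
#' \code{(KL(p, q) + KL(q, p)) / 2}: symmetric under argument exchange
#' and zero iff the posteriors are identical. This is the
#' distinguishability measure reported in the look-up tables.
#'
#' @inheritParams kl_inverse_gamma
#' @return Symmetrized divergence in nats, >= 0.
#' @export
symmetric_kl <- function(p, q) {
  (kl_inverse_gamma(p, q) + kl_inverse_gamma(q, p)) / 2
}

#' Substitutable-observations interpretation of a KL divergence
#'
#' The inverse of a KL divergence can be read as the number of
#' observations that can be drawn from one distribution in place of the
#' other before the information loss becomes significant: a divergence of
#' 0.01 permits about 100 substitutable measurements (the posteriors are
#' practically interchangeable), while a divergence of 1 or more permits
#' at most one, indicating genuinely distinct diffusivities.
#'
#' @param kl non-negative divergence (nats).
#' @return A list with \code{n_observations} (\code{1/kl}; \code{Inf}
#'   when \code{kl = 0}) and \code{interpretation}, one of
#'   \code{"identical"} (kl = 0), \code{"distinct"} (kl >= 1, one or
#'   fewer substitutable observations) or \code{"substitutable"}.
#' @examples
#' substitutable_observations(0.01)  # 100 measurements
#' @export
substitutable_observations <- function(kl) {
  if (!is.numeric(kl) || length(kl) != 1 || is.na(kl) || kl < 0)
    stop("'kl' must be a single non-negative number", call. = FALSE)
  if (kl == 0)
    return(list(n_observations = Inf, interpretation = "identical"))
  n <- 1 / kl
  list(n_observations = n,
       interpretation = if (kl >= 1) "distinct" else "substitutable")
}

#' Pairwise symmetrized KL divergences for a set of posteriors
#'
#' @param posteriors named list of \code{"invgamma_posterior"} objects
#'   (names become track identifiers).
#' @return A data.frame over all unordered pairs with columns
#'   \code{track_id_1}, \code{track_id_2}, \code{kl_sym},
#'   \code{n_substitutable} and \code{interpretation}.
#' @export
kl_pairs <- function(posteriors) {
  stopifnot(is.list(posteriors))
  if (length(posteriors) < 2)
    stop("at least 2 posteriors are required for pairwise comparison",
         call. = FALSE)
  ids <- names(posteriors)
  if (is.null(ids)) ids <- as.character(seq_along(posteriors))
  idx <- utils::combn(length(posteriors), 2)
  rows <- apply(idx, 2, function(ij) {
    kl <- symmetric_kl(posteriors[[ij[1]]], posteriors[[ij[2]]])
    interp <- substitutable_observations(kl)
    data.frame(track_id_1 = ids[ij[1]], track_id_2 = ids[ij[2]],
               kl_sym = kl, n_substitutable = interp$n_observations,
               interpretation = interp$interpretation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

as_ig_params <- function(x) {
  if (inherits(x, "invgamma_posterior"))
    return(list(a = x$shape_a, b = x$scale_b))
  if (is.list(x) && all(c("shape_a", "scale_b") %in% names(x)))
    return(list(a = x$shape_a, b = x$scale_b))
  stop("expected an 'invgamma_posterior' or a list with shape_a/scale_b",
       call. = FALSE)
}

check_same_variable <- function(p, q) {
  if (inherits(p, "invgamma_posterior") && inherits(q, "invgamma_posterior") &&
      !identical(p$variable, q$variable))
    stop("posteriors are over different variables (", p$variable, " vs ",
         q$variable, "); convert both to the same scale first",
         call. = FALSE)
  pa <- as_ig_params(p); qa <- as_ig_params(q)
  if (any(c(pa$a, pa$b, qa$a, qa$b) <= 0))
    stop("inverse-gamma parameters must be positive", call. = FALSE)
  invisible(TRUE)
}
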