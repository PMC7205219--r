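test_that("step extraction on hand-built trajectories", {
  traj <- make_trajectory(cbind(c(0, 1, 2, 3)))
  s <- extract_steps(traj)
  expect_equal(s$components, c(1, 1, 1))
  expect_equal(s$n_components, 3L)
  expect_equal(s$sum_sq, 3)

  traj2 <- make_trajectory(matrix(rnorm(10), 5, 2))
  expect_equal(extract_steps(traj2)$n_components, 8L)

  still <- make_trajectory(matrix(1, 4, 2))
  s0 <- extract_steps(still)
  expect_true(all(s0$components == 0))
  expect_equal(s0$sum_sq, 0)

  expect_error(extract_steps(make_trajectory(matrix(0, 1, 2))),
               "at least 2 frames")
  uneven <- make_trajectory(cbind(0:3))
  uneven$times <- c(0, 1, 2, 4)
  expect_error(extract_steps(uneven), "uniformly spaced")
})

test_that("conjugate update gives IG(a0 + N/2, b0 + S/2)", {
  s <- make_step_sample(rep(0.1, 8))
  post <- fit_variance_posterior(s)
  expect_equal(post$shape_a, 4)
  expect_equal(post$scale_b, 0.04)
  expect_identical(post$variable, "step_variance")

  post2 <- fit_variance_posterior(make_step_sample(0.5),
                                  prior_spec(3, 2))
  expect_equal(post2$shape_a, 3.5)
  expect_equal(post2$scale_b, 2.125)

  expect_error(fit_variance_posterior(make_step_sample(c(0, 0, 0))),
               "degenerate")
})

test_that("posterior density is proportional to prior x likelihood (grid Bayes oracle)", {
  x <- c(-0.12, 0.31, 0.05, -0.27, 0.18, 0.09)
  s <- make_step_sample(x)
  grid <- seq(0.005, 0.5, length.out = 400)
  for (pr in list(prior_spec(0, 0), prior_spec(2, 0.1))) {
    post <- fit_variance_posterior(s, pr)
    loglik <- vapply(grid, function(v)
      sum(dnorm(x, 0, sqrt(v), log = TRUE)), 0)
    logprior <- -(pr$a0 + 1) * log(grid) - pr$b0 / grid
    log_unnorm <- loglik + logprior
    log_closed <- dinvgamma(grid, post$shape_a, post$scale_b, log = TRUE)
    ratio <- log_unnorm - log_closed
    expect_lt(diff(range(ratio)), 1e-8)  # constant => proportional
  }
})

test_that("sufficient statistics are additive and updating is conjugate", {
  set.seed(31)
  x <- rnorm(40, sd = 0.2)
  s_all <- make_step_sample(x)
  doubled <- make_step_sample(c(x, x))
  p1 <- fit_variance_posterior(s_all, prior_spec(1, 0.5))
  p2 <- fit_variance_posterior(doubled, prior_spec(1, 0.5))
  expect_equal(p2$shape_a - 1, 2 * (p1$shape_a - 1))
  expect_equal(p2$scale_b - 0.5, 2 * (p1$scale_b - 0.5))

  # sequential update on halves == single update on the whole set
  h1 <- fit_variance_posterior(make_step_sample(x[1:20]))
  h2 <- fit_variance_posterior(make_step_sample(x[21:40]),
                               prior_spec(h1$shape_a, h1$scale_b))
  expect_identical(h2$shape_a, p_whole <- fit_variance_posterior(s_all)$shape_a)
  expect_identical(h2$scale_b, fit_variance_posterior(s_all)$scale_b)
})

test_that("variance-to-diffusivity transform divides the scale by 2*dt", {
  s <- make_step_sample(rep(0.1, 8), dt = 1)
  post <- to_diffusivity_posterior(fit_variance_posterior(s))
  expect_equal(post$shape_a, 4)
  expect_equal(post$scale_b, 0.02)
  expect_identical(post$variable, "diffusivity")
  expect_error(to_diffusivity_posterior(post), "already")

  s2 <- make_step_sample(rep(0.1, 8), dt = 0.5)
  expect_equal(to_diffusivity_posterior(fit_variance_posterior(s2))$scale_b,
               0.04)
})

test_that("the transform matches the inverse-gamma scaling property on draws", {
  set.seed(32)
  a <- 7; b <- 0.3; dt <- 0.25
  draws <- rinvgamma(1e5, a, b) / (2 * dt)
  p <- suppressWarnings(
    ks.test(draws, function(q) pinvgamma(q, a, b / (2 * dt))))$p.value
  expect_gt(p, 0.01)
})

test_that("posterior mode is b/(a+1) and equals the density argmax", {
  s <- make_step_sample(rep(0.1, 8))
  post <- to_diffusivity_posterior(fit_variance_posterior(s))
  expect_equal(posterior_mode(post), 0.004)
  expect_equal(posterior_mode(structure(list(shape_a = 1, scale_b = 2),
                                        class = "invgamma_posterior")), 1)
  for (a in c(0.5, 1, 5, 50)) {
    for (b in c(0.01, 1, 100)) {
      argmax <- stats::optimize(function(x) dinvgamma(x, a, b, log = TRUE),
                                c(b / (a + 1) / 20, b / (a + 1) * 20),
                                maximum = TRUE, tol = 1e-12)$maximum
      expect_lt(abs(argmax - b / (a + 1)) / (b / (a + 1)), 1e-6)
    }
  }
})

test_that("posterior mean and interval agree with Monte-Carlo draws", {
  set.seed(33)
  post <- structure(list(shape_a = 6, scale_b = 0.5,
                         variable = "diffusivity", dt = 1, n_dim = 2),
                    class = "invgamma_posterior")
  expect_equal(posterior_mean(post), 0.1)
  draws <- rinvgamma(1e5, 6, 0.5)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.1), 3 * se)
  ci <- posterior_interval(post, 0.9)
  expect_lt(abs(mean(draws >= ci["lower"] & draws <= ci["upper"]) - 0.9),
            0.01)
})

test_that("percent error is the magnitude of the relative deviation", {
  expect_equal(percent_error(0.1, 0.1), 0)
  expect_equal(percent_error(0.115, 0.1), 15)
  expect_equal(percent_error(0.085, 0.1), 15)
  expect_error(percent_error(1, 0), "true_d")
})

test_that("inverse-gamma density integrates to one", {
  for (p in list(c(0.5, 0.2), c(4, 0.04), c(50, 100))) {
    z <- integrate(dinvgamma, 0, Inf, a = p[1], b = p[2],
                   rel.tol = 1e-9)$value
    expect_lt(abs(z - 1), 1e-6)
  }
})
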