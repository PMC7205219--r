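test_that("table specs validate their grids", {
  expect_error(error_table_spec(lengths = c(100, 10)), "lengths")
  expect_error(error_table_spec(loc_errors = c(0.1, 0.1)), "loc_errors")
  expect_error(error_table_spec(diffusivity = 0), "diffusivity")
  expect_error(kl_table_spec(ratios = c(-1, 2)), "ratios")
})

test_that("error tables are reproducible and shaped by their grids", {
  spec <- error_table_spec(diffusivity = 0.1, lengths = c(10, 50),
                           loc_errors = c(0, 0.1), n_replicates = 50,
                           master_seed = 9)
  t1 <- error_table(spec)
  t2 <- error_table(spec)
  expect_identical(t1$values, t2$values)
  expect_equal(dim(t1$values), c(2, 2))
  expect_true(all(t1$values >= 0))
  expect_true(all(is.finite(t1$values)))
  expect_equal(t1$n_excluded, 0L)
})

test_that("estimation error is non-increasing in trajectory length without noise", {
  tab <- error_table(error_table_spec(diffusivity = 0.1,
                                      lengths = c(10, 100, 1000),
                                      loc_errors = 0, n_replicates = 200,
                                      master_seed = 5))
  v <- tab$values[, 1]
  se <- tab$standard_errors[, 1]
  for (i in 1:2)
    expect_lt(v[i + 1] - v[i], 3 * sqrt(se[i]^2 + se[i + 1]^2))
  # and clearly decreasing from 10 to 1000 steps
  expect_lt(v[3], v[1])
})

test_that("long noisy trajectories approach the localization bias floor", {
  # mode -> D + sd^2/dt, so |%err| -> 100 * sd^2 / (D dt) = 10%
  tab <- error_table(error_table_spec(diffusivity = 0.1, lengths = 10000,
                                      loc_errors = 0.1,
                                      n_replicates = 200,
                                      master_seed = 6))
  expect_lt(abs(tab$values[1, 1] - 10), 3 * tab$standard_errors[1, 1])
})

test_that("KL table gradients follow separation and trajectory length", {
  tab <- kl_table(kl_table_spec(base_diffusivity = 0.1, ratios = c(1, 5),
                                lengths = c(10, 100, 1000),
                                n_replicates = 200, master_seed = 7))
  expect_true(all(tab$values >= 0))
  # same length, bigger ratio => more distinguishable
  expect_true(all(tab$values[2, ] > tab$values[1, ]))
  # fixed ratio != 1: divergence grows with length
  expect_true(all(diff(tab$values[2, ]) > 0))
  # ratio 1 floor shrinks with length
  expect_lt(tab$values[1, 3], tab$values[1, 1])
  # qualitative Fig-6 gradient: extreme corners differ by >= 10x
  expect_gt(tab$values[2, 3], 10 * tab$values[1, 1])
})

test_that("KL divergence is symmetric in the diffusivity ratio", {
  t_up <- kl_table(kl_table_spec(base_diffusivity = 0.1, ratios = 2,
                                 lengths = 100, n_replicates = 400,
                                 master_seed = 8))
  t_dn <- kl_table(kl_table_spec(base_diffusivity = 0.1, ratios = 0.5,
                                 lengths = 100, n_replicates = 400,
                                 master_seed = 88))
  se <- sqrt(t_up$standard_errors[1, 1]^2 + t_dn$standard_errors[1, 1]^2)
  expect_lt(abs(t_up$values[1, 1] - t_dn$values[1, 1]), 3 * se)
})

test_that("standard errors shrink as the replicate count grows", {
  ses <- sapply(c(50, 200, 800), function(n)
    error_table(error_table_spec(diffusivity = 0.1, lengths = 100,
                                 loc_errors = 0, n_replicates = n,
                                 master_seed = 10))$standard_errors[1, 1])
  # each 4x increase should halve the SE, within 20%
  expect_lt(abs(ses[1] / ses[2] - 2), 0.4)
  expect_lt(abs(ses[2] / ses[3] - 2), 0.4)
})

test_that("bilinear interpolation is exact at nodes and linear between them", {
  tab <- error_table(error_table_spec(diffusivity = 0.1,
                                      lengths = c(10, 100),
                                      loc_errors = c(0, 0.1),
                                      n_replicates = 50, master_seed = 11))
  expect_equal(predict_error(tab, 10, 0), tab$values[1, 1])
  expect_equal(predict_error(tab, 100, 0.1), tab$values[2, 2])
  expect_equal(predict_error(tab, 55, 0),
               mean(tab$values[, 1]))
  expect_equal(predict_error(tab, 10, 0.05),
               mean(tab$values[1, ]))
  expect_error(predict_error(tab, 5000, 0), "outside the table grid")
})

test_that("tables round-trip through long-format CSV", {
  et <- error_table(error_table_spec(diffusivity = 0.1,
                                     lengths = c(10, 100),
                                     loc_errors = c(0, 0.1),
                                     n_replicates = 30, master_seed = 12))
  f <- tempfile(fileext = ".csv")
  write_table_csv(et, f)
  back <- read_table_csv(f)
  expect_s3_class(back, "error_table")
  expect_equal(back$values, et$values)
  expect_equal(back$standard_errors, et$standard_errors)
  expect_equal(back$spec$diffusivity, et$spec$diffusivity)

  kt <- kl_table(kl_table_spec(ratios = c(1, 2), lengths = c(10, 50),
                               n_replicates = 30, master_seed = 13))
  f2 <- tempfile(fileext = ".csv")
  write_table_csv(kt, f2)
  back2 <- read_table_csv(f2)
  expect_s3_class(back2, "kl_table")
  expect_equal(back2$values, kt$values)
})

test_that("FBM error tables are generated through the same engine", {
  tab <- error_table(error_table_spec(diffusivity = 0.1, lengths = 100,
                                      loc_errors = 0, n_replicates = 100,
                                      hurst = 0.375, master_seed = 14))
  expect_true(is.finite(tab$values[1, 1]))
  expect_gt(tab$values[1, 1], 0)
})
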